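#' Alpha-diversity indices
#'
#' Per-sample community summaries computed on raw counts (no rarefaction):
#' observed richness, the Chao1 estimator, Shannon entropy (natural log by
#' default), the Gini--Simpson index `1 - sum(p^2)` and Good's coverage
#' `1 - F1/N`.
#'
#' `chao1()` uses the classic estimator `S_obs + F1^2 / (2 F2)` and the
#' bias-corrected fallback `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` when there
#' are no doubletons (`F1`, `F2`: singleton and doubleton counts). It
#' requires integer counts.
#'
#' @param counts Non-negative numeric vector of taxon counts for one sample.
#' @param base Logarithm base for `shannon()` (default natural log).
#' @return A scalar.
#' @name alpha_indices
NULL

#' @rdname alpha_indices
#' @export
observed_otus <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts > 0)
}

#' @rdname alpha_indices
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0))
  if (any(counts != round(counts))) {
    cw_abort("Chao1 requires integer counts", "cwevalkit_domain_error")
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname alpha_indices
#' @export
shannon <- function(counts, base = exp(1)) {
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) cw_abort("empty sample", "cwevalkit_domain_error")
  p <- counts[counts > 0] / n
  -sum(p * log(p, base = base))
}

#' @rdname alpha_indices
#' @export
simpson <- function(counts) {
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) cw_abort("empty sample", "cwevalkit_domain_error")
  p <- counts / n
  1 - sum(p^2)
}

#' @rdname alpha_indices
#' @export
goods_coverage <- function(counts) {
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) cw_abort("empty sample", "cwevalkit_domain_error")
  1 - sum(counts == 1) / n
}

#' Per-sample alpha-diversity table
#'
#' @param x A count table (see [validate_count_table()]).
#' @param groups Optional tibble (`sample`, `group`); adds a `group` column.
#' @param base Logarithm base for Shannon.
#' @return A tibble with one row per sample: `sample`, optional `group`,
#'   `otus`, `chao1`, `shannon`, `simpson`, `coverage` (fraction).
#' @export
alpha_table <- function(x, groups = NULL, base = exp(1)) {
  x <- validate_count_table(x)
  samples <- count_table_samples(x)
  out <- purrr::map_dfr(samples, function(s) {
    v <- x[[s]]
    tibble(sample = s, otus = observed_otus(v), chao1 = chao1(v),
           shannon = shannon(v, base), simpson = simpson(v),
           coverage = goods_coverage(v))
  })
  if (!is.null(groups)) {
    cw_assert_cols(groups, c("sample", "group"), "sample groups")
    out <- dplyr::left_join(out, as_tibble(groups), by = "sample") |>
      dplyr::relocate("group", .after = "sample")
    if (anyNA(out$group)) {
      cw_abort("every sample must have a group", "cwevalkit_schema_error")
    }
  }
  out
}

# Compact letter display from a symmetric logical "significantly different"
# matrix: letters are maximal cliques of the NOT-different graph, ordered by
# descending group mean.
compact_letters <- function(signif_mat, means) {
  g <- igraph::graph_from_adjacency_matrix(!signif_mat, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  groups <- rownames(signif_mat)
  # order cliques by the best (largest) mean they contain
  best <- vapply(cliques, function(cl) max(means[groups[as.integer(cl)]]),
                 numeric(1))
  cliques <- cliques[order(-best)]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(cliques)) {
    members <- groups[as.integer(cliques[[i]])]
    letters_out[members] <- paste0(letters_out[members], letters[i])
  }
  letters_out
}

# One-way ANOVA + Tukey HSD letters for `value` by `group`; returns a named
# character vector of letters, or NULL when groups lack replication.
tukey_letters <- function(value, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) < 2)) return(NULL)
  if (sd(value) == 0) {
    return(setNames(rep("a", nlevels(group)), levels(group)))
  }
  fit <- aov(value ~ group, data = data.frame(value = value, group = group))
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  lv <- levels(group)
  sig <- matrix(FALSE, nlevels(group), nlevels(group),
                dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    s <- tk[i, "p adj"] < alpha
    sig[a, b] <- s; sig[b, a] <- s
  }
  means <- tapply(value, group, mean)
  compact_letters(sig, means)
}

#' Group summary of alpha diversity with significance letters
#'
#' Per-group means of every index, with compact-letter displays from one-way
#' ANOVA followed by Tukey's HSD at `alpha` (groups sharing a letter do not
#' differ significantly). Letters require >= 2 replicates in every group and
#' are omitted otherwise.
#'
#' @param x A count table.
#' @param groups Tibble (`sample`, `group`).
#' @param alpha Significance level (default 0.05).
#' @param base Logarithm base for Shannon.
#' @return A tibble with one row per group: mean indices, plus
#'   `<index>_letter` columns when replication allows.
#' @export
alpha_summary <- function(x, groups, alpha = 0.05, base = exp(1)) {
  at <- alpha_table(x, groups, base)
  idx <- c("otus", "chao1", "shannon", "simpson", "coverage")
  means <- at |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(idx), mean), n = dplyr::n())
  for (v in idx) {
    lt <- tukey_letters(at[[v]], at$group, alpha)
    if (!is.null(lt)) means[[paste0(v, "_letter")]] <- lt[means$group]
  }
  means
}
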