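#' Bray--Curtis dissimilarity between samples
#'
#' `d(u, v) = 1 - 2 sum(min(u_i, v_i)) / (sum u + sum v)` over taxa, computed
#' on relative abundances so every sample contributes equally regardless of
#' sequencing depth.
#'
#' @param x A relative-abundance table (columns must each sum to 1 within
#'   1e-6; see [relative_abundance()]).
#' @return A labelled symmetric matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
bray_curtis <- function(x) {
  x <- validate_count_table(x)
  samples <- count_table_samples(x)
  mat <- t(as.matrix(x[samples]))
  rownames(mat) <- samples
  sums <- rowSums(mat)
  bad <- samples[abs(sums - 1) > 1e-6]
  if (length(bad) > 0) {
    cw_abort(sprintf("sample(s) not normalized to 1: %s",
                     paste(bad, collapse = ", ")),
             class = "cwevalkit_domain_error")
  }
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

#' UPGMA clustering of a distance matrix
#'
#' Agglomerative clustering with size-weighted average linkage: the closest
#' pair is merged at height d/2 (so leaf-to-root path lengths are equal and
#' the tree is ultrametric), and the new cluster's distance to any other is
#' the size-weighted mean of its members' distances. Ties are broken by
#' lexicographic label order.
#'
#' @param d A symmetric distance matrix (labelled) or `dist` object with
#'   >= 2 leaves.
#' @return A list of class `cw_upgma`: `phylo` (an [ape::as.phylo()] tree
#'   with branch lengths), `merges` (tibble `step`, `height`) and `labels`.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  }
  if (nrow(d) < 2) cw_abort("need >= 2 leaves", "cwevalkit_domain_error")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # as.phylo() halves hclust heights itself, giving merge heights of d/2
  structure(
    list(phylo = ape::as.phylo(hc),
         merges = tibble(step = seq_along(hc$height),
                         height = hc$height / 2),
         labels = hc$labels),
    class = "cw_upgma"
  )
}

#' Write a UPGMA tree as Newick
#'
#' @param tree A `cw_upgma` object.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cw_upgma"))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' Leaf-to-root path lengths of a UPGMA tree
#'
#' For an ultrametric tree all depths are equal; exposed so the property is
#' checkable.
#'
#' @param tree A `cw_upgma` object.
#' @return Named numeric vector of root-to-leaf distances.
#' @export
leaf_depths <- function(tree) {
  ph <- tree$phylo
  nt <- length(ph$tip.label)
  depth <- ape::node.depth.edgelength(ph)
  setNames(depth[seq_len(nt)], ph$tip.label)
}

#' Filter to dominant taxa
#'
#' Keeps taxa whose relative abundance exceeds `threshold` in at least one
#' sample; the rest are pooled into a single `"other"` row, so columns still
#' sum to 1.
#'
#' @param x A relative-abundance table.
#' @param threshold Fraction in \[0, 1) (default 0.001, i.e. the 0.1 percent
#'   dominance convention).
#' @return A filtered relative-abundance table.
#' @export
dominant_taxa <- function(x, threshold = 0.001) {
  stopifnot(threshold >= 0, threshold < 1)
  x <- validate_count_table(x)
  samples <- count_table_samples(x)
  keep <- apply(as.matrix(x[samples]), 1, max) > threshold
  kept <- x[keep, , drop = FALSE]
  if (any(!keep)) {
    pooled <- dplyr::bind_cols(
      tibble(taxon_id = "other", lineage = "other"),
      as_tibble(as.list(colSums(as.matrix(x[!keep, samples, drop = FALSE]))))
    )
    kept <- dplyr::bind_rows(kept, pooled)
  }
  kept
}

# midrank Kruskal-Wallis H with tie correction
kw_statistic <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h / corr else 0
}

#' Kruskal--Wallis rank test
#'
#' Midranks with tie correction. For total n <= 8 the p-value is exact,
#' computed by enumerating every permutation of the observations across the
#' group-size pattern; otherwise the chi-square approximation with
#' `df = groups - 1` is used. Identical values in all groups give H = 0,
#' p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return A tibble with `H`, `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) == 0)) {
    cw_abort("need >= 2 non-empty groups", "cwevalkit_domain_error")
  }
  n <- length(values)
  df <- nlevels(groups) - 1
  if (length(unique(values)) == 1) {
    return(tibble(H = 0, df = df, p_value = 1, method = "degenerate"))
  }
  h <- kw_statistic(values, groups)
  if (n <= 8) {
    perms <- permutations_of(n)
    hs <- apply(perms, 1, function(ix) kw_statistic(values[ix], groups))
    p <- mean(hs >= h - 1e-12)
    tibble(H = h, df = df, p_value = p, method = "exact_permutation")
  } else {
    tibble(H = h, df = df, p_value = pchisq(h, df, lower.tail = FALSE),
           method = "chisq")
  }
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# regularized two-class linear discriminant axis on rows = samples
lda_axis <- function(xa, xb) {
  mu_a <- colMeans(xa)
  mu_b <- colMeans(xb)
  ca <- if (nrow(xa) > 1) stats::cov(xa) else matrix(0, ncol(xa), ncol(xa))
  cb <- if (nrow(xb) > 1) stats::cov(xb) else matrix(0, ncol(xb), ncol(xb))
  pool <- ((nrow(xa) - 1) * ca + (nrow(xb) - 1) * cb) /
    max(nrow(xa) + nrow(xb) - 2, 1)
  ridge <- max(mean(diag(pool)), 1) * 1e-4
  w <- solve(pool + diag(ridge, ncol(pool)), mu_a - mu_b)
  nw <- sqrt(sum(w^2))
  if (nw == 0) w else w / nw
}

#' LEfSe-style differential feature detection
#'
#' A seeded, documented variant of the LDA-effect-size procedure:
#' (1) relative abundances are scaled to one million;
#' (2) features are screened with an (unadjusted) Kruskal--Wallis test at
#' `alpha`;
#' (3) for each surviving feature, a one-vs-rest two-class comparison against
#' its highest-mean group is summarized over `boot` bootstrap resamples by a
#' regularized linear discriminant fitted on all surviving features: per
#' resample, `effect(f) = |w_f * s + delta_f| / 2`, where `w` is the unit
#' discriminant axis, `s` the projected class-mean separation and `delta_f`
#' the raw class-mean difference of the feature; the reported
#' `lda_score = log10(max(mean effect, 1))`.
#' Features with `lda_score >= lda_threshold` are reported with their
#' enriched group. The subclass-consistency step of the original procedure
#' is not implemented (no subclass structure here).
#'
#' @param x A count table.
#' @param groups Tibble (`sample`, `group`); >= 2 groups with >= 2 replicates
#'   each.
#' @param alpha Screen significance level (default 0.05).
#' @param lda_threshold Minimum log10 effect size (default 2).
#' @param boot Bootstrap resamples (default 30).
#' @param seed Integer seed.
#' @return A tibble `taxon`, `enriched_group`, `kw_p`, `lda_score`, sorted by
#'   descending score.
#' @export
lefse_like <- function(x, groups, alpha = 0.05, lda_threshold = 2,
                       boot = 30, seed = 1) {
  x <- validate_count_table(x)
  cw_assert_cols(groups, c("sample", "group"), "sample groups")
  samples <- count_table_samples(x)
  grp <- setNames(groups$group, groups$sample)[samples]
  if (anyNA(grp)) cw_abort("every sample needs a group",
                           "cwevalkit_schema_error")
  sizes <- table(grp)
  if (length(sizes) < 2 || any(sizes < 2)) {
    cw_abort("need >= 2 groups with >= 2 replicates each",
             class = "cwevalkit_domain_error")
  }
  rel <- relative_abundance(x)
  mat <- as.matrix(rel[samples]) * 1e6  # features x samples
  rownames(mat) <- rel$taxon_id

  kw_p <- apply(mat, 1, function(v) {
    if (length(unique(v)) == 1) return(1)
    kruskal_wallis(v, grp)$p_value
  })
  surv <- which(kw_p < alpha)
  empty <- tibble(taxon = character(), enriched_group = character(),
                  kw_p = numeric(), lda_score = numeric())
  if (length(surv) == 0) return(empty)

  sm <- t(mat[surv, , drop = FALSE])  # samples x surviving features
  gmeans <- apply(sm, 2, function(v) tapply(v, grp, mean))
  top_group <- rownames(gmeans)[apply(gmeans, 2, which.max)]

  set.seed(seed)
  scores <- setNames(numeric(ncol(sm)), colnames(sm))
  for (g in unique(top_group)) {
    ia <- which(grp == g)
    ib <- which(grp != g)
    eff <- matrix(0, boot, ncol(sm))
    for (b in seq_len(boot)) {
      sa <- sm[sample(ia, length(ia), replace = TRUE), , drop = FALSE]
      sb <- sm[sample(ib, length(ib), replace = TRUE), , drop = FALSE]
      w <- lda_axis(sa, sb)
      delta <- colMeans(sa) - colMeans(sb)
      s <- sum(w * delta)
      eff[b, ] <- abs(w * s + delta) / 2
    }
    f_idx <- which(top_group == g)
    scores[f_idx] <- log10(pmax(colMeans(eff)[f_idx], 1))
  }
  out <- tibble(taxon = colnames(sm), enriched_group = top_group,
                kw_p = unname(kw_p[surv]), lda_score = unname(scores))
  out |>
    dplyr::filter(.data$lda_score >= lda_threshold) |>
    dplyr::arrange(dplyr::desc(.data$lda_score))
}

#' Between-group shifts in relative abundance
#'
#' Per-taxon difference of mean relative abundance (in percentage points)
#' between two groups, with a two-sided Wilcoxon rank-sum p-value per taxon
#' and Benjamini--Hochberg adjustment across taxa. Differences sum to zero
#' across taxa (compositional identity).
#'
#' @param x A count table.
#' @param groups Tibble (`sample`, `group`).
#' @param group_a,group_b Group labels to compare (a minus b).
#' @param rank Optional `"phylum"`/`"genus"` aggregation before comparison.
#' @return A tibble `taxon`, `mean_a`, `mean_b`, `delta` (percentage points),
#'   `p_value`, `q_value`.
#' @export
abundance_shift <- function(x, groups, group_a, group_b, rank = NULL) {
  x <- validate_count_table(x)
  if (!is.null(rank)) x <- aggregate_lineage(x, rank)
  cw_assert_cols(groups, c("sample", "group"), "sample groups")
  sa <- groups$sample[groups$group == group_a]
  sb <- groups$sample[groups$group == group_b]
  if (length(sa) == 0 || length(sb) == 0) {
    cw_abort("both groups must be present", "cwevalkit_domain_error")
  }
  rel <- relative_abundance(x)
  ma <- as.matrix(rel[sa]) * 100
  mb <- as.matrix(rel[sb]) * 100
  p <- vapply(seq_len(nrow(rel)), function(i) {
    a <- ma[i, ]; b <- mb[i, ]
    if (length(unique(c(a, b))) == 1) return(1)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  tibble(
    taxon = rel$taxon_id,
    mean_a = rowMeans(ma), mean_b = rowMeans(mb),
    delta = rowMeans(ma) - rowMeans(mb),
    p_value = p, q_value = p.adjust(p, "BH")
  )
}
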