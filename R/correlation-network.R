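#' Spearman rank correlation with small-sample exact p-value
#'
#' Rho is the Pearson correlation of midranks. For n <= 7 the two-sided
#' p-value is exact, from enumeration of all n! rank permutations; for larger
#' n the t approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom is used.
#'
#' @param x,y Paired numeric vectors (n >= 3, neither constant).
#' @return A tibble with `rho`, `p_value`, `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    cw_abort("need >= 3 paired observations", "cwevalkit_domain_error")
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    cw_abort("constant vector: Spearman correlation undefined",
             class = "cwevalkit_domain_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  if (n <= 7) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    tibble(rho = rho, p_value = p, method = "exact_permutation")
  } else {
    if (abs(rho) >= 1) {
      return(tibble(rho = rho, p_value = 0, method = "t_approximation"))
    }
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    tibble(rho = rho, p_value = 2 * pt(-abs(tstat), n - 2),
           method = "t_approximation")
  }
}

#' Taxon-by-variable correlation grid
#'
#' Correlates every taxon's relative abundance with every external variable
#' (pollutant removal rate or concentration) over shared samples, adjusts
#' p-values across the whole grid with Benjamini--Hochberg, and flags
#' significance at raw p < 0.05 (the field convention; the adjusted `q` is
#' reported alongside).
#'
#' @param taxa A relative-abundance (or count) table: `taxon_id`, `lineage`,
#'   one column per sample.
#' @param variables A tibble with a `sample` column and one numeric column
#'   per variable; samples are matched by name (>= 3 shared).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A tibble `taxon`, `variable`, `rho`, `p_value`, `q_value`,
#'   `significant`.
#' @export
correlation_table <- function(taxa, variables,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  taxa <- validate_count_table(taxa)
  variables <- as_tibble(variables)
  cw_assert_cols(variables, "sample", "variables table")
  shared <- intersect(count_table_samples(taxa), variables$sample)
  if (length(shared) < 3) {
    cw_abort("need >= 3 shared samples", "cwevalkit_domain_error")
  }
  vmat <- variables[match(shared, variables$sample), , drop = FALSE]
  vars <- setdiff(names(vmat), "sample")
  grid <- tidyr::expand_grid(taxon = taxa$taxon_id, variable = vars)
  res <- purrr::pmap_dfr(grid, function(taxon, variable) {
    a <- unlist(taxa[taxa$taxon_id == taxon, shared], use.names = FALSE)
    v <- vmat[[variable]]
    if (method == "spearman") {
      s <- spearman_cor(a, v)
      tibble(taxon = taxon, variable = variable, rho = s$rho,
             p_value = s$p_value)
    } else {
      ct <- stats::cor.test(a, v, method = "pearson")
      tibble(taxon = taxon, variable = variable,
             rho = unname(ct$estimate), p_value = ct$p.value)
    }
  })
  res |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, "BH"),
                  significant = .data$p_value < 0.05)
}

#' Build a signed taxon--pollutant network
#'
#' A bipartite network whose edges are the correlation pairs passing
#' `|rho| >= rho_min` and `p < alpha`. Node sizes carry mean relative
#' abundance (taxa) or mean concentration (variables); edge sign is the sign
#' of rho, thickness its magnitude. Deterministic.
#'
#' @param cor_tbl Output of [correlation_table()].
#' @param node_sizes Tibble (`name`, `size`) covering nodes; missing nodes
#'   get size 1.
#' @param rho_min Minimum absolute correlation (default 0.6).
#' @param alpha Maximum raw p-value (default 0.05).
#' @return A list of class `cw_network` with `nodes`
#'   (`name`, `kind`, `size`) and `edges` (`from`, `to`, `rho`, `p_value`,
#'   `sign`).
#' @export
build_network <- function(cor_tbl, node_sizes = NULL, rho_min = 0.6,
                          alpha = 0.05) {
  cw_assert_cols(cor_tbl, c("taxon", "variable", "rho", "p_value"),
                 "correlation table")
  edges <- cor_tbl |>
    dplyr::filter(abs(.data$rho) >= rho_min, .data$p_value < alpha) |>
    dplyr::transmute(from = .data$taxon, to = .data$variable,
                     rho = .data$rho, p_value = .data$p_value,
                     sign = ifelse(.data$rho >= 0, "positive", "negative"))
  nodes <- dplyr::bind_rows(
    tibble(name = unique(cor_tbl$taxon), kind = "taxon"),
    tibble(name = unique(cor_tbl$variable), kind = "pollutant")
  )
  nodes$size <- 1
  if (!is.null(node_sizes)) {
    cw_assert_cols(node_sizes, c("name", "size"), "node sizes")
    i <- match(nodes$name, node_sizes$name)
    nodes$size <- ifelse(is.na(i), 1, node_sizes$size[i])
  }
  structure(list(nodes = nodes, edges = edges), class = "cw_network")
}

#' Write a network as GraphML and edge-list TSV
#'
#' @param net A `cw_network`.
#' @param graphml_path,edges_path Output paths (either may be `NULL` to
#'   skip).
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  stopifnot(inherits(net, "cw_network"))
  if (!is.null(edges_path)) readr::write_tsv(net$edges, edges_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(net)
}
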