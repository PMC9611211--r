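#' @export
print.cw_factor_model <- function(x, ...) {
  cat(sprintf("Factor model: %d of %d components retained (Kaiser)\n",
              x$k, length(x$eigenvalues)))
  cat(sprintf("Cumulative explained variance: %.3f%%\n",
              x$cumulative_pct[x$k]))
  if (!is.null(x$loadings_rotated)) {
    cat("Rotated loadings:\n")
    print(round(x$loadings_rotated, 3))
  }
  invisible(x)
}

#' @export
print.cw_score_result <- function(x, ...) {
  cat("Composite treatment scoring\n")
  cat(sprintf("  KMO %.3f | Bartlett chi2 %.2f (df %d, p %.3g) | n = %d\n",
              x$diagnostics$kmo, x$diagnostics$chisq, x$diagnostics$df,
              x$diagnostics$p_value, x$diagnostics$n_obs))
  cat(sprintf("  %d factor(s); factor weights: %s\n", x$model$k,
              paste(sprintf("%.3f", x$factor_weights$weight),
                    collapse = ", ")))
  cat("Indicator weights:\n")
  print(x$indicator_weights)
  invisible(x)
}

#' Tidy and glance methods
#'
#' `tidy()` on a factor model returns the long loading table (one row per
#' indicator x factor, unrotated and rotated values side by side); on a score
#' result it returns the per-(system, day) composite scores. `glance()`
#' summarizes retention and adequacy diagnostics in one row.
#'
#' @param x A `cw_factor_model` or `cw_score_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name cw_tidiers
NULL

#' @rdname cw_tidiers
#' @export
tidy.cw_factor_model <- function(x, ...) {
  L <- x$loadings_unrotated
  out <- tibble(
    indicator = rep(rownames(L), times = ncol(L)),
    factor = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L)
  )
  if (!is.null(x$loadings_rotated)) {
    out$loading_rotated <- as.vector(x$loadings_rotated)
  }
  out
}

#' @rdname cw_tidiers
#' @export
glance.cw_factor_model <- function(x, ...) {
  tibble(
    k = x$k,
    p = length(x$eigenvalues),
    cumulative_variance_pct = x$cumulative_pct[x$k],
    total_ss_rotated = if (is.null(x$ss_loadings_rotated)) NA_real_
                       else sum(x$ss_loadings_rotated)
  )
}

#' @rdname cw_tidiers
#' @export
tidy.cw_score_result <- function(x, ...) x$scores

#' @rdname cw_tidiers
#' @export
glance.cw_score_result <- function(x, ...) {
  dplyr::bind_cols(x$diagnostics, tibble(k = x$model$k))
}

#' Variance-explained table of a factor model
#'
#' One row per component: eigenvalue, percentage of variance and cumulative
#' percentage, with the retained flag.
#'
#' @param m A `cw_factor_model`.
#' @return A tibble.
#' @export
variance_table <- function(m) {
  stopifnot(inherits(m, "cw_factor_model"))
  tibble(
    component = seq_along(m$eigenvalues),
    eigenvalue = m$eigenvalues,
    variance_pct = m$variance_pct,
    cumulative_pct = m$cumulative_pct,
    retained = seq_along(m$eigenvalues) <= m$k
  )
}
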