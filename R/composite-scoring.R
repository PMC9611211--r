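#' Pearson correlation matrix of removal indicators
#'
#' Reshapes a long removal table into observations x indicators and computes
#' the Pearson correlation matrix that factor analysis consumes. Observations
#' are (system, day) cells after averaging replicates (the default), or raw
#' (system, day, replicate) rows.
#'
#' @param x A removal table.
#' @param aggregate `"replicate_mean"` (default) averages replicates per
#'   (system, pollutant, day); `"none"` keeps replicate rows as observations.
#' @return A labelled p x p correlation matrix (class `cw_cormat`) with the
#'   observation count attached as attribute `"n_obs"`.
#' @export
correlation_matrix <- function(x, aggregate = c("replicate_mean", "none")) {
  aggregate <- match.arg(aggregate)
  x <- validate_removal_table(x)
  if (aggregate == "replicate_mean") {
    x <- x |>
      dplyr::group_by(.data$system, .data$pollutant, .data$day) |>
      dplyr::summarise(removal = mean(.data$removal), .groups = "drop") |>
      dplyr::mutate(replicate = 1L)
  }
  wide <- tidyr::pivot_wider(x, id_cols = c("system", "day", "replicate"),
                             names_from = "pollutant",
                             values_from = "removal")
  mat <- as.matrix(wide[, setdiff(names(wide),
                                  c("system", "day", "replicate"))])
  if (ncol(mat) < 2) {
    cw_abort("need >= 2 indicators for a correlation matrix",
             "cwevalkit_domain_error")
  }
  if (nrow(mat) < 3) {
    cw_abort("need >= 3 observations after aggregation",
             "cwevalkit_domain_error")
  }
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    cw_abort(sprintf("constant indicator(s): %s (correlation undefined)",
                     paste(colnames(mat)[sds == 0], collapse = ", ")),
             class = "cwevalkit_domain_error")
  }
  r <- cor(mat)
  structure(r, n_obs = nrow(mat), class = c("cw_cormat", class(r)))
}

#' Kaiser--Meyer--Olkin sampling adequacy
#'
#' KMO compares raw correlations with anti-image partial correlations:
#' `sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal entries, where the
#' partials `q_ij = -s_ij / sqrt(s_ii s_jj)` come from the inverse `S` of the
#' correlation matrix. Values above 0.6 conventionally justify factor
#' analysis.
#'
#' @param r A correlation matrix.
#' @return The overall KMO statistic in (0, 1\].
#' @export
kmo <- function(r) {
  r <- unclass(r)
  inv <- tryCatch(solve(r), error = function(e) {
    cw_abort(paste("correlation matrix is singular; consider removing a",
                   "collinear indicator"), "cwevalkit_domain_error")
  })
  q <- -inv / sqrt(outer(diag(inv), diag(inv)))
  off <- upper.tri(r) | lower.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix differs from the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * log(det(R))` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param r A correlation matrix.
#' @param n Number of observations used to estimate `r` (must exceed p).
#' @return A tibble with `chisq`, `df`, `p_value`.
#' @export
bartlett <- function(r, n = attr(r, "n_obs")) {
  r <- unclass(r)
  p <- ncol(r)
  if (is.null(n)) cw_abort("observation count n is required",
                           "cwevalkit_domain_error")
  if (n <= p) cw_abort("need n > p observations", "cwevalkit_domain_error")
  d <- det(r)
  if (d <= 0) cw_abort("correlation matrix has non-positive determinant",
                       "cwevalkit_domain_error")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  tibble(chisq = chisq, df = df, p_value = pchisq(chisq, df,
                                                  lower.tail = FALSE))
}

# flip column signs so each column's largest-|entry| is positive
# (ties broken by first index)
fix_loading_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Extract principal-component factors from a correlation matrix
#'
#' Eigendecomposition of the correlation matrix; unrotated loading column j
#' is `eigenvector_j * sqrt(lambda_j)` with signs fixed so each column's
#' largest-magnitude entry is positive. Retention follows the Kaiser
#' criterion (eigenvalue > 1) by default, or a fixed count.
#'
#' @param r A correlation matrix (e.g. from [correlation_matrix()]).
#' @param retain `"kaiser"` or an integer number of factors.
#' @return A `cw_factor_model`: eigenvalues, variance percentages, retained
#'   count `k` and the unrotated p x k loading matrix. Rotation fields are
#'   filled by [rotate_factors()].
#' @export
extract_factors <- function(r, retain = "kaiser") {
  rm_ <- unclass(r)
  eig <- eigen(rm_, symmetric = TRUE)
  lambda <- eig$values
  p <- ncol(rm_)
  k <- if (identical(retain, "kaiser")) sum(lambda > 1) else as.integer(retain)
  if (k < 1) {
    cw_abort("retention policy keeps no factors (no eigenvalue > 1)",
             class = "cwevalkit_domain_error")
  }
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(k)]), k)
  rownames(L) <- colnames(rm_)
  colnames(L) <- paste0("factor", seq_len(k))
  L <- fix_loading_signs(L)
  structure(
    list(
      eigenvalues = lambda,
      variance_pct = lambda / p * 100,
      cumulative_pct = cumsum(lambda / p * 100),
      k = k,
      loadings_unrotated = L,
      loadings_rotated = NULL,
      ss_loadings_rotated = NULL,
      n_obs = attr(r, "n_obs")
    ),
    class = "cw_factor_model"
  )
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the raw (non-Kaiser-normalized) varimax
#' criterion `sum_j [ sum_i l_ij^4 - (sum_i l_ij^2)^2 / p ]`. Columns of the
#' result are ordered by descending sum of squared loadings and sign-fixed as
#' in [extract_factors()]. A single column is returned unchanged.
#'
#' @param L A p x k loading matrix.
#' @param normalize Kaiser row-normalization before rotation (default FALSE).
#' @param eps Convergence tolerance passed to the rotation.
#' @return The rotated p x k matrix.
#' @export
varimax_rotation <- function(L, normalize = FALSE, eps = 1e-10) {
  if (ncol(L) == 1) return(L)
  k <- ncol(L)
  # the iteration can stall on symmetric saddle points (e.g. loadings at
  # exactly 45 degrees), so restart it from a fixed fan of orthogonal
  # rotations and keep the best criterion value
  starts <- list(diag(k))
  if (k == 2) {
    for (a in c(15, 30, 45, 60, 75) * pi / 180) {
      starts <- c(starts, list(matrix(c(cos(a), -sin(a), sin(a), cos(a)),
                                      2, 2)))
    }
  } else {
    for (s in 1:4) {
      starts <- c(starts,
                  list(qr.Q(qr(matrix(sin(seq_len(k * k) * s * 1.7), k)))))
    }
  }
  best <- NULL
  best_crit <- -Inf
  for (R0 in starts) {
    cand <- tryCatch(
      stats::varimax(L %*% R0, normalize = normalize, eps = eps),
      error = function(e) NULL
    )
    if (is.null(cand)) next
    Lc <- matrix(as.numeric(cand$loadings), nrow(L), k)
    crit <- varimax_criterion(Lc)
    if (crit > best_crit + 1e-12) {
      best_crit <- crit
      best <- Lc
    }
  }
  R <- best
  dimnames(R) <- dimnames(L)
  ord <- order(colSums(R^2), decreasing = TRUE)
  R <- R[, ord, drop = FALSE]
  colnames(R) <- paste0("factor", seq_len(ncol(R)))
  fix_loading_signs(R)
}

#' Varimax simplicity criterion
#'
#' @param L A loading matrix.
#' @return The scalar criterion value.
#' @export
varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(colSums(L^4) - colSums(L^2)^2 / p)
}

#' Apply varimax rotation to a factor model
#'
#' Fills `loadings_rotated` and `ss_loadings_rotated` (per-factor sums of
#' squared rotated loadings, the post-rotation explained variances).
#'
#' @param m A `cw_factor_model`.
#' @inheritParams varimax_rotation
#' @return The updated model.
#' @export
rotate_factors <- function(m, normalize = FALSE) {
  stopifnot(inherits(m, "cw_factor_model"))
  R <- varimax_rotation(m$loadings_unrotated, normalize = normalize)
  m$loadings_rotated <- R
  m$ss_loadings_rotated <- colSums(R^2)
  m
}

get_rotated <- function(m) {
  if (inherits(m, "cw_factor_model")) {
    if (is.null(m$loadings_rotated)) m <- rotate_factors(m)
    m$loadings_rotated
  } else {
    as.matrix(m)
  }
}

#' Factor weights from post-rotation explained variance
#'
#' Each retained factor's weight is its share of the explained variance after
#' rotation: `T_j = SS_j / sum(SS)` where `SS_j` is the column sum of squared
#' rotated loadings. On the published six-indicator loading matrix this gives
#' (0.5694, 0.4306), i.e. the printed 0.569 / 0.43.
#'
#' @param m A `cw_factor_model` (rotated on demand) or a rotated loading
#'   matrix.
#' @return A tibble with `factor`, `ss_loading`, `weight`; weights sum to 1.
#' @export
factor_weights <- function(m) {
  R <- get_rotated(m)
  ss <- colSums(R^2)
  tibble(factor = colnames(R) %||% paste0("factor", seq_along(ss)),
         ss_loading = unname(ss), weight = unname(ss / sum(ss)))
}

#' Indicator weights from rotated loadings and factor weights
#'
#' Default (`method = "normalized"`): each loading column is L1-normalized
#' into within-factor shares, and shares are combined with the factor
#' weights, `B_i = sum_j T_j * l_ij / sum_i l_ij`; the result sums to 1. The
#' `"literal"` method combines raw loadings, `B_i = sum_j T_j * l_ij`,
#' without normalization. Negative rotated loadings (after sign fixing)
#' trigger a warning and are used in absolute value.
#'
#' @param m A `cw_factor_model` or rotated loading matrix.
#' @param tw Factor weights tibble from [factor_weights()] (computed from `m`
#'   when omitted).
#' @param method `"normalized"` (default) or `"literal"`.
#' @return A tibble with `indicator`, `weight`.
#' @export
indicator_weights <- function(m, tw = factor_weights(m),
                              method = c("normalized", "literal")) {
  method <- match.arg(method)
  R <- get_rotated(m)
  if (any(R < 0)) {
    warn("negative rotated loadings; using absolute values for weighting")
    R <- abs(R)
  }
  tvec <- tw$weight
  if (length(tvec) != ncol(R)) {
    cw_abort("factor weight length does not match loading columns",
             class = "cwevalkit_domain_error")
  }
  if (method == "normalized") {
    csum <- colSums(R)
    if (any(csum == 0)) cw_abort("zero loading column sum",
                                 "cwevalkit_domain_error")
    B <- as.vector(sweep(R, 2, csum, `/`) %*% tvec)
  } else {
    B <- as.vector(R %*% tvec)
  }
  tibble(indicator = rownames(R) %||% paste0("ind", seq_len(nrow(R))),
         weight = B)
}

#' Composite treatment score
#'
#' The weighted sum `E = sum_i A_i B_i` of removal fractions `A_i` with
#' indicator weights `B_i`. With normalized weights and fractional removals,
#' `E` lies in \[0, 1\].
#'
#' @param removals Numeric vector of removal fractions.
#' @param weights Numeric vector of indicator weights (same length), or an
#'   [indicator_weights()] tibble.
#' @return The scalar score.
#' @export
composite_score <- function(removals, weights) {
  if (is.data.frame(weights)) weights <- weights$weight
  if (length(removals) != length(weights)) {
    cw_abort("removals and weights must have equal length",
             class = "cwevalkit_domain_error")
  }
  if (any(removals < 0 | removals > 1)) {
    cw_abort("removals must lie in [0, 1]", "cwevalkit_range_error")
  }
  sum(removals * weights)
}

#' Composite score series per system and day
#'
#' @param x A removal table.
#' @param w An [indicator_weights()] tibble covering every pollutant in `x`.
#' @return A tibble with `system`, `day`, `E`.
#' @export
score_series <- function(x, w) {
  x <- validate_removal_table(x)
  missing <- setdiff(unique(x$pollutant), w$indicator)
  if (length(missing) > 0) {
    cw_abort(sprintf("no weight for pollutant(s): %s",
                     paste(missing, collapse = ", ")),
             class = "cwevalkit_domain_error")
  }
  x |>
    dplyr::group_by(.data$system, .data$pollutant, .data$day) |>
    dplyr::summarise(removal = mean(.data$removal), .groups = "drop") |>
    dplyr::left_join(w, by = c(pollutant = "indicator")) |>
    dplyr::group_by(.data$system, .data$day) |>
    dplyr::summarise(E = sum(.data$removal * .data$weight),
                     .groups = "drop") |>
    dplyr::arrange(.data$system, .data$day)
}

#' Full composite-scoring pipeline
#'
#' Runs correlation -> KMO / Bartlett diagnostics (reported, and a warning is
#' raised when KMO <= 0.6) -> eigendecomposition with Kaiser retention ->
#' varimax rotation -> factor and indicator weights -> per-(system, day)
#' composite scores. Deterministic for a fixed input table.
#'
#' @param x A removal table.
#' @param aggregate Observation policy, see [correlation_matrix()].
#' @param retain Factor retention, see [extract_factors()].
#' @param eq3 Indicator-weight method, see [indicator_weights()].
#' @return A list of class `cw_score_result` with elements `cormat`,
#'   `diagnostics` (tibble: kmo, chisq, df, p_value, n_obs), `model`,
#'   `factor_weights`, `indicator_weights`, `scores`.
#' @export
score_pipeline <- function(x, aggregate = c("replicate_mean", "none"),
                           retain = "kaiser",
                           eq3 = c("normalized", "literal")) {
  aggregate <- match.arg(aggregate)
  eq3 <- match.arg(eq3)
  r <- correlation_matrix(x, aggregate)
  kmo_v <- kmo(r)
  if (kmo_v <= 0.6) {
    warn(sprintf("KMO = %.3f <= 0.6: sampling adequacy is marginal", kmo_v))
  }
  bt <- bartlett(r)
  m <- rotate_factors(extract_factors(r, retain))
  tw <- factor_weights(m)
  iw <- indicator_weights(m, tw, method = eq3)
  structure(
    list(
      cormat = r,
      diagnostics = tibble(kmo = kmo_v, chisq = bt$chisq, df = bt$df,
                           p_value = bt$p_value, n_obs = attr(r, "n_obs")),
      model = m,
      factor_weights = tw,
      indicator_weights = iw,
      scores = score_series(x, iw)
    ),
    class = "cw_score_result"
  )
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence `phi_j = |sum_i a_ij b_ij| /
#' sqrt(sum a_ij^2 sum b_ij^2)` after greedily matching columns of `b` to
#' columns of `a` by maximal congruence (sign-blind).
#'
#' @param a,b Loading matrices with equal dimensions.
#' @return The minimum matched congruence (scalar in \[0, 1\]).
#' @export
tucker_congruence <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  k <- ncol(a)
  phi <- abs(crossprod(a, b)) /
    sqrt(outer(colSums(a^2), colSums(b^2)))
  best <- numeric(k)
  used <- integer(0)
  for (j in seq_len(k)) {
    cand <- setdiff(seq_len(k), used)
    pick <- cand[which.max(phi[j, cand])]
    best[j] <- phi[j, pick]
    used <- c(used, pick)
  }
  min(best)
}
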