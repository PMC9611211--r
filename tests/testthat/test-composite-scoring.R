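test_that("correlation_matrix reshapes, validates and has unit diagonal", {
  pf <- simulate_planted_factors(n = 50, seed = 4)
  r <- correlation_matrix(pf, aggregate = "none")
  expect_equal(unname(diag(unclass(r))), rep(1, 6))
  expect_equal(unclass(r), t(unclass(r)))
  expect_equal(attr(r, "n_obs"), 50)

  # perfectly collinear indicators give off-diagonal 1
  coll <- tibble::tibble(
    system = rep(paste0("s", 1:5), each = 2),
    pollutant = rep(c("a", "b"), 5),
    day = 1L, replicate = 1L,
    removal = c(rbind(seq(0.1, 0.5, 0.1), seq(0.2, 0.6, 0.1)))
  )
  rc <- correlation_matrix(coll, aggregate = "none")
  expect_equal(rc["a", "b"], 1)

  const <- dplyr::mutate(coll,
                         removal = ifelse(pollutant == "a", 0.5, removal))
  expect_error(correlation_matrix(const, "none"), "a")
})

test_that("independent indicators decorrelate at large n", {
  set.seed(1)
  n <- 10000
  tbl <- tibble::tibble(
    system = rep(sprintf("o%05d", 1:n), times = 3),
    pollutant = rep(c("a", "b", "c"), each = n),
    day = 1L, replicate = 1L,
    removal = runif(3 * n)
  )
  r <- unclass(correlation_matrix(tbl, "none"))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("KMO matches closed forms", {
  r3 <- matrix(0.5, 3, 3); diag(r3) <- 1
  expect_equal(kmo(r3), 1.5 / (1.5 + 6 / 9), tolerance = 1e-9)
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(kmo(r2), 0.5, tolerance = 1e-9)
  near_id <- diag(4); near_id[near_id == 0] <- 1e-4
  k <- kmo(near_id)
  expect_gt(k, 0); expect_lte(k, 1)
})

test_that("Bartlett sphericity matches the closed form", {
  r3 <- matrix(0.5, 3, 3); diag(r3) <- 1
  bt <- bartlett(r3, n = 20)
  expect_equal(bt$chisq, -(19 - 11 / 6) * log(0.5), tolerance = 1e-9)
  expect_equal(bt$df, 3)
  id6 <- diag(6)
  bt0 <- bartlett(id6, n = 30)
  expect_equal(bt0$chisq, 0)
  expect_equal(bt0$df, 15)
  expect_equal(bt0$p_value, 1)
})

test_that("factor extraction matches the 2x2 eigensystem and trace identity", {
  r2 <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  m <- extract_factors(r2)
  expect_equal(m$eigenvalues, c(1.6, 0.4))
  expect_equal(m$k, 1)
  expect_equal(unname(m$loadings_unrotated[, 1]), c(0.8944272, 0.8944272),
               tolerance = 1e-6)
  expect_error(extract_factors(diag(4)), class = "cwevalkit_domain_error")
  # trace identity on random PSD correlation matrices
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(200), 40, 5)
    r <- cor(X)
    m <- extract_factors(r, retain = 2)
    expect_equal(sum(m$eigenvalues), 5, tolerance = 1e-8)
  }
})

test_that("varimax fixes axis-aligned loadings and beats identity rotation", {
  axis <- matrix(c(1, 0, 0.9, 0, 1, 0), 3, 2)
  rot <- varimax_rotation(axis)
  expect_equal(abs(rot), abs(axis)[, order(-colSums(axis^2))],
               tolerance = 1e-6, ignore_attr = TRUE)
  for (seed in 1:5) {
    set.seed(seed)
    L <- matrix(rnorm(12, sd = 0.5), 6, 2)
    R <- varimax_rotation(L)
    # communalities preserved by orthogonality
    expect_equal(rowSums(R^2), rowSums(L^2), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_gte(varimax_criterion(R), varimax_criterion(L) - 1e-12)
  }
})

test_that("varimax equals a fine grid-search oracle on 2-factor toys", {
  toys <- list(
    matrix(c(0.707, 0.707, 0.707, -0.707), 2, 2, byrow = TRUE),
    reference_rotated_loadings() %*%
      matrix(c(cos(0.6), -sin(0.6), sin(0.6), cos(0.6)), 2, 2),
    matrix(c(0.9, 0.1, 0.8, 0.2, 0.1, 0.95, 0.2, 0.85), 4, 2, byrow = TRUE)
  )
  for (L in toys) {
    achieved <- varimax_criterion(varimax_rotation(L))
    oracle <- grid_varimax_max(L)
    expect_lt(abs(achieved - oracle), 1e-6)
  }
})

test_that("factor weights normalize post-rotation explained variance", {
  fw <- factor_weights(reference_rotated_loadings())
  expect_equal(fw$weight, c(0.5694, 0.4306), tolerance = 1e-3)
  expect_equal(sum(fw$weight), 1, tolerance = 1e-9)
  # planted SS loadings (3, 1) -> weights (0.75, 0.25)
  planted <- matrix(c(sqrt(1.5), sqrt(1.5), 0, 0, 0, 0, sqrt(0.5),
                      sqrt(0.5)), 4, 2)
  expect_equal(factor_weights(planted)$weight, c(0.75, 0.25))
  # single factor
  one <- matrix(c(0.7, 0.8), 2, 1)
  expect_equal(factor_weights(one)$weight, 1)
})

test_that("indicator weights combine within-factor shares and sum to one", {
  # one factor, equal loadings
  eq <- matrix(0.6, 4, 1, dimnames = list(paste0("i", 1:4), "factor1"))
  expect_equal(indicator_weights(eq)$weight, rep(0.25, 4))
  # sum-to-one identity on random non-negative loadings
  for (seed in 1:5) {
    set.seed(seed)
    L <- matrix(runif(12, 0.05, 1), 6, 2)
    expect_equal(sum(indicator_weights(L)$weight), 1, tolerance = 1e-9)
  }
  # literal method reproduces the raw combination
  L <- reference_rotated_loadings()
  tw <- factor_weights(L)
  lit <- indicator_weights(L, tw, method = "literal")
  expect_equal(lit$weight, as.vector(L %*% tw$weight), tolerance = 1e-12)
})

test_that("composite_score is the weighted dot product and monotone", {
  w <- reference_indicator_weights()$weight
  expect_equal(composite_score(rep(1, 6), w), sum(w))
  expect_equal(composite_score(c(1, 0, 0, 0, 0, 0), w), w[1])
  expect_error(composite_score(c(0.5, 0.5), w),
               class = "cwevalkit_domain_error")
  a <- runif(6)
  bumped <- pmin(a + 0.05, 1)
  expect_gte(composite_score(bumped, w), composite_score(a, w))
})

test_that("score_pipeline retains the planted factor count and is deterministic", {
  pf <- simulate_planted_factors(n = 500, seed = 1)
  res1 <- score_pipeline(pf, aggregate = "none")
  res2 <- score_pipeline(pf, aggregate = "none")
  expect_equal(res1$indicator_weights, res2$indicator_weights)
  expect_equal(res1$model$k, 2)
  # day-7 score ranking equals ranking by weighted mean removal
  noisy <- simulate_removal(default_calibration(seed = 2))
  resq <- suppressWarnings(score_pipeline(noisy))
  d7 <- dplyr::filter(resq$scores, day == 7)
  wm <- dplyr::filter(noisy, day == 7) |>
    dplyr::group_by(system, pollutant) |>
    dplyr::summarise(removal = mean(removal), .groups = "drop") |>
    dplyr::left_join(resq$indicator_weights,
                     by = c(pollutant = "indicator")) |>
    dplyr::group_by(system) |>
    dplyr::summarise(E = sum(removal * weight))
  expect_equal(d7$system[order(-d7$E)], wm$system[order(-wm$E)])
})

test_that("rotation preserves total explained variance and communalities", {
  pf <- simulate_planted_factors(n = 300, seed = 7)
  m <- rotate_factors(extract_factors(correlation_matrix(pf, "none")))
  expect_equal(sum(m$ss_loadings_rotated), sum(m$eigenvalues[seq_len(m$k)]),
               tolerance = 1e-6)
  expect_equal(rowSums(m$loadings_rotated^2), rowSums(m$loadings_unrotated^2),
               tolerance = 1e-8)
  expect_equal(m$variance_pct, m$eigenvalues / 6 * 100, tolerance = 1e-9)
})

test_that("factor recovery: planted loadings found with high congruence", {
  for (seed in 1:5) {
    pf <- simulate_planted_factors(n = 500, seed = seed)
    m <- rotate_factors(extract_factors(correlation_matrix(pf, "none")))
    expect_equal(m$k, 2)
    expect_gte(tucker_congruence(attr(pf, "planted_loadings"),
                                 m$loadings_rotated), 0.95)
  }
})
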