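test_that("Bray-Curtis matches hand values and bounds", {
  rel <- tibble::tibble(
    taxon_id = c("t1", "t2"), lineage = c("l1", "l2"),
    u = c(1, 0), v = c(0.5, 0.5), w = c(1, 0), x = c(0, 1)
  )
  d <- bray_curtis(rel)
  expect_equal(d["u", "v"], 0.5)
  expect_equal(d["u", "w"], 0)   # identical samples
  expect_equal(d["u", "x"], 1)   # disjoint supports
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_true(all(d >= 0 & d <= 1))
  unnorm <- dplyr::mutate(rel, u = u * 2)
  expect_error(bray_curtis(unnorm), "u")
})

test_that("UPGMA reproduces hand-computed merge heights", {
  d <- matrix(c(0, 2, 6,
                2, 0, 6,
                6, 6, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_equal(tr$merges$height, c(1, 3))
  expect_equal(unname(leaf_depths(tr)), rep(3, 3))
  # equal distances: all merges at the same height
  deq <- matrix(4, 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  treq <- upgma(deq)
  expect_equal(treq$merges$height, rep(2, 3))
})

test_that("UPGMA trees are ultrametric on random distance fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 6
    x <- matrix(runif(n * 3), n)
    d <- as.matrix(dist(x))
    rownames(d) <- colnames(d) <- paste0("s", 1:n)
    tr <- upgma(d)
    depths <- leaf_depths(tr)
    expect_lt(diff(range(depths)), 1e-9)
    expect_true(all(diff(tr$merges$height) >= -1e-12))
  }
})

test_that("UPGMA on an ultrametric input reconstructs its merge heights", {
  # build an ultrametric matrix from a known tree:
  # ((A,B):h1, (C,D):h2):h3 with heights 1, 1.5, 4
  d <- matrix(8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 3
  tr <- upgma(d)
  expect_equal(sort(tr$merges$height), c(1, 1.5, 4))
})

test_that("dominant_taxa pools sub-threshold taxa and conserves mass", {
  rel <- tibble::tibble(
    taxon_id = c("big", "mid", "tiny"),
    lineage = c("b", "m", "t"),
    s1 = c(0.6, 0.3995, 0.0005),
    s2 = c(0.7, 0.2995, 0.0005)
  )
  out <- dominant_taxa(rel, 0.001)
  expect_setequal(out$taxon_id, c("big", "mid", "other"))
  expect_equal(colSums(as.matrix(out[c("s1", "s2")])), c(s1 = 1, s2 = 1))
  expect_equal(nrow(dominant_taxa(rel, 0)), 3)
})

test_that("Kruskal-Wallis matches enumeration and the chi-square oracle", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$H, 2.4, tolerance = 1e-9)
  expect_equal(kw$p_value, 2 / 6, tolerance = 1e-9)

  same <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  # H agrees with stats::kruskal.test (independent implementation),
  # including under ties
  set.seed(8)
  for (i in 1:5) {
    v <- sample(1:6, 12, replace = TRUE)
    g <- rep(c("a", "b", "c"), each = 4)
    ours <- kruskal_wallis(v, g)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }

  # chi-square branch tracks exhaustive enumeration at n = 9
  # (all 9!/(3!3!3!) = 1680 distinct assignments via nested combinations);
  # the exact distribution is discrete, so individual fixtures can sit on a
  # jump: require every deviation < 0.1 and the average < 0.05
  exact_kw_p <- function(v9) {
    g9 <- factor(rep(c("a", "b", "c"), each = 3))
    h_obs <- cwevalkit:::kw_statistic(v9, g9)
    hs <- c()
    for (a_idx in asplit(combn(9, 3), 2)) {
      rest <- setdiff(1:9, a_idx)
      for (b_idx in asplit(combn(rest, 3), 2)) {
        g <- integer(9)
        g[a_idx] <- 1L; g[b_idx] <- 2L; g[g == 0L] <- 3L
        hs <- c(hs, cwevalkit:::kw_statistic(v9, factor(g)))
      }
    }
    mean(hs >= h_obs - 1e-12)
  }
  devs <- sapply(c(1, 5, 8), function(sd) {
    set.seed(sd)
    v9 <- rnorm(9)
    approx_p <- kruskal_wallis(v9, rep(c("a", "b", "c"), each = 3))$p_value
    abs(approx_p - exact_kw_p(v9))
  })
  expect_true(all(devs < 0.1))
  expect_lt(mean(devs), 0.05)
})

test_that("lefse_like controls per-feature type I error on null data", {
  lineage <- tibble::tibble(taxon_id = paste0("t", 1:12), phylum = "P",
                            genus = paste0("g", 1:12))
  n_flagged <- 0
  n_tested <- 0
  n_seeds <- 200
  for (seed in seq_len(n_seeds)) {
    cfg <- community_sim_config(lineage, groups = c("a", "b", "c"),
                                depth = 2000, replicates_per_group = 3,
                                seed = seed)
    sim <- simulate_community(cfg)
    res <- lefse_like(sim$counts, sim$groups, seed = seed)
    n_flagged <- n_flagged + nrow(res)
    n_tested <- n_tested + nrow(lineage)
  }
  expect_lte(n_flagged / n_tested, 0.1)
})

test_that("lefse_like detects a planted 100-fold feature with score >= 4", {
  set.seed(21)
  n <- 10
  depth <- 1e6
  p_a <- c(0.1, rep(0.9 / 9, 9))     # feature 1 at 1e5 per 1e6
  p_b <- c(0.001, rep(0.999 / 9, 9)) # feature 1 at 1e3 per 1e6
  cols <- list()
  for (r in 1:n) cols[[paste0("a_r", r)]] <- as.integer(rmultinom(1, depth, p_a))
  for (r in 1:n) cols[[paste0("b_r", r)]] <- as.integer(rmultinom(1, depth, p_b))
  counts <- dplyr::bind_cols(
    tibble::tibble(taxon_id = paste0("f", 1:10),
                   lineage = paste0("B;P;", paste0("g", 1:10))),
    tibble::as_tibble(cols)
  )
  groups <- tibble::tibble(sample = names(cols),
                           group = rep(c("a", "b"), each = n))
  res <- lefse_like(counts, groups, seed = 3)
  hit <- dplyr::filter(res, taxon == "f1")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$enriched_group, "a")
  expect_gte(hit$lda_score, 4)
})

test_that("lefse_like is invariant to per-sample count scaling", {
  sc <- shifted_counts(n_rep = 4, depth = 5000)
  r1 <- lefse_like(sc$counts, sc$groups, seed = 2)
  scaled <- sc$counts
  samples <- setdiff(names(scaled), c("taxon_id", "lineage"))
  for (i in seq_along(samples)) {
    scaled[[samples[i]]] <- scaled[[samples[i]]] * (i + 1)
  }
  r2 <- lefse_like(scaled, sc$groups, seed = 2)
  expect_equal(r1, r2)
})

test_that("lefse_like recovers planted marker genera in their groups", {
  sim <- simulate_community(default_community_config(depth = 20000,
                                                     seed = 6))
  res <- lefse_like(sim$counts, sim$groups, seed = 6)
  markers <- c(Clostridium = "T1", Paludibacterium = "T1",
               Kluyvera = "T2", Enterobacter = "T5",
               Chryseobacterium = "T5", Paludibacter = "T6",
               Pseudomonas = "T6", Janthinobacterium = "T6")
  found <- res$enriched_group[match(names(markers), res$taxon)]
  expect_equal(unname(found), unname(markers))
})

test_that("abundance_shift recovers a planted shift and sums to zero", {
  sim <- simulate_community(default_community_config(
    depth = 1e5, replicates_per_group = 6, seed = 13))
  shift <- abundance_shift(sim$counts, sim$groups, "T1", "T0",
                           rank = "phylum")
  expect_lt(abs(sum(shift$delta)), 1e-9)
  firmicutes <- dplyr::filter(shift, taxon == "Firmicutes")
  expect_gt(firmicutes$delta, 0)
  expect_lt(firmicutes$q_value, 0.05)
  # duplicated groups: zero shift, no discoveries at FDR 0.05
  same <- tiny_counts()
  same$s3 <- same$s1
  same$s4 <- same$s2
  null_shift <- abundance_shift(
    same,
    tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
                   group = c("g1", "g1", "g2", "g2")),
    "g1", "g2"
  )
  expect_equal(null_shift$delta, rep(0, 3))
  expect_true(all(null_shift$q_value > 0.05))
})
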