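# in-code fixtures shared across test files

tiny_removal <- function() {
  tibble::tibble(
    system = c("S", "S", "A"),
    pollutant = c("COD", "TP", "COD"),
    day = c(1L, 1L, 1L),
    replicate = 1L,
    removal = c(0.1, 0.5, 0.9)
  )
}

tiny_counts <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    lineage = c("Bacteria;Firmicutes;C;O;F;Clostridium",
                "Bacteria;Firmicutes;C;O;F;Bacillus",
                "Bacteria;Proteobacteria;C;O;F;Pseudomonas"),
    s1 = c(1L, 3L, 0L),
    s2 = c(2L, 2L, 4L)
  )
}

# two-group count fixture with a strongly shifted taxon and n reps per group
shifted_counts <- function(n_rep = 3, depth = 1000, seed = 42) {
  set.seed(seed)
  p_a <- c(0.5, 0.3, 0.2)
  p_b <- c(0.1, 0.4, 0.5)
  cols <- list()
  groups <- character()
  for (r in seq_len(n_rep)) {
    cols[[paste0("a_r", r)]] <- as.integer(rmultinom(1, depth, p_a))
    cols[[paste0("b_r", r)]] <- as.integer(rmultinom(1, depth, p_b))
  }
  counts <- dplyr::bind_cols(
    tibble::tibble(taxon_id = c("x", "y", "z"),
                   lineage = c("B;P1;g1", "B;P1;g2", "B;P2;g3")),
    tibble::as_tibble(cols)
  )
  list(counts = counts,
       groups = tibble::tibble(sample = names(cols),
                               group = rep(c("a", "b"), times = n_rep)))
}

# brute-force varimax criterion maximum for a p x 2 loading matrix over a
# rotation-angle grid (degrees)
grid_varimax_max <- function(L, step_deg = 0.01) {
  angles <- seq(0, 90, by = step_deg) * pi / 180
  best <- -Inf
  for (a in angles) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    best <- max(best, varimax_criterion(L %*% R))
  }
  best
}
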