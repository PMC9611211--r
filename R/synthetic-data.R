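#' Saturating first-order removal kinetics
#'
#' Noise-free removal after `day` days of operation:
#' `r_max * (1 - exp(-k * day))`. A two-parameter saturating exponential
#' captures the observed dynamics — rapid early gains that flatten after about
#' day 5 — without asserting a mechanistic model.
#'
#' @param day Days of operation (>= 0).
#' @param r_max Asymptotic removal fraction in \[0, 1\].
#' @param k First-order rate constant per day (> 0).
#' @return Removal fraction(s).
#' @export
saturating_removal <- function(day, r_max, k) {
  stopifnot(all(day >= 0), all(r_max >= 0), all(r_max <= 1), all(k > 0))
  r_max * (1 - exp(-k * day))
}

#' Configuration for the removal-rate simulator
#'
#' @param systems,pollutants Character vectors of labels.
#' @param days Number of operation days (series runs day 1..days).
#' @param replicates Replicates per system.
#' @param params Tibble with columns `system`, `pollutant`, `r_max`, `k`
#'   covering every (system, pollutant) pair; `r_max` in \[0, 1\], `k` > 0.
#' @param noise_sd SD of additive Gaussian noise on the removal fraction
#'   (default 0.02, a realistic assay-level scatter for composited effluent
#'   chemistry); results are truncated back into \[0, 1\].
#' @param seed Integer seed; generators never touch global random state
#'   beyond an explicit `set.seed`.
#' @return A list of class `cw_removal_sim_config`.
#' @export
removal_sim_config <- function(systems, pollutants, days = 7, replicates = 3,
                               params, noise_sd = 0.02, seed = 1) {
  params <- as_tibble(params)
  cw_assert_cols(params, c("system", "pollutant", "r_max", "k"),
                 "removal simulation params")
  if (days < 1) cw_abort("days must be >= 1", "cwevalkit_domain_error")
  if (any(params$r_max < 0 | params$r_max > 1)) {
    cw_abort("r_max must lie in [0, 1]", "cwevalkit_range_error")
  }
  if (any(params$k <= 0)) cw_abort("k must be > 0", "cwevalkit_range_error")
  grid <- tidyr::expand_grid(system = systems, pollutant = pollutants)
  missing <- dplyr::anti_join(grid, params, by = c("system", "pollutant"))
  if (nrow(missing) > 0) {
    cw_abort(sprintf("params missing %d (system, pollutant) pair(s)",
                     nrow(missing)), "cwevalkit_schema_error")
  }
  structure(
    list(systems = systems, pollutants = pollutants, days = as.integer(days),
         replicates = as.integer(replicates), params = params,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cw_removal_sim_config"
  )
}

#' Default removal-simulation calibration
#'
#' Returns a [removal_sim_config()] for the six microcosm systems (S, SG, A,
#' AG, AS, ASG) and six pollutant indicators, calibrated so that the
#' noise-free day-7 removal equals each published final removal rate (see
#' [reference_final_removals()]). Pairs without a published endpoint default
#' to a final removal of 0.85. The rate constant defaults to `k0` = 0.5/day;
#' where the published endpoint is so close to 1 that the implied asymptote
#' would exceed 1, `r_max` is capped at 1 and `k` is raised to
#' `-log(1 - final)/7` so the day-7 value still matches exactly.
#'
#' @param noise_sd,seed Passed to [removal_sim_config()].
#' @param k0 Default rate constant per day.
#' @return A `cw_removal_sim_config`.
#' @export
default_calibration <- function(noise_sd = 0.02, seed = 1, k0 = 0.5) {
  finals <- tidyr::expand_grid(system = cw_systems(),
                               pollutant = cw_indicators()) |>
    dplyr::left_join(reference_final_removals(),
                     by = c("system", "pollutant")) |>
    dplyr::mutate(final = dplyr::coalesce(.data$removal, 0.85))
  sat7 <- 1 - exp(-k0 * 7)
  params <- finals |>
    dplyr::mutate(
      r_max = pmin(1, .data$final / sat7),
      k = dplyr::if_else(.data$final / sat7 > 1,
                         -log(1 - .data$final) / 7, k0)
    ) |>
    dplyr::select("system", "pollutant", "r_max", "k")
  removal_sim_config(cw_systems(), cw_indicators(), days = 7, replicates = 3,
                     params = params, noise_sd = noise_sd, seed = seed)
}

#' Simulate a removal-rate table
#'
#' Draws `removal = clip(r_max (1 - exp(-k day)) + eps, 0, 1)` with
#' `eps ~ N(0, noise_sd^2)` for every (system, pollutant, day, replicate)
#' combination of the configuration. Identical seeds give identical tables.
#'
#' @param cfg A `cw_removal_sim_config`.
#' @return A validated removal tibble.
#' @export
simulate_removal <- function(cfg) {
  stopifnot(inherits(cfg, "cw_removal_sim_config"))
  grid <- tidyr::expand_grid(
    system = cfg$systems, pollutant = cfg$pollutants,
    day = seq_len(cfg$days), replicate = seq_len(cfg$replicates)
  ) |>
    dplyr::left_join(cfg$params, by = c("system", "pollutant"))
  set.seed(cfg$seed)
  eps <- if (cfg$noise_sd > 0) rnorm(nrow(grid), 0, cfg$noise_sd) else 0
  grid |>
    dplyr::mutate(
      removal = pmin(pmax(
        saturating_removal(.data$day, .data$r_max, .data$k) + eps, 0), 1)
    ) |>
    dplyr::select("system", "pollutant", "day", "replicate", "removal") |>
    validate_removal_table()
}

#' Simulate a removal table with a planted two-factor correlation structure
#'
#' Generates `n` independent observations of the six removal indicators from
#' a two-latent-factor model: COD, NO3-N and CED load on factor 1, TP, TN and
#' NH4-N on factor 2, with small cross-loadings. Latent scores are mapped
#' affinely into the removal scale (0.5 +- 0.1 per latent SD), which preserves
#' the Pearson correlation structure. Used to check that factor extraction
#' retains exactly two factors and recovers the planted loadings.
#'
#' @param n Number of observations (rows per indicator).
#' @param seed Integer seed.
#' @param loading Primary loading (default 0.85).
#' @param cross Cross-loading (default 0.2).
#' @return A removal tibble; the planted 6 x 2 loading matrix is attached as
#'   attribute `"planted_loadings"`.
#' @export
simulate_planted_factors <- function(n = 500, seed = 1, loading = 0.85,
                                     cross = 0.2) {
  ind <- cw_indicators()
  L <- matrix(cross, nrow = 6, ncol = 2, dimnames = list(ind, NULL))
  L[c("COD", "NO3-N", "CED"), 1] <- loading
  L[c("TP", "TN", "NH4-N"), 2] <- loading
  uniq <- 1 - rowSums(L^2)
  stopifnot(all(uniq > 0))
  set.seed(seed)
  f <- matrix(rnorm(n * 2), n, 2)
  e <- matrix(rnorm(n * 6), n, 6)
  z <- f %*% t(L) + sweep(e, 2, sqrt(uniq), `*`)
  removal <- pmin(pmax(0.5 + 0.1 * z, 0), 1)
  out <- tibble(
    system = rep(sprintf("obs%04d", seq_len(n)), times = 6),
    pollutant = rep(ind, each = n),
    day = 7L, replicate = 1L,
    removal = as.vector(removal)
  )
  out <- validate_removal_table(out)
  attr(out, "planted_loadings") <- L
  out
}

#' Configuration for the community count simulator
#'
#' @param lineage Tibble with columns `taxon_id`, `phylum`, `genus` (one row
#'   per taxon; >= 2 taxa).
#' @param groups Character vector of group labels.
#' @param effects Tibble with columns `group`, `taxon_id`, `log2fc`: planted
#'   per-group log2 fold-changes on the baseline composition (absent pairs
#'   mean no change).
#' @param base_log_abundance_sd SD of the baseline log-abundances drawn once
#'   per configuration seed (default 1).
#' @param depth Reads per sample (> 0).
#' @param replicates_per_group Samples per group.
#' @param overdispersion Optional Dirichlet concentration scale; `Inf`
#'   (default) gives pure multinomial sampling, smaller values add
#'   between-replicate compositional noise.
#' @param seed Integer seed.
#' @return A list of class `cw_community_sim_config`.
#' @export
community_sim_config <- function(lineage, groups, effects = NULL,
                                 base_log_abundance_sd = 1, depth = 10000,
                                 replicates_per_group = 3,
                                 overdispersion = Inf, seed = 1) {
  lineage <- as_tibble(lineage)
  cw_assert_cols(lineage, c("taxon_id", "phylum", "genus"), "lineage pool")
  if (nrow(lineage) < 2) cw_abort("need >= 2 taxa", "cwevalkit_domain_error")
  if (depth <= 0) cw_abort("depth must be > 0", "cwevalkit_domain_error")
  if (is.null(effects)) {
    effects <- tibble(group = character(), taxon_id = character(),
                      log2fc = numeric())
  }
  effects <- as_tibble(effects)
  cw_assert_cols(effects, c("group", "taxon_id", "log2fc"), "effects")
  structure(
    list(lineage = lineage, groups = groups, effects = effects,
         base_log_abundance_sd = base_log_abundance_sd,
         depth = as.integer(depth),
         replicates_per_group = as.integer(replicates_per_group),
         overdispersion = overdispersion, seed = as.integer(seed)),
    class = "cw_community_sim_config"
  )
}

#' Simulate a multi-sample taxon count table
#'
#' Baseline log-abundances are drawn once (seeded); each group's expected
#' composition is `softmax(base + ln(2) * log2fc)`; each replicate is a
#' multinomial draw at the configured depth (optionally Dirichlet-perturbed
#' for overdispersion). Sample columns are named `<group>_r<replicate>`.
#'
#' @param cfg A `cw_community_sim_config`.
#' @return A list with `counts` (count table) and `groups`
#'   (tibble `sample`, `group`).
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "cw_community_sim_config"))
  n_taxa <- nrow(cfg$lineage)
  set.seed(cfg$seed)
  base <- rnorm(n_taxa, 0, cfg$base_log_abundance_sd)
  names(base) <- cfg$lineage$taxon_id
  counts <- list()
  groups <- list()
  for (g in cfg$groups) {
    eff <- setNames(rep(0, n_taxa), cfg$lineage$taxon_id)
    ge <- dplyr::filter(cfg$effects, .data$group == g)
    eff[ge$taxon_id] <- ge$log2fc
    logw <- base + log(2) * eff
    p <- exp(logw - max(logw))
    p <- p / sum(p)
    for (r in seq_len(cfg$replicates_per_group)) {
      p_r <- p
      if (is.finite(cfg$overdispersion)) {
        gam <- rgamma(n_taxa, shape = p * cfg$overdispersion)
        p_r <- gam / sum(gam)
      }
      nm <- sprintf("%s_r%d", g, r)
      counts[[nm]] <- as.integer(rmultinom(1, cfg$depth, p_r))
      groups[[nm]] <- g
    }
  }
  tbl <- tibble(
    taxon_id = cfg$lineage$taxon_id,
    lineage = paste("Bacteria", cfg$lineage$phylum, cfg$lineage$genus,
                    sep = ";")
  )
  tbl <- dplyr::bind_cols(tbl, as_tibble(counts))
  list(
    counts = validate_count_table(tbl),
    groups = tibble(sample = names(groups),
                    group = unlist(groups, use.names = FALSE))
  )
}

#' Default community simulation: antibiotic-stressed wetland microbiota
#'
#' Emulates the direction of the observed community shifts across the
#' sequenced groups (T0 initial, T1 = S, T2 = SG, T5 = AS, T6 = ASG):
#' Firmicutes genera enriched in T1/T2, Proteobacteria and Bacteroidetes
#' genera enriched in T5/T6, Acidobacteria (and other sensitive phyla)
#' depleted in every treated system, with marker genera (Clostridium,
#' Paludibacterium -> T1; Kluyvera -> T2; Enterobacter, Chryseobacterium ->
#' T5; Paludibacter, Pseudomonas, Janthinobacterium -> T6).
#'
#' @param depth Reads per sample.
#' @param replicates_per_group Samples per group.
#' @param seed Integer seed.
#' @return A `cw_community_sim_config`.
#' @export
default_community_config <- function(depth = 10000, replicates_per_group = 3,
                                     seed = 1) {
  lineage <- tibble::tribble(
    ~taxon_id,            ~phylum,           ~genus,
    "Clostridium",        "Firmicutes",      "Clostridium",
    "Bacillus",           "Firmicutes",      "Bacillus",
    "Paludibacterium",    "Proteobacteria",  "Paludibacterium",
    "Kluyvera",           "Proteobacteria",  "Kluyvera",
    "Enterobacter",       "Proteobacteria",  "Enterobacter",
    "Pseudomonas",        "Proteobacteria",  "Pseudomonas",
    "Janthinobacterium",  "Proteobacteria",  "Janthinobacterium",
    "Chryseobacterium",   "Bacteroidetes",   "Chryseobacterium",
    "Paludibacter",       "Bacteroidetes",   "Paludibacter",
    "Flavobacterium",     "Bacteroidetes",   "Flavobacterium",
    "Gp6",                "Acidobacteria",   "Gp6",
    "Gp16",               "Acidobacteria",   "Gp16",
    "Saccharimonas",      "Patescibacteria", "Saccharimonas",
    "Luteolibacter",      "Verrucomicrobia", "Luteolibacter",
    "Anaerolinea",        "Chloroflexi",     "Anaerolinea"
  )
  treated <- c("T1", "T2", "T5", "T6")
  down <- tidyr::expand_grid(
    group = treated,
    taxon_id = c("Gp6", "Gp16", "Saccharimonas", "Luteolibacter",
                 "Anaerolinea")
  ) |>
    dplyr::mutate(log2fc = -2)
  up <- tibble::tribble(
    ~group, ~taxon_id,           ~log2fc,
    "T1",   "Clostridium",        3,
    "T1",   "Paludibacterium",    3,
    "T1",   "Bacillus",           2,
    "T2",   "Kluyvera",           3,
    "T2",   "Bacillus",           2,
    "T5",   "Enterobacter",       3,
    "T5",   "Chryseobacterium",   3,
    "T6",   "Paludibacter",       3,
    "T6",   "Pseudomonas",        3,
    "T6",   "Janthinobacterium",  3
  )
  community_sim_config(
    lineage, groups = c("T0", treated),
    effects = dplyr::bind_rows(up, down),
    depth = depth, replicates_per_group = replicates_per_group, seed = seed
  )
}

#' Configuration for the microalgal growth simulator
#'
#' Logistic growth of Chlorella measured as OD680, with an antibiotic-stress
#' lag: before `lag` days, effective time advances at a fraction
#' `1 - lag_inhibition` of clock time (0 = no suppression).
#'
#' @param system System label.
#' @param od0 Initial OD680 (> 0; inoculation standard 0.1).
#' @param carrying_od Asymptotic OD680 (>= od0).
#' @param growth_rate Logistic rate per day.
#' @param lag Days of stress-suppressed growth.
#' @param lag_inhibition Suppression fraction in \[0, 1).
#' @param days,replicates Series length and replicates.
#' @param noise_sd SD of additive measurement noise (results floored at 0).
#' @param seed Integer seed.
#' @return A list of class `cw_growth_sim_config`.
#' @export
growth_sim_config <- function(system = "A", od0 = 0.1, carrying_od = 1,
                              growth_rate = 0.8, lag = 2, lag_inhibition = 0.5,
                              days = 7, replicates = 3, noise_sd = 0.01,
                              seed = 1) {
  if (od0 <= 0) cw_abort("od0 must be > 0", "cwevalkit_domain_error")
  if (carrying_od < od0) {
    cw_abort("carrying_od must be >= od0", "cwevalkit_domain_error")
  }
  if (lag_inhibition < 0 || lag_inhibition >= 1) {
    cw_abort("lag_inhibition must lie in [0, 1)", "cwevalkit_range_error")
  }
  structure(
    list(system = system, od0 = od0, carrying_od = carrying_od,
         growth_rate = growth_rate, lag = lag,
         lag_inhibition = lag_inhibition, days = as.integer(days),
         replicates = as.integer(replicates), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cw_growth_sim_config"
  )
}

logistic_od <- function(t, od0, K, r) {
  K / (1 + ((K - od0) / od0) * exp(-r * t))
}

#' Simulate OD680 growth series
#'
#' @param cfg A `cw_growth_sim_config` or a list of them (one per system).
#' @return A validated OD series tibble.
#' @export
simulate_growth <- function(cfg) {
  if (inherits(cfg, "cw_growth_sim_config")) cfg <- list(cfg)
  out <- purrr::map(cfg, function(cf) {
    stopifnot(inherits(cf, "cw_growth_sim_config"))
    grid <- tidyr::expand_grid(day = 0:cf$days,
                               replicate = seq_len(cf$replicates))
    t_eff <- (1 - cf$lag_inhibition) * pmin(grid$day, cf$lag) +
      pmax(grid$day - cf$lag, 0)
    od <- logistic_od(t_eff, cf$od0, cf$carrying_od, cf$growth_rate)
    set.seed(cf$seed)
    if (cf$noise_sd > 0) od <- pmax(od + rnorm(length(od), 0, cf$noise_sd), 0)
    tibble(system = cf$system, day = as.integer(grid$day),
           replicate = as.integer(grid$replicate), od680 = od)
  })
  validate_od_series(dplyr::bind_rows(out))
}
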