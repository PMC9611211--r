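#' Validate a removal-rate table
#'
#' A removal table is the long-format record of treatment performance: one row
#' per (system, pollutant, day, replicate) holding the removal fraction in
#' \[0, 1\]. It is the input of the composite-scoring pipeline.
#'
#' @param x A data frame with columns `system`, `pollutant`, `day`,
#'   `replicate`, `removal`.
#' @return The validated table as a tibble.
#' @export
validate_removal_table <- function(x) {
  x <- as_tibble(x)
  cw_assert_cols(x, c("system", "pollutant", "day", "replicate", "removal"),
                 "removal table")
  bad <- which(!is.finite(x$removal) | x$removal < 0 | x$removal > 1)
  if (length(bad) > 0) {
    cw_abort(
      sprintf("removal must lie in [0, 1]; offending row(s): %s",
              paste(head(bad, 5), collapse = ", ")),
      class = "cwevalkit_range_error"
    )
  }
  if (any(x$day < 0)) cw_abort("day must be >= 0", "cwevalkit_range_error")
  if (any(x$replicate < 1)) {
    cw_abort("replicate must be >= 1", "cwevalkit_range_error")
  }
  keys <- paste(x$system, x$pollutant, x$day, x$replicate, sep = "\r")
  if (anyDuplicated(keys) > 0) {
    cw_abort("(system, pollutant, day, replicate) keys must be unique",
             class = "cwevalkit_schema_error")
  }
  dplyr::mutate(x, day = as.integer(.data$day),
                replicate = as.integer(.data$replicate))
}

#' Read and write removal-rate tables
#'
#' Long TSV (columns `system`, `pollutant`, `day`, `replicate`, `removal`) is
#' the canonical on-disk format. A wide dialect with one column per pollutant
#' (plus `system`, `day`, `replicate`) is accepted on read and melted to long.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect `"long"` (canonical) or `"wide"` (pollutants as columns).
#' @return A validated removal tibble.
#' @export
read_removal_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    cw_abort(sprintf("file not found: %s", path), "cwevalkit_io_error")
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "wide") {
    cw_assert_cols(x, c("system", "day", "replicate"), "wide removal table")
    x <- tidyr::pivot_longer(
      x, cols = -c("system", "day", "replicate"),
      names_to = "pollutant", values_to = "removal"
    )
  }
  validate_removal_table(x)
}

#' @param x A removal table.
#' @rdname read_removal_table
#' @export
write_removal_table <- function(x, path) {
  x <- validate_removal_table(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Convert influent/effluent concentrations to removal fractions
#'
#' Removal is defined as (influent - effluent) / influent. Effluent
#' concentrations that transiently exceed the influent yield a negative value,
#' which is clipped to 0 with a warning rather than rejected: such excursions
#' occur in real wetland effluent.
#'
#' @param x Data frame with columns `system`, `pollutant`, `day`, `replicate`,
#'   `influent_mg_per_L` (> 0) and `effluent_mg_per_L` (>= 0).
#' @return A validated removal tibble.
#' @export
removal_from_concentrations <- function(x) {
  x <- as_tibble(x)
  cw_assert_cols(x, c("system", "pollutant", "day", "replicate",
                      "influent_mg_per_L", "effluent_mg_per_L"),
                 "concentration table")
  if (any(!is.finite(x$influent_mg_per_L) | x$influent_mg_per_L <= 0)) {
    cw_abort("influent_mg_per_L must be > 0", "cwevalkit_domain_error")
  }
  if (any(x$effluent_mg_per_L < 0)) {
    cw_abort("effluent_mg_per_L must be >= 0", "cwevalkit_domain_error")
  }
  removal <- (x$influent_mg_per_L - x$effluent_mg_per_L) / x$influent_mg_per_L
  n_neg <- sum(removal < 0)
  if (n_neg > 0) {
    warn(sprintf(
      "%d observation(s) had effluent > influent; removal clipped to 0", n_neg
    ))
  }
  out <- dplyr::transmute(
    x, .data$system, .data$pollutant, .data$day, .data$replicate,
    removal = pmin(pmax(removal, 0), 1)
  )
  validate_removal_table(out)
}

#' Validate a taxon count table
#'
#' A count table holds one row per taxon (`taxon_id`, semicolon-delimited
#' `lineage` from kingdom down to genus, at most 7 ranks) and one non-negative
#' integer column per sample. Sample-to-group assignments travel in a separate
#' two-column tibble (`sample`, `group`).
#'
#' @param x Data frame with `taxon_id`, `lineage` and >= 1 sample column.
#' @return Validated tibble.
#' @export
validate_count_table <- function(x) {
  x <- as_tibble(x)
  cw_assert_cols(x, c("taxon_id", "lineage"), "count table")
  samples <- count_table_samples(x)
  if (length(samples) < 1) {
    cw_abort("count table needs at least one sample column",
             "cwevalkit_schema_error")
  }
  counts <- as.matrix(x[samples])
  if (any(counts < 0) || any(!is.finite(counts))) {
    cw_abort("counts must be finite and >= 0", "cwevalkit_range_error")
  }
  n_ranks <- lengths(strsplit(x$lineage, ";", fixed = TRUE))
  if (any(n_ranks > 7)) {
    cw_abort("lineage must have at most 7 ranks (kingdom..genus, etc.)",
             class = "cwevalkit_schema_error")
  }
  x
}

count_table_samples <- function(x) {
  setdiff(names(x), c("taxon_id", "lineage"))
}

#' @param path Path to a TSV count table.
#' @rdname validate_count_table
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    cw_abort(sprintf("file not found: %s", path), "cwevalkit_io_error")
  }
  validate_count_table(readr::read_tsv(path, show_col_types = FALSE,
                                       progress = FALSE))
}

#' @rdname validate_count_table
#' @export
write_count_table <- function(x, path) {
  readr::write_tsv(validate_count_table(x), path)
  invisible(path)
}

#' Read and write optical-density time series
#'
#' Columns: `system`, `day`, `replicate`, `od680` (absorbance at 680 nm,
#' >= 0), the chlorophyll-driven proxy for Chlorella biomass.
#'
#' @param path TSV path.
#' @export
read_od_series <- function(path) {
  if (!file.exists(path)) {
    cw_abort(sprintf("file not found: %s", path), "cwevalkit_io_error")
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_od_series(x)
}

#' @param x An OD series data frame.
#' @rdname read_od_series
#' @export
validate_od_series <- function(x) {
  x <- as_tibble(x)
  cw_assert_cols(x, c("system", "day", "replicate", "od680"), "OD series")
  if (any(x$od680 < 0)) cw_abort("od680 must be >= 0", "cwevalkit_range_error")
  x
}

#' @rdname read_od_series
#' @export
write_od_series <- function(x, path) {
  readr::write_tsv(validate_od_series(x), path)
  invisible(path)
}

#' Aggregate a count table to phylum or genus level
#'
#' Counts of taxa sharing the same rank label are summed. Taxa whose lineage
#' lacks the requested rank (or whose label is empty) are pooled under
#' `"unclassified"`. Total counts per sample are conserved.
#'
#' @param x A count table (see [validate_count_table()]).
#' @param rank `"phylum"` or `"genus"`. Lineages are read positionally:
#'   kingdom is rank 1, phylum rank 2, ..., genus rank 6.
#' @return A count table with one row per rank label.
#' @export
aggregate_lineage <- function(x, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  x <- validate_count_table(x)
  if (nrow(x) == 0) return(x)
  idx <- c(phylum = 2L, genus = 6L)[[rank]]
  parts <- strsplit(x$lineage, ";", fixed = TRUE)
  label <- vapply(parts, function(p) {
    v <- if (length(p) >= idx) trimws(p[[idx]]) else ""
    if (is.na(v) || v == "") "unclassified" else v
  }, character(1))
  samples <- count_table_samples(x)
  x |>
    dplyr::mutate(taxon_id = label, lineage = label) |>
    dplyr::group_by(.data$taxon_id, .data$lineage) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), sum),
                     .groups = "drop")
}

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its total so columns sum to 1.
#'
#' @param x A count table.
#' @return A tibble of the same shape with fractional abundances.
#' @export
relative_abundance <- function(x) {
  x <- validate_count_table(x)
  samples <- count_table_samples(x)
  totals <- vapply(x[samples], sum, numeric(1))
  zero <- samples[totals == 0]
  if (length(zero) > 0) {
    cw_abort(sprintf("sample(s) with zero total counts: %s",
                     paste(zero, collapse = ", ")),
             class = "cwevalkit_domain_error")
  }
  x[samples] <- purrr::map2(x[samples], totals, `/`)
  x
}
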