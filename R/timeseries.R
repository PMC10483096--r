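#' Abundance time-series tables
#'
#' The pipeline's central exchange format is a long-format table with one
#' row per (microcosm, sampling day, species) holding the measured density
#' in individuals/mL. `hoi_timeseries()` validates a data frame and stamps
#' it with the `hoi_ts` class; all downstream stages accept this format.
#'
#' Validation enforces: required columns present; densities numeric,
#' finite and non-negative (explicit zeros, never missing values); no
#' duplicated (microcosm, day, species) triple; species codes drawn from
#' the five-species vocabulary; for the six canonical treatment codes,
#' species consistent with the treatment's community; within a microcosm
#' every species sampled on the same day grid.
#'
#' @param df A data frame with columns `microcosm_id`, `treatment`,
#'   `replicate`, `day`, `species`, `density`.
#' @return A validated `hoi_ts` data frame, rows ordered by
#'   (microcosm, day, species).
#' @seealso [read_timeseries()], [write_timeseries()], [validate_design()]
#' @export
hoi_timeseries <- function(df) {
  errs <- validate_timeseries(df)
  if (length(errs) > 0) {
    stop("invalid abundance table:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  df <- df[, c("microcosm_id", "treatment", "replicate", "day",
               "species", "density")]
  df <- df[order(df$microcosm_id, df$day, match(df$species, SPECIES_CODES)), ]
  rownames(df) <- NULL
  class(df) <- c("hoi_ts", "data.frame")
  df
}

#' List invariant violations of an abundance table
#'
#' Validation is total: any data frame either passes every invariant or
#' yields at least one named violation; no exception is thrown here.
#'
#' @param df A data frame (candidate abundance table).
#' @return Character vector of violations; empty if the table is valid.
#' @export
validate_timeseries <- function(df) {
  errs <- character(0)
  required <- c("microcosm_id", "treatment", "replicate", "day",
                "species", "density")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    return(sprintf("missing column '%s'", missing_cols))
  }
  if (nrow(df) == 0) return(errs)

  if (!is.numeric(df$density)) {
    errs <- c(errs, "column 'density' is not numeric")
  } else {
    bad <- which(!is.finite(df$density) | df$density < 0)
    if (length(bad) > 0) {
      errs <- c(errs, sprintf(
        "negative or non-finite density at row(s) %s",
        paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (!is.numeric(df$day) || any(!is.finite(df$day)) || any(df$day < 0)) {
    errs <- c(errs, "column 'day' must be finite non-negative numbers")
  }
  unknown_sp <- setdiff(unique(df$species), SPECIES_CODES)
  if (length(unknown_sp) > 0) {
    errs <- c(errs, sprintf("unknown species code(s): %s",
                            paste(unknown_sp, collapse = ", ")))
  }

  key <- paste(df$microcosm_id, df$day, df$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    errs <- c(errs, sprintf(
      "duplicate (microcosm, day, species) at row(s) %s",
      paste(utils::head(dup, 5), collapse = ", ")))
  }

  # species must belong to the treatment's community (known treatments only)
  for (tr in unique(df$treatment)) {
    if (!is_known_treatment(tr)) next
    extra <- setdiff(unique(df$species[df$treatment == tr]),
                     TREATMENT_SPECIES[[tr]])
    if (length(extra) > 0) {
      errs <- c(errs, sprintf("species %s not part of treatment %s",
                              paste(extra, collapse = ", "), tr))
    }
  }

  # identical day grid across species within each microcosm
  for (m in unique(df$microcosm_id)) {
    sub <- df[df$microcosm_id == m, ]
    grids <- tapply(sub$day, sub$species, function(d) paste(sort(d), collapse = ","))
    if (length(unique(grids)) > 1) {
      errs <- c(errs, sprintf(
        "microcosm %s: sampling days differ across species", m))
    }
  }
  errs
}

#' Read an abundance time series from CSV
#'
#' Reads a long-format CSV (UTF-8, header row, "." decimal separator) and
#' returns a validated [hoi_timeseries()] table. Files with non-canonical
#' column names are supported through `schema`, a named character vector
#' mapping canonical names to the file's column names, e.g.
#' `c(microcosm_id = "jar", density = "indiv_per_ml")`.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (`microcosm_id`, `treatment`, `replicate`, `day`, `species`,
#'   `density`) to the file's column names.
#' @return An `hoi_ts` data frame.
#' @export
read_timeseries <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop(sprintf("schema error: column '%s' (mapped to '%s') not in file",
                     src, canon), call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  required <- c("microcosm_id", "treatment", "replicate", "day",
                "species", "density")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }
  df$day <- as.numeric(df$day)
  df$density <- as.numeric(df$density)
  hoi_timeseries(df)
}

#' Write an abundance time series to CSV
#'
#' Writes the canonical long format: header
#' `microcosm_id,treatment,replicate,day,species,density`, one observation
#' per row, rows ordered by (microcosm, day, species).
#'
#' @param table An `hoi_ts` table (or a data frame accepted by
#'   [hoi_timeseries()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(table, path) {
  if (!inherits(table, "hoi_ts")) table <- hoi_timeseries(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Cross-check a table against the experimental design
#'
#' Produces a report (never an error) describing how well a table matches
#' the 6-treatment x 4-replicate design: per-treatment replicate counts,
#' the sampling-day grid, and any species missing from each treatment's
#' expected community.
#'
#' @param table An `hoi_ts` table.
#' @param replicates Expected replicates per treatment (default 4).
#' @return A list of class `hoi_design_report` with elements
#'   `n_microcosms`, `replicate_counts`, `expected_replicates`,
#'   `sampling_days`, `grid_consistent`, `missing_species`, `complete`.
#' @export
validate_design <- function(table, replicates = 4) {
  stopifnot(inherits(table, "hoi_ts") || is.data.frame(table))
  units <- unique(table[, c("microcosm_id", "treatment")])
  counts <- integer(length(TREATMENT_SPECIES))
  names(counts) <- names(TREATMENT_SPECIES)
  tab <- table(units$treatment)
  counts[names(tab)[names(tab) %in% names(counts)]] <-
    as.integer(tab[names(tab) %in% names(counts)])

  grids <- tapply(table$day, table$microcosm_id,
                  function(d) paste(sort(unique(d)), collapse = ","))
  grid_consistent <- length(unique(grids)) <= 1
  days <- sort(unique(table$day))

  missing_sp <- list()
  for (tr in intersect(unique(table$treatment), names(TREATMENT_SPECIES))) {
    seen <- unique(table$species[table$treatment == tr])
    miss <- setdiff(TREATMENT_SPECIES[[tr]], seen)
    if (length(miss) > 0) missing_sp[[tr]] <- miss
  }

  out <- list(
    n_microcosms = nrow(units),
    replicate_counts = counts,
    expected_replicates = replicates,
    sampling_days = days,
    grid_consistent = grid_consistent,
    missing_species = missing_sp,
    complete = all(counts == replicates) && grid_consistent &&
      length(missing_sp) == 0
  )
  class(out) <- "hoi_design_report"
  out
}

#' @export
print.hoi_design_report <- function(x, ...) {
  cat("Design report:", x$n_microcosms, "microcosm(s)\n")
  cat("Replicates per treatment (expected ", x$expected_replicates, "):\n",
      sep = "")
  print(x$replicate_counts)
  cat("Sampling days:", length(x$sampling_days), "per microcosm",
      if (!x$grid_consistent) "(grid differs across microcosms!)" else "",
      "\n")
  if (length(x$missing_species) > 0) {
    for (tr in names(x$missing_species)) {
      cat("Treatment", tr, "missing species:",
          paste(x$missing_species[[tr]], collapse = ", "), "\n")
    }
  }
  cat(if (x$complete) "Design complete.\n" else "Design incomplete.\n")
  invisible(x)
}
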