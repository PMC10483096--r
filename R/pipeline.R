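#' Configure an end-to-end analysis run
#'
#' Collects every option of the simulate -> growth-rates -> fit -> select
#' -> survival -> abundance pipeline in one validated list. All
#' randomness flows from the single `seed`.
#'
#' @param seed Integer root seed.
#' @param replicates Microcosms per treatment when simulating (default 4).
#' @param focal_species Focal species for interaction-strength estimation
#'   (default C and D).
#' @param survival_species Species whose persistence is analyzed (default
#'   C, D and the predator).
#' @param growth_method Response convention of [compute_growth_rates()].
#' @param study_end Censoring time for survival extraction (days).
#' @param sim Optional named list of `hoi_sim_params` per treatment;
#'   defaults to [default_sim_params()] for each.
#' @param obs Observation parameters ([obs_params()]).
#' @param data Optional `hoi_ts` table of real data; when supplied the
#'   simulation stage is skipped.
#' @param pairwise_adjust Multiplicity adjustment for pairwise log-rank
#'   tests (`"BH"` or `"none"`).
#' @param out_dir Optional directory: when set, [run_pipeline()] writes
#'   CSV/JSON artifacts and a manifest there.
#' @return A list of class `hoi_config`.
#' @export
pipeline_config <- function(seed = 1, replicates = 4,
                            focal_species = c("C", "D"),
                            survival_species = c("C", "D", "Pd"),
                            growth_method = "ratio_per_day",
                            study_end = 53,
                            sim = NULL, obs = obs_params(),
                            data = NULL,
                            pairwise_adjust = "BH",
                            out_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  focal_species <- match.arg(focal_species, SPECIES_CODES, several.ok = TRUE)
  survival_species <- match.arg(survival_species, SPECIES_CODES,
                                several.ok = TRUE)
  structure(list(
    seed = as.integer(seed), replicates = replicates,
    focal_species = focal_species, survival_species = survival_species,
    growth_method = growth_method, study_end = study_end,
    sim = sim, obs = obs, data = data,
    pairwise_adjust = pairwise_adjust, out_dir = out_dir
  ), class = "hoi_config")
}

#' Run the full analysis pipeline
#'
#' Executes, deterministically for a given seed: (1) synthetic study
#' generation (unless real data are supplied), (2) design validation,
#' (3) growth-rate computation and the six-model fit + AICc selection for
#' every focal species in every predator-free community — predator
#' treatments are never fitted — and (4) Kaplan-Meier persistence
#' analysis with log-rank tests (pairwise comparisons when the overall
#' test is significant), plus (5) the two-factor abundance effect
#' analysis per species. When `config$out_dir` is set, artifacts
#' (`data.csv`, `selection.csv`, `survival.json`, `abundance.csv`,
#' `manifest.json`) are written there.
#'
#' @param config An `hoi_config` from [pipeline_config()].
#' @return A list of class `hoi_run`: `data`, `design_report`,
#'   `selections` (list of `hoi_selection`), `selection_table`,
#'   `survival` (per species: `data`, `km` per group, `logrank`,
#'   `pairwise`), `abundance` (`summaries`, `effects`), `log` (stage
#'   counts), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "hoi_config"))
  log <- list()

  ## stage: data
  data <- if (!is.null(config$data)) {
    if (!inherits(config$data, "hoi_ts")) hoi_timeseries(config$data)
    else config$data
  } else {
    generate_study(params_by_treatment = config$sim, obs = config$obs,
                   replicates = config$replicates, seed = config$seed)
  }
  design_report <- validate_design(data, replicates = config$replicates)
  log$n_microcosms <- design_report$n_microcosms
  log$n_records <- nrow(data)

  ## stage: interaction strengths (predator-free communities only)
  pf_communities <- intersect(
    Filter(function(tr) !treatment_info(tr)$predator_present,
           treatment_codes()),
    unique(data$treatment))
  selections <- list()
  n_obs_total <- 0
  for (focal in config$focal_species) {
    growth <- suppressWarnings(
      compute_growth_rates(data, focal, method = config$growth_method))
    for (comm in pf_communities) {
      if (!focal %in% treatment_info(comm)$consumers) next
      obs_comm <- growth[growth$treatment == comm, , drop = FALSE]
      if (nrow(obs_comm) == 0) next
      reg <- assemble_regression_table(obs_comm, comm)
      n_obs_total <- n_obs_total + nrow(reg)
      fits <- suppressWarnings(fit_all_models(reg, focal, comm))
      sel <- tryCatch(select_model(fits), error = function(e) NULL)
      if (!is.null(sel)) {
        selections[[paste(focal, comm, sep = "_")]] <- sel
      }
    }
  }
  log$n_growth_observations <- n_obs_total
  selection_table <- selection_report(selections)

  ## stage: persistence
  surv <- list()
  for (sp in config$survival_species) {
    sdat <- suppressWarnings(
      extract_survival(data, sp, study_end = config$study_end))
    if (nrow(sdat) == 0) next
    # compare within predator stratum: prey across predator-free and
    # predator-bearing communities separately; predator across its hosts
    strata <- split(sdat, vapply(sdat$group, function(tr) {
      if (treatment_info(tr)$predator_present) "predator" else "competitive"
    }, character(1)))
    res <- list(data = sdat)
    for (st in names(strata)) {
      block <- strata[[st]]
      entry <- list(
        km = lapply(split(block, block$group), km_estimate))
      if (length(unique(block$group)) >= 2) {
        lr <- logrank_test(block)
        entry$logrank <- lr
        if (lr$p_value < 0.05 && length(unique(block$group)) >= 3) {
          entry$pairwise <- pairwise_logrank(
            block, adjust = config$pairwise_adjust)
        }
      }
      res[[st]] <- entry
    }
    surv[[sp]] <- res
  }

  ## stage: abundance
  summaries <- summarize_abundance(data)
  effects <- list()
  for (sp in intersect(unique(summaries$species), SPECIES_CODES)) {
    effects[[sp]] <- tryCatch(abundance_effects(summaries, sp),
                              error = function(e) NULL)
  }

  manifest <- list(
    package = "hoiscan",
    version = as.character(utils::packageVersion("hoiscan")),
    seed = config$seed,
    replicates = config$replicates,
    growth_method = config$growth_method,
    simulated = is.null(config$data),
    n_microcosms = log$n_microcosms,
    n_records = log$n_records,
    n_growth_observations = log$n_growth_observations,
    n_selections = length(selections)
  )

  result <- structure(list(
    data = data, design_report = design_report,
    selections = selections, selection_table = selection_table,
    survival = surv,
    abundance = list(summaries = summaries, effects = effects),
    log = log, manifest = manifest
  ), class = "hoi_run")

  if (!is.null(config$out_dir)) write_run_artifacts(result, config)
  result
}

write_run_artifacts <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_timeseries(result$data, out("data.csv"))
  utils::write.csv(result$selection_table, out("selection.csv"),
                   row.names = FALSE)
  utils::write.csv(result$abundance$summaries, out("abundance.csv"),
                   row.names = FALSE)
  surv_json <- lapply(result$survival, function(res) {
    lapply(res[setdiff(names(res), "data")], function(entry) {
      o <- list(km = lapply(entry$km, function(k) as.data.frame(k)))
      if (!is.null(entry$logrank)) {
        o$logrank <- entry$logrank[c("statistic", "df", "p_value")]
      }
      if (!is.null(entry$pairwise)) o$pairwise <- entry$pairwise
      o
    })
  })
  jsonlite::write_json(surv_json, out("survival.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- result$manifest
  manifest$config_hash <- unname(tools::md5sum(out("data.csv")))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' @export
print.hoi_run <- function(x, ...) {
  cat("<hoi_run>\n")
  cat("  microcosms:", x$log$n_microcosms,
      "| records:", x$log$n_records, "\n")
  cat("  growth observations:", x$log$n_growth_observations, "\n")
  cat("  model selections:", length(x$selections), "\n")
  for (nm in names(x$selections)) {
    s <- x$selections[[nm]]
    cat(sprintf("    %s/%s -> %s\n", s$focal, s$community,
                s$most_parsimonious_model))
  }
  cat("  survival analyses:", paste(names(x$survival), collapse = ", "),
      "\n")
  invisible(x)
}
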