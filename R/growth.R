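#' Per-capita growth-rate observations
#'
#' Converts an abundance time series into one regression observation per
#' consecutive sample pair for a focal species. The default response is
#' the interval-scaled density ratio
#'
#'   r = (N_{t+dt} / N_t) / dt              (`method = "ratio_per_day"`)
#'
#' which is the response the discrete LV/Ricker model equations predict;
#' the log-ratio convention common in time-series helper packages,
#'
#'   r = ln(N_{t+dt} / N_t) / dt            (`method = "log_ratio_per_day"`)
#'
#' is also available. Transitions with N_t = 0 are always dropped (the
#' per-capita rate is undefined at zero); under the log method transitions
#' with N_{t+dt} = 0 are dropped too. Covariates are the densities of the
#' community's consumer species at the interval start t.
#'
#' Predator-bearing treatments are excluded by default, mirroring the
#' restriction of interaction-strength estimation to predator-free
#' communities (predators drove prey extinct too early for the growth
#' regression to be meaningful).
#'
#' @param table An `hoi_ts` abundance table.
#' @param focal Focal species code.
#' @param method Response convention (see above).
#' @param include_predator_treatments If `TRUE`, predator treatments are
#'   retained (the predator's density is then also a covariate).
#' @return A data frame of class `hoi_growth` with columns `microcosm_id`,
#'   `treatment`, `focal`, `t`, `dt`, `r`, `method` and one density column
#'   `N_<sp>` per covariate species (NA where a species is not part of a
#'   row's community).
#' @export
compute_growth_rates <- function(table, focal,
                                 method = c("ratio_per_day",
                                            "log_ratio_per_day"),
                                 include_predator_treatments = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(table, "hoi_ts") || is.data.frame(table))
  focal <- match.arg(focal, SPECIES_CODES)

  tab <- as.data.frame(table)
  if (!include_predator_treatments) {
    keep <- !vapply(tab$treatment, function(tr) {
      is_known_treatment(tr) && treatment_info(tr)$predator_present
    }, logical(1))
    tab <- tab[keep, , drop = FALSE]
  }
  if (nrow(tab) == 0) {
    stop("no data left after excluding predator treatments", call. = FALSE)
  }

  cov_species <- canonical_species_order(unique(tab$species))
  if (!include_predator_treatments) {
    cov_species <- setdiff(cov_species, PREDATOR_CODE)
  }

  rows <- list()
  for (m in unique(tab$microcosm_id)) {
    sub <- tab[tab$microcosm_id == m, ]
    if (!focal %in% sub$species) {
      warning("focal species ", focal, " absent from microcosm ", m,
              "; skipped", call. = FALSE)
      next
    }
    days <- sort(unique(sub$day))
    if (length(days) < 2) next
    # wide species x day matrix of densities
    wide <- matrix(NA_real_, length(unique(sub$species)), length(days),
                   dimnames = list(unique(sub$species), as.character(days)))
    wide[cbind(sub$species, as.character(sub$day))] <- sub$density

    nf <- wide[focal, ]
    for (s in seq_len(length(days) - 1L)) {
      n0 <- nf[s]; n1 <- nf[s + 1L]
      dts <- days[s + 1L] - days[s]
      if (is.na(n0) || n0 <= 0) next
      if (method == "log_ratio_per_day" && n1 <= 0) next
      r <- if (method == "ratio_per_day") (n1 / n0) / dts
           else log(n1 / n0) / dts
      covs <- stats::setNames(rep(NA_real_, length(cov_species)),
                              paste0("N_", cov_species))
      present <- intersect(cov_species, rownames(wide))
      covs[paste0("N_", present)] <- wide[present, s]
      rows[[length(rows) + 1L]] <- data.frame(
        microcosm_id = m, treatment = sub$treatment[1], focal = focal,
        t = days[s], dt = dts, r = r, as.list(covs),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(microcosm_id = character(0), treatment = character(0),
                      focal = character(0), t = numeric(0), dt = numeric(0),
                      r = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$microcosm_id, out$t), ]
    rownames(out) <- NULL
  }
  attr(out, "method") <- method
  class(out) <- c("hoi_growth", "data.frame")
  out
}

#' Assemble the regression table for one community
#'
#' Restricts growth observations to a single community composition and
#' returns the rectangular table consumed by the model fits: the response
#' `r` plus one named density column per consumer species, in canonical
#' order (C, D, then the third species). Rows are ordered by
#' (microcosm, t), so the result is invariant to input row order.
#'
#' @param observations An `hoi_growth` data frame.
#' @param community Treatment code of the (predator-free) community.
#' @return A data frame with columns `microcosm_id`, `t`, `r` and the
#'   community's `N_<sp>` columns; attributes `community`, `focal`,
#'   `method`.
#' @export
assemble_regression_table <- function(observations, community) {
  stopifnot(is.data.frame(observations))
  community <- match.arg(community, treatment_codes())
  trts <- unique(observations$treatment)
  if (length(setdiff(trts, community)) > 0) {
    stop("observations contain communities other than ", community, ": ",
         paste(setdiff(trts, community), collapse = ", "),
         "; filter or recompute per community", call. = FALSE)
  }
  obs <- observations[observations$treatment == community, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations for community ", community,
                           call. = FALSE)
  consumers <- treatment_info(community)$consumers
  cols <- paste0("N_", canonical_species_order(consumers))
  missing_cols <- setdiff(cols, names(obs))
  if (length(missing_cols) > 0) {
    stop("observations lack density column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- obs[order(obs$microcosm_id, obs$t),
             c("microcosm_id", "t", "r", cols)]
  rownames(out) <- NULL
  attr(out, "community") <- community
  attr(out, "focal") <- unique(obs$focal)
  attr(out, "method") <- attr(observations, "method")
  out
}
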