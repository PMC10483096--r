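#' Extract extinction times with right-censoring
#'
#' For each microcosm containing the species, the extinction time is the
#' first sampled day of a terminal run of zeros — i.e. a day with observed
#' density 0 such that every later sample is also 0. A single zero
#' followed by detections is treated as a detection failure of the small
#' subsample volume, not an extinction. Units whose species is still
#' present at the last sample (or that rebounded) are right-censored at
#' `study_end`: the extinction, if any, lies beyond the recorded window.
#'
#' @param table An `hoi_ts` abundance table.
#' @param species Species code whose persistence is analyzed.
#' @param study_end Censoring time in days (default 53, the study length).
#' @return A data frame of class `hoi_survival`: `unit_id`, `group`
#'   (treatment code), `species`, `time`, `event` (`TRUE` = extinction
#'   observed).
#' @export
extract_survival <- function(table, species, study_end = 53) {
  stopifnot(inherits(table, "hoi_ts") || is.data.frame(table))
  species <- match.arg(species, SPECIES_CODES)
  tab <- as.data.frame(table)
  tab <- tab[tab$species == species, , drop = FALSE]
  if (nrow(tab) == 0) {
    warning("species ", species, " absent from every microcosm",
            call. = FALSE)
    return(structure(data.frame(unit_id = character(0),
                                group = character(0),
                                species = character(0),
                                time = numeric(0), event = logical(0)),
                     class = c("hoi_survival", "data.frame")))
  }
  rows <- lapply(split(tab, tab$microcosm_id), function(sub) {
    sub <- sub[order(sub$day), ]
    if (all(sub$density == 0)) return(NULL) # never established
    last_pos <- max(which(sub$density > 0))
    if (last_pos == nrow(sub)) {
      time <- study_end; event <- FALSE
    } else {
      time <- sub$day[last_pos + 1L]; event <- TRUE
    }
    data.frame(unit_id = sub$microcosm_id[1], group = sub$treatment[1],
               species = species, time = time, event = event,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("hoi_survival", "data.frame")
  out
}

#' Kaplan-Meier estimate of persistence
#'
#' Product-limit estimator S(t) = prod_{t_i <= t} (1 - d_i/n_i) with 95%
#' confidence bands from the Greenwood variance on the log-survival
#' scale. A time-zero row (S = 1, everyone at risk) is prepended so the
#' curve starts at 1.
#'
#' @param data An `hoi_survival` data frame (columns `time`, `event`).
#' @return A data frame of class `hoi_km`: `time`, `at_risk`, `n_events`,
#'   `survival`, `ci_lower`, `ci_upper`.
#' @export
km_estimate <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = data, conf.type = "log")
  out <- data.frame(
    time = c(0, sf$time),
    at_risk = c(nrow(data), sf$n.risk),
    n_events = c(0, sf$n.event),
    survival = c(1, sf$surv),
    ci_lower = c(1, ifelse(is.na(sf$lower), 0, sf$lower)),
    ci_upper = c(1, ifelse(is.na(sf$upper), 1, sf$upper))
  )
  class(out) <- c("hoi_km", "data.frame")
  out
}

#' k-group log-rank test
#'
#' Standard observed-vs-expected log-rank chi-square comparing survival
#' across the `group` levels, with df = number of groups - 1 and the
#' p-value from the chi-square upper tail.
#'
#' @param data An `hoi_survival` data frame with >= 2 groups, each with
#'   at least one unit.
#' @return A list of class `hoi_logrank`: `statistic`, `df`, `p_value`,
#'   `groups`.
#' @export
logrank_test <- function(data) {
  stopifnot(is.data.frame(data))
  groups <- unique(data$group)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  counts <- table(data$group)
  if (any(counts == 0)) stop("every group needs >= 1 unit", call. = FALSE)
  stat <- tryCatch(
    as.numeric(survival::survdiff(survival::Surv(time, event) ~ group,
                                  data = data)$chisq),
    # degenerate configurations (e.g. every unit sharing one event time)
    # make the O-E covariance singular; fall back to the generalized
    # inverse form of the same statistic
    error = function(e) logrank_ginv(data))
  df <- length(groups) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 groups = sort(groups)),
            class = "hoi_logrank")
}

#' @export
print.hoi_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g (groups: %s)\n",
              x$statistic, x$df, x$p_value,
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

# k-group log-rank statistic (O-E)' V^- (O-E) with a Moore-Penrose
# inverse, defined for singular V (zero-variance tables give statistic 0)
logrank_ginv <- function(data) {
  groups <- sort(unique(data$group))
  k <- length(groups)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(data$time[data$event]))) {
    at_risk <- data$time >= t
    n_t <- sum(at_risk)
    d_t <- sum(data$event & data$time == t)
    n_gt <- vapply(groups, function(g)
      sum(at_risk & data$group == g), numeric(1))
    d_gt <- vapply(groups, function(g)
      sum(data$event & data$time == t & data$group == g), numeric(1))
    O <- O + d_gt
    E <- E + d_t * n_gt / n_t
    if (n_t > 1) {
      p <- n_gt / n_t
      V <- V + d_t * (n_t - d_t) / (n_t - 1) *
        (diag(p, k) - outer(p, p))
    }
  }
  d <- O - E
  as.numeric(t(d) %*% MASS::ginv(V) %*% d)
}

#' Pairwise log-rank comparisons
#'
#' Tests every unordered pair of groups with [logrank_test()] and adjusts
#' the p-values for multiplicity (Benjamini-Hochberg by default).
#'
#' @param data An `hoi_survival` data frame with >= 2 groups.
#' @param adjust `"BH"` (default) or `"none"`.
#' @return A symmetric matrix of adjusted p-values (diagonal `NA`).
#' @export
pairwise_logrank <- function(data, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  groups <- sort(unique(data$group))
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  cmb <- utils::combn(groups, 2)
  raw <- apply(cmb, 2, function(pr) {
    logrank_test(data[data$group %in% pr, , drop = FALSE])$p_value
  })
  adj <- if (adjust == "BH") stats::p.adjust(raw, method = "BH") else raw
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_len(ncol(cmb))) {
    m[cmb[1, i], cmb[2, i]] <- adj[i]
    m[cmb[2, i], cmb[1, i]] <- adj[i]
  }
  m
}
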