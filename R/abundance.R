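#' Per-microcosm mean abundance
#'
#' Mean density of each species in each microcosm over every sampling day
#' of the study, zeros included, with the standard error of that mean
#' across sampling days.
#'
#' @param table An `hoi_ts` abundance table.
#' @return A data frame with one row per (species, microcosm): `species`,
#'   `treatment`, `replicate`, `microcosm_id`, `mean_density`, `sem`,
#'   `n_days`.
#' @export
summarize_abundance <- function(table) {
  stopifnot(inherits(table, "hoi_ts") || is.data.frame(table))
  tab <- as.data.frame(table)
  key <- interaction(tab$species, tab$microcosm_id, drop = TRUE)
  rows <- lapply(split(tab, key), function(sub) {
    n <- nrow(sub)
    data.frame(
      species = sub$species[1], treatment = sub$treatment[1],
      replicate = sub$replicate[1], microcosm_id = sub$microcosm_id[1],
      mean_density = mean(sub$density),
      sem = if (n > 1) stats::sd(sub$density) / sqrt(n) else 0,
      n_days = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$species, SPECIES_CODES), out$microcosm_id), ]
  rownames(out) <- NULL
  out
}

#' Two-factor effect analysis of mean abundance
#'
#' Models one species' per-microcosm mean densities as a function of the
#' identity of the third community member (none, Paramecium or
#' Spirostomum) crossed with predator presence: a least-squares linear
#' model with interaction on the transformed scale, reported as effect
#' estimates b with normal-theory 95% confidence intervals plus the
#' two-way ANOVA F table. The default transform is log10(mean + 1); mean
#' densities span orders of magnitude, and the +1 offset keeps empty
#' microcosms finite.
#'
#' @param summaries Output of [summarize_abundance()].
#' @param species Species whose abundance is analyzed.
#' @param transform `"log10p1"` (default) or `"identity"`.
#' @return A list of class `hoi_effects`: `species`, `transform`,
#'   `effects` (term, b, ci_lower, ci_upper, n), `anova` (factor F-tests),
#'   `fit` (the underlying `lm`).
#' @export
abundance_effects <- function(summaries, species,
                              transform = c("log10p1", "identity")) {
  transform <- match.arg(transform)
  species <- match.arg(species, SPECIES_CODES)
  dat <- summaries[summaries$species == species, , drop = FALSE]
  if (nrow(dat) == 0) stop("no summaries for species ", species,
                           call. = FALSE)

  third_of <- c(CD = "none", CDPd = "none", CDP = "P", CDPPd = "P",
                CDS = "S", CDSPd = "S")
  unknown <- setdiff(unique(dat$treatment), names(third_of))
  if (length(unknown) > 0) {
    stop("unknown treatment code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dat$third <- factor(third_of[dat$treatment],
                      levels = intersect(c("none", "P", "S"),
                                         third_of[unique(dat$treatment)]))
  dat$predator <- factor(
    ifelse(vapply(dat$treatment,
                  function(tr) treatment_info(tr)$predator_present,
                  logical(1)), "present", "absent"),
    levels = c("absent", "present"))
  dat$predator <- droplevels(dat$predator)
  if (nlevels(dat$third) < 2 || nlevels(dat$predator) < 2) {
    stop("degenerate design: both factors need >= 2 levels ",
         "(third-species levels: ", nlevels(dat$third),
         ", predator levels: ", nlevels(dat$predator), ")", call. = FALSE)
  }

  dat$y <- switch(transform,
                  log10p1 = log10(dat$mean_density + 1),
                  identity = dat$mean_density)
  fit <- stats::lm(y ~ third * predator, data = dat)
  ci <- stats::confint(fit)
  n_cell <- min(table(dat$third, dat$predator))
  effects <- data.frame(
    term = names(stats::coef(fit)),
    b = unname(stats::coef(fit)),
    ci_lower = ci[, 1], ci_upper = ci[, 2],
    n = n_cell, stringsAsFactors = FALSE)
  rownames(effects) <- NULL

  structure(list(species = species, transform = transform,
                 effects = effects, anova = stats::anova(fit), fit = fit),
            class = "hoi_effects")
}

#' @export
print.hoi_effects <- function(x, ...) {
  cat(sprintf("Abundance effects for %s (scale: %s)\n",
              x$species, x$transform))
  eff <- x$effects
  eff$b <- round(eff$b, 3)
  eff$ci_lower <- round(eff$ci_lower, 3)
  eff$ci_upper <- round(eff$ci_upper, 3)
  print(eff, row.names = FALSE)
  invisible(x)
}
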