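#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1). The correction term
#' requires n > K + 1; it vanishes as n grows, recovering plain AIC.
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated parameters (intercept, slopes and the
#'   Gaussian dispersion).
#' @param n Number of observations.
#' @return The AICc value (vectorized over its arguments).
#' @examples
#' aicc(0, 2, 10) # 4 + 12/7
#' @export
aicc <- function(loglik, K, n) {
  if (any(n <= K + 1)) {
    stop("AICc undefined: need n > K + 1 (correction term denominator)",
         call. = FALSE)
  }
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank fits by AICc and apply the parsimony rule
#'
#' Computes each converged fit's AICc and its difference dAICc to the
#' minimum. Models within dAICc < 2 of the best are treated as equally
#' supported; among them the model with the fewest parameters K is the
#' most parsimonious and is reported as the selected model. Ties on K are
#' broken by lower AICc, then by a fixed model-name order, so selection
#' is deterministic. Non-converged fits are excluded from the ranking and
#' listed, never silently crowned by competitor failure.
#'
#' @param fits An `hoi_fits` list (or any list of `hoi_fit` objects
#'   sharing one observation set).
#' @return A list of class `hoi_selection`: `table` (model, family,
#'   hoi_structure, K, AICc, dAICc, parsimonious flag; sorted by AICc),
#'   `best_aicc_model`, `most_parsimonious_model`, `excluded`, `focal`,
#'   `community`, `n_obs`.
#' @export
select_model <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) {
    stop("no converged fits to select among", call. = FALSE)
  }
  ns <- unique(vapply(conv, `[[`, numeric(1), "n_obs"))
  if (length(ns) != 1) {
    stop("fits do not share one observation set (n_obs differ)",
         call. = FALSE)
  }
  tab <- data.frame(
    model = vapply(conv, function(f) f$spec$name, character(1)),
    family = vapply(conv, function(f) f$spec$family, character(1)),
    hoi_structure = vapply(conv, function(f) f$spec$hoi_structure,
                           character(1)),
    K = vapply(conv, `[[`, integer(1), "K"),
    AICc = vapply(conv, function(f) aicc(f$loglik, f$K, f$n_obs),
                  numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$dAICc <- tab$AICc - min(tab$AICc)
  candidate <- tab$dAICc < 2
  ord <- order(!candidate, tab$K, tab$AICc, match(tab$model, MODEL_NAMES))
  winner <- tab$model[ord[1]]
  tab$parsimonious <- tab$model == winner
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL

  excluded <- setdiff(vapply(fits, function(f) f$spec$name, character(1)),
                      tab$model)
  structure(list(
    table = tab,
    best_aicc_model = tab$model[1],
    most_parsimonious_model = winner,
    excluded = excluded,
    focal = attr(fits, "focal") %||% conv[[1]]$focal,
    community = attr(fits, "community") %||% conv[[1]]$community,
    n_obs = ns
  ), class = "hoi_selection")
}

#' @export
print.hoi_selection <- function(x, ...) {
  cat(sprintf("Model selection | focal %s | community %s | n = %d\n",
              x$focal %||% "?", x$community %||% "?", x$n_obs))
  tab <- x$table
  tab$AICc <- round(tab$AICc, 2)
  tab$dAICc <- round(tab$dAICc, 2)
  print(tab[, c("model", "K", "AICc", "dAICc", "parsimonious")],
        row.names = FALSE)
  if (length(x$excluded) > 0) {
    cat("excluded (not converged):", paste(x$excluded, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Combine selections into a report table
#'
#' Stacks several per-(focal, community) selections into one long table
#' mirroring the layout of a model-selection results table: one row per
#' focal species x community x model with K, AICc, dAICc and the
#' most-parsimonious flag.
#'
#' @param selections A list of `hoi_selection` objects (a single one is
#'   also accepted).
#' @return A data frame with columns `focal`, `community`, `model`,
#'   `family`, `hoi_structure`, `K`, `AICc`, `dAICc`, `parsimonious`.
#' @export
selection_report <- function(selections) {
  if (inherits(selections, "hoi_selection")) selections <- list(selections)
  if (length(selections) == 0) {
    return(data.frame(focal = character(0), community = character(0),
                      model = character(0), family = character(0),
                      hoi_structure = character(0), K = integer(0),
                      AICc = numeric(0), dAICc = numeric(0),
                      parsimonious = logical(0)))
  }
  rows <- lapply(selections, function(s) {
    cbind(data.frame(focal = s$focal %||% NA_character_,
                     community = s$community %||% NA_character_,
                     stringsAsFactors = FALSE),
          s$table)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
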