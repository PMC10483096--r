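MODEL_NAMES <- c("additive_LV", "interactive_LV_intra",
                 "interactive_LV_inter", "interactive_LV_full",
                 "additive_Ricker", "interactive_Ricker")

#' The six competition model structures
#'
#' The candidate set compares additive (pairwise-only) and interactive
#' (HOI-bearing) forms of two discrete-time growth models:
#'
#' | name                 | family | HOI terms        | link     |
#' |----------------------|--------|------------------|----------|
#' | additive_LV          | LV     | none             | identity |
#' | interactive_LV_intra | LV     | quadratic N_j^2  | identity |
#' | interactive_LV_inter | LV     | cross N_j N_k    | identity |
#' | interactive_LV_full  | LV     | both             | identity |
#' | additive_Ricker      | Ricker | none             | log      |
#' | interactive_Ricker   | Ricker | cross N_j N_k    | log      |
#'
#' All are fitted by Gaussian maximum likelihood: the LV (identity-link)
#' models are linear regressions of the growth-rate response on densities,
#' the Ricker (log-link) models regress the response on densities through
#' an exponential mean.
#'
#' @return `model_specs()` returns a data frame describing all six models;
#'   `model_spec(name)` returns one spec as a list.
#' @export
model_specs <- function() {
  data.frame(
    name = MODEL_NAMES,
    family = c("LV", "LV", "LV", "LV", "Ricker", "Ricker"),
    hoi_structure = c("none", "intra", "inter", "full", "none", "inter"),
    link = c("identity", "identity", "identity", "identity", "log", "log"),
    stringsAsFactors = FALSE
  )
}

#' @rdname model_specs
#' @param name One of the six model names.
#' @export
model_spec <- function(name) {
  name <- match.arg(name, MODEL_NAMES)
  specs <- model_specs()
  as.list(specs[specs$name == name, ])
}

#' Number of estimated parameters of a model
#'
#' Closed-form parameter count K for a community of `n_species`
#' consumers: the intercept (lambda), one linear slope per species, one
#' quadratic slope per species for intraspecific HOIs, one cross-product
#' slope per unordered species pair for interspecific HOIs, plus the
#' Gaussian dispersion. Counting the intercept and the dispersion is the
#' convention under which the model-selection table's K values are exact:
#'
#'   additive:            K = 2 + n
#'   intra HOI:           K = 2 + 2n
#'   inter HOI / i.Ricker K = 2 + n + choose(n, 2)
#'   full HOI:            K = 2 + 2n + choose(n, 2)
#'
#' @param spec A model name or the result of [model_spec()].
#' @param n_species Number of consumer species (>= 1).
#' @return Integer K.
#' @examples
#' count_parameters("interactive_LV_full", 3) # 11
#' count_parameters("additive_LV", 2)         # 4
#' @export
count_parameters <- function(spec, n_species) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (!is.numeric(n_species) || n_species < 1 ||
      n_species != floor(n_species)) {
    stop("n_species must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_species)
  n_slopes <- switch(spec$hoi_structure,
    none = n,
    intra = 2L * n,
    inter = n + choose(n, 2L),
    full = 2L * n + choose(n, 2L)
  )
  as.integer(2L + n_slopes)
}

#' Build the design matrix for one model
#'
#' Expands a regression table into the model's named predictor columns:
#' linear terms `N_j` for every consumer always; quadratic terms
#' `N_j:N_j` when the HOI structure is `intra` or `full`; cross-product
#' terms `N_j:N_k` (j < k in canonical species order) when it is `inter`
#' or `full`. By default cross terms cover ALL unordered distinct species
#' pairs, including pairs containing the focal species — the counting
#' under which the published parameter counts are reproduced for both
#' focal species; `inter_pairs = "exclude_focal"` restricts to pairs not
#' containing the focal species (the stricter textual reading).
#'
#' @param table Regression table from [assemble_regression_table()] (any
#'   data frame with an `r` column and `N_<sp>` density columns works).
#' @param spec Model name or [model_spec()] list.
#' @param inter_pairs `"all"` (default) or `"exclude_focal"`.
#' @param focal Focal species code; taken from the table's attribute when
#'   omitted. Only needed for `inter_pairs = "exclude_focal"`.
#' @return A list of class `hoi_design`: `response`, `X` (named slope
#'   matrix), `n_obs`, `spec`, `species`, `focal`.
#' @export
build_design <- function(table, spec, inter_pairs = c("all", "exclude_focal"),
                         focal = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  inter_pairs <- match.arg(inter_pairs)
  if (nrow(table) == 0) stop("empty regression table", call. = FALSE)
  if (is.null(focal)) focal <- attr(table, "focal")

  dens_cols <- grep("^N_", names(table), value = TRUE)
  if (length(dens_cols) == 0) stop("no density columns (N_<sp>) in table",
                                   call. = FALSE)
  species <- canonical_species_order(sub("^N_", "", dens_cols))
  dens <- as.matrix(table[, paste0("N_", species), drop = FALSE])
  colnames(dens) <- paste0("N_", species)

  X <- dens
  if (spec$hoi_structure %in% c("intra", "full")) {
    quad <- dens^2
    colnames(quad) <- sprintf("N_%s:N_%s", species, species)
    X <- cbind(X, quad)
  }
  if (spec$hoi_structure %in% c("inter", "full") && length(species) >= 2) {
    cmb <- utils::combn(species, 2)
    if (inter_pairs == "exclude_focal") {
      if (is.null(focal)) stop("focal needed for inter_pairs='exclude_focal'",
                               call. = FALSE)
      keep <- colSums(cmb == focal) == 0
      cmb <- cmb[, keep, drop = FALSE]
    }
    if (ncol(cmb) > 0) {
      cross <- dens[, paste0("N_", cmb[1, ]), drop = FALSE] *
        dens[, paste0("N_", cmb[2, ]), drop = FALSE]
      colnames(cross) <- sprintf("N_%s:N_%s", cmb[1, ], cmb[2, ])
      X <- cbind(X, cross)
    }
  }
  structure(list(response = table$r, X = X, n_obs = nrow(table),
                 spec = spec, species = species, focal = focal),
            class = "hoi_design")
}

#' Fit one model by Gaussian maximum likelihood
#'
#' Identity-link (LV) models are fitted by ordinary least squares, which
#' is the Gaussian MLE. Log-link (Ricker) models maximize the same
#' Gaussian likelihood with mean `exp(intercept + X b)` by iteratively
#' reweighted least squares (deviance tolerance 1e-10, at most 200
#' iterations), started from least squares on `log(pmax(r, eps))` with
#' `eps` = smallest positive response x 1e-3. Observed responses are used
#' as-is, including zeros: a Gaussian error with a log-linked mean admits
#' them.
#'
#' Coefficients are mapped to the ecological sign convention: the
#' intercept gives the intrinsic growth rate (`lambda_hat = intercept`
#' for the identity link, `exp(intercept)` for the log link), and slope
#' coefficients are negated so positive alpha/beta values mean
#' suppression of the focal species' growth.
#'
#' The residual variance uses the MLE denominator n (consistent with the
#' likelihood entering AICc), floored at 1e-12 so degenerate zero-residual
#' fits keep a finite log-likelihood. K counts the intercept, all slope
#' coefficients and the dispersion.
#'
#' @param design An `hoi_design` from [build_design()].
#' @param community Optional treatment code stamped on the result.
#' @return A list of class `hoi_fit`: `spec`, `focal`, `community`,
#'   `lambda_hat`, `alpha_hat`, `beta_intra_hat`, `beta_inter_hat`,
#'   `sigma2_hat`, `n_obs`, `K`, `loglik`, `converged`, `raw_coef`.
#' @export
fit_model <- function(design, community = NA_character_) {
  stopifnot(inherits(design, "hoi_design"))
  y <- design$response
  X <- design$X
  n <- design$n_obs
  p <- ncol(X) + 1L # slopes + intercept
  if (n <= p) {
    stop(sprintf("underdetermined fit: %d observations for %d coefficients",
                 n, p), call. = FALSE)
  }
  Xfull <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xfull)
  if (qrX$rank < p) {
    aliased <- colnames(Xfull)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  if (design$spec$link == "identity") {
    fit <- stats::lm.fit(Xfull, y)
    coefs <- fit$coefficients
    fitted <- Xfull %*% coefs
    converged <- TRUE
  } else {
    pos <- y[y > 0]
    eps <- if (length(pos) > 0) min(pos) * 1e-3 else 1e-6
    start <- stats::lm.fit(Xfull, log(pmax(y, eps)))$coefficients
    start[is.na(start)] <- 0
    fit <- suppressWarnings(stats::glm.fit(
      x = Xfull, y = y, family = stats::gaussian(link = "log"),
      start = start,
      control = stats::glm.control(epsilon = 1e-10, maxit = 200)
    ))
    coefs <- fit$coefficients
    fitted <- fit$fitted.values
    converged <- isTRUE(fit$converged)
  }

  rss <- sum((y - fitted)^2)
  sigma2 <- max(rss / n, 1e-12)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)

  slopes <- coefs[colnames(X)]
  sp <- design$species
  lin <- -slopes[paste0("N_", sp)]
  names(lin) <- sp
  intra_cols <- sprintf("N_%s:N_%s", sp, sp)
  beta_intra <- if (any(intra_cols %in% colnames(X))) {
    stats::setNames(-slopes[intra_cols[intra_cols %in% colnames(X)]],
                    sp[intra_cols %in% colnames(X)])
  } else NULL
  cross_cols <- setdiff(grep(":", colnames(X), value = TRUE), intra_cols)
  beta_inter <- if (length(cross_cols) > 0) {
    stats::setNames(-slopes[cross_cols],
                    gsub("N_", "", cross_cols, fixed = TRUE))
  } else NULL

  K <- 2L + ncol(X)
  structure(list(
    spec = design$spec, focal = design$focal, community = community,
    lambda_hat = if (design$spec$link == "identity") unname(coefs[1])
                 else exp(unname(coefs[1])),
    alpha_hat = lin,
    beta_intra_hat = beta_intra,
    beta_inter_hat = beta_inter,
    sigma2_hat = sigma2, n_obs = n, K = K, loglik = loglik,
    converged = converged, raw_coef = coefs
  ), class = "hoi_fit")
}

#' @export
print.hoi_fit <- function(x, ...) {
  cat(sprintf("<hoi_fit> %s | focal %s | n=%d K=%d logLik=%.3f%s\n",
              x$spec$name, x$focal %||% "?", x$n_obs, x$K, x$loglik,
              if (!x$converged) " (NOT converged)" else ""))
  cat("  lambda_hat:", signif(x$lambda_hat, 5), "\n")
  cat("  alpha_hat: ",
      paste(sprintf("%s=%.4g", names(x$alpha_hat), x$alpha_hat),
            collapse = "  "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit all six models on one observation set
#'
#' Builds and fits every model of [model_specs()] on the identical set of
#' growth observations. A model whose fit fails (e.g. underdetermined or
#' rank-deficient) is recorded with `converged = FALSE` and an `error`
#' message while the remaining models proceed.
#'
#' @param table Regression table from [assemble_regression_table()].
#' @param focal Focal species code (defaults to the table's attribute).
#' @param community Treatment code (defaults to the table's attribute).
#' @param inter_pairs Passed to [build_design()].
#' @return A list of class `hoi_fits` with one element per model name.
#' @export
fit_all_models <- function(table, focal = NULL, community = NULL,
                           inter_pairs = "all") {
  focal <- focal %||% attr(table, "focal")
  community <- community %||% attr(table, "community")
  fits <- lapply(MODEL_NAMES, function(nm) {
    tryCatch({
      des <- build_design(table, nm, inter_pairs = inter_pairs,
                          focal = focal)
      fit_model(des, community = community)
    }, error = function(e) {
      structure(list(spec = model_spec(nm), focal = focal,
                     community = community, converged = FALSE,
                     error = conditionMessage(e), n_obs = nrow(table),
                     K = NA_integer_, loglik = NA_real_),
                class = "hoi_fit")
    })
  })
  names(fits) <- MODEL_NAMES
  failed <- vapply(fits, function(f) !isTRUE(f$converged), logical(1))
  if (any(failed)) {
    warning("model(s) did not fit/converge: ",
            paste(MODEL_NAMES[failed], collapse = ", "), call. = FALSE)
  }
  structure(fits, class = "hoi_fits", focal = focal, community = community)
}
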