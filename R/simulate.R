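#' Simulation parameters for a microcosm community
#'
#' Bundles everything needed to simulate one community's dynamics under a
#' discrete-time Lotka-Volterra or Ricker map with optional higher-order
#' interaction (HOI) terms. The per-capita growth-rate response of species
#' i at densities N is
#'
#' * LV:     r_i = lambda_i - sum_j alpha_ij N_j - sum_j beta_ijj N_j^2
#'                  - sum_{j<k} beta_ijk N_j N_k   (clamped at 0)
#' * Ricker: r_i = lambda_i * exp(-sum_j alpha_ij N_j - HOI terms)
#'
#' and densities advance as N_{i,t+dt} = N_{i,t} * r_i * dt * eps, with
#' eps lognormal (median 1, sdlog `process_noise_sd`). The response is in
#' per-day ratio units, so a population at its fixed point has r * dt = 1.
#'
#' @param species Character vector of species codes in the community.
#' @param lambda Named numeric: intrinsic growth rate lambda_i (per-day
#'   ratio scale).
#' @param alpha Square numeric matrix (row i, column j): per-capita effect
#'   of species j's density on species i's response. Positive values
#'   suppress growth.
#' @param beta_intra Square matrix of intraspecific-HOI coefficients
#'   beta_ijj (effect of N_j^2 on species i), or `NULL` for none.
#' @param beta_inter Matrix with one row per species i and one column per
#'   unordered species pair "j:k" (canonical order), holding beta_ijk, or
#'   `NULL` for none.
#' @param family `"LV"` or `"Ricker"`.
#' @param treatment Treatment code the community corresponds to (one of
#'   [treatment_codes()]), or `NA` for ad-hoc communities.
#' @param carrying_capacity Named numeric, individuals/mL; used to set
#'   initial consumer densities to `init_fraction` of K.
#' @param init_fraction Fraction of carrying capacity at which consumers
#'   start (default 0.10, the experimental protocol).
#' @param dt Sampling interval in days (default 2).
#' @param horizon Study length in days (default 53).
#' @param process_noise_sd Lognormal sdlog of the multiplicative step
#'   noise (default 0.05).
#' @param extinction_threshold Density below which a species is set to 0
#'   and stays 0 (default 0.01/mL, i.e. one individual in 100 mL).
#' @param predator_schedule Data frame with columns `day`, `individuals`,
#'   `volume_ml`: scheduled predator introductions. Defaults to 10
#'   individuals at day 4 and 10 more at day 8 into 100 mL when the
#'   predator is in the community, otherwise empty.
#' @return A list of class `hoi_sim_params`.
#' @seealso [default_sim_params()], [simulate_community()]
#' @export
sim_params <- function(species, lambda, alpha,
                       beta_intra = NULL, beta_inter = NULL,
                       family = c("LV", "Ricker"),
                       treatment = NA_character_,
                       carrying_capacity = NULL,
                       init_fraction = 0.10,
                       dt = 2, horizon = 53,
                       process_noise_sd = 0.05,
                       extinction_threshold = 0.01,
                       predator_schedule = NULL) {
  family <- match.arg(family)
  n <- length(species)
  stopifnot(n >= 1, !anyDuplicated(species),
            init_fraction > 0, init_fraction <= 1,
            dt > 0, horizon >= dt, process_noise_sd >= 0,
            extinction_threshold >= 0)

  lambda <- resolve_named(lambda, species, "lambda")
  alpha <- resolve_matrix(alpha, species, "alpha")
  if (is.null(beta_intra)) {
    beta_intra <- matrix(0, n, n, dimnames = list(species, species))
  } else {
    beta_intra <- resolve_matrix(beta_intra, species, "beta_intra")
  }
  pairs <- species_pairs(species)
  if (is.null(beta_inter)) {
    beta_inter <- matrix(0, n, length(pairs),
                         dimnames = list(species, pairs))
  } else {
    if (!is.matrix(beta_inter) || nrow(beta_inter) != n ||
        ncol(beta_inter) != length(pairs)) {
      stop("beta_inter must be a ", n, " x ", length(pairs),
           " matrix with pair columns ", paste(pairs, collapse = ", "),
           call. = FALSE)
    }
    rownames(beta_inter) <- species
    colnames(beta_inter) <- pairs
  }
  if (is.null(carrying_capacity)) {
    carrying_capacity <- stats::setNames(rep(NA_real_, n), species)
  } else {
    carrying_capacity <- resolve_named(carrying_capacity, species,
                                       "carrying_capacity")
  }
  if (is.null(predator_schedule)) {
    predator_schedule <- if (PREDATOR_CODE %in% species) {
      default_predator_schedule()
    } else {
      data.frame(day = numeric(0), individuals = numeric(0),
                 volume_ml = numeric(0))
    }
  }
  structure(list(
    species = species, lambda = lambda, alpha = alpha,
    beta_intra = beta_intra, beta_inter = beta_inter,
    family = family, treatment = treatment,
    carrying_capacity = carrying_capacity,
    init_fraction = init_fraction, dt = dt, horizon = horizon,
    process_noise_sd = process_noise_sd,
    extinction_threshold = extinction_threshold,
    predator_schedule = predator_schedule
  ), class = "hoi_sim_params")
}

default_predator_schedule <- function(volume_ml = 100) {
  data.frame(day = c(4, 8), individuals = c(10, 10),
             volume_ml = c(volume_ml, volume_ml))
}

resolve_named <- function(x, species, what) {
  n <- length(species)
  if (length(x) == 1) x <- rep(x, n)
  if (is.null(names(x))) names(x) <- species
  if (length(x) != n || !all(species %in% names(x))) {
    stop(what, " must be named over species ",
         paste(species, collapse = ", "), call. = FALSE)
  }
  x[species]
}

resolve_matrix <- function(m, species, what) {
  n <- length(species)
  if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
    stop(what, " must be a ", n, "x", n, " matrix", call. = FALSE)
  }
  dimnames(m) <- list(species, species)
  m
}

# unordered distinct pairs "j:k" in canonical species order
species_pairs <- function(species) {
  sp <- canonical_species_order(species)
  if (length(sp) < 2) return(character(0))
  cmb <- utils::combn(sp, 2)
  paste(cmb[1, ], cmb[2, ], sep = ":")
}

#' Field-plausible default simulation parameters for a treatment
#'
#' Builds a coherent additive (or HOI-bearing) parameterization for one of
#' the six experimental communities. Intrinsic growth rates and carrying
#' capacities are plausible for the ciliates involved (fast-growing small
#' bacterivores at high K, large slow species at low K); intraspecific
#' competition is scaled so the monoculture LV fixed point sits at K, and
#' interspecific competition is a fraction `rho_inter` of that. The
#' predator declines without prey, gains growth from the densities of the
#' species it can consume, and suppresses prey growth.
#'
#' When `hoi_structure` is `"intra"` or `"full"`, a share `hoi_share` of
#' each intraspecific suppression channel is moved from the linear alpha
#' term to a quadratic beta_ijj term (the fixed point is preserved). When
#' it is `"inter"` or `"full"`, cross-product terms beta_ijk of comparable
#' magnitude (|beta N_j N_k| ~ hoi_share x linear suppression at K) are
#' added for every unordered species pair.
#'
#' @param treatment One of the six treatment codes.
#' @param family `"LV"` or `"Ricker"`.
#' @param hoi_structure `"none"`, `"intra"`, `"inter"` or `"full"`.
#' @param hoi_share Fraction of suppression carried by HOI terms when
#'   present (default 0.5).
#' @param rho_inter Interspecific-to-intraspecific competition ratio among
#'   consumers (default 0.4).
#' @param process_noise_sd,extinction_threshold,dt,horizon Passed through
#'   to [sim_params()].
#' @return An `hoi_sim_params` object.
#' @export
default_sim_params <- function(treatment,
                               family = "LV",
                               hoi_structure = c("none", "intra", "inter", "full"),
                               hoi_share = 0.5,
                               rho_inter = 0.4,
                               process_noise_sd = 0.05,
                               extinction_threshold = 0.01,
                               dt = 2, horizon = 53) {
  hoi_structure <- match.arg(hoi_structure)
  info <- treatment_info(treatment)
  sp <- info$species
  n <- length(sp)

  lambda_all <- c(C = 1.2, D = 1.25, P = 0.9, S = 0.8, Pd = 0.35)
  kcc_all <- c(C = 1200, D = 1500, P = 150, S = 80, Pd = 40)
  lambda <- lambda_all[sp]
  kcc <- kcc_all[sp]

  # surplus growth to be absorbed by density dependence at equilibrium
  surplus <- lambda - 1 / dt # per-day response in excess of replacement

  rho <- matrix(rho_inter, n, n, dimnames = list(sp, sp))
  diag(rho) <- 1
  alpha <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in info$consumers) {
    for (j in info$consumers) {
      alpha[i, j] <- rho[i, j] * surplus[i] / kcc[j]
    }
  }
  if (info$predator_present) {
    # predation pressure on edible prey; interference-level effects on
    # the large species; predator gains from consumable prey densities
    alpha[intersect(c("C", "D"), sp), PREDATOR_CODE] <- 0.6
    if ("P" %in% sp) alpha["P", PREDATOR_CODE] <- 0.15
    if ("S" %in% sp) alpha["S", PREDATOR_CODE] <- 0.10
    gains <- c(C = -7e-4, D = -7e-4, P = -1e-3, S = 0)
    for (j in intersect(names(gains), sp)) {
      alpha[PREDATOR_CODE, j] <- gains[[j]]
    }
    alpha[PREDATOR_CODE, PREDATOR_CODE] <- 0.1
  }

  beta_intra <- NULL
  beta_inter <- NULL
  if (hoi_structure %in% c("intra", "full")) {
    beta_intra <- matrix(0, n, n, dimnames = list(sp, sp))
    for (i in info$consumers) {
      for (j in info$consumers) {
        beta_intra[i, j] <- hoi_share * alpha[i, j] / kcc[j]
        alpha[i, j] <- (1 - hoi_share) * alpha[i, j]
      }
    }
  }
  if (hoi_structure %in% c("inter", "full")) {
    pairs <- species_pairs(sp)
    beta_inter <- matrix(0, n, length(pairs), dimnames = list(sp, pairs))
    for (i in info$consumers) {
      for (pr in pairs) {
        jk <- strsplit(pr, ":", fixed = TRUE)[[1]]
        if (PREDATOR_CODE %in% jk) next
        beta_inter[i, pr] <- hoi_share * rho_inter * surplus[i] /
          (kcc[jk[1]] * kcc[jk[2]])
      }
    }
  }

  sim_params(
    species = sp, lambda = lambda, alpha = alpha,
    beta_intra = beta_intra, beta_inter = beta_inter,
    family = family, treatment = treatment,
    carrying_capacity = kcc,
    process_noise_sd = process_noise_sd,
    extinction_threshold = extinction_threshold,
    dt = dt, horizon = horizon
  )
}

#' Observation (subsample counting) parameters
#'
#' Density is measured as the mean of `n_subsamples` subsample counts:
#' each count is Poisson with mean density x `subsample_volume_ml`
#' (`counting_noise = "poisson"`), converted back to individuals/mL. With
#' `counting_noise = "none"` the expectation is passed through unchanged.
#' A latent zero always observes as exactly zero.
#'
#' @param subsample_volume_ml Subsample volume in mL (default 0.25, i.e.
#'   250 uL).
#' @param n_subsamples Number of subsamples averaged (default 3).
#' @param counting_noise `"poisson"` or `"none"`.
#' @return A list of class `hoi_obs_params`.
#' @export
obs_params <- function(subsample_volume_ml = 0.25, n_subsamples = 3,
                       counting_noise = c("poisson", "none")) {
  counting_noise <- match.arg(counting_noise)
  stopifnot(subsample_volume_ml > 0, n_subsamples >= 1)
  structure(list(subsample_volume_ml = subsample_volume_ml,
                 n_subsamples = as.integer(n_subsamples),
                 counting_noise = counting_noise),
            class = "hoi_obs_params")
}

#' Sampling-day grid
#'
#' Days `0, dt, 2*dt, ...` up to and including the largest multiple of
#' `dt` that does not exceed `horizon`.
#'
#' @param dt Sampling interval (days).
#' @param horizon Study length (days).
#' @return Numeric vector of sampling days.
#' @export
sampling_days <- function(dt = 2, horizon = 53) {
  stopifnot(dt > 0, horizon >= dt)
  seq(0, dt * floor(horizon / dt), by = dt)
}

#' Enumerate the experimental design
#'
#' Crosses the six treatment codes with replicate indices, producing
#' deterministic microcosm identifiers `"<treatment>_R<replicate>"`.
#'
#' @param replicates Replicates per treatment (the experiment used 4).
#' @return Data frame with columns `microcosm_id`, `treatment`,
#'   `replicate`.
#' @examples
#' nrow(generate_design(4)) # 24 microcosms
#' @export
generate_design <- function(replicates = 4) {
  if (!is.numeric(replicates) || length(replicates) != 1 ||
      replicates < 1 || replicates != floor(replicates)) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  trts <- treatment_codes()
  df <- expand.grid(replicate = seq_len(replicates), treatment = trts,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("treatment", "replicate")]
  df$microcosm_id <- sprintf("%s_R%d", df$treatment, df$replicate)
  df[, c("microcosm_id", "treatment", "replicate")]
}

#' Model-predicted per-capita growth-rate response
#'
#' Evaluates the chosen family's growth-rate response r_i (per-day ratio
#' scale) for every species at densities `N`. LV responses are clamped at
#' zero, since the discrete map is otherwise unbounded below.
#'
#' @param N Named numeric vector of densities (individuals/mL) over
#'   `params$species`.
#' @param params An `hoi_sim_params` object.
#' @return Named numeric vector of responses.
#' @export
growth_response <- function(N, params) {
  sp <- params$species
  N <- N[sp]
  suppression <- as.vector(params$alpha %*% N) +
    as.vector(params$beta_intra %*% (N^2))
  pairs <- colnames(params$beta_inter)
  if (length(pairs) > 0) {
    jk <- do.call(rbind, strsplit(pairs, ":", fixed = TRUE))
    cross <- N[jk[, 1]] * N[jk[, 2]]
    suppression <- suppression + as.vector(params$beta_inter %*% cross)
  }
  r <- if (params$family == "LV") {
    pmax(params$lambda - suppression, 0)
  } else {
    params$lambda * exp(-suppression)
  }
  stats::setNames(as.numeric(r), sp)
}

#' Simulate one microcosm's latent density trajectory
#'
#' Iterates the discrete map N_{t+dt} = N_t * r(N_t) * dt * eps on the
#' sampling grid, where r is the model response of [growth_response()] and
#' eps is lognormal process noise (median 1, sdlog
#' `params$process_noise_sd`). Densities falling below the extinction
#' threshold are set to zero and stay zero; scheduled predator additions
#' are applied on their day as individuals/volume. Consumers start at
#' `init_fraction` x carrying capacity; the predator starts at zero and
#' enters via its schedule.
#'
#' @param params An `hoi_sim_params` object.
#' @param microcosm_id,replicate Identifiers stamped on the output rows.
#' @param seed Optional integer seed for reproducibility.
#' @param init Optional named vector of initial densities overriding the
#'   carrying-capacity rule.
#' @return An `hoi_ts` table of latent (true) densities.
#' @export
simulate_community <- function(params, microcosm_id = "M1", replicate = 1,
                               seed = NULL, init = NULL) {
  stopifnot(inherits(params, "hoi_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  sp <- params$species
  days <- sampling_days(params$dt, params$horizon)
  n_steps <- length(days)

  if (is.null(init)) {
    init <- params$init_fraction * params$carrying_capacity
    if (PREDATOR_CODE %in% sp) init[PREDATOR_CODE] <- 0
    if (anyNA(init)) {
      stop("no carrying_capacity to derive initial densities from; ",
           "supply init=", call. = FALSE)
    }
  } else {
    init <- resolve_named(init, sp, "init")
  }

  N <- matrix(0, n_steps, length(sp), dimnames = list(NULL, sp))
  N[1, ] <- pmax(init, 0)
  sched <- params$predator_schedule
  for (s in seq_len(n_steps - 1L)) {
    cur <- N[s, ]
    r <- growth_response(cur, params)
    eps <- if (params$process_noise_sd > 0) {
      stats::rlnorm(length(sp), meanlog = 0, sdlog = params$process_noise_sd)
    } else rep(1, length(sp))
    nxt <- cur * r * params$dt * eps
    nxt[nxt < params$extinction_threshold] <- 0
    nxt[cur == 0] <- 0 # extinct stays extinct
    day_next <- days[s + 1L]
    if (nrow(sched) > 0 && PREDATOR_CODE %in% sp) {
      add <- sched[sched$day > days[s] & sched$day <= day_next, , drop = FALSE]
      if (nrow(add) > 0) {
        nxt[PREDATOR_CODE] <- nxt[PREDATOR_CODE] +
          sum(add$individuals / add$volume_ml)
      }
    }
    if (any(!is.finite(nxt))) {
      bad <- sp[!is.finite(nxt)]
      stop(sprintf("non-finite density at day %s for species %s",
                   day_next, paste(bad, collapse = ", ")), call. = FALSE)
    }
    N[s + 1L, ] <- nxt
  }

  df <- data.frame(
    microcosm_id = microcosm_id,
    treatment = params$treatment,
    replicate = replicate,
    day = rep(days, times = length(sp)),
    species = rep(sp, each = n_steps),
    density = as.vector(N),
    stringsAsFactors = FALSE
  )
  hoi_timeseries(df)
}

#' Apply subsample-count observation to a latent table
#'
#' For each latent density, draws `n_subsamples` Poisson counts with mean
#' density x subsample volume, converts each to a density and returns
#' their mean — the experimental density measure. All-zero counts yield an
#' exact observed zero; with `counting_noise = "none"` the latent density
#' is passed through unchanged.
#'
#' @param latent An `hoi_ts` table of latent densities.
#' @param obs An `hoi_obs_params` object.
#' @param seed Optional integer seed.
#' @return An `hoi_ts` table of observed densities.
#' @export
observe <- function(latent, obs = obs_params(), seed = NULL) {
  stopifnot(inherits(latent, "hoi_ts"), inherits(obs, "hoi_obs_params"))
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(latent)
  if (obs$counting_noise == "none" || nrow(out) == 0) {
    return(hoi_timeseries(out))
  }
  v <- obs$subsample_volume_ml
  k <- obs$n_subsamples
  mu <- out$density * v
  counts <- matrix(stats::rpois(length(mu) * k, rep(mu, each = k)),
                   nrow = k)
  out$density <- colMeans(counts) / v
  hoi_timeseries(out)
}

#' Generate a full synthetic study
#'
#' Composes [generate_design()], [simulate_community()] and [observe()]
#' into the complete observed dataset: all six treatments x `replicates`
#' microcosms on the 2-day grid over 53 days. Replicates of a treatment
#' share parameters and differ only in their process/observation noise
#' draws; all randomness derives deterministically from `seed`.
#'
#' @param params_by_treatment Named list of `hoi_sim_params`, one per
#'   treatment code; defaults to [default_sim_params()] for each.
#' @param obs An `hoi_obs_params` object.
#' @param replicates Replicates per treatment (default 4).
#' @param seed Integer root seed.
#' @return An `hoi_ts` table covering every microcosm.
#' @export
generate_study <- function(params_by_treatment = NULL,
                           obs = obs_params(),
                           replicates = 4, seed = 1) {
  design <- generate_design(replicates)
  if (is.null(params_by_treatment)) {
    params_by_treatment <- lapply(
      stats::setNames(nm = treatment_codes()), default_sim_params)
  }
  missing_tr <- setdiff(unique(design$treatment),
                        names(params_by_treatment))
  if (length(missing_tr) > 0) {
    stop("missing SimParams for treatment(s): ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nrow(design) + 1L)
  pieces <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    pieces[[i]] <- as.data.frame(simulate_community(
      params_by_treatment[[design$treatment[i]]],
      microcosm_id = design$microcosm_id[i],
      replicate = design$replicate[i],
      seed = seeds[i]
    ))
  }
  latent <- hoi_timeseries(do.call(rbind, pieces))
  observe(latent, obs, seed = seeds[nrow(design) + 1L])
}
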