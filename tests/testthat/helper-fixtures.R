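# shared fixture builders for the test suite

# long-format table for one microcosm from a named list of density vectors
ts_one <- function(dens_by_species, days = NULL, microcosm = "M1",
                   treatment = "CD", replicate = 1) {
  n <- length(dens_by_species[[1]])
  if (is.null(days)) days <- seq(0, by = 2, length.out = n)
  df <- do.call(rbind, lapply(names(dens_by_species), function(sp) {
    data.frame(microcosm_id = microcosm, treatment = treatment,
               replicate = replicate, day = days, species = sp,
               density = dens_by_species[[sp]], stringsAsFactors = FALSE)
  }))
  hoi_timeseries(df)
}

# pooled regression table for the CD community from n_mc replicate
# simulations of one parameter set
sim_cd_regression <- function(params, n_mc = 4, seed = 1, focal = "C") {
  set.seed(seed)
  seeds <- sample.int(2^31 - 1, n_mc)
  pieces <- lapply(seq_len(n_mc), function(k) {
    as.data.frame(simulate_community(
      params, microcosm_id = sprintf("CD_R%d", k), replicate = k,
      seed = seeds[k]))
  })
  tab <- hoi_timeseries(do.call(rbind, pieces))
  assemble_regression_table(compute_growth_rates(tab, focal), "CD")
}

# minimal converged fit object with a prescribed AICc, for testing the
# selection rule in isolation (log-likelihood back-solved from AICc)
stub_fit <- function(name, K, aicc_value, n = 100, focal = "C",
                     community = "CD") {
  K <- as.integer(K)
  corr <- 2 * K * (K + 1) / (n - K - 1)
  loglik <- -(aicc_value - 2 * K - corr) / 2
  structure(list(spec = model_spec(name), focal = focal,
                 community = community, n_obs = n, K = K,
                 loglik = loglik, converged = TRUE),
            class = "hoi_fit")
}

# survival data frame shortcut
surv_df <- function(time, event, group = "G1", unit = NULL) {
  data.frame(
    unit_id = unit %||% paste0("u", seq_along(time)),
    group = group, species = "C", time = time, event = event,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
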