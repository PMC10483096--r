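test_that("parameter counts follow the closed forms for both community sizes", {
  # two-species community
  expect_equal(count_parameters("additive_LV", 2), 4L)
  expect_equal(count_parameters("interactive_LV_intra", 2), 6L)
  expect_equal(count_parameters("interactive_LV_inter", 2), 5L)
  expect_equal(count_parameters("interactive_LV_full", 2), 7L)
  expect_equal(count_parameters("additive_Ricker", 2), 4L)
  expect_equal(count_parameters("interactive_Ricker", 2), 5L)
  # three-species community
  expect_equal(count_parameters("additive_LV", 3), 5L)
  expect_equal(count_parameters("interactive_LV_intra", 3), 8L)
  expect_equal(count_parameters("interactive_LV_inter", 3), 8L)
  expect_equal(count_parameters("interactive_LV_full", 3), 11L)
  expect_equal(count_parameters("additive_Ricker", 3), 5L)
  expect_equal(count_parameters("interactive_Ricker", 3), 8L)
  # degenerate single-species community: no distinct pairs exist
  expect_equal(count_parameters("interactive_LV_inter", 1), 3L)
  expect_error(count_parameters("additive_LV", 0), "positive integer")
})

test_that("design matrices expand the expected named columns", {
  reg3 <- data.frame(r = 1:20 / 10, N_C = runif(20, 0, 100),
                     N_D = runif(20, 0, 100), N_S = runif(20, 0, 10))
  d_full <- build_design(reg3, "interactive_LV_full")
  expect_equal(ncol(d_full$X), 9) # 3 linear + 3 quadratic + 3 cross
  expect_identical(colnames(d_full$X),
                   c("N_C", "N_D", "N_S", "N_C:N_C", "N_D:N_D", "N_S:N_S",
                     "N_C:N_D", "N_C:N_S", "N_D:N_S"))

  reg2 <- reg3[, c("r", "N_C", "N_D")]
  d_inter <- build_design(reg2, "interactive_LV_inter")
  expect_identical(colnames(d_inter$X), c("N_C", "N_D", "N_C:N_D"))

  # literal reading: pairs containing the focal species excluded
  d_lit <- build_design(reg3, "interactive_LV_inter",
                        inter_pairs = "exclude_focal", focal = "C")
  expect_identical(colnames(d_lit$X), c("N_C", "N_D", "N_S", "N_D:N_S"))

  # single species: an interactive Ricker has no cross terms
  reg1 <- reg3[, c("r", "N_C")]
  expect_identical(colnames(build_design(reg1, "interactive_Ricker")$X),
                   "N_C")

  expect_error(build_design(reg3[0, ], "additive_LV"), "empty")
})

test_that("noiseless LV data are recovered to machine precision", {
  p <- default_sim_params("CD", process_noise_sd = 0)
  reg <- sim_cd_regression(p, n_mc = 2, seed = 1)
  fit <- fit_model(build_design(reg, "additive_LV"), community = "CD")
  expect_lt(abs(fit$lambda_hat - p$lambda["C"]), 1e-8)
  expect_lt(max(abs(fit$alpha_hat - p$alpha["C", c("C", "D")])), 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$K, 4L)
})

test_that("log-link fit recovers Ricker truth and matches a quasi-Newton
           minimizer of the same objective", {
  p <- default_sim_params("CD", family = "Ricker", process_noise_sd = 0)
  reg <- sim_cd_regression(p, n_mc = 2, seed = 2)
  des <- build_design(reg, "additive_Ricker")
  fit <- fit_model(des)
  expect_lt(abs(fit$lambda_hat - p$lambda["C"]), 1e-6)
  expect_lt(max(abs(fit$alpha_hat - p$alpha["C", c("C", "D")])), 1e-6)

  # independent oracle: minimize the RSS of the exponential mean directly,
  # started from least squares on the logged response
  X <- cbind(1, des$X)
  rss_fun <- function(b) sum((des$response - exp(X %*% b))^2)
  y <- des$response
  b_start <- qr.solve(X, log(pmax(y, min(y[y > 0]) * 1e-3)))
  opt <- optim(b_start, rss_fun, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000,
                              parscale = c(1, 1e-4, 1e-4)))
  rss_fit <- fit$sigma2_hat * fit$n_obs
  expect_lt(rss_fit, opt$value + 1e-8)
  expect_equal(unname(fit$lambda_hat), unname(exp(opt$par[1])),
               tolerance = 1e-4)
})

test_that("noiseless full-HOI data round-trip coefficients and signs", {
  p <- default_sim_params("CD", hoi_structure = "full",
                          process_noise_sd = 0)
  reg <- sim_cd_regression(p, n_mc = 2, seed = 3)
  fit <- fit_model(build_design(reg, "interactive_LV_full"))
  expect_equal(unname(fit$alpha_hat["C"]), p$alpha["C", "C"],
               tolerance = 1e-6)
  expect_equal(unname(fit$alpha_hat["D"]), p$alpha["C", "D"],
               tolerance = 1e-6)
  expect_equal(unname(fit$beta_intra_hat[c("C", "D")]),
               unname(p$beta_intra["C", c("C", "D")]), tolerance = 1e-6)
  expect_equal(unname(fit$beta_inter_hat["C:D"]),
               unname(p$beta_inter["C", "C:D"]), tolerance = 1e-6)
  # suppressive effects carry positive signs under the convention
  expect_true(all(fit$alpha_hat > 0))
  expect_true(all(fit$beta_intra_hat > 0))
})

test_that("every fit's K agrees with count_parameters and likelihoods nest", {
  p <- default_sim_params("CDS")
  set.seed(4)
  seeds <- sample.int(2^31 - 1, 4)
  pieces <- lapply(1:4, function(k) as.data.frame(
    simulate_community(p, microcosm_id = sprintf("CDS_R%d", k),
                       replicate = k, seed = seeds[k])))
  tab <- hoi_timeseries(do.call(rbind, pieces))
  reg <- assemble_regression_table(compute_growth_rates(tab, "D"), "CDS")
  fits <- fit_all_models(reg)

  expect_length(fits, 6)
  for (nm in names(fits)) {
    expect_equal(fits[[nm]]$K, count_parameters(nm, 3))
  }
  expect_equal(sort(unname(vapply(fits, `[[`, integer(1), "K"))),
               sort(c(5L, 8L, 8L, 11L, 5L, 8L)))

  # adding HOI columns never lowers the maximized likelihood (OLS nesting)
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  expect_gte(ll["interactive_LV_intra"], ll["additive_LV"])
  expect_gte(ll["interactive_LV_inter"], ll["additive_LV"])
  expect_gte(ll["interactive_LV_full"], ll["interactive_LV_intra"])
  expect_gte(ll["interactive_LV_full"], ll["interactive_LV_inter"])
  expect_gte(ll["interactive_Ricker"], ll["additive_Ricker"] - 1e-6)
})

test_that("gaussian log-likelihood matches the reference implementation", {
  set.seed(5)
  reg <- data.frame(r = runif(30, 0.2, 1.5), N_C = runif(30, 0, 100),
                    N_D = runif(30, 0, 100))
  fit <- fit_model(build_design(reg, "additive_LV"))
  ref <- lm(r ~ N_C + N_D, data = reg)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
  # and the reported K matches the reference df (coefficients + dispersion)
  expect_equal(fit$K, attr(logLik(ref), "df"))
})

test_that("underdetermined and collinear designs fail loudly, others fit", {
  reg <- data.frame(r = runif(6, 0.5, 1), N_C = runif(6, 0, 100),
                    N_D = runif(6, 0, 100))
  expect_error(fit_model(build_design(reg, "interactive_LV_full")),
               "underdetermined")
  fits <- suppressWarnings(fit_all_models(reg, focal = "C",
                                          community = "CD"))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  expect_false(conv[["interactive_LV_full"]])
  expect_true(conv[["additive_LV"]])

  coll <- data.frame(r = runif(20, 0.5, 1), N_C = 1:20)
  coll$N_D <- 2 * coll$N_C
  expect_error(fit_model(build_design(coll, "additive_LV")),
               "collinear")
})

test_that("estimator error shrinks as transitions double under noise", {
  p <- default_sim_params("CD") # process_noise_sd = 0.05
  a_true <- p$alpha["C", "C"]
  est <- function(n_mc, seed) {
    reg <- sim_cd_regression(p, n_mc = n_mc, seed = seed)
    fit_model(build_design(reg, "additive_LV"))$alpha_hat["C"]
  }
  n_rep <- 60
  e26 <- vapply(seq_len(n_rep), function(i) est(1, 300 + i), numeric(1))
  e52 <- vapply(seq_len(n_rep), function(i) est(2, 900 + i), numeric(1))
  rmse <- function(e) sqrt(mean((e - a_true)^2))
  expect_lt(rmse(e52), rmse(e26))
})
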