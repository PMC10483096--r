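test_that("extinction times and censoring follow the terminal-zero rule", {
  # positive through the final sample: censored at study end
  alive <- ts_one(list(C = rep(100, 27), D = rep(50, 27)))
  s1 <- extract_survival(alive, "C")
  expect_equal(s1$time, 53)
  expect_false(s1$event)

  # zeros from day 21 onward (days 0..52 by 2 is not aligned to 21, so
  # use the grid value): first day of the terminal zero run is the event
  dens <- c(rep(80, 11), rep(0, 16)) # zero from day 22 on
  gone <- ts_one(list(C = dens, D = rep(50, 27)))
  s2 <- extract_survival(gone, "C")
  expect_equal(s2$time, 22)
  expect_true(s2$event)

  # an isolated zero followed by detections is not an extinction
  blip <- ts_one(list(C = c(100, 0, 60, 70), D = rep(5, 4)))
  s3 <- extract_survival(blip, "C")
  expect_false(s3$event)
  expect_equal(s3$time, 53)
})

test_that("extraction matches a brute-force scan on random series", {
  set.seed(11)
  for (rep in 1:20) {
    m <- sample(4:15, 1)
    dens <- round(runif(m, 0, 50))
    dens[runif(m) < 0.35] <- 0
    if (all(dens == 0)) dens[1] <- 10
    days <- seq(0, by = 2, length.out = m)
    tab <- ts_one(list(C = dens, D = rep(1, m)), days = days)
    got <- extract_survival(tab, "C", study_end = 53)

    # oracle: scan forward for the first zero with no later positives
    oracle_time <- 53; oracle_event <- FALSE
    for (s in seq_len(m)) {
      if (dens[s] == 0 && all(dens[s:m] == 0)) {
        oracle_time <- days[s]; oracle_event <- TRUE; break
      }
    }
    expect_equal(got$time, oracle_time)
    expect_equal(got$event, oracle_event)
  }
})

test_that("product-limit estimate matches hand-computed tables", {
  # one event among four units: S(2) = 3/4
  km1 <- km_estimate(surv_df(time = c(2, 5, 5, 5),
                             event = c(TRUE, FALSE, FALSE, FALSE)))
  expect_equal(km1$survival[km1$time == 2], 3 / 4)
  expect_equal(km1$survival[km1$time == 0], 1)

  # no events: survival stays at 1
  km2 <- km_estimate(surv_df(time = rep(6, 3), event = rep(FALSE, 3)))
  expect_true(all(km2$survival == 1))

  # mixed events and censoring over 8 units, hand-computed product limit:
  # t=2: 8 at risk, 1 event -> 7/8
  # t=4: 6 at risk, 2 events -> 7/8 * 4/6 = 7/12
  # t=6: 3 at risk, 1 event -> 7/12 * 2/3 = 7/18
  km3 <- km_estimate(surv_df(
    time = c(2, 3, 4, 4, 5, 6, 8, 8),
    event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)))
  expect_equal(km3$survival[km3$time == 2], 7 / 8)
  expect_equal(km3$survival[km3$time == 4], 7 / 12)
  expect_equal(km3$survival[km3$time == 6], 7 / 18)
  # a step function, non-increasing, within [0, 1], bands bracket it
  expect_true(all(diff(km3$survival) <= 0))
  expect_true(all(km3$survival >= 0 & km3$survival <= 1))
  expect_true(all(km3$ci_lower <= km3$survival + 1e-12))
  expect_true(all(km3$ci_upper >= km3$survival - 1e-12))
})

test_that("survival curves are monotone on random inputs", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    d <- surv_df(time = sample(1:10, n, replace = TRUE),
                 event = runif(n) < 0.6)
    km <- km_estimate(d)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
  }
})

test_that("log-rank statistic matches a hand-computed O/E table", {
  # all-event two-group configuration; observed-vs-expected worked by
  # hand over the six event times gives O_A=3, E_A=1.15, V=0.6775
  d <- surv_df(time = c(1, 2, 3, 4, 5, 6), event = rep(TRUE, 6),
               group = rep(c("A", "B"), each = 3))
  lr <- logrank_test(d)
  expect_equal(lr$statistic, (3 - 1.15)^2 / 0.6775, tolerance = 1e-9)
  expect_equal(lr$df, 1)
})

test_that("log-rank degenerate and structural properties hold", {
  # identical groups: statistic 0, p = 1
  base <- surv_df(time = c(3, 5, 7, 9), event = c(TRUE, TRUE, FALSE, TRUE))
  two <- rbind(transform(base, group = "A", unit_id = paste0("a", 1:4)),
               transform(base, group = "B", unit_id = paste0("b", 1:4)))
  lr <- logrank_test(two)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # df = k - 1 and invariance to group relabeling
  three <- rbind(two, transform(base, group = "C",
                                unit_id = paste0("c", 1:4)))
  expect_equal(logrank_test(three)$df, 2)
  relabeled <- three
  relabeled$group <- c(A = "Z", B = "Y", C = "X")[relabeled$group]
  expect_equal(logrank_test(relabeled)$statistic,
               logrank_test(three)$statistic, tolerance = 1e-12)

  expect_error(logrank_test(surv_df(1:3, rep(TRUE, 3))), ">= 2 groups")
})

test_that("two-group p-value agrees with the exact permutation oracle", {
  perm_oracle <- function(time, event, idx_a) {
    n <- length(time)
    stat_of <- function(ix) {
      g <- ifelse(seq_len(n) %in% ix, "A", "B")
      logrank_test(surv_df(time, event, group = g))$statistic
    }
    obs <- stat_of(idx_a)
    assignments <- utils::combn(n, length(idx_a))
    stats <- apply(assignments, 2, stat_of)
    c(p_perm = mean(stats >= obs - 1e-9),
      p_chisq = stats::pchisq(obs, 1, lower.tail = FALSE))
  }
  # strong separation: both routes call it significant, and agree closely
  strong <- perm_oracle(1:8, rep(TRUE, 8), 1:4)
  expect_lt(abs(strong["p_perm"] - strong["p_chisq"]), 0.1)
  expect_lt(strong[["p_perm"]], 0.05)
  expect_lt(strong[["p_chisq"]], 0.05)
  # interleaved groups: both routes are far from significance
  mild <- perm_oracle(c(1, 3, 5, 7, 2, 4, 6, 8), rep(TRUE, 8), 1:4)
  expect_lt(abs(mild["p_perm"] - mild["p_chisq"]), 0.1)
  expect_gt(mild[["p_perm"]], 0.3)
})

test_that("pairwise log-rank wiring and adjustment are consistent", {
  base <- surv_df(time = c(3, 5, 7, 9), event = c(TRUE, TRUE, FALSE, TRUE))
  three <- rbind(transform(base, group = "A", unit_id = paste0("a", 1:4)),
                 transform(base, group = "B", unit_id = paste0("b", 1:4)),
                 transform(base, group = "C", unit_id = paste0("c", 1:4)))
  m <- pairwise_logrank(three)
  expect_true(all(m[upper.tri(m)] == 1)) # identical groups
  expect_true(isSymmetric(m))

  # raw mode reproduces individual tests; BH matches p.adjust directly
  set.seed(13)
  mixed <- rbind(
    surv_df(c(2, 4, 6, 8), rep(TRUE, 4), group = "A", unit = paste0("a", 1:4)),
    surv_df(c(10, 12, 14, 16), rep(TRUE, 4), group = "B", unit = paste0("b", 1:4)),
    surv_df(c(3, 9, 15, 21), c(TRUE, TRUE, FALSE, TRUE), group = "C",
            unit = paste0("c", 1:4)))
  raw <- pairwise_logrank(mixed, adjust = "none")
  expect_equal(raw["A", "B"],
               logrank_test(mixed[mixed$group %in% c("A", "B"), ])$p_value)
  bh <- pairwise_logrank(mixed, adjust = "BH")
  raw_vec <- c(raw["A", "B"], raw["A", "C"], raw["B", "C"])
  bh_vec <- c(bh["A", "B"], bh["A", "C"], bh["B", "C"])
  expect_equal(bh_vec, unname(p.adjust(raw_vec, "BH")), tolerance = 1e-12)
})
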