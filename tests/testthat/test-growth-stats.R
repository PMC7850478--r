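test_that("cumulative division probability follows D(t)/N(t) accounting", {
  dt <- 1 / 6
  # 2 channels alive; one division in bin 1, one in bin 2
  ev <- rbind(
    data.frame(channel_id = "a", time_h = c(dt, 2 * dt),
               event = c("division", "end_of_observation")),
    data.frame(channel_id = "b", time_h = c(2 * dt, 2 * dt + 1e-3),
               event = c("division", "end_of_observation"))
  )
  curve <- cumulative_division_probability(ev, dt)
  expect_equal(curve$cumulative[1:2], c(0.5, 1.0))

  # no divisions: all zeros
  ev0 <- data.frame(channel_id = c("a", "b"), time_h = c(1, 1),
                    event = "end_of_observation")
  expect_true(all(cumulative_division_probability(ev0, dt)$cumulative == 0))

  # channel dies in bin 1 (N drops to 1), division in bin 2: [0, 1]
  ev2 <- rbind(
    data.frame(channel_id = "a", time_h = dt, event = "death"),
    data.frame(channel_id = "b", time_h = c(2 * dt, 1),
               event = c("division", "end_of_observation"))
  )
  curve2 <- cumulative_division_probability(ev2, dt)
  expect_equal(curve2$cumulative[1:2], c(0, 1))

  # curves are non-decreasing
  set.seed(19)
  for (i in 1:5) {
    tab <- random_event_table(n_channels = 8)
    expect_true(all(diff(cumulative_division_probability(tab)$cumulative)
                    >= 0))
  }
})

test_that("division-rate fit recovers an exact line and is shift-invariant", {
  curve <- data.frame(bin_time_h = seq(1, 50), cumulative = 0.09 * seq(1, 50))
  class(curve) <- c("division_curve", "data.frame")
  fit <- suppressWarnings(fit_division_rate(curve))  # exact fit
  expect_equal(fit$rate_per_h, 0.09, tolerance = 1e-12)
  shifted <- curve
  shifted$bin_time_h <- shifted$bin_time_h + 37
  expect_equal(suppressWarnings(fit_division_rate(shifted))$rate_per_h, 0.09,
               tolerance = 1e-12)
  expect_error(fit_division_rate(curve[1:2, ]), "3 points")
})

test_that("division-rate on simulated balanced growth matches the lineage rate", {
  cfg <- generator_config(n_channels = 300, baseline_hazard_per_h = 0,
                          seed = 23)
  ev <- simulate_lineages(cfg)
  slope <- fit_division_rate(cumulative_division_probability(ev))$rate_per_h
  # oracle: mean over lineages of 1 / (mean generation time of the lineage)
  cyc <- extract_cycles(ev)
  lin_rate <- mean(vapply(split(cyc$tau_h, cyc$channel_id),
                          function(x) 1 / mean(x), numeric(1)))
  expect_lt(abs(slope - lin_rate) / lin_rate, 0.10)
})

test_that("death rate comes from the log-survival slope with honest errors", {
  # no deaths: rate 0, flagged
  ev0 <- data.frame(channel_id = c("a", "b"), time_h = c(10, 10),
                    event = "end_of_observation")
  dr0 <- death_rate(ev0)
  expect_equal(dr0$rate_per_h, 0)
  expect_true(dr0$no_deaths)
  expect_true(is.na(dr0$se))

  # recovery of the generative hazard, one seed (20-seed sweep in acceptance)
  set.seed(101)
  cfg <- generator_config(n_channels = 500, seed = 14)
  dr <- death_rate(simulate_lineages(cfg))
  expect_lt(abs(dr$rate_per_h - 2.239e-3), 3 * dr$se)
  # survival curve invariants
  expect_true(all(diff(dr$curve$surviving_fraction) <= 0))
  expect_equal(dr$curve$surviving_fraction[1], 1)
  expect_true(all(dr$curve$surviving_fraction >= 0 &
                    dr$curve$surviving_fraction <= 1))
})

test_that("per-generation death probability at reference values rounds to 2%", {
  p_gen <- 1 - exp(-2.239e-3 * 10.40)
  expect_equal(round(100 * p_gen), 2)
})

test_that("correlation agrees with the direct-formula oracle", {
  expect_equal(correlation(cbind(1:3, 1:3), "pearson")$estimate, 1)
  expect_equal(correlation(cbind(1:3, 1:3), "spearman")$estimate, 1)
  expect_equal(correlation(cbind(1:3, 3:1), "pearson")$estimate, -1)
  expect_error(correlation(cbind(1:2, 2:1)), "3 pairs")
  expect_error(correlation(cbind(c(1, 1, 1), 1:3)), "constant")

  # brute-force oracles: explicit covariance sums and explicit rank formula
  pearson_oracle <- function(x, y) {
    n <- length(x)
    sxy <- sum(x * y) - sum(x) * sum(y) / n
    sxx <- sum(x^2) - sum(x)^2 / n
    syy <- sum(y^2) - sum(y)^2 / n
    sxy / sqrt(sxx * syy)
  }
  set.seed(29)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    expect_equal(correlation(cbind(x, y), "pearson")$estimate,
                 pearson_oracle(x, y), tolerance = 1e-12)
    expect_equal(correlation(cbind(x, y), "spearman")$estimate,
                 pearson_oracle(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("one-pair-per-lineage resampling is unbiased and reproducible", {
  # lineages holding exactly one pair each: zero resampling variance
  cyc1 <- do.call(rbind, lapply(1:6, function(i) {
    extract_cycles(events_from_divisions(c(0, 7 + i, 16 + 2 * i),
                                         sprintf("c%d", i), end = 100))
  }))
  r <- one_pair_per_lineage_correlation(cyc1, n_resamples = 50, seed = 1)
  expect_equal(r$sd, 0)

  # bit-exact reproducibility under a fixed seed
  cfg <- generator_config(n_channels = 150, seed = 33)
  cyc <- extract_cycles(simulate_lineages(cfg))
  a <- one_pair_per_lineage_correlation(cyc, 200, seed = 5)
  b <- one_pair_per_lineage_correlation(cyc, 200, seed = 5)
  expect_identical(a$values, b$values)

  # mean over resamples close to the pooled coefficient on calibrated data
  pooled <- correlation(ancestor_descendant_pairs(cyc, 1),
                        "spearman")$estimate
  expect_lt(abs(a$mean - pooled), 0.05)
})

test_that("autocorrelation pools pairs correctly and vanishes for iid data", {
  # single long lineage: matches the pooled-pair oracle at each lag
  set.seed(31)
  tau <- cumsum(runif(40, 5, 15))
  cyc <- extract_cycles(events_from_divisions(c(0, tau), end = max(tau) + 1))
  ac <- autocorrelation(cyc, max_lag = 3)
  for (l in 1:3) {
    pr <- ancestor_descendant_pairs(cyc, l)
    expect_equal(ac$estimate[l],
                 stats::cor(pr$tau_ancestor, pr$tau_descendant))
  }

  # iid generation times: the lag profile is jointly consistent with zero.
  # A fixed window length-biases the pairs (channels reaching high lags are
  # selected for short generation times), so the independence check uses the
  # first 12 cycles of every channel under a window long enough that all
  # channels qualify, and a portmanteau statistic sum n_k r_k^2 ~ chi2(5)
  # handles the multiplicity of the five lags at the 0.1% level.
  cfg <- generator_config(lineage_var_frac_c = 0, ar1_phi = 0,
                          n_channels = 400, window_h = 280,
                          baseline_hazard_per_h = 0, seed = 37)
  cyc_i <- extract_cycles(simulate_lineages(cfg))
  cyc_i <- cyc_i[cyc_i$generation_index <= 12, ]
  expect_equal(sum(table(cyc_i$channel_id) == 12), 400L)
  ac_i <- autocorrelation(cyc_i, max_lag = 5)
  Q <- sum(ac_i$n_pairs * ac_i$estimate^2)
  expect_lt(Q, stats::qchisq(0.999, df = 5))

  # lag-0 value is 1 when requested
  expect_equal(autocorrelation(cyc, 2, include_zero = TRUE)$estimate[1], 1)
})

test_that("intra-lineage correlations isolate the within-lineage component", {
  # strictly increasing taus give coefficient 1
  lin <- list(list(channel_id = "c1", taus = c(8, 9, 10, 11, 12),
                   fate = NA, last_observed_time_h = 50))
  class(lin[[1]]) <- "lineage_series"
  expect_equal(intra_lineage_correlations(lin)$per_lineage$estimate, 1)

  # per-lineage values equal the pooled oracle applied to each lineage alone
  cfg <- generator_config(n_channels = 120, seed = 41)
  cyc <- extract_cycles(simulate_lineages(cfg))
  lins <- filter_lineages(cyc, 5, events = NULL)
  res <- intra_lineage_correlations(lins)
  for (i in seq_len(min(10, nrow(res$per_lineage)))) {
    tau <- lins[[i]]$taus
    expect_equal(res$per_lineage$estimate[i],
                 stats::cor(tau[-length(tau)], tau[-1], method = "spearman"))
  }

  # on heritable data the intra-lineage mean is positive but smaller than
  # the pooled coefficient (between-lineage differences removed)
  pooled <- correlation(ancestor_descendant_pairs(cyc, 1),
                        "spearman")$estimate
  expect_gt(res$mean, 0)
  expect_lt(res$mean, pooled)

  expect_error(intra_lineage_correlations(list(c(1, 2, 3))), "at least 3")
})

test_that("division counts are tallied per channel within the window", {
  tab <- rbind(events_from_divisions(c(10, 20, 31), end = 100),
               events_from_divisions(c(40, 90), "c2", end = 95,
                                     end_event = "death"))
  dc <- division_count_distribution(tab, 100)
  expect_equal(dc$count[dc$channel_id == "c1"], 3L)
  expect_equal(dc$count[dc$channel_id == "c2"], 2L)
  dcs <- division_count_distribution(tab, 100, only_survivors = TRUE)
  expect_equal(dcs$channel_id, "c1")
})
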