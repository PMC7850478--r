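test_that("sample_mixture draws match the model density", {
  p <- l1210_params()
  tau <- sample_mixture(2e5, p, seed = 1)
  expect_true(all(tau >= p$tau0))

  # closed-form mean verified against quadrature of tau * g(tau)
  m_quad <- stats::integrate(function(x) x * mixture_pdf(x, p),
                             p$tau0, Inf, rel.tol = 1e-10)$value
  expect_equal(mixture_mean(p), m_quad, tolerance = 1e-8)
  expect_equal(m_quad, 10.469, tolerance = 1e-4)
  # sample mean within 4 MC standard errors of the model mean
  v <- stats::integrate(function(x) (x - m_quad)^2 * mixture_pdf(x, p),
                        p$tau0, Inf)$value
  expect_lt(abs(mean(tau) - m_quad), 4 * sqrt(v / length(tau)))

  # empirical survival at tau0 is exactly 1
  expect_equal(mean(tau >= p$tau0), 1)
  expect_error(mixture_params(0.1, 0.5, 8, 0.1), "lambda1")
})

test_that("mixture quantile inverts the CDF to bisection tolerance", {
  p <- l1210_params()
  pr <- c(0, 1e-6, 0.01, 0.5, 0.9, 0.999, 0.999999)
  q <- mixture_quantile(pr, p)
  expect_equal(mixture_cdf(q, p), pr, tolerance = 1e-7)
  expect_equal(mixture_quantile(0, p), p$tau0)
  expect_error(mixture_quantile(1, p), "\\[0, 1\\)")
})

test_that("simulated lineages are seed-deterministic and respect hazards", {
  cfg <- generator_config(n_channels = 30, seed = 99)
  ev1 <- simulate_lineages(cfg)
  ev2 <- simulate_lineages(cfg)
  expect_identical(ev1, ev2)

  # zero hazard: every channel survives to the end of observation
  cfg0 <- generator_config(n_channels = 40, baseline_hazard_per_h = 0,
                           seed = 3)
  ev0 <- simulate_lineages(cfg0)
  expect_equal(sum(ev0$event == "death"), 0L)
  expect_equal(sum(ev0$event == "end_of_observation"), 40L)

  # snapped event times sit on the frame grid
  expect_true(all(abs(ev0$time_h / cfg0$dt_h -
                        round(ev0$time_h / cfg0$dt_h)) < 1e-6))

  # c = 0, phi = 0: mother-daughter correlation indistinguishable from 0
  cfg_i <- generator_config(lineage_var_frac_c = 0, ar1_phi = 0,
                            n_channels = 300, seed = 5)
  pr <- ancestor_descendant_pairs(extract_cycles(simulate_lineages(cfg_i)), 1)
  r <- stats::cor(pr$tau_ancestor, pr$tau_descendant)
  expect_lt(abs(r), 3 / sqrt(nrow(pr)))
})

test_that("generated generation times keep the mixture marginal", {
  # first cycles of every channel, long window, no deaths, no frame snapping:
  # no length-biased selection and no discretization
  p <- l1210_params()
  cfg <- generator_config(n_channels = 1000, window_h = 600,
                          baseline_hazard_per_h = 0, snap_to_grid = FALSE,
                          seed = 31)
  cyc <- extract_cycles(simulate_lineages(cfg))
  first10 <- do.call(c, lapply(split(cyc$tau_h, cyc$channel_id), head, 10))
  ref <- sample_mixture(length(first10), p, seed = 32)
  ks <- suppressWarnings(stats::ks.test(first10, ref))
  expect_gt(ks$p.value, 0.01)

  # frame snapping perturbs each recorded division by less than one frame
  cfg_s <- generator_config(n_channels = 50, baseline_hazard_per_h = 0,
                            snap_to_grid = TRUE, seed = 77)
  cfg_u <- generator_config(n_channels = 50, baseline_hazard_per_h = 0,
                            snap_to_grid = FALSE, seed = 77)
  ts <- simulate_lineages(cfg_s)
  tu <- simulate_lineages(cfg_u)
  ds <- ts$time_h[ts$event == "division"]
  du <- tu$time_h[tu$event == "division"]
  expect_equal(length(ds), length(du))
  expect_true(all(ds - du >= -1e-9 & ds - du < cfg_s$dt_h + 1e-9))
})

test_that("lag-correlation profile decays monotonically within noise", {
  cfg <- generator_config(n_channels = 800, seed = 17)
  cyc <- extract_cycles(simulate_lineages(cfg))
  ac <- autocorrelation(cyc, max_lag = 10)
  expect_equal(ac$lag, 1:10)
  # non-increasing up to Monte-Carlo error
  expect_true(all(diff(ac$estimate) < 0.04))
  expect_gt(ac$estimate[1], ac$estimate[10])
})

test_that("calibrate_copula handles limits and latent algebra", {
  expect_equal(calibrate_copula(target_lag1 = 0)[c("c", "phi")],
               list(c = 0, phi = 0))
  expect_error(calibrate_copula(0.2, 0.62), "targets")

  # latent lag-k correlation c + (1-c) phi^k is monotone in c and phi
  ck <- function(c, phi, k) c + (1 - c) * phi^k
  grid_c <- seq(0, 0.9, by = 0.1)
  grid_phi <- seq(0.05, 0.9, by = 0.1)
  for (k in c(1, 5, 10)) {
    for (phi in grid_phi) expect_true(all(diff(ck(grid_c, phi, k)) > 0))
    for (c in grid_c) expect_true(all(diff(ck(c, grid_phi, k)) > 0))
  }
  # the closed-form solver inverts the latent profile
  sol <- mmlineage:::solve_latent_cphi(0.7, 0.3)
  expect_equal(ck(sol$c, sol$phi, 1), 0.7, tolerance = 1e-6)
  expect_equal(ck(sol$c, sol$phi, 10), 0.3, tolerance = 1e-6)
})

test_that("shifted-gamma comparator series are i.i.d. draws of the stated law", {
  len <- 200L
  s <- sample_shifted_gamma(n_series = 100, length_series = len,
                            shape = 2, scale = 1.5, shift = 8.375, seed = 9)
  expect_length(s, 100L)
  x <- unlist(s)
  expect_true(all(x >= 8.375))
  # mean = shift + shape * scale, within 4 SE
  se <- sqrt(2 * 1.5^2 / length(x))
  expect_lt(abs(mean(x) - (8.375 + 3)), 4 * se)
  # mean lag-1 autocorrelation at its finite-sample center -1/(len-1),
  # within 3 SE of the mean over series
  r1 <- mean(vapply(s, function(v) stats::cor(v[-1], v[-length(v)]),
                    numeric(1)))
  expect_lt(abs(r1 + 1 / (len - 1)), 3 / sqrt(len - 1) / sqrt(100))
  expect_error(sample_shifted_gamma(shape = -1), "shape")
})

test_that("deterministic comparator series are reproducible orbits", {
  d1 <- deterministic_series(n_series = 20, length_series = 12, seed = 4)
  d2 <- deterministic_series(n_series = 20, length_series = 12, seed = 4)
  expect_identical(d1, d2)
  # distinct initial conditions give distinct orbits
  expect_gt(min(vapply(2:20, function(i) max(abs(d1[[1]] - d1[[i]])),
                       numeric(1))), 1e-6)
  # ensemble spans the requested generation-time range
  x <- unlist(d1)
  expect_equal(range(x), c(8, 40))
})

test_that("pseudo-lineage division counts follow the accumulation rule", {
  expect_equal(pseudo_lineage_division_counts(10.0, 7, 168, seed = 1),
               rep(16L, 7))
  expect_equal(pseudo_lineage_division_counts(c(9, 11), 5, 5, seed = 1),
               rep(0L, 5))
  expect_error(pseudo_lineage_division_counts(numeric(0), 5, 10),
               "non-empty")
})
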