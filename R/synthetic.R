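#' Configuration of the synthetic lineage generator
#'
#' Describes a simulated mother-machine experiment. Generation times have the
#' mixed shifted-exponential marginal `marginal`; their heritability across
#' generations comes from a Gaussian copula with two timescales: a latent
#' standard-normal score \eqn{z_k = u + x_k} per generation, where `u` is a
#' channel-persistent component with variance `lineage_var_frac_c` and `x_k`
#' a stationary AR(1) with coefficient `ar1_phi` and variance
#' `1 - lineage_var_frac_c`; the generation time is the marginal quantile of
#' \eqn{\Phi(z_k)}. The latent lag-k autocorrelation is
#' \eqn{c + (1-c)\phi^k}. Death occurs with a constant baseline hazard;
#' an optional drug phase switches, after a delay, to a hazard that depends
#' on each lineage's pre-exposure growth state. Division and death times are
#' snapped to the `dt_h` time-lapse grid (default 10 min), emulating frame
#' sampling.
#'
#' The default `lineage_var_frac_c` and `ar1_phi` were produced by
#' [calibrate_copula()] at the default heritability targets (mother-daughter
#' correlation 0.62, lag-10 correlation 0.20).
#'
#' @param marginal A [mixture_params()] object (default [l1210_params()]).
#' @param lineage_var_frac_c Fraction in `[0, 1)` of latent variance that is
#'   lineage-persistent.
#' @param ar1_phi AR(1) coefficient of the within-lineage latent innovation,
#'   in `(-1, 1)`.
#' @param n_channels Number of growth channels.
#' @param window_h Observation window, hours (default 168, i.e. seven days).
#' @param dt_h Time-lapse frame interval, hours (default 1/6, i.e. 10 min).
#' @param baseline_hazard_per_h Constant death hazard per hour under benign
#'   conditions (default 2.239e-3).
#' @param drug Optional [drug_phase_config()].
#' @param snap_to_grid Snap recorded event times to the `dt_h` grid
#'   (default `TRUE`).
#' @param seed Integer seed; every run is reproducible from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(marginal = l1210_params(),
                             lineage_var_frac_c = 0.382,
                             ar1_phi = 0.583,
                             n_channels = 500L,
                             window_h = 168,
                             dt_h = 1 / 6,
                             baseline_hazard_per_h = 2.239e-3,
                             drug = NULL,
                             snap_to_grid = TRUE,
                             seed = 1L) {
  marginal <- as_mixture_params(marginal)
  stopifnot(lineage_var_frac_c >= 0, lineage_var_frac_c < 1,
            abs(ar1_phi) < 1, n_channels >= 1, window_h > 0, dt_h > 0,
            baseline_hazard_per_h >= 0)
  if (!is.null(drug)) {
    drug <- as_drug_phase_config(drug)
    if (drug$exposure_start_h <= 0 || drug$exposure_start_h >= window_h) {
      stop("drug exposure_start_h must lie inside the observation window")
    }
  }
  structure(list(
    marginal = marginal, lineage_var_frac_c = lineage_var_frac_c,
    ar1_phi = ar1_phi, n_channels = as.integer(n_channels),
    window_h = window_h, dt_h = dt_h,
    baseline_hazard_per_h = baseline_hazard_per_h, drug = drug,
    snap_to_grid = isTRUE(snap_to_grid), seed = as.integer(seed)
  ), class = "generator_config")
}

#' Drug-phase configuration
#'
#' Defines delayed, growth-state-dependent killing: from
#' `exposure_start_h + onset_delay_h` onward, lineages classified fast-cycling
#' (at least `fast_threshold` divisions before exposure) die with hazard
#' `hazard_fast_per_h` and slow-cycling lineages with `hazard_slow_per_h`.
#' The defaults (50 h delay; 0.02 and 0.002 per hour) emulate the qualitative
#' pattern of Mitomycin C exposure: an endurance period followed by
#' accelerating death of fast-cycling lineages, while slow-cycling lineages
#' decay slowly and retain survivors.
#'
#' @param exposure_start_h Start of drug exposure, hours.
#' @param onset_delay_h Delay between exposure and the rise in death rate,
#'   hours (default 50).
#' @param hazard_fast_per_h,hazard_slow_per_h Post-onset death hazards per
#'   hour for fast- and slow-cycling lineages.
#' @param fast_threshold Minimum pre-exposure division count for the
#'   fast-cycling label (default 7).
#' @return An object of class `drug_phase_config`.
#' @export
drug_phase_config <- function(exposure_start_h = 96,
                              onset_delay_h = 50,
                              hazard_fast_per_h = 0.02,
                              hazard_slow_per_h = 0.002,
                              fast_threshold = 7L) {
  stopifnot(exposure_start_h > 0, onset_delay_h >= 0,
            hazard_fast_per_h >= 0, hazard_slow_per_h >= 0,
            fast_threshold >= 0)
  structure(list(exposure_start_h = exposure_start_h,
                 onset_delay_h = onset_delay_h,
                 hazard_fast_per_h = hazard_fast_per_h,
                 hazard_slow_per_h = hazard_slow_per_h,
                 fast_threshold = as.integer(fast_threshold)),
            class = "drug_phase_config")
}

as_drug_phase_config <- function(x) {
  if (inherits(x, "drug_phase_config")) return(x)
  if (is.list(x)) return(do.call(drug_phase_config, x))
  stop("cannot interpret object as drug_phase_config")
}

#' Sample generation times from the mixture model
#'
#' Draws i.i.d. generation times: with probability `1 - a` the draw is
#' `tau0 + Exponential(lambda1)`, with probability `a` it is
#' `tau0 + Exponential(lambda2)`.
#'
#' @param n Number of draws.
#' @param params A [mixture_params()] object.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return Numeric vector of generation times in hours (all `>= tau0`).
#' @export
sample_mixture <- function(n, params, seed = NULL) {
  params <- as_mixture_params(params)
  if (!is.null(seed)) set.seed(seed)
  slow <- stats::runif(n) < params$a
  rate <- ifelse(slow, params$lambda2, params$lambda1)
  params$tau0 + stats::rexp(n, rate = 1) / rate
}

snap_up <- function(t, dt) ceiling(t / dt - 1e-9) * dt

#' Simulate a mother-machine experiment
#'
#' Generates an event table (see [read_events()] for the data model) under a
#' [generator_config()]. Per channel: a lineage-persistent latent component
#' plus an AR(1) innovation drive generation times through the Gaussian
#' copula (quantile inversion of the mixture CDF by bisection to 1e-9 h); the
#' first generation is drawn from the stationary latent distribution. Death
#' competes with division as an inhomogeneous Poisson event whose hazard is
#' the baseline rate before drug onset and the state-appropriate drug hazard
#' after it. Events are recorded at the end of their time-lapse frame when
#' `snap_to_grid` is set; each channel ends with a `death` or an
#' `end_of_observation` event.
#'
#' @param config A [generator_config()].
#' @return A validated event `data.frame`.
#' @export
#' @examples
#' ev <- simulate_lineages(generator_config(n_channels = 20, seed = 7))
#' table(ev$event)
simulate_lineages <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  pm <- config$marginal
  cc <- config$lineage_var_frac_c
  phi <- config$ar1_phi
  n <- config$n_channels
  W <- config$window_h
  dt <- config$dt_h

  u <- stats::rnorm(n, 0, sqrt(cc))
  sd_x <- sqrt(1 - cc)
  sd_in <- sd_x * sqrt(1 - phi^2)

  # draw generation-time and death-exponential matrices blockwise until every
  # channel's cumulative division time exceeds the window
  x <- stats::rnorm(n, 0, sd_x)
  taus <- NULL
  dexp <- NULL
  block <- max(8L, ceiling(W / max(pm$tau0, 1)) + 2L)
  repeat {
    Tb <- matrix(0, n, block)
    Eb <- matrix(0, n, block)
    for (k in seq_len(block)) {
      Tb[, k] <- mixture_quantile(stats::pnorm(u + x), pm)
      Eb[, k] <- stats::rexp(n)
      x <- phi * x + stats::rnorm(n, 0, sd_in)
    }
    taus <- cbind(taus, Tb)
    dexp <- cbind(dexp, Eb)
    if (all(rowSums(taus) > W)) break
  }

  drug <- config$drug
  t_exp <- if (is.null(drug)) Inf else drug$exposure_start_h
  t_on <- if (is.null(drug)) Inf else drug$exposure_start_h + drug$onset_delay_h
  h0 <- config$baseline_hazard_per_h
  rec <- function(t) if (config$snap_to_grid) snap_up(t, dt) else t

  ids <- sprintf("ch%04d", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tdiv <- cumsum(taus[i, ])
    times <- numeric(0)
    events <- character(0)
    t_prev <- 0
    t_rec_prev <- -Inf
    hz_state <- NA_real_  # post-onset hazard, fixed once growth state is known
    dead <- FALSE
    push <- function(t, ev) {
      t <- max(rec(t), t_rec_prev + if (config$snap_to_grid) dt else 1e-12)
      times <<- c(times, t)
      events <<- c(events, ev)
      t_rec_prev <<- t
    }
    for (k in seq_along(tdiv)) {
      t_next <- tdiv[k]
      t_cap <- min(t_next, W)
      if (is.na(hz_state) && t_cap >= t_exp) {
        ndiv_pre <- sum(times[events == "division"] < t_exp)
        fast <- ndiv_pre >= drug$fast_threshold
        hz_state <- if (fast) drug$hazard_fast_per_h else drug$hazard_slow_per_h
      }
      # cumulative hazard over (t_prev, t_cap): baseline before onset,
      # state hazard after
      a1 <- max(0, min(t_cap, t_on) - t_prev)
      a2 <- max(0, t_cap - max(t_prev, t_on))
      H <- h0 * a1 + ifelse(a2 > 0, hz_state * a2, 0)
      E <- dexp[i, k]
      if (is.finite(H) && E < H) {
        # death inside this generation: invert the piecewise hazard
        if (h0 > 0 && E < h0 * a1) {
          t_death <- t_prev + E / h0
        } else {
          t_death <- max(t_prev, t_on) + (E - h0 * a1) / hz_state
        }
        push(min(t_death, W), "death")
        dead <- TRUE
        break
      }
      if (t_next > W) break
      push(t_next, "division")
      t_prev <- t_next
    }
    if (!dead) {
      # survivors end with an explicit end-of-observation record
      t_end <- max(W, t_rec_prev + if (config$snap_to_grid) dt else 1e-12)
      times <- c(times, t_end)
      events <- c(events, "end_of_observation")
    }
    out[[i]] <- data.frame(channel_id = ids[i], time_h = times,
                           event = events, stringsAsFactors = FALSE)
  }
  validate_events(do.call(rbind, out))
}

# solve c + (1 - c) * phi^k for (c, phi) given latent lag-1 and lag-10 targets
solve_latent_cphi <- function(rho1, rho10) {
  stopifnot(rho1 > 0, rho10 > 0, rho10 < rho1, rho1 < 1)
  f <- function(phi) {
    cc <- (rho1 - phi) / (1 - phi)
    cc + (1 - cc) * phi^10 - rho10
  }
  lo <- 1e-6
  hi <- rho1 - 1e-9
  if (f(lo) < 0) return(list(c = rho1, phi = 0))  # rho10 ~= rho1: pure lineage effect
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  list(c = max(0, (rho1 - root) / (1 - root)), phi = root)
}

measure_lag_correlations <- function(config, lags = c(1L, 10L)) {
  ev <- simulate_lineages(config)
  cyc <- extract_cycles(ev)
  vapply(lags, function(l) {
    p <- ancestor_descendant_pairs(cyc, lag = l)
    stats::cor(p$tau_ancestor, p$tau_descendant)
  }, numeric(1))
}

#' Calibrate the heritability copula to target lag correlations
#'
#' Finds the lineage-persistent variance fraction `c` and AR(1) coefficient
#' `phi` such that the generator reproduces target mother-daughter (lag-1)
#' and lag-10 Pearson correlations of generation time. The search starts at
#' the latent-scale closed form (latent lag-k correlation
#' \eqn{c + (1-c)\phi^k}) and corrects the attenuation introduced by the
#' nonlinear marginal transform by iterated simulation: after each
#' simulation, the latent targets are scaled by the ratio of target to
#' achieved correlation and `(c, phi)` re-solved.
#'
#' @param target_lag1 Target mother-daughter Pearson correlation (default
#'   0.62).
#' @param target_lag10 Target lag-10 correlation (default 0.20); must satisfy
#'   `0 < target_lag10 < target_lag1 < 1` (a zero `target_lag1` returns the
#'   independence limit `c = phi = 0`).
#' @param params Marginal [mixture_params()] (default [l1210_params()]).
#' @param seed Integer seed for the calibration simulations.
#' @param n_channels Channels per calibration simulation (default 1500).
#' @param window_h Observation window used in calibration (default 168 h).
#' @param tol Acceptable absolute deviation of both achieved correlations in
#'   the verification stage (default 0.02).
#' @param n_search Stochastic-approximation iterations (default 6).
#' @param n_verify Verification simulations averaged per check (default 3).
#' @return A list with elements `c`, `phi`, `achieved` (named lag-1/lag-10
#'   correlations averaged over the verification simulations) and `trace`
#'   (one row per search iteration).
#' @export
calibrate_copula <- function(target_lag1 = 0.62, target_lag10 = 0.20,
                             params = l1210_params(), seed = 1L,
                             n_channels = 1500L, window_h = 168,
                             tol = 0.02, n_search = 6L, n_verify = 3L) {
  params <- as_mixture_params(params)
  if (abs(target_lag1) < 1e-12) {
    return(list(c = 0, phi = 0, achieved = c(lag1 = 0, lag10 = 0),
                trace = NULL))
  }
  if (!(target_lag10 > 0 && target_lag10 < target_lag1 && target_lag1 < 1)) {
    stop("targets must satisfy 0 < target_lag10 < target_lag1 < 1")
  }
  sim_counter <- 0L
  measure <- function(cc, phi, reps = 1L) {
    got <- vapply(seq_len(reps), function(i) {
      sim_counter <<- sim_counter + 1L
      cfg <- generator_config(marginal = params,
                              lineage_var_frac_c = cc, ar1_phi = phi,
                              n_channels = n_channels, window_h = window_h,
                              seed = seed + sim_counter)
      measure_lag_correlations(cfg)
    }, numeric(2))
    rowMeans(got)
  }
  clamp <- function(rho1, rho10) {
    rho1 <- min(max(rho1, 1e-4), 0.995)
    rho10 <- min(max(rho10, 1e-5), 0.98 * rho1)
    c(rho1, rho10)
  }
  # stochastic approximation on the latent lag targets: each iteration
  # measures the generated correlations once and takes a damped
  # through-origin Newton step; the implied fixed-point estimates
  # rho * target/measured from the later iterations are averaged to cancel
  # simulation noise (single-iteration acceptance would select noise)
  rho <- clamp(target_lag1, target_lag10)
  trace <- NULL
  implied <- NULL
  for (it in seq_len(n_search)) {
    sol <- solve_latent_cphi(rho[1], rho[2])
    got <- measure(sol$c, sol$phi)
    trace <- rbind(trace, data.frame(iter = it, c = sol$c, phi = sol$phi,
                                     lag1 = got[1], lag10 = got[2]))
    imp <- clamp(rho[1] * target_lag1 / got[1],
                 rho[2] * target_lag10 / got[2])
    if (it >= 2L) implied <- rbind(implied, imp)
    gain <- if (it <= 2L) 0.9 else 0.6
    rho <- clamp(rho[1] + gain * (imp[1] - rho[1]),
                 rho[2] + gain * (imp[2] - rho[2]))
  }
  best <- NULL
  for (round in seq_len(3L)) {
    rho_hat <- clamp(mean(implied[, 1]), mean(implied[, 2]))
    sol <- solve_latent_cphi(rho_hat[1], rho_hat[2])
    got <- measure(sol$c, sol$phi, reps = n_verify)
    err <- c(got[1] - target_lag1, got[2] - target_lag10)
    if (is.null(best) || max(abs(err)) < best$err) {
      best <- list(c = sol$c, phi = sol$phi,
                   achieved = c(lag1 = got[1], lag10 = got[2]),
                   err = max(abs(err)))
    }
    if (all(abs(err) <= 0.9 * tol)) {
      return(list(c = sol$c, phi = sol$phi,
                  achieved = c(lag1 = got[1], lag10 = got[2]),
                  trace = trace))
    }
    # fold the averaged verification measurement into the estimate
    implied <- rbind(implied,
                     matrix(clamp(rho_hat[1] * target_lag1 / got[1],
                                  rho_hat[2] * target_lag10 / got[2]),
                            nrow = n_verify, ncol = 2, byrow = TRUE))
  }
  if (best$err <= tol) {
    return(list(c = best$c, phi = best$phi, achieved = best$achieved,
                trace = trace))
  }
  stop(sprintf(paste0(
    "calibration did not reach targets (%.3f, %.3f) within +/-%.3f; ",
    "best achieved (%.3f, %.3f) at c = %.3f, phi = %.3f"),
    target_lag1, target_lag10, tol,
    best$achieved[1], best$achieved[2], best$c, best$phi))
}

#' Sample i.i.d. shifted-gamma generation-time series
#'
#' Comparator ensemble for the correlation-dimension analysis: generation
#' times drawn i.i.d. from `shift + Gamma(shape, scale)` and reshaped into
#' lineage-like series. Being memoryless across generations, this is the
#' canonical stochastic comparator: its correlation-dimension estimate grows
#' with the embedding dimension without saturating.
#'
#' @param n_series Number of series (default 300).
#' @param length_series Generations per series (default 12).
#' @param shape,scale Gamma shape and scale (defaults 2 and 1.5 give a
#'   right-skewed generation-time-like spread of mean 3 h above the shift).
#' @param shift Minimum value in hours (default 8.375).
#' @param seed Optional integer seed.
#' @return A list of `n_series` numeric vectors.
#' @export
sample_shifted_gamma <- function(n_series = 300L, length_series = 12L,
                                 shape = 2, scale = 1.5, shift = 8.375,
                                 seed = NULL) {
  stopifnot(shape > 0, scale > 0, n_series >= 1, length_series >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- shift + stats::rgamma(n_series * length_series, shape = shape,
                                 scale = scale)
  split(draws, rep(seq_len(n_series), each = length_series))
}

rossler_deriv <- function(s, a = 0.2, b = 0.2, cc = 5.7) {
  cbind(-s[, 2] - s[, 3],
        s[, 1] + a * s[, 2],
        b + s[, 3] * (s[, 1] - cc))
}

rossler_rk4 <- function(s, h) {
  k1 <- rossler_deriv(s)
  k2 <- rossler_deriv(s + h / 2 * k1)
  k3 <- rossler_deriv(s + h / 2 * k2)
  k4 <- rossler_deriv(s + h * k3)
  s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Deterministic chaotic comparator series
#'
#' Comparator ensemble for the correlation-dimension analysis representing
#' deterministic low-dimensional dynamics: each series samples the
#' x-coordinate of one orbit of the Rossler system (a = b = 0.2, c = 5.7), a
#' canonical low-dimensional chaotic benchmark, from a random initial
#' condition after a transient onto the attractor, at a fixed stride; the
#' ensemble is affinely rescaled to span the generation-time range `range_h`.
#' Because the flow winds smoothly and stretches little over the sampled
#' span, an ensemble of a few hundred orbits resolves the attractor: the
#' correlation-dimension estimate saturates near the attractor dimension
#' (about 2) as the embedding dimension grows, the signature distinguishing
#' deterministic from stochastic generation-time dynamics.
#'
#' @param n_series Number of orbits (default 300).
#' @param length_series Points per orbit (default 12).
#' @param range_h Target range in hours after rescaling (default `c(8, 40)`).
#' @param stride Time units of the flow between consecutive samples (default
#'   0.5; the mean revolution takes about 6).
#' @param transient Time units discarded before sampling (default 100).
#' @param seed Optional integer seed for the initial conditions.
#' @return A list of `n_series` numeric vectors.
#' @export
deterministic_series <- function(n_series = 300L, length_series = 12L,
                                 range_h = c(8, 40), stride = 0.5,
                                 transient = 100, seed = NULL) {
  stopifnot(length_series >= 2, n_series >= 1, stride > 0)
  if (!is.null(seed)) set.seed(seed)
  h <- 0.05
  s <- cbind(stats::runif(n_series, -5, 5),
             stats::runif(n_series, -5, 5),
             stats::runif(n_series, 0, 1))
  for (i in seq_len(round(transient / h))) s <- rossler_rk4(s, h)
  xs <- matrix(0, n_series, length_series)
  per <- round(stride / h)
  for (j in seq_len(length_series)) {
    xs[, j] <- s[, 1]
    for (k in seq_len(per)) s <- rossler_rk4(s, h)
  }
  lo <- min(xs)
  hi <- max(xs)
  xs <- range_h[1] + (xs - lo) / (hi - lo) * (range_h[2] - range_h[1])
  lapply(seq_len(n_series), function(i) xs[i, ])
}

#' Division counts of i.i.d. pseudo-lineages
#'
#' Builds the no-heritability null for the division-count distribution:
#' pseudo-lineages assembled by sampling generation times i.i.d. with
#' replacement from a pool, accumulated from time zero; the count is the
#' number of divisions completed within the observation window. Compared with
#' lineages generated under heritable generation times, the i.i.d. null has a
#' narrower left tail (smaller count variance).
#'
#' @param tau_pool Non-empty pool of generation times, hours.
#' @param n_lineages Number of pseudo-lineages.
#' @param window_h Observation window, hours.
#' @param seed Optional integer seed.
#' @return Integer vector of division counts, one per pseudo-lineage.
#' @export
#' @examples
#' pseudo_lineage_division_counts(10.0, 5, 168, seed = 1)  # all 16
pseudo_lineage_division_counts <- function(tau_pool, n_lineages, window_h,
                                           seed = NULL) {
  if (!length(tau_pool)) stop("tau_pool must be non-empty")
  stopifnot(all(tau_pool > 0), n_lineages >= 1, window_h > 0)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_lineages), function(i) {
    t <- 0
    count <- 0L
    repeat {
      t <- t + tau_pool[sample.int(length(tau_pool), 1L)]
      if (t > window_h) break
      count <- count + 1L
    }
    count
  }, integer(1))
}
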