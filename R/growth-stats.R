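#' Cumulative instantaneous division probability
#'
#' For each time-lapse bin `(t, t + dt]`, the instantaneous division
#' probability is `D(t)/N(t)`, where `N(t)` is the number of lineages alive
#' at `t` and `D(t)` the number of divisions recorded in the bin. The
#' returned curve is the running sum of `D/N`; under balanced growth it
#' increases linearly with slope equal to the population division rate.
#'
#' @param events A validated event `data.frame`.
#' @param dt_h Bin width in hours (default 1/6, the 10-min frame interval).
#' @return An object of class `division_curve`: a `data.frame` with columns
#'   `bin_time_h` (right bin edge) and `cumulative`. If some bin has no
#'   lineage alive the curve is truncated there with a warning.
#' @export
cumulative_division_probability <- function(events, dt_h = 1 / 6) {
  stopifnot(dt_h > 0)
  events <- validate_events(events)
  end_t <- vapply(split(events$time_h, events$channel_id), max, numeric(1))
  t_max <- max(events$time_h)
  n_bins <- ceiling(t_max / dt_h - 1e-9)
  div_t <- events$time_h[events$event == "division"]
  div_bin <- pmax(1L, ceiling(div_t / dt_h - 1e-9))
  D <- tabulate(div_bin, nbins = n_bins)
  starts <- (seq_len(n_bins) - 1L) * dt_h
  # alive at the bin start: terminal event strictly later
  N <- vapply(starts, function(t0) sum(end_t > t0 + 1e-9), numeric(1))
  if (any(N == 0)) {
    keep <- seq_len(min(which(N == 0)) - 1L)
    warning("no lineage alive from bin ", min(which(N == 0)),
            "; curve truncated")
    D <- D[keep]; N <- N[keep]; n_bins <- length(keep)
  }
  out <- data.frame(bin_time_h = seq_len(n_bins) * dt_h,
                    cumulative = cumsum(D / N))
  class(out) <- c("division_curve", "data.frame")
  out
}

#' Fit the population division rate
#'
#' Ordinary least-squares slope of the cumulative division probability versus
#' time; under balanced growth this is the constant per-hour division rate.
#'
#' @param curve A `division_curve` from [cumulative_division_probability()].
#' @return List with `rate_per_h`, `se` and the underlying `lm` fit.
#' @export
fit_division_rate <- function(curve) {
  if (nrow(curve) < 3L) stop("need at least 3 points to fit a rate")
  if (stats::var(curve$bin_time_h) == 0) stop("degenerate time vector")
  fit <- stats::lm(cumulative ~ bin_time_h, data = curve)
  co <- summary(fit)$coefficients
  list(rate_per_h = unname(co["bin_time_h", "Estimate"]),
       se = unname(co["bin_time_h", "Std. Error"]), fit = fit)
}

survival_curve_from_events <- function(events, dt_h) {
  events <- validate_events(events)
  n0 <- length(unique(events$channel_id))
  deaths <- events$time_h[events$event == "death"]
  t_max <- max(events$time_h)
  tg <- seq(0, snap_up(t_max, dt_h), by = dt_h)
  surv <- vapply(tg, function(t) (n0 - sum(deaths <= t + 1e-9)) / n0,
                 numeric(1))
  out <- data.frame(time_h = tg, surviving_fraction = surv,
                    se = sqrt(pmax(surv * (1 - surv), 0) / n0))
  attr(out, "n0") <- n0
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Lineage death rate from the exponential survival decay
#'
#' Plots the fraction of surviving lineages over time on the time-lapse grid
#' and fits a line to its logarithm by ordinary least squares over the span
#' where the fraction is positive; the death rate is minus the slope.
#' Lineages alive at the end of observation are censored: they contribute to
#' the at-risk count throughout but never as events. The standard error of
#' the rate is estimated by a nonparametric bootstrap over channels (the
#' per-point OLS standard error would ignore the strong serial correlation of
#' a survival curve). Per-point curve standard errors are binomial,
#' `sqrt(S(1-S)/N0)`.
#'
#' @param events A validated event `data.frame`.
#' @param dt_h Grid interval in hours (default 1/6).
#' @param n_boot Bootstrap replicates for the rate standard error (default
#'   200; uses the current RNG stream).
#' @return List with `rate_per_h`, `se`, `n_deaths`, `curve` (a
#'   `survival_curve` with columns `time_h`, `surviving_fraction`, `se`) and
#'   `no_deaths` flag. With no deaths the rate is 0 and the standard error
#'   `NA` (infinite relative error).
#' @export
death_rate <- function(events, dt_h = 1 / 6, n_boot = 200L) {
  events <- validate_events(events)
  channels <- unique(events$channel_id)
  if (length(channels) < 2L) stop("need at least 2 lineages")
  curve <- survival_curve_from_events(events, dt_h)
  deaths <- events$time_h[events$event == "death"]
  ends <- vapply(split(events$time_h, events$channel_id), max, numeric(1))
  is_death <- vapply(split(events$event, events$channel_id),
                     function(e) any(e == "death"), logical(1))
  if (!length(deaths)) {
    return(list(rate_per_h = 0, se = NA_real_, n_deaths = 0L, curve = curve,
                no_deaths = TRUE))
  }
  slope_from <- function(death_times, n0, t_grid) {
    s <- vapply(t_grid, function(t) (n0 - sum(death_times <= t + 1e-9)) / n0,
                numeric(1))
    ok <- s > 0
    -unname(stats::coef(stats::lm(log(s[ok]) ~ t_grid[ok]))[2])
  }
  n0 <- length(channels)
  rate <- slope_from(deaths, n0, curve$time_h)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n0, n0, replace = TRUE)
    slope_from(ends[idx][is_death[idx]], n0, curve$time_h)
  }, numeric(1))
  list(rate_per_h = rate, se = stats::sd(boots),
       n_deaths = length(deaths), curve = curve, no_deaths = FALSE)
}

fisher_z_se <- function(r, n) {
  if (n <= 3) return(NA_real_)
  z <- atanh(r)
  sz <- 1 / sqrt(n - 3)
  (tanh(z + sz) - tanh(z - sz)) / 2
}

#' Correlation coefficient of generation-time pairs, with standard error
#'
#' Pearson product-moment or Spearman rank correlation of ancestor-descendant
#' generation-time pairs. Standard errors come from the Fisher z transform
#' (applied at the rank scale for Spearman).
#'
#' @param pairs A `data.frame` from [ancestor_descendant_pairs()] (columns
#'   `tau_ancestor`, `tau_descendant`), or a two-column numeric matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `estimate`, `se`, `n` and `method`.
#' @export
correlation <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(pairs) && all(c("tau_ancestor", "tau_descendant") %in%
                                  names(pairs))) {
    x <- pairs$tau_ancestor
    y <- pairs$tau_descendant
  } else {
    pairs <- as.matrix(pairs)
    x <- pairs[, 1]
    y <- pairs[, 2]
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- stats::cor(x, y, method = method)
  list(estimate = r, se = fisher_z_se(r, n), n = n, method = method)
}

#' Correlation from one mother-daughter pair per lineage
#'
#' Fast-cycling lineages contribute many more mother-daughter pairs than
#' slow-cycling ones, biasing the pooled correlation toward the fast state.
#' This resampling estimator removes that bias: in each resample, one
#' uniformly chosen mother-daughter pair per lineage enters the coefficient;
#' the mean and standard deviation over resamples are reported.
#'
#' @param cycles A cycle `data.frame` from [extract_cycles()].
#' @param n_resamples Number of resamples (default 1000).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param seed Optional integer seed.
#' @return List with `mean`, `sd`, `n_lineages`, `method` and the per-resample
#'   `values`.
#' @export
one_pair_per_lineage_correlation <- function(cycles, n_resamples = 1000L,
                                             method = c("spearman", "pearson"),
                                             seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  pairs <- ancestor_descendant_pairs(cycles, lag = 1L)
  by_ch <- split(seq_len(nrow(pairs)), pairs$channel_id)
  if (length(by_ch) < 3L) stop("need at least 3 lineages with pairs")
  values <- vapply(seq_len(n_resamples), function(b) {
    idx <- vapply(by_ch, function(rows) {
      if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
    }, integer(1))
    stats::cor(pairs$tau_ancestor[idx], pairs$tau_descendant[idx],
               method = method)
  }, numeric(1))
  list(mean = mean(values), sd = stats::sd(values),
       n_lineages = length(by_ch), method = method, values = values)
}

#' Autocorrelation of generation time across generations
#'
#' For each lag k, the Pearson (or Spearman) correlation over all
#' within-channel generation-time pairs separated by k generations, pooled
#' across channels; lag 1 is the mother-daughter correlation.
#'
#' @param cycles A cycle `data.frame` from [extract_cycles()].
#' @param max_lag Largest lag (default 10).
#' @param method Correlation method (default `"pearson"`).
#' @param include_zero If `TRUE`, prepend the trivial lag-0 value of 1.
#' @return A `data.frame` with columns `lag`, `estimate`, `se`, `n_pairs`;
#'   lags with fewer than 3 pairs are omitted with a warning.
#' @export
autocorrelation <- function(cycles, max_lag = 10L,
                            method = c("pearson", "spearman"),
                            include_zero = FALSE) {
  method <- match.arg(method)
  if (max_lag < 1) stop("max_lag must be >= 1")
  rows <- lapply(seq_len(max_lag), function(l) {
    p <- ancestor_descendant_pairs(cycles, lag = l)
    if (nrow(p) < 3L) {
      warning("fewer than 3 pairs at lag ", l, "; lag omitted")
      return(NULL)
    }
    cc <- correlation(p, method = method)
    data.frame(lag = l, estimate = cc$estimate, se = cc$se, n_pairs = cc$n)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (include_zero) {
    out <- rbind(data.frame(lag = 0L, estimate = 1, se = 0,
                            n_pairs = nrow(cycles)), out)
  }
  rownames(out) <- NULL
  out
}

#' Intra-lineage mother-daughter correlations
#'
#' The pooled mother-daughter correlation mixes within-lineage inheritance
#' with between-lineage differences in mean generation time. Computing the
#' coefficient separately for each lineage from its own consecutive-pair
#' series isolates the within-lineage component; the distribution across
#' lineages is summarized by its mean and standard deviation.
#'
#' @param lineages A list of `lineage_series` from [filter_lineages()]; each
#'   must hold at least 3 mother-daughter pairs, i.e. at least 4 complete
#'   cycles (filter at the division count that guarantees this).
#' @param method Correlation method (default `"spearman"`).
#' @return List with `per_lineage` (`data.frame` of `channel_id`, `estimate`,
#'   `n_pairs`), `mean`, `sd`, and `n_excluded` (lineages with constant
#'   generation times, for which the coefficient is undefined).
#' @export
intra_lineage_correlations <- function(lineages,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  series <- as_tau_series(lineages)
  if (any(vapply(series, length, integer(1)) < 4L)) {
    stop("every lineage must hold at least 3 mother-daughter pairs ",
         "(4 complete cycles); filter lineages first")
  }
  est <- vapply(series, function(tau) {
    x <- tau[-length(tau)]
    y <- tau[-1]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }, numeric(1))
  n_pairs <- vapply(series, length, integer(1)) - 1L
  per <- data.frame(channel_id = names(series) %||% seq_along(series),
                    estimate = est, n_pairs = n_pairs)
  rownames(per) <- NULL
  ok <- !is.na(est)
  list(per_lineage = per, mean = mean(est[ok]), sd = stats::sd(est[ok]),
       n_excluded = sum(!ok))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Division counts per lineage
#'
#' Counts the division events of each channel within the observation window,
#' optionally restricted to lineages that survived to the end of the window.
#'
#' @param events A validated event `data.frame`.
#' @param window_h Observation window, hours.
#' @param only_survivors If `TRUE`, drop channels with a `death` event.
#' @return A `data.frame` with columns `channel_id`, `count`, `fate`.
#' @export
division_count_distribution <- function(events, window_h,
                                        only_survivors = FALSE) {
  stopifnot(window_h > 0)
  events <- validate_events(events)
  channels <- unique(events$channel_id)
  count <- vapply(channels, function(ch) {
    sum(events$event == "division" & events$channel_id == ch &
          events$time_h <= window_h + 1e-9)
  }, integer(1))
  fate <- vapply(channels, function(ch) {
    if (any(events$event == "death" & events$channel_id == ch)) "died"
    else "alive_at_end"
  }, character(1))
  out <- data.frame(channel_id = channels, count = count, fate = fate)
  rownames(out) <- NULL
  if (only_survivors) out <- out[out$fate == "alive_at_end", , drop = FALSE]
  out
}
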