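#' Split an event table at drug-exposure onset
#'
#' Partitions each channel's events into a pre-exposure phase, restricted to
#' `[0, exposure_start_h)`, and a post-exposure phase containing only the
#' channels still alive at the onset of exposure. Events at exactly the
#' exposure instant belong to the post phase (half-open pre-window).
#'
#' @param events A validated event `data.frame`.
#' @param exposure_start_h Onset of drug exposure, hours; must lie strictly
#'   inside the observed time span.
#' @return List with elements `pre` (events before exposure, all channels)
#'   and `post` (events at or after exposure, surviving channels only), plus
#'   `n_at_onset`, the number of channels alive at onset.
#' @export
split_phases <- function(events, exposure_start_h) {
  events <- validate_events(events)
  t_end <- max(events$time_h)
  if (exposure_start_h <= 0 || exposure_start_h >= t_end) {
    stop("exposure_start_h must lie inside the observation window (0, ",
         t_end, ")")
  }
  died_pre <- unique(events$channel_id[events$event == "death" &
                                         events$time_h < exposure_start_h])
  alive <- setdiff(unique(events$channel_id), died_pre)
  pre <- events[events$time_h < exposure_start_h, , drop = FALSE]
  post <- events[events$time_h >= exposure_start_h &
                   events$channel_id %in% alive, , drop = FALSE]
  rownames(pre) <- rownames(post) <- NULL
  list(pre = pre, post = post, n_at_onset = length(alive))
}

#' Growth-state-stratified survival curves under drug exposure
#'
#' Survival analysis of the post-exposure phase stratified by pre-exposure
#' growth state. Each stratum's surviving fraction is normalized to that
#' stratum's channel count at the onset of exposure and plotted against time
#' since onset, with binomial standard errors `sqrt(S(1-S)/n0)`. The
#' size-weighted average of the stratum curves equals the pooled survival
#' curve exactly.
#'
#' @param post_events Post-phase events from [split_phases()].
#' @param labels A classification `data.frame` from [classify_lineages()]
#'   (columns `channel_id`, `label`); channels present in `post_events` must
#'   all be labelled.
#' @param exposure_start_h Onset of exposure, hours (time origin of the
#'   curves).
#' @param dt_h Grid interval, hours (default 1/6).
#' @return A `data.frame` with columns `time_h` (since onset), `stratum`,
#'   `surviving_fraction`, `se`, `n0`. If only one stratum is populated a
#'   warning is given and that stratum alone is returned.
#' @export
stratified_survival <- function(post_events, labels, exposure_start_h,
                                dt_h = 1 / 6) {
  post_events <- validate_events(post_events)
  channels <- unique(post_events$channel_id)
  lab <- labels$label[match(channels, labels$channel_id)]
  if (any(is.na(lab))) {
    stop("unlabelled channel(s): ",
         paste(utils::head(channels[is.na(lab)], 5), collapse = ", "))
  }
  strata <- sort(unique(lab))
  if (length(strata) < 2L) {
    warning("only one stratum (", strata, ") is populated")
  }
  t_max <- max(post_events$time_h) - exposure_start_h
  tg <- seq(0, snap_up(t_max, dt_h), by = dt_h)
  out <- do.call(rbind, lapply(strata, function(s) {
    chs <- channels[lab == s]
    n0 <- length(chs)
    deaths <- post_events$time_h[post_events$event == "death" &
                                   post_events$channel_id %in% chs] -
      exposure_start_h
    surv <- vapply(tg, function(t) (n0 - sum(deaths <= t + 1e-9)) / n0,
                   numeric(1))
    data.frame(time_h = tg, stratum = s, surviving_fraction = surv,
               se = sqrt(pmax(surv * (1 - surv), 0) / n0), n0 = n0)
  }))
  rownames(out) <- NULL
  out
}
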