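# in-code fixtures: random event tables and survival curves

# a random valid event table: per channel, sorted division times plus a
# terminal death or end-of-observation event
random_event_table <- function(n_channels = 5, max_div = 8, window = 100,
                               p_death = 0.3) {
  rows <- lapply(seq_len(n_channels), function(i) {
    nd <- sample.int(max_div + 1L, 1L) - 1L
    tdiv <- sort(round(runif(nd, 0.5, window - 1), 3))
    died <- runif(1) < p_death
    tend <- if (died) round(runif(1, max(tdiv, 0) + 0.5, window), 3) else window
    data.frame(
      channel_id = sprintf("c%02d", i),
      time_h = c(tdiv, tend),
      event = c(rep("division", nd),
                if (died) "death" else "end_of_observation")
    )
  })
  do.call(rbind, rows)
}

events_from_divisions <- function(div_times, channel = "c1", end = NULL,
                                  end_event = "end_of_observation") {
  df <- data.frame(channel_id = character(0), time_h = numeric(0),
                   event = character(0))
  if (length(div_times)) {
    df <- data.frame(channel_id = channel, time_h = div_times,
                     event = "division")
  }
  if (!is.null(end)) {
    df <- rbind(df, data.frame(channel_id = channel, time_h = end,
                               event = end_event))
  }
  df
}

model_survival_df <- function(params, grid = seq(0, 60, by = 0.1)) {
  data.frame(tau = grid, survival = mixture_survival(grid, params))
}
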