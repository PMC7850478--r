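#' Read a mother-machine event table
#'
#' An event table records the time-lapse observations of every growth channel
#' of a mother-machine device as one row per event. The CSV dialect is:
#' header `channel_id,time_h,event`; `time_h` in decimal hours since the start
#' of observation; `event` one of `"division"`, `"death"`,
#' `"end_of_observation"`. Per channel, event times must be strictly
#' increasing and at most one terminal event (`death` or
#' `end_of_observation`) may occur, as the last event. The end of observation
#' is an explicit event so that truncated files fail validation loudly.
#'
#' @param source Path to a CSV file, or a connection.
#' @return A validated `data.frame` with columns `channel_id` (character),
#'   `time_h` (numeric), `event` (character), sorted by channel and time.
#' @seealso [write_events()], [extract_cycles()], [validate_events()]
#' @export
read_events <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  need <- c("channel_id", "time_h", "event")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("event table must have header 'channel_id,time_h,event', got: ",
         paste(names(df), collapse = ","))
  }
  time_h <- suppressWarnings(as.numeric(df$time_h))
  bad <- which(!is.finite(time_h) | is.na(df$channel_id) | df$channel_id == "")
  if (length(bad)) {
    stop("malformed event row(s) at data line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (line numbers exclude the header)")
  }
  events <- data.frame(channel_id = df$channel_id, time_h = time_h,
                       event = df$event, stringsAsFactors = FALSE)
  validate_events(events)
}

#' Validate an event table
#'
#' Checks the event-table invariants: known event types, non-negative times,
#' strictly increasing times per channel, and at most one terminal event per
#' channel occurring last. Returns the table sorted by channel then time.
#'
#' @param events A `data.frame` with columns `channel_id`, `time_h`, `event`.
#' @return The sorted, validated `data.frame`.
#' @export
validate_events <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("channel_id", "time_h", "event") %in% names(events)))
  events <- events[, c("channel_id", "time_h", "event")]
  events$channel_id <- as.character(events$channel_id)
  known <- c("division", "death", "end_of_observation")
  bad_ev <- !(events$event %in% known)
  if (any(bad_ev)) {
    stop("unknown event type(s): ",
         paste(unique(events$event[bad_ev]), collapse = ", "))
  }
  if (any(events$time_h < 0)) stop("event times must be >= 0")
  events <- events[order(events$channel_id, events$time_h), , drop = FALSE]
  rownames(events) <- NULL
  for (ch in unique(events$channel_id)) {
    e <- events[events$channel_id == ch, , drop = FALSE]
    if (any(diff(e$time_h) <= 0)) {
      stop("channel ", ch, ": event times must be strictly increasing")
    }
    term <- which(e$event %in% c("death", "end_of_observation"))
    if (length(term) > 1L) {
      stop("channel ", ch, ": more than one terminal event")
    }
    if (length(term) == 1L && term != nrow(e)) {
      stop("channel ", ch, ": event recorded after the terminal (",
           e$event[term], ") event")
    }
  }
  events
}

#' Write an event table in canonical CSV form
#'
#' Writes the CSV dialect accepted by [read_events()]. The output is
#' canonical: sorted by channel then time, times printed with up to 10
#' significant digits, no quoting. `write_events(read_events(f))` is the
#' canonical form of `f` and round-trips byte-identically thereafter.
#'
#' @param events A validated event `data.frame`.
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  out <- data.frame(
    channel_id = events$channel_id,
    time_h = vapply(events$time_h, function(t) format(t, digits = 10,
                                                      scientific = FALSE),
                    character(1)),
    event = events$event, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract complete cell cycles from an event table
#'
#' A complete cycle spans two consecutive division events of the tracked cell
#' in one growth channel. The incomplete first generation (birth unobserved)
#' and the incomplete last generation (censored by death or by the end of
#' observation) are excluded. In the mother-machine geometry the tracked cell
#' after each division is the retained closed-end cell, so consecutive cycles
#' within a channel are mother-daughter pairs by construction.
#'
#' @param events A validated event `data.frame` (see [read_events()]).
#' @param window_end_h Optional end of the observation window in hours; if
#'   given, events beyond it are an error.
#' @return A `data.frame` with columns `channel_id`, `generation_index`
#'   (1-based, consecutive within a channel), `birth_time_h`,
#'   `division_time_h` and `tau_h = division_time_h - birth_time_h`.
#'   Channels with fewer than two divisions contribute zero rows.
#' @export
#' @examples
#' ev <- data.frame(channel_id = "c1", time_h = c(10, 20, 31),
#'                  event = "division")
#' extract_cycles(ev)$tau_h   # 10, 11
extract_cycles <- function(events, window_end_h = NULL) {
  events <- validate_events(events)
  if (!is.null(window_end_h) && any(events$time_h > window_end_h)) {
    stop("events beyond window_end_h = ", window_end_h)
  }
  div <- events[events$event == "division", , drop = FALSE]
  res <- lapply(split(div$time_h, div$channel_id), function(t) {
    if (length(t) < 2L) return(NULL)
    data.frame(generation_index = seq_len(length(t) - 1L),
               birth_time_h = t[-length(t)],
               division_time_h = t[-1L])
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(channel_id = character(0), generation_index = integer(0),
                      birth_time_h = numeric(0), division_time_h = numeric(0),
                      tau_h = numeric(0)))
  }
  out <- do.call(rbind, Map(function(ch, d) cbind(channel_id = ch, d),
                            names(res), res))
  rownames(out) <- NULL
  out$tau_h <- out$division_time_h - out$birth_time_h
  out
}

#' Ancestor-descendant generation-time pairs
#'
#' Within each channel, pairs the generation time of cycle `k` with that of
#' cycle `k + lag`. `lag = 1` gives mother-daughter pairs; larger lags give
#' ancestor-descendant pairs separated by `lag` generations. A channel with
#' `m` complete cycles contributes `max(0, m - lag)` pairs.
#'
#' @param cycles A cycle `data.frame` from [extract_cycles()].
#' @param lag Generation separation, an integer `>= 1`.
#' @return A `data.frame` with columns `channel_id`, `tau_ancestor`,
#'   `tau_descendant`.
#' @export
ancestor_descendant_pairs <- function(cycles, lag = 1L) {
  if (!is.numeric(lag) || length(lag) != 1L || lag < 1 || lag != round(lag)) {
    stop("lag must be an integer >= 1")
  }
  lag <- as.integer(lag)
  cycles <- cycles[order(cycles$channel_id, cycles$generation_index), ,
                   drop = FALSE]
  parts <- lapply(split(cycles$tau_h, cycles$channel_id), function(tau) {
    m <- length(tau)
    if (m <= lag) return(NULL)
    k <- seq_len(m - lag)
    data.frame(tau_ancestor = tau[k], tau_descendant = tau[k + lag])
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    return(data.frame(channel_id = character(0), tau_ancestor = numeric(0),
                      tau_descendant = numeric(0)))
  }
  out <- do.call(rbind, Map(function(ch, d) cbind(channel_id = ch, d),
                            names(parts), parts))
  rownames(out) <- NULL
  out
}

#' Filter lineages by division count and build per-lineage series
#'
#' Retains only channels with at least `min_divisions` division events and
#' returns one generation-time series per retained channel. Retaining
#' channels with `>= k` divisions guarantees `>= k - 1` complete cycles and
#' `>= k - 2` mother-daughter pairs per lineage (the reference analysis uses
#' `min_divisions = 4`, guaranteeing at least three pairs).
#'
#' @param cycles A cycle `data.frame` from [extract_cycles()].
#' @param min_divisions Minimum number of division events per channel
#'   (`>= 0`).
#' @param events Optional event `data.frame`; when supplied, division counts
#'   and lineage fates are taken from the events (so channels with fewer than
#'   two divisions are also visible), otherwise counts are inferred from the
#'   cycles (divisions = cycles + 1) and fate is `NA`.
#' @return A list of `lineage_series` objects, each a list with elements
#'   `channel_id`, `taus` (ordered generation times, hours), `fate`
#'   (`"died"`, `"alive_at_end"` or `NA`), and `last_observed_time_h`.
#' @export
filter_lineages <- function(cycles, min_divisions, events = NULL) {
  if (min_divisions < 0) stop("min_divisions must be >= 0")
  taus_by_ch <- lapply(
    split(cycles[order(cycles$channel_id, cycles$generation_index), ],
          cycles$channel_id[order(cycles$channel_id,
                                  cycles$generation_index)]),
    function(d) d$tau_h
  )
  if (is.null(events)) {
    channels <- names(taus_by_ch)
    ndiv <- vapply(taus_by_ch, length, integer(1)) + 1L
    fate <- rep(NA_character_, length(channels))
    last_t <- vapply(channels, function(ch) {
      d <- cycles[cycles$channel_id == ch, ]
      max(d$division_time_h)
    }, numeric(1))
  } else {
    events <- validate_events(events)
    channels <- unique(events$channel_id)
    ndiv <- vapply(channels, function(ch) {
      sum(events$event == "division" & events$channel_id == ch)
    }, integer(1))
    fate <- vapply(channels, function(ch) {
      if (any(events$event == "death" & events$channel_id == ch)) "died"
      else "alive_at_end"
    }, character(1))
    last_t <- vapply(channels, function(ch) {
      max(events$time_h[events$channel_id == ch])
    }, numeric(1))
  }
  keep <- which(ndiv >= min_divisions)
  out <- lapply(keep, function(i) {
    ch <- channels[i]
    taus <- taus_by_ch[[ch]]
    if (is.null(taus)) taus <- numeric(0)
    structure(list(channel_id = ch, taus = unname(taus),
                   fate = unname(fate[i]),
                   last_observed_time_h = unname(last_t[i])),
              class = "lineage_series")
  })
  names(out) <- channels[keep]
  out
}

#' @export
print.lineage_series <- function(x, ...) {
  cat(sprintf("lineage %s: %d complete cycles, fate %s, last observed %.2f h\n",
              x$channel_id, length(x$taus),
              ifelse(is.na(x$fate), "unknown", x$fate),
              x$last_observed_time_h))
  invisible(x)
}

# coerce assorted inputs (list of lineage_series / numeric vectors) to a
# plain list of numeric generation-time series
as_tau_series <- function(series) {
  if (is.data.frame(series)) {
    return(lapply(split(series$tau_h[order(series$channel_id,
                                           series$generation_index)],
                        series$channel_id[order(series$channel_id,
                                                series$generation_index)]),
                  as.numeric))
  }
  lapply(series, function(s) {
    if (inherits(s, "lineage_series")) s$taus else as.numeric(s)
  })
}
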