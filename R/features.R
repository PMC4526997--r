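# The ten behavioral features: eight location features and two usage features.

#' Log-variance of stationary locations
#'
#' Natural log of the sum of the population variances of latitude and
#' longitude (degrees squared) over stationary samples. The log compensates
#' for the strong right skew of raw location variance across participants.
#' Returns `NA` for fewer than two samples or a degenerate zero-variance
#' input.
#'
#' @param lat,lon Stationary-sample coordinates, degrees.
#' @return Scalar, or `NA`.
#' @export
location_variance <- function(lat, lon) {
  n <- length(lat)
  if (n < 2) return(NA_real_)
  pv <- function(x) mean((x - mean(x))^2)
  s2 <- pv(lat) + pv(lon)
  if (s2 <= 0) {
    warning("zero location variance; returning NA")
    return(NA_real_)
  }
  log(s2)
}

#' Entropy of the cluster occupancy distribution
#'
#' `-sum(p_i * log(p_i))` in nats, with `0 log 0 = 0`. Measures how evenly a
#' participant's stationary time spreads over their significant places: a
#' participant spending 80%/20% of their time across two places scores about
#' 0.500, an even 50%/50% split about 0.693.
#'
#' @param p Occupancy distribution: non-negative, sums to 1 (tolerance 1e-8).
#' @return Entropy in nats.
#' @examples
#' cluster_entropy(c(0.8, 0.2))
#' cluster_entropy(c(0.5, 0.5))
#' @export
cluster_entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a probability distribution")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Normalized entropy
#'
#' Entropy divided by its maximum `log(N)`, so the value depends only on the
#' shape of the occupancy distribution: 0 means all stationary time in one
#' cluster, 1 a perfectly uniform spread. Defined as 0 when `N = 1`.
#'
#' @inheritParams cluster_entropy
#' @param N Number of clusters; defaults to `length(p)`.
#' @return Value in \[0, 1\].
#' @export
normalized_entropy <- function(p, N = length(p)) {
  stopifnot(N >= 1)
  if (N == 1) return(0)
  cluster_entropy(p) / log(N)
}

#' Fraction of stationary time spent at home
#'
#' @param model A `cluster_model` with `home_cluster` set (see
#'   [identify_home_cluster()]).
#' @return Fraction of stationary samples assigned to the home cluster.
#' @export
home_stay <- function(model) {
  if (is.null(model$home_cluster)) stop("home cluster not identified")
  mean(model$assignment == model$home_cluster)
}

# ---- Lomb-Scargle -----------------------------------------------------------

#' Lomb-Scargle periodogram for irregularly sampled series
#'
#' Classic (unnormalized) least-squares spectral power at the requested
#' frequencies, using the phase-shift form with
#' `tan(2*w*tau) = sum(sin(2*w*t)) / sum(cos(2*w*t))`:
#' `P(w) = 0.5 * ((sum(y cos w(t - tau)))^2 / sum(cos^2) +
#'                (sum(y sin w(t - tau)))^2 / sum(sin^2))`.
#' The input series should be mean-centered by the caller when a DC offset is
#' not of interest.
#'
#' @param t Sample times, seconds (need not be evenly spaced).
#' @param y Series values at `t`.
#' @param freq Frequencies to evaluate, cycles per second (> 0).
#' @return Numeric vector of spectral power, one per frequency.
#' @export
lomb_scargle_psd <- function(t, y, freq) {
  stopifnot(length(t) == length(y), all(freq > 0))
  vapply(freq, function(f) {
    w <- 2 * pi * f
    wt <- w * t
    tau <- atan2(sum(sin(2 * wt)), sum(cos(2 * wt))) / (2 * w)
    arg <- w * (t - tau)
    cc <- cos(arg); ss <- sin(arg)
    0.5 * (sum(y * cc)^2 / sum(cc^2) + sum(y * ss)^2 / sum(ss^2))
  }, numeric(1))
}

#' Frequency grid and circadian band for a trace
#'
#' The grid runs from 1/(total span) to 1/(2 x median sampling interval) with
#' spacing 1/(oversample x span). The band holds the grid frequencies whose
#' periods lie in `[period_h - half_width_h, period_h + half_width_h]` hours
#' (24 +/- 0.5 by default), bounded by indices `i1 <= i2` into the full grid.
#'
#' @param t Sample times (s).
#' @param period_h Center period, hours.
#' @param half_width_h Band half-width, hours.
#' @param oversample Grid oversampling factor.
#' @return List with `freq_band` (cycles/s), `i1`, `i2`, `df`, `n_grid`.
#' @export
spectral_band <- function(t, period_h = 24, half_width_h = 0.5,
                          oversample = 5) {
  span <- diff(range(t))
  stopifnot(span > 0)
  df <- 1 / (oversample * span)
  f_max <- 1 / (2 * stats::median(diff(sort(t))))
  n_grid <- floor(f_max / df)
  f_lo <- 1 / ((period_h + half_width_h) * 3600)
  f_hi <- 1 / ((period_h - half_width_h) * 3600)
  i1 <- max(1L, ceiling(f_lo / df))
  i2 <- min(n_grid, floor(f_hi / df))
  if (i2 < i1) return(NULL)
  list(freq_band = (i1:i2) * df, i1 = i1, i2 = i2, df = df, n_grid = n_grid)
}

#' Circadian movement
#'
#' Quantifies how strongly a participant's sequence of locations follows a
#' 24-hour rhythm. Latitude and longitude are mean-centered and analyzed
#' separately with the Lomb-Scargle periodogram on the irregular time grid;
#' the band energy E is the mean spectral power over the grid bins whose
#' periods fall within 24 +/- 0.5 h, and the feature is
#' `log(E_lat + E_lon)` (natural log, for skew). Requires at least 24 h of
#' data; a constant trace (zero band energy) gives `NA`.
#'
#' @param trace A [location_trace()] (labels not required).
#' @return Scalar, or `NA`.
#' @export
circadian_movement <- function(trace) {
  s <- trace$samples
  if (nrow(s) < 3 || diff(range(s$t)) < 86400) return(NA_real_)
  band <- spectral_band(s$t)
  if (is.null(band)) return(NA_real_)
  e_lat <- mean(lomb_scargle_psd(s$t, s$lat - mean(s$lat), band$freq_band))
  e_lon <- mean(lomb_scargle_psd(s$t, s$lon - mean(s$lon), band$freq_band))
  tot <- e_lat + e_lon
  if (tot <= 0 || !is.finite(tot)) return(NA_real_)
  log(tot)
}

#' Fraction of labeled samples in a transition state
#'
#' Transition count over (stationary + transition) count; `unknown` samples
#' are excluded from both numerator and denominator.
#'
#' @param labeled A `labeled_trace`.
#' @return Fraction in \[0, 1\], or `NA` if no sample is labeled.
#' @export
transition_time <- function(labeled) {
  st <- labeled$samples$state
  n_lab <- sum(st != "unknown")
  if (n_lab == 0) return(NA_real_)
  sum(st == "transition") / n_lab
}

#' Total distance traveled
#'
#' Sum of haversine distances between consecutive samples, in km. Legs across
#' gaps longer than `max_gap_s` contribute zero (position during an outage is
#' unknown).
#'
#' @param trace A [location_trace()].
#' @param max_gap_s Gap cutoff, seconds.
#' @return Kilometers (0 for a single sample).
#' @export
total_distance <- function(trace, max_gap_s = 900) {
  s <- trace$samples
  n <- nrow(s)
  if (n < 2) return(0)
  d <- haversine_km(cbind(s$lat[-n], s$lon[-n]), cbind(s$lat[-1], s$lon[-1]))
  keep <- diff(s$t) <= max_gap_s
  if (any(!keep))
    message(sprintf("total_distance: %d gap leg(s) > %d s contribute 0 km",
                    sum(!keep), max_gap_s))
  sum(d[keep])
}

# ---- phone usage ------------------------------------------------------------

#' Pair screen on/off events into usage sessions
#'
#' Each `on` event is paired with the next `off`; consecutive `on` events
#' collapse to the first; a trailing unpaired `on` is dropped with a warning.
#' Sessions shorter than `min_session_s` (default 30 s) are removed — these
#' are typically screen wakes from notifications, not participant-initiated
#' use. The duration boundary is strict: a session of exactly
#' `min_session_s` is kept.
#'
#' @param events A [screen_events()] data frame (sorted by time).
#' @param cfg A [preprocess_config()].
#' @return Data frame with columns `start`, `end`, `duration_s`.
#' @export
usage_sessions <- function(events, cfg = preprocess_config()) {
  start <- numeric(0); end <- numeric(0)
  open_t <- NA_real_
  for (i in seq_len(nrow(events))) {
    if (events$state[i] == "on") {
      if (is.na(open_t)) open_t <- events$t[i]  # on-on collapses to first
    } else if (!is.na(open_t)) {
      start <- c(start, open_t); end <- c(end, events$t[i])
      open_t <- NA_real_
    }
  }
  if (!is.na(open_t))
    warning("unpaired trailing 'on' event dropped")
  out <- data.frame(start = start, end = end, duration_s = end - start)
  out[out$duration_s >= cfg$min_session_s, , drop = FALSE]
}

#' Daily phone-usage frequency and duration
#'
#' @param sessions Output of [usage_sessions()].
#' @param n_days Number of calendar days covered (>= 1).
#' @return Named numeric vector: `usage_frequency` (sessions/day) and
#'   `usage_duration` (seconds/day).
#' @export
usage_features <- function(sessions, n_days) {
  stopifnot(n_days >= 1)
  c(usage_frequency = nrow(sessions) / n_days,
    usage_duration = sum(sessions$duration_s) / n_days)
}

# ---- per-participant assembly -----------------------------------------------

#' Feature names computed by [extract_features()]
#' @export
feature_names <- function() {
  c("location_variance", "entropy", "normalized_entropy", "home_stay",
    "circadian_movement", "transition_time", "total_distance", "n_clusters",
    "usage_frequency", "usage_duration")
}

#' Extract the full feature vector for one participant
#'
#' Runs the preprocessing chain (speed labeling, adaptive clustering, home
#' identification, session pairing) and computes the ten behavioral features.
#' Features whose preconditions fail (e.g. circadian movement on under a day
#' of data) come back `NA`.
#'
#' @param record A [participant_record()].
#' @param cfg A [preprocess_config()].
#' @param seed RNG seed for the clustering restarts.
#' @return One-row data frame: `participant_id`, the ten features, `phq9`.
#' @export
extract_features <- function(record, cfg = preprocess_config(), seed = 1L) {
  stopifnot(inherits(record, "participant_record"))
  labeled <- estimate_speeds(record$location, cfg)
  st_idx <- which(labeled$samples$state == "stationary")
  lv <- ent <- nent <- hs <- nK <- NA_real_
  if (length(st_idx) >= 1) {
    model <- cluster_stationary(labeled, cfg, seed = seed)
    model <- identify_home_cluster(model, labeled)
    ent <- cluster_entropy(model$p)
    nent <- normalized_entropy(model$p, model$K)
    hs <- home_stay(model)
    nK <- model$K
    lv <- location_variance(labeled$samples$lat[st_idx],
                            labeled$samples$lon[st_idx])
  }
  cm <- circadian_movement(record$location)
  tt <- transition_time(labeled)
  td <- suppressMessages(total_distance(record$location, cfg$max_gap_s))
  sess <- suppressWarnings(usage_sessions(record$screen, cfg))
  tz <- record$location$tz_offset
  n_days <- if (nrow(record$screen) == 0) 1 else
    diff(range(floor((record$screen$t + tz * 3600) / 86400))) + 1
  uf <- usage_features(sess, max(1, n_days))
  out <- data.frame(participant_id = record$participant_id,
                    location_variance = lv, entropy = ent,
                    normalized_entropy = nent, home_stay = hs,
                    circadian_movement = cm, transition_time = tt,
                    total_distance = td, n_clusters = nK,
                    usage_frequency = unname(uf["usage_frequency"]),
                    usage_duration = unname(uf["usage_duration"]),
                    phq9 = record$phq9)
  rownames(out) <- NULL
  out
}

#' Extract features for a whole cohort
#'
#' @param records List of [participant_record()]s.
#' @param cfg A [preprocess_config()].
#' @param seed Base RNG seed; participant i clusters with seed `seed + i`.
#' @return Data frame, one row per participant (see [extract_features()]).
#' @export
extract_features_cohort <- function(records, cfg = preprocess_config(),
                                    seed = 1L) {
  rows <- lapply(seq_along(records), function(i)
    extract_features(records[[i]], cfg, seed = seed + i))
  do.call(rbind, rows)
}

#' Write / read a feature table
#'
#' CSV with one row per participant and one column per feature; undefined
#' feature values are written as `NA`.
#'
#' @param features Feature data frame from [extract_features_cohort()].
#' @param path File path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
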