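#' mobmood: behavioral sensing features for depressive-symptom severity
#'
#' Tools to go from raw per-participant GPS and screen-state logs to
#' behavioral features, association statistics against PHQ-9 scores, and
#' regularized severity models with a bootstrapped leave-one-participant-out
#' evaluation. See `vignette("mobmood-methods")` for the underlying model.
#'
#' @keywords internal
"_PACKAGE"

# ---- domain types -----------------------------------------------------------

#' Construct a location trace for one participant
#'
#' A location trace is the time-ordered GPS stream of one participant:
#' epoch timestamps (UTC seconds), latitude and longitude in degrees, plus a
#' fixed UTC offset used to convert to local time (no DST handling).
#'
#' @param participant_id Opaque participant identifier (scalar character).
#' @param t Numeric vector of epoch timestamps in seconds (UTC).
#' @param lat,lon Numeric vectors of coordinates in degrees.
#' @param tz_offset Signed UTC offset in hours for local-time conversion.
#' @return An object of class `location_trace`: a list with elements
#'   `participant_id`, `samples` (data frame with columns `t`, `lat`, `lon`,
#'   sorted by `t`, duplicate timestamps dropped) and `tz_offset`.
#' @examples
#' tr <- location_trace("p1", t = c(0, 300, 600), lat = rep(41.88, 3),
#'                      lon = rep(-87.63, 3), tz_offset = -6)
#' n_samples(tr)
#' @export
location_trace <- function(participant_id, t, lat, lon, tz_offset = 0) {
  stopifnot(length(t) == length(lat), length(t) == length(lon))
  if (length(t) > 0) {
    if (any(!is.finite(t))) stop("timestamps must be finite")
    if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
    if (any(lon < -180 | lon > 180)) stop("longitude out of [-180, 180]")
  }
  ord <- order(t)
  s <- data.frame(t = as.numeric(t)[ord], lat = lat[ord], lon = lon[ord])
  s <- s[!duplicated(s$t), , drop = FALSE]
  rownames(s) <- NULL
  structure(
    list(participant_id = as.character(participant_id), samples = s,
         tz_offset = tz_offset),
    class = "location_trace"
  )
}

#' @rdname location_trace
#' @param x A `location_trace`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @export
print.location_trace <- function(x, ...) {
  cat(sprintf("<location_trace> participant %s: %d samples", x$participant_id,
              n_samples(x)))
  if (n_samples(x) > 1) {
    span_h <- diff(range(x$samples$t)) / 3600
    cat(sprintf(" spanning %.1f h", span_h))
  }
  cat(sprintf(", tz offset %+g h\n", x$tz_offset))
  invisible(x)
}

#' Construct a screen-event table
#'
#' @param t Numeric epoch timestamps (seconds).
#' @param state Character vector of `"on"` / `"off"` states (case-insensitive).
#' @return Data frame with columns `t` (numeric) and `state` (character,
#'   lower-case), sorted by `t`.
#' @export
screen_events <- function(t, state) {
  stopifnot(length(t) == length(state))
  state <- tolower(as.character(state))
  if (length(t) > 0) {
    if (any(!is.finite(t))) stop("timestamps must be finite")
    if (!all(state %in% c("on", "off"))) stop("state must be 'on' or 'off'")
  }
  ord <- order(t)
  out <- data.frame(t = as.numeric(t)[ord], state = state[ord])
  rownames(out) <- NULL
  out
}

#' Bundle one participant's sensor streams and PHQ-9 score
#'
#' @param participant_id Participant identifier.
#' @param location A [location_trace()].
#' @param screen A [screen_events()] data frame.
#' @param phq9 Integer PHQ-9 score in 0..27, or `NA` if unknown.
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(participant_id, location, screen,
                               phq9 = NA_integer_) {
  stopifnot(inherits(location, "location_trace"))
  if (!is.na(phq9) && (phq9 < 0 || phq9 > 27))
    stop("phq9 must lie in [0, 27]")
  structure(
    list(participant_id = as.character(participant_id), location = location,
         screen = screen, phq9 = as.integer(phq9)),
    class = "participant_record"
  )
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant_record> %s: %d GPS samples, %d screen events, PHQ-9 = %s\n",
              x$participant_id, n_samples(x$location), nrow(x$screen),
              ifelse(is.na(x$phq9), "NA", x$phq9)))
  invisible(x)
}

# ---- log readers and writers ------------------------------------------------

parse_timestamp <- function(x) {
  # epoch seconds or ISO-8601; NA where unparseable
  num <- suppressWarnings(as.numeric(x))
  out <- ifelse(is.finite(num), num, NA_real_)
  bad <- is.na(out)
  if (any(bad)) {
    for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                  "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      parsed <- as.numeric(strptime(x[bad], fmt, tz = "UTC"))
      out[bad] <- parsed
      bad <- is.na(out)
      if (!any(bad)) break
    }
  }
  out
}

#' Read a GPS location log
#'
#' Expects delimiter-separated text with a header row naming (at least) the
#' columns `timestamp`, `latitude`, `longitude`. Timestamps may be epoch
#' seconds or ISO-8601. Rows that fail to parse (non-finite timestamp or
#' out-of-range coordinates) are dropped and counted; duplicate timestamps
#' keep the first occurrence; output is sorted by time.
#'
#' @param path Path to the log file.
#' @param tz_offset UTC offset in hours for the participant.
#' @param participant_id Identifier; defaults to the file name sans extension.
#' @param sep Field delimiter (default `","`).
#' @return A [location_trace()] with attribute `n_rejected` giving the number
#'   of malformed rows dropped.
#' @export
read_location_log <- function(path, tz_offset = 0,
                              participant_id = sub("\\.[^.]*$", "", basename(path)),
                              sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  names(raw) <- tolower(names(raw))
  need <- c("timestamp", "latitude", "longitude")
  if (!all(need %in% names(raw)))
    stop("location log must have columns timestamp, latitude, longitude")
  t <- parse_timestamp(raw$timestamp)
  lat <- suppressWarnings(as.numeric(raw$latitude))
  lon <- suppressWarnings(as.numeric(raw$longitude))
  ok <- is.finite(t) & is.finite(lat) & is.finite(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  n_rejected <- sum(!ok)
  if (n_rejected > 0)
    message(sprintf("read_location_log: dropped %d malformed row(s) from %s",
                    n_rejected, path))
  if (!any(ok)) stop("no valid rows in location log: ", path)
  tr <- location_trace(participant_id, t[ok], lat[ok], lon[ok], tz_offset)
  attr(tr, "n_rejected") <- n_rejected
  tr
}

#' Write a location trace as CSV
#'
#' Inverse of [read_location_log()]; timestamps are written as epoch seconds
#' and coordinates with enough digits for a 1e-7 degree round trip.
#'
#' @param trace A [location_trace()].
#' @param path Output file path.
#' @export
write_location_log <- function(trace, path) {
  stopifnot(inherits(trace, "location_trace"))
  df <- data.frame(timestamp = sprintf("%.0f", trace$samples$t),
                   latitude = sprintf("%.8f", trace$samples$lat),
                   longitude = sprintf("%.8f", trace$samples$lon))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a screen-state log
#'
#' Expects columns `timestamp`, `state` with state in on/off
#' (case-insensitive). Rows with unrecognized states or unparseable
#' timestamps are dropped and counted.
#'
#' @inheritParams read_location_log
#' @return A [screen_events()] data frame with attribute `n_rejected`.
#' @export
read_screen_log <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  names(raw) <- tolower(names(raw))
  if (!all(c("timestamp", "state") %in% names(raw)))
    stop("screen log must have columns timestamp, state")
  t <- parse_timestamp(raw$timestamp)
  state <- tolower(trimws(raw$state))
  ok <- is.finite(t) & state %in% c("on", "off")
  n_rejected <- sum(!ok)
  if (n_rejected > 0)
    message(sprintf("read_screen_log: dropped %d malformed row(s) from %s",
                    n_rejected, path))
  if (!any(ok)) stop("no valid rows in screen log: ", path)
  ev <- screen_events(t[ok], state[ok])
  attr(ev, "n_rejected") <- n_rejected
  ev
}

#' @rdname read_screen_log
#' @param events A [screen_events()] data frame.
#' @param path Output file path.
#' @export
write_screen_log <- function(events, path) {
  df <- data.frame(timestamp = sprintf("%.0f", events$t), state = events$state)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a participant scores table
#'
#' @param path CSV with header `participant_id,phq9`.
#' @return Data frame with character `participant_id` and integer `phq9`.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("participant_id", "phq9") %in% names(df)))
    stop("scores file must have columns participant_id, phq9")
  data.frame(participant_id = as.character(df$participant_id),
             phq9 = as.integer(df$phq9))
}

# ---- data-sufficiency filter ------------------------------------------------

#' Assess sensor coverage over a study period
#'
#' Location coverage is the fraction of the study period's nominal sampling
#' bins (default 5 min) that contain at least one GPS sample; usage coverage
#' is the fraction of calendar days (participant-local time) containing at
#' least one screen event. A stream is eligible for analysis only when its
#' coverage strictly exceeds 0.5, the study's data-sufficiency rule.
#'
#' @param record A [participant_record()].
#' @param study_start,study_end Epoch seconds bounding the study period.
#' @param bin_s Nominal sampling period in seconds (default 300).
#' @return A one-row data frame (class `coverage_report`) with columns
#'   `participant_id`, `location_coverage`, `usage_coverage`,
#'   `eligible_location`, `eligible_usage`.
#' @examples
#' tr <- location_trace("p", t = seq(0, 86100, by = 300),
#'                      lat = rep(0, 288), lon = rep(0, 288))
#' rec <- participant_record("p", tr, screen_events(numeric(), character()))
#' assess_coverage(rec, 0, 86400)
#' @export
assess_coverage <- function(record, study_start, study_end, bin_s = 300) {
  stopifnot(inherits(record, "participant_record"), study_end > study_start)
  n_bins <- ceiling((study_end - study_start) / bin_s)
  ts <- record$location$samples$t
  ts <- ts[ts >= study_start & ts < study_end]
  loc_cov <- if (length(ts) == 0) 0 else
    length(unique(floor((ts - study_start) / bin_s))) / n_bins
  tz <- record$location$tz_offset
  n_days <- ceiling((study_end - study_start) / 86400)
  se <- record$screen$t
  se <- se[se >= study_start & se < study_end]
  use_cov <- if (length(se) == 0) 0 else
    min(1, length(unique(floor((se + tz * 3600) / 86400))) / n_days)
  out <- data.frame(participant_id = record$participant_id,
                    location_coverage = loc_cov, usage_coverage = use_cov,
                    eligible_location = loc_cov > 0.5,
                    eligible_usage = use_cov > 0.5)
  class(out) <- c("coverage_report", class(out))
  out
}
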