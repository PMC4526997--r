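# Synthetic cohort generator: participants whose mobility and phone-usage
# behavior are monotone functions of a latent severity score, so the full
# pipeline (preprocess -> features -> associations -> models) can be
# exercised and validated without access to sensitive raw sensor data.

KM_PER_DEG_LAT <- 6371 * pi / 180  # ~111.195 km, consistent with haversine_km

#' Behavioral generator parameters for one participant
#'
#' These parameters encode the behavioral constructs the features measure:
#' how many significant places a participant visits, what fraction of time
#' they spend at home, how regular their daily schedule is, how far apart
#' their places lie, and how often/long they use the phone.
#'
#' @param n_anchors Number of candidate significant places (>= 1), home
#'   included.
#' @param home_stay_frac Target fraction of the day spent at home, \[0, 1\].
#' @param regularity Probability that a day follows the canonical schedule
#'   (fixed departure/return times and destinations), \[0, 1\].
#' @param mobility_scale_km Spatial spread of the non-home anchors (km > 0).
#' @param gps_noise_m Per-coordinate GPS jitter SD in meters.
#' @param usage_rate_per_day Mean screen sessions per day (Poisson).
#' @param usage_mean_s Mean session duration in seconds (exponential; a
#'   sizeable share falls under 30 s, exercising the session filter).
#' @param coverage Probability a scheduled GPS sample is actually recorded,
#'   (0, 1\].
#' @return List of class `behavior_params`.
#' @export
behavior_params <- function(n_anchors = 4, home_stay_frac = 0.55,
                            regularity = 0.9, mobility_scale_km = 5,
                            gps_noise_m = 15, usage_rate_per_day = 12,
                            usage_mean_s = 70, coverage = 0.85) {
  stopifnot(n_anchors >= 1, home_stay_frac >= 0, home_stay_frac <= 1,
            regularity >= 0, regularity <= 1, mobility_scale_km > 0,
            gps_noise_m >= 0, usage_rate_per_day >= 0, usage_mean_s > 0,
            coverage > 0, coverage <= 1)
  structure(as.list(environment()), class = "behavior_params")
}

#' Cohort-level simulation settings
#'
#' @param n_participants Cohort size.
#' @param days Observation window in days (default 14, a two-week study).
#' @param sampling_period_s Nominal GPS sampling period (default 300 s).
#' @param seed Master RNG seed for the cohort.
#' @param origin_lat,origin_lon Coordinates the cohort's home anchors are
#'   scattered around (a local planar patch of a few tens of km).
#' @param travel_speed_kmh Speed of simulated transitions between anchors.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 28, days = 14,
                        sampling_period_s = 300, seed = 1L,
                        origin_lat = 41.88, origin_lon = -87.63,
                        travel_speed_kmh = 25) {
  stopifnot(n_participants >= 1, days >= 1, sampling_period_s >= 1,
            travel_speed_kmh > 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Link from latent severity to behavior and PHQ-9
#'
#' Each participant draws a latent severity `u ~ U(0, 1)`. Behavioral
#' parameters are `baseline + slope * u` (clamped to their valid ranges) and
#' the PHQ-9 score is `round(clip(score_max * u + noise))` with Gaussian
#' noise, clipped to `score_range`. The default slopes plant the direction of
#' association the features are designed to detect: with rising severity,
#' home stay and phone usage increase while schedule regularity and spatial
#' spread decrease.
#'
#' @param slopes Named list of per-parameter slopes (names as in
#'   [behavior_params()]); parameters not named get slope 0.
#' @param noise_sd SD of the Gaussian PHQ-9 noise (score units).
#' @param score_range Length-2 integer range the score is scaled and clipped
#'   to. The default `c(0, 27)` spans the full PHQ-9 scale; `c(0, 10)` puts
#'   the >= 5 symptom cutoff at the latent median, giving a cohort split
#'   roughly in half.
#' @return List of class `severity_link`.
#' @export
severity_link <- function(slopes = list(home_stay_frac = 0.35,
                                        regularity = -0.65,
                                        mobility_scale_km = -3.5,
                                        usage_rate_per_day = 20,
                                        usage_mean_s = 90),
                          noise_sd = 1.5, score_range = c(0L, 27L)) {
  stopifnot(noise_sd >= 0, length(score_range) == 2,
            score_range[1] >= 0, score_range[2] <= 27,
            score_range[2] > score_range[1])
  structure(list(slopes = slopes, noise_sd = noise_sd,
                 score_range = score_range), class = "severity_link")
}

#' A severity link with no behavior-score association
#'
#' All slopes zero: features are independent of the PHQ-9 score. Useful as a
#' null model for calibration checks. Defaults to the balanced
#' `score_range = c(0, 10)` so the symptom classes are near 50/50.
#'
#' @inheritParams severity_link
#' @export
null_severity_link <- function(noise_sd = 1.5, score_range = c(0L, 10L)) {
  severity_link(slopes = list(), noise_sd = noise_sd,
                score_range = score_range)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# shift baseline params by slope * u, respecting each parameter's range
apply_link <- function(baseline, slopes, u) {
  p <- unclass(baseline)
  for (nm in names(slopes)) {
    if (!nm %in% names(p)) stop("unknown behavior parameter in link: ", nm)
    p[[nm]] <- p[[nm]] + slopes[[nm]] * u
  }
  p$n_anchors <- max(1L, as.integer(round(p$n_anchors)))
  p$home_stay_frac <- clamp(p$home_stay_frac, 0.02, 0.995)
  p$regularity <- clamp(p$regularity, 0, 1)
  p$mobility_scale_km <- max(0.5, p$mobility_scale_km)
  p$gps_noise_m <- max(0, p$gps_noise_m)
  p$usage_rate_per_day <- max(0, p$usage_rate_per_day)
  p$usage_mean_s <- max(5, p$usage_mean_s)
  p$coverage <- clamp(p$coverage, 0.02, 1)
  class(p) <- "behavior_params"
  p
}

# place home at the origin and the other anchors at spread angles, with
# pairwise separation > 2 x the 0.5 km clustering radius so every anchor maps
# to one recoverable cluster; coordinates in planar km relative to the origin
place_anchors <- function(n_anchors, mobility_scale_km, min_sep_km = 1.001) {
  if (n_anchors == 1) return(matrix(0, nrow = 1, ncol = 2))
  n_away <- n_anchors - 1
  for (attempt in 1:50) {
    ang <- 2 * pi * (seq_len(n_away) - 1) / n_away +
      stats::runif(1, 0, 2 * pi) + stats::rnorm(n_away, 0, 0.05)
    r <- pmax(min_sep_km * 1.05,
              stats::runif(n_away, 0.5, 1) * mobility_scale_km)
    pts <- rbind(c(0, 0), cbind(r * cos(ang), r * sin(ang)))
    d <- stats::dist(pts)
    if (min(d) > min_sep_km) return(pts)
  }
  stop("cannot place ", n_anchors, " anchors with pairwise separation > ",
       min_sep_km, " km at mobility scale ", mobility_scale_km, " km")
}

# one day's itinerary as a segment matrix (start_h, end_h, from, to);
# from == to marks a stay, from != to a constant-speed transition
day_segments <- function(params, spec, anchors_km, canonical) {
  away_h <- (1 - params$home_stay_frac) * 24
  if (away_h < 0.75 || params$n_anchors == 1) {
    return(matrix(c(0, 24, 1, 1), nrow = 1,
                  dimnames = list(NULL, c("start_h", "end_h", "from", "to"))))
  }
  away_h <- min(away_h, 20)
  half <- away_h / 2
  center <- if (canonical) 13.5 else stats::runif(1, half + 0.5, 23.5 - half)
  dep <- center - half
  ret <- center + half
  two_stops <- params$n_anchors >= 3 && away_h >= 6
  if (canonical) {
    dests <- if (two_stops) c(2L, 3L) else 2L
  } else {
    k <- if (two_stops) 2 else 1
    dests <- sample(2:params$n_anchors, k,
                    replace = params$n_anchors - 1 < k)
  }
  # stop boundaries: equal shares of the away window
  bounds <- seq(dep, ret, length.out = length(dests) + 1)
  rows <- vector("list", 2 * length(dests) + 3)
  rows[[1]] <- c(0, dep, 1, 1)
  prev <- 1L
  for (j in seq_along(dests)) {
    tt_h <- haver_km_planar(anchors_km[prev, ], anchors_km[dests[j], ]) /
      spec$travel_speed_kmh
    s0 <- bounds[j]
    arr <- min(s0 + tt_h, bounds[j + 1])
    rows[[2 * j]] <- c(s0, arr, prev, dests[j])
    rows[[2 * j + 1]] <- c(arr, bounds[j + 1], dests[j], dests[j])
    prev <- dests[j]
  }
  tt_back <- haver_km_planar(anchors_km[prev, ], anchors_km[1, ]) /
    spec$travel_speed_kmh
  back <- min(ret + tt_back, 24)
  rows[[2 * length(dests) + 2]] <- c(ret, back, prev, 1)
  rows[[2 * length(dests) + 3]] <- c(back, 24, 1, 1)
  segs <- do.call(rbind, rows)
  colnames(segs) <- c("start_h", "end_h", "from", "to")
  segs[segs[, "end_h"] > segs[, "start_h"], , drop = FALSE]
}

haver_km_planar <- function(a, b) sqrt(sum((a - b)^2))

#' Simulate one participant's sensor record
#'
#' Anchors (significant places) are laid out on a local planar patch with
#' pairwise separation wide enough that each maps to one recoverable cluster.
#' Each day is either canonical (fixed departure/return schedule, with
#' probability `regularity`) or irregular (shuffled times and destinations).
#' Transitions between anchors are constant-speed interpolated runs, so the
#' speed-threshold labeling sees genuine transition samples. Within-anchor
#' positions get Gaussian GPS jitter; scheduled samples are dropped uniformly
#' at random to the `coverage` fraction. Screen sessions follow a
#' Poisson-count, exponential-duration model. Deterministic for a fixed seed.
#'
#' @param params [behavior_params()].
#' @param spec [cohort_spec()] (its `n_participants` is ignored here).
#' @param seed Integer seed.
#' @param participant_id Identifier for the record.
#' @return A [participant_record()] with `phq9 = NA` (scores are assigned by
#'   [generate_cohort()]).
#' @export
generate_participant <- function(params, spec = cohort_spec(), seed = 1L,
                                 participant_id = "sim") {
  stopifnot(inherits(params, "behavior_params"), inherits(spec, "cohort_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  anchors <- place_anchors(params$n_anchors, params$mobility_scale_km)
  horizon_s <- spec$days * 86400
  grid <- seq(0, horizon_s - 1, by = spec$sampling_period_s)

  # per-day itineraries stitched into one segment table in absolute hours
  segs <- do.call(rbind, lapply(seq_len(spec$days), function(d) {
    sg <- day_segments(params, spec, anchors,
                       canonical = stats::runif(1) < params$regularity)
    sg[, c("start_h", "end_h")] <- sg[, c("start_h", "end_h")] + (d - 1) * 24
    sg
  }))

  h <- grid / 3600
  si <- findInterval(h, segs[, "start_h"])
  si[si < 1] <- 1L
  frac <- (h - segs[si, "start_h"]) /
    pmax(segs[si, "end_h"] - segs[si, "start_h"], 1e-9)
  from <- anchors[segs[si, "from"], , drop = FALSE]
  to <- anchors[segs[si, "to"], , drop = FALSE]
  pos <- from + frac * (to - from)  # km east/north of origin

  keep <- stats::runif(length(grid)) < params$coverage
  noise_km <- params$gps_noise_m / 1000
  x <- pos[keep, 1] + stats::rnorm(sum(keep), 0, noise_km)
  y <- pos[keep, 2] + stats::rnorm(sum(keep), 0, noise_km)
  lat <- spec$origin_lat + y / KM_PER_DEG_LAT
  lon <- spec$origin_lon + x / (KM_PER_DEG_LAT * cos(spec$origin_lat * pi / 180))
  trace <- location_trace(participant_id, grid[keep], lat, lon, tz_offset = 0)

  # screen sessions: Poisson daily counts, exponential durations, merged
  n_sess <- stats::rpois(spec$days, params$usage_rate_per_day)
  starts <- unlist(lapply(seq_len(spec$days), function(d)
    sort(stats::runif(n_sess[d], (d - 1) * 86400, d * 86400))))
  durs <- stats::rexp(length(starts), rate = 1 / params$usage_mean_s)
  ev <- merge_sessions(starts, starts + durs)
  screen <- screen_events(c(ev$start, ev$end),
                          rep(c("on", "off"), each = nrow(ev)))
  participant_record(participant_id, trace, screen, phq9 = NA_integer_)
}

# merge overlapping [start, end) intervals so on/off events pair cleanly
merge_sessions <- function(start, end) {
  if (length(start) == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Simulate a full cohort with severity-linked behavior
#'
#' Draws a latent severity `u ~ U(0, 1)` per participant, shifts the baseline
#' behavioral parameters along the link's slopes, simulates each record, and
#' assigns `phq9 = round(clip(score_max * u + noise))`. Optionally a fraction
#' of participants is given low sensor coverage (drawn from U(0.2, 0.45)) to
#' emulate the real-world participants excluded by the > 50% availability
#' rule.
#'
#' @param spec [cohort_spec()].
#' @param link [severity_link()].
#' @param baseline [behavior_params()] at severity `u = 0`.
#' @param low_coverage_frac Fraction of participants forced to low coverage
#'   (default 0).
#' @return List of class `cohort`: `records` (list of
#'   [participant_record()]), `truth` (data frame with `participant_id`, `u`,
#'   `phq9`, and the realized behavioral parameters).
#' @export
generate_cohort <- function(spec = cohort_spec(), link = severity_link(),
                            baseline = behavior_params(),
                            low_coverage_frac = 0) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(link, "severity_link"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_participants
  u <- stats::runif(n)
  noise <- stats::rnorm(n, 0, link$noise_sd)
  lo_cov <- stats::runif(n) < low_coverage_frac
  cov_draw <- stats::runif(n, 0.2, 0.45)
  seeds <- sample.int(.Machine$integer.max - 1, n)
  smax <- link$score_range[2]
  phq9 <- as.integer(round(clamp(smax * u + noise,
                                 link$score_range[1], smax)))
  ids <- sprintf("P%03d", seq_len(n))
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- apply_link(baseline, link$slopes, u[i])
    if (lo_cov[i]) p_i$coverage <- cov_draw[i]
    rec <- generate_participant(p_i, spec, seed = seeds[i],
                                participant_id = ids[i])
    rec$phq9 <- phq9[i]
    records[[i]] <- rec
    truth[[i]] <- data.frame(participant_id = ids[i], u = u[i],
                             phq9 = phq9[i],
                             as.data.frame(unclass(p_i)))
  }
  structure(list(records = records, truth = do.call(rbind, truth),
                 spec = spec, link = link),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  scores <- vapply(x$records, function(r) r$phq9, integer(1))
  cat(sprintf("<cohort> %d participants, %d days; PHQ-9 median %.1f, %d with score >= 5\n",
              length(x$records), x$spec$days, stats::median(scores),
              sum(scores >= 5)))
  invisible(x)
}

#' Write a simulated cohort to per-participant CSV logs
#'
#' Emits one location log and one screen log per participant (in the formats
#' [read_location_log()] / [read_screen_log()] expect), a `scores.csv`, and a
#' `truth.csv` with the generative parameters.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "location"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "screen"), recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$records) {
    write_location_log(rec$location,
                       file.path(dir, "location", paste0(rec$participant_id, ".csv")))
    write_screen_log(rec$screen,
                     file.path(dir, "screen", paste0(rec$participant_id, ".csv")))
  }
  scores <- data.frame(
    participant_id = vapply(cohort$records, `[[`, "", "participant_id"),
    phq9 = vapply(cohort$records, `[[`, 0L, "phq9"))
  utils::write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort back from per-participant CSV logs
#'
#' @param dir Directory layout produced by [write_cohort()].
#' @param tz_offset UTC offset applied to every participant.
#' @return List of [participant_record()]s.
#' @export
read_cohort <- function(dir, tz_offset = 0) {
  scores <- read_scores(file.path(dir, "scores.csv"))
  lapply(seq_len(nrow(scores)), function(i) {
    id <- scores$participant_id[i]
    tr <- read_location_log(file.path(dir, "location", paste0(id, ".csv")),
                            tz_offset = tz_offset, participant_id = id)
    ev <- read_screen_log(file.path(dir, "screen", paste0(id, ".csv")))
    participant_record(id, tr, ev, phq9 = scores$phq9[i])
  })
}
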