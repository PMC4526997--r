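# Small programmatic fixtures shared across tests.

# a trace sampled every `by` seconds at fixed coordinates
make_still_trace <- function(n = 10, by = 300, lat = 41.88, lon = -87.63,
                             t0 = 0, tz = 0, id = "p") {
  t <- t0 + seq(0, by = by, length.out = n)
  location_trace(id, t, rep(lat, n), rep(lon, n), tz_offset = tz)
}

# a labeled trace whose stationary samples sit at given planar points;
# points: matrix of (lat, lon)
labeled_from_points <- function(points, by = 300, t0 = 0, tz = 0) {
  n <- nrow(points)
  tr <- location_trace("p", t0 + seq(0, by = by, length.out = n),
                       points[, 1], points[, 2], tz_offset = tz)
  lab <- tr
  lab$samples$speed_kmh <- rep(0, n)
  lab$samples$state <- rep("stationary", n)
  class(lab) <- c("labeled_trace", "location_trace")
  lab
}

# k tight blobs of points around well-separated centers; returns matrix
blob_points <- function(centers, n_per, sd_deg = 1e-4, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      cbind(centers[i, 1] + rnorm(n_per[i], 0, sd_deg),
            centers[i, 2] + rnorm(n_per[i], 0, sd_deg))))
  })
}

# a small strong-link cohort, cached across tests in one session
strong_cohort_features <- local({
  cache <- NULL
  function(n = 28, seed = 42) {
    key <- paste(n, seed)
    if (!is.null(cache) && cache$key == key) return(cache$features)
    co <- generate_cohort(
      cohort_spec(n_participants = n, days = 14, seed = seed),
      severity_link(noise_sd = 0.75, score_range = c(0L, 10L)))
    f <- suppressWarnings(extract_features_cohort(co$records, seed = seed))
    cache <<- list(key = key, features = f)
    f
  }
})
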