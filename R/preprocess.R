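# Stationary/transition labeling and radius-bounded adaptive K-means.

#' Preprocessing configuration
#'
#' @param speed_threshold_kmh Movement speed (km/h) separating stationary from
#'   transition samples; samples strictly below are stationary. Default 1.
#' @param cluster_radius_m Maximum allowed distance (m) from any stationary
#'   sample to its cluster center; the adaptive K-means grows K until this
#'   holds. Default 500.
#' @param max_gap_s Largest inter-sample gap (s) across which a speed is
#'   computed; samples following a longer gap are labeled `unknown`.
#'   Default 900.
#' @param min_session_s Screen sessions shorter than this (s) are discarded as
#'   notification blips not initiated by the participant. Default 30.
#' @param k_max Safety cap on the cluster search. Default 50.
#' @param kmeans_restarts Random restarts per K. Default 10.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(speed_threshold_kmh = 1, cluster_radius_m = 500,
                              max_gap_s = 900, min_session_s = 30,
                              k_max = 50, kmeans_restarts = 10) {
  stopifnot(speed_threshold_kmh > 0, cluster_radius_m > 0, max_gap_s > 0,
            min_session_s > 0, k_max >= 1)
  structure(list(speed_threshold_kmh = speed_threshold_kmh,
                 cluster_radius_m = cluster_radius_m, max_gap_s = max_gap_s,
                 min_session_s = min_session_s, k_max = k_max,
                 kmeans_restarts = kmeans_restarts),
            class = "preprocess_config")
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance with Earth radius 6371 km. Vectorized over rows.
#'
#' @param p1,p2 Numeric vectors `c(lat, lon)` in degrees, or two-column
#'   matrices (lat, lon) of equal row count.
#' @return Distance(s) in kilometers.
#' @examples
#' haversine_km(c(0, 0), c(0, 0.01))
#' @export
haversine_km <- function(p1, p2) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 2)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 2)
  rad <- pi / 180
  la1 <- p1[, 1] * rad; la2 <- p2[, 1] * rad
  dla <- (p2[, 1] - p1[, 1]) * rad / 2
  dlo <- (p2[, 2] - p1[, 2]) * rad / 2
  a <- sin(dla)^2 + cos(la1) * cos(la2) * sin(dlo)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Label each GPS sample as stationary or transition by movement speed
#'
#' The speed at sample k is the backward difference: haversine distance from
#' sample k-1 divided by the elapsed time, in km/h. The first sample inherits
#' the second's speed. Samples following a gap longer than `max_gap_s` get
#' state `unknown` (no speed estimate is meaningful across an outage).
#' Samples with speed strictly below `speed_threshold_kmh` are `stationary`,
#' the rest `transition`.
#'
#' @param trace A [location_trace()].
#' @param cfg A [preprocess_config()].
#' @return A `labeled_trace`: the trace plus per-sample `speed_kmh` and
#'   `state` columns in `$samples`.
#' @export
estimate_speeds <- function(trace, cfg = preprocess_config()) {
  stopifnot(inherits(trace, "location_trace"))
  s <- trace$samples
  n <- nrow(s)
  speed <- rep(NA_real_, n)
  state <- rep("unknown", n)
  if (n >= 2) {
    dt <- diff(s$t)
    dist_km <- haversine_km(cbind(s$lat[-n], s$lon[-n]),
                            cbind(s$lat[-1], s$lon[-1]))
    sp <- dist_km / (dt / 3600)
    ok <- dt <= cfg$max_gap_s
    speed[-1][ok] <- sp[ok]
    # first sample inherits the second's speed (if that one is defined)
    speed[1] <- speed[2]
    defined <- !is.na(speed)
    state[defined] <- ifelse(speed[defined] < cfg$speed_threshold_kmh,
                             "stationary", "transition")
  }
  out <- trace
  out$samples$speed_kmh <- speed
  out$samples$state <- state
  class(out) <- c("labeled_trace", "location_trace")
  out
}

#' @export
print.labeled_trace <- function(x, ...) {
  tab <- table(factor(x$samples$state,
                      levels = c("stationary", "transition", "unknown")))
  cat(sprintf("<labeled_trace> %s: %d samples (%d stationary, %d transition, %d unknown)\n",
              x$participant_id, nrow(x$samples), tab[1], tab[2], tab[3]))
  invisible(x)
}

# farthest point-to-own-center haversine distance, meters
max_center_dist_m <- function(pts, centers, assignment) {
  d <- haversine_km(pts, centers[assignment, , drop = FALSE]) * 1000
  max(d)
}

#' Cluster stationary samples with radius-bounded adaptive K-means
#'
#' Runs K-means on the stationary (lat, lon) samples for K = 1, 2, ... and
#' returns the smallest K for which the farthest sample-to-own-center
#' haversine distance falls below `cluster_radius_m`. Each K uses
#' `kmeans_restarts` random starts with a fixed RNG seed, so results are
#' reproducible. Cluster centers are coordinate means; occupancy `p` is the
#' fraction of stationary samples per cluster.
#'
#' @param labeled A `labeled_trace` from [estimate_speeds()].
#' @param cfg A [preprocess_config()].
#' @param seed Integer RNG seed for the K-means restarts.
#' @return A `cluster_model`: list with `K`, `centers` (K x 2 matrix lat,
#'   lon), `assignment` (cluster index per stationary sample), `p`
#'   (occupancy), `stationary_idx` (row indices into the trace samples),
#'   `max_radius_m`, and `radius_ok` (whether the bound was met before the
#'   `k_max` cap).
#' @export
cluster_stationary <- function(labeled, cfg = preprocess_config(), seed = 1L) {
  stopifnot(inherits(labeled, "labeled_trace"))
  idx <- which(labeled$samples$state == "stationary")
  if (length(idx) == 0) stop("no stationary samples to cluster")
  pts <- cbind(labeled$samples$lat[idx], labeled$samples$lon[idx])
  n_unique <- length(unique(complex(real = pts[, 1], imaginary = pts[, 2])))
  k_cap <- min(cfg$k_max, n_unique)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  for (K in seq_len(k_cap)) {
    if (K == 1) {
      centers <- matrix(colMeans(pts), ncol = 2)
      assignment <- rep(1L, nrow(pts))
    } else {
      km <- suppressWarnings(
        stats::kmeans(pts, centers = K, nstart = cfg$kmeans_restarts,
                      iter.max = 100))
      centers <- km$centers
      assignment <- km$cluster
    }
    r <- max_center_dist_m(pts, centers, assignment)
    if (r < cfg$cluster_radius_m || K == k_cap) {
      p <- as.numeric(tabulate(assignment, nbins = K)) / length(assignment)
      return(structure(
        list(K = K, centers = unname(centers), assignment = assignment,
             p = p, stationary_idx = idx, max_radius_m = r,
             radius_ok = r < cfg$cluster_radius_m),
        class = "cluster_model"))
    }
  }
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d clusters over %d stationary samples (max radius %.0f m)\n",
              x$K, length(x$assignment), x$max_radius_m))
  if (!is.null(x$home_cluster))
    cat(sprintf("  home cluster: %d (occupancy %.2f)%s\n", x$home_cluster,
                x$p[x$home_cluster],
                if (isTRUE(x$home_fallback)) " [fallback: no night samples]" else ""))
  invisible(x)
}

#' Identify the home cluster
#'
#' Home is taken to be, among the top-3 most-visited clusters, the one with
#' the most stationary samples whose participant-local time falls in
#' midnight to 6 a.m. Ties break by overall visit count, then lowest cluster
#' index. If no stationary sample falls in the night window, the most-visited
#' cluster is returned with `home_fallback = TRUE`.
#'
#' @param model A `cluster_model`.
#' @param labeled The `labeled_trace` the model was fit on.
#' @param tz_offset UTC offset (h); defaults to the trace's own.
#' @return The model with `home_cluster` (index) and `home_fallback` fields.
#' @export
identify_home_cluster <- function(model, labeled, tz_offset = labeled$tz_offset) {
  stopifnot(inherits(model, "cluster_model"))
  counts <- tabulate(model$assignment, nbins = model$K)
  top3 <- order(counts, decreasing = TRUE)[seq_len(min(3, model$K))]
  t_loc <- labeled$samples$t[model$stationary_idx] + tz_offset * 3600
  hour <- (t_loc %% 86400) / 3600
  night <- hour < 6  # [00:00, 06:00) local
  night_counts <- tabulate(model$assignment[night], nbins = model$K)
  if (!any(night)) {
    model$home_cluster <- top3[1]
    model$home_fallback <- TRUE
    return(model)
  }
  # most night samples among top-3; ties by overall count, then lowest index
  ord <- order(-night_counts[top3], -counts[top3], top3)
  model$home_cluster <- top3[ord[1]]
  model$home_fallback <- FALSE
  model
}

# save/restore .Random.seed so seeded helpers don't clobber the caller's RNG
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
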