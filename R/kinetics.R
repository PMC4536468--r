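#' Pair sister kinetochores in one frame
#'
#' Mutual-nearest-neighbour pairing with a distance gate: candidate pairs
#' whose members are each other's nearest neighbour and closer than
#' \code{max_pair_um} are accepted greedily in order of increasing
#' distance. Unpaired kinetochores are excluded and counted.
#'
#' @param pts Matrix (n x 3) of kinetochore positions, or a detection
#'   data frame (its \code{KT_INNER} rows are used).
#' @param max_pair_um Pairing gate, about twice the inter-kinetochore
#'   rest length.
#' @return Object of class \code{sister_pairs}: data frame \code{pairs}
#'   with point indices \code{a}, \code{b} and \code{inter_kt_um}, plus
#'   \code{n_unpaired}.
#' @export
pair_sisters <- function(pts, max_pair_um = 2.0) {
  if (is.data.frame(pts)) {
    pts <- det_pos(pts[pts$channel == "KT_INNER", , drop = FALSE])
  }
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2L) stop("need >= 2 kinetochore points to pair", call. = FALSE)
  dmat <- as.matrix(stats::dist(pts))
  diag(dmat) <- Inf
  nn <- apply(dmat, 1L, which.min)
  cand <- which(nn[nn] == seq_len(n) & seq_len(n) < nn)  # mutual, once
  cand <- cand[dmat[cbind(cand, nn[cand])] <= max_pair_um]
  ord <- order(dmat[cbind(cand, nn[cand])])
  taken <- rep(FALSE, n)
  pairs <- list()
  for (i in cand[ord]) {
    j <- nn[i]
    if (!taken[i] && !taken[j]) {
      taken[i] <- taken[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, j, dmat[i, j])
    }
  }
  pairs <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(a = as.integer(m[, 1]), b = as.integer(m[, 2]),
               inter_kt_um = m[, 3])
  } else {
    warning("no mutual-nearest-neighbour pair within the gate",
            call. = FALSE)
    data.frame(a = integer(0), b = integer(0), inter_kt_um = numeric(0))
  }
  structure(list(pairs = pairs, n_unpaired = n - 2L * nrow(pairs),
                 max_pair_um = max_pair_um),
            class = "sister_pairs")
}

#' @export
print.sister_pairs <- function(x, ...) {
  cat(sprintf("<sister_pairs> %d pairs, %d unpaired (gate %g um)\n",
              nrow(x$pairs), x$n_unpaired, x$max_pair_um))
  invisible(x)
}

#' Per-frame inter-kinetochore distance of a sister pair
#'
#' Euclidean sister-to-sister distance at every frame where both tracks
#' are sampled; frames missing from either track yield \code{NA} (no
#' imputation).
#'
#' @param track_a,track_b Track data frames (\code{frame}, \code{x_um},
#'   \code{y_um}, \code{z_um}).
#' @param frames Frame grid to evaluate on (default: union of both
#'   tracks' frames).
#' @return Data frame \code{frame}, \code{inter_kt_um}.
#' @export
inter_kt_series <- function(track_a, track_b,
                            frames = sort(union(track_a$frame,
                                                track_b$frame))) {
  ia <- match(frames, track_a$frame)
  ib <- match(frames, track_b$frame)
  d <- sqrt((track_a$x_um[ia] - track_b$x_um[ib])^2 +
              (track_a$y_um[ia] - track_b$y_um[ib])^2 +
              (track_a$z_um[ia] - track_b$z_um[ib])^2)
  data.frame(frame = frames, inter_kt_um = d)
}

#' Intra-kinetochore offset from sister distances
#'
#' Half the difference between the outer-marker and inner-marker sister
#' distances of one pair: delta = (d_outer - d_inner) / 2. Noise can make
#' individual values negative; such values are kept (and may be flagged
#' downstream), since averaging over pairs removes the sign noise.
#'
#' @param d_inner_um Inner-marker (e.g. CENPA-CENPA) sister distance.
#' @param d_outer_um Outer-marker (e.g. HEC1-HEC1) sister distance.
#' @return Intra-kinetochore offset(s) in micrometres.
#' @export
intra_kt_delta <- function(d_inner_um, d_outer_um) {
  stopifnot(all(d_inner_um >= 0), all(d_outer_um >= 0))
  (d_outer_um - d_inner_um) / 2
}

#' Axis-projected position of a pair centre
#'
#' Signed projection of the sister-pair centre onto the spindle axis,
#' with origin at the spindle centre and positive direction towards the
#' reference pole.
#'
#' @param center Matrix (m x 3) of pair-centre positions (one row per
#'   frame) or a single 3-vector.
#' @param geometry A \code{\link{plate_metrics}} result (or a list of
#'   them, one per row of \code{center}).
#' @return Signed axial positions in micrometres.
#' @export
axis_position_series <- function(center, geometry) {
  if (is.null(dim(center))) center <- matrix(center, nrow = 1L)
  if (inherits(geometry, "plate_geometry")) {
    geometry <- rep(list(geometry), nrow(center))
  }
  stopifnot(length(geometry) == nrow(center))
  vapply(seq_len(nrow(center)), function(i) {
    g <- geometry[[i]]
    if (is.null(g)) return(NA_real_)
    sum(g$u * (center[i, ] - g$spindle_center))
  }, numeric(1))
}

#' Autocorrelation of an oscillation series
#'
#' Mean-subtracted, biased-normalised autocorrelation
#' ac[k] = sum_t x~(t) x~(t+k) / sum_t x~(t)^2 on the lag grid
#' 0, dt, 2 dt, ... Gaps (\code{NA}) are tolerated up to 20\% of the
#' series; products involving a gap are omitted from the numerator.
#'
#' @param series Numeric vector sampled at a fixed interval (may contain
#'   \code{NA} gaps).
#' @param dt_s Sampling interval (s).
#' @param max_lag_s Largest lag evaluated.
#' @return Object of class \code{ac_profile}: \code{lags_s}, \code{ac}
#'   and the number of valid samples \code{n}.
#' @export
oscillation_autocorrelation <- function(series, dt_s, max_lag_s = 150) {
  series <- as.numeric(series)
  n <- length(series)
  valid <- sum(!is.na(series))
  if (valid < 8L) stop("need >= 8 valid samples", call. = FALSE)
  if ((n - valid) / n > 0.2) {
    stop("more than 20% of the series is missing", call. = FALSE)
  }
  x <- series - mean(series, na.rm = TRUE)
  denom <- sum(x^2, na.rm = TRUE)
  if (denom <= 0 || stats::sd(series, na.rm = TRUE) < 1e-12) {
    stop("constant series: zero variance", call. = FALSE)
  }
  kmax <- min(n - 1L, floor(max_lag_s / dt_s))
  ac <- vapply(0:kmax, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k], na.rm = TRUE) / denom
  }, numeric(1))
  structure(list(lags_s = (0:kmax) * dt_s, ac = ac, n = valid),
            class = "ac_profile")
}

#' Average autocorrelation profiles pointwise
#'
#' Profiles from multiple pairs (or cells) are averaged on the common lag
#' grid; profiles shorter than the longest one contribute up to their own
#' maximal lag.
#'
#' @param profiles List of \code{ac_profile} objects with a common
#'   \code{dt}.
#' @return A pointwise-mean \code{ac_profile}.
#' @export
average_ac_profiles <- function(profiles) {
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  if (length(profiles) == 0L) stop("no profiles to average", call. = FALSE)
  kmax <- max(vapply(profiles, function(p) length(p$ac), integer(1)))
  lags <- profiles[[which.max(vapply(profiles, function(p) length(p$ac),
                                     integer(1)))]]$lags_s
  acc <- matrix(NA_real_, length(profiles), kmax)
  for (i in seq_along(profiles)) {
    acc[i, seq_along(profiles[[i]]$ac)] <- profiles[[i]]$ac
  }
  structure(list(lags_s = lags, ac = colMeans(acc, na.rm = TRUE),
                 n = sum(vapply(profiles, function(p) p$n, numeric(1)))),
            class = "ac_profile")
}

#' @export
print.ac_profile <- function(x, ...) {
  hp <- half_period(x)
  cat(sprintf("<ac_profile> %d lags up to %g s%s\n", length(x$ac),
              max(x$lags_s),
              if (is.na(hp$half_period_s)) ", no first minimum" else
                sprintf(", half-period %g s (depth %.3f)",
                        hp$half_period_s, hp$depth)))
  invisible(x)
}

#' Oscillation half-period from an autocorrelation profile
#'
#' The first strict local minimum of the autocorrelation over positive
#' lags marks the half-period of the oscillation; its value (depth)
#' reflects the regularity. A minimum is only called when its depth lies
#' below \code{min_depth}; noise-like profiles yield no call.
#'
#' @param profile An \code{ac_profile}.
#' @param min_depth Depth threshold (a first minimum must be below it).
#' @return List with \code{half_period_s} (\code{NA} if no call) and
#'   \code{depth} (autocorrelation value at the minimum, \code{NA} if no
#'   call).
#' @export
half_period <- function(profile, min_depth = -0.1) {
  ac <- profile$ac
  m <- length(ac)
  for (k in 2:(m - 1L)) {       # interior lags > 0
    if (ac[k] < ac[k - 1L] && ac[k] < ac[k + 1L]) {
      if (ac[k] < min_depth) {
        return(list(half_period_s = profile$lags_s[k], depth = ac[k]))
      }
      # a shallow first minimum forfeits the call only if no deeper
      # strict minimum follows; continue scanning
    }
  }
  list(half_period_s = NA_real_, depth = NA_real_)
}
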