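#' Detect anaphase onset from inter-kinetochore distances
#'
#' Sister separation jumps at anaphase. The onset is called at the first
#' frame where the median inter-kinetochore distance reaches
#' \code{fold} times the baseline (the median over the first
#' \code{baseline_frames} frames), sustained for at least
#' \code{sustain_frames} consecutive frames.
#'
#' @param inter_kt Data frame (or matrix) of per-frame median
#'   inter-kinetochore distances: columns \code{frame} and
#'   \code{inter_kt_um}, one row per frame (e.g. medians across pairs).
#' @param fold Fold over baseline marking onset.
#' @param baseline_frames Frames defining the baseline median.
#' @param sustain_frames Consecutive frames the fold must hold.
#' @return Onset frame (0-based) or \code{NA} if never reached.
#' @export
detect_anaphase_onset <- function(inter_kt, fold = 1.5,
                                  baseline_frames = 3L,
                                  sustain_frames = 2L) {
  inter_kt <- as.data.frame(inter_kt)
  stopifnot(all(c("frame", "inter_kt_um") %in% names(inter_kt)))
  inter_kt <- inter_kt[order(inter_kt$frame), , drop = FALSE]
  d <- inter_kt$inter_kt_um
  ok <- !is.na(d)
  if (sum(ok) < 5L) stop("need >= 5 frames with paired sisters",
                         call. = FALSE)
  base <- stats::median(d[ok][seq_len(min(baseline_frames, sum(ok)))])
  hit <- !is.na(d) & d >= fold * base
  run <- 0L
  for (i in seq_along(hit)) {
    run <- if (hit[i]) run + 1L else 0L
    if (run >= sustain_frames) {
      return(inter_kt$frame[i - sustain_frames + 1L])
    }
  }
  NA_integer_
}

#' Detect spindle rotation
#'
#' The spindle axis of each frame (signed, reference pole to other pole)
#' is projected onto the XY plane and compared with the initial axis;
#' the maximum angular deviation over the video is reported, and the
#' spindle is called rotating when it exceeds the threshold (net
#' orientation change, not cumulative path angle).
#'
#' @param axes Matrix (n_frames x 3) of per-frame axis vectors (any
#'   consistent sign convention), or a list of \code{plate_geometry}
#'   objects (possibly with \code{NULL} gaps).
#' @param threshold_deg Rotation call threshold.
#' @return List of class \code{rotation_call}: \code{max_xy_angle_deg}
#'   in [0, 180] and logical \code{rotating}.
#' @export
detect_rotation <- function(axes, threshold_deg = 90) {
  if (is.list(axes) && !is.data.frame(axes)) {
    axes <- t(vapply(axes, function(g) {
      if (is.null(g)) c(NA_real_, NA_real_, NA_real_) else -g$u
    }, numeric(3)))
  }
  axes <- as.matrix(axes)
  keep <- rowSums(is.na(axes)) == 0L
  axes <- axes[keep, , drop = FALSE]
  if (nrow(axes) < 2L) stop("need >= 2 frames with geometry", call. = FALSE)
  xy <- axes[, 1:2, drop = FALSE]
  nrm <- sqrt(rowSums(xy^2))
  if (any(nrm < 1e-9)) {
    warning("axis parallel to Z in some frame(s); skipped", call. = FALSE)
    xy <- xy[nrm >= 1e-9, , drop = FALSE]
    nrm <- nrm[nrm >= 1e-9]
    if (nrow(xy) < 2L) stop("no usable XY projections", call. = FALSE)
  }
  xy <- xy / nrm
  ref <- xy[1L, ]
  cosang <- pmin(1, pmax(-1, xy %*% ref))
  ang <- acos(cosang) * 180 / pi
  max_ang <- max(ang)
  structure(list(max_xy_angle_deg = max_ang,
                 rotating = max_ang > threshold_deg,
                 threshold_deg = threshold_deg),
            class = "rotation_call")
}

#' @export
print.rotation_call <- function(x, ...) {
  cat(sprintf("<rotation_call> max XY angle %.1f deg -> %s (> %g deg)\n",
              x$max_xy_angle_deg,
              if (x$rotating) "rotating" else "not rotating",
              x$threshold_deg))
  invisible(x)
}

#' Classify a division as symmetric or asymmetric
#'
#' The daughter size ratio is max(size)/min(size); the division is called
#' asymmetric when the ratio strictly exceeds the threshold (default 1.2,
#' i.e. daughters differing by more than 20\%). Sizes may be areas or
#' volumes; the ratio semantics are identical.
#'
#' @param size_a,size_b Positive daughter sizes (a.u.).
#' @param threshold Ratio threshold (strict).
#' @return List of class \code{division_call}: \code{size_a},
#'   \code{size_b}, \code{ratio} and logical \code{asymmetric}.
#' @export
classify_division <- function(size_a, size_b, threshold = 1.2) {
  if (!is.finite(size_a) || !is.finite(size_b) || size_a <= 0 ||
      size_b <= 0) {
    stop("daughter sizes must be positive", call. = FALSE)
  }
  ratio <- max(size_a, size_b) / min(size_a, size_b)
  structure(list(size_a = size_a, size_b = size_b, ratio = ratio,
                 asymmetric = ratio > threshold, threshold = threshold),
            class = "division_call")
}

#' @export
print.division_call <- function(x, ...) {
  cat(sprintf("<division_call> ratio %.3f -> %s (> %g)\n", x$ratio,
              if (x$asymmetric) "asymmetric" else "symmetric",
              x$threshold))
  invisible(x)
}

#' Classify a cell by attachment-marker-negative pairs
#'
#' A kinetochore is marker-negative when its attachment-marker intensity
#' falls below \code{neg_rel_threshold} times the cell median of marker
#' intensities; a sister pair counts as negative when at least one member
#' is negative. The cell is called positive (partially unstable
#' kinetochore-microtubules) when the negative-pair fraction strictly
#' exceeds \code{frac_threshold}.
#'
#' @param pair_intensities Two-column matrix (or data frame) of
#'   attachment-marker intensities, one row per sister pair.
#' @param neg_rel_threshold Fraction of the cell median below which a
#'   kinetochore is negative.
#' @param frac_threshold Negative-pair fraction above which the cell is
#'   positive (strict).
#' @return List of class \code{skap_call}: logical \code{positive},
#'   \code{frac_negative}, \code{n_pairs}, \code{negative_pairs} (row
#'   indices) and the absolute intensity \code{threshold} used.
#' @export
classify_skap_cell <- function(pair_intensities, neg_rel_threshold = 0.3,
                               frac_threshold = 0.30) {
  m <- as.matrix(pair_intensities)
  stopifnot(ncol(m) == 2L, nrow(m) >= 1L, all(m >= 0))
  thr <- neg_rel_threshold * stats::median(as.numeric(m))
  neg_pair <- (m[, 1] < thr) | (m[, 2] < thr)
  frac <- mean(neg_pair)
  structure(list(positive = frac > frac_threshold,
                 frac_negative = frac,
                 n_pairs = nrow(m),
                 negative_pairs = which(neg_pair),
                 threshold = thr),
            class = "skap_call")
}

#' @export
print.skap_call <- function(x, ...) {
  cat(sprintf("<skap_call> %d/%d pairs negative (%.0f%%) -> %s\n",
              length(x$negative_pairs), x$n_pairs, 100 * x$frac_negative,
              if (x$positive) "marker-positive cell" else "normal"))
  invisible(x)
}

#' Classify minus-end intensity asymmetry between poles
#'
#' Cold-stable kinetochore-fibre intensity at the two poles is called
#' asymmetric when the brighter pole exceeds the dimmer by more than
#' \code{fold}; the side is reported. The fold threshold is analyst-set
#' (visual scoring in the original assay) and configurable.
#'
#' @param i_pole1,i_pole2 Non-negative pole intensities, not both zero.
#' @param fold Fold threshold (strict).
#' @return One of \code{"SYMMETRIC"}, \code{"POLE1_MORE"},
#'   \code{"POLE2_MORE"}.
#' @export
classify_minus_end_asymmetry <- function(i_pole1, i_pole2, fold = 1.5) {
  stopifnot(i_pole1 >= 0, i_pole2 >= 0)
  if (i_pole1 + i_pole2 == 0) {
    stop("both pole intensities are zero; call undefined", call. = FALSE)
  }
  hi <- max(i_pole1, i_pole2)
  lo <- min(i_pole1, i_pole2)
  if (lo == 0 || hi / lo > fold) {
    if (i_pole1 > i_pole2) "POLE1_MORE" else "POLE2_MORE"
  } else {
    "SYMMETRIC"
  }
}
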