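#' Cluster centriole detections into two spindle poles
#'
#' Partitions 2-4 centriole detections into two groups by exhaustively
#' minimising the total within-group pairwise distance over all two-group
#' partitions (at most 7 for four points). Each group becomes a pole with
#' its centroid, member centrioles, centriole count and summed intensity.
#'
#' @param det Detection data frame of \code{CENTRIOLE} rows (a single
#'   frame of one cell).
#' @return List of two \code{pole} objects, ordered so the first pole has
#'   at least as many centrioles as the second.
#' @export
cluster_poles <- function(det) {
  if (is.data.frame(det)) {
    det <- det[det$channel == "CENTRIOLE", , drop = FALSE]
  }
  n <- nrow(det)
  if (is.null(n) || n < 2L) {
    stop("need at least 2 centriole detections to form poles",
         call. = FALSE)
  }
  if (n > 4L) stop("more than 4 centriole detections", call. = FALSE)
  pos <- det_pos(det)
  dmat <- as.matrix(stats::dist(pos))
  within_cost <- function(idx) {
    cost <- 0
    for (g in list(idx, setdiff(seq_len(n), idx))) {
      if (length(g) > 1L) cost <- cost + sum(dmat[g, g]) / 2
    }
    cost
  }
  # enumerate partitions: subsets containing point 1, proper and nonempty
  best <- NULL
  best_cost <- Inf
  second_cost <- Inf
  rest <- setdiff(seq_len(n), 1L)
  for (k in 0:(length(rest) - 1L)) {
    combs <- utils::combn(rest, k)
    for (j in seq_len(ncol(combs))) {
      idx <- c(1L, combs[, j, drop = TRUE])
      cost <- within_cost(idx)
      if (cost < best_cost) {
        second_cost <- best_cost
        best_cost <- cost
        best <- idx
      } else if (cost < second_cost) {
        second_cost <- cost
      }
    }
  }
  if (is.finite(second_cost) && second_cost - best_cost < 1e-6) {
    stop("ambiguous pole partition: two partitions within 1e-6",
         call. = FALSE)
  }
  make_pole <- function(idx) {
    p <- pos[idx, , drop = FALSE]
    centroid <- colMeans(p)
    if (any(sqrt(rowSums(sweep(p, 2, centroid)^2)) > 1.5)) {
      stop("pole members farther than 1.5 um from their centroid",
           call. = FALSE)
    }
    structure(list(centroid = centroid,
                   members = data.frame(x_um = p[, 1], y_um = p[, 2],
                                        z_um = p[, 3],
                                        intensity = det$intensity[idx]),
                   n_centrioles = length(idx),
                   total_intensity = sum(det$intensity[idx])),
              class = "pole")
  }
  g1 <- best
  g2 <- setdiff(seq_len(n), best)
  poles <- list(make_pole(g1), make_pole(g2))
  if (poles[[2]]$n_centrioles > poles[[1]]$n_centrioles) {
    poles <- poles[c(2, 1)]
  }
  d <- sqrt(sum((poles[[1]]$centroid - poles[[2]]$centroid)^2))
  if (d < 3) {
    stop("pole centroids closer than 3 um; not a bipolar spindle",
         call. = FALSE)
  }
  poles
}

#' @export
print.pole <- function(x, ...) {
  cat(sprintf("<pole> centroid (%.2f, %.2f, %.2f) um, %d centriole(s), I = %g\n",
              x$centroid[1], x$centroid[2], x$centroid[3],
              x$n_centrioles, x$total_intensity))
  invisible(x)
}

#' Assign the reference pole
#'
#' The reference pole carries the numerator half-spindle L1. In 2:1 cells
#' (\code{C21}) it is the pole with two centrioles; in all other
#' configurations it is the pole containing the single brightest
#' centriole detection (the grandmother centriole by the centrin-marker
#' intensity convention).
#'
#' @param poles List of two poles from \code{\link{cluster_poles}}.
#' @param config_label Centriole configuration label.
#' @return Index (1 or 2) of the reference pole within \code{poles}.
#' @export
assign_reference_pole <- function(poles, config_label = "WT") {
  config_label <- match.arg(config_label, c("WT", "C22", "C21", "C11"))
  stopifnot(length(poles) == 2L)
  if (config_label == "C21") {
    ns <- vapply(poles, function(p) p$n_centrioles, integer(1))
    if (ns[1] == ns[2]) {
      stop("C21 cell but both poles have the same centriole count",
           call. = FALSE)
    }
    return(which.max(ns))
  }
  brightest <- vapply(poles, function(p) max(p$members$intensity),
                      numeric(1))
  if (abs(brightest[1] - brightest[2]) < 1e-9) {
    stop("brightest centrioles tie; cannot assign grandmother pole",
         call. = FALSE)
  }
  which.max(brightest)
}

#' Fit the metaphase plate plane
#'
#' Orthogonal (total) least-squares plane through a 3D kinetochore point
#' cloud: the plane passes through the centroid and its normal is the
#' smallest principal axis of the centred points, i.e. the direction
#' minimising the sum of squared perpendicular distances.
#'
#' @param pts Numeric matrix (n x 3) of kinetochore positions, or a
#'   detection data frame.
#' @return List of class \code{plate_plane}: unit \code{normal} n, signed
#'   \code{offset} d with n.x = d, the \code{centroid}, and \code{rss}
#'   (sum of squared perpendicular residuals).
#' @export
fit_plate_plane <- function(pts) {
  if (is.data.frame(pts)) pts <- det_pos(pts)
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stop("plane fit needs >= 3 points", call. = FALSE)
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  # principal variances; collinear clouds have two vanishing directions
  lam <- sv$d^2
  scale2 <- max(lam[1], 1)
  if (lam[2] < 1e-12 * scale2) {
    stop("points are collinear; plate plane is degenerate", call. = FALSE)
  }
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  structure(list(normal = normal,
                 offset = sum(normal * ctr),
                 centroid = ctr,
                 rss = lam[3]),
            class = "plate_plane")
}

#' @export
print.plate_plane <- function(x, ...) {
  cat(sprintf("<plate_plane> n = (%.4f, %.4f, %.4f), d = %.4f, rss = %.3g\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset, x$rss))
  invisible(x)
}

#' Plate position and half-spindle ratio
#'
#' Intersects the fitted plate plane with the spindle axis (the line
#' through the two pole centroids) and derives the half-spindle lengths:
#' L1 from the reference pole to the intersection, L2 from the other
#' pole, and their ratio R = L1/L2. The plane normal is re-oriented so
#' that it points towards the reference pole. Intersections outside the
#' pole-to-pole segment are flagged but still reported.
#'
#' @param plane A \code{\link{fit_plate_plane}} result.
#' @param poles List of two poles.
#' @param reference Index of the reference pole (1 or 2).
#' @return Object of class \code{plate_geometry} with the plane, axis
#'   (point \code{p0} and unit direction \code{u} towards the reference
#'   pole), \code{intersection}, \code{L1}, \code{L2}, \code{R},
#'   \code{spindle_center} and the \code{outside_segment} flag.
#' @export
plate_metrics <- function(plane, poles, reference = 1L) {
  stopifnot(inherits(plane, "plate_plane"), length(poles) == 2L,
            reference %in% c(1L, 2L))
  ref <- poles[[reference]]$centroid
  oth <- poles[[3L - reference]]$centroid
  p0 <- oth
  u <- ref - oth
  pole_dist <- sqrt(sum(u^2))
  u <- u / pole_dist
  n <- plane$normal
  denom <- sum(n * u)
  if (abs(denom) <= 1e-6) {
    stop("spindle axis is parallel to the plate plane", call. = FALSE)
  }
  if (denom < 0) {           # orient normal towards the reference pole
    n <- -n
    plane$normal <- n
    plane$offset <- -plane$offset
    denom <- -denom
  }
  t <- (plane$offset - sum(n * p0)) / denom
  inter <- p0 + t * u
  l1 <- sqrt(sum((inter - ref)^2))
  l2 <- sqrt(sum((inter - oth)^2))
  if (l1 <= 0 || l2 <= 0) {
    stop("plate intersection coincides with a pole", call. = FALSE)
  }
  structure(list(plane = plane,
                 p0 = p0, u = u,
                 intersection = inter,
                 L1 = l1, L2 = l2, R = l1 / l2,
                 reference = as.integer(reference),
                 pole_distance = pole_dist,
                 spindle_center = (ref + oth) / 2,
                 outside_segment = (t < 0 || t > pole_dist)),
            class = "plate_geometry")
}

#' @export
print.plate_geometry <- function(x, ...) {
  cat(sprintf("<plate_geometry> L1 = %.3f, L2 = %.3f, R = %.4f%s\n",
              x$L1, x$L2, x$R,
              if (x$outside_segment) " [intersection outside pole segment]"
              else ""))
  invisible(x)
}

#' Spindle-centre offset from the cell centre
#'
#' The spindle centre is the midpoint of the two pole centroids; the cell
#' centre is the midpoint of the two axis-cortex intersection points
#' (the nearest cortex point on each side of the spindle, projected onto
#' the spindle axis). Returns the distance between the two centres.
#'
#' @param poles List of two poles.
#' @param cortex Matrix (m x 3) of cortex points, or a detection data
#'   frame with \code{CORTEX} rows.
#' @return Offset in micrometres.
#' @export
spindle_center_offset <- function(poles, cortex) {
  if (is.data.frame(cortex)) {
    cortex <- cortex[cortex$channel == "CORTEX", , drop = FALSE]
    cortex <- det_pos(cortex)
  }
  cortex <- as.matrix(cortex)
  if (nrow(cortex) < 2L) stop("need >= 2 cortex points", call. = FALSE)
  ctr <- (poles[[1]]$centroid + poles[[2]]$centroid) / 2
  u <- poles[[1]]$centroid - poles[[2]]$centroid
  u <- u / sqrt(sum(u^2))
  proj <- as.numeric(sweep(cortex, 2, ctr) %*% u)   # signed axial coords
  if (!any(proj > 0) || !any(proj < 0)) {
    stop("cortex points all on one side of the spindle", call. = FALSE)
  }
  # nearest cortex point (in 3D) on each side, projected onto the axis
  d3 <- sqrt(rowSums(sweep(cortex, 2, ctr)^2))
  side_pos <- which(proj > 0)
  side_neg <- which(proj < 0)
  t_pos <- proj[side_pos[which.min(d3[side_pos])]]
  t_neg <- proj[side_neg[which.min(d3[side_neg])]]
  cell_center <- ctr + (t_pos + t_neg) / 2 * u
  sqrt(sum((ctr - cell_center)^2))
}

#' Kinetochore-to-nearest-centriole distances
#'
#' For monopolar (monastrol-type) spindles: the distance from each
#' kinetochore to its closest centriole, whose average reflects the polar
#' ejection force.
#'
#' @param kt Matrix or detection data frame of kinetochore positions.
#' @param centrioles Matrix or detection data frame of centriole
#'   positions.
#' @return Numeric vector, one distance per kinetochore (um).
#' @export
monopole_kt_distances <- function(kt, centrioles) {
  if (is.data.frame(kt)) kt <- det_pos(kt[kt$channel %in%
                                            c("KT_INNER", "KT_OUTER"), ,
                                          drop = FALSE])
  if (is.data.frame(centrioles)) {
    centrioles <- det_pos(centrioles[centrioles$channel == "CENTRIOLE", ,
                                     drop = FALSE])
  }
  kt <- as.matrix(kt)
  centrioles <- as.matrix(centrioles)
  if (nrow(kt) < 1L || nrow(centrioles) < 1L) {
    stop("need >= 1 kinetochore and >= 1 centriole", call. = FALSE)
  }
  apply(kt, 1L, function(p) {
    min(sqrt(colSums((t(centrioles) - p)^2)))
  })
}

#' Normalised pole-intensity asymmetry
#'
#' Signed, scale-free contrast (I1 - I2) / (I1 + I2) in [-1, 1] between
#' the summed marker intensities of the two poles (or half-spindles).
#'
#' @param i1,i2 Non-negative intensities, not both zero.
#' @return Dimensionless asymmetry.
#' @export
pole_intensity_asymmetry <- function(i1, i2) {
  stopifnot(all(i1 >= 0), all(i2 >= 0))
  if (any(i1 + i2 == 0)) {
    stop("both intensities are zero; asymmetry undefined", call. = FALSE)
  }
  (i1 - i2) / (i1 + i2)
}
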