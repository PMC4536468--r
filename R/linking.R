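#' Link detections into tracks by gated nearest-neighbour assignment
#'
#' A deliberately simple per-frame greedy linker for detection tables that
#' lack track identities. Within each cell and channel, detections of
#' successive frames are attached to the spatially nearest active track
#' whose last sample is within \code{max_step_um} and at most
#' \code{max_gap_frames} frames old. Detections are processed in input
#' (row) order, so equidistant candidates are resolved towards the lowest
#' row index. Detections with no admissible track start a new track, so
#' every detection is assigned to exactly one track and no link ever
#' exceeds the gate.
#'
#' @param det Detection data frame.
#' @param max_step_um Gate: maximum displacement between linked samples
#'   (micrometres).
#' @param max_gap_frames Maximum number of missed frames bridged by a link.
#' @return An object of class \code{track_set}: list with \code{tracks}
#'   (each a data frame of \code{frame}, \code{time_s}, \code{x_um},
#'   \code{y_um}, \code{z_um}, \code{intensity} plus \code{cell_id} and
#'   \code{channel} attributes) and the linking parameters.
#' @export
link_tracks <- function(det, max_step_um = 0.8, max_gap_frames = 1L) {
  det <- validate_detections(det)
  stopifnot(max_step_um > 0, max_gap_frames >= 0)
  tracks <- list()
  for (cid in unique(det$cell_id)) {
    for (ch in unique(det$channel[det$cell_id == cid])) {
      sub <- det[det$cell_id == cid & det$channel == ch, , drop = FALSE]
      # stable sort: ties within a frame keep input row order
      sub <- sub[order(sub$frame), , drop = FALSE]
      last_pos <- NULL     # matrix of last positions, one row per open track
      last_frame <- integer(0)
      members <- list()    # row indices (into sub) per track
      for (f in sort(unique(sub$frame))) {
        rows <- which(sub$frame == f)
        claimed <- rep(FALSE, length(last_frame))
        for (r in rows) {
          p <- c(sub$x_um[r], sub$y_um[r], sub$z_um[r])
          best <- 0L
          best_d <- Inf
          if (length(last_frame) > 0L) {
            ok <- !claimed & (f - last_frame) >= 1L &
              (f - last_frame) <= (max_gap_frames + 1L)
            for (k in which(ok)) {
              d <- sqrt(sum((p - last_pos[k, ])^2))
              if (d <= max_step_um && d < best_d) {
                best_d <- d
                best <- k
              }
            }
          }
          if (best > 0L) {
            members[[best]] <- c(members[[best]], r)
            last_pos[best, ] <- p
            last_frame[best] <- f
            claimed[best] <- TRUE
          } else {
            members[[length(members) + 1L]] <- r
            last_pos <- rbind(last_pos, p)
            last_frame <- c(last_frame, f)
            claimed <- c(claimed, TRUE)
          }
        }
      }
      for (m in members) {
        tr <- sub[m, c("frame", "time_s", "x_um", "y_um", "z_um",
                       "intensity"), drop = FALSE]
        rownames(tr) <- NULL
        attr(tr, "cell_id") <- cid
        attr(tr, "channel") <- ch
        tracks[[length(tracks) + 1L]] <- tr
      }
    }
  }
  structure(list(tracks = tracks,
                 linking_params = list(max_step_um = max_step_um,
                                       max_gap_frames = as.integer(max_gap_frames))),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  lens <- vapply(x$tracks, nrow, integer(1))
  cat(sprintf("<track_set> %d tracks (lengths %s), gate %g um, gap %d\n",
              length(x$tracks),
              if (length(lens)) paste0(min(lens), "-", max(lens)) else "-",
              x$linking_params$max_step_um, x$linking_params$max_gap_frames))
  invisible(x)
}
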