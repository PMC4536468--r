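#' Analyse a fixed-cell snapshot
#'
#' For a one-frame (fixed and stained) cell: pairs the inner-marker
#' kinetochores, and then, per sister pair, computes the inner-inner and
#' outer-outer sister distances and the intra-kinetochore offset
#' delta = (outer - inner) / 2 (when an outer channel is present), and
#' classifies the cell by its attachment-marker-negative pair fraction
#' (when an attachment-marker channel is present). Outer and marker
#' points are matched to inner kinetochores by nearest neighbour.
#'
#' @param cell A one-frame (or first-frame-only) \code{\link{cell_series}}
#'   from fixed imaging.
#' @param config An \code{\link{analysis_config}}.
#' @return Object of class \code{snapshot_analysis}: \code{pairs}
#'   (a \code{sister_pairs}), \code{per_pair} (data frame with
#'   \code{d_inner_um}, \code{d_outer_um}, \code{delta_um},
#'   \code{delta_negative} flag), \code{mean_delta_um} and
#'   \code{skap} (a \code{skap_call} or \code{NULL}).
#' @export
analyze_snapshot <- function(cell, config = analysis_config()) {
  stopifnot(inherits(cell, "cell_series"))
  det <- frame_detections(cell, cell$frames[1L])
  inner <- det[det$channel == "KT_INNER", , drop = FALSE]
  if (nrow(inner) < 2L) stop("snapshot has < 2 inner kinetochores",
                             call. = FALSE)
  ppos <- det_pos(inner)
  sp <- pair_sisters(ppos, max_pair_um = config$max_pair_um)
  outer <- det[det$channel == "KT_OUTER", , drop = FALSE]
  per_pair <- data.frame(d_inner_um = sp$pairs$inter_kt_um,
                         d_outer_um = NA_real_,
                         delta_um = NA_real_,
                         delta_negative = NA)
  if (nrow(outer) >= 2L && nrow(sp$pairs) > 0L) {
    opos <- det_pos(outer)
    match_outer <- apply(ppos, 1L, function(p) {
      which.min(colSums((t(opos) - p)^2))
    })
    oa <- opos[match_outer[sp$pairs$a], , drop = FALSE]
    ob <- opos[match_outer[sp$pairs$b], , drop = FALSE]
    per_pair$d_outer_um <- sqrt(rowSums((oa - ob)^2))
    per_pair$delta_um <- intra_kt_delta(per_pair$d_inner_um,
                                        per_pair$d_outer_um)
    per_pair$delta_negative <- per_pair$delta_um < 0
  }
  skap <- NULL
  mark <- det[det$channel == "ATTACH_MARK", , drop = FALSE]
  if (nrow(mark) >= 2L && nrow(sp$pairs) > 0L) {
    mpos <- det_pos(mark)
    match_mark <- apply(ppos, 1L, function(p) {
      which.min(colSums((t(mpos) - p)^2))
    })
    intens <- cbind(mark$intensity[match_mark[sp$pairs$a]],
                    mark$intensity[match_mark[sp$pairs$b]])
    skap <- classify_skap_cell(intens,
                               neg_rel_threshold = config$skap_neg_rel_threshold,
                               frac_threshold = config$skap_cell_frac_threshold)
  }
  structure(list(pairs = sp, per_pair = per_pair,
                 mean_delta_um = mean(per_pair$delta_um),
                 skap = skap),
            class = "snapshot_analysis")
}

#' @export
print.snapshot_analysis <- function(x, ...) {
  cat(sprintf("<snapshot_analysis> %d pairs, mean delta = %s um%s\n",
              nrow(x$per_pair),
              if (is.na(x$mean_delta_um)) "NA" else
                sprintf("%.4f", x$mean_delta_um),
              if (is.null(x$skap)) "" else
                sprintf(", %.0f%% marker-negative pairs",
                        100 * x$skap$frac_negative)))
  invisible(x)
}
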