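#' Analyse one cell series
#'
#' Runs the full geometry and kinetics pipeline on a single cell:
#' per-frame pole clustering (pole identity maintained across frames by
#' nearest-centroid matching, reference pole fixed at the first frame),
#' orthogonal plate-plane fit, plane-axis intersection and half-spindle
#' ratio R, optional spindle-centre offset; sister tracking and pairing,
#' inter-kinetochore distances, axis-projected oscillation
#' autocorrelation with half-period, anaphase-onset detection and the
#' rotation call.
#'
#' @param cell A \code{\link{cell_series}}.
#' @param config An \code{\link{analysis_config}}.
#' @return Object of class \code{cell_analysis}: \code{frames} (per-frame
#'   geometry table), \code{summary} (one-row per-cell data frame),
#'   \code{geometry} (per-frame \code{plate_geometry} list),
#'   \code{pair_series} (per-pair inter-KT and axis-position matrices)
#'   and \code{ac} (the cell's averaged \code{ac_profile}, or
#'   \code{NULL}).
#' @export
analyze_cell <- function(cell, config = analysis_config()) {
  stopifnot(inherits(cell, "cell_series"))
  frames <- cell$frames
  nf <- length(frames)
  geom <- vector("list", nf)
  offs <- rep(NA_real_, nf)
  ref_idx <- NA_integer_
  prev_centroids <- NULL
  for (i in seq_len(nf)) {
    det_f <- frame_detections(cell, frames[i])
    cen <- det_f[det_f$channel == "CENTRIOLE", , drop = FALSE]
    kt <- det_f[det_f$channel == "KT_INNER", , drop = FALSE]
    if (nrow(cen) < 2L || nrow(kt) < 3L) next
    poles <- tryCatch(cluster_poles(cen), error = function(e) NULL)
    if (is.null(poles)) next
    if (is.null(prev_centroids)) {
      ref_idx <- assign_reference_pole(poles, cell$config_label)
    } else {
      # keep pole identity: match to the previous frame's centroids
      d11 <- sum((poles[[1]]$centroid - prev_centroids[[1]])^2)
      d12 <- sum((poles[[1]]$centroid - prev_centroids[[2]])^2)
      if (d12 < d11) poles <- poles[c(2, 1)]
    }
    prev_centroids <- list(poles[[1]]$centroid, poles[[2]]$centroid)
    plane <- tryCatch(fit_plate_plane(kt), error = function(e) NULL)
    if (is.null(plane)) next
    g <- tryCatch(plate_metrics(plane, poles, ref_idx),
                  error = function(e) NULL)
    if (is.null(g)) next
    geom[[i]] <- g
    cortex <- det_f[det_f$channel == "CORTEX", , drop = FALSE]
    if (nrow(cortex) >= 2L) {
      offs[i] <- tryCatch(spindle_center_offset(poles, cortex),
                          error = function(e) NA_real_)
    }
  }
  r <- vapply(geom, function(g) if (is.null(g)) NA_real_ else g$R,
              numeric(1))
  l1 <- vapply(geom, function(g) if (is.null(g)) NA_real_ else g$L1,
               numeric(1))
  l2 <- vapply(geom, function(g) if (is.null(g)) NA_real_ else g$L2,
               numeric(1))
  flag <- vapply(geom, function(g) if (is.null(g)) NA else
    g$outside_segment, logical(1))
  frames_df <- data.frame(cell_id = cell$cell_id, frame = frames,
                          time_s = cell$times, L1 = l1, L2 = l2, R = r,
                          spindle_center_offset_um = offs,
                          outside_segment = flag,
                          stringsAsFactors = FALSE)

  # sister tracking and pairing
  kt_det <- cell$detections[cell$detections$channel == "KT_INNER", ,
                            drop = FALSE]
  pair_series <- NULL
  ac <- NULL
  median_inter_kt <- rep(NA_real_, nf)
  if (nrow(kt_det) >= 2L) {
    ts <- link_tracks(kt_det, max_step_um = config$max_step_um,
                      max_gap_frames = config$max_gap_frames)
    tracks <- ts$tracks
    f0 <- frames[1L]
    at0 <- vapply(tracks, function(tr) f0 %in% tr$frame, logical(1))
    tr0 <- tracks[at0]
    if (length(tr0) >= 2L) {
      pos0 <- t(vapply(tr0, function(tr) {
        i <- match(f0, tr$frame)
        c(tr$x_um[i], tr$y_um[i], tr$z_um[i])
      }, numeric(3)))
      sp <- pair_sisters(pos0, max_pair_um = config$max_pair_um)
      np <- nrow(sp$pairs)
      if (np > 0L) {
        inter <- matrix(NA_real_, nf, np)
        axpos <- matrix(NA_real_, nf, np)
        for (p in seq_len(np)) {
          ta <- tr0[[sp$pairs$a[p]]]
          tb <- tr0[[sp$pairs$b[p]]]
          iks <- inter_kt_series(ta, tb, frames)
          inter[, p] <- iks$inter_kt_um
          ia <- match(frames, ta$frame)
          ib <- match(frames, tb$frame)
          ctr <- cbind((ta$x_um[ia] + tb$x_um[ib]) / 2,
                       (ta$y_um[ia] + tb$y_um[ib]) / 2,
                       (ta$z_um[ia] + tb$z_um[ib]) / 2)
          axpos[, p] <- axis_position_series(ctr, geom)
        }
        median_inter_kt <- apply(inter, 1L, stats::median, na.rm = TRUE)
        pair_series <- list(pairs = sp, inter_kt_um = inter,
                            axis_position_um = axpos)
      }
    }
  }

  # anaphase onset: annotated frame wins, detection fills in
  detected_onset <- NA_integer_
  if (sum(is.finite(median_inter_kt)) >= 5L) {
    detected_onset <- detect_anaphase_onset(
      data.frame(frame = frames, inter_kt_um = median_inter_kt),
      fold = config$anaphase_fold,
      baseline_frames = config$anaphase_baseline_frames,
      sustain_frames = config$anaphase_sustain_frames)
  }
  onset <- if (!is.na(cell$anaphase_frame)) cell$anaphase_frame else
    detected_onset

  # oscillation autocorrelation on metaphase frames only
  if (!is.null(pair_series)) {
    meta_rows <- if (is.na(onset)) seq_len(nf) else which(frames < onset)
    if (length(meta_rows) >= 8L) {
      profs <- lapply(seq_len(ncol(pair_series$axis_position_um)),
                      function(p) {
        x <- pair_series$axis_position_um[meta_rows, p]
        if (sum(!is.na(x)) < 8L || (sum(is.na(x)) / length(x)) > 0.2) {
          return(NULL)
        }
        tryCatch(oscillation_autocorrelation(x, cell$dt_s,
                                             config$max_lag_s),
                 error = function(e) NULL)
      })
      profs <- Filter(Negate(is.null), profs)
      if (length(profs) > 0L) ac <- average_ac_profiles(profs)
    }
  }
  hp <- if (is.null(ac)) list(half_period_s = NA_real_, depth = NA_real_)
        else half_period(ac, config$ac_min_depth)

  rot <- tryCatch(detect_rotation(geom, config$rotation_threshold_deg),
                  error = function(e) NULL)
  rsel <- metaphase_R_selection(r, frames, onset, config$metaphase_k)
  meta_rows <- if (is.na(onset)) seq_len(nf) else which(frames < onset)
  mean_ikt <- if (!is.null(pair_series) && length(meta_rows) > 0L) {
    mean(pair_series$inter_kt_um[meta_rows, ], na.rm = TRUE)
  } else NA_real_

  summary <- data.frame(
    cell_id = cell$cell_id,
    config_label = cell$config_label,
    group_label = cell$group_label,
    n_frames = nf,
    dt_s = cell$dt_s,
    metaphase_R = rsel$metaphase_R,
    anaphase_R = rsel$anaphase_R,
    anaphase_frame = onset,
    anaphase_frame_detected = detected_onset,
    mean_inter_kt_um = mean_ikt,
    half_period_s = hp$half_period_s,
    ac_depth = hp$depth,
    max_xy_angle_deg = if (is.null(rot)) NA_real_ else rot$max_xy_angle_deg,
    rotating = if (is.null(rot)) NA else rot$rotating,
    mean_spindle_center_offset_um = if (all(is.na(offs))) NA_real_ else
      mean(offs, na.rm = TRUE),
    stringsAsFactors = FALSE)

  structure(list(frames = frames_df, summary = summary, geometry = geom,
                 pair_series = pair_series, ac = ac),
            class = "cell_analysis")
}

#' @export
print.cell_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cell_analysis> %s: metaphase R = %.3f, anaphase frame = %s\n",
              s$cell_id, s$metaphase_R,
              if (is.na(s$anaphase_frame)) "none" else s$anaphase_frame))
  invisible(x)
}

#' Analyse a cohort of cells
#'
#' Applies \code{\link{analyze_cell}} to every cell and binds the
#' per-frame and per-cell tables.
#'
#' @param cells List of \code{\link{cell_series}} (e.g. from
#'   \code{\link{assemble_cells}} or \code{\link{simulate_cohort}}).
#' @param config An \code{\link{analysis_config}}.
#' @return List of class \code{cohort_analysis}: \code{per_cell} (data
#'   frame), \code{per_frame} (data frame) and \code{analyses} (named
#'   list of \code{cell_analysis}).
#' @export
analyze_cohort <- function(cells, config = analysis_config()) {
  analyses <- lapply(cells, analyze_cell, config = config)
  names(analyses) <- vapply(analyses, function(a) a$summary$cell_id,
                            character(1))
  structure(list(
    per_cell = do.call(rbind, c(lapply(analyses, function(a) a$summary),
                                make.row.names = FALSE)),
    per_frame = do.call(rbind, c(lapply(analyses, function(a) a$frames),
                                 make.row.names = FALSE)),
    analyses = analyses), class = "cohort_analysis")
}

#' Export an averaged autocorrelation profile as a long table
#'
#' @param ac An \code{ac_profile}.
#' @param condition Condition label attached to every row.
#' @return Data frame \code{lag_s}, \code{ac}, \code{condition}.
#' @export
ac_profile_table <- function(ac, condition = "all") {
  data.frame(lag_s = ac$lags_s, ac = ac$ac, condition = condition,
             stringsAsFactors = FALSE)
}

#' Write an analysis report
#'
#' Writes the per-cell metrics table as CSV and the cohort summary as
#' JSON into a directory. Numbers survive a read/write round trip
#' bit-identically for integers and to at least 12 significant digits
#' for reals.
#'
#' @param summary A \code{\link{summarize_cohort}} result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(summary, dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  metrics_path <- file.path(dir, "metrics.csv")
  summary_path <- file.path(dir, "summary.json")
  utils::write.csv(format_numeric_df(summary$per_cell), metrics_path,
                   row.names = FALSE, quote = FALSE)
  body <- list(conditions = summary$conditions,
               trajectory = summary$trajectory,
               tests = lapply(summary$tests, unclass),
               provenance = summary$provenance)
  jsonlite::write_json(body, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(metrics = metrics_path, summary = summary_path))
}

#' Read an analysis report back
#'
#' @param dir Directory written by \code{\link{write_report}}.
#' @return List with \code{per_cell} (data frame) and \code{summary}
#'   (parsed JSON list).
#' @export
read_report <- function(dir) {
  metrics_path <- file.path(dir, "metrics.csv")
  summary_path <- file.path(dir, "summary.json")
  if (!file.exists(metrics_path) || !file.exists(summary_path)) {
    stop("not a report directory: ", dir, call. = FALSE)
  }
  list(per_cell = utils::read.csv(metrics_path, stringsAsFactors = FALSE),
       summary = jsonlite::read_json(summary_path, simplifyVector = TRUE))
}
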