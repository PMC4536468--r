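#' Channel labels understood by the pipeline
#'
#' The five point channels a detection table may contain: \code{CENTRIOLE}
#' (centrin-marked centrioles), \code{KT_INNER} (inner-kinetochore marker,
#' e.g. CENPA), \code{KT_OUTER} (outer-kinetochore marker, e.g. HEC1),
#' \code{ATTACH_MARK} (attachment-maturity marker, e.g. SKAP) and
#' \code{CORTEX} (cell-boundary points from phase contrast).
#'
#' @return Character vector of valid channel names.
#' @export
detection_channels <- function() {
  c("CENTRIOLE", "KT_INNER", "KT_OUTER", "ATTACH_MARK", "CORTEX")
}

# Fixed column contract of a detection table.
DETECTION_COLUMNS <- c("cell_id", "frame", "time_s", "channel",
                       "x_um", "y_um", "z_um", "intensity")

#' Validate a detection table
#'
#' Checks a data frame against the detection-table contract: the eight
#' documented columns, finite micrometre coordinates, non-negative
#' intensities and frame indices, valid channel labels, and a strictly
#' increasing frame -> time mapping within each cell.
#'
#' @param det Data frame of detections.
#' @param channels Allowed channel set (defaults to all five).
#' @return The validated table, invisibly, with columns coerced to their
#'   documented types.
#' @export
validate_detections <- function(det, channels = detection_channels()) {
  stopifnot(is.data.frame(det))
  missing <- setdiff(DETECTION_COLUMNS, names(det))
  if (length(missing) > 0L) {
    stop("detection table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  det$cell_id <- as.character(det$cell_id)
  det$channel <- as.character(det$channel)
  for (col in c("frame", "time_s", "x_um", "y_um", "z_um", "intensity")) {
    v <- det[[col]]
    if (is.character(v) || is.factor(v)) {
      v2 <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s' at data row %d",
                     col, bad[1L]), call. = FALSE)
      }
      det[[col]] <- v2
    }
  }
  if (nrow(det) == 0L) return(invisible(det))
  pos <- as.matrix(det[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(pos))) {
    stop("non-finite coordinate at data row ",
         which(!apply(is.finite(pos), 1L, all))[1L], call. = FALSE)
  }
  if (any(det$frame < 0) || any(det$frame != round(det$frame))) {
    stop("'frame' must contain non-negative integers", call. = FALSE)
  }
  det$frame <- as.integer(det$frame)
  if (any(det$time_s < 0)) stop("'time_s' must be >= 0", call. = FALSE)
  if (any(det$intensity < 0)) stop("'intensity' must be >= 0", call. = FALSE)
  bad_ch <- setdiff(unique(det$channel), channels)
  if (length(bad_ch) > 0L) {
    stop("unknown channel label(s): ", paste(bad_ch, collapse = ", "),
         call. = FALSE)
  }
  # frame -> time_s must be a strictly increasing function within a cell
  for (cid in unique(det$cell_id)) {
    sub <- det[det$cell_id == cid, c("frame", "time_s")]
    map <- unique(sub[order(sub$frame), ])
    if (anyDuplicated(map$frame)) {
      stop("cell ", cid, ": a frame maps to more than one time_s",
           call. = FALSE)
    }
    if (is.unsorted(map$time_s, strictly = TRUE)) {
      stop("cell ", cid, ": time_s is not strictly increasing with frame",
           call. = FALSE)
    }
  }
  invisible(det)
}

#' Read a detection table from CSV
#'
#' The detection CSV schema is fixed: header
#' \code{cell_id,frame,time_s,channel,x_um,y_um,z_um,intensity},
#' comma-separated, '.' decimal. Coordinates are in micrometres with any
#' voxel anisotropy already applied upstream; frames are 0-based and
#' times in seconds.
#'
#' @param path Path to a CSV file.
#' @return A validated detection data frame (row order preserved).
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  det <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  missing <- setdiff(DETECTION_COLUMNS, names(det))
  if (length(missing) > 0L) {
    stop("detection file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  det <- det[, DETECTION_COLUMNS]
  validate_detections(det)
}

#' Write a detection table to CSV
#'
#' @param det Detection data frame (validated before writing).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_detections <- function(det, path) {
  det <- validate_detections(det)
  utils::write.csv(format_numeric_df(det), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Format numeric columns at full double precision for text round-trips.
format_numeric_df <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
    }
  }
  df
}

#' Read per-cell metadata
#'
#' Metadata CSV with columns \code{cell_id}, \code{config_label}
#' (\code{WT}, \code{C22}, \code{C21} or \code{C11}), \code{group_label},
#' and optionally \code{anaphase_frame} (0-based, blank if unknown).
#'
#' @param path Path to the metadata CSV.
#' @return Data frame with one row per cell.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "config_label", "group_label")
  missing <- setdiff(need, names(md))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  md$cell_id <- as.character(md$cell_id)
  bad <- setdiff(unique(md$config_label), c("WT", "C22", "C21", "C11"))
  if (length(bad) > 0L) {
    stop("unknown config_label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(md$cell_id)) stop("duplicated cell_id in metadata",
                                      call. = FALSE)
  if (!"anaphase_frame" %in% names(md)) md$anaphase_frame <- NA_integer_
  md$anaphase_frame <- suppressWarnings(as.integer(md$anaphase_frame))
  md
}

#' Construct a cell series
#'
#' A \code{cell_series} bundles the ordered frames of detections of one
#' cell with its metadata: centriole configuration label, treatment group,
#' nominal sampling interval and (optionally) an annotated anaphase frame.
#'
#' @param detections Detection data frame for a single cell.
#' @param config_label One of \code{WT}, \code{C22}, \code{C21},
#'   \code{C11} (2:2 / 2:1 / 1:1 centriole configurations).
#' @param group_label Free-text treatment group.
#' @param dt_s Nominal sampling interval in seconds; inferred as the
#'   median inter-frame interval when \code{NULL}.
#' @param anaphase_frame Optional annotated anaphase-onset frame (0-based).
#' @return An object of class \code{cell_series}.
#' @export
cell_series <- function(detections, config_label = "WT",
                        group_label = "none", dt_s = NULL,
                        anaphase_frame = NA_integer_) {
  detections <- validate_detections(detections)
  if (nrow(detections) == 0L) stop("a cell series needs >= 1 frame",
                                   call. = FALSE)
  cid <- unique(detections$cell_id)
  if (length(cid) != 1L) stop("detections span more than one cell_id",
                              call. = FALSE)
  config_label <- match.arg(config_label, c("WT", "C22", "C21", "C11"))
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  times <- vapply(frames, function(f) {
    detections$time_s[match(f, detections$frame)]
  }, numeric(1))
  if (is.null(dt_s)) {
    dt_s <- if (length(times) > 1L) stats::median(diff(times)) else 1
  }
  if (dt_s <= 0) stop("dt_s must be > 0", call. = FALSE)
  anaphase_frame <- as.integer(anaphase_frame)
  if (!is.na(anaphase_frame) && !(anaphase_frame %in% frames)) {
    stop("anaphase_frame does not index an existing frame", call. = FALSE)
  }
  structure(list(cell_id = cid, detections = detections, frames = frames,
                 times = times, dt_s = dt_s, config_label = config_label,
                 group_label = group_label, anaphase_frame = anaphase_frame),
            class = "cell_series")
}

#' @export
print.cell_series <- function(x, ...) {
  cat(sprintf("<cell_series> %s: %d frames, dt = %g s, config %s, group %s\n",
              x$cell_id, length(x$frames), x$dt_s, x$config_label,
              x$group_label))
  if (!is.na(x$anaphase_frame)) {
    cat(sprintf("  annotated anaphase frame: %d\n", x$anaphase_frame))
  }
  tab <- table(x$detections$channel)
  cat("  detections:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Assemble per-cell series from a detection table
#'
#' Splits a detection table by \code{cell_id} and attaches metadata. The
#' sampling interval of each cell is inferred as the median inter-frame
#' interval. Cells with zero kinetochore (\code{KT_INNER}) detections are
#' excluded with a warning.
#'
#' @param det Detection data frame.
#' @param metadata Metadata data frame (see \code{\link{read_metadata}});
#'   must cover every retained cell.
#' @return Named list of \code{\link{cell_series}} objects.
#' @export
assemble_cells <- function(det, metadata) {
  det <- validate_detections(det)
  out <- list()
  for (cid in unique(det$cell_id)) {
    sub <- det[det$cell_id == cid, , drop = FALSE]
    if (!any(sub$channel == "KT_INNER")) {
      warning("cell ", cid, " has no kinetochore detections; excluded",
              call. = FALSE)
      next
    }
    i <- match(cid, metadata$cell_id)
    if (is.na(i)) stop("no metadata for cell ", cid, call. = FALSE)
    out[[cid]] <- cell_series(
      sub,
      config_label = metadata$config_label[i],
      group_label = metadata$group_label[i],
      anaphase_frame = if ("anaphase_frame" %in% names(metadata))
        metadata$anaphase_frame[i] else NA_integer_)
  }
  out
}

# Detections of one frame (and optionally one channel) of a cell series.
frame_detections <- function(cell, frame, channel = NULL) {
  d <- cell$detections[cell$detections$frame == frame, , drop = FALSE]
  if (!is.null(channel)) d <- d[d$channel %in% channel, , drop = FALSE]
  d
}

# 3-column position matrix of a detection data frame.
det_pos <- function(det) {
  unname(as.matrix(det[, c("x_um", "y_um", "z_um"), drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
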