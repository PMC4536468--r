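#' Analysis configuration
#'
#' All tunables of the analysis pipeline with their defaults. Unknown
#' keys are rejected, so a configuration file round-trips exactly.
#'
#' @param max_step_um Track-linking gate (um).
#' @param max_gap_frames Track-linking gap tolerance (frames).
#' @param max_pair_um Sister-pairing gate (um), about twice the
#'   inter-kinetochore rest length.
#' @param max_lag_s Largest autocorrelation lag evaluated (s).
#' @param ac_min_depth Depth threshold for calling a first autocorrelation
#'   minimum (a minimum must lie below this value).
#' @param anaphase_fold Inter-kinetochore distance fold over baseline that
#'   marks anaphase onset.
#' @param anaphase_baseline_frames Number of initial frames defining the
#'   inter-kinetochore baseline.
#' @param anaphase_sustain_frames Consecutive frames the fold must hold.
#' @param rotation_threshold_deg Net XY-rotation angle above which a
#'   spindle is called rotating.
#' @param division_ratio_threshold Daughter size ratio above which a
#'   division is called asymmetric (strict).
#' @param skap_neg_rel_threshold A kinetochore is marker-negative when its
#'   attachment-marker intensity is below this fraction of the cell
#'   median.
#' @param skap_cell_frac_threshold A cell is marker-positive when more
#'   than this fraction of pairs is negative (strict).
#' @param minus_end_fold Pole-intensity fold above which minus-end levels
#'   are called asymmetric (analyst-set, not taken from data).
#' @param ratio_lo,ratio_hi Boundaries of the "centred" R band; fractions
#'   outside use strict inequalities.
#' @param metaphase_k Number of earliest frames averaged for the per-cell
#'   metaphase R.
#' @param n_boot Bootstrap draws for trajectory confidence bands.
#' @param seed Seed for the bootstrap and any other analysis randomness.
#' @return Object of class \code{analysis_config} (a named list).
#' @export
analysis_config <- function(max_step_um = 0.8,
                            max_gap_frames = 1L,
                            max_pair_um = 2.0,
                            max_lag_s = 150,
                            ac_min_depth = -0.1,
                            anaphase_fold = 1.5,
                            anaphase_baseline_frames = 3L,
                            anaphase_sustain_frames = 2L,
                            rotation_threshold_deg = 90,
                            division_ratio_threshold = 1.2,
                            skap_neg_rel_threshold = 0.3,
                            skap_cell_frac_threshold = 0.30,
                            minus_end_fold = 1.5,
                            ratio_lo = 0.85,
                            ratio_hi = 1.15,
                            metaphase_k = 3L,
                            n_boot = 1000L,
                            seed = 1L) {
  cfg <- list(max_step_um = max_step_um,
              max_gap_frames = as.integer(max_gap_frames),
              max_pair_um = max_pair_um,
              max_lag_s = max_lag_s,
              ac_min_depth = ac_min_depth,
              anaphase_fold = anaphase_fold,
              anaphase_baseline_frames = as.integer(anaphase_baseline_frames),
              anaphase_sustain_frames = as.integer(anaphase_sustain_frames),
              rotation_threshold_deg = rotation_threshold_deg,
              division_ratio_threshold = division_ratio_threshold,
              skap_neg_rel_threshold = skap_neg_rel_threshold,
              skap_cell_frac_threshold = skap_cell_frac_threshold,
              minus_end_fold = minus_end_fold,
              ratio_lo = ratio_lo,
              ratio_hi = ratio_hi,
              metaphase_k = as.integer(metaphase_k),
              n_boot = as.integer(n_boot),
              seed = as.integer(seed))
  stopifnot(cfg$max_step_um > 0, cfg$max_pair_um > 0, cfg$max_lag_s > 0,
            cfg$anaphase_fold > 1, cfg$ratio_lo < cfg$ratio_hi,
            cfg$metaphase_k >= 1L, cfg$n_boot >= 1L)
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML or JSON
#'
#' Keys not known to \code{\link{analysis_config}} raise an error; absent
#' keys take their defaults.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return An \code{analysis_config}.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, raw)
}

#' Write an analysis configuration
#'
#' @param cfg An \code{analysis_config}.
#' @param path Output path ending in \code{.yaml}/\code{.yml} or
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_analysis_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}
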