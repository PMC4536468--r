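#' Summary of a half-spindle ratio distribution
#'
#' Median (midpoint rule for even n), fraction of values strictly outside
#' the centred band [lo, hi], and fraction strictly above hi.
#'
#' @param r Numeric vector of per-cell R values.
#' @param lo,hi Band boundaries (strict inequalities).
#' @return List: \code{median}, \code{frac_outside}, \code{frac_above_hi},
#'   \code{n}.
#' @export
ratio_distribution_summary <- function(r, lo = 0.85, hi = 1.15) {
  r <- r[is.finite(r)]
  if (length(r) == 0L) stop("no finite R values", call. = FALSE)
  list(median = stats::median(r),
       frac_outside = mean(r < lo | r > hi),
       frac_above_hi = mean(r > hi),
       n = length(r))
}

#' Per-cell metaphase and anaphase R selection
#'
#' The per-cell metaphase R is the mean of R over the first \code{k}
#' available frames (fewer if the recording is shorter), ensuring the
#' value reflects early metaphase; the per-cell anaphase R is R at the
#' last frame before the (detected or annotated) anaphase onset.
#'
#' @param r Per-frame R values of one cell, ordered by frame.
#' @param frames Frame indices matching \code{r} (default
#'   \code{0, 1, ...}).
#' @param anaphase_frame Anaphase-onset frame (0-based) or \code{NA}.
#' @param k Number of earliest frames averaged for the metaphase value.
#' @return List: \code{metaphase_R} and \code{anaphase_R} (\code{NA} when
#'   no onset is known or no earlier frame exists).
#' @export
metaphase_R_selection <- function(r, frames = seq_along(r) - 1L,
                                  anaphase_frame = NA_integer_, k = 3L) {
  ok <- is.finite(r)
  if (!any(ok)) stop("no frame with a finite R", call. = FALSE)
  r_ok <- r[ok]
  f_ok <- frames[ok]
  meta <- mean(r_ok[seq_len(min(k, length(r_ok)))])
  ana <- NA_real_
  if (!is.na(anaphase_frame)) {
    before <- which(f_ok < anaphase_frame)
    if (length(before) > 0L) ana <- r_ok[max(before)]
  }
  list(metaphase_R = meta, anaphase_R = ana)
}

#' Anaphase-aligned median-R trajectories with bootstrap bands
#'
#' Aligns the per-frame R series of each cell to its anaphase onset
#' (t = 0), bins times on multiples of \code{dt_s}, and reports for each
#' bin with at least \code{min_cells} contributing cells the median R
#' across cells and a 95\% percentile bootstrap confidence band obtained
#' by resampling whole cells with replacement.
#'
#' @param cells List, one element per cell: a list or data frame with
#'   \code{time_s}, \code{R} and scalar \code{anaphase_time_s}.
#' @param dt_s Bin width (sampling interval).
#' @param n_boot Bootstrap draws.
#' @param seed Seed making the bands reproducible.
#' @param min_cells Minimum cells per retained bin.
#' @return Data frame: \code{time_to_anaphase_s}, \code{n_cells},
#'   \code{median_R}, \code{ci_lo}, \code{ci_hi}.
#' @export
anaphase_aligned_trajectories <- function(cells, dt_s, n_boot = 1000L,
                                          seed = 1L, min_cells = 3L) {
  cells <- Filter(function(cl) is.finite(cl$anaphase_time_s %||% NA), cells)
  if (length(cells) == 0L) stop("no cell with an anaphase onset",
                                call. = FALSE)
  aligned <- lapply(cells, function(cl) {
    bin <- round((cl$time_s - cl$anaphase_time_s) / dt_s) * dt_s
    ok <- is.finite(cl$R)
    stats::aggregate(list(R = cl$R[ok]), list(bin = bin[ok]), mean)
  })
  bins <- sort(unique(unlist(lapply(aligned, function(a) a$bin))))
  mat <- matrix(NA_real_, length(cells), length(bins))
  for (i in seq_along(aligned)) {
    mat[i, match(aligned[[i]]$bin, bins)] <- aligned[[i]]$R
  }
  n_per_bin <- colSums(!is.na(mat))
  keep <- n_per_bin >= min_cells
  mat <- mat[, keep, drop = FALSE]
  bins <- bins[keep]
  med <- apply(mat, 2L, stats::median, na.rm = TRUE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(bins))
  nc <- nrow(mat)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    boot[b, ] <- apply(mat[idx, , drop = FALSE], 2L, stats::median,
                       na.rm = TRUE)
  }
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  data.frame(time_to_anaphase_s = bins,
             n_cells = n_per_bin[keep],
             median_R = med,
             ci_lo = ci[1L, ],
             ci_hi = ci[2L, ])
}

# Construct a test_result record.
test_result <- function(name, statistic, p_value, n, alternative,
                        method = NULL) {
  structure(list(name = name, statistic = unname(statistic),
                 p_value = unname(p_value), n = n,
                 alternative = alternative, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (%s; n = %s)\n",
              x$name, x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = "/")))
  if (!is.null(x$method)) cat("  ", x$method, "\n")
  invisible(x)
}

#' Two-group comparisons of continuous measurements
#'
#' The battery used for cohort comparisons: Welch's unpaired t test
#' (\code{welch_t}), the Mann-Whitney U test (\code{mann_whitney_u};
#' exact when both groups have n <= 20 and no ties, otherwise the normal
#' approximation with tie correction), the Brown-Forsythe/Levene test of
#' equal variances (\code{levene}, median-centred) and the paired t test
#' (\code{paired_t}). All tests are two-sided and p values are reported
#' raw (no multiplicity correction).
#'
#' @param a,b Numeric samples (paired and equal length for
#'   \code{paired_t}).
#' @param test Test name.
#' @return A \code{test_result}.
#' @export
compare_groups <- function(a, b, test = c("welch_t", "mann_whitney_u",
                                          "levene", "paired_t")) {
  test <- match.arg(test)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need >= 2 observations per group", call. = FALSE)
  }
  n <- c(length(a), length(b))
  if (test == "welch_t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        return(test_result("welch_t", 0, 1, n, "two.sided",
                           "degenerate zero-variance samples with equal means"))
      }
      stop("zero variance in both groups with unequal means", call. = FALSE)
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    test_result("welch_t", ht$statistic, ht$p.value, n, "two.sided",
                sprintf("Welch df = %.2f", ht$parameter))
  } else if (test == "mann_whitney_u") {
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- all(n <= 20L) && !ties
    ht <- stats::wilcox.test(a, b, exact = exact, correct = FALSE)
    test_result("mann_whitney_u", ht$statistic, ht$p.value, n, "two.sided",
                if (exact) "exact U distribution"
                else "normal approximation with tie correction")
  } else if (test == "levene") {
    y <- c(a, b)
    g <- factor(rep(c("a", "b"), n))
    lt <- car::leveneTest(y, g, center = stats::median)
    test_result("levene", lt[1, "F value"], lt[1, "Pr(>F)"], n,
                "two.sided", "Brown-Forsythe (median-centred)")
  } else {
    if (length(a) != length(b)) stop("paired test needs equal n",
                                     call. = FALSE)
    d <- a - b
    if (stats::sd(d) == 0) stop("zero variance of paired differences",
                                call. = FALSE)
    ht <- stats::t.test(a, b, paired = TRUE)
    test_result("paired_t", ht$statistic, ht$p.value,
                c(length(a), length(a)), "two.sided",
                sprintf("df = %d", as.integer(ht$parameter)))
  }
}

#' Exact tests for count data
#'
#' \code{fisher_exact}: two-sided Fisher's exact test on a 2x2 table
#' (the p value sums the hypergeometric probabilities, at fixed margins,
#' of all tables no more probable than the observed one).
#' \code{exact_binomial}: two-sided exact binomial test of k successes in
#' n trials against p0 (the p value sums P(X = i) over all i with
#' P(X = i) <= P(X = k)).
#'
#' @param x For \code{fisher_exact}: a 2x2 matrix of non-negative
#'   counts. For \code{exact_binomial}: the success count k.
#' @param test Which test to run.
#' @param n,p0 Trials and null success probability
#'   (\code{exact_binomial} only).
#' @return A \code{test_result}.
#' @export
count_tests <- function(x, test = c("fisher_exact", "exact_binomial"),
                        n = NULL, p0 = 0.5) {
  test <- match.arg(test)
  if (test == "fisher_exact") {
    x <- as.matrix(x)
    stopifnot(all(dim(x) == 2L), all(x >= 0), all(x == round(x)))
    ht <- stats::fisher.test(x)
    test_result("fisher_exact", ht$estimate, ht$p.value,
                c(sum(x[, 1]), sum(x[, 2])), "two.sided",
                "conditional odds-ratio estimate as statistic")
  } else {
    stopifnot(length(x) == 1L, x >= 0, x == round(x), !is.null(n),
              n >= x, p0 > 0, p0 < 1)
    ht <- stats::binom.test(x, n, p0)
    test_result("exact_binomial", x, ht$p.value, n, "two.sided",
                sprintf("null p0 = %g", p0))
  }
}

#' Cohort summary
#'
#' Per-condition cohort statistics: cell counts, median metaphase R,
#' boundary fractions, phenotype rates, optional anaphase-aligned
#' trajectory and a list of test results. The thresholds and seed in
#' force are echoed for provenance.
#'
#' @param per_cell Data frame with one row per cell; must contain
#'   \code{cell_id}, \code{config_label} and \code{metaphase_R}, and may
#'   contain \code{anaphase_R}, \code{rotating}, \code{asymmetric_division},
#'   \code{skap_positive_cell}.
#' @param trajectory Optional trajectory data frame from
#'   \code{\link{anaphase_aligned_trajectories}}.
#' @param tests Optional named list of \code{test_result}s.
#' @param config The \code{\link{analysis_config}} in force.
#' @return Object of class \code{cohort_summary}.
#' @export
summarize_cohort <- function(per_cell, trajectory = NULL, tests = list(),
                             config = analysis_config()) {
  stopifnot(is.data.frame(per_cell),
            all(c("cell_id", "config_label", "metaphase_R") %in%
                  names(per_cell)))
  conditions <- list()
  for (lab in unique(per_cell$config_label)) {
    sub <- per_cell[per_cell$config_label == lab, , drop = FALSE]
    rs <- ratio_distribution_summary(sub$metaphase_R, config$ratio_lo,
                                     config$ratio_hi)
    cond <- list(n_cells = nrow(sub),
                 median_R = rs$median,
                 frac_outside = rs$frac_outside,
                 frac_above_hi = rs$frac_above_hi)
    if ("anaphase_R" %in% names(sub) && any(is.finite(sub$anaphase_R))) {
      cond$median_anaphase_R <- stats::median(sub$anaphase_R, na.rm = TRUE)
    }
    for (col in c("rotating", "asymmetric_division", "skap_positive_cell")) {
      if (col %in% names(sub) && any(!is.na(sub[[col]]))) {
        cond[[paste0("frac_", col)]] <- mean(sub[[col]], na.rm = TRUE)
      }
    }
    conditions[[lab]] <- cond
  }
  structure(list(conditions = conditions,
                 per_cell = per_cell,
                 trajectory = trajectory,
                 tests = tests,
                 provenance = list(
                   ratio_lo = config$ratio_lo, ratio_hi = config$ratio_hi,
                   metaphase_k = config$metaphase_k,
                   division_ratio_threshold = config$division_ratio_threshold,
                   rotation_threshold_deg = config$rotation_threshold_deg,
                   skap_cell_frac_threshold = config$skap_cell_frac_threshold,
                   minus_end_fold = config$minus_end_fold,
                   n_boot = config$n_boot, seed = config$seed,
                   p_values = "raw, two-sided, no multiplicity correction")),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  for (lab in names(x$conditions)) {
    cnd <- x$conditions[[lab]]
    cat(sprintf("  %-4s n = %3d  median R = %.3f  outside [%g, %g]: %.1f%%  above: %.1f%%\n",
                lab, cnd$n_cells, cnd$median_R, x$provenance$ratio_lo,
                x$provenance$ratio_hi, 100 * cnd$frac_outside,
                100 * cnd$frac_above_hi))
  }
  if (!is.null(x$trajectory)) {
    cat(sprintf("  trajectory: %d bins, %s to %s s\n",
                nrow(x$trajectory), min(x$trajectory$time_to_anaphase_s),
                max(x$trajectory$time_to_anaphase_s)))
  }
  for (nm in names(x$tests)) {
    tr <- x$tests[[nm]]
    cat(sprintf("  test %s [%s]: p = %.4g\n", nm, tr$name, tr$p_value))
  }
  invisible(x)
}
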