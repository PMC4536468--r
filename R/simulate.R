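#' Simulation configuration
#'
#' Parameters of the synthetic spindle generator. Defaults emulate a
#' metaphase HeLa spindle as seen in live 3D imaging: two poles about
#' 10 um apart, ~23 tracked sister-kinetochore pairs congressed on a
#' plate, quasi-periodic sister oscillations along the spindle axis,
#' isotropic localisation noise, and optional spindle rotation, plate
#' centering relaxation and anaphase onset. The default short regime is
#' a 5-min video sampled every 7.5 s; pass \code{duration_s = 900,
#' dt_s = 30} for the long regime.
#'
#' @param n_cells Number of cells in a cohort.
#' @param config_label Centriole configuration: \code{WT}, \code{C22}
#'   (2:2), \code{C21} (2:1) or \code{C11} (1:1).
#' @param pole_distance_um Pole-to-pole distance (um).
#' @param n_pairs Number of sister-kinetochore pairs.
#' @param plate_offset_ratio_true Target half-spindle ratio R at t = 0.
#'   A single number (all cells identical), a vector of per-cell values,
#'   or \code{list(median =, sd_log =)} for a log-normal across cells.
#' @param osc_amplitude_um Sister oscillation amplitude along the axis.
#' @param osc_period_s Sister oscillation period.
#' @param noise_sigma_um Isotropic Gaussian localisation noise s.d.
#' @param rotation_deg_per_min Rigid rotation rate of the spindle axis in
#'   the XY plane.
#' @param centering_tau_s Optional exponential relaxation time constant of
#'   the plate offset towards the spindle centre (\code{NULL}: static).
#' @param anaphase_at_s Optional anaphase onset time; sister separation
#'   ramps up linearly thereafter (doubling after
#'   \code{anaphase_double_s}).
#' @param anaphase_double_s Time for the sister separation to double after
#'   anaphase onset.
#' @param duration_s Video duration.
#' @param dt_s Sampling interval; must divide \code{duration_s}.
#' @param seed Master seed; fixes the full output.
#' @param inter_kt_rest_um Sister rest separation (inner marker to inner
#'   marker).
#' @param plate_radius_um Radius of the disc on which pair centres lie.
#' @param plate_min_spacing_um Minimum lateral spacing between pair
#'   centres.
#' @param cell_radius_um Cell radius (sets the cortex points).
#' @param cell_center_offset_um Offset of the cell centre from the spindle
#'   centre along the initial axis.
#' @param daughter_size_ratio True daughter-cell size ratio (max/min);
#'   single number or per-cell vector.
#' @param delta_true_um True intra-kinetochore offset (inner to outer
#'   marker) used by fixed snapshots.
#' @param skap_negative_fraction Fraction of pairs that are
#'   attachment-marker negative in fixed snapshots.
#' @param intensity_scale Base fluorescence intensity (a.u.).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_cells = 1L,
                       config_label = "WT",
                       pole_distance_um = 10,
                       n_pairs = 23L,
                       plate_offset_ratio_true = 1.0,
                       osc_amplitude_um = 0.3,
                       osc_period_s = 80,
                       noise_sigma_um = 0.05,
                       rotation_deg_per_min = 0,
                       centering_tau_s = NULL,
                       anaphase_at_s = NULL,
                       anaphase_double_s = 15,
                       duration_s = 300,
                       dt_s = 7.5,
                       seed = 1L,
                       inter_kt_rest_um = 1.0,
                       plate_radius_um = 5,
                       plate_min_spacing_um = 1.5,
                       cell_radius_um = 9,
                       cell_center_offset_um = 0,
                       daughter_size_ratio = 1.0,
                       delta_true_um = 0.110,
                       skap_negative_fraction = 0,
                       intensity_scale = 100) {
  config_label <- match.arg(config_label, c("WT", "C22", "C21", "C11"))
  cfg <- as.list(environment())
  stopifnot(cfg$n_cells >= 1L, cfg$pole_distance_um > 0, cfg$n_pairs >= 1L,
            cfg$osc_period_s > 0, cfg$noise_sigma_um >= 0,
            cfg$duration_s > 0, cfg$dt_s > 0, cfg$inter_kt_rest_um > 0,
            cfg$plate_radius_um > 0, cfg$cell_radius_um > 0,
            cfg$anaphase_double_s > 0, cfg$intensity_scale > 0,
            cfg$skap_negative_fraction >= 0, cfg$skap_negative_fraction <= 1,
            cfg$delta_true_um >= 0, all(cfg$daughter_size_ratio >= 1))
  if (abs(cfg$duration_s / cfg$dt_s - round(cfg$duration_s / cfg$dt_s)) >
      1e-9) {
    stop("dt_s must divide duration_s", call. = FALSE)
  }
  if (!is.null(cfg$centering_tau_s)) stopifnot(cfg$centering_tau_s > 0)
  if (!is.null(cfg$anaphase_at_s)) {
    stopifnot(cfg$anaphase_at_s >= 0, cfg$anaphase_at_s <= cfg$duration_s)
  }
  if (cfg$cell_radius_um <= cfg$pole_distance_um / 2) {
    stop("cell_radius_um must exceed half the pole distance", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d %s cell(s), %g um poles, %d pairs, %g-%g s @ %g s\n",
    x$n_cells, x$config_label, x$pole_distance_um, x$n_pairs, 0,
    x$duration_s, x$dt_s))
  invisible(x)
}

# Derive a per-cell seed below 2^31 from the master seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                as.double(index) * 104729) %% 2147483563) + 1L
}

# Per-cell target R at t = 0 under the configured specification.
draw_r_true <- function(spec, index) {
  if (is.list(spec)) {
    stopifnot(!is.null(spec$median))
    sd_log <- spec$sd_log %||% 0
    spec$median * exp(stats::rnorm(1L, 0, sd_log))
  } else if (length(spec) > 1L) {
    spec[[((index - 1L) %% length(spec)) + 1L]]
  } else {
    spec
  }
}

# Lateral pair-centre positions on the plate disc with a minimum spacing
# (random sequential adsorption).
sample_plate_positions <- function(n, radius, min_spacing, max_tries = 5000L) {
  a <- numeric(n)
  b <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " pairs with spacing ", min_spacing,
           " um on a ", radius, " um plate", call. = FALSE)
    }
    r <- radius * sqrt(stats::runif(1L))
    th <- stats::runif(1L, 0, 2 * pi)
    ca <- r * cos(th)
    cb <- r * sin(th)
    if (placed == 0L ||
        all(sqrt((a[seq_len(placed)] - ca)^2 +
                   (b[seq_len(placed)] - cb)^2) >= min_spacing)) {
      placed <- placed + 1L
      a[placed] <- ca
      b[placed] <- cb
    }
  }
  cbind(a = a, b = b)
}

# Centriole complement per configuration: intensities in units of
# intensity_scale, strictly decreasing grandmother > mother > daughters
# (4:3:2:2). Pole 1 always carries the grandmother; in 2:1 cells the
# 2-centriole pole retains the grandmother and its daughter.
centriole_layout <- function(config_label) {
  switch(config_label,
         WT = ,
         C22 = list(pole1 = c(4, 2), pole2 = c(3, 2)),
         C21 = list(pole1 = c(4, 2), pole2 = 3),
         C11 = list(pole1 = 4, pole2 = 3))
}

#' Simulate one cell
#'
#' Generates the detection series of a single synthetic spindle together
#' with its full ground truth. The spindle centre sits at the origin;
#' the axis starts at a random orientation in the XY plane and rotates at
#' the configured rate. Pole 1 (carrying the grandmother centriole, and
#' in 2:1 cells the 2-centriole complement) defines the reference side.
#' The plate plane is orthogonal to the axis and intersects it so that
#' L1/L2 = R_true, relaxing exponentially towards 1 when
#' \code{centering_tau_s} is set. Output is deterministic given
#' \code{(seed, index)}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param index Cell index within the cohort (1-based).
#' @return List with elements \code{cell} (a \code{\link{cell_series}})
#'   and \code{truth} (per-frame ground-truth parameters).
#' @export
simulate_cell <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(cfg$seed, index))

  D <- cfg$pole_distance_um
  times <- seq(0, cfg$duration_s, by = cfg$dt_s)
  nf <- length(times)
  r0 <- draw_r_true(cfg$plate_offset_ratio_true, index)
  stopifnot(r0 > 0)
  theta0 <- stats::runif(1L, 0, 2 * pi)
  omega <- cfg$rotation_deg_per_min / 60 * pi / 180   # rad/s
  x0 <- D * (1 - r0) / (2 * (1 + r0))                 # axial plate offset
  x_plate <- if (is.null(cfg$centering_tau_s)) {
    rep(x0, nf)
  } else {
    x0 * exp(-times / cfg$centering_tau_s)
  }
  r_true <- (D / 2 - x_plate) / (D / 2 + x_plate)
  lat <- sample_plate_positions(cfg$n_pairs, cfg$plate_radius_um,
                                cfg$plate_min_spacing_um)
  phases <- stats::runif(cfg$n_pairs, 0, 2 * pi)
  sep <- rep(cfg$inter_kt_rest_um, nf)
  ana_frame <- NA_integer_
  if (!is.null(cfg$anaphase_at_s)) {
    ana_frame <- which(times >= cfg$anaphase_at_s)[1L] - 1L
    after <- times >= cfg$anaphase_at_s
    sep[after] <- cfg$inter_kt_rest_um *
      (1 + (times[after] - cfg$anaphase_at_s) / cfg$anaphase_double_s)
  }
  layout <- centriole_layout(cfg$config_label)
  ratio <- if (length(cfg$daughter_size_ratio) > 1L) {
    cfg$daughter_size_ratio[[((index - 1L) %% length(cfg$daughter_size_ratio)) + 1L]]
  } else cfg$daughter_size_ratio
  cell_id <- sprintf("cell_%03d", index)
  c0 <- cfg$cell_center_offset_um * c(cos(theta0), sin(theta0), 0)

  rows <- vector("list", nf)
  pole1 <- matrix(NA_real_, nf, 3)
  pole2 <- matrix(NA_real_, nf, 3)
  for (i in seq_len(nf)) {
    t <- times[i]
    th <- theta0 + omega * t
    u <- c(cos(th), sin(th), 0)
    v1 <- c(-sin(th), cos(th), 0)
    v2 <- c(0, 0, 1)
    p1 <- D / 2 * u
    p2 <- -D / 2 * u
    pole1[i, ] <- p1
    pole2[i, ] <- p2
    # centrioles: fixed sub-diffraction offsets within each pole
    cen <- list()
    for (side in 1:2) {
      lv <- layout[[side]]
      pc <- if (side == 1) p1 else p2
      offs <- if (length(lv) == 2L) list(0.2 * v2, -0.2 * v2) else list(0 * v2)
      for (j in seq_along(lv)) {
        cen[[length(cen) + 1L]] <- c(pc + offs[[j]],
                                     lv[j] * cfg$intensity_scale)
      }
    }
    cen <- do.call(rbind, cen)
    # sister kinetochores
    xp <- x_plate[i] + cfg$osc_amplitude_um *
      sin(2 * pi * t / cfg$osc_period_s + phases)
    centre <- cbind(xp * u[1] + lat[, 1] * v1[1] + lat[, 2] * v2[1],
                    xp * u[2] + lat[, 1] * v1[2] + lat[, 2] * v2[2],
                    xp * u[3] + lat[, 1] * v1[3] + lat[, 2] * v2[3])
    s1 <- centre + sep[i] / 2 * matrix(u, cfg$n_pairs, 3, byrow = TRUE)
    s2 <- centre - sep[i] / 2 * matrix(u, cfg$n_pairs, 3, byrow = TRUE)
    kt <- rbind(s1, s2)
    # cortex: intersections of the current axis with the cell sphere
    uc <- sum(u * c0)
    disc <- uc^2 - (sum(c0^2) - cfg$cell_radius_um^2)
    tc <- uc + c(1, -1) * sqrt(disc)
    cortex <- rbind(tc[1] * u, tc[2] * u)
    pos <- rbind(cen[, 1:3, drop = FALSE], kt, cortex)
    rows[[i]] <- data.frame(
      cell_id = cell_id,
      frame = i - 1L,
      time_s = t,
      channel = c(rep("CENTRIOLE", nrow(cen)),
                  rep("KT_INNER", nrow(kt)),
                  rep("CORTEX", 2L)),
      x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
      intensity = c(cen[, 4], rep(cfg$intensity_scale, nrow(kt)),
                    rep(cfg$intensity_scale / 10, 2L)),
      stringsAsFactors = FALSE)
  }
  det <- do.call(rbind, rows)
  if (cfg$noise_sigma_um > 0) {
    det$x_um <- det$x_um + stats::rnorm(nrow(det), 0, cfg$noise_sigma_um)
    det$y_um <- det$y_um + stats::rnorm(nrow(det), 0, cfg$noise_sigma_um)
    det$z_um <- det$z_um + stats::rnorm(nrow(det), 0, cfg$noise_sigma_um)
  }
  cell <- cell_series(det, config_label = cfg$config_label,
                      group_label = "simulated", dt_s = cfg$dt_s,
                      anaphase_frame = ana_frame)
  truth <- list(cell_id = cell_id,
                config_label = cfg$config_label,
                times = times,
                r_true = r_true,
                x_plate = x_plate,
                theta_deg = (theta0 + omega * times) * 180 / pi,
                rotation_net_deg = abs(omega) * times * 180 / pi,
                pole1 = pole1, pole2 = pole2,
                pair_lateral = lat, phases = phases,
                sep_um = sep,
                inter_kt_rest_um = cfg$inter_kt_rest_um,
                anaphase_frame = ana_frame,
                daughter_sizes = c(100 * ratio, 100),
                daughter_size_ratio = ratio,
                spindle_center_offset_um = abs(sum(
                  c(cos(theta0), sin(theta0), 0) * c0)))
  list(cell = cell, truth = truth)
}

#' Simulate a cohort of cells
#'
#' Independent cells with per-cell seeds derived from the master seed.
#'
#' @param cfg A \code{\link{sim_config}} with \code{n_cells} cells.
#' @return List with \code{cells} (named list of \code{cell_series}) and
#'   \code{truths} (named list of ground-truth records).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- list()
  truths <- list()
  for (i in seq_len(cfg$n_cells)) {
    sim <- simulate_cell(cfg, i)
    cells[[sim$cell$cell_id]] <- sim$cell
    truths[[sim$cell$cell_id]] <- sim$truth
  }
  list(cells = cells, truths = truths)
}

#' Simulate a fixed-cell snapshot
#'
#' One-frame series emulating a fixed, antibody-stained cell: inner
#' kinetochores plus an outer-kinetochore channel displaced outward by
#' \code{delta_true_um} along the sister axis, and an attachment-marker
#' channel with bimodal (positive/negative) intensities according to the
#' ground-truth pair labels. Centrioles and cortex points are included so
#' the geometry stage runs unchanged.
#'
#' @param cfg A \code{\link{sim_config}}; \code{delta_true_um} and
#'   \code{skap_negative_fraction} control the snapshot-specific truth.
#' @param index Cell index (sets the per-cell seed).
#' @return List with \code{cell} (one-frame \code{cell_series}) and
#'   \code{truth} (includes \code{delta_true_um} and per-pair
#'   \code{negative_pairs} labels).
#' @export
simulate_fixed_snapshot <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  base <- sim_config_modify(cfg, duration_s = cfg$dt_s * 1, dt_s = cfg$dt_s,
                            osc_amplitude_um = cfg$osc_amplitude_um,
                            anaphase_at_s = NULL, noise_sigma_um = 0,
                            rotation_deg_per_min = 0)
  sim <- simulate_cell(base, index)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(cfg$seed, index) + 7L)
  det <- sim$cell$detections
  det <- det[det$frame == 0L, , drop = FALSE]
  kt <- det[det$channel == "KT_INNER", , drop = FALSE]
  n <- nrow(kt) / 2L
  # rows 1..n are the +u sisters, n+1..2n the -u sisters (generator order)
  u_th <- sim$truth$theta_deg[1] * pi / 180
  u <- c(cos(u_th), sin(u_th), 0)
  outer_kt <- kt
  sgn <- rep(c(1, -1), each = n)
  outer_kt$x_um <- outer_kt$x_um + sgn * cfg$delta_true_um * u[1]
  outer_kt$y_um <- outer_kt$y_um + sgn * cfg$delta_true_um * u[2]
  outer_kt$z_um <- outer_kt$z_um + sgn * cfg$delta_true_um * u[3]
  outer_kt$channel <- "KT_OUTER"
  n_neg <- round(cfg$skap_negative_fraction * n)
  neg_pairs <- sort(sample.int(n, n_neg))
  mark <- kt
  mark$channel <- "ATTACH_MARK"
  pos_level <- 10 * cfg$intensity_scale
  neg_level <- cfg$intensity_scale
  lvl <- matrix(pos_level, n, 2)
  for (p in neg_pairs) {
    both <- stats::runif(1L) < 0.5
    lvl[p, ] <- if (both) c(neg_level, neg_level) else
      sample(c(neg_level, pos_level))
  }
  mark$intensity <- c(lvl[, 1], lvl[, 2]) * stats::runif(2L * n, 0.9, 1.1)
  out <- rbind(det, outer_kt, mark)
  if (cfg$noise_sigma_um > 0) {
    jitter_rows <- out$channel %in% c("KT_INNER", "KT_OUTER", "CENTRIOLE")
    k <- sum(jitter_rows)
    out$x_um[jitter_rows] <- out$x_um[jitter_rows] +
      stats::rnorm(k, 0, cfg$noise_sigma_um)
    out$y_um[jitter_rows] <- out$y_um[jitter_rows] +
      stats::rnorm(k, 0, cfg$noise_sigma_um)
    out$z_um[jitter_rows] <- out$z_um[jitter_rows] +
      stats::rnorm(k, 0, cfg$noise_sigma_um)
  }
  cell <- cell_series(out, config_label = cfg$config_label,
                      group_label = "simulated_fixed", dt_s = cfg$dt_s)
  truth <- sim$truth
  truth$delta_true_um <- cfg$delta_true_um
  truth$negative_pairs <- neg_pairs
  truth$n_pairs <- n
  list(cell = cell, truth = truth)
}

# Copy a sim_config with some fields replaced (revalidates).
sim_config_modify <- function(cfg, ...) {
  args <- utils::modifyList(unclass(cfg), list(...), keep.null = TRUE)
  keep <- names(formals(sim_config))
  do.call(sim_config, args[intersect(names(args), keep)])
}

#' Flatten ground truth to a per-frame table
#'
#' @param truths List of ground-truth records from
#'   \code{\link{simulate_cohort}} (or a single record).
#' @return Data frame with one row per cell and frame: true R, plate
#'   offset, axis angle, sister separation, anaphase frame and daughter
#'   size ratio.
#' @export
truth_table <- function(truths) {
  if (!is.null(truths$cell_id)) truths <- list(truths)
  do.call(rbind, lapply(truths, function(tr) {
    data.frame(cell_id = tr$cell_id,
               frame = seq_along(tr$times) - 1L,
               time_s = tr$times,
               r_true = tr$r_true,
               x_plate_um = tr$x_plate,
               theta_deg = tr$theta_deg,
               sep_um = tr$sep_um,
               anaphase_frame = tr$anaphase_frame,
               daughter_size_ratio = tr$daughter_size_ratio,
               stringsAsFactors = FALSE)
  }))
}
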