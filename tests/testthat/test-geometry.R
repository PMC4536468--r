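make_centrioles <- function(pos, intensity = rep(100, nrow(pos))) {
  data.frame(cell_id = "c", frame = 0L, time_s = 0, channel = "CENTRIOLE",
             x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("pole clustering recovers tight pairs, 2:1 splits and 1:1 splits", {
  # two tight pairs 10 um apart
  pos <- rbind(c(-5, 0.1, 0), c(-5, -0.1, 0), c(5, 0, 0.1), c(5, 0, -0.1))
  poles <- cluster_poles(make_centrioles(pos))
  cents <- sort(vapply(poles, function(p) p$centroid[1], numeric(1)))
  expect_equal(cents, c(-5, 5), tolerance = 1e-12)
  expect_equal(vapply(poles, function(p) p$n_centrioles, integer(1)),
               c(2L, 2L))

  # pair + singleton: 2:1 split, checked against an exhaustive oracle
  pos3 <- rbind(c(5, 0.2, 0), c(5, -0.2, 0), c(-5, 0, 0))
  oracle_best <- function(pos) {
    dm <- as.matrix(dist(pos))
    n <- nrow(pos)
    best <- NULL
    best_cost <- Inf
    for (mask in 1:(2^n - 2)) {
      g1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      g2 <- setdiff(seq_len(n), g1)
      cost <- sum(dm[g1, g1]) / 2 + sum(dm[g2, g2]) / 2
      if (cost < best_cost) {
        best_cost <- cost
        best <- sort(vapply(list(g1, g2), length, integer(1)))
      }
    }
    best
  }
  poles3 <- cluster_poles(make_centrioles(pos3))
  expect_equal(sort(vapply(poles3, function(p) p$n_centrioles, integer(1))),
               oracle_best(pos3))
  expect_equal(poles3[[1]]$n_centrioles, 2L)   # bigger pole first
  expect_equal(poles3[[1]]$centroid, c(5, 0, 0), tolerance = 1e-12)

  # two points: 1:1
  poles2 <- cluster_poles(make_centrioles(rbind(c(-5, 0, 0), c(5, 0, 0))))
  expect_equal(vapply(poles2, function(p) p$n_centrioles, integer(1)),
               c(1L, 1L))
  expect_error(cluster_poles(make_centrioles(matrix(0, 1, 3))),
               "at least 2")
})

test_that("reference pole follows the 2:1 override and brightness otherwise", {
  pos <- rbind(c(5, 0.2, 0), c(5, -0.2, 0), c(-5, 0, 0))
  # 2-centriole pole dimmer overall per centriole: C21 still picks it
  poles <- cluster_poles(make_centrioles(pos, intensity = c(200, 200, 400)))
  two_pole <- which(vapply(poles, function(p) p$n_centrioles, integer(1)) == 2L)
  expect_equal(assign_reference_pole(poles, "C21"), two_pole)
  # brightness rules in C22/C11
  pos4 <- rbind(c(-5, 0.1, 0), c(-5, -0.1, 0), c(5, 0.1, 0), c(5, -0.1, 0))
  poles4 <- cluster_poles(make_centrioles(pos4, intensity = c(400, 200, 300, 200)))
  ref <- assign_reference_pole(poles4, "C22")
  expect_equal(poles4[[ref]]$centroid[1], -5, tolerance = 1e-12)
  poles1 <- cluster_poles(make_centrioles(rbind(c(-5, 0, 0), c(5, 0, 0)),
                                          intensity = c(300, 400)))
  ref1 <- assign_reference_pole(poles1, "C11")
  expect_equal(poles1[[ref1]]$centroid[1], 5, tolerance = 1e-12)
  # exact intensity tie is an error
  polest <- cluster_poles(make_centrioles(rbind(c(-5, 0, 0), c(5, 0, 0)),
                                          intensity = c(400, 400)))
  expect_error(assign_reference_pole(polest, "WT"), "tie")
})

test_that("plate plane fit is exact on coplanar points and optimal on noise", {
  pts <- rbind(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  pl <- fit_plate_plane(pts)
  expect_equal(abs(pl$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(pl$offset, 0, tolerance = 1e-12)

  # points on x + y = 1 recovered exactly
  set.seed(7)
  s <- stats::rnorm(100)
  t <- stats::rnorm(100)
  pts2 <- cbind(0.5 + s / sqrt(2), 0.5 - s / sqrt(2), t)
  pl2 <- fit_plate_plane(pts2)
  n2 <- pl2$normal * sign(pl2$normal[1])
  expect_equal(n2, c(1, 1, 0) / sqrt(2), tolerance = 1e-9)
  expect_equal(abs(pl2$offset), 1 / sqrt(2), tolerance = 1e-9)
  expect_lt(pl2$rss, 1e-18)

  # noisy cloud: no random plane does better (random-search oracle)
  set.seed(8)
  pts3 <- cbind(stats::rnorm(60, 0, 0.1), stats::rnorm(60, 0, 2),
                stats::rnorm(60, 0, 2))
  pl3 <- fit_plate_plane(pts3)
  cand <- matrix(stats::rnorm(3 * 10000), ncol = 3)
  cand <- cand / sqrt(rowSums(cand^2))
  best_random <- min(vapply(seq_len(nrow(cand)), function(i) {
    n <- cand[i, ]
    d <- sum(n * colMeans(pts3))   # best offset for a given normal
    sum((pts3 %*% n - d)^2)
  }, numeric(1)))
  expect_gte(best_random, pl3$rss - 1e-12)
  expect_error(fit_plate_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("plate metrics match hand geometry and flag off-segment cuts", {
  mk_poles <- function(p1, p2) {
    list(structure(list(centroid = p1, n_centrioles = 2L), class = "pole"),
         structure(list(centroid = p2, n_centrioles = 2L), class = "pole"))
  }
  poles <- mk_poles(c(5, 0, 0), c(-5, 0, 0))
  plane05 <- structure(list(normal = c(1, 0, 0), offset = 0.5,
                            centroid = c(0.5, 0, 0), rss = 0),
                       class = "plate_plane")
  g <- plate_metrics(plane05, poles, 1L)
  expect_equal(g$L1, 4.5)
  expect_equal(g$L2, 5.5)
  expect_equal(g$R, 4.5 / 5.5, tolerance = 1e-12)
  expect_false(g$outside_segment)

  plane0 <- structure(list(normal = c(1, 0, 0), offset = 0,
                           centroid = c(0, 0, 0), rss = 0),
                      class = "plate_plane")
  expect_equal(plate_metrics(plane0, poles, 1L)$R, 1.0)

  # oblique plane x + y = 1
  planexy <- structure(list(normal = c(1, 1, 0) / sqrt(2),
                            offset = 1 / sqrt(2),
                            centroid = c(0.5, 0.5, 0), rss = 0),
                       class = "plate_plane")
  g2 <- plate_metrics(planexy, poles, 1L)
  expect_equal(g2$intersection, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(g2$L1, 4)
  expect_equal(g2$L2, 6)
  expect_equal(g2$R, 2 / 3, tolerance = 1e-12)

  # off-segment intersection is flagged but still reported
  planeoff <- structure(list(normal = c(1, 0, 0), offset = 7,
                             centroid = c(7, 0, 0), rss = 0),
                        class = "plate_plane")
  g3 <- plate_metrics(planeoff, poles, 1L)
  expect_true(g3$outside_segment)
  expect_equal(g3$R, 2 / 12, tolerance = 1e-12)

  # parallel axis is a geometry error
  planez <- structure(list(normal = c(0, 0, 1), offset = 0,
                           centroid = c(0, 0, 0), rss = 0),
                      class = "plate_plane")
  expect_error(plate_metrics(planez, poles, 1L), "parallel")
})

test_that("plate metrics agree with a brute-force line-plane oracle and are
           invariant to rigid motions and reference swap", {
  set.seed(11)
  for (i in 1:200) {
    p1 <- stats::rnorm(3, c(5, 0, 0), 1)
    p2 <- stats::rnorm(3, c(-5, 0, 0), 1)
    n <- stats::rnorm(3)
    n <- n / sqrt(sum(n^2))
    u <- (p1 - p2) / sqrt(sum((p1 - p2)^2))
    if (abs(sum(n * u)) < 1e-3) next
    d <- sum(n * ((p1 + p2) / 2 + stats::rnorm(3, 0, 0.5)))
    plane <- structure(list(normal = n, offset = d, centroid = d * n,
                            rss = 0), class = "plate_plane")
    poles <- list(structure(list(centroid = p1), class = "pole"),
                  structure(list(centroid = p2), class = "pole"))
    g <- plate_metrics(plane, poles, 1L)
    # independent oracle: scan the segment parametrically for the root of
    # the signed plane distance
    f <- function(t) sum(n * (p2 + t * u)) - d
    t_star <- stats::uniroot(f, c(-100, 100), tol = 1e-14)$root
    inter <- p2 + t_star * u
    expect_equal(g$intersection, inter, tolerance = 1e-9)
    expect_equal(g$L1, sqrt(sum((inter - p1)^2)), tolerance = 1e-9)
    expect_equal(g$L2, sqrt(sum((inter - p2)^2)), tolerance = 1e-9)
    # reference swap inverts R
    g_swap <- plate_metrics(plane, poles, 2L)
    expect_equal(g_swap$R, 1 / g$R, tolerance = 1e-9)
    # rigid motion leaves L1, L2, R unchanged
    rot <- random_rotation()
    shift <- stats::rnorm(3, 0, 10)
    tf <- function(p) as.numeric(rot %*% p + shift)
    n_t <- as.numeric(rot %*% n)
    plane_t <- structure(list(normal = n_t,
                              offset = sum(n_t * tf(d * n)),
                              centroid = tf(d * n), rss = 0),
                         class = "plate_plane")
    poles_t <- list(structure(list(centroid = tf(p1)), class = "pole"),
                    structure(list(centroid = tf(p2)), class = "pole"))
    g_t <- plate_metrics(plane_t, poles_t, 1L)
    expect_equal(g_t$L1, g$L1, tolerance = 1e-9)
    expect_equal(g_t$L2, g$L2, tolerance = 1e-9)
    expect_equal(g_t$R, g$R, tolerance = 1e-9)
  }
})

test_that("spindle-centre offset matches explicit projections", {
  poles <- list(structure(list(centroid = c(5, 0, 0)), class = "pole"),
                structure(list(centroid = c(-5, 0, 0)), class = "pole"))
  expect_equal(spindle_center_offset(poles, rbind(c(-7, 0, 0), c(9, 0, 0))),
               1.0, tolerance = 1e-12)
  expect_equal(spindle_center_offset(poles, rbind(c(-8, 0, 0), c(8, 0, 0))),
               0, tolerance = 1e-12)
  expect_error(spindle_center_offset(poles, rbind(c(7, 0, 0), c(9, 0, 0))),
               "one side")

  # tilted axis, off-axis cortex points: compare to an independent
  # reimplementation with explicit projections
  set.seed(12)
  for (i in 1:20) {
    p1 <- stats::rnorm(3, c(4, 3, 1), 0.5)
    p2 <- stats::rnorm(3, c(-4, -3, -1), 0.5)
    ctr <- (p1 + p2) / 2
    u <- (p1 - p2) / sqrt(sum((p1 - p2)^2))
    cortex <- rbind(ctr + 8 * u + stats::rnorm(3, 0, 0.5),
                    ctr - 7 * u + stats::rnorm(3, 0, 0.5),
                    ctr + 10 * u + stats::rnorm(3, 0, 0.5))
    poles_i <- list(structure(list(centroid = p1), class = "pole"),
                    structure(list(centroid = p2), class = "pole"))
    got <- spindle_center_offset(poles_i, cortex)
    proj <- apply(cortex, 1, function(p) sum(u * (p - ctr)))
    d3 <- apply(cortex, 1, function(p) sqrt(sum((p - ctr)^2)))
    tp <- proj[proj > 0][which.min(d3[proj > 0])]
    tn <- proj[proj < 0][which.min(d3[proj < 0])]
    expect_equal(got, abs((tp + tn) / 2), tolerance = 1e-9)
  }
})

test_that("monopole kinetochore distances use the nearest centriole", {
  set.seed(13)
  dirs <- matrix(stats::rnorm(30), 10, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_equal(monopole_kt_distances(2 * dirs, matrix(0, 1, 3)),
               rep(2, 10), tolerance = 1e-12)
  cen <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(monopole_kt_distances(matrix(c(9, 0, 0), 1), cen), 1)
  # a 0.5-um shell shrink moves the mean by exactly 0.5
  expect_equal(mean(monopole_kt_distances(1.5 * dirs, matrix(0, 1, 3))) -
                 mean(monopole_kt_distances(2 * dirs, matrix(0, 1, 3))),
               -0.5, tolerance = 1e-12)
})

test_that("pole intensity asymmetry is normalised, signed and antisymmetric", {
  expect_equal(pole_intensity_asymmetry(100, 100), 0)
  expect_equal(pole_intensity_asymmetry(150, 50), 0.5)
  set.seed(14)
  i1 <- stats::runif(50, 0, 1000)
  i2 <- stats::runif(50, 0, 1000)
  expect_equal(pole_intensity_asymmetry(i1, i2),
               -pole_intensity_asymmetry(i2, i1), tolerance = 1e-12)
  expect_true(all(abs(pole_intensity_asymmetry(i1, i2)) <= 1))
  expect_error(pole_intensity_asymmetry(0, 0), "undefined")
})
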