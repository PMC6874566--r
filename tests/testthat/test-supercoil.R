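test_that("discrete curvature/torsion recover the closed forms on exact curves", {
  H <- study_helix
  poly <- sample_helix(H$R, H$h, n = 30, ds = 4.145, handedness = "left")
  ct <- centerline_curvature_torsion(poly)
  expect_equal(ct$kappa, 2.378e-3, tolerance = 1e-3)
  expect_equal(ct$tau, -2.959e-3, tolerance = 1e-3)
  # collinear points: zero curvature and torsion
  line <- cbind(seq(0, 100, by = 4), 0, 0)
  ctl <- centerline_curvature_torsion(line)
  expect_identical(ctl$kappa, 0)
  expect_identical(ctl$tau, 0)
  # planar circle of radius 420
  t <- seq(0, 1.2, by = 0.01)
  circ <- cbind(420 * cos(t), 420 * sin(t), 0)
  ctc <- centerline_curvature_torsion(circ)
  expect_equal(ctc$kappa, 1 / 420, tolerance = 1e-4)
  expect_equal(ctc$tau, 0, tolerance = 1e-9)
  expect_error(centerline_curvature_torsion(poly[1:4, ]), "insufficient")
})

test_that("inverse Frenet relations give the printed pitch and diameter", {
  p <- helix_from_kappa_tau(2.378e-3, -2.959e-3)
  expect_equal(p$pitch, 1290, tolerance = 1)
  expect_equal(p$radius, 165, tolerance = 0.1)
  expect_identical(p$handedness, "left")
  # type invariants hold to 1e-9 relative
  expect_equal(p$radius, p$kappa / (p$kappa^2 + p$tau^2), tolerance = 1e-9)
  expect_equal(p$h, abs(p$tau) / (p$kappa^2 + p$tau^2), tolerance = 1e-9)
  circle <- helix_from_kappa_tau(1e-3, 0)
  expect_identical(circle$pitch, 0)
  expect_identical(circle$handedness, "none")
  straight <- helix_from_kappa_tau(0, 0)
  expect_identical(straight$radius, 0)
  expect_identical(straight$pitch, Inf)
})

test_that("discrete estimator and least-squares fit agree on noiseless helices", {
  for (cfg in list(c(R = 165, h = 205.3), c(R = 90, h = 300), c(R = 250, h = 130))) {
    poly <- sample_helix(cfg["R"], cfg["h"], n = 25, ds = 5, handedness = "right")
    ct <- centerline_curvature_torsion(poly)
    disc <- helix_from_kappa_tau(ct$kappa, ct$tau)
    lsq <- fit_helix_lsq(poly, boot = 0)
    expect_lt(abs(disc$pitch - lsq$params$pitch) / lsq$params$pitch, 0.01)
    expect_lt(abs(disc$radius - lsq$params$radius) / lsq$params$radius, 0.01)
    expect_lt(abs(lsq$params$radius - cfg["R"]) / cfg["R"], 0.005)
    expect_lt(abs(lsq$params$pitch - 2 * pi * cfg["h"]) / (2 * pi * cfg["h"]), 0.005)
  }
})

test_that("least-squares fit tolerates vertex noise and flags straight polylines", {
  # the arc must determine the torsion: with 1 A vertex noise this needs
  # a substantial fraction of a supercoil turn (see the methods vignette
  # for the short-arc information limit)
  set.seed(3)
  poly <- sample_helix(165, 205.3, n = 100, ds = 6, handedness = "left") +
    matrix(rnorm(300, sd = 1), ncol = 3)
  fit <- fit_helix_lsq(poly, boot = 50)
  expect_lt(abs(fit$params$pitch - 1290) / 1290, 0.03)
  expect_lt(abs(fit$params$radius - 165) / 165, 0.03)
  expect_identical(fit$params$handedness, "left")
  expect_length(fit$ci$pitch, 2L)
  line <- cbind(seq(0, 200, by = 5), 0.01 * sin(seq(0, 200, by = 5)), 0)
  fl <- fit_helix_lsq(line)
  expect_true(fl$straight)
})

test_that("bootstrap confidence intervals are reproducible and leave the RNG alone", {
  poly <- sample_helix(165, 205.3, n = 20, ds = 6, handedness = "left")
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  f1 <- fit_helix_lsq(poly, boot = 50)
  after <- rnorm(1)
  f2 <- fit_helix_lsq(poly, boot = 50)
  expect_identical(f1$ci, f2$ci)
  expect_identical(before, after)
})

test_that("study-preset supercoil is recovered from the assembly", {
  g <- fx_supercoiled()
  fit <- estimate_supercoil(g$assembly, g$lattice, boot = 0)
  expect_identical(fit$params$handedness, "left")
  expect_lt(abs(fit$params$pitch - 1290) / 1290, 0.02)
  expect_lt(abs(fit$params$diameter - 330) / 330, 0.02)
  # bend faces away from the extended protofilament 1
  expect_gt(abs(fit$bend_azimuth_deg), 180 - 33)
})

test_that("mirror image flips handedness and preserves pitch and radius", {
  g <- fx_supercoiled()
  fit <- estimate_supercoil(g$assembly, g$lattice, boot = 0)
  mir <- mirror_assembly(g$assembly)
  lat_m <- index_lattice(mir)
  fit_m <- estimate_supercoil(mir, lat_m, boot = 0)
  expect_identical(fit_m$params$handedness, "right")
  expect_lt(abs(fit_m$params$pitch - fit$params$pitch) / fit$params$pitch, 0.01)
  expect_lt(abs(fit_m$params$radius - fit$params$radius) / fit$params$radius, 0.01)
})

test_that("screw extension spans one pitch and reproduces the input parameters", {
  g <- fx_supercoiled()
  fit <- estimate_supercoil(g$assembly, g$lattice, boot = 0)
  expect_identical(extend_assembly(g$assembly, g$lattice, fit, length = 0),
                   g$assembly)
  ext <- extend_assembly(g$assembly, g$lattice, fit, length = 1.0)
  expect_gt(length(ext), 26L)
  cen <- hookjoint:::assembly_centroids(ext)
  span <- diff(range(drop(sweep(cen, 2, fit$axis$point) %*% fit$axis$dir)))
  expect_gte(span, fit$params$pitch * 0.98)
  refit <- fit_helix_lsq(estimate_tube_axis(ext), boot = 0)
  expect_lt(abs(refit$params$pitch - fit$params$pitch) / fit$params$pitch, 0.01)
  expect_lt(abs(refit$params$radius - fit$params$radius) / fit$params$radius, 0.01)
  expect_identical(refit$params$handedness, "left")
  # straight assemblies cannot be extended
  gs <- fx_straight()
  fs <- estimate_supercoil(gs$assembly, gs$lattice, boot = 0)
  expect_error(extend_assembly(gs$assembly, gs$lattice, fs), "straight")
})
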