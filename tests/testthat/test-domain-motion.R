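test_that("Kabsch superposition recovers identity and constructed rotations", {
  set.seed(42)
  pts <- matrix(rnorm(150, sd = 10), ncol = 3)
  tr0 <- kabsch_superpose(pts, pts)
  expect_lt(tr0$rmsd, 1e-9)
  expect_lt(tr0$angle_deg, 1e-6)
  ax <- hookjoint:::unit3(c(1, -2, 0.5))
  Rm <- hookjoint:::rot_axis_angle(ax, 24 * pi / 180)
  rot <- pts %*% t(Rm)
  tr <- kabsch_superpose(pts, rot)
  expect_equal(tr$angle_deg, 24, tolerance = 1e-6)
  expect_gt(abs(sum(tr$axis * ax)), 1 - 1e-9)
  # idempotence: re-superposing the aligned set gives identity
  aligned <- hookjoint:::apply_transform(pts, tr)
  tr2 <- kabsch_superpose(aligned, rot)
  expect_lt(tr2$angle_deg, 1e-6)
})

test_that("Kabsch RMSD under noise matches the independent bio3d superposition", {
  set.seed(7)
  pts <- matrix(rnorm(150, sd = 12), ncol = 3)
  Rm <- hookjoint:::rot_axis_angle(c(0, 1, 1), 0.9)
  moved <- sweep(pts %*% t(Rm), 2, c(5, -3, 8), `+`) + matrix(rnorm(150, sd = 0.2), ncol = 3)
  ours <- kabsch_superpose(moved, pts)$rmsd
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(pts)), mobile = as.vector(t(moved))))
  ref <- bio3d::rmsd(as.vector(t(pts)), fitted)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:10, 2 * (1:10), -1:-10 * 0.5)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
})

test_that("conformation classes: 11 on the supercoil, positional-only when straight", {
  g <- fx_supercoiled()
  cl <- conformation_classes(g$assembly, g$lattice)
  expect_identical(cl$n_classes, 11L)
  expect_false(cl$conformationally_uniform)
  gs <- fx_straight()
  cls <- conformation_classes(gs$assembly, gs$lattice)
  expect_identical(cls$n_classes, 11L)
  expect_true(cls$conformationally_uniform)
})

test_that("hinge-applied domain motions are recovered exactly", {
  g <- generate_straight(study_spec(radius = 0, pitch = 0))
  hingedD2 <- apply_hinge(g$assembly, g$truth, "D2", 24, chains = "A")
  m <- relative_domain_motion(g$assembly[["A"]], hingedD2[["A"]],
                              g$truth$domains, c(0, 0, 1))
  expect_equal(m$domains$D2$tilt_deg, 24, tolerance = 0.2)
  expect_lt(m$domains$D0c$tilt_deg, 0.1)
  expect_lt(abs(m$domains$D0c$axial_shift), 0.05)
  hingedD1 <- apply_hinge(g$assembly, g$truth, "D1", 4, shift = 5, chains = "A")
  m2 <- relative_domain_motion(g$assembly[["A"]], hingedD1[["A"]],
                               g$truth$domains, c(0, 0, 1))
  expect_equal(m2$domains$D1$tilt_deg, 4, tolerance = 0.2)
  expect_equal(m2$domains$D1$axial_shift, 5, tolerance = 0.1)
  # self comparison is the identity
  m0 <- relative_domain_motion(g$assembly[["A"]], g$assembly[["A"]],
                               g$truth$domains, c(0, 0, 1))
  for (d in m0$domains) {
    expect_lt(d$tilt_deg, 0.1)
    expect_lt(abs(d$axial_shift), 0.05)
  }
})

test_that("tilt and RMSD are invariant to a common rigid motion", {
  g <- generate_straight(study_spec(radius = 0, pitch = 0))
  hinged <- apply_hinge(g$assembly, g$truth, "D2", 15, chains = "A")
  both <- hookjoint:::new_assembly(list(g$assembly[["A"]], local({
    s <- hinged[["A"]]; s$chain <- "B"; s
  })))
  moved <- rigid_move(both)
  Rm <- hookjoint:::rot_axis_angle(c(1, 2, 2), 0.7)
  m1 <- relative_domain_motion(both[["A"]], both[["B"]], g$truth$domains, c(0, 0, 1))
  m2 <- relative_domain_motion(moved[["A"]], moved[["B"]], g$truth$domains,
                               drop(Rm %*% c(0, 0, 1)))
  expect_equal(m1$domains$D2$tilt_deg, m2$domains$D2$tilt_deg, tolerance = 1e-6)
  expect_equal(m1$domains$D2$axial_shift, m2$domains$D2$axial_shift, tolerance = 1e-6)
})

test_that("subunit length extension reflects an imposed axial stretch", {
  g <- generate_straight(study_spec(radius = 0, pitch = 0))
  stretched <- apply_hinge(g$assembly, g$truth, "D2", 0, shift = 6, chains = "A")
  # brute-force expectation from coordinates
  dz <- diff(range(stretched[["A"]]$ca[, 3])) - diff(range(g$assembly[["A"]]$ca[, 3]))
  got <- extension(stretched[["A"]], g$assembly[["A"]], c(0, 0, 1))
  expect_equal(got, dz, tolerance = 1e-9)
  expect_equal(extension(g$assembly[["A"]], g$assembly[["A"]], c(0, 0, 1)), 0)
})

test_that("domain axis tilt measures the principal-axis angle against the tube axis", {
  set.seed(11)
  t <- seq(0, 40, length.out = 30)
  xyz <- cbind(t * sin(pi / 6), 0, t * cos(pi / 6)) +
    matrix(rnorm(90, sd = 0.3), ncol = 3)
  sub <- hookjoint:::new_subunit("T", data.frame(
    resno = 1:30, resid = "ALA", elety = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  tilt <- domain_axis_tilt(sub, domain_set(D = c(1, 30)), "D", c(0, 0, 1))
  expect_equal(tilt, 30, tolerance = 1.5)
})

test_that("class RMSD matrix is symmetric with the expected structure", {
  g <- fx_supercoiled()
  M <- class_rmsd_matrix(g$assembly, g$lattice)
  expect_identical(dim(M), c(11L, 11L))
  expect_identical(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_true(all(M[upper.tri(M)] > 0))
})

test_that("class representatives order like the ground-truth stretch around the circumference", {
  g <- fx_supercoiled()
  exp_pf <- stats::aggregate(expected ~ pf, expected_spacing(g$truth), mean)
  # ranks of measured per-protofilament means must match the closed form
  lat0 <- index_lattice(g$assembly)
  prof0 <- axial_distance_map(g$assembly, lat0)
  ch_of_pf <- vapply(1:11, function(p) names(g$truth$pf)[g$truth$pf == p][1], character(1))
  est_by_truth_pf <- prof0$pf_mean[as.character(unname(lat0$pf[ch_of_pf]))]
  expect_identical(order(est_by_truth_pf), order(exp_pf$expected))
})
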