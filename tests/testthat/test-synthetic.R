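test_that("spec validation rejects impossible configurations", {
  expect_error(synthetic_spec(n_subunits = 0), "invalid spec")
  expect_error(synthetic_spec(layers = data.frame(name = c("A", "B"),
                                                  radius = c(50, 40),
                                                  n_atoms = c(10L, 10L),
                                                  spread = c(2, 2))),
               "increasing")
  expect_error(synthetic_spec(noise_sd = -1), "invalid spec")
  # kappa * r_max >= 1 is unphysical compression (tight coil, kappa ~ 1/13 A^-1)
  expect_error(synthetic_spec(pitch = 40, radius = 7), "unphysical")
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_supercoiled(study_spec(seed = 5))
  b <- generate_supercoiled(study_spec(seed = 5))
  expect_identical(a$assembly, b$assembly)
  c <- generate_supercoiled(study_spec(seed = 6))
  expect_false(identical(a$assembly, c$assembly))
})

test_that("straight generator places one subunit per protofilament slot", {
  g <- generate_straight(study_spec(n_subunits = 11, radius = 0, pitch = 0))
  expect_identical(sort(unique(unname(g$truth$pf))), 1:11)
  expect_identical(anyDuplicated(g$truth$pf), 0L)
  # azimuth of k and k+11 coincide modulo 360 within 1e-9
  g26 <- fx_straight()
  a0 <- atan2(hookjoint:::subunit_centroid(g26$assembly[[1]])[2],
              hookjoint:::subunit_centroid(g26$assembly[[1]])[1])
  a11 <- atan2(hookjoint:::subunit_centroid(g26$assembly[[12]])[2],
               hookjoint:::subunit_centroid(g26$assembly[[12]])[1])
  expect_lt(abs(hookjoint:::wrap_angle(a11 - a0)), 1e-9)
})

test_that("the supercoil map is continuous in the straight limit", {
  spec_tiny <- study_spec(pitch = 1290, radius = 1e-4)
  gt <- generate_supercoiled(spec_tiny)
  gs <- generate_straight(study_spec(radius = 0, pitch = 0))
  dev <- max(abs(gt$assembly[["A"]]$ca - gs$assembly[["A"]]$ca))
  expect_lt(dev, 1e-4)
})

test_that("ground-truth spacing formula matches brute-force distances within 1%", {
  g <- fx_supercoiled()
  lat0 <- index_lattice(g$assembly)
  prof <- axial_distance_map(g$assembly, lat0)
  dm <- domain_mean_distances(prof, g$truth$domains)
  exp_pf <- stats::aggregate(expected ~ pf + layer, expected_spacing(g$truth), mean)
  worst <- 0
  for (i in seq_len(nrow(exp_pf))) {
    ch <- names(g$truth$pf)[g$truth$pf == exp_pf$pf[i]][1L]
    got <- dm$mean_dist[dm$pf == unname(lat0$pf[ch]) & dm$domain == exp_pf$layer[i]]
    worst <- max(worst, abs(got - exp_pf$expected[i]) / exp_pf$expected[i])
  }
  expect_lt(worst, 0.01)
})

test_that("hinges validate their angle and act as exact fixtures", {
  g <- generate_straight(study_spec(radius = 0, pitch = 0))
  expect_error(apply_hinge(g$assembly, g$truth, "D2", 60), "validation")
  expect_error(apply_hinge(g$assembly, g$truth, "ghost", 10), "unknown layer")
  same <- apply_hinge(g$assembly, g$truth, "D2", 0, chains = "A")
  expect_equal(same[["A"]]$ca, g$assembly[["A"]]$ca, tolerance = 1e-12)
})

test_that("coordinate noise is seed-reproducible with the right magnitude", {
  g <- fx_straight()
  expect_identical(add_noise(g$assembly, 0), g$assembly)
  n1 <- add_noise(g$assembly, 0.3, seed = 17)
  n2 <- add_noise(g$assembly, 0.3, seed = 17)
  expect_identical(n1, n2)
  disp <- unlist(lapply(names(g$assembly), function(ch)
    rowSums((n1[[ch]]$ca - g$assembly[[ch]]$ca)^2)))
  # per-atom RMS displacement = sd * sqrt(3)
  expect_equal(sqrt(mean(disp)), 0.3 * sqrt(3), tolerance = 0.05)
  # caller RNG state untouched
  set.seed(123); x <- rnorm(1)
  set.seed(123); invisible(add_noise(g$assembly, 0.1, seed = 4)); y <- rnorm(1)
  expect_identical(x, y)
})
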