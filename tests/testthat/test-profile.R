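test_that("straight-lattice spacings equal d0 everywhere", {
  g <- fx_straight()
  prof <- axial_distance_map(g$assembly, g$lattice)
  expect_true(all(abs(prof$per_residue$dist - 45.6) < 0.1))
  expect_identical(length(prof$pf_mean), 11L)
})

test_that("supercoiled spacings follow the elastic-bending closed form", {
  g <- fx_supercoiled()
  # note: renumbering relabels protofilaments; compare against ground
  # truth through the chain bookkeeping instead
  lat0 <- index_lattice(g$assembly)
  prof <- axial_distance_map(g$assembly, lat0)
  dm <- domain_mean_distances(prof, g$truth$domains)
  k_est <- lat0$k[names(g$truth$k)]
  reversed <- !all(k_est == g$truth$k)
  exp_pf <- stats::aggregate(expected ~ pf + layer, expected_spacing(g$truth), mean)
  for (i in seq_len(nrow(exp_pf))) {
    pf_t <- exp_pf$pf[i]
    ch <- names(g$truth$pf)[g$truth$pf == pf_t][1L]
    pf_e <- unname(lat0$pf[ch])
    got <- dm$mean_dist[dm$pf == pf_e & dm$domain == exp_pf$layer[i]]
    expect_lt(abs(got - exp_pf$expected[i]) / exp_pf$expected[i], 0.01)
  }
})

test_that("per-layer modulation amplitude is linear in layer radius", {
  g <- fx_supercoiled()
  dm <- domain_mean_distances(g$profile, g$truth$domains)
  amp <- vapply(split(dm, dm$domain), function(d)
    (max(d$mean_dist) - min(d$mean_dist)) / 2, numeric(1))
  radii <- stats::setNames(g$truth$layer_centroids$radius,
                           g$truth$layer_centroids$layer)
  ratio <- amp[names(radii)] / radii
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.03)
  # and the outer layer modulates the most
  expect_identical(names(which.max(amp)), "D2")
})

test_that("spacing map is invariant under rigid motion of the assembly", {
  g <- fx_supercoiled()
  moved <- rigid_move(g$assembly)
  lat_m <- index_lattice(moved)
  prof_m <- axial_distance_map(moved, lat_m)
  a <- g$profile$per_residue[order(g$profile$per_residue$resno), ]
  b <- prof_m$per_residue[order(prof_m$per_residue$resno), ]
  # per-residue distances sorted within residue are label-free
  for (r in unique(a$resno)[c(1, 50, 100)]) {
    expect_equal(sort(a$dist[a$resno == r]), sort(b$dist[b$resno == r]),
                 tolerance = 1e-6)
  }
})

test_that("bending midpoints stay at d0 and deviations vanish when straight", {
  g <- fx_supercoiled()
  bc <- bending_consistency(g$profile, g$truth$domains)
  expect_true(all(abs(bc$rel_dev) < 0.01))
  gs <- fx_straight()
  profs <- axial_distance_map(gs$assembly, gs$lattice)
  bcs <- bending_consistency(profs, gs$truth$domains)
  expect_true(all(abs(bcs$rel_dev) < 1e-6))
})

test_that("profile errors are informative", {
  g <- fx_supercoiled()
  toy <- generate_straight(study_spec(n_subunits = 11, radius = 0, pitch = 0))
  lat <- index_lattice(toy$assembly)
  expect_error(axial_distance_map(toy$assembly, lat), "insufficient")
  expect_error(domain_mean_distances(g$profile,
                                     domain_set(ghost = c(5000, 5100))),
               "configuration error")
})

test_that("profile CSV export has one row per (protofilament, residue, pair)", {
  g <- fx_supercoiled()
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(g$profile, f)
  tab <- utils::read.csv(f)
  expect_identical(nrow(tab), nrow(g$profile$long))
  expect_true(all(tab$color01 >= 0 & tab$color01 <= 1))
})
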