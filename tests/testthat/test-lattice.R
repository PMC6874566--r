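test_that("tube axis of a straight assembly is collinear with the generator axis", {
  g <- fx_straight()
  poly <- estimate_tube_axis(g$assembly)
  line <- hookjoint:::fit_line(poly)
  expect_lt(line$rms, 0.5)
  expect_gt(abs(sum(line$dir * c(0, 0, 1))), 0.999)
})

test_that("tube axis of the study supercoil lies on the generating superhelix", {
  g <- fx_supercoiled()
  poly <- g$lattice$axis
  H <- study_helix
  cc <- sqrt(H$R^2 + H$h^2)
  sgrid <- seq(-60, 180, by = 0.25)
  cl <- cbind(H$R * cos(sgrid / cc), -H$R * sin(sgrid / cc), H$h * sgrid / cc)
  dev <- vapply(seq_len(nrow(poly)), function(i)
    sqrt(min(rowSums(sweep(cl, 2, poly[i, ])^2))), numeric(1))
  expect_lt(max(dev), 2)
})

test_that("lattice indexing recovers construction order, protofilaments and neighbour maps", {
  g <- fx_supercoiled()
  lat <- g$lattice
  expect_true(k_matches_truth(lat, g$truth))
  expect_identical(sort(unique(unname(lat$pf))), 1:11)
  expect_lt(lat$step_sd_deg, 15)
  expect_true(all(diff(lat$z[lat$chains]) > 0))
  # (+5) then (+6) equals (+11) on the common domain
  p5 <- neighbor_pairs(lat, 5); p6 <- neighbor_pairs(lat, 6); p11 <- neighbor_pairs(lat, 11)
  comp <- merge(p5, p6, by.x = "k_to", by.y = "k_from")
  comp <- comp[comp$k_to.y <= max(lat$k), ]
  expect_identical(sort(comp$k_to.y - comp$k_from), sort(p11$k_to - p11$k_from))
  expect_true(all(comp$k_to.y - comp$k_from == 11L))
})

test_that("indexing is invariant to chain shuffling and rigid motion (up to polarity)", {
  g <- fx_supercoiled()
  shuffled <- hookjoint:::new_assembly(unclass(g$assembly)[sample(26)])
  lat_s <- index_lattice(shuffled)
  expect_true(k_matches_truth(lat_s, g$truth))
  moved <- rigid_move(g$assembly)
  lat_m <- index_lattice(moved)
  expect_true(k_matches_truth(lat_m, g$truth))
})

test_that("an 11-subunit single-turn toy has no axial pairs but partial 5/6 maps", {
  toy <- generate_straight(study_spec(n_subunits = 11, radius = 0, pitch = 0))
  lat <- index_lattice(toy$assembly)
  expect_identical(nrow(neighbor_pairs(lat, 11)), 0L)
  expect_identical(nrow(neighbor_pairs(lat, 5)), 6L)
  expect_identical(nrow(neighbor_pairs(lat, 6)), 5L)
  expect_identical(sort(unique(unname(lat$pf))), 1:11)
})

test_that("too few subunits raise an insufficient-data error", {
  toy <- generate_straight(study_spec(n_subunits = 5, radius = 0, pitch = 0))
  expect_error(estimate_tube_axis(toy$assembly), "insufficient")
  expect_error(index_lattice(toy$assembly), "insufficient")
})

test_that("protofilament renumbering puts the extended side at 1 and the compressed at 6-7", {
  g <- fx_supercoiled()
  expect_identical(unname(which.max(g$profile$pf_mean)), 1L)
  expect_true(which.min(g$profile$pf_mean) %in% 6:7)
  # extended and compressed protofilaments sit on opposite sides
  az <- hookjoint:::protofilament_azimuths(g$lattice)
  dphi <- abs(hookjoint:::wrap_angle(az[which.max(g$profile$pf_mean)] -
                                       az[which.min(g$profile$pf_mean)]))
  expect_gt(dphi * 180 / pi, 180 - 360 / 11)
})

test_that("renumbering a straight assembly warns on the tie and stays deterministic", {
  g <- fx_straight()
  prof <- axial_distance_map(g$assembly, g$lattice)
  expect_warning(l1 <- renumber_protofilaments(g$lattice, prof), "tie")
  suppressWarnings(l2 <- renumber_protofilaments(g$lattice, prof))
  expect_identical(l1$pf, l2$pf)
})

test_that("protofilament assignment matches ground truth across curvatures and noise", {
  for (cfg in list(list(pitch = 2000, radius = 80, noise = 0.1, seed = 11),
                   list(pitch = 1000, radius = 180, noise = 0.3, seed = 12))) {
    g <- generate_supercoiled(study_spec(pitch = cfg$pitch, radius = cfg$radius,
                                         noise_sd = cfg$noise, seed = cfg$seed))
    lat <- index_lattice(g$assembly)
    expect_true(k_matches_truth(lat, g$truth))
    ke <- lat$k[names(g$truth$k)]
    pf_est <- (ke %% 11L) + 1L
    pf_tru <- g$truth$pf[names(ke)]
    # protofilament sets must coincide (ids may be relabeled consistently)
    expect_identical(unname(tapply(names(ke), pf_est, function(x) sort(x))[
      order(vapply(tapply(names(ke), pf_est, sort), `[`, character(1), 1))]),
      unname(tapply(names(ke), pf_tru, function(x) sort(x))[
        order(vapply(tapply(names(ke), pf_tru, sort), `[`, character(1), 1))]))
  }
})
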