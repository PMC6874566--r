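test_that("contact classification finds constant and switching pairs across contexts", {
  g <- fx_supercoiled()
  tab <- find_contacts(g$assembly, g$lattice, 11, cutoff = 45.6)
  expect_gt(sum(tab$class == "constant"), 0L)
  expect_gt(sum(tab$class == "switching"), 0L)
  # constant means present in every context
  expect_true(all(tab$n_present[tab$class == "constant"] == 11L))
  expect_true(all(tab$n_present[tab$class == "switching"] < 11L))
  expect_true(all(tab$sd >= 0, na.rm = TRUE))
  # a zero cutoff yields an empty table; invalid direction errors
  expect_identical(nrow(find_contacts(g$assembly, g$lattice, 11, cutoff = 0)), 0L)
  expect_error(find_contacts(g$assembly, g$lattice, 7), "invalid direction")
})

test_that("classification is stable under small cutoff perturbation", {
  g <- fx_supercoiled()
  sens <- contact_sensitivity(g$assembly, g$lattice, 11, cutoff = 45.6,
                              delta = c(-0.2, 0, 0.2))
  expect_identical(nrow(sens), 3L)
  base <- sens$n_constant[sens$cutoff == 45.6]
  expect_lt(max(abs(sens$n_constant - base)) / base, 0.15)
})

test_that("contact distances are symmetric under role reversal", {
  g <- fx_supercoiled()
  ctx <- hookjoint:::context_pairs(g$lattice, 5)
  i <- 3L
  fwd <- hookjoint:::min_residue_distances(g$assembly[[ctx$chain_from[i]]],
                                           g$assembly[[ctx$chain_to[i]]], 50)
  rev <- hookjoint:::min_residue_distances(g$assembly[[ctx$chain_to[i]]],
                                           g$assembly[[ctx$chain_from[i]]], 50)
  key_f <- paste(fwd$res_a, fwd$res_b)
  key_r <- paste(rev$res_b, rev$res_a)
  expect_setequal(key_f, key_r)
  expect_equal(fwd$dist[order(key_f)], rev$dist[order(key_r)], tolerance = 1e-9)
})

test_that("neighbour-distance variability vanishes when straight and grows with layer radius", {
  gs <- fx_straight()
  vs <- residue_variability(gs$assembly, gs$lattice, 11)
  expect_lt(max(vs$sd, na.rm = TRUE), 1e-9)
  g <- fx_supercoiled()
  v <- residue_variability(g$assembly, g$lattice, 11, defs = g$truth$domains)
  agg <- stats::aggregate(sd ~ domain, v, mean)
  sds <- stats::setNames(agg$sd, agg$domain)
  expect_true(sds["D0c"] < sds["D1"] && sds["D1"] < sds["D2"])
  sm <- attr(v, "summary")
  expect_identical(sm$max_sd$domain, "D2")
  expect_identical(sm$min_sd$domain, "D0c")
})

test_that("variability is invariant under rigid motion", {
  g <- fx_supercoiled()
  v <- residue_variability(g$assembly, g$lattice, 11)
  moved <- rigid_move(g$assembly)
  latm <- index_lattice(moved)
  profm <- axial_distance_map(moved, latm)
  latm <- renumber_protofilaments(latm, profm)
  vm <- residue_variability(moved, latm, 11)
  expect_equal(v$sd[order(v$resno)], vm$sd[order(vm$resno)], tolerance = 1e-6)
})

test_that("the mesh-layer triangle gap closes on the compressed side", {
  g <- fx_supercoiled()
  gap_c <- d1_triangle_gap(g$assembly, g$lattice, 7, g$truth$domains)
  gap_e <- d1_triangle_gap(g$assembly, g$lattice, 1, g$truth$domains)
  expect_lt(gap_c$gap, gap_e$gap)
  expect_lt(gap_c$triangle_area, gap_e$triangle_area)
  expect_length(gap_c$min_dist, 3L)
  # analytic centroid-triangle area for the straight lattice
  gs <- fx_straight()
  gap_s <- d1_triangle_gap(gs$assembly, gs$lattice, 3, gs$truth$domains)
  d1res <- gs$truth$template$resno[gs$truth$template$layer == "D1"]
  cent <- function(ch) colMeans(gs$assembly[[ch]]$ca[as.character(d1res), ])
  tri <- t(vapply(gap_s$chains, cent, numeric(3)))
  area <- 0.5 * sqrt(sum(hookjoint:::cross3(tri[2, ] - tri[1, ],
                                            tri[3, ] - tri[1, ])^2))
  expect_equal(gap_s$triangle_area, area, tolerance = 1e-9)
  # missing neighbours raise an error
  toy <- generate_straight(study_spec(n_subunits = 11, radius = 0, pitch = 0))
  latt <- index_lattice(toy$assembly)
  expect_error(d1_triangle_gap(toy$assembly, latt, 1, toy$truth$domains),
               "missing")
})
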