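# Shared fixtures, built once per test run. The "study" preset encodes the
# native supercoiled hook conditions: 26 subunits, 11 protofilaments,
# d0 = 45.6 A, left-handed supercoil of pitch 1290 A and radius 165 A.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

study_spec <- function(...) synthetic_spec(...)

fx_supercoiled <- function() fixture("supercoiled", function() {
  g <- generate_supercoiled(study_spec())
  g$lattice <- index_lattice(g$assembly)
  g$profile <- axial_distance_map(g$assembly, g$lattice)
  g$lattice <- renumber_protofilaments(g$lattice, g$profile)
  g$profile <- axial_distance_map(g$assembly, g$lattice)
  g
})

fx_straight <- function() fixture("straight", function() {
  g <- generate_straight(study_spec(radius = 0, pitch = 0))
  g$lattice <- index_lattice(g$assembly)
  g
})

# exact reference helix for the study supercoil: P = 1290 A, R = 165 A
study_helix <- list(R = 165, h = 1290 / (2 * pi),
                    kappa = 165 / (165^2 + (1290 / (2 * pi))^2),
                    tau = -(1290 / (2 * pi)) / (165^2 + (1290 / (2 * pi))^2))

rigid_move <- function(assembly, axis = c(1, 2, 2), angle = 0.7,
                       shift = c(25, -40, 60)) {
  Rm <- hookjoint:::rot_axis_angle(axis, angle)
  subs <- unclass(assembly)
  for (ch in names(subs)) {
    s <- subs[[ch]]
    s$ca <- sweep(s$ca %*% t(Rm), 2, shift, `+`)
    rownames(s$ca) <- s$resno
    xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(Rm)
    s$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, `+`)
    subs[[ch]] <- s
  }
  hookjoint:::new_assembly(subs)
}

mirror_assembly <- function(assembly) {
  subs <- unclass(assembly)
  for (ch in names(subs)) {
    subs[[ch]]$ca[, 1] <- -subs[[ch]]$ca[, 1]
    subs[[ch]]$atoms$x <- -subs[[ch]]$atoms$x
  }
  hookjoint:::new_assembly(subs)
}

# indexing match up to the intrinsic polarity ambiguity of a 1-start helix
k_matches_truth <- function(lattice, truth) {
  ke <- lattice$k[names(truth$k)]
  n <- length(ke)
  all(ke == truth$k) || all(ke == (n - 1L) - truth$k)
}
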