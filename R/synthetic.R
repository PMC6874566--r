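# Coarse-grained generator of straight and supercoiled 11-protofilament
# tubular assemblies with known ground truth.

#' Specification of a synthetic hook-like assembly
#'
#' Defaults encode the geometry of the native supercoiled hook segment:
#' 26 subunits on an 11-start lattice with a 1-start twist of 720/11
#' degrees and rise d0/11, three radial pseudo-domain layers (inner tube
#' D0c at 25 A, mesh D1 at 45 A, outer spring D2 at 70 A), straight-form
#' protofilament spacing d0 = 45.6 A, and a left-handed supercoil of pitch
#' 1290 A and radius 165 A.
#'
#' @param n_subunits number of subunits (default 26).
#' @param start_number protofilament count S (default 11).
#' @param d0 straight protofilament spacing (Angstrom); the 1-start rise
#'   is `d0 / start_number` and the twist `2 * 360 / start_number` degrees
#'   (11 subunits span two turns).
#' @param layers data.frame with columns `name`, `radius`, `n_atoms`,
#'   `spread`: one pseudo-atom cluster per radial layer; radii must be
#'   strictly increasing.
#' @param pitch,radius supercoil pitch and superhelix radius (Angstrom);
#'   set `radius = 0` for a straight assembly.
#' @param handedness `"left"` or `"right"`.
#' @param noise_sd isotropic Gaussian coordinate noise SD (Angstrom).
#' @param seed RNG seed freezing the template cloud (and noise).
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subunits = 26L, start_number = 11L, d0 = 45.6,
                           layers = data.frame(
                             name = c("D0c", "D1", "D2"),
                             radius = c(25, 45, 70),
                             n_atoms = c(30L, 40L, 35L),
                             spread = c(6, 8, 8)),
                           pitch = 1290, radius = 165,
                           handedness = c("left", "right"),
                           noise_sd = 0, seed = 1L) {
  handedness <- match.arg(handedness)
  if (n_subunits < 1L) stop("invalid spec: need at least one subunit")
  if (any(diff(layers$radius) <= 0)) stop("invalid spec: layer radii must be strictly increasing")
  if (noise_sd < 0) stop("invalid spec: negative noise SD")
  if (radius > 0 && pitch <= 0) stop("invalid spec: pitch must be positive for a supercoil")
  twist <- 2 * 360 / start_number
  rise <- d0 / start_number
  kappa <- tau <- 0
  if (radius > 0) {
    h <- pitch / (2 * pi)
    kappa <- radius / (radius^2 + h^2)
    tau <- (if (handedness == "left") -1 else 1) * h / (radius^2 + h^2)
    if (kappa * (max(layers$radius) + 2 * max(layers$spread)) >= 1)
      stop("unphysical compression: kappa * r_max >= 1")
  }
  structure(list(n_subunits = as.integer(n_subunits),
                 start_number = as.integer(start_number),
                 d0 = d0, twist = twist, rise = rise,
                 layers = layers, pitch = pitch, radius = radius,
                 handedness = handedness, kappa = kappa, tau = tau,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# frozen per-seed template pseudo-atom cloud; one residue per pseudo-atom,
# layers occupy contiguous author-number ranges
synthetic_template <- function(spec) {
  ly <- spec$layers
  with_local_seed(spec$seed, {
    rows <- list()
    res0 <- 1L
    for (i in seq_len(nrow(ly))) {
      n <- ly$n_atoms[i]
      xyz <- cbind(ly$radius[i] + stats::rnorm(n, 0, ly$spread[i] / 2),
                   stats::rnorm(n, 0, ly$spread[i] / 2),
                   stats::rnorm(n, 0, ly$spread[i] / 2))
      rows[[i]] <- data.frame(layer = ly$name[i],
                              resno = seq.int(res0, res0 + n - 1L),
                              x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                              stringsAsFactors = FALSE)
      res0 <- res0 + n
    }
    do.call(rbind, rows)
  })
}

# domain_set matching the template's contiguous layer ranges
synthetic_domains <- function(spec) {
  ly <- spec$layers
  ends <- cumsum(ly$n_atoms)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  args <- lapply(seq_len(nrow(ly)), function(i) c(starts[i], ends[i]))
  names(args) <- ly$name
  do.call(domain_set, args)
}

synthetic_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, as.vector(outer(pool, pool, paste0)))[seq_len(n)]
}

#' Generate a straight synthetic assembly
#'
#' Subunit k (0-based) is a rigid copy of the frozen template cloud rotated
#' to azimuth `k * twist` and raised to `k * rise`. Ground-truth
#' bookkeeping (construction index, protofilament, layer ranges, effective
#' layer radii) is attached for recovery tests.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `assembly` (a `hook_assembly`) and `truth`.
#' @export
generate_straight <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tmpl <- synthetic_template(spec)
  chains <- synthetic_chain_ids(spec$n_subunits)
  subs <- vector("list", spec$n_subunits)
  for (k in seq_len(spec$n_subunits) - 1L) {
    ang <- k * spec$twist * pi / 180
    Rm <- rot_axis_angle(c(0, 0, 1), ang)
    xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(Rm)
    xyz[, 3L] <- xyz[, 3L] + k * spec$rise
    subs[[k + 1L]] <- new_subunit(chains[k + 1L],
      data.frame(resno = tmpl$resno, resid = "ALA", elety = "CA",
                 x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                 stringsAsFactors = FALSE))
  }
  assembly <- new_assembly(subs)
  if (spec$noise_sd > 0) assembly <- add_noise(assembly, spec$noise_sd, spec$seed + 1L)
  ly <- spec$layers
  # effective layer geometry of the frozen template (sample centroids)
  eff <- do.call(rbind, lapply(split(tmpl, tmpl$layer), function(g) {
    data.frame(layer = g$layer[1L], x = mean(g$x), y = mean(g$y), z = mean(g$z),
               radius = sqrt(mean(g$x)^2 + mean(g$y)^2),
               stringsAsFactors = FALSE)
  }))
  truth <- list(spec = spec, template = tmpl, chains = chains,
                k = stats::setNames(seq_len(spec$n_subunits) - 1L, chains),
                pf = stats::setNames((seq_len(spec$n_subunits) - 1L) %% spec$start_number + 1L, chains),
                domains = synthetic_domains(spec),
                layer_centroids = eff)
  list(assembly = assembly, truth = truth)
}

# map a straight-frame point (x, y, z) onto the superhelical centerline
# using the closed-form parallel-transport frame of a circular helix; the
# straight axial coordinate is the centerline arclength
supercoil_map <- function(xyz, spec) {
  pt_helix_map(xyz, spec$kappa, spec$tau)
}

#' Generate a supercoiled synthetic assembly
#'
#' The straight assembly is bent onto a superhelical centerline of
#' curvature kappa and signed torsion tau via a closed-form
#' parallel-transport (twist-free) frame, with the straight axial
#' coordinate as centerline arclength. This realizes the elastic-bending
#' deformation: local material stretch is `1 + kappa * x_out` where
#' `x_out` is the offset away from the bend center, so protofilaments on
#' the outside of the bend extend and those inside compress. Ground truth
#' includes the closed-form expected spacing per protofilament and layer,
#' `d = d0 * (1 - kappa * r * cos(phi - phi0(s)))`, evaluated at each
#' axial pair's midpoint (the bend-facing azimuth `phi0` precesses with
#' the torsion along the segment).
#'
#' @param spec a `synthetic_spec` with `radius > 0`.
#' @return list with `assembly`, `truth` (including `expected_spacing`).
#' @export
generate_supercoiled <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$radius <= 0) stop("spec has no supercoil: radius must be positive")
  noise_sd <- spec$noise_sd
  spec_clean <- spec; spec_clean$noise_sd <- 0
  gs <- generate_straight(spec_clean)
  assembly <- gs$assembly
  subs <- unclass(assembly)
  for (ch in names(subs)) {
    s <- subs[[ch]]
    s$ca <- supercoil_map(s$ca, spec)
    rownames(s$ca) <- s$resno
    s$atoms[, c("x", "y", "z")] <- supercoil_map(as.matrix(s$atoms[, c("x", "y", "z")]), spec)
    subs[[ch]] <- s
  }
  assembly <- new_assembly(subs)
  if (noise_sd > 0) assembly <- add_noise(assembly, noise_sd, spec$seed + 1L)
  truth <- gs$truth
  truth$spec <- spec
  truth$expected_spacing <- expected_spacing(truth)
  list(assembly = assembly, truth = truth)
}

#' Closed-form elastic-bending spacing prediction
#'
#' Expected axial C-alpha spacing per (protofilament, layer), from the
#' generator's elastic-bending model: for an axial pair with straight-frame
#' layer-centroid offset (x, y) and pair-midpoint arclength s,
#' `d = d0 * (1 + kappa * (x * cos(tau * s) + y * sin(tau * s)))` in the
#' generator's material frame (equivalently
#' `d0 * (1 - kappa * r * cos(phi - phi0(s)))` with `phi0 = pi + tau * s`).
#'
#' @param truth ground-truth list from [generate_supercoiled()] /
#'   [generate_straight()].
#' @return data.frame with `pf`, `layer`, `k_from`, `expected` (Angstrom).
#' @export
expected_spacing <- function(truth) {
  spec <- truth$spec
  S <- spec$start_number
  N <- spec$n_subunits
  if (N <= S) return(NULL)
  eff <- truth$layer_centroids
  rows <- list()
  for (k in 0:(N - S - 1L)) {
    pf <- (k %% S) + 1L
    phi_k <- k * spec$twist * pi / 180
    for (i in seq_len(nrow(eff))) {
      x0 <- eff$x[i] * cos(phi_k) - eff$y[i] * sin(phi_k)
      y0 <- eff$x[i] * sin(phi_k) + eff$y[i] * cos(phi_k)
      s_mid <- (k + S / 2) * spec$rise + eff$z[i]
      d <- spec$d0 * (1 + spec$kappa * (x0 * cos(spec$tau * s_mid) +
                                          y0 * sin(spec$tau * s_mid)))
      rows[[length(rows) + 1L]] <- data.frame(pf = pf, layer = eff$layer[i],
                                              k_from = k, expected = d,
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Apply a hinge (tilt and/or axial shift) to one layer
#'
#' Rotates the named layer of the target subunits by `angle_deg` about the
#' circumferential (tangential) axis through the layer's own centroid, and
#' optionally translates it axially by `shift`. Rotating about the layer
#' centroid decouples the imposed tilt from the imposed shift, so both are
#' exact ground truth for domain-motion recovery. Intended for straight
#' fixtures.
#'
#' @param assembly a `hook_assembly` from the generator.
#' @param truth matching ground-truth list.
#' @param layer layer name (e.g. `"D2"`).
#' @param angle_deg hinge angle in degrees, within [-45, 45].
#' @param shift axial translation of the layer (Angstrom, default 0).
#' @param chains chains to modify (default all).
#' @return the modified `hook_assembly`.
#' @export
apply_hinge <- function(assembly, truth, layer, angle_deg, shift = 0,
                        chains = names(assembly)) {
  stopifnot(inherits(assembly, "hook_assembly"))
  if (abs(angle_deg) > 45) stop("validation error: hinge angle outside [-45, 45] degrees")
  if (!layer %in% truth$spec$layers$name) stop("unknown layer: ", layer)
  res_layer <- truth$template$resno[truth$template$layer == layer]
  subs <- unclass(assembly)
  for (ch in chains) {
    s <- subs[[ch]]
    idx <- s$resno %in% res_layer
    xyz <- s$ca[idx, , drop = FALSE]
    pivot <- colMeans(xyz)
    phi <- atan2(pivot[2L], pivot[1L])
    axis <- c(-sin(phi), cos(phi), 0)    # circumferential direction
    Rm <- rot_axis_angle(axis, angle_deg * pi / 180)
    moved <- sweep(sweep(xyz, 2L, pivot) %*% t(Rm), 2L, pivot, `+`)
    moved[, 3L] <- moved[, 3L] + shift
    s$ca[idx, ] <- moved
    aidx <- s$atoms$resno %in% res_layer
    axyz <- as.matrix(s$atoms[aidx, c("x", "y", "z")])
    amoved <- sweep(sweep(axyz, 2L, pivot) %*% t(Rm), 2L, pivot, `+`)
    amoved[, 3L] <- amoved[, 3L] + shift
    s$atoms[aidx, c("x", "y", "z")] <- amoved
    subs[[ch]] <- s
  }
  new_assembly(subs)
}

#' Add isotropic Gaussian coordinate noise
#'
#' @param assembly a `hook_assembly`.
#' @param sd noise standard deviation per coordinate (Angstrom).
#' @param seed RNG seed (reproducible; caller RNG state is untouched).
#' @return the noisy `hook_assembly`.
#' @export
add_noise <- function(assembly, sd, seed = 1L) {
  stopifnot(inherits(assembly, "hook_assembly"), sd >= 0)
  if (sd == 0) return(assembly)
  subs <- unclass(assembly)
  with_local_seed(seed, {
    for (ch in names(subs)) {
      s <- subs[[ch]]
      n <- nrow(s$atoms)
      eps <- matrix(stats::rnorm(3L * n, 0, sd), n, 3L)
      s$atoms[, c("x", "y", "z")] <- as.matrix(s$atoms[, c("x", "y", "z")]) + eps
      ca_rows <- match(s$resno, s$atoms$resno[s$atoms$elety == "CA"])
      ca_tab <- s$atoms[s$atoms$elety == "CA", , drop = FALSE]
      ca_tab <- ca_tab[!duplicated(ca_tab$resno), , drop = FALSE]
      s$ca <- as.matrix(ca_tab[match(s$resno, ca_tab$resno), c("x", "y", "z")])
      rownames(s$ca) <- s$resno
      subs[[ch]] <- s
    }
  })
  new_assembly(subs)
}
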