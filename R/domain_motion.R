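# Rigid-domain motion decomposition: Kabsch superposition, conformation
# classes, domain shift/tilt relative to the inner reference domain,
# subunit length and extension.

#' Least-squares (Kabsch) superposition of paired point sets
#'
#' Finds the proper rigid transform `x -> R x + t` that minimizes the RMSD
#' of `moving` onto `fixed`, via SVD of the cross-covariance with the
#' determinant-corrected rotation.
#'
#' @param moving n x 3 matrix.
#' @param fixed n x 3 matrix, paired row-by-row with `moving`.
#' @return a `rigid_transform`: rotation `R` (3 x 3, det +1), translation
#'   `t`, `rmsd` (Angstrom), rotation `angle_deg` and rotation `axis`.
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed) || ncol(moving) != 3L || ncol(fixed) != 3L)
    stop("point sets must be paired n x 3 matrices")
  if (nrow(moving) < 3L) stop("degenerate input: need at least 3 points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2L, cm); B <- sweep(fixed, 2L, cf)
  if (min(svd(A)$d) < 1e-8 * max(svd(A)$d))
    stop("degenerate input: points are (near-)collinear")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cf - drop(R %*% cm)
  moved <- sweep(A %*% t(R), 2L, cf, `+`)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  ang <- acos(min(max((sum(diag(R)) - 1) / 2, -1), 1))
  axis <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  axis <- if (sqrt(sum(axis^2)) > 1e-9) unit3(axis) else c(NA_real_, NA_real_, NA_real_)
  structure(list(R = R, t = t, rmsd = rmsd,
                 angle_deg = ang * 180 / pi, axis = axis),
            class = "rigid_transform")
}

apply_transform <- function(xyz, tr) {
  sweep(as.matrix(xyz) %*% t(tr$R), 2L, tr$t, `+`)
}

# superposed CA RMSD between two subunits on their common residues
superposed_rmsd <- function(a, b) {
  common <- as.character(intersect(a$resno, b$resno))
  if (length(common) < 3L) stop("too few shared residues for superposition")
  kabsch_superpose(b$ca[common, , drop = FALSE], a$ca[common, , drop = FALSE])$rmsd
}

#' Group subunits into per-protofilament conformation classes
#'
#' Subunits are grouped by protofilament; the member closest to the axial
#' middle of the segment is the class representative. Within-class
#' superposed CA RMSDs are checked against `rmsd_tol` (violations are
#' reported, not fatal), and representative-vs-representative RMSDs between
#' azimuthally adjacent classes are reported. If all representatives are
#' conformationally identical (maximum between-class RMSD below
#' `uniform_tol`), the classes are positional only and
#' `conformationally_uniform` is set.
#'
#' @param assembly a `hook_assembly`.
#' @param lattice a `hook_lattice`.
#' @param rmsd_tol within-class RMSD tolerance (Angstrom, default 0.8).
#' @param uniform_tol between-class RMSD below which the assembly is
#'   flagged as a single conformational class (Angstrom).
#' @return list with `n_classes`, `representative` (chain per class),
#'   `within_max_rmsd`, `between_adjacent_rmsd`, `conformationally_uniform`
#'   and `warnings`.
#' @export
conformation_classes <- function(assembly, lattice, rmsd_tol = 0.8,
                                 uniform_tol = 0.1) {
  stopifnot(inherits(assembly, "hook_assembly"), inherits(lattice, "hook_lattice"))
  S <- lattice$start_number
  zmid <- mean(range(lattice$z))
  rep_chain <- character(S)
  within <- rep(NA_real_, S)
  warns <- character(0)
  for (p in seq_len(S)) {
    members <- lattice$chains[lattice$pf == p]
    if (length(members) == 0L) next
    rep_chain[p] <- members[which.min(abs(lattice$z[members] - zmid))]
    if (length(members) > 1L) {
      cmb <- utils::combn(members, 2L)
      r <- vapply(seq_len(ncol(cmb)), function(j)
        superposed_rmsd(assembly[[cmb[1L, j]]], assembly[[cmb[2L, j]]]), numeric(1L))
      within[p] <- max(r)
      if (max(r) > rmsd_tol)
        warns <- c(warns, sprintf("protofilament %d within-class RMSD %.2f A exceeds %.2f A",
                                  p, max(r), rmsd_tol))
    } else {
      within[p] <- 0
    }
  }
  present <- which(rep_chain != "")
  between <- rep(NA_real_, S)
  for (p in present) {
    q <- if (p == S) 1L else p + 1L
    if (rep_chain[q] != "")
      between[p] <- superposed_rmsd(assembly[[rep_chain[p]]], assembly[[rep_chain[q]]])
  }
  for (w in warns) warning(w)
  list(n_classes = length(present),
       representative = rep_chain,
       within_max_rmsd = within,
       between_adjacent_rmsd = between,
       conformationally_uniform = all(is.na(between) | between < uniform_tol),
       warnings = warns)
}

#' Pairwise superposed RMSD matrix of the class representatives
#'
#' All-against-all superposed CA RMSDs between the per-protofilament
#' conformer representatives; adjacent conformers around the circumference
#' differ the least.
#'
#' @param assembly a `hook_assembly`.
#' @param lattice a `hook_lattice`.
#' @return symmetric matrix (Angstrom) with representative chain ids as
#'   dimnames.
#' @export
class_rmsd_matrix <- function(assembly, lattice) {
  cl <- suppressWarnings(conformation_classes(assembly, lattice))
  reps <- cl$representative[cl$representative != ""]
  S <- length(reps)
  M <- matrix(0, S, S, dimnames = list(reps, reps))
  for (i in seq_len(S - 1L)) {
    for (j in (i + 1L):S) {
      M[i, j] <- M[j, i] <- superposed_rmsd(assembly[[reps[i]]], assembly[[reps[j]]])
    }
  }
  M
}

#' Relative domain motion between two subunit conformers
#'
#' Superposes the reference domain (default `D0c`) of `conf_b` onto that of
#' `conf_a`, then measures for every domain the residual rigid transform of
#' the aligned `conf_b` domain CA set relative to `conf_a`: the residual
#' rotation angle is the domain tilt, and the centroid displacement
#' projected on the local tube axis (positive toward the distal end) is the
#' axial shift.
#'
#' @param conf_a,conf_b `hook_subunit` conformers sharing residue numbering.
#' @param defs a `domain_set`.
#' @param axis_dir local tube-axis direction (length-3 unit vector) at the
#'   conformers' axial position.
#' @param reference name of the reference domain (default `"D0c"`).
#' @return a `domain_motion`: per-domain `tilt_deg`, `axial_shift`,
#'   `rmsd`, plus the reference-superposition transform.
#' @export
relative_domain_motion <- function(conf_a, conf_b, defs, axis_dir,
                                   reference = "D0c") {
  stopifnot(inherits(conf_a, "hook_subunit"), inherits(conf_b, "hook_subunit"))
  if (!reference %in% names(defs)) stop("reference domain ", reference, " not in defs")
  axis_dir <- unit3(axis_dir)
  dom_a <- assign_domains(conf_a, defs)
  sel <- function(sub, res) sub$ca[as.character(res), , drop = FALSE]
  common_dom <- lapply(names(defs), function(nm)
    intersect(intersect(dom_a[[nm]], conf_b$resno), conf_a$resno))
  names(common_dom) <- names(defs)
  for (nm in names(defs)) if (length(common_dom[[nm]]) < 3L)
    stop("configuration error: fewer than 3 shared residues in domain ", nm)
  ref_tr <- kabsch_superpose(sel(conf_b, common_dom[[reference]]),
                             sel(conf_a, common_dom[[reference]]))
  per_domain <- lapply(names(defs), function(nm) {
    a_xyz <- sel(conf_a, common_dom[[nm]])
    b_xyz <- apply_transform(sel(conf_b, common_dom[[nm]]), ref_tr)
    res <- kabsch_superpose(b_xyz, a_xyz)
    shift <- sum((colMeans(b_xyz) - colMeans(a_xyz)) * axis_dir)
    list(domain = nm, tilt_deg = res$angle_deg, axial_shift = shift,
         rmsd = res$rmsd, axis = res$axis)
  })
  names(per_domain) <- names(defs)
  structure(list(reference = reference, domains = per_domain,
                 reference_transform = ref_tr, axis_dir = axis_dir),
            class = "domain_motion")
}

#' @export
print.domain_motion <- function(x, ...) {
  cat("domain_motion (reference", x$reference, "):\n")
  for (d in x$domains)
    cat(sprintf("  %-4s tilt %6.2f deg  axial shift %+6.2f A  residual rmsd %.3f A\n",
                d$domain, d$tilt_deg, d$axial_shift, d$rmsd))
  invisible(x)
}

#' Subunit length along the protofilament direction
#'
#' Length is the extent (max minus min) of the CA projections onto the
#' local protofilament direction, which for a near-axial protofilament is
#' the local tube-axis direction.
#'
#' @param sub a `hook_subunit`.
#' @param axis_dir local axis direction (length-3).
#' @return length in Angstrom.
#' @export
subunit_length <- function(sub, axis_dir) {
  proj <- drop(sub$ca %*% unit3(axis_dir))
  diff(range(proj))
}

#' Subunit length extension between two conformers
#'
#' @param conf_a,conf_b `hook_subunit` conformers (extended, compressed).
#' @param axis_dir local axis direction.
#' @return `length(conf_a) - length(conf_b)` in Angstrom.
#' @export
extension <- function(conf_a, conf_b, axis_dir) {
  subunit_length(conf_a, axis_dir) - subunit_length(conf_b, axis_dir)
}

#' Tilt of a domain relative to the tube axis
#'
#' Angle between the domain's longest principal axis (CA inertia) and the
#' local tube-axis direction, folded to [0, 90] degrees.
#'
#' @param sub a `hook_subunit`.
#' @param defs a `domain_set`.
#' @param domain domain name.
#' @param axis_dir local axis direction.
#' @return angle in degrees.
#' @export
domain_axis_tilt <- function(sub, defs, domain, axis_dir) {
  res <- assign_domains(sub, defs)[[domain]]
  if (length(res) < 3L) stop("domain ", domain, " has fewer than 3 residues")
  xyz <- sub$ca[as.character(res), , drop = FALSE]
  pc1 <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors[, 1L]
  ang <- acos(min(abs(sum(unit3(pc1) * unit3(axis_dir))), 1)) * 180 / pi
  ang
}
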