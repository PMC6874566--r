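# Helical lattice indexing: tube axis, 1-start ordering, neighbour maps,
# protofilament assignment.

# Straight axis through a tubular point cloud: minimizes the variance of
# point-to-line distances (cylinder-style fit), multi-started from the three
# principal directions so the result does not depend on whether the tube is
# longer than it is wide.
fit_cylinder_axis <- function(P) {
  P <- as.matrix(P)
  m <- colMeans(P)
  ev <- eigen(stats::cov(P), symmetric = TRUE)$vectors
  best <- NULL
  for (j in 1:3) {
    a0 <- ev[, j]
    e <- perp_basis(a0)
    obj <- function(par) {
      d <- unit3(a0 + par[1L] * e[, 1L] + par[2L] * e[, 2L])
      p0 <- m + par[3L] * e[, 1L] + par[4L] * e[, 2L]
      X <- sweep(P, 2L, p0)
      proj <- drop(X %*% d)
      rho <- sqrt(pmax(rowSums(X^2) - proj^2, 0))
      stats::var(rho)
    }
    o <- stats::optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- c(o, list(a0 = a0, e = e))
  }
  d <- unit3(best$a0 + best$par[1L] * best$e[, 1L] + best$par[2L] * best$e[, 2L])
  p0 <- m + best$par[3L] * best$e[, 1L] + best$par[4L] * best$e[, 2L]
  list(dir = d, point = p0, spread = best$value)
}

# Savitzky-Golay style smoothing of polyline vertices: local polynomial fit
# per coordinate against cumulative chord length. Suppresses the residual
# lattice-frequency ripple of sliding-window centroids without biasing
# smooth curvature.
cum_chord <- function(P) {
  m <- nrow(P)
  c(0, cumsum(sqrt(rowSums((P[-1L, , drop = FALSE] - P[-m, , drop = FALSE])^2))))
}

# local polynomial regression of vertex coordinates against arclength:
# predictions at eval_s use a window of the nearest data vertices
local_poly_eval <- function(P, s, eval_s, degree, half_window) {
  t(vapply(eval_s, function(s0) {
    i0 <- which.min(abs(s - s0))
    idx <- max(1L, i0 - half_window):min(length(s), i0 + half_window)
    deg <- min(degree, length(idx) - 2L)
    if (deg < 1L) return(P[i0, ])
    X <- outer(s[idx] - s0, 0:deg, `^`)
    coefs <- qr.coef(qr(X), P[idx, , drop = FALSE])
    coefs[1L, ]
  }, numeric(3L)))
}

smooth_polyline <- function(pts, degree = 4L, half_window = 25L, extend = 0L) {
  pts <- as.matrix(pts)
  nv <- nrow(pts)
  if (nv < degree + 3L) return(pts)
  # vertices corrupted by a locally mis-ordered window are rejected outright
  # before smoothing, so they distort neither the fit nor the arclength
  # parameterization
  keep <- rep(TRUE, nv)
  for (round in 1:3) {
    P <- pts[keep, , drop = FALSE]
    s <- cum_chord(P)
    fitted <- local_poly_eval(P, s, s, degree, half_window)
    resid <- sqrt(rowSums((P - fitted)^2))
    thr <- max(4 * stats::median(resid), 0.5)
    if (all(resid <= thr)) break
    cand <- keep
    cand[which(keep)[resid > thr]] <- FALSE
    if (sum(cand) < degree + 3L) break
    keep <- cand
  }
  P <- pts[keep, , drop = FALSE]
  s <- cum_chord(P)
  m <- nrow(P)
  ds_mean <- (s[m] - s[1L]) / (m - 1L)
  grid <- seq(s[1L] - extend * ds_mean, s[m] + extend * ds_mean, by = ds_mean)
  inside <- grid >= s[1L] & grid <= s[m]
  out <- matrix(NA_real_, length(grid), 3L)
  out[inside, ] <- local_poly_eval(P, s, grid[inside], degree, half_window)
  if (any(!inside)) {
    # extrapolate with a local quadratic (osculating circle) over the
    # terminal vertices: higher degrees diverge quickly beyond the data
    extrap <- function(at_s, tail_end) {
      idx <- if (tail_end) seq(max(1L, m - 10L), m) else seq_len(min(m, 11L))
      s0 <- if (tail_end) s[m] else s[1L]
      X <- outer(s[idx] - s0, 0:2, `^`)
      coefs <- qr.coef(qr(X), P[idx, , drop = FALSE])
      drop(outer(at_s - s0, 0:2, `^`) %*% coefs)
    }
    lo <- !inside & grid < s[1L]
    hi <- !inside & grid > s[m]
    if (any(lo)) out[lo, ] <- extrap(grid[lo], FALSE)
    if (any(hi)) out[hi, ] <- extrap(grid[hi], TRUE)
  }
  attr(out, "interior") <- inside
  out
}

# Initial 1-start ordering from the helical coordinate about a fitted
# cylinder axis. Subunit centroids wind helically about the axis (the
# local tube axis for short segments, the superhelix axis for assemblies
# that wrap a substantial part of a supercoil turn); the circle wobble of
# the lattice is perpendicular to that helix's tangent, so the
# tangent-projected coordinate R^2*theta + h*z orders subunits far more
# reliably than the axial projection alone.
# Combine a coarse arclength estimate s (reliable to +- pi/a, where a is
# the lattice twist rate per Angstrom) with the winding phase th measured
# about the tube: th selects the position within each 2*pi branch to
# ~(azimuth error)/a, while s selects the branch, so the combination beats
# either coordinate alone. Returns the phase-corrected arclength, or NULL
# when no consistent winding exists.
phase_coordinate <- function(s_raw, th) {
  ordz <- order(s_raw)
  rise <- stats::median(diff(s_raw[ordz]))
  if (!is.finite(rise) || rise <= 1e-6) return(NULL)
  # twist rate by periodogram: the concentration of (th - a*s) mod 2*pi
  # peaks at the true winding rate, and unlike a median of consecutive
  # steps it does not require the coarse ordering to be correct
  agrid <- seq(-0.45, 0.45, by = 5e-4)
  agrid <- agrid[abs(agrid) > 1e-3]
  conc <- vapply(agrid, function(aa)
    Mod(mean(exp(1i * (th - aa * s_raw)))), numeric(1L))
  a <- agrid[which.max(conc)]
  if (max(conc) < 0.2) {
    a <- stats::median(wrap_angle(diff(th[ordz]))) / rise
  }
  if (!is.finite(a) || abs(a) < 1e-5) return(NULL)
  for (round in 1:3) {
    n <- round((a * s_raw - th) / (2 * pi))
    th_un <- th + 2 * pi * n
    cf <- stats::coef(stats::lm(th_un ~ s_raw))
    if (any(!is.finite(cf)) || abs(cf[2L]) < 1e-6 ||
        sign(cf[2L]) != sign(a)) break
    a <- cf[2L]
    th <- th - cf[1L]    # absorb the phase offset so rounding is centred
  }
  n <- round((a * s_raw - th) / (2 * pi))
  s <- (th + 2 * pi * n) / a
  # a residual branch error displaces a subunit by exactly one winding
  # period, leaving a duplicated lattice slot and a hole: repair by moving
  # duplicated members one period into a free slot
  period <- 2 * pi / a
  for (rep in 1:6) {
    ordl <- order(s)
    rise2 <- stats::median(diff(s[ordl]))
    if (!is.finite(rise2) || rise2 <= 1e-6) break
    k <- round((s - min(s)) / rise2)
    cf2 <- tryCatch(stats::coef(stats::lm(s ~ k)), error = function(e) NULL)
    if (is.null(cf2) || !is.finite(cf2[2L]) || cf2[2L] <= 1e-6) break
    k <- round((s - cf2[1L]) / cf2[2L])
    dup_slots <- unique(k[duplicated(k)])
    if (length(dup_slots) == 0L) break
    changed <- FALSE
    for (sl in dup_slots) {
      members <- which(k == sl)
      best <- NULL
      for (i in members) {
        for (m in c(-1, 1)) {
          cand <- s[i] + m * period
          kc <- round((cand - cf2[1L]) / cf2[2L])
          if (any(k[-i] == kc)) next
          rsd <- abs(cand - cf2[1L] - kc * cf2[2L])
          if (rsd > 0.35 * cf2[2L]) next
          if (is.null(best) || rsd < best$rsd)
            best <- list(i = i, cand = cand, kc = kc, rsd = rsd)
        }
      }
      if (!is.null(best)) {
        s[best$i] <- best$cand
        k[best$i] <- best$kc
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (stats::cor(s, s_raw) < 0) s <- -s
  s
}

helical_order_coordinate <- function(cen, ax) {
  X <- sweep(cen, 2L, ax$point)
  z <- drop(X %*% ax$dir)
  e <- perp_basis(ax$dir)
  rad <- X - outer(z, ax$dir)
  th <- atan2(drop(rad %*% e[, 2L]), drop(rad %*% e[, 1L]))
  s <- phase_coordinate(z, th)
  if (is.null(s)) z else s
}

# Gaussian kernel mean of positions against an arclength estimate: a
# single coarse principal-curve pass (not iterated; repeated passes
# contract the curve). Used to linearize strongly bent segments before
# phase ordering.
kernel_curve <- function(P, s, bandwidth = 25, step = 4) {
  grid <- seq(min(s), max(s), by = step)
  if (length(grid) < 3L) return(NULL)
  t(vapply(grid, function(s0) {
    w <- exp(-0.5 * ((s - s0) / bandwidth)^2)
    colSums(P * w) / sum(w)
  }, numeric(3L)))
}

# phase ordering in curved coordinates: arclength and parallel-transport
# azimuth about a coarse kernel principal curve
curved_order_coordinate <- function(cen, proj) {
  curve <- kernel_curve(cen, proj)
  if (is.null(curve)) return(NULL)
  pr <- tryCatch(polyline_project(cen, curve), error = function(e) NULL)
  if (is.null(pr)) return(NULL)
  phase_coordinate(pr$s, pr$phi)
}

# Lattice-phase correction of arclength estimates. On a 1-start helical
# lattice the material azimuth advances by a fixed step per subunit, so
# the azimuth measured in the parallel-transport frame pins each subunit
# to its lattice position much more sharply than the axial projection
# alone: an arclength error ds shifts the phase residual by -a*ds with
# a = twist rate per Angstrom (~0.28 rad/A here). Returns corrected
# arclengths, or NULL when no consistent phase model exists.
lattice_phase_correct <- function(cen, poly) {
  pr <- polyline_project(cen, poly)
  n <- nrow(cen)
  if (n < 8L) return(NULL)
  ord <- order(pr$s)
  dss <- diff(pr$s[ord])
  rise <- stats::median(dss)
  if (!is.finite(rise) || rise <= 1e-3) return(NULL)
  a <- stats::median(wrap_angle(diff(pr$phi[ord]))) / rise
  if (!is.finite(a) || abs(a) < 1e-4) return(NULL)
  s_ord <- pr$s[ord]
  zeta <- unwrap_angles(pr$phi[ord] - a * s_ord)
  # slow drift of the phase offset (torsion precession, frame drift)
  X <- outer(s_ord - mean(s_ord), 0:3, `^`)
  cf <- qr.coef(qr(X), zeta)
  for (r in 1:2) {
    resid <- drop(zeta - X %*% cf)
    keep <- abs(resid) <= pmax(4 * stats::mad(resid), 0.2)
    if (sum(keep) < 6L) break
    cf <- qr.coef(qr(X[keep, , drop = FALSE]), zeta[keep])
  }
  resid <- wrap_angle(drop(zeta - X %*% cf))
  s_corr <- numeric(n)
  s_corr[ord] <- s_ord + resid / a
  s_corr
}

#' Estimate the tube-axis polyline of a helical assembly
#'
#' Subunit centroids are ordered along a fitted straight reference axis and
#' averaged over a sliding window of `window` consecutive subunits. With
#' `window` equal to the start number (default 11, i.e. two full turns of
#' the 1-start helix) the circular lattice component cancels and the window
#' means trace the tube centerline. Vertices are then smoothed by a local
#' polynomial filter. For assemblies too short to support at least four
#' window positions, the fitted straight axis itself is returned as the
#' polyline.
#'
#' @param assembly a `hook_assembly`.
#' @param window sliding-window size in subunits (default 11).
#' @param smooth logical; apply the local-polynomial smoothing pass.
#' @return an n x 3 matrix of ordered polyline vertices (Angstrom) with
#'   attribute `order` (subunit indices ordered along the axis).
#' @export
estimate_tube_axis <- function(assembly, window = 11L, smooth = TRUE) {
  stopifnot(inherits(assembly, "hook_assembly"))
  cen <- assembly_centroids(assembly)
  n <- nrow(cen)
  if (n < window) stop("insufficient data: need at least ", window, " subunits")
  ax <- fit_cylinder_axis(cen)
  proj <- drop(sweep(cen, 2L, ax$point) %*% ax$dir)
  xi <- tryCatch(helical_order_coordinate(cen, ax), error = function(e) proj)
  ord <- order(xi)
  nv <- n - window + 1L
  if (nv < 4L) {
    # short assembly: straight-axis fallback, one vertex per subunit
    poly <- t(vapply(sort(proj), function(t) ax$point + t * ax$dir, numeric(3L)))
    attr(poly, "order") <- ord
    attr(poly, "straight_fallback") <- TRUE
    return(poly)
  }
  # the window means only cover the interior; extrapolate the smoothed
  # polyline by half a window at each end so terminal subunits project
  # onto the curved axis rather than a straight extension
  ext <- ceiling(window / 2) + 2L
  build <- function(ord) {
    sorted <- cen[ord, , drop = FALSE]
    poly <- t(vapply(seq_len(nv), function(i)
      colMeans(sorted[i:(i + window - 1L), , drop = FALSE]), numeric(3L)))
    if (smooth) poly <- smooth_polyline(poly, extend = ext)
    poly
  }
  # a straight reference axis can mis-order subunits along a curved
  # segment; re-project onto the curved polyline until the order is stable
  # quality: subunit centroids of a tubular lattice sit at a constant
  # transverse radius from the true centerline
  assess <- function(ord) {
    poly <- build(ord)
    pr <- polyline_project(cen, poly)
    list(poly = poly, ord = ord,
         quality = stats::sd(pr$rho) / (mean(pr$rho) + 1e-9),
         s = pr$s)
  }
  refine <- function(ord) {
    best <- cur <- assess(ord)
    for (it in 1:5) {
      ord2 <- order(cur$s)
      if (identical(ord2, cur$ord)) break
      cur <- assess(ord2)
      if (cur$quality < best$quality) best <- cur
    }
    best
  }
  res <- refine(ord)
  if (res$quality > 0.02) {
    # straight-axis phase ordering can break on strongly bent segments
    # (branch errors): retry in curved coordinates, and from the plain
    # axial projection as a last resort
    xi2 <- curved_order_coordinate(cen, proj)
    if (!is.null(xi2)) {
      res2 <- refine(order(xi2))
      if (res2$quality < res$quality) res <- res2
    }
    if (res$quality > 0.15) {
      res3 <- refine(order(proj))
      if (res3$quality < res$quality) res <- res3
    }
  }
  # local search: residual ordering errors show up as corrupted window
  # means that widen the transverse-radius spread; greedy adjacent
  # transpositions minimize it directly (short assemblies only - the
  # search is quadratic in subunit count)
  if (res$quality > 0.02 && n <= 60L) {
    candidate_orders <- function(ord) {
      outs <- list()
      for (j in seq_len(n - 1L)) {
        o <- ord
        o[c(j, j + 1L)] <- o[c(j + 1L, j)]
        outs[[length(outs) + 1L]] <- o
      }
      # displacements by two escape the single-swap local minima
      for (j in seq_len(n)) {
        for (tgt in c(j - 2L, j + 2L)) {
          if (tgt < 1L || tgt > n) next
          o <- append(ord[-j], ord[j], after = tgt - 1L)
          outs[[length(outs) + 1L]] <- o
        }
      }
      outs
    }
    for (round in 1:10) {
      improved <- FALSE
      for (ord2 in candidate_orders(res$ord)) {
        r2 <- assess(ord2)
        if (r2$quality < res$quality - 1e-6) {
          res <- r2
          improved <- TRUE
        }
      }
      if (!improved || res$quality <= 0.02) break
    }
  }
  # final polish: correct residual ordering errors with the lattice phase
  for (round in 1:3) {
    s_corr <- lattice_phase_correct(cen, res$poly)
    if (is.null(s_corr)) break
    ord2 <- order(s_corr)
    if (identical(ord2, res$ord)) break
    poly2 <- build(ord2)
    pr2 <- polyline_project(cen, poly2)
    q2 <- stats::sd(pr2$rho) / (mean(pr2$rho) + 1e-9)
    if (q2 <= res$quality + 1e-9) {
      res <- list(poly = poly2, ord = ord2, quality = q2)
    } else break
  }
  poly <- res$poly
  attr(poly, "order") <- res$ord
  attr(poly, "straight_fallback") <- FALSE
  poly
}

# interior (non-extrapolated) part of an axis polyline; the quadratic end
# extensions exist for projection robustness and carry no torsion signal,
# so curvature/torsion estimation must not see them
axis_interior <- function(poly) {
  inside <- attr(poly, "interior")
  if (is.null(inside)) poly else poly[inside, , drop = FALSE]
}

#' Index subunits on the 1-start helical lattice
#'
#' Orders subunits by axial position along the (oriented) tube axis,
#' assigns the 0-based 1-start index k, builds the +5/+6/+11 neighbour
#' maps and the provisional protofilament ids `(k mod start_number) + 1`.
#' The axis is oriented so that the azimuthal step between consecutive
#' subunits is positive (right-handed 1-start); the numbering origin is the
#' axially lowest subunit. Azimuths are measured in a parallel-transport
#' frame along the axis polyline.
#'
#' @param assembly a `hook_assembly`.
#' @param start_number number of protofilaments (default 11).
#' @param axis optional axis polyline from [estimate_tube_axis()].
#' @param max_step_sd_deg lattice-consistency threshold: maximum circular
#'   standard deviation of the consecutive-subunit azimuthal steps.
#' @return a `hook_lattice`: chain order, k, protofilament ids, cylindrical
#'   coordinates (z, phi, rho), per-subunit local tangent, axis polyline
#'   and neighbour maps.
#' @export
index_lattice <- function(assembly, start_number = 11L, axis = NULL,
                          max_step_sd_deg = 15) {
  stopifnot(inherits(assembly, "hook_assembly"))
  n <- length(assembly)
  if (n < start_number)
    stop("insufficient data: need at least start_number subunits")
  if (is.null(axis)) axis <- estimate_tube_axis(assembly, window = start_number)
  cen <- assembly_centroids(assembly)

  build <- function(poly) {
    frames <- pt_frames(poly)
    pr <- polyline_project(cen, poly, frames)
    ord <- order(pr$s)
    dphi <- wrap_angle(diff(pr$phi[ord]))
    list(pr = pr, ord = ord, mean_step = circular_mean(dphi), dphi = dphi)
  }
  b <- build(axis)
  if (b$mean_step < 0) {
    flipped <- axis[rev(seq_len(nrow(axis))), , drop = FALSE]
    if (!is.null(attr(axis, "interior")))
      attr(flipped, "interior") <- rev(attr(axis, "interior"))
    axis <- flipped
    b <- build(axis)
  }
  step_sd <- circular_sd(b$dphi) * 180 / pi
  if (step_sd >= max_step_sd_deg) {
    worst <- order(abs(b$dphi - b$mean_step), decreasing = TRUE)[1:min(3L, length(b$dphi))]
    stop("inconsistent lattice: circular SD of azimuthal steps ",
         sprintf("%.1f", step_sd), " deg >= ", max_step_sd_deg,
         " deg (offending subunits near order positions ",
         paste(worst, collapse = ", "), ")")
  }
  chains <- names(assembly)[b$ord]
  k <- seq_len(n) - 1L
  names(k) <- chains
  pf <- (k %% start_number) + 1L
  dirs <- unique(c(5L, 6L, as.integer(start_number)))
  nbr <- lapply(dirs, function(d) {
    from <- k[k + d <= max(k)]
    data.frame(k_from = unname(from), k_to = unname(from) + d,
               chain_from = chains[from + 1L], chain_to = chains[from + d + 1L],
               stringsAsFactors = FALSE)
  })
  names(nbr) <- as.character(dirs)
  z <- b$pr$s[b$ord]; names(z) <- chains
  phi <- b$pr$phi[b$ord]; names(phi) <- chains
  rho <- b$pr$rho[b$ord]; names(rho) <- chains
  tangent <- b$pr$tangent[b$ord, , drop = FALSE]
  rownames(tangent) <- chains
  structure(list(chains = chains, k = k, pf = pf, z = z, phi = phi, rho = rho,
                 tangent = tangent, axis = axis, start_number = as.integer(start_number),
                 neighbors = nbr, step_sd_deg = step_sd,
                 mean_step_deg = b$mean_step * 180 / pi),
            class = "hook_lattice")
}

#' @export
print.hook_lattice <- function(x, ...) {
  cat("hook_lattice:", length(x$k), "subunits,", x$start_number,
      "protofilaments; mean 1-start step", sprintf("%.2f", x$mean_step_deg),
      "deg (SD", sprintf("%.2f", x$step_sd_deg), "deg)\n")
  invisible(x)
}

#' Neighbour pairs along a helical direction
#'
#' @param lattice a `hook_lattice`.
#' @param direction one of 5, 6, 11 (the -5/6/11-start contact directions).
#' @return data.frame with `k_from`, `k_to`, `chain_from`, `chain_to`.
#' @export
neighbor_pairs <- function(lattice, direction) {
  d <- as.character(direction)
  if (!d %in% names(lattice$neighbors)) stop("invalid direction: ", direction)
  lattice$neighbors[[d]]
}

# circular azimuth of each protofilament (mean over member subunits)
protofilament_azimuths <- function(lattice) {
  vapply(seq_len(lattice$start_number), function(p) {
    circular_mean(lattice$phi[lattice$pf == p])
  }, numeric(1L))
}

#' Renumber protofilaments by the extended/compressed convention
#'
#' Protofilament 1 is the one with the largest mean axial spacing (the
#' extended side of the bend); ids then increase consecutively around the
#' circumference in the direction that places the smallest mean spacing at
#' id 7 (or 6). Ties in the largest mean beyond `tol` Angstrom are broken
#' deterministically by lowest azimuth, with a warning.
#'
#' @param lattice a `hook_lattice`.
#' @param profile a `pf_profile` from [axial_distance_map()] computed on the
#'   same lattice (its protofilament ids must match).
#' @param tol tie tolerance on the largest mean spacing (Angstrom).
#' @return the lattice with `pf` renumbered; attribute `pf_map` gives the
#'   old-to-new id mapping.
#' @export
renumber_protofilaments <- function(lattice, profile, tol = 0.05) {
  stopifnot(inherits(lattice, "hook_lattice"), inherits(profile, "pf_profile"))
  S <- lattice$start_number
  means <- profile$pf_mean
  if (length(means) != S) stop("profile does not cover all protofilaments")
  az <- protofilament_azimuths(lattice)
  top <- which(means >= max(means) - tol)
  if (length(top) > 1L) {
    warning("tie for the most extended protofilament; breaking by lowest azimuth")
    anchor <- top[which.min(wrap_angle(az[top]) %% (2 * pi))]
  } else {
    anchor <- top
  }
  ring <- order(az)                       # azimuthal order of old ids
  pos <- match(seq_len(S), ring)          # position of each old id on the ring
  ids_for <- function(dirn) {
    offs <- ((pos - pos[anchor]) * dirn) %% S
    offs + 1L
  }
  cand <- list(ids_for(1L), ids_for(-1L))
  minpf <- which.min(means)
  id_min <- vapply(cand, function(ids) ids[minpf], integer(1L))
  pick <- if (any(id_min == 7L)) which(id_min == 7L)[1L]
          else if (any(id_min == 6L)) which(id_min == 6L)[1L] else 1L
  map <- cand[[pick]]
  lattice$pf <- map[lattice$pf]
  names(lattice$pf) <- lattice$chains
  attr(lattice, "pf_map") <- map
  attr(lattice, "pf_direction") <- if (pick == 1L) "ccw" else "cw"
  lattice
}

#' Export a lattice as JSON
#'
#' @param lattice a `hook_lattice`.
#' @param path output path.
#' @export
write_lattice_json <- function(lattice, path) {
  out <- list(start_number = lattice$start_number,
              chains = lattice$chains,
              k = as.list(lattice$k),
              protofilament = as.list(lattice$pf),
              z = as.list(round(lattice$z, 4)),
              phi_deg = as.list(round(lattice$phi * 180 / pi, 3)),
              neighbors = lattice$neighbors,
              step_sd_deg = lattice$step_sd_deg,
              axis = unname(apply(lattice$axis, 1L, function(r) round(r, 4), simplify = FALSE)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
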