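# Low-level 3D geometry helpers shared across modules.

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (!is.finite(n) || n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula for the rotation by `theta` (radians) about the unit
#' direction `axis`.
#'
#' @param axis numeric length-3 direction (normalized internally).
#' @param theta rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis_angle <- function(axis, theta) {
  a <- unit3(axis)
  K <- matrix(c(0, a[3L], -a[2L],
                -a[3L], 0, a[1L],
                a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

circular_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

# circular standard deviation (radians); 0 for perfectly concentrated angles
circular_sd <- function(a) {
  rbar <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  rbar <- min(max(rbar, 1e-12), 1)
  sqrt(-2 * log(rbar))
}

# two unit vectors spanning the plane perpendicular to d
perp_basis <- function(d) {
  d <- unit3(d)
  ref <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(cross3(d, ref))
  e2 <- cross3(d, e1)
  cbind(e1, e2)
}

#' Parallel-transport (rotation-minimizing) frames along a polyline
#'
#' Computes tangents by central differences and propagates a twist-free
#' normal pair along the vertices with the double-reflection method. The
#' frame is used to measure subunit azimuths consistently along a curved
#' tube axis without introducing spurious lattice twist.
#'
#' @param pts n x 3 matrix of ordered polyline vertices.
#' @return list with n x 3 matrices `tangent`, `n1`, `n2`.
#' @keywords internal
pt_frames <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 polyline vertices for frames")
  tg <- matrix(0, n, 3L)
  tg[1L, ] <- pts[2L, ] - pts[1L, ]
  tg[n, ] <- pts[n, ] - pts[n - 1L, ]
  if (n > 2L) tg[2:(n - 1L), ] <- pts[3:n, , drop = FALSE] - pts[1:(n - 2L), , drop = FALSE]
  tg <- t(apply(tg, 1L, unit3))
  n1 <- matrix(0, n, 3L)
  n2 <- matrix(0, n, 3L)
  n1[1L, ] <- perp_basis(tg[1L, ])[, 1L]
  n2[1L, ] <- cross3(tg[1L, ], n1[1L, ])
  for (i in seq_len(n - 1L)) {
    # double reflection (Wang et al. 2008): reflect in the chord bisector,
    # then in the bisector of the reflected and next tangent
    v1 <- pts[i + 1L, ] - pts[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-20) stop("degenerate polyline: coincident consecutive vertices")
    rl <- n1[i, ] - (2 / c1) * sum(v1 * n1[i, ]) * v1
    tl <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1L, ] - tl
    c2 <- sum(v2 * v2)
    n1[i + 1L, ] <- if (c2 < 1e-20) rl else rl - (2 / c2) * sum(v2 * rl) * v2
    # keep exactly orthonormal to the tangent
    n1[i + 1L, ] <- unit3(n1[i + 1L, ] - sum(n1[i + 1L, ] * tg[i + 1L, ]) * tg[i + 1L, ])
    n2[i + 1L, ] <- cross3(tg[i + 1L, ], n1[i + 1L, ])
  }
  list(tangent = tg, n1 = n1, n2 = n2)
}

# Arclength coordinate, transverse offset, azimuth and local tangent of
# points relative to a polyline with parallel-transport frames.
# Points beyond the ends are extrapolated along the terminal segments.
polyline_project <- function(points, poly, frames = NULL) {
  poly <- as.matrix(poly)
  points <- as.matrix(points)
  nv <- nrow(poly)
  if (nv < 2L) stop("polyline needs at least 2 vertices")
  if (is.null(frames)) frames <- pt_frames(poly)
  seg <- poly[-1L, , drop = FALSE] - poly[-nv, , drop = FALSE]
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len < 1e-9)) stop("degenerate polyline: zero-length segment")
  cum <- c(0, cumsum(seg_len))
  np <- nrow(points)
  out <- data.frame(s = numeric(np), rho = numeric(np), phi = numeric(np))
  tangents <- matrix(0, np, 3L)
  for (i in seq_len(np)) {
    p <- points[i, ]
    best <- NULL
    for (j in seq_len(nv - 1L)) {
      d <- seg[j, ] / seg_len[j]
      t <- sum((p - poly[j, ]) * d)
      tc <- min(max(t, 0), seg_len[j])
      foot <- poly[j, ] + tc * d
      dist2 <- sum((p - foot)^2)
      if (is.null(best) || dist2 < best$dist2) {
        best <- list(dist2 = dist2, j = j, t = tc, foot = foot, d = d, t_raw = t)
      }
    }
    # points beyond the polyline ends extrapolate along the terminal segments
    if (best$j == 1L && best$t_raw < 0) {
      best$t <- best$t_raw
      best$foot <- poly[1L, ] + best$t * best$d
    } else if (best$j == nv - 1L && best$t_raw > seg_len[best$j]) {
      best$t <- best$t_raw
      best$foot <- poly[best$j, ] + best$t * best$d
    }
    j <- best$j
    w <- min(max(best$t / seg_len[j], 0), 1)
    tg <- unit3((1 - w) * frames$tangent[j, ] + w * frames$tangent[j + 1L, ])
    n1 <- (1 - w) * frames$n1[j, ] + w * frames$n1[j + 1L, ]
    n1 <- unit3(n1 - sum(n1 * tg) * tg)
    n2 <- cross3(tg, n1)
    off <- p - best$foot
    x <- sum(off * n1)
    y <- sum(off * n2)
    out$s[i] <- cum[j] + best$t
    out$rho[i] <- sqrt(x * x + y * y)
    out$phi[i] <- atan2(y, x)
    tangents[i, ] <- tg
  }
  out$tangent <- tangents
  out
}

# Evaluate with a temporarily-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
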