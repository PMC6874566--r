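# Inter-subunit contact enumeration along the -5/6/11-start directions,
# constant/switching classification across the protofilament contexts, and
# per-residue neighbour-distance variability.

# squared-distance-safe cross distance matrix between two coordinate sets
cross_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# representative neighbour pair per protofilament context: the pair whose
# axial midpoint is closest to the segment middle (minimizes end effects)
context_pairs <- function(lattice, direction) {
  pairs <- neighbor_pairs(lattice, direction)
  if (nrow(pairs) == 0L) stop("no +", direction, " pairs in the lattice")
  zmid <- mean(range(lattice$z))
  pairs$pf <- lattice$pf[pairs$chain_from]
  pairs$z_pair <- (lattice$z[pairs$chain_from] + lattice$z[pairs$chain_to]) / 2
  out <- do.call(rbind, lapply(split(pairs, pairs$pf), function(g)
    g[which.min(abs(g$z_pair - zmid)), , drop = FALSE]))
  rownames(out) <- NULL
  out
}

# minimum heavy-atom distance per residue pair for one subunit pair;
# returns data.frame(res_a, res_b, dist) for pairs with dist <= max_dist
min_residue_distances <- function(sub_a, sub_b, max_dist, block = 400L) {
  A <- as.matrix(sub_a$atoms[, c("x", "y", "z")])
  B <- as.matrix(sub_b$atoms[, c("x", "y", "z")])
  ra <- sub_a$atoms$resno
  rb <- sub_b$atoms$resno
  hits <- list()
  for (lo in seq(1L, nrow(A), by = block)) {
    hi <- min(lo + block - 1L, nrow(A))
    D <- cross_dist(A[lo:hi, , drop = FALSE], B)
    idx <- which(D <= max_dist, arr.ind = TRUE)
    if (nrow(idx)) {
      hits[[length(hits) + 1L]] <- data.frame(res_a = ra[lo:hi][idx[, 1L]],
                                              res_b = rb[idx[, 2L]],
                                              dist = D[idx])
    }
  }
  if (!length(hits)) return(data.frame(res_a = integer(), res_b = integer(), dist = numeric()))
  all <- do.call(rbind, hits)
  out <- stats::aggregate(dist ~ res_a + res_b, all, min)
  out
}

#' Enumerate inter-subunit residue contacts along a helical direction
#'
#' For each protofilament context (one representative subunit pair per
#' protofilament along the +5, +6 or +11 direction), residue pairs whose
#' minimum heavy-atom distance is within `cutoff` are recorded. The union
#' of contacting pairs is then tracked across all contexts: a pair present
#' in every context is `constant`, a pair present in at least one and
#' absent in at least one is `switching`.
#'
#' @param assembly a `hook_assembly`.
#' @param lattice a `hook_lattice` (protofilaments renumbered or not).
#' @param direction 5, 6 or 11.
#' @param cutoff contact distance cutoff (Angstrom, default 4.0).
#' @param track_margin extra margin (Angstrom) up to which out-of-contact
#'   distances of tracked pairs are still resolved (beyond it they are
#'   reported as `Inf`).
#' @return a `contact_table` data.frame: `res_a`, `res_b`, one distance
#'   column per context (`pf_<id>`), `mean`, `sd`, `n_present`, `class`;
#'   attributes `direction`, `cutoff`, `contexts`.
#' @export
find_contacts <- function(assembly, lattice, direction, cutoff = 4.0,
                          track_margin = 6.0) {
  stopifnot(inherits(assembly, "hook_assembly"), inherits(lattice, "hook_lattice"))
  if (!as.character(direction) %in% names(lattice$neighbors))
    stop("invalid direction: ", direction)
  ctx <- context_pairs(lattice, direction)
  if (cutoff <= 0) {
    out <- data.frame(res_a = integer(), res_b = integer())
    attr(out, "direction") <- direction
    attr(out, "cutoff") <- cutoff
    attr(out, "contexts") <- ctx
    class(out) <- c("contact_table", "data.frame")
    return(out)
  }
  per_ctx <- lapply(seq_len(nrow(ctx)), function(i)
    min_residue_distances(assembly[[ctx$chain_from[i]]],
                          assembly[[ctx$chain_to[i]]],
                          max_dist = cutoff + track_margin))
  keys <- unique(do.call(rbind, lapply(per_ctx, function(d) {
    d <- d[d$dist <= cutoff, c("res_a", "res_b"), drop = FALSE]
    d
  })))
  if (is.null(keys) || nrow(keys) == 0L) {
    out <- data.frame(res_a = integer(), res_b = integer())
  } else {
    keys <- keys[order(keys$res_a, keys$res_b), , drop = FALSE]
    dmat <- matrix(Inf, nrow(keys), nrow(ctx))
    for (i in seq_along(per_ctx)) {
      m <- match(paste(keys$res_a, keys$res_b),
                 paste(per_ctx[[i]]$res_a, per_ctx[[i]]$res_b))
      ok <- !is.na(m)
      dmat[ok, i] <- per_ctx[[i]]$dist[m[ok]]
    }
    present <- dmat <= cutoff
    finite_stats <- function(f) apply(dmat, 1L, function(r) {
      r <- r[is.finite(r)]
      if (length(r)) f(r) else NA_real_
    })
    out <- data.frame(res_a = keys$res_a, res_b = keys$res_b)
    colnames(dmat) <- paste0("pf_", ctx$pf)
    out <- cbind(out, as.data.frame(dmat))
    out$mean <- finite_stats(mean)
    out$sd <- finite_stats(stats::sd)
    out$n_present <- rowSums(present)
    out$class <- ifelse(out$n_present == nrow(ctx), "constant", "switching")
  }
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  attr(out, "cutoff") <- cutoff
  attr(out, "contexts") <- ctx
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Cutoff sensitivity of the contact classification
#'
#' Re-classifies contacts at perturbed cutoffs and tabulates how many
#' constant/switching calls change.
#'
#' @param assembly,lattice,direction as in [find_contacts()].
#' @param cutoff central cutoff (Angstrom).
#' @param delta vector of cutoff offsets to test.
#' @return data.frame with one row per cutoff: counts of constant and
#'   switching pairs.
#' @export
contact_sensitivity <- function(assembly, lattice, direction, cutoff = 4.0,
                                delta = c(-0.5, -0.2, 0, 0.2, 0.5)) {
  do.call(rbind, lapply(cutoff + delta, function(cc) {
    tab <- find_contacts(assembly, lattice, direction, cutoff = cc)
    data.frame(cutoff = cc,
               n_constant = sum(tab$class == "constant"),
               n_switching = sum(tab$class == "switching"))
  }))
}

#' Per-residue neighbour-distance variability across protofilaments
#'
#' For each residue, the distance between its C-alpha and the
#' corresponding C-alpha of the directional neighbour is computed in each
#' of the protofilament contexts; the standard deviation across contexts
#' measures how much that inter-subunit disposition changes around the
#' circumference. Low-SD regions are the conserved pivots of the lattice;
#' high-SD regions absorb the compression/extension.
#'
#' @param assembly a `hook_assembly`.
#' @param lattice a `hook_lattice`.
#' @param direction 5, 6 or 11.
#' @param defs optional `domain_set`; adds a domain column and a min/max
#'   SD summary by domain.
#' @return a `residue_variability` data.frame: `resno`, `n_contexts`,
#'   `mean_dist`, `sd`, optional `domain`; attribute `summary`.
#' @export
residue_variability <- function(assembly, lattice, direction, defs = NULL) {
  ctx <- context_pairs(lattice, direction)
  S <- lattice$start_number
  if (nrow(ctx) < S)
    warning("only ", nrow(ctx), " of ", S, " protofilament contexts available; ",
            "SDs are computed over the available contexts")
  dl <- lapply(seq_len(nrow(ctx)), function(i) {
    a <- assembly[[ctx$chain_from[i]]]
    b <- assembly[[ctx$chain_to[i]]]
    common <- intersect(a$resno, b$resno)
    stats::setNames(sqrt(rowSums((a$ca[as.character(common), , drop = FALSE] -
                                  b$ca[as.character(common), , drop = FALSE])^2)),
                    common)
  })
  all_res <- sort(unique(as.integer(unlist(lapply(dl, names)))))
  m <- vapply(dl, function(d) d[as.character(all_res)], numeric(length(all_res)))
  m <- matrix(m, nrow = length(all_res))
  out <- data.frame(resno = all_res,
                    n_contexts = rowSums(!is.na(m)),
                    mean_dist = rowMeans(m, na.rm = TRUE),
                    sd = apply(m, 1L, stats::sd, na.rm = TRUE))
  if (!is.null(defs)) out$domain <- domain_of(out$resno, defs)
  full <- out[out$n_contexts == nrow(ctx), , drop = FALSE]
  smin <- full[which.min(full$sd), , drop = FALSE]
  smax <- full[which.max(full$sd), , drop = FALSE]
  attr(out, "summary") <- list(min_sd = smin, max_sd = smax,
                               direction = direction)
  class(out) <- c("residue_variability", "data.frame")
  out
}

#' Gap among the three D1 domains around a protofilament context
#'
#' Measures, for the mesh-layer triangle formed by a reference subunit and
#' its +6 and +11 neighbours, the pairwise minimum heavy-atom distances
#' between the D1 domains and the area of the triangle of D1 centroids.
#' The gap closes on the compressed side of the bend and opens on the
#' extended side.
#'
#' @param assembly a `hook_assembly`.
#' @param lattice a `hook_lattice`.
#' @param context protofilament id of the reference subunit.
#' @param defs a `domain_set` naming `D1` (or `domain` to use).
#' @param domain domain name forming the gap (default `"D1"`).
#' @return list with `context`, `min_dist` (named pairwise minima, A),
#'   `gap` (smallest of the three), `triangle_area` (A^2), `chains`.
#' @export
d1_triangle_gap <- function(assembly, lattice, context, defs, domain = "D1") {
  stopifnot(inherits(assembly, "hook_assembly"), inherits(lattice, "hook_lattice"))
  zmid <- mean(range(lattice$z))
  cand <- lattice$k[lattice$pf == context]
  cand <- cand[cand + 11L <= max(lattice$k) & cand + 6L <= max(lattice$k)]
  if (length(cand) == 0L) stop("context ", context, ": missing +6/+11 neighbours")
  k0 <- cand[which.min(abs(lattice$z[names(cand)] - zmid))]
  chains <- lattice$chains[c(k0, k0 + 6L, k0 + 11L) + 1L]
  sel <- lapply(chains, function(ch) {
    sub <- assembly[[ch]]
    res <- assign_domains(sub, defs)[[domain]]
    if (length(res) == 0L) stop("configuration error: empty domain ", domain)
    sub$atoms[sub$atoms$resno %in% res, c("x", "y", "z"), drop = FALSE]
  })
  pairs <- utils::combn(3L, 2L)
  md <- apply(pairs, 2L, function(p) min(cross_dist(sel[[p[1L]]], sel[[p[2L]]])))
  names(md) <- apply(pairs, 2L, function(p) paste(c("0", "+6", "+11")[p], collapse = ":"))
  cen <- t(vapply(sel, colMeans, numeric(3L)))
  area <- 0.5 * sqrt(sum(cross3(cen[2L, ] - cen[1L, ], cen[3L, ] - cen[1L, ])^2))
  list(context = context, chains = chains, min_dist = md,
       gap = min(md), triangle_area = area)
}
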