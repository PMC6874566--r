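# Domain range definitions and residue-to-domain assignment.

#' Define a set of radial domains by residue ranges
#'
#' Each domain is a list of inclusive author-numbered residue intervals.
#' Intervals must be non-empty and non-overlapping across the whole set.
#'
#' @param ... named arguments, one per domain; each a list (or single
#'   vector) of `c(first, last)` inclusive ranges.
#' @return a `domain_set`: named list of k x 2 integer range matrices.
#' @examples
#' domain_set(D0c = list(c(1, 71), c(358, 402)),
#'            D1 = list(c(72, 144), c(285, 357)),
#'            D2 = c(145, 284))
#' @export
domain_set <- function(...) {
  defs <- list(...)
  if (length(defs) && is.null(names(defs))) stop("domains must be named")
  out <- lapply(defs, function(d) {
    if (is.numeric(d)) d <- list(d)
    m <- do.call(rbind, lapply(d, function(r) {
      if (length(r) != 2L || r[2L] < r[1L]) stop("each range must be c(first, last) with last >= first")
      as.integer(r)
    }))
    colnames(m) <- c("first", "last")
    m
  })
  all_res <- unlist(lapply(out, function(m) {
    unlist(lapply(seq_len(nrow(m)), function(i) m[i, 1L]:m[i, 2L]))
  }))
  if (anyDuplicated(all_res)) stop("overlapping residue ranges across domains")
  structure(out, class = "domain_set")
}

#' Default FlgE domain layout
#'
#' The inner D0-Dc layer (N- and C-terminal helices plus the Dc
#' beta-hairpin) spans residues 1-71 and 358-402. The D1/D2 boundary is not
#' uniquely fixed by the hook literature; the defaults used here place the
#' D1 triangular loop (residues 117-135) and the short beta-hairpin tip
#' (329-330) in D1 and the outer-surface contacts (159-284) in D2, and can
#' be overridden via [domain_set()].
#'
#' @return a `domain_set` with domains `D0c`, `D1`, `D2`.
#' @export
flge_domains <- function() {
  domain_set(D0c = list(c(1, 71), c(358, 402)),
             D1 = list(c(72, 144), c(285, 357)),
             D2 = c(145, 284))
}

# domain name (or NA) for each residue number
domain_of <- function(resno, defs) {
  out <- rep(NA_character_, length(resno))
  for (nm in names(defs)) {
    m <- defs[[nm]]
    for (i in seq_len(nrow(m))) {
      out[resno >= m[i, 1L] & resno <= m[i, 2L]] <- nm
    }
  }
  out
}

#' Assign residues of a subunit to domains
#'
#' @param subunit a `hook_subunit`.
#' @param defs a `domain_set`.
#' @return named list: for each domain the member residue numbers, plus
#'   `unassigned` for residues outside all ranges.
#' @export
assign_domains <- function(subunit, defs) {
  stopifnot(inherits(subunit, "hook_subunit"))
  if (!inherits(defs, "domain_set")) defs <- do.call(domain_set, defs)
  dom <- domain_of(subunit$resno, defs)
  out <- lapply(names(defs), function(nm) subunit$resno[!is.na(dom) & dom == nm])
  names(out) <- names(defs)
  out$unassigned <- subunit$resno[is.na(dom)]
  out
}
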