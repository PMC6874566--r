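# Reading and writing assemblies; subunit and assembly containers.

new_subunit <- function(chain, atoms) {
  # atoms: data.frame(resno, resid, elety, x, y, z), author numbering
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  if (nrow(ca) == 0L) return(NULL)
  # keep only residues that retain a CA record
  atoms <- atoms[atoms$resno %in% ca$resno, , drop = FALSE]
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in chain ", chain)
  if (any(diff(ca$resno) <= 0))
    stop("residue numbers not strictly increasing in chain ", chain)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  rownames(xyz) <- ca$resno
  structure(list(chain = as.character(chain),
                 resno = ca$resno,
                 resid = ca$resid,
                 ca = xyz,
                 atoms = atoms[, c("resno", "resid", "elety", "x", "y", "z")]),
            class = "hook_subunit")
}

new_assembly <- function(subunits) {
  subunits <- subunits[!vapply(subunits, is.null, logical(1L))]
  if (length(subunits) == 0L) stop("empty assembly: no polymer chains with CA atoms")
  names(subunits) <- vapply(subunits, function(s) s$chain, character(1L))
  structure(subunits, class = "hook_assembly")
}

#' @export
print.hook_assembly <- function(x, ...) {
  nres <- vapply(x, function(s) length(s$resno), integer(1L))
  cat("hook_assembly:", length(x), "chains,",
      sum(nres), "residues (", min(nres), "-", max(nres), "per chain )\n")
  invisible(x)
}

subunit_centroid <- function(sub) colMeans(sub$ca)

assembly_centroids <- function(assembly) {
  t(vapply(assembly, subunit_centroid, numeric(3L)))
}

#' Read a helical assembly from a PDB or mmCIF file
#'
#' Parses the file with bio3d, drops non-polymer entities and hydrogens,
#' keeps the first alternate location, and returns one subunit per polymer
#' chain ordered by chain identifier. Author residue numbering is used
#' throughout; residues carrying insertion codes are dropped with a warning.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a `hook_assembly`: a named list of subunits, each holding the
#'   chain id, ordered author residue numbers, residue names, an n x 3
#'   C-alpha coordinate matrix (Angstrom) and a heavy-atom table.
#' @export
read_assembly <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty assembly: no polymer ATOM records in ", path)
  if (!is.null(at$insert) && any(!is.na(at$insert) & at$insert != "")) {
    warning("dropping residues with insertion codes")
    at <- at[is.na(at$insert) | at$insert == "", , drop = FALSE]
  }
  if (!is.null(at$alt)) {
    keep_alt <- is.na(at$alt) | at$alt == "" | at$alt == sort(unique(at$alt[!is.na(at$alt) & at$alt != ""]))[1L]
    at <- at[keep_alt, , drop = FALSE]
  }
  if (!is.null(at$elesy)) at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  subs <- lapply(split(at, at$chain), function(ch) {
    new_subunit(ch$chain[1L],
                data.frame(resno = ch$resno, resid = ch$resid, elety = ch$elety,
                           x = ch$x, y = ch$y, z = ch$z,
                           stringsAsFactors = FALSE))
  })
  subs <- subs[order(names(subs))]
  new_assembly(subs)
}

#' Write an assembly to a PDB file
#'
#' One chain per subunit. Chain identifiers longer than one character are
#' remapped to single characters (with a warning) to stay within the PDB
#' fixed-column format.
#'
#' @param assembly a `hook_assembly`.
#' @param path output file path.
#' @export
write_assembly <- function(assembly, path) {
  stopifnot(inherits(assembly, "hook_assembly"))
  pool <- c(LETTERS, letters, as.character(0:9))
  chains <- names(assembly)
  if (any(nchar(chains) > 1L) || length(chains) > length(pool)) {
    warning("remapping chain identifiers to single characters for PDB output")
    chains <- pool[((seq_along(chains) - 1L) %% length(pool)) + 1L]
  }
  rows <- lapply(seq_along(assembly), function(i) {
    a <- assembly[[i]]$atoms
    a$chain <- chains[i]
    a
  })
  tab <- do.call(rbind, rows)
  if (any(!is.finite(as.matrix(tab[, c("x", "y", "z")]))))
    stop("non-finite coordinates; refusing to write")
  xyz <- as.vector(t(as.matrix(tab[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = tab$resno, resid = tab$resid,
                   eleno = seq_len(nrow(tab)), elety = tab$elety,
                   chain = tab$chain)
  invisible(path)
}

#' Write a table with a units/metadata sidecar
#'
#' @param records a data.frame.
#' @param path output path (`.csv` or `.json`).
#' @param format `"csv"` or `"json"`.
#' @param meta optional named list written as `<path>.meta.json` (csv) or
#'   embedded under `$meta` (json).
#' @export
write_table <- function(records, path, format = c("csv", "json"), meta = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
    if (!is.null(meta)) {
      jsonlite::write_json(meta, paste0(path, ".meta.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  } else {
    payload <- if (is.null(meta)) records else list(meta = meta, records = records)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
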