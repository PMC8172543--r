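#' Peptide structure container
#'
#' A `vet_structure` holds one chain of one model of a peptide structure as a
#' flat atom table, the representation used by all network-building functions.
#'
#' @param atoms data.frame with columns `resno` (1-based residue number),
#'   `resid` (3-letter residue name), `elety` (atom name, e.g. "CA"),
#'   `elesy` (element symbol), `x`, `y`, `z` (Angstrom).
#' @param chain single chain identifier.
#'
#' @return An object of class `vet_structure`.
#' @export
vet_structure <- function(atoms, chain = "A") {
  stopifnot(is.data.frame(atoms),
            all(c("resno", "resid", "elety", "elesy", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("structure has no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  resno <- unique(atoms$resno)
  if (is.unsorted(resno, strictly = TRUE))
    stop("residue indices must be strictly increasing")
  for (r in resno) {
    have <- atoms$elety[atoms$resno == r]
    miss <- setdiff(c("N", "CA", "C"), have)
    if (length(miss) > 0L)
      stop(sprintf("missing backbone atom %s in residue %d",
                   paste(miss, collapse = ","), r))
  }
  structure(list(atoms = atoms, chain = chain), class = "vet_structure")
}

#' @export
print.vet_structure <- function(x, ...) {
  cat(sprintf("<vet_structure> chain %s: %d residues, %d atoms\n",
              x$chain, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `vet_structure`.
#' @return integer count.
#' @export
n_residues <- function(structure) length(unique(structure$atoms$resno))

#' Residue numbers of a structure
#' @param structure a `vet_structure`.
#' @return integer vector of residue numbers in order.
#' @export
residue_numbers <- function(structure) unique(structure$atoms$resno)

#' Parse a PDB-format text into a structure
#'
#' Reads ATOM records via [bio3d::read.pdb()]. Only the first model of an NMR
#' ensemble and the first chain present are used; hydrogens are dropped (they
#' are re-inferred geometrically where needed).
#'
#' @param pdb_text character scalar (or vector of lines) of PDB-format text.
#' @return A [vet_structure].
#' @export
parse_pdb <- function(pdb_text) {
  if (length(pdb_text) == 0L || !nzchar(paste(pdb_text, collapse = "")))
    stop("empty PDB input")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n")), tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in PDB input")
  first_chain <- at$chain[1]
  if (is.na(first_chain)) first_chain <- "A" else at <- at[at$chain == first_chain, ]
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(!nzchar(trimws(elesy))))
    elesy <- substr(trimws(at$elety), 1, 1)
  keep <- toupper(trimws(elesy)) != "H"
  atoms <- data.frame(resno = at$resno[keep],
                      resid = trimws(at$resid[keep]),
                      elety = trimws(at$elety[keep]),
                      elesy = toupper(trimws(elesy[keep])),
                      x = at$x[keep], y = at$y[keep], z = at$z[keep],
                      stringsAsFactors = FALSE)
  vet_structure(atoms, chain = first_chain)
}

#' Write a structure as PDB text
#'
#' Serializes via [bio3d::write.pdb()]; `parse_pdb(write_pdb(s))` round-trips
#' residue numbering, atom names and coordinates (to PDB's 3-decimal format).
#'
#' @param structure a [vet_structure].
#' @param file optional path; if `NULL` the PDB text is returned invisibly.
#' @return character vector of PDB lines (invisibly if written to `file`).
#' @export
write_pdb <- function(structure, file = NULL) {
  a <- structure$atoms
  tf <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = tf,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   eleno = seq_len(nrow(a)), chain = rep(structure$chain, nrow(a)),
                   elesy = a$elesy)
  lines <- readLines(tf)
  if (is.null(file)) { unlink(tf); lines } else invisible(lines)
}

# coordinates of one named atom of one residue; NULL if absent
atom_coord <- function(structure, resno, elety) {
  a <- structure$atoms
  i <- which(a$resno == resno & a$elety == elety)
  if (length(i) == 0L) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

# coordinate matrix of all heavy atoms of one residue
residue_coords <- function(structure, resno, exclude_backbone = FALSE) {
  a <- structure$atoms
  sel <- a$resno == resno
  if (exclude_backbone) sel <- sel & !(a$elety %in% c("N", "CA", "C", "O", "OXT"))
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}
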