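#' Construct a structure object
#'
#' A \code{helix_structure} holds an atom table (author residue numbering, one
#' row per atom, grouped contiguously by residue) and an N x 3 coordinate
#' matrix in Angstrom.
#'
#' @param atoms data.frame with columns \code{atom_name}, \code{residue_number}
#'   (integer, author numbering), \code{residue_name} (3-letter code),
#'   \code{chain_id}, \code{element}.
#' @param coords numeric matrix, \code{nrow(atoms)} x 3, Angstrom.
#' @param label optional text label.
#' @return object of class \code{helix_structure}.
#' @export
new_structure <- function(atoms, coords, label = "") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  req <- c("atom_name", "residue_number", "residue_name", "chain_id", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3 || nrow(coords) != nrow(atoms))
    stop("coords must be a numeric nrow(atoms) x 3 matrix")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  atoms$residue_number <- as.integer(atoms$residue_number)
  # residues must be contiguous blocks
  key <- paste(atoms$chain_id, atoms$residue_number)
  if (anyDuplicated(rle(key)$values))
    stop("atoms must be grouped contiguously by residue")
  rownames(atoms) <- NULL
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, coords = coords, label = label),
            class = "helix_structure")
}

#' @export
print.helix_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[c("chain_id", "residue_number")]))
  cat(sprintf("<helix_structure> %s: %d atoms, %d residues, %d chain(s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms), nres, length(unique(x$atoms$chain_id))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x a \code{helix_structure}
#' @return integer atom count
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Residue table of a structure
#'
#' One row per residue in atom order, with columns \code{chain_id},
#' \code{residue_number}, \code{residue_name}.
#' @param x a \code{helix_structure}
#' @return data.frame
#' @export
residue_table <- function(x) {
  a <- x$atoms
  keep <- !duplicated(paste(a$chain_id, a$residue_number))
  out <- a[keep, c("chain_id", "residue_number", "residue_name")]
  rownames(out) <- NULL
  out
}

# index vector into the atom table; any filter left NULL is a no-op
atom_indices <- function(x, residues = NULL, atom_names = NULL, chain = NULL) {
  a <- x$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(residues)) sel <- sel & a$residue_number %in% residues
  if (!is.null(atom_names)) sel <- sel & a$atom_name %in% atom_names
  if (!is.null(chain)) sel <- sel & a$chain_id %in% chain
  which(sel)
}

#' Select atoms from a structure
#'
#' @param x a \code{helix_structure}
#' @param residues integer vector of author residue numbers (NULL = all)
#' @param atom_names character vector of atom names (NULL = all)
#' @param chain chain id(s) (NULL = all)
#' @return integer vector of row indices into the atom table
#' @export
atom_select <- function(x, residues = NULL, atom_names = NULL, chain = NULL) {
  atom_indices(x, residues, atom_names, chain)
}

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
                 "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
                 "TYR", "VAL", "HSD", "HSE", "HSP", "HID", "HIE", "HIP")

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  first <- substr(nm, 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, first)
}

#' Read a protein structure from a PDB file
#'
#' Loads ATOM/HETATM records of standard amino-acid residues, keeping author
#' residue numbering.  Alternate locations: the first altloc is kept.
#' Insertion codes are rejected with an error, since silently accepting them
#' risks mis-numbering residues used as network keys.
#'
#' @param path PDB file path
#' @param label optional label (defaults to the file name)
#' @return \code{helix_structure}
#' @export
read_structure <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file: ", path,
                                           " (", conditionMessage(e), ")"))
  at <- pdb$atom
  ins <- trimws(as.character(at$insert))
  ins[is.na(ins)] <- ""
  if (any(nzchar(ins) & at$resid %in% STANDARD_AA))
    stop("insertion codes are not supported; renumber the PDB first")
  alt <- trimws(as.character(at$alt))
  alt[is.na(alt)] <- ""
  keep_alt <- alt %in% c("", "A", "1")
  keep <- keep_alt & at$resid %in% STANDARD_AA
  if (!any(keep)) stop("no protein atoms found in ", path)
  at <- at[keep, , drop = FALSE]
  chain <- as.character(at$chain)
  chain[is.na(chain) | !nzchar(trimws(chain))] <- "A"
  elem <- trimws(as.character(at$elesy))
  bad <- is.na(elem) | !nzchar(elem)
  elem[bad] <- guess_element(at$elety[bad])
  atoms <- data.frame(atom_name = trimws(at$elety),
                      residue_number = as.integer(at$resno),
                      residue_name = trimws(at$resid),
                      chain_id = chain,
                      element = elem,
                      stringsAsFactors = FALSE)
  new_structure(atoms, cbind(at$x, at$y, at$z), label = label)
}

structure_to_bio3d <- function(x, xyz = NULL) {
  if (is.null(xyz)) xyz <- as.numeric(t(x$coords))
  pdb_xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  list(atoms = x$atoms, xyz = pdb_xyz)
}

#' Write a structure to a PDB file
#'
#' @param x \code{helix_structure}
#' @param path output path
#' @param xyz optional coordinate override: a frames x (3 * n_atoms) matrix
#'   writes a multi-model PDB.
#' @return invisibly, the path
#' @export
write_structure <- function(x, path, xyz = NULL) {
  if (is.null(xyz)) xyz <- as.numeric(t(x$coords))
  a <- x$atoms
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$residue_number, resid = a$residue_name,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain_id, elesy = a$element)
  invisible(path)
}

#' Truncate a residue's side chain to alanine
#'
#' Removes side-chain atoms beyond C-beta and renames the residue ALA,
#' emulating an in-silico alanine substitution (backbone and C-beta
#' coordinates are untouched).  Idempotent; alanine inputs pass through
#' unchanged.
#'
#' @param x \code{helix_structure}
#' @param residue_number author residue number to mutate
#' @param chain chain id (default first chain)
#' @return mutated \code{helix_structure}
#' @export
truncate_to_alanine <- function(x, residue_number, chain = NULL) {
  a <- x$atoms
  if (is.null(chain)) chain <- a$chain_id[1]
  in_res <- a$residue_number == residue_number & a$chain_id == chain
  if (!any(in_res)) stop("residue ", residue_number, " not found in chain ", chain)
  resname <- a$residue_name[which(in_res)[1]]
  if (resname == "GLY") stop("glycine has no C-beta; cannot truncate to alanine")
  if (resname == "PRO") stop("proline backbone is cyclic; refusing alanine truncation")
  keep_names <- c("N", "CA", "C", "O", "CB", "H", "HA", "HN", "OXT", "HB1", "HB2", "HB3")
  drop <- in_res & !(a$atom_name %in% keep_names)
  a$residue_name[in_res] <- "ALA"
  new_structure(a[!drop, , drop = FALSE], x$coords[!drop, , drop = FALSE],
                label = x$label)
}
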