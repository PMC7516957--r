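# PDB reading/writing and the flat residue/atom table that every downstream
# stage consumes. A "residue table" is a data.frame with one row per atom:
#   chain, res_ordinal (0-based within chain), resname, res_author, icode,
#   atom, element, altloc, occupancy, x, y, z, het
# Residues are identified by (chain, res_ordinal); ordinals are assigned per
# chain in file order, 0,1,2,... over the observed polymer sequence.

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
# HETATM residue names accepted as polymer amino acids (crystallographic
# substitutions); everything else in HETATM records is a ligand and dropped.
.het_polymer <- c("MSE", "SEC", "PYL")
.waters <- c("HOH", "WAT", "DOD", "H2O")
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

residue_table_cols <- c(
  "chain", "res_ordinal", "resname", "res_author", "icode", "atom",
  "element", "altloc", "occupancy", "x", "y", "z", "het"
)

#' Coerce to a residue/atom table
#'
#' Accepts a `rcc_structure` (from [read_pdb()]) or a residue table
#' data.frame (e.g. from [make_ideal_helix()]) and returns the flat atom
#' table used by all geometry operations.
#'
#' @param x a `rcc_structure` or a data.frame with the residue-table columns.
#' @return a data.frame, one row per atom.
#' @export
as_residue_table <- function(x) {
  if (inherits(x, "rcc_structure")) return(x$atoms)
  if (is.data.frame(x)) {
    need <- c("chain", "res_ordinal", "atom", "x", "y", "z")
    miss <- setdiff(need, names(x))
    if (length(miss))
      rcc_error(paste0("not a residue table; missing column(s): ",
                       paste(miss, collapse = ", ")), "rcc_input_error")
    return(x)
  }
  rcc_error("cannot interpret input as a residue table", "rcc_input_error")
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", toupper(atom_name))
  el <- ifelse(startsWith(nm, "SE"), "SE", substr(nm, 1, 1))
  el[el == ""] <- "X"
  el
}

#' Read a protein structure from a PDB file or text
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL records into an ordered residue/atom
#' model. Waters are always excluded; HETATM records are excluded unless the
#' residue name is in `het_polymer` (selenomethionine and friends, which are
#' genuine polymer positions); hydrogens are excluded by default. One model
#' and one alternate-location conformer per atom are retained.
#'
#' @param path path to a PDB file, or a character vector of PDB lines (a
#'   single string containing newlines is also accepted).
#' @param model `"first"` (default) or an integer MODEL number to select
#'   from multi-model (NMR) files.
#' @param altloc alternate-location policy; only `"occupancy"` is
#'   implemented: keep the conformer with the highest occupancy, ties broken
#'   by the alphabetically first altloc id.
#' @param include_hydrogens keep hydrogen/deuterium atoms (default `FALSE`;
#'   most depositions lack them, and including them would make contact
#'   graphs resolution-dependent).
#' @param het_polymer HETATM residue names treated as polymer amino acids.
#' @param id structure identifier; defaults to the file name without
#'   extension (or `"structure"` for raw text).
#' @return an object of class `rcc_structure`: a list with elements `id`,
#'   `model` (the model number used) and `atoms` (the residue table).
#' @export
read_pdb <- function(path, model = "first", altloc = "occupancy",
                     include_hydrogens = FALSE, het_polymer = .het_polymer,
                     id = NULL) {
  altloc <- match.arg(altloc, "occupancy")
  if (length(path) == 1L && !grepl("\n", path, fixed = TRUE)) {
    if (!file.exists(path))
      rcc_error(paste0("cannot read PDB file: ", path), "rcc_input_error")
    lines <- readLines(path, warn = FALSE)
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  } else {
    lines <- unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(id)) id <- "structure"
  }
  parse_pdb_lines(lines, model = model, include_hydrogens = include_hydrogens,
                  het_polymer = het_polymer, id = id)
}

parse_pdb_lines <- function(lines, model = "first", include_hydrogens = FALSE,
                            het_polymer = .het_polymer, id = "structure") {
  rec <- substr(lines, 1, 6)
  atom_line <- rec == "ATOM  " | rec == "HETATM"

  # model membership: atoms between "MODEL n" and the next MODEL belong to n
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts)) {
    model_ids <- suppressWarnings(as.integer(substr(lines[model_starts], 7, 80)))
    model_ids[is.na(model_ids)] <- seq_along(model_ids)
    line_model <- model_ids[findInterval(seq_along(lines), model_starts)]
    # atoms before the first MODEL record (unusual) inherit the first model
    line_model[seq_len(min(model_starts) - 1L)] <- model_ids[1L]
  } else {
    line_model <- rep.int(1L, length(lines))
  }
  if (identical(model, "first")) {
    keep_model <- if (length(model_starts)) model_ids[1L] else 1L
  } else {
    keep_model <- as.integer(model)
    if (length(model_starts) && !keep_model %in% model_ids)
      rcc_error(paste0("model ", keep_model, " not present"), "rcc_lookup_error")
  }
  sel <- atom_line & line_model == keep_model
  ln <- lines[sel]
  if (!length(ln)) rcc_error("no ATOM/HETATM records found", "rcc_empty_structure_error")
  ln <- formatC(ln, width = 80, flag = "-")  # pad short lines

  at <- data.frame(
    chain = substr(ln, 22, 22),
    resname = trimws(substr(ln, 18, 20)),
    res_author = suppressWarnings(as.integer(substr(ln, 23, 26))),
    icode = trimws(substr(ln, 27, 27)),
    atom = trimws(substr(ln, 13, 16)),
    altloc = trimws(substr(ln, 17, 17)),
    occupancy = suppressWarnings(as.numeric(substr(ln, 55, 60))),
    x = as.numeric(substr(ln, 31, 38)),
    y = as.numeric(substr(ln, 39, 46)),
    z = as.numeric(substr(ln, 47, 54)),
    element = trimws(substr(ln, 77, 78)),
    het = substr(ln, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z))
    rcc_error("malformed coordinate field in ATOM/HETATM record", "rcc_input_error")
  at$occupancy[is.na(at$occupancy)] <- 1
  noelem <- at$element == ""
  at$element[noelem] <- guess_element(at$atom[noelem])
  at$element <- toupper(at$element)

  at <- at[!(at$resname %in% .waters), , drop = FALSE]
  at <- at[!at$het | at$resname %in% het_polymer, , drop = FALSE]
  if (!include_hydrogens) at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at))
    rcc_error("no amino-acid residues after filtering", "rcc_empty_structure_error")

  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties -> alphabetically first altloc id; file order preserved afterwards
  akey <- paste(at$chain, at$res_author, at$icode, at$resname, at$atom, sep = "\r")
  ord <- order(akey, -at$occupancy, at$altloc, method = "radix")
  keep <- ord[!duplicated(akey[ord])]
  at <- at[sort(keep), , drop = FALSE]

  # 0-based ordinal per chain over observed residues, file order
  rkey <- paste(at$chain, at$res_author, at$icode, sep = "\r")
  first <- !duplicated(rkey)
  u_chain <- at$chain[first]
  ord0 <- stats::ave(seq_along(u_chain), u_chain, FUN = seq_along) - 1L
  at$res_ordinal <- ord0[match(rkey, rkey[first])]

  rownames(at) <- NULL
  structure(
    list(id = id, model = keep_model, atoms = at[, residue_table_cols]),
    class = "rcc_structure"
  )
}

#' @export
print.rcc_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "res_ordinal")]))
  cat(sprintf("<rcc_structure> %s (model %d): %d residue(s), %d atom(s), chain(s) %s\n",
              x$id, x$model, nres, nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Select residues by chain
#'
#' Returns the atoms of the requested chains as a flat residue table, in
#' original file order (not request order); ordinal indices are untouched.
#'
#' @param x a `rcc_structure` or residue table.
#' @param chain_ids character vector of chain ids, or `NULL` (default) for
#'   all chains.
#' @return a residue table data.frame.
#' @export
select_residues <- function(x, chain_ids = NULL) {
  at <- as_residue_table(x)
  if (is.null(chain_ids)) return(at)
  missing_ch <- setdiff(chain_ids, unique(at$chain))
  if (length(missing_ch))
    rcc_error(paste0("unknown chain id(s): ", paste(missing_ch, collapse = ", ")),
              "rcc_lookup_error")
  out <- at[at$chain %in% chain_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strip side-chain atoms
#'
#' Keeps only the peptide backbone (N, CA, C, O, plus terminal OXT).
#' Residues left with zero retained atoms disappear from the table; the
#' ordinal indices of the survivors are NOT renumbered, so sequence
#' adjacency is unaffected. Idempotent. CA-only traces pass through intact.
#'
#' @param x a `rcc_structure` or residue table.
#' @return a residue table with backbone atoms only.
#' @export
strip_side_chains <- function(x) {
  at <- as_residue_table(x)
  out <- at[at$atom %in% .backbone_atoms, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue bounding-sphere envelope
#'
#' The envelope of a residue is the sphere centred at the unweighted
#' geometric centre of its retained atoms with radius equal to the distance
#' to the farthest atom. Envelopes drive the quick include/exclude rules of
#' the contact-graph builder and must be computed on the same atom set used
#' for the exact atom-pair checks.
#'
#' @param x a residue table holding exactly one residue's atoms.
#' @return a list with `center` (length-3 numeric) and `radius` (scalar, Angstrom).
#' @export
residue_envelope <- function(x) {
  at <- as_residue_table(x)
  if (!nrow(at)) rcc_error("residue has no atoms", "rcc_contract_error")
  ctr <- c(mean(at$x), mean(at$y), mean(at$z))
  rad <- sqrt(max((at$x - ctr[1])^2 + (at$y - ctr[2])^2 + (at$z - ctr[3])^2))
  list(center = ctr, radius = rad)
}

# Vectorized envelopes for all residues; returns a data.table keyed by
# (chain, res_ordinal) with cx, cy, cz, radius.
residue_envelopes <- function(at) {
  dt <- as.data.table(at)
  dt[, {
    cx <- mean(x); cy <- mean(y); cz <- mean(z)
    .(cx = cx, cy = cy, cz = cz,
      radius = sqrt(max((x - cx)^2 + (y - cy)^2 + (z - cz)^2)))
  }, by = .(chain, res_ordinal)]
}

#' Write a residue table to a PDB file
#'
#' Emits column-exact ATOM/HETATM records (coordinates at 3 decimals, the
#' format's precision) followed by END. Round-tripping through
#' [read_pdb()] reproduces residues, ordinals and coordinates on the
#' retained content.
#'
#' @param x a `rcc_structure` or residue table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  at <- as_residue_table(x)
  nm <- ifelse(nchar(at$atom) >= 4L, substr(at$atom, 1, 4),
               sprintf(" %-3s", at$atom))
  chain <- ifelse(at$chain == "", " ", substr(at$chain, 1, 1))
  icode <- ifelse(is.na(at$icode) | at$icode == "", " ", substr(at$icode, 1, 1))
  alt <- ifelse(is.na(at$altloc) | at$altloc == "", " ", substr(at$altloc, 1, 1))
  res_author <- if ("res_author" %in% names(at)) at$res_author else at$res_ordinal + 1L
  res_author[is.na(res_author)] <- 0L
  het <- if ("het" %in% names(at)) at$het else FALSE
  occ <- if ("occupancy" %in% names(at)) at$occupancy else 1
  elem <- if ("element" %in% names(at)) at$element else guess_element(at$atom)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(het, "HETATM", "ATOM"),
    (seq_len(nrow(at)) - 1L) %% 99999L + 1L,
    nm, alt, at$resname, chain, res_author, icode,
    at$x, at$y, at$z, occ, 0, formatC(elem, width = 2)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Round atom coordinates to PDB file precision (3 decimals). Useful when an
# in-memory fixture must be bit-comparable with its file round-trip.
#' Round coordinates to PDB precision
#' @param x a `rcc_structure` or residue table.
#' @param digits decimal places (default 3, the PDB fixed-format precision).
#' @return a residue table with rounded x, y, z.
#' @export
round_coords <- function(x, digits = 3) {
  at <- as_residue_table(x)
  at$x <- round(at$x, digits); at$y <- round(at$y, digits)
  at$z <- round(at$z, digits)
  at
}

# Unique residues of a residue table, file order: data.frame with
# chain, res_ordinal, resname, res_author and 0-based vertex id.
residue_nodes <- function(at) {
  key <- paste(at$chain, at$res_ordinal, sep = "\r")
  first <- !duplicated(key)
  nodes <- at[first, intersect(c("chain", "res_ordinal", "resname", "res_author"),
                               names(at)), drop = FALSE]
  nodes$vertex <- seq_len(nrow(nodes)) - 1L
  rownames(nodes) <- NULL
  nodes
}
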