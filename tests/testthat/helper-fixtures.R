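# Shared fixture builders and independent oracle helpers.

# Hand-specified, column-exact PDB record (independent of write_pdb()).
pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     occ = 1, alt = " ", elem = NULL, rec = "ATOM", icode = " ") {
  if (is.null(elem)) elem <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, alt, resname, chain, resseq, icode,
          x, y, z, occ, 0, formatC(elem, width = 2))
}

# Minimal 3-glycine chain (N, CA, C, O each), 1 chain, author numbering 1..3.
pdb_three_gly <- function() {
  ln <- character(0)
  s <- 0
  for (i in 1:3) {
    base <- c(4 * (i - 1), 0, 0)
    for (at in list(c("N", -0.7, 0.8, 0), c("CA", 0, 0, 0),
                    c("C", 0.7, 0.8, 0), c("O", 0.9, 2.0, 0))) {
      s <- s + 1
      ln <- c(ln, pdb_line(s, at[1], "GLY", "A", i,
                           base[1] + as.numeric(at[2]),
                           base[2] + as.numeric(at[3]),
                           base[3] + as.numeric(at[4])))
    }
  }
  c(ln, "END")
}

# Residue table of single-atom (CA) point residues at given coordinates.
point_residues <- function(coords, ordinals = NULL, chains = "A") {
  coords <- matrix(coords, ncol = 3, byrow = FALSE)
  n <- nrow(coords)
  if (is.null(ordinals)) ordinals <- seq_len(n) - 1L
  chains <- rep_len(chains, n)
  data.frame(
    chain = chains, res_ordinal = as.integer(ordinals), resname = "ALA",
    res_author = as.integer(ordinals) + 1L, icode = "", atom = "CA",
    element = "C", altloc = "", occupancy = 1,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    het = FALSE, stringsAsFactors = FALSE
  )
}

# Canonical edge-set key of a contact graph, for exact set comparison.
edge_key <- function(cg) {
  if (!nrow(cg$edges)) return(character(0))
  sort(paste(cg$edges$i, cg$edges$j, sep = "-"))
}

# Canonical key of a clique list.
clique_key <- function(cliques) {
  sort(vapply(cliques, paste, character(1), collapse = ","))
}

# Independent recursive enumeration of integer partitions of n with parts
# bounded by max_part, in non-decreasing form (oracle for the catalog).
enum_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in enum_partitions(n - k, k)) out[[length(out) + 1L]] <- c(rest, k)
  }
  out
}

# The mixed fixture population used by oracle-equivalence suites:
# deterministic list of (residue table, label) covering helices and random
# chains across atom modes.
fixture_structures <- function(n_random = 42, helix_sizes = seq(30, 300, 30),
                               random_sizes = c(30, 45, 60, 75, 90, 120, 150),
                               modes = c("ca_only", "backbone",
                                         "backbone_plus_dummy_sidechain")) {
  out <- list()
  for (k in seq_along(helix_sizes)) {
    out[[length(out) + 1L]] <- list(
      atoms = make_ideal_helix(helix_sizes[k], modes[(k - 1L) %% 3L + 1L]),
      label = sprintf("helix%d", helix_sizes[k]))
  }
  for (k in seq_len(n_random)) {
    n <- random_sizes[(k - 1L) %% length(random_sizes) + 1L]
    out[[length(out) + 1L]] <- list(
      atoms = make_random_chain(n, seed = 1000L + k,
                                atom_mode = modes[(k - 1L) %% 3L + 1L]),
      label = sprintf("chain%d_s%d", n, 1000L + k))
  }
  out
}
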