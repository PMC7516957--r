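# Synthetic structures and graphs with known properties, plus the
# end-to-end brute-force oracle. Everything here is a pure function of its
# arguments and seed, so the test suite needs no external data.

.atom_modes <- c("ca_only", "backbone", "backbone_plus_dummy_sidechain")

# Build a residue table from per-residue atom coordinate blocks.
# coords: list (one per residue) of matrices with rownames = atom names.
assemble_residues <- function(coords, chain = "A", resname = "ALA") {
  rows <- lapply(seq_along(coords), function(i) {
    m <- coords[[i]]
    data.frame(
      chain = chain, res_ordinal = i - 1L, resname = resname,
      res_author = i, icode = "", atom = rownames(m),
      element = guess_element(rownames(m)), altloc = "",
      occupancy = 1, x = m[, 1L], y = m[, 2L], z = m[, 3L],
      het = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, residue_table_cols]
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(c(1, 0, 0))
  v / nv
}

# Schematic backbone/side-chain atoms around a CA trace. t = local chain
# direction (central difference), w = local "outward" direction (away from
# the midpoint of the flanking CAs, i.e. opposite the local backbone);
# offsets are fixed so generation is deterministic and strip_side_chains()
# produces a genuinely different atom set.
decorate_trace <- function(ca, atom_mode) {
  n <- nrow(ca)
  lapply(seq_len(n), function(i) {
    if (atom_mode == "ca_only")
      return(matrix(ca[i, ], 1, 3, dimnames = list("CA", NULL)))
    prev <- if (i > 1L) ca[i - 1L, ] else NULL
    nxt <- if (i < n) ca[i + 1L, ] else NULL
    tvec <- if (!is.null(prev) && !is.null(nxt)) unit(nxt - prev)
            else if (!is.null(nxt)) unit(nxt - ca[i, ])
            else if (!is.null(prev)) unit(ca[i, ] - prev)
            else c(1, 0, 0)
    wraw <- if (!is.null(prev) && !is.null(nxt)) ca[i, ] - (prev + nxt) / 2
            else c(-tvec[2], tvec[1], 0.3)
    # orthogonalize against t; fall back to a fixed perpendicular if collinear
    w <- wraw - sum(wraw * tvec) * tvec
    if (sqrt(sum(w^2)) < 1e-9) {
      w <- c(-tvec[2], tvec[1], 0) + c(0, -tvec[3], tvec[2])
      w <- w - sum(w * tvec) * tvec
    }
    w <- unit(w)
    m <- rbind(
      N  = ca[i, ] - 0.75 * tvec + 0.90 * w,
      CA = ca[i, ],
      C  = ca[i, ] + 0.75 * tvec + 0.90 * w,
      O  = ca[i, ] + 0.90 * tvec + 2.00 * w
    )
    if (atom_mode == "backbone_plus_dummy_sidechain")
      m <- rbind(m, CB = ca[i, ] - 2.4 * w)   # 2.4 A from CA, opposite the backbone side
    m
  })
}

#' Ideal alpha-helix fixture
#'
#' CA atoms lie on a canonical alpha-helix: rise 1.5 Angstrom and 100
#' degrees of turn per residue on a cylinder of radius 2.3 Angstrom.
#' Optional schematic backbone (N, C, O at fixed local offsets) and a dummy
#' side-chain pseudo-atom (CB, 2.4 Angstrom from CA pointing away from the
#' backbone) make side-chain inclusion observable in contact graphs.
#'
#' @param n number of residues (>= 1).
#' @param atom_mode `"ca_only"`, `"backbone"` or
#'   `"backbone_plus_dummy_sidechain"`.
#' @return a residue table.
#' @export
make_ideal_helix <- function(n, atom_mode = c("ca_only", "backbone",
                                              "backbone_plus_dummy_sidechain")) {
  atom_mode <- match.arg(atom_mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) rcc_error("n must be >= 1", "rcc_contract_error")
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  assemble_residues(decorate_trace(ca, atom_mode))
}

#' Self-avoiding random-chain fixture
#'
#' Random walk with fixed 3.8 Angstrom CA-CA steps; any placement bringing
#' a non-consecutive CA pair closer than 4.0 Angstrom is rejected and
#' redrawn (up to 10000 attempts per residue, then a generation error).
#' Deterministic for a fixed seed.
#'
#' @param n number of residues.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @param atom_mode as in [make_ideal_helix()].
#' @return a residue table.
#' @export
make_random_chain <- function(n, seed,
                              atom_mode = c("ca_only", "backbone",
                                            "backbone_plus_dummy_sidechain")) {
  atom_mode <- match.arg(atom_mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) rcc_error("n must be >= 1", "rcc_contract_error")
  ca <- with_seed(seed, {
    pts <- matrix(0, n, 3)
    for (i in seq_len(n)[-1]) {
      placed <- FALSE
      for (att in seq_len(10000L)) {
        step <- unit(rnorm(3))
        cand <- pts[i - 1L, ] + 3.8 * step
        if (i > 2L) {
          prev <- pts[seq_len(i - 2L), , drop = FALSE]
          mind2 <- min((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
                         (prev[, 3] - cand[3])^2)
          if (mind2 < 16) next   # 4.0 A self-clash radius
        }
        pts[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed)
        rcc_error("could not place residue within 10000 attempts",
                  "rcc_generation_error")
    }
    pts
  })
  assemble_residues(decorate_trace(ca, atom_mode))
}

#' Erdos-Renyi random graph fixture
#'
#' @param n number of vertices.
#' @param p edge probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return a `rcc_graph`.
#' @export
make_random_graph <- function(n, p, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) rcc_error("n must be >= 1", "rcc_contract_error")
  if (!is.numeric(p) || p < 0 || p > 1)
    rcc_error("p must be in [0, 1]", "rcc_contract_error")
  edges <- with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs[runif(nrow(pairs)) < p, , drop = FALSE] - 1L
  })
  rcc_graph(n, edges)
}

#' Apply a rigid motion to all atoms
#'
#' @param x a `rcc_structure` or residue table.
#' @param rotation 3x3 rotation matrix; must be orthonormal with
#'   determinant +1 (checked to 1e-9).
#' @param translation length-3 numeric.
#' @return a residue table with transformed coordinates; all other fields
#'   unchanged.
#' @export
rigid_transform <- function(x, rotation, translation = c(0, 0, 0)) {
  at <- as_residue_table(x)
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    rcc_error("rotation must be orthonormal with determinant +1",
              "rcc_contract_error")
  xyz <- cbind(at$x, at$y, at$z) %*% t(R)
  at$x <- xyz[, 1] + translation[1]
  at$y <- xyz[, 2] + translation[2]
  at$z <- xyz[, 3] + translation[3]
  at
}

#' Uniform random rotation matrix
#'
#' Haar-distributed rotation from the QR decomposition of a Gaussian
#' matrix; uses the current RNG state (seed with [set.seed()]).
#'
#' @return a 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' End-to-end brute-force RCC (test oracle)
#'
#' Computes the RCC vector with zero optimizations: all-pairs all-atom
#' contact graph, exhaustive bitmask clique scan (<= 18 residues) or a
#' plain pivot-free Bron-Kerbosch recursion for somewhat larger but sparse
#' contact graphs, then classification.
#'
#' @param x a `rcc_structure` or residue table.
#' @param params a `rcc_contact_params` or a number interpreted as `d`.
#' @param min_size,max_size clique-size window (see [rcc_vector()]).
#' @param structure_id identifier carried into the result.
#' @return a `rcc_vector`.
#' @export
brute_force_rcc <- function(x, params = contact_params(), min_size = 3L,
                            max_size = 6L, structure_id = "") {
  params <- as_contact_params(params)
  cg <- brute_force_contact_graph(x, params)
  n <- nrow(cg$nodes)
  if (n > 400L)
    rcc_error("brute-force RCC limited to 400 residues", "rcc_size_error")
  cl <- if (n <= 18L) brute_force_maximal_cliques(cg) else bk_plain_cliques(cg)
  rcc_vector(cl, cg$nodes, params, structure_id,
             min_size = min_size, max_size = max_size)
}
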