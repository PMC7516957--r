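# Residue contact graph construction. Two residues are in contact when some
# pair of their retained atoms lies within the distance threshold d. The
# optimized builder hashes atoms into a 3D grid of cell width d (candidate
# pairs must share a cell or touch neighboring cells), then applies
# bounding-sphere quick include/exclude rules before the exact atom-pair
# scan. A brute-force all-pairs builder defines ground truth.

#' Contact definition parameters
#'
#' @param d distance threshold in Angstrom; must be > 0. The field's common
#'   choices are 5--15 (the batch default sweeps 5,6,7,8,9,10,15).
#' @param include_side_chains if `FALSE`, only backbone atoms
#'   (N, CA, C, O, OXT) enter both the envelopes and the atom-pair checks.
#' @param inclusive if `TRUE` (default) contact means minimum atom-pair
#'   distance `<= d`; if `FALSE`, strictly `< d`.
#' @param filter_mode `"sound"` (default) uses the exact bounding-sphere
#'   bounds: exclude when `D - r_d - s_d > d`, include when
#'   `D + r_d + s_d <= d` (`< d` in strict mode); the result always equals
#'   the brute-force predicate. `"paper"` applies the literal quick rules
#'   include when `D < d`, exclude when `min(D - r_d, D - s_d) > d`, which
#'   can misclassify pairs with extended residues and is provided for
#'   comparison studies only.
#' @return an object of class `rcc_contact_params`.
#' @export
contact_params <- function(d = 5, include_side_chains = TRUE,
                           inclusive = TRUE,
                           filter_mode = c("sound", "paper")) {
  filter_mode <- match.arg(filter_mode)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    rcc_error("contact distance threshold d must be a single positive number",
              "rcc_contract_error")
  structure(
    list(d = as.numeric(d), include_side_chains = isTRUE(include_side_chains),
         inclusive = isTRUE(inclusive), filter_mode = filter_mode),
    class = "rcc_contact_params"
  )
}

as_contact_params <- function(params) {
  if (inherits(params, "rcc_contact_params")) return(params)
  if (is.numeric(params) && length(params) == 1L) return(contact_params(d = params))
  if (is.list(params)) return(do.call(contact_params, params))
  rcc_error("cannot interpret contact parameters", "rcc_contract_error")
}

# Retained atom set under params, with 1-based residue id column `rid`
# (row number into residue_nodes()).
retained_atoms <- function(x, params) {
  at <- as_residue_table(x)
  if (!params$include_side_chains) at <- strip_side_chains(at)
  if (!nrow(at))
    rcc_error("no atoms retained under the contact parameters", "rcc_empty_structure_error")
  nodes <- residue_nodes(at)
  key <- paste(at$chain, at$res_ordinal, sep = "\r")
  at$rid <- match(key, paste(nodes$chain, nodes$res_ordinal, sep = "\r"))
  list(atoms = at, nodes = nodes)
}

#' Hash atoms into a 3D grid
#'
#' Grid cells are axis-aligned cubes of width `d`; an atom at `(x,y,z)`
#' lives in cell `(floor(x/d), floor(y/d), floor(z/d))`. Hashing is per
#' ATOM (not per residue centre), so a residue spanning several cells is
#' present in all of them and no contacting pair can be missed.
#'
#' @param x a `rcc_structure` or residue table (atoms already filtered to
#'   the retained set).
#' @param d cell width = contact distance threshold, Angstrom.
#' @return an object of class `rcc_grid` with elements `cell_width` and
#'   `cells` (a data.table: cx, cy, cz, rid, ai).
#' @export
build_grid <- function(x, d) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0)
    rcc_error("grid cell width must be a single positive number", "rcc_contract_error")
  at <- as_residue_table(x)
  rid <- if ("rid" %in% names(at)) at$rid else {
    nodes <- residue_nodes(at)
    match(paste(at$chain, at$res_ordinal, sep = "\r"),
          paste(nodes$chain, nodes$res_ordinal, sep = "\r"))
  }
  cells <- data.table(
    cx = as.integer(floor(at$x / d)),
    cy = as.integer(floor(at$y / d)),
    cz = as.integer(floor(at$z / d)),
    rid = as.integer(rid),
    ai = seq_len(nrow(at))
  )
  structure(list(cell_width = as.numeric(d), cells = cells), class = "rcc_grid")
}

# The 13 neighbor offsets whose first nonzero component is positive; joining
# cells against these (plus the same-cell case) covers all 26 neighbors once.
.half_offsets <- local({
  g <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
  keep <- apply(g, 1L, function(v) {
    nz <- v[v != 0]
    length(nz) > 0L && nz[1] > 0L
  })
  as.matrix(g[keep, , drop = FALSE])
})

#' Candidate residue pairs from the grid
#'
#' Yields every unordered residue pair that has at least one atom pair in
#' the same or 26-neighboring grid cells, each pair exactly once. Because
#' atoms are hashed individually with cell width d, every truly contacting
#' pair (min atom distance <= d) is guaranteed to be yielded; false
#' positives are allowed and are removed by the distance checks.
#'
#' @param grid a `rcc_grid` built with cell width equal to the threshold.
#' @return a data.table with integer columns `i`, `j` (1-based residue ids,
#'   `i < j`), sorted.
#' @export
candidate_pairs <- function(grid) {
  if (!inherits(grid, "rcc_grid")) rcc_error("not a rcc_grid", "rcc_contract_error")
  cr <- unique(grid$cells[, .(cx, cy, cz, rid)])
  setkey(cr, cx, cy, cz)
  # residues sharing a cell
  same <- cr[cr, on = .(cx, cy, cz), allow.cartesian = TRUE][
    rid < i.rid, .(i = rid, j = i.rid)]
  out <- list(same)
  for (k in seq_len(nrow(.half_offsets))) {
    off <- .half_offsets[k, ]
    nb <- cr[, .(cx = cx + off[1L], cy = cy + off[2L], cz = cz + off[3L], rid2 = rid)]
    hit <- cr[nb, on = .(cx, cy, cz), nomatch = 0L, allow.cartesian = TRUE,
              .(a = x.rid, b = i.rid2)]
    if (nrow(hit)) {
      hit <- hit[a != b]
      out[[length(out) + 1L]] <- hit[, .(i = pmin(a, b), j = pmax(a, b))]
    }
  }
  pairs <- unique(rbindlist(out))
  setorder(pairs, i, j)
  pairs[]
}

#' Exact contact predicate for one residue pair
#'
#' Applies the configured quick include/exclude envelope rules and, when
#' they are inconclusive, the exact minimum atom-pair distance check (early
#' stop on the first pair within d). In `filter_mode = "sound"` the result
#' always equals the brute-force any-atom-pair predicate; in `"paper"` mode
#' the literal centre-distance rules are applied and may misclassify.
#'
#' @param r,s residue tables holding one residue each (retained atoms).
#' @param params a `rcc_contact_params`.
#' @param r_env,s_env optional precomputed [residue_envelope()]s; they must
#'   correspond to the same atom sets as `r` and `s`.
#' @return `TRUE` if the residues are in contact.
#' @export
residues_in_contact <- function(r, s, params, r_env = NULL, s_env = NULL) {
  params <- as_contact_params(params)
  r <- as_residue_table(r); s <- as_residue_table(s)
  if (is.null(r_env)) r_env <- residue_envelope(r)
  if (is.null(s_env)) s_env <- residue_envelope(s)
  d <- params$d
  D <- sqrt(sum((r_env$center - s_env$center)^2))
  cmp <- if (params$inclusive) `<=` else `<`
  if (params$filter_mode == "sound") {
    if (D - r_env$radius - s_env$radius > d) return(FALSE)
    if (cmp(D + r_env$radius + s_env$radius, d)) return(TRUE)
  } else {
    if (D < d) return(TRUE)
    if (min(D - r_env$radius, D - s_env$radius) > d) return(FALSE)
  }
  d2 <- d * d
  for (k in seq_len(nrow(r))) {
    dd <- (s$x - r$x[k])^2 + (s$y - r$y[k])^2 + (s$z - r$z[k])^2
    if (any(cmp(dd, d2))) return(TRUE)
  }
  FALSE
}

new_contact_graph <- function(nodes, edges, params, atoms) {
  edges <- as.data.table(edges)
  if (nrow(edges)) setorder(edges, i, j) else edges <- data.table(i = integer(), j = integer())
  structure(
    list(nodes = nodes, edges = edges[], params = params, atoms = atoms),
    class = "rcc_contact_graph"
  )
}

#' @export
print.rcc_contact_graph <- function(x, ...) {
  cat(sprintf("<rcc_contact_graph> %d residue(s), %d edge(s), d = %g A, side chains %s, %s filter\n",
              nrow(x$nodes), nrow(x$edges), x$params$d,
              if (x$params$include_side_chains) "included" else "excluded",
              x$params$filter_mode))
  invisible(x)
}

#' Build the residue contact graph (grid-accelerated)
#'
#' Grid hashing restricts the search to residue pairs sharing or adjoining
#' a cell; bounding-sphere rules then settle most pairs without touching
#' atom coordinates; the remainder get an exact minimum atom-pair distance
#' check. With the default `filter_mode = "sound"` the edge set is exactly
#' `{ {r,s} : min atom-pair distance <= d }` on the retained atoms --
#' identical to [brute_force_contact_graph()].
#'
#' @param x a `rcc_structure` or residue table.
#' @param params a `rcc_contact_params`, or a number interpreted as `d`.
#' @return an object of class `rcc_contact_graph`: `nodes` (residues in
#'   file order with 0-based `vertex` ids), `edges` (data.table of 1-based
#'   node row indices `i < j`), `params`, and the retained `atoms`.
#' @export
build_contact_graph <- function(x, params = contact_params()) {
  params <- as_contact_params(params)
  ra <- retained_atoms(x, params)
  at <- ra$atoms; nodes <- ra$nodes
  d <- params$d
  env <- residue_envelopes(at)
  env[, rid := match(paste(chain, res_ordinal, sep = "\r"),
                     paste(nodes$chain, nodes$res_ordinal, sep = "\r"))]
  setkey(env, rid)

  grid <- build_grid(at, d)
  pairs <- candidate_pairs(grid)
  if (!nrow(pairs)) return(new_contact_graph(nodes, NULL, params, at))

  pairs[, `:=`(
    D = sqrt((env$cx[i] - env$cx[j])^2 + (env$cy[i] - env$cy[j])^2 +
               (env$cz[i] - env$cz[j])^2),
    ri = env$radius[i], rj = env$radius[j]
  )]
  if (params$filter_mode == "sound") {
    pairs <- pairs[D - ri - rj <= d]
    qinc <- if (params$inclusive) pairs$D + pairs$ri + pairs$rj <= d
            else pairs$D + pairs$ri + pairs$rj < d
  } else {
    qinc <- pairs$D < d
    keep <- qinc | !(pmin(pairs$D - pairs$ri, pairs$D - pairs$rj) > d)
    pairs <- pairs[keep]; qinc <- qinc[keep]
  }
  included <- pairs[qinc, .(i, j)]
  rest <- pairs[!qinc, .(i, j)]
  if (nrow(rest)) {
    mind2 <- min_pair_dist2(rest, at)
    hit <- if (params$inclusive) mind2 <= d * d else mind2 < d * d
    included <- rbind(included, rest[hit])
  }
  new_contact_graph(nodes, included, params, at)
}

# Minimum squared atom-pair distance for each residue pair in `pairs`
# (columns i, j), vectorized via a cartesian atom join.
min_pair_dist2 <- function(pairs, at) {
  adt <- data.table(rid = at$rid, x = at$x, y = at$y, z = at$z)
  p <- data.table(pid = seq_len(nrow(pairs)), i = pairs$i, j = pairs$j)
  left <- adt[p, on = .(rid = i), allow.cartesian = TRUE][
    , .(pid, j, ax = x, ay = y, az = z)]
  both <- adt[left, on = .(rid = j), allow.cartesian = TRUE]
  both[, d2 := (x - ax)^2 + (y - ay)^2 + (z - az)^2]
  both[, min(d2), by = pid][order(pid), V1]
}

#' Brute-force contact graph (test oracle)
#'
#' All-pairs, all-atom-pairs scan with no grid and no envelope pruning;
#' defines ground truth for [build_contact_graph()]. Intended for small
#' inputs (roughly <= 500 residues / 8000 atoms).
#'
#' @inheritParams build_contact_graph
#' @return a `rcc_contact_graph`.
#' @export
brute_force_contact_graph <- function(x, params = contact_params()) {
  params <- as_contact_params(params)
  ra <- retained_atoms(x, params)
  at <- ra$atoms; nodes <- ra$nodes
  m <- nrow(at)
  if (m > 8000L)
    rcc_error("brute-force contact graph limited to 8000 atoms", "rcc_size_error")
  X <- cbind(at$x, at$y, at$z)
  D2 <- as.matrix(dist(X))^2
  A <- if (params$inclusive) D2 <= params$d^2 else D2 < params$d^2
  g <- factor(at$rid, levels = seq_len(nrow(nodes)))
  B <- rowsum(A + 0, g)            # residues x atoms: counts of contacts
  C <- rowsum(t(B), g)             # residues x residues
  adj <- t(C) > 0
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.table(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
  new_contact_graph(nodes, edges, params, at)
}

#' Contact-graph edge list with minimum atom-pair distances
#'
#' @param graph a `rcc_contact_graph`.
#' @return a data.frame: chain1, ordinal1, chain2, ordinal2, min_dist (Angstrom).
#' @export
contact_edge_list <- function(graph) {
  if (!inherits(graph, "rcc_contact_graph"))
    rcc_error("not a rcc_contact_graph", "rcc_contract_error")
  e <- graph$edges
  if (!nrow(e)) {
    return(data.frame(chain1 = character(), ordinal1 = integer(),
                      chain2 = character(), ordinal2 = integer(),
                      min_dist = numeric()))
  }
  mind <- sqrt(min_pair_dist2(e, graph$atoms))
  data.frame(
    chain1 = graph$nodes$chain[e$i], ordinal1 = graph$nodes$res_ordinal[e$i],
    chain2 = graph$nodes$chain[e$j], ordinal2 = graph$nodes$res_ordinal[e$j],
    min_dist = mind
  )
}

#' Write a contact-graph edge list as TSV
#' @param graph a `rcc_contact_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- contact_edge_list(graph)
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Contact graph as a dense adjacency matrix
#' @param graph a `rcc_contact_graph`.
#' @return a symmetric logical matrix with `chain:ordinal` dimnames.
#' @export
adjacency_matrix <- function(graph) {
  if (!inherits(graph, "rcc_contact_graph"))
    rcc_error("not a rcc_contact_graph", "rcc_contract_error")
  n <- nrow(graph$nodes)
  lab <- paste0(graph$nodes$chain, ":", graph$nodes$res_ordinal)
  A <- matrix(FALSE, n, n, dimnames = list(lab, lab))
  if (nrow(graph$edges)) {
    A[cbind(graph$edges$i, graph$edges$j)] <- TRUE
    A[cbind(graph$edges$j, graph$edges$i)] <- TRUE
  }
  A
}
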