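# Residue cluster classes: maximal cliques of 3-6 residues classified by
# the multiset of run lengths of sequence-adjacent residues (an integer
# partition of the clique size). Sequence adjacency means consecutive
# 0-based ordinals within the SAME chain; residues in different chains are
# never adjacent. The 26 classes have a fixed canonical order so feature
# columns are comparable across datasets.

# Canonical catalog order: sizes 3 (3 classes), 4 (5), 5 (7), 6 (11).
# Within a size the listing is the conventional published order, which is
# NOT a mechanical partition order ([2,2] precedes [1,3]; [1,4] precedes
# [1,2,2]); it is reproduced verbatim.
.catalog_partitions <- list(
  c(1L, 1L, 1L), c(1L, 2L), 3L,
  c(1L, 1L, 1L, 1L), c(1L, 1L, 2L), c(2L, 2L), c(1L, 3L), 4L,
  c(1L, 1L, 1L, 1L, 1L), c(1L, 1L, 1L, 2L), c(1L, 1L, 3L), c(1L, 4L),
  c(1L, 2L, 2L), c(2L, 3L), 5L,
  c(1L, 1L, 1L, 1L, 1L, 1L), c(1L, 1L, 1L, 1L, 2L), c(1L, 1L, 1L, 3L),
  c(1L, 1L, 2L, 2L), c(1L, 1L, 4L), c(1L, 2L, 3L), c(1L, 5L),
  c(2L, 2L, 2L), c(2L, 4L), c(3L, 3L), 6L
)

partition_key <- function(size, partition) {
  paste0(size, ":", paste(partition, collapse = "."))
}

#' The canonical catalog of the 26 residue cluster classes
#'
#' One row per class, ordered as published: the first 3 classes are the
#' maximal cliques of 3 residues, the next 5 of 4 residues, the next 7 of
#' 5 residues and the last 11 of 6 residues.
#'
#' @return a data.frame with columns `index` (0-based position), `size`,
#'   `partition` (list column of non-decreasing integer vectors summing to
#'   `size`) and `column` (stable export name, e.g. `"c4_22"`).
#' @export
class_catalog <- function() {
  sizes <- vapply(.catalog_partitions, sum, integer(1))
  data.frame(
    index = seq_along(.catalog_partitions) - 1L,
    size = sizes,
    partition = I(.catalog_partitions),
    column = sprintf("c%d_%s", sizes,
                     vapply(.catalog_partitions, paste, character(1), collapse = "")),
    stringsAsFactors = FALSE
  )
}

.catalog_lookup <- local({
  cat <- NULL
  function() {
    if (is.null(cat)) {
      cc <- class_catalog()
      keys <- mapply(partition_key, cc$size, cc$partition)
      cat <<- stats::setNames(cc$index, keys)
    }
    cat
  }
})

#' Column names of the 26 RCC classes, canonical order
#' @return character vector of length 26 (`c3_111` ... `c6_6`).
#' @export
rcc_class_names <- function() class_catalog()$column

#' Sequence-adjacency partition of a residue set
#'
#' Sorts the residues by (chain, ordinal), groups maximal runs of
#' consecutive same-chain ordinals, and returns the run lengths sorted
#' non-decreasing -- an integer partition of the set size. Residues in
#' different chains are never adjacent, even if their ordinals happen to be
#' consecutive.
#'
#' @param ordinals integer vector of 0-based residue ordinals.
#' @param chains chain ids aligned with `ordinals`; default: one chain.
#' @return non-decreasing integer vector summing to `length(ordinals)`.
#' @export
adjacency_partition <- function(ordinals, chains = NULL) {
  n <- length(ordinals)
  if (!n) rcc_error("empty residue set", "rcc_contract_error")
  if (is.null(chains)) chains <- rep("A", n)
  if (length(chains) != n)
    rcc_error("chains and ordinals lengths differ", "rcc_contract_error")
  if (anyDuplicated(paste(chains, ordinals, sep = "\r")))
    rcc_error("duplicate residues in clique", "rcc_contract_error")
  o <- order(chains, ordinals, method = "radix")
  ch <- chains[o]; rd <- ordinals[o]
  newrun <- c(TRUE, ch[-1] != ch[-n] | diff(rd) != 1L)
  sort.int(as.integer(tabulate(cumsum(newrun))))
}

#' Classify a clique into its residue cluster class
#'
#' Cliques of fewer than 3 or more than 6 residues contribute nothing and
#' classify to `NA` (larger cliques are dropped, not decomposed: their
#' sub-cliques are not maximal and counting them would double-count).
#'
#' @inheritParams adjacency_partition
#' @return the 0-based catalog index (integer in 0..25), or `NA_integer_`.
#' @export
classify_clique <- function(ordinals, chains = NULL) {
  size <- length(ordinals)
  if (size < 3L || size > 6L) return(NA_integer_)
  p <- adjacency_partition(ordinals, chains)
  idx <- .catalog_lookup()[partition_key(size, p)]
  unname(idx)
}

#' Assemble the 26-dimensional RCC vector from maximal cliques
#'
#' @param cliques list of integer vectors of 0-based vertex ids, as
#'   returned by [maximal_cliques()].
#' @param nodes data.frame mapping vertex ids to residues: row `v + 1`
#'   holds columns `chain` and `res_ordinal` of vertex `v` (the `nodes`
#'   element of a `rcc_contact_graph`).
#' @param params the `rcc_contact_params` used to build the graph
#'   (metadata only).
#' @param structure_id identifier carried into the result.
#' @param min_size,max_size clique sizes counted; the catalog spans 3--6
#'   and narrower windows zero the excluded classes.
#' @return an object of class `rcc_vector`: list with `counts` (named
#'   integer vector of length 26, canonical order), `n_cliques` (= sum of
#'   counts), `structure_id`, `params`.
#' @export
rcc_vector <- function(cliques, nodes, params = NULL, structure_id = "",
                       min_size = 3L, max_size = 6L) {
  lo <- max(3L, as.integer(min_size)); hi <- min(6L, as.integer(max_size))
  counts <- stats::setNames(integer(26L), rcc_class_names())
  for (m in cliques) {
    sz <- length(m)
    if (sz < lo || sz > hi) next
    idx <- classify_clique(nodes$res_ordinal[m + 1L], nodes$chain[m + 1L])
    if (!is.na(idx)) counts[idx + 1L] <- counts[idx + 1L] + 1L
  }
  structure(
    list(counts = counts, n_cliques = sum(counts),
         structure_id = structure_id, params = params),
    class = "rcc_vector"
  )
}

#' @export
print.rcc_vector <- function(x, ...) {
  cat(sprintf("<rcc_vector> %s: %d maximal clique(s) of size 3-6\n",
              if (nzchar(x$structure_id)) x$structure_id else "(unnamed)",
              x$n_cliques))
  nz <- x$counts[x$counts > 0L]
  if (length(nz)) print(nz) else cat("  (all classes zero)\n")
  invisible(x)
}

#' Full in-process RCC pipeline
#'
#' Convenience wrapper: contact graph, maximal cliques, classification.
#'
#' @param x a `rcc_structure` or residue table.
#' @param d contact distance threshold, Angstrom.
#' @param side_chains include side-chain atoms in the contact definition.
#' @param chains optional chain selection (see [select_residues()]).
#' @param filter_mode,inclusive see [contact_params()].
#' @param min_size,max_size clique-size window (see [rcc_vector()]).
#' @param structure_id identifier; defaults to the structure's own id.
#' @return a `rcc_vector`.
#' @export
rcc <- function(x, d = 5, side_chains = TRUE, chains = NULL,
                filter_mode = "sound", inclusive = TRUE,
                min_size = 3L, max_size = 6L, structure_id = NULL) {
  if (is.null(structure_id))
    structure_id <- if (inherits(x, "rcc_structure")) x$id else ""
  at <- select_residues(x, chains)
  params <- contact_params(d = d, include_side_chains = side_chains,
                           inclusive = inclusive, filter_mode = filter_mode)
  cg <- build_contact_graph(at, params)
  cl <- maximal_cliques(cg)
  rcc_vector(cl, cg$nodes, params, structure_id,
             min_size = min_size, max_size = max_size)
}

#' Compare the sound and literal envelope filter modes
#'
#' Builds the contact graph under both `filter_mode = "sound"` and
#' `filter_mode = "paper"` and reports any disagreement, rather than
#' silently picking one. Useful for quantifying how much the literal
#' centre-distance quick rules distort a given structure's RCC.
#'
#' @inheritParams rcc
#' @return a list: `edges_only_sound`, `edges_only_paper` (data.frames of
#'   vertex pairs), `rcc_sound`, `rcc_paper`, and `identical` (logical).
#' @export
compare_filter_modes <- function(x, d = 5, side_chains = TRUE, chains = NULL) {
  at <- select_residues(x, chains)
  gs <- build_contact_graph(at, contact_params(d, side_chains, filter_mode = "sound"))
  gp <- build_contact_graph(at, contact_params(d, side_chains, filter_mode = "paper"))
  key <- function(e) paste(e$i, e$j)
  os <- gs$edges[!key(gs$edges) %in% key(gp$edges)]
  op <- gp$edges[!key(gp$edges) %in% key(gs$edges)]
  vs <- rcc_vector(maximal_cliques(gs), gs$nodes, gs$params)
  vp <- rcc_vector(maximal_cliques(gp), gp$nodes, gp$params)
  list(edges_only_sound = as.data.frame(os), edges_only_paper = as.data.frame(op),
       rcc_sound = vs, rcc_paper = vp,
       identical = nrow(os) == 0L && nrow(op) == 0L)
}
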