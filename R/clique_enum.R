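# Maximal clique enumeration. Vertices are 0-based integers (residues are
# mapped to 0,1,2,... in file order before enumeration). The enumerator is
# Bron-Kerbosch with Tomita pivoting, run under a degeneracy ordering
# (minimum-degree peeling) for the outer level; an exhaustive bitmask
# subset scan serves as the oracle on small graphs.

#' Construct an undirected graph on vertices 0..n-1
#'
#' @param n number of vertices.
#' @param edges a two-column matrix/data.frame of 0-based vertex pairs, or
#'   `NULL` for an edgeless graph. Self-loops are rejected; duplicate and
#'   reversed pairs are merged.
#' @return an object of class `rcc_graph` with elements `n` and `adj`
#'   (symmetric logical matrix; row/column `v + 1` describes vertex `v`).
#' @export
rcc_graph <- function(n, edges = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) rcc_error("n must be a non-negative integer", "rcc_contract_error")
  adj <- matrix(FALSE, n, n)
  if (!is.null(edges) && NROW(edges) > 0L) {
    e <- as.matrix(as.data.frame(edges)[, 1:2])
    storage.mode(e) <- "integer"
    if (any(e < 0L) || any(e >= n))
      rcc_error("edge endpoint outside 0..n-1", "rcc_contract_error")
    if (any(e[, 1L] == e[, 2L]))
      rcc_error("self-loops are not allowed", "rcc_contract_error")
    adj[e + 1L] <- TRUE
    adj[e[, 2:1, drop = FALSE] + 1L] <- TRUE
  }
  structure(list(n = n, adj = adj), class = "rcc_graph")
}

as_rcc_graph <- function(x) {
  if (inherits(x, "rcc_graph")) return(x)
  if (inherits(x, "rcc_contact_graph")) {
    e <- cbind(x$edges$i - 1L, x$edges$j - 1L)
    return(rcc_graph(nrow(x$nodes), e))
  }
  rcc_error("cannot interpret input as a graph", "rcc_contract_error")
}

#' @export
print.rcc_graph <- function(x, ...) {
  cat(sprintf("<rcc_graph> %d vertices, %d edges\n", x$n, sum(x$adj) / 2))
  invisible(x)
}

#' Degeneracy ordering
#'
#' Repeatedly removes a vertex of minimum remaining degree (ties broken by
#' smallest vertex id). The degeneracy is the largest degree encountered at
#' removal time; every vertex has at most that many neighbors later in the
#' returned order.
#'
#' @param g a `rcc_graph` or `rcc_contact_graph`.
#' @return a list with `order` (0-based vertex ids) and `degeneracy`.
#' @export
degeneracy_order <- function(g) {
  g <- as_rcc_graph(g)
  n <- g$n
  if (n == 0L) return(list(order = integer(), degeneracy = 0L))
  deg <- colSums(g$adj)
  alive <- rep(TRUE, n)
  ord <- integer(n)
  k <- 0L
  for (t in seq_len(n)) {
    dmasked <- deg
    dmasked[!alive] <- Inf
    v <- which.min(dmasked)          # ties -> smallest id (first minimum)
    k <- max(k, as.integer(deg[v]))
    ord[t] <- v
    alive[v] <- FALSE
    nb <- which(g$adj[, v] & alive)
    deg[nb] <- deg[nb] - 1L
  }
  list(order = ord - 1L, degeneracy = k)
}

#' Enumerate all maximal cliques
#'
#' Bron-Kerbosch with Tomita pivoting: at each recursion the pivot `u` is
#' the vertex of P union X with the most neighbors in P (ties -> smallest
#' id), and only P \ N(u) is branched on. The outer level iterates over a
#' degeneracy ordering, which bounds the recursion by degeneracy + 2.
#' All maximal cliques are reported, including singletons and pairs;
#' size filtering belongs to the RCC layer.
#'
#' @param g a `rcc_graph` or `rcc_contact_graph`.
#' @return a list of integer vectors (0-based vertex ids, each sorted
#'   ascending), in lexicographic order; deterministic for a fixed graph.
#' @export
maximal_cliques <- function(g) {
  g <- as_rcc_graph(g)
  n <- g$n
  if (n == 0L) return(list())
  adj <- g$adj
  degord <- degeneracy_order(g)$order + 1L    # 1-based internal
  pos <- integer(n); pos[degord] <- seq_len(n)

  res <- vector("list", 64L)
  cnt <- 0L
  emit <- function(members) {
    cnt <<- cnt + 1L
    if (cnt > length(res)) length(res) <<- 2L * cnt
    res[[cnt]] <<- sort.int(members)
  }

  bk <- function(R, P, X) {
    if (!length(P)) {
      if (!length(X)) emit(R)
      return(invisible())
    }
    cand <- c(P, X)
    counts <- colSums(adj[P, cand, drop = FALSE])
    u <- cand[order(-counts, cand)[1L]]       # max |P & N(u)|, ties smallest id
    ext <- sort.int(P[!adj[P, u]])
    for (v in ext) {
      nb <- adj[, v]
      bk(c(R, v), P[nb[P]], X[nb[X]])
      P <- P[P != v]
      X <- c(X, v)
    }
    invisible()
  }

  for (idx in seq_len(n)) {
    v <- degord[idx]
    nb <- which(adj[, v])
    bk(v, nb[pos[nb] > idx], nb[pos[nb] < idx])
  }
  res <- res[seq_len(cnt)]
  res <- lapply(res, function(m) m - 1L)
  res[order_clique_list(res)]
}

# Lexicographic order of a list of sorted integer vectors.
order_clique_list <- function(cliques) {
  if (!length(cliques)) return(integer())
  keys <- vapply(cliques, function(m) paste(sprintf("%08d", m), collapse = ","),
                 character(1))
  order(keys, method = "radix")
}

#' Exhaustive maximal-clique enumeration (test oracle)
#'
#' Scans every subset of vertices (bitmask sweep), keeping the subsets that
#' are cliques and cannot be extended. Limited to 20 vertices.
#'
#' @param g a `rcc_graph` or `rcc_contact_graph`.
#' @return same format as [maximal_cliques()].
#' @export
brute_force_maximal_cliques <- function(g) {
  g <- as_rcc_graph(g)
  n <- g$n
  if (n > 20L)
    rcc_error("exhaustive clique scan limited to 20 vertices", "rcc_size_error")
  if (n == 0L) return(list())
  s <- 0:(2^n - 1L)
  nmask <- vapply(seq_len(n), function(v) {
    nb <- which(g$adj[, v]) - 1L
    as.integer(sum(2^nb))
  }, integer(1))
  full <- as.integer(2^n - 1)
  is_clique <- rep(TRUE, length(s))
  for (v in seq_len(n)) {
    bitv <- bitwShiftL(1L, v - 1L)
    in_m <- bitwAnd(s, bitv) != 0L
    forbidden <- bitwAnd(full, bitwNot(bitwOr(nmask[v], bitv)))
    viol <- bitwAnd(s, forbidden) != 0L
    is_clique <- is_clique & !(in_m & viol)
  }
  is_clique[1L] <- FALSE                       # empty set
  extendable <- rep(FALSE, length(s))
  for (v in seq_len(n)) {
    bitv <- bitwShiftL(1L, v - 1L)
    ext_v <- bitwAnd(s, bitv) == 0L & bitwAnd(s, nmask[v]) == s
    extendable <- extendable | ext_v
  }
  masks <- s[is_clique & !extendable]
  bits <- 2^(0:(n - 1L))
  out <- lapply(masks, function(m) which(bitwAnd(m, as.integer(bits)) != 0L) - 1L)
  out[order_clique_list(out)]
}

# Plain Bron-Kerbosch without pivoting or ordering: an independent slow
# path used by the end-to-end oracle when the graph exceeds the bitmask
# scan's 20-vertex cap but is still modest.
bk_plain_cliques <- function(g) {
  g <- as_rcc_graph(g)
  adj <- g$adj
  res <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      res[[length(res) + 1L]] <<- sort.int(R)
      return(invisible())
    }
    for (v in P) {
      nb <- adj[, v]
      bk(c(R, v), P[nb[P]], X[nb[X]])
      P <- P[P != v]
      X <- c(X, v)
    }
    invisible()
  }
  if (g$n > 0L) bk(integer(), seq_len(g$n), integer())
  res <- lapply(res, function(m) m - 1L)
  res[order_clique_list(res)]
}

# Independent validity check: every reported clique is pairwise adjacent
# and maximal. Returns TRUE or a message describing the first violation.
check_cliques <- function(g, cliques) {
  g <- as_rcc_graph(g)
  adj <- g$adj
  for (m in cliques) {
    v <- m + 1L
    if (length(v) > 1L) {
      sub <- adj[v, v, drop = FALSE]
      diag(sub) <- TRUE
      if (!all(sub)) return(sprintf("not a clique: {%s}", paste(m, collapse = ",")))
    }
    outside <- setdiff(seq_len(g$n), v)
    if (length(outside)) {
      can_ext <- colSums(adj[v, outside, drop = FALSE]) == length(v)
      if (any(can_ext)) return(sprintf("not maximal: {%s}", paste(m, collapse = ",")))
    }
  }
  TRUE
}
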