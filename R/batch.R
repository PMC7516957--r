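# Batch driver: compute RCC records for many structures across distance
# cutoffs and side-chain settings, and write machine-readable feature
# tables. Computation over (structure x setting) combinations is
# embarrassingly parallel; output order is fixed by sorting, so results are
# invariant to worker count and input ordering.

#' Compute one RCC record from a structure file
#'
#' Runs the full pipeline (parse, optional side-chain strip, contact graph,
#' maximal cliques, classification) and returns a record with counts,
#' graph summaries and informational timings.
#'
#' @param path readable PDB file.
#' @param d contact distance threshold, Angstrom.
#' @param side_chains include side-chain atoms.
#' @param chains optional chain selection.
#' @param filter_mode,inclusive see [contact_params()].
#' @param min_clique,max_clique clique-size window counted (within 3--6).
#' @param model model selection passed to [read_pdb()].
#' @return an object of class `rcc_record`: list with `structure_id`,
#'   `chain`, `d`, `side_chains`, `counts` (named, length 26),
#'   `n_residues`, `n_edges`, `n_cliques_3_6`, timing fields `read_ms`,
#'   `graph_ms`, `clique_ms` (informational only) and `ok = TRUE`.
#' @export
compute_rcc <- function(path, d = 5, side_chains = TRUE, chains = NULL,
                        filter_mode = "sound", inclusive = TRUE,
                        min_clique = 3L, max_clique = 6L, model = "first") {
  t0 <- proc.time()[["elapsed"]]
  s <- read_pdb(path, model = model)
  at <- select_residues(s, chains)
  t1 <- proc.time()[["elapsed"]]
  params <- contact_params(d = d, include_side_chains = side_chains,
                           inclusive = inclusive, filter_mode = filter_mode)
  cg <- build_contact_graph(at, params)
  t2 <- proc.time()[["elapsed"]]
  cl <- maximal_cliques(cg)
  v <- rcc_vector(cl, cg$nodes, params, s$id,
                  min_size = min_clique, max_size = max_clique)
  t3 <- proc.time()[["elapsed"]]
  structure(
    list(
      structure_id = s$id,
      chain = if (is.null(chains)) "*" else paste(chains, collapse = ";"),
      d = as.numeric(d), side_chains = isTRUE(side_chains),
      counts = v$counts, n_residues = nrow(cg$nodes),
      n_edges = nrow(cg$edges), n_cliques_3_6 = v$n_cliques,
      read_ms = round(1000 * (t1 - t0), 3),
      graph_ms = round(1000 * (t2 - t1), 3),
      clique_ms = round(1000 * (t3 - t2), 3),
      ok = TRUE, error = NA_character_
    ),
    class = "rcc_record"
  )
}

failed_record <- function(path, d, side_chains, chains, msg) {
  structure(
    list(
      structure_id = sub("\\.[^.]*$", "", basename(path)),
      chain = if (is.null(chains)) "*" else paste(chains, collapse = ";"),
      d = as.numeric(d), side_chains = isTRUE(side_chains),
      counts = stats::setNames(rep(NA_integer_, 26L), rcc_class_names()),
      n_residues = NA_integer_, n_edges = NA_integer_,
      n_cliques_3_6 = NA_integer_,
      read_ms = NA_real_, graph_ms = NA_real_, clique_ms = NA_real_,
      ok = FALSE, error = msg
    ),
    class = "rcc_record"
  )
}

#' Batch RCC computation over structures and settings
#'
#' One record per (structure x distance x side-chain setting). Failures on
#' individual files are recorded (`ok = FALSE`) and the batch continues; an
#' error is raised only when every input fails. Output order is
#' deterministic -- sorted by (structure_id, d, side_chains) -- regardless
#' of worker scheduling.
#'
#' @param paths character vector of PDB files (globs are expanded).
#' @param distances distance cutoffs, Angstrom; default the published sweep
#'   5, 6, 7, 8, 9, 10, 15.
#' @param side_chains logical vector of side-chain settings; default both.
#' @param chains optional chain selection applied to every structure.
#' @param workers number of parallel workers ([parallel::mclapply]); 1 =
#'   serial. Results are independent of this value.
#' @param filter_mode,inclusive,min_clique,max_clique per-record settings,
#'   see [compute_rcc()].
#' @return a list of `rcc_record`s with attribute `n_failed`.
#' @export
batch_compute <- function(paths, distances = c(5, 6, 7, 8, 9, 10, 15),
                          side_chains = c(TRUE, FALSE), chains = NULL,
                          workers = 1L, filter_mode = "sound",
                          inclusive = TRUE, min_clique = 3L, max_clique = 6L) {
  if (!length(paths)) rcc_error("no input files", "rcc_run_error")
  expanded <- unlist(lapply(paths, function(p)
    if (file.exists(p)) p else Sys.glob(p)), use.names = FALSE)
  if (!length(expanded)) rcc_error("no input files matched", "rcc_run_error")
  if (!is.numeric(distances) || !length(distances) || any(distances <= 0))
    rcc_error("distances must be positive", "rcc_run_error")

  tasks <- expand.grid(path = unique(expanded), d = distances,
                       sc = unique(side_chains),
                       stringsAsFactors = FALSE)
  run1 <- function(k) {
    tk <- tasks[k, ]
    tryCatch(
      compute_rcc(tk$path, d = tk$d, side_chains = tk$sc, chains = chains,
                  filter_mode = filter_mode, inclusive = inclusive,
                  min_clique = min_clique, max_clique = max_clique),
      error = function(e) failed_record(tk$path, tk$d, tk$sc, chains,
                                        conditionMessage(e))
    )
  }
  ks <- seq_len(nrow(tasks))
  recs <- if (workers > 1L) {
    parallel::mclapply(ks, run1, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(ks, run1)
  }
  # mclapply can surface worker-level failures as try-error objects
  bad <- vapply(recs, function(r) !inherits(r, "rcc_record"), logical(1))
  for (k in which(bad))
    recs[[k]] <- failed_record(tasks$path[k], tasks$d[k], tasks$sc[k], chains,
                               "worker failure")
  ord <- order(vapply(recs, `[[`, "", "structure_id"),
               vapply(recs, `[[`, 0, "d"),
               vapply(recs, `[[`, TRUE, "side_chains"),
               method = "radix")
  recs <- recs[ord]
  n_failed <- sum(!vapply(recs, `[[`, TRUE, "ok"))
  if (n_failed == length(recs))
    rcc_error("all inputs failed", "rcc_run_error")
  attr(recs, "n_failed") <- n_failed
  recs
}

records_to_table <- function(records) {
  records <- records[vapply(records, `[[`, TRUE, "ok")]
  if (!length(records))
    rcc_error("no successful records to write", "rcc_run_error")
  meta <- data.frame(
    structure_id = vapply(records, `[[`, "", "structure_id"),
    chain = vapply(records, `[[`, "", "chain"),
    d = vapply(records, `[[`, 0, "d"),
    side_chains = vapply(records, `[[`, TRUE, "side_chains"),
    n_residues = vapply(records, `[[`, 0L, "n_residues"),
    n_edges = vapply(records, `[[`, 0L, "n_edges"),
    stringsAsFactors = FALSE
  )
  counts <- do.call(rbind, lapply(records, function(r) as.integer(r$counts)))
  colnames(counts) <- rcc_class_names()
  cbind(meta, as.data.frame(counts))
}

#' Write RCC records as a feature table
#'
#' CSV (default) with header `structure_id, chain, d, side_chains,
#' n_residues, n_edges` followed by the 26 class columns in canonical
#' order; counts are written as integers. `"jsonl"` writes one JSON object
#' per record with a 26-element `counts` array. Failed records are skipped
#' with a warning.
#'
#' @param records list of `rcc_record`s from [batch_compute()] /
#'   [compute_rcc()].
#' @param path output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (inherits(records, "rcc_record")) records <- list(records)
  n_bad <- sum(!vapply(records, `[[`, TRUE, "ok"))
  if (n_bad) warning(sprintf("skipping %d failed record(s)", n_bad))
  ok <- records[vapply(records, `[[`, TRUE, "ok")]
  if (format == "csv") {
    tab <- records_to_table(ok)
    utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  } else {
    lines <- vapply(ok, function(r) {
      as.character(jsonlite::toJSON(list(
        structure_id = r$structure_id, chain = r$chain, d = r$d,
        side_chains = r$side_chains, n_residues = r$n_residues,
        n_edges = r$n_edges, n_cliques_3_6 = r$n_cliques_3_6,
        counts = as.integer(r$counts)
      ), auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a CSV feature table
#' @param path file written by [write_feature_table()] (CSV format).
#' @return a data.frame with the documented columns.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

cli_usage <- function() {
  paste(
    "usage: rcc compute <files...> [options]",
    "  --distance D          contact cutoff in Angstrom; repeatable or",
    "                        comma-separated (default: 5,6,7,8,9,10,15)",
    "  --no-side-chains      backbone-only contacts (default: side chains included)",
    "  --both-side-chain-modes  run each structure with and without side chains",
    "  --chains A,B          restrict to the listed chains",
    "  --filter-mode M       sound | paper (default sound)",
    "  --min-clique K        smallest clique size counted (default 3)",
    "  --max-clique K        largest clique size counted (default 6)",
    "  --format F            csv | jsonl (default csv)",
    "  --workers N           parallel workers (default 1)",
    "  --output PATH         feature table path (default rcc_features.csv)",
    "  --edge-list PATH      also write contact edges (TSV) for each record",
    "exit status: 0 all ok, 2 partial failure, 1 total failure/usage error",
    sep = "\n"
  )
}

#' Command-line interface
#'
#' Implements `rcc compute <files...> [options]` (see `inst/exec/rcc` for
#' the executable wrapper). Designed to be called from `Rscript`; returns
#' the process exit status instead of quitting so it is testable in
#' process.
#'
#' @param args character vector of command-line arguments; defaults to
#'   [commandArgs()]`(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly: 0 = all records computed, 2 =
#'   some inputs failed, 1 = usage error or total failure.
#' @export
rcc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(msg) {
    message("rcc: ", msg, "\n\n", cli_usage())
    invisible(1L)
  }
  if (!length(args) || args[1] != "compute") return(fail("expected subcommand 'compute'"))
  args <- args[-1]
  opt <- list(distances = numeric(), side_modes = NULL, chains = NULL,
              filter_mode = "sound", min_clique = 3L, max_clique = 6L,
              format = "csv", workers = 1L, output = "rcc_features.csv",
              edge_list = NULL, files = character())
  i <- 1L
  take <- function() {
    if (i + 1L > length(args)) rcc_error(paste0(args[i], " needs a value"), "rcc_cli_error")
    i <<- i + 1L
    args[i]
  }
  res <- tryCatch({
    while (i <= length(args)) {
      a <- args[i]
      switch(a,
        "--distance" = { opt$distances <- c(opt$distances, as.numeric(strsplit(take(), ",")[[1]])) },
        "--no-side-chains" = { opt$side_modes <- FALSE },
        "--both-side-chain-modes" = { opt$side_modes <- c(TRUE, FALSE) },
        "--chains" = { opt$chains <- strsplit(take(), ",")[[1]] },
        "--filter-mode" = { opt$filter_mode <- take() },
        "--min-clique" = { opt$min_clique <- as.integer(take()) },
        "--max-clique" = { opt$max_clique <- as.integer(take()) },
        "--format" = { opt$format <- take() },
        "--workers" = { opt$workers <- as.integer(take()) },
        "--output" = { opt$output <- take() },
        "--edge-list" = { opt$edge_list <- take() },
        {
          if (startsWith(a, "--")) rcc_error(paste0("unknown option ", a), "rcc_cli_error")
          opt$files <- c(opt$files, a)
        }
      )
      i <- i + 1L
    }
    opt
  }, error = function(e) conditionMessage(e))
  if (is.character(res)) return(fail(res))
  opt <- res
  if (!length(opt$files)) return(fail("no input files given"))
  if (!length(opt$distances)) opt$distances <- c(5, 6, 7, 8, 9, 10, 15)
  if (is.null(opt$side_modes)) opt$side_modes <- TRUE
  if (anyNA(opt$distances) || any(opt$distances <= 0)) return(fail("bad --distance value"))
  if (!opt$filter_mode %in% c("sound", "paper")) return(fail("bad --filter-mode"))
  if (!opt$format %in% c("csv", "jsonl")) return(fail("bad --format"))

  recs <- tryCatch(
    batch_compute(opt$files, distances = opt$distances,
                  side_chains = opt$side_modes, chains = opt$chains,
                  workers = opt$workers, filter_mode = opt$filter_mode,
                  min_clique = opt$min_clique, max_clique = opt$max_clique),
    rcc_error = function(e) conditionMessage(e)
  )
  if (is.character(recs)) return(fail(recs))
  suppressWarnings(write_feature_table(recs, opt$output, format = opt$format))
  if (!is.null(opt$edge_list)) write_edge_lists_for(recs, opt, opt$edge_list)
  n_failed <- attr(recs, "n_failed")
  for (r in recs) if (!r$ok) message("rcc: failed: ", r$structure_id, " (", r$error, ")")
  invisible(if (n_failed > 0L) 2L else 0L)
}

# Recompute and write contact edge lists (TSV) for every successful record;
# one file, with structure_id/d/side_chains key columns prepended.
write_edge_lists_for <- function(recs, opt, path) {
  files <- unlist(lapply(opt$files, function(p)
    if (file.exists(p)) p else Sys.glob(p)), use.names = FALSE)
  ids <- sub("\\.[^.]*$", "", basename(files))
  rows <- list()
  for (r in recs) {
    if (!r$ok) next
    f <- files[match(r$structure_id, ids)]
    if (is.na(f)) next
    at <- select_residues(read_pdb(f), opt$chains)
    cg <- build_contact_graph(at, contact_params(
      d = r$d, include_side_chains = r$side_chains,
      filter_mode = opt$filter_mode))
    el <- contact_edge_list(cg)
    if (nrow(el))
      rows[[length(rows) + 1L]] <- cbind(
        structure_id = r$structure_id, d = r$d, side_chains = r$side_chains, el)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure_id = character(), d = numeric(),
               side_chains = logical(), chain1 = character(),
               ordinal1 = integer(), chain2 = character(),
               ordinal2 = integer(), min_dist = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
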