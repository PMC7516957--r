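test_that("grid hashing uses floor semantics per atom", {
  g <- build_grid(point_residues(c(0.5, 0.5, 0.5)), d = 1)
  expect_identical(unname(as.matrix(g$cells[, .(cx, cy, cz)])[1, ]),
                   c(0L, 0L, 0L))
  g2 <- build_grid(point_residues(c(-0.1, 0, 0)), d = 1)
  expect_identical(g2$cells$cx, -1L)
  g3 <- build_grid(point_residues(rbind(c(0.2, 0, 0), c(0.8, 0, 0)),
                                  ordinals = 0:1), d = 1)
  expect_identical(unique(g3$cells[, .(cx, cy, cz)]),
                   data.table::data.table(cx = 0L, cy = 0L, cz = 0L))
  expect_error(build_grid(point_residues(c(0, 0, 0)), d = 0),
               class = "rcc_contract_error")
})

test_that("candidate_pairs yields near pairs once and misses no contact", {
  d <- 5
  near <- point_residues(rbind(c(0, 0, 0), c(0.9 * d, 0, 0)), ordinals = 0:1)
  expect_identical(nrow(candidate_pairs(build_grid(near, d))), 1L)
  far <- point_residues(rbind(c(0, 0, 0), c(3 * d, 0, 0)), ordinals = 0:1)
  expect_identical(nrow(candidate_pairs(build_grid(far, d))), 0L)

  # completeness: candidate set is a superset of the brute-force edge set
  for (seed in 1:20) {
    at <- make_random_chain(40, seed, "ca_only")
    for (d in c(5, 8)) {
      cand <- candidate_pairs(build_grid(at, d))
      ck <- paste(cand$i, cand$j, sep = "-")
      bf <- brute_force_contact_graph(at, contact_params(d))
      expect_true(all(edge_key(bf) %in% ck),
                  label = sprintf("seed %d d %g grid superset", seed, d))
    }
  }
})

test_that("residues_in_contact matches hand-enumerated atom pairs", {
  p5 <- contact_params(5)
  a <- point_residues(c(0, 0, 0)); b <- point_residues(c(4.9, 0, 0))
  expect_true(residues_in_contact(a, b, p5))
  b2 <- point_residues(c(5.1, 0, 0))
  expect_false(residues_in_contact(a, b2, p5))
  # threshold convention: exactly d is a contact when inclusive
  b3 <- point_residues(c(5, 0, 0))
  expect_true(residues_in_contact(a, b3, p5))
  expect_false(residues_in_contact(a, b3, contact_params(5, inclusive = FALSE)))

  # extended residue: r spans x = 0..6 (centre 3, radius 3), s at x = 7.
  # The two atom pairs have distances 7 and 1; contact because 1 <= 5.
  r <- point_residues(rbind(c(0, 0, 0), c(6, 0, 0)), ordinals = c(0, 0))
  s <- point_residues(c(7, 0, 0), ordinals = 1)
  expect_true(residues_in_contact(r, s, p5))
  expect_true(residues_in_contact(r, s, contact_params(5, filter_mode = "paper")))
})

test_that("the literal quick rules (paper mode) can disagree with ground truth", {
  # false inclusion by the literal centre rule: centres 4.9 apart (< d = 5)
  # but nearest atoms ~10.2 apart
  r <- point_residues(rbind(c(0, 0, 0), c(6, 0, 0)), ordinals = c(0, 0))
  s <- point_residues(rbind(c(7.9, 0, 10), c(7.9, 0, -10)), ordinals = c(1, 1))
  p_sound <- contact_params(5, filter_mode = "sound")
  p_paper <- contact_params(5, filter_mode = "paper")
  expect_false(residues_in_contact(r, s, p_sound))
  expect_true(residues_in_contact(r, s, p_paper))

  # false exclusion by the literal envelope rule: r_d = s_d = 3, D = 8.5,
  # min{D - r_d, D - s_d} = 5.5 > 5 excludes, yet the nearest atoms are
  # 2.5 A apart (a true contact). This pair also survives grid hashing
  # (the contacting atoms share a cell), so the whole-graph builders differ.
  r2 <- point_residues(rbind(c(0, 0, 0), c(6, 0, 0)), ordinals = c(0, 0))
  s2 <- point_residues(rbind(c(8.5, 0, 0), c(14.5, 0, 0)), ordinals = c(1, 1))
  expect_true(residues_in_contact(r2, s2, p_sound))
  expect_false(residues_in_contact(r2, s2, p_paper))
  at <- rbind(r2, s2)
  expect_identical(nrow(build_contact_graph(at, p_sound)$edges), 1L)
  expect_identical(nrow(build_contact_graph(at, p_paper)$edges), 0L)
  cmp <- compare_filter_modes(at, d = 5)
  expect_false(cmp$identical)
  expect_identical(nrow(cmp$edges_only_sound), 1L)
})

test_that("three collinear point residues give the expected edges", {
  at <- point_residues(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  cg <- build_contact_graph(at, contact_params(5))
  expect_identical(edge_key(cg), c("1-2", "2-3"))
})

test_that("grid builder equals brute force on helix and random chains", {
  h <- make_ideal_helix(30, "ca_only")
  expect_identical(edge_key(build_contact_graph(h, contact_params(5))),
                   edge_key(brute_force_contact_graph(h, contact_params(5))))
  for (seed in 1:6) {
    at <- make_random_chain(35, seed,
                            c("ca_only", "backbone",
                              "backbone_plus_dummy_sidechain")[seed %% 3 + 1])
    for (d in c(5, 8)) {
      for (sc in c(TRUE, FALSE)) {
        p <- contact_params(d, include_side_chains = sc)
        expect_identical(edge_key(build_contact_graph(at, p)),
                         edge_key(brute_force_contact_graph(at, p)),
                         label = sprintf("seed %d d %g sc %s", seed, d, sc))
      }
    }
  }
})

test_that("edges are monotone in d and shrink when side chains are stripped", {
  at <- make_random_chain(40, 11, "backbone_plus_dummy_sidechain")
  e5 <- edge_key(build_contact_graph(at, contact_params(5)))
  e15 <- edge_key(build_contact_graph(at, contact_params(15)))
  expect_true(all(e5 %in% e15))
  ebb <- edge_key(build_contact_graph(at, contact_params(5, include_side_chains = FALSE)))
  expect_true(all(ebb %in% e5))
})

test_that("the edge set is invariant under rigid motions", {
  at <- make_ideal_helix(25, "backbone")
  ref <- edge_key(build_contact_graph(at, contact_params(6)))
  set.seed(99)
  for (k in 1:5) {
    moved <- rigid_transform(at, random_rotation(), rnorm(3, sd = 20))
    expect_identical(edge_key(build_contact_graph(moved, contact_params(6))), ref)
  }
})

test_that("brute force handles the degenerate extremes", {
  apart <- point_residues(rbind(c(0, 0, 0), c(100, 0, 0)), ordinals = 0:1)
  expect_identical(nrow(brute_force_contact_graph(apart, contact_params(15))$edges), 0L)
  close5 <- point_residues(matrix(runif(15, 0, 1.5), 5, 3))
  cg <- brute_force_contact_graph(close5, contact_params(5))
  expect_identical(nrow(cg$edges), 10L)     # complete graph on 5
})

test_that("edge list and adjacency matrix exports are consistent", {
  at <- make_ideal_helix(12, "ca_only")
  cg <- build_contact_graph(at, contact_params(6))
  el <- contact_edge_list(cg)
  expect_identical(nrow(el), nrow(cg$edges))
  expect_true(all(el$min_dist <= 6))
  A <- adjacency_matrix(cg)
  expect_true(isSymmetric(A))
  expect_identical(sum(A) / 2, as.numeric(nrow(cg$edges)))
  expect_false(any(diag(A)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(cg, f)
  back <- utils::read.delim(f)
  expect_equal(back$min_dist, el$min_dist, tolerance = 1e-12)
})
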