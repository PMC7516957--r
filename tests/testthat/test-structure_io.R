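test_that("a minimal PDB parses to ordered residues with 0-based ordinals", {
  s <- read_pdb(pdb_three_gly(), id = "gly3")
  expect_s3_class(s, "rcc_structure")
  expect_identical(unique(s$atoms$chain), "A")
  expect_identical(sort(unique(s$atoms$res_ordinal)), 0:2)
  expect_identical(nrow(s$atoms), 12L)
  expect_identical(unique(s$atoms$resname), "GLY")
})

test_that("waters and non-polymer HETATM are dropped; MSE is kept", {
  ln <- pdb_three_gly()
  extra <- c(
    pdb_line(90, "O", "HOH", "A", 50, 1, 1, 1, rec = "HETATM", elem = "O"),
    pdb_line(91, "SE", "MSE", "A", 4, 12, 0, 0, rec = "HETATM", elem = "SE"),
    pdb_line(92, "C1", "LIG", "A", 60, 2, 2, 2, rec = "HETATM", elem = "C")
  )
  s0 <- read_pdb(ln)
  s1 <- read_pdb(c(head(ln, -1), extra, "END"))
  # water + ligand dropped; MSE becomes residue ordinal 3
  expect_identical(sort(unique(s1$atoms$res_ordinal)), 0:3)
  expect_identical(s1$atoms$resname[s1$atoms$res_ordinal == 3], "MSE")
  expect_identical(s1$atoms[s1$atoms$res_ordinal < 3, ], s0$atoms)
  # water alone changes nothing
  s2 <- read_pdb(c(head(ln, -1), extra[1], "END"))
  expect_identical(s2$atoms, s0$atoms)
})

test_that("altloc conformers resolve to highest occupancy, ties alphabetical", {
  ln <- c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, elem = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.6, alt = "A"),
    pdb_line(3, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.4, alt = "B"),
    pdb_line(4, "C", "ALA", "A", 1, 2, 0, 0),
    # tie on occupancy: altloc A must win
    pdb_line(5, "O", "ALA", "A", 1, 3, 0, 0, occ = 0.5, alt = "B"),
    pdb_line(6, "O", "ALA", "A", 1, 4, 0, 0, occ = 0.5, alt = "A"),
    "END"
  )
  s <- read_pdb(ln)
  ca <- s$atoms[s$atoms$atom == "CA", ]
  expect_identical(nrow(ca), 1L)
  expect_identical(ca$x, 1)
  o <- s$atoms[s$atoms$atom == "O", ]
  expect_identical(o$x, 4)
  # file order preserved: N, CA, C, O
  expect_identical(s$atoms$atom, c("N", "CA", "C", "O"))
})

test_that("hydrogens are excluded by default and kept on request", {
  ln <- c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "HA2", "GLY", "A", 1, 0.5, 0, 0, elem = "H"),
    "END"
  )
  expect_identical(read_pdb(ln)$atoms$atom, "CA")
  expect_identical(read_pdb(ln, include_hydrogens = TRUE)$atoms$atom,
                   c("CA", "HA2"))
})

test_that("multi-model files yield one model, selectable by number", {
  mk <- function(xoff, mdl) c(
    sprintf("MODEL     %4d", mdl),
    pdb_line(1, "CA", "GLY", "A", 1, xoff, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, xoff + 4, 0, 0),
    "ENDMDL"
  )
  ln <- c(mk(0, 1), mk(100, 2), "END")
  s1 <- read_pdb(ln)
  expect_identical(s1$model, 1L)
  expect_identical(s1$atoms$x, c(0, 4))
  s2 <- read_pdb(ln, model = 2)
  expect_identical(s2$atoms$x, c(100, 104))
  expect_error(read_pdb(ln, model = 7), class = "rcc_lookup_error")
})

test_that("parse errors are classed", {
  expect_error(read_pdb(tempfile(fileext = ".pdb")), class = "rcc_input_error")
  expect_error(read_pdb(c("REMARK nothing here", "END")),
               class = "rcc_empty_structure_error")
  only_water <- c(pdb_line(1, "O", "HOH", "A", 1, 0, 0, 0, rec = "HETATM"), "END")
  expect_error(read_pdb(only_water), class = "rcc_empty_structure_error")
})

test_that("select_residues filters chains in file order", {
  ln <- c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "B", 1, 10, 0, 0),
    pdb_line(3, "CA", "GLY", "A", 2, 4, 0, 0),
    "END"
  )
  s <- read_pdb(ln)
  expect_identical(select_residues(s, "A")$x, c(0, 4))
  expect_identical(select_residues(s)$x, c(0, 10, 4))       # default: everything
  expect_identical(select_residues(s, c("B", "A"))$x, c(0, 10, 4))  # file order, not request order
  expect_error(select_residues(s, "Z"), class = "rcc_lookup_error")
})

test_that("strip_side_chains keeps the backbone, drops emptied residues, is idempotent", {
  ala <- data.frame(
    chain = "A", res_ordinal = 0L, resname = "ALA", res_author = 1L,
    icode = "", atom = c("N", "CA", "C", "O", "CB"), element = "C",
    altloc = "", occupancy = 1, x = 1:5, y = 0, z = 0, het = FALSE
  )
  out <- strip_side_chains(ala)
  expect_identical(out$atom, c("N", "CA", "C", "O"))
  gly <- ala[ala$atom != "CB", ]
  expect_identical(strip_side_chains(gly)$atom, gly$atom)
  catrace <- ala[ala$atom == "CA", ]
  expect_identical(strip_side_chains(catrace)$atom, "CA")
  expect_identical(strip_side_chains(out), out)             # idempotent
  # residue of side-chain atoms only disappears; ordinals not renumbered
  two <- rbind(ala, within(ala[5, ], { res_ordinal <- 1L; res_author <- 2L }))
  two$atom[nrow(two)] <- "CG"
  stripped <- strip_side_chains(two)
  expect_identical(unique(stripped$res_ordinal), 0L)
  three <- rbind(two, within(catrace, { res_ordinal <- 2L }))
  expect_identical(unique(strip_side_chains(three)$res_ordinal), c(0L, 2L))
})

test_that("residue envelopes are the geometric centre + farthest-atom radius", {
  one <- point_residues(c(1, 2, 3))
  e1 <- residue_envelope(one)
  expect_equal(e1$center, c(1, 2, 3))
  expect_identical(e1$radius, 0)

  two <- point_residues(rbind(c(0, 0, 0), c(2, 0, 0)), ordinals = c(0, 0))
  e2 <- residue_envelope(two)
  expect_equal(e2$center, c(1, 0, 0))
  expect_equal(e2$radius, 1)

  # three atoms: frozen from explicit per-atom distances to the centroid
  tri <- point_residues(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)),
                        ordinals = c(0, 0, 0))
  e3 <- residue_envelope(tri)
  ctr <- c(4 / 3, 4 / 3, 0)
  dists <- apply(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)), 1,
                 function(p) sqrt(sum((p - ctr)^2)))
  expect_equal(e3$center, ctr)
  expect_equal(e3$radius, max(dists))
  expect_equal(e3$radius, sqrt(80) / 3)
  expect_error(residue_envelope(one[0, ]), class = "rcc_contract_error")
})

test_that("every retained atom lies within its residue envelope (property)", {
  for (seed in 1:5) {
    at <- make_random_chain(12, seed, "backbone_plus_dummy_sidechain")
    for (stripped in list(at, strip_side_chains(at))) {
      for (o in unique(stripped$res_ordinal)) {
        r <- stripped[stripped$res_ordinal == o, ]
        e <- residue_envelope(r)
        d <- sqrt((r$x - e$center[1])^2 + (r$y - e$center[2])^2 +
                    (r$z - e$center[3])^2)
        expect_true(all(d <= e$radius + 1e-9))
      }
    }
  }
})

test_that("write_pdb/read_pdb round-trips retained content exactly", {
  at <- round_coords(make_random_chain(25, 7, "backbone_plus_dummy_sidechain"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(at, f)
  s <- read_pdb(f)
  expect_identical(s$atoms$res_ordinal, at$res_ordinal)
  expect_identical(s$atoms$atom, at$atom)
  expect_identical(s$atoms$x, at$x)
  expect_identical(s$atoms$y, at$y)
  expect_identical(s$atoms$z, at$z)
  # and re-writing re-parses identically (fixed point)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s$atoms, f2)
  expect_identical(read_pdb(f2)$atoms, s$atoms)
})
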