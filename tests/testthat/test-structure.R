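# Parsing, validation and inclusion filters for AlphaFold-dialect PDBs.

test_that("a hand-written poly-Ala PDB parses into residues and heavy atoms", {
  helix <- make_ideal_helix(5, sequence = "AAAAA", plddt = 80)
  f <- tempfile(fileext = ".pdb")
  write_protein_pdb(helix, f)
  s <- read_protein_pdb(f)
  expect_equal(n_residues(s), 5)
  expect_equal(sum(s$atoms$elesy != "H"), 25) # N, CA, C, O, CB per Ala
  expect_equal(s$residues$plddt, rep(80, 5))
})

test_that("write -> parse round-trips coordinates to PDB precision", {
  h <- make_ideal_helix(12, plddt = seq(70, 92, length.out = 12))
  f <- tempfile(fileext = ".pdb")
  write_protein_pdb(h, f)
  s <- read_protein_pdb(f)
  expect_equal(as.matrix(s$atoms[, c("x", "y", "z")]),
               as.matrix(h$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(s$residues$plddt, h$residues$plddt)
  # a second round trip is exact: values are already at PDB precision
  f2 <- tempfile(fileext = ".pdb")
  write_protein_pdb(s, f2)
  s2 <- read_protein_pdb(f2)
  expect_identical(s2$atoms[, c("x", "y", "z")], s$atoms[, c("x", "y", "z")])
})

test_that("out-of-range pLDDT values are clamped with a warning", {
  h <- make_ideal_helix(5)
  h$atoms$b <- 101
  expect_warning(s <- protein_structure(h$atoms, alphafold = TRUE),
                 "clamping")
  expect_true(all(s$atoms$b == 100))
  expect_silent(protein_structure(transform(h$atoms, b = 101),
                                  alphafold = FALSE))
})

test_that("malformed ATOM records raise an error naming the line", {
  txt <- c("ATOM      1  N   ALA A   1      0.000   0.000   0.000  1.00 90.00           N",
           "ATOM      2  CA  ALA A   1      1.458   0.000   bad      1.00 90.00           C")
  expect_error(parse_pdb(paste(txt, collapse = "\n")), "line 2")
  expect_error(parse_pdb("REMARK nothing"), "no ATOM records")
})

test_that("multiple chains are concatenated with a warning", {
  h <- make_ideal_helix(6)
  a <- h$atoms
  a$chain[a$resno > 3] <- "B"
  expect_warning(s <- protein_structure(a), "multiple chains")
  expect_equal(n_residues(s), 6)
})

test_that("radii are assigned by element with default and custom tables", {
  h <- assign_radii(make_ideal_helix(5))
  expect_true(all(h$atoms$vdw[h$atoms$elesy == "C"] == 1.70))
  expect_true(all(h$atoms$vdw[h$atoms$elesy == "N"] == 1.55))
  custom <- c(C = 1.70, N = 1.55, O = 1.40, S = 1.80)
  h2 <- assign_radii(make_ideal_helix(5), radii_table = custom)
  expect_true(all(h2$atoms$vdw[h2$atoms$elesy == "O"] == 1.40))
  # unknown element errors unless a fallback is configured
  m <- make_ideal_helix(5)
  m$atoms$elesy[1] <- "SE"
  expect_error(assign_radii(m), "SE")
  expect_equal(assign_radii(m, fallback = 1.9)$atoms$vdw[1], 1.9)
})

test_that("inclusion filters follow the length and mean-pLDDT rules", {
  short <- make_ideal_helix(99, plddt = 90)
  f <- passes_inclusion_filters(short)
  expect_false(f$pass)
  expect_match(f$reasons, "length", all = FALSE)

  border <- make_ideal_helix(300, plddt = 50) # mean exactly 50: excluded
  f2 <- passes_inclusion_filters(border)
  expect_false(f2$pass)
  expect_match(f2$reasons, "pLDDT", all = FALSE)

  good <- make_ideal_helix(300, plddt = 85)
  expect_true(passes_inclusion_filters(good)$pass)
})

test_that("filter decision ignores atom order within residues", {
  h <- make_ideal_helix(120, plddt = 60)
  perm <- withr::with_seed(1, {
    a <- h$atoms
    idx <- unlist(lapply(split(seq_len(nrow(a)), a$resno), sample))
    a[idx, ]
  })
  s <- protein_structure(perm)
  expect_equal(passes_inclusion_filters(s), passes_inclusion_filters(h))
})

test_that("per-residue pLDDT is taken from CA when atoms disagree", {
  h <- make_ideal_helix(5)
  a <- h$atoms
  a$b[a$elety != "CA"] <- 55
  a$b[a$elety == "CA"] <- 91
  expect_warning(s <- protein_structure(a), "CA value")
  expect_equal(s$residues$plddt, rep(91, 5))
})
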