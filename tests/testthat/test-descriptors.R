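# Pseudo-B-factors, hydrophobicity, charge and the descriptor vector.

# build a bare CA-trace structure with chosen per-residue pLDDT
ca_structure <- function(plddt) {
  n <- length(plddt)
  atoms <- data.frame(
    elety = "CA", elesy = "C", resid = "ALA", resno = seq_len(n),
    chain = "A", x = 4 * seq_len(n), y = 0, z = 0, b = plddt,
    stringsAsFactors = FALSE
  )
  protein_structure(atoms)
}

all_surface_mask <- function(s, surface = TRUE) {
  data.frame(resno = s$residues$resno, resid = s$residues$resid,
             sasa = 100, max_sas = 129, rel_acc = 0.775,
             surface = rep(surface, nrow(s$residues)))
}

test_that("pLDDT-to-RMSD follows the empirical formula", {
  expect_identical(plddt_to_rmsd(50), 1.5)
  expect_equal(plddt_to_rmsd(100), 1.5 * exp(-2), tolerance = 1e-12)
  expect_equal(plddt_to_rmsd(100), 0.2030, tolerance = 1e-4)
  expect_equal(plddt_to_rmsd(70), 1.5 * exp(-0.8), tolerance = 1e-12)
  expect_equal(plddt_to_rmsd(70), 0.6740, tolerance = 1e-4)
  expect_error(plddt_to_rmsd(101), "\\[0, 100\\]")
})

test_that("RMSD-to-B follows the Debye-Waller relation", {
  expect_equal(rmsd_to_b(1.5), 6 * pi^2, tolerance = 1e-12)
  expect_lt(rmsd_to_b(1.5), 60) # the quoted B <= 60 equivalence
  expect_identical(rmsd_to_b(0), 0)
  expect_equal(rmsd_to_b(plddt_to_rmsd(70)), 11.96, tolerance = 1e-2)
  expect_error(rmsd_to_b(-1), "non-negative")
})

test_that("the pLDDT-to-B composition is monotone and maps 50 to 6 pi^2", {
  grid <- seq(0, 100, by = 2.5)
  delta <- plddt_to_rmsd(grid)
  expect_true(all(diff(delta) < 0))       # strictly decreasing
  b <- rmsd_to_b(delta)
  expect_true(all(diff(b) < 0))
  expect_true(all((grid >= 50) == (b <= 6 * pi^2 + 1e-12)))
})

test_that("whole-structure B-normalization has mean 0 and population SD 1", {
  s <- ca_structure(plddt = c(55, 62, 70, 78, 85, 91, 96))
  rec <- bfactor_records(s)
  expect_equal(mean(rec$b_norm), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(rec$b_norm^2)), 1, tolerance = 1e-12)
})

test_that("norm_s_b: symmetric set averages to zero, spreadsheet oracle", {
  # choose pLDDTs that give B = 10, 20, 30 exactly
  b_target <- c(10, 20, 30)
  delta <- sqrt(3 * b_target / (8 * pi^2))
  plddt <- 100 * (0.5 - log(delta / 1.5) / 4)
  s <- ca_structure(plddt)
  rec <- bfactor_records(s)
  expect_equal(rec$b, b_target, tolerance = 1e-9)
  expect_true(all(rec$included))
  expect_equal(normalized_surface_b(s, all_surface_mask(s)), 0,
               tolerance = 1e-9)

  # mixed fixture vs an independent hand computation
  plddt2 <- c(52, 60, 75, 88, 95)
  s2 <- ca_structure(plddt2)
  mask2 <- all_surface_mask(s2)
  mask2$surface <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  b2 <- 8 * pi^2 * (1.5 * exp(4 * (0.5 - plddt2 / 100)))^2 / 3
  bn2 <- (b2 - mean(b2)) / sqrt(mean((b2 - mean(b2))^2))
  keep <- mask2$surface & (1.5 * exp(4 * (0.5 - plddt2 / 100))) <= 1.5
  expect_equal(normalized_surface_b(s2, mask2), mean(bn2[keep]),
               tolerance = 1e-12)
})

test_that("degenerate B-factor cases are flagged", {
  s <- ca_structure(rep(80, 4))
  w <- capture_warnings(rec <- bfactor_records(s))
  expect_match(w, "one pLDDT", all = FALSE)
  expect_equal(rec$b_norm, rep(0, 4))
  # nothing passes the RMSD filter below pLDDT 50
  s2 <- ca_structure(rep(30, 4))
  mask <- all_surface_mask(s2)
  w2 <- capture_warnings(v <- normalized_surface_b(s2, mask))
  expect_match(w2, "undefined", all = FALSE)
  expect_true(is.na(v))
})

test_that("surface hydrophobicity hits the scale extremes", {
  s <- ca_structure(rep(90, 3))
  s$residues$resid <- c("ILE", "ILE", "ILE")
  mask <- all_surface_mask(s); mask$resid <- s$residues$resid
  expect_equal(avg_surface_hydrophobicity(s, mask), 0.73) # scale maximum
  s$residues$resid <- mask$resid <- rep("ARG", 3)
  expect_equal(avg_surface_hydrophobicity(s, mask), -1.76) # scale minimum
  expect_warning(v <- avg_surface_hydrophobicity(s, all_surface_mask(s, FALSE)),
                 "undefined")
  expect_true(is.na(v))
})

test_that("charged-area fractions partition the SASA correctly", {
  h <- assign_radii(make_ideal_helix(10, sequence = "AAAAAAAAAA"))
  sasa <- shrake_rupley_sasa(h)
  expect_equal(unname(charged_area_fractions(sasa, h)), c(0, 0, 0))

  # one Asp + one Lys with forged equal SASA
  s <- ca_structure(rep(90, 2))
  s$residues$resid <- c("ASP", "LYS")
  sasa2 <- list(total = 200, per_residue = c(100, 100))
  expect_equal(unname(charged_area_fractions(sasa2, s)), c(0.5, 0.5, 1.0))

  # mixed helix vs a per-residue spreadsheet oracle
  hx <- assign_radii(make_ideal_helix(12, sequence = "ADKLEGRSIVAE"))
  sx <- shrake_rupley_sasa(hx)
  resid <- hx$residues$resid
  neg <- sum(sx$per_residue[resid %in% c("ASP", "GLU")]) / sx$total
  pos <- sum(sx$per_residue[resid %in% c("LYS", "ARG")]) / sx$total
  expect_equal(unname(charged_area_fractions(sx, hx)),
               c(pos, neg, pos + neg), tolerance = 1e-12)
})

test_that("Henderson-Hasselbalch net charge matches direct evaluation", {
  s <- ca_structure(rep(90, 1)); s$residues$resid <- "ASP"
  mask <- all_surface_mask(s); mask$resid <- "ASP"
  expect_equal(net_surface_charge(s, mask), -1 / (1 + 10^(3.65 - 7)),
               tolerance = 1e-12)
  expect_equal(net_surface_charge(s, mask), -0.99955, tolerance = 1e-4)

  s$residues$resid <- mask$resid <- "HIS" # half-protonated at pH = pKa
  expect_equal(net_surface_charge(s, mask, pH = 6.0), 0.5, tolerance = 1e-12)

  s2 <- ca_structure(rep(90, 2))
  mask2 <- all_surface_mask(s2)
  s2$residues$resid <- mask2$resid <- c("ASP", "LYS")
  expect_lt(abs(net_surface_charge(s2, mask2)), 0.01) # near-cancellation

  s3 <- ca_structure(rep(90, 1))
  mask3 <- all_surface_mask(s3); mask3$resid <- "HIS"
  expect_error(net_surface_charge(s3, mask3,
                                  pka = pka_table()[1:2, ]), "missing pKa")
})

test_that("the descriptor vector satisfies its identities", {
  v <- suppressWarnings(
    compute_descriptor_vector(make_ideal_helix(25, plddt = seq(60, 95,
                                                               length.out = 25)),
                              check_filters = FALSE))
  expect_equal(v$s_charge_avg, v$s_pos_area + v$s_neg_area, tolerance = 1e-12)
  expect_equal(v$s_ah + v$s_bs + v$s_do, 1, tolerance = 1e-12)
  fracs <- c(v$s_pos_area, v$s_neg_area, v$s_charge_avg, v$s_ah, v$s_bs, v$s_do)
  expect_true(all(fracs >= 0 & fracs <= 1))
  expect_gt(v$fd, 2); expect_lt(v$fd, 3)
  expect_gt(v$s_ah, 0.6) # a helix fixture is helix-dominated
})

test_that("filters gate compute_descriptor_vector", {
  small <- make_ideal_helix(10)
  expect_error(compute_descriptor_vector(small), "inclusion filters")
})

test_that("descriptor tables are deterministic and log exclusions", {
  structs <- list(make_ideal_helix(20, plddt = seq(70, 90, length.out = 20),
                                   id = "b"),
                  make_ideal_helix(16, plddt = seq(65, 85, length.out = 16),
                                   id = "a"))
  t1 <- suppressWarnings(compute_descriptor_table(structs,
                                                  check_filters = FALSE))
  t2 <- suppressWarnings(compute_descriptor_table(structs,
                                                  check_filters = FALSE))
  expect_identical(t1, t2)
  expect_equal(t1$id, c("a", "b")) # ordered by id
  t3 <- suppressWarnings(compute_descriptor_table(
    list(make_ideal_helix(20, id = "ok", plddt = 80),
         make_ideal_helix(20, id = "low", plddt = 30))))
  expect_equal(nrow(attr(t3, "exclusions")), 2) # both fail default filters
})
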