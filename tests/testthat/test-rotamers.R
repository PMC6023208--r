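test_that("fixture-dialect libraries load and renormalise per amino acid", {
  lib <- load_rotamer_library(c("S * * 0.6 64", "S * * 0.4 -65", "A * * 1.0"))
  s <- lib$records[lib$records$aa == "S", ]
  expect_equal(sum(s$prob), 1)
  expect_equal(s$prob, c(0.6, 0.4))
  expect_false(lib$backbone_dependent)

  expect_warning(
    lib2 <- load_rotamer_library(c("V * * 0.3 175", "V * * 0.2 -60")),
    "renormalised")
  expect_equal(sum(lib2$records$prob), 1)

  expect_error(load_rotamer_library("Z * * 1.0"), class = "cf_format_error")
  expect_error(load_rotamer_library("S * * 1.0"), class = "cf_format_error") # chi missing
})

test_that("the bundled fixture library reads cleanly", {
  lib <- load_rotamer_library(cf_extdata("mini_rotlib.txt"))
  expect_setequal(unique(lib$records$aa), c("A", "S", "C", "V", "L"))
  sums <- tapply(lib$records$prob, lib$records$aa, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("dunbrack2010 dialect parses and keys records to backbone bins", {
  lines <- c(
    "SER  -60  -40    82   1 0 0 0  0.500000   64.0    0.0    0.0    0.0   8.0  0.0  0.0  0.0",
    "SER  -60  -40    82   2 0 0 0  0.300000  -65.0    0.0    0.0    0.0   8.0  0.0  0.0  0.0",
    "SER  -60  -40    82   3 0 0 0  0.200000  178.0    0.0    0.0    0.0   8.0  0.0  0.0  0.0",
    "SER  -50  -40    90   1 0 0 0  1.000000   70.0    0.0    0.0    0.0   8.0  0.0  0.0  0.0")
  lib <- load_rotamer_library(lines, dialect = "dunbrack2010")
  expect_true(lib$backbone_dependent)
  # nearest 10-degree bin: (-58, -41) goes to the (-60, -40) bin
  rec <- contactforge:::lookup_rotamers(lib, "S", -58, -41)
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$prob), 1)
  expect_equal(rec$chi1, c(64, -65, 178))
  rec2 <- contactforge:::lookup_rotamers(lib, "S", -52, -44)
  expect_equal(rec2$chi1, 70)
})

test_that("rotamer library round-trips through the fixture writer", {
  lib <- make_mini_rotlib(seed = 11)
  lib2 <- load_rotamer_library(write_rotamer_library(lib))
  expect_equal(lib2$records$aa, lib$records$aa)
  expect_equal(lib2$records$prob, lib$records$prob, tolerance = 1e-5)
  expect_equal(lib2$records$chi1, lib$records$chi1, tolerance = 1e-3)
})

test_that("build_sidechain reproduces the ideal-geometry table for Ala", {
  st <- make_toy_backbone("helix", 4)
  r <- st$residues[[2]]
  pr <- build_sidechain(r, "A")
  geom <- contactforge:::.sidechain_geom$A[[1]]
  ca <- r$atoms$xyz[r$atoms$name == "CA", ]
  n <- r$atoms$xyz[r$atoms$name == "N", ]
  expect_equal(sqrt(sum((pr$atoms["CB", ] - ca)^2)), geom[[6]], tolerance = 1e-6)
  expect_equal(contactforge:::vec_angle(n, ca, pr$atoms["CB", ]), geom[[7]],
               tolerance = 1e-4)
})

test_that("placed chi dihedrals are recovered exactly for every residue type", {
  st <- make_toy_backbone("helix", 4)
  r <- st$residues[[2]]
  chi_atoms <- list(
    R = c("CG", "CD", "NE", "CZ"), N = c("CG", "OD1"), D = c("CG", "OD1"),
    C = "SG", Q = c("CG", "CD", "OE1"), E = c("CG", "CD", "OE1"),
    H = c("CG", "ND1"), I = c("CG1", "CD1"), L = c("CG", "CD1"),
    K = c("CG", "CD", "CE", "NZ"), M = c("CG", "SD", "CE"),
    F = c("CG", "CD1"), P = c("CG", "CD"), S = "OG", T = "OG1",
    W = c("CG", "CD1"), Y = c("CG", "CD1"), V = "CG1")
  withr::with_seed(7, {
    for (aa in names(chi_atoms)) {
      nchi <- length(chi_atoms[[aa]])
      chi <- runif(nchi, -180, 180)
      pr <- build_sidechain(r, aa, chi)
      chain <- c("N", "CA", "CB", chi_atoms[[aa]])
      coords <- lapply(chain, function(nm)
        if (nm %in% rownames(pr$atoms)) pr$atoms[nm, ]
        else r$atoms$xyz[r$atoms$name == nm, ])
      for (k in seq_len(nchi)) {
        got <- contactforge:::vec_dihedral(coords[[k]], coords[[k + 1]],
                                           coords[[k + 2]], coords[[k + 3]])
        d <- abs(got - chi[k]) %% 360
        expect_lt(min(d, 360 - d), 0.5)
      }
      # bond lengths reproduce the table
      geom <- contactforge:::.sidechain_geom[[aa]]
      for (row in geom) {
        parent <- if (row[[4]] %in% rownames(pr$atoms)) pr$atoms[row[[4]], ]
                  else r$atoms$xyz[r$atoms$name == row[[4]], ]
        expect_equal(sqrt(sum((pr$atoms[row[[1]], ] - parent)^2)), row[[6]],
                     tolerance = 0.1)
      }
    }
  })
  expect_equal(nrow(build_sidechain(r, "G")$atoms), 0)
  expect_error(build_sidechain(toy_residue("A", list(CA = c(0, 0, 0))), "A"),
               class = "cf_missing_atom")
})

test_that("allowed_rotamers renormalises, prunes clashes, and can empty out", {
  lib <- make_mini_rotlib(seed = 3)
  iso <- make_toy_backbone("collinear", 2, spacing = 30)
  ar <- allowed_rotamers(iso, 1, lib)
  n_rec <- nrow(lib$records)
  expect_equal(length(ar), n_rec)  # nothing within reach, all survive
  expect_equal(sum(vapply(ar, `[[`, 0, "prob")), 1, tolerance = 1e-9)

  # plant a fake backbone atom 1.5 A beyond where Ser chi1 = 60 puts OG
  # (on the far side from CB, so only that rotamer is within the clash cut)
  st <- make_toy_backbone("collinear", 2, spacing = 30)
  sc60 <- build_sidechain(st$residues[[1]], "S", 60)$atoms
  og <- sc60["OG", ]
  away <- (og - sc60["CB", ]) / sqrt(sum((og - sc60["CB", ])^2))
  blocker <- toy_residue("G", list(N = og + 1.5 * away), num = 3)
  st$residues <- c(st$residues, list(blocker))
  st$chain <- c(st$chain, "A")
  st$chain_pos <- c(st$chain_pos, 3L)
  slib <- load_rotamer_library(c("S * * 0.5 60", "S * * 0.5 180"))
  ar2 <- allowed_rotamers(st, 1, slib)
  expect_equal(length(ar2), 1)
  expect_equal(ar2[[1]]$chi[1], 180)
  expect_equal(ar2[[1]]$prob, 1)

  # blockers at both rotamer positions -> empty enumeration
  st3 <- make_toy_backbone("collinear", 2, spacing = 30)
  og180 <- build_sidechain(st3$residues[[1]], "S", 180)$atoms["OG", ]
  st3$residues <- c(st3$residues,
                    list(toy_residue("G", list(N = og + 0.5 * away), num = 3),
                         toy_residue("G", list(N = og180), num = 4)))
  st3$chain <- c(st3$chain, "A", "A")
  st3$chain_pos <- c(st3$chain_pos, 3L, 4L)
  expect_length(allowed_rotamers(st3, 1, slib), 0)
})

test_that("pruning is monotone in the clash cutoff", {
  lib <- make_mini_rotlib(seed = 5)
  st <- make_toy_backbone("helix", 8, sequence = "AVLSF")
  for (pos in c(2, 4, 6)) {
    keys <- function(cut) {
      ar <- allowed_rotamers(st, pos, lib, backbone_clash_cut = cut)
      vapply(ar, function(r) paste(r$aa, paste(round(r$chi, 3), collapse = ",")), "")
    }
    k1 <- keys(1.0); k2 <- keys(2.0); k3 <- keys(3.0)
    expect_true(all(k2 %in% k1))
    expect_true(all(k3 %in% k2))
  }
})

test_that("undefined backbone dihedrals fall back with a warning", {
  lines <- c("SER  -60  -40  10  1 0 0 0  1.0  64.0 0 0 0 0 0 0 0")
  lib <- load_rotamer_library(lines, dialect = "dunbrack2010")
  expect_warning(contactforge:::lookup_rotamers(lib, "S", NA, -40), "phi")
})
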