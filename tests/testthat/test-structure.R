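test_that("parse_structure reads a minimal ALA-GLY fixture", {
  st <- parse_structure(pdb_ala_gly(), id = "mini")
  expect_equal(n_residues(st), 2)
  expect_equal(structure_sequence(st), "AG")
  gly <- st$residues[[2]]
  expect_false("CB" %in% gly$atoms$name)
  # Gly C-beta falls back to C-alpha
  expect_equal(get_cbeta(gly), c(3.910, 1.312, 2.630))
  ala <- st$residues[[1]]
  expect_equal(get_cbeta(ala), c(1.988, -1.420, 0.080))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  txt <- paste(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA ASER A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BSER A   1       9.000   9.000   9.000  0.40  0.00           C",
    "ATOM      4  C   SER A   1       2.000   1.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  st <- parse_structure(txt)
  r <- st$residues[[1]]
  expect_equal(sum(r$atoms$name == "CA"), 1)
  expect_equal(r$atoms$xyz[r$atoms$name == "CA", ], c(1, 0, 0))

  # occupancy tie resolves by altloc identifier order
  txt2 <- gsub("0.60", "0.40", txt, fixed = TRUE)
  st2 <- parse_structure(txt2)
  r2 <- st2$residues[[1]]
  expect_equal(r2$atoms$xyz[r2$atoms$name == "CA", ], c(1, 0, 0))
})

test_that("hetero handling: MSE mapped to MET, waters dropped, junk warned", {
  txt <- paste(c(
    "HETATM    1  N   MSE A   1       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  CA  MSE A   1       1.458   0.000   0.000  1.00  0.00           C",
    "HETATM    3  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), collapse = "\n")
  st <- parse_structure(txt)
  expect_equal(n_residues(st), 1)
  expect_equal(st$residues[[1]]$aa, "M")
  bad <- paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  P1  XYZ A   2       1.000   1.000   1.000  1.00  0.00           P",
    "END"), collapse = "\n")
  expect_warning(parse_structure(bad), "XYZ")
})

test_that("multi-model files follow the model policy", {
  one <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C")
  txt <- paste(c("MODEL     1", one, "ENDMDL", "MODEL     2",
                 gsub("0.000   0.000   0.000", "9.000   9.000   9.000", one),
                 "ENDMDL", "END"), collapse = "\n")
  st <- parse_structure(txt, model_policy = "first")
  expect_equal(n_residues(st), 1)
  expect_equal(atom_xyz <- st$residues[[1]]$atoms$xyz[1, ], c(0, 0, 0))
  expect_error(parse_structure(txt, model_policy = "error-on-multi"),
               class = "cf_format_error")
})

test_that("parse errors are classified", {
  expect_error(parse_structure("END"), class = "cf_empty_structure")
  bad <- "ATOM      1  N   ALA A   1       xxx       0.000   0.000  1.00  0.00"
  expect_error(parse_structure(bad), class = "cf_format_error")
})

test_that("write/parse round trip preserves counts, order and coordinates", {
  st <- make_toy_backbone("helix", 20, sequence = "AVLSFGMKDE")
  st2 <- parse_structure(write_pdb(st))
  expect_equal(n_residues(st2), 20)
  expect_equal(structure_sequence(st2), structure_sequence(st))
  for (k in c(1, 7, 20)) {
    expect_equal(st2$residues[[k]]$atoms$name, st$residues[[k]]$atoms$name)
    expect_equal(st2$residues[[k]]$atoms$xyz, st$residues[[k]]$atoms$xyz,
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("get_centroid averages heavy side-chain atoms with declared fallbacks", {
  r <- toy_residue("L", list(CA = c(9, 9, 9), CB = c(0, 0, 0), CG = c(2, 0, 0)))
  expect_equal(get_centroid(r), c(1, 0, 0))
  ala <- toy_residue("A", list(CA = c(5, 5, 5), CB = c(1, 2, 3)))
  expect_equal(get_centroid(ala), c(1, 2, 3))
  gly <- toy_residue("G", list(N = c(0, 0, 0), CA = c(1, 2, 3)))
  expect_equal(get_centroid(gly), c(1, 2, 3))
  # hydrogens never contribute
  rh <- toy_residue("S", list(CB = c(2, 0, 0), HB1 = c(50, 0, 0)))
  expect_equal(get_centroid(rh), c(2, 0, 0))
  expect_error(get_cbeta(toy_residue("S", list(CA = c(0, 0, 0)))),
               class = "cf_missing_atom")
})

test_that("centroid is equivariant under side-chain translation", {
  r <- toy_residue("L", list(CB = c(0.3, -1, 2), CG = c(1.5, 0.5, 0), CD1 = c(2, 2, 2)))
  v <- c(3.2, -1.7, 0.4)
  r2 <- r
  r2$atoms$xyz <- sweep(r$atoms$xyz, 2, v, "+")
  expect_equal(get_centroid(r2), get_centroid(r) + v)
})

test_that("min_heavy_distance matches brute force and obeys the triangle bound", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      na <- sample(2:4, 1); nb <- sample(2:4, 1)
      A <- toy_residue("L", setNames(lapply(seq_len(na), function(k) rnorm(3, 0, 4)),
                                     paste0("C", seq_len(na))))
      B <- toy_residue("F", setNames(lapply(seq_len(nb), function(k) rnorm(3, 3, 4)),
                                     paste0("C", seq_len(nb))))
      d <- min_heavy_distance(A, B)
      brute <- min(apply(A$atoms$xyz, 1, function(x)
        min(sqrt(colSums((t(B$atoms$xyz) - x)^2)))))
      expect_equal(d, brute, tolerance = 1e-12)
      expect_equal(d, min_heavy_distance(B, A))
      ca <- colMeans(A$atoms$xyz); cb <- colMeans(B$atoms$xyz)
      ra <- sqrt(max(rowSums(sweep(A$atoms$xyz, 2, ca)^2)))
      rb <- sqrt(max(rowSums(sweep(B$atoms$xyz, 2, cb)^2)))
      expect_lte(d, sqrt(sum((ca - cb)^2)) + ra + rb + 1e-9)
    }
  })
})

test_that("hydrogen identification falls back to atom-name heuristics", {
  # no element column at all
  txt <- paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3 HB21 ALA A   1       2.000   1.000   0.000  1.00  0.00",
    "END"), collapse = "\n")
  st <- parse_structure(txt)
  a <- st$residues[[1]]$atoms
  expect_true(a$is_hydrogen[a$name == "HB21"])
  expect_false(any(a$is_hydrogen[a$name %in% c("N", "CA")]))
})
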