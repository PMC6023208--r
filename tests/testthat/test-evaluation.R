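test_that("map_structure_to_msa handles identity, gaps, and row choice", {
  msa <- contactforge:::new_msa(c("r1", "r2"), c("AVLSF", "AV-SF"))
  m1 <- map_structure_to_msa("AVLSF", msa)
  expect_equal(m1$row, 1)
  expect_equal(m1$map, 1:5)
  expect_equal(m1$similarity, 1)

  # the shorter sequence maps around the gapped column (both rows reach
  # full similarity here, so only the column map is asserted)
  m2 <- map_structure_to_msa("AVSF", msa)
  expect_equal(m2$map, c(1, 2, 4, 5))

  # highest-similarity row wins
  msa3 <- contactforge:::new_msa(c("bad", "good"), c("AAAAAAAAAA", "AVLSFAVLSV"))
  m3 <- map_structure_to_msa("AVLSFAVLSF", msa3)
  expect_equal(m3$row, 2)
  expect_equal(m3$similarity, 0.9)

  empty <- structure(list(ids = character(0), seqs = character(0)),
                     class = "cf_msa")
  expect_error(map_structure_to_msa("AV", empty), class = "cf_config_error")
})

test_that("true_contacts unions structures and filters separations in column space", {
  mk_map <- function(pairs, n = 30) structure(list(
    id = "x", definition = contact_definition("cbeta"),
    pairs = data.frame(i = pairs[, 1], j = pairs[, 2],
                       chain_i = "A", resnum_i = "1", chain_j = "A",
                       resnum_j = "2", value = 1,
                       is_contact = TRUE)), class = "cf_contact_map")
  cm1 <- mk_map(rbind(c(1, 10)))
  cm2 <- mk_map(rbind(c(2, 20)))
  idmap <- 1:30
  tc <- true_contacts(list(cm1, cm2), list(idmap, idmap), rule = "any-structure")
  expect_equal(nrow(tc$pairs), 2)
  tc1 <- true_contacts(list(cm1, cm2), list(idmap, idmap), rule = "single-structure")
  expect_equal(tc1$pairs, data.frame(i = 1L, j = 10L))

  # separation 4 is excluded under the family-style >= 5 rule
  cm3 <- mk_map(rbind(c(1, 5), c(1, 6)))
  tc3 <- true_contacts(list(cm3), list(idmap), min_separation = 5)
  expect_equal(tc3$pairs, data.frame(i = 1L, j = 6L))
})

test_that("ppv_at counts true contacts among the top ranked pairs", {
  ranked <- data.frame(i = 1:5, j = 11:15, score = 5:1)
  truth <- data.frame(i = c(1, 2, 4), j = c(11, 12, 14))
  expect_equal(ppv_at(ranked, truth, N = 3), 2 / 3)
  expect_equal(ppv_at(ranked, truth, N = 2), 1)
  expect_equal(ppv_at(ranked, data.frame(i = integer(0), j = integer(0)), N = 3), 0)
  # k = all pairs equals the base rate
  expect_equal(ppv_at(ranked, truth, N = 5), 3 / 5)
  # f-based cutoff: round-half-up with floor 1
  expect_equal(ppv_at(ranked, truth, f = 0.05, L = 10), 1)      # k = 1
  expect_equal(ppv_at(ranked, truth, f = 0.25, L = 10), 2 / 3)  # k = round(2.5) = 3
})

test_that("ppv_at equals brute-force evaluation on random fixtures", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- 30
      ranked <- data.frame(i = sample(1:20, n, TRUE), j = sample(21:40, n, TRUE),
                           score = runif(n))
      ranked <- ranked[!duplicated(paste(ranked$i, ranked$j)), ]
      truth <- unique(ranked[sample(nrow(ranked), 8, TRUE), c("i", "j")])
      N <- sample(3:10, 1)
      ord <- ranked[order(-ranked$score, ranked$i, ranked$j), ]
      top <- utils::head(ord, N)
      brute <- mean(paste(top$i, top$j) %in% paste(truth$i, truth$j))
      expect_equal(ppv_at(ranked, truth, N = N), brute)
    }
  })
})

test_that("separation bins follow the documented boundaries", {
  ranked <- data.frame(i = c(1, 1, 1), j = c(8, 20, 31), score = 3:1)
  truth <- data.frame(i = 1, j = 31)
  out <- separation_binned_ppv(ranked, truth, N = 5)
  expect_equal(unname(out["short"]), 0)   # (1, 8): separation 7, not true
  expect_equal(unname(out["long"]), 1)
  # separation exactly 23 is long-range
  r23 <- data.frame(i = 1, j = 24, score = 1)
  out23 <- separation_binned_ppv(r23, data.frame(i = 1, j = 24), N = 5)
  expect_equal(unname(out23["long"]), 1)
  expect_true(is.na(out23["medium"]))
})

test_that("contact diversity reproduces the entropy examples", {
  # all pairs in one cell
  one <- data.frame(i = c(1, 2, 3), j = c(12, 13, 14), score = 3:1)
  expect_equal(contact_diversity(one, L = 100, n_top = 3), 0)
  # uniform over all 100 cells
  grid <- expand.grid(ci = 0:9, cj = 0:9)
  unif <- data.frame(i = grid$ci * 10 + 1, j = grid$cj * 10 + 1, score = 1)
  expect_equal(contact_diversity(unif, L = 100, n_top = 100), log2(100))
  # four pairs split 3/1 over two cells
  split <- data.frame(i = c(1, 2, 3, 11), j = c(15, 15, 16, 25), score = 4:1)
  expect_equal(contact_diversity(split, L = 100, n_top = 4),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-9)
  expect_error(contact_diversity(one, L = 1), class = "cf_config_error")
})

test_that("diversity is bounded and blind to within-cell placement", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- 25; L <- 60
      r <- data.frame(i = sample(L, n, TRUE), j = sample(L, n, TRUE),
                      score = runif(n))
      d <- contact_diversity(r, L, n_top = n)
      expect_gte(d, 0)
      expect_lte(d, log2(100) + 1e-9)
    }
  })
  # moving a pair within its cell leaves D unchanged
  a <- data.frame(i = c(1, 3), j = c(15, 42), score = c(2, 1))
  b <- data.frame(i = c(5, 3), j = c(11, 42), score = c(2, 1))  # same cells
  expect_equal(contact_diversity(a, L = 100, n_top = 2),
               contact_diversity(b, L = 100, n_top = 2))
})
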