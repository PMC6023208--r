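# Shared fixtures and independent oracles.

cf_extdata <- function(f) system.file("extdata", f, package = "contactforge")

# Independent contact-degree oracle: plain exhaustive double sum over all
# allowed rotamer pairs with naive atom-by-atom distance loops. Kept free of
# the bounding-sphere pruning and vectorised distance code that compute_cd
# uses.
brute_cd <- function(st, i, j, lib, cut = 3) {
  ri <- allowed_rotamers(st, i, lib)
  rj <- allowed_rotamers(st, j, lib)
  if (!length(ri) || !length(rj)) return(0)
  tot <- 0
  for (a in ri) {
    for (b in rj) {
      hit <- FALSE
      if (nrow(a$atoms) > 0 && nrow(b$atoms) > 0) {
        for (x in seq_len(nrow(a$atoms))) {
          for (y in seq_len(nrow(b$atoms))) {
            if (sqrt(sum((a$atoms[x, ] - b$atoms[y, ])^2)) < cut) hit <- TRUE
          }
        }
      }
      if (hit) tot <- tot + a$prob * b$prob
    }
  }
  tot
}

# minimal hand-written two-residue ALA-GLY PDB text
pdb_ala_gly <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.004   0.775   1.194  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   1.572   1.756  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -1.420   0.080  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.290   0.608   1.520  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.910   1.312   2.630  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.350   0.890   2.880  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       5.790  -0.160   2.420  1.00  0.00           O",
    "END"), collapse = "\n")
}

# one-atom-per-residue toy: residue records usable by the geometric accessors
toy_residue <- function(aa, coords, chain = "A", num = 1) {
  nm <- names(coords)
  list(chain = chain, resnum = as.character(num), aa = aa,
       atoms = list(name = nm, element = substr(nm, 1, 1),
                    xyz = do.call(rbind, coords),
                    is_backbone = nm %in% c("N", "CA", "C", "O", "OXT"),
                    is_hydrogen = grepl("^H", nm)),
       phi = NA_real_, psi = NA_real_)
}

# two-amino-acid count fixture over A and V
counts_av <- function(aa_av_vv) {
  nc <- matrix(0, 2, 2, dimnames = list(c("A", "V"), c("A", "V")))
  nc["A", "A"] <- aa_av_vv[1]
  nc["A", "V"] <- nc["V", "A"] <- aa_av_vv[2]
  nc["V", "V"] <- aa_av_vv[3]
  list(nc = nc, f = c(A = 0.5, V = 0.5), nc_total = sum(aa_av_vv))
}
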