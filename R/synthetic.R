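# Seeded generators for every input the test surface needs: toy backbones,
# miniature rotamer libraries, synthetic structure databases with planted
# amino-acid pair enrichment, synthetic alignments with planted contacts and
# co-evolution scores, and coordinate-perturbation decoys. All randomness
# flows through an explicit seed (withr::with_seed), so fixtures are
# reproducible bit-for-bit.

BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.5)

#' Build a toy backbone structure
#'
#' Constructs an ideal-geometry backbone (N, CA, C, O, and CB for
#' non-glycine residues) by sequential internal-coordinate placement.
#' Kinds: `"helix"` (phi -57, psi -47), `"strand"` (phi -139, psi 135),
#' `"strand_pair"` (two strand chains A and B separated by `spacing`
#' Angstroms), and `"collinear"` (disconnected single-residue clusters
#' spaced `spacing` Angstroms along the x axis, each residue's atoms lying
#' in a plane perpendicular to it).
#'
#' @param kind Backbone kind.
#' @param length Residues per chain.
#' @param sequence One-letter sequence (recycled); default poly-alanine.
#' @param spacing Inter-chain or inter-residue spacing in Angstroms.
#' @param phi,psi Override backbone dihedrals (degrees).
#' @param jitter Gaussian coordinate noise (sd, Angstroms) applied to all
#'   atoms; requires `seed`.
#' @param seed Seed for `jitter`.
#' @param id Structure id.
#' @return A `cf_structure`.
#' @export
make_toy_backbone <- function(kind = c("helix", "strand", "strand_pair", "collinear"),
                              length = 10L, sequence = "A", spacing = 5,
                              phi = NULL, psi = NULL, jitter = 0, seed = 1L,
                              id = NULL) {
  kind <- match.arg(kind)
  if (is.null(id)) id <- paste0("toy_", kind)
  seq1 <- rep(strsplit(paste(sequence, collapse = ""), "")[[1]],
              length.out = length)
  if (any(!seq1 %in% AA1)) cf_stop("sequence contains non-standard codes",
                                   "cf_config_error")
  defaults <- switch(kind, helix = c(-57, -47), strand = c(-139, 135),
                     strand_pair = c(-139, 135), collinear = c(NA, NA))
  if (is.null(phi)) phi <- defaults[1]
  if (is.null(psi)) psi <- defaults[2]

  chain_residues <- function(chain, origin) {
    if (kind == "collinear") return(collinear_residues(chain, seq1, spacing, origin))
    g <- BB_GEOM
    res <- vector("list", length)
    N <- origin
    CA <- origin + c(g$n_ca, 0, 0)
    C <- place_atom(origin + c(0, 1, 0), N, CA, g$ca_c, g$ang_n_ca_c, phi)
    for (k in seq_len(length)) {
      Nn <- place_atom(N, CA, C, g$c_n, g$ang_ca_c_n, psi)
      O <- place_atom(N, CA, C, g$c_o, g$ang_ca_c_o, psi + 180)
      res[[k]] <- new_residue(chain, k, seq1[k], list(N = N, CA = CA, C = C, O = O))
      if (k < length) {
        CAn <- place_atom(CA, C, Nn, g$n_ca, g$ang_c_n_ca, 180)
        Cn <- place_atom(C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi)
        N <- Nn; CA <- CAn; C <- Cn
      }
    }
    res
  }
  residues <- chain_residues("A", c(0, 0, 0))
  if (kind == "strand_pair")
    residues <- c(residues, lapply(chain_residues("B", c(0, 0, 0)), function(r) {
      r$chain <- "B"
      r$atoms$xyz <- sweep(r$atoms$xyz, 2, c(0, spacing, 0), "+")
      r
    }))

  st <- assemble_structure(id, residues)
  st <- add_cbeta(st)
  if (jitter > 0)
    st <- withr::with_seed(seed, perturb_structure(st, jitter, reseed = FALSE))
  compute_backbone_dihedrals(st)
}

collinear_residues <- function(chain, seq1, spacing, origin) {
  g <- BB_GEOM
  # local backbone laid out in the y-z plane and translated along x only,
  # so every inter-residue atom distance is at least `spacing`
  N0 <- c(0, 0, 0)
  CA0 <- c(0, g$n_ca, 0)
  u <- c(0, -cos(g$ang_n_ca_c * pi / 180), sin(g$ang_n_ca_c * pi / 180))
  C0 <- CA0 + g$ca_c * u
  O0 <- C0 + g$c_o * c(0, 0.55, 0.835) / vec_norm(c(0, 0.55, 0.835))
  lapply(seq_along(seq1), function(k) {
    sh <- c(origin[1] + (k - 1) * spacing, origin[2], origin[3])
    new_residue(chain, k, seq1[k],
                list(N = N0 + sh, CA = CA0 + sh, C = C0 + sh, O = O0 + sh))
  })
}

new_residue <- function(chain, num, aa, coords) {
  nm <- names(coords)
  list(chain = chain, resnum = as.character(num), aa = aa,
       atoms = list(name = nm,
                    element = substr(nm, 1, 1),
                    xyz = do.call(rbind, coords),
                    is_backbone = nm %in% BACKBONE_ATOMS,
                    is_hydrogen = rep(FALSE, length(nm))),
       phi = NA_real_, psi = NA_real_)
}

assemble_structure <- function(id, residues) {
  ch <- vapply(residues, `[[`, "", "chain")
  structure(list(id = id, residues = residues, chain = ch,
                 chain_pos = stats::ave(seq_along(ch), ch, FUN = seq_along)),
            class = "cf_structure")
}

# place CB on every non-Gly residue from its ideal-geometry row
add_cbeta <- function(st) {
  for (k in seq_along(st$residues)) {
    r <- st$residues[[k]]
    if (r$aa == "G" || "CB" %in% r$atoms$name) next
    row <- .sidechain_geom[[r$aa]][[1]]
    cb <- place_atom(atom_xyz(r, row[[2]]), atom_xyz(r, row[[3]]),
                     atom_xyz(r, row[[4]]), row[[6]], row[[7]], row[[8]])
    r$atoms$name <- c(r$atoms$name, "CB")
    r$atoms$element <- c(r$atoms$element, "C")
    r$atoms$xyz <- rbind(r$atoms$xyz, cb)
    r$atoms$is_backbone <- c(r$atoms$is_backbone, FALSE)
    r$atoms$is_hydrogen <- c(r$atoms$is_hydrogen, FALSE)
    st$residues[[k]] <- r
  }
  st
}

#' Add Gaussian coordinate noise to every atom
#' @param st A `cf_structure`.
#' @param sd Noise standard deviation in Angstroms.
#' @param seed Seed; `reseed = FALSE` uses the current RNG state.
#' @param reseed Whether to seed the RNG (default `TRUE`).
#' @export
perturb_structure <- function(st, sd, seed = 1L, reseed = TRUE) {
  body <- function() {
    for (k in seq_along(st$residues)) {
      xyz <- st$residues[[k]]$atoms$xyz
      st$residues[[k]]$atoms$xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, sd),
                                                 nrow(xyz), 3)
    }
    compute_backbone_dihedrals(st)
  }
  if (reseed) withr::with_seed(seed, body()) else body()
}

#' Generate a miniature rotamer library
#'
#' Backbone-independent fixture library over a small alphabet, sized so
#' brute-force contact-degree enumeration stays trivially cheap.
#'
#' @param aas One-letter codes (default five types spanning 0-2 chi angles).
#' @param rotamers_per_aa Rotamers per type with at least one chi.
#' @param seed Seed.
#' @return A `cf_rotlib`.
#' @export
make_mini_rotlib <- function(aas = c("A", "S", "V", "L", "F"),
                             rotamers_per_aa = 2L, seed = 1L) {
  withr::with_seed(seed, {
    rows <- list()
    for (aa in aas) {
      nchi <- .n_chi[[aa]]
      k <- if (nchi == 0) 1L else rotamers_per_aa
      pr <- stats::rexp(k)
      pr <- pr / sum(pr)
      for (r in seq_len(k)) {
        chi <- rep(NA_real_, 4)
        if (nchi > 0)
          chi[seq_len(nchi)] <- sample(c(-60, 60, 180), nchi, replace = TRUE) +
            stats::runif(nchi, -15, 15)
        rows[[length(rows) + 1]] <- data.frame(aa = aa, phi = NA_real_,
                                               psi = NA_real_, prob = pr[r],
                                               chi1 = chi[1], chi2 = chi[2],
                                               chi3 = chi[3], chi4 = chi[4])
      }
    }
    rec <- do.call(rbind, rows)
    aw <- setNames(rep(1 / length(aas), length(aas)), sort(aas))
    structure(list(records = rec, backbone_dependent = FALSE, aa_weights = aw),
              class = "cf_rotlib")
  })
}

#' Generate a synthetic structure database with planted pair enrichment
#'
#' Reuses one ideal helix geometry and assigns each structure a sequence
#' drawn from a pairwise model in which contacts between the chosen
#' amino-acid pair are favored by `multiplier`:
#' `P(seq) propto prod f(a_i) * multiplier^(# enriched contacts)`.
#' Sequences are sampled by seeded Metropolis sweeps over single-site
#' changes (a tractable equivalent of rejection sampling on the same
#' target). The derived potential's planted cell approaches
#' `-ln(multiplier)`; measured amino-acid frequencies are themselves
#' slightly enriched by the planting, which attenuates the recovered
#' energy by roughly `2 ln(21/20)` (about 0.1 for multiplier 2) even in
#' the ideal disjoint-pair limit.
#'
#' @param n_structures Number of structures.
#' @param chain_length Residues per structure.
#' @param geometry `"helix"` (compact, protein-like contact graph, default)
#'   or `"extended"` (sparse `(i, i + 2)` path graph).
#' @param enrich_pair Length-2 one-letter vector, default `c("L", "F")`.
#' @param multiplier Contact-rate multiplier (> 0), default 2.
#' @param definition Contact definition used for the planted-contact graph;
#'   default C-beta < 8 A with separation filter 2.
#' @param n_sweeps Metropolis sweeps per structure.
#' @param seed Seed.
#' @return List of `cf_structure`.
#' @export
make_synthetic_database <- function(n_structures = 200L, chain_length = 50L,
                                    enrich_pair = c("L", "F"), multiplier = 2,
                                    definition = contact_definition("cbeta",
                                                                    min_separation = 2),
                                    geometry = c("helix", "extended"),
                                    n_sweeps = 60L, seed = 1L) {
  stopifnot(multiplier > 0, length(enrich_pair) == 2)
  geometry <- match.arg(geometry)
  template <- if (geometry == "extended")
    make_toy_backbone("collinear", chain_length, spacing = 3.8,
                      id = "synthdb_template")
  else
    make_toy_backbone("helix", chain_length, id = "synthdb_template")
  cm <- compute_contact_map(template, definition)
  cp <- cm$pairs[cm$pairs$is_contact, c("i", "j")]
  # neighbor lists for the Metropolis energy delta
  nbr <- lapply(seq_len(chain_length), function(k)
    c(cp$j[cp$i == k], cp$i[cp$j == k]))
  lj <- log(multiplier)
  a1 <- enrich_pair[1]; a2 <- enrich_pair[2]

  withr::with_seed(seed, {
    lapply(seq_len(n_structures), function(s) {
      aa <- sample(AA1, chain_length, replace = TRUE)
      n_enr <- function(x, k) sum((x == a1 & aa[nbr[[k]]] == a2) |
                                  (x == a2 & aa[nbr[[k]]] == a1))
      for (sweep in seq_len(n_sweeps)) {
        for (k in sample.int(chain_length)) {
          prop <- sample(AA1, 1)
          dE <- lj * (n_enr(prop, k) - n_enr(aa[k], k))
          if (dE >= 0 || stats::runif(1) < exp(dE)) aa[k] <- prop
        }
      }
      st <- template
      st$id <- sprintf("synthdb_%03d", s)
      for (k in seq_len(chain_length)) st$residues[[k]]$aa <- aa[k]
      st
    })
  })
}

#' Random symmetric contact-potential table
#'
#' Synthetic stand-in for a database-derived potential: independent
#' Gaussian energies (mean 0) symmetrised over the 20 standard types.
#' @param sd Energy standard deviation (default 0.5).
#' @param seed Seed.
#' @return A `cf_potential` (convention `"synthetic"`).
#' @export
make_random_potential <- function(sd = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    E <- matrix(stats::rnorm(400, 0, sd), 20, 20, dimnames = list(AA1, AA1))
    E <- (E + t(E)) / 2
    structure(list(E = E, convention = "synthetic",
                   provenance = list(sd = sd, seed = seed)),
              class = "cf_potential")
  })
}

#' Generate a synthetic alignment with planted contacts and scores
#'
#' Plants `n_pairs` disjoint column pairs (separation at least
#' `min_separation`) whose rows carry amino-acid pairs drawn with
#' probability proportional to `exp(-bias * E(a, b))`, i.e. biased toward
#' the favorable tail of the supplied potential; all other columns are
#' filled uniformly at random. Co-evolution scores are the true-contact
#' indicator plus Gaussian noise, clipped at zero (a DI-like score).
#'
#' @param potential A `cf_potential` (e.g. [make_random_potential()]).
#' @param L Alignment length (columns), default 50.
#' @param depth Alignment depth (rows), default 80.
#' @param n_pairs Planted contact pairs, default 10.
#' @param bias Energy bias in the planted-pair sampler, default 2.
#' @param noise_sd Score noise standard deviation, default 0.5.
#' @param min_separation Separation filter, default 5.
#' @param seed Seed.
#' @return List with `msa` (`cf_msa`), `scores` (`cf_coev_scores`) and
#'   `truth` (`cf_true_contacts`).
#' @export
make_synthetic_msa <- function(potential, L = 50L, depth = 80L, n_pairs = 10L,
                               bias = 2, noise_sd = 0.5, min_separation = 5L,
                               seed = 1L) {
  stopifnot(2L * n_pairs <= L)
  withr::with_seed(seed, {
    cols <- sample.int(L)
    planted <- matrix(NA_integer_, 0, 2)
    used <- integer(0)
    for (c1 in cols) {
      if (nrow(planted) >= n_pairs) break
      if (c1 %in% used) next
      cand <- setdiff(cols[abs(cols - c1) >= min_separation], used)
      cand <- setdiff(cand, c1)
      if (!length(cand)) next
      c2 <- cand[1]
      planted <- rbind(planted, sort(c(c1, c2)))
      used <- c(used, c1, c2)
    }
    M <- matrix(sample(AA1, depth * L, replace = TRUE), depth, L)
    aas <- rownames(potential$E)
    combos <- expand.grid(a = aas, b = aas, stringsAsFactors = FALSE)
    w <- exp(-bias * potential_energy(potential, combos$a, combos$b))
    w[!is.finite(w)] <- 0
    for (p in seq_len(nrow(planted))) {
      pick <- sample.int(nrow(combos), depth, replace = TRUE, prob = w)
      M[, planted[p, 1]] <- combos$a[pick]
      M[, planted[p, 2]] <- combos$b[pick]
    }
    msa <- new_msa(sprintf("seq%03d", seq_len(depth)),
                   apply(M, 1, paste, collapse = ""))
    pk <- paste(planted[, 1], planted[, 2], sep = ":")
    ij <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    ij <- ij[ij[, 2] - ij[, 1] >= min_separation, , drop = FALSE]
    ind <- paste(ij[, 1], ij[, 2], sep = ":") %in% pk
    sc <- pmax(0, as.numeric(ind) + stats::rnorm(nrow(ij), 0, noise_sd))
    scores <- structure(list(pairs = data.frame(i = ij[, 1], j = ij[, 2],
                                                score = sc),
                             s_max = max(sc), kind = "DI",
                             min_separation = as.integer(min_separation)),
                        class = "cf_coev_scores")
    truth <- structure(list(pairs = data.frame(i = planted[, 1],
                                               j = planted[, 2]),
                            min_separation = as.integer(min_separation),
                            rule = "planted"),
                       class = "cf_true_contacts")
    list(msa = msa, scores = scores, truth = truth)
  })
}

#' Generate a coordinate-perturbation decoy set
#'
#' @param native A `cf_structure`.
#' @param n Number of decoys.
#' @param perturbation Gaussian coordinate noise sd in Angstroms; larger
#'   values retain fewer native contacts.
#' @param seed Seed.
#' @return List with `id`, `native` and `decoys`.
#' @export
make_decoys <- function(native, n = 10L, perturbation = 2, seed = 1L) {
  stopifnot(n >= 1)
  decoys <- withr::with_seed(seed, lapply(seq_len(n), function(k) {
    d <- perturb_structure(native, perturbation, reseed = FALSE)
    d$id <- sprintf("%s_decoy%03d", native$id, k)
    d
  }))
  list(id = native$id, native = native, decoys = decoys)
}
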