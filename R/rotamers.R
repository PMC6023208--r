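# Rotamer libraries and side-chain placement.
#
# A rotamer library holds per-amino-acid side-chain conformations (chi
# dihedrals) with probabilities, optionally indexed by backbone (phi, psi)
# bins. Side chains are built onto a backbone from ideal internal
# coordinates (see geometry-data.R) by sequential NeRF placement.

#' Load a rotamer library
#'
#' Two dialects are supported. `"dunbrack2010"` reads the backbone-dependent
#' 2010 text format: whitespace-separated lines
#' `aa3 phi psi count r1 r2 r3 r4 prob chi1 chi2 chi3 chi4 ...`.
#' `"fixture"` reads the compact table used by in-repo fixtures:
#' `aa1 phi psi prob chi1 [chi2 chi3 chi4]`, where `phi`/`psi` may be `*`
#' for a backbone-independent record. Lines starting with `#` are ignored.
#' Probabilities are renormalised to sum to one within each
#' (amino acid, phi bin, psi bin) group; a warning is emitted when the raw
#' sum differs from one by more than 1e-3.
#'
#' @param text Library text, a character vector of lines, or a file path.
#' @param dialect `"fixture"` or `"dunbrack2010"`.
#' @param aa_weights Prior over amino-acid types used when rotamers of all
#'   types compete at one position; default uniform over the types present.
#' @return An object of class `cf_rotlib` with elements `records`
#'   (data.frame `aa, phi, psi, prob, chi1..chi4`), `backbone_dependent`,
#'   and `aa_weights`.
#' @export
load_rotamer_library <- function(text, dialect = c("fixture", "dunbrack2010"),
                                 aa_weights = NULL) {
  dialect <- match.arg(dialect)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  else
    text <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- text[!grepl("^\\s*(#|$)", text)]
  if (!length(lines)) cf_stop("empty rotamer library", "cf_format_error")

  parse_line <- function(ln, k) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (dialect == "dunbrack2010") {
      if (length(f) < 13)
        cf_stop(sprintf("malformed library line %d: '%s'", k, ln), "cf_format_error")
      aa <- unname(AA3TO1[toupper(f[1])])
      if (is.na(aa))
        cf_stop(sprintf("unknown amino acid '%s' at line %d", f[1], k), "cf_format_error")
      vals <- suppressWarnings(as.numeric(f[c(2, 3, 9, 10:13)]))
      if (any(!is.finite(vals)))
        cf_stop(sprintf("malformed library line %d: '%s'", k, ln), "cf_format_error")
      c(list(aa = aa, phi = vals[1], psi = vals[2], prob = vals[3]),
        as.list(vals[4:7]))
    } else {
      if (length(f) < 4)
        cf_stop(sprintf("malformed library line %d: '%s'", k, ln), "cf_format_error")
      aa <- toupper(f[1])
      if (!aa %in% AA1)
        cf_stop(sprintf("unknown amino acid '%s' at line %d", f[1], k), "cf_format_error")
      ang <- function(s) if (s == "*") NA_real_ else suppressWarnings(as.numeric(s))
      phi <- ang(f[2]); psi <- ang(f[3])
      prob <- suppressWarnings(as.numeric(f[4]))
      nchi <- .n_chi[[aa]]
      chi <- rep(NA_real_, 4)
      if (nchi > 0) {
        got <- suppressWarnings(as.numeric(f[5:(4 + nchi)]))
        if (length(got) < nchi || any(!is.finite(got)))
          cf_stop(sprintf("line %d: expected %d chi angle(s) for %s", k, nchi, aa),
                  "cf_format_error")
        chi[seq_len(nchi)] <- got
      }
      if (!is.finite(prob) || prob < 0 || prob > 1)
        cf_stop(sprintf("line %d: bad probability '%s'", k, f[4]), "cf_format_error")
      c(list(aa = aa, phi = phi, psi = psi, prob = prob), as.list(chi))
    }
  }
  rows <- lapply(seq_along(lines), function(k) parse_line(lines[k], k))
  rec <- do.call(rbind, lapply(rows, function(r)
    data.frame(aa = r$aa, phi = r$phi, psi = r$psi, prob = r$prob,
               chi1 = r[[5]], chi2 = r[[6]], chi3 = r[[7]], chi4 = r[[8]])))

  key <- paste(rec$aa, rec$phi, rec$psi)
  sums <- tapply(rec$prob, key, sum)
  if (any(abs(sums - 1) > 1e-3))
    warning("rotamer probabilities renormalised to sum to 1 for: ",
            paste(utils::head(names(sums)[abs(sums - 1) > 1e-3], 5), collapse = ", "))
  rec$prob <- rec$prob / as.numeric(sums[key])

  aas <- sort(unique(rec$aa))
  if (is.null(aa_weights)) aa_weights <- setNames(rep(1 / length(aas), length(aas)), aas)
  structure(list(records = rec,
                 backbone_dependent = any(is.finite(rec$phi)),
                 aa_weights = aa_weights),
            class = "cf_rotlib")
}

#' @export
print.cf_rotlib <- function(x, ...) {
  cat(sprintf("<cf_rotlib: %d records, %d amino acid(s), %s>\n",
              nrow(x$records), length(unique(x$records$aa)),
              if (x$backbone_dependent) "backbone-dependent" else "backbone-independent"))
  invisible(x)
}

#' Write a rotamer library in the fixture dialect
#' @param lib A `cf_rotlib`.
#' @param path Optional output path; if `NULL` the text is returned.
#' @export
write_rotamer_library <- function(lib, path = NULL) {
  rec <- lib$records
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.3f", v), "*")
  ln <- vapply(seq_len(nrow(rec)), function(k) {
    nchi <- .n_chi[[rec$aa[k]]]
    chis <- if (nchi > 0)
      paste(sprintf("%.3f", as.numeric(rec[k, 4 + seq_len(nchi)])), collapse = " ")
    else ""
    trimws(paste(rec$aa[k], fmt(rec$phi[k]), fmt(rec$psi[k]),
                 sprintf("%.6f", rec$prob[k]), chis))
  }, "")
  txt <- paste(c("# fixture rotamer library: aa phi psi prob chi1..chi4", ln),
               collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

# records for one amino acid at backbone (phi, psi), nearest 10-degree bin,
# probabilities renormalised within the chosen bin
lookup_rotamers <- function(lib, aa, phi = NA, psi = NA) {
  rec <- lib$records[lib$records$aa == aa, , drop = FALSE]
  if (!nrow(rec)) return(rec)
  if (lib$backbone_dependent && any(is.finite(rec$phi))) {
    if (!is.finite(phi)) { warning("undefined phi at terminus; using -60"); phi <- -60 }
    if (!is.finite(psi)) { warning("undefined psi at terminus; using -45"); psi <- -45 }
    circ <- function(a, b) { d <- abs(a - b) %% 360; pmin(d, 360 - d) }
    d <- circ(rec$phi, phi) + circ(rec$psi, psi)
    rec <- rec[d == min(d), , drop = FALSE]
  }
  rec$prob <- rec$prob / sum(rec$prob)
  rec
}

#' Build side-chain heavy atoms for a rotamer on a backbone
#'
#' Places all heavy side-chain atoms (CB included) from ideal bond lengths
#' and angles and the record's chi dihedrals, by sequential
#' internal-coordinate (NeRF) construction. Deterministic for fixed inputs.
#' Proline's ring is built serially; the small ring-closure error is
#' tolerated. Glycine yields an empty placement.
#'
#' @param res_backbone A residue record providing N, CA and C coordinates.
#' @param aa One-letter amino-acid code to build.
#' @param chi Numeric vector of chi dihedrals in degrees (length as required
#'   by `aa`; extra entries ignored).
#' @return A `cf_placed_rotamer`: list with `aa`, `atoms` (coordinate matrix
#'   with atom-name rownames) and `chi`.
#' @export
build_sidechain <- function(res_backbone, aa, chi = numeric(0)) {
  bb <- list(N = atom_xyz(res_backbone, "N"),
             CA = atom_xyz(res_backbone, "CA"),
             C = atom_xyz(res_backbone, "C"))
  if (any(vapply(bb, is.null, TRUE)))
    cf_stop("backbone atom(s) N/CA/C missing", "cf_missing_atom")
  if (aa == "G")
    return(structure(list(aa = "G", atoms = matrix(numeric(0), 0, 3), chi = numeric(0)),
                     class = "cf_placed_rotamer"))
  geom <- .sidechain_geom[[aa]]
  if (is.null(geom)) cf_stop(sprintf("no geometry for amino acid '%s'", aa),
                             "cf_format_error")
  coords <- bb
  for (row in geom) {
    k <- row[[5]]
    tau <- row[[8]] + if (k > 0) {
      if (length(chi) < k || !is.finite(chi[k]))
        cf_stop(sprintf("chi%d required to build %s", k, aa), "cf_format_error")
      chi[k]
    } else 0
    coords[[row[[1]]]] <- place_atom(coords[[row[[2]]]], coords[[row[[3]]]],
                                     coords[[row[[4]]]], row[[6]], row[[7]], tau)
  }
  nm <- vapply(geom, `[[`, "", 1)
  m <- do.call(rbind, coords[nm])
  rownames(m) <- nm
  structure(list(aa = aa, atoms = m, chi = chi[seq_len(.n_chi[[aa]])]),
            class = "cf_placed_rotamer")
}

# heavy backbone atoms of the whole structure, excluding one residue
structure_backbone_xyz <- function(st, exclude = 0L) {
  mats <- lapply(seq_along(st$residues), function(k) {
    if (k == exclude) return(NULL)
    a <- st$residues[[k]]$atoms
    a$xyz[a$is_backbone & !a$is_hydrogen, , drop = FALSE]
  })
  do.call(rbind, mats)
}

#' Enumerate non-clashing rotamers at a position
#'
#' Builds rotamers of every amino-acid type in the library at the given
#' position and removes any whose heavy side-chain atoms come within
#' `backbone_clash_cut` of a heavy backbone atom of the structure (the
#' position's own backbone excepted). Surviving probabilities
#' (amino-acid prior times within-type rotamer probability) are
#' renormalised to sum to one.
#'
#' @param st A `cf_structure`.
#' @param pos 1-based global residue index.
#' @param lib A `cf_rotlib`.
#' @param backbone_clash_cut Clash cutoff in Angstroms (default 2.0).
#' @param prob_floor Rotamer records below this library probability are
#'   skipped before pruning (default 1e-4).
#' @param backbone_xyz Optional precomputed heavy-backbone coordinate matrix
#'   excluding `pos` (performance hook for contact-map computation).
#' @return List of placed rotamers, each with an additional `prob` element;
#'   empty list if every rotamer clashes.
#' @export
allowed_rotamers <- function(st, pos, lib, backbone_clash_cut = 2.0,
                             prob_floor = 1e-4, backbone_xyz = NULL) {
  res <- st$residues[[pos]]
  if (is.null(atom_xyz(res, "N")) || is.null(atom_xyz(res, "CA")) ||
      is.null(atom_xyz(res, "C")))
    cf_stop(sprintf("position %d lacks backbone atoms", pos), "cf_missing_atom")
  if (is.null(backbone_xyz)) backbone_xyz <- structure_backbone_xyz(st, exclude = pos)

  out <- list()
  w <- numeric(0)
  for (aa in sort(unique(lib$records$aa))) {
    aw <- lib$aa_weights[[aa]]
    if (is.null(aw) || aw <= 0) next
    rec <- lookup_rotamers(lib, aa, res$phi, res$psi)
    rec <- rec[rec$prob >= prob_floor, , drop = FALSE]
    for (k in seq_len(nrow(rec))) {
      chi <- as.numeric(rec[k, c("chi1", "chi2", "chi3", "chi4")])
      pr <- build_sidechain(res, aa, chi)
      if (nrow(pr$atoms) > 0 && nrow(backbone_xyz) > 0 &&
          min_cross_dist(pr$atoms, backbone_xyz) < backbone_clash_cut) next
      pr$prob <- aw * rec$prob[k]
      out[[length(out) + 1]] <- pr
      w <- c(w, pr$prob)
    }
  }
  if (length(out)) {
    w <- w / sum(w)
    for (k in seq_along(out)) out[[k]]$prob <- w[k]
  }
  out
}
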