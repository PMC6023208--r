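# Contact definitions, contact degree, and per-structure contact maps.

#' Contact definition
#'
#' Bundles a contact metric with its threshold and a sequence-separation
#' filter. Default thresholds: contact degree >= 0.1 (`cd`), minimum
#' heavy-atom distance < 8 A (`any_heavy`), C-beta distance < 8 A
#' (`cbeta`), side-chain centroid distance < 6 A (`centroid`). Contact
#' degree uses an inclusive threshold; the distance metrics are strict.
#'
#' @param kind One of `"cd"`, `"any_heavy"`, `"cbeta"`, `"centroid"`.
#' @param threshold CD cutoff or distance cutoff in Angstroms; `NULL`
#'   selects the default for `kind`.
#' @param min_separation Minimum `|i - j|` along the chain for a pair to be
#'   considered (default 1 = all non-identical pairs).
#' @return A `cf_contact_def`.
#' @export
contact_definition <- function(kind = c("cd", "any_heavy", "cbeta", "centroid"),
                               threshold = NULL, min_separation = 1L) {
  kind <- match.arg(kind)
  if (is.null(threshold))
    threshold <- c(cd = 0.1, any_heavy = 8, cbeta = 8, centroid = 6)[[kind]]
  stopifnot(threshold > 0, min_separation >= 1)
  structure(list(kind = kind, threshold = threshold,
                 min_separation = as.integer(min_separation)),
            class = "cf_contact_def")
}

#' @export
print.cf_contact_def <- function(x, ...) {
  cat(sprintf("<contact definition: %s, threshold %s, min separation %d>\n",
              x$kind, format(x$threshold), x$min_separation))
  invisible(x)
}

#' Sequence separation between two chain positions
#' @param i,j Residue indices within a chain.
#' @return `|i - j|`.
#' @export
sequence_separation <- function(i, j) abs(i - j)

#' Contact degree between two positions
#'
#' Probability-weighted fraction of allowed rotamer pairs at positions `i`
#' and `j` whose heavy side-chain atoms (CB included) come within
#' `interfere_cut` of each other. Rotamer sets are the backbone-clash-pruned,
#' renormalised enumerations of [allowed_rotamers()]; the value is the double
#' sum over rotamer pairs of `P_i * P_j * C_ij` with `C_ij` the interference
#' indicator. Returns 0 when either allowed set is empty.
#'
#' @param st A `cf_structure`.
#' @param i,j 1-based global residue indices, `i != j`.
#' @param lib A `cf_rotlib`.
#' @param interfere_cut Interference distance in Angstroms (default 3.0).
#' @param backbone_clash_cut Passed to [allowed_rotamers()].
#' @param rot_i,rot_j Optional precomputed allowed-rotamer lists.
#' @return Contact degree in `[0, 1]`.
#' @export
compute_cd <- function(st, i, j, lib, interfere_cut = 3.0,
                       backbone_clash_cut = 2.0, rot_i = NULL, rot_j = NULL) {
  stopifnot(i != j)
  if (is.null(rot_i)) rot_i <- allowed_rotamers(st, i, lib, backbone_clash_cut)
  if (is.null(rot_j)) rot_j <- allowed_rotamers(st, j, lib, backbone_clash_cut)
  if (!length(rot_i) || !length(rot_j)) return(0)

  # bounding spheres let distant rotamer pairs be skipped wholesale
  centers_i <- lapply(rot_i, rot_center)
  centers_j <- lapply(rot_j, rot_center)
  cd <- 0
  for (a in seq_along(rot_i)) {
    A <- rot_i[[a]]$atoms
    if (!nrow(A)) next
    ca <- centers_i[[a]]
    for (b in seq_along(rot_j)) {
      B <- rot_j[[b]]$atoms
      if (!nrow(B)) next
      cb <- centers_j[[b]]
      if (vec_norm(ca$c - cb$c) - ca$r - cb$r >= interfere_cut) next
      if (min_cross_dist(A, B) < interfere_cut)
        cd <- cd + rot_i[[a]]$prob * rot_j[[b]]$prob
    }
  }
  cd
}

rot_center <- function(pr) {
  if (!nrow(pr$atoms)) return(list(c = c(0, 0, 0), r = 0))
  ctr <- colMeans(pr$atoms)
  list(c = ctr, r = sqrt(max(rowSums(sweep(pr$atoms, 2, ctr)^2))))
}

#' Compute a contact map for a structure
#'
#' Evaluates the definition's metric for every residue pair `i < j` passing
#' the separation filter and derives binary contact calls. For the CD
#' metric, pairs whose C-alpha atoms are farther apart than `reach_bound`
#' are assigned value 0 without rotamer enumeration (no rotamer pair can
#' span such distances). Pairs for which the metric is undefined (e.g. a
#' missing C-beta on a non-glycine residue) are skipped with a warning.
#'
#' @param st A `cf_structure`.
#' @param definition A `cf_contact_def`.
#' @param lib A `cf_rotlib`; required when `definition$kind == "cd"`.
#' @param cross_chain Include pairs from different chains (they always pass
#'   the separation filter)? Default `TRUE`.
#' @param reach_bound C-alpha distance in Angstroms beyond which CD is 0
#'   (default 25; must exceed twice the maximum side-chain reach).
#' @param interfere_cut,backbone_clash_cut CD parameters, see [compute_cd()].
#' @return A `cf_contact_map`: list with `id`, `definition` and `pairs`, a
#'   data.frame with columns `i, j` (global indices), `chain_i, resnum_i,
#'   chain_j, resnum_j`, `value` and `is_contact`.
#' @export
compute_contact_map <- function(st, definition, lib = NULL, cross_chain = TRUE,
                                reach_bound = 25, interfere_cut = 3.0,
                                backbone_clash_cut = 2.0) {
  stopifnot(inherits(definition, "cf_contact_def"))
  if (definition$kind == "cd" && is.null(lib))
    cf_stop("contact definition 'cd' requires a rotamer library", "cf_config_error")
  n <- n_residues(st)
  cp <- st$chain_pos
  ch <- st$chain

  pre <- switch(definition$kind,
    cd = NULL,
    any_heavy = lapply(st$residues, residue_heavy_xyz),
    cbeta = lapply(st$residues, function(r) tryCatch(get_cbeta(r), error = function(e) NULL)),
    centroid = lapply(st$residues, function(r) tryCatch(get_centroid(r), error = function(e) NULL)))
  ca <- t(vapply(st$residues, function(r) {
    p <- atom_xyz(r, "CA"); if (is.null(p)) c(NA_real_, NA_real_, NA_real_) else p
  }, numeric(3)))

  rot_cache <- vector("list", n)
  get_rot <- function(k) {
    if (is.null(rot_cache[[k]]))
      rot_cache[[k]] <<- allowed_rotamers(st, k, lib, backbone_clash_cut,
                                          backbone_xyz = structure_backbone_xyz(st, exclude = k))
    rot_cache[[k]]
  }

  rows <- vector("list", n * (n - 1) / 2)
  nr <- 0L
  skipped <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- ch[i] == ch[j]
      if (!same && !cross_chain) next
      if (same && sequence_separation(cp[i], cp[j]) < definition$min_separation) next
      val <- switch(definition$kind,
        any_heavy = {
          if (!nrow(pre[[i]]) || !nrow(pre[[j]])) NULL
          else min_cross_dist(pre[[i]], pre[[j]])
        },
        cbeta = if (is.null(pre[[i]]) || is.null(pre[[j]])) NULL
                else vec_norm(pre[[i]] - pre[[j]]),
        centroid = if (is.null(pre[[i]]) || is.null(pre[[j]])) NULL
                   else vec_norm(pre[[i]] - pre[[j]]),
        cd = {
          if (anyNA(ca[i, ]) || anyNA(ca[j, ])) NULL
          else if (vec_norm(ca[i, ] - ca[j, ]) > reach_bound) 0
          else compute_cd(st, i, j, lib, interfere_cut, backbone_clash_cut,
                          rot_i = get_rot(i), rot_j = get_rot(j))
        })
      if (is.null(val)) { skipped <- skipped + 1L; next }
      nr <- nr + 1L
      rows[[nr]] <- list(i = i, j = j, value = val)
    }
  }
  if (skipped > 0)
    warning(sprintf("%d pair(s) skipped (undefined metric)", skipped))
  pairs <- if (nr == 0)
    data.frame(i = integer(0), j = integer(0), value = numeric(0))
  else
    data.frame(i = vapply(rows[seq_len(nr)], `[[`, 0L, "i"),
               j = vapply(rows[seq_len(nr)], `[[`, 0L, "j"),
               value = vapply(rows[seq_len(nr)], `[[`, 0, "value"))
  pairs$chain_i <- ch[pairs$i]
  pairs$resnum_i <- vapply(st$residues[pairs$i], `[[`, "", "resnum")
  pairs$chain_j <- ch[pairs$j]
  pairs$resnum_j <- vapply(st$residues[pairs$j], `[[`, "", "resnum")
  pairs$is_contact <- if (definition$kind == "cd")
    pairs$value >= definition$threshold
  else
    pairs$value < definition$threshold
  structure(list(id = st$id, definition = definition,
                 pairs = pairs[c("i", "j", "chain_i", "resnum_i", "chain_j",
                                 "resnum_j", "value", "is_contact")]),
            class = "cf_contact_map")
}

#' @export
print.cf_contact_map <- function(x, ...) {
  cat(sprintf("<cf_contact_map '%s': %s, %d pairs, %d contacts>\n",
              x$id, x$definition$kind, nrow(x$pairs), sum(x$pairs$is_contact)))
  invisible(x)
}

#' Write a contact map as TSV
#'
#' Emits a provenance header (definition, threshold, separation filter)
#' followed by one row per evaluated pair.
#' @param map A `cf_contact_map`.
#' @param path Output path; if `NULL` the text is returned.
#' @export
write_contact_map <- function(map, path = NULL) {
  hdr <- c(sprintf("# structure=%s", map$id),
           sprintf("# definition=%s threshold=%g min_separation=%d",
                   map$definition$kind, map$definition$threshold,
                   map$definition$min_separation),
           paste(c("chain_i", "resnum_i", "chain_j", "resnum_j",
                   "metric_value", "is_contact"), collapse = "\t"))
  p <- map$pairs
  body <- sprintf("%s\t%s\t%s\t%s\t%.6f\t%d", p$chain_i, p$resnum_i,
                  p$chain_j, p$resnum_j, p$value, as.integer(p$is_contact))
  txt <- paste(c(hdr, body), collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

# set of contacting pairs as "i:j" keys (i < j global indices)
contact_keys <- function(map) {
  p <- map$pairs[map$pairs$is_contact, , drop = FALSE]
  paste(p$i, p$j, sep = ":")
}
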