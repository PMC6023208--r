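# PDB structure model: parsing, residue accessors, geometric primitives.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1 <- sort(unname(AA3TO1))
AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

cf_stop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records into a residue/atom model. Only the 20 standard
#' amino acids are retained (selenomethionine `MSE` is mapped to `MET`);
#' waters and other hetero ligands are dropped. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altloc
#' identifier order). Hydrogen (and deuterium) atoms are kept but flagged so
#' that all distance computations can exclude them. Backbone dihedrals phi
#' and psi are computed where both flanking peptide bonds are intact.
#'
#' @param pdb Either PDB-format text (single string or character vector of
#'   lines) or a path to a PDB file.
#' @param id Structure identifier; defaults to the HEADER/file name or "pdb".
#' @param model_policy `"first"` keeps the first MODEL of a multi-model file;
#'   `"error-on-multi"` raises an error instead.
#' @return An object of class `cf_structure`: a list with `id`, `residues`
#'   (list of residue records), `chain` (chain id per residue) and
#'   `chain_pos` (1-based position of each residue within its chain).
#' @examples
#' s <- make_toy_backbone("helix", 5)
#' txt <- write_pdb(s)
#' s2 <- parse_structure(txt)
#' n_residues(s2)
#' @export
parse_structure <- function(pdb, id = NULL, model_policy = c("first", "error-on-multi")) {
  model_policy <- match.arg(model_policy)
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    if (is.null(id)) id <- tools::file_path_sans_ext(basename(pdb))
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  if (is.null(id)) id <- "pdb"

  rec <- substr(lines, 1, 6)
  n_model <- sum(trimws(rec) == "MODEL")
  if (n_model > 1) {
    if (model_policy == "error-on-multi")
      cf_stop(sprintf("structure has %d models", n_model), "cf_format_error")
    endmdl <- which(trimws(rec) == "ENDMDL")[1]
    if (!is.na(endmdl)) {
      lines <- lines[seq_len(endmdl)]
      rec <- rec[seq_len(endmdl)]
    }
  }

  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(sel)) cf_stop("no ATOM/HETATM records found", "cf_empty_structure")
  al <- lines[sel]
  resname <- toupper(trimws(substr(al, 18, 20)))

  keep_std <- resname %in% names(AA3TO1)
  keep_mse <- resname == "MSE"
  odd <- resname[substr(rec[sel], 1, 4) == "ATOM" & !keep_std & !keep_mse]
  if (length(odd))
    warning(sprintf("dropping nonstandard residue(s): %s",
                    paste(unique(odd), collapse = ", ")))
  idx <- which(keep_std | keep_mse)
  if (!length(idx)) cf_stop("no standard amino-acid residues found", "cf_empty_structure")
  al <- al[idx]
  lineno <- sel[idx]
  resname <- resname[idx]
  resname[resname == "MSE"] <- "MET"

  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    cf_stop(sprintf("unparseable coordinates at line %d", lineno[bad[1]]),
            "cf_format_error")
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[!is.finite(occ)] <- 1
  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  chain <- substr(al, 22, 22)
  resseq <- trimws(substr(al, 23, 26))
  icode <- trimws(substr(al, 27, 27))
  element <- toupper(trimws(substr(al, 77, 78)))
  no_el <- element == ""
  if (any(no_el)) element[no_el] <- guess_element(name[no_el])

  res_key <- paste(chain, resseq, icode, sep = "|")
  # altloc resolution: within (residue, atom name) keep highest occupancy,
  # ties by altloc identifier order
  ord <- order(res_key, name, -occ, altloc)
  dup <- duplicated(paste(res_key, name, sep = "|")[ord])
  keep <- sort(ord[!dup])

  res_key <- res_key[keep]
  ures <- unique(res_key)  # file order preserved by sort(ord[..])
  residues <- vector("list", length(ures))
  rchain <- character(length(ures))
  for (k in seq_along(ures)) {
    ai <- which(res_key == ures[k])
    el <- element[keep][ai]
    residues[[k]] <- list(
      chain = chain[keep][ai[1]],
      resnum = paste0(resseq[keep][ai[1]], icode[keep][ai[1]]),
      aa = unname(AA3TO1[resname[keep][ai[1]]]),
      atoms = list(
        name = name[keep][ai],
        element = el,
        xyz = cbind(x[keep][ai], y[keep][ai], z[keep][ai]),
        is_backbone = name[keep][ai] %in% BACKBONE_ATOMS,
        is_hydrogen = el %in% c("H", "D")
      ),
      phi = NA_real_, psi = NA_real_
    )
    rchain[k] <- chain[keep][ai[1]]
  }

  st <- structure(list(id = id, residues = residues, chain = rchain,
                       chain_pos = stats::ave(seq_along(rchain), rchain,
                                              FUN = seq_along)),
                  class = "cf_structure")
  compute_backbone_dihedrals(st)
}

# infer element from a PDB atom name: strip digits, leading H/D is hydrogen
guess_element <- function(name) {
  core <- gsub("[0-9']", "", name)
  first <- substr(core, 1, 1)
  el <- first
  el[first %in% c("H", "D")] <- "H"
  el[core %in% c("SE", "FE", "ZN", "MG", "CL", "BR")] <- core[core %in% c("SE", "FE", "ZN", "MG", "CL", "BR")]
  el
}

atom_xyz <- function(res, name) {
  i <- match(name, res$atoms$name)
  if (is.na(i)) NULL else res$atoms$xyz[i, ]
}

compute_backbone_dihedrals <- function(st) {
  n <- length(st$residues)
  for (k in seq_len(n)) {
    r <- st$residues[[k]]
    Ni <- atom_xyz(r, "N"); CAi <- atom_xyz(r, "CA"); Ci <- atom_xyz(r, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (k > 1 && st$chain[k - 1] == st$chain[k]) {
      Cp <- atom_xyz(st$residues[[k - 1]], "C")
      if (!is.null(Cp) && vec_norm(Ni - Cp) < 2.5)
        st$residues[[k]]$phi <- vec_dihedral(Cp, Ni, CAi, Ci)
    }
    if (k < n && st$chain[k + 1] == st$chain[k]) {
      Nn <- atom_xyz(st$residues[[k + 1]], "N")
      if (!is.null(Nn) && vec_norm(Nn - Ci) < 2.5)
        st$residues[[k]]$psi <- vec_dihedral(Ni, CAi, Ci, Nn)
    }
  }
  st
}

#' @export
print.cf_structure <- function(x, ...) {
  cat(sprintf("<cf_structure '%s': %d residues, %d chain(s)>\n",
              x$id, length(x$residues), length(unique(x$chain))))
  invisible(x)
}

#' Number of residues in a structure
#' @param st A `cf_structure`.
#' @export
n_residues <- function(st) length(st$residues)

#' One-letter sequence of a structure
#' @param st A `cf_structure`.
#' @param chain Chain identifier; default the first chain.
#' @export
structure_sequence <- function(st, chain = NULL) {
  if (is.null(chain)) chain <- st$chain[1]
  paste(vapply(st$residues[st$chain == chain], `[[`, "", "aa"), collapse = "")
}

# heavy-atom coordinate matrix for a residue
residue_heavy_xyz <- function(res, sidechain_only = FALSE) {
  sel <- !res$atoms$is_hydrogen
  if (sidechain_only) sel <- sel & !res$atoms$is_backbone
  m <- res$atoms$xyz[sel, , drop = FALSE]
  rownames(m) <- res$atoms$name[sel]
  m
}

#' C-beta coordinates of a residue (C-alpha for glycine)
#'
#' @param res A residue record from a [parse_structure()] result.
#' @return Numeric length-3 coordinate vector.
#' @export
get_cbeta <- function(res) {
  cb <- atom_xyz(res, "CB")
  if (!is.null(cb)) return(cb)
  if (res$aa == "G") {
    ca <- atom_xyz(res, "CA")
    if (!is.null(ca)) return(ca)
  }
  cf_stop(sprintf("residue %s%s (%s) has no CB atom", res$chain, res$resnum, res$aa),
          "cf_missing_atom")
}

#' Side-chain centroid of a residue
#'
#' Mean coordinates of the non-hydrogen side-chain atoms (CB included).
#' Glycine, which has no side-chain heavy atoms, falls back to C-alpha.
#'
#' @param res A residue record.
#' @return Numeric length-3 coordinate vector.
#' @export
get_centroid <- function(res) {
  m <- residue_heavy_xyz(res, sidechain_only = TRUE)
  if (nrow(m) > 0) return(colMeans(m))
  ca <- atom_xyz(res, "CA")
  if (!is.null(ca)) return(ca)
  cf_stop(sprintf("residue %s%s has no heavy atoms", res$chain, res$resnum),
          "cf_missing_atom")
}

#' Minimum heavy-atom distance between two residues
#'
#' Minimum over all pairs of non-hydrogen atoms, backbone included.
#'
#' @param res_i,res_j Residue records.
#' @return Distance in Angstroms.
#' @export
min_heavy_distance <- function(res_i, res_j) {
  A <- residue_heavy_xyz(res_i)
  B <- residue_heavy_xyz(res_j)
  if (nrow(A) == 0 || nrow(B) == 0)
    cf_stop("residue has no heavy atoms", "cf_missing_atom")
  min_cross_dist(A, B)
}

#' Write a structure as PDB-format text
#'
#' @param st A `cf_structure`.
#' @param path Optional file path; if `NULL` the text is returned.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(st, path = NULL) {
  serial <- 0L
  out <- character(0)
  for (k in seq_along(st$residues)) {
    r <- st$residues[[k]]
    res3 <- AA1TO3[r$aa]
    num <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", r$resnum)))
    if (is.na(num)) num <- k
    for (a in seq_along(r$atoms$name)) {
      serial <- serial + 1L
      nm <- r$atoms$name[a]
      nmf <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      out <- c(out, sprintf(
        "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nmf, res3, r$chain, num,
        r$atoms$xyz[a, 1], r$atoms$xyz[a, 2], r$atoms$xyz[a, 3],
        1.0, 0.0, r$atoms$element[a]))
    }
  }
  out <- c(out, "END")
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
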