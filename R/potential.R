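# Statistical contact potentials: counting, derivation, I/O.
#
# The potential for amino acids a, b is the log-odds of observing an (a, b)
# contact relative to random redistribution of amino acids among contacts:
#   E(a, b) = -ln[ Nc(a, b) / ((1 + I_ab) f(a) f(b) Nc) ]
# with I_ab = 1 for a != b and 0 otherwise, f() database amino-acid
# frequencies and Nc the total contact count ("null-normalized" convention;
# the "as-printed" convention puts (1 + I_ab) in the numerator instead, which
# shifts hetero cells by exactly 2 ln 2).

#' Count amino-acid pair contacts over a structure set
#'
#' Each contacting pair (i < j) under the definition increments the count for
#' its unordered amino-acid pair once. Frequencies `f(a)` are computed over
#' all residues of all structures. Residues outside the 20 standard types
#' are excluded from both counts and frequencies.
#'
#' @param structures List of `cf_structure` objects.
#' @param definition A `cf_contact_def`.
#' @param lib Rotamer library, required for the CD definition.
#' @param min_separation Minimum sequence separation for counted pairs
#'   (default 2, excluding backbone-forced adjacent contacts). Overrides the
#'   definition's filter.
#' @param cross_chain Passed to [compute_contact_map()].
#' @return A `cf_contact_counts`: list with `nc` (symmetric 20 x 20 matrix;
#'   the upper triangle including the diagonal carries the unordered
#'   counts, mirrored below), `f` (named frequency vector), `nc_total`,
#'   and `provenance`.
#' @export
count_contacts <- function(structures, definition, lib = NULL,
                           min_separation = 2L, cross_chain = TRUE) {
  if (!length(structures)) cf_stop("no structures given", "cf_config_error")
  definition$min_separation <- as.integer(min_separation)
  nc <- matrix(0, 20, 20, dimnames = list(AA1, AA1))
  naa <- setNames(numeric(20), AA1)
  for (st in structures) {
    aa <- vapply(st$residues, `[[`, "", "aa")
    tab <- table(factor(aa[aa %in% AA1], levels = AA1))
    naa <- naa + as.numeric(tab)
    map <- compute_contact_map(st, definition, lib, cross_chain = cross_chain)
    p <- map$pairs[map$pairs$is_contact, , drop = FALSE]
    for (k in seq_len(nrow(p))) {
      a <- aa[p$i[k]]; b <- aa[p$j[k]]
      if (!(a %in% AA1) || !(b %in% AA1)) next
      lo <- min(a, b); hi <- max(a, b)
      nc[lo, hi] <- nc[lo, hi] + 1
    }
  }
  nc[lower.tri(nc)] <- t(nc)[lower.tri(nc)]
  structure(list(nc = nc, f = naa / sum(naa),
                 nc_total = sum(nc[upper.tri(nc, diag = TRUE)]),
                 provenance = list(definition = definition,
                                   n_structures = length(structures),
                                   min_separation = min_separation)),
            class = "cf_contact_counts")
}

#' Derive a statistical contact potential from contact counts
#'
#' @param counts A `cf_contact_counts`, or a list with elements `nc`
#'   (symmetric named 20 x 20 count matrix or a named subset), `f` (named
#'   frequencies summing to 1) and optionally `nc_total`.
#' @param convention `"null-normalized"` (reference state = random
#'   redistribution of amino acids among contacts, so the null case gives
#'   E = 0 everywhere) or `"as-printed"` (the `(1 + I)` factor multiplies
#'   the numerator; hetero cells shift by `2 ln 2`).
#' @param pseudocount Added to every unordered cell before totals are
#'   normalised, keeping zero-count cells finite (default 0.5; set 0 for
#'   exact closed-form checks).
#' @return A `cf_potential`: list with `E` (symmetric matrix), `convention`
#'   and `provenance`.
#' @export
derive_potential <- function(counts,
                             convention = c("null-normalized", "as-printed"),
                             pseudocount = 0.5) {
  convention <- match.arg(convention)
  nc <- counts$nc
  aas <- rownames(nc)
  f <- counts$f[aas]
  if (any(!is.finite(f)))
    cf_stop("frequencies missing for some amino acids in the count matrix",
            "cf_config_error")
  used <- rowSums(nc) + colSums(nc) > 0
  if (any(f[used] <= 0))
    cf_stop(sprintf("zero frequency for amino acid(s) with contacts: %s",
                    paste(aas[used & f <= 0], collapse = ", ")), "cf_config_error")
  nca <- nc + pseudocount  # one unordered cell per (a, b); mirrored storage
  # totals over unordered pairs
  tot <- sum(nca[upper.tri(nca, diag = TRUE)])
  if (tot <= 0) cf_stop("no contacts counted", "cf_config_error")
  ff <- outer(f, f)
  I <- 1 - diag(nrow(nc))
  E <- if (convention == "null-normalized")
    -log(nca / ((1 + I) * ff * tot))
  else
    -log(nca * (1 + I) / (ff * tot))
  E[nca == 0] <- Inf
  structure(list(E = E, convention = convention,
                 provenance = c(counts$provenance,
                                list(pseudocount = pseudocount))),
            class = "cf_potential")
}

#' @export
print.cf_potential <- function(x, ...) {
  cat(sprintf("<cf_potential: %d types, %s, mean |E| = %.3f>\n",
              nrow(x$E), x$convention, mean_absolute_energy(x)))
  invisible(x)
}

#' Mean absolute energy of a potential
#'
#' Mean of `|E(a, b)|` over the unordered amino-acid pairs (210 for the full
#' 20-type table).
#' @param potential A `cf_potential`.
#' @export
mean_absolute_energy <- function(potential) {
  E <- potential$E
  mean(abs(E[upper.tri(E, diag = TRUE)]))
}

# energy lookup for one-letter codes; NA for unknown types
potential_energy <- function(potential, a, b) {
  E <- potential$E
  ia <- match(a, rownames(E)); ib <- match(b, colnames(E))
  out <- rep(NA_real_, length(ia))
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- E[cbind(ia[ok], ib[ok])]
  out
}

#' Read / write a contact-potential CSV table
#'
#' The format is one unordered amino-acid pair per line, `aa1,aa2,energy`
#' (an optional header line is tolerated on read). All 210 unordered pairs
#' of the 20 standard types must be present; a smaller alphabet is accepted
#' when `complete = FALSE`.
#'
#' @param text CSV text or a file path.
#' @param complete Require all 210 pairs (default `TRUE`).
#' @return A `cf_potential` with `convention = "as-read"`.
#' @export
read_potential_csv <- function(text, complete = TRUE) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  else
    text <- unlist(strsplit(text, "\n", fixed = TRUE))
  text <- text[!grepl("^\\s*(#|$)", text)]
  parts <- strsplit(text, "[,\t ]+")
  parts <- parts[vapply(parts, length, 0L) >= 3]
  if (length(parts) && is.na(suppressWarnings(as.numeric(parts[[1]][3]))))
    parts <- parts[-1]  # header line
  rows <- do.call(rbind, lapply(parts, function(p) p[1:3]))
  a <- toupper(rows[, 1]); b <- toupper(rows[, 2])
  e <- suppressWarnings(as.numeric(rows[, 3]))
  keep <- a %in% AA1 & b %in% AA1 & is.finite(e)
  a <- a[keep]; b <- b[keep]; e <- e[keep]
  if (!length(a)) cf_stop("no parseable potential rows", "cf_format_error")
  aas <- AA1
  E <- matrix(NA_real_, 20, 20, dimnames = list(aas, aas))
  E[cbind(a, b)] <- e
  E[cbind(b, a)] <- e
  miss <- which(is.na(E[upper.tri(E, diag = TRUE)]))
  if (complete && length(miss)) {
    ut <- which(upper.tri(E, diag = TRUE), arr.ind = TRUE)
    bad <- ut[is.na(E[upper.tri(E, diag = TRUE)]), , drop = FALSE]
    cf_stop(sprintf("potential table missing %d pair(s): %s%s",
                    nrow(bad),
                    paste(utils::head(paste0(aas[bad[, 1]], "-", aas[bad[, 2]]), 8),
                          collapse = ", "),
                    if (nrow(bad) > 8) ", ..." else ""),
            "cf_format_error")
  }
  structure(list(E = E, convention = "as-read", provenance = list(source = "csv")),
            class = "cf_potential")
}

#' @rdname read_potential_csv
#' @param potential A `cf_potential`.
#' @param path Output path; if `NULL` the CSV text is returned.
#' @export
write_potential_csv <- function(potential, path = NULL) {
  E <- potential$E
  aas <- rownames(E)
  ut <- which(upper.tri(E, diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  ln <- sprintf("%s,%s,%.6f", aas[ut[, 1]], aas[ut[, 2]], E[ut])
  txt <- paste(ln, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
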