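# Hybrid contact scoring: co-evolution scores augmented with MSA-averaged
# contact-potential energies,
#   S'_{i,j} = S_{i,j} * (1 - Ehat_{i,j} / S_max),
# where Ehat is the mean potential energy over the amino-acid pairs observed
# at MSA columns (i, j) and S_max the maximal co-evolution score among the
# separation-filtered pairs. Favorable (negative) energies boost a pair.

#' Read a multiple sequence alignment
#'
#' FASTA is parsed with Biostrings; single-block and interleaved Stockholm
#' are parsed directly. Sequences are upper-cased and `.` gaps converted
#' to `-`.
#'
#' @param text Alignment text or a file path.
#' @param format `"auto"`, `"fasta"`, or `"stockholm"`.
#' @return A `cf_msa`: list with `ids` and `seqs` (aligned character vector),
#'   all rows of equal length.
#' @export
read_msa <- function(text, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  is_file <- length(text) == 1 && !grepl("\n", text) && file.exists(text)
  lines <- if (is_file) readLines(text, warn = FALSE)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  if (format == "auto")
    format <- if (any(grepl("^# STOCKHOLM", lines))) "stockholm" else "fasta"
  if (format == "fasta") {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf))
    writeLines(lines, tf)
    ss <- Biostrings::readBStringSet(tf)
    msa <- new_msa(names(ss), as.character(ss))
  } else {
    body <- lines[!grepl("^(#|//)", lines) & grepl("\\S", lines)]
    parts <- strsplit(trimws(body), "\\s+")
    ids <- vapply(parts, `[[`, "", 1)
    seqs <- vapply(parts, `[[`, "", 2)
    agg <- tapply(seqs, factor(ids, levels = unique(ids)), paste, collapse = "")
    msa <- new_msa(names(agg), as.character(agg))
  }
  msa
}

new_msa <- function(ids, seqs) {
  seqs <- chartr(".", "-", toupper(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    cf_stop("alignment rows have unequal lengths", "cf_format_error")
  structure(list(ids = ids, seqs = unname(seqs)), class = "cf_msa")
}

#' @export
print.cf_msa <- function(x, ...) {
  cat(sprintf("<cf_msa: %d sequences x %d columns>\n",
              length(x$seqs), msa_width(x)))
  invisible(x)
}

#' Number of columns of an alignment
#' @param msa A `cf_msa`.
#' @export
msa_width <- function(msa) nchar(msa$seqs[1])

# characters of one column across rows
msa_column <- function(msa, i) substring(msa$seqs, i, i)

#' Parse a co-evolution score file
#'
#' Whitespace/comma-tolerant triples `i j score` with 1-based column
#' indices. `S_max` is the maximal score among pairs passing the separation
#' filter (only those are ranked downstream). DCA direct-information scores
#' must be non-negative; MetaPSICOV precision scores are nominally in
#' `[0, 1]` but values slightly outside are accepted with a warning.
#'
#' @param text Score text or a file path.
#' @param kind `"DI"` or `"precision"`.
#' @param min_separation Minimum `|i - j|` for a pair to be ranked
#'   (default 5).
#' @return A `cf_coev_scores`: list with `pairs` (data.frame `i, j, score`
#'   for pairs passing the filter, `i < j`), `s_max`, `kind`,
#'   `min_separation`.
#' @export
parse_scores <- function(text, kind = c("DI", "precision"), min_separation = 5L) {
  kind <- match.arg(kind)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  else
    text <- unlist(strsplit(text, "\n", fixed = TRUE))
  text <- text[!grepl("^\\s*(#|$)", text)]
  parts <- strsplit(trimws(text), "[,\t ]+")
  bad <- which(vapply(parts, length, 0L) < 3)
  if (length(bad))
    cf_stop(sprintf("malformed score line %d", bad[1]), "cf_format_error")
  i <- as.integer(vapply(parts, `[[`, "", 1))
  j <- as.integer(vapply(parts, `[[`, "", 2))
  s <- as.numeric(vapply(parts, `[[`, "", 3))
  if (any(is.na(i) | is.na(j) | !is.finite(s)))
    cf_stop("unparseable score triple(s)", "cf_format_error")
  ii <- pmin(i, j); jj <- pmax(i, j)
  if (anyDuplicated(paste(ii, jj)))
    cf_stop("duplicate position pair(s) in score file", "cf_format_error")
  if (kind == "DI" && any(s < 0))
    cf_stop("negative DI score(s)", "cf_format_error")
  if (kind == "precision" && any(s < -0.01 | s > 1.01))
    warning("precision score(s) outside [0, 1]")
  keep <- (jj - ii) >= min_separation
  pairs <- data.frame(i = ii[keep], j = jj[keep], score = s[keep])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 s_max = if (nrow(pairs)) max(pairs$score) else NA_real_,
                 kind = kind, min_separation = as.integer(min_separation)),
            class = "cf_coev_scores")
}

#' MSA-averaged contact-potential energy for a column pair
#'
#' In `"msa"` mode, the mean of `E(a, b)` over alignment rows whose symbols
#' at both columns are standard amino acids (gapped and unknown rows are
#' skipped). In `"single"` mode, the energy is evaluated on one row only
#' (by default chosen at random with `seed`), emulating prediction in the
#' context of a single sequence.
#'
#' @param msa A `cf_msa`.
#' @param i,j 1-based column indices.
#' @param potential A `cf_potential`.
#' @param mode `"msa"` or `"single"`.
#' @param row Row index for `"single"` mode; when `NULL` a seeded random row
#'   with usable symbols is drawn.
#' @param seed Seed for the random row choice.
#' @return Mean energy, or `NA_real_` when no usable rows exist (callers
#'   fall back to the unadjusted co-evolution score).
#' @export
average_pair_energy <- function(msa, i, j, potential, mode = c("msa", "single"),
                                row = NULL, seed = 1L) {
  mode <- match.arg(mode)
  a <- msa_column(msa, i)
  b <- msa_column(msa, j)
  usable <- a %in% rownames(potential$E) & b %in% rownames(potential$E)
  if (mode == "single") {
    if (is.null(row)) {
      if (!any(usable)) return(NA_real_)
      row <- withr::with_seed(seed, sample(which(usable), 1))
    }
    if (!usable[row]) return(NA_real_)
    return(potential_energy(potential, a[row], b[row]))
  }
  if (!any(usable)) return(NA_real_)
  mean(potential_energy(potential, a[usable], b[usable]))
}

#' Combine co-evolution scores with pair energies into hybrid scores
#'
#' @param scores A `cf_coev_scores`.
#' @param energies Numeric vector of `Ehat` values aligned with
#'   `scores$pairs` rows; `NA` entries keep the raw score.
#' @return A `cf_hybrid_scores`: `pairs` data.frame with columns
#'   `i, j, score, ehat, hybrid`, plus `s_max`.
#' @export
hybrid_score <- function(scores, energies) {
  if (!nrow(scores$pairs)) cf_stop("no scored pairs", "cf_config_error")
  if (!is.finite(scores$s_max) || scores$s_max <= 0)
    cf_stop("degenerate input: S_max must be positive", "cf_config_error")
  stopifnot(length(energies) == nrow(scores$pairs))
  p <- scores$pairs
  adj <- 1 - energies / scores$s_max
  p$ehat <- energies
  p$hybrid <- ifelse(is.na(energies), p$score, p$score * adj)
  structure(list(pairs = p, s_max = scores$s_max, kind = scores$kind),
            class = "cf_hybrid_scores")
}

#' Rank alignment column pairs by hybrid (or raw) score
#'
#' Convenience pipeline: computes `Ehat` for every scored pair and returns
#' the pairs sorted by descending hybrid score, ties broken by `(i, j)`
#' lexicographic order for determinism.
#'
#' @param msa A `cf_msa`.
#' @param scores A `cf_coev_scores`.
#' @param potential A `cf_potential`; `NULL` ranks by the raw score.
#' @param mode,row,seed Passed to [average_pair_energy()].
#' @return Data frame `i, j, score, ehat, hybrid`, ranked.
#' @export
hybrid_rank <- function(msa, scores, potential = NULL, mode = "msa",
                        row = NULL, seed = 1L) {
  p <- scores$pairs
  if (is.null(potential)) {
    p$ehat <- NA_real_
    p$hybrid <- p$score
  } else {
    if (mode == "single" && is.null(row)) {
      # one row drawn per alignment, reused for all pairs (single-sequence
      # context), skipping rows that are entirely gaps
      ok <- which(vapply(strsplit(msa$seqs, ""), function(s)
        any(s %in% rownames(potential$E)), TRUE))
      row <- withr::with_seed(seed, sample(ok, 1))
    }
    e <- vapply(seq_len(nrow(p)), function(k)
      average_pair_energy(msa, p$i[k], p$j[k], potential, mode, row = row), 0)
    h <- hybrid_score(scores, e)
    p <- h$pairs
  }
  p[order(-p$hybrid, p$i, p$j), , drop = FALSE]
}

#' Write ranked pairs as TSV (i, j, S, Ehat, S')
#' @param ranked Data frame from [hybrid_rank()].
#' @param path Output path; if `NULL` the text is returned.
#' @export
write_ranked_pairs <- function(ranked, path = NULL) {
  hdr <- paste(c("i", "j", "S", "Ehat", "Sprime"), collapse = "\t")
  body <- sprintf("%d\t%d\t%.6f\t%s\t%.6f", ranked$i, ranked$j, ranked$score,
                  ifelse(is.na(ranked$ehat), "NA", sprintf("%.6f", ranked$ehat)),
                  ranked$hybrid)
  txt <- paste(c(hdr, body), collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
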