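# Evaluation: mapping structures to alignment columns, true-contact sets,
# PPV curves (top-N and top-f*L), separation-binned PPV, and contact-map
# diversity entropy.

#' Map a structure sequence onto MSA columns
#'
#' Globally aligns the structure sequence against each alignment row's
#' ungapped sequence with identity scoring and affine gaps
#' (Biostrings). The best row with similarity of at least `min_similarity`
#' is chosen; if no row reaches it, the highest-similarity row is used.
#' Similarity is the fraction of identical aligned positions over the
#' structure sequence length. The returned map sends structure positions to
#' alignment columns through the chosen row's gap pattern.
#'
#' @param struct_seq One-letter structure sequence.
#' @param msa A `cf_msa`.
#' @param min_similarity Similarity threshold for an accepted match
#'   (default 0.95).
#' @return List with `row` (chosen alignment row index), `similarity`, and
#'   `map` (integer vector: `map[k]` = alignment column of structure
#'   position `k`, `NA` where unaligned).
#' @export
map_structure_to_msa <- function(struct_seq, msa, min_similarity = 0.95) {
  if (!length(msa$seqs)) cf_stop("empty alignment", "cf_config_error")
  ungapped <- gsub("-", "", msa$seqs)
  alpha <- c(AA1, "X")
  submat <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(submat) <- 1
  best <- NULL
  for (r in seq_along(ungapped)) {
    if (!nchar(ungapped[r])) next
    aln <- Biostrings::pairwiseAlignment(struct_seq, ungapped[r],
                                         substitutionMatrix = submat,
                                         gapOpening = 5, gapExtension = 1,
                                         type = "global")
    sim <- Biostrings::nmatch(aln) / nchar(struct_seq)
    if (is.null(best) || sim > best$sim) best <- list(r = r, sim = sim, aln = aln)
    if (sim >= 1) break
  }
  if (is.null(best)) cf_stop("alignment has no usable rows", "cf_config_error")

  # structure position -> position in the ungapped row sequence
  pat <- strsplit(as.character(Biostrings::alignedPattern(best$aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(best$aln)), "")[[1]]
  map_row <- rep(NA_integer_, nchar(struct_seq))
  pi <- 0L; si <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") pi <- pi + 1L
    if (sub[k] != "-") si <- si + 1L
    if (pat[k] != "-" && sub[k] != "-") map_row[pi] <- si
  }
  # ungapped row position -> alignment column
  row_chars <- strsplit(msa$seqs[best$r], "")[[1]]
  col_of <- which(row_chars != "-")
  map <- ifelse(is.na(map_row), NA_integer_, col_of[map_row])
  if (best$sim < min_similarity)
    message(sprintf("no row reached %.0f%% similarity; best row %d at %.1f%% used",
                    100 * min_similarity, best$r, 100 * best$sim))
  list(row = best$r, similarity = best$sim, map = map)
}

#' True contacts in MSA column space
#'
#' Projects the contacts of one or more structures into alignment columns
#' through their structure-to-MSA maps. Under the `"any-structure"` rule a
#' column pair is a true contact if it is in contact in any contributing
#' structure (family-wide rule); `"single-structure"` uses the first
#' structure only (target-specific rule). The separation filter is applied
#' in column space.
#'
#' @param contact_maps List of `cf_contact_map` objects.
#' @param msa_maps List of map vectors (from [map_structure_to_msa()]`$map`),
#'   one per contact map.
#' @param rule `"any-structure"` or `"single-structure"`.
#' @param min_separation Minimum column separation (5 for the family-style
#'   rule, 6 for the CASP-style rule).
#' @return A `cf_true_contacts`: list with `pairs` (data.frame `i, j`,
#'   `i < j`, alignment columns) and `min_separation`.
#' @export
true_contacts <- function(contact_maps, msa_maps,
                          rule = c("any-structure", "single-structure"),
                          min_separation = 5L) {
  rule <- match.arg(rule)
  stopifnot(length(contact_maps) == length(msa_maps))
  take <- if (rule == "single-structure") 1L else seq_along(contact_maps)
  keys <- character(0)
  for (k in take) {
    p <- contact_maps[[k]]$pairs
    p <- p[p$is_contact, , drop = FALSE]
    m <- msa_maps[[k]]
    ci <- m[p$i]; cj <- m[p$j]
    ok <- !is.na(ci) & !is.na(cj) & abs(ci - cj) >= min_separation
    keys <- union(keys, paste(pmin(ci[ok], cj[ok]), pmax(ci[ok], cj[ok]), sep = ":"))
  }
  ij <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  pairs <- if (is.null(ij)) data.frame(i = integer(0), j = integer(0))
           else data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, min_separation = as.integer(min_separation),
                 rule = rule),
            class = "cf_true_contacts")
}

truth_keys <- function(truth) {
  if (inherits(truth, "cf_true_contacts")) truth <- truth$pairs
  paste(pmin(truth$i, truth$j), pmax(truth$i, truth$j), sep = ":")
}

# deterministic ranking: descending score, ties by (i, j)
order_ranked <- function(pairs, col = "hybrid") {
  if (!col %in% names(pairs)) col <- "score"
  pairs[order(-pairs[[col]], pairs$i, pairs$j), , drop = FALSE]
}

#' Positive predictive value of a ranking
#'
#' Fraction of true contacts among the top `k` ranked pairs, with `k = N`
#' or `k = round(f * L)` (half-up, floored at 1). Score ties are broken by
#' `(i, j)` lexicographic order so small-`N` values are deterministic.
#'
#' @param ranked Data frame with columns `i, j` and `score` (and optionally
#'   `hybrid`, which takes precedence).
#' @param truth A `cf_true_contacts` or a data.frame with columns `i, j`.
#' @param N Number of top pairs; give either `N` or `f`.
#' @param f Fraction of protein length.
#' @param L Protein (alignment) length, required with `f`.
#' @return PPV in `[0, 1]`.
#' @export
ppv_at <- function(ranked, truth, N = NULL, f = NULL, L = NULL) {
  if (is.null(N)) {
    if (is.null(f) || is.null(L)) cf_stop("give N, or f with L", "cf_config_error")
    N <- max(1L, as.integer(floor(f * L + 0.5)))
  }
  ranked <- order_ranked(ranked)
  k <- min(N, nrow(ranked))
  if (k < 1) return(0)
  top <- ranked[seq_len(k), ]
  tk <- truth_keys(truth)
  if (!length(tk)) return(0)
  mean(paste(pmin(top$i, top$j), pmax(top$i, top$j), sep = ":") %in% tk)
}

#' PPV split by sequence-separation bin
#'
#' Pairs are partitioned by column separation before ranking within each
#' bin. Default bins: short 6-11, medium 12-22, long >= 23 (a separation of
#' exactly 23 is classed long-range).
#'
#' @param ranked,truth As in [ppv_at()].
#' @param N Top pairs per bin.
#' @param bins Data frame with columns `name, lo, hi`.
#' @return Named numeric vector of per-bin PPVs (`NA` for empty bins).
#' @export
separation_binned_ppv <- function(ranked, truth, N = 10L,
                                  bins = data.frame(
                                    name = c("short", "medium", "long"),
                                    lo = c(6, 12, 23), hi = c(11, 22, Inf))) {
  sep <- abs(ranked$j - ranked$i)
  out <- setNames(rep(NA_real_, nrow(bins)), bins$name)
  tk <- truth_keys(truth)
  tt <- if (inherits(truth, "cf_true_contacts")) truth$pairs else truth
  tsep <- abs(tt$j - tt$i)
  for (b in seq_len(nrow(bins))) {
    sel <- sep >= bins$lo[b] & sep <= bins$hi[b]
    if (!any(sel)) next
    sub <- ranked[sel, , drop = FALSE]
    tsel <- tt[tsep >= bins$lo[b] & tsep <= bins$hi[b], , drop = FALSE]
    out[b] <- ppv_at(sub, tsel, N = N)
  }
  out
}

#' Contact-map diversity entropy
#'
#' The contact map of an `L`-column alignment is divided into a 10 x 10
#' grid of equal-sized regions; the diversity `D` is the Shannon entropy
#' (base 2) of the distribution of the top `n_top` ranked pairs over these
#' regions, with `0 log 0 = 0`. Ranges from 0 (all predictions in one
#' region) to `log2(100)` (uniform coverage).
#'
#' @param ranked Data frame with `i, j` and a score column, as in [ppv_at()].
#' @param L Alignment length (number of columns).
#' @param n_top Number of top pairs to use; default `floor(L / 2)`.
#' @return Diversity in bits.
#' @export
contact_diversity <- function(ranked, L, n_top = NULL) {
  if (L < 2) cf_stop("alignment length must be at least 2", "cf_config_error")
  if (is.null(n_top)) n_top <- max(1L, floor(L / 2))
  ranked <- order_ranked(ranked)
  top <- ranked[seq_len(min(n_top, nrow(ranked))), , drop = FALSE]
  if (!nrow(top)) return(0)
  cell <- function(k) pmin(9L, as.integer(floor(10 * (k - 1) / L)))
  id <- cell(top$i) * 10L + cell(top$j)
  p <- as.numeric(table(id)) / nrow(top)
  -sum(p * log2(p))
}
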