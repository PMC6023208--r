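# Decoy discrimination: structure scoring, native ranking, rank-table
# statistics (medians, best-method counts, paired Friedman tests) and
# per-contact decoy elimination.

#' Score a structure with a contact potential
#'
#' Sum of `E(a_i, a_j)` over all contacting pairs under the definition;
#' lower scores are more favorable. Pairs involving residues outside the 20
#' standard types are skipped with a warning.
#'
#' @param st A `cf_structure`.
#' @param potential A `cf_potential`.
#' @param definition A `cf_contact_def`.
#' @param lib Rotamer library for the CD definition.
#' @param min_separation Sequence-separation filter (default 2, matching the
#'   potential-derivation default).
#' @param cross_chain Passed to [compute_contact_map()].
#' @return Numeric score.
#' @export
score_structure <- function(st, potential, definition, lib = NULL,
                            min_separation = 2L, cross_chain = TRUE) {
  definition$min_separation <- as.integer(min_separation)
  map <- compute_contact_map(st, definition, lib, cross_chain = cross_chain)
  p <- map$pairs[map$pairs$is_contact, , drop = FALSE]
  if (!nrow(p)) return(0)
  aa <- vapply(st$residues, `[[`, "", "aa")
  e <- potential_energy(potential, aa[p$i], aa[p$j])
  if (anyNA(e)) {
    warning(sprintf("%d contact(s) with non-standard residues skipped", sum(is.na(e))))
    e <- e[!is.na(e)]
  }
  sum(e)
}

#' Competition rank of the native among decoy scores
#'
#' Ascending-score (lower = better) min-rank: ties with decoys do not worsen
#' the native's rank, so a native tied for the best score still ranks 1.
#'
#' @param native_score Native structure score.
#' @param decoy_scores Numeric vector of decoy scores.
#' @return Integer rank in `[1, 1 + length(decoy_scores)]`.
#' @export
rank_native <- function(native_score, decoy_scores) {
  1L + sum(decoy_scores < native_score)
}

#' Read a rank table (TSV: protein id column followed by method columns)
#' @param text TSV text or a file path.
#' @return Data frame; first column `protein`, remaining columns integer ranks.
#' @export
read_rank_table <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    df <- utils::read.delim(text, comment.char = "#", stringsAsFactors = FALSE)
  else
    df <- utils::read.delim(textConnection(text), comment.char = "#",
                            stringsAsFactors = FALSE)
  names(df)[1] <- "protein"
  df
}

#' Per-method counts of best (or tied-best) native ranks
#'
#' For each protein (row) the minimum rank across methods is found; every
#' method achieving it is credited, so ties count for all tied methods.
#'
#' @param table Rank table data frame (see [read_rank_table()]).
#' @return Named integer vector of counts per method.
#' @export
best_method_counts <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), "protein"), drop = FALSE])
  best <- apply(m, 1, min)
  colSums(m == best)
}

#' Column median of a rank table
#' @param table Rank table data frame.
#' @param method Method column name.
#' @export
column_median <- function(table, method) stats::median(table[[method]])

#' Paired two-treatment Friedman test on a rank table
#'
#' Compares two methods' per-protein native ranks with the Friedman test
#' (chi-square approximation, 1 degree of freedom, mid-rank tie handling,
#' as in [stats::friedman.test()]). With no within-row ties the statistic
#' reduces to `(n_plus - n_minus)^2 / n`.
#'
#' @param table Rank table data frame.
#' @param method_a,method_b Method column names.
#' @return List with `statistic` and `p.value`.
#' @export
friedman_paired <- function(table, method_a, method_b) {
  a <- table[[method_a]]
  b <- table[[method_b]]
  if (length(a) < 3) cf_stop("need at least 3 rows for the Friedman test",
                             "cf_config_error")
  if (all(a == b)) return(list(statistic = 0, p.value = 1))
  ft <- stats::friedman.test(cbind(a, b))
  list(statistic = unname(ft$statistic), p.value = ft$p.value)
}

#' Average decoy-elimination fraction of native contacts
#'
#' For every contact of the native structure, the fraction of decoys in
#' which that pair is *not* a contact under the same definition, averaged
#' uniformly over the native contacts. Measures the structural information
#' contributed by knowledge of a single native contact.
#'
#' @param decoy_set List with elements `native` (a `cf_structure`) and
#'   `decoys` (list of `cf_structure` with the same sequence), e.g. from
#'   [make_decoys()].
#' @param definition A `cf_contact_def` (its own `min_separation` is used).
#' @param lib Rotamer library for the CD definition.
#' @param cross_chain Passed to [compute_contact_map()].
#' @return Fraction in `[0, 1]`; `NaN` when the native has no contacts.
#' @export
elimination_fraction <- function(decoy_set, definition, lib = NULL,
                                 cross_chain = TRUE) {
  native_keys <- contact_keys(compute_contact_map(decoy_set$native, definition,
                                                  lib, cross_chain = cross_chain))
  if (!length(native_keys)) return(NaN)
  pres <- vapply(decoy_set$decoys, function(d) {
    native_keys %in% contact_keys(compute_contact_map(d, definition, lib,
                                                      cross_chain = cross_chain))
  }, logical(length(native_keys)))
  pres <- matrix(pres, nrow = length(native_keys))
  elimination_from_presence(pres)
}

#' Elimination fraction from a presence matrix
#'
#' Core arithmetic of [elimination_fraction()]: rows are native contacts,
#' columns are decoys, entries indicate the contact being present in the
#' decoy. Exposed for direct testing against enumeration.
#'
#' @param presence Logical/0-1 matrix (contacts x decoys).
#' @return Mean over contacts of the fraction of decoys lacking the contact.
#' @export
elimination_from_presence <- function(presence) {
  presence <- matrix(as.logical(presence), nrow = nrow(presence))
  mean(rowMeans(!presence))
}
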