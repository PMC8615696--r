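#' Jaccard index of two gene sets
#'
#' \deqn{J(A, B) = |A \cap B| / |A \cup B|.}
#' This is the reversal score between a disease up-set and a drug down-set:
#' the larger the overlap relative to the union, the more the drug's
#' down-regulated genes oppose the disease's up-regulated state.
#'
#' @param set_a,set_b character vectors (duplicates ignored). Both empty is
#'   an error, not a silent 0.
#' @return a number in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(as.character(set_a)); b <- unique(as.character(set_b))
  if (length(a) == 0 && length(b) == 0)
    stop("Jaccard undefined: both sets are empty")
  length(intersect(a, b)) / length(union(a, b))
}

# score one signature against one disease signature; gene sets restricted
# to the intersection of the two universes so a universe mismatch cannot
# deflate the union asymmetrically
score_one <- function(disease, sig, symmetric = FALSE) {
  shared <- intersect(disease$gene_universe, sig$gene_universe)
  a <- intersect(disease$up, shared)
  b <- intersect(sig$down, shared)
  s <- if (length(a) == 0 || length(b) == 0) 0 else jaccard(a, b)
  if (symmetric) {
    a2 <- intersect(disease$down, shared)
    b2 <- intersect(sig$up, shared)
    s2 <- if (length(a2) == 0 || length(b2) == 0) 0 else jaccard(a2, b2)
    s <- (s + s2) / 2
  }
  s
}

#' Best Jaccard score of a drug against a disease up-set
#'
#' A drug is profiled under many conditions (cell line, dose, time); the
#' drug's score is the maximum Jaccard score over all its signatures,
#' regardless of condition. Signatures with an empty down set contribute 0.
#'
#' @param disease_up a [disease_signature()] (its up set is used) .
#' @param drug_signatures non-empty list of [perturbation_signature()] objects, all for
#'   one drug.
#' @param symmetric if `TRUE`, average in the mirrored disease-down vs
#'   drug-up Jaccard term (off by default; the canonical score is up-vs-down
#'   only).
#' @return the best score, a number in `[0, 1]`.
#' @export
best_score_for_drug <- function(disease_up, drug_signatures,
                                symmetric = FALSE) {
  if (length(drug_signatures) == 0)
    stop("drug has no signatures")
  max(vapply(drug_signatures, function(sig)
    score_one(disease_up, sig, symmetric), 0))
}

#' Score a signature library against disease signatures
#'
#' For every drug: take the best (max over that drug's signatures) Jaccard
#' score against each disease signature's up-set, then average those best
#' scores across disease signatures. Drugs are ranked by descending
#' average score, ties broken lexicographically by drug id.
#'
#' @param disease_signatures non-empty list of [disease_signature()]s with
#'   unique names.
#' @param library non-empty list of [perturbation_signature()] objects.
#' @param symmetric see [best_score_for_drug()].
#' @return a `reversal score table`: data.frame with columns `drug_id`,
#'   one `score_<disease name>` per disease signature, `average_score`,
#'   `rank`; rows ordered by rank.
#' @export
score_library <- function(disease_signatures, library, symmetric = FALSE) {
  if (length(disease_signatures) == 0) stop("need >= 1 disease signature")
  if (length(library) == 0) stop("signature library is empty")
  for (ds in disease_signatures)
    if (length(ds$up) == 0) stop("disease up set is empty: ", ds$name)
  dnames <- vapply(disease_signatures, `[[`, "", "name")
  if (anyDuplicated(dnames)) stop("disease signature names must be unique")
  drug_of <- vapply(library, `[[`, "", "drug_id")
  drugs <- sort(unique(drug_of))
  per_disease <- vapply(disease_signatures, function(ds) {
    vapply(drugs, function(dr)
      best_score_for_drug(ds, library[drug_of == dr], symmetric), 0)
  }, numeric(length(drugs)))
  per_disease <- matrix(per_disease, nrow = length(drugs),
                        dimnames = list(drugs, paste0("score_", dnames)))
  avg <- rowMeans(per_disease)
  out <- data.frame(drug_id = drugs, per_disease, average_score = avg,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  ord <- order(-out$average_score, out$drug_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Keep the top-k drugs of a reversal score table
#'
#' @param table a reversal score table from [score_library()].
#' @param k number of drugs to keep; must not exceed the table size.
#' @return the first `k` rows by rank.
#' @export
top_k <- function(table, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be a positive integer")
  if (k > nrow(table))
    stop("k = ", k, " exceeds the number of drugs (", nrow(table), ")")
  table[seq_len(k), , drop = FALSE]
}
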