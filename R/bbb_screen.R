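#' Read a blood-brain-barrier probability table
#'
#' Reads a TSV of per-compound BBB+ probability scores (admetSAR-style,
#' each in `[-1, 1]`; higher means more likely to cross the barrier).
#'
#' @param path TSV with header columns `compound_id` and
#'   `bbb_probability`.
#' @return named numeric vector of scores.
#' @export
read_bbb_table <- function(path) {
  read_score_table(path, id_column = "compound_id",
                   score_column = "bbb_probability", range = c(-1, 1))
}

#' Re-rank reversal candidates by BBB permeability and retain the top n
#'
#' The second screening stage: among the top reversal candidates, keep the
#' `n` compounds with the highest BBB+ probability. Candidates without a
#' BBB score are excluded with a warning naming them — a missing
#' prediction is not evidence of impermeability, so they are never
#' silently dropped.
#'
#' @param candidates data.frame with columns `drug_id` and `average_score`
#'   (e.g. a [top_k()] slice of a reversal score table).
#' @param scores named numeric vector of BBB probabilities in `[-1, 1]`
#'   (see [read_bbb_table()]).
#' @param n how many compounds to retain; must not exceed the number of
#'   candidates that have a score.
#' @return data.frame with columns `rank`, `drug_id`, `average_score`,
#'   `bbb_probability`, sorted by descending BBB probability (ties: higher
#'   average reversal score, then drug id).
#' @export
screen_by_bbb <- function(candidates, scores, n = 10) {
  if (!all(c("drug_id", "average_score") %in% names(candidates)))
    stop("candidates need columns 'drug_id' and 'average_score'")
  if (any(scores < -1 | scores > 1))
    stop("BBB probabilities must lie in [-1, 1]")
  has <- candidates$drug_id %in% names(scores)
  if (!any(has)) stop("no candidate has a BBB score")
  if (!all(has))
    warning("excluding ", sum(!has), " candidate(s) without a BBB score: ",
            paste(candidates$drug_id[!has], collapse = ", "))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (n > sum(has))
    stop("n = ", n, " exceeds the ", sum(has), " scoreable candidates")
  kept <- candidates[has, , drop = FALSE]
  kept$bbb_probability <- unname(scores[kept$drug_id])
  ord <- order(-kept$bbb_probability, -kept$average_score, kept$drug_id)
  kept <- kept[ord[seq_len(n)],
               c("drug_id", "average_score", "bbb_probability")]
  kept <- data.frame(rank = seq_len(n), kept, row.names = NULL)
  kept
}
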