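#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `k` common elements between two sets
#' of sizes `n1` and `n2` drawn without replacement from a universe of
#' size `N`: \eqn{P(X \ge k)} with
#' \eqn{X \sim \mathrm{Hypergeom}(N, n1, n2)}. Used to test whether a
#' candidate drug's down-regulated genes overlap the disease up-regulated
#' genes more than chance.
#'
#' @param k observed overlap, `0 <= k <= min(n1, n2)`.
#' @param n1,n2 set sizes, each `<= N`.
#' @param N universe size.
#' @return p-value in `(0, 1]`.
#' @export
hypergeometric_overlap_p <- function(k, n1, n2, N) {
  v <- c(k = k, n1 = n1, n2 = n2, N = N)
  if (any(!is.finite(v)) || any(v != round(v)) || any(v < 0))
    stop("k, n1, n2, N must be non-negative integers")
  if (n1 > N || n2 > N) stop("set sizes cannot exceed the universe size N")
  if (k > min(n1, n2)) stop("overlap k cannot exceed min(n1, n2)")
  stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values (same order), capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric term enrichment of a query set
#'
#' Tests each annotation term for over-representation in the query via the
#' upper-tail hypergeometric test, after intersecting every term with the
#' background. Terms with no overlap with the query (`k = 0`) are not
#' reported; BH adjustment is computed over the reported terms. This is
#' the core used both for mechanism-of-action enrichment over top-ranked
#' drugs and for gene-set enrichment of DEG lists against a GMT library.
#'
#' @param query character vector of ids; must be a subset of `background`.
#' @param annotations named list mapping term -> character vector of ids.
#' @param background character vector: the universe ids.
#' @return data.frame with columns `term`, `k` (overlap), `K` (term size in
#'   background), `n` (query size), `N` (background size), `p_value`,
#'   `p_adjusted`, `neg_log10_p_adjusted`, sorted by ascending `p_value`
#'   (ties: term name).
#' @export
term_enrichment <- function(query, annotations, background) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background is empty")
  query <- unique(as.character(query))
  stray <- setdiff(query, background)
  if (length(stray) > 0)
    stop("query ids missing from background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  if (is.null(names(annotations)) || anyDuplicated(names(annotations)))
    stop("`annotations` must be a uniquely named list")
  N <- length(background); n <- length(query)
  rows <- lapply(names(annotations), function(term) {
    members <- intersect(unique(annotations[[term]]), background)
    k <- length(intersect(query, members))
    if (k == 0) return(NULL)
    data.frame(term = term, k = k, K = length(members), n = n, N = N,
               p_value = hypergeometric_overlap_p(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      p_adjusted = numeric(0),
                      neg_log10_p_adjusted = numeric(0)))
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$neg_log10_p_adjusted <- -log10(out$p_adjusted)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mechanism-of-action enrichment of top-ranked drugs
#'
#' Convenience wrapper around [term_enrichment()] for a drug -> MOA
#' annotation table. The background defaults to every drug in the scored
#' library: the only defensible universe inside the pipeline.
#'
#' @param top_drugs character vector of drug ids (e.g. the top-100 of a
#'   reversal score table).
#' @param moa table: data.frame with columns `drug_id` and `moa`, or a
#'   named character vector (names = drug ids).
#' @param background character vector of all scored drug ids.
#' @return see [term_enrichment()].
#' @export
moa_enrichment <- function(top_drugs, moa, background) {
  if (is.data.frame(moa)) {
    if (!all(c("drug_id", "moa") %in% names(moa)))
      stop("moa table needs columns 'drug_id' and 'moa'")
    moa <- stats::setNames(as.character(moa$moa), moa$drug_id)
  }
  ann <- split(names(moa), unname(moa))
  term_enrichment(top_drugs, ann, background)
}
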