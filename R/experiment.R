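#' Construct a replicated treatment/control expression experiment
#'
#' An `expression_experiment` bundles a genes x samples numeric matrix
#' (log-scale expression or z-scores) with a per-sample class label in
#' `{"control", "treatment"}`. It is the raw material from which one
#' perturbation signature is computed.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be finite.
#' @param sample_class character vector, one of `"control"` / `"treatment"`
#'   per column of `values`. If named, names must match the column names.
#'
#' @return An object of class `expression_experiment`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `sample_class`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ee <- expression_experiment(m, c("control", "control", "treatment", "treatment"))
#' @export
expression_experiment <- function(values, sample_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  if (!is.null(names(sample_class))) {
    missing <- setdiff(colnames(values), names(sample_class))
    if (length(missing) > 0)
      stop("sample_class has no entry for sample(s): ",
           paste(missing, collapse = ", "))
    sample_class <- unname(sample_class[colnames(values)])
  }
  x <- structure(
    list(values = values,
         gene_ids = rownames(values),
         sample_ids = colnames(values),
         sample_class = as.character(sample_class)),
    class = "expression_experiment")
  validate_experiment(x)
  x
}

#' Validate an expression experiment's invariants
#'
#' Checks dimensional consistency, uniqueness of gene and sample ids,
#' finiteness of values, and the presence of at least one control and one
#' treatment sample.
#'
#' @param x an `expression_experiment`.
#' @return `x`, invisibly; errors on any violated invariant.
#' @export
validate_experiment <- function(x) {
  if (!inherits(x, "expression_experiment"))
    stop("not an expression_experiment")
  if (nrow(x$values) != length(x$gene_ids) ||
      ncol(x$values) != length(x$sample_ids))
    stop("matrix dimensions disagree with gene/sample id lengths")
  if (anyDuplicated(x$gene_ids))
    stop("duplicated gene ids: ",
         paste(unique(x$gene_ids[duplicated(x$gene_ids)]), collapse = ", "))
  if (anyDuplicated(x$sample_ids))
    stop("duplicated sample ids")
  if (length(x$sample_class) != length(x$sample_ids))
    stop("sample_class length disagrees with sample count")
  bad <- setdiff(unique(x$sample_class), c("control", "treatment"))
  if (length(bad) > 0)
    stop("sample_class labels must be 'control' or 'treatment', got: ",
         paste(bad, collapse = ", "))
  if (sum(x$sample_class == "control") < 1 ||
      sum(x$sample_class == "treatment") < 1)
    stop("need at least one control and one treatment sample")
  if (!all(is.finite(x$values)))
    stop("expression values must all be finite")
  invisible(x)
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat(sprintf("expression_experiment: %d genes x %d samples (%d control, %d treatment)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_class == "control"),
              sum(x$sample_class == "treatment")))
  invisible(x)
}
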