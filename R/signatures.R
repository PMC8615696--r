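#' Characteristic-direction coefficients for a two-class experiment
#'
#' Computes the characteristic direction of a replicated
#' treatment-vs-control experiment: the unit vector
#' \deqn{b \propto \Sigma_\gamma^{-1} (\mu_t - \mu_c), \qquad
#'       \Sigma_\gamma = (1-\gamma)\,\hat\Sigma + \gamma\,\nu I, \quad
#'       \nu = \mathrm{tr}(\hat\Sigma)/p,}
#' where \eqn{\hat\Sigma} is the pooled within-class sample covariance and
#' \eqn{\gamma \in [0,1]} shrinks it towards a scaled identity. This is the
#' regularized linear-discriminant direction separating the two classes in
#' gene space. Because \eqn{\hat\Sigma} has rank at most \eqn{n-2}, the
#' inverse is applied analytically through the eigendecomposition of the
#' sample-spanned subspace; no \eqn{p \times p} matrix is ever inverted
#' when \eqn{p \gg n}.
#'
#' The returned vector has unit Euclidean norm and is oriented so that
#' \eqn{b \cdot (\mu_t - \mu_c) \ge 0}: a positive coefficient means the
#' gene is higher in treatment.
#'
#' @param experiment an [expression_experiment()].
#' @param gamma shrinkage weight in `[0, 1]`. `gamma = 1` gives the scaled
#'   normalized mean difference; `gamma = 0` requires a full-rank pooled
#'   covariance (only possible when samples outnumber genes).
#' @return named numeric vector of per-gene coefficients, unit norm.
#' @export
characteristic_direction <- function(experiment, gamma = 0.5) {
  validate_experiment(experiment)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma > 1)
    stop("gamma must be a single number in [0, 1]")
  X <- experiment$values
  p <- nrow(X); n <- ncol(X)
  is_t <- experiment$sample_class == "treatment"
  d <- rowMeans(X[, is_t, drop = FALSE]) - rowMeans(X[, !is_t, drop = FALSE])
  if (all(d == 0))
    stop("degenerate signal: treatment and control means are identical")
  # pooled within-class residuals; Sigma_hat = R R' / (n - 2)
  R <- X
  R[, is_t]  <- X[, is_t, drop = FALSE]  - rowMeans(X[, is_t, drop = FALSE])
  R[, !is_t] <- X[, !is_t, drop = FALSE] - rowMeans(X[, !is_t, drop = FALSE])
  df <- n - 2L
  if (df < 1L || all(R == 0)) {
    # no estimable within-class covariance (1v1 design or noise-free
    # replicates): Sigma_hat = 0, so the shrunk inverse is proportional to
    # the identity for any gamma > 0 and b is the normalized mean difference
    if (gamma == 0)
      stop("singular shrunk covariance at gamma = 0; use gamma > 0")
    b <- d
  } else {
    sv <- svd(R, nu = min(p, n), nv = 0)
    lam_all <- sv$d^2 / df
    nu <- sum(lam_all) / p
    keep <- lam_all > max(lam_all) * 1e-12
    U <- sv$u[, keep, drop = FALSE]
    lam <- lam_all[keep]
    if (gamma == 0) {
      if (sum(keep) < p)
        stop("singular shrunk covariance at gamma = 0 (rank ", sum(keep),
             " < ", p, " genes); use gamma > 0")
      b <- drop(U %*% ((crossprod(U, d)) / lam))
    } else {
      gnu <- gamma * nu
      shrunk <- (1 - gamma) * lam + gnu
      # Sigma_gamma^-1 d = d/(gamma*nu) + U [(1/shrunk - 1/(gamma*nu)) (U'd)]
      b <- d / gnu + drop(U %*% ((1 / shrunk - 1 / gnu) * crossprod(U, d)))
    }
  }
  if (sum(b * d) < 0) b <- -b
  b <- b / sqrt(sum(b^2))
  names(b) <- experiment$gene_ids
  b
}

#' Call up/down differentially expressed genes by z-test
#'
#' Standardizes the coefficient vector over genes,
#' \eqn{z_g = (b_g - \bar b)/\mathrm{sd}(b)}, computes two-sided normal
#' p-values \eqn{p_g = 2(1 - \Phi(|z_g|))}, and assigns gene \eqn{g} to the
#' up set iff \eqn{p_g < \alpha} and \eqn{b_g > 0}, to the down set iff
#' \eqn{p_g < \alpha} and \eqn{b_g < 0}.
#'
#' @param coefficients named numeric vector (e.g. from
#'   [characteristic_direction()]).
#' @param alpha significance threshold in `(0, 1)`; default 0.01.
#' @return list with character vectors `up` and `down` (gene ids, in input
#'   order) and the numeric vector `p_value`.
#' @export
call_degs <- function(coefficients, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  b <- coefficients
  if (length(b) < 3) stop("need at least 3 genes to standardize")
  if (is.null(names(b))) stop("coefficients must be named by gene id")
  s <- stats::sd(b)
  if (s == 0) stop("degenerate coefficients: zero standard deviation")
  z <- (b - mean(b)) / s
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  sig <- p < alpha
  list(up = names(b)[sig & b > 0],
       down = names(b)[sig & b < 0],
       p_value = p)
}

#' Construct a perturbation signature
#'
#' A signature couples a perturbation's (optional) coefficient vector with
#' its derived up/down DEG sets, its gene universe, and its condition
#' metadata (drug, cell line, dose, time). Set-only signatures
#' (`coefficients = NULL`) support libraries supplied directly as up/down
#' GMT pairs.
#'
#' @param signature_id,drug_id identifiers.
#' @param up,down character vectors of gene ids; must be disjoint subsets
#'   of `gene_universe`.
#' @param gene_universe ordered gene ids the signature is defined over.
#' @param coefficients optional named unit-norm numeric vector over
#'   `gene_universe`; up genes must have positive and down genes negative
#'   coefficients.
#' @param cell_line,dose,time condition annotations (free text).
#' @return an object of class `perturbation_signature`.
#' @export
perturbation_signature <- function(signature_id, drug_id, up, down, gene_universe,
                      coefficients = NULL, cell_line = NA_character_,
                      dose = NA_character_, time = NA_character_) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0)
    stop("up and down sets intersect for signature ", signature_id)
  outside <- setdiff(c(up, down), gene_universe)
  if (length(outside) > 0)
    stop("DEGs outside gene universe for signature ", signature_id, ": ",
         paste(utils::head(outside, 5), collapse = ", "))
  if (!is.null(coefficients)) {
    if (abs(sqrt(sum(coefficients^2)) - 1) > 1e-9)
      stop("coefficients must have unit Euclidean norm")
    if (any(coefficients[up] <= 0) || any(coefficients[down] >= 0))
      stop("sign of coefficients disagrees with up/down membership")
  }
  structure(list(signature_id = signature_id, drug_id = drug_id,
                 up = up, down = down,
                 gene_universe = as.character(gene_universe),
                 coefficients = coefficients,
                 cell_line = cell_line, dose = dose, time = time),
            class = "perturbation_signature")
}

#' @export
print.perturbation_signature <- function(x, ...) {
  cat(sprintf("signature %s (drug %s): %d up / %d down of %d genes\n",
              x$signature_id, x$drug_id, length(x$up), length(x$down),
              length(x$gene_universe)))
  invisible(x)
}

#' Construct a disease signature (named up/down gene sets)
#'
#' Disease signatures arrive as curated up/down gene lists (CREEDS-style)
#' over a stated gene universe; only the up set is required for reversal
#' matching against drug down sets.
#'
#' @param name identifier.
#' @param up,down character vectors of gene ids (disjoint). `up` must be
#'   non-empty.
#' @param gene_universe ordered gene ids.
#' @return an object of class `disease_signature`.
#' @export
disease_signature <- function(name, up, down = character(0),
                              gene_universe) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(up) == 0) stop("disease up set must be non-empty")
  if (length(intersect(up, down)) > 0)
    stop("disease up and down sets intersect")
  outside <- setdiff(c(up, down), gene_universe)
  if (length(outside) > 0)
    stop("disease genes outside universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  structure(list(name = name, up = up, down = down,
                 gene_universe = as.character(gene_universe)),
            class = "disease_signature")
}

#' Build a signature library from experiments plus metadata
#'
#' Applies [characteristic_direction()] and [call_degs()] to each
#' experiment and attaches the condition metadata. Output order is
#' deterministic: sorted by `signature_id`.
#'
#' @param experiments named list of [expression_experiment()] objects;
#'   names are signature ids and must match `metadata$signature_id`
#'   exactly.
#' @param metadata data.frame with columns `signature_id`, `drug_id`,
#'   `cell_line`, `dose`, `time`.
#' @param gamma,alpha passed to [characteristic_direction()] and
#'   [call_degs()].
#' @return list of [perturbation_signature()] objects sorted by signature id.
#' @export
build_signature_library <- function(experiments, metadata,
                                    gamma = 0.5, alpha = 0.01) {
  if (length(experiments) == 0) return(list())
  if (is.null(names(experiments)))
    stop("`experiments` must be a named list keyed by signature_id")
  only_exp <- setdiff(names(experiments), metadata$signature_id)
  only_meta <- setdiff(metadata$signature_id, names(experiments))
  if (length(only_exp) > 0 || length(only_meta) > 0)
    stop("experiment/metadata key mismatch; without metadata: [",
         paste(only_exp, collapse = ", "), "]; without experiment: [",
         paste(only_meta, collapse = ", "), "]")
  ids <- sort(names(experiments))
  out <- lapply(ids, function(id) {
    ee <- experiments[[id]]
    b <- characteristic_direction(ee, gamma = gamma)
    degs <- call_degs(b, alpha = alpha)
    row <- metadata[metadata$signature_id == id, , drop = FALSE]
    perturbation_signature(id, row$drug_id[1], degs$up, degs$down,
              gene_universe = ee$gene_ids, coefficients = b,
              cell_line = row$cell_line[1], dose = row$dose[1],
              time = row$time[1])
  })
  names(out) <- ids
  out
}

#' Assemble a set-only signature library from up/down GMT pairs
#'
#' The precomputed bypass: libraries distributed as a pair of GMT files
#' (set name = signature id) plus a metadata table skip the
#' characteristic-direction stage entirely.
#'
#' @param up_sets,down_sets named lists of gene-id vectors (e.g. from
#'   [read_gmt()]); names are signature ids. A signature may be absent
#'   from one of the two (empty set).
#' @param metadata signature metadata data.frame (see
#'   [read_signature_metadata()]).
#' @param gene_universe ordered gene ids all sets live in.
#' @return list of set-only [perturbation_signature()] objects sorted by signature id.
#' @export
signatures_from_sets <- function(up_sets, down_sets, metadata,
                                 gene_universe) {
  ids <- sort(union(names(up_sets), names(down_sets)))
  only <- setdiff(ids, metadata$signature_id)
  if (length(only) > 0)
    stop("signatures missing from metadata: ",
         paste(utils::head(only, 5), collapse = ", "))
  out <- lapply(ids, function(id) {
    row <- metadata[metadata$signature_id == id, , drop = FALSE]
    perturbation_signature(id, row$drug_id[1],
              up = if (id %in% names(up_sets)) up_sets[[id]] else character(0),
              down = if (id %in% names(down_sets)) down_sets[[id]] else character(0),
              gene_universe = gene_universe,
              cell_line = row$cell_line[1], dose = row$dose[1],
              time = row$time[1])
  })
  names(out) <- ids
  out
}

#' Serialize a signature library as up/down GMT files plus metadata TSV
#'
#' @param library list of [perturbation_signature()] objects.
#' @param up_path,down_path,metadata_path output paths. Signatures with an
#'   empty up (down) set are omitted from the corresponding GMT.
#' @return invisibly, a list of the three paths.
#' @export
write_signature_library <- function(library, up_path, down_path,
                                    metadata_path) {
  ups <- lapply(library, `[[`, "up")
  downs <- lapply(library, `[[`, "down")
  names(ups) <- names(downs) <- vapply(library, `[[`, "", "signature_id")
  write_gmt(ups[lengths(ups) > 0], up_path)
  write_gmt(downs[lengths(downs) > 0], down_path)
  meta <- data.frame(
    signature_id = vapply(library, `[[`, "", "signature_id"),
    drug_id = vapply(library, `[[`, "", "drug_id"),
    cell_line = vapply(library, `[[`, "", "cell_line"),
    dose = vapply(library, `[[`, "", "dose"),
    time = vapply(library, `[[`, "", "time"),
    stringsAsFactors = FALSE)
  write_tsv(meta, metadata_path)
  invisible(list(up = up_path, down = down_path, metadata = metadata_path))
}
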