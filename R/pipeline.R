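#' Build a validated pipeline configuration
#'
#' Collects the paths and parameters of a full screen. Inputs may be
#' given as file paths (disease GMT pair; library GMT pair or a directory
#' of GCT experiments; MOA and BBB TSVs) or, programmatically, as a
#' pre-generated in-memory bundle via `inputs`.
#'
#' @param inputs optional in-memory bundle from
#'   [generate_screen_inputs()]; when given, path arguments are ignored.
#' @param disease_up,disease_down paths to the disease GMT pair
#'   (`disease_down` optional).
#' @param library_up,library_down paths to the library GMT pair (set
#'   mode), or `experiments_dir` a directory of `<signature_id>.gct` +
#'   `<signature_id>.classes.tsv` pairs (expression mode).
#' @param metadata path to the signature metadata TSV.
#' @param moa,bbb paths to the annotation TSVs.
#' @param gene_sets optional path to a GMT for gene-set enrichment
#'   reports.
#' @param experiments_dir see above.
#' @param gamma covariance shrinkage for the characteristic direction.
#' @param alpha DEG-calling threshold, in `(0, 1)`.
#' @param top_k reversal candidates passed to the BBB stage.
#' @param retain_n compounds retained after BBB screening; must not
#'   exceed `top_k`.
#' @param outdir output directory for the result tables.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL, disease_up = NULL,
                            disease_down = NULL, library_up = NULL,
                            library_down = NULL, metadata = NULL,
                            moa = NULL, bbb = NULL, gene_sets = NULL,
                            experiments_dir = NULL, gamma = 0.5,
                            alpha = 0.01, top_k = 100, retain_n = 10,
                            outdir = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (retain_n > top_k)
    stop("retain_n (", retain_n, ") exceeds top_k (", top_k, ")")
  cfg <- list(inputs = inputs, disease_up = disease_up,
              disease_down = disease_down, library_up = library_up,
              library_down = library_down, metadata = metadata,
              moa = moa, bbb = bbb, gene_sets = gene_sets,
              experiments_dir = experiments_dir, gamma = gamma,
              alpha = alpha, top_k = as.integer(top_k),
              retain_n = as.integer(retain_n), outdir = outdir)
  if (is.null(inputs)) {
    for (f in c("disease_up", "metadata", "moa", "bbb"))
      if (is.null(cfg[[f]]))
        stop("pipeline_config requires ", f, " when no in-memory inputs ",
             "are given")
    if (is.null(cfg$library_down) && is.null(cfg$experiments_dir))
      stop("either library_down (set mode) or experiments_dir ",
           "(expression mode) is required")
    paths <- unlist(cfg[c("disease_up", "disease_down", "library_up",
                          "library_down", "metadata", "moa", "bbb",
                          "gene_sets", "experiments_dir")])
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    bundle <- config$inputs
    lib <- bundle$library
    if (lib$mode == "expression") {
      sigs <- build_signature_library(lib$experiments, lib$metadata,
                                      gamma = config$gamma,
                                      alpha = config$alpha)
    } else sigs <- lib$signatures
    return(list(disease = bundle$disease, signatures = sigs,
                moa = bundle$annotations$moa,
                bbb = stats::setNames(bundle$annotations$bbb$bbb_probability,
                                      bundle$annotations$bbb$compound_id)))
  }
  meta <- read_signature_metadata(config$metadata)
  if (!is.null(config$experiments_dir)) {
    ids <- meta$signature_id
    experiments <- stats::setNames(lapply(ids, function(sid) {
      read_gct(file.path(config$experiments_dir, paste0(sid, ".gct")),
               file.path(config$experiments_dir,
                         paste0(sid, ".classes.tsv")))
    }), ids)
    sigs <- build_signature_library(experiments, meta,
                                    gamma = config$gamma,
                                    alpha = config$alpha)
    universe <- experiments[[1]]$gene_ids
  } else {
    up_sets <- read_gmt(config$library_up)
    down_sets <- read_gmt(config$library_down)
    universe <- NULL
    sigs <- NULL  # deferred until the universe is known
  }
  dup <- read_gmt(config$disease_up)
  ddn <- if (!is.null(config$disease_down)) read_gmt(config$disease_down)
         else stats::setNames(rep(list(character(0)), length(dup)),
                              names(dup))
  if (is.null(universe))
    universe <- sort(unique(c(unlist(dup), unlist(ddn), unlist(up_sets),
                              unlist(down_sets))))
  if (is.null(sigs))
    sigs <- signatures_from_sets(up_sets, down_sets, meta, universe)
  disease <- stats::setNames(lapply(names(dup), function(nm)
    disease_signature(nm, dup[[nm]],
                      if (nm %in% names(ddn)) ddn[[nm]] else character(0),
                      universe)), names(dup))
  list(disease = disease, signatures = sigs,
       moa = utils::read.delim(config$moa, stringsAsFactors = FALSE),
       bbb = read_bbb_table(config$bbb))
}

#' Run the full reversal-and-BBB drug screen
#'
#' Orchestrates the whole screen: build or load the signature library,
#' call DEGs, rank every drug by averaged best Jaccard reversal score
#' against the disease up-sets, keep the top-k, test the
#' mechanism-of-action classes of the top-k for enrichment, re-rank the
#' top-k by BBB probability and retain the top-n. Writes
#' `reversal_scores.tsv`, `top_k.tsv`, `moa_enrichment.tsv`,
#' `bbb_top.tsv` and `manifest.json` to `config$outdir` (if set) and
#' logs per-stage counts to stderr.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `scores`, `top`, `moa`, `bbb_top`,
#'   `manifest`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inp <- stage("load_inputs", load_pipeline_inputs(config))
  message(sprintf("[signatures] %d signatures over %d drugs",
                  length(inp$signatures),
                  length(unique(vapply(inp$signatures, `[[`, "",
                                       "drug_id")))))
  scores <- stage("match", score_library(inp$disease, inp$signatures))
  message(sprintf("[match] scored %d drugs against %d disease signatures",
                  nrow(scores), length(inp$disease)))
  top <- stage("top_k", top_k(scores, config$top_k))
  moa_res <- stage("moa_enrichment",
                   moa_enrichment(top$drug_id, inp$moa, scores$drug_id))
  message(sprintf("[enrich] %d MOA terms tested", nrow(moa_res)))
  bbb_top <- stage("bbb_screen",
                   screen_by_bbb(top, inp$bbb, config$retain_n))
  message(sprintf("[bbb] retained %d of %d candidates",
                  nrow(bbb_top), nrow(top)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("sigreverse")),
    config_hash = config_hash(config),
    parameters = config[c("gamma", "alpha", "top_k", "retain_n")],
    n_signatures = length(inp$signatures), n_drugs = nrow(scores),
    n_moa_terms_tested = nrow(moa_res),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res <- list(scores = scores, top = top, moa = moa_res,
              bbb_top = bbb_top, manifest = manifest)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(scores, file.path(config$outdir, "reversal_scores.tsv"))
    write_tsv(top, file.path(config$outdir, "top_k.tsv"))
    write_tsv(moa_res, file.path(config$outdir, "moa_enrichment.tsv"))
    write_tsv(bbb_top, file.path(config$outdir, "bbb_top.tsv"))
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

# stable hash of the configuration (paths + parameters), for the manifest
config_hash <- function(config) {
  plain <- config[!vapply(config, is.null, TRUE)]
  plain$inputs <- if (!is.null(plain$inputs)) "in-memory" else NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Overlap report for one candidate drug
#'
#' For a chosen candidate, quantifies how its DEGs oppose the disease: for
#' each disease signature, the candidate's best-scoring condition is
#' selected and the overlap of its down-set with the disease up-set (and
#' of its up-set with the disease down-set) is tested with the upper-tail
#' hypergeometric test over the shared gene universe. If a gene-set GMT is
#' supplied, the reversal overlap genes are additionally tested for
#' term enrichment against it.
#'
#' @param drug_id the candidate.
#' @param disease_signatures list of [disease_signature()]s.
#' @param library list of [perturbation_signature()]s.
#' @param gene_sets optional named list of gene sets (e.g. [read_gmt()]).
#' @return list with one entry per disease signature (`signature_id`,
#'   overlap genes and counts, hypergeometric p-values) and, if
#'   `gene_sets` was given, `enrichment` over the pooled reversal-overlap
#'   genes.
#' @export
candidate_overlap_report <- function(drug_id, disease_signatures, library,
                                     gene_sets = NULL) {
  drug_of <- vapply(library, `[[`, "", "drug_id")
  if (!drug_id %in% drug_of) {
    known <- sort(unique(drug_of))
    near <- known[order(utils::adist(drug_id, known))]
    stop("unknown drug '", drug_id, "'; nearest known ids: ",
         paste(utils::head(near, 3), collapse = ", "))
  }
  sigs <- library[drug_of == drug_id]
  per_disease <- lapply(disease_signatures, function(ds) {
    sc <- vapply(sigs, function(s) score_one(ds, s), 0)
    best <- sigs[[which.max(sc)]]
    shared <- intersect(ds$gene_universe, best$gene_universe)
    dn <- intersect(best$down, shared); up_d <- intersect(ds$up, shared)
    ov <- intersect(dn, up_d)
    up <- intersect(best$up, shared); dn_d <- intersect(ds$down, shared)
    ov2 <- intersect(up, dn_d)
    list(disease = ds$name, signature_id = best$signature_id,
         reversal_overlap_genes = sort(ov),
         k = length(ov), n_drug_down = length(dn),
         n_disease_up = length(up_d), N = length(shared),
         p_down_vs_up = hypergeometric_overlap_p(
           length(ov), length(dn), length(up_d), length(shared)),
         p_up_vs_down = if (length(up) > 0 && length(dn_d) > 0)
           hypergeometric_overlap_p(length(ov2), length(up),
                                    length(dn_d), length(shared))
         else NA_real_)
  })
  names(per_disease) <- vapply(disease_signatures, `[[`, "", "name")
  out <- list(drug_id = drug_id, per_disease = per_disease)
  if (!is.null(gene_sets)) {
    pooled <- sort(unique(unlist(lapply(per_disease,
                                        `[[`, "reversal_overlap_genes"))))
    universe <- sort(unique(unlist(lapply(disease_signatures,
                                          `[[`, "gene_universe"))))
    out$enrichment <- term_enrichment(pooled, gene_sets, universe)
  }
  out
}
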