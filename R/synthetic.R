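#' Configuration for the synthetic LINCS-like screen generator
#'
#' Bundles every knob of the synthetic-data module with validated
#' defaults. The defaults emulate a landmark-scale screen at desk size:
#' a 978-gene universe, 3 vs 3 replicate experiments with z-score-like
#' unit Gaussian noise and 2-SD planted mean shifts, a 300-drug x
#' 4-condition library hiding 5 planted reversal drugs whose down-sets
#' capture 30% of the disease up-genes (background drugs capture 2%), one
#' enriched mechanism-of-action class, and 10 high-BBB-permeability
#' compounds.
#'
#' @param n_genes gene universe size.
#' @param n_control,n_treatment replicates per experiment.
#' @param deg_fraction fraction of genes planted as DEGs per signature
#'   (each of up and down).
#' @param effect_size planted mean shift, in units of the noise SD.
#' @param noise i.i.d. Gaussian noise SD.
#' @param n_drugs,conditions_per_drug library shape.
#' @param n_planted_reversers drugs planted as strong reversers.
#' @param reversal_overlap fraction of each disease up-set present in a
#'   planted reverser's down-set (every condition).
#' @param partial_overlap same, for the partial reversers that fill out
#'   the planted MOA class (must lie between `background_overlap` and
#'   `reversal_overlap`).
#' @param background_overlap same, for background drugs.
#' @param disease_shared_fraction fraction of up (and down) genes shared
#'   by the two disease signatures.
#' @param n_moa_terms number of MOA classes including the planted one.
#' @param planted_moa_size size of the planted MOA class; its members are
#'   the planted reversers plus enough partial reversers to fill it.
#' @param n_bbb_high compounds planted with BBB probability in
#'   `[0.8, 1]`; all other compounds score in `[-1, 0.75]` so the planted
#'   set is identifiable.
#' @param seed integer seed; mandatory, drives every generation call.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 978, n_control = 3, n_treatment = 3,
                             deg_fraction = 0.05, effect_size = 2.0,
                             noise = 1.0, n_drugs = 300,
                             conditions_per_drug = 4,
                             n_planted_reversers = 5,
                             reversal_overlap = 0.3,
                             partial_overlap = 0.15,
                             background_overlap = 0.02,
                             disease_shared_fraction = 0.5,
                             n_moa_terms = 20, planted_moa_size = 10,
                             n_bbb_high = 10, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for any generation call")
  cfg <- list(n_genes = as.integer(n_genes),
              n_control = as.integer(n_control),
              n_treatment = as.integer(n_treatment),
              deg_fraction = deg_fraction, effect_size = effect_size,
              noise = noise, n_drugs = as.integer(n_drugs),
              conditions_per_drug = as.integer(conditions_per_drug),
              n_planted_reversers = as.integer(n_planted_reversers),
              reversal_overlap = reversal_overlap,
              partial_overlap = partial_overlap,
              background_overlap = background_overlap,
              disease_shared_fraction = disease_shared_fraction,
              n_moa_terms = as.integer(n_moa_terms),
              planted_moa_size = as.integer(planted_moa_size),
              n_bbb_high = as.integer(n_bbb_high),
              seed = as.integer(seed))
  fr <- c("deg_fraction", "reversal_overlap", "partial_overlap",
          "background_overlap", "disease_shared_fraction")
  for (f in fr)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]")
  cnt <- c("n_genes", "n_control", "n_treatment", "n_drugs",
           "conditions_per_drug", "n_planted_reversers", "n_moa_terms",
           "planted_moa_size", "n_bbb_high")
  for (f in cnt)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1)
      stop(f, " must be a positive count")
  if (cfg$effect_size < 0 || cfg$noise <= 0)
    stop("effect_size must be >= 0 and noise > 0")
  if (round(cfg$deg_fraction * cfg$n_genes) < 1)
    stop("deg_fraction x n_genes < 1: no DEGs can be planted")
  if (cfg$reversal_overlap <= cfg$background_overlap)
    stop("reversal_overlap must exceed background_overlap, ",
         "otherwise the planted signal is not identifiable")
  if (max(cfg$planted_moa_size, cfg$n_planted_reversers) > cfg$n_drugs)
    stop("too few drugs for the planted roles")
  if (cfg$n_bbb_high > cfg$n_drugs) stop("n_bbb_high exceeds n_drugs")
  if (cfg$planted_moa_size < cfg$n_planted_reversers)
    warning("planted_moa_size < n_planted_reversers: the planted MOA ",
            "class cannot contain every planted reverser")
  structure(cfg, class = "synthetic_config")
}

synthetic_genes <- function(config) {
  sprintf("G%04d", seq_len(config$n_genes))
}

#' Generate the pair of synthetic disease signatures
#'
#' Emulates a disease profiled twice (two CREEDS-style signatures from
#' related cell populations): two up-sets of `deg_fraction * n_genes`
#' genes sharing `disease_shared_fraction` of their members, plus
#' matching down-sets disjoint from both up-sets.
#'
#' @param config a [synthetic_config()].
#' @return list with `signatures` (two [disease_signature()]s) and
#'   `truth` (the planted sets).
#' @export
generate_disease_signature <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- synthetic_genes(config)
  n_deg <- round(config$deg_fraction * config$n_genes)
  n_shared <- round(config$disease_shared_fraction * n_deg)
  n_own <- n_deg - n_shared
  need <- 2 * (n_shared + 2 * n_own)
  if (need > config$n_genes)
    stop("gene universe too small for two disease signatures")
  perm <- sample(genes)
  take <- function(k) {
    if (k == 0) return(character(0))
    out <- perm[seq_len(k)]; perm <<- perm[-seq_len(k)]; out
  }
  up_shared <- take(n_shared)
  up1 <- c(up_shared, take(n_own)); up2 <- c(up_shared, take(n_own))
  dn_shared <- take(n_shared)
  dn1 <- c(dn_shared, take(n_own)); dn2 <- c(dn_shared, take(n_own))
  sigs <- list(
    disease_1 = disease_signature("disease_1", up1, dn1, genes),
    disease_2 = disease_signature("disease_2", up2, dn2, genes))
  list(signatures = sigs,
       truth = list(disease_up = list(disease_1 = up1, disease_2 = up2),
                    disease_down = list(disease_1 = dn1, disease_2 = dn2)))
}

# planted up/down DEG sets for one drug signature: the down-set captures
# `rho` of each disease up-set, the rest of both sets avoids disease
# up-genes so overlap is controlled exactly
plant_deg_sets <- function(genes, disease, rho, n_deg) {
  up_union <- unique(unlist(lapply(disease, `[[`, "up")))
  n_ov <- round(rho * n_deg)
  ov <- unique(unlist(lapply(disease, function(ds)
    sample(ds$up, min(n_ov, length(ds$up))))))
  pool <- setdiff(genes, c(up_union, ov))
  down <- c(ov, sample(pool, n_deg - length(ov)))
  up <- sample(setdiff(pool, down), n_deg)
  list(up = up, down = down)
}

#' Generate the synthetic drug signature library
#'
#' For each drug x condition, emits either a precomputed set-only
#' signature (`mode = "sets"`, mirroring libraries distributed as GMT
#' pairs) or a replicated treatment/control expression experiment
#' (`mode = "expression"`, mirroring level-4-like z-score profiles) in
#' which the planted DEG sets appear as mean shifts of
#' `effect_size * noise` over i.i.d. Gaussian noise. Planted reversal
#' drugs capture `reversal_overlap` of each disease up-set in the
#' down-set of every one of their conditions; partial reversers capture
#' `partial_overlap`; background drugs `background_overlap`.
#'
#' @param config a [synthetic_config()].
#' @param disease output of [generate_disease_signature()].
#' @param mode `"sets"` or `"expression"`.
#' @return list with `mode`, `metadata` (signature metadata data.frame),
#'   `truth` (per-drug role and planted MOA/BBB-relevant ids), and either
#'   `signatures` (named list of [perturbation_signature()]) or `experiments` (named
#'   list of [expression_experiment()]).
#' @export
generate_drug_library <- function(config, disease,
                                  mode = c("sets", "expression")) {
  stopifnot(inherits(config, "synthetic_config"))
  mode <- match.arg(mode)
  if (config$partial_overlap <= config$background_overlap ||
      config$partial_overlap >= config$reversal_overlap)
    stop("partial_overlap must lie strictly between background_overlap ",
         "and reversal_overlap")
  set.seed(config$seed + 1L)
  genes <- synthetic_genes(config)
  n_deg <- round(config$deg_fraction * config$n_genes)
  drugs <- sprintf("drug%03d", seq_len(config$n_drugs))
  n_partial <- max(0L, config$planted_moa_size - config$n_planted_reversers)
  special <- sample(drugs, config$n_planted_reversers + n_partial)
  reversers <- special[seq_len(config$n_planted_reversers)]
  partials <- setdiff(special, reversers)
  role <- stats::setNames(rep("background", config$n_drugs), drugs)
  role[reversers] <- "reverser"; role[partials] <- "partial"
  rho_of <- c(reverser = config$reversal_overlap,
              partial = config$partial_overlap,
              background = config$background_overlap)
  n_ctl <- config$n_control; n_trt <- config$n_treatment
  sample_ids <- c(paste0("ctl_", seq_len(n_ctl)),
                  paste0("trt_", seq_len(n_trt)))
  classes <- c(rep("control", n_ctl), rep("treatment", n_trt))
  shift <- config$effect_size * config$noise
  sig_ids <- c(); meta_rows <- list(); items <- list()
  for (dr in drugs) {
    for (j in seq_len(config$conditions_per_drug)) {
      sid <- sprintf("%s_c%02d", dr, j)
      sets <- plant_deg_sets(genes, disease$signatures, rho_of[[role[[dr]]]],
                             n_deg)
      if (mode == "sets") {
        items[[sid]] <- perturbation_signature(
          sid, dr, sets$up, sets$down, genes,
          cell_line = paste0("CL", 1 + (j - 1) %% 4),
          dose = c("1uM", "10uM")[1 + (j - 1) %% 2], time = "24h")
      } else {
        m <- matrix(stats::rnorm(config$n_genes * (n_ctl + n_trt),
                                 sd = config$noise),
                    nrow = config$n_genes,
                    dimnames = list(genes, sample_ids))
        trt_cols <- which(classes == "treatment")
        m[sets$up, trt_cols] <- m[sets$up, trt_cols] + shift
        m[sets$down, trt_cols] <- m[sets$down, trt_cols] - shift
        items[[sid]] <- expression_experiment(m, classes)
      }
      sig_ids <- c(sig_ids, sid)
      meta_rows[[sid]] <- data.frame(
        signature_id = sid, drug_id = dr,
        cell_line = paste0("CL", 1 + (j - 1) %% 4),
        dose = c("1uM", "10uM")[1 + (j - 1) %% 2], time = "24h",
        stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta_rows[sig_ids])
  rownames(metadata) <- NULL
  truth <- list(role = role, reversers = sort(reversers),
                partial_reversers = sort(partials))
  out <- list(mode = mode, metadata = metadata, truth = truth)
  if (mode == "sets") out$signatures <- items else out$experiments <- items
  out
}

#' Generate MOA and BBB annotation tables with planted structure
#'
#' The planted MOA class contains every planted reverser and partial
#' reverser (plus random background drugs if `planted_moa_size` is
#' larger); all other drugs are assigned uniformly to the remaining
#' classes. BBB-high compounds (default: the planted reversers and
#' partial reversers, i.e. the drugs expected to survive the reversal
#' top-k) score uniformly in `[0.8, 1]`; every other compound scores in
#' `[-1, 0.75]`, keeping the planted set identifiable by construction.
#'
#' @param config a [synthetic_config()].
#' @param truth the `truth` element of [generate_drug_library()] output.
#' @return list with `moa` (data.frame `drug_id`, `moa`), `bbb`
#'   (data.frame `compound_id`, `bbb_probability`), and `truth` fragment
#'   (`planted_moa`, `moa_members`, `bbb_high`).
#' @export
generate_annotations <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  drugs <- names(truth$role)
  planted <- c(truth$reversers, truth$partial_reversers)
  if (config$planted_moa_size > length(planted)) {
    extra <- sample(setdiff(drugs, planted),
                    config$planted_moa_size - length(planted))
    planted <- c(planted, extra)
  } else if (config$planted_moa_size < length(truth$reversers)) {
    warning("planted MOA class smaller than the planted reverser count")
  }
  other_terms <- sprintf("moa_%02d", seq_len(config$n_moa_terms - 1L))
  moa <- stats::setNames(rep(NA_character_, length(drugs)), drugs)
  moa[planted] <- "planted_moa"
  rest <- setdiff(drugs, planted)
  moa[rest] <- sample(other_terms, length(rest), replace = TRUE)
  bbb_high <- c(truth$reversers, truth$partial_reversers)
  if (config$n_bbb_high <= length(bbb_high)) {
    bbb_high <- bbb_high[seq_len(config$n_bbb_high)]
  } else {
    bbb_high <- c(bbb_high,
                  sample(setdiff(drugs, bbb_high),
                         config$n_bbb_high - length(bbb_high)))
  }
  bbb <- stats::setNames(stats::runif(length(drugs), -1, 0.75), drugs)
  bbb[bbb_high] <- stats::runif(length(bbb_high), 0.8, 1.0)
  list(moa = data.frame(drug_id = drugs, moa = unname(moa),
                        stringsAsFactors = FALSE),
       bbb = data.frame(compound_id = drugs,
                        bbb_probability = unname(bbb),
                        stringsAsFactors = FALSE),
       truth = list(planted_moa = "planted_moa",
                    moa_members = sort(planted),
                    bbb_high = sort(bbb_high)))
}

#' Generate a complete in-memory synthetic screen input bundle
#'
#' Runs the three generators in sequence under the config's seed and
#' returns everything the pipeline needs: the disease signature pair, the
#' drug library (set-only signatures or expression experiments plus
#' metadata), MOA and BBB tables, and the merged ground truth.
#'
#' @param config a [synthetic_config()].
#' @param mode library emission mode, `"sets"` or `"expression"`.
#' @return list with `disease`, `library`, `annotations`, `truth`.
#' @export
generate_screen_inputs <- function(config, mode = c("sets", "expression")) {
  mode <- match.arg(mode)
  disease <- generate_disease_signature(config)
  lib <- generate_drug_library(config, disease, mode = mode)
  ann <- generate_annotations(config, lib$truth)
  list(disease = disease$signatures, library = lib,
       annotations = ann[c("moa", "bbb")],
       truth = c(disease$truth, lib$truth, ann$truth))
}

#' Write a synthetic screen input bundle to disk
#'
#' Emits the disease up/down GMT pair, the library (up/down GMT pair for
#' set mode, or one GCT plus class sidecar per experiment for expression
#' mode), the signature metadata TSV, the MOA and BBB TSVs, and the
#' ground-truth JSON. Byte-identical across runs with the same config.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @param mode `"sets"` or `"expression"`.
#' @return invisibly, the in-memory bundle (see
#'   [generate_screen_inputs()]).
#' @export
write_screen_inputs <- function(config, dir, mode = c("sets", "expression")) {
  mode <- match.arg(mode)
  bundle <- generate_screen_inputs(config, mode = mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gmt(lapply(bundle$disease, `[[`, "up"),
            file.path(dir, "disease_up.gmt"))
  write_gmt(lapply(bundle$disease, `[[`, "down"),
            file.path(dir, "disease_down.gmt"))
  if (mode == "sets") {
    write_signature_library(bundle$library$signatures,
                            file.path(dir, "library_up.gmt"),
                            file.path(dir, "library_down.gmt"),
                            file.path(dir, "metadata.tsv"))
  } else {
    expdir <- file.path(dir, "experiments")
    dir.create(expdir, showWarnings = FALSE)
    for (sid in names(bundle$library$experiments)) {
      ee <- bundle$library$experiments[[sid]]
      write_gct(ee, file.path(expdir, paste0(sid, ".gct")))
      write_tsv(data.frame(sample_id = ee$sample_ids,
                           class = ee$sample_class),
                file.path(expdir, paste0(sid, ".classes.tsv")))
    }
    write_tsv(bundle$library$metadata, file.path(dir, "metadata.tsv"))
  }
  write_tsv(bundle$annotations$moa, file.path(dir, "moa.tsv"))
  write_tsv(bundle$annotations$bbb, file.path(dir, "bbb.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "ground_truth.json"))
  invisible(bundle)
}
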