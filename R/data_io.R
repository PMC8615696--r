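#' Read an expression matrix from a GCT file
#'
#' Parses the GCT 1.2 and 1.3 text dialects. For 1.3 files any extra row or
#' column annotations are parsed past but discarded: only the gene ids and
#' the numeric matrix are retained. Sample class labels are not part of GCT
#' and come from an explicit sidecar table (see [read_sample_classes()]);
#' when `class_file` is given the result is a validated
#' [expression_experiment()], otherwise a bare named matrix is returned.
#'
#' @param path path to a GCT file.
#' @param class_file optional path to a two-column TSV (`sample_id`,
#'   `class`) assigning each sample to `control` or `treatment`.
#' @return an `expression_experiment` if `class_file` is given, else the
#'   numeric matrix with gene ids as rownames.
#' @export
read_gct <- function(path, class_file = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("malformed GCT (line 1): fewer than 3 lines in ", path)
  version <- trimws(lines[1])
  if (!version %in% c("#1.2", "#1.3"))
    stop("malformed GCT (line 1): unsupported version tag '", version, "'")
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if ((version == "#1.2" && length(dims) != 2) ||
      (version == "#1.3" && length(dims) != 4))
    stop("malformed GCT (line 2): expected ",
         if (version == "#1.2") 2 else 4, " dimension fields")
  dims <- suppressWarnings(as.integer(dims))
  if (anyNA(dims)) stop("malformed GCT (line 2): non-integer dimensions")
  nr <- dims[1]; nc <- dims[2]
  n_rmeta <- if (version == "#1.3") dims[3] else 1L  # 1.2 has Description col
  n_cmeta <- if (version == "#1.3") dims[4] else 0L
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  expected_cols <- 1L + n_rmeta + nc
  if (length(header) != expected_cols)
    stop("malformed GCT (line 3): ", length(header),
         " header fields, expected ", expected_cols)
  sample_ids <- header[(2L + n_rmeta):expected_cols]
  data_start <- 4L + n_cmeta
  data_lines <- lines[seq.int(data_start, length.out = length(lines) - data_start + 1L)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) != nr)
    stop("malformed GCT: declared ", nr, " data rows but found ",
         length(data_lines), " (line ", data_start, " onward)")
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != expected_cols)
  if (length(bad) > 0)
    stop("malformed GCT (line ", data_start + bad[1] - 1L, "): ",
         nf[bad[1]], " fields, expected ", expected_cols)
  gene_ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- vapply(fields,
                 function(f) as.numeric(f[(2L + n_rmeta):expected_cols]),
                 numeric(nc))
  values <- if (nc == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (!all(is.finite(values)))
    stop("non-finite expression values in ", path)
  dimnames(values) <- list(gene_ids, sample_ids)
  if (is.null(class_file)) return(values)
  cls <- read_sample_classes(class_file)
  expression_experiment(values, cls)
}

#' Write an expression experiment (or matrix) as GCT 1.2
#'
#' @param x an `expression_experiment` or a named numeric matrix.
#' @param path output path.
#' @param digits significant digits for the values (default keeps full
#'   double precision via `format`'s 15 digits).
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path, digits = 15) {
  if (inherits(x, "expression_experiment")) {
    validate_experiment(x)
    m <- x$values
  } else if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("matrix must have row and column names")
    m <- x
  } else stop("`x` must be an expression_experiment or a numeric matrix")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], "na",
            format(m[i, ], digits = digits, trim = TRUE, scientific = FALSE)),
          collapse = "\t"), "")
  writeLines(body, con)
  invisible(path)
}

#' Read a sample-class sidecar table
#'
#' @param path TSV with header columns `sample_id` and `class`; `class`
#'   must be `control` or `treatment`.
#' @return named character vector of classes, names = sample ids.
#' @export
read_sample_classes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(df)))
    stop("class file must have columns 'sample_id' and 'class': ", path)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in ", path)
  stats::setNames(df$class, df$sample_id)
}

#' Read a GMT gene-set library
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' Members are deduplicated (first occurrence kept); the order of entries
#' is preserved.
#'
#' @param path GMT file path.
#' @return a `gene_set_library`: named list of character vectors of member
#'   ids, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- structure(list(), descriptions = character(0),
                     class = "gene_set_library")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad) > 0)
    stop("malformed GMT (line ", bad[1], "): ", nf[bad[1]],
         " fields, need at least 3 (name, description, >=1 member)")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicated set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  structure(sets,
            descriptions = stats::setNames(vapply(fields, `[[`, "", 2L), nm),
            class = "gene_set_library")
}

#' Write a GMT gene-set library
#'
#' @param sets named list of character vectors (or a `gene_set_library`).
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions;
#'   defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("`sets` must be a uniquely named list")
  if (any(lengths(sets) == 0)) stop("empty gene sets cannot be written")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], unique(sets[[i]])),
          collapse = "\t"), "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a compound score table (e.g. BBB permeability probabilities)
#'
#' Reads a TSV with a header and returns a named numeric vector mapping
#' compound ids to scores. With `range` given (e.g. `c(-1, 1)` for
#' admetSAR-style blood-brain-barrier probabilities) any out-of-range
#' score is an error.
#'
#' @param path TSV path.
#' @param id_column,score_column column names holding compound ids and
#'   numeric scores.
#' @param range optional length-2 numeric: allowed closed interval.
#' @return named numeric vector.
#' @export
read_score_table <- function(path, id_column = "compound_id",
                             score_column = "score", range = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c(id_column, score_column))
    if (!col %in% names(df))
      stop("missing column '", col, "' in ", path,
           " (found: ", paste(names(df), collapse = ", "), ")")
  ids <- as.character(df[[id_column]])
  scores <- as.numeric(df[[score_column]])
  if (anyDuplicated(ids))
    stop("duplicated compound ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!all(is.finite(scores))) stop("non-finite scores in ", path)
  if (!is.null(range)) {
    out <- scores < range[1] | scores > range[2]
    if (any(out))
      stop("scores outside [", range[1], ", ", range[2], "] in ", path,
           " for: ", paste(ids[out], collapse = ", "))
  }
  stats::setNames(scores, ids)
}

#' Read a signature metadata table
#'
#' @param path TSV with header columns `signature_id`, `drug_id`,
#'   `cell_line`, `dose`, `time`.
#' @return data.frame with those columns; `signature_id` unique.
#' @export
read_signature_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("signature_id", "drug_id", "cell_line", "dose", "time")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("metadata table missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$signature_id))
    stop("duplicated signature_id in ", path)
  df[need]
}

#' Write a data.frame as a deterministic UTF-8 TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
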