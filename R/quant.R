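#' Protein-by-sample quantification matrix with sample metadata
#'
#' The central data container of the pipeline: a numeric matrix of positive
#' reporter intensities (proteins in rows, samples in columns) together
#' with per-sample design metadata. Mirrors the matrix + column-data
#' convention of expression-analysis containers, kept as a light list so
#' tables round-trip through plain TSV.
#'
#' @param values Numeric matrix, proteins x samples, with dimnames; all
#'   non-missing values must be positive.
#' @param meta Data frame with one row per sample column, columns
#'   `sample_id`, `condition` ("drug" or "vehicle"), `time_h`, `conc_M`,
#'   `replicate`, and optionally `pooled` (logical) and `channel`.
#' @param truth Optional list of simulation ground truth, carried along
#'   untouched.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, meta, truth = NULL) {
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(meta))
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("'values' must carry protein rownames and sample colnames")
  req <- c("sample_id", "condition", "time_h", "conc_M", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(meta$condition %in% c("drug", "vehicle")))
    stop("'condition' must be 'drug' or 'vehicle'")
  if (nrow(meta) != ncol(values) ||
      !identical(as.character(meta$sample_id),
                 as.character(colnames(values))))
    stop("metadata rows must match the sample columns of 'values' in order")
  if (any(values[!is.na(values)] <= 0))
    stop("all non-missing intensities must be positive")
  if (is.null(meta$pooled)) meta$pooled <- FALSE
  if (is.null(meta$channel)) meta$channel <- NA_character_
  structure(list(values = values, meta = meta, truth = truth),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %d proteins x %d samples (%d drug, %d vehicle)\n",
              nrow(x$values), ncol(x$values),
              sum(x$meta$condition == "drug"),
              sum(x$meta$condition == "vehicle")))
  if (!is.null(x$truth)) cat("  simulation ground truth attached\n")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Keep only proteins quantified in every sample
#'
#' Complete-case filtering: drops every protein with at least one missing
#' intensity, the convention used for multiplexed PISA tables.
#'
#' @param qm A [quant_matrix()].
#' @return A [quant_matrix()] restricted to fully quantified proteins.
#' @export
complete_cases <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  keep <- stats::complete.cases(qm$values)
  quant_matrix(qm$values[keep, , drop = FALSE], qm$meta, truth = qm$truth)
}

#' Write / read a quantification matrix as TSV
#'
#' `write_quant_matrix()` writes two files: `<stem>_intensities.tsv`
#' (protein column + one column per sample) and `<stem>_samples.tsv` (the
#' sample metadata). `read_quant_matrix()` reads them back.
#'
#' @param qm A [quant_matrix()].
#' @param stem Path stem (without suffix) for the two TSV files.
#' @return `write_quant_matrix()` returns the two paths invisibly;
#'   `read_quant_matrix()` returns a [quant_matrix()].
#' @export
write_quant_matrix <- function(qm, stem) {
  stopifnot(inherits(qm, "quant_matrix"))
  vp <- paste0(stem, "_intensities.tsv")
  mp <- paste0(stem, "_samples.tsv")
  df <- data.frame(protein = rownames(qm$values), qm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, vp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qm$meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(intensities = vp, samples = mp))
}

#' @rdname write_quant_matrix
#' @export
read_quant_matrix <- function(stem) {
  vp <- paste0(stem, "_intensities.tsv")
  mp <- paste0(stem, "_samples.tsv")
  df <- utils::read.delim(vp, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(mp, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$protein
  quant_matrix(values, meta)
}
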