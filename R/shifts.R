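#' Normalize drug-treated samples to their matched vehicle controls
#'
#' Each drug-treated sample is divided, protein by protein, by the
#' vehicle-treated sample at the same time point with the same replicate
#' index. When the vehicle samples form a single group (as in compressed
#' designs with one shared vehicle set), matching falls back to the
#' replicate index alone. Because any shared degradation multiplier
#' `g(t)` hits drug and vehicle alike, it cancels from every fold change.
#'
#' @param qm A [quant_matrix()] without missing values (apply
#'   [complete_cases()] first, or pass `allow_missing = TRUE` to propagate
#'   `NA` fold changes).
#' @param allow_missing Keep proteins with missing values and propagate
#'   `NA`s instead of rejecting them.
#' @return Data frame with one row per (protein, drug sample):
#'   `protein`, `sample_id`, `time_h`, `conc_M`, `pooled`, `replicate`,
#'   `drug`, `vehicle`, `fc` (linear fold change drug/vehicle) and
#'   `log2fc`.
#' @export
normalize_to_vehicle <- function(qm, allow_missing = FALSE) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (!allow_missing && anyNA(qm$values))
    stop("matrix contains missing values; run complete_cases() first or ",
         "set allow_missing = TRUE")
  meta <- qm$meta
  drug <- meta[meta$condition == "drug", , drop = FALSE]
  veh <- meta[meta$condition == "vehicle", , drop = FALSE]
  if (nrow(veh) == 0L) stop("no vehicle samples in the matrix")
  one_veh_group <- length(unique(veh$time_h)) == 1L

  partner <- character(nrow(drug))
  for (j in seq_len(nrow(drug))) {
    cand <- veh[!is.na(veh$time_h) & !is.na(drug$time_h[j]) &
                  veh$time_h == drug$time_h[j] &
                  veh$replicate == drug$replicate[j], , drop = FALSE]
    if (nrow(cand) == 0L && (one_veh_group || is.na(drug$time_h[j])))
      cand <- veh[veh$replicate == drug$replicate[j], , drop = FALSE]
    if (nrow(cand) == 0L)
      stop(sprintf("no vehicle partner for drug sample at time %s, replicate %s",
                   format(drug$time_h[j]), format(drug$replicate[j])))
    partner[j] <- cand$sample_id[1L]
  }

  prot <- rownames(qm$values)
  out <- do.call(rbind, lapply(seq_len(nrow(drug)), function(j) {
    dv <- qm$values[, drug$sample_id[j]]
    vv <- qm$values[, partner[j]]
    data.frame(protein = prot, sample_id = drug$sample_id[j],
               vehicle_sample = partner[j],
               time_h = drug$time_h[j], conc_M = drug$conc_M[j],
               pooled = drug$pooled[j], replicate = drug$replicate[j],
               drug = dv, vehicle = vv, fc = dv / vv,
               log2fc = log2(dv / vv),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Correct intact-cell PISA intensities for protein expression changes
#'
#' Divides each PISA intensity by the matched expression-proteomics
#' intensity of the same protein (matched by condition, time point and
#' replicate; by condition and time point when the expression table has no
#' replicate structure) before vehicle normalization, so expression drift
#' over the washout is not mistaken for a solubility change. Proteins with
#' a zero or missing expression value are flagged and excluded at that
#' sample (set to `NA`); the run continues.
#'
#' @param cell_qm PISA [quant_matrix()] from intact cells.
#' @param expression_qm Matched expression-proteomics [quant_matrix()]
#'   covering the same proteins and time points.
#' @return A [quant_matrix()] of expression-corrected intensities; the
#'   attribute `"excluded"` lists (protein, sample) pairs dropped for zero
#'   or missing expression.
#' @export
normalize_expression <- function(cell_qm, expression_qm) {
  stopifnot(inherits(cell_qm, "quant_matrix"),
            inherits(expression_qm, "quant_matrix"))
  missing_prot <- setdiff(rownames(cell_qm$values),
                          rownames(expression_qm$values))
  if (length(missing_prot))
    stop("expression matrix lacks protein(s): ",
         paste(utils::head(missing_prot, 5), collapse = ", "))
  em <- expression_qm$meta
  key <- function(m) paste(m$condition, m$time_h, m$replicate, sep = "|")
  ekey <- key(em)
  ckey <- key(cell_qm$meta)
  j_expr <- match(ckey, ekey)
  if (anyNA(j_expr)) {                 # fall back: no replicate structure
    ekey2 <- paste(em$condition, em$time_h, sep = "|")
    ckey2 <- paste(cell_qm$meta$condition, cell_qm$meta$time_h, sep = "|")
    j_expr <- ifelse(is.na(j_expr), match(ckey2, ekey2), j_expr)
  }
  if (anyNA(j_expr))
    stop("expression matrix does not cover all (condition, time) groups")

  evals <- expression_qm$values[rownames(cell_qm$values), j_expr, drop = FALSE]
  bad <- is.na(evals) | evals == 0
  evals[bad] <- NA_real_
  corrected <- cell_qm$values / evals
  excluded <- which(bad, arr.ind = TRUE)
  excl_df <- data.frame(
    protein = rownames(cell_qm$values)[excluded[, 1L]],
    sample_id = cell_qm$meta$sample_id[excluded[, 2L]],
    stringsAsFactors = FALSE)
  out <- quant_matrix(corrected, cell_qm$meta, truth = cell_qm$truth)
  attr(out, "excluded") <- excl_df
  out
}

#' Equal-variance two-sample t-test for a solubility shift
#'
#' Pooled-variance two-tailed t-test on log2 intensities, the test used to
#' call drug-induced solubility alterations. Degenerate input with zero
#' pooled variance returns `p = 1` when the group means are equal (no
#' evidence either way, by convention) and `p = 0` otherwise.
#'
#' @param drug_values Log2 intensities of the drug-treated group (>= 2).
#' @param vehicle_values Log2 intensities of the vehicle group (>= 2).
#' @return List with `t_statistic`, `df` and `p_value`.
#' @export
#' @examples
#' test_shift(c(1.0, 1.1, 0.9), c(0.0, 0.1, -0.1))
test_shift <- function(drug_values, vehicle_values) {
  if (length(drug_values) < 2L || length(vehicle_values) < 2L)
    stop("both groups need at least 2 values")
  n1 <- length(drug_values); n2 <- length(vehicle_values)
  sp2 <- ((n1 - 1) * stats::var(drug_values) +
            (n2 - 1) * stats::var(vehicle_values)) / (n1 + n2 - 2)
  dm <- mean(drug_values) - mean(vehicle_values)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    if (dm == 0) return(list(t_statistic = 0, df = df, p_value = 1))
    return(list(t_statistic = sign(dm) * Inf, df = df, p_value = 0))
  }
  tt <- stats::t.test(drug_values, vehicle_values, var.equal = TRUE)
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

# Vectorized pooled t-test across matrix rows (drug vs vehicle columns of
# a log2 matrix); same statistic as test_shift, computed row-wise.
.row_ttest <- function(x_drug, x_veh) {
  n1 <- ncol(x_drug); n2 <- ncol(x_veh)
  m1 <- rowMeans(x_drug); m2 <- rowMeans(x_veh)
  v1 <- rowSums((x_drug - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_veh - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- sp2 == 0
  tt[zero] <- ifelse(m1[zero] == m2[zero], 0, sign(m1 - m2)[zero] * Inf)
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  list(t = tt, df = df, p = p)
}

#' Per-protein solubility-shift table
#'
#' For each protein and each drug-sample group (a washout time point, a
#' drug concentration, or a pooled compressed sample) this computes the
#' mean log2 fold change over vehicle and an equal-variance two-tailed
#' t-test of the log2 drug intensities against the log2 vehicle
#' intensities. Benjamini-Hochberg q-values are added per group as an
#' extra column; hit calling itself thresholds the raw p-values.
#'
#' @param qm A [quant_matrix()].
#' @param allow_missing Passed to [normalize_to_vehicle()].
#' @return Data frame of class `shift_table`: `protein`, `time_h`,
#'   `conc_M`, `pooled`, `log2fc` (mean over replicates), `fc_mean` (mean
#'   linear fold change), `t_statistic`, `p_value`, `q_value`, `n_drug`,
#'   `n_vehicle`. Per-replicate fold changes are attached as attribute
#'   `"replicate_fc"` (the [normalize_to_vehicle()] table).
#' @export
compute_shifts <- function(qm, allow_missing = FALSE) {
  stopifnot(inherits(qm, "quant_matrix"))
  fc <- normalize_to_vehicle(qm, allow_missing = allow_missing)
  meta <- qm$meta
  gkey <- function(m) paste(ifelse(m$pooled, "pooled", "single"),
                            format(m$time_h), format(m$conc_M), sep = "|")
  drug_meta <- meta[meta$condition == "drug", , drop = FALSE]
  groups <- unique(gkey(drug_meta))
  l2 <- log2(qm$values)

  res <- lapply(groups, function(g) {
    dcols <- drug_meta$sample_id[gkey(drug_meta) == g]
    grp <- fc[fc$sample_id %in% dcols, , drop = FALSE]
    vcols <- unique(grp$vehicle_sample)
    tt <- .row_ttest(l2[, dcols, drop = FALSE], l2[, vcols, drop = FALSE])
    agg_fc <- tapply(grp$fc, grp$protein, mean)
    agg_l2 <- tapply(grp$log2fc, grp$protein, mean)
    prot <- rownames(qm$values)
    data.frame(protein = prot,
               time_h = drug_meta$time_h[match(dcols[1L], drug_meta$sample_id)],
               conc_M = drug_meta$conc_M[match(dcols[1L], drug_meta$sample_id)],
               pooled = drug_meta$pooled[match(dcols[1L], drug_meta$sample_id)],
               log2fc = as.numeric(agg_l2[prot]),
               fc_mean = as.numeric(agg_fc[prot]),
               t_statistic = tt$t, p_value = tt$p,
               q_value = stats::p.adjust(tt$p, method = "BH"),
               n_drug = length(dcols), n_vehicle = length(vcols),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "replicate_fc") <- fc
  class(out) <- c("shift_table", class(out))
  out
}

#' Call significantly solubility-shifted proteins
#'
#' A protein is a hit at a given condition when its absolute log2 fold
#' change is at least `lfc_min` and its p-value is strictly below `p_max`.
#' The fold-change threshold is inclusive, the p-value threshold exclusive.
#'
#' @param table A `shift_table` from [compute_shifts()] (any data frame
#'   with `log2fc` and `p_value` columns works).
#' @param lfc_min Minimal absolute log2 fold change (default 0.3).
#' @param p_max Exclusive p-value ceiling (default 0.05).
#' @return The input with logical column `hit` and integer column
#'   `direction` (+1 stabilized, -1 destabilized, 0 for non-hits with zero
#'   fold change).
#' @export
call_hits <- function(table, lfc_min = 0.3, p_max = 0.05) {
  stopifnot(lfc_min > 0, p_max >= 0,
            all(c("log2fc", "p_value") %in% names(table)))
  table$hit <- abs(table$log2fc) >= lfc_min & table$p_value < p_max
  table$direction <- sign(table$log2fc)
  table
}
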