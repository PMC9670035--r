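#' Configuration of an end-to-end pipeline run
#'
#' Collects every tunable of the pipeline with its default: the 20 ppm
#' reporter extraction window, the hit thresholds (|log2fc| >= 0.3,
#' p < 0.05), the 0.6 model-routing threshold, and the 3x replicate-sd
#' noise filter. Serializable to YAML via [write_pipeline_config()].
#'
#' @param n_proteins Number of simulated proteins.
#' @param frac_targets Fraction of simulated proteins that are true
#'   targets.
#' @param noise_cv Lognormal noise CV of the simulation.
#' @param seed Integer seed; all randomness in a run flows from it.
#' @param time_points,concentrations,n_replicates Passed to
#'   [experiment_design()].
#' @param tol_ppm Reporter extraction window (ppm).
#' @param lfc_min,p_max Hit-calling thresholds, see [call_hits()].
#' @param model_threshold Off-curve model-routing threshold, see
#'   [select_model()].
#' @param sd_multiplier Replicate-noise filter multiplier, see
#'   [filter_targets()].
#' @param sd_rule Noise-filter reading, see [filter_targets()].
#' @param auc_method `"sum"` or `"trapezoid"`, see [compute_auc()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("kinetics", "score")`; simulation and shift testing always run.
#' @param degradation Optional shared degradation function `g(t)`.
#' @param out_dir Optional directory; when set, all stage tables and a run
#'   manifest are written there as TSV/JSON.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_proteins = 100, frac_targets = 0.3,
                            noise_cv = 0.05, seed = 1L,
                            time_points = c(0, 1.5, 3, 7, 24),
                            concentrations = c(2e-6, 2e-7, 2e-8, 2e-9,
                                               2e-10, 2e-11, 2e-12),
                            n_replicates = 3,
                            tol_ppm = 20, lfc_min = 0.3, p_max = 0.05,
                            model_threshold = 0.6, sd_multiplier = 3,
                            sd_rule = "per_protein",
                            auc_method = "sum",
                            stages = c("kinetics", "score"),
                            degradation = NULL,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(all(stages %in% c("kinetics", "score")))
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()] (functions such as `degradation`
#'   are not serialized).
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ser <- config[!vapply(config, is.function, logical(1))]
  ser <- ser[!vapply(ser, is.null, logical(1))]
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# ---- internal stage helpers -------------------------------------------

# Reference-condition summary per protein from a replicate fc table:
# mean/sd of the log2 fold change at the reference (T0 or max conc) plus
# the mean linear fold change used for scaling.
.ref_summary <- function(fc, ref_rows) {
  sub <- fc[ref_rows, , drop = FALSE]
  data.frame(
    protein = sort(unique(sub$protein)),
    mean_ref = as.numeric(tapply(sub$log2fc, sub$protein, mean)),
    sd_ref = as.numeric(tapply(sub$log2fc, sub$protein, stats::sd)),
    fc_ref_mean = as.numeric(tapply(sub$fc, sub$protein, mean)),
    stringsAsFactors = FALSE, row.names = NULL)
}

# Scale the pooled compressed readout of every protein that carries a
# measurable reference shift; proteins without one come back NA.
.scaled_pooled <- function(fc, ref, epsilon = 1e-6) {
  pooled <- fc[fc$pooled, , drop = FALSE]
  pooled_mean <- tapply(pooled$fc, pooled$protein, mean)
  idx <- match(ref$protein, names(pooled_mean))
  out <- rep(NA_real_, nrow(ref))
  for (i in seq_len(nrow(ref))) {
    if (is.na(idx[i])) next
    if (abs(ref$fc_ref_mean[i] - 1) <= epsilon) next
    out[i] <- scale_compressed(as.numeric(pooled_mean[idx[i]]),
                               ref$fc_ref_mean[i], epsilon)
  }
  out
}

#' Run the full pipeline on a simulated experiment
#'
#' Simulates an off-curve experiment plus compressed cResT-PISA and
#' conc-PISA experiments over one shared target panel, then runs shift
#' testing, hit calling, off-curve kinetics for the T0 hits, and combined
#' target scoring on the compressed readouts. Deterministic given the
#' config seed. When `config$out_dir` is set, every stage table is
#' written there as TSV together with a JSON manifest recording the
#' package version, the configuration and per-stage row counts.
#'
#' @param config A [pipeline_config()].
#' @param panel Optional named list of [binding_params()] to use instead of
#'   drawing a random panel; overrides `config$n_proteins`.
#' @return List of class `pipeline_result` with elements `panel` (true
#'   parameters), `offcurve`, `crest`, `conc` (quant matrices), `shifts`,
#'   `hits`, `kinetics`, `targets`, `scores`, `removed`, and `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(n_proteins = 40, seed = 7))
#' head(res$scores)
#' }
run_pipeline <- function(config, panel = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(panel))
    panel <- simulate_target_panel(config$n_proteins,
                                   frac_targets = config$frac_targets,
                                   seed = config$seed)
  design <- experiment_design(time_points = config$time_points,
                              concentrations = config$concentrations,
                              n_replicates = config$n_replicates,
                              noise_cv = config$noise_cv,
                              degradation = config$degradation,
                              seed = config$seed)

  off_qm <- simulate_offcurve_experiment(panel, design)
  crest_qm <- simulate_compressed_rest(panel, design)
  conc_qm <- simulate_concpisa(panel, design)

  shifts <- compute_shifts(off_qm)
  shifts <- call_hits(shifts, lfc_min = config$lfc_min, p_max = config$p_max)
  fc_off <- attr(shifts, "replicate_fc")
  t0 <- shifts[shifts$time_h == 0 & !shifts$pooled, , drop = FALSE]
  hit_proteins <- t0$protein[t0$hit]

  kin <- NULL
  if ("kinetics" %in% config$stages && length(hit_proteins)) {
    kin <- fit_kinetics(fc_off, proteins = hit_proteins,
                        threshold = config$model_threshold,
                        auc_method = config$auc_method)
  }

  targets <- scores <- removed <- NULL
  if ("score" %in% config$stages) {
    crest_shift <- call_hits(compute_shifts(crest_qm),
                             lfc_min = config$lfc_min, p_max = config$p_max)
    conc_shift <- call_hits(compute_shifts(conc_qm),
                            lfc_min = config$lfc_min, p_max = config$p_max)
    fc_crest <- attr(crest_shift, "replicate_fc")
    fc_conc <- attr(conc_shift, "replicate_fc")

    # gate: significant at T0 (cResT) or the maximal concentration (conc)
    crest_ref <- crest_shift[!crest_shift$pooled, , drop = FALSE]
    conc_single <- conc_shift[!conc_shift$pooled, , drop = FALSE]
    max_conc <- max(conc_single$conc_M, na.rm = TRUE)
    conc_ref <- conc_single[!is.na(conc_single$conc_M) &
                              conc_single$conc_M == max_conc, , drop = FALSE]
    sig <- intersect(crest_ref$protein[crest_ref$hit],
                     conc_ref$protein[conc_ref$hit])

    if (length(sig)) {
      ref_crest <- .ref_summary(fc_crest, !fc_crest$pooled &
                                  fc_crest$protein %in% sig)
      ref_conc <- .ref_summary(
        fc_conc, !fc_conc$pooled & !is.na(fc_conc$conc_M) &
          fc_conc$conc_M == max_conc & fc_conc$protein %in% sig)
      crest_scaled <- .scaled_pooled(fc_crest, ref_crest)
      conc_scaled <- .scaled_pooled(fc_conc, ref_conc)
      stopifnot(identical(ref_crest$protein, ref_conc$protein))
      targets <- data.frame(
        protein = ref_crest$protein,
        delta_sm = ref_conc$mean_ref,     # dSm at maximal concentration
        mean_ref = ref_crest$mean_ref, sd_ref = ref_crest$sd_ref,
        crest_scaled = crest_scaled, conc_scaled = conc_scaled,
        stringsAsFactors = FALSE)
      flt <- filter_targets(targets, sd_multiplier = config$sd_multiplier,
                            rule = config$sd_rule)
      removed <- flt$removed
      if (nrow(flt$retained))
        scores <- combined_score(flt$retained[, c("protein", "delta_sm",
                                                  "conc_scaled",
                                                  "crest_scaled")])
    } else {
      targets <- data.frame()
      removed <- data.frame(protein = character(0), rule = character(0))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("restpisa")),
    seed = config$seed,
    n_proteins = config$n_proteins,
    rows = list(shifts = nrow(shifts),
                kinetics = if (is.null(kin)) 0L else nrow(kin),
                scores = if (is.null(scores)) 0L else nrow(scores)))

  res <- structure(
    list(panel = panel, offcurve = off_qm, crest = crest_qm, conc = conc_qm,
         shifts = shifts, hits = hit_proteins, kinetics = kin,
         targets = targets, scores = scores, removed = removed,
         manifest = manifest),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config)
  res
}

.write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df) && nrow(df))
      utils::write.table(df, file.path(config$out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_quant_matrix(res$offcurve, file.path(config$out_dir, "offcurve"))
  w(as.data.frame(res$shifts), "shifts")
  w(res$kinetics, "kinetics")
  w(as.data.frame(res$scores), "scores")
  w(res$removed, "removed")
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  res$manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(res$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d proteins; %d T0 hits; %s kinetic fits; %s scored targets\n",
              length(x$panel), length(x$hits),
              if (is.null(x$kinetics)) "no" else nrow(x$kinetics),
              if (is.null(x$scores)) "no" else nrow(x$scores)))
  invisible(x)
}
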