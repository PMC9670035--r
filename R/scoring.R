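#' Scale a pooled compressed readout to the full-engagement PISA level
#'
#' Places a pooled cResT-PISA or conc-PISA fold change on the engagement
#' scale: 0 is vehicle-like, 1 is the full-engagement level measured in
#' the PISA sample kept at the maximal drug concentration (or T0):
#' `scaled = (pooled_fc - 1) / (pisa_max_fc_mean - 1)`, the same
#' convention as [scale_profile()]. Proteins whose reference PISA mean
#' fold change is within `epsilon` of 1 carry no measurable shift and are
#' rejected.
#'
#' @param pooled_fc Pooled-sample fold change(s) over vehicle.
#' @param pisa_max_fc_mean Mean fold change of the reference PISA sample
#'   (maximal concentration or T0).
#' @param epsilon Exclusion half-width around 1 for the reference mean.
#' @return Scaled value(s), nominally in `[0, 1]`.
#' @export
#' @examples
#' scale_compressed(1.1, 1.4)  # 0.25
scale_compressed <- function(pooled_fc, pisa_max_fc_mean, epsilon = 1e-6) {
  if (abs(pisa_max_fc_mean - 1) <= epsilon)
    stop("reference PISA fold change within epsilon of 1; protein excluded")
  (pooled_fc - 1) / (pisa_max_fc_mean - 1)
}

#' Quality-filter candidate targets before scoring
#'
#' Applies the two filters used on compressed readouts, logging which rule
#' fired for each removed protein:
#' \describe{
#'   \item{replicate noise}{removed when the replicate standard deviation
#'     at the reference condition (maximal concentration or first time
#'     point) exceeds `sd_multiplier` times the mean there. By default the
#'     mean is that same protein's reference mean (`rule =
#'     "per_protein"`, i.e. remove when the CV exceeds 300%); `rule =
#'     "global_max"` compares against the largest absolute reference mean
#'     across proteins instead.}
#'   \item{range}{removed when a scaled cResT or conc-PISA value falls
#'     above 1 or below 0 (outside the vehicle-to-full-engagement
#'     interval).}
#' }
#'
#' @param records Data frame with columns `protein`, `sd_ref`, `mean_ref`,
#'   `crest_scaled`, `conc_scaled` (either scaled column may be `NA` and
#'   is then not range-checked).
#' @param sd_multiplier Noise-filter multiplier (default 3).
#' @param rule `"per_protein"` (default) or `"global_max"`; see above.
#' @return List with `retained` (surviving rows) and `removed` (data frame
#'   `protein`, `rule` naming the rule that fired first).
#' @export
filter_targets <- function(records, sd_multiplier = 3,
                           rule = c("per_protein", "global_max")) {
  rule <- match.arg(rule)
  req <- c("protein", "sd_ref", "mean_ref", "crest_scaled", "conc_scaled")
  stopifnot(all(req %in% names(records)))
  ref <- if (rule == "per_protein") abs(records$mean_ref)
  else rep(max(abs(records$mean_ref)), nrow(records))
  noisy <- records$sd_ref > sd_multiplier * ref
  out_of_range <- (!is.na(records$crest_scaled) &
                     (records$crest_scaled > 1 | records$crest_scaled < 0)) |
    (!is.na(records$conc_scaled) &
       (records$conc_scaled > 1 | records$conc_scaled < 0))
  removed_rule <- ifelse(noisy, "replicate_sd",
                         ifelse(out_of_range, "scaled_range", NA_character_))
  removed <- data.frame(protein = records$protein[!is.na(removed_rule)],
                        rule = removed_rule[!is.na(removed_rule)],
                        stringsAsFactors = FALSE)
  list(retained = records[is.na(removed_rule), , drop = FALSE],
       removed = removed)
}

#' Combine alteration, concentration and residence readouts into a ranked
#' target score
#'
#' Each component is scaled to `[0, 1]` by the largest value among the
#' filtered proteins: the alteration score is `|dSm| / max |dSm|` (sign
#' carried separately so destabilized targets compete equally), the
#' concentration score is the scaled conc-PISA value over its maximum, and
#' the residence score the scaled cResT-PISA value over its maximum. The
#' combined score is their unweighted sum (range `[0, 3]`); proteins are
#' ranked by descending combined score, ties broken by alteration score
#' and then protein identifier. A component whose maximum is 0 is set to 0
#' for all proteins and flagged via the `"degenerate_components"`
#' attribute.
#'
#' @param records Data frame with columns `protein`, `delta_sm` (signed
#'   log2 solubility alteration at the reference condition),
#'   `conc_scaled` and `crest_scaled`.
#' @param weights Length-3 numeric weights for (alteration, concentration,
#'   residence); default equal weights of 1.
#' @return Data frame of class `target_scores`: `protein`, `delta_sm`,
#'   `sign`, `alteration_score`, `concentration_score`, `residence_score`,
#'   `combined`, `rank`, ordered by rank.
#' @export
#' @examples
#' combined_score(data.frame(
#'   protein = c("A", "B", "C"), delta_sm = c(0.8, 0.4, 0.8),
#'   conc_scaled = c(0.6, 0.6, 0.3), crest_scaled = c(0.9, 0.3, 0.45)))
combined_score <- function(records, weights = c(1, 1, 1)) {
  req <- c("protein", "delta_sm", "conc_scaled", "crest_scaled")
  stopifnot(all(req %in% names(records)), length(weights) == 3L)
  if (nrow(records) == 0L) stop("no proteins to score")
  scale01 <- function(v) {
    mx <- max(v, na.rm = TRUE)
    if (!is.finite(mx) || mx == 0) return(list(s = rep(0, length(v)),
                                               degenerate = TRUE))
    list(s = v / mx, degenerate = FALSE)
  }
  alt <- scale01(abs(records$delta_sm))
  conc <- scale01(records$conc_scaled)
  crest <- scale01(records$crest_scaled)
  out <- data.frame(protein = records$protein,
                    delta_sm = records$delta_sm,
                    sign = sign(records$delta_sm),
                    alteration_score = alt$s,
                    concentration_score = conc$s,
                    residence_score = crest$s,
                    stringsAsFactors = FALSE)
  out$combined <- weights[1L] * out$alteration_score +
    weights[2L] * out$concentration_score +
    weights[3L] * out$residence_score
  o <- order(-out$combined, -out$alteration_score, out$protein)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  deg <- c(alteration = alt$degenerate, concentration = conc$degenerate,
           residence = crest$degenerate)
  if (any(deg)) attr(out, "degenerate_components") <- names(deg)[deg]
  class(out) <- c("target_scores", class(out))
  out
}
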