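#' Binding parameters for one simulated protein
#'
#' Bundles the kinetic and thermodynamic ground truth of a simulated
#' drug-protein interaction: the full-engagement solubility shift, the
#' dissociation kinetics governing the washout off-curve, and the
#' dose-response occupancy parameters.
#'
#' @param delta_sm Log2 solubility shift at full target engagement
#'   (dimensionless). Positive values stabilize the protein (more soluble
#'   after the thermal gradient), negative values destabilize it.
#' @param k_d Dissociation rate constant of the drug-target complex, in
#'   1/hour. The residence time is `1/k_d`.
#' @param b Asymptotic non-recovering engagement fraction in `[0, 1]`;
#'   `b > 0` emulates covalent-like binding that never washes out.
#' @param ec50 Half-maximal engagement concentration in molar; must be
#'   positive.
#' @param hill Hill coefficient of the occupancy curve (dimensionless,
#'   positive).
#' @return An object of class `binding_params`.
#' @seealso [experiment_design()], [simulate_offcurve_experiment()]
#' @export
#' @examples
#' binding_params(delta_sm = 0.8, k_d = log(2) / 1.5, b = 0.1)
binding_params <- function(delta_sm, k_d, b = 0, ec50 = 2e-8, hill = 1) {
  stopifnot(is.numeric(delta_sm), length(delta_sm) == 1L, is.finite(delta_sm))
  if (!is.numeric(k_d) || length(k_d) != 1L || !is.finite(k_d) || k_d < 0)
    stop("'k_d' must be a single non-negative finite number (1/hour)")
  if (!is.numeric(b) || length(b) != 1L || b < 0 || b > 1)
    stop("'b' must be a single number in [0, 1]")
  if (!is.numeric(ec50) || length(ec50) != 1L || ec50 <= 0)
    stop("'ec50' must be a single positive number (molar)")
  if (!is.numeric(hill) || length(hill) != 1L || hill <= 0)
    stop("'hill' must be a single positive number")
  structure(
    list(delta_sm = delta_sm, k_d = k_d, b = b, ec50 = ec50, hill = hill),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf(
    "<binding_params> delta_sm=%.3g  k_d=%.3g /h  b=%.3g  ec50=%.3g M  hill=%.3g\n",
    x$delta_sm, x$k_d, x$b, x$ec50, x$hill
  ))
  invisible(x)
}

#' Design of a simulated PISA experiment
#'
#' Describes the measurement grid and noise of a simulated experiment:
#' washout time points, drug concentration series, replication, and the
#' coefficient of variation of the multiplicative lognormal measurement
#' noise. An optional shared degradation profile `g(t)` multiplies treated
#' and vehicle samples alike, emulating time-dependent protein loss in the
#' lysate; because it is shared, it cancels from every fold change.
#'
#' @param time_points Washout time points in hours, strictly increasing,
#'   first element 0 (the drug-maintained reference).
#' @param concentrations Drug concentration series in molar, all positive.
#' @param n_replicates Number of replicates per condition, at least 2.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on the natural intensity scale; 0 disables noise.
#' @param degradation `NULL`, or a function of time (hours) returning a
#'   positive abundance multiplier applied to treated and vehicle samples
#'   at that time point.
#' @param seed Integer seed for the simulation's random number stream.
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' experiment_design(noise_cv = 0.05, seed = 7)
experiment_design <- function(time_points = c(0, 1.5, 3, 7, 24),
                              concentrations = c(2e-6, 2e-7, 2e-8, 2e-9,
                                                 2e-10, 2e-11, 2e-12),
                              n_replicates = 3,
                              noise_cv = 0,
                              degradation = NULL,
                              seed = 1L) {
  stopifnot(is.numeric(time_points), length(time_points) >= 1L)
  if (time_points[1L] != 0)
    stop("'time_points' must start at 0 (the drug-maintained reference)")
  if (any(diff(time_points) <= 0))
    stop("'time_points' must be strictly increasing")
  if (any(concentrations <= 0))
    stop("'concentrations' must all be positive")
  if (n_replicates < 2)
    stop("'n_replicates' must be at least 2")
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0)
    stop("'noise_cv' must be a single non-negative number")
  if (!is.null(degradation) && !is.function(degradation))
    stop("'degradation' must be NULL or a function of time")
  structure(
    list(time_points = as.numeric(time_points),
         concentrations = as.numeric(sort(concentrations, decreasing = TRUE)),
         n_replicates = as.integer(n_replicates),
         noise_cv = noise_cv,
         degradation = degradation,
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' Fraction of target still engaged at time t after drug removal
#'
#' The off-curve model: `E(t) = (1 - b) * exp(-k_d * t) + b`. A reversible
#' binder (`b = 0`) decays to zero with rate `k_d`; a purely covalent binder
#' (`b = 1` or `k_d = 0`) stays fully engaged.
#'
#' @param params A [binding_params()] object.
#' @param t Time in hours (vectorized).
#' @return Engagement fraction in `[0, 1]`, same length as `t`.
#' @export
engagement <- function(params, t) {
  (1 - params$b) * exp(-params$k_d * t) + params$b
}

#' Equilibrium occupancy at a given drug concentration
#'
#' Hill occupancy `theta(c) = c^h / (c^h + ec50^h)`.
#'
#' @param params A [binding_params()] object.
#' @param conc Drug concentration in molar (vectorized, positive).
#' @return Occupancy in `[0, 1]`.
#' @export
occupancy <- function(params, conc) {
  if (any(conc <= 0)) stop("'conc' must be positive")
  ch <- conc^params$hill
  ch / (ch + params$ec50^params$hill)
}

# Mean-one multiplicative lognormal noise at a given CV (natural scale).
.lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -sigma2 / 2, sd = sqrt(sigma2)))
}

# Baselines span 3 decades; irrelevant to ratios, exercises normalization.
.draw_baselines <- function(n) 10^stats::runif(n, 5, 8)

.protein_names <- function(params_per_protein) {
  nm <- names(params_per_protein)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    nm <- sprintf("P%04d", seq_along(params_per_protein))
  nm
}

.check_params_list <- function(params_per_protein) {
  if (length(params_per_protein) == 0L)
    stop("'params_per_protein' must contain at least one protein")
  if (!all(vapply(params_per_protein, inherits, logical(1), "binding_params")))
    stop("every element of 'params_per_protein' must be a binding_params object")
}

# Fold change of the soluble pool at engagement E: a linear two-state
# mixture of the fully engaged state (2^delta_sm) and the free state (1).
# At E = 1 the log2 fold change equals delta_sm exactly.
.fc_at_engagement <- function(delta_sm, E) 1 + (2^delta_sm - 1) * E

.new_quant <- function(values, meta, truth) {
  quant_matrix(values, meta, truth = truth)
}

#' Simulate a full off-curve (washout time course) PISA experiment
#'
#' Generates drug-treated and vehicle-treated sample columns for every
#' (time point, replicate) combination. The engagement decays as
#' `E(t) = (1 - b) * exp(-k_d * t) + b` and the treated soluble-pool
#' abundance follows a two-state mixture:
#' `treated = baseline * (1 + (2^delta_sm - 1) * E(t))`, vehicle =
#' baseline. If the design carries a degradation profile `g(t)`, both
#' conditions are multiplied by it before lognormal noise is applied, so
#' fold changes are unaffected.
#'
#' @param params_per_protein List of [binding_params()], optionally named by
#'   protein; unnamed lists get identifiers `P0001`, ...
#' @param design An [experiment_design()].
#' @return A [quant_matrix()] whose `truth` element records the parameters,
#'   baselines and the noiseless engagement matrix `E(t)` per protein.
#' @export
#' @examples
#' pars <- list(KIN1 = binding_params(0.8, k_d = 0.5, b = 0.2))
#' qm <- simulate_offcurve_experiment(pars, experiment_design())
#' dim(qm$values)
simulate_offcurve_experiment <- function(params_per_protein, design) {
  .check_params_list(params_per_protein)
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  prot <- .protein_names(params_per_protein)
  np <- length(prot)
  tp <- design$time_points
  nr <- design$n_replicates
  g <- if (is.null(design$degradation)) function(t) 1 else design$degradation

  meta <- expand.grid(replicate = seq_len(nr), time_h = tp,
                      condition = c("drug", "vehicle"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$conc_M <- NA_real_
  meta$pooled <- FALSE
  meta$channel <- NA_character_
  meta$sample_id <- sprintf("%s_t%g_r%d", meta$condition, meta$time_h,
                            meta$replicate)
  meta <- meta[, c("sample_id", "condition", "time_h", "conc_M",
                   "replicate", "pooled", "channel")]

  baseline <- .draw_baselines(np)
  E <- vapply(params_per_protein, engagement, numeric(length(tp)), t = tp)
  E <- if (length(tp) == 1L) matrix(E, ncol = 1L) else t(E)
  dimnames(E) <- list(prot, paste0("t", tp))
  dsm <- vapply(params_per_protein, `[[`, numeric(1), "delta_sm")

  values <- matrix(NA_real_, np, nrow(meta),
                   dimnames = list(prot, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    ti <- match(meta$time_h[j], tp)
    mu <- if (meta$condition[j] == "drug")
      baseline * .fc_at_engagement(dsm, E[, ti]) else baseline
    values[, j] <- mu * g(meta$time_h[j]) * .lognorm_noise(np, design$noise_cv)
  }

  truth <- list(kind = "offcurve",
                params = params_per_protein, baseline = baseline,
                engagement = E, time_points = tp)
  .new_quant(values, meta, truth)
}

#' Simulate a pooled dose-response (conc-PISA) experiment
#'
#' Per-concentration occupancy follows the Hill model
#' `theta(c) = c^hill / (c^hill + ec50^hill)`. Emits treated columns at each
#' single concentration, vehicle columns, and pooled conc-PISA columns whose
#' noiseless value is the mean of the per-concentration abundances
#' (aliquots of equal volume pooled before measurement). Under the
#' two-state mixture effect model this equals planting the mean occupancy.
#'
#' @inheritParams simulate_offcurve_experiment
#' @return A [quant_matrix()]; `truth$occupancy` holds the per-concentration
#'   occupancies and `truth$pooled_engagement` their mean per protein.
#' @export
simulate_concpisa <- function(params_per_protein, design) {
  .check_params_list(params_per_protein)
  stopifnot(inherits(design, "experiment_design"))
  if (length(design$concentrations) < 2L)
    stop("conc-PISA simulation needs at least 2 concentrations")
  set.seed(design$seed + 1L)
  prot <- .protein_names(params_per_protein)
  np <- length(prot)
  conc <- design$concentrations
  nc <- length(conc)
  nr <- design$n_replicates

  theta <- t(vapply(params_per_protein, occupancy, numeric(nc), conc = conc))
  dimnames(theta) <- list(prot, sprintf("c%g", conc))
  dsm <- vapply(params_per_protein, `[[`, numeric(1), "delta_sm")
  baseline <- .draw_baselines(np)

  meta_one <- function(condition, conc_M, pooled, tag) {
    data.frame(sample_id = sprintf("%s_r%d", tag, seq_len(nr)),
               condition = condition, time_h = NA_real_, conc_M = conc_M,
               replicate = seq_len(nr), pooled = pooled,
               channel = NA_character_, stringsAsFactors = FALSE)
  }
  meta <- rbind(
    do.call(rbind, lapply(seq_len(nc), function(i)
      meta_one("drug", conc[i], FALSE, sprintf("drug_c%02d", i)))),
    meta_one("vehicle", NA_real_, FALSE, "vehicle"),
    meta_one("drug", NA_real_, TRUE, "conc_pool")
  )

  per_conc_mu <- baseline * .fc_at_engagement(
    matrix(dsm, np, nc), theta)       # np x nc matrix of treated means
  pooled_mu <- rowMeans(per_conc_mu)

  values <- matrix(NA_real_, np, nrow(meta),
                   dimnames = list(prot, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    mu <- if (meta$pooled[j]) pooled_mu
    else if (meta$condition[j] == "vehicle") baseline
    else per_conc_mu[, match(meta$conc_M[j], conc)]
    values[, j] <- mu * .lognorm_noise(np, design$noise_cv)
  }

  truth <- list(kind = "concpisa", params = params_per_protein,
                baseline = baseline, occupancy = theta,
                pooled_engagement = rowMeans(theta), concentrations = conc)
  .new_quant(values, meta, truth)
}

#' Simulate a compressed residence-time (cResT-PISA) experiment
#'
#' Emulates pooling all washout time points of one replicate into a single
#' sample: the pooled cResT column's noiseless value is the mean over time
#' points of the off-curve treated abundances, so it is proportional to the
#' off-curve area under the curve. Also emits T0 PISA (drug maintained) and
#' vehicle columns needed for downstream scaling. A single-time-point
#' design is allowed and pools to that time point itself.
#'
#' @inheritParams simulate_offcurve_experiment
#' @return A [quant_matrix()]; `truth$pooled_engagement` is the per-protein
#'   mean engagement over the time grid.
#' @export
simulate_compressed_rest <- function(params_per_protein, design) {
  .check_params_list(params_per_protein)
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed + 2L)
  prot <- .protein_names(params_per_protein)
  np <- length(prot)
  tp <- design$time_points
  nr <- design$n_replicates

  E <- vapply(params_per_protein, engagement, numeric(length(tp)), t = tp)
  E <- if (length(tp) == 1L) matrix(E, ncol = 1L) else t(E)
  dimnames(E) <- list(prot, paste0("t", tp))
  dsm <- vapply(params_per_protein, `[[`, numeric(1), "delta_sm")
  baseline <- .draw_baselines(np)

  fc <- .fc_at_engagement(matrix(dsm, np, length(tp)), E)  # np x nt
  pooled_mu <- baseline * rowMeans(fc)
  t0_mu <- baseline * fc[, 1L]

  meta_one <- function(condition, time_h, pooled, tag) {
    data.frame(sample_id = sprintf("%s_r%d", tag, seq_len(nr)),
               condition = condition, time_h = time_h, conc_M = NA_real_,
               replicate = seq_len(nr), pooled = pooled,
               channel = NA_character_, stringsAsFactors = FALSE)
  }
  meta <- rbind(meta_one("drug", 0, FALSE, "drug_t0"),
                meta_one("vehicle", 0, FALSE, "vehicle"),
                meta_one("drug", NA_real_, TRUE, "crest_pool"))

  values <- matrix(NA_real_, np, nrow(meta),
                   dimnames = list(prot, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    mu <- if (meta$pooled[j]) pooled_mu
    else if (meta$condition[j] == "vehicle") baseline
    else t0_mu
    values[, j] <- mu * .lognorm_noise(np, design$noise_cv)
  }

  truth <- list(kind = "crest", params = params_per_protein,
                baseline = baseline, engagement = E,
                pooled_engagement = rowMeans(E), time_points = tp)
  .new_quant(values, meta, truth)
}

#' Simulate centroided reporter-region MS2 spectra with known truth
#'
#' Plants one reporter peak per channel at the theoretical m/z, jittered by
#' at most `ppm_jitter` parts per million, with the requested intensity.
#' Channels with intensity 0 (or `NA`) get no peak. Decoy peaks are placed
#' at least 50 ppm away from every channel so that a 20 ppm extraction
#' window can never pick them up.
#'
#' @param true_channel_intensities Numeric matrix (spectra in rows, channels
#'   in columns) or a single numeric vector for one spectrum.
#' @param channel_mzs Theoretical reporter m/z values (Th), one per channel.
#' @param ppm_jitter Maximal mass error of the planted peaks in ppm; must be
#'   strictly below 20 so planted peaks stay recoverable.
#' @param n_decoy_peaks Number of decoy peaks per spectrum.
#' @param seed Integer seed.
#' @return List with `spectra` (list of [spectrum()]) and `truth` (the
#'   intensity matrix actually planted).
#' @export
simulate_reporter_spectra <- function(true_channel_intensities, channel_mzs,
                                      ppm_jitter = 0, n_decoy_peaks = 0,
                                      seed = 1L) {
  if (is.null(dim(true_channel_intensities)))
    true_channel_intensities <- matrix(true_channel_intensities, nrow = 1L)
  nchan <- length(channel_mzs)
  stopifnot(ncol(true_channel_intensities) == nchan, all(channel_mzs > 0))
  if (ppm_jitter >= 20)
    stop("'ppm_jitter' must be below 20 ppm: planted peaks would leave the ",
         "extraction window")
  set.seed(seed)
  ns <- nrow(true_channel_intensities)

  mz_lo <- min(channel_mzs) * 0.98
  mz_hi <- max(channel_mzs) * 1.02
  draw_decoys <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      cand <- stats::runif(2L * (n - length(out)), mz_lo, mz_hi)
      ok <- vapply(cand, function(m)
        all(abs(m - channel_mzs) / channel_mzs > 50e-6), logical(1))
      out <- c(out, cand[ok])
    }
    out[seq_len(n)]
  }

  spectra <- vector("list", ns)
  for (i in seq_len(ns)) {
    inten <- true_channel_intensities[i, ]
    planted <- which(!is.na(inten) & inten > 0)
    jit <- stats::runif(length(planted), -ppm_jitter, ppm_jitter) * 1e-6
    mz <- channel_mzs[planted] * (1 + jit)
    ii <- inten[planted]
    if (n_decoy_peaks > 0) {
      dm <- draw_decoys(n_decoy_peaks)
      mz <- c(mz, dm)
      ii <- c(ii, 10^stats::runif(n_decoy_peaks, 2, 7))
    }
    o <- order(mz)
    spectra[[i]] <- spectrum(scan_id = sprintf("scan%05d", i),
                             mz = mz[o], intensity = ii[o])
  }
  list(spectra = spectra, truth = true_channel_intensities)
}

#' Draw a random panel of binding parameters for demo pipelines
#'
#' A convenience generator for end-to-end runs: a fraction of proteins are
#' true targets with a solubility shift and kinetics drawn over realistic
#' ranges; the rest are nulls (`delta_sm = 0`).
#'
#' @param n_proteins Number of proteins.
#' @param frac_targets Fraction of proteins that are true targets.
#' @param delta_sm_range Absolute log2 shift range for targets.
#' @param k_d_range Dissociation rate range, 1/hour.
#' @param b_range Asymptotic fraction range.
#' @param ec50_range EC50 range in molar (log-uniform).
#' @param frac_destabilized Fraction of targets with negative `delta_sm`.
#' @param seed Integer seed.
#' @return Named list of [binding_params()].
#' @export
simulate_target_panel <- function(n_proteins = 100, frac_targets = 0.3,
                                  delta_sm_range = c(0.4, 1),
                                  k_d_range = c(0.05, 2),
                                  b_range = c(0, 0.5),
                                  ec50_range = c(1e-9, 1e-6),
                                  frac_destabilized = 0.25,
                                  seed = 1L) {
  set.seed(seed)
  n_t <- round(n_proteins * frac_targets)
  pars <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    if (i <= n_t) {
      sgn <- if (stats::runif(1) < frac_destabilized) -1 else 1
      pars[[i]] <- binding_params(
        delta_sm = sgn * stats::runif(1, delta_sm_range[1], delta_sm_range[2]),
        k_d = stats::runif(1, k_d_range[1], k_d_range[2]),
        b = stats::runif(1, b_range[1], b_range[2]),
        ec50 = 10^stats::runif(1, log10(ec50_range[1]), log10(ec50_range[2]))
      )
    } else {
      pars[[i]] <- binding_params(delta_sm = 0, k_d = 1)
    }
  }
  names(pars) <- sprintf("P%04d", seq_len(n_proteins))
  pars
}
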