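# Shared fixtures and independent oracles for the suite.

# Brute-force reporter oracle: scan every peak of the spectrum for every
# channel, keep in-window peaks, pick max intensity with the same
# tie-break (closest in m/z, then lower m/z). Deliberately unoptimized and
# independent of the extraction code path.
oracle_extract <- function(spec, channels, tol_ppm = 20) {
  vapply(channels$mz, function(mz0) {
    inw <- which(spec$mz >= mz0 * (1 - tol_ppm * 1e-6) &
                   spec$mz <= mz0 * (1 + tol_ppm * 1e-6))
    if (!length(inw)) return(NA_real_)
    o <- order(-spec$intensity[inw], abs(spec$mz[inw] - mz0), spec$mz[inw])
    spec$intensity[inw[o[1L]]]
  }, numeric(1))
}

# Random centroided spectrum with peaks scattered around the reporter
# region, including some inside channel windows.
random_spectrum <- function(id, channels, n_peaks = 40) {
  base <- runif(n_peaks, min(channels$mz) - 0.5, max(channels$mz) + 0.5)
  # push a handful of peaks into (or near) channel windows, some at the
  # window edges to exercise the closed-interval boundary
  k <- sample(seq_along(channels$mz), 5, replace = TRUE)
  off <- sample(c(-25, -20, -10, 0, 10, 20, 25), 5, replace = TRUE)
  near <- channels$mz[k] * (1 + off * 1e-6)
  mz <- sort(c(base, near))
  spectrum(id, mz, intensity = round(10^runif(length(mz), 2, 7)))
}

# Tiny hand-built quant matrix: `fc_by_time` gives the treated/vehicle
# ratio planted at each time point (same for all replicates, noiseless).
toy_quant <- function(fc_by_time, times = as.numeric(names(fc_by_time)),
                      n_rep = 3, baseline = 1e6, proteins = "P1") {
  np <- length(proteins)
  meta <- expand.grid(replicate = seq_len(n_rep), time_h = times,
                      condition = c("drug", "vehicle"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$conc_M <- NA_real_
  meta$pooled <- FALSE
  meta$channel <- NA_character_
  meta$sample_id <- sprintf("%s_t%g_r%d", meta$condition, meta$time_h,
                            meta$replicate)
  meta <- meta[, c("sample_id", "condition", "time_h", "conc_M",
                   "replicate", "pooled", "channel")]
  values <- matrix(NA_real_, np, nrow(meta),
                   dimnames = list(proteins, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    fc <- fc_by_time[match(meta$time_h[j], times)]
    values[, j] <- if (meta$condition[j] == "drug") baseline * fc else baseline
  }
  quant_matrix(values, meta)
}

default_grid <- c(0, 1.5, 3, 7, 24)
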