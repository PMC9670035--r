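#' Scale an off-curve to the drug-maintained reference at time 0
#'
#' Shift-normalizes fold changes so that the mean at time 0 is 1 and a
#' return to the vehicle level is 0:
#' `S(t, r) = (FC(t, r) - 1) / (FC0_mean - 1)`.
#' Stabilized (`FC > 1`) and destabilized (`FC < 1`) proteins are treated
#' identically — the sign of the shift cancels. Proteins whose mean fold
#' change at time 0 is within `epsilon` of 1 carry no measurable shift and
#' are rejected (they cannot be scaled).
#'
#' @param fc Numeric vector (or matrix, time points in rows and replicates
#'   in columns) of linear fold changes drug/vehicle.
#' @param t0_mean_fc Mean fold change of the drug-maintained sample at
#'   time 0.
#' @param epsilon Exclusion half-width around 1 for `t0_mean_fc`.
#' @return Scaled engagement values, same shape as `fc`.
#' @export
#' @examples
#' scale_profile(c(1.5, 1.25, 1.0), t0_mean_fc = 1.5)  # 1, 0.5, 0
scale_profile <- function(fc, t0_mean_fc, epsilon = 1e-6) {
  if (abs(t0_mean_fc - 1) <= epsilon)
    stop("no measurable shift at time 0 (mean fold change within epsilon of 1); ",
         "protein cannot be scaled")
  (fc - 1) / (t0_mean_fc - 1)
}

#' Build a scaled off-curve profile for one protein
#'
#' @param protein Protein identifier.
#' @param times Time points in hours, strictly increasing.
#' @param S Matrix of scaled engagement values, `length(times)` rows and
#'   one column per replicate.
#' @return An object of class `scaled_profile`.
#' @export
scaled_profile <- function(protein, times, S) {
  S <- as.matrix(S)
  stopifnot(length(times) == nrow(S), all(diff(times) > 0))
  structure(list(protein = protein, times = as.numeric(times), S = S),
            class = "scaled_profile")
}

#' @export
print.scaled_profile <- function(x, ...) {
  cat(sprintf("<scaled_profile> %s: %d time points x %d replicates\n",
              x$protein, nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' Choose the off-curve model for a scaled profile
#'
#' Exponential-with-asymptote when the mean scaled value at the last time
#' point has dropped below `threshold` (the protein visibly dissociates
#' within the time course); otherwise a linear function (slow unbinder).
#' The boundary is exclusive: a mean of exactly `threshold` routes linear.
#'
#' @param profile A [scaled_profile()] with at least 3 time points.
#' @param threshold Routing threshold on the last-time-point mean
#'   (default 0.6).
#' @return `"exponential"` or `"linear"`.
#' @export
select_model <- function(profile, threshold = 0.6) {
  stopifnot(inherits(profile, "scaled_profile"))
  if (nrow(profile$S) < 3L) stop("model selection needs at least 3 time points")
  last_mean <- mean(profile$S[nrow(profile$S), ])
  if (last_mean < threshold) "exponential" else "linear"
}

# Residual sum of squares of the exponential-with-asymptote model.
.exp_rss <- function(par, t, s) {
  pred <- (1 - par[2L]) * exp(-par[1L] * t) + par[2L]
  sum((s - pred)^2)
}

#' Fit the off-curve model to a scaled profile
#'
#' Exponential branch: least squares over
#' `S(t) = (1 - b) * exp(-k_d * t) + b` with `k_d >= 0` and `b` in
#' `[0, 1]`, all replicate values pooled into one problem. The amplitude
#' is fixed so that `S(0) = 1`, consistent with the scaling. Fitting uses
#' bounded Levenberg-Marquardt with multi-start initialization (a
#' log-linear estimate of `k_d` plus a fixed restart grid); the best
#' converged restart by residual sum of squares wins. Linear branch:
#' ordinary least squares `S = c - k_d * t` with the decay rate clamped at
#' 0 when the fitted slope is positive; the residence time is not
#' extrapolated from a linear slope.
#'
#' @param profile A [scaled_profile()].
#' @param model `"exponential"`, `"linear"`, or `NULL` to route via
#'   [select_model()].
#' @param threshold Passed to [select_model()] when `model` is `NULL`.
#' @return A one-row data frame: `protein`, `model`, `k_d` (1/hour), `b`
#'   (`NA` for linear fits), `residence_time_h` (`1/k_d`; `Inf` and
#'   flagged when `k_d = 0`; `NA` for linear fits), `rss`, `converged`,
#'   `flag`.
#' @export
fit_offcurve <- function(profile, model = NULL, threshold = 0.6) {
  stopifnot(inherits(profile, "scaled_profile"))
  if (nrow(profile$S) < 3L) stop("fitting needs at least 3 time points")
  if (is.null(model)) model <- select_model(profile, threshold)
  model <- match.arg(model, c("exponential", "linear"))
  t <- rep(profile$times, times = ncol(profile$S))
  s <- as.vector(profile$S)

  if (model == "linear") {
    ols <- stats::lm(s ~ t)
    slope <- unname(stats::coef(ols)[2L])
    k_d <- max(0, -slope)
    if (slope > 0) {               # clamped at the boundary: flat profile
      rss <- sum((s - mean(s))^2)
      flag <- "slope_clamped"
    } else {
      rss <- sum(stats::resid(ols)^2)
      flag <- if (k_d == 0) "no_decay" else "slow_unbinder"
    }
    return(data.frame(protein = profile$protein, model = "linear",
                      k_d = k_d, b = NA_real_,
                      residence_time_h = NA_real_, rss = rss,
                      converged = TRUE, flag = flag,
                      stringsAsFactors = FALSE))
  }

  # starting values: b0 from the last-time-point mean, k_d from a
  # log-linear regression of max(S - b0, eps)
  b0 <- min(max(mean(profile$S[nrow(profile$S), ]), 0), 0.99)
  amp <- pmax(s - b0, 1e-6)
  use <- s > b0 + 1e-6
  kd0 <- if (sum(use) >= 2L) {
    sl <- stats::coef(stats::lm(log(amp[use]) ~ t[use]))[2L]
    max(min(-unname(sl), 50), 1e-3)
  } else 0.5
  starts <- rbind(c(kd0, b0),
                  expand.grid(k_d = c(0.05, 0.2, 0.5, 1, 2),
                              b = c(0, b0, 0.5)))
  colnames(starts) <- c("k_d", "b")

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- as.numeric(starts[i, ])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(k_d = st[1L], b = st[2L]),
        lower = c(0, 0), upper = c(1e3, 1),
        fn = function(p) s - ((1 - p$b) * exp(-p$k_d * t) + p$b),
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                             maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(k_d = fit$par$k_d, b = fit$par$b, rss = rss,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best)) {             # all restarts failed: flagged, AUC-only
    return(data.frame(protein = profile$protein, model = "exponential",
                      k_d = NA_real_, b = NA_real_,
                      residence_time_h = NA_real_, rss = NA_real_,
                      converged = FALSE, flag = "fit_failed",
                      stringsAsFactors = FALSE))
  }
  tau <- if (best$k_d > 0) 1 / best$k_d else Inf
  data.frame(protein = profile$protein, model = "exponential",
             k_d = best$k_d, b = best$b, residence_time_h = tau,
             rss = best$rss, converged = best$converged,
             flag = if (best$k_d == 0) "no_decay" else "",
             stringsAsFactors = FALSE)
}

#' Area under the off-curve, per replicate
#'
#' The default AUC of a replicate is the plain sum of its scaled values
#' over all time points (no spacing weights). `method = "trapezoid"`
#' instead integrates with the actual time spacings for users who want
#' time-weighted areas.
#'
#' @param profile A [scaled_profile()] with a complete replicate-by-time
#'   grid (no missing cells).
#' @param method `"sum"` (default) or `"trapezoid"`.
#' @return List with `auc` (per replicate), `mean` and `sd`.
#' @export
compute_auc <- function(profile, method = c("sum", "trapezoid")) {
  stopifnot(inherits(profile, "scaled_profile"))
  method <- match.arg(method)
  if (anyNA(profile$S))
    stop("profile has missing cells; complete replicate x time grid required")
  auc <- if (method == "sum") colSums(profile$S)
  else apply(profile$S, 2L, function(y)
    sum(diff(profile$times) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  list(auc = unname(auc), mean = mean(auc), sd = stats::sd(auc))
}

#' Normalize mean AUCs to the maximum across proteins
#'
#' @param auc_means Named or unnamed numeric vector of mean AUCs.
#' @return Vector of the same shape divided by its maximum finite value.
#' @export
normalize_auc <- function(auc_means) {
  fin <- is.finite(auc_means)
  if (!any(fin)) stop("no finite AUC values")
  mx <- max(auc_means[fin])
  if (mx == 0) stop("all AUCs are zero; cannot normalize")
  auc_means / mx
}

#' Pearson correlation with degenerate-input flagging
#'
#' @param x,y Paired numeric vectors; at least 3 finite pairs required.
#' @return Pearson's r, or `NA` (with a warning) when either vector has
#'   zero variance over the complete pairs.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need at least 3 paired finite values")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok], method = "pearson")
}

#' Full kinetic analysis of a replicate fold-change table
#'
#' For each requested protein: computes the drug-maintained T0 mean fold
#' change, scales the off-curve ([scale_profile()]), routes the model
#' ([select_model()]), fits it ([fit_offcurve()]) and summarizes the area
#' under the curve ([compute_auc()]). Proteins with no measurable T0
#' shift are reported with flag `"no_t0_shift"` and no fit.
#'
#' @param fc_table Replicate fold-change table from
#'   [normalize_to_vehicle()] (or the `"replicate_fc"` attribute of a
#'   shift table), restricted to non-pooled washout samples.
#' @param proteins Proteins to analyze; default all in the table.
#' @param threshold Model-routing threshold (default 0.6).
#' @param epsilon T0-shift exclusion half-width (default 1e-6).
#' @param auc_method Passed to [compute_auc()].
#' @return Data frame with one row per protein: the [fit_offcurve()]
#'   columns plus `auc_mean`, `auc_sd` and `auc_norm` (mean AUC divided by
#'   the maximum across the analyzed set).
#' @export
fit_kinetics <- function(fc_table, proteins = NULL, threshold = 0.6,
                         epsilon = 1e-6, auc_method = "sum") {
  fc_table <- fc_table[!fc_table$pooled & !is.na(fc_table$time_h), ,
                       drop = FALSE]
  if (is.null(proteins)) proteins <- unique(fc_table$protein)
  rows <- lapply(proteins, function(p) {
    sub <- fc_table[fc_table$protein == p, , drop = FALSE]
    times <- sort(unique(sub$time_h))
    reps <- sort(unique(sub$replicate))
    fcm <- matrix(NA_real_, length(times), length(reps))
    fcm[cbind(match(sub$time_h, times), match(sub$replicate, reps))] <- sub$fc
    t0_mean <- mean(fcm[1L, ], na.rm = TRUE)
    if (abs(t0_mean - 1) <= epsilon) {
      return(data.frame(protein = p, model = NA_character_, k_d = NA_real_,
                        b = NA_real_, residence_time_h = NA_real_,
                        rss = NA_real_, converged = NA,
                        flag = "no_t0_shift", auc_mean = NA_real_,
                        auc_sd = NA_real_, stringsAsFactors = FALSE))
    }
    prof <- scaled_profile(p, times, scale_profile(fcm, t0_mean, epsilon))
    fit <- fit_offcurve(prof, model = NULL, threshold = threshold)
    a <- compute_auc(prof, method = auc_method)
    cbind(fit, data.frame(auc_mean = a$mean, auc_sd = a$sd))
  })
  out <- do.call(rbind, rows)
  out$auc_norm <- NA_real_
  fin <- is.finite(out$auc_mean)
  if (any(fin)) out$auc_norm <- out$auc_mean / max(out$auc_mean[fin])
  out
}
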