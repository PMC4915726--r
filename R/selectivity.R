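#' Signed enantiomeric excess from enantiomer peak areas
#'
#' `ee = (area_ref - area_other) / (area_ref + area_other)`, positive
#' toward the designated reference enantiomer. Which retention time is
#' which enantiomer is assay metadata, declared by the caller; the
#' formula itself is scale-invariant in total area.
#'
#' @param area_ref peak area of the reference enantiomer (>= 0).
#' @param area_other peak area of the other enantiomer (>= 0).
#' @return ee as a fraction in \[-1, 1\]. A value of exactly +/-1 (one
#'   zero area) raises a "single enantiomer" warning.
#' @examples
#' ee_from_areas(95.5, 4.5)  # 0.91
#' @export
ee_from_areas <- function(area_ref, area_other) {
  if (any(area_ref < 0) || any(area_other < 0))
    stop("peak areas must be non-negative")
  tot <- area_ref + area_other
  if (any(tot == 0)) stop("both peak areas are zero")
  ee <- (area_ref - area_other) / tot
  if (any(abs(ee) == 1))
    warning("single enantiomer detected (|ee| = 1)")
  ee
}

#' Convert enantiomeric excess to the log(E) selectivity scale
#'
#' `log(E) = log10((1 + ee) / (1 - ee))`, the odds form of the
#' enantioselectivity; antisymmetric in ee and zero iff ee is zero. The
#' base-10 logarithm is fixed by the convention of the selectivity
#' tables this package reproduces (natural log does not).
#'
#' @param ee enantiomeric excess as a fraction, |ee| < 1.
#' @return log10(E); vectorized.
#' @examples
#' round(log_e_from_ee(0.91), 2)   # 1.33
#' round(log_e_from_ee(-0.96), 2)  # -1.69
#' @export
log_e_from_ee <- function(ee) {
  if (any(!is.finite(ee))) stop("ee must be finite")
  if (any(abs(ee) >= 1)) stop("enantiopure: E unbounded at |ee| >= 1")
  log10((1 + ee) / (1 - ee))
}

#' Aggregate replicate ee measurements
#'
#' Arithmetic mean and sample standard deviation (n - 1), as used for
#' triplicate assay readouts reported as mean +/- SD percent.
#'
#' @param ee_pct numeric vector of ee values (conventionally percent).
#' @return list with `mean`, `sd` (`NA` with a warning when n = 1) and
#'   `n`.
#' @examples
#' aggregate_replicates(c(89, 91, 93))  # 91 +/- 2, n = 3
#' @export
aggregate_replicates <- function(ee_pct) {
  if (length(ee_pct) == 0L) stop("no replicates")
  s <- if (length(ee_pct) > 1L) stats::sd(ee_pct) else {
    warning("single replicate: SD undefined")
    NA_real_
  }
  list(mean = mean(ee_pct), sd = s, n = length(ee_pct))
}

mm_rate <- function(S, K_M, k_cat) k_cat * S / (K_M + S)

#' Fit Michaelis-Menten kinetics by nonlinear least squares
#'
#' Fits `v = k_cat * S / (K_M + S)` with a damped Gauss-Newton
#' iteration on log-parameters (which keeps both parameters positive).
#' Initialization: `K_M0 = median(S)`, `k_cat0 = max(v)`. Convergence is
#' declared when the relative parameter change drops below `tol`
#' (default 1e-8) within `max_iter` iterations (default 500); a
#' degenerate design (e.g. saturated-only, constant-rate data, which
#' leaves K_M unidentifiable) fails to converge and raises an error.
#' Standard errors come from the local curvature (Jacobian
#' cross-product) at the optimum.
#'
#' @param S substrate concentrations, mM (>= 4 points recommended,
#'   spanning below and above the K_M scale).
#' @param rate observed rates, 1/s.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return an object of class `KineticsFit`: list with `K_M`, `K_M_se`,
#'   `k_cat`, `k_cat_se`, `efficiency` (= k_cat / K_M), `efficiency_se`,
#'   `cov` (2 x 2 covariance of (K_M, k_cat)), `n_points`, `converged`,
#'   `iterations`, `residuals`.
#' @export
fit_michaelis_menten <- function(S, rate, tol = 1e-8, max_iter = 500L) {
  S <- as.numeric(S); v <- as.numeric(rate)
  if (length(S) != length(v)) stop("S and rate differ in length")
  if (length(S) < 4L) stop("need at least 4 (S, rate) points")
  if (any(S <= 0) || any(v < 0)) stop("S must be > 0 and rates >= 0")
  if (max(v) <= 0) stop("all rates are zero")
  theta <- c(log(stats::median(S)), log(max(v)))  # (log K_M, log k_cat)
  lambda <- 1e-8
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    K <- exp(theta[1]); k <- exp(theta[2])
    f <- mm_rate(S, K, k)
    r <- v - f
    # Jacobian wrt log-params
    J <- cbind(-k * S * K / (K + S)^2, f)
    A <- crossprod(J) + diag(lambda, 2)
    g <- crossprod(J, r)
    step <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(step)) stop("non-convergence: singular curvature (K_M unidentifiable?)")
    new_theta <- theta + as.numeric(step)
    # simple damping: halve the step while the fit worsens
    sse_old <- sum(r^2)
    half <- 0L
    repeat {
      f_new <- mm_rate(S, exp(new_theta[1]), exp(new_theta[2]))
      if (sum((v - f_new)^2) <= sse_old || half >= 30L) break
      new_theta <- theta + (new_theta - theta) / 2
      half <- half + 1L
    }
    rel <- max(abs(new_theta - theta) / pmax(abs(theta), 1))
    theta <- new_theta
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("non-convergence after ", max_iter,
         " iterations (K_M may be unidentifiable for this design)")
  K <- exp(theta[1]); k <- exp(theta[2])
  f <- mm_rate(S, K, k)
  r <- v - f
  dof <- length(S) - 2L
  sigma2 <- if (dof > 0) sum(r^2) / dof else 0
  # Jacobian wrt the natural parameters (K_M, k_cat)
  Jn <- cbind(-k * S / (K + S)^2, S / (K + S))
  JtJ <- crossprod(Jn)
  cov <- tryCatch(sigma2 * solve(JtJ), error = function(e)
    matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(cov), 0))
  eff <- k / K
  eff_se <- efficiency_se(K, k, cov, use_covariance = FALSE)
  structure(list(K_M = K, K_M_se = se[1], k_cat = k, k_cat_se = se[2],
                 efficiency = eff, efficiency_se = eff_se, cov = cov,
                 n_points = length(S), converged = converged,
                 iterations = it, residuals = r),
            class = "KineticsFit")
}

efficiency_se <- function(K, k, cov, use_covariance = FALSE) {
  if (any(!is.finite(cov))) return(NA_real_)
  var_eff <- (1 / K)^2 * cov[2, 2] + (k / K^2)^2 * cov[1, 1]
  if (use_covariance) var_eff <- var_eff - 2 * (1 / K) * (k / K^2) * cov[1, 2]
  sqrt(max(var_eff, 0))
}

#' @export
print.KineticsFit <- function(x, ...) {
  cat(sprintf("KineticsFit: K_M = %.4g +/- %.2g mM, k_cat = %.4g +/- %.2g 1/s, k_cat/K_M = %.4g 1/s/mM (n = %d)\n",
              x$K_M, x$K_M_se, x$k_cat, x$k_cat_se, x$efficiency,
              x$n_points))
  invisible(x)
}

#' Catalytic efficiency with propagated standard error
#'
#' `k_cat / K_M` with first-order (delta-method) error propagation. The
#' K_M-k_cat covariance is ignored by default; pass
#' `use_covariance = TRUE` for the covariance-aware propagation.
#'
#' @param fit a converged `KineticsFit`.
#' @param use_covariance include the off-diagonal covariance term?
#' @return list with `value` (1/s/mM) and `se`.
#' @export
catalytic_efficiency <- function(fit, use_covariance = FALSE) {
  stopifnot(inherits(fit, "KineticsFit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  list(value = fit$k_cat / fit$K_M,
       se = efficiency_se(fit$K_M, fit$k_cat, fit$cov, use_covariance))
}

#' Turn a peak-area table into per-sample ee statistics
#'
#' Input mirrors a chiral-chromatography export: one row per detected
#' peak with columns `sample`, `enantiomer_label`, `area` (and
#' optionally `retention_min`). The reference enantiomer is named
#' explicitly; per sample, replicate runs are aggregated with
#' [aggregate_replicates()].
#'
#' @param peaks data frame of peaks; replicate runs distinguished by a
#'   `run_id` column (optional).
#' @param reference label of the reference enantiomer (e.g. `"R"`).
#' @return data frame: `sample`, `ee_pct`, `sd_ee_pct`, `n_replicates`,
#'   `log_E`.
#' @export
ee_table <- function(peaks, reference) {
  stopifnot(all(c("sample", "enantiomer_label", "area") %in% names(peaks)))
  if (!reference %in% peaks$enantiomer_label)
    stop("reference enantiomer '", reference, "' not present")
  if (is.null(peaks$run_id)) peaks$run_id <- 1L
  out <- lapply(split(peaks, peaks$sample), function(p) {
    ee_reps <- vapply(split(p, p$run_id), function(run) {
      a_ref <- sum(run$area[run$enantiomer_label == reference])
      a_oth <- sum(run$area[run$enantiomer_label != reference])
      ee_from_areas(a_ref, a_oth)
    }, numeric(1))
    agg <- aggregate_replicates(100 * ee_reps)
    data.frame(sample = p$sample[1], ee_pct = agg$mean,
               sd_ee_pct = agg$sd, n_replicates = agg$n,
               log_E = log_e_from_ee(agg$mean / 100))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
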