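#' Percentile trimming of paired f_inv / R1 estimates
#'
#' Outlier removal before calibration: a pair is kept iff its f_inv value
#' lies within the [p_low, p_high] percentile band of the f_inv sample AND
#' its R1 value lies within the corresponding R1 band (intersection rule).
#' Percentiles use linear-interpolation quantiles (R type 7); band limits
#' are inclusive.
#'
#' @param finv Apparent inversion efficiencies.
#' @param r1 Relaxation rates (1/s), same length.
#' @param p_low,p_high Percentile band, defaults 5 and 95.
#' @return Logical keep-flags, one per pair.
#' @export
trim_percentiles <- function(finv, r1, p_low = 5, p_high = 95) {
  if (length(finv) != length(r1))
    stop("`finv` and `r1` must be paired (equal length)")
  if (p_low < 0 || p_high > 100 || p_low >= p_high)
    stop("need 0 <= p_low < p_high <= 100")
  band <- function(x) {
    q <- stats::quantile(x, c(p_low, p_high) / 100, names = FALSE, type = 7)
    x >= q[1] & x <= q[2]
  }
  keep <- band(finv) & band(r1)
  if (sum(keep) < 3L)
    stop("calibration error: fewer than 3 pairs survive trimming")
  keep
}

#' Robust linear fit of f_inv against R1
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685) and residual scale from the median absolute
#' deviation (`median(|r|) / 0.6745`), started from ordinary least squares.
#' Iteration stops when the largest coefficient change is below `tol` or
#' after `max_iter` passes.
#'
#' @param r1 Relaxation rates (1/s); must not be all equal.
#' @param finv Apparent inversion efficiencies, same length (>= 3).
#' @param tune Bisquare tuning constant.
#' @param tol Convergence tolerance on the coefficients.
#' @param max_iter Maximum number of reweighting passes.
#' @return An object of class `c("finv_calibration", "finv_model")`: a linear
#'   inversion-efficiency model (fields `slope`, `intercept`, `clamp`,
#'   usable directly by [finv_evaluate()] and [lut_build()]) plus `n_used`,
#'   `converged`, `weights` and `iterations`.
#' @export
robust_line_fit <- function(r1, finv, tune = 4.685, tol = 1e-10,
                            max_iter = 50L) {
  if (length(r1) != length(finv))
    stop("`r1` and `finv` must be paired (equal length)")
  ok <- is.finite(r1) & is.finite(finv)
  r1 <- r1[ok]; finv <- finv[ok]
  n <- length(r1)
  if (n < 3L) stop("calibration error: need at least 3 pairs")
  if (max(r1) == min(r1))
    stop("calibration error: rank-deficient design (all R1 equal)")
  X <- cbind(1, r1)
  beta <- stats::lm.fit(X, finv)$coefficients
  w <- rep(1, n)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r <- finv - drop(X %*% beta)
    s <- stats::median(abs(r)) / 0.6745
    if (s == 0) { converged <- TRUE; break }  # exact fit
    u <- r / (tune * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 3L)
      stop("calibration error: robust weights collapsed")
    beta_new <- stats::lm.wfit(X, finv, w)$coefficients
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  structure(list(mode = "linear",
                 slope = unname(beta[2]), intercept = unname(beta[1]),
                 clamp = c(0.05, 1),
                 n_used = n, n_trimmed = NA_integer_,
                 converged = converged, iterations = it, weights = w),
            class = c("finv_calibration", "finv_model"))
}

#' @export
print.finv_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibrated inversion-efficiency model: f_inv = %.4f * R1 + %.4f\n",
    x$slope, x$intercept))
  cat(sprintf("  n = %d pairs%s, IRLS %s in %d iterations\n", x$n_used,
              if (is.na(x$n_trimmed)) ""
              else sprintf(" (%d trimmed)", x$n_trimmed),
              if (x$converged) "converged" else "did NOT converge",
              x$iterations))
  invisible(x)
}

#' @export
summary.finv_calibration <- function(object, ...) {
  print(object)
  if (!is.null(object$per_subject)) {
    cat("  per-subject contributions:\n")
    print(object$per_subject)
  }
  invisible(object)
}

#' Calibrate the linear f_inv(R1) model from fitted maps
#'
#' Per subject: voxels under the exclusion mask (CSF, globus pallidus) and
#' invalid fits are dropped, then the lowest/highest percentiles of both
#' f_inv and R1 are trimmed. Survivors are pooled across subjects (pooling
#' averages out individual B1+ patterns) and a robust line is fitted to the
#' pool.
#'
#' @param maps_per_subject List of [psmp4rage_fit()] results (or plain lists
#'   with `f_inv` and `t1` arrays in ms and optionally `valid`).
#' @param exclusion_masks Optional list of logical arrays, `TRUE` = exclude;
#'   one per subject (or `NULL` for none).
#' @param p_low,p_high Trimming percentiles, see [trim_percentiles()].
#' @param pool_first If `TRUE`, trim once on the pooled sample instead of per
#'   subject.
#' @param ... Passed to [robust_line_fit()].
#' @return An `finv_calibration` with a `per_subject` count table attached.
#' @export
calibrate_pipeline <- function(maps_per_subject, exclusion_masks = NULL,
                               p_low = 5, p_high = 95, pool_first = FALSE,
                               ...) {
  ns <- length(maps_per_subject)
  if (ns < 1L) stop("calibration error: no subjects")
  if (!is.null(exclusion_masks) && length(exclusion_masks) != ns)
    stop("need one exclusion mask per subject")
  finv_all <- list(); r1_all <- list()
  tab <- data.frame(subject = seq_len(ns), n_candidate = 0L, n_kept = 0L)
  for (i in seq_len(ns)) {
    mp <- maps_per_subject[[i]]
    finv <- as.vector(mp$f_inv)
    t1 <- as.vector(mp$t1)
    keep <- is.finite(finv) & is.finite(t1) & t1 > 0
    if (!is.null(mp$valid)) keep <- keep & as.vector(mp$valid)
    if (!is.null(exclusion_masks))
      keep <- keep & !as.vector(exclusion_masks[[i]])
    finv <- finv[keep]
    r1 <- 1000 / t1[keep]
    tab$n_candidate[i] <- length(finv)
    if (length(finv) == 0L) { tab$n_kept[i] <- 0L; next }
    if (!pool_first) {
      tk <- trim_percentiles(finv, r1, p_low, p_high)
      finv <- finv[tk]; r1 <- r1[tk]
    }
    tab$n_kept[i] <- length(finv)
    finv_all[[length(finv_all) + 1L]] <- finv
    r1_all[[length(r1_all) + 1L]] <- r1
  }
  finv <- unlist(finv_all); r1 <- unlist(r1_all)
  if (length(finv) == 0L)
    stop("calibration error: empty pool after masking")
  if (pool_first) {
    tk <- trim_percentiles(finv, r1, p_low, p_high)
    finv <- finv[tk]; r1 <- r1[tk]
  }
  fit <- robust_line_fit(r1, finv, ...)
  fit$n_trimmed <- sum(tab$n_candidate) - length(finv)
  fit$per_subject <- tab
  fit
}
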