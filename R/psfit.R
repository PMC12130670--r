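#' Bundle complex per-train volumes with their timing
#'
#' @param volumes 4D complex array (x, y, z, train) of per-train images, or a
#'   list of identically shaped complex 3D arrays.
#' @param ti Inversion times (ms), one per train, ascending.
#' @param t_cycle Cycle duration (ms).
#' @param alpha_nominal Nominal train flip angle (degrees).
#' @param tr_echo Excitation spacing (ms).
#' @return An object of class `complex_train_set`.
#' @export
complex_train_set <- function(volumes, ti, t_cycle, alpha_nominal, tr_echo) {
  if (is.list(volumes)) {
    dm <- dim(volumes[[1]])
    if (!all(vapply(volumes, function(v) identical(dim(v), dm), logical(1))))
      stop("all train volumes must share the same shape")
    volumes <- array(unlist(volumes), c(dm, length(volumes)))
  }
  if (length(dim(volumes)) != 4L)
    stop("`volumes` must be a 4D array with trains along the 4th axis")
  nt <- dim(volumes)[4]
  if (nt < 2L) stop("at least 2 trains are required")
  if (length(ti) != nt) stop("`ti` must have one entry per train")
  if (any(diff(ti) <= 0)) stop("`ti` must be strictly increasing")
  structure(list(volumes = volumes, ti = as.numeric(ti),
                 t_cycle = as.numeric(t_cycle),
                 alpha_nominal = as.numeric(alpha_nominal),
                 tr_echo = as.numeric(tr_echo)),
            class = "complex_train_set")
}

#' Reference phase from the late trains
#'
#' The late trains of a PS-MP4RAGE cycle carry positive longitudinal
#' magnetization, so their common phase is the receiver phase. The reference
#' is the circular mean of the individual phases: the angle of
#' `sum(exp(1i * phi_k))` (unweighted).
#'
#' @param late_signals Complex signals of the late trains (>= 2), or an
#'   n-voxel x n-train complex matrix.
#' @param weighted If `TRUE`, weight each phasor by its magnitude (i.e. use
#'   the angle of the plain signal sum).
#' @return Reference phase(s) in radians; `NA` where all inputs are zero.
#' @export
phase_reference <- function(late_signals, weighted = FALSE) {
  if (is.matrix(late_signals)) {
    if (ncol(late_signals) < 2L) stop("need at least 2 late trains")
    ph <- if (weighted) late_signals
          else ifelse(Mod(late_signals) == 0, 0+0i,
                      late_signals / Mod(late_signals))
    s <- rowSums(ph)
    out <- Arg(s)
    out[Mod(s) == 0] <- NA_real_
    return(out)
  }
  if (length(late_signals) < 2L) stop("need at least 2 late trains")
  phase_reference(matrix(late_signals, nrow = 1), weighted = weighted)[1]
}

#' Signed (phase-corrected real) signal
#'
#' Rotates a complex signal by the reference phase and keeps the real part:
#' `|s| * cos(phase(s) - phi_ref)`. Restores the polarity of the longitudinal
#' magnetization at each inversion time.
#'
#' @param s Complex signal(s).
#' @param phi_ref Reference phase (radians), scalar or matching `s`.
#' @return Real signed signal(s).
#' @export
signed_signal <- function(s, phi_ref) {
  Re(s * exp(-1i * phi_ref))
}

# Vectorised Levenberg-Marquardt for the 3-parameter inversion-recovery
# model S(TI) = s_ss - (s_ss - s_start) exp(-TI / t1_star), fitted
# independently for each row of Y (n voxels x length(ti) samples).
# Initialisation: s_ss from the last sample, t1_star = 1500 ms, s_start from
# forcing the model through the first sample. t1_star is kept in
# [bounds[1], bounds[2]] by projection. Convergence: maximum relative
# parameter change of an accepted step < tol, or max_iter iterations.
.monoexp_lm <- function(ti, Y, t1_init = 1500, bounds = c(50, 8000),
                        tol = 1e-8, max_iter = 200L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  m <- length(ti)
  stopifnot(ncol(Y) == m, m >= 4L)
  TImat <- matrix(ti, n, m, byrow = TRUE)

  spread <- rowSums(abs(Y - Y[, 1]))
  degen <- !is.finite(spread) | spread == 0
  sss <- Y[, m]
  t1s <- rep(t1_init, n)
  sst <- sss - (sss - Y[, 1]) / exp(-ti[1] / t1s)

  sse_of <- function(sss, sst, t1s) {
    E <- exp(-TImat / t1s)
    rowSums((sss - (sss - sst) * E - Y)^2)
  }
  sse <- sse_of(sss, sst, t1s)
  lambda <- rep(1e-3, n)
  converged <- degen            # degenerate voxels never iterate
  active <- !degen

  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    E <- exp(-TImat / t1s)
    Fv <- sss - (sss - sst) * E
    R <- Fv - Y
    J1 <- 1 - E
    J2 <- E
    J3 <- -(sss - sst) * E * TImat / t1s^2
    a11 <- rowSums(J1 * J1); a12 <- rowSums(J1 * J2); a13 <- rowSums(J1 * J3)
    a22 <- rowSums(J2 * J2); a23 <- rowSums(J2 * J3); a33 <- rowSums(J3 * J3)
    g1 <- rowSums(J1 * R); g2 <- rowSums(J2 * R); g3 <- rowSums(J3 * R)
    b11 <- a11 * (1 + lambda); b22 <- a22 * (1 + lambda)
    b33 <- a33 * (1 + lambda)
    det <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
      a13 * (a12 * a23 - b22 * a13)
    det[det == 0 | !is.finite(det)] <- NA_real_
    d1 <- -(g1 * (b22 * b33 - a23^2) - g2 * (a12 * b33 - a13 * a23) +
              g3 * (a12 * a23 - a13 * b22)) / det
    d2 <- -(-g1 * (a12 * b33 - a23 * a13) + g2 * (b11 * b33 - a13^2) -
              g3 * (b11 * a23 - a12 * a13)) / det
    d3 <- -(g1 * (a12 * a23 - b22 * a13) - g2 * (b11 * a23 - a12 * a13) +
              g3 * (b11 * b22 - a12^2)) / det
    bad <- !is.finite(d1) | !is.finite(d2) | !is.finite(d3)
    d1[bad] <- 0; d2[bad] <- 0; d3[bad] <- 0

    sss_c <- sss + d1
    sst_c <- sst + d2
    t1s_c <- pmin(pmax(t1s + d3, bounds[1]), bounds[2])
    sse_c <- sse_of(sss_c, sst_c, t1s_c)
    accept <- active & !bad & is.finite(sse_c) & (sse_c <= sse)

    relch <- pmax(abs(sss_c - sss) / (abs(sss) + 1e-12),
                  abs(sst_c - sst) / (abs(sst) + 1e-12),
                  abs(t1s_c - t1s) / (abs(t1s) + 1e-12))
    newly <- accept & (relch < tol)

    sss[accept] <- sss_c[accept]
    sst[accept] <- sst_c[accept]
    t1s[accept] <- t1s_c[accept]
    sse[accept] <- sse_c[accept]
    lambda[accept] <- pmax(lambda[accept] / 10, 1e-12)
    rej <- active & !accept
    lambda[rej] <- lambda[rej] * 10
    stalled <- rej & lambda > 1e12
    converged <- converged | newly
    active <- active & !newly & !stalled
  }
  list(s_ss = sss, s_start = sst, t1_star = t1s, rss = sse,
       converged = converged & !degen, degenerate = degen)
}

#' Fit the monoexponential inversion-recovery model to signed signals
#'
#' Nonlinear least squares for
#' `S(TI) = s_ss - (s_ss - s_start) * exp(-TI / t1_star)`,
#' the signed signal sampled at the zeroth k-space line of each train.
#' Initialisation: `s_ss` from the last sample, `t1_star = 1500` ms,
#' `s_start` from forcing the model through the first sample;
#' `t1_star` is bounded in [50, 8000] ms.
#'
#' @param ti Inversion times (ms), at least 4.
#' @param s_signed Signed signals, same length as `ti`.
#' @return A list with `s_ss`, `s_start`, `t1_star` (ms), `rss` and `valid`
#'   (`FALSE` for degenerate or non-converged fits, in which case parameters
#'   are undefined).
#' @export
fit_monoexp <- function(ti, s_signed) {
  if (length(ti) < 4L) stop("need at least 4 samples to fit 3 parameters")
  if (length(s_signed) != length(ti))
    stop("`ti` and `s_signed` must have the same length")
  r <- .monoexp_lm(ti, matrix(s_signed, nrow = 1))
  valid <- r$converged[1] && !r$degenerate[1]
  list(s_ss = if (valid) r$s_ss[1] else NA_real_,
       s_start = if (valid) r$s_start[1] else NA_real_,
       t1_star = if (valid) r$t1_star[1] else NA_real_,
       rss = if (valid) r$rss[1] else NA_real_,
       valid = valid)
}

#' Apparent inversion efficiency from a fitted inversion-recovery curve
#'
#' Evaluates the fitted curve at the end of the cycle,
#' `s_end = S(t_cycle)`, and returns `f_inv = -s_start / s_end`. The ratio is
#' undefined when the end-of-cycle signal is numerically zero
#' (|s_end| below `1e-6 * |s_ss|`).
#'
#' @param fit A fit as returned by [fit_monoexp()] (fields `s_ss`, `s_start`,
#'   `t1_star`); vector fields are accepted.
#' @param t_cycle Cycle duration (ms).
#' @return `f_inv` values; `NA` where undefined.
#' @export
finv_from_fit <- function(fit, t_cycle) {
  s_end <- fit$s_ss - (fit$s_ss - fit$s_start) * exp(-t_cycle / fit$t1_star)
  bad <- !is.finite(s_end) | abs(s_end) < 1e-6 * abs(fit$s_ss)
  out <- -fit$s_start / s_end
  out[bad] <- NA_real_
  out
}

#' Convert the apparent relaxation time T1* to T1
#'
#' During a continuous low-flip-angle readout the longitudinal magnetization
#' relaxes with an apparent rate `1/T1* = 1/T1 + (fT * alpha)^2 / (2 TR)`
#' (small-angle, short-TR approximation), so
#' `T1 = 1 / (1/T1* - (fT * alpha)^2 / (2 TR))`.
#'
#' @param t1_star Apparent relaxation time (ms). Vectorised.
#' @param fT Local-to-nominal flip-angle ratio. Vectorised.
#' @param alpha_nominal Nominal flip angle (degrees).
#' @param tr_echo Excitation spacing (ms).
#' @param ft_squared If `TRUE` (default) the correction uses `(fT * alpha)^2`,
#'   i.e. fT scales the flip angle before squaring; `FALSE` uses the literal
#'   `fT * alpha^2`.
#' @return T1 (ms); `NA` (with no error) where the corrected rate is
#'   non-positive and T1 is undefined.
#' @export
t1_from_t1star <- function(t1_star, fT, alpha_nominal, tr_echo,
                           ft_squared = TRUE) {
  a <- alpha_nominal * pi / 180
  term <- if (ft_squared) (fT * a)^2 else fT * a^2
  rate <- 1 / t1_star - term / (2 * tr_echo)
  out <- 1 / rate
  out[!is.finite(rate) | rate <= 0] <- NA_real_
  out
}

#' Voxelwise PS-MP4RAGE fitting
#'
#' Composes, per masked voxel: reference phase from the late trains
#' (2..n), signed signals for all trains, the monoexponential
#' inversion-recovery fit, the apparent inversion efficiency from the fitted
#' curve, and the T1* to T1 conversion using the local flip angle.
#'
#' @param trains A [complex_train_set()].
#' @param b1 3D array of flip-angle ratios fT on the trains' grid, or `NULL`
#'   for a uniform 1.
#' @param mask Logical 3D array; voxels outside are skipped. `NULL` fits all.
#' @param ft_squared Passed to [t1_from_t1star()].
#' @param weighted_phase Passed to [phase_reference()].
#' @return An object of class `psfit_maps`: 3D arrays `s_ss`, `s_start`,
#'   `t1_star`, `f_inv`, `t1`, `rss` (`NA` where invalid or unmasked),
#'   logical arrays `valid` and `polarity_ok`, and a named integer vector
#'   `invalid_counts` tallying causes.
#' @export
psmp4rage_fit <- function(trains, b1 = NULL, mask = NULL,
                          ft_squared = TRUE, weighted_phase = FALSE) {
  stopifnot(inherits(trains, "complex_train_set"))
  dm <- dim(trains$volumes)[1:3]
  nt <- dim(trains$volumes)[4]
  if (nt < 3L)
    stop("phase-sensitive fitting needs at least 3 trains ",
         "(>= 2 late trains for the phase reference)")
  if (is.null(b1)) b1 <- array(1, dm)
  if (!identical(dim(b1), dm))
    stop("shape mismatch: `b1` is not on the trains' grid")
  if (is.null(mask)) mask <- array(TRUE, dm)
  if (!identical(dim(mask), dm))
    stop("shape mismatch: `mask` is not on the trains' grid")

  nvox <- prod(dm)
  S <- matrix(trains$volumes, nvox, nt)
  idx <- which(mask)
  blank <- array(NA_real_, dm)
  maps <- list(s_ss = blank, s_start = blank, t1_star = blank,
               f_inv = blank, t1 = blank, rss = blank,
               phi_ref = blank,
               valid = array(FALSE, dm), polarity_ok = array(TRUE, dm))
  counts <- c(all_zero = 0L, degenerate = 0L, non_converged = 0L,
              s_end_zero = 0L, t1_undefined = 0L, polarity = 0L)

  if (length(idx)) {
    Sv <- S[idx, , drop = FALSE]
    phi <- phase_reference(Sv[, -1, drop = FALSE], weighted = weighted_phase)
    allzero <- rowSums(Mod(Sv)) == 0 | is.na(phi)
    counts["all_zero"] <- sum(allzero)
    signed <- signed_signal(Sv, phi)
    pol_bad <- rowSums(signed[, -1, drop = FALSE] < 0) > 0
    counts["polarity"] <- sum(pol_bad & !allzero)

    fit <- .monoexp_lm(trains$ti, signed)
    counts["degenerate"] <- sum(fit$degenerate & !allzero)
    counts["non_converged"] <- sum(!fit$converged & !fit$degenerate & !allzero)
    finv <- finv_from_fit(fit, trains$t_cycle)
    t1 <- t1_from_t1star(fit$t1_star, b1[idx], trains$alpha_nominal,
                         trains$tr_echo, ft_squared = ft_squared)
    ok <- fit$converged & !allzero
    counts["s_end_zero"] <- sum(ok & is.na(finv))
    counts["t1_undefined"] <- sum(ok & is.na(t1))
    valid <- ok & !is.na(finv) & !is.na(t1)

    maps$phi_ref[idx] <- phi
    maps$s_ss[idx] <- ifelse(ok, fit$s_ss, NA_real_)
    maps$s_start[idx] <- ifelse(ok, fit$s_start, NA_real_)
    maps$t1_star[idx] <- ifelse(ok, fit$t1_star, NA_real_)
    maps$rss[idx] <- ifelse(ok, fit$rss, NA_real_)
    maps$f_inv[idx] <- ifelse(valid, finv, NA_real_)
    maps$t1[idx] <- ifelse(valid, t1, NA_real_)
    maps$valid[idx] <- valid
    maps$polarity_ok[idx] <- !pol_bad
  }
  structure(c(maps, list(invalid_counts = counts, n_masked = length(idx),
                         ti = trains$ti, t_cycle = trains$t_cycle)),
            class = "psfit_maps")
}

#' @export
print.psfit_maps <- function(x, ...) {
  cat("PS-MP4RAGE voxelwise fit\n")
  cat(sprintf("  %d voxels fitted, %d valid\n", x$n_masked, sum(x$valid)))
  if (any(x$invalid_counts > 0)) {
    cc <- x$invalid_counts[x$invalid_counts > 0]
    cat("  flags:", paste(sprintf("%s=%d", names(cc), cc), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.psfit_maps <- function(object, ...) {
  q <- function(v) stats::quantile(v[object$valid], c(.05, .5, .95),
                                   na.rm = TRUE)
  out <- rbind(t1 = q(object$t1), t1_star = q(object$t1_star),
               f_inv = q(object$f_inv))
  colnames(out) <- c("q05", "median", "q95")
  print.psfit_maps(object)
  cat("  quantiles over valid voxels:\n")
  print(round(out, 4))
  invisible(out)
}
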