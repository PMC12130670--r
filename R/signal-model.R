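#' Tissue description for the forward signal model
#'
#' @param t1 Longitudinal relaxation time (ms), positive.
#' @param m0 Equilibrium magnetization / proton density (arbitrary units).
#' @param fT Ratio of local to nominal flip angle (B1+ scaling), >= 0.
#' @return An object of class `mp_tissue`.
#' @export
tissue <- function(t1, m0 = 1, fT = 1) {
  if (!is.numeric(t1) || any(t1 <= 0)) stop("`t1` must be positive (ms)")
  if (any(m0 < 0)) stop("`m0` must be non-negative")
  if (any(fT < 0)) stop("`fT` must be non-negative")
  structure(list(t1 = as.numeric(t1), m0 = as.numeric(m0),
                 fT = as.numeric(fT)), class = "mp_tissue")
}

#' Free longitudinal relaxation
#'
#' Monoexponential recovery of the longitudinal magnetization towards
#' equilibrium: `m0 + (mz - m0) * exp(-dt / t1)`.
#'
#' @param mz Starting longitudinal magnetization.
#' @param m0 Equilibrium magnetization.
#' @param t1 Relaxation time (ms), positive.
#' @param dt Elapsed time (ms), non-negative.
#' @return Magnetization after `dt`.
#' @export
relax_free <- function(mz, m0, t1, dt) {
  if (any(t1 <= 0)) stop("`t1` must be positive")
  if (any(dt < 0)) stop("`dt` must be non-negative")
  m0 + (mz - m0) * exp(-dt / t1)
}

#' Propagate magnetization through one RAGE train
#'
#' Applies `tf` repetitions of {flip-angle scaling by cos(local flip), free
#' relaxation over one echo spacing} in closed form. With
#' `E1 = exp(-tr_echo/t1)` and `c = cos(local flip)` the magnetization after
#' `k` excitations is `mz_driven + (mz_in - mz_driven) (E1 c)^k` with driven
#' equilibrium `mz_driven = m0 (1 - E1) / (1 - E1 c)`; the signal decays
#' towards it with an apparent time constant T1* shorter than T1.
#'
#' @param mz_in Longitudinal magnetization at the start of the train.
#' @param tissue A [tissue()].
#' @param alpha_nominal Nominal flip angle of the train (degrees); the local
#'   flip is `fT * alpha_nominal` and must stay below 90 degrees.
#' @param protocol An [mp_protocol()] supplying `tf`, `tr_echo` and
#'   `center_index`.
#' @return A list with `mz_out` (after the full train) and `mz_center`
#'   (immediately before the excitation of the zeroth k-space line).
#' @export
train_propagate <- function(mz_in, tissue, alpha_nominal, protocol) {
  loc <- tissue$fT * alpha_nominal
  if (any(loc >= 90)) stop("local flip angle must be below 90 degrees")
  E1 <- exp(-protocol$tr_echo / tissue$t1)
  cc <- cos(loc * pi / 180)
  Ec <- E1 * cc
  mzd <- tissue$m0 * (1 - E1) / (1 - Ec)
  k <- protocol$center_index
  list(
    mz_center = mzd + (mz_in - mzd) * Ec^k,
    mz_out = mzd + (mz_in - mzd) * Ec^protocol$tf
  )
}

# Vectorised affine propagation of one full steady-state cycle.
# t1, m0, fT, finv are recycled to a common length n; returns the
# steady-state centre-line magnetization and signed signal for each train
# as n x n_trains matrices. Every step of the cycle (inversion, free
# relaxation, RAGE train) is affine in mz, so the periodic steady state is
# the exact fixed point of the composed map mz' = A mz + B, mz_eq = B/(1-A).
.cycle_affine <- function(protocol, t1, m0, fT, finv) {
  n <- max(length(t1), length(m0), length(fT), length(finv))
  t1 <- rep_len(as.numeric(t1), n)
  m0 <- rep_len(as.numeric(m0), n)
  fT <- rep_len(as.numeric(fT), n)
  finv <- rep_len(as.numeric(finv), n)
  d <- protocol_delays(protocol)
  nt <- protocol$n_trains
  alph <- protocol$alphas * pi / 180
  E1 <- exp(-protocol$tr_echo / t1)

  A <- -finv                       # inversion: mz -> -finv * mz
  B <- numeric(n)
  Ac <- matrix(0, n, nt)
  Bc <- matrix(0, n, nt)
  sinmat <- matrix(0, n, nt)
  for (j in seq_len(nt)) {
    a <- exp(-d$pre[j] / t1)       # free relaxation before train j
    A <- a * A
    B <- a * B + m0 * (1 - a)
    loc <- fT * alph[j]
    if (any(loc >= pi / 2)) stop("local flip angle must be below 90 degrees")
    Ec <- E1 * cos(loc)
    mzd <- m0 * (1 - E1) / (1 - Ec)
    ak <- Ec^protocol$center_index # snapshot at the zeroth k-space line
    Ac[, j] <- ak * A
    Bc[, j] <- ak * B + mzd * (1 - ak)
    af <- Ec^protocol$tf
    A <- af * A
    B <- af * B + mzd * (1 - af)
    sinmat[, j] <- sin(loc)
  }
  a <- exp(-d$tail / t1)
  A <- a * A
  B <- a * B + m0 * (1 - a)

  mz0 <- B / (1 - A)               # magnetization just before the inversion
  mzc <- Ac * mz0 + Bc
  list(mz_center = mzc, signal = sinmat * mzc, mz_pre_inversion = mz0)
}

#' Steady-state train signals over one magnetization-prepared cycle
#'
#' Composes inversion (scaling by `-finv_value`), the free-relaxation delays
#' implied by the protocol timing, and the RAGE-train propagation over one
#' cycle. Because each step is affine in the longitudinal magnetization the
#' periodic steady state is solved exactly as the fixed point of the composed
#' affine map, with no iteration.
#'
#' @param protocol An [mp_protocol()].
#' @param tissue A [tissue()].
#' @param finv_value Apparent inversion efficiency in [0, 1].
#' @return Numeric vector of signed, noiseless centre-line signals
#'   `sin(local flip) * mz_center`, one per train, with attribute
#'   `"mz_center"` holding the underlying longitudinal magnetization.
#' @examples
#' cycle_steady_state(protocol_mp2rage(1), tissue(1365), 0.743)
#' @export
cycle_steady_state <- function(protocol, tissue, finv_value) {
  if (length(finv_value) != 1L || finv_value < 0 || finv_value > 1)
    stop("`finv_value` must be a single number in [0, 1]")
  r <- .cycle_affine(protocol, tissue$t1, tissue$m0, tissue$fT, finv_value)
  out <- drop(r$signal)
  attr(out, "mz_center") <- drop(r$mz_center)
  out
}

#' MP2RAGE uniform (UNI) combination of two train signals
#'
#' For real-valued (signed) model signals the MP2RAGE ratio image is
#' `s1 * s2 / (s1^2 + s2^2)`, bounded in [-0.5, 0.5]. Voxels where both
#' signals vanish get the sentinel value 0 and are flagged.
#'
#' @param s1,s2 Signed centre-line signals of the two trains. Vectorised.
#' @return Values in [-0.5, 0.5]; attribute `"invalid"` flags voxels where
#'   both inputs are zero (if any).
#' @export
uni_combine <- function(s1, s2) {
  den <- s1^2 + s2^2
  bad <- den == 0
  out <- ifelse(bad, 0, s1 * s2 / ifelse(bad, 1, den))
  if (any(bad)) attr(out, "invalid") <- bad
  out
}

#' UNI combination of complex train signals
#'
#' `Re(s1 * Conj(s2)) / (|s1|^2 + |s2|^2)`; reduces to [uni_combine()] for
#' real inputs and is insensitive to a common receiver phase.
#'
#' @param s1,s2 Complex train signals. Vectorised.
#' @return Values in [-0.5, 0.5].
#' @export
uni_combine_complex <- function(s1, s2) {
  den <- Mod(s1)^2 + Mod(s2)^2
  bad <- den == 0
  out <- ifelse(bad, 0, Re(s1 * Conj(s2)) / ifelse(bad, 1, den))
  if (any(bad)) attr(out, "invalid") <- bad
  out
}
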