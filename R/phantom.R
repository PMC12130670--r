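#' Specification of a synthetic brain phantom
#'
#' Describes a three-compartment (WM / GM / CSF) brain-like phantom built
#' from concentric ellipsoids, with a small separately labelled
#' globus-pallidus surrogate (short T1, iron-like) so that calibration
#' exclusion rules can be exercised. Per-voxel T1 is drawn from a truncated
#' normal (+- 3 SD) around the tissue mean; the transmit-field ratio fT and
#' the receiver phase are smooth low-order polynomial fields; the
#' ground-truth apparent inversion efficiency per voxel follows `finv_law`
#' evaluated at the voxel's R1.
#'
#' @param shape Voxel grid triple, default `c(48, 48, 48)`.
#' @param tissue_params Data frame with columns `label`, `name`, `t1_mean`,
#'   `t1_sd` (ms), `m0_mean`, `m0_sd`. Default: WM 1365 +- 40 ms,
#'   GM 1965 +- 60 ms, CSF 4300 +- 150 ms, globus pallidus 1100 +- 30 ms;
#'   proton densities 0.70 / 0.82 / 1.00 / 0.75 (+- 0.02).
#' @param b1_range Range of the smooth fT field, default `c(0.7, 1.2)`.
#' @param finv_law An `finv_model` used as ground truth; default the TR-FOCI
#'   calibration [finv_model_trfoci()].
#' @param phase_range Range of the smooth receiver-phase field (radians).
#' @param noise_sigma Default complex-Gaussian noise SD (per real/imaginary
#'   component, signal units) used by [simulate_acquisition()].
#' @param seed Integer seed; identical spec + seed give identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 48),
                         tissue_params = default_tissue_params(),
                         b1_range = c(0.7, 1.2),
                         finv_law = finv_model_trfoci(),
                         phase_range = c(-1.5, 1.5),
                         noise_sigma = 0,
                         seed = 1L) {
  if (length(shape) != 3L || any(shape < 16))
    stop("degenerate phantom geometry: `shape` must be 3 dims of >= 16 voxels")
  stopifnot(inherits(finv_law, "finv_model"), noise_sigma >= 0)
  if (any(tissue_params$t1_mean <= 0)) stop("tissue T1 means must be positive")
  structure(list(shape = as.integer(shape), tissue_params = tissue_params,
                 b1_range = as.numeric(b1_range), finv_law = finv_law,
                 phase_range = as.numeric(phase_range),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_tissue_params <- function() {
  data.frame(
    label = 1:4,
    name = c("WM", "GM", "CSF", "GP"),
    t1_mean = c(1365, 1965, 4300, 1100),
    t1_sd = c(40, 60, 150, 30),
    m0_mean = c(0.70, 0.82, 1.00, 0.75),
    m0_sd = c(0.02, 0.02, 0.02, 0.02))
}

# truncated normal on mean +- 3 sd via inverse-CDF sampling
.rtruncnorm3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(-3), stats::pnorm(3))
  mean + sd * stats::qnorm(p)
}

# smooth random quadratic field over normalised coords, rescaled to `range`
# within `inside`
.smooth_field <- function(u, inside, range) {
  co <- stats::rnorm(10, sd = 1)
  f <- co[1] + co[2] * u$x + co[3] * u$y + co[4] * u$z +
    co[5] * u$x * u$y + co[6] * u$x * u$z + co[7] * u$y * u$z +
    co[8] * u$x^2 + co[9] * u$y^2 + co[10] * u$z^2
  lo <- min(f[inside]); hi <- max(f[inside])
  if (hi == lo) return(array(mean(range), dim(f)))
  range[1] + (f - lo) / (hi - lo) * (range[2] - range[1])
}

#' Generate a synthetic brain phantom
#'
#' Builds the label geometry (CSF rim, GM shell, WM core, two CSF
#' "ventricles", a globus-pallidus sphere) and draws the per-voxel T1, M0,
#' fT, receiver-phase and ground-truth f_inv volumes from the seeded spec.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `mp_phantom`: integer array `labels`
#'   (0 = background, 1 WM, 2 GM, 3 CSF, 4 globus pallidus) and numeric
#'   arrays `t1`, `m0`, `fT`, `phase`, `finv` (`NA`/0 outside the head),
#'   plus the `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$shape
  ax <- function(n) (seq_len(n) - (n + 1) / 2) / (n / 2)  # [-1, 1]
  x <- array(rep(ax(dm[1]), times = dm[2] * dm[3]), dm)
  y <- array(rep(rep(ax(dm[2]), each = dm[1]), times = dm[3]), dm)
  z <- array(rep(ax(dm[3]), each = dm[1] * dm[2]), dm)
  ell <- function(cx, cy, cz, rx, ry, rz)
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 + ((z - cz) / rz)^2 <= 1

  labels <- array(0L, dm)
  labels[ell(0, 0, 0, 0.92, 0.95, 0.88)] <- 3L           # head: CSF rim
  labels[ell(0, 0, 0, 0.78, 0.82, 0.74)] <- 2L           # GM shell
  labels[ell(0, 0, 0, 0.58, 0.64, 0.55)] <- 1L           # WM core
  labels[ell(-0.16, 0.05, 0, 0.10, 0.22, 0.10)] <- 3L    # ventricles
  labels[ell(0.16, 0.05, 0, 0.10, 0.22, 0.10)] <- 3L
  labels[ell(0.30, -0.20, 0.05, 0.09, 0.09, 0.09)] <- 4L # globus pallidus
  if (!all(1:3 %in% labels))
    stop("degenerate phantom geometry: a tissue class is empty")

  inside <- labels > 0L
  t1 <- array(NA_real_, dm)
  m0 <- array(NA_real_, dm)
  tp <- spec$tissue_params
  for (i in seq_len(nrow(tp))) {
    idx <- which(labels == tp$label[i])
    t1[idx] <- .rtruncnorm3(length(idx), tp$t1_mean[i], tp$t1_sd[i])
    m0[idx] <- pmax(.rtruncnorm3(length(idx), tp$m0_mean[i], tp$m0_sd[i]), 0)
  }
  fT <- .smooth_field(list(x = x, y = y, z = z), inside, spec$b1_range)
  phase <- .smooth_field(list(x = x, y = y, z = z), inside, spec$phase_range)
  fT[!inside] <- NA_real_
  phase[!inside] <- NA_real_
  finv <- array(NA_real_, dm)
  finv[inside] <- finv_evaluate(spec$finv_law, 1000 / t1[inside])
  structure(list(labels = labels, t1 = t1, m0 = m0, fT = fT,
                 phase = phase, finv = finv, spec = spec),
            class = "mp_phantom")
}

#' @export
print.mp_phantom <- function(x, ...) {
  cat(sprintf("Synthetic brain phantom %s, seed %d\n",
              paste(x$spec$shape, collapse = "x"), x$spec$seed))
  tab <- table(factor(x$labels, 0:4,
                      c("background", "WM", "GM", "CSF", "GP")))
  print(tab)
  invisible(x)
}

#' Parenchyma mask of a phantom (WM + GM)
#' @param phantom An [make_phantom()] result.
#' @param include_gp Include the globus-pallidus surrogate.
#' @return Logical array.
#' @export
parenchyma_mask <- function(phantom, include_gp = FALSE) {
  phantom$labels == 1L | phantom$labels == 2L |
    (include_gp & phantom$labels == 4L)
}

#' Forward-simulate a magnetization-prepared acquisition of a phantom
#'
#' Per voxel, the steady-state centre-line signals of all trains are
#' computed from the ground-truth T1, M0, fT and f_inv using the forward
#' cycle model, rotated by the receiver phase, and corrupted by independent
#' complex Gaussian noise (equal SD on the real and imaginary components of
#' every train). A two-train protocol yields an MP2RAGE set; a four-train
#' protocol a PS-MP4RAGE set.
#'
#' @param phantom An [make_phantom()] result.
#' @param protocol An [mp_protocol()].
#' @param noise_sigma Noise SD per component in signal units; `NULL` uses the
#'   spec's value (ignored when `snr` is given).
#' @param snr If given, the noise SD is set to
#'   `median(|last-train signal|) / snr` over the parenchyma: the SNR of the
#'   PD-weighted readout.
#' @param seed Seed for the noise; default derives from the spec seed.
#' @return A [complex_train_set()] whose `alpha_nominal` is the protocol's
#'   first train flip angle (all-equal flip angles assumed for PS fitting);
#'   attributes `noise_sigma` and `seed` record the simulation.
#' @export
simulate_acquisition <- function(phantom, protocol, noise_sigma = NULL,
                                 snr = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "mp_phantom"), inherits(protocol, "mp_protocol"))
  if (is.null(seed)) seed <- phantom$spec$seed + 1000L
  dm <- dim(phantom$labels)
  nt <- protocol$n_trains
  inside <- which(phantom$labels > 0L)
  sig <- .cycle_affine(protocol,
                       phantom$t1[inside], phantom$m0[inside],
                       phantom$fT[inside], phantom$finv[inside])$signal
  vol <- array(0+0i, c(dm, nt))
  rot <- exp(1i * phantom$phase[inside])
  nvox <- prod(dm)
  for (j in seq_len(nt))
    vol[inside + (j - 1L) * nvox] <- sig[, j] * rot

  if (is.null(noise_sigma)) noise_sigma <- phantom$spec$noise_sigma
  if (!is.null(snr)) {
    par <- phantom$labels[inside] %in% c(1L, 2L)
    noise_sigma <- stats::median(abs(sig[par, nt])) / snr
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    n <- length(vol)
    vol <- vol + complex(real = stats::rnorm(n, 0, noise_sigma),
                         imaginary = stats::rnorm(n, 0, noise_sigma))
  }
  out <- complex_train_set(vol, protocol$ti, protocol$t_cycle,
                           protocol$alphas[1], protocol$tr_echo)
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "seed") <- seed
  out
}
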