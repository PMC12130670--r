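#' Write a complex train set as NIfTI volumes plus a JSON sidecar
#'
#' Two 4D NIfTI files (trains along the 4th axis) are written, either
#' real/imaginary or magnitude/phase components, together with
#' `<prefix>.json` recording the timing metadata.
#'
#' @param set A [complex_train_set()].
#' @param prefix Output path prefix; files become
#'   `<prefix>_real.nii.gz` / `<prefix>_imag.nii.gz` (or `_mag` / `_phase`)
#'   and `<prefix>.json`.
#' @param layout `"realimag"` or `"magphase"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_complex_set <- function(set, prefix, layout = c("realimag", "magphase")) {
  stopifnot(inherits(set, "complex_train_set"))
  layout <- match.arg(layout)
  v <- set$volumes
  if (layout == "realimag") {
    a <- Re(v); b <- Im(v)
    pa <- paste0(prefix, "_real.nii.gz"); pb <- paste0(prefix, "_imag.nii.gz")
  } else {
    a <- Mod(v); b <- Arg(v)
    pa <- paste0(prefix, "_mag.nii.gz"); pb <- paste0(prefix, "_phase.nii.gz")
  }
  RNifti::writeNifti(a, pa, datatype = "double")
  RNifti::writeNifti(b, pb, datatype = "double")
  side <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(layout = layout, ti = set$ti, t_cycle = set$t_cycle,
         alpha_nominal = set$alpha_nominal, tr_echo = set$tr_echo,
         noise_sigma = attr(set, "noise_sigma"), seed = attr(set, "seed")),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(a = pa, b = pb, sidecar = side))
}

#' Read a complex train set from NIfTI component volumes
#'
#' @param paths Two NIfTI paths: real+imaginary or magnitude+phase 4D
#'   volumes, trains along the 4th axis.
#' @param layout `"realimag"` or `"magphase"`.
#' @param protocol Optional [mp_protocol()] supplying the timing; if `NULL`,
#'   a `<common prefix>.json` sidecar is required.
#' @param sidecar Optional explicit sidecar path.
#' @return A [complex_train_set()].
#' @export
read_complex_set <- function(paths, layout = c("realimag", "magphase"),
                             protocol = NULL, sidecar = NULL) {
  layout <- match.arg(layout)
  if (length(paths) != 2L) stop("`paths` must name the two component files")
  for (p in paths) if (!file.exists(p)) stop("input file not found: ", p)
  a <- as.array(RNifti::readNifti(paths[1]))
  b <- as.array(RNifti::readNifti(paths[2]))
  if (length(dim(a)) != 4L || length(dim(b)) != 4L)
    stop("format error: expected 4D volumes (trains along the 4th axis)")
  if (!identical(dim(a), dim(b)))
    stop("format error: component volumes differ in shape")
  v <- if (layout == "realimag") complex(real = a, imaginary = b)
       else complex(modulus = a, argument = b)
  v <- array(v, dim(a))
  meta <- if (!is.null(protocol)) {
    list(ti = protocol$ti, t_cycle = protocol$t_cycle,
         alpha_nominal = protocol$alphas[1], tr_echo = protocol$tr_echo)
  } else {
    sc <- sidecar %||% paste0(
      sub("_(real|imag|mag|phase)\\.nii(\\.gz)?$", "", paths[1]), ".json")
    if (!file.exists(sc))
      stop("no protocol given and sidecar not found: ", sc)
    jsonlite::fromJSON(sc, simplifyVector = TRUE)
  }
  complex_train_set(v, meta$ti, meta$t_cycle, meta$alpha_nominal,
                    meta$tr_echo)
}

#' Write fitted maps as NIfTI volumes
#'
#' Writes `t1.nii.gz`, `t1star.nii.gz`, `finv.nii.gz`, `sss.nii.gz` (32-bit
#' floats, T1 in ms, invalid voxels `NaN`) and `valid.nii.gz` (0/1) into a
#' directory.
#'
#' @param maps A [psmp4rage_fit()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fit_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "psfit_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f, datatype = "float")
    RNifti::writeNifti(x, file.path(dir, f), datatype = datatype)
  w(maps$t1, "t1.nii.gz")
  w(maps$t1_star, "t1star.nii.gz")
  w(maps$f_inv, "finv.nii.gz")
  w(maps$s_ss, "sss.nii.gz")
  w(maps$valid + 0, "valid.nii.gz", datatype = "uint8")
  invisible(dir)
}

#' Read a 3D NIfTI volume as a plain array
#' @param path NIfTI file path.
#' @return A numeric array.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  as.array(RNifti::readNifti(path))
}

#' Write an array as NIfTI
#' @param x Numeric array.
#' @param path Destination path.
#' @param datatype NIfTI storage type.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, datatype = "float") {
  RNifti::writeNifti(x, path, datatype = datatype)
  invisible(path)
}
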