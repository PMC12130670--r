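#' Build an MP2RAGE look-up table for T1 mapping
#'
#' Runs the forward steady-state signal model over a grid of T1 values and
#' tabulates the resulting UNI intensity. When the inversion-efficiency model
#' is linear in R1, the efficiency is re-evaluated at every grid point
#' (`f_inv = slope * (1000/t1) + intercept`), so the table embodies the
#' R1-dependent inversion efficiency. The largest strictly monotone
#' contiguous span of the UNI curve is identified; T1 can only be recovered
#' on that span.
#'
#' @param protocol An [mp_protocol()] with at least two trains; the first two
#'   trains form the UNI combination.
#' @param fT Local-to-nominal flip-angle ratio assumed for the table
#'   (a scalar; build one table per B1+ level).
#' @param model An `finv_model` ([finv_constant()], [finv_linear()] or a
#'   fitted calibration).
#' @param t1_grid Ascending T1 grid (ms). Default 50-5000 ms in 5-ms steps.
#' @return An object of class `mp2rage_lut` with fields `t1`, `uni`, `finv`,
#'   `span` (index range of the monotone span), `fT`, `protocol`, `model`.
#' @examples
#' lut <- lut_build(protocol_mp2rage(1), 1, finv_constant(0.96))
#' lut_invert(lut, 0.1)
#' @export
lut_build <- function(protocol, fT = 1, model = finv_constant(0.96),
                      t1_grid = seq(50, 5000, by = 5)) {
  stopifnot(inherits(protocol, "mp_protocol"), inherits(model, "finv_model"))
  if (protocol$n_trains < 2L)
    stop("UNI requires a protocol with at least two trains")
  if (length(fT) != 1L || fT < 0) stop("`fT` must be a single value >= 0")
  if (is.unsorted(t1_grid, strictly = TRUE) || any(t1_grid <= 0))
    stop("`t1_grid` must be strictly ascending and positive")
  f <- finv_evaluate(model, 1000 / t1_grid)
  ncl <- attr(f, "n_clamped")
  if (!is.null(ncl) && ncl > 0) {
    cl <- attr(f, "clamped")
    warning(sprintf(
      "f_inv clamped to [%.3g, %.3g] for %d grid points (T1 %.0f-%.0f ms)",
      model$clamp[1], model$clamp[2], ncl,
      min(t1_grid[cl]), max(t1_grid[cl])))
  }
  sig <- .cycle_affine(protocol, t1_grid, 1, fT, f)$signal
  uni <- uni_combine(sig[, 1], sig[, 2])
  span <- .longest_monotone_span(uni)
  if (is.null(span))
    stop("unusable protocol: the UNI curve has no monotone span")
  structure(list(t1 = as.numeric(t1_grid), uni = as.numeric(uni),
                 finv = as.numeric(f), span = span, fT = fT,
                 protocol = protocol, model = model),
            class = "mp2rage_lut")
}

# longest contiguous run of strictly monotone values; returns c(first, last)
# index or NULL when no two consecutive values differ. Ties break to the
# first (earliest) run.
.longest_monotone_span <- function(x) {
  s <- sign(diff(x))
  if (all(s == 0)) return(NULL)
  r <- rle(s)
  ok <- r$values != 0
  if (!any(ok)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- which(ok)[which.max(r$lengths[ok])]
  c(starts[best], ends[best] + 1L)  # diff index -> value index
}

#' Invert a look-up table: UNI to T1
#'
#' Piecewise-linear interpolation of T1 on the strictly monotone span of the
#' table. UNI values outside the span's range are clamped to the nearest end
#' and flagged.
#'
#' @param lut An [lut_build()] table.
#' @param uni UNI values in [-0.5, 0.5]. Vectorised; `NA`s pass through.
#' @return T1 values (ms) with attribute `"clamped"`: logical, `TRUE` where
#'   the UNI value fell outside the invertible range.
#' @export
lut_invert <- function(lut, uni) {
  stopifnot(inherits(lut, "mp2rage_lut"))
  i <- seq(lut$span[1], lut$span[2])
  u <- lut$uni[i]
  t1 <- lut$t1[i]
  if (u[1] > u[length(u)]) { u <- rev(u); t1 <- rev(t1) }
  lo <- u[1]; hi <- u[length(u)]
  clamped <- !is.na(uni) & (uni < lo | uni > hi)
  x <- pmin(pmax(uni, lo), hi)
  out <- stats::approx(u, t1, xout = x, ties = "ordered")$y
  attr(out, "clamped") <- clamped
  out
}

#' @export
predict.mp2rage_lut <- function(object, uni, ...) lut_invert(object, uni)

#' @export
print.mp2rage_lut <- function(x, ...) {
  cat("MP2RAGE look-up table\n")
  print(x$protocol)
  print(x$model)
  cat(sprintf("  fT = %.3g; grid %.0f-%.0f ms (%d points, step %.3g ms)\n",
              x$fT, min(x$t1), max(x$t1), length(x$t1),
              if (length(x$t1) > 1) x$t1[2] - x$t1[1] else NA))
  cat(sprintf("  monotone span: T1 %.0f-%.0f ms, UNI %.4f..%.4f\n",
              x$t1[x$span[1]], x$t1[x$span[2]],
              x$uni[x$span[1]], x$uni[x$span[2]]))
  invisible(x)
}

#' @export
plot.mp2rage_lut <- function(x, ...) {
  graphics::plot(x$t1, x$uni, type = "l", xlab = "T1 (ms)", ylab = "UNI",
                 main = "MP2RAGE look-up table", ...)
  graphics::abline(v = x$t1[x$span], lty = 3)
  invisible(x)
}

#' Export a look-up table as CSV
#'
#' Writes a two-column table `t1_ms, uni`.
#'
#' @param lut An [lut_build()] table.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
lut_export_csv <- function(lut, path) {
  stopifnot(inherits(lut, "mp2rage_lut"))
  utils::write.csv(data.frame(t1_ms = lut$t1, uni = lut$uni), path,
                   row.names = FALSE)
  invisible(path)
}

#' T1 map from a UNI image and a B1+ map
#'
#' Builds look-up tables for the discretised local flip-angle ratio (bins of
#' width `ft_step`) and inverts every voxel's UNI value with the table
#' matching its fT. Voxels with UNI outside the invertible range are clamped
#' and flagged.
#'
#' @param uni 3D array of UNI values in [-0.5, 0.5] (`NA` outside the head).
#' @param b1 3D array of flip-angle ratios fT, same shape; `NULL` means 1.
#' @param protocol An [mp_protocol()].
#' @param model An `finv_model`.
#' @param mask Optional logical array; voxels outside get `NA`.
#' @param t1_grid T1 grid passed to [lut_build()].
#' @param ft_step Width of the fT bins (dimensionless).
#' @return A list with `t1` (ms, array), `clamped` (logical array).
#' @export
t1map_from_uni <- function(uni, b1 = NULL, protocol, model,
                           mask = NULL, t1_grid = seq(50, 5000, by = 5),
                           ft_step = 0.01) {
  dm <- dim(uni)
  if (is.null(b1)) b1 <- array(1, dm)
  if (!identical(dim(b1), dm))
    stop("shape mismatch between `uni` and `b1`")
  if (is.null(mask)) mask <- array(TRUE, dm)
  if (!identical(dim(mask), dm))
    stop("shape mismatch between `uni` and `mask`")
  t1 <- array(NA_real_, dm)
  clamped <- array(FALSE, dm)
  idx <- which(mask & is.finite(uni) & is.finite(b1))
  if (length(idx)) {
    ftbin <- round(b1[idx] / ft_step) * ft_step
    for (ft in unique(ftbin)) {
      sel <- idx[ftbin == ft]
      lut <- lut_build(protocol, ft, model, t1_grid)
      v <- lut_invert(lut, uni[sel])
      t1[sel] <- v
      clamped[sel] <- attr(v, "clamped")
    }
  }
  list(t1 = t1, clamped = clamped)
}
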