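#' Define an MP*n*RAGE acquisition protocol
#'
#' Describes the timing and flip angles of one magnetization-prepared cycle:
#' an (instantaneous) adiabatic inversion followed by `length(ti)` RAGE
#' readout trains separated by delays of free relaxation. Times are referenced
#' to the centre of the inversion pulse; each inversion time `ti[j]` is the
#' delay to the excitation of the zeroth (contrast-defining) k-space line of
#' train `j`.
#'
#' With linear phase-encode ordering the zeroth k-space line sits at the
#' middle of the train (`center_index = tf %/% 2`); with centric ordering it
#' is the first excitation (`center_index = 0`). The inter-train delays and
#' the tail delay before the next inversion are derived from `ti`, `tf`,
#' `tr_echo` and `center_index`; all must be non-negative for the protocol to
#' be realisable.
#'
#' @param t_cycle Cycle duration between two successive inversion pulses (ms).
#' @param ti Inversion times, one per train (ms), strictly increasing.
#' @param alphas Nominal train flip angles (degrees), one per train.
#' @param tf Turbo factor: number of excitations per train.
#' @param tr_echo Excitation spacing within a train (ms).
#' @param center_index Position of the zeroth k-space line within the train
#'   (0-based). Defaults to `tf %/% 2` for `ordering = "linear"` and `0` for
#'   `ordering = "centric"`.
#' @param ordering Phase-encode ordering, used only to default `center_index`.
#' @param name Optional protocol label.
#' @return An object of class `mp_protocol`.
#' @examples
#' p <- protocol_mp2rage(1)
#' protocol_delays(p)
#' @export
mp_protocol <- function(t_cycle, ti, alphas, tf, tr_echo,
                        center_index = NULL,
                        ordering = c("linear", "centric"),
                        name = NULL) {
  ordering <- match.arg(ordering)
  if (is.null(center_index))
    center_index <- if (ordering == "linear") tf %/% 2 else 0
  if (length(ti) != length(alphas))
    stop("`ti` and `alphas` must have one entry per train")
  if (length(ti) < 1L) stop("at least one train is required")
  if (any(diff(ti) <= 0)) stop("`ti` must be strictly increasing")
  if (t_cycle <= 0 || tr_echo <= 0 || tf < 1)
    stop("invalid protocol: all durations must be positive and tf >= 1")
  if (center_index < 0 || center_index > tf - 1)
    stop("`center_index` must lie within the train (0 .. tf-1)")
  p <- structure(
    list(t_cycle = as.numeric(t_cycle),
         ti = as.numeric(ti),
         alphas = as.numeric(alphas),
         tf = as.integer(tf),
         tr_echo = as.numeric(tr_echo),
         center_index = as.integer(center_index),
         n_trains = length(ti),
         name = name),
    class = "mp_protocol")
  protocol_delays(p)  # errors on infeasible timing
  p
}

#' Free-relaxation delays implied by a protocol
#'
#' @param protocol An [mp_protocol()].
#' @return A list with `pre` (delay before each train, ms; `pre[1]` is the
#'   post-inversion delay) and `tail` (delay from the end of the last train to
#'   the next inversion, ms).
#' @export
protocol_delays <- function(protocol) {
  p <- protocol
  train_len <- p$tf * p$tr_echo
  start <- p$ti - p$center_index * p$tr_echo
  pre <- c(start[1], diff(p$ti) - train_len)
  tail <- p$t_cycle - (start[p$n_trains] + train_len)
  for (j in seq_along(pre)) {
    if (pre[j] < 0)
      stop(sprintf(
        "infeasible protocol timing: delay before train %d is negative (%.2f ms)",
        j, pre[j]))
  }
  if (tail < 0)
    stop(sprintf(
      "infeasible protocol timing: last train ends %.2f ms after the cycle",
      -tail))
  list(pre = pre, tail = tail)
}

#' @export
print.mp_protocol <- function(x, ...) {
  cat(sprintf("MP%dRAGE protocol%s\n", x$n_trains,
              if (is.null(x$name)) "" else paste0(" '", x$name, "'")))
  cat(sprintf("  cycle %.0f ms | TI %s ms | flips %s deg\n",
              x$t_cycle, paste(x$ti, collapse = "/"),
              paste(x$alphas, collapse = "/")))
  cat(sprintf("  turbo factor %d, echo spacing %.2f ms, zeroth line at index %d\n",
              x$tf, x$tr_echo, x$center_index))
  invisible(x)
}

#' Built-in MP2RAGE protocols
#'
#' Three 7T MP2RAGE protocols with differing timings and flip angles,
#' all using linear phase-encode ordering:
#' \describe{
#'   \item{1}{cycle 5000 ms, TI 900/2750 ms, flips 5/3 deg, TF 256,
#'     TR 6.8 ms. High WM-GM-CSF contrast variant; the package default.}
#'   \item{2}{cycle 8250 ms, TI 1000/3300 ms, flips 7/5 deg, TF 160,
#'     TR 6.9 ms. The classic 7T protocol.}
#'   \item{3}{cycle 6000 ms, TI 900/2700 ms, flips 7/5 deg, TF 256,
#'     TR 6.9 ms. Accelerated high-resolution variant.}
#' }
#' @param which Protocol number, 1, 2 or 3.
#' @return An [mp_protocol()] with two trains.
#' @export
protocol_mp2rage <- function(which = 1) {
  switch(as.character(which),
    "1" = mp_protocol(5000, c(900, 2750), c(5, 3), 256, 6.8,
                      name = "MP2RAGE #1"),
    "2" = mp_protocol(8250, c(1000, 3300), c(7, 5), 160, 6.9,
                      name = "MP2RAGE #2"),
    "3" = mp_protocol(6000, c(900, 2700), c(7, 5), 256, 6.9,
                      name = "MP2RAGE #3"),
    stop("unknown MP2RAGE protocol: ", which))
}

#' Built-in PS-MP4RAGE protocol
#'
#' Four identical low-flip-angle trains per inversion cycle for
#' phase-sensitive inversion-recovery fitting: flip 2 deg, TR 7.45 ms,
#' TF 192, cycle 5738 ms, linear ordering. The inversion times are
#' 725/2156/3587/5018 ms: an even spacing of 1431 ms, the smallest spacing
#' that accommodates contiguous 192-excitation trains (192 x 7.45 =
#' 1430.4 ms) with the zeroth line at mid-train.
#'
#' @return An [mp_protocol()] with four trains.
#' @export
protocol_psmp4rage <- function() {
  mp_protocol(5738, c(725, 2156, 3587, 5018), rep(2, 4), 192, 7.45,
              name = "PS-MP4RAGE")
}

#' Read a protocol from a YAML or JSON config file
#'
#' The file must contain keys `t_cycle`, `ti`, `alphas`, `tf`, `tr_echo` and
#' optionally `center_index`, `ordering`, `name`. Units are fixed: ms and
#' degrees.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [mp_protocol()].
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("t_cycle", "ti", "alphas", "tf", "tr_echo")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("protocol file misses keys: ", paste(missing, collapse = ", "))
  mp_protocol(cfg$t_cycle, cfg$ti, cfg$alphas, cfg$tf, cfg$tr_echo,
              center_index = cfg$center_index,
              ordering = if (is.null(cfg$ordering)) "linear" else cfg$ordering,
              name = cfg$name)
}

#' Write a protocol to a YAML or JSON config file
#'
#' @param protocol An [mp_protocol()].
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  x <- unclass(protocol)
  x$n_trains <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  invisible(path)
}

# resolve a --protocol CLI/file argument: preset name or config path
.resolve_protocol <- function(spec) {
  if (inherits(spec, "mp_protocol")) return(spec)
  key <- tolower(gsub("[ _-]", "", as.character(spec)))
  switch(key,
    "mp2rage1" = , "mp2rage#1" = protocol_mp2rage(1),
    "mp2rage2" = , "mp2rage#2" = protocol_mp2rage(2),
    "mp2rage3" = , "mp2rage#3" = protocol_mp2rage(3),
    "psmp4rage" = protocol_psmp4rage(),
    read_protocol(spec))
}
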