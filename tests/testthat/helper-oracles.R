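# Brute-force per-pulse oracles: explicit loops over every excitation and
# cycle, independent of the closed-form / affine fixed-point implementation.

brute_relax <- function(mz, m0, t1, dt) m0 + (mz - m0) * exp(-dt / t1)

# one RAGE train, pulse by pulse; snapshot before the center_index-th pulse
brute_train <- function(mz, m0, t1, flip_deg, tr, tf, center_index) {
  cc <- cos(flip_deg * pi / 180)
  mzc <- NA_real_
  for (k in 0:(tf - 1)) {
    if (k == center_index) mzc <- mz
    mz <- brute_relax(mz * cc, m0, t1, tr)
  }
  list(mz_out = mz, mz_center = mzc)
}

# iterate whole cycles until the periodic steady state, recording centres
brute_cycle <- function(protocol, t1, m0, fT, finv, n_cycles = 80) {
  d <- protocol_delays(protocol)
  mz <- m0
  centers <- numeric(protocol$n_trains)
  for (cy in seq_len(n_cycles)) {
    mz <- -finv * mz
    for (j in seq_len(protocol$n_trains)) {
      mz <- brute_relax(mz, m0, t1, d$pre[j])
      r <- brute_train(mz, m0, t1, fT * protocol$alphas[j],
                       protocol$tr_echo, protocol$tf, protocol$center_index)
      centers[j] <- r$mz_center
      mz <- r$mz_out
    }
    mz <- brute_relax(mz, m0, t1, d$tail)
  }
  list(mz_center = centers,
       signal = sin(fT * protocol$alphas * pi / 180) * centers)
}

# small phantom spec used across tests (kept >= the 16-voxel minimum)
tiny_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(24, 24, 24), seed = seed, ...)
}

# forward-simulated UNI of a two-train protocol at one T1
uni_combine2_at <- function(protocol, fT, model, t1) {
  f <- as.numeric(finv_evaluate(model, 1000 / t1))
  s <- cycle_steady_state(protocol, tissue(t1, 1, fT), f)
  as.numeric(uni_combine(s[1], s[2]))
}
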