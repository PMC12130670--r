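test_that("free relaxation obeys the monoexponential recovery law", {
  expect_equal(relax_free(1, 1, 1234, 999), 1)        # equilibrium fixed point
  expect_equal(relax_free(-1, 1, 1000, 1e9), 1)       # asymptotic limit
  expect_equal(relax_free(0, 1, 1000, 1000 * log(2)), 0.5)
  expect_equal(relax_free(0.3, 1, 800, 0), 0.3)       # dt = 0 identity
  expect_error(relax_free(0, 1, -5, 10), "positive")
  expect_error(relax_free(0, 1, 100, -1), "non-negative")
})

test_that("closed-form train propagation matches the per-pulse loop", {
  set.seed(42)
  for (rep in 1:25) {
    t1 <- runif(1, 300, 4500)
    m0 <- runif(1, 0.3, 1.2)
    fT <- runif(1, 0.6, 1.3)
    alpha <- runif(1, 0.5, 8)
    tf <- sample(c(32, 128, 192, 256), 1)
    tr <- runif(1, 5, 9)
    ci <- sample(0:(tf - 1), 1)
    mz_in <- runif(1, -1, 1)
    p <- mp_protocol(t_cycle = 20000, ti = ci * tr + 1,
                     alphas = alpha, tf = tf, tr_echo = tr,
                     center_index = ci)
    got <- train_propagate(mz_in, tissue(t1, m0, fT), alpha, p)
    want <- brute_train(mz_in, m0, t1, fT * alpha, tr, tf, ci)
    expect_lt(abs(got$mz_out - want$mz_out) / abs(want$mz_out), 1e-12)
    expect_lt(abs(got$mz_center - want$mz_center) /
                max(abs(want$mz_center), 1e-12), 1e-12)
  }
})

test_that("train propagation limits: no excitation and first-line train", {
  p <- mp_protocol(20000, ti = 96 * 7.45, alphas = 2, tf = 192,
                   tr_echo = 7.45, center_index = 96)
  tis <- tissue(1365, 0.9, 1)
  got <- train_propagate(-0.5, tis, 0, p)
  expect_equal(got$mz_out, relax_free(-0.5, 0.9, 1365, 192 * 7.45))
  p1 <- mp_protocol(20000, ti = 1, alphas = 2, tf = 1, tr_echo = 7.45,
                    center_index = 0)
  expect_equal(train_propagate(-0.74, tis, 2, p1)$mz_center, -0.74)
  expect_error(train_propagate(0.5, tissue(1000, 1, 1.2), 80, p),
               "below 90")
})

test_that("zero-flip cycle reduces to classic periodic inversion recovery", {
  # with alpha = 0 the trains are pure relaxation, so the centre-line
  # magnetization must follow mz(TI) = m0 (1 - 2 exp(-TI/T1) / (1 + exp(-tC/T1)))
  p <- mp_protocol(6000, ti = c(800, 2600), alphas = c(0, 0), tf = 64,
                   tr_echo = 6, center_index = 32)
  for (t1 in c(400, 1365, 2163, 4300)) {
    s <- cycle_steady_state(p, tissue(t1, 1, 1), 1)
    mzc <- attr(s, "mz_center")
    want <- 1 - 2 * exp(-p$ti / t1) / (1 + exp(-p$t_cycle / t1))
    expect_lt(max(abs(mzc - want) / abs(want)), 1e-9)
    expect_equal(as.numeric(s), c(0, 0))  # no flip, no signal
  }
})

test_that("steady-state cycle matches the iterated per-pulse oracle", {
  p <- protocol_mp2rage(1)
  for (case in list(list(t1 = 1365, fT = 1, finv = 0.743),
                    list(t1 = 1965, fT = 0.8, finv = 0.85),
                    list(t1 = 4300, fT = 1.15, finv = 0.96))) {
    got <- cycle_steady_state(p, tissue(case$t1, 1, case$fT), case$finv)
    want <- brute_cycle(p, case$t1, 1, case$fT, case$finv)
    expect_equal(length(got), 2L)
    expect_equal(as.numeric(got), want$signal, tolerance = 1e-10)
  }
})

test_that("without inversion the first-train magnetization is non-negative", {
  p <- protocol_mp2rage(1)
  for (t1 in c(300, 900, 1365, 3000))
    expect_gte(attr(cycle_steady_state(p, tissue(t1), 0), "mz_center")[1], 0)
})

test_that("infeasible timing is rejected naming the offending segment", {
  expect_error(mp_protocol(5000, c(900, 2000), c(5, 3), 256, 6.8),
               "delay before train 2")
  expect_error(mp_protocol(3500, c(900, 2750), c(5, 3), 256, 6.8),
               "after the cycle")
  expect_error(cycle_steady_state(protocol_mp2rage(1), tissue(1000), 1.2),
               "0, 1")
})

test_that("UNI combination is bounded and handles degenerate inputs", {
  expect_equal(uni_combine(0.3, 0.3), 0.5)
  expect_equal(uni_combine(0.3, -0.3), -0.5)
  expect_equal(as.numeric(uni_combine(0, 0.4)), 0)
  z <- uni_combine(0, 0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "invalid"))
  set.seed(7)
  s1 <- rnorm(2000); s2 <- rnorm(2000)
  u <- uni_combine(s1, s2)
  expect_true(all(u >= -0.5 & u <= 0.5))
  # complex form agrees with the real form up to a common receiver phase
  ph <- runif(2000, -pi, pi)
  uc <- uni_combine_complex(s1 * exp(1i * ph), s2 * exp(1i * ph))
  expect_equal(uc, as.numeric(u), tolerance = 1e-12)
})
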