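test_that("reference phase is the circular mean of the late-train phases", {
  expect_equal(phase_reference(exp(1i * c(0.3, 0.3, 0.3))), 0.3)
  expect_equal(phase_reference(exp(1i * c(0.1, -0.1))), 0)
  # direct phasor-sum oracle, magnitudes must not matter when unweighted
  ph <- c(0.2, 0.4, 2.9)
  want <- Arg(sum(exp(1i * ph)))
  expect_equal(phase_reference(c(5, 0.1, 2) * exp(1i * ph)), want)
  expect_true(is.na(phase_reference(c(0+0i, 0+0i))))
  expect_error(phase_reference(1 + 0i), "at least 2")
})

test_that("signed signals restore magnetization polarity", {
  expect_equal(signed_signal(2 * exp(1i * 0.7), 0.7), 2)
  expect_equal(signed_signal(2 * exp(1i * (0.7 + pi)), 0.7), -2)
  expect_equal(signed_signal(1 + 1i, 0), 1)
  set.seed(11)
  s <- complex(real = rnorm(50), imaginary = rnorm(50))
  phi <- runif(50, -pi, pi)
  expect_equal(signed_signal(s, phi) + signed_signal(s * exp(1i * pi), phi),
               rep(0, 50), tolerance = 1e-12)
})

test_that("noiseless inversion-recovery curves are recovered exactly", {
  ti <- c(725, 2146, 3576, 5006)
  truth <- list(s_ss = 1, s_start = -0.8, t1_star = 1200)
  y <- truth$s_ss - (truth$s_ss - truth$s_start) * exp(-ti / truth$t1_star)
  fit <- fit_monoexp(ti, y)
  expect_true(fit$valid)
  expect_lt(abs(fit$s_ss - 1), 1e-6)
  expect_lt(abs(fit$s_start + 0.8) / 0.8, 1e-6)
  expect_lt(abs(fit$t1_star - 1200) / 1200, 1e-6)
})

test_that("degenerate and undersampled inputs are rejected or flagged", {
  expect_false(fit_monoexp(c(725, 2146, 3576, 5006), rep(0.4, 4))$valid)
  expect_error(fit_monoexp(c(1, 2, 3), c(1, 2, 3)), "at least 4")
})

test_that("the fit is unbiased at moderate noise (Monte-Carlo)", {
  ti <- c(725, 2146, 3576, 5006)
  y0 <- 1 - (1 - (-0.8)) * exp(-ti / 1200)
  set.seed(99)
  n <- 1000
  Y <- matrix(y0, n, 4, byrow = TRUE) + matrix(rnorm(4 * n, 0, 0.01), n, 4)
  r <- psmp4rage:::.monoexp_lm(ti, Y)
  expect_gt(mean(r$converged), 0.99)
  bias <- abs(mean(r$t1_star[r$converged]) - 1200) / 1200
  expect_lt(bias, 0.02)
})

test_that("the vectorised fit agrees with an independent NLS solver", {
  skip_if_not_installed("minpack.lm")
  ti <- c(725, 2146, 3576, 5006)
  set.seed(3)
  for (rep in 1:12) {
    p <- c(s_ss = runif(1, 0.5, 1.5), s_start = runif(1, -1.2, -0.3),
           t1_star = runif(1, 600, 2500))
    y <- p[1] - (p[1] - p[2]) * exp(-ti / p[3]) + rnorm(4, 0, 0.005)
    fit <- fit_monoexp(ti, y)
    ref <- minpack.lm::nlsLM(
      y ~ a - (a - b) * exp(-ti / tt),
      start = list(a = y[4], b = y[1], tt = 1500),
      lower = c(-Inf, -Inf, 50), upper = c(Inf, Inf, 8000),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- coef(ref)
    expect_equal(fit$s_ss, unname(co["a"]), tolerance = 1e-4)
    expect_equal(fit$s_start, unname(co["b"]), tolerance = 1e-3)
    expect_equal(fit$t1_star, unname(co["tt"]), tolerance = 1e-4)
  }
})

test_that("inversion efficiency follows from the fitted end-of-cycle signal", {
  fit <- list(s_ss = 1, s_start = -0.8, t1_star = 1200)
  want <- 0.8 / (1 - 1.8 * exp(-5738 / 1200))
  expect_equal(finv_from_fit(fit, 5738), want)
  # saturation limit: t1_star << t_cycle means s_end -> s_ss
  fit2 <- list(s_ss = 1, s_start = -0.8, t1_star = 100)
  expect_equal(finv_from_fit(fit2, 50000), 0.8, tolerance = 1e-10)
  # perfect inversion: parameters crafted so that s_start = -s_end
  E <- exp(-5738 / 2000)
  f3 <- list(s_ss = 1, s_start = -(1 - E) / (1 + E), t1_star = 2000)
  expect_equal(finv_from_fit(f3, 5738), 1, tolerance = 1e-12)
  # vanishing end-of-cycle signal is flagged undefined
  s_start0 <- 1 - 1 / exp(-1200 / 1200)
  expect_true(is.na(finv_from_fit(list(s_ss = 1, s_start = s_start0,
                                       t1_star = 1200), 1200)))
})

test_that("T1* converts to T1 by the small-angle readout correction", {
  expect_equal(t1_from_t1star(1200, 0, 2, 7.45), 1200)
  expect_equal(t1_from_t1star(1200, 1, 0, 7.45), 1200)
  a <- 2 * pi / 180
  want <- 1 / (1 / 1200 - a^2 / (2 * 7.45))
  expect_equal(t1_from_t1star(1200, 1, 2, 7.45), want)
  # the correction uses the *local* flip angle squared by default
  want08 <- 1 / (1 / 1200 - (0.8 * a)^2 / (2 * 7.45))
  expect_equal(t1_from_t1star(1200, 0.8, 2, 7.45), want08)
  # literal fT * alpha^2 reading available behind the switch
  wantlit <- 1 / (1 / 1200 - 0.8 * a^2 / (2 * 7.45))
  expect_equal(t1_from_t1star(1200, 0.8, 2, 7.45, ft_squared = FALSE),
               wantlit)
  expect_true(is.na(t1_from_t1star(8000, 1.3, 10, 7)))  # non-positive rate
})

test_that("noiseless driven-equilibrium mismatch stays below 2 percent", {
  # the monoexponential model is an approximation during the readout trains;
  # at 2 degrees the residual T1 error after the correction must be < 2%
  p <- protocol_psmp4rage()
  law <- finv_model_trfoci()
  for (t1 in c(1100, 1365, 1965, 2800)) {
    f <- as.numeric(finv_evaluate(law, 1000 / t1))
    s <- cycle_steady_state(p, tissue(t1, 0.8, 1), f)
    fit <- fit_monoexp(p$ti, as.numeric(s))
    t1_hat <- t1_from_t1star(fit$t1_star, 1, p$alphas[1], p$tr_echo)
    expect_lt(abs(t1_hat - t1) / t1, 0.02)
    expect_lt(abs(finv_from_fit(fit, p$t_cycle) - f), 0.01)
  }
})

test_that("voxelwise fitting recovers a noiseless phantom", {
  ph <- make_phantom(tiny_phantom_spec(seed = 5))
  set <- simulate_acquisition(ph, protocol_psmp4rage(), noise_sigma = 0)
  mask <- parenchyma_mask(ph)
  maps <- psmp4rage_fit(set, b1 = ph$fT, mask = mask)
  ok <- maps$valid & mask
  rel <- abs(maps$t1[ok] - ph$t1[ok]) / ph$t1[ok]
  expect_gte(mean(rel <= 0.02), 0.99)
  expect_lt(median(abs(maps$f_inv[ok] - ph$finv[ok])), 0.01)
  expect_gte(maps$t1[ok][1], maps$t1_star[ok][1])  # correction lengthens T1
})

test_that("fit contracts: empty mask, grid mismatch, polarity flags", {
  ph <- make_phantom(tiny_phantom_spec(seed = 6))
  set <- simulate_acquisition(ph, protocol_psmp4rage(), noise_sigma = 0)
  empty <- psmp4rage_fit(set, mask = array(FALSE, dim(ph$labels)))
  expect_equal(sum(empty$valid), 0)
  expect_equal(empty$n_masked, 0)
  expect_error(psmp4rage_fit(set, b1 = array(1, c(2, 2, 2))),
               "shape mismatch")
  expect_error(psmp4rage_fit(set, mask = array(TRUE, c(2, 2, 2))),
               "shape mismatch")
  # a voxel whose late train is phase-flipped gets flagged, not corrected
  vol <- array(0.5 + 0i, c(1, 1, 1, 4))
  vol[1, 1, 1, ] <- c(-0.4, 0.3, 0.4, -0.45) + 0i
  ts <- complex_train_set(vol, c(725, 2146, 3576, 5006), 5738, 2, 7.45)
  m <- psmp4rage_fit(ts)
  expect_false(m$polarity_ok[1, 1, 1])
  expect_gt(m$invalid_counts["polarity"], 0)
})

test_that("train-set construction validates its invariants", {
  vol <- array(1 + 0i, c(2, 2, 2, 2))
  two <- complex_train_set(vol, c(700, 2000), 5738, 2, 7.45)
  expect_error(psmp4rage_fit(two), "at least 3")
  vol4 <- array(1 + 0i, c(2, 2, 2, 4))
  expect_error(complex_train_set(vol4, c(700, 2000, 1500, 5000), 5738, 2,
                                 7.45), "increasing")
  expect_error(complex_train_set(vol4, c(700, 2000, 3000), 5738, 2, 7.45),
               "one entry per train")
})
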