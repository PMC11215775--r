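# Random-number differences, log-weight assembly and the file formats.

test_that("delta_eta vanishes without a perturbation force and flips for biases", {
  lp <- langevin_params(0.002, 3, 300, c(1, 2))
  op <- operator_params(lp)
  zero <- list(before = c(0, 0), intermediate = c(0, 0), after = c(0, 0))
  g <- list(before = c(0.3, -1), intermediate = c(0.5, 0.1),
            after = c(-0.2, 0.8))
  for (sch in c("ABO", "ABOBA", "AOBOA", "BOAOB", "OBABO")) {
    scheme <- parse_scheme(sch)
    d0 <- delta_eta(scheme, op, zero)
    expect_identical(d0$delta1, c(0, 0))
    if (!is.null(d0$delta2)) expect_identical(d0$delta2, c(0, 0))
    # bias input is the sign-flipped perturbation (U = -U_bias)
    dp <- delta_eta(scheme, op, g)
    db <- delta_eta(scheme, op, lapply(g, `-`), as_bias = TRUE)
    expect_identical(dp$delta1, db$delta1)
    if (!is.null(dp$delta2)) expect_identical(dp$delta2, db$delta2)
  }
  expect_error(delta_eta(parse_scheme("ABO"),
                         operator_params(langevin_params(0.002, 0, 300, 1)),
                         list(after = 1)),
               "f = 0")
  expect_error(delta_eta(parse_scheme("ABOBA"), op, list(after = c(1, 1))),
               "intermediate")
})

test_that("log_m_increment matches the Gaussian density-ratio identity", {
  lp <- langevin_params(0.002, 3, 300, 1)
  op <- operator_params(lp)
  scheme <- parse_scheme("ABO")
  # quadratic-term-only case
  de <- delta_eta(scheme, op, list(after = op$f / (op$d * lp$dt) * 1e-3))
  expect_equal(de$delta1, 1e-3, tolerance = 1e-15)
  expect_equal(log_m_increment(list(0), de), 0.5 * 1e-6, tolerance = 1e-12)
  expect_identical(log_m_increment(list(0.7),
                                   delta_eta(scheme, op, list(after = 0))),
                   0)
  # exp(-s) equals the ratio of shifted to unshifted normal densities
  set.seed(15)
  for (i in 1:200) {
    eta <- rnorm(3)
    delta <- rnorm(3, sd = 0.3)
    de <- delta_eta(scheme, op,
                    list(after = delta * op$f / (op$d * lp$dt)))
    s <- log_m_increment(list(eta), de)
    ratio <- sum(dnorm(eta + delta, log = TRUE) - dnorm(eta, log = TRUE))
    expect_equal(-s, ratio, tolerance = 1e-12)
  }
  expect_error(log_m_increment(list(c(1, 2)),
                               delta_eta(scheme, op, list(after = 1))),
               "mismatch")
})

test_that("exp(-s_k) equals the one-step transition-density ratio (oracle)", {
  # every supported scheme, random states/noises, harmonic + polynomial U
  lp <- langevin_params(0.002, 3, 300, c(1.3, 0.8))
  op <- operator_params(lp)
  target <- harmonic_potential(c(50, 80))
  U <- bias_potential("polynomial", k = 5,
                      coefficients = c(0.3, -0.2, 0.05), ndim = 2)
  pair <- potential_pair(target, perturbation = U)
  set.seed(77)
  for (sch in c("ABO", "ABOBA", "AOBOA", "BOAOB", "OBABO")) {
    scheme <- parse_scheme(sch)
    worst <- 0
    for (i in 1:200) {
      st <- phase_state(rnorm(2, 0, 0.3), rnorm(2, 0, sqrt(lp$rt)))
      stp <- step_langevin(st, scheme, pair, lp)
      inv <- invert_step_noise(st, stp$state, scheme, pair$V_target, lp)
      if (scheme$combined) {
        v <- 1 + op$d_half^2
        comb <- op$d_half * stp$noise[[1]] + stp$noise[[2]]
        ratio <- sum(dnorm(inv$eta1, sd = sqrt(v), log = TRUE) -
                       dnorm(comb, sd = sqrt(v), log = TRUE))
      } else if (is.null(inv$eta2)) {
        ratio <- sum(dnorm(inv$eta1, log = TRUE) -
                       dnorm(stp$noise[[1]], log = TRUE))
      } else {
        ratio <- sum(dnorm(inv$eta1, log = TRUE) -
                       dnorm(stp$noise[[1]], log = TRUE)) +
          sum(dnorm(inv$eta2, log = TRUE) -
                dnorm(stp$noise[[2]], log = TRUE))
      }
      worst <- max(worst, abs(-stp$increment - ratio))
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("interval accumulation is exact and order-insensitive", {
  expect_identical(accumulate_interval(rep(0, 10), 10), 0)
  expect_identical(accumulate_interval(rep(0.1, 10), 10), sum(rep(0.1, 10)))
  expect_error(accumulate_interval(1:5, 10), "expected 10")
  # streaming (simulate with n_out = 1) equals batch grouping (n_out = 10)
  pair <- potential_pair(harmonic_potential(20),
                         bias = bias_potential("linear", 2, ndim = 1))
  lp <- langevin_params(0.002, 5, 300, 1)
  fine <- simulate_langevin(pair, "ABOBA", lp, 0.1, p0 = 0.2,
                            n_steps = 100, n_out = 1, seed = 8)
  coarse <- simulate_langevin(pair, "ABOBA", lp, 0.1, p0 = 0.2,
                              n_steps = 100, n_out = 10, seed = 8)
  batch <- vapply(1:10, function(j)
    sum(fine$records$dS[(10 * (j - 1) + 2):(10 * j + 1)]), 0)
  expect_equal(coarse$records$dS[-1], batch, tolerance = 1e-15)
})

test_that("the initial-state ratio is the Boltzmann ratio of the first frame", {
  rt <- 2.494
  expect_identical(initial_state_log_ratio(0, rt), 0)
  expect_equal(initial_state_log_ratio(-rt, rt), 1)
  expect_error(initial_state_log_ratio(1, 0), "RT")
  # density-ratio oracle on a harmonic toy: for U = -c q the weight
  # exp(log g) must reproduce exp(-Vtilde/RT) / exp(-V/RT) pointwise
  k <- 10; cc <- 2
  for (q in seq(-1, 1, length.out = 11)) {
    u <- -cc * q                       # perturbation energy at q
    direct <- (-(0.5 * k * q^2 - cc * q) + 0.5 * k * q^2) / rt
    expect_equal(initial_state_log_ratio(u, rt), direct, tolerance = 1e-12)
  }
})

test_that("window weights reduce, telescope and importance-sample correctly", {
  lp <- langevin_params(0.002, 5, 300, 1)
  # U == 0: every window weight is exactly 1
  p0 <- potential_pair(harmonic_potential(10),
                       bias = bias_potential("linear", 0, ndim = 1))
  t0 <- simulate_langevin(p0, "ABOBA", lp, 0, n_steps = 500, n_out = 10,
                          seed = 2)
  expect_identical(t0$records$dS, rep(0, 51))
  w0 <- window_log_weights(t0, 5)
  expect_identical(w0$log_w, rep(0, 46))

  # telescoping additivity of log M
  pb <- potential_pair(harmonic_potential(10),
                       bias = bias_potential("linear", 2, ndim = 1))
  tb <- simulate_langevin(pb, "ABOBA", lp, 0, n_steps = 500, n_out = 10,
                          seed = 2)
  for (s in c(1, 10, 30)) {
    expect_equal(window_weight(tb, s, 2)$log_M,
                 window_weight(tb, s, 1)$log_M +
                   window_weight(tb, s + 1, 1)$log_M, tolerance = 1e-12)
  }
  expect_error(window_weight(tb, 50, 5), "exceeds")
  expect_error(window_log_weights(tb, 0), "n_interval")

  # importance-sampling identity: V = k q^2 / 2 simulated, target shifted
  k <- 10; cc <- 2
  target <- potential_sum(harmonic_potential(k),
                          scale_potential(bias_potential("linear", cc,
                                                         ndim = 1), -1))
  pair <- potential_pair(target, bias = bias_potential("linear", cc,
                                                       ndim = 1))
  traj <- simulate_langevin(pair, "ABOBA", lp, 0, n_steps = 5e5,
                            n_out = 10, seed = 33)
  lw <- window_log_weights(traj, 20)
  w <- exp(lw$log_w - max(lw$log_w))
  q_end <- traj$q[lw$start_row + 20, 1]
  est <- weighted_block_estimates(w, q_end, 40)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - cc / k), 3 * se)
})

test_that("reweighting files round-trip losslessly and validate alignment", {
  pair <- potential_pair(harmonic_potential(10),
                         bias = bias_potential("linear", 1, ndim = 1))
  lp <- langevin_params(0.002, 5, 300, 1)
  traj <- simulate_langevin(pair, "ABOBA", lp, 0.3, n_steps = 60,
                            n_out = 10, seed = 4)
  fr <- tempfile(fileext = ".tsv")
  fp <- tempfile(fileext = ".tsv")
  write_reweighting_file(traj, fr)
  write_position_file(traj, fp)
  rec <- read_reweighting_file(fr)
  expect_identical(rec$dS, traj$records$dS)
  expect_identical(rec$U_kJ_per_mol, traj$records$U_kJ_per_mol)
  expect_identical(rec$frame_index, traj$records$frame_index)
  pos <- read_position_file(fp)
  expect_identical(as.numeric(pos$q[, 1]), traj$q[, 1])

  # hand-written three-row fixture
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("frame_index\ttime_ps\tdS\tU_kJ_per_mol",
               "0\t0\t0\t0.5",
               "1\t0.005\t-0.25\t0.125",
               "2\t0.01\t0.0625\t-2"), f3)
  r3 <- read_reweighting_file(f3)
  expect_identical(r3$dS, c(0, -0.25, 0.0625))
  expect_identical(r3$U_kJ_per_mol, c(0.5, 0.125, -2))

  # empty trajectory: header-only file reads back as zero records
  empty <- traj$records[0, ]
  fe <- tempfile(fileext = ".tsv")
  write_reweighting_file(empty, fe)
  expect_identical(nrow(read_reweighting_file(fe)), 0L)

  # misaligned frame indices are reported with the first bad row
  fbad <- tempfile(fileext = ".tsv")
  writeLines(c("frame_index\ttime_ps\tdS\tU_kJ_per_mol",
               "0\t0\t0\t0.5",
               "2\t0.01\t0.1\t0.2"), fbad)
  expect_error(read_reweighting_file(fbad), "row 2")
  fcols <- tempfile(fileext = ".tsv")
  writeLines("frame\tdS", fcols)
  expect_error(read_reweighting_file(fcols), "columns")
})
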