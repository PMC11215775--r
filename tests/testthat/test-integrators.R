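# Splitting-scheme parsing, operator parameters and integrator behaviour.

test_that("scheme strings parse, alias and validate correctly", {
  s <- parse_scheme("ABOBA")
  expect_identical(s$letters, c("A", "B", "O", "B", "A"))
  expect_identical(s$half, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(s$canonical, "ABOBA")
  expect_identical(s$n_noise, 1L)
  expect_true(s$reweightable)

  r <- parse_scheme("R V O V R")   # velocity alphabet, spaces, any case
  expect_identical(r$letters, s$letters)
  expect_identical(r$half, s$half)
  expect_identical(parse_scheme("rvo")$canonical, "ABO")

  two <- parse_scheme("AOBOA")
  expect_identical(two$n_noise, 2L)
  expect_true(two$combined)
  expect_identical(parse_scheme("BOAOB")$eval_points, c("before", "after"))

  expect_error(parse_scheme("ABX"), "unknown update operator")
  expect_error(parse_scheme(""), "empty")
  expect_error(parse_scheme("BAOAB"), "reweighting is undefined")
  baoab <- parse_scheme("BAOAB", require_reweightable = FALSE)
  expect_false(baoab$reweightable)
  expect_identical(baoab$n_noise, 1L)
})

test_that("operator parameters obey the fluctuation-dissipation identities", {
  lp <- langevin_params(dt = 5e-4, xi = 5, temperature = 300,
                        masses = c(1, 2.5))
  op <- operator_params(lp)
  expect_equal(op$d, exp(-0.0025))
  # stationarity: d^2 RT M + f^2 = RT M, per dof
  expect_equal(op$d^2 * lp$rt * lp$masses + op$f^2, lp$rt * lp$masses,
               tolerance = 1e-12)
  expect_equal(op$d_half^2, op$d, tolerance = 1e-15)
  # two half O-steps compose to one full step in distribution
  expect_equal(op$f_half^2 * (1 + op$d_half^2), op$f^2, tolerance = 1e-12)

  # frictionless and zero-temperature limits
  op0 <- operator_params(langevin_params(1e-3, 0, 300, 1))
  expect_identical(op0$d, 1)
  expect_identical(op0$f, 0)
  opT0 <- operator_params(langevin_params(1e-3, 5, 0, 1))
  expect_identical(opT0$f, 0)
})

test_that("update operators act on their own variables only", {
  lp <- langevin_params(0.1, 2, 300, 1)
  op <- operator_params(lp)
  h <- harmonic_potential(1)
  st <- phase_state(1, 0.3)

  a <- apply_operator("A", st, h, op)
  expect_identical(a$p, st$p)
  expect_equal(a$q, 1 + 0.1 * 0.3)

  b <- apply_operator("B", st, h, op)
  expect_identical(b$q, st$q)
  expect_equal(b$p, 0.3 - 0.1 * 1)   # force -k q = -1 at q = 1

  o <- apply_operator("O", st, h, op, noise = 0.5)
  expect_identical(o$q, st$q)
  expect_equal(o$p, op$d * 0.3 + op$f * 0.5)
  expect_error(apply_operator("O", st, h, op), "noise")
})

test_that("the O update preserves the stationary momentum distribution", {
  lp <- langevin_params(0.01, 5, 300, 1.4)
  op <- operator_params(lp)
  set.seed(21)
  n <- 1e5
  p <- rnorm(n, 0, sqrt(lp$rt * lp$masses))
  p2 <- op$d * p + op$f * rnorm(n)
  target <- lp$rt * lp$masses
  se <- sd(p2^2) / sqrt(n)   # SE of the variance estimate (mean of p^2)
  expect_lt(abs(mean(p2^2) - target), 3 * se)
})

test_that("one ABO step matches a hand-unrolled A,B,O composition", {
  lp <- langevin_params(0.002, 3, 300, 1.2)
  op <- operator_params(lp)
  pair <- potential_pair(harmonic_potential(50))
  st <- phase_state(0.4, -0.8)
  set.seed(5)
  eta <- rnorm(1)
  stp <- step_langevin(st, parse_scheme("ABO"), pair, lp,
                       noise = list(eta))
  q1 <- 0.4 + lp$dt / 1.2 * (-0.8)
  p1 <- -0.8 + lp$dt * (-50 * q1)
  p2 <- op$d * p1 + op$f * eta
  expect_equal(stp$state$q, q1, tolerance = 1e-15)
  expect_equal(stp$state$p, p2, tolerance = 1e-15)
  expect_identical(stp$increment, 0)   # no perturbation
})

test_that("steps are deterministic under a fixed seed and engines agree", {
  mb <- mueller_brown()
  pair <- potential_pair(mb, bias = bias_potential("linear", 1, ndim = 2))
  lp <- langevin_params(5e-4, 5, 300, c(1, 1))
  t1 <- simulate_langevin(pair, "ABOBA", lp, c(-0.5, 1.5), n_steps = 200,
                          n_out = 10, seed = 42, engine = "cpp")
  t2 <- simulate_langevin(pair, "ABOBA", lp, c(-0.5, 1.5), n_steps = 200,
                          n_out = 10, seed = 42, engine = "cpp")
  expect_identical(t1$q, t2$q)
  expect_identical(t1$records$dS, t2$records$dS)

  tr <- simulate_langevin(pair, "ABOBA", lp, c(-0.5, 1.5), n_steps = 200,
                          n_out = 10, seed = 42, engine = "r")
  expect_equal(tr$q, t1$q, tolerance = 1e-13)
  expect_equal(tr$p, t1$p, tolerance = 1e-13)
  expect_equal(tr$records$dS, t1$records$dS, tolerance = 1e-13)
  expect_equal(tr$records$U_kJ_per_mol, t1$records$U_kJ_per_mol,
               tolerance = 1e-13)

  # all supported schemes agree across engines
  for (sch in c("ABO", "AOBOA", "BOAOB", "OBABO")) {
    a <- simulate_langevin(pair, sch, lp, c(0, 0.5), n_steps = 50,
                           n_out = 5, seed = 7, engine = "cpp")
    b <- simulate_langevin(pair, sch, lp, c(0, 0.5), n_steps = 50,
                           n_out = 5, seed = 7, engine = "r")
    expect_equal(a$q, b$q, tolerance = 1e-13)
    expect_equal(a$records$dS, b$records$dS, tolerance = 1e-13)
  }
})

test_that("momentum and velocity formulations coincide to float precision", {
  # same scheme driven by the same noise stream, ABO vs RVO arithmetic
  mb <- mueller_brown()
  pair <- potential_pair(mb, bias = bias_potential("linear", 1, ndim = 2))
  lp <- langevin_params(5e-4, 5, 300, c(1.7, 1.7))   # non-unit masses
  scheme <- parse_scheme("ABOBA")
  set.seed(31)
  noise <- lapply(1:100, function(i) list(rnorm(2)))
  sa <- phase_state(c(-0.5, 1.5), c(0.4, -0.2))
  sr <- sa
  dmax <- 0
  for (k in 1:100) {
    sa <- step_langevin(sa, scheme, pair, lp, noise = noise[[k]],
                        formulation = "abo")$state
    sr <- step_langevin(sr, scheme, pair, lp, noise = noise[[k]],
                        formulation = "rvo")$state
    dmax <- max(dmax, abs(sa$p - sr$p), abs(sa$q - sr$q))
  }
  expect_lt(dmax, 1e-13)
})

test_that("simulate records frames and reweighting intervals correctly", {
  pair <- potential_pair(harmonic_potential(10),
                         bias = bias_potential("linear", 1, ndim = 1))
  lp <- langevin_params(0.002, 5, 300, 1)
  traj <- simulate_langevin(pair, "ABOBA", lp, 0, n_steps = 100,
                            n_out = 10, seed = 1)
  expect_identical(nrow(traj$q), 11L)
  expect_identical(nrow(traj$records), 11L)
  expect_identical(traj$records$dS[1], 0)
  expect_identical(traj$records$frame_index, 0:10)
  expect_equal(traj$records$time_ps, 0.002 * 10 * (0:10))
  expect_error(simulate_langevin(pair, "ABOBA", lp, 0, n_steps = 105,
                                 n_out = 10), "divide")
  expect_error(simulate_langevin(pair, "BAOAB", lp, 0, n_steps = 100,
                                 n_out = 10), "undefined")
  lp0 <- langevin_params(0.002, 0, 300, 1)
  expect_error(simulate_langevin(pair, "ABOBA", lp0, 0, n_steps = 100,
                                 n_out = 10), "xi = 0")
})

test_that("a long harmonic run samples the Boltzmann distribution", {
  k <- 10
  pair <- potential_pair(harmonic_potential(k))
  lp <- langevin_params(0.002, 5, 300, 1)
  traj <- simulate_langevin(pair, "ABOBA", lp, 0, n_steps = 4e5,
                            n_out = 10, seed = 99)
  q <- traj$q[-(1:1000), 1]
  p <- traj$p[-(1:1000), 1]
  se_q <- block_se(q^2)
  expect_lt(abs(mean(q^2) - lp$rt / k), 3 * se_q)
  se_p <- block_se(p^2)
  expect_lt(abs(mean(p^2) - lp$rt), 3 * se_p)
})

test_that("at zero friction the integrator is symplectic-like in energy", {
  k <- 50
  pair <- potential_pair(harmonic_potential(k))
  drift <- function(dt) {
    lp <- langevin_params(dt, 0, 300, 1)
    traj <- simulate_langevin(pair, "ABOBA", lp, 0.3, p0 = 0.1,
                              n_steps = 1000, n_out = 1)
    e <- 0.5 * traj$p[, 1]^2 + 0.5 * k * traj$q[, 1]^2
    max(abs(e - e[1]))
  }
  d1 <- drift(0.004)
  d2 <- drift(0.002)
  expect_lt(d1, 0.05)              # bounded drift
  expect_gt(d1 / d2, 2.5)          # ~ O(dt^2) scaling
  expect_lt(d1 / d2, 6)
})

test_that("blow-up is detected and reported with a step index", {
  pair <- potential_pair(harmonic_potential(1))
  lp <- langevin_params(0.002, 5, 300, 1)
  expect_error(
    simulate_langevin(pair, "ABOBA", lp, 0, n_steps = 100, n_out = 10,
                      seed = 1, blow_up_bound = 1e-6),
    "step")
})

test_that("step inversion reproduces the recorded noise for every scheme", {
  lp <- langevin_params(0.002, 3, 300, c(1.3, 0.8))
  op <- operator_params(lp)
  V <- harmonic_potential(c(50, 80))
  pair <- potential_pair(V)   # invert with the very potential simulated
  set.seed(13)
  for (sch in c("ABO", "ABOBA", "AOBOA", "BOAOB", "OBABO")) {
    scheme <- parse_scheme(sch)
    for (i in 1:20) {
      st <- phase_state(rnorm(2, 0, 0.2), rnorm(2, 0, sqrt(lp$rt)))
      stp <- step_langevin(st, scheme, pair, lp)
      inv <- invert_step_noise(st, stp$state, scheme, V, lp)
      if (scheme$combined) {
        comb <- op$d_half * stp$noise[[1]] + stp$noise[[2]]
        expect_equal(inv$eta1, comb, tolerance = 1e-11)
      } else {
        expect_equal(inv$eta1, stp$noise[[1]], tolerance = 1e-11)
        if (!is.null(inv$eta2))
          expect_equal(inv$eta2, stp$noise[[2]], tolerance = 1e-11)
      }
    }
  }
  # continuity: a tiny endpoint shift changes eta by O(eps / f)
  scheme <- parse_scheme("ABO")
  st <- phase_state(c(0.1, 0), c(0.5, -0.5))
  stp <- step_langevin(st, scheme, pair, lp, noise = list(c(0.2, -0.3)))
  pert <- stp$state
  eps <- 1e-12
  pert$p <- pert$p + eps
  i0 <- invert_step_noise(st, stp$state, scheme, V, lp)
  i1 <- invert_step_noise(st, pert, scheme, V, lp)
  expect_equal(i1$eta1 - i0$eta1, eps / op$f, tolerance = 1e-6)
  # inversion refused when the noise amplitude vanishes
  expect_error(invert_step_noise(st, stp$state, scheme, V,
                                 langevin_params(0.002, 0, 300, c(1.3, 0.8))),
               "undefined")
})

test_that("the ABO step at a linear perturbation shifts noise by d dt gradU / f", {
  # eta_tilde - eta = (d dt / f) * gradU for ABO, checked numerically
  lp <- langevin_params(0.002, 3, 300, 1)
  op <- operator_params(lp)
  cc <- 4
  target <- potential_sum(harmonic_potential(30),
                          bias_potential("linear", cc, ndim = 1))
  pair <- potential_pair(target, perturbation = bias_potential("linear",
                                                               cc, ndim = 1))
  scheme <- parse_scheme("ABO")
  set.seed(3)
  st <- phase_state(0.25, 0.9)
  stp <- step_langevin(st, scheme, pair, lp)
  inv <- invert_step_noise(st, stp$state, scheme, pair$V_target, lp)
  expect_equal(inv$eta1 - stp$noise[[1]], op$d * lp$dt * cc / op$f,
               tolerance = 1e-10)
})

test_that("a fixed-seed golden trajectory is stable across releases", {
  golden_dir <- system.file("extdata", "golden", package = "girsanov")
  expect_true(nzchar(golden_dir))
  tmp <- file.path(tempdir(), "golden-regen")
  unlink(tmp, recursive = TRUE)
  generate_fixtures(tmp, seed = 20240612)
  for (f in list.files(golden_dir)) {
    expect_identical(readLines(file.path(tmp, f)),
                     readLines(file.path(golden_dir, f)),
                     info = f)
  }
})
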