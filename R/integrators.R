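# Langevin splitting integrators.
#
# Underdamped Langevin dynamics
#   M dv/dt = -grad V(q) - xi M v + sqrt(2 RT xi M) eta(t)
# is integrated by composing three update operators per time step:
#   A (drift):  q <- q + (dt/M) p
#   B (kick):   p <- p + dt * (-grad V(q))
#   O (bath):   p <- d p + f eta,  d = exp(-xi dt), f = sqrt(RT M (1 - d^2))
# Letters repeated in a symmetric sequence are applied with dt/2 (primed
# parameters).  The RVO alphabet is the velocity formulation of the same
# operators (R ~ A, V ~ B) and maps onto ABO letter by letter.

#' Langevin parameters
#'
#' @param dt integration time step, ps.
#' @param xi collision (friction) rate, 1/ps (>= 0).
#' @param temperature temperature, K.
#' @param masses per-degree-of-freedom masses, amu.
#' @param gas_constant molar gas constant, kJ/(mol K). Default 8.314e-3.
#' @return object of class `langevin_params` with derived thermal energy
#'   `rt` = R*T in kJ/mol.
#' @export
langevin_params <- function(dt, xi, temperature, masses,
                            gas_constant = 8.314e-3) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0,
            is.numeric(xi), length(xi) == 1, xi >= 0,
            is.numeric(temperature), length(temperature) == 1,
            temperature >= 0,
            is.numeric(masses), all(masses > 0), all(is.finite(masses)))
  structure(list(dt = dt, xi = xi, temperature = temperature,
                 masses = as.numeric(masses), gas_constant = gas_constant,
                 rt = gas_constant * temperature,
                 ndim = length(masses)),
            class = "langevin_params")
}

#' @export
print.langevin_params <- function(x, ...) {
  cat(sprintf(
    "<langevin_params> dt = %g ps, xi = %g 1/ps, T = %g K, RT = %.6g kJ/mol, %d dof\n",
    x$dt, x$xi, x$temperature, x$rt, x$ndim))
  invisible(x)
}

#' Operator parameters for the splitting updates
#'
#' Dissipation d, fluctuation amplitude f (momentum units, per dof), position
#' drift factor a = dt/M, and their half-step (primed) analogues obtained by
#' replacing dt with dt/2. They satisfy d_half^2 = d and the stationarity
#' identity d^2 RT M + f^2 = RT M per degree of freedom.
#'
#' @param params a [langevin_params()] object.
#' @return object of class `operator_params`.
#' @export
operator_params <- function(params) {
  stopifnot(inherits(params, "langevin_params"))
  d <- exp(-params$xi * params$dt)
  d_half <- exp(-params$xi * params$dt / 2)
  f <- sqrt(params$rt * params$masses * (1 - d^2))
  f_half <- sqrt(params$rt * params$masses * (1 - d_half^2))
  structure(list(d = d, d_half = d_half, f = f, f_half = f_half,
                 a = params$dt / params$masses,
                 a_half = params$dt / (2 * params$masses),
                 dt = params$dt, dt_half = params$dt / 2,
                 rt = params$rt, masses = params$masses),
            class = "operator_params")
}

table1_schemes <- function() c("ABO", "ABOBA", "AOBOA", "BOAOB", "OBABO")

#' Parse a splitting-scheme string
#'
#' Accepts sequences over the ABO alphabet or the equivalent RVO alphabet
#' (R -> A, V -> B), case-insensitively and ignoring spaces. Letters that
#' occur more than once in the sequence are applied as half steps. Path
#' reweighting is defined only for the schemes ABO, ABOBA, AOBOA, BOAOB and
#' OBABO (equivalently RVO, RVOVR, ROVOR, VOROV, OVRVO); for any other
#' sequence `require_reweightable = TRUE` raises an error, while
#' `require_reweightable = FALSE` returns a scheme usable for plain
#' simulation only.
#'
#' @param text scheme string, e.g. `"ABOBA"` or `"R V O V R"`.
#' @param require_reweightable refuse schemes without a defined path
#'   probability ratio (default TRUE).
#' @return object of class `splitting_scheme` with fields `letters`, `half`,
#'   `canonical`, `n_noise`, `reweightable`, `eval_points`, `combined`.
#' @export
parse_scheme <- function(text, require_reweightable = TRUE) {
  stopifnot(is.character(text), length(text) == 1)
  cleaned <- gsub("[[:space:]]", "", toupper(text))
  if (!nzchar(cleaned)) stop("empty splitting scheme")
  chars <- strsplit(cleaned, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "B", "O", "R", "V"))
  if (length(bad))
    stop("unknown update operator(s) in scheme '", text, "': ",
         paste(bad, collapse = ", "))
  letters <- chartr("RV", "AB", chars)
  canonical <- paste(letters, collapse = "")
  reweightable <- canonical %in% table1_schemes()
  if (require_reweightable && !reweightable)
    stop("path reweighting is undefined for splitting '", text,
         "'; supported schemes: ABO, ABOBA, AOBOA, BOAOB, OBABO ",
         "(equivalently RVO, RVOVR, ROVOR, VOROV, OVRVO)")
  counts <- table(letters)
  half <- as.vector(counts[letters] > 1L)
  n_noise <- sum(letters == "O")
  eval_points <- switch(canonical,
                        ABO = "after",
                        ABOBA = "intermediate",
                        AOBOA = "intermediate",
                        BOAOB = c("before", "after"),
                        OBABO = c("before", "after"),
                        NULL)
  structure(list(text = text, letters = letters, half = half,
                 canonical = canonical, n_noise = n_noise,
                 reweightable = reweightable, eval_points = eval_points,
                 combined = identical(canonical, "AOBOA")),
            class = "splitting_scheme")
}

#' @export
print.splitting_scheme <- function(x, ...) {
  lab <- paste0(x$letters, ifelse(x$half, "'", ""), collapse = " ")
  cat(sprintf("<splitting_scheme> %s [%s], %d noise vector(s)/step%s\n",
              x$canonical, lab, x$n_noise,
              if (x$reweightable) ", reweightable" else ""))
  invisible(x)
}

#' Phase-space state
#' @param q positions (nm); @param p momenta (amu nm/ps); @param k step index.
#' @export
phase_state <- function(q, p, k = 0L) {
  q <- as.numeric(q); p <- as.numeric(p)
  if (length(q) != length(p)) stop("q and p must have the same length")
  if (k < 0) stop("step index must be >= 0")
  structure(list(q = q, p = p, k = as.integer(k)), class = "phase_state")
}

#' Apply a single update operator
#'
#' A updates positions only, B and O momenta only. O requires a noise vector.
#'
#' @param letter `"A"`, `"B"` or `"O"`.
#' @param state a [phase_state()].
#' @param potential potential supplying the B-step force -grad V.
#' @param op an [operator_params()] object.
#' @param half apply the half-step (primed) parameters.
#' @param noise standard-normal vector for O.
#' @export
apply_operator <- function(letter, state, potential, op, half = FALSE,
                           noise = NULL) {
  stopifnot(inherits(state, "phase_state"), inherits(op, "operator_params"))
  q <- state$q; p <- state$p
  if (letter == "A") {
    q <- q + (if (half) op$a_half else op$a) * p
  } else if (letter == "B") {
    f <- -potential_gradient(potential, q)
    p <- p + (if (half) op$dt_half else op$dt) * f
  } else if (letter == "O") {
    if (is.null(noise)) stop("O update requires a noise vector")
    d <- if (half) op$d_half else op$d
    fl <- if (half) op$f_half else op$f
    p <- d * p + fl * noise
  } else {
    stop("unknown operator letter: ", letter)
  }
  phase_state(q, p, state$k)
}

#' Draw Maxwell-Boltzmann momenta
#' @param params a [langevin_params()]; @param n number of draws.
#' @return a vector (n = 1) or n x ndof matrix of momenta, amu nm/ps.
#' @export
maxwell_boltzmann_momenta <- function(params, n = 1) {
  sd <- sqrt(params$rt * params$masses)
  m <- matrix(stats::rnorm(n * params$ndim), nrow = n, byrow = TRUE) *
    rep(sd, each = n)
  if (n == 1) as.numeric(m[1, ]) else m
}

# One full integrator step, pure R.  `formulation` selects momentum (abo) or
# velocity (rvo) arithmetic; both apply the same operator sequence.  Returns
# the new state, the noise actually used, and the Girsanov log-weight
# increment s_k (0 when the pair carries no perturbation).

#' Single Langevin splitting step (reference engine)
#'
#' @param state a [phase_state()].
#' @param scheme a [parse_scheme()] result.
#' @param pair a [potential_pair()]; the B-step uses the full simulation
#'   force -grad V, the perturbation force -grad U enters only the
#'   reweighting increment.
#' @param params a [langevin_params()].
#' @param noise optional list of standard-normal vectors (one per O
#'   occurrence); drawn from R's RNG when NULL.
#' @param op precomputed [operator_params()] (recomputed when NULL).
#' @param formulation `"abo"` (momentum updates) or `"rvo"` (velocity
#'   updates); both realise the same scheme.
#' @return list with `state`, `noise` (list of vectors), and `increment`
#'   (the per-step log-weight contribution s_k).
#' @export
step_langevin <- function(state, scheme, pair, params, noise = NULL,
                          op = NULL, formulation = c("abo", "rvo")) {
  formulation <- match.arg(formulation)
  stopifnot(inherits(state, "phase_state"),
            inherits(scheme, "splitting_scheme"),
            inherits(pair, "potential_pair"),
            inherits(params, "langevin_params"))
  if (is.null(op)) op <- operator_params(params)
  nd <- length(state$q)
  if (is.null(noise))
    noise <- lapply(seq_len(scheme$n_noise),
                    function(i) stats::rnorm(nd))
  if (length(noise) != scheme$n_noise)
    stop("scheme draws ", scheme$n_noise, " noise vector(s) per step")
  if (pair$has_perturbation && !scheme$reweightable)
    stop("path reweighting is undefined for this splitting scheme")
  if (pair$has_perturbation && any(op$f == 0))
    stop("reweighting undefined for f = 0 (xi = 0 or T = 0)")

  q <- state$q
  mass <- params$masses
  p <- state$p
  v <- p / mass
  q_pre <- q
  q_mid <- NULL
  i_noise <- 0L
  for (i in seq_along(scheme$letters)) {
    l <- scheme$letters[i]
    h <- scheme$half[i]
    if (l == "A") {
      if (formulation == "abo") {
        q <- q + (if (h) op$a_half else op$a) * p
      } else {
        q <- q + (if (h) op$dt_half else op$dt) * v
      }
      if (is.null(q_mid)) q_mid <- q
    } else if (l == "B") {
      f <- -potential_gradient(pair$V, q)
      if (formulation == "abo") {
        p <- p + (if (h) op$dt_half else op$dt) * f
      } else {
        v <- v + (if (h) op$dt_half else op$dt) * f / mass
      }
    } else {
      i_noise <- i_noise + 1L
      eta <- noise[[i_noise]]
      d <- if (h) op$d_half else op$d
      if (formulation == "abo") {
        p <- d * p + (if (h) op$f_half else op$f) * eta
      } else {
        v <- d * v + (if (h) op$f_half else op$f) / mass * eta
      }
    }
  }
  if (formulation == "rvo") p <- v * mass
  if (any(!is.finite(q)) || any(!is.finite(p)))
    stop("simulation blow-up at step ", state$k + 1L,
         " (|q| or energy not finite)")
  if (is.null(q_mid)) q_mid <- q

  increment <- 0
  if (pair$has_perturbation) {
    increment <- reweight_increment(scheme, op, noise, q_pre, q_mid, q,
                                    pair$U)
  }
  list(state = phase_state(q, p, state$k + 1L), noise = noise,
       increment = increment)
}

#' Run a Langevin simulation with on-the-fly reweighting records
#'
#' Propagates `n_steps` integrator steps and records a frame every `n_out`
#' steps (frames at k = 0, n_out, 2 n_out, ...). The reweighting record at
#' frame k' holds the log-weight buffer accumulated over the `n_out` steps
#' ending at k' (frame 0 holds 0) together with the perturbation energy
#' U(q_k'). The compiled engine and the pure-R engine share R's RNG stream
#' and produce identical trajectories for a given seed.
#'
#' @param pair a [potential_pair()].
#' @param scheme a [parse_scheme()] result or scheme string.
#' @param params a [langevin_params()].
#' @param q0 initial positions (nm).
#' @param p0 initial momenta; drawn from the Maxwell-Boltzmann distribution
#'   at `params$temperature` when NULL (consuming RNG draws before the
#'   integration starts).
#' @param n_steps number of integrator steps; must be divisible by `n_out`.
#' @param n_out recording interval in steps (default 10).
#' @param seed optional integer passed to [set.seed()].
#' @param engine `"auto"` (compiled when all potentials carry compiled
#'   terms), `"cpp"` or `"r"`.
#' @param record_noise also return the per-step noise vectors (short runs).
#' @param blow_up_bound abort when any |q| exceeds this bound (nm).
#' @return object of class `langevin_trajectory`: frame matrices `q`, `p`,
#'   a `records` data frame (frame_index, time_ps, dS, U_kJ_per_mol), and
#'   the run metadata.
#' @export
simulate_langevin <- function(pair, scheme, params, q0, p0 = NULL,
                              n_steps, n_out = 10L, seed = NULL,
                              engine = c("auto", "cpp", "r"),
                              record_noise = FALSE, blow_up_bound = 1e4) {
  engine <- match.arg(engine)
  if (is.character(scheme)) scheme <- parse_scheme(scheme,
                                                   require_reweightable = FALSE)
  stopifnot(inherits(pair, "potential_pair"),
            inherits(scheme, "splitting_scheme"),
            inherits(params, "langevin_params"))
  n_steps <- as.integer(n_steps)
  n_out <- as.integer(n_out)
  if (n_out < 1L) stop("n_out must be >= 1")
  if (n_steps < 1L || n_steps %% n_out != 0L)
    stop("n_out (", n_out, ") must divide n_steps (", n_steps, ")")
  if (pair$ndim != params$ndim)
    stop("potential pair and Langevin parameters disagree on dimensionality")
  if (pair$has_perturbation && !scheme$reweightable)
    stop("path reweighting is undefined for splitting '", scheme$text, "'")
  if (pair$has_perturbation && (params$xi == 0 || params$temperature == 0))
    stop("reweighting undefined for f = 0 (xi = 0 or T = 0)")

  if (!is.null(seed)) set.seed(as.integer(seed))
  q0 <- check_position(q0, pair$ndim)
  if (is.null(p0)) p0 <- maxwell_boltzmann_momenta(params)
  p0 <- as.numeric(p0)
  if (length(p0) != pair$ndim) stop("p0 has wrong length")

  compiled_ok <- !is.null(pair$V$terms) && !is.null(pair$U$terms)
  use_cpp <- switch(engine,
                    auto = compiled_ok,
                    cpp = { if (!compiled_ok)
                      stop("compiled engine requires compiled potential terms")
                      TRUE },
                    r = FALSE)

  if (use_cpp) {
    res <- .simulate_core(q0, p0, scheme$letters, scheme$half,
                          scheme$canonical, params$masses, params$dt,
                          params$xi, params$rt, n_steps, n_out,
                          pair$V$terms, pair$U$terms,
                          pair$has_perturbation, record_noise,
                          blow_up_bound)
  } else {
    res <- simulate_r_engine(pair, scheme, params, q0, p0, n_steps, n_out,
                             record_noise, blow_up_bound)
  }

  records <- data.frame(frame_index = seq_len(length(res$dS)) - 1L,
                        time_ps = res$time_ps,
                        dS = res$dS,
                        U_kJ_per_mol = res$U_q)
  class(records) <- c("reweighting_records", "data.frame")
  out <- list(q = res$q, p = res$p, records = records,
              dt = params$dt, n_out = n_out, rt = params$rt,
              scheme = scheme$canonical, ndim = pair$ndim,
              has_perturbation = pair$has_perturbation)
  if (record_noise) {
    out$eta1 <- res$eta1
    out$eta2 <- res$eta2
  }
  structure(out, class = "langevin_trajectory")
}

simulate_r_engine <- function(pair, scheme, params, q0, p0, n_steps, n_out,
                              record_noise, blow_up_bound) {
  op <- operator_params(params)
  nd <- pair$ndim
  n_frames <- n_steps %/% n_out + 1L
  Q <- matrix(NA_real_, n_frames, nd)
  P <- matrix(NA_real_, n_frames, nd)
  dS <- numeric(n_frames)
  Uq <- numeric(n_frames)
  tp <- numeric(n_frames)
  E1 <- if (record_noise) matrix(NA_real_, n_steps, nd)
  E2 <- if (record_noise && scheme$n_noise > 1) matrix(NA_real_, n_steps, nd)

  state <- phase_state(q0, p0, 0L)
  Q[1, ] <- q0; P[1, ] <- p0
  Uq[1] <- if (pair$has_perturbation) potential_energy(pair$U, q0) else 0
  buffer <- 0
  for (k in seq_len(n_steps)) {
    stp <- step_langevin(state, scheme, pair, params, op = op)
    state <- stp$state
    if (any(abs(state$q) > blow_up_bound))
      stop("simulation blow-up at step ", k, " (|q| or energy not finite)")
    buffer <- buffer + stp$increment
    if (record_noise) {
      E1[k, ] <- stp$noise[[1]]
      if (!is.null(E2)) E2[k, ] <- stp$noise[[2]]
    }
    if (k %% n_out == 0L) {
      fr <- k %/% n_out + 1L
      Q[fr, ] <- state$q
      P[fr, ] <- state$p
      dS[fr] <- buffer
      buffer <- 0
      Uq[fr] <- if (pair$has_perturbation) potential_energy(pair$U, state$q)
                else 0
      tp[fr] <- k * params$dt
    }
  }
  list(q = Q, p = P, dS = dS, U_q = Uq, time_ps = tp, eta1 = E1, eta2 = E2)
}

#' @export
print.langevin_trajectory <- function(x, ...) {
  cat(sprintf(
    "<langevin_trajectory> %s, %d frames x %d dof, frame spacing %g ps%s\n",
    x$scheme, nrow(x$q), x$ndim, x$n_out * x$dt,
    if (x$has_perturbation) ", with reweighting records" else ""))
  invisible(x)
}

#' Solve one integrator step for its noise (inversion oracle)
#'
#' Given consecutive states of a splitting-integrator step, returns the
#' standard-normal vector that produces the transition under the supplied
#' potential. For the two-noise scheme AOBOA only the endpoint-determined
#' combination d' eta1 + eta2 is returned (`combined = TRUE`); for BOAOB and
#' OBABO both channels are individually determined. Used to certify the
#' random-number-difference formulas.
#'
#' @param state_k,state_k1 consecutive [phase_state()]s.
#' @param scheme a reweightable [parse_scheme()] result.
#' @param potential the potential whose dynamics is inverted (simulation or
#'   target).
#' @param params a [langevin_params()].
#' @return list with `eta1` (or the combination for AOBOA), optional `eta2`,
#'   and the flag `combined`.
#' @export
invert_step_noise <- function(state_k, state_k1, scheme, potential, params) {
  stopifnot(inherits(scheme, "splitting_scheme"))
  if (!scheme$reweightable)
    stop("inversion implemented for Table-supported schemes only")
  op <- operator_params(params)
  if (any(op$f == 0))
    stop("noise inversion undefined for f = 0 (xi = 0 or T = 0)")
  qk <- state_k$q; pk <- state_k$p
  qk1 <- state_k1$q; pk1 <- state_k1$p
  force <- function(q) -potential_gradient(potential, q)
  dt <- op$dt
  switch(scheme$canonical,
    ABO = {
      q1 <- qk + op$a * pk
      eta <- (pk1 - op$d * (pk + dt * force(q1))) / op$f
      list(eta1 = eta, eta2 = NULL, combined = FALSE)
    },
    ABOBA = {
      q1 <- qk + op$a_half * pk
      fmid <- force(q1)
      eta <- (pk1 - (dt / 2) * fmid - op$d * (pk + (dt / 2) * fmid)) / op$f
      list(eta1 = eta, eta2 = NULL, combined = FALSE)
    },
    AOBOA = {
      q1 <- qk + op$a_half * pk
      comb <- (pk1 - op$d_half^2 * pk - op$d_half * dt * force(q1)) /
        op$f_half
      list(eta1 = comb, eta2 = NULL, combined = TRUE)
    },
    BOAOB = {
      p1 <- pk + (dt / 2) * force(qk)
      p2 <- (qk1 - qk) / op$a
      eta1 <- (p2 - op$d_half * p1) / op$f_half
      p3 <- pk1 - (dt / 2) * force(qk1)
      eta2 <- (p3 - op$d_half * p2) / op$f_half
      list(eta1 = eta1, eta2 = eta2, combined = FALSE)
    },
    OBABO = {
      p2 <- (qk1 - qk) / op$a
      eta1 <- (p2 - (dt / 2) * force(qk) - op$d_half * pk) / op$f_half
      eta2 <- (pk1 - op$d_half * (p2 + (dt / 2) * force(qk1))) / op$f_half
      list(eta1 = eta1, eta2 = eta2, combined = FALSE)
    })
}
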