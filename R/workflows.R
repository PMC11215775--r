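# Config-driven experiment runners: the Mueller-Brown reweighting study, a
# 1D double-well study, fixture generation and a thin CLI dispatcher.

#' Configuration of the Mueller-Brown reweighting study
#'
#' Desk-scale defaults: 5 replicas of 5e6 steps per condition (ABOBA,
#' dt = 0.5 fs, xi = 5/ps, T = 300 K, unit mass), frames every n_out = 10
#' steps, a 6 x 6 grid over -3.5 <= x <= 1.5, -1.5 <= y <= 3.5 and lag
#' times 0.5-4.5 ps. The linear bias k = 1 kJ/mol/nm is the reweighted
#' condition; the negative control uses a deliberately strong bias
#' (`negative_control_k`) so that the unreweighted MSM visibly departs from
#' the target stationary density.
#'
#' @param n_steps steps per replica (after `scale`).
#' @param n_out recording interval, steps.
#' @param n_replicas replicas per condition.
#' @param dt time step, ps. @param xi collision rate, 1/ps.
#' @param temperature K. @param mass amu (both dofs).
#' @param bias_k linear-bias prefactor, kJ/mol/nm.
#' @param negative_control_k bias prefactor of the negative control.
#' @param lags_ps MSM lag times, ps (multiples of the frame spacing).
#' @param report_lag_ps lag at which headline comparisons are made.
#' @param burn_in_steps equilibration steps discarded before analysis.
#' @param scheme splitting scheme string.
#' @param energy_cap initial positions are redrawn until the simulation
#'   potential is below this energy (kJ/mol).
#' @param seed base seed; replica seeds are derived from it.
#' @param scale multiplies `n_steps` and `burn_in_steps` (quick runs).
#' @export
mb_experiment_config <- function(n_steps = 5e6, n_out = 10, n_replicas = 5,
                                 dt = 5e-4, xi = 5, temperature = 300,
                                 mass = 1, bias_k = 1,
                                 negative_control_k = 3,
                                 lags_ps = seq(0.5, 4.5, by = 1),
                                 report_lag_ps = 2.5,
                                 burn_in_steps = 5e4,
                                 scheme = "ABOBA",
                                 energy_cap = 0, seed = 1, scale = 1) {
  n_steps <- scaled_steps(n_steps, scale, n_out)
  burn_in_steps <- scaled_steps(burn_in_steps, scale, n_out)
  structure(list(system = "mueller_brown", n_steps = n_steps, n_out = n_out,
                 n_replicas = n_replicas, dt = dt, xi = xi,
                 temperature = temperature, mass = mass, bias_k = bias_k,
                 negative_control_k = negative_control_k,
                 grid_mins = c(-3.5, -1.5), grid_maxs = c(1.5, 3.5),
                 grid_bins = c(6L, 6L),
                 lags_ps = lags_ps, report_lag_ps = report_lag_ps,
                 burn_in_steps = burn_in_steps, scheme = scheme,
                 energy_cap = energy_cap, seed = seed),
            class = "experiment_config")
}

#' Configuration of the 1D double-well surrogate study
#'
#' A quartic double well stands in for a barrier-crossing reaction
#' coordinate; the bias is linear with k = 5 kJ/mol/nm and the MSM uses a
#' 50-state grid over the coordinate range.
#'
#' @inheritParams mb_experiment_config
#' @param barrier_height kJ/mol. @param q_min minima at +-q_min, nm.
#' @export
doublewell_experiment_config <- function(n_steps = 2e6, n_out = 10,
                                         n_replicas = 5,
                                         dt = 1e-3, xi = 2,
                                         temperature = 300, mass = 1,
                                         barrier_height = 5, q_min = 0.15,
                                         bias_k = 5,
                                         lags_ps = c(1, 2, 4),
                                         report_lag_ps = 2,
                                         burn_in_steps = 5e4,
                                         scheme = "ABOBA",
                                         seed = 1, scale = 1) {
  n_steps <- scaled_steps(n_steps, scale, n_out)
  burn_in_steps <- scaled_steps(burn_in_steps, scale, n_out)
  structure(list(system = "double_well", n_steps = n_steps, n_out = n_out,
                 n_replicas = n_replicas, dt = dt, xi = xi,
                 temperature = temperature, mass = mass,
                 barrier_height = barrier_height, q_min = q_min,
                 bias_k = bias_k,
                 grid_mins = -2 * q_min, grid_maxs = 2 * q_min,
                 grid_bins = 50L,
                 lags_ps = lags_ps, report_lag_ps = report_lag_ps,
                 burn_in_steps = burn_in_steps, scheme = scheme,
                 seed = seed),
            class = "experiment_config")
}

scaled_steps <- function(n, scale, n_out) {
  n <- max(n_out, round(n * scale / n_out) * n_out)
  as.integer(n)
}

#' Load an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [mb_experiment_config()] /
#' [doublewell_experiment_config()]; the key `system` selects the study
#' (`mueller_brown` or `double_well`) and `dt_fs` may be given instead of
#' `dt` (converted once here).
#'
#' @param path YAML file.
#' @export
load_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  system <- raw$system %||% "mueller_brown"
  raw$system <- NULL
  if (!is.null(raw$dt_fs)) {
    raw$dt <- raw$dt_fs * 1e-3
    raw$dt_fs <- NULL
  }
  maker <- switch(system,
                  mueller_brown = mb_experiment_config,
                  double_well = doublewell_experiment_config,
                  stop("unknown system '", system, "'"))
  bad <- setdiff(names(raw), names(formals(maker)))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(maker, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform start inside a box, redrawn until the potential is below `cap`.
draw_start <- function(potential, mins, maxs, cap = Inf, max_tries = 10000) {
  for (i in seq_len(max_tries)) {
    q <- stats::runif(length(mins), mins, maxs)
    if (potential_energy(potential, q) < cap) return(q)
  }
  stop("could not draw an initial position below the energy cap")
}

# Drop the first `n_frames` recorded frames (equilibration).
discard_burn_in <- function(traj, n_frames) {
  if (n_frames <= 0) return(traj)
  keep <- seq(n_frames + 1L, nrow(traj$q))
  traj$q <- traj$q[keep, , drop = FALSE]
  traj$p <- traj$p[keep, , drop = FALSE]
  traj$records <- traj$records[keep, ]
  traj$records$frame_index <- seq_len(nrow(traj$records)) - 1L
  rownames(traj$records) <- NULL
  traj
}

run_replicas <- function(pair, scheme, params, cfg, seeds, start_potential,
                         start_mins, start_maxs, cap) {
  lapply(seeds, function(s) {
    set.seed(s)
    q0 <- draw_start(start_potential, start_mins, start_maxs, cap)
    traj <- simulate_langevin(pair, scheme, params, q0, p0 = NULL,
                              n_steps = cfg$n_steps + cfg$burn_in_steps,
                              n_out = cfg$n_out)
    discard_burn_in(traj, cfg$burn_in_steps %/% cfg$n_out)
  })
}

lag_to_frames <- function(lag_ps, cfg) {
  spacing <- cfg$n_out * cfg$dt
  fr <- lag_ps / spacing
  if (abs(fr - round(fr)) > 1e-9)
    stop("lag ", lag_ps, " ps is not a multiple of the frame spacing ",
         spacing, " ps")
  as.integer(round(fr))
}

weight_stats <- function(log_w) {
  list(min_log_w = min(log_w), median_log_w = stats::median(log_w),
       max_log_w = max(log_w), n_windows = length(log_w),
       ess = effective_sample_size(log_w))
}

three_way_msms <- function(dtraj_direct, dtraj_biased, records_biased,
                           lag_frames, n_states, rt) {
  lw <- lapply(records_biased, function(r)
    window_log_weights(r, lag_frames, rt)$log_w)
  list(direct = msm_estimate(dtraj_direct, lag_frames, n_states),
       biased = msm_estimate(dtraj_biased, lag_frames, n_states),
       reweighted = msm_estimate(dtraj_biased, lag_frames, n_states,
                                 log_weights = lw),
       log_weights = lw)
}

#' Run the Mueller-Brown reweighting study
#'
#' Simulates unbiased replicas at the target potential and biased replicas
#' at the linearly tilted potential, builds direct, biased-unreweighted and
#' biased-reweighted MSMs across the lag list, and reports stationary-vector
#' total-variation distances, implied timescales (with per-replica spreads)
#' and window-weight statistics. A separate strongly biased condition
#' (`negative_control_k`) provides the unreweighted negative control.
#'
#' @param config a [mb_experiment_config()].
#' @return list of class `mb_experiment` (see the README for a walk-through).
#' @export
run_mb_experiment <- function(config = mb_experiment_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "experiment_config"),
            cfg$system == "mueller_brown")
  mb <- mueller_brown()
  params <- langevin_params(cfg$dt, cfg$xi, cfg$temperature,
                            rep(cfg$mass, 2))
  scheme <- parse_scheme(cfg$scheme)
  grid <- grid_discretization(cfg$grid_mins, cfg$grid_maxs, cfg$grid_bins)
  pair_direct <- potential_pair(mb)
  pair_biased <- potential_pair(
    mb, bias = bias_potential("linear", k = cfg$bias_k, ndim = 2))
  pair_negctl <- potential_pair(
    mb, bias = bias_potential("linear", k = cfg$negative_control_k,
                              ndim = 2))

  seeds <- function(offset) cfg$seed + offset + seq_len(cfg$n_replicas)
  run <- function(pair, offset)
    run_replicas(pair, scheme, params, cfg, seeds(offset), mb,
                 cfg$grid_mins, cfg$grid_maxs, cfg$energy_cap)

  trajs_direct <- run(pair_direct, 0L)
  trajs_biased <- run(pair_biased, 100000L)
  trajs_negctl <- run(pair_negctl, 200000L)

  dtraj <- function(trajs) lapply(trajs, function(t) discretize(t$q, grid))
  dt_direct <- dtraj(trajs_direct)
  dt_biased <- dtraj(trajs_biased)
  dt_negctl <- dtraj(trajs_negctl)
  rec_biased <- lapply(trajs_biased, function(t) t$records)
  rec_negctl <- lapply(trajs_negctl, function(t) t$records)
  rt <- params$rt

  per_lag <- lapply(cfg$lags_ps, function(lag_ps) {
    lf <- lag_to_frames(lag_ps, cfg)
    m <- three_way_msms(dt_direct, dt_biased, rec_biased, lf,
                        grid$n_states, rt)
    list(lag_ps = lag_ps, lag_frames = lf, msms = m,
         t1 = vapply(m[c("direct", "biased", "reweighted")], function(x)
           implied_timescales(x$spectral$values, lag_ps)[1], 0))
  })
  names(per_lag) <- paste0("lag_", cfg$lags_ps)

  rep_lf <- lag_to_frames(cfg$report_lag_ps, cfg)
  rep_idx <- which(abs(cfg$lags_ps - cfg$report_lag_ps) < 1e-9)[1]
  if (is.na(rep_idx)) stop("report_lag_ps must be one of lags_ps")
  rep_msms <- per_lag[[rep_idx]]$msms
  l0 <- lapply(rep_msms[c("direct", "biased", "reweighted")],
               stationary_distribution, n_states = grid$n_states)

  neg <- three_way_msms(dt_direct, dt_negctl, rec_negctl, rep_lf,
                        grid$n_states, rt)
  l0$negative_control <- stationary_distribution(neg$biased, grid$n_states)
  l0$negative_control_reweighted <-
    stationary_distribution(neg$reweighted, grid$n_states)

  # per-replica slowest timescale at the report lag (direct and reweighted)
  t1_rep <- function(dts, recs = NULL) {
    vapply(seq_along(dts), function(r) {
      lw <- if (!is.null(recs))
        list(window_log_weights(recs[[r]], rep_lf, rt)$log_w)
      m <- msm_estimate(dts[r], rep_lf, grid$n_states, log_weights = lw)
      implied_timescales(m$spectral$values, cfg$report_lag_ps)[1]
    }, 0)
  }
  t1_direct_reps <- t1_rep(dt_direct)
  t1_reweighted_reps <- t1_rep(dt_biased, rec_biased)

  its <- data.frame(
    lag_ps = cfg$lags_ps,
    t1_direct = vapply(per_lag, function(x) x$t1[["direct"]], 0),
    t1_biased = vapply(per_lag, function(x) x$t1[["biased"]], 0),
    t1_reweighted = vapply(per_lag, function(x) x$t1[["reweighted"]], 0))

  structure(list(
    config = cfg, grid = grid, per_lag = per_lag,
    stationary = l0,
    tv_reweighted = total_variation(l0$reweighted, l0$direct),
    tv_unreweighted = total_variation(l0$biased, l0$direct),
    tv_negative_control = total_variation(l0$negative_control, l0$direct),
    tv_negative_control_reweighted =
      total_variation(l0$negative_control_reweighted, l0$direct),
    implied_timescales = its,
    t1_direct_replicas = t1_direct_reps,
    t1_reweighted_replicas = t1_reweighted_reps,
    weight_stats = weight_stats(unlist(rep_msms$log_weights))),
    class = "mb_experiment")
}

#' @export
print.mb_experiment <- function(x, ...) {
  cat("<mb_experiment>\n",
      sprintf("  TV(reweighted, direct)        = %.4f\n", x$tv_reweighted),
      sprintf("  TV(unreweighted, direct)      = %.4f\n", x$tv_unreweighted),
      sprintf("  TV(negative control, direct)  = %.4f\n",
              x$tv_negative_control),
      sprintf("  slowest timescale (direct)    = %.2f ps\n",
              x$implied_timescales$t1_direct[
                which(abs(x$implied_timescales$lag_ps -
                            x$config$report_lag_ps) < 1e-9)[1]]),
      sep = "")
  invisible(x)
}

#' Run the 1D double-well surrogate study
#'
#' Same three-way comparison as [run_mb_experiment()] on a quartic double
#' well with a linear bias, plus a quadrature Boltzmann reference for the
#' target stationary density.
#'
#' @param config a [doublewell_experiment_config()].
#' @export
run_doublewell_experiment <- function(config = doublewell_experiment_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "experiment_config"), cfg$system == "double_well")
  dw <- double_well_potential(cfg$barrier_height, cfg$q_min)
  params <- langevin_params(cfg$dt, cfg$xi, cfg$temperature, cfg$mass)
  scheme <- parse_scheme(cfg$scheme)
  grid <- grid_discretization(cfg$grid_mins, cfg$grid_maxs, cfg$grid_bins)
  pair_direct <- potential_pair(dw)
  pair_biased <- potential_pair(
    dw, bias = bias_potential("linear", k = cfg$bias_k, ndim = 1))

  seeds <- function(offset) cfg$seed + offset + seq_len(cfg$n_replicas)
  run <- function(pair, offset)
    run_replicas(pair, scheme, params, cfg, seeds(offset), dw,
                 cfg$grid_mins, cfg$grid_maxs, Inf)

  trajs_direct <- run(pair_direct, 0L)
  trajs_biased <- run(pair_biased, 100000L)
  dt_direct <- lapply(trajs_direct, function(t) discretize(t$q, grid))
  dt_biased <- lapply(trajs_biased, function(t) discretize(t$q, grid))
  rec_biased <- lapply(trajs_biased, function(t) t$records)
  rt <- params$rt

  lf <- lag_to_frames(cfg$report_lag_ps, cfg)
  m <- three_way_msms(dt_direct, dt_biased, rec_biased, lf, grid$n_states,
                      rt)
  l0 <- lapply(m[c("direct", "biased", "reweighted")],
               stationary_distribution, n_states = grid$n_states)
  boltz <- boltzmann_reference(dw, grid, rt)

  structure(list(
    config = cfg, grid = grid, msms = m, stationary = l0,
    boltzmann = boltz,
    tv_reweighted_vs_boltzmann = total_variation(l0$reweighted, boltz),
    tv_biased_vs_boltzmann = total_variation(l0$biased, boltz),
    tv_direct_vs_boltzmann = total_variation(l0$direct, boltz),
    weight_stats = weight_stats(unlist(m$log_weights))),
    class = "doublewell_experiment")
}

#' Discretized Boltzmann density of a potential on a grid
#'
#' Midpoint quadrature of `exp(-V/RT)` inside each bin (independent of any
#' simulation; used as an oracle for stationary densities).
#'
#' @param potential a `potential` (1D or 2D).
#' @param grid a [grid_discretization()].
#' @param rt thermal energy, kJ/mol.
#' @param n_quad quadrature points per dimension and bin.
#' @export
boltzmann_reference <- function(potential, grid, rt, n_quad = 24) {
  stopifnot(grid$ndim %in% c(1L, 2L))
  w <- numeric(grid$n_states)
  offs <- lapply(seq_len(grid$ndim), function(d)
    (seq_len(n_quad) - 0.5) / n_quad * grid$widths[d])
  state <- 0L
  idx_ranges <- lapply(grid$bins, seq_len)
  if (grid$ndim == 1L) {
    for (i in idx_ranges[[1]]) {
      state <- state + 1L
      xs <- grid$mins[1] + (i - 1) * grid$widths[1] + offs[[1]]
      w[state] <- sum(exp(-vapply(xs, function(x)
        potential_energy(potential, x), 0) / rt))
    }
  } else {
    for (i in idx_ranges[[1]]) for (j in idx_ranges[[2]]) {
      state <- state + 1L
      xs <- grid$mins[1] + (i - 1) * grid$widths[1] + offs[[1]]
      ys <- grid$mins[2] + (j - 1) * grid$widths[2] + offs[[2]]
      e <- outer(xs, ys, function(x, y)
        mapply(function(xx, yy)
          potential_energy(potential, base::c(xx, yy)), x, y))
      w[state] <- sum(exp(-e / rt))
    }
  }
  w / sum(w)
}

#' Generate deterministic golden fixtures
#'
#' Writes a 20-step position/reweighting file pair for every supported
#' splitting scheme (harmonic potential with a linear perturbation) and a
#' tiny hand-checkable MSM fixture. Regeneration with the same seed is
#' byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, the vector of files written.
#' @export
generate_fixtures <- function(dir, seed = 20240612) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- langevin_params(dt = 0.01, xi = 2, temperature = 300, masses = 1)
  pair <- potential_pair(harmonic_potential(100),
                         perturbation = scale_potential(
                           bias_potential("linear", k = 2, ndim = 1), -1))
  files <- character(0)
  for (sch in table1_schemes()) {
    traj <- simulate_langevin(pair, sch, params, q0 = 0.1, p0 = 0.5,
                              n_steps = 20, n_out = 5, seed = seed)
    fp <- file.path(dir, paste0("scheme_", sch, "_positions.tsv"))
    fr <- file.path(dir, paste0("scheme_", sch, "_reweighting.tsv"))
    write_position_file(traj, fp)
    write_reweighting_file(traj, fr)
    files <- base::c(files, fp, fr)
  }
  msm_file <- file.path(dir, "msm_fixture.csv")
  utils::write.csv(data.frame(dtraj = base::c(1L, 1L, 2L, 2L)),
                   msm_file, row.names = FALSE)
  files <- base::c(files, msm_file)
  invisible(files)
}

# --- CLI -------------------------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: girsanov-cli <subcommand> [flags]",
    "",
    "subcommands:",
    "  simulate    --scheme ABOBA --potential mueller_brown",
    "              --bias linear|polynomial|none --k 1.0 --steps N",
    "              --nout 10 --seed S [--dt-fs 0.5 --xi 5 --temperature 300",
    "              --mass 1 --q0 x,y] --out PREFIX",
    "  msm         --positions FILE [--reweighting FILE] --lag-frames L",
    "              --mins a,b --maxs c,d --bins m,n --rt RT --out PREFIX",
    "  experiment  --system mb|doublewell [--config FILE] [--scale F]",
    "              [--seed S] --out DIR",
    "  fixtures    --out DIR [--seed S]",
    "",
    "exit codes: 0 ok, 2 configuration error, 3 numerical failure",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

num_list <- function(x) as.numeric(strsplit(x, ",")[[1]])

cli_log <- function(...) {
  cat(jsonlite::toJSON(list(...), auto_unbox = TRUE), "\n")
}

cli_simulate <- function(flags) {
  scheme <- flags$scheme %||% "ABOBA"
  pot_name <- flags$potential %||% "mueller_brown"
  bias_kind <- flags$bias %||% "none"
  n_steps <- as.integer(flags$steps %||% 10000)
  n_out <- as.integer(flags$nout %||% 10)
  seed <- as.integer(flags$seed %||% 1)
  dt <- (as.numeric(flags[["dt-fs"]] %||% 0.5)) * 1e-3
  xi <- as.numeric(flags$xi %||% 5)
  temperature <- as.numeric(flags$temperature %||% 300)
  mass <- as.numeric(flags$mass %||% 1)
  out <- flags$out %||% stop("--out PREFIX is required")

  target <- switch(pot_name,
                   mueller_brown = mueller_brown(),
                   harmonic = harmonic_potential(as.numeric(flags$k %||% 1)),
                   double_well = double_well_potential(),
                   stop("unknown potential '", pot_name, "'"))
  nd <- target$ndim
  bias <- switch(bias_kind,
                 none = NULL,
                 linear = bias_potential("linear",
                                         k = as.numeric(flags$k %||% 1),
                                         ndim = nd),
                 polynomial = bias_potential(
                   "polynomial", k = as.numeric(flags$k %||% 50),
                   coefficients = mb_polynomial_coefficients(), ndim = nd),
                 stop("unknown bias '", bias_kind, "'"))
  pair <- potential_pair(target, bias = bias)
  params <- langevin_params(dt, xi, temperature, rep(mass, nd))
  q0 <- if (!is.null(flags$q0)) num_list(flags$q0) else rep(0, nd)
  traj <- simulate_langevin(pair, scheme, params, q0, n_steps = n_steps,
                            n_out = n_out, seed = seed)
  write_position_file(traj, paste0(out, "_positions.tsv"))
  write_reweighting_file(traj, paste0(out, "_reweighting.tsv"))
  cli_log(subcommand = "simulate", scheme = scheme, potential = pot_name,
          bias = bias_kind, steps = n_steps, n_out = n_out, seed = seed,
          frames = nrow(traj$q), out = out)
  0L
}

cli_msm <- function(flags) {
  pos <- read_position_file(flags$positions %||%
                              stop("--positions FILE is required"))
  lag <- as.integer(flags[["lag-frames"]] %||%
                      stop("--lag-frames is required"))
  grid <- grid_discretization(num_list(flags$mins), num_list(flags$maxs),
                              num_list(flags$bins))
  out <- flags$out %||% stop("--out PREFIX is required")
  dtraj <- discretize(pos$q, grid)
  lw <- NULL
  if (!is.null(flags$reweighting)) {
    rec <- read_reweighting_file(flags$reweighting)
    rt <- as.numeric(flags$rt %||% stop("--rt required with --reweighting"))
    lw <- list(window_log_weights(rec, lag, rt)$log_w)
  }
  m <- msm_estimate(dtraj, lag, grid$n_states, log_weights = lw)
  utils::write.csv(unclass(m$C), paste0(out, "_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(unclass(m$P), paste0(out, "_transition.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(eigenvalue = Re(m$spectral$values)),
                   paste0(out, "_eigenvalues.csv"), row.names = FALSE)
  summary <- list(n_frames = nrow(pos$q), lag_frames = lag,
                  n_states = grid$n_states,
                  n_active = length(m$active_set),
                  dropped_states = setdiff(seq_len(grid$n_states),
                                           m$active_set),
                  reweighted = !is.null(lw))
  jsonlite::write_json(summary, paste0(out, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cli_log(subcommand = "msm", out = out, n_active = length(m$active_set))
  0L
}

cli_experiment <- function(flags) {
  out <- flags$out %||% stop("--out DIR is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  scale <- as.numeric(flags$scale %||% 1)
  seed <- as.integer(flags$seed %||% 1)
  cfg <- if (!is.null(flags$config)) {
    load_experiment_config(flags$config)
  } else {
    sys <- flags$system %||% "mb"
    switch(sys,
           mb = mb_experiment_config(seed = seed, scale = scale),
           doublewell = doublewell_experiment_config(seed = seed,
                                                     scale = scale),
           stop("unknown system '", sys, "'"))
  }
  res <- if (cfg$system == "mueller_brown") run_mb_experiment(cfg)
         else run_doublewell_experiment(cfg)
  if (inherits(res, "mb_experiment")) {
    utils::write.csv(res$implied_timescales,
                     file.path(out, "implied_timescales.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$stationary),
                     file.path(out, "stationary_vectors.csv"),
                     row.names = FALSE)
    summ <- base::c(res[c("tv_reweighted", "tv_unreweighted",
                          "tv_negative_control")], res$weight_stats)
  } else {
    utils::write.csv(data.frame(boltzmann = res$boltzmann,
                                direct = res$stationary$direct,
                                biased = res$stationary$biased,
                                reweighted = res$stationary$reweighted),
                     file.path(out, "stationary_vectors.csv"),
                     row.names = FALSE)
    summ <- base::c(res[c("tv_reweighted_vs_boltzmann",
                          "tv_biased_vs_boltzmann",
                          "tv_direct_vs_boltzmann")], res$weight_stats)
  }
  jsonlite::write_json(summ, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cli_log(subcommand = "experiment", system = cfg$system, out = out)
  0L
}

#' CLI dispatcher
#'
#' Thin command-line front end over the package functions; see
#' `inst/scripts/girsanov-cli` for the executable wrapper. Returns the exit
#' code instead of quitting so it can be tested in-process.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code: 0 ok, 2 configuration error, 3 numerical
#'   failure.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "-h", "help")) {
    cat(cli_usage(), "\n")
    return(0L)
  }
  sub <- args[1]
  rest <- args[-1]
  if (length(rest) && rest[1] %in% c("--help", "-h")) {
    cat(cli_usage(), "\n")
    return(0L)
  }
  handler <- switch(sub,
                    simulate = cli_simulate,
                    msm = cli_msm,
                    experiment = cli_experiment,
                    fixtures = function(flags) {
                      out <- flags$out %||% stop("--out DIR is required")
                      generate_fixtures(out,
                                        as.integer(flags$seed %||% 20240612))
                      cli_log(subcommand = "fixtures", out = out)
                      0L
                    },
                    NULL)
  if (is.null(handler)) {
    message("unknown subcommand '", sub, "'\n", cli_usage())
    return(2L)
  }
  tryCatch({
    flags <- parse_cli_flags(rest)
    handler(flags)
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("blow-up|not finite|eigen", msg)) 3L else 2L
  })
}
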