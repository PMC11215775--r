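# Girsanov path-weight machinery.
#
# Convention (fixed once, here): the target potential is Vtilde = V + U with
# perturbation U; an enhanced-sampling bias satisfies U = -U_bias.  For a
# path simulated at V with noise sequence eta, the weight of the window
# [k', k' + n_interval] is
#   log W = log g + log M,
#   log g = -U(q_{k'}) / RT                (initial-state Boltzmann ratio,
#                                           partition-function constant omitted)
#   log M = -sum_k s_k,  s_k = sum_l (eta Deta + Deta^2 / 2)
# where the random-number difference Deta is the shift that makes the step
# at V coincide with the same step at Vtilde; its form depends on the
# splitting scheme and is certified against the step-inversion oracle.

#' Random-number difference for one integrator step
#'
#' Returns the per-degree-of-freedom shift between the noise that realises a
#' step at the simulation potential and the noise that realises the same
#' step at the target potential, for the supported splitting schemes:
#' \describe{
#'   \item{ABO}{`Deta = d dt grad U(q_after) / f`}
#'   \item{ABOBA}{`Deta = (1 + d) dt grad U(q_mid) / (2 f)`}
#'   \item{AOBOA}{combined channel `d' Deta1 + Deta2 =
#'     d' dt grad U(q_mid) / f'` with variance `1 + d'^2` (the endpoint
#'     determines only this combination)}
#'   \item{BOAOB}{`Deta1 = d' dt grad U(q_before) / (2 f')`,
#'     `Deta2 = dt grad U(q_after) / (2 f')`}
#'   \item{OBABO}{`Deta1 = dt grad U(q_before) / (2 f')`,
#'     `Deta2 = d' dt grad U(q_after) / (2 f')`}
#' }
#'
#' @param scheme a reweightable [parse_scheme()] result.
#' @param op an [operator_params()] object (requires f > 0).
#' @param gradU named list of perturbation gradients evaluated where the
#'   scheme needs them: any of `before`, `intermediate`, `after` (positions
#'   at the start of the step, after the first position update, and at the
#'   end of the step).
#' @param as_bias the supplied gradients are of the bias potential
#'   U_bias = -U; flips the sign.
#' @return object of class `delta_eta`: list with `delta1`, optional
#'   `delta2`, `combined` flag and `comb_var` (channel variance; 1 except
#'   for the AOBOA combination).
#' @export
delta_eta <- function(scheme, op, gradU, as_bias = FALSE) {
  stopifnot(inherits(scheme, "splitting_scheme"),
            inherits(op, "operator_params"))
  if (!scheme$reweightable)
    stop("random-number difference undefined for this splitting scheme")
  if (any(op$f == 0) || any(op$f_half == 0))
    stop("random-number difference undefined for f = 0 (xi = 0 or T = 0)")
  sgn <- if (as_bias) -1 else 1
  need <- function(name) {
    g <- gradU[[name]]
    if (is.null(g))
      stop("delta_eta for ", scheme$canonical,
           " needs gradU$", name)
    sgn * g
  }
  dt <- op$dt
  res <- switch(scheme$canonical,
    ABO = list(delta1 = op$d * dt * need("after") / op$f,
               delta2 = NULL, combined = FALSE, comb_var = 1),
    ABOBA = list(delta1 = (1 + op$d) * dt * need("intermediate") /
                   (2 * op$f),
                 delta2 = NULL, combined = FALSE, comb_var = 1),
    AOBOA = list(delta1 = op$d_half * dt * need("intermediate") / op$f_half,
                 delta2 = NULL, combined = TRUE,
                 comb_var = 1 + op$d_half^2),
    BOAOB = list(delta1 = op$d_half * dt * need("before") / (2 * op$f_half),
                 delta2 = dt * need("after") / (2 * op$f_half),
                 combined = FALSE, comb_var = 1),
    OBABO = list(delta1 = dt * need("before") / (2 * op$f_half),
                 delta2 = op$d_half * dt * need("after") / (2 * op$f_half),
                 combined = FALSE, comb_var = 1))
  structure(res, class = "delta_eta")
}

#' Per-step log-weight increment
#'
#' `s_k = sum_l (eta Deta + Deta^2 / 2) / var` summed over the noise
#' channels; the conditional path-probability ratio over a window is
#' `M = exp(-sum_k s_k)`. For the AOBOA combined channel, `noise` must hold
#' the combination `d' eta1 + eta2` and the variance `1 + d'^2` is applied.
#'
#' @param noise list of noise vectors: `eta1` and optionally `eta2` (or the
#'   combination for AOBOA).
#' @param delta a [delta_eta()] result.
#' @return scalar increment s_k.
#' @export
log_m_increment <- function(noise, delta) {
  stopifnot(inherits(delta, "delta_eta"))
  eta1 <- noise[[1]]
  if (length(eta1) != length(delta$delta1))
    stop("noise/delta shape mismatch")
  s <- sum(eta1 * delta$delta1 + 0.5 * delta$delta1^2) / delta$comb_var
  if (!is.null(delta$delta2)) {
    eta2 <- noise[[2]]
    if (is.null(eta2) || length(eta2) != length(delta$delta2))
      stop("noise/delta shape mismatch (second channel)")
    s <- s + sum(eta2 * delta$delta2 + 0.5 * delta$delta2^2)
  }
  s
}

# Internal: full per-step increment from raw step data.  q_pre/q_mid/q_post
# are the positions before the step, after the first position update, and
# after the step; `noise` is the list of raw draws.
reweight_increment <- function(scheme, op, noise, q_pre, q_mid, q_post, U) {
  pts <- scheme$eval_points
  gradU <- list()
  if ("before" %in% pts) gradU$before <- potential_gradient(U, q_pre)
  if ("intermediate" %in% pts)
    gradU$intermediate <- potential_gradient(U, q_mid)
  if ("after" %in% pts) gradU$after <- potential_gradient(U, q_post)
  de <- delta_eta(scheme, op, gradU)
  if (de$combined) {
    comb <- op$d_half * noise[[1]] + noise[[2]]
    log_m_increment(list(comb), de)
  } else {
    log_m_increment(noise, de)
  }
}

#' Accumulate per-step increments over one recording interval
#'
#' @param increments numeric vector of per-step increments.
#' @param n_out expected number of increments (checked when supplied).
#' @return their sum (the dS entry of one reweighting record).
#' @export
accumulate_interval <- function(increments, n_out = NULL) {
  if (!is.null(n_out) && length(increments) != n_out)
    stop("expected ", n_out, " increments, got ", length(increments))
  sum(increments)
}

#' Log initial-state ratio
#'
#' `log g = -U(q_0) / RT` (equivalently `+U_bias(q_0) / RT`): the Boltzmann
#' density ratio of the window's first frame between target and simulation
#' ensembles, up to the partition-function constant that cancels after row
#' normalisation of the transition matrix. Momentum factors cancel because
#' both ensembles share the Maxwell-Boltzmann momentum density.
#'
#' @param u_q0 perturbation energy U(q_0), kJ/mol.
#' @param rt thermal energy RT, kJ/mol (> 0).
#' @export
initial_state_log_ratio <- function(u_q0, rt) {
  if (!is.numeric(rt) || rt <= 0) stop("RT must be > 0")
  -u_q0 / rt
}

as_records <- function(x) {
  if (inherits(x, "langevin_trajectory")) x$records
  else if (is.data.frame(x)) x
  else stop("expected a langevin_trajectory or a records data frame")
}

#' Path weight of one sliding window
#'
#' Window of `n_interval` recording intervals starting at record row
#' `start` (1-based): `log M = -sum_{j = start+1}^{start+n_interval} dS_j`,
#' `log g` from the record at `start`, `log W = log g + log M`.
#'
#' @param x a `langevin_trajectory` or its `records` data frame.
#' @param start 1-based row index of the window's first record.
#' @param n_interval window length in recording intervals (>= 1).
#' @param rt thermal energy RT (taken from the trajectory when available).
#' @return list with `log_g`, `log_M`, `log_w`.
#' @export
window_weight <- function(x, start, n_interval, rt = NULL) {
  if (is.null(rt) && inherits(x, "langevin_trajectory")) rt <- x$rt
  rec <- as_records(x)
  n <- nrow(rec)
  if (n_interval < 1) stop("n_interval must be >= 1")
  if (start < 1 || start + n_interval > n)
    stop("window [", start, ", ", start + n_interval,
         "] exceeds the trajectory (", n, " records)")
  log_m <- -sum(rec$dS[(start + 1):(start + n_interval)])
  log_g <- initial_state_log_ratio(rec$U_kJ_per_mol[start], rt)
  list(log_g = log_g, log_M = log_m, log_w = log_g + log_m)
}

#' Path weights of all sliding windows
#'
#' Vectorised [window_weight()] over every admissible start record.
#'
#' @inheritParams window_weight
#' @return data frame with columns `start_row`, `frame_index`, `log_g`,
#'   `log_M`, `log_w` (one row per window start).
#' @export
window_log_weights <- function(x, n_interval, rt = NULL) {
  if (is.null(rt) && inherits(x, "langevin_trajectory")) rt <- x$rt
  if (is.null(rt)) stop("rt required")
  rec <- as_records(x)
  n <- nrow(rec)
  if (n_interval < 1 || n_interval >= n)
    stop("n_interval must be in [1, ", n - 1, "]")
  starts <- seq_len(n - n_interval)
  cs <- cumsum(rec$dS)
  log_m <- -(cs[starts + n_interval] - cs[starts])
  log_g <- initial_state_log_ratio(rec$U_kJ_per_mol[starts], rt)
  data.frame(start_row = starts,
             frame_index = rec$frame_index[starts],
             log_g = log_g, log_M = log_m, log_w = log_g + log_m)
}

#' Effective sample size of a set of log weights
#'
#' Kish effective sample size `(sum w)^2 / sum w^2`, computed in the log
#' domain with a max-shift.
#'
#' @param log_w numeric vector of log weights.
#' @export
effective_sample_size <- function(log_w) {
  m <- max(log_w)
  w <- exp(log_w - m)
  sum(w)^2 / sum(w^2)
}

# --- columnar file formats -------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read the position-trajectory file
#'
#' Tab-separated text, header row, columns `frame_index`, `time_ps`, then
#' one `q_<l>` column per degree of freedom; one row per recorded frame.
#'
#' @param traj a `langevin_trajectory`.
#' @param path file path.
#' @export
write_position_file <- function(traj, path) {
  stopifnot(inherits(traj, "langevin_trajectory"))
  nd <- traj$ndim
  df <- data.frame(frame_index = traj$records$frame_index,
                   time_ps = fmt_num(traj$records$time_ps))
  for (l in seq_len(nd)) df[[paste0("q_", l)]] <- fmt_num(traj$q[, l])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_position_file
#' @return `read_position_file()` returns a list with the frame matrix `q`,
#'   `frame_index` and `time_ps`.
#' @export
read_position_file <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  qcols <- grep("^q_", names(df), value = TRUE)
  if (!all(c("frame_index", "time_ps") %in% names(df)) || !length(qcols))
    stop("malformed position file: expected frame_index, time_ps, q_* columns")
  check_frame_index(df$frame_index, path)
  list(q = as.matrix(df[qcols]), frame_index = df$frame_index,
       time_ps = df$time_ps)
}

check_frame_index <- function(idx, path) {
  expect <- seq_along(idx) - 1L
  bad <- which(idx != expect)
  if (length(bad))
    stop("misaligned or truncated file '", path, "': row ", bad[1],
         " has frame_index ", idx[bad[1]], ", expected ", expect[bad[1]])
  invisible(TRUE)
}

#' Write / read the reweighting-factor file
#'
#' Tab-separated text written in lockstep with the position trajectory:
#' columns `frame_index`, `time_ps`, `dS`, `U_kJ_per_mol`. The round trip
#' is lossless (values are written with 17 significant digits).
#'
#' @param x a `langevin_trajectory` or a records data frame.
#' @param path file path.
#' @export
write_reweighting_file <- function(x, path) {
  rec <- as_records(x)
  df <- data.frame(frame_index = rec$frame_index,
                   time_ps = fmt_num(rec$time_ps),
                   dS = fmt_num(rec$dS),
                   U_kJ_per_mol = fmt_num(rec$U_kJ_per_mol))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reweighting_file
#' @return `read_reweighting_file()` returns a `reweighting_records` data
#'   frame.
#' @export
read_reweighting_file <- function(path) {
  df <- utils::read.delim(path)
  want <- c("frame_index", "time_ps", "dS", "U_kJ_per_mol")
  if (!identical(names(df), want))
    stop("malformed reweighting file '", path, "': columns must be ",
         paste(want, collapse = ", "))
  if (nrow(df)) check_frame_index(df$frame_index, path)
  class(df) <- c("reweighting_records", "data.frame")
  df
}
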