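# Markov state models over grid discretizations, with Girsanov-reweighted
# transition-count estimation, spectral analysis and implied timescales.

#' Regular grid discretization of position space
#'
#' @param mins,maxs per-dimension range limits (nm), `mins < maxs`.
#' @param bins per-dimension bin counts.
#' @return object of class `grid_discretization` with `n_states =
#'   prod(bins)`. States are numbered 1..n_states in row-major order (last
#'   dimension fastest).
#' @export
grid_discretization <- function(mins, maxs, bins) {
  mins <- as.numeric(mins); maxs <- as.numeric(maxs)
  bins <- as.integer(bins)
  stopifnot(length(mins) == length(maxs), length(bins) == length(mins),
            all(bins >= 1), all(maxs > mins))
  structure(list(mins = mins, maxs = maxs, bins = bins,
                 widths = (maxs - mins) / bins,
                 ndim = length(bins),
                 n_states = as.integer(prod(bins))),
            class = "grid_discretization")
}

#' @export
print.grid_discretization <- function(x, ...) {
  cat(sprintf("<grid_discretization> %s bins, %d states\n",
              paste(x$bins, collapse = " x "), x$n_states))
  invisible(x)
}

#' Bin centres of a grid discretization
#' @param grid a [grid_discretization()].
#' @return n_states x ndim matrix of bin centres in state order.
#' @export
grid_centers <- function(grid) {
  axes <- lapply(seq_len(grid$ndim), function(d)
    grid$mins[d] + (seq_len(grid$bins[d]) - 0.5) * grid$widths[d])
  g <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, rev(seq_len(grid$ndim)), drop = FALSE])
}

#' Assign trajectory frames to grid states
#'
#' Bins are half-open `[lo, hi)` except the last bin of each dimension,
#' which is closed. Frames outside the grid are clipped to the edge bin
#' (default) and counted in a warning, or dropped (returned as NA) with
#' `out_of_range = "drop"`.
#'
#' @param positions frame matrix (frames x ndim) or vector for 1D grids.
#' @param grid a [grid_discretization()].
#' @param out_of_range `"clip"` or `"drop"`.
#' @return integer vector of 1-based state indices, with attribute
#'   `n_out_of_range`.
#' @export
discretize <- function(positions, grid, out_of_range = c("clip", "drop")) {
  out_of_range <- match.arg(out_of_range)
  stopifnot(inherits(grid, "grid_discretization"))
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1)
  if (ncol(positions) != grid$ndim)
    stop("positions have ", ncol(positions), " dimensions, grid has ",
         grid$ndim)
  if (nrow(positions) == 0) stop("empty trajectory")
  n <- nrow(positions)
  oor <- rep(FALSE, n)
  idx <- rep(0L, n)
  for (d in seq_len(grid$ndim)) {
    x <- positions[, d]
    ix <- floor((x - grid$mins[d]) / grid$widths[d])
    ix[x == grid$maxs[d]] <- grid$bins[d] - 1L  # closed last bin
    oor <- oor | ix < 0 | ix > grid$bins[d] - 1L
    ix <- pmin(pmax(ix, 0), grid$bins[d] - 1L)
    idx <- idx * grid$bins[d] + as.integer(ix)
  }
  res <- idx + 1L
  n_oor <- sum(oor)
  if (n_oor > 0) {
    if (out_of_range == "drop") {
      res[oor] <- NA_integer_
    } else {
      warning(n_oor, " of ", n,
              " frames outside the grid were clipped to edge bins")
    }
  }
  attr(res, "n_out_of_range") <- n_oor
  res
}

#' Girsanov-reweighted transition-count matrix
#'
#' Sliding-window estimator with stride 1: for every start frame m with
#' m + lag in range, `exp(log_w_m - max(log_w))` is added to
#' `C[s_m, s_{m+lag}]`. With `log_weights = NULL` all weights are 1 and the
#' estimator reduces to the direct maximum-likelihood count matrix. The
#' global rescaling constant `max(log_w)` is stored as attribute
#' `log_rescale`; it cancels in the row normalisation of the transition
#' matrix.
#'
#' @param dtraj integer state sequence (1-based), or a list of sequences
#'   (one per trajectory).
#' @param lag lag time in recorded frames (>= 1).
#' @param n_states number of grid states.
#' @param log_weights numeric vector of window log weights aligned with the
#'   start frames (length `length(dtraj) - lag` per trajectory), or a list
#'   matching `dtraj`; NULL for unit weights.
#' @return `reweighted_count_matrix`: an n_states x n_states matrix with
#'   attributes `lag`, `log_rescale`, `total_weight`.
#' @export
reweighted_count_matrix <- function(dtraj, lag, n_states,
                                    log_weights = NULL) {
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1 frame")
  if (!is.list(dtraj)) dtraj <- list(dtraj)
  if (!is.null(log_weights) && !is.list(log_weights))
    log_weights <- list(log_weights)
  if (!is.null(log_weights) && length(log_weights) != length(dtraj))
    stop("log_weights must supply one vector per trajectory in dtraj")
  n_states <- as.integer(n_states)

  max_lw <- 0
  if (!is.null(log_weights))
    max_lw <- max(vapply(log_weights, max, 0))

  C <- matrix(0, n_states, n_states)
  for (t in seq_along(dtraj)) {
    s <- as.integer(dtraj[[t]])
    n <- length(s)
    if (n <= lag) next
    starts <- seq_len(n - lag)
    i <- s[starts]
    j <- s[starts + lag]
    w <- if (is.null(log_weights)) rep(1, length(starts))
         else {
           lw <- log_weights[[t]]
           if (length(lw) != length(starts))
             stop("log_weights misaligned: trajectory ", t, " has ",
                  length(starts), " window starts but ", length(lw),
                  " weights")
           exp(lw - max_lw)
         }
    ok <- !is.na(i) & !is.na(j)
    if (!all(ok)) { i <- i[ok]; j <- j[ok]; w <- w[ok] }
    if (any(i < 1 | i > n_states | j < 1 | j > n_states))
      stop("state indices outside 1..n_states")
    key <- (i - 1) * n_states + j
    agg <- rowsum(w, key)
    ki <- as.integer(rownames(agg))
    C[cbind((ki - 1L) %/% n_states + 1L, (ki - 1L) %% n_states + 1L)] <-
      C[cbind((ki - 1L) %/% n_states + 1L, (ki - 1L) %% n_states + 1L)] +
      agg[, 1]
  }
  structure(C, lag = lag, log_rescale = max_lw, total_weight = sum(C),
            class = c("reweighted_count_matrix", "matrix", "array"))
}

#' Row-stochastic transition matrix from a count matrix
#'
#' States without outgoing weight are dropped (iteratively, so that every
#' remaining row has positive weight within the active set) rather than
#' patched with self-loops; the retained state indices are stored in the
#' `active_set` attribute. Reversibility is not enforced.
#'
#' @param C nonnegative count matrix.
#' @return `transition_matrix`: row-stochastic matrix over the active set
#'   with attribute `active_set`.
#' @export
transition_matrix <- function(C) {
  C <- unclass(C)
  if (any(C < 0)) stop("count matrix must be nonnegative")
  if (all(C == 0)) stop("all-zero count matrix")
  active <- seq_len(nrow(C))
  repeat {
    sub <- C[active, active, drop = FALSE]
    rs <- rowSums(sub)
    if (all(rs > 0)) break
    active <- active[rs > 0]
    if (!length(active)) stop("all-zero count matrix after trimming")
  }
  P <- sub / rs
  structure(P, active_set = active,
            class = c("transition_matrix", "matrix", "array"))
}

#' Eigenvalues and left eigenvectors of a transition matrix
#'
#' Eigenpairs sorted by descending modulus (ties broken by descending real
#' part). The stationary vector l_0 is normalised to sum 1 with nonnegative
#' entries; the remaining left eigenvectors are sign-fixed (largest-modulus
#' entry positive) and scaled to unit 2-norm. Eigenvalues with imaginary
#' part above `tol_imag` trigger a warning and are returned as complex.
#'
#' @param P a row-stochastic matrix.
#' @param tol_imag imaginary-part tolerance (default 1e-10).
#' @return `spectral_result`: list with `values`, `left_vectors` (columns
#'   l_0, l_1, ...), and the `is_complex` flag.
#' @export
spectral_analysis <- function(P, tol_imag = 1e-10) {
  P <- unclass(P)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (max(abs(rowSums(P) - 1)) > 1e-8 || any(P < -1e-12))
    stop("input is not row-stochastic")
  e <- eigen(t(P))
  ord <- order(-Mod(e$values), -Re(e$values))
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  is_complex <- any(abs(Im(vals)) > tol_imag)
  if (is_complex) {
    warning("complex eigenvalues above tolerance; returning complex results")
  } else {
    vals <- Re(vals)
    vecs <- Re(vecs)
  }
  # stationary vector: normalise to sum 1 (fixes the sign)
  vecs[, 1] <- vecs[, 1] / sum(vecs[, 1])
  if (ncol(vecs) > 1) {
    for (i in 2:ncol(vecs)) {
      v <- vecs[, i]
      sgn <- sign(Re(v[which.max(Mod(v))]))
      if (sgn == 0) sgn <- 1
      vecs[, i] <- sgn * v / sqrt(sum(Mod(v)^2))
    }
  }
  structure(list(values = vals, left_vectors = vecs,
                 n_states = nrow(P), is_complex = is_complex),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  k <- min(5, length(x$values))
  cat("<spectral_result> leading eigenvalues:",
      paste(signif(x$values[seq_len(k)], 6), collapse = ", "), "\n")
  invisible(x)
}

#' Implied timescales from MSM eigenvalues
#'
#' `t_i(tau) = -tau / log |lambda_i|` for i >= 1. Nonpositive real
#' eigenvalues and moduli >= 1 yield NA (undefined) rather than an error.
#'
#' @param values eigenvalues sorted as in [spectral_analysis()] (the leading
#'   eigenvalue 1 is skipped).
#' @param lag_ps lag time in ps.
#' @return numeric vector of timescales t_1, t_2, ... in ps.
#' @export
implied_timescales <- function(values, lag_ps) {
  stopifnot(lag_ps > 0)
  lam <- values[-1]
  out <- rep(NA_real_, length(lam))
  for (i in seq_along(lam)) {
    l <- lam[i]
    if (is.complex(l) && abs(Im(l)) < 1e-12) l <- Re(l)
    m <- Mod(l)
    if (m >= 1) next
    if (!is.complex(l) && l <= 0) next
    out[i] <- -lag_ps / log(m)
  }
  out
}

#' Estimate an MSM at one lag
#'
#' Convenience wrapper: count matrix (optionally reweighted), transition
#' matrix and spectral analysis in one call.
#'
#' @inheritParams reweighted_count_matrix
#' @return list with `C`, `P`, `spectral`, `active_set`.
#' @export
msm_estimate <- function(dtraj, lag, n_states, log_weights = NULL) {
  C <- reweighted_count_matrix(dtraj, lag, n_states, log_weights)
  P <- transition_matrix(C)
  sp <- spectral_analysis(P)
  list(C = C, P = P, spectral = sp, active_set = attr(P, "active_set"))
}

#' Stationary distribution on the full state set
#'
#' Embeds the stationary left eigenvector of an MSM into the full grid,
#' zero at inactive states.
#'
#' @param msm result of [msm_estimate()].
#' @param n_states total number of grid states.
#' @export
stationary_distribution <- function(msm, n_states) {
  full <- numeric(n_states)
  l0 <- Re(msm$spectral$left_vectors[, 1])
  full[msm$active_set] <- l0
  full / sum(full)
}

#' Total variation distance between two probability vectors
#' @param p,q probability vectors of equal length.
#' @export
total_variation <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}

#' Exact simulation of a discrete Markov chain
#'
#' Utility for self-consistency tests: samples a state sequence from a
#' known row-stochastic matrix.
#'
#' @param P row-stochastic matrix.
#' @param n_steps number of transitions.
#' @param init initial state (1-based); uniform draw when NULL.
#' @export
sample_markov_chain <- function(P, n_steps, init = NULL) {
  P <- unclass(P)
  n <- nrow(P)
  s <- integer(n_steps + 1)
  s[1] <- if (is.null(init)) sample.int(n, 1) else as.integer(init)
  cum <- t(apply(P, 1, cumsum))
  u <- stats::runif(n_steps)
  for (k in seq_len(n_steps)) {
    s[k + 1] <- findInterval(u[k], cum[s[k], ]) + 1L
  }
  s
}
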