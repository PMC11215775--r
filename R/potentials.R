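# Potential-energy surfaces and simulation/target potential pairs.
#
# A potential bundles analytic energy/gradient closures with an optional list
# of parametric "terms" that the compiled simulation core evaluates directly.
# Energies are molar (kJ/mol), positions nm, so gradients are kJ/mol/nm.

new_potential <- function(energy, gradient, ndim, terms = NULL,
                          label = "custom") {
  stopifnot(is.function(energy), is.function(gradient), ndim >= 1)
  structure(list(energy = energy, gradient = gradient,
                 ndim = as.integer(ndim), terms = terms, label = label),
            class = "potential")
}

check_position <- function(q, ndim) {
  q <- as.numeric(q)
  if (length(q) != ndim)
    stop("position has ", length(q), " components, potential expects ", ndim)
  if (any(!is.finite(q)))
    stop("non-finite position supplied to potential")
  q
}

#' Evaluate a potential
#'
#' @param pot a `potential` object.
#' @param q numeric position vector (nm), length `pot$ndim`.
#' @return `potential_energy()` returns the energy in kJ/mol;
#'   `potential_gradient()` the analytic gradient in kJ/mol/nm.
#' @export
potential_energy <- function(pot, q) {
  stopifnot(inherits(pot, "potential"))
  pot$energy(check_position(q, pot$ndim))
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(pot, q) {
  stopifnot(inherits(pot, "potential"))
  pot$gradient(check_position(q, pot$ndim))
}

#' @export
print.potential <- function(x, ...) {
  cat("<potential> ", x$label, " (", x$ndim, "D",
      if (is.null(x$terms)) ", closure-only" else ", compiled terms",
      ")\n", sep = "")
  invisible(x)
}

#' Mueller-Brown parameter set
#'
#' Four-term exponential parameterisation of the Mueller-Brown surface.
#' Defaults are the benchmark values used throughout the package: amplitudes
#' `A` in kJ/mol, exponent coefficients `a`, `b`, `c` in nm^-2 and term
#' centres `x0`, `y0` in nm.
#'
#' @param A,a,b,c,x0,y0 numeric vectors of length 4.
#' @return an object of class `mueller_brown_params`.
#' @export
mueller_brown_params <- function(A = base::c(-20, -10, -17, 1.5),
                                 a = base::c(-1, -1, -6.5, 0.7),
                                 b = base::c(0, 0, 11, 0.6),
                                 c = base::c(-10, -10, -6.5, 0.7),
                                 x0 = base::c(1, 0, -0.5, -1),
                                 y0 = base::c(0, 0.5, 1.5, 1)) {
  params <- list(A = A, a = a, b = b, c = c, x0 = x0, y0 = y0)
  len <- vapply(params, length, 1L)
  if (any(len != 4L))
    stop("Mueller-Brown parameters must have exactly 4 terms per field")
  if (!all(vapply(params, function(v) all(is.finite(v)), TRUE)))
    stop("Mueller-Brown parameters must be finite")
  structure(params, class = "mueller_brown_params")
}

#' Mueller-Brown potential
#'
#' Two-dimensional benchmark surface
#' \deqn{V(x, y) = \sum_{n=1}^{4} A_n \exp[a_n (x-x_n)^2 +
#'   b_n (x-x_n)(y-y_n) + c_n (y-y_n)^2]}
#' with a global minimum near (-0.5, 1.5) nm and two local minima near
#' (0, 0.5) and (0.5, 0) nm at the default parameters.
#'
#' @param params a [mueller_brown_params()] object.
#' @return a `potential`.
#' @export
mueller_brown <- function(params = mueller_brown_params()) {
  stopifnot(inherits(params, "mueller_brown_params"))
  A <- params$A; a <- params$a; b <- params$b
  cc <- params$c; x0 <- params$x0; y0 <- params$y0
  energy <- function(q) {
    dx <- q[1] - x0; dy <- q[2] - y0
    sum(A * exp(a * dx^2 + b * dx * dy + cc * dy^2))
  }
  gradient <- function(q) {
    dx <- q[1] - x0; dy <- q[2] - y0
    en <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    base::c(sum(en * (2 * a * dx + b * dy)),
            sum(en * (b * dx + 2 * cc * dy)))
  }
  terms <- list(list(kind = "mueller_brown", scale = 1,
                     par = base::c(A, a, b, cc, x0, y0)))
  new_potential(energy, gradient, 2L, terms, "Mueller-Brown")
}

#' Polynomial bias coefficients for the Mueller-Brown benchmark
#'
#' Degree-13 coefficient vector a_1..a_13 of the built-in polynomial bias
#' (used with prefactor k = 50 kJ/mol/nm).
#'
#' @return numeric vector of length 13.
#' @export
mb_polynomial_coefficients <- function() {
  c(2.06e-02, -2.32e-02, 3.83e-03, 3.92e-02, -1.39e-02, -3.39e-02,
    3.82e-04, 1.24e-02, 3.37e-03, -1.18e-03, -7.50e-04, -1.38e-04,
    -8.81e-06)
}

# Horner evaluation of sum_{i=1..m} a_i x^i and its derivative.
poly_series_value <- function(x, coef) {
  s <- 0
  for (i in rev(seq_along(coef))) s <- coef[i] + x * s
  x * s
}

poly_series_deriv <- function(x, coef) {
  d <- coef * seq_along(coef)
  s <- 0
  for (i in rev(seq_along(d))) s <- d[i] + x * s
  s
}

#' Bias potentials along the x-coordinate
#'
#' Linear bias `k * x` or polynomial bias `k * sum_i a_i x^i` acting on the
#' first degree of freedom of an `ndim`-dimensional system. `k` is in
#' kJ/mol/nm; the benchmark values are k = 1 (linear) and k = 50 with the
#' [mb_polynomial_coefficients()] (polynomial).
#'
#' @param kind `"linear"` or `"polynomial"`.
#' @param k prefactor, kJ/mol/nm.
#' @param coefficients polynomial coefficients a_1..a_m (required for
#'   `"polynomial"`).
#' @param ndim dimensionality of positions the bias will be applied to.
#' @return a `potential`.
#' @export
bias_potential <- function(kind = c("linear", "polynomial"), k = 1,
                           coefficients = NULL, ndim = 2L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(k), length(k) == 1, is.finite(k))
  ndim <- as.integer(ndim)
  if (kind == "linear") {
    energy <- function(q) k * q[1]
    gradient <- function(q) base::c(k, rep(0, ndim - 1L))
    terms <- list(list(kind = "linear_x", scale = 1, par = base::c(k, ndim)))
    label <- sprintf("linear bias (k = %g kJ/mol/nm)", k)
  } else {
    if (is.null(coefficients) || !length(coefficients))
      stop("polynomial bias requires a coefficient vector a_1..a_m")
    coefficients <- as.numeric(coefficients)
    energy <- function(q) k * poly_series_value(q[1], coefficients)
    gradient <- function(q)
      base::c(k * poly_series_deriv(q[1], coefficients), rep(0, ndim - 1L))
    terms <- list(list(kind = "poly_x", scale = 1,
                       par = base::c(k, coefficients)))
    label <- sprintf("polynomial bias (k = %g, degree %d)", k,
                     length(coefficients))
  }
  new_potential(energy, gradient, ndim, terms, label)
}

#' Harmonic toy potential
#'
#' `V(q) = 1/2 sum_l k_l q_l^2`; `k` may be a scalar (1D) or per-dof vector
#' of stiffnesses in kJ/mol/nm^2.
#'
#' @export
harmonic_potential <- function(k = 1) {
  k <- as.numeric(k)
  if (any(k <= 0) || any(!is.finite(k))) stop("harmonic stiffness must be > 0")
  ndim <- length(k)
  new_potential(function(q) 0.5 * sum(k * q^2),
                function(q) k * q,
                ndim,
                list(list(kind = "harmonic", scale = 1, par = k)),
                sprintf("harmonic (k = %s)", paste(k, collapse = ", ")))
}

#' Quartic double-well toy potential (1D)
#'
#' `V(q) = h ((q^2 - q0^2) / q0^2)^2`: minima at q = +-q0 with V = 0 and a
#' barrier of height `h` (kJ/mol) at q = 0.
#'
#' @param height barrier height h, kJ/mol (> 0).
#' @param q_min location of the minima, nm (> 0).
#' @export
double_well_potential <- function(height = 6, q_min = 0.15) {
  stopifnot(is.numeric(height), height > 0, is.numeric(q_min), q_min > 0)
  q04 <- q_min^4
  new_potential(function(q) height * (q[1]^2 - q_min^2)^2 / q04,
                function(q) 4 * height * q[1] * (q[1]^2 - q_min^2) / q04,
                1L,
                list(list(kind = "double_well", scale = 1,
                          par = base::c(height, q_min))),
                sprintf("double well (h = %g kJ/mol, q0 = %g nm)",
                        height, q_min))
}

#' Zero potential
#' @param ndim dimensionality.
#' @export
zero_potential <- function(ndim = 1L) {
  ndim <- as.integer(ndim)
  new_potential(function(q) 0, function(q) rep(0, ndim), ndim,
                list(), "zero")
}

#' Scale a potential by a constant
#' @param pot a `potential`; @param s scalar multiplier.
#' @export
scale_potential <- function(pot, s) {
  stopifnot(inherits(pot, "potential"), is.numeric(s), length(s) == 1)
  terms <- if (!is.null(pot$terms)) {
    lapply(pot$terms, function(t) { t$scale <- t$scale * s; t })
  }
  new_potential(function(q) s * pot$energy(q),
                function(q) s * pot$gradient(q),
                pot$ndim, terms, sprintf("%g * (%s)", s, pot$label))
}

#' Sum of potentials
#'
#' Pointwise sum; compiled terms are concatenated when all summands carry
#' them, otherwise the sum is closure-only.
#' @param ... `potential` objects of equal dimensionality.
#' @export
potential_sum <- function(...) {
  pots <- list(...)
  stopifnot(length(pots) >= 1)
  for (p in pots) stopifnot(inherits(p, "potential"))
  ndim <- unique(vapply(pots, function(p) p$ndim, 1L))
  if (length(ndim) != 1)
    stop("cannot sum potentials of different dimensionality")
  terms <- if (all(!vapply(pots, function(p) is.null(p$terms), TRUE)))
    do.call(base::c, lapply(pots, function(p) p$terms))
  new_potential(function(q) sum(vapply(pots, function(p) p$energy(q), 0)),
                function(q) Reduce(`+`, lapply(pots, function(p) p$gradient(q))),
                ndim, terms,
                paste(vapply(pots, function(p) p$label, ""), collapse = " + "))
}

#' Simulation/target potential pair
#'
#' Bundles the simulation potential V (the surface actually propagated), the
#' target potential Vtilde (the surface reweighted to) and the perturbation
#' U with the convention Vtilde = V + U. Supply either `perturbation` (U
#' directly, so V = target - U) or `bias` (enhanced-sampling viewpoint:
#' V = target + U_bias and U = -U_bias). With neither, U = 0 and V = target.
#'
#' @param target the target potential Vtilde.
#' @param perturbation optional perturbation potential U.
#' @param bias optional bias potential U_bias.
#' @return an object of class `potential_pair` with fields `V`, `V_target`,
#'   `U`, `convention_note`.
#' @export
potential_pair <- function(target, perturbation = NULL, bias = NULL) {
  stopifnot(inherits(target, "potential"))
  if (!is.null(perturbation) && !is.null(bias))
    stop("supply either `perturbation` or `bias`, not both")
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "potential"))
    if (bias$ndim != target$ndim) stop("bias dimensionality mismatch")
    U <- scale_potential(bias, -1)
    V <- potential_sum(target, bias)
    note <- "bias"
    has_u <- TRUE
  } else if (!is.null(perturbation)) {
    stopifnot(inherits(perturbation, "potential"))
    if (perturbation$ndim != target$ndim)
      stop("perturbation dimensionality mismatch")
    U <- perturbation
    V <- potential_sum(target, scale_potential(perturbation, -1))
    note <- "perturbation"
    has_u <- TRUE
  } else {
    U <- zero_potential(target$ndim)
    V <- target
    note <- "none"
    has_u <- FALSE
  }
  structure(list(V = V, V_target = target, U = U,
                 convention_note = note, has_perturbation = has_u,
                 ndim = target$ndim),
            class = "potential_pair")
}

#' @export
print.potential_pair <- function(x, ...) {
  cat("<potential_pair> Vtilde = V + U (input viewpoint: ",
      x$convention_note, ")\n  V      : ", x$V$label,
      "\n  Vtilde : ", x$V_target$label,
      "\n  U      : ", x$U$label, "\n", sep = "")
  invisible(x)
}

#' Central finite-difference gradient
#'
#' Oracle used to validate the analytic gradients of the built-in potentials.
#'
#' @param pot a `potential`; @param q position; @param h step (nm, > 0).
#' @export
finite_difference_gradient <- function(pot, q, h = 1e-6) {
  stopifnot(h > 0)
  q <- check_position(q, pot$ndim)
  vapply(seq_along(q), function(l) {
    qp <- q; qm <- q
    qp[l] <- qp[l] + h
    qm[l] <- qm[l] - h
    (pot$energy(qp) - pot$energy(qm)) / (2 * h)
  }, 0)
}
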