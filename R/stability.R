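#' @title Linearized mode matrices of the contraction model
#'
#' @description The model linearized about the homogeneous equilibrium
#' decouples per Fourier mode into a 6x6 system \eqn{y' + A y = 0} in the
#' variable order (c, M, N, rho, v, eps). The leading 4x4 (chemical) block is
#' lower-triangular in this order, so four eigenvalues are diagonal entries;
#' the trailing 2x2 (mechanical) block couples velocity and effective strain
#' through imaginary first-derivative entries whose product
#' \eqn{A_{56} A_{65}} is real.
#'
#' `assemble_continuous()` builds the matrix for continuous Fourier mode `k`
#' on a domain of length `omega_len`; `assemble_discrete()` builds the Von
#' Neumann matrix of the central finite-difference semi-discretization on a
#' uniform grid with `n` intervals of size `h`, where the continuous factors
#' \eqn{(2\pi k)^2} and \eqn{(2\pi k)} are replaced by
#' \eqn{4\sin^2(\pi\beta/n)/h^2} and \eqn{\sin(2\pi\beta/n)/h}.
#'
#' @param params a [wound_params()] object.
#' @param eq an [equilibrium_state()] object.
#' @param k integer Fourier mode index (any integer; `k = 0` is the
#'   constant mode, for which both mechanical eigenvalues vanish).
#' @param omega_len domain length in cm (default 1, the half-domain used for
#'   the stability experiments).
#' @return An object of class `linearized_system`: list with the complex
#'   6x6 matrix `A`, the real product `A56A65`, and mode metadata.
#' @name linearized_system
NULL

# Shared entry assembly. s2 replaces (2 pi k)^2, s1 replaces (2 pi k);
# `conv_sign` is +1 for the continuous problem and -1 for the discrete one
# (the discrete Fourier ansatz uses the conjugate exponential, flipping the
# sign of the imaginary first-derivative couplings; eigenvalues only involve
# the product A56*A65 and are unaffected).
assemble_mode_matrix <- function(params, eq, s2, s1, conv_sign) {
  p <- params
  Nb <- eq$N_bar; rb <- eq$rho_bar; eb <- eq$eps_bar
  if (p$kappa_F * Nb >= 1)
    stop("invalid equilibrium: kappa_F * N_bar >= 1")
  A <- matrix(0 + 0i, 6, 6,
              dimnames = list(c("c", "M", "N", "rho", "v", "eps"),
                              c("c", "M", "N", "rho", "v", "eps")))
  A[1, 1] <- p$D_c * s2 + Nb * (p$delta_c * rb - p$k_c / p$a_c_I)
  A[2, 1] <- -p$k_F * Nb
  A[2, 2] <- p$D_F * Nb * s2 + p$delta_M
  A[3, 1] <- -p$chi_F * Nb * s2 -
    Nb * (p$r_F * p$r_F_max / p$a_c_III * (1 - p$kappa_F * Nb) * Nb^p$q -
            p$k_F)
  A[3, 2] <- p$r_F * p$kappa_F * Nb^(1 + p$q)
  A[3, 3] <- p$D_F * Nb * s2 + p$delta_N -
    p$r_F * Nb^p$q * ((1 + p$q) * (1 - p$kappa_F * Nb) - p$kappa_F * Nb)
  A[4, 1] <- -p$delta_rho * rb^2 * Nb * (p$k_rho_max / p$a_c_IV + p$a_c_II)
  A[4, 2] <- p$delta_rho * rb^2 * (p$eta_II - p$eta_I)
  A[4, 4] <- 2 * p$delta_rho * Nb * rb
  iu <- conv_sign * 1i
  A[5, 2] <- -iu * p$xi * rb / (p$rho_t * (p$R^2 + rb^2)) * s1
  A[5, 4] <- -iu * p$E * eb / (2 * p$rho_t * sqrt(rb)) * s1
  A[5, 5] <- p$mu / p$rho_t * s2
  A[5, 6] <- -iu * p$E * sqrt(rb) / p$rho_t * s1
  A[6, 1] <- p$zeta * eb * Nb
  A[6, 5] <- iu * (eb - 1) * s1
  A
}

#' @rdname linearized_system
#' @export
assemble_continuous <- function(params, eq, k, omega_len = 1) {
  stopifnot(k == round(k), omega_len > 0)
  s1 <- 2 * pi * k / omega_len
  A <- assemble_mode_matrix(params, eq, s1^2, s1, conv_sign = +1)
  structure(list(A = A, A56A65 = Re(A[5, 6] * A[6, 5]),
                 kind = "continuous", k = k, omega_len = omega_len),
            class = "linearized_system")
}

#' @rdname linearized_system
#' @param beta integer discrete mode index, 1 <= beta <= n - 1.
#' @param h uniform grid spacing in cm.
#' @param n number of grid intervals; `h * n` is the domain length
#'   (default `round(1/h)`, a unit domain).
#' @export
assemble_discrete <- function(params, eq, beta, h, n = round(1 / h)) {
  stopifnot(beta == round(beta), h > 0, n >= 2)
  theta <- pi * beta / n               # = pi * beta * h / |Omega|
  s2 <- 4 * sin(theta)^2 / h^2
  s1 <- sin(2 * theta) / h
  A <- assemble_mode_matrix(params, eq, s2, s1, conv_sign = -1)
  structure(list(A = A, A56A65 = Re(A[5, 6] * A[6, 5]),
                 kind = "discrete", beta = beta, h = h, n = n),
            class = "linearized_system")
}

#' @export
print.linearized_system <- function(x, ...) {
  cat("<linearized_system>", x$kind, "mode",
      if (x$kind == "continuous") paste0("k = ", x$k)
      else paste0("beta = ", x$beta, ", h = ", format(x$h)), "\n")
  print(x$A)
  invisible(x)
}

#' Eigenvalues of a linearized mode system
#'
#' The 6x6 mode matrix is block-triangular up to the mechanical pair: its
#' eigenvalues are the four chemical diagonal entries plus the roots of
#' \eqn{\lambda^2 - A_{55}\lambda - A_{56}A_{65}}, i.e.
#' \eqn{\lambda = \tfrac12 A_{55} \pm \tfrac12\sqrt{A_{55}^2 + 4 A_{56}A_{65}}}.
#' With the sign convention \eqn{y' + A y = 0}, non-negative real parts mean
#' decay of the perturbation.
#'
#' @param sys a `linearized_system` from [assemble_continuous()] or
#'   [assemble_discrete()].
#' @param method `"analytic"` (pivot structure, default) or `"dense"`
#'   (generic dense eigensolver on the full complex matrix, used as an
#'   independent cross-check).
#' @return Complex vector of six eigenvalues. The analytic ordering is
#'   (c, M, N, rho, mechanical +, mechanical -); the dense solver's ordering
#'   is unspecified.
#' @export
eigenvalues_continuous <- function(sys, method = c("analytic", "dense")) {
  stopifnot(inherits(sys, "linearized_system"))
  method <- match.arg(method)
  if (method == "dense")
    return(eigen(sys$A, only.values = TRUE)$values)
  A <- sys$A
  a55 <- complex(real = Re(A[5, 5]))
  disc <- sqrt(as.complex(a55^2 + 4 * sys$A56A65))
  c(A[1, 1], A[2, 2], A[3, 3], A[4, 4],
    0.5 * a55 + 0.5 * disc, 0.5 * a55 - 0.5 * disc)
}

#' @rdname eigenvalues_continuous
#' @export
eigenvalues_discrete <- eigenvalues_continuous

#' Viscosity threshold for monotonic relaxation (continuous problem)
#'
#' The mechanical eigenvalue pair is real-valued (monotonic relaxation of
#' velocity/strain perturbations) if and only if
#' \deqn{\mu \ge \frac{\sqrt{\rho_t E \sqrt{\bar\rho}(1-\bar\varepsilon)}}{\pi},}
#' evaluated at the most restrictive mode k = 1 on a unit domain. Below the
#' threshold the pair is complex and relaxation is oscillatory.
#'
#' @inheritParams linearized_system
#' @return Threshold viscosity in (N day)/cm2; `NA` with a warning when
#'   `eps_bar > 1` (saddle/degenerate case, threshold not applicable).
#' @export
mu_threshold_continuous <- function(params, eq) {
  if (eq$eps_bar > 1) {
    warning("eps_bar > 1: saddle/degenerate case, threshold not applicable")
    return(NA_real_)
  }
  sqrt(params$rho_t * params$E * sqrt(eq$rho_bar) * (1 - eq$eps_bar)) / pi
}

#' Viscosity threshold for monotonic relaxation (semi-discrete problem)
#'
#' Von Neumann counterpart of [mu_threshold_continuous()]:
#' \deqn{\mu \ge \frac{h}{\tan(\pi\beta h)}
#'   \sqrt{\rho_t E \sqrt{\bar\rho}(1-\bar\varepsilon)}.}
#' Since \eqn{h/\tan(\pi\beta h) \le 1/(\pi\beta)}, the discrete threshold
#' never exceeds the continuous one: the semi-discrete problem can relax
#' monotonically where the continuous one does not, and it converges to the
#' continuous threshold as \eqn{h \to 0} with an O(h^2) gap.
#'
#' @inheritParams linearized_system
#' @return Threshold viscosity in (N day)/cm2. Zero where `tan` diverges
#'   (beta*h an odd multiple of 1/2); an error where `beta*h` is an integer
#'   (degenerate aliased mode, threshold undefined).
#' @export
mu_threshold_discrete <- function(params, eq, h, beta) {
  if (eq$eps_bar > 1) {
    warning("eps_bar > 1: saddle/degenerate case, threshold not applicable")
    return(NA_real_)
  }
  bh <- beta * h
  guard <- 1e-12
  if (abs(bh - round(bh)) < guard)
    stop("beta * h is an integer: aliased mode, threshold undefined")
  if (abs(bh * 2 - round(bh * 2)) < guard) return(0)  # tan -> infinity
  h / tan(pi * bh) *
    sqrt(params$rho_t * params$E * sqrt(eq$rho_bar) * (1 - eq$eps_bar))
}

#' Upper bound on the fibroblast apoptosis rate
#'
#' Substituting the equilibrium relation for \eqn{\delta_N} into the
#' fibroblast stability requirement at the constant mode gives
#' \eqn{q \le \kappa_F\bar N/(1-\kappa_F\bar N) =: q_{max}}, hence the bound
#' \eqn{\delta_N < r_F(1-\kappa_F\bar N)\bar N^{q_{max}}} on apoptosis rates
#' compatible with a stable equilibrium.
#'
#' @inheritParams linearized_system
#' @return List with `q_max` and the rate bound `delta_N_max` (1/day).
#' @export
delta_N_upper_bound <- function(params, eq = equilibrium_state(params)) {
  kN <- params$kappa_F * eq$N_bar
  if (kN >= 1) stop("invalid equilibrium: kappa_F * N_bar >= 1")
  q_max <- kN / (1 - kN)
  list(q_max = q_max,
       delta_N_max = params$r_F * (1 - kN) * eq$N_bar^q_max)
}

stability_conditions <- function(params, eq, tol = 1e-12) {
  p <- params
  lhs_sig <- p$delta_c * eq$rho_bar
  rhs_sig <- p$k_c / p$a_c_I
  lhs_fib <- p$q * p$delta_N
  rhs_fib <- p$kappa_F * p$r_F * eq$N_bar^(1 + p$q)
  list(
    cond_signaling  = lhs_sig >= rhs_sig - tol,
    cond_fibroblast = lhs_fib <= rhs_fib + tol,
    cond_strain     = eq$eps_bar <= 1 + tol,
    marginal = (abs(lhs_sig - rhs_sig) <= tol) ||
      (abs(lhs_fib - rhs_fib) <= tol) || (abs(eq$eps_bar - 1) <= tol),
    signaling_lhs = lhs_sig, signaling_rhs = rhs_sig,
    fibroblast_lhs = lhs_fib, fibroblast_rhs = rhs_fib,
    delta_c_threshold = p$k_c / (p$a_c_I * eq$rho_bar)
  )
}

#' Linear stability report (continuous problem)
#'
#' Evaluates the three closed-form stability criteria of the homogeneous
#' equilibrium — sufficient signaling-molecule decay
#' (\eqn{\delta_c\bar\rho \ge k_c/a_c^I}), the fibroblast crowding condition
#' (\eqn{q\delta_N \le \kappa_F r_F \bar N^{1+q}}) and small equilibrium
#' strain (\eqn{\bar\varepsilon \le 1}) — together with the per-mode
#' eigenvalues over a range of Fourier modes and the monotonicity
#' (real-eigenvalue) viscosity threshold. The equilibrium is linearly stable
#' iff all three criteria hold; equality within `tol` is reported as stable
#' with `marginal = TRUE`.
#'
#' @inheritParams linearized_system
#' @param k_range integer modes to tabulate (default 0:10).
#' @param tol tolerance for boundary cases (default 1e-12).
#' @return An object of class `stability_report`.
#' @export
check_stability_continuous <- function(params, eq = equilibrium_state(params),
                                       k_range = 0:10, omega_len = 1,
                                       tol = 1e-12) {
  conds <- stability_conditions(params, eq, tol)
  eigs <- t(vapply(k_range, function(k)
    eigenvalues_continuous(assemble_continuous(params, eq, k, omega_len)),
    complex(6)))
  rownames(eigs) <- paste0("k=", k_range)
  colnames(eigs) <- c("c", "M", "N", "rho", "mech+", "mech-")
  thr <- mu_threshold_continuous(params, eq)
  structure(list(
    kind = "continuous", modes = k_range,
    cond_signaling = conds$cond_signaling,
    cond_fibroblast = conds$cond_fibroblast,
    cond_strain = conds$cond_strain,
    stable = conds$cond_signaling && conds$cond_fibroblast &&
      conds$cond_strain,
    marginal = conds$marginal,
    monotonic = is.finite(thr) && params$mu >= thr,
    mu_threshold = thr,
    delta_c_threshold = conds$delta_c_threshold,
    fibroblast_lhs = conds$fibroblast_lhs,
    fibroblast_rhs = conds$fibroblast_rhs,
    eigenvalues = eigs,
    min_re = min(Re(eigs))
  ), class = "stability_report")
}

#' Linear stability report (semi-discrete problem)
#'
#' Von Neumann analysis of the central finite-difference semi-discretization
#' on a uniform grid: same criteria and report as
#' [check_stability_continuous()], with per-mode eigenvalues over discrete
#' modes `beta = 1, ..., n-1`. Every added discrete term is non-negative, so
#' stability of the continuous problem implies stability of the
#' semi-discrete problem for every grid spacing; the verdict always matches
#' the continuous one.
#'
#' @inheritParams assemble_discrete
#' @param beta_range discrete modes to tabulate (default all, `1:(n-1)`).
#' @inheritParams check_stability_continuous
#' @return An object of class `stability_report`.
#' @export
check_stability_discrete <- function(params, eq = equilibrium_state(params),
                                     h, n = round(1 / h),
                                     beta_range = seq_len(n - 1),
                                     tol = 1e-12) {
  conds <- stability_conditions(params, eq, tol)
  eigs <- t(vapply(beta_range, function(b)
    eigenvalues_discrete(assemble_discrete(params, eq, b, h, n)),
    complex(6)))
  rownames(eigs) <- paste0("beta=", beta_range)
  colnames(eigs) <- c("c", "M", "N", "rho", "mech+", "mech-")
  thr_d <- suppressWarnings(
    if (eq$eps_bar > 1) NA_real_
    else max(0, mu_threshold_discrete(params, eq, h, beta_range[1])))
  structure(list(
    kind = "discrete", modes = beta_range, h = h, n = n,
    cond_signaling = conds$cond_signaling,
    cond_fibroblast = conds$cond_fibroblast,
    cond_strain = conds$cond_strain,
    stable = conds$cond_signaling && conds$cond_fibroblast &&
      conds$cond_strain,
    marginal = conds$marginal,
    monotonic = is.finite(thr_d) && params$mu >= thr_d,
    mu_threshold = thr_d,
    delta_c_threshold = conds$delta_c_threshold,
    fibroblast_lhs = conds$fibroblast_lhs,
    fibroblast_rhs = conds$fibroblast_rhs,
    eigenvalues = eigs,
    min_re = min(Re(eigs))
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", x$kind, "problem\n")
  cat(sprintf("  signaling decay condition : %s (threshold delta_c >= %.4g)\n",
              x$cond_signaling, x$delta_c_threshold))
  cat(sprintf("  fibroblast condition      : %s (%.4g <= %.4g)\n",
              x$cond_fibroblast, x$fibroblast_lhs, x$fibroblast_rhs))
  cat(sprintf("  strain condition          : %s\n", x$cond_strain))
  cat(sprintf("  verdict: %s%s; min Re(lambda) over modes = %.4g\n",
              if (x$stable) "STABLE" else "UNSTABLE",
              if (x$marginal) " (marginal)" else "", x$min_re))
  cat(sprintf("  monotonic relaxation: %s (mu threshold %.6g)\n",
              x$monotonic, x$mu_threshold))
  invisible(x)
}

#' Discrete-to-continuous eigenvalue consistency order
#'
#' Measures the gap between the Von Neumann eigenvalues at mode `beta = k`
#' and the continuous Fourier eigenvalues at mode `k` over a ladder of grid
#' spacings, and fits the log-log slope per eigenvalue. The semi-discrete
#' analysis is second-order consistent, so slopes near 2 are expected for
#' every eigenvalue whose gap is nonzero.
#'
#' @inheritParams linearized_system
#' @param h_list decreasing positive grid spacings.
#' @return List with the per-eigenvalue `gaps` matrix (|discrete -
#'   continuous|, rows = h values), fitted `slopes` (NA where the gap
#'   vanishes identically), and the inputs.
#' @export
consistency_gap <- function(params, eq, k, h_list) {
  stopifnot(all(h_list > 0), !is.unsorted(rev(h_list)))
  lam_c <- eigenvalues_continuous(assemble_continuous(params, eq, k))
  gaps <- t(vapply(h_list, function(h) {
    lam_d <- eigenvalues_discrete(
      assemble_discrete(params, eq, beta = k, h = h))
    Mod(lam_d - lam_c)
  }, numeric(6)))
  colnames(gaps) <- c("c", "M", "N", "rho", "mech+", "mech-")
  rownames(gaps) <- paste0("h=", format(h_list))
  slopes <- apply(gaps, 2, function(g) {
    if (all(g < .Machine$double.eps * max(1, Mod(lam_c)) * 100))
      return(NA_real_)
    unname(stats::coef(stats::lm(log(g) ~ log(h_list)))[2])
  })
  list(k = k, h_list = h_list, gaps = gaps, slopes = slopes)
}
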