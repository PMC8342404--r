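#' Kinetic and mechanical parameters of the contraction model
#'
#' Constructs the full parameter set of the one-dimensional morphoelastic
#' skin-contraction model. Defaults are the published reference values for
#' human dermis. Two parameters are consequences of the others and are derived
#' unless supplied explicitly:
#' \itemize{
#'   \item `q`, the fibroblast growth exponent, from the fibroblast
#'     equilibrium relation \eqn{\delta_N = r_F (1-\kappa_F \bar N) \bar N^q}
#'     (see [derive_q()]);
#'   \item `k_rho`, the collagen secretion rate, from the collagen
#'     equilibrium \eqn{\bar\rho = \sqrt{k_\rho/\delta_\rho}} with
#'     \eqn{\bar\rho = 0.1125} g/cm3, giving `6e-6 * 0.1125^2 = 7.59375e-8`.
#' }
#' Deriving them keeps the homogeneous equilibrium an exact fixed point of the
#' kinetics, which the solver and the stability analysis rely on.
#'
#' Units (cm, g, cells, days, N): `D_c` cm2/day; `D_F` cm5/(cells day);
#' `chi_F` cm5/(g day); `k_c`, `k_rho` g/(cells day); `r_F` cm^{3q}/(cells^q
#' day); `r_F_max`, `k_rho_max`, `eta_I`, `eta_II`, `q` dimensionless;
#' `a_c_I`, `a_c_III`, `a_c_IV` g/cm3; `a_c_II` cm3/g; `k_F` cm3/(g day);
#' `kappa_F` cm3/cells; `delta_c`, `delta_rho`, `zeta` cm6/(cells g day);
#' `delta_N`, `delta_M` 1/day; `rho_t`, `R` g/cm3; `mu` (N day)/cm2; `E`
#' N/((g cm)^0.5); `xi` (N g)/(cells cm2); `N_bar` cells/cm3. Units are
#' documentation metadata only; no runtime unit algebra is performed.
#'
#' @param ... named overrides of any parameter listed above.
#' @return An object of class `wound_params`: a named list of parameters.
#' @examples
#' p <- wound_params()
#' p$q                     # derived growth exponent, about -0.4151
#' wound_params(delta_c = 2e-4)$delta_c
#' @export
wound_params <- function(...) {
  defaults <- list(
    D_c       = 2.88e-3,
    D_F       = 1e-7,
    chi_F     = 2e-3,
    k_c       = 4e-13,
    r_F       = 9.24e-1,
    r_F_max   = 2,
    k_rho     = 6e-6 * 0.1125^2,  # 7.59375e-8, prints as 7.6e-8
    k_rho_max = 10,
    a_c_I     = 1e-8,
    a_c_II    = 2e8,
    a_c_III   = 1e-8,
    a_c_IV    = 1e-9,
    eta_I     = 2,
    eta_II    = 5e-1,
    k_F       = 1.08e7,
    kappa_F   = 1e-6,
    q         = NA_real_,          # derived below unless supplied
    delta_c   = 5e-4,
    delta_N   = 2e-2,
    delta_M   = 6e-2,
    delta_rho = 6e-6,
    zeta      = 4e2,
    rho_t     = 1.09,
    mu        = 1e2,
    E         = 2.1e2,
    xi        = 4.4e-2,
    R         = 9.95e-1,
    N_bar     = 1e4
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  p <- defaults
  if (is.na(p$q))
    p$q <- derive_q(p$delta_N, p$r_F, p$kappa_F, p$N_bar)
  p <- lapply(p, as.numeric)
  class(p) <- "wound_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  positive <- c("D_c", "D_F", "chi_F", "k_c", "r_F", "k_rho", "a_c_I",
                "a_c_II", "a_c_III", "a_c_IV", "eta_I", "k_F", "kappa_F",
                "delta_c", "delta_N", "delta_M", "delta_rho", "zeta",
                "rho_t", "mu", "E", "xi", "R", "N_bar")
  nonneg <- c("eta_II", "r_F_max", "k_rho_max")
  for (nm in positive)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive")
  for (nm in nonneg)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative")
  if (!is.finite(p$q)) stop("parameter 'q' must be finite")
  if (p$kappa_F * p$N_bar >= 1)
    stop("invalid equilibrium: kappa_F * N_bar must be < 1 ",
         "(crowding would force a non-positive apoptosis rate)")
  invisible(p)
}

#' @export
print.wound_params <- function(x, ...) {
  cat("<wound_params> 1D morphoelastic skin-contraction parameters\n")
  nm <- names(x)
  val <- vapply(unclass(x), function(v) format(v, digits = 6), "")
  cat(paste0("  ", format(nm, width = 10), " = ", val), sep = "\n")
  invisible(x)
}

#' Equilibrium state of the contraction model
#'
#' The analysed spatially homogeneous equilibrium
#' \eqn{(c, N, M, \rho, v, \varepsilon) = (0, \bar N, 0, \bar\rho, 0,
#' \bar\varepsilon)}, with \eqn{\bar\rho = \sqrt{k_\rho/\delta_\rho}}.
#'
#' @param params a [wound_params()] object.
#' @param eps_bar equilibrium effective strain (dimensionless, default 0).
#'   Values above 1 violate the small-strain stability requirement and are
#'   flagged with a warning.
#' @return An object of class `equilibrium_state` with fields `c_bar`,
#'   `N_bar`, `M_bar`, `rho_bar`, `v_bar`, `eps_bar` and the derived
#'   apoptosis-consistent `delta_N`.
#' @export
equilibrium_state <- function(params, eps_bar = 0) {
  stopifnot(inherits(params, "wound_params"))
  if (eps_bar > 1)
    warning("eps_bar > 1: equilibrium violates the small-strain requirement")
  eq <- list(
    c_bar   = 0,
    N_bar   = params$N_bar,
    M_bar   = 0,
    rho_bar = collagen_equilibrium(params$k_rho, params$delta_rho),
    v_bar   = 0,
    eps_bar = eps_bar,
    delta_N = derive_delta_N(params$r_F, params$kappa_F, params$N_bar,
                             params$q)
  )
  class(eq) <- "equilibrium_state"
  eq
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("<equilibrium_state>\n")
  cat(sprintf("  c = %g g/cm3, N = %g cells/cm3, M = %g cells/cm3\n",
              x$c_bar, x$N_bar, x$M_bar))
  cat(sprintf("  rho = %g g/cm3, v = %g cm/day, eps = %g\n",
              x$rho_bar, x$v_bar, x$eps_bar))
  invisible(x)
}

#' Fibroblast apoptosis rate consistent with equilibrium
#'
#' Solves the fibroblast reaction term at the healthy equilibrium for the
#' apoptosis rate: \eqn{\delta_N = r_F (1 - \kappa_F \bar N)\, \bar N^{q}}.
#'
#' @param r_F cell division rate, cm^{3q}/(cells^q day).
#' @param kappa_F crowding coefficient, cm3/cells; `kappa_F * N_bar` must be
#'   below 1, otherwise the implied apoptosis rate would be non-positive and
#'   the equilibrium invalid.
#' @param N_bar equilibrium fibroblast density, cells/cm3.
#' @param q dimensionless growth exponent (may be negative).
#' @return Apoptosis rate in 1/day (strictly positive).
#' @seealso [derive_q()] for the inverse relation.
#' @export
derive_delta_N <- function(r_F, kappa_F, N_bar, q) {
  if (N_bar <= 0) stop("N_bar must be strictly positive")
  if (kappa_F * N_bar >= 1)
    stop("invalid equilibrium: kappa_F * N_bar >= 1 implies delta_N <= 0")
  r_F * (1 - kappa_F * N_bar) * N_bar^q
}

#' Growth exponent consistent with a given apoptosis rate
#'
#' Inverts the equilibrium relation of [derive_delta_N()]:
#' \deqn{q = \frac{\log(\delta_N) - \log(r_F (1 - \kappa_F \bar N))}
#'   {\log(\bar N)}.}
#' Natural logarithms are used; any consistent base gives the same ratio.
#'
#' @param delta_N fibroblast apoptosis rate, 1/day.
#' @inheritParams derive_delta_N
#' @return Dimensionless exponent `q` such that
#'   `derive_delta_N(r_F, kappa_F, N_bar, q) == delta_N`.
#' @export
derive_q <- function(delta_N, r_F, kappa_F, N_bar) {
  if (delta_N <= 0 || r_F <= 0 || N_bar <= 0)
    stop("delta_N, r_F and N_bar must be strictly positive")
  if (kappa_F * N_bar >= 1)
    stop("invalid equilibrium: kappa_F * N_bar >= 1")
  if (N_bar == 1) stop("N_bar = 1: exponent undetermined (log(N_bar) = 0)")
  (log(delta_N) - log(r_F * (1 - kappa_F * N_bar))) / log(N_bar)
}

#' Equilibrium collagen density
#'
#' Balances collagen secretion against proteolytic breakdown at the healthy
#' state: \eqn{\bar\rho = \sqrt{k_\rho / \delta_\rho}}.
#'
#' @param k_rho collagen secretion rate, g/(cells day).
#' @param delta_rho collagen degradation rate, cm6/(cells g day).
#' @return Equilibrium collagen density in g/cm3.
#' @export
collagen_equilibrium <- function(k_rho, delta_rho) {
  if (k_rho <= 0 || delta_rho <= 0)
    stop("k_rho and delta_rho must be strictly positive")
  sqrt(k_rho / delta_rho)
}

#' Apoptosis rate from cell lifespan data
#'
#' Converts a fibroblast lifespan expressed as population doublings at a
#' given doubling time into a first-order apoptosis rate:
#' \eqn{\delta_N = \ln 2 / (\mathrm{PD} \cdot \mathrm{DT} / 24)}.
#'
#' @param PD lifespan in population doublings (> 0).
#' @param DT doubling time in hours (> 0).
#' @return Apoptosis rate in 1/day.
#' @examples
#' apoptosis_rate_from_lifespan(70, 20)  # lower end of the plausible range
#' apoptosis_rate_from_lifespan(40, 18)  # upper end
#' @export
apoptosis_rate_from_lifespan <- function(PD, DT) {
  if (PD <= 0 || DT <= 0) stop("PD and DT must be strictly positive")
  log(2) / (PD * DT / 24)
}
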