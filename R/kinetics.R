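#' Reaction kinetics of the four constituents
#'
#' Evaluates the (nonlinear) reaction terms of the signaling-molecule,
#' fibroblast, myofibroblast and collagen balance equations at given local
#' values. Vectorised over nodal values; used both by the finite-element
#' solver and as the nonlinear right-hand side that the linear stability
#' matrices are verified against.
#'
#' The terms are, per constituent:
#' \itemize{
#'   \item `c`: saturating net secretion by (myo)fibroblasts minus
#'     MMP-mediated proteolytic breakdown (inhibited by `c` itself);
#'   \item `N`: logistic proliferation with exponent `1 + q` and
#'     signaling-enhanced division, minus differentiation to myofibroblasts
#'     and apoptosis;
#'   \item `M`: signaling-dependent logistic proliferation, plus
#'     differentiation influx, minus apoptosis;
#'   \item `rho`: signaling-enhanced secretion minus MMP-mediated breakdown.
#' }
#'
#' @param c,N,M,rho numeric vectors of local densities (g/cm3, cells/cm3,
#'   cells/cm3, g/cm3).
#' @param params a [wound_params()] object.
#' @return A list with components `c`, `N`, `M`, `rho`: reaction rates in
#'   units of the respective density per day.
#' @export
reaction_rates <- function(c, N, M, rho, params) {
  p <- params
  inhib <- 1 + p$a_c_II * c           # MMP secretion inhibition factor
  crowd <- 1 - p$kappa_F * (N + M)    # crowding factor
  list(
    c = p$k_c * c / (p$a_c_I + c) * (N + p$eta_I * M) -
      p$delta_c * (N + p$eta_II * M) * rho * c / inhib,
    N = p$r_F * (1 + p$r_F_max * c / (p$a_c_III + c)) * crowd *
      pow_pos(N, 1 + p$q) - p$k_F * c * N - p$delta_N * N,
    M = p$r_F * ((1 + p$r_F_max) * c / (p$a_c_III + c)) * crowd *
      pow_pos(M, 1 + p$q) + p$k_F * c * N - p$delta_M * M,
    rho = p$k_rho * (1 + p$k_rho_max * c / (p$a_c_IV + c)) *
      (N + p$eta_I * M) -
      p$delta_rho * (N + p$eta_II * M) * rho^2 / inhib
  )
}

# z^a for z >= 0 with z < 0 mapped to 0; keeps the fractional-power growth
# terms defined if a density undershoots zero transiently.
pow_pos <- function(z, a) ifelse(z > 0, z, 0)^a

#' Morphoelastic strain decay rate
#'
#' Local rate \eqn{\alpha = \zeta (N + \eta^{II} M) c / (1 + a_c^{II} c)}
#' at which effective strain is actively released (permanent contraction),
#' driven by (myo)fibroblasts and signaling molecules.
#'
#' @inheritParams reaction_rates
#' @return Vector of rates in 1/day.
#' @export
strain_decay_rate <- function(c, N, M, params) {
  params$zeta * (N + params$eta_II * M) * c / (1 + params$a_c_II * c)
}
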