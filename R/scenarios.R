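#' Uniform mesh
#'
#' @param n number of elements.
#' @param domain length-2 numeric, domain endpoints in cm.
#' @return Node coordinates (length `n + 1`).
#' @export
make_uniform_mesh <- function(n, domain = c(0, 1)) {
  stopifnot(n >= 2, domain[2] > domain[1])
  seq(domain[1], domain[2], length.out = n + 1)
}

#' Wound scenario (convergence-study initial condition)
#'
#' A burn wound of `wound_length` cm centred in a `domain_length` cm stretch
#' of skin. Inside the wound, fibroblasts, signaling molecules and collagen
#' sit at the wound plateau values; outside the wound-plus-ramp region they
#' sit at the healthy equilibria; over each `ramp_length` cm transition the
#' profile follows a half-period sine ramp (so the ramp midpoint is the
#' arithmetic mean of plateau and equilibrium). Myofibroblasts, velocity and
#' effective strain start at zero everywhere.
#'
#' @param domain_length,wound_length,ramp_length geometry in cm; the wound
#'   plus both ramps must fit in the domain.
#' @param c_w,N_w,rho_w wound plateau values of signaling molecules (g/cm3),
#'   fibroblasts (cells/cm3) and collagen (g/cm3).
#' @return An object of class `wound_scenario`.
#' @export
wound_scenario <- function(domain_length = 10, wound_length = 4,
                           ramp_length = 1, c_w = 1e-8, N_w = 2000,
                           rho_w = 0.01125) {
  if (wound_length + 2 * ramp_length > domain_length)
    stop("wound plus ramps exceed the domain")
  stopifnot(wound_length > 0, ramp_length > 0)
  structure(list(domain_length = domain_length,
                 wound_length = wound_length, ramp_length = ramp_length,
                 c_w = c_w, N_w = N_w, rho_w = rho_w),
            class = "wound_scenario")
}

# smooth 0 -> 1 half-period sine ramp on s in [0, 1]
sine_ramp <- function(s) (1 + sin(pi * (s - 0.5))) / 2

#' Evaluate the wound profile on a mesh
#'
#' @param scn a [wound_scenario()].
#' @param x node coordinates spanning the scenario domain.
#' @param eq an [equilibrium_state()] providing the far-field values.
#' @return Named list of nodal fields (`c`, `N`, `M`, `rho`, `v`, `eps`).
#' @export
make_wound_profile <- function(scn, x, eq) {
  stopifnot(inherits(scn, "wound_scenario"))
  if (min(x) > 0 || max(x) < scn$domain_length)
    stop("mesh does not span the scenario domain")
  centre <- scn$domain_length / 2
  d <- abs(x - centre)
  hw <- scn$wound_length / 2
  w <- numeric(length(x))          # blending weight: 1 in wound, 0 outside
  w[d <= hw] <- 1
  ramp <- d > hw & d <= hw + scn$ramp_length
  w[ramp] <- 1 - sine_ramp((d[ramp] - hw) / scn$ramp_length)
  list(c   = w * scn$c_w + (1 - w) * eq$c_bar,
       N   = w * scn$N_w + (1 - w) * eq$N_bar,
       M   = numeric(length(x)),
       rho = w * scn$rho_w + (1 - w) * eq$rho_bar,
       v   = numeric(length(x)),
       eps = numeric(length(x)))
}

#' Build a ready-to-run wound simulation state
#'
#' Convenience wrapper: uniform mesh over the scenario domain, wound initial
#' profile, full-domain Dirichlet boundaries and wound-edge marker nodes for
#' the relative-surface-area readout.
#'
#' @inheritParams make_wound_profile
#' @param n number of elements.
#' @param params a [wound_params()] object.
#' @return A [sim_state()].
#' @export
wound_state <- function(scn, n, params, eq = equilibrium_state(params)) {
  x <- make_uniform_mesh(n, c(0, scn$domain_length))
  centre <- scn$domain_length / 2
  hw <- scn$wound_length / 2
  markers <- c(which.min(abs(x - (centre - hw))),
               which.min(abs(x - (centre + hw))))
  sim_state(x, make_wound_profile(scn, x, eq), params,
            boundary = "full", markers = markers)
}

#' Perturbed-equilibrium scenario (stability validation)
#'
#' Initial conditions for the half-domain [0, 1] stability experiments:
#' fibroblasts, collagen, velocity and effective strain are perturbed about
#' their equilibria by sine waves with `k` full periods, `sin(2 k \pi x)`
#' (vanishing at both endpoints, so Dirichlet boundary values stay at
#' equilibrium, and zero-mean, matching the Fourier mode index `k` of the
#' linear stability analysis on the unit domain), while the
#' strictly non-negative myofibroblast and signaling-molecule bumps are
#' natural cubic splines through `2k + 1` equally spaced knots, zero at the
#' boundary knots and alternating between two levels (starting with the
#' lower) at the interior knots.
#'
#' @param k number of waves (1, 5 and 10 in the validation experiments).
#' @param amp_N,amp_rho sine amplitudes for fibroblasts (cells/cm3) and
#'   collagen (g/cm3).
#' @param M_levels,c_levels the two alternating interior knot levels for the
#'   myofibroblast (cells/cm3) and signaling-molecule (g/cm3) splines.
#' @param amp_v,amp_eps sine amplitudes of displacement velocity (cm/day)
#'   and effective strain (dimensionless; kept at or below 0.5 so that the
#'   strain stays within the small-strain regime).
#' @return An object of class `perturbation_scenario`.
#' @export
perturbation_scenario <- function(k = 1, amp_N = 10, amp_rho = 1e-2,
                                  M_levels = c(3, 6),
                                  c_levels = c(0.5e-15, 2e-15),
                                  amp_v = 0.05, amp_eps = 0.5) {
  stopifnot(k >= 1, k == round(k), length(M_levels) == 2,
            length(c_levels) == 2, all(M_levels >= 0), all(c_levels >= 0))
  structure(list(k = k, amp_N = amp_N, amp_rho = amp_rho,
                 M_levels = sort(M_levels), c_levels = sort(c_levels),
                 amp_v = amp_v, amp_eps = amp_eps, domain = c(0, 1)),
            class = "perturbation_scenario")
}

spline_bump <- function(k, levels, x) {
  knots_x <- seq(0, 1, length.out = 2 * k + 1)
  top <- max(levels)
  interior <- rep(levels / top, length.out = 2 * k - 1) # low, high, ...
  knots_y <- c(0, interior, 0)
  # interpolate at unit scale (levels can be ~1e-15) and rescale
  f <- stats::splinefun(knots_x, knots_y, method = "natural")
  y <- f(x)
  # a natural cubic through alternating knots can undershoot slightly below
  # zero next to the boundary knots; truncate that (the densities must stay
  # non-negative), but treat larger excursions as a generation error
  if (min(y) < -0.01)
    stop("generated spline bump is negative beyond the boundary-undershoot ",
         "tolerance")
  pmax(y, 0) * top
}

#' Evaluate the perturbation profile on a mesh
#'
#' @param scn a [perturbation_scenario()].
#' @param x node coordinates in [0, 1].
#' @param eq an [equilibrium_state()].
#' @return Named list of nodal fields. The myofibroblast and
#'   signaling-molecule bumps are guaranteed non-negative: the natural cubic
#'   interpolant's small boundary undershoot (below 1% of the upper knot
#'   level) is truncated at zero, and anything larger raises a generation
#'   error.
#' @export
make_perturbation_profile <- function(scn, x, eq) {
  stopifnot(inherits(scn, "perturbation_scenario"))
  s <- sin(2 * scn$k * pi * x)
  M <- spline_bump(scn$k, scn$M_levels, x)
  cc <- spline_bump(scn$k, scn$c_levels, x)
  list(c   = cc,
       N   = eq$N_bar + scn$amp_N * s,
       M   = M,
       rho = eq$rho_bar + scn$amp_rho * s,
       v   = scn$amp_v * s,
       eps = eq$eps_bar + scn$amp_eps * s)
}

#' Build a ready-to-run perturbed-equilibrium simulation state
#'
#' Uniform mesh on the half domain [0, 1] with symmetric (half-domain)
#' boundary handling; the right endpoint represents the centre of the
#' modelled skin.
#'
#' @inheritParams make_perturbation_profile
#' @param n number of elements (500 in the validation experiments).
#' @param params a [wound_params()] object.
#' @return A [sim_state()].
#' @export
perturbation_state <- function(scn, n, params,
                               eq = equilibrium_state(params)) {
  x <- make_uniform_mesh(n, scn$domain)
  sim_state(x, make_perturbation_profile(scn, x, eq), params,
            boundary = "half", markers = c(1L, n + 1L))
}
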