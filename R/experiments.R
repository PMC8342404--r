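#' Coarse-grid l1 error between two solutions
#'
#' Sum of absolute differences of two solutions evaluated at the same shared
#' comparison points (a variant of the L1 norm evaluated on the coarsest
#' grid's points).
#'
#' @param z_h,z_ref numeric vectors: the two solutions evaluated at the same
#'   comparison points.
#' @return Non-negative error.
#' @export
error_norm_41 <- function(z_h, z_ref) {
  if (length(z_h) != length(z_ref))
    stop("solutions evaluated at different numbers of comparison points")
  sum(abs(z_ref - z_h))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' Four error norms between a coarse and a reference solution
#'
#' Computes the four errors used by the convergence study:
#' \itemize{
#'   \item `e41`: [error_norm_41()] at the comparison points
#'     `coarse_points` (the coarsest grid's node positions);
#'   \item `eL1`, `eL2`: composite-trapezoid approximations of
#'     \eqn{\int |z - z_h| dx} and \eqn{(\int (z - z_h)^2 dx)^{1/2}} on the
#'     reference mesh after linear interpolation of the coarse solution;
#'   \item `eb`: absolute difference at the wound-boundary position
#'     `boundary_x`.
#' }
#' Solutions live on (possibly different, possibly moved) meshes and are
#' compared in physical space by linear interpolation.
#'
#' @param z_h,z_ref nodal solutions on `mesh_h` and `mesh_ref`.
#' @param mesh_h,mesh_ref node coordinates.
#' @param coarse_points comparison points for `e41`.
#' @param boundary_x wound-edge position for `eb`.
#' @return Named numeric vector `c(e41, eL1, eL2, eb)`.
#' @export
error_norms <- function(z_h, z_ref, mesh_h, mesh_ref, coarse_points,
                        boundary_x) {
  fh <- stats::approx(mesh_h, z_h, xout = mesh_ref, rule = 2)$y
  d <- abs(z_ref - fh)
  c(e41 = error_norm_41(
      stats::approx(mesh_h, z_h, xout = coarse_points, rule = 2)$y,
      stats::approx(mesh_ref, z_ref, xout = coarse_points, rule = 2)$y),
    eL1 = trapz(mesh_ref, d),
    eL2 = sqrt(trapz(mesh_ref, d^2)),
    eb = abs(stats::approx(mesh_h, z_h, xout = boundary_x, rule = 2)$y -
               stats::approx(mesh_ref, z_ref, xout = boundary_x, rule = 2)$y))
}

fit_slope <- function(h, err) {
  ok <- err > 0 & is.finite(err)
  if (sum(ok) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(log(err[ok]) ~ log(h[ok])))[2])
}

#' Grid-convergence study of the wound simulation
#'
#' Runs the wound-contraction scenario for one simulated day on a ladder of
#' uniform resolutions with \eqn{\Delta t = h^2}, compares each run against
#' the finest (reference) run in the four norms of [error_norms()] for all
#' six fields plus the relative wound surface area, and fits least-squares
#' log-log slopes of error versus element size. Slopes near 2 confirm the
#' expected second-order spatial convergence.
#'
#' Resolutions are node counts of nested uniform grids (41 nodes = 40
#' elements, and each refinement doubles the element count), so the 41
#' coarse-grid nodes are initially shared by every run of the ladder and the
#' reference (`n_ref = 1281` nodes corresponds to h = 0.0078 cm). The
#' default ladder (41, 81, 161, 321 nodes against a 641-node reference) is
#' the package's desk-scale study; pass
#' `resolutions = c(41, 81, 161, 321, 641), n_ref = 1281` for the full
#' ladder.
#'
#' @param params a [wound_params()] object.
#' @param scn a [wound_scenario()].
#' @param resolutions node counts of the ladder runs.
#' @param n_ref node count of the reference run (finer than the ladder).
#' @param t_end simulated time in days (default 1).
#' @param picard_tol,picard_max Picard settings for all runs.
#' @return An object of class `convergence_table`: list with the `errors`
#'   array (resolution x variable x norm), `rsaw_errors`, fitted `slopes`
#'   (variable x norm, plus the RSAW slope), and run metadata.
#' @export
convergence_study <- function(params = wound_params(),
                              scn = wound_scenario(),
                              resolutions = c(41, 81, 161, 321),
                              n_ref = 641, t_end = 1,
                              picard_tol = 1e-8, picard_max = 25) {
  stopifnot(all(resolutions < n_ref))
  eq <- equilibrium_state(params)
  L <- scn$domain_length
  coarse_points <- seq(0, L, length.out = min(resolutions))
  boundary_x <- L / 2 - scn$wound_length / 2
  run_one <- function(nodes) {
    n <- nodes - 1L                    # elements
    h <- L / n
    st <- wound_state(scn, n, params, eq)
    cfg <- solver_config(dt_schedule = data.frame(start = 0, dt = h^2),
                         picard_tol = picard_tol, picard_max = picard_max)
    tr <- simulate_contraction(st, t_end, cfg, record_every = 1e9, eq = eq)
    if (tr$termination != "blowup") return(tr)
    stop("convergence run with ", nodes, " nodes blew up: ", tr$reason)
  }
  ref <- run_one(n_ref)
  vars <- c("c", "N", "M", "rho", "v", "eps")
  norms <- c("e41", "eL1", "eL2", "eb")
  errors <- array(NA_real_,
                  dim = c(length(resolutions), length(vars), length(norms)),
                  dimnames = list(paste0("n=", resolutions), vars, norms))
  rsaw_errors <- numeric(length(resolutions))
  rsaw_ref <- relative_surface_area(ref$state)
  for (i in seq_along(resolutions)) {
    tr <- run_one(resolutions[i])
    for (v in vars)
      errors[i, v, ] <- error_norms(tr$state$fields[[v]],
                                    ref$state$fields[[v]],
                                    tr$state$x, ref$state$x,
                                    coarse_points, boundary_x)
    rsaw_errors[i] <- abs(relative_surface_area(tr$state) - rsaw_ref)
  }
  h <- L / (resolutions - 1)
  slopes <- sapply(norms, function(nrm)
    sapply(vars, function(v) fit_slope(h, errors[, v, nrm])))
  structure(list(resolutions = resolutions, n_ref = n_ref, h = h,
                 errors = errors, rsaw_errors = rsaw_errors,
                 slopes = cbind(slopes,
                                Averaged = rowMeans(slopes, na.rm = TRUE)),
                 rsaw_slope = fit_slope(h, rsaw_errors),
                 rsaw_ref = rsaw_ref, t_end = t_end),
            class = "convergence_table")
}

#' @export
print.convergence_table <- function(x, ...) {
  cat(sprintf("<convergence_table> ladder n = %s, reference n = %d, %g day(s)\n",
              paste(x$resolutions, collapse = ", "), x$n_ref, x$t_end))
  cat("fitted log-log slopes (order of convergence):\n")
  print(round(x$slopes, 4))
  cat(sprintf("relative-wound-surface-area error slope: %.4f\n",
              x$rsaw_slope))
  invisible(x)
}

#' Convergence table as a data frame
#'
#' @param x a `convergence_table`.
#' @param ... unused.
#' @return Data frame of fitted slopes, one row per variable (plus the
#'   relative wound surface area), one column per error norm.
#' @export
as.data.frame.convergence_table <- function(x, ...) {
  df <- as.data.frame(x$slopes)
  df <- rbind(df, RSAW = c(x$rsaw_slope, NA, NA, NA, x$rsaw_slope))
  df
}

#' One stability-validation simulation
#'
#' Runs the perturbed-equilibrium half-domain scenario for given
#' signaling-molecule decay rate `delta_c`, viscosity `mu` and wave count
#' `k`, and classifies the outcome as `"converged-to-equilibrium"`,
#' `"converged-to-new-equilibrium"` or `"blow-up"`. Classification compares
#' the constituents and the velocity against the healthy equilibria
#' (relative tolerance `tol_eq`); effective strain is only required to be
#' stationary, since any strain profile is an equilibrium once the tissue is
#' at rest and signaling has ceased. The a-priori criterion verdict from
#' [check_stability_continuous()] is reported alongside the empirical
#' outcome: a run slightly below the signaling-decay bound may still settle
#' onto a shifted equilibrium.
#'
#' @param delta_c signaling-molecule decay rate, cm6/(cells g day).
#' @param mu viscosity, (N day)/cm2.
#' @param k perturbation wave count.
#' @param t_end simulated days.
#' @param n elements on the half domain (default 500).
#' @param dt_schedule time-step schedule; default 0.5-day steps, or the
#'   finer 0.01/1/2-day staged schedule when `mu < 10` (the oscillatory
#'   regime needs small early steps to resolve the velocity transient).
#' @param tol_eq relative tolerance for "at equilibrium" (default 1%).
#' @param record_every record cadence in steps.
#' @param ... further overrides passed to [wound_params()].
#' @return An object of class `validation_run`: outcome classification,
#'   criterion verdict, end-state centre values (right boundary, the centre
#'   of the modelled skin), velocity-norm monotonicity diagnostics, the
#'   recorded series and the final state.
#' @export
stability_validation_run <- function(delta_c, mu, k, t_end, n = 500,
                                     dt_schedule = NULL, tol_eq = 0.01,
                                     record_every = 2L, ...) {
  params <- wound_params(delta_c = delta_c, mu = mu, ...)
  eq <- equilibrium_state(params)
  if (is.null(dt_schedule))
    dt_schedule <- if (mu < 10)
      data.frame(start = c(0, 2, 50), dt = c(0.01, 1, 2))
    else data.frame(start = 0, dt = 0.5)
  verdict <- check_stability_continuous(params, eq, k_range = 0:max(10, k))
  st <- perturbation_state(perturbation_scenario(k = k), n, params, eq)
  tr <- simulate_contraction(st, t_end,
                             solver_config(dt_schedule = dt_schedule),
                             record_every = record_every, eq = eq)
  s <- tr$series
  last <- s[nrow(s), ]
  scale_ref <- c(c = params$a_c_I, N = eq$N_bar, M = eq$N_bar,
                 rho = eq$rho_bar, v = 1)
  rel_dev <- c(c = last$dev_c, N = last$dev_N, M = last$dev_M,
               rho = last$dev_rho, v = last$dev_v) / scale_ref
  # velocity-norm monotonicity: count sign changes of the increments of
  # max|v| over the recorded series (before it reaches the noise floor)
  vm <- s$v_maxabs[s$v_maxabs > 1e-12]
  dv <- diff(vm)
  dv <- dv[abs(dv) > 0]
  v_sign_changes <- if (length(dv) > 1) sum(diff(sign(dv)) != 0) else 0L
  # absolute rate of change of the strain envelope, 1/day (stationarity)
  eps_rate <- if (nrow(s) >= 2) {
    abs(last$eps_max - s$eps_max[nrow(s) - 1]) /
      max(last$t - s$t[nrow(s) - 1], 1e-12)
  } else NA_real_
  outcome <- if (tr$termination == "blowup") "blow-up"
  else if (max(rel_dev) < tol_eq) "converged-to-equilibrium"
  else "converged-to-new-equilibrium"
  structure(list(delta_c = delta_c, mu = mu, k = k, n = n, t_end = t_end,
                 outcome = outcome, blowup_reason = tr$reason,
                 t_stop = tr$state$t,
                 criterion_stable = verdict$stable,
                 criterion = verdict,
                 centre = c(c = last$c_end, N = last$N_end, M = last$M_end,
                            rho = last$rho_end),
                 rel_dev = rel_dev, eps_final = last$eps_max,
                 eps_rate = eps_rate,
                 v_sign_changes = v_sign_changes,
                 series = s, state = tr$state, params = params),
            class = "validation_run")
}

#' @export
print.validation_run <- function(x, ...) {
  cat(sprintf("<validation_run> delta_c = %g, mu = %g, k = %d, n = %d\n",
              x$delta_c, x$mu, x$k, x$n))
  cat(sprintf("  criterion verdict: %s | empirical outcome: %s (t = %.1f d)\n",
              if (x$criterion_stable) "stable" else "unstable",
              x$outcome, x$t_stop))
  if (x$outcome != "blow-up")
    cat(sprintf("  centre values: c = %.4g g/cm3, N = %.1f, M = %.2f cells/cm3, rho = %.5g g/cm3\n",
                x$centre[["c"]], x$centre[["N"]], x$centre[["M"]],
                x$centre[["rho"]]))
  else
    cat(sprintf("  blow-up: %s\n", x$blowup_reason))
  invisible(x)
}

#' Reversion of the hypertrophic state
#'
#' Continues a simulation after resetting the signaling molecules to their
#' healthy equilibrium (zero) everywhere — the numerical analogue of lifting
#' the growth-factor over-stimulation of a hypertrophic scar — and records
#' when the myofibroblasts, collagen and fibroblasts re-reach their healthy
#' equilibria (relative tolerance `tol`). The expected ordering is
#' myofibroblasts first, then collagen, then fibroblasts.
#'
#' @param state a [sim_state()], typically the final state of the
#'   shifted-equilibrium validation run.
#' @param t_extra additional days to simulate after the reset.
#' @param decay_factor a field counts as recovered once its deviation from
#'   the healthy equilibrium has fallen below this fraction of its own
#'   deviation at the moment of reset and stays there (default 1e-3). This
#'   is the plot-scale reading of "reaches equilibrium": each constituent is
#'   judged against its own departure, so the recovery order reflects the
#'   relaxation rates rather than the incidental sizes of the initial gaps.
#' @param dt step size in days.
#' @param record_every record cadence in steps.
#' @return List with recovery times (days after reset, NA when not reached)
#'   for `M`, `rho` and `N`, the recorded series, and the final state.
#' @export
reversion_experiment <- function(state, t_extra, decay_factor = 1e-3,
                                 dt = 0.5, record_every = 2L) {
  stopifnot(inherits(state, "sim_state"))
  eq <- equilibrium_state(state$params)
  state$fields$c <- numeric(length(state$x))
  t0 <- state$t
  tr <- simulate_contraction(state, t0 + t_extra,
                             solver_config(
                               dt_schedule = data.frame(start = 0, dt = dt)),
                             record_every = record_every, eq = eq)
  s <- tr$series
  first_below <- function(dev) {
    below <- dev < decay_factor * dev[1]
    # first record from which the field stays recovered to the end
    stays <- rev(cumprod(rev(below))) == 1
    if (!any(stays)) return(NA_real_)
    s$t[which(stays)[1]] - t0
  }
  list(recovery = c(M = first_below(s$dev_M),
                    rho = first_below(s$dev_rho),
                    N = first_below(s$dev_N)),
       series = s, state = tr$state, termination = tr$termination)
}
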