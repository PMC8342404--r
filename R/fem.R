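#' @title Moving-grid finite-element solver
#'
#' @description Discretizes the six-field contraction model with linear
#' basis functions on a moving mesh whose nodes are advected with the tissue
#' velocity (a Lagrangian arbitrary-Lagrangian-Eulerian limit: mesh velocity
#' equals material velocity, so passive convection is absorbed into the mesh
#' motion and the basis functions have vanishing material derivative).
#' Time integration is backward Euler; the nonlinear terms are handled by
#' monolithic inner Picard iterations in which every nonlinear coefficient
#' (logistic and Hill factors, velocity in the mesh motion, collagen in the
#' stress and body force, strain in the geometric term) is frozen at the
#' previous iterate so that all six fields enter linearly and are solved for
#' simultaneously. Mass matrices are lumped by default to preserve
#' monotonicity.
#'
#' @name fem_solver
NULL

#' Create a simulation state
#'
#' @param x strictly increasing node coordinates (cm).
#' @param fields list with numeric vectors `c`, `N`, `M`, `rho`, `v`, `eps`,
#'   one value per node.
#' @param t simulation time in days.
#' @param boundary `"full"` (Dirichlet c=0, N=N_bar, M=0, v=0 at both ends)
#'   or `"half"` (Dirichlet at the left/outer end; symmetry at the right end:
#'   v = 0 and natural zero flux for c, N, M).
#' @param params a [wound_params()] object (kept with the state for boundary
#'   values).
#' @param markers integer indices of two material marker nodes used for the
#'   relative wound surface area (optional).
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(x, fields, params, t = 0,
                      boundary = c("full", "half"), markers = NULL) {
  boundary <- match.arg(boundary)
  np <- length(x)
  stopifnot(np >= 3, all(diff(x) > 0))
  need <- c("c", "N", "M", "rho", "v", "eps")
  stopifnot(all(need %in% names(fields)),
            all(vapply(fields[need], length, 0L) == np))
  structure(list(x = x, x0 = x, u = numeric(np), t = t,
                 fields = fields[need], boundary = boundary,
                 params = params, markers = markers,
                 markers_dist0 = if (!is.null(markers))
                   diff(x[markers]) else NA_real_),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %g days, %d nodes on [%g, %g] (%s domain)\n",
              x$t, length(x$x), min(x$x), max(x$x), x$boundary))
  rng <- vapply(x$fields, range, numeric(2))
  cat("  field ranges:\n")
  for (nm in colnames(rng))
    cat(sprintf("    %-4s [%.6g, %.6g]\n", nm, rng[1, nm], rng[2, nm]))
  invisible(x)
}

#' Solver configuration
#'
#' @param dt_schedule data.frame with columns `start` (days) and `dt` (days):
#'   piecewise-constant time-step schedule. Default a single step size of
#'   0.5 days.
#' @param picard_tol relative l2 update tolerance of the inner Picard
#'   iterations (default 1e-8).
#' @param picard_max maximum inner iterations per time step (default 25).
#' @param lumping use lumped (diagonal) mass matrices (default TRUE).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt_schedule = data.frame(start = 0, dt = 0.5),
                          picard_tol = 1e-8, picard_max = 25,
                          lumping = TRUE) {
  stopifnot(is.data.frame(dt_schedule),
            all(c("start", "dt") %in% names(dt_schedule)),
            all(dt_schedule$dt > 0), picard_max >= 1, picard_tol > 0)
  dt_schedule <- dt_schedule[order(dt_schedule$start), , drop = FALSE]
  structure(list(dt_schedule = dt_schedule, picard_tol = picard_tol,
                 picard_max = picard_max, lumping = lumping),
            class = "solver_config")
}

schedule_dt <- function(schedule, t) {
  i <- findInterval(t + 1e-12, schedule$start)
  schedule$dt[max(1L, i)]
}

# Precomputed sparsity pattern and triplet->CSC map for a given problem
# size/boundary mode. Rebuilding only the numeric values each Picard
# iteration keeps assembly cost linear in the node count.
fem_pattern <- function(np, boundary, lumping,
                        scales = c(c = 1e-8, N = 1e4, M = 1e4, rho = 0.1,
                                   v = 1, eps = 1)) {
  n <- np - 1L
  off <- c(c = 0L, N = 1L, M = 2L, rho = 3L, v = 4L, eps = 5L) * np
  ndof <- 6L * np
  p <- seq_len(n); pp <- p + 1L
  # element-local pattern [ (p,p), (p,p+1), (p+1,p), (p+1,p+1) ]
  ei <- c(p, p, pp, pp)
  ej <- c(p, pp, p, pp)
  blocks_i <- integer(0); blocks_j <- integer(0)
  add <- function(bi, bj, ii, jj) {
    blocks_i <<- c(blocks_i, off[[bi]] + ii)
    blocks_j <<- c(blocks_j, off[[bj]] + jj)
  }
  dg <- seq_len(np)
  for (f in c("c", "N", "M", "rho", "v", "eps")) add(f, f, dg, dg) # diagonals
  add("c", "c", ei, ej)    # D_c stiffness
  add("N", "N", ei, ej)    # D_F (N+M) stiffness
  add("N", "c", ei, ej)    # chemotaxis of fibroblasts
  add("M", "M", ei, ej)    # D_F (N+M) stiffness
  add("M", "c", ei, ej)    # chemotaxis of myofibroblasts
  add("M", "N", dg, dg)    # differentiation source k_F c N
  add("v", "v", ei, ej)    # viscous stiffness
  add("v", "eps", ei, ej)  # elastic stress E sqrt(rho) eps
  add("eps", "v", ei, ej)  # geometric term (integral of dv/dx)
  if (!lumping) {          # consistent-mass off-diagonals
    for (f in c("c", "N", "M", "rho", "v", "eps")) {
      add(f, f, p, pp); add(f, f, pp, p)
    }
  }
  constrained <- rep(FALSE, ndof)
  dirich_left <- off[c("c", "N", "M", "v")] + 1L
  constrained[dirich_left] <- TRUE
  if (boundary == "full") {
    constrained[off[c("c", "N", "M", "v")] + np] <- TRUE
  } else {
    constrained[off[["v"]] + np] <- TRUE
  }
  constrained_of <- constrained[blocks_i]  # mask for non-identity triplets
  idn <- which(constrained)
  blocks_i <- c(blocks_i, idn)
  blocks_j <- c(blocks_j, idn)
  key <- (as.double(blocks_j) - 1) * ndof + as.double(blocks_i)
  uk <- sort(unique(key))
  pos <- match(key, uk)
  iu <- as.integer((uk - 1) %% ndof) + 1L
  ju <- as.integer((uk - 1) %/% ndof) + 1L
  template <- Matrix::sparseMatrix(i = iu, j = ju,
                                   x = rep(0, length(uk)),
                                   dims = c(ndof, ndof))
  # diagonal scaling of the unknowns by per-field characteristic magnitudes
  # (fields span ~1e-15 .. 1e4 in raw units; scaling keeps the monolithic
  # solve well conditioned and makes update norms comparable across fields)
  Sdof <- rep(unname(scales[c("c", "N", "M", "rho", "v", "eps")]),
              each = np)
  list(np = np, n = n, off = off, ndof = ndof, pos = pos,
       n_id = length(idn), constrained = constrained,
       constrained_of = constrained_of,
       template = template, boundary = boundary, lumping = lumping,
       Sdof = Sdof, csc_scale = Sdof[ju] / Sdof[iu])
}

lump_mass <- function(x) {
  h <- diff(x)
  c(h, 0) / 2 + c(0, h) / 2
}

cons_mass_mult <- function(x, z) {
  # consistent linear-FEM mass matrix times nodal vector
  h <- diff(x); n <- length(h)
  zl <- z[seq_len(n)]; zr <- z[-1]
  el <- h * (zl / 3 + zr / 6)
  er <- h * (zl / 6 + zr / 3)
  c(el, 0) + c(0, er)
}

#' Assemble one backward-Euler/Picard linear system
#'
#' Builds the monolithic Galerkin system for all six fields for one implicit
#' step of size `dt`, with every nonlinear coefficient frozen at the supplied
#' Picard iterate and the mesh already moved to the iterate's velocity.
#' Exposed mainly for verification; [fem_advance()] drives it.
#'
#' @param fields_old nodal fields at the start of the step.
#' @param x_old,x_new node coordinates at the start of the step and at the
#'   current Picard iterate of the end of the step.
#' @param iterate current Picard iterate of the end-of-step fields
#'   (coefficient freezing).
#' @param params a [wound_params()] object.
#' @param dt step size in days.
#' @param pattern internal sparsity pattern from `fem_pattern()`; rebuilt
#'   when omitted.
#' @param boundary,lumping see [sim_state()] and [solver_config()].
#' @param scales named per-field characteristic magnitudes used to
#'   diagonally scale the unknowns (conditioning); pass all ones to obtain
#'   the raw-unit Galerkin system.
#' @return List with the sparse matrix `A` (class `dgCMatrix`, unknowns
#'   stacked as c, N, M, rho, v, eps, each scaled by its characteristic
#'   magnitude) and right-hand side `b`; the physical solution is
#'   `pattern$Sdof * solve(A, b)`.
#' @export
assemble_step_system <- function(fields_old, x_old, x_new, iterate, params,
                                 dt, boundary = c("full", "half"),
                                 lumping = TRUE, pattern = NULL,
                                 scales = default_field_scales(params)) {
  boundary <- match.arg(boundary)
  np <- length(x_old)
  if (is.null(pattern)) pattern <- fem_pattern(np, boundary, lumping, scales)
  pr <- params
  g <- iterate
  h1 <- diff(x_new)
  m0 <- lump_mass(x_old)
  m1 <- lump_mass(x_new)
  n <- np - 1L
  il <- seq_len(n); ir <- il + 1L

  elem_mean <- function(z) (z[il] + z[ir]) / 2

  inhib <- 1 + pr$a_c_II * g$c
  NM <- g$N + g$M
  crowd <- 1 - pr$kappa_F * NM
  hillIII <- g$c / (pr$a_c_III + g$c)
  secr_c  <- pr$k_c * (g$N + pr$eta_I * g$M) / (pr$a_c_I + g$c)
  decay_c <- pr$delta_c * (g$N + pr$eta_II * g$M) * g$rho / inhib
  prolif_N <- pr$r_F * (1 + pr$r_F_max * hillIII) * crowd *
    ifelse(g$N > 0, g$N, 1)^pr$q * (g$N > 0)
  prolif_M <- pr$r_F * ((1 + pr$r_F_max) * hillIII) * crowd *
    ifelse(g$M > 1e-8, g$M, 1)^pr$q * (g$M > 1e-8)
  decay_rho <- pr$delta_rho * (g$N + pr$eta_II * g$M) * g$rho / inhib
  prod_rho  <- pr$k_rho * (1 + pr$k_rho_max * g$c / (pr$a_c_IV + g$c)) *
    (g$N + pr$eta_I * g$M)
  alpha <- strain_decay_rate(g$c, g$N, g$M, pr)
  sqr <- pr$E * sqrt(pmax(g$rho, 0))
  bodyf <- pr$xi * g$M * g$rho / (pr$R^2 + g$rho^2)

  mt <- if (lumping) m1 / dt else {
    # consistent mass: diagonal part; off-diagonals appended below
    (c(h1, 0) / 3 + c(0, h1) / 3) / dt
  }
  # block diagonals (reaction terms always lumped)
  d_c   <- mt + m1 * (decay_c - secr_c)
  d_N   <- mt + m1 * (pr$delta_N + pr$k_F * g$c - prolif_N)
  d_M   <- mt + m1 * (pr$delta_M - prolif_M)
  d_rho <- mt + m1 * decay_rho
  d_v   <- pr$rho_t * mt
  d_eps <- mt + m1 * alpha

  stiff <- function(w_nodal) {
    we <- elem_mean(w_nodal) / h1
    c(we, -we, -we, we)
  }
  x_vals <- c(d_c, d_N, d_M, d_rho, d_v, d_eps,
              stiff(rep(pr$D_c, np)),
              stiff(pr$D_F * NM),
              stiff(-pr$chi_F * g$N),
              stiff(pr$D_F * NM),
              stiff(-pr$chi_F * g$M),
              -m1 * pr$k_F * g$c,
              stiff(rep(pr$mu, np)))
  # elastic stress: integral of E sqrt(rho) eps against test gradients
  se <- elem_mean(sqr)
  x_vals <- c(x_vals, c(-se / 2, -se / 2, se / 2, se / 2))
  # geometric strain source: -integral of phi dv/dx
  half <- rep(0.5, n)
  x_vals <- c(x_vals, c(half, -half, half, -half))
  if (!lumping) {
    # consistent-mass off-diagonals, field order c, N, M, rho, v, eps
    om <- h1 / 6 / dt
    x_vals <- c(x_vals,
                unlist(lapply(c(1, 1, 1, 1, pr$rho_t, 1),
                              function(s) c(s * om, s * om)),
                       use.names = FALSE))
  }
  # Dirichlet rows: zero out, then unit diagonal
  x_vals[pattern$constrained_of] <- 0
  x_vals <- c(x_vals, rep(1, pattern$n_id))

  A <- pattern$template
  A@x <- as.numeric(rowsum(x_vals, pattern$pos, reorder = TRUE)) *
    pattern$csc_scale

  mass_old <- function(z, scale = 1) {
    if (lumping) scale * m0 * z / dt else scale * cons_mass_mult(x_old, z) / dt
  }
  b_c   <- mass_old(fields_old$c)
  b_N   <- mass_old(fields_old$N)
  b_M   <- mass_old(fields_old$M)
  b_rho <- mass_old(fields_old$rho) + m1 * prod_rho
  # body force enters the velocity rows through the test-function gradients
  be <- elem_mean(bodyf)
  gv <- numeric(np)
  gv[il]  <- gv[il] + be
  gv[ir]  <- gv[ir] - be
  b_v   <- mass_old(fields_old$v, pr$rho_t) + gv
  b_eps <- mass_old(fields_old$eps)
  b <- c(b_c, b_N, b_M, b_rho, b_v, b_eps)

  # boundary values
  off <- pattern$off
  Nb <- pr$N_bar
  b[off[["c"]] + 1L] <- 0
  b[off[["N"]] + 1L] <- Nb
  b[off[["M"]] + 1L] <- 0
  b[off[["v"]] + 1L] <- 0
  if (boundary == "full") {
    b[off[["c"]] + np] <- 0
    b[off[["N"]] + np] <- Nb
    b[off[["M"]] + np] <- 0
    b[off[["v"]] + np] <- 0
  } else {
    b[off[["v"]] + np] <- 0
  }
  list(A = A, b = b / pattern$Sdof, pattern = pattern)
}

default_field_scales <- function(params) {
  c(c = params$a_c_I, N = params$N_bar, M = params$N_bar,
    rho = collagen_equilibrium(params$k_rho, params$delta_rho),
    v = 1, eps = 1)
}

blowup_result <- function(state, reason, iterations = NA_integer_) {
  structure(list(state = state, converged = FALSE, iterations = iterations,
                 blowup = TRUE, reason = reason), class = "fem_step")
}

#' Advance the solution by one implicit time step
#'
#' One backward-Euler step with monolithic Picard iterations: each iteration
#' moves the mesh with the iterate's end-of-step velocity
#' (\eqn{x^{t+\Delta t} = x^t + \Delta t\, v^{t+\Delta t}}), reassembles the
#' frozen-coefficient Galerkin system on the moved mesh and solves for all
#' six fields at once, until the relative l2 update falls below
#' `config$picard_tol`. Displacements accumulate as
#' \eqn{u^{t+\Delta t} = u^t + \Delta t\, v^{t+\Delta t}}.
#'
#' @param state a [sim_state()].
#' @param dt step size in days.
#' @param config a [solver_config()].
#' @param pattern optional precomputed sparsity pattern (internal reuse).
#' @return List of class `fem_step` with the updated `state`, `converged`
#'   flag, Picard `iterations` used, and on failure `blowup = TRUE` with a
#'   `reason` (mesh tangling, singular matrix, or non-finite solution) and
#'   the last finite state.
#' @export
fem_advance <- function(state, dt, config = solver_config(), pattern = NULL) {
  stopifnot(inherits(state, "sim_state"))
  params <- state$params
  np <- length(state$x)
  if (is.null(pattern))
    pattern <- fem_pattern(np, state$boundary, config$lumping,
                           default_field_scales(params))
  old <- state$fields
  x0 <- state$x
  guess <- old
  iterations <- 0L
  converged <- FALSE
  x1 <- x0
  repeat {
    iterations <- iterations + 1L
    x1 <- x0 + dt * guess$v
    if (any(diff(x1) <= 0)) {
      if (iterations == 1L) {
        # the start-of-step velocity can overshoot the implicit one badly
        # (it is strongly damped within the step); fall back to a frozen
        # mesh for the first iterate and move with solved velocities after
        x1 <- x0
      } else {
        return(blowup_result(state, "mesh tangling", iterations))
      }
    }
    sys <- assemble_step_system(old, x0, x1, guess, params, dt,
                                boundary = state$boundary,
                                lumping = config$lumping, pattern = pattern)
    sol <- tryCatch(as.numeric(Matrix::solve(sys$A, sys$b)),
                    error = function(e)
                      structure(conditionMessage(e), class = "solve_error"))
    if (inherits(sol, "solve_error"))
      return(blowup_result(state, paste("singular matrix:", sol), iterations))
    if (!all(is.finite(sol)))
      return(blowup_result(state, "non-finite solution", iterations))
    # sol is in scaled units; update norm measured there so that all six
    # fields contribute on comparable footing
    prev_scaled <- unlist(guess, use.names = FALSE) / pattern$Sdof
    upd <- sqrt(sum((sol - prev_scaled)^2)) / max(sqrt(sum(sol^2)), 1)
    phys <- sol * pattern$Sdof
    newf <- list(c   = phys[pattern$off[["c"]] + seq_len(np)],
                 N   = phys[pattern$off[["N"]] + seq_len(np)],
                 M   = phys[pattern$off[["M"]] + seq_len(np)],
                 rho = phys[pattern$off[["rho"]] + seq_len(np)],
                 v   = phys[pattern$off[["v"]] + seq_len(np)],
                 eps = phys[pattern$off[["eps"]] + seq_len(np)])
    guess <- newf
    if (upd < config$picard_tol) { converged <- TRUE; break }
    if (iterations >= config$picard_max) break
  }
  x1 <- x0 + dt * guess$v
  if (any(diff(x1) <= 0))
    return(blowup_result(state, "mesh tangling", iterations))
  state$x <- x1
  state$u <- state$u + dt * guess$v
  state$fields <- guess
  state$t <- state$t + dt
  structure(list(state = state, converged = converged,
                 iterations = iterations, blowup = FALSE, reason = NULL),
            class = "fem_step")
}

#' Relative surface area of the wound
#'
#' Current distance between the two material wound-edge marker nodes divided
#' by their initial distance; equals 1 at the start and falls below 1 under
#' contraction.
#'
#' @param state a [sim_state()] carrying marker indices.
#' @return Dimensionless ratio.
#' @export
relative_surface_area <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  if (is.null(state$markers)) return(NA_real_)
  d <- diff(state$x[state$markers])
  if (d <= 0) stop("wound-edge markers crossed: nonphysical configuration")
  d / state$markers_dist0
}

#' Run a simulation to a target time
#'
#' Steps [fem_advance()] from the state's current time to `t_end` following
#' the config's time-step schedule, recording a per-step time series of
#' observables (field extrema, values at the domain centre/right end,
#' relative wound surface area, mass-weighted l2 distance to the healthy
#' equilibrium, Picard statistics). On blow-up the partial trajectory is
#' returned with the termination reason.
#'
#' @param state a [sim_state()].
#' @param t_end target time in days.
#' @param config a [solver_config()].
#' @param snapshot_times times (days) at which to store full nodal snapshots
#'   (matched to the nearest completed step).
#' @param record_every record the observable series every this many steps
#'   (default 1).
#' @param eq optional [equilibrium_state()] used for the distance series.
#' @return An object of class `sim_trajectory`: list with `series`
#'   (data.frame), `snapshots`, the final `state`, `termination`
#'   (`"completed"` or `"blowup"`), `reason`, and Picard statistics.
#' @export
simulate_contraction <- function(state, t_end, config = solver_config(),
                                 snapshot_times = numeric(0),
                                 record_every = 1L, eq = NULL) {
  stopifnot(inherits(state, "sim_state"), t_end > state$t)
  if (is.null(eq)) eq <- equilibrium_state(state$params)
  pattern <- fem_pattern(length(state$x), state$boundary, config$lumping)
  eqv <- c(c = eq$c_bar, N = eq$N_bar, M = eq$M_bar, rho = eq$rho_bar,
           v = eq$v_bar, eps = eq$eps_bar)
  rec <- list(); snaps <- list()
  snap_pending <- sort(snapshot_times)
  step <- 0L; pic_total <- 0L; pic_max <- 0L; nonconv <- 0L
  neg_warned <- FALSE
  record <- function(s) {
    f <- s$fields
    m <- lump_mass(s$x)
    dev <- vapply(names(f), function(nm) {
      sqrt(sum(m * (f[[nm]] - eqv[[nm]])^2))
    }, 0)
    np <- length(s$x)
    data.frame(t = s$t,
               v_min = min(f$v), v_max = max(f$v),
               v_maxabs = max(abs(f$v)),
               eps_min = min(f$eps), eps_max = max(f$eps),
               c_max = max(f$c), N_min = min(f$N), N_max = max(f$N),
               M_max = max(f$M), rho_min = min(f$rho), rho_max = max(f$rho),
               c_end = f$c[np], N_end = f$N[np], M_end = f$M[np],
               rho_end = f$rho[np],
               rsaw = relative_surface_area(s),
               dev_c = dev[["c"]], dev_N = dev[["N"]], dev_M = dev[["M"]],
               dev_rho = dev[["rho"]], dev_v = dev[["v"]],
               dev_eps = dev[["eps"]])
  }
  rec[[length(rec) + 1L]] <- record(state)
  termination <- "completed"; reason <- NULL
  while (state$t < t_end - 1e-9) {
    dt <- min(schedule_dt(config$dt_schedule, state$t), t_end - state$t)
    stp <- fem_advance(state, dt, config, pattern)
    if (isTRUE(stp$blowup)) {
      termination <- "blowup"; reason <- stp$reason
      state <- stp$state
      break
    }
    state <- stp$state
    step <- step + 1L
    pic_total <- pic_total + stp$iterations
    pic_max <- max(pic_max, stp$iterations)
    if (!stp$converged) nonconv <- nonconv + 1L
    if (!neg_warned &&
        (min(state$fields$c, state$fields$N, state$fields$M,
             state$fields$rho) < -1e-8)) {
      warning("negative density encountered (monotonicity loss); continuing")
      neg_warned <- TRUE
    }
    if (step %% record_every == 0L || state$t >= t_end - 1e-9)
      rec[[length(rec) + 1L]] <- record(state)
    while (length(snap_pending) && state$t >= snap_pending[1] - 1e-9) {
      snaps[[sprintf("t=%g", snap_pending[1])]] <-
        list(t = state$t, x = state$x, fields = state$fields)
      snap_pending <- snap_pending[-1]
    }
  }
  structure(list(series = do.call(rbind, rec), snapshots = snaps,
                 state = state, termination = termination, reason = reason,
                 steps = step, picard_total = pic_total,
                 picard_max = pic_max, nonconverged_steps = nonconv),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("<sim_trajectory> %d steps to t = %g days (%s%s)\n",
              x$steps, x$state$t, x$termination,
              if (!is.null(x$reason)) paste0(": ", x$reason) else ""))
  cat(sprintf("  Picard: %.2f iterations/step (max %d), %d non-converged\n",
              if (x$steps > 0) x$picard_total / x$steps else NA,
              x$picard_max, x$nonconverged_steps))
  if (!is.na(utils::tail(x$series$rsaw, 1)))
    cat(sprintf("  relative wound surface area: %.6f\n",
                utils::tail(x$series$rsaw, 1)))
  invisible(x)
}

#' @export
plot.sim_trajectory <- function(x, what = c("deviation", "velocity", "rsaw"),
                                ...) {
  what <- match.arg(what)
  s <- x$series
  if (what == "deviation") {
    cols <- c("dev_c", "dev_N", "dev_M", "dev_rho", "dev_v", "dev_eps")
    keep <- s[, cols, drop = FALSE]
    keep[keep <= 0] <- NA
    graphics::matplot(s$t, as.matrix(keep), type = "l", log = "y",
                      xlab = "time (days)",
                      ylab = "mass-weighted l2 distance to equilibrium", ...)
    graphics::legend("topright", legend = sub("dev_", "", cols),
                     col = seq_along(cols), lty = seq_along(cols), bty = "n")
  } else if (what == "velocity") {
    graphics::plot(s$t, s$v_maxabs, type = "l", xlab = "time (days)",
                   ylab = "max |v| (cm/day)", ...)
  } else {
    graphics::plot(s$t, s$rsaw, type = "l", xlab = "time (days)",
                   ylab = "relative wound surface area", ...)
  }
  invisible(x)
}
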