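test_that("homogeneous equilibrium is an exact fixed point of the stepper", {
  p <- wound_params()
  eq <- equilibrium_state(p)
  np <- 41
  st <- sim_state(make_uniform_mesh(np - 1, c(0, 1)),
                  equilibrium_fields(eq, np), p, boundary = "half")
  for (dt in c(0.5, 5)) {
    s <- st
    for (i in 1:10) {
      stp <- fem_advance(s, dt)
      expect_false(stp$blowup)
      expect_true(stp$converged)
      expect_equal(stp$iterations, 1L)   # fixed point seen immediately
      s <- stp$state
    }
    expect_equal(s$x, st$x)              # mesh stationary
    for (f in names(st$fields)) {
      scale <- max(1, abs(st$fields[[f]][1]))
      expect_lt(max(abs(s$fields[[f]] - st$fields[[f]])) / scale, 1e-12)
    }
  }
})

test_that("pure-diffusion reduction matches a hand-assembled lumped system", {
  # 3 elements, uniform h, only D_c active; compare the c block of the
  # monolithic system (unscaled) with the textbook lumped FEM heat system
  p <- diffusion_only_params(D_c = 0.7)
  np <- 4; h <- 1 / 3; dt <- 0.2
  x <- make_uniform_mesh(3, c(0, 1))
  f <- list(c = c(0, 2, 1, 0), N = rep(0, np), M = rep(0, np),
            rho = rep(1e-300, np), v = rep(0, np), eps = rep(0, np))
  ones <- c(c = 1, N = 1, M = 1, rho = 1, v = 1, eps = 1)
  sys <- assemble_step_system(f, x, x, f, p, dt, boundary = "full",
                              scales = ones)
  Ac <- as.matrix(sys$A[1:np, 1:np])
  m <- c(h / 2, h, h, h / 2)
  K <- p$D_c / h * (diag(c(1, 2, 2, 1)) -
                      (col(diag(np)) == row(diag(np)) + 1) -
                      (col(diag(np)) == row(diag(np)) - 1))
  expected <- diag(m) / dt + K
  expected[1, ] <- c(1, 0, 0, 0)        # Dirichlet rows
  expected[np, ] <- c(0, 0, 0, 1)
  expect_equal(Ac, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.numeric(sys$b[1:np]), c(0, m[2] * 2 / dt, m[3] / dt, 0),
               tolerance = 1e-12)
})

test_that("implicit diffusion step damps sine modes at the exact discrete rate", {
  # on a uniform Dirichlet grid, sin modes are eigenvectors of the lumped
  # FEM heat operator with eigenvalue D*4 sin^2(beta pi h / 2)/h^2, so one
  # backward Euler step must multiply them by 1/(1 + dt lambda)
  p <- diffusion_only_params(D_c = 2.88e-3)
  n <- 32; np <- n + 1; h <- 1 / n; dt <- 0.37
  x <- make_uniform_mesh(n, c(0, 1))
  for (beta in c(1, 4, 9)) {
    mode <- sin(pi * beta * x)
    f <- list(c = 1e-8 * mode, N = rep(0, np), M = rep(0, np),
              rho = rep(1e-300, np), v = rep(0, np), eps = rep(0, np))
    st <- sim_state(x, f, p, boundary = "full")
    s2 <- fem_advance(st, dt)$state
    lam <- p$D_c * 4 * sin(pi * beta * h / 2)^2 / h^2
    expect_equal(s2$fields$c, 1e-8 * mode / (1 + dt * lam),
                 tolerance = 1e-8)
  }
})

test_that("small signaling perturbations decay at the continuous-mode rate", {
  # k = 1 Fourier-mode perturbation of c only, full domain of length 1:
  # the linearized decay rate is A11(k = 1); verify over early steps
  p <- wound_params()
  eq <- equilibrium_state(p)
  n <- 128; np <- n + 1
  x <- make_uniform_mesh(n, c(0, 1))
  f <- equilibrium_fields(eq, np)
  amp0 <- 1e-12
  # sin(2 pi x) has one full period on the unit domain: it carries exactly
  # the k = 1 Fourier wavelength and satisfies the Dirichlet condition
  f$c <- f$c + amp0 * sin(2 * pi * x)
  st <- sim_state(x, f, p, boundary = "full")
  lam <- Re(eigenvalues_continuous(assemble_continuous(p, eq, 1))[1])
  dt <- 0.02
  s <- st
  for (i in 1:10) s <- fem_advance(s, dt)$state
  amp <- max(abs(s$fields$c))
  decay_obs <- -log(amp / amp0) / (10 * dt)
  expect_equal(decay_obs, lam, tolerance = 0.1)
})

test_that("strain perturbations relax at the slow mechanical eigenvalue", {
  p <- wound_params()
  eq <- equilibrium_state(p)
  n <- 200; np <- n + 1
  x <- make_uniform_mesh(n, c(0, 1))
  f <- equilibrium_fields(eq, np)
  f$eps <- 1e-6 * sin(2 * pi * x)
  st <- sim_state(x, f, p, boundary = "half")
  lam <- Re(eigenvalues_continuous(assemble_continuous(p, eq, 1))[6])
  cfg <- solver_config(dt_schedule = data.frame(start = 0, dt = 0.05))
  tr <- simulate_contraction(st, 2, cfg, eq = eq)
  s <- tr$series
  a1 <- s$dev_eps[which.min(abs(s$t - 1))]
  a2 <- s$dev_eps[which.min(abs(s$t - 2))]
  expect_equal(-log(a2 / a1), lam, tolerance = 0.1)
})

test_that("half-domain symmetric run matches the mirrored full-domain run", {
  p <- wound_params()
  eq <- equilibrium_state(p)
  n <- 80; np <- n + 1
  xh <- make_uniform_mesh(n, c(0, 1))
  fh <- make_perturbation_profile(perturbation_scenario(k = 1), xh, eq)
  sth <- sim_state(xh, fh, p, boundary = "half")
  # mirrored initial condition on [0, 2]: scalars even, velocity odd
  xf <- make_uniform_mesh(2 * n, c(0, 2))
  ff <- lapply(names(fh), function(nm) {
    z <- fh[[nm]]
    mir <- if (nm == "v") -rev(z[-np]) else rev(z[-np])
    c(z, mir)
  })
  names(ff) <- names(fh)
  stf <- sim_state(xf, ff, p, boundary = "full")
  cfg <- solver_config()
  trh <- simulate_contraction(sth, 5, cfg, eq = eq)
  trf <- simulate_contraction(stf, 5, cfg, eq = eq)
  for (nm in names(fh)) {
    zh <- trh$state$fields[[nm]]
    zf <- trf$state$fields[[nm]][1:np]
    scale <- max(abs(zh), 1e-12)
    expect_lt(max(abs(zh - zf)) / scale, 1e-6)
  }
  expect_lt(max(abs(trh$state$x - trf$state$x[1:np])), 1e-8)
})

test_that("mass lumping preserves the discrete maximum principle", {
  # pure diffusion, spike initial condition: the lumped scheme stays within
  # the initial bounds, the consistent-mass scheme overshoots
  p <- diffusion_only_params(D_c = 1)
  n <- 20; np <- n + 1
  x <- make_uniform_mesh(n, c(0, 1))
  f <- list(c = rep(0, np), N = rep(0, np), M = rep(0, np),
            rho = rep(1e-300, np), v = rep(0, np), eps = rep(0, np))
  f$c[10] <- 1
  dt <- 1e-4   # small step: consistent mass oscillates, lumped must not
  st <- sim_state(x, f, p, boundary = "full")
  lump <- fem_advance(st, dt, solver_config(lumping = TRUE))$state
  cons <- fem_advance(st, dt, solver_config(lumping = FALSE))$state
  expect_gte(min(lump$fields$c), -1e-14)
  expect_lte(max(lump$fields$c), 1 + 1e-12)
  expect_lt(min(cons$fields$c), -1e-6)   # loss of monotonicity
})

test_that("relative wound surface area tracks the marker nodes", {
  p <- wound_params()
  scn <- wound_scenario()
  st <- wound_state(scn, 100, p)
  expect_equal(relative_surface_area(st), 1.0)
  # equilibrium state: no motion, area ratio stays 1
  eq <- equilibrium_state(p)
  ste <- sim_state(st$x, equilibrium_fields(eq, length(st$x)), p,
                   boundary = "full", markers = st$markers)
  tr <- simulate_contraction(ste, 2, solver_config())
  expect_equal(relative_surface_area(tr$state), 1.0)
  # wound scenario: after the early myofibroblast build-up at the wound
  # border (which transiently pushes the edges outward), the maturing
  # myofibroblast population inside the wound pulls the edges inward
  tr2 <- simulate_contraction(st, 15, solver_config(
    dt_schedule = data.frame(start = c(0, 2), dt = c(0.1, 0.5))))
  expect_lt(relative_surface_area(tr2$state), 1.0)
  # velocity points into the wound at the edges while contracting
  v <- tr2$state$fields$v
  expect_gt(v[st$markers[1]], 0)
  expect_lt(v[st$markers[2]], 0)
})

test_that("implicit kinetics linearization matches the collagen eigenvalue", {
  # uniform collagen perturbation (k = 0 mode, no boundary constraint on
  # rho): one converged Picard step must damp it by 1/(1 + dt A44)
  p <- wound_params()
  eq <- equilibrium_state(p)
  np <- 21
  st <- sim_state(make_uniform_mesh(np - 1, c(0, 1)),
                  equilibrium_fields(eq, np), p, boundary = "half")
  d0 <- 1e-8
  st$fields$rho <- st$fields$rho + d0
  dt <- 2
  s <- fem_advance(st, dt, solver_config(picard_tol = 1e-13))$state
  A44 <- 2 * p$delta_rho * eq$N_bar * eq$rho_bar
  expect_equal(max(s$fields$rho - eq$rho_bar), d0 / (1 + dt * A44),
               tolerance = 1e-5)
})
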