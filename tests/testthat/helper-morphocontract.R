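# Shared test helpers: randomized-but-valid parameter sets, equilibrium
# field constructors, and a cache for expensive shared simulations.

# Randomized valid parameter set: every positive parameter jittered
# lognormally around the reference values, q re-derived so the equilibrium
# stays exact. With `stable = TRUE` the signaling-decay condition is
# enforced by construction (delta_c scaled up from the threshold).
random_params <- function(stable = TRUE, sd = 0.3) {
  jit <- function(x) x * exp(stats::rnorm(1, 0, sd))
  p <- wound_params()
  ov <- list(D_c = jit(p$D_c), D_F = jit(p$D_F), chi_F = jit(p$chi_F),
             k_c = jit(p$k_c), r_F = jit(p$r_F), k_rho = jit(p$k_rho),
             a_c_I = jit(p$a_c_I), a_c_II = jit(p$a_c_II),
             a_c_III = jit(p$a_c_III), a_c_IV = jit(p$a_c_IV),
             k_F = jit(p$k_F), kappa_F = jit(p$kappa_F),
             delta_N = jit(p$delta_N), delta_M = jit(p$delta_M),
             delta_rho = jit(p$delta_rho), zeta = jit(p$zeta),
             rho_t = jit(p$rho_t), mu = jit(p$mu), E = jit(p$E),
             xi = jit(p$xi), R = jit(p$R), N_bar = jit(p$N_bar))
  if (ov$kappa_F * ov$N_bar >= 0.99)
    ov$kappa_F <- 0.5 / ov$N_bar
  if (stable) {
    rb <- sqrt(ov$k_rho / ov$delta_rho)
    ov$delta_c <- ov$k_c / (ov$a_c_I * rb) * stats::runif(1, 1, 3)
  } else {
    ov$delta_c <- jit(p$delta_c)
  }
  do.call(wound_params, ov)
}

equilibrium_fields <- function(eq, np) {
  list(c = rep(eq$c_bar, np), N = rep(eq$N_bar, np),
       M = rep(eq$M_bar, np), rho = rep(eq$rho_bar, np),
       v = rep(eq$v_bar, np), eps = rep(eq$eps_bar, np))
}

# near-pure-diffusion parameter set: all kinetic rates driven to a
# negligible level so only D_c transport remains active for the c field
diffusion_only_params <- function(D_c = 2.88e-3) {
  wound_params(D_c = D_c, k_c = 1e-300, delta_c = 1e-300, r_F = 1e-300,
               delta_N = 1e-300, k_F = 1e-300, delta_M = 1e-300,
               k_rho = 1e-300, delta_rho = 1e-300, zeta = 1e-300,
               xi = 1e-300, chi_F = 1e-300, D_F = 1e-300, q = 0)
}

# cache for expensive simulations shared between acceptance blocks
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}
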