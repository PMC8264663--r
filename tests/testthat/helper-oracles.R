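# Independent numerical oracles used to cross-check the sparse stationary
# solver, plus small shared fixtures. These deliberately use different
# algorithms from the implementation under test.

# Jacobi relaxation: u_i <- D * sum(neighbors) / (4D + gamma), sources
# re-imposed each sweep, ghost boundary zero. Converges for gamma > 0.
jacobi_solve <- function(input, grid, tol = 1e-12, max_iter = 200000L) {
  L <- grid$L; D <- grid$D; gam <- grid$gamma
  src <- input > 0
  u <- input
  pad <- matrix(0, L + 2L, L + 2L)
  for (it in seq_len(max_iter)) {
    pad[2:(L + 1L), 2:(L + 1L)] <- u
    nb <- pad[1:L, 2:(L + 1L)] + pad[3:(L + 2L), 2:(L + 1L)] +
          pad[2:(L + 1L), 1:L] + pad[2:(L + 1L), 3:(L + 2L)]
    unew <- D * nb / (4 * D + gam)
    unew[src] <- input[src]
    delta <- max(abs(unew - u))
    u <- unew
    if (delta < tol) return(u)
  }
  stop("Jacobi relaxation did not converge")
}

# Explicit-Euler time stepping of du/dt = D lap(u) - gamma u to steady state;
# sources held fixed; dt chosen inside the stability bound.
euler_solve <- function(input, grid, tol = 1e-12, max_iter = 400000L) {
  L <- grid$L; D <- grid$D; gam <- grid$gamma
  dt <- 0.9 / (4 * D + gam)
  src <- input > 0
  u <- input
  pad <- matrix(0, L + 2L, L + 2L)
  for (it in seq_len(max_iter)) {
    pad[2:(L + 1L), 2:(L + 1L)] <- u
    lap <- pad[1:L, 2:(L + 1L)] + pad[3:(L + 2L), 2:(L + 1L)] +
           pad[2:(L + 1L), 1:L] + pad[2:(L + 1L), 3:(L + 2L)] - 4 * u
    unew <- u + dt * (D * lap - gam * u)
    unew[src] <- input[src]
    delta <- max(abs(unew - u))
    u <- unew
    if (delta < tol * dt) return(u)
  }
  stop("Euler time stepping did not converge")
}

# Closed form of the 1-d recurrence D (u_{k+1} - 2 u_k + u_{k-1}) = gamma u_k
# on rows 0..L-1 with ghost values u_{-1} = u_L = 0 and u_{r0} = v imposed.
# General solution A lam^k + B lam^-k with lam the root > 1 of
# D lam^2 - (2D + gamma) lam + D = 0; constants fixed per segment by its two
# boundary conditions.
strip_1d_closed_form <- function(L, D, gam, r0, v) {
  a <- 2 * D + gam
  lam <- (a + sqrt(a^2 - 4 * D^2)) / (2 * D)
  S <- function(j) lam^j - lam^(-j)   # discrete sinh; S(0) = 0
  # segment with ghost zero at g and imposed value v at s: v * S(|k-g|)/S(|s-g|)
  u <- numeric(L)
  u[r0 + 1L] <- v
  if (r0 > 0) {
    ks <- 0:(r0 - 1L)
    u[ks + 1L] <- v * S(ks + 1L) / S(r0 + 1L)
  }
  if (r0 < L - 1L) {
    ks <- (r0 + 1L):(L - 1L)
    u[ks + 1L] <- v * S(L - ks) / S(L - r0)
  }
  u
}

# Mirror a configuration left-right (columns c -> L-1-c).
mirror_config <- function(config) {
  L <- config$grid$L
  source_configuration(lapply(config$disks, function(d)
    source_disk(d$center_row, L - 1 - d$center_col, d$radius, d$value)),
    config$grid)
}

# Tiny surrogate used in gradient and serialization tests (no dropout so the
# forward pass is deterministic given parameters).
tiny_surrogate <- function(seed = 5, dropout = c(0, 0, 0, 0)) {
  spec <- surrogate_spec(16L, p1 = 1, p2 = 1, dropout = dropout,
                         base_channels = 2L)
  build_surrogate(spec, seed = seed)
}
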