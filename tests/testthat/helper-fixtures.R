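# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# a random non-pathological particle fixture for force checks: monomer
# pairs kept away from the WCA cap radius and the cutoff so the potential
# is smooth at every sampled point
force_fixture <- function(n = 20, m = 10, seed = 42, Delta = 2) {
  set.seed(seed)
  params <- sim_params(n_chains = 1, N = n, M = m, Cr = 0,
                       F_cond = 1, Delta = Delta)
  repeat {
    pos <- matrix(runif(3 * n, 0, 4), n, 3)
    d <- as.matrix(dist(pos)); diag(d) <- Inf
    cut <- 2^(1 / 6)
    ok <- min(d) > wca_cap_radius() * 1.1 &&
      !any(abs(d - cut) < 0.02) && !any(abs(d - Delta) < 0.02)
    if (ok) break
  }
  repeat {
    cpos <- matrix(runif(3 * m, 0, 4), m, 3)
    dc <- as.matrix(dist(cpos)); diag(dc) <- Inf
    # keep condensin pairs off the attraction threshold, where the force
    # has a kink and finite differences straddle it
    if (!any(abs(dc - Delta) < 0.02)) break
  }
  springs <- cbind(1:(n - 1), 2:n)
  anchors <- cbind(sample(n, m, replace = TRUE), sample(n, m, replace = TRUE))
  state <- chromo_state(pos, rep(1L, n), cpos, rep(1L, m))
  topology <- chromo_topology(springs, anchors)
  list(state = state, topology = topology, params = params)
}

# free single particle (no interactions)
free_particle_state <- function(v = c(0, 0, 0)) {
  chromo_state(matrix(0, 1, 3), 1L,
               mono_vel = matrix(v, 1, 3))
}

empty_topology <- function(n_cond = 0) {
  chromo_topology(matrix(integer(0), 0, 2),
                  if (n_cond > 0) matrix(1L, n_cond, 2)
                  else matrix(integer(0), 0, 2))
}

# an ideal (phantom) harmonic chain: springs only, no excluded volume
ideal_chain_system <- function(N = 100, seed = 7) {
  set.seed(seed)
  params <- sim_params(n_chains = 1, N = N, M = 1, Cr = 0,
                       F_loop = 0, F_cond = 0, eps = 0)
  pos <- random_walk_chain(N)
  state <- chromo_state(pos, rep(1L, N),
                        mono_vel = matrix(rnorm(3 * N), N, 3))
  topology <- chromo_topology(cbind(1:(N - 1), 2:N),
                              matrix(c(1L, N), 1, 2))
  state$cond_pos <- matrix(0, 0, 3)
  state$cond_vel <- matrix(0, 0, 3)
  state$cond_chain <- integer(0)
  topology$anchors <- matrix(integer(0), 0, 2)
  list(state = state, topology = topology, params = params)
}
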