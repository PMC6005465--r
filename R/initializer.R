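#' Ideal random-walk chain
#'
#' Freely jointed starting coil: consecutive monomers at fixed distance
#' `d_B` in uniformly random directions, centred at its centre of mass.
#' Self-avoidance is not enforced; overlaps relax under the capped WCA
#' potential during subsequent dynamics.
#'
#' @param N monomer count (>= 2).
#' @param d_B step (bond) length.
#' @return N x 3 position matrix.
#' @export
random_walk_chain <- function(N, d_B = 1) {
  if (N < 2) stop("N must be >= 2")
  steps <- matrix(rnorm(3 * (N - 1)), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * d_B
  pos <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  sweep(pos, 2, colMeans(pos))
}

# Random walk confined to a sphere of radius R by step rejection: for
# N >> R^2 the walk fills the sphere quasi-uniformly, which is the
# equilibrium of a confined self-avoiding chain. Starting there makes the
# in-shell equilibration local instead of requiring the chain to swell
# across the shell diffusively.
confined_random_walk <- function(N, R, d_B = 1) {
  pos <- matrix(0, N, 3)
  cur <- c(0, 0, 0)
  lim2 <- (R - d_B)^2
  for (i in 2:N) {
    repeat {
      s <- rnorm(3)
      nxt <- cur + s / sqrt(sum(s^2)) * d_B
      if (sum(nxt^2) <= lim2) break
    }
    pos[i, ] <- nxt
    cur <- nxt
  }
  pos
}

#' Shell diameter and radius for n chains
#'
#' The confining shell keeps a constant per-chain volume: diameter
#' `shell_D1 * n_chains^(1/3)` (22.85 for one chain gives 28.79 for two).
#'
#' @param params a [sim_params()].
#' @param n_chains chain count; defaults to `params$n_chains`.
#' @return Shell diameter (`shell_diameter`) or radius (`shell_radius`).
#' @export
shell_diameter <- function(params, n_chains = params$n_chains) {
  params$shell_D1 * n_chains^(1 / 3)
}

#' @rdname shell_diameter
#' @export
shell_radius <- function(params, n_chains = params$n_chains) {
  shell_diameter(params, n_chains) / 2
}

#' Compact chains into a spherical shell and equilibrate
#'
#' Applies a harmonic confining wall at the shell radius (stiffness `eps_cut`
#' per unit length squared) and runs thermostatted dynamics. The wall force
#' is clamped during an initial gathering phase so that far-flung coil ends
#' drift in at a bounded speed, then unclamped to hold the assembly at the
#' target density while it equilibrates.
#'
#' The starting coil has no self-avoidance, so deeply overlapped monomer
#' pairs exist at first; at the production timestep the capped potential
#' releases their energy impulsively and the system self-heats. A warmup
#' stage at `dt / 10` therefore precedes the main compaction: overlaps then
#' resolve gently and the kinetic temperature settles at `kT` before the
#' full timestep takes over.
#'
#' @param state a [chromo_state()] (no condensins required).
#' @param topology chain-spring topology.
#' @param params a [sim_params()].
#' @param n_steps main-stage steps (half gathering, half
#'   holding/equilibration) at the production timestep.
#' @param warmup_steps steps of the reduced-timestep warmup stage.
#' @param tol monomers may protrude up to `tol` beyond the shell radius at
#'   the end (default one `sigma`).
#' @return Compacted, equilibrated `chromo_state`.
#' @export
compact_into_shell <- function(state, topology, params,
                               n_steps = 10000L, warmup_steps = 5000L,
                               tol = params$sigma) {
  R <- shell_radius(params)
  if (warmup_steps > 0L) {
    pw <- params
    pw$dt <- params$dt / 10
    state <- langevin_step(state, topology, pw, n_steps = warmup_steps,
                           wall = list(R = R, k = params$eps_cut, fmax = 10))
  }
  n1 <- n_steps %/% 2L
  state <- langevin_step(state, topology, params, n_steps = n1,
                         wall = list(R = R, k = params$eps_cut, fmax = 10))
  state <- langevin_step(state, topology, params, n_steps = n_steps - n1,
                         wall = list(R = R, k = params$eps_cut, fmax = Inf))
  r <- sqrt(rowSums(state$mono_pos^2))
  frac_out <- mean(r > R + tol)
  if (frac_out > 0)
    stop(sprintf(paste0("compaction did not converge: %.1f%% of monomers ",
                        "outside the shell (R = %.2f) after %d steps"),
                 100 * frac_out, R, n_steps))
  state
}

#' Rewire two chain springs into a crossing
#'
#' Given a condensin bond pair `(a, b)` (1-based monomer indices, `a < b`,
#' same chain), replaces springs `(a-1, a)` and `(b, b+1)` by `(a-1, b)` and
#' `(a, b+1)`. This reverses the path segment between `a` and `b`, creating
#' one crossing in the loop's bond graph while keeping the chain's spring
#' graph a single path over all its monomers.
#'
#' @param springs integer spring matrix (bonds x 2).
#' @param a,b the bond pair.
#' @return Rewired spring matrix.
#' @export
crossing_rewire <- function(springs, a, b) {
  if (a >= b) stop("rewire requires a < b")
  i1 <- find_spring(springs, a - 1L, a)
  i2 <- find_spring(springs, b, b + 1L)
  if (is.na(i1) || is.na(i2))
    stop("cannot rewire at (", a, ", ", b, "): flanking spring missing ",
         "(chain boundary)")
  springs[i1, ] <- c(a - 1L, b)
  springs[i2, ] <- c(a, b + 1L)
  springs
}

# deterministic kinetic-temperature rescale to kT (initializer use only)
rescale_velocities <- function(state, params) {
  ntot <- nrow(state$mono_pos) + nrow(state$cond_pos)
  ke <- 0.5 * params$mass * (sum(state$mono_vel^2) + sum(state$cond_vel^2))
  t_inst <- 2 * ke / (3 * ntot)
  if (t_inst > 0) {
    fac <- sqrt(params$kT / t_inst)
    state$mono_vel <- state$mono_vel * fac
    state$cond_vel <- state$cond_vel * fac
  }
  state
}

find_spring <- function(springs, i, j) {
  hit <- which((springs[, 1] == i & springs[, 2] == j) |
               (springs[, 1] == j & springs[, 2] == i))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# consecutive springs for block-wise chains
consecutive_springs <- function(params) {
  do.call(rbind, lapply(seq_len(params$n_chains), function(ch) {
    off <- (ch - 1L) * params$N
    cbind(off + seq_len(params$N - 1L), off + 2:params$N)
  }))
}

#' Deterministic loop extrusion with crossings
#'
#' Installs `M` consecutive loops of length `L` per chain. Each condensin
#' starts with both bonds on the monomer at the middle of its future loop
#' (`(i - 0.5) L`, rounded down for odd `L`); the two bonds then advance
#' symmetrically, one monomer per extrusion round on each side (clamping at
#' the terminal anchors), with `md_steps_per_advance` thermostatted MD
#' steps between rounds so the springs relax. Each time the extruded loop
#' (monomer count between the bonds, inclusive) reaches a further multiple
#' of `L / Cr`, one [crossing_rewire()] is applied at the pre-advance bond
#' pair; on the clamped side the pair is pulled in by one monomer when
#' needed so a rewire never touches the spring joining two loops —
#' consecutive loop bases must stay adjacent. Extrusion ends with
#' condensin `i` anchored at
#' monomers `(i-1) L + 1` and `i L` (1-based) and exactly `Cr` crossings in
#' every loop.
#'
#' A rewire reconnects a stiff chain spring across a finite gap, injecting
#' elastic energy impulsively. The relaxation between rounds therefore runs
#' at a tenth of the production timestep and the kinetic temperature is
#' rescaled back to `kT` after every round, so extrusion stays quasi-static
#' and the emerging configuration is thermal rather than shock-heated.
#'
#' @param state a [chromo_state()] without condensins.
#' @param params a [sim_params()]; requires `L` divisible by `Cr` and
#'   `L >= 2 Cr` so crossings are at least one round apart.
#' @param md_steps_per_advance MD relaxation steps (at `dt / 10`) between
#'   bond advances.
#' @return List with the final `state` (condensins added) and `topology`.
#' @export
extrude_loops <- function(state, params, md_steps_per_advance = 100L) {
  L <- params$L; M <- params$M; Cr <- params$Cr
  if (Cr > 0 && L %% Cr != 0)
    stop("configuration error: loop length L = ", L,
         " not divisible by Cr = ", Cr)
  if (Cr > 0 && L < 2 * Cr)
    stop("configuration error: need L >= 2 Cr so crossings are one round apart")
  springs <- consecutive_springs(params)
  nch <- params$n_chains

  # local (0-based within chain) start monomer of loop i: floor((i - 0.5) L)
  start_local <- floor((seq_len(M) - 0.5) * L)
  lo_local <- (seq_len(M) - 1L) * L          # terminal anchors, 0-based
  hi_local <- seq_len(M) * L - 1L

  m_tot <- nch * M
  cond_pos <- matrix(0, m_tot, 3)
  cond_chain <- integer(m_tot)
  a <- b <- integer(m_tot)                    # current bonds, global 1-based
  lo <- hi <- integer(m_tot)
  for (ch in seq_len(nch)) {
    off <- (ch - 1L) * params$N
    idx <- (ch - 1L) * M + seq_len(M)
    a[idx] <- b[idx] <- off + start_local + 1L
    lo[idx] <- off + lo_local + 1L
    hi[idx] <- off + hi_local + 1L
    cond_chain[idx] <- ch
    cond_pos[idx, ] <- state$mono_pos[a[idx], , drop = FALSE]
  }
  st <- state
  st$cond_pos <- cond_pos
  st$cond_vel <- matrix(0, m_tot, 3)
  st$cond_chain <- cond_chain

  next_k <- rep(1L, m_tot)                    # next crossing index per loop
  log_rows <- list()
  n_rounds <- max(start_local - lo_local)
  for (round in seq_len(n_rounds)) {
    na <- pmax(a - 1L, lo)
    nb <- pmin(b + 1L, hi)
    if (Cr > 0) {
      count_new <- nb - na + 1L
      due <- which(next_k <= Cr & count_new >= next_k * (L %/% Cr))
      for (k in due) {
        aa <- a[k]; bb <- b[k]
        # keep the rewire inside the loop: never touch the inter-loop
        # spring (hi, hi+1), which keeps consecutive loop bases adjacent
        if (bb >= hi[k]) bb <- hi[k] - 1L
        springs <- crossing_rewire(springs, aa, bb)
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(chain = cond_chain[k],
                     loop = (k - 1L) %% M + 1L, a = aa, b = bb)
        next_k[k] <- next_k[k] + 1L
      }
    }
    a <- na; b <- nb
    topo <- chromo_topology(springs, cbind(a, b))
    pe <- params
    pe$dt <- params$dt / 10
    st <- langevin_step(st, topo, pe, n_steps = md_steps_per_advance)
    st <- rescale_velocities(st, params)
  }
  crossings <- if (length(log_rows)) do.call(rbind, log_rows) else NULL
  topology <- chromo_topology(springs, cbind(a, b), crossings)
  list(state = st, topology = topology)
}

#' Build an initial configuration
#'
#' The full initialization pipeline: ideal-coil chains, compaction into the
#' density-matched spherical shell with equilibration, release of the
#' confinement during extrusion, then deterministic loop extrusion with
#' crossings, and a short reduced-timestep anneal run with the confinement
#' re-applied. The anneal lets monomer pairs left deep inside the
#' flat-capped WCA core, and the elastic energy stored by crossing
#' rewires, relax gently: handed straight to the production timestep they
#' can ignite a self-sustaining hot state. Re-applying the wall during
#' this numerical stage keeps the physical post-release expansion out of
#' the initialization, so the report describes the system at the moment of
#' release. The
#' returned report records, per chain, the radius of gyration and
#' asphericity, and for multi-chain systems the overlap, all measured
#' immediately after extrusion completes (the report's `time` field records
#' when).
#'
#' @param params a [sim_params()].
#' @param seed RNG seed; the build is fully deterministic given
#'   `(params, seed)`.
#' @param compact_steps steps of the compaction + in-shell equilibration
#'   stage.
#' @param warmup_steps reduced-timestep warmup steps, see
#'   [compact_into_shell()].
#' @param md_steps_per_advance extrusion pacing, see [extrude_loops()].
#' @param anneal_steps reduced-timestep anneal steps after extrusion.
#' @return Object of class `chromo_system`: list with `state`, `topology`,
#'   `params`, `report`, and `seed`.
#' @export
build_initial <- function(params, seed = 1L, compact_steps = 10000L,
                          warmup_steps = 5000L,
                          md_steps_per_advance = 100L,
                          anneal_steps = 5000L) {
  set.seed(seed)
  R <- shell_radius(params)
  pos <- do.call(rbind, lapply(seq_len(params$n_chains),
                               function(ch) confined_random_walk(params$N, R, params$d_B)))
  mono_chain <- rep(seq_len(params$n_chains), each = params$N)
  vel <- matrix(rnorm(length(pos), sd = sqrt(params$kT / params$mass)),
                ncol = 3)
  st <- chromo_state(pos, mono_chain, mono_vel = vel)
  topo0 <- chromo_topology(consecutive_springs(params))
  st <- compact_into_shell(st, topo0, params, n_steps = compact_steps,
                           warmup_steps = warmup_steps)
  ext <- extrude_loops(st, params, md_steps_per_advance = md_steps_per_advance)
  st <- ext$state
  if (anneal_steps > 0L) {
    # anneal under the confining wall so stored elastic energy drains
    # without conflating initialization with the physical post-release
    # expansion; the report below is the state at the moment of release
    pa <- params
    pa$dt <- params$dt / 10
    st <- langevin_step(st, ext$topology, pa, n_steps = anneal_steps,
                        wall = list(R = shell_radius(params),
                                    k = params$eps_cut, fmax = Inf))
    st <- rescale_velocities(st, params)
  }
  sys <- list(state = st, topology = ext$topology, params = params,
              report = initial_report(st, params), seed = seed)
  class(sys) <- "chromo_system"
  sys
}

initial_report <- function(state, params) {
  rg <- asph <- numeric(params$n_chains)
  for (ch in seq_len(params$n_chains)) {
    pos <- state$mono_pos[state$mono_chain == ch, , drop = FALSE]
    gt <- gyration_tensor(pos)
    rg[ch] <- gt$rg
    asph[ch] <- asphericity(gt$lambda2)
  }
  ov <- if (params$n_chains >= 2L)
    overlap(state$mono_pos[state$mono_chain == 1L, , drop = FALSE],
            state$mono_pos[state$mono_chain == 2L, , drop = FALSE],
            params$L)$overlap
  else NA_real_
  list(rg = rg, asphericity = asph, overlap = ov, time = state$time)
}

#' @export
print.chromo_system <- function(x, ...) {
  p <- x$params
  cat(sprintf("chromo_system: %d chain(s) x %d monomers, %d loops of %d (Cr = %d), seed %d\n",
              p$n_chains, p$N, p$M, p$L, p$Cr, x$seed))
  cat(sprintf("  initial report (t = %g): Rg = %s, asphericity = %s",
              x$report$time,
              paste(sprintf("%.2f", x$report$rg), collapse = "/"),
              paste(sprintf("%.3f", x$report$asphericity), collapse = "/")))
  if (!is.na(x$report$overlap))
    cat(sprintf(", overlap = %.3f", x$report$overlap))
  cat("\n")
  invisible(x)
}

#' @export
summary.chromo_system <- function(object, ...) {
  p <- object$params
  cat("Initial configuration summary\n")
  print(p)
  rep <- object$report
  cat(sprintf("  measured at t = %g\n", rep$time))
  for (ch in seq_len(p$n_chains))
    cat(sprintf("  chain %d: Rg = %.3f, asphericity = %.4f\n",
                ch, rep$rg[ch], rep$asphericity[ch]))
  if (!is.na(rep$overlap))
    cat(sprintf("  overlap (chains 1-2): %.4f\n", rep$overlap))
  nloops <- p$n_chains * p$M
  cat(sprintf("  topology: %d springs, %d loops, %d crossings installed\n",
              nrow(object$topology$springs), nloops,
              nrow(object$topology$crossings)))
  invisible(object)
}
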