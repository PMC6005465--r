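#' Integration schedule
#'
#' @param n_steps number of timesteps to take.
#' @param dt timestep.
#' @param sample_every observable sampling interval in time units; must be a
#'   positive multiple of `dt` (rounded to the nearest step count).
#' @param seed optional RNG seed applied at the start of a run; recorded in
#'   the returned series so every trajectory is regenerable.
#' @return Object of class `sim_schedule`.
#' @export
sim_schedule <- function(n_steps, dt = 0.01, sample_every = 100 * dt,
                         seed = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (sample_every <= 0) stop("sample_every must be > 0")
  chunk <- max(1L, as.integer(round(sample_every / dt)))
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 sample_every = chunk * dt, chunk = chunk, seed = seed),
            class = "sim_schedule")
}

#' Advance the system by Langevin-thermostatted velocity Verlet
#'
#' Integrates the equations of motion with the Gronbech-Jensen/Farago
#' discretization of Langevin dynamics: a velocity-Verlet step with friction
#' `gamma` and Gaussian noise satisfying fluctuation-dissipation at `kT`.
#' At `gamma = 0` the scheme reduces exactly to plain (microcanonical)
#' velocity Verlet and no noise is drawn. Noise comes from the R RNG, so a
#' run is bit-reproducible after `set.seed()`.
#'
#' @param state a [chromo_state()].
#' @param topology a [chromo_topology()].
#' @param params a [sim_params()].
#' @param n_steps number of steps to take (default 1).
#' @param wall optional confining shell, a list with `R` (radius), `k`
#'   (stiffness) and `fmax` (force clamp); used by the compaction stage.
#' @return The advanced `chromo_state`, with attributes `epot` (final
#'   potential energy) and `ke_half_mean` (run-averaged kinetic energy from
#'   half-step velocities, the estimator whose stationary average is exact
#'   for harmonic forces at any stable `dt`).
#' @export
langevin_step <- function(state, topology, params, n_steps = 1L,
                          wall = NULL) {
  check_sizes(state, topology, params = NULL)
  pot <- if (is.null(wall)) cpp_pot(params)
         else cpp_pot(params, wall_R = wall$R, wall_k = wall$k,
                      wall_fmax = wall$fmax %||% Inf)
  out <- cpp_run(state$mono_pos, state$mono_vel,
                 state$cond_pos, state$cond_vel,
                 topology$springs - 1L, topology$anchors - 1L, pot,
                 as.integer(n_steps), params$dt, params$gamma, params$kT,
                 params$mass, as.integer(round(state$time / params$dt)))
  st <- state
  st$mono_pos <- out$mono_pos; st$mono_vel <- out$mono_vel
  st$cond_pos <- out$cond_pos; st$cond_vel <- out$cond_vel
  st$time <- state$time + n_steps * params$dt
  attr(st, "epot") <- out$epot
  attr(st, "ke_half_mean") <- out$ke_half_mean
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run dynamics with observable sampling
#'
#' Advances the system for `schedule$n_steps` steps, invoking each observer
#' every `schedule$sample_every` time units (including at the initial
#' state). Observers are functions `f(state, topology, params)` returning a
#' named numeric vector; their outputs are assembled into a time-stamped
#' series.
#'
#' @inheritParams langevin_step
#' @param schedule a [sim_schedule()].
#' @param observers named list of observer functions.
#' @return List with `state` (final [chromo_state()]) and `series` (a
#'   data frame of class `observable_series`: column `time` plus one column
#'   per observer output, timestamps strictly increasing).
#' @export
run_dynamics <- function(state, topology, params, schedule,
                         observers = list(), wall = NULL) {
  stopifnot(inherits(schedule, "sim_schedule"))
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  sample_obs <- function(st) {
    vals <- unlist(lapply(names(observers), function(nm) {
      v <- tryCatch(observers[[nm]](st, topology, params),
                    error = function(e) stop("observer '", nm, "' failed at t = ",
                                             st$time, ": ", conditionMessage(e)))
      if (is.null(names(v)) && length(v) == 1L) names(v) <- nm
      v
    }))
    c(time = st$time, vals)
  }
  rows <- list(sample_obs(state))
  steps_left <- schedule$n_steps
  while (steps_left > 0L) {
    take <- min(schedule$chunk, steps_left)
    state <- langevin_step(state, topology, params, n_steps = take,
                           wall = wall)
    steps_left <- steps_left - take
    if (take == schedule$chunk) rows[[length(rows) + 1L]] <- sample_obs(state)
  }
  series <- as.data.frame(do.call(rbind, rows))
  class(series) <- c("observable_series", "data.frame")
  list(state = state, series = series)
}

#' @export
print.observable_series <- function(x, ...) {
  cat(sprintf("observable_series: %d samples, t in [%g, %g]\n",
              nrow(x), min(x$time), max(x$time)))
  cat("  columns:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Standard observer set for shaping/segregation runs
#'
#' Builds observers recording, per sample: asphericity and radius of
#' gyration of each chain, and for multi-chain systems the loop-sphere
#' overlap of the first chain pair plus the trans-/cis-attraction
#' fractions.
#'
#' @param params a [sim_params()].
#' @return Named list of observer functions for [run_dynamics()].
#' @export
standard_observers <- function(params) {
  obs <- list(
    shape = function(st, tp, pp) {
      vals <- c()
      for (ch in seq_len(pp$n_chains)) {
        pos <- st$mono_pos[st$mono_chain == ch, , drop = FALSE]
        gt <- gyration_tensor(pos)
        vals <- c(vals, setNames(c(asphericity(gt$lambda2), gt$rg),
                                 paste0(c("asphericity", "rg"), ch)))
      }
      vals
    })
  if (params$n_chains >= 2L) {
    obs$segregation <- function(st, tp, pp) {
      ov <- overlap(st$mono_pos[st$mono_chain == 1L, , drop = FALSE],
                    st$mono_pos[st$mono_chain == 2L, , drop = FALSE],
                    pp$L)
      at <- attraction_fractions(st$cond_pos, st$cond_chain, pp$Delta)
      c(overlap = ov$overlap, trans = at$trans, cis = at$cis)
    }
  }
  obs
}
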