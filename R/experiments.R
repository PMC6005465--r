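#' Experiment configuration
#'
#' Bundles everything needed to reproduce an experiment: mode, model
#' parameters, schedule, replication, and optional parameter grids.
#'
#' @param mode one of `"init_only"` (build initial configurations and
#'   report their statistics), `"equilibrium_shape"` (single- or
#'   multi-chain production run, equilibrium asphericity/Rg),
#'   `"segregation"` (two-chain production run, overlap/trans decay and
#'   segregation metrics), `"axis_density"` (production run plus the
#'   condensin-axis radial density profile).
#' @param params a [sim_params()].
#' @param production_time production run length in time units (ignored by
#'   `init_only`).
#' @param sample_every observable sampling interval in time units.
#' @param n_replicates independent replicate runs (default 5; headline
#'   observables are replicate means).
#' @param seed master seed; replicate `r` uses `seed + 7919 * (r - 1)`.
#' @param sweep optional named list of grids over `F_cond`, `Delta`,
#'   `F_loop` for [sweep_experiment()].
#' @param compact_steps,md_steps_per_advance initializer controls, see
#'   [build_initial()].
#' @param equilibrium_fraction fraction of the series tail averaged for
#'   equilibrium values (default last half).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("init_only", "equilibrium_shape",
                                       "segregation", "axis_density"),
                              params = sim_params(),
                              production_time = if (match.arg(mode) == "segregation") 10000 else 2000,
                              sample_every = 10,
                              n_replicates = 5L, seed = 1L, sweep = NULL,
                              compact_steps = 10000L,
                              md_steps_per_advance = 100L,
                              equilibrium_fraction = 0.5) {
  mode <- match.arg(mode)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (mode == "segregation" && params$n_chains < 2)
    stop("segregation mode needs at least two chains")
  if (!is.null(sweep)) {
    bad <- setdiff(names(sweep), c("F_cond", "Delta", "F_loop"))
    if (length(bad)) stop("unknown sweep dimension(s): ", paste(bad, collapse = ", "))
    if (any(lengths(sweep) == 0)) stop("sweep grids must be non-empty")
  }
  structure(list(mode = mode, params = params,
                 production_time = production_time,
                 sample_every = sample_every,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), sweep = sweep,
                 compact_steps = as.integer(compact_steps),
                 md_steps_per_advance = as.integer(md_steps_per_advance),
                 equilibrium_fraction = equilibrium_fraction),
            class = "experiment_config")
}

replicate_seed <- function(master, r) as.integer(master + 7919L * (r - 1L))

#' Run one experiment
#'
#' Per replicate: build the initial configuration from the replicate seed,
#' run production dynamics with the standard observers, and compute the
#' mode's summary observables. Replicates that fail are recorded and the
#' aggregate is formed from the successes. Aggregates are means over
#' replicates (over uncensored replicates for segregation times/speeds,
#' with the count reported).
#'
#' @param config an [experiment_config()].
#' @param keep_series keep the full observable series of each replicate.
#' @return Object of class `experiment_result`: list with `per_replicate`
#'   (data frame), `aggregate` (named list), `series` (if kept), `config`.
#' @export
run_experiment <- function(config, keep_series = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  p <- config$params
  rows <- list(); all_series <- list(); profiles <- list()
  for (r in seq_len(config$n_replicates)) {
    seed_r <- replicate_seed(config$seed, r)
    res <- tryCatch(run_one_replicate(config, seed_r, keep_series),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("replicate ", r, " failed: ", conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <- cbind(replicate = r, seed = seed_r, res$row)
    if (keep_series && !is.null(res$series))
      all_series[[length(all_series) + 1L]] <- res$series
    if (!is.null(res$profile)) profiles[[length(profiles) + 1L]] <- res$profile
  }
  if (length(rows) == 0) stop("all replicates failed")
  per <- do.call(rbind, rows)
  out <- list(per_replicate = per, aggregate = aggregate_result(per),
              series = if (keep_series) all_series else NULL,
              profiles = if (length(profiles)) profiles else NULL,
              config = config)
  class(out) <- "experiment_result"
  out
}

run_one_replicate <- function(config, seed_r, keep_series) {
  p <- config$params
  sys <- build_initial(p, seed = seed_r,
                       compact_steps = config$compact_steps,
                       md_steps_per_advance = config$md_steps_per_advance)
  rep0 <- sys$report
  row <- data.frame(init_rg = mean(rep0$rg),
                    init_asphericity = mean(rep0$asphericity),
                    init_overlap = rep0$overlap)
  if (config$mode == "init_only")
    return(list(row = row, series = NULL, profile = NULL))

  n_steps <- as.integer(round(config$production_time / p$dt))
  sched <- sim_schedule(n_steps, dt = p$dt, sample_every = config$sample_every)
  run <- run_dynamics(sys$state, sys$topology, p, sched,
                      observers = standard_observers(p))
  ser <- run$series
  tail_idx <- ser$time >= max(ser$time) * (1 - config$equilibrium_fraction)
  row$equilibrium_asphericity <- mean(ser$asphericity1[tail_idx])
  row$equilibrium_rg <- mean(ser$rg1[tail_idx])
  profile <- NULL
  if (config$mode == "segregation") {
    sm <- segregation_metrics(ser$time, ser$overlap, ser$trans)
    row <- cbind(row, as.data.frame(sm))
  }
  if (config$mode == "axis_density") {
    cp <- run$state$cond_pos[run$state$cond_chain == 1L, , drop = FALSE]
    profile <- axis_density(cp)
  }
  list(row = row, series = if (keep_series) ser else NULL, profile = profile)
}

aggregate_result <- function(per) {
  agg <- list(n_replicates = nrow(per))
  num <- setdiff(names(per)[vapply(per, is.numeric, TRUE)],
                 c("replicate", "seed"))
  for (nm in num) agg[[nm]] <- mean(per[[nm]], na.rm = TRUE)
  if ("segregation_censored" %in% names(per)) {
    ok <- !per$segregation_censored
    agg$n_uncensored <- sum(ok)
    agg$segregation_time <- if (any(ok)) mean(per$segregation_time[ok]) else NA_real_
    # censored replicates contribute speed 0, never a finite fake speed
    agg$segregation_speed <- mean(ifelse(ok, per$segregation_speed, 0))
    okt <- !per$trans_censored
    agg$trans_decay_time <- if (any(okt)) mean(per$trans_decay_time[okt]) else NA_real_
    agg$trans_decay_speed <- mean(ifelse(okt, per$trans_decay_speed, 0))
  }
  agg
}

#' @export
print.experiment_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("experiment_result: mode = %s, %d replicate(s), master seed %d\n",
              cfg$mode, nrow(x$per_replicate), cfg$seed))
  a <- x$aggregate
  nm <- setdiff(names(a), "n_replicates")
  for (k in nm)
    if (is.numeric(a[[k]]) && length(a[[k]]) == 1L)
      cat(sprintf("  %-24s %s\n", k,
                  if (is.na(a[[k]])) "NA (censored)" else format(signif(a[[k]], 5))))
  invisible(x)
}

#' Parameter sweep
#'
#' Runs [run_experiment()] at every point of the grid in
#' `config$sweep` (cartesian product over `F_cond`, `Delta`, `F_loop`) and
#' assembles the shape-segregation correlation table. Each row is labelled
#' by the attraction-range branch (`Delta < 2.5` vs `>= 2.5`), the split at
#' which the shape-segregation correlation bifurcates.
#'
#' @param config an [experiment_config()] with a non-`NULL` `sweep`.
#' @return Data frame with one row per grid point: the parameter values,
#'   equilibrium asphericity, segregation metrics where applicable, and
#'   `branch`.
#' @export
sweep_experiment <- function(config) {
  if (is.null(config$sweep)) stop("config has no sweep grids")
  grid <- expand.grid(F_cond = config$sweep$F_cond %||% config$params$F_cond,
                      Delta = config$sweep$Delta %||% config$params$Delta,
                      F_loop = config$sweep$F_loop %||% config$params$F_loop)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- config$params
    p$F_cond <- grid$F_cond[g]; p$Delta <- grid$Delta[g]
    p$F_loop <- grid$F_loop[g]
    cfg <- config
    cfg$params <- p
    cfg$sweep <- NULL
    res <- run_experiment(cfg)
    a <- res$aggregate
    row <- data.frame(F_cond = p$F_cond, Delta = p$Delta, F_loop = p$F_loop,
                      asphericity = a$equilibrium_asphericity %||% a$init_asphericity,
                      rg = a$equilibrium_rg %||% a$init_rg)
    if (!is.null(a$segregation_speed)) {
      row$segregation_speed <- a$segregation_speed
      row$n_uncensored <- a$n_uncensored
    }
    row$branch <- if (p$Delta < 2.5) "low" else "high"
    rows[[g]] <- row
  }
  do.call(rbind, rows)
}

#' Fixture registry
#'
#' Deterministic miniature configurations for testing and desk-scale
#' studies, with precomputed topology facts. Shell radii are rescaled
#' as `22.85 * (N / 5000)^(1/3)` so the initial chromatin density matches
#' the reference system at every size.
#'
#' Names: `"tiny"` (1 chain, N = 60, M = 3, Cr = 1), `"tiny2"` (two-chain
#' tiny), `"small"` (2 chains, N = 500, M = 10, Cr = 5), `"reference"`
#' (2 chains, N = 5000, M = 100, Cr = 5, the full-scale study system).
#'
#' @param name registry key.
#' @param n_chains optional override of the chain count.
#' @return List with `params` (a [sim_params()]) and `expected`: per-chain
#'   1-based `anchors` matrix, `crossings_per_loop`, and `n_loops`.
#' @export
make_fixture <- function(name, n_chains = NULL) {
  registry <- list(
    tiny = list(n_chains = 1L, N = 60L, M = 3L, Cr = 1L),
    tiny2 = list(n_chains = 2L, N = 60L, M = 3L, Cr = 1L),
    small = list(n_chains = 2L, N = 500L, M = 10L, Cr = 5L),
    reference = list(n_chains = 2L, N = 5000L, M = 100L, Cr = 5L))
  if (!name %in% names(registry))
    stop("unknown fixture '", name, "'; registry: ",
         paste(names(registry), collapse = ", "))
  entry <- registry[[name]]
  if (!is.null(n_chains)) entry$n_chains <- as.integer(n_chains)
  params <- sim_params(n_chains = entry$n_chains, N = entry$N, M = entry$M,
                       Cr = entry$Cr,
                       shell_D1 = 22.85 * (entry$N / 5000)^(1 / 3))
  L <- params$L
  anchors <- cbind((seq_len(params$M) - 1L) * L + 1L, seq_len(params$M) * L)
  list(params = params,
       expected = list(anchors = anchors,
                       crossings_per_loop = params$Cr,
                       n_loops = params$M * params$n_chains))
}
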