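#' Simulation parameters
#'
#' Collects every physical and numerical constant of the model. Energies are
#' in units of the thermal energy kT, lengths in units of the monomer
#' diameter `sigma`, and time in units of `sigma * sqrt(mass / kT)` with
#' friction `gamma = 1`.
#'
#' @param n_chains number of chromosome chains.
#' @param N monomers per chain. Must be an exact multiple of `M`.
#' @param M condensins (loops) per chain; the loop length is `L = N / M`.
#' @param Cr crossings installed per loop by the extrusion initializer.
#' @param F_cond strength of the finite-range inter-condensin attraction
#'   (kT per sigma squared); the attraction well depth for a pair at
#'   contact is `F_cond * Delta^2` kT, which spans inert (below 1 kT at
#'   `Delta < 1`) to irreversibly aggregating (tens of kT at `Delta > 3`).
#' @param Delta threshold distance of the attraction (units of `sigma`);
#'   pairs farther apart than `Delta` do not interact.
#' @param F_loop strength of the harmonic loop-holding bond between a
#'   condensin and its two base-point monomers (kT per sigma squared).
#' @param sigma monomer diameter (length unit).
#' @param d_B natural length of the chain springs.
#' @param eps WCA contact energy: the pair energy at `(r = sigma)`.
#' @param eps_cut cap on the WCA pair energy, avoiding numerical blow-up at
#'   strong overlaps.
#' @param eps_spr spring coefficient of the chain springs; defaults to
#'   `eps_cut`.
#' @param mass particle mass (monomers and condensins alike).
#' @param gamma Langevin friction coefficient.
#' @param kT thermal energy (energy unit).
#' @param dt integrator timestep.
#' @param shell_D1 diameter of the spherical shell used to compact a single
#'   chain before loop extrusion; for `n` chains the shell diameter is
#'   `shell_D1 * n^(1/3)` (constant per-chain volume). The default 22.85
#'   reproduces the nuclear chromatin density for the reference chain of
#'   5000 monomers; see [make_fixture()] for density-preserving rescaling
#'   at other chain lengths.
#' @param wca_cap how the energy cap is realized: `"flat"` clamps the pair
#'   energy at `eps_cut` with zero force inside the cap radius; `"force"`
#'   continues linearly with the constant force attained at the cap radius.
#'
#' @return An object of class `sim_params` (a named list, with the derived
#'   loop length `L` included).
#' @examples
#' p <- sim_params(n_chains = 1, N = 60, M = 3, Cr = 1)
#' p$L
#' @export
sim_params <- function(n_chains = 2, N = 5000, M = 100, Cr = 5,
                       F_cond = 1, Delta = 1, F_loop = 1,
                       sigma = 1, d_B = 1, eps = 1, eps_cut = 1000,
                       eps_spr = eps_cut, mass = 1, gamma = 1, kT = 1,
                       dt = 0.01, shell_D1 = 22.85,
                       wca_cap = c("flat", "force")) {
  wca_cap <- match.arg(wca_cap)
  p <- list(n_chains = as.integer(n_chains), N = as.integer(N),
            M = as.integer(M), Cr = as.integer(Cr),
            F_cond = F_cond, Delta = Delta, F_loop = F_loop,
            sigma = sigma, d_B = d_B, eps = eps, eps_cut = eps_cut,
            eps_spr = eps_spr, mass = mass, gamma = gamma, kT = kT,
            dt = dt, shell_D1 = shell_D1, wca_cap = wca_cap)
  if (p$n_chains < 1) stop("n_chains must be >= 1")
  if (p$N < 2) stop("N must be >= 2")
  if (p$M < 1) stop("M must be >= 1")
  if (p$N %% p$M != 0L)
    stop("N (", p$N, ") must be an exact multiple of M (", p$M,
         "): loops partition the chain")
  p$L <- p$N %/% p$M
  if (p$Cr < 0) stop("Cr must be >= 0")
  for (nm in c("sigma", "d_B", "mass", "kT", "dt"))
    if (p[[nm]] <= 0) stop(nm, " must be > 0")
  if (p$gamma < 0) stop("gamma must be >= 0")
  for (nm in c("F_loop", "F_cond", "Delta"))
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  if (p$eps < 0 || p$eps_cut <= 0 || p$eps_spr < 0)
    stop("eps must be >= 0; eps_cut > 0; eps_spr >= 0")
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (condensim)\n")
  cat(sprintf("  system : %d chain(s) x %d monomers, %d loops of %d (Cr = %d)\n",
              x$n_chains, x$N, x$M, x$L, x$Cr))
  cat(sprintf("  condensin : F_cond = %g, Delta = %g, F_loop = %g\n",
              x$F_cond, x$Delta, x$F_loop))
  cat(sprintf("  chain : sigma = %g, d_B = %g, eps = %g, eps_cut = %g (%s cap), eps_spr = %g\n",
              x$sigma, x$d_B, x$eps, x$eps_cut, x$wca_cap, x$eps_spr))
  cat(sprintf("  dynamics : mass = %g, gamma = %g, kT = %g, dt = %g\n",
              x$mass, x$gamma, x$kT, x$dt))
  invisible(x)
}

# Parameter list consumed by the C++ core. The confining wall is a stage
# property (compaction only), not a model parameter, so it is spliced in
# here.
cpp_pot <- function(params, wall_R = -1, wall_k = params$eps_cut,
                    wall_fmax = Inf) {
  list(sigma = params$sigma, eps = params$eps, eps_cut = params$eps_cut,
       eps_spr = params$eps_spr, d_B = params$d_B,
       F_loop = params$F_loop, F_cond = params$F_cond, Delta = params$Delta,
       cap_force = if (identical(params$wca_cap, "force")) 1L else 0L,
       wall_R = wall_R, wall_k = wall_k,
       wall_fmax = if (is.finite(wall_fmax)) wall_fmax else 1e30)
}
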