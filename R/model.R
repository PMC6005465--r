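#' WCA excluded-volume potential with energy cap
#'
#' Purely repulsive truncated-and-shifted Lennard-Jones (Weeks-Chandler-
#' Andersen) pair potential between chromatin monomers:
#' `U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6 + 1/4)` for `(r < 2^(1/6) sigma)`
#' and 0 beyond. To keep strong overlaps integrable the energy is capped at
#' `eps_cut`: below the cap radius `r_cap` (where the unclamped energy first
#' reaches `eps_cut`) the energy is held flat at `eps_cut` with zero force
#' (`cap = "flat"`), or continued linearly with the constant force attained
#' at `r_cap` (`cap = "force"`).
#'
#' @param r center-to-center distance(s); must be > 0.
#' @param eps contact energy (energy at `(r = sigma)`).
#' @param sigma monomer diameter.
#' @param eps_cut energy cap.
#' @param cap `"flat"` or `"force"`; see above.
#' @return A list with numeric vectors `energy` and `force`; `force` is
#'   `-dU/dr` (positive = repulsive).
#' @examples
#' wca_energy_force(1)$energy        # contact energy: 1 kT
#' wca_energy_force(2^(1/6))$energy  # cutoff: 0
#' @export
wca_energy_force <- function(r, eps = 1, sigma = 1, eps_cut = 1000,
                             cap = c("flat", "force")) {
  cap <- match.arg(cap)
  if (any(r <= 0)) stop("invalid geometry: WCA distance must be > 0")
  rc <- wca_cap_radius(eps, sigma, eps_cut)
  cut <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  u <- 4 * eps * (s6^2 - s6 + 0.25)
  f <- 24 * eps * (2 * s6^2 - s6) / r
  u[r >= cut] <- 0
  f[r >= cut] <- 0
  inside <- r < rc
  if (cap == "flat") {
    u[inside] <- eps_cut
    f[inside] <- 0
  } else {
    fc <- wca_cap_force(eps, sigma, eps_cut)
    u[inside] <- eps_cut + fc * (rc - r[inside])
    f[inside] <- fc
  }
  list(energy = u, force = f)
}

#' Cap radius of the capped WCA potential
#'
#' The distance below which the unclamped WCA energy exceeds `eps_cut`.
#' Solving `4 eps (x^2 - x + 1/4) = eps_cut` for `x = (sigma/r)^6` gives
#' `x = (1 + sqrt(eps_cut/eps)) / 2`, hence `r_cap = sigma * x^(-1/6)`.
#'
#' @inheritParams wca_energy_force
#' @return The cap radius (same length unit as `sigma`).
#' @export
wca_cap_radius <- function(eps = 1, sigma = 1, eps_cut = 1000) {
  if (eps <= 0) return(0)
  x <- (1 + sqrt(eps_cut / eps)) / 2
  sigma * x^(-1 / 6)
}

# magnitude of the WCA force at the cap radius (used by cap = "force")
wca_cap_force <- function(eps = 1, sigma = 1, eps_cut = 1000) {
  rc <- wca_cap_radius(eps, sigma, eps_cut)
  s6 <- (sigma / rc)^6
  24 * eps * (2 * s6^2 - s6) / rc
}

#' Harmonic chain-spring potential
#'
#' `U(r) = (eps_spr / 2) (r - d_B)^2` between bonded neighbours. Springs are
#' phantom: they carry no excluded volume of their own, so spring-spring and
#' spring-monomer crossings are unimpeded (a proxy for topoisomerase II
#' strand passage); monomer-monomer excluded volume still applies.
#'
#' @param r bonded distance(s), >= 0.
#' @param eps_spr spring coefficient.
#' @param d_B natural length.
#' @return List with `energy` and `force` (magnitude of the restoring force,
#'   `eps_spr * |r - d_B|`).
#' @export
spring_energy_force <- function(r, eps_spr = 1000, d_B = 1) {
  if (any(r < 0)) stop("spring distance must be >= 0")
  list(energy = 0.5 * eps_spr * (r - d_B)^2,
       force = eps_spr * abs(r - d_B))
}

#' Loop-holding potential of one condensin
#'
#' A condensin is tethered to its two base-point monomers by harmonic
#' springs of zero natural length:
#' `U = (F_loop / 2) (|r - a1|^2 + |r - a2|^2)`.
#'
#' @param cond_pos condensin position (length-3 numeric).
#' @param anchor1,anchor2 base-point monomer positions (length-3 numerics).
#' @param F_loop loop-holding strength.
#' @return List with `energy`, `f_cond` (net force on the condensin), and
#'   `f_anchor1`, `f_anchor2` (forces on the two monomers). Action-reaction
#'   holds pairwise.
#' @export
loop_energy_force <- function(cond_pos, anchor1, anchor2, F_loop = 1) {
  d1 <- cond_pos - anchor1
  d2 <- cond_pos - anchor2
  list(energy = 0.5 * F_loop * (sum(d1^2) + sum(d2^2)),
       f_cond = -F_loop * (d1 + d2),
       f_anchor1 = F_loop * d1,
       f_anchor2 = F_loop * d2)
}

#' Finite-range inter-condensin attraction
#'
#' `U(r) = -F_cond (r - Delta)^2` for `(r < Delta)` and 0 at or beyond
#' `Delta`. The potential acts between *all* condensin pairs within the
#' threshold, on the same chromosome (cis) and across chromosomes (trans)
#' alike. The resulting radial force is attractive with magnitude
#' `2 F_cond (Delta - r)`, continuous (zero) at the threshold.
#'
#' @param r condensin pair distance(s), >= 0.
#' @param F_cond attraction strength.
#' @param Delta threshold distance.
#' @return List with `energy` (<= 0) and `force` (attractive magnitude,
#'   >= 0).
#' @export
attraction_energy_force <- function(r, F_cond = 1, Delta = 1) {
  if (any(r < 0)) stop("distance must be >= 0")
  inside <- r < Delta
  u <- ifelse(inside, -F_cond * (r - Delta)^2, 0)
  f <- ifelse(inside, 2 * F_cond * (Delta - r), 0)
  list(energy = u, force = f)
}

#' Total forces on every particle
#'
#' Sums WCA excluded volume over all monomer pairs (within and across
#' chains), chain springs over the topology's bond list, loop-holding
#' bonds over the condensin anchors, and the inter-condensin attraction
#' over all condensin pairs within `Delta`. Condensins feel no excluded
#' volume (point particles). All interactions are conservative pair forces,
#' so the total force sums to zero.
#'
#' @param state a [chromo_state()].
#' @param topology a [chromo_topology()].
#' @param params a [sim_params()].
#' @return List with matrices `monomer` and `condensin` of per-particle
#'   force vectors and the scalar potential `energy`.
#' @export
total_forces <- function(state, topology, params) {
  check_sizes(state, topology, params)
  out <- cpp_forces(state$mono_pos, state$cond_pos,
                    topology$springs - 1L, topology$anchors - 1L,
                    cpp_pot(params))
  list(monomer = out$f_mono, condensin = out$f_cond, energy = out$energy)
}

#' Total potential energy
#'
#' @inheritParams total_forces
#' @return Scalar potential energy (kT units).
#' @export
total_energy <- function(state, topology, params) {
  check_sizes(state, topology, params)
  cpp_energy(state$mono_pos, state$cond_pos,
             topology$springs - 1L, topology$anchors - 1L, cpp_pot(params))
}

check_sizes <- function(state, topology, params = NULL) {
  n <- nrow(state$mono_pos); m <- nrow(state$cond_pos)
  if (nrow(topology$anchors) != m)
    stop("configuration error: ", m, " condensins but ",
         nrow(topology$anchors), " anchor pairs")
  if (nrow(topology$springs) > 0 && max(topology$springs) > n)
    stop("configuration error: spring index exceeds monomer count")
  if (m > 0 && max(topology$anchors) > n)
    stop("configuration error: anchor index exceeds monomer count")
  if (!is.null(params)) {
    if (n != params$n_chains * params$N)
      stop("configuration error: expected ", params$n_chains * params$N,
           " monomers, got ", n)
    if (m != params$n_chains * params$M)
      stop("configuration error: expected ", params$n_chains * params$M,
           " condensins, got ", m)
  }
  invisible(TRUE)
}
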