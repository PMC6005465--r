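# Interaction potentials: closed-form values, caps, and force consistency.

test_that("WCA potential reproduces contact energy, cutoff, and cap", {
  # contact energy at r = sigma is the unit energy
  expect_equal(wca_energy_force(1)$energy, 1, tolerance = 1e-12)
  # minimum of the truncated-shifted potential: zero energy and force
  at_cut <- wca_energy_force(2^(1 / 6))
  expect_equal(at_cut$energy, 0, tolerance = 1e-12)
  expect_equal(at_cut$force, 0, tolerance = 1e-10)
  expect_equal(wca_energy_force(1.5)$energy, 0)

  # the cap radius from an independent bisection on the unclamped energy
  unclamped <- function(r) 4 * ((1 / r)^12 - (1 / r)^6 + 0.25) - 1000
  lo <- 0.3; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (unclamped(mid) > 0) lo <- mid else hi <- mid
  }
  r_cap_bisect <- (lo + hi) / 2
  expect_equal(wca_cap_radius(), r_cap_bisect, tolerance = 1e-10)
  # clamp engages exactly there
  expect_equal(wca_energy_force(r_cap_bisect * (1 + 1e-9))$energy, 1000,
               tolerance = 1e-3)
  expect_equal(wca_energy_force(r_cap_bisect * 0.9)$energy, 1000)
  expect_equal(wca_energy_force(r_cap_bisect * 0.9)$force, 0)

  # cap invariant over a grid of separations
  r <- seq(0.05, 1.6, by = 0.004)
  expect_true(all(wca_energy_force(r)$energy <= 1000 + 1e-9))

  # force-cap variant: energy continues linearly, force constant inside
  fc <- wca_energy_force(c(0.3, 0.5), cap = "force")
  expect_equal(fc$force[1], fc$force[2])
  expect_gt(fc$energy[1], fc$energy[2])
  expect_gt(fc$energy[2], 1000)

  expect_error(wca_energy_force(0), "invalid geometry")
})

test_that("spring potential is harmonic and symmetric about d_B", {
  at_rest <- spring_energy_force(1)
  expect_equal(at_rest$energy, 0)
  expect_equal(at_rest$force, 0)
  # direct evaluation at unit extension with the default stiffness
  expect_equal(spring_energy_force(2)$energy, 500)
  expect_equal(spring_energy_force(0.5)$energy,
               spring_energy_force(1.5)$energy)
  expect_error(spring_energy_force(-0.1), ">= 0")
})

test_that("loop-holding potential: zero at coincidence, additive, linear in F_loop", {
  z <- loop_energy_force(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), F_loop = 1)
  expect_equal(z$energy, 0)
  expect_equal(z$f_cond, c(0, 0, 0))

  # unit distance to each anchor: energy (1/2)(1 + 1)
  u <- loop_energy_force(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), F_loop = 1)
  expect_equal(u$energy, 1)
  # action-reaction: the three forces cancel
  expect_equal(u$f_cond + u$f_anchor1 + u$f_anchor2, c(0, 0, 0))

  # doubling F_loop doubles energies and forces
  u2 <- loop_energy_force(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), F_loop = 2)
  expect_equal(u2$energy, 2 * u$energy)
  expect_equal(u2$f_cond, 2 * u$f_cond)
})

test_that("inter-condensin attraction: threshold, depth, and force law", {
  # zero at and beyond the threshold (continuity)
  expect_equal(attraction_energy_force(2, F_cond = 1, Delta = 2)$energy, 0)
  expect_equal(attraction_energy_force(2, F_cond = 1, Delta = 2)$force, 0)
  expect_equal(attraction_energy_force(3, F_cond = 1, Delta = 2)$energy, 0)
  # direct evaluation at contact: -F_cond * Delta^2
  expect_equal(attraction_energy_force(0, F_cond = 1, Delta = 2)$energy, -4)
  # attractive force magnitude 2 F_cond (Delta - r)
  expect_equal(attraction_energy_force(0.5, F_cond = 1.5, Delta = 2)$force,
               2 * 1.5 * 1.5)
})

test_that("assembled forces match finite differences of the total energy", {
  fx <- force_fixture()
  fr <- total_forces(fx$state, fx$topology, fx$params)
  # Newton's third law: forces sum to the zero vector
  expect_equal(colSums(fr$monomer) + colSums(fr$condensin),
               c(0, 0, 0), tolerance = 1e-10)

  h <- 1e-6
  energy_at <- function(state) total_energy(state, fx$topology, fx$params)
  check_block <- function(block, fmat) {
    pos <- fx$state[[block]]
    worst <- 0
    for (i in seq_len(nrow(pos))) {
      for (d in 1:3) {
        sp <- fx$state; sp[[block]][i, d] <- pos[i, d] + h
        sm <- fx$state; sm[[block]][i, d] <- pos[i, d] - h
        fd <- -(energy_at(sp) - energy_at(sm)) / (2 * h)
        worst <- max(worst, abs(fmat[i, d] - fd) / max(1, abs(fd)))
      }
    }
    expect_lt(worst, 1e-5)
  }
  check_block("mono_pos", fr$monomer)
  check_block("cond_pos", fr$condensin)
})

test_that("forces obey locality and the point-particle contract", {
  fx <- force_fixture()
  # two isolated monomers beyond all cutoffs: zero force (condensin forces
  # switched off, the lone condensin parked far away)
  far <- chromo_state(matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE),
                      c(1L, 1L),
                      cond_pos = matrix(c(50, 0, 0), 1, 3), cond_chain = 1L)
  f0 <- total_forces(far, chromo_topology(matrix(integer(0), 0, 2),
                                          matrix(c(1L, 2L), 1, 2)),
                     sim_params(n_chains = 1, N = 2, M = 1, Cr = 0,
                                F_loop = 0, F_cond = 0))
  expect_equal(f0$monomer, matrix(0, 2, 3))
  expect_equal(f0$energy, 0)

  # attraction locality: moving a condensin that is farther than Delta from
  # all others leaves every attraction force unchanged
  st <- fx$state
  iso <- which.max(apply(as.matrix(dist(st$cond_pos)), 1,
                         function(r) min(r[r > 0])))
  f_before <- total_forces(st, fx$topology, fx$params)
  st2 <- st
  st2$cond_pos[iso, ] <- st2$cond_pos[iso, ] + 100  # far away
  f_after <- total_forces(st2, fx$topology, fx$params)
  others <- setdiff(seq_len(nrow(st$cond_pos)), iso)
  # the isolated condensin still feels its loop tether, but no condensin
  # interaction changes for the others beyond its (removed) contribution
  dc <- as.matrix(dist(st$cond_pos))[iso, others]
  if (all(dc >= fx$params$Delta))
    expect_equal(f_before$condensin[others, ], f_after$condensin[others, ],
                 tolerance = 1e-12)
})

test_that("coincident particles return capped energy and zero force", {
  st <- chromo_state(matrix(0, 2, 3), c(1L, 1L),
                     cond_pos = matrix(c(50, 0, 0), 1, 3), cond_chain = 1L)
  p <- sim_params(n_chains = 1, N = 2, M = 1, Cr = 0,
                  F_loop = 0, F_cond = 0)
  f <- total_forces(st, chromo_topology(matrix(integer(0), 0, 2),
                                        matrix(c(1L, 2L), 1, 2)), p)
  expect_equal(f$energy, 1000)
  expect_equal(f$monomer, matrix(0, 2, 3))
})

test_that("configuration size mismatches are rejected", {
  fx <- force_fixture()
  bad <- fx$state
  bad$cond_pos <- bad$cond_pos[-1, , drop = FALSE]
  bad$cond_vel <- bad$cond_vel[-1, , drop = FALSE]
  bad$cond_chain <- bad$cond_chain[-1]
  expect_error(total_forces(bad, fx$topology, fx$params), "configuration error")
})
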