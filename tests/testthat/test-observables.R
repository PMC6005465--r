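# Order parameters: gyration tensor, asphericity, loop spheres, overlap,
# attraction fractions, threshold crossings, axis density.

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

test_that("gyration tensor matches direct evaluation and is rotation-invariant", {
  # single point: zero tensor
  g0 <- gyration_tensor(matrix(c(1, 2, 3), 1, 3))
  expect_equal(g0$tensor, matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(g0$rg, 0)

  # cube corners at +/-1: identity tensor, Rg = sqrt(3)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  g <- gyration_tensor(cube)
  expect_equal(g$tensor, diag(3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(g$lambda2, rep(1, 3))
  expect_equal(g$rg, sqrt(3))

  # eigenvalues invariant under rigid rotation
  set.seed(8)
  pts <- matrix(rnorm(60), 20, 3) %*% diag(c(3, 1, 0.3))
  rot <- pts %*% random_rotation()
  expect_equal(gyration_tensor(pts)$lambda2, gyration_tensor(rot)$lambda2,
               tolerance = 1e-10)

  # Rg consistency: eigenvalue sum equals RMS distance from the CM
  rms <- sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2)))
  expect_equal(gyration_tensor(pts)$rg, rms, tolerance = 1e-10)

  expect_error(gyration_tensor(matrix(numeric(0), 0, 3)), "empty")
})

test_that("asphericity spans sphere (0) to rod (1) with the stated arithmetic", {
  # isotropic eigenvalues -> 0
  expect_equal(asphericity(c(2, 2, 2)), 0)
  # collinear points -> 1
  line <- cbind(seq(-5, 5, length.out = 30), 0, 0)
  expect_equal(asphericity(line), 1)
  # direct arithmetic: (4 - (1+1)/2) / 6
  expect_equal(asphericity(c(4, 1, 1)), 0.5)
  # undefined for coincident points
  expect_error(asphericity(matrix(1, 5, 3)), "undefined")
})

test_that("loop spheres: centers, radii, and rigid-motion behaviour", {
  # coincident loop monomers: radius 0
  expect_equal(loop_spheres(matrix(2, 10, 3), 10)$radius, 0)

  # ring of radius rho: center at origin, radius rho
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  ring <- cbind(3 * cos(th), 3 * sin(th), 0)
  sp <- loop_spheres(ring, 20)
  expect_equal(unlist(sp[1, c("cx", "cy", "cz")]), c(0, 0, 0),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sp$radius, 3, tolerance = 1e-12)

  # translation moves centers, preserves radii
  sp2 <- loop_spheres(sweep(ring, 2, c(5, -2, 1), `+`), 20)
  expect_equal(sp2$radius, sp$radius)
  expect_equal(unlist(sp2[1, c("cx", "cy", "cz")]), c(5, -2, 1),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(loop_spheres(ring, 7), "multiple")
})

test_that("overlap agrees with a brute-force membership oracle", {
  # identical chains: every monomer inside its own spheres -> 1
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(overlap(a, a, 5)$overlap, 1)

  # far-apart chains -> 0
  expect_equal(overlap(a, a + 1000, 5)$overlap, 0)

  # hand-built two-loop toys vs double-loop oracle
  b <- matrix(rnorm(30, sd = 2), 10, 3) + 1
  res <- overlap(a, b, 5)
  oracle_dir <- function(pts, other, L) {
    sp <- loop_spheres(other, L)
    hits <- 0
    for (i in seq_len(nrow(pts))) {
      inside <- FALSE
      for (s in seq_len(nrow(sp))) {
        d <- sqrt(sum((pts[i, ] - c(sp$cx[s], sp$cy[s], sp$cz[s]))^2))
        if (d <= sp$radius[s]) inside <- TRUE
      }
      hits <- hits + inside
    }
    hits / nrow(pts)
  }
  expect_equal(res$a_in_b, oracle_dir(a, b, 5))
  expect_equal(res$b_in_a, oracle_dir(b, a, 5))
  expect_equal(res$overlap, (res$a_in_b + res$b_in_a) / 2)
  expect_true(res$overlap >= 0 && res$overlap <= 1)
})

test_that("attraction fractions match pair enumeration", {
  # all condensins mutually beyond Delta
  spread <- diag(3) * 10
  expect_equal(attraction_fractions(spread, c(1L, 1L, 2L), 1)$trans, 0)
  expect_equal(attraction_fractions(spread, c(1L, 1L, 2L), 1)$cis, 0)

  # 4-condensin toy: one trans pair within Delta
  pos <- rbind(c(0, 0, 0), c(5, 0, 0), c(0.5, 0, 0), c(9, 0, 0))
  chain <- c(1L, 1L, 2L, 2L)
  fr <- attraction_fractions(pos, chain, 1)
  expect_equal(fr$trans, 0.5)   # condensins 1 and 3
  expect_equal(fr$cis, 0)

  # interleaved chains: everyone has a trans partner
  pos2 <- cbind(seq(0, 3.5, by = 0.5), 0, 0)
  chain2 <- rep(c(1L, 2L), 4)
  expect_equal(attraction_fractions(pos2, chain2, 0.75)$trans, 1)

  # a condensin may count toward both trans and cis
  pos3 <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0, 0.4, 0))
  fr3 <- attraction_fractions(pos3, c(1L, 1L, 2L), 1)
  expect_equal(fr3$trans, 1)     # every condensin has an other-chain partner
  expect_equal(fr3$cis, 2 / 3)   # the chain-2 condensin has no own-chain one
})

test_that("segregation metrics interpolate crossings and honour censoring", {
  # linear overlap ramp crossing 0.2 exactly at t = 1000
  tm <- seq(0, 2000, by = 100)
  ov <- 1 - 0.8 * tm / 1000
  sm <- segregation_metrics(tm, overlap = ov)
  expect_equal(sm$segregation_time, 1000)
  expect_equal(sm$segregation_speed, 1e-3)
  expect_false(sm$segregation_censored)

  # crossing between samples: linear interpolation, stable under 2x
  # resampling on a nested grid
  tm2 <- c(0, 300, 700)
  ov2 <- c(0.9, 0.5, 0.1)
  s1 <- segregation_metrics(tm2, overlap = ov2)
  tmr <- c(0, 150, 300, 500, 700)
  ovr <- approx(tm2, ov2, xout = tmr)$y
  s2 <- segregation_metrics(tmr, overlap = ovr)
  expect_equal(s1$segregation_time, s2$segregation_time, tolerance = 1e-12)

  # never below threshold: censored, speed reported as 0
  sm0 <- segregation_metrics(tm, overlap = rep(0.5, length(tm)))
  expect_true(sm0$segregation_censored)
  expect_true(is.na(sm0$segregation_time))
  expect_equal(sm0$segregation_speed, 0)

  # trans decay requires a sustained zero
  tr <- c(0.4, 0.2, 0, 0.1, 0, 0, 0)
  smt <- segregation_metrics(seq_along(tr) * 10, trans = tr)
  expect_equal(smt$trans_decay_time, 50)  # first sustained zero, not the blip
  expect_equal(smt$trans_decay_speed, 1 / 50)
  # a terminal single zero is not sustained
  smt2 <- segregation_metrics(1:3, trans = c(0.3, 0.1, 0))
  expect_true(smt2$trans_censored)

  expect_error(segregation_metrics(c(1, 3, 2), overlap = c(1, 1, 1)),
               "increasing")
})

test_that("axis density concentrates where the condensins sit", {
  # straight line: all mass in the origin bin
  line <- cbind(seq_len(20), 0, 0)
  prof <- axis_density(line, interval = 5, bin_width = 0.25)
  expect_equal(sum(prof$count), 20)
  expect_equal(prof$count[1], 20)
  expect_equal(prof$density_norm[1], 1)

  # condensins on a cylinder of radius rho about a straight axis polyline:
  # mass concentrated near rho (the segment endpoints themselves lie on
  # the cylinder, so distances are <= rho)
  rho <- 2
  z <- seq(0, 19, length.out = 20)
  ang <- rep(c(0, pi / 2, pi, 3 * pi / 2), 5)
  cyl <- cbind(rho * cos(ang), rho * sin(ang), z)
  pr <- axis_density(cyl, interval = 5, bin_width = 0.5)
  # brute-force point-segment oracle
  d_oracle <- sapply(seq_len(20), function(j) {
    seg <- (j - 1) %/% 5
    point_segment_distance(cyl[j, ], cyl[seg * 5 + 1, ], cyl[(seg + 1) * 5, ])
  })
  expect_equal(sum(pr$count * (pr$r_lo + 0.25)) / 20,
               mean(pmin(d_oracle, max(pr$r_hi) - 1e-9)) , tolerance = 0.3)
  expect_gt(mean(d_oracle > rho / 2), 0.5)  # most sit off-axis

  # rigid motion invariance
  rot <- random_rotation(2)
  pr2 <- axis_density(sweep(cyl %*% rot, 2, c(3, 1, -2), `+`),
                      interval = 5, bin_width = 0.5)
  expect_equal(pr$count, pr2$count)

  expect_error(axis_density(line[1:5, , drop = FALSE], interval = 5),
               "too few|multiple")
})
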