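#' Gyration tensor, eigenvalues, and radius of gyration
#'
#' `G_ab = (1/N) sum_i (r_i,a - r_cm,a)(r_i,b - r_cm,b)`: the covariance
#' tensor of the monomer configuration. Its eigenvalues `lambda_1^2 >=
#' lambda_2^2 >= lambda_3^2` are the squared principal-axis lengths of the
#' gyration ellipsoid, and `Rg = sqrt(sum_i lambda_i^2)`.
#'
#' @param positions numeric matrix (points x 3), at least one row.
#' @return List with `tensor` (3 x 3), `lambda2` (eigenvalues, descending),
#'   and `rg`.
#' @export
gyration_tensor <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1) stop("gyration tensor of an empty point set")
  centered <- sweep(positions, 2, colMeans(positions))
  G <- crossprod(centered) / nrow(positions)
  lambda2 <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values,
                  decreasing = TRUE)
  lambda2 <- pmax(lambda2, 0)
  list(tensor = G, lambda2 = lambda2, rg = sqrt(sum(lambda2)))
}

#' Normalized asphericity
#'
#' `A = (lambda_1^2 - (lambda_2^2 + lambda_3^2) / 2) / (lambda_1^2 +
#' lambda_2^2 + lambda_3^2)`, in `[0, 1]`: 0 for a spherically symmetric
#' cloud, 1 for a collinear (rod-like) one.
#'
#' @param x either a positions matrix (points x 3) or a length-3 numeric
#'   vector of gyration-tensor eigenvalues.
#' @return Asphericity value in `[0, 1]`.
#' @export
asphericity <- function(x) {
  lambda2 <- if (is.matrix(x) || (is.data.frame(x))) gyration_tensor(x)$lambda2
             else sort(as.numeric(x), decreasing = TRUE)
  tot <- sum(lambda2)
  if (tot <= 0)
    stop("asphericity undefined: all points coincide (zero gyration tensor)")
  (lambda2[1] - 0.5 * (lambda2[2] + lambda2[3])) / tot
}

#' Loop spheres of a chain
#'
#' The region of loop `i` is the sphere centred at the mean position of its
#' `L` monomers (indices `(i-1)L + 1 .. iL` along the chain) with radius
#' equal to the maximum centre-to-monomer distance. The chromosome region
#' is the union of its loop spheres.
#'
#' @param positions one chain's monomer positions in chain order
#'   (rows = monomers).
#' @param L loop length in monomers; `nrow(positions)` must be a multiple.
#' @return Data frame with one row per loop: `loop`, `cx`, `cy`, `cz`,
#'   `radius`.
#' @export
loop_spheres <- function(positions, L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n %% L != 0) stop("chain length is not a multiple of the loop length")
  nl <- n %/% L
  out <- data.frame(loop = seq_len(nl), cx = 0, cy = 0, cz = 0, radius = 0)
  for (i in seq_len(nl)) {
    seg <- positions[((i - 1) * L + 1):(i * L), , drop = FALSE]
    ctr <- colMeans(seg)
    d <- sqrt(rowSums(sweep(seg, 2, ctr)^2))
    out[i, 2:4] <- ctr
    out$radius[i] <- max(d)
  }
  out
}

#' Overlap of two chromosomes
#'
#' Fraction of one chromosome's monomers lying inside the other
#' chromosome's region (union of its loop spheres). The headline scalar is
#' the mean of the two directions; both directional values are returned.
#'
#' @param pos_a,pos_b monomer positions of the two chains, in chain order.
#' @param L loop length in monomers.
#' @return List with `overlap` (symmetrized), `a_in_b`, and `b_in_a`.
#' @export
overlap <- function(pos_a, pos_b, L) {
  pos_a <- as.matrix(pos_a); pos_b <- as.matrix(pos_b)
  frac_inside <- function(pts, spheres) {
    inside <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(spheres))) {
      d2 <- (pts[, 1] - spheres$cx[i])^2 + (pts[, 2] - spheres$cy[i])^2 +
            (pts[, 3] - spheres$cz[i])^2
      inside <- inside | (d2 <= spheres$radius[i]^2)
      if (all(inside)) break
    }
    mean(inside)
  }
  sa <- loop_spheres(pos_a, L)
  sb <- loop_spheres(pos_b, L)
  a_in_b <- frac_inside(pos_a, sb)
  b_in_a <- frac_inside(pos_b, sa)
  list(overlap = (a_in_b + b_in_a) / 2, a_in_b = a_in_b, b_in_a = b_in_a)
}

#' Trans- and cis-attraction fractions
#'
#' A condensin counts toward the trans fraction if at least one condensin
#' of *another* chain lies within the threshold distance `Delta`, and
#' toward the cis fraction if at least one condensin of its *own* chain
#' does. Each fraction divides by the total condensin count; a condensin
#' may count toward both.
#'
#' @param cond_pos condensin positions (rows).
#' @param cond_chain chain index per condensin.
#' @param Delta attraction threshold distance.
#' @return List with `trans` and `cis`, both in `[0, 1]`.
#' @export
attraction_fractions <- function(cond_pos, cond_chain, Delta) {
  m <- nrow(cond_pos)
  if (m == 0) return(list(trans = NA_real_, cis = NA_real_))
  d <- as.matrix(stats::dist(cond_pos))
  within <- d < Delta
  diag(within) <- FALSE
  same <- outer(cond_chain, cond_chain, `==`)
  trans_i <- apply(within & !same, 1, any)
  cis_i <- apply(within & same, 1, any)
  list(trans = mean(trans_i), cis = mean(cis_i))
}

#' Segregation and trans-decay metrics from time series
#'
#' The segregation time is the first time the overlap series crosses below
#' 0.2 (linearly interpolated between samples) and the segregation speed its
#' inverse. The trans-decay time is the first sample at which the
#' trans-attraction is exactly zero and stays zero for at least one further
#' sample (guarding against flicker); its inverse is the trans-decay speed.
#' Series that never cross are censored: time `NA`, speed 0.
#'
#' @param time strictly increasing sample times.
#' @param overlap overlap series (same length as `time`); may be `NULL`.
#' @param trans trans-attraction series; may be `NULL`.
#' @param threshold overlap threshold defining segregation (default 0.2).
#' @return List with `segregation_time`, `segregation_speed`,
#'   `segregation_censored`, `trans_decay_time`, `trans_decay_speed`,
#'   `trans_censored`.
#' @export
segregation_metrics <- function(time, overlap = NULL, trans = NULL,
                                threshold = 0.2) {
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  res <- list(segregation_time = NA_real_, segregation_speed = 0,
              segregation_censored = TRUE,
              trans_decay_time = NA_real_, trans_decay_speed = 0,
              trans_censored = TRUE)
  if (!is.null(overlap)) {
    tc <- first_crossing(time, overlap, threshold)
    if (!is.na(tc)) {
      res$segregation_time <- tc
      res$segregation_speed <- 1 / tc
      res$segregation_censored <- FALSE
    }
  }
  if (!is.null(trans)) {
    zero <- trans == 0
    sustained <- which(zero & c(zero[-1], FALSE))
    if (length(sustained) > 0) {
      res$trans_decay_time <- time[sustained[1]]
      res$trans_decay_speed <- 1 / time[sustained[1]]
      res$trans_censored <- FALSE
    }
  }
  res
}

# first time y crosses to/below the threshold, linearly interpolated
first_crossing <- function(time, y, threshold) {
  below <- y <= threshold
  if (!any(below)) return(NA_real_)
  i <- which(below)[1]
  if (i == 1L || y[i] == threshold) return(time[i])
  t0 <- time[i - 1]; t1 <- time[i]
  y0 <- y[i - 1]; y1 <- y[i]
  t0 + (y0 - threshold) / (y0 - y1) * (t1 - t0)
}

#' Radial density profile of condensins about their axis
#'
#' The condensin axis of a chain is approximated by a piecewise-linear
#' series of segments: segment `i` connects the `(interval*(i-1)+1)`-th and
#' the `(interval*i)`-th condensin in chain order. Each condensin's axial
#' distance is its point-to-segment distance to the segment of its own
#' order. The histogram of distances is returned both raw and normalized to
#' 1 at the origin bin.
#'
#' @param cond_pos one chain's condensin positions in chain order.
#' @param interval condensins per axis segment (default 5). The condensin
#'   count must be a multiple of `interval` and at least `2 * interval`.
#' @param bin_width histogram bin width (default 0.25 sigma).
#' @return Data frame with `r_lo`, `r_hi`, `count`, `density` (count per
#'   bin width), and `density_norm` (density / origin-bin density; `NaN`
#'   when the origin bin is empty).
#' @export
axis_density <- function(cond_pos, interval = 5, bin_width = 0.25) {
  cond_pos <- as.matrix(cond_pos)
  m <- nrow(cond_pos)
  if (m %% interval != 0)
    stop("condensin count must be a multiple of the segment interval")
  if (m < 2 * interval)
    stop("too few condensins for an axis: need at least ", 2 * interval)
  nseg <- m %/% interval
  dists <- numeric(m)
  for (j in seq_len(m)) {
    seg <- (j - 1) %/% interval + 1
    p0 <- cond_pos[(seg - 1) * interval + 1, ]
    p1 <- cond_pos[seg * interval, ]
    dists[j] <- point_segment_distance(cond_pos[j, ], p0, p1)
  }
  nbin <- max(1L, ceiling(max(dists) / bin_width + 1e-9))
  idx <- pmin(nbin, floor(dists / bin_width) + 1L)
  counts <- tabulate(idx, nbins = nbin)
  density <- counts / bin_width
  data.frame(r_lo = (seq_len(nbin) - 1) * bin_width,
             r_hi = seq_len(nbin) * bin_width,
             count = counts, density = density,
             density_norm = density / density[1])
}

#' Distance from a point to a line segment
#'
#' @param p query point (length-3).
#' @param a,b segment endpoints (length-3).
#' @return Euclidean distance from `p` to the closest point of segment
#'   `ab`.
#' @export
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}
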