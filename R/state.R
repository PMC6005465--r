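#' System state: positions and velocities
#'
#' Holds the instantaneous mechanical state: one position and velocity
#' 3-vector per chromatin monomer and per condensin, chain membership for
#' both, and the simulation time.
#'
#' @param mono_pos numeric matrix, monomers x 3.
#' @param mono_chain integer chain index (1-based) per monomer.
#' @param cond_pos numeric matrix, condensins x 3 (may have zero rows).
#' @param cond_chain integer chain index per condensin.
#' @param mono_vel,cond_vel velocity matrices; default zero.
#' @param time simulation time attached to this snapshot.
#'
#' @return An object of class `chromo_state`.
#' @export
chromo_state <- function(mono_pos, mono_chain,
                         cond_pos = matrix(numeric(0), 0, 3),
                         cond_chain = integer(0),
                         mono_vel = NULL, cond_vel = NULL, time = 0) {
  mono_pos <- as.matrix(mono_pos)
  cond_pos <- as.matrix(cond_pos)
  if (ncol(mono_pos) != 3 || ncol(cond_pos) != 3)
    stop("positions must be 3-column matrices")
  if (is.null(mono_vel)) mono_vel <- matrix(0, nrow(mono_pos), 3)
  if (is.null(cond_vel)) cond_vel <- matrix(0, nrow(cond_pos), 3)
  st <- list(mono_pos = mono_pos, mono_vel = as.matrix(mono_vel),
             cond_pos = cond_pos, cond_vel = as.matrix(cond_vel),
             mono_chain = as.integer(mono_chain),
             cond_chain = as.integer(cond_chain),
             time = time)
  validate_state(st)
  class(st) <- "chromo_state"
  st
}

validate_state <- function(st) {
  n <- nrow(st$mono_pos); m <- nrow(st$cond_pos)
  if (length(st$mono_chain) != n || length(st$cond_chain) != m)
    stop("chain id length does not match particle count")
  if (!all(dim(st$mono_vel) == dim(st$mono_pos)) ||
      !all(dim(st$cond_vel) == dim(st$cond_pos)))
    stop("velocity dimensions do not match positions")
  if (n > 0 && (min(st$mono_chain) < 1L))
    stop("chain ids must be >= 1")
  invisible(st)
}

#' @export
print.chromo_state <- function(x, ...) {
  cat(sprintf("chromo_state: %d monomers, %d condensins, %d chain(s), t = %g\n",
              nrow(x$mono_pos), nrow(x$cond_pos),
              length(unique(x$mono_chain)), x$time))
  invisible(x)
}

#' Bond topology: chain springs and condensin anchors
#'
#' The spring list is the chain connectivity *after* any crossing rewires;
#' each chain's spring graph must remain a single path visiting all its
#' monomers. Anchors give, per condensin, the ordered pair of monomers it
#' holds (the loop base points). All indices are 1-based global monomer
#' indices.
#'
#' @param springs integer matrix, bonds x 2.
#' @param anchors integer matrix, condensins x 2.
#' @param crossings optional data frame logging installed crossings
#'   (columns `chain`, `loop`, `a`, `b`: the bond pair at which the rewire
#'   was applied).
#'
#' @return An object of class `chromo_topology`.
#' @export
chromo_topology <- function(springs, anchors = matrix(integer(0), 0, 2),
                            crossings = NULL) {
  springs <- matrix(as.integer(as.matrix(springs)), ncol = 2)
  anchors <- matrix(as.integer(as.matrix(anchors)), ncol = 2)
  if (is.null(crossings))
    crossings <- data.frame(chain = integer(0), loop = integer(0),
                            a = integer(0), b = integer(0))
  tp <- list(springs = springs, anchors = anchors, crossings = crossings)
  class(tp) <- "chromo_topology"
  tp
}

#' @export
print.chromo_topology <- function(x, ...) {
  cat(sprintf("chromo_topology: %d springs, %d condensin anchor pairs, %d crossings\n",
              nrow(x$springs), nrow(x$anchors), nrow(x$crossings)))
  invisible(x)
}

#' Verify that a chain's spring graph is a single path
#'
#' Traverses the spring graph restricted to the monomers of one chain and
#' checks it is one simple path visiting all of them (every monomer has
#' degree <= 2, exactly two endpoints of degree 1, and a walk from one
#' endpoint reaches all monomers).
#'
#' @param topology a [chromo_topology()].
#' @param monomers integer vector of (global) monomer indices of the chain.
#' @return `TRUE` or `FALSE`.
#' @export
is_single_path <- function(topology, monomers) {
  sp <- topology$springs
  keep <- sp[, 1] %in% monomers & sp[, 2] %in% monomers
  sp <- sp[keep, , drop = FALSE]
  n <- length(monomers)
  if (nrow(sp) != n - 1) return(FALSE)
  idx <- match(c(sp[, 1], sp[, 2]), monomers)
  deg <- tabulate(idx, nbins = n)
  if (any(deg > 2) || sum(deg == 1) != 2) return(FALSE)
  adj <- vector("list", n)
  a <- match(sp[, 1], monomers); b <- match(sp[, 2], monomers)
  for (k in seq_len(nrow(sp))) {
    adj[[a[k]]] <- c(adj[[a[k]]], b[k])
    adj[[b[k]]] <- c(adj[[b[k]]], a[k])
  }
  start <- which(deg == 1)[1]
  visited <- logical(n)
  cur <- start; prev <- 0L; visited[cur] <- TRUE
  for (step in seq_len(n - 1)) {
    nxt <- setdiff(adj[[cur]], prev)
    if (length(nxt) != 1) return(FALSE)
    prev <- cur; cur <- nxt
    if (visited[cur]) return(FALSE)
    visited[cur] <- TRUE
  }
  all(visited)
}

# Monomer indices (global, 1-based) of chain c laid out block-wise.
chain_monomers <- function(params, chain) {
  (chain - 1L) * params$N + seq_len(params$N)
}

# Condensin indices (global, 1-based) of chain c.
chain_condensins <- function(params, chain) {
  (chain - 1L) * params$M + seq_len(params$M)
}
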