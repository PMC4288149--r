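# Twist, writhe and linking-number bookkeeping. Twist is the winding of
# the minor-groove patch ribbon about the chain axis; writhe is the
# self-coiling of the axis (discrete Gauss double integral, evaluated with
# the exact per-segment-pair solid-angle formula); for a closed ribbon
# White's theorem Lk = Tw + Wr holds to discretization accuracy.

#' Twist of a chain (in turns)
#'
#' Sum over consecutive beads of the signed dihedral of the patch vectors
#' about the local bond tangent; additive over contiguous ranges. For a
#' circular chain the closing joint is included.
#'
#' @param chain a [dna_chain()] (or a list with `positions` and `quat`).
#' @param range integer bead interval (e.g. `5:40`); NULL = whole chain.
#' @return twist in turns.
#' @export
twist <- function(chain, range = NULL) {
  P <- chain$positions
  U <- quat_rotate(chain$quat, c(0, 1, 0))
  n <- nrow(P)
  if (is.null(range)) range <- seq_len(n)
  range <- sort(unique(as.integer(range)))
  if (length(range) < 2) {
    warning("twist over an empty or single-bead range is zero")
    return(0)
  }
  idx <- range[-length(range)]
  jdx <- range[-1]
  if (!is.null(chain$topology) && chain$topology == "circular" &&
      length(range) == n) {
    idx <- c(idx, n); jdx <- c(jdx, 1L)
  }
  b <- P[jdx, , drop = FALSE] - P[idx, , drop = FALSE]
  b <- b / sqrt(rowSums(b^2))
  a1 <- U[idx, , drop = FALSE]
  a2 <- U[jdx, , drop = FALSE]
  a1 <- a1 - rowSums(a1 * b) * b
  a2 <- a2 - rowSums(a2 * b) * b
  crx <- cbind(a1[, 2] * a2[, 3] - a1[, 3] * a2[, 2],
               a1[, 3] * a2[, 1] - a1[, 1] * a2[, 3],
               a1[, 1] * a2[, 2] - a1[, 2] * a2[, 1])
  ang <- atan2(rowSums(crx * b), rowSums(a1 * a2))
  sum(ang) / (2 * pi)
}

#' Writhe of a space curve
#'
#' Discrete Gauss double integral over all non-adjacent segment pairs,
#' with each pair evaluated by the exact solid-angle (spherical
#' quadrilateral) formula, so the result is the exact writhe of the
#' polyline. Open curves are handled by a closure convention:
#' * `extended-axis` (default for linear DNA): both termini are extended
#'   outward along their end tangents by `leg` nm and the open Gauss
#'   integral of the extended curve is returned (closure at infinity
#'   contributes nothing).
#' * `minimal`: the curve is closed by the straight chord end-to-start.
#' * `closed`: the input is already a closed loop.
#'
#' @param curve an n x 3 matrix of vertices, or a [dna_chain()].
#' @param closure `"extended-axis"`, `"minimal"` or `"closed"`.
#' @param leg extension length for `extended-axis`, nm.
#' @return dimensionless writhe.
#' @export
writhe <- function(curve, closure = c("extended-axis", "minimal", "closed"),
                   leg = 100) {
  closure <- match.arg(closure)
  if (inherits(curve, "dna_chain")) {
    if (curve$topology == "circular") closure <- "closed"
    curve <- curve$positions
  }
  P <- as.matrix(curve)
  if (nrow(P) < 4) stop("writhe needs at least 4 vertices", call. = FALSE)
  if (closure == "closed") return(cpp_writhe(P, TRUE))
  if (closure == "minimal") return(cpp_writhe(P, TRUE))
  n <- nrow(P)
  t0 <- unit3(P[1, ] - P[2, ])
  t1 <- unit3(P[n, ] - P[n - 1, ])
  P2 <- rbind(P[1, ] + leg * t0, P, P[n, ] + leg * t1)
  cpp_writhe(P2, FALSE)
}

#' Gauss linking number of the bead axis and its patch-offset curve
#'
#' Independent of the Tw + Wr decomposition: evaluates the Gauss linking
#' double integral between the closed centreline and the closed ribbon
#' edge traced by the patch vectors at offset `eps`.
#'
#' @param chain a circular [dna_chain()].
#' @param eps ribbon offset, nm.
#' @return (near-integer) linking number.
#' @export
linking_number_gauss <- function(chain, eps = 0.5) {
  stopifnot(chain$topology == "circular")
  P <- chain$positions
  U <- quat_rotate(chain$quat, c(0, 1, 0))
  cpp_link(P, P + eps * U)
}

#' Linking number by signed crossings in random projections
#'
#' Projects the centreline and the patch-offset edge onto random planes
#' and counts signed crossings between the two curves; Lk is half the
#' signed crossing count. Used as a brute-force oracle for White's
#' theorem.
#'
#' @param chain a circular [dna_chain()].
#' @param n_proj number of random projection directions.
#' @param eps ribbon offset, nm.
#' @param seed seed for the projection draws.
#' @return the modal Lk over projections.
#' @export
linking_number_crossings <- function(chain, n_proj = 25, eps = 0.5,
                                     seed = 1L) {
  stopifnot(chain$topology == "circular")
  set.seed(seed)
  P <- chain$positions
  U <- quat_rotate(chain$quat, c(0, 1, 0))
  Q <- P + eps * U
  vals <- vapply(seq_len(n_proj), function(k) {
    R <- rotation_between(unit3(stats::rnorm(3)), c(0, 0, 1))
    signed_crossings(P %*% t(R), Q %*% t(R)) / 2
  }, 1)
  as.numeric(names(sort(table(round(vals)), decreasing = TRUE))[1])
}

# signed crossings between two closed polylines projected on z = 0;
# sign from over/under (z) and orientation
signed_crossings <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  A2 <- rbind(A, A[1, ]); B2 <- rbind(B, B[1, ])
  tot <- 0
  for (i in seq_len(nA)) {
    p <- A2[i, ]; pq <- A2[i + 1, ] - p
    for (j in seq_len(nB)) {
      r <- B2[j, ]; rs <- B2[j + 1, ] - r
      den <- pq[1] * rs[2] - pq[2] * rs[1]
      if (abs(den) < 1e-14) next
      t <- ((r[1] - p[1]) * rs[2] - (r[2] - p[2]) * rs[1]) / den
      u <- ((r[1] - p[1]) * pq[2] - (r[2] - p[2]) * pq[1]) / den
      if (t <= 0 || t > 1 || u <= 0 || u > 1) next
      zA <- p[3] + t * pq[3]
      zB <- r[3] + u * rs[3]
      s <- sign(den) * sign(zA - zB)
      tot <- tot + s
    }
  }
  tot
}

#' Topology report of a system state
#'
#' Whole-chain twist, writhe, their sum (equal to the linking number for
#' closed chains), and per-nucleosome linking-number changes for fully
#' wrapped cores.
#'
#' @param state a [system_state()].
#' @param params [ff_params()].
#' @param wrap_threshold_bp minimum wrapped bp for a core to get a
#'   per-nucleosome entry.
#' @return list of class `topology_report`.
#' @export
topology_report <- function(state, params = ff_params(),
                            wrap_threshold_bp = 130) {
  ch <- state$chains[[1]]
  Tw <- twist(ch)
  Wr <- writhe(ch)
  rep_ <- list(Tw = Tw, Wr = Wr, Lk = Tw + Wr,
               closed = ch$topology == "circular")
  percore <- list()
  for (i in seq_along(state$cores)) {
    wa <- try(wrapped_bp(state, i, params), silent = TRUE)
    if (inherits(wa, "try-error") || wa$wrapped_bp < wrap_threshold_bp) next
    percore[[length(percore) + 1]] <-
      c(core = i, unlist(delta_lk_per_nucleosome(state, i, params,
                                                 wrap_threshold_bp)))
  }
  rep_$per_nucleosome <- if (length(percore)) do.call(rbind, percore) else NULL
  class(rep_) <- "topology_report"
  rep_
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> Tw = %+.3f  Wr = %+.3f  Tw+Wr = %+.3f%s\n",
              x$Tw, x$Wr, x$Lk, if (x$closed) " (closed: = Lk)" else ""))
  if (!is.null(x$per_nucleosome))
    print(round(x$per_nucleosome, 3))
  invisible(x)
}

#' Linking-number change attributed to one wrapped nucleosome
#'
#' Delta Tw is the measured twist of the patch ribbon across the wrapped
#' bead range; Delta Wr is the writhe of the wrapped centreline extended
#' a few beads into the flanking linkers and then along straight legs
#' (the extended-axis convention); Delta Lk is their sum. For the
#' twist-storing model (stored twist +0.75) this is about -1, for the
#' naive model about -1.75.
#'
#' @param state a [system_state()].
#' @param core_id index of the core.
#' @param params [ff_params()].
#' @param wrap_threshold_bp minimum wrapped bp; below it the per-nucleosome
#'   topology is undefined and an error is thrown.
#' @param pad flanking beads of linker included in the writhe curve.
#' @return list with `delta_Tw`, `delta_Wr`, `delta_Lk` (turns).
#' @export
delta_lk_per_nucleosome <- function(state, core_id, params = ff_params(),
                                    wrap_threshold_bp = 130, pad = 3L) {
  wa <- wrapped_bp(state, core_id, params)
  if (wa$wrapped_bp < wrap_threshold_bp)
    stop(sprintf(
      "undefined topology: core %d wraps only %.0f bp (< %.0f bp)",
      core_id, wa$wrapped_bp, wrap_threshold_bp), call. = FALSE)
  ch <- state$chains[[wa$chain]]
  beads <- wa$bound_beads$bead
  lo <- max(1L, min(beads) - pad)
  hi <- min(n_beads(ch), max(beads) + pad)
  dTw <- twist(ch, lo:hi)
  dWr <- writhe(ch$positions[lo:hi, , drop = FALSE], "extended-axis")
  list(delta_Tw = dTw, delta_Wr = dWr, delta_Lk = dTw + dWr)
}
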