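#' Ordered equidistant nodes of a proton-transfer pathway
#'
#' Constructor for the `path_nodes` class: an ordered set of 3D node
#' coordinates with equal arc-length spacing, plus the frame metadata (origin
#' node and orientation) that maps node index to the signed path coordinate
#' xi* in Angstrom-comparable units.
#'
#' @param nodes Numeric matrix, one row per node, columns x/y/z (Angstrom).
#' @param origin_index Index (1-based) of the node assigned xi* = 0.
#' @param orientation `+1` or `-1`; sign mapping increasing node index to
#'   positive xi*.
#' @return An object of class `path_nodes` with elements `nodes`, `n_nodes`,
#'   `spacing`, `origin_index`, `orientation`.
#' @export
path_nodes <- function(nodes, origin_index = 1L, orientation = 1L) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns (x, y, z)")
  n <- nrow(nodes)
  if (n < 3L) stop("at least 3 nodes required")
  if (!all(is.finite(nodes))) stop("node coordinates must be finite")
  seg <- sqrt(rowSums((nodes[-1L, , drop = FALSE] -
                       nodes[-n, , drop = FALSE])^2))
  spacing <- mean(seg)
  if (spacing <= 0) stop("degenerate path: zero spacing")
  if (max(abs(seg / spacing - 1)) > 1e-6)
    stop("nodes are not equidistant (relative spread > 1e-6)")
  if (origin_index < 1L || origin_index > n) stop("origin_index out of range")
  if (!orientation %in% c(-1L, 1L, -1, 1)) stop("orientation must be +1 or -1")
  structure(
    list(nodes = unname(nodes), n_nodes = n, spacing = spacing,
         origin_index = as.integer(origin_index),
         orientation = as.integer(sign(orientation))),
    class = "path_nodes")
}

#' @export
print.path_nodes <- function(x, ...) {
  cat(sprintf(
    "path_nodes: %d equidistant nodes, spacing %.4f A, length %.2f A\n",
    x$n_nodes, x$spacing, x$spacing * (x$n_nodes - 1)))
  cat(sprintf("  origin at node %d, orientation %+d\n",
              x$origin_index, x$orientation))
  invisible(x)
}

#' Signed path coordinate of each node
#'
#' @param nodes A `path_nodes` object.
#' @return Numeric vector of xi* values (Angstrom-comparable), one per node.
#' @export
node_xi <- function(nodes) {
  stopifnot(inherits(nodes, "path_nodes"))
  (seq_len(nodes$n_nodes) - nodes$origin_index) *
    nodes$spacing * nodes$orientation
}

cumulative_arclength <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  c(0, cumsum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                            pts[-n, , drop = FALSE])^2))))
}

#' Resample a polyline to equidistant nodes
#'
#' Places `n_nodes` nodes at arc lengths k L / (n_nodes - 1),
#' k = 0, ..., n_nodes - 1, by linear interpolation along the polyline; the
#' first and last nodes coincide with the polyline endpoints.
#'
#' @param polyline Numeric matrix of ordered vertices (rows) in 3D.
#' @param n_nodes Number of nodes (>= 2; the returned `path_nodes` object
#'   requires >= 3).
#' @param as_path If `FALSE`, return the bare coordinate matrix (used for
#'   2-node resampling and internal iteration).
#' @return A `path_nodes` object (or matrix when `as_path = FALSE`).
#' @export
resample_equidistant <- function(polyline, n_nodes, as_path = TRUE) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 vertices")
  if (n_nodes < 2L) stop("n_nodes must be >= 2")
  s <- cumulative_arclength(polyline)
  L <- s[length(s)]
  if (L <= 0) stop("zero-length polyline")
  # drop zero-length segments so approx() sees strictly increasing abscissae
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; polyline <- polyline[keep, , drop = FALSE]
  at <- function(tgt) {
    out <- vapply(1:3, function(j)
      stats::approx(s, polyline[, j], xout = tgt)$y, numeric(length(tgt)))
    matrix(out, nrow = length(tgt))
  }
  tgt <- seq(0, L, length.out = n_nodes)
  nodes <- at(tgt)
  # equalise consecutive (chord) distances: on curved polylines equal arc
  # steps give slightly unequal chords, so iterate a chord-length
  # reparameterisation to a fixed point (straight polylines are unchanged)
  for (it in 1:100) {
    ch <- sqrt(rowSums(diff(nodes)^2))
    if (any(ch <= 0)) break
    if (max(ch) / min(ch) - 1 < 1e-9) break
    cum <- c(0, cumsum(ch))
    tgt <- stats::approx(cum, tgt, xout = seq(0, cum[n_nodes],
                                              length.out = n_nodes))$y
    nodes <- at(tgt)
  }
  if (!as_path) return(nodes)
  path_nodes(nodes)
}

#' Set the path frame (origin node and orientation)
#'
#' Returns the same nodes with the origin/orientation metadata replaced:
#' the origin node gets xi* = 0 and `orientation` decides which direction
#' along the path counts as positive.
#'
#' @param nodes A `path_nodes` object.
#' @param origin_index 1-based node index set to xi* = 0.
#' @param orientation `+1` or `-1`.
#' @return A `path_nodes` object; node coordinates are unchanged.
#' @export
set_path_frame <- function(nodes, origin_index, orientation = 1L) {
  stopifnot(inherits(nodes, "path_nodes"))
  path_nodes(nodes$nodes, origin_index = origin_index,
             orientation = orientation)
}

#' Fit a principal curve through a point cloud
#'
#' Iterative projection/local-averaging principal-curve fit
#' (Hastie-Stuetzle style). The curve is initialised along the first
#' principal component of the cloud; each iteration projects every point
#' onto the current polyline, kernel-smooths each coordinate against the
#' projected arc length (Gaussian Nadaraya-Watson with bandwidth
#' `smoothing` x total arc length), and resamples to equidistant nodes.
#' Iteration stops when the mean node displacement falls below `tol`
#' (Angstrom) or after `max_iter` iterations.
#'
#' @param points Numeric matrix of 3D positions (rows), e.g. water-oxygen
#'   coordinates pooled over frames.
#' @param n_nodes Number of equidistant nodes on the returned path
#'   (default 25).
#' @param smoothing Kernel bandwidth as a fraction of total arc length
#'   (default 0.10).
#' @param max_iter Maximum number of projection/smoothing iterations.
#' @param tol Convergence threshold on mean node displacement (Angstrom).
#' @param weights Optional non-negative per-point weights.
#' @return A `path_nodes` object.
#' @export
fit_principal_curve <- function(points, n_nodes = 25L, smoothing = 0.10,
                                max_iter = 50L, tol = 1e-4, weights = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns")
  if (nrow(points) < 4L) stop("need at least 4 points")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  if (smoothing <= 0 || max_iter < 1L || tol <= 0)
    stop("smoothing, max_iter and tol must be positive")
  if (nrow(points) < n_nodes) stop("need at least n_nodes points")
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (length(weights) != nrow(points) || any(weights < 0))
    stop("weights must be non-negative, one per point")

  extent <- max(apply(points, 2, function(v) diff(range(v))))
  if (extent <= 1e-12) stop("degenerate point cloud")

  # initial curve: first principal component segment through the cloud
  ctr <- colMeans(points)
  pc1 <- svd(sweep(points, 2, ctr), nu = 0, nv = 1)$v[, 1]
  t0 <- drop(sweep(points, 2, ctr) %*% pc1)
  init <- rbind(ctr + min(t0) * pc1, ctr + max(t0) * pc1)
  curve <- resample_equidistant(init, n_nodes, as_path = FALSE)

  for (iter in seq_len(max_iter)) {
    proj <- project_onto_polyline(points, curve)
    lam <- proj$arclen
    L <- max(cumulative_arclength(curve))
    bw <- smoothing * L
    # local linear kernel smooth of each coordinate against projected arc
    # length (local-linear rather than constant to avoid boundary
    # shrinkage), evaluated at quantile-spread targets of the projections
    targets <- stats::quantile(lam, probs = seq(0, 1, length.out = n_nodes),
                               names = FALSE, type = 7)
    sm <- vapply(targets, function(t0) {
      w <- weights * exp(-0.5 * ((lam - t0) / bw)^2)
      d <- lam - t0
      sw <- sum(w); sd1 <- sum(w * d); sd2 <- sum(w * d^2)
      det <- sw * sd2 - sd1^2
      vapply(1:3, function(j) {
        sy <- sum(w * points[, j]); sdy <- sum(w * d * points[, j])
        if (abs(det) < 1e-12 * max(sw, 1)^2 * max(sd2, 1e-12))
          sy / sw
        else
          (sd2 * sy - sd1 * sdy) / det   # local-linear fit value at t0
      }, numeric(1))
    }, numeric(3))
    sm <- t(sm)
    new_curve <- resample_equidistant(sm, n_nodes, as_path = FALSE)
    disp <- mean(sqrt(rowSums((new_curve - curve)^2)))
    curve <- new_curve
    if (disp < tol) break
  }
  path_nodes(curve)
}

# Project points onto a polyline; returns per-point arc length and squared
# distance. Ties between segments resolved toward the lower segment index.
project_onto_polyline <- function(points, polyline) {
  nseg <- nrow(polyline) - 1L
  s0 <- cumulative_arclength(polyline)
  best_d2 <- rep(Inf, nrow(points))
  best_lam <- numeric(nrow(points))
  for (k in seq_len(nseg)) {
    a <- polyline[k, ]; b <- polyline[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 <= 0) next
    t <- (sweep(points, 2, a) %*% ab) / len2
    t <- pmin(pmax(drop(t), 0), 1)
    foot <- outer(t, ab) + matrix(a, nrow(points), 3, byrow = TRUE)
    d2 <- rowSums((points - foot)^2)
    upd <- d2 < best_d2 - 1e-15   # strict: keep lower segment index on ties
    best_d2[upd] <- d2[upd]
    best_lam[upd] <- s0[k] + t[upd] * sqrt(len2)
  }
  list(arclen = best_lam, dist2 = best_d2)
}
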