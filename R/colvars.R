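#' One snapshot of channel hydration
#'
#' A `hydration_frame` holds the water-oxygen positions and the
#' excess-charge probe position (the tracked centre of excess charge of the
#' shuttling proton) for one configuration.
#'
#' @param water_oxygens Numeric matrix of water-oxygen coordinates
#'   (rows, Angstrom).
#' @param probe Numeric length-3 probe coordinate (Angstrom).
#' @param box Optional length-3 orthorhombic box lengths (Angstrom); when
#'   present, minimum-image distances are used.
#' @return An object of class `hydration_frame`.
#' @export
hydration_frame <- function(water_oxygens, probe, box = NULL) {
  water_oxygens <- as.matrix(water_oxygens)
  if (ncol(water_oxygens) != 3L) stop("water_oxygens must have 3 columns")
  if (!all(is.finite(water_oxygens))) stop("water coordinates must be finite")
  probe <- as.numeric(probe)
  if (length(probe) != 3L || !all(is.finite(probe)))
    stop("probe must be a finite 3-vector")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box lengths must be three positive finite values")
  }
  structure(list(water_oxygens = unname(water_oxygens), probe = probe,
                 box = box), class = "hydration_frame")
}

#' @export
print.hydration_frame <- function(x, ...) {
  cat(sprintf("hydration_frame: %d water oxygens, probe at (%.2f, %.2f, %.2f)%s\n",
              nrow(x$water_oxygens), x$probe[1], x$probe[2], x$probe[3],
              if (is.null(x$box)) "" else " [periodic]"))
  invisible(x)
}

# pairwise distances from one point to rows of a matrix, minimum image if box
point_distances <- function(point, coords, box = NULL) {
  d <- sweep(coords, 2, point)
  if (!is.null(box)) d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  sqrt(rowSums(d^2))
}

# rational switching function sigma(r) = (1-(r/r0)^n)/(1-(r/r0)^m), n < m;
# removable singularity at r = r0 handled by the l'Hopital limit n/m.
# A finite dmax applies the usual shift-and-rescale so sigma is exactly 0
# beyond dmax (and 1 at r = 0), keeping occupancies compactly supported.
switch_rational <- function(r, r0, n = 6L, m = 12L, dmax = Inf) {
  raw <- function(r) {
    x <- r / r0
    num <- 1 - x^n
    den <- 1 - x^m
    pmax(ifelse(abs(den) < 1e-10, (n / m) * x^(n - m), num / den), 0)
  }
  if (!is.finite(dmax)) return(raw(r))
  sd <- raw(dmax)
  ifelse(r >= dmax, 0, pmax((raw(r) - sd) / (1 - sd), 0))
}

# smooth cap of a non-negative sum at 1: softmin x - log(1+exp(k(x-1)))/k
soft_cap <- function(x, k = 20) {
  y <- k * (x - 1)
  sp <- ifelse(y > 30, y, log1p(exp(pmin(y, 30))))
  x - sp / k
}

#' Water occupancy of a single path node
#'
#' Sums a smooth rational switching function
#' \eqn{\sigma(r) = (1-(r/r_0)^n)/(1-(r/r_0)^m)} over all water oxygens and
#' smoothly caps the sum at 1 (softmin with sharpness `cap_k`), giving a
#' continuous, differentiable occupancy in \[0, 1\].
#'
#' @param frame A `hydration_frame`.
#' @param node Numeric length-3 node coordinate (Angstrom).
#' @param switch_r0 Switching radius r0 in Angstrom (default 2.5).
#' @param switch_exponents Integer pair (n, m), n < m (default c(6, 12)).
#' @param switch_dmax Hard cutoff beyond which sigma is exactly 0, applied
#'   by shift-and-rescale (default `2.5 * switch_r0`; `Inf` disables).
#' @param cap Apply the smooth cap at 1 (default `TRUE`); `FALSE` returns the
#'   raw switching-function sum.
#' @param cap_k Sharpness of the soft cap (default 20).
#' @return Occupancy value.
#' @export
node_occupancy <- function(frame, node, switch_r0 = 2.5,
                           switch_exponents = c(6L, 12L),
                           switch_dmax = 2.5 * switch_r0,
                           cap = TRUE, cap_k = 20) {
  stopifnot(inherits(frame, "hydration_frame"))
  if (switch_r0 <= 0) stop("switch_r0 must be positive")
  n <- switch_exponents[1]; m <- switch_exponents[2]
  if (n >= m) stop("switch exponents must satisfy n < m")
  r <- point_distances(as.numeric(node), frame$water_oxygens, frame$box)
  s <- sum(switch_rational(r, switch_r0, n, m, switch_dmax))
  if (cap) soft_cap(s, cap_k) else s
}

#' Per-node occupancy profile of a frame
#'
#' @inheritParams node_occupancy
#' @param nodes A `path_nodes` object.
#' @return Numeric vector of occupancies, one per node, in \[0, 1\].
#' @export
occupancy_profile <- function(frame, nodes, switch_r0 = 2.5,
                              switch_exponents = c(6L, 12L),
                              switch_dmax = 2.5 * switch_r0,
                              cap = TRUE, cap_k = 20) {
  stopifnot(inherits(nodes, "path_nodes"))
  vapply(seq_len(nodes$n_nodes), function(i)
    node_occupancy(frame, nodes$nodes[i, ], switch_r0, switch_exponents,
                   switch_dmax, cap, cap_k),
    numeric(1))
}

#' Water-wire connectivity phi
#'
#' The geometric mean of the pair-averaged node occupancies
#' \eqn{\phi = (\prod_{i=1}^{N-1} f_{i,i+1})^{1/(N-1)}} with
#' \eqn{f_{i,i+1} = (o_i + o_{i+1})/2}. Computed in log space; returns 0 if
#' any pair average is 0.
#'
#' @param occ Numeric vector of per-node occupancies in \[0, 1\].
#' @return phi in \[0, 1\].
#' @export
water_wire_connectivity <- function(occ) {
  occ <- as.numeric(occ)
  n <- length(occ)
  if (n < 2L) stop("need at least 2 node occupancies")
  if (any(occ < -1e-9 | occ > 1 + 1e-9)) stop("occupancies must be in [0,1]")
  f <- (occ[-n] + occ[-1L]) / 2
  if (any(f <= 0)) return(0)
  exp(mean(log(f)))
}

#' Proton-localised water-wire connectivity phi*
#'
#' Weighted geometric mean of the pair-averaged occupancies, each pair
#' weighted by a Gaussian in the distance from the excess-charge probe to
#' the midpoint of the node pair, so the value reflects hydration in the
#' immediate vicinity of the proton. Reduces to [water_wire_connectivity()]
#' as `locality_sigma` grows large.
#'
#' @param occ Numeric vector of per-node occupancies.
#' @param nodes A `path_nodes` object.
#' @param probe Numeric length-3 probe coordinate (Angstrom).
#' @param locality_sigma Gaussian locality width in Angstrom (default 3).
#' @return phi* in \[0, 1\].
#' @export
local_connectivity <- function(occ, nodes, probe, locality_sigma = 3) {
  stopifnot(inherits(nodes, "path_nodes"))
  if (locality_sigma <= 0) stop("locality_sigma must be positive")
  occ <- as.numeric(occ)
  n <- nodes$n_nodes
  if (length(occ) != n) stop("occupancy length must match node count")
  f <- (occ[-n] + occ[-1L]) / 2
  mid <- (nodes$nodes[-n, , drop = FALSE] + nodes$nodes[-1L, , drop = FALSE]) / 2
  d <- point_distances(as.numeric(probe), mid)
  w <- exp(-d^2 / (2 * locality_sigma^2))
  if (all(w < 1e-12)) stop("probe off-path")
  if (any(f <= 0 & w > 0)) return(0)
  exp(sum(w * log(f)) / sum(w))
}

#' Path-progress collective variable xi
#'
#' Continuous progress of the excess-charge probe along the node path: the
#' geometric path CV built from the closest node i1, the adjacent node i2
#' nearer the probe, and the vectors v1 (node i1 to probe, negated), v2
#' (probe relative to the node opposite i2) and v3 (node i1 to node i2):
#' \deqn{\xi' = i_1 + \mathrm{sign}(i_2-i_1)\,
#'   \frac{\sqrt{(v_1\cdot v_3)^2 - |v_3|^2(|v_1|^2-|v_2|^2)} - v_1\cdot v_3
#'   - |v_3|^2}{2|v_3|^2}}
#' At a path terminus the missing opposite neighbour is linearly
#' extrapolated. The raw value `xi_raw` is a continuous (1-based) node
#' index; `xi_star = (xi_raw - origin_index) * spacing * orientation` is the
#' shifted/rescaled form, numerically comparable to distances in Angstrom.
#'
#' @param probe Numeric length-3 probe coordinate.
#' @param nodes A `path_nodes` object.
#' @param cutoff Maximum allowed probe-to-closest-node distance (Angstrom);
#'   beyond it the probe is considered off-path (default `Inf`).
#' @return List with `xi_raw`, `xi_star`, `i1`, `i2`, and the vectors
#'   `v1`, `v2`, `v3`.
#' @export
path_progress <- function(probe, nodes, cutoff = Inf) {
  stopifnot(inherits(nodes, "path_nodes"))
  probe <- as.numeric(probe)
  if (length(probe) != 3L || !all(is.finite(probe)))
    stop("probe must be a finite 3-vector")
  nd <- nodes$nodes
  n <- nodes$n_nodes
  d <- point_distances(probe, nd)
  i1 <- which.min(d)                       # ties resolve to lower index
  if (d[i1] > cutoff) stop("probe off-path")
  cand <- c(i1 - 1L, i1 + 1L)
  cand <- cand[cand >= 1L & cand <= n]
  i2 <- cand[which.min(d[cand])]           # adjacent node nearer the probe
  sgn <- sign(i2 - i1)
  v1 <- nd[i1, ] - probe
  v3 <- nd[i2, ] - nd[i1, ]
  iv <- 2L * i1 - i2                       # node on the opposite side of i2
  opp <- if (iv >= 1L && iv <= n) nd[iv, ] else 2 * nd[i1, ] - nd[i2, ]
  v2 <- probe - opp
  v33 <- sum(v3^2)
  v13 <- sum(v1 * v3)
  disc <- v13^2 - v33 * (sum(v1^2) - sum(v2^2))
  disc <- max(disc, 0)                     # clamp round-off at exact node hits
  xi_raw <- i1 + sgn * (sqrt(disc) - v13 - v33) / (2 * v33)
  xi_star <- (xi_raw - nodes$origin_index) * nodes$spacing * nodes$orientation
  list(xi_raw = xi_raw, xi_star = xi_star, i1 = i1, i2 = i2,
       v1 = v1, v2 = v2, v3 = v3)
}

#' Collective-variable time series over hydration frames
#'
#' Evaluates xi*, phi and phi* for every frame and returns a COLVAR-style
#' table.
#'
#' @param frames List of `hydration_frame` objects.
#' @param nodes A `path_nodes` object.
#' @param dt Time increment per frame (arbitrary units, default 1).
#' @param switch_r0,switch_exponents,cap,cap_k Occupancy parameters, see
#'   [node_occupancy()].
#' @param locality_sigma Locality width for phi*, see [local_connectivity()].
#' @param cutoff Off-path cutoff for [path_progress()].
#' @return A `colvar_series` data frame with columns `time`, `xi_star`,
#'   `phi`, `phi_star`.
#' @export
cv_timeseries <- function(frames, nodes, dt = 1,
                          switch_r0 = 2.5, switch_exponents = c(6L, 12L),
                          switch_dmax = 2.5 * switch_r0,
                          cap = TRUE, cap_k = 20, locality_sigma = 3,
                          cutoff = Inf) {
  if (length(frames) == 0L) stop("no frames")
  rows <- lapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    occ <- occupancy_profile(fr, nodes, switch_r0, switch_exponents,
                             switch_dmax, cap, cap_k)
    pp <- path_progress(fr$probe, nodes, cutoff)
    data.frame(time = (k - 1) * dt,
               xi_star = pp$xi_star,
               phi = water_wire_connectivity(occ),
               phi_star = local_connectivity(occ, nodes, fr$probe,
                                             locality_sigma))
  })
  colvar_series(do.call(rbind, rows))
}

#' COLVAR-style time series container
#'
#' A data frame of time-stamped collective-variable values, optionally
#' carrying the harmonic restraints under which it was sampled (needed by
#' WHAM) and the instantaneous bias energy.
#'
#' @param df Data frame whose first column is `time` (strictly increasing).
#' @param restraints Optional list of restraints, each
#'   `list(cv = <column name>, center = <numeric>, k = <numeric>)` with `k`
#'   in kcal/mol per CV unit squared.
#' @return A `colvar_series` object.
#' @export
colvar_series <- function(df, restraints = NULL) {
  stopifnot(is.data.frame(df), names(df)[1] == "time")
  if (nrow(df) > 1L && any(diff(df$time) <= 0))
    stop("time stamps must be strictly increasing")
  if (anyNA(df)) stop("missing values in series")
  if (!is.null(restraints)) {
    for (r in restraints) {
      stopifnot(is.list(r), r$cv %in% names(df), r$k > 0)
    }
  }
  structure(df, class = c("colvar_series", "data.frame"),
            restraints = restraints)
}

#' @export
print.colvar_series <- function(x, ...) {
  r <- attr(x, "restraints")
  cat(sprintf("colvar_series: %d rows, fields %s\n", nrow(x),
              paste(names(x), collapse = ", ")))
  if (!is.null(r))
    for (ri in r)
      cat(sprintf("  restraint: %s centered at %.4g, k = %.4g kcal/mol\n",
                  ri$cv, ri$center, ri$k))
  invisible(x)
}
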