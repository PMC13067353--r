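#' Minimum free-energy path through a 2D PMF
#'
#' Computes, on the 8-connected graph of sampled bins, the path from the
#' reactant to the product region that minimises the maximum free energy
#' encountered (the min-max / lowest-saddle criterion), tie-broken by the
#' minimal path integral of F; masked (unsampled) bins are never crossed.
#' The bin path is then smoothed by a width-3 moving average and projected
#' onto the first axis to give the 1D profile, barrier and reaction free
#' energy.
#'
#' @param pmf A 2D [fe_grid()].
#' @param start_region,end_region Named lists of coordinate ranges defining
#'   the reactant/product basins, e.g.
#'   `list(xi_star = c(-1, 1), phi_star = c(0.6, 0.9))`; omitted axes span
#'   the full range. The basin anchor is the minimum-F sampled bin inside
#'   the region.
#' @return An `mfep_result`: `path` (smoothed xi/phi/F table), `path_bins`
#'   (raw bin-index path), `profile` (projected 1D profile), `barrier`,
#'   `dG`, `reverse_barrier` (kcal/mol) and `saddle` location.
#' @export
find_mfep <- function(pmf, start_region, end_region) {
  stopifnot(inherits(pmf, "fe_grid"), pmf$dim == 2L)
  n1 <- pmf$axes[[1]]$n; n2 <- pmf$axes[[2]]$n
  mids1 <- axis_mids(pmf$axes[[1]]); mids2 <- axis_mids(pmf$axes[[2]])
  Fv <- as.numeric(pmf$F)
  mask <- as.logical(pmf$mask)

  region_bins <- function(region) {
    keep1 <- rep(TRUE, n1); keep2 <- rep(TRUE, n2)
    for (nm in names(region)) {
      rg <- region[[nm]]
      if (nm == pmf$axes[[1]]$name) keep1 <- mids1 >= rg[1] & mids1 <= rg[2]
      else if (nm == pmf$axes[[2]]$name) keep2 <- mids2 >= rg[1] & mids2 <= rg[2]
      else stop("unknown axis in region: ", nm)
    }
    which(outer(keep1, keep2) & matrix(mask, n1, n2))
  }
  sb <- region_bins(start_region)
  eb <- region_bins(end_region)
  if (length(sb) == 0L || length(eb) == 0L)
    stop("basin region contains no sampled bins")
  start <- sb[which.min(Fv[sb])]
  end <- eb[which.min(Fv[eb])]

  # stage 1: bottleneck Dijkstra (minimise max F along the path);
  # stage 2: sum-Dijkstra restricted to bins with F <= bottleneck, which
  # yields the minimal path integral among all min-max-optimal paths.
  nb <- n1 * n2
  off_i <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  off_j <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  neighbours <- function(u, allowed) {
    ui <- (u - 1L) %% n1 + 1L
    uj <- (u - 1L) %/% n1 + 1L
    vi <- ui + off_i; vj <- uj + off_j
    okv <- vi >= 1L & vi <= n1 & vj >= 1L & vj <= n2
    v <- vi[okv] + (vj[okv] - 1L) * n1
    v[allowed[v]]
  }
  dijkstra <- function(cost_update, allowed) {
    dist <- rep(Inf, nb); parent <- rep(NA_integer_, nb)
    visited <- rep(FALSE, nb)
    dist[start] <- Fv[start]
    repeat {
      open <- !visited & is.finite(dist)
      if (!any(open)) break
      u <- which(open)[which.min(dist[open])]
      if (u == end) break
      visited[u] <- TRUE
      v <- neighbours(u, allowed)
      v <- v[!visited[v]]
      if (length(v)) {
        nd <- cost_update(dist[u], Fv[v])
        upd <- nd < dist[v] - 1e-12
        v <- v[upd]
        dist[v] <- nd[upd]; parent[v] <- u
      }
    }
    list(dist = dist, parent = parent)
  }
  s1 <- dijkstra(function(d, f) pmax(d, f), mask)
  if (!is.finite(s1$dist[end]))
    stop("basins are disconnected through sampled bins")
  L <- s1$dist[end]
  allowed2 <- mask & Fv <= L + 1e-9
  s2 <- dijkstra(function(d, f) d + f, allowed2)
  parent <- s2$parent

  path <- end
  while (path[1] != start) path <- c(parent[path[1]], path)
  pi_ <- (path - 1L) %% n1 + 1L
  pj <- (path - 1L) %/% n1 + 1L
  raw <- data.frame(xi = mids1[pi_], phi = mids2[pj], F = Fv[path])

  ma3 <- function(v) {
    n <- length(v)
    if (n < 3L) return(v)
    out <- v
    out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
    out
  }
  smooth <- data.frame(xi = ma3(raw$xi), phi = ma3(raw$phi), F = ma3(raw$F))
  names(smooth) <- names(raw) <- c(pmf$axes[[1]]$name, pmf$axes[[2]]$name, "F")

  res <- structure(list(path = smooth, path_raw = raw,
                        path_bins = cbind(i = pi_, j = pj),
                        axes = pmf$axes, bottleneck = L),
                   class = "mfep_result")
  res$profile <- project_profile(res)
  bd <- barrier_and_dg(res$profile,
                       reactant_range = range(smooth[[1]][1]) + c(-1, 1) * 1e-9,
                       product_range = range(smooth[[1]][nrow(smooth)]) + c(-1, 1) * 1e-9,
                       widen = TRUE)
  res$barrier <- bd$barrier
  res$dG <- bd$dG
  res$reverse_barrier <- bd$reverse_barrier
  ksad <- which.max(smooth$F)
  res$saddle <- c(smooth[[1]][ksad], smooth[[2]][ksad], F = smooth$F[ksad])
  names(res$saddle) <- c(names(smooth)[1:2], "F")
  res
}

#' @export
print.mfep_result <- function(x, ...) {
  cat(sprintf("mfep_result: %d path points; barrier %.3f, dG %.3f, reverse %.3f kcal/mol\n",
              nrow(x$path), x$barrier, x$dG, x$reverse_barrier))
  cat(sprintf("  saddle at %s = %.3f, %s = %.3f\n",
              names(x$saddle)[1], x$saddle[1], names(x$saddle)[2], x$saddle[2]))
  invisible(x)
}

#' Project an MFEP onto its progress coordinate
#'
#' Bins the path points by the first-axis coordinate and takes the minimum
#' F per bin (so hairpin stretches where the path doubles back collapse to
#' their lowest branch), returning a monotone 1D profile shifted to
#' minimum 0.
#'
#' @param x An `mfep_result`, or a data frame whose first column is the
#'   progress coordinate and whose `F` column holds free energies (then
#'   `breaks` is required).
#' @param breaks Bin boundaries for the progress coordinate (ignored for
#'   `mfep_result`, which uses the PMF axis).
#' @return Data frame with the binned coordinate and `F` (kcal/mol, min 0).
#' @export
project_profile <- function(x, breaks = NULL) {
  if (inherits(x, "mfep_result")) {
    ax <- x$axes[[1]]
    breaks <- seq(ax$min, ax$max, length.out = ax$n + 1L)
    df <- x$path
  } else {
    df <- x
    if (is.null(breaks)) stop("breaks required for a bare path table")
  }
  co <- df[[1]]
  Fv <- df$F
  bin <- findInterval(co, breaks, rightmost.closed = TRUE)
  ok <- bin >= 1L & bin <= length(breaks) - 1L
  bin <- bin[ok]; co <- co[ok]; Fv <- Fv[ok]
  ub <- sort(unique(bin))
  if (length(ub) < 2L) stop("path spans a single bin of the progress coordinate")
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  Fmin <- vapply(ub, function(b) min(Fv[bin == b]), numeric(1))
  out <- data.frame(mids[ub], Fmin - min(Fmin))
  names(out) <- c(names(df)[1], "F")
  out
}

#' Barrier and reaction free energy from a 1D profile
#'
#' `dF = max F between the basin minima - reactant minimum`,
#' `dG = product minimum - reactant minimum`; the reverse barrier is
#' `dF - dG`.
#'
#' @param profile Data frame: first column the progress coordinate, column
#'   `F` the free energy (kcal/mol).
#' @param reactant_range,product_range Coordinate ranges containing the two
#'   basins.
#' @param widen Internal: expand degenerate single-point ranges to the
#'   nearest profile point.
#' @return List with `barrier`, `dG`, `reverse_barrier`, `saddle_x`,
#'   `reactant_x`, `product_x`.
#' @export
barrier_and_dg <- function(profile, reactant_range, product_range,
                           widen = FALSE) {
  x <- profile[[1]]; Fv <- profile$F
  pick_min <- function(rg) {
    in_rg <- which(x >= rg[1] & x <= rg[2])
    if (length(in_rg) == 0L) {
      if (!widen) stop("basin range contains no profile points")
      in_rg <- which.min(abs(x - mean(rg)))
    }
    in_rg[which.min(Fv[in_rg])]
  }
  iR <- pick_min(reactant_range)
  iP <- pick_min(product_range)
  lo <- min(iR, iP); hi <- max(iR, iP)
  if (hi - lo < 2L) stop("barrierless: no interior points between basins")
  interior <- (lo + 1L):(hi - 1L)
  imax <- interior[which.max(Fv[interior])]
  if (Fv[imax] <= max(Fv[iR], Fv[iP]) + 1e-12)
    stop("barrierless: no interior maximum above the basin minima")
  barrier <- Fv[imax] - Fv[iR]
  dG <- Fv[iP] - Fv[iR]
  list(barrier = barrier, dG = dG, reverse_barrier = barrier - dG,
       saddle_x = x[imax], reactant_x = x[iR], product_x = x[iP])
}

#' Eyring transition-state-theory rate
#'
#' `k = (kB T / h) exp(-dF / (R T))` with CODATA constants and R in
#' kcal/(mol K).
#'
#' @param barrier Free-energy barrier dF in kcal/mol.
#' @param temperature Temperature in K (default 310).
#' @return A `rate_estimate`: `barrier`, `temperature`, `prefactor` (1/s)
#'   and `rate` (1/s).
#' @examples
#' tst_rate(22, 310)$rate  # ~0.002 1/s
#' @export
tst_rate <- function(barrier, temperature = 310) {
  if (temperature <= 0) stop("temperature must be positive")
  pref <- pt_constants$kB * temperature / pt_constants$h
  rate <- pref * exp(-barrier / (pt_constants$R_kcal * temperature))
  structure(list(barrier = barrier, temperature = temperature,
                 prefactor = pref, rate = rate),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: dF = %.3f kcal/mol at %g K -> k = %.4g 1/s (kBT/h = %.4g 1/s)\n",
              x$barrier, x$temperature, x$rate, x$prefactor))
  invisible(x)
}
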