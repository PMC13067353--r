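# shared fixtures and small oracles used across test files

# straight equidistant path along x: n nodes, spacing d, origin at node 1
straight_path <- function(n = 25, d = 1, origin = 1L, orientation = 1L) {
  set_path_frame(resample_equidistant(cbind(c(0, (n - 1) * d), 0, 0), n),
                 origin_index = origin, orientation = orientation)
}

# rotation matrix about a fixed arbitrary axis (Rodrigues formula)
fixed_rotation <- function(angle = 1.1, axis = c(1, 2, 3)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# direct evaluation of the rational switching function (independent of the
# package's internals), with the same shift-and-rescale cutoff
oracle_switch <- function(r, r0, n = 6, m = 12, dmax = 2.5 * r0) {
  raw <- function(r) {
    x <- r / r0
    if (abs(1 - x^m) < 1e-10) return((n / m) * x^(n - m))
    (1 - x^n) / (1 - x^m)
  }
  if (r >= dmax) return(0)
  sd <- raw(dmax)
  max((raw(r) - sd) / (1 - sd), 0)
}

# brute-force weighted geometric mean of pair-averaged occupancies
oracle_phi_local <- function(occ, nodes, probe, sigma) {
  n <- length(occ)
  f <- (occ[-n] + occ[-1]) / 2
  mid <- (nodes$nodes[-n, , drop = FALSE] + nodes$nodes[-1, , drop = FALSE]) / 2
  d <- sqrt(rowSums(sweep(mid, 2, probe)^2))
  w <- exp(-d^2 / (2 * sigma^2))
  exp(sum(w * log(f)) / sum(w))
}

# analytic 1D quartic double well used as a WHAM reference
dw_quartic <- function(x, a = 3, tilt = 0.5) a * (x^2 - 1)^2 + tilt * x

# build a colvar_series of direct (exact) Boltzmann samples from a biased
# 1D potential, carried in the xi_star column
exact_window <- function(f, center, k, n, temperature = 310,
                         domain = c(-1.8, 1.8), n_grid = 8192L) {
  x <- sample_boltzmann_1d(f, domain, temperature, n,
                           bias = function(x) 0.5 * k * (x - center)^2,
                           n_grid = n_grid)
  colvar_series(data.frame(time = seq_len(n), xi_star = x),
                restraints = list(restraint("xi_star", center, k)))
}

# independent, loop-based WHAM fixed-point oracle (textbook equations,
# no vectorisation shared with the implementation)
oracle_wham <- function(counts, U, N, kT, n_iter = 20000, tol = 1e-12) {
  K <- nrow(counts); nbins <- ncol(counts)
  f <- numeric(K)
  H <- colSums(counts)
  for (it in seq_len(n_iter)) {
    p <- numeric(nbins)
    for (b in seq_len(nbins)) {
      den <- 0
      for (k in seq_len(K)) den <- den + N[k] * exp((f[k] - U[k, b]) / kT)
      p[b] <- if (den > 0) H[b] / den else 0
    }
    p <- p / sum(p)
    fn <- numeric(K)
    for (k in seq_len(K)) {
      z <- 0
      for (b in seq_len(nbins)) z <- z + exp(-U[k, b] / kT) * p[b]
      fn[k] <- -kT * log(z)
    }
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  list(f = f, p = p)
}

# independent bottleneck oracle: smallest threshold L such that start and
# end are connected through sampled bins with F <= L (8-connected BFS)
oracle_bottleneck <- function(F, mask, start, end) {
  n1 <- nrow(F); n2 <- ncol(F)
  levels <- sort(unique(as.numeric(F[mask])))
  connected_at <- function(L) {
    ok <- mask & F <= L
    if (!ok[start[1], start[2]] || !ok[end[1], end[2]]) return(FALSE)
    seen <- matrix(FALSE, n1, n2)
    queue <- list(start)
    seen[start[1], start[2]] <- TRUE
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      if (all(c0 == end)) return(TRUE)
      for (di in -1:1) for (dj in -1:1) {
        i <- c0[1] + di; j <- c0[2] + dj
        if (i >= 1 && i <= n1 && j >= 1 && j <= n2 &&
            ok[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
    FALSE
  }
  for (L in levels) if (connected_at(L)) return(L)
  Inf
}
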