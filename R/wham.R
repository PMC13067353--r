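#' Free-energy grid axis
#'
#' @param name CV name (must match a `colvar_series` column for WHAM).
#' @param min,max Axis range; bins are half-open `[low, high)`.
#' @param n Number of bins.
#' @return An `fe_axis` list.
#' @export
fe_axis <- function(name, min, max, n) {
  stopifnot(max > min, n >= 2)
  structure(list(name = name, min = min, max = max, n = as.integer(n)),
            class = "fe_axis")
}

axis_mids <- function(ax) {
  w <- (ax$max - ax$min) / ax$n
  ax$min + (seq_len(ax$n) - 0.5) * w
}

as_axes <- function(grid) {
  if (inherits(grid, "fe_axis")) list(grid) else grid
}

#' Free-energy grid (PMF) container
#'
#' @param axes List of [fe_axis()] (length 1 or 2).
#' @param F Free energy per bin (kcal/mol), `NA` in unsampled bins; vector
#'   (1D) or matrix (2D). Shifted so the minimum over sampled bins is 0.
#' @param se Per-bin standard error (same shape), 0/NA allowed.
#' @param mask Logical, `TRUE` where the bin is sampled.
#' @param counts Optional per-bin total counts.
#' @param temperature Temperature in K used in the reconstruction.
#' @return An `fe_grid` object.
#' @export
fe_grid <- function(axes, F, se = NULL, mask = NULL, counts = NULL,
                    temperature = NA_real_) {
  axes <- as_axes(axes)
  dims <- vapply(axes, function(a) a$n, integer(1))
  F <- array(F, dim = if (length(dims) == 1) c(dims, 1) else dims)
  if (length(dims) == 1) F <- drop(F)
  if (is.null(mask)) mask <- !is.na(F)
  if (is.null(se)) se <- array(0, dim = dim(as.array(F)))
  m <- suppressWarnings(min(F[mask]))
  F <- F - m
  structure(list(dim = length(dims), axes = axes, F = F, se = se,
                 mask = mask, counts = counts, temperature = temperature),
            class = "fe_grid")
}

#' @export
print.fe_grid <- function(x, ...) {
  cat(sprintf("fe_grid: %dD PMF over %s; %d/%d bins sampled, max F %.3f kcal/mol\n",
              x$dim,
              paste(vapply(x$axes, function(a)
                sprintf("%s [%g, %g] x %d", a$name, a$min, a$max, a$n),
                character(1)), collapse = " x "),
              sum(x$mask), length(x$mask), max(x$F[x$mask])))
  invisible(x)
}

# flattened bin index for each sample row; NA outside the grid
bin_index <- function(series, axes) {
  idx <- rep(1L, nrow(series))
  mult <- 1L
  for (ax in axes) {
    v <- series[[ax$name]]
    if (is.null(v)) stop("series lacks CV column: ", ax$name)
    w <- (ax$max - ax$min) / ax$n
    i <- floor((v - ax$min) / w)          # half-open [low, high)
    i[i < 0 | i >= ax$n] <- NA
    idx <- idx + as.integer(i) * mult
    mult <- mult * ax$n
  }
  idx
}

window_bias_energy <- function(restraints, axes) {
  # bias energy of one window evaluated at every bin centre (flattened)
  mids <- lapply(axes, axis_mids)
  coords <- if (length(axes) == 1L) {
    list(mids[[1]])
  } else {
    list(rep(mids[[1]], times = length(mids[[2]])),
         rep(mids[[2]], each = length(mids[[1]])))
  }
  names(coords) <- vapply(axes, `[[`, character(1), "name")
  U <- numeric(length(coords[[1]]))
  for (r in restraints %||% list()) {
    if (!r$cv %in% names(coords))
      stop("restrained CV not on the grid: ", r$cv)
    U <- U + 0.5 * r$k * (coords[[r$cv]] - r$center)^2
  }
  U
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted histogram analysis method (WHAM)
#'
#' Solves the standard self-consistent WHAM equations for a set of
#' harmonically restrained windows on a 1D or 2D grid: per-window free
#' energy constants `f_k` and the unbiased bin probabilities are iterated to
#' a relative tolerance `tol` on the `f_k` (kcal/mol). Unsampled bins are
#' masked, never interpolated.
#'
#' @param windows List of `colvar_series`, each carrying its restraints
#'   (an unrestrained series is treated as an unbiased window).
#' @param grid An [fe_axis()] or list of two.
#' @param temperature Temperature in K (default 310).
#' @param tol Convergence threshold on max |delta f_k| (default 1e-7).
#' @param max_iter Maximum iterations (default 1e5).
#' @param min_overlap Warn when a window shares fewer pooled counts than
#'   this with every other window (default 10).
#' @return An `fe_grid` with attributes `f_window` (converged constants)
#'   and `iterations`.
#' @export
wham <- function(windows, grid, temperature = 310, tol = 1e-7,
                 max_iter = 1e5, min_overlap = 10) {
  axes <- as_axes(grid)
  stopifnot(length(windows) >= 1L, length(axes) %in% 1:2)
  kT <- kT_kcal(temperature)
  nb <- prod(vapply(axes, function(a) a$n, integer(1)))
  K <- length(windows)

  counts <- matrix(0, K, nb)
  for (k in seq_len(K)) {
    idx <- bin_index(windows[[k]], axes)
    idx <- idx[!is.na(idx)]
    tb <- tabulate(idx, nbins = nb)
    counts[k, ] <- tb
  }
  N <- rowSums(counts)
  if (any(N == 0)) stop("window ", which(N == 0)[1], " has no samples on the grid")

  if (K > 1L) {
    # connectivity through shared sampled bins
    sampled <- counts > 0
    adj <- tcrossprod(sampled * 1) > 0    # windows sharing >= 1 sampled bin
    comp <- seq_len(K)
    repeat {
      new_comp <- vapply(seq_len(K), function(k) min(comp[adj[k, ]]),
                         numeric(1))
      if (identical(new_comp, comp)) break
      comp <- new_comp
    }
    if (length(unique(comp)) > 1L) {
      a <- which(comp == comp[1])[1]
      b <- which(comp != comp[1])[1]
      stop(sprintf("non-overlapping windows: no sampled-bin overlap between window %d and window %d", a, b))
    }
    ov <- vapply(seq_len(K), function(k) {
      others <- which(adj[k, ] & seq_len(K) != k)
      if (length(others) == 0L) return(0)
      max(vapply(others, function(l)
        sum(pmin(counts[k, ], counts[l, ])), numeric(1)))
    }, numeric(1))
    if (any(ov < min_overlap))
      warning(sprintf("window %d overlaps its best neighbour by only %d counts",
                      which.min(ov), as.integer(min(ov))))
  }

  H <- colSums(counts)
  B <- exp(-do.call(rbind, lapply(windows, function(w)
    window_bias_energy(attr(w, "restraints"), axes))) / kT)
  f <- numeric(K)
  sampled_bins <- H > 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    z <- N * exp(f / kT)
    denom <- drop(crossprod(B, z))
    p <- ifelse(denom > 0, H / denom, 0)
    p <- p / sum(p)
    Zk <- drop(B %*% p)
    f_new <- -kT * log(Zk)
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                   as.integer(max_iter), delta))
  }
  F <- ifelse(sampled_bins, -kT * log(pmax(p, .Machine$double.xmin)), NA_real_)
  dims <- vapply(axes, function(a) a$n, integer(1))
  shape <- function(v) if (length(dims) == 1L) v else matrix(v, dims[1], dims[2])
  out <- fe_grid(axes, shape(F), mask = shape(sampled_bins),
                 counts = shape(H), temperature = temperature)
  attr(out, "f_window") <- f
  attr(out, "iterations") <- iter
  out
}

split_blocks <- function(series, n_blocks) {
  n <- nrow(series)
  if (n < n_blocks) stop("series too short to split into ", n_blocks, " blocks")
  br <- floor(seq(0, n, length.out = n_blocks + 1))
  lapply(seq_len(n_blocks), function(j) {
    sub <- series[(br[j] + 1):br[j + 1], , drop = FALSE]
    colvar_series(as.data.frame(sub), restraints = attr(series, "restraints"))
  })
}

#' Block-averaged WHAM
#'
#' Splits every window's series into `n_blocks` equal time blocks, runs
#' WHAM per block, and averages the last `keep_last` block PMFs bin-wise
#' (bins must be sampled in all retained blocks), reporting the per-bin
#' standard error across the retained blocks. The early blocks, which carry
#' the slow relaxation of the sampled coordinates, are discarded; the
#' defaults follow the 8-block/keep-4 protocol of 2D umbrella sets (use
#' 6/3 for 1D sets).
#'
#' @inheritParams wham
#' @param n_blocks Number of equal time blocks (default 8).
#' @param keep_last Number of trailing blocks averaged (default 4).
#' @return List with `grid` (the block-averaged `fe_grid`, `se` filled) and
#'   `report` (a `block_report`: per-block PMFs, retained indices, per-bin SE).
#' @export
block_averaged_wham <- function(windows, grid, temperature = 310,
                                n_blocks = 8L, keep_last = 4L,
                                tol = 1e-7, max_iter = 1e5) {
  stopifnot(keep_last >= 1L, keep_last <= n_blocks)
  axes <- as_axes(grid)
  blocks <- lapply(seq_len(n_blocks), function(j) {
    ws <- lapply(seq_along(windows), function(k) {
      s <- split_blocks(windows[[k]], n_blocks)[[j]]
      idx <- bin_index(s, axes)
      if (all(is.na(idx)))
        stop(sprintf("empty histogram in window %d, block %d", k, j))
      s
    })
    suppressWarnings(wham(ws, axes, temperature, tol, max_iter))
  })
  retained <- (n_blocks - keep_last + 1L):n_blocks
  Fs <- lapply(blocks[retained], function(g) as.array(g$F))
  masks <- lapply(blocks[retained], function(g) as.array(g$mask))
  mask <- Reduce(`&`, masks)
  stack <- simplify2array(Fs)              # dims x keep_last
  nd <- length(dim(stack))
  Fbar <- apply(stack, seq_len(nd - 1L), mean)
  Fsd <- apply(stack, seq_len(nd - 1L), stats::sd)
  Fbar[!mask] <- NA_real_
  se <- Fsd / sqrt(keep_last)
  se[!mask] <- NA_real_
  g <- fe_grid(axes, Fbar, se = se, mask = mask, temperature = temperature)
  report <- structure(list(n_blocks = as.integer(n_blocks),
                           keep_last = as.integer(keep_last),
                           retained = retained, blocks = blocks,
                           se = se),
                      class = "block_report")
  list(grid = g, report = report)
}

#' @export
print.block_report <- function(x, ...) {
  cat(sprintf("block_report: %d blocks, averaged over the last %d (blocks %s)\n",
              x$n_blocks, x$keep_last, paste(x$retained, collapse = ", ")))
  cat(sprintf("  median per-bin SE %.3g kcal/mol\n",
              stats::median(x$se, na.rm = TRUE)))
  invisible(x)
}

#' Free energy from a well-tempered metadynamics hill log
#'
#' Evaluates the accumulated bias `V(s)` on the grid by summing the
#' deposited Gaussians and returns the bias-inversion estimate
#' `F(s) = -(gamma/(gamma-1)) V(s)`, minimum-shifted. An infinite bias
#' factor (standard metadynamics) gives `F = -V`. Because the instantaneous
#' bias oscillates around the free energy with an amplitude of order the
#' hill height, the inversion estimate is by default averaged over the
#' deposition history from `average_from` of the run onward (hills must be
#' in deposition order, as produced by [merge_walkers()]); `average_from =
#' 1` uses only the final bias.
#'
#' @param hills A `hills_log` (possibly merged across walkers).
#' @param grid An [fe_axis()] for the biased CV.
#' @param average_from Fraction of the deposition history after which the
#'   running inversion estimates are averaged (default 0.5).
#' @return An `fe_grid` (1D).
#' @export
metad_free_energy <- function(hills, grid, average_from = 0.5) {
  stopifnot(inherits(hills, "hills_log"),
            average_from >= 0, average_from <= 1)
  if (nrow(hills) == 0L) stop("empty hill log")
  ax <- as_axes(grid)[[1]]
  x <- axis_mids(ax)
  M <- nrow(hills)
  # averaging the running estimate over checkpoints M0..M is a weighted
  # hill sum: hill i contributes to all checkpoints j >= i
  M0 <- min(max(1L, floor(average_from * M) + 1L), M)
  K <- M - M0 + 1L
  w <- pmin(1, (M - pmax(seq_len(M), M0) + 1L) / K)
  V <- numeric(length(x))
  for (i in seq_len(M))
    V <- V + w[i] * hills$height[i] *
      exp(-0.5 * ((x - hills$center[i]) / hills$sigma[i])^2)
  g <- hills$biasf[1]
  fac <- if (is.finite(g)) g / (g - 1) else 1
  fe_grid(list(ax), -fac * V, mask = rep(TRUE, length(x)))
}

#' Merge walker hill logs
#'
#' Time-ordered merge of multiple hill logs (stable tie-break by walker id).
#'
#' @param logs List of `hills_log` objects with identical CV and bias factor.
#' @return A single merged `hills_log`.
#' @export
merge_walkers <- function(logs) {
  stopifnot(length(logs) >= 1L)
  cvs <- unique(vapply(logs, attr, character(1), "cv"))
  if (length(cvs) != 1L) stop("hill logs bias different CVs")
  bfs <- unique(unlist(lapply(logs, function(l) l$biasf)))
  if (length(bfs) > 1L) stop("hill logs have mismatched bias factors")
  df <- do.call(rbind, lapply(logs, as.data.frame))
  df <- df[order(df$time, df$walker), , drop = FALSE]
  rownames(df) <- NULL
  hills_log(df, cv = cvs)
}
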