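#' Sampler configuration
#'
#' Configuration of the overdamped Langevin (Euler-Maruyama) sampler used to
#' generate synthetic biased trajectories in CV space.
#'
#' @param n_steps Number of integration steps.
#' @param timestep Integration step in reduced time units (default 2e-4).
#' @param friction Friction coefficient in reduced units (default 1).
#' @param temperature Temperature in K (default 310).
#' @param seed RNG seed.
#' @param stride Record every `stride` steps (default 10).
#' @param x0 Optional initial point `c(xi, phi)`.
#' @param guard Divergence guard: error if xi leaves the surface domain
#'   extended by this fraction of its span on either side (default 0.5).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_steps, timestep = 2e-4, friction = 1,
                           temperature = 310, seed = 1, stride = 10,
                           x0 = NULL, guard = 0.5) {
  stopifnot(n_steps >= 1, timestep > 0, friction > 0, temperature > 0,
            stride >= 1, guard > 0)
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 friction = friction, temperature = temperature,
                 seed = as.integer(seed), stride = as.integer(stride),
                 x0 = x0, guard = guard),
            class = "sampler_config")
}

#' Harmonic restraint on one collective variable
#'
#' @param cv `"xi_star"` or `"phi_star"`.
#' @param center Restraint centre (CV units).
#' @param k Force constant in kcal/mol per CV unit squared.
#' @return A restraint spec list.
#' @export
restraint <- function(cv, center, k) {
  cv <- match.arg(cv, c("xi_star", "phi_star"))
  stopifnot(is.finite(center), k > 0)
  list(cv = cv, center = center, k = k)
}

restraints_matrix <- function(restraints) {
  if (is.null(restraints) || length(restraints) == 0L)
    return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(restraints, function(r)
    c(if (r$cv == "xi_star") 0 else 1, r$center, r$k)))
}

series_from_matrix <- function(m, restraints = NULL) {
  df <- data.frame(time = m[, 1], xi_star = m[, 2], phi_star = m[, 3],
                   bias = m[, 4])
  colvar_series(df, restraints = restraints)
}

#' Overdamped Langevin sampling on a model surface
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics on
#' `F(xi, phi)` plus any harmonic restraints, with reflecting boundaries on
#' phi at \[0, 1\]. Deterministic given the seed.
#'
#' @param surface A `model_surface`.
#' @param restraints Optional list of [restraint()] specs.
#' @param cfg A [sampler_config()].
#' @return A `colvar_series` with columns `time`, `xi_star`, `phi_star` and
#'   `bias` (instantaneous restraint energy, kcal/mol), carrying the
#'   restraints as metadata.
#' @export
langevin_sample <- function(surface, restraints = NULL, cfg) {
  stopifnot(inherits(surface, "model_surface"),
            inherits(cfg, "sampler_config"))
  x0 <- cfg$x0
  if (is.null(x0))
    x0 <- c(surface$stationary$reactant["xi"],
            surface$stationary$reactant["phi"])
  set.seed(cfg$seed)
  m <- langevin_cpp(surface$par, restraints_matrix(restraints),
                    as.numeric(x0), cfg$timestep, cfg$friction,
                    kT_kcal(cfg$temperature), cfg$n_steps, cfg$stride,
                    cfg$guard)
  series_from_matrix(m, restraints)
}

#' Umbrella-sampling window sets
#'
#' Builds the window lists for the two sampling protocols: 24
#' one-dimensional windows restraining xi*, or 130 two-dimensional windows
#' (13 xi* centres x 10 phi* centres) restraining both CVs with force
#' constants of 10-30 kcal/mol on xi* and 2500 kcal/mol on phi*.
#'
#' @param surface A `model_surface` (provides the xi range).
#' @param type `"1d"` or `"2d"`.
#' @param n_xi,n_phi Number of window centres per CV.
#' @param k_xi,k_phi Force constants (kcal/mol per CV unit^2).
#' @param phi_range Range of phi* window centres (2D only).
#' @return List of windows; each window is a list of [restraint()] specs.
#' @export
umbrella_windows <- function(surface, type = c("2d", "1d"),
                             n_xi = if (type == "2d") 13L else 24L,
                             n_phi = 10L, k_xi = if (type == "2d") 10 else 20,
                             k_phi = 2500, phi_range = c(0.65, 0.965)) {
  type <- match.arg(type)
  p <- surface$params
  xc <- seq(p$xi_R, p$xi_P, length.out = n_xi)
  if (type == "1d")
    return(lapply(xc, function(c1) list(restraint("xi_star", c1, k_xi))))
  pc <- seq(phi_range[1], phi_range[2], length.out = n_phi)
  out <- list()
  for (c1 in xc) for (c2 in pc)
    out[[length(out) + 1L]] <- list(restraint("xi_star", c1, k_xi),
                                    restraint("phi_star", c2, k_phi))
  out
}

#' Run a set of umbrella-sampling windows
#'
#' Samples each window with [langevin_sample()]; the initial configuration
#' of each window is the final point of the previous one (the proton is
#' dragged along the path), and the first window starts on the channel
#' floor at its xi* centre.
#'
#' @param surface A `model_surface`.
#' @param windows Window list from [umbrella_windows()] (>= 2 windows).
#' @param cfg A [sampler_config()]; `n_steps` applies per window.
#' @return List of `colvar_series`, one per window, each carrying its
#'   restraints.
#' @export
run_umbrella_set <- function(surface, windows, cfg) {
  stopifnot(inherits(surface, "model_surface"), length(windows) >= 2L)
  set.seed(cfg$seed)
  rmat <- lapply(windows, restraints_matrix)
  out <- vector("list", length(windows))
  x <- NULL
  for (k in seq_along(windows)) {
    rs <- windows[[k]]
    cx <- NULL; cp <- NULL
    for (r in rs) {
      if (r$cv == "xi_star") cx <- r$center
      if (r$cv == "phi_star") cp <- r$center
    }
    if (is.null(x)) {                 # first window: start on channel floor
      x_xi <- if (is.null(cx)) surface$stationary$reactant["xi"] else cx
      x <- c(x_xi, surface$phi_min(x_xi))
    }
    # drag toward the new window centre before sampling
    if (!is.null(cx)) x[1] <- cx
    if (!is.null(cp)) x[2] <- min(max(cp, 0), 1)
    m <- langevin_cpp(surface$par, rmat[[k]], as.numeric(x), cfg$timestep,
                      cfg$friction, kT_kcal(cfg$temperature), cfg$n_steps,
                      cfg$stride, cfg$guard)
    x <- c(m[nrow(m), 2], m[nrow(m), 3])
    out[[k]] <- series_from_matrix(m, rs)
  }
  out
}

#' Well-tempered metadynamics specification
#'
#' Defaults follow the multiple-walker protocol: Gaussian hills of height
#' 0.6 kcal/mol and width 0.02 deposited every 1000 steps, bias factor 35,
#' 8 walkers sharing the bias every 100 steps.
#'
#' @param height Initial hill height w0 (kcal/mol).
#' @param sigma Hill width per CV (CV units).
#' @param pace Deposition pace (steps).
#' @param bias_factor Well-tempered bias factor gamma (> 1); `Inf` gives
#'   standard (untempered) metadynamics.
#' @param n_walkers Number of walkers.
#' @param share Bias-sharing interval (steps).
#' @param cv Biased CV: `"phi_star"` or `"xi_star"`.
#' @param grid Bias-grid spec `c(min, max, n_points)` for the biased CV.
#' @return A `metad_spec` list.
#' @export
metad_spec <- function(height = 0.6, sigma = 0.02, pace = 1000L,
                       bias_factor = 35, n_walkers = 8L, share = 100L,
                       cv = c("phi_star", "xi_star"),
                       grid = c(0, 1, 801)) {
  cv <- match.arg(cv)
  stopifnot(height > 0, sigma > 0, pace >= 1, bias_factor > 1,
            n_walkers >= 1, share >= 1, length(grid) == 3, grid[3] >= 2)
  structure(list(height = height, sigma = sigma, pace = as.integer(pace),
                 bias_factor = bias_factor, n_walkers = as.integer(n_walkers),
                 share = as.integer(share), cv = cv, grid = grid),
            class = "metad_spec")
}

#' Multiple-walker well-tempered metadynamics on a model surface
#'
#' Walkers evolve under `F` plus the history-dependent Gaussian bias; every
#' `pace` steps the active walker deposits a hill with well-tempered height
#' `w0 * exp(-V(s) / ((gamma - 1) kB T))`, and walkers refresh their view of
#' the shared bias every `share` steps.
#'
#' @param surface A `model_surface`.
#' @param spec A [metad_spec()].
#' @param cfg A [sampler_config()]; `n_steps` applies per walker.
#' @return List with `hills` (a `hills_log`) and `series` (list of
#'   per-walker `colvar_series`, `bias` column = instantaneous bias energy).
#' @export
run_metadynamics <- function(surface, spec, cfg) {
  stopifnot(inherits(surface, "model_surface"), inherits(spec, "metad_spec"),
            inherits(cfg, "sampler_config"))
  x0 <- cfg$x0
  if (is.null(x0))
    x0 <- c(surface$stationary$reactant["xi"],
            surface$stationary$reactant["phi"])
  x0m <- matrix(rep(as.numeric(x0), each = spec$n_walkers), ncol = 2)
  set.seed(cfg$seed)
  res <- metad_cpp(surface$par, if (spec$cv == "xi_star") 0L else 1L,
                   spec$height, spec$sigma, spec$pace,
                   if (is.finite(spec$bias_factor)) spec$bias_factor else -1,
                   spec$n_walkers, spec$share, spec$grid, x0m,
                   cfg$timestep, cfg$friction, kT_kcal(cfg$temperature),
                   cfg$n_steps, cfg$stride, cfg$guard)
  hills <- hills_log(data.frame(time = res$hill_time,
                                center = res$hill_center,
                                sigma = spec$sigma,
                                height = res$hill_height,
                                biasf = spec$bias_factor,
                                walker = res$hill_walker),
                     cv = spec$cv)
  series <- lapply(res$series, series_from_matrix)
  list(hills = hills, series = series)
}

#' Metadynamics hill log
#'
#' @param df Data frame with columns `time`, `center`, `sigma`, `height`,
#'   `biasf`, `walker`.
#' @param cv Name of the biased CV.
#' @return A `hills_log` object.
#' @export
hills_log <- function(df, cv = "phi_star") {
  need <- c("time", "center", "sigma", "height", "biasf", "walker")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (any(df$height <= 0)) stop("hill heights must be positive")
  if (any(df$sigma <= 0)) stop("hill widths must be positive")
  bf <- unique(df$biasf)
  if (length(bf) > 1L) stop("bias factor must be constant within a log")
  if (nrow(df) > 0L && is.finite(bf) && bf <= 1)
    stop("bias factor must exceed 1")
  structure(df[, need], class = c("hills_log", "data.frame"), cv = cv)
}

#' @export
print.hills_log <- function(x, ...) {
  cat(sprintf("hills_log: %d hills on %s, bias factor %s, %d walker(s)\n",
              nrow(x), attr(x, "cv"), format(x$biasf[1]),
              length(unique(x$walker))))
  invisible(x)
}

#' Synthetic hydration frames along a straight channel
#'
#' Places water oxygens along a straight channel with Gaussian jitter,
#' thinning the water density inside a weakly hydrated gap by
#' `gap_occupancy_factor` (1 = no thinning, 0 = dry gap), and puts the
#' excess-charge probe at a chosen arc-length position. Emulates a channel
#' whose resolved waters leave a gap between two titratable residues.
#'
#' @param n_frames Number of frames.
#' @param channel_length Channel length in Angstrom (default 24).
#' @param n_waters Number of water sites along the channel (default 30).
#' @param gap_center Gap centre along the channel axis (Angstrom).
#' @param gap_width Gap width (Angstrom, default 4.5).
#' @param gap_occupancy_factor Retention probability for waters whose site
#'   lies inside the gap, in \[0, 1\].
#' @param seed RNG seed.
#' @param n_nodes Number of path nodes (default 25).
#' @param jitter Positional jitter s.d. (Angstrom, default 0.35).
#' @param probe_arc Probe position along the axis (default `gap_center`).
#' @return List with `nodes` (a `path_nodes`) and `frames` (list of
#'   `hydration_frame`).
#' @export
generate_hydration_frames <- function(n_frames, channel_length = 24,
                                      n_waters = 30L, gap_center = 12,
                                      gap_width = 4.5,
                                      gap_occupancy_factor = 1,
                                      seed = 1, n_nodes = 25L,
                                      jitter = 0.35,
                                      probe_arc = gap_center) {
  stopifnot(n_frames >= 1, channel_length > 0, gap_width > 0,
            gap_occupancy_factor >= 0, gap_occupancy_factor <= 1)
  if (n_waters < 1L) stop("n_waters must be positive")
  set.seed(seed)
  axis_x <- seq(0, channel_length, length.out = n_waters)
  in_gap <- abs(axis_x - gap_center) <= gap_width / 2
  nodes <- resample_equidistant(
    cbind(c(0, channel_length), 0, 0), n_nodes)
  frames <- lapply(seq_len(n_frames), function(i) {
    keep <- !in_gap | (stats::runif(n_waters) < gap_occupancy_factor)
    nw <- sum(keep)
    if (nw == 0L) keep[which(!in_gap)[1]] <- TRUE
    w <- cbind(axis_x[keep] + stats::rnorm(sum(keep), 0, jitter),
               stats::rnorm(sum(keep), 0, jitter),
               stats::rnorm(sum(keep), 0, jitter))
    hydration_frame(w, probe = c(probe_arc, 0, 0))
  })
  list(nodes = nodes, frames = frames)
}

#' Direct Boltzmann sampling of a 1D potential
#'
#' Draws samples exactly (to grid resolution) from
#' `p(x) ~ exp(-(f(x) + bias(x)) / kBT)` by inverse-CDF sampling on a fine
#' grid with uniform jitter within bins. Used as an exact-sampling reference
#' for free-energy estimators, independent of the Langevin integrator.
#'
#' @param f Function of x returning energy in kcal/mol (vectorised).
#' @param domain Length-2 range of x.
#' @param temperature Temperature in K.
#' @param n Number of samples.
#' @param bias Optional bias function of x (kcal/mol).
#' @param n_grid Grid resolution (default 8192).
#' @return Numeric vector of samples.
#' @export
sample_boltzmann_1d <- function(f, domain, temperature, n, bias = NULL,
                                n_grid = 8192L) {
  kT <- kT_kcal(temperature)
  dx <- diff(domain) / n_grid
  x <- seq(domain[1] + dx / 2, domain[2] - dx / 2, length.out = n_grid)
  e <- f(x) + if (is.null(bias)) 0 else bias(x)
  w <- exp(-(e - min(e)) / kT)
  idx <- sample.int(n_grid, n, replace = TRUE, prob = w)
  x[idx] + stats::runif(n, -dx / 2, dx / 2)
}
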