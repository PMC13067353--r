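test_that("model surface honours its declared stationary points", {
  # symmetric case: equal basin free energies
  sym <- make_surface(dF = 5, dG = 0, phi_R = 0.8, phi_S = 0.9, phi_P = 0.8)
  expect_equal(sym$stationary$reactant[["F"]], sym$stationary$product[["F"]],
               tolerance = 1e-9)
  # barrier preset verified by a dense grid-search oracle
  s <- surface_preset("recovery")
  xi <- seq(s$params$xi_R, s$params$xi_P, length.out = 600)
  phi <- seq(0.4, 1, length.out = 300)
  floor_profile <- vapply(xi, function(x) min(s$f(rep(x, 300), phi)),
                          numeric(1))
  expect_equal(max(floor_profile), 6, tolerance = 0.05)
  expect_equal(s$f(s$params$xi_P, s$params$phi_P) -
               s$f(s$params$xi_R, s$params$phi_R), 3, tolerance = 1e-6)
  expect_error(make_surface(dF = 2, dG = 3), "saddle")
})

test_that("default surface presets match the described topology", {
  s <- surface_preset("headline")
  expect_equal(unname(s$stationary$reactant[c("xi", "phi")]), c(0, 0.75))
  expect_equal(unname(s$stationary$saddle[["xi"]]), 6, tolerance = 0.35)
  expect_gt(s$stationary$saddle[["phi"]], 0.9)
  expect_equal(unname(s$stationary$saddle[["F"]]), 17.1, tolerance = 1e-6)
})

test_that("Langevin sampling satisfies equipartition on a harmonic potential", {
  # near-flat surface so the restraint dominates: var -> kBT/k
  s <- make_surface(dF = 0.01, dG = 0, xi_R = 0, xi_P = 9,
                    phi_R = 0.75, phi_S = 0.76, phi_P = 0.75,
                    kappa_phi = 0.01, phi_coupling = 0, wall = 0.01)
  cfg <- sampler_config(n_steps = 2e5, seed = 2, stride = 25,
                        temperature = 310, x0 = c(4.5, 0.75))
  ts <- langevin_sample(s, list(restraint("xi_star", 4.5, 20)), cfg)
  v <- stats::var(ts$xi_star)
  v_exp <- kT_kcal(310) / 20
  n_eff <- nrow(ts) / 10              # stride 25 leaves mild correlation
  expect_lt(abs(v - v_exp), 3 * v_exp * sqrt(2 / n_eff))
})

test_that("zero-temperature Langevin descends to the nearest minimum", {
  s <- surface_preset("recovery")
  cfg <- sampler_config(n_steps = 5e4, seed = 1, temperature = 1e-8,
                        x0 = c(1.2, 0.7))
  ts <- langevin_sample(s, NULL, cfg)
  last <- as.numeric(ts[nrow(ts), c("xi_star", "phi_star")])
  expect_equal(last[1], s$stationary$reactant[["xi"]], tolerance = 1e-2)
  expect_equal(last[2], s$stationary$reactant[["phi"]], tolerance = 1e-2)
})

test_that("sampling is deterministic given the seed", {
  s <- surface_preset("recovery")
  cfg <- sampler_config(n_steps = 2e4, seed = 99)
  a <- langevin_sample(s, list(restraint("xi_star", 3, 15)), cfg)
  b <- langevin_sample(s, list(restraint("xi_star", 3, 15)), cfg)
  expect_identical(a, b)
  spec <- metad_spec(cv = "xi_star", grid = c(-0.5, 9.5, 201),
                     pace = 100L)
  m1 <- run_metadynamics(s, spec, cfg)
  m2 <- run_metadynamics(s, spec, cfg)
  expect_identical(m1, m2)
})

test_that("unbiased Langevin sampling is Boltzmann-consistent", {
  # compact low-barrier landscape so inter-basin mixing is fast relative to
  # the run; compare the xi histogram with the analytic marginal
  # exp(-F_marg/kBT)
  s <- make_surface(dF = 0.5, dG = 0.2, xi_R = 0, xi_P = 3)
  cfg <- sampler_config(n_steps = 1e6, seed = 4, stride = 10,
                        timestep = 4e-4, friction = 0.5)
  ts <- langevin_sample(s, NULL, cfg)
  kT <- kT_kcal(310)
  br <- seq(floor(min(ts$xi_star)) - 0.25, ceiling(max(ts$xi_star)) + 0.25,
            by = 0.1)
  h <- hist(ts$xi_star, breaks = br, plot = FALSE)
  phig <- seq(0.3, 1.0, by = 0.005)
  marg <- vapply(h$mids, function(x)
    sum(exp(-s$f(rep(x, length(phig)), phig) / kT)), numeric(1))
  p_ref <- marg / sum(marg)
  p_obs <- h$counts / sum(h$counts)
  keep <- p_ref > 1e-6
  kl <- sum(p_obs[keep] * log(pmax(p_obs[keep], 1e-12) / p_ref[keep]))
  expect_lt(kl, 0.01)
})

test_that("umbrella windows stay near their centres and presets count windows", {
  s <- surface_preset("recovery")
  expect_length(umbrella_windows(s, "1d"), 24L)
  expect_length(umbrella_windows(s, "2d"), 130L)
  wins <- umbrella_windows(s, "1d", n_xi = 8L, k_xi = 20)
  cfg <- sampler_config(n_steps = 3e4, seed = 6)
  series <- run_umbrella_set(s, wins, cfg)
  sigma <- sqrt(kT_kcal(310) / 20)
  for (k in seq_along(series)) {
    ctr <- attr(series[[k]], "restraints")[[1]]$center
    expect_lt(abs(mean(series[[k]]$xi_star) - ctr), 3 * sigma)
  }
})

test_that("each umbrella window matches its biased Boltzmann distribution", {
  s <- surface_preset("recovery")
  kT <- kT_kcal(310)
  k_xi <- 20
  for (ctr in c(2.25, 5.25)) {
    cfg <- sampler_config(n_steps = 1e6, seed = 10, stride = 500,
                          x0 = c(ctr, 0.85))
    ts <- langevin_sample(s, list(restraint("xi_star", ctr, k_xi)), cfg)
    br <- seq(ctr - 0.8, ctr + 0.8, by = 0.1)
    obs <- hist(pmin(pmax(ts$xi_star, br[1]), br[length(br)]),
                breaks = br, plot = FALSE)$counts
    phig <- seq(0.4, 1, by = 0.005)
    dens <- vapply(br, function(x)
      sum(exp(-(s$f(rep(x, length(phig)), phig) +
                0.5 * k_xi * (x - ctr)^2) / kT)), numeric(1))
    pb <- (dens[-length(dens)] + dens[-1]) / 2
    pb <- pb / sum(pb)
    keep <- pb * sum(obs) >= 5
    chi2 <- sum((obs[keep] - sum(obs) * pb[keep])^2 / (sum(obs) * pb[keep]))
    df <- sum(keep) - 1
    expect_lt(chi2, stats::qchisq(0.99, df))
  }
})

test_that("metadynamics bookkeeping follows the deposition schedule", {
  s <- surface_preset("metad1d")
  cfg <- sampler_config(n_steps = 5000, seed = 3, timestep = 2e-5)
  spec <- metad_spec(cv = "xi_star", grid = c(0.05, 0.95, 201),
                     pace = 250L, n_walkers = 4L)
  res <- run_metadynamics(s, spec, cfg)
  expect_equal(nrow(res$hills), floor(5000 / 250) * 4)
  expect_true(all(res$hills$height <= 0.6 + 1e-12))
  # infinite bias factor: standard metadynamics, constant hill height
  spec_inf <- metad_spec(cv = "xi_star", grid = c(0.05, 0.95, 201),
                         pace = 250L, n_walkers = 2L, bias_factor = Inf)
  res_inf <- run_metadynamics(s, spec_inf, cfg)
  expect_true(all(res_inf$hills$height == 0.6))
})

test_that("hydration-frame generator responds to the gap factor", {
  mean_phi <- function(gen) {
    mean(vapply(gen$frames, function(fr)
      water_wire_connectivity(occupancy_profile(fr, gen$nodes)),
      numeric(1)))
  }
  # factor 1: statistically indistinguishable from the no-gap construction
  with_gap <- generate_hydration_frames(60, gap_occupancy_factor = 1,
                                        seed = 21)
  no_gap <- generate_hydration_frames(60, gap_width = 1e-9,
                                      gap_occupancy_factor = 0, seed = 22)
  phi_a <- vapply(with_gap$frames, function(fr)
    water_wire_connectivity(occupancy_profile(fr, with_gap$nodes)), numeric(1))
  phi_b <- vapply(no_gap$frames, function(fr)
    water_wire_connectivity(occupancy_profile(fr, no_gap$nodes)), numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(phi_a, phi_b)$p.value), 0.01)

  # dry wide gap straddling node pairs: zero pair average -> phi = 0
  dry <- generate_hydration_frames(10, channel_length = 30, n_waters = 31,
                                   gap_center = 15, gap_width = 16,
                                   gap_occupancy_factor = 0, seed = 5,
                                   jitter = 0.1)
  phi_dry <- vapply(dry$frames, function(fr)
    water_wire_connectivity(occupancy_profile(fr, dry$nodes)), numeric(1))
  expect_true(all(phi_dry == 0))

  # decreasing factor: monotone decreasing mean phi
  factors <- seq(1, 0, length.out = 12)
  mphi <- vapply(seq_along(factors), function(i)
    mean_phi(generate_hydration_frames(25, channel_length = 30,
                                       n_waters = 31, gap_center = 15,
                                       gap_width = 8,
                                       gap_occupancy_factor = factors[i],
                                       seed = 100 + i)),
    numeric(1))
  expect_lt(stats::cor(seq_along(factors), mphi, method = "spearman"), -0.9)
  expect_error(generate_hydration_frames(5, n_waters = 0), "n_waters")
})

test_that("generators are bit-reproducible given seed and config", {
  a <- generate_hydration_frames(8, gap_occupancy_factor = 0.4, seed = 12)
  b <- generate_hydration_frames(8, gap_occupancy_factor = 0.4, seed = 12)
  expect_identical(a, b)
})
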