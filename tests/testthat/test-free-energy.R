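test_that("single unbiased window reduces WHAM to -kT ln(histogram)", {
  set.seed(31)
  x <- sample_boltzmann_1d(dw_quartic, c(-1.8, 1.8), 310, 20000)
  win <- colvar_series(data.frame(time = seq_along(x), xi_star = x))
  ax <- fe_axis("xi_star", -1.8, 1.8, 36)
  g <- wham(list(win), ax, temperature = 310)
  h <- hist(x, breaks = seq(-1.8, 1.8, length.out = 37), plot = FALSE)$counts
  ref <- -kT_kcal(310) * log(h / sum(h))
  ref[h == 0] <- NA
  ref <- ref - min(ref, na.rm = TRUE)
  expect_equal(g$F, ref, tolerance = 1e-10)
})

test_that("WHAM recovers a quartic double well from exact-sampling windows", {
  set.seed(32)
  centers <- seq(-1.4, 1.4, length.out = 10)
  wins <- lapply(centers, function(c0)
    exact_window(dw_quartic, c0, 15, 30000))
  ax <- fe_axis("xi_star", -1.7, 1.7, 50)
  g <- wham(wins, ax, temperature = 310)
  # analytic reference on the same bins (Boltzmann-averaged within bins)
  kT <- kT_kcal(310)
  br <- seq(-1.7, 1.7, length.out = 51)
  ref <- vapply(seq_len(50), function(b) {
    xs <- seq(br[b], br[b + 1], length.out = 20)
    -kT * log(mean(exp(-dw_quartic(xs) / kT)))
  }, numeric(1))
  ok <- g$mask & (g$counts > 50)
  d <- (g$F - ref)[ok]
  d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), 0.2)
})

test_that("small-instance WHAM matches the loop-based fixed-point oracle", {
  set.seed(33)
  centers <- c(-0.8, 0, 0.8)
  wins <- lapply(centers, function(c0)
    exact_window(dw_quartic, c0, 8, 4000, domain = c(-1.5, 1.5)))
  ax <- fe_axis("xi_star", -1.5, 1.5, 18)
  g <- wham(wins, ax, temperature = 310, tol = 1e-12)
  kT <- kT_kcal(310)
  mids <- seq(-1.5 + 1.5 / 18, 1.5 - 1.5 / 18, length.out = 18)
  counts <- t(vapply(wins, function(w)
    hist(w$xi_star, breaks = seq(-1.5, 1.5, length.out = 19),
         plot = FALSE)$counts, numeric(18)))
  U <- t(vapply(seq_along(centers), function(k)
    0.5 * 8 * (mids - centers[k])^2, numeric(18)))
  orc <- oracle_wham(counts, U, rowSums(counts), kT)
  expect_equal(attr(g, "f_window"), orc$f, tolerance = 1e-8)
  Forc <- -kT * log(orc$p)
  Forc <- Forc - min(Forc[colSums(counts) > 0])
  expect_equal(g$F[g$mask], Forc[colSums(counts) > 0], tolerance = 1e-8)
})

test_that("WHAM is covariant under translation of surface and windows", {
  shift <- 0.6
  centers <- seq(-1.2, 1.2, length.out = 8)
  make_set <- function(s0) {
    set.seed(34)   # same RNG stream: shifted potential gives shifted samples
    lapply(centers + s0, function(c0)
      exact_window(function(x) dw_quartic(x - s0), c0, 12, 20000,
                   domain = c(-1.8 + s0, 1.8 + s0)))
  }
  g0 <- wham(make_set(0), fe_axis("xi_star", -1.7, 1.7, 40), 310)
  g1 <- wham(make_set(shift), fe_axis("xi_star", -1.7 + shift, 1.7 + shift, 40),
             310)
  expect_equal(g1$F, g0$F, tolerance = 1e-9)
})

test_that("converged WHAM weights reproduce each window's biased histogram", {
  set.seed(35)
  centers <- seq(-1.2, 1.2, length.out = 6)
  # sample on the WHAM bins themselves (n_grid = n_bins) so the observed
  # histograms follow exactly the bin-centre model WHAM solves
  wins <- lapply(centers, function(c0)
    exact_window(dw_quartic, c0, 12, 30000, n_grid = 30L))
  ax <- fe_axis("xi_star", -1.8, 1.8, 30)
  g <- wham(wins, ax, 310)
  kT <- kT_kcal(310)
  mids <- seq(-1.8 + 0.06, 1.8 - 0.06, length.out = 30)
  p <- exp(-g$F / kT)
  p[!g$mask] <- 0
  p <- p / sum(p)
  f <- attr(g, "f_window")
  for (k in seq_along(wins)) {
    obs <- hist(wins[[k]]$xi_star, breaks = seq(-1.8, 1.8, length.out = 31),
                plot = FALSE)$counts
    ek <- p * exp((f[k] - 0.5 * 12 * (mids - centers[k])^2) / kT)
    ek <- ek / sum(ek) * sum(obs)
    keep <- ek >= 5
    chi2 <- sum((obs[keep] - ek[keep])^2 / ek[keep])
    expect_lt(chi2, stats::qchisq(0.99, sum(keep) - 1))
  }
})

test_that("WHAM errors on non-overlapping windows and warns on thin overlap", {
  set.seed(36)
  w1 <- exact_window(function(x) 0 * x, -1.2, 400, 4000)
  w2 <- exact_window(function(x) 0 * x, 1.2, 400, 4000)
  expect_error(wham(list(w1, w2), fe_axis("xi_star", -1.8, 1.8, 60), 310),
               "non-overlapping")
  w3 <- exact_window(function(x) 0 * x, -0.35, 40, 1500)
  w4 <- exact_window(function(x) 0 * x, 0.35, 40, 1500)
  expect_warning(wham(list(w3, w4), fe_axis("xi_star", -1.2, 1.2, 24), 310),
                 "overlaps")
})

test_that("block averaging agrees with full WHAM on stationary series", {
  set.seed(37)
  centers <- seq(-1.3, 1.3, length.out = 8)
  wins <- lapply(centers, function(c0) exact_window(dw_quartic, c0, 12, 24000))
  ax <- fe_axis("xi_star", -1.7, 1.7, 34)
  ba <- block_averaged_wham(wins, ax, 310, n_blocks = 6, keep_last = 3)
  expect_equal(ba$report$retained, 4:6)
  full <- wham(wins, ax, 310)
  common <- ba$grid$mask & full$mask
  d <- (ba$grid$F - full$F)[common]
  d <- d - mean(d)
  se <- pmax(ba$grid$se[common], 0.02)
  expect_lt(stats::median(abs(d) / se), 2)
})

test_that("block averaging discards a drifting early half", {
  set.seed(38)
  centers <- seq(-1.3, 1.3, length.out = 8)
  drift_wins <- lapply(centers, function(c0) {
    # first half sampled from a tilted (wrong) potential, second half clean
    bias <- function(x) 0.5 * 12 * (x - c0)^2
    bad <- sample_boltzmann_1d(function(x) dw_quartic(x) + 1.5 * x,
                               c(-1.8, 1.8), 310, 8000, bias)
    good <- sample_boltzmann_1d(dw_quartic, c(-1.8, 1.8), 310, 8000, bias)
    colvar_series(data.frame(time = 1:16000, xi_star = c(bad, good)),
                  restraints = list(restraint("xi_star", c0, 12)))
  })
  clean_wins <- lapply(drift_wins, function(w) {
    colvar_series(data.frame(time = 1:8000, xi_star = w$xi_star[8001:16000]),
                  restraints = attr(w, "restraints"))
  })
  ax <- fe_axis("xi_star", -1.7, 1.7, 34)
  ba <- block_averaged_wham(drift_wins, ax, 310, n_blocks = 8, keep_last = 4)
  ref <- wham(clean_wins, ax, 310)
  early <- wham(lapply(drift_wins, function(w)
    colvar_series(data.frame(time = 1:8000, xi_star = w$xi_star[1:8000]),
                  restraints = attr(w, "restraints"))), ax, 310)
  common <- ba$grid$mask & ref$mask & early$mask
  align <- function(a, b) { d <- (a - b)[common]; d - mean(d) }
  d_ret <- align(ba$grid$F, ref$F)
  d_early <- align(early$F, ref$F)
  se <- pmax(ba$grid$se[common], 0.05)
  # retained average tracks the equilibrated half; early blocks deviate
  expect_lt(stats::median(abs(d_ret) / se), 2)
  expect_gt(sqrt(mean(d_early^2)), 2 * sqrt(mean(d_ret^2)))
})

test_that("metadynamics free energy inverts the accumulated bias", {
  one <- hills_log(data.frame(time = 1, center = 0.4, sigma = 0.05,
                              height = 0.5, biasf = 35, walker = 1))
  g <- metad_free_energy(one, fe_axis("xi_star", 0, 1, 100))
  mids <- seq(0.005, 0.995, by = 0.01)
  expect_lt(abs(mids[which.min(g$F)] - 0.4), 0.011)
  ref <- 0.5 * exp(-0.5 * ((mids - 0.4) / 0.05)^2)
  expect_equal(g$F, (35 / 34) * (max(ref) - ref), tolerance = 1e-12)
  # infinite bias factor: F = -V exactly
  inf1 <- hills_log(data.frame(time = 1, center = 0.4, sigma = 0.05,
                               height = 0.5, biasf = Inf, walker = 1))
  ginf <- metad_free_energy(inf1, fe_axis("xi_star", 0, 1, 100))
  expect_equal(ginf$F, max(ref) - ref, tolerance = 1e-12)
  expect_error(metad_free_energy(one[0, ], fe_axis("x", 0, 1, 10)), "empty")
})

test_that("walker logs merge time-ordered and order-independently", {
  l1 <- hills_log(data.frame(time = c(1, 3, 5), center = c(0.1, 0.2, 0.3),
                             sigma = 0.02, height = 0.6, biasf = 35,
                             walker = 1))
  l2 <- hills_log(data.frame(time = c(2, 3, 6), center = c(0.5, 0.6, 0.7),
                             sigma = 0.02, height = 0.6, biasf = 35,
                             walker = 2))
  expect_equal(as.data.frame(merge_walkers(list(l1))), as.data.frame(l1))
  m12 <- merge_walkers(list(l1, l2))
  m21 <- merge_walkers(list(l2, l1))
  expect_equal(nrow(m12), 6L)
  expect_true(all(diff(m12$time) >= 0))
  expect_identical(as.data.frame(m12), as.data.frame(m21))
  l3 <- hills_log(data.frame(time = 1, center = 0, sigma = 0.02,
                             height = 0.6, biasf = 20, walker = 3))
  expect_error(merge_walkers(list(l1, l3)), "bias factors")
  # merged-order invariance of the free-energy estimate
  g12 <- metad_free_energy(m12, fe_axis("xi_star", 0, 1, 50))
  g21 <- metad_free_energy(m21, fe_axis("xi_star", 0, 1, 50))
  expect_equal(g12$F, g21$F, tolerance = 1e-12)
})

test_that("free-energy grid files round-trip", {
  set.seed(40)
  F2 <- matrix(runif(12 * 8, 0, 5), 12, 8)
  mask <- matrix(TRUE, 12, 8); mask[1, ] <- FALSE; F2[1, ] <- NA
  g <- fe_grid(list(fe_axis("xi_star", 0, 9, 12), fe_axis("phi_star", 0, 1, 8)),
               F2, mask = mask, temperature = 310)
  f <- tempfile(fileext = ".dat")
  write_fes(g, f)
  g2 <- read_fes(f)
  expect_equal(g2$F, g$F, tolerance = 1e-9)
  expect_equal(g2$mask, g$mask)
  expect_equal(g2$axes, g$axes)
})
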