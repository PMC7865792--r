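test_that("contact maps count strict-threshold contacts over frames", {
  ann <- bead_annotation(1L, 0:2, (0:2) * 1e5, c("F", "P", "F"),
                         FALSE, FALSE)
  at <- function(d12, d13 = 10) {
    list(rbind(c(0, 0, 0), c(d12, 0, 0), c(d13, 5, 0)))
  }
  m_in <- contact_map_from_frames(at(2.4), ann)
  expect_equal(m_in$matrix[1, 2], 1.0)
  m_edge <- contact_map_from_frames(at(2.5), ann)
  expect_equal(m_edge$matrix[1, 2], 0.0)  # strictly less than
  # 4 hand-written frames vs brute-force counting
  frames <- list(rbind(c(0, 0, 0), c(1, 0, 0), c(4, 0, 0)),
                 rbind(c(0, 0, 0), c(3, 0, 0), c(1, 2, 0)),
                 rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1, 0)),
                 rbind(c(0, 0, 0), c(5, 0, 0), c(0, 0, 2)))
  cm <- contact_map_from_frames(frames, ann)
  brute <- matrix(0, 3, 3)
  for (fr in frames) {
    d <- as.matrix(dist(fr))
    brute <- brute + (d < 2.5)
  }
  brute <- brute / 4; diag(brute) <- 1
  expect_equal(cm$matrix, unname(brute))
  expect_true(isSymmetric(cm$matrix))
  expect_true(all(cm$matrix >= 0 & cm$matrix <= 1))
  expect_error(contact_map_from_frames(list(), ann))
})

test_that("P(N) averages pairs at equal separation with class filters", {
  # constant off-diagonal map -> P(N) constant
  m <- matrix(0.3, 6, 6); diag(m) <- 1
  map <- toy_map(m, rep(c("F", "P"), 3))
  ps <- ps_curve(map)
  expect_equal(ps$N_kbps, (1:5) * 100)
  expect_equal(ps$P, rep(0.3, 5))
  # FF filter on alternating classes: only even separations have FF pairs
  psff <- ps_curve(map, "FF")
  expect_equal(psff$N_kbps, c(200, 400))
  expect_equal(psff$n_pairs, c(2, 1))  # (1,3),(3,5) and (1,5)
  # enumeration check on a structured map
  m2 <- matrix(0, 6, 6)
  m2[upper.tri(m2)] <- seq(0.01, 0.15, by = 0.01)
  m2 <- m2 + t(m2); diag(m2) <- 1
  map2 <- toy_map(m2, rep(c("F", "P"), 3))
  ps2 <- ps_curve(map2, "PP")
  manual <- mean(c(m2[2, 4], m2[4, 6]))
  expect_equal(ps2$P[ps2$N_kbps == 200], manual)
})

test_that("P(N) on multiple chains never crosses chains", {
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  m[1:2, 3:4] <- 0.9; m[3:4, 1:2] <- 0.9
  map <- toy_map(m, rep("F", 4), chain = c(1L, 1L, 2L, 2L))
  ps <- ps_curve(map)
  expect_equal(ps$N_kbps, 100)       # chains of 2: only N = 1 bead
  expect_equal(ps$P, 0.5)            # inter-chain 0.9 never enters
})

test_that("power-law fits recover exponents exactly and under noise", {
  n <- seq(300, 700, by = 100)
  ps <- data.frame(N_kbps = n, P = n^(-1.3))
  expect_equal(fit_power_law(ps, c(300, 700))$alpha, 1.3, tolerance = 1e-10)
  flat <- data.frame(N_kbps = n, P = rep(0.2, length(n)))
  expect_equal(fit_power_law(flat, c(300, 700))$alpha, 0, tolerance = 1e-12)
  # multiplicative lognormal noise, 50 points
  set.seed(31)
  n2 <- exp(seq(log(300), log(7000), length.out = 50))
  ps2 <- data.frame(N_kbps = n2,
                    P = n2^(-1.3) * exp(rnorm(50, sd = 0.1)))
  expect_equal(fit_power_law(ps2, c(300, 7000))$alpha, 1.3, tolerance = 0.05 / 1.3)
  # non-positive points are dropped; too few points error
  ps3 <- data.frame(N_kbps = n, P = c(0, 0, 0.1, 0.05, 0))
  expect_error(fit_power_law(ps3, c(300, 700)), "fewer than 3")
  expect_error(fit_power_law(ps, c(800, 900)))
})

test_that("F/P contact ratio divides matched grid points", {
  a <- data.frame(N_kbps = c(100, 200, 300), P = c(0.4, 0.2, 0.1))
  expect_equal(fp_ratio_curve(a, a)$ratio, rep(1, 3))
  b <- a; b$P <- a$P / 2
  expect_equal(fp_ratio_curve(a, b)$ratio, rep(2, 3))
  # undefined points omitted
  b2 <- a; b2$P[2] <- 0
  expect_equal(fp_ratio_curve(a, b2)$N_kbps, c(100, 300))
  disjoint <- data.frame(N_kbps = c(150, 250), P = c(1, 1))
  expect_error(fp_ratio_curve(a, disjoint))
})

test_that("radial profiles use equal-thickness shells that tile the sphere", {
  rad <- 10
  vol <- attr(rdf_from_frames(list(matrix(0, 2, 3) + 0.1), c("F", "P"), rad),
              "shell_volumes")
  expect_equal(sum(vol), 4 / 3 * pi * rad^3, tolerance = 1e-12)
  # all beads at the centre -> everything in shell 1
  ctr <- rdf_from_frames(list(matrix(1e-6, 4, 3)), rep(c("F", "P"), 2), rad)
  expect_true(all(ctr$dens_F[-1] == 0) && all(ctr$dens_P[-1] == 0))
  expect_gt(ctr$dens_F[1], 0)
  # escape is an integrity violation
  expect_error(rdf_from_frames(list(rbind(c(11, 0, 0))), "F", rad),
               "outside")
})

test_that("uniform points give a flat radial density", {
  set.seed(91)
  rad <- 5
  n <- 1e5
  pts <- matrix(rnorm(3 * n), n, 3)
  u <- runif(n)^(1 / 3) * rad
  pts <- pts / sqrt(rowSums(pts^2)) * u
  prof <- rdf_from_frames(list(pts), rep("F", n), rad, n_shells = 200)
  vol <- attr(prof, "shell_volumes")
  expected <- n * vol / sum(vol)     # Poisson mean per shell
  counts <- prof$dens_F * vol
  big <- expected >= 30
  dev <- abs(counts[big] - expected[big]) / sqrt(expected[big])
  expect_lt(max(dev), 4)             # every well-populated shell within 4 SE
  expect_gt(mean(dev < 2), 0.9)
  # distribution check on the radii themselves
  ks <- suppressWarnings(stats::ks.test((u / rad)^3, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("windowed Fourier spectra separate F and P diagonals", {
  n <- 60
  cls <- rep("F", n)
  m <- matrix(0, n, n)
  # constant 5th diagonal -> spectrum identically zero after mean removal
  for (i in 1:(n - 5)) m[i, i + 5] <- m[i + 5, i] <- 0.7
  sp <- windowed_fft(toy_map(m, cls))
  expect_equal(length(sp$freq), 11)
  expect_true(all(sp$spec_F < 1e-12))
  expect_null(sp$spec_P)
  expect_equal(sp$missing_class, "P")
  # cosine of period 5 bins peaks at 4 cycles / 20-bin window
  for (i in 1:(n - 5)) {
    v <- 0.5 + 0.2 * cos(2 * pi * (i - 1) / 5)
    m[i, i + 5] <- m[i + 5, i] <- v
  }
  sp2 <- windowed_fft(toy_map(m, cls))
  expect_equal(which.max(sp2$spec_F), 5)  # freq index 5 = 4/20 cycles/bin
  expect_equal(sp2$freq[5], 4 / 20)
  # windows are classified by strict bead majority
  cls2 <- c(rep("P", 25), rep("F", 35))
  sp3 <- windowed_fft(toy_map(m, cls2))
  expect_gt(sp3$n_windows_P, 0)
  expect_gt(sp3$n_windows_F, 0)
})

test_that("intra/inter-chain statistics filter by genomic range", {
  # two chains of 4 beads, 100-kbp bins: use a small long-range cutoff so
  # the toy map has eligible pairs
  m <- matrix(0.2, 8, 8)
  m[1:4, 5:8] <- 0.05; m[5:8, 1:4] <- 0.05
  diag(m) <- 1
  map <- toy_map(m, rep("F", 8), chain = rep(1:2, each = 4L))
  st <- interchain_stats(map, long_range_kbps = 200)
  # intra: pairs separated by > 2 beads, i.e. (1,4) and (5,8)
  expect_equal(st$intra$mean_p, c(0.2, 0.2))
  expect_equal(st$intra$n_pairs, c(1, 1))
  expect_equal(st$inter$mean_p, 0.05)
  expect_equal(st$inter$n_pairs, 16)
  # chains never in contact
  m0 <- m; m0[1:4, 5:8] <- 0; m0[5:8, 1:4] <- 0
  expect_equal(interchain_stats(toy_map(m0, rep("F", 8),
                                        chain = rep(1:2, each = 4L)),
                                200)$inter$mean_p, 0)
  expect_error(interchain_stats(toy_map(m[1:4, 1:4], rep("F", 4)), 200))
})

test_that("experimental curves are aligned at the 300-kbp anchor", {
  sim <- data.frame(N_kbps = c(100, 200, 300, 400), P = c(0.8, 0.6, 0.4, 0.3))
  class(sim) <- c("ps_curve", "data.frame")
  same <- align_experimental(sim[, c("N_kbps", "P")], sim)
  expect_equal(attr(same, "scale_factor"), 1)
  tenx <- sim; tenx$P <- sim$P * 10
  al <- align_experimental(tenx[, c("N_kbps", "P")], sim)
  expect_equal(attr(al, "scale_factor"), 0.1)
  expect_equal(al$P, sim$P)
  half <- data.frame(N = c(295, 400), P = c(0.2, 0.1))  # nearest grid point
  al2 <- align_experimental(half, sim)
  expect_equal(attr(al2, "scale_factor"), 2)
  bad <- data.frame(N = 300, P = 0)
  expect_error(align_experimental(bad, sim))
})
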