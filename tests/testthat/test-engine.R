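test_that("initial conformations are valid self-avoiding chains", {
  ann <- generate_annotation(synth_config(n_beads = 120, seed = 3))
  topo <- build_topology(ann)
  cont <- build_container(120)
  st <- init_conformation(topo, cont, seed = 5)
  # determinism
  expect_identical(st, init_conformation(topo, cont, seed = 5))
  expect_false(identical(st$coords,
                         init_conformation(topo, cont, seed = 6)$coords))
  # bond lengths exactly 1 sigma0
  bl <- sqrt(rowSums((st$coords[topo$bonds[, 1], ] -
                        st$coords[topo$bonds[, 2], ])^2))
  expect_equal(bl, rep(1, nrow(topo$bonds)), tolerance = 1e-12)
  # all pair distances >= 0.8, all beads inside the sphere
  d <- dist(st$coords)
  expect_gte(min(d), 0.8 - 1e-9)
  expect_true(all(sqrt(rowSums(st$coords^2)) < cont$radius))
  # velocities are thermal at the annealing start temperature
  expect_equal(kinetic_temperature(st), 5, tolerance = 0.15)
  # too-small containers are rejected with a helpful error
  expect_error(init_conformation(topo, build_container(120,
                                                       radius_override = 2.2),
                                 seed = 1), "larger container")
})

test_that("annealing lands on the working temperature", {
  ann <- generate_annotation(synth_config(n_beads = 60, seed = 2))
  p <- ff_params()
  topo <- build_topology(ann, p)
  cont <- build_container(60)
  st <- init_conformation(topo, cont, seed = 4)
  st$coords <- minimize_energy(st$coords, topo, cont, p)$coords
  # anneal_steps = 0: direct quench to the target
  cfg0 <- sim_config(n_steps = 1e3, anneal_steps = 0, seed = 7)
  q <- anneal(st, topo, cont, p, cfg0)
  expect_equal(q$temperature, 1.0)
  expect_equal(kinetic_temperature(q), 1.0, tolerance = 1e-9)
  # gradual anneal, then the kinetic estimator over a production stretch
  cfg <- sim_config(n_steps = 1e5, anneal_steps = 2e4,
                    snapshot_interval = 1e3, seed = 7)
  st2 <- anneal(st, topo, cont, p, cfg)
  expect_equal(st2$temperature, 1.0)
  tr <- run_md(st2, topo, cont, p, cfg)
  expect_equal(mean(tr$log$temp_kinetic), 1.0, tolerance = 0.05)
})

test_that("trajectories are deterministic and sized by the snapshot rule", {
  ann <- generate_annotation(synth_config(n_beads = 40, seed = 8))
  p <- ff_params()
  topo <- build_topology(ann, p)
  cont <- build_container(40)
  st <- init_conformation(topo, cont, seed = 1)
  st$coords <- minimize_energy(st$coords, topo, cont, p)$coords
  cfg <- sim_config(n_steps = 25000, anneal_steps = 5000,
                    snapshot_interval = 4000, seed = 3)
  st2 <- anneal(st, topo, cont, p, cfg)
  tr1 <- run_md(st2, topo, cont, p, cfg)
  tr2 <- run_md(st2, topo, cont, p, cfg)
  expect_equal(length(tr1$frames), floor(25000 / 4000))
  expect_identical(tr1$frames, tr2$frames)
  expect_false(identical(tr1$frames,
                         run_md(st2, topo, cont, p, cfg, seed = 99)$frames))
})

test_that("every saved frame respects containment and FENE bounds", {
  ann <- generate_annotation(synth_config(n_beads = 80, seed = 12))
  p <- ff_params()
  cfg <- sim_config(n_steps = 4e4, anneal_steps = 1e4,
                    snapshot_interval = 2e3, seed = 21)
  tr <- simulate_chromatin(ann, p, cfg)
  r0 <- p$fene_r0
  for (fr in tr$frames) {
    expect_true(all(sqrt(rowSums(fr^2)) < tr$container$radius))
    bl <- sqrt(rowSums((fr[tr$topology$bonds[, 1], ] -
                          fr[tr$topology$bonds[, 2], ])^2))
    expect_true(all(bl < r0))
  }
})

test_that("analytic forces match the numerical energy gradient", {
  s <- make_small_system(n = 10, seed = 20)
  f <- forces(s$x, s$topo, s$cont, s$p)
  h <- 1e-6
  num <- matrix(0, 10, 3)
  for (i in 1:10) {
    for (k in 1:3) {
      xp <- s$x; xp[i, k] <- xp[i, k] + h
      xm <- s$x; xm[i, k] <- xm[i, k] - h
      num[i, k] <- -(potential_energy(xp, s$topo, s$cont, s$p) -
                       potential_energy(xm, s$topo, s$cont, s$p)) / (2 * h)
    }
  }
  expect_lt(max(abs(num - f)) / max(abs(f)), 1e-6)
})

test_that("NVE dynamics conserve total energy", {
  # 10-bead chain vibrating longitudinally along its axis: genuine FENE+LJ
  # dynamics, but no pair ever crosses the truncation radius, where the
  # (deliberately unsmoothed) truncated-shifted force is discontinuous and
  # would contaminate the conservation measurement
  s10 <- make_small_system(n = 10)
  p <- ff_params()
  topo <- build_topology(s10$ann, p)
  cont <- build_container(10, radius_override = 12)
  # place the bonds at the FENE+WCA minimum so the stored elastic energy
  # (and hence the integrator's energy oscillation) is tiny
  rmin <- stats::optimize(function(r) fene_energy(r, p) +
                            pair_energy(r, 1, 2^(1 / 6)),
                          c(0.8, 1.2))$minimum
  xx <- (1:10 - 5.5) * rmin
  x <- cbind(xx, 0, 0)
  v <- cbind(rep(c(0.02, -0.02), 5), 0, 0)
  st <- structure(list(coords = x, velocities = v, step = 0L,
                       temperature = 0), class = "sim_state")
  # thermostat off, dt reduced 10x
  cfg <- sim_config(dt = 0.001, n_steps = 2e4, anneal_steps = 0,
                    friction = 0, snapshot_interval = 100, seed = 1,
                    anneal_from = 1, anneal_to = 1)
  tr <- run_md(st, topo, cont, p, cfg)
  etot <- tr$log$pe + tr$log$ke
  drift <- max(abs(etot - etot[1])) / (2e4 / 1e4)
  expect_lt(drift, 1e-4)
  # the motion is genuinely alive: kinetic energy keeps oscillating
  expect_gt(min(tr$log$ke), 0)
})

test_that("a two-bead bond samples its Boltzmann distribution", {
  # one F-F dimer: U(r) = FENE + pair LJ; oracle by radial quadrature
  ann <- bead_annotation(1L, 0:1, c(0, 1e5), "F", FALSE, FALSE)
  p <- ff_params()
  topo <- build_topology(ann, p)
  cont <- build_container(2, radius_override = 1e4)
  # bonded pairs interact through FENE plus the unit WCA core
  u <- function(r) fene_energy(r, p) + pair_energy(r, 1, 2^(1 / 6))
  w <- function(r) r^2 * exp(-u(r))  # kT = 1
  z <- stats::integrate(w, 1e-6, 1.5 - 1e-9)$value
  mean_r_exact <- stats::integrate(function(r) r * w(r), 1e-6,
                                   1.5 - 1e-9)$value / z
  st <- structure(list(coords = rbind(c(-0.5, 0, 0), c(0.5, 0, 0)),
                       velocities = matrix(0, 2, 3), step = 0L,
                       temperature = 1), class = "sim_state")
  cfg <- sim_config(n_steps = 4e5, anneal_steps = 0,
                    snapshot_interval = 50, seed = 17)
  tr <- run_md(st, topo, cont, p, cfg)
  r_sim <- vapply(tr$frames, function(fr) sqrt(sum((fr[1, ] - fr[2, ])^2)),
                  numeric(1))
  expect_equal(mean(r_sim), mean_r_exact, tolerance = 0.02)
})

test_that("free chains diffuse with the Langevin centre-of-mass law", {
  # 20 ideal dimers (all interactions off): COM of each is an independent
  # Langevin particle with D = T / (2 m gamma)
  cfgs <- lapply(1:20, function(i) synth_config(n_beads = 10, seed = i,
                                                lad_coverage = 0))
  ann <- generate_multichain(cfgs, seed = 1)
  ann <- ann[ann$bin < 2, ]  # two beads per chain
  ann$is_tad_boundary <- FALSE
  p <- suppressWarnings(ff_params(eps_pp = 0, eps_ff = 0, eps_pf = 0,
                                  eps_lc = 0, eps_wall_rep = 0, check = FALSE))
  topo <- build_topology(ann, p)
  cont <- build_container(40, radius_override = 500)
  st <- init_conformation(topo, cont, seed = 33, temperature = 1,
                          margin = 450)
  cfg <- sim_config(n_steps = 2e4, anneal_steps = 0, snapshot_interval = 1e3,
                    seed = 12)
  tr <- run_md(st, topo, cont, p, cfg)
  com <- function(fr) t(vapply(1:20, function(ch)
    colMeans(fr[topo$chain == ch, , drop = FALSE]), numeric(3)))
  c0 <- com(st$coords)
  msd <- vapply(tr$frames, function(fr) mean(rowSums((com(fr) - c0)^2)),
                numeric(1))
  tt <- tr$log$step * cfg$dt
  d_com <- 1 / 2  # T / (2 m gamma)
  expected <- 6 * d_com * tt
  # linear growth within sampling error, and roughly the right magnitude
  expect_equal(msd[20] / msd[10], 2, tolerance = 0.35)
  expect_equal(msd[20], expected[20], tolerance = 0.4)
})

test_that("replicas are independent, order-free and four by default", {
  ann <- generate_annotation(synth_config(n_beads = 30, seed = 4))
  cfg <- sim_config(n_steps = 5000, anneal_steps = 1000,
                    snapshot_interval = 1000, seed = 5, n_replicas = 2)
  trs <- run_replicas(ann, ff_params(), cfg)
  expect_length(trs, 2)
  expect_false(identical(trs[[1]]$frames, trs[[2]]$frames))
  # identical when re-run (execution order cannot matter: seeds are derived)
  trs2 <- run_replicas(ann, ff_params(), cfg)
  expect_identical(trs[[2]]$frames, trs2[[2]]$frames)
  expect_equal(sim_config()$n_replicas, 4L)
})

test_that("trajectories survive the extended-XYZ round trip", {
  ann <- make_small_system(n = 25)$ann
  cfg <- sim_config(n_steps = 3000, anneal_steps = 500,
                    snapshot_interval = 1000, seed = 2)
  tr <- simulate_chromatin(ann, ff_params(), cfg)
  f <- tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  back <- read_xyz(f)
  expect_equal(length(back$frames), length(tr$frames))
  expect_equal(back$frames[[2]], tr$frames[[2]], tolerance = 1e-7)
  expect_equal(back$species, tr$topology$class)
  expect_equal(back$lad, tr$topology$is_lad)
  expect_equal(back$radius, tr$container$radius, tolerance = 1e-5)
})

test_that("the ziggurat normal sampler has correct moments and tails", {
  z <- chromoblock:::cpp_rnorm_stream(1e6, 77)
  expect_equal(mean(z), 0, tolerance = 0.01)
  expect_equal(stats::var(z), 1, tolerance = 0.01)
  expect_equal(mean(z^3), 0, tolerance = 0.02)
  expect_equal(mean(z^4), 3, tolerance = 0.05)
  expect_equal(mean(abs(z) > 1.959964), 0.05, tolerance = 0.05)
  expect_equal(mean(abs(z) > 3.290527), 1e-3, tolerance = 0.15)
  # deterministic per seed, distinct across seeds
  expect_identical(z[1:10], chromoblock:::cpp_rnorm_stream(10, 77))
  expect_false(identical(z[1:10], chromoblock:::cpp_rnorm_stream(10, 78)))
})
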