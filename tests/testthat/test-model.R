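test_that("FENE bond energy matches its closed form and diverges at R0", {
  p <- ff_params()
  expect_equal(fene_energy(0, p), 0)
  expect_equal(fene_energy(1.0, p), -0.5 * 30 * 1.5^2 * log(1 - (1 / 1.5)^2))
  expect_identical(fene_energy(1.5, p), Inf)
  expect_identical(fene_energy(2.0, p), Inf)
  # smooth below R0
  r <- seq(0, 1.49, by = 0.01)
  expect_true(all(is.finite(fene_energy(r, p))))
  expect_true(all(diff(fene_energy(r, p)) >= 0))
})

test_that("truncated-shifted LJ is zero at the cutoff and continuous", {
  expect_equal(pair_energy(1.3, eps = 4.0, rc = 1.3), 0)
  expect_equal(pair_energy(2.0, eps = 4.0, rc = 1.3), 0)
  expect_lt(abs(pair_energy(1.3 - 1e-9, eps = 4.0, rc = 1.3)), 1e-6)
  # minimum value: 4*(-1/4 + 1.3^-12 - 1.3^-6) * eps
  shift <- (1 / 1.3)^12 - (1 / 1.3)^6
  expect_equal(pair_energy(2^(1 / 6), eps = 1, rc = 1.3), 4 * (-0.25 - shift))
  expect_identical(pair_energy(0, eps = 1, rc = 1.3), Inf)
})

test_that("the pair well depth spans 1-2 eps0 over the physical range", {
  depth <- function(eps) pair_energy(1.3, eps, 1.3) - pair_energy(2^(1/6), eps, 1.3)
  expect_gte(depth(3.0), 1.0)
  expect_lte(depth(5.0), 2.0)
  expect_equal(depth(1), 0.34299, tolerance = 1e-4)
})

test_that("energy ordering in the well follows the interaction strengths", {
  p <- ff_params()
  r <- 2^(1 / 6)
  u_pp <- pair_energy(r, p$eps_pp, p$rc_pair)
  u_ff <- pair_energy(r, p$eps_ff, p$rc_pair)
  u_pf <- pair_energy(r, p$eps_pf, p$rc_pair)
  expect_lt(u_pp, u_ff)
  expect_lt(u_ff, u_pf)
})

test_that("boundary bonds are plain eps_b * r^2 springs", {
  expect_equal(boundary_bond_energy(0, 0.2), 0)
  expect_equal(boundary_bond_energy(2, 0.2), 0.8)
  expect_equal(boundary_bond_energy(c(1, 3), 0), c(0, 0))
})

test_that("wall terms separate LAD attraction from plain repulsion", {
  p <- ff_params()
  expect_equal(wall_energy(1.2, is_lad = FALSE, p), 0)  # beyond 2^(1/6)
  expect_equal(wall_energy(1.3, is_lad = TRUE, p), 0)   # at cutoff
  expect_equal(wall_energy(2^(1 / 6), is_lad = TRUE, p),
               pair_energy(2^(1 / 6), 6.7, 1.3))
  expect_lt(wall_energy(2^(1 / 6), is_lad = TRUE, p), -2.29)
  # repulsive branch is never negative
  d <- seq(0.8, 1.5, by = 0.01)
  expect_true(all(wall_energy(d, is_lad = FALSE, p) >= 0))
  expect_error(wall_energy(0, is_lad = TRUE, p))
})

test_that("parameter validation flags unphysical sets", {
  expect_warning(ff_params(eps_pp = 4.0, eps_ff = 4.3), "ordering")
  expect_warning(ff_params(eps_pb = 0.6, eps_fb = 0.7), "below 0.5")
  expect_warning(ff_params(eps_pb = 0.3, eps_fb = 0.2), "eps_fb")
  expect_silent(ff_params(eps_pb = 0.4, eps_fb = 0.4))  # equality is used
  expect_warning(ff_params(eps_lc = 9), "6.0-8.0")
  expect_error(ff_params(fene_r0 = -1))
  expect_silent(ff_params())
  expect_equal(round(thermal_energy_kj_mol(308), 1), 2.6)
})

test_that("topology builds backbone, boundary bonds and classes", {
  cls <- c("F", "F", "F", "P", "P", "P", "P", "P", "F", "F")
  bd <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  ann <- bead_annotation(1L, 0:9, (0:9) * 1e5, cls, FALSE, bd)
  topo <- build_topology(ann)
  expect_equal(nrow(topo$bonds), 9)
  expect_equal(topo$bonds[, 2] - topo$bonds[, 1], rep(1L, 9))
  # boundary beads 1, 5, 10 (1-based): adjacent pairs only
  expect_equal(topo$boundary_bonds, matrix(c(1L, 5L, 5L, 10L), 2, 2))
  # span 1..5 = F,F,F,P,P -> 3/5 F -> F-TAD; span 5..10 = P,P,P,P,F,F -> P-TAD
  expect_equal(topo$boundary_class, c("F", "P"))
  expect_equal(pair_class(topo, 1, 2), "FF")
  expect_equal(pair_class(topo, 4, 5), "PP")
  expect_equal(pair_class(topo, 1, 4), "PF")
})

test_that("boundary-bond class ties resolve to P", {
  cls <- c("F", "F", "P", "P")
  bd <- c(TRUE, FALSE, FALSE, TRUE)
  ann <- bead_annotation(1L, 0:3, (0:3) * 1e5, cls, FALSE, bd)
  topo <- build_topology(ann)
  expect_equal(topo$boundary_class, "P")  # 2/4 F is not a strict majority
})

test_that("topology rejects unsorted or degenerate chains", {
  ann <- bead_annotation(c(1L, 1L, 2L), c(0L, 1L, 0L), c(0, 1e5, 0),
                         "F", FALSE, FALSE)
  expect_error(build_topology(ann), "at least 2 beads")
  bad <- bead_annotation(1L, c(1L, 0L), c(1e5, 0), "F", FALSE, FALSE)
  expect_error(build_topology(bad), "sorted")
})

test_that("multi-chain topologies never bond across chains", {
  cfgs <- list(synth_config(n_beads = 40, seed = 1),
               synth_config(n_beads = 40, seed = 2))
  ann <- generate_multichain(cfgs)
  topo <- build_topology(ann)
  expect_equal(nrow(topo$bonds), 78)  # 39 per chain
  expect_true(all(topo$chain[topo$bonds[, 1]] == topo$chain[topo$bonds[, 2]]))
  bb <- topo$boundary_bonds
  expect_true(all(topo$chain[bb[, 1]] == topo$chain[bb[, 2]]))
})

test_that("container radius follows the volume-fraction formula", {
  expect_equal(container_radius(8, 0.05), (2.5 * 8)^(1 / 3))
  expect_equal(container_radius(16, 0.05) / container_radius(8, 0.05),
               2^(1 / 3))
  expect_equal(build_container(500, radius_override = 16.7)$radius, 16.7)
  expect_error(container_radius(8, 0))
  expect_error(container_radius(8, 0.9))
})

test_that("engine total energy equals the brute-force term sum", {
  for (seed in c(4, 14, 24)) {
    s <- make_small_system(n = 12, seed = seed)
    e_engine <- potential_energy(s$x, s$topo, s$cont, s$p)
    e_brute <- brute_force_energy(s$x, s$topo, s$cont, s$p)
    expect_lt(abs(e_engine - e_brute) / abs(e_brute), 1e-10)
  }
  # also with the class pair potential applied to bonded pairs
  s <- make_small_system(n = 10, seed = 8)
  p2 <- ff_params(exclude_bonded = FALSE)
  topo2 <- build_topology(s$ann[1:10, ], p2)
  e_engine <- potential_energy(s$x, topo2, s$cont, p2)
  e_brute <- brute_force_energy(s$x, topo2, s$cont, p2)
  expect_lt(abs(e_engine - e_brute) / abs(e_brute), 1e-10)
})

test_that("LAMMPS export round-trips the topology exactly", {
  ann <- generate_annotation(synth_config(n_beads = 60, seed = 6))
  p <- ff_params()
  topo <- build_topology(ann, p)
  cont <- build_container(60)
  cfg <- sim_config(n_steps = 1000, seed = 3)
  dd <- tempfile(fileext = ".data"); ii <- tempfile(fileext = ".in")
  export_lammps(topo, cont, p, cfg, path_data = dd, path_input = ii)
  back <- read_lammps_data(dd)
  expect_equal(back$topology$bonds, topo$bonds)
  expect_equal(back$topology$boundary_bonds, topo$boundary_bonds)
  expect_equal(back$topology$boundary_class, topo$boundary_class)
  expect_equal(back$topology$class, topo$class)
  expect_equal(back$topology$is_lad, topo$is_lad)
  expect_equal(back$topology$chain, topo$chain)
  # data file declares one type-1 bond per backbone link
  expect_equal(sum(grepl("^\\d+ 1 \\d+ \\d+$",
                         readLines(dd)[-(1:20)])), nrow(topo$bonds))
  # input script carries the boundary-bond coefficients
  script <- readLines(ii)
  expect_true(any(grepl(sprintf("bond_coeff 2 harmonic %.4f", p$eps_fb),
                        script, fixed = TRUE)))
  expect_true(any(grepl(sprintf("bond_coeff 3 harmonic %.4f", p$eps_pb),
                        script, fixed = TRUE)))
})
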