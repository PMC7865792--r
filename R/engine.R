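#' Simulation configuration
#'
#' Langevin-dynamics settings in reduced units (time in \eqn{\tau_0},
#' temperature in \eqn{T_0}). The defaults are the desk-scale protocol:
#' timestep \eqn{0.01\,\tau_0}, annealing from \eqn{5\,T_0} down to
#' \eqn{1\,T_0} over 10% of the production length, \eqn{2\times 10^6}
#' production steps with a snapshot every 10,000 steps, and 4 independent
#' replicas. (The published long protocol, \eqn{2\times 10^8} steps, is
#' intended for the LAMMPS export path rather than the in-package engine.)
#'
#' @param dt production integration timestep (\eqn{\tau_0}).
#' @param anneal_dt timestep used during annealing; default `dt/2`, which
#'   keeps the integrator stable against FENE overstretch at the elevated
#'   start temperature.
#' @param n_steps production steps.
#' @param anneal_from,anneal_to thermostat targets for annealing
#'   (\eqn{T_0}); must satisfy `anneal_from >= anneal_to`.
#' @param anneal_steps annealing length; default 10% of `n_steps`.
#' @param friction Langevin friction (\eqn{1/\tau_0}); 0 gives NVE dynamics.
#' @param mass bead mass (reduced units).
#' @param snapshot_interval steps between saved frames.
#' @param n_replicas number of independent replicas.
#' @param seed master integer seed.
#' @param neighbor_skin Verlet-list skin (\eqn{\sigma_0}); a pure
#'   efficiency parameter (any positive value yields correct forces)
#'   balancing rebuild frequency against pair-list size.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, anneal_dt = dt / 2, n_steps = 2e6,
                       anneal_from = 5.0, anneal_to = 1.0,
                       anneal_steps = NULL, friction = 1.0, mass = 1.0,
                       snapshot_interval = 1e4, n_replicas = 4L, seed = 1L,
                       neighbor_skin = 0.3) {
  if (dt <= 0 || anneal_dt <= 0) stop("timesteps must be positive")
  if (anneal_from < anneal_to) stop("anneal_from must be >= anneal_to")
  if (snapshot_interval < 1) stop("snapshot_interval must be >= 1")
  if (is.null(anneal_steps)) anneal_steps <- round(0.1 * n_steps)
  structure(list(dt = dt, anneal_dt = anneal_dt, n_steps = n_steps,
                 anneal_from = anneal_from,
                 anneal_to = anneal_to, anneal_steps = anneal_steps,
                 friction = friction, mass = mass,
                 snapshot_interval = snapshot_interval,
                 n_replicas = as.integer(n_replicas), seed = as.integer(seed),
                 neighbor_skin = neighbor_skin), class = "sim_config")
}

#' Initial conformation: random self-avoiding chain in the container
#'
#' Each chain is grown as a random walk with step length \eqn{1\,\sigma_0},
#' rejecting candidate beads closer than `min_dist` to any placed bead or
#' within `margin` of the container wall (backtracking on repeated failure).
#' Velocities are drawn from the Maxwell distribution at `temperature`.
#'
#' @param x a bead annotation or a [build_topology()] object (the chain
#'   layout is all that is used).
#' @param container a [build_container()] object.
#' @param seed integer seed; the construction is deterministic given it.
#' @param temperature initial kinetic temperature (\eqn{T_0}); the annealing
#'   start temperature by convention.
#' @param min_dist self-avoidance distance (\eqn{\sigma_0}).
#' @param margin clearance kept from the wall (\eqn{\sigma_0}).
#' @param mass bead mass.
#' @return object of class `sim_state`: list with `coords`, `velocities`,
#'   `step`, `temperature`.
#' @export
init_conformation <- function(x, container, seed = 1L, temperature = 5.0,
                              min_dist = 0.8, margin = 1.0, mass = 1.0) {
  chain <- if (inherits(x, "chromo_topology")) x$chain else x$chain
  n <- length(chain)
  rmax <- container$radius - margin
  if (rmax <= 0.5) stop("container too small to place the chain")
  set.seed(seed)
  coords <- matrix(NA_real_, n, 3)
  placed <- 0L
  fail_total <- 0L
  md2 <- min_dist^2
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    k <- 1L
    while (k <= length(idx)) {
      tries <- 0L
      repeat {
        if (k == 1L) {
          cand <- stats::runif(3, -rmax, rmax)
          ok_sphere <- sum(cand^2) <= rmax^2
        } else {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          cand <- coords[idx[k - 1L], ] + dir
          ok_sphere <- sum(cand^2) <= rmax^2
        }
        ok <- ok_sphere
        if (ok && placed > 0L) {
          prev <- coords[seq_len(placed), , drop = FALSE]
          # a bonded predecessor sits exactly 1 sigma away; exclude it
          if (k > 1L) prev <- prev[-(placed), , drop = FALSE]
          if (nrow(prev) > 0) {
            d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
              (prev[, 3] - cand[3])^2
            ok <- min(d2) >= md2
          }
        }
        if (ok) break
        tries <- tries + 1L
        fail_total <- fail_total + 1L
        if (fail_total > 400L * n)
          stop("failed to place the chain; try a larger container")
        if (tries >= 50L && k > 1L) {  # backtrack one bead
          coords[idx[k - 1L], ] <- NA_real_
          placed <- placed - 1L
          k <- k - 1L
          tries <- 0L
        }
      }
      coords[idx[k], ] <- cand
      placed <- placed + 1L
      k <- k + 1L
    }
  }
  vel <- matrix(stats::rnorm(3 * n, sd = sqrt(temperature / mass)), n, 3)
  structure(list(coords = coords, velocities = vel, step = 0L,
                 temperature = temperature), class = "sim_state")
}

md_core <- function(state, topology, container, params, config, n_steps,
                    temp_from, temp_to, anneal_steps, seed, save_frames,
                    dt = config$dt) {
  a <- topo_args(topology, container, params)
  cpp_run_md(state$coords, state$velocities, a$type, a$chain, a$lad, a$bonds,
             a$bbonds, a$bbond_eps, a$eps_pair, a$rc_pair, a$fene_k,
             a$fene_r0, a$radius, a$eps_lc, a$rc_wall_lad, a$eps_wall_rep,
             a$rc_wall_rep, a$exclude_bonded, dt, n_steps,
             config$snapshot_interval, temp_from, temp_to, anneal_steps,
             config$friction, config$mass, as.integer(seed %% .Machine$integer.max),
             config$neighbor_skin, save_frames)
}

#' Anneal a configuration from a high to the working temperature
#'
#' The thermostat target decreases linearly from `anneal_from` to
#' `anneal_to` over `anneal_steps`; with `anneal_steps = 0` the temperature
#' is set directly (velocities rescaled to the target). No frames are saved.
#'
#' @param state a [init_conformation()] state.
#' @param topology,container,params model definition.
#' @param config a [sim_config()].
#' @param seed seed for the thermostat noise; defaults to `config$seed`.
#' @return the annealed `sim_state` (with the thermostat log as attribute
#'   `"log"`).
#' @export
anneal <- function(state, topology, container, params = ff_params(),
                   config = sim_config(), seed = config$seed) {
  if (config$anneal_steps == 0) {
    tk <- kinetic_temperature(state, config$mass)
    if (tk > 0) state$velocities <- state$velocities * sqrt(config$anneal_to / tk)
    state$temperature <- config$anneal_to
    return(state)
  }
  res <- md_core(state, topology, container, params, config,
                 n_steps = config$anneal_steps,
                 temp_from = config$anneal_from, temp_to = config$anneal_to,
                 anneal_steps = config$anneal_steps, seed = seed,
                 save_frames = FALSE, dt = config$anneal_dt)
  out <- structure(list(coords = res$coords, velocities = res$velocities,
                        step = state$step + config$anneal_steps,
                        temperature = config$anneal_to), class = "sim_state")
  attr(out, "log") <- res$log
  out
}

#' Kinetic temperature of a state
#'
#' Ideal-gas estimator \eqn{T = 2 E_{kin} / (3 N k_B)} in \eqn{T_0} units.
#'
#' @param state a `sim_state`.
#' @param mass bead mass.
#' @return temperature in \eqn{T_0}.
#' @export
kinetic_temperature <- function(state, mass = 1.0) {
  v2 <- sum(state$velocities^2)
  mass * v2 / (3 * nrow(state$velocities))
}

#' Run Langevin production dynamics
#'
#' BAOAB Langevin integration at the fixed working temperature
#' (`config$anneal_to`), saving a frame every `snapshot_interval` steps.
#' Forces are the full model: FENE backbone, type-dependent
#' truncated-shifted LJ pairs, harmonic TAD-boundary bonds and wall terms.
#' Deterministic given `seed`.
#'
#' @param state an annealed `sim_state`.
#' @param topology,container,params model definition.
#' @param config a [sim_config()].
#' @param seed noise seed; defaults to `config$seed`.
#' @return object of class `chromo_trajectory`: frames (list of n x 3
#'   matrices), their step numbers, the energy/temperature log, and
#'   references to annotation, container, params and config.
#' @export
run_md <- function(state, topology, container, params = ff_params(),
                   config = sim_config(), seed = config$seed) {
  res <- md_core(state, topology, container, params, config,
                 n_steps = config$n_steps, temp_from = config$anneal_to,
                 temp_to = config$anneal_to, anneal_steps = 0, seed = seed,
                 save_frames = TRUE)
  structure(list(frames = res$frames, steps = res$log$step + state$step,
                 log = res$log, annotation = topology$annotation,
                 topology = topology, container = container,
                 params = params, config = config,
                 final_state = structure(
                   list(coords = res$coords, velocities = res$velocities,
                        step = state$step + config$n_steps,
                        temperature = config$anneal_to), class = "sim_state")),
            class = "chromo_trajectory")
}

#' @export
print.chromo_trajectory <- function(x, ...) {
  cat(sprintf("Chromatin trajectory: %d frames of %d beads (every %g steps)\n",
              length(x$frames), x$topology$n_beads,
              x$config$snapshot_interval))
  invisible(x)
}

#' Full single-replica pipeline
#'
#' Builds topology and container from an annotation, grows an initial
#' self-avoiding conformation, anneals, and runs production dynamics.
#'
#' @param beads a bead annotation.
#' @param params an [ff_params()].
#' @param config a [sim_config()].
#' @param phi chromatin volume fraction for the container.
#' @param radius_override fixed container radius (\eqn{\sigma_0}), or `NULL`.
#' @param seed seed for this replica; defaults to `config$seed`.
#' @return a `chromo_trajectory`.
#' @export
simulate_chromatin <- function(beads, params = ff_params(),
                               config = sim_config(), phi = 0.05,
                               radius_override = NULL, seed = config$seed) {
  topology <- build_topology(beads, params)
  container <- build_container(topology$n_beads, phi = phi,
                               radius_override = radius_override)
  state <- init_conformation(topology, container, seed = seed,
                             temperature = config$anneal_from,
                             mass = config$mass)
  mn <- minimize_energy(state$coords, topology, container, params,
                        skin = config$neighbor_skin)
  state$coords <- mn$coords
  state <- anneal(state, topology, container, params, config, seed = seed + 31L)
  run_md(state, topology, container, params, config, seed = seed + 137L)
}

#' Run independent replicas
#'
#' Repeats [simulate_chromatin()] `config$n_replicas` times from
#' independent initial conformations and velocities. Replica seeds are
#' derived from the master seed (`config$seed + 7919 * replica`), so results
#' do not depend on execution order.
#'
#' @inheritParams simulate_chromatin
#' @return list of `chromo_trajectory` objects.
#' @export
run_replicas <- function(beads, params = ff_params(), config = sim_config(),
                         phi = 0.05, radius_override = NULL) {
  if (config$n_replicas < 1) stop("n_replicas must be >= 1")
  lapply(seq_len(config$n_replicas), function(r) {
    simulate_chromatin(beads, params, config, phi = phi,
                       radius_override = radius_override,
                       seed = config$seed + 7919L * r)
  })
}

#' Write/read trajectories as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying the step number
#' and container radius, then `species x y z lad` rows with the species
#' column holding the F/P class.
#'
#' @param traj a `chromo_trajectory`.
#' @param path file path.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` a list with
#'   `frames`, `steps`, `species`, `lad`, `radius`.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cls <- traj$topology$class
  lad <- as.integer(traj$topology$is_lad)
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf(
      "step=%d radius=%.6f Properties=species:S:1:pos:R:3:lad:I:1",
      as.integer(traj$steps[f]), traj$container$radius), con)
    writeLines(sprintf("%s %.8f %.8f %.8f %d", cls, fr[, 1], fr[, 2],
                       fr[, 3], lad), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); steps <- integer(0); species <- NULL; lad <- NULL
  radius <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    m <- regmatches(hdr, regexec("step=(\\d+)", hdr))[[1]]
    steps <- c(steps, if (length(m) == 2) as.integer(m[2]) else NA_integer_)
    m <- regmatches(hdr, regexec("radius=([0-9.eE+-]+)", hdr))[[1]]
    if (length(m) == 2) radius <- as.numeric(m[2])
    rows <- strsplit(lines[(i + 2L):(i + 1L + n)], "\\s+")
    mat <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), n, 3, byrow = TRUE)
    frames[[length(frames) + 1L]] <- mat
    if (is.null(species)) {
      species <- vapply(rows, `[`, character(1), 1)
      lad <- as.integer(vapply(rows, `[`, character(1), 5))
    }
    i <- i + 2L + n
  }
  list(frames = frames, steps = steps, species = species,
       lad = as.logical(lad), radius = radius)
}
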