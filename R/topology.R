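#' Build the bonded topology from a bead annotation
#'
#' Creates the full interaction topology: a FENE backbone bond between every
#' pair of consecutive same-chain beads, one harmonic bond between every
#' pair of consecutive TAD-boundary beads of the same chain, per-bead pair
#' classes (F/P) for the type-dependent Lennard-Jones table, and per-bead
#' wall classes (LAD-attractive vs repulsive). Each boundary bond is classed
#' F-TAD when strictly more than half of the beads it spans (endpoints
#' included) are F, and P-TAD otherwise (ties are P).
#'
#' @param beads a bead annotation, sorted by (chain, bin).
#' @param params an [ff_params()] object (kept for reference).
#' @return object of class `chromo_topology`.
#' @export
build_topology <- function(beads, params = ff_params()) {
  ord <- order(beads$chain, beads$bin)
  if (!identical(ord, seq_len(nrow(beads))))
    stop("beads must be sorted by (chain, bin)")
  n <- nrow(beads)
  tab <- table(beads$chain)
  if (any(tab < 2)) stop("every chain needs at least 2 beads")

  same_chain <- beads$chain[-n] == beads$chain[-1]
  i1 <- which(same_chain)
  bonds <- cbind(i1, i1 + 1L)

  bb <- matrix(integer(0), ncol = 2)
  bclass <- character(0)
  for (ch in unique(beads$chain)) {
    rows <- which(beads$chain == ch)
    bd <- rows[beads$is_tad_boundary[rows]]
    if (length(bd) >= 2) {
      for (k in seq_len(length(bd) - 1)) {
        i <- bd[k]; j <- bd[k + 1]
        span <- beads$class[i:j]
        cls <- if (mean(span == "F") > 0.5) "F" else "P"
        bb <- rbind(bb, c(i, j))
        bclass <- c(bclass, cls)
      }
    }
  }

  structure(list(
    n_beads = n,
    chain = as.integer(beads$chain),
    class = beads$class,
    type = ifelse(beads$class == "F", 0L, 1L),
    is_lad = beads$is_lad,
    bonds = matrix(as.integer(bonds), ncol = 2),
    boundary_bonds = matrix(as.integer(bb), ncol = 2),
    boundary_class = bclass,
    annotation = beads,
    params = params), class = "chromo_topology")
}

#' @export
print.chromo_topology <- function(x, ...) {
  cat(sprintf("Chromatin topology: %d beads, %d chain(s)\n", x$n_beads,
              length(unique(x$chain))))
  cat(sprintf("  FENE backbone bonds: %d\n", nrow(x$bonds)))
  cat(sprintf("  TAD-boundary bonds: %d (%d F-TAD, %d P-TAD)\n",
              nrow(x$boundary_bonds), sum(x$boundary_class == "F"),
              sum(x$boundary_class == "P")))
  cat(sprintf("  LAD (wall-attractive) beads: %d\n", sum(x$is_lad)))
  invisible(x)
}

#' Pair interaction class of two beads
#'
#' @param topology a [build_topology()] object.
#' @param i,j bead indices (1-based).
#' @return `"FF"`, `"PP"` or `"PF"`.
#' @export
pair_class <- function(topology, i, j) {
  a <- topology$class[i]; b <- topology$class[j]
  ifelse(a == "F" & b == "F", "FF", ifelse(a == "P" & b == "P", "PP", "PF"))
}

# marshal everything for the C++ entry points
topo_args <- function(topology, container, params) {
  eps <- matrix(c(params$eps_ff, params$eps_pf,
                  params$eps_pf, params$eps_pp), 2, 2)
  beps <- ifelse(topology$boundary_class == "F", params$eps_fb, params$eps_pb)
  bb <- topology$boundary_bonds
  storage.mode(bb) <- "integer"
  bonds <- topology$bonds
  storage.mode(bonds) <- "integer"
  list(type = topology$type, chain = topology$chain,
       lad = topology$is_lad, bonds = bonds, bbonds = bb,
       bbond_eps = as.numeric(beps), eps_pair = eps,
       rc_pair = params$rc_pair, fene_k = params$fene_k,
       fene_r0 = params$fene_r0, radius = container$radius,
       eps_lc = params$eps_lc, rc_wall_lad = params$rc_wall_lad,
       eps_wall_rep = params$eps_wall_rep, rc_wall_rep = params$rc_wall_rep,
       exclude_bonded = params$exclude_bonded)
}

#' Total potential energy and forces of a configuration
#'
#' Evaluates the complete force field (FENE backbone, type-dependent pair
#' LJ, harmonic TAD-boundary bonds, wall terms) with the engine's
#' neighbour-list machinery. `forces()` returns the analytic forces,
#' `potential_energy()` the scalar energy.
#'
#' @param coords n x 3 coordinate matrix in \eqn{\sigma_0}.
#' @param topology a [build_topology()] object.
#' @param container a [build_container()] object.
#' @param params an [ff_params()] object.
#' @param skin neighbour-list skin in \eqn{\sigma_0}.
#' @return `potential_energy()`: a number (\eqn{\epsilon_0});
#'   `forces()`: an n x 3 matrix (\eqn{\epsilon_0/\sigma_0}).
#' @export
potential_energy <- function(coords, topology, container,
                             params = ff_params(), skin = 0.3) {
  a <- topo_args(topology, container, params)
  res <- cpp_forces_energy(coords, a$type, a$chain, a$lad, a$bonds, a$bbonds,
                           a$bbond_eps, a$eps_pair, a$rc_pair, a$fene_k,
                           a$fene_r0, a$radius, a$eps_lc, a$rc_wall_lad,
                           a$eps_wall_rep, a$rc_wall_rep, a$exclude_bonded,
                           skin)
  res$energy
}

#' Relax a configuration by capped steepest descent
#'
#' Displacement-capped steepest-descent minimization of the total potential
#' energy. Freshly grown self-avoiding chains contain overlaps (down to the
#' 0.8 \eqn{\sigma_0} self-avoidance distance) whose repulsive forces are
#' far too steep for the production timestep; a short relaxation removes
#' them before annealing. Deterministic (no randomness involved).
#'
#' @inheritParams potential_energy
#' @param max_iter iteration cap.
#' @param max_disp largest per-bead displacement per iteration
#'   (\eqn{\sigma_0}).
#' @param ftol stop when the largest force magnitude falls below this.
#' @return list with `coords`, `energy`, `iterations`.
#' @export
minimize_energy <- function(coords, topology, container,
                            params = ff_params(), skin = 0.3,
                            max_iter = 2000, max_disp = 0.05, ftol = 10) {
  a <- topo_args(topology, container, params)
  cpp_minimize(coords, a$type, a$chain, a$lad, a$bonds, a$bbonds,
               a$bbond_eps, a$eps_pair, a$rc_pair, a$fene_k, a$fene_r0,
               a$radius, a$eps_lc, a$rc_wall_lad, a$eps_wall_rep,
               a$rc_wall_rep, a$exclude_bonded, skin, as.integer(max_iter),
               max_disp, ftol)
}

#' @rdname potential_energy
#' @export
forces <- function(coords, topology, container, params = ff_params(),
                   skin = 0.3) {
  a <- topo_args(topology, container, params)
  res <- cpp_forces_energy(coords, a$type, a$chain, a$lad, a$bonds, a$bbonds,
                           a$bbond_eps, a$eps_pair, a$rc_pair, a$fene_k,
                           a$fene_r0, a$radius, a$eps_lc, a$rc_wall_lad,
                           a$eps_wall_rep, a$rc_wall_rep, a$exclude_bonded,
                           skin)
  res$forces
}
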