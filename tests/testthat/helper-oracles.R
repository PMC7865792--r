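# Brute-force O(n^2) total potential energy built from the exported
# term-wise functions: the independent oracle for the engine's total.
brute_force_energy <- function(x, topo, cont, p) {
  n <- nrow(x)
  eps_of <- function(a, b) {
    if (a == "F" && b == "F") p$eps_ff
    else if (a == "P" && b == "P") p$eps_pp
    else p$eps_pf
  }
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (p$exclude_bonded && topo$chain[i] == topo$chain[j] &&
          abs(i - j) == 1) next
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      e <- e + pair_energy(r, eps_of(topo$class[i], topo$class[j]), p$rc_pair)
    }
  }
  for (b in seq_len(nrow(topo$bonds))) {
    r <- sqrt(sum((x[topo$bonds[b, 1], ] - x[topo$bonds[b, 2], ])^2))
    e <- e + fene_energy(r, p)
    if (p$exclude_bonded && r < 2^(1 / 6))
      e <- e + pair_energy(r, 1, 2^(1 / 6)) + 0  # WCA = shifted LJ cut at min
  }
  if (nrow(topo$boundary_bonds) > 0) {
    for (b in seq_len(nrow(topo$boundary_bonds))) {
      r <- sqrt(sum((x[topo$boundary_bonds[b, 1], ] -
                       x[topo$boundary_bonds[b, 2], ])^2))
      eb <- if (topo$boundary_class[b] == "F") p$eps_fb else p$eps_pb
      e <- e + boundary_bond_energy(r, eb)
    }
  }
  d <- cont$radius - sqrt(rowSums(x^2))
  e + sum(wall_energy(d, topo$is_lad, p))
}

# tiny valid (topology, container, jittered chain) system for oracle tests;
# the annotation is deterministic so every force-field term is exercised
make_small_system <- function(n = 12, seed = 4, radius = 4, jitter = 0.05) {
  cls <- rep(c("F", "F", "F", "P", "P", "P", "P"), length.out = n)
  bd <- seq_len(n) %% 4 == 1
  lad <- cls == "P" & rep(c(TRUE, FALSE), length.out = n)
  ann <- bead_annotation(1L, seq_len(n) - 1L, (seq_len(n) - 1L) * 1e5,
                         cls, lad, bd)
  p <- ff_params()
  topo <- build_topology(ann, p)
  cont <- build_container(n, radius_override = radius)
  st <- init_conformation(topo, cont, seed = seed + 1)
  set.seed(seed + 2)
  x <- st$coords + matrix(rnorm(3 * n, sd = jitter), n, 3)
  list(ann = ann, p = p, topo = topo, cont = cont, state = st, x = x)
}

# hand-built contact map from an explicit matrix + annotation
toy_map <- function(m, classes, chain = NULL, threshold = 2.5) {
  n <- nrow(m)
  if (is.null(chain)) chain <- rep(1L, n)
  bins <- stats::ave(seq_len(n), chain, FUN = seq_along) - 1L
  ann <- bead_annotation(chain = chain, bin = bins, bp_start = bins * 1e5,
                         class = classes, is_lad = FALSE,
                         is_tad_boundary = FALSE)
  structure(list(matrix = m, annotation = ann, threshold = threshold,
                 n_frames = 1L), class = "contact_map")
}
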