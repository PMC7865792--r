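#' Export the model for LAMMPS
#'
#' Writes a LAMMPS data file (atom style `molecular`) and a companion input
#' script. Atom types encode class and wall behaviour: 1 = F, 2 = P,
#' 3 = F in an LAD, 4 = P in an LAD. Bond types: 1 = FENE backbone,
#' 2 = F-TAD boundary harmonic, 3 = P-TAD boundary harmonic (LAMMPS
#' `harmonic` is \eqn{K(r-r_0)^2}, so \eqn{K = \epsilon_b}, \eqn{r_0 = 0}
#' matches the \eqn{\epsilon_b r^2} form exactly). The script uses
#' `bond_style hybrid fene harmonic`; LAMMPS' FENE style carries its own
#' WCA core for bonded pairs, so 1-2 pairs are excluded from the pair table
#' there (`special_bonds lj 0 1 1`). Pair interactions are
#' `lj/cut 1.3` with `pair_modify shift yes`; the spherical wall is a
#' `region` + `fix wall/region lj126`, with the LAD group cut at 1.3 and
#' the rest at \eqn{2^{1/6}}. The run section reproduces the annealing
#' protocol (5.0 to 1.0 T0) and the configured production length, timestep
#' and dump interval.
#'
#' @param topology a [build_topology()] object.
#' @param container a [build_container()] object.
#' @param params an [ff_params()] object.
#' @param config a [sim_config()]; supplies steps, timestep, dump interval.
#' @param path_data,path_input output paths.
#' @param state optional `sim_state` supplying coordinates; by default an
#'   initial self-avoiding conformation is grown with `config$seed`.
#' @return invisible list with the two paths.
#' @export
export_lammps <- function(topology, container, params = ff_params(),
                          config = sim_config(),
                          path_data = "chromatin.data",
                          path_input = "chromatin.in", state = NULL) {
  if (!all(topology$boundary_class %in% c("F", "P")))
    stop("unsupported boundary-bond class: cannot map to a hybrid bond style")
  if (is.null(state))
    state <- init_conformation(topology, container, seed = config$seed,
                               temperature = config$anneal_from)
  n <- topology$n_beads
  atype <- ifelse(topology$class == "F", 1L, 2L) + 2L * topology$is_lad
  btype <- c(rep(1L, nrow(topology$bonds)),
             ifelse(topology$boundary_class == "F", 2L, 3L))
  ball <- rbind(topology$bonds, topology$boundary_bonds)
  nb <- nrow(ball)
  R <- container$radius

  lines <- c(
    "LAMMPS data file: chromatin block-copolymer model (reduced units)",
    "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nb),
    "4 atom types",
    "3 bond types",
    "",
    sprintf("%.6f %.6f xlo xhi", -R - 1, R + 1),
    sprintf("%.6f %.6f ylo yhi", -R - 1, R + 1),
    sprintf("%.6f %.6f zlo zhi", -R - 1, R + 1),
    "",
    "Masses",
    "",
    sprintf("%d 1.0", 1:4),
    "",
    "Atoms # molecular",
    "",
    sprintf("%d %d %d %.8f %.8f %.8f", seq_len(n), topology$chain, atype,
            state$coords[, 1], state$coords[, 2], state$coords[, 3]),
    "",
    "Bonds",
    "",
    sprintf("%d %d %d %d", seq_len(nb), btype, ball[, 1], ball[, 2]))
  writeLines(lines, path_data)

  # class of each atom type for the pair table
  tcl <- c("F", "P", "F", "P")
  eps_of <- function(a, b) {
    if (tcl[a] == "F" && tcl[b] == "F") params$eps_ff
    else if (tcl[a] == "P" && tcl[b] == "P") params$eps_pp
    else params$eps_pf
  }
  pc <- character(0)
  for (a in 1:4) for (b in a:4)
    pc <- c(pc, sprintf("pair_coeff %d %d %.4f 1.0", a, b, eps_of(a, b)))

  seed1 <- config$seed %% 900000 + 1
  input <- c(
    "# chromatin block-copolymer model: annealing + production",
    "units lj",
    "atom_style molecular",
    "boundary f f f",
    sprintf("read_data %s", basename(path_data)),
    "",
    "bond_style hybrid fene harmonic",
    sprintf("bond_coeff 1 fene %.4f %.4f 1.0 1.0", params$fene_k,
            params$fene_r0),
    sprintf("bond_coeff 2 harmonic %.4f 0.0", params$eps_fb),
    sprintf("bond_coeff 3 harmonic %.4f 0.0", params$eps_pb),
    "special_bonds lj 0.0 1.0 1.0  # FENE carries its own WCA for 1-2 pairs",
    "",
    sprintf("pair_style lj/cut %.6f", params$rc_pair),
    "pair_modify shift yes",
    pc,
    "",
    sprintf("region nucleus sphere 0.0 0.0 0.0 %.6f side in", R),
    "group lads type 3 4",
    "group nonlads type 1 2",
    sprintf("fix wall_lad lads wall/region nucleus lj126 %.4f 1.0 %.6f",
            params$eps_lc, params$rc_wall_lad),
    sprintf("fix wall_rep nonlads wall/region nucleus lj126 %.4f 1.0 %.6f",
            params$eps_wall_rep, params$rc_wall_rep),
    "",
    sprintf("velocity all create %.2f %d", config$anneal_from, seed1),
    "fix integrate all nve",
    sprintf("fix thermo all langevin %.2f %.2f %.4f %d", config$anneal_from,
            config$anneal_to, 1 / config$friction, seed1 + 1),
    sprintf("timestep %.4f", config$dt),
    sprintf("thermo %d", as.integer(config$snapshot_interval)),
    sprintf("dump traj all custom %d chromatin.lammpstrj id mol type x y z",
            as.integer(config$snapshot_interval)),
    sprintf("run %d  # annealing", as.integer(config$anneal_steps)),
    "unfix thermo",
    sprintf("fix thermo all langevin %.2f %.2f %.4f %d", config$anneal_to,
            config$anneal_to, 1 / config$friction, seed1 + 2),
    sprintf("run %d  # production", as.integer(config$n_steps)))
  writeLines(input, path_input)
  invisible(list(data = path_data, input = path_input))
}

#' Parse a LAMMPS data file back into a topology
#'
#' Reads a data file written by [export_lammps()] and reconstructs the bead
#' classes, LAD flags, chain ids, backbone and boundary bond lists, plus
#' the stored coordinates. Round-tripping a topology through the data file
#' reproduces its bond lists exactly.
#'
#' @param path data-file path.
#' @return list with `topology` (a `chromo_topology` rebuilt from the file)
#'   and `coords`.
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  get_count <- function(pat) {
    ln <- grep(pat, lines, value = TRUE)[1]
    as.integer(strsplit(trimws(ln), "\\s+")[[1]][1])
  }
  n <- get_count(" atoms$")
  nb <- get_count(" bonds$")
  sec <- function(name, nrows) {
    i <- grep(paste0("^", name), lines)[1]
    block <- lines[(i + 2):(i + 1 + nrows)]
    do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
  }
  atoms <- sec("Atoms", n)
  atoms <- atoms[order(atoms[, 1]), , drop = FALSE]
  bonds <- sec("Bonds", nb)

  atype <- as.integer(atoms[, 3])
  cls <- ifelse(atype %in% c(1L, 3L), "F", "P")
  lad <- atype > 2L
  chain <- as.integer(atoms[, 2])
  coords <- atoms[, 4:6, drop = FALSE]

  bt <- as.integer(bonds[, 2])
  backbone <- matrix(as.integer(bonds[bt == 1L, 3:4]), ncol = 2)
  bbn <- matrix(as.integer(bonds[bt > 1L, 3:4]), ncol = 2)
  bcls <- ifelse(bt[bt > 1L] == 2L, "F", "P")

  ann <- bead_annotation(
    chain = chain, bin = stats::ave(seq_len(n), chain, FUN = seq_along) - 1L,
    bp_start = (stats::ave(seq_len(n), chain, FUN = seq_along) - 1L) * 1e5,
    class = cls, is_lad = lad, is_tad_boundary = FALSE)
  topo <- structure(list(
    n_beads = n, chain = chain, class = cls,
    type = ifelse(cls == "F", 0L, 1L), is_lad = lad,
    bonds = backbone, boundary_bonds = bbn, boundary_class = bcls,
    annotation = ann, params = NULL), class = "chromo_topology")
  list(topology = topo, coords = coords)
}
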