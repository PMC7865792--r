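#' Force-field parameters for the block-copolymer chromatin model
#'
#' Collects every interaction constant of the model in reduced units:
#' lengths in \eqn{\sigma_0} (150 nm, the diameter of a 100-kbp bead) and
#' energies in \eqn{\epsilon_0 = k_B T_0} with \eqn{T_0 = 308} K (about
#' 2.6 kJ/mol).
#'
#' The defaults are the reference parameter set: attractive truncated-shifted
#' Lennard-Jones pair interactions \eqn{\epsilon_{PP} = 4.6},
#' \eqn{\epsilon_{FF} = 4.3}, \eqn{\epsilon_{PF} = 3.0} (cutoff
#' \eqn{1.3\,\sigma_0}), harmonic TAD-boundary bonds
#' \eqn{U = \epsilon_b r^2} with \eqn{\epsilon_{PB} = 0.2},
#' \eqn{\epsilon_{FB} = 0.4}, a FENE backbone (\eqn{K = 30},
#' \eqn{R_0 = 1.5\,\sigma_0}), and a LAD--wall attraction
#' \eqn{\epsilon_{LC} = 6.7} (cutoff \eqn{1.3\,\sigma_0}); all other beads
#' see a purely repulsive wall cut at \eqn{2^{1/6}\,\sigma_0}.
#'
#' Pair strengths are physically meaningful in 3.0--5.0 \eqn{\epsilon_0}
#' (well depth of the truncated form 1.0--2.0 \eqn{\epsilon_0}) and
#' \eqn{\epsilon_{LC}} in 6.0--8.0 \eqn{\epsilon_0}; values outside those
#' ranges are accepted (they are useful for controls such as ideal chains)
#' but trigger a warning unless `check = FALSE`.
#'
#' @param eps_pp,eps_ff,eps_pf pair attraction strengths (\eqn{\epsilon_0}).
#' @param eps_pb,eps_fb harmonic TAD-boundary bond strengths for P-TADs and
#'   F-TADs (\eqn{\epsilon_0/\sigma_0^2}); must satisfy `eps_fb > eps_pb`
#'   and both below 0.5.
#' @param eps_lc LAD--wall attraction strength (\eqn{\epsilon_0}).
#' @param eps_wall_rep strength of the repulsive wall term for non-LAD beads;
#'   the cutoff at \eqn{2^{1/6}\sigma_0} makes the term purely repulsive for
#'   any strength.
#' @param rc_pair pair cutoff (\eqn{\sigma_0}).
#' @param rc_wall_lad,rc_wall_rep wall cutoffs for LAD and non-LAD beads.
#' @param fene_k,fene_r0 FENE spring constant and divergence length.
#' @param sigma0_nm physical bead diameter in nm (metadata only).
#' @param t0_kelvin reference temperature in K (metadata only).
#' @param exclude_bonded if `TRUE` (default), the class pair potential acts
#'   only on non-bonded pairs -- directly bonded (1-2) pairs interact through
#'   the FENE bond plus a unit-strength WCA core, the standard bead-spring
#'   convention (and what the LAMMPS export encodes). `FALSE` instead applies
#'   the class pair potential to every pair including bonded ones.
#' @param check validate ranges and orderings.
#' @return an object of class `ff_params` (a named list).
#' @examples
#' p <- ff_params()
#' p$eps_pp
#' @export
ff_params <- function(eps_pp = 4.6, eps_ff = 4.3, eps_pf = 3.0,
                      eps_pb = 0.2, eps_fb = 0.4, eps_lc = 6.7,
                      eps_wall_rep = 1.0, rc_pair = 1.3,
                      rc_wall_lad = 1.3, rc_wall_rep = 2^(1/6),
                      fene_k = 30.0, fene_r0 = 1.5,
                      sigma0_nm = 150, t0_kelvin = 308,
                      exclude_bonded = TRUE, check = TRUE) {
  p <- list(eps_pp = eps_pp, eps_ff = eps_ff, eps_pf = eps_pf,
            eps_pb = eps_pb, eps_fb = eps_fb, eps_lc = eps_lc,
            eps_wall_rep = eps_wall_rep, rc_pair = rc_pair,
            rc_wall_lad = rc_wall_lad, rc_wall_rep = rc_wall_rep,
            fene_k = fene_k, fene_r0 = fene_r0,
            sigma0_nm = sigma0_nm, t0_kelvin = t0_kelvin,
            eps0_kJ_per_mol = thermal_energy_kj_mol(t0_kelvin),
            exclude_bonded = isTRUE(exclude_bonded))
  num <- vapply(p[!(names(p) %in% "exclude_bonded")], is.numeric, logical(1))
  if (!all(num)) stop("all force-field parameters must be numeric")
  if (any(unlist(p[c("rc_pair", "rc_wall_lad", "rc_wall_rep",
                     "fene_k", "fene_r0")]) <= 0))
    stop("cutoffs and FENE constants must be positive")
  if (any(unlist(p[c("eps_pp", "eps_ff", "eps_pf", "eps_pb", "eps_fb",
                     "eps_lc", "eps_wall_rep")]) < 0))
    stop("interaction strengths must be non-negative")
  if (check) {
    if (eps_pp < eps_ff || eps_ff < eps_pf)
      warning("expected ordering eps_pp >= eps_ff >= eps_pf not satisfied")
    if (eps_fb < eps_pb)
      warning("expected eps_fb >= eps_pb (F-TAD boundary bonds are stronger)")
    if (eps_pb >= 0.5 || eps_fb >= 0.5)
      warning("TAD-boundary bond strengths are meant to stay below 0.5 eps0")
    eps3 <- c(eps_pp, eps_ff, eps_pf)
    if (any(eps3 > 0 & (eps3 < 3.0 | eps3 > 5.0)))
      warning("pair strengths outside the physical 3.0-5.0 eps0 range")
    if (eps_lc > 0 && (eps_lc < 6.0 || eps_lc > 8.0))
      warning("eps_lc outside the physical 6.0-8.0 eps0 range")
  }
  class(p) <- "ff_params"
  p
}

#' @export
print.ff_params <- function(x, ...) {
  cat("Force-field parameters (reduced units)\n")
  cat(sprintf("  pair eps (PP/FF/PF): %.2f / %.2f / %.2f eps0, rc = %.4g sigma0\n",
              x$eps_pp, x$eps_ff, x$eps_pf, x$rc_pair))
  cat(sprintf("  TAD boundary bonds (PB/FB): %.2f / %.2f eps0/sigma0^2\n",
              x$eps_pb, x$eps_fb))
  cat(sprintf("  FENE: K = %.1f, R0 = %.2f sigma0\n", x$fene_k, x$fene_r0))
  cat(sprintf("  wall: eps_lc = %.2f (rc %.4g), repulsive eps = %.2f (rc %.4g)\n",
              x$eps_lc, x$rc_wall_lad, x$eps_wall_rep, x$rc_wall_rep))
  cat(sprintf("  units: sigma0 = %g nm, eps0 = kB*%g K = %.3g kJ/mol\n",
              x$sigma0_nm, x$t0_kelvin, x$eps0_kJ_per_mol))
  invisible(x)
}

#' Thermal energy per mole
#'
#' \eqn{k_B T N_A} in kJ/mol; at the reference temperature 308 K this is the
#' model's energy unit \eqn{\epsilon_0 \approx 2.6} kJ/mol.
#'
#' @param t_kelvin temperature in K.
#' @return energy in kJ/mol.
#' @export
thermal_energy_kj_mol <- function(t_kelvin = 308) {
  kb <- 1.380649e-23      # J/K
  na <- 6.02214076e23     # 1/mol
  kb * na * t_kelvin / 1000
}

#' FENE backbone bond energy
#'
#' \eqn{U(r) = -\tfrac12 K R_0^2 \ln[1 - (r/R_0)^2]} for \eqn{r < R_0} and
#' \eqn{+\infty} beyond: the bond is finitely extensible and a configuration
#' with \eqn{r \ge R_0} is rejected.
#'
#' @param r bond length(s) in \eqn{\sigma_0}; vectorised.
#' @param params an [ff_params()] object.
#' @return energy in \eqn{\epsilon_0}; `Inf` at and beyond `fene_r0`.
#' @examples
#' fene_energy(1.0, ff_params())  # about 19.78 eps0
#' @export
fene_energy <- function(r, params = ff_params()) {
  stopifnot(all(r >= 0))
  k <- params$fene_k; r0 <- params$fene_r0
  out <- ifelse(r < r0, -0.5 * k * r0^2 * log(pmax(1 - (r / r0)^2, 0)), Inf)
  out[r >= r0] <- Inf
  out
}

#' Truncated-and-shifted Lennard-Jones pair energy
#'
#' \eqn{U(r) = 4\epsilon[(\sigma_0/r)^{12} - (\sigma_0/r)^6 -
#' (\sigma_0/r_c)^{12} + (\sigma_0/r_c)^6]} for \eqn{r < r_c}, zero beyond:
#' continuous at the cutoff by construction.
#'
#' @param r pair distance(s) in \eqn{\sigma_0}; vectorised.
#' @param eps interaction strength in \eqn{\epsilon_0}.
#' @param rc cutoff in \eqn{\sigma_0}.
#' @return energy in \eqn{\epsilon_0}; `Inf` at distance zero.
#' @examples
#' pair_energy(2^(1/6), eps = 1, rc = 1.3)  # well depth, about -0.343
#' @export
pair_energy <- function(r, eps, rc = 1.3) {
  stopifnot(all(r >= 0), rc > 0)
  shift <- (1 / rc)^12 - (1 / rc)^6
  out <- numeric(length(r))
  inside <- r < rc & r > 0
  ri <- r[inside]
  out[inside] <- 4 * eps * ((1 / ri)^12 - (1 / ri)^6 - shift)
  out[r == 0] <- Inf
  out
}

#' Harmonic TAD-boundary bond energy
#'
#' \eqn{U(r) = \epsilon_b r^2}: a weak zero-rest-length spring between
#' consecutive TAD-boundary beads that drives loop formation.
#'
#' @param r bond length(s) in \eqn{\sigma_0}.
#' @param eps_b bond strength (\eqn{\epsilon_0/\sigma_0^2}).
#' @return energy in \eqn{\epsilon_0}.
#' @export
boundary_bond_energy <- function(r, eps_b) {
  stopifnot(all(r >= 0))
  eps_b * r^2
}

#' Wall interaction energy
#'
#' Energy of a bead at distance `d` from the spherical container surface
#' (measured radially from the bead centre to the surface). LAD beads feel an
#' attractive truncated-shifted LJ with strength `eps_lc` and cutoff
#' \eqn{1.3\,\sigma_0}; all other beads a purely repulsive LJ cut at
#' \eqn{2^{1/6}\,\sigma_0}.
#'
#' @param d distance(s) to the wall in \eqn{\sigma_0}; must be positive
#'   (a bead at or beyond the wall is an invalid configuration).
#' @param is_lad logical, whether the bead is in a lamina-associated domain.
#' @param params an [ff_params()] object.
#' @return energy in \eqn{\epsilon_0}.
#' @examples
#' wall_energy(2^(1/6), is_lad = TRUE, params = ff_params())  # about -2.30
#' @export
wall_energy <- function(d, is_lad, params = ff_params()) {
  if (any(d <= 0)) stop("bead at or outside the container wall (d <= 0)")
  if (length(is_lad) == 1) is_lad <- rep(is_lad, length(d))
  stopifnot(length(is_lad) == length(d))
  out <- numeric(length(d))
  out[is_lad]  <- pair_energy(d[is_lad], params$eps_lc, params$rc_wall_lad)
  out[!is_lad] <- pair_energy(d[!is_lad], params$eps_wall_rep, params$rc_wall_rep)
  out
}

#' Spherical container
#'
#' The nucleus is a sphere the chromatin occupies at volume fraction `phi`
#' (default 5%, i.e. container volume 20 times the chromatin volume). With
#' the bead volume taken as a sphere of diameter \eqn{\sigma_0},
#' \eqn{R = (n\,v_{bead} / (\tfrac43\pi\,\phi))^{1/3}}. `radius_override`
#' pins the radius directly (e.g. the published \eqn{16.7\,\sigma_0} for a
#' single-chromosome system), bypassing the formula.
#'
#' @param n_beads number of beads.
#' @param phi chromatin volume fraction, in (0, 0.74).
#' @param radius_override radius in \eqn{\sigma_0}, or `NULL` to derive it.
#' @return object of class `chromo_container`: list with `radius` and `phi`.
#' @examples
#' container_radius(8, phi = 0.05)   # (2.5 * 8)^(1/3)
#' @export
build_container <- function(n_beads, phi = 0.05, radius_override = NULL) {
  r <- if (is.null(radius_override)) {
    container_radius(n_beads, phi)
  } else {
    stopifnot(is.numeric(radius_override), radius_override > 0)
    radius_override
  }
  structure(list(radius = r, phi = phi, n_beads = n_beads),
            class = "chromo_container")
}

#' @rdname build_container
#' @export
container_radius <- function(n_beads, phi = 0.05) {
  stopifnot(n_beads >= 1)
  if (!is.numeric(phi) || phi <= 0 || phi >= 0.74)
    stop("phi must lie in (0, 0.74)")
  v_bead <- (4 / 3) * pi * 0.5^3
  (n_beads * v_bead / ((4 / 3) * pi * phi))^(1 / 3)
}

#' @export
print.chromo_container <- function(x, ...) {
  cat(sprintf("Spherical container: radius %.3f sigma0 (phi = %g, %d beads)\n",
              x$radius, x$phi, x$n_beads))
  invisible(x)
}
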