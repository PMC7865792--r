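#' Ensemble contact map
#'
#' Two beads are in contact in a frame when their centre-to-centre distance
#' is strictly less than `threshold` (default \eqn{2.5\,\sigma_0}). The map
#' entry (i, j) is the fraction of pooled frames (all trajectories weighted
#' equally per frame) in which i and j are in contact; the diagonal is
#' defined as 1.
#'
#' @param trajectories a `chromo_trajectory` or a list of them (replicas).
#' @param threshold contact distance in \eqn{\sigma_0}.
#' @return object of class `contact_map`: list with `matrix` (n x n,
#'   values in `[0, 1]`), `annotation`, `threshold`, `n_frames`.
#' @export
contact_map <- function(trajectories, threshold = 2.5) {
  if (inherits(trajectories, "chromo_trajectory"))
    trajectories <- list(trajectories)
  frames <- do.call(c, lapply(trajectories, function(t) t$frames))
  if (length(frames) == 0) stop("no frames in the trajectories")
  counts <- cpp_contact_counts(frames, threshold)
  m <- counts / length(frames)
  diag(m) <- 1
  structure(list(matrix = m, annotation = trajectories[[1]]$annotation,
                 threshold = threshold, n_frames = length(frames)),
            class = "contact_map")
}

#' Build a contact map from raw frames
#'
#' Lower-level constructor for toy inputs and tests.
#'
#' @param frames list of n x 3 coordinate matrices.
#' @param annotation a bead annotation for the n beads.
#' @param threshold contact distance in \eqn{\sigma_0}.
#' @return a `contact_map`.
#' @export
contact_map_from_frames <- function(frames, annotation, threshold = 2.5) {
  if (length(frames) == 0) stop("no frames")
  counts <- cpp_contact_counts(frames, threshold)
  m <- counts / length(frames)
  diag(m) <- 1
  structure(list(matrix = m, annotation = annotation, threshold = threshold,
                 n_frames = length(frames)), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: %d x %d beads, %d frames, threshold %g sigma0\n",
              nrow(x$matrix), ncol(x$matrix), x$n_frames, x$threshold))
  invisible(x)
}

#' Contact probability versus genomic distance
#'
#' \eqn{P(N)}: the mean contact probability over all same-chain bead pairs
#' at sequential separation \eqn{N} (multiples of the 100-kbp bin). The
#' diagonal is excluded (\eqn{N \ge 100} kbps). `class_filter = "FF"`
#' (`"PP"`) restricts the average to pairs in which both beads are F (P).
#'
#' @param map a [contact_map()].
#' @param class_filter `"all"`, `"FF"` or `"PP"`.
#' @return object of class `ps_curve`: data.frame with `N_kbps`, `P`,
#'   `n_pairs`; separations with no eligible pair are absent.
#' @export
ps_curve <- function(map, class_filter = c("all", "FF", "PP")) {
  class_filter <- match.arg(class_filter)
  ann <- map$annotation
  if (is.null(ann)) stop("contact map carries no annotation")
  bin_kbp <- (attr(ann, "bin_bp") %||% 1e5) / 1000
  m <- map$matrix
  chains <- unique(ann$chain)
  smax <- max(table(ann$chain)) - 1
  ssum <- numeric(smax); scount <- numeric(smax)
  for (ch in chains) {
    rows <- which(ann$chain == ch)
    k <- length(rows)
    want <- switch(class_filter,
                   all = rep(TRUE, k),
                   FF = ann$class[rows] == "F",
                   PP = ann$class[rows] == "P")
    for (s in seq_len(k - 1)) {
      i <- seq_len(k - s)
      sel <- want[i] & want[i + s]
      if (!any(sel)) next
      v <- m[cbind(rows[i][sel], rows[i + s][sel])]
      ssum[s] <- ssum[s] + sum(v)
      scount[s] <- scount[s] + length(v)
    }
  }
  keep <- scount > 0
  out <- data.frame(N_kbps = which(keep) * bin_kbp, P = ssum[keep] / scount[keep],
                    n_pairs = scount[keep])
  attr(out, "class_filter") <- class_filter
  class(out) <- c("ps_curve", "data.frame")
  out
}

#' Fit a power law to a P(N) window
#'
#' Least-squares line on \eqn{(\log_{10} N, \log_{10} P)} restricted to
#' `window_kbps` (inclusive); \eqn{\alpha} is minus the slope. Points with
#' \eqn{P \le 0} are dropped; fewer than 3 remaining points is an error.
#' The standard regime windows are 300--700 kbps, 700 kbps--7 Mbps and
#' 7--20 Mbps.
#'
#' @param ps a [ps_curve()] (or any data.frame with `N_kbps` and `P`).
#' @param window_kbps numeric `(low, high)` in kbps.
#' @return object of class `regime_fit`: list with `window_kbps`, `alpha`,
#'   `intercept` (log10 P at N = 1 kbp), `residual` (RMS of log10
#'   residuals), `n_points`.
#' @export
fit_power_law <- function(ps, window_kbps = c(300, 700)) {
  stopifnot(length(window_kbps) == 2, window_kbps[1] < window_kbps[2])
  sel <- ps$N_kbps >= window_kbps[1] & ps$N_kbps <= window_kbps[2] & ps$P > 0
  d <- ps[sel, , drop = FALSE]
  if (nrow(d) < 3) stop("fewer than 3 positive points in the fit window")
  fit <- stats::lm(log10(P) ~ log10(N_kbps), data = d)
  structure(list(window_kbps = window_kbps,
                 alpha = -unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 n_points = nrow(d)), class = "regime_fit")
}

#' @export
print.regime_fit <- function(x, ...) {
  cat(sprintf("P(N) ~ N^-alpha, alpha = %.3f  (window %g-%g kbps, %d points, rms %.3g)\n",
              x$alpha, x$window_kbps[1], x$window_kbps[2], x$n_points,
              x$residual))
  invisible(x)
}

#' Ratio of F-domain to P-domain contact curves
#'
#' \eqn{P_{FF}(N) / P_{PP}(N)} on the shared N grid; points where
#' \eqn{P_{PP} = 0} are omitted.
#'
#' @param ps_ff,ps_pp [ps_curve()]s with filters FF and PP.
#' @return data.frame with `N_kbps` and `ratio`.
#' @export
fp_ratio_curve <- function(ps_ff, ps_pp) {
  common <- intersect(ps_ff$N_kbps, ps_pp$N_kbps)
  if (length(common) == 0) stop("curves share no N grid points")
  a <- ps_ff[match(common, ps_ff$N_kbps), ]
  b <- ps_pp[match(common, ps_pp$N_kbps), ]
  keep <- b$P > 0
  data.frame(N_kbps = common[keep], ratio = a$P[keep] / b$P[keep])
}

#' Radial density profile in the spherical container
#'
#' The container is divided into `n_shells` shells of equal thickness; per
#' frame the number of F and of P beads in each shell is divided by the
#' shell volume, and densities are averaged over all pooled frames. The
#' abscissa is the normalized radius r/R at the shell midpoint.
#'
#' @param trajectories a `chromo_trajectory` or list of them.
#' @param n_shells number of shells (default 200).
#' @param subset optional bead indices to restrict to (e.g. one chain).
#' @return object of class `radial_profile`: data.frame with `r_norm`,
#'   `dens_F`, `dens_P` plus attributes `shell_volumes` and `radius`.
#' @export
rdf_profile <- function(trajectories, n_shells = 200, subset = NULL) {
  if (inherits(trajectories, "chromo_trajectory"))
    trajectories <- list(trajectories)
  ann <- trajectories[[1]]$annotation
  radius <- trajectories[[1]]$container$radius
  frames <- do.call(c, lapply(trajectories, function(t) t$frames))
  cls <- ann$class
  rdf_from_frames(frames, cls, radius, n_shells = n_shells, subset = subset)
}

#' @rdname rdf_profile
#' @param frames list of n x 3 coordinate matrices.
#' @param classes character vector of per-bead classes (`"F"`/`"P"`).
#' @param radius container radius in \eqn{\sigma_0}.
#' @export
rdf_from_frames <- function(frames, classes, radius, n_shells = 200,
                            subset = NULL) {
  if (length(frames) == 0) stop("no frames")
  dr <- radius / n_shells
  edges3 <- (seq_len(n_shells) * dr)^3
  vol <- (4 / 3) * pi * diff(c(0, edges3))
  accF <- numeric(n_shells); accP <- numeric(n_shells)
  keep <- if (is.null(subset)) seq_along(classes) else subset
  isF <- classes[keep] == "F"
  for (fr in frames) {
    xyz <- fr[keep, , drop = FALSE]
    r <- sqrt(rowSums(xyz^2))
    if (any(r > radius))
      stop("bead outside the container: integrity violation")
    sh <- pmin(pmax(ceiling(r / dr), 1L), n_shells)
    accF <- accF + tabulate(sh[isF], n_shells)
    accP <- accP + tabulate(sh[!isF], n_shells)
  }
  nf <- length(frames)
  out <- data.frame(r_norm = (seq_len(n_shells) - 0.5) / n_shells,
                    dens_F = accF / (nf * vol), dens_P = accP / (nf * vol))
  attr(out, "shell_volumes") <- vol
  attr(out, "radius") <- radius
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Windowed Fourier spectrum of a contact-map diagonal
#'
#' Extracts the `diagonal_offset`-th diagonal of the contact matrix
#' (contacts between beads i and i + offset), slides non-overlapping
#' windows of `window_beads` bins along each chain, mean-subtracts each
#' window and computes its magnitude spectrum. Windows are classified F
#' when strictly more than half of the beads they start from are F, else P,
#' and spectra are averaged per class. With the 100-kbp bin the default
#' window of 20 beads spans 2 Mbps.
#'
#' @param map a [contact_map()].
#' @param diagonal_offset which diagonal (default 5).
#' @param window_beads window size in beads (default 20).
#' @return object of class `spectrum_summary`: list with `freq`
#'   (cycles/bin, length `window_beads/2 + 1`), `spec_F`, `spec_P` (mean
#'   magnitude spectra; `NULL` with a flag when a class has no window),
#'   `n_windows_F`, `n_windows_P`.
#' @export
windowed_fft <- function(map, diagonal_offset = 5, window_beads = 20) {
  ann <- map$annotation
  m <- map$matrix
  nf <- 0L; np <- 0L
  accF <- NULL; accP <- NULL
  nbin <- window_beads %/% 2 + 1
  for (ch in unique(ann$chain)) {
    rows <- which(ann$chain == ch)
    k <- length(rows)
    if (k <= window_beads + diagonal_offset) next
    i <- seq_len(k - diagonal_offset)
    v <- m[cbind(rows[i], rows[i + diagonal_offset])]
    nw <- length(v) %/% window_beads
    for (w in seq_len(nw)) {
      ix <- ((w - 1) * window_beads + 1):(w * window_beads)
      seg <- v[ix]
      spec <- Mod(stats::fft(seg - mean(seg)))[seq_len(nbin)]
      cls <- ann$class[rows[ix]]
      if (mean(cls == "F") > 0.5) {
        accF <- if (is.null(accF)) spec else accF + spec
        nf <- nf + 1L
      } else {
        accP <- if (is.null(accP)) spec else accP + spec
        np <- np + 1L
      }
    }
  }
  if (nf + np == 0L) stop("chain too short for any window")
  structure(list(freq = (seq_len(nbin) - 1) / window_beads,
                 spec_F = if (nf > 0) accF / nf else NULL,
                 spec_P = if (np > 0) accP / np else NULL,
                 n_windows_F = nf, n_windows_P = np,
                 missing_class = c(if (nf == 0) "F", if (np == 0) "P")),
            class = "spectrum_summary")
}

#' Intra- versus inter-chromosome contact statistics
#'
#' Per chain, the mean contact probability over same-chain pairs separated
#' by strictly more than `long_range_kbps` (default 5 Mbps); per chain
#' pair, the mean over all inter-chain bead pairs. Chromosome-territory
#' formation shows up as intra-chain means exceeding the inter-chain means.
#'
#' @param map a [contact_map()] of a multi-chain system.
#' @param long_range_kbps separation threshold for the intra-chain average.
#' @return list with data.frames `intra` (`chain`, `mean_p`, `n_pairs`) and
#'   `inter` (`chain_a`, `chain_b`, `mean_p`, `n_pairs`).
#' @export
interchain_stats <- function(map, long_range_kbps = 5000) {
  ann <- map$annotation
  chains <- unique(ann$chain)
  if (length(chains) < 2) stop("interchain_stats needs at least 2 chains")
  bin_kbp <- (attr(ann, "bin_bp") %||% 1e5) / 1000
  smin <- floor(long_range_kbps / bin_kbp) + 1  # strictly > threshold
  m <- map$matrix
  intra <- do.call(rbind, lapply(chains, function(ch) {
    rows <- which(ann$chain == ch)
    k <- length(rows)
    tot <- 0; cnt <- 0
    if (k > smin) {
      for (s in smin:(k - 1)) {
        i <- seq_len(k - s)
        tot <- tot + sum(m[cbind(rows[i], rows[i + s])])
        cnt <- cnt + length(i)
      }
    }
    data.frame(chain = ch, mean_p = if (cnt > 0) tot / cnt else NA_real_,
               n_pairs = cnt)
  }))
  pairs <- utils::combn(chains, 2)
  inter <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    ra <- which(ann$chain == pairs[1, k])
    rb <- which(ann$chain == pairs[2, k])
    sub <- m[ra, rb, drop = FALSE]
    data.frame(chain_a = pairs[1, k], chain_b = pairs[2, k],
               mean_p = mean(sub), n_pairs = length(sub))
  }))
  list(intra = intra, inter = inter)
}

#' Align an experimental P(N) curve to a simulated one
#'
#' Rescales the experimental curve by a single factor so that its value at
#' the 300-kbps anchor equals the simulated one (nearest grid point when
#' the exact anchor is absent); the simulation curve is unchanged.
#'
#' @param exp_curve data.frame with two columns, N (kbps) and P.
#' @param sim a [ps_curve()].
#' @param anchor_kbps alignment anchor (default 300 kbps).
#' @return the rescaled experimental curve (columns `N_kbps`, `P`), with
#'   the factor as attribute `"scale_factor"`.
#' @export
align_experimental <- function(exp_curve, sim, anchor_kbps = 300) {
  ec <- data.frame(N_kbps = exp_curve[[1]], P = exp_curve[[2]])
  ie <- which.min(abs(ec$N_kbps - anchor_kbps))
  is <- which.min(abs(sim$N_kbps - anchor_kbps))
  if (ec$P[ie] <= 0) stop("experimental P at the anchor is not positive")
  f <- sim$P[is] / ec$P[ie]
  out <- data.frame(N_kbps = ec$N_kbps, P = ec$P * f)
  attr(out, "scale_factor") <- f
  out
}
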