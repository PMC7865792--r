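#' Configuration for the synthetic bead-annotation generator
#'
#' Describes a synthetic chromosome as an alternating F/P block copolymer
#' with the block statistics of real chromosomes: blocks are built from a
#' geometric number of TADs whose lengths are shifted-geometric with class
#' means 4.4 beads (F-TADs) and 6.6 beads (P-TADs); lamina-associated
#' domains are whole P domains chosen to reach a target coverage, either a
#' few large ones (`concentrated`) or many small ones (`dispersed`).
#'
#' Block-length means may be given explicitly; when left `NULL` they are
#' derived from `f_fraction` and `mean_block` as
#' `mean_f_block = 2 * f_fraction * mean_block` (and the complement for P),
#' which makes the expected F bead fraction equal `f_fraction`.
#'
#' @param n_beads chain length in beads (>= 10).
#' @param f_fraction expected fraction of F beads, in (0, 1).
#' @param mean_f_block,mean_p_block mean block lengths in beads (>= 2), or
#'   `NULL` to derive from `f_fraction`.
#' @param mean_block overall mean block length used for the derivation.
#' @param mean_f_tad,mean_p_tad mean TAD sizes in beads (>= 2).
#' @param lad_coverage target fraction of P beads inside LADs, in `[0, 1]`.
#' @param lad_style `"dispersed"` (many small LAD domains) or
#'   `"concentrated"` (fewest largest).
#' @param lads_in_f also allow LADs on F domains (off by default: P domains
#'   are the ones that colocalize with LADs).
#' @param seed integer seed; generation is deterministic given the config.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_beads = 1000, f_fraction = 0.5,
                         mean_f_block = NULL, mean_p_block = NULL,
                         mean_block = 16, mean_f_tad = 4.4,
                         mean_p_tad = 6.6, lad_coverage = 0.5,
                         lad_style = c("dispersed", "concentrated"),
                         lads_in_f = FALSE, seed = 1L) {
  lad_style <- match.arg(lad_style)
  if (n_beads < 10) stop("n_beads must be at least 10")
  if (f_fraction <= 0 || f_fraction >= 1) stop("f_fraction must be in (0, 1)")
  if (lad_coverage < 0 || lad_coverage > 1) stop("lad_coverage must be in [0, 1]")
  # a block is a run of whole TADs, so its mean length cannot fall below
  # the class TAD mean; when the f_fraction-derived value would, the short
  # class is floored at one TAD and the other class rescaled to keep the
  # requested bead-fraction ratio
  if (is.null(mean_f_block) && is.null(mean_p_block)) {
    mean_f_block <- 2 * f_fraction * mean_block
    mean_p_block <- 2 * (1 - f_fraction) * mean_block
    if (mean_p_block < mean_p_tad) {
      mean_p_block <- mean_p_tad
      mean_f_block <- mean_p_block * f_fraction / (1 - f_fraction)
    }
    if (mean_f_block < mean_f_tad) {
      mean_f_block <- mean_f_tad
      mean_p_block <- mean_f_block * (1 - f_fraction) / f_fraction
    }
  } else {
    if (is.null(mean_f_block)) mean_f_block <- 2 * f_fraction * mean_block
    if (is.null(mean_p_block)) mean_p_block <- 2 * (1 - f_fraction) * mean_block
  }
  for (m in c(mean_f_block, mean_p_block, mean_f_tad, mean_p_tad))
    if (m < 2) stop("block and TAD mean lengths must be at least 2 beads")
  structure(list(n_beads = as.integer(n_beads), f_fraction = f_fraction,
                 mean_f_block = mean_f_block, mean_p_block = mean_p_block,
                 mean_f_tad = mean_f_tad, mean_p_tad = mean_p_tad,
                 lad_coverage = lad_coverage, lad_style = lad_style,
                 lads_in_f = lads_in_f, seed = as.integer(seed)),
            class = "synth_config")
}

# shifted geometric on {1, 2, ...} with the given mean (>= 1)
rgeom_shift <- function(n, mean) {
  if (mean <= 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / mean)
}

#' Generate a synthetic bead annotation
#'
#' Draws alternating F/P blocks until `n_beads` is reached. Each block is a
#' run of complete TADs: the number of TADs per block is shifted-geometric
#' with mean `mean_block/mean_tad` for its class, and each TAD length is
#' shifted-geometric with the class mean, so realized block and TAD means
#' converge to the configured values. The first bead of every TAD is flagged
#' as a TAD boundary. LADs are then assigned to whole P domains until the
#' requested coverage of P beads is reached (within one domain).
#'
#' @param cfg a [synth_config()].
#' @param chain_id chain identifier for the output beads.
#' @return a bead annotation (see [bin_to_beads()] for the format).
#' @export
generate_annotation <- function(cfg, chain_id = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_beads
  cls_chr <- character(0); boundary <- logical(0); block_id <- integer(0)
  cur <- if (stats::runif(1) < cfg$f_fraction) "F" else "P"
  nb <- 0L; blk <- 0L
  while (length(cls_chr) < n) {
    blk <- blk + 1L
    mb <- if (cur == "F") cfg$mean_f_block else cfg$mean_p_block
    mt <- if (cur == "F") cfg$mean_f_tad else cfg$mean_p_tad
    k <- rgeom_shift(1, max(mb / mt, 1))
    tads <- rgeom_shift(k, mt)
    for (L in tads) {
      cls_chr <- c(cls_chr, rep(cur, L))
      boundary <- c(boundary, TRUE, rep(FALSE, L - 1L))
      block_id <- c(block_id, rep(blk, L))
    }
    cur <- if (cur == "F") "P" else "F"
  }
  cls_chr <- cls_chr[1:n]; boundary <- boundary[1:n]; block_id <- block_id[1:n]

  is_lad <- rep(FALSE, n)
  if (cfg$lad_coverage > 0) {
    eligible <- if (cfg$lads_in_f) rep(TRUE, n) else cls_chr == "P"
    n_target_base <- sum(cls_chr == "P")
    if (n_target_base == 0 && !cfg$lads_in_f)
      stop("lad_coverage > 0 but the chain has no P beads")
    target <- cfg$lad_coverage * n_target_base
    dom_sizes <- table(block_id[eligible])
    ord <- order(as.integer(dom_sizes),
                 decreasing = (cfg$lad_style == "concentrated"))
    got <- 0
    for (d in names(dom_sizes)[ord]) {
      if (got >= target) break
      is_lad[block_id == as.integer(d) & eligible] <- TRUE
      got <- got + dom_sizes[[d]]
    }
  }

  bead_annotation(chain = chain_id, bin = seq_len(n) - 1L,
                      bp_start = (seq_len(n) - 1L) * 1e5,
                      class = cls_chr, is_lad = is_lad,
                      is_tad_boundary = boundary,
                      bin_bp = 1e5, chrom = sprintf("synth%d", chain_id))
}

#' Generate a multi-chromosome synthetic annotation
#'
#' Concatenates per-chain annotations with distinct `chain` ids; chains are
#' generated independently (no bonds across chains are implied downstream).
#' When `seed` is given it overrides each config's own seed with a derived
#' per-chain stream, so the whole system is reproducible from one integer.
#'
#' @param cfgs a list of [synth_config()] objects (at least one).
#' @param seed optional master seed.
#' @return a bead annotation with `length(cfgs)` chains.
#' @export
generate_multichain <- function(cfgs, seed = NULL) {
  if (length(cfgs) == 0) stop("need at least one synth_config")
  out <- vector("list", length(cfgs))
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    if (!is.null(seed)) cfg$seed <- as.integer(seed + 1009 * i)
    out[[i]] <- generate_annotation(cfg, chain_id = i)
  }
  beads <- do.call(rbind, lapply(out, as.data.frame))
  bead_annotation(beads$chain, beads$bin, beads$bp_start, beads$class,
                      beads$is_lad, beads$is_tad_boundary,
                      bin_bp = 1e5, chrom = "synth")
}

#' Realized TAD sizes of an annotation
#'
#' Sizes (in beads) of the segments between consecutive TAD-boundary beads
#' within each chain, with the majority class of the beads they span. Used
#' to check that generated annotations reproduce the configured mean F-TAD
#' and P-TAD sizes.
#'
#' @param beads a bead annotation.
#' @return data.frame with columns `chain`, `size`, `class`.
#' @export
tad_sizes <- function(beads) {
  res <- list()
  for (ch in unique(beads$chain)) {
    b <- beads[beads$chain == ch, , drop = FALSE]
    idx <- which(b$is_tad_boundary)
    if (length(idx) < 2) next
    sizes <- diff(idx)
    cls <- vapply(seq_len(length(idx) - 1), function(k) {
      seg <- b$class[idx[k]:(idx[k + 1] - 1)]
      if (mean(seg == "F") > 0.5) "F" else "P"
    }, character(1))
    res[[length(res) + 1]] <- data.frame(chain = ch, size = sizes, class = cls)
  }
  if (length(res) == 0) return(data.frame(chain = integer(), size = integer(),
                                          class = character()))
  do.call(rbind, res)
}
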