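#' Genomic interval track
#'
#' A minimal strand-less interval track: 0-based half-open intervals with an
#' optional text label. This is the common currency for forest/prairie
#' domains, lamina-association signal, TAD boundaries and centromere masks.
#'
#' @param start,end integer vectors, 0-based half-open coordinates.
#' @param label character vector of labels (recycled); may be `NA`.
#' @param chrom chromosome name (single string).
#' @return object of class `genomic_track`: a data.frame with columns
#'   `chrom`, `start`, `end`, `label`, sorted and validated.
#' @export
genomic_track <- function(start, end, label = NA_character_, chrom = "chr") {
  stopifnot(length(start) == length(end))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) stop("NA coordinates")
  if (any(start < 0)) stop("coordinates must be non-negative")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   label = rep_len(as.character(label), length(start)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_track", "data.frame")
  df
}

#' Read a BED3/BED4 file as a genomic track
#'
#' Wraps [rtracklayer::import()] and converts back to 0-based half-open
#' coordinates. The BED name column (if present) becomes the track label,
#' which is how forest/prairie calls are encoded (`"F"`/`"P"`).
#'
#' @param path BED file path.
#' @param chrom optional chromosome to restrict to.
#' @return a [genomic_track()].
#' @export
read_bed_track <- function(path, chrom = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(chrom)) gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (length(gr) == 0) stop("no intervals in ", path)
  lab <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  genomic_track(start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr),
                label = lab,
                chrom = as.character(GenomicRanges::seqnames(gr))[1])
}

#' Write a genomic track as BED
#'
#' @param track a [genomic_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(track, path) {
  df <- data.frame(chrom = track$chrom, start = format(track$start, scientific = FALSE, trim = TRUE),
                   end = format(track$end, scientific = FALSE, trim = TRUE),
                   name = ifelse(is.na(track$label), ".", track$label))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a bead annotation
#'
#' The central data structure: one row per 100-kbp bead with its chain id,
#' consecutive bin index, genomic start, F/P class, LAD flag and
#' TAD-boundary flag. Usually produced by [bin_to_beads()] or
#' [generate_annotation()]; the constructor is exported for building small
#' annotations directly.
#'
#' @param chain integer chain ids.
#' @param bin 0-based consecutive bin index within each chain.
#' @param bp_start genomic start of the bead's bin (bp).
#' @param class `"F"` or `"P"` per bead.
#' @param is_lad,is_tad_boundary logical flags.
#' @param bin_bp bin size in bp.
#' @param chrom chromosome name (metadata).
#' @return object of class `bead_annotation` (a data.frame).
#' @export
bead_annotation <- function(chain, bin, bp_start, class, is_lad,
                            is_tad_boundary, bin_bp = 1e5, chrom = "chr") {
  df <- data.frame(chain = as.integer(chain), bin = as.integer(bin),
                   bp_start = as.numeric(bp_start),
                   class = as.character(class),
                   is_lad = as.logical(is_lad),
                   is_tad_boundary = as.logical(is_tad_boundary),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$class %in% c("F", "P")))
  attr(df, "bin_bp") <- bin_bp
  attr(df, "chrom") <- chrom
  class(df) <- c("bead_annotation", "data.frame")
  df
}

#' @export
print.bead_annotation <- function(x, ...) {
  nb <- nrow(x)
  cat(sprintf("Bead annotation: %d beads, %d chain(s), bin size %g bp\n",
              nb, length(unique(x$chain)), attr(x, "bin_bp")))
  cat(sprintf("  F: %d (%.1f%%)  P: %d  LAD beads: %d  TAD boundaries: %d\n",
              sum(x$class == "F"), 100 * mean(x$class == "F"),
              sum(x$class == "P"), sum(x$is_lad), sum(x$is_tad_boundary)))
  NextMethod()
}

#' Bin a forest/prairie track into 100-kbp beads
#'
#' Divides the chromosome into `bin_bp` segments and represents each by one
#' bead. A bead is class F if strictly more than 50% of its base pairs carry
#' the forest label, P if strictly more than 50% carry prairie; a bin that
#' meets neither rule (ties, uncovered sequence) falls back to `tie_class`
#' (default P, the CGI-poor background). A trailing partial bin is kept when
#' it spans at least half a bin, otherwise dropped.
#'
#' @param fp_track a [genomic_track()] whose labels are `"F"`/`"P"` (also
#'   accepts `"forest"`/`"prairie"`, case-insensitively).
#' @param bin_bp bin size in base pairs (default 100,000).
#' @param tie_class class assigned when neither label wins a strict majority.
#' @return a [bead_annotation()] data.frame (single chain, `is_lad` and
#'   `is_tad_boundary` all `FALSE`).
#' @export
bin_to_beads <- function(fp_track, bin_bp = 1e5, tie_class = "P") {
  if (!inherits(fp_track, "genomic_track")) stop("fp_track must be a genomic_track")
  if (nrow(fp_track) == 0) stop("empty track")
  if (!is.numeric(bin_bp) || bin_bp <= 0) stop("bin_bp must be positive")
  stopifnot(tie_class %in% c("F", "P"))
  lab <- toupper(substr(fp_track$label, 1, 1))
  if (!all(lab %in% c("F", "P")))
    stop("fp_track labels must be F(orest) or P(rairie)")

  chrom_len <- max(fp_track$end)
  n_full <- floor(chrom_len / bin_bp)
  rem <- chrom_len - n_full * bin_bp
  n_bins <- n_full + as.integer(rem >= bin_bp / 2)
  if (n_bins == 0) stop("chromosome shorter than half a bin")
  bin_start <- (seq_len(n_bins) - 1) * bin_bp
  bin_end <- pmin(bin_start + bin_bp, chrom_len)

  cover <- matrix(0, n_bins, 2, dimnames = list(NULL, c("F", "P")))
  for (k in seq_len(nrow(fp_track))) {
    s <- fp_track$start[k]; e <- min(fp_track$end[k], max(bin_end))
    if (e <= s) next
    b0 <- max(floor(s / bin_bp) + 1, 1)
    b1 <- min(floor((e - 1) / bin_bp) + 1, n_bins)
    if (b0 > b1) next
    bs <- b0:b1
    ov <- pmin(bin_end[bs], e) - pmax(bin_start[bs], s)
    cover[bs, lab[k]] <- cover[bs, lab[k]] + ov
  }
  width <- bin_end - bin_start
  cls <- ifelse(cover[, "F"] > width / 2, "F",
                ifelse(cover[, "P"] > width / 2, "P", tie_class))
  bead_annotation(chain = 1L, bin = seq_len(n_bins) - 1L,
                      bp_start = bin_start, class = cls,
                      is_lad = FALSE, is_tad_boundary = FALSE,
                      bin_bp = bin_bp, chrom = fp_track$chrom[1])
}

#' Convert a bead annotation back to a forest/prairie track
#'
#' Inverse of [bin_to_beads()]: each bead becomes one interval carrying its
#' class label, so re-binning the result reproduces the bead classes exactly.
#'
#' @param beads a bead annotation.
#' @return a [genomic_track()].
#' @export
beads_to_track <- function(beads, bin_bp = attr(beads, "bin_bp")) {
  if (is.null(bin_bp)) bin_bp <- 1e5
  genomic_track(start = beads$bp_start, end = beads$bp_start + bin_bp,
                label = beads$class,
                chrom = attr(beads, "chrom") %||% "chr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# maximal runs of equal class within each chain -> integer domain id
domain_ids <- function(beads) {
  key <- paste(beads$chain, beads$class)
  changed <- c(TRUE, key[-1] != key[-length(key)] |
                 beads$chain[-1] != beads$chain[-length(key)])
  cumsum(changed)
}

#' Call lamina-associated domains at the domain level
#'
#' A bead "has signal" when the lamina-association intervals cover more than
#' `overlap_frac` of its bin. LADs are then called per domain (a maximal run
#' of same-class beads): if strictly more than 50% of a domain's beads have
#' signal, the whole domain is an LAD and every one of its beads gets
#' `is_lad = TRUE`; otherwise none do.
#'
#' @param beads a bead annotation.
#' @param lad_signal_track a [genomic_track()] of lamina-association signal;
#'   an empty/`NULL` track yields no LADs.
#' @param overlap_frac fraction of the bin that must be covered by signal for
#'   the bead to count as signal-positive (default 0.5).
#' @return the annotation with `is_lad` filled in.
#' @export
call_lads <- function(beads, lad_signal_track = NULL, overlap_frac = 0.5) {
  bin_bp <- attr(beads, "bin_bp") %||% 1e5
  n <- nrow(beads)
  has_signal <- rep(FALSE, n)
  if (!is.null(lad_signal_track) && nrow(lad_signal_track) > 0) {
    cov <- numeric(n)
    for (k in seq_len(nrow(lad_signal_track))) {
      s <- lad_signal_track$start[k]; e <- lad_signal_track$end[k]
      ov <- pmin(beads$bp_start + bin_bp, e) - pmax(beads$bp_start, s)
      cov <- cov + pmax(ov, 0)
    }
    has_signal <- cov > overlap_frac * bin_bp
  }
  dom <- domain_ids(beads)
  frac <- tapply(has_signal, dom, mean)
  beads$is_lad <- as.vector(frac[as.character(dom)] > 0.5)
  beads
}

#' Flag beads containing TAD boundaries
#'
#' A bead is a TAD boundary iff at least one boundary position (any overlap
#' of a boundary interval, half-open convention) falls inside its bin.
#'
#' @param beads a bead annotation.
#' @param boundary_track a [genomic_track()] of boundary positions (points
#'   encoded as 1-bp intervals, or short intervals).
#' @return the annotation with `is_tad_boundary` filled in.
#' @export
mark_tad_boundaries <- function(beads, boundary_track = NULL) {
  bin_bp <- attr(beads, "bin_bp") %||% 1e5
  hit <- rep(FALSE, nrow(beads))
  if (!is.null(boundary_track) && nrow(boundary_track) > 0) {
    for (k in seq_len(nrow(boundary_track))) {
      s <- boundary_track$start[k]; e <- boundary_track$end[k]
      hit <- hit | (beads$bp_start < e & beads$bp_start + bin_bp > s)
    }
  }
  beads$is_tad_boundary <- hit
  beads
}

#' Remove centromeric beads and close the chain
#'
#' Beads whose bin midpoint lies inside the centromere interval are removed
#' (the model has no sequence there), and the remaining beads are re-indexed
#' consecutively so the polymer is bonded directly across the gap.
#'
#' @param beads a bead annotation.
#' @param centromere_track a [genomic_track()] with the centromere interval
#'   (multiple rows are merged to their spanning range); `NULL` or empty is
#'   the identity.
#' @return the filtered, re-indexed annotation.
#' @export
drop_centromere <- function(beads, centromere_track = NULL) {
  if (is.null(centromere_track) || nrow(centromere_track) == 0) return(beads)
  bin_bp <- attr(beads, "bin_bp") %||% 1e5
  s <- min(centromere_track$start); e <- max(centromere_track$end)
  mid <- beads$bp_start + bin_bp / 2
  keep <- !(mid >= s & mid < e)
  if (!any(keep)) stop("centromere covers the whole chromosome")
  out <- beads[keep, , drop = FALSE]
  out$bin <- stats::ave(seq_len(nrow(out)), out$chain,
                        FUN = function(ix) seq_along(ix) - 1L)
  rownames(out) <- NULL
  out
}

#' Read/write the bead-annotation table
#'
#' TSV with columns `chain`, `bin`, `bp_start`, `class`, `is_lad`,
#' `is_tad_boundary`; the bin size travels in a `# bin_bp=` header comment.
#'
#' @param beads a bead annotation.
#' @param path file path.
#' @return `write_bead_annotation()` returns `path` invisibly;
#'   `read_bead_annotation()` the annotation.
#' @export
write_bead_annotation <- function(beads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_bp=%g chrom=%s", attr(beads, "bin_bp") %||% 1e5,
                     attr(beads, "chrom") %||% "chr"), con)
  utils::write.table(as.data.frame(beads), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bead_annotation
#' @export
read_bead_annotation <- function(path) {
  first <- readLines(path, n = 1)
  bin_bp <- 1e5; chrom <- "chr"
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("bin_bp=([0-9.e+]+)", first))[[1]]
    if (length(m) == 2) bin_bp <- as.numeric(m[2])
    m <- regmatches(first, regexec("chrom=(\\S+)", first))[[1]]
    if (length(m) == 2) chrom <- m[2]
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  bead_annotation(df$chain, df$bin, df$bp_start, df$class, df$is_lad,
                      df$is_tad_boundary, bin_bp = bin_bp, chrom = chrom)
}

#' Full annotation pipeline
#'
#' Convenience wrapper running [bin_to_beads()], [call_lads()],
#' [mark_tad_boundaries()] and [drop_centromere()] in the standard order
#' (centromere removal last, then LAD/TAD flags are preserved).
#'
#' @param fp_track forest/prairie track.
#' @param lad_track,tad_track,centromere_track optional tracks.
#' @inheritParams bin_to_beads
#' @return a bead annotation.
#' @export
annotate_chromosome <- function(fp_track, lad_track = NULL, tad_track = NULL,
                                centromere_track = NULL, bin_bp = 1e5,
                                tie_class = "P") {
  beads <- bin_to_beads(fp_track, bin_bp = bin_bp, tie_class = tie_class)
  beads <- call_lads(beads, lad_track)
  beads <- mark_tad_boundaries(beads, tad_track)
  drop_centromere(beads, centromere_track)
}
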