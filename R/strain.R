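## Strain-variation profiling on a single-copy marker gene (e.g. gyrB):
## the marker is cut into fixed-width windows, each aligned read contributes
## its bases over every window it fully covers, and the distinct
## window-restricted haplotype strings are counted. The maximum number of
## well-supported variants in any window is a lower bound on the number of
## strains in the sample.

#' Per-window variant read counts along a marker gene
#'
#' Reads are aligned to the marker (both strands, exact k-mer seeding with
#' gapless extension); a read contributes to every window its alignment
#' fully covers, the read's bases over that window defining its variant
#' string. Variants supported by fewer than `min_support` reads are dropped
#' as sequencing noise.
#'
#' @param marker Marker nucleotide sequence.
#' @param reads Named character vector of reads, or a `marker_mixture`
#'   from [make_marker_mixture()].
#' @param window_bp Window width in bp (default 50).
#' @param min_overlap_bp Minimum width a window must have to be profiled;
#'   only the trailing window can be shorter than `window_bp`. Default 50,
#'   i.e. only full-width windows are profiled.
#' @param min_support Minimum reads supporting a variant (default 2).
#' @param seed_k Seed k-mer size for read placement (default 16).
#' @param max_read_divergence Reads whose best placement shows a mismatch
#'   fraction above this are discarded as non-marker (default 0.2).
#' @param marker_id Label for the profile.
#' @return List of class `marker_window_profile`: `marker_id`, `window_bp`,
#'   `windows` (data.table `window`, `start`, `end`, `variant`, `count`),
#'   `n_reads_total`, `n_reads_aligned`.
#' @export
window_profile <- function(marker, reads, window_bp = 50L,
                           min_overlap_bp = 50L, min_support = 2L,
                           seed_k = 16L, max_read_divergence = 0.2,
                           marker_id = "marker") {
  if (inherits(reads, "marker_mixture")) reads <- reads$reads
  marker <- toupper(marker)
  L <- nchar(marker)
  if (L < window_bp) stop("marker shorter than one window", call. = FALSE)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d", seq_along(reads))
  n_total <- length(reads)

  targets <- c(marker = marker)
  idx <- .kmer_table(targets, seed_k)
  best <- .best_placements(reads, targets, idx, seed_k, strands = TRUE)

  w_starts <- seq(1L, L, by = window_bp)
  w_ends <- pmin(w_starts + window_bp - 1L, L)
  keep_w <- (w_ends - w_starts + 1L) >= min_overlap_bp
  w_starts <- w_starts[keep_w]; w_ends <- w_ends[keep_w]
  empty <- structure(
    list(marker_id = marker_id, window_bp = window_bp,
         windows = data.table(window = integer(), start = integer(),
                              end = integer(), variant = character(),
                              count = integer()),
         n_reads_total = n_total, n_reads_aligned = 0L),
    class = "marker_window_profile"
  )
  if (nrow(best) == 0L) {
    warning("no read aligns to the marker", call. = FALSE)
    return(empty)
  }
  best <- best[mismatches / overlap <= max_read_divergence]
  if (nrow(best) == 0L) {
    warning("no read covers any window", call. = FALSE)
    return(empty)
  }
  rows <- vector("list", nrow(best))
  for (i in seq_len(nrow(best))) {
    rid <- best$query_id[i]
    qs <- reads[[rid]]
    if (best$strand[i] == "-") qs <- .revcomp(qs)
    d <- best$diag_off[i]
    rlen <- nchar(qs)
    aln_from <- max(1L, 1L + d)          # marker coords covered by the read
    aln_to <- min(L, rlen + d)
    covered <- which(w_starts >= aln_from & w_ends <= aln_to)
    if (length(covered) == 0L) next
    variants <- substring(qs, w_starts[covered] - d, w_ends[covered] - d)
    rows[[i]] <- data.table(window = covered, variant = variants)
  }
  tab <- rbindlist(rows)
  if (nrow(tab) == 0L) {
    warning("no read fully covers any window", call. = FALSE)
    return(empty)
  }
  counts <- tab[, .(count = .N), by = .(window, variant)]
  counts <- counts[count >= min_support]
  counts[, start := w_starts[window]]
  counts[, end := w_ends[window]]
  setorder(counts, window, -count, variant)
  setcolorder(counts, c("window", "start", "end", "variant", "count"))
  structure(
    list(marker_id = marker_id, window_bp = window_bp, windows = counts,
         n_reads_total = n_total, n_reads_aligned = length(unique(best$query_id))),
    class = "marker_window_profile"
  )
}

#' @export
print.marker_window_profile <- function(x, ...) {
  nw <- length(unique(x$windows$window))
  poly <- x$windows[, .N, by = window][N > 1L, .N]
  cat(sprintf(
    "<marker_window_profile> %s: %d profiled window(s) of %d bp, %d polymorphic; %d/%d reads aligned\n",
    x$marker_id, nw, x$window_bp, poly, x$n_reads_aligned, x$n_reads_total))
  invisible(x)
}

#' Minimum strain number and mixture estimate from a window profile
#'
#' `min_strains` is the maximum, over windows, of the number of distinct
#' well-supported variants — a lower bound on the number of strains
#' present. The mixture estimate pools variant-frequency ranks across
#' polymorphic windows (median per rank, renormalized): an estimator of the
#' strain proportions, valid when the same strains dominate every window.
#'
#' @param profile A `marker_window_profile` from [window_profile()].
#' @return List of class `strain_summary`: `min_strains`,
#'   `per_window_major_fraction`, `mixture_estimate` (named numeric, ranks
#'   `rank1..rankK` summing to 1).
#' @export
summarize_strains <- function(profile) {
  stopifnot(inherits(profile, "marker_window_profile"))
  w <- profile$windows
  if (nrow(w) == 0L) stop("empty profile", call. = FALSE)
  per_window <- w[, .(n_var = .N, total = sum(count), major = max(count)),
                  by = window]
  min_strains <- max(per_window$n_var)
  major_frac <- per_window$major / per_window$total
  poly <- w[window %in% per_window[n_var > 1L, window]]
  if (nrow(poly) == 0L) {
    mix <- c(rank1 = 1)
  } else {
    poly <- copy(poly)
    poly[, fraction := count / sum(count), by = window]
    poly[, rank_idx := frank(-fraction, ties.method = "first"), by = window]
    med <- poly[, .(m = median(fraction)), by = rank_idx]
    setorder(med, rank_idx)
    mix <- med$m / sum(med$m)
    names(mix) <- sprintf("rank%d", med$rank_idx)
  }
  structure(list(min_strains = min_strains,
                 per_window_major_fraction = major_frac,
                 mixture_estimate = mix),
            class = "strain_summary")
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf("<strain_summary> minimum strain number: %d\n", x$min_strains))
  cat("  mixture estimate:",
      paste(sprintf("%s = %.3f", names(x$mixture_estimate), x$mixture_estimate),
            collapse = ", "), "\n")
  invisible(x)
}
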