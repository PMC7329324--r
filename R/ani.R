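## Fragment-based gANI/AF. The query is cut into consecutive fixed-size
## fragments; each fragment is placed on the reference (both strands) by
## exact k-mer seeding and gapless extension. A fragment "maps" when its
## best placement covers >= 70% of the fragment at >= 70% identity. This
## fragment formulation needs no gene calls and, on substitution-only data,
## converges to the gene-based gANI it stands in for.

#' Compute gANI and alignment fraction between a query and a reference
#'
#' @param query A `contig_bin`, `genome_record`, or named character vector
#'   of contigs.
#' @param reference A [genome_record()].
#' @param fragment_bp Fragment size in bp (>= 200; default 1000). Trailing
#'   contig fragments shorter than 200 bp are not aligned but stay in the
#'   AF denominator.
#' @param min_fragment_cov,min_fragment_ident Mapping thresholds for a
#'   fragment (defaults 0.7/0.7) — chosen to exclude spurious placements.
#' @param seed_k Seed k-mer size for fragment placement (default 16).
#' @return List of class `ani_result`: `query_id`, `reference_id`, `gani`
#'   (length-weighted mean identity of mapped fragments; `NA` when nothing
#'   maps), `af` (mapped fragment bp / total query bp), `aligned_bp`, and
#'   `query_bp` (total query size, used for length-weighted aggregation).
#' @examples
#' g <- random_genome("g", 20000, seed = 1)
#' compute_ani(g, g)$gani
#' @export
compute_ani <- function(query, reference, fragment_bp = 1000L,
                        min_fragment_cov = 0.7, min_fragment_ident = 0.7,
                        seed_k = 16L) {
  contigs <- .contigs_of(query)
  refs <- .contigs_of(reference)
  if (length(contigs) == 0L || sum(nchar(contigs)) == 0L) {
    stop("empty query", call. = FALSE)
  }
  if (fragment_bp < 200L) stop("fragment_bp must be >= 200", call. = FALSE)
  query_bp <- sum(nchar(contigs))

  ## cut query into consecutive fragments
  frags <- character(0)
  for (cn in names(contigs)) {
    L <- nchar(contigs[[cn]])
    starts <- seq(1L, L, by = fragment_bp)
    fr <- substring(contigs[[cn]], starts, pmin(starts + fragment_bp - 1L, L))
    names(fr) <- sprintf("%s|%d", cn, starts)
    frags <- c(frags, fr)
  }
  frags <- frags[nchar(frags) >= 200L]
  if (length(frags) == 0L) stop("query has no alignable fragments", call. = FALSE)

  idx <- .kmer_table(refs, seed_k)
  best <- .best_placements(frags, refs, idx, seed_k, strands = TRUE)
  res <- structure(
    list(query_id = .id_of(query), reference_id = .id_of(reference),
         gani = NA_real_, af = 0, aligned_bp = 0L, query_bp = query_bp),
    class = "ani_result"
  )
  if (nrow(best) == 0L) return(res)
  ## best reference placement per fragment
  best[, best := overlap - mismatches]
  setorder(best, query_id, -best, mismatches, seq_id)
  best <- best[, head(.SD, 1L), by = query_id]
  flen <- nchar(frags)[best$query_id]
  cov <- best$overlap / flen
  ident <- (best$overlap - best$mismatches) / best$overlap
  mapped <- cov >= min_fragment_cov & ident >= min_fragment_ident
  if (!any(mapped)) return(res)
  res$aligned_bp <- as.integer(sum(flen[mapped]))
  res$af <- sum(flen[mapped]) / query_bp
  res$gani <- weighted.mean(ident[mapped], flen[mapped])
  res
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %s vs %s: gANI = %s, AF = %.3f (%s / %s bp aligned)\n",
              x$query_id, x$reference_id,
              ifelse(is.na(x$gani), "undefined", sprintf("%.4f", x$gani)),
              x$af, format(x$aligned_bp, big.mark = ","),
              format(x$query_bp, big.mark = ",")))
  invisible(x)
}

.ani_table <- function(results) {
  if (inherits(results, "ani_result")) results <- list(results)
  rbindlist(lapply(results, function(r) {
    data.table(query_id = r$query_id, reference_id = r$reference_id,
               gani = r$gani, af = r$af, aligned_bp = r$aligned_bp,
               query_bp = r$query_bp)
  }))
}

#' Assign a metagenome bin to a cultivated reference genome
#'
#' Among references passing both cutoffs (strict inequalities, AF > 0.5 and
#' gANI > 0.9 by default), the reference with maximal gANI wins; ties break
#' by larger AF, then lexicographic reference id. When no reference passes,
#' the bin is `UNASSIGNED`.
#'
#' @param results List of `ani_result` objects for one query bin (or a
#'   data.frame with columns `query_id`, `reference_id`, `gani`, `af`).
#' @param af_min,gani_min Cutoffs (strict `>`); defaults 0.5 and 0.9.
#' @return List of class `bin_assignment`: `bin_id`, `assigned_reference`
#'   (or `"UNASSIGNED"`), `gani`, `af`.
#' @export
assign_bin <- function(results, af_min = 0.5, gani_min = 0.9) {
  tab <- if (is.data.frame(results)) as.data.table(results) else .ani_table(results)
  if (nrow(tab) == 0L) {
    warning("no ANI results supplied; bin is UNASSIGNED", call. = FALSE)
    return(structure(list(bin_id = NA_character_,
                          assigned_reference = "UNASSIGNED",
                          gani = NA_real_, af = NA_real_),
                     class = "bin_assignment"))
  }
  if (length(unique(tab$query_id)) != 1L) {
    stop("assign_bin expects results for a single query bin", call. = FALSE)
  }
  pass <- tab[!is.na(gani) & af > af_min & gani > gani_min]
  if (nrow(pass) == 0L) {
    out <- list(bin_id = tab$query_id[1L], assigned_reference = "UNASSIGNED",
                gani = NA_real_, af = NA_real_)
  } else {
    setorder(pass, -gani, -af, reference_id)
    out <- list(bin_id = pass$query_id[1L],
                assigned_reference = pass$reference_id[1L],
                gani = pass$gani[1L], af = pass$af[1L])
  }
  structure(out, class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  if (identical(x$assigned_reference, "UNASSIGNED")) {
    cat(sprintf("<bin_assignment> %s: UNASSIGNED\n", x$bin_id))
  } else {
    cat(sprintf("<bin_assignment> %s -> %s (gANI %.4f, AF %.3f)\n",
                x$bin_id, x$assigned_reference, x$gani, x$af))
  }
  invisible(x)
}

#' Length-weighted aggregate gANI over a group of bins
#'
#' The aggregate value for a group (e.g. all bins of one host species
#' mapped to one reference) is the bin-length-weighted mean gANI,
#' `sum(gani_i * len_i) / sum(len_i)`, with `len_i` the total bin size.
#'
#' @param results List of `ani_result` objects (or data.frame with columns
#'   `gani` and `query_bp`); members with undefined gANI are excluded.
#' @param group_label Label for the group (species or comparison name).
#' @return List of class `aggregate_ani`: `group_label`, `total_bin_bp`,
#'   `weighted_gani`, `n_bins`.
#' @export
aggregate_gani <- function(results, group_label = "group") {
  tab <- if (is.data.frame(results)) as.data.table(results) else .ani_table(results)
  tab <- tab[!is.na(gani)]
  if (nrow(tab) == 0L || sum(tab$query_bp) == 0) {
    stop("no bins with defined gANI (zero total length)", call. = FALSE)
  }
  structure(
    list(group_label = group_label,
         total_bin_bp = sum(tab$query_bp),
         weighted_gani = sum(tab$gani * tab$query_bp) / sum(tab$query_bp),
         n_bins = nrow(tab)),
    class = "aggregate_ani"
  )
}

#' @export
print.aggregate_ani <- function(x, ...) {
  cat(sprintf("<aggregate_ani> %s: %d bin(s), %s bp, weighted gANI = %.4f\n",
              x$group_label, x$n_bins, format(x$total_bin_bp, big.mark = ","),
              x$weighted_gani))
  invisible(x)
}

#' Conspecificity call from gANI
#'
#' Two genomes are called conspecific when their gANI is at least 0.95
#' (the proposed species boundary for bacterial genomes).
#'
#' @param gani gANI value(s) in `[0, 1]`; must be defined (not `NA`).
#' @return Logical vector.
#' @examples
#' call_conspecific(c(0.95, 0.92, 1.0))
#' @export
call_conspecific <- function(gani) {
  if (any(is.na(gani))) stop("gani must be defined", call. = FALSE)
  gani >= 0.95
}

#' Classify a bin as bacterial
#'
#' A bin is called bacterial when its coding density exceeds 0.5 and at
#' least 60% of its taxonomically classified genes carry a bacterial label.
#' Per-gene labels come from an external taxonomy oracle (see
#' [contig_bin()]).
#'
#' @param bin A [contig_bin()] with `coding_density` and `gene_taxa` set.
#' @param min_coding_density Coding-density floor (strict `>`; default 0.5).
#' @param min_bacterial_frac Bacterial-gene fraction threshold (`>=`;
#'   default 0.6).
#' @param denominator Either `"classified"` (default: unassigned genes are
#'   excluded from the denominator) or `"all"`.
#' @return `TRUE`/`FALSE`.
#' @export
classify_bacterial_bin <- function(bin, min_coding_density = 0.5,
                                   min_bacterial_frac = 0.6,
                                   denominator = c("classified", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(bin, "contig_bin"))
  if (is.na(bin$coding_density)) {
    stop("bin ", bin$bin_id, " is missing coding_density", call. = FALSE)
  }
  if (is.null(bin$gene_taxa) || length(bin$gene_taxa) == 0L) {
    stop("bin ", bin$bin_id, " is missing gene_taxa annotations", call. = FALSE)
  }
  if (bin$coding_density <= min_coding_density) return(FALSE)
  denom <- if (denominator == "classified") {
    sum(bin$gene_taxa != "unassigned")
  } else {
    length(bin$gene_taxa)
  }
  if (denom == 0L) return(FALSE)
  sum(bin$gene_taxa == "bacterial") / denom >= min_bacterial_frac
}
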