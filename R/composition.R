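## Read mapping under an explicit contract (translated from the bbwrap
## parameter triple kfilter/subfilter/maxindel): a read maps to a reference
## iff its best local alignment contains an exact match of at least
## `min_exact_seed` bp, at most `max_subs` substitutions, and at most
## `max_indel` total indel bp. Exact seeds are found by k-mer lookup with
## k = min_exact_seed; extension is gapless first, with a banded gapped
## fallback. Ties across references break by fewest mismatches, then fewest
## indel bp, then lexicographic reference id — a total order, so mapping is
## deterministic.

#' Map reads to candidate reference genomes
#'
#' @param reads Named character vector of reads, or a `read_set` from
#'   [simulate_reads()].
#' @param references List of [genome_record()] objects.
#' @param min_exact_seed Minimum exact-match seed length in bp (default 22).
#' @param max_subs Maximum substitutions for a valid mapping (default 15).
#' @param max_indel Maximum total indel bp (default 80).
#' @return data.table of class `read_assignments`: `read_id`,
#'   `reference_id` (`"UNMAPPED"` when no reference qualifies),
#'   `mismatches`, `indel_bp`.
#' @export
map_reads <- function(reads, references, min_exact_seed = 22L, max_subs = 15L,
                      max_indel = 80L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  stopifnot(is.character(reads), length(reads) >= 1L)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d", seq_along(reads))
  if (min(nchar(reads)) < min_exact_seed) {
    stop("reads shorter than min_exact_seed cannot be mapped", call. = FALSE)
  }
  unmapped <- data.table(read_id = names(reads), reference_id = "UNMAPPED",
                         mismatches = NA_integer_, indel_bp = NA_integer_)
  if (length(references) == 0L) {
    warning("empty reference set; all reads UNMAPPED", call. = FALSE)
    return(structure(unmapped, class = c("read_assignments", class(unmapped))))
  }
  ## index all reference contigs; contig -> reference lookup
  ref_contigs <- character(0)
  contig2ref <- character(0)
  for (g in references) {
    cs <- .contigs_of(g)
    names(cs) <- paste0(.id_of(g), "\r", names(cs))  # \r never occurs in ids
    ref_contigs <- c(ref_contigs, cs)
    contig2ref <- c(contig2ref,
                    stats::setNames(rep(.id_of(g), length(cs)), names(cs)))
  }
  idx <- .kmer_table(ref_contigs, min_exact_seed)
  best <- .best_placements(reads, ref_contigs, idx, min_exact_seed,
                           strands = TRUE, top_diags = 3L)
  if (nrow(best)) {
    best[, reference_id := contig2ref[seq_id]]
    best[, indel_bp := 0L]
    ## gapped fallback for placements exceeding the substitution cap
    over <- which(best$mismatches > max_subs)
    for (i in over) {
      qs <- reads[[best$query_id[i]]]
      if (best$strand[i] == "-") qs <- .revcomp(qs)
      ts <- ref_contigs[[best$seq_id[i]]]
      w_from <- max(1L, best$diag_off[i] + 1L - max_indel)
      w_to <- min(nchar(ts), best$diag_off[i] + nchar(qs) + max_indel)
      ## global-local: the whole read must align into the reference window,
      ## so substitutions cannot be clipped away at the read ends
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(qs),
        Biostrings::DNAString(substr(ts, w_from, w_to)),
        type = "global-local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
        gapOpening = 4, gapExtension = 1
      )
      ins <- sum(Biostrings::width(unlist(
        Biostrings::insertion(Biostrings::indel(aln)))))
      del <- sum(Biostrings::width(unlist(
        Biostrings::deletion(Biostrings::indel(aln)))))
      best$mismatches[i] <- Biostrings::nmismatch(aln)
      best$indel_bp[i] <- as.integer(ins + del)
    }
    ## best reference per read under the contract
    ok <- best[mismatches <= max_subs & indel_bp <= max_indel]
  } else {
    ok <- best
  }
  if (nrow(ok)) {
    setorder(ok, query_id, mismatches, indel_bp, reference_id)
    ok <- ok[, head(.SD, 1L), by = query_id]
    assigned <- ok[, .(read_id = query_id, reference_id,
                       mismatches = as.integer(mismatches),
                       indel_bp = as.integer(indel_bp))]
  } else {
    assigned <- unmapped[0L]
  }
  out <- rbind(assigned, unmapped[!names(reads) %in% assigned$read_id])
  out <- out[match(names(reads), read_id)]
  structure(out, class = c("read_assignments", class(out)))
}

#' Per-species community composition from read assignments
#'
#' Converts read-to-reference assignments into percentages of reads per
#' bacterial species. Species whose share falls below `minor_floor`
#' percent are pooled into a `"minor"` category (the gray "minor, sporadic,
#' unidentified strains" slice of a stacked composition plot).
#'
#' @param assignments Output of [map_reads()].
#' @param metadata Named character vector mapping `reference_id` ->
#'   species, or a data.frame with columns `reference_id`, `species`.
#' @param specimen_id Specimen label carried into the profile.
#' @param minor_floor Pooling floor in percent (default 0.5).
#' @return List of class `composition_profile`: `specimen_id`, `fractions`
#'   (data.table `species`, `percent`), `unmapped_pct`, `n_reads`.
#' @export
composition <- function(assignments, metadata, specimen_id = "specimen",
                        minor_floor = 0.5) {
  tab <- as.data.table(assignments)
  if (nrow(tab) == 0L) stop("zero reads", call. = FALSE)
  if (is.data.frame(metadata)) {
    metadata <- stats::setNames(metadata$species, metadata$reference_id)
  }
  mapped <- tab[reference_id != "UNMAPPED"]
  missing_md <- setdiff(unique(mapped$reference_id), names(metadata))
  if (length(missing_md)) {
    stop("references missing a species label: ", paste(missing_md, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(tab)
  unmapped_pct <- 100 * (n - nrow(mapped)) / n
  if (nrow(mapped)) {
    per <- mapped[, .(percent = 100 * .N / n), by = .(species = metadata[reference_id])]
  } else {
    per <- data.table(species = character(), percent = numeric())
  }
  minor <- per[percent < minor_floor]
  per <- per[percent >= minor_floor]
  if (nrow(minor)) {
    per <- rbind(per, data.table(species = "minor", percent = sum(minor$percent)))
  }
  setorder(per, -percent)
  structure(list(specimen_id = specimen_id, fractions = per,
                 unmapped_pct = unmapped_pct, n_reads = n),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %s (%d reads):\n", x$specimen_id, x$n_reads))
  for (i in seq_len(nrow(x$fractions))) {
    cat(sprintf("  %-24s %6.2f%%\n", x$fractions$species[i], x$fractions$percent[i]))
  }
  cat(sprintf("  %-24s %6.2f%%\n", "unmapped", x$unmapped_pct))
  invisible(x)
}
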