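## GCF occurrence across specimens and the fragment-collapse estimator.
## Occurrence evidence for a GCF in a specimen comes from two routes:
## metagenome BGCs that are members of the GCF's network component, and
## translated (tblastn) hits of the GCF's core biosynthetic proteins in the
## specimen's assembly. Evidence landing on the same locus is deduplicated.

#' Extract the core biosynthetic proteins of a GCF
#'
#' Core proteins are taken from the member with the most genes (ties by
#' larger span, then lexicographic id): its `is_core`-flagged genes when
#' any are flagged, otherwise the fallback consensus — its proteins with
#' strict-tier homologs (>= 60% identity, >= 80% both coverages) in at
#' least half of the members.
#'
#' @param gcf_members List of [bgc_record()] objects sharing a GCF.
#' @return Named character vector of protein sequences (names are the
#'   donor member's gene ids).
#' @export
extract_core_proteins <- function(gcf_members) {
  stopifnot(length(gcf_members) >= 1L)
  ng <- vapply(gcf_members, function(r) nrow(r$genes), integer(1))
  spans <- vapply(gcf_members, function(r) as.double(r$span_bp %||% 0), double(1))
  ids <- vapply(gcf_members, `[[`, character(1), "bgc_id")
  donor <- gcf_members[[order(-ng, -spans, ids)[1L]]]
  core <- donor$genes[donor$genes$is_core, , drop = FALSE]
  if (nrow(core) > 0L) {
    return(stats::setNames(core$protein, core$gene_id))
  }
  if (length(gcf_members) == 1L) {
    stop("member has no core-flagged genes and no consensus is possible",
         call. = FALSE)
  }
  ## consensus fallback: donor proteins strict-shared by >= half the members
  qt <- .bgc_protein_table(list(donor), prefix = "q")
  st <- .bgc_protein_table(gcf_members, prefix = "s")
  hits <- .tier_filter(.blastp_bgc(qt, st), "strict")
  need <- ceiling(length(gcf_members) / 2)
  if (nrow(hits)) {
    present <- hits[, .(n_members = uniqueN(subject_bgc)), by = query_gene]
    sel <- present[n_members >= need, query_gene]
  } else {
    sel <- character(0)
  }
  if (length(sel) == 0L) {
    stop("no core-flagged genes and no protein is shared by half the members",
         call. = FALSE)
  }
  keep <- donor$genes$gene_id %in% sel
  stats::setNames(donor$genes$protein[keep], donor$genes$gene_id[keep])
}

#' Translated search of core proteins against an assembly
#'
#' Queries proteins (tblastn) against the six-frame translation of the
#' contigs. A hit is kept when it covers more than `min_query_coverage`
#' percent of the protein at more than `min_identity` percent amino-acid
#' identity over the aligned span (strict inequalities); the best locus is
#' reported per protein per contig. Frames interrupted by stop codons
#' inside the aligned span are not reported as single hits.
#'
#' @param core_proteins Named character vector of protein sequences.
#' @param contigs A `contig_bin`, `genome_record`, or named character
#'   vector of nucleotide contigs.
#' @param min_query_coverage Query-coverage threshold in percent (default 50).
#' @param min_identity Identity threshold in percent (default 90).
#' @return data.table: `protein_id`, `contig_id`, `identity_pct`,
#'   `query_coverage_pct`, `sstart`, `send`, `frame`, `bitscore`
#'   (empty when nothing passes).
#' @export
translated_search <- function(core_proteins, contigs, min_query_coverage = 50,
                              min_identity = 90) {
  stopifnot(length(core_proteins) >= 1L)
  seqs <- .contigs_of(contigs)
  if (length(seqs) == 0L) stop("empty contig set", call. = FALSE)
  if (is.null(names(core_proteins))) {
    names(core_proteins) <- sprintf("prot%03d", seq_along(core_proteins))
  }
  hits <- .run_blast("tblastn", core_proteins, seqs, db_type = "nucl",
                     evalue = 1e-5)
  hits <- hits[pident > min_identity & qcov > min_query_coverage]
  if (nrow(hits) == 0L) {
    return(data.table(protein_id = character(), contig_id = character(),
                      identity_pct = numeric(), query_coverage_pct = numeric(),
                      sstart = integer(), send = integer(), frame = integer(),
                      bitscore = numeric()))
  }
  setorder(hits, qseqid, sseqid, -bitscore, sstart)
  hits <- hits[, head(.SD, 1L), by = .(qseqid, sseqid)]
  hits[, .(protein_id = qseqid, contig_id = sseqid, identity_pct = pident,
           query_coverage_pct = qcov, sstart, send, frame = sframe, bitscore)]
}

## merge intervals on one contig with a gap tolerance -> cluster intervals
.cluster_intervals <- function(lo, hi, gap) {
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]
  cl <- integer(length(lo))
  cur <- 1L; cur_hi <- hi[1L]; cl[1L] <- 1L
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] <= cur_hi + gap) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      cur <- cur + 1L
      cur_hi <- hi[i]
    }
    cl[i] <- cur
  }
  data.table(cluster = cl, lo = lo, hi = hi)[, .(lo = min(lo), hi = max(hi)),
                                             by = cluster]
}

#' GCF-by-specimen occurrence matrix
#'
#' Counts, per GCF and specimen, the distinct loci evidencing the GCF:
#' metagenome member BGCs of the GCF's component, plus translated-search
#' hit clusters not overlapping a member BGC locus on the same contig.
#' Per-species values are mean occurrences per specimen (total counts over
#' the species' specimens divided by the number of specimens of that
#' species); values above 1 indicate multiple subtype loci in a specimen.
#'
#' @param network A `gcf_network` from [refine_and_build()].
#' @param search_hits Optional data.frame of translated-search evidence
#'   with columns `gcf`, `specimen_id`, `contig_id`, `sstart`, `send`
#'   (e.g. [translated_search()] output, tagged with the GCF searched and
#'   the specimen whose assembly was the target). `NULL` for none.
#' @param specimen_metadata data.frame with columns `specimen_id`,
#'   `species` listing every metagenome specimen (zero-count specimens
#'   included in per-species denominators).
#' @param locus_gap Hits within this many bp on one contig are merged into
#'   one locus (default 10000).
#' @return List of class `occurrence_matrix`: `counts` (integer matrix,
#'   GCF x specimen), `per_specimen` (numeric matrix, GCF x species),
#'   `metadata`.
#' @export
build_occurrence_matrix <- function(network, search_hits = NULL,
                                    specimen_metadata, locus_gap = 10000L) {
  stopifnot(inherits(network, "gcf_network"))
  md <- as.data.table(specimen_metadata)
  stopifnot(all(c("specimen_id", "species") %in% names(md)))
  members <- network$membership[source == "metagenome"]
  miss <- setdiff(unique(members$origin_id), md$specimen_id)
  if (length(miss)) {
    stop("specimen(s) missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  gcfs <- sort(unique(c(network$membership$gcf,
                        if (!is.null(search_hits)) as.character(search_hits$gcf))))
  specimens <- md$specimen_id
  counts <- matrix(0L, length(gcfs), length(specimens),
                   dimnames = list(gcfs, specimens))
  rec_by_id <- stats::setNames(network$records,
                               vapply(network$records, `[[`, character(1), "bgc_id"))
  sh <- if (!is.null(search_hits)) as.data.table(search_hits) else NULL
  if (!is.null(sh) && nrow(sh)) {
    bad <- setdiff(unique(sh$specimen_id), specimens)
    if (length(bad)) {
      stop("specimen(s) missing from metadata: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  for (gcf_id in gcfs) {
    for (sp in specimens) {
      mem <- members[gcf == gcf_id & origin_id == sp, bgc_id]
      ## member loci: genomic interval when known, otherwise a private token
      mem_loci <- lapply(mem, function(bid) {
        r <- rec_by_id[[bid]]
        if (!is.null(r) && !is.na(r$contig_id) && !is.na(r$start)) {
          list(contig = r$contig_id, lo = r$start, hi = r$end)
        } else {
          list(contig = paste0("\rbgc:", bid), lo = 0L, hi = 0L)
        }
      })
      n_loci <- length(mem_loci)
      if (!is.null(sh) && nrow(sh)) {
        hits <- sh[gcf == gcf_id & specimen_id == sp]
        if (nrow(hits)) {
          hits[, `:=`(lo = pmin(sstart, send), hi = pmax(sstart, send))]
          for (ctg in unique(hits$contig_id)) {
            cl <- .cluster_intervals(hits[contig_id == ctg, lo],
                                     hits[contig_id == ctg, hi], locus_gap)
            for (k in seq_len(nrow(cl))) {
              dup <- any(vapply(mem_loci, function(m) {
                identical(m$contig, ctg) && cl$lo[k] <= m$hi && cl$hi[k] >= m$lo
              }, logical(1)))
              if (!dup) n_loci <- n_loci + 1L
            }
          }
        }
      }
      counts[gcf_id, sp] <- n_loci
    }
  }
  species <- sort(unique(md$species))
  per_specimen <- matrix(0, length(gcfs), length(species),
                         dimnames = list(gcfs, species))
  for (s in species) {
    cols <- md[species == s, specimen_id]
    per_specimen[, s] <- rowSums(counts[, cols, drop = FALSE]) / length(cols)
  }
  structure(list(counts = counts, per_specimen = per_specimen,
                 metadata = as.data.frame(md)),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("<occurrence_matrix> %d GCF(s) x %d specimen(s) (%d species)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$per_specimen)))
  invisible(x)
}

#' Write an occurrence matrix as TSV
#'
#' @param x An `occurrence_matrix`.
#' @param path Output path.
#' @param what `"counts"` (GCF x specimen), `"per_specimen"` (GCF x
#'   species means) or `"long"` (tidy long counts).
#' @export
write_occurrence_tsv <- function(x, path, what = c("counts", "per_specimen", "long")) {
  what <- match.arg(what)
  if (what == "long") {
    long <- as.data.table(as.table(x$counts))
    setnames(long, c("gcf", "specimen_id", "count"))
    fwrite(long, path, sep = "\t")
  } else {
    m <- x[[what]]
    fwrite(data.table(gcf = rownames(m), as.data.table(m)), path, sep = "\t")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# fragment collapse

#' Collapse fragmented metagenome BGCs against reference BGCs
#'
#' Each metagenome BGC is assigned to its best-hitting reference BGC (by
#' directional-hit score; ties lexicographic). Within one (specimen,
#' reference) group, fragments whose hit ranges on the reference gene order
#' are disjoint are merged — they are complementary pieces of one
#' underlying cluster split by assembly — while fragments with overlapping
#' ranges stay separate (genuinely distinct copies). Unassigned metagenome
#' BGCs count once each.
#'
#' @param metag_bgcs List of metagenome [bgc_record()] objects
#'   (class-filtered; `origin_id` = specimen).
#' @param reference_bgcs List of reference (isolate) [bgc_record()]
#'   objects.
#' @param min_shared Minimum loose-tier shared genes for an assignment
#'   (default 3).
#' @return List of class `collapse_result`: `n_metagenome_bgcs`,
#'   `n_matched_metag`, `n_matched_reference_bgcs`,
#'   `n_unique_after_collapse` (all inputs; unassigned count once),
#'   `n_matched_unique` (clusters among matched fragments only),
#'   `inflation_factor` (= matched metagenome BGCs / matched unique
#'   clusters), `assignments` (data.table).
#' @export
collapse_fragments <- function(metag_bgcs, reference_bgcs, min_shared = 3L) {
  n_metag <- length(metag_bgcs)
  stopifnot(n_metag >= 1L)
  if (anyDuplicated(vapply(metag_bgcs, `[[`, character(1), "bgc_id"))) {
    stop("metagenome bgc_ids must be unique", call. = FALSE)
  }
  empty_res <- function(n_matched = 0L, n_refs = 0L, n_matched_unique = 0L,
                        assignments = NULL) {
    structure(list(
      n_metagenome_bgcs = n_metag, n_matched_metag = n_matched,
      n_matched_reference_bgcs = n_refs,
      n_unique_after_collapse = n_matched_unique + (n_metag - n_matched),
      n_matched_unique = n_matched_unique,
      inflation_factor = if (n_matched_unique > 0L) n_matched / n_matched_unique
                         else NA_real_,
      assignments = assignments
    ), class = "collapse_result")
  }
  if (length(reference_bgcs) == 0L) return(empty_res())
  qt <- .bgc_protein_table(metag_bgcs, prefix = "m")
  st <- .bgc_protein_table(reference_bgcs, prefix = "r")
  loose <- .best_per_query_gene(.tier_filter(.blastp_bgc(qt, st), "loose"))
  if (nrow(loose) == 0L) return(empty_res())
  pair <- loose[, {
    sc <- .pair_score(copy(.SD))
    .(shared_genes = sc$shared_genes, score = sc$score,
      ref_gene_min = min(subject_idx), ref_gene_max = max(subject_idx))
  }, by = .(query_bgc, subject_bgc)]
  pair <- pair[shared_genes >= min_shared]
  if (nrow(pair) == 0L) return(empty_res())
  setorder(pair, query_bgc, -score, subject_bgc)
  best <- pair[, head(.SD, 1L), by = query_bgc]
  origin_of <- stats::setNames(
    vapply(metag_bgcs, function(r) as.character(r$origin_id), character(1)),
    vapply(metag_bgcs, `[[`, character(1), "bgc_id"))
  best[, specimen_id := origin_of[query_bgc]]

  ## first-fit merging of complementary fragments per (specimen, reference)
  n_clusters <- 0L
  cluster_id <- character(nrow(best))
  setorder(best, specimen_id, subject_bgc, ref_gene_min, ref_gene_max, query_bgc)
  for (grp in split(seq_len(nrow(best)),
                    paste(best$specimen_id, best$subject_bgc, sep = "\r"))) {
    clusters <- list()  # each: list of occupied [lo, hi] intervals
    for (i in grp) {
      lo <- best$ref_gene_min[i]; hi <- best$ref_gene_max[i]
      placed <- FALSE
      for (k in seq_along(clusters)) {
        if (!any(vapply(clusters[[k]], function(iv) lo <= iv[2L] && hi >= iv[1L],
                        logical(1)))) {
          clusters[[k]] <- c(clusters[[k]], list(c(lo, hi)))
          cluster_id[i] <- sprintf("%s|%s|%d", best$specimen_id[i],
                                   best$subject_bgc[i], k)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        clusters[[length(clusters) + 1L]] <- list(c(lo, hi))
        cluster_id[i] <- sprintf("%s|%s|%d", best$specimen_id[i],
                                 best$subject_bgc[i], length(clusters))
      }
    }
    n_clusters <- n_clusters + length(clusters)
  }
  best[, cluster := cluster_id]
  assignments <- best[, .(bgc_id = query_bgc, reference_bgc = subject_bgc,
                          specimen_id, score, ref_gene_min, ref_gene_max,
                          cluster)]
  empty_res(n_matched = nrow(best),
            n_refs = length(unique(best$subject_bgc)),
            n_matched_unique = n_clusters,
            assignments = assignments)
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf(
    "<collapse_result> %d metagenome BGC(s): %d matched to %d reference BGC(s), collapsing to %d unique (inflation %.2f); %d unique overall\n",
    x$n_metagenome_bgcs, x$n_matched_metag, x$n_matched_reference_bgcs,
    x$n_matched_unique,
    ifelse(is.na(x$inflation_factor), NA, x$inflation_factor),
    x$n_unique_after_collapse))
  invisible(x)
}

#' Estimate the total number of unique BGCs from the measured inflation
#'
#' Fragmentation inflates the raw metagenome BGC count; dividing the total
#' count by the inflation factor measured on the matched subset estimates
#' the number of distinct underlying clusters.
#'
#' @param n_total_metag Total number of metagenome BGCs observed.
#' @param collapse A `collapse_result` computed on the matched subset.
#' @return The estimate (`NA` with a message when nothing matched).
#' @examples
#' \dontrun{estimate_total_unique(401, collapse)}
#' @export
estimate_total_unique <- function(n_total_metag, collapse) {
  stopifnot(inherits(collapse, "collapse_result"))
  if (is.na(collapse$inflation_factor)) {
    message("no matched metagenome BGCs; estimate undefined")
    return(NA_real_)
  }
  n_total_metag / collapse$inflation_factor
}
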