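## Gene cluster family (GCF) construction. Clusters of well-characterized
## product classes are compared all-vs-all at the protein level;
## cluster-to-cluster hits in both directions make reliable edges, while
## single-directional hits (typically a metagenomic fragment against a
## full-length cluster) are retained only when almost all of the truncated
## member's proteins (at least n - 2 of its n genes, floored at 1) find
## strict homologs (>= 60% identity, >= 80% coverage of both sequences) in
## the partner. GCFs are the connected components of the resulting network.

KEEP_BGC_CLASSES <- c("pks", "nrps", "siderophore", "terpene", "hserlactone",
                      "thiopeptide")

.canonical_class <- function(x) {
  x <- tolower(x)
  x <- gsub("homoserine[ _-]?lactone", "hserlactone", x)
  x
}

#' Filter BGCs to well-characterized product classes
#'
#' Keeps clusters whose product-class set touches the well-characterized
#' biosynthetic families — PKSs, NRPSs, siderophores, terpenes, homoserine
#' lactones, thiopeptides — including hybrids of these (e.g. `nrps-t1pks`).
#' Input order is preserved.
#'
#' @param records List of [bgc_record()] objects.
#' @param keep Class tokens to keep (matched as substrings of the
#'   canonicalized class labels).
#' @return The retained subset of `records`.
#' @examples
#' \dontrun{filter_bgc_classes(records)}
#' @export
filter_bgc_classes <- function(records, keep = KEEP_BGC_CLASSES) {
  hit <- vapply(records, function(r) {
    cls <- .canonical_class(r$product_classes)
    any(vapply(keep, function(k) any(grepl(k, cls, fixed = TRUE)), logical(1)))
  }, logical(1))
  records[hit]
}

#' Per-gene protein homology between two BGCs
#'
#' All-vs-all local protein alignment (blastp) between the genes of two
#' clusters. The `loose` tier (identity >= 30%, both coverages >= 25%)
#' stands in for a multi-gene comparison tool's defaults; the `strict`
#' tier (identity >= 60%, both coverages >= 80%) is the refinement filter
#' for valid hits. Each query gene reports at most its best subject hit.
#'
#' @param a,b [bgc_record()] objects (query and subject).
#' @param tier `"loose"` or `"strict"`.
#' @return data.table with columns `query_gene_id`, `subject_gene_id`,
#'   `identity_pct`, `query_coverage_pct`, `subject_coverage_pct`,
#'   `bitlike_score`.
#' @export
gene_hits <- function(a, b, tier = c("loose", "strict")) {
  tier <- match.arg(tier)
  stopifnot(inherits(a, "bgc_record"), inherits(b, "bgc_record"))
  qt <- .bgc_protein_table(list(a), prefix = "q")
  st <- .bgc_protein_table(list(b), prefix = "s")
  hits <- .best_per_query_gene(.tier_filter(.blastp_bgc(qt, st), tier))
  if (nrow(hits) == 0L) {
    return(data.table(query_gene_id = character(), subject_gene_id = character(),
                      identity_pct = numeric(), query_coverage_pct = numeric(),
                      subject_coverage_pct = numeric(), bitlike_score = numeric()))
  }
  hits[, .(query_gene_id = query_gene, subject_gene_id = subject_gene,
           identity_pct = pident, query_coverage_pct = qcov,
           subject_coverage_pct = scov, bitlike_score = bitscore)]
}

## shared-gene count, synteny weight and score from a per-pair loose-tier
## best-hit table (one row per query gene)
.pair_score <- function(pair_hits) {
  shared <- nrow(pair_hits)
  setorder(pair_hits, query_idx)
  synteny <- if (shared == 0L) 0 else .lis_length(pair_hits$subject_idx) / shared
  list(shared_genes = shared, synteny_weight = synteny,
       score = shared * (1 + synteny))
}

#' Directional cluster-to-cluster hit
#'
#' A hit from `query` to `subject` is declared when at least `min_shared`
#' query genes have a loose-tier homolog in the subject. The score is
#' `shared_genes * (1 + synteny_weight)`, where the synteny weight is the
#' longest common subsequence of the hit order divided by the shared gene
#' count — a documented stand-in for a multi-gene alignment score with the
#' same monotone behaviour (more homologs in conserved order scores
#' higher).
#'
#' @param query,subject [bgc_record()] objects.
#' @param min_shared Minimum shared genes to declare a hit (default 3).
#' @return List of class `directional_hit` (`query_bgc`, `subject_bgc`,
#'   `n_query_genes`, `shared_genes`, `synteny_weight`, `score`), or
#'   `NULL` when below threshold.
#' @export
directional_hit <- function(query, subject, min_shared = 3L) {
  qt <- .bgc_protein_table(list(query), prefix = "q")
  st <- .bgc_protein_table(list(subject), prefix = "s")
  hits <- .best_per_query_gene(.tier_filter(.blastp_bgc(qt, st), "loose"))
  if (nrow(hits) < min_shared) return(NULL)
  sc <- .pair_score(hits)
  structure(c(list(query_bgc = query$bgc_id, subject_bgc = subject$bgc_id,
                   n_query_genes = nrow(query$genes)), sc),
            class = "directional_hit")
}

#' @export
print.directional_hit <- function(x, ...) {
  cat(sprintf("<directional_hit> %s -> %s: %d/%d genes shared, synteny %.2f, score %.2f\n",
              x$query_bgc, x$subject_bgc, x$shared_genes, x$n_query_genes,
              x$synteny_weight, x$score))
  invisible(x)
}

#' Single-directional hit retention rule
#'
#' A single-directional hit is retained when the truncated member (the BGC
#' with fewer genes, `n` genes in total) has at least `max(n - 2, 1)`
#' genes with strict-tier homologs in the partner. The floor of 1 avoids
#' evidence-free edges for degenerate clusters with `n <= 2`.
#'
#' @param n_genes Gene count of the truncated member.
#' @param n_strict_hits Its number of strict-tier gene hits in the partner.
#' @return Logical.
#' @examples
#' gcf_refine_rule(5, 3)  # TRUE:  3 >= 5 - 2
#' gcf_refine_rule(5, 2)  # FALSE
#' gcf_refine_rule(3, 1)  # TRUE:  floor(1)
#' @export
gcf_refine_rule <- function(n_genes, n_strict_hits) {
  n_strict_hits >= pmax(n_genes - 2L, 1L)
}

#' Build the GCF similarity network from class-filtered BGCs
#'
#' Runs the all-vs-all protein comparison (one batched blastp call),
#' derives directional cluster-to-cluster hits, applies the bidirectional
#' and refined single-directional edge rules, and labels gene cluster
#' families as connected components (numbered by descending component
#' size, ties by lexicographic smallest member id).
#'
#' @param records List of class-filtered [bgc_record()] objects.
#' @param min_shared Minimum loose-tier shared genes for a directional hit
#'   (default 3).
#' @return List of class `gcf_network`: `graph` (igraph, node attributes
#'   `source`, `origin`, `gcf`; edge attributes `weight`, `edge_type`),
#'   `membership` (data.table `bgc_id`, `gcf`, `source`, `origin_id`,
#'   `n_genes`), `directional` (all declared directional hits), `records`.
#' @export
refine_and_build <- function(records, min_shared = 3L) {
  stopifnot(length(records) >= 1L)
  ids <- vapply(records, `[[`, character(1), "bgc_id")
  if (anyDuplicated(ids)) stop("duplicate bgc_ids", call. = FALSE)
  ptab <- .bgc_protein_table(records, prefix = "n")
  raw <- .blastp_bgc(ptab, ptab)
  raw <- raw[query_bgc != subject_bgc]
  loose_best <- .best_per_query_gene(.tier_filter(raw, "loose"))
  strict_best <- .best_per_query_gene(.tier_filter(raw, "strict"))

  ## directional hits per ordered pair
  if (nrow(loose_best)) {
    dir_tab <- loose_best[, {
      sc <- .pair_score(copy(.SD))
      .(n_query_genes = n_query_genes[1L], shared_genes = sc$shared_genes,
        synteny_weight = sc$synteny_weight, score = sc$score)
    }, by = .(query_bgc, subject_bgc)]
    dir_tab <- dir_tab[shared_genes >= min_shared]
  } else {
    dir_tab <- data.table(query_bgc = character(), subject_bgc = character(),
                          n_query_genes = integer(), shared_genes = integer(),
                          synteny_weight = numeric(), score = numeric())
  }
  strict_counts <- if (nrow(strict_best)) {
    strict_best[, .(n_strict = .N), by = .(query_bgc, subject_bgc)]
  } else {
    data.table(query_bgc = character(), subject_bgc = character(),
               n_strict = integer())
  }
  n_genes_of <- stats::setNames(vapply(records, function(r) nrow(r$genes),
                                       integer(1)), ids)

  ## unordered pairs with at least one declared direction
  edges <- list()
  if (nrow(dir_tab)) {
    dir_tab[, `:=`(a = pmin(query_bgc, subject_bgc),
                   b = pmax(query_bgc, subject_bgc))]
    for (key in unique(paste(dir_tab$a, dir_tab$b, sep = "\r"))) {
      ab <- strsplit(key, "\r", fixed = TRUE)[[1L]]
      sub <- dir_tab[a == ab[1L] & b == ab[2L]]
      if (nrow(sub) == 2L) {
        edges[[key]] <- data.table(from = ab[1L], to = ab[2L],
                                   weight = max(sub$score),
                                   edge_type = "bidirectional")
      } else {
        ## single-directional: refine against the truncated member
        ng <- n_genes_of[ab]
        trunc_id <- if (ng[1L] != ng[2L]) ab[which.min(ng)] else min(ab)
        partner <- setdiff(ab, trunc_id)
        s <- strict_counts[query_bgc == trunc_id & subject_bgc == partner, n_strict]
        s <- if (length(s)) s else 0L
        if (gcf_refine_rule(n_genes_of[[trunc_id]], s)) {
          edges[[key]] <- data.table(from = ab[1L], to = ab[2L],
                                     weight = sub$score[1L],
                                     edge_type = "refined_single")
        }
      }
    }
  }
  edge_tab <- rbindlist(edges)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
                            source = vapply(records, `[[`, character(1), "source"),
                            origin = vapply(records, function(r) {
                              as.character(r$origin_id %||% NA_character_)
                            }, character(1)))
  if (length(edges)) {
    g <- igraph::add_edges(g, t(as.matrix(edge_tab[, .(from, to)])),
                           weight = edge_tab$weight,
                           edge_type = edge_tab$edge_type)
  }
  comp <- igraph::components(g)
  ## number GCFs by descending size, then lexicographic smallest member
  comp_members <- split(ids, comp$membership)
  ord <- order(-lengths(comp_members),
               vapply(comp_members, min, character(1)))
  gcf_of_comp <- integer(length(comp_members))
  gcf_of_comp[ord] <- seq_along(comp_members)
  gcf_ids <- sprintf("GCF_%d", gcf_of_comp[comp$membership])
  g <- igraph::set_vertex_attr(g, "gcf", value = gcf_ids)
  membership <- data.table(
    bgc_id = ids, gcf = gcf_ids,
    source = vapply(records, `[[`, character(1), "source"),
    origin_id = vapply(records, function(r) as.character(r$origin_id),
                       character(1)),
    n_genes = unname(n_genes_of)
  )
  structure(list(graph = g, membership = membership, directional = dir_tab,
                 records = records),
            class = "gcf_network")
}

#' @rdname refine_and_build
#' @export
gcf_network <- refine_and_build

#' @export
print.gcf_network <- function(x, ...) {
  n_gcf <- length(unique(x$membership$gcf))
  cat(sprintf("<gcf_network> %d BGC(s) in %d GCF(s); %d edge(s) (%d bidirectional, %d refined single-directional)\n",
              nrow(x$membership), n_gcf, igraph::ecount(x$graph),
              sum(igraph::E(x$graph)$edge_type == "bidirectional"),
              sum(igraph::E(x$graph)$edge_type == "refined_single")))
  invisible(x)
}

#' Export a GCF network to GraphML
#'
#' @param network A `gcf_network`.
#' @param path Output path.
#' @export
write_gcf_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Export a GCF network in SIF format
#'
#' One line per edge: `source <edge_type> target`; isolated nodes are
#' written as single-column lines.
#'
#' @param network A `gcf_network`.
#' @param path Output path.
#' @export
write_gcf_sif <- function(network, path) {
  g <- network$graph
  el <- igraph::as_edgelist(g)
  lines <- character(0)
  if (nrow(el)) {
    lines <- sprintf("%s\t%s\t%s", el[, 1L], igraph::E(g)$edge_type, el[, 2L])
  }
  iso <- setdiff(igraph::V(g)$name, unique(c(el)))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Write the GCF membership table as TSV
#'
#' @param network A `gcf_network`.
#' @param path Output path.
#' @export
write_gcf_membership <- function(network, path) {
  fwrite(network$membership, path, sep = "\t")
  invisible(path)
}
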