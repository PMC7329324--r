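## Synthetic-data module: every input class the pipeline consumes can be
## generated with machine-readable ground truth. All generators are
## substitution-only (no indels), so expected identities have the closed
## form 1 - divergence, and all are deterministic given `seed` (the global
## RNG state is left untouched via withr::with_seed).

AA20 <- setdiff(AA_ALPHABET, "X")

#' Generate a random genome
#'
#' @param id Genome id.
#' @param n_bp Total genome size in bp.
#' @param n_contigs Number of contigs to split the genome into (equal sizes,
#'   remainder on the last contig).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A [genome_record()].
#' @export
random_genome <- function(id, n_bp, n_contigs = 1L, seed = 1L) {
  stopifnot(n_bp >= n_contigs, n_contigs >= 1L)
  withr::with_seed(seed, {
    base_len <- n_bp %/% n_contigs
    lens <- rep(base_len, n_contigs)
    lens[n_contigs] <- lens[n_contigs] + n_bp %% n_contigs
    contigs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    names(contigs) <- sprintf("%s_c%02d", id, seq_len(n_contigs))
    genome_record(id, contigs)
  })
}

#' Mutate a genome to a target divergence
#'
#' Introduces `round(divergence * genome length)` point substitutions at
#' positions sampled uniformly without replacement (never at `N` sites);
#' each substitution changes the base. Indels are not modelled, so the
#' realized per-site mismatch fraction equals the realized divergence
#' exactly.
#'
#' @param parent A [genome_record()].
#' @param divergence Target per-site divergence in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param child_id Id for the mutated genome; default `<parent>_d<divergence>`.
#' @return List with elements `genome` (the child [genome_record()]) and
#'   `log`, a mutation log: list with `parent_id`, `child_id`,
#'   `substitutions` (data.table of `contig_id`, `position`, `from_base`,
#'   `to_base`) and `realized_divergence`.
#' @export
mutate_genome <- function(parent, divergence, seed = 1L, child_id = NULL) {
  stopifnot(inherits(parent, "genome_record"))
  if (divergence < 0 || divergence >= 0.5) {
    stop("divergence must be in [0, 0.5)", call. = FALSE)
  }
  child_id <- child_id %||% sprintf("%s_d%g", parent$id, divergence)
  n_sub <- round(divergence * parent$total_length)
  if (n_sub == 0L) {
    contigs <- parent$contigs
    return(list(genome = genome_record(child_id, contigs),
                log = list(parent_id = parent$id, child_id = child_id,
                           substitutions = data.table(contig_id = character(),
                                                      position = integer(),
                                                      from_base = character(),
                                                      to_base = character()),
                           realized_divergence = 0)))
  }
  withr::with_seed(seed, {
    lens <- nchar(parent$contigs)
    offsets <- cumsum(c(0L, unname(lens[-length(lens)])))
    names(offsets) <- names(lens)
    ## genome-wide positions, excluding N sites
    concat <- paste(parent$contigs, collapse = "")
    eligible <- which(strsplit(concat, "")[[1L]] != "N")
    if (n_sub > length(eligible)) stop("divergence too high for eligible sites", call. = FALSE)
    picks <- sort(sample(eligible, n_sub))
    contig_idx <- findInterval(picks, cumsum(lens) + 1L) + 1L
    contig_ids <- names(lens)[contig_idx]
    local_pos <- picks - offsets[contig_idx]
    from <- substring(concat, picks, picks)
    to <- vapply(from, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                 character(1), USE.NAMES = FALSE)
    contigs <- parent$contigs
    for (i in seq_along(picks)) {
      substr(contigs[[contig_ids[i]]], local_pos[i], local_pos[i]) <- to[i]
    }
    log <- list(
      parent_id = parent$id, child_id = child_id,
      substitutions = data.table(contig_id = contig_ids,
                                 position = as.integer(local_pos),
                                 from_base = from, to_base = to),
      realized_divergence = n_sub / parent$total_length
    )
    list(genome = genome_record(child_id, contigs), log = log)
  })
}

#' Assemble a synthetic metagenome bin from weighted source genomes
#'
#' Draws `n_fragments` contigs as subsequences of the source genomes,
#' choosing the source of each fragment with the given weights (so a bin
#' emulates the fragmented mixture of closely related strains seen in real
#' metagenome bins). The provenance of every contig is recorded.
#'
#' @param sources List of [genome_record()] objects.
#' @param weights Positive weights summing to 1, one per source.
#' @param n_fragments Number of contigs to draw.
#' @param mean_fragment_bp,sd_fragment_bp Normal fragment-length model
#'   (lengths rounded, floored at 200 bp). Defaults emulate short
#'   metagenome contigs (mean 3 kb).
#' @param fragment_sampler Optional function `n -> integer lengths`
#'   overriding the normal model.
#' @param bin_id,specimen_id Identifiers for the bin.
#' @param coding_density,gene_taxa Passed to [contig_bin()].
#' @param seed Integer seed.
#' @return A [contig_bin()] whose `provenance` field maps every contig to
#'   `(source_id, src_contig, start, end)`.
#' @export
make_bin <- function(sources, weights, n_fragments = 50L,
                     mean_fragment_bp = 3000, sd_fragment_bp = 1000,
                     fragment_sampler = NULL, bin_id = "bin1",
                     specimen_id = "spec1", coding_density = NA_real_,
                     gene_taxa = NULL, seed = 1L) {
  stopifnot(length(sources) == length(weights), all(weights > 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  withr::with_seed(seed, {
    lens <- if (is.null(fragment_sampler)) {
      pmax(200L, as.integer(round(rnorm(n_fragments, mean_fragment_bp, sd_fragment_bp))))
    } else {
      as.integer(fragment_sampler(n_fragments))
    }
    src_idx <- sample.int(length(sources), n_fragments, replace = TRUE, prob = weights)
    contigs <- character(n_fragments)
    prov <- vector("list", n_fragments)
    for (i in seq_len(n_fragments)) {
      g <- sources[[src_idx[i]]]
      clens <- nchar(g$contigs)
      ci <- sample.int(length(clens), 1L, prob = clens)
      if (lens[i] > clens[ci]) {
        stop(sprintf("fragment length %d exceeds source contig %s (%d bp)",
                     lens[i], names(g$contigs)[ci], clens[ci]), call. = FALSE)
      }
      start <- sample.int(clens[ci] - lens[i] + 1L, 1L)
      contigs[i] <- substr(g$contigs[[ci]], start, start + lens[i] - 1L)
      prov[[i]] <- data.table(source_id = g$id, src_contig = names(g$contigs)[ci],
                              start = start, end = start + lens[i] - 1L)
    }
    names(contigs) <- sprintf("%s_frag%04d", bin_id, seq_len(n_fragments))
    prov <- rbindlist(prov)
    prov[, contig_id := names(contigs)]
    setcolorder(prov, "contig_id")
    contig_bin(bin_id, specimen_id, contigs, coding_density = coding_density,
               gene_taxa = gene_taxa, provenance = as.data.frame(prov))
  })
}

#' Simulate unpaired reads from weighted source genomes
#'
#' Reads start uniformly along the concatenated source, are drawn from
#' either strand with probability 1/2, and carry independent per-base
#' substitution errors. A truth table maps every read to its source.
#'
#' @param sources List of [genome_record()] objects.
#' @param weights Positive weights summing to 1.
#' @param n_reads Number of reads (> 0).
#' @param read_length Read length in bp; must not exceed the shortest contig.
#' @param error_rate Per-base substitution error rate in `[0, 0.1)`.
#' @param seed Integer seed.
#' @return List of class `read_set`: `reads` (named character),
#'   `truth` (data.table of `read_id`, `source_id`, `contig_id`, `start`,
#'   `strand`, `n_errors`) and the call parameters.
#' @export
simulate_reads <- function(sources, weights, n_reads, read_length = 125L,
                           error_rate = 0, seed = 1L) {
  if (n_reads <= 0) stop("n_reads must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.1) stop("error_rate must be in [0, 0.1)", call. = FALSE)
  stopifnot(length(sources) == length(weights), all(weights > 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  min_contig <- min(unlist(lapply(sources, function(g) nchar(g$contigs))))
  if (read_length > min_contig) {
    stop("read_length exceeds the shortest source contig", call. = FALSE)
  }
  withr::with_seed(seed, {
    src_idx <- sample.int(length(sources), n_reads, replace = TRUE, prob = weights)
    reads <- character(n_reads)
    t_source <- character(n_reads); t_contig <- character(n_reads)
    t_start <- integer(n_reads); t_nerr <- integer(n_reads)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n_reads)) {
      g <- sources[[src_idx[i]]]
      clens <- nchar(g$contigs)
      ok <- which(clens >= read_length)
      ci <- ok[sample.int(length(ok), 1L, prob = clens[ok] - read_length + 1L)]
      start <- sample.int(clens[ci] - read_length + 1L, 1L)
      seqv <- substr(g$contigs[[ci]], start, start + read_length - 1L)
      n_err <- 0L
      if (error_rate > 0) {
        err_pos <- which(runif(read_length) < error_rate)
        n_err <- length(err_pos)
        for (p in err_pos) {
          substr(seqv, p, p) <- sample(setdiff(bases, substr(seqv, p, p)), 1L)
        }
      }
      reads[i] <- seqv
      t_source[i] <- g$id; t_contig[i] <- names(g$contigs)[ci]
      t_start[i] <- start; t_nerr[i] <- n_err
    }
    strands <- ifelse(runif(n_reads) < 0.5, "+", "-")
    flip <- strands == "-"
    if (any(flip)) reads[flip] <- .revcomp(reads[flip])
    names(reads) <- sprintf("read_%06d", seq_len(n_reads))
    truth <- data.table(read_id = names(reads), source_id = t_source,
                        contig_id = t_contig, start = t_start,
                        strand = strands, n_errors = t_nerr)
    structure(list(reads = reads, truth = truth, read_length = read_length,
                   error_rate = error_rate, weights = weights,
                   source_ids = vapply(sources, `[[`, character(1), "id")),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads of %d bp, error rate %g, %d source(s)\n",
              length(x$reads), x$read_length, x$error_rate, length(x$source_ids)))
  invisible(x)
}

#' Simulate a marker-gene read pool from a strain mixture
#'
#' Builds one haplotype of the marker per strain by applying its SNP set,
#' then draws error-free reads from the haplotypes at the given mixture
#' proportions (uniform start positions, both strands).
#'
#' @param marker Reference marker nucleotide sequence (e.g. a gyrB gene).
#' @param strain_snp_sets List (one per strain) of data.frames with columns
#'   `pos` (1-based position in the marker) and `base` (the strain's base).
#'   An empty data.frame (or `NULL`) means the strain equals the reference.
#' @param proportions Mixture proportions summing to 1.
#' @param n_reads,read_length Read pool size and read length.
#' @param seed Integer seed.
#' @return List of class `marker_mixture`: `reads`, `truth` (read_id ->
#'   strain), `haplotypes`, `proportions`, `snp_sets`.
#' @export
make_marker_mixture <- function(marker, strain_snp_sets, proportions,
                                n_reads = 2000L, read_length = 100L, seed = 1L) {
  marker <- toupper(marker)
  stopifnot(length(strain_snp_sets) == length(proportions))
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1", call. = FALSE)
  L <- nchar(marker)
  if (read_length > L) stop("read_length exceeds marker length", call. = FALSE)
  haps <- vapply(seq_along(strain_snp_sets), function(i) {
    snp <- strain_snp_sets[[i]]
    h <- marker
    if (!is.null(snp) && nrow(snp)) {
      if (any(snp$pos < 1L | snp$pos > L)) {
        stop("SNP position outside marker", call. = FALSE)
      }
      dup <- duplicated(snp$pos)
      if (any(dup)) {
        agree <- all(vapply(unique(snp$pos[dup]), function(p) {
          length(unique(snp$base[snp$pos == p])) == 1L
        }, logical(1)))
        if (!agree) {
          stop(sprintf("contradictory SNP definitions within strain %d", i),
               call. = FALSE)
        }
        snp <- snp[!dup, , drop = FALSE]
      }
      for (j in seq_len(nrow(snp))) {
        substr(h, snp$pos[j], snp$pos[j]) <- toupper(snp$base[j])
      }
    }
    h
  }, character(1))
  strain_ids <- names(strain_snp_sets) %||% sprintf("strain%d", seq_along(haps))
  if (is.null(names(strain_snp_sets))) names(strain_snp_sets) <- strain_ids
  withr::with_seed(seed, {
    strain_idx <- sample.int(length(haps), n_reads, replace = TRUE, prob = proportions)
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    strands <- ifelse(runif(n_reads) < 0.5, "+", "-")
    reads <- substring(haps[strain_idx], starts, starts + read_length - 1L)
    flip <- strands == "-"
    if (any(flip)) reads[flip] <- .revcomp(reads[flip])
    names(reads) <- sprintf("mread_%06d", seq_len(n_reads))
    truth <- data.table(read_id = names(reads), strain = strain_ids[strain_idx],
                        start = starts, strand = strands)
    structure(list(reads = reads, truth = truth,
                   haplotypes = stats::setNames(haps, strain_ids),
                   proportions = stats::setNames(proportions, strain_ids),
                   snp_sets = strain_snp_sets, marker = marker),
              class = "marker_mixture")
  })
}

# ---------------------------------------------------------------------------
# BGC generators

#' Generate a random prototype BGC
#'
#' Random protein sequences over the 20-letter amino-acid alphabet; the
#' longest gene is flagged as the core biosynthetic gene.
#'
#' @param bgc_id Cluster id.
#' @param n_genes Number of genes (>= 1).
#' @param classes Product-class labels.
#' @param origin_id,source Passed to [bgc_record()].
#' @param len_range Protein length range (uniform draw).
#' @param n_core Number of genes (the longest ones) flagged `is_core`.
#' @param seed Integer seed.
#' @return A [bgc_record()].
#' @export
random_bgc <- function(bgc_id, n_genes = 10L, classes = "t1pks",
                       origin_id = "strainA", source = "isolate",
                       len_range = c(120L, 400L), n_core = 1L, seed = 1L) {
  withr::with_seed(seed, {
    lens <- sample(len_range[1L]:len_range[2L], n_genes, replace = TRUE)
    prots <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, character(1))
    core <- rank(-lens, ties.method = "first") <= n_core
    genes <- data.frame(gene_id = sprintf("%s_g%02d", bgc_id, seq_len(n_genes)),
                        protein = prots, is_core = core, stringsAsFactors = FALSE)
    bgc_record(bgc_id, source = source, origin_id = origin_id,
               product_classes = classes, genes = genes)
  })
}

.mutate_protein <- function(prot, divergence) {
  L <- nchar(prot)
  ## floor keeps the realized divergence at or below the drawn value, so
  ## identity >= 1 - divergence holds exactly
  n_mut <- floor(divergence * L)
  if (n_mut == 0L) return(prot)
  pos <- sample.int(L, n_mut)
  for (p in pos) {
    substr(prot, p, p) <- sample(setdiff(AA20, substr(prot, p, p)), 1L)
  }
  prot
}

#' Generate a family of related BGC variants from a prototype
#'
#' Each variant drops a contiguous terminal run of genes (a uniform
#' truncation fraction up to `max_truncation`, from either end — emulating
#' contig-edge fragmentation of metagenomic BGCs) and mutates the remaining
#' protein sequences at a per-variant divergence drawn uniformly up to
#' `max_protein_divergence`. Labels record the realized values.
#'
#' @param prototype A [bgc_record()] with at least 4 genes.
#' @param n_variants Number of variants to generate.
#' @param max_truncation Maximum fraction of genes to drop, in `[0, 1)`.
#' @param max_protein_divergence Maximum per-residue divergence, in `[0, 1)`.
#' @param family_id Family label; default the prototype's id.
#' @param origin_ids Origin labels for the variants (recycled); default
#'   `specimen1..n`.
#' @param source Source label for variants (default `"metagenome"`).
#' @param seed Integer seed.
#' @return List with `records` (list of [bgc_record()]) and `labels`
#'   (data.table: `bgc_id`, `family_id`, `truncation_fraction`,
#'   `protein_divergence`, `kept_from`, `kept_to`).
#' @export
make_bgc_family <- function(prototype, n_variants, max_truncation = 0.3,
                            max_protein_divergence = 0.1, family_id = NULL,
                            origin_ids = NULL, source = "metagenome", seed = 1L) {
  stopifnot(inherits(prototype, "bgc_record"))
  n_genes <- nrow(prototype$genes)
  if (n_genes < 4L) stop("prototype must have at least 4 genes", call. = FALSE)
  if (max_truncation < 0 || max_truncation >= 1) {
    stop("max_truncation must be in [0, 1)", call. = FALSE)
  }
  family_id <- family_id %||% prototype$bgc_id
  origin_ids <- rep_len(origin_ids %||% sprintf("specimen%d", seq_len(n_variants)),
                        n_variants)
  withr::with_seed(seed, {
    records <- vector("list", n_variants)
    labels <- vector("list", n_variants)
    for (v in seq_len(n_variants)) {
      trunc_frac <- runif(1, 0, max_truncation)
      n_drop <- floor(trunc_frac * n_genes)
      if (n_genes - n_drop < 1L) stop("truncation would leave no genes", call. = FALSE)
      from_start <- runif(1) < 0.5
      keep <- if (from_start) (n_drop + 1L):n_genes else 1L:(n_genes - n_drop)
      div <- runif(1, 0, max_protein_divergence)
      genes <- prototype$genes[keep, , drop = FALSE]
      genes$protein <- vapply(genes$protein, .mutate_protein, character(1),
                              divergence = div, USE.NAMES = FALSE)
      vid <- sprintf("%s_v%02d", family_id, v)
      genes$gene_id <- sprintf("%s_g%02d", vid, seq_along(keep))
      records[[v]] <- bgc_record(vid, source = source, origin_id = origin_ids[v],
                                 product_classes = prototype$product_classes,
                                 genes = genes)
      labels[[v]] <- data.table(bgc_id = vid, family_id = family_id,
                                truncation_fraction = n_drop / n_genes,
                                protein_divergence = div,
                                kept_from = min(keep), kept_to = max(keep))
    }
    list(records = records, labels = rbindlist(labels))
  })
}

#' Split a BGC into contiguous gene fragments
#'
#' Cuts the gene list into `n_pieces` contiguous, complementary runs —
#' emulating one cluster split across assembly contigs. Each piece becomes
#' its own `bgc_record` tagged with the parent id in its label.
#'
#' @param record A [bgc_record()].
#' @param n_pieces Number of fragments (each receives >= `min_genes` genes).
#' @param min_genes Minimum genes per fragment (default 3, the default
#'   directional-hit evidence floor).
#' @param origin_id Origin for the fragments; default the record's.
#' @param seed Integer seed.
#' @return List with `records` and `labels` (bgc_id, parent_id, gene_from,
#'   gene_to).
#' @export
fragment_bgc <- function(record, n_pieces, min_genes = 3L, origin_id = NULL,
                         seed = 1L) {
  n_genes <- nrow(record$genes)
  if (n_pieces * min_genes > n_genes) {
    stop("not enough genes for the requested number of pieces", call. = FALSE)
  }
  origin_id <- origin_id %||% record$origin_id
  withr::with_seed(seed, {
    ## random composition of n_genes into n_pieces parts, each >= min_genes
    extra <- n_genes - n_pieces * min_genes
    add <- if (n_pieces == 1L) extra else {
      cuts <- sort(sample.int(extra + n_pieces - 1L, n_pieces - 1L))
      diff(c(0L, cuts, extra + n_pieces)) - 1L
    }
    sizes <- min_genes + add
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    records <- vector("list", n_pieces)
    labels <- vector("list", n_pieces)
    for (p in seq_len(n_pieces)) {
      keep <- starts[p]:ends[p]
      genes <- record$genes[keep, , drop = FALSE]
      pid <- sprintf("%s_p%02d", record$bgc_id, p)
      genes$gene_id <- sprintf("%s_g%02d", pid, seq_along(keep))
      records[[p]] <- bgc_record(pid, source = "metagenome", origin_id = origin_id,
                                 product_classes = record$product_classes,
                                 genes = genes)
      labels[[p]] <- data.table(bgc_id = pid, parent_id = record$bgc_id,
                                gene_from = starts[p], gene_to = ends[p])
    }
    list(records = records, labels = rbindlist(labels))
  })
}

#' Back-translate a protein into a nucleotide coding sequence
#'
#' Deterministic single-codon table (one canonical codon per amino acid,
#' `X` encoded as `NNN`), with a terminal stop codon. Used to plant known
#' proteins in synthetic assemblies for translated-search tests.
#'
#' @param protein Amino-acid sequence.
#' @return Nucleotide sequence of length `3 * (nchar(protein) + 1)`.
#' @export
back_translate <- function(protein) {
  codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
             H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
             P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
             W = "TGG", Y = "TAT", X = "NNN")
  aa <- strsplit(toupper(protein), "")[[1L]]
  bad <- setdiff(unique(aa), names(codon))
  if (length(bad)) stop("cannot back-translate residue(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  paste0(paste(codon[aa], collapse = ""), "TAA")
}
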