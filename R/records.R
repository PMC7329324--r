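## Domain record classes. Plain lists with light S3 classes: sequences are
## stored as named uppercase character vectors so that downstream string
## arithmetic (fragmenting, k-mer seeding, windowing) stays cheap; Biostrings
## objects are created at I/O and alignment boundaries only.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.check_dna <- function(seqs, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    stop(sprintf(
      "%s %s contains characters outside {A,C,G,T,N}; ambiguity codes other than N are not supported",
      what, names(seqs)[bad][1L] %||% which(bad)[1L]
    ), call. = FALSE)
  }
  invisible(seqs)
}

.check_protein <- function(seqs, what = "protein") {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    stop(sprintf("%s contains non-amino-acid characters (allowed: 20-letter alphabet plus X)",
                 what), call. = FALSE)
  }
  invisible(seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a genome record
#'
#' A named set of nucleotide contigs representing one genome (an isolate
#' genome or any other reference sequence set).
#'
#' @param id Genome identifier.
#' @param contigs Named character vector of contig sequences over
#'   `{A,C,G,T,N}`; names are contig ids and must be unique.
#' @return An object of class `genome_record` with fields `id`, `contigs`
#'   and `total_length` (sum of contig lengths in bp).
#' @examples
#' g <- genome_record("toy", c(c1 = "ACGTACGT", c2 = "GGGTTT"))
#' g$total_length
#' @export
genome_record <- function(id, contigs) {
  stopifnot(is.character(id), length(id) == 1L, is.character(contigs),
            length(contigs) >= 1L)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)) ||
      any(!nzchar(names(contigs)))) {
    stop("contigs must be uniquely named", call. = FALSE)
  }
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L)) stop("contig sequences must be non-empty", call. = FALSE)
  .check_dna(contigs, "contig")
  structure(
    list(id = id, contigs = contigs, total_length = sum(nchar(contigs))),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %s bp\n",
              x$id, length(x$contigs), format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Construct a metagenome contig bin
#'
#' A cluster of metagenome contigs putatively representing a single
#' organism's genome, tied to the specimen it was assembled from.
#'
#' @param bin_id Bin identifier (unique within a specimen).
#' @param specimen_id Specimen the bin was assembled from.
#' @param contigs Named character vector of contig sequences.
#' @param coding_density Fraction of the bin covered by predicted genes, in
#'   `[0, 1]`, or `NA` when unknown.
#' @param gene_taxa Optional character vector of per-gene taxonomy labels,
#'   each one of `"bacterial"`, `"non-bacterial"`, `"unassigned"` (from an
#'   external per-gene taxonomy oracle).
#' @param provenance Optional data.frame recording, per contig, the source
#'   it was drawn from (filled by [make_bin()]).
#' @return An object of class `contig_bin`.
#' @export
contig_bin <- function(bin_id, specimen_id, contigs, coding_density = NA_real_,
                       gene_taxa = NULL, provenance = NULL) {
  stopifnot(is.character(bin_id), length(bin_id) == 1L,
            is.character(specimen_id), length(specimen_id) == 1L)
  g <- genome_record(bin_id, contigs)  # reuse contig validation
  if (!is.na(coding_density) &&
      (coding_density < 0 || coding_density > 1)) {
    stop("coding_density must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(gene_taxa)) {
    bad <- setdiff(unique(gene_taxa), c("bacterial", "non-bacterial", "unassigned"))
    if (length(bad)) {
      stop("gene_taxa labels must be bacterial / non-bacterial / unassigned; got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(bin_id = bin_id, specimen_id = specimen_id, contigs = g$contigs,
         total_length = g$total_length, coding_density = coding_density,
         gene_taxa = gene_taxa, provenance = provenance),
    class = "contig_bin"
  )
}

#' @export
print.contig_bin <- function(x, ...) {
  cat(sprintf("<contig_bin> %s (specimen %s): %d contig(s), %s bp, coding density %s\n",
              x$bin_id, x$specimen_id, length(x$contigs),
              format(x$total_length, big.mark = ","),
              ifelse(is.na(x$coding_density), "unknown",
                     sprintf("%.2f", x$coding_density))))
  invisible(x)
}

#' Construct a biosynthetic gene cluster record
#'
#' An ordered list of genes (protein translations) with product-class
#' labels, as produced by a cluster predictor or by [make_bgc_family()].
#' Gene order follows genomic coordinates and is preserved as given.
#'
#' @param bgc_id Cluster identifier.
#' @param source Either `"isolate"` or `"metagenome"`.
#' @param origin_id Strain (isolate) or specimen (metagenome) of origin.
#' @param product_classes Character vector of product-class labels; stored
#'   lower-cased (e.g. `"t1pks"`, `"nrps"`, `"terpene"`).
#' @param genes data.frame with columns `gene_id`, `protein`, `is_core`
#'   (proteins over the 20-letter amino-acid alphabet plus X).
#' @param span_bp Nucleotide span of the cluster in bp.
#' @param contig_id,start,end Optional genomic locus of the cluster; used to
#'   deduplicate occurrence evidence landing on the same locus.
#' @return An object of class `bgc_record`.
#' @export
bgc_record <- function(bgc_id, source = c("isolate", "metagenome"), origin_id,
                       product_classes, genes, span_bp = NA_integer_,
                       contig_id = NA_character_, start = NA_integer_,
                       end = NA_integer_) {
  source <- match.arg(source)
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "protein", "is_core") %in% names(genes)))
  if (nrow(genes) < 1L) stop("a BGC must contain at least one gene", call. = FALSE)
  genes <- data.frame(gene_id = as.character(genes$gene_id),
                      protein = toupper(as.character(genes$protein)),
                      is_core = as.logical(genes$is_core),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique within a BGC", call. = FALSE)
  .check_protein(genes$protein, sprintf("BGC %s gene protein", bgc_id))
  if (is.na(span_bp)) span_bp <- as.integer(sum(nchar(genes$protein)) * 3L)
  structure(
    list(bgc_id = bgc_id, source = source, origin_id = origin_id,
         product_classes = tolower(product_classes), genes = genes,
         span_bp = as.integer(span_bp), contig_id = contig_id,
         start = as.integer(start), end = as.integer(end)),
    class = "bgc_record"
  )
}

#' @export
print.bgc_record <- function(x, ...) {
  cat(sprintf("<bgc_record> %s [%s/%s]: %d gene(s), classes: %s, span %s bp\n",
              x$bgc_id, x$source, x$origin_id, nrow(x$genes),
              paste(x$product_classes, collapse = "+"),
              format(x$span_bp, big.mark = ",")))
  invisible(x)
}

## contig accessor shared by genome_record / contig_bin
.contigs_of <- function(x) {
  if (inherits(x, "genome_record") || inherits(x, "contig_bin")) return(x$contigs)
  if (is.character(x) && !is.null(names(x))) return(toupper(x))
  stop("expected a genome_record, contig_bin, or named character vector", call. = FALSE)
}

.id_of <- function(x) {
  if (inherits(x, "genome_record")) return(x$id)
  if (inherits(x, "contig_bin")) return(x$bin_id)
  "query"
}
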