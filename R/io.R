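## On-disk formats: FASTA via Biostrings; BGC interchange JSON via jsonlite;
## a best-effort reader for annotated (antiSMASH-style) GenBank; TSV metadata.

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  ## keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param protein Write as amino-acid sequences (default nucleotide).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, protein = FALSE) {
  set <- if (protein) Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a genome FASTA as a genome record
#'
#' @param path FASTA path.
#' @param id Genome id; defaults to the file name without extension.
#' @return A [genome_record()].
#' @export
read_genome_fasta <- function(path, id = NULL) {
  id <- id %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  genome_record(id, read_fasta(path))
}

#' Write a genome record or contig bin to FASTA
#'
#' @param x A `genome_record` or `contig_bin`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(x, path) {
  write_fasta(.contigs_of(x), path)
}

#' Read a specimen/bin metadata table
#'
#' Expects a TSV with at least `specimen_id` and `species` columns; a
#' `bin_id` column is kept when present.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_specimen_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("specimen_id", "species")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  md
}

# ---------------------------------------------------------------------------
# assembly statistics

#' Assembly statistics (contig count, total size, N50)
#'
#' N50 is the largest contig length `L` such that contigs of length `>= L`
#' together cover at least half of the assembly.
#'
#' @param record A `genome_record`, `contig_bin`, or named character vector
#'   of contigs.
#' @return List of class `assembly_stats` with `n_contigs`, `total_bp`, `n50`.
#' @examples
#' compute_assembly_stats(genome_record("g", c(a = strrep("A", 80),
#'                                             b = strrep("C", 70),
#'                                             c = strrep("G", 50))))
#' @export
compute_assembly_stats <- function(record) {
  lens <- nchar(.contigs_of(record))
  if (length(lens) == 0L) stop("record has no contigs", call. = FALSE)
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  n50 <- unname(lens[which(cumsum(lens) >= total / 2)[1L]])
  structure(list(n_contigs = length(lens), total_bp = total, n50 = n50),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("<assembly_stats> %d contig(s), %s bp, N50 = %s bp\n",
              x$n_contigs, format(x$total_bp, big.mark = ","),
              format(x$n50, big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# BGC interchange JSON — the canonical cluster carrier

#' Write BGC records to the interchange JSON format
#'
#' The interchange file is the canonical on-disk carrier for clusters:
#' a JSON object with a `clusters` array, each cluster holding `bgc_id`,
#' `source`, `origin_id`, `product_classes`, `span_bp`, optional locus
#' fields, and an ordered `genes` array of `{gene_id, protein, is_core}`.
#'
#' @param records List of [bgc_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bgc_json <- function(records, path) {
  clusters <- lapply(records, function(r) {
    cl <- list(
      bgc_id = r$bgc_id, source = r$source, origin_id = r$origin_id,
      product_classes = as.list(r$product_classes), span_bp = r$span_bp,
      genes = lapply(seq_len(nrow(r$genes)), function(i) {
        list(gene_id = r$genes$gene_id[i], protein = r$genes$protein[i],
             is_core = r$genes$is_core[i])
      })
    )
    if (!is.na(r$contig_id)) {
      cl$contig_id <- r$contig_id
      cl$start <- r$start
      cl$end <- r$end
    }
    cl
  })
  json <- jsonlite::toJSON(
    list(format = "bgc-interchange", version = 1L, clusters = clusters),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  writeLines(json, path)
  invisible(path)
}

#' Parse a BGC interchange file
#'
#' Reads the interchange JSON written by [write_bgc_json()] (or an
#' antiSMASH-style annotated GenBank file via [read_bgc_genbank()] when
#' `path` ends in `.gb`/`.gbk`). Product classes are lower-cased.
#'
#' @param path Path to an interchange JSON or annotated GenBank file.
#' @param ... Passed on to [read_bgc_genbank()] for GenBank input.
#' @return List of [bgc_record()] objects (empty, with a warning, for a
#'   file containing no clusters).
#' @export
parse_bgc_interchange <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE)) {
    return(read_bgc_genbank(path, ...))
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed interchange JSON in ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  clusters <- doc$clusters %||% list()
  if (length(clusters) == 0L) {
    warning("no clusters in ", path, call. = FALSE)
    return(list())
  }
  lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    cl_id <- cl$bgc_id %||% sprintf("cluster %d", i)
    genes <- cl$genes %||% list()
    if (length(genes) == 0L) {
      stop(sprintf("cluster %s has no genes (CDS features)", cl_id), call. = FALSE)
    }
    gtab <- tryCatch(
      data.frame(
        gene_id = vapply(genes, function(g) as.character(g$gene_id), character(1)),
        protein = vapply(genes, function(g) as.character(g$protein), character(1)),
        is_core = vapply(genes, function(g) isTRUE(g$is_core), logical(1)),
        stringsAsFactors = FALSE
      ),
      error = function(e) stop(sprintf("malformed gene entry in cluster %s", cl_id),
                               call. = FALSE)
    )
    bgc_record(
      bgc_id = cl_id, source = cl$source %||% "isolate",
      origin_id = cl$origin_id %||% NA_character_,
      product_classes = unlist(cl$product_classes) %||% character(0),
      genes = gtab, span_bp = cl$span_bp %||% NA_integer_,
      contig_id = cl$contig_id %||% NA_character_,
      start = cl$start %||% NA_integer_, end = cl$end %||% NA_integer_
    )
  })
}

#' Best-effort reader for antiSMASH-style annotated GenBank
#'
#' Extracts one cluster per GenBank record that carries a `cluster` or
#' `region` feature: the product-class labels come from the feature's
#' `/product` qualifiers, genes from `CDS` features with `/translation`,
#' ordered by their genomic start coordinate. This adapter is intentionally
#' minimal — the interchange JSON is the canonical carrier.
#'
#' @param path GenBank file path (may contain multiple LOCUS records).
#' @param source,origin_id Source labels attached to every parsed record.
#' @param min_contig_bp Records whose sequence length (from the LOCUS line)
#'   is below this floor are skipped. Default 500 bp.
#' @return List of [bgc_record()] objects.
#' @export
read_bgc_genbank <- function(path, source = "isolate", origin_id = NA_character_,
                             min_contig_bp = 500L) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("no LOCUS records in ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (ri in seq_along(starts)) {
    rec <- lines[starts[ri]:ends[ri]]
    locus <- strsplit(trimws(rec[1L]), "\\s+")[[1L]]
    locus_id <- locus[2L]
    locus_len <- suppressWarnings(as.integer(locus[3L]))
    if (!is.na(locus_len) && locus_len < min_contig_bp) next
    ## feature table slice
    ft_start <- grep("^FEATURES", rec)[1L]
    if (is.na(ft_start)) next
    ft_end <- grep("^(ORIGIN|//)", rec)
    ft_end <- if (length(ft_end)) min(ft_end[ft_end > ft_start]) - 1L else length(rec)
    ft <- rec[(ft_start + 1L):ft_end]
    ## split into features: a feature starts at column 6 with a key
    is_key <- grepl("^ {4,5}\\S", ft)
    if (!any(is_key)) next
    idx <- cumsum(is_key)
    feats <- split(ft, idx)
    keys <- vapply(feats, function(f) strsplit(trimws(f[1L]), "\\s+")[[1L]][1L],
                   character(1))
    get_qual <- function(f, q) {
      txt <- paste(trimws(f), collapse = " ")
      m <- regmatches(txt, gregexpr(sprintf('/%s="([^"]*)"', q), txt))[[1L]]
      sub(sprintf('/%s="', q), "", sub('"$', "", m))
    }
    cl_i <- which(keys %in% c("cluster", "region", "protocluster"))
    if (length(cl_i) == 0L) next
    classes <- unique(tolower(unlist(lapply(feats[cl_i], function(f) {
      c(get_qual(f, "product"), get_qual(f, "category"))
    }))))
    cds_i <- which(keys == "CDS")
    if (length(cds_i) == 0L) {
      stop(sprintf("cluster %s has no CDS features", locus_id), call. = FALSE)
    }
    cds <- lapply(feats[cds_i], function(f) {
      loc <- trimws(sub("^CDS", "", trimws(f[1L])))
      coords <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
      tr <- get_qual(f, "translation")
      tr <- if (length(tr)) gsub("\\s", "", tr[1L]) else NA_character_
      gid <- get_qual(f, "locus_tag")
      list(start = if (length(coords)) min(coords) else NA_integer_,
           end = if (length(coords)) max(coords) else NA_integer_,
           translation = tr, gene_id = if (length(gid)) gid[1L] else NA_character_)
    })
    cds <- Filter(function(x) !is.na(x$translation), cds)
    if (length(cds) == 0L) {
      stop(sprintf("cluster %s has no translated CDS features", locus_id), call. = FALSE)
    }
    ord <- order(vapply(cds, `[[`, integer(1), "start"))
    cds <- cds[ord]
    genes <- data.frame(
      gene_id = vapply(seq_along(cds), function(i) {
        cds[[i]]$gene_id %||% NA_character_
      }, character(1)),
      protein = vapply(cds, `[[`, character(1), "translation"),
      is_core = FALSE, stringsAsFactors = FALSE
    )
    genes$gene_id[is.na(genes$gene_id)] <-
      sprintf("%s_cds%02d", locus_id, which(is.na(genes$gene_id)))
    span <- max(vapply(cds, `[[`, integer(1), "end")) -
      min(vapply(cds, `[[`, integer(1), "start")) + 1L
    out[[length(out) + 1L]] <- bgc_record(
      bgc_id = locus_id, source = source, origin_id = origin_id,
      product_classes = classes[nzchar(classes)], genes = genes, span_bp = span,
      contig_id = locus_id,
      start = min(vapply(cds, `[[`, integer(1), "start")),
      end = max(vapply(cds, `[[`, integer(1), "end"))
    )
  }
  if (length(out) == 0L) warning("no clusters parsed from ", path, call. = FALSE)
  out
}
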