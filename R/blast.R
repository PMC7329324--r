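## Thin wrappers around NCBI BLAST+ (blastp / tblastn / makeblastdb), which
## must be on the PATH. All-vs-all protein comparison and translated
## searches go through a single batched call per analysis; runs are
## single-threaded so that outputs are deterministic.

.blast_fields <- c("qseqid", "sseqid", "pident", "length", "qlen", "slen",
                   "qstart", "qend", "sstart", "send", "bitscore", "sframe")

.require_blast <- function(tool) {
  if (!nzchar(Sys.which(tool))) {
    stop(sprintf("NCBI BLAST+ tool '%s' not found on PATH", tool), call. = FALSE)
  }
}

.run_blast <- function(tool, query_seqs, db_seqs, db_type, evalue = 1e-3,
                       extra_args = character()) {
  .require_blast(tool)
  .require_blast("makeblastdb")
  tmp <- tempfile("blastwork")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  qf <- file.path(tmp, "query.fa")
  dbf <- file.path(tmp, "db.fa")
  outf <- file.path(tmp, "hits.tsv")
  write_fasta(query_seqs, qf, protein = (tool != "blastn"))
  write_fasta(db_seqs, dbf, protein = (db_type == "prot"))
  st <- system2("makeblastdb",
                c("-in", dbf, "-dbtype", db_type,
                  "-logfile", file.path(tmp, "mkdb.log")),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed", call. = FALSE)
  st <- system2(tool,
                c("-query", qf, "-db", dbf, "-out", outf,
                  "-outfmt", shQuote(paste("6", paste(.blast_fields, collapse = " "))),
                  "-evalue", format(evalue, scientific = TRUE),
                  "-num_threads", "1", "-max_target_seqs", "5000",
                  extra_args),
                stdout = FALSE, stderr = file.path(tmp, "err.log"))
  if (st != 0L) {
    stop(tool, " failed: ", paste(readLines(file.path(tmp, "err.log"), warn = FALSE),
                                  collapse = " "), call. = FALSE)
  }
  if (file.size(outf) == 0L) {
    return(data.table(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(), qlen = integer(),
                      slen = integer(), qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(), bitscore = numeric(),
                      sframe = integer()))
  }
  hits <- fread(outf, header = FALSE, col.names = .blast_fields, sep = "\t")
  hits[, qcov := 100 * (qend - qstart + 1L) / qlen]
  hits[, scov := 100 * (abs(send - sstart) + 1L) / slen]
  hits
}

## flatten a list of bgc_records into a protein table with unique ids
.bgc_protein_table <- function(records, prefix = "b") {
  rbindlist(lapply(seq_along(records), function(i) {
    r <- records[[i]]
    .check_protein(r$genes$protein, sprintf("BGC %s protein", r$bgc_id))
    data.table(protein_uid = sprintf("%s%04d_g%03d", prefix, i, seq_len(nrow(r$genes))),
               bgc_id = r$bgc_id, gene_id = r$genes$gene_id,
               gene_idx = seq_len(nrow(r$genes)), n_genes = nrow(r$genes),
               is_core = r$genes$is_core, protein = r$genes$protein)
  }))
}

## batched all-vs-all blastp between two protein tables, annotated with
## BGC ids and gene indices on both sides
.blastp_bgc <- function(query_tab, db_tab, evalue = 1e-3) {
  hits <- .run_blast("blastp",
                     stats::setNames(query_tab$protein, query_tab$protein_uid),
                     stats::setNames(db_tab$protein, db_tab$protein_uid),
                     db_type = "prot", evalue = evalue)
  if (nrow(hits) == 0L) {
    return(data.table(query_bgc = character(), query_gene = character(),
                      query_idx = integer(), n_query_genes = integer(),
                      subject_bgc = character(), subject_gene = character(),
                      subject_idx = integer(), pident = numeric(),
                      qcov = numeric(), scov = numeric(), bitscore = numeric()))
  }
  qmap <- query_tab[, .(qseqid = protein_uid, query_bgc = bgc_id,
                        query_gene = gene_id, query_idx = gene_idx,
                        n_query_genes = n_genes)]
  smap <- db_tab[, .(sseqid = protein_uid, subject_bgc = bgc_id,
                     subject_gene = gene_id, subject_idx = gene_idx)]
  hits <- qmap[hits, on = "qseqid"]
  hits <- smap[hits, on = "sseqid"]
  hits[, .(query_bgc, query_gene, query_idx, n_query_genes, subject_bgc,
           subject_gene, subject_idx, pident, qcov, scov, bitscore)]
}

.tier_filter <- function(hits, tier) {
  if (tier == "strict") {
    hits[pident >= 60 & qcov >= 80 & scov >= 80]
  } else {
    hits[pident >= 30 & qcov >= 25 & scov >= 25]
  }
}

## best subject hit per query gene within each (query_bgc, subject_bgc) pair
.best_per_query_gene <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  setorder(hits, query_bgc, subject_bgc, query_gene, -bitscore, subject_gene)
  hits[, head(.SD, 1L), by = .(query_bgc, subject_bgc, query_gene)]
}
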