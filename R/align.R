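## Internal nucleotide alignment machinery: exact k-mer seeding onto target
## diagonals followed by gapless extension. On substitution-only data a
## single diagonal is the exact alignment; a banded gapped fallback (via
## Biostrings) is used by the read mapper when the gapless pass fails.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## all k-mers of a set of sequences -> data.table(kmer, seq_id, pos)
.kmer_table <- function(seqs, k) {
  parts <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    L <- nchar(s)
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    data.table(kmer = substring(s, pos, pos + k - 1L), seq_id = nm, pos = pos)
  })
  out <- rbindlist(parts)
  if (nrow(out)) out <- out[!grepl("N", kmer, fixed = TRUE)]
  out
}

## seed queries (named character) against a prebuilt target k-mer table;
## returns per (query, target, diagonal) seed counts
.seed_diagonals <- function(queries, target_index, k) {
  qk <- .kmer_table(queries, k)
  if (nrow(qk) == 0L || nrow(target_index) == 0L) {
    return(data.table(query_id = character(), seq_id = character(),
                      diag_off = integer(), n_seed = integer()))
  }
  setnames(qk, c("seq_id", "pos"), c("query_id", "qpos"))
  hits <- target_index[qk, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) == 0L) {
    return(data.table(query_id = character(), seq_id = character(),
                      diag_off = integer(), n_seed = integer()))
  }
  hits[, diag_off := pos - qpos]
  hits[, .(n_seed = .N), by = .(query_id, seq_id, diag_off)]
}

## gapless comparison of query vs target along one diagonal
## diag_off d: query position i pairs with target position i + d
.gapless_eval <- function(qseq, tseq, d, qlen = nchar(qseq), tlen = nchar(tseq)) {
  q_from <- max(1L, 1L - d)
  q_to <- min(qlen, tlen - d)
  if (q_to < q_from) {
    return(list(overlap = 0L, mismatches = NA_integer_, q_from = NA_integer_))
  }
  a <- substr(qseq, q_from, q_to)
  b <- substr(tseq, q_from + d, q_to + d)
  list(overlap = q_to - q_from + 1L,
       mismatches = sum(charToRaw(a) != charToRaw(b)),
       q_from = q_from)
}

## best gapless placement of each query on the indexed target set.
## queries: named character; target_index from .kmer_table(targets, k);
## targets: named character. Both strands are tried when strands = TRUE.
## Returns data.table(query_id, seq_id, strand, diag_off, overlap, mismatches)
## with one row per (query, target): the placement maximising matched bases.
.best_placements <- function(queries, targets, target_index, k,
                             strands = TRUE, top_diags = 3L) {
  qset <- list(`+` = queries)
  if (strands) qset$`-` <- stats::setNames(.revcomp(queries), names(queries))
  rows <- list()
  for (st in names(qset)) {
    cand <- .seed_diagonals(qset[[st]], target_index, k)
    if (nrow(cand) == 0L) next
    setorder(cand, query_id, seq_id, -n_seed, diag_off)
    cand <- cand[, head(.SD, top_diags), by = .(query_id, seq_id)]
    cand[, strand := st]
    rows[[st]] <- cand
  }
  cand <- rbindlist(rows)
  if (nrow(cand) == 0L) {
    return(data.table(query_id = character(), seq_id = character(),
                      strand = character(), diag_off = integer(),
                      overlap = integer(), mismatches = integer()))
  }
  ev <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    qs <- qset[[cand$strand[i]]][[cand$query_id[i]]]
    ts <- targets[[cand$seq_id[i]]]
    ev[[i]] <- .gapless_eval(qs, ts, cand$diag_off[i])
  }
  cand[, overlap := vapply(ev, `[[`, integer(1), "overlap")]
  cand[, mismatches := vapply(ev, function(e) {
    if (is.na(e$mismatches)) NA_integer_ else as.integer(e$mismatches)
  }, integer(1))]
  cand <- cand[overlap > 0L]
  if (nrow(cand) == 0L) {
    return(data.table(query_id = character(), seq_id = character(),
                      strand = character(), diag_off = integer(),
                      overlap = integer(), mismatches = integer()))
  }
  ## best per (query, target): most matched bases, then deterministic order
  cand[, best := overlap - mismatches]
  setorder(cand, query_id, seq_id, -best, mismatches, strand, diag_off)
  cand <- cand[, head(.SD, 1L), by = .(query_id, seq_id)]
  cand[, c("n_seed", "best") := NULL]
  cand[]
}

## longest non-decreasing subsequence length (synteny over subject ranks)
.lis_length <- function(x) {
  n <- length(x)
  if (n <= 1L) return(n)
  best <- integer(n)
  for (i in seq_len(n)) {
    prev <- best[seq_len(i - 1L)]
    ok <- which(x[seq_len(i - 1L)] <= x[i])
    best[i] <- 1L + if (length(ok)) max(prev[ok]) else 0L
  }
  max(best)
}
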