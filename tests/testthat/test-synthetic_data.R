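test_that("mutate_genome plants exactly the requested substitutions", {
  g <- fix_parent
  id0 <- mutate_genome(g, 0, seed = 1)
  expect_identical(id0$genome$contigs, g$contigs)
  expect_equal(nrow(id0$log$substitutions), 0)

  m <- fix_child5
  expect_equal(nrow(m$log$substitutions), round(0.05 * g$total_length))
  expect_equal(m$log$realized_divergence, 0.05)

  # position-by-position oracle: realized mismatches equal the log size
  mism <- sum(vapply(names(g$contigs), function(cn) {
    sum(charToRaw(g$contigs[[cn]]) != charToRaw(m$genome$contigs[[cn]]))
  }, numeric(1)))
  expect_equal(mism, nrow(m$log$substitutions))
  # and the log replays onto the parent
  sub <- m$log$substitutions
  for (i in seq_len(min(50, nrow(sub)))) {
    expect_equal(substr(g$contigs[[sub$contig_id[i]]], sub$position[i], sub$position[i]),
                 sub$from_base[i])
    expect_equal(substr(m$genome$contigs[[sub$contig_id[i]]], sub$position[i], sub$position[i]),
                 sub$to_base[i])
  }
  expect_error(mutate_genome(g, 0.6), "divergence")
})

test_that("make_bin draws fragments proportionally with full provenance", {
  a <- random_genome("srcA", 40000, seed = 11)
  b <- random_genome("srcB", 40000, seed = 12)
  single <- make_bin(list(a), 1, n_fragments = 10, seed = 13)
  expect_true(all(single$provenance$source_id == "srcA"))
  # every contig is the recorded subsequence of its source
  for (i in seq_len(10)) {
    p <- single$provenance[i, ]
    expect_identical(unname(single$contigs[[p$contig_id]]),
                     substr(a$contigs[[p$src_contig]], p$start, p$end))
  }

  n <- 1000
  mix <- make_bin(list(a, b), c(0.7, 0.3), n_fragments = n,
                  mean_fragment_bp = 3000, sd_fragment_bp = 600, seed = 14)
  nA <- sum(mix$provenance$source_id == "srcA")
  expect_lt(abs(nA - 0.7 * n), 3 * sqrt(n * 0.7 * 0.3))
  mean_len <- mean(nchar(mix$contigs))
  expect_lt(abs(mean_len - 3000) / 3000, 0.10)

  expect_error(make_bin(list(a), 1, n_fragments = 1,
                        fragment_sampler = function(n) rep(50000L, n)),
               "exceeds")
})

test_that("simulate_reads reproduces sources, weights and error rates", {
  a <- random_genome("gA", 20000, seed = 21)
  b <- random_genome("gB", 20000, seed = 22)

  clean <- simulate_reads(list(a), 1, n_reads = 50, read_length = 80, seed = 23)
  for (i in seq_len(50)) {
    r <- clean$reads[[i]]
    fwd <- grepl(r, a$contigs[[clean$truth$contig_id[i]]], fixed = TRUE)
    rev <- grepl(r, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(a$contigs[[clean$truth$contig_id[i]]]))), fixed = TRUE)
    expect_true(fwd || rev)
  }

  n <- 6000
  rs <- simulate_reads(list(a, b), c(0.6, 0.4), n_reads = n, read_length = 100,
                       error_rate = 0.01, seed = 24)
  nA <- sum(rs$truth$source_id == "gA")
  expect_lt(abs(nA - 0.6 * n), 3 * sqrt(n * 0.6 * 0.4))
  # mean substitutions per read ~ read_length * error_rate
  expect_lt(abs(mean(rs$truth$n_errors) - 1.0) / 1.0, 0.10)
  expect_error(simulate_reads(list(a), 1, n_reads = 0), "n_reads")
  expect_error(simulate_reads(list(a), 1, n_reads = 5, error_rate = 0.5), "error_rate")
})

test_that("marker mixtures hit their planted site frequencies", {
  marker <- random_genome("gyrB", 1800, seed = 31)$contigs[[1]]
  snp2 <- data.frame(pos = c(210, 730, 1240, 1610), base = c("A", "C", "G", "T"))
  # force SNPs to actually change the reference base
  for (i in seq_len(nrow(snp2))) {
    if (substr(marker, snp2$pos[i], snp2$pos[i]) == snp2$base[i]) {
      snp2$base[i] <- setdiff(c("A", "C", "G", "T"), snp2$base[i])[1]
    }
  }
  n <- 2000
  mix <- make_marker_mixture(marker, list(s1 = NULL, s2 = snp2), c(0.7, 0.3),
                             n_reads = n, read_length = 100, seed = 32)
  expect_equal(unname(mix$proportions), c(0.7, 0.3))
  n2 <- sum(mix$truth$strain == "s2")
  expect_lt(abs(n2 - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
  # per-site variant reads among reads covering the site
  for (p in snp2$pos) {
    cov <- mix$truth[mix$truth$start <= p - 0 & mix$truth$start + 100 - 1 >= p, ]
    alt <- sum(cov$strain == "s2")
    expect_lt(abs(alt - 0.3 * nrow(cov)), 3 * sqrt(nrow(cov) * 0.3 * 0.7) + 1)
  }
  # contradictory SNP definitions rejected
  expect_error(make_marker_mixture(marker,
                                   list(s1 = data.frame(pos = c(10, 10), base = c("A", "C"))),
                                   1, n_reads = 10, seed = 1),
               "contradictory")
})

test_that("BGC family variants respect truncation and divergence bounds", {
  proto <- random_bgc("proto", n_genes = 10, seed = 41)
  ident <- make_bgc_family(proto, 3, max_truncation = 0, max_protein_divergence = 0,
                           seed = 42)
  for (r in ident$records) expect_equal(r$genes$protein, proto$genes$protein)

  fam <- make_bgc_family(proto, 8, max_truncation = 0.35,
                         max_protein_divergence = 0.1, seed = 43)
  for (v in seq_len(8)) {
    rec <- fam$records[[v]]
    lab <- fam$labels[v, ]
    n_kept <- 10 - floor(lab$truncation_fraction * 10)
    expect_equal(nrow(rec$genes), n_kept)
    # kept genes are a contiguous prefix or suffix of the prototype order
    expect_equal(lab$kept_to - lab$kept_from + 1L, n_kept)
    expect_true(lab$kept_from == 1L || lab$kept_to == 10L)
    # pairwise alignment oracle: per-protein identity >= 1 - divergence bound
    for (j in seq_len(n_kept)) {
      orig <- proto$genes$protein[lab$kept_from + j - 1L]
      pid <- Biostrings::pid(Biostrings::pairwiseAlignment(
        Biostrings::AAString(rec$genes$protein[j]), Biostrings::AAString(orig),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 4)) / 100
      expect_gte(pid, 1 - lab$protein_divergence - 1e-9)
      expect_gte(pid, 0.9 - 1e-9)
    }
  }
})

test_that("generators are byte-identical given the same seed", {
  g1 <- random_genome("d", 8000, n_contigs = 2, seed = 99)
  g2 <- random_genome("d", 8000, n_contigs = 2, seed = 99)
  expect_identical(g1, g2)
  expect_identical(mutate_genome(g1, 0.03, seed = 7), mutate_genome(g2, 0.03, seed = 7))
  b1 <- make_bin(list(g1), 1, n_fragments = 20, mean_fragment_bp = 1000,
                 sd_fragment_bp = 200, seed = 8)
  b2 <- make_bin(list(g2), 1, n_fragments = 20, mean_fragment_bp = 1000,
                 sd_fragment_bp = 200, seed = 8)
  expect_identical(b1$contigs, b2$contigs)
  r1 <- simulate_reads(list(g1), 1, 200, read_length = 90, error_rate = 0.01, seed = 9)
  r2 <- simulate_reads(list(g2), 1, 200, read_length = 90, error_rate = 0.01, seed = 9)
  expect_identical(r1$reads, r2$reads)
  f1 <- make_bgc_family(random_bgc("p", seed = 1), 3, seed = 10)
  f2 <- make_bgc_family(random_bgc("p", seed = 1), 3, seed = 10)
  expect_identical(lapply(f1$records, `[[`, "genes"),
                   lapply(f2$records, `[[`, "genes"))
})
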