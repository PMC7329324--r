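test_that("gANI is exact on identity, strand flips, and planted divergence", {
  g <- fix_parent
  self <- compute_ani(g, g)
  expect_equal(self$gani, 1.0)
  expect_gte(self$af, 0.99)

  rc <- genome_record("rc", stats::setNames(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(g$contigs))), names(g$contigs)))
  flipped <- compute_ani(rc, g)
  expect_equal(flipped$gani, 1.0)
  expect_gte(flipped$af, 0.99)

  r <- compute_ani(fix_child5$genome, g)
  expect_lt(abs(r$gani - 0.95), 0.01)
  expect_gte(r$af, 0.95)

  # MutationLog oracle: per-fragment mismatch counts give the exact gANI
  sub <- fix_child5$log$substitutions
  frag_of <- 1L + (sub$position - 1L) %/% 1000L
  n_frag <- ceiling(nchar(g$contigs[[1]]) / 1000)
  per_frag <- tabulate(frag_of, nbins = n_frag)
  flens <- c(rep(1000L, n_frag - 1L),
             nchar(g$contigs[[1]]) - 1000L * (n_frag - 1L))
  expected_gani <- sum((flens - per_frag)) / sum(flens)
  expect_equal(r$gani, expected_gani, tolerance = 1e-12)
})

test_that("gANI is symmetric and strictly decreasing in planted divergence", {
  g <- fix_parent
  ganis <- vapply(c(0, 0.02, 0.05, 0.10), function(d) {
    child <- if (d == 0) g else mutate_genome(g, d, seed = 300 + round(1000 * d))$genome
    fwd <- compute_ani(child, g)
    bwd <- compute_ani(g, child)
    expect_lt(abs(fwd$gani - bwd$gani), 0.01)
    expect_lt(abs(fwd$gani - (1 - d)), 0.01)
    fwd$gani
  }, numeric(1))
  expect_true(all(diff(ganis) < 0))
})

test_that("bin assignment applies strict cutoffs and deterministic tie-breaks", {
  mk <- function(ref, gani, af) {
    data.frame(query_id = "bin1", reference_id = ref, gani = gani, af = af,
               aligned_bp = 1L, query_bp = 1L)
  }
  expect_equal(assign_bin(mk("r1", 0.92, 0.6))$assigned_reference, "r1")
  # boundary values read as strict inequalities
  expect_equal(assign_bin(mk("r1", 0.90, 0.6))$assigned_reference, "UNASSIGNED")
  expect_equal(assign_bin(mk("r1", 0.92, 0.5))$assigned_reference, "UNASSIGNED")
  two <- rbind(mk("rA", 0.97, 0.6), mk("rB", 0.93, 0.9))
  expect_equal(assign_bin(two)$assigned_reference, "rA")
  tie <- rbind(mk("rB", 0.95, 0.7), mk("rA", 0.95, 0.7))
  expect_equal(assign_bin(tie)$assigned_reference, "rA")
  tie_af <- rbind(mk("rB", 0.95, 0.8), mk("rA", 0.95, 0.7))
  expect_equal(assign_bin(tie_af)$assigned_reference, "rB")
  expect_warning(out <- assign_bin(data.frame()), "UNASSIGNED")
  expect_equal(out$assigned_reference, "UNASSIGNED")
})

test_that("bins assign to their parent at 2% divergence, never at 12%", {
  parent <- random_genome("refP", 40000, seed = 310)
  other <- random_genome("refQ", 40000, seed = 311)
  near <- mutate_genome(parent, 0.02, seed = 312)$genome
  far <- mutate_genome(parent, 0.12, seed = 313)$genome
  for (s in 1:3) {
    bin_near <- make_bin(list(near), 1, n_fragments = 8, bin_id = paste0("bn", s),
                         seed = 320 + s)
    res <- list(compute_ani(bin_near, parent), compute_ani(bin_near, other))
    expect_equal(assign_bin(res)$assigned_reference, "refP")
    bin_far <- make_bin(list(far), 1, n_fragments = 8, bin_id = paste0("bf", s),
                        seed = 330 + s)
    res <- list(compute_ani(bin_far, parent), compute_ani(bin_far, other))
    expect_equal(assign_bin(res)$assigned_reference, "UNASSIGNED")
  }
})

test_that("aggregate gANI is the length-weighted mean and order-invariant", {
  one <- data.frame(gani = 0.97, query_bp = 12345)
  expect_equal(aggregate_gani(one)$weighted_gani, 0.97)
  two <- data.frame(gani = c(0.95, 0.99), query_bp = c(100e3, 300e3))
  expect_equal(aggregate_gani(two)$weighted_gani, 0.98)
  expect_equal(aggregate_gani(two)$total_bin_bp, 400e3)

  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(2:14, 1)
      tab <- data.frame(gani = runif(n, 0.85, 1), query_bp = sample.int(5e5, n))
      agg <- aggregate_gani(tab)
      expect_equal(agg$weighted_gani,
                   sum(tab$gani * tab$query_bp) / sum(tab$query_bp),
                   tolerance = 1e-12)
      perm <- tab[sample(n), ]
      expect_equal(aggregate_gani(perm)$weighted_gani, agg$weighted_gani,
                   tolerance = 1e-15)
      expect_gte(agg$weighted_gani, min(tab$gani))
      expect_lte(agg$weighted_gani, max(tab$gani))
    }
  })
  expect_error(aggregate_gani(data.frame(gani = NA_real_, query_bp = 100)),
               "zero total length")
})

test_that("conspecificity threshold sits at 0.95", {
  expect_true(call_conspecific(0.95))
  expect_false(call_conspecific(0.92))
  expect_true(call_conspecific(1.0))
  expect_error(call_conspecific(NA_real_), "defined")
})

test_that("bacterial-bin rule combines coding density and gene taxonomy", {
  mk <- function(density, n_bact, n_other, n_unassigned = 0) {
    contig_bin("b", "s", c(c1 = "ACGT"), coding_density = density,
               gene_taxa = c(rep("bacterial", n_bact),
                             rep("non-bacterial", n_other),
                             rep("unassigned", n_unassigned)))
  }
  expect_true(classify_bacterial_bin(mk(0.7, 80, 20)))
  expect_false(classify_bacterial_bin(mk(0.7, 59, 41)))
  expect_true(classify_bacterial_bin(mk(0.7, 60, 40)))
  expect_false(classify_bacterial_bin(mk(0.4, 100, 0)))
  expect_false(classify_bacterial_bin(mk(0.5, 100, 0)))  # strict >
  # unassigned genes excluded from the default denominator
  expect_true(classify_bacterial_bin(mk(0.7, 30, 10, 60)))
  expect_false(classify_bacterial_bin(mk(0.7, 30, 10, 60), denominator = "all"))
  expect_error(classify_bacterial_bin(contig_bin("b", "s", c(c1 = "ACGT"))),
               "coding_density")
  expect_error(
    classify_bacterial_bin(contig_bin("b", "s", c(c1 = "ACGT"),
                                      coding_density = 0.8)),
    "gene_taxa")
})
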