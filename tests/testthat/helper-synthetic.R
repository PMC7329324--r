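# Shared synthetic fixtures, built once per test run.

# small genome pair at known divergence for ANI tests
fix_parent <- random_genome("parent", 30000, seed = 101)
fix_child5 <- mutate_genome(fix_parent, 0.05, seed = 102)

# a compact planted-family scene for network tests
make_family_scene <- function(n_families = 3, n_variants = 3, n_singletons = 3,
                              max_truncation = 0.3, max_divergence = 0.1,
                              n_genes = 8, seed = 500) {
  protos <- lapply(seq_len(n_families), function(i) {
    random_bgc(sprintf("fam%d", i), n_genes = n_genes, seed = seed + i)
  })
  fams <- lapply(seq_len(n_families), function(i) {
    make_bgc_family(protos[[i]], n_variants, max_truncation = max_truncation,
                    max_protein_divergence = max_divergence,
                    seed = seed + 100 + i)
  })
  singles <- lapply(seq_len(n_singletons), function(i) {
    random_bgc(sprintf("lone%d", i), n_genes = 6, seed = seed + 200 + i)
  })
  records <- c(unlist(lapply(fams, `[[`, "records"), recursive = FALSE), singles)
  labels <- data.table::rbindlist(lapply(fams, `[[`, "labels"))
  truth <- c(stats::setNames(labels$family_id, labels$bgc_id),
             stats::setNames(vapply(singles, `[[`, character(1), "bgc_id"),
                             vapply(singles, `[[`, character(1), "bgc_id")))
  list(records = records, protos = protos, labels = labels, truth = truth)
}

# adjusted Rand index between two labelings (named vectors over same ids)
ari <- function(truth, pred) {
  ids <- names(truth)
  mclust::adjustedRandIndex(truth[ids], pred[ids])
}

# mutate a protein to an exact divergence (deterministic given seed)
mutate_protein_at <- function(prot, divergence, seed = 1) {
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "")
  withr::with_seed(seed, {
    L <- nchar(prot)
    pos <- sample.int(L, round(divergence * L))
    for (p in pos) {
      substr(prot, p, p) <- sample(setdiff(aa, substr(prot, p, p)), 1)
    }
    prot
  })
}
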