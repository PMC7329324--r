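test_that("core proteins come from flags, else from the strict consensus", {
  proto <- random_bgc("pr", n_genes = 6, n_core = 2, seed = 701)
  single <- extract_core_proteins(list(proto))
  expect_length(single, 2)
  expect_setequal(names(single), proto$genes$gene_id[proto$genes$is_core])

  # unflagged members: consensus = proteins strict-shared by >= half
  fam <- make_bgc_family(proto, 3, max_truncation = 0.3,
                         max_protein_divergence = 0.05, seed = 702)
  members <- lapply(fam$records, function(r) {
    r$genes$is_core <- FALSE
    r
  })
  cons <- extract_core_proteins(members)
  ng <- vapply(members, function(r) nrow(r$genes), integer(1))
  spans <- vapply(members, function(r) as.double(r$span_bp), double(1))
  ids <- vapply(members, `[[`, character(1), "bgc_id")
  donor <- members[[order(-ng, -spans, ids)[1]]]
  expect_true(all(names(cons) %in% donor$genes$gene_id))
  expect_gte(length(cons), 1)

  # planted family: extracted set comes from prototype gene content
  flagged <- extract_core_proteins(c(list(proto), fam$records))
  expect_setequal(unname(flagged),
                  proto$genes$protein[proto$genes$is_core])

  lone <- random_bgc("alone", n_genes = 4, n_core = 0, seed = 703)
  lone$genes$is_core <- FALSE
  expect_error(extract_core_proteins(list(lone)), "core")
})

test_that("translated search honours identity and coverage gates", {
  proto <- random_bgc("ts", n_genes = 5, seed = 711)
  core <- extract_core_proteins(list(proto))
  pad <- function(s) paste0(strrep("ACGT", 200), s, strrep("TGCA", 200))
  planted <- c(ctg1 = pad(back_translate(core[[1]])))
  hit <- translated_search(core, planted)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$query_coverage_pct, 100)

  # 15% protein divergence falls under the >90% identity gate
  far <- mutate_protein_at(core[[1]], 0.15, seed = 712)
  expect_equal(nrow(translated_search(core[1], c(ctg = pad(back_translate(far))))), 0L)
  # 5% divergence passes
  near <- mutate_protein_at(core[[1]], 0.05, seed = 713)
  expect_equal(nrow(translated_search(core[1], c(ctg = pad(back_translate(near))))), 1L)

  # a coding region split so only ~45% lies on the contig fails coverage
  cds <- back_translate(core[[1]])
  partial <- substr(cds, 1, floor(nchar(cds) * 0.45))
  expect_equal(nrow(translated_search(core[1], c(ctg = pad(partial)))), 0L)
})

test_that("occurrence counts combine membership and search evidence per locus", {
  proto <- random_bgc("gA", n_genes = 8, seed = 721)
  fam <- make_bgc_family(proto, 3, max_truncation = 0.2,
                         max_protein_divergence = 0.05,
                         origin_ids = c("s1", "s2", "s2"), seed = 722)
  net <- gcf_network(c(list(proto), fam$records))
  md <- data.frame(specimen_id = c("s1", "s2", "s3"),
                   species = c("spX", "spX", "spY"))
  om <- build_occurrence_matrix(net, NULL, md)
  gcf_id <- net$membership[bgc_id == "gA_v01", gcf]
  expect_equal(unname(om$counts[gcf_id, ]), c(1L, 2L, 0L))   # two subtype loci in s2
  expect_equal(unname(om$per_specimen[gcf_id, "spX"]), 1.5)
  expect_equal(unname(om$per_specimen[gcf_id, "spY"]), 0)

  # search-only evidence adds a locus in s3; evidence on a member locus is
  # deduplicated
  hits <- data.frame(gcf = gcf_id, specimen_id = "s3", contig_id = "ctgZ",
                     sstart = c(1000, 2500), send = c(1900, 3200))
  om2 <- build_occurrence_matrix(net, hits, md)
  expect_equal(unname(om2$counts[gcf_id, "s3"]), 1L)  # clustered into one locus
  expect_equal(unname(om2$per_specimen[gcf_id, "spY"]), 1)

  expect_error(
    build_occurrence_matrix(net, data.frame(gcf = gcf_id, specimen_id = "sX",
                                            contig_id = "c", sstart = 1, send = 2),
                            md),
    "missing from metadata")
})

test_that("fragment collapse merges complementary pieces only", {
  refs <- lapply(1:4, function(i) random_bgc(sprintf("rf%d", i), n_genes = 9,
                                             seed = 730 + i))
  pieces <- unlist(lapply(1:4, function(i) {
    fragment_bgc(refs[[i]], n_pieces = 2 + i %% 2, origin_id = "sp1",
                 seed = 740 + i)$records
  }), recursive = FALSE)
  cr <- collapse_fragments(pieces, refs)
  expect_equal(cr$n_matched_metag, length(pieces))
  expect_equal(cr$n_unique_after_collapse, 4L)
  expect_equal(cr$n_matched_reference_bgcs, 4L)
  expect_equal(estimate_total_unique(length(pieces), cr), 4)

  # unfragmented inputs collapse to themselves
  whole <- lapply(1:3, function(i) {
    r <- fragment_bgc(refs[[i]], 1, origin_id = "sp1", seed = 750 + i)$records[[1]]
    r
  })
  cw <- collapse_fragments(whole, refs)
  expect_equal(cw$n_unique_after_collapse, 3L)
  expect_equal(cw$inflation_factor, 1)

  # two full-length copies at distinct loci stay distinct (ranges overlap)
  twin <- fragment_bgc(refs[[1]], 1, origin_id = "sp1", seed = 760)$records[[1]]
  twin2 <- twin
  twin2$bgc_id <- "twin2"
  twin2$genes$gene_id <- paste0("t2", twin2$genes$gene_id)
  c2 <- collapse_fragments(list(twin, twin2), refs[1])
  expect_equal(c2$n_unique_after_collapse, 2L)

  # empty reference set: everything unique, inflation undefined
  ce <- collapse_fragments(pieces[1:3], list())
  expect_equal(ce$n_unique_after_collapse, 3L)
  expect_true(is.na(ce$inflation_factor))
  expect_message(est <- estimate_total_unique(10, ce), "undefined")
  expect_true(is.na(est))
})

test_that("collapse never merges across references or specimens", {
  refs <- lapply(1:2, function(i) random_bgc(sprintf("cr%d", i), n_genes = 8,
                                             seed = 770 + i))
  pa <- fragment_bgc(refs[[1]], 2, origin_id = "spA", seed = 772)$records
  pb <- lapply(fragment_bgc(refs[[1]], 2, origin_id = "spB", seed = 773)$records,
               function(r) { r$bgc_id <- paste0("B", r$bgc_id); r })
  qc <- fragment_bgc(refs[[2]], 2, origin_id = "spA", seed = 774)$records
  cr <- collapse_fragments(c(pa, pb, qc), refs)
  # one cluster per (specimen, reference): spA/cr1, spB/cr1, spA/cr2
  expect_equal(cr$n_unique_after_collapse, 3L)
  asn <- cr$assignments
  expect_equal(length(unique(asn$cluster)), 3L)
  expect_true(all(asn[specimen_id == "spA" & reference_bgc == "cr1", cluster] !=
                    asn[specimen_id == "spB" & reference_bgc == "cr1", cluster]))
})

test_that("the inflation estimate reproduces the headline arithmetic", {
  # 305 matched metagenome BGCs collapsing to 148 unique references
  fake <- structure(list(n_metagenome_bgcs = 305L, n_matched_metag = 305L,
                         n_matched_reference_bgcs = 148L,
                         n_unique_after_collapse = 148L,
                         n_matched_unique = 148L,
                         inflation_factor = 305 / 148, assignments = NULL),
                    class = "collapse_result")
  expect_equal(estimate_total_unique(401, fake), 401 / (305 / 148),
               tolerance = 1e-12)
  expect_lt(abs(estimate_total_unique(401, fake) - 194.6), 0.1)
})
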