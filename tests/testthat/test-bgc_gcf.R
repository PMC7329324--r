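test_that("class filtering keeps the well-characterized families and hybrids", {
  mk <- function(id, classes) {
    bgc_record(id, "isolate", "st", classes,
               data.frame(gene_id = "g1", protein = "MKLV", is_core = FALSE))
  }
  recs <- list(mk("a", "t1pks"), mk("b", "bacteriocin"),
               mk("c", c("nrps", "t1pks")), mk("d", "terpene"),
               mk("e", "homoserine lactone"), mk("f", "lassopeptide"),
               mk("g", "thiopeptide"), mk("h", "siderophore"))
  kept <- filter_bgc_classes(recs)
  expect_equal(vapply(kept, `[[`, character(1), "bgc_id"),
               c("a", "c", "d", "e", "g", "h"))
  expect_length(filter_bgc_classes(list()), 0)
})

test_that("gene hits report best hits per query under both tiers", {
  a <- random_bgc("idA", n_genes = 5, seed = 601)
  self <- gene_hits(a, a, tier = "strict")
  expect_equal(nrow(self), 5L)
  expect_true(all(self$identity_pct == 100))
  expect_equal(self$query_gene_id, self$subject_gene_id)

  # a ~50%-identical counterpart: loose hit, not strict
  b <- a
  b$bgc_id <- "idB"
  b$genes$protein[2] <- mutate_protein_at(a$genes$protein[2], 0.5, seed = 602)
  b$genes$gene_id <- paste0("B", b$genes$gene_id)
  loose <- gene_hits(a, b, tier = "loose")
  strict <- gene_hits(a, b, tier = "strict")
  expect_true("idA_g02" %in% loose$query_gene_id)
  expect_false("idA_g02" %in% strict$query_gene_id)
  expect_equal(nrow(strict), 4L)

  # family variant at 10% divergence, no truncation: all genes strict
  fam <- make_bgc_family(a, 1, max_truncation = 0, max_protein_divergence = 0.1,
                         seed = 603)
  strict_v <- gene_hits(fam$records[[1]], a, tier = "strict")
  expect_equal(nrow(strict_v), 5L)

  bad <- a
  bad$genes$protein[1] <- "MK*LV"
  expect_error(gene_hits(bad, a), "amino-acid")
})

test_that("directional hits score shared genes weighted by synteny", {
  x <- random_bgc("x8", n_genes = 8, seed = 611)
  h <- directional_hit(x, x)
  expect_equal(h$shared_genes, 8L)
  expect_equal(h$synteny_weight, 1.0)
  expect_equal(h$score, 16)

  # 4-gene query with only 2 homologs in the subject: below min_shared
  y <- random_bgc("y4", n_genes = 4, seed = 612)
  y$genes$protein[1:2] <- x$genes$protein[1:2]
  expect_null(directional_hit(y, x, min_shared = 3))
  expect_false(is.null(directional_hit(y, x, min_shared = 2)))

  # truncated variant hits its prototype with all its genes
  half <- make_bgc_family(x, 1, max_truncation = 0.5, max_protein_divergence = 0,
                          seed = 613)
  v <- half$records[[1]]
  hv <- directional_hit(v, x)
  expect_equal(hv$shared_genes, nrow(v$genes))
  expect_equal(hv$synteny_weight, 1.0)
})

test_that("the single-directional retention rule follows n - 2 with a floor", {
  expect_true(gcf_refine_rule(5, 3))
  expect_false(gcf_refine_rule(5, 2))
  expect_true(gcf_refine_rule(3, 1))
  expect_false(gcf_refine_rule(2, 0))   # floor: n <= 2 still needs 1 strict hit
  expect_true(gcf_refine_rule(2, 1))
  expect_true(gcf_refine_rule(1, 1))
  expect_false(gcf_refine_rule(10, 7))
  expect_true(gcf_refine_rule(10, 8))
})

test_that("planted families are recovered as exact components", {
  scene <- make_family_scene(n_families = 3, n_variants = 3, n_singletons = 3,
                             seed = 620)
  net <- gcf_network(scene$records)
  pred <- stats::setNames(net$membership$gcf, net$membership$bgc_id)
  expect_equal(ari(scene$truth, pred), 1.0)
  # no edges between different planted families
  el <- igraph::as_edgelist(net$graph)
  fam_of <- scene$truth
  expect_true(all(fam_of[el[, 1]] == fam_of[el[, 2]]))
  # GCF numbering: descending component size, lexicographic tie-break
  sizes <- table(net$membership$gcf)
  ord <- order(as.integer(sub("GCF_", "", names(sizes))))
  expect_true(!is.unsorted(rev(as.integer(sizes[ord]))))
})

test_that("edge sets are invariant under input order", {
  scene <- make_family_scene(n_families = 2, n_variants = 3, n_singletons = 2,
                             seed = 630)
  net1 <- gcf_network(scene$records)
  net2 <- gcf_network(rev(scene$records))
  canon <- function(net) {
    el <- igraph::as_edgelist(net$graph)
    sorted <- t(apply(el, 1, sort))
    sorted[order(sorted[, 1], sorted[, 2]), , drop = FALSE]
  }
  expect_equal(canon(net1), canon(net2))
  m1 <- net1$membership[order(bgc_id)]
  m2 <- net2$membership[order(bgc_id)]
  expect_equal(m1$gcf, m2$gcf)
})

test_that("network exports write GraphML, SIF and membership tables", {
  scene <- make_family_scene(n_families = 2, n_variants = 3, n_singletons = 1,
                             seed = 640)
  net <- gcf_network(scene$records)
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_gcf_graphml(net, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), length(scene$records))
  expect_setequal(igraph::V(g2)$gcf, net$membership$gcf)
  write_gcf_sif(net, sif)
  expect_equal(length(readLines(sif)),
               igraph::ecount(net$graph) +
                 sum(igraph::degree(net$graph) == 0))
  write_gcf_membership(net, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), length(scene$records))
})
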