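test_that("gc_content forced values and N handling", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ANGC"), 2 / 3)
  expect_error(gc_content(""), class = "lancmine_domain_error")
  expect_error(gc_content("NNNN"), class = "lancmine_domain_error")
  expect_error(gc_content("AXGT"))
})

test_that("gc_content identities hold on fuzzed sequences", {
  set.seed(61)
  for (i in 1:50) {
    s <- random_dna(sample(10:500, 1L))
    gc <- gc_content(s)
    at <- 1 - gc
    counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
    expect_equal(gc + (counts[["A"]] + counts[["T"]]) / nchar(s), 1)
    expect_equal(gc_content(revcomp(s)), gc)
    expect_gte(gc, 0); expect_lte(gc, 1)
  }
})

test_that("annotate_genes hits the planted domain gene only, cutoff enforced", {
  bgc <- fx_bgc_call()
  hs <- fx_hmms()
  ## the class II dehydratase-domain model should hit exactly the planted
  ## class2 gene of the cluster
  ann <- annotate_genes(bgc, list(hs$config$class2), e_cutoff = 1e-5)
  n_hit <- vapply(ann$per_gene, nrow, integer(1))
  expect_equal(sum(n_hit > 0L), 1L)
  hit_gene <- names(which(n_hit > 0L))
  prods <- vapply(bgc$neighborhood$genes, `[[`, character(1), "product")
  ids <- vapply(bgc$neighborhood$genes, function(g)
    lancmine:::gene_pid(bgc$neighborhood$record_id, g), character(1))
  expect_match(prods[ids == hit_gene], "dehydratase")
  expect_true(all(unlist(lapply(ann$per_gene, function(h) h$evalue)) <= 1e-5))

  ## empty model list
  ann0 <- annotate_genes(bgc, list())
  expect_true(all(vapply(ann0$per_gene, nrow, integer(1)) == 0L))

  ## a cutoff far below every fixture E-value excludes everything
  ann_tight <- annotate_genes(bgc, list(hs$config$class2), e_cutoff = 1e-300)
  expect_true(all(vapply(ann_tight$per_gene, nrow, integer(1)) == 0L))
})

fake_annotation <- function(bgc_id, gene_hits) {
  per_gene <- lapply(gene_hits, function(doms)
    data.frame(protein_id = rep("x", length(doms)), hmm_name = doms,
               evalue = rep(1e-10, length(doms)),
               bitscore = rep(50, length(doms)), stringsAsFactors = FALSE))
  structure(list(bgc_id = bgc_id, per_gene = per_gene, e_cutoff = 1e-5),
            class = "tailoring_annotation")
}

fake_call <- function(bgc_id, lan_class) {
  structure(list(bgc_id = bgc_id, lan_class = lan_class),
            class = "bgc_call")
}

test_that("census counts BGCs, not genes, with per-class columns", {
  anns <- list(
    fake_annotation("b1", list(g1 = "protease", g2 = "protease")),
    fake_annotation("b2", list(g1 = c("protease", "transporter"))),
    fake_annotation("b3", list(g1 = character(0))))
  calls <- list(fake_call("b1", "I"), fake_call("b2", "II"),
                fake_call("b3", "I"))
  tab <- census(anns, calls)
  expect_equal(tab$domain, c("protease", "transporter"))
  expect_equal(tab$n_bgcs, c(2L, 1L))          # b1 counted once despite 2 genes
  expect_equal(tab$n_I, c(1L, 0L))
  expect_equal(tab$n_II, c(1L, 1L))
  expect_true(all(tab$n_I + tab$n_II == tab$n_bgcs))
  expect_true(all(tab$n_bgcs <= length(calls)))

  ## permutation invariance
  tab2 <- census(anns[c(3, 1, 2)], calls[c(2, 3, 1)])
  expect_equal(tab2, tab)
  ## empty input
  expect_equal(nrow(census(list(), list())), 0L)
})

test_that("summarize_mining tallies classes, phyla, GG fraction, histogram", {
  g <- fx_genome()
  gb <- tempfile(fileext = ".gbk")
  write_genbank(g$record, gb)
  report <- run_mine(gb, fx_pipeline_config(), verbose = FALSE)

  expect_equal(unname(report$class_counts[c("I", "II", "III")]),
               rep(1L, 3L), ignore_attr = TRUE)
  expect_equal(report$n_precursors, 3L)
  ## all records share the fixture lineage; phylum = 2nd lineage element
  expect_equal(names(report$phylum_counts), "Synthetica")
  expect_equal(unname(report$phylum_counts[[1]]), 3L)
  ## every planted leader ends in GG
  expect_equal(report$gg_fraction, 1.0)
  ## one precursor per BGC
  expect_equal(names(report$precursors_per_bgc), "1")
  expect_equal(unname(report$precursors_per_bgc[[1]]), 3L)
  ## GC pairs cover every BGC with sane values
  expect_equal(nrow(report$gc_pairs), 3L)
  expect_true(all(report$gc_pairs$bgc_gc > 0.2 & report$gc_pairs$bgc_gc < 0.8))
  expect_true(all(abs(report$gc_pairs$genome_gc - 0.5) < 0.1))
  ## class counts equal the multiset of call labels
  expect_equal(unname(report$class_counts),
               unname(table(factor(vapply(report$bgc_calls, `[[`,
                                          character(1), "lan_class"),
                                   levels = names(report$class_counts)))),
               ignore_attr = TRUE)
})
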