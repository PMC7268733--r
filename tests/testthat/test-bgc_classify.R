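# Class assignment is pure given a hits table, so the truth table is
# exercised with fabricated hits against the fixture model names.

toy_neighborhood <- function() {
  dna <- strrep("ACGT", 3000L)
  genes <- lapply(0:3, function(i)
    gene_feature(sprintf("L%d", i + 1L), 4000L + i * 400L,
                 4000L + i * 400L + 300L, 1L,
                 protein_id = sprintf("P%d", i + 1L)))
  rec <- genome_record("TREC", dna, genes)
  extract_neighborhood(rec, 2L)          # anchor = P2
}

hit_row <- function(pid, hmm, e) {
  data.frame(protein_id = pid, hmm_name = hmm$name, evalue = e,
             bitscore = 50, stringsAsFactors = FALSE)
}

test_that("assign_class matches the 16-row hit-pattern truth table", {
  cfgc <- fx_hmms()$config
  nb <- toy_neighborhood()
  for (dehN in c(FALSE, TRUE)) for (dehC in c(FALSE, TRUE))
    for (duf in c(FALSE, TRUE)) for (kin in c(FALSE, TRUE)) {
      hits <- hit_row("P2", cfgc$anchor, 1e-30)   # anchor model on anchor
      if (dehN) hits <- rbind(hits, hit_row("P1", cfgc$class1_n, 1e-20))
      if (dehC) hits <- rbind(hits, hit_row("P3", cfgc$class1_c, 1e-18))
      if (duf) hits <- rbind(hits, hit_row("P4", cfgc$class2, 1e-25))
      if (kin) hits <- rbind(hits, hit_row("P2", cfgc$kinase, 1e-15),
                             hit_row("P2", cfgc$class3, 1e-40),
                             hit_row("P2", cfgc$class4, 1e-12))
      call <- assign_class(nb, hits, cfgc)
      expected <- if (dehN && dehC) "I"
        else if (duf) "II"
        else if (kin) "III"
        else "unclassified"
      n_fired <- sum(dehN && dehC, duf, kin)
      expect_equal(call$lan_class, expected,
                   info = sprintf("N=%d C=%d D=%d K=%d", dehN, dehC, duf, kin))
      expect_equal(call$multi_class_flag, n_fired > 1L)
    }
})

test_that("class III/IV E-value comparison and tie rule", {
  cfgc <- fx_hmms()$config
  nb <- toy_neighborhood()
  base <- rbind(hit_row("P2", cfgc$anchor, 1e-30),
                hit_row("P2", cfgc$kinase, 1e-15))
  expect_equal(assign_class(nb, rbind(base,
    hit_row("P2", cfgc$class3, 1e-40),
    hit_row("P2", cfgc$class4, 1e-12)), cfgc)$lan_class, "III")
  expect_equal(assign_class(nb, rbind(base,
    hit_row("P2", cfgc$class3, 1e-12),
    hit_row("P2", cfgc$class4, 1e-40)), cfgc)$lan_class, "IV")
  ## exact tie -> III (documented deterministic tie-break)
  expect_equal(assign_class(nb, rbind(base,
    hit_row("P2", cfgc$class3, 1e-20),
    hit_row("P2", cfgc$class4, 1e-20)), cfgc)$lan_class, "III")
  ## kinase-positive anchor but no subfamily hit at all -> III
  expect_equal(assign_class(nb, base, cfgc)$lan_class, "III")
})

test_that("dehydratase roles may sit on one or two polypeptides", {
  cfgc <- fx_hmms()$config
  nb <- toy_neighborhood()
  split_lanb <- rbind(hit_row("P2", cfgc$anchor, 1e-30),
                      hit_row("P1", cfgc$class1_n, 1e-20),
                      hit_row("P4", cfgc$class1_c, 1e-21))
  expect_equal(assign_class(nb, split_lanb, cfgc)$lan_class, "I")
  fused <- rbind(hit_row("P2", cfgc$anchor, 1e-30),
                 hit_row("P1", cfgc$class1_n, 1e-20),
                 hit_row("P1", cfgc$class1_c, 1e-21))
  expect_equal(assign_class(nb, fused, cfgc)$lan_class, "I")
})

test_that("gene order permutation never changes the class", {
  cfgc <- fx_hmms()$config
  nb <- toy_neighborhood()
  hits <- rbind(hit_row("P2", cfgc$anchor, 1e-30),
                hit_row("P1", cfgc$class1_n, 1e-20),
                hit_row("P3", cfgc$class1_c, 1e-18),
                hit_row("P4", cfgc$class2, 1e-25))
  base_call <- assign_class(nb, hits, cfgc)
  set.seed(6)
  for (i in 1:5) {
    nb2 <- nb
    nb2$genes <- nb$genes[sample(length(nb$genes))]
    call2 <- assign_class(nb2, hits[sample(nrow(hits)), ], cfgc)
    expect_equal(call2$lan_class, base_call$lan_class)
    expect_equal(call2$multi_class_flag, base_call$multi_class_flag)
  }
  expect_true(base_call$multi_class_flag)
})

test_that("anchor protein missing from hits is a pipeline error", {
  cfgc <- fx_hmms()$config
  nb <- toy_neighborhood()
  orphan <- hit_row("P1", cfgc$class1_n, 1e-20)
  expect_error(assign_class(nb, orphan, cfgc), "anchor protein")
})

test_that("find_lanc_proteins returns the planted anchor only, best hit kept", {
  hs <- fx_hmms()
  fam <- hs$families$anchor
  member <- lancmine:::with_seed(77L,
    lancmine:::mutate_protein(fam$consensus, fam$divergence))
  ## two anchor domains on one protein: still a single deduplicated hit
  double <- paste0(member, member)
  set.seed(13)
  prots <- c(one = member, twice = double, junk = random_peptide(150L))
  hits <- find_lanc_proteins(prots, hs$config)
  expect_setequal(hits$protein_id, c("one", "twice"))
  expect_equal(anyDuplicated(hits$protein_id), 0L)
  expect_equal(nrow(find_lanc_proteins(character(0), hs$config)), 0L)
})
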