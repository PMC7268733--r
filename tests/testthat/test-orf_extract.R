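test_that("enumerate_orfs handles hand-translatable cases", {
  o <- enumerate_orfs("ATGTGTTAA")
  expect_equal(nrow(o), 1L)
  expect_equal(o$aa_seq, "MC")
  expect_equal(o$strand, 1L)
  expect_equal(o$start, 0L)
  expect_equal(o$end, 9L)
  expect_equal(o$stop_pos, 6L)

  expect_equal(nrow(enumerate_orfs("CCCCCCCCCCCC")), 0L)

  ## offset shifts coordinates into record space
  o2 <- enumerate_orfs("ATGTGTTAA", span_offset = 100L)
  expect_equal(o2$start, 100L)
  expect_equal(o2$stop_pos, 106L)

  ## GTG initiator still yields Met
  o3 <- enumerate_orfs("GTGTGCTGTTAA")
  expect_equal(o3$aa_seq[o3$start == 0], "MCC")

  ## N never makes a start or stop, and translates to X
  oN <- enumerate_orfs("ATGNNNTGTTAA")
  expect_equal(oN$aa_seq[oN$strand == 1 & oN$start == 0], "MXC")
  expect_equal(nrow(enumerate_orfs("NTGTGTTAA")), 0L)
})

test_that("enumerate_orfs matches the brute-force scanner on random spans", {
  set.seed(101)
  for (i in 1:12) {
    dna <- random_dna(600L)
    mine <- enumerate_orfs(dna, span_offset = 17L)
    oracle <- oracle_orfs(dna, offset = 17L)
    expect_identical(orf_key(mine), orf_key(oracle), info = paste("span", i))
  }
})

test_that("reverse complement mirrors the ORF set", {
  set.seed(55)
  for (i in 1:6) {
    dna <- random_dna(500L)
    L <- nchar(dna)
    fwd <- enumerate_orfs(dna)
    rev <- enumerate_orfs(revcomp(dna))
    mirrored <- data.frame(start = L - rev$end, end = L - rev$start,
                           strand = -rev$strand, aa_seq = rev$aa_seq)
    expect_identical(
      sort(sprintf("%d:%d:%d:%s", fwd$start, fwd$end, fwd$strand, fwd$aa_seq)),
      sort(sprintf("%d:%d:%d:%s", mirrored$start, mirrored$end,
                   mirrored$strand, mirrored$aa_seq)))
  }
})

test_that("filter_orfs applies length, Cys, and nesting rules", {
  mk <- function(start, len_aa, aa_seq, strand = 1L) {
    data.frame(record_id = "r", start = start, end = start + 3L * (len_aa + 1L),
               strand = strand, start_codon = "ATG", aa_seq = aa_seq,
               stop_pos = start + 3L * len_aa,
               stop_key = paste0(strand, "@", start + 3L * len_aa),
               annotated = FALSE, stringsAsFactors = FALSE)
  }
  pep <- function(n) paste0("M", strrep("A", n - 2L), "C")
  orfs <- rbind(
    mk(0L, 29L, pep(29L)),                       # too short
    mk(200L, 30L, pep(30L)),                     # minimum length, kept
    mk(400L, 120L, pep(120L)),                   # maximum length, kept
    mk(1000L, 121L, pep(121L)),                  # too long
    mk(2000L, 60L, paste0("M", strrep("A", 59L))),  # no Cys
    mk(3000L, 40L, pep(40L)),                    # nested in gene below
    mk(5000L, 40L, pep(40L)))                    # exact gene span, kept
  genes <- list(gene_feature("host", 2900L, 3900L, 1L),
                gene_feature("coincident", 5000L, 5123L, 1L))
  kept <- filter_orfs(orfs, genes)
  expect_equal(kept$start, c(200L, 400L, 5000L))
  expect_equal(kept$annotated, c(FALSE, FALSE, TRUE))
  ## idempotence
  expect_equal(filter_orfs(kept, genes), kept)
  ## bounds are inclusive and counted with the initiator Met
  expect_true(all(nchar(kept$aa_seq) >= 30L & nchar(kept$aa_seq) <= 120L))
})

test_that("dedup_by_stop keeps the longest ORF per stop", {
  dna <- paste0("ATGAAA", "GTGAAA", "ATGTGT", "TAA")  # three starts, one stop
  orfs <- enumerate_orfs(dna)
  shared <- orfs[orfs$strand == 1L & orfs$stop_pos == 18L, ]
  expect_equal(nrow(shared), 3L)
  dd <- dedup_by_stop(orfs)
  surv <- dd[dd$strand == 1L & dd$stop_pos == 18L, ]
  expect_equal(nrow(surv), 1L)
  expect_equal(surv$start, 0L)
  expect_equal(nchar(surv$aa_seq), 6L)
  ## singleton input unchanged
  expect_equal(dedup_by_stop(surv), surv)
})

test_that("dedup agrees with a grouping oracle on random spans", {
  set.seed(202)
  for (i in 1:10) {
    dna <- random_dna(400L)
    orfs <- enumerate_orfs(dna)
    dd <- dedup_by_stop(orfs)
    expect_equal(anyDuplicated(dd$stop_key), 0L)
    ## oracle: group by stop key, keep max length
    by_stop <- split(seq_len(nrow(orfs)), orfs$stop_key)
    expected <- sort(vapply(by_stop, function(idx)
      idx[which.max(nchar(orfs$aa_seq[idx]))], integer(1)))
    expect_setequal(
      sprintf("%d:%d:%d", dd$start, dd$end, dd$strand),
      sprintf("%d:%d:%d", orfs$start[expected], orfs$end[expected],
              orfs$strand[expected]))
  }
})

test_that("survivors always satisfy the filter contract", {
  set.seed(77)
  genes <- list(gene_feature("g1", 100L, 400L, 1L))
  for (i in 1:5) {
    dna <- random_dna(1500L)
    surv <- dedup_by_stop(filter_orfs(enumerate_orfs(dna), genes))
    if (!nrow(surv)) next
    expect_true(all(nchar(surv$aa_seq) >= 30L))
    expect_true(all(nchar(surv$aa_seq) <= 120L))
    expect_true(all(grepl("C", surv$aa_seq)))
    expect_equal(anyDuplicated(surv$stop_key), 0L)
  }
})
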