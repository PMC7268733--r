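make_toy_genbank <- function(path) {
  writeLines(c(
    "LOCUS       TOY001 120 bp    DNA     linear   BCT 01-JAN-1970",
    "DEFINITION  toy record.",
    "SOURCE      Toyobacter exemplaris",
    "  ORGANISM  Toyobacter exemplaris",
    "            Bacteria; Toyophyta; Toyales.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             10..18",
    "                     /locus_tag=\"TOY_0001\"",
    "                     /protein_id=\"TP1\"",
    "                     /product=\"thing one\"",
    "                     /translation=\"MC\"",
    "     CDS             complement(21..29)",
    "                     /locus_tag=\"TOY_0002\"",
    "     CDS             31..45",
    "                     /locus_tag=\"TOY_0003\"",
    "     CDS             47..58",
    "                     /locus_tag=\"TOY_0004\"",
    "     CDS             61..78",
    "                     /locus_tag=\"TOY_0005\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), path)
  path
}

test_that("read_genbank parses records, coordinates, lineage", {
  gb <- make_toy_genbank(tempfile(fileext = ".gbk"))
  recs <- read_genbank(gb)
  expect_length(recs, 1L)
  rec <- recs[[1]]
  expect_equal(rec$record_id, "TOY001")
  expect_equal(rec$length_nt, 120L)
  expect_length(rec$genes, 5L)
  expect_equal(vapply(rec$genes, `[[`, integer(1), "start"),
               sort(vapply(rec$genes, `[[`, integer(1), "start")))
  ## GenBank "10..18" (1-based inclusive) -> internal 0-based half-open
  g1 <- rec$genes[[1]]
  expect_equal(g1$start, 9L)
  expect_equal(g1$end, 18L)
  expect_equal(g1$strand, 1L)
  expect_equal(g1$protein_id, "TP1")
  expect_equal(g1$protein_seq, "MC")
  expect_equal(rec$genes[[2]]$strand, -1L)
  expect_equal(rec$organism, "Toyobacter exemplaris")
  expect_equal(rec$lineage, c("Bacteria", "Toyophyta", "Toyales"))
  expect_false(rec$circular)
})

test_that("read_genbank handles missing files and CDS-free records", {
  expect_error(read_genbank(tempfile()), class = "lancmine_io_error")
  nocds <- tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       EMPTY1 30 bp    DNA     linear   BCT 01-JAN-1970",
               "FEATURES             Location/Qualifiers",
               "     source          1..30",
               "ORIGIN",
               "        1 acgtacgtac acgtacgtac acgtacgtac",
               "//"), nocds)
  expect_warning(recs <- read_genbank(nocds), "no parseable CDS")
  expect_length(recs[[1]]$genes, 0L)
  expect_equal(recs[[1]]$length_nt, 30L)
})

test_that("fixture genomes round-trip through GenBank write/read", {
  g <- fx_genome()
  gb <- tempfile(fileext = ".gbk")
  write_genbank(g$record, gb)
  back <- read_genbank(gb)[[1]]
  expect_equal(back$record_id, g$record$record_id)
  expect_equal(back$dna, g$record$dna)
  expect_equal(back$lineage, g$record$lineage)
  expect_equal(length(back$genes), length(g$record$genes))
  for (i in seq_along(back$genes)) {
    a <- back$genes[[i]]; b <- g$record$genes[[i]]
    expect_equal(a[c("locus_id", "protein_id", "start", "end", "strand",
                     "protein_seq")],
                 b[c("locus_id", "protein_id", "start", "end", "strand",
                     "protein_seq")])
  }
})

## a 30-gene record with 100-nt genes spaced 200 nt apart
make_grid_record <- function(n_genes = 30L, gene_len = 100L, gap = 100L,
                             lead = 5000L, circular = FALSE) {
  starts <- lead + (seq_len(n_genes) - 1L) * (gene_len + gap)
  dna <- strrep("ACGT", (max(starts) + gene_len + 5000L) / 4 + 1)
  genes <- lapply(seq_len(n_genes), function(i)
    gene_feature(sprintf("G%02d", i), starts[i], starts[i] + gene_len, 1L))
  genome_record("GRID", substr(dna, 1, max(starts) + gene_len + 5000L),
                genes, circular = circular)
}

test_that("extract_neighborhood windows and truncation", {
  rec <- make_grid_record()
  nb <- extract_neighborhood(rec, 10L)
  expect_equal(vapply(nb$genes, `[[`, character(1), "locus_id"),
               sprintf("G%02d", 3:17))
  expect_length(nb$genes, 15L)
  nb2 <- extract_neighborhood(rec, 2L)
  expect_equal(vapply(nb2$genes, `[[`, character(1), "locus_id"),
               sprintf("G%02d", 1:9))
  expect_error(extract_neighborhood(rec, 31L))
})

test_that("contig_edge flag follows the 3 kb rule and circularity", {
  rec <- make_grid_record(lead = 5000L)
  expect_false(extract_neighborhood(rec, 15L)$contig_edge)
  near <- make_grid_record(lead = 1200L)
  expect_true(extract_neighborhood(near, 1L)$contig_edge)
  ## an anchor deep inside a short-flank record: within window reach of
  ## the first gene, the span start drops under 3 kb
  expect_true(extract_neighborhood(near, 5L)$contig_edge)
  circ <- make_grid_record(lead = 1200L, circular = TRUE)
  expect_false(extract_neighborhood(circ, 1L)$contig_edge)
})

test_that("contig_edge is monotone under flank shrinking", {
  for (lead in c(6000L, 4000L, 2500L, 800L)) {
    rec <- make_grid_record(lead = lead)
    flags <- vapply(c(1L, 8L, 15L), function(i)
      extract_neighborhood(rec, i)$contig_edge, logical(1))
    if (lead >= 4000L + 0) expect_false(flags[3]) # central anchor, wide flank
  }
  ## direct monotonicity: trim the leading flank of one record
  rec <- make_grid_record(lead = 5000L)
  nb_before <- extract_neighborhood(rec, 3L)
  trimmed <- genome_record("GRID2", substr(rec$dna, 3001L, rec$length_nt),
                           lapply(rec$genes, function(g) {
                             g$start <- g$start - 3000L; g$end <- g$end - 3000L
                             gene_feature(g$locus_id, g$start, g$end, g$strand)
                           }))
  nb_after <- extract_neighborhood(trimmed, 3L)
  expect_true(!nb_before$contig_edge || nb_after$contig_edge)
  expect_true(nb_after$contig_edge >= nb_before$contig_edge)
})

test_that("neighborhood size bound holds on random anchors", {
  rec <- make_grid_record()
  set.seed(11)
  for (i in sample(seq_along(rec$genes), 10L)) {
    nb <- extract_neighborhood(rec, i)
    expect_lte(length(nb$genes), 15L)
    if (i > 7L && i <= length(rec$genes) - 7L) expect_length(nb$genes, 15L)
    expect_true(any(vapply(nb$genes, function(g)
      identical(g$locus_id, nb$anchor$locus_id), logical(1))))
  }
})

test_that("coordinate conversions GenBank -> internal -> GFF3 are lossless", {
  set.seed(23)
  for (rep in 1:50) {
    start1 <- sample(1:5000, 1L)              # GenBank 1-based inclusive
    len <- sample(seq(30L, 300L, 3L), 1L)
    end1 <- start1 + len - 1L
    internal_start <- start1 - 1L             # 0-based half-open
    internal_end <- end1
    expect_equal(internal_end - internal_start, len)
    expect_equal(internal_start + 1L, start1) # back out to GFF3/GenBank
    expect_equal(internal_end, end1)
  }
})

test_that("write_report emits stable TSV/GFF3/FASTA and round-trips", {
  g <- fx_genome()
  cfg <- fx_pipeline_config()
  gb <- tempfile(fileext = ".gbk")
  write_genbank(g$record, gb)
  report <- run_mine(gb, cfg, verbose = FALSE)

  out1 <- tempfile("rep1"); out2 <- tempfile("rep2")
  write_report(report, out1)
  write_report(report, out2)
  expect_identical(readLines(file.path(out1, "precursor_calls.tsv")),
                   readLines(file.path(out2, "precursor_calls.tsv")))

  tab <- read_report_tsv(file.path(out1, "precursor_calls.tsv"))
  expect_equal(nrow(tab), nrow(report$precursor_calls))
  expect_equal(as.integer(tab$orf_start), report$precursor_calls$start)
  expect_equal(tab$core_seq, report$precursor_calls$core)
  expect_equal(as.logical(tab$is_precursor), report$precursor_calls$is_precursor)

  gff <- readLines(file.path(out1, "precursor_orfs.gff3"))
  expect_equal(gff[1], "##gff-version 3")
  expect_equal(length(gff) - 1L, nrow(report$precursor_calls))
  f1 <- strsplit(gff[2], "\t")[[1]]
  expect_equal(as.integer(f1[4]), report$precursor_calls$start[1] + 1L)
  expect_equal(as.integer(f1[5]), report$precursor_calls$end[1])

  ## empty report
  empty <- summarize_mining(list(), lancmine:::empty_precursor_calls(), list())
  out3 <- tempfile("rep3")
  write_report(empty, out3)
  expect_length(readLines(file.path(out3, "precursor_calls.tsv")), 1L)
})
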