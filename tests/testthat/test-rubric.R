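toy_call <- function(rule = "GG", motif = "FxLD", core = "ISSTCSSTC") {
  pep <- paste0(strrep("N", 12L), core)
  structure(list(peptide = pep, boundary = 12L,
                 leader = strrep("N", 12L), core = core,
                 rule_used = rule, motif_name = motif),
            class = "boundary_call")
}

test_that("rubric sums fired rules and SVM points", {
  empty <- score_rubric(list(), svm_points = 10L, threshold = 10L)
  expect_equal(apply_rubric(toy_call(), svm_decision = FALSE,
                            rubric = empty)$total_score, 0L)
  expect_equal(apply_rubric(toy_call(), svm_decision = TRUE,
                            rubric = empty)$total_score, 10L)

  ## default rubric, hand-audited per predicate: motif (+3), GG boundary
  ## (+2), core STC fraction 7/9 >= 0.2 (+2); no BGC context (+0)
  r <- default_rubric()
  sc <- apply_rubric(toy_call(), svm_decision = FALSE, rubric = r)
  expect_equal(sc$points, 7L)
  expect_equal(sc$total_score, 7L)
  sc2 <- apply_rubric(toy_call(), svm_decision = TRUE, rubric = r)
  expect_equal(sc2$total_score, 17L)

  ## remove the motif and the GG rule: only the STC fraction fires
  sc3 <- apply_rubric(toy_call(rule = "fallback-half", motif = NA_character_),
                      svm_decision = FALSE, rubric = r)
  expect_equal(sc3$points, 2L)

  ## STC-poor core (1 C in 9 residues = 0.11 < 0.2): nothing fires
  sc4 <- apply_rubric(toy_call(rule = "fallback-half", motif = NA_character_,
                               core = "INNNNNNNC"),
                      svm_decision = FALSE, rubric = r)
  expect_equal(sc4$points, 0L)
})

test_that("core_stc_fraction threshold is honored exactly", {
  r <- score_rubric(list(list(name = "core_stc_fraction",
                              params = list(min_fraction = 0.2),
                              points = 2L)), svm_points = 0L, threshold = 1L)
  at <- apply_rubric(toy_call(core = "CNNNN"), svm_decision = FALSE, rubric = r)
  expect_equal(at$points, 2L)            # 1/5 = 0.2 fires (>=)
  below <- apply_rubric(toy_call(core = "CNNNNN"), svm_decision = FALSE,
                        rubric = r)
  expect_equal(below$points, 0L)         # 1/6 < 0.2
})

test_that("adjacent_codirectional consults the BGC context", {
  bgc <- fx_bgc_call()
  anchor <- bgc$neighborhood$anchor
  near_orf <- list(start = anchor$end + 100L, end = anchor$end + 250L,
                   strand = anchor$strand)
  far_orf <- list(start = anchor$end + 5000L, end = anchor$end + 5150L,
                  strand = anchor$strand)
  wrong_strand <- list(start = anchor$end + 100L, end = anchor$end + 250L,
                       strand = -anchor$strand)
  r <- score_rubric(list(list(name = "adjacent_codirectional",
                              params = list(max_gap_nt = 1000), points = 2L)),
                    svm_points = 0L, threshold = 1L)
  expect_equal(apply_rubric(toy_call(), list(orf = near_orf, bgc = bgc),
                            FALSE, r)$points, 2L)
  expect_equal(apply_rubric(toy_call(), list(orf = far_orf, bgc = bgc),
                            FALSE, r)$points, 0L)
  expect_equal(apply_rubric(toy_call(), list(orf = wrong_strand, bgc = bgc),
                            FALSE, r)$points, 0L)
})

test_that("adding a fired positive rule never decreases the total", {
  base <- score_rubric(list(list(name = "gg_ga_boundary", points = 2L)),
                       svm_points = 5L, threshold = 5L)
  more <- score_rubric(list(list(name = "gg_ga_boundary", points = 2L),
                            list(name = "motif_present", points = 3L)),
                       svm_points = 5L, threshold = 5L)
  for (svm in c(TRUE, FALSE)) {
    t_base <- apply_rubric(toy_call(), svm_decision = svm,
                           rubric = base)$total_score
    t_more <- apply_rubric(toy_call(), svm_decision = svm,
                           rubric = more)$total_score
    expect_gte(t_more, t_base)
  }
})

test_that("rubrics round-trip through JSON", {
  r <- default_rubric()
  f <- tempfile(fileext = ".json")
  write_rubric(r, f)
  back <- read_rubric(f)
  expect_equal(back$svm_points, r$svm_points)
  expect_equal(back$threshold, r$threshold)
  expect_equal(length(back$rules), length(r$rules))
  sc_r <- apply_rubric(toy_call(), svm_decision = TRUE, rubric = r)
  sc_b <- apply_rubric(toy_call(), svm_decision = TRUE, rubric = back)
  expect_equal(sc_r, sc_b)
  expect_error(score_rubric(list(list(name = "nope", points = 1L))),
               "unknown rubric predicate")
})
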