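# Heuristic scoring rubric. Predicates live in a registry so rubrics are
# JSON-configurable: each rule names a predicate, optional parameters, and
# a signed point value. The exact point tables of the original mining
# rubrics are not public; the defaults below are declared substitutes with
# the same structure and are fully replaceable.

rubric_predicates <- list(
  ## a leader motif was matched
  motif_present = function(ctx, pars) !is.na(ctx$boundary$motif_name),
  ## boundary set by a protease-style GG/GA cleavage motif
  gg_ga_boundary = function(ctx, pars) ctx$boundary$rule_used %in% c("GG", "GA"),
  ## core enriched in the modifiable residues Ser/Thr plus Cys
  core_stc_fraction = function(ctx, pars) {
    core <- ctx$boundary$core
    frac <- sum(split_chars(core) %in% c("S", "T", "C")) / nchar(core)
    frac >= (pars$min_fraction %||% 0.2)
  },
  ## ORF encoded near and co-directional with a class-evidence gene
  adjacent_codirectional = function(ctx, pars) {
    if (is.null(ctx$orf) || is.null(ctx$bgc)) return(FALSE)
    max_gap <- pars$max_gap_nt %||% 1000
    ev_pids <- unique(ctx$bgc$evidence$protein_id)
    genes <- ctx$bgc$neighborhood$genes
    rid <- ctx$bgc$neighborhood$record_id
    for (g in genes) {
      if (!(gene_pid(rid, g) %in% ev_pids)) next
      if (g$strand != ctx$orf$strand) next
      gap <- max(ctx$orf$start - g$end, g$start - ctx$orf$end, 0L)
      if (gap <= max_gap) return(TRUE)
    }
    FALSE
  })

#' Construct a scoring rubric
#'
#' @param rules list of rules, each a list with `name` (a registered
#'   predicate: motif_present, gg_ga_boundary, core_stc_fraction,
#'   adjacent_codirectional), optional `params`, and integer `points`.
#' @param svm_points points granted on a positive SVM decision.
#' @param threshold total score at or above which a candidate is called a
#'   precursor.
#' @return object of class `score_rubric`.
#' @export
score_rubric <- function(rules, svm_points = 10L, threshold = 10L) {
  for (r in rules) {
    stopifnot(is.list(r), !is.null(r$name), !is.null(r$points))
    if (!r$name %in% names(rubric_predicates))
      lancmine_error(sprintf("unknown rubric predicate '%s'", r$name))
  }
  structure(list(rules = rules, svm_points = as.integer(svm_points),
                 threshold = as.integer(threshold)),
            class = "score_rubric")
}

#' Default scoring rubric
#'
#' Leader motif present +3; GG/GA boundary +2; core S+T+C fraction >= 0.2
#' +2; encoded adjacent (<= 1 kb) and co-directional with a class-evidence
#' gene +2; positive SVM decision +10; precursor threshold 10 (so an SVM
#' positive or a near-full house of heuristics is required).
#'
#' @return `score_rubric`.
#' @export
default_rubric <- function() {
  score_rubric(list(
    list(name = "motif_present", points = 3L),
    list(name = "gg_ga_boundary", points = 2L),
    list(name = "core_stc_fraction", params = list(min_fraction = 0.2), points = 2L),
    list(name = "adjacent_codirectional", params = list(max_gap_nt = 1000), points = 2L)),
    svm_points = 10L, threshold = 10L)
}

#' Read / write a rubric as JSON
#'
#' @param path JSON file.
#' @param rubric a `score_rubric`.
#' @return the rubric (read) or `path` (write).
#' @export
read_rubric <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  score_rubric(x$rules, svm_points = x$svm_points, threshold = x$threshold)
}

#' @rdname read_rubric
#' @export
write_rubric <- function(rubric, path) {
  jsonlite::write_json(unclass(rubric), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Apply a scoring rubric to one candidate
#'
#' @param call a `boundary_call`.
#' @param context list with optional `orf` (one-row candidate-ORF
#'   data.frame turned into a list) and `bgc` (`bgc_call`).
#' @param svm_decision logical SVM verdict.
#' @param rubric a `score_rubric`.
#' @return list with `points` (rubric rules only) and `total_score`
#'   (rules + SVM points when positive).
#' @export
apply_rubric <- function(call, context = list(), svm_decision = FALSE,
                         rubric = default_rubric()) {
  ctx <- list(boundary = call, orf = context$orf, bgc = context$bgc)
  pts <- 0L
  for (r in rubric$rules) {
    fired <- isTRUE(rubric_predicates[[r$name]](ctx, r$params %||% list()))
    if (fired) pts <- pts + as.integer(r$points)
  }
  total <- pts + if (isTRUE(svm_decision)) rubric$svm_points else 0L
  list(points = pts, total_score = total)
}

#' Score candidate ORFs of one gene cluster
#'
#' Runs the per-ORF chain motif -> leader/core boundary -> features ->
#' SVM -> rubric and returns one row per surviving candidate, sorted by
#' descending total score. ORFs rejected at the boundary step (no core
#' Cys) are dropped.
#'
#' @param bgc a `bgc_call`; its class must match `model$lan_class`.
#' @param orfs candidate-ORF data.frame (after filtering/dedup).
#' @param model a `lancmine_svm`.
#' @param rubric a `score_rubric`.
#' @param library motif library.
#' @param catalog feature catalog (version must match the model).
#' @param boundary boundary parameters.
#' @return data.frame of precursor calls.
#' @export
call_precursors <- function(bgc, orfs, model, rubric = default_rubric(),
                            library = default_motif_library(),
                            catalog = feature_catalog(),
                            boundary = boundary_params()) {
  if (!identical(model$lan_class, bgc$lan_class))
    lancmine_error(sprintf("model class %s does not match BGC class %s",
                           model$lan_class, bgc$lan_class))
  if (!identical(model$catalog_version, catalog$version))
    lancmine_error("model catalog version does not match supplied catalog")
  out <- list()
  if (nrow(orfs)) for (i in seq_len(nrow(orfs))) {
    orf <- as.list(orfs[i, ])
    bc <- split_leader_core(orf$aa_seq,
                            match_leader_motif(orf$aa_seq, library), boundary)
    if (is.null(bc)) next
    fv <- compute_features(bc, catalog)
    pred <- predict(model, fv)
    sc <- apply_rubric(bc, list(orf = orf, bgc = bgc), pred$decision, rubric)
    out[[length(out) + 1L]] <- data.frame(
      record_id = orf$record_id, bgc_id = bgc$bgc_id,
      lan_class = bgc$lan_class,
      anchor_protein_id = gene_pid(bgc$neighborhood$record_id,
                                   bgc$neighborhood$anchor),
      orf_id = sprintf("%s_orf_%d_%d_%s", bgc$bgc_id, orf$start, orf$end,
                       if (orf$strand == 1L) "p" else "m"),
      start = orf$start, end = orf$end, strand = orf$strand,
      start_codon = orf$start_codon, annotated = orf$annotated,
      peptide = orf$aa_seq, leader = bc$leader, core = bc$core,
      rule_used = bc$rule_used, motif_name = bc$motif_name,
      svm_decision = pred$decision, svm_margin = pred$margin,
      rubric_points = sc$points, total_score = sc$total_score,
      is_precursor = sc$total_score >= rubric$threshold,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_precursor_calls())
  res <- do.call(rbind, out)
  res <- res[order(-res$total_score, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_precursor_calls <- function() {
  data.frame(record_id = character(0), bgc_id = character(0),
             lan_class = character(0), anchor_protein_id = character(0),
             orf_id = character(0), start = integer(0), end = integer(0),
             strand = integer(0), start_codon = character(0),
             annotated = logical(0), peptide = character(0),
             leader = character(0), core = character(0),
             rule_used = character(0), motif_name = character(0),
             svm_decision = logical(0), svm_margin = numeric(0),
             rubric_points = integer(0), total_score = integer(0),
             is_precursor = logical(0), stringsAsFactors = FALSE)
}
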