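#' Pipeline configuration
#'
#' Collects the constants and file references of an end-to-end mining run.
#' All referenced files are checked at run start; a missing file is a
#' fatal configuration error raised before any compute.
#'
#' @param classifier a [classifier_config()] (or path to its JSON mapping).
#' @param models named list of `lancmine_svm` models (or bundle paths)
#'   keyed by class label; a BGC of a class without a model is reported
#'   but not precursor-scored.
#' @param rubric a `score_rubric` or JSON path.
#' @param motif_library a motif library or JSON path.
#' @param catalog a [feature_catalog()].
#' @param annotation_hmms optional list of `profile_hmm` (or HMM file
#'   paths) for accessory-domain annotation.
#' @param window neighborhood half-width in genes.
#' @param edge_distance_nt contig-edge distance.
#' @param orf an [orf_params()].
#' @param boundary a [boundary_params()].
#' @param annotation_e_cutoff accessory-annotation E-value cutoff.
#' @param anchor_e_cutoff reporting threshold of the anchor search
#'   (backend default 10).
#' @param formats report formats for [write_report()].
#' @param seed run seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(classifier, models = list(),
                            rubric = default_rubric(),
                            motif_library = default_motif_library(),
                            catalog = feature_catalog(),
                            annotation_hmms = list(),
                            window = 7L, edge_distance_nt = 3000L,
                            orf = orf_params(), boundary = boundary_params(),
                            annotation_e_cutoff = 1e-5,
                            anchor_e_cutoff = 10,
                            formats = c("tsv", "gff3", "fasta"),
                            seed = 1L) {
  if (is.character(classifier)) classifier <- read_classifier_config(classifier)
  if (is.character(rubric)) rubric <- read_rubric(rubric)
  if (is.character(motif_library)) motif_library <- read_motif_library(motif_library)
  models <- lapply(models, function(m)
    if (is.character(m)) read_svm_bundle(m) else m)
  annotation_hmms <- lapply(annotation_hmms, function(h)
    if (is.character(h)) profile_hmm_from_file(h) else h)
  for (h in c(config_hmms(classifier), annotation_hmms))
    if (!file.exists(h$file))
      lancmine_error(sprintf("HMM file '%s' missing", h$file),
                     "lancmine_config_error")
  structure(list(classifier = classifier, models = models, rubric = rubric,
                 motif_library = motif_library, catalog = catalog,
                 annotation_hmms = annotation_hmms,
                 window = as.integer(window),
                 edge_distance_nt = as.integer(edge_distance_nt),
                 orf = orf, boundary = boundary,
                 annotation_e_cutoff = annotation_e_cutoff,
                 anchor_e_cutoff = anchor_e_cutoff,
                 formats = formats, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  object_md5(list(
    hmms = lapply(config_hmms(config$classifier), function(h)
      list(h$name, h$model_length)),
    models = lapply(config$models, function(m)
      list(m$lan_class, m$hyperparameters, sum(m$selected_mask), m$seed)),
    rubric = unclass(config$rubric),
    motifs = as.data.frame(config$motif_library),
    catalog = config$catalog$version,
    window = config$window, edge = config$edge_distance_nt,
    orf = unclass(config$orf), boundary = unclass(config$boundary),
    ann_cutoff = config$annotation_e_cutoff,
    anchor_cutoff = config$anchor_e_cutoff,
    seed = config$seed))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[lancmine] ", fmt), ...))
}

#' Run the end-to-end mining pipeline
#'
#' Reads annotated genomes, finds LanC-like anchor proteins, extracts and
#' classifies anchor neighborhoods, enumerates/filters/deduplicates
#' candidate precursor ORFs per cluster, scores candidates with the
#' class-matched SVM plus rubric, optionally annotates accessory domains,
#' and returns a [summarize_mining()] report with run metadata and the
#' per-stage count funnel. Deterministic given inputs, configuration, and
#' backend version.
#'
#' @param inputs character vector of GenBank paths, or a list of
#'   `genome_record` objects.
#' @param config a [pipeline_config()].
#' @param verbose log per-stage counters to stderr.
#' @return `mining_report`.
#' @export
run_mine <- function(inputs, config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- list()
  if (is.character(inputs)) {
    for (path in inputs) {
      recs <- tryCatch(read_genbank(path), error = function(e) {
        warning(sprintf("skipping '%s': %s", path, conditionMessage(e)))
        NULL
      })
      records <- c(records, recs)
    }
    if (!length(records))
      lancmine_error("no input record could be parsed", "lancmine_input_error")
  } else records <- inputs

  ## translations for genes lacking one, so downstream search sees all
  records <- lapply(records, function(rec) {
    prots <- record_proteins(rec)
    for (i in seq_along(rec$genes))
      if (is.na(rec$genes[[i]]$protein_seq))
        rec$genes[[i]]$protein_seq <- unname(prots[i])
    rec
  })

  proteins <- unlist(lapply(records, record_proteins))
  log_stage(verbose, "records: %d, proteins: %d", length(records),
            length(proteins))

  funnel <- c(anchors = 0L, neighborhoods = 0L, classified = 0L,
              orfs_enumerated = 0L, orfs_filtered = 0L, orfs_dedup = 0L,
              precursors = 0L)
  calls <- list(); precursors <- list(); annotations <- list()

  if (length(proteins)) {
    anchors <- find_lanc_proteins(proteins, config$classifier)
    funnel["anchors"] <- nrow(anchors)
    log_stage(verbose, "anchor hits: %d", nrow(anchors))
    class_hits <- if (nrow(anchors))
      hmm_search(config_hmms(config$classifier), proteins,
                 e_cutoff = config$anchor_e_cutoff)
    else NULL

    for (rec in records) {
      pids <- vapply(rec$genes, function(g) gene_pid(rec$record_id, g),
                     character(1))
      hit_idx <- which(pids %in% anchors$protein_id)
      for (gi in hit_idx) {
        nb <- extract_neighborhood(rec, gi, config$window,
                                   config$edge_distance_nt)
        funnel["neighborhoods"] <- funnel["neighborhoods"] + 1L
        bgc <- assign_class(nb, class_hits, config$classifier,
                            bgc_id = sprintf("%s_bgc_%03d", rec$record_id, gi))
        calls[[length(calls) + 1L]] <- bgc
        if (bgc$lan_class != "unclassified")
          funnel["classified"] <- funnel["classified"] + 1L

        model <- config$models[[bgc$lan_class]]
        if (!is.null(model)) {
          span <- substr(rec$dna, nb$span_start + 1L, nb$span_end)
          orfs <- enumerate_orfs(span, nb$span_start, config$orf,
                                 record_id = rec$record_id)
          funnel["orfs_enumerated"] <- funnel["orfs_enumerated"] + nrow(orfs)
          orfs <- filter_orfs(orfs, rec$genes, config$orf)
          funnel["orfs_filtered"] <- funnel["orfs_filtered"] + nrow(orfs)
          orfs <- dedup_by_stop(orfs)
          funnel["orfs_dedup"] <- funnel["orfs_dedup"] + nrow(orfs)
          pc <- call_precursors(bgc, orfs, model, config$rubric,
                                config$motif_library, config$catalog,
                                config$boundary)
          precursors[[length(precursors) + 1L]] <- pc
        }
        if (length(config$annotation_hmms))
          annotations[[length(annotations) + 1L]] <-
            annotate_genes(bgc, config$annotation_hmms,
                           config$annotation_e_cutoff)
      }
    }
  }

  pc_all <- if (length(precursors)) do.call(rbind, precursors)
            else empty_precursor_calls()
  funnel["precursors"] <- sum(pc_all$is_precursor)
  log_stage(verbose,
            "neighborhoods: %d, classified: %d, ORFs %d -> %d -> %d, precursors: %d",
            funnel["neighborhoods"], funnel["classified"],
            funnel["orfs_enumerated"], funnel["orfs_filtered"],
            funnel["orfs_dedup"], funnel["precursors"])

  report <- summarize_mining(calls, pc_all, records)
  report$census <- if (length(annotations)) census(annotations, calls) else NULL
  report$run_meta <- list(
    config_hash = config_hash(config),
    n_inputs = length(records),
    input_digests = vapply(records, function(r)
      object_md5(list(r$record_id, r$length_nt, length(r$genes))), character(1)),
    funnel = as.list(funnel),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  report
}

#' Train a precursor SVM from labeled peptides
#'
#' Reads a labeled FASTA (a `label=1` / `label=0` key in each description
#' line), runs the boundary/feature chain, selects features by ANOVA, and
#' trains the class SVM. Writes the model bundle and a JSON training
#' report when paths are given.
#'
#' @param labeled_fasta FASTA path with `label=` descriptions.
#' @param lan_class class label for the model.
#' @param cfg a [training_config()].
#' @param catalog a [feature_catalog()].
#' @param out_model optional bundle output path.
#' @param out_report optional JSON report path.
#' @return the trained `lancmine_svm`, invisibly.
#' @export
run_train <- function(labeled_fasta, lan_class, cfg = training_config(),
                      catalog = feature_catalog(), out_model = NULL,
                      out_report = NULL) {
  seqs <- read_fasta(labeled_fasta)
  desc <- attr(seqs, "descriptions")
  m <- regmatches(desc, regexec("label=([01])", desc))
  labels <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
                   character(1))
  if (anyNA(labels))
    lancmine_error("every FASTA description needs a label=0|1 key",
                   "lancmine_input_error")
  train_peptide_model(setNames(as.character(seqs), names(seqs)),
                      as.integer(labels), lan_class, cfg, catalog,
                      out_model, out_report)
}

#' Train a model from an in-memory labeled peptide set
#'
#' @param peptides named character vector.
#' @param labels integer 0/1 labels aligned to `peptides`.
#' @inheritParams run_train
#' @return `lancmine_svm`, invisibly.
#' @export
train_peptide_model <- function(peptides, labels, lan_class = "II",
                                cfg = training_config(),
                                catalog = feature_catalog(),
                                out_model = NULL, out_report = NULL) {
  if (length(unique(labels)) < 2L)
    lancmine_error("training input contains a single class",
                   "lancmine_input_error")
  fz <- featurize_peptides(peptides, catalog)
  y <- labels[fz$kept]
  if (length(unique(y)) < 2L)
    lancmine_error("after boundary rejection only one class remains",
                   "lancmine_input_error")
  mask <- select_features(fz$X, y, cfg)
  model <- train_svm(fz$X, y, mask, cfg, lan_class = lan_class,
                     catalog_version = catalog$version)
  if (!is.null(out_model)) write_svm_bundle(model, out_model)
  if (!is.null(out_report))
    jsonlite::write_json(list(
      lan_class = lan_class, n_selected = sum(mask),
      selected_features = model$feature_names,
      cv_accuracy = model$cv_accuracy,
      hyperparameters = model$hyperparameters,
      n_pos = model$n_pos, n_neg = model$n_neg, seed = cfg$seed),
      out_report, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(model)
}
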