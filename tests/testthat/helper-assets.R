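# Expensive shared assets (HMMER builds, SVM training), created lazily and
# memoized for the whole test run. Everything is seeded and deterministic.

.assets <- new.env(parent = emptyenv())

fx_hmms <- function() {
  if (is.null(.assets$hmms))
    .assets$hmms <- fixture_hmm_set(file.path(tempdir(), "lancmine_fx_hmms"),
                                    seed = 101L)
  .assets$hmms
}

fx_models <- function() {
  if (is.null(.assets$models)) {
    tp <- make_training_peptides(120L, 120L, separation = 1, seed = 5L)
    cfg <- training_config(seed = 3L, cv_folds = 5L, cost_grid = c(1, 10))
    .assets$models <- lapply(c(I = "I", II = "II", III = "III", IV = "IV"),
                             function(cl)
      train_peptide_model(setNames(tp$seq, tp$id), tp$label,
                          lan_class = cl, cfg = cfg))
  }
  .assets$models
}

fx_genome <- function() {
  if (is.null(.assets$genome))
    .assets$genome <- make_genome(fixture_spec(seed = 1L))
  .assets$genome
}

fx_pipeline_config <- function() {
  pipeline_config(classifier = fx_hmms()$config, models = fx_models())
}

## a ready bgc_call for annotation / rubric tests: class II fixture BGC
fx_bgc_call <- function() {
  if (is.null(.assets$bgc)) {
    g <- fx_genome()
    rec <- g$record
    anchor_start <- g$truth$bgcs$anchor_start[g$truth$bgcs$lan_class == "II"][1]
    idx <- which(vapply(rec$genes, `[[`, integer(1), "start") == anchor_start)
    nb <- extract_neighborhood(rec, idx)
    prots <- record_proteins(rec)
    nb_ids <- vapply(nb$genes, function(gg) lancmine:::gene_pid(rec$record_id, gg),
                     character(1))
    hits <- hmm_search(lancmine:::config_hmms(fx_hmms()$config),
                       prots[nb_ids], e_cutoff = 10)
    .assets$bgc <- assign_class(nb, hits, fx_hmms()$config)
  }
  .assets$bgc
}
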