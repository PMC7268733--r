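#' Annotate a cluster's genes against accessory domain models
#'
#' Every neighborhood gene product is searched against the supplied models;
#' hits above the E-value cutoff are discarded (1e-5, the standard Pfam
#' annotation threshold of the mining procedure).
#'
#' @param bgc a `bgc_call`.
#' @param domain_models list of `profile_hmm`.
#' @param e_cutoff full-sequence E-value cutoff.
#' @return object of class `tailoring_annotation`: `bgc_id` plus `per_gene`,
#'   a list of hit data.frames keyed by protein id (empty data.frames for
#'   genes without hits).
#' @export
annotate_genes <- function(bgc, domain_models, e_cutoff = 1e-5) {
  nb <- bgc$neighborhood
  prots <- vapply(nb$genes, function(g) gene_pid(nb$record_id, g), character(1))
  ## gene products with a stored translation (the reader fills these in)
  seqs <- vapply(nb$genes, function(g) {
    if (!is.na(g$protein_seq) && nzchar(g$protein_seq)) g$protein_seq
    else NA_character_
  }, character(1))
  names(seqs) <- prots
  seqs <- seqs[!is.na(seqs)]
  hits <- if (length(domain_models) && length(seqs))
    hmm_search(domain_models, seqs, e_cutoff = e_cutoff)
  else data.frame(protein_id = character(0), hmm_name = character(0),
                  evalue = numeric(0), bitscore = numeric(0))
  per_gene <- lapply(prots, function(p)
    hits[hits$protein_id == p, , drop = FALSE])
  names(per_gene) <- prots
  structure(list(bgc_id = bgc$bgc_id, per_gene = per_gene, e_cutoff = e_cutoff),
            class = "tailoring_annotation")
}

#' Domain co-occurrence census over annotated clusters
#'
#' Counts, for each domain model, the number of BGCs containing at least
#' one hit (BGC-level, not gene-level), overall and per lanthipeptide
#' class, sorted by descending total count.
#'
#' @param annotations list of `tailoring_annotation`.
#' @param calls list of `bgc_call` aligned by `bgc_id`.
#' @return data.frame with columns `domain`, `n_bgcs`, and one `n_<class>`
#'   column per observed class.
#' @export
census <- function(annotations, calls) {
  if (!length(annotations))
    return(data.frame(domain = character(0), n_bgcs = integer(0),
                      stringsAsFactors = FALSE))
  class_by_id <- setNames(vapply(calls, `[[`, character(1), "lan_class"),
                          vapply(calls, `[[`, character(1), "bgc_id"))
  rows <- do.call(rbind, lapply(annotations, function(a) {
    doms <- unique(unlist(lapply(a$per_gene, function(h) h$hmm_name)))
    if (!length(doms)) return(NULL)
    data.frame(bgc_id = a$bgc_id, domain = doms,
               lan_class = unname(class_by_id[a$bgc_id]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    return(data.frame(domain = character(0), n_bgcs = integer(0),
                      stringsAsFactors = FALSE))
  classes <- sort(unique(rows$lan_class))
  doms <- sort(unique(rows$domain))
  out <- data.frame(domain = doms,
                    n_bgcs = vapply(doms, function(d)
                      length(unique(rows$bgc_id[rows$domain == d])), integer(1)),
                    stringsAsFactors = FALSE)
  for (cl in classes)
    out[[paste0("n_", cl)]] <- vapply(doms, function(d)
      length(unique(rows$bgc_id[rows$domain == d & rows$lan_class == cl])),
      integer(1))
  out <- out[order(-out$n_bgcs, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GC content of a DNA string
#'
#' (G+C)/(A+C+G+T); N bases are excluded from both numerator and
#' denominator. Errors on empty or all-N input.
#'
#' @param dna DNA string over A,C,G,T,N.
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(dna) {
  stopifnot(grepl("^[ACGTN]*$", dna))
  counts <- table(factor(split_chars(dna), levels = c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0)
    lancmine_error("gc_content undefined on empty or all-N sequence",
                   "lancmine_domain_error")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' Summarize a mining run
#'
#' Builds the whole-run summary: per-class BGC counts, precursor count,
#' per-phylum tallies (phylum = second lineage element, else "unknown"),
#' the fraction of called precursor leaders ending in Gly-Gly, per-BGC
#' (cluster GC, genome GC) pairs computed over the neighborhood span, and
#' a precursors-per-BGC histogram.
#'
#' @param calls list of `bgc_call`.
#' @param precursors data.frame of precursor calls (rbind of
#'   [call_precursors()] outputs).
#' @param records list of `genome_record` the calls came from.
#' @return object of class `mining_report`.
#' @export
summarize_mining <- function(calls, precursors, records) {
  recs <- setNames(records, vapply(records, `[[`, character(1), "record_id"))
  cls <- vapply(calls, `[[`, character(1), "lan_class")
  class_counts <- table(factor(cls, levels = c("I", "II", "III", "IV",
                                               "unclassified")))
  phylum_of <- function(rec)
    if (length(rec$lineage) >= 2L) rec$lineage[[2L]] else "unknown"
  phyla <- vapply(calls, function(b) phylum_of(recs[[b$neighborhood$record_id]]),
                  character(1))
  if (is.null(precursors)) precursors <- empty_precursor_calls()
  called <- precursors[precursors$is_precursor, , drop = FALSE]
  gg_fraction <- if (nrow(called)) mean(endsWith(called$leader, "GG")) else NA_real_

  gc_pairs <- do.call(rbind, lapply(calls, function(b) {
    rec <- recs[[b$neighborhood$record_id]]
    span <- substr(rec$dna, b$neighborhood$span_start + 1L,
                   b$neighborhood$span_end)
    data.frame(bgc_id = b$bgc_id, lan_class = b$lan_class,
               bgc_gc = gc_content(span), genome_gc = gc_content(rec$dna),
               stringsAsFactors = FALSE)
  }))
  if (is.null(gc_pairs))
    gc_pairs <- data.frame(bgc_id = character(0), lan_class = character(0),
                           bgc_gc = numeric(0), genome_gc = numeric(0))

  per_bgc <- vapply(calls, function(b) sum(called$bgc_id == b$bgc_id), integer(1))
  hist <- if (length(per_bgc)) table(per_bgc) else table(integer(0))

  structure(list(bgc_calls = calls, precursor_calls = precursors,
                 class_counts = class_counts,
                 n_precursors = nrow(called),
                 phylum_counts = if (length(phyla)) table(phyla) else table(character(0)),
                 gg_fraction = gg_fraction,
                 gc_pairs = gc_pairs,
                 precursors_per_bgc = hist,
                 census = NULL, run_meta = list()),
            class = "mining_report")
}

#' @export
print.mining_report <- function(x, ...) {
  cat("<mining_report>\n  BGCs by class:",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = " "),
      sprintf("\n  precursors called: %d", x$n_precursors),
      sprintf("\n  GG-leader fraction: %s",
              ifelse(is.na(x$gg_fraction), "NA", sprintf("%.2f", x$gg_fraction))),
      "\n")
  invisible(x)
}

#' Write census and summary tallies as TSV
#'
#' @param report a `mining_report`.
#' @param out_dir output directory.
#' @return written paths, invisibly.
#' @export
write_summary_tsv <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(out_dir, "class_counts.tsv")
  utils::write.table(as.data.frame(report$class_counts),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "gc_pairs.tsv")
  utils::write.table(report$gc_pairs, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$census)) {
    p <- file.path(out_dir, "census.tsv")
    utils::write.table(report$census, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
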