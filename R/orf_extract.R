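#' ORF enumeration parameters
#'
#' Defaults follow the mining procedure: bacterial initiators ATG/GTG/TTG,
#' precursor length bounds 30-120 aa (inclusive, counting the initiator
#' Met), at least one Cys, genetic code table 11.
#'
#' @param start_codons permitted start codons.
#' @param min_len_aa,max_len_aa inclusive peptide length bounds.
#' @param require_cys discard ORFs without Cys when TRUE.
#' @param genetic_code NCBI genetic code id (only 11 supported).
#' @return object of class `orf_params`.
#' @export
orf_params <- function(start_codons = c("ATG", "GTG", "TTG"),
                       min_len_aa = 30L, max_len_aa = 120L,
                       require_cys = TRUE, genetic_code = 11L) {
  stopifnot(min_len_aa <= max_len_aa,
            all(grepl("^[ACGT]{3}$", start_codons)))
  structure(list(start_codons = start_codons,
                 min_len_aa = as.integer(min_len_aa),
                 max_len_aa = as.integer(max_len_aa),
                 require_cys = isTRUE(require_cys),
                 genetic_code = as.integer(genetic_code)),
            class = "orf_params")
}

empty_orfs <- function() {
  data.frame(record_id = character(0), start = integer(0), end = integer(0),
             strand = integer(0), start_codon = character(0),
             aa_seq = character(0), stop_pos = integer(0),
             stop_key = character(0), annotated = logical(0),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate ORFs in a DNA span
#'
#' Returns every in-frame (start codon ... stop codon) pair on both strands,
#' one row per start codon. The reported interval `[start, end)` covers the
#' stop codon; `aa_seq` excludes the stop and always begins with M (the
#' initiator codon is rendered as Met). Codons containing N never act as
#' start or stop and translate to X. ORFs running off the span without an
#' in-frame stop are excluded. `stop_pos` is the record-space coordinate of
#' the stop codon's first nucleotide; `stop_key` combines it with strand.
#'
#' @param span_dna DNA string over A,C,G,T,N.
#' @param span_offset record-space coordinate of the span's first base
#'   (0-based); output coordinates are record-space.
#' @param params an [orf_params()].
#' @param record_id record identifier copied into the output.
#' @return data.frame of candidate ORFs (class `candidate_orfs`).
#' @export
enumerate_orfs <- function(span_dna, span_offset = 0L, params = orf_params(),
                           record_id = "") {
  stopifnot(grepl("^[ACGTN]*$", span_dna))
  L <- nchar(span_dna)
  rows <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) span_dna else revcomp(span_dna)
    for (frame in 0:2) {
      n_cod <- (L - frame) %/% 3L
      if (n_cod < 2L) next
      cpos <- frame + 3L * (seq_len(n_cod) - 1L)     # local 0-based codon starts
      codons <- substring(s, cpos + 1L, cpos + 3L)
      stop_i <- which(codons %in% STOP_CODONS)
      start_i <- which(codons %in% params$start_codons)
      if (!length(stop_i) || !length(start_i)) next
      nxt <- findInterval(start_i, stop_i) + 1L      # first stop codon after start
      has_stop <- nxt <= length(stop_i)
      start_i <- start_i[has_stop]
      if (!length(start_i)) next
      stop_at <- stop_i[nxt[has_stop]]
      aa <- vapply(seq_along(start_i), function(k) {
        i <- start_i[k]; j <- stop_at[k]
        translate_dna(substr(s, cpos[i] + 1L, cpos[j]), init_met = TRUE)
      }, character(1))
      loc_start <- cpos[start_i]
      loc_end <- cpos[stop_at] + 3L
      if (strand == 1L) {
        st <- loc_start; en <- loc_end; sp <- loc_end - 3L
      } else {
        st <- L - loc_end; en <- L - loc_start; sp <- st
      }
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = record_id,
        start = span_offset + st, end = span_offset + en,
        strand = strand,
        start_codon = codons[start_i],
        aa_seq = aa,
        stop_pos = span_offset + sp,
        annotated = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_orfs())
  out <- do.call(rbind, rows)
  out$stop_key <- paste0(out$strand, "@", out$stop_pos)
  out <- out[order(out$start, out$strand, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_orfs", "data.frame")
  out
}

#' Filter candidate ORFs by length, Cys content, and gene nesting
#'
#' Keeps ORFs whose peptide length lies within the inclusive bounds, that
#' encode at least one Cys (when required), and that are not strictly
#' nested inside an annotated gene interval (strand-agnostic). An ORF whose
#' interval exactly equals an annotated gene's interval is kept and marked
#' `annotated = TRUE`: annotated precursors remain candidates.
#'
#' @param orfs data.frame from [enumerate_orfs()].
#' @param genes list of `gene_feature` for the same record.
#' @param params an [orf_params()].
#' @return filtered data.frame.
#' @export
filter_orfs <- function(orfs, genes = list(), params = orf_params()) {
  if (!nrow(orfs)) return(orfs)
  len <- nchar(orfs$aa_seq)
  keep <- len >= params$min_len_aa & len <= params$max_len_aa
  if (params$require_cys) keep <- keep & grepl("C", orfs$aa_seq, fixed = TRUE)
  annotated <- rep(FALSE, nrow(orfs))
  nested <- rep(FALSE, nrow(orfs))
  for (g in genes) {
    inside <- orfs$start >= g$start & orfs$end <= g$end
    exact <- orfs$start == g$start & orfs$end == g$end
    annotated <- annotated | exact
    nested <- nested | (inside & !exact)
  }
  keep <- keep & !(nested & !annotated)
  out <- orfs[keep, , drop = FALSE]
  out$annotated <- annotated[keep]
  rownames(out) <- NULL
  out
}

#' Deduplicate ORFs sharing a stop codon
#'
#' For each (strand, stop coordinate) the longest ORF (most upstream start)
#' is retained. Output is sorted by (start, strand).
#'
#' @param orfs data.frame of candidate ORFs.
#' @return deduplicated data.frame.
#' @export
dedup_by_stop <- function(orfs) {
  if (!nrow(orfs)) return(orfs)
  len <- nchar(orfs$aa_seq)
  ord <- order(orfs$stop_key, -len)
  orfs <- orfs[ord, , drop = FALSE]
  out <- orfs[!duplicated(orfs$stop_key), , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
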