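# Profile-HMM construction and search behind a backend-agnostic contract.
# Backend: HMMER3 (hmmbuild / hmmsearch), expected on PATH. Only
# full-sequence E-values and bitscores are consumed downstream.

hmmer_binary <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path))
    lancmine_error(sprintf("HMMER binary '%s' not found on PATH", name),
                   "lancmine_backend_error")
  path
}

#' Construct an amino-acid alignment
#'
#' @param id alignment identifier.
#' @param seqs named character vector of aligned rows (gap symbol `-`),
#'   all of equal length.
#' @return object of class `aa_alignment`.
#' @export
alignment <- function(id, seqs) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  seqs <- setNames(unname(unclass(seqs)), names(seqs))
  attr(seqs, "descriptions") <- NULL
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    lancmine_error("alignment rows have unequal lengths")
  structure(list(id = id, seqs = seqs, n_columns = widths[[1L]]),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %s: %d rows x %d columns\n",
              x$id, length(x$seqs), x$n_columns))
  invisible(x)
}

#' Read an aligned FASTA file as an alignment
#'
#' @param path aligned FASTA.
#' @param id alignment id (defaults to the file base name).
#' @return `aa_alignment`.
#' @export
read_alignment_fasta <- function(path, id = NULL) {
  seqs <- read_fasta(path)
  alignment(id %||% sub("\\.[^.]*$", "", basename(path)), toupper(seqs))
}

#' Read a (minimal, single-block-per-row) Stockholm alignment
#'
#' @param path Stockholm file.
#' @param id alignment id.
#' @return `aa_alignment`.
#' @export
read_alignment_stockholm <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^(#|//|\\s*$)", lines)]
  parts <- strsplit(trimws(body), "\\s+")
  ids <- vapply(parts, `[`, character(1), 1L)
  rows <- vapply(parts, `[`, character(1), 2L)
  agg <- vapply(split(rows, factor(ids, levels = unique(ids))),
                paste, character(1), collapse = "")
  agg <- chartr(".", "-", toupper(agg))
  alignment(id %||% sub("\\.[^.]*$", "", basename(path)), agg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncate an alignment to a column range
#'
#' Rows that become all-gap within the slice are dropped; row order is
#' preserved. Errors if fewer than 2 rows with residues remain.
#'
#' @param aln an `aa_alignment`.
#' @param first_col,last_col 1-based inclusive column range.
#' @return `aa_alignment`.
#' @export
truncate_alignment <- function(aln, first_col, last_col) {
  stopifnot(first_col >= 1L, first_col <= last_col, last_col <= aln$n_columns)
  sl <- substr(aln$seqs, first_col, last_col)
  keep <- grepl("[^-]", sl)
  if (sum(keep) < 2L)
    lancmine_error("truncation leaves fewer than 2 non-gap rows")
  alignment(aln$id, sl[keep])
}

#' Build a profile HMM from an alignment
#'
#' Runs `hmmbuild` (deterministic for a fixed alignment and HMMER version)
#' and normalizes the DATE header so rebuilding from the same alignment
#' yields byte-identical model files.
#'
#' @param aln an `aa_alignment`.
#' @param name model name.
#' @param file output HMM file (default: tempfile).
#' @return object of class `profile_hmm` (fields: name, accession,
#'   model_length, provenance, source, file).
#' @export
build_hmm <- function(aln, name, file = tempfile(fileext = ".hmm")) {
  if (!any(grepl("[^-]", aln$seqs)))
    lancmine_error("degenerate alignment: no residues")
  afa <- tempfile(fileext = ".afa")
  on.exit(unlink(afa))
  write_fasta(aln$seqs, afa)
  status <- system2(hmmer_binary("hmmbuild"),
                    c("--amino", "-n", shQuote(name), shQuote(file), shQuote(afa)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L)
    lancmine_error(sprintf("hmmbuild failed (status %d) for '%s'", status, name),
                   "lancmine_backend_error")
  lines <- readLines(file, warn = FALSE)
  lines[grepl("^DATE ", lines)] <- "DATE  Thu Jan  1 00:00:00 1970"
  writeLines(lines, file)
  profile_hmm_from_file(file, provenance = "built-from-alignment", source = aln$id)
}

#' Load an existing HMM text file as a `profile_hmm`
#'
#' @param file HMM file in HMMER3 text format (may hold one model).
#' @param provenance provenance tag.
#' @param source source identifier.
#' @return `profile_hmm`.
#' @export
profile_hmm_from_file <- function(file, provenance = "external-file", source = file) {
  if (!file.exists(file)) lancmine_error(sprintf("HMM file '%s' missing", file),
                                         "lancmine_io_error")
  lines <- readLines(file, n = 30L, warn = FALSE)
  getf <- function(tag) {
    ln <- grep(sprintf("^%s ", tag), lines, value = TRUE)
    if (length(ln)) trimws(sub(sprintf("^%s", tag), "", ln[1L])) else NA_character_
  }
  leng <- suppressWarnings(as.integer(getf("LENG")))
  if (is.na(leng) || leng < 1L)
    lancmine_error(sprintf("'%s' is not a HMMER3 model file", file))
  structure(list(name = getf("NAME"), accession = getf("ACC"),
                 model_length = leng, provenance = provenance,
                 source = source, file = normalizePath(file)),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s (%d match states, %s)\n",
              x$name, x$model_length, x$provenance))
  invisible(x)
}

VALID_AA_RE <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

#' Search proteins with one or more profile HMMs
#'
#' Runs `hmmsearch` and returns full-sequence hits as a data.frame with
#' columns `protein_id`, `hmm_name`, `evalue`, `bitscore`, sorted by
#' ascending E-value (ties broken by protein then model name for
#' determinism). With `e_cutoff = NULL` the backend's default reporting
#' threshold applies. Sequences containing characters outside the 20-letter
#' alphabet plus X are skipped with a warning.
#'
#' @param hmms a `profile_hmm` or list of them.
#' @param proteins named character vector of amino-acid sequences.
#' @param e_cutoff maximum full-sequence E-value, or NULL for backend default.
#' @return data.frame of hits (zero rows when nothing passes).
#' @export
hmm_search <- function(hmms, proteins, e_cutoff = NULL) {
  if (inherits(hmms, "profile_hmm")) hmms <- list(hmms)
  stopifnot(length(hmms) >= 1L)
  empty <- data.frame(protein_id = character(0), hmm_name = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(proteins)) return(empty)
  stopifnot(!is.null(names(proteins)), !anyDuplicated(names(proteins)))
  ok <- grepl(VALID_AA_RE, proteins)
  if (any(!ok)) {
    for (bad in names(proteins)[!ok])
      warning(sprintf("sequence '%s' contains invalid characters; skipped", bad))
    proteins <- proteins[ok]
  }
  if (!length(proteins)) return(empty)

  hmmfile <- tempfile(fileext = ".hmm")
  seqfile <- tempfile(fileext = ".faa")
  tbl <- tempfile(fileext = ".tbl")
  on.exit(unlink(c(hmmfile, seqfile, tbl)))
  writeLines(unlist(lapply(hmms, function(h) readLines(h$file, warn = FALSE))),
             hmmfile)
  write_fasta(proteins, seqfile)
  args <- c("--noali", "--tblout", shQuote(tbl))
  if (!is.null(e_cutoff)) args <- c(args, "-E", format(e_cutoff, scientific = TRUE))
  status <- system2(hmmer_binary("hmmsearch"),
                    c(args, shQuote(hmmfile), shQuote(seqfile)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L)
    lancmine_error(sprintf("hmmsearch failed (status %d)", status),
                   "lancmine_backend_error")
  hits <- parse_hmmer_tblout(tbl)
  if (!is.null(e_cutoff)) hits <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
  hits <- hits[order(hits$evalue, hits$protein_id, hits$hmm_name), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

parse_hmmer_tblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines))
    return(data.frame(protein_id = character(0), hmm_name = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(protein_id = vapply(parts, `[`, character(1), 1L),
             hmm_name = vapply(parts, `[`, character(1), 3L),
             evalue = as.numeric(vapply(parts, `[`, character(1), 5L)),
             bitscore = as.numeric(vapply(parts, `[`, character(1), 6L)),
             stringsAsFactors = FALSE)
}
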