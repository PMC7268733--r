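#' @keywords internal
"_PACKAGE"

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Kyte-Doolittle hydropathy; X and unknowns score 0
KD_HYDROPATHY <- c(
  A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
  M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3, X = 0)

STOP_CODONS <- c("TAA", "TAG", "TGA")

lancmine_error <- function(msg, class = "lancmine_error") {
  stop(errorCondition(msg, class = c(class, "lancmine_error")))
}

## run `expr` under a private RNG stream; global .Random.seed untouched
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of a DNA string
#'
#' @param dna character scalar over A,C,G,T,N.
#' @return character scalar.
#' @export
revcomp <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  x <- chartr("ACGTN", "TGCAN", dna)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

## genetic code table 11 (translation table identical to the standard code;
## table 11 differs only in permitted initiators, handled by the caller)
genetic_code_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::getGeneticCode("11")
    tab
  }
})

#' Translate a DNA string
#'
#' Codons containing N (or any non-ACGT base) translate to X. The stop
#' symbol is `*`. Trailing incomplete codons are dropped.
#'
#' @param dna character scalar.
#' @param init_met if TRUE the first codon is rendered as M (bacterial
#'   initiators GTG/TTG code for fMet).
#' @return amino-acid string.
#' @export
translate_dna <- function(dna, init_met = FALSE) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  pos <- 3L * (seq_len(n) - 1L)
  codons <- substring(dna, pos + 1L, pos + 3L)
  aa <- unname(genetic_code_table()[codons])
  aa[is.na(aa)] <- "X"
  if (init_met) aa[1L] <- "M"
  paste(aa, collapse = "")
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## stable md5 of an R object via canonical JSON serialization
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

## simple FASTA I/O (wrapped at 60 columns); used for proteins, peptides
## and gapped alignments alike, so sequences stay plain character vectors
write_fasta <- function(seqs, path, width = 60L) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(structure(character(0), names = character(0)))
  idx <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  body <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  seqs <- character(length(ids))
  present <- as.integer(names(body))
  seqs[present] <- unname(body)
  names(seqs) <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  attr(seqs, "descriptions") <- ids
  seqs
}
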