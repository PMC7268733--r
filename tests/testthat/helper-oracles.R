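# Independent oracles, written deliberately in a different style from the
# package implementation (per-position walks and plain loops, no shared
# helpers beyond revcomp/translate primitives).

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

## naive six-frame scanner: for every position try "start codon, then walk
## in steps of 3 until a stop codon"; one ORF per start
oracle_orfs <- function(dna, offset = 0L, starts = c("ATG", "GTG", "TTG"),
                        record_id = "") {
  out <- list()
  scan_one <- function(s, strand) {
    L <- nchar(s)
    for (i in seq_len(L - 5L)) {            # 1-based position of codon start
      codon <- substr(s, i, i + 2L)
      if (!(codon %in% starts)) next
      j <- i
      found <- NA_integer_
      while (j + 2L <= L) {
        cj <- substr(s, j, j + 2L)
        if (j > i && cj %in% ORACLE_STOPS) { found <- j; break }
        j <- j + 3L
      }
      if (is.na(found)) next
      aa <- character(0)
      k <- i
      while (k < found) {
        aa <- c(aa, lancmine::translate_dna(substr(s, k, k + 2L)))
        k <- k + 3L
      }
      aa[1L] <- "M"
      if (strand == 1L) {
        st <- i - 1L; en <- found + 2L; sp <- found - 1L
      } else {
        st <- L - (found + 2L); en <- L - (i - 1L); sp <- st
      }
      out[[length(out) + 1L]] <<- data.frame(
        start = offset + st, end = offset + en, strand = strand,
        start_codon = codon, aa_seq = paste(aa, collapse = ""),
        stop_pos = offset + sp, stringsAsFactors = FALSE)
    }
  }
  scan_one(dna, 1L)
  scan_one(lancmine::revcomp(dna), -1L)
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = integer(0), start_codon = character(0),
                      aa_seq = character(0), stop_pos = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$strand, res$end), , drop = FALSE]
}

orf_key <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(sprintf("%d:%d:%d:%s", df$start, df$end, df$strand, df$aa_seq))
}

## exhaustive leader/core boundary oracle: enumerate every rule occurrence
## with plain loops, then apply exclusion, longest-core choice, fallback,
## and core-Cys rejection
oracle_boundary <- function(peptide, motif_end = 0L, c_term = 10L) {
  len <- nchar(peptide)
  ch <- strsplit(peptide, "")[[1]]
  occ <- data.frame(boundary = integer(0), rule = character(0),
                    pos = integer(0), prio = integer(0))
  for (i in 0:(len - 2L)) {                 # 0-based occurrence starts
    two <- paste0(ch[i + 1L], ch[i + 2L])
    prio <- if (two == "GG") 1L else if (two == "GA") 2L else NA_integer_
    if (!is.na(prio))
      occ <- rbind(occ, data.frame(boundary = i + 2L, rule = two,
                                   pos = i, prio = prio))
  }
  for (k in 0:(len - 1L)) {
    if (!(ch[k + 1L] %in% c("S", "T"))) next
    hit <- FALSE
    for (d in 2:7) if (k + d + 1L <= len - 1L && ch[k + d + 2L] == "C")
      hit <- TRUE
    if (hit)
      occ <- rbind(occ, data.frame(boundary = k - 1L, rule = "STC",
                                   pos = k, prio = 3L))
  }
  ok <- occ[occ$pos >= motif_end & occ$pos < len - c_term &
              occ$boundary >= 1L & occ$boundary <= len - 1L, , drop = FALSE]
  if (nrow(ok)) {
    ok <- ok[order(ok$boundary, ok$prio, ok$pos), , drop = FALSE]
    boundary <- ok$boundary[1L]; rule <- ok$rule[1L]
  } else {
    boundary <- len %/% 2L; rule <- "fallback-half"
  }
  core <- substr(peptide, boundary + 1L, len)
  if (!grepl("C", core)) return(NULL)
  list(boundary = boundary, rule = rule,
       leader = substr(peptide, 1L, boundary), core = core)
}

random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## counting oracle for dipeptide frequencies
oracle_dipeptides <- function(seq) {
  n <- nchar(seq)
  counts <- setNames(numeric(400), as.vector(outer(
    c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y"),
    c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y"),
    paste0)))
  if (n < 2) return(counts)
  for (i in 1:(n - 1L)) {
    dp <- substr(seq, i, i + 1L)
    if (dp %in% names(counts)) counts[dp] <- counts[dp] + 1
  }
  counts / (n - 1L)
}
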