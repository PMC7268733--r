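#' Construct a gene feature
#'
#' Coordinates are 0-based half-open on the forward strand, the package-wide
#' internal convention. Emitted formats (GenBank, GFF3) use their native
#' 1-based inclusive coordinates.
#'
#' @param locus_id locus tag.
#' @param start,end 0-based half-open nucleotide interval.
#' @param strand +1 or -1.
#' @param protein_id protein accession or NA.
#' @param product free-text product description.
#' @param protein_seq amino-acid string or NA.
#' @param index ordinal of the gene within its record.
#' @return object of class `gene_feature`.
#' @export
gene_feature <- function(locus_id, start, end, strand, protein_id = NA_character_,
                         product = "", protein_seq = NA_character_, index = NA_integer_) {
  stopifnot(start >= 0, end > start, strand %in% c(1L, -1L))
  structure(list(locus_id = locus_id, protein_id = protein_id,
                 start = as.integer(start), end = as.integer(end),
                 strand = as.integer(strand), product = product,
                 protein_seq = protein_seq, index = as.integer(index)),
            class = "gene_feature")
}

#' Construct a genome record
#'
#' @param record_id sequence accession / LOCUS name.
#' @param dna genome sequence over A,C,G,T,N.
#' @param genes list of [gene_feature()] objects; re-sorted by start.
#' @param organism organism name.
#' @param lineage character vector of taxon names, outermost first.
#' @param circular TRUE for circular replicons.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(record_id, dna, genes = list(), organism = "",
                          lineage = character(0), circular = FALSE) {
  len <- nchar(dna)
  if (length(genes)) {
    genes <- genes[order(vapply(genes, `[[`, integer(1), "start"))]
    for (i in seq_along(genes)) {
      g <- genes[[i]]
      if (g$end > len) lancmine_error(sprintf("gene %s exceeds record length", g$locus_id))
      genes[[i]]$index <- i
    }
  }
  structure(list(record_id = record_id, organism = organism,
                 lineage = lineage, dna = dna, length_nt = len,
                 circular = circular, genes = genes),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d nt, %d genes, %s\n", x$record_id,
              x$length_nt, length(x$genes),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

gene_pid <- function(record_id, g) {
  if (!is.na(g$protein_id) && nzchar(g$protein_id)) g$protein_id
  else paste0(record_id, "|", g$locus_id)
}

## amino-acid sequences of a record's genes, named by protein id; genes
## lacking a /translation are translated in software (code 11)
record_proteins <- function(rec) {
  if (!length(rec$genes)) return(structure(character(0), names = character(0)))
  seqs <- vapply(rec$genes, function(g) {
    if (!is.na(g$protein_seq) && nzchar(g$protein_seq)) return(g$protein_seq)
    cds <- substr(rec$dna, g$start + 1L, g$end)
    if (g$strand == -1L) cds <- revcomp(cds)
    aa <- translate_dna(cds, init_met = TRUE)
    sub("\\*$", "", aa)
  }, character(1))
  names(seqs) <- vapply(rec$genes, function(g) gene_pid(rec$record_id, g), character(1))
  seqs
}

# ---------------------------------------------------------------------------
# GenBank flat-file I/O (minimal subset: LOCUS, DEFINITION, ORGANISM +
# lineage continuation lines, CDS features with complement(), /locus_tag,
# /protein_id, /product, /translation, ORIGIN). No R package in the stack
# parses GenBank, so this subset is implemented here and round-trip tested.
# ---------------------------------------------------------------------------

#' Read a GenBank flat file
#'
#' Returns one [genome_record()] per LOCUS. CDS features become gene
#' features with coordinates converted from GenBank 1-based inclusive to
#' internal 0-based half-open. Joined (multi-interval) CDS are skipped with
#' a warning; records without CDS features yield an empty gene list with a
#' warning.
#'
#' @param path GenBank flat file.
#' @return list of `genome_record`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) lancmine_error(sprintf("cannot read '%s'", path),
                                         "lancmine_io_error")
  lines <- readLines(path, warn = FALSE)
  bounds <- which(grepl("^LOCUS", lines))
  if (!length(bounds)) lancmine_error("no LOCUS line found", "lancmine_io_error")
  ends <- c(bounds[-1L] - 1L, length(lines))
  lapply(seq_along(bounds), function(i) {
    parse_genbank_record(lines[bounds[i]:ends[i]])
  })
}

parse_genbank_record <- function(lines) {
  locus_line <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  record_id <- locus_line[2L]
  circular <- any(tolower(locus_line) == "circular")

  organism <- ""
  lineage <- character(0)
  org_i <- grep("^  ORGANISM", lines)
  if (length(org_i)) {
    organism <- trimws(sub("^  ORGANISM", "", lines[org_i[1L]]))
    j <- org_i[1L] + 1L
    lin <- character(0)
    while (j <= length(lines) && grepl("^\\s{4,}\\S", lines[j]) &&
           !grepl("^\\S", lines[j])) {
      if (grepl("^(REFERENCE|FEATURES|COMMENT)", lines[j])) break
      lin <- c(lin, trimws(lines[j]))
      j <- j + 1L
    }
    if (length(lin)) {
      lineage <- strsplit(sub("\\.$", "", paste(lin, collapse = " ")), ";\\s*")[[1L]]
      lineage <- trimws(lineage[nzchar(trimws(lineage))])
    }
  }

  ## sequence
  ori <- grep("^ORIGIN", lines)
  dna <- ""
  if (length(ori)) {
    seq_lines <- lines[(ori[1L] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    dna <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  ## features
  feat_i <- grep("^FEATURES", lines)
  genes <- list()
  if (length(feat_i)) {
    fend <- if (length(ori)) ori[1L] - 1L else length(lines)
    flines <- lines[(feat_i[1L] + 1L):fend]
    key_i <- which(grepl("^ {5}\\S", flines))
    key_names <- vapply(strsplit(trimws(flines[key_i]), "\\s+"), `[`, character(1), 1L)
    cds_i <- key_i[key_names == "CDS"]
    key_ends <- c(key_i[-1L] - 1L, length(flines))
    names(key_ends) <- key_i
    for (ci in cds_i) {
      block <- flines[ci:key_ends[as.character(ci)]]
      g <- parse_cds_block(block)
      if (!is.null(g)) genes[[length(genes) + 1L]] <- g
    }
  }
  if (!length(genes))
    warning(sprintf("record %s has no parseable CDS features", record_id))
  genome_record(record_id, dna, genes, organism = organism,
                lineage = lineage, circular = circular)
}

parse_cds_block <- function(block) {
  loc <- trimws(sub("^ {5}CDS", "", block[1L]))
  quals <- paste(trimws(block[-1L]), collapse = "\n")
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order", loc)) {
    warning(sprintf("skipping multi-interval CDS at '%s'", loc))
    return(NULL)
  }
  m <- regmatches(loc, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", loc))[[1L]]
  if (length(m) != 3L) {
    warning(sprintf("skipping unparseable CDS location '%s'", loc))
    return(NULL)
  }
  start1 <- as.integer(m[2L]); end1 <- as.integer(m[3L])
  qual <- function(name) {
    mm <- regmatches(quals, regexec(sprintf('/%s="([^"]*)"', name), quals))[[1L]]
    if (length(mm) == 2L) gsub("\\s+", " ", mm[2L]) else NA_character_
  }
  translation <- qual("translation")
  if (!is.na(translation)) translation <- gsub(" ", "", translation)
  gene_feature(locus_id = if (!is.na(qual("locus_tag"))) qual("locus_tag")
                          else sprintf("cds_%d_%d", start1, end1),
               start = start1 - 1L, end = end1, strand = strand,
               protein_id = qual("protein_id"),
               product = if (!is.na(qual("product"))) qual("product") else "",
               protein_seq = translation)
}

#' Write a genome record as a GenBank flat file
#'
#' @param rec a `genome_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(rec, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %s %d bp    DNA     %s   BCT 01-JAN-1970",
     rec$record_id, rec$length_nt, if (rec$circular) "circular" else "linear")
  wl("DEFINITION  %s synthetic record.", rec$record_id)
  wl("SOURCE      %s", rec$organism)
  wl("  ORGANISM  %s", rec$organism)
  if (length(rec$lineage)) {
    lin <- paste0(paste(rec$lineage, collapse = "; "), ".")
    for (chunk in strwrap(lin, width = 67)) wl("            %s", chunk)
  }
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", rec$length_nt)
  for (g in rec$genes) {
    span <- sprintf("%d..%d", g$start + 1L, g$end)
    if (g$strand == -1L) span <- sprintf("complement(%s)", span)
    wl("     CDS             %s", span)
    wl("                     /locus_tag=\"%s\"", g$locus_id)
    if (!is.na(g$protein_id)) wl("                     /protein_id=\"%s\"", g$protein_id)
    if (nzchar(g$product)) wl("                     /product=\"%s\"", g$product)
    if (!is.na(g$protein_seq)) {
      tr <- sprintf("/translation=\"%s\"", g$protein_seq)
      for (chunk in substring(tr, seq(1L, nchar(tr), 58L),
                              pmin(seq(1L, nchar(tr), 58L) + 57L, nchar(tr))))
        wl("                     %s", chunk)
    }
  }
  wl("ORIGIN")
  dna <- tolower(rec$dna)
  for (off in seq(1L, nchar(dna), 60L)) {
    row <- substring(dna, off + 10L * (0:5), pmin(off + 10L * (0:5) + 9L, nchar(dna)))
    row <- row[nzchar(row)]
    wl("%9d %s", off, paste(row, collapse = " "))
  }
  wl("//")
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Extract the gene neighborhood around an anchor gene
#'
#' Includes up to `window` genes on each side of the anchor (truncated at
#' record ends; circular records are not wrapped). The neighborhood is
#' flagged `contig_edge` when its span starts within `edge_nt` of the record
#' start or ends within `edge_nt` of the record end; circular records are
#' never edge-flagged.
#'
#' @param record a `genome_record`.
#' @param anchor_index 1-based index of the anchor gene in `record$genes`.
#' @param window genes to include per side (default 7).
#' @param edge_nt contig-edge distance in nt (default 3000).
#' @return object of class `neighborhood`.
#' @export
extract_neighborhood <- function(record, anchor_index, window = 7L, edge_nt = 3000L) {
  n <- length(record$genes)
  if (anchor_index < 1L || anchor_index > n)
    lancmine_error("anchor_index out of range")
  lo <- max(1L, anchor_index - window)
  hi <- min(n, anchor_index + window)
  genes <- record$genes[lo:hi]
  span_start <- min(vapply(genes, `[[`, integer(1), "start"))
  span_end <- max(vapply(genes, `[[`, integer(1), "end"))
  edge <- !record$circular &&
    (span_start < edge_nt || (record$length_nt - span_end) < edge_nt)
  structure(list(record_id = record$record_id,
                 anchor = record$genes[[anchor_index]],
                 anchor_index = as.integer(anchor_index),
                 genes = genes,
                 span_start = span_start, span_end = span_end,
                 contig_edge = edge, window = as.integer(window)),
            class = "neighborhood")
}

#' Write mining outputs
#'
#' Writes a TSV of precursor calls (one row per call, fixed column set), a
#' GFF3 of precursor ORF coordinates (1-based inclusive), and a FASTA of
#' core peptides. Output bytes are stable across runs for an identical
#' report.
#'
#' @param report a `mining_report` from [summarize_mining()] or [run_mine()].
#' @param out_dir output directory (created if absent).
#' @param formats subset of `c("tsv", "gff3", "fasta")`.
#' @return named character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir, formats = c("tsv", "gff3", "fasta")) {
  formats <- match.arg(formats, several.ok = TRUE)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) lancmine_error(sprintf("cannot create '%s'", out_dir), "lancmine_io_error")
  pc <- report$precursor_calls
  out <- character(0)
  cols <- c("record_id", "bgc_id", "lan_class", "anchor_protein_id",
            "orf_start", "orf_end", "strand", "start_codon", "annotated",
            "leader_seq", "core_seq", "rule_used", "motif_name",
            "svm_decision", "svm_margin", "rubric_points", "total_score",
            "is_precursor")
  if ("tsv" %in% formats) {
    path <- file.path(out_dir, "precursor_calls.tsv")
    tab <- if (nrow(pc)) data.frame(
      record_id = pc$record_id, bgc_id = pc$bgc_id, lan_class = pc$lan_class,
      anchor_protein_id = pc$anchor_protein_id,
      orf_start = pc$start, orf_end = pc$end, strand = pc$strand,
      start_codon = pc$start_codon, annotated = pc$annotated,
      leader_seq = pc$leader, core_seq = pc$core, rule_used = pc$rule_used,
      motif_name = ifelse(is.na(pc$motif_name), ".", pc$motif_name),
      svm_decision = pc$svm_decision, svm_margin = fmt_num(pc$svm_margin),
      rubric_points = pc$rubric_points, total_score = pc$total_score,
      is_precursor = pc$is_precursor, stringsAsFactors = FALSE)
    else as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    lines <- c(paste(cols, collapse = "\t"),
               if (nrow(tab)) do.call(paste, c(unname(tab), sep = "\t")))
    writeLines(lines, path)
    out["tsv"] <- path
  }
  if ("gff3" %in% formats) {
    path <- file.path(out_dir, "precursor_orfs.gff3")
    lines <- "##gff-version 3"
    if (nrow(pc)) {
      attrs <- sprintf("ID=%s;bgc_id=%s;rule_used=%s;total_score=%d;is_precursor=%s",
                       pc$orf_id, pc$bgc_id, pc$rule_used, pc$total_score,
                       ifelse(pc$is_precursor, "true", "false"))
      lines <- c(lines, sprintf("%s\tlancmine\tCDS\t%d\t%d\t%s\t%s\t0\t%s",
                                pc$record_id, pc$start + 1L, pc$end,
                                fmt_num(pc$total_score),
                                ifelse(pc$strand == 1L, "+", "-"), attrs))
    }
    writeLines(lines, path)
    out["gff3"] <- path
  }
  if ("fasta" %in% formats) {
    path <- file.path(out_dir, "core_peptides.fasta")
    if (nrow(pc)) {
      seqs <- pc$core
      names(seqs) <- pc$orf_id
      write_fasta(seqs, path)
    } else writeLines(character(0), path)
    out["fasta"] <- path
  }
  invisible(out)
}

#' Re-read a precursor-call TSV written by [write_report()]
#'
#' @param path TSV file.
#' @return data.frame with the written columns (all character).
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", colClasses = "character",
                    stringsAsFactors = FALSE)
}
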