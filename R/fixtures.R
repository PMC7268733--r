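# Deterministic synthetic fixtures: alignment families for HMM building,
# genomes with planted LanC-anchored BGCs, and labeled peptide sets. All
# randomness flows from one seeded stream per call; no global RNG state
# leaks. Generated sequences are synthetic stand-ins for real domain
# families, not reproductions of any database entry.

## codon choices that never create an in-frame internal start codon
## (no ATG, GTG, TTG): planted ORFs then contain exactly one ORF per stop
SAFE_CODONS <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) {
      tab <- Biostrings::getGeneticCode("11")
      by_aa <- split(names(tab), tab)
      by_aa <- lapply(by_aa, setdiff, y = c("ATG", "GTG", "TTG"))
      by_aa$M <- "ATG"   # Met has no alternative; planted peptides avoid M
      gc <<- by_aa
    }
    gc
  }
})

reverse_translate <- function(protein, init_codon = "ATG") {
  aas <- split_chars(protein)
  safe <- SAFE_CODONS()
  codons <- vapply(aas, function(a) {
    opts <- safe[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  codons[1L] <- init_codon
  paste(codons, collapse = "")
}

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, rate) {
  aas <- split_chars(seq)
  hit <- stats::runif(length(aas)) < rate
  if (any(hit))
    aas[hit] <- vapply(aas[hit], function(a)
      sample(setdiff(AA20, a), 1L), character(1))
  paste(aas, collapse = "")
}

#' Generate a synthetic alignment family
#'
#' Samples `n_rows` sequences from a common random consensus, substituting
#' each column independently with probability `divergence`. The result is
#' an ungapped alignment whose consensus is stored as an attribute for
#' reuse by the genome generator.
#'
#' @param n_rows number of rows (>= 2).
#' @param length columns.
#' @param divergence per-column substitution probability.
#' @param seed RNG seed.
#' @param id alignment id.
#' @param consensus optional consensus to sample around (generated when NULL).
#' @return `aa_alignment` with attribute `consensus`.
#' @export
make_alignment_family <- function(n_rows, length, divergence, seed,
                                  id = sprintf("fam_s%d", seed),
                                  consensus = NULL) {
  stopifnot(n_rows >= 2L)
  with_seed(seed, {
    if (is.null(consensus)) consensus <- random_protein(length)
    rows <- vapply(seq_len(n_rows), function(i)
      mutate_protein(consensus, divergence), character(1))
    names(rows) <- sprintf("%s_r%02d", id, seq_len(n_rows))
    aln <- alignment(id, rows)
    attr(aln, "consensus") <- consensus
    aln
  })
}

#' Synthetic domain-family definitions for the fixture HMM set
#'
#' Defines the consensus sequences of the seven fixture roles. The class
#' III and class IV cyclase subfamilies are derived from the shared anchor
#' consensus (35% between-family divergence) so that the anchor model hits
#' members of both while the subfamily models separate them.
#'
#' @param seed RNG seed.
#' @return named list of family definitions (consensus, divergence).
#' @export
fixture_families <- function(seed = 101L) {
  with_seed(seed, {
    anchor_cons <- random_protein(110L)
    fams <- list(
      anchor = list(consensus = anchor_cons, divergence = 0.15),
      class3 = list(consensus = mutate_protein(anchor_cons, 0.35),
                    divergence = 0.10),
      class4 = list(consensus = mutate_protein(anchor_cons, 0.35),
                    divergence = 0.10),
      class1_n = list(consensus = random_protein(120L), divergence = 0.15),
      class1_c = list(consensus = random_protein(100L), divergence = 0.15),
      class2 = list(consensus = random_protein(130L), divergence = 0.15),
      kinase = list(consensus = random_protein(100L), divergence = 0.15))
    fams
  })
}

#' Build the fixture HMM set
#'
#' Builds one profile HMM per classifier role from synthetic alignment
#' families and returns a ready [classifier_config()]. Deterministic per
#' seed.
#'
#' @param dir directory for the HMM files.
#' @param seed family seed (must match the genomes mined against it).
#' @param n_rows alignment rows per family.
#' @return list with `config` (classifier_config), `families`, `dir`,
#'   and `paths`.
#' @export
fixture_hmm_set <- function(dir = tempfile("hmms"), seed = 101L, n_rows = 20L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fams <- fixture_families(seed)
  paths <- character(0)
  hmms <- lapply(seq_along(fams), function(i) {
    role <- names(fams)[i]
    fam <- fams[[i]]
    aln <- make_alignment_family(n_rows, nchar(fam$consensus), fam$divergence,
                                 seed = seed + i, id = paste0("fx_", role),
                                 consensus = fam$consensus)
    build_hmm(aln, paste0("fx_", role), file.path(dir, paste0(role, ".hmm")))
  })
  names(hmms) <- names(fams)
  list(config = classifier_config(anchor = hmms$anchor,
                                  class1_n = hmms$class1_n,
                                  class1_c = hmms$class1_c,
                                  class2 = hmms$class2,
                                  kinase = hmms$kinase,
                                  class3 = hmms$class3,
                                  class4 = hmms$class4),
       families = fams, dir = dir,
       paths = vapply(hmms, `[[`, character(1), "file"))
}

#' Fixture genome specification
#'
#' The stated world of the synthetic genomes: how many BGCs of which
#' classes are planted, the intergenic GC fraction, how many precursors
#' and rule-violating decoys accompany each BGC, which leader motif and
#' cleavage signal the precursors carry, and how Ser/Thr/Cys-rich their
#' cores are.
#'
#' @param seed genome RNG seed.
#' @param n_bgcs number of planted BGCs.
#' @param classes class labels recycled over the BGCs.
#' @param intergenic_gc GC fraction of intergenic sequence.
#' @param precursors_per_bgc planted precursor ORFs per BGC.
#' @param decoys_per_bgc decoy ORFs per BGC, cycling through the four
#'   filter rules (too_short, too_long, no_cys, nested).
#' @param leader_motif leader motif planted (FxLD, LxLxK5L, LxLQ, EDLM).
#' @param cleavage cleavage signal planted: GG, GA, STC, or none
#'   (C-terminal-half fallback).
#' @param core_stc_fraction target S+T+C fraction of planted cores.
#' @param contig_edge_case place the first BGC within 3 kb of the record
#'   start.
#' @param family_seed seed of the domain families (see [fixture_families()]).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_bgcs = 3L,
                         classes = c("I", "II", "III"),
                         intergenic_gc = 0.5, precursors_per_bgc = 1L,
                         decoys_per_bgc = 4L, leader_motif = "FxLD",
                         cleavage = "GG", core_stc_fraction = 0.5,
                         contig_edge_case = FALSE, family_seed = 101L) {
  stopifnot(intergenic_gc > 0, intergenic_gc < 1, precursors_per_bgc >= 0,
            cleavage %in% c("GG", "GA", "STC", "none"),
            leader_motif %in% c("FxLD", "LxLxK5L", "LxLQ", "EDLM"))
  structure(list(seed = as.integer(seed), n_bgcs = as.integer(n_bgcs),
                 classes = rep_len(classes, n_bgcs),
                 intergenic_gc = intergenic_gc,
                 precursors_per_bgc = as.integer(precursors_per_bgc),
                 decoys_per_bgc = as.integer(decoys_per_bgc),
                 leader_motif = leader_motif, cleavage = cleavage,
                 core_stc_fraction = core_stc_fraction,
                 contig_edge_case = isTRUE(contig_edge_case),
                 family_seed = as.integer(family_seed)),
            class = "fixture_spec")
}

## residue pools engineered so planted peptides contain no spurious
## leader/cleavage motif: no F/K/Q (motif starts), no G (GG/GA), no S/T
## outside planted positions, no M (in-frame ATG via reverse translation)
LEADER_POOL <- c("L", "I", "V", "E", "D", "N", "R", "H", "W", "Y", "P", "A")
CORE_POOL <- c("N", "I", "V", "L", "E", "D", "R", "H", "W", "Y", "P", "A")

plant_motif <- function(name) {
  x <- function() sample(setdiff(LEADER_POOL, c("L", "E", "D")), 1L)
  switch(name,
         FxLD = paste0("F", x(), "LD"),
         LxLxK5L = paste0("L", x(), "L", x(), "K",
                          paste(replicate(5L, x()), collapse = ""), "L"),
         LxLQ = paste0("L", x(), "LQ"),
         EDLM = paste0(sample(c("E", "D"), 1L), "L"),
         lancmine_error(sprintf("unknown fixture motif '%s'", name)))
}

## build one precursor peptide with a known boundary; returns peptide plus
## planted ground truth (validated against the real heuristics)
build_precursor_peptide <- function(spec) {
  for (attempt in 1:25) {
    pre <- random_protein(sample(4:7, 1L), LEADER_POOL)
    motif <- plant_motif(spec$leader_motif)
    post <- random_protein(sample(4:8, 1L), LEADER_POOL)
    core_len <- sample(22:30, 1L)
    stc <- c("S", "T", "C")
    core_body <- vapply(seq_len(core_len - 1L), function(i)
      if (stats::runif(1) < spec$core_stc_fraction) sample(stc, 1L)
      else sample(CORE_POOL, 1L), character(1))
    core <- paste0("I", paste(core_body, collapse = ""))
    if (spec$cleavage == "STC") {
      ## core = I S x x C ... : boundary lands 1 before the S
      mid <- split_chars(core)
      mid[2L] <- "S"
      mid[3:4] <- sample(CORE_POOL, 2L, replace = TRUE)
      mid[5L] <- "C"
      core <- paste(mid, collapse = "")
    }
    if (spec$cleavage == "none") {
      ## no S/T anywhere in the core: only GG/GA/STC-free fallback remains
      mid <- split_chars(core)
      mid[mid %in% c("S", "T")] <- sample(c("C", "N", "I", "V"),
                                          sum(mid %in% c("S", "T")),
                                          replace = TRUE)
      core <- paste(mid, collapse = "")
    }
    if (!grepl("C", core, fixed = TRUE)) {
      pos <- sample(2:nchar(core), 1L)
      core <- paste0(substr(core, 1L, pos - 1L), "C",
                     substr(core, pos + 1L, nchar(core)))
    }
    cleave <- switch(spec$cleavage, GG = "GG", GA = "GA", "")
    leader <- paste0("M", pre, motif, post, cleave)
    peptide <- paste0(leader, core)
    if (nchar(peptide) < 30L || nchar(peptide) > 120L) next

    expected_rule <- switch(spec$cleavage, GG = "GG", GA = "GA", STC = "STC",
                            none = "fallback-half")
    expected_boundary <- if (spec$cleavage == "none") nchar(peptide) %/% 2L
                         else nchar(leader)
    hit <- match_leader_motif(peptide)
    if (is.null(hit) || hit$motif_name != spec$leader_motif) next
    if (hit$match_start != 1L + nchar(pre)) next
    bc <- split_leader_core(peptide, hit)
    if (is.null(bc) || bc$rule_used != expected_rule ||
        bc$boundary != expected_boundary) next
    return(list(peptide = peptide, leader = bc$leader, core = bc$core,
                boundary = bc$boundary, rule = bc$rule_used,
                motif = spec$leader_motif, motif_start = hit$match_start))
  }
  lancmine_error("could not construct a valid planted precursor")
}

build_decoy_peptide <- function(rule) {
  pool_c <- c(CORE_POOL, "C", "S", "T")
  switch(rule,
         too_short = paste0("M", random_protein(17L, CORE_POOL), "C",
                            random_protein(1L, CORE_POOL)),
         too_long = paste0("M", random_protein(80L, pool_c), "C",
                           random_protein(48L, pool_c)),
         no_cys = paste0("M", random_protein(44L, CORE_POOL)),
         nested = paste0("M", random_protein(30L, pool_c), "C",
                         random_protein(8L, pool_c)),
         lancmine_error(sprintf("unknown decoy rule '%s'", rule)))
}

DECOY_RULES <- c("too_short", "too_long", "no_cys", "nested")

## intergenic filler between genes: target GC, rejection-sampled so no
## chunk-internal ORF of >= 30 aa exists on either strand
intergenic_dna <- function(len, gc, min_len_aa = 30L) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (attempt in 1:60) {
    s <- paste(sample(names(probs), len, replace = TRUE, prob = probs),
               collapse = "")
    orfs <- enumerate_orfs(s)
    if (!nrow(orfs) || max(nchar(orfs$aa_seq)) < min_len_aa) return(s)
  }
  lancmine_error("could not sample ORF-free intergenic sequence")
}

## genome flanks lie outside every anchor neighborhood span, so plain
## GC-targeted sampling suffices (no ORF rejection needed)
flank_dna <- function(len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate a synthetic genome with planted lanthipeptide BGCs
#'
#' Plants, per BGC: an anchor gene emitting a LanC-like fixture-family
#' protein (fused to a kinase-family domain for classes III/IV),
#' class-defining genes per class, intergenic precursor ORFs carrying the
#' requested leader motif and cleavage signal, and decoy ORFs violating
#' exactly one candidate-filter rule each. The generator validates its own
#' ground truth against the real ORF machinery (enumerate/filter/dedup over
#' each anchor neighborhood) and redraws on the rare background collision,
#' so the stated invariants hold for any seed. Deterministic per spec.
#'
#' @param spec a [fixture_spec()].
#' @param families domain families from [fixture_families()] (regenerated
#'   from `spec$family_seed` when NULL).
#' @return list with `record` (a `genome_record`) and `truth` (ground
#'   truth: `bgcs`, `precursors`, `decoys` data.frames).
#' @export
make_genome <- function(spec, families = NULL) {
  if (is.null(families)) families <- fixture_families(spec$family_seed)
  with_seed(spec$seed, {
    for (attempt in 1:10) {
      out <- try(build_genome_once(spec, families), silent = TRUE)
      if (!inherits(out, "try-error")) return(out)
    }
    lancmine_error(paste("fixture generation failed:",
                         attr(out, "condition")$message))
  })
}

build_genome_once <- function(spec, families) {
  parts <- character(0)
  cursor <- 0L
  genes <- list()
  truth_bgcs <- list(); truth_prec <- list(); truth_dec <- list()
  locus_n <- 0L

  emit <- function(dna) {
    parts[[length(parts) + 1L]] <<- dna
    start <- cursor
    cursor <<- cursor + nchar(dna)
    start
  }
  emit_intergenic <- function(len)
    emit(intergenic_dna(len, spec$intergenic_gc))
  next_locus <- function() {
    locus_n <<- locus_n + 1L
    sprintf("SYN_%04d", locus_n)
  }
  emit_gene <- function(protein, product, strand = 1L) {
    dna <- paste0(reverse_translate(protein), "TAA")
    if (strand == -1L) dna <- revcomp(dna)
    start <- emit(dna)
    locus <- next_locus()
    g <- gene_feature(locus, start, start + nchar(dna), strand,
                      protein_id = paste0(locus, "_p"), product = product,
                      protein_seq = protein)
    genes[[length(genes) + 1L]] <<- g
    g
  }
  sample_member <- function(role, pad_to = 140L) {
    fam <- families[[role]]
    p <- mutate_protein(fam$consensus, fam$divergence)
    if (nchar(p) < pad_to)
      p <- paste0(p, random_protein(pad_to - nchar(p)))
    p
  }
  filler_gene <- function()
    emit_gene(random_protein(sample(140:160, 1L)), "hypothetical protein")

  emit(flank_dna(if (spec$contig_edge_case) 500L else 3800L,
                 spec$intergenic_gc))

  for (b in seq_len(spec$n_bgcs)) {
    cls <- spec$classes[b]
    bgc_id <- sprintf("planted_%02d", b)
    if (b > 1L) for (k in 1:6) { filler_gene(); emit_intergenic(sample(120:200, 1L)) }

    filler_gene(); emit_intergenic(150L)
    if (cls == "I") {
      emit_gene(sample_member("class1_n"), "lanthipeptide dehydratase N-terminal domain protein")
      emit_intergenic(130L)
      emit_gene(sample_member("class1_c"), "lanthipeptide dehydratase C-terminal domain protein")
      emit_intergenic(130L)
      anchor <- emit_gene(sample_member("anchor"), "lanthipeptide cyclase")
    } else if (cls == "II") {
      emit_gene(sample_member("class2"), "lanthipeptide synthetase dehydratase domain protein")
      emit_intergenic(130L)
      anchor <- emit_gene(sample_member("anchor"), "lanthipeptide cyclase")
    } else {
      sub <- if (cls == "III") "class3" else "class4"
      fusion <- paste0(sample_member(sub, pad_to = 0L),
                       sample_member("kinase", pad_to = 0L))
      anchor <- emit_gene(fusion, "lanthipeptide synthetase (kinase-cyclase fusion)")
    }
    truth_bgcs[[b]] <- data.frame(
      bgc_id = bgc_id, lan_class = cls, anchor_locus = anchor$locus_id,
      anchor_protein_id = anchor$protein_id,
      anchor_start = anchor$start, anchor_end = anchor$end,
      stringsAsFactors = FALSE)

    emit_intergenic(140L)
    for (p in seq_len(spec$precursors_per_bgc)) {
      pp <- build_precursor_peptide(spec)
      dna <- paste0(reverse_translate(pp$peptide), "TAA")
      ## in-frame stop wall: no upstream start can share the planted stop
      start <- emit(paste0("TAA", dna)) + 3L
      truth_prec[[length(truth_prec) + 1L]] <- data.frame(
        bgc_id = bgc_id, start = start, end = start + nchar(dna),
        strand = 1L, peptide = pp$peptide, leader = pp$leader,
        core = pp$core, boundary = pp$boundary, rule = pp$rule,
        motif = pp$motif, stringsAsFactors = FALSE)
      emit_intergenic(120L)
    }

    for (d in seq_len(spec$decoys_per_bgc)) {
      rule <- DECOY_RULES[((d - 1L) %% 4L) + 1L]
      pep <- build_decoy_peptide(rule)
      dna <- paste0(reverse_translate(pep), "TAA")
      if (rule == "nested") {
        ## shim TAACTAA: a host-frame stop wall (host gene never yields an
        ## exact-span candidate ORF), a +1 frame shift for the decoy, and
        ## a decoy-frame stop wall blocking upstream start extension
        host_pre <- reverse_translate(random_protein(20L))
        host_post <- random_dna_codons(20L)
        host_dna <- paste0(host_pre, "TAACTAA", dna, "AA", host_post, "TAA")
        start <- emit(host_dna)
        locus <- next_locus()
        host_prot <- gsub("\\*", "X", translate_dna(
          substr(host_dna, 1L, nchar(host_dna) - 3L), init_met = TRUE))
        genes[[length(genes) + 1L]] <- gene_feature(
          locus, start, start + nchar(host_dna), 1L,
          protein_id = paste0(locus, "_p"),
          product = "hypothetical protein", protein_seq = host_prot)
        dstart <- start + nchar(host_pre) + 7L
        truth_dec[[length(truth_dec) + 1L]] <- data.frame(
          bgc_id = bgc_id, rule = rule, start = dstart,
          end = dstart + nchar(dna), strand = 1L, peptide = pep,
          stringsAsFactors = FALSE)
      } else {
        start <- emit(paste0("TAA", dna)) + 3L
        truth_dec[[length(truth_dec) + 1L]] <- data.frame(
          bgc_id = bgc_id, rule = rule, start = start,
          end = start + nchar(dna), strand = 1L, peptide = pep,
          stringsAsFactors = FALSE)
      }
      emit_intergenic(110L)
    }
    filler_gene()
    emit_intergenic(150L)
  }
  emit(flank_dna(3500L, spec$intergenic_gc))

  record <- genome_record(sprintf("SYNFIX_%04d", spec$seed),
                          paste(parts, collapse = ""), genes,
                          organism = "Synthetibacter fixturae (synthetic)",
                          lineage = c("Bacteria", "Synthetica",
                                      "Syntheticales", "Synthetibacteraceae"),
                          circular = FALSE)
  truth <- list(bgcs = do.call(rbind, truth_bgcs),
                precursors = if (length(truth_prec)) do.call(rbind, truth_prec)
                             else NULL,
                decoys = if (length(truth_dec)) do.call(rbind, truth_dec)
                         else NULL)
  validate_fixture(record, truth)
  list(record = record, truth = truth)
}

random_dna_codons <- function(n_codons) {
  reverse_translate(random_protein(n_codons))
}

## the generator's own contract check: planted precursors survive the
## candidate filters within their anchor neighborhood and decoys are
## enumerated but fail. Incidental background ORFs (e.g. reverse-strand
## reads straddling gene boundaries) are left in place deliberately --
## real neighborhoods contain them too, and rejecting them is the
## scorer's job, not the generator's.
validate_fixture <- function(record, truth) {
  key <- function(df) if (is.null(df) || !nrow(df)) character(0)
                      else sprintf("%d-%d-%d", df$start, df$end, df$strand)
  gene_starts <- vapply(record$genes, `[[`, integer(1), "start")
  for (i in seq_len(nrow(truth$bgcs))) {
    anchor_idx <- match(truth$bgcs$anchor_start[i], gene_starts)
    nb <- extract_neighborhood(record, anchor_idx)
    span <- substr(record$dna, nb$span_start + 1L, nb$span_end)
    orfs <- enumerate_orfs(span, nb$span_start, record_id = record$record_id)
    surv <- dedup_by_stop(filter_orfs(orfs, record$genes))
    bid <- truth$bgcs$bgc_id[i]
    prec <- truth$precursors[truth$precursors$bgc_id == bid, , drop = FALSE]
    dec <- truth$decoys[truth$decoys$bgc_id == bid, , drop = FALSE]
    if (!all(key(prec) %in% key(surv)))
      lancmine_error("planted precursor lost in filtering")
    if (any(key(dec) %in% key(surv)))
      lancmine_error("decoy survived filtering")
    if (!all(key(dec) %in% key(orfs)))
      lancmine_error("decoy not enumerated")
  }
  invisible(TRUE)
}

#' Generate labeled training peptides
#'
#' Positives are precursor-like peptides (leader motif, cleavage signal,
#' Ser/Thr/Cys-rich core); negatives are random peptides. `separation` in
#' [0, 1] is the structure strength: at 0 positives are drawn from the
#' same distribution as negatives (a label-permutation null), at >= 1 all
#' positives are fully structured. Deterministic per seed.
#'
#' @param n_pos,n_neg set sizes (>= 10).
#' @param separation structure strength, clamped to [0, 1].
#' @param seed RNG seed.
#' @param leader_motif,cleavage,core_stc_fraction passed to the precursor
#'   builder (see [fixture_spec()]).
#' @return data.frame with columns `id`, `seq`, `label` (1 = precursor).
#' @export
make_training_peptides <- function(n_pos, n_neg, separation, seed,
                                   leader_motif = "FxLD", cleavage = "GG",
                                   core_stc_fraction = 0.5) {
  stopifnot(n_pos >= 10L, n_neg >= 10L)
  s <- min(max(separation, 0), 1)
  pspec <- fixture_spec(seed = 1L, leader_motif = leader_motif,
                        cleavage = cleavage,
                        core_stc_fraction = core_stc_fraction)
  ## negatives emulate translation products of random noncoding DNA, so
  ## their residue composition follows the codon multiplicities of the
  ## genetic code rather than a uniform amino-acid draw
  code <- Biostrings::getGeneticCode("11")
  codon_aa <- table(code[code != "*"])
  aa_pool <- names(codon_aa)
  aa_prob <- as.numeric(codon_aa) / sum(codon_aa)
  with_seed(seed, {
    random_pep <- function() {
      n <- sample(40:60, 1L)
      pep <- paste0("M", paste(sample(aa_pool, n - 1L, replace = TRUE,
                                      prob = aa_prob), collapse = ""))
      half <- n %/% 2L
      if (!grepl("C", substr(pep, half + 1L, n), fixed = TRUE)) {
        pos <- sample((half + 1L):n, 1L)
        pep <- paste0(substr(pep, 1L, pos - 1L), "C",
                      substr(pep, pos + 1L, n))
      }
      pep
    }
    pos <- vapply(seq_len(n_pos), function(i)
      if (stats::runif(1) < s) build_precursor_peptide(pspec)$peptide
      else random_pep(), character(1))
    neg <- vapply(seq_len(n_neg), function(i) random_pep(), character(1))
    data.frame(id = c(sprintf("pos_%03d", seq_len(n_pos)),
                      sprintf("neg_%03d", seq_len(n_neg))),
               seq = c(pos, neg),
               label = rep(c(1L, 0L), c(n_pos, n_neg)),
               stringsAsFactors = FALSE)
  })
}

#' Write a fixture genome, its proteins, and its ground truth to disk
#'
#' @param genome result of [make_genome()].
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_fixture <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gb <- file.path(dir, paste0(genome$record$record_id, ".gbk"))
  write_genbank(genome$record, gb)
  fa <- file.path(dir, paste0(genome$record$record_id, ".faa"))
  write_fasta(record_proteins(genome$record), fa)
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(genome$truth, gt, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(genbank = gb, proteins = fa, truth = gt))
}
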