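#' Default leader-peptide motif library
#'
#' The motifs the mining heuristic consumes, shipped as data rather than
#' discovered de novo: FxLD (class I), LxLxKx5L (a class II leader motif),
#' LxLQ (class III/IV), the (E/D)(L/M) pair near the cleavage site, and a
#' terminal double-Gly. Patterns are regular expressions over amino acids;
#' library order encodes priority (most specific first).
#'
#' @return data.frame with columns `name`, `pattern` (class `motif_library`).
#' @export
default_motif_library <- function() {
  lib <- data.frame(
    name = c("LxLxK5L", "FxLD", "LxLQ", "EDLM", "GGterm"),
    pattern = c("L.L.K.{5}L", "F.LD", "L.LQ", "[ED][LM]", "GG"),
    stringsAsFactors = FALSE)
  class(lib) <- c("motif_library", "data.frame")
  lib
}

#' Read a motif library from JSON
#'
#' @param path JSON array of objects with `name` and `pattern` fields.
#' @return `motif_library` data.frame.
#' @export
read_motif_library <- function(path) {
  lib <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("name", "pattern") %in% names(lib)), nrow(lib) >= 1L)
  lib <- lib[, c("name", "pattern")]
  class(lib) <- c("motif_library", "data.frame")
  lib
}

## all match positions (0-based starts) of a regex, overlapping included
regex_starts0 <- function(peptide, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), peptide, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Locate a leader-peptide motif
#'
#' Scans the peptide with each library motif in priority order and returns
#' the first motif with a qualifying occurrence: the leftmost match whose
#' end lies within the N-terminal two thirds of the peptide. Returns NULL
#' when no motif qualifies.
#'
#' @param peptide amino-acid string.
#' @param library a motif library (see [default_motif_library()]).
#' @return list with `motif_name`, `match_start`, `match_end` (0-based,
#'   half-open), or NULL.
#' @export
match_leader_motif <- function(peptide, library = default_motif_library()) {
  stopifnot(nchar(peptide) >= 1L)
  limit <- (2L * nchar(peptide)) %/% 3L        # match end must be <= limit
  for (i in seq_len(nrow(library))) {
    m <- gregexpr(library$pattern[i], peptide, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m) - 1L
    ends <- starts + attr(m, "match.length")
    ok <- which(ends <= limit)
    if (length(ok)) {
      k <- ok[1L]
      return(list(motif_name = library$name[i],
                  match_start = starts[k], match_end = ends[k]))
    }
  }
  NULL
}

#' Leader/core boundary parameters
#'
#' @param cleavage_motifs protease-motif dipeptides searched for (GG, GA).
#' @param st_spacer_min,st_spacer_max spacer bounds of the S/T(x)2-7C rule.
#' @param c_term_exclusion candidate motifs starting within this many
#'   residues of the C-terminus are ignored.
#' @return object of class `boundary_params`.
#' @export
boundary_params <- function(cleavage_motifs = c("GG", "GA"),
                            st_spacer_min = 2L, st_spacer_max = 7L,
                            c_term_exclusion = 10L) {
  stopifnot(st_spacer_min <= st_spacer_max)
  structure(list(cleavage_motifs = cleavage_motifs,
                 st_spacer_min = as.integer(st_spacer_min),
                 st_spacer_max = as.integer(st_spacer_max),
                 c_term_exclusion = as.integer(c_term_exclusion)),
            class = "boundary_params")
}

#' Split a peptide into leader and core regions
#'
#' The region after the leader motif (the whole peptide when no motif hit
#' is supplied) is searched for GG/GA dipeptides and for S/T followed by a
#' Cys at a 2-7 residue spacer. A GG/GA occurrence puts the core start
#' immediately after the second residue; an S/T...C occurrence puts it one
#' residue before the S/T. Occurrences starting within `c_term_exclusion`
#' residues of the C-terminus, or leaving an empty leader, are ignored.
#' Among qualifying occurrences the one yielding the longest core wins
#' (ties broken GG before GA before S/T...C, then leftmost). With no
#' qualifying occurrence the C-terminal half is the core (the core takes
#' the extra residue of odd-length peptides). A call whose core contains
#' no Cys is rejected: the function returns NULL.
#'
#' @param peptide amino-acid string (length >= 4).
#' @param motif_hit result of [match_leader_motif()], or NULL.
#' @param params a [boundary_params()].
#' @return list of class `boundary_call` (fields `peptide`, `boundary`
#'   (0-based index where the core starts), `leader`, `core`, `rule_used`,
#'   `motif_name`), or NULL on rejection.
#' @export
split_leader_core <- function(peptide, motif_hit = NULL,
                              params = boundary_params()) {
  len <- nchar(peptide)
  stopifnot(len >= 4L)
  search_from <- if (is.null(motif_hit)) 0L else as.integer(motif_hit$match_end)

  cand <- data.frame(boundary = integer(0), rule = character(0),
                     occ = integer(0), prio = integer(0))
  add <- function(occ0, boundary, rule, prio) {
    ok <- occ0 >= search_from & occ0 < (len - params$c_term_exclusion) &
      boundary >= 1L & boundary <= len - 1L
    if (any(ok))
      cand <<- rbind(cand, data.frame(boundary = boundary[ok], rule = rule,
                                      occ = occ0[ok], prio = prio))
  }
  prio <- 1L
  for (cm in params$cleavage_motifs) {
    occ <- regex_starts0(peptide, paste0(substr(cm, 1, 1), "(?=",
                                         substr(cm, 2, 2), ")"))
    add(occ, occ + 2L, cm, prio)
    prio <- prio + 1L
  }
  st_pat <- sprintf("[ST](?=.{%d,%d}C)", params$st_spacer_min,
                    params$st_spacer_max)
  occ <- regex_starts0(peptide, st_pat)
  add(occ, occ - 1L, "STC", prio)

  if (nrow(cand)) {
    cand <- cand[order(cand$boundary, cand$prio, cand$occ), , drop = FALSE]
    boundary <- cand$boundary[1L]
    rule <- cand$rule[1L]
  } else {
    boundary <- len %/% 2L
    rule <- "fallback-half"
  }
  core <- substr(peptide, boundary + 1L, len)
  if (!grepl("C", core, fixed = TRUE)) return(NULL)
  structure(list(peptide = peptide, boundary = boundary,
                 leader = substr(peptide, 1L, boundary), core = core,
                 rule_used = rule,
                 motif_name = if (is.null(motif_hit)) NA_character_
                              else motif_hit$motif_name),
            class = "boundary_call")
}
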