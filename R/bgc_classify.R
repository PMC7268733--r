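#' Classifier configuration: the six domain-model roles
#'
#' Roles mirror the class rules of lanthipeptide mining: the LanC-like
#' cyclase anchor (PF05147 role), the split dehydratase pair for class I
#' (PF04738/PF14028 roles), the LanM dehydratase domain for class II
#' (PF13575 role), the protein kinase for class III/IV (PF00069 role), and
#' two custom LanC-like subfamily models separating class III (LanKC) from
#' class IV (LanL).
#'
#' @param anchor,class1_n,class1_c,class2,kinase,class3,class4 `profile_hmm`
#'   objects for each role.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(anchor, class1_n, class1_c, class2, kinase,
                              class3, class4) {
  cfg <- list(anchor = anchor, class1_n = class1_n, class1_c = class1_c,
              class2 = class2, kinase = kinase, class3 = class3,
              class4 = class4)
  for (role in names(cfg))
    if (!inherits(cfg[[role]], "profile_hmm"))
      lancmine_error(sprintf("role '%s' must be a profile_hmm", role))
  structure(cfg, class = "classifier_config")
}

#' Load a classifier configuration from a JSON role-to-path mapping
#'
#' @param path JSON file mapping role names (anchor, class1_n, class1_c,
#'   class2, kinase, class3, class4) to HMM file paths.
#' @return `classifier_config`.
#' @export
read_classifier_config <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  do.call(classifier_config,
          lapply(m[c("anchor", "class1_n", "class1_c", "class2", "kinase",
                     "class3", "class4")],
                 function(p) profile_hmm_from_file(resolve(p))))
}

config_hmms <- function(config) {
  list(config$anchor, config$class1_n, config$class1_c, config$class2,
       config$kinase, config$class3, config$class4)
}

#' Find LanC-like anchor proteins
#'
#' Searches the protein set with the anchor model at the backend's default
#' significance and keeps at most one hit per protein (best E-value).
#'
#' @param proteins named character vector of protein sequences.
#' @param config a [classifier_config()].
#' @return data.frame of hits, ascending E-value.
#' @export
find_lanc_proteins <- function(proteins, config) {
  hits <- hmm_search(config$anchor, proteins)
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$evalue, hits$protein_id), , drop = FALSE]
  hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assign a lanthipeptide class to a gene neighborhood
#'
#' The class rules fire independently: class I iff some neighborhood
#' protein(s) hit both dehydratase roles (split dehydratases on two
#' polypeptides still count); class II iff some protein hits the DUF4135
#' role; class III/IV iff the anchor protein itself hits both the anchor
#' and kinase models, split by the lower custom-subfamily E-value (ties,
#' including both-absent, resolve to III). When several rules fire the
#' label follows the precedence I > II > III/IV and `multi_class_flag` is
#' set; when none fire the neighborhood is `unclassified`.
#'
#' @param nbhd a `neighborhood`.
#' @param hits data.frame of HMM hits covering the neighborhood's proteins
#'   searched against all configured models.
#' @param config a [classifier_config()].
#' @param bgc_id identifier for the call.
#' @return object of class `bgc_call`.
#' @export
assign_class <- function(nbhd, hits, config, bgc_id = NULL) {
  pids <- vapply(nbhd$genes, function(g) gene_pid(nbhd$record_id, g), character(1))
  anchor_pid <- gene_pid(nbhd$record_id, nbhd$anchor)
  ev <- hits[hits$protein_id %in% pids, , drop = FALSE]
  if (!any(ev$protein_id == anchor_pid))
    lancmine_error(sprintf(
      "anchor protein '%s' absent from hits: pipeline bug", anchor_pid))

  has_role <- function(hmm, on = pids)
    any(ev$hmm_name == hmm$name & ev$protein_id %in% on)
  best_e <- function(hmm, on) {
    e <- ev$evalue[ev$hmm_name == hmm$name & ev$protein_id %in% on]
    if (length(e)) min(e) else Inf
  }

  fire_I <- has_role(config$class1_n) && has_role(config$class1_c)
  fire_II <- has_role(config$class2)
  fire_III_IV <- has_role(config$anchor, anchor_pid) &&
    has_role(config$kinase, anchor_pid)

  n_fired <- sum(fire_I, fire_II, fire_III_IV)
  lan_class <- if (fire_I) "I"
    else if (fire_II) "II"
    else if (fire_III_IV) {
      e3 <- best_e(config$class3, anchor_pid)
      e4 <- best_e(config$class4, anchor_pid)
      if (e3 <= e4) "III" else "IV"
    } else "unclassified"

  structure(list(neighborhood = nbhd, lan_class = lan_class,
                 evidence = ev, contig_edge = nbhd$contig_edge,
                 multi_class_flag = n_fired > 1L,
                 bgc_id = bgc_id %||%
                   sprintf("%s_bgc_%d", nbhd$record_id, nbhd$anchor_index)),
            class = "bgc_call")
}

#' @export
print.bgc_call <- function(x, ...) {
  cat(sprintf("<bgc_call> %s: class %s, %d genes, %d evidence hits%s%s\n",
              x$bgc_id, x$lan_class, length(x$neighborhood$genes),
              nrow(x$evidence),
              if (x$contig_edge) ", contig-edge" else "",
              if (x$multi_class_flag) ", multi-class" else ""))
  invisible(x)
}
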