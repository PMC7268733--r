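DIPEPTIDES <- as.vector(outer(AA20, AA20, paste0))

#' Feature catalog for precursor-peptide scoring
#'
#' A fixed, versioned ordering of the numeric features computed per
#' peptide: lengths of the full peptide, leader and core; per region
#' (full/leader/core) the 20 amino-acid counts and frequencies, Ser+Thr+Cys
#' count and fraction, net charge (K+R-D-E), mean Kyte-Doolittle
#' hydropathy, and aromaticity; dipeptide frequencies per region (400 x 3);
#' and one indicator per leader motif in the library. 1343 features with
#' the default library.
#'
#' @param motif_names motif names contributing indicator features.
#' @param version catalog version string.
#' @return object of class `feature_catalog`.
#' @export
feature_catalog <- function(motif_names = default_motif_library()$name,
                            version = "lancmine-1.0") {
  regions <- c("full", "leader", "core")
  per_region <- function(r) c(
    paste0("count_", AA20, "_", r), paste0("freq_", AA20, "_", r),
    paste0("stc_count_", r), paste0("stc_fraction_", r),
    paste0("net_charge_", r), paste0("hydropathy_", r),
    paste0("aromaticity_", r))
  nm <- c(paste0("len_", regions),
          unlist(lapply(regions, per_region)),
          unlist(lapply(regions, function(r) paste0("di_", DIPEPTIDES, "_", r))),
          paste0("motif_", motif_names))
  structure(list(version = version, names = nm,
                 motif_names = motif_names, n = length(nm)),
            class = "feature_catalog")
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %s: %d features\n", x$version, x$n))
  invisible(x)
}

region_features <- function(seq) {
  n <- nchar(seq)
  chars <- factor(split_chars(seq), levels = AA20)
  counts <- as.integer(table(chars))
  names(counts) <- AA20
  freq <- counts / n
  c(counts, freq,
    stc_count = sum(counts[c("S", "T", "C")]),
    stc_fraction = sum(freq[c("S", "T", "C")]),
    net_charge = sum(counts[c("K", "R")]) - sum(counts[c("D", "E")]),
    hydropathy = {
      h <- KD_HYDROPATHY[split_chars(seq)]
      h[is.na(h)] <- 0
      mean(h)
    },
    aromaticity = sum(freq[c("F", "W", "Y")]))
}

dipeptide_freqs <- function(seq) {
  n <- nchar(seq)
  if (n < 2L) return(setNames(numeric(400L), DIPEPTIDES))
  dp <- substring(seq, 1:(n - 1L), 2:n)
  counts <- table(factor(dp, levels = DIPEPTIDES))
  as.numeric(counts) / (n - 1L)
}

#' Compute the feature vector of a boundary call
#'
#' @param call a `boundary_call`.
#' @param catalog a [feature_catalog()].
#' @return named numeric vector aligned to the catalog (attribute
#'   `catalog_version` set).
#' @export
compute_features <- function(call, catalog = feature_catalog()) {
  regions <- list(full = call$peptide, leader = call$leader, core = call$core)
  v <- c(vapply(regions, nchar, integer(1)),
         unlist(lapply(regions, region_features), use.names = FALSE),
         unlist(lapply(regions, dipeptide_freqs), use.names = FALSE),
         as.numeric(!is.na(call$motif_name) &
                      catalog$motif_names == call$motif_name))
  names(v) <- catalog$names
  stopifnot(length(v) == catalog$n, all(is.finite(v)))
  attr(v, "catalog_version") <- catalog$version
  v
}

#' Feature matrix for a set of peptides
#'
#' Runs the motif -> boundary -> feature chain per peptide; peptides whose
#' boundary call is rejected (no core Cys) are dropped.
#'
#' @param peptides named character vector.
#' @param catalog a [feature_catalog()].
#' @param library motif library.
#' @param params boundary parameters.
#' @return list with `X` (matrix, rows = surviving peptides), `calls`
#'   (list of boundary calls), `kept` (logical over the input).
#' @export
featurize_peptides <- function(peptides, catalog = feature_catalog(),
                               library = default_motif_library(),
                               params = boundary_params()) {
  calls <- lapply(peptides, function(p)
    split_leader_core(p, match_leader_motif(p, library), params))
  kept <- !vapply(calls, is.null, logical(1))
  X <- do.call(rbind, lapply(calls[kept], compute_features, catalog = catalog))
  if (is.null(X)) X <- matrix(numeric(0), 0L, catalog$n,
                              dimnames = list(NULL, catalog$names))
  rownames(X) <- names(peptides)[kept]
  list(X = X, calls = calls[kept], kept = kept)
}

#' Training configuration
#'
#' @param anova_alpha feature-selection significance level (strict `<`).
#' @param cv_folds cross-validation folds.
#' @param seed RNG seed for fold assignment.
#' @param kernel SVM kernel (`rbf` only).
#' @param cost_grid,gamma_grid hyperparameter grids searched by CV;
#'   `gamma_grid = NULL` means 1 / n_selected_features.
#' @return object of class `training_config`.
#' @export
training_config <- function(anova_alpha = 0.05, cv_folds = 5L, seed = 1L,
                            kernel = "rbf", cost_grid = c(1, 10),
                            gamma_grid = NULL) {
  stopifnot(anova_alpha > 0, anova_alpha < 1, cv_folds >= 2L,
            kernel == "rbf")
  structure(list(anova_alpha = anova_alpha, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), kernel = kernel,
                 cost_grid = cost_grid, gamma_grid = gamma_grid),
            class = "training_config")
}

#' Select features by one-way ANOVA
#'
#' Computes the one-way F statistic between label groups for every
#' non-constant feature and selects those with p strictly below
#' `cfg$anova_alpha`. Zero-variance features are dropped before testing
#' and never selected.
#'
#' @param X numeric matrix (samples x features).
#' @param y label vector (2+ groups, each with >= 2 samples).
#' @param cfg a [training_config()].
#' @return logical mask over columns of `X`, with attribute `pvalues`
#'   (NA for dropped constants).
#' @export
select_features <- function(X, y, cfg = training_config()) {
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), nlevels(y) >= 2L,
            all(table(y) >= 2L))
  k <- nlevels(y)
  N <- nrow(X)
  variable <- apply(X, 2L, function(col) any(col != col[1L]))
  if (!any(variable)) lancmine_error("all features are constant")
  gm <- colMeans(X)
  ssb <- rep(0, ncol(X)); ssw <- rep(0, ncol(X))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    mg <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * (mg - gm)^2
    ssw <- ssw + colSums((X[idx, , drop = FALSE] -
                            matrix(mg, length(idx), ncol(X), byrow = TRUE))^2)
  }
  f <- (ssb / (k - 1L)) / (ssw / (N - k))
  p <- stats::pf(f, k - 1L, N - k, lower.tail = FALSE)
  p[!variable] <- NA_real_
  ## within-group-constant but between-group-different => ssw 0, F = Inf, p = 0
  p[variable & ssw == 0] <- 0
  mask <- variable & !is.na(p) & p < cfg$anova_alpha
  names(mask) <- colnames(X)
  attr(mask, "pvalues") <- p
  mask
}
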