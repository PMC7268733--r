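# RBF-kernel support vector machine trained by SMO (sequential minimal
# optimization) with maximal-violating-pair working-set selection on the
# standard C-SVC dual. Implemented in-package: no SVM library ships with
# the supported environment. Deterministic for fixed inputs.

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

## y in {-1, +1}; K precomputed kernel; returns alpha and intercept b
smo_solve <- function(K, y, C, tol = 1e-3, max_iter = 50000L) {
  n <- length(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)                        # grad of 0.5 a'Qa - e'a at a = 0
  Q <- K * tcrossprod(y)
  tau <- 1e-12
  for (iter in seq_len(max_iter)) {
    yg <- -y * grad
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    lo <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] < tol) break
    ai_old <- alpha[i]; aj_old <- alpha[j]
    if (y[i] != y[j]) {
      quad <- max(Q[i, i] + Q[j, j] + 2 * K[i, j], tau)
      delta <- (-grad[i] - grad[j]) / quad
      diff <- alpha[i] - alpha[j]
      alpha[i] <- alpha[i] + delta; alpha[j] <- alpha[j] + delta
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- diff }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- -diff }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] <- C; alpha[j] <- C - diff }
      } else {
        if (alpha[j] > C) { alpha[j] <- C; alpha[i] <- C + diff }
      }
    } else {
      quad <- max(Q[i, i] + Q[j, j] - 2 * K[i, j], tau)
      delta <- (grad[i] - grad[j]) / quad
      s <- alpha[i] + alpha[j]
      alpha[i] <- alpha[i] - delta; alpha[j] <- alpha[j] + delta
      if (s > C) {
        if (alpha[i] > C) { alpha[i] <- C; alpha[j] <- s - C }
      } else {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- s }
      }
      if (s > C) {
        if (alpha[j] > C) { alpha[j] <- C; alpha[i] <- s - C }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- s }
      }
    }
    grad <- grad + Q[, i] * (alpha[i] - ai_old) + Q[, j] * (alpha[j] - aj_old)
  }
  free <- alpha > tau & alpha < C - tau
  b <- if (any(free)) mean((-y * grad)[free]) else {
    yg <- -y * grad
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    lo <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    (max(yg[lo], -Inf) + min(yg[up], Inf)) / 2
  }
  list(alpha = alpha, b = b)
}

svm_fit <- function(X, y, C, gamma) {
  K <- rbf_kernel(X, X, gamma)
  sol <- smo_solve(K, y, C)
  sv <- sol$alpha > 1e-8
  list(sv_x = X[sv, , drop = FALSE], sv_coef = (sol$alpha * y)[sv],
       b = sol$b, gamma = gamma, C = C)
}

svm_decision_values <- function(fit, X) {
  if (!nrow(fit$sv_x)) return(rep(fit$b, nrow(X)))
  as.numeric(rbf_kernel(X, fit$sv_x, fit$gamma) %*% fit$sv_coef + fit$b)
}

#' Train the precursor-peptide SVM
#'
#' Standardizes the ANOVA-selected features with training-set mean/sd,
#' grid-searches cost (and optionally gamma) by k-fold cross-validation
#' with seeded fold assignment, and refits on the full data. Binary labels
#' only.
#'
#' @param X feature matrix (samples x catalog features).
#' @param y binary labels (coerced to factor; second level is positive).
#' @param mask logical feature mask from [select_features()].
#' @param cfg a [training_config()].
#' @param lan_class lanthipeptide class the model applies to.
#' @param catalog_version catalog version the mask refers to.
#' @return object of class `lancmine_svm` with cross-validated accuracy in
#'   `$cv_accuracy`.
#' @export
train_svm <- function(X, y, mask, cfg = training_config(), lan_class = "II",
                      catalog_version = "lancmine-1.0") {
  y <- as.factor(y)
  if (nlevels(y) != 2L) lancmine_error("training labels must have exactly 2 classes")
  stopifnot(length(mask) == ncol(X))
  sel <- which(mask)
  if (!length(sel)) lancmine_error(
    "no features selected; lower anova_alpha stringency or provide more data")
  Xs <- X[, sel, drop = FALSE]
  yn <- ifelse(y == levels(y)[2L], 1, -1)
  n <- nrow(Xs)

  gamma_grid <- cfg$gamma_grid %||% (1 / length(sel))
  grid <- expand.grid(C = cfg$cost_grid, gamma = gamma_grid)
  folds <- with_seed(cfg$seed, sample(rep_len(seq_len(cfg$cv_folds), n)))

  standardize <- function(M, center = NULL, scale = NULL) {
    if (is.null(center)) {
      center <- colMeans(M)
      scale <- apply(M, 2L, stats::sd)
      scale[scale == 0] <- 1
    }
    list(M = sweep(sweep(M, 2L, center), 2L, scale, "/"),
         center = center, scale = scale)
  }

  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(cfg$cv_folds)) {
      tr <- folds != f
      std <- standardize(Xs[tr, , drop = FALSE])
      fit <- svm_fit(std$M, yn[tr], grid$C[g], grid$gamma[g])
      te <- standardize(Xs[!tr, , drop = FALSE], std$center, std$scale)$M
      pred <- sign(svm_decision_values(fit, te))
      correct <- correct + sum(pred == yn[!tr])
    }
    correct / n
  }, numeric(1))

  best <- which.max(cv_acc)
  std <- standardize(Xs)
  fit <- svm_fit(std$M, yn, grid$C[best], grid$gamma[best])

  structure(list(lan_class = lan_class, selected_mask = as.logical(mask),
                 feature_names = colnames(X)[sel],
                 center = std$center, scale = std$scale,
                 kernel = "rbf",
                 hyperparameters = list(C = grid$C[best],
                                        gamma = grid$gamma[best]),
                 decision_threshold = 0,
                 fit = fit,
                 cv_accuracy = cv_acc[best],
                 cv_grid = cbind(grid, accuracy = cv_acc),
                 n_pos = sum(yn == 1), n_neg = sum(yn == -1),
                 seed = cfg$seed,
                 positive_label = levels(y)[2L],
                 catalog_version = catalog_version),
            class = "lancmine_svm")
}

#' @export
print.lancmine_svm <- function(x, ...) {
  cat(sprintf(paste0("<lancmine_svm> class %s: %d selected features, ",
                     "C=%g gamma=%.4g, CV accuracy %.3f (n=%d+%d)\n"),
              x$lan_class, length(x$feature_names), x$hyperparameters$C,
              x$hyperparameters$gamma, x$cv_accuracy, x$n_pos, x$n_neg))
  invisible(x)
}

#' Predict with a trained precursor SVM
#'
#' @param object a `lancmine_svm`.
#' @param newdata feature matrix aligned to the training catalog.
#' @param ... unused.
#' @return data.frame with `margin` (decision value) and `decision`
#'   (logical, margin above the model threshold).
#' @export
predict.lancmine_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1L,
                                               dimnames = list(NULL, names(newdata)))
  Xs <- newdata[, object$selected_mask, drop = FALSE]
  Xs <- sweep(sweep(Xs, 2L, object$center), 2L, object$scale, "/")
  margin <- svm_decision_values(object$fit, Xs)
  data.frame(margin = margin,
             decision = margin > object$decision_threshold)
}

#' Save / load a trained model bundle
#'
#' The bundle is a single serialized file pinning the catalog version.
#'
#' @param model a `lancmine_svm`.
#' @param path bundle file.
#' @return `path` (write) or the model (read).
#' @export
write_svm_bundle <- function(model, path) {
  stopifnot(inherits(model, "lancmine_svm"))
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname write_svm_bundle
#' @export
read_svm_bundle <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "lancmine_svm"))
    lancmine_error("file is not a lancmine model bundle")
  model
}
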