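#' Default SVM hyperparameter grid
#'
#' Growing power-of-two sequences spanning `C` in `[2^-5, 2^15]` and `gamma`
#' in `[2^-15, 2^3]` (exponent step 2 — the conventional coarse grid for the
#' RBF kernel), with 10-fold cross-validation.
#'
#' @param C,gamma Candidate values (positive).
#' @param k Number of cross-validation folds.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(C = 2^seq(-5, 15, by = 2),
                      gamma = 2^seq(-15, 3, by = 2),
                      k = 10) {
  if (length(C) == 0 || length(gamma) == 0 || any(C <= 0) || any(gamma <= 0)) {
    abort("`C` and `gamma` grids must be non-empty and positive.",
          class = "connectoms_range_error")
  }
  structure(list(C = C, gamma = gamma, k = as.integer(k)), class = "grid_spec")
}

#' Radial basis function kernel
#'
#' `K(x, y) = exp(-||x - y||^2 * gamma)`; equals 1 iff `x == y`.
#'
#' @param x,y Equal-length numeric vectors.
#' @param gamma Kernel width parameter (> 0).
#' @return Kernel value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    abort("`gamma` must be a single positive number.",
          class = "connectoms_range_error")
  }
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "connectoms_range_error")
  }
  exp(-sum((x - y)^2) * gamma)
}

#' Standardize features using training-set statistics only
#'
#' Centers and scales each feature by the training rows' mean and standard
#' deviation, then applies the same transformation to `apply_rows` — the
#' leakage-safe pattern used inside every cross-validation fold. Features
#' that are constant in the training rows get their scale clamped to 1 with
#' a warning.
#'
#' @param train_rows Data frame of training rows.
#' @param apply_rows Data frame to transform with the training parameters
#'   (default: the training rows themselves).
#' @param features Columns to standardize (default: all numeric columns).
#' @return List with `train`, `apply` (transformed data frames), `center`
#'   and `scale` (named numeric vectors).
#' @export
standardize <- function(train_rows, apply_rows = train_rows, features = NULL) {
  if (nrow(train_rows) == 0) {
    abort("Empty training set.", class = "connectoms_invalid_input")
  }
  if (is.null(features)) {
    features <- names(train_rows)[vapply(train_rows, is.numeric, logical(1))]
  }
  center <- vapply(train_rows[features], mean, numeric(1), na.rm = TRUE)
  scale <- vapply(train_rows[features], sd, numeric(1), na.rm = TRUE)
  const <- is.na(scale) | scale < 1e-12
  if (any(const)) {
    warn(sprintf("Constant feature(s) %s: scale clamped to 1.",
                 paste(features[const], collapse = ", ")))
    scale[const] <- 1
  }
  tf <- function(df) {
    df[features] <- purrr::map2(df[features], seq_along(features),
                                function(v, i) (v - center[i]) / scale[i])
    df
  }
  list(train = tf(train_rows), apply = tf(apply_rows),
       center = center, scale = scale)
}

# Fit impute-then-standardize parameters on training rows; NA feature values
# are replaced by the training-fold feature mean (count reported upstream).
prep_fit <- function(train_x) {
  means <- vapply(train_x, mean, numeric(1), na.rm = TRUE)
  means[is.na(means)] <- 0
  imputed <- purrr::imap_dfc(train_x, function(v, nm) {
    v[is.na(v)] <- means[nm]
    v
  })
  std <- suppressWarnings(standardize(imputed))
  list(impute = means, center = std$center, scale = std$scale,
       n_imputed = sum(is.na(train_x)))
}

prep_apply <- function(prep, x) {
  out <- purrr::imap_dfc(x, function(v, nm) {
    v[is.na(v)] <- prep$impute[nm]
    (v - prep$center[nm]) / prep$scale[nm]
  })
  as.matrix(out)
}

#' Train a soft-margin SVM with RBF kernel
#'
#' Solves the dual soft-margin problem (via libsvm) on standardized
#' features; for binary labels the dual coefficients are extracted and
#' checked against the KKT box constraint `0 <= alpha_i <= C` and the
#' equality `sum(alpha_i y_i) = 0` (within 1e-6). The decision value of a
#' point `x` is `sum_i alpha_i y_i K(x_i, x) + b`.
#'
#' @param rows Data frame with one label column and numeric feature columns.
#' @param C Error penalty (> 0).
#' @param gamma RBF kernel parameter (> 0).
#' @param label Name of the label column (default `"group"`).
#' @param features Feature columns (default: all numeric columns).
#' @return A `connectome_svm` model object.
#' @export
train_svm <- function(rows, C = 1, gamma = 1, label = "group",
                      features = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))], label)
  }
  y <- droplevels(factor(rows[[label]]))
  if (nlevels(y) < 2) {
    abort("Training data must contain at least two classes.",
          class = "connectoms_invalid_input")
  }
  prep <- prep_fit(rows[features])
  x <- prep_apply(prep, rows[features])
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  dual <- NULL
  if (nlevels(y) == 2) {
    alpha_y <- as.numeric(fit$coefs) # y_i * alpha_i for the support vectors
    dual <- list(
      alpha = abs(alpha_y),
      sum_alpha_y = sum(alpha_y),
      max_box_violation = max(0, max(abs(alpha_y)) - C),
      b = -fit$rho
    )
  }
  structure(
    list(fit = fit, C = C, gamma = gamma, label = label, features = features,
         levels = levels(y), prep = prep, dual = dual, n = nrow(rows)),
    class = "connectome_svm"
  )
}

#' @export
predict.connectome_svm <- function(object, newdata, decision_values = FALSE, ...) {
  x <- prep_apply(object$prep, newdata[object$features])
  p <- predict(object$fit, x, decision.values = decision_values)
  if (decision_values) {
    attr(p, "decision.values") <- attr(p, "decision.values")
  }
  p
}

#' @export
print.connectome_svm <- function(x, ...) {
  cat(sprintf("<connectome_svm> %s | C = %g, gamma = %g, %d SV, n = %d\n",
              paste(x$levels, collapse = " vs "), x$C, x$gamma,
              x$fit$tot.nSV, x$n))
  invisible(x)
}

#' @rdname train_svm
#' @param x A `connectome_svm` model.
#' @param ... Unused.
#' @export
tidy.connectome_svm <- function(x, ...) {
  sv <- x$fit$index
  if (is.null(x$dual)) {
    return(tibble(sv_index = sv))
  }
  tibble(sv_index = sv, alpha = x$dual$alpha,
         alpha_y = as.numeric(x$fit$coefs))
}

#' @rdname train_svm
#' @export
glance.connectome_svm <- function(x, ...) {
  tibble(
    n = x$n, n_sv = x$fit$tot.nSV, C = x$C, gamma = x$gamma,
    bias = if (is.null(x$dual)) NA_real_ else x$dual$b,
    sum_alpha_y = if (is.null(x$dual)) NA_real_ else x$dual$sum_alpha_y,
    max_box_violation = if (is.null(x$dual)) NA_real_ else x$dual$max_box_violation
  )
}

#' Stratified cross-validation folds
#'
#' Assigns each row to exactly one test fold, stratifying by label so every
#' fold sees (approximately) the class proportions of the whole table.
#'
#' @param y Label vector.
#' @param k Number of folds (`<= length(y)`).
#' @param seed RNG seed; the caller's RNG state is preserved.
#' @return Integer vector of fold ids in `1..k`.
#' @export
cv_folds <- function(y, k, seed = 1L) {
  n <- length(y)
  if (n < k) {
    abort(sprintf("Cannot make %d folds from %d rows.", k, n),
          class = "connectoms_fold_error")
  }
  folds <- integer(n)
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(sample(k), length(idx))
    }
  })
  folds
}

#' Precision, recall, and F-measure from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`; a zero denominator
#' yields a flagged 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (vectorized).
#' @return Tibble with `precision`, `recall`, `f_measure`.
#' @export
precision_recall_f <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) {
    abort("Confusion counts must be non-negative.",
          class = "connectoms_range_error")
  }
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  tibble(precision = p, recall = r, f_measure = f)
}

# Per-class confusion counts and support-weighted aggregate P/R/F.
confusion_report <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  per_class <- purrr::map_dfr(levels(truth), function(cls) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    tn <- sum(truth != cls & pred != cls)
    dplyr::bind_cols(
      tibble(class = cls, support = sum(truth == cls),
             tp = tp, fp = fp, tn = tn, fn = fn),
      precision_recall_f(tp, fp, tn, fn)
    )
  })
  w <- per_class$support / sum(per_class$support)
  aggregate <- tibble(
    precision = sum(w * per_class$precision),
    recall = sum(w * per_class$recall),
    f_measure = sum(w * per_class$f_measure)
  )
  list(per_class = per_class, aggregate = aggregate)
}

#' Grid search over (C, gamma) with stratified K-fold cross-validation
#'
#' For each hyperparameter pair, out-of-fold predictions are collected with
#' imputation and standardization re-fitted inside each training fold (no
#' information from held-out rows enters the preprocessing), confusion
#' counts are pooled over folds, and the support-weighted F-measure scored.
#' The best pair (ties: smaller `C`, then smaller `gamma`) is returned with
#' its fold-aggregated report. Deterministic given `seed`.
#'
#' @param rows Data frame with a label column and numeric features.
#' @param grid A [grid_spec()].
#' @param seed RNG seed for the fold assignment.
#' @param label Label column name.
#' @param features Feature columns (default: all numeric columns).
#' @param diagnostics Keep per-fold preprocessing parameters? (used to audit
#'   the no-leakage contract).
#' @return List with `best_C`, `best_gamma`, `cv_results` (one row per grid
#'   pair), `report` (per-class + aggregate for the best pair), `folds`, and
#'   optionally `fold_prep`.
#' @export
grid_search_cv <- function(rows, grid = grid_spec(), seed = 1L,
                           label = "group", features = NULL,
                           diagnostics = FALSE) {
  y <- droplevels(factor(rows[[label]]))
  if (is.null(features)) {
    features <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))], label)
  }
  k <- min(grid$k, min(table(y)))
  if (k < grid$k) {
    warn(sprintf("Smallest class has %d members; folds reduced from %d to %d.",
                 min(table(y)), grid$k, k))
  }
  folds <- cv_folds(y, k, seed = seed)
  n_imputed <- sum(is.na(rows[features]))
  if (n_imputed > 0) {
    warn(sprintf("%d missing feature values will be imputed with training-fold means.",
                 n_imputed))
  }
  fold_prep <- vector("list", k)
  pairs <- expand.grid(C = grid$C, gamma = grid$gamma, KEEP.OUT.ATTRS = FALSE)
  evaluate_pair <- function(C, gamma, keep_prep = FALSE) {
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (fold in seq_len(k)) {
      tr <- folds != fold
      model <- suppressWarnings(
        train_svm(rows[tr, , drop = FALSE], C = C, gamma = gamma,
                  label = label, features = features)
      )
      if (keep_prep) fold_prep[[fold]] <<- model$prep
      pred[!tr] <- predict(model, rows[!tr, , drop = FALSE])
    }
    list(pred = pred, report = confusion_report(y, pred))
  }
  cv_results <- purrr::pmap_dfr(pairs, function(C, gamma) {
    res <- evaluate_pair(C, gamma)
    dplyr::bind_cols(tibble(C = C, gamma = gamma), res$report$aggregate)
  })
  ord <- order(-cv_results$f_measure, cv_results$C, cv_results$gamma)
  best <- cv_results[ord[1], ]
  best_res <- evaluate_pair(best$C, best$gamma, keep_prep = diagnostics)
  out <- list(best_C = best$C, best_gamma = best$gamma,
              cv_results = cv_results, report = best_res$report,
              folds = folds, k = k, n_imputed = n_imputed)
  if (diagnostics) out$fold_prep <- fold_prep
  out
}

#' Run one classification task on a cohort metric table
#'
#' Restricts the metric table to the requested groups and feature columns,
#' grid-searches the RBF-SVM hyperparameters with stratified
#' cross-validation, and reports precision, recall and F-measure. With more
#' than two groups the underlying solver uses one-vs-one voting. The
#' aggregate triple is the support-weighted average over classes (per-class
#' values are also kept); for binary tasks each group in turn plays the
#' positive class in its per-class row.
#'
#' @param cohort_metrics Metric table from [connectome_metrics()].
#' @param groups Character vector of 2+ group labels (subset of
#'   HC/CIS/RR/SP/PP).
#' @param features `"all"` or a subset of `c("D","r","T","Eg","Q","CPL")`.
#' @param grid A [grid_spec()].
#' @param seed RNG seed.
#' @return A `classification_report` object.
#' @export
run_task <- function(cohort_metrics, groups, features = "all",
                     grid = grid_spec(), seed = 1L) {
  bad <- setdiff(groups, GROUP_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("Unknown group(s): %s. Valid: %s.",
                  paste(bad, collapse = ", "),
                  paste(GROUP_LEVELS, collapse = ", ")),
          class = "connectoms_invalid_input")
  }
  feat <- if (identical(features, "all")) METRIC_COLS else features
  bad_f <- setdiff(feat, METRIC_COLS)
  if (length(bad_f) > 0) {
    abort(sprintf("Unknown metric(s): %s. Valid: %s.",
                  paste(bad_f, collapse = ", "),
                  paste(METRIC_COLS, collapse = ", ")),
          class = "connectoms_invalid_input")
  }
  rows <- cohort_metrics[cohort_metrics$group %in% groups, ]
  rows$group <- droplevels(factor(rows$group, levels = GROUP_LEVELS))
  if (nlevels(rows$group) < length(groups)) {
    abort("Some requested groups have no subjects in the metric table.",
          class = "connectoms_invalid_input")
  }
  gs <- grid_search_cv(rows, grid = grid, seed = seed, label = "group",
                       features = feat)
  structure(
    list(task = paste(groups, collapse = "-"),
         feature_set = if (identical(features, "all")) "All"
                       else paste(feat, collapse = "+"),
         per_class = gs$report$per_class,
         aggregate = gs$report$aggregate,
         best_C = gs$best_C, best_gamma = gs$best_gamma,
         k = gs$k, n = nrow(rows), n_imputed = gs$n_imputed,
         averaging = "support-weighted one-vs-rest over classes"),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> task %s | features %s | n = %d, %d-fold CV\n",
              x$task, x$feature_set, x$n, x$k))
  cat(sprintf("  best C = %g, gamma = %g | P = %.3f, R = %.3f, F = %.3f (%s)\n",
              x$best_C, x$best_gamma, x$aggregate$precision,
              x$aggregate$recall, x$aggregate$f_measure, x$averaging))
  invisible(x)
}

#' @rdname run_task
#' @param x A `classification_report`.
#' @param ... Unused.
#' @export
tidy.classification_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(task = x$task, feature_set = x$feature_set),
    x$per_class
  )
}

#' @rdname run_task
#' @export
glance.classification_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(task = x$task, feature_set = x$feature_set, n = x$n, k = x$k,
           C = x$best_C, gamma = x$best_gamma),
    x$aggregate
  )
}
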