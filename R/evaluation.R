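# Evaluation: label generation from model-vs-native superposition,
# accuracy and MCC, 5-fold cross-validation, neighbour-cutoff comparison
# and the secondary-structure edge-weight grid search.

#' Generate true per-residue labels from a native structure
#'
#' After global superposition of the model onto the native, a residue gets
#' label 1 ("good", within cutoff) when its Calpha-Calpha distance is
#' strictly below `ca_cutoff`, else 0. Residues absent from the native are
#' unscored (`NA`).
#'
#' @param model,native StructureModel objects
#' @param ca_cutoff Calpha error cutoff in Angstrom (2, 4, 5, 6 and 8 are
#'   the conventional choices)
#' @return integer vector of 0/1/NA labels, one per model residue
#' @export
make_labels <- function(model, native, ca_cutoff = 5.0) {
  sp <- superpose(model, native)
  d <- sp$per_residue_distance
  lab <- rep(NA_integer_, length(d))
  lab[!is.na(d)] <- as.integer(d[!is.na(d)] < ca_cutoff)
  lab
}

#' Classification accuracy over scored residues
#'
#' @param pred,truth 0/1 label vectors of equal length; `NA` in either
#'   marks an unscored residue, excluded from the denominator
#' @return fraction correct in [0, 1]
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok)) stop("undefined: no scored residues")
  mean(pred[ok] == truth[ok])
}

#' Confusion table of a binary prediction
#'
#' Label 1 ("within cutoff") is the positive class.
#'
#' @param pred,truth 0/1 label vectors (`NA` = unscored, excluded)
#' @return an object of class `ConfusionTable` with tp, fp, tn, fn
#' @export
confusion_table <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  p <- pred[ok]; t <- truth[ok]
  structure(list(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
                 tn = sum(p == 0 & t == 0), fn = sum(p == 0 & t == 1)),
            class = "ConfusionTable")
}

#' @export
print.ConfusionTable <- function(x, ...) {
  cat(sprintf("ConfusionTable: tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' Returns `NA` (an explicit undefined marker, not 0) whenever any factor
#' of the denominator is zero — e.g. an all-positive prediction, where
#' both true negatives and false negatives are 0.
#'
#' @param table a [confusion_table()], or tp count when the individual
#'   counts are given
#' @param fp,tn,fn individual counts (when `table` is numeric tp)
#' @return MCC in [-1, 1], or `NA_real_` when undefined
#' @export
mcc <- function(table, fp = NULL, tn = NULL, fn = NULL) {
  if (inherits(table, "ConfusionTable")) {
    tp <- table$tp; fp <- table$fp; tn <- table$tn; fn <- table$fn
  } else {
    tp <- table
  }
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(NA_real_)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
}

#' Two-sided paired t-test
#'
#' @param a,b paired numeric vectors (e.g. per-target accuracies of two
#'   methods), length >= 2
#' @return p-value, or `NA` when the differences have zero variance
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  d <- a - b
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) return(NA_real_)
  tstat <- mean(d) / (s / sqrt(n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

#' Dataset entry for cross-validation
#'
#' Bundles one structure model with its raw (unnormalised) feature matrix,
#' true labels and secondary structure, so that Z-scoring and training can
#' be redone per fold on training folds only.
#'
#' @param model a StructureModel
#' @param features raw feature matrix (residues x m)
#' @param labels 0/1 true labels
#' @param ss secondary-structure string (computed when `NULL`)
#' @return a list of class `gmq_entry`
#' @export
gmq_entry <- function(model, features, labels, ss = NULL) {
  if (is.null(ss)) ss <- assign_secondary_structure(model)
  structure(list(model = model, features = as.matrix(features),
                 labels = as.integer(labels), ss = ss),
            class = "gmq_entry")
}

# Seeded model-level fold assignment.
cv_folds <- function(n_models, k, seed) {
  if (n_models < k) {
    stop(sprintf("fewer models (%d) than folds (%d)", n_models, k))
  }
  with_seed(seed, sample(rep(seq_len(k), length.out = n_models)))
}

# Train on a list of entries and predict another list; normalisation is
# fitted on the training residues only. Returns per-model accuracies.
train_predict_entries <- function(train, test, neighbor_cutoff, w,
                                  learning_rate, epochs, l2_penalty, seed,
                                  method = c("crf", "logistic"),
                                  average_tail = 0L) {
  method <- match.arg(method)
  zfit <- zscore_fit(do.call(rbind, lapply(train, `[[`, "features")))
  if (method == "logistic") {
    Xtr <- do.call(rbind, lapply(train, function(e)
      zscore_transform(zfit, e$features)))
    ytr <- unlist(lapply(train, `[[`, "labels"))
    res <- lapply(test, function(e) {
      pr <- logistic_regression_baseline(Xtr, ytr,
                                         zscore_transform(zfit, e$features))
      list(pred = pr$labels, truth = e$labels)
    })
  } else {
    insts <- lapply(train, function(e)
      gmq_instance(e$model, zscore_transform(zfit, e$features),
                   neighbor_cutoff = neighbor_cutoff, ss = e$ss,
                   labels = e$labels))
    params <- train_sgd(insts, learning_rate = learning_rate,
                        epochs = epochs, l2_penalty = l2_penalty,
                        seed = seed, w = w, average_tail = average_tail,
                        neighbor_cutoff = neighbor_cutoff)
    res <- lapply(test, function(e) {
      inst <- gmq_instance(e$model, zscore_transform(zfit, e$features),
                           neighbor_cutoff = neighbor_cutoff, ss = e$ss)
      list(pred = infer_map(inst, params), truth = e$labels)
    })
  }
  vapply(res, function(r) accuracy(r$pred, r$truth), numeric(1))
}

#' k-fold cross-validated quality prediction
#'
#' The dataset is split at model level (never residue level); for each
#' fold, Z-scoring is fitted and the CRF trained on the training folds
#' only, then the held-out models are predicted.
#'
#' @param entries list of [gmq_entry()] objects (>= k models)
#' @param k number of folds (default 5)
#' @param neighbor_cutoff graph cutoff in Angstrom
#' @param w edge-class weights (default uniform)
#' @param method "crf", "linear" (the 1.0 Angstrom cutoff pipeline) or
#'   "logistic"
#' @param learning_rate,epochs,l2_penalty SGD hyperparameters
#' @param average_tail Polyak tail-averaging window (see [train_sgd()])
#' @param seed seed controlling fold assignment and training shuffles
#' @return list with `fold` (per-model fold ids), `model_accuracy`,
#'   `fold_accuracy`, and `mean_accuracy` (mean over models)
#' @export
cross_validate <- function(entries, k = 5L, neighbor_cutoff = 4.5,
                           w = stats::setNames(rep(1, 5), .edge_classes),
                           method = c("crf", "linear", "logistic"),
                           learning_rate = 0.05, epochs = 50L,
                           l2_penalty = 1e-3, average_tail = 0L,
                           seed = 1L) {
  method <- match.arg(method)
  nc <- if (method == "linear") 1.0 else neighbor_cutoff
  inner <- if (method == "logistic") "logistic" else "crf"
  fold <- cv_folds(length(entries), k, seed)
  model_acc <- numeric(length(entries))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- entries[fold != f]; te <- entries[fold == f]
    acc <- train_predict_entries(tr, te, nc, w, learning_rate, epochs,
                                 l2_penalty, seed, inner, average_tail)
    model_acc[fold == f] <- acc
    fold_acc[f] <- mean(acc)
  }
  list(fold = fold, model_accuracy = model_acc, fold_accuracy = fold_acc,
       mean_accuracy = mean(model_acc))
}

#' Compare neighbour cutoffs by per-model accuracy
#'
#' For every pair of cutoffs, the percentage of models whose
#' cross-validated accuracy under the larger cutoff is better than or
#' equal to that under the smaller one (ties count as better-or-equal).
#' Fold assignment is shared across cutoffs.
#'
#' @param entries list of [gmq_entry()] objects
#' @param cutoffs numeric vector of >= 2 neighbour cutoffs
#' @param ... passed to [cross_validate()]
#' @param k,seed folds and seed (shared across cutoffs)
#' @return list with `accuracy` (models x cutoffs matrix) and
#'   `better_or_equal` (lower-triangular percentage matrix,
#'   rows = larger cutoff)
#' @export
compare_cutoffs <- function(entries, cutoffs, k = 5L, seed = 1L, ...) {
  if (length(cutoffs) < 2L) stop("need at least 2 cutoffs")
  cutoffs <- sort(cutoffs)
  acc <- sapply(cutoffs, function(nc) {
    cross_validate(entries, k = k, neighbor_cutoff = nc, seed = seed,
                   ...)$model_accuracy
  })
  colnames(acc) <- sprintf("%.1f", cutoffs)
  nc <- length(cutoffs)
  pct <- matrix(NA_real_, nc, nc, dimnames = list(colnames(acc),
                                                  colnames(acc)))
  for (a in seq_len(nc)) {
    for (b in seq_len(nc)) {
      if (cutoffs[a] > cutoffs[b]) {
        pct[a, b] <- 100 * mean(acc[, a] >= acc[, b])
      }
    }
  }
  list(accuracy = acc, better_or_equal = pct)
}

#' The full secondary-structure edge-weight grid
#'
#' HH, BB and HB range over 0.5..1.0 and CHB, CC over 0.0..0.5, both in
#' steps of 0.1: 6^5 = 7776 combinations.
#'
#' @return data.frame with columns HH, BB, HB, CHB, CC
#' @export
edge_weight_grid <- function() {
  g <- expand.grid(CC = seq(0, 0.5, by = 0.1), CHB = seq(0, 0.5, by = 0.1),
                   HB = seq(0.5, 1, by = 0.1), BB = seq(0.5, 1, by = 0.1),
                   HH = seq(0.5, 1, by = 0.1))
  g[, c("HH", "BB", "HB", "CHB", "CC")]
}

#' Grid search over secondary-structure edge-class weights
#'
#' Evaluates cross-validated accuracy at each grid point (training is
#' redone per point, since the weights enter the likelihood). The full
#' 7776-point grid is exhaustive and expensive; a subset can be supplied.
#' All co-optimal points are reported.
#'
#' @param entries list of [gmq_entry()] objects
#' @param grid data.frame of weights (default [edge_weight_grid()])
#' @param ... passed to [cross_validate()]
#' @return list with `grid` (the grid plus an `accuracy` column), `best`
#'   (all rows attaining the maximum), `best_accuracy`
#' @export
grid_search_edge_weights <- function(entries, grid = edge_weight_grid(),
                                     ...) {
  acc <- vapply(seq_len(nrow(grid)), function(r) {
    w <- stats::setNames(as.numeric(grid[r, .edge_classes]), .edge_classes)
    cross_validate(entries, w = w, ...)$mean_accuracy
  }, numeric(1))
  grid$accuracy <- acc
  best <- grid[acc == max(acc), , drop = FALSE]
  list(grid = grid, best = best, best_accuracy = max(acc))
}
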