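#' Configuration for the one-vs-rest dominance classifier
#'
#' Two binary multilayer perceptrons (three tanh hidden layers each) are
#' trained on single-stimulus cells: one recognizes stimulus-A cells, the
#' other stimulus-B cells. Applied jointly to co-stimulated cells, the two
#' positive/negative decisions combine into one of four dominance labels.
#'
#' @param feature_set `"all_genes"` or `"cross_inhibited_ucgs"` (requires
#'   cross-regulation labels from [classify_cross_regulation()]).
#' @param hidden_layers Sizes of the three hidden layers.
#' @param train_fraction Fraction of single-stimulus cells used for
#'   training (stratified); the rest are the held-out test set.
#' @param decision_threshold Positive-class probability above which a
#'   classifier votes positive.
#' @param cv_folds Number of stratified cross-validation folds (>= 2).
#' @param run_cv Run the cross-validation sweep in addition to the
#'   held-out split (default `TRUE`; turn off for speed when only the
#'   held-out accuracy is needed).
#' @param epochs,batch_size,learning_rate Optimizer settings.
#' @param include_controls Also use control cells as negatives (off by
#'   default: the training universe is the single-stimulus cells).
#' @param seed Seed controlling split, initialization and batching.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(feature_set = c("all_genes", "cross_inhibited_ucgs"),
                              hidden_layers = c(64L, 32L, 16L),
                              train_fraction = 0.8,
                              decision_threshold = 0.5,
                              cv_folds = 5L,
                              run_cv = TRUE,
                              epochs = 40L,
                              batch_size = 64L,
                              learning_rate = 1e-3,
                              include_controls = FALSE,
                              seed = 1L) {
  feature_set <- match.arg(feature_set)
  if (length(hidden_layers) != 3L) {
    abort("The classifier uses exactly three hidden layers.")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1).")
  }
  if (decision_threshold <= 0 || decision_threshold > 1) {
    abort("`decision_threshold` must lie in (0, 1].")
  }
  if (cv_folds < 2L) abort("`cv_folds` must be at least 2.")
  structure(list(feature_set = feature_set,
                 hidden_layers = as.integer(hidden_layers),
                 train_fraction = train_fraction,
                 decision_threshold = decision_threshold,
                 cv_folds = as.integer(cv_folds),
                 run_cv = isTRUE(run_cv),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 include_controls = include_controls,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

select_features <- function(norm, config, program) {
  if (config$feature_set == "all_genes") {
    colnames(norm$values)
  } else {
    if (is.null(program) || !nrow(program$cross_regulation)) {
      abort(paste("feature_set = 'cross_inhibited_ucgs' needs cross-regulation",
                  "labels; run `classify_cross_regulation()` first."))
    }
    feats <- cross_inhibited_ucgs(program)
    if (!length(feats)) {
      warn("No UCG shows cross-inhibition; falling back to all UCGs.")
      feats <- c(program$ucg_A, program$ucg_B)
    }
    if (!length(feats)) abort("No UCG features available.")
    feats
  }
}

stratified_split <- function(y, train_fraction) {
  train <- logical(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    n_train <- max(1L, round(length(idx) * train_fraction))
    train[sample(idx, n_train)] <- TRUE
  }
  train
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in unique(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the one-vs-rest dominance classifier
#'
#' The training universe is the single-stimulus cells (plus controls as
#' negatives if configured). Each binary MLP separates its stimulus from
#' the rest of the universe on standardized normalized values (training
#' mean/SD, stored with the model). Reports held-out accuracy from a
#' stratified split and stratified k-fold cross-validation accuracy.
#'
#' @param norm A `normalized_matrix` containing the single-stimulus
#'   conditions.
#' @param config A [classifier_config()].
#' @param program A [classify_cross_regulation()] result; required when
#'   `feature_set = "cross_inhibited_ucgs"`.
#' @param stimA_condition,stimB_condition,control_condition Condition
#'   labels.
#' @return An `ovr_classifier`: the two fitted networks, the feature
#'   list, standardization constants, the config, and a `report` tibble
#'   (classifier, accuracy_holdout, accuracy_cv, cv_sd, n_train, n_test,
#'   n_positive, n_features). `tidy()` returns the report; `glance()` a
#'   one-row summary.
#' @export
train_ovr <- function(norm, config = classifier_config(), program = NULL,
                      stimA_condition = "stimA", stimB_condition = "stimB",
                      control_condition = "control") {
  stopifnot(inherits(norm, "normalized_matrix"),
            inherits(config, "classifier_config"))
  for (cond in c(stimA_condition, stimB_condition)) {
    if (sum(norm$condition == cond) < 20L) {
      abort(sprintf("Condition '%s' needs at least 20 cells.", cond))
    }
  }
  features <- select_features(norm, config, program)
  universe <- norm$condition %in% c(stimA_condition, stimB_condition)
  if (config$include_controls) {
    universe <- universe | norm$condition == control_condition
  }
  X_all <- dense_block(norm$values, rows = which(universe), cols = features)
  y_cond <- norm$condition[universe]

  withr::with_seed(config$seed, {
    train <- stratified_split(y_cond, config$train_fraction)
    center <- colMeans(X_all[train, , drop = FALSE])
    scale_ <- apply(X_all[train, , drop = FALSE], 2L, sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    Xs <- sweep(sweep(X_all, 2L, center), 2L, scale_, `/`)

    fit_one <- function(target_condition) {
      y <- as.numeric(y_cond == target_condition)
      net <- mlp_train(Xs[train, , drop = FALSE], y[train],
                       hidden = config$hidden_layers, epochs = config$epochs,
                       batch_size = config$batch_size,
                       lr = config$learning_rate)
      prob_test <- mlp_prob(net, Xs[!train, , drop = FALSE])
      acc <- mean((prob_test >= config$decision_threshold) == (y[!train] == 1))
      if (!config$run_cv) {
        return(list(net = net, accuracy_holdout = acc,
                    accuracy_cv = NA_real_, cv_sd = NA_real_,
                    n_positive = sum(y[train])))
      }
      fold <- stratified_folds(y_cond, config$cv_folds)
      cv_acc <- vapply(seq_len(config$cv_folds), function(k) {
        in_fold <- fold == k
        cv_net <- mlp_train(Xs[!in_fold, , drop = FALSE], y[!in_fold],
                            hidden = config$hidden_layers,
                            epochs = config$epochs,
                            batch_size = config$batch_size,
                            lr = config$learning_rate)
        p_k <- mlp_prob(cv_net, Xs[in_fold, , drop = FALSE])
        mean((p_k >= config$decision_threshold) == (y[in_fold] == 1))
      }, numeric(1))
      list(net = net, accuracy_holdout = acc, accuracy_cv = mean(cv_acc),
           cv_sd = sd(cv_acc), n_positive = sum(y[train]))
    }
    fit_A <- fit_one(stimA_condition)
    fit_B <- fit_one(stimB_condition)
  })

  report <- tibble(
    classifier = c("A", "B"),
    accuracy_holdout = c(fit_A$accuracy_holdout, fit_B$accuracy_holdout),
    accuracy_cv = c(fit_A$accuracy_cv, fit_B$accuracy_cv),
    cv_sd = c(fit_A$cv_sd, fit_B$cv_sd),
    n_train = sum(train), n_test = sum(!train),
    n_positive = c(fit_A$n_positive, fit_B$n_positive),
    n_features = length(features))
  structure(list(net_A = fit_A$net, net_B = fit_B$net, features = features,
                 center = center, scale = scale_, config = config,
                 conditions = c(A = stimA_condition, B = stimB_condition),
                 report = report),
            class = "ovr_classifier")
}

#' @export
print.ovr_classifier <- function(x, ...) {
  cat(sprintf("<ovr_classifier> %s features (%d), hidden layers (%s), tanh\n",
              x$config$feature_set, length(x$features),
              paste(x$config$hidden_layers, collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' @method tidy ovr_classifier
#' @export
tidy.ovr_classifier <- function(x, ...) x$report

#' @method glance ovr_classifier
#' @export
glance.ovr_classifier <- function(x, ...) {
  tibble(feature_set = x$config$feature_set,
         n_features = length(x$features),
         min_accuracy_holdout = min(x$report$accuracy_holdout),
         min_accuracy_cv = min(x$report$accuracy_cv),
         decision_threshold = x$config$decision_threshold)
}

#' Dominance labels for co-stimulated cells
#'
#' Scores each co-stimulated cell with both classifiers. A classifier
#' votes positive when its probability reaches the decision threshold;
#' the two votes combine into `A-dominant` (+,-), `B-dominant` (-,+),
#' `mixed` (+,+) or `unclassified` (-,-).
#'
#' @param model An [train_ovr()] result.
#' @param norm A `normalized_matrix` holding the cells to classify.
#' @param condition Condition label of the cells to classify (default
#'   `"costim"`).
#' @param decision_threshold Optional override of the trained threshold.
#' @return Tibble (cell_id, label, p_A, p_B); `label` is a factor with
#'   levels A-dominant, B-dominant, mixed, unclassified.
#' @export
classify_costim <- function(model, norm, condition = "costim",
                            decision_threshold = NULL) {
  stopifnot(inherits(model, "ovr_classifier"),
            inherits(norm, "normalized_matrix"))
  missing_f <- setdiff(model$features, colnames(norm$values))
  if (length(missing_f)) {
    abort(sprintf("Matrix lacks %d model features (e.g. %s).",
                  length(missing_f), paste(head(missing_f, 3), collapse = ", ")))
  }
  thr <- decision_threshold %||% model$config$decision_threshold
  rows <- which(norm$condition %in% condition)
  if (!length(rows)) {
    warn("No cells in the requested condition; returning an empty table.")
    return(tibble(cell_id = character(),
                  label = factor(character(), levels = dominance_levels()),
                  p_A = numeric(), p_B = numeric()))
  }
  X <- dense_block(norm$values, rows = rows, cols = model$features)
  X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  p_A <- mlp_prob(model$net_A, X)
  p_B <- mlp_prob(model$net_B, X)
  pos_A <- p_A >= thr
  pos_B <- p_B >= thr
  label <- dplyr::case_when(pos_A & !pos_B ~ "A-dominant",
                            !pos_A & pos_B ~ "B-dominant",
                            pos_A & pos_B ~ "mixed",
                            TRUE ~ "unclassified")
  tibble(cell_id = rownames(X),
         label = factor(label, levels = dominance_levels()),
         p_A = p_A, p_B = p_B)
}

dominance_levels <- function() {
  c("A-dominant", "B-dominant", "mixed", "unclassified")
}

#' Compare dominance calls across feature sets
#'
#' Trains the classifier on all genes and on cross-inhibited UCGs, labels
#' the co-stimulated cells with each, and tabulates the label counts side
#' by side.
#'
#' @inheritParams train_ovr
#' @param condition Condition labelled by the classifiers.
#' @return Tibble (label, n_all_genes, n_cross_inhibited_ucgs) with the
#'   per-model label fractions in attribute `fractions`.
#' @export
compare_feature_sets <- function(norm, program, config = classifier_config(),
                                 condition = "costim",
                                 stimA_condition = "stimA",
                                 stimB_condition = "stimB") {
  stopifnot(inherits(program, "program_sets"))
  run <- function(feature_set) {
    cfg <- config
    cfg$feature_set <- feature_set
    model <- train_ovr(norm, cfg, program, stimA_condition, stimB_condition)
    classify_costim(model, norm, condition)
  }
  if (!any(norm$condition %in% condition)) {
    warn("No co-stimulated cells; returning an empty comparison.")
    return(tibble(label = factor(character(), levels = dominance_levels()),
                  n_all_genes = integer(), n_cross_inhibited_ucgs = integer()))
  }
  all_genes <- run("all_genes")
  ucgs <- run("cross_inhibited_ucgs")
  tab <- function(labels) {
    as.integer(table(labels$label)[dominance_levels()])
  }
  out <- tibble(label = factor(dominance_levels(), levels = dominance_levels()),
                n_all_genes = tab(all_genes),
                n_cross_inhibited_ucgs = tab(ucgs))
  attr(out, "fractions") <- tibble(
    label = out$label,
    frac_all_genes = out$n_all_genes / sum(out$n_all_genes),
    frac_cross_inhibited_ucgs =
      out$n_cross_inhibited_ucgs / sum(out$n_cross_inhibited_ucgs))
  out
}

#' Serialize / restore a trained classifier as plain text
#'
#' Writes the networks, feature list, standardization constants and
#' config as a single JSON-free plain-text file (dput representation).
#'
#' @param model An `ovr_classifier`.
#' @param file Path.
#' @return `file` (write) or the restored model (read).
#' @export
write_classifier <- function(model, file) {
  stopifnot(inherits(model, "ovr_classifier"))
  dput(unclass(model), file = file)
  invisible(file)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(file) {
  structure(dget(file), class = "ovr_classifier")
}
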