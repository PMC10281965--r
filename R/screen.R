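#' Enumerate the shape-combination screening models
#'
#' All non-empty subsets of the given shapes, in deterministic order:
#' singletons first, then pairs, then the full set, lexicographic within
#' size. Three shapes yield the seven screening models.
#'
#' @param shapes Character vector of shapes (subset of
#'   `c("spiral", "square", "triangular")`).
#' @return A list of `model_spec` objects (element `shapes`).
#' @export
#' @examples
#' length(enumerate_models())  # 7
enumerate_models <- function(shapes = SHAPES) {
  if (length(shapes) == 0) stop_validation("shape set must be non-empty")
  shapes <- sort(unique(match.arg(shapes, SHAPES, several.ok = TRUE)))
  out <- list()
  for (k in seq_along(shapes)) {
    for (idx in seq_len(ncol(utils::combn(length(shapes), k)))) {
      sel <- shapes[utils::combn(length(shapes), k)[, idx]]
      out[[length(out) + 1]] <- structure(list(shapes = sel),
                                          class = "model_spec")
    }
  }
  out
}

model_label <- function(model) paste(model$shapes, collapse = "+")

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%d feature columns)\n", model_label(x),
              3 * length(x$shapes)))
  invisible(x)
}

#' Assemble the participant-by-feature matrix for one model
#'
#' One row per participant, columns ordered shape-major
#' (`<shape>_DT, <shape>_AP, <shape>_SP` for each shape in the model).
#' Participants missing any required shape are dropped with a message.
#'
#' @param features Labeled feature table from [extract_features()].
#' @param model A `model_spec` from [enumerate_models()].
#' @return List with `x` (numeric matrix), `labels` (factor,
#'   levels `nonCM`, `CM`), `participant_id`, `n_dropped`.
#' @export
assemble_matrix <- function(features, model) {
  stopifnot(inherits(model, "model_spec"))
  wide <- NULL
  for (s in model$shapes) {
    sub <- features[features$shape == s,
                    c("participant_id", "group", "DT", "AP", "SP")]
    names(sub)[3:5] <- paste(s, c("DT", "AP", "SP"), sep = "_")
    wide <- if (is.null(wide)) sub
            else merge(wide, sub[-2], by = "participant_id", sort = FALSE)
  }
  n_all <- length(unique(features$participant_id))
  wide <- wide[stats::complete.cases(wide), ]
  n_dropped <- n_all - nrow(wide)
  if (n_dropped > 0)
    message(sprintf("assemble_matrix: dropped %d participant(s) missing %s",
                    n_dropped, model_label(model)))
  if (nrow(wide) == 0) stop_validation("no complete participants for model")
  wide <- wide[order(wide$participant_id), ]
  x <- as.matrix(wide[, -(1:2), drop = FALSE])
  rownames(x) <- wide$participant_id
  if (any(is.na(wide$group)))
    stop_validation("labels missing for some participants")
  list(x = x, labels = factor(wide$group, levels = c("nonCM", "CM")),
       participant_id = wide$participant_id, n_dropped = n_dropped)
}

# Column standardization helper; zero-variance columns get scale 1.
std_params <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  zero <- !is.finite(sd) | sd == 0
  sd[zero] <- 1
  list(mu = mu, sd = sd, n_zero_var = sum(zero))
}
std_apply <- function(x, sp) sweep(sweep(x, 2, sp$mu), 2, sp$sd, "/")

# Median-heuristic RBF bandwidth: gamma = 1 / median squared pairwise
# distance of the (standardized) training rows.
median_gamma <- function(x) {
  d2 <- stats::median(stats::dist(x)^2)
  if (!is.finite(d2) || d2 == 0) 1 / ncol(x) else 1 / d2
}

# Fit an SVM and return decision values oriented so larger = more CM-like.
# With `standardize_scores` the test-row values are centered and scaled by
# the decision values of the training rows (training information only):
# raw SVM decision values carry a fold-dependent offset and scale, and at
# one held-out row per fold that offset depends on which class was removed,
# so pooling raw values across folds into one ROC is biased. Standardizing
# on the training fold makes the pooled scores comparable.
svm_decision <- function(xtr, ytr, xte, hp, standardize_scores = TRUE) {
  gamma <- hp$gamma %||% median_gamma(xtr)
  fit <- e1071::svm(xtr, ytr, type = "C-classification",
                    kernel = hp$kernel %||% "radial",
                    cost = hp$cost %||% 1, gamma = gamma, scale = FALSE)
  pr <- stats::predict(fit, rbind(xte, xtr), decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  pos_first <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
  if (pos_first != "CM") dv <- -dv
  out <- dv[seq_len(nrow(xte))]
  if (standardize_scores) {
    tr <- dv[-seq_len(nrow(xte))]
    out <- out - mean(tr)
    if (stats::sd(tr) > 0) out <- out / stats::sd(tr)
  }
  out
}

#' Leave-one-out cross-validated decision values
#'
#' For each participant, the SVM is trained on the other `n - 1` rows and
#' the held-out row's signed decision value recorded. With
#' `normalization = "fold"` (default) each training fold's column
#' means/SDs standardize both the fold and the held-out row, so no
#' information leaks from the test row into its own scaling;
#' `"global"` standardizes the whole matrix once (the simpler, leakier
#' variant some published pipelines use). Zero-variance columns within a
#' fold get unit scale. Decision values are oriented so larger = more
#' CM-like and, by default, centered and scaled by the training fold's own
#' decision values so that the pooled values are comparable across folds
#' (raw per-fold values carry a fold- and class-composition-dependent
#' offset; `standardize_scores = FALSE` gives the raw values).
#' Deterministic given inputs.
#'
#' @param x Numeric matrix (participants x features).
#' @param labels Factor with levels `nonCM`, `CM`.
#' @param hyperparams List: `kernel` (`"radial"` or `"linear"`), `cost`,
#'   optional `gamma` (default: median heuristic per training fold).
#' @param normalization `"fold"` or `"global"`.
#' @param standardize_scores Standardize each fold's decision value on the
#'   training fold (default `TRUE`).
#' @return Numeric vector of out-of-fold decision values, one per row.
#' @export
loocv_scores <- function(x, labels, hyperparams = list(kernel = "radial",
                                                       cost = 1),
                         normalization = c("fold", "global"),
                         standardize_scores = TRUE) {
  normalization <- match.arg(normalization)
  if (nlevels(droplevels(labels)) < 2)
    stop_validation("both classes must be present")
  if (any(!is.finite(x))) stop_validation("missing values in feature matrix")
  n <- nrow(x)
  if (normalization == "global") x <- std_apply(x, std_params(x))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- droplevels(labels[-i])
    if (nlevels(ytr) < 2)
      stop_validation("training fold %d has a single class", i)
    xte <- x[i, , drop = FALSE]
    if (normalization == "fold") {
      sp <- std_params(xtr)
      xtr <- std_apply(xtr, sp)
      xte <- std_apply(xte, sp)
    }
    scores[i] <- svm_decision(xtr, ytr, xte, hyperparams,
                              standardize_scores)
  }
  scores
}

#' ROC curve from decision scores
#'
#' Thresholds sweep the unique score values in descending order (positives
#' = CM, predicted positive when `score >= threshold`); tied scores share
#' one vertex. The curve starts at `(0, 0)` (threshold `Inf`) and ends at
#' `(1, 1)`.
#'
#' @param scores Numeric decision values, larger = more CM-like.
#' @param labels Factor/character with values `nonCM`, `CM`.
#' @return data.frame `fpr`, `tpr`, `threshold`, monotone in both rates.
#' @export
roc_curve <- function(scores, labels) {
  pos <- labels == "CM"
  if (!any(pos) || all(pos)) stop_validation("both classes required for ROC")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(u) mean(scores[pos] >= u), numeric(1))
  fpr <- vapply(th, function(u) mean(scores[!pos] >= u), numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr), threshold = c(Inf, th))
}

#' Trapezoidal area under an ROC curve
#'
#' Equals the tie-corrected rank statistic `U / (n1 * n2)` computed from
#' the same scores.
#'
#' @param roc data.frame from [roc_curve()].
#' @return Number in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

#' Operating point closest to the upper-left ROC corner
#'
#' Selects the ROC vertex minimizing the Euclidean distance
#' `sqrt((1 - TPR)^2 + FPR^2)` to the ideal point (sensitivity 1,
#' specificity 1). Ties are broken in favor of higher sensitivity, then
#' higher specificity.
#'
#' @param roc data.frame from [roc_curve()].
#' @return List `threshold`, `sensitivity`, `specificity`.
#' @export
best_threshold <- function(roc) {
  d2 <- (1 - roc$tpr)^2 + roc$fpr^2
  cand <- which(d2 <= min(d2) + 1e-12)
  cand <- cand[roc$tpr[cand] == max(roc$tpr[cand])]
  cand <- cand[roc$fpr[cand] == min(roc$fpr[cand])][1]
  list(threshold = roc$threshold[cand], sensitivity = roc$tpr[cand],
       specificity = 1 - roc$fpr[cand])
}

new_eval_result <- function(model, scores, labels, participant_id,
                            hyperparams, mode, normalization) {
  roc <- roc_curve(scores, labels)
  structure(list(model = model, scores = scores, labels = labels,
                 participant_id = participant_id, roc = roc,
                 auc = roc_auc(roc), operating_point = best_threshold(roc),
                 hyperparams = hyperparams, mode = mode,
                 normalization = normalization),
            class = "cm_eval")
}

#' @export
print.cm_eval <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf(
    "<cm_eval> %s [%s]: AUC %.3f, sens %.2f, spec %.2f (cost %s)\n",
    model_label(x$model), x$mode, x$auc, op$sensitivity, op$specificity,
    paste(format(x$hyperparams$cost), collapse = ",")))
  invisible(x)
}

#' Tune SVM hyperparameters over a regularization grid
#'
#' Two labeled tuning modes. `"paper_faithful"`: for each grid value the
#' full LOOCV is run, the upper-left operating point taken, and the grid
#' value maximizing sensitivity + specificity selected (ties: smaller cost,
#' i.e. larger margin). This aggregate maximization matches the published
#' description and is optimistic. `"nested"`: each outer fold selects its
#' cost by an inner LOOCV on the remaining rows, giving an honest
#' out-of-sample estimate. Results record which mode produced them.
#'
#' @inheritParams loocv_scores
#' @param grid Numeric vector of candidate costs.
#' @param mode `"paper_faithful"` or `"nested"`.
#' @param kernel SVM kernel, `"radial"` (default) or `"linear"`.
#' @param model Optional `model_spec` carried into the result.
#' @param participant_id Optional ids carried into the result.
#' @return A `cm_eval`: scores, ROC, AUC, operating point, chosen
#'   hyperparameters, mode.
#' @export
tune_hyperparameters <- function(x, labels, grid = c(0.1, 1, 10, 100),
                                 mode = c("paper_faithful", "nested"),
                                 kernel = "radial",
                                 normalization = "fold",
                                 model = structure(list(shapes = "?"),
                                                   class = "model_spec"),
                                 participant_id = rownames(x)) {
  mode <- match.arg(mode)
  if (length(grid) == 0) stop_validation("empty hyperparameter grid")
  grid <- sort(grid)
  if (mode == "paper_faithful") {
    best <- NULL
    for (cost in grid) {
      sc <- loocv_scores(x, labels, list(kernel = kernel, cost = cost),
                         normalization)
      op <- best_threshold(roc_curve(sc, labels))
      obj <- op$sensitivity + op$specificity
      if (is.null(best) || obj > best$obj + 1e-12) {
        best <- list(obj = obj, cost = cost, scores = sc)
      }
    }
    new_eval_result(model, best$scores, labels, participant_id,
                    list(kernel = kernel, cost = best$cost), mode,
                    normalization)
  } else {
    n <- nrow(x)
    scores <- numeric(n)
    chosen <- numeric(n)
    for (i in seq_len(n)) {
      xtr <- x[-i, , drop = FALSE]
      ytr <- droplevels(labels[-i])
      inner_best <- NULL
      for (cost in grid) {
        sc <- loocv_scores(xtr, ytr, list(kernel = kernel, cost = cost),
                           normalization)
        op <- best_threshold(roc_curve(sc, ytr))
        obj <- op$sensitivity + op$specificity
        if (is.null(inner_best) || obj > inner_best$obj + 1e-12)
          inner_best <- list(obj = obj, cost = cost)
      }
      chosen[i] <- inner_best$cost
      sp <- if (normalization == "fold") std_params(xtr) else
        std_params(x)
      scores[i] <- svm_decision(std_apply(xtr, sp), ytr,
                                std_apply(x[i, , drop = FALSE], sp),
                                list(kernel = kernel,
                                     cost = inner_best$cost))
    }
    new_eval_result(model, scores, labels, participant_id,
                    list(kernel = kernel, cost = chosen), mode,
                    normalization)
  }
}

#' Evaluate the shape-combination SVM screening models
#'
#' The package's central fitting function. For every non-empty combination
#' of the given shapes (seven models for three shapes) it assembles the
#' participant feature matrix (DT, AP, SP per shape), runs leave-one-out
#' cross-validated soft-margin SVM classification with per-fold
#' standardization, tunes the regularization cost over `grid`, and derives
#' the ROC curve, AUC and the upper-left operating point
#' (sensitivity/specificity at the threshold closest to the ROC's top-left
#' corner). Positive class is CM.
#'
#' @param features Labeled feature table ([extract_features()]).
#' @param shapes Shapes to combine (default all three).
#' @inheritParams tune_hyperparameters
#' @return An object of class `cm_screen`: list with `results` (named list
#'   of `cm_eval`), `table` (one row per model: sensitivity, specificity,
#'   AUC, cost), `best` (label of the highest-AUC model) and the call.
#'   Methods: `print`, `summary`, `plot` (ROC), `predict`.
#' @export
#' @examples
#' \donttest{
#' co <- simulate_cohort(n_noncm = 12, n_cm = 10, seed = 1)
#' fit <- cm_screen(extract_features(co), grid = 1)
#' fit
#' }
cm_screen <- function(features, shapes = SHAPES, grid = c(0.1, 1, 10, 100),
                      mode = c("paper_faithful", "nested"),
                      kernel = "radial", normalization = "fold") {
  mode <- match.arg(mode)
  models <- enumerate_models(shapes)
  results <- list()
  for (m in models) {
    am <- assemble_matrix(features, m)
    results[[model_label(m)]] <- tune_hyperparameters(
      am$x, am$labels, grid = grid, mode = mode, kernel = kernel,
      normalization = normalization, model = m,
      participant_id = am$participant_id)
  }
  tab <- do.call(rbind, lapply(results, function(r) {
    op <- r$operating_point
    data.frame(model = model_label(r$model),
               sensitivity = op$sensitivity, specificity = op$specificity,
               auc = r$auc,
               cost = paste(format(unique(r$hyperparams$cost)),
                            collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(results = results, table = tab,
                 best = tab$model[which.max(tab$auc)], features = features,
                 mode = mode, kernel = kernel, normalization = normalization,
                 grid = grid, call = match.call()),
            class = "cm_screen")
}

#' @export
print.cm_screen <- function(x, digits = 3, ...) {
  cat(sprintf("Shape-combination SVM screening (%s, %s kernel, %s normalization)\n\n",
              x$mode, x$kernel, x$normalization))
  tab <- x$table
  tab$sensitivity <- round(tab$sensitivity, digits)
  tab$specificity <- round(tab$specificity, digits)
  tab$auc <- round(tab$auc, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nBest model by AUC: %s\n", x$best))
  invisible(x)
}

#' @export
summary.cm_screen <- function(object, ...) {
  n <- length(object$results[[1]]$labels)
  cat(sprintf("cm_screen: %d models, %d participants (%d CM / %d nonCM)\n",
              length(object$results), n,
              sum(object$results[[1]]$labels == "CM"),
              sum(object$results[[1]]$labels == "nonCM")))
  print(object)
}

#' Plot the ROC curve of a screening model
#'
#' @param x A `cm_screen` fit.
#' @param model Model label (e.g. `"triangular"`); default the best model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cm_screen <- function(x, model = x$best, ...) {
  r <- x$results[[model]]
  if (is.null(r)) stop_validation("unknown model '%s'", model)
  graphics::plot(r$roc$fpr, r$roc$tpr, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("%s (AUC %.2f)", model, r$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  op <- r$operating_point
  graphics::points(1 - op$specificity, op$sensitivity, pch = 19,
                   col = "red3")
  invisible(x)
}

#' Classify new feature tables with a fitted screening model
#'
#' Retrains the chosen model's SVM on all fitted participants (with the
#' tuned cost, full-sample standardization) and applies the stored LOOCV
#' operating threshold to the new decision values.
#'
#' @param object A `cm_screen` fit.
#' @param newdata Feature table with the model's shapes (group may be
#'   absent).
#' @param model Model label; default the best model.
#' @param ... Unused.
#' @return data.frame `participant_id`, `score`, `class`.
#' @export
predict.cm_screen <- function(object, newdata, model = object$best, ...) {
  r <- object$results[[model]]
  if (is.null(r)) stop_validation("unknown model '%s'", model)
  am <- assemble_matrix(object$features, r$model)
  nd <- newdata
  if (!"group" %in% names(nd)) nd$group <- "nonCM"  # placeholder for reshape
  wide <- NULL
  for (s in r$model$shapes) {
    sub <- nd[nd$shape == s, c("participant_id", "DT", "AP", "SP")]
    names(sub)[2:4] <- paste(s, c("DT", "AP", "SP"), sep = "_")
    wide <- if (is.null(wide)) sub else merge(wide, sub,
                                              by = "participant_id")
  }
  xn <- as.matrix(wide[, -1, drop = FALSE])[, colnames(am$x), drop = FALSE]
  sp <- std_params(am$x)
  cost <- r$hyperparams$cost
  if (length(cost) > 1) cost <- stats::median(cost)  # nested: per-fold costs
  dv <- svm_decision(std_apply(am$x, sp), am$labels, std_apply(xn, sp),
                     list(kernel = r$hyperparams$kernel, cost = cost))
  data.frame(participant_id = wide$participant_id, score = dv,
             class = ifelse(dv >= r$operating_point$threshold, "CM",
                            "nonCM"),
             stringsAsFactors = FALSE)
}
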