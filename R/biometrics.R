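#' Quantize templates to 8-bit unsigned integers
#'
#' Per-template min-max mapping to integers 0..255, the representation used
#' to shrink the classifier input's memory footprint. A constant template
#' (zero range) maps to all-128 by convention.
#'
#' @param x A `template_set` or a numeric matrix (one template per row).
#' @return Integer matrix of the same shape with values in 0..255.
#' @export
quantize_templates <- function(x) {
  m <- if (inherits(x, "template_set")) valid_templates(x) else as.matrix(x)
  if (!all(is.finite(m))) stop("templates must be finite")
  out <- t(apply(m, 1, function(r) {
    rng <- max(r) - min(r)
    if (rng == 0) rep(128L, length(r))
    else as.integer(round(255 * (r - min(r)) / rng))
  }))
  storage.mode(out) <- "integer"
  out
}

#' Fit per-feature standardization parameters on training data
#'
#' @param x Training matrix (rows = templates).
#' @return List with `mean` and `sd` per column (sd floored at 1e-8 so
#'   constant features map to 0, not NaN).
#' @export
fit_standardization <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s < 1e-8] <- 1e-8
  list(mean = mu, sd = s)
}

#' Apply fitted standardization
#' @param x Matrix to transform.
#' @param std Parameters from [fit_standardization()].
#' @return Standardized matrix.
#' @export
apply_standardization <- function(x, std) {
  sweep(sweep(x, 2, std$mean, "-"), 2, std$sd, "/")
}

#' Construct a train/test protocol specification
#'
#' Two template-selection protocols are supported. `random`: a seeded random
#' disjoint train/test split of each subject's templates (train fraction
#' `train_fraction`, fresh per repetition). `static`: train on the *first*
#' `n_train` templates and test on the *last* `n_test` of each subject, so a
#' temporal gap separates enrolment from probing; the split is identical
#' across repetitions. Standard static splits are 30/30, 30/20 and 30/15.
#'
#' @param mode `"random"` or `"static"`.
#' @param n_train Static-mode training templates per subject (default 30).
#' @param n_test Static-mode test templates per subject (30, 20 or 15).
#' @param train_fraction Random-mode training fraction (default 2/3).
#' @param n_repetitions Number of repetitions (>= 1, default 30).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(mode = c("random", "static"), n_train = 30,
                          n_test = 30, train_fraction = 2 / 3,
                          n_repetitions = 30) {
  mode <- match.arg(mode)
  if (n_repetitions < 1) stop("`n_repetitions` must be >= 1")
  if (mode == "static" && (n_train < 1 || n_test < 1))
    stop("static protocol needs positive `n_train` and `n_test`")
  if (mode == "random" && (train_fraction <= 0 || train_fraction >= 1))
    stop("`train_fraction` must lie in (0, 1)")
  structure(list(mode = mode, n_train = n_train, n_test = n_test,
                 train_fraction = train_fraction,
                 n_repetitions = n_repetitions),
            class = "protocol_spec")
}

#' Split per-subject templates into train and test collections
#'
#' @param sets Named list mapping subject id to a template matrix (one
#'   template per row; pass valid templates only) or to a `template_set`.
#' @param protocol A [protocol_spec()].
#' @param rep Repetition index (only the random protocol depends on it).
#' @param seed Base seed; random-mode draws use `seed + rep`.
#' @return List with `train` and `test`, each a list of `x` (matrix) and
#'   `y` (factor of subject ids).
#' @export
split_templates <- function(sets, protocol, rep = 1, seed = 1) {
  mats <- lapply(sets, function(s)
    if (inherits(s, "template_set")) valid_templates(s) else as.matrix(s))
  ids <- names(mats)
  if (is.null(ids)) ids <- paste0("S", seq_along(mats))
  do_split <- function() {
    tr_x <- list(); tr_y <- character(0); te_x <- list(); te_y <- character(0)
    for (i in seq_along(mats)) {
      m <- mats[[i]]; n <- nrow(m)
      if (protocol$mode == "static") {
        need <- protocol$n_train + protocol$n_test
        if (n < need)
          stop(sprintf("subject %s has %d templates; static %d/%d needs %d",
                       ids[i], n, protocol$n_train, protocol$n_test, need))
        itr <- seq_len(protocol$n_train)
        ite <- seq.int(n - protocol$n_test + 1L, n)
      } else {
        if (n < 10)
          stop(sprintf("subject %s has %d templates; random protocol needs >= 10",
                       ids[i], n))
        itr <- sort(sample.int(n, round(protocol$train_fraction * n)))
        ite <- setdiff(seq_len(n), itr)
      }
      tr_x[[i]] <- m[itr, , drop = FALSE]
      te_x[[i]] <- m[ite, , drop = FALSE]
      tr_y <- c(tr_y, rep(ids[i], length(itr)))
      te_y <- c(te_y, rep(ids[i], length(ite)))
    }
    list(train = list(x = do.call(rbind, tr_x), y = factor(tr_y, levels = ids)),
         test  = list(x = do.call(rbind, te_x), y = factor(te_y, levels = ids)))
  }
  if (protocol$mode == "random") with_seed(seed + rep, do_split()) else do_split()
}

#' Train an identification classifier
#'
#' All four classifiers share one interface and one feature representation:
#' flattened heartbeat templates, standardized with parameters fitted on the
#' training set only. The binary-weight CNN additionally quantizes templates
#' to 8-bit unsigned integers before standardization.
#'
#' \itemize{
#'   \item `SVM` — linear-kernel one-against-all multiclass SVM (C = 1); one
#'     binary machine per class, fused by maximum decision value.
#'   \item `GaussianNB` — Gaussian naive Bayes.
#'   \item `KNN3` — 3-nearest-neighbours, majority vote, ties broken by the
#'     nearest neighbour's class.
#'   \item `BCNN` — binary-weight 1D convolutional network (see
#'     [bcnn_train()]).
#' }
#'
#' @param kind One of `"BCNN"`, `"SVM"`, `"GaussianNB"`, `"KNN3"`.
#' @param x Training template matrix (one template per row).
#' @param y Factor (or vector) of subject labels, >= 2 classes.
#' @param seed Seed for the BCNN's initialization/shuffling.
#' @param ... Extra arguments passed to [bcnn_train()].
#' @return An object of class `ecg_classifier` usable with `predict()`.
#' @export
train_classifier <- function(kind = c("BCNN", "SVM", "GaussianNB", "KNN3"),
                             x, y, seed = 1, ...) {
  kind <- match.arg(kind)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training needs at least 2 classes")
  if (any(tabulate(y) < 1)) stop("every class needs at least one template")
  x <- as.matrix(x)
  if (kind == "BCNN") x <- quantize_templates(x)
  std <- fit_standardization(x)
  xs <- apply_standardization(x, std)
  fit <- switch(kind,
    SVM = {
      lapply(levels(y), function(k) {
        yk <- factor(ifelse(y == k, "pos", "neg"), levels = c("pos", "neg"))
        e1071::svm(xs, yk, kernel = "linear", cost = 1, scale = FALSE)
      })
    },
    GaussianNB = {
      m <- e1071::naiveBayes(xs, y)
      # floor per-class sds so zero-variance features keep finite densities
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2][tb[, 2] < 1e-3] <- 1e-3
        tb
      })
      m
    },
    KNN3 = list(x = xs, y = y),
    BCNN = bcnn_train(xs, y, seed = seed, ...)
  )
  structure(list(kind = kind, std = std, fit = fit, levels = levels(y)),
            class = "ecg_classifier")
}

#' Predict subject identities
#'
#' @param object An `ecg_classifier` from [train_classifier()].
#' @param newdata Template matrix (raw, unstandardized; one per row).
#' @param ... Unused.
#' @return Factor of predicted subject ids.
#' @export
predict.ecg_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (object$kind == "BCNN") x <- quantize_templates(x)
  xs <- apply_standardization(x, object$std)
  lv <- object$levels
  pred <- switch(object$kind,
    SVM = {
      dv <- vapply(object$fit, function(m) {
        p <- attr(predict(m, xs, decision.values = TRUE), "decision.values")
        as.numeric(p) * if (colnames(p) == "pos/neg") 1 else -1
      }, numeric(nrow(xs)))
      dv <- matrix(dv, nrow = nrow(xs))
      lv[max.col(dv, ties.method = "first")]
    },
    GaussianNB = as.character(predict(object$fit, xs)),
    KNN3 = knn3_predict(object$fit$x, object$fit$y, xs),
    BCNN = as.character(bcnn_predict(object$fit, xs))
  )
  factor(pred, levels = lv)
}

#' @keywords internal
#' Deterministic 3-NN: majority vote over the three nearest training rows,
#' ties broken by the single nearest neighbour's class.
knn3_predict <- function(train_x, train_y, test_x, k = 3) {
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * test_x %*% t(train_x)
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(min(k, length(row)))]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else as.character(train_y[nn[1]])
  })
}

#' Classification metrics
#'
#' Accuracy plus macro-averaged recall and precision, all in percent. A class
#' that is never predicted contributes precision 0 to the macro average.
#'
#' @param truth,pred Factors over the same classes.
#' @return Named numeric vector `accuracy`, `recall`, `precision` (percent).
#' @export
classification_metrics <- function(truth, pred) {
  lv <- levels(truth)
  pred <- factor(pred, levels = lv)
  tab <- table(truth, pred)
  tp <- diag(tab)
  rec <- ifelse(rowSums(tab) > 0, tp / rowSums(tab), NA)
  prec <- ifelse(colSums(tab) > 0, tp / colSums(tab), 0)
  c(accuracy = 100 * sum(tp) / length(truth),
    recall = 100 * mean(rec, na.rm = TRUE),
    precision = 100 * mean(prec[rowSums(tab) > 0]))
}

#' Identification sweep over classifiers, protocol and population sizes
#'
#' For each repetition and target population size, draws a fresh seeded
#' subject subset, splits templates per the protocol, trains each classifier
#' and scores it on the held-out templates — the evaluation harness for the
#' household-identification experiment.
#'
#' @param sets Named list of per-subject template matrices (or
#'   `template_set`s; only valid templates are used).
#' @param classifiers Character vector of classifier kinds.
#' @param protocol A [protocol_spec()].
#' @param population_sizes Integer vector of cohort sizes to test.
#' @param seed Base seed controlling subset draws, random splits and BCNN
#'   training; the whole sweep is reproducible given the seed.
#' @param ... Passed to [train_classifier()] (e.g. BCNN epochs).
#' @return Data frame with columns `classifier`, `protocol`, `pop_size`,
#'   `rep`, `accuracy`, `recall`, `precision`.
#' @export
evaluate_identification <- function(sets, classifiers = c("SVM", "GaussianNB", "KNN3", "BCNN"),
                                    protocol = protocol_spec("random"),
                                    population_sizes = length(sets),
                                    seed = 1, ...) {
  ids <- names(sets)
  if (max(population_sizes) > length(ids))
    stop("population size exceeds the available cohort")
  out <- list()
  for (rep in seq_len(protocol$n_repetitions)) {
    for (ps in population_sizes) {
      subset_ids <- with_seed(seed + 1000L * rep + ps,
                              sample(ids, ps))
      split <- split_templates(sets[subset_ids], protocol, rep = rep,
                               seed = seed)
      for (cl in classifiers) {
        model <- train_classifier(cl, split$train$x, split$train$y,
                                  seed = seed + rep, ...)
        met <- classification_metrics(split$test$y,
                                      predict(model, split$test$x))
        out[[length(out) + 1L]] <- data.frame(
          classifier = cl, protocol = protocol$mode, pop_size = ps,
          rep = rep, accuracy = met[["accuracy"]], recall = met[["recall"]],
          precision = met[["precision"]])
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate an identification sweep
#'
#' @param results Data frame from [evaluate_identification()].
#' @return Data frame of per-(classifier, protocol, pop_size) means and sds
#'   of accuracy, recall and precision over repetitions.
#' @export
summarize_identification <- function(results) {
  agg <- aggregate(cbind(accuracy, recall, precision) ~
                     classifier + protocol + pop_size, data = results,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  out <- data.frame(agg[, 1:3],
                    accuracy_mean = agg$accuracy[, "mean"],
                    accuracy_sd = agg$accuracy[, "sd"],
                    recall_mean = agg$recall[, "mean"],
                    recall_sd = agg$recall[, "sd"],
                    precision_mean = agg$precision[, "mean"],
                    precision_sd = agg$precision[, "sd"])
  out[order(out$classifier, out$protocol, out$pop_size), ]
}
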