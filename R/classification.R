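## Feature ranking, leave-one-out classifier comparison and
## information-gain decision trees over a cohort feature table.
## Labels are binary throughout: HighFlex vs LowFlex.

# Shannon entropy (bits) of a label vector
.entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# best binary split of a continuous feature by information gain:
# candidate thresholds are midpoints between consecutive distinct values
.best_split <- function(x, labels) {
  ok <- !is.na(x)
  x <- x[ok]; labels <- labels[ok]
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L) {
    return(list(gain = 0, threshold = NA_real_))
  }
  o <- order(x)
  xs <- x[o]; ls <- labels[o]
  h0 <- .entropy(ls)
  classes <- sort(unique(labels))
  left_counts <- numeric(length(classes))
  names(left_counts) <- classes
  total <- table(factor(ls, levels = classes))
  best_gain <- 0; best_thr <- NA_real_
  for (i in seq_len(n - 1L)) {
    left_counts[ls[i]] <- left_counts[ls[i]] + 1
    if (xs[i] == xs[i + 1L]) next
    nl <- i; nr <- n - i
    pl <- left_counts / nl
    pr <- (as.numeric(total) - left_counts) / nr
    hl <- -sum(ifelse(pl > 0, pl * log2(pl), 0))
    hr <- -sum(ifelse(pr > 0, pr * log2(pr), 0))
    gain <- h0 - (nl * hl + nr * hr) / n
    if (gain > best_gain + 1e-12) {
      best_gain <- gain
      best_thr <- (xs[i] + xs[i + 1L]) / 2
    }
  }
  list(gain = best_gain, threshold = best_thr)
}

#' Rank features by information gain
#'
#' Each continuous feature is discretized by its entropy-minimizing
#' binary split and scored by the information gain of the discretized
#' feature with respect to the binary group label; `"gain_ratio"`
#' divides by the split entropy. Features are returned in descending
#' score order with alphabetical tie-break. A constant feature scores 0.
#'
#' @param cohort Cohort `data.frame` with a `group` column.
#' @param method `"info_gain"` (default) or `"gain_ratio"`.
#' @param features Columns to rank; default all numeric features except
#'   `CFI` (the label source) and identifiers.
#' @return `data.frame` with `feature`, `score`, `threshold` (the
#'   discretization split), in rank order.
#' @export
rank_features <- function(cohort, method = c("info_gain", "gain_ratio"),
                          features = NULL) {
  method <- match.arg(method)
  if (!"group" %in% names(cohort)) stop("cohort needs a `group` column",
                                        call. = FALSE)
  if (is.null(features)) {
    num <- vapply(cohort, is.numeric, logical(1))
    features <- setdiff(names(cohort)[num], c("CFI", "subject_id"))
  }
  labels <- cohort$group
  out <- lapply(features, function(f) {
    sp <- .best_split(cohort[[f]], labels)
    score <- sp$gain
    if (method == "gain_ratio" && !is.na(sp$threshold)) {
      x <- cohort[[f]][!is.na(cohort[[f]])]
      p <- mean(x <= sp$threshold)
      hs <- if (p > 0 && p < 1) -(p * log2(p) + (1 - p) * log2(1 - p)) else 0
      if (hs > 0) score <- score / hs
    }
    data.frame(feature = f, score = score, threshold = sp$threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Restrict a cohort to the top-k ranked features
#'
#' @param ranking Output of [rank_features()].
#' @param k Number of features to keep (1..nrow(ranking)).
#' @param cohort The cohort the ranking was computed on.
#' @return The cohort with feature columns subset to the top k, in rank
#'   order; identifier, `group` and `CFI` columns untouched.
#' @export
select_top_k <- function(ranking, k, cohort) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > nrow(ranking)) stop("k exceeds the number of ranked features",
                              call. = FALSE)
  keep <- ranking$feature[seq_len(k)]
  meta <- intersect(c("subject_id", "group", "CFI"), names(cohort))
  cohort[, c(meta, keep), drop = FALSE]
}

#' Classifier specification for the LOOCV harness
#'
#' Defaults follow common practice where nothing else is dictated: kNN
#' with k = 5, Euclidean metric, uniform vote; RBF SVM with C = 1 on
#' unit-scaled features; random forest of 100 trees; Gaussian naive
#' Bayes.
#'
#' @param method One of `"kNN"`, `"SVM"`, `"RandomForest"`,
#'   `"NaiveBayes"`.
#' @param seed Integer seed fixing any training randomness.
#' @param ... Hyperparameter overrides (`k`, `cost`, `ntree`, ...).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(method = c("kNN", "SVM", "RandomForest",
                                       "NaiveBayes"), seed = 1L, ...) {
  method <- match.arg(method)
  hp <- utils::modifyList(
    switch(method,
           kNN = list(k = 5L),
           SVM = list(cost = 1, kernel = "radial"),
           RandomForest = list(ntree = 100L),
           NaiveBayes = list()),
    list(...))
  structure(list(method = method, hyperparameters = hp, seed = seed),
            class = "classifier_spec")
}

# train on (x, y), return P(class = positive) for newdata rows.
# x, newx: numeric matrices already standardized by the caller.
.fit_predict_prob <- function(spec, x, y, newx, positive) {
  y <- factor(y)
  set.seed(spec$seed)
  switch(spec$method,
    kNN = {
      k <- min(spec$hyperparameters$k, nrow(x))
      apply(newx, 1L, function(q) {
        d <- sqrt(colSums((t(x) - q)^2))
        nn <- order(d, seq_along(d))[seq_len(k)]  # index tie-break
        w <- 1 / (d[nn] + 1e-8)
        sum(w[y[nn] == positive]) / sum(w)        # distance-weighted score
      })
    },
    SVM = {
      fit <- e1071::svm(x, y, kernel = spec$hyperparameters$kernel,
                        cost = spec$hyperparameters$cost,
                        probability = TRUE, scale = FALSE)
      pr <- attr(stats::predict(fit, newx, probability = TRUE),
                 "probabilities")
      pr[, positive]
    },
    RandomForest = {
      fit <- randomForest::randomForest(x, y,
                                        ntree = spec$hyperparameters$ntree)
      stats::predict(fit, newx, type = "prob")[, positive]
    },
    NaiveBayes = {
      fit <- e1071::naiveBayes(x, y)
      stats::predict(fit, newx, type = "raw")[, positive]
    })
}

# hard prediction; kNN predicts by uniform majority vote (distance
# tie-break), others threshold the probability at 0.5
.fit_predict_class <- function(spec, x, y, newx, positive, negative, prob) {
  if (spec$method == "kNN") {
    y <- factor(y)
    k <- min(spec$hyperparameters$k, nrow(x))
    apply(newx, 1L, function(q) {
      d <- sqrt(colSums((t(x) - q)^2))
      nn <- order(d, seq_along(d))[seq_len(k)]
      votes <- table(y[nn])
      top <- names(votes)[votes == max(votes)]
      if (length(top) == 1L) top else as.character(y[nn[1L]])
    })
  } else {
    ifelse(prob >= 0.5, positive, negative)
  }
}

#' Area under the ROC curve from scores
#'
#' Rank (Wilcoxon) formulation: the probability that a random positive
#' scores above a random negative, with ties counted half.
#'
#' @param labels Actual labels.
#' @param scores Classifier scores for the positive class.
#' @param positive Which label is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification metrics from a confusion matrix
#'
#' CA is the proportion classified correctly; precision, recall and F1
#' are computed per class and averaged with class-support weights (the
#' weighted-average convention of the standard toolkits).
#'
#' @param confusion 2x2 matrix, rows = actual, columns = predicted, with
#'   matching dimnames.
#' @return List `ca`, `f1`, `precision`, `recall`.
#' @export
confusion_metrics <- function(confusion) {
  total <- sum(confusion)
  classes <- rownames(confusion)
  support <- rowSums(confusion)
  prec <- rec <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    tp <- confusion[i, i]
    prec[i] <- if (sum(confusion[, i]) > 0) tp / sum(confusion[, i]) else 0
    rec[i] <- if (support[i] > 0) tp / support[i] else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  w <- support / total
  list(ca = sum(diag(confusion)) / total,
       f1 = sum(w * f1), precision = sum(w * prec), recall = sum(w * rec))
}

#' Leave-one-out cross-validated evaluation of one classifier
#'
#' Every subject is predicted once by a model trained on all the others.
#' Features are standardized with training-fold mean/SD only (no
#' leakage); the held-out subject's class score feeds the AUC, its hard
#' prediction the confusion matrix. Folds whose training set degenerates
#' to a single class are skipped with a warning.
#'
#' @param cohort Cohort `data.frame` with `group` and feature columns;
#'   no missing values among the used features.
#' @param spec A [classifier_spec()].
#' @param features Feature columns; default all numeric except `CFI`.
#' @param positive The positive class for AUC/score purposes.
#' @return A `cv_result`: `method`, `auc`, `ca`, `f1`, `precision`,
#'   `recall`, `confusion_matrix`, `scores`, `actual`, `predicted`,
#'   `n_folds_used`.
#' @export
loocv_evaluate <- function(cohort, spec, features = NULL,
                           positive = "HighFlex") {
  if (!"group" %in% names(cohort)) stop("cohort needs a `group` column",
                                        call. = FALSE)
  if (is.null(features)) {
    num <- vapply(cohort, is.numeric, logical(1))
    features <- setdiff(names(cohort)[num], c("CFI", "subject_id"))
  }
  X <- as.matrix(cohort[, features, drop = FALSE])
  if (anyNA(X)) stop("missing values among selected features; impute upstream",
                     call. = FALSE)
  y <- cohort$group
  n <- nrow(X)
  if (n < 6L) stop("need at least 6 subjects for LOOCV", call. = FALSE)
  classes <- sort(unique(y))
  negative <- setdiff(classes, positive)[1L]
  scores <- rep(NA_real_, n)
  pred <- rep(NA_character_, n)
  used <- 0L
  for (i in seq_len(n)) {
    xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      warning("fold ", i, " skipped: single-class training set")
      next
    }
    mu <- colMeans(xtr)
    sg <- apply(xtr, 2L, stats::sd)
    sg[sg == 0] <- 1
    xtr_s <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
    xte_s <- matrix((X[i, ] - mu) / sg, nrow = 1L,
                    dimnames = list(NULL, colnames(X)))
    p <- .fit_predict_prob(spec, xtr_s, ytr, xte_s, positive)
    scores[i] <- p
    pred[i] <- .fit_predict_class(spec, xtr_s, ytr, xte_s, positive,
                                  negative, p)
    used <- used + 1L
  }
  keep <- !is.na(pred)
  cm <- table(factor(y[keep], levels = classes),
              factor(pred[keep], levels = classes))
  cm <- matrix(as.integer(cm), 2L, 2L, dimnames = dimnames(cm))
  m <- confusion_metrics(cm)
  structure(
    list(method = spec$method,
         auc = auc_score(y[keep], scores[keep], positive),
         ca = m$ca, f1 = m$f1, precision = m$precision, recall = m$recall,
         confusion_matrix = cm, scores = scores, actual = y,
         predicted = pred, n_folds_used = used, positive = positive),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: AUC %.3f CA %.3f F1 %.3f P %.3f R %.3f (%d folds)\n",
              x$method, x$auc, x$ca, x$f1, x$precision, x$recall,
              x$n_folds_used))
  invisible(x)
}

#' Compare several classifiers under LOOCV
#'
#' @param cohort Cohort table.
#' @param methods Character vector of methods for [classifier_spec()].
#' @param seed Seed shared across methods.
#' @param features Optional feature subset.
#' @return Named list of `cv_result` objects.
#' @export
compare_classifiers <- function(cohort,
                                methods = c("kNN", "SVM", "RandomForest",
                                            "NaiveBayes"),
                                seed = 1L, features = NULL) {
  res <- lapply(methods, function(m) {
    loocv_evaluate(cohort, classifier_spec(m, seed = seed),
                   features = features)
  })
  names(res) <- methods
  res
}

#' Fit an information-gain decision tree with threshold rules
#'
#' Greedy binary splits maximizing information gain over midpoint
#' candidate thresholds; growth stops at pure nodes, at `min_leaf`
#' samples, or at `max_depth`. Leaves carry class proportions. The tree
#' is the rule-extraction stage: its root-to-leaf paths read as
#' threshold rules on named features.
#'
#' @param cohort Cohort table with binary `group` labels.
#' @param features Candidate split features; default all numeric except
#'   `CFI`.
#' @param max_depth Maximum depth (root split = depth 1; default 3).
#' @param min_leaf Minimum samples in a leaf (default 2).
#' @return A `decision_tree` (nested node list).
#' @export
fit_decision_tree <- function(cohort, features = NULL, max_depth = 3L,
                              min_leaf = 2L) {
  if (!"group" %in% names(cohort)) stop("cohort needs a `group` column",
                                        call. = FALSE)
  if (is.null(features)) {
    num <- vapply(cohort, is.numeric, logical(1))
    features <- setdiff(names(cohort)[num], c("CFI", "subject_id"))
  }
  labels <- cohort$group
  classes <- sort(unique(labels))
  grow <- function(idx, depth) {
    lab <- labels[idx]
    counts <- table(factor(lab, levels = classes))
    prop <- as.numeric(counts) / length(idx)
    names(prop) <- classes
    leaf <- list(type = "leaf", n = length(idx),
                 class = classes[which.max(counts)], proportions = prop)
    if (length(unique(lab)) == 1L || depth > max_depth ||
        length(idx) < 2L * min_leaf) {
      return(leaf)
    }
    best <- list(gain = 0)
    for (f in features) {
      sp <- .best_split(cohort[[f]][idx], lab)
      if (!is.na(sp$threshold) && sp$gain > best$gain + 1e-12) {
        best <- list(gain = sp$gain, feature = f, threshold = sp$threshold)
      }
    }
    if (best$gain <= 0) return(leaf)
    left <- idx[cohort[[best$feature]][idx] <= best$threshold]
    right <- setdiff(idx, left)
    if (length(left) < min_leaf || length(right) < min_leaf) return(leaf)
    list(type = "split", n = length(idx), feature = best$feature,
         threshold = best$threshold, gain = best$gain,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  structure(list(root = grow(seq_along(labels), 1L), classes = classes),
            class = "decision_tree")
}

#' Predict with a fitted decision tree
#'
#' @param object A `decision_tree`.
#' @param newdata Cohort-shaped `data.frame`.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.decision_tree <- function(object, newdata, ...) {
  one <- function(node, row) {
    while (node$type == "split") {
      node <- if (row[[node$feature]] <= node$threshold) node$left else
        node$right
    }
    node$class
  }
  vapply(seq_len(nrow(newdata)), function(i) one(object$root, newdata[i, ]),
         character(1))
}

#' Decision-tree depth
#' @param tree A `decision_tree`.
#' @return Number of split levels on the deepest path.
#' @export
tree_depth <- function(tree) {
  rec <- function(node) {
    if (node$type == "leaf") 0L else 1L + max(rec(node$left), rec(node$right))
  }
  rec(tree$root)
}

#' Extract the tree as indented threshold rules
#'
#' @param tree A `decision_tree`.
#' @param digits Threshold rounding for display.
#' @return Character vector of rule lines.
#' @export
tree_rules <- function(tree, digits = 2) {
  out <- character(0)
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      out <<- c(out, sprintf("%s-> %s (%.0f%%, n=%d)", pad, node$class,
                             100 * max(node$proportions), node$n))
    } else {
      out <<- c(out, sprintf("%sif %s <= %.*f:", pad, node$feature, digits,
                             node$threshold))
      rec(node$left, indent + 1L)
      out <<- c(out, sprintf("%selse (%s > %.*f):", pad, node$feature,
                             digits, node$threshold))
      rec(node$right, indent + 1L)
    }
  }
  rec(tree$root, 0L)
  out
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(tree_rules(x), sep = "\n")
  invisible(x)
}
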