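#' Gini impurity of a two-class node
#'
#' \code{1 - sum(p_k^2)} over the class proportions; 0 for a pure node and
#' 0.5 at a 50/50 two-class mix.
#'
#' @param class_counts numeric vector of per-class counts, total >= 1.
#' @return Impurity in [0, 0.5] for two classes.
#' @export
gini_impurity <- function(class_counts) {
  n <- sum(class_counts)
  if (n < 1) stop("empty node has no Gini impurity")
  p <- class_counts / n
  1 - sum(p^2)
}

# Coerce label vector to 0/1 integers (alert = 0, fatigued = 1).
label01 <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels))
  if (!all(labels %in% c("alert", "fatigued"))) {
    stop("labels must be 'alert'/'fatigued'")
  }
  as.integer(labels == "fatigued")
}

#' Best binary split of a labelled feature table
#'
#' Scans every candidate threshold — the midpoints between consecutive
#' distinct sorted values of each feature — and returns the (feature,
#' threshold) pair minimising the sample-weighted Gini impurity of the two
#' children. Tie-breaking is deterministic: earlier feature (report order)
#' first, then the lower threshold. Returns feature \code{NA} when no split
#' reduces impurity (e.g. all feature columns constant).
#'
#' @param x numeric matrix or data frame of features (rows = segments).
#' @param labels class labels (\code{"alert"}/\code{"fatigued"} or 0/1).
#' @return List: \code{feature} (column name or \code{NA}),
#'   \code{threshold}, \code{impurity} (weighted child Gini).
#' @export
best_split <- function(x, labels) {
  x <- as.matrix(x)
  y <- label01(labels)
  if (nrow(x) < 2) stop("need at least 2 rows to split")
  s <- .cpp_best_split(x, y)
  if (s$feature == 0) {
    return(list(feature = NA_character_, threshold = NA_real_,
                impurity = NA_real_))
  }
  list(feature = colnames(x)[s$feature], threshold = s$threshold,
       impurity = s$impurity)
}

#' Grow a CART decision tree
#'
#' Recursive binary splitting with the Gini criterion. A node becomes a leaf
#' when it is pure, contains fewer than \code{min_samples} rows, or no
#' impurity-reducing split exists; no pruning is applied. Leaves predict
#' their majority class, ties going to \code{fatigued} (the majority state
#' of the study design).
#'
#' @param x numeric matrix or data frame of features.
#' @param labels class labels (\code{"alert"}/\code{"fatigued"} or 0/1).
#' @param min_samples minimum node size still eligible for splitting
#'   (default 5).
#' @return Object of class \code{cart_tree}: a flat node table (split
#'   feature, threshold, node Gini, class counts, children, prediction) plus
#'   the feature names.
#' @export
build_tree <- function(x, labels, min_samples = 5) {
  x <- as.matrix(x)
  y <- label01(labels)
  if (nrow(x) < 1) stop("training set is empty")
  nodes <- .cpp_build_tree(x, y, as.integer(min_samples))
  structure(list(nodes = nodes, features = colnames(x),
                 min_samples = min_samples),
            class = "cart_tree")
}

#' Predict labels with a CART tree
#'
#' Routes each row down the tree: left when the split feature's value is at
#' or below the threshold, right otherwise.
#'
#' @param object a \code{cart_tree}.
#' @param newdata matrix or data frame containing at least the tree's
#'   features.
#' @param ... unused.
#' @return Character vector of \code{"alert"}/\code{"fatigued"}.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  missing <- setdiff(object$features, colnames(nd))
  if (length(missing)) {
    stop("missing feature value(s): ", paste(missing, collapse = ", "))
  }
  xm <- as.matrix(nd[, object$features, drop = FALSE])
  nodes <- object$nodes
  y <- .cpp_predict_tree(nodes$feature, nodes$threshold, nodes$left,
                         nodes$right, nodes$pred, xm)
  c("alert", "fatigued")[y + 1]
}

#' @export
print.cart_tree <- function(x, ...) {
  nodes <- x$nodes
  rec <- function(id, depth) {
    pad <- strrep("  ", depth)
    nd <- nodes[id, ]
    if (nd$feature == 0) {
      cat(sprintf("%sleaf: %s (alert %d / fatigued %d, gini %.3f)\n", pad,
                  c("alert", "fatigued")[nd$pred + 1], nd$n_alert,
                  nd$n_fatigued, nd$gini))
    } else {
      cat(sprintf("%s%s <= %.4g (alert %d / fatigued %d, gini %.3f)\n", pad,
                  x$features[nd$feature], nd$threshold, nd$n_alert,
                  nd$n_fatigued, nd$gini))
      rec(nd$left, depth + 1)
      rec(nd$right, depth + 1)
    }
  }
  cat("CART tree:\n")
  rec(1, 1)
  invisible(x)
}

#' Reproducible train/test split
#'
#' Shuffles rows with the given seed and holds out \code{test_fraction} of
#' them; with \code{stratify} the split is performed per label so both
#' classes keep the 8:2 proportion (sizes within one row of the target).
#'
#' @param n number of rows, or a data frame whose rows are split.
#' @param labels class labels (required when \code{stratify = TRUE}).
#' @param test_fraction held-out fraction, default 0.2.
#' @param seed integer seed.
#' @param stratify split per label (default TRUE).
#' @return List with integer row indices \code{train} and \code{test}.
#' @export
train_test_split <- function(n, labels = NULL, test_fraction = 0.2,
                             seed = 1L, stratify = TRUE) {
  if (is.data.frame(n)) n <- nrow(n)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  set.seed(as.integer(seed))
  if (stratify) {
    if (is.null(labels) || length(labels) != n) {
      stop("stratified split needs one label per row")
    }
    test <- integer(0)
    for (lab in unique(labels)) {
      rows <- which(labels == lab)
      if (length(rows) < 2) {
        stop(sprintf("label '%s' has fewer than 2 rows; cannot stratify", lab))
      }
      k <- round(test_fraction * length(rows))
      k <- min(max(k, 1L), length(rows) - 1L)
      test <- c(test, sample(rows, k))
    }
    test <- sort(test)
  } else {
    test <- sort(sample.int(n, round(test_fraction * n)))
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Confusion counts and performance metrics
#'
#' Fatigued is the positive class: TP and FN count fatigued segments
#' detected / missed, TN and FP count alert segments detected / mislabelled.
#' \code{SEN = TP/(TP+FN)}, \code{SPE = TN/(TN+FP)}, \code{PPV = TP/(TP+FP)},
#' \code{ACC = (TP+TN)/(TP+TN+FP+FN)}, all in percent; a metric with a zero
#' denominator is \code{NA}.
#'
#' @param tree a \code{cart_tree}.
#' @param x feature rows of the test set.
#' @param labels true labels of the test set.
#' @return List of class \code{confusion_counts}: \code{TP}, \code{TN},
#'   \code{FP}, \code{FN}, \code{SEN}, \code{SPE}, \code{PPV}, \code{ACC}.
#' @export
evaluate <- function(tree, x, labels) {
  if (length(labels) == 0) stop("test set is empty")
  pred <- predict(tree, x)
  truth <- c("alert", "fatigued")[label01(labels) + 1]
  confusion_counts(
    tp = sum(pred == "fatigued" & truth == "fatigued"),
    tn = sum(pred == "alert" & truth == "alert"),
    fp = sum(pred == "fatigued" & truth == "alert"),
    fn = sum(pred == "alert" & truth == "fatigued")
  )
}

#' @rdname evaluate
#' @param tp,tn,fp,fn confusion counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  pct <- function(num, den) if (den > 0) num / den * 100 else NA_real_
  structure(
    list(TP = tp, TN = tn, FP = fp, FN = fn,
         SEN = pct(tp, tp + fn), SPE = pct(tn, tn + fp),
         PPV = pct(tp, tp + fp), ACC = pct(tp + tn, tp + tn + fp + fn)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d | SEN %.1f%%  SPE %.1f%%  PPV %.1f%%  ACC %.1f%%\n",
              x$TP, x$TN, x$FP, x$FN, x$SEN, x$SPE, x$PPV, x$ACC))
  invisible(x)
}

#' Exhaustive feature-subset search
#'
#' Enumerates every subset of \code{k} features out of the twenty, trains one
#' CART per subset on a single shared train/test split (so accuracies are
#' comparable across subsets), and ranks subsets by test accuracy, ties
#' broken by sensitivity and then by lexicographic subset order. Choosing 2,
#' 3 or 4 of twenty features enumerates 190, 1140 and 4845 subsets.
#'
#' @param features feature matrix (data frame with \code{label} column and
#'   feature columns) for one group.
#' @param k subset size, 1..number of features.
#' @param min_samples CART stopping threshold (default 5).
#' @param seed seed for the shared 8:2 split.
#' @param test_fraction held-out fraction (default 0.2).
#' @param feature_names candidate features (default the twenty report
#'   features).
#' @param subject_wise split by subject instead of by segment (avoids
#'   leakage from overlapping windows across the split; requires a
#'   \code{subject_id} column).
#' @return A \code{data.frame} ranked by accuracy: one row per subset with
#'   \code{subset} (comma-joined names), \code{SEN}, \code{SPE}, \code{PPV},
#'   \code{ACC}, \code{rank}.
#' @export
exhaustive_subset_search <- function(features, k, min_samples = 5, seed = 1L,
                                     test_fraction = 0.2,
                                     feature_names = hrv_feature_names(),
                                     subject_wise = FALSE) {
  if (k < 1 || k > length(feature_names)) stop("k out of range")
  labels <- features$label
  if (subject_wise) {
    subj <- unique(features$subject_id)
    set.seed(as.integer(seed))
    test_subj <- sample(subj, max(1, round(test_fraction * length(subj))))
    test <- which(features$subject_id %in% test_subj)
    train <- setdiff(seq_len(nrow(features)), test)
    split <- list(train = train, test = test)
  } else {
    split <- train_test_split(nrow(features), labels,
                              test_fraction = test_fraction, seed = seed)
  }
  xm <- as.matrix(features[, feature_names, drop = FALSE])
  y <- label01(labels)
  combs <- utils::combn(length(feature_names), k)
  res <- matrix(NA_real_, ncol(combs), 4)
  for (i in seq_len(ncol(combs))) {
    cols <- combs[, i]
    tree <- build_tree(xm[split$train, cols, drop = FALSE], y[split$train],
                       min_samples = min_samples)
    cm <- evaluate(tree, xm[split$test, cols, drop = FALSE], y[split$test])
    res[i, ] <- c(cm$SEN, cm$SPE, cm$PPV, cm$ACC)
  }
  subset_names <- apply(combs, 2, function(cols) {
    paste(feature_names[cols], collapse = ",")
  })
  out <- data.frame(subset = subset_names, k = k,
                    SEN = res[, 1], SPE = res[, 2], PPV = res[, 3],
                    ACC = res[, 4], stringsAsFactors = FALSE)
  ord <- order(-out$ACC, -out$SEN, out$subset)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "split") <- split
  out
}

#' Majority-class baseline accuracy
#'
#' Test-set accuracy of always predicting the training set's majority label;
#' the reference the feature-based classifiers must beat.
#'
#' @param train_labels,test_labels label vectors.
#' @return Accuracy in percent.
#' @export
majority_baseline <- function(train_labels, test_labels) {
  y_tr <- label01(train_labels)
  maj <- as.integer(mean(y_tr) >= 0.5)
  mean(label01(test_labels) == maj) * 100
}
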