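# Decision-DAG SVM: the N-class problem is split into N(N-1)/2 linear
# soft-margin binary classifiers on embeddings; prediction walks a directed
# acyclic elimination path, evaluating exactly N-1 of them. Pairwise fits
# are delegated to the libsvm backend (e1071); the DAG traversal, margin
# voting and the metric panel are implemented here.

#' Train a DAG-SVM on embeddings
#'
#' Fits one linear soft-margin SVM per unordered class pair, each on the
#' samples of its two classes only. The stored convention is
#' `w_ij . x + b_ij > 0` votes for the earlier class of the pair in
#' `class_order`.
#'
#' @param X embedding matrix, `n x D`.
#' @param labels class labels, length `n`; at least 2 classes with at least
#'   2 samples each.
#' @param cost soft-margin regularization constant.
#' @param class_order DAG node order; default lexicographic.
#' @return an object of class `dagsvm` with `classes` and `pairs` (each a
#'   list with `i`, `j`, `w`, `b`).
#' @export
train_dagsvm <- function(X, labels, cost = 1, class_order = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- class_order %||% sort(unique(labels))
  if (!setequal(classes, unique(labels)))
    stop("class_order must contain exactly the observed classes")
  if (length(classes) < 2) stop("need at least 2 classes")
  cnt <- table(labels)
  if (any(cnt < 2))
    stop("every class needs at least 2 samples; got ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  n_cl <- length(classes)
  pairs <- list()
  for (i in seq_len(n_cl - 1)) {
    for (j in (i + 1):n_cl) {
      sel <- labels %in% classes[c(i, j)]
      Xi <- X[sel, , drop = FALSE]
      yi <- factor(labels[sel], levels = classes[c(i, j)])
      fit <- e1071::svm(Xi, yi, kernel = "linear", cost = cost, scale = FALSE)
      w <- as.numeric(t(fit$coefs) %*% fit$SV)
      b <- -fit$rho
      # orient so positive margin votes for class i
      f <- Xi %*% w + b
      if (mean(f[yi == classes[i]]) < mean(f[yi == classes[j]])) {
        w <- -w; b <- -b
      }
      pairs[[paste(classes[i], classes[j], sep = "|")]] <-
        list(i = classes[i], j = classes[j], w = w, b = b)
    }
  }
  structure(list(classes = classes, pairs = pairs, dim = ncol(X), cost = cost),
            class = "dagsvm")
}

#' @export
print.dagsvm <- function(x, ...) {
  cat(sprintf("<dagsvm: %d classes (%s), %d pairwise linear classifiers, dim %d>\n",
              length(x$classes), paste(x$classes, collapse = " > "),
              length(x$pairs), x$dim))
  invisible(x)
}

pair_key <- function(model, a, b) {
  ia <- match(a, model$classes); ib <- match(b, model$classes)
  if (ia < ib) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

#' Classify one embedding by DAG traversal
#'
#' Maintains the ordered candidate list and, `N - 1` times, evaluates the
#' pairwise classifier of the current (first, last) candidates, removing the
#' losing class; the survivor is the prediction. A margin of exactly zero
#' eliminates the class later in the node order.
#'
#' @param model a [train_dagsvm()] model.
#' @param x embedding vector of length `model$dim`.
#' @param trace if `TRUE`, return the elimination trace as well.
#' @return the predicted class label, or (with `trace`) a list with `label`,
#'   `trace` (evaluated pairs) and `n_evals`.
#' @export
predict_dag <- function(model, x, trace = FALSE) {
  stopifnot(inherits(model, "dagsvm"))
  x <- as.numeric(x)
  if (length(x) != model$dim)
    stop("embedding has dimension ", length(x), ", model expects ", model$dim)
  cand <- model$classes
  path <- list()
  n_evals <- 0L
  while (length(cand) > 1) {
    a <- cand[1]; b <- cand[length(cand)]
    pr <- model$pairs[[pair_key(model, a, b)]]
    f <- sum(pr$w * x) + pr$b
    n_evals <- n_evals + 1L
    path[[n_evals]] <- c(pr$i, pr$j)
    # positive margin votes for pr$i (earlier in node order); ties
    # eliminate the later class
    loser <- if (f >= 0) pr$j else pr$i
    cand <- setdiff(cand, loser)
  }
  stopifnot(n_evals == length(model$classes) - 1L)
  if (trace) list(label = cand, trace = path, n_evals = n_evals) else cand
}

#' Classify a matrix of embeddings
#'
#' @param model a `dagsvm` model.
#' @param X embedding matrix `n x D`.
#' @return character vector of predicted labels.
#' @export
predict_dag_matrix <- function(model, X) {
  X <- as.matrix(X)
  vapply(seq_len(nrow(X)), function(r) predict_dag(model, X[r, ]), "")
}

#' Per-class margin-vote scores
#'
#' Continuous surrogate scores for AUC computation: each class's score is
#' the sum of its signed margins over all pairwise classifiers involving it
#' (one-vs-one margin voting).
#'
#' @param model a `dagsvm` model.
#' @param X embedding matrix `n x D`.
#' @return numeric matrix `n x N`, columns named by class.
#' @export
decision_scores <- function(model, X) {
  stopifnot(inherits(model, "dagsvm"))
  X <- as.matrix(X)
  S <- matrix(0, nrow(X), length(model$classes),
              dimnames = list(NULL, model$classes))
  for (pr in model$pairs) {
    f <- as.numeric(X %*% pr$w + pr$b)
    S[, pr$i] <- S[, pr$i] + f
    S[, pr$j] <- S[, pr$j] - f
  }
  S
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace/n` and chance agreement `p_e = sum_k row_k col_k / n^2`.
#'
#' @param cm square nonnegative matrix (rows = truth, columns = predicted).
#' @return kappa, or `NA` when `p_e = 1` (degenerate single-cell matrix).
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix must have positive total")
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Rank-based (Mann-Whitney) ROC AUC
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half; equals the normalized Mann-Whitney U statistic.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (logical, 0/1, or two-level factor where the
#'   second level is positive).
#' @return AUC in \[0, 1\]; `NA` if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Micro- and macro-averaged multiclass AUC
#'
#' One-vs-rest aggregation of [roc_auc()]: micro pools all (score,
#' indicator) pairs across classes into one ranking; macro averages the
#' per-class AUCs, skipping (with a warning) classes absent from the truth.
#'
#' @param scores matrix `n x K`, columns named by class.
#' @param labels true class labels, length `n`.
#' @return list with `micro`, `macro` and `per_class`.
#' @export
multiclass_auc <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- colnames(scores)
  stopifnot(!is.null(classes))
  per <- vapply(classes, function(cl) roc_auc(scores[, cl], labels == cl), 0)
  if (any(is.na(per)))
    warning("classes absent from truth skipped in macro AUC: ",
            paste(classes[is.na(per)], collapse = ", "))
  micro <- roc_auc(as.numeric(scores),
                   as.logical(outer(labels, classes, "==")))
  list(micro = micro, macro = mean(per, na.rm = TRUE), per_class = per)
}

#' Full classification metric panel
#'
#' Confusion matrix, overall accuracy, per-class and macro precision and
#' recall, Cohen's kappa, and micro/macro AUC when scores are supplied.
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param scores optional `n x K` score matrix for the AUCs.
#' @return object of class `metric_panel` (a list).
#' @export
metric_panel <- function(truth, predicted, scores = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(union(truth, predicted))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  out <- list(confusion = cm, accuracy = acc,
              precision = prec, recall = rec,
              macro_precision = mean(prec), macro_recall = mean(rec),
              kappa = cohens_kappa(cm))
  if (!is.null(scores)) {
    auc <- multiclass_auc(scores, truth)
    out$micro_auc <- auc$micro
    out$macro_auc <- auc$macro
    out$per_class_auc <- auc$per_class
  }
  structure(out, class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  cat(sprintf("accuracy %.4f | kappa %.4f | macro P %.4f R %.4f",
              x$accuracy, x$kappa, x$macro_precision, x$macro_recall))
  if (!is.null(x$micro_auc))
    cat(sprintf(" | AUC micro %.4f macro %.4f", x$micro_auc, x$macro_auc))
  cat("\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize a DAG-SVM model to JSON
#' @param model a `dagsvm` model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dagsvm <- function(model, path) {
  jsonlite::write_json(
    list(classes = model$classes, dim = model$dim, cost = model$cost,
         pairs = lapply(model$pairs, function(p)
           list(i = p$i, j = p$j, w = p$w, b = p$b))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a DAG-SVM model from JSON
#' @param path file written by [write_dagsvm()].
#' @return a `dagsvm` model.
#' @export
read_dagsvm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- lapply(j$pairs, function(p)
    list(i = p$i, j = p$j, w = as.numeric(p$w), b = as.numeric(p$b)))
  structure(list(classes = j$classes, pairs = pairs, dim = j$dim,
                 cost = j$cost), class = "dagsvm")
}
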