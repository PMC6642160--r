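# hand-built 2-class-pair model in 2-D for traversal tests
hand_model <- function() {
  structure(list(
    classes = c("c1", "c2", "c3"),
    pairs = list(
      "c1|c2" = list(i = "c1", j = "c2", w = c(1, 0), b = 0),    # x>0 -> c1
      "c1|c3" = list(i = "c1", j = "c3", w = c(0, 1), b = 0),    # y>0 -> c1
      "c2|c3" = list(i = "c2", j = "c3", w = c(-1, 0), b = 0)    # x<0 -> c2
    ), dim = 2L, cost = 1), class = "dagsvm")
}

test_that("a 3-class model holds N(N-1)/2 pairwise classifiers", {
  ec <- generate_embedding_clusters(3, 30, dim = 8, separation = 8, seed = 1)
  m <- train_dagsvm(ec$X, ec$labels)
  expect_length(m$pairs, 3)
  expect_true(all(vapply(m$pairs, function(p) length(p$w), 0L) == 8))
  ec4 <- generate_embedding_clusters(4, 20, dim = 8, separation = 8, seed = 2)
  expect_length(train_dagsvm(ec4$X, ec4$labels)$pairs, 6)
})

test_that("training rejects undersized classes", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(train_dagsvm(X, c("a", "a", "a", "a", "b")), "at least 2 samples")
  expect_error(train_dagsvm(X, rep("a", 5)), "at least 2 classes")
})

test_that("a separable pair's classifier is perfect on its own classes", {
  ec <- generate_embedding_clusters(3, 40, dim = 4, separation = 12, seed = 3)
  m <- train_dagsvm(ec$X, ec$labels)
  pr <- m$pairs[["C1|C2"]]
  sel <- ec$labels %in% c("C1", "C2")
  f <- ec$X[sel, ] %*% pr$w + pr$b
  expect_true(all((f > 0) == (ec$labels[sel] == "C1")))
})

test_that("DAG traversal follows the documented elimination order", {
  m <- hand_model()
  # x = (1, 1): (c1,c3) node: y>0 eliminates c3; (c1,c2): x>0 eliminates c2
  res <- predict_dag(m, c(1, 1), trace = TRUE)
  expect_equal(res$label, "c1")
  expect_equal(res$n_evals, 2)
  expect_equal(res$trace, list(c("c1", "c3"), c("c1", "c2")))
  # x = (-1, 1): c3 out, then c2 beats c1
  expect_equal(predict_dag(m, c(-1, 1)), "c2")
  # x = (-1, -1): c1 out at (c1,c3), then (c2,c3) with x<0 -> c2
  res3 <- predict_dag(m, c(-1, -1), trace = TRUE)
  expect_equal(res3$trace[[1]], c("c1", "c3"))
  expect_equal(res3$trace[[2]], c("c2", "c3"))
  expect_equal(res3$label, "c2")
  # zero margin eliminates the later-ordered class
  expect_equal(predict_dag(m, c(0, 0)), "c1")
  expect_error(predict_dag(m, c(1, 2, 3)), "dimension")
})

test_that("two-class prediction reduces to the classifier sign", {
  ec <- generate_embedding_clusters(2, 30, dim = 4, separation = 9, seed = 4)
  m <- train_dagsvm(ec$X, ec$labels)
  expect_length(m$pairs, 1)
  pr <- m$pairs[[1]]
  te <- generate_embedding_clusters(2, 50, dim = 4, separation = 9, seed = 5)
  f <- te$X %*% pr$w + pr$b
  expect_identical(predict_dag_matrix(m, te$X),
                   ifelse(f >= 0, "C1", "C2")[, 1])
})

test_that("well-separated clusters are classified near-perfectly", {
  tr <- generate_embedding_clusters(3, 100, dim = 16, separation = 10, seed = 6)
  m <- train_dagsvm(tr$X, tr$labels)
  te <- generate_embedding_clusters(3, 500, dim = 16, separation = 10, seed = 7)
  acc <- mean(predict_dag_matrix(m, te$X) == as.character(te$labels))
  expect_gte(acc, 0.999)
  auc <- multiclass_auc(decision_scores(m, te$X), te$labels)
  expect_gte(auc$micro, 0.999)
})

test_that("margin-vote scores are symmetric and definitionally consistent", {
  m2 <- structure(list(classes = c("a", "b"),
                       pairs = list("a|b" = list(i = "a", j = "b",
                                                 w = c(2, 0), b = -1)),
                       dim = 2L, cost = 1), class = "dagsvm")
  # boundary point: both scores zero
  expect_equal(as.numeric(decision_scores(m2, matrix(c(0.5, 3), 1))), c(0, 0))
  # single pair: scores are (+m, -m)
  s <- decision_scores(m2, matrix(c(2, 0), 1))
  expect_equal(as.numeric(s), c(3, -3))
})

test_that("an isolated class is never predicted across its margins", {
  # class Z lives at x > 5; points with every Z-hyperplane against them
  # must never be labeled Z
  set.seed(8)
  X <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 1.5), 40, 2),
             cbind(rnorm(40, 8), rnorm(40)))
  y <- rep(c("A", "B", "Z"), each = 40)
  m <- train_dagsvm(X, y)
  probe <- cbind(rnorm(100, -2), rnorm(100))
  keyAZ <- rccpath:::pair_key(m, "A", "Z"); keyBZ <- rccpath:::pair_key(m, "B", "Z")
  fa <- probe %*% m$pairs[[keyAZ]]$w + m$pairs[[keyAZ]]$b
  fb <- probe %*% m$pairs[[keyBZ]]$w + m$pairs[[keyBZ]]$b
  # orientation: positive votes for the earlier class (A or B)
  wrong_side <- fa > 0 & fb > 0
  pred <- predict_dag_matrix(m, probe)
  expect_false(any(pred[wrong_side] == "Z"))
})

test_that("kappa matches the chance-corrected agreement formula", {
  expect_equal(cohens_kappa(diag(c(5, 3, 2))), 1)
  expect_equal(cohens_kappa(matrix(c(2, 1, 1, 2), 2)), 1 / 3, tolerance = 1e-9)
  # independence: confusion = outer product of marginals -> kappa 0
  r <- c(30, 20, 50)
  cm <- outer(r, r) / sum(r)
  expect_equal(cohens_kappa(cm), 0, tolerance = 1e-12)
  # invariant under simultaneous row/column permutation
  set.seed(9)
  cm2 <- matrix(rpois(9, 10), 3)
  perm <- c(3, 1, 2)
  expect_equal(cohens_kappa(cm2), cohens_kappa(cm2[perm, perm]))
  expect_true(is.na(cohens_kappa(matrix(c(4, 0, 0, 0), 2))))
  expect_error(cohens_kappa(matrix(0, 2, 3)), "square")
})

test_that("AUC equals the concordant-pair fraction", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(roc_auc(1:5, rep(1, 5))))
  set.seed(10)
  for (k in 1:50) {
    n <- sample(2:50, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    expect_equal(roc_auc(sc, lb), oracle_auc(sc, lb))
  }
})

test_that("macro AUC skips absent classes with a warning", {
  set.seed(14)
  sc <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  truth <- rep(c("a", "b"), 5)   # class c never occurs
  expect_warning(res <- multiclass_auc(sc, truth), "skipped")
  expect_true(is.finite(res$macro))
  expect_true(is.na(res$per_class["c"]))
})

test_that("the metric panel is internally consistent", {
  truth <- rep(c("a", "b", "c"), times = c(10, 10, 10))
  set.seed(11)
  pred <- ifelse(runif(30) < 0.8, truth, sample(c("a", "b", "c"), 30, TRUE))
  mp <- metric_panel(truth, pred)
  expect_equal(mp$accuracy, sum(diag(mp$confusion)) / sum(mp$confusion))
  expect_equal(unname(mp$recall["a"]),
               sum(truth == "a" & pred == "a") / sum(truth == "a"))
  expect_lte(mp$kappa, mp$accuracy)
})

test_that("models survive a JSON round-trip", {
  ec <- generate_embedding_clusters(3, 20, dim = 4, separation = 8, seed = 12)
  m <- train_dagsvm(ec$X, ec$labels)
  path <- tempfile(fileext = ".json")
  write_dagsvm(m, path)
  m2 <- read_dagsvm(path)
  te <- generate_embedding_clusters(3, 50, dim = 4, separation = 8, seed = 13)
  expect_identical(predict_dag_matrix(m, te$X), predict_dag_matrix(m2, te$X))
})
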