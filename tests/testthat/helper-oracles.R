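# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles, without calling the
# package implementation they check.

# background rule: count pixels whose mean-RGB intensity exceeds the cut
oracle_is_background <- function(img, threshold = 210, fraction = 0.5) {
  n_above <- 0L
  h <- dim(img)[1]; w <- dim(img)[2]
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mean(img[i, j, ]) > threshold) n_above <- n_above + 1L
  }
  n_above / (h * w) >= fraction
}

# 8-connectivity labeling by breadth-first search
oracle_label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0) {
        q <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- q[1] + di; nj <- q[2] + dj
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# AUC as the concordant-pair fraction (ties half)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# log-rank O/E/V by explicit risk-set bookkeeping at every event time
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  O <- 0; E <- 0; V <- 0
  for (tj in sort(unique(time[event == 1]))) {
    risk <- which(time >= tj)
    d <- sum(time == tj & event == 1)
    n <- length(risk)
    n1 <- sum(g1[risk])
    O <- O + sum(time == tj & event == 1 & g1)
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(NA_real_)
  (O - E)^2 / V
}

# random blob mask: union of random discs on an empty field
random_blob_mask <- function(h = 64, w = 64, n_blobs = 5, rmax = 9) {
  m <- matrix(FALSE, h, w)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w); r <- runif(1, 2, rmax)
    yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    m <- m | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
  }
  m
}

# flat-color patch helper
flat_patch <- function(value, size = 16) {
  array(value, c(size, size, 3))
}

# nearest-centroid classifier (train/test), used as the embedding oracle
nearest_centroid_acc <- function(X_tr, y_tr, X_te, y_te) {
  cls <- sort(unique(as.character(y_tr)))
  cents <- t(vapply(cls, function(cl)
    colMeans(X_tr[as.character(y_tr) == cl, , drop = FALSE]), numeric(ncol(X_tr))))
  d <- as.matrix(dist(rbind(cents, X_te)))[-(seq_along(cls)), seq_along(cls)]
  mean(cls[apply(d, 1, which.min)] == as.character(y_te))
}

# small labeled texture dataset: two visually distinct slide classes tiled
# into labeled patches (slide-level fixture for scorer tests)
two_class_patchset <- function(n_slides = 6, slide_px = 96, tile = 32, seed = 1) {
  out <- list()
  k <- 0
  for (i in seq_len(n_slides)) {
    lab <- if (i %% 2 == 0) "KIRC" else "KICH"
    s <- generate_slide(slide_spec(slide_px, slide_px, label = lab,
                                   tumor_fraction = 1, seed = seed * 100 + i))
    p <- tile_slide(s$img, tile_grid(tile, 0.5), sprintf("sl%d", i), lab)
    out <- c(out, filter_patches(p)$kept)
    k <- k + 1
  }
  out
}
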