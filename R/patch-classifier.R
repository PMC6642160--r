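# Patch scorer contract and training utilities: slide-level data split,
# minority-class augmentation, inverse-frequency resampling weights, and a
# small reference scorer trainable on CPU in seconds. The scorer exposes
# class probabilities and a penultimate-layer embedding; heavier convolutional
# backbones can be plugged in behind the same contract.

#' Scorer configuration
#'
#' @param hidden_dim size of the hidden (penultimate) layer; this is the
#'   embedding dimension of the reference scorer.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation-accuracy improvement before
#'   early stop.
#' @param iters_per_epoch optimizer iterations per epoch.
#' @param decay weight decay of the network.
#' @param seed integer seed for weight initialization.
#' @return an object of class `scorer_config`.
#' @export
scorer_config <- function(hidden_dim = 16, max_epochs = 40, patience = 5,
                          iters_per_epoch = 25, decay = 1e-3, seed = 1) {
  structure(list(hidden_dim = hidden_dim, max_epochs = max_epochs,
                 patience = patience, iters_per_epoch = iters_per_epoch,
                 decay = decay, seed = as.integer(seed)),
            class = "scorer_config")
}

#' Summary features of a patch
#'
#' The reference scorer's input representation: channel statistics, an
#' 8-bin intensity histogram, gradient energy and dark/bright pixel
#' fractions. 20 values per patch.
#'
#' @param img `H x W x 3` array, 0-255 (or an `rcc_patch`).
#' @return named numeric vector of length 20.
#' @export
patch_features <- function(img) {
  if (inherits(img, "rcc_patch")) img <- img$img
  stop_if_not_rgb(img)
  inten <- pixel_intensity(img)
  ch_mean <- vapply(1:3, function(ch) mean(img[, , ch]), 0)
  ch_sd <- vapply(1:3, function(ch) sd(img[, , ch]), 0)
  hist8 <- tabulate(pmin(floor(inten / 32) + 1, 8), 8) / length(inten)
  gx <- mean(abs(inten[, -1] - inten[, -ncol(inten)]))
  gy <- mean(abs(inten[-1, ] - inten[-nrow(inten), ]))
  c(r_mean = ch_mean[1], g_mean = ch_mean[2], b_mean = ch_mean[3],
    r_sd = ch_sd[1], g_sd = ch_sd[2], b_sd = ch_sd[3],
    setNames(hist8, paste0("hist", 1:8)),
    grad_x = gx, grad_y = gy,
    dark_frac = mean(inten < 120), bright_frac = mean(inten > 210),
    rg_diff = ch_mean[1] - ch_mean[2], gb_diff = ch_mean[2] - ch_mean[3])
}

#' Split a slide manifest into train/validation/test
#'
#' The split is made at slide level so that all patches of a slide land in
#' one fold (50%-overlap patches are near-duplicates; patch-level splits
#' would leak). Fold sizes follow the largest-remainder rounding of the
#' requested fractions.
#'
#' @param manifest data.frame with one row per slide and columns `slide_id`,
#'   `label`.
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed.
#' @param stratify if `TRUE`, apply the largest-remainder allocation within
#'   each class, guaranteeing class presence in every fold when each class
#'   has at least 3 slides.
#' @return list of character vectors `train`, `val`, `test` (slide ids).
#' @export
split_dataset <- function(manifest, fractions = c(0.70, 0.15, 0.15), seed = 1,
                          stratify = FALSE) {
  stopifnot(all(c("slide_id", "label") %in% names(manifest)))
  if (anyNA(manifest$label)) stop("every slide needs a label before splitting")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  tab <- table(manifest$label)
  if (any(tab < 3))
    stop("each class needs at least 3 slides; got ",
         paste(names(tab)[tab < 3], tab[tab < 3], collapse = ", "))
  set.seed(seed)
  assign_fold <- function(ids) {
    n <- length(ids)
    q <- n * fractions
    base <- floor(q)
    left <- n - sum(base)
    if (left > 0) {
      extra <- order(q - base, decreasing = TRUE)[seq_len(left)]
      base[extra] <- base[extra] + 1
    }
    ids <- sample(ids)
    fold <- factor(rep(c("train", "val", "test"), times = base),
                   levels = c("train", "val", "test"))
    split(ids, fold)
  }
  if (stratify) {
    parts <- lapply(split(manifest$slide_id, manifest$label), assign_fold)
    out <- list(
      train = unname(unlist(lapply(parts, `[[`, "train"))),
      val = unname(unlist(lapply(parts, `[[`, "val"))),
      test = unname(unlist(lapply(parts, `[[`, "test")))
    )
  } else {
    p <- assign_fold(manifest$slide_id)
    out <- list(train = unname(p$train %||% character()),
                val = unname(p$val %||% character()),
                test = unname(p$test %||% character()))
  }
  out
}

patch_feature_matrix <- function(patches) {
  X <- t(vapply(patches, patch_features, numeric(20)))
  rownames(X) <- NULL
  X
}

# hidden-layer activations of a single-hidden-layer nnet
nnet_hidden <- function(net, X) {
  p <- net$n[1]; h <- net$n[2]
  W1 <- matrix(net$wts[seq_len((p + 1) * h)], p + 1, h)
  z <- cbind(1, X) %*% W1
  1 / (1 + exp(-z))
}

#' Train the reference patch scorer
#'
#' A single-hidden-layer softmax network over [patch_features()], trained in
#' epochs with warm restarts; the epoch with the best validation accuracy is
#' kept and training stops early after `patience` epochs without
#' improvement. Features are standardized by training-set mean/sd.
#'
#' @param train_patches,val_patches lists of labeled `rcc_patch` objects.
#' @param config a [scorer_config()].
#' @return an object of class `rcc_scorer` with fields `classes`,
#'   `embed_dim`, `val_trace`, `epochs_run`.
#' @export
train_scorer <- function(train_patches, val_patches, config = scorer_config()) {
  stopifnot(inherits(config, "scorer_config"))
  y_tr <- factor(vapply(train_patches, `[[`, "", "label"))
  if (nlevels(y_tr) < 2) stop("training data must contain at least 2 classes")
  y_va <- factor(vapply(val_patches, `[[`, "", "label"), levels = levels(y_tr))
  X_tr <- patch_feature_matrix(train_patches)
  X_va <- patch_feature_matrix(val_patches)
  ctr <- colMeans(X_tr)
  scl <- apply(X_tr, 2, sd)
  scl[scl < 1e-8] <- 1
  X_tr <- scale(X_tr, ctr, scl)
  X_va <- scale(X_va, ctr, scl)
  Y_tr <- nnet::class.ind(y_tr)

  set.seed(config$seed)
  net <- NULL
  best <- list(acc = -Inf, wts = NULL, epoch = 0L)
  trace <- numeric(0)
  for (ep in seq_len(config$max_epochs)) {
    net <- if (is.null(net)) {
      nnet::nnet(X_tr, Y_tr, size = config$hidden_dim, softmax = TRUE,
                 maxit = config$iters_per_epoch, decay = config$decay,
                 trace = FALSE, MaxNWts = 50000)
    } else {
      nnet::nnet(X_tr, Y_tr, size = config$hidden_dim, softmax = TRUE,
                 maxit = config$iters_per_epoch, decay = config$decay,
                 trace = FALSE, MaxNWts = 50000, Wts = net$wts)
    }
    pred <- levels(y_tr)[max.col(predict(net, X_va))]
    acc <- mean(pred == as.character(y_va))
    trace <- c(trace, acc)
    if (acc > best$acc + 1e-9) best <- list(acc = acc, wts = net$wts, epoch = ep)
    if (ep - best$epoch >= config$patience) break
  }
  net$wts <- best$wts
  structure(list(net = net, classes = levels(y_tr), center = ctr, scale = scl,
                 embed_dim = config$hidden_dim, val_trace = trace,
                 epochs_run = length(trace), best_val_acc = best$acc,
                 trained = TRUE),
            class = "rcc_scorer")
}

#' @export
print.rcc_scorer <- function(x, ...) {
  cat(sprintf("<rcc_scorer: %d classes (%s), embed dim %d, %d epochs, best val acc %.3f>\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              x$embed_dim, x$epochs_run, x$best_val_acc))
  invisible(x)
}

#' Class probabilities for patches
#'
#' @param scorer a trained `rcc_scorer`.
#' @param patches list of `rcc_patch` objects (or a feature matrix).
#' @return matrix `n x K` of class probabilities; rows sum to 1.
#' @export
score_patches <- function(scorer, patches) {
  stopifnot(inherits(scorer, "rcc_scorer"), isTRUE(scorer$trained))
  X <- if (is.matrix(patches)) patches else patch_feature_matrix(patches)
  X <- scale(X, scorer$center, scorer$scale)
  P <- predict(scorer$net, X)
  if (is.null(dim(P))) P <- cbind(1 - P, P)
  colnames(P) <- scorer$classes
  P / rowSums(P)
}

#' Penultimate-layer embeddings for patches
#'
#' @inheritParams score_patches
#' @return matrix `n x D` (D = `scorer$embed_dim`), deterministic given the
#'   scorer's weights.
#' @export
extract_embeddings <- function(scorer, patches) {
  if (!inherits(scorer, "rcc_scorer") || !isTRUE(scorer$trained))
    stop("scorer must be a trained rcc_scorer")
  X <- if (is.matrix(patches)) patches else patch_feature_matrix(patches)
  X <- scale(X, scorer$center, scorer$scale)
  E <- nnet_hidden(scorer$net, X)
  if (any(!is.finite(E))) stop("non-finite embedding values")
  E
}

#' Vertical flip of an image
#' @param img `H x W x 3` array.
#' @return flipped array.
#' @export
flip_vertical <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]

#' Rotate an image with mirror-reflected borders
#'
#' Nearest-neighbor rotation about the image center; source coordinates
#' falling outside the image are mirror-reflected back in, so no
#' background-colored corners are introduced.
#'
#' @param img `H x W x 3` array.
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @return rotated array of the same size.
#' @export
rotate_reflect <- function(img, angle_deg) {
  h <- dim(img)[1]; w <- dim(img)[2]
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- matrix(seq_len(h), h, w) - cy
  gx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sy <- reflect_index(round(cy + gy * cos(th) - gx * sin(th)), h)
  sx <- reflect_index(round(cx + gy * sin(th) + gx * cos(th)), w)
  out <- img
  idx <- cbind(as.vector(sy), as.vector(sx))
  for (ch in 1:3)
    out[, , ch] <- matrix(img[, , ch][idx], h, w)
  out
}

#' Additive Gaussian pixel noise
#' @param img `H x W x 3` array, 0-255.
#' @param sd noise standard deviation in intensity units.
#' @return noisy array, clipped to \[0, 255\].
#' @export
add_gaussian_noise <- function(img, sd = 10) {
  clamp255(img + array(rnorm(length(img), 0, sd), dim(img)))
}

#' Augment a minority class to a target count
#'
#' Keeps the original patches and appends `target_count - n` new ones, each
#' drawn by sampling a source patch uniformly with replacement and applying
#' three stochastic transforms independently with probability `p_apply`:
#' vertical flip, rotation in `angle_range` (mirror-filled corners) and
#' Gaussian pixel noise.
#'
#' @param patches non-empty list of `rcc_patch` objects.
#' @param target_count desired output count (at least `length(patches)`).
#' @param seed integer seed.
#' @param p_apply per-transform application probability.
#' @param angle_range rotation range in degrees.
#' @param noise_sd Gaussian noise sd, intensity units.
#' @return list of `target_count` patches (originals first).
#' @export
augment_minority <- function(patches, target_count, seed = 1, p_apply = 0.5,
                             angle_range = c(-25, 25), noise_sd = 10) {
  if (length(patches) == 0) stop("cannot augment an empty patch list")
  if (target_count < length(patches))
    stop("target_count must be at least the input count")
  set.seed(seed)
  out <- patches
  n_new <- target_count - length(patches)
  for (k in seq_len(n_new)) {
    src <- patches[[sample.int(length(patches), 1)]]
    img <- src$img
    if (runif(1) < p_apply) img <- flip_vertical(img)
    if (runif(1) < p_apply)
      img <- rotate_reflect(img, runif(1, angle_range[1], angle_range[2]))
    if (runif(1) < p_apply) img <- add_gaussian_noise(img, noise_sd)
    aug <- src
    aug$img <- img
    aug$augmented <- TRUE
    out[[length(patches) + k]] <- aug
  }
  out
}

#' Inverse-frequency sampling weights
#'
#' Weight of sample i is proportional to `1 / count(class(i))`, normalized
#' to sum to 1; under weighted resampling every class is drawn with equal
#' expected frequency.
#'
#' @param labels vector of class labels (length at least 1).
#' @return numeric weights summing to 1.
#' @export
weighted_sample_weights <- function(labels) {
  if (length(labels) == 0) stop("need at least one sample")
  cnt <- table(labels)
  w <- 1 / as.numeric(cnt[as.character(labels)])
  w / sum(w)
}
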