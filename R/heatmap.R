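# Tumor-probability heatmaps and cleaned high-probability masks. Overlapping
# patch probabilities are combined by per-pixel averaging; masks use strict
# thresholds and the one-third-of-main-region cleanup rule.

#' Build a per-pixel probability heatmap from scored patches
#'
#' Each covered pixel's value is the mean tumor probability of all patches
#' whose footprint covers it; pixels covered by no kept patch are `NA`
#' (absent).
#'
#' @param manifest data.frame with one row per kept patch: columns `x`, `y`
#'   (0-based pixel origin) and `score` in \[0, 1\].
#' @param slide_shape integer `c(height, width)` of the slide.
#' @param grid the [tile_grid()] used for tiling.
#' @param scale optional downsampling factor in (0, 1\]; the heatmap is
#'   materialized at `slide_shape * scale`. Package-scale slides default to
#'   full resolution.
#' @return numeric matrix (`NA` = uncovered), with attribute `scale`.
#' @export
build_heatmap <- function(manifest, slide_shape, grid, scale = 1) {
  if (nrow(manifest) == 0) stop("empty patch manifest")
  if (any(manifest$score < 0 | manifest$score > 1))
    stop("patch scores must lie in [0, 1]")
  h <- max(1L, as.integer(round(slide_shape[1] * scale)))
  w <- max(1L, as.integer(round(slide_shape[2] * scale)))
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  ts <- grid$tile_size
  for (r in seq_len(nrow(manifest))) {
    y0 <- max(1L, as.integer(floor(manifest$y[r] * scale)) + 1L)
    x0 <- max(1L, as.integer(floor(manifest$x[r] * scale)) + 1L)
    y1 <- min(h, as.integer(ceiling((manifest$y[r] + ts) * scale)))
    x1 <- min(w, as.integer(ceiling((manifest$x[r] + ts) * scale)))
    if (y1 < y0 || x1 < x0) next
    acc[y0:y1, x0:x1] <- acc[y0:y1, x0:x1] + manifest$score[r]
    cnt[y0:y1, x0:x1] <- cnt[y0:y1, x0:x1] + 1L
  }
  heat <- acc / cnt
  heat[cnt == 0L] <- NA_real_
  attr(heat, "scale") <- scale
  heat
}

#' Slide-level score: fraction of positively classified patches
#'
#' @param scores per-patch tumor probabilities of the kept patches.
#' @param threshold positivity cut; a patch counts as positive when its
#'   score is strictly greater.
#' @return fraction in \[0, 1\]; `NA` (with warning) when no patch was kept.
#' @export
slide_score <- function(scores, threshold = 0.5) {
  if (length(scores) == 0) {
    warning("no kept patches; slide score undefined")
    return(NA_real_)
  }
  mean(scores > threshold)
}

#' High-probability binary mask
#'
#' @param heatmap matrix from [build_heatmap()] (`NA` = uncovered).
#' @param threshold probability cut; strictly-greater pixels are masked.
#' @return logical matrix; uncovered pixels are `FALSE`.
#' @export
high_prob_mask <- function(heatmap, threshold = 0.95) {
  m <- heatmap > threshold
  m[is.na(m)] <- FALSE
  m
}

#' 8-connectivity connected-component labeling
#'
#' 4-connectivity labeling (EBImage) followed by union-find merging of
#' labels that touch diagonally, yielding 8-connected components.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  nl <- max(lab)
  if (nl <= 1) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  parent <- seq_len(nl)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  h <- nrow(lab); w <- ncol(lab)
  # diagonal neighbor pairs: down-right and down-left
  a <- lab[-h, -w]; b <- lab[-1, -1]
  for (k in which(a > 0 & b > 0 & a != b)) unite(a[k], b[k])
  a <- lab[-h, -1]; b <- lab[-1, -w]
  for (k in which(a > 0 & b > 0 & a != b)) unite(a[k], b[k])
  roots <- vapply(seq_len(nl), find, 0L)
  dense <- match(roots, sort(unique(roots)))
  out <- matrix(0L, h, w)
  nz <- lab > 0
  out[nz] <- dense[lab[nz]]
  out
}

#' Clean a tumor mask with the one-third-of-main-region rule
#'
#' Labels the mask with 8-connectivity, takes the largest component as the
#' main region and removes every component whose area is less than one
#' third of the main region's area.
#'
#' @param mask logical matrix (e.g. from [high_prob_mask()]).
#' @param min_frac area fraction of the main region below which components
#'   are dropped.
#' @return object of class `tumor_mask`: a list with `mask` (cleaned
#'   logical matrix), `labels` (cleaned label matrix), `components`
#'   (data.frame `id, area, retained`) and `main_id`.
#' @export
clean_mask <- function(mask, min_frac = 1 / 3) {
  lab <- label_components(mask)
  nl <- max(lab)
  if (nl == 0) {
    return(structure(list(mask = matrix(FALSE, nrow(mask), ncol(mask)),
                          labels = lab,
                          components = data.frame(id = integer(),
                                                  area = integer(),
                                                  retained = logical()),
                          main_id = NA_integer_),
                     class = "tumor_mask"))
  }
  areas <- tabulate(lab[lab > 0], nl)
  main <- which.max(areas)
  retained <- areas >= min_frac * areas[main]
  keep <- lab > 0 & retained[pmax(lab, 1)]
  out_lab <- lab
  out_lab[!keep] <- 0L
  structure(list(mask = keep, labels = out_lab,
                 components = data.frame(id = seq_len(nl), area = areas,
                                         retained = retained),
                 main_id = main),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask: %d/%d components retained, main area %s px>\n",
              sum(x$components$retained), nrow(x$components),
              if (is.na(x$main_id)) "NA" else x$components$area[x$main_id]))
  invisible(x)
}
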