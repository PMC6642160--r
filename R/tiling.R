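# Slide tiling and background filtering. Patches are extracted on a regular
# grid with configurable overlap; near-white patches are discarded by the
# intensity-threshold rule used throughout renal WSI pipelines.

#' Define a tiling grid
#'
#' @param tile_size patch side length in pixels.
#' @param overlap_fraction fraction of overlap between neighboring patches,
#'   in \[0, 1). The stride is `tile_size * (1 - overlap_fraction)`, which
#'   must be a whole number of pixels.
#' @return an object of class `tile_grid` with fields `tile_size`,
#'   `overlap_fraction`, `stride`.
#' @export
tile_grid <- function(tile_size = 512, overlap_fraction = 0.5) {
  if (tile_size <= 0) stop("tile_size must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  stride <- tile_size * (1 - overlap_fraction)
  if (abs(stride - round(stride)) > 1e-8)
    stop("tile_size * (1 - overlap_fraction) must be an integer stride")
  stride <- as.integer(round(stride))
  if (stride < 1) stop("stride must be at least 1 px")
  structure(list(tile_size = as.integer(tile_size),
                 overlap_fraction = overlap_fraction, stride = stride),
            class = "tile_grid")
}

new_patch <- function(slide_id, row, col, x, y, img, label = NA_character_) {
  structure(list(slide_id = slide_id, row = row, col = col, x = x, y = y,
                 img = img, label = label), class = "rcc_patch")
}

#' @export
print.rcc_patch <- function(x, ...) {
  cat(sprintf("<patch %s row %d col %d at (x=%d, y=%d), %dpx, label=%s>\n",
              x$slide_id, x$row, x$col, x$x, x$y, dim(x$img)[1], x$label))
  invisible(x)
}

#' Tile a slide into overlapping patches
#'
#' Extracts `tile_size`-square patches at offsets `k * stride` along each
#' axis (0-based, half-open pixel bounds), in row-major order. Partial tiles
#' at the right/bottom edges are dropped, not padded, so the patch count is
#' `(floor((W - T)/s) + 1) * (floor((H - T)/s) + 1)`.
#'
#' @param img numeric `H x W x 3` array, 0-255.
#' @param grid a [tile_grid()].
#' @param slide_id identifier stored on each patch.
#' @param label optional slide-level label propagated to the patches.
#' @return list of `rcc_patch` objects.
#' @export
tile_slide <- function(img, grid, slide_id = "slide", label = NA_character_) {
  stop_if_not_rgb(img)
  stopifnot(inherits(grid, "tile_grid"))
  h <- dim(img)[1]; w <- dim(img)[2]
  ts <- grid$tile_size; s <- grid$stride
  if (h < ts || w < ts)
    stop(sprintf("image %dx%d is smaller than one %d-px tile", w, h, ts))
  nx <- floor((w - ts) / s) + 1
  ny <- floor((h - ts) / s) + 1
  patches <- vector("list", nx * ny)
  k <- 1L
  for (r in seq_len(ny)) {          # row-major: rows (y) outer, cols inner
    y <- (r - 1L) * s
    for (cl in seq_len(nx)) {
      x <- (cl - 1L) * s
      patches[[k]] <- new_patch(slide_id, r - 1L, cl - 1L, x, y,
                                img[(y + 1):(y + ts), (x + 1):(x + ts), , drop = FALSE],
                                label)
      k <- k + 1L
    }
  }
  patches
}

#' Background test for a patch
#'
#' A patch is background when bright pixels dominate it. Under the default
#' `"fraction_above"` reading, the patch is background iff at least
#' `fraction` of its pixels have mean-RGB intensity strictly above
#' `threshold`. The alternative `"brightest_mean"` reading flags the patch
#' when the mean intensity of its brightest `fraction` of pixels exceeds
#' `threshold`.
#'
#' @param patch an `rcc_patch` or an `H x W x 3` array (0-255).
#' @param threshold intensity threshold, 0-255.
#' @param fraction pixel fraction entering the rule.
#' @param method which reading of the rule to apply.
#' @return logical: `TRUE` if the patch is background (to be discarded).
#' @export
is_background <- function(patch, threshold = 210, fraction = 0.5,
                          method = c("fraction_above", "brightest_mean")) {
  method <- match.arg(method)
  img <- if (inherits(patch, "rcc_patch")) patch$img else patch
  inten <- pixel_intensity(img)
  if (method == "fraction_above") {
    mean(inten > threshold) >= fraction
  } else {
    k <- max(1L, ceiling(length(inten) * fraction))
    mean(sort(as.numeric(inten), decreasing = TRUE)[seq_len(k)]) > threshold
  }
}

#' Filter background patches
#'
#' Order-preserving: keeps exactly the patches for which [is_background()]
#' is `FALSE`.
#'
#' @param patches list of patches.
#' @inheritParams is_background
#' @return list with `kept` (patch list) and `discarded` (count).
#' @export
filter_patches <- function(patches, threshold = 210, fraction = 0.5,
                           method = c("fraction_above", "brightest_mean")) {
  method <- match.arg(method)
  if (length(patches) == 0) return(list(kept = list(), discarded = 0L))
  bg <- vapply(patches, is_background, logical(1),
               threshold = threshold, fraction = fraction, method = method)
  list(kept = patches[!bg], discarded = sum(bg))
}

#' Patch manifest
#'
#' Tabulates a patch list into the manifest written next to exported patch
#' images: one row per patch with its grid position and pixel origin.
#'
#' @param patches list of `rcc_patch` objects.
#' @param kept optional logical vector marking patches kept by the filter.
#' @return data.frame with columns `slide_id, row, col, x, y, label, kept`.
#' @export
patch_manifest <- function(patches, kept = rep(TRUE, length(patches))) {
  if (length(patches) == 0)
    return(data.frame(slide_id = character(), row = integer(), col = integer(),
                      x = integer(), y = integer(), label = character(),
                      kept = logical()))
  data.frame(
    slide_id = vapply(patches, `[[`, "", "slide_id"),
    row = vapply(patches, `[[`, 0L, "row"),
    col = vapply(patches, `[[`, 0L, "col"),
    x = vapply(patches, `[[`, 0L, "x"),
    y = vapply(patches, `[[`, 0L, "y"),
    label = vapply(patches, `[[`, "", "label"),
    kept = kept
  )
}
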