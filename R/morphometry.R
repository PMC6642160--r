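# Region and nuclei morphometry. Shape features follow the regionprops
# conventions: pixel-count areas, convex-hull area, outer-boundary perimeter
# from the half-level contour with staircase correction, and axes /
# eccentricity of the second-moment-matched ellipse.

# boundary length of a binary matrix: marching-squares contour at level 0.5
# on the zero-padded mask, corrected for staircase overestimation by
# Kulpa's factor pi / (8 * (sqrt(2) - 1)) ~ 0.948.
boundary_length <- function(mask) {
  pm <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pm[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  cl <- contourLines(seq_len(nrow(pm)), seq_len(ncol(pm)), pm, levels = 0.5)
  raw <- sum(vapply(cl, function(cc) {
    x <- c(cc$x, cc$x[1]); y <- c(cc$y, cc$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, 0))
  0.948 * raw
}

# pixel count of the convex hull of the component's pixel centers
convex_area_px <- function(idx) {
  if (nrow(idx) < 3) return(nrow(idx))
  hull <- grDevices::chull(idx[, 2], idx[, 1])   # x = col, y = row
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  if (length(hull) < 3) return(nrow(idx))
  rr <- min(idx[, 1]):max(idx[, 1])
  cc <- min(idx[, 2]):max(idx[, 2])
  py <- matrix(rr, length(rr), length(cc))
  px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  inside <- matrix(TRUE, length(rr), length(cc))
  nh <- length(hull)
  for (k in seq_len(nh)) {
    k2 <- if (k == nh) 1L else k + 1L
    cr <- (hx[k2] - hx[k]) * (py - hy[k]) - (hy[k2] - hy[k]) * (px - hx[k])
    inside <- inside & (cr <= 1e-9)   # chull returns clockwise order
  }
  sum(inside)
}

#' Shape features of one connected component
#'
#' Area, filled area (holes closed), convex area, perimeter, axis lengths
#' and eccentricity of the ellipse with matching second central moments
#' (with the 1/12 per-pixel variance term), solidity and the two
#' perimeter-area ratios.
#'
#' @param mask logical matrix containing a single nonempty component.
#' @return named list with fields `area`, `convex_area`, `filled_area`,
#'   `perimeter`, `major_axis`, `minor_axis`, `eccentricity`, `solidity`,
#'   `perimeter_by_area`, `perimeter2_by_area`.
#' @export
region_shape <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty component")
  area <- nrow(idx)
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  sub <- matrix(FALSE, max(idx[, 1]) - r0 + 1, max(idx[, 2]) - c0 + 1)
  sub[cbind(idx[, 1] - r0 + 1, idx[, 2] - c0 + 1)] <- TRUE
  filled <- EBImage::imageData(EBImage::fillHull(sub * 1)) > 0
  filled_area <- sum(filled)
  convex <- convex_area_px(idx)
  per <- boundary_length(filled)
  # second-moment ellipse; 1/12 is the variance of a unit pixel
  if (area == 1) {
    l1 <- l2 <- 1 / 12
  } else {
    ev <- eigen(cov(idx) * (area - 1) / area, symmetric = TRUE)$values
    l1 <- ev[1] + 1 / 12; l2 <- max(ev[2], 0) + 1 / 12
  }
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- sqrt(max(0, 1 - l2 / l1))
  list(area = area, convex_area = convex, filled_area = filled_area,
       perimeter = per, major_axis = major, minor_axis = minor,
       eccentricity = ecc, solidity = area / convex,
       perimeter_by_area = per / area, perimeter2_by_area = per^2 / area)
}

sum_fields <- c("area", "convex_area", "filled_area", "perimeter",
                "major_axis", "minor_axis")

#' Tumor-region features of a cleaned mask
#'
#' "Total" features sum each quantity over all retained components (ratio
#' features are re-derived from the summed numerator and denominator);
#' "main region" features describe the largest component alone.
#'
#' @param tumor_mask a [clean_mask()] result with at least one retained
#'   component; an empty mask yields an all-`NA` row with a warning.
#' @return named numeric vector with `total_*` and `main_*` entries.
#' @export
slide_tumor_features <- function(tumor_mask) {
  stopifnot(inherits(tumor_mask, "tumor_mask"))
  comp <- tumor_mask$components
  kept <- comp$id[comp$retained]
  nm_total <- c(paste0("total_", c(sum_fields, "perimeter_by_area",
                                   "perimeter2_by_area", "solidity")))
  nm_main <- paste0("main_", c(sum_fields, "perimeter_by_area",
                               "perimeter2_by_area", "solidity", "eccentricity"))
  if (length(kept) == 0) {
    warning("empty tumor mask; features undefined")
    return(setNames(rep(NA_real_, length(nm_total) + length(nm_main)),
                    c(nm_total, nm_main)))
  }
  shapes <- lapply(kept, function(id) region_shape(tumor_mask$labels == id))
  tot <- vapply(sum_fields, function(f)
    sum(vapply(shapes, `[[`, 0, f)), 0)
  total <- c(tot,
             perimeter_by_area = unname(tot["perimeter"] / tot["area"]),
             perimeter2_by_area = unname(tot["perimeter"]^2 / tot["area"]),
             solidity = unname(tot["area"] / tot["convex_area"]))
  main_shape <- shapes[[which.max(vapply(shapes, `[[`, 0, "area"))]]
  main <- c(unlist(main_shape[sum_fields]),
            perimeter_by_area = main_shape$perimeter_by_area,
            perimeter2_by_area = main_shape$perimeter2_by_area,
            solidity = main_shape$solidity,
            eccentricity = main_shape$eccentricity)
  setNames(c(total, main), c(nm_total, nm_main))
}

#' Canonical tumor-feature roster
#'
#' The 15 tumor shape features entering survival analysis by default: the
#' six summed quantities plus perimeter-by-area for both the total and the
#' main-region sets, and the main-region eccentricity. Solidity and
#' perimeter-squared-by-area are additionally emitted by
#' [slide_tumor_features()] but flagged non-canonical.
#'
#' @return character vector of 15 feature names.
#' @export
canonical_tumor_features <- function() {
  c(paste0("total_", c(sum_fields, "perimeter_by_area")),
    paste0("main_", c(sum_fields, "perimeter_by_area")),
    "main_eccentricity")
}

# Otsu threshold on a numeric vector (0-255 scale), 256-bin histogram.
# Returns the threshold maximizing between-class variance.
otsu_threshold <- function(v) {
  h <- tabulate(pmin(floor(v) + 1, 256), 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1
}

#' Segment nuclei by hierarchical Otsu thresholding
#'
#' Mean-RGB intensity is thresholded by Otsu's rule; while the darker
#' stratum retains a substantial share of the image's intensity spread
#' (still heterogeneous, e.g. cytoplasm plus nuclei), it is re-thresholded,
#' so the number of levels adapts to the image. The final dark stratum is
#' accepted only if its mean intensity is nucleus-dark; components below
#' `min_area` are removed.
#'
#' @param img `H x W x 3` array, 0-255 (or an `rcc_patch`).
#' @param min_area minimum nucleus area in pixels.
#' @param dark_max maximum mean intensity (0-255) for an accepted nucleus
#'   stratum; a blank bright patch therefore yields no nuclei.
#' @param spread_ratio recursion rule: re-threshold while the stratum's
#'   intensity sd exceeds this fraction of the whole image's sd.
#' @param max_depth maximum number of threshold levels.
#' @return integer label matrix (0 = background), one label per nucleus.
#' @export
segment_nuclei <- function(img, min_area = 15, dark_max = 150,
                           spread_ratio = 1 / 3, max_depth = 3) {
  if (inherits(img, "rcc_patch")) img <- img$img
  inten <- pixel_intensity(img)
  sd_all <- sd(inten)
  if (!is.finite(sd_all) || sd_all < 1)
    return(matrix(0L, nrow(inten), ncol(inten)))
  thr <- otsu_threshold(as.numeric(inten))
  depth <- 1
  repeat {
    stratum <- inten[inten <= thr]
    if (depth >= max_depth || length(stratum) < 2 ||
        sd(stratum) <= spread_ratio * sd_all) break
    thr <- otsu_threshold(as.numeric(stratum))
    depth <- depth + 1
  }
  cand <- inten <= thr
  if (!any(cand) || mean(inten[cand]) > dark_max)
    return(matrix(0L, nrow(inten), ncol(inten)))
  lab <- label_components(cand)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    small <- which(areas < min_area)
    if (length(small) > 0) {
      lab[lab %in% small] <- 0L
      keep <- sort(unique(lab[lab > 0]))
      lab[lab > 0] <- match(lab[lab > 0], keep)
    }
  }
  lab
}

nuclei_fields <- c("area", "convex_area", "filled_area", "perimeter",
                   "major_axis", "minor_axis", "eccentricity")

#' Nuclei features totaled over high-probability patches
#'
#' Segments every patch with [segment_nuclei()] and sums each per-nucleus
#' shape quantity over all nuclei of all patches: the seven totals are
#' area, convex area, filled area, perimeter, major axis, minor axis and
#' eccentricity.
#'
#' @param patches list of `rcc_patch` objects or raw `H x W x 3` arrays.
#' @param ... passed to [segment_nuclei()].
#' @return named numeric vector `nuc_total_*` (plus `nuc_count`); all-zero
#'   with a warning when no nucleus is found.
#' @export
slide_nuclei_features <- function(patches, ...) {
  if (length(patches) == 0) stop("need at least one patch")
  tot <- setNames(rep(0, length(nuclei_fields)),
                  paste0("nuc_total_", nuclei_fields))
  n_nuc <- 0L
  for (p in patches) {
    lab <- segment_nuclei(p, ...)
    for (id in seq_len(max(lab))) {
      sh <- region_shape(lab == id)
      tot <- tot + unlist(sh[nuclei_fields])
      n_nuc <- n_nuc + 1L
    }
  }
  if (n_nuc == 0L) warning("no nuclei segmented in any patch")
  c(tot, nuc_count = n_nuc)
}

#' Aggregate slide features to patient level
#'
#' Unweighted mean of every numeric feature over each patient's slides;
#' slides with any missing feature are dropped, and patients left without a
#' usable slide are excluded with a warning.
#'
#' @param slide_features data.frame with a `slide_id` column and numeric
#'   feature columns.
#' @param slide_to_patient data.frame with columns `slide_id`, `patient_id`.
#' @return data.frame with `patient_id` and per-feature means.
#' @export
aggregate_patients <- function(slide_features, slide_to_patient) {
  stopifnot("slide_id" %in% names(slide_features),
            all(c("slide_id", "patient_id") %in% names(slide_to_patient)))
  df <- merge(slide_features, slide_to_patient, by = "slide_id")
  feat_cols <- setdiff(names(df), c("slide_id", "patient_id"))
  usable <- stats::complete.cases(df[, feat_cols, drop = FALSE])
  lost <- setdiff(unique(df$patient_id), unique(df$patient_id[usable]))
  if (length(lost) > 0)
    warning("patients excluded (no usable slide): ", paste(lost, collapse = ", "))
  df <- df[usable, , drop = FALSE]
  out <- aggregate(df[, feat_cols, drop = FALSE],
                   by = list(patient_id = df$patient_id), FUN = mean)
  out[order(out$patient_id), , drop = FALSE]
}
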