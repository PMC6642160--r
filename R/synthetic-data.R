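# Synthetic fixtures: tissue-like slides with known tumor masks, nuclei
# scenes with analytic geometry, separable embedding clusters, and survival
# cohorts with known hazard structure. Every generator is deterministic in
# its seed.

default_texture_params <- function() {
  list(
    KIRC   = list(base_rgb = c(195, 115, 160), blob_density = 30, blob_radius = c(2, 5)),
    KIRP   = list(base_rgb = c(115, 170, 150), blob_density = 60, blob_radius = c(1, 3)),
    KICH   = list(base_rgb = c(170, 150, 105), blob_density = 15, blob_radius = c(4, 8)),
    normal = list(base_rgb = c(205, 175, 195), blob_density = 8,  blob_radius = c(1, 3))
  )
}

#' Specification for a synthetic slide
#'
#' Describes a tissue-like RGB slide: a near-white background, a rectangular
#' tissue region and (optionally) a tumor sub-region rendered with a
#' class-specific texture. Region corners are laid out on a coarse pixel
#' lattice so that ground-truth masks have crisp, reproducible boundaries.
#'
#' @param width,height slide size in pixels (each at least 32).
#' @param label slide class; must name an entry of `texture_params`. Use
#'   `"normal"` for a non-cancer slide (forces `tumor_fraction = 0`).
#' @param tumor_fraction fraction of the tissue area flagged tumor in the
#'   ground truth, in \[0, 1\].
#' @param background_level background intensity, 0-255; must exceed 210 so
#'   background patches trip the standard intensity filter.
#' @param tissue_fraction approximate fraction of the slide covered by
#'   tissue.
#' @param texture_params named list of per-class textures, each with
#'   `base_rgb` (length-3, mean strictly below 210), `blob_density`
#'   (blobs per 10^4 px^2) and `blob_radius` (range, px).
#' @param lattice granularity (px) of region corner placement.
#' @param seed integer seed.
#' @return an object of class `slide_spec`.
#' @export
slide_spec <- function(width, height, label = "KIRC", tumor_fraction = 1,
                       background_level = 245, tissue_fraction = 0.7,
                       texture_params = default_texture_params(),
                       lattice = 16, seed = 1) {
  if (width < 32 || height < 32) stop("slide must be at least 32 x 32 px")
  if (tumor_fraction < 0 || tumor_fraction > 1) stop("tumor_fraction must be in [0, 1]")
  if (background_level <= 210) stop("background_level must exceed 210")
  if (!label %in% names(texture_params)) stop("no texture for label ", label)
  for (tp in texture_params) {
    if (mean(tp$base_rgb) >= 210)
      stop("tissue base colors must average below 210 so the filter separates them")
  }
  if (identical(label, "normal")) tumor_fraction <- 0
  structure(list(width = width, height = height, label = label,
                 tumor_fraction = tumor_fraction,
                 background_level = background_level,
                 tissue_fraction = tissue_fraction,
                 texture_params = texture_params, lattice = lattice,
                 seed = as.integer(seed)),
            class = "slide_spec")
}

# snap v to the lattice, keeping it within [lo, hi]
snap <- function(v, lattice, lo, hi) min(max(round(v / lattice) * lattice, lo), hi)

# paint a textured region of `img` (H x W x 3) where `region` (H x W logical)
render_texture <- function(img, region, tp, noise_sd = 8) {
  h <- dim(img)[1]; w <- dim(img)[2]
  n_in <- sum(region)
  if (n_in == 0) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[region] <- clamp255(tp$base_rgb[ch] + rnorm(n_in, 0, noise_sd))
    img[, , ch] <- plane
  }
  # dark chromatin-like blobs
  area <- n_in
  n_blob <- round(tp$blob_density * area / 1e4)
  if (n_blob > 0) {
    idx <- which(region, arr.ind = TRUE)
    ctr <- idx[sample.int(nrow(idx), n_blob, replace = TRUE), , drop = FALSE]
    rad <- runif(n_blob, tp$blob_radius[1], tp$blob_radius[2])
    dark <- tp$base_rgb * 0.45
    for (b in seq_len(n_blob)) {
      r <- rad[b]
      rr <- max(1, floor(ctr[b, 1] - r)):min(h, ceiling(ctr[b, 1] + r))
      cc <- max(1, floor(ctr[b, 2] - r)):min(w, ceiling(ctr[b, 2] + r))
      d2 <- outer((rr - ctr[b, 1])^2, (cc - ctr[b, 2])^2, "+")
      hit <- d2 <= r^2 & region[rr, cc]
      for (ch in 1:3) {
        plane <- img[rr, cc, ch]
        plane[hit] <- dark[ch]
        img[rr, cc, ch] <- plane
      }
    }
  }
  img
}

#' Generate a synthetic slide with ground-truth tumor mask
#'
#' Renders a near-white background, a rectangular tissue region textured as
#' normal parenchyma, and a tumor sub-region textured with the class of
#' `spec$label` covering `spec$tumor_fraction` of the tissue. The returned
#' mask marks exactly the tumor-textured pixels.
#'
#' @param spec a [slide_spec()].
#' @return list with `img` (H x W x 3, 0-255), `tumor_mask` (H x W logical),
#'   `tissue_mask` (H x W logical) and `label`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width; lat <- spec$lattice

  img <- array(0, c(h, w, 3))
  bg <- clamp255(spec$background_level + rnorm(h * w, 0, 3))
  bg <- pmax(bg, 212)  # background never dips into tissue intensity range
  for (ch in 1:3) img[, , ch] <- matrix(bg, h, w)

  # tissue rectangle on the lattice, roughly centered
  tw <- snap(w * sqrt(spec$tissue_fraction), lat, lat, w)
  th <- snap(h * sqrt(spec$tissue_fraction), lat, lat, h)
  x0 <- snap((w - tw) / 2, lat, 0, w - tw)
  y0 <- snap((h - th) / 2, lat, 0, h - th)
  tissue <- matrix(FALSE, h, w)
  tissue[(y0 + 1):(y0 + th), (x0 + 1):(x0 + tw)] <- TRUE

  # tumor sub-rectangle anchored at the tissue corner, area ~ tumor_fraction
  tumor <- matrix(FALSE, h, w)
  if (spec$tumor_fraction > 0) {
    if (spec$tumor_fraction >= 1) {
      uw <- tw; uh <- th
    } else {
      uw <- snap(tw * sqrt(spec$tumor_fraction), lat, lat, tw)
      uh <- snap(th * sqrt(spec$tumor_fraction), lat, lat, th)
    }
    tumor[(y0 + 1):(y0 + uh), (x0 + 1):(x0 + uw)] <- TRUE
  }
  normal_region <- tissue & !tumor

  img <- render_texture(img, normal_region, spec$texture_params[["normal"]])
  if (any(tumor)) img <- render_texture(img, tumor, spec$texture_params[[spec$label]])

  list(img = img, tumor_mask = tumor, tissue_mask = tissue, label = spec$label)
}

#' Generate a nuclei scene with analytic ground truth
#'
#' Places `n_nuclei` non-overlapping dark ellipses on a light background by
#' rejection sampling and returns, for each nucleus, its analytic geometry:
#' area `pi*a*b`, axis lengths `2a`, `2b` and orientation.
#'
#' @param n_nuclei number of nuclei to place.
#' @param width,height image size in pixels.
#' @param semi_major,semi_minor ranges (px) for the semi-axes `a`, `b`
#'   (`b <= a` enforced per nucleus).
#' @param seed integer seed.
#' @param max_tries placement attempts per nucleus before giving up.
#' @return list with `img` (H x W x 3, 0-255) and `truth`, a data.frame with
#'   one row per nucleus: `id, cx, cy, a, b, theta, area, major, minor`.
#' @export
generate_nuclei_image <- function(n_nuclei, width = 256, height = 256,
                                  semi_major = c(8, 14), semi_minor = c(5, 10),
                                  seed = 1, max_tries = 500) {
  set.seed(seed)
  img <- array(0, c(height, width, 3))
  bg <- c(235, 225, 232)
  for (ch in 1:3) img[, , ch] <- clamp255(bg[ch] + rnorm(height * width, 0, 3))
  truth <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      a = numeric(), b = numeric(), theta = numeric(),
                      area = numeric(), major = numeric(), minor = numeric())
  if (n_nuclei == 0) return(list(img = img, truth = truth))

  amax <- max(semi_major)
  placed <- matrix(numeric(0), 0, 3)  # cx, cy, a
  for (i in seq_len(n_nuclei)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      a <- runif(1, semi_major[1], semi_major[2])
      b <- runif(1, semi_minor[1], min(semi_minor[2], a))
      cx <- runif(1, amax + 2, width - amax - 2)
      cy <- runif(1, amax + 2, height - amax - 2)
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) > placed[, 3] + a + 3)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", n_nuclei, " non-overlapping nuclei; ",
                  "placed ", nrow(placed), " - enlarge the image or shrink the nuclei")
    placed <- rbind(placed, c(cx, cy, a))
    theta <- runif(1, 0, pi)
    # rasterize: pixel centers with normalized quadratic form <= 1
    rr <- max(1, floor(cy - a)):min(height, ceiling(cy + a))
    cc <- max(1, floor(cx - a)):min(width, ceiling(cx + a))
    gy <- matrix(rr, length(rr), length(cc)) - cy
    gx <- matrix(cc, length(rr), length(cc), byrow = TRUE) - cx
    xr <- gx * cos(theta) + gy * sin(theta)
    yr <- -gx * sin(theta) + gy * cos(theta)
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    dark <- c(60, 50, 110)
    for (ch in 1:3) {
      plane <- img[rr, cc, ch]
      plane[inside] <- clamp255(dark[ch] + rnorm(sum(inside), 0, 4))
      img[rr, cc, ch] <- plane
    }
    truth <- rbind(truth, data.frame(id = i, cx = cx, cy = cy, a = a, b = b,
                                     theta = theta, area = pi * a * b,
                                     major = 2 * a, minor = 2 * b))
  }
  list(img = img, truth = truth)
}

#' Generate Gaussian embedding clusters
#'
#' Class-conditional spherical unit-variance Gaussians at mutually
#' equidistant centers (scaled standard-basis vectors), emulating
#' penultimate-layer embeddings of well-trained networks.
#'
#' @param n_classes number of classes (at least 2, at most `dim`).
#' @param n_per_class points per class.
#' @param dim embedding dimension.
#' @param separation distance between any two class centers, in units of the
#'   within-class standard deviation.
#' @param seed integer seed.
#' @return list with `X` (matrix, `n_classes*n_per_class` x `dim`) and
#'   `labels` (factor).
#' @export
generate_embedding_clusters <- function(n_classes, n_per_class, dim = 512,
                                        separation = 10, seed = 1) {
  if (n_classes < 2) stop("need at least 2 classes")
  if (dim < n_classes) stop("dim must be >= n_classes")
  set.seed(seed)
  n <- n_classes * n_per_class
  X <- matrix(rnorm(n * dim), n, dim)
  labels <- factor(rep(paste0("C", seq_len(n_classes)), each = n_per_class))
  scale <- separation / sqrt(2)  # unit basis vectors are sqrt(2) apart
  for (k in seq_len(n_classes))
    X[as.integer(labels) == k, k] <- X[as.integer(labels) == k, k] + scale
  list(X = X, labels = labels)
}

#' Specification for a synthetic survival cohort
#'
#' @param n_patients cohort size (at least 2).
#' @param n_features number of standard-normal image-feature covariates.
#' @param beta true log-hazard coefficients (length `n_features`).
#' @param baseline_rate exponential baseline hazard (events per time unit).
#' @param censor_rate expected fraction of patients censored, in \[0, 1).
#' @param covariates if `TRUE`, also generate clinical covariates
#'   (age, gender, stage, grade).
#' @param covariate_beta named log-hazards for the clinical covariates.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, n_features = 1,
                        beta = rep(0, n_features), baseline_rate = 0.1,
                        censor_rate = 0.3, covariates = FALSE,
                        covariate_beta = c(age = 0, gender = 0, stage = 0, grade = 0),
                        seed = 1) {
  if (n_patients < 2) stop("need at least 2 patients")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (length(beta) != n_features) stop("beta must have length n_features")
  structure(list(n_patients = n_patients, n_features = n_features,
                 beta = beta, baseline_rate = baseline_rate,
                 censor_rate = censor_rate, covariates = covariates,
                 covariate_beta = covariate_beta, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a survival cohort with known hazard structure
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(x' beta + z' covariate_beta)`; censoring times are
#' independent exponential with rate calibrated so the expected censored
#' fraction equals `censor_rate`.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `patient_id`, `time`, `event`, optional clinical
#'   covariates, and features `f1..fp`.
#' @export
generate_survival_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients; p <- spec$n_features
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  lp <- as.numeric(X %*% spec$beta)
  clin <- NULL
  if (spec$covariates) {
    cb <- spec$covariate_beta
    clin <- data.frame(age = round(rnorm(n, 60, 10)),
                       gender = rbinom(n, 1, 0.5),
                       stage = sample(1:4, n, replace = TRUE),
                       grade = sample(1:4, n, replace = TRUE))
    lp <- lp + cb["age"] * (clin$age - 60) + cb["gender"] * clin$gender +
      cb["stage"] * clin$stage + cb["grade"] * clin$grade
  }
  haz <- spec$baseline_rate * exp(lp)
  t_event <- rexp(n, rate = haz)
  if (spec$censor_rate > 0) {
    # calibrate the censoring rate c: mean_i c/(c + haz_i) = censor_rate
    f <- function(logc) mean(exp(logc) / (exp(logc) + haz)) - spec$censor_rate
    logc <- uniroot(f, lower = -20, upper = 20)$root
    t_cens <- rexp(n, rate = exp(logc))
  } else {
    t_cens <- rep(Inf, n)
  }
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    time = pmin(t_event, t_cens),
                    event = as.integer(t_event <= t_cens))
  if (!is.null(clin)) out <- cbind(out, clin)
  cbind(out, as.data.frame(X))
}
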