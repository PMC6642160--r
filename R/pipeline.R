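# End-to-end orchestration at demonstration scale: a classification run
# (tile -> filter -> split -> scorer -> embeddings -> DAG-SVM -> metrics)
# and a survival run (heatmap -> mask -> morphometry -> patient aggregation
# -> univariate screen -> integrative stratification -> multivariate Cox),
# both fully determined by one seed. The subtype and heatmap stages use
# separate tile sizes, mirroring the use of different magnifications for
# the two tasks.

#' Pipeline configuration
#'
#' All stage parameters in one place. The defaults are the full-scale
#' settings (512-px tiles with 50% overlap, background threshold 210 on
#' half the pixels, heatmap cut 0.95, one-third cleanup, 10 inner folds,
#' 70/15/15 split); [demo_config()] overrides the geometry to fixture
#' scale.
#'
#' @param tile_size subtype-stage tile side (px).
#' @param heatmap_tile_size heatmap-stage tile side (px).
#' @param overlap_fraction tile overlap for both stages.
#' @param bg_threshold,bg_fraction background-filter parameters.
#' @param prob_threshold heatmap probability cut.
#' @param min_frac mask-cleanup fraction of the main region.
#' @param split_fractions train/val/test fractions.
#' @param folds inner cross-validation folds for lasso-Cox.
#' @param alpha significance level of the univariate screen.
#' @param scorer a [scorer_config()].
#' @param svm_cost DAG-SVM soft-margin constant.
#' @param nuclei_max_patches per-slide cap on high-probability patches
#'   entering nuclei morphometry.
#' @param nuclei_min_area minimum nucleus area (px).
#' @param heatmap_scale heatmap downsampling factor.
#' @param seed global seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(tile_size = 512, heatmap_tile_size = 512,
                            overlap_fraction = 0.5, bg_threshold = 210,
                            bg_fraction = 0.5, prob_threshold = 0.95,
                            min_frac = 1 / 3,
                            split_fractions = c(0.70, 0.15, 0.15),
                            folds = 10, alpha = 0.05,
                            scorer = scorer_config(), svm_cost = 1,
                            nuclei_max_patches = 30, nuclei_min_area = 15,
                            heatmap_scale = 1, seed = 1) {
  structure(list(tile_size = tile_size, heatmap_tile_size = heatmap_tile_size,
                 overlap_fraction = overlap_fraction,
                 bg_threshold = bg_threshold, bg_fraction = bg_fraction,
                 prob_threshold = prob_threshold, min_frac = min_frac,
                 split_fractions = split_fractions, folds = folds,
                 alpha = alpha, scorer = scorer, svm_cost = svm_cost,
                 nuclei_max_patches = nuclei_max_patches,
                 nuclei_min_area = nuclei_min_area,
                 heatmap_scale = heatmap_scale, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Demonstration-scale configuration
#'
#' Fixture geometry small enough for CPU runs: 192-px slides, 32-px subtype
#' tiles and 16-px heatmap tiles (both with 50% overlap).
#'
#' @param seed global seed.
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
demo_config <- function(seed = 1, ...) {
  pipeline_config(tile_size = 32, heatmap_tile_size = 16, seed = seed, ...)
}

#' Generate the demonstration dataset
#'
#' Three RCC subtypes (8 tumor slides each, fully tumor-textured tissue),
#' 8 normal slides, and a 40-patient survival cohort whose per-slide tumor
#' fraction is driven by a latent hazard variable (log-hazard 1 per unit),
#' with independent clinical covariates and ~30% censoring.
#'
#' @param seed integer seed.
#' @param n_per_class tumor slides per subtype.
#' @param n_normal normal slides.
#' @param n_patients survival cohort size.
#' @param slide_px slide side length.
#' @return list with `subtype_slides`, `normal_slides`, `survival` (list of
#'   `slides`, `truth_masks`, `clinical`, `slide_to_patient`, `latent`).
#' @export
make_fixture_dataset <- function(seed = 1, n_per_class = 8, n_normal = 8,
                                 slide_px = 192, n_patients = 40) {
  classes <- c("KIRC", "KIRP", "KICH")
  subtype <- list()
  k <- 0
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      s <- generate_slide(slide_spec(slide_px, slide_px, label = cl,
                                     tumor_fraction = 1,
                                     seed = seed * 1000 + k))
      subtype[[sprintf("%s_%02d", cl, i)]] <-
        list(img = s$img, tumor_mask = s$tumor_mask,
             tissue_mask = s$tissue_mask, label = cl,
             slide_id = sprintf("%s_%02d", cl, i))
    }
  }
  normal <- list()
  for (i in seq_len(n_normal)) {
    s <- generate_slide(slide_spec(slide_px, slide_px, label = "normal",
                                   seed = seed * 1000 + 500 + i))
    normal[[sprintf("NORM_%02d", i)]] <-
      list(img = s$img, tumor_mask = s$tumor_mask,
           tissue_mask = s$tissue_mask, label = "normal",
           slide_id = sprintf("NORM_%02d", i))
  }
  # survival cohort: tumor burden proportional to a latent hazard driver
  set.seed(seed + 777)
  z <- rnorm(n_patients)
  tf <- pmin(pmax(0.35 + 0.18 * z, 0.08), 0.95)
  haz <- 0.02 * exp(1.0 * z)
  t_event <- rexp(n_patients, haz)
  cfun <- function(logc) mean(exp(logc) / (exp(logc) + haz)) - 0.3
  t_cens <- rexp(n_patients, exp(uniroot(cfun, c(-20, 20))$root))
  clinical <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    age = round(rnorm(n_patients, 60, 10)),
    gender = rbinom(n_patients, 1, 0.5),
    stage = sample(1:4, n_patients, replace = TRUE),
    grade = sample(1:4, n_patients, replace = TRUE))
  surv_slides <- list(); truth_masks <- list()
  for (i in seq_len(n_patients)) {
    s <- generate_slide(slide_spec(slide_px, slide_px, label = "KIRC",
                                   tumor_fraction = tf[i],
                                   seed = seed * 1000 + 2000 + i))
    sid <- sprintf("S%03d", i)
    surv_slides[[sid]] <- list(img = s$img, slide_id = sid)
    truth_masks[[sid]] <- s$tumor_mask
  }
  list(subtype_slides = subtype, normal_slides = normal,
       survival = list(slides = surv_slides, truth_masks = truth_masks,
                       clinical = clinical,
                       slide_to_patient = data.frame(
                         patient_id = clinical$patient_id,
                         slide_id = names(surv_slides)),
                       latent = z, tumor_fraction = tf))
}

# tile + background-filter one slide, returning labeled kept patches
tile_and_filter <- function(slide, grid, config) {
  patches <- tile_slide(slide$img, grid, slide_id = slide$slide_id,
                        label = slide$label %||% NA_character_)
  filter_patches(patches, threshold = config$bg_threshold,
                 fraction = config$bg_fraction)$kept
}

#' Run the classification pipeline
#'
#' Tiles and filters every slide, splits at slide level, trains the patch
#' scorer, extracts embeddings, trains the DAG-SVM on the training-fold
#' embeddings and evaluates the metric panel on the held-out test patches.
#' With exactly two classes a slide-wise AUC (fraction of positive patches
#' per slide against slide labels) is also computed.
#'
#' @param slides list of slides, each `list(img, label, slide_id)`.
#' @param config a [pipeline_config()].
#' @return list with `metrics` (a [metric_panel()]), `scorer`, `dagsvm`,
#'   `split`, `n_patches`, and `slide_auc` (binary tasks only).
#' @export
run_classification <- function(slides, config = demo_config()) {
  grid <- tile_grid(config$tile_size, config$overlap_fraction)
  manifest <- data.frame(
    slide_id = vapply(slides, `[[`, "", "slide_id"),
    label = vapply(slides, `[[`, "", "label"))
  split <- split_dataset(manifest, config$split_fractions,
                         seed = config$seed, stratify = TRUE)
  kept <- lapply(slides, tile_and_filter, grid = grid, config = config)
  names(kept) <- manifest$slide_id
  pool <- function(ids) do.call(c, unname(kept[ids]))
  tr <- pool(split$train); va <- pool(split$val); te <- pool(split$test)
  if (length(tr) == 0 || length(te) == 0)
    stop("empty train or test fold; provide more slides per class")
  if (length(va) == 0) va <- tr
  cfg <- config$scorer
  cfg$seed <- config$seed
  scorer <- train_scorer(tr, va, cfg)
  emb_tr <- extract_embeddings(scorer, tr)
  emb_te <- extract_embeddings(scorer, te)
  y_tr <- vapply(tr, `[[`, "", "label")
  y_te <- vapply(te, `[[`, "", "label")
  dag <- train_dagsvm(emb_tr, y_tr, cost = config$svm_cost)
  pred <- predict_dag_matrix(dag, emb_te)
  scores <- decision_scores(dag, emb_te)
  metrics <- metric_panel(y_te, pred, scores)
  out <- list(metrics = metrics, scorer = scorer, dagsvm = dag, split = split,
              n_patches = c(train = length(tr), val = length(va),
                            test = length(te)))
  classes <- sort(unique(manifest$label))
  if (length(classes) == 2) {
    pos <- classes[2]
    ss <- vapply(split$test, function(sid) {
      pr <- score_patches(scorer, kept[[sid]])[, pos]
      slide_score(pr)
    }, 0)
    out$slide_auc <- roc_auc(ss, manifest$label[match(split$test,
                                                      manifest$slide_id)] == pos)
  }
  out
}

# score one slide with the cancer/normal scorer and build its cleaned mask
slide_heatmap_stage <- function(slide, scorer, grid, config) {
  patches <- tile_slide(slide$img, grid, slide_id = slide$slide_id)
  flt <- filter_patches(patches, threshold = config$bg_threshold,
                        fraction = config$bg_fraction)
  if (length(flt$kept) == 0)
    return(list(mask = NULL, features = NULL, patches = NULL, scores = NULL))
  pr <- score_patches(scorer, flt$kept)[, "tumor"]
  man <- patch_manifest(flt$kept)
  man$score <- pr
  heat <- build_heatmap(man, dim(slide$img)[1:2], grid,
                        scale = config$heatmap_scale)
  tm <- clean_mask(high_prob_mask(heat, config$prob_threshold),
                   min_frac = config$min_frac)
  list(mask = tm, heatmap = heat, patches = flt$kept, scores = pr)
}

#' Run the survival pipeline
#'
#' Trains a tumor/normal scorer at the heatmap tile size, builds per-slide
#' probability heatmaps and cleaned high-probability masks, extracts tumor
#' and nuclei morphometry, aggregates to patients, screens features
#' univariately and stratifies with the integrative two-level
#' cross-validated lasso-Cox, finishing with log-rank, Kaplan-Meier and
#' multivariate Cox outputs.
#'
#' @param surv_slides list of patient slides (`list(img, slide_id)`).
#' @param clinical data.frame with `patient_id, time, event, age, gender,
#'   stage, grade`.
#' @param slide_to_patient data.frame mapping `slide_id` to `patient_id`.
#' @param tumor_slides,normal_slides labeled slides used to train the
#'   tumor/normal scorer (ignored when `scorer` is given).
#' @param config a [pipeline_config()].
#' @param scorer optional pre-trained tumor/normal `rcc_scorer`.
#' @param screen_features feature names entering the univariate screen;
#'   default is the canonical tumor roster plus the nuclei totals.
#' @return list with `screen` (per-feature p-values), `stratification`
#'   (integrative [two_level_cv_stratify()] result), `multivariate`,
#'   `patient_features`, `masks`, `scorer`.
#' @export
run_survival <- function(surv_slides, clinical, slide_to_patient,
                         tumor_slides = NULL, normal_slides = NULL,
                         config = demo_config(), scorer = NULL,
                         screen_features = NULL) {
  grid <- tile_grid(config$heatmap_tile_size, config$overlap_fraction)
  if (is.null(scorer)) {
    if (is.null(tumor_slides) || is.null(normal_slides))
      stop("either a scorer or tumor/normal training slides are required")
    train_set <- c(lapply(tumor_slides, function(s) {
      s$label <- "tumor"; s
    }), lapply(normal_slides, function(s) {
      s$label <- "normal"; s
    }))
    kept <- lapply(train_set, tile_and_filter, grid = grid, config = config)
    manifest <- data.frame(
      slide_id = vapply(train_set, `[[`, "", "slide_id"),
      label = vapply(train_set, `[[`, "", "label"))
    split <- split_dataset(manifest, c(0.8, 0.2, 0), seed = config$seed,
                           stratify = TRUE)
    cfg <- config$scorer
    cfg$seed <- config$seed
    scorer <- train_scorer(
      do.call(c, unname(kept[match(split$train, manifest$slide_id)])),
      do.call(c, unname(kept[match(split$val, manifest$slide_id)])), cfg)
  }
  set.seed(config$seed)
  masks <- list()
  feat_rows <- list()
  for (sid in names(surv_slides)) {
    st <- slide_heatmap_stage(surv_slides[[sid]], scorer, grid, config)
    masks[[sid]] <- st$mask
    if (is.null(st$mask) || sum(st$mask$components$retained) == 0) {
      warning("slide ", sid, " has an empty tumor mask; excluded")
      next
    }
    tumor_feat <- slide_tumor_features(st$mask)
    hp <- which(st$scores > config$prob_threshold)
    if (length(hp) > config$nuclei_max_patches)
      hp <- sample(hp, config$nuclei_max_patches)
    nuc_feat <- if (length(hp) > 0) {
      suppressWarnings(slide_nuclei_features(st$patches[hp],
                                             min_area = config$nuclei_min_area))
    } else {
      setNames(rep(0, 8), c(paste0("nuc_total_", nuclei_fields), "nuc_count"))
    }
    feat_rows[[sid]] <- data.frame(slide_id = sid,
                                   t(c(tumor_feat, nuc_feat)))
  }
  slide_features <- do.call(rbind, feat_rows)
  patient_features <- aggregate_patients(slide_features, slide_to_patient)
  data <- merge(clinical, patient_features, by = "patient_id")
  screen_features <- screen_features %||%
    c(canonical_tumor_features(), paste0("nuc_total_", nuclei_fields))
  screen_features <- intersect(screen_features, names(data))
  # drop features that are constant across patients (unidentifiable)
  ok <- vapply(screen_features, function(f) sd(data[[f]]) > 1e-10, TRUE)
  screen_features <- screen_features[ok]
  screen <- univariate_feature_screen(data, screen_features,
                                      seed = config$seed,
                                      alpha = config$alpha,
                                      nfolds = config$folds)
  sig <- screen$feature[screen$significant]
  strat <- NULL
  multiv <- NULL
  if (length(sig) > 0) {
    strat <- two_level_cv_stratify(data, sig, seed = config$seed,
                                   nfolds = config$folds)
    data$risk_index <- strat$risk_index
    if (sd(data$risk_index) > 1e-10 && !strat$degenerate) {
      multiv <- multivariate_cox(data, c("risk_index", "age", "gender",
                                         "stage", "grade"))
    }
  } else {
    warning("no feature passed the univariate screen; integrative model skipped")
  }
  list(screen = screen, stratification = strat, multivariate = multiv,
       patient_features = patient_features, masks = masks, scorer = scorer,
       data = data)
}

#' Materialize the demonstration dataset on disk
#'
#' Writes the fixture slides as PNG files plus `labels.csv`,
#' `clinical.csv`, `slide_to_patient.csv` and ground-truth tumor masks
#' (PNG, white = tumor) under `dir`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param ... passed to [make_fixture_dataset()].
#' @return `dir`, invisibly.
#' @export
write_fixture_dataset <- function(dir, seed = 1, ...) {
  ds <- make_fixture_dataset(seed = seed, ...)
  slide_dir <- file.path(dir, "slides")
  mask_dir <- file.path(dir, "masks")
  dir.create(slide_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  all_slides <- c(ds$subtype_slides, ds$normal_slides)
  for (s in all_slides) {
    write_slide_png(s$img, file.path(slide_dir, paste0(s$slide_id, ".png")))
    png::writePNG(s$tumor_mask * 1,
                  file.path(mask_dir, paste0(s$slide_id, "_mask.png")))
  }
  for (sid in names(ds$survival$slides))
    write_slide_png(ds$survival$slides[[sid]]$img,
                    file.path(slide_dir, paste0(sid, ".png")))
  labels <- data.frame(
    slide_id = vapply(all_slides, `[[`, "", "slide_id"),
    label = vapply(all_slides, `[[`, "", "label"))
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  write.csv(ds$survival$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  write.csv(ds$survival$slide_to_patient,
            file.path(dir, "slide_to_patient.csv"), row.names = FALSE)
  invisible(dir)
}

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices of equal size.
#' @return IoU in \[0, 1\]; `NA` when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Run the full demonstration pipeline
#'
#' Generates the fixture dataset, runs the subtype classification and the
#' survival stages, and evaluates the cleaned tumor masks of the fully
#' tumorous subtype slides against their ground-truth masks.
#'
#' @param config a [pipeline_config()]; geometry must match the fixture
#'   scale (see [demo_config()]).
#' @param n_mask_slides number of subtype slides used for the mask
#'   fidelity check.
#' @return list with `classification`, `survival`, `mask_iou` (mean IoU)
#'   and `dataset`.
#' @export
run_all <- function(config = demo_config(), n_mask_slides = 6) {
  ds <- make_fixture_dataset(seed = config$seed)
  cls <- run_classification(ds$subtype_slides, config)
  surv <- run_survival(ds$survival$slides, ds$survival$clinical,
                       ds$survival$slide_to_patient,
                       tumor_slides = ds$subtype_slides[grep("^KIRC",
                                                             names(ds$subtype_slides))],
                       normal_slides = ds$normal_slides, config = config)
  grid <- tile_grid(config$heatmap_tile_size, config$overlap_fraction)
  eval_ids <- head(names(ds$subtype_slides)[grep("^KIRC",
                                                 names(ds$subtype_slides))],
                   n_mask_slides)
  ious <- vapply(eval_ids, function(sid) {
    st <- slide_heatmap_stage(ds$subtype_slides[[sid]], surv$scorer, grid,
                              config)
    if (is.null(st$mask)) return(NA_real_)
    mask_iou(st$mask$mask, ds$subtype_slides[[sid]]$tumor_mask)
  }, 0)
  list(classification = cls, survival = surv, mask_iou = mean(ious, na.rm = TRUE),
       per_slide_iou = ious, dataset = ds)
}
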