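# Survival stratification: lasso-Cox risk indices inside a two-level
# cross-validation (outer leave-one-out assignment against the training
# median, inner 10-fold penalty selection), with log-rank, Kaplan-Meier and
# multivariate Cox reporting. The log-rank statistic, product-limit
# estimator and risk indexing are implemented here and oracle-tested; the
# penalized and unpenalized Cox fits are delegated to glmnet and survival.

#' Two-sample log-rank test
#'
#' At each distinct event time `t_j` with `n_j` at risk, `d_j` events and
#' `n_1j` at risk in group 1: `O = sum d_1j`, `E = sum d_j n_1j / n_j`,
#' `V = sum d_j (n_1j/n_j)(1 - n_1j/n_j)(n_j - d_j)/(n_j - 1)`; the
#' statistic `(O - E)^2 / V` is chi-square with 1 df.
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @param group two-level grouping vector.
#' @return list with `statistic`, `p_value`, `observed`, `expected`,
#'   `variance`. `V = 0` yields `NA` statistic and p.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("log-rank test requires exactly two groups")
  if (sum(event) < 1) stop("need at least one event")
  g1 <- g == levels(g)[1]
  O <- 0; E <- 0; V <- 0
  for (tj in sort(unique(time[event == 1]))) {
    at_risk <- time >= tj
    n_j <- sum(at_risk)
    d_j <- sum(event == 1 & time == tj)
    n_1j <- sum(at_risk & g1)
    d_1j <- sum(event == 1 & time == tj & g1)
    O <- O + d_1j
    E <- E + d_j * n_1j / n_j
    if (n_j > 1)
      V <- V + d_j * (n_1j / n_j) * (1 - n_1j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  if (V <= 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                observed = O, expected = E, variance = V))
  stat <- (O - E)^2 / V
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E, variance = V)
}

#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_(t_j <= t) (1 - d_j / n_j)` over distinct event times;
#' censored subjects leave the risk set after their censoring time.
#'
#' @inheritParams logrank_test
#' @return data.frame with `time` (distinct event times), `n_risk`,
#'   `n_event`, `survival`; zero rows when there is no event.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  tj <- sort(unique(time[event == 1]))
  if (length(tj) == 0)
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), survival = numeric()))
  n_risk <- vapply(tj, function(t) sum(time >= t), 0L)
  n_event <- vapply(tj, function(t) sum(time == t & event == 1), 0L)
  data.frame(time = tj, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

# glmnet needs >= 2 columns; pad univariate designs with a zero column
# (which always receives a zero coefficient)
pad_design <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, .pad = 0)
}

#' Fit a cross-validated lasso-Cox model
#'
#' L1-penalized Cox partial likelihood (glmnet) with the penalty chosen by
#' `nfolds`-fold cross-validated partial-likelihood deviance; coefficients
#' are returned on the original feature scale.
#'
#' @param X feature matrix `n x p` (finite values).
#' @param time,event survival outcome; at least 2 events required.
#' @param nfolds inner cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @param lambda optional penalty path; chosen automatically by default.
#' @param nlambda path length when `lambda` is `NULL`.
#' @return list with `beta` (named, original scale), `lambda` (selected),
#'   `nonzero` (names of selected features) and the `cv.glmnet` fit.
#' @export
fit_lasso_cox <- function(X, time, event, nfolds = 10, seed = 1,
                          lambda = NULL, nlambda = 30) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (sum(event) < 2) stop("need at least 2 events to fit a Cox model")
  if (all(apply(X, 2, sd) < 1e-12)) {
    # no informative variation: the penalized fit is the null model
    return(list(beta = setNames(rep(0, ncol(X)), colnames(X)),
                lambda = NA_real_, nonzero = character(0), cvfit = NULL))
  }
  set.seed(seed)
  y <- survival::Surv(time, event)
  cv <- tryCatch(
    glmnet::cv.glmnet(pad_design(X), y, family = "cox", nfolds = nfolds,
                      lambda = lambda, nlambda = nlambda),
    error = function(e) {
      # a fold whose design carries no variation has nothing to fit:
      # degrade to the null (all-zero) model rather than abort
      if (grepl("zero variance", conditionMessage(e)))
        return(NULL)
      stop(e)
    })
  if (is.null(cv)) {
    return(list(beta = setNames(rep(0, ncol(X)), colnames(X)),
                lambda = NA_real_, nonzero = character(0), cvfit = NULL))
  }
  b <- as.numeric(coef(cv, s = "lambda.min"))[seq_len(ncol(X))]
  names(b) <- colnames(X)
  list(beta = b, lambda = cv$lambda.min,
       nonzero = names(b)[b != 0], cvfit = cv)
}

#' Cox risk index (linear predictor)
#'
#' @param beta named coefficient vector.
#' @param X feature matrix or data.frame containing every named feature.
#' @return numeric risk index per row, `x . beta` (Cox has no intercept).
#' @export
risk_index <- function(beta, X) {
  missing <- setdiff(names(beta), colnames(X))
  if (length(missing) > 0)
    stop("features missing from X: ", paste(missing, collapse = ", "))
  as.numeric(as.matrix(X[, names(beta), drop = FALSE]) %*% beta)
}

#' Two-level cross-validated risk stratification
#'
#' Outer leave-one-out loop: each patient is held out, a lasso-Cox model is
#' fitted on the remaining patients with the penalty selected by inner
#' `nfolds`-fold cross-validation, and the held-out patient is assigned to
#' the high-risk group iff their risk index exceeds the median training
#' risk index (ties go to low risk). The held-out patient's outcome never
#' enters their own assignment (asserted inside the loop). The assembled
#' groups are compared by the log-rank test and a group-contrast hazard
#' ratio.
#'
#' @param data data.frame with `time`, `event` and feature columns.
#' @param features character vector of feature column names.
#' @param seed integer seed.
#' @param nfolds inner cross-validation folds.
#' @param nlambda penalty path length.
#' @return object of class `risk_stratification`: `risk_index`, `group`
#'   (factor low/high), `logrank` (list), `hr`, `hr_ci`, `km` (per-group
#'   curves), `degenerate`.
#' @export
two_level_cv_stratify <- function(data, features, seed = 1, nfolds = 10,
                                  nlambda = 30) {
  stopifnot(all(c("time", "event") %in% names(data)),
            all(features %in% names(data)))
  n <- nrow(data)
  if (n < 20) stop("need at least 20 patients")
  if (sum(data$event) < 2) stop("need at least 2 events")
  X <- as.matrix(data[, features, drop = FALSE])
  risk <- numeric(n)
  high <- logical(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    stopifnot(!(i %in% tr))  # the held-out outcome must not train its own model
    fit <- fit_lasso_cox(X[tr, , drop = FALSE], data$time[tr], data$event[tr],
                         nfolds = nfolds, seed = seed + i, nlambda = nlambda)
    risk_tr <- risk_index(fit$beta, X[tr, , drop = FALSE])
    risk[i] <- risk_index(fit$beta, X[i, , drop = FALSE])
    high[i] <- risk[i] > median(risk_tr)
  }
  group <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  if (length(unique(group)) < 2) {
    warning("degenerate stratification: all patients in one group")
    return(structure(list(risk_index = risk, group = group,
                          logrank = list(statistic = NA_real_, p_value = NA_real_),
                          hr = NA_real_, hr_ci = c(NA_real_, NA_real_),
                          km = NULL, degenerate = TRUE),
                     class = "risk_stratification"))
  }
  lr <- logrank_test(data$time, data$event, group)
  cph <- survival::coxph(survival::Surv(time, event) ~ group, data = data)
  ci <- exp(stats::confint(cph))
  structure(list(risk_index = risk, group = group, logrank = lr,
                 hr = unname(exp(coef(cph)[1])), hr_ci = unname(ci[1, ]),
                 km = list(low = km_curve(data$time[group == "low"],
                                          data$event[group == "low"]),
                           high = km_curve(data$time[group == "high"],
                                           data$event[group == "high"])),
                 degenerate = FALSE),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  if (x$degenerate) {
    cat("<risk_stratification: degenerate (single group)>\n")
  } else {
    cat(sprintf("<risk_stratification: %d low / %d high; log-rank chi2 %.3f, p %.3g; HR %.3f (%.3f-%.3f)>\n",
                sum(x$group == "low"), sum(x$group == "high"),
                x$logrank$statistic, x$logrank$p_value, x$hr,
                x$hr_ci[1], x$hr_ci[2]))
  }
  invisible(x)
}

#' Multivariate Cox model of risk index and clinical covariates
#'
#' Unpenalized Cox fit; hazard ratios are `exp(beta)` with Wald confidence
#' intervals and p-values.
#'
#' @param data data.frame with `time`, `event` and the covariates.
#' @param covariates character vector of covariate columns (e.g. a risk
#'   index or group plus age, gender, stage, grade).
#' @param conf_level confidence level for the intervals.
#' @return data.frame with `variable`, `hr`, `ci_lower`, `ci_upper`,
#'   `p_value`.
#' @export
multivariate_cox <- function(data, covariates, conf_level = 0.95) {
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  if (sum(data$event) < 2) stop("need at least 2 events")
  for (v in covariates) {
    x <- data[[v]]
    if (is.numeric(x) && sd(x) < 1e-12)
      stop("covariate has zero variance: ", v)
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  cph <- tryCatch(survival::coxph(f, data = data),
                  error = function(e) stop("Cox fit failed: ",
                                           conditionMessage(e), call. = FALSE))
  s <- summary(cph, conf.int = conf_level)
  data.frame(variable = rownames(s$coefficients),
             hr = unname(s$coefficients[, "exp(coef)"]),
             ci_lower = unname(s$conf.int[, 3]),
             ci_upper = unname(s$conf.int[, 4]),
             p_value = unname(s$coefficients[, "Pr(>|z|)"]),
             row.names = NULL)
}

#' Univariate feature screen by per-feature stratification
#'
#' Runs [two_level_cv_stratify()] on each feature alone and tabulates the
#' log-rank p-values; the significant subset (raw p < `alpha`, no
#' multiplicity correction by default) feeds the integrative model.
#'
#' @param data data.frame with `time`, `event` and the features.
#' @param features character vector of feature columns.
#' @param seed integer seed.
#' @param alpha significance level.
#' @param adjust if `TRUE`, apply Benjamini-Hochberg correction before the
#'   significance call.
#' @param ... passed to [two_level_cv_stratify()].
#' @return data.frame with `feature`, `p_value`, `significant`.
#' @export
univariate_feature_screen <- function(data, features, seed = 1, alpha = 0.05,
                                      adjust = FALSE, ...) {
  if (length(features) == 0)
    return(data.frame(feature = character(), p_value = numeric(),
                      significant = logical()))
  p <- vapply(features, function(f) {
    s <- two_level_cv_stratify(data, f, seed = seed, ...)
    s$logrank$p_value %||% NA_real_
  }, 0)
  p_eff <- if (adjust) stats::p.adjust(p, "BH") else p
  data.frame(feature = features, p_value = unname(p),
             significant = !is.na(p_eff) & p_eff < alpha, row.names = NULL)
}
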