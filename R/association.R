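# Presence/absence association stage: nonparametric screening, collinearity
# pruning, binomial logistic regression, and cross-validated random forest.

#' Two-group Kruskal-Wallis test
#'
#' Rank-based H statistic with tie correction and a chi-square (df = 1)
#' p-value, for comparing one covariate between presence and absence
#' groups. A pooled sample in which every value is tied has no rank
#' separation: H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping (factor, logical or 0/1).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis_two_group <- function(values, groups) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L) {
    stop("argument error: exactly two non-empty groups required",
         call. = FALSE)
  }
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks. A constant vector has no
#' rank ordering; the coefficient is undefined and returned as `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("argument error: x and y must have equal length >= 3",
         call. = FALSE)
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Screen covariates by Kruskal-Wallis and Spearman collinearity
#'
#' Stage 1 drops every covariate whose Kruskal-Wallis p-value against the
#' presence groups is `>= alpha` (the Bonferroni-corrected significance
#' level, default 0.0005). Stage 2 walks the survivors in ascending-p
#' order; whenever a retained pair correlates with `|r_s| > rs_threshold`,
#' the member with the larger Kruskal-Wallis p is dropped. The full audit
#' trail (per-variable test results and every keep/drop pair) is returned.
#'
#' @param table Data frame with a 0/1 `presence` column and numeric
#'   covariate columns.
#' @param covariates Covariate names to screen; default every non-presence
#'   column.
#' @param alpha Stage-1 significance level.
#' @param rs_threshold Absolute Spearman correlation above which a pair is
#'   considered collinear.
#' @return An object of class `screening_report`: `tests` (variable, H, p,
#'   stage-1 pass), `pruning` (kept, dropped, r_s), `retained`, and an
#'   `empty` flag set when nothing survives stage 1.
#' @export
screen_variables <- function(table, covariates = NULL, alpha = 0.0005,
                             rs_threshold = 0.7) {
  if (!"presence" %in% names(table)) {
    stop("`table` must contain a `presence` column", call. = FALSE)
  }
  if (is.null(covariates)) covariates <- setdiff(names(table), "presence")
  if (length(covariates) < 2L) {
    stop("at least two candidate covariates required", call. = FALSE)
  }
  tests <- do.call(rbind, lapply(covariates, function(v) {
    kw <- kruskal_wallis_two_group(table[[v]], table$presence)
    data.frame(variable = v, H = kw$H, p = kw$p,
               stage1_pass = kw$p < alpha, stringsAsFactors = FALSE)
  }))
  surv <- tests[tests$stage1_pass, , drop = FALSE]
  surv <- surv[order(surv$p), , drop = FALSE]
  kept <- character(0)
  pruning <- data.frame(kept = character(0), dropped = character(0),
                        r_s = numeric(0), p_kept = numeric(0),
                        p_dropped = numeric(0), stringsAsFactors = FALSE)
  dropped <- character(0)
  for (v in surv$variable) {
    if (v %in% dropped) next
    collinear_with <- NULL
    for (k in kept) {
      rs <- spearman_correlation(table[[k]], table[[v]])
      if (!is.na(rs) && abs(rs) > rs_threshold) {
        collinear_with <- c(collinear_with, list(c(k, rs)))
      }
    }
    if (length(collinear_with)) {
      # v has larger p than every already-kept variable: drop v
      for (cw in collinear_with) {
        pruning <- rbind(pruning, data.frame(
          kept = cw[1], dropped = v, r_s = as.numeric(cw[2]),
          p_kept = surv$p[surv$variable == cw[1]],
          p_dropped = surv$p[surv$variable == v],
          stringsAsFactors = FALSE))
      }
      dropped <- c(dropped, v)
    } else {
      kept <- c(kept, v)
    }
  }
  structure(list(tests = tests, pruning = pruning, retained = kept,
                 alpha = alpha, rs_threshold = rs_threshold,
                 empty = length(kept) == 0L),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "<screening_report> alpha = %g, |r_s| threshold = %g\n", x$alpha,
    x$rs_threshold))
  print(transform(x$tests, H = signif(H, 4), p = signif(p, 3)))
  if (nrow(x$pruning)) {
    cat("collinearity pruning:\n")
    print(transform(x$pruning, r_s = round(r_s, 3)))
  }
  cat("retained:", if (length(x$retained)) {
    paste(x$retained, collapse = ", ")
  } else "(none survived screening)", "\n")
  invisible(x)
}

#' Binomial logistic regression of presence on covariates
#'
#' Maximum-likelihood fit by iteratively reweighted least squares (via
#' [stats::glm()]), reporting the estimate, standard error, Wald z and
#' p-value of each term, plus AIC, residual deviance and residual degrees
#' of freedom. Rank-deficient designs and perfect separation (diverging
#' estimates) raise errors, the latter naming the separating covariate.
#'
#' @param table Data frame with a 0/1 `presence` column.
#' @param covariates Covariate names entering the model.
#' @param backward If `TRUE`, backward elimination by AIC
#'   ([stats::step()]) is applied after the initial fit and the reduced
#'   model is reported.
#' @return An object of class `logistic_fit`.
#' @export
fit_logistic <- function(table, covariates, backward = FALSE) {
  if (!all(covariates %in% names(table))) {
    stop("missing covariate column(s): ",
         paste(setdiff(covariates, names(table)), collapse = ", "),
         call. = FALSE)
  }
  y <- table$presence
  if (length(unique(y)) != 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  X <- stats::model.matrix(
    ~ ., data = table[, covariates, drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    stop("fit error: rank-deficient design matrix", call. = FALSE)
  }
  f <- stats::as.formula(paste("presence ~",
                               paste(covariates, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = table, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (backward) {
    fit <- stats::step(fit, direction = "backward", trace = 0)
    covariates <- intersect(covariates, attr(stats::terms(fit),
                                             "term.labels"))
  }
  coefs <- summary(fit)$coefficients
  diverged <- separation &&
    (stats::deviance(fit) < 1e-6 || max(coefs[, "Std. Error"]) > 100)
  if (diverged) {
    slopes <- coefs[rownames(coefs) != "(Intercept)", , drop = FALSE]
    sds <- vapply(rownames(slopes),
                  function(v) stats::sd(table[[v]]), 0)
    worst <- rownames(slopes)[which.max(abs(slopes[, "Estimate"]) * sds)]
    stop("fit error: perfect separation, diverging estimate for `",
         worst, "`", call. = FALSE)
  }
  structure(list(
    coefficients = data.frame(term = rownames(coefs),
                              estimate = coefs[, "Estimate"],
                              std_error = coefs[, "Std. Error"],
                              z_value = coefs[, "z value"],
                              p_value = coefs[, "Pr(>|z|)"],
                              row.names = NULL),
    aic = stats::AIC(fit), residual_deviance = stats::deviance(fit),
    df_residual = stats::df.residual(fit), converged = fit$converged,
    model = fit, covariates = covariates),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> AIC = %.1f; residual deviance = %.2f on %d degrees of freedom\n",
    x$aic, x$residual_deviance, x$df_residual))
  cf <- x$coefficients
  out <- data.frame(Variable = cf$term, Estimate = round(cf$estimate, 3),
                    `Std. Error` = round(cf$std_error, 3),
                    `Z value` = round(cf$z_value, 3),
                    `Pr(>|z|)` = signif(cf$p_value, 3),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Predicted occurrence probability
#'
#' Inverse-logit of the linear predictor. Accepts either a fitted
#' `logistic_fit` or a named coefficient vector (with an `(Intercept)` or
#' `intercept` element), so published coefficient tables can be evaluated
#' directly.
#'
#' @param fit A `logistic_fit`, or a named numeric coefficient vector.
#' @param covariates Data frame (or named list/vector) of covariate values
#'   covering every model term.
#' @return Numeric vector of probabilities.
#' @export
predict_occurrence <- function(fit, covariates) {
  covariates <- as.data.frame(covariates)
  if (inherits(fit, "logistic_fit")) {
    beta <- stats::setNames(fit$coefficients$estimate,
                            fit$coefficients$term)
  } else {
    beta <- fit
    names(beta)[names(beta) %in% c("intercept", "Intercept")] <-
      "(Intercept)"
  }
  terms <- setdiff(names(beta), "(Intercept)")
  missing <- setdiff(terms, names(covariates))
  if (length(missing)) {
    stop("argument error: missing model term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lp <- rep(beta[["(Intercept)"]], nrow(covariates))
  for (t in terms) lp <- lp + beta[[t]] * covariates[[t]]
  inv_logit(lp)
}

#' Threshold and ranking metrics for binary scores
#'
#' AUC by the rank (Mann-Whitney) formulation with tie correction;
#' sensitivity and specificity at the given probability threshold (scores
#' `>= threshold` predict presence); `TSS = sensitivity + specificity - 1`;
#' and binary kappa from the thresholded confusion table.
#'
#' @param scores Numeric scores (higher = more likely present).
#' @param labels 0/1 labels, both classes present.
#' @param threshold Classification threshold (default 0.5).
#' @return List with `auc`, `sensitivity`, `specificity`, `tss`, `kappa`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("metric error: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  n <- n1 + n0
  po <- (tp + tn) / n
  pe <- ((tp + fp) * n1 + (tn + fn) * n0) / n^2
  kap <- if (1 - pe <= .Machine$double.eps) NA_real_ else (po - pe) / (1 - pe)
  list(auc = auc, sensitivity = sens, specificity = spec,
       tss = sens + spec - 1, kappa = kap)
}

#' Stratified k-fold cross-validated random forest
#'
#' Builds seeded stratified folds (every fold contains both classes, or an
#' error is raised), fits a random forest on each training split via
#' \pkg{randomForest}, scores the held-out fold, and evaluates
#' [classification_metrics()] per fold. The folds, metrics and report are
#' computed in-package; only the forest learner is delegated.
#'
#' @param table Data frame with 0/1 `presence` and covariate columns.
#' @param covariates Covariate names used by the forest.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment and forest fitting.
#' @param ntree Trees per forest (default 500).
#' @return An object of class `cv_report`: `folds` (per-row assignment),
#'   `per_fold` (metrics data frame) and `mean` (averaged metrics).
#' @export
random_forest_cv <- function(table, covariates = NULL, k = 10L, seed = 1L,
                             ntree = 500L) {
  if (is.null(covariates)) covariates <- setdiff(names(table), "presence")
  y <- as.integer(table$presence)
  n <- nrow(table)
  if (n < k) stop("fewer rows than folds", call. = FALSE)
  if (min(table(y)) < k) {
    stop("fold-construction error: class with fewer members than folds; ",
         "stratification impossible", call. = FALSE)
  }
  folds <- integer(n)
  metrics <- withr::with_seed(as.integer(seed), {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    per_fold <- lapply(seq_len(k), function(fold) {
      tr <- folds != fold; te <- !tr
      rf <- randomForest::randomForest(
        x = table[tr, covariates, drop = FALSE],
        y = factor(y[tr], levels = c(0, 1)), ntree = ntree)
      sc <- stats::predict(rf, table[te, covariates, drop = FALSE],
                           type = "prob")[, "1"]
      m <- classification_metrics(sc, y[te])
      data.frame(fold = fold, auc = m$auc, sensitivity = m$sensitivity,
                 specificity = m$specificity, tss = m$tss, kappa = m$kappa)
    })
    do.call(rbind, per_fold)
  })
  structure(list(folds = folds, per_fold = metrics,
                 mean = colMeans(metrics[, -1]), k = k, seed = seed,
                 covariates = covariates),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold stratified CV, seed %d\n", x$k, x$seed))
  cat("  mean:", paste(sprintf("%s = %.3f", names(x$mean), x$mean),
                       collapse = ", "), "\n")
  invisible(x)
}
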