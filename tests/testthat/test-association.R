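test_that("two-group Kruskal-Wallis matches the closed-form rank statistic", {
  # all-tied pooled sample: no rank separation
  expect_equal(kruskal_wallis_two_group(rep(4, 6), rep(0:1, 3)),
               list(H = 0, p = 1))

  # {1,2,3} vs {4,5,6}: H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2)
  kw <- kruskal_wallis_two_group(1:6, c(0, 0, 0, 1, 1, 1))
  expect_equal(kw$H, 12 / 42 * (3 * 1.5^2 + 3 * 1.5^2), tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(kw$H, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(kruskal_wallis_two_group(1:4, rep(1, 4)), "two non-empty")
})

test_that("the chi-square p approximates a permutation null at moderate n", {
  withr::with_seed(31, {
    x <- c(stats::rnorm(20, 0), stats::rnorm(20, 0.8))
    g <- rep(0:1, each = 20)
    kw <- kruskal_wallis_two_group(x, g)
    perm <- replicate(4000, kruskal_wallis_two_group(x, sample(g))$H)
    p_perm <- mean(perm >= kw$H - 1e-12)
    expect_lt(abs(p_perm - kw$p), 0.02)
  })
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  withr::with_seed(5, {
    x <- stats::rexp(40); g <- rep(0:1, 20)
  })
  h0 <- kruskal_wallis_two_group(x, g)$H
  for (f in list(log, sqrt, function(v) v^3 + 2)) {
    expect_equal(kruskal_wallis_two_group(f(x), g)$H, h0, tolerance = 1e-12)
  }
})

test_that("Spearman correlation follows the rank formula", {
  expect_equal(spearman_correlation(c(1, 4, 9), c(10, 40, 90)), 1)
  expect_equal(spearman_correlation(1:5, -(1:5)), -1)
  # d = (rank x - rank y): sum d^2 = 6 -> 1 - 36/24
  expect_equal(spearman_correlation(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_true(is.na(spearman_correlation(rep(2, 5), 1:5)))
  expect_error(spearman_correlation(1:2, 1:2), "length")
})

test_that("screening drops null covariates and prunes collinear pairs", {
  # forced duplicate: the copy with the smaller KW p is the one retained
  withr::with_seed(17, {
    n <- 300
    presence <- rep(0:1, each = n / 2)
    signal <- presence * 1.2 + stats::rnorm(n)
    tab <- data.frame(presence = presence,
                      v_clean = signal + stats::rnorm(n, sd = 0.05),
                      v_noisy = signal + stats::rnorm(n, sd = 0.40))
  })
  rep1 <- screen_variables(tab)
  expect_identical(rep1$retained, "v_clean")
  expect_identical(rep1$pruning$dropped, "v_noisy")
  expect_gt(abs(rep1$pruning$r_s), 0.7)
  expect_lt(rep1$pruning$p_kept, rep1$pruning$p_dropped)

  # slope engineered to shadow ruggedness with a larger p: slope dropped
  withr::with_seed(23, {
    tri <- stats::rgamma(400, 8, 0.4)
    presence <- stats::rbinom(400, 1, stats::plogis(-3 + 0.17 * tri))
    slope <- tri + stats::rnorm(400, sd = 1.5)
    tab2 <- data.frame(presence = presence, TRI = tri, S = slope,
                       junk = stats::rnorm(400))
  })
  rep2 <- screen_variables(tab2)
  expect_true("TRI" %in% rep2$retained)
  expect_false("S" %in% rep2$retained)
  expect_false("junk" %in% rep2$retained)
  expect_true(all(rep2$pruning$p_dropped >= rep2$pruning$p_kept))
})

test_that("a pure-noise covariate passes stage 1 at far below alpha rate", {
  withr::with_seed(71, {
    passes <- sum(replicate(200, {
      tab <- data.frame(presence = rep(0:1, each = 50),
                        noise = stats::rnorm(100),
                        other = stats::rnorm(100))
      sum(screen_variables(tab)$tests$stage1_pass)
    }))
  })
  # 400 null screens at alpha = 5e-4: expect ~0.2 passes
  expect_lte(passes, 2)
})

test_that("logistic fit matches closed forms and a direct ML oracle", {
  # grouped 2x2: slope is the log odds ratio log(16)
  tab <- data.frame(presence = c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2)),
                    x = c(rep(0, 10), rep(1, 10)))
  fit <- fit_logistic(tab, "x")
  expect_equal(fit$coefficients$estimate[2], log(16), tolerance = 1e-6)
  expect_equal(fit$df_residual, 18)

  # IRLS equals direct maximization of the binomial log-likelihood
  withr::with_seed(13, {
    n <- 120
    tab2 <- data.frame(a = stats::rnorm(n), b = stats::runif(n))
    eta <- -0.4 + 1.1 * tab2$a - 0.8 * tab2$b
    tab2$presence <- stats::rbinom(n, 1, stats::plogis(eta))
  })
  fit2 <- fit_logistic(tab2, c("a", "b"))
  X <- cbind(1, tab2$a, tab2$b)
  nll <- function(beta) {
    lp <- X %*% beta
    -sum(tab2$presence * lp - log1p(exp(lp)))
  }
  opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(fit2$coefficients$estimate, unname(opt$par),
               tolerance = 1e-6)
  expect_equal(fit2$residual_deviance, 2 * opt$value, tolerance = 1e-6)
  expect_equal(fit2$aic, 2 * opt$value + 2 * 3, tolerance = 1e-6)
  expect_equal(fit2$df_residual, n - 3)

  # backward elimination never worsens AIC and keeps the informative terms
  tab3 <- transform(tab2, junk = withr::with_seed(99, stats::rnorm(n)))
  full <- fit_logistic(tab3, c("a", "b", "junk"))
  fit3 <- fit_logistic(tab3, c("a", "b", "junk"), backward = TRUE)
  expect_lte(fit3$aic, full$aic)
  expect_true(all(c("a", "b") %in% fit3$coefficients$term))
  expect_true(all(fit3$covariates %in% c("a", "b", "junk")))

  sep <- data.frame(presence = rep(0:1, each = 20),
                    z = c(stats::rnorm(20, -5), stats::rnorm(20, 5)))
  expect_error(fit_logistic(sep, "z"), "separation")
  dup <- transform(tab2, a2 = a)
  expect_error(fit_logistic(dup, c("a", "a2")), "rank-deficient")
})

test_that("occurrence prediction is the inverse-logit of the linear predictor", {
  beta <- c(intercept = 0, x = 2)
  expect_equal(predict_occurrence(beta, data.frame(x = 0)), 0.5)

  # published coefficient table evaluated at the covariate means
  b5 <- c(intercept = 25.351, MTWM = -1.159, TRI = 0.178, VRM = 28.476)
  p <- predict_occurrence(b5, data.frame(MTWM = 24.52, TRI = 20.33,
                                         VRM = 0.005))
  expect_equal(p, 0.667, tolerance = 0.001)

  # positive ruggedness coefficient: probability strictly increasing in TRI
  tri_seq <- data.frame(MTWM = 24.52, TRI = seq(5, 35, 2), VRM = 0.005)
  expect_true(all(diff(predict_occurrence(b5, tri_seq)) > 0))

  expect_error(predict_occurrence(b5, data.frame(TRI = 10, VRM = 0)),
               "MTWM")
})

test_that("classification metrics follow their defining formulas", {
  perfect <- classification_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$tss, 1)

  # 4 positive-negative pairs, 3 concordant
  m <- classification_metrics(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 3 / 4)

  # AUC invariant under strictly monotone transforms of the scores
  withr::with_seed(3, {
    sc <- stats::runif(60); lb <- stats::rbinom(60, 1, sc)
  })
  a0 <- classification_metrics(sc, lb)$auc
  expect_equal(classification_metrics(stats::qlogis(sc), lb)$auc, a0)
  skip_if_not_installed("pROC")
  expect_equal(a0, as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))
})

test_that("TSS identity holds exactly at any threshold", {
  withr::with_seed(19, {
    sc <- stats::runif(200)
    lb <- stats::rbinom(200, 1, stats::plogis(4 * (sc - 0.5)))
  })
  for (thr in c(0.3, 0.5, 0.7)) {
    m <- classification_metrics(sc, lb, threshold = thr)
    expect_identical(m$tss, m$sensitivity + m$specificity - 1)
  }
  # the published operating point: sens 0.812, spec 0.878 -> TSS 0.690
  n1 <- 1000; n0 <- 1000
  scores <- c(rep(0.9, 812), rep(0.1, n1 - 812),
              rep(0.1, 878), rep(0.9, n0 - 878))
  labels <- c(rep(1, n1), rep(0, n0))
  m <- classification_metrics(scores, labels)
  expect_equal(m$sensitivity, 0.812)
  expect_equal(m$specificity, 0.878)
  expect_equal(m$tss, 0.690)
  expect_error(classification_metrics(sc, rep(1, 200)), "both classes")
})

test_that("cross-validated random forest is stratified, seeded and skilful", {
  withr::with_seed(41, {
    n <- 200
    x <- stats::rnorm(n)
    tab <- data.frame(presence = as.integer(x > 0), x = x,
                      j = stats::rnorm(n))
  })
  cv <- random_forest_cv(tab, k = 2, seed = 5, ntree = 100)
  expect_equal(unname(cv$mean["auc"]), 1, tolerance = 1e-9)
  cv2 <- random_forest_cv(tab, k = 2, seed = 5, ntree = 100)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$per_fold, cv2$per_fold)
  # every fold contains both classes
  expect_true(all(vapply(1:2, function(f) {
    length(unique(tab$presence[cv$folds == f])) == 2
  }, TRUE)))

  tiny <- data.frame(presence = c(rep(1, 3), rep(0, 20)),
                     x = stats::rnorm(23))
  expect_error(random_forest_cv(tiny, k = 10), "stratification")
})

test_that("a strong ruggedness effect yields the high-AUC regime", {
  aucs <- vapply(1:5, function(s) {
    # strong, balanced ruggedness effect: steeper TRI slope with the
    # intercept recentred so both classes stay well represented
    sc <- scene_config(grid_rows = 70, grid_cols = 70,
                       truth_model = c(intercept = 13.0, TRI = 0.30,
                                       MTWM = -1.159, VRM = 28.476),
                       seed = s)
    dem <- generate_dem(sc)
    terrain <- compute_terrain(dem)
    cov <- generate_covariates(dem, sc)
    cover <- generate_cover_truth(dem, terrain, cov, sc)
    el <- which(!is.na(dem$values) & dem$values >= sc$pine_floor)
    cells <- withr::with_seed(1000 + s, sample(el, 500))
    tab <- data.frame(presence = as.integer(cover$values[cells] == 1),
                      TRI = terrain$tri$values[cells],
                      VRM = terrain$vrm$values[cells],
                      MTWM = cov$MTWM$values[cells])
    unname(random_forest_cv(tab, k = 10, seed = s,
                            ntree = 150)$mean["auc"])
  }, 0)
  expect_gt(mean(aucs), 0.8)
})
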