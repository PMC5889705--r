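test_that("error matrices cross-tabulate samples and carry area weights", {
  em <- table3_em()
  expect_equal(unname(em$weights["P"]), 5395 / 31823, tolerance = 1e-12)
  expect_equal(em$total_area, 31823)
  expect_equal(unname(em$row_totals), c(536, 764, 405, 438))

  # cross-tabulation path reproduces the same matrix
  samples <- do.call(rbind, lapply(rownames(em$counts), function(i) {
    do.call(rbind, lapply(colnames(em$counts), function(j) {
      k <- em$counts[i, j]
      if (k == 0) return(NULL)
      data.frame(mapped_class = rep(i, k), true_class = rep(j, k))
    }))
  }))
  em2 <- build_error_matrix(samples, em$mapped_areas)
  expect_equal(em2$counts, em$counts)

  one <- error_matrix(matrix(7, 1, 1, dimnames = list("p", "p")), 100)
  expect_equal(unname(one$weights), 1)

  expect_error(build_error_matrix(samples[0, ], em$mapped_areas),
               "empty sample table")
  expect_error(error_matrix(rbind(c(3, 1), c(0, 2)), c(0, 50)),
               "zero mapped area")
})

test_that("poststratified proportions follow W_i * n_ij / n_i.", {
  em <- table3_em()
  pp <- poststratified_proportions(em)
  expect_equal(pp$p["S", "S"], (12309 / 31823) * (619 / 764),
               tolerance = 1e-12)
  expect_equal(sum(pp$p), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(pp$p)), unname(em$weights), tolerance = 1e-12)

  # a perfect diagonal map estimates exactly the area weights
  diag_em <- error_matrix(diag(c(10, 20, 30)), c(5, 60, 35),
                          class_names = c("a", "b", "c"))
  expect_equal(unname(poststratified_proportions(diag_em)$col_totals),
               c(0.05, 0.60, 0.35), tolerance = 1e-12)

  zero_row <- error_matrix(rbind(c(2, 1), c(1, 1)), c(10, 10),
                           class_names = c("a", "b"))
  zero_row$counts["b", ] <- 0; zero_row$row_totals["b"] <- 0
  expect_error(poststratified_proportions(zero_row), "stratum b")
})

test_that("area estimates match a written-out evaluation of the estimators", {
  # 2x2 example evaluated by hand:
  # counts [[8,2],[1,9]], areas (60,40), A = 100, W = (0.6, 0.4)
  em <- error_matrix(rbind(c(8, 2), c(1, 9)), c(60, 40),
                     class_names = c("x", "y"))
  est <- estimate_areas(em)
  p11 <- 0.6 * 8 / 10; p12 <- 0.6 * 2 / 10
  p21 <- 0.4 * 1 / 10; p22 <- 0.4 * 9 / 10
  expect_equal(est$area_ha, 100 * c(p11 + p21, p12 + p22), tolerance = 1e-12)
  v1 <- 0.6^2 * (0.8 * 0.2) / 9 + 0.4^2 * (0.1 * 0.9) / 9
  v2 <- 0.6^2 * (0.2 * 0.8) / 9 + 0.4^2 * (0.9 * 0.1) / 9
  expect_equal(est$se_ha, 100 * sqrt(c(v1, v2)), tolerance = 1e-12)
  expect_equal(est$margin_ha, 1.96 * est$se_ha, tolerance = 1e-12)
  expect_equal(est$margin_2se_ha, 2 * est$se_ha, tolerance = 1e-12)

  # conservation: estimated areas always resum to the mapped total
  expect_equal(sum(est$area_ha), 100, tolerance = 1e-12)
  t3 <- estimate_areas(table3_em())
  expect_equal(sum(t3$area_ha), 31823, tolerance = 1e-9)

  # perfect diagonal: zero within-stratum variance
  diag_em <- error_matrix(diag(c(12, 8)), c(30, 70),
                          class_names = c("a", "b"))
  expect_equal(estimate_areas(diag_em)$se_ha, c(0, 0))

  # single off-diagonal sample leaves the variance undefined
  single <- error_matrix(rbind(c(0, 1), c(0, 5)), c(10, 90),
                         class_names = c("a", "b"))
  expect_error(estimate_areas(single), "single-sample")
})

test_that("area scaling leaves proportions and accuracies invariant", {
  em <- table3_em()
  em_scaled <- error_matrix(em$counts, em$mapped_areas * 3.5)
  a1 <- estimate_areas(em); a2 <- estimate_areas(em_scaled)
  expect_equal(a2$area_ha, 3.5 * a1$area_ha, tolerance = 1e-9)
  expect_equal(a2$se_ha, 3.5 * a1$se_ha, tolerance = 1e-9)
  expect_equal(a2$proportion, a1$proportion, tolerance = 1e-12)
  expect_equal(accuracies(em_scaled), accuracies(em), tolerance = 1e-12)
})

test_that("accuracy measures behave at the degenerate extremes", {
  ident <- error_matrix(diag(c(5, 5, 5)), c(20, 30, 50),
                        class_names = c("a", "b", "c"))
  acc <- accuracies(ident)
  expect_equal(acc$overall, 1)
  expect_equal(unname(acc$users), c(1, 1, 1))
  expect_equal(unname(acc$producers), c(1, 1, 1))
  expect_equal(kappa_coefficient(ident), 1)

  # empty reference column: producer's accuracy undefined, not an error
  em <- error_matrix(rbind(c(5, 0), c(5, 0)), c(50, 50),
                     class_names = c("a", "b"))
  expect_true(is.na(accuracies(em)$producers["b"]))

  # equal margins, half agreement: kappa exactly zero
  chance <- error_matrix(rbind(c(5, 5), c(5, 5)), c(50, 50),
                         class_names = c("a", "b"))
  expect_equal(kappa_coefficient(chance), 0)
})

test_that("kappa on the Table 3 counts matches the margin formula by hand", {
  em <- table3_em()
  po <- 1907 / 2143
  pe <- (536 * 596 + 764 * 619 + 405 * 501 + 438 * 427) / 2143^2
  expect_equal(kappa_coefficient(em, "counts"), (po - pe) / (1 - pe),
               tolerance = 1e-12)
  # area basis differs (weights replace count margins)
  k_area <- kappa_coefficient(em, "area_proportions")
  expect_false(isTRUE(all.equal(k_area, kappa_coefficient(em, "counts"))))
  expect_true(k_area > 0.8 && k_area < 0.87)
})

test_that("CSV parsing validates layout, counts, and is order-equivariant", {
  em <- table3_em()
  lines <- readLines(table3_fixture())
  perm <- c(lines[1], lines[c(4, 2, 5, 3)])
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(perm, f)
  em_p <- read_error_matrix_csv(f)
  ord <- em$class_names
  expect_equal(em_p$counts[ord, ord], em$counts)
  rep1 <- area_report(em); rep2 <- area_report(em_p)
  expect_equal(rep2$users[ord], rep1$users[ord], tolerance = 1e-12)
  expect_equal(rep2$overall, rep1$overall, tolerance = 1e-12)

  writeLines(c("map_class,P,S,mapped_area", "P,5,-1,10", "S,0,5,10"), f)
  expect_error(read_error_matrix_csv(f), "negative count at line")
  writeLines(c("map_class,P,S", "P,5,1", "S,0,5"), f)
  expect_error(read_error_matrix_csv(f), "mapped_area")
})

test_that("the analytic SE matches Monte-Carlo resampling on a fixed map", {
  # fixed generating map: per-stratum reference distributions and weights
  em0 <- table3_em()
  r <- sweep(em0$counts, 1, em0$row_totals, "/")
  n_i <- c(80, 80, 80, 80)
  draws <- 2000
  p_hat <- matrix(0, draws, 4)
  se_est <- matrix(0, draws, 4)
  withr::with_seed(99, {
    for (d in seq_len(draws)) {
      counts <- t(sapply(1:4, function(i) {
        stats::rmultinom(1, n_i[i], r[i, ])[, 1]
      }))
      em <- error_matrix(counts, em0$mapped_areas,
                         class_names = em0$class_names)
      est <- estimate_areas(em)
      p_hat[d, ] <- est$proportion
      se_est[d, ] <- est$se_proportion
    }
  })
  emp_sd <- apply(p_hat, 2, stats::sd)
  mean_se <- colMeans(se_est)
  expect_true(all(abs(mean_se - emp_sd) / emp_sd < 0.10))
})
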