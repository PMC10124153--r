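# Inferential machinery: CBP test, residualization, rank-normal transform,
# permutation Spearman, exposure correlations.

test_that("cbp_paired_test finds no clusters for identical conditions", {
  set.seed(10)
  b <- matrix(rnorm(8 * 50), 8)
  r <- cbp_paired_test(b, b, n_perm = 200)
  expect_equal(nrow(r$clusters), 0L)
  expect_error(cbp_paired_test(b[1:4, ], b[1:4, ]), ">= 5")
  expect_warning(cbp_paired_test(b + 1, b, n_perm = 50), "low")
})

test_that("exact CBP p-values equal brute-force sign-flip enumeration", {
  set.seed(11)
  n <- 8
  b <- matrix(rnorm(n * 40), n)
  a <- b + matrix(rnorm(n * 40, sd = 1), n)
  a[, 15:25] <- a[, 15:25] + 4
  r <- cbp_paired_test(a, b, exact = TRUE)
  expect_gte(nrow(r$clusters), 1L)
  null <- oracle_signflip_null(a - b, r$threshold)
  for (i in seq_len(nrow(r$clusters))) {
    expect_equal(r$clusters$p[i], mean(null >= abs(r$clusters$mass[i]) - 1e-12))
  }
  # Monte-Carlo mode is seed-deterministic
  r1 <- cbp_paired_test(a, b, n_perm = 300, seed = 5)
  r2 <- cbp_paired_test(a, b, n_perm = 300, seed = 5)
  expect_identical(r1$clusters, r2$clusters)
  expect_true(all(r1$clusters$p >= 1 / 301) && all(r1$clusters$p <= 1))
})

test_that("an injected offset cluster is detected where it was injected", {
  set.seed(12)
  n <- 8
  b <- matrix(rnorm(n * 100), n)
  a <- b + matrix(rnorm(n * 100, sd = 1), n)
  a[, 40:60] <- a[, 40:60] + 10
  r <- cbp_paired_test(a, b, n_perm = 500, seed = 1)
  sig <- r$clusters[r$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 1L)
  main <- sig[which.max(abs(sig$mass)), ]
  covered <- length(intersect(main$start_bin:main$end_bin, 40:60))
  expect_gte(covered / 21, 0.8)
  expect_gt(main$mass, 0)  # signed mass keeps the direction of the increase
})

test_that("residualize yields exact OLS residuals with orthogonality", {
  v <- c(3, 5, 7, 9, 11)
  cov0 <- data.frame(experiment = rep(1, 5), age_days = rep(100, 5))
  expect_equal(residualize(v, cov0), v - mean(v))

  age <- c(80, 90, 100, 110, 120)
  expect_equal(residualize(2 * age, data.frame(age_days = age)), rep(0, 5),
               tolerance = 1e-10)

  set.seed(13)
  vals <- 2 * age + rnorm(5)
  res <- residualize(vals, data.frame(experiment = c(1, 1, 2, 2, 2), age_days = age))
  expect_lt(abs(sum(res)), 1e-10)
  expect_lt(abs(sum(res * age)), 1e-8)

  expect_error(residualize(vals, data.frame(a = age, b = age * 2)), "collinear")
})

test_that("transform_to_normal is the rank-preserving inverse-normal map", {
  set.seed(14)
  x <- rexp(50)
  z <- transform_to_normal(x)
  expect_identical(rank(z), rank(x))
  skew <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(abs(skew), 0.3)
  y <- rexp(50)
  expect_equal(cor(x, y, method = "spearman"),
               cor(transform_to_normal(x), transform_to_normal(y), method = "spearman"))
  expect_equal(z, qnorm((rank(x) - 0.5) / 50))
  expect_error(transform_to_normal(rep(1, 5)), "equal")
  expect_error(transform_to_normal(c(1, 2)), ">= 3")
})

test_that("spearman_perm matches exhaustive enumeration and handles extremes", {
  sp <- spearman_perm(1:6, c(2, 4, 5, 7, 8, 11), exact = TRUE)
  expect_equal(sp$rho, 1)
  expect_equal(sp$p, 2 / 720)  # identity and full reversal

  anti <- spearman_perm(1:8, seq(16, 2, by = -2), n_perm = 1000, seed = 2)
  expect_equal(anti$rho, -1)
  expect_equal(anti$p, 1 / 1001, tolerance = 2e-3)

  # Monte-Carlo p close to the oracle-enumerated exact p at n = 6
  set.seed(15)
  x <- rnorm(6)
  y <- x + rnorm(6, sd = 1.5)
  rx <- rank(x); ry <- rank(y)
  perms <- oracle_permutations(6)
  rhos <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
  p_exact <- mean(abs(rhos) >= abs(cor(rx, ry)) - 1e-12)
  mc <- spearman_perm(x, y, n_perm = 1000, seed = 3)
  expect_equal(mc$p, p_exact, tolerance = 2 / sqrt(1000))
  expect_equal(spearman_perm(x, y, exact = TRUE)$p, p_exact)

  expect_error(spearman_perm(rep(1, 5), 1:5), "constant")
  expect_error(spearman_perm(1:3, 1:3), ">= 4")
})

test_that("exposure_correlation recovers signs and flags degenerate rows", {
  set.seed(16)
  n <- 12
  animals <- sprintf("r%02d", 1:n)
  expo <- data.frame(animal = animals, condition = "compound",
                     exposure_ng_ml = runif(n, 20, 120))
  expo <- rbind(expo, data.frame(animal = animals, condition = "vehicle",
                                 exposure_ng_ml = 0))
  cov <- data.frame(animal = animals, experiment = rep(1:2, each = 6),
                    age_days = round(runif(n, 85, 150)))
  dose <- expo$exposure_ng_ml[match(animals, expo$animal[expo$condition == "compound"])]
  mk <- function(cond, amp) data.frame(animal = animals, region = "parietal",
                                       condition = cond, band = "beta",
                                       amplitude_db = amp,
                                       modal_freq_hz = 15 + 0.01 * amp,
                                       auc_db_hz = amp * 2)
  metrics <- rbind(mk("vehicle", 2 + rnorm(n, 0, 0.05)),
                   mk("compound", 2 + 0.02 * dose + rnorm(n, 0, 0.05)))
  tab <- exposure_correlation(metrics, exposures = expo, covariates = cov,
                              compound = "compound", n_perm = 500, seed = 4)
  amp_row <- tab[tab$parameter == "amplitude", ]
  expect_gt(amp_row$rho, 0.5)
  expect_lt(amp_row$p, 0.05)
  expect_equal(amp_row$contrast, "vehicle_difference")
  modal_row <- tab[tab$parameter == "modal_frequency", ]
  expect_equal(modal_row$contrast, "compound_only")

  # vehicle == compound -> exact-zero contrasts are flagged, not dropped
  same <- rbind(mk("vehicle", rep(2, n)), mk("compound", rep(2, n)))
  tab2 <- exposure_correlation(same, exposures = expo, covariates = cov,
                               compound = "compound", n_perm = 200, seed = 4)
  expect_true(all(tab2$flag[tab2$parameter %in% c("amplitude", "auc")] == "degenerate"))

  # too few animals -> insufficient_n flag
  few <- metrics[metrics$animal %in% animals[1:3] | metrics$condition == "vehicle", ]
  few <- few[few$animal %in% animals[1:3], ]
  tab3 <- exposure_correlation(few, exposures = expo, covariates = cov,
                               compound = "compound", n_perm = 200, seed = 4)
  expect_true(all(tab3$flag == "insufficient_n"))
  expect_true(all(!is.na(tab3$n)))
})
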