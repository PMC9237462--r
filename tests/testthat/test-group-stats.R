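test_that("PCA explains variance along the right axes", {
  set.seed(21)
  one_dim <- cbind(stats::rnorm(50), 0.5)
  one_dim[, 2] <- one_dim[, 2] + 1e-12 * stats::rnorm(50)  # avoid exact tie
  pc <- pca_components(one_dim, "center")
  expect_gt(pc$explained[1], 1 - 1e-10)
  # orthogonal rotation leaves explained variances unchanged
  x <- matrix(stats::rnorm(200 * 3), 200, 3) %*% diag(c(3, 2, 1))
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  p1 <- pca_components(x, "center")
  p2 <- pca_components(x %*% q, "center")
  expect_equal(p1$explained, p2$explained, tolerance = 1e-10)
  # known covariance [[2,1],[1,2]]: eigenvalues 3 and 1 -> 3/4, 1/4
  ch <- chol(matrix(c(2, 1, 1, 2), 2))
  y <- matrix(stats::rnorm(20000 * 2), ncol = 2) %*% ch
  py <- pca_components(y, "center")
  expect_equal(py$explained, c(3, 1) / 4, tolerance = 0.03)
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(py$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
})

test_that("PCA reconstruction reproduces the input", {
  set.seed(22)
  x <- matrix(stats::rnorm(40 * 4), 40, 4)
  pc <- pca_components(x, "center")
  recon <- pc$scores %*% t(pc$loadings) +
    matrix(colMeans(x), 40, 4, byrow = TRUE)
  expect_lt(max(abs(recon - x)), 1e-10)
})

test_that("ITPC components behave on degenerate and planted structure", {
  set.seed(23)
  base <- stats::runif(60, 0.1, 0.5)
  df <- data.frame(participant = rep(1:12, 5),
                   condition = rep(letters[1:5], each = 12),
                   f4 = base, f8 = 0.8 * base, f12 = 0.5 * base,
                   f16 = 0.3 * base)
  comp <- itpc_components(df)
  expect_gt(comp$explained[1], 1 - 1e-9)
  expect_true(all(comp$loadings[, 1] > 0))
  expect_equal(unname(which.max(comp$loadings[, 1])), 1L)  # 4 Hz heaviest
  # planted two-factor structure: explained split recovered within 5%
  n <- 4000
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  m <- cbind(f4 = 2 * f1, f8 = 2 * f1 + 0.01 * stats::rnorm(n),
             f12 = f2, f16 = f2 + 0.01 * stats::rnorm(n))
  pc <- pca_components(m, "center")
  expect_equal(pc$explained[1], 8 / 10, tolerance = 0.05)
  expect_equal(pc$explained[2], 2 / 10, tolerance = 0.05)
  expect_error(itpc_components(df[, -3]), "missing harmonic")
})

test_that("marker PCA z-scores its heterogeneous units", {
  set.seed(24)
  mk <- data.frame(md_latency = stats::runif(15, 20, 150),
                   ma_latency = stats::runif(15, 50, 200),
                   sharpness = stats::runif(15, 2, 5),
                   gini = stats::runif(15, 0.1, 0.6),
                   plateau = stats::runif(15, 20, 120))
  pc <- marker_components(mk)
  mk_s <- mk
  mk_s$md_latency <- mk_s$md_latency / 1000   # ms -> s
  pc_s <- marker_components(mk_s)
  expect_equal(abs(pc$scores), abs(pc_s$scores), tolerance = 1e-10)
  mk0 <- mk
  mk0$gini <- 0.3
  expect_error(marker_components(mk0), "gini")
  perfect <- data.frame(md_latency = 1:10, ma_latency = 2 * (1:10),
                        sharpness = -(1:10), gini = (1:10) / 10,
                        plateau = 1:10 + 5)
  expect_gt(marker_components(perfect)$explained[1], 1 - 1e-10)
})

test_that("Pearson correlation and its p transform are exact", {
  x <- 1:10
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -2 * x + 3)$r, -1)
  expect_error(pearson_cor(x, rep(1, 10)), "zero-variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
  # construct n = 25 pairs with sample correlation exactly 0.54
  set.seed(25)
  n <- 25
  z1 <- scale(stats::rnorm(n))[, 1]
  z2 <- stats::rnorm(n)
  z2 <- scale(stats::residuals(stats::lm(z2 ~ z1)))[, 1]
  r <- 0.54
  y <- r * z1 + sqrt(1 - r^2) * z2
  res <- pearson_cor(z1, y)
  expect_equal(res$r, 0.54, tolerance = 1e-12)
  expect_gt(res$p.value, 0.005)
  expect_lt(res$p.value, 0.006)
})

test_that("repeated-measures ANOVA matches its references", {
  set.seed(26)
  # two conditions: epsilon is exactly 1
  y2 <- matrix(stats::rnorm(16 * 2), 16, 2)
  a2 <- rm_anova_gg(y2)
  expect_equal(a2$epsilon, 1)
  # epsilon agrees with the orthonormal-contrast eigenvalue formula
  Y <- matrix(stats::rnorm(20 * 6), 20, 6) %*% matrix(stats::rnorm(36), 6)
  mine <- rm_anova_gg(Y)
  p <- ncol(Y)
  C <- qr.Q(qr(cbind(1, diag(p))))[, 2:p]      # orthonormal contrasts
  lam <- eigen(t(C) %*% stats::cov(Y) %*% C, symmetric = TRUE)$values
  eps_ref <- sum(lam)^2 / ((p - 1) * sum(lam^2))
  expect_equal(mine$epsilon, eps_ref, tolerance = 1e-10)
  # forcing epsilon to 1 recovers the uncorrected p
  expect_equal(stats::pf(mine$F, mine$df1, mine$df2, lower.tail = FALSE),
               mine$p.uncorrected)
  # planted effect is detected
  yy <- matrix(stats::rnorm(10 * 4, sd = 0.1), 10, 4)
  yy <- sweep(yy, 2, c(0, 1, 2, 3), "+")
  expect_lt(rm_anova_gg(yy)$p.value, 0.001)
  # long-format input is accepted
  long <- data.frame(participant = rep(1:16, 2),
                     condition = rep(c("a", "b"), each = 16),
                     value = as.vector(y2))
  expect_equal(rm_anova_gg(long)$F, a2$F, tolerance = 1e-10)
  expect_error(rm_anova_gg(y2[1, , drop = FALSE]), "at least 2")
})

test_that("null simulation keeps the ANOVA near its nominal level", {
  set.seed(27)
  rej <- mean(replicate(400,
    rm_anova_gg(matrix(stats::rnorm(12 * 5), 12, 5))$p.value < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("Bonferroni post-hocs apply the multiplication rule", {
  set.seed(28)
  Y <- matrix(stats::rnorm(12 * 4), 12, 4,
              dimnames = list(NULL, letters[1:4]))
  ph <- bonferroni_posthoc(Y)
  expect_equal(nrow(ph), 6L)
  expect_equal(ph$p.adjusted, pmin(1, 6 * ph$p.raw))
  one <- bonferroni_posthoc(Y, pairs = list(c("a", "b")))
  expect_equal(one$p.adjusted, one$p.raw)
  same <- bonferroni_posthoc(cbind(a = Y[, 1], b = Y[, 1]))
  expect_equal(same$t, 0)
  expect_equal(same$p.adjusted, 1)
  expect_error(bonferroni_posthoc(Y[1, , drop = FALSE]), "at least 2")
})

test_that("k-means recovers separated condition clusters", {
  set.seed(29)
  blobs <- rbind(matrix(stats::rnorm(10, 0, 0.05), 5, 2),
                 matrix(stats::rnorm(10, 5, 0.05), 5, 2),
                 matrix(stats::rnorm(10, 10, 0.05), 5, 2))
  rownames(blobs) <- paste0("c", 1:15)
  km <- kmeans_conditions(blobs, k = 3, seed = 4)
  expect_equal(length(unique(km$cluster[1:5])), 1L)
  expect_equal(length(unique(km$cluster[6:10])), 1L)
  expect_equal(length(unique(km$cluster[11:15])), 1L)
  expect_equal(length(unique(km$cluster)), 3L)
  km1 <- kmeans_conditions(blobs, k = 1, seed = 4)
  tot <- sum(scale(blobs, scale = FALSE)^2)
  expect_equal(km1$tot.withinss, tot, tolerance = 1e-10)
  dup <- rbind(a = c(1, 1), b = c(1, 1), c = c(9, 9))
  kd <- kmeans_conditions(dup, k = 2, seed = 4)
  expect_equal(kd$cluster[["a"]], kd$cluster[["b"]])
  expect_error(kmeans_conditions(dup, k = 5), "exceeds")
  expect_identical(kmeans_conditions(blobs, k = 3, seed = 9)$cluster,
                   kmeans_conditions(blobs, k = 3, seed = 9)$cluster)
})

test_that("phoneme partitions match the experimental design", {
  pg <- phoneme_groups()
  expect_setequal(pg$three$stops, c("b", "d", "g", "k", "p", "t"))
  expect_setequal(pg$three$fricatives_sibilants, c("f", "v", "s", "z"))
  expect_setequal(pg$three$nasals_liquids, c("m", "n", "l", "r"))
  expect_setequal(pg$voicing_stops$voiced, c("b", "d", "g"))
  expect_setequal(pg$voicing_stops$unvoiced, c("k", "p", "t"))
  expect_setequal(unname(unlist(pg$five)), unname(unlist(pg$three)))
})

test_that("group aggregation averages conditions within groups", {
  pg <- phoneme_groups()
  set.seed(30)
  sc <- expand.grid(participant = 1:6,
                    condition = condition_labels(),
                    stringsAsFactors = FALSE)
  sc$ITPC1 <- stats::rnorm(nrow(sc))
  ga <- group_aggregate(sc, pg$three)
  expect_equal(colnames(ga$by_participant),
               c("stops", "fricatives_sibilants", "nasals_liquids"))
  # vowel rows are dropped, groups average their conditions
  p1_stops <- mean(sc$ITPC1[sc$participant == 1 &
                              sc$condition %in% pg$three$stops])
  expect_equal(unname(ga$by_participant[1, "stops"]), p1_stops)
  # single-condition groups reduce to the condition means
  single <- list(g1 = "b", g2 = "m")
  gs <- group_aggregate(sc, single)
  expect_equal(unname(gs$by_participant[2, "g1"]),
               sc$ITPC1[sc$participant == 2 & sc$condition == "b"])
  bad <- sc
  bad$condition[1] <- "x"
  expect_error(group_aggregate(bad, pg$three), "unknown condition")
})
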