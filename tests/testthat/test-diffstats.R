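test_that("one-way ANOVA matches the closed-form example", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  a <- anova_oneway(g)
  expect_equal(a$F, 3)
  expect_equal(c(a$df1, a$df2), c(2, 6))
  expect_equal(a$p, pf(3, 2, 6, lower.tail = FALSE))
  expect_equal(a$p, 0.125, tolerance = 1e-3)
})

test_that("ANOVA and Tukey agree with stats::aov / stats::TukeyHSD", {
  set.seed(42)
  for (i in 1:150) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(sample(2:10, 1), mean = rnorm(1)))
    names(g) <- paste0("g", seq_len(k))
    a <- anova_oneway(g)
    df <- data.frame(y = unlist(g),
                     grp = factor(rep(names(g), lengths(g)), levels = names(g)))
    fit <- stats::aov(y ~ grp, data = df)
    s <- summary(fit)[[1]]
    expect_equal(a$F, s[["F value"]][1], tolerance = 1e-8)
    expect_equal(a$p, s[["Pr(>F)"]][1], tolerance = 1e-8)
    tk <- tukey_hsd(g)
    ref <- stats::TukeyHSD(fit)$grp
    key <- paste(tk$group_j, tk$group_i, sep = "-")
    expect_equal(tk$difference, unname(ref[key, "diff"]), tolerance = 1e-8)
    expect_equal(tk$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-8)
  }
})

test_that("Tukey q follows the studentized-range formula", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  tk <- tukey_hsd(g)
  pair13 <- tk[tk$group_i == "1" & tk$group_j == "3", ]
  expect_equal(pair13$difference, 2)
  expect_equal(pair13$q, 2 / sqrt(1 / 3), tolerance = 1e-12) # MSw = 1, n = 3
  # identical groups: zero difference, adjusted p near 1
  tk2 <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 6, 7)))
  ab <- tk2[tk2$group_i == "a" & tk2$group_j == "b", ]
  expect_equal(ab$difference, 0)
  expect_equal(ab$p_adj, 1, tolerance = 1e-6)
})

test_that("Tukey adjusted p matches numerical integration of the range CDF", {
  skip_if_not_installed("pracma")
  set.seed(11)
  worst <- 0
  for (i in 1:15) {
    k <- sample(3:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1), rnorm(1)))
    tk <- tukey_hsd(g)
    a <- anova_oneway(g)
    for (r in seq_len(nrow(tk))) {
      worst <- max(worst,
                   abs(tk$p_adj[r] - (1 - oracle_ptukey(tk$q[r], k, a$df2))))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("BH adjustment matches the hand step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(200)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential features detect planted effects and respect invariants", {
  design <- tiny_design()
  set.seed(9)
  n_null <- 60
  x <- base::matrix(2^(10 + rnorm(n_null * 12, 0, 0.15)), n_null, 12)
  eff <- 2^(10 + rnorm(12, 0, 0.15) + ifelse(design$day == 6, 1, 0))
  m <- tiny_matrix(rbind(x, eff), design, level = "kme_site_normalized")
  d <- differential_features(m, design)
  last <- d[d$feature_id == paste0("f", n_null + 1), ]
  expect_true(last$significant)
  expect_gt(last$log2fc_6v0, 0)
  expect_true(all(d$padj >= d$p))
  expect_true(all(d$p >= 0 & d$p <= 1))
  # significance needs both levels below alpha
  expect_true(all(!d$significant |
                    (d$padj < 0.05 &
                       (pmin(d$padj_2v0, d$padj_6v0, d$padj_6v2, na.rm = TRUE) < 0.05))))
})

test_that("degenerate and constant features are handled explicitly", {
  design <- tiny_design()
  m <- tiny_matrix(rbind(rep(5, 12), rep(c(1, 2, 4), each = 4)), design,
                   level = "kme_site_normalized")
  d <- differential_features(m, design)
  skip_rep <- attr(d, "skip_report")
  expect_equal(skip_rep$feature_id, "f1")
  expect_equal(skip_rep$reason, "zero_variance")
  # zero within-group variance with real between-group differences
  expect_true(d$degenerate[d$feature_id == "f2"])
  expect_equal(d$p[d$feature_id == "f2"], 0)
  # noise-free 2x at day 6 gives log2FC exactly 1
  m2 <- tiny_matrix(base::matrix(rep(c(3, 3.2, 6) / 3, each = 4), 1, byrow = TRUE),
                    design, level = "kme_site_normalized")
  d2 <- differential_features(m2, design)
  expect_equal(d2$log2fc_6v0, 1, tolerance = 1e-12)
  # insufficient replicates are skipped with reason
  mm <- base::matrix(2, 2, 12); mm[2, design$day == 2] <- NA
  mm[2, 1] <- 3
  m3 <- tiny_matrix(mm, design, level = "kme_site_normalized")
  d3 <- differential_features(m3, design)
  expect_true("insufficient_replicates" %in% attr(d3, "skip_report")$reason)
})

test_that("replicate correlation is symmetric with exact extremes", {
  design <- tiny_design()
  set.seed(2)
  f <- runif(20, 10, 100)               # feature profile
  x <- cbind(f, 2 * f, 300 - f,
             base::matrix(runif(20 * 9, 10, 100), 20, 9))
  m <- tiny_matrix(x, design)
  rc <- replicate_correlation(m, log2_transform = FALSE)
  get_r <- function(i, j) rc$r[rc$sample_i == design$sample[i] &
                                 rc$sample_j == design$sample[j]]
  expect_equal(get_r(1, 1), 1)                     # diagonal
  expect_equal(get_r(1, 4), get_r(4, 1))           # symmetry
  expect_equal(get_r(1, 2), 1)                     # scaled duplicate column
  expect_equal(get_r(1, 3), -1)                    # negated linear column
  # scaled duplicate is exact on log2 values too
  rc2 <- replicate_correlation(m)
  expect_equal(rc2$r[rc2$sample_i == design$sample[1] &
                       rc2$sample_j == design$sample[2]], 1)
  # too few complete pairs -> missing r, with n reported
  x3 <- x; x3[3:20, 1] <- NA
  rc3 <- replicate_correlation(tiny_matrix(x3, design),
                               log2_transform = FALSE)
  expect_true(is.na(rc3$r[rc3$sample_i == design$sample[1] &
                            rc3$sample_j == design$sample[4]]))
})

test_that("sample PCA has fixed sign, ordered variance, stable duplicates", {
  design <- tiny_design()
  set.seed(4)
  x <- 2^(base::matrix(rnorm(50 * 12, 10, 1), 50, 12))
  x[, design$day == 6] <- x[, design$day == 6] * 4
  m <- tiny_matrix(x, design)
  pc <- pca_samples(m)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-9)
  # duplicated samples receive identical scores
  x2 <- cbind(x[, 1], x[, 1], x[, -(1:2)])
  pc2 <- pca_samples(tiny_matrix(x2, design))
  expect_equal(unlist(pc2$scores[1, c("PC1", "PC2")]),
               unlist(pc2$scores[2, c("PC1", "PC2")]), tolerance = 1e-9)
  expect_error(pca_samples(tiny_matrix(x, design)[0, ]), ".")
  # day-6 separation appears on PC1
  sc <- tidy(pc)
  d6 <- sc$PC1[design$day == 6]; d0 <- sc$PC1[design$day == 0]
  expect_gt(abs(mean(d6) - mean(d0)), 0)
  g <- glance(pc)
  expect_equal(g$n_features, 50)
})
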