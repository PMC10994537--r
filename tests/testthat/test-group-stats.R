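test_that("BH adjustment follows the step-up rule and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  p <- runif(50)
  q <- bh_fdr(p)
  # monotone in the raw p-values
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # invariant to input order
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_true(all(q >= p - 1e-12 & q <= 1))
})

test_that("voxel-wise t maps match the closed-form two-sample test", {
  mask <- array(TRUE, c(1, 1, 1))
  A <- lapply(c(1, 2, 3), function(v) array(v, c(1, 1, 1)))
  B <- lapply(c(4, 5, 6), function(v) array(v, c(1, 1, 1)))
  vs <- voxelwise_ttest(A, B, mask)
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(vs$t[1, 1, 1], unname(oracle$statistic))
  expect_equal(vs$p[1, 1, 1], oracle$p.value)
  d_oracle <- (2 - 5) / 1  # pooled SD = 1
  expect_equal(vs$d[1, 1, 1], d_oracle)

  # identical groups: p = 1, empty z map
  null <- voxelwise_ttest(A, A, mask)
  expect_equal(null$p[1, 1, 1], 1)
  expect_equal(null$z[1, 1, 1], 0)

  # constant maps: zero pooled variance is flagged and set to p = 1
  C <- replicate(3, array(3, c(1, 1, 1)), simplify = FALSE)
  expect_warning(flatv <- voxelwise_ttest(C, C, mask), "zero pooled variance")
  expect_equal(flatv$p[1, 1, 1], 1)

  # invariants on a random multi-voxel problem
  set.seed(23)
  d3 <- c(5, 4, 3)
  mk <- function() array(rnorm(prod(d3)), d3)
  ga <- replicate(6, mk(), simplify = FALSE)
  gb <- replicate(7, mk(), simplify = FALSE)
  m <- array(TRUE, d3)
  vs2 <- voxelwise_ttest(ga, gb, m)
  expect_true(all(vs2$q >= vs2$p - 1e-12))
  expect_true(all((vs2$z != 0) == (vs2$q <= 0.05)))
  expect_true(all(vs2$d_class %in% c("moderate", "large", "very_large")))
  expect_equal(as.integer(table(d_class(c(0.5, -0.79, 0.8, 1.2, -1.21, 3)))[
    c("moderate", "large", "very_large")]), c(2L, 2L, 2L))
})

test_that("the VOI table samples regional binding with lesion flags", {
  pl <- noiseless_pipeline()
  ph <- pl$phantom
  subjects <- data.frame(id = "S01", group = "anoxic", genotype = "HAB",
                         outcome = "unfavourable", crs_r = 4)
  expect_length(default_voi_list(), 14)
  tab <- voi_table(list(S01 = pl$quant$map), ph$labels, subjects = subjects)
  expect_equal(nrow(tab), 14)
  tr <- ph$truth
  for (r in c("thalamus", "precentral")) {
    expect_equal(tab$bp[tab$voi == r],
                 mean(pl$quant$map$bp[region_mask(ph$labels, r)]),
                 tolerance = 1e-12)
    expect_lt(abs(tab$bp[tab$voi == r] - tr$bp[tr$region == r]), 0.02)
  }
  expect_false(any(tab$excluded))

  lesion <- region_mask(ph$labels, "thalamus")
  tab2 <- voi_table(list(S01 = pl$quant$map), ph$labels, subjects = subjects,
                    lesion_masks = list(S01 = lesion))
  expect_true(tab2$excluded[tab2$voi == "thalamus"])
  expect_equal(sum(tab2$excluded), 1)

  expect_error(voi_table(list(S01 = pl$quant$map), ph$labels,
                         voi_list = c("thalamus", "amygdala"),
                         subjects = subjects),
               "amygdala")
})

test_that("two-way ANOVA matches hand-computed sums of squares on a balanced design", {
  # 2 x 2 balanced, 3 replicates per cell
  cells <- expand.grid(g = c("a", "b"), v = c("x", "y"))
  mu <- c(10, 12, 11, 16)
  set.seed(41)
  tab <- do.call(rbind, lapply(1:4, function(i)
    data.frame(group = cells$g[i], voi = cells$v[i],
               bp = mu[i] + c(-0.5, 0, 0.5))))
  res <- two_way_anova(tab, covariate = NULL)

  # closed-form balanced two-way ANOVA
  n <- 3; gm <- mean(tab$bp)
  mg <- tapply(tab$bp, tab$group, mean)
  mv <- tapply(tab$bp, tab$voi, mean)
  mc <- tapply(tab$bp, interaction(tab$group, tab$voi), mean)
  ss_g <- 2 * n * sum((mg - gm)^2)
  ss_v <- 2 * n * sum((mv - gm)^2)
  ss_i <- n * sum((mc - gm)^2) - ss_g - ss_v
  ss_e <- sum((tab$bp - mc[interaction(tab$group, tab$voi)])^2)
  f_g <- (ss_g / 1) / (ss_e / 8)
  f_v <- (ss_v / 1) / (ss_e / 8)
  f_i <- (ss_i / 1) / (ss_e / 8)
  expect_equal(res$F[res$term == "group"], f_g)
  expect_equal(res$F[res$term == "voi"], f_v)
  expect_equal(res$F[res$term == "group:voi"], f_i)

  # constant response collapses to F = 0, p = 1
  tab0 <- tab; tab0$bp <- 5
  res0 <- two_way_anova(tab0, covariate = NULL)
  expect_true(all(res0$F == 0) && all(res0$p == 1))

  tab1 <- tab; tab1$group <- "a"
  expect_error(two_way_anova(tab1, covariate = NULL), "fewer than 2")
})

test_that("Tukey HSD reduces to the pooled t-test for two groups and matches ptukey", {
  set.seed(43)
  two <- data.frame(group = rep(c("a", "b"), each = 6),
                    bp = c(rnorm(6, 1), rnorm(6, 1.6)))
  tk <- tukey_hsd(two)
  tt <- t.test(bp ~ group, data = two, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)

  # identical group means: nothing to detect
  flat <- data.frame(group = rep(c("a", "b", "c"), each = 4),
                     bp = rep(c(1, 2, 3, 4), 3))
  tk0 <- tukey_hsd(flat)
  expect_true(all(tk0$p_adj > 0.99))

  # 3-group case against a direct studentized-range computation
  three <- data.frame(group = rep(c("a", "b", "c"), each = 5),
                      bp = c(rnorm(5, 0), rnorm(5, 0.8), rnorm(5, 2)))
  tk3 <- tukey_hsd(three)
  mse <- summary(aov(bp ~ group, data = three))[[1]]$`Mean Sq`[2]
  mns <- tapply(three$bp, three$group, mean)
  for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
    qstat <- abs(mns[pair[1]] - mns[pair[2]]) / sqrt(mse / 5)
    p_or <- 1 - ptukey(qstat, nmeans = 3, df = 12)
    got <- tk3$p_adj[tk3$comparison == paste(pair, collapse = "-")]
    expect_equal(got, unname(p_or), tolerance = 1e-8)
  }
  # adjusted p never below the unadjusted pairwise p for k >= 3
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    sub <- three[three$group %in% pair, ]
    p_raw <- t.test(bp ~ group, data = sub, var.equal = TRUE)$p.value
    got <- tk3$p_adj[tk3$comparison %in% c(paste(pair, collapse = "-"),
                                           paste(rev(pair), collapse = "-"))]
    expect_gt(got, p_raw * 0.999)
  }

  expect_error(tukey_hsd(data.frame(group = "a", bp = 1)), "2 levels")
})

test_that("Spearman correlation uses mid-ranks and exact small-sample p-values", {
  expect_equal(spearman_cor(1:6, 6:1)$rho, -1)

  # hand rank computation: d = (-1, 1, -1, 1, 0), sum d^2 = 4,
  # rho = 1 - 6*4/(5*24) = 0.8
  s <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 0.8)
  expect_equal(s$rho, cor(1:5, c(2, 1, 4, 3, 5), method = "spearman"))

  # exact p at n = 5 against the independent implementation in stats
  set.seed(47)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    got <- spearman_cor(x, y)
    orc <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$rho, unname(orc$estimate))
    expect_equal(got$p, orc$p.value, tolerance = 1e-10)
  }

  # t-approximation route for larger n
  x <- rnorm(20); y <- x + rnorm(20)
  got <- spearman_cor(x, y)
  orc <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(got$p, orc$p.value, tolerance = 1e-10)

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "length >= 3")
})

test_that("descriptive tests route by type and normality", {
  # 2x2 diagonal table: chi-square without continuity correction is 20
  tab <- data.frame(group = rep(c("a", "b"), each = 10),
                    cat = rep(c("x", "y"), each = 10))
  res <- descriptive_tests(tab, vars = "cat")
  expect_equal(res$test, "chi-square")
  expect_equal(res$statistic, 20)

  # normal data routes to ANOVA, heavy-tailed data to Kruskal-Wallis
  set.seed(53)
  norm_tab <- data.frame(group = rep(c("a", "b"), each = 30),
                         val = rnorm(60))
  r1 <- descriptive_tests(norm_tab, vars = "val")
  expect_true(r1$test %in% c("anova", "kruskal-wallis"))

  skew_tab <- data.frame(group = rep(c("a", "b"), each = 40),
                         val = exp(rnorm(80, 0, 2)))
  r2 <- descriptive_tests(skew_tab, vars = "val")
  expect_equal(r2$test, "kruskal-wallis")
  kw <- kruskal.test(skew_tab$val, factor(skew_tab$group))
  expect_equal(r2$p, kw$p.value)

  # calibration: under identical distributions the tests rarely reject
  rejections <- 0
  for (i in 1:40) {
    d <- data.frame(group = rep(c("a", "b"), each = 15), val = rnorm(30))
    r <- descriptive_tests(d, vars = "val")
    if (r$p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / 40, 0.2)

  expect_error(descriptive_tests(data.frame(group = "a", val = 1)), "levels")
})
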