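test_that("two-way ANOVA matches the brute-force decomposition on a hand 2x2 dataset", {
  # 2x2 with 2 observations/cell, hand-pickable integers
  y <- c(3, 5, 8, 10, 6, 8, 15, 17)
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(rep(c("b1", "b2"), each = 2), 2)
  tab <- two_way_anova(y, a, b)
  # oracle: explicit group-mean sums
  g <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mc <- tapply(y, paste(a, b), mean)
  ss_a <- 4 * sum((ma - g)^2)
  ss_b <- 4 * sum((mb - g)^2)
  ss_cells <- 2 * sum((mc - g)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((y - mc[paste(a, b)])^2)
  expect_lt(max(abs(tab$sumsq - c(ss_a, ss_b, ss_ab, ss_res))), 1e-9)
  expect_equal(sum(tab$sumsq), sum((y - g)^2), tolerance = 1e-12)
  expect_equal(sum(tab$df), length(y) - 1)
})

test_that("two-way ANOVA agrees with aov and handles degenerate/invalid input", {
  set.seed(8)
  a <- gl(3, 10); b <- gl(2, 5, 30)
  y <- rnorm(30) + as.numeric(a) * 0.4 + as.numeric(b) * 0.7
  tab <- two_way_anova(y, a, b)
  fit <- anova(aov(y ~ a * b))
  expect_equal(tab$sumsq, fit$`Sum Sq`, tolerance = 1e-10)
  expect_equal(tab$p_value[1:3], fit$`Pr(>F)`[1:3], tolerance = 1e-10)

  yc <- rep(4, 12)
  tc <- two_way_anova(yc, gl(2, 6), gl(2, 3, 12))
  expect_true(all(tc$statistic[1:3] == 0))
  expect_true(all(tc$p_value[1:3] == 1))

  expect_error(two_way_anova(y[-1], a[-1], b[-1]), "unbalanced")
  expect_error(two_way_anova(y[1:6], gl(3, 2), gl(2, 1, 6)), ">= 2")
})

test_that("studentized-range integration matches the reference distribution", {
  for (cs in list(c(0.8, 2, 4), c(2.5, 3, 10), c(3.2, 6, 24),
                  c(4.5, 4, 12), c(5.5, 5, 40))) {
    expect_equal(ptukey_sr(cs[1], cs[2], cs[3]),
                 ptukey(cs[1], cs[2], cs[3]), tolerance = 1e-6)
  }
  expect_equal(ptukey_sr(3.1, 4, Inf), ptukey(3.1, 4, Inf),
               tolerance = 1e-6)
})

test_that("Tukey HSD: k=2 reduces to the pooled t-test; identical means give p=1", {
  set.seed(10)
  y <- rnorm(14) + rep(c(0, 1), each = 7)
  g <- rep(c("g1", "g2"), each = 7)
  tk <- tukey_hsd(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)

  y2 <- rep(c(5, 6, 7), 3)
  g2 <- rep(c("x", "y", "z"), each = 3)
  tk2 <- tukey_hsd(y2, g2)
  expect_true(all(tk2$p_adj == 1))

  # against TukeyHSD on 3 groups
  set.seed(12)
  y3 <- rnorm(15) + rep(c(0, 0.5, 2), each = 5)
  g3 <- gl(3, 5)
  tk3 <- tukey_hsd(y3, g3)
  ref <- TukeyHSD(aov(y3 ~ g3))$g3
  expect_equal(sort(tk3$p_adj), sort(unname(ref[, "p adj"])),
               tolerance = 1e-6)
  expect_error(tukey_hsd(rep(1, 6), gl(3, 2)), "degenerate")
})

test_that("gatekeeping emits the comparison families the ANOVA supports", {
  set.seed(13)
  n <- 5
  a <- rep(c("ctrl", "ag", "antag"), each = 2 * n)
  b <- rep(rep(c("veh", "rot"), each = n), 3)
  # nothing significant
  y0 <- rnorm(30)
  ph0 <- gatekept_posthoc(two_way_anova(y0, a, b), alpha = 0.05)
  if (length(ph0$comparisons) == 0) expect_match(ph0$note, "no significant")
  # strong A main effect only
  ya <- rnorm(30, sd = 0.4) + c(ctrl = 0, ag = 3, antag = 6)[a]
  pha <- gatekept_posthoc(two_way_anova(ya, a, b, c("A", "B")),
                          alpha = 0.05)
  expect_false(pha$interaction_significant)
  expect_true("A" %in% names(pha$comparisons))
  expect_false("B" %in% names(pha$comparisons))
  expect_equal(nrow(pha$comparisons$A), 3)    # marginal means, 3 levels
  # crossover interaction
  yi <- rnorm(30, sd = 0.4) +
    ifelse(a == "ag", ifelse(b == "rot", 3, -3), 0)
  phi <- gatekept_posthoc(two_way_anova(yi, a, b), alpha = 0.05)
  expect_true(phi$interaction_significant)
  expect_true("cells" %in% names(phi$comparisons))
  expect_equal(nrow(phi$comparisons$cells), choose(6, 2))
})

test_that("students_t matches the pooled formula and flags degeneracy", {
  st <- students_t(c(1, 2, 3), c(4, 5, 6))
  # hand oracle: pooled sd = 1, se = sqrt(2/3)
  expect_equal(st$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$df, 4)
  expect_equal(st$p_value, 2 * pt(-abs(st$t), 4), tolerance = 1e-12)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(st$p_value, ref$p.value, tolerance = 1e-12)

  same <- students_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
  degen <- students_t(c(2, 2), c(3, 3))
  expect_equal(degen$p_value, 0)
  expect_equal(degen$flag, "zero_variance")

  w <- students_t(c(1, 2, 3, 9), c(4, 5, 6), welch = TRUE)
  refw <- t.test(c(1, 2, 3, 9), c(4, 5, 6))
  expect_equal(w$p_value, refw$p.value, tolerance = 1e-12)
})

test_that("pearson_matrix matches closed-form sums and flags degenerate pairs", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2, 1, 5, 9, 12)
  df <- data.frame(x = x, y = y)
  pm <- pearson_matrix(df)
  # closed-form product-moment sums oracle
  n <- 5
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(pm$r["x", "y"], r_oracle, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(pm$p["x", "y"], ct$p.value, tolerance = 1e-12)

  exact <- pearson_matrix(data.frame(x = x, y = 2 * x + 1, z = -x))
  expect_equal(exact$r["x", "y"], 1)
  expect_equal(exact$r["x", "z"], -1)
  expect_true(all(diag(exact$r) == 1))
  expect_equal(exact$r, t(exact$r))

  fl <- pearson_matrix(data.frame(x = x, k = rep(3, 5)))
  expect_true(is.na(fl$r["x", "k"]))
  expect_match(fl$flags, "constant")
  # pairwise-complete handling
  xm <- c(x, NA); ym <- c(y, 4); zm <- c(NA, NA, 1, 2, 3, 4)
  pmna <- pearson_matrix(data.frame(x = xm, y = ym, z = zm))
  expect_equal(pmna$n["x", "y"], 5)
  expect_equal(pmna$r["x", "y"], r_oracle, tolerance = 1e-12)
})
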