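test_that("routing follows Shapiro-Wilk and Bartlett on residuals", {
  set.seed(181)
  # heavily right-skewed groups: nonparametric
  x <- c(rlnorm(20, 0, 1.5), rlnorm(20, 0.5, 1.5), rlnorm(20, 1, 1.5))
  g <- rep(c("a", "b", "c"), each = 20)
  expect_equal(route_test(x, g)$decision, "nonparametric")

  # Gaussian equal-variance groups route parametric in ~(1-alpha)^2 of
  # seeds (theoretical 0.9025); assert with finite-sample slack
  hits <- 0
  for (s in 1:200) {
    set.seed(s)
    x <- rnorm(60)
    r <- route_test(x, g)
    if (r$decision == "parametric") hits <- hits + 1
  }
  expect_gte(hits / 200, 0.85)

  # identical routing to a direct reimplementation on fixed vectors
  set.seed(191)
  for (i in 1:5) {
    x <- switch(i, rnorm(30), rlnorm(30), rt(30, 2), runif(30),
                rnorm(30, sd = rep(c(1, 5, 1), each = 10)))
    gg <- factor(rep(c("a", "b", "c"), 10))
    r <- route_test(x, gg)
    res <- x - tapply(x, gg, mean)[gg]
    want <- shapiro.test(res)$p.value > 0.05 &&
      bartlett.test(x, gg)$p.value > 0.05
    expect_equal(r$decision == "parametric", want)
  }
  expect_error(route_test(1:5, c("a", "a", "a", "b", "b")), "fewer than 3")
})

test_that("Kruskal-Wallis H matches the hand rank computation", {
  x <- 1:9
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(x, g)
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))

  # invariance under strictly monotone transforms
  expect_equal(kruskal_wallis(exp(x), g)$H, kw$H)
  expect_equal(kruskal_wallis(rank(x)^3, g)$H, kw$H)

  # exchangeability: permuting labels within the pooled sample leaves
  # the null distribution unchanged (check statistic recomputes)
  set.seed(201)
  xp <- sample(x)
  expect_equal(kruskal_wallis(xp, g)$H,
               kruskal.test(xp, factor(g))$statistic[[1]])

  expect_true(kruskal_wallis(rep(2, 9), g)$degenerate)
})

test_that("Dunn z matches the explicit pooled-rank oracle", {
  # two identical groups: their pair has z = 0, p = 1
  x <- c(1, 2, 3, 1, 2, 3, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_posthoc(x, g)
  ab <- d[d$group1 == "a" & d$group2 == "b", ]
  expect_equal(ab$z, 0)
  expect_equal(ab$p, 1)

  # small case without ties against explicit rank arithmetic
  x <- c(3, 1, 4, 10, 12, 9, 22, 18, 25)
  d <- dunn_posthoc(x, g)
  r <- rank(x)
  N <- 9
  se <- sqrt((N * (N + 1) / 12) * (1 / 3 + 1 / 3))
  for (k in seq_len(nrow(d))) {
    i <- d$group1[k]; j <- d$group2[k]
    z_oracle <- (mean(r[g == i]) - mean(r[g == j])) / se
    expect_equal(d$z[k], z_oracle)
    expect_equal(d$p[k], 2 * pnorm(-abs(z_oracle)))
  }

  # tie correction: oracle with explicit tie term
  x <- c(5, 5, 2, 7, 7, 7, 1, 3, 5)
  d <- dunn_posthoc(x, g)
  r <- rank(x)
  ties <- table(x)
  tt <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - tt) * (2 / 3))
  expect_equal(d$z[1], (mean(r[g == "a"]) - mean(r[g == "b"])) / se)

  # adjusted p never below unadjusted
  dh <- dunn_posthoc(x, g, adjustment = "holm")
  expect_true(all(dh$p_adj >= dh$p - 1e-12))
  expect_equal(dh$p, d$p)
})

test_that("ANOVA F equals t-squared for two groups and the SS oracle", {
  set.seed(211)
  x <- c(rnorm(12, 0), rnorm(15, 1))
  g <- rep(c("a", "b"), c(12, 15))
  at <- anova_tukey(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(at$F, unname(tt$statistic)^2)
  expect_equal(at$p, tt$p.value)

  x <- c(2, 4, 3, 8, 9, 7, 4, 5, 6)
  g3 <- rep(c("a", "b", "c"), each = 3)
  at <- anova_tukey(x, g3)
  gm <- tapply(x, g3, mean)
  ssb <- sum(3 * (gm - mean(x))^2)
  ssw <- sum((x - gm[g3])^2)
  expect_equal(at$F, (ssb / 2) / (ssw / 6))
  expect_equal(nrow(at$pairwise), 3)

  expect_true(anova_tukey(rep(c(1, 2, 3), each = 3), g3)$degenerate)
})

test_that("significance letters mirror the pairwise threshold", {
  pw <- data.frame(group1 = c("F", "F", "M"), group2 = c("M", "R", "R"),
                   p_adj = c(0.2, 0.01, 0.3))
  lt <- significance_letters(pw, alpha = 0.05)
  expect_equal(lt$F, "R")
  expect_equal(lt$R, "F")
  expect_equal(lt$M, character(0))
  lt0 <- significance_letters(transform(pw, p_adj = 0.9))
  expect_true(all(lengths(lt0) == 0))

  set.seed(221)
  g <- c("F", "M", "H", "R", "N")
  pairs <- t(combn(g, 2))
  pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                   p_adj = runif(10))
  lt <- significance_letters(pw, alpha = 0.5)
  for (k in 1:10) {
    sig <- pw$p_adj[k] < 0.5
    expect_equal(pw$group2[k] %in% lt[[pw$group1[k]]], sig)
    expect_equal(pw$group1[k] %in% lt[[pw$group2[k]]], sig)
  }
})

test_that("Spearman correlogram matches rank-then-Pearson", {
  agg <- data.frame(legend_id = 1:8, group = "M")
  set.seed(231)
  base <- sort(runif(8))
  agg$regulating_capacity <- base
  agg$regulating_flow <- base^3          # monotone: rho = 1
  agg$provisioning_capacity <- -base     # decreasing: rho = -1
  agg$provisioning_flow <- runif(8)
  agg$cultural_capacity <- c(1, 1, 2, 3, 4, 5, 6, 7)  # one tie
  agg$cultural_flow <- runif(8)
  co <- spearman_correlogram(agg)
  expect_equal(co$rho["regulating_capacity", "regulating_flow"], 1)
  expect_equal(co$rho["regulating_capacity", "provisioning_capacity"], -1)
  expect_equal(co$rho, t(co$rho))
  expect_true(all(diag(co$rho) == 1))
  # tie-handling via average ranks: rank then Pearson
  expect_equal(
    co$rho["cultural_capacity", "provisioning_flow"],
    cor(rank(agg$cultural_capacity), rank(agg$provisioning_flow)))
  expect_error(spearman_correlogram(agg[1:3, ]), "at least 4")
})

test_that("routed workflow composes the right branches", {
  set.seed(241)
  x <- c(rlnorm(10, 0, 1), rlnorm(10, 1.5, 1), rlnorm(10, 0.5, 1))
  g <- rep(c("a", "b", "c"), each = 10)
  res <- compare_groups(x, g)
  expect_equal(res$routing$decision, "nonparametric")
  expect_equal(res$omnibus$statistic, "H")
  expect_equal(nrow(res$pairwise), 3)
  # Dunn and KW share the pooled ranking: z sign agrees with the rank
  # mean difference computed independently
  r <- rank(x)
  for (k in seq_len(nrow(res$pairwise))) {
    dm <- mean(r[g == res$pairwise$group1[k]]) -
      mean(r[g == res$pairwise$group2[k]])
    expect_equal(sign(res$pairwise$z[k]), sign(dm))
  }

  set.seed(251)
  x <- rnorm(60, rep(c(0, 2), each = 30))
  g <- rep(c("a", "b"), each = 30)
  res <- compare_groups(x, g)
  expect_equal(res$routing$decision, "parametric")
  expect_equal(res$omnibus$statistic, "F")
})
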