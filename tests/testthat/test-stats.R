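make_table <- function(seed = 1) generate_group_tables(seed = seed)

test_that("descriptives match the two-pass mean/SD formulas", {
  t3 <- data.frame(group = rep(c("a", "b"), each = 3),
                   x = c(1, 2, 3, 5, 5, 5))
  d <- descriptives(t3, "x")
  expect_equal(d$mean[d$group == "a"], 2)
  expect_equal(d$sd[d$group == "a"], 1)
  expect_equal(d$sd[d$group == "b"], 0)

  tab <- make_table(3)
  d2 <- descriptives(tab, group = "group")
  # independent two-pass oracle
  for (i in sample(nrow(d2), 8)) {
    v <- tab[[d2$variable[i]]][tab$group == d2$group[i]]
    expect_equal(d2$mean[i], sum(v) / length(v))
    expect_equal(d2$sd[i], sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
  }
  expect_error(descriptives(data.frame(group = c("a", "a", "b"),
                                       x = c(1, 2, 3)), "x"),
               "at least 2")
})

test_that("ANOVA with Tukey comparisons behaves at the extremes", {
  same <- data.frame(group = rep(c("a", "b"), each = 10), x = rep(1:10, 2))
  res <- anova_pairwise(same, "x")
  expect_gt(res$anova$p, 0.95)

  set.seed(5)
  far <- data.frame(group = rep(c("a", "b"), each = 20),
                    x = c(rnorm(20), rnorm(20, 100)))
  res2 <- anova_pairwise(far, "x")
  expect_lt(res2$pairwise$p_adj, 1e-4)
  expect_equal(res2$pairwise$code, "***")

  flat <- data.frame(group = rep(c("a", "b"), each = 5), x = rep(3, 10))
  expect_error(anova_pairwise(flat, "x"), "degenerate")

  tab <- make_table(7)
  res4 <- anova_pairwise(tab, "da")
  expect_equal(nrow(res4$pairwise), choose(4, 2))
  expect_true(all(res4$pairwise$p_adj >= 0 & res4$pairwise$p_adj <= 1))
})

test_that("significance codes follow the printed thresholds", {
  expect_equal(sig_codes(c(5e-4, 5e-3, 0.03, 0.07, 0.5)),
               c("***", "**", "*", ".", "ns"))
})

test_that("Pearson correlations match the covariance-ratio formula", {
  x <- 1:20
  perfect <- data.frame(x = x, y = 2 * x + 1)
  cm <- correlation_matrix(perfect)
  expect_equal(cm$r["x", "y"], 1)

  set.seed(19)
  noise <- data.frame(x = rnorm(2000), y = rnorm(2000))
  expect_lt(abs(correlation_matrix(noise)$r["x", "y"]), 0.06)

  set.seed(23)
  tab <- as.data.frame(matrix(rnorm(40), 10))
  cm2 <- correlation_matrix(tab)
  for (i in 1:3) for (j in (i + 1):4) {
    a <- tab[[i]]; b <- tab[[j]]
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(cm2$r[i, j], r_oracle)
    expect_equal(cm2$p[i, j], stats::cor.test(a, b)$p.value)
  }

  const <- data.frame(x = rnorm(10), y = rep(1, 10))
  expect_warning(cmc <- correlation_matrix(const), "zero-variance")
  expect_true(is.na(cmc$r["x", "y"]))
})

test_that("Wilks lambda matches stats::manova and the eigenvalue identity", {
  tab <- make_table(11)
  mw <- manova_wilks(tab, group = "group")
  ref <- summary(stats::manova(
    cbind(da, db, dc, bl, bs, ba) ~ group, tab), test = "Wilks")$stats
  expect_equal(mw$lambda, unname(ref[1, "Wilks"]), tolerance = 1e-8)
  expect_equal(mw$F, unname(ref[1, "approx F"]), tolerance = 1e-6)
  expect_equal(mw$p.value, unname(ref[1, "Pr(>F)"]), tolerance = 1e-8)

  fit <- cda(group ~ da + db + dc + bl + bs + ba, tab)
  expect_equal(mw$lambda, prod(1 / (1 + fit$eigenvalues)), tolerance = 1e-10)

  # labels permuted: no between-group structure, lambda near 1
  set.seed(42)
  perm <- tab; perm$group <- sample(perm$group)
  expect_gt(manova_wilks(perm, group = "group")$lambda, 0.8)

  # two groups, one variable: Wilks lambda reduces to SSW / SST and the
  # Rao F equals the one-way ANOVA F
  two <- tab[tab$group %in% c("amazonica_AF", "obtusa"), c("group", "da")]
  two$group <- droplevels(factor(two$group))
  mw2 <- manova_wilks(two, "da", "group")
  a2 <- anova_pairwise(two, "da")
  expect_equal(mw2$F, a2$anova$F, tolerance = 1e-8)
  expect_equal(mw2$lambda, 1 / (1 + a2$anova$F * (4 - 3) / (nrow(two) - 2)),
               tolerance = 1e-8)
})

test_that("CDA satisfies its algebraic identities on random tables", {
  for (sd in 1:5) {
    tab <- make_table(sd)
    fit <- cda(group ~ da + db + dc + bl + bs + ba, tab)
    expect_equal(length(fit$eigenvalues), 3L)   # min(g-1, p)
    # eigenvalues match a direct eigen solve of W^-1 B
    lam_ref <- sort(Re(eigen(solve(fit$W) %*% fit$B)$values),
                    decreasing = TRUE)[1:3]
    expect_equal(fit$eigenvalues, lam_ref, tolerance = 1e-8)
    expect_equal(fit$canonical_correlation,
                 sqrt(fit$eigenvalues / (1 + fit$eigenvalues)),
                 tolerance = 1e-10)
    expect_equal(fit$wilks[1], prod(1 / (1 + fit$eigenvalues)),
                 tolerance = 1e-10)
    expect_equal(sum(fit$proportion), 1, tolerance = 1e-10)
    # canonical variables have unit pooled within-group variance
    n <- nrow(tab); g <- 4
    wv <- diag(t(fit$coef) %*% fit$W %*% fit$coef) / (n - g)
    expect_equal(unname(wv), rep(1, 3), tolerance = 1e-10)
  }
})

test_that("two-group CDA is collinear with the Fisher discriminant", {
  tab <- make_table(2)
  two <- tab[tab$group %in% c("compacta", "obtusa"), ]
  two$group <- droplevels(factor(two$group))
  fit <- cda(group ~ da + db + dc + bl + bs + ba, two)
  expect_equal(ncol(fit$coef), 1L)
  sm <- branchmorph:::scatter_matrices(
    as.matrix(two[c("da", "db", "dc", "bl", "bs", "ba")]), two$group)
  mdiff <- colMeans(two[two$group == "compacta",
                        c("da", "db", "dc", "bl", "bs", "ba")]) -
           colMeans(two[two$group == "obtusa",
                        c("da", "db", "dc", "bl", "bs", "ba")])
  fisher <- solve(sm$W, mdiff)
  cosang <- abs(sum(fit$coef[, 1] * fisher)) /
    sqrt(sum(fit$coef[, 1]^2) * sum(fisher^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("CDA coefficients agree with lda up to sign and scale", {
  skip_if_not_installed("MASS")
  tab <- make_table(6)
  fit <- cda(group ~ da + db + dc + bl + bs + ba, tab)
  ld <- MASS::lda(group ~ da + db + dc + bl + bs + ba, tab)
  for (j in 1:3) {
    cosang <- abs(sum(fit$coef[, j] * ld$scaling[, j])) /
      sqrt(sum(fit$coef[, j]^2) * sum(ld$scaling[, j]^2))
    expect_equal(cosang, 1, tolerance = 1e-6)
  }
})

test_that("classification is sane: separation, chance, counting identity", {
  set.seed(8)
  apart <- data.frame(group = rep(c("a", "b"), each = 25),
                      x = c(rnorm(25), rnorm(25, 10)),
                      y = c(rnorm(25), rnorm(25, -10)))
  fit <- cda(group ~ x + y, apart)
  cls <- cda_classify(fit)
  expect_equal(cls$correct_rate, 1)

  tab <- make_table(4)
  fit4 <- cda(group ~ da + db + dc + bl + bs + ba, tab)
  cls4 <- cda_classify(fit4)
  expect_equal(unname(rowSums(cls4$matrix)), unname(c(table(tab$group))))
  expect_gt(cls4$correct_rate, 0.25)  # far better than 4-group chance

  # permuted labels: chance-level accuracy on held-out data (resubstitution
  # on permuted labels sits a few points above chance by optimism, so the
  # chance check is out-of-sample)
  set.seed(77)
  fresh <- generate_group_tables(seed = 1234)
  rates <- replicate(40, {
    perm <- tab
    perm$group <- sample(perm$group)
    fit_p <- cda(group ~ da + db + dc + bl + bs + ba, perm)
    cda_classify(fit_p, fresh)$correct_rate
  })
  expect_lt(abs(mean(rates) - 0.25), 0.05)

  # affine rescaling of all variables leaves assignments unchanged
  sc <- tab
  for (v in c("da", "db", "dc", "bl", "bs", "ba"))
    sc[[v]] <- 3.7 * sc[[v]] + 2
  fit_sc <- cda(group ~ da + db + dc + bl + bs + ba, sc)
  expect_identical(predict(fit4)$class, predict(fit_sc)$class)

  expect_error(predict(fit4, data.frame(da = 1)), "lacks model variables")
})

test_that("cda guards its preconditions", {
  tab <- make_table(9)
  expect_error(cda(group ~ da, tab[tab$group == "obtusa", ]), "two groups")
  tiny <- tab[c(1:4, 38:41), ]
  expect_error(cda(group ~ da + db + dc + bl + bs + ba, tiny), "n - g > p")
  # collinear variables: singular within matrix
  col <- tab; col$dup <- col$da
  expect_error(cda(group ~ da + dup, col), "singular|collinear")
})

test_that("group table generator honours its parameters", {
  empty <- generate_group_tables(list(a = list(
    n = 0, mean = c(x = 1), sd = c(x = 1))), seed = 1)
  expect_equal(nrow(empty), 0L)

  tight <- generate_group_tables(list(a = list(
    n = 10, mean = c(x = 5, y = -2), sd = c(x = 1e-9, y = 1e-9))), seed = 1)
  expect_equal(tight$x, rep(5, 10), tolerance = 1e-6)
  expect_equal(tight$y, rep(-2, 10), tolerance = 1e-6)

  tab <- generate_group_tables(seed = 1)
  expect_equal(nrow(tab), 37 + 26 + 25 + 50)
  gp <- example_group_params()
  for (g in names(gp)) for (v in c("da", "bl", "ba")) {
    se <- gp[[g]]$sd[[v]] / sqrt(gp[[g]]$n)
    expect_lt(abs(mean(tab[[v]][tab$group == g]) - gp[[g]]$mean[[v]]), 3.5 * se)
  }
  # deterministic under a fixed seed
  expect_identical(tab, generate_group_tables(seed = 1))
  expect_false(identical(tab$da, generate_group_tables(seed = 2)$da))

  # optional correlation structure
  cor_m <- matrix(0.9, 2, 2); diag(cor_m) <- 1
  tc <- generate_group_tables(list(a = list(
    n = 400, mean = c(x = 0, y = 0), sd = c(x = 1, y = 1))),
    seed = 3, correlation = cor_m)
  expect_gt(stats::cor(tc$x, tc$y), 0.8)
})
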