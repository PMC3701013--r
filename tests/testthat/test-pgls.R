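sim_xy <- function(tree, slope = -0.068, intercept = -0.39,
                   sigma2_x = 0.05, sigma2_res = 0.002, seed = 1) {
  set.seed(seed)
  x <- calcelong:::.bm_draw(tree, sigma2_x, z_root = 6)
  eps <- calcelong:::.bm_draw(tree, sigma2_res)
  data.frame(species = names(x), x = as.numeric(x),
             y = slope * as.numeric(x) + intercept + as.numeric(eps))
}

test_that("PGLS with lambda 0 on an ultrametric tree equals OLS", {
  tr <- ultra_tree(16, depth = 10)
  d <- sim_xy(tr, seed = 5)
  f <- pgls_fit(y ~ x, d, tr, lambda = 0)
  o <- ols_fit(d$x, d$y)
  expect_lt(max(abs(coef(f) - c(o$intercept, o$slope))), 1e-8)
  expect_lt(abs(f$SE[["x"]] - o$slope_SE), 1e-8)

  st <- star_tree(12, depth = 2)
  d2 <- sim_xy(st, seed = 6)
  f2 <- pgls_fit(y ~ x, d2, st, lambda = 1)
  o2 <- ols_fit(d2$x, d2$y)
  expect_lt(max(abs(coef(f2) - c(o2$intercept, o2$slope))), 1e-8)
})

test_that("PGLS coefficients equal the dense GLS oracle on a fixed 6-tip tree", {
  tr <- read_newick("(((A:1,B:1):2,(C:2,D:1):1):1,(E:2,F:2):2);")
  d <- data.frame(species = c("A", "B", "C", "D", "E", "F"),
                  x = c(1.2, 0.8, -0.4, 0.1, 2.0, -1.1),
                  y = c(0.9, 1.1, -0.2, 0.3, 1.7, -0.8))
  for (lam in c(0.3, 0.7, 1)) {
    f <- pgls_fit(y ~ x, d, tr, lambda = lam)
    V <- apply_scaling(phylo_covariance(tr), scaling_params(lambda = lam))
    V <- V[d$species, d$species]
    beta <- gls_oracle(cbind(1, d$x), d$y, V)
    expect_lt(max(abs(coef(f) - beta)), 1e-8)
  }
})

test_that("PGLS agrees with nlme gls + corPagel cross-check", {
  skip_if_not_installed("nlme")
  tr <- ultra_tree(16, depth = 10)
  d <- sim_xy(tr, seed = 9)
  rownames(d) <- d$species
  f <- pgls_fit(y ~ x, d, tr, lambda = 0.6)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corPagel(0.6, tr, fixed = TRUE,
                                             form = ~species))
  expect_lt(max(abs(coef(f) - coef(g))), 1e-6)
  fml <- pgls_fit(y ~ x, d, tr, lambda = "ML")
  gml <- nlme::gls(y ~ x, data = d, method = "ML",
                   correlation = ape::corPagel(0.6, tr, form = ~species))
  lam_nlme <- unname(coef(gml$modelStruct$corStruct, unconstrained = FALSE))
  expect_lt(abs(fml$lambda - lam_nlme), 0.02)
})

test_that("ML lambda is near 1 for Brownian data and near 0 for iid noise", {
  set.seed(21)
  lam_bm <- lam_iid <- numeric(100)
  spec <- sim_spec(n_tips = 100, seed = 0)
  for (i in 1:100) {
    tr <- simulate_tree(spec, seed = i)
    x <- calcelong:::.bm_draw(tr, 0.05, z_root = 0)
    d <- data.frame(species = names(x), x = as.numeric(x))
    d$y <- -0.07 * d$x + as.numeric(calcelong:::.bm_draw(tr, 0.002))
    lam_bm[i] <- pgls_fit(y ~ x, d, tr)$lambda
    d$y <- -0.07 * d$x + rnorm(100, 0, 0.3)
    lam_iid[i] <- pgls_fit(y ~ x, d, tr)$lambda
  }
  expect_gt(median(lam_bm), 0.9)
  expect_lt(median(lam_iid), 0.1)
})

test_that("profile likelihood at the ML lambda dominates a fixed grid", {
  spec <- sim_spec(n_tips = 40, seed = 2)
  tr <- simulate_tree(spec)
  d <- sim_xy(tr, seed = 3)
  f <- pgls_fit(y ~ x, d, tr, lambda = "ML")
  for (lam in c(0, 0.5, 1))
    expect_gte(f$logL, pgls_fit(y ~ x, d, tr, lambda = lam)$logL - 1e-8)
})

test_that("species mismatches and degenerate inputs raise errors", {
  tr <- ultra_tree(8)
  d <- data.frame(species = c(tr$tip.label[1:7], "nosuch"),
                  x = rnorm(8), y = rnorm(8))
  expect_error(pgls_fit(y ~ x, d, tr), "nosuch")
  d2 <- data.frame(species = tr$tip.label[1:2], x = 1:2, y = 1:2)
  expect_error(pgls_fit(y ~ x, d2, tr), "at least 3")
})

test_that("sequential Dunn-Sidak thresholds and stopping rule are exact", {
  out <- sequential_dunn_sidak(c(0.001, 0.02, 0.04), alpha = 0.05)
  thr <- sort(out$threshold)
  expect_equal(thr[1], 1 - 0.95^(1 / 3))
  expect_lt(abs(thr[1] - 0.016952), 1e-6)
  expect_lt(abs(thr[2] - 0.025321), 1e-6)
  expect_equal(thr[3], 0.05)
  expect_equal(out$significant, c(TRUE, TRUE, TRUE))

  ## all three pass when each clears its step-down threshold
  expect_equal(sequential_dunn_sidak(c(0.02, 0.03, 0.001))$significant,
               c(TRUE, TRUE, TRUE))
  ## stop at first failure: 0.03 fails the second threshold (0.0253), so
  ## the larger 0.5 is never declared significant either
  out3 <- sequential_dunn_sidak(c(0.5, 0.03, 0.001))
  expect_equal(out3$significant, c(FALSE, FALSE, TRUE))
  out4 <- sequential_dunn_sidak(c(0.5, 0.018, 0.03))
  expect_equal(out4$significant, c(FALSE, FALSE, FALSE))

  ## k = 1 reduces to alpha
  expect_equal(sequential_dunn_sidak(0.04)$threshold, 0.05)
  expect_error(sequential_dunn_sidak(c(0.1, 1.2)), "0, 1")
  expect_error(sequential_dunn_sidak(0.1, alpha = 0), "alpha")
})

test_that("phylo ANOVA with lambda 0 equals textbook ANOVA and t-tests", {
  tr <- ultra_tree(16, depth = 1)
  set.seed(12)
  g <- rep(c("a", "b", "c"), c(6, 5, 5))
  y <- rnorm(16) + c(0, 0.5, 1)[match(g, c("a", "b", "c"))]
  names(y) <- tr$tip.label
  res <- phylo_anova(y, g, tr, lambda = 0)
  a <- anova(lm(y ~ factor(g)))
  expect_lt(abs(res$F - a$`F value`[1]), 1e-8)
  expect_lt(abs(res$MS - a$`Mean Sq`[2]), 1e-8)
  expect_lt(abs(res$p - a$`Pr(>F)`[1]), 1e-8)
  ## pairwise contrasts equal pooled-variance t-tests on the same model
  fit <- lm(y ~ factor(g))
  em <- c(a = coef(fit)[1], b = sum(coef(fit)[c(1, 2)]),
          c = sum(coef(fit)[c(1, 3)]))
  pw <- res$pairwise
  expect_lt(abs(pw$diff[pw$group1 == "a" & pw$group2 == "b"] -
                  (em[1] - em[2])), 1e-8)
})

test_that("identical trait values give a zero F statistic", {
  tr <- ultra_tree(8)
  y <- rep(1.5, 8); names(y) <- tr$tip.label
  g <- rep(c("a", "b"), each = 4)
  res <- phylo_anova(y, g, tr, lambda = 0)
  expect_equal(res$F, 0)
})

test_that("groups with fewer than two species are rejected", {
  tr <- ultra_tree(8)
  y <- rnorm(8); names(y) <- tr$tip.label
  expect_error(phylo_anova(y, c("a", rep("b", 7)), tr), "fewer than 2")
})

test_that("PGLS slope recovery: true slope covered by the 95% CI", {
  ## mirrors the all-euprimate elongation regression structure
  spec <- sim_spec(n_tips = 100, seed = 0)
  hits <- 0L
  for (i in 1:200) {
    tr <- simulate_tree(spec, seed = 5000 + i)
    d <- sim_xy(tr, slope = -0.068, intercept = -0.39, sigma2_x = 0.05,
                sigma2_res = 0.002, seed = 5000 + i)
    f <- pgls_fit(y ~ x, d, tr)
    ci <- confint(f)["x", ]
    hits <- hits + (ci[1] <= -0.068 && -0.068 <= ci[2])
  }
  expect_gte(hits / 200, 0.9)
})

test_that("phylo ANOVA detects a 0.3 group offset with high power", {
  rej <- 0L
  for (i in 1:100) {
    spc <- sim_spec(n_tips = 64, group_offsets = c(g1 = 0.3, g2 = 0),
                    residual_sigma2 = 0.01 / 60, seed = 30000 + i)
    tr <- simulate_tree(spc, seed = 30000 + i)
    tra <- simulate_traits(tr, spc, seed = 30000 + i)
    rv <- setNames(tra$elong - (-0.068 * tra$lnBM - 0.39), tra$species)
    rej <- rej + (phylo_anova(rv, tra$behavior, tr)$p < 0.05)
  }
  expect_gt(rej / 100, 0.9)
})
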