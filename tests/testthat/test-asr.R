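# closed-form posterior under the package's priors (flat z_root/beta,
# log-uniform sigma2): z_root | data has mean = GLS/ML estimate; sigma2 |
# data is inverse-gamma with mean RSS_gls / (n - p - 2), p = number of mean
# parameters (1 for model A)
post_oracle <- function(tree, trait, directional = FALSE) {
  sp <- names(trait)
  V <- phylo_covariance(tree)[sp, sp]
  dep <- node_depths(tree)[match(sp, tree$tip.label)]
  X <- if (directional) cbind(1, dep) else matrix(1, length(trait), 1)
  Vi <- solve(V)
  beta <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% trait))
  r <- trait - drop(X %*% beta)
  rss <- drop(t(r) %*% Vi %*% r)
  n <- length(trait); p <- ncol(X)
  list(mean = beta, sigma2_mean = rss / (n - p - 2))
}

test_that("BM log-likelihood matches dense multivariate-normal oracles", {
  ## single tip: univariate normal with variance sigma2 * T
  tr1 <- read_newick("(A:3);")
  x1 <- c(A = 1.4)
  m <- bm_model(sigma2 = 0.5, z_root = 1)
  expect_equal(bm_loglik(tr1, x1, m),
               dnorm(1.4, 1, sqrt(0.5 * 3), log = TRUE))

  ## 3-tip tree against an independently coded dense logpdf
  tr <- read_newick("((A:1,B:1):1,C:2);")
  x <- c(A = 0.3, B = -0.2, C = 1.1)
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3)
  m2 <- bm_model(sigma2 = 0.7, z_root = 0.1)
  expect_equal(bm_loglik(tr, x, m2),
               mvn_logpdf(x, rep(0.1, 3), 0.7 * V), tolerance = 1e-10)

  ## model B with beta 0 reduces to model A exactly
  mB <- bm_model(sigma2 = 0.7, z_root = 0.1, beta_trend = 0,
                 model_type = "B")
  expect_identical(bm_loglik(tr, x, mB), bm_loglik(tr, x, m2))

  ## directional mean structure on a non-ultrametric tree
  trf <- read_newick("((A:1,B:2):1,C:3);")
  xf <- c(A = 0.5, B = 0.9, C = 1.2)
  mBt <- bm_model(sigma2 = 0.3, z_root = 0, beta_trend = 0.2,
                  model_type = "B")
  dep <- node_depths(trf)[match(names(xf), trf$tip.label)]
  Vf <- phylo_covariance(trf)[names(xf), names(xf)]
  expect_equal(bm_loglik(trf, xf, mBt),
               mvn_logpdf(xf, 0.2 * dep, 0.3 * Vf), tolerance = 1e-10)

  ## invariance under tip relabeling
  perm <- c(C = 1.1, A = 0.3, B = -0.2)
  expect_equal(bm_loglik(tr, perm, m2), bm_loglik(tr, x, m2))
})

test_that("bm_model enforces its invariants", {
  expect_error(bm_model(sigma2 = -1), "positive")
  expect_error(bm_model(beta_trend = 0.1, model_type = "A"),
               "non-directional")
  expect_identical(bm_model(beta_trend = 0.1)$model_type, "B")
})

test_that("posterior means match the closed-form posterior within 3 MC SEs", {
  spec <- sim_spec(n_tips = 10, seed = 1)
  tr <- simulate_tree(spec, seed = 31)
  set.seed(32)
  x <- calcelong:::.bm_draw(tr, 0.04, z_root = 5)
  ch <- mcmc_sample(tr, x, "A", config = mcmc_config(iterations = 60000,
                                                     burnin = 5000,
                                                     seed = 11))
  s <- pooled_samples(ch)
  or <- post_oracle(tr, x)
  se_z <- mcse(s[, "z_root"])
  expect_lt(abs(mean(s[, "z_root"]) - or$mean[1]), 3 * se_z)
  se_s2 <- mcse(s[, "sigma2"])
  expect_lt(abs(mean(s[, "sigma2"]) - or$sigma2_mean), 3 * se_s2)
  ## acceptance was tuned into the window
  for (c in ch$chains)
    expect_true(c$acceptance >= 0.15 && c$acceptance <= 0.45)
})

test_that("flat tip data concentrate the posterior at the common value", {
  tr <- ultra_tree(8, depth = 5)
  x <- rep(2.5, 8); names(x) <- tr$tip.label
  ## tuning may warn on degenerate data; only the posterior matters here
  ch <- suppressWarnings(
    mcmc_sample(tr, x, "A", config = mcmc_config(iterations = 30000,
                                                 burnin = 3000, seed = 4)))
  pm <- posterior_means(ch)
  expect_lt(abs(pm[["z_root"]] - 2.5), 0.01)
  expect_lt(pm[["sigma2"]], 1e-3)
})

test_that("two chains with different seeds agree in mean logL", {
  spec <- sim_spec(n_tips = 12, seed = 2)
  tr <- simulate_tree(spec, seed = 7)
  set.seed(8)
  x <- calcelong:::.bm_draw(tr, 0.05, z_root = 4)
  ch <- mcmc_sample(tr, x, "A", config = mcmc_config(iterations = 60000,
                                                     burnin = 5000,
                                                     seed = 21))
  ll1 <- ch$chains[[1]]$samples[, "logL"]
  ll2 <- ch$chains[[2]]$samples[, "logL"]
  se <- sqrt(mcse(ll1)^2 + mcse(ll2)^2)
  expect_lt(abs(mean(ll1) - mean(ll2)), max(2 * se, 0.5))
})

test_that("model comparison applies the 1-log-unit rule and prefers simplicity", {
  mk <- function(mean_logL, model = "A", scaling = "none", n_params = 2L) {
    structure(list(chains = list(), model = model, scaling = scaling,
                   n_params = n_params, mean_logL = mean_logL,
                   harmonic_mean_logL = mean_logL - 0.5),
              class = "bm_chains")
  }
  ## 0.5 log-unit advantage: baseline retained
  out <- compare_models(list(A = mk(-100), B = mk(-99.5, "B",
                                                  n_params = 3L)))
  expect_identical(out$selected, "A")
  ## 1.5 log-unit advantage: candidate wins
  out2 <- compare_models(list(A = mk(-100), B = mk(-98.5, "B",
                                                   n_params = 3L)))
  expect_identical(out2$selected, "B")
  ## identical candidates: the simpler is selected
  out3 <- compare_models(list(A = mk(-100), Bsame = mk(-100, "B",
                                                       n_params = 3L)))
  expect_identical(out3$selected, "A")
})

test_that("directional simulations select model B by the logL rule", {
  ## strong trend on a tree with fossil tips, mirroring the body-mass
  ## analyses where the directional model fit better
  spec <- sim_spec(n_tips = 100, fossil_fraction = 0.4, seed = 3)
  cfg <- function(seed) mcmc_config(iterations = 20000, burnin = 4000,
                                    seed = seed)
  wins <- 0L
  for (i in 1:20) {
    tr <- simulate_tree(spec, seed = 300 + i)
    set.seed(300 + i)
    x <- calcelong:::.bm_draw(tr, 0.04, z_root = 5, beta = 0.05)
    cs <- list(A = mcmc_sample(tr, x, "A", config = cfg(300 + i)),
               B = mcmc_sample(tr, x, "B", config = cfg(300 + i)))
    wins <- wins + (compare_models(cs)$selected == "B")
  }
  expect_gte(wins / 20, 0.8)
})

test_that("node reconstructions match closed-form conditionals", {
  ## unbalanced star: root posterior mean ~ inverse-branch-length weighted
  ## average of the tip values (the GLS root estimate); four tips keep the
  ## marginal posterior of the root heavy-tail-free so the mean exists
  tr <- read_newick("(A:1,B:4,C:2,D:2);")
  x <- c(A = 1, B = 3, C = 2, D = 1.5)
  a <- reconstruct_nodes(tr, x, "A",
                         config = mcmc_config(iterations = 40000,
                                              burnin = 4000, seed = 9))
  w <- 1 / c(1, 4, 2, 2)
  expect_lt(abs(a$nodes$mean[1] - sum(w * x) / sum(w)), 0.15)
  expect_true(a$nodes$hpd_low[1] <= a$nodes$mean[1] &&
                a$nodes$mean[1] <= a$nodes$hpd_high[1])

  ## star tree: root mean ~ arithmetic tip mean
  st <- star_tree(10, depth = 2)
  set.seed(10)
  xs <- rnorm(10, 1, 0.5); names(xs) <- st$tip.label
  as_ <- reconstruct_nodes(st, xs, "A",
                           config = mcmc_config(iterations = 40000,
                                                burnin = 4000, seed = 10))
  expect_lt(abs(as_$nodes$mean[1] - mean(xs)), 0.1)
})

test_that("node HPD widths widen with the Brownian rate", {
  tr <- ultra_tree(8, depth = 10)
  set.seed(13)
  base <- calcelong:::.bm_draw(tr, 0.01, z_root = 0)
  widths <- sapply(c(0.5, 2, 8), function(mult) {
    x <- base * sqrt(mult)
    a <- reconstruct_nodes(tr, x, "A",
                           config = mcmc_config(iterations = 20000,
                                                burnin = 3000, seed = 14))
    mean(a$nodes$hpd_high - a$nodes$hpd_low)
  })
  expect_true(all(diff(widths) > 0))
})

test_that("hpd_interval finds the shortest covering interval", {
  set.seed(15)
  x <- rnorm(20000)
  h <- hpd_interval(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.08)
  expect_lt(abs(h[2] - 1.96), 0.08)
  ## skewed distribution: HPD is shorter than the equal-tail interval
  y <- rexp(20000)
  hy <- hpd_interval(y, 0.95)
  et <- quantile(y, c(0.025, 0.975))
  expect_lt(diff(hy), diff(et))
  expect_lt(hy[1], 0.05)
})

test_that("nodal residual elongation subtracts the reference line", {
  mk_asr <- function(means) {
    structure(list(nodes = data.frame(node = paste0("n", seq_along(means)),
                                      mean = means,
                                      hpd_low = means - 1,
                                      hpd_high = means + 1)),
              class = "asr")
  }
  line <- reference_line(-0.068, -0.39, "elong")
  ## node exactly on the line
  m <- mk_asr(4.0); e <- mk_asr(-0.068 * 4.0 - 0.39)
  expect_equal(nodal_residual_elongation(m, e, line)$residual, 0)
  ## worked value
  e2 <- mk_asr(-0.5)
  expect_equal(nodal_residual_elongation(m, e2, line)$residual, 0.162,
               tolerance = 1e-6)
  ## node mismatch
  bad <- mk_asr(c(1, 2))
  expect_error(nodal_residual_elongation(bad, e2, line), "node sets")
})

test_that("a clade simulated above the line has positive nodal residuals", {
  spec <- sim_spec(n_tips = 24, seed = 6, residual_sigma2 = 1e-4)
  tr <- simulate_tree(spec, seed = 61)
  tra <- simulate_traits(tr, spec, seed = 61)
  offset <- 0.2
  mass <- setNames(tra$lnBM, tra$species)
  elong <- setNames(tra$elong + offset, tra$species)
  cfg <- mcmc_config(iterations = 30000, burnin = 4000, seed = 62)
  am <- reconstruct_nodes(tr, mass, "A", config = cfg)
  ae <- reconstruct_nodes(tr, elong, "A", config = cfg)
  res <- nodal_residual_elongation(am, ae, spec$allometry)
  expect_gt(mean(res$residual > 0), 0.9)
  expect_lt(abs(mean(res$residual) - offset), 0.1)
})
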