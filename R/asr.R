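#' Brownian-motion model specification
#'
#' Model "A" is the non-directional constant-variance random walk; model
#' "B" adds a directional trend so a tip's expected value is
#' z_root + beta_trend * t_i, with t_i the root-to-tip path length. The
#' trend is identifiable only on trees with non-contemporaneous (fossil)
#' tips.
#'
#' @param sigma2 Brownian rate per Ma (> 0).
#' @param z_root root state.
#' @param beta_trend per-Ma drift; must be 0 for model A.
#' @param model_type `"A"` or `"B"`; inferred from `beta_trend` if missing.
#' @param scaling a [scaling_params()] object.
#' @return list of class `"bm_model"`.
#' @export
bm_model <- function(sigma2 = 1, z_root = 0, beta_trend = 0,
                     model_type = NULL, scaling = scaling_params()) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (is.null(model_type)) model_type <- if (beta_trend == 0) "A" else "B"
  model_type <- match.arg(model_type, c("A", "B"))
  if (model_type == "A" && beta_trend != 0)
    stop("model A is non-directional: beta_trend must be 0")
  structure(list(sigma2 = sigma2, z_root = z_root, beta_trend = beta_trend,
                 model_type = model_type, scaling = scaling),
            class = "bm_model")
}

#' Log-likelihood of tip data under (directional) Brownian motion
#'
#' Multivariate-normal log density with mean z_root + beta_trend * t_i and
#' covariance sigma2 * V, where V is the (optionally Pagel-scaled)
#' Brownian covariance of the tree.
#'
#' @param tree a `"phylo"` object.
#' @param trait named numeric vector covering all tips.
#' @param model a [bm_model()].
#' @return the log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, trait, model) {
  sp <- .match_species(trait, tree, "`trait`")
  if (!setequal(sp, tree$tip.label)) stop("trait must cover all tips")
  V <- scaled_covariance(tree, model$scaling)[sp, sp, drop = FALSE]
  depths <- node_depths(tree)[match(sp, tree$tip.label)]
  mu <- model$z_root + model$beta_trend * depths
  x <- as.numeric(trait) - mu
  L <- tryCatch(chol(model$sigma2 * V), error = function(e)
    stop("covariance is singular", call. = FALSE))
  w <- backsolve(L, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(w^2))
}

#' MCMC sampler settings
#'
#' @param iterations total Metropolis-Hastings iterations per chain.
#' @param burnin iterations discarded (proposal tuning happens only here).
#' @param proposal_scale initial random-walk proposal SD (auto-tuned during
#'   burnin toward the acceptance window).
#' @param acceptance_window target acceptance-rate interval.
#' @param n_chains number of independent chains.
#' @param thin keep every `thin`-th post-burnin sample.
#' @param seed integer seed; chain c uses seed + c.
#' @return list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(iterations = 100000, burnin = 5000,
                        proposal_scale = 0.5,
                        acceptance_window = c(0.20, 0.40),
                        n_chains = 2, thin = 20, seed = 1) {
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (any(acceptance_window <= 0) || any(acceptance_window >= 1) ||
      diff(acceptance_window) <= 0)
    stop("acceptance_window must be an increasing pair inside (0, 1)")
  structure(list(iterations = iterations, burnin = burnin,
                 proposal_scale = proposal_scale,
                 acceptance_window = acceptance_window,
                 n_chains = n_chains, thin = thin, seed = seed),
            class = "mcmc_config")
}

## Single Metropolis-Hastings chain over (z_root, log sigma2, [beta],
## [lambda]). With lambda fixed, the likelihood reduces to precomputed
## inner products and each iteration costs O(1).
.run_chain <- function(tree, trait, directional, sample_lambda, config,
                       chain_seed) {
  set.seed(chain_seed)
  sp <- names(trait)
  ord <- match(sp, tree$tip.label)
  depths_all <- node_depths(tree)
  tvec <- depths_all[ord]
  n <- length(trait)
  x <- as.numeric(trait)

  C0 <- phylo_covariance(tree)[sp, sp, drop = FALSE]
  prep <- function(lambda) {
    V <- apply_scaling(C0, scaling_params(lambda = lambda))
    L <- chol(V)
    wx <- backsolve(L, x, transpose = TRUE)
    w1 <- backsolve(L, rep(1, n), transpose = TRUE)
    wt <- backsolve(L, tvec, transpose = TRUE)
    list(logdet = 2 * sum(log(diag(L))),
         cxx = sum(wx * wx), cx1 = sum(wx * w1), cxt = sum(wx * wt),
         c11 = sum(w1 * w1), c1t = sum(w1 * wt), ctt = sum(wt * wt))
  }
  loglik <- function(pr, z0, s2, beta) {
    Q <- pr$cxx - 2 * z0 * pr$cx1 - 2 * beta * pr$cxt +
      z0^2 * pr$c11 + 2 * z0 * beta * pr$c1t + beta^2 * pr$ctt
    -0.5 * (n * log(2 * pi * s2) + pr$logdet + Q / s2)
  }
  ## priors: flat on z0 and beta, log-uniform on sigma2 within broad bounds,
  ## uniform lambda in [0, 1]; log prior contributes -log(s2) via the
  ## log-scale proposal Jacobian handled by sampling log(s2) directly.
  lb_ls2 <- log(1e-8); ub_ls2 <- log(1e8)

  ## initialise at the GLS solution under the starting covariance so the
  ## chain starts in the typical set and burnin only has to tune proposals
  lambda <- if (sample_lambda) 0.5 else 1
  pr <- prep(lambda)
  z0 <- pr$cx1 / pr$c11
  beta <- 0
  s2 <- max((pr$cxx - 2 * z0 * pr$cx1 + z0^2 * pr$c11) / n, 1e-8)
  ll <- loglik(pr, z0, s2, beta)

  npar <- 2L + directional + sample_lambda
  scales <- rep(config$proposal_scale, npar)
  ## parameter order: z0, log s2, [beta], [lambda]
  acc <- integer(npar); tries <- integer(npar)
  acc_total <- 0L; tries_total <- 0L

  nkeep <- floor((config$iterations - config$burnin) / config$thin)
  samples <- matrix(NA_real_, nkeep, npar + 1L)
  colnames(samples) <- c("z_root", "sigma2",
                         if (directional) "beta_trend",
                         if (sample_lambda) "lambda", "logL")[
                           c(seq_len(npar), npar + 1L)]
  kept <- 0L

  for (it in seq_len(config$iterations)) {
    j <- ((it - 1L) %% npar) + 1L
    tries[j] <- tries[j] + 1L
    accept <- FALSE
    if (j == 1L) {                       # z_root
      z0p <- z0 + stats::rnorm(1, 0, scales[1])
      llp <- loglik(pr, z0p, s2, beta)
      if (log(stats::runif(1)) < llp - ll) { z0 <- z0p; ll <- llp
        accept <- TRUE }
    } else if (j == 2L) {                # log sigma2 (log-uniform prior)
      ls2p <- log(s2) + stats::rnorm(1, 0, scales[2])
      if (ls2p > lb_ls2 && ls2p < ub_ls2) {
        llp <- loglik(pr, z0, exp(ls2p), beta)
        if (log(stats::runif(1)) < llp - ll) { s2 <- exp(ls2p); ll <- llp
          accept <- TRUE }
      }
    } else if (directional && j == 3L) { # beta
      bp <- beta + stats::rnorm(1, 0, scales[3])
      llp <- loglik(pr, z0, s2, bp)
      if (log(stats::runif(1)) < llp - ll) { beta <- bp; ll <- llp
        accept <- TRUE }
    } else {                             # lambda (uniform prior on [0,1])
      lp <- lambda + stats::rnorm(1, 0, scales[j])
      if (lp >= 0 && lp <= 1) {
        prp <- prep(lp)
        llp <- loglik(prp, z0, s2, beta)
        if (log(stats::runif(1)) < llp - ll) {
          lambda <- lp; pr <- prp; ll <- llp; accept <- TRUE }
      }
    }
    if (accept) acc[j] <- acc[j] + 1L
    if (it <= config$burnin) {
      ## tune every 200 proposals per parameter toward the window
      if (tries[j] %% 200L == 0L) {
        rate <- acc[j] / tries[j]
        if (rate < config$acceptance_window[1]) scales[j] <- scales[j] * 0.7
        if (rate > config$acceptance_window[2]) scales[j] <- scales[j] * 1.4
        acc[j] <- 0L; tries[j] <- 0L       # restart the window estimate
      }
      if (it == config$burnin) { acc[] <- 0L; tries[] <- 0L }
    } else {
      tries_total <- tries_total + 1L
      if (accept) acc_total <- acc_total + 1L
      if ((it - config$burnin) %% config$thin == 0L && kept < nkeep) {
        kept <- kept + 1L
        samples[kept, ] <- c(z0, s2, if (directional) beta,
                             if (sample_lambda) lambda, ll)
      }
    }
  }
  rate <- acc_total / max(tries_total, 1L)
  if (rate < config$acceptance_window[1] ||
      rate > config$acceptance_window[2])
    warning(sprintf(
      "post-burnin acceptance %.2f outside the target window [%.2f, %.2f]",
      rate, config$acceptance_window[1], config$acceptance_window[2]))
  lls <- samples[seq_len(kept), "logL"]
  list(samples = samples[seq_len(kept), , drop = FALSE],
       acceptance = rate, scales = scales,
       mean_logL = mean(lls),
       harmonic_mean_logL = .harmonic_mean_logl(lls))
}

## log of the harmonic mean of likelihoods, computed stably in log space.
## High-variance estimator; reported alongside the mean logL, which drives
## model selection.
.harmonic_mean_logl <- function(ll) {
  m <- max(-ll)
  -(m + log(mean(exp(-ll - m))))
}

#' Metropolis-Hastings sampling of Brownian-motion model parameters
#'
#' Samples (z_root, sigma2) for model A, plus the trend beta for model B,
#' plus Pagel's lambda when `scaling = "lambda"`. Proposal scales are tuned
#' automatically during burnin toward the 20-40% acceptance window and then
#' frozen, preserving detailed balance for the retained samples. Priors are
#' flat on z_root and beta, log-uniform on sigma2 within broad bounds, and
#' uniform on lambda, so the posterior tracks the likelihood.
#'
#' @param tree a `"phylo"` object.
#' @param trait named numeric vector covering all tips.
#' @param model `"A"` (non-directional) or `"B"` (directional).
#' @param scaling `"none"` or `"lambda"`.
#' @param config an [mcmc_config()].
#' @return object of class `"bm_chains"`: per-chain sample matrices,
#'   acceptance rates, mean and harmonic-mean log-likelihoods.
#' @export
mcmc_sample <- function(tree, trait, model = c("A", "B"),
                        scaling = c("none", "lambda"),
                        config = mcmc_config()) {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  sp <- .match_species(trait, tree, "`trait`")
  if (!setequal(sp, tree$tip.label)) stop("trait must cover all tips")
  if (model == "B") {
    d <- node_depths(tree)[seq_along(tree$tip.label)]
    if (diff(range(d)) < 1e-8)
      warning("tree is ultrametric: the directional trend is not ",
              "identifiable without fossil tips")
  }
  chains <- lapply(seq_len(config$n_chains), function(ch)
    .run_chain(tree, trait, directional = (model == "B"),
               sample_lambda = (scaling == "lambda"),
               config, chain_seed = config$seed + ch))
  structure(list(chains = chains, model = model, scaling = scaling,
                 config = config,
                 n_params = 2L + (model == "B") + (scaling == "lambda"),
                 mean_logL = mean(vapply(chains, `[[`, 1, "mean_logL")),
                 harmonic_mean_logL =
                   mean(vapply(chains, `[[`, 1, "harmonic_mean_logL"))),
            class = "bm_chains")
}

#' @export
print.bm_chains <- function(x, ...) {
  cat(sprintf(
    "BM MCMC: model %s%s, %d chain(s) x %d iterations (burnin %d)\n",
    x$model, if (x$scaling != "none") paste0(" + ", x$scaling) else "",
    length(x$chains), x$config$iterations, x$config$burnin))
  cat(sprintf("  mean logL %.3f, harmonic mean logL %.3f (high-variance)\n",
              x$mean_logL, x$harmonic_mean_logL))
  for (i in seq_along(x$chains))
    cat(sprintf("  chain %d acceptance %.2f\n", i, x$chains[[i]]$acceptance))
  pm <- posterior_means(x)
  cat("  posterior means:",
      paste(names(pm), signif(pm, 4), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Pooled posterior samples from all chains
#' @param chains a `"bm_chains"` object.
#' @return matrix of pooled post-burnin samples.
#' @export
pooled_samples <- function(chains) {
  do.call(rbind, lapply(chains$chains, `[[`, "samples"))
}

#' Posterior means of sampled parameters
#' @param chains a `"bm_chains"` object.
#' @return named numeric vector.
#' @export
posterior_means <- function(chains) {
  s <- pooled_samples(chains)
  colMeans(s[, setdiff(colnames(s), "logL"), drop = FALSE])
}

#' Shortest 95% highest posterior density interval
#'
#' The shortest contiguous interval containing `prob` of the sorted
#' samples.
#'
#' @param x numeric samples.
#' @param prob posterior mass (default 0.95).
#' @return numeric pair (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Select among Brownian-motion model candidates
#'
#' Implements the conservative selection rule used for ancestral
#' reconstructions: a directional and/or scaled candidate replaces the
#' non-directional unscaled baseline only if its average mean
#' log-likelihood exceeds the baseline's by at least `threshold` (default
#' 1.0) log-units; ties and near-ties keep the simpler model (fewer
#' parameters).
#'
#' @param chain_sets named list of `"bm_chains"` objects fitted to the same
#'   data and tree; the baseline is the entry with model A and no scaling
#'   (or, failing that, the fewest parameters).
#' @param threshold required log-likelihood advantage.
#' @return list with `selected` (name), `table` (data.frame of logL
#'   summaries) and the selected `"bm_chains"` object as `chains`.
#' @export
compare_models <- function(chain_sets, threshold = 1.0) {
  if (length(chain_sets) < 2) stop("need at least 2 candidate models")
  if (is.null(names(chain_sets)))
    names(chain_sets) <- paste0("model", seq_along(chain_sets))
  np <- vapply(chain_sets, `[[`, 1L, "n_params")
  mls <- vapply(chain_sets, `[[`, 1, "mean_logL")
  hms <- vapply(chain_sets, `[[`, 1, "harmonic_mean_logL")
  base_idx <- which(vapply(chain_sets, function(cs)
    cs$model == "A" && cs$scaling == "none", logical(1)))
  if (!length(base_idx)) base_idx <- which.min(np)
  base_idx <- base_idx[1]
  tab <- data.frame(model = names(chain_sets), n_params = np,
                    mean_logL = mls, harmonic_mean_logL = hms,
                    advantage = mls - mls[base_idx], row.names = NULL)
  qual <- which(tab$advantage >= threshold & seq_along(mls) != base_idx)
  sel <- if (length(qual)) {
    best <- qual[order(-tab$mean_logL[qual], tab$n_params[qual])][1]
    ## prefer the simpler among candidates within numerical ties
    tied <- qual[abs(tab$mean_logL[qual] - tab$mean_logL[best]) < 1e-9]
    tied[which.min(tab$n_params[tied])]
  } else base_idx
  list(selected = names(chain_sets)[sel], table = tab,
       chains = chain_sets[[sel]])
}

## Joint tips+nodes covariance and node means under the (lambda-) scaled
## directional BM model, from the literal internal-branch-multiplication
## view of lambda: internal branches are scaled by lambda while tip depths
## are preserved.
.joint_structure <- function(tree, lambda = 1) {
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  depths <- node_depths(tree)
  tt <- tree
  if (lambda != 1) {
    internal_child <- tt$edge[, 2] > n
    tt$edge.length[internal_child] <- tt$edge.length[internal_child] * lambda
    ## stretch terminal branches so tip depths stay unchanged
    d2 <- ape::node.depth.edgelength(tt)
    term <- which(tt$edge[, 2] <= n)
    tt$edge.length[term] <- tt$edge.length[term] +
      (depths[tt$edge[term, 2]] - d2[tt$edge[term, 2]])
  }
  dep_t <- ape::node.depth.edgelength(tt)
  ## mrca depths over all node pairs (tips + internals)
  M <- ape::mrca(tt, full = TRUE)
  Vfull <- matrix(dep_t[M], nrow(M), ncol(M))
  list(Vfull = Vfull, depths_orig = depths, ntip = n, nnode = nnode)
}

#' Ancestral state reconstruction by MCMC
#'
#' Samples model parameters by [mcmc_sample()] and, for each retained draw,
#' samples the internal-node states from their exact conditional Gaussian
#' distribution given the tips and the drawn parameters. Posterior node
#' summaries therefore integrate over parameter uncertainty. Node labels
#' are taken from the tree when present, else `"node<k>"`.
#'
#' @param tree a `"phylo"` object.
#' @param trait named numeric vector covering all tips.
#' @param model `"A"` or `"B"`.
#' @param scaling `"none"` or `"lambda"`.
#' @param config an [mcmc_config()].
#' @param max_draws cap on the number of posterior draws used for node
#'   sampling.
#' @return object of class `"asr"`: data.frame `nodes` (label, mean, HPD
#'   bounds, age), the parameter `chains`, and per-chain log-likelihood
#'   summaries.
#' @export
reconstruct_nodes <- function(tree, trait, model = c("A", "B"),
                              scaling = c("none", "lambda"),
                              config = mcmc_config(), max_draws = 1000) {
  model <- match.arg(model); scaling <- match.arg(scaling)
  chains <- mcmc_sample(tree, trait, model, scaling, config)
  s <- pooled_samples(chains)
  if (nrow(s) > max_draws)
    s <- s[round(seq(1, nrow(s), length.out = max_draws)), , drop = FALSE]
  sp <- names(trait)
  ord <- match(sp, tree$tip.label)
  n <- length(sp); nnode <- tree$Nnode
  x <- as.numeric(trait)

  node_states <- matrix(NA_real_, nrow(s), nnode)
  lam_vals <- if ("lambda" %in% colnames(s)) s[, "lambda"] else rep(1, nrow(s))
  ## group draws by (rounded) lambda so the expensive joint structure is
  ## rebuilt only when lambda changes materially
  lam_key <- round(lam_vals, 3)
  set.seed(config$seed + 999L)
  for (key in unique(lam_key)) {
    idx <- which(lam_key == key)
    js <- .joint_structure(tree, lambda = key)
    Vtt <- js$Vfull[ord, ord, drop = FALSE]
    Vat <- js$Vfull[n + seq_len(nnode), ord, drop = FALSE]
    Vaa <- js$Vfull[n + seq_len(nnode), n + seq_len(nnode), drop = FALSE]
    ## ridge for the root row/col (variance 0 at the root)
    Lt <- chol(Vtt + diag(1e-10, n))
    A <- Vat %*% chol2inv(Lt)          # Vat Vtt^-1
    Sig <- Vaa - A %*% t(Vat)
    Sig <- (Sig + t(Sig)) / 2
    es <- eigen(Sig, symmetric = TRUE)
    ev <- pmax(es$values, 0)
    B <- es$vectors %*% diag(sqrt(ev), length(ev))
    dep_tip <- js$depths_orig[ord]
    dep_node <- js$depths_orig[n + seq_len(nnode)]
    for (i in idx) {
      z0 <- s[i, "z_root"]; s2 <- s[i, "sigma2"]
      beta <- if ("beta_trend" %in% colnames(s)) s[i, "beta_trend"] else 0
      mu_t <- z0 + beta * dep_tip
      mu_a <- z0 + beta * dep_node
      cond_mean <- mu_a + drop(A %*% (x - mu_t))
      node_states[i, ] <- cond_mean +
        sqrt(s2) * drop(B %*% stats::rnorm(nnode))
    }
  }
  labs <- if (!is.null(tree$node.label) &&
              all(nzchar(tree$node.label))) tree$node.label
          else paste0("node", n + seq_len(nnode))
  hp <- t(apply(node_states, 2, hpd_interval))
  nodes <- data.frame(node = labs,
                      mean = colMeans(node_states),
                      hpd_low = hp[, 1], hpd_high = hp[, 2],
                      age = node_ages(tree)[n + seq_len(nnode)],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, chains = chains, model = model,
                 scaling = scaling), class = "asr")
}

#' @export
print.asr <- function(x, ...) {
  cat(sprintf("Ancestral state reconstruction (model %s%s):\n", x$model,
              if (x$scaling != "none") paste0(" + ", x$scaling) else ""))
  print(utils::head(within(x$nodes, {
    mean <- round(mean, 4); hpd_low <- round(hpd_low, 4)
    hpd_high <- round(hpd_high, 4); age <- round(age, 2)
  }), 10))
  if (nrow(x$nodes) > 10) cat("  ...", nrow(x$nodes), "nodes total\n")
  invisible(x)
}

#' Nodal residual elongation
#'
#' Per internal node, the reconstructed elongation index minus the value
#' predicted from the reconstructed ln body mass by a reference line:
#' elong_mean - (slope * mass_mean + intercept).
#'
#' @param asr_mass `"asr"` result for ln body mass.
#' @param asr_elong `"asr"` result for the elongation index.
#' @param line a [reference_line()] with response `"elong"`.
#' @return data.frame with node labels and residuals.
#' @export
nodal_residual_elongation <- function(asr_mass, asr_elong,
                                      line = standard_line("resA")) {
  if (!identical(asr_mass$nodes$node, asr_elong$nodes$node))
    stop("node sets differ between the two reconstructions")
  if (line$response != "elong")
    stop("line must predict the elongation index")
  data.frame(node = asr_mass$nodes$node,
             residual = asr_elong$nodes$mean -
               (line$slope * asr_mass$nodes$mean + line$intercept),
             stringsAsFactors = FALSE)
}
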