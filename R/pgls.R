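## GLS machinery shared by pgls_fit and phylo_anova. All solves go through
## the Cholesky factor of V; V must be positive definite (lambda < 1 usually
## repairs a singular Brownian covariance from duplicated tip positions).

.gls_core <- function(X, y, V) {
  L <- tryCatch(chol(V), error = function(e)
    stop("phylogenetic covariance is singular; try lambda < 1", call. = FALSE))
  ## whiten: solve L' z = . (L is upper triangular with V = L'L)
  Xw <- backsolve(L, X, transpose = TRUE)
  colnames(Xw) <- colnames(X)
  yw <- backsolve(L, y, transpose = TRUE)
  qr_ <- qr(Xw)
  beta <- qr.coef(qr_, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  n <- length(y); p <- ncol(X)
  logdetV <- 2 * sum(log(diag(L)))
  sigma2_ml <- rss / n
  logL <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  XtVX_inv <- chol2inv(qr.R(qr_))
  dimnames(XtVX_inv) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(drop(beta), colnames(X))
  list(beta = beta, rss = rss, logdetV = logdetV, logL = logL,
       XtVX_inv = XtVX_inv, n = n, p = p, L = L, res_w = drop(res_w))
}

.match_species <- function(values, tree, what = "data") {
  sp <- names(values)
  if (is.null(sp)) stop(what, " must be named by species")
  missing_tips <- setdiff(sp, tree$tip.label)
  if (length(missing_tips))
    stop("species absent from tree: ", paste(missing_tips, collapse = ", "))
  sp
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' GLS regression whose error covariance is the Brownian-motion covariance
#' of the tree, optionally scaled by Pagel's lambda (off-diagonal
#' multiplier). Lambda may be fixed or estimated by maximising the profile
#' (ML, not REML) log-likelihood over \[0, 1\] with a bounded scalar search
#' (tolerance 1e-6). At lambda = 0 the phylogeny collapses and the fit
#' equals ordinary least squares.
#'
#' @param formula model formula, e.g. `elong ~ est_lnBM`.
#' @param data data.frame with a `species` column (or row names) matching
#'   tip labels.
#' @param tree a `"phylo"` object containing all species in `data`.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param delta,kappa further Pagel transforms, fixed (defaults 1).
#' @return an object of class `"pgls"`: coefficients with SEs, t and
#'   two-tailed p values, `lambda`, `logL`, `adjR2`, overall `F` with
#'   degrees of freedom, residual SE and df.
#' @examples
#' tr <- ape::rtree(8)
#' d <- data.frame(species = tr$tip.label,
#'                 x = rnorm(8))
#' d$y <- 2 * d$x + rnorm(8)
#' pgls_fit(y ~ x, d, tr, lambda = 0)
#' @export
pgls_fit <- function(formula, data, tree, lambda = "ML",
                     delta = 1, kappa = 1) {
  if (!"species" %in% names(data)) data$species <- rownames(data)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  sp <- data$species[match(rownames(mf), rownames(data))]
  if (anyNA(sp)) sp <- data$species
  names(y) <- sp
  .match_species(y, tree)
  n <- length(y)
  if (n < 3) stop("need at least 3 species")

  C0 <- phylo_covariance(tree)
  C0 <- C0[sp, sp, drop = FALSE]
  if (kappa != 1) {
    Ck <- scaled_covariance(tree, scaling_params(kappa = kappa))
    C0 <- Ck[sp, sp, drop = FALSE]
  }
  Vfun <- function(lam)
    apply_scaling(C0, scaling_params(lambda = lam, delta = delta))

  profile <- function(lam) .gls_core(X, y, Vfun(lam))$logL
  if (identical(lambda, "ML")) {
    opt <- stats::optimize(profile, interval = c(0, 1), maximum = TRUE,
                           tol = 1e-6)
    ## guard the boundaries: optimize() never evaluates exactly at 0 or 1
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective, profile(0), profile(1))
    lambda_hat <- cand[which.max(ll)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("`lambda` must be \"ML\" or a number in [0, 1]")
    lambda_hat <- lambda
  }
  g <- .gls_core(X, y, Vfun(lambda_hat))
  p <- g$p
  resid_df <- n - p
  sigma2 <- g$rss / resid_df
  se <- sqrt(sigma2 * diag(g$XtVX_inv))
  tval <- g$beta / se
  pval <- 2 * stats::pt(abs(tval), resid_df, lower.tail = FALSE)

  ## R^2 and F against the GLS intercept-only model under the same V
  g0 <- .gls_core(matrix(1, n, 1), y, Vfun(lambda_hat))
  r2 <- 1 - g$rss / g0$rss
  adjR2 <- 1 - (1 - r2) * (n - 1) / resid_df
  Fval <- if (p > 1) ((g0$rss - g$rss) / (p - 1)) / sigma2 else NA_real_
  ## constant response: both model and null RSS vanish, F is 0 by definition
  tol0 <- 1e-10 * (1 + sum(y^2))
  if (p > 1 && g0$rss < tol0 && g$rss < tol0) Fval <- 0
  Fdf <- c(p - 1, resid_df)
  Fp <- if (p > 1) stats::pf(Fval, Fdf[1], Fdf[2], lower.tail = FALSE)
        else NA_real_

  ## raw-scale residuals and fitted values
  fitted <- drop(X %*% g$beta)
  structure(list(
    coefficients = g$beta, SE = se, t = tval, p = pval,
    lambda = lambda_hat, lambda_mode = if (identical(lambda, "ML")) "ML"
                                       else "fixed",
    logL = g$logL, adjR2 = adjR2, r2 = r2,
    F = Fval, F_df = Fdf, F_p = Fp,
    residual_SE = sqrt(sigma2), residual_df = resid_df,
    sigma2 = sigma2, vcov = sigma2 * g$XtVX_inv,
    fitted = fitted, residuals = drop(y - fitted),
    residuals_normalized = g$res_w,
    species = sp, n = n, formula = formula, tree = tree,
    call = match.call()), class = "pgls")
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d species, lambda = %.4f (%s), logL = %.3f\n",
              x$n, x$lambda, x$lambda_mode, x$logL))
  tab <- cbind(Estimate = x$coefficients, SE = x$SE, t = x$t, p = x$p)
  print(round(tab, 5))
  cat(sprintf("  adj R2 = %.3f, F = %.3f on (%d, %d) df, p = %.4g\n",
              x$adjR2, x$F, x$F_df[1], x$F_df[2], x$F_p))
  cat(sprintf("  residual SE %.4f on %d df\n", x$residual_SE, x$residual_df))
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logL, df = length(object$coefficients) + 2,
            class = "logLik")
}

#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals else object$residuals_normalized
}

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
predict.pgls <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(
    stats::terms(object$formula)), newdata)
  drop(X %*% object$coefficients)
}

#' @export
summary.pgls <- function(object, ...) { print(object); invisible(object) }

#' Confidence intervals for PGLS coefficients
#' @param object a `"pgls"` fit.
#' @param parm coefficients to include (default all).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.pgls <- function(object, parm, level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, object$residual_df)
  ci <- cbind(object$coefficients - q * object$SE,
              object$coefficients + q * object$SE)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Sequential Dunn-Sidak correction
#'
#' Step-down multiple-comparison correction: with p-values sorted
#' ascending, the threshold at step j of k is 1 - (1 - alpha)^(1/(k-j+1));
#' testing stops at the first failure and all later p-values are declared
#' non-significant. For k = 3 and alpha = 0.05 the thresholds are 0.016952,
#' 0.025321 and 0.05.
#'
#' @param p vector of p-values.
#' @param alpha family-wise level.
#' @return data.frame in the original order with columns `p`, `rank`,
#'   `threshold`, `significant`.
#' @export
sequential_dunn_sidak <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  k <- length(p)
  ord <- order(p)
  thr_sorted <- 1 - (1 - alpha)^(1 / (k - seq_len(k) + 1))
  sig_sorted <- logical(k)
  for (j in seq_len(k)) {
    ok <- !is.na(p[ord[j]]) && p[ord[j]] <= thr_sorted[j]
    sig_sorted[j] <- ok
    if (!ok) break
  }
  out <- data.frame(p = p,
                    rank = match(seq_along(p), ord),
                    threshold = thr_sorted[match(seq_along(p), ord)],
                    significant = sig_sorted[match(seq_along(p), ord)])
  out
}

#' Phylogenetic ANOVA of a trait across behavioural groups
#'
#' PGLS with a reference-coded categorical design matrix and a single
#' ML-estimated lambda shared by the overall test and the post-hoc
#' contrasts. Reports the overall F, the GLS residual mean square, and all
#' pairwise group-mean differences as GLS contrasts with t and two-tailed p
#' values, flagged for significance under the sequential Dunn-Sidak
#' correction.
#'
#' @param values named numeric vector (typically residual elongation by
#'   species).
#' @param groups factor or character of group membership, same order/names.
#'   `NA` entries (e.g. suspensory taxa excluded by precedence) are dropped.
#' @param tree a `"phylo"` object.
#' @param lambda `"ML"` or fixed value.
#' @param alpha level for the post-hoc correction.
#' @return object of class `"phylo_anova"`: `F`, `df`, `MS` (GLS residual
#'   mean square), `p`, `lambda`, and a `pairwise` data.frame.
#' @export
phylo_anova <- function(values, groups, tree, lambda = "ML", alpha = 0.05) {
  sp <- .match_species(values, tree, "`values`")
  groups <- as.factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep]); sp <- sp[keep]
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  small <- names(which(table(groups) < 2))
  if (length(small))
    stop("group(s) with fewer than 2 species: ",
         paste(small, collapse = ", "))
  d <- data.frame(species = sp, y = as.numeric(values), g = groups)
  fit <- pgls_fit(y ~ g, d, tree, lambda = lambda)

  ## pairwise contrasts on the reference-coded coefficients
  lev <- levels(groups)
  B <- fit$coefficients; Vb <- fit$vcov
  contr <- function(a, b) {
    ## group mean(a) - group mean(b) as a linear combination of coefficients
    ca <- cb <- numeric(length(B))
    names(ca) <- names(cb) <- names(B)
    if (a != lev[1]) ca[paste0("g", a)] <- 1
    if (b != lev[1]) cb[paste0("g", b)] <- 1
    l <- ca - cb
    est <- sum(l * B)
    se <- sqrt(drop(t(l) %*% Vb %*% l))
    c(diff = est, t = est / se,
      p = 2 * stats::pt(abs(est / se), fit$residual_df, lower.tail = FALSE))
  }
  prs <- utils::combn(lev, 2)
  pw <- t(apply(prs, 2, function(ab) contr(ab[1], ab[2])))
  pw <- data.frame(group1 = prs[1, ], group2 = prs[2, ], pw,
                   stringsAsFactors = FALSE)
  dd <- sequential_dunn_sidak(pw$p, alpha)
  pw$threshold <- dd$threshold
  pw$significant <- dd$significant

  structure(list(F = fit$F, df = fit$F_df, MS = fit$sigma2, p = fit$F_p,
                 lambda = fit$lambda, pairwise = pw, fit = fit,
                 groups = table(groups)), class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic ANOVA: F = %.3f on (%d, %d) df, p = %.4g; lambda = %.3f\n",
    x$F, x$df[1], x$df[2], x$p, x$lambda))
  cat(sprintf("  within-group mean square (GLS) = %.5g\n", x$MS))
  cat("  group sizes:", paste(names(x$groups), x$groups, sep = "=",
                              collapse = ", "), "\n")
  cat("  pairwise contrasts (sequential Dunn-Sidak):\n")
  print(within(x$pairwise, {
    diff <- round(diff, 4); t <- round(t, 3); p <- signif(p, 3)
    threshold <- round(threshold, 5)
  }))
  invisible(x)
}
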