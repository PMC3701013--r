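#' Run the full calcaneal-allometry analysis pipeline
#'
#' Sequences the package's stages over a specimen table (or a pre-computed
#' species-mean table) and optional tree(s): species aggregation,
#' reference-line residuals, per-group OLS regressions, PGLS per tree,
#' phylogenetic ANOVA of residuals across behavioural categories, ancestral
#' state reconstruction, nodal residual elongation and the biomechanical
#' effort curves. Stages whose inputs are absent are skipped with a logged
#' notice; any stage failure aborts with the stage name while earlier
#' outputs are retained in the returned bundle.
#'
#' @param config a named list or path to a YAML file. Recognised entries:
#'   `specimens` (CSV path) or `species_table` (data.frame / TSV path with
#'   `species`, `est_lnBM`, `lnDL`, `elong`, optionally `behavior`),
#'   `trees` (named list/vector of Newick paths or strings),
#'   `calibration` (list `slope`, `intercept`), `lines` (named list of
#'   lists `slope`, `intercept`, `response`), `groups` (named list: group
#'   name -> character vector of species for the OLS stage), `anova`
#'   (list: `line` name to take residuals from), `asr` (list: `iterations`,
#'   `burnin`, `models`), `biomech` (list: `ancestor_mass`, `line`),
#'   `seed`, `outdir`.
#' @param seed overrides `config$seed`.
#' @param outdir if non-NULL, every table is also written as TSV with a
#'   header line naming the config hash.
#' @return list of class `"calcelong_run"` with elements `species`,
#'   `residuals`, `ols`, `pgls`, `anova`, `asr`, `nodal_residuals`,
#'   `biomech`, `log`, `config_hash`.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML path")
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(outdir)) outdir <- config$outdir
  hash <- .config_hash(config)
  logl <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message("[calcelong] ", msg)
    logl <<- c(logl, msg)
  }
  out <- list(config_hash = hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  calib <- c(slope = 1.3274, intercept = 3.0238)
  if (!is.null(config$calibration))
    calib <- c(slope = config$calibration$slope,
               intercept = config$calibration$intercept)

  ## --- species table -------------------------------------------------
  sp_tab <- stage("species_summary", {
    if (!is.null(config$specimens)) {
      rec <- read_specimens(config$specimens)
      species_summary(rec, calibration = calib)
    } else if (!is.null(config$species_table)) {
      st <- config$species_table
      if (is.character(st)) st <- utils::read.delim(st,
                                                    stringsAsFactors = FALSE)
      st
    } else stop("config needs `specimens` or `species_table`")
  })
  note("species table: %d species", nrow(sp_tab))
  out$species <- sp_tab

  ## --- reference lines & residuals ----------------------------------
  lines <- list(resA = standard_line("resA"), resB = standard_line("resB"),
                eocene = standard_line("eocene"))
  if (!is.null(config$lines))
    for (nm in names(config$lines)) {
      cl <- config$lines[[nm]]
      lines[[nm]] <- reference_line(cl$slope, cl$intercept,
                                    cl$response %||% "elong", nm)
    }
  res <- data.frame(species = sp_tab$species)
  for (nm in names(lines)) {
    ln <- lines[[nm]]
    ok <- (ln$response == "elong" && "elong" %in% names(sp_tab)) ||
      (ln$response == "lnDL" && "lnDL" %in% names(sp_tab))
    if (ok) res[[nm]] <- residual_from_line(sp_tab, ln)
  }
  out$residuals <- res

  ## --- per-group OLS -------------------------------------------------
  if (!is.null(config$groups)) {
    out$ols <- stage("ols", {
      tabs <- lapply(names(config$groups), function(g) {
        sel <- sp_tab[sp_tab$species %in% config$groups[[g]], ]
        if (nrow(sel) < 3) return(NULL)
        f <- ols_fit(sel$est_lnBM, sel$elong)
        data.frame(group = g, n = f$n, slope = f$slope,
                   slope_SE = f$slope_SE, intercept = f$intercept,
                   int_SE = f$intercept_SE, r = f$r, t = f$t, p = f$p,
                   SLCI = f$slope_CI95[1], SUCI = f$slope_CI95[2],
                   ILCI = f$intercept_CI95[1], IUCI = f$intercept_CI95[2])
      })
      do.call(rbind, tabs)
    })
    note("OLS stage: %d group fits", NROW(out$ols))
  } else note("OLS stage skipped: no `groups` in config")

  ## --- trees ----------------------------------------------------------
  trees <- NULL
  if (!is.null(config$trees)) {
    trees <- stage("trees", {
      lapply(config$trees, function(t)
        if (file.exists(t)) read_newick(file = t) else read_newick(t))
    })
    if (is.null(names(trees)))
      names(trees) <- paste0("tree", seq_along(trees))
  }

  ## --- PGLS per tree --------------------------------------------------
  if (!is.null(trees)) {
    out$pgls <- stage("pgls", {
      tabs <- lapply(names(trees), function(tn) {
        tr <- trees[[tn]]
        sel <- sp_tab[sp_tab$species %in% tr$tip.label, ]
        fit <- pgls_fit(elong ~ est_lnBM, sel, tr, lambda = "ML")
        data.frame(tree = tn, n = fit$n, lambda = fit$lambda,
                   adjR2 = fit$adjR2,
                   slope = fit$coefficients[["est_lnBM"]],
                   slope_SE = fit$SE[["est_lnBM"]],
                   intercept = fit$coefficients[["(Intercept)"]],
                   int_SE = fit$SE[["(Intercept)"]],
                   t = fit$t[["est_lnBM"]], p = fit$p[["est_lnBM"]],
                   RSE = fit$residual_SE, RDF = fit$residual_df,
                   F = fit$F, F_p = fit$F_p)
      })
      do.call(rbind, tabs)
    })
    note("PGLS stage: %d tree(s)", nrow(out$pgls))
  } else note("PGLS stage skipped: no trees in config")

  ## --- phylogenetic ANOVA ---------------------------------------------
  beh <- if ("behavior" %in% names(sp_tab))
    behavior_category(sp_tab$behavior) else NULL
  if (!is.null(trees) && !is.null(beh) && sum(!is.na(beh)) >= 4) {
    out$anova <- stage("anova", {
      lapply(names(trees), function(tn) {
        tr <- trees[[tn]]
        line <- lines[[config$anova$line %||% "resA"]]
        rv <- stats::setNames(residual_from_line(sp_tab, line),
                              sp_tab$species)
        keep <- !is.na(beh) & sp_tab$species %in% tr$tip.label
        phylo_anova(rv[keep], beh[keep], tr)
      })
    })
    names(out$anova) <- names(trees)
    note("ANOVA stage: %d tree(s)", length(out$anova))
  } else note("ANOVA stage skipped: no behaviour map or trees")

  ## --- ASR -------------------------------------------------------------
  if (!is.null(trees) && isTRUE(config$asr$run %||% FALSE)) {
    out$asr <- stage("asr", {
      cfg <- mcmc_config(iterations = config$asr$iterations %||% 100000,
                         burnin = config$asr$burnin %||% 5000,
                         seed = config$seed)
      tr <- trees[[1]]
      sel <- sp_tab[sp_tab$species %in% tr$tip.label, ]
      mass <- stats::setNames(sel$est_lnBM, sel$species)
      elong <- stats::setNames(sel$elong, sel$species)
      list(mass = reconstruct_nodes(tr, mass, "A", config = cfg),
           elong = reconstruct_nodes(tr, elong, "A", config = cfg))
    })
    out$nodal_residuals <- nodal_residual_elongation(
      out$asr$mass, out$asr$elong, lines[[config$asr$line %||% "resA"]])
    note("ASR stage: %d nodes", nrow(out$nodal_residuals))
  } else note("ASR stage skipped (set asr: {run: yes})")

  ## --- biomechanics ----------------------------------------------------
  bm_line <- lines[[config$biomech$line %||% "eocene"]]
  model <- lever_model(config$biomech$ancestor_mass %||% 10, bm_line)
  out$biomech <- effort_curve(model)
  note("biomech stage: ancestor %.4g g on line '%s'",
       model$ancestor_mass, bm_line$name %||% "custom")

  out$log <- logl
  class(out) <- "calcelong_run"
  if (!is.null(outdir)) .write_bundle(out, outdir, hash)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

.write_bundle <- function(out, outdir, hash) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    p <- file.path(outdir, paste0(name, ".tsv"))
    con <- file(p, "w")
    writeLines(paste0("# calcelong config ", hash), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  for (nm in c("species", "residuals", "ols", "pgls", "biomech",
               "nodal_residuals"))
    if (!is.null(out[[nm]]) && is.data.frame(out[[nm]])) wr(out[[nm]], nm)
  writeLines(out$log, file.path(outdir, "run.log"))
  invisible(out)
}

#' @export
print.calcelong_run <- function(x, ...) {
  cat("calcelong pipeline run (config", substr(x$config_hash, 1, 8), ")\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
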