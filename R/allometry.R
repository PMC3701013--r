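#' Reference allometric line
#'
#' A straight line in log space against which residuals are computed. The
#' package ships three named lines used throughout the calcaneal analyses:
#' `"resA"` (elongation index on ln body mass: slope -0.068, intercept
#' -0.39), `"resB"` (ln distal segment length on ln body mass: slope 0.25,
#' intercept 0.36) and `"eocene"` (the early-Eocene euprimate elongation
#' line: slope -0.068, intercept -0.386).
#'
#' @param slope,intercept line coefficients (natural-log space, mass in g).
#' @param response which trait the line predicts: `"elong"` for ln(DL/TL) or
#'   `"lnDL"` for ln distal segment length.
#' @param name optional label.
#' @return an object of class `"reference_line"`.
#' @export
reference_line <- function(slope, intercept, response = c("elong", "lnDL"),
                           name = NULL) {
  response <- match.arg(response)
  stopifnot(is.numeric(slope), is.numeric(intercept))
  structure(list(slope = slope, intercept = intercept, response = response,
                 name = name),
            class = "reference_line")
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf("Reference line%s: %s = %.4g * ln(BM) + %.4g\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              if (x$response == "elong") "ln(DL/TL)" else "ln(DL)",
              x$slope, x$intercept))
  invisible(x)
}

#' @rdname reference_line
#' @param which one of `"resA"`, `"resB"`, `"eocene"`.
#' @export
standard_line <- function(which = c("resA", "resB", "eocene")) {
  which <- match.arg(which)
  switch(which,
         resA   = reference_line(-0.068, -0.39,  "elong", "resA"),
         resB   = reference_line(0.25,    0.36,  "lnDL",  "resB"),
         eocene = reference_line(-0.068, -0.386, "elong", "eocene"))
}

#' Body mass estimated from cuboid facet dimensions
#'
#' The cuboid facet area, proxied by the product of its mediolateral width
#' (CW) and dorsoplantar depth (CD), predicts body mass across primates via
#' ln(BM) = a * ln(CW * CD) + b with default coefficients a = 1.3274 and
#' b = 3.0238 (mass in grams, facet dimensions in mm). The anti-logged mass
#' may optionally carry a smearing-type quasi-maximum-likelihood (QMLE)
#' correction, the mean of exp(residuals) of the calibration fit; analyses
#' in log space use uncorrected estimates.
#'
#' @param CW,CD cuboid facet width and depth in mm (vectors recycled).
#' @param slope,intercept calibration coefficients; defaults are the
#'   all-primate calibration values.
#' @param qmle_factor multiplicative correction applied to the anti-logged
#'   mass only (1 = none). A fit from [fit_mass_calibration()] carries its
#'   own factor as `$qmle_factor`.
#' @return a data.frame with columns `ln_g` (ln grams) and `g` (grams).
#' @examples
#' estimate_body_mass(1.76, 1.28) # early-Eocene tarsiiform-sized: ~60 g
#' @export
estimate_body_mass <- function(CW, CD, slope = 1.3274, intercept = 3.0238,
                               qmle_factor = 1) {
  if (any(CW <= 0) || any(CD <= 0))
    stop("facet dimensions must be positive")
  ln_g <- slope * log(CW * CD) + intercept
  data.frame(ln_g = ln_g, g = exp(ln_g) * qmle_factor)
}

#' Calcaneal elongation index
#'
#' ln(DL/TL): the natural log of the ratio of the distal calcaneal segment
#' to total calcaneal length. Always negative, and invariant to a common
#' change of measurement units.
#'
#' @param DL distal segment length (mm).
#' @param TL total calcaneal length (mm).
#' @return ln(DL/TL).
#' @export
elongation_index <- function(DL, TL) {
  if (any(DL <= 0)) stop("DL must be positive")
  if (any(DL >= TL)) stop("DL must be strictly less than TL")
  log(DL / TL)
}

#' Validate a specimen table
#'
#' A specimen table holds one measured calcaneus per row with columns
#' `specimen_id`, `species`, `TL`, `DL`, `CW`, `CD` (all mm) and optionally
#' `known_mass` (g), `higher_taxon` and `behavior`.
#'
#' @param records a data.frame of specimen records.
#' @return `records`, invisibly; stops with the offending rows otherwise.
#' @export
validate_specimens <- function(records) {
  need <- c("specimen_id", "species", "TL", "DL", "CW", "CD")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(records$DL > 0 & records$DL < records$TL &
                   records$CW > 0 & records$CD > 0))
  if (length(bad))
    stop("invalid measurements (need 0 < DL < TL, CW > 0, CD > 0) in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if ("known_mass" %in% names(records)) {
    bad <- which(!is.na(records$known_mass) & records$known_mass <= 0)
    if (length(bad))
      stop("non-positive known_mass in rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  invisible(records)
}

#' Read a specimen CSV
#'
#' @param file path to a CSV with the columns of [validate_specimens()].
#' @return validated data.frame.
#' @export
read_specimens <- function(file) {
  rec <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_specimens(rec)
  rec
}

#' Species means and standard errors of the analysis variables
#'
#' Per-specimen natural-log values are computed first (estimated ln body
#' mass from the cuboid facet, ln DL, ln(DL/TL)) and then averaged within
#' species; standard errors are sample SD / sqrt(n) and are `NA` for
#' single-specimen species.
#'
#' @param records specimen data.frame (see [validate_specimens()]).
#' @param calibration named list or vector with `slope` and `intercept` for
#'   the mass calibration.
#' @return data.frame with one row per species: `species`, `n`, `est_lnBM`,
#'   `est_lnBM_SE`, `lnDL`, `lnDL_SE`, `elong`, `elong_SE`, `behavior`,
#'   `higher_taxon`.
#' @export
species_summary <- function(records,
                            calibration = c(slope = 1.3274,
                                            intercept = 3.0238)) {
  validate_specimens(records)
  lnBM <- estimate_body_mass(records$CW, records$CD,
                             slope = calibration[["slope"]],
                             intercept = calibration[["intercept"]])$ln_g
  lnDL <- log(records$DL)
  elong <- elongation_index(records$DL, records$TL)
  sp <- records$species
  mse <- function(x) {
    m <- tapply(x, sp, mean)
    s <- tapply(x, sp, function(v)
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_)
    list(mean = m, se = s)
  }
  a <- mse(lnBM); b <- mse(lnDL); e <- mse(elong)
  species <- names(a$mean)
  first <- function(col) {
    if (!col %in% names(records)) return(rep(NA_character_, length(species)))
    as.character(tapply(as.character(records[[col]]), sp, `[`, 1))[
      match(species, names(a$mean))]
  }
  data.frame(species = species,
             n = as.integer(table(sp)[species]),
             est_lnBM = as.numeric(a$mean), est_lnBM_SE = as.numeric(a$se),
             lnDL = as.numeric(b$mean), lnDL_SE = as.numeric(b$se),
             elong = as.numeric(e$mean), elong_SE = as.numeric(e$se),
             behavior = first("behavior"),
             higher_taxon = first("higher_taxon"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ordinary least squares with full inference
#'
#' Bivariate OLS returning the full inference set used in the allometric
#' tables: slope and intercept with standard errors, correlation, the
#' two-tailed t-test of the slope against zero on n - 2 degrees of freedom,
#' and 95% confidence intervals from the t quantile. For an elongation
#' ratio regressed on body mass the isometry null is a slope of zero, so
#' `p` is directly the isometry test.
#'
#' @param x,y numeric vectors (covariate, response).
#' @return object of class `"ols_fit"` with elements `slope`, `slope_SE`,
#'   `intercept`, `intercept_SE`, `r`, `r2`, `t`, `p`, `n`, `df`,
#'   `slope_CI95`, `intercept_CI95`, and the underlying `lm` fit.
#' @export
ols_fit <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("`x` is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silence "essentially perfect fit"
  co <- sm$coefficients
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  structure(list(
    slope = co["x", "Estimate"], slope_SE = co["x", "Std. Error"],
    intercept = co["(Intercept)", "Estimate"],
    intercept_SE = co["(Intercept)", "Std. Error"],
    r = sign(co["x", "Estimate"]) * sqrt(sm$r.squared),
    r2 = sm$r.squared,
    t = co["x", "t value"], p = co["x", "Pr(>|t|)"],
    n = n, df = n - 2L,
    slope_CI95 = unname(ci["x", ]),
    intercept_CI95 = unname(ci["(Intercept)", ]),
    lm = fit), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "OLS fit (n = %d): slope %.4f (SE %.4f), intercept %.4f (SE %.4f)\n",
    x$n, x$slope, x$slope_SE, x$intercept, x$intercept_SE))
  cat(sprintf("  r = %.3f, t = %.2f on %d df, two-tailed p = %.4g\n",
              x$r, x$t, x$df, x$p))
  cat(sprintf("  95%% CI slope [%.4f, %.4f], intercept [%.4f, %.4f]\n",
              x$slope_CI95[1], x$slope_CI95[2],
              x$intercept_CI95[1], x$intercept_CI95[2]))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.ols_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::fitted(object$lm))
  object$intercept + object$slope * newdata
}

#' @export
residuals.ols_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
summary.ols_fit <- function(object, ...) summary(object$lm, ...)

#' Fit the body-mass calibration regression
#'
#' OLS of ln(known body mass) on ln(CW * CD) over specimens with known
#' masses. The returned fit also carries `qmle_factor`, the smearing
#' estimator mean(exp(residuals)), applicable when anti-logging predictions.
#'
#' @param records specimen data.frame with a `known_mass` column, or a list
#'   with numeric `CW`, `CD`, `known_mass`.
#' @return an `"ols_fit"` with extra element `qmle_factor`.
#' @export
fit_mass_calibration <- function(records) {
  if (!all(c("CW", "CD", "known_mass") %in% names(records)))
    stop("records must have CW, CD and known_mass")
  keep <- !is.na(records$known_mass)
  if (sum(keep) < 3) stop("need at least 3 records with known mass")
  x <- log(records$CW[keep] * records$CD[keep])
  y <- log(records$known_mass[keep])
  fit <- ols_fit(x, y)
  fit$qmle_factor <- mean(exp(stats::residuals(fit$lm)))
  fit
}

#' Residual from a reference line
#'
#' observed - (slope * ln body mass + intercept), where the observed trait
#' is chosen by the line's `response`: the elongation index for `"elong"`
#' lines, ln DL for `"lnDL"` lines.
#'
#' @param summary a data.frame from [species_summary()] (needs `est_lnBM`
#'   and `elong` or `lnDL`), or a numeric trait vector.
#' @param line a [reference_line()].
#' @param lnBM ln body mass, required when `summary` is a bare vector.
#' @return numeric vector of residuals.
#' @export
residual_from_line <- function(summary, line, lnBM = NULL) {
  if (!inherits(line, "reference_line"))
    stop("`line` must be a reference_line")
  if (is.data.frame(summary)) {
    col <- if (line$response == "elong") "elong" else "lnDL"
    if (!col %in% names(summary))
      stop("summary lacks the '", col, "' column the line's response needs")
    obs <- summary[[col]]
    lnBM <- summary$est_lnBM
  } else {
    if (is.null(lnBM)) stop("supply `lnBM` with a bare trait vector")
    obs <- summary
  }
  obs - (line$slope * lnBM + line$intercept)
}

#' Intercept-on-slope meta-regression across group fits
#'
#' Across a set of group-level allometric fits, regresses intercepts on
#' slopes and returns each group's intercept residual (IR): the observed
#' intercept minus the intercept predicted from the group's slope. Groups
#' with high IR have elevated elongation at any mass for their scaling
#' slope.
#'
#' @param slopes,intercepts numeric vectors (one entry per group), or
#'   `slopes` may be a list of `"ols_fit"` objects.
#' @param labels optional group names.
#' @param line optional [reference_line()]-like coefficients (`slope`,
#'   `intercept`) of a fixed meta-line; if omitted the line is fitted by OLS
#'   across the groups.
#' @return list with `fit` (the meta OLS, or NULL when a fixed line is
#'   given), `line` (slope/intercept used) and `IR` (named residuals).
#' @export
slope_intercept_meta <- function(slopes, intercepts = NULL, labels = NULL,
                                 line = NULL) {
  if (is.list(slopes) && !is.data.frame(slopes)) {
    fits <- slopes
    slopes <- vapply(fits, function(f) f$slope, numeric(1))
    intercepts <- vapply(fits, function(f) f$intercept, numeric(1))
    if (is.null(labels)) labels <- names(fits)
  }
  if (is.null(line)) {
    if (length(slopes) < 3) stop("need at least 3 group fits")
    fit <- ols_fit(slopes, intercepts)
    use <- list(slope = fit$slope, intercept = fit$intercept)
  } else {
    fit <- NULL
    use <- list(slope = line$slope, intercept = line$intercept)
  }
  ir <- intercepts - (use$slope * slopes + use$intercept)
  names(ir) <- labels
  list(fit = fit, line = use, IR = ir)
}

#' Bundled species-mean reference table
#'
#' Species mean values (estimated ln body mass, ln distal segment length,
#' elongation index, behavioural codes and reference-line residuals) for 113
#' extant and fossil euarchontan taxa: the comparative dataset behind the
#' package's reference regressions. Values are natural logs; masses in
#' grams, lengths in mm.
#'
#' @param group `"all"`, `"extant"` or `"fossil"`.
#' @return data.frame with columns `species`, `higher_taxon`, `group`, `n`,
#'   `behavior`, `est_lnBM`, `est_lnBM_SE`, `lnDL`, `lnDL_SE`, `elong`,
#'   `elong_SE`, `resA`, `resB`.
#' @export
species_means <- function(group = c("all", "extant", "fossil")) {
  group <- match.arg(group)
  f <- system.file("extdata", "species_means.tsv", package = "calcelong",
                   mustWork = TRUE)
  d <- utils::read.delim(f, stringsAsFactors = FALSE)
  if (group != "all") d <- d[d$group == group, ]
  d
}

#' Map a behavioural code to an analysis category
#'
#' Combination codes are resolved by precedence: any code containing `SUS`
#' (committed suspension) is excluded (`NA`), otherwise the first listed
#' category wins. `VC` and `VCL/L` map to `"VCL/L"` (acrobatic leaping),
#' `AQ` to `"AQ"` (arboreal quadrupedalism), `SC` and `T` to `"SC/T"`
#' (slow-climbing/terrestrial).
#'
#' @param code character vector of behaviour codes.
#' @return factor with levels `VCL/L`, `AQ`, `SC/T` (NA = excluded).
#' @export
behavior_category <- function(code) {
  out <- rep(NA_character_, length(code))
  code <- toupper(trimws(as.character(code)))
  sus <- grepl("SUS", code)
  out[!sus & grepl("^VC", code)] <- "VCL/L"
  out[!sus & grepl("^AQ", code)] <- "AQ"
  out[!sus & grepl("^(SC|T)", code)] <- "SC/T"
  factor(out, levels = c("VCL/L", "AQ", "SC/T"))
}
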