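#' Simulation specification for the synthetic-data generator
#'
#' Encodes the generative structure the analyses assume: a time-scaled tree,
#' ln body mass evolving by (optionally directional) Brownian motion, an
#' elongation index tied to ln mass by a reference line with group-specific
#' intercept offsets, Brownian (or i.i.d.) residual noise around that line,
#' and log-normal within-species measurement noise on the facet area and
#' segment lengths. Defaults follow the comparative study conditions: a
#' 64-tip tree of root age 60 Ma, the resA elongation line, a Brownian mass
#' rate giving a realistic ~2.3 SD spread of ln mass at the tips, strongly
#' phylogenetic residual noise (the large-sample analyses estimate lambda
#' near 0.95), and 5% measurement CV.
#'
#' @param n_tips number of species.
#' @param tree_model `"birth_death"`, `"balanced"` or `"star"`.
#' @param birth,death birth-death rates per Ma.
#' @param root_age tree depth in Ma.
#' @param fossil_fraction fraction of tips truncated before the present at
#'   uniform random ages.
#' @param lnBM_model a [bm_model()] for ln body mass (g).
#' @param allometry a [reference_line()] linking elongation to ln mass.
#' @param group_offsets named numeric: intercept shift per behavioural
#'   category (empty = no groups).
#' @param residual_sigma2 Brownian rate of the elongation residual noise.
#' @param residual_iid if `TRUE`, residual noise is i.i.d. normal with
#'   variance `residual_sigma2 * root_age` instead of Brownian.
#' @param measurement_cv within-species lognormal coefficient of variation
#'   of CW*CD and of the length measurements.
#' @param specimens_per_species specimens emitted per species.
#' @param calibration mass-calibration coefficients used to invert facet
#'   sizes from ln mass.
#' @param seed integer seed.
#' @return list of class `"sim_spec"`.
#' @export
sim_spec <- function(n_tips = 64, tree_model = c("birth_death", "balanced",
                                                 "star"),
                     birth = 0.15, death = 0.05, root_age = 60,
                     fossil_fraction = 0,
                     lnBM_model = bm_model(sigma2 = 0.09, z_root = 6),
                     allometry = standard_line("resA"),
                     group_offsets = numeric(0),
                     residual_sigma2 = 0.0015, residual_iid = FALSE,
                     measurement_cv = 0.05, specimens_per_species = 3,
                     calibration = c(slope = 1.3274, intercept = 3.0238),
                     seed = 1) {
  tree_model <- match.arg(tree_model)
  if (n_tips < 3) stop("n_tips must be at least 3")
  if (residual_sigma2 < 0 || measurement_cv < 0)
    stop("rates and CVs must be non-negative")
  structure(as.list(environment()), class = "sim_spec")
}

## complete birth-death realisation (extinct lineages kept), for the fossil
## generator and for the tip-count theory checks
.rbd_complete <- function(birth, death, Tmax) {
  ape::rlineage(birth, death, Tmax)
}

#' Simulate a time-scaled tree
#'
#' Reproducible from `(spec, seed)`. Birth-death trees come from a complete
#' birth-death process in which extinct lineages are retained, so fossil
#' tips terminate at their natural extinction times throughout the tree's
#' history — the age structure of a comparative sample that mixes extant
#' species with Paleogene fossils. The simulation horizon is set so the
#' expected tip count matches `n_tips`; realisations are retried (bounded)
#' until enough extant and extinct tips exist, then tips are subsampled to
#' exactly `n_tips` with `fossil_fraction` of them extinct, and the tree is
#' rescaled to `root_age`. Balanced and star trees are deterministic
#' shapes (with `fossil_fraction` applied by truncating pendant edges at
#' uniform random ages, the only option on a shape with no extinction
#' process).
#'
#' @param spec a [sim_spec()].
#' @param seed optional override of `spec$seed`.
#' @param max_tries attempts before giving up on the birth-death process.
#' @return a `"phylo"` object with `n_tips` tips labelled `sp1..spN`.
#' @export
simulate_tree <- function(spec, seed = spec$seed, max_tries = 50) {
  set.seed(seed)
  n <- spec$n_tips
  if (spec$tree_model == "birth_death") {
    b <- spec$birth; d <- spec$death
    if (b <= d) stop("birth rate must exceed death rate")
    n_fossil <- round(spec$fossil_fraction * n)
    n_extant <- n - n_fossil
    ## horizon with expected extant count ~ 1.5 * n for subsampling slack
    Tmax <- log(1.5 * n) / (b - d)
    tr <- NULL
    for (try in seq_len(max_tries)) {
      cand <- .rbd_complete(b, d, Tmax)
      dep <- ape::node.depth.edgelength(cand)
      ntip <- length(cand$tip.label)
      extant <- which(dep[seq_len(ntip)] > max(dep) - 1e-8)
      extinct <- setdiff(seq_len(ntip), extant)
      if (length(extant) >= max(n_extant, 2) &&
          length(extinct) >= n_fossil) {
        keep <- c(sample(extant, n_extant),
                  if (n_fossil > 0) sample(extinct, n_fossil))
        tr <- ape::keep.tip(cand, keep)
        break
      }
    }
    if (is.null(tr))
      stop("birth-death simulation failed to yield enough extant and ",
           "extinct tips after ", max_tries, " attempts")
    tr$node.label <- NULL
  } else {
    tr <- switch(spec$tree_model,
      balanced = ape::compute.brlen(ape::stree(n, type = "balanced"),
                                    power = 1),
      star = ape::stree(n, type = "star"))
    if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
    if (spec$tree_model == "star") tr$edge.length <- rep(1, nrow(tr$edge))
  }
  ## rescale to the requested root age
  dd <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * spec$root_age / max(dd)
  tr$tip.label <- paste0("sp", seq_len(length(tr$tip.label)))
  if (spec$tree_model != "birth_death" && spec$fossil_fraction > 0) {
    k <- max(1L, round(spec$fossil_fraction * n))
    fossils <- sample.int(n, k)
    ages <- node_ages(tr)
    for (tip in fossils) {
      e <- which(tr$edge[, 2] == tip)
      parent_age <- ages[tr$edge[e, 1]]
      cut_age <- stats::runif(1, 0, parent_age)
      tr$edge.length[e] <- parent_age - cut_age
    }
  }
  validate_phylogeny(tr)
  tr
}

## draw one multivariate-normal realisation on the tree
.bm_draw <- function(tree, sigma2, z_root = 0, beta = 0, lambda = 1) {
  V <- scaled_covariance(tree, scaling_params(lambda = lambda))
  L <- chol(V + diag(1e-12, nrow(V)))
  depths <- node_depths(tree)[seq_len(length(tree$tip.label))]
  mu <- z_root + beta * depths
  x <- mu + sqrt(sigma2) * drop(t(L) %*% stats::rnorm(nrow(V)))
  names(x) <- tree$tip.label
  x
}

#' Simulate species-level traits on a tree
#'
#' ln body mass evolves by the spec's Brownian (optionally directional)
#' model; the elongation index is the allometric line evaluated at each
#' species' ln mass, plus the species' group offset, plus residual noise
#' that is itself Brownian on the tree (or i.i.d. when `residual_iid`).
#' Group membership, when offsets are given, is assigned by splitting the
#' tip order into contiguous blocks, giving groups phylogenetic structure.
#'
#' @param tree a `"phylo"` object.
#' @param spec a [sim_spec()].
#' @param seed optional override.
#' @return data.frame with `species`, `lnBM`, `elong`, `behavior`.
#' @export
simulate_traits <- function(tree, spec, seed = spec$seed) {
  set.seed(seed + 1L)
  m <- spec$lnBM_model
  lnBM <- .bm_draw(tree, m$sigma2, m$z_root, m$beta_trend,
                   m$scaling$lambda)
  line <- spec$allometry
  n <- length(lnBM)
  groups <- rep(NA_character_, n)
  offset <- numeric(n)
  if (length(spec$group_offsets)) {
    gnames <- names(spec$group_offsets)
    blocks <- cut(seq_len(n), breaks = length(gnames), labels = gnames)
    groups <- as.character(blocks)
    offset <- spec$group_offsets[groups]
  }
  if (spec$residual_sigma2 > 0) {
    if (spec$residual_iid) {
      eps <- stats::rnorm(n, 0, sqrt(spec$residual_sigma2 * spec$root_age))
      names(eps) <- tree$tip.label
    } else {
      eps <- .bm_draw(tree, spec$residual_sigma2)
    }
  } else eps <- stats::setNames(numeric(n), tree$tip.label)
  elong <- line$slope * lnBM + line$intercept + offset + eps[names(lnBM)]
  ## keep the elongation ratio physically valid (DL < TL)
  elong <- pmin(elong, -1e-3)
  data.frame(species = names(lnBM), lnBM = as.numeric(lnBM),
             elong = as.numeric(elong), behavior = groups,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Emit specimen-level measurement records from species traits
#'
#' Inverts the analysis chain: per specimen, the facet area CW*CD is drawn
#' so the mass calibration maps back to the species ln mass plus lognormal
#' measurement noise, and TL/DL are drawn consistent with the species
#' elongation index plus noise. With `measurement_cv = 0` and one specimen
#' per species the pipeline recovers the traits exactly.
#'
#' @param traits data.frame from [simulate_traits()].
#' @param spec a [sim_spec()].
#' @param seed optional override.
#' @return validated specimen data.frame (see [validate_specimens()]);
#'   `known_mass` holds the true species mass in g.
#' @export
emit_specimens <- function(traits, spec, seed = spec$seed) {
  set.seed(seed + 2L)
  cv <- spec$measurement_cv
  sdlog <- sqrt(log(1 + cv^2))
  k <- spec$specimens_per_species
  a <- spec$calibration[["slope"]]; b <- spec$calibration[["intercept"]]
  rows <- lapply(seq_len(nrow(traits)), function(i) {
    sp <- traits$species[i]
    ln_area <- (traits$lnBM[i] - b) / a + stats::rnorm(k, 0, sdlog)
    ## split area into width x depth with a fixed 4:3 aspect
    CW <- sqrt(exp(ln_area) * 4 / 3)
    CD <- exp(ln_area) / CW
    ## total length loosely isometric with mass; exact value is irrelevant
    ## to the analyses, which only use the DL/TL ratio and facet area
    TL <- exp(0.33 * traits$lnBM[i] + 0.2 + stats::rnorm(k, 0, sdlog))
    ratio <- exp(traits$elong[i] + stats::rnorm(k, 0, sdlog))
    ratio <- pmin(ratio, 0.95)
    DL <- ratio * TL
    data.frame(specimen_id = paste0(sp, "-", seq_len(k)),
               species = sp, TL = TL, DL = DL, CW = CW, CD = CD,
               known_mass = exp(traits$lnBM[i]),
               higher_taxon = NA_character_,
               behavior = traits$behavior[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  validate_specimens(out)
  out
}

#' Synthetic mass-calibration sample
#'
#' Emulates the taxonomically comprehensive calibration dataset behind the
#' facet-area body-mass regression: `n` individuals whose ln body masses
#' span the primate range (defaults ~38 g to ~110 kg), generated around the
#' calibration line with normal residuals whose SD is chosen to give the
#' target r-squared in expectation.
#'
#' @param n individuals (default 129).
#' @param slope,intercept calibration line (ln g on ln mm^2).
#' @param r2 target coefficient of determination (default 0.98).
#' @param lnBM_range range of ln body mass covered.
#' @param seed integer seed.
#' @return data.frame with `CW`, `CD`, `known_mass` ready for
#'   [fit_mass_calibration()].
#' @export
simulate_calibration <- function(n = 129, slope = 1.3274,
                                 intercept = 3.0238, r2 = 0.98,
                                 lnBM_range = c(log(38), log(110000)),
                                 seed = 1) {
  set.seed(seed)
  ln_area <- stats::runif(n, (lnBM_range[1] - intercept) / slope,
                          (lnBM_range[2] - intercept) / slope)
  var_fit <- slope^2 * diff(range(ln_area))^2 / 12
  sd_res <- sqrt(var_fit * (1 - r2) / r2)
  lnBM <- slope * ln_area + intercept + stats::rnorm(n, 0, sd_res)
  CW <- sqrt(exp(ln_area) * 4 / 3)
  data.frame(specimen_id = paste0("cal", seq_len(n)),
             CW = CW, CD = exp(ln_area) / CW,
             known_mass = exp(lnBM), stringsAsFactors = FALSE)
}
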