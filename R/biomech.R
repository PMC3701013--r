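#' Class-2 lever model of calcaneal effort multiplication
#'
#' The distal calcaneal segment is the load arm and the heel the lever arm
#' of a class-2 lever worked by the triceps surae. With total calcaneal
#' length 1 and distal fraction r, statically balancing body weight m
#' requires plantar-flexor force m * r / (1 - r) (gram-equivalents), while
#' the force available at constant effort scales as mass^(2/3) from an
#' ancestral reference state. The allometric line supplies the distal
#' fraction expected at each mass; the model compares effort under those
#' allometric proportions against retaining the ancestor's constant
#' proportions.
#'
#' @param ancestor_mass ancestral body mass in g.
#' @param line a [reference_line()] with response `"elong"`; the default is
#'   the early-Eocene euprimate line (slope -0.068, intercept -0.386).
#' @param muscle_exponent scaling exponent of available muscle force
#'   (default 2/3).
#' @return list of class `"lever_model"` with the ancestor's predicted
#'   distal fraction and required force.
#' @examples
#' m <- lever_model(10)
#' effort_multiplier(100, m, "constant")   # ~2.15, i.e. +115%
#' effort_multiplier(7000, m, "allometric")# ~3.8
#' @export
lever_model <- function(ancestor_mass = 10,
                        line = standard_line("eocene"),
                        muscle_exponent = 2 / 3) {
  if (ancestor_mass <= 0) stop("ancestor_mass must be positive")
  if (line$response != "elong")
    stop("the lever model needs an elongation-index line")
  ratio <- predicted_ratio(ancestor_mass, line)
  structure(list(ancestor_mass = ancestor_mass, line = line,
                 muscle_exponent = muscle_exponent,
                 ancestor_ratio = ratio,
                 ancestor_force = required_force(ancestor_mass, ratio)),
            class = "lever_model")
}

#' @export
print.lever_model <- function(x, ...) {
  cat(sprintf(
    "Lever model: ancestor %.4g g, distal fraction %.3f (%.0f%%), force %.4g g\n",
    x$ancestor_mass, x$ancestor_ratio, 100 * x$ancestor_ratio,
    x$ancestor_force))
  print(x$line)
  cat(sprintf("  available muscle force ~ mass^%.3f\n", x$muscle_exponent))
  invisible(x)
}

#' Distal-segment fraction predicted by an allometric line
#'
#' exp(a * ln(mass) + b): the DL/TL fraction the line predicts at a body
#' mass. For the default euprimate line a 10 g animal carries a distal
#' fraction of about 0.58.
#'
#' @param mass body mass in g.
#' @param line a [reference_line()] with response `"elong"`.
#' @return predicted DL/TL fraction in (0, 1).
#' @export
predicted_ratio <- function(mass, line = standard_line("eocene")) {
  if (any(mass <= 0)) stop("mass must be positive")
  r <- exp(line$slope * log(mass) + line$intercept)
  if (any(r >= 1))
    stop("line predicts a distal fraction >= 1 at this mass; ",
         "the line is invalid there")
  r
}

#' Static plantar-flexor force required to balance body weight
#'
#' For a class-2 lever of unit total length with distal (load-arm)
#' fraction r, balancing mass m requires force m * r / (1 - r), in
#' gram-equivalents.
#'
#' @param mass body mass in g.
#' @param ratio distal fraction in (0, 1).
#' @return force in gram-equivalents.
#' @export
required_force <- function(mass, ratio) {
  if (any(ratio <= 0 | ratio >= 1)) stop("ratio must lie in (0, 1)")
  mass * ratio / (1 - ratio)
}

#' Muscle force available at constant effort
#'
#' ancestor_force * (mass / ancestor_mass)^muscle_exponent: the force the
#' plantar flexors can deliver at the ancestor's effort level, assuming
#' physiological cross-sectional area scales isometrically so force goes as
#' mass^(2/3).
#'
#' @param mass body mass in g.
#' @param model a [lever_model()].
#' @return force in gram-equivalents.
#' @export
available_force <- function(mass, model) {
  if (any(mass <= 0)) stop("mass must be positive")
  model$ancestor_force *
    (mass / model$ancestor_mass)^model$muscle_exponent
}

#' Relative muscular effort at a body mass
#'
#' required_force / available_force, normalised so the ancestor's effort is
#' 1. `mode = "constant"` keeps the ancestor's distal fraction at every
#' mass (effort then grows as mass^(1/3)); `mode = "allometric"` lets the
#' fraction follow the line.
#'
#' @param mass body mass in g (vectorised).
#' @param model a [lever_model()].
#' @param mode `"constant"` or `"allometric"`.
#' @return effort multiplier (1 at the ancestor's mass).
#' @export
effort_multiplier <- function(mass, model,
                              mode = c("constant", "allometric")) {
  mode <- match.arg(mode)
  ratio <- if (mode == "constant") model$ancestor_ratio
           else predicted_ratio(mass, model$line)
  required_force(mass, ratio) / available_force(mass, model)
}

#' Body mass at which a target effort multiplier is reached
#'
#' Inverts [effort_multiplier()] by bracketed root finding (relative
#' tolerance 1e-6). Used, e.g., to find the mass at which a
#' constant-proportion lineage experiences the effort an allometric lineage
#' only meets at 7 kg.
#'
#' @param target effort multiplier (>= 1 above the ancestor's mass).
#' @param model a [lever_model()].
#' @param mode `"constant"` or `"allometric"`.
#' @param interval search bracket in g.
#' @return body mass in g.
#' @export
equivalent_mass <- function(target, model,
                            mode = c("constant", "allometric"),
                            interval = c(1e-3, 1e7)) {
  mode <- match.arg(mode)
  if (target < 0) stop("target must be non-negative")
  f <- function(m) effort_multiplier(m, model, mode) - target
  lo <- f(interval[1]); hi <- f(interval[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop("target effort not reachable within the bracket")
  stats::uniroot(f, interval, tol = 1e-6 * model$ancestor_mass)$root
}

#' Maximum elongation gain at constant muscle effort under size decrease
#'
#' When a lineage shrinks, the effort budget frees up: the distal fraction
#' r at the descendant mass m_d that exactly spends the ancestor's effort
#' solves m_d * r / (1 - r) = available_force(m_d). Returns that maximal
#' fraction and its percent excess over the allometric prediction at the
#' descendant mass.
#'
#' @param ancestor_mass,descendant_mass body masses in g.
#' @param line a [reference_line()] with response `"elong"`.
#' @param muscle_exponent force-scaling exponent.
#' @return list with `ratio` (maximal distal fraction), `allometric_ratio`,
#'   and `pct_increase` (percent above the allometric prediction).
#' @export
constant_effort_max_ratio <- function(ancestor_mass, descendant_mass,
                                      line = standard_line("eocene"),
                                      muscle_exponent = 2 / 3) {
  if (ancestor_mass <= 0 || descendant_mass <= 0)
    stop("masses must be positive")
  model <- lever_model(ancestor_mass, line, muscle_exponent)
  avail <- available_force(descendant_mass, model)
  ## m r / (1 - r) = avail  =>  r = avail / (m + avail)
  r <- avail / (descendant_mass + avail)
  if (r >= 1) stop("no valid distal fraction below 1 at this mass")
  r_allo <- predicted_ratio(descendant_mass, line)
  list(ratio = r, allometric_ratio = r_allo,
       pct_increase = 100 * (r / r_allo - 1))
}

#' Effort-multiplication curves across body mass
#'
#' Tabulates the constant-proportion and allometric-proportion effort
#' multipliers over a mass grid; both equal 1 at the ancestor's mass, and
#' the allometric curve lies below the constant one above it.
#'
#' @param model a [lever_model()].
#' @param masses mass grid in g (default log-spaced from the ancestor's
#'   mass to 7 kg).
#' @return data.frame of class `"effort_curve"` with columns `mass`,
#'   `effort_constant`, `effort_allometric`.
#' @export
effort_curve <- function(model,
                         masses = exp(seq(log(model$ancestor_mass),
                                          log(7000), length.out = 200))) {
  out <- data.frame(
    mass = masses,
    effort_constant = effort_multiplier(masses, model, "constant"),
    effort_allometric = effort_multiplier(masses, model, "allometric"))
  class(out) <- c("effort_curve", "data.frame")
  out
}

#' @export
plot.effort_curve <- function(x, ...) {
  graphics::matplot(x$mass, cbind(x$effort_constant, x$effort_allometric),
                    type = "l", lty = c(2, 1), log = "x",
                    xlab = "body mass (g)",
                    ylab = "relative muscular effort", ...)
  graphics::legend("topleft", c("constant proportions",
                                "allometric proportions"),
                   lty = c(2, 1), bty = "n")
  invisible(x)
}
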