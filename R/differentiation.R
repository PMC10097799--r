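#' Combined shear/flow stimulus
#'
#' The biphasic differentiation stimulus `stim = OSS / 3.75 + FF / 3`
#' combining octahedral shear strain (percent) and fluid-flow speed (um/s).
#'
#' @param oss Octahedral shear strain, percent (non-negative).
#' @param ff Fluid-flow speed, um/s (non-negative).
#' @return Dimensionless stimulus (vectorized).
#' @export
stim_combined <- function(oss, ff) {
  if (any(oss < 0) || any(ff < 0))
    stop("oss and ff must be non-negative", call. = FALSE)
  oss / 3.75 + ff / 3
}

#' Endochondral gate parameters
#'
#' @param strain_threshold Maximum principal strain (percent) below which
#'   ossification is mechanically admissible.
#' @param rho_c Cartilage density fraction that must be exceeded for
#'   bone to form where no bone exists yet; the two values explored are
#'   0.20 and 0.25.
#' @return An object of class `endo_gate_params`.
#' @export
endo_gate_params <- function(strain_threshold = 2, rho_c = 0.25) {
  stopifnot(strain_threshold > 0, rho_c > 0)
  structure(list(strain_threshold = strain_threshold, rho_c = rho_c),
            class = "endo_gate_params")
}

rule_pred <- function(var, lo = -Inf, hi = Inf, lo_closed = FALSE,
                      hi_closed = FALSE, abs = FALSE, equals = NULL) {
  list(var = var, lo = lo, hi = hi, lo_closed = lo_closed,
       hi_closed = hi_closed, abs = abs, equals = equals)
}

rule_row <- function(tissue, ...) list(tissue = tissue, preds = list(...))

#' Mechanoregulatory rule sets
#'
#' Declarative tissue-differentiation rule tables: ordered rules, each a
#' conjunction of interval predicates over the biophysical stimuli, plus a
#' fallback tissue. The five shipped tables are:
#' \describe{
#'   \item{PE / PE-ENDO}{maximum principal strain only: bone `< 2`%,
#'     cartilage `2--4`%, tendon `> 4`% (PE-ENDO additionally passes bone
#'     proposals through the [endochondral_gate()]).}
#'   \item{PE-HS}{Carter-type: with `e1 <= 5`%, compressive hydrostatic
#'     stress above 0.2 MPa gives cartilage, below gives bone; otherwise
#'     tendon (fibrous).}
#'   \item{PE-PP}{Claes-Heigele-type: cartilage for `e1 <= 15`% with
#'     compressive pore pressure `>= 0.15` MPa; bone for `e1 <= 5`% with
#'     `|PP| < 0.15` MPa; otherwise tendon.}
#'   \item{OSS-FF}{Prendergast-type on [stim_combined()]: bone `stim < 1`,
#'     cartilage `1 <= stim <= 3`, tendon `stim > 3`.}
#'   \item{PE-OXY}{oxygen/angiogenesis coupled: hypoxia (`oxygen < 3`%)
#'     gives cartilage regardless of strain; at vascularized sites
#'     (matured-vessel blood supply) fat forms above 25% strain, bone below
#'     2%, tendon between; normoxic but avascular sites produce nothing.}
#' }
#' Interval ties are closed on the cartilage side. Tissue density and
#' oxygen predicates are in percent, stresses in MPa.
#'
#' @param name One of `"PE"`, `"PE-HS"`, `"PE-PP"`, `"OSS-FF"`,
#'   `"PE-OXY"`, `"PE-ENDO"`.
#' @param endo An [endo_gate_params()] (used by `PE-ENDO`).
#' @return An object of class `rule_set` with fields `name`, `rules`,
#'   `fallback`, `tendon_law` (`"strain"` or `"constant"`), `needs_oxygen`
#'   and (for PE-ENDO) `endo`.
#' @export
rule_set <- function(name = c("PE", "PE-HS", "PE-PP", "OSS-FF", "PE-OXY",
                              "PE-ENDO"),
                     endo = endo_gate_params()) {
  name <- match.arg(name)
  base <- switch(
    name,
    "PE" = ,
    "PE-ENDO" = list(
      rules = list(
        rule_row("bone", rule_pred("e1", hi = 2)),
        rule_row("cartilage", rule_pred("e1", lo = 2, hi = 4,
                                        lo_closed = TRUE,
                                        hi_closed = TRUE))),
      fallback = "tendon", tendon_law = "strain", needs_oxygen = FALSE),
    "PE-HS" = list(
      rules = list(
        rule_row("cartilage", rule_pred("e1", hi = 5, hi_closed = TRUE),
                 rule_pred("hydro_comp", lo = 0.2, lo_closed = TRUE)),
        rule_row("bone", rule_pred("e1", hi = 5, hi_closed = TRUE),
                 rule_pred("hydro_comp", hi = 0.2))),
      fallback = "tendon", tendon_law = "constant", needs_oxygen = FALSE),
    "PE-PP" = list(
      rules = list(
        rule_row("cartilage", rule_pred("e1", hi = 15, hi_closed = TRUE),
                 rule_pred("pp", lo = 0.15, lo_closed = TRUE)),
        rule_row("bone", rule_pred("e1", hi = 5, hi_closed = TRUE),
                 rule_pred("pp", hi = 0.15, abs = TRUE))),
      fallback = "tendon", tendon_law = "constant", needs_oxygen = FALSE),
    "OSS-FF" = list(
      rules = list(
        rule_row("bone", rule_pred("stim", hi = 1)),
        rule_row("cartilage", rule_pred("stim", lo = 1, hi = 3,
                                        lo_closed = TRUE,
                                        hi_closed = TRUE))),
      fallback = "tendon", tendon_law = "constant", needs_oxygen = FALSE),
    "PE-OXY" = list(
      rules = list(
        rule_row("cartilage", rule_pred("oxygen", hi = 3)),
        rule_row("fat", rule_pred("oxygen", lo = 3, lo_closed = TRUE),
                 rule_pred("blood", equals = TRUE),
                 rule_pred("e1", lo = 25)),
        rule_row("bone", rule_pred("oxygen", lo = 3, lo_closed = TRUE),
                 rule_pred("blood", equals = TRUE),
                 rule_pred("e1", hi = 2)),
        rule_row("tendon", rule_pred("oxygen", lo = 3, lo_closed = TRUE),
                 rule_pred("blood", equals = TRUE),
                 rule_pred("e1", lo = 2, hi = 25, lo_closed = TRUE,
                           hi_closed = TRUE)),
        rule_row("none", rule_pred("oxygen", lo = 3, lo_closed = TRUE),
                 rule_pred("blood", equals = FALSE))),
      fallback = "none", tendon_law = "strain", needs_oxygen = TRUE))
  rs <- c(list(name = name), base)
  if (name == "PE-ENDO") rs$endo <- endo
  structure(rs, class = "rule_set")
}

eval_pred <- function(pred, data) {
  x <- data[[pred$var]]
  if (is.null(x))
    stop("stimulus '", pred$var, "' missing from classification input",
         call. = FALSE)
  if (!is.null(pred$equals)) return(x == pred$equals)
  if (pred$abs) x <- abs(x)
  lo_ok <- if (pred$lo_closed) x >= pred$lo else x > pred$lo
  hi_ok <- if (pred$hi_closed) x <= pred$hi else x < pred$hi
  lo_ok & hi_ok
}

rule_matches <- function(rule, data) {
  m <- TRUE
  for (p in rule$preds) m <- m & eval_pred(p, data)
  m
}

# Derived stimulus columns shared by all rule sets.
augment_stimuli <- function(data) {
  if (is.null(data$hydro_comp) && !is.null(data$hydro))
    data$hydro_comp <- -data$hydro
  if (is.null(data$stim) && !is.null(data$oss) && !is.null(data$ff))
    data$stim <- stim_combined(data$oss, data$ff)
  data
}

#' Classify elements into the tissue produced
#'
#' Applies a [rule_set()] to per-element stimulus data: the first matching
#' rule wins, the fallback tissue covers the rest. `"none"` means no tissue
#' is produced this iteration.
#'
#' @param rs A `rule_set` (validated tables ship with the package).
#' @param data List or data frame of per-element stimuli; recognized
#'   entries: `e1` (percent), `hydro` (MPa), `pp` (MPa, compression
#'   positive), `oss` (percent), `ff` (um/s), `oxygen` (percent), `blood`
#'   (logical). Derived: `hydro_comp = -hydro`, `stim` via
#'   [stim_combined()].
#' @return Character vector of tissue labels (`"fat"`, `"tendon"`,
#'   `"cartilage"`, `"bone"`, `"none"`).
#' @export
classify_elements <- function(rs, data) {
  if (!inherits(rs, "rule_set")) stop("unvalidated rule set", call. = FALSE)
  data <- augment_stimuli(as.list(data))
  n <- max(vapply(data, length, 1L))
  out <- rep(NA_character_, n)
  for (rule in rs$rules) {
    m <- rule_matches(rule, data)
    hit <- is.na(out) & m
    out[hit] <- rule$tissue
  }
  out[is.na(out)] <- rs$fallback
  out
}

#' Classify a single stimulus tuple
#'
#' Scalar convenience wrapper around [classify_elements()].
#'
#' @inheritParams classify_elements
#' @param ... Named stimuli, e.g. `e1 = 3`, `oxygen = 2`, `blood = TRUE`.
#' @return A single tissue label.
#' @export
classify <- function(rs, ...) classify_elements(rs, list(...))

#' Validate exclusivity of a rule set
#'
#' Randomized coverage check: draws stimulus tuples across the physiologic
#' ranges and verifies that no tuple matches more than one rule (with the
#' fallback, every tuple then maps to exactly one tissue).
#'
#' @param rs A `rule_set`.
#' @param n Number of random tuples.
#' @param seed RNG seed for reproducibility.
#' @return Invisibly, a list with `max_matches` (must be <= 1) and `n`.
#'   Errors if two rules overlap.
#' @export
validate_rule_set <- function(rs, n = 2000, seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  data <- augment_stimuli(list(
    e1 = stats::runif(n, -5, 45), hydro = stats::runif(n, -1, 1),
    pp = stats::runif(n, -1, 1), oss = stats::runif(n, 0, 25),
    ff = stats::runif(n, 0, 12), oxygen = stats::runif(n, 0, 100),
    blood = sample(c(TRUE, FALSE), n, replace = TRUE)))
  counts <- integer(n)
  for (rule in rs$rules) counts <- counts + as.integer(rule_matches(rule, data))
  if (max(counts) > 1L)
    stop("rule set '", rs$name, "' has overlapping rules", call. = FALSE)
  invisible(list(max_matches = max(counts), n = n))
}

#' Endochondral ossification gate
#'
#' Bone may only form through ossification of cartilage or apposition on
#' existing bone: a proposed bone classification passes only if the
#' maximum principal strain is below the strain threshold AND the element
#' already holds cartilage above `rho_c` OR any bone. Blocked proposals
#' produce nothing this iteration; non-bone proposals pass unchanged.
#'
#' @param proposed Character vector of proposed tissue labels.
#' @param e1 Maximum principal strain, percent.
#' @param rho_c,rho_b Current cartilage and bone density fractions.
#' @param params An [endo_gate_params()].
#' @return Character vector of allowed tissue labels.
#' @export
endochondral_gate <- function(proposed, e1, rho_c, rho_b,
                              params = endo_gate_params()) {
  allowed <- e1 < params$strain_threshold &
    (rho_c > params$rho_c | rho_b > 0)
  ifelse(proposed == "bone" & !allowed, "none", proposed)
}

#' Strain-dependent tendon production rate law
#'
#' Continuous piecewise-linear default: zero production at zero strain,
#' rising linearly to the peak rate at `peak_strain`, falling linearly back
#' to zero at `zero_strain`, and zero beyond (tissue production decreases
#' with strain above about 15%).
#'
#' @param e1 Maximum principal strain, percent (non-negative, vectorized).
#' @param peak_rate Peak production rate (fraction/day); default 0.02, the
#'   default daily production rate.
#' @param peak_strain Strain (percent) of peak production.
#' @param zero_strain Strain (percent) at which production returns to zero.
#' @return Production rate(s), fraction/day.
#' @export
tendon_rate_law <- function(e1, peak_rate = 0.02, peak_strain = 15,
                            zero_strain = 30) {
  if (any(e1 < 0)) stop("negative strain", call. = FALSE)
  up <- peak_rate * e1 / peak_strain
  down <- peak_rate * (zero_strain - e1) / (zero_strain - peak_strain)
  pmax(0, ifelse(e1 <= peak_strain, up, pmin(down, peak_rate)))
}

#' Recover a classification boundary by bisection
#'
#' Bisects one stimulus axis against the classifier until the label switch
#' is bracketed to `tol`, holding the remaining stimuli fixed.
#'
#' @param rs A `rule_set`.
#' @param var Stimulus name to bisect over (e.g. `"e1"`, `"oxygen"`).
#' @param lower,upper Bracket; the labels at the two ends must differ. If
#'   the bracket spans several boundaries, the one adjacent to the lower
#'   end's label is returned.
#' @param fixed Named list of the remaining stimuli.
#' @param tol Bracket tolerance.
#' @return Midpoint of the final bracket (the boundary value).
#' @export
classification_boundary <- function(rs, var, lower, upper,
                                    fixed = list(), tol = 1e-6) {
  lab <- function(x) {
    fixed[[var]] <- x
    classify_elements(rs, fixed)
  }
  lab_lo <- lab(lower)
  threshold_recover(function(x) lab(x) != lab_lo, lower, upper, tol)
}

#' Phase diagram of a rule set over a stimulus pair
#'
#' Tabulates the classified tissue over a grid of two stimuli, holding the
#' others fixed — a quick way to visualize a rule table or check an edited
#' one.
#'
#' @param rs A `rule_set`.
#' @param var_x,var_y Stimulus names for the grid axes.
#' @param x,y Numeric grid values.
#' @param fixed Named list of the remaining stimuli.
#' @return Character matrix of tissue labels with `x` values as rows and
#'   `y` values as columns (dimnames carry the grid values).
#' @export
phase_diagram <- function(rs, var_x, var_y, x, y, fixed = list()) {
  grid <- expand.grid(x = x, y = y)
  data <- fixed
  data[[var_x]] <- grid$x
  data[[var_y]] <- grid$y
  labs <- classify_elements(rs, data)
  matrix(labs, length(x), length(y),
         dimnames = list(format(x, trim = TRUE),
                         format(y, trim = TRUE)))
}

#' Recover a predicate switching point by bisection
#'
#' Generic bisection for a monotone logical predicate: `f(lower)` must be
#' `FALSE` and `f(upper)` `TRUE`.
#'
#' @param f Vector-unaware predicate function of one numeric argument.
#' @param lower,upper Bracket.
#' @param tol Bracket tolerance.
#' @return Midpoint of the final bracket.
#' @export
threshold_recover <- function(f, lower, upper, tol = 1e-6) {
  flo <- f(lower); fhi <- f(upper)
  if (identical(flo, fhi))
    stop("predicate does not switch over the bracket", call. = FALSE)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (identical(f(mid), fhi)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}
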