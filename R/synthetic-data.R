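#' Ground-truth clone specification for the synthetic-data generator
#'
#' A `clone_spec` bundles the true parameters that drive one simulated
#' clone: the quadratic-plateau growth curve (`g_intercept`, `g_slope`,
#' `g_breakpoint` — the true ILL for somatic growth), the age-at-first-
#' reproduction profile, the saturating clutch-size curve, survival, and
#' noise/scale parameters.
#'
#' @param clone_id Clone label (e.g. `"B2"`).
#' @param g_intercept True growth-curve intercept b0 (day^-1); may be
#'   negative (a positive threshold food level).
#' @param g_slope True initial slope b1 (day^-1 per mg C L^-1), positive.
#' @param g_breakpoint True break-point / ILL (mg C L^-1), positive.
#' @param afr_min Age at first reproduction at food saturation (days).
#' @param afr_max Age at first reproduction near the threshold food level
#'   (days); must be >= `afr_min`.
#' @param clutch_max Mean clutch size at saturation (eggs).
#' @param clutch_halfsat Half-saturation food concentration of the clutch
#'   curve (mg C L^-1).
#' @param survival_prob Probability of surviving to first reproduction, in
#'   (0, 1].
#' @param g_noise_sd Additive Gaussian noise on the growth rate (day^-1).
#' @param clutch_dispersion Negative-binomial size parameter for clutch
#'   counts (larger = closer to Poisson); `Inf` gives exact Poisson draws.
#' @param initial_mass_mean Mean neonate dry mass (µg).
#' @param initial_mass_cv Coefficient of variation of neonate dry mass.
#' @return An object of class `clone_spec`.
#' @export
clone_spec <- function(clone_id,
                       g_intercept = -0.05,
                       g_slope = 1.2,
                       g_breakpoint = 0.7,
                       afr_min = 7,
                       afr_max = 13,
                       clutch_max = 15,
                       clutch_halfsat = 0.12,
                       survival_prob = 0.97,
                       g_noise_sd = 0.03,
                       clutch_dispersion = 15,
                       initial_mass_mean = 1.6,
                       initial_mass_cv = 0.1) {
  stopifnot(is.character(clone_id), length(clone_id) == 1L, nzchar(clone_id))
  if (!is.finite(g_breakpoint) || g_breakpoint <= 0) {
    stop("`g_breakpoint` must be positive")
  }
  if (!is.finite(g_slope) || g_slope <= 0) stop("`g_slope` must be positive")
  if (afr_min > afr_max) stop("`afr_min` must not exceed `afr_max`")
  if (afr_min <= 0) stop("`afr_min` must be positive")
  if (!is.finite(survival_prob) || survival_prob <= 0 || survival_prob > 1) {
    stop("`survival_prob` must be in (0, 1]")
  }
  for (nm in c("g_noise_sd", "clutch_dispersion", "initial_mass_mean",
               "initial_mass_cv", "clutch_max", "clutch_halfsat")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("`", nm, "` must be a non-negative number")
    }
  }
  structure(
    list(clone_id = clone_id, g_intercept = g_intercept, g_slope = g_slope,
         g_breakpoint = g_breakpoint, afr_min = afr_min, afr_max = afr_max,
         clutch_max = clutch_max, clutch_halfsat = clutch_halfsat,
         survival_prob = survival_prob, g_noise_sd = g_noise_sd,
         clutch_dispersion = clutch_dispersion,
         initial_mass_mean = initial_mass_mean,
         initial_mass_cv = initial_mass_cv),
    class = "clone_spec"
  )
}

#' Default four-clone ground truth
#'
#' Four simulated clones whose growth-curve truths span the pond/lake range
#' of incipient limiting levels observed in *Daphnia magna* (ILL roughly
#' 0.65-1.05 mg C L^-1) with plateau growth rates near 0.38-0.50 day^-1.
#' Clutch and maturation parameters are set so the emergent early-life
#' intrinsic rate of increase saturates around 0.33-0.42 day^-1, with one
#' clone (D4) saturating only at clearly higher food.
#'
#' @return A named list of four [clone_spec()] objects (B2, B3, D2, D4).
#' @export
default_clone_specs <- function() {
  list(
    B2 = clone_spec("B2", g_intercept = -0.05, g_slope = 1.27,
                    g_breakpoint = 0.74, clutch_max = 15,
                    clutch_halfsat = 0.06),
    B3 = clone_spec("B3", g_intercept = -0.05, g_slope = 1.37,
                    g_breakpoint = 0.65, clutch_max = 13,
                    clutch_halfsat = 0.06),
    D2 = clone_spec("D2", g_intercept = -0.05, g_slope = 1.07,
                    g_breakpoint = 1.02, clutch_max = 19,
                    clutch_halfsat = 0.08),
    D4 = clone_spec("D4", g_intercept = -0.05, g_slope = 0.82,
                    g_breakpoint = 1.05, clutch_max = 10,
                    clutch_halfsat = 0.45)
  )
}

#' Experimental design for the food gradient
#'
#' @param concentrations Nominal initial food concentrations (mg C L^-1),
#'   strictly positive and strictly increasing.
#' @param replicates_per_cell Individuals per clone x concentration cell.
#' @param seed Integer seed controlling dataset generation.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(concentrations, replicates_per_cell, seed = 1L) {
  stopifnot(is.numeric(concentrations), length(concentrations) >= 1L)
  if (any(concentrations <= 0)) stop("concentrations must be strictly positive")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  if (replicates_per_cell < 1) stop("`replicates_per_cell` must be >= 1")
  structure(
    list(concentrations = as.numeric(concentrations),
         replicates_per_cell = as.integer(replicates_per_cell),
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' Standard 12-concentration, 10-replicate design
#'
#' The twelve nominal *A. obliquus* concentrations 0.0125, 0.025, 0.05, 0.1,
#' 0.15, 0.25, 0.35, 0.5, 1.0, 1.5, 2.5 and 4.5 mg C L^-1 with ten
#' replicates per clone x concentration cell (120 individuals per clone; 480
#' for four clones).
#'
#' @param seed Integer seed (default 1).
#' @return An `experiment_design` object.
#' @export
default_design <- function(seed = 1L) {
  experiment_design(
    concentrations = c(0.0125, 0.025, 0.05, 0.1, 0.15, 0.25, 0.35, 0.5,
                       1.0, 1.5, 2.5, 4.5),
    replicates_per_cell = 10L,
    seed = seed
  )
}

true_growth_curve <- function(spec, concentration) {
  p <- quadplateau_params(spec$g_intercept, spec$g_slope, spec$g_breakpoint)
  pmax(quadplateau_predict(p, concentration), 0)
}

true_afr <- function(spec, concentration) {
  frac <- pmax(0, 1 - concentration / spec$g_breakpoint)
  as.integer(ceiling(spec$afr_min + (spec$afr_max - spec$afr_min) * frac))
}

true_clutch_mean <- function(spec, concentration) {
  spec$clutch_max * concentration / (concentration + spec$clutch_halfsat)
}

#' Draw one simulated individual
#'
#' Samples a single animal at one food concentration from a clone's ground
#' truth, using the current RNG stream. Survival is Bernoulli; initial dry
#' mass is log-normal; the observed growth rate is the true quadratic-plateau
#' value (truncated below at zero) plus additive Gaussian noise (negative
#' observed rates are allowed — mass loss near the threshold food level);
#' the age at first reproduction decreases linearly with food from `afr_max`
#' to `afr_min` at the break-point and is rounded up to whole days (daily
#' inspections); the clutch is negative-binomial with a saturating mean;
#' final mass is `initial_mass * exp(g * afr)`. Non-survivors carry no final
#' mass, age or clutch.
#'
#' @param spec A [clone_spec()].
#' @param concentration Food concentration (mg C L^-1), positive.
#' @return A one-row tibble in the individual-record schema.
#' @export
sample_individual <- function(spec, concentration) {
  stopifnot(inherits(spec, "clone_spec"))
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration <= 0) {
    stop("`concentration` must be a single positive number")
  }
  survived <- stats::runif(1) <= spec$survival_prob
  sdlog <- sqrt(log(1 + spec$initial_mass_cv^2))
  meanlog <- log(spec$initial_mass_mean) - sdlog^2 / 2
  m0 <- stats::rlnorm(1, meanlog, sdlog)
  if (!survived) {
    return(tibble::tibble(
      clone_id = spec$clone_id, concentration = concentration,
      initial_mass = m0, final_mass = NA_real_,
      age_first_repro = NA_integer_, clutch_size = NA_integer_,
      survived = FALSE
    ))
  }
  g_true <- true_growth_curve(spec, concentration)
  g_obs <- g_true + if (spec$g_noise_sd > 0) {
    stats::rnorm(1, 0, spec$g_noise_sd)
  } else 0
  afr <- true_afr(spec, concentration)
  mu <- true_clutch_mean(spec, concentration)
  clutch <- if (is.infinite(spec$clutch_dispersion)) {
    stats::rpois(1, mu)
  } else {
    stats::rnbinom(1, size = spec$clutch_dispersion, mu = mu)
  }
  tibble::tibble(
    clone_id = spec$clone_id, concentration = concentration,
    initial_mass = m0, final_mass = m0 * exp(g_obs * afr),
    age_first_repro = afr, clutch_size = as.integer(clutch),
    survived = TRUE
  )
}

# vectorized cell draw used by generate_dataset: same distributions as
# sample_individual, one block of RNG calls per clone x concentration cell
sample_stratum <- function(spec, concentration, n) {
  survived <- stats::runif(n) <= spec$survival_prob
  sdlog <- sqrt(log(1 + spec$initial_mass_cv^2))
  meanlog <- log(spec$initial_mass_mean) - sdlog^2 / 2
  m0 <- stats::rlnorm(n, meanlog, sdlog)
  ns <- sum(survived)
  final_mass <- rep(NA_real_, n)
  afr <- rep(NA_integer_, n)
  clutch <- rep(NA_integer_, n)
  if (ns > 0L) {
    g_true <- true_growth_curve(spec, concentration)
    g_obs <- g_true + if (spec$g_noise_sd > 0) {
      stats::rnorm(ns, 0, spec$g_noise_sd)
    } else 0
    a <- true_afr(spec, concentration)
    mu <- true_clutch_mean(spec, concentration)
    cl <- if (is.infinite(spec$clutch_dispersion)) {
      stats::rpois(ns, mu)
    } else {
      stats::rnbinom(ns, size = spec$clutch_dispersion, mu = mu)
    }
    afr[survived] <- a
    final_mass[survived] <- m0[survived] * exp(g_obs * a)
    clutch[survived] <- as.integer(cl)
  }
  tibble::tibble(
    clone_id = rep(spec$clone_id, n), concentration = rep(concentration, n),
    initial_mass = m0, final_mass = final_mass,
    age_first_repro = afr, clutch_size = clutch, survived = survived
  )
}

#' Generate a full synthetic experiment
#'
#' One simulated individual per clone x concentration x replicate,
#' deterministic given the design's seed. The generating truth (true ILL,
#' plateau, intercept, slope and TFL of each clone's growth curve) travels
#' with the table as the `"truth"` attribute, retrievable with
#' [dataset_truth()], so parameter-recovery tests can compare estimates
#' against it.
#'
#' @param design An [experiment_design()].
#' @param specs A list of [clone_spec()] objects with distinct `clone_id`s.
#' @param seed Overrides `design$seed` when given.
#' @return A tibble of individual records (one row per animal) with a
#'   `"truth"` attribute.
#' @export
#' @examples
#' d <- generate_dataset(default_design(seed = 42), default_clone_specs())
#' nrow(d)  # 480
generate_dataset <- function(design, specs, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"), is.list(specs))
  if (length(specs) == 0L) stop("`specs` must be non-empty")
  ids <- vapply(specs, function(s) s$clone_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate clone_ids in `specs`: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  set.seed(if (is.null(seed)) design$seed else as.integer(seed))
  rows <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    cells <- lapply(design$concentrations, function(conc) {
      sample_stratum(spec, conc, design$replicates_per_cell)
    })
    rows[[k]] <- dplyr::bind_rows(cells)
  }
  out <- dplyr::bind_rows(rows)
  specs <- unname(specs)
  truth <- tibble::tibble(
    clone_id = unname(ids),
    true_ill_g = vapply(specs, function(s) s$g_breakpoint, numeric(1)),
    true_b0_g = vapply(specs, function(s) s$g_intercept, numeric(1)),
    true_b1_g = vapply(specs, function(s) s$g_slope, numeric(1)),
    true_plateau_g = vapply(specs, function(s) {
      s$g_intercept + s$g_slope * s$g_breakpoint / 2
    }, numeric(1)),
    true_tfl_g = vapply(specs, function(s) {
      derive_tfl(quadplateau_params(s$g_intercept, s$g_slope, s$g_breakpoint))
    }, numeric(1)),
    survival_prob = vapply(specs, function(s) s$survival_prob, numeric(1))
  )
  attr(out, "truth") <- truth
  out
}

#' Generating truth of a synthetic dataset
#'
#' @param dataset A table produced by [generate_dataset()].
#' @return The truth tibble stored alongside the records (one row per
#'   clone), or `NULL` for real data.
#' @export
dataset_truth <- function(dataset) {
  attr(dataset, "truth")
}
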