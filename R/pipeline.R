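#' Read an individual-records CSV
#'
#' Parses the standard records schema: columns `clone_id`,
#' `concentration_mgC_per_L`, `initial_mass_ug`, `final_mass_ug`,
#' `age_first_repro_d`, `clutch_size`, `survived`. Empty cells map to
#' missing fields. Row-wise invariants are validated (positive
#' concentrations and masses, age >= 1, clutch >= 0, and non-survivors must
#' carry no final mass, age or clutch); every violation is reported with its
#' row number before the read aborts.
#'
#' @param path Path to a UTF-8 comma-separated file with a header.
#' @return A tibble of individual records (internal column names
#'   `clone_id`, `concentration`, `initial_mass`, `final_mass`,
#'   `age_first_repro`, `clutch_size`, `survived`).
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           clone_id = readr::col_character(),
                           concentration_mgC_per_L = readr::col_double(),
                           initial_mass_ug = readr::col_double(),
                           final_mass_ug = readr::col_double(),
                           age_first_repro_d = readr::col_double(),
                           clutch_size = readr::col_double(),
                           survived = readr::col_logical()
                         ))
  req <- c("clone_id", "concentration_mgC_per_L", "initial_mass_ug",
           "final_mass_ug", "age_first_repro_d", "clutch_size", "survived")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  rec <- tibble::tibble(
    clone_id = raw$clone_id,
    concentration = raw$concentration_mgC_per_L,
    initial_mass = raw$initial_mass_ug,
    final_mass = raw$final_mass_ug,
    age_first_repro = raw$age_first_repro_d,
    clutch_size = raw$clutch_size,
    survived = raw$survived
  )
  problems <- character()
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) {
      problems <<- c(problems,
                     sprintf("row %d: %s", rows, msg))
    }
  }
  bad(is.na(rec$clone_id) | !nzchar(rec$clone_id), "missing clone_id")
  bad(is.na(rec$concentration) | rec$concentration <= 0,
      "concentration must be positive")
  bad(is.na(rec$initial_mass) | rec$initial_mass <= 0,
      "initial_mass must be positive")
  bad(!is.na(rec$final_mass) & rec$final_mass <= 0,
      "final_mass must be positive when present")
  bad(!is.na(rec$age_first_repro) & rec$age_first_repro < 1,
      "age_first_repro must be >= 1 when present")
  bad(!is.na(rec$clutch_size) & rec$clutch_size < 0,
      "clutch_size must be >= 0 when present")
  bad(is.na(rec$survived), "survived flag missing")
  nonsurv <- rec$survived %in% FALSE
  bad(nonsurv & (!is.na(rec$final_mass) | !is.na(rec$age_first_repro) |
                   !is.na(rec$clutch_size)),
      "non-survivor must have empty final_mass, age_first_repro and clutch_size")
  bad(rec$survived %in% TRUE &
        (is.na(rec$final_mass) | is.na(rec$age_first_repro) |
           is.na(rec$clutch_size)),
      "survivor must have final_mass, age_first_repro and clutch_size")
  if (length(problems)) {
    stop("invalid records in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }
  rec
}

#' Write individual records (and truth sidecar) to CSV
#'
#' Writes the standard records schema. When the table carries a generating
#' truth (see [generate_dataset()]), a `<path>_truth.csv` sidecar with one
#' row per clone is written next to it.
#'
#' @param records Individual-record table.
#' @param path Output CSV path.
#' @return Invisibly, the path(s) written.
#' @export
write_records_csv <- function(records, path) {
  check_records(records)
  out <- tibble::tibble(
    clone_id = records$clone_id,
    concentration_mgC_per_L = records$concentration,
    initial_mass_ug = records$initial_mass,
    final_mass_ug = records$final_mass,
    age_first_repro_d = records$age_first_repro,
    clutch_size = records$clutch_size,
    survived = records$survived
  )
  readr::write_csv(out, path, na = "")
  paths <- path
  truth <- dataset_truth(records)
  if (!is.null(truth)) {
    tpath <- sub("\\.csv$", "", path)
    tpath <- paste0(tpath, "_truth.csv")
    readr::write_csv(truth, tpath, na = "NA")
    paths <- c(paths, tpath)
  }
  invisible(paths)
}

#' Pipeline configuration
#'
#' @param input_path Path to a records CSV; `NULL` (default) generates a
#'   synthetic dataset from `design` and `specs`.
#' @param design [experiment_design()] used when simulating.
#' @param specs List of [clone_spec()]s used when simulating.
#' @param traits Subset of `c("g", "r")`: somatic growth rate and/or
#'   intrinsic rate of increase.
#' @param models Subset of `c("quadratic_plateau", "hockey_stick")`.
#' @param n_resamples Bootstrap iterations per clone x trait x model.
#' @param ci_level Confidence level for bootstrap percentile intervals.
#' @param lx_scope Survival scope, `"stratum"` or `"clone"`.
#' @param fit_scope Fit to `"individual_points"` (default) or
#'   `"stratum_means"`.
#' @param seed Master seed: drives simulation and every bootstrap stream.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_path = NULL,
                            design = default_design(),
                            specs = default_clone_specs(),
                            traits = c("g", "r"),
                            models = c("quadratic_plateau", "hockey_stick"),
                            n_resamples = 1000L,
                            ci_level = 0.95,
                            lx_scope = c("stratum", "clone"),
                            fit_scope = c("individual_points", "stratum_means"),
                            seed = 1L) {
  traits <- match.arg(traits, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  lx_scope <- match.arg(lx_scope)
  fit_scope <- match.arg(fit_scope)
  if (length(traits) == 0L || length(models) == 0L) {
    stop("`traits` and `models` must be non-empty")
  }
  structure(
    list(input_path = input_path, design = design, specs = specs,
         traits = traits, models = models,
         n_resamples = as.integer(n_resamples), ci_level = ci_level,
         lx_scope = lx_scope, fit_scope = fit_scope,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stratum_means <- function(obs, value_col) {
  agg <- dplyr::summarise(
    dplyr::group_by(obs, .data$concentration),
    y = mean(.data[[value_col]]), .groups = "drop")
  tibble::tibble(concentration = agg$concentration, y = agg$y)
}

#' Run the full ILL analysis pipeline
#'
#' Reads (or simulates) individual records, computes per-individual somatic
#' growth rates and Euler-Lotka intrinsic rates of increase, fits the
#' requested plateau models per clone x trait, bootstraps confidence
#' intervals for the ILL, plateau elevation and TFL (growth-stratified
#' scheme for `g`; individual-level scheme for `r`), and derives
#' CI-overlap clone orderings per trait x model x statistic. All randomness
#' derives from `config$seed`; identical configs give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `illfit_results`: `results` (one row per clone x
#'   trait x model with estimates, CIs and diagnostics), `orderings`
#'   (tibble of order strings), `bootstraps` (nested `illfit_bootstrap`
#'   objects), `records`, `report` (character lines: config echo, seeds,
#'   warnings, accounting of every individual).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warn_log <- character()
  note <- function(...) warn_log <<- c(warn_log, sprintf(...))

  records <- if (!is.null(config$input_path)) {
    read_records_csv(config$input_path)
  } else {
    generate_dataset(config$design, config$specs, seed = config$seed)
  }
  clones <- unique(records$clone_id)

  rows <- list()
  boots <- list()
  ord_rows <- list()
  combo <- 0L
  for (trait in config$traits) {
    for (model in config$models) {
      per_clone <- list()
      for (clone in clones) {
        combo <- combo + 1L
        rec <- records[records$clone_id == clone, , drop = FALSE]
        bseed <- config$seed + 7919L * combo
        scheme <- if (trait == "g") "growth_stratified" else "r_individual"
        bcfg <- bootstrap_config(config$n_resamples, config$ci_level,
                                 seed = bseed, scheme = scheme)
        bt <- withCallingHandlers(
          if (trait == "g") {
            if (config$fit_scope == "stratum_means") {
              obs <- growth_observations(rec)
              m <- stratum_means(obs, "g")
              rec_m <- tibble::tibble(
                clone_id = clone, concentration = m$concentration,
                initial_mass = 1, final_mass = exp(m$y),
                age_first_repro = 1, clutch_size = 1L, survived = TRUE)
              bootstrap_growth_fit(rec_m, bcfg, model)
            } else {
              bootstrap_growth_fit(rec, bcfg, model)
            }
          } else {
            bootstrap_r_fit(rec, bcfg, model, lx_scope = config$lx_scope)
          },
          warning = function(w) {
            note("WARN [%s/%s/%s]: %s", clone, trait, model,
                 conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        )
        if (bt$point$optimizer_tag != "primary") {
          note("WARN [%s/%s/%s]: fallback optimizer used for point fit",
               clone, trait, model)
        }
        boots[[paste(clone, trait, model, sep = ".")]] <- bt
        p <- bt$point
        rows[[length(rows) + 1L]] <- tibble::tibble(
          clone_id = clone, trait = trait, model = model,
          n_obs = p$n_obs,
          b0 = p$params$b0, b1 = p$params$b1,
          ill = p$ill,
          ill_lower = bt$statistics$ill$ci$lower,
          ill_upper = bt$statistics$ill$ci$upper,
          plateau = p$plateau_elevation,
          plateau_lower = bt$statistics$plateau$ci$lower,
          plateau_upper = bt$statistics$plateau$ci$upper,
          tfl = p$tfl,
          tfl_lower = bt$statistics$tfl$ci$lower,
          tfl_upper = bt$statistics$tfl$ci$upper,
          rss = p$rss, converged = p$converged,
          optimizer = p$optimizer_tag, boundary = p$boundary,
          n_failed_resamples = bt$n_failed
        )
        per_clone[[clone]] <- bt
      }
      if (length(per_clone) >= 2L) {
        for (stat in c("ill", "plateau")) {
          est <- data.frame(
            clone_id = names(per_clone),
            estimate = vapply(per_clone, function(b) {
              if (stat == "ill") b$point$ill else b$point$plateau_elevation
            }, numeric(1)),
            lower = vapply(per_clone,
                           function(b) b$statistics[[stat]]$ci$lower,
                           numeric(1)),
            upper = vapply(per_clone,
                           function(b) b$statistics[[stat]]$ci$upper,
                           numeric(1))
          )
          ord <- compare_by_ci(est)
          ord_rows[[length(ord_rows) + 1L]] <- tibble::tibble(
            trait = trait, model = model, statistic = stat,
            ordering = ord$ordering)
        }
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  orderings <- if (length(ord_rows)) dplyr::bind_rows(ord_rows) else
    tibble::tibble(trait = character(), model = character(),
                   statistic = character(), ordering = character())

  accounting <- account_individuals(records)
  report <- c(
    sprintf("illfit %s pipeline run",
            as.character(utils::packageVersion("illfit"))),
    sprintf("seed: %d", config$seed),
    sprintf("input: %s",
            if (is.null(config$input_path)) "synthetic" else config$input_path),
    sprintf("traits: %s; models: %s", paste(config$traits, collapse = ","),
            paste(config$models, collapse = ",")),
    sprintf("bootstrap: %d resamples, %.2f level",
            config$n_resamples, config$ci_level),
    sprintf("lx_scope: %s; fit_scope: %s", config$lx_scope, config$fit_scope),
    sprintf("clones: %s", paste(clones, collapse = ",")),
    accounting,
    if (length(warn_log)) warn_log else "no warnings"
  )
  structure(
    list(results = results, orderings = orderings, bootstraps = boots,
         records = records, report = report, config = config),
    class = "illfit_results"
  )
}

account_individuals <- function(records) {
  n <- nrow(records)
  nonsurv <- sum(records$survived %in% FALSE)
  zero_clutch <- sum(records$survived %in% TRUE &
                       !is.na(records$clutch_size) & records$clutch_size == 0)
  used_g <- sum(records$survived %in% TRUE & !is.na(records$final_mass))
  used_r <- sum(records$survived %in% TRUE & !is.na(records$clutch_size) &
                  records$clutch_size >= 1)
  sprintf(
    "individuals: %d total; %d in g fits; %d in r fits; %d l_x-only (died); %d zero-clutch (l_x only for r)",
    n, used_g, used_r, nonsurv, zero_clutch)
}

#' @export
print.illfit_results <- function(x, ...) {
  cat(sprintf("<illfit results: %d clones x %s x %s>\n",
              length(unique(x$results$clone_id)),
              paste(unique(x$results$trait), collapse = "/"),
              paste(unique(x$results$model), collapse = "/")))
  print(x$results[, c("clone_id", "trait", "model", "ill", "ill_lower",
                      "ill_upper", "plateau", "tfl")])
  if (nrow(x$orderings)) {
    cat("orderings:\n")
    for (i in seq_len(nrow(x$orderings))) {
      cat(sprintf("  %s/%s %s: %s\n", x$orderings$trait[i],
                  x$orderings$model[i], x$orderings$statistic[i],
                  x$orderings$ordering[i]))
    }
  }
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Writes `results.csv` (one row per clone x trait x model; not-estimable
#' TFLs are written as literal `NA`, never blank), `orderings.csv` and a
#' `run_report.txt` echoing the configuration, seed and warnings. Reruns
#' with the same configuration produce byte-identical files.
#'
#' @param res An `illfit_results` object from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(res, dir) {
  stopifnot(inherits(res, "illfit_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rp <- file.path(dir, "results.csv")
  op <- file.path(dir, "orderings.csv")
  tp <- file.path(dir, "run_report.txt")
  readr::write_csv(res$results, rp, na = "NA")
  readr::write_csv(res$orderings, op, na = "NA")
  writeLines(res$report, tp)
  invisible(c(rp, op, tp))
}
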