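#' Bootstrap configuration
#'
#' @param n_resamples Number of bootstrap iterations (default 1000).
#' @param ci_level Confidence level in (0, 1) (default 0.95).
#' @param seed Integer seed for the resampling stream.
#' @param scheme Resampling scheme: `"growth_stratified"` (growth
#'   observations resampled within each clone x concentration stratum) or
#'   `"r_individual"` (individuals resampled within strata, survival and `r`
#'   recomputed before refitting).
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_resamples = 1000L, ci_level = 0.95,
                             seed = 1L,
                             scheme = c("growth_stratified", "r_individual")) {
  scheme <- match.arg(scheme)
  if (n_resamples < 1) stop("`n_resamples` must be >= 1")
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("`ci_level` must be in (0, 1)")
  }
  structure(
    list(n_resamples = as.integer(n_resamples), ci_level = ci_level,
         seed = as.integer(seed), scheme = scheme),
    class = "bootstrap_config"
  )
}

#' Percentile bootstrap confidence interval
#'
#' Empirical `(1-level)/2` and `1-(1-level)/2` quantiles of the bootstrap
#' samples, using the linear-interpolation quantile convention
#' ([stats::quantile()] type 7) for bit-reproducibility. Missing samples
#' (failed refits) are dropped.
#'
#' @param samples Bootstrap statistic values; at least 2 non-missing.
#' @param level Confidence level in (0, 1).
#' @return A list with `lower`, `upper`, `level`, `method_tag`
#'   (`"percentile"`).
#' @export
#' @examples
#' percentile_ci(1:1000, 0.95)  # [25.975, 975.025]
percentile_ci <- function(samples, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)")
  }
  s <- samples[!is.na(samples)]
  if (length(s) < 2L) {
    stop("need at least 2 non-missing bootstrap samples, got ", length(s))
  }
  alpha <- (1 - level) / 2
  q <- unname(stats::quantile(s, probs = c(alpha, 1 - alpha), type = 7,
                              names = FALSE))
  list(lower = q[1L], upper = q[2L], level = level, method_tag = "percentile")
}

resample_within <- function(strata) {
  # indices resampled with replacement within each stratum, preserving n
  unlist(lapply(split(seq_along(strata), strata), function(idx) {
    idx[sample.int(length(idx), length(idx), replace = TRUE)]
  }), use.names = FALSE)
}

fit_fun_for <- function(model) {
  switch(model,
         quadratic_plateau = fit_quadratic_plateau,
         hockey_stick = fit_hockey_stick,
         stop("unknown model: ", model))
}

collect_bootstrap <- function(point_fit, samples_tbl, n_failed, config) {
  n_res <- config$n_resamples
  if (n_failed > 0.5 * n_res) {
    cond <- structure(
      class = c("illfit_inference_failure", "error", "condition"),
      list(message = sprintf(
        "bootstrap inference failed: %d of %d refits did not converge",
        n_failed, n_res), call = NULL)
    )
    stop(cond)
  }
  if (n_failed > 0.05 * n_res) {
    warning(sprintf("%d of %d bootstrap refits failed (> 5%%); intervals may be unstable",
                    n_failed, n_res), call. = FALSE)
  }
  stats_tags <- c("ill", "plateau", "tfl")
  out <- lapply(stats_tags, function(tag) {
    smp <- samples_tbl[[tag]]
    ci <- if (sum(!is.na(smp)) >= 2L) {
      percentile_ci(smp, config$ci_level)
    } else {
      list(lower = NA_real_, upper = NA_real_, level = config$ci_level,
           method_tag = "percentile")
    }
    list(statistic_tag = tag, samples = smp, n_failed = n_failed, ci = ci)
  })
  names(out) <- stats_tags
  structure(
    list(point = point_fit, statistics = out, samples = samples_tbl,
         n_failed = n_failed, config = config),
    class = "illfit_bootstrap"
  )
}

#' @export
print.illfit_bootstrap <- function(x, ...) {
  cat(sprintf("<bootstrap: %s, %d resamples, %d failed>\n",
              x$config$scheme, x$config$n_resamples, x$n_failed))
  for (tag in names(x$statistics)) {
    ci <- x$statistics[[tag]]$ci
    cat(sprintf("  %-8s point = %s,  %d%% CI [%s, %s]\n", tag,
                format(switch(tag, ill = x$point$ill,
                              plateau = x$point$plateau_elevation,
                              tfl = x$point$tfl), digits = 4),
                round(ci$level * 100),
                format(ci$lower, digits = 4), format(ci$upper, digits = 4)))
  }
  invisible(x)
}

#' Stratified bootstrap for the somatic-growth plateau fit
#'
#' Nonparametric bootstrap of one clone's growth curve: each iteration
#' resamples the growth observations with replacement within every
#' concentration stratum (preserving per-stratum n), refits the plateau
#' model, and collects the ILL, the plateau elevation (the refitted curve's
#' predicted response at its own ILL, so parameter covariance propagates)
#' and the TFL. Failed refits are dropped and counted (a warning is issued
#' above 5% failures; above 50% the bootstrap errors out). Percentile
#' confidence intervals are attached. Deterministic given `config$seed`.
#'
#' @param records Individual records of a single clone.
#' @param config A [bootstrap_config()] with scheme `"growth_stratified"`.
#' @param model `"quadratic_plateau"` (default) or `"hockey_stick"`.
#' @return An `illfit_bootstrap` object: the point fit, per-statistic
#'   bootstrap samples and CIs, and the failure count.
#' @export
bootstrap_growth_fit <- function(records, config,
                                 model = "quadratic_plateau") {
  stopifnot(inherits(config, "bootstrap_config"))
  if (config$scheme != "growth_stratified") {
    stop("config$scheme must be 'growth_stratified' for bootstrap_growth_fit")
  }
  check_records(records)
  if (length(unique(records$clone_id)) != 1L) {
    stop("bootstrap_growth_fit expects records of a single clone")
  }
  obs <- growth_observations(records)
  fit_fun <- fit_fun_for(model)
  point_fit <- fit_fun(obs$concentration, obs$g)
  set.seed(config$seed)
  n_res <- config$n_resamples
  ill <- plateau <- tfl <- rep(NA_real_, n_res)
  n_failed <- 0L
  for (b in seq_len(n_res)) {
    idx <- resample_within(obs$concentration)
    fit <- tryCatch(fit_fun(obs$concentration[idx], obs$g[idx]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
    } else {
      ill[b] <- fit$ill
      plateau[b] <- fit$plateau_elevation
      tfl[b] <- fit$tfl
    }
  }
  collect_bootstrap(point_fit,
                    tibble::tibble(ill = ill, plateau = plateau, tfl = tfl),
                    n_failed, config)
}

#' Individual-level bootstrap for the intrinsic-rate plateau fit
#'
#' Bootstrap of one clone's `r` curve: each iteration resamples individuals
#' (their age at first reproduction, clutch size and survival flag jointly)
#' with replacement within every concentration stratum, recomputes the
#' stratum survival `l_x` from the resample (so survival uncertainty
#' propagates; set `vary_lx = FALSE` to hold the observed `l_x` fixed),
#' re-solves the Euler-Lotka equation for every resampled individual, refits
#' the plateau model to the resampled `(concentration, r)` points, and
#' collects ILL / plateau / TFL as in [bootstrap_growth_fit()].
#'
#' @param records Individual records of a single clone.
#' @param config A [bootstrap_config()] with scheme `"r_individual"`.
#' @param model `"quadratic_plateau"` (default) or `"hockey_stick"`.
#' @param lx_scope Survival scope passed to [compute_r_observations()].
#' @param vary_lx Recompute `l_x` within each resample (default `TRUE`).
#' @return An `illfit_bootstrap` object.
#' @export
bootstrap_r_fit <- function(records, config, model = "quadratic_plateau",
                            lx_scope = "stratum", vary_lx = TRUE) {
  stopifnot(inherits(config, "bootstrap_config"))
  if (config$scheme != "r_individual") {
    stop("config$scheme must be 'r_individual' for bootstrap_r_fit")
  }
  check_records(records)
  if (length(unique(records$clone_id)) != 1L) {
    stop("bootstrap_r_fit expects records of a single clone")
  }
  fit_fun <- fit_fun_for(model)
  obs0 <- suppressWarnings(compute_r_observations(records, lx_scope))
  point_fit <- fit_fun(obs0$concentration, obs0$r)
  fixed_lx <- if (!vary_lx) cohort_survival(records, scope = lx_scope) else NULL
  set.seed(config$seed)
  n_res <- config$n_resamples
  ill <- plateau <- tfl <- rep(NA_real_, n_res)
  n_failed <- 0L
  for (b in seq_len(n_res)) {
    idx <- resample_within(records$concentration)
    res <- records[idx, , drop = FALSE]
    fit <- tryCatch({
      obs <- if (vary_lx) {
        suppressWarnings(compute_r_observations(res, lx_scope))
      } else {
        recompute_r_fixed_lx(res, fixed_lx, lx_scope)
      }
      fit_fun(obs$concentration, obs$r)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
    } else {
      ill[b] <- fit$ill
      plateau[b] <- fit$plateau_elevation
      tfl[b] <- fit$tfl
    }
  }
  collect_bootstrap(point_fit,
                    tibble::tibble(ill = ill, plateau = plateau, tfl = tfl),
                    n_failed, config)
}

recompute_r_fixed_lx <- function(res, fixed_lx, lx_scope) {
  s <- res[res$survived %in% TRUE & !is.na(res$clutch_size) &
             res$clutch_size >= 1, , drop = FALSE]
  lx <- if (lx_scope == "stratum") {
    key <- paste(s$clone_id, s$concentration)
    fixed_lx$l_x[match(key, paste(fixed_lx$clone_id, fixed_lx$concentration))]
  } else {
    fixed_lx$l_x[match(s$clone_id, fixed_lx$clone_id)]
  }
  r <- vapply(seq_len(nrow(s)), function(i) {
    tryCatch(solve_euler_lotka(s$age_first_repro[i], lx[i], s$clutch_size[i]),
             illfit_undefined_r = function(e) NA_real_)
  }, numeric(1))
  tibble::tibble(concentration = s$concentration, r = r)[!is.na(r), ]
}

#' Order clones by confidence-interval overlap
#'
#' Clone A is declared below clone B (`<`) only when A's upper confidence
#' bound lies strictly below B's lower bound; overlapping intervals are not
#' distinguished (`=`). Clones are sorted by point estimate and the relation
#' between consecutive clones is emitted as an order string (e.g.
#' `"B3 = B2 < D2 = D4"`). Chained overlaps are reported as-is; no
#' transitive closure is taken.
#'
#' @param estimates A data frame with columns `clone_id`, `estimate`,
#'   `lower`, `upper` (one row per clone, >= 2 clones).
#' @return An object of class `clone_ordering`: `ordering` (the string),
#'   `clones` (sorted), `relations` (consecutive-pair relations) and
#'   `pairwise` (full logical matrix of strict separations).
#' @export
#' @examples
#' compare_by_ci(data.frame(
#'   clone_id = c("B2", "D2"), estimate = c(0.739, 1.02),
#'   lower = c(0.694, 0.97), upper = c(0.783, 1.12)
#' ))$ordering  # "B2 < D2"
compare_by_ci <- function(estimates) {
  req <- c("clone_id", "estimate", "lower", "upper")
  if (!all(req %in% names(estimates))) {
    stop("`estimates` must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(estimates) < 2L) stop("need at least 2 clones to order")
  e <- estimates[order(estimates$estimate), , drop = FALSE]
  n <- nrow(e)
  rel <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    rel[i] <- if (e$upper[i] < e$lower[i + 1L]) "<" else "="
  }
  ordering <- paste(
    c(rbind(e$clone_id[-n], rel), e$clone_id[n]), collapse = " ")
  pairwise <- outer(seq_len(n), seq_len(n),
                    Vectorize(function(i, j) e$upper[i] < e$lower[j]))
  dimnames(pairwise) <- list(e$clone_id, e$clone_id)
  structure(
    list(ordering = ordering, clones = e$clone_id, relations = rel,
         pairwise = pairwise),
    class = "clone_ordering"
  )
}

#' @export
print.clone_ordering <- function(x, ...) {
  cat(x$ordering, "\n")
  invisible(x)
}
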