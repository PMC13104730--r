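# shared fixtures: the 12-level food gradient and deterministic curve data

gradient_levels <- function() default_design()$concentrations

# noiseless (x, y) data on the standard gradient, n_per points per level
curve_data <- function(params, n_per = 10,
                       predict_fun = quadplateau_predict) {
  x <- rep(gradient_levels(), each = n_per)
  list(x = x, y = predict_fun(params, x))
}

noisy_curve_data <- function(params, sd = 0.03, n_per = 10, seed = 1,
                             predict_fun = quadplateau_predict) {
  d <- curve_data(params, n_per, predict_fun)
  set.seed(seed)
  d$y <- d$y + rnorm(length(d$y), 0, sd)
  d
}

# minimal single-clone record table built by hand
make_records <- function(clone_id = "A", concentration = 1,
                         initial_mass = 2, final_mass = 20,
                         age_first_repro = 8, clutch_size = 10,
                         survived = TRUE) {
  n <- max(lengths(list(concentration, final_mass, age_first_repro,
                        clutch_size, survived)))
  tibble::tibble(
    clone_id = rep_len(clone_id, n),
    concentration = rep_len(concentration, n),
    initial_mass = rep_len(initial_mass, n),
    final_mass = rep_len(final_mass, n),
    age_first_repro = rep_len(age_first_repro, n),
    clutch_size = rep_len(clutch_size, n),
    survived = rep_len(survived, n)
  )
}

# clone whose truth curve passes through the origin (no truncation at work),
# used for exact zero-noise recovery through the generator
zero_noise_spec <- function(clone_id = "Z", b1 = 0.8, cx = 1) {
  clone_spec(clone_id, g_intercept = 0, g_slope = b1, g_breakpoint = cx,
             g_noise_sd = 0, survival_prob = 1)
}
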