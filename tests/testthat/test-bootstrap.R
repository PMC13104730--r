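make_growth_records <- function(truth, sd = 0.03, n_per = 10, seed = 1,
                                clone_id = "A") {
  d <- noisy_curve_data(truth, sd = sd, n_per = n_per, seed = seed)
  tibble::tibble(
    clone_id = clone_id, concentration = d$x, initial_mass = 2,
    final_mass = 2 * exp(d$y * 8), age_first_repro = 8,
    clutch_size = 10L, survived = TRUE
  )
}

test_that("percentile intervals use the linear-interpolation convention", {
  ci <- percentile_ci(1:1000, 0.95)
  expect_equal(ci$lower, 25.975)
  expect_equal(ci$upper, 975.025)
  expect_equal(ci$method_tag, "percentile")

  same <- percentile_ci(rep(3.14, 10), 0.95)
  expect_equal(same$lower, 3.14)
  expect_equal(same$upper, 3.14)

  expect_error(percentile_ci(1:10, 0), "level")
  expect_error(percentile_ci(1:10, 1), "level")
  expect_error(percentile_ci(c(NA, NA, 1)), "non-missing")
})

test_that("noiseless data give zero-width intervals equal to the point fit", {
  truth <- quadplateau_params(-0.05, 1.2, 0.7)
  rec <- make_growth_records(truth, sd = 0)
  bt <- bootstrap_growth_fit(rec, bootstrap_config(50, seed = 3))
  expect_equal(bt$n_failed, 0L)
  expect_equal(bt$statistics$ill$ci$lower, bt$point$ill, tolerance = 1e-6)
  expect_equal(bt$statistics$ill$ci$upper, bt$point$ill, tolerance = 1e-6)
  expect_equal(bt$statistics$plateau$ci$lower, bt$point$plateau_elevation,
               tolerance = 1e-6)
  expect_equal(bt$statistics$tfl$ci$upper, bt$point$tfl, tolerance = 1e-6)
})

test_that("bootstrap is deterministic given the seed", {
  truth <- quadplateau_params(-0.05, 1.2, 0.7)
  rec <- make_growth_records(truth, sd = 0.03, seed = 9)
  cfg <- bootstrap_config(60, seed = 21)
  b1 <- bootstrap_growth_fit(rec, cfg)
  b2 <- bootstrap_growth_fit(rec, cfg)
  expect_identical(b1$samples, b2$samples)
  expect_identical(b1$statistics$ill$ci, b2$statistics$ill$ci)
  b3 <- bootstrap_growth_fit(rec, bootstrap_config(60, seed = 22))
  expect_false(identical(b1$samples$ill, b3$samples$ill))
})

test_that("growth bootstrap covers the point estimate and the truth", {
  truth <- quadplateau_params(-0.05, 1.2, 0.7)
  rec <- make_growth_records(truth, sd = 0.03, seed = 4)
  bt <- bootstrap_growth_fit(rec, bootstrap_config(200, seed = 8))
  ci <- bt$statistics$ill$ci
  expect_lte(ci$lower, bt$point$ill)
  expect_gte(ci$upper, bt$point$ill)
  expect_lt(ci$lower, ci$upper)
})

test_that("identical individuals within strata give a zero-width r interval", {
  rec <- make_records(concentration = rep(gradient_levels(), each = 4),
                      age_first_repro = rep(
                        pmax(7, 13 - round(6 * rep(gradient_levels(), each = 4))), 1),
                      clutch_size = rep(
                        pmin(12L, 1L + round(10 * rep(gradient_levels(), each = 4))), 1))
  cfg <- bootstrap_config(40, seed = 5, scheme = "r_individual")
  bt <- bootstrap_r_fit(rec, cfg)
  expect_equal(bt$statistics$ill$ci$lower, bt$statistics$ill$ci$upper,
               tolerance = 1e-8)
  expect_equal(bt$statistics$ill$ci$lower, bt$point$ill, tolerance = 1e-8)
})

test_that("r bootstrap varies survival unless told otherwise", {
  set.seed(6)
  rec <- generate_dataset(default_design(seed = 6),
                          list(clone_spec("A", survival_prob = 0.85)))
  cfg <- bootstrap_config(80, seed = 10, scheme = "r_individual")
  bt_vary <- bootstrap_r_fit(rec, cfg)
  bt_fixed <- bootstrap_r_fit(rec, cfg, vary_lx = FALSE)
  expect_false(identical(bt_vary$samples$ill, bt_fixed$samples$ill))
  expect_equal(bt_vary$point$ill, bt_fixed$point$ill)
})

test_that("schemes are enforced and mixed-clone input is rejected", {
  rec <- make_growth_records(quadplateau_params(0, 1, 0.7))
  expect_error(
    bootstrap_growth_fit(rec, bootstrap_config(10, scheme = "r_individual")),
    "growth_stratified")
  rec2 <- rec
  rec2$clone_id[1] <- "B"
  expect_error(bootstrap_growth_fit(rec2, bootstrap_config(10)), "single clone")
})

test_that("halving per-stratum n does not shrink the interval", {
  truth <- quadplateau_params(-0.05, 1.2, 0.7)
  widths <- sapply(1:8, function(i) {
    w10 <- {
      rec <- make_growth_records(truth, sd = 0.03, n_per = 10, seed = 100 + i)
      bt <- bootstrap_growth_fit(rec, bootstrap_config(100, seed = i))
      bt$statistics$ill$ci$upper - bt$statistics$ill$ci$lower
    }
    w5 <- {
      rec <- make_growth_records(truth, sd = 0.03, n_per = 5, seed = 100 + i)
      bt <- bootstrap_growth_fit(rec, bootstrap_config(100, seed = i))
      bt$statistics$ill$ci$upper - bt$statistics$ill$ci$lower
    }
    c(w10 = w10, w5 = w5)
  })
  expect_gte(median(widths["w5", ]), median(widths["w10", ]))
})

test_that("clones are ordered by strict interval separation", {
  ord <- compare_by_ci(data.frame(
    clone_id = c("B2", "D2"),
    estimate = c(0.739, 1.02),
    lower = c(0.694, 0.97),
    upper = c(0.783, 1.12)
  ))
  expect_equal(ord$ordering, "B2 < D2")

  tied <- compare_by_ci(data.frame(
    clone_id = c("A", "B"), estimate = c(1, 1.01),
    lower = c(0.9, 0.9), upper = c(1.1, 1.1)
  ))
  expect_equal(tied$ordering, "A = B")

  # chained overlap: consecutive ties reported as-is, but the ends separate
  chain <- compare_by_ci(data.frame(
    clone_id = c("A", "B", "C"), estimate = c(1, 2.5, 4),
    lower = c(0, 1.5, 3), upper = c(2, 3.5, 5)
  ))
  expect_equal(chain$ordering, "A = B = C")
  expect_true(chain$pairwise["A", "C"])
  expect_false(chain$pairwise["A", "B"])

  expect_error(compare_by_ci(data.frame(clone_id = "A", estimate = 1,
                                        lower = 0, upper = 2)),
               "at least 2")
})
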