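test_that("zero-noise identity: all values equal the baseline", {
  sites <- data.frame(site = c("A", "B"), catchment = "C",
                      group = c("treated", "reference"),
                      class = "headwater")
  baseline <- matrix(10, 2, 1, dimnames = list(sites$site, "DIN"))
  effect <- matrix(1, 2, 1, dimnames = list(sites$group, "DIN"))
  cfg <- simulation_config(sites, groups = sites$group,
                           pre_years = 2001:2002, post_years = 2004:2005,
                           attributes = "DIN", baseline = baseline,
                           effect = effect, noise_cv = c(DIN = 0),
                           site_sd = 0, seed = 7)
  tab <- simulate_study(cfg)
  expect_equal(nrow(tab), 2 * 4)
  expect_true(all(tab$value == 10))
})

test_that("same config and seed give byte-identical tables", {
  cfg <- default_trask_design(seed = 42)
  expect_identical(simulate_study(cfg), simulate_study(cfg))
  cfg2 <- default_trask_design(seed = 43)
  expect_false(identical(simulate_study(cfg), simulate_study(cfg2)))
})

test_that("default design matches the paired-watershed layout", {
  cfg <- default_trask_design()
  hw <- cfg$sites[cfg$sites$class == "headwater", ]
  ds <- cfg$sites[cfg$sites$class == "downstream", ]
  expect_equal(nrow(hw), 12)
  expect_equal(nrow(ds), 4)
  expect_equal(length(cfg$pre_years), 5)
  expect_equal(length(cfg$post_years), 4)
  expect_setequal(unique(hw$group),
                  c("clearcut variable", "clearcut uniform", "thinned",
                    "reference"))
  expect_equal(sum(hw$group == "clearcut variable"), 3)
  expect_equal(sum(hw$group == "clearcut uniform"), 3)
  expect_equal(sum(hw$group == "thinned"), 1)
  expect_equal(sum(hw$group == "reference"), 5)
  expect_equal(sum(ds$group == "downstream harvested"), 3)
  ## replicate counts per protocol
  expect_equal(cfg$replicates[["epilithon"]][["headwater"]], 4)
  expect_equal(cfg$replicates[["epilithon"]][["downstream"]], 6)
  expect_equal(cfg$replicates[["sediment"]][["headwater"]], 3)
  expect_equal(cfg$replicates[["sediment"]][["downstream"]], 5)
  expect_equal(cfg$replicates[["DIN"]][["headwater"]], 1)
})

test_that("invalid configurations are rejected", {
  cfg <- default_trask_design()
  cfg$baseline[1, 1] <- -1
  expect_error(simulate_study(cfg), "non-positive")
  expect_error(set_effect(default_trask_design(), "reference", "DIN", 0))
  expect_error(simulation_config(
    data.frame(site = "A", group = "g", class = "headwater"),
    groups = "g", pre_years = 2001, post_years = 2001,
    attributes = "DIN",
    baseline = matrix(1, 1, 1, dimnames = list("A", "DIN")),
    effect = matrix(1, 1, 1, dimnames = list("g", "DIN")),
    noise_cv = c(DIN = 0.1)), "disjoint")
})

test_that("injected effect factor is recovered in the group mean ratio", {
  ## Monte-Carlo over seeds; with mean-one lognormal noise the expected
  ## post/pre ratio of group means is the injected factor
  n_seeds <- 200
  ratios <- vapply(seq_len(n_seeds), function(s) {
    cfg <- default_trask_design(seed = 10000 + s)
    cfg$noise_cv["DIN"] <- 0.3
    cfg <- set_effect(cfg, c("clearcut variable", "clearcut uniform"),
                      "DIN", 6)
    tab <- simulate_study(cfg)
    din <- tab[tab$attribute == "DIN" &
                 tab$group == "clearcut variable", ]
    mean(din$value[din$period == "post"]) /
      mean(din$value[din$period == "pre"])
  }, numeric(1))
  se <- sd(ratios) / sqrt(n_seeds)
  expect_lt(abs(mean(ratios) - 6), 3 * se + 6 * 0.02)
})

test_that("log-values per site-attribute are Gaussian with configured sd", {
  cfg <- default_trask_design(seed = 5)
  cfg$sites <- cfg$sites[1, , drop = FALSE]
  cfg$pre_years <- 1:400
  cfg$post_years <- 401:500
  cfg$attributes <- "DIN"
  cfg$site_sd <- 0
  tab <- simulate_study(cfg)
  lv <- log(tab$value)
  cv <- cfg$noise_cv[["DIN"]]
  expect_gt(shapiro.test(sample(lv, 400))$p.value, 1e-3)
  expect_equal(sd(lv), sqrt(log(1 + cv^2)), tolerance = 0.1)
})

test_that("observation and config serialization round-trips", {
  cfg <- default_trask_design(seed = 9)
  cfg <- set_effect(cfg, "thinned", "DOC", 2.5)
  f <- tempfile(fileext = ".json")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_identical(simulate_study(cfg), simulate_study(cfg2))

  tab <- simulate_study(cfg)
  fc <- tempfile(fileext = ".csv")
  write_observations(tab, fc)
  tab2 <- read_observations(fc)
  expect_equal(tab$value, tab2$value, tolerance = 1e-12)
  expect_identical(tab$site, tab2$site)
})

test_that("percent attributes stay within [0, 100]", {
  cfg <- default_trask_design(seed = 2)
  cfg <- set_effect(cfg, "clearcut variable", "canopy closure", 0.05)
  tab <- simulate_study(cfg)
  cc <- tab$value[tab$attribute == "canopy closure"]
  expect_true(all(cc >= 0 & cc <= 100))
})
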