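study_regions <- function() {
  data.frame(label = c("RWEPA", "periphery"),
             total = c(180, 131), mean_q = c(0.437, 0.024))
}

test_that("the composition solver balances ancestry and conserves totals", {
  comp <- solve_composition(study_regions(), p_h = 0.386)
  expect_equal(comp$per_region$H[1], 69)   # hybrids inside the core
  expect_equal(comp$per_region$H[2], 6)    # periphery: six hybrids
  expect_equal(comp$per_region$C[2], 125)  # ... and 125 coyotes
  expect_equal(sum(comp$counts), comp$total)
  # pure-parental single region
  lone <- solve_composition(data.frame(label = "all", total = 50, mean_q = 1),
                            p_h = 0)
  expect_equal(unname(lone$counts["P1"]), 50)
  # increasing the hybrid proportion weakly decreases the wolves needed
  rs <- vapply(seq(0, 0.5, by = 0.05), function(ph)
    unname(solve_composition(study_regions(), ph)$counts["P1"]), numeric(1))
  expect_true(all(diff(rs) <= 0))
  # hybrid split never differs by more than one across classes
  for (ph in c(0.386, 0.276, 0.189, 0.1)) {
    cc <- solve_composition(study_regions(), ph)$counts
    hy <- cc[c("F1", "F2", "BC1", "BC2")]
    expect_lte(max(hy) - min(hy), 1)
  }
  expect_error(solve_composition(
    data.frame(label = "x", total = 10, mean_q = 0), p_h = 1), "infeasible")
})

test_that("scenario datasets realize their compositions", {
  pools <- diag_pools(6)
  comp <- solve_composition(study_regions(), p_h = 0.386, label = "random")
  dat <- build_scenario_dataset(comp, pools$p1, pools$p2, seed = 1)
  expect_equal(n_ind(dat), comp$total)
  expect_equal(as.integer(table(dat$meta$class)[names(comp$counts)]),
               unname(comp$counts))
  dat2 <- build_scenario_dataset(comp, pools$p1, pools$p2, seed = 1)
  expect_identical(dat$a1, dat2$a1)
  # the no-interbreeding composition contains no hybrid classes
  mix <- solve_composition(study_regions(), p_h = 0, label = "spatial")
  dmix <- build_scenario_dataset(mix, pools$p1, pools$p2, seed = 2)
  expect_true(all(dmix$meta$class %in% c("P1", "P2")))
})

test_that("ancestry thresholds classify individuals as managed", {
  expect_equal(classify_ancestry(c(1, 0, 0.5, 0.8644, 0.125, 0.875)),
               c("red wolf", "coyote", "hybrid", "hybrid", "hybrid",
                 "red wolf"))
  expect_error(classify_ancestry(1.2), "\\[0, 1\\]")
  expect_error(classify_ancestry(0.5, 0.1, 0.9), "below")
  expect_equal(hybrid_percentage(rep("hybrid", 4)), 100)
  expect_equal(hybrid_percentage(rep("coyote", 4)), 0)
  expect_error(hybrid_percentage(character(0)), "non-empty")
})

test_that("zone summaries produce the ANOVA, letters and hybrid chi-square", {
  set.seed(2)
  q <- c(pmin(pmax(rnorm(20, 0.9, 0.05), 0), 1),
         pmin(pmax(rnorm(20, 0.1, 0.05), 0), 1))
  z <- rep(c("east", "west"), each = 20)
  zs <- zone_summary(q, z, n_mc = 500)
  expect_lt(zs$anova_p, 0.001)
  expect_false(zs$per_zone$letters[1] == zs$per_zone$letters[2])
  expect_true(all(zs$per_zone$lower < zs$per_zone$mean_q &
                    zs$per_zone$mean_q < zs$per_zone$upper))
  # constant ancestry: no variance to test, single letter group
  zc <- zone_summary(rep(0.5, 12), rep(c("a", "b", "c"), each = 4),
                     n_mc = 0)
  expect_true(length(unique(zc$per_zone$letters)) == 1)
  # evenly spread hybrids: chi-square exactly zero, p = 1
  qh <- rep(0.5, 12)
  zh <- zone_summary(qh, rep(paste0("z", 1:6), each = 2), n_mc = 500)
  expect_equal(unname(zh$hybrid_counts), rep(2L, 6))
  expect_equal(zh$chisq$statistic, 0)
  expect_equal(zh$chisq$p_asymptotic, 1)
  expect_warning(zone_summary(c(0.1, 0.2, 0.3), c("a", "a", "b")),
                 "excluded")
})

test_that("the K-S statistic equals independent oracles, ties included", {
  expect_equal(ks_compare(c(0.1, 0.2), c(0.1, 0.2))$d, 0)
  expect_equal(ks_compare(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))$d, 1 / 3)
  expect_equal(ks_compare(c(0.1, 0.2), c(0.8, 0.9))$d, 1)
  set.seed(3)
  for (r in 1:25) {
    nx <- sample(2:50, 1); ny <- sample(2:50, 1)
    x <- round(runif(nx), sample(1:3, 1))  # rounding forces ties
    y <- round(rbeta(ny, 2, 1), sample(1:3, 1))
    expect_equal(ks_compare(x, y)$d, ks_brute(x, y))
  }
  # tie-free case agrees with the stock two-sample test
  x <- runif(40); y <- rbeta(35, 2, 2)
  kc <- ks_compare(x, y)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(kc$d, unname(kt$statistic))
  expect_equal(kc$p, kt$p.value, tolerance = 0.02)
})

test_that("the ranked logistic fit recovers parameters and ranks steepness", {
  x <- 1:311
  y <- 1 / (1 + exp(-0.364 * (x - 150)))
  fit <- fit_logistic(y)
  expect_lt(abs(fit$a - 1), 1e-4)
  expect_lt(abs(fit$b - 150), 1e-4)
  expect_lt(abs(fit$c - 0.364), 1e-4)
  expect_true(fit$converged)
  # near-step (bimodal) data is steeper than a linear ramp
  step_q <- c(rep(0.01, 150), rep(0.99, 161))
  ramp_q <- seq(0.01, 0.99, length.out = 311)
  expect_gt(fit_logistic(step_q)$c, fit_logistic(ramp_q)$c)
  expect_error(fit_logistic(c(0.1, 0.5, 0.9)), ">= 4")
})

test_that("scenario comparison orchestrates composition through K-S per scenario", {
  pools <- diag_pools(8)
  scen <- data.frame(label = c("random", "challenges"),
                     p_h = c(0.386, 0.189))
  regions <- data.frame(label = c("core", "edge"), total = c(40, 20),
                        mean_q = c(0.45, 0.05))
  emp <- c(rep(0.02, 40), rep(0.97, 20))
  rep_out <- run_scenario_comparison(emp, scen, regions, pools$p1, pools$p2,
                                     runs = 2, seed = 4,
                                     model = "uncorrelated", burnin = 300,
                                     reps = 1500, thin = 5)
  expect_equal(nrow(rep_out$table), 2)
  expect_true(all(c("d", "p", "c") %in% names(rep_out$table)))
  expect_true(all(rep_out$table$d >= 0 & rep_out$table$d <= 1))
  # comparing a scenario's own composite against itself gives D ~ 0
  own <- rep_out$details[["random"]]$q
  expect_lt(ks_compare(own, own)$d, 1e-12)
  # an impossible scenario is reported, not fatal
  scen_bad <- data.frame(label = "broken", p_h = 1)
  reg_bad <- data.frame(label = "x", total = 10, mean_q = 0)
  out_bad <- run_scenario_comparison(emp, scen_bad, reg_bad, pools$p1,
                                     pools$p2, runs = 2, seed = 5,
                                     model = "uncorrelated", burnin = 200,
                                     reps = 1000, thin = 5)
  expect_true(is.na(out_bad$table$d))
  expect_match(out_bad$details[["broken"]]$error, "infeasible")
})

test_that("scenario configuration files load from JSON and YAML", {
  cfg <- list(regions = list(list(label = "core", total = 180, mean_q = 0.437),
                             list(label = "edge", total = 131, mean_q = 0.024)),
              scenarios = list(list(label = "random", p_h = 0.386),
                               list(label = "none", p_h = 0)),
              runs = 10, seed = 7)
  jf <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jf, auto_unbox = TRUE)
  got <- read_scenario_config(jf)
  expect_equal(got$regions$total, c(180, 131))
  expect_equal(got$scenarios$p_h, c(0.386, 0))
  yf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yf)
  got2 <- read_scenario_config(yf)
  expect_equal(got2$regions$mean_q, c(0.437, 0.024))
  expect_equal(got2$runs, 10)
})
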