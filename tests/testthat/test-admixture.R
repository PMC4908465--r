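# tests use short chains with uncorrelated frequencies for speed; the
# desk-scale correlated settings are exercised in test-acceptance.R

test_that("single-cluster fits are the degenerate simplex", {
  pools <- diag_pools(5)
  g <- sample_population(pools$p1, 10, seed = 1)
  fit <- fit_admixture(g, K = 1, burnin = 100, reps = 500, thin = 5, seed = 2)
  expect_true(all(fit$q == 1))
  expect_equal(coef(fit), fit$q)
})

test_that("diagnostic parental pools resolve to the simplex corners", {
  pools <- diag_pools(10)
  g <- bind_genotypes(simulate_class(pools$p1, pools$p2, "P1", 15, seed = 3),
                      simulate_class(pools$p1, pools$p2, "P2", 15))
  fit <- fit_admixture(g, K = 2, model = "uncorrelated", burnin = 500,
                       reps = 3000, thin = 5, seed = 4)
  qp1 <- fit$q[g$meta$class == "P1", 1]
  hi <- if (mean(qp1) > 0.5) 1 else 2
  expect_true(all(abs(fit$q[g$meta$class == "P1", hi] - 1) < 0.02))
  expect_true(all(abs(fit$q[g$meta$class == "P2", hi]) < 0.02))
  # simplex conservation and credibility-interval bracketing
  expect_true(all(abs(rowSums(fit$q) - 1) < 1e-6))
  expect_true(all(fit$ci_lower <= fit$q + 1e-9))
  expect_true(all(fit$ci_upper >= fit$q - 1e-9))
})

test_that("hybrid classes recover their pedigree ancestry expectations", {
  pools <- diag_pools(12)
  g <- bind_genotypes(simulate_class(pools$p1, pools$p2, "P1", 20, seed = 5),
                      simulate_class(pools$p1, pools$p2, "P2", 20),
                      simulate_class(pools$p1, pools$p2, "F1", 20),
                      simulate_class(pools$p1, pools$p2, "BC1", 20))
  fit <- fit_admixture(g, K = 2, model = "uncorrelated", burnin = 500,
                       reps = 4000, thin = 5, seed = 6)
  known <- setNames(ifelse(g$meta$class == "P1", "wolf", "coyote"),
                    g$ids)[g$meta$class %in% c("P1", "P2")]
  fit <- anchor_clusters(fit, known)
  cls <- tapply(fit$q[, "wolf"], g$meta$class, mean)
  expect_lt(abs(cls[["F1"]] - 0.5), 0.05)
  expect_lt(abs(cls[["BC1"]] - 0.75), 0.05)
})

test_that("fits are reproducible under a fixed seed", {
  pools <- diag_pools(6)
  g <- sample_population(pools$p1, 12, seed = 7)
  f1 <- fit_admixture(g, K = 2, burnin = 200, reps = 1000, thin = 5, seed = 8)
  f2 <- fit_admixture(g, K = 2, burnin = 200, reps = 1000, thin = 5, seed = 8)
  expect_identical(f1$q, f2$q)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("run alignment undoes label switching and averages noise", {
  pools <- diag_pools(8)
  g <- bind_genotypes(simulate_class(pools$p1, pools$p2, "P1", 10, seed = 9),
                      simulate_class(pools$p1, pools$p2, "P2", 10))
  fit <- fit_admixture(g, K = 2, model = "uncorrelated", burnin = 300,
                       reps = 2000, thin = 5, seed = 10)
  swapped <- fit
  swapped$q <- fit$q[, 2:1]
  swapped$ci_lower <- fit$ci_lower[, 2:1]
  swapped$ci_upper <- fit$ci_upper[, 2:1]
  comp <- align_runs(list(fit, swapped))
  expect_equal(unname(comp$q), unname(fit$q), tolerance = 1e-12)
  expect_identical(align_runs(list(fit)), fit)
  # independent +-0.01 noise shrinks toward the common signal
  noisy <- lapply(1:6, function(i) {
    f <- fit
    eps <- runif(nrow(f$q), -0.01, 0.01)
    f$q[, 1] <- pmin(pmax(f$q[, 1] + eps, 0), 1)
    f$q[, 2] <- 1 - f$q[, 1]
    f
  })
  comp2 <- align_runs(noisy)
  expect_lt(max(abs(comp2$q - fit$q)), 0.01)
  bad <- fit
  bad$ids <- rev(bad$ids)
  expect_error(align_runs(list(fit, bad)), "individuals")
})

test_that("Evanno deltaK selects two clusters for two-pool data", {
  mk <- function(K, lnpd) structure(list(K = K, lnpd = lnpd),
                                    class = "admix_fit")
  # exactly linear mean L(K): zero second difference at every interior K
  lin <- list(mk(1, -10), mk(1, -12), mk(2, -20), mk(2, -22),
              mk(3, -30), mk(3, -32), mk(4, -40), mk(4, -42))
  ev <- evanno_deltaK(lin)
  expect_equal(ev$table$delta_k[2:3], c(0, 0))
  expect_error(evanno_deltaK(lin[1:4]), ">= 3 consecutive")
  expect_error(evanno_deltaK(lin[c(1, 3, 5, 7)]), ">= 2 runs")
  pools <- diag_pools(8)
  g <- bind_genotypes(simulate_class(pools$p1, pools$p2, "P1", 15, seed = 11),
                      simulate_class(pools$p1, pools$p2, "P2", 15))
  runs <- list()
  for (K in 1:4) {
    runs <- c(runs, fit_admixture_runs(g, K = K, n_runs = 2, seed = 20 + K,
                                       model = "uncorrelated", burnin = 300,
                                       reps = 2000, thin = 5))
  }
  expect_equal(evanno_deltaK(runs)$best_k, 2)
})

test_that("cluster anchoring orients the wolf cluster first", {
  pools <- diag_pools(8)
  g <- bind_genotypes(simulate_class(pools$p1, pools$p2, "P1", 8, seed = 12),
                      simulate_class(pools$p1, pools$p2, "P2", 8))
  fit <- fit_admixture(g, K = 2, model = "uncorrelated", burnin = 300,
                       reps = 2000, thin = 5, seed = 13)
  known <- setNames(ifelse(g$meta$class == "P1", "wolf", "coyote"), g$ids)
  anc <- anchor_clusters(fit, known)
  expect_equal(anc$cluster_labels, c("wolf", "coyote"))
  expect_gt(mean(anc$q[g$meta$class == "P1", "wolf"]), 0.95)
  # anchoring then classifying the knowns reproduces their labels
  lab <- classify_ancestry(anc$q[, "wolf"])
  expect_true(all(lab[g$meta$class == "P1"] == "red wolf"))
  expect_true(all(lab[g$meta$class == "P2"] == "coyote"))
  # knowns of both species pointing at one cluster raise an error
  confused <- c(setNames(rep("wolf", 4), g$ids[1:4]),
                setNames(rep("coyote", 2), g$ids[5:6]))
  expect_error(anchor_clusters(fit, confused), "conflicting")
})

test_that("label-permuted initial states yield the same composite", {
  pools <- diag_pools(8)
  g <- bind_genotypes(simulate_class(pools$p1, pools$p2, "P1", 10, seed = 14),
                      simulate_class(pools$p1, pools$p2, "P2", 10))
  runs <- fit_admixture_runs(g, K = 2, n_runs = 3, seed = 15,
                             model = "uncorrelated", burnin = 300,
                             reps = 2000, thin = 5)
  comp_a <- align_runs(runs)
  flipped <- lapply(runs, function(f) {
    f$q <- f$q[, 2:1]; f$ci_lower <- f$ci_lower[, 2:1]
    f$ci_upper <- f$ci_upper[, 2:1]; f
  })
  comp_b <- align_runs(flipped)
  expect_equal(unname(comp_a$q), unname(comp_b$q[, 2:1]), tolerance = 1e-12)
})
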