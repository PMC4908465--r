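#' Solve a scenario composition against observed mean ancestry
#'
#' Given region totals and their observed mean ancestry toward the
#' focal species, and a scenario's hybrid proportion `p_h` applied to
#' the core (first) region, solves how many focal-species individuals
#' (R), other-species individuals (C) and hybrids (H) the scenario
#' requires, using the ancestry balance `qbar * T = h * H + R` with
#' each hybrid contributing ancestry `h` (default 0.5).
#'
#' In the core region `H = round(p_h * T)` and
#' `R = round(qbar * T - h * H)`. Peripheral regions are assumed to
#' hold no focal-species individuals while hybridization is occurring:
#' their ancestry is carried entirely by hybrids,
#' `H = round(qbar * T / h)`; with `p_h = 0` (no interbreeding) it is
#' carried by focal-species individuals instead. All rounding is
#' half-up. The hybrid total is split across the four hybrid classes as
#' evenly as possible, any remainder going to F1, BC1, BC2 then F2.
#'
#' @param regions data frame with columns `label`, `total`, `mean_q`;
#'   the first row is the core region, later rows are peripheral.
#' @param p_h scenario hybrid proportion in `[0, 1]`, applied to the
#'   core region's total.
#' @param hybrid_mean_ancestry mean focal ancestry of a hybrid
#'   (default 0.5).
#' @param label optional scenario label.
#' @return An object of class `scenario_composition`: list with
#'   `label`, `p_h`, `counts` (named vector `P1`, `P2`, `F1`, `F2`,
#'   `BC1`, `BC2`), `per_region` breakdown and `total`.
#' @examples
#' regions <- data.frame(label = c("RWEPA", "periphery"),
#'                       total = c(180, 131), mean_q = c(0.437, 0.024))
#' solve_composition(regions, p_h = 0.386)
#' @export
solve_composition <- function(regions, p_h, hybrid_mean_ancestry = 0.5,
                              label = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("label", "total", "mean_q") %in% names(regions)))
  if (p_h < 0 || p_h > 1) stop("p_h must be in [0, 1]")
  if (any(regions$total < 0) || any(regions$mean_q < 0 | regions$mean_q > 1))
    stop("invalid region specification")
  h <- hybrid_mean_ancestry
  per <- regions
  per$H <- per$R <- per$C <- 0
  for (i in seq_len(nrow(per))) {
    T_r <- per$total[i]; q_r <- per$mean_q[i]
    if (i == 1) {
      H <- round_half_up(p_h * T_r)
      R <- round_half_up(q_r * T_r - h * H)
      C <- T_r - H - R
    } else if (p_h > 0) {
      H <- round_half_up(q_r * T_r / h)
      R <- 0
      C <- T_r - H
    } else {
      H <- 0
      R <- round_half_up(q_r * T_r)
      C <- T_r - R
    }
    if (R < 0 || C < 0)
      stop("infeasible composition in region '", per$label[i],
           "' (R = ", R, ", C = ", C, ")")
    per$H[i] <- H; per$R[i] <- R; per$C[i] <- C
  }
  H_tot <- sum(per$H)
  base <- H_tot %/% 4
  extra <- H_tot %% 4
  # remainder order: F1, BC1 (x focal), BC2 (x other), then F2
  split <- c(F1 = base, F2 = base, BC1 = base, BC2 = base)
  if (extra > 0)
    split[c("F1", "BC1", "BC2", "F2")[seq_len(extra)]] <-
      split[c("F1", "BC1", "BC2", "F2")[seq_len(extra)]] + 1
  counts <- c(P1 = sum(per$R), P2 = sum(per$C), split)
  structure(list(label = label, p_h = p_h,
                 hybrid_mean_ancestry = h, counts = counts,
                 per_region = per, total = sum(regions$total)),
            class = "scenario_composition")
}

round_half_up <- function(x) floor(x + 0.5)

#' @export
print.scenario_composition <- function(x, ...) {
  cat(sprintf("scenario_composition%s: p_h = %.3f, total = %d\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$p_h, x$total))
  print(x$counts)
  invisible(x)
}

#' Assemble the simulated genotype dataset for a scenario
#'
#' Simulates each class of a solved composition from the two parental
#' pools via [simulate_class()].
#'
#' @param comp a [solve_composition()] result.
#' @param p1_pool,p2_pool [allele_freqs()] tables over a shared
#'   registry.
#' @param seed optional integer seed.
#' @return A [genotype_matrix()] with `class` metadata.
#' @export
build_scenario_dataset <- function(comp, p1_pool, p2_pool, seed = NULL) {
  stopifnot(inherits(comp, "scenario_composition"))
  if (!is.null(seed)) set.seed(seed)
  pre <- if (is.null(comp$label)) "sim" else gsub("[^A-Za-z0-9]", "", comp$label)
  parts <- list()
  for (cl in names(hybrid_classes())) {
    n <- comp$counts[[cl]]
    if (n == 0) next
    parts[[length(parts) + 1L]] <-
      simulate_class(p1_pool, p2_pool, cl, n, prefix = paste0(pre, "_", cl))
  }
  if (length(parts) == 0) stop("empty composition")
  bind_genotypes(parts)
}

#' Classify individuals from their focal-species ancestry
#'
#' Management-style thresholds: `q >= wolf_threshold` is a red wolf,
#' `q < coyote_threshold` a coyote, anything between a hybrid. The
#' defaults (0.875 / 0.125) are the expected ancestries after two
#' generations of backcrossing, beyond which classes are not separable
#' from q alone.
#'
#' @param q ancestry values in `[0, 1]`.
#' @param wolf_threshold,coyote_threshold classification cutoffs with
#'   `coyote_threshold < wolf_threshold`.
#' @return Character vector over `"red wolf"`, `"hybrid"`, `"coyote"`.
#' @export
classify_ancestry <- function(q, wolf_threshold = 0.875,
                              coyote_threshold = 0.125) {
  if (any(is.na(q)) || any(q < 0 | q > 1)) stop("q must be in [0, 1]")
  if (coyote_threshold >= wolf_threshold)
    stop("coyote_threshold must be below wolf_threshold")
  ifelse(q >= wolf_threshold, "red wolf",
         ifelse(q < coyote_threshold, "coyote", "hybrid"))
}

#' Percentage of hybrids among classified individuals
#'
#' @param labels classification labels from [classify_ancestry()].
#' @return Percentage of `"hybrid"` labels, rounded to two decimals.
#' @export
hybrid_percentage <- function(labels) {
  if (length(labels) == 0) stop("labels must be non-empty")
  round(100 * mean(labels == "hybrid"), 2)
}

#' Per-zone ancestry summary with ANOVA, LSD letters and hybrid counts
#'
#' Zone means of ancestry with pooled-error 95% confidence intervals, a
#' one-way ANOVA of ancestry on zone, Fisher's LSD pairwise t-tests on
#' the pooled mean square error with letter groups assigned by a greedy
#' sweep over the ordered means, and a chi-squared test of the hybrid
#' counts against equal expected proportions (with a Monte Carlo
#' p-value for small counts).
#'
#' @param q ancestry values in `[0, 1]`.
#' @param zone zone labels, one per individual; summarised in the order
#'   of first appearance (pass a factor to control ordering).
#' @param alpha significance level of the LSD letters (default 0.05).
#' @param n_mc Monte Carlo draws for the chi-squared p-value.
#' @param wolf_threshold,coyote_threshold thresholds passed to
#'   [classify_ancestry()] for the hybrid counts.
#' @return List with `per_zone` (n, mean, CI, letters), `anova_f`,
#'   `anova_p`, `lsd_p` (pairwise p matrix), `hybrid_counts`,
#'   `chisq` (statistic, asymptotic and Monte Carlo p-values).
#' @export
zone_summary <- function(q, zone, alpha = 0.05, n_mc = 10000,
                         wolf_threshold = 0.875, coyote_threshold = 0.125) {
  zone <- if (is.factor(zone)) as.character(zone) else as.character(zone)
  labs <- unique(zone)
  sizes <- table(zone)[labs]
  small <- labs[sizes < 2]
  if (length(small) > 0)
    warning("zones excluded from ANOVA (<2 individuals): ",
            paste(small, collapse = ", "))
  keep <- !(zone %in% small)
  zq <- q[keep]; zz <- factor(zone[keep], levels = setdiff(labs, small))
  means <- tapply(zq, zz, mean)
  ns <- tapply(zq, zz, length)
  if (nlevels(zz) < 2) {
    warning("fewer than two zones usable: ANOVA not performed")
    per_zone <- data.frame(zone = levels(zz), n = as.integer(ns),
                           mean_q = as.numeric(means), lower = NA_real_,
                           upper = NA_real_, letters = "a",
                           stringsAsFactors = FALSE)
    hyb <- classify_ancestry(q, wolf_threshold, coyote_threshold) == "hybrid"
    hybrid_counts <- vapply(labs, function(z) sum(hyb[zone == z]), integer(1))
    return(list(per_zone = per_zone, anova_f = NA_real_, anova_p = NA_real_,
                lsd_p = NULL, hybrid_counts = hybrid_counts,
                chisq = chisq_equal_test(hybrid_counts, n_mc)))
  }
  fit <- aov(zq ~ zz)
  an <- anova(fit)
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  tcrit <- qt(1 - alpha / 2, dfe)
  per_zone <- data.frame(zone = levels(zz), n = as.integer(ns),
                         mean_q = as.numeric(means),
                         lower = as.numeric(means) - tcrit * sqrt(mse / ns),
                         upper = as.numeric(means) + tcrit * sqrt(mse / ns),
                         stringsAsFactors = FALSE)
  # pairwise LSD t-tests on the pooled error
  nz <- nlevels(zz)
  lsd_p <- matrix(NA_real_, nz, nz, dimnames = list(levels(zz), levels(zz)))
  for (i in seq_len(nz - 1)) for (j in seq(i + 1, nz)) {
    tstat <- (means[i] - means[j]) /
      sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    lsd_p[i, j] <- lsd_p[j, i] <- 2 * pt(-abs(tstat), dfe)
  }
  per_zone$letters <- lsd_letters(means, lsd_p, alpha)
  hyb <- classify_ancestry(q, wolf_threshold, coyote_threshold) == "hybrid"
  hybrid_counts <- vapply(labs, function(z) sum(hyb[zone == z]), integer(1))
  chisq <- chisq_equal_test(hybrid_counts, n_mc)
  list(per_zone = per_zone,
       anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       lsd_p = lsd_p, hybrid_counts = hybrid_counts, chisq = chisq)
}

# compact letter display: sweep maximal runs of pairwise-nonsignificant
# zones over the descending means
lsd_letters <- function(means, lsd_p, alpha) {
  ord <- order(means, decreasing = TRUE)
  nz <- length(means)
  runs <- list()
  i <- 1
  while (i <= nz) {
    j <- i
    while (j < nz &&
           all(lsd_p[ord[i:j], ord[j + 1]] >= alpha, na.rm = TRUE)) j <- j + 1
    run <- ord[i:j]
    if (length(runs) == 0 || !all(run %in% runs[[length(runs)]]))
      runs[[length(runs) + 1L]] <- run
    i <- i + 1
  }
  letters_out <- rep("", nz)
  for (r in seq_along(runs))
    letters_out[runs[[r]]] <- paste0(letters_out[runs[[r]]], letters[r])
  letters_out
}

# chi-squared test of counts against equal proportions, asymptotic and
# Monte Carlo reference distributions
chisq_equal_test <- function(counts, n_mc = 10000) {
  k <- length(counts)
  n <- sum(counts)
  expd <- rep(n / k, k)
  stat <- sum((counts - expd)^2 / expd)
  p_asym <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  p_mc <- NA_real_
  if (n > 0 && n_mc > 0) {
    sims <- rmultinom(n_mc, n, rep(1 / k, k))
    stats <- colSums((sims - expd)^2 / expd)
    p_mc <- (sum(stats >= stat - 1e-12) + 1) / (n_mc + 1)
  }
  list(statistic = stat, df = k - 1, p_asymptotic = p_asym, p_mc = p_mc)
}

#' Two-sample Kolmogorov-Smirnov comparison of ancestry distributions
#'
#' `D` is the supremum distance between the two empirical distribution
#' functions, evaluated at every pooled data point (so ties are handled
#' exactly); the p-value is the asymptotic Kolmogorov distribution at
#' `sqrt(n1 n2 / (n1 + n2)) * D`.
#'
#' @param x,y numeric samples.
#' @return List with `d`, `p`, `n_x`, `n_y`.
#' @export
ks_compare <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  d <- max(abs(fx - fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  t <- sqrt(n_eff) * d
  j <- seq_len(100)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  list(d = d, p = min(max(p, 0), 1), n_x = length(x), n_y = length(y))
}

#' Logistic fit to a ranked ancestry distribution
#'
#' Sorts the ancestry values ascending and fits
#' `y = a / (1 + exp(-c (x - b)))` with `x` the 1-based rank, by
#' Levenberg-Marquardt nonlinear least squares. The steepness `c`
#' reflects the scarcity of intermediate ancestry values: a bimodal
#' (parentals-only) distribution has a much steeper transition than one
#' rich in hybrids. Starting values are `a = max(y)`, `b = N/2` and a
#' quartile-based slope.
#'
#' @param q ancestry values (>= 4).
#' @param max_iter maximum optimizer iterations.
#' @return An object of class `logistic_fit`: list with `a`, `b`, `c`,
#'   `converged`, `rss`, `n`.
#' @export
fit_logistic <- function(q, max_iter = 200) {
  n <- length(q)
  if (n < 4) stop("need >= 4 values")
  y <- sort(unname(q))
  x <- seq_len(n)
  a0 <- max(y)
  b0 <- n / 2
  c0 <- 4 * (y[ceiling(3 * n / 4)] - y[ceiling(n / 4)]) / (n / 2)
  if (!is.finite(c0) || c0 <= 0) c0 <- 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a / (1 + exp(-cc * (x - b))),
                      start = list(a = a0, b = b0, cc = c0),
                      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred0 <- a0 / (1 + exp(-c0 * (x - b0)))
    return(structure(list(a = a0, b = b0, c = c0, converged = FALSE,
                          rss = sum((y - pred0)^2), n = n),
                     class = "logistic_fit"))
  }
  cf <- coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["cc"]),
                 converged = fit$convInfo$isConv %||% TRUE,
                 rss = sum(stats::residuals(fit)^2), n = n),
            class = "logistic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: a = %.4f, b = %.3f, c = %.4f (rss = %.3g, n = %d%s)\n",
              x$a, x$b, x$c, x$rss, x$n,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Compare an empirical ancestry distribution against scenarios
#'
#' The headline orchestration: for each scenario, solve its composition
#' against the observed region ancestries, simulate the implied
#' genotypes from the parental pools, estimate ancestry with the
#' admixture model at K = 2 (several runs, aligned, composited and
#' anchored on the simulated parental individuals), and compare the
#' scenario's ancestry distribution with the empirical one by the
#' Kolmogorov-Smirnov statistic and the fitted logistic steepness.
#'
#' @param q_empirical observed ancestry values.
#' @param scenarios data frame with columns `label` and `p_h`.
#' @param regions region table passed to [solve_composition()].
#' @param p1_pool,p2_pool parental [allele_freqs()] tables.
#' @param hybrid_mean_ancestry passed to [solve_composition()].
#' @param runs admixture runs per scenario composite (default 10).
#' @param seed integer seed driving every stochastic step.
#' @param ... further arguments to [fit_admixture()] (model, burnin,
#'   reps, thin...).
#' @return An object of class `scenario_report`: list with `table` (one
#'   row per scenario: composition counts, K-S `d` and `p`, logistic
#'   `a`, `b`, `c`), `empirical_logistic`, and `details` (per-scenario
#'   composition, composite q and errors, if any).
#' @export
run_scenario_comparison <- function(q_empirical, scenarios, regions,
                                    p1_pool, p2_pool,
                                    hybrid_mean_ancestry = 0.5, runs = 10,
                                    seed = NULL, ...) {
  stopifnot(is.data.frame(scenarios),
            all(c("label", "p_h") %in% names(scenarios)))
  if (!is.null(seed)) set.seed(seed)
  emp_fit <- fit_logistic(q_empirical)
  rows <- vector("list", nrow(scenarios))
  details <- list()
  for (s in seq_len(nrow(scenarios))) {
    lab <- scenarios$label[s]
    res <- tryCatch({
      comp <- solve_composition(regions, scenarios$p_h[s],
                                hybrid_mean_ancestry, label = lab)
      sseed <- if (!is.null(seed)) seed + 1000 * s
      dat <- build_scenario_dataset(comp, p1_pool, p2_pool, seed = sseed)
      fits <- fit_admixture_runs(dat, K = 2, n_runs = runs,
                                 seed = if (!is.null(sseed)) sseed + 1, ...)
      comp_fit <- align_runs(fits)
      comp_fit <- anchor_on_classes(comp_fit, dat$meta$class)
      qsim <- comp_fit$q[, 1]
      ks <- ks_compare(q_empirical, qsim)
      lf <- fit_logistic(qsim)
      list(row = data.frame(label = lab, p_h = scenarios$p_h[s],
                            R = comp$counts[["P1"]], C = comp$counts[["P2"]],
                            H = sum(comp$counts[c("F1", "F2", "BC1", "BC2")]),
                            d = ks$d, p = ks$p,
                            a = lf$a, b = lf$b, c = lf$c,
                            stringsAsFactors = FALSE),
           detail = list(composition = comp, q = qsim, ks = ks,
                         logistic = lf))
    }, error = function(e) {
      list(row = data.frame(label = lab, p_h = scenarios$p_h[s],
                            R = NA, C = NA, H = NA, d = NA, p = NA,
                            a = NA, b = NA, c = NA,
                            stringsAsFactors = FALSE),
           detail = list(error = conditionMessage(e)))
    })
    rows[[s]] <- res$row
    details[[lab]] <- res$detail
  }
  structure(list(table = do.call(rbind, rows),
                 empirical_logistic = emp_fit, details = details),
            class = "scenario_report")
}

# anchor a composite fit using the simulated class labels: parental
# classes play the role of known individuals
anchor_on_classes <- function(fit, classes) {
  known <- character(0)
  if (any(classes == "P1"))
    known <- c(known, setNames(rep("wolf", sum(classes == "P1")),
                               fit$ids[classes == "P1"]))
  if (any(classes == "P2"))
    known <- c(known, setNames(rep("coyote", sum(classes == "P2")),
                               fit$ids[classes == "P2"]))
  if (length(known) == 0) return(fit)
  if (any(known == "wolf"))
    return(anchor_clusters(fit, known, target = "wolf"))
  # no simulated wolves: anchor on coyotes, then move the wolf
  # (non-coyote) cluster to column 1
  out <- anchor_clusters(fit, known, target = "coyote",
                         labels = c("coyote", "wolf"))
  perm <- c(2, 1, seq_len(fit$K)[-(1:2)])
  out$q <- out$q[, perm, drop = FALSE]
  out$ci_lower <- out$ci_lower[, perm, drop = FALSE]
  out$ci_upper <- out$ci_upper[, perm, drop = FALSE]
  out$cluster_labels <- colnames(out$q)
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("scenario_report:\n")
  print(x$table, row.names = FALSE)
  cat("empirical logistic steepness c =",
      format(x$empirical_logistic$c, digits = 4), "\n")
  invisible(x)
}

#' Read a scenario configuration file
#'
#' JSON or YAML (by extension) with fields `regions` (list of `label`,
#' `total`, `mean_q`), `scenarios` (list of `label`, `p_h`) and
#' optional `hybrid_mean_ancestry`, `runs`, `seed`.
#'
#' @param file path to a `.json`, `.yaml` or `.yml` file.
#' @return List with `regions` and `scenarios` as data frames plus any
#'   scalar options present.
#' @export
read_scenario_config <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
    yaml::read_yaml(file)
  else jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  to_df <- function(x) {
    if (is.data.frame(x)) x
    else do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  cfg$regions <- to_df(cfg$regions)
  cfg$scenarios <- to_df(cfg$scenarios)
  num <- function(d, cols) { for (cn in cols) d[[cn]] <- as.numeric(d[[cn]]); d }
  cfg$regions <- num(cfg$regions, c("total", "mean_q"))
  cfg$scenarios <- num(cfg$scenarios, "p_h")
  cfg
}
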