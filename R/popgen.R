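#' Observed and unbiased expected heterozygosity
#'
#' Per locus, `H_O` is the fraction of heterozygotes among typed
#' individuals and `H_E` is Nei's unbiased expected heterozygosity
#' `(2n/(2n-1)) * (1 - sum(p_i^2))` with `n` the number of typed
#' individuals.
#'
#' @param x a [genotype_matrix()].
#' @return Data frame with columns `locus`, `n`, `ho`, `he`.
#' @export
heterozygosity <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  out <- data.frame(locus = x$loci, n = NA_integer_, ho = NA_real_,
                    he = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(n_loci(x))) {
    typed <- !is.na(x$a1[, j])
    n <- sum(typed)
    out$n[j] <- n
    if (n < 1) next
    out$ho[j] <- mean(x$a1[typed, j] != x$a2[typed, j])
    p <- table(c(x$a1[typed, j], x$a2[typed, j])) / (2 * n)
    if (n >= 1) out$he[j] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  }
  out
}

#' Hardy-Weinberg exact test with Monte Carlo replicates
#'
#' Conditional-on-allele-counts exact test: the observed genotype table
#' is compared with tables generated by randomly pairing the observed
#' allele pool into diploid genotypes. The p-value is the proportion of
#' tables (the observed one included in numerator and denominator)
#' whose conditional probability under the Hardy-Weinberg null (Levene's
#' multivariate hypergeometric) is at most that of the observed table.
#'
#' @param x a [genotype_matrix()].
#' @param locus locus label or index.
#' @param n_mc number of Monte Carlo tables (default 1000).
#' @param seed optional integer seed.
#' @return The Monte Carlo p-value.
#' @export
hwe_exact_test <- function(x, locus, n_mc = 1000, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.character(locus)) locus <- match(locus, x$loci)
  typed <- !is.na(x$a1[, locus])
  if (sum(typed) < 2) stop("need >= 2 typed individuals")
  a1 <- x$a1[typed, locus]; a2 <- x$a2[typed, locus]
  pool <- c(a1, a2)
  if (length(unique(pool)) == 1) {
    warning("monomorphic locus: p = 1")
    return(1)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- hwe_table_stat(a1, a2)
  n2 <- length(pool)
  hits <- 0L
  for (r in seq_len(n_mc)) {
    perm <- pool[sample.int(n2)]
    g1 <- perm[seq(1, n2, 2)]; g2 <- perm[seq(2, n2, 2)]
    if (hwe_table_stat(g1, g2) <= obs + 1e-9) hits <- hits + 1L
  }
  (hits + 1) / (n_mc + 1)
}

# log relative probability of a genotype table given its allele counts:
# log P = const + h*log2 - sum(lgamma(n_g + 1)) over genotype categories
hwe_table_stat <- function(a1, a2) {
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  h <- sum(lo != hi)
  code <- lo * 100003 + hi
  cnt <- tabulate(match(code, unique(code)))
  h * log(2) - sum(lgamma(cnt + 1))
}

#' Global Hardy-Weinberg test across loci
#'
#' Runs [hwe_exact_test()] per locus and combines the p-values with
#' Fisher's method.
#'
#' @inheritParams hwe_exact_test
#' @param loci loci to include; default all polymorphic typed loci.
#' @return List with `p_global`, `statistic`, `df` and the per-locus
#'   p-values.
#' @export
hwe_global_test <- function(x, loci = x$loci, n_mc = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ps <- vapply(loci, function(l) {
    tryCatch(suppressWarnings(hwe_exact_test(x, l, n_mc)),
             error = function(e) NA_real_)
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  stat <- -2 * sum(log(ps))
  list(p_global = pchisq(stat, df = 2 * length(ps), lower.tail = FALSE),
       statistic = stat, df = 2 * length(ps), p_locus = ps)
}

#' Weir-Cockerham F-statistics
#'
#' Variance-components estimators of F_IS and F_ST. With a single
#' subpopulation only F_IS is estimable (the between-population
#' component is dropped). Missing genotypes are excluded per locus, and
#' the multilocus estimates are ratios of components summed over loci
#' and alleles.
#'
#' @param x a [genotype_matrix()].
#' @param pops subpopulation labels, one per individual; default one
#'   population.
#' @return List with `per_locus` (data frame `locus`, `fis`, `fst`) and
#'   `multilocus` (named vector `fis`, `fst`).
#' @export
f_statistics <- function(x, pops = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(pops)) pops <- rep("pop", n_ind(x))
  pops <- as.character(pops)
  per <- data.frame(locus = x$loci, fis = NA_real_, fst = NA_real_,
                    stringsAsFactors = FALSE)
  A <- B <- C <- BC_b <- BC_c <- 0  # multilocus accumulators
  for (j in seq_len(n_loci(x))) {
    comp <- wc_components(x$a1[, j], x$a2[, j], pops)
    if (is.null(comp)) next
    per$fis[j] <- 1 - comp$c / (comp$b + comp$c)
    if (!is.na(comp$a))
      per$fst[j] <- comp$a / (comp$a + comp$b + comp$c)
    if (!is.na(comp$a)) A <- A + comp$a
    B <- B + comp$b; C <- C + comp$c
  }
  multi <- c(fis = 1 - C / (B + C),
             fst = if (length(unique(pops)) > 1) A / (A + B + C) else NA_real_)
  list(per_locus = per, multilocus = multi)
}

# Weir & Cockerham (1984) per-locus variance components summed over
# alleles; a is NA when fewer than two populations are typed
wc_components <- function(a1, a2, pops) {
  typed <- !is.na(a1)
  if (sum(typed) < 2) return(NULL)
  a1 <- a1[typed]; a2 <- a2[typed]; pops <- pops[typed]
  ni <- table(pops)
  ni <- ni[ni > 0]
  r <- length(ni)
  alleles <- unique(c(a1, a2))
  if (length(alleles) < 2) return(list(a = if (r > 1) 0 else NA_real_,
                                       b = 0, c = 0))
  nbar <- mean(ni)
  nc <- if (r > 1) (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1) else NA_real_
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    pi <- vapply(names(ni), function(g) {
      idx <- pops == g
      (sum(a1[idx] == al) + sum(a2[idx] == al)) / (2 * sum(idx))
    }, numeric(1))
    hi <- vapply(names(ni), function(g) {
      idx <- pops == g
      mean(a1[idx] != a2[idx] & (a1[idx] == al | a2[idx] == al))
    }, numeric(1))
    pbar <- sum(ni * pi) / (r * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    s2 <- if (r > 1) sum(ni * (pi - pbar)^2) / ((r - 1) * nbar) else 0
    between <- if (r > 1) (r - 1) / r * s2 else 0
    if (r > 1) {
      a_tot <- a_tot + nbar / nc *
        (s2 - (pbar * (1 - pbar) - between - hbar / 4) / (nbar - 1))
    }
    b_tot <- b_tot + nbar / (nbar - 1) *
      (pbar * (1 - pbar) - between - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_tot <- c_tot + hbar / 2
  }
  list(a = if (r > 1) a_tot else NA_real_, b = b_tot, c = c_tot)
}

#' Allelic richness by bootstrap to the smallest group
#'
#' Each group is resampled with replacement to the smallest group's
#' size; allelic richness is the mean over resamples of the mean number
#' of distinct alleles per locus, with a percentile 95% confidence
#' interval over resamples.
#'
#' @param x a [genotype_matrix()].
#' @param groups group labels, one per individual.
#' @param n_boot number of resamples (default 1000).
#' @param seed optional integer seed.
#' @return Data frame with per-group `ar`, `lower`, `upper`.
#' @export
allelic_richness <- function(x, groups, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  groups <- as.character(groups)
  if (!is.null(seed)) set.seed(seed)
  sizes <- table(groups)
  nmin <- min(sizes)
  labs <- names(sizes)
  out <- data.frame(group = labs, ar = NA_real_, lower = NA_real_,
                    upper = NA_real_, stringsAsFactors = FALSE)
  for (g in labs) {
    idx <- which(groups == g)
    reps <- vapply(seq_len(n_boot), function(b) {
      take <- idx[sample.int(length(idx), nmin, replace = TRUE)]
      mean(vapply(seq_len(n_loci(x)), function(j) {
        al <- c(x$a1[take, j], x$a2[take, j])
        length(unique(al[!is.na(al)]))
      }, numeric(1)))
    }, numeric(1))
    out[out$group == g, c("ar", "lower", "upper")] <-
      c(mean(reps), quantile(reps, c(0.025, 0.975), names = FALSE))
  }
  out
}

#' Wahlund-effect regression of F_IS on F_ST
#'
#' Pooling two differentiated populations inflates homozygosity in
#' proportion to between-population differentiation, so per-locus F_IS
#' and F_ST become positively correlated. Ordinary least squares of
#' F_IS on F_ST, with the Pearson correlation and its two-sided t-test.
#'
#' @param fis,fst per-locus statistics (paired; `NA` pairs dropped).
#' @return List with `r`, `p`, `slope`, `intercept`, `n_loci`.
#' @export
wahlund_regression <- function(fis, fst) {
  ok <- !is.na(fis) & !is.na(fst)
  fis <- fis[ok]; fst <- fst[ok]
  if (length(fis) < 3) stop("need >= 3 loci with both statistics")
  if (var(fst) == 0) {
    warning("zero variance in F_ST: slope undefined")
    return(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = mean(fis), n_loci = length(fis)))
  }
  ct <- cor.test(fst, fis)
  fit <- lm(fis ~ fst)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_loci = length(fis))
}

#' Bootstrap confidence interval for multilocus F_IS
#'
#' Resamples loci with replacement and recomputes the multilocus
#' Weir-Cockerham F_IS; the interval is the bias-corrected percentile
#' interval over `n_boot` replicates.
#'
#' @param x a [genotype_matrix()].
#' @param pops optional subpopulation labels.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return List with `fis`, `lower`, `upper`, `n_boot`.
#' @export
fis_bootstrap_ci <- function(x, pops = NULL, n_boot = 1000, conf = 0.95,
                             seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  point <- f_statistics(x, pops)$multilocus["fis"]
  if (n_loci(x) < 2) {
    warning("single locus: point estimate only")
    return(list(fis = unname(point), lower = NA_real_, upper = NA_real_,
                n_boot = 0L))
  }
  boot <- vapply(seq_len(n_boot), function(b) {
    jj <- sample.int(n_loci(x), replace = TRUE)
    xb <- genotype_matrix(x$a1[, jj, drop = FALSE],
                          x$a2[, jj, drop = FALSE], ids = x$ids,
                          loci = paste0("boot", seq_along(jj)))
    f_statistics(xb, pops)$multilocus["fis"]
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  alpha <- 1 - conf
  z0 <- stats::qnorm(pmin(pmax(mean(boot < point), 1 / length(boot)),
                          1 - 1 / length(boot)))
  lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha / 2))
  hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha / 2))
  ci <- quantile(boot, c(lo, hi), names = FALSE)
  list(fis = unname(point), lower = ci[1], upper = ci[2],
       n_boot = length(boot))
}

#' Per-group population-genetic summary
#'
#' Convenience wrapper producing the per-locus and per-group summary
#' table: observed and unbiased expected heterozygosity, F_IS, HWE
#' exact-test p-value per locus within each group, plus per-group
#' allelic richness with confidence interval and the bootstrap F_IS
#' interval.
#'
#' @param x a [genotype_matrix()].
#' @param groups group labels (e.g. zones), one per individual.
#' @param n_mc Monte Carlo replicates for the HWE tests.
#' @param n_boot bootstrap replicates for A_R and F_IS intervals.
#' @param seed optional integer seed.
#' @return List with `per_locus` (long data frame) and `per_group`.
#' @export
popgen_summary <- function(x, groups, n_mc = 1000, n_boot = 1000,
                           seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  groups <- as.character(groups)
  if (!is.null(seed)) set.seed(seed)
  labs <- unique(groups)
  per_locus <- do.call(rbind, lapply(labs, function(g) {
    xg <- x[groups == g, ]
    het <- heterozygosity(xg)
    fs <- f_statistics(xg)$per_locus
    hwe <- vapply(x$loci, function(l) {
      tryCatch(suppressWarnings(hwe_exact_test(xg, l, n_mc)),
               error = function(e) NA_real_)
    }, numeric(1))
    data.frame(group = g, het[c("locus", "n", "ho", "he")],
               fis = fs$fis, hwe_p = unname(hwe),
               stringsAsFactors = FALSE)
  }))
  ar <- allelic_richness(x, groups, n_boot)
  fis_ci <- do.call(rbind, lapply(labs, function(g) {
    ci <- fis_bootstrap_ci(x[groups == g, ], n_boot = n_boot)
    data.frame(group = g, fis = ci$fis, fis_lower = ci$lower,
               fis_upper = ci$upper, stringsAsFactors = FALSE)
  }))
  per_group <- merge(fis_ci, ar, by = "group", sort = FALSE)
  list(per_locus = per_locus, per_group = per_group)
}
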