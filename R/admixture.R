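#' Fit the Bayesian admixture model
#'
#' Gibbs sampler for the K-cluster admixture model on diploid unlinked
#' multilocus genotypes: each allele copy originates from one of K
#' clusters with individual-specific proportions `q` drawn from a
#' symmetric Dirichlet whose hyperparameter `alpha` is learned by
#' Metropolis steps on the log scale (uniform prior on `(0,
#' alpha_max)`). Cluster allele frequencies follow either independent
#' `Dirichlet(lambda)` priors (`model = "uncorrelated"`) or the
#' correlated-frequencies prior in which cluster frequencies drift
#' around a common ancestral vector with per-cluster drift parameters
#' (`model = "correlated"`, the default, suited to recently diverged
#' populations). Missing loci contribute nothing to the likelihood.
#'
#' Point estimates are posterior means of `q` over the post-burn-in
#' thinned samples, with equal-tailed credibility intervals. The model
#' log-probability reported for model choice is
#' `mean(logLik) - var(logLik)/2` over retained samples.
#'
#' @param x a [genotype_matrix()].
#' @param K number of clusters (>= 1, at most the number of
#'   individuals).
#' @param model `"correlated"` (default) or `"uncorrelated"` cluster
#'   allele frequencies.
#' @param burnin,reps burn-in sweeps and post-burn-in sweeps.
#' @param thin keep every `thin`-th post-burn-in sweep (default 10).
#' @param lambda Dirichlet parameter of the frequency prior
#'   (uncorrelated model and the ancestral vector; default 1).
#' @param alpha,alpha_max initial value and prior upper bound of the
#'   Dirichlet hyperparameter.
#' @param ci credibility-interval mass (default 0.90, equal-tailed).
#' @param seed optional integer seed.
#' @param keep_samples keep the full thinned `q` sample array.
#' @return An object of class `admix_fit` with posterior mean `q`
#'   (individuals x clusters), interval bounds `ci_lower`/`ci_upper`,
#'   `lnpd` (model log-probability), traces of the log-likelihood,
#'   `alpha` and drift `f`, and the sampler settings.
#' @seealso [align_runs()], [evanno_deltaK()], [anchor_clusters()]
#' @export
fit_admixture <- function(x, K = 2, model = c("correlated", "uncorrelated"),
                          burnin = 5000, reps = 50000, thin = 10,
                          lambda = 1, alpha = 1, alpha_max = 10,
                          ci = 0.90, seed = NULL, keep_samples = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"))
  model <- match.arg(model)
  if (K < 1) stop("K must be >= 1")
  if (K > n_ind(x)) stop("K exceeds the number of individuals")
  if (burnin < 0 || reps < thin) stop("need reps >= thin and burnin >= 0")
  if (any(typed_loci(x) == 0))
    stop("individuals without any typed locus: ",
         paste(x$ids[typed_loci(x) == 0], collapse = ", "))
  enc <- encode_genotypes(x)
  if (!is.null(seed)) set.seed(seed)
  if (K == 1) {
    q <- matrix(1, n_ind(x), 1, dimnames = list(x$ids, "cluster1"))
    # likelihood at the pooled-frequency point, for Delta-K bookkeeping
    raw <- admix_gibbs(enc$geno, enc$n_alleles, 1L, as.integer(burnin),
                       as.integer(reps), as.integer(thin),
                       model == "correlated", lambda, alpha, alpha_max,
                       0.1, 0.01, 0.05, 0.05)
    return(new_admix_fit(q, q, q, raw, K, model, burnin, reps, thin, seed,
                         x, if (keep_samples) raw$q_samples))
  }
  raw <- admix_gibbs(enc$geno, enc$n_alleles, as.integer(K),
                     as.integer(burnin), as.integer(reps),
                     as.integer(thin), model == "correlated", lambda,
                     alpha, alpha_max, 0.1, 0.01, 0.05, 0.05)
  qs <- raw$q_samples  # nsamp x n x K
  qmean <- apply(qs, c(2, 3), mean)
  a <- (1 - ci) / 2
  qlo <- apply(qs, c(2, 3), quantile, probs = a, names = FALSE)
  qhi <- apply(qs, c(2, 3), quantile, probs = 1 - a, names = FALSE)
  dimnames(qmean) <- dimnames(qlo) <- dimnames(qhi) <-
    list(x$ids, paste0("cluster", seq_len(K)))
  new_admix_fit(qmean, qlo, qhi, raw, K, model, burnin, reps, thin, seed,
                x, if (keep_samples) qs)
}

new_admix_fit <- function(q, lo, hi, raw, K, model, burnin, reps, thin,
                          seed, x, samples = NULL) {
  ll <- raw$loglik
  structure(list(
    q = q, ci_lower = lo, ci_upper = hi,
    lnpd = mean(ll) - var(ll) / 2,
    loglik = ll, alpha = raw$alpha, f = raw$f,
    K = K, cluster_labels = colnames(q),
    ids = rownames(q), loci = x$loci,
    settings = list(model = model, burnin = burnin, reps = reps,
                    thin = thin, seed = seed),
    samples = samples), class = "admix_fit")
}

# map allele labels to per-locus 1-based registry indices (0 = missing)
encode_genotypes <- function(x) {
  L <- n_loci(x)
  geno <- matrix(0L, n_ind(x), 2 * L)
  n_alleles <- integer(L)
  registry <- vector("list", L)
  for (j in seq_len(L)) {
    labs <- sort(unique(c(x$a1[, j], x$a2[, j])))
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0) labs <- 0L  # untyped locus: placeholder allele
    registry[[j]] <- labs
    n_alleles[j] <- length(labs)
    i1 <- match(x$a1[, j], labs); i2 <- match(x$a2[, j], labs)
    geno[, 2 * j - 1] <- ifelse(is.na(i1), 0L, i1)
    geno[, 2 * j] <- ifelse(is.na(i2), 0L, i2)
  }
  list(geno = geno, n_alleles = n_alleles, registry = registry)
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admix_fit: K = %d (%s frequencies), %d individuals\n",
              x$K, x$settings$model, nrow(x$q)))
  cat(sprintf("  Ln P(D) = %.2f; mean alpha = %.3f\n", x$lnpd,
              mean(x$alpha)))
  cat("  mean q per cluster:",
      paste(sprintf("%s %.3f", x$cluster_labels, colMeans(x$q)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.admix_fit <- function(object, ...) {
  out <- list(K = object$K, model = object$settings$model,
              n = nrow(object$q), lnpd = object$lnpd,
              alpha = mean(object$alpha),
              mean_q = colMeans(object$q),
              q = data.frame(id = rownames(object$q), object$q,
                             check.names = FALSE))
  class(out) <- "summary.admix_fit"
  out
}

#' @export
print.summary.admix_fit <- function(x, ...) {
  cat(sprintf("Admixture model, K = %d, %s frequencies, %d individuals\n",
              x$K, x$model, x$n))
  cat(sprintf("Ln P(D) = %.2f, posterior mean alpha = %.3f\n", x$lnpd,
              x$alpha))
  print(head(x$q, 10))
  if (nrow(x$q) > 10) cat("...", nrow(x$q) - 10, "more individuals\n")
  invisible(x)
}

#' @export
coef.admix_fit <- function(object, ...) object$q

#' @export
fitted.admix_fit <- function(object, ...) object$q

#' @export
logLik.admix_fit <- function(object, ...) {
  structure(object$lnpd, df = nrow(object$q) * (object$K - 1),
            class = "logLik")
}

#' @export
predict.admix_fit <- function(object, cluster = 1,
                              wolf_threshold = 0.875,
                              coyote_threshold = 0.125, ...) {
  classify_ancestry(object$q[, cluster], wolf_threshold, coyote_threshold)
}

#' @export
plot.admix_fit <- function(x, cluster = 1, ...) {
  q <- sort(x$q[, cluster])
  plot(seq_along(q), q, pch = 16, cex = 0.5, xlab = "individual (ranked)",
       ylab = sprintf("ancestry q (%s)", x$cluster_labels[cluster]),
       ylim = c(0, 1), ...)
  invisible(x)
}

#' Run the admixture sampler several times
#'
#' Independent restarts with distinct seeds, as used for composite
#' q-value estimation and Delta-K model choice.
#'
#' @inheritParams fit_admixture
#' @param n_runs number of independent runs.
#' @param seed base seed; run `r` uses `seed + r - 1`.
#' @param ... passed to [fit_admixture()].
#' @return List of `admix_fit` objects.
#' @export
fit_admixture_runs <- function(x, K = 2, n_runs = 5, seed = NULL, ...) {
  lapply(seq_len(n_runs), function(r) {
    fit_admixture(x, K = K, seed = if (!is.null(seed)) seed + r - 1, ...)
  })
}

#' Align replicate runs and composite their q-matrices
#'
#' Cluster labels are arbitrary within each run. Each run after the
#' first is permuted by the cluster permutation maximizing the
#' inner-product similarity of its q-matrix with the running mean of
#' the already-aligned runs (exhaustive over the K! permutations), then
#' the composite is the mean of aligned posterior means; interval
#' bounds and the model log-probability are averaged the same way.
#'
#' @param runs list of `admix_fit` objects sharing K and individuals.
#' @return A composite `admix_fit`.
#' @export
align_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  K <- runs[[1]]$K
  ids <- runs[[1]]$ids
  for (r in runs) {
    if (r$K != K) stop("all runs must share K")
    if (!identical(r$ids, ids)) stop("all runs must share individuals")
  }
  if (length(runs) == 1) return(runs[[1]])
  if (K > 8) stop("exhaustive alignment supports K <= 8")
  perms <- permutations(K)
  acc_q <- runs[[1]]$q
  acc_lo <- runs[[1]]$ci_lower
  acc_hi <- runs[[1]]$ci_upper
  n_acc <- 1
  for (r in runs[-1]) {
    ref <- acc_q / n_acc
    sims <- vapply(seq_len(nrow(perms)), function(p)
      sum(ref * r$q[, perms[p, ], drop = FALSE]), numeric(1))
    best <- perms[which.max(sims), ]
    acc_q <- acc_q + r$q[, best, drop = FALSE]
    acc_lo <- acc_lo + r$ci_lower[, best, drop = FALSE]
    acc_hi <- acc_hi + r$ci_upper[, best, drop = FALSE]
    n_acc <- n_acc + 1
  }
  out <- runs[[1]]
  out$q <- acc_q / n_acc
  out$ci_lower <- acc_lo / n_acc
  out$ci_upper <- acc_hi / n_acc
  colnames(out$q) <- colnames(out$ci_lower) <- colnames(out$ci_upper) <-
    paste0("cluster", seq_len(K))
  out$lnpd <- mean(vapply(runs, `[[`, numeric(1), "lnpd"))
  out$settings$n_runs <- length(runs)
  out$samples <- NULL
  out
}

# all permutations of 1..K as a matrix (K! rows)
permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- permutations(K - 1)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Evanno Delta-K table for choosing the number of clusters
#'
#' Groups replicate runs by K and computes, for each interior K,
#' `deltaK = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))` where `L(K)` is the
#' mean model log-probability over runs. Requires at least three
#' consecutive K values with at least two runs each.
#'
#' @param runs list of `admix_fit` objects spanning several K values.
#' @return List with `table` (data frame `K`, `mean_lnpd`, `sd_lnpd`,
#'   `delta_k`) and `best_k` (argmax of the defined deltaK values).
#' @export
evanno_deltaK <- function(runs) {
  ks <- vapply(runs, `[[`, numeric(1), "K")
  lnpd <- vapply(runs, `[[`, numeric(1), "lnpd")
  kk <- sort(unique(ks))
  if (length(kk) < 3 || any(diff(kk) != 1))
    stop("need >= 3 consecutive K values")
  if (any(table(ks) < 2)) stop("need >= 2 runs per K")
  mu <- tapply(lnpd, ks, mean)[as.character(kk)]
  sdv <- tapply(lnpd, ks, sd)[as.character(kk)]
  dk <- rep(NA_real_, length(kk))
  for (i in seq(2, length(kk) - 1)) {
    if (sdv[i] > 0) {
      dk[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sdv[i]
    } else {
      warning("zero sd at K = ", kk[i], ": deltaK undefined")
    }
  }
  tab <- data.frame(K = kk, mean_lnpd = unname(mu), sd_lnpd = unname(sdv),
                    delta_k = dk)
  list(table = tab, best_k = if (all(is.na(dk))) NA_integer_
                             else kk[which.max(dk)])
}

#' Anchor clusters to species via known individuals
#'
#' Noninvasive surveys carry no a priori cluster labels; individuals
#' whose genotypes match known reference animals identify which cluster
#' is which. The cluster with the highest mean q among known
#' individuals of the target species is moved to column 1 and the
#' columns relabelled.
#'
#' @param fit an `admix_fit`.
#' @param known named character vector mapping individual ids to
#'   species labels.
#' @param target species label whose cluster becomes cluster 1
#'   (default `"wolf"`).
#' @param labels cluster labels after anchoring; default
#'   `c("wolf", "coyote")` padded with the remaining cluster numbers.
#' @return The fit with permuted, relabelled clusters and an
#'   `anchoring` element (per-species cluster and mean q of knowns).
#' @export
anchor_clusters <- function(fit, known, target = "wolf",
                            labels = c("wolf", "coyote")) {
  stopifnot(inherits(fit, "admix_fit"))
  ids <- intersect(names(known), fit$ids)
  if (length(ids) == 0) stop("no known individual present in the fit")
  known <- known[ids]
  species <- unique(known)
  if (!target %in% species) stop("no known individual of species ", target)
  cluster_of <- vapply(species, function(s) {
    which.max(colMeans(fit$q[names(known)[known == s], , drop = FALSE]))
  }, integer(1))
  if (length(species) > 1 && anyDuplicated(cluster_of)) {
    # two species claim the same cluster: list individuals whose own
    # majority cluster disagrees with their species' majority
    maj <- apply(fit$q[ids, , drop = FALSE], 1, which.max)
    bad <- ids[maj != cluster_of[known[ids]]]
    stop("conflicting anchor assignments; offending individuals: ",
         paste(bad, collapse = ", "))
  }
  kw <- cluster_of[[target]]
  perm <- c(kw, setdiff(seq_len(fit$K), kw))
  fit$q <- fit$q[, perm, drop = FALSE]
  fit$ci_lower <- fit$ci_lower[, perm, drop = FALSE]
  fit$ci_upper <- fit$ci_upper[, perm, drop = FALSE]
  lab <- c(labels, paste0("cluster", seq_len(fit$K)))[seq_len(fit$K)]
  colnames(fit$q) <- colnames(fit$ci_lower) <- colnames(fit$ci_upper) <- lab
  fit$cluster_labels <- lab
  fit$anchoring <- data.frame(
    species = species, cluster = unname(cluster_of),
    mean_q = vapply(species, function(s)
      mean(fit$q[names(known)[known == s],
                 which(perm == cluster_of[[s]])]), numeric(1)),
    row.names = NULL)
  fit
}
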