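#' Generate a pair of divergent parental allele-frequency pools
#'
#' Draws an ancestral frequency vector per locus from a flat Dirichlet
#' and perturbs it once per parental pool with a Dirichlet whose
#' concentration is `(1 - divergence) / divergence` (a Balding-Nichols
#' construction), so the expected Weir-Cockerham F_ST between the pools
#' increases monotonically with `divergence`. `divergence = 0` returns
#' two identical pools (the shared ancestral draw); `divergence = 1`
#' fixes the pools for alternate alleles wherever the locus carries at
#' least two alleles.
#'
#' @param n_loci number of loci (>= 1); default 17.
#' @param alleles_per_locus allele count, scalar or per-locus vector.
#' @param divergence dissimilarity parameter in `[0, 1]`.
#' @param seed optional integer seed.
#' @return List with elements `p1` and `p2`, both [allele_freqs()] over
#'   an identical locus/allele registry.
#' @examples
#' pools <- generate_parental_frequencies(4, 3, divergence = 0.5, seed = 1)
#' pools$p1
#' @export
generate_parental_frequencies <- function(n_loci = 17, alleles_per_locus = 5,
                                          divergence, seed = NULL) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  A <- rep_len(alleles_per_locus, n_loci)
  if (any(A < 1)) stop("alleles_per_locus must be >= 1")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  loci <- sprintf("L%02d", seq_len(n_loci))
  f1 <- f2 <- list()
  for (j in seq_len(n_loci)) {
    labs <- as.character(100L + 2L * (seq_len(A[j]) - 1L))  # fragment sizes
    anc <- rdirichlet1(rep(1, A[j]))
    if (divergence == 0) {
      p1 <- p2 <- anc
    } else if (divergence == 1) {
      p1 <- p2 <- numeric(A[j])
      p1[1] <- 1
      p2[min(2, A[j])] <- if (A[j] >= 2) 1 else p2[1] + 1
    } else {
      conc <- (1 - divergence) / divergence
      p1 <- rdirichlet1(anc * conc)
      p2 <- rdirichlet1(anc * conc)
    }
    f1[[loci[j]]] <- setNames(p1, labs)
    f2[[loci[j]]] <- setNames(p2, labs)
  }
  list(p1 = allele_freqs(f1, "P1"), p2 = allele_freqs(f2, "P2"))
}

# one Dirichlet draw; zero concentrations give structural zeros
rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, rgamma(length(alpha), alpha), 0)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Landscape configuration for the synthetic survey generator
#'
#' Describes the zoned hybrid-zone survey to simulate: marker panel,
#' parental divergence, and per-zone counts of each genotype class.
#' Zones are listed east to west; when no polygon geometry is supplied
#' the zones occupy consecutive unit intervals on a one-dimensional
#' east-west axis (the analyses only use zone order, not real
#' geography). The default emulates a survey of 75 red wolves, 224
#' coyotes and 12 hybrids across six zones with parental classes forming
#' an east-west gradient.
#'
#' @param zone_counts data frame of per-zone class counts with columns
#'   `P1`, `P2`, `F1`, `F2`, `BC1`, `BC2` and row names giving unique
#'   zone labels in east-to-west order.
#' @param n_loci,alleles_per_locus,divergence,seed passed to
#'   [generate_parental_frequencies()].
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(zone_counts = default_zone_counts(),
                             n_loci = 17, alleles_per_locus = 5,
                             divergence = 0.5, seed = NULL) {
  zone_counts <- as.data.frame(zone_counts)
  need <- names(hybrid_classes())
  if (!all(need %in% names(zone_counts)))
    stop("zone_counts needs columns ", paste(need, collapse = ", "))
  zone_counts <- zone_counts[need]
  if (anyDuplicated(rownames(zone_counts))) stop("zone labels must be unique")
  if (any(as.matrix(zone_counts) < 0)) stop("zone counts must be >= 0")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  structure(list(zone_counts = zone_counts, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 divergence = divergence, seed = seed),
            class = "landscape_config")
}

#' @rdname landscape_config
#' @export
default_zone_counts <- function() {
  # east -> west; P1 confined to the three eastern (managed-area) zones,
  # hybrids spread evenly, two per zone
  z <- data.frame(
    P1  = c(30, 25, 20, 0, 0, 0),
    P2  = c(6, 10, 80, 50, 20, 58),
    F1  = c(1, 0, 1, 0, 1, 0),
    F2  = c(0, 1, 0, 1, 0, 1),
    BC1 = c(1, 0, 1, 0, 1, 0),
    BC2 = c(0, 1, 0, 1, 0, 1),
    row.names = c("Z1", "Z2", "Z3", "ZB", "ZC", "ZD"))
  z
}

#' Simulate a zoned hybrid-zone survey
#'
#' Generates parental pools at the configured divergence, simulates each
#' zone's individuals class by class via [simulate_class()], and places
#' them on a one-dimensional east-west axis: with `n` zones listed east
#' to west, the easternmost zone occupies `[n-1, n)` and the westernmost
#' `[0, 1)`, with uniform scatter inside the interval and a uniform `y`
#' in `[0, 1]`. Each individual's expected admixture ancestry (`true_q`)
#' and class are recorded.
#'
#' @param config a [landscape_config()].
#' @return An object of class `survey_dataset`: list with `genotypes`
#'   (a [genotype_matrix()] whose metadata holds `class`, `true_q`,
#'   `zone`, `x`, `y`), `freqs` (the parental pools), and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  zc <- config$zone_counts
  if (sum(as.matrix(zc)) == 0) stop("all zone counts are zero: empty dataset")
  if (!is.null(config$seed)) set.seed(config$seed)
  pools <- generate_parental_frequencies(config$n_loci,
                                         config$alleles_per_locus,
                                         config$divergence)
  nz <- nrow(zc)
  parts <- list()
  for (i in seq_len(nz)) {
    zone <- rownames(zc)[i]
    x_lo <- nz - i  # east-to-west listing -> descending x intervals
    for (cl in names(hybrid_classes())) {
      n <- zc[i, cl]
      if (n == 0) next
      g <- simulate_class(pools$p1, pools$p2, cl, n,
                          prefix = paste0(zone, "_", cl))
      g$meta$zone <- zone
      g$meta$x <- x_lo + runif(n)
      g$meta$y <- runif(n)
      parts[[length(parts) + 1L]] <- g
    }
  }
  geno <- bind_genotypes(parts)
  structure(list(genotypes = geno, freqs = pools, config = config),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("survey_dataset:\n")
  print(x$genotypes)
  print(table(zone = x$genotypes$meta$zone, class = x$genotypes$meta$class))
  invisible(x)
}

#' Replicate-PCR observation model
#'
#' Error model for noninvasive genotyping: per PCR a locus fails
#' entirely with `failure_rate`; otherwise each allele of a heterozygote
#' drops out independently with `dropout_rate`, and a spurious allele
#' (uniform over the locus registry, different from the true alleles) is
#' added with `false_allele_rate`.
#'
#' @param dropout_rate,false_allele_rate,failure_rate probabilities in
#'   `[0, 1]`.
#' @param n_replicates number of PCR replicates per sample x locus.
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(dropout_rate = 0.1, false_allele_rate = 0.02,
                              failure_rate = 0.1, n_replicates = 4) {
  p <- c(dropout_rate, false_allele_rate, failure_rate)
  if (any(p < 0 | p > 1)) stop("rates must be probabilities in [0, 1]")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(dropout_rate = dropout_rate,
                 false_allele_rate = false_allele_rate,
                 failure_rate = failure_rate,
                 n_replicates = as.integer(n_replicates)),
            class = "observation_model")
}

#' Simulate noisy replicate PCRs from true genotypes
#'
#' @param truth a [genotype_matrix()] of true genotypes.
#' @param model an [observation_model()].
#' @param seed optional integer seed.
#' @param registry optional per-locus list of candidate allele labels
#'   for false alleles; defaults to the alleles present in `truth`.
#' @return A `replicate_obs` object ([replicate_obs()]).
#' @export
simulate_replicate_pcrs <- function(truth, model, seed = NULL,
                                    registry = NULL) {
  stopifnot(inherits(truth, "genotype_matrix"),
            inherits(model, "observation_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(registry))
    registry <- lapply(seq_len(n_loci(truth)), function(j)
      sort(unique(c(truth$a1[, j], truth$a2[, j]))))
  rows <- vector("list", n_ind(truth) * n_loci(truth) * model$n_replicates)
  k <- 0L
  for (i in seq_len(n_ind(truth))) {
    for (j in seq_len(n_loci(truth))) {
      true_all <- unique(c(truth$a1[i, j], truth$a2[i, j]))
      true_all <- true_all[!is.na(true_all)]
      for (r in seq_len(model$n_replicates)) {
        obs <- integer(0)
        if (length(true_all) > 0 && runif(1) >= model$failure_rate) {
          obs <- true_all
          if (length(true_all) == 2)  # dropout acts on heterozygotes
            obs <- obs[runif(2) >= model$dropout_rate]
          if (runif(1) < model$false_allele_rate) {
            cand <- setdiff(registry[[j]], true_all)
            if (length(cand) > 0)
              obs <- c(obs, cand[sample.int(length(cand), 1)])
          }
        }
        k <- k + 1L
        rows[[k]] <- list(sample = truth$ids[i], locus = truth$loci[j],
                          replicate = r, alleles = sort(obs))
      }
    }
  }
  tab <- data.frame(
    sample = vapply(rows, `[[`, character(1), "sample"),
    locus = vapply(rows, `[[`, character(1), "locus"),
    replicate = vapply(rows, `[[`, integer(1), "replicate"),
    stringsAsFactors = FALSE)
  tab$alleles <- lapply(rows, `[[`, "alleles")
  replicate_obs(tab)
}
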