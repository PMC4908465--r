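#' Consensus genotypes from replicate PCRs
#'
#' Applies the replication acceptance rules used for noninvasive
#' samples: a heterozygous genotype is accepted only when exactly two
#' distinct alleles are each observed in at least two independent PCRs;
#' a homozygous genotype only when a single allele is observed alone in
#' at least three independent PCRs. Any other pattern leaves the locus
#' missing, and a locus where more than two alleles gain replicate
#' support is set missing and flagged. Samples whose accepted loci fall
#' below `min_loci` are excluded and reported.
#'
#' @param obs a [replicate_obs()] table.
#' @param min_loci minimum accepted loci for a sample to be retained
#'   (default 6).
#' @param samples optional character vector of expected sample ids, so
#'   samples without any replicate are reported as excluded.
#' @param loci optional locus ordering for the output.
#' @return An object of class `consensus_result`: list with `genotypes`
#'   (a [genotype_matrix()] of retained samples), `locus_counts`
#'   (accepted-locus count for every sample), `excluded` (data frame of
#'   sample, reason) and `flagged` (data frame of sample, locus, reason).
#' @export
call_consensus <- function(obs, min_loci = 6, samples = NULL, loci = NULL) {
  stopifnot(inherits(obs, "replicate_obs"))
  if (min_loci < 1) stop("min_loci must be >= 1")
  tab <- obs$table
  if (is.null(samples)) samples <- unique(tab$sample)
  if (is.null(loci)) loci <- unique(tab$locus)
  a1 <- a2 <- matrix(NA_integer_, length(samples), length(loci),
                     dimnames = list(samples, loci))
  flagged <- list()
  for (s in samples) {
    sub <- tab[tab$sample == s, , drop = FALSE]
    for (l in unique(sub$locus)) {
      reps <- sub$alleles[sub$locus == l]
      g <- consensus_locus(reps)
      if (g$flag != "")
        flagged[[length(flagged) + 1L]] <- data.frame(sample = s, locus = l,
                                                      reason = g$flag)
      if (!is.null(g$genotype)) {
        a1[s, l] <- g$genotype[1]
        a2[s, l] <- g$genotype[2]
      }
    }
  }
  counts <- rowSums(!is.na(a1))
  no_reps <- setdiff(samples, unique(tab$sample))
  keep <- counts >= min_loci & !(samples %in% no_reps)
  excluded <- data.frame(
    sample = samples[!keep],
    reason = ifelse(samples[!keep] %in% no_reps, "no replicates",
                    sprintf("only %d accepted loci (< %d)",
                            counts[!keep], min_loci)),
    stringsAsFactors = FALSE)
  geno <- if (any(keep))
    genotype_matrix(a1[keep, , drop = FALSE], a2[keep, , drop = FALSE],
                    ids = samples[keep], loci = loci)
  structure(list(genotypes = geno,
                 locus_counts = setNames(counts, samples),
                 excluded = excluded,
                 flagged = if (length(flagged)) do.call(rbind, flagged)
                           else data.frame(sample = character(0),
                                           locus = character(0),
                                           reason = character(0))),
            class = "consensus_result")
}

# acceptance rule for one sample x locus; reps = list of integer vectors
consensus_locus <- function(reps) {
  alleles <- unlist(reps)
  if (length(alleles) == 0) return(list(genotype = NULL, flag = ""))
  # replicate support: number of PCRs in which each allele was seen
  support <- table(unlist(lapply(reps, unique)))
  backed <- as.integer(names(support)[support >= 2])
  if (length(backed) > 2)
    return(list(genotype = NULL, flag = ">2 replicate-supported alleles"))
  if (length(backed) == 2)
    return(list(genotype = sort(backed), flag = ""))
  if (length(backed) == 1) {
    solo <- sum(vapply(reps, function(r) identical(unique(r), backed),
                       logical(1)))
    if (solo >= 3)
      return(list(genotype = c(backed, backed), flag = ""))
  }
  list(genotype = NULL, flag = "")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d samples retained, %d excluded, %d flagged loci\n",
              if (is.null(x$genotypes)) 0L else n_ind(x$genotypes),
              nrow(x$excluded), nrow(x$flagged)))
  invisible(x)
}
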