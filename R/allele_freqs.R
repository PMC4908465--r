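#' Per-locus allele frequency table
#'
#' Allele frequencies for one population over an ordered set of loci.
#' Each locus holds a named numeric vector over that locus's allele
#' registry (names are integer allele labels, e.g. fragment sizes).
#'
#' @param freq named list (one element per locus) of named non-negative
#'   numeric vectors, each summing to 1.
#' @param population_id label of the population the frequencies describe.
#' @return An object of class `allele_freqs` with elements
#'   `population_id`, `loci`, `freq`.
#' @examples
#' allele_freqs(list(L1 = c(`100` = 0.5, `104` = 0.5)), "wolf")
#' @export
allele_freqs <- function(freq, population_id = "pop") {
  if (!is.list(freq) || length(freq) == 0)
    stop("freq must be a non-empty list of per-locus frequency vectors")
  if (is.null(names(freq)) || anyDuplicated(names(freq)))
    stop("freq must be named by unique locus labels")
  for (l in names(freq)) {
    p <- freq[[l]]
    if (length(p) < 1) stop("locus ", l, " has no alleles")
    if (is.null(names(p)) || anyDuplicated(names(p)))
      stop("allele labels at locus ", l, " must be unique and named")
    if (any(p < 0)) stop("negative frequency at locus ", l)
    if (abs(sum(p) - 1) > 1e-9)
      stop("frequencies at locus ", l, " do not sum to 1")
  }
  structure(list(population_id = as.character(population_id),
                 loci = names(freq), freq = freq),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  na <- vapply(x$freq, length, integer(1))
  cat(sprintf("allele_freqs '%s': %d loci, %d-%d alleles per locus\n",
              x$population_id, length(x$loci), min(na), max(na)))
  invisible(x)
}

#' Estimate allele frequencies from a parental genotype sample
#'
#' Frequencies are allele counts divided by the number of typed allele
#' copies per locus; missing genotypes are excluded. Loci with zero typed
#' copies are dropped with a warning.
#'
#' @param x a [genotype_matrix()] of reference individuals.
#' @param population_id label for the resulting table.
#' @return An [allele_freqs()] table.
#' @export
estimate_frequencies <- function(x, population_id = "pop") {
  stopifnot(inherits(x, "genotype_matrix"))
  freq <- list()
  for (j in seq_len(n_loci(x))) {
    copies <- c(x$a1[, j], x$a2[, j])
    copies <- copies[!is.na(copies)]
    if (length(copies) == 0) {
      warning("locus ", x$loci[j], " has no typed copies; dropped")
      next
    }
    tab <- table(copies)
    p <- as.numeric(tab) / length(copies)
    names(p) <- names(tab)
    freq[[x$loci[j]]] <- p[order(as.numeric(names(p)))]
  }
  if (length(freq) == 0) stop("no locus with typed copies")
  allele_freqs(freq, population_id)
}

# shared registry: union of allele labels per locus across tables
shared_registry <- function(...) {
  tabs <- list(...)
  loci <- tabs[[1]]$loci
  for (t in tabs) if (!identical(t$loci, loci))
    stop("allele frequency tables must share the same loci")
  lapply(setNames(loci, loci), function(l) {
    labs <- unique(unlist(lapply(tabs, function(t) names(t$freq[[l]]))))
    labs[order(as.numeric(labs))]
  })
}

# expand a frequency vector onto a registry (absent alleles get 0)
expand_freq <- function(p, registry) {
  out <- setNames(numeric(length(registry)), registry)
  out[names(p)] <- p
  out
}
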