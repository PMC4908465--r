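#' Hybrid classes and their expected ancestry
#'
#' The six genotype classes of a two-species hybrid zone and the expected
#' proportion of ancestry each carries from parental population 1 (the
#' red wolf pool in the motivating system): pure parentals, first- and
#' second-generation hybrids, and the two first-generation backcrosses.
#'
#' @return Named numeric vector of expected P1 ancestry:
#'   P1 = 1, P2 = 0, F1 = 0.5, F2 = 0.5, BC1 (F1 x P1) = 0.75,
#'   BC2 (F1 x P2) = 0.25.
#' @export
hybrid_classes <- function() {
  c(P1 = 1, P2 = 0, F1 = 0.5, F2 = 0.5, BC1 = 0.75, BC2 = 0.25)
}

# draw n gametes (n x L allele matrix) from a parental pool
draw_gametes <- function(freqs, n, registry = NULL) {
  L <- length(freqs$loci)
  m <- matrix(0L, n, L)
  for (j in seq_len(L)) {
    p <- freqs$freq[[j]]
    labs <- as.integer(names(p))
    m[, j] <- labs[sample.int(length(p), n, replace = TRUE, prob = p)]
  }
  m
}

# F1 gamete: per locus, pick parental origin with prob 1/2, then draw
draw_f1_gametes <- function(freqs_p1, freqs_p2, n) {
  g1 <- draw_gametes(freqs_p1, n)
  g2 <- draw_gametes(freqs_p2, n)
  from_p1 <- matrix(runif(length(g1)) < 0.5, nrow(g1), ncol(g1))
  out <- g2
  out[from_p1] <- g1[from_p1]
  out
}

#' Sample a Hardy-Weinberg population from allele frequencies
#'
#' Each individual receives two allele copies per locus drawn
#' independently from the locus frequency vector; no missing data.
#'
#' @param freqs an [allele_freqs()] table.
#' @param n number of individuals (>= 1).
#' @param seed optional integer seed.
#' @param prefix prefix for generated individual ids.
#' @return A [genotype_matrix()].
#' @export
sample_population <- function(freqs, n, seed = NULL, prefix = "ind") {
  stopifnot(inherits(freqs, "allele_freqs"))
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  a1 <- draw_gametes(freqs, n)
  a2 <- draw_gametes(freqs, n)
  genotype_matrix(a1, a2, ids = paste0(prefix, seq_len(n)), loci = freqs$loci)
}

#' Simulate genotypes for a parental or hybrid class
#'
#' Gamete-based simulation with unlinked loci, in the manner of
#' HybridLab: a parental gamete draws one allele per locus from that
#' pool's frequencies; an F1 individual is one P1 gamete plus one P2
#' gamete; an F1 gamete picks its origin pool with probability 1/2
#' independently per locus; an F2 is two F1 gametes; a backcross is one
#' F1 gamete plus one parental gamete.
#'
#' @param freqs_p1,freqs_p2 [allele_freqs()] tables for the two parental
#'   pools over the same loci.
#' @param class one of `"P1"`, `"P2"`, `"F1"`, `"F2"`, `"BC1"` (F1 x P1),
#'   `"BC2"` (F1 x P2).
#' @param n number of individuals (>= 1).
#' @param seed optional integer seed.
#' @param prefix prefix for generated ids (defaults to the class name).
#' @return A [genotype_matrix()] with a `class` metadata column.
#' @examples
#' p1 <- allele_freqs(list(L1 = c(`1` = 1)), "w")
#' p2 <- allele_freqs(list(L1 = c(`2` = 1)), "c")
#' simulate_class(p1, p2, "F1", 3, seed = 1)
#' @export
simulate_class <- function(freqs_p1, freqs_p2, class, n, seed = NULL,
                           prefix = class) {
  class <- match.arg(class, names(hybrid_classes()))
  if (!identical(freqs_p1$loci, freqs_p2$loci))
    stop("parental pools must share the same locus registry")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- switch(class,
    P1 = list(draw_gametes(freqs_p1, n), draw_gametes(freqs_p1, n)),
    P2 = list(draw_gametes(freqs_p2, n), draw_gametes(freqs_p2, n)),
    F1 = list(draw_gametes(freqs_p1, n), draw_gametes(freqs_p2, n)),
    F2 = list(draw_f1_gametes(freqs_p1, freqs_p2, n),
              draw_f1_gametes(freqs_p1, freqs_p2, n)),
    BC1 = list(draw_f1_gametes(freqs_p1, freqs_p2, n),
               draw_gametes(freqs_p1, n)),
    BC2 = list(draw_f1_gametes(freqs_p1, freqs_p2, n),
               draw_gametes(freqs_p2, n)))
  genotype_matrix(g[[1]], g[[2]], ids = paste0(prefix, "_", seq_len(n)),
                  loci = freqs_p1$loci,
                  meta = data.frame(class = rep(class, n),
                                    true_q = rep(unname(hybrid_classes()[class]), n)))
}
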