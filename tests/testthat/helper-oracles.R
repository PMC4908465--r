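# Independent oracles and fixture builders shared across the test files.
# These deliberately use different algorithms (enumeration, double loops,
# frequency-level formulas) from the package implementations they check.

# fully diagnostic parental pools: two alleles per locus, alternately fixed
diag_pools <- function(L = 10) {
  f1 <- f2 <- list()
  for (j in seq_len(L)) {
    lab <- c("100", "102")
    f1[[paste0("L", j)]] <- setNames(c(1, 0), lab)
    f2[[paste0("L", j)]] <- setNames(c(0, 1), lab)
  }
  list(p1 = allele_freqs(f1, "P1"), p2 = allele_freqs(f2, "P2"))
}

# frequency-level per-locus F_ST between two frequency vectors (Nei,
# equal pool weights): (HT - HS) / HT
nei_fst <- function(p1, p2) {
  vapply(seq_along(p1$loci), function(j) {
    q1 <- p1$freq[[j]]; q2 <- p2$freq[[j]]
    labs <- union(names(q1), names(q2))
    a <- setNames(numeric(length(labs)), labs); a[names(q1)] <- q1
    b <- setNames(numeric(length(labs)), labs); b[names(q2)] <- q2
    hs <- 1 - (sum(a^2) + sum(b^2)) / 2
    ht <- 1 - sum(((a + b) / 2)^2)
    if (ht == 0) NA_real_ else (ht - hs) / ht
  }, numeric(1))
}

# brute-force single-locus identity probabilities by enumeration over
# ordered genotypes (Hardy-Weinberg population with frequencies p)
pid_enum <- function(p) {
  A <- length(p)
  # unordered genotype list with HW probabilities
  gprob <- list()
  for (i in seq_len(A)) for (j in i:A) {
    gprob[[paste(i, j)]] <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
  }
  unrelated <- sum(unlist(gprob)^2)
  # full sibs: enumerate ordered parental genotypes, then the shared
  # offspring genotype distribution
  sib <- 0
  for (m1 in seq_len(A)) for (m2 in seq_len(A))
    for (f1 in seq_len(A)) for (f2 in seq_len(A)) {
      pp <- p[m1] * p[m2] * p[f1] * p[f2]
      kid <- setNames(numeric(0), character(0))
      for (ma in c(m1, m2)) for (fa in c(f1, f2)) {
        g <- paste(min(ma, fa), max(ma, fa))
        kid[g] <- (if (g %in% names(kid)) kid[g] else 0) + 0.25
      }
      sib <- sib + pp * sum(kid^2)
    }
  c(unrelated = unrelated, sibs = sib)
}

# complete-enumeration Hardy-Weinberg exact p-value for one locus:
# all genotype tables compatible with the observed allele counts,
# Levene conditional probabilities, tail = tables no more probable
hwe_exact_enum <- function(a1, a2) {
  alleles <- sort(unique(c(a1, a2)))
  A <- length(alleles)
  cnt <- vapply(alleles, function(a) sum(a1 == a) + sum(a2 == a), numeric(1))
  n <- length(a1)
  cats <- list()
  for (i in seq_len(A)) for (j in i:A) cats[[length(cats) + 1]] <- c(i, j)
  tables <- list()
  # recursive enumeration over genotype-category counts with pruning
  enum <- function(k, counts, left, rem) {
    if (k > length(cats)) {
      if (left == 0 && all(rem == 0))
        tables[[length(tables) + 1]] <<- counts
      return()
    }
    ij <- cats[[k]]
    use <- if (ij[1] == ij[2]) 2 else 1
    maxn <- left
    maxn <- min(maxn, floor(rem[ij[1]] / (if (ij[1] == ij[2]) 2 else 1)))
    if (ij[1] != ij[2]) maxn <- min(maxn, rem[ij[2]])
    for (m in 0:maxn) {
      rem2 <- rem
      rem2[ij[1]] <- rem2[ij[1]] - m * (if (ij[1] == ij[2]) 2 else 1)
      if (ij[1] != ij[2]) rem2[ij[2]] <- rem2[ij[2]] - m
      enum(k + 1, c(counts, m), left - m, rem2)
    }
  }
  enum(1, integer(0), n, cnt)
  logw <- vapply(tables, function(tb) {
    h <- sum(tb[vapply(cats, function(ij) ij[1] != ij[2], logical(1))])
    h * log(2) - sum(lgamma(tb + 1))
  }, numeric(1))
  w <- exp(logw - max(logw))
  probs <- w / sum(w)
  # observed table
  obs <- vapply(cats, function(ij) {
    sum(pmin(a1, a2) == alleles[ij[1]] & pmax(a1, a2) == alleles[ij[2]])
  }, numeric(1))
  idx <- which(vapply(tables, function(tb) all(tb == obs), logical(1)))
  sum(probs[probs <= probs[idx] + 1e-12])
}

# double-loop two-sample Kolmogorov-Smirnov statistic
ks_brute <- function(x, y) {
  d <- 0
  for (t in c(x, y)) {
    d <- max(d, abs(sum(x <= t) / length(x) - sum(y <= t) / length(y)))
  }
  d
}

# exhaustive rule-checker for the consensus acceptance rules, written as
# candidate-genotype enumeration rather than support counting
consensus_oracle <- function(reps) {
  alleles <- sort(unique(unlist(reps)))
  hets <- list()
  if (length(alleles) >= 2) {
    cmb <- combn(alleles, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      if (sum(vapply(reps, function(r) a %in% r, logical(1))) >= 2 &&
          sum(vapply(reps, function(r) b %in% r, logical(1))) >= 2)
        hets[[length(hets) + 1]] <- c(a, b)
    }
  }
  homs <- list()
  for (a in alleles) {
    if (sum(vapply(reps, function(r) identical(sort(unique(r)), a),
                   logical(1))) >= 3)
      homs[[length(homs) + 1]] <- c(a, a)
  }
  # exactly one replicate-backed pair <=> exactly two backed alleles
  if (length(hets) == 1) return(hets[[1]])
  if (length(hets) == 0 && length(homs) == 1) return(homs[[1]])
  NULL
}

# independent scalar transcription of the Weir-Cockerham (1984)
# components for two populations and two alleles
wc_two_pop_oracle <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# small genotype matrix from explicit allele pairs (one locus per list
# element: n x 2 matrix)
gm_from_pairs <- function(..., ids = NULL) {
  loci <- list(...)
  a1 <- do.call(cbind, lapply(loci, function(m) m[, 1]))
  a2 <- do.call(cbind, lapply(loci, function(m) m[, 2]))
  genotype_matrix(a1, a2, ids = ids)
}
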