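#' Match multilocus genotypes against a reference panel
#'
#' Compares every query individual with every reference individual over
#' the loci typed in both. A pair is a `match` when the shared loci
#' number at least `min_overlap` and at most `max_mismatch` loci carry
#' different (unordered) genotypes; pairs with too little overlap are
#' reported as `no-comparison`. When more than one reference matches a
#' query, those reports are downgraded to `ambiguous`.
#'
#' @param query,reference [genotype_matrix()] objects over the same
#'   locus registry (extra loci on either side are ignored).
#' @param min_overlap minimum shared typed loci for a verdict
#'   (default 6).
#' @param max_mismatch maximum mismatching loci still counted as a match
#'   (default 0, exact matching on shared loci).
#' @return Data frame with columns `query`, `reference`,
#'   `loci_compared`, `mismatches`, `verdict`.
#' @export
match_genotypes <- function(query, reference, min_overlap = 6,
                            max_mismatch = 0) {
  stopifnot(inherits(query, "genotype_matrix"),
            inherits(reference, "genotype_matrix"))
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")
  shared <- intersect(query$loci, reference$loci)
  nq <- n_ind(query); nr <- n_ind(reference)
  if (length(shared) == 0) {
    return(data.frame(query = rep(query$ids, each = nr),
                      reference = rep(reference$ids, nq),
                      loci_compared = 0L, mismatches = 0L,
                      verdict = "no-comparison", stringsAsFactors = FALSE))
  }
  q <- query[, shared]; r <- reference[, shared]
  out <- vector("list", nq)
  for (i in seq_len(nq)) {
    both <- !is.na(q$a1[rep(i, nr), , drop = FALSE]) & !is.na(r$a1)
    diff <- (q$a1[rep(i, nr), , drop = FALSE] != r$a1) |
            (q$a2[rep(i, nr), , drop = FALSE] != r$a2)
    overlap <- rowSums(both)
    mism <- rowSums(both & diff)
    verdict <- ifelse(overlap < min_overlap, "no-comparison",
                      ifelse(mism <= max_mismatch, "match", "no-match"))
    is_match <- verdict == "match"
    if (sum(is_match) > 1) verdict[is_match] <- "ambiguous"
    out[[i]] <- data.frame(query = q$ids[i], reference = r$ids,
                           loci_compared = overlap, mismatches = mism,
                           verdict = verdict, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Regroup scat samples into unique individuals
#'
#' Pairwise matches ([match_genotypes()] of the sample set against
#' itself) are closed transitively; each resulting group is one
#' individual. A group in which some internal pair disagrees (shared
#' loci but mismatches above the threshold) is still merged but flagged
#' as an ambiguous cluster. Per individual, the consensus genotype takes
#' at each locus the most frequent genotype among its typed samples, the
#' coordinate is the arithmetic mean of the samples' coordinates, and
#' the zone is looked up from that centroid.
#'
#' @param samples a [genotype_matrix()] whose metadata may carry `x` and
#'   `y` coordinates.
#' @param min_overlap,max_mismatch matching thresholds, as in
#'   [match_genotypes()].
#' @param zones optional zone table for centroid assignment: a data
#'   frame with columns `zone`, `xmin`, `xmax` (east-west interval
#'   mode), or `NULL` to skip zone assignment.
#' @return An object of class `regroup_result`: list with `genotypes`
#'   (unique individuals; metadata `x`, `y`, `zone`, `n_detections`),
#'   `membership` (sample to individual map) and `ambiguous` (labels of
#'   flagged clusters).
#' @export
regroup_individuals <- function(samples, min_overlap = 6, max_mismatch = 0,
                                zones = NULL) {
  stopifnot(inherits(samples, "genotype_matrix"))
  n <- n_ind(samples)
  rep_match <- match_genotypes(samples, samples, min_overlap, max_mismatch)
  linked <- rep_match$verdict %in% c("match", "ambiguous") &
    rep_match$query != rep_match$reference
  # union-find with union-by-minimum, so each group's root is its first sample
  parent <- seq_len(n)
  for (k in which(linked)) {
    i <- match(rep_match$query[k], samples$ids)
    j <- match(rep_match$reference[k], samples$ids)
    ri <- find2(parent, i); rj <- find2(parent, j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), function(i) find2(parent, i), integer(1))
  groups <- split(seq_len(n), root)
  # an ambiguous cluster: some internal pair with enough overlap disagrees
  key <- paste(rep_match$query, rep_match$reference)
  disagree <- setNames(rep_match$verdict == "no-match", key)
  ids <- x <- y <- zone <- ndet <- vector("list", length(groups))
  a1 <- a2 <- matrix(NA_integer_, length(groups), n_loci(samples),
                     dimnames = list(NULL, samples$loci))
  ambiguous <- character(0)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    ids[[g]] <- samples$ids[idx[1]]
    ndet[[g]] <- length(idx)
    if (length(idx) > 1) {
      pairs <- combn(samples$ids[idx], 2)
      if (any(disagree[paste(pairs[1, ], pairs[2, ])], na.rm = TRUE))
        ambiguous <- c(ambiguous, ids[[g]])
    }
    for (j in seq_len(n_loci(samples))) {
      g1 <- samples$a1[idx, j]; g2 <- samples$a2[idx, j]
      typed <- !is.na(g1)
      if (!any(typed)) next
      gt <- paste(g1[typed], g2[typed])
      best <- names(sort(table(gt), decreasing = TRUE))[1]
      ab <- as.integer(strsplit(best, " ")[[1]])
      a1[g, j] <- ab[1]; a2[g, j] <- ab[2]
    }
    if (!is.null(samples$meta) && all(c("x", "y") %in% names(samples$meta))) {
      x[[g]] <- mean(samples$meta$x[idx])
      y[[g]] <- mean(samples$meta$y[idx])
      zone[[g]] <- if (!is.null(zones)) assign_zone(x[[g]], zones) else NA
    } else {
      x[[g]] <- NA_real_; y[[g]] <- NA_real_; zone[[g]] <- NA
    }
  }
  meta <- data.frame(x = unlist(x), y = unlist(y),
                     zone = unlist(zone), n_detections = unlist(ndet),
                     stringsAsFactors = FALSE)
  structure(list(
    genotypes = genotype_matrix(a1, a2, ids = unlist(ids),
                                loci = samples$loci, meta = meta),
    membership = data.frame(sample = samples$ids,
                            individual = samples$ids[root],
                            stringsAsFactors = FALSE),
    ambiguous = ambiguous), class = "regroup_result")
}

find2 <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' East-west interval lookup for zones
#'
#' Builds the interval table matching [generate_landscape()] (zones
#' listed east to west occupy descending unit intervals) and assigns a
#' coordinate to the zone containing it, clamping to the outermost
#' intervals.
#'
#' @param zone_labels zone labels in east-to-west order.
#' @param x numeric coordinate(s).
#' @param zones interval table from `zone_intervals()`.
#' @return `zone_intervals()` a data frame (`zone`, `xmin`, `xmax`);
#'   `assign_zone()` the zone label(s).
#' @export
zone_intervals <- function(zone_labels) {
  nz <- length(zone_labels)
  data.frame(zone = zone_labels, xmin = nz - seq_len(nz),
             xmax = nz - seq_len(nz) + 1, stringsAsFactors = FALSE)
}

#' @rdname zone_intervals
#' @export
assign_zone <- function(x, zones) {
  vapply(x, function(xi) {
    i <- which(xi >= zones$xmin & xi < zones$xmax)
    if (length(i) == 0) i <- if (xi < min(zones$xmin)) which.min(zones$xmin)
                             else which.max(zones$xmax)
    zones$zone[i[1]]
  }, character(1))
}

#' @export
print.regroup_result <- function(x, ...) {
  cat(sprintf("regroup_result: %d samples -> %d individuals (%d ambiguous clusters)\n",
              nrow(x$membership), n_ind(x$genotypes), length(x$ambiguous)))
  invisible(x)
}

#' Probability of identity for unrelated individuals and siblings
#'
#' Per locus with allele frequencies `p_i`,
#' `PID = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2` and
#' `PID_sibs = 0.25 + 0.5 sum(p_i^2) + 0.5 (sum(p_i^2))^2 - 0.25 sum(p_i^4)`.
#' Multilocus values are products over the requested loci, reported
#' cumulatively in the given order (the conventional check that a panel
#' can distinguish even full siblings).
#'
#' @param freqs an [allele_freqs()] table.
#' @param loci loci to use, in order; default all.
#' @return Data frame with per-locus `pid_unrelated`, `pid_sibs` and
#'   cumulative products `cum_unrelated`, `cum_sibs`.
#' @export
compute_pid <- function(freqs, loci = freqs$loci) {
  stopifnot(inherits(freqs, "allele_freqs"))
  if (length(loci) == 0) stop("loci must be non-empty")
  if (!all(loci %in% freqs$loci))
    stop("unknown loci: ", paste(setdiff(loci, freqs$loci), collapse = ", "))
  pid_u <- pid_s <- numeric(length(loci))
  for (k in seq_along(loci)) {
    p <- freqs$freq[[loci[k]]]
    s2 <- sum(p^2); s4 <- sum(p^4)
    het <- outer(p, p)
    pid_u[k] <- s4 + sum((2 * het[upper.tri(het)])^2)
    pid_s[k] <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  }
  data.frame(locus = loci, pid_unrelated = pid_u, pid_sibs = pid_s,
             cum_unrelated = cumprod(pid_u), cum_sibs = cumprod(pid_s),
             stringsAsFactors = FALSE)
}
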