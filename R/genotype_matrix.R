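#' Diploid multilocus genotype matrix
#'
#' The universal container of the pipeline: unordered diploid allele pairs
#' for a set of individuals at a shared set of loci. Allele labels are
#' integers (fragment sizes in practice). A missing genotype is missing for
#' the whole locus; allele pairs are stored sorted so that unordered
#' equality is plain element-wise equality.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two
#'   allele copies; `NA` in both marks a missing locus.
#' @param ids character vector of individual identifiers (unique).
#' @param loci character vector of locus labels (unique).
#' @param meta optional `data.frame` of per-individual metadata (zone,
#'   coordinates, known-identity label, true class...), one row per
#'   individual.
#' @return An object of class `genotype_matrix` with elements `a1`, `a2`,
#'   `ids`, `loci`, `meta`.
#' @examples
#' g <- genotype_matrix(matrix(c(1L, 1L), 2, 1), matrix(c(2L, 1L), 2, 1),
#'                      ids = c("s1", "s2"), loci = "L1")
#' is_heterozygote(g)
#' @export
genotype_matrix <- function(a1, a2, ids = NULL, loci = NULL, meta = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  ids <- as.character(ids); loci <- as.character(loci)
  if (length(ids) != nrow(a1)) stop("length(ids) must equal nrow(a1)")
  if (length(loci) != ncol(a1)) stop("length(loci) must equal ncol(a1)")
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (anyDuplicated(loci)) stop("locus labels must be unique")
  if (any(is.na(a1) != is.na(a2)))
    stop("missing genotypes must be missing for the whole locus")
  # store unordered pairs sorted
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != length(ids)) stop("meta must have one row per individual")
    rownames(meta) <- ids
  }
  structure(list(a1 = a1, a2 = a2, ids = ids, loci = loci, meta = meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              n_ind(x), n_loci(x), 100 * mean(is.na(x$a1))))
  if (!is.null(x$meta))
    cat("metadata columns:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Numbers of individuals and loci
#' @param x a [genotype_matrix()].
#' @return An integer count.
#' @export
n_ind <- function(x) nrow(x$a1)

#' @rdname n_ind
#' @export
n_loci <- function(x) ncol(x$a1)

#' @export
dim.genotype_matrix <- function(x) c(n_ind(x), n_loci(x))

#' Subset a genotype matrix by individuals and/or loci
#' @param x a [genotype_matrix()].
#' @param i individual index (integer, logical or id).
#' @param j locus index (integer, logical or label).
#' @param ... unused.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_ind(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  if (is.character(i)) i <- match(i, x$ids)
  if (is.character(j)) j <- match(j, x$loci)
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  ids = x$ids[i], loci = x$loci[j],
                  meta = if (!is.null(x$meta)) x$meta[i, , drop = FALSE])
}

#' Stack genotype matrices over individuals
#'
#' All inputs must share the same locus registry. Metadata columns are
#' merged by union, padding absent columns with `NA`.
#'
#' @param ... `genotype_matrix` objects.
#' @return A combined `genotype_matrix`.
#' @export
bind_genotypes <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !inherits(gs[[1]], "genotype_matrix"))
    gs <- gs[[1]]
  loci <- gs[[1]]$loci
  for (g in gs) if (!identical(g$loci, loci)) stop("loci must match across inputs")
  ids <- unlist(lapply(gs, `[[`, "ids"))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  metas <- lapply(gs, `[[`, "meta")
  meta <- NULL
  if (any(!vapply(metas, is.null, logical(1)))) {
    cols <- unique(unlist(lapply(metas, names)))
    meta <- do.call(rbind, lapply(seq_along(gs), function(k) {
      m <- metas[[k]]
      out <- as.data.frame(matrix(NA, n_ind(gs[[k]]), length(cols),
                                  dimnames = list(NULL, cols)))
      if (!is.null(m)) for (cn in names(m)) out[[cn]] <- m[[cn]]
      out
    }))
  }
  genotype_matrix(do.call(rbind, lapply(gs, `[[`, "a1")),
                  do.call(rbind, lapply(gs, `[[`, "a2")),
                  ids = ids, loci = loci, meta = meta)
}

#' Heterozygosity indicator per individual and locus
#' @param x a [genotype_matrix()].
#' @return Logical matrix (individuals x loci); `NA` where the locus is
#'   missing.
#' @export
is_heterozygote <- function(x) x$a1 != x$a2

#' Count typed (non-missing) loci per individual
#' @param x a [genotype_matrix()].
#' @return Integer vector named by individual id.
#' @export
typed_loci <- function(x) {
  setNames(rowSums(!is.na(x$a1)), x$ids)
}
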