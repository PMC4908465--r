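#' Read and write genotype tables
#'
#' Two plain-text formats are supported. The package CSV has one row per
#' individual, an `id` column, two columns per locus (`<locus>.1`,
#' `<locus>.2`) and any further columns kept as metadata; missing alleles
#' are coded `-9`. The STRUCTURE-style text format has one row per
#' individual: the id followed by two whitespace-separated allele columns
#' per locus, `-9` for missing, with an optional header row of locus
#' labels.
#'
#' @param x a [genotype_matrix()].
#' @param file path to read or write.
#' @return `read_genotypes()` / `read_structure()` return a
#'   [genotype_matrix()]; the writers return `file` invisibly.
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
write_genotypes <- function(x, file) {
  stopifnot(inherits(x, "genotype_matrix"))
  a1 <- x$a1; a2 <- x$a2
  a1[is.na(a1)] <- -9L; a2[is.na(a2)] <- -9L
  df <- data.frame(id = x$ids, stringsAsFactors = FALSE)
  for (j in seq_len(n_loci(x))) {
    df[[paste0(x$loci[j], ".1")]] <- a1[, j]
    df[[paste0(x$loci[j], ".2")]] <- a2[, j]
  }
  if (!is.null(x$meta)) df <- cbind(df, x$meta)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname genotype_io
#' @export
read_genotypes <- function(file) {
  df <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  allele_cols <- grep("\\.[12]$", names(df), value = TRUE)
  loci <- unique(sub("\\.[12]$", "", allele_cols))
  a1 <- as.matrix(df[paste0(loci, ".1")])
  a2 <- as.matrix(df[paste0(loci, ".2")])
  a1[a1 == -9] <- NA; a2[a2 == -9] <- NA
  meta_cols <- setdiff(names(df), c("id", allele_cols))
  genotype_matrix(a1, a2, ids = df$id, loci = loci,
                  meta = if (length(meta_cols)) df[meta_cols])
}

#' @rdname genotype_io
#' @export
write_structure <- function(x, file) {
  stopifnot(inherits(x, "genotype_matrix"))
  a1 <- x$a1; a2 <- x$a2
  a1[is.na(a1)] <- -9L; a2[is.na(a2)] <- -9L
  m <- matrix(0L, n_ind(x), 2L * n_loci(x))
  m[, seq(1, ncol(m), 2)] <- a1
  m[, seq(2, ncol(m), 2)] <- a2
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(x$loci, collapse = " "), con)
  writeLines(paste(x$ids, apply(m, 1, paste, collapse = " ")), con)
  invisible(file)
}

#' @rdname genotype_io
#' @export
read_structure <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  # header = row with an odd field count relative to the data rows, all
  # non-numeric entries
  has_header <- all(is.na(suppressWarnings(as.numeric(fields[[1]]))))
  loci <- NULL
  if (has_header) {
    loci <- fields[[1]]
    fields <- fields[-1]
  }
  ids <- vapply(fields, `[`, character(1), 1)
  vals <- lapply(fields, function(f) as.integer(f[-1]))
  L <- length(vals[[1]]) / 2
  if (L != floor(L)) stop("odd number of allele columns")
  m <- do.call(rbind, vals)
  a1 <- m[, seq(1, 2 * L, 2), drop = FALSE]
  a2 <- m[, seq(2, 2 * L, 2), drop = FALSE]
  a1[a1 == -9] <- NA; a2[a2 == -9] <- NA
  genotype_matrix(a1, a2, ids = ids, loci = loci)
}

#' Read and write replicate-PCR observation tables
#'
#' Long-format CSV with columns `sample`, `locus`, `replicate`, `alleles`
#' (pipe-separated integer labels, empty string for a failed
#' amplification).
#'
#' @param obs a `replicate_obs` object ([simulate_replicate_pcrs()]).
#' @param file path to read or write.
#' @return `read_replicates()` returns a `replicate_obs` object; the
#'   writer returns `file` invisibly.
#' @name replicate_io
NULL

#' @rdname replicate_io
#' @export
write_replicates <- function(obs, file) {
  stopifnot(inherits(obs, "replicate_obs"))
  df <- obs$table
  df$alleles <- vapply(df$alleles, function(a) paste(a, collapse = "|"),
                       character(1))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname replicate_io
#' @export
read_replicates <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  df$alleles <- lapply(strsplit(as.character(df$alleles), "|", fixed = TRUE),
                       function(a) as.integer(a[nzchar(a)]))
  replicate_obs(df)
}

#' Replicate-PCR observation table
#'
#' Wraps a long-format data frame (`sample`, `locus`, `replicate`,
#' `alleles` as a list column of integer vectors) and checks that
#' replicate indices are unique within each sample x locus.
#'
#' @param table data frame as described above.
#' @return An object of class `replicate_obs`.
#' @export
replicate_obs <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("sample", "locus", "replicate", "alleles") %in% names(table)))
  if (!is.list(table$alleles)) table$alleles <- as.list(table$alleles)
  key <- paste(table$sample, table$locus, table$replicate)
  if (anyDuplicated(key))
    stop("replicate indices must be unique within sample x locus")
  structure(list(table = table), class = "replicate_obs")
}

#' @export
print.replicate_obs <- function(x, ...) {
  cat(sprintf("replicate_obs: %d observations, %d samples, %d loci\n",
              nrow(x$table), length(unique(x$table$sample)),
              length(unique(x$table$locus))))
  invisible(x)
}
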