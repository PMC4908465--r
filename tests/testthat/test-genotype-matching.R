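mk_obs <- function(reps, sample = "s1", locus = "L1") {
  tab <- data.frame(sample = sample, locus = locus,
                    replicate = seq_along(reps), stringsAsFactors = FALSE)
  tab$alleles <- lapply(reps, as.integer)
  replicate_obs(tab)
}

test_that("consensus calling applies the replication acceptance rules", {
  het <- call_consensus(mk_obs(list(c(1, 2), c(1, 2))), min_loci = 1)
  expect_equal(unname(c(het$genotypes$a1[1, 1], het$genotypes$a2[1, 1])),
               c(1L, 2L))
  # two clean homozygous replicates are not enough (three required)
  hom2 <- call_consensus(mk_obs(list(1, 1)), min_loci = 1)
  expect_equal(nrow(hom2$excluded), 1L)
  hom3 <- call_consensus(mk_obs(list(1, 1, 1)), min_loci = 1)
  expect_equal(unname(hom3$genotypes$a2[1, 1]), 1L)
  # three replicate-backed alleles: flagged, locus missing
  tri <- call_consensus(mk_obs(list(c(1, 2), c(1, 3), c(2, 3))), min_loci = 1)
  expect_equal(tri$flagged$reason, ">2 replicate-supported alleles")
})

test_that("samples below the locus threshold are excluded with reasons", {
  # 5 accepted loci, min_loci = 6 -> excluded
  tab <- do.call(rbind, lapply(1:5, function(j) {
    d <- data.frame(sample = "s1", locus = paste0("L", j), replicate = 1:2)
    d$alleles <- list(c(1L, 2L), c(1L, 2L))
    d
  }))
  res <- call_consensus(replicate_obs(tab), min_loci = 6)
  expect_null(res$genotypes)
  expect_match(res$excluded$reason, "only 5 accepted loci")
  expect_equal(unname(res$locus_counts["s1"]), 5)
  # a sample with no replicates at all is reported separately
  res2 <- call_consensus(replicate_obs(tab), min_loci = 5,
                         samples = c("s1", "ghost"))
  expect_equal(res2$excluded$sample, "ghost")
  expect_equal(res2$excluded$reason, "no replicates")
})

test_that("consensus equals the exhaustive rule-checker on enumerated sets", {
  subsets <- list(integer(0), 1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L),
                  c(1L, 2L, 3L))
  set.seed(1)
  combos <- expand.grid(r1 = 1:8, r2 = 1:8, r3 = 1:8)
  for (k in seq_len(nrow(combos))) {
    reps <- subsets[as.integer(combos[k, ])]
    got <- consensus_locus(reps)$genotype
    want <- consensus_oracle(reps)
    expect_identical(got, want,
                     info = paste("reps:", paste(vapply(reps, paste,
                       character(1), collapse = ","), collapse = " | ")))
  }
  # spot-check four-replicate sets at random
  for (k in 1:300) {
    reps <- subsets[sample.int(8, 4, replace = TRUE)]
    expect_identical(consensus_locus(reps)$genotype, consensus_oracle(reps))
  }
})

test_that("genotype matching verdicts follow overlap and mismatch rules", {
  pools <- generate_parental_frequencies(17, 6, divergence = 0.2, seed = 3)
  ref <- sample_population(pools$p1, 5, seed = 4)
  hit <- match_genotypes(ref[1, ], ref, min_overlap = 6)
  expect_equal(hit$verdict[1], "match")
  expect_equal(hit$mismatches[1], 0L)
  expect_equal(hit$loci_compared[1], 17L)
  # one allele difference defeats exact matching
  q <- ref[1, ]
  q$a1[1, 1] <- q$a1[1, 1] + 1000L
  q$a2[1, 1] <- max(q$a1[1, 1], q$a2[1, 1])
  res <- match_genotypes(q, ref[1, ], max_mismatch = 0)
  expect_equal(res$verdict, "no-match")
  expect_equal(match_genotypes(q, ref[1, ], max_mismatch = 1)$verdict,
               "match")
  # disjoint loci: no-comparison, not an error
  r2 <- ref
  r2$loci <- paste0("other", seq_along(r2$loci))
  expect_true(all(match_genotypes(ref, r2)$verdict == "no-comparison"))
})

test_that("a self-matched reference panel identifies every individual uniquely", {
  pools <- generate_parental_frequencies(17, 6, divergence = 0.2, seed = 5)
  panel <- sample_population(pools$p1, 100, seed = 6)
  # the panel is individually resolvable: sibling PID below 1/100
  pid <- compute_pid(estimate_frequencies(panel))
  expect_lt(pid$cum_sibs[17], 1 / 100)
  rep <- match_genotypes(panel, panel)
  matches <- rep[rep$verdict %in% c("match", "ambiguous"), ]
  expect_equal(matches$verdict, rep("match", 100))
  expect_equal(matches$query, matches$reference)
})

test_that("regrouping merges repeat detections and averages coordinates", {
  pools <- generate_parental_frequencies(8, 5, divergence = 0.3, seed = 7)
  ind <- sample_population(pools$p1, 4, seed = 8)
  scats <- bind_genotypes(ind[1, ], ind[1, ], ind[1, ], ind[2, ],
                          ind[3, ], ind[4, ])
  scats$meta <- data.frame(x = c(0, 1, 2, 3.2, 1.1, 0.4), y = rep(0.5, 6))
  rg <- regroup_individuals(scats, min_overlap = 6,
                            zones = zone_intervals(c("E", "W")))
  expect_equal(n_ind(rg$genotypes), 4L)
  merged <- rg$genotypes$meta[1, ]
  expect_equal(merged$x, 1)          # centroid of 0, 1, 2
  expect_equal(merged$n_detections, 3)
  expect_equal(merged$zone, "E")     # straddles the boundary; centroid wins
  # no matches anywhere -> individuals are the samples
  lone <- regroup_individuals(ind, min_overlap = 6)
  expect_equal(n_ind(lone$genotypes), 4L)
  expect_equal(lone$membership$individual, ind$ids)
  # input order does not change the partition
  perm <- c(4, 2, 6, 1, 3, 5)
  rg2 <- regroup_individuals(scats[perm, ], min_overlap = 6)
  part1 <- split(rg$membership$sample, rg$membership$individual)
  part2 <- split(rg2$membership$sample, rg2$membership$individual)
  norm <- function(p) unname(lapply(p, sort))[order(vapply(lapply(p, sort),
                                                           `[`, character(1), 1))]
  expect_equal(norm(part1), norm(part2))
})

test_that("probability of identity matches enumeration and multiplies over loci", {
  even <- allele_freqs(list(L1 = c(`1` = 0.5, `2` = 0.5)))
  pid <- compute_pid(even)
  expect_equal(pid$pid_unrelated, 0.375)
  expect_equal(pid$pid_sibs, 0.59375)
  # enumeration oracle at an asymmetric three-allele locus
  p <- c(0.5, 0.3, 0.2)
  tri <- allele_freqs(list(L1 = setNames(p, c("1", "2", "3"))))
  oracle <- pid_enum(p)
  got <- compute_pid(tri)
  expect_equal(got$pid_unrelated, unname(oracle["unrelated"]), tolerance = 1e-12)
  expect_equal(got$pid_sibs, unname(oracle["sibs"]), tolerance = 1e-12)
  # single allele: identical genotypes are certain
  expect_equal(compute_pid(allele_freqs(list(L1 = c(`1` = 1))))$pid_sibs, 1)
  # each added polymorphic locus strictly lowers the cumulative values,
  # and siblings are always harder to tell apart than unrelated pairs
  pools <- generate_parental_frequencies(10, 5, divergence = 0.3, seed = 9)
  tab <- compute_pid(pools$p1)
  expect_true(all(diff(tab$cum_unrelated) < 0))
  expect_true(all(diff(tab$cum_sibs) < 0))
  expect_true(all(tab$pid_sibs >= tab$pid_unrelated))
  expect_error(compute_pid(pools$p1, loci = "nope"), "unknown loci")
})
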