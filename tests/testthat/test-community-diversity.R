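make_records <- function(seqs, samples = NULL) {
  data.frame(id = paste0("seq", seq_along(seqs)),
             sample = if (is.null(samples)) "S1" else samples,
             bases = seqs, stringsAsFactors = FALSE)
}

test_that("pairwise_distances computes p-distances over comparable sites", {
  dm <- pairwise_distances(make_records(c("ACGT", "ACGT", "ACGA")))
  expect_equal(dm["seq1", "seq2"], 0)
  expect_equal(dm["seq1", "seq3"], 0.25)  # one mismatch in four
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), setNames(rep(0, 3), rownames(dm)))

  # planted substitutions at known sites
  withr::with_seed(99, {
    base <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
    mut <- base
    sites <- sample(300, 15)
    for (s in sites) mut[s] <- setdiff(c("A", "C", "G", "T"), base[s])[1]
  })
  dm2 <- pairwise_distances(make_records(
    c(paste(base, collapse = ""), paste(mut, collapse = ""))))
  expect_equal(dm2[1, 2], 15 / 300)

  # ambiguous bases drop out of the denominator pairwise
  dm3 <- pairwise_distances(make_records(c("ACGTN", "ACGAN")))
  expect_equal(dm3[1, 2], 0.25)
})

test_that("unequal-length pairs are aligned before the distance", {
  # identical apart from a terminal overhang: distance 0
  dm <- pairwise_distances(make_records(c("ACGTACGTACGT", "ACGTACGTACGTAAAA")))
  expect_equal(dm[1, 2], 0)
  # one substitution inside the shared region
  dm2 <- pairwise_distances(make_records(c("ACGTACGTACGT", "ACGTACTTACGTAAAA")))
  expect_equal(dm2[1, 2], 1 / 12)
})

test_that("cluster_otus implements inclusive-boundary complete linkage", {
  d <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  d["s1", "s2"] <- d["s2", "s1"] <- 0.01
  d["s1", "s3"] <- d["s3", "s1"] <- 0.05
  d["s2", "s3"] <- d["s3", "s2"] <- 0.05
  # brute force over all partitions of 3 items: only {12}{3} is feasible
  # with fewest blocks at cutoff 0.03
  feas <- feasible_partitions(d, 0.03)
  best <- min(lengths(feas))
  expect_equal(best, 2L)
  ot <- cluster_otus(d, cutoff = 0.03)
  expect_equal(nrow(ot$counts), 2L)

  # boundary inclusive: distance exactly at the cutoff merges
  d["s1", "s2"] <- d["s2", "s1"] <- 0.03
  expect_equal(nrow(cluster_otus(d, cutoff = 0.03)$counts), 2L)

  # all identical -> one OTU
  same <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(nrow(cluster_otus(same)$counts), 1L)
  # undefined distances are rejected
  same[1, 2] <- same[2, 1] <- NA
  expect_error(cluster_otus(same), "undefined")
})

test_that("cluster_otus matches exhaustive partition search (<= 8 seqs)", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(5:8, 1)
      membership <- sample(1:3, n, replace = TRUE)
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          d[i, j] <- d[j, i] <- if (membership[i] == membership[j]) {
            runif(1, 0, 0.02)
          } else runif(1, 0.06, 0.2)
        }
      }
      dimnames(d) <- list(paste0("q", 1:n), paste0("q", 1:n))
    })
    ot <- cluster_otus(d, cutoff = 0.03)
    feas <- feasible_partitions(d, 0.03)
    expect_equal(nrow(ot$counts), min(lengths(feas)))
    planted <- canonical_partition(unname(split(seq_len(nrow(d)), membership)))
    expect_equal(otu_partition(ot, rownames(d)), planted)
  }
})

test_that("OTU counts conserve sequences and shrink as the cutoff grows", {
  cs <- generate_sequences(three_cluster_spec(seed = 21))
  dm <- pairwise_distances(cs)
  ot <- cluster_otus(dm)
  expect_equal(sum(ot$counts), nrow(cs$records))
  expect_equal(colSums(ot$counts),
               setNames(as.numeric(table(cs$records$sample)),
                        sort(unique(cs$records$sample))))
  n_otus <- vapply(c(0.01, 0.03, 0.1, 0.2),
                   function(cc) nrow(cluster_otus(dm, cutoff = cc)$counts), 0)
  expect_true(all(diff(n_otus) <= 0))
  # representative: minimum summed distance, and a member of its own OTU
  for (otu in rownames(ot$counts)) {
    members <- ot$assignments$id[ot$assignments$otu == otu]
    expect_true(ot$representatives[[otu]] %in% members)
    sums <- rowSums(dm[members, members, drop = FALSE])
    expect_equal(unname(sums[ot$representatives[[otu]]]), min(sums))
  }
})

test_that("planted cluster structure is recoverable across seeds", {
  for (seed in 1:20) {
    cs <- generate_sequences(three_cluster_spec(seed = seed, n_per_sample = 5))
    ot <- cluster_otus(pairwise_distances(cs))
    expect_equal(nrow(ot$counts), 3L)
    # each OTU maps to exactly one planted cluster
    joined <- merge(ot$assignments, cs$truth, by = "id")
    expect_true(all(rowSums(table(joined$otu, joined$cluster) > 0) == 1))
  }
})

test_that("diversity_indices matches the frozen index arithmetic", {
  counts1 <- matrix(10, 1, 1, dimnames = list("OTU1", "S1"))
  d1 <- diversity_indices(counts1)
  expect_equal(d1$shannon, 0)
  expect_equal(d1$chao1, 1)

  counts2 <- matrix(c(5, 3, 2), 3, 1,
                    dimnames = list(paste0("OTU", 1:3), "S1"))
  expect_equal(diversity_indices(counts2)$shannon, 1.0297, tolerance = 1e-4)
  # base-2 option
  expect_equal(diversity_indices(counts2, base = 2)$shannon,
               1.0297 / log(2), tolerance = 1e-3)

  counts3 <- matrix(c(1, 1, 2, 3), 4, 1,
                    dimnames = list(paste0("OTU", 1:4), "S1"))
  expect_equal(diversity_indices(counts3)$chao1, 4.5)  # S 4, n1 2, n2 1

  expect_error(diversity_indices(matrix(0, 2, 1,
    dimnames = list(c("a", "b"), "S1"))), "no counts")
})

test_that("Chao1 >= observed richness, equality without singletons", {
  for (seed in 1:25) {
    x <- withr::with_seed(seed, rpois(8, 3))
    if (sum(x) == 0) x[1] <- 5
    m <- matrix(x, length(x), 1,
                dimnames = list(paste0("OTU", seq_along(x)), "S1"))
    d <- diversity_indices(m)
    expect_gte(d$chao1, d$s_obs)
    if (sum(x == 1) == 0) expect_equal(d$chao1, d$s_obs)
  }
})

test_that("shared_otu_network flags shared, unique and omnipresent OTUs", {
  counts <- matrix(c(3, 2, 1, 1, 1, 0, 2, 5, 1, 2, 4, 0), 2, 6, byrow = FALSE,
                   dimnames = list(c("OTU1", "OTU2"), paste0("S", 1:6)))
  net <- shared_otu_network(counts)
  expect_true(net$otu_flags$omnipresent[net$otu_flags$otu == "OTU1"])
  expect_true(net$otu_flags$shared[net$otu_flags$otu == "OTU2"])
  single <- shared_otu_network(matrix(c(4, 0), 1, 2,
    dimnames = list("OTU1", c("S1", "S2"))))
  expect_true(single$otu_flags$unique)
  expect_false(single$otu_flags$shared)

  # synthetic community with disjoint sample placement
  clusters <- list(
    list(label = "C1", length = 200, within = 0, abundance = c(S1 = 4)),
    list(label = "C2", length = 200, within = 0, abundance = c(S2 = 4)),
    list(label = "C3", length = 200, within = 0, abundance = c(S1 = 2, S2 = 2)))
  cs <- generate_sequences(community_spec(clusters, 0.15, seed = 31))
  net2 <- shared_otu_network(cluster_otus(pairwise_distances(cs)))
  expect_equal(sum(net2$otu_flags$shared), 1L)
  expect_equal(sum(net2$otu_flags$unique), 2L)
  expect_equal(nrow(net2$edges), 4L)
})

test_that("otu_proportions tallies per-OTU sequence shares", {
  p <- otu_proportions(c(OTU1 = 152, rest = 5))
  expect_equal(p$percent, c(96.8152866, 3.1847134), tolerance = 1e-6)
  expect_equal(sum(p$fraction), 1)
  expect_error(otu_proportions(c(a = 0, b = 0)), "positive sum")
})

test_that("OTU table and edge list writers emit loadable text", {
  cs <- generate_sequences(three_cluster_spec(seed = 51, n_per_sample = 3))
  ot <- cluster_otus(pairwise_distances(cs))
  csv <- withr::local_tempfile(fileext = ".csv")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_otu_csv(ot, csv)
  back <- read.csv(csv, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]),
               matrix(ot$counts, nrow(ot$counts),
                      dimnames = list(NULL, colnames(ot$counts))))
  write_edge_tsv(ot, tsv)
  edges <- read.delim(tsv)
  expect_equal(nrow(edges), sum(ot$counts > 0))
  reps <- otu_representatives(ot, cs)
  expect_equal(nrow(reps), nrow(ot$counts))
  expect_true(all(grepl("^OTU", reps$id)))
})
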