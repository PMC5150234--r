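# Shared fixture builders and independent oracles.

# A 3-cluster, 2-sample community spec with clean separation.
three_cluster_spec <- function(seed = 42, within = 0.005, between = 0.15,
                               n_per_sample = 10) {
  clusters <- lapply(1:3, function(k) {
    list(label = paste0("C", k), length = 300, within = within,
         abundance = setNames(rep(n_per_sample, 2), c("S1", "S2")))
  })
  community_spec(clusters, between_divergence = between, seed = seed)
}

default_incubation_spec <- function(seed = 1, noise_sd = 0,
                                    cells = c(aoa = 1e5, aob = 5e3,
                                              comammox = 1e3),
                                    r_in = c(aoa = 0.5, aob = 1,
                                             comammox = 0.5)) {
  incubation_spec(guild_cells = cells, guild_r_in = r_in,
                  nh4_start = 0.65, blank_level = 0.35,
                  noise_sd = noise_sd, seed = seed)
}

# ---- independent oracles -------------------------------------------------

# All set partitions of 1..n (restricted-growth enumeration).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(i, blocks) {
    if (i > n) {
      out[[length(out) + 1L]] <<- blocks
      return(invisible())
    }
    for (b in seq_along(blocks)) {
      nb <- blocks
      nb[[b]] <- c(nb[[b]], i)
      recurse(i + 1L, nb)
    }
    recurse(i + 1L, c(blocks, list(i)))
  }
  recurse(2L, list(1L))
  out
}

# Partitions feasible under the complete-linkage criterion at a cutoff:
# every within-block pair at distance <= cutoff.
feasible_partitions <- function(dm, cutoff) {
  Filter(function(blocks) {
    all(vapply(blocks, function(b) {
      length(b) < 2L || max(dm[b, b]) <= cutoff
    }, logical(1)))
  }, all_partitions(nrow(dm)))
}

# Canonical form of a partition (sorted blocks) for set comparison.
canonical_partition <- function(blocks) {
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, `[`, 0L, 1L))]
}

# Partition realized by an otu_table, in terms of row indices of `ids`.
otu_partition <- function(otus, ids) {
  canonical_partition(unname(
    split(match(otus$assignments$id, ids), otus$assignments$otu)))
}

# Random additive distance matrix from a random tree; returns both.
random_additive_matrix <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, br = NULL)
    tr$edge.length <- round(runif(nrow(tr$edge), 0.05, 1), 3)
    list(tree = tr, dm = ape::cophenetic.phylo(tr))
  })
}

# Hierarchical 6-taxon alignment with one weakly supported internal edge.
# Topology ((A,B),(C,D),(E,F)): the AB|rest split rests on `weak_cols`
# columns, the other splits on `strong_cols` columns each.
weak_edge_alignment <- function(seed, len = 300, weak_cols = 3,
                                strong_cols = 40) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, len, replace = TRUE)
    flip <- function(s, cols) {
      s[cols] <- vapply(s[cols], function(b) sample(setdiff(bases, b), 1), "")
      s
    }
    free <- sample(len)
    cols_ab <- free[seq_len(weak_cols)]
    cols_cd <- free[weak_cols + seq_len(strong_cols)]
    cols_ef <- free[weak_cols + strong_cols + seq_len(strong_cols)]
    ab <- flip(anc, cols_ab); cd <- flip(anc, cols_cd); ef <- flip(anc, cols_ef)
    jitter1 <- function(s) flip(s, sample(len, 1))
    seqs <- c(A = paste(jitter1(ab), collapse = ""),
              B = paste(jitter1(ab), collapse = ""),
              C = paste(jitter1(cd), collapse = ""),
              D = paste(jitter1(cd), collapse = ""),
              E = paste(jitter1(ef), collapse = ""),
              F = paste(jitter1(ef), collapse = ""))
    data.frame(id = names(seqs), sample = "S1", bases = unname(seqs),
               stringsAsFactors = FALSE)
  })
}
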