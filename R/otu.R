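#' Pairwise p-distances between marker-gene sequences
#'
#' For equal-length sequences the uncorrected p-distance is computed over
#' positions where both bases are unambiguous (A, C, G or T); ambiguous
#' bases and shared gap columns drop out of the denominator pairwise. For
#' unequal lengths a global ends-free pairwise alignment is run first
#' (match +1, mismatch -1, gap -2, terminal gaps unpenalized and excluded
#' from the denominator).
#'
#' @param records Sequence records (data.frame with `id`, `sample`, `bases`)
#'   or a `community_set`.
#' @return A symmetric distance matrix with `id` dimnames and a `samples`
#'   attribute (named `id -> sample` vector). Pairs with no comparable
#'   positions are `NA` (rejected later at clustering time).
#' @export
pairwise_distances <- function(records) {
  if (inherits(records, "community_set")) records <- records$records
  check_records(records)
  n <- nrow(records)
  if (n < 2L) stop("need >= 2 sequences")
  chars <- strsplit(records$bases, "", fixed = TRUE)
  lens <- lengths(chars)
  dm <- matrix(0, n, n, dimnames = list(records$id, records$id))
  submat <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (lens[i] == lens[j]) {
        a <- chars[[i]]; b <- chars[[j]]
      } else {
        if (is.null(submat)) {
          submat <- Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -1, baseOnly = FALSE)
        }
        aln <- Biostrings::pairwiseAlignment(
          records$bases[i], records$bases[j], type = "overlap",
          substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
        a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
        b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      }
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      denom <- sum(ok)
      dm[i, j] <- dm[j, i] <-
        if (denom == 0) NA_real_ else sum(a[ok] != b[ok]) / denom
    }
  }
  attr(dm, "samples") <- setNames(records$sample, records$id)
  dm
}

#' Cluster sequences into OTUs at a distance cutoff
#'
#' Furthest-neighbour (complete-linkage) agglomeration: two sequences end up
#' in the same OTU only if every cross-pair distance is at or below the
#' cutoff (97% similarity = 0.03 distance, boundary inclusive). Single and
#' average linkage are available for comparison. OTUs are numbered by
#' decreasing total abundance; each OTU's representative is its
#' minimum-summed-distance member, ties broken by lexicographic id.
#'
#' @param dm Distance matrix from [pairwise_distances()] (or any symmetric
#'   matrix with id dimnames plus a `samples` attribute or `samples`
#'   argument).
#' @param cutoff Distance cutoff in (0, 1); default 0.03.
#' @param linkage `"complete"` (default), `"single"` or `"average"`.
#' @param samples Optional named `id -> sample` vector overriding the
#'   attribute.
#' @return A list of class `otu_table`: `counts` (OTU x sample matrix),
#'   `representatives` (named id vector), `assignments` (id -> otu
#'   data.frame).
#' @export
cluster_otus <- function(dm, cutoff = 0.03,
                         linkage = c("complete", "single", "average"),
                         samples = NULL) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must be in (0, 1)")
  if (anyNA(dm)) stop("undefined distances present; cannot cluster")
  if (max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  ids <- rownames(dm)
  if (is.null(samples)) samples <- attr(dm, "samples")
  if (is.null(samples)) samples <- setNames(rep("all", length(ids)), ids)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  link_fun <- switch(linkage, complete = max, single = min, average = mean)
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        d <- link_fun(dm[clusters[[i]], clusters[[j]]])
        if (d <= cutoff && (is.null(best) || d < best$d)) {
          best <- list(i = i, j = j, d = d)  # ties keep smallest (i, j)
        }
      }
    }
    if (is.null(best)) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  # representative: minimum summed distance, ties by lexicographic id
  reps <- vapply(clusters, function(m) {
    sums <- rowSums(dm[m, m, drop = FALSE])
    cand <- ids[m[sums == min(sums)]]
    sort(cand)[1]
  }, "")
  sizes <- lengths(clusters)
  ord <- order(-sizes, reps)
  clusters <- clusters[ord]
  reps <- reps[ord]
  otu_ids <- paste0("OTU", seq_along(clusters))
  smp_levels <- unique(unname(samples[ids]))
  counts <- matrix(0L, length(clusters), length(smp_levels),
                   dimnames = list(otu_ids, smp_levels))
  assignments <- data.frame(id = character(0), otu = character(0))
  for (ci in seq_along(clusters)) {
    member_ids <- ids[clusters[[ci]]]
    tab <- table(factor(samples[member_ids], levels = smp_levels))
    counts[ci, ] <- counts[ci, ] + as.integer(tab)
    assignments <- rbind(assignments,
                         data.frame(id = member_ids, otu = otu_ids[ci]))
  }
  rownames(assignments) <- NULL
  structure(
    list(counts = counts, representatives = setNames(reps, otu_ids),
         assignments = assignments, cutoff = cutoff, linkage = linkage),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples (%s linkage, cutoff %.3f)\n",
              nrow(x$counts), ncol(x$counts), x$linkage, x$cutoff))
  print(x$counts)
  invisible(x)
}

#' Alpha-diversity indexes per sample
#'
#' Observed richness, Shannon index (natural log by default) and the
#' bias-corrected Chao1 estimator
#' `S_obs + n1 (n1 - 1) / (2 (n2 + 1))` (n1 singletons, n2 doubletons),
#' which stays defined when no doubletons occur; the classic form
#' `S_obs + n1^2 / (2 n2)` is available.
#'
#' @param otus An `otu_table` or a plain OTU x sample count matrix.
#' @param base Log base for Shannon (default `exp(1)`, nats; use 2 for
#'   bits).
#' @param chao1 `"bias-corrected"` (default) or `"classic"`.
#' @return Data.frame with one row per sample: `sample`, `n_seqs`, `s_obs`,
#'   `shannon`, `chao1`.
#' @export
diversity_indices <- function(otus, base = exp(1),
                              chao1 = c("bias-corrected", "classic")) {
  chao1 <- match.arg(chao1)
  counts <- if (inherits(otus, "otu_table")) otus$counts else as.matrix(otus)
  rows <- lapply(colnames(counts), function(smp) {
    x <- counts[, smp]
    x <- x[x > 0]
    if (length(x) == 0L) stop("sample ", smp, " has no counts")
    p <- x / sum(x)
    n1 <- sum(x == 1); n2 <- sum(x == 2)
    ch <- switch(chao1,
      "bias-corrected" = length(x) + n1 * (n1 - 1) / (2 * (n2 + 1)),
      classic = {
        if (n2 == 0 && n1 > 0) {
          warning("classic Chao1 undefined with no doubletons (sample ",
                  smp, ")")
        }
        length(x) + if (n1 == 0) 0 else n1^2 / (2 * n2)
      })
    data.frame(sample = smp, n_seqs = sum(x), s_obs = length(x),
               shannon = -sum(p * log(p, base = base)), chao1 = ch,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-OTU share of the total sequence tally
#'
#' The fraction (and percent) of all clones falling in each OTU, the
#' quantity quoted when a community is summarized as "OTUx holds 96.82% of
#' sequences". Accepts an `otu_table`, a count matrix, or a named vector of
#' per-OTU totals.
#'
#' @param otus An `otu_table`, OTU x sample count matrix, or named numeric
#'   vector of OTU totals.
#' @return Data.frame `otu`, `count`, `fraction`, `percent`, ordered as the
#'   input.
#' @export
otu_proportions <- function(otus) {
  totals <- if (inherits(otus, "otu_table")) rowSums(otus$counts)
            else if (is.matrix(otus)) rowSums(otus)
            else otus
  if (any(totals < 0) || sum(totals) == 0) {
    stop("OTU totals must be >= 0 with a positive sum")
  }
  data.frame(otu = names(totals), count = unname(totals),
             fraction = unname(totals) / sum(totals),
             percent = 100 * unname(totals) / sum(totals),
             stringsAsFactors = FALSE)
}

#' Shared-OTU bipartite network
#'
#' Edge list linking OTUs to the samples they occur in, with per-OTU flags:
#' `shared` (present in at least 2 samples), `unique` (exactly 1) and
#' `omnipresent` (present in every sample). The edge list loads directly
#' into network-visualization tools.
#'
#' @param otus An `otu_table` or OTU x sample count matrix.
#' @return A list: `edges` (data.frame `otu`, `sample`, `count`) and
#'   `otu_flags` (data.frame `otu`, `n_samples`, `shared`, `unique`,
#'   `omnipresent`).
#' @export
shared_otu_network <- function(otus) {
  counts <- if (inherits(otus, "otu_table")) otus$counts else as.matrix(otus)
  idx <- which(counts > 0, arr.ind = TRUE)
  edges <- data.frame(
    otu = rownames(counts)[idx[, 1]],
    sample = colnames(counts)[idx[, 2]],
    count = counts[idx], stringsAsFactors = FALSE
  )
  edges <- edges[order(match(edges$otu, rownames(counts)),
                       match(edges$sample, colnames(counts))), ]
  rownames(edges) <- NULL
  n_smp <- rowSums(counts > 0)
  flags <- data.frame(
    otu = rownames(counts), n_samples = unname(n_smp),
    shared = unname(n_smp >= 2), unique = unname(n_smp == 1),
    omnipresent = unname(n_smp == ncol(counts)), stringsAsFactors = FALSE
  )
  list(edges = edges, otu_flags = flags)
}

#' Write an OTU table (counts) to CSV, or its network edge list to TSV
#'
#' @param otus An `otu_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_csv <- function(otus, path) {
  counts <- if (inherits(otus, "otu_table")) otus$counts else as.matrix(otus)
  write.csv(data.frame(otu = rownames(counts), counts, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_csv
#' @export
write_edge_tsv <- function(otus, path) {
  net <- shared_otu_network(otus)
  utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Extract OTU representative sequences as records
#'
#' @param otus An `otu_table` from [cluster_otus()].
#' @param records The sequence records the table was built from.
#' @return Data.frame of representative records with ids `OTUk|<orig id>`.
#' @export
otu_representatives <- function(otus, records) {
  if (inherits(records, "community_set")) records <- records$records
  stopifnot(inherits(otus, "otu_table"))
  sel <- records[match(otus$representatives, records$id), ]
  sel$id <- paste(names(otus$representatives), sel$id, sep = "|")
  rownames(sel) <- NULL
  sel
}
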