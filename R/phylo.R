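#' Jukes-Cantor corrected evolutionary distance
#'
#' `d = -(3/4) ln(1 - (4/3) p)`, the one-parameter correction of an observed
#' proportion of differing sites for multiple substitutions. The formula
#' saturates at p = 0.75 (the expectation between random sequences under the
#' model); such inputs are rejected.
#'
#' @param p Proportion of differing sites, in `[0, 0.75)`. Vectorized.
#' @return Distance in substitutions per site; always `>= p`.
#' @export
jukes_cantor <- function(p) {
  if (any(is.na(p)) || any(p < 0)) stop("p must be in [0, 0.75)")
  if (any(p >= 0.75)) {
    stop("p-distance ", max(p), " at or beyond the Jukes-Cantor saturation ",
         "point 0.75; distance undefined")
  }
  -0.75 * log(1 - 4 * p / 3)
}

# Core NJ agglomeration on a plain symmetric matrix with labelled taxa.
# Returns a newick string plus a record of clamped (negative) branches.
nj_build <- function(d, labels) {
  n <- nrow(d)
  frag <- labels
  neg <- list()
  brl <- function(x) sprintf("%.15g", x)
  clamp <- function(li, lj, desc) {
    # shift a negative length onto the sibling edge; keep raw for diagnosis
    if (li < 0) {
      neg[[length(neg) + 1L]] <<- data.frame(edge = desc[1], raw = li)
      lj <- lj + li; li <- 0
    }
    if (lj < 0) {
      neg[[length(neg) + 1L]] <<- data.frame(edge = desc[2], raw = lj)
      li <- li + lj; lj <- 0
    }
    c(li, lj)
  }
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # smallest Q; ties broken by smallest (i, j), row-major
    best <- c(NA_integer_, NA_integer_); qmin <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        if (q[i, j] < qmin) { qmin <- q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    ll <- clamp(li, lj, c(frag[i], frag[j]))
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], brl(ll[1]),
                        frag[j], brl(ll[2]))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
  }
  dd <- d
  la <- (dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2
  lb <- (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2
  lc <- (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2
  for (k in which(c(la, lb, lc) < 0)) {
    neg[[length(neg) + 1L]] <- data.frame(edge = frag[k],
                                          raw = c(la, lb, lc)[k])
  }
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], brl(la),
                 frag[2], brl(lb), frag[3], brl(lc))
  list(newick = nwk,
       negative_branches = if (length(neg)) do.call(rbind, neg) else NULL)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion. For an additive input matrix
#' the tree's leaf-to-leaf path lengths reproduce the input exactly.
#' Negative branch-length estimates are clamped to zero with the deficit
#' shifted to the sibling edge; the raw values are kept in the tree's
#' `negative_branches` field.
#'
#' @param dm Symmetric distance matrix (or `dist`) with taxon dimnames;
#'   at least 3 taxa.
#' @return An unrooted `phylo` tree (ape) with branch lengths in the input's
#'   units.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3L) stop("neighbor joining needs >= 3 taxa")
  if (anyNA(dm)) stop("undefined distances in matrix")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(dm)))
  built <- nj_build(unname(dm), labels)
  tree <- ape::read.tree(text = built$newick)
  tree$negative_branches <- built$negative_branches
  tree
}

# Canonical keys for the non-trivial bipartitions induced by internal edges.
# Each bipartition is keyed by the side not containing the reference taxon,
# so the keys are rooting-invariant.
tree_bipartitions <- function(tree, ref = NULL) {
  tips <- tree$tip.label
  if (is.null(ref)) ref <- sort(tips)[1]
  n <- length(tips)
  internal <- setdiff(unique(tree$edge[, 1]), n + 1L)  # exclude root
  keys <- character(0)
  nodes <- integer(0)
  for (v in internal) {
    below <- tips_under(tree, v)
    if (length(below) <= 1L || length(below) >= n - 1L) next
    side <- if (ref %in% below) setdiff(tips, below) else below
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, v)
  }
  setNames(keys, nodes)
}

# Tip labels descending from internal node v.
tips_under <- function(tree, v) {
  n <- length(tree$tip.label)
  stack <- v
  out <- integer(0)
  while (length(stack)) {
    x <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == x, 2]
    out <- c(out, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  tree$tip.label[out]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate (same distance model as the point estimate) and reports, for
#' each internal edge of the point tree, the percentage of replicate trees
#' containing the same bipartition. Supports land in the tree's node labels.
#'
#' @param records Aligned equal-length sequences: a record data.frame, a
#'   `community_set`, or a named character vector.
#' @param n_replicates Bootstrap replicates (reference analyses use 1000;
#'   scale down for quick runs).
#' @param seed Integer seed.
#' @param model `"JC"` (Jukes-Cantor, default) or `"raw"` (p-distance) for
#'   both the point tree and the replicates.
#' @return A `phylo` tree with `node.label` holding integer percent support
#'   (root label empty) and a `support` data.frame field.
#' @export
bootstrap_support <- function(records, n_replicates = 1000L, seed = 1L,
                              model = c("JC", "raw")) {
  model <- match.arg(model)
  if (inherits(records, "community_set")) records <- records$records
  if (is.character(records)) {
    records <- data.frame(id = names(records), sample = NA, bases = records,
                          stringsAsFactors = FALSE)
  }
  check_records(records)
  if (nrow(records) < 4L) stop("bootstrap needs >= 4 taxa")
  lens <- nchar(records$bases)
  if (length(unique(lens)) != 1L) {
    stop("bootstrap requires an alignment of equal-length sequences")
  }
  mat <- do.call(rbind, strsplit(records$bases, "", fixed = TRUE))
  rownames(mat) <- records$id
  dist_fun <- function(m) {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        ok <- m[i, ] %in% c("A", "C", "G", "T") &
              m[j, ] %in% c("A", "C", "G", "T")
        if (!any(ok)) stop("no comparable positions between ",
                           rownames(m)[i], " and ", rownames(m)[j])
        p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
        d[i, j] <- d[j, i] <- if (model == "JC") jukes_cantor(p) else p
      }
    }
    d
  }
  point <- nj_tree(dist_fun(mat))
  point_bp <- tree_bipartitions(point)
  hits <- setNames(numeric(length(point_bp)), point_bp)
  withr::with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample(ncol(mat), ncol(mat), replace = TRUE)
      rep_tree <- nj_tree(dist_fun(mat[, cols, drop = FALSE]))
      rep_keys <- tree_bipartitions(rep_tree, ref = sort(point$tip.label)[1])
      present <- point_bp %in% rep_keys
      hits[present] <- hits[present] + 1
    }
  })
  support <- 100 * hits / n_replicates
  n_tip <- length(point$tip.label)
  labels <- rep("", point$Nnode)
  nodes <- as.integer(names(point_bp))
  labels[nodes - n_tip] <- as.character(round(unname(support)))
  point$node.label <- labels
  point$support <- data.frame(node = nodes,
                              support = unname(support),
                              bipartition = unname(point_bp))
  point$n_replicates <- n_replicates
  point
}

#' Write a tree to a newick file
#'
#' Branch lengths and any integer support labels are preserved.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
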