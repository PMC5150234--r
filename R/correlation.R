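#' Spearman rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). With no
#' ties this equals `1 - 6 * sum(d^2) / (n (n^2 - 1))`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return rho in `[-1, 1]`, or `NA` when either vector is constant
#'   (undefined).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  sum(rxc * ryc) / sqrt(sum(rxc^2) * sum(ryc^2))
}

# All permutations of 1..n as an (n! x n) matrix, lexicographic order.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Permutation p-value for a Spearman correlation
#'
#' Two-sided p: the proportion of permutations of `y` whose |rho| meets or
#' exceeds the observed |rho|, the identity permutation included. With
#' `n_perm = "exact"` all n! orderings are enumerated (limited to n <= 8;
#' at n = 6 the p-value grid has resolution 1/720). Monte Carlo mode draws
#' `n_perm` random permutations and adds the identity to both counts.
#'
#' @param x,y Numeric vectors.
#' @param n_perm `"exact"` (default, n <= 8) or a number of random
#'   permutations (a value below 99 triggers a warning).
#' @param seed Integer seed (Monte Carlo mode only).
#' @return A list of class `perm_test`: `rho`, `p_value`, `method`, `n`.
#' @export
permutation_pvalue <- function(x, y, n_perm = "exact", seed = 1L) {
  rho_obs <- spearman_rho(x, y)
  n <- length(x)
  if (is.na(rho_obs)) {
    return(structure(list(rho = NA_real_, p_value = NA_real_,
                          method = "undefined", n = n), class = "perm_test"))
  }
  ry <- rank(y, ties.method = "average")
  eps <- 1e-12
  if (identical(n_perm, "exact")) {
    if (n > 8L) stop("exact enumeration limited to n <= 8; use Monte Carlo")
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) spearman_rho(x, ry[p]))
    p_val <- mean(abs(rhos) >= abs(rho_obs) - eps)
    method <- "exact-permutation"
  } else {
    check_number(n_perm, "n_perm", min = 1)
    if (n_perm < 99) warning("n_perm < 99 gives a very coarse p-value")
    hits <- withr::with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        abs(spearman_rho(x, ry[sample(n)])) >= abs(rho_obs) - eps
      }, logical(1)))
    })
    p_val <- (hits + 1) / (n_perm + 1)  # identity permutation included
    method <- "monte-carlo"
  }
  structure(list(rho = rho_obs, p_value = p_val, method = method, n = n),
            class = "perm_test")
}

# Two-sided t-approximation p-value for a Spearman rho (large-n fallback).
asymptotic_pvalue <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Spearman correlation matrix between factors and response variables
#'
#' Every variable x factor pair, as a heatmap-ready long table. For small
#' campaigns (n <= 8 shared samples) p-values come from exact permutation
#' enumeration; larger n falls back to the t-approximation. No
#' multiple-testing correction is applied by default (mirroring common
#' reporting practice at n = 6); Benjamini-Hochberg is available.
#'
#' @param factors Data.frame keyed on a `sample` column, one numeric column
#'   per environmental factor.
#' @param variables Data.frame keyed on `sample`, one numeric column per
#'   response (taxon relative abundance, diversity index, guild
#'   abundance, ...).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05).
#' @param method `"auto"` (default: exact for n <= 8), `"exact"`,
#'   `"asymptotic"`, or a number of Monte Carlo permutations.
#' @param seed Seed for Monte Carlo mode.
#' @return Long-format data.frame: `variable`, `factor`, `rho`, `p_value`,
#'   `method`, `n`, `significant`.
#' @export
correlation_matrix <- function(factors, variables, p_adjust = c("none", "BH"),
                               alpha = 0.05, method = "auto", seed = 1L) {
  p_adjust <- match.arg(p_adjust)
  stopifnot("sample" %in% names(factors), "sample" %in% names(variables))
  shared <- intersect(factors$sample, variables$sample)
  if (length(shared) < 4L) stop("need >= 4 shared samples")
  f <- factors[match(shared, factors$sample), , drop = FALSE]
  v <- variables[match(shared, variables$sample), , drop = FALSE]
  fac_names <- setdiff(names(f), "sample")
  var_names <- setdiff(names(v), "sample")
  if (anyDuplicated(fac_names)) stop("duplicate factor names")
  n <- length(shared)
  use <- if (identical(method, "auto")) {
    if (n <= 8L) "exact" else "asymptotic"
  } else method
  rows <- list()
  for (vn in var_names) {
    for (fn in fac_names) {
      x <- v[[vn]]; y <- f[[fn]]
      if (identical(use, "asymptotic")) {
        rho <- spearman_rho(x, y)
        p <- if (is.na(rho)) NA_real_ else asymptotic_pvalue(rho, n)
        meth <- "asymptotic"
      } else {
        pt <- permutation_pvalue(x, y, n_perm = use, seed = seed)
        rho <- pt$rho; p <- pt$p_value; meth <- pt$method
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = vn, factor = fn, rho = rho, p_value = p,
        method = meth, n = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_value) & out$p_value <= alpha
  rownames(out) <- NULL
  out
}
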