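#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies) over a serial-dilution
#' series. Amplification efficiency is `10^(-1/slope) - 1`; a perfect
#' doubling per cycle gives slope `-1/log10(2) = -3.3219` and efficiency 1.
#' Assays are expected to sit near the 90.6-106.0% efficiency window with
#' R-squared above 0.99; values outside trigger a warning (not an error), so
#' degraded plates still flow through.
#'
#' @param standards Data.frame with columns `copies` (> 0) and `cq`, one row
#'   per standard well; a `qpcr_plate` is also accepted (its standards are
#'   used).
#' @return A list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_levels`, `qc_pass`.
#' @export
fit_standard_curve <- function(standards) {
  if (inherits(standards, "qpcr_plate")) standards <- standards$standards
  stopifnot(is.data.frame(standards),
            all(c("copies", "cq") %in% names(standards)))
  standards <- standards[!is.na(standards$cq), ]
  if (any(standards$copies <= 0)) stop("standard copies must be > 0")
  lx <- log10(standards$copies)
  n_levels <- length(unique(standards$copies))
  if (n_levels < 3L) stop("need >= 3 distinct dilution levels")
  if (sd(lx) == 0) stop("zero variance in log10(copies)")
  fit <- lm(standards$cq ~ lx)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) stop("fitted slope is non-negative; not a qPCR dilution series")
  r2 <- 1 - sum(residuals(fit)^2) / sum((standards$cq - mean(standards$cq))^2)
  eff <- 10^(-1 / slope) - 1
  qc <- eff >= 0.90 && eff <= 1.10 && r2 >= 0.99
  if (!qc) {
    warning(sprintf(
      "standard-curve QC: efficiency %.1f%% / R2 %.4f outside 90-110%% / >=0.99",
      100 * eff, r2))
  }
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = r2, efficiency = eff, n_levels = n_levels,
         qc_pass = qc),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: Cq = %.4f * log10(copies) + %.4f  (E = %.1f%%, R2 = %.4f%s)\n",
    x$slope, x$intercept, 100 * x$efficiency, x$r_squared,
    if (x$qc_pass) "" else ", QC warning"))
  invisible(x)
}

#' Invert a standard curve: replicate Cq values to template copies
#'
#' Per replicate, `copies = 10^((cq - intercept) / slope)`; replicates are
#' then summarized as mean and sd on the linear (copies) scale, matching how
#' abundances are reported as mean +/- sd. A geometric-mean alternative
#' (mean on the log scale) is available via `aggregate = "geometric"`.
#' `NA` Cq values are the no-amplification sentinel: wells with no detected
#' template are excluded from the replicate summary, and if nothing
#' amplified the result is zero copies with `no_amplification = TRUE`.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param cqs Numeric vector of replicate Cq values (`NA` = no
#'   amplification).
#' @param aggregate `"linear"` (default) or `"geometric"`.
#' @return A list: `copies_mean`, `copies_sd`, `copies` (per detected
#'   replicate), `n_replicates`, `n_detected`, `no_amplification`.
#' @export
quantify_unknowns <- function(curve, cqs, aggregate = c("linear", "geometric")) {
  stopifnot(inherits(curve, "standard_curve"))
  aggregate <- match.arg(aggregate)
  if (length(cqs) < 1L) stop("need >= 1 replicate Cq")
  detected <- !is.na(cqs)
  if (!any(detected)) {
    return(list(copies_mean = 0, copies_sd = 0, copies = numeric(0),
                n_replicates = length(cqs), n_detected = 0L,
                no_amplification = TRUE))
  }
  copies <- 10^((cqs[detected] - curve$intercept) / curve$slope)
  m <- switch(aggregate,
              linear = mean(copies),
              geometric = 10^mean(log10(copies)))
  list(copies_mean = m,
       copies_sd = if (length(copies) > 1L) sd(copies) else 0,
       copies = copies,
       n_replicates = length(cqs), n_detected = sum(detected),
       no_amplification = FALSE)
}

#' Convert gene copies to cell numbers
#'
#' Standard per-cell copy numbers: 1 amoA copy per AOA and per comammox
#' cell, 2.5 amoA copies per AOB cell, and 3.6 16S rRNA gene copies per
#' average prokaryotic cell; any positive factor is accepted.
#'
#' @param copies Gene copies (>= 0), vectorized.
#' @param copies_per_cell Copies per cell (> 0).
#' @return Cell numbers, `copies / copies_per_cell`.
#' @export
copies_to_cells <- function(copies, copies_per_cell) {
  if (any(copies < 0)) stop("copies must be >= 0")
  check_number(copies_per_cell, "copies_per_cell", min = 0, strict_min = TRUE)
  copies / copies_per_cell
}

#' Assay configuration for per-air-volume normalization
#'
#' @param target_name Assay target label (e.g. `"AOA"`).
#' @param copies_per_cell Marker copies per cell for this target.
#' @param extract_scaleup Reaction-to-whole-extract factor (template volume,
#'   elution volume and dilutions folded into one explicit number; the
#'   reference protocol does not print these, so it is configuration, not a
#'   default).
#' @param filter_fraction Fraction of the filter extracted (1/4 in the
#'   reference protocol).
#' @param air_volume Sampled air per filter (m3; 144 m3 for 100 l min-1
#'   over 24 h).
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(target_name, copies_per_cell, extract_scaleup = 1,
                         filter_fraction = 0.25, air_volume = 144) {
  check_number(copies_per_cell, "copies_per_cell", min = 0, strict_min = TRUE)
  check_number(extract_scaleup, "extract_scaleup", min = 0, strict_min = TRUE)
  check_number(filter_fraction, "filter_fraction", min = 0, strict_min = TRUE)
  if (filter_fraction > 1) stop("filter_fraction must be <= 1")
  check_number(air_volume, "air_volume", min = 0, strict_min = TRUE)
  structure(
    list(target_name = target_name, copies_per_cell = copies_per_cell,
         extract_scaleup = extract_scaleup, filter_fraction = filter_fraction,
         air_volume = air_volume),
    class = "assay_config"
  )
}

#' Normalize reaction-scale cell numbers to cells per m3 of air
#'
#' `cells_per_m3 = cells * extract_scaleup / filter_fraction / air_volume`.
#' Replicate-wise conversion keeps the sd on the same scale.
#'
#' @param cells_in_reaction Cells at reaction scale (vector of replicates or
#'   a single mean).
#' @param cfg An [assay_config()].
#' @param sample Sample label.
#' @return A one-row data.frame of class `abundance_estimate`: `sample`,
#'   `target`, `cells_per_m3`, `sd`, `n_replicates`.
#' @export
cells_per_m3 <- function(cells_in_reaction, cfg, sample = NA) {
  stopifnot(inherits(cfg, "assay_config"))
  if (any(cells_in_reaction < 0)) stop("cells must be >= 0")
  per_m3 <- cells_in_reaction * cfg$extract_scaleup /
    cfg$filter_fraction / cfg$air_volume
  out <- data.frame(
    sample = sample, target = cfg$target_name,
    cells_per_m3 = mean(per_m3),
    sd = if (length(per_m3) > 1L) sd(per_m3) else 0,
    n_replicates = length(per_m3), stringsAsFactors = FALSE
  )
  class(out) <- c("abundance_estimate", class(out))
  out
}

#' One-call quantification of a plate's unknowns to cells per m3
#'
#' Fits the standard curve, inverts each unknown's replicate Cqs and
#' normalizes to the air basis.
#'
#' @param plate A `qpcr_plate` (or list with `standards`/`unknowns`).
#' @param cfg An [assay_config()].
#' @param aggregate Passed to [quantify_unknowns()].
#' @return Data.frame of abundance estimates, one row per unknown sample.
#' @export
quantify_plate <- function(plate, cfg, aggregate = "linear") {
  curve <- fit_standard_curve(plate$standards)
  rows <- lapply(split(plate$unknowns, plate$unknowns$sample), function(u) {
    q <- quantify_unknowns(curve, u$cq, aggregate = aggregate)
    cells <- copies_to_cells(
      if (q$no_amplification) 0 else q$copies, cfg$copies_per_cell)
    cells_per_m3(cells, cfg, sample = u$sample[1])
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$sample, unique(plate$unknowns$sample))), ]
  rownames(out) <- NULL
  out
}

#' Ratio and proportion summaries across guild abundances
#'
#' Per-sample ratios AOA/AOB, AOA/comammox, AOB/comammox and proportions
#' AOA/archaea, AOB/bacteria. A zero denominator yields `NA` with
#' `undefined = TRUE` (never `Inf`); a missing member of a pair yields `NA`
#' with `missing = TRUE`.
#'
#' @param estimates Data.frame with columns `sample`, `target`,
#'   `cells_per_m3`; targets are matched case-insensitively against
#'   `AOA`, `AOB`, `Comammox`, `Archaea`, `Bacteria`.
#' @return Long-format data.frame: `sample`, `statistic`, `value`,
#'   `undefined`, `missing`.
#' @export
abundance_summaries <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("sample", "target", "cells_per_m3") %in% names(estimates)))
  pairs <- list(
    "AOA/AOB" = c("aoa", "aob"),
    "AOA/Comammox" = c("aoa", "comammox"),
    "AOB/Comammox" = c("aob", "comammox"),
    "AOA/Archaea" = c("aoa", "archaea"),
    "AOB/Bacteria" = c("aob", "bacteria")
  )
  tgt <- tolower(estimates$target)
  rows <- list()
  for (smp in unique(estimates$sample)) {
    for (st in names(pairs)) {
      num_i <- which(estimates$sample == smp & tgt == pairs[[st]][1])
      den_i <- which(estimates$sample == smp & tgt == pairs[[st]][2])
      miss <- length(num_i) == 0L || length(den_i) == 0L
      undef <- FALSE
      val <- NA_real_
      if (!miss) {
        den <- estimates$cells_per_m3[den_i[1]]
        undef <- den == 0
        if (!undef) val <- estimates$cells_per_m3[num_i[1]] / den
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, statistic = st, value = val,
        undefined = undef, missing = miss, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write qPCR plates as CSV
#'
#' Plate layout columns: `well`, `role` (`standard`, `unknown`, `ntc`),
#' `sample`, `target`, `copies` (standards only), `cq` (empty = no
#' amplification).
#'
#' @param plate A `qpcr_plate`.
#' @param path CSV path.
#' @param target Target label written to the CSV.
#' @return `read_qpcr_csv` returns a list with `standards` and `unknowns`
#'   data.frames compatible with [fit_standard_curve()] and
#'   [quantify_plate()].
#' @export
write_qpcr_csv <- function(plate, path, target = "target") {
  std <- plate$standards
  unk <- plate$unknowns
  out <- rbind(
    data.frame(well = sprintf("S%02d.%d", std$level, std$replicate),
               role = "standard", sample = sprintf("std%02d", std$level),
               target = target, copies = std$copies, cq = std$cq),
    data.frame(well = sprintf("U.%s.%d", unk$sample, unk$replicate),
               role = "unknown", sample = unk$sample, target = target,
               copies = NA_real_, cq = unk$cq)
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_csv
#' @export
read_qpcr_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  std <- d[d$role == "standard", ]
  unk <- d[d$role == "unknown", ]
  list(
    standards = data.frame(copies = std$copies, cq = std$cq),
    unknowns = data.frame(sample = unk$sample, replicate =
                            stats::ave(seq_len(nrow(unk)), unk$sample,
                                       FUN = seq_along),
                          cq = unk$cq, stringsAsFactors = FALSE)
  )
}
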