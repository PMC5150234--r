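#' Construct an incubation time series
#'
#' Container for a blank-paired nitrification-potential incubation of a
#' PM2.5 suspension: triplicate-mean concentrations of ammonium, nitrite and
#' nitrate in the sample and its filter blank over the incubation, plus the
#' two physical constants needed to express rates per m3 of sampled air.
#'
#' @param sample Sample label.
#' @param data Data.frame with columns `time_h`, `analyte` (one of
#'   `"nh4"`, `"no2"`, `"no3"`), `sample`, `blank` (mg l-1).
#' @param Q1 Incubation volume (l); 0.25 l in the reference protocol.
#' @param Q2 Volume of sampled air (m3); 48 m3 for a 100 l min-1, 8 h x 3
#'   collection.
#' @param truth Optional ground-truth list attached by the synthetic
#'   generator.
#' @return An object of class `incubation_series`.
#' @export
incubation_series <- function(sample, data, Q1 = 0.25, Q2 = 48, truth = NULL) {
  stopifnot(is.data.frame(data),
            all(c("time_h", "analyte", "sample", "blank") %in% names(data)))
  if (!all(data$analyte %in% c("nh4", "no2", "no3"))) {
    stop("analyte must be nh4, no2 or no3")
  }
  for (an in unique(data$analyte)) {
    tp <- data$time_h[data$analyte == an]
    if (tp[1] != 0 || any(diff(tp) <= 0)) {
      stop("times must start at 0 and increase strictly (analyte ", an, ")")
    }
  }
  if (any(data$sample < 0) || any(data$blank < 0)) {
    stop("concentrations must be >= 0")
  }
  check_number(Q1, "Q1", min = 0, strict_min = TRUE)
  check_number(Q2, "Q2", min = 0, strict_min = TRUE)
  structure(
    list(sample = sample, data = data, Q1 = Q1, Q2 = Q2,
         t_end = max(data$time_h), truth = truth),
    class = "incubation_series"
  )
}

#' Blank-correct an incubation series
#'
#' Net concentration = sample - blank, per analyte and timepoint. Negative
#' net values (blank above sample) are preserved, not clipped, and flagged
#' with a warning so downstream rate estimates stay faithful to the data.
#'
#' @param series An [incubation_series()].
#' @return Data.frame `time_h`, `analyte`, `net` (mg l-1), with attribute
#'   `negative_flagged` (logical vector).
#' @export
net_concentrations <- function(series) {
  stopifnot(inherits(series, "incubation_series"))
  d <- series$data
  net <- data.frame(time_h = d$time_h, analyte = d$analyte,
                    net = d$sample - d$blank, stringsAsFactors = FALSE)
  neg <- net$net < 0
  if (any(neg)) {
    warning(sum(neg), " net concentration(s) below zero (blank > sample); ",
            "preserved, not clipped")
  }
  attr(net, "negative_flagged") <- neg
  net
}

#' Maximum nitrification rate from net ammonium endpoints
#'
#' Two-point rate on the sampled-air basis:
#' `NNR_max = (net_0 - net_t) * Q1 * 1000 / (t * Q2)` in
#' ug (NH4+-N) m-3 air h-1 (the factor 1000 converts mg to ug). The default
#' uses only the first and last timepoints, which is how the printed rates of
#' the reference incubations arise; `method = "regression"` instead fits an
#' ordinary least-squares slope through all net NH4 timepoints.
#'
#' @param net Net-concentration data.frame from [net_concentrations()], or an
#'   [incubation_series()] (blank-corrected on the fly).
#' @param Q1 Incubation volume (l).
#' @param t Incubation time (h); defaults to the last NH4 timepoint.
#' @param Q2 Volume of sampled air (m3).
#' @param method `"endpoint"` (default) or `"regression"`.
#' @param sample Sample label carried into the result.
#' @return A list of class `rate_result`: `sample`, `nnr_max`
#'   (ug m-3 air h-1), `net_start`, `net_end` (mg l-1), `method`.
#' @export
nnr_max <- function(net, Q1 = 0.25, t = NULL, Q2 = 48,
                    method = c("endpoint", "regression"), sample = NA) {
  method <- match.arg(method)
  if (inherits(net, "incubation_series")) {
    Q1 <- net$Q1; Q2 <- net$Q2
    if (is.na(sample)) sample <- net$sample
    net <- suppressWarnings(net_concentrations(net))
  }
  check_number(Q1, "Q1", min = 0, strict_min = TRUE)
  check_number(Q2, "Q2", min = 0, strict_min = TRUE)
  nh4 <- net[net$analyte == "nh4", ]
  if (nrow(nh4) < 2L) stop("need net NH4 values at >= 2 timepoints")
  if (is.null(t)) t <- max(nh4$time_h)
  check_number(t, "t", min = 0, strict_min = TRUE)
  if (!any(nh4$time_h == 0) || !any(nh4$time_h == t)) {
    stop("net NH4 series must contain timepoints 0 and ", t)
  }
  net_start <- nh4$net[nh4$time_h == 0][1]
  net_end <- nh4$net[nh4$time_h == t][1]
  drop_rate <- switch(method,
    endpoint = (net_start - net_end) / t,          # mg l-1 h-1
    regression = {
      use <- nh4[nh4$time_h <= t, ]
      -unname(coef(lm(net ~ time_h, data = use))[2])
    }
  )
  structure(
    list(sample = sample,
         nnr_max = drop_rate * Q1 * 1000 / Q2,
         net_start = net_start, net_end = net_end,
         t = t, method = method),
    class = "rate_result"
  )
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "NNR_max (%s): %.4f ug (NH4+-N) m-3 air h-1  [net NH4 %.2f -> %.2f mg l-1 over %g h, %s]\n",
    x$sample, x$nnr_max, x$net_start, x$net_end, x$t, x$method))
  invisible(x)
}

#' Nitrogen mass-balance check for an incubation
#'
#' Compares cumulative net NH4+-N consumed against cumulative net
#' NO2--N + NO3--N produced at each timepoint. The imbalance fraction is
#' `|consumed - produced| / max(consumed, eps)`; the series is judged
#' balanced when the final imbalance is at or below `tolerance`.
#'
#' @param net Net-concentration data.frame (all three analytes present), or
#'   an [incubation_series()].
#' @param tolerance Balanced verdict threshold on the final imbalance
#'   fraction (default 0.10).
#' @param eps Floor for the denominator (default 1e-12).
#' @return A list of class `balance_report`: per-timepoint `consumed`,
#'   `produced`, `imbalance`, plus `final_imbalance` and `balanced`.
#' @export
nitrogen_balance <- function(net, tolerance = 0.10, eps = 1e-12) {
  if (inherits(net, "incubation_series")) {
    net <- suppressWarnings(net_concentrations(net))
  }
  if (!all(c("nh4", "no2", "no3") %in% net$analyte)) {
    stop("nitrogen balance needs nh4, no2 and no3 net series")
  }
  wide <- Reduce(function(a, b) merge(a, b, by = "time_h"), lapply(
    c("nh4", "no2", "no3"), function(an) {
      out <- net[net$analyte == an, c("time_h", "net")]
      names(out)[2] <- an
      out
    }))
  wide <- wide[order(wide$time_h), ]
  consumed <- wide$nh4[1] - wide$nh4
  produced <- (wide$no2 + wide$no3) - (wide$no2[1] + wide$no3[1])
  imbalance <- abs(consumed - produced) / pmax(consumed, eps)
  n <- nrow(wide)
  structure(
    list(time_h = wide$time_h, consumed = consumed, produced = produced,
         imbalance = imbalance, final_imbalance = imbalance[n],
         balanced = imbalance[n] <= tolerance, tolerance = tolerance),
    class = "balance_report"
  )
}

#' Read / write incubation series as long-format CSV
#'
#' Columns: `time_h`, `analyte`, `role` (`sample` or `blank`),
#' `value_mg_per_l`; `Q1`/`Q2`/sample label travel as extra constant columns.
#'
#' @param series An [incubation_series()].
#' @param path CSV path.
#' @return `read_incubation_csv` returns an [incubation_series()];
#'   `write_incubation_csv` returns `path` invisibly.
#' @export
write_incubation_csv <- function(series, path) {
  stopifnot(inherits(series, "incubation_series"))
  d <- series$data
  long <- rbind(
    data.frame(time_h = d$time_h, analyte = d$analyte, role = "sample",
               value_mg_per_l = d$sample),
    data.frame(time_h = d$time_h, analyte = d$analyte, role = "blank",
               value_mg_per_l = d$blank)
  )
  long$sample_label <- series$sample
  long$Q1 <- series$Q1
  long$Q2 <- series$Q2
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_incubation_csv
#' @export
read_incubation_csv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  s <- long[long$role == "sample", ]
  b <- long[long$role == "blank", ]
  d <- merge(s[, c("time_h", "analyte", "value_mg_per_l")],
             b[, c("time_h", "analyte", "value_mg_per_l")],
             by = c("time_h", "analyte"), suffixes = c("_s", "_b"))
  d <- d[order(d$analyte, d$time_h), ]
  dat <- data.frame(time_h = d$time_h, analyte = d$analyte,
                    sample = d$value_mg_per_l_s, blank = d$value_mg_per_l_b,
                    stringsAsFactors = FALSE)
  incubation_series(sample = long$sample_label[1], data = dat,
                    Q1 = long$Q1[1], Q2 = long$Q2[1])
}
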