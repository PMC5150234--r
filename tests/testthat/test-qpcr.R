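test_that("fit_standard_curve recovers exact lines and their efficiency", {
  copies <- 10^(3:7)
  exact <- data.frame(copies = copies, cq = 38 - 3.3219 * log10(copies))
  cv <- fit_standard_curve(exact)
  expect_equal(cv$slope, -3.3219, tolerance = 1e-10)
  expect_equal(cv$efficiency, 1, tolerance = 1e-4)  # perfect doubling
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_true(cv$qc_pass)

  # efficiency formula at the low edge of the acceptable window
  low <- data.frame(copies = copies, cq = 38 - 3.585 * log10(copies))
  cv2 <- fit_standard_curve(low)
  expect_equal(cv2$efficiency, 10^(1 / 3.585) - 1, tolerance = 1e-12)
  expect_equal(cv2$efficiency, 0.901, tolerance = 1e-3)
})

test_that("degraded curves warn instead of failing", {
  copies <- 10^(3:7)
  # slope -4.2 -> efficiency ~73%, outside the 90-110% gate
  bad <- data.frame(copies = copies, cq = 40 - 4.2 * log10(copies))
  expect_warning(cv <- fit_standard_curve(bad), "QC")
  expect_false(cv$qc_pass)
  expect_error(fit_standard_curve(data.frame(copies = c(10, 100), cq = c(30, 27))),
               "3 distinct")
  expect_error(
    fit_standard_curve(data.frame(copies = rep(100, 4), cq = c(30, 30, 31, 29))),
    "distinct")
})

test_that("fitting a noisy synthetic plate recovers the true slope", {
  spec <- qpcr_plate_spec(-3.4, 37, 1e7, 5, c(u = 1e4),
                          cq_noise_sd = 0.1, seed = 123)
  cv <- fit_standard_curve(generate_qpcr_plate(spec))
  expect_lt(abs(cv$slope - (-3.4)), 0.1)
})

test_that("quantify_unknowns inverts the curve", {
  copies <- 10^(3:7)
  cv <- fit_standard_curve(
    data.frame(copies = copies, cq = 38 - 3.3219 * log10(copies)))
  # Cq at the intercept means one template copy
  expect_equal(quantify_unknowns(cv, 38)$copies_mean, 1, tolerance = 1e-9)
  # frozen line inversion: 10^((24.7124 - 38) / -3.3219) = 1e4
  q <- quantify_unknowns(cv, rep(24.7124, 3))
  expect_equal(q$copies_mean, 1e4, tolerance = 1e-6)
  expect_equal(q$copies_sd, 0)
  # all-sentinel input flags no amplification, zero copies
  q0 <- quantify_unknowns(cv, c(NA, NA, NA))
  expect_true(q0$no_amplification)
  expect_equal(q0$copies_mean, 0)
  # geometric aggregation equals linear for identical replicates
  expect_equal(quantify_unknowns(cv, rep(30, 3), aggregate = "geometric"),
               quantify_unknowns(cv, rep(30, 3)), tolerance = 1e-12)
})

test_that("copies_to_cells applies per-cell copy numbers", {
  expect_equal(copies_to_cells(3.6e3, 3.6), 1e3)  # 16S, average prokaryote
  expect_equal(copies_to_cells(2.5e3, 2.5), 1e3)  # amoA per AOB
  expect_equal(copies_to_cells(42, 1), 42)
  expect_error(copies_to_cells(-1, 1), ">= 0")
  expect_error(copies_to_cells(10, 0), "> 0")
})

test_that("cells_per_m3 normalizes by extract, filter fraction and air volume", {
  cfg <- assay_config("AOA", copies_per_cell = 1, extract_scaleup = 1,
                      filter_fraction = 0.25, air_volume = 144)
  est <- cells_per_m3(9e4, cfg, sample = "BJ")
  expect_equal(est$cells_per_m3, 2.5e3)  # 9e4 / 0.25 / 144
  ident <- assay_config("x", 1, 1, filter_fraction = 1, air_volume = 1)
  expect_equal(cells_per_m3(123, ident)$cells_per_m3, 123)
  # scale equivariance: doubling air volume halves the answer exactly
  cfg2 <- assay_config("AOA", 1, 1, 0.25, air_volume = 288)
  expect_equal(cells_per_m3(9e4, cfg2)$cells_per_m3, est$cells_per_m3 / 2)
})

test_that("noiseless plate -> fit -> quantify round trip is exact", {
  true_copies <- c(s1 = 3.7e5, s2 = 820, s3 = 5.5e3)
  plate <- generate_qpcr_plate(
    qpcr_plate_spec(-3.32, 38.5, 1e7, 6, true_copies, cq_noise_sd = 0))
  cv <- fit_standard_curve(plate)
  for (s in names(true_copies)) {
    q <- quantify_unknowns(cv, plate$unknowns$cq[plate$unknowns$sample == s])
    expect_equal(q$copies_mean, unname(true_copies[s]),
                 tolerance = 1e-9)
  }
  # monotonicity: larger Cq means fewer copies
  cqs <- seq(15, 35, by = 2)
  est <- vapply(cqs, function(cq) quantify_unknowns(cv, cq)$copies_mean, 0)
  expect_true(all(diff(est) < 0))
})

test_that("quantify_plate runs plate -> abundance end to end", {
  cfg <- assay_config("AOA", copies_per_cell = 1, extract_scaleup = 2,
                      filter_fraction = 0.25, air_volume = 144)
  true_cells_m3 <- 2.5e3
  copies_rxn <- true_cells_m3 * 0.25 * 144 / 2
  plate <- generate_qpcr_plate(
    qpcr_plate_spec(-3.3219, 38, 1e7, 5, c(BJ = copies_rxn, none = 0),
                    cq_noise_sd = 0))
  est <- quantify_plate(plate, cfg)
  expect_equal(est$cells_per_m3[est$sample == "BJ"], true_cells_m3,
               tolerance = 1e-9)
  expect_equal(est$cells_per_m3[est$sample == "none"], 0)
})

test_that("abundance_summaries forms ratios and flags degenerate cells", {
  est <- data.frame(
    sample = "BJ",
    target = c("AOA", "AOB", "Comammox", "Archaea", "Bacteria"),
    cells_per_m3 = c(2.82e4, 4.65e3, 1.15e3, 1.2e5, 0))
  s <- abundance_summaries(est)
  get <- function(st) s$value[s$statistic == st]
  expect_equal(get("AOA/AOB"), 2.82e4 / 4.65e3)     # ~6.06
  expect_equal(round(get("AOA/AOB"), 2), 6.06)
  expect_equal(get("AOA/Comammox"), 2.82e4 / 1.15e3)
  # zero denominator -> undefined marker, not Inf
  expect_true(s$undefined[s$statistic == "AOB/Bacteria"])
  expect_true(is.na(get("AOB/Bacteria")))
  # equal abundances -> ratio 1
  eq <- abundance_summaries(data.frame(
    sample = "x", target = c("AOA", "AOB"), cells_per_m3 = c(5, 5)))
  expect_equal(eq$value[eq$statistic == "AOA/AOB"], 1)
  # missing pair member -> missing marker
  expect_true(eq$missing[eq$statistic == "AOA/Archaea"])
})

test_that("plate CSV round trip preserves the quantification", {
  plate <- generate_qpcr_plate(
    qpcr_plate_spec(-3.35, 37.5, 1e6, 5, c(a = 2e4, b = 0),
                    cq_noise_sd = 0.1, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_qpcr_csv(plate, path, target = "AOA")
  back <- read_qpcr_csv(path)
  expect_equal(fit_standard_curve(back$standards)$slope,
               fit_standard_curve(plate)$slope, tolerance = 1e-9)
  expect_equal(back$unknowns$cq[back$unknowns$sample == "a"],
               plate$unknowns$cq[plate$unknowns$sample == "a"],
               tolerance = 1e-9)
  expect_true(all(is.na(back$unknowns$cq[back$unknowns$sample == "b"])))
})
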