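#' Specify a synthetic marker-gene clone community
#'
#' Describes a clustered sequence community with known OTU structure, the
#' stand-in for clone libraries of ammonia-oxidizer marker genes (amoA, 16S
#' rRNA) recovered from PM2.5 filters. Cluster centroids are placed at a
#' controlled between-cluster divergence; members diverge from their centroid
#' by per-site substitution, so the true p-distances stay analytically
#' tractable (no indels).
#'
#' @param clusters A list; each element is a list with fields `label`,
#'   `length` (centroid length, nt, >= 100), `within` (expected per-site
#'   divergence of a member from its centroid, fraction) and `abundance`
#'   (named integer vector of clone counts per sample).
#' @param between_divergence Expected pairwise p-distance between cluster
#'   centroids (fraction). Must exceed `cutoff + 2 * max(within)` so the
#'   planted clusters remain separable by complete-linkage clustering.
#' @param seed Integer seed; the single source of randomness.
#' @param cutoff Clustering cutoff the community must be separable at
#'   (default 0.03, i.e. 97% identity).
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(clusters, between_divergence, seed, cutoff = 0.03) {
  stopifnot(is.list(clusters), length(clusters) >= 1L)
  labs <- vapply(clusters, function(cl) as.character(cl$label), "")
  if (anyDuplicated(labs)) stop("cluster labels must be unique")
  samples <- NULL
  for (cl in clusters) {
    check_number(cl$length, "centroid length", min = 100)
    check_number(cl$within, "within-cluster divergence", min = 0)
    if (is.null(names(cl$abundance)) || any(cl$abundance < 0)) {
      stop("each cluster needs a named, non-negative abundance vector")
    }
    samples <- union(samples, names(cl$abundance))
  }
  check_number(between_divergence, "between_cluster_divergence", min = 0)
  within_max <- max(vapply(clusters, function(cl) cl$within, 0))
  if (between_divergence <= cutoff + 2 * within_max) {
    stop("clusters are not separable at cutoff ", cutoff,
         ": between-cluster divergence (", between_divergence,
         ") must exceed cutoff + 2 * max within-cluster divergence (",
         cutoff + 2 * within_max, ")")
  }
  structure(
    list(clusters = clusters, between_divergence = between_divergence,
         samples = samples, cutoff = cutoff, seed = as.integer(seed)),
    class = "community_spec"
  )
}

# Substitute the bases at `sites` with a uniform draw from the 3 other bases.
mutate_sites <- function(chars, sites) {
  if (length(sites) == 0L) return(chars)
  bases <- c("A", "C", "G", "T")
  for (s in sites) {
    chars[s] <- sample(setdiff(bases, chars[s]), 1L)
  }
  chars
}

#' Generate a labelled clone-sequence set with known OTU assignments
#'
#' Draws a random ancestor, derives one centroid per cluster by mutating
#' disjoint site sets (so centroid p-distances hit the requested
#' between-cluster divergence exactly on the shared region), then mutates
#' Binomial(length, within) sites per member sequence. Headers follow the
#' `sample|cluster|index` convention.
#'
#' @param spec A [community_spec()].
#' @return A list of class `community_set`: `records` (data.frame `id`,
#'   `sample`, `cluster`, `bases`) and `truth` (id to true-cluster table).
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, {
    lens <- vapply(spec$clusters, function(cl) cl$length, 0)
    l_min <- min(lens)
    k <- length(spec$clusters)
    m <- round(spec$between_divergence / 2 * l_min)
    if (k * m > l_min) {
      stop("between-cluster divergence too large for ", k,
           " clusters of length ", l_min)
    }
    ancestor <- sample(c("A", "C", "G", "T"), max(lens), replace = TRUE)
    # disjoint marker blocks within the common region -> exact centroid spacing
    block_sites <- if (m > 0) split(sample(l_min, k * m), rep(seq_len(k), each = m))
                   else rep(list(integer(0)), k)
    rows <- vector("list", 0L)
    for (ki in seq_len(k)) {
      cl <- spec$clusters[[ki]]
      centroid <- mutate_sites(ancestor[seq_len(cl$length)], block_sites[[ki]])
      for (smp in names(cl$abundance)) {
        n_i <- cl$abundance[[smp]]
        if (n_i == 0) next
        for (i in seq_len(n_i)) {
          # truncate so the cluster diameter provably stays under the cutoff
          n_mut <- min(rbinom(1L, cl$length, cl$within),
                       floor(spec$cutoff * cl$length / 2))
          seq_i <- mutate_sites(centroid, sample(cl$length, n_mut))
          rows[[length(rows) + 1L]] <- data.frame(
            id = paste(smp, cl$label, i, sep = "|"),
            sample = smp, cluster = as.character(cl$label),
            bases = paste(seq_i, collapse = ""),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    structure(
      list(records = records,
           truth = records[, c("id", "sample", "cluster")]),
      class = "community_set"
    )
  })
}

#' Specify a synthetic qPCR plate
#'
#' A 10-fold standard-dilution series with log-linear Cq response plus
#' Gaussian Cq noise, and unknowns drawn from the same line. This is the
#' stand-in for plates quantifying marker genes from PM2.5 DNA extracts
#' against linearized-plasmid standards.
#'
#' @param true_slope Cq per log10(copies); must be negative (around
#'   -3.32 for 100% amplification efficiency).
#' @param true_intercept Cq at 1 copy.
#' @param dilution_top Copy number of the top standard.
#' @param dilution_levels Number of 10-fold steps (>= 4).
#' @param unknown_true_copies Named numeric vector of true template copies
#'   per unknown sample; 0 means no template (emitted as a no-amplification
#'   sentinel, `NA` Cq).
#' @param cq_noise_sd Gaussian Cq noise standard deviation (>= 0), applied
#'   to standards and unknowns alike.
#' @param replicates Technical replicates per well group (default 3).
#' @param seed Integer seed.
#' @return An object of class `qpcr_plate_spec`.
#' @export
qpcr_plate_spec <- function(true_slope, true_intercept, dilution_top,
                            dilution_levels, unknown_true_copies,
                            cq_noise_sd = 0, replicates = 3L, seed = 1L) {
  check_number(true_slope, "true_slope")
  if (true_slope >= 0) stop("true_slope must be negative")
  check_number(true_intercept, "true_intercept")
  check_number(dilution_top, "dilution_top", min = 0, strict_min = TRUE)
  check_number(dilution_levels, "dilution_levels", min = 4)
  check_number(cq_noise_sd, "cq_noise_sd", min = 0)
  check_number(replicates, "replicates", min = 1)
  if (is.null(names(unknown_true_copies)) || any(unknown_true_copies < 0)) {
    stop("unknown_true_copies must be a named, non-negative vector")
  }
  structure(
    list(true_slope = true_slope, true_intercept = true_intercept,
         dilution_top = dilution_top,
         dilution_levels = as.integer(dilution_levels),
         unknown_true_copies = unknown_true_copies,
         cq_noise_sd = cq_noise_sd, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "qpcr_plate_spec"
  )
}

#' Generate a synthetic qPCR plate (standards and unknowns)
#'
#' @param spec A [qpcr_plate_spec()].
#' @return A list of class `qpcr_plate`: `standards` (data.frame `level`,
#'   `copies`, `replicate`, `cq`) and `unknowns` (data.frame `sample`,
#'   `true_copies`, `replicate`, `cq`; `NA` Cq marks no amplification).
#' @export
generate_qpcr_plate <- function(spec) {
  stopifnot(inherits(spec, "qpcr_plate_spec"))
  withr::with_seed(spec$seed, {
    line_cq <- function(copies) {
      spec$true_slope * log10(copies) + spec$true_intercept
    }
    lev <- seq_len(spec$dilution_levels)
    std <- expand.grid(replicate = seq_len(spec$replicates), level = lev)
    std <- std[order(std$level, std$replicate), c("level", "replicate")]
    std$copies <- spec$dilution_top / 10^(std$level - 1)
    std$cq <- line_cq(std$copies) +
      rnorm(nrow(std), 0, spec$cq_noise_sd)
    rownames(std) <- NULL
    unk <- expand.grid(replicate = seq_len(spec$replicates),
                       sample = names(spec$unknown_true_copies),
                       stringsAsFactors = FALSE)
    unk <- unk[order(match(unk$sample, names(spec$unknown_true_copies)),
                     unk$replicate), c("sample", "replicate")]
    unk$true_copies <- spec$unknown_true_copies[unk$sample]
    unk$cq <- ifelse(
      unk$true_copies > 0,
      line_cq(pmax(unk$true_copies, .Machine$double.xmin)) +
        rnorm(nrow(unk), 0, spec$cq_noise_sd),
      NA_real_
    )
    rownames(unk) <- NULL
    structure(
      list(standards = std[, c("level", "copies", "replicate", "cq")],
           unknowns = unk[, c("sample", "true_copies", "replicate", "cq")],
           spec = spec),
      class = "qpcr_plate"
    )
  })
}

#' Specify a synthetic nitrification-potential incubation
#'
#' Encodes the stated world of a PM2.5 suspension incubation: per-guild cell
#' abundances and cell-specific ammonia-oxidation rates translate into a
#' constant (zero-order) total ammonia removal rate; ammonia loss is matched
#' by nitrite-plus-nitrate gain, with the comammox share routed to nitrate
#' and the AOA/AOB share to nitrite; the paired blank sits at a constant
#' level. The implied maximum nitrification rate per m3 of sampled air is
#' recorded as ground truth.
#'
#' @param guild_cells Named vector of cell abundances (cells m-3 air) for
#'   `aoa`, `aob`, `comammox`.
#' @param guild_r_in Named vector of cell-specific ammonia oxidation rates
#'   (fmol cell-1 h-1) for the same guilds.
#' @param timepoints Sampling times in hours, strictly increasing from 0
#'   (default 0..16 h every 2 h).
#' @param nh4_start Net NH4+-N at time 0 (mg l-1).
#' @param blank_level Constant blank concentration added to every analyte
#'   (mg l-1).
#' @param noise_sd Gaussian concentration noise sd (mg l-1), truncated at 0.
#' @param Q1 Incubation volume (l, default 0.25).
#' @param Q2 Volume of sampled air (m3, default 48).
#' @param seed Integer seed.
#' @return An object of class `incubation_spec`.
#' @export
incubation_spec <- function(guild_cells, guild_r_in,
                            timepoints = seq(0, 16, by = 2),
                            nh4_start = 0.65, blank_level = 0.35,
                            noise_sd = 0, Q1 = 0.25, Q2 = 48, seed = 1L) {
  guilds <- c("aoa", "aob", "comammox")
  if (!all(guilds %in% names(guild_cells)) ||
      !all(guilds %in% names(guild_r_in))) {
    stop("guild_cells and guild_r_in must name aoa, aob and comammox")
  }
  if (any(guild_cells < 0) || any(guild_r_in < 0)) {
    stop("cell abundances and rates must be >= 0")
  }
  if (timepoints[1] != 0 || any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing and start at 0")
  }
  check_number(nh4_start, "nh4_start", min = 0)
  check_number(blank_level, "blank_level", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(Q1, "Q1", min = 0, strict_min = TRUE)
  check_number(Q2, "Q2", min = 0, strict_min = TRUE)
  structure(
    list(guild_cells = guild_cells[guilds], guild_r_in = guild_r_in[guilds],
         timepoints = timepoints, nh4_start = nh4_start,
         blank_level = blank_level, noise_sd = noise_sd,
         Q1 = Q1, Q2 = Q2, seed = as.integer(seed)),
    class = "incubation_spec"
  )
}

#' Generate an incubation time series with known true rate
#'
#' The total removal rate on the air basis is
#' `sum(cells_g * r_in_g) * Mr_N * 1e-9` ug (NH4+-N) m-3 air h-1; on the
#' incubation basis it is that times `Q2 / (Q1 * 1000)` mg l-1 h-1.
#'
#' @param spec An [incubation_spec()].
#' @param sample Sample label (default `"synthetic"`).
#' @return An [incubation_series()] whose `truth` field records the true
#'   NNR_max (ug m-3 air h-1), the per-guild rates and the true relative
#'   contributions.
#' @export
generate_incubation <- function(spec, sample = "synthetic") {
  stopifnot(inherits(spec, "incubation_spec"))
  guild_rates <- guild_rate(spec$guild_cells, spec$guild_r_in)  # ug m-3 h-1
  rate_air <- sum(guild_rates)
  rate_mgl <- rate_air * spec$Q2 / (spec$Q1 * 1000)
  t_end <- max(spec$timepoints)
  if (spec$nh4_start - rate_mgl * t_end < 0) {
    stop("total removal rate ", signif(rate_mgl, 4),
         " mg l-1 h-1 would drive NH4 below 0 before ", t_end, " h")
  }
  withr::with_seed(spec$seed, {
    tp <- spec$timepoints
    frac_no3 <- if (rate_air > 0) guild_rates[["comammox"]] / rate_air else 0
    net <- list(
      nh4 = spec$nh4_start - rate_mgl * tp,
      no2 = rate_mgl * tp * (1 - frac_no3),
      no3 = rate_mgl * tp * frac_no3
    )
    rows <- lapply(names(net), function(an) {
      data.frame(time_h = tp, analyte = an,
                 sample = net[[an]] + spec$blank_level,
                 blank = spec$blank_level, stringsAsFactors = FALSE)
    })
    dat <- do.call(rbind, rows)
    if (spec$noise_sd > 0) {
      dat$sample <- pmax(0, dat$sample + rnorm(nrow(dat), 0, spec$noise_sd))
      dat$blank <- pmax(0, dat$blank + rnorm(nrow(dat), 0, spec$noise_sd))
    }
    rownames(dat) <- NULL
    truth <- list(
      nnr_max = rate_air,
      guild_rates = guild_rates,
      rc = if (rate_air > 0) guild_rates / rate_air else
        c(aoa = 0, aob = 0, comammox = 0)
    )
    incubation_series(sample = sample, data = dat, Q1 = spec$Q1, Q2 = spec$Q2,
                      truth = truth)
  })
}

#' Specify a synthetic environmental-factor table
#'
#' @param n_samples Number of samples (>= 4; field campaigns of this kind
#'   typically have ~6 sites).
#' @param factors Character vector of factor names (no duplicates).
#' @param planted_links Data.frame with columns `taxon`, `factor`, `sign`
#'   (+1 monotone increasing, -1 decreasing, 0 independent).
#' @param noise_sd Gaussian noise sd added to planted taxon responses.
#' @param seed Integer seed.
#' @return An object of class `env_table_spec`.
#' @export
env_table_spec <- function(n_samples, factors, planted_links,
                           noise_sd = 0, seed = 1L) {
  check_number(n_samples, "n_samples", min = 4)
  if (anyDuplicated(factors)) stop("duplicate factor names")
  stopifnot(is.data.frame(planted_links),
            all(c("taxon", "factor", "sign") %in% names(planted_links)))
  if (!all(planted_links$sign %in% c(-1, 0, 1))) {
    stop("planted signs must be -1, 0 or +1")
  }
  if (!all(planted_links$factor %in% factors)) {
    stop("planted links refer to unknown factors")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  structure(
    list(n_samples = as.integer(n_samples), factors = factors,
         planted_links = planted_links, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "env_table_spec"
  )
}

#' Generate environmental-factor and taxon tables with planted correlations
#'
#' @param spec An [env_table_spec()].
#' @return A list of class `env_tables`: `factors` and `taxa`, both
#'   data.frames keyed on a `sample` column.
#' @export
generate_env_table <- function(spec) {
  stopifnot(inherits(spec, "env_table_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    samples <- sprintf("S%02d", seq_len(n))
    fac <- as.data.frame(setNames(
      lapply(spec$factors, function(f) rnorm(n)), spec$factors
    ))
    taxa <- data.frame(row.names = seq_len(n))
    for (i in seq_len(nrow(spec$planted_links))) {
      lk <- spec$planted_links[i, ]
      base <- if (lk$sign == 0) rnorm(n) else lk$sign * fac[[lk$factor]]
      taxa[[lk$taxon]] <- base + rnorm(n, 0, spec$noise_sd)
    }
    list_out <- list(
      factors = cbind(data.frame(sample = samples), fac),
      taxa = cbind(data.frame(sample = samples), taxa)
    )
    structure(list_out, class = "env_tables")
  })
}
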