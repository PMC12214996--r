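# Synthetic-diploid simulator. Emulates, at binned-depth resolution, a
# diploid chromosome assembled from two independently amplified haploid
# sources, so CNAs can be spiked into a single haplotype without
# disturbing the other: per-haplotype bin counts carry a Gamma-distributed
# multiplicative amplification field (autocorrelated, PTA-like waviness),
# allelic-dropout intervals that silence one haplotype locally, GC-linked
# depth bias, and Poisson sampling noise; gHET allele depths are drawn
# from the local haplotype depth with Poisson noise and phase-switch
# flips.

#' Simulation configuration for synthetic-diploid experiments
#'
#' Defaults describe the reference condition: a single 150 Mb
#' autosome-like chromosome in 100 kb bins at 30x-equivalent total depth
#' (15x per haplotype, 150 bp reads), PTA-like amplification (Gamma
#' multiplicative field, CV 0.1, 300 kb correlation length; kb-scale
#' log-normal dropout at 5 events/Mb), 5 gHETs per 10 kb, phase-switch
#' probability 0.01 and Poisson depth noise. The CNA plan spikes one
#' event per mutated cell; the default plan is a single condition of 100
#' single-copy losses of 1 Mb.
#'
#' @param genome_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param depth_per_haplotype Haploid sequencing depth (x coverage).
#' @param read_length Read length in bp (converts depth to read counts).
#' @param amp_cv Coefficient of variation of the Gamma amplification
#'   field.
#' @param amp_corr_length Correlation length of the amplification field
#'   in bp.
#' @param gc_coef Log-linear GC effect on depth.
#' @param ado_rate_per_mb Expected dropout events per Mb per haplotype.
#' @param ado_meanlog,ado_sdlog Log-normal dropout length parameters.
#' @param ghet_per_10kb gHET loci per 10 kb region.
#' @param phase_switch_prob Per-site probability of flipping the
#'   allele-specific depths.
#' @param poisson_noise Draw Poisson counts (TRUE) or use expectations.
#' @param seed Base seed; per-cell seeds are derived from it.
#' @param cna_plan `data.frame` with columns `type`
#'   (`loss_1_0`, `gain_2_1`, `gain_3_1`, `cnloh_2_0`), `size` (bp) and
#'   `n` (cells, one spiked event each).
#' @param exclude Optional `data.frame` of `start`,`end` intervals where
#'   no truth interval may be placed.
#' @return List of class `sdx_config`.
#' @export
sdx_config <- function(genome_length = 150e6,
                       chrom = "chr1",
                       bin_size = 1e5,
                       depth_per_haplotype = 15,
                       read_length = 150,
                       amp_cv = 0.1,
                       amp_corr_length = 3e5,
                       gc_coef = 1.5,
                       ado_rate_per_mb = 5,
                       ado_meanlog = log(2000),
                       ado_sdlog = 0.8,
                       ghet_per_10kb = 5,
                       phase_switch_prob = 0.01,
                       poisson_noise = TRUE,
                       seed = 1L,
                       cna_plan = data.frame(type = "loss_1_0",
                                             size = 1e6, n = 100L),
                       exclude = NULL) {
  stopifnot(genome_length >= bin_size, bin_size > 0,
            depth_per_haplotype > 0, read_length > 0,
            amp_cv >= 0, phase_switch_prob >= 0, phase_switch_prob <= 1,
            ghet_per_10kb >= 1)
  cna_plan <- data.table::as.data.table(cna_plan)
  if (nrow(cna_plan) > 0L) {
    stopifnot(all(cna_plan$type %in% c("loss_1_0", "gain_2_1",
                                       "gain_3_1", "cnloh_2_0")),
              all(cna_plan$size > 0 & cna_plan$size <= genome_length))
  }
  structure(list(
    genome_length = genome_length, chrom = chrom, bin_size = bin_size,
    depth_per_haplotype = depth_per_haplotype, read_length = read_length,
    amp_cv = amp_cv, amp_corr_length = amp_corr_length,
    gc_coef = gc_coef, ado_rate_per_mb = ado_rate_per_mb,
    ado_meanlog = ado_meanlog, ado_sdlog = ado_sdlog,
    ghet_per_10kb = ghet_per_10kb,
    phase_switch_prob = phase_switch_prob,
    poisson_noise = poisson_noise, seed = as.integer(seed),
    cna_plan = cna_plan,
    exclude = if (is.null(exclude)) {
      data.table::data.table(start = numeric(), end = numeric())
    } else data.table::as.data.table(exclude)
  ), class = "sdx_config")
}

#' Geometric size grid for spiked CNAs
#'
#' `n` sizes in geometric progression from `min_size` to `max_size`
#' (defaults: 13 sizes, 200 kb to 5 Mb, midpoint 1 Mb).
#'
#' @param min_size,max_size Range in bp, `min_size < max_size`.
#' @param n Number of sizes (>= 2).
#' @return Numeric vector of sizes.
#' @export
make_size_grid <- function(min_size = 2e5, max_size = 5e6, n = 13L) {
  if (!(min_size > 0 && min_size < max_size && n >= 2L)) {
    stop("invalid size range")
  }
  exp(seq(log(min_size), log(max_size), length.out = n))
}

# deterministic GC track per genome: smooth composition waves around 0.45
.sim_gc_track <- function(config) {
  bins <- make_bins(config$chrom, config$genome_length, config$bin_size)
  mid <- (bins$start + bins$end) / 2
  gc <- 0.45 + 0.05 * sin(2 * pi * mid / 23e6) +
    0.025 * sin(2 * pi * mid / 4.7e6 + 1)
  bins[, gc := gc]
  bins[]
}

# gHET loci are germline: fixed per genome (seeded by config$seed only)
.sim_ghet_positions <- function(config) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  n_win <- floor(config$genome_length / 1e4)
  k <- config$ghet_per_10kb
  offs <- matrix(runif(n_win * k, 0, 1e4), nrow = k)
  pos <- as.vector(offs) + rep((seq_len(n_win) - 1) * 1e4, each = k)
  sort(as.integer(ceiling(pos)))
}

#' Simulate one haplotype's binned depth track
#'
#' Per-bin expected count = reads-per-bp x mappable span x amplification
#' factor x GC factor, with allelic-dropout intervals (Poisson process of
#' log-normal lengths) zeroing the haplotype locally; observed counts add
#' Poisson noise. Reproducible under `seed`.
#'
#' @param config An `sdx_config`.
#' @param haplotype_id `"A"` or `"B"` (label only).
#' @param seed Seed for this haplotype's randomness.
#' @return List of class `hap_track`: `bins` (`data.table` with `chrom`,
#'   `start`, `end`, `gc`, `amp_factor`, `ado_frac`, `expected`,
#'   `observed`), `ado_events` (`data.table` `start`,`end`), and the
#'   scalars needed to compute site-level depth (`reads_per_bp`,
#'   `site_depth`).
#' @export
simulate_haplotype_depth <- function(config, haplotype_id, seed) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  bins <- .sim_gc_track(config)
  n <- nrow(bins)
  # autocorrelated Gamma field via a Gaussian AR(1) copula
  if (config$amp_cv > 0) {
    rho <- exp(-config$bin_size / config$amp_corr_length)
    z <- numeric(n)
    z[1] <- rnorm(1)
    innov <- rnorm(n - 1, sd = sqrt(1 - rho^2))
    for (i in 2:n) z[i] <- rho * z[i - 1] + innov[i - 1]
    shape <- 1 / config$amp_cv^2
    amp <- qgamma(pnorm(z), shape = shape, rate = shape)
  } else {
    amp <- rep(1, n)
  }
  # dropout intervals: Poisson count, uniform starts, log-normal lengths
  n_ado <- rpois(1, config$ado_rate_per_mb * config$genome_length / 1e6)
  if (n_ado > 0L) {
    st <- runif(n_ado, 0, config$genome_length)
    len <- rlnorm(n_ado, config$ado_meanlog, config$ado_sdlog)
    ado <- data.table::data.table(start = st,
                                  end = pmin(st + len,
                                             config$genome_length))
    data.table::setorder(ado, start)
  } else {
    ado <- data.table::data.table(start = numeric(), end = numeric())
  }
  ado_frac <- .interval_bin_fraction(ado, bins$start, bins$end)
  gc_factor <- exp(config$gc_coef * (bins$gc - 0.45))
  reads_per_bp <- config$depth_per_haplotype / config$read_length
  expected <- reads_per_bp * (bins$end - bins$start) *
    (1 - ado_frac) * amp * gc_factor
  observed <- if (config$poisson_noise) {
    rpois(n, expected)
  } else {
    expected
  }
  bins[, `:=`(amp_factor = amp, ado_frac = ado_frac,
              expected = expected, observed = as.numeric(observed))]
  structure(list(
    haplotype = haplotype_id, bins = bins[], ado_events = ado,
    reads_per_bp = reads_per_bp,
    site_depth = config$depth_per_haplotype,
    gc_factor = gc_factor
  ), class = "hap_track")
}

# fraction of each bin covered by the union of (non-overlapping-ish)
# intervals; intervals may overlap bins partially
.interval_bin_fraction <- function(intervals, bin_start, bin_end) {
  frac <- numeric(length(bin_start))
  if (nrow(intervals) == 0L) return(frac)
  bs <- as.numeric(bin_start); be <- as.numeric(bin_end)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    lo <- findInterval(s, bs)
    hi <- findInterval(e - 1e-9, bs)
    lo <- max(lo, 1L)
    hi <- min(hi, length(bs))
    if (hi < lo) next
    for (j in lo:hi) {
      frac[j] <- frac[j] + max(0, min(e, be[j]) - max(s, bs[j]))
    }
  }
  pmin(frac / (be - bs), 1)
}

#' Spike a CNA into a pair of haplotype depth tracks
#'
#' Modifies the affected haplotype (`B` by convention) inside the truth
#' interval: `loss_1_0` zeroes its depth; `gain_2_1` adds one
#' independently amplified replicate; `gain_3_1` adds two; `cnloh_2_0`
#' leaves depth untouched (the allele identity swap happens at the gHET
#' level in [place_ghets()]).
#'
#' @param track_a,track_b `hap_track` objects from
#'   [simulate_haplotype_depth()].
#' @param truth One-row `data.table` with `type`, `start`, `end`.
#' @param config The `sdx_config` used for the tracks.
#' @param seed Seed for the replicate tracks of gains.
#' @return List with modified `track_a`, `track_b`.
#' @export
spike_cna <- function(track_a, track_b, truth, config, seed) {
  stopifnot(nrow(truth) == 1L,
            truth$start >= 0, truth$end <= config$genome_length)
  type <- truth$type
  if (type == "cnloh_2_0") {
    return(list(track_a = track_a, track_b = track_b))
  }
  bins <- track_b$bins
  frac <- .interval_bin_fraction(
    data.table::data.table(start = truth$start, end = truth$end),
    bins$start, bins$end
  )
  if (type == "loss_1_0") {
    bins[, expected := expected * (1 - frac)]
    bins[, observed := ifelse(frac >= 1, 0,
                              ifelse(frac > 0,
                                     rbinom(.N, round(observed),
                                            pmax(1 - frac, 0)),
                                     observed))]
  } else if (type %in% c("gain_2_1", "gain_3_1")) {
    n_rep <- if (type == "gain_2_1") 1L else 2L
    for (r in seq_len(n_rep)) {
      rep_track <- simulate_haplotype_depth(config, "B_rep",
                                            seed = seed + r)
      bins[, expected := expected + rep_track$bins$expected * frac]
      bins[, observed := observed +
             ifelse(frac > 0,
                    rbinom(.N, round(rep_track$bins$observed),
                           pmin(frac, 1)), 0)]
    }
  } else {
    stop("unknown CNA type: ", type)
  }
  track_b$bins <- bins
  list(track_a = track_a, track_b = track_b)
}

#' Place gHETs and draw allele-specific depths
#'
#' gHET loci are fixed per genome (5 uniform positions per 10 kb by
#' default, seeded by the genome seed). Per-site allele depths are
#' Poisson draws around the local haplotype depth (amplification field x
#' GC factor, zero inside a dropout interval of that haplotype, spiked
#' multiplicity inside gain/loss intervals). Inside cnLOH intervals the
#' B-haplotype reads carry the A allele, so `depth_a` absorbs them and
#' `depth_b` becomes 0. Finally each site's `(depth_a, depth_b)` pair is
#' swapped with probability `phase_switch_prob` (a phase-switch error),
#' recorded in the `flipped` column.
#'
#' @param config `sdx_config`.
#' @param track_a,track_b `hap_track` objects (after [spike_cna()]).
#' @param truth `data.table` of truth intervals for this cell (0 or more
#'   rows, columns `type`, `start`, `end`).
#' @param seed Seed for this cell's site-level randomness.
#' @return `data.table` with `chrom`, `pos`, `depth_a`, `depth_b`,
#'   `flipped`.
#' @export
place_ghets <- function(config, track_a, track_b, truth, seed) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  pos <- .sim_ghet_positions(config)
  set.seed(seed)
  n <- length(pos)
  bin_idx <- pmin(pmax(findInterval(pos - 1L, track_a$bins$start), 1L),
                  nrow(track_a$bins))
  site_mean <- config$depth_per_haplotype
  lam_a <- site_mean * track_a$bins$amp_factor[bin_idx] *
    track_a$gc_factor[bin_idx] * (1 - .in_intervals(pos, track_a$ado_events))
  lam_b <- site_mean * track_b$bins$amp_factor[bin_idx] *
    track_b$gc_factor[bin_idx] * (1 - .in_intervals(pos, track_b$ado_events))
  # spiked multiplicity of haplotype B
  mult_b <- rep(1, n)
  cnloh <- rep(FALSE, n)
  if (nrow(truth) > 0L) {
    for (i in seq_len(nrow(truth))) {
      inside <- pos > truth$start[i] & pos <= truth$end[i]
      if (truth$type[i] == "loss_1_0") mult_b[inside] <- 0
      if (truth$type[i] == "gain_2_1") mult_b[inside] <- 2
      if (truth$type[i] == "gain_3_1") mult_b[inside] <- 3
      if (truth$type[i] == "cnloh_2_0") cnloh[inside] <- TRUE
    }
  }
  lam_b <- lam_b * mult_b
  depth_a <- if (config$poisson_noise) rpois(n, lam_a) else round(lam_a)
  depth_b <- if (config$poisson_noise) rpois(n, lam_b) else round(lam_b)
  # cnLOH: second copy is haplotype A's sequence sampled independently
  if (any(cnloh)) {
    depth_a[cnloh] <- depth_a[cnloh] + depth_b[cnloh]
    depth_b[cnloh] <- 0L
  }
  flip <- runif(n) < config$phase_switch_prob
  tmp <- depth_a[flip]
  depth_a[flip] <- depth_b[flip]
  depth_b[flip] <- tmp
  data.table::data.table(
    chrom = config$chrom, pos = pos,
    depth_a = as.numeric(depth_a), depth_b = as.numeric(depth_b),
    flipped = flip
  )
}

.in_intervals <- function(pos, intervals) {
  if (nrow(intervals) == 0L) return(numeric(length(pos)))
  hit <- logical(length(pos))
  idx <- findInterval(pos, intervals$start)
  ok <- idx >= 1L
  hit[ok] <- pos[ok] <= intervals$end[idx[ok]]
  as.numeric(hit)
}

#' Simulate one synthetic-diploid cell
#'
#' Builds two independently amplified haplotype tracks, spikes the cell's
#' truth interval (if any), places gHETs, and assembles the per-bin
#' profile (total observed count and haplotype-aggregated allele counts).
#'
#' @param config `sdx_config`.
#' @param truth `data.table` of truth intervals for this cell (0 or 1
#'   rows).
#' @param cell_id Cell identifier.
#' @param seed Seed for this cell.
#' @return List of class `sdx_cell`: `cell_id`, `bins` (`chrom`,
#'   `start`, `end`, `gc`, `mappable_bp`, `observed`), `snps`, `truth`.
#' @export
simulate_cell <- function(config, truth, cell_id, seed) {
  ta <- simulate_haplotype_depth(config, "A", seed = seed * 2L + 1L)
  tb <- simulate_haplotype_depth(config, "B", seed = seed * 2L + 2L)
  if (nrow(truth) > 0L) {
    sp <- spike_cna(ta, tb, truth[1], config, seed = seed * 2L + 3L)
    ta <- sp$track_a
    tb <- sp$track_b
  }
  snps <- place_ghets(config, ta, tb, truth, seed = seed * 2L + 4L)
  bins <- ta$bins[, .(chrom, start, end, gc)]
  bins[, mappable_bp := end - start]
  bins[, observed := ta$bins$observed + tb$bins$observed]
  structure(list(cell_id = cell_id, bins = bins[], snps = snps,
                 truth = truth), class = "sdx_cell")
}

#' Run a full synthetic-diploid experiment
#'
#' For each row of the CNA plan, simulates `n` mutated cells — each
#' carrying one truth interval of the row's type and size at a uniform
#' start (outside `exclude` regions) — plus one unmutated control cell
#' per condition. Returns an in-memory bundle; when `out_dir` is given,
#' the truth BED and a manifest JSON are written (and per-cell bin/SNP
#' tables too when `write_tables = TRUE`).
#'
#' @param config `sdx_config`.
#' @param out_dir Optional output directory.
#' @param write_tables Also write per-cell bin and SNP TSVs (default
#'   FALSE; the bundle holds them in memory).
#' @return List of class `sdx_bundle`: `cells` (list of `sdx_cell`),
#'   `truth` (`data.table` with `chrom`, `start`, `end`, `cell_id`,
#'   `type`, `haplotype`), `config`, `manifest`.
#' @export
run_sdx_experiment <- function(config, out_dir = NULL,
                               write_tables = FALSE) {
  stopifnot(inherits(config, "sdx_config"))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  plan <- config$cna_plan
  cells <- list()
  truth_all <- list()
  cell_seed <- config$seed
  draw_interval <- function(size) {
    for (try in 1:1000) {
      s <- floor(runif(1, 0, config$genome_length - size))
      e <- s + size
      if (nrow(config$exclude) > 0L &&
          any(pmax(s, config$exclude$start) <
              pmin(e, config$exclude$end))) next
      return(c(s, e))
    }
    stop("could not place truth interval outside exclusion regions")
  }
  conditions <- if (nrow(plan) > 0L) seq_len(nrow(plan)) else integer(0)
  for (ci in conditions) {
    type <- plan$type[ci]
    size <- plan$size[ci]
    n <- plan$n[ci]
    size_label <- formatC(size / 1e3, format = "d")
    for (i in seq_len(n)) {
      iv <- draw_interval(size)
      cid <- sprintf("%s_%skb_c%03d", type, size_label, i)
      tr <- data.table::data.table(
        chrom = config$chrom, start = iv[1], end = iv[2],
        cell_id = cid, type = type, haplotype = "B"
      )
      cell_seed <- cell_seed + 7L
      cells[[cid]] <- simulate_cell(config, tr, cid, seed = cell_seed)
      truth_all[[length(truth_all) + 1L]] <- tr
    }
    cid <- sprintf("%s_%skb_control", type, size_label)
    cell_seed <- cell_seed + 7L
    cells[[cid]] <- simulate_cell(
      config,
      data.table::data.table(chrom = character(), start = numeric(),
                             end = numeric(), cell_id = character(),
                             type = character(), haplotype = character()),
      cid, seed = cell_seed
    )
  }
  if (nrow(plan) == 0L) {
    cell_seed <- cell_seed + 7L
    cells[["control"]] <- simulate_cell(
      config,
      data.table::data.table(chrom = character(), start = numeric(),
                             end = numeric(), cell_id = character(),
                             type = character(), haplotype = character()),
      "control", seed = cell_seed
    )
  }
  truth <- if (length(truth_all) > 0L) {
    data.table::rbindlist(truth_all)
  } else {
    data.table::data.table(chrom = character(), start = numeric(),
                           end = numeric(), cell_id = character(),
                           type = character(), haplotype = character())
  }
  manifest <- list(
    tool = "cnascanner", version = as.character(packageVersion("cnascanner")),
    seed = config$seed, n_cells = length(cells),
    n_truth = nrow(truth),
    conditions = if (nrow(plan) > 0L) {
      sprintf("%s@%skb x%d", plan$type, plan$size / 1e3, plan$n)
    } else character(0)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(truth, file.path(out_dir, "truth.bed"), sep = "\t")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (write_tables) {
      for (cell in cells) {
        data.table::fwrite(cell$bins,
                           file.path(out_dir,
                                     paste0(cell$cell_id, ".bins.tsv")),
                           sep = "\t")
        data.table::fwrite(cell$snps,
                           file.path(out_dir,
                                     paste0(cell$cell_id, ".snps.tsv")),
                           sep = "\t")
      }
    }
  }
  structure(list(cells = cells, truth = truth, config = config,
                 manifest = manifest), class = "sdx_bundle")
}
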