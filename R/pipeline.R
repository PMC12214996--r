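# End-to-end orchestration: preprocess -> (ado) -> normalize -> segment
# -> baf -> call, over an in-memory bundle of cells sharing a bin grid.

#' Pipeline configuration
#'
#' @param bin_size Bin size in bp (must match the input bins).
#' @param lambda Segmentation tuning parameter for the multi-sample BIC.
#'   The default (12) was calibrated once on the simulator's reference
#'   PTA-like condition (pairs of cells at 30x-equivalent depth, 100 kb
#'   bins) and balances private-event sensitivity against
#'   over-segmentation of amplification waviness.
#' @param alpha LOH test significance level.
#' @param edge_band Dropout-peak exclusion band for segment BAF.
#' @param loh_min_bins Minimum informative bins for the LOH test.
#' @param baf_refine Split depth-derived segments at decisive per-cell
#'   BAF changepoints before the LOH test (see
#'   [baf_changepoint_split()]); recovers the edges of copy-neutral LOH,
#'   which leaves no read-depth signature (default TRUE).
#' @param split_penalty Scaled-deviance threshold for the BAF split.
#' @param theta_max Maximum number of whole-genome duplications
#'   considered (candidate thetas are `1:theta_max`).
#' @param state_prior Parsimony prior strength passed to
#'   [infer_cell_cn()].
#' @param max_total Maximum total copy number per segment.
#' @param min_mappable_frac Bin mappability mask threshold.
#' @param balanced_band Exclusive pBAF band defining balanced bins.
#' @param exclude_chroms Chromosomes dropped before analysis (sex
#'   chromosomes by default).
#' @param run_ado Run the ADO bin-size stage (fits the dropout HMM on
#'   the first cell's site BAF and records the recommended bin size in
#'   the manifest; it cannot re-bin already-binned input).
#' @param seed Seed for the stochastic stages (ADO HMM restarts).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_size = 1e5, lambda = 12, alpha = 0.05,
                            edge_band = 0.1, loh_min_bins = 10L,
                            baf_refine = TRUE, split_penalty = 30,
                            theta_max = 2L, state_prior = 2,
                            max_total = 8L,
                            min_mappable_frac = 0.5,
                            balanced_band = c(0.45, 0.55),
                            exclude_chroms = c("chrX", "chrY"),
                            run_ado = FALSE, seed = 1L) {
  stopifnot(lambda > 0, alpha > 0, alpha < 1, theta_max >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# map an allelic state to the event-type vocabulary used by the
# simulator/evaluator; baseline balanced states map to "balanced"
.state_type <- function(cn_a, cn_b, theta) {
  ifelse(cn_a == theta & cn_b == theta, "balanced",
  ifelse(cn_a == 1 & cn_b == 0, "loss_1_0",
  ifelse(cn_a == 2 & cn_b == 1, "gain_2_1",
  ifelse(cn_a == 3 & cn_b == 1, "gain_3_1",
  ifelse(cn_a == 2 & cn_b == 0, "cnloh_2_0",
         sprintf("%d|%d", cn_a, cn_b))))))
}

#' Run the full CNA-calling pipeline on a cell bundle
#'
#' Stages, in order: `preprocess` (chromosome filtering, shared-grid
#' checks), `ado` (optional dropout bin-size recommendation), `normalize`
#' (per-cell GC model and RDR), `segment` (joint multi-cell BIC
#' segmentation of RDR counts), `baf` (per-cell per-segment LOH test and
#' BAF refinement) and `call` (per-cell scale factor and allelic copy
#' numbers; adjacent same-state segments merged into call intervals).
#' Two runs with the same bundle and configuration produce identical
#' output.
#'
#' @param bundle An `sdx_bundle` from [run_sdx_experiment()], or a list
#'   with `cells` = list of objects each having `cell_id`, `bins`
#'   (`chrom`, `start`, `end`, `gc`, `mappable_bp`, `observed`) and
#'   `snps` (`chrom`, `pos`, `depth_a`, `depth_b`).
#' @param config A [pipeline_config()].
#' @return List of class `cnascanner_run`: `calls` (CNA call intervals,
#'   i.e. non-balanced states, BED-style), `segments` (all per-cell
#'   per-segment states), `per_cell` (gamma/theta/ploidy), `manifest`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cells <- bundle$cells
  if (length(cells) == 0L) stop("stage preprocess: no cells in bundle")
  stages <- c("preprocess", "ado", "normalize", "segment", "baf", "call")

  # -- preprocess: drop excluded chromosomes, check the shared grid
  grids <- lapply(cells, function(cell) {
    b <- data.table::as.data.table(cell$bins)
    b <- b[!chrom %in% config$exclude_chroms]
    if (nrow(b) == 0L) stop("stage preprocess: no bins left for cell ",
                            cell$cell_id)
    b
  })
  ref <- grids[[1]][, .(chrom, start, end)]
  for (g in grids) {
    if (!isTRUE(all.equal(ref, g[, .(chrom, start, end)]))) {
      stop("stage preprocess: cells do not share one bin grid")
    }
  }
  span <- ref$end - ref$start
  if (any(abs(span - config$bin_size) > 1e-6 * config$bin_size)) {
    stop("stage preprocess: bin grid does not match config bin_size")
  }
  n_bins <- nrow(ref)

  # -- ado (optional): recommend a minimum bin size from the first cell
  ado_report <- NULL
  if (isTRUE(config$run_ado)) {
    s <- data.table::as.data.table(cells[[1]]$snps)
    s <- s[!chrom %in% config$exclude_chroms & depth_a + depth_b > 0]
    site_baf <- s$depth_b / (s$depth_a + s$depth_b)
    obs <- binarize_baf(site_baf)
    # parameters are learned on a prefix of the sequence (plenty for a
    # 2-state chain); decoding runs over every site
    hmm <- fit_ado_hmm(head(obs, 10000L), seed = config$seed)
    ev <- decode_ado_events(hmm, s$pos, obs, chrom = s$chrom[1])
    sel <- select_bin_size(ev$length)
    ado_report <- list(n_events = nrow(ev), p95 = sel$p95,
                       recommended_bin_size = sel$bin_size)
  }

  # -- normalize: per-cell GC model, expected counts and RDR
  obs_mat <- matrix(0, length(cells), n_bins)
  exp_mat <- matrix(0, length(cells), n_bins)
  gc_factor_list <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    b <- grids[[i]]
    model <- fit_gc_model(b$observed, b$gc)
    b <- compute_rdr(b, model,
                     min_mappable_frac = config$min_mappable_frac)
    obs_mat[i, ] <- b$observed
    exp_mat[i, ] <- b$expected
    gc_factor_list[[i]] <- predict(model, b$gc)
    grids[[i]] <- b
  }

  # -- segment: joint multi-sample BIC on observed vs expected counts
  segm <- joint_segment(obs_mat, exp_mat, lambda = config$lambda,
                        chrom = ref$chrom)
  segs <- segm$segments

  # -- baf + call, per cell
  all_segments <- list()
  all_calls <- list()
  per_cell <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    b <- grids[[i]]
    snps <- data.table::as.data.table(cell$snps)
    snps <- snps[!chrom %in% config$exclude_chroms]
    b <- aggregate_bin_counts(snps, b)
    b[, gc_factor := gc_factor_list[[i]]]
    cell_segs <- segs
    if (isTRUE(config$baf_refine)) {
      # per-cell split of depth-derived segments at BAF changepoints
      # (recovers LOH edges, which leave no read-depth signature)
      near_bal0 <- b$pbaf[is.finite(b$pbaf) & b$pbaf > 0.3 & b$pbaf < 0.7]
      sdb0 <- max(sd(pmin(near_bal0, 1 - near_bal0)), 0.01)
      pieces <- lapply(seq_len(nrow(segs)), function(si) {
        idx <- segs$start_bin[si]:segs$end_bin[si]
        folded <- pmin(b$pbaf[idx], 1 - b$pbaf[idx])
        lens <- baf_changepoint_split(folded, sd_baf_bin = sdb0,
                                      split_penalty = config$split_penalty)
        ends <- segs$start_bin[si] - 1L + cumsum(lens)
        starts <- c(segs$start_bin[si], head(ends, -1L) + 1L)
        data.table::data.table(chrom = segs$chrom[si],
                               start_bin = starts, end_bin = ends)
      })
      cell_segs <- data.table::rbindlist(pieces)
      cell_segs[, n_bins := end_bin - start_bin + 1L]
    }
    seg_rows <- lapply(seq_len(nrow(cell_segs)), function(si) {
      sb <- b[cell_segs$start_bin[si]:cell_segs$end_bin[si]]
      res <- segment_baf(sb, alpha = config$alpha,
                         edge_band = config$edge_band,
                         min_bins = config$loh_min_bins)
      res[, `:=`(chrom = cell_segs$chrom[si],
                 start = sb$start[1], end = sb$end[nrow(sb)],
                 start_bin = cell_segs$start_bin[si],
                 end_bin = cell_segs$end_bin[si],
                 n_bins = cell_segs$n_bins[si],
                 rdr = mean(sb$rdr, na.rm = TRUE))]
      res
    })
    seg_dt <- data.table::rbindlist(seg_rows)

    balanced <- find_balanced_bins(b$pbaf, config$balanced_band[1],
                                   config$balanced_band[2])
    balanced_rdr <- b$rdr[balanced]
    core <- tryCatch(
      balanced[largest_balanced_cluster(balanced_rdr,
                                        t = config$theta_max)],
      error = function(e) balanced
    )
    gammas <- candidate_gammas(b$rdr[core],
                               theta_grid = seq_len(config$theta_max))
    sd_bin <- sd(b$rdr[core], na.rm = TRUE)
    # per-bin folded-BAF scatter of (loosely) balanced bins: captures
    # allelic amplification imbalance, which dwarfs binomial sampling at
    # high depth
    near_bal <- b$pbaf[is.finite(b$pbaf) & b$pbaf > 0.3 & b$pbaf < 0.7]
    sd_baf_bin <- max(sd(pmin(near_bal, 1 - near_bal)), 0.01)
    r <- b$rdr[core]
    r <- r[is.finite(r)]
    rho1 <- if (length(r) > 10) {
      suppressWarnings(stats::cor(r[-1], r[-length(r)]))
    } else 0
    if (!is.finite(rho1)) rho1 <- 0
    rho1 <- min(max(rho1, 0), 0.95)
    ess <- (1 + rho1) / (1 - rho1)
    inf <- infer_cell_cn(seg_dt, gammas, max_total = config$max_total,
                         sd_rdr_bin = sd_bin, sd_baf_bin = sd_baf_bin,
                         ess_factor = ess,
                         state_prior = config$state_prior)
    calls <- inf$calls
    calls[, cell_id := cell$cell_id]
    calls[, type := .state_type(cn_a, cn_b, inf$theta)]
    all_segments[[i]] <- calls
    per_cell[[i]] <- data.table::data.table(
      cell_id = cell$cell_id, gamma = inf$gamma, theta = inf$theta,
      ploidy = sum(calls$total_cn * calls$n_bins) / sum(calls$n_bins)
    )
    # merge adjacent same-state segments into CNA call intervals
    cna <- calls[type != "balanced"]
    if (nrow(cna) > 0L) {
      cna <- cna[order(chrom, start)]
      run_id <- cumsum(
        c(1L, as.integer(cna$chrom[-1] != cna$chrom[-nrow(cna)] |
                           cna$start_bin[-1] != cna$end_bin[-nrow(cna)] + 1L |
                           cna$cn_a[-1] != cna$cn_a[-nrow(cna)] |
                           cna$cn_b[-1] != cna$cn_b[-nrow(cna)]))
      )
      cna[, run := run_id]
      merged <- cna[, .(
        chrom = chrom[1], start = min(start), end = max(end),
        cell_id = cell_id[1], cn_a = cn_a[1], cn_b = cn_b[1],
        total_cn = total_cn[1],
        rdr = sum(rdr * n_bins) / sum(n_bins),
        baf = sum(baf * n_bins) / sum(n_bins),
        loh_flag = any(loh), type = type[1]
      ), by = run][, run := NULL]
      all_calls[[i]] <- merged
    }
  }
  calls <- if (length(all_calls) > 0L) {
    out <- data.table::rbindlist(all_calls)
    out[order(cell_id, chrom, start)]
  } else {
    data.table::data.table(chrom = character(), start = numeric(),
                           end = numeric(), cell_id = character(),
                           cn_a = integer(), cn_b = integer(),
                           total_cn = integer(), rdr = numeric(),
                           baf = numeric(), loh_flag = logical(),
                           type = character())
  }
  manifest <- list(
    tool = "cnascanner",
    version = as.character(packageVersion("cnascanner")),
    stages = stages,
    stage_status = stats::setNames(
      ifelse(stages == "ado" & !isTRUE(config$run_ado),
             "skipped", "executed"), stages),
    parameters = config[setdiff(names(config), "")],
    seed = config$seed,
    n_cells = length(cells), n_bins = n_bins,
    n_segments = nrow(segs),
    ado = ado_report
  )
  structure(list(
    calls = calls,
    segments = data.table::rbindlist(all_segments),
    per_cell = data.table::rbindlist(per_cell),
    segmentation = segm,
    manifest = manifest
  ), class = "cnascanner_run")
}

#' Benchmark the pipeline on a synthetic-diploid experiment
#'
#' Runs the full pipeline for each mutated synthetic cell jointly with
#' its condition's unmutated control cell (mirroring per-individual
#' analysis: each synthetic diploid is assembled from its own pair of
#' haploid sources, so cells from different conditions share no clonal
#' structure), pools the mutated cells' calls, and scores them against
#' the simulator's truth with reciprocal-overlap matching.
#'
#' @param bundle An `sdx_bundle` from [run_sdx_experiment()].
#' @param config A [pipeline_config()].
#' @param min_reciprocal_overlap Matching threshold (default 0.5).
#' @return List: `calls` (pooled calls of mutated cells), `truth`,
#'   `by_type` (named list of [match_calls()] results restricted to
#'   calls/truths of each spiked type).
#' @export
run_sdx_benchmark <- function(bundle, config = pipeline_config(),
                              min_reciprocal_overlap = 0.5) {
  stopifnot(inherits(bundle, "sdx_bundle"))
  truth <- bundle$truth
  ids <- names(bundle$cells)
  mutated <- ids[ids %in% truth$cell_id]
  calls_list <- vector("list", length(mutated))
  for (i in seq_along(mutated)) {
    cid <- mutated[i]
    ctl <- sub("c[0-9]+$", "control", cid)
    group <- if (ctl %in% ids) c(cid, ctl) else cid
    run <- run_pipeline(list(cells = bundle$cells[group]), config)
    calls_list[[i]] <- run$calls[cell_id == cid]
  }
  calls <- data.table::rbindlist(calls_list)
  types <- unique(truth$type)
  by_type <- lapply(stats::setNames(types, types), function(tp) {
    tr <- truth[type == tp]
    match_calls(calls[type == tp & cell_id %in% tr$cell_id], tr,
                min_reciprocal_overlap = min_reciprocal_overlap,
                n_boot = 0L)
  })
  list(calls = calls, truth = truth, by_type = by_type)
}

#' Version and configuration-schema report
#'
#' @param config Optional [pipeline_config()] whose fingerprint is
#'   included.
#' @return Character string (invisibly printed).
#' @export
version_report <- function(config = NULL) {
  ver <- as.character(packageVersion("cnascanner"))
  schema <- "pipeline_config/1"
  line <- sprintf("cnascanner %s (config schema %s)", ver, schema)
  if (!is.null(config)) {
    fp <- paste(names(config), vapply(config, function(x)
      paste(format(x), collapse = ","), character(1)),
      sep = "=", collapse = ";")
    line <- paste0(line, sprintf(" [config fingerprint %08x]",
                                 sum(utf8ToInt(fp) *
                                       seq_along(utf8ToInt(fp))) %%
                                   .Machine$integer.max))
  }
  line
}
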