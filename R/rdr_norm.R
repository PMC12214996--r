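# GC-bias normalisation of binned read counts. A robust loess of count
# versus GC fraction, rescaled so the fitted relative depth averages 1
# over the training bins; the read-depth ratio is observed / expected.

#' Fit a semi-parametric GC bias model to binned counts
#'
#' Fits a robust loess (locally quadratic, symmetric family) of observed
#' bin count against GC fraction and rescales the fit so that the fitted
#' relative depth averages exactly 1 over the training bins. With
#' (near-)constant GC the model degenerates to the global mean with a
#' warning.
#'
#' @param observed Observed per-bin read counts.
#' @param gc Per-bin GC fractions in \[0, 1\].
#' @param span Loess span (default 0.75).
#' @return Object of class `gc_model`.
#' @export
fit_gc_model <- function(observed, gc, span = 0.75) {
  stopifnot(length(observed) == length(gc))
  ok <- is.finite(observed) & is.finite(gc)
  observed <- observed[ok]
  gc <- gc[ok]
  if (length(observed) < 50L) stop("need at least 50 bins to fit GC model")
  if (any(gc < 0 | gc > 1)) stop("gc must be in [0, 1]")
  mean_count <- mean(observed)
  if (sd(gc) < 1e-8) {
    warning("constant GC; GC model degenerates to the global mean")
    model <- list(fit = NULL, norm = 1, mean_count = mean_count,
                  gc_range = range(gc), n = length(observed),
                  resid_var = var(observed))
    return(structure(model, class = "gc_model"))
  }
  fit <- loess(observed ~ gc, span = span, degree = 2,
               family = "symmetric", surface = "direct",
               control = loess.control(iterations = 6))
  fitted_rel <- predict(fit, gc)
  norm <- mean(fitted_rel)
  if (!is.finite(norm) || norm <= 0) stop("degenerate GC fit")
  resid_var <- var(observed - fitted_rel)
  model <- list(fit = fit, norm = norm, mean_count = mean_count,
                gc_range = range(gc), n = length(observed),
                resid_var = resid_var)
  structure(model, class = "gc_model")
}

#' Predict relative expected depth from a GC model
#'
#' Returns the expected depth relative to the cell mean (averages 1 over
#' the training bins). GC values outside the training range are clamped
#' to its edges.
#'
#' @param object A `gc_model`.
#' @param gc GC fractions to predict at.
#' @param ... Unused.
#' @return Numeric vector of relative expected depths (floored at 0.01).
#' @export
predict.gc_model <- function(object, gc, ...) {
  if (is.null(object$fit)) return(rep(1, length(gc)))
  gcc <- pmin(pmax(gc, object$gc_range[1]), object$gc_range[2])
  rel <- predict(object$fit, gcc) / object$norm
  pmax(rel, 0.01)
}

#' Compute read-depth ratios from a GC model
#'
#' Sets `expected = mean_count * f(gc)` where `f` is the fitted relative
#' depth, and `rdr = observed / expected`. Bins with non-positive
#' expected count or with `mappable_bp` below `min_mappable_frac` of the
#' bin span are masked (`rdr = NA`).
#'
#' @param profile `data.table` with `observed`, `gc` and optionally
#'   `start`, `end`, `mappable_bp`.
#' @param model A fitted `gc_model` for the same cell.
#' @param min_mappable_frac Minimum mappable fraction to keep a bin.
#' @return Copy of `profile` with `expected` and `rdr` columns.
#' @export
compute_rdr <- function(profile, model, min_mappable_frac = 0.5) {
  stopifnot(inherits(model, "gc_model"))
  out <- data.table::copy(data.table::as.data.table(profile))
  out[, expected := model$mean_count * predict(model, gc)]
  out[, rdr := observed / expected]
  mask <- !is.finite(out$rdr) | out$expected <= 0
  if (all(c("mappable_bp", "start", "end") %in% names(out))) {
    mask <- mask | out$mappable_bp < min_mappable_frac * (out$end - out$start)
  }
  if (any(mask)) out[mask, rdr := NA_real_]
  out[]
}

#' Serialize a GC model to JSON
#'
#' Stores the relative-depth curve on a GC grid (plus the training
#' summary) so an externally produced expected-count track can be
#' compared with or substituted for it.
#'
#' @param model A `gc_model`.
#' @param path Output JSON path.
#' @export
write_gc_model <- function(model, path) {
  stopifnot(inherits(model, "gc_model"))
  grid <- seq(model$gc_range[1], model$gc_range[2], length.out = 101)
  obj <- list(gc = grid, relative_depth = predict(model, grid),
              mean_count = model$mean_count, n = model$n,
              resid_var = model$resid_var)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
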