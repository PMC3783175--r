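# End-to-end parameter-recovery runs: simulate -> render -> segment ->
# trace -> pooled statistics. These are the package's calibration
# experiments (persistence length and contour length against generator
# ground truth) packaged as single calls.

#' Recover the persistence length through the full imaging pipeline
#'
#' Simulates an ensemble at a known persistence length, renders each chain
#' as an AFM image, traces the backbones, pools the tangent correlation and
#' fits the 2D worm-like-chain decay.
#'
#' @param n_molecules ensemble size.
#' @param lp_nm ground-truth persistence length, nm.
#' @param contour_nm chain contour length, nm.
#' @param closed simulate circular molecules?
#' @param seed master seed.
#' @param step_nm trace resampling step, nm.
#' @param fit_range fit window `(Lmin, Lmax)`, nm.
#' @param height_nm imaged ridge height, nm.
#' @return list with `fit` (a `pl_fit`), `traces`, `n_traced`.
#' @export
recover_persistence_length <- function(n_molecules = 30, lp_nm = 56,
                                       contour_nm = 856, closed = TRUE,
                                       seed = 1L, step_nm = 8,
                                       fit_range = c(8, 120),
                                       height_nm = 0.6) {
  cond <- afm_condition(n_molecules, lp_nm = lp_nm, contour_nm = contour_nm,
                        height_nm = height_nm, closed = closed,
                        label = "lp-recovery")
  ens <- make_condition_ensemble(cond, seed)
  traces <- trace_ensemble(ens, height_nm, step_nm)
  curve <- tangent_correlation(traces, max_sep_nm = fit_range[2] + 2 * step_nm)
  list(fit = fit_persistence_length(curve, fit_range), traces = traces,
       n_traced = length(traces))
}

#' Recover the mean contour length through the full imaging pipeline
#'
#' @inheritParams recover_persistence_length
#' @return list with `stats` (from [contour_length_stats()]), `traces`,
#'   `n_traced`.
#' @export
recover_contour_length <- function(n_molecules = 40, lp_nm = 56,
                                   contour_nm = 328, closed = FALSE,
                                   seed = 1L, step_nm = 8, height_nm = 0.6) {
  cond <- afm_condition(n_molecules, lp_nm = lp_nm, contour_nm = contour_nm,
                        height_nm = height_nm, closed = closed,
                        label = "contour-recovery")
  ens <- make_condition_ensemble(cond, seed)
  traces <- trace_ensemble(ens, height_nm, step_nm)
  list(stats = contour_length_stats(traces), traces = traces,
       n_traced = length(traces))
}

#' Segment and trace every traceable molecule of an ensemble
#'
#' @param ensemble list of `list(polymer, image)` pairs from
#'   [make_condition_ensemble()].
#' @param height_nm imaged single-strand height used for thresholding, nm.
#' @param step_nm trace step, nm.
#' @return list of [trace_result]; molecules whose image segments to a
#'   reject/compact class (or fails to trace) are skipped.
#' @export
trace_ensemble <- function(ensemble, height_nm = 0.6, step_nm = 8) {
  traces <- list()
  for (i in seq_along(ensemble)) {
    regs <- segment_molecules(ensemble[[i]]$image,
                              height_band = c(height_nm, height_nm))
    for (rg in regs) {
      if (!rg$class_hint %in% c("linear", "circular")) next
      tr <- tryCatch(trace_backbone(ensemble[[i]]$image, rg, step_nm),
                     error = function(e) NULL)
      if (!is.null(tr)) {
        tr$molecule_id <- sprintf("mol%03d", i)
        traces[[length(traces) + 1L]] <- tr
      }
    }
  }
  traces
}
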