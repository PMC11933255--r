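#' Pipeline configuration
#'
#' Collects every tunable of the decoding pipeline with the study's
#' defaults: five signal streams, 15 CSP filter pairs (30 rows) per
#' stream on a 31-channel montage giving 150 features, Fisher filtering
#' to 40 features then wrapper selection of 5, 5-fold outer and inner
#' cross-validation, fourteen 200-ms target windows at 100-ms steps over
#' 0-1500 ms, and candidate source windows within 0-600 ms.
#'
#' Reduced settings (fewer channels/streams, smaller `m`, coarser grids)
#' are intended for simulation studies; the defaults match the
#' full-montage analysis.
#'
#' @param streams signal streams to use.
#' @param m CSP filter pairs per stream.
#' @param filter_k Fisher-filter size.
#' @param select_k wrapper-selection size.
#' @param use_sfs logical; `FALSE` replaces the wrapper step by taking the
#'   Fisher top `select_k` (fast screening in simulations).
#' @param outer_folds,inner_folds cross-validation folds.
#' @param alpha_grid,beta_grid RCSP weight grids searched in the inner CV.
#' @param window_span,window_length,window_step target window grid (ms).
#' @param source_window_span span searched for the optimal source window.
#' @param smote_k SMOTE neighborhood size.
#' @param seed integer seed for all fold assignments and resampling.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(streams = c("voltage", "theta", "alpha", "beta",
                                        "gamma"),
                            m = 15, filter_k = 40, select_k = 5,
                            use_sfs = TRUE,
                            outer_folds = 5, inner_folds = 5,
                            alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                            beta_grid = c(0, 0.01, 0.1, 1),
                            window_span = c(0, 1500), window_length = 200,
                            window_step = 100,
                            source_window_span = c(0, 600),
                            smote_k = 5, seed = 1) {
  stopifnot(m >= 1, filter_k >= 1, select_k >= 1, select_k <= filter_k,
            outer_folds >= 2, inner_folds >= 2,
            all(alpha_grid >= 0 & alpha_grid <= 1), all(beta_grid >= 0))
  cfg <- list(streams = streams, m = m, filter_k = filter_k,
              select_k = select_k, use_sfs = use_sfs,
              outer_folds = outer_folds, inner_folds = inner_folds,
              alpha_grid = alpha_grid, beta_grid = beta_grid,
              window_span = window_span, window_length = window_length,
              window_step = window_step,
              window_grid = window_grid(window_span, window_length,
                                        window_step),
              source_window_span = source_window_span,
              smote_k = smote_k, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}
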