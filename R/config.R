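#' Pipeline configuration
#'
#' Every numeric threshold of the pipeline in one nested list, written and
#' read as YAML so that analyses are reproducible from a single file.
#' `default_config()` carries the package defaults: the buoyant-density
#' model constants, the SIP enrichment thresholds (10-fold, 2-fold, 10%
#' dominance), the recruitment thresholds (70% dataset expansion, 50%
#' identity over >= 75 columns), the LCA retention band and report rank, the
#' 1% display cutoff and the 60% prevalence threshold.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    density_model = list(
      rho0 = 1.660, gc_coeff = 0.098, label_shift = 0.036,
      sigma_rho = 0.006, n_fractions = 20L,
      density_range = c(1.66, 1.78), detection_threshold = 0.005
    ),
    sip = list(
      fold_hi = 10.0, fold_lo = 2.0, dominance = 0.10, window_width = 2L
    ),
    recruitment = list(
      dataset_identity = 0.70, read_identity = 0.50, min_len = 75L,
      match = 1L, mismatch = -1L, gap_open = -2L, gap_extend = -1L
    ),
    lca = list(top_percent = 10.0, report_rank = "order"),
    report = list(display_cutoff = 0.01, prevalence_threshold = 0.60),
    seeds = list(community = 1L, amplicon = 2L, reads = 3L, kinetics = 4L)
  )
}

#' @rdname default_config
#' @param config A configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' @rdname default_config
#' @export
validate_config <- function(config) {
  need <- names(default_config())
  miss <- setdiff(need, names(config))
  if (length(miss) > 0) {
    stop(sprintf("config lacks section(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  with(config$sip, stopifnot(fold_hi > 0, fold_lo > 0, fold_lo <= fold_hi,
                             dominance >= 0, dominance <= 1))
  with(config$recruitment, stopifnot(dataset_identity >= 0, dataset_identity <= 1,
                                     read_identity >= 0, read_identity <= 1,
                                     min_len >= 1))
  with(config$density_model, stopifnot(sigma_rho > 0, n_fractions >= 3,
                                       detection_threshold >= 0))
  with(config$report, stopifnot(display_cutoff >= 0, display_cutoff <= 1,
                                prevalence_threshold >= 0, prevalence_threshold <= 1))
  invisible(config)
}
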