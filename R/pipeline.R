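#' Run the whole analysis workflow from a config
#'
#' Automates the import → prepare → measure → fit → collate workflow for a
#' batch of treatments described in a YAML config (or an equivalent nested
#' list). Each treatment is processed independently: a failure in one stage
#' is logged with the stage name and treatment label, and the remaining
#' treatments still run. The run is deterministic given the config (any
#' synthetic treatments carry their own seeds).
#'
#' Config schema (YAML keys):
#' \preformatted{
#' output:
#'   collated: results.csv        # optional; collated CSV written here
#'   plots: plots/                # optional; one fit plot per treatment
#' constants:                     # shared calibration constants
#'   background: 0
#'   fmax: 250                    # needed for preparation: calcium
#'   kd: 400
#'   f0: 1.0                      # or per-treatment f0_region
#' treatments:
#'   - label: control
#'     file: control.csv          # or simulate: {transient_spec() args}
#'     preparation: f_over_f0     # none|background|ratio|calcium|f_over_f0
#'     file_denominator: den.csv  # ratio only
#'     f0_region: [0, 40]         # F/F0 without a shared f0
#'     measure:
#'       baseline_region: [0, 40] # or diastolic: / systolic: levels
#'       peak_region: [40, 120]
#'     fit:
#'       region: [50, 1400]
#'       baseline: 1.0            # Y0 cursor
#'       peak: 1.5                # peak cursor
#'       model: both              # single|double|both
#'       zero_fit_range: false
#'       smart_rc: true
#'       divisors: [2, 2, 0.5, 2]
#' }
#'
#' @param config Path to a YAML config file, or the equivalent list.
#' @param quiet Suppress per-stage log messages?
#' @return The collated tibble, with attributes `errors` (a tibble of
#'   label/stage/message for failed stages) and `exit_code` (0 all clean,
#'   1 partial failures, 2 config error).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  log <- function(...) if (!quiet) message(...)

  cc <- config$constants %||% list()
  constants <- calibration_constants(
    f_background = cc$background %||% 0,
    f_max = cc$fmax %||% cc$f_max,
    kd = cc$kd,
    f0 = cc$f0)

  treatments <- config$treatments %||% list()
  errors <- list()
  records <- list()
  plots_dir <- config$output$plots
  if (!is.null(plots_dir) && !dir.exists(plots_dir)) {
    dir.create(plots_dir, recursive = TRUE)
  }

  for (tr_cfg in treatments) {
    label <- tr_cfg$label %||% "(unlabelled)"
    stage <- "import"
    rec <- tryCatch({
      trace <- pipeline_import(tr_cfg, label)
      stage <- "prepare"
      prep_kind <- tr_cfg$preparation %||% "none"
      prepared <- pipeline_prepare(trace, tr_cfg, prep_kind, constants, label)
      log("[", label, "] prepared as ", signal_kind(prepared))

      stage <- "measure"
      levels <- NULL
      if (!is.null(tr_cfg$measure)) {
        m <- tr_cfg$measure
        levels <- if (!is.null(m$diastolic)) {
          measure_levels_manual(prepared, m$diastolic, m$systolic, label = label)
        } else {
          measure_levels_auto(prepared, as_region(unlist(m$baseline_region)),
                              as_region(unlist(m$peak_region)), label = label)
        }
        log("[", label, "] amplitude = ", signif(levels$amplitude, 6))
      }

      stage <- "fit"
      single <- double <- NULL
      if (!is.null(tr_cfg$fit)) {
        f <- tr_cfg$fit
        model <- f$model %||% "both"
        res <- fit_decay(prepared, as_region(unlist(f$region)),
                         y0_cursor = f$baseline, peak_cursor = f$peak,
                         model = model,
                         zero_fit_range = isTRUE(f$zero_fit_range),
                         smart_rc = f$smart_rc %||% TRUE,
                         divisors = unlist(f$divisors %||% c(2, 2, 0.5, 2)))
        if (model == "both") {
          single <- res$single; double <- res$double
          log("[", label, "] best fit: ", res$best)
        } else if (model == "single") single <- res else double <- res
        if (!is.null(plots_dir)) {
          p <- if (!is.null(single) && !is.null(double)) {
            plot_fit_comparison(list(single = single, double = double))
          } else autoplot(single %||% double)
          ggplot2::ggsave(file.path(plots_dir, paste0(label, "_fit.png")),
                          p, width = 6, height = 4, dpi = 120)
        }
      }

      stage <- "collate"
      collated_record(label, preparation = signal_kind(prepared),
                      levels = levels, single = single, double = double)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- tibble::tibble(
        label = label, stage = stage, message = conditionMessage(e))
      log("[", label, "] FAILED at ", stage, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }

  collated <- collate(records, path = config$output$collated)
  attr(collated, "errors") <- dplyr::bind_rows(errors)
  attr(collated, "exit_code") <- if (length(errors) == 0L) 0L else 1L
  collated
}

pipeline_import <- function(tr_cfg, label) {
  if (!is.null(tr_cfg$simulate)) {
    spec <- do.call(transient_spec, c(tr_cfg$simulate, list(label = label)))
    make_transient(spec)
  } else if (!is.null(tr_cfg$file)) {
    read_trace(tr_cfg$file,
               delim = tr_cfg$delim %||% ",",
               time_units = tr_cfg$time_units %||% "ms",
               label = label)
  } else {
    stop("treatment needs a `file` or a `simulate` block", call. = FALSE)
  }
}

pipeline_prepare <- function(trace, tr_cfg, kind, constants, label) {
  if (kind == "none") return(trace)
  if (kind == "ratio") {
    if (is.null(tr_cfg$file_denominator)) {
      stop("ratio preparation needs `file_denominator`", call. = FALSE)
    }
    den <- read_trace(tr_cfg$file_denominator, delim = tr_cfg$delim %||% ",",
                      time_units = tr_cfg$time_units %||% "ms")
    return(ratio_traces(trace, den,
                        bg_nom = constants$f_background,
                        bg_denom = tr_cfg$background_denominator %||%
                          constants$f_background,
                        label = label))
  }
  f0_region <- if (!is.null(tr_cfg$f0_region)) as_region(unlist(tr_cfg$f0_region))
  prepare_trace(trace,
                kind = switch(kind, background = "background",
                              calcium = "calcium", f_over_f0 = "f_over_f0",
                              stop("unknown preparation kind: ", kind,
                                   call. = FALSE)),
                constants = constants, f0_region = f0_region)
}
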