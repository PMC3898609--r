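#' Assemble one collated record for a treatment
#'
#' Flattens a treatment's measurements — level analysis and/or single and
#' double decay fits — into the one-row wide form used by the collated
#' results table. When both fits are present the best-model indicator is
#' filled in via [indicate_best_fit()].
#'
#' @param label Treatment label.
#' @param preparation Signal kind the analysis was run on (free text, e.g.
#'   `"f_over_f0"`).
#' @param levels Optional `ca_levels` row from the measurement stage.
#' @param single,double Optional `ca_fit` objects from the regression stage.
#' @return A one-row tibble with the stable collated column set.
#' @export
collated_record <- function(label, preparation = NA_character_,
                            levels = NULL, single = NULL, double = NULL) {
  row <- tibble::tibble(
    label = as.character(label),
    preparation = as.character(preparation),
    diastolic = NA_real_, systolic = NA_real_, amplitude = NA_real_,
    levels_flagged = NA,
    single_y0 = NA_real_, single_a = NA_real_, single_k = NA_real_,
    single_ss_reg = NA_real_, single_r2 = NA_real_, single_adj_r2 = NA_real_,
    single_converged = NA,
    double_y0 = NA_real_, double_a1 = NA_real_, double_k1 = NA_real_,
    double_a2 = NA_real_, double_k2 = NA_real_,
    double_ss_reg = NA_real_, double_r2 = NA_real_, double_adj_r2 = NA_real_,
    double_converged = NA,
    best_model = NA_character_)
  if (!is.null(levels)) {
    row$diastolic <- levels$diastolic
    row$systolic <- levels$systolic
    row$amplitude <- levels$amplitude
    row$levels_flagged <- levels$flagged
  }
  if (!is.null(single)) {
    stopifnot(single$model == "single")
    cf <- single$coefficients
    row$single_y0 <- cf[["y0"]]; row$single_a <- cf[["a"]]
    row$single_k <- cf[["k"]]
    row$single_ss_reg <- single$ss_reg
    row$single_r2 <- single$r_squared
    row$single_adj_r2 <- single$adjusted_r_squared
    row$single_converged <- single$converged
  }
  if (!is.null(double)) {
    stopifnot(double$model == "double")
    cf <- double$coefficients
    row$double_y0 <- cf[["y0"]]
    row$double_a1 <- cf[["a1"]]; row$double_k1 <- cf[["k1"]]
    row$double_a2 <- cf[["a2"]]; row$double_k2 <- cf[["k2"]]
    row$double_ss_reg <- double$ss_reg
    row$double_r2 <- double$r_squared
    row$double_adj_r2 <- double$adjusted_r_squared
    row$double_converged <- double$converged
  }
  # best-model verdict only when both fits exist for the label
  if (!is.null(single) && !is.null(double)) {
    row$best_model <- indicate_best_fit(single, double)
  }
  row
}

collated_columns <- function() names(collated_record("x"))

#' Collate treatment records into the results table
#'
#' Merges records into one row per treatment label. Within a label the
#' latest non-missing value of each column wins: level measurements and fit
#' results sent separately land in the same row, and re-sending after
#' re-analysis overwrites the earlier values, as does re-running against an
#' existing collated file on disk. The column order is stable across runs.
#'
#' @param records A list of one-row records from [collated_record()] (or a
#'   data frame of them). May be empty.
#' @param path Optional CSV path. If the file exists its rows are loaded
#'   first (so new records update it); the merged table is then written
#'   back.
#' @return The collated tibble, one row per label.
#' @examples
#' tr <- ca_trace(0:9, rep(1, 10))
#' r1 <- collated_record("control",
#'                       levels = measure_levels_manual(tr, 1, 1.5))
#' collate(list(r1))
#' @export
collate <- function(records, path = NULL) {
  if (is.data.frame(records)) records <- list(records)
  rows <- dplyr::bind_rows(records)
  if (nrow(rows) > 0 && !all(collated_columns() %in% names(rows))) {
    stop("records do not share the collated schema; build them with ",
         "collated_record()", call. = FALSE)
  }
  existing <- NULL
  if (!is.null(path) && file.exists(path)) existing <- read_collated(path)
  out <- dplyr::bind_rows(existing, rows)
  if (nrow(out) > 0) {
    # one row per label; for each column the latest non-missing value wins,
    # so level and fit records sent separately merge into the same row and
    # re-analysis overwrites earlier values
    last_seen <- function(x) {
      v <- x[!is.na(x)]
      if (length(v)) v[length(v)] else x[length(x)]
    }
    out <- out |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), last_seen),
                       .groups = "drop")
    out <- out[collated_columns()]
  } else {
    out <- collated_record("drop")[0, ]
  }
  if (!is.null(path)) write_collated(out, path)
  out
}

#' Read and write the collated results CSV
#'
#' @param path CSV path.
#' @return `read_collated()` returns the collated tibble.
#' @export
read_collated <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    label = readr::col_character(),
                    preparation = readr::col_character(),
                    best_model = readr::col_character(),
                    levels_flagged = readr::col_logical(),
                    single_converged = readr::col_logical(),
                    double_converged = readr::col_logical(),
                    .default = readr::col_double()))
}

#' @rdname read_collated
#' @param collated A collated tibble.
#' @export
write_collated <- function(collated, path) {
  readr::write_csv(collated, path)
  invisible(path)
}
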