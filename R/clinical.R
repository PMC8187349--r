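#' Percent delta change between cohort means
#'
#' The delta change of a circulating analyte is the percent change of the
#' cohort mean between baseline and follow-up,
#' `100 * (followup - baseline) / baseline`, rounded half-away-from-zero to
#' the nearest integer percent (so -14.1 reports as -14 and -16.5 as -17).
#'
#' @param baseline_mean,followup_mean Cohort mean concentrations
#'   (baseline > 0). Vectorised.
#' @return Integer percent change(s).
#' @examples
#' delta_change(290, 249) # -14
#' delta_change(313, 259) # -17
#' @export
delta_change <- function(baseline_mean, followup_mean) {
  if (any(!is.finite(baseline_mean)) || any(baseline_mean <= 0)) {
    stop("baseline mean must be positive", call. = FALSE)
  }
  pct <- 100 * (followup_mean - baseline_mean) / baseline_mean
  round_half_away(pct)
}

# round() in R rounds half to even; printed integer percents use
# half-away-from-zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Assemble a bioflag measurement panel
#'
#' @param measurements Long-format data frame with columns `patient_id`,
#'   `analyte`, `timepoint` and `concentration` (non-negative).
#'   `timepoint` must take exactly two values: `baseline_label` and
#'   `followup_label`.
#' @param metadata Data frame with columns `analyte`, `range_min`,
#'   `range_max` and optionally `units` and `sensitivity`, declaring each
#'   assay's dynamic range. May be `NULL` if [range_check()] is not needed.
#' @param baseline_label,followup_label Timepoint labels.
#' @return An object of class `bioflag_panel`.
#' @export
bioflag_panel <- function(measurements, metadata = NULL,
                          baseline_label = "baseline", followup_label = "month12") {
  measurements <- tibble::as_tibble(measurements)
  need <- c("patient_id", "analyte", "timepoint", "concentration")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  bad_tp <- setdiff(unique(measurements$timepoint), c(baseline_label, followup_label))
  if (length(bad_tp)) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(measurements$concentration < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    if (!all(c("analyte", "range_min", "range_max") %in% names(metadata))) {
      stop("metadata must have columns analyte, range_min, range_max",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      measurements = measurements, metadata = metadata,
      baseline_label = baseline_label, followup_label = followup_label
    ),
    class = "bioflag_panel"
  )
}

#' @export
print.bioflag_panel <- function(x, ...) {
  cat("<bioflag_panel> ", length(unique(x$measurements$analyte)), " analyte(s), ",
    length(unique(x$measurements$patient_id)), " patient(s), timepoints ",
    x$baseline_label, "/", x$followup_label, "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a bioflag panel from CSV plus a YAML metadata file
#'
#' The CSV is long format (`patient_id`, `analyte`, `timepoint`,
#' `concentration`). The YAML maps analyte names to entries with
#' `range_min`, `range_max` and optionally `units` and `sensitivity`.
#'
#' @param csv_path Measurement CSV path.
#' @param yaml_path Optional metadata YAML path.
#' @inheritParams bioflag_panel
#' @return A [bioflag_panel()].
#' @export
read_bioflag_panel <- function(csv_path, yaml_path = NULL,
                               baseline_label = "baseline",
                               followup_label = "month12") {
  meas <- readr::read_csv(csv_path, col_types = readr::cols(
    patient_id = readr::col_character(),
    analyte = readr::col_character(),
    timepoint = readr::col_character(),
    concentration = readr::col_double()
  ))
  metadata <- NULL
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    metadata <- purrr::imap(y, function(entry, analyte) {
      tibble::tibble(
        analyte = analyte,
        range_min = entry$range_min, range_max = entry$range_max,
        units = entry$units %||% NA_character_,
        sensitivity = entry$sensitivity %||% NA_real_
      )
    }) |> dplyr::bind_rows()
  }
  bioflag_panel(meas, metadata, baseline_label, followup_label)
}

#' Summarise a bioflag panel per analyte and timepoint
#'
#' Computes mean, SD, SEM (SD / sqrt(n)) and n per analyte and timepoint
#' over pairwise-complete patients (patients missing either timepoint are
#' excluded from that analyte, with the excluded count reported), plus the
#' delta change of cohort means and, as a secondary column, the mean of
#' per-patient percent changes.
#'
#' @param panel A [bioflag_panel()].
#' @return A tibble of class `panel_summary` with one row per analyte:
#'   `analyte`, `n`, `n_excluded`, `mean_baseline`, `sd_baseline`,
#'   `sem_baseline`, `mean_followup`, `sd_followup`, `sem_followup`,
#'   `delta_percent` (integer, delta of means) and
#'   `mean_patient_delta_percent`.
#' @export
summarize_panel <- function(panel) {
  stopifnot(inherits(panel, "bioflag_panel"))
  wide <- panel$measurements |>
    dplyr::filter(!is.na(.data$concentration)) |>
    tidyr::pivot_wider(
      id_cols = c("analyte", "patient_id"),
      names_from = "timepoint", values_from = "concentration"
    )
  for (lbl in c(panel$baseline_label, panel$followup_label)) {
    if (!lbl %in% names(wide)) wide[[lbl]] <- NA_real_
  }
  b <- panel$baseline_label
  f <- panel$followup_label
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x) # singleton cohort: SD 0
  out <- wide |>
    dplyr::mutate(complete = !is.na(.data[[b]]) & !is.na(.data[[f]])) |>
    dplyr::summarise(
      n = sum(.data$complete),
      n_excluded = sum(!.data$complete),
      mean_baseline = mean(.data[[b]][.data$complete]),
      sd_baseline = sd0(.data[[b]][.data$complete]),
      sem_baseline = .data$sd_baseline / sqrt(.data$n),
      mean_followup = mean(.data[[f]][.data$complete]),
      sd_followup = sd0(.data[[f]][.data$complete]),
      sem_followup = .data$sd_followup / sqrt(.data$n),
      mean_patient_delta_percent = mean(
        100 * (.data[[f]][.data$complete] - .data[[b]][.data$complete]) /
          .data[[b]][.data$complete]
      ),
      .by = "analyte"
    )
  empty <- out$n == 0
  if (any(empty)) {
    warning("analyte(s) with no complete baseline/follow-up pair excluded: ",
      paste(out$analyte[empty], collapse = ", "),
      call. = FALSE
    )
    out <- out[!empty, ]
  }
  out$delta_percent <- delta_change(out$mean_baseline, out$mean_followup)
  out <- dplyr::relocate(out, "delta_percent", .before = "mean_patient_delta_percent")
  class(out) <- c("panel_summary", class(out))
  out
}

#' Flag measurements against declared assay ranges
#'
#' @param panel A [bioflag_panel()] with range metadata.
#' @return The measurement tibble with an added `range_flag` column:
#'   `"below-range"`, `"in-range"` or `"above-range"`.
#' @export
range_check <- function(panel) {
  stopifnot(inherits(panel, "bioflag_panel"))
  if (is.null(panel$metadata)) {
    stop("panel has no range metadata", call. = FALSE)
  }
  missing_meta <- setdiff(unique(panel$measurements$analyte), panel$metadata$analyte)
  if (length(missing_meta)) {
    stop("no range metadata for analyte(s): ",
      paste(missing_meta, collapse = ", "),
      call. = FALSE
    )
  }
  panel$measurements |>
    dplyr::left_join(
      dplyr::select(panel$metadata, "analyte", "range_min", "range_max"),
      by = "analyte"
    ) |>
    dplyr::mutate(
      range_flag = dplyr::case_when(
        .data$concentration < .data$range_min ~ "below-range",
        .data$concentration > .data$range_max ~ "above-range",
        TRUE ~ "in-range"
      )
    ) |>
    dplyr::select(-"range_min", -"range_max")
}
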