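#' Phenotype quality control for longitudinal body weights
#'
#' Three screens, applied in a fixed order by [qc_phenotypes()]:
#' 1. [mask_outliers_3sd()] — at each time point, records deviating by more
#'    than three standard deviations from that time point's mean are set
#'    missing (mean/SD computed once, before any masking);
#' 2. [enforce_decrease_rule()] — body weight may decrease by less than 5%
#'    between consecutive records; a larger drop sets the later record
#'    missing (comparison is against the nearest earlier surviving record);
#' 3. [drop_high_missing_individuals()] — individuals with more than two
#'    missing values over the schedule are removed entirely.
#'
#' Screens only mask or drop; no surviving weight is ever altered. Each
#' function returns the phenotype tibble with its report appended to the
#' `qc_reports` attribute (retrieve with [qc_report()]).
#'
#' @param phenotypes Long tibble with columns `individual_id`, `day`,
#'   `weight_g` (NA = missing) and optionally `sex`; at most one record per
#'   (individual, day).
#' @param schedule The declared weighing schedule; defaults to the days
#'   present in the data. Used to count missing values per individual.
#' @return The cleaned phenotype tibble (same columns), with attribute
#'   `qc_reports`.
#' @name phenotype_qc
#' @examples
#' ph <- tibble::tibble(individual_id = rep("a", 3), day = c(35, 42, 49),
#'                      weight_g = c(1000, 940, 980))
#' cleaned <- enforce_decrease_rule(ph)  # 940 is a 6% drop -> masked
#' qc_report(cleaned)
NULL

check_phenotypes <- function(phenotypes) {
  need <- c("individual_id", "day", "weight_g")
  if (!all(need %in% names(phenotypes))) {
    abort("`phenotypes` needs columns individual_id, day, weight_g.")
  }
  dup <- phenotypes |> dplyr::count(.data$individual_id, .data$day) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) abort("At most one record per (individual, day).")
  if (any(phenotypes$weight_g <= 0, na.rm = TRUE)) {
    abort("Non-missing weights must be positive.")
  }
  invisible(phenotypes)
}

append_report <- function(phenotypes, name, report) {
  reps <- attr(phenotypes, "qc_reports") %||% list()
  reps[[name]] <- report
  attr(phenotypes, "qc_reports") <- reps
  phenotypes
}

#' Retrieve quality-control reports attached by the QC screens
#' @param phenotypes A phenotype tibble that passed through one or more QC
#'   screens.
#' @return Named list of report tibbles (one per screen run).
#' @export
qc_report <- function(phenotypes) attr(phenotypes, "qc_reports") %||% list()

#' @rdname phenotype_qc
#' @export
mask_outliers_3sd <- function(phenotypes) {
  check_phenotypes(phenotypes)
  stats <- phenotypes |>
    group_by(.data$day) |>
    summarise(n = sum(!is.na(.data$weight_g)),
              mean = mean(.data$weight_g, na.rm = TRUE),
              sd = sd(.data$weight_g, na.rm = TRUE))
  skipped <- stats$day[stats$n < 2]
  if (length(skipped)) {
    warn(paste0("3-SD rule skipped at day(s) ", paste(skipped, collapse = ", "),
                ": fewer than 2 records."))
  }
  out <- phenotypes |>
    left_join(stats, by = "day") |>
    mutate(mask = .data$n >= 2 & !is.na(.data$weight_g) &
             abs(.data$weight_g - .data$mean) > 3 * .data$sd,
           weight_g = ifelse(.data$mask, NA_real_, .data$weight_g))
  report <- out |>
    group_by(.data$day) |>
    summarise(n_masked = sum(.data$mask)) |>
    mutate(rule = "outlier_3sd")
  out <- out |> select(-"n", -"mean", -"sd", -"mask")
  attr(out, "qc_reports") <- attr(phenotypes, "qc_reports")
  append_report(out, "outlier_3sd", report)
}

#' @rdname phenotype_qc
#' @export
enforce_decrease_rule <- function(phenotypes) {
  check_phenotypes(phenotypes)
  out <- phenotypes |>
    arrange(.data$individual_id, .data$day) |>
    group_by(.data$individual_id) |>
    mutate(weight_g = {
      w <- .data$weight_g
      last <- NA_real_
      for (k in seq_along(w)) {
        if (is.na(w[k])) next
        if (!is.na(last) && w[k] < 0.95 * last) {
          w[k] <- NA_real_  # >5% drop vs nearest earlier survivor
        } else {
          last <- w[k]
        }
      }
      w
    }) |>
    ungroup()
  n_masked <- sum(is.na(out$weight_g)) - sum(is.na(phenotypes$weight_g))
  report <- tibble(rule = "decrease_5pct", n_masked = n_masked)
  attr(out, "qc_reports") <- attr(phenotypes, "qc_reports")
  append_report(out, "decrease_5pct", report)
}

#' @rdname phenotype_qc
#' @export
drop_high_missing_individuals <- function(phenotypes, schedule = NULL) {
  check_phenotypes(phenotypes)
  schedule <- schedule %||% sort(unique(phenotypes$day))
  miss <- phenotypes |>
    filter(.data$day %in% schedule) |>
    group_by(.data$individual_id) |>
    summarise(n_present = sum(!is.na(.data$weight_g))) |>
    mutate(n_missing = length(schedule) - .data$n_present)
  drop_ids <- miss$individual_id[miss$n_missing > 2]
  out <- phenotypes |> filter(!(.data$individual_id %in% drop_ids))
  report <- tibble(rule = "drop_gt2_missing", n_dropped = length(drop_ids),
                   dropped_ids = list(drop_ids))
  attr(out, "qc_reports") <- attr(phenotypes, "qc_reports")
  append_report(out, "drop_gt2_missing", report)
}

#' @rdname phenotype_qc
#' @export
qc_phenotypes <- function(phenotypes, schedule = NULL) {
  phenotypes |>
    mask_outliers_3sd() |>
    enforce_decrease_rule() |>
    drop_high_missing_individuals(schedule = schedule)
}

#' Per-time-point descriptive statistics of surviving records
#'
#' @param phenotypes A phenotype tibble.
#' @return Tibble with day, number of records, min, max, mean and SD of
#'   body weight among non-missing records.
#' @export
describe_weights <- function(phenotypes) {
  check_phenotypes(phenotypes)
  phenotypes |>
    filter(!is.na(.data$weight_g)) |>
    group_by(.data$day) |>
    summarise(n = n(),
              min = min(.data$weight_g), max = max(.data$weight_g),
              mean = mean(.data$weight_g), sd = sd(.data$weight_g))
}
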