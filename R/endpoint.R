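# Half-up rounding: 1.5 -> 2, 2.5 -> 3. Base round() is round-half-even,
# which is NOT what the endpoint definition prescribes.
round_half_up <- function(x) floor(x + 0.5)

#' Pool CTCAE follow-up reports into the binary G2 endpoint
#'
#' Late (6-15 months) and long-term (15-24 months) xerostomia follow-up
#' reports are pooled: reports inside the window (inclusive bounds) are
#' averaged per patient, the mean grade is rounded to the nearest integer
#' with halves rounding up, and the endpoint is positive when the pooled
#' grade is >= 2 (moderate-to-severe xerostomia). Patients with no report
#' inside the window are dropped with a warning rather than an error.
#'
#' @param reports data.frame with columns `patient_id`,
#'   `months_after_rt` (> 0) and `grade` (integer 0-4).
#' @param window_months Inclusive pooling window in months after RT.
#' @return data.frame with one row per labelled patient: `patient_id`,
#'   `pooled_grade`, `label` (1 = grade >= 2), `n_reports_used`.
#' @examples
#' reports <- data.frame(patient_id = c("a", "a", "b"),
#'                       months_after_rt = c(8, 20, 12),
#'                       grade = c(1, 2, 0))
#' pool_reports(reports)  # patient a pools to grade 2 (1.5 rounds up)
#' @export
pool_reports <- function(reports, window_months = c(6, 24)) {
  need <- c("patient_id", "months_after_rt", "grade")
  if (!is.data.frame(reports) || !all(need %in% names(reports)))
    stop("`reports` must have columns patient_id, months_after_rt, grade")
  if (any(!is.finite(reports$months_after_rt)) ||
      any(reports$months_after_rt <= 0))
    stop("`months_after_rt` must be positive")
  if (any(!reports$grade %in% 0:4))
    stop("`grade` must be an integer between 0 and 4")
  if (length(window_months) != 2L || window_months[1] > window_months[2])
    stop("`window_months` must be an increasing pair")

  inside <- reports$months_after_rt >= window_months[1] &
    reports$months_after_rt <= window_months[2]
  kept <- reports[inside, , drop = FALSE]
  dropped <- setdiff(unique(reports$patient_id), unique(kept$patient_id))
  if (length(dropped) > 0L)
    warning("excluded ", length(dropped),
            " patient(s) with no report inside the window: ",
            paste(dropped, collapse = ", "))
  if (nrow(kept) == 0L)
    return(data.frame(patient_id = character(), pooled_grade = integer(),
                      label = integer(), n_reports_used = integer(),
                      stringsAsFactors = FALSE))
  ids <- unique(kept$patient_id)
  pooled <- vapply(ids, function(id) {
    round_half_up(mean(kept$grade[kept$patient_id == id]))
  }, numeric(1))
  data.frame(
    patient_id = ids,
    pooled_grade = as.integer(pooled),
    label = as.integer(pooled >= 2),
    n_reports_used = as.integer(table(kept$patient_id)[ids]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
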