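#' Keep only patients with a minimum number of encounters
#'
#' Cohort construction retains patients with at least `min_visits` medical
#' encounters (default three); all visits of surviving patients are kept.
#' The operation is idempotent.
#'
#' @param visits A visit table (one row per visit) with a `patient_id`
#'   column.
#' @param min_visits Minimum number of visits a patient must have.
#' @return The filtered visit table (same columns).
#' @export
filter_min_encounters <- function(visits, min_visits = 3L) {
  stopifnot(is.data.frame(visits), "patient_id" %in% names(visits))
  if (min_visits < 1L) stop("`min_visits` must be >= 1.", call. = FALSE)
  dplyr::group_by(visits, .data$patient_id) |>
    dplyr::filter(dplyr::n() >= min_visits) |>
    dplyr::ungroup()
}

#' Random, leakage-safe patient-level splits
#'
#' Assigns each patient id to one role. Role sizes are
#' `floor(N * fraction)` with the remainder going to the first role, so the
#' assignment is deterministic in size; membership is randomized by `seed`.
#' Splitting is always by patient id (never by visit) so a patient's visits
#' can never straddle roles.
#'
#' @param patient_ids Vector of unique patient ids.
#' @param fractions Named or unnamed nonnegative numeric vector summing
#'   to 1; names become role labels (defaults `role1`, `role2`, ...).
#' @param seed Integer seed controlling the permutation.
#' @return A tibble with columns `patient_id`, `role` (factor, levels in
#'   the order of `fractions`).
#' @examples
#' assign_splits(paste0("p", 1:10), c(train = 0.8, test = 0.2), seed = 1)
#' @export
assign_splits <- function(patient_ids, fractions, seed = 1L) {
  patient_ids <- unique(patient_ids)
  if (any(fractions < 0)) stop("Fractions must be nonnegative.", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("Fractions must sum to 1 (got ", sum(fractions), ").", call. = FALSE)
  }
  roles <- names(fractions)
  if (is.null(roles)) roles <- paste0("role", seq_along(fractions))
  n <- length(patient_ids)
  sizes <- floor(n * fractions)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  perm <- with_seed_(seed, sample.int(n))
  role <- rep(roles, sizes)
  tibble::tibble(
    patient_id = patient_ids[perm],
    role = factor(role, levels = roles)
  ) |>
    dplyr::arrange(.data$patient_id)
}

#' Derive length of stay in whole days
#'
#' LoS is the difference between discharge and admission dates; a same-day
#' discharge (including emergency visits without admission) is 0 days.
#'
#' @param admit_date,discharge_date `Date` vectors (or coercible).
#' @return Integer vector of nonnegative day counts.
#' @export
derive_los_days <- function(admit_date, discharge_date) {
  admit_date <- as.Date(admit_date)
  discharge_date <- as.Date(discharge_date)
  d <- as.integer(discharge_date - admit_date)
  if (any(d < 0, na.rm = TRUE)) {
    stop("Discharge date precedes admission date.", call. = FALSE)
  }
  d
}

#' Length-of-stay class
#'
#' Bins LoS days into three classes: 0 = discharged the same day,
#' 1 = stay of `lower` to `upper` days (default 1-3), 2 = longer than
#' `upper` days. The classes partition the nonnegative integers.
#'
#' @param los_days Nonnegative integer vector.
#' @param lower,upper Boundaries of the middle class (inclusive).
#' @return Integer vector of classes in `{0, 1, 2}`.
#' @export
los_class <- function(los_days, lower = 1L, upper = 3L) {
  if (any(los_days < 0, na.rm = TRUE)) {
    stop("`los_days` must be nonnegative.", call. = FALSE)
  }
  ifelse(los_days < lower, 0L, ifelse(los_days <= upper, 1L, 2L))
}

#' Serialize a split assignment as two-column delimited text
#'
#' @param splits Tibble from [assign_splits()].
#' @param path File path.
#' @export
write_splits <- function(splits, path) {
  utils::write.table(splits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
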