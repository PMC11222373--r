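#' Configuration for the synthetic linked mother-baby EHR generator
#'
#' The generator emulates the statistical structure a visit-sequence model
#' assumes in pediatric claims data: patients accumulate 1-3 diagnosis
#' codes per visit, codes co-occur within latent disease clusters, the
#' cluster of successive visits follows a Markov chain, ages are
#' nondecreasing, length of stay depends on the visit's cluster through a
#' two-part model (a point mass at zero days for same-day/ER discharges
#' plus a shifted Poisson), and designated codes have gender-skewed
#' prevalence.
#'
#' @param n_patients Number of patients to simulate.
#' @param n_codes Number of distinct sub-chapter codes (drawn from
#'   [default_code_set()]).
#' @param n_clusters Number of latent disease co-occurrence clusters; codes
#'   are assigned to clusters round-robin by vocabulary order.
#' @param cluster_transition Row-stochastic `n_clusters x n_clusters`
#'   matrix governing the latent cluster of successive visits. Default: stay
#'   with probability `0.7`, otherwise move uniformly.
#' @param within_visit_extra_code_prob Probability that a visit carries a
#'   2nd code, and, given a 2nd, a 3rd.
#' @param gender_skew Named numeric vector mapping codes to male:female
#'   prevalence ratios, applied symmetrically (the code's sampling weight
#'   is multiplied by `sqrt(r)` for male patients and divided by `sqrt(r)`
#'   for female patients, then each cluster's distribution is
#'   renormalized, so the realized prevalence ratio is close to, but —
#'   because of renormalization — not exactly, `r`). Default skews the
#'   tuberculosis ("01") and congenital-anomaly ("74") sub-chapters 3:1
#'   toward males.
#' @param los_params Data frame with one row per cluster and columns
#'   `p_zero` (probability of a zero-day stay) and `lambda` (mean of the
#'   shifted Poisson for stays of >= 1 day). Defaults interpolate from
#'   mostly same-day discharges to long stays across clusters.
#' @param visits_dist Probability vector over visit counts `1, 2, ...`.
#'   Default concentrates on 3-7 visits with a tail to 12.
#' @param age_gap_dist List with `values` (years between visits) and
#'   `probs`. First visit is at age 0.
#' @param n_counties Number of counties; zips are synthesized as the county
#'   id plus three random digits (no real geography).
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return A validated list of class `ehr_sim_config`.
#' @export
ehr_sim_config <- function(n_patients,
                           n_codes = 115L,
                           n_clusters = 6L,
                           cluster_transition = NULL,
                           within_visit_extra_code_prob = 0.35,
                           gender_skew = c("01" = 3, "74" = 3),
                           los_params = NULL,
                           visits_dist = NULL,
                           age_gap_dist = NULL,
                           n_counties = 10L,
                           seed = 1L) {
  if (is.null(cluster_transition)) {
    cluster_transition <- matrix(0.3 / max(1, n_clusters - 1),
                                 n_clusters, n_clusters)
    diag(cluster_transition) <- if (n_clusters == 1) 1 else 0.7
  }
  if (is.null(los_params)) {
    los_params <- tibble::tibble(
      p_zero = seq(0.85, 0.10, length.out = n_clusters),
      lambda = seq(0.3, 5.0, length.out = n_clusters)
    )
  }
  if (is.null(visits_dist)) {
    visits_dist <- c(0.08, 0.12, 0.22, 0.18, 0.14, 0.10, 0.07,
                     0.04, 0.02, 0.015, 0.01, 0.005)
    visits_dist <- visits_dist / sum(visits_dist)
  }
  if (is.null(age_gap_dist)) {
    age_gap_dist <- list(values = c(0.25, 0.5, 1, 2, 3),
                         probs = c(0.30, 0.25, 0.25, 0.15, 0.05))
  }
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients), n_codes = as.integer(n_codes),
      n_clusters = as.integer(n_clusters),
      cluster_transition = cluster_transition,
      within_visit_extra_code_prob = within_visit_extra_code_prob,
      gender_skew = gender_skew, los_params = los_params,
      visits_dist = visits_dist, age_gap_dist = age_gap_dist,
      n_counties = as.integer(n_counties), seed = as.integer(seed)
    ),
    class = "ehr_sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_patients >= 1L, "n_patients must be >= 1")
  chk(cfg$n_codes >= 1L, "n_codes must be >= 1")
  chk(cfg$n_clusters >= 1L, "n_clusters must be >= 1")
  chk(cfg$n_counties >= 1L, "n_counties must be >= 1")
  tm <- cfg$cluster_transition
  chk(is.matrix(tm) && all(dim(tm) == cfg$n_clusters),
      "cluster_transition must be an n_clusters x n_clusters matrix")
  if (is.matrix(tm) && all(dim(tm) == cfg$n_clusters)) {
    chk(all(tm >= 0) && all(abs(rowSums(tm) - 1) < 1e-9),
        "cluster_transition rows must be nonnegative and sum to 1")
  }
  p <- cfg$within_visit_extra_code_prob
  chk(p >= 0 && p <= 1, "within_visit_extra_code_prob must lie in [0, 1]")
  chk(all(cfg$gender_skew > 0), "gender_skew ratios must be positive")
  lp <- cfg$los_params
  chk(is.data.frame(lp) && nrow(lp) == cfg$n_clusters &&
        all(c("p_zero", "lambda") %in% names(lp)),
      "los_params must have one row per cluster with columns p_zero, lambda")
  if (is.data.frame(lp) && all(c("p_zero", "lambda") %in% names(lp))) {
    chk(all(lp$p_zero >= 0 & lp$p_zero <= 1) && all(lp$lambda >= 0),
        "los_params: p_zero in [0,1], lambda >= 0")
  }
  chk(all(cfg$visits_dist >= 0) && abs(sum(cfg$visits_dist) - 1) < 1e-9,
      "visits_dist must be a probability vector")
  chk(all(cfg$age_gap_dist$values >= 0) &&
        abs(sum(cfg$age_gap_dist$probs) - 1) < 1e-9,
      "age_gap_dist probs must sum to 1, values nonnegative")
  if (length(problems) > 0) {
    stop("Invalid generator configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(cfg)
}

# Cluster assignment and per-(cluster, gender) emission weights over codes.
# Round-robin assignment; weights decay 1/rank within a cluster. A skew
# ratio r (male:female prevalence) is applied symmetrically — male weight
# times sqrt(r), female weight divided by sqrt(r) — then each per-cluster
# distribution is renormalized at sampling time.
code_emission_weights <- function(cfg) {
  codes <- default_code_set(cfg$n_codes)
  cluster_of <- ((seq_along(codes) - 1L) %% cfg$n_clusters) + 1L
  base <- numeric(length(codes))
  for (k in seq_len(cfg$n_clusters)) {
    idx <- which(cluster_of == k)
    base[idx] <- 1 / seq_along(idx)
  }
  skew <- rep(1, length(codes))
  hit <- match(names(cfg$gender_skew), codes)
  skew[hit[!is.na(hit)]] <- cfg$gender_skew[!is.na(hit)]
  list(codes = codes, cluster_of = cluster_of,
       w_female = base / sqrt(skew), w_male = base * sqrt(skew))
}

#' Simulate a linked mother-baby cohort
#'
#' Draws `n_patients` patients, each with a mother-attribute record and an
#' ordered visit sequence, and returns the two interchange tables described
#' in [ehr_sim_config()]. Identical configurations (including seed) give
#' identical tables.
#'
#' @param config An [ehr_sim_config()].
#' @return A list of class `ehr_cohort` with elements `visits` (tibble:
#'   `patient_id`, `visit_ordinal`, `dx1`, `dx2`, `dx3`, `age_years`,
#'   `county`, `zip`, `los_days`, plus the latent `cluster` for
#'   diagnostics) and `mothers` (tibble keyed by `patient_id` with the
#'   mother/birth attributes, including `baby_gender`).
#' @examples
#' coh <- simulate_cohort(ehr_sim_config(n_patients = 20, seed = 7))
#' head(coh$visits)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed_(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  em <- code_emission_weights(cfg)
  pid <- sprintf("p%06d", seq_len(n))

  mothers <- simulate_mothers(cfg, pid)
  gender <- mothers$baby_gender

  n_visits <- sample.int(length(cfg$visits_dist), n, replace = TRUE,
                         prob = cfg$visits_dist)
  maxT <- max(n_visits)

  # Latent cluster paths (n x maxT), Markov over cluster_transition.
  path <- matrix(0L, n, maxT)
  path[, 1] <- sample.int(cfg$n_clusters, n, replace = TRUE)
  if (maxT > 1) {
    for (t in 2:maxT) {
      prev <- path[, t - 1]
      nxt <- integer(n)
      for (k in seq_len(cfg$n_clusters)) {
        idx <- which(prev == k)
        if (length(idx) > 0) {
          nxt[idx] <- sample.int(cfg$n_clusters, length(idx), replace = TRUE,
                                 prob = cfg$cluster_transition[k, ])
        }
      }
      path[, t] <- nxt
    }
  }

  # Ages: first visit at 0 years, then nondecreasing gaps.
  gaps <- matrix(sample(cfg$age_gap_dist$values, n * maxT, replace = TRUE,
                        prob = cfg$age_gap_dist$probs), n, maxT)
  gaps[, 1] <- 0
  ages <- t(apply(gaps, 1, cumsum))
  if (maxT == 1) ages <- matrix(gaps[, 1], n, 1)

  # Counties: birth county, small per-visit move probability.
  county <- matrix(0L, n, maxT)
  county[, 1] <- mothers$birth_county_id
  if (maxT > 1) {
    for (t in 2:maxT) {
      move <- runif(n) < 0.05
      county[, t] <- ifelse(move, sample.int(cfg$n_counties, n, replace = TRUE),
                            county[, t - 1])
    }
  }

  # Flatten to one row per realized visit.
  keep <- sequence_mask(n_visits, maxT)
  i_pat <- rep(seq_len(n), each = maxT)[keep]
  ordinal <- rep(seq_len(maxT), times = n)[keep]
  v_cluster <- as.vector(t(path))[keep]
  v_age <- as.vector(t(ages))[keep]
  v_county <- as.vector(t(county))[keep]
  v_gender <- gender[i_pat]
  nv <- length(i_pat)

  # Diagnosis codes: 1-3 per visit, drawn from the visit's cluster with
  # gender-skewed weights; duplicate extras within a visit are dropped.
  dx1 <- draw_codes(em, v_cluster, v_gender)
  q <- cfg$within_visit_extra_code_prob
  has2 <- runif(nv) < q
  has3 <- has2 & (runif(nv) < q)
  dx2 <- rep(NA_character_, nv)
  dx3 <- rep(NA_character_, nv)
  dx2[has2] <- draw_codes(em, v_cluster[has2], v_gender[has2])
  dx3[has3] <- draw_codes(em, v_cluster[has3], v_gender[has3])
  dx2[!is.na(dx2) & dx2 == dx1] <- NA_character_
  dup3 <- !is.na(dx3) & (dx3 == dx1 | (!is.na(dx2) & dx3 == dx2))
  dx3[dup3] <- NA_character_
  # keep the code block left-packed (dx2 empty but dx3 set)
  shift <- is.na(dx2) & !is.na(dx3)
  dx2[shift] <- dx3[shift]
  dx3[shift] <- NA_character_

  # Two-part LoS: point mass at zero, else shifted Poisson, per cluster.
  p_zero <- cfg$los_params$p_zero[v_cluster]
  lambda <- cfg$los_params$lambda[v_cluster]
  los <- ifelse(runif(nv) < p_zero, 0L, 1L + rpois(nv, lambda))

  zip_digits <- sprintf("%03d", sample.int(1000, nv, replace = TRUE) - 1L)
  visits <- tibble::tibble(
    patient_id = pid[i_pat],
    visit_ordinal = ordinal,
    dx1 = dx1, dx2 = dx2, dx3 = dx3,
    age_years = v_age,
    county = sprintf("c%02d", v_county),
    zip = sprintf("%02d%s", v_county, zip_digits),
    los_days = as.integer(los),
    cluster = v_cluster
  )
  structure(list(visits = visits, mothers = mothers), class = "ehr_cohort")
}

# Logical mask selecting the first n_visits[i] slots of each row-major
# (n x maxT) grid flattened by patient.
sequence_mask <- function(n_visits, maxT) {
  rep(seq_len(maxT), times = length(n_visits)) <= rep(n_visits, each = maxT)
}

# Vectorized emission sampling grouped by (cluster, gender).
draw_codes <- function(em, cluster, gender) {
  out <- character(length(cluster))
  for (k in sort(unique(cluster))) {
    for (g in c("F", "M")) {
      idx <- which(cluster == k & gender == g)
      if (length(idx) == 0) next
      w <- if (g == "M") em$w_male else em$w_female
      w <- w * (em$cluster_of == k)
      out[idx] <- sample(em$codes, length(idx), replace = TRUE, prob = w)
    }
  }
  out
}

simulate_mothers <- function(cfg, pid) {
  n <- length(pid)
  races <- c("AS_PI", "Bl", "Hisp_Oth", "NAm_EA", "Wh")
  race_probs <- c(0.12, 0.06, 0.40, 0.01, 0.41)
  edu <- c("<HS", "HS", "college", "grad", "unknown")
  edu_probs <- c(0.30, 0.25, 0.30, 0.10, 0.05)
  countries <- c("US", "MX", "CN", "PH", "VN", "other", "unknown")
  country_probs <- c(0.55, 0.25, 0.04, 0.04, 0.02, 0.08, 0.02)
  birth_county_id <- sample.int(cfg$n_counties, n, replace = TRUE)
  month <- sample(c(1:9, NA), n, replace = TRUE,
                  prob = c(0.30, 0.25, 0.15, 0.08, 0.06, 0.05, 0.04, 0.03,
                           0.02, 0.02))
  tibble::tibble(
    patient_id = pid,
    baby_gender = sample(c("F", "M"), n, replace = TRUE),
    baby_race = sample(races, n, replace = TRUE, prob = race_probs),
    mother_race = sample(races, n, replace = TRUE, prob = race_probs),
    mother_education = sample(edu, n, replace = TRUE, prob = edu_probs),
    prenatal_care_month = as.integer(month),
    n_prenatal_visits = rpois(n, 10),
    mother_visits_before = rpois(n, 0.4),
    mother_visits_after = rpois(n, 0.8),
    birth_county_id = birth_county_id,
    birth_county = sprintf("c%02d", birth_county_id),
    birth_zip = sprintf("%02d%03d", birth_county_id,
                        sample.int(1000, n, replace = TRUE) - 1L),
    mother_birth_country = sample(countries, n, replace = TRUE,
                                  prob = country_probs)
  )
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort> ", nrow(x$mothers), " patients, ", nrow(x$visits),
      " visits\n", sep = "")
  invisible(x)
}

#' Summarize a cohort's categorical attributes and histograms
#'
#' @param visits Visit table (columns `patient_id`, `visit_ordinal`, `dx1`,
#'   `dx2`, `dx3`, `los_days`).
#' @param mothers Mother table keyed by `patient_id`.
#' @return A list of class `cohort_summary` with tibbles `attributes`
#'   (attribute, level, n over the categorical mother attributes),
#'   `visit_counts` (visits per patient), `los` (LoS-day histogram), and
#'   `unique_codes` (distinct codes per patient).
#' @export
summarize_cohort <- function(visits, mothers) {
  need_v <- c("patient_id", "visit_ordinal", "dx1", "los_days")
  miss <- setdiff(need_v, names(visits))
  if (length(miss) > 0) {
    stop("Visit table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cat_cols <- intersect(
    c("baby_gender", "baby_race", "mother_race", "mother_education",
      "prenatal_care_month", "birth_county", "mother_birth_country"),
    names(mothers)
  )
  if (!"patient_id" %in% names(mothers)) {
    stop("Mother table is missing column(s): patient_id", call. = FALSE)
  }
  attributes <- purrr::map_dfr(cat_cols, function(col) {
    mothers |>
      dplyr::count(level = as.character(.data[[col]])) |>
      dplyr::mutate(attribute = col, .before = 1)
  })
  visit_counts <- visits |>
    dplyr::count(.data$patient_id, name = "n_visits") |>
    dplyr::count(.data$n_visits, name = "n_patients")
  los <- dplyr::count(visits, .data$los_days, name = "n_visits")
  unique_codes <- visits |>
    tidyr::pivot_longer(dplyr::any_of(c("dx1", "dx2", "dx3")),
                        values_to = "code") |>
    dplyr::filter(!is.na(.data$code)) |>
    dplyr::distinct(.data$patient_id, .data$code) |>
    dplyr::count(.data$patient_id, name = "n_unique_codes") |>
    dplyr::count(.data$n_unique_codes, name = "n_patients")
  structure(list(attributes = attributes, visit_counts = visit_counts,
                 los = los, unique_codes = unique_codes),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$attributes, n = 20)
  invisible(x)
}
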