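#' Generate a synthetic case-control cohort table
#'
#' Draws demographics and clinical scores for a matched case-control design:
#' age and sex are sampled from the same distribution in both groups
#' (uniform age, fixed male fraction), symptom scores are truncated-Poisson
#' counts on 0-9 with patient means well above control means, medication is
#' restricted to patients, and comorbidity counts are Poisson. Deterministic
#' under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` (class `cohort_table`) with columns `subject_id`,
#'   `age`, `sex`, `diagnosis`, `hyperactivity`, `inattention`, `medication`,
#'   `comorbidity`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_c <- config$n_controls
  n_p <- config$n_patients
  n <- n_c + n_p
  with_seed(config$seed, {
    diagnosis <- c(rep("control", n_c), rep("patient", n_p))
    age <- runif(n, config$age_min, config$age_max)
    sex <- ifelse(runif(n) < config$p_male, "male", "female")
    trunc_pois <- function(lambda) pmin(rpois(length(lambda), lambda), 9L)
    lam_h <- ifelse(diagnosis == "patient",
                    config$hyperactivity_means[1], config$hyperactivity_means[2])
    lam_i <- ifelse(diagnosis == "patient",
                    config$inattention_means[1], config$inattention_means[2])
    hyperactivity <- trunc_pois(lam_h)
    inattention <- trunc_pois(lam_i)
    medication <- ifelse(
      diagnosis == "patient" & runif(n) < config$medication_p_patient,
      "yes", "no")
    lam_co <- ifelse(diagnosis == "patient",
                     config$comorbidity_means[1], config$comorbidity_means[2])
    comorbidity <- rpois(n, lam_co)
    out <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, diagnosis = diagnosis,
      hyperactivity = hyperactivity, inattention = inattention,
      medication = medication, comorbidity = comorbidity,
      stringsAsFactors = FALSE)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

validate_cohort <- function(cohort) {
  need <- c("subject_id", "age", "sex", "diagnosis")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop_config("cohort table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$subject_id))
    stop_config("subject_id values are not unique")
  if (!all(cohort$diagnosis %in% c("control", "patient")))
    stop_config("diagnosis must be 'control' or 'patient'")
  if (!all(cohort$sex %in% c("female", "male")))
    stop_config("sex must be 'female' or 'male'")
  invisible(cohort)
}

#' Write / read a cohort covariate table as CSV
#'
#' The on-disk header is
#' `subject_id,age,sex,diagnosis,hyperactivity,inattention,medication,comorbidity`.
#'
#' @param cohort a cohort table.
#' @param path CSV path.
#' @return `read_cohort_csv` returns the cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_config("covariate file not found: %s", path)
  out <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(out)
  class(out) <- c("cohort_table", "data.frame")
  out
}
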