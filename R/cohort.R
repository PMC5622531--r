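# The EHR bundle (five flat tables) and cohort selection: registry members
# unioned with patients meeting the warehouse criteria.

#' Assemble an EHR bundle
#'
#' The cohort substrate: five flat tables with referential integrity (every
#' child row's `patient_id` must exist in `patients`).
#'
#' @param patients Tibble: `patient_id`, `sex` (`female`/`male`/`unknown`),
#'   `age_years`, `registry_member` (logical).
#' @param encounters Tibble: `patient_id`, `date` (Date), `department`,
#'   `setting` (`inpatient`/`outpatient`).
#' @param documents Tibble: `doc_id`, `patient_id`, `date`, `text`,
#'   `doc_type`.
#' @param diagnoses Tibble: `patient_id`, `code` (ICD-10), `date`.
#' @param prescriptions Tibble: `patient_id`, `date`, `code` (ATC).
#' @return An `ehr_bundle` (validated list of tibbles).
#' @export
ehr_bundle <- function(patients, encounters, documents, diagnoses, prescriptions) {
  check_columns(patients, c("patient_id", "sex", "age_years", "registry_member"),
                "patients")
  check_columns(encounters, c("patient_id", "date", "department", "setting"),
                "encounters")
  check_columns(documents, c("doc_id", "patient_id", "date", "text", "doc_type"),
                "documents")
  check_columns(diagnoses, c("patient_id", "code", "date"), "diagnoses")
  check_columns(prescriptions, c("patient_id", "date", "code"), "prescriptions")
  if (anyDuplicated(patients$patient_id) > 0) {
    stop_field("duplicate patient_id in patients table")
  }
  if (any(is.na(documents$text))) {
    stop_field("documents.text must be non-null (empty string allowed)")
  }
  kids <- list(encounters = encounters, documents = documents,
               diagnoses = diagnoses, prescriptions = prescriptions)
  for (nm in names(kids)) {
    orphan <- setdiff(kids[[nm]]$patient_id, patients$patient_id)
    if (length(orphan) > 0) {
      stop_field("%s refers to unknown patient_id '%s'", nm, orphan[1])
    }
  }
  structure(list(patients = as_tibble(patients),
                 encounters = as_tibble(encounters),
                 documents = as_tibble(documents),
                 diagnoses = as_tibble(diagnoses),
                 prescriptions = as_tibble(prescriptions)),
            class = "ehr_bundle")
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat(sprintf(paste0("<ehr_bundle> %d patients, %d encounters, %d documents, ",
                     "%d diagnoses, %d prescriptions\n"),
              nrow(x$patients), nrow(x$encounters), nrow(x$documents),
              nrow(x$diagnoses), nrow(x$prescriptions)))
  invisible(x)
}

#' Read / write an EHR bundle as CSV tables
#'
#' The on-disk form is five CSV files (`patients.csv`, `encounters.csv`,
#' `documents.csv`, `diagnoses.csv`, `prescriptions.csv`) with ISO-8601
#' dates.
#'
#' @param dir Directory holding (or to receive) the five tables.
#' @return For `read_ehr_bundle`, an `ehr_bundle`; `write_ehr_bundle`
#'   returns `dir` invisibly.
#' @export
read_ehr_bundle <- function(dir) {
  rd <- function(f, types) {
    readr::read_csv(file.path(dir, f), col_types = types, progress = FALSE)
  }
  ehr_bundle(
    patients = rd("patients.csv", "ccnl"),
    encounters = rd("encounters.csv", "cDcc"),
    documents = rd("documents.csv", "ccDcc"),
    diagnoses = rd("diagnoses.csv", "ccD"),
    prescriptions = rd("prescriptions.csv", "cDc")
  )
}

#' @rdname read_ehr_bundle
#' @param bundle An `ehr_bundle`.
#' @export
write_ehr_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$patients, file.path(dir, "patients.csv"), progress = FALSE)
  readr::write_csv(bundle$encounters, file.path(dir, "encounters.csv"), progress = FALSE)
  readr::write_csv(bundle$documents, file.path(dir, "documents.csv"), progress = FALSE)
  readr::write_csv(bundle$diagnoses, file.path(dir, "diagnoses.csv"), progress = FALSE)
  readr::write_csv(bundle$prescriptions, file.path(dir, "prescriptions.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Select the study cohort
#'
#' The cohort is the union of (a) registry members and (b) patients from the
#' warehouse satisfying all of: at least one encounter inside the study
#' window; at least one coded diagnosis matching the index-disease ICD
#' pattern; at least one encounter in the index department; and at least one
#' document whose text matches any index term. Registry membership overrides
#' the warehouse criteria.
#'
#' @param bundle An [ehr_bundle()].
#' @param index_icd [icd_pattern()] for the index disease (e.g. `"K90*"`).
#' @param index_terms Tibble of term patterns ([term_pattern()] rows) naming
#'   the index disease in text.
#' @param dept_filter Department label required for at least one encounter.
#' @param window Length-2 Date vector, closed interval.
#' @return Sorted character vector of included patient identifiers.
#' @export
select_cohort <- function(bundle, index_icd, index_terms, dept_filter, window) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  window <- as.Date(window)
  if (length(window) != 2 || any(is.na(window)) || window[1] > window[2]) {
    stop_field("study window must be a valid, non-empty date interval")
  }
  registry <- bundle$patients$patient_id[bundle$patients$registry_member]

  enc <- bundle$encounters
  has_window_enc <- unique(enc$patient_id[enc$date >= window[1] & enc$date <= window[2]])
  has_dept <- unique(enc$patient_id[enc$department == dept_filter])
  has_code <- unique(bundle$diagnoses$patient_id[icd_matches(index_icd,
                                                             bundle$diagnoses$code)])
  folded <- fold_text(bundle$documents$text)
  hit_doc <- rep(FALSE, length(folded))
  for (p in index_terms$pattern) {
    hit_doc <- hit_doc | stringr::str_detect(folded, stringr::regex(p))
  }
  has_doc <- unique(bundle$documents$patient_id[hit_doc])

  cdw <- Reduce(intersect, list(has_window_enc, has_code, has_dept, has_doc))
  sort(union(registry, cdw))
}

#' Summarise a cohort
#'
#' Descriptive statistics of the included patients: size, sex proportions,
#' age mean/SD, per-patient document and encounter medians with
#' interquartile ranges and maxima, follow-up-time strata (span between
#' first and last encounter; one encounter counts as zero follow-up) and
#' strata of distinct non-index ICD-10 codes per patient.
#'
#' @param bundle An [ehr_bundle()].
#' @param cohort Character vector of patient identifiers.
#' @param index_icd Optional [icd_pattern()]; codes matching it are excluded
#'   from the distinct-code count.
#' @return A long tibble with columns `statistic`, `value`.
#' @export
describe_cohort <- function(bundle, cohort, index_icd = NULL) {
  stopifnot(inherits(bundle, "ehr_bundle"), length(cohort) > 0)
  pts <- filter(bundle$patients, .data$patient_id %in% cohort)
  per_patient_count <- function(tbl) {
    counts <- table(factor(tbl$patient_id[tbl$patient_id %in% cohort],
                           levels = cohort))
    as.numeric(counts)
  }
  docs <- per_patient_count(bundle$documents)
  encs <- per_patient_count(bundle$encounters)

  enc <- filter(bundle$encounters, .data$patient_id %in% cohort)
  fup <- enc |>
    group_by(.data$patient_id) |>
    summarise(years = as.numeric(max(.data$date) - min(.data$date)) / 365.25,
              n_enc = n(), .groups = "drop")
  fup_full <- left_join(tibble(patient_id = cohort), fup, by = "patient_id") |>
    mutate(years = ifelse(is.na(.data$years), 0, .data$years),
           n_enc = ifelse(is.na(.data$n_enc), 0L, .data$n_enc))
  fup_strata <- cut(fup_full$years, c(-Inf, 1e-9, 1, 2, 5, Inf),
                    labels = c("0", "0-1", "1-2", "2-5", ">5"))

  dx <- filter(bundle$diagnoses, .data$patient_id %in% cohort)
  if (!is.null(index_icd)) {
    dx <- filter(dx, !icd_matches(index_icd, .data$code))
  }
  ncodes <- dx |>
    distinct(.data$patient_id, code = normalize_icd(.data$code)) |>
    group_by(.data$patient_id) |>
    summarise(n = n(), .groups = "drop")
  ncodes_full <- left_join(tibble(patient_id = cohort), ncodes, by = "patient_id") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  code_strata <- cut(ncodes_full$n, c(-Inf, 0, 1, 5, Inf),
                     labels = c("0", "1", "2-5", ">5"))

  q <- function(x) unname(quantile(x, c(.25, .5, .75)))
  dq <- q(docs); eq <- q(encs)
  stat <- function(nm, v) tibble(statistic = nm, value = v)
  bind_rows(
    stat("n", length(cohort)),
    stat("prop_female", mean(pts$sex == "female")),
    stat("prop_male", mean(pts$sex == "male")),
    stat("age_mean", mean(pts$age_years)),
    stat("age_sd", sd(pts$age_years)),
    stat("documents_median", dq[2]), stat("documents_q1", dq[1]),
    stat("documents_q3", dq[3]), stat("documents_max", max(docs)),
    stat("encounters_median", eq[2]), stat("encounters_q1", eq[1]),
    stat("encounters_q3", eq[3]), stat("encounters_max", max(encs)),
    purrr::imap_dfr(table(fup_strata),
                    function(v, nm) stat(paste0("followup_", nm, "_n"), as.numeric(v))),
    purrr::imap_dfr(table(code_strata),
                    function(v, nm) stat(paste0("distinct_codes_", nm, "_n"), as.numeric(v)))
  )
}
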