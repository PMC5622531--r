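# In-code fixtures shared across test files.

# a small hand-built bundle: 4 patients with known detections
tiny_bundle <- function() {
  patients <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    sex = c("female", "male", "female", "female"),
    age_years = c(40, 55, 33, 61),
    registry_member = c(TRUE, FALSE, FALSE, FALSE)
  )
  encounters <- tibble::tibble(
    patient_id = c("P2", "P2", "P3", "P3", "P4"),
    date = as.Date(c("2005-03-01", "2006-03-01", "2010-06-15", "2010-09-15",
                     "2012-01-10")),
    department = c("gastroenterology", "endocrinology", "gastroenterology",
                   "gastroenterology", "internal_medicine"),
    setting = c("inpatient", "outpatient", "inpatient", "inpatient",
                "outpatient")
  )
  documents <- tibble::tibble(
    doc_id = c("D1", "D2", "D3", "D4"),
    patient_id = c("P2", "P3", "P3", "P4"),
    date = as.Date(c("2005-03-02", "2010-06-16", "2010-09-16", "2012-01-11")),
    text = c("Suivi de maladie cœliaque. Diabète de type 1 connu.",
             "Patient with celiac disease and Hashimoto thyroiditis.",
             "Thyroïdite auto-immune traitée.",
             "Examen normal."),
    doc_type = c("discharge", "letter", "outpatient_report", "letter")
  )
  diagnoses <- tibble::tibble(
    patient_id = c("P2", "P2", "P3", "P4"),
    code = c("K90.0", "E10.1", "K900", "K900"),
    date = as.Date(c("2005-03-01", "2005-03-01", "2010-06-15", "2012-01-10"))
  )
  prescriptions <- tibble::tibble(
    patient_id = c("P2", "P3"),
    date = as.Date(c("2005-03-05", "2010-06-20")),
    code = c("A10AB01", "H03AA01")
  )
  ehr_bundle(patients, encounters, documents, diagnoses, prescriptions)
}

tiny_mappings <- function() {
  dplyr::bind_rows(
    disease_mapping("D003922", "Type 1 diabetes", icd = "E10*", atc = "A10A",
                    terms = list("diab\\w+")),
    disease_mapping("D013967", "Autoimmune thyroiditis", icd = "E063",
                    atc = "H03AA",
                    terms = list("thyroidit\\w+", "hashimoto"))
  )
}

shipped <- function(name) {
  system.file("extdata", name, package = "litcomorbid")
}

study_window <- function() as.Date(c("2000-01-01", "2014-12-31"))
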