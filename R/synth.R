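# Synthetic-data generators: a co-occurrence file with planted signal and
# an EHR bundle with configurable prevalence, per-source sensitivity and
# encounter-timing regularity.

#' Default synthetic disease table
#'
#' One row per panel disease with the generator's study conditions: the
#' published case counts over 741 patients as true prevalences (the disease
#' absent from the prevalence table counts as 0), text detection
#' sensitivity 0.95 for all diseases, ICD sensitivity 0.15, and drug
#' sensitivity 0.08 for the two diseases with a specific drug marker
#' (autoimmune thyroiditis / levothyroxine, type 1 diabetes / insulin).
#' `trigger` is the literal inserted into a document when text detection
#' fires; `icd_code` and `atc_code` are the representative codes written on
#' structured firing.
#'
#' @return A tibble with columns `dui`, `name`, `true_prevalence`,
#'   `p_text`, `p_icd`, `p_drug`, `trigger`, `icd_code`, `atc_code`.
#' @export
synth_disease_defaults <- function() {
  fx <- fixture_tables()
  prev <- fx$prevalence[c("dui", "n_cases")]
  tbl <- left_join(fx$panel[c("dui", "name")], prev, by = "dui") |>
    mutate(n_cases = ifelse(is.na(.data$n_cases), 0L, .data$n_cases),
           true_prevalence = .data$n_cases / fx$n_cohort,
           p_text = 0.95,
           p_icd = 0.15,
           p_drug = ifelse(.data$dui %in% c("D013967", "D003922"), 0.08, 0)) |>
    select(-"n_cases")
  extras <- tibble(
    dui = c("D003922", "D003874", "D013967", "D001172", "D008180", "D009103",
            "D012859", "D000224", "D001171", "D019693", "D006111", "D005922",
            "D009157", "D016884", "D016736"),
    trigger = c("diabète de type 1", "dermatite herpétiforme",
                "thyroïdite de Hashimoto", "polyarthrite rhumatoïde",
                "lupus érythémateux systémique",
                "sclérose en plaques", "syndrome de Sjögren",
                "maladie d'Addison", "arthrite juvénile idiopathique",
                "hépatite auto-immune", "maladie de Basedow",
                "néphropathie à IgA", "myasthénie",
                "polyendocrinopathie auto-immune",
                "syndrome des antiphospholipides"),
    icd_code = c("E10.9", "L13.0", "E06.3", "M06.9", "M32.9", "G35", "M35.0",
                 "E27.1", "M08.9", "K75.4", "E05.0", "N03.30", "G70.0",
                 "E31.9", "D68.6"),
    atc_code = c("A10AB01", NA, "H03AA01", NA, NA, NA, NA, NA, NA, NA, NA,
                 NA, NA, NA, NA)
  )
  left_join(tbl, extras, by = "dui")
}

#' Configuration for the synthetic EHR generator
#'
#' @param n_patients Cohort size (default 741, the study scale).
#' @param seed Mandatory RNG seed; identical configs generate identical
#'   bundles.
#' @param diseases Disease table as in [synth_disease_defaults()].
#' @param registry_fraction Fraction of patients on the index-disease
#'   registry; the rest must satisfy the warehouse criteria to enter the
#'   cohort, so the generator gives them the index code, department and
#'   document.
#' @param encounter_size,encounter_mu Negative-binomial parameters for the
#'   number of encounters beyond the first (defaults give a median around 3).
#' @param regularity Encounter-timing scheme: `clustered` (encounters
#'   arrive in admission-like bursts, the hospital pattern that depresses
#'   the regularity index to the observed ~0.76 level; default), `regular`
#'   (equal spacing) or `jittered` (equal spacing plus noise).
#' @param jitter_sd Noise scale for `jittered`, as a fraction of the mean gap.
#' @param source_correlation Probability that the three detectors share one
#'   latent severity draw instead of firing independently.
#' @param false_positive_rate Per-source firing probability for non-cases
#'   (default 0: the generator plants no false positives).
#' @param p_english Fraction of documents using the English template
#'   (the rest are French-like, exercising accent folding).
#' @param window Study window (closed date interval).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_patients = 741, seed,
                         diseases = synth_disease_defaults(),
                         registry_fraction = 0.6,
                         encounter_size = 2, encounter_mu = 2.5,
                         regularity = c("clustered", "regular", "jittered"),
                         jitter_sd = 0.3,
                         source_correlation = 0,
                         false_positive_rate = 0,
                         p_english = 0.15,
                         window = as.Date(c("2000-01-01", "2014-12-31"))) {
  regularity <- match.arg(regularity)
  if (missing(seed)) stop_field("synth_config requires an explicit seed")
  stopifnot(n_patients >= 1)
  probs <- c(diseases$true_prevalence, diseases$p_text, diseases$p_icd,
             diseases$p_drug, registry_fraction, source_correlation,
             false_positive_rate, p_english)
  if (any(probs < 0 | probs > 1)) {
    stop_field("all probabilities must lie in [0, 1]")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 diseases = diseases, registry_fraction = registry_fraction,
                 encounter_size = encounter_size, encounter_mu = encounter_mu,
                 regularity = regularity, jitter_sd = jitter_sd,
                 source_correlation = source_correlation,
                 false_positive_rate = false_positive_rate,
                 p_english = p_english, window = as.Date(window)),
            class = "synth_config")
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic descriptor co-occurrence file
#'
#' Plants (index, disease) pairs with a configured descending count
#' sequence — by default the published 15-disease ranking — plus decoy
#' descriptors outside the autoimmune subtree whose pair counts may exceed
#' the planted ones, so subtree restriction is actually exercised.
#'
#' @param seed RNG seed.
#' @param planted Tibble `dui`, `name`, `count` of planted partners
#'   (default: the reference panel).
#' @param index_dui Index-disease descriptor.
#' @param n_decoys Number of decoy descriptors (each contributes an
#'   index-decoy pair and some decoy-decoy pairs).
#' @param subtree_root Tree prefix that planted members carry.
#' @return A list: `descriptors` tibble, `records` tibble, and `truth`
#'   (the expected panel, count-descending).
#' @export
generate_cooccurrence <- function(seed, planted = NULL, index_dui = "D002446",
                                  n_decoys = 30, subtree_root = "C20.111") {
  if (is.null(planted)) {
    fx <- fixture_tables()$panel
    planted <- tibble(dui = fx$dui, name = fx$name, count = fx$n_cooccurrence)
  }
  with_preserved_rng(seed, {
    desc_planted <- tibble(
      dui = planted$dui, name = planted$name,
      tree_numbers = purrr::map(seq_len(nrow(planted)),
                                function(i) sprintf("%s.%d", subtree_root, 100 + i)))
    index_desc <- tibble(dui = index_dui, name = "Index disease",
                         tree_numbers = list("C06.405.469.637.250"))
    outside <- c("C10.114", "C06.405", "E01.370", "C14.280", "C04.557")
    decoys <- tibble(
      dui = sprintf("D9%05d", seq_len(n_decoys)),
      name = sprintf("Decoy condition %d", seq_len(n_decoys)),
      tree_numbers = purrr::map(sample(outside, n_decoys, replace = TRUE),
                                function(t) sprintf("%s.%d", t, sample(100:999, 1))))
    descriptors <- bind_rows(index_desc, desc_planted, decoys)

    rec_planted <- tibble(dui_a = index_dui, dui_b = planted$dui,
                          count = as.integer(planted$count))
    rec_decoy <- tibble(dui_a = index_dui, dui_b = decoys$dui,
                        count = as.integer(sample(1:1500, n_decoys, replace = TRUE)))
    n_cross <- min(n_decoys, 10)
    rec_cross <- tibble(dui_a = sample(decoys$dui, n_cross),
                        dui_b = sample(planted$dui, n_cross, replace = TRUE),
                        count = as.integer(sample(1:300, n_cross, replace = TRUE)))
    records <- parse_cooccurrence(bind_rows(rec_planted, rec_decoy, rec_cross))
    truth <- planted |> arrange(desc(.data$count), .data$dui)
    list(descriptors = parse_mesh_descriptors(descriptors),
         records = records, truth = truth)
  })
}

#' Generate a synthetic EHR bundle with known ground truth
#'
#' For each patient and panel disease, case status is drawn
#' Bernoulli(true prevalence); conditional on a case, each source fires
#' with its sensitivity (optionally through a shared latent severity draw):
#' a text firing inserts the disease's trigger term into a generated
#' document, an ICD firing adds a matching coded diagnosis, a drug firing
#' adds a matching prescription. Encounter dates follow the configured
#' regularity scheme inside the study window. Every patient carries the
#' index disease (registry membership or the full warehouse criteria:
#' index code, index-department encounter, index-term document).
#'
#' @param config A [synth_config()].
#' @return A list: `bundle` (an [ehr_bundle()]), `truth` (tibble
#'   `patient_id`, `dui`, `case`, `text_fired`, `icd_fired`, `drug_fired`),
#'   and `config`.
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_preserved_rng(config$seed, generate_bundle_impl(config))
}

generate_bundle_impl <- function(config) {
  n <- config$n_patients
  dz <- config$diseases
  ids <- sprintf("P%05d", seq_len(n))
  window <- config$window
  span_days <- as.numeric(window[2] - window[1])

  patients <- tibble(
    patient_id = ids,
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.736, 0.264)),
    age_years = pmax(18, round(rnorm(n, 42.5, 16.9))),
    registry_member = runif(n) < config$registry_fraction
  )

  # encounters: first date uniform in the window, follow-up span, positions
  n_enc <- 1L + rnbinom(n, size = config$encounter_size, mu = config$encounter_mu)
  fup <- ifelse(n_enc > 1, runif(n, 60, 5000), 0)
  start <- window[1] + floor(runif(n, 0, pmax(1, span_days - fup)))
  pos_list <- lapply(seq_len(n), function(i) {
    k <- n_enc[i]
    if (k == 1) return(0)
    switch(config$regularity,
      regular = seq(0, 1, length.out = k),
      jittered = {
        base <- seq(0, 1, length.out = k)
        if (k > 2) {
          mid <- base[2:(k - 1)] +
            rnorm(k - 2, 0, config$jitter_sd / (k - 1))
          base[2:(k - 1)] <- pmin(pmax(mid, 0), 1)
        }
        sort(base)
      },
      clustered = {
        # encounters arrive in bursts (an admission generates several
        # close-by contacts), which is what depresses regularity in
        # hospital data
        nc <- max(2, min(k, 1 + stats::rpois(1, k / 3)))
        centres <- sort(runif(nc))
        sort(sample(centres, k, replace = TRUE) + runif(k, 0, 0.01))
      }
    )
  })
  enc_pid <- rep(ids, n_enc)
  enc_date <- rep(start, n_enc) + round(unlist(pos_list) * rep(fup, n_enc))
  dept <- sample(c("gastroenterology", "internal_medicine", "endocrinology"),
                 length(enc_pid), replace = TRUE, prob = c(0.6, 0.25, 0.15))
  dept[cumsum(n_enc) - n_enc + 1L] <- "gastroenterology"
  encounters <- tibble(
    patient_id = enc_pid,
    date = as.Date(enc_date, origin = "1970-01-01"),
    department = dept,
    setting = sample(c("inpatient", "outpatient"), length(enc_pid),
                     replace = TRUE, prob = c(0.8, 0.2)))

  # disease truth and per-source firing
  nd <- nrow(dz)
  truth <- tidyr::expand_grid(patient_id = ids, j = seq_len(nd)) |>
    mutate(dui = dz$dui[.data$j],
           case = runif(n * nd) < dz$true_prevalence[.data$j])
  u_common <- runif(n * nd)
  fire <- function(p_source) {
    u <- ifelse(runif(n * nd) < config$source_correlation, u_common,
                runif(n * nd))
    fired_case <- truth$case & u < p_source[truth$j]
    fired_fp <- !truth$case & runif(n * nd) < config$false_positive_rate
    fired_case | fired_fp
  }
  truth$text_fired <- fire(dz$p_text)
  truth$icd_fired <- fire(dz$p_icd)
  truth$drug_fired <- fire(dz$p_drug)

  # anchor clinical events on the patient's first encounter date
  first_date <- start + round(vapply(pos_list, `[`, 0, 1) * fup)
  event_date <- function(pid) first_date[match(pid, ids)]

  # documents: one index-mention report per patient (+ a neutral note),
  # plus one report per text firing
  fr_index <- "Patient suivi dans le service pour une maladie coeliaque confirmée par biopsie."
  en_index <- "Patient followed in the department for biopsy-confirmed celiac disease."
  neutral <- c("Consultation de suivi, examen clinique sans particularité.",
               "Bilan biologique de routine, resultats dans les normes.",
               "Routine follow-up visit, unremarkable clinical examination.")
  use_en <- runif(n) < config$p_english
  base_docs <- tibble(
    doc_id = sprintf("DOCI%05d", seq_len(n)), patient_id = ids,
    date = event_date(ids),
    text = ifelse(use_en, en_index, fr_index),
    doc_type = "discharge")
  neutral_docs <- tibble(
    doc_id = sprintf("DOCN%05d", seq_len(n)), patient_id = ids,
    date = event_date(ids),
    text = sample(neutral, n, replace = TRUE),
    doc_type = "letter")
  text_rows <- filter(truth, .data$text_fired)
  fr_tpl <- "Antecedents notables : %s, suivie conjointement avec la maladie coeliaque."
  en_tpl <- "Relevant history: %s, managed alongside the celiac disease."
  disease_docs <- if (nrow(text_rows) > 0) {
    en <- runif(nrow(text_rows)) < config$p_english
    tibble(
      doc_id = sprintf("DOCD%06d", seq_len(nrow(text_rows))),
      patient_id = text_rows$patient_id,
      date = event_date(text_rows$patient_id),
      text = sprintf(ifelse(en, en_tpl, fr_tpl), dz$trigger[text_rows$j]),
      doc_type = "outpatient_report")
  } else NULL
  documents <- bind_rows(base_docs, neutral_docs, disease_docs)

  # diagnoses: index code for everyone (harmless for registry members,
  # required for warehouse inclusion), plus disease codes on ICD firing
  dx_index <- tibble(patient_id = ids, code = "K900", date = event_date(ids))
  icd_rows <- filter(truth, .data$icd_fired)
  dx_disease <- if (nrow(icd_rows) > 0) {
    tibble(patient_id = icd_rows$patient_id,
           code = dz$icd_code[icd_rows$j],
           date = event_date(icd_rows$patient_id))
  } else NULL
  diagnoses <- bind_rows(dx_index, dx_disease)

  drug_rows <- filter(truth, .data$drug_fired, !is.na(dz$atc_code[.data$j]))
  prescriptions <- if (nrow(drug_rows) > 0) {
    tibble(patient_id = drug_rows$patient_id,
           date = event_date(drug_rows$patient_id),
           code = dz$atc_code[drug_rows$j])
  } else {
    tibble(patient_id = character(), date = as.Date(character()),
           code = character())
  }

  truth_out <- truth |>
    mutate(drug_fired = .data$drug_fired & !is.na(dz$atc_code[.data$j])) |>
    select("patient_id", "dui", "case", "text_fired", "icd_fired", "drug_fired")
  list(bundle = ehr_bundle(patients, encounters, documents, diagnoses,
                           prescriptions),
       truth = truth_out, config = config)
}

#' Index-disease selection patterns used by the generator
#'
#' The ICD pattern and text terms that match what [generate_bundle()]
#' writes for the index disease, for use with [select_cohort()].
#'
#' @return List with elements `icd` ([icd_pattern()]), `terms` (term
#'   tibble) and `department`.
#' @export
synth_index_detectors <- function() {
  list(icd = icd_pattern("K90*"),
       terms = bind_rows(term_pattern("maladie\\s+c\\w?eliaque", label = "celiac (fr)",
                                      anchor = FALSE),
                         term_pattern("celiac\\s+disease", label = "celiac (en)",
                                      anchor = FALSE)),
       department = "gastroenterology")
}
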