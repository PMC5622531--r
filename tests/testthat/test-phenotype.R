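test_that("structured detectors find coded and prescribed cases", {
  b <- tiny_bundle()
  m <- tiny_mappings()
  cohort <- b$patients$patient_id

  icd <- detect_icd_cases(b, m, cohort)
  expect_equal(nrow(icd), 1)
  expect_equal(icd$patient_id, "P2")   # E10.1 under E10*
  expect_equal(icd$dui, "D003922")

  drug <- detect_drug_cases(b, m, cohort)
  expect_equal(drug$dui[drug$patient_id == "P2"], "D003922")   # insulin
  expect_equal(drug$dui[drug$patient_id == "P3"], "D013967")   # levothyroxine

  # empty prescriptions -> empty drug set
  b0 <- ehr_bundle(b$patients, b$encounters, b$documents, b$diagnoses,
                   b$prescriptions[0, ])
  expect_equal(nrow(detect_drug_cases(b0, m, cohort)), 0)

  # one code matching two diseases' patterns yields two pairs
  m2 <- dplyr::bind_rows(m,
    disease_mapping("D999999", "shadow", icd = "E101"))
  icd2 <- detect_icd_cases(b, m2, cohort)
  expect_setequal(icd2$dui[icd2$patient_id == "P2"],
                  c("D003922", "D999999"))
})

test_that("document scanning is accent-folded with verifiable spans", {
  b <- tiny_bundle()
  m <- tiny_mappings()
  matches <- scan_documents(b, m, b$patients$patient_id)

  # French 'Diabète' matches the diab stem; 'Thyroïdite' the thyroidit stem
  expect_true(any(matches$dui == "D003922" & matches$patient_id == "P2"))
  expect_true(any(matches$dui == "D013967" & matches$patient_id == "P3"))

  # snippet equals the folded-document substring at the 0-based half-open span
  folded <- fold_text(b$documents$text)
  names(folded) <- b$documents$doc_id
  for (i in seq_len(nrow(matches))) {
    expect_equal(matches$snippet[i],
                 substr(folded[[matches$doc_id[i]]],
                        matches$start[i] + 1, matches$end[i]))
  }

  # a term occurring twice yields two distinct spans; oracle: all offsets
  b2 <- ehr_bundle(b$patients[1, ],
                   b$encounters[0, ],
                   tibble::tibble(doc_id = "DD", patient_id = "P1",
                                  date = as.Date("2010-01-01"),
                                  text = "hashimoto puis encore hashimoto",
                                  doc_type = "letter"),
                   b$diagnoses[0, ], b$prescriptions[0, ])
  m_thy <- m[m$dui == "D013967", ]
  two <- scan_documents(b2, m_thy, "P1")
  two <- two[two$pattern_label == "hashimoto", ]
  txt <- "hashimoto puis encore hashimoto"
  oracle_starts <- which(vapply(seq_len(nchar(txt)), function(i) {
    substr(txt, i, i + nchar("hashimoto") - 1) == "hashimoto"
  }, logical(1))) - 1L
  expect_equal(sort(two$start), oracle_starts)

  # empty document produces nothing
  expect_equal(nrow(scan_documents(
    ehr_bundle(b$patients[1, ], b$encounters[0, ],
               tibble::tibble(doc_id = "DE", patient_id = "P1",
                              date = as.Date("2010-01-01"), text = "",
                              doc_type = "other"),
               b$diagnoses[0, ], b$prescriptions[0, ]),
    m, "P1")), 0)
})

test_that("fuzzy terms tolerate one edit on word tokens", {
  b <- tiny_bundle()
  mis <- ehr_bundle(b$patients[1, ], b$encounters[0, ],
                    tibble::tibble(doc_id = "DF", patient_id = "P1",
                                   date = as.Date("2010-01-01"),
                                   text = "Syndrome de Sjogrem suspecté.",
                                   doc_type = "letter"),
                    b$diagnoses[0, ], b$prescriptions[0, ])
  m_sjo <- disease_mapping("D012859", "Sjogren",
                           terms = list(list(pattern = "sjogren", fuzzy = TRUE)))
  hits <- scan_documents(mis, m_sjo, "P1")
  expect_true(any(hits$snippet == "sjogrem"))
  # without fuzzy, the misspelling is missed
  m_strict <- disease_mapping("D012859", "Sjogren", terms = list("sjogren"))
  expect_equal(nrow(scan_documents(mis, m_strict, "P1")), 0)
})

test_that("adjudication policies resolve vote patterns as specified", {
  matches <- tibble::tibble(
    doc_id = "X", patient_id = c("P1", "P2", "P3", "P4"),
    dui = "D003922", pattern_label = "diabetes",
    start = 0L, end = 4L, snippet = "diab")
  votes <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3"),
    dui = "D003922",
    reviewer_id = rep(c("R1", "R2"), 3),
    vote = c("approve", "approve", "reject", "reject", "approve", "reject"))

  adj <- adjudicate(matches, votes, "consensus")
  res <- function(p) adj$resolution[adj$patient_id == p]
  expect_equal(res("P1"), "case")         # both approve
  expect_equal(res("P2"), "non_case")     # both reject
  expect_equal(res("P3"), "unresolved")   # mutual disagreement
  expect_equal(res("P4"), "unresolved")   # matched but never voted

  adj2 <- adjudicate(matches, votes, "any_approve")
  expect_equal(adj2$resolution[adj2$patient_id == "P3"], "case")

  adj3 <- adjudicate(matches, votes, "single_reader")
  expect_equal(adj3$resolution[adj3$patient_id == "P3"], "case")  # R1 approved

  # a vote with no underlying match is an integrity error
  bad_votes <- tibble::tibble(patient_id = "P9", dui = "D003922",
                              reviewer_id = "R1", vote = "approve")
  expect_error(adjudicate(matches, bad_votes), "no text match")
})

test_that("source combination is an OR and attribution partitions the cases", {
  cohort <- sprintf("P%02d", 1:20)
  panel <- c("D003922", "D013967")
  icd <- tibble::tibble(patient_id = c("P01", "P02"), dui = "D003922")
  drug <- tibble::tibble(patient_id = c("P02", "P03"), dui = "D003922")
  text <- tibble::tibble(patient_id = c("P03", "P04"), dui = "D003922")
  calls <- combine_sources(icd, drug, text, cohort, panel)

  expect_equal(nrow(calls), 40)  # full grid
  expect_true(all(calls$present == (calls$src_text | calls$src_icd | calls$src_drug)))
  one <- function(p) calls[calls$patient_id == p & calls$dui == "D003922", ]
  expect_equal(one("P01")$sources, "icd")
  expect_equal(one("P02")$sources, "icd+drug")
  expect_equal(one("P03")$sources, "text+drug")
  expect_equal(one("P04")$sources, "text")
  expect_false(one("P05")$present)

  att <- attribute_sources(calls)
  t1d <- att[att$dui == "D003922", ]
  expect_equal(t1d$n_text_only, 1)         # P04
  expect_equal(t1d$n_structured_only, 2)   # P01, P02
  expect_equal(t1d$n_both, 1)              # P03
  expect_equal(t1d$n_total,
               t1d$n_text_only + t1d$n_structured_only + t1d$n_both)
  # zero-case disease: undefined proportions
  thy <- att[att$dui == "D013967", ]
  expect_equal(thy$n_total, 0)
  expect_true(is.na(thy$pct_text_only))
})

test_that("a 3/4/10 source split reproduces the published percentage pattern", {
  cohort <- sprintf("P%02d", 1:30)
  text_only <- sprintf("P%02d", 1:3)
  struct_only <- sprintf("P%02d", 4:7)
  both <- sprintf("P%02d", 8:17)
  icd <- tibble::tibble(patient_id = c(struct_only, both), dui = "D003922")
  text <- tibble::tibble(patient_id = c(text_only, both), dui = "D003922")
  drug <- tibble::tibble(patient_id = character(), dui = character())
  att <- attribute_sources(combine_sources(icd, drug, text, cohort, "D003922"))
  expect_equal(att$n_total, 17)
  expect_equal(round(att$pct_text_only, 1), 17.6)
  expect_equal(round(att$pct_structured_only, 1), 23.5)
  expect_equal(round(att$pct_both, 1), 58.8)
})

test_that("phenotype calls are invariant to event dates (chronic-disease rule)", {
  b <- tiny_bundle()
  m <- tiny_mappings()
  cohort <- b$patients$patient_id
  shift <- function(tbl) dplyr::mutate(tbl, date = date + 3650)
  b2 <- ehr_bundle(b$patients, b$encounters, shift(b$documents),
                   shift(b$diagnoses), shift(b$prescriptions))
  calls1 <- combine_sources(detect_icd_cases(b, m, cohort),
                            detect_drug_cases(b, m, cohort),
                            dplyr::distinct(scan_documents(b, m, cohort),
                                            patient_id, dui),
                            cohort, m$dui)
  calls2 <- combine_sources(detect_icd_cases(b2, m, cohort),
                            detect_drug_cases(b2, m, cohort),
                            dplyr::distinct(scan_documents(b2, m, cohort),
                                            patient_id, dui),
                            cohort, m$dui)
  expect_equal(as.data.frame(calls1), as.data.frame(calls2))
})
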