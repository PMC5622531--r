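test_that("identical configs generate identical bundles", {
  a <- generate_bundle(synth_config(n_patients = 120, seed = 3))
  b <- generate_bundle(synth_config(n_patients = 120, seed = 3))
  expect_identical(a$bundle, b$bundle)
  expect_identical(a$truth, b$truth)
  c <- generate_bundle(synth_config(n_patients = 120, seed = 4))
  expect_false(identical(a$truth$case, c$truth$case))
})

test_that("empirical prevalence converges to the planted prevalence", {
  big <- generate_bundle(synth_config(n_patients = 50000, seed = 2026))
  emp <- big$truth |>
    dplyr::group_by(dui) |>
    dplyr::summarise(p = mean(case))
  tbl <- dplyr::left_join(emp,
                          synth_disease_defaults()[c("dui", "true_prevalence")],
                          by = "dui") |>
    dplyr::filter(true_prevalence > 0)
  se <- sqrt(tbl$true_prevalence * (1 - tbl$true_prevalence) / 50000)
  z <- abs(tbl$p - tbl$true_prevalence) / se
  # simultaneous bound across the panel at family-wise level 1%
  z_crit <- qnorm(1 - 0.01 / (2 * nrow(tbl)))
  expect_true(all(z < z_crit))
})

test_that("generated text firings are always detectable (generator/detector consistency)", {
  m <- read_mapping_config(shipped("mappings.yaml"))
  sim <- generate_bundle(synth_config(n_patients = 300, seed = 17))
  cohort <- sim$bundle$patients$patient_id
  detected <- dplyr::distinct(scan_documents(sim$bundle, m, cohort),
                              patient_id, dui)
  fired <- sim$truth[sim$truth$text_fired, c("patient_id", "dui")]
  # every firing is matched by at least one term pattern of that disease
  expect_equal(nrow(dplyr::anti_join(fired, detected,
                                     by = c("patient_id", "dui"))), 0)
  # and with no false-positive knob, nothing else is matched
  expect_equal(nrow(dplyr::anti_join(detected, fired,
                                     by = c("patient_id", "dui"))), 0)
})

test_that("perfect sensitivities recover the planted cases exactly", {
  m <- read_mapping_config(shipped("mappings.yaml"))
  dz <- synth_disease_defaults()
  dz$p_text <- 1
  dz$p_icd <- 1
  dz$p_drug <- ifelse(is.na(dz$atc_code), 0, 1)
  sim <- generate_bundle(synth_config(n_patients = 400, seed = 29,
                                      diseases = dz))
  cohort <- sim$bundle$patients$patient_id
  calls <- combine_sources(
    detect_icd_cases(sim$bundle, m, cohort),
    detect_drug_cases(sim$bundle, m, cohort),
    dplyr::distinct(scan_documents(sim$bundle, m, cohort), patient_id, dui),
    cohort, m$dui)
  detected <- dplyr::filter(calls, present)[c("patient_id", "dui")]
  truth <- sim$truth[sim$truth$case, c("patient_id", "dui")]
  expect_equal(nrow(dplyr::anti_join(detected, truth,
                                     by = c("patient_id", "dui"))), 0)
  expect_equal(nrow(dplyr::anti_join(truth, detected,
                                     by = c("patient_id", "dui"))), 0)
})

test_that("text-only sensitivities yield pure text-only attribution", {
  m <- read_mapping_config(shipped("mappings.yaml"))
  dz <- synth_disease_defaults()
  dz$p_text <- 1
  dz$p_icd <- 0
  dz$p_drug <- 0
  sim <- generate_bundle(synth_config(n_patients = 400, seed = 31,
                                      diseases = dz))
  cohort <- sim$bundle$patients$patient_id
  calls <- combine_sources(
    detect_icd_cases(sim$bundle, m, cohort),
    detect_drug_cases(sim$bundle, m, cohort),
    dplyr::distinct(scan_documents(sim$bundle, m, cohort), patient_id, dui),
    cohort, m$dui)
  att <- attribute_sources(calls)
  att <- att[att$n_total > 0, ]
  expect_true(all(att$pct_text_only == 100))
  expect_true(all(att$n_structured_only == 0 & att$n_both == 0))
})

test_that("the synthetic co-occurrence file hides the planted panel among decoys", {
  co <- generate_cooccurrence(seed = 99)
  allowed <- mesh_subtree(co$descriptors, "C20.111")
  panel <- rank_comorbidities(co$records, "D002446", allowed, 15)
  expect_equal(panel$dui, co$truth$dui)
  expect_equal(panel$count, co$truth$count)
  # decoys include pair counts above the top planted count
  decoy_counts <- co$records$count[grepl("^D9", co$records$dui_b) |
                                     grepl("^D9", co$records$dui_a)]
  expect_gt(max(decoy_counts), max(co$truth$count))

  # zero decoys and k = planted size: panel is exactly the planted set
  co0 <- generate_cooccurrence(seed = 99, n_decoys = 0)
  p0 <- rank_comorbidities(co0$records, "D002446",
                           mesh_subtree(co0$descriptors, "C20.111"), 15)
  expect_equal(p0$dui, co0$truth$dui)

  # a planted tie at the cut surfaces through the tie rule
  tied <- tibble::tibble(dui = c("D000111", "D000222", "D000333"),
                         name = c("a", "b", "c"), count = c(9L, 5L, 5L))
  cot <- generate_cooccurrence(seed = 1, planted = tied, n_decoys = 5)
  expect_warning(
    pt <- rank_comorbidities(cot$records, "D002446",
                             mesh_subtree(cot$descriptors, "C20.111"), 2),
    "tie")
  expect_equal(nrow(pt), 3)
})

test_that("the generated bundle passes cohort selection wholesale", {
  sim <- generate_bundle(synth_config(n_patients = 150, seed = 8))
  idx <- synth_index_detectors()
  cohort <- select_cohort(sim$bundle, idx$icd, idx$terms, idx$department,
                          as.Date(c("2000-01-01", "2014-12-31")))
  expect_setequal(cohort, sim$bundle$patients$patient_id)
})
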