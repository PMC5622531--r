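# End-to-end orchestration: rank -> map -> phenotype -> stats, with every
# intermediate artifact persisted for auditability.

#' Run the full comorbidity-burden pipeline
#'
#' Executes the workflow stages in order — literature ranking, terminology
#' mapping, cohort selection, per-source phenotyping with optional
#' adjudication, prevalence and burden estimation, source attribution,
#' literature concordance — and persists every intermediate artifact
#' (panel, mapping echo, calls, prevalence, attribution, summary) in the
#' output directory, together with a run log of row counts per stage.
#' Reruns with identical inputs produce identical outputs.
#'
#' @param descriptors Descriptor tibble or path to a descriptor file.
#' @param cooccurrence Co-occurrence tibble or path.
#' @param mappings Mapping tibble or path to the YAML config.
#' @param bundle An [ehr_bundle()] or path to a bundle directory.
#' @param votes Optional vote tibble (`patient_id`, `dui`, `reviewer_id`,
#'   `vote`) or path to the vote CSV; when supplied, text detections are
#'   adjudicated and only resolved cases count.
#' @param index_dui Index-disease descriptor identifier.
#' @param subtree_root Tree-number prefix restricting candidate partners.
#' @param top_k Panel size.
#' @param index_icd Compact ICD pattern string for the index disease.
#' @param index_terms Term tibble for the index disease in text.
#' @param dept_filter Index department label.
#' @param window Study window (length-2 Date).
#' @param policy Adjudication policy, see [adjudicate()].
#' @param alpha Significance level for intervals.
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return A list of stage results: `panel`, `mappings`, `cohort`, `calls`,
#'   `adjudication`, `prevalence`, `attribution`, `burden`, `regularity`,
#'   `concordance`, `summary`.
#' @export
run_pipeline <- function(descriptors, cooccurrence, mappings, bundle,
                         votes = NULL,
                         index_dui = "D002446", subtree_root = "C20.111",
                         top_k = 15, index_icd = "K90*",
                         index_terms = synth_index_detectors()$terms,
                         dept_filter = "gastroenterology",
                         window = as.Date(c("2000-01-01", "2014-12-31")),
                         policy = "consensus", alpha = 0.05,
                         out_dir = NULL) {
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "litcomorbid_stage_error")
    })
  }

  if (is.character(descriptors)) descriptors <- read_mesh_descriptors(descriptors)
  if (is.character(cooccurrence)) cooccurrence <- read_cooccurrence(cooccurrence)
  if (is.character(mappings)) mappings <- read_mapping_config(mappings)
  if (is.character(bundle)) bundle <- read_ehr_bundle(bundle)
  if (is.character(votes)) {
    votes <- readr::read_csv(votes, col_types = "cccc", progress = FALSE)
  }

  panel <- stage("rank", {
    allowed <- mesh_subtree(descriptors, subtree_root)
    rank_comorbidities(cooccurrence, index_dui, allowed, top_k)
  })
  note("rank: %d panel members (top count %s)", nrow(panel),
       if (nrow(panel) > 0) panel$count[1] else "-")

  mappings <- stage("map", {
    m <- semi_join(mappings, as_tibble(panel), by = "dui")
    missing <- setdiff(panel$dui, m$dui)
    if (length(missing) > 0) {
      warn(sprintf("no mapping for panel member(s): %s",
                   paste(missing, collapse = ", ")))
    }
    m
  })
  note("map: %d disease mappings", nrow(mappings))

  cohort <- stage("cohort", {
    select_cohort(bundle, icd_pattern(index_icd), index_terms, dept_filter,
                  window)
  })
  note("cohort: %d patients", length(cohort))

  icd_cases <- stage("phenotype", detect_icd_cases(bundle, mappings, cohort))
  drug_cases <- stage("phenotype", detect_drug_cases(bundle, mappings, cohort))
  matches <- stage("phenotype", scan_documents(bundle, mappings, cohort))
  adjudication <- NULL
  text_cases <- if (!is.null(votes)) {
    adjudication <- stage("adjudicate", adjudicate(matches, votes, policy))
    filter(adjudication, .data$resolution == "case")[c("patient_id", "dui")]
  } else {
    distinct(matches, .data$patient_id, .data$dui)
  }
  calls <- stage("combine",
                 combine_sources(icd_cases, drug_cases, text_cases, cohort,
                                 mappings$dui))
  note("phenotype: %d icd, %d drug, %d text pairs -> %d cases",
       nrow(icd_cases), nrow(drug_cases), nrow(text_cases),
       sum(calls$present))

  prevalence <- stage("stats", {
    counts <- calls |>
      group_by(.data$dui) |>
      summarise(n_cases = sum(.data$present), .groups = "drop")
    prevalence_ci(counts$n_cases, length(cohort), alpha = alpha,
                  dui = counts$dui) |>
      left_join(mappings[c("dui", "name")], by = "dui") |>
      arrange(desc(.data$n_cases), .data$dui)
  })
  attribution <- stage("stats", attribute_sources(calls))
  burden <- stage("stats", burden_summary(calls, alpha = alpha))
  regularity <- stage("stats", sperrin_scores(bundle, cohort))
  concordance <- stage("stats", {
    joined <- left_join(as_tibble(panel)[c("dui", "count")],
                        prevalence[c("dui", "n_cases")], by = "dui") |>
      mutate(n_cases = ifelse(is.na(.data$n_cases), 0L, .data$n_cases))
    if (nrow(joined) >= 3 && length(unique(joined$n_cases)) > 1) {
      spearman_rho(joined$count, joined$n_cases)
    } else NULL
  })

  summary <- list(
    n_cohort = length(cohort),
    n_panel = nrow(panel),
    burden_per_1000 = burden$p_per_1000,
    burden_ci_per_1000 = c(burden$ci_low_per_1000, burden$ci_high_per_1000),
    mean_sperrin_I = if (nrow(regularity) > 0) mean(regularity$I) else NA,
    spearman_rho = if (!is.null(concordance)) concordance$rho else NA,
    n_adjudicated = if (!is.null(adjudication)) nrow(adjudication) else 0L
  )
  note("summary: burden %.1f per 1000, mean I %.3f",
       summary$burden_per_1000, summary$mean_sperrin_I)

  result <- list(panel = panel, mappings = mappings, cohort = cohort,
                 matches = matches, adjudication = adjudication,
                 calls = calls, prevalence = prevalence,
                 attribution = attribution, burden = burden,
                 regularity = regularity, concordance = concordance,
                 summary = summary, log = log_lines)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  invisible(result)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(result$panel), file.path(out_dir, "panel.csv"),
                   progress = FALSE)
  serialize_mappings(result$mappings, file.path(out_dir, "mappings.yaml"))
  readr::write_csv(select(as_tibble(result$calls), "patient_id", "dui",
                          "present", "sources"),
                   file.path(out_dir, "calls.csv"), progress = FALSE)
  readr::write_csv(tidy(result$prevalence), file.path(out_dir, "prevalence.csv"),
                   progress = FALSE)
  readr::write_csv(result$attribution, file.path(out_dir, "attribution.csv"),
                   progress = FALSE)
  if (!is.null(result$adjudication)) {
    readr::write_csv(result$adjudication, file.path(out_dir, "adjudication.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(lapply(result$summary, unname),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  if (nrow(result$matches) > 0) {
    con <- file(file.path(out_dir, "matches.jsonl"), open = "w")
    on.exit(close(con))
    apply_rows <- purrr::transpose(as.list(result$matches))
    writeLines(purrr::map_chr(apply_rows, jsonlite::toJSON, auto_unbox = TRUE),
               con)
  }
  invisible(out_dir)
}
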