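# Per-source disease detection, reviewer adjudication of text candidates,
# OR-combination across sources, and source attribution.

#' Detect cases from coded diagnoses
#'
#' A (patient, disease) pair is detected when the patient carries at least
#' one ICD-10 coded diagnosis matching any of the disease's ICD patterns.
#' Detection is timeless: the studied comorbidities are chronic, so a code
#' at any date suffices.
#'
#' @param bundle An [ehr_bundle()].
#' @param mappings Mapping tibble from [read_mapping_config()].
#' @param cohort Character vector of patient identifiers.
#' @return Tibble with columns `patient_id`, `dui` (one row per detected pair).
#' @export
detect_icd_cases <- function(bundle, mappings, cohort) {
  dx <- filter(bundle$diagnoses, .data$patient_id %in% cohort)
  purrr::pmap_dfr(mappings[c("dui", "icd")], function(dui, icd) {
    hit <- rep(FALSE, nrow(dx))
    for (p in icd) hit <- hit | icd_matches(p, dx$code)
    tibble(patient_id = unique(dx$patient_id[hit]), dui = dui)
  }) |>
    arrange(.data$patient_id, .data$dui)
}

#' Detect cases from drug prescriptions
#'
#' A (patient, disease) pair is detected when the patient has at least one
#' prescription whose ATC code starts with any of the disease's ATC
#' prefixes. Diseases without a specific drug marker are never drug-detected.
#'
#' @inheritParams detect_icd_cases
#' @return Tibble with columns `patient_id`, `dui`.
#' @export
detect_drug_cases <- function(bundle, mappings, cohort) {
  rx <- filter(bundle$prescriptions, .data$patient_id %in% cohort)
  purrr::pmap_dfr(mappings[c("dui", "atc")], function(dui, atc) {
    if (length(atc) == 0 || nrow(rx) == 0) {
      return(tibble(patient_id = character(), dui = character()))
    }
    hit <- rep(FALSE, nrow(rx))
    for (p in atc) hit <- hit | atc_matches(p, rx$code)
    tibble(patient_id = unique(rx$patient_id[hit]), dui = dui)
  }) |>
    arrange(.data$patient_id, .data$dui)
}

#' Scan cohort documents for disease terms
#'
#' Applies every disease's term patterns to every cohort document.
#' Documents and pattern literals are accent-folded and lower-cased before
#' matching, so French text ("diabète") matches ASCII stems. Matches are
#' non-overlapping per pattern; spans are 0-based, half-open character
#' offsets into the folded text, and `snippet` is the folded substring at
#' the span. Terms flagged `fuzzy` additionally match word tokens within
#' edit distance 1 of the term literal.
#'
#' @inheritParams detect_icd_cases
#' @return Tibble of text matches: `doc_id`, `patient_id`, `dui`,
#'   `pattern_label`, `start`, `end`, `snippet`.
#' @export
scan_documents <- function(bundle, mappings, cohort) {
  docs <- filter(bundle$documents, .data$patient_id %in% cohort)
  empty <- tibble(doc_id = character(), patient_id = character(),
                  dui = character(), pattern_label = character(),
                  start = integer(), end = integer(), snippet = character())
  if (nrow(docs) == 0) return(empty)
  folded <- fold_text(docs$text)

  scan_one <- function(dui, terms) {
    if (nrow(terms) == 0) return(empty)
    purrr::pmap_dfr(terms, function(pattern, label, fuzzy) {
      loc <- tryCatch(stringr::str_locate_all(folded, stringr::regex(pattern)),
                      error = function(e) {
                        stop_field("pattern '%s' failed during scan: %s",
                                   pattern, conditionMessage(e))
                      })
      hits <- which(vapply(loc, nrow, 0L) > 0)
      out <- purrr::map_dfr(hits, function(i) {
        m <- loc[[i]]
        tibble(doc_id = docs$doc_id[i], patient_id = docs$patient_id[i],
               dui = dui, pattern_label = label,
               start = m[, 1] - 1L, end = m[, 2],
               snippet = stringr::str_sub(folded[i], m[, 1], m[, 2]))
      })
      if (fuzzy) {
        out <- bind_rows(out, fuzzy_scan(docs, folded, dui, pattern, label))
      }
      out
    })
  }
  res <- purrr::pmap_dfr(mappings[c("dui", "terms")],
                         function(dui, terms) scan_one(dui, terms))
  if (nrow(res) == 0) return(empty)
  res |>
    distinct(.data$doc_id, .data$dui, .data$start, .data$end, .keep_all = TRUE) |>
    arrange(.data$doc_id, .data$dui, .data$start)
}

# approximate token matching: word tokens within edit distance 1 of the
# pattern's literal (only meaningful for plain-word patterns)
fuzzy_scan <- function(docs, folded, dui, pattern, label) {
  literal <- gsub("\\\\b", "", pattern)
  if (!grepl("^[a-z0-9]+$", literal)) return(NULL)  # not a plain word
  # cheap pre-filter: only tokenize documents with an approximate hit
  cand <- which(agrepl(literal, folded, max.distance = 1, fixed = TRUE))
  if (length(cand) == 0) return(NULL)
  locs <- stringr::str_locate_all(folded[cand], "\\b[a-z0-9]+\\b")
  purrr::map_dfr(seq_along(cand), function(ci) {
    i <- cand[ci]
    m <- locs[[ci]]
    if (nrow(m) == 0) return(NULL)
    tok <- stringr::str_sub(folded[i], m[, 1], m[, 2])
    near <- utils::adist(tok, literal) <= 1
    if (!any(near)) return(NULL)
    tibble(doc_id = docs$doc_id[i], patient_id = docs$patient_id[i],
           dui = dui, pattern_label = label,
           start = m[near, 1] - 1L, end = m[near, 2],
           snippet = tok[near])
  })
}

#' Adjudicate text-detected candidates
#'
#' Groups text matches per (patient, disease) item and resolves each item
#' from reviewer votes under a policy: `consensus` (case only when all
#' voting reviewers approve, non-case when all reject, `unresolved` on
#' disagreement — the default, mirroring a two-physician review),
#' `any_approve` (one approval suffices), or `single_reader` (the first
#' reviewer's vote decides). Items without votes stay `unresolved`.
#'
#' @param matches Text matches from [scan_documents()].
#' @param votes Tibble `patient_id`, `dui`, `reviewer_id`,
#'   `vote` (`approve`/`reject`). Votes on pairs without matches are errors.
#' @param policy Adjudication policy.
#' @return Tibble `patient_id`, `dui`, `n_approve`, `n_reject`, `resolution`
#'   (`case` / `non_case` / `unresolved`).
#' @export
adjudicate <- function(matches, votes,
                       policy = c("consensus", "any_approve", "single_reader")) {
  policy <- match.arg(policy)
  items <- distinct(matches, .data$patient_id, .data$dui)
  if (nrow(votes) > 0) {
    bad <- anti_join(distinct(votes, .data$patient_id, .data$dui), items,
                     by = c("patient_id", "dui"))
    if (nrow(bad) > 0) {
      stop_field("vote on (%s, %s) but no text match exists for that pair",
                 bad$patient_id[1], bad$dui[1])
    }
    if (!all(votes$vote %in% c("approve", "reject"))) {
      stop_field("votes must be 'approve' or 'reject'")
    }
  }
  tallied <- votes |>
    group_by(.data$patient_id, .data$dui) |>
    summarise(n_approve = sum(.data$vote == "approve"),
              n_reject = sum(.data$vote == "reject"),
              first_vote = .data$vote[order(.data$reviewer_id)][1],
              .groups = "drop")
  out <- left_join(items, tallied, by = c("patient_id", "dui")) |>
    mutate(n_approve = ifelse(is.na(.data$n_approve), 0L, .data$n_approve),
           n_reject = ifelse(is.na(.data$n_reject), 0L, .data$n_reject))
  out$resolution <- dplyr::case_when(
    out$n_approve + out$n_reject == 0 ~ "unresolved",
    policy == "consensus" & out$n_reject == 0 ~ "case",
    policy == "consensus" & out$n_approve == 0 ~ "non_case",
    policy == "consensus" ~ "unresolved",
    policy == "any_approve" & out$n_approve > 0 ~ "case",
    policy == "any_approve" ~ "non_case",
    policy == "single_reader" & out$first_vote == "approve" ~ "case",
    .default = "non_case"
  )
  select(out, "patient_id", "dui", "n_approve", "n_reject", "resolution") |>
    arrange(.data$patient_id, .data$dui)
}

#' Combine detection sources into phenotype calls
#'
#' One call per (patient, disease) over the full cohort-by-panel grid. A
#' case is a patient detected by at least one source (ICD code, drug
#' prescription, or text mention); `sources` records which detectors fired.
#' When adjudicated text items are supplied, only items resolved as `case`
#' count as text detections; raw matches (no review) are over-sensitive and
#' should be treated as such.
#'
#' @param icd_cases,drug_cases Tibbles (`patient_id`, `dui`) from the
#'   structured detectors.
#' @param text_cases Tibble (`patient_id`, `dui`): adjudicated cases, or
#'   distinct pairs from raw matches.
#' @param cohort Character vector of patient identifiers.
#' @param panel_duis Character vector of panel disease DUIs.
#' @return A `phenotype_calls` tibble: `patient_id`, `dui`, `present`,
#'   `src_text`, `src_icd`, `src_drug`, `sources`.
#' @export
combine_sources <- function(icd_cases, drug_cases, text_cases, cohort, panel_duis) {
  grid <- tidyr::expand_grid(patient_id = sort(unique(cohort)),
                             dui = sort(unique(panel_duis)))
  mark <- function(cases) {
    if (nrow(cases) == 0) return(rep(FALSE, nrow(grid)))
    key <- paste(grid$patient_id, grid$dui)
    key %in% paste(cases$patient_id, cases$dui)
  }
  out <- grid |>
    mutate(src_icd = mark(icd_cases),
           src_drug = mark(drug_cases),
           src_text = mark(text_cases)) |>
    mutate(present = .data$src_text | .data$src_icd | .data$src_drug,
           sources = purrr::pmap_chr(
             list(.data$src_text, .data$src_icd, .data$src_drug),
             function(t, i, d) paste(c("text", "icd", "drug")[c(t, i, d)],
                                     collapse = "+")))
  class(out) <- c("phenotype_calls", class(out))
  out
}

#' Attribute cases to their detection sources
#'
#' Partitions each disease's cases into those found by text alone, by
#' structured sources alone (ICD code and/or drug prescription, no text
#' mention), or by both. The three counts always sum to the case count;
#' proportions are undefined (NA) for diseases with no cases.
#'
#' @param calls A `phenotype_calls` tibble from [combine_sources()].
#' @return Tibble per disease: `dui`, `n_text_only`, `n_structured_only`,
#'   `n_both`, `n_total` and the corresponding `pct_*` percentages.
#' @export
attribute_sources <- function(calls) {
  calls |>
    group_by(.data$dui) |>
    summarise(
      n_text_only = sum(.data$src_text & !.data$src_icd & !.data$src_drug),
      n_structured_only = sum(!.data$src_text & (.data$src_icd | .data$src_drug)),
      n_both = sum(.data$src_text & (.data$src_icd | .data$src_drug)),
      n_total = sum(.data$present),
      .groups = "drop") |>
    mutate(pct_text_only = ifelse(.data$n_total > 0,
                                  100 * .data$n_text_only / .data$n_total, NA_real_),
           pct_structured_only = ifelse(.data$n_total > 0,
                                        100 * .data$n_structured_only / .data$n_total,
                                        NA_real_),
           pct_both = ifelse(.data$n_total > 0,
                             100 * .data$n_both / .data$n_total, NA_real_))
}
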