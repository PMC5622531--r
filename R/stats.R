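# Estimators: binomial prevalence with Wald/Wilson interval selection,
# Sperrin's encounter-regularity index, Cohen's kappa, tie-aware Spearman
# correlation, and the any-comorbidity burden summary.

#' Prevalence with a 95% confidence interval per 1000 patients
#'
#' Point estimate is `1000 * n_cases / n_total`. The interval is the normal
#' (Wald) approximation unless its lower bound would fall below zero, or the
#' case count is zero (where the Wald interval degenerates to a point) — the
#' operational reading of "close to 0%" — in which case the Wilson score
#' interval is used instead. Wilson bounds always lie inside `[0, 1000]`;
#' the selection rule therefore guarantees non-negative reported bounds.
#'
#' @param n_cases Integer vector of case counts.
#' @param n_total Cohort size(s), `>= 1`.
#' @param alpha Significance level (default 0.05, i.e. `z = 1.959964`).
#' @param dui Optional identifier column carried through.
#' @return A `prevalence_estimate` tibble: `dui`, `n_cases`, `n_total`,
#'   `p_per_1000`, `ci_low_per_1000`, `ci_high_per_1000`, `method`.
#' @export
#' @examples
#' prevalence_ci(c(93, 3, 0), 741)
prevalence_ci <- function(n_cases, n_total, alpha = 0.05, dui = NA_character_) {
  if (any(n_total < 1)) stop_field("n_total must be >= 1")
  if (any(n_cases < 0 | n_cases > n_total)) {
    stop_field("n_cases must lie in [0, n_total]")
  }
  k <- max(length(n_cases), length(n_total))
  n_cases <- rep_len(as.numeric(n_cases), k)
  n_total <- rep_len(as.numeric(n_total), k)
  dui <- rep_len(dui, k)
  z <- qnorm(1 - alpha / 2)
  p <- n_cases / n_total
  se <- sqrt(p * (1 - p) / n_total)
  wald_low <- p - z * se
  wald_high <- p + z * se
  # Wilson score interval
  denom <- 1 + z^2 / n_total
  centre <- (p + z^2 / (2 * n_total)) / denom
  half <- z * sqrt(p * (1 - p) / n_total + z^2 / (4 * n_total^2)) / denom
  # zero successes give a degenerate Wald interval (0, 0); that is the
  # "close to 0%" case par excellence, so Wilson applies there too
  use_wilson <- wald_low < 0 | n_cases == 0
  low <- ifelse(use_wilson, centre - half, wald_low)
  high <- ifelse(use_wilson, centre + half, wald_high)
  out <- tibble(dui = dui, n_cases = as.integer(n_cases),
                n_total = as.integer(n_total),
                p_per_1000 = 1000 * p,
                ci_low_per_1000 = 1000 * low,
                ci_high_per_1000 = 1000 * high,
                method = ifelse(use_wilson, "wilson", "normal"))
  class(out) <- c("prevalence_estimate", class(out))
  out
}

#' @rdname prevalence_ci
#' @param x A `prevalence_estimate`.
#' @param ... Unused.
#' @method tidy prevalence_estimate
#' @export
tidy.prevalence_estimate <- function(x, ...) {
  mutate(as_tibble(x),
         across(c("p_per_1000", "ci_low_per_1000", "ci_high_per_1000"),
                round_half_up))
}

#' @rdname prevalence_ci
#' @method glance prevalence_estimate
#' @export
glance.prevalence_estimate <- function(x, ...) {
  tibble(n_diseases = nrow(x), n_total = x$n_total[1],
         n_wilson = sum(x$method == "wilson"),
         max_p_per_1000 = max(x$p_per_1000))
}

# report rounding: 1 decimal, half-up (not banker's)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Sperrin's encounter-regularity index
#'
#' Measures how regularly a patient's encounters cover the follow-up span.
#' With `n` encounters, the `n - 1` consecutive gaps are normalised to
#' fractions of the total span (they sum to 1) and
#' \deqn{I = 2/n + ((n-2)/n)\,[1 - \sqrt{(n-1)\,\mathrm{Var}(g_i)}]}
#' where Var is the mean squared deviation over the `n - 1` gaps. Perfectly
#' regular visits give `I = 1` (the variance term vanishes); so does
#' `n = 2`, where the single gap carries no irregularity information. The
#' result is clamped to `[0, 1]`. The index is invariant to shifting or
#' scaling the date axis.
#'
#' @param dates Vector of encounter dates (Date or numeric), at least 2
#'   distinct values with a positive span.
#' @return A single regularity score in `[0, 1]`.
#' @export
#' @examples
#' sperrin_index(as.Date("2005-01-01") + c(0, 100, 200, 300))  # 1
sperrin_index <- function(dates) {
  d <- sort(unique(as.numeric(dates)))
  n <- length(d)
  if (n < 2) {
    stop_field("Sperrin's I is defined only for >= 2 distinct encounter dates",
               class = "litcomorbid_undefined")
  }
  span <- d[n] - d[1]
  if (span <= 0) {
    stop_field("Sperrin's I is undefined for a zero follow-up span",
               class = "litcomorbid_undefined")
  }
  g <- diff(d) / span
  v <- mean((g - mean(g))^2)  # population variance over the n-1 gaps
  i_raw <- 2 / n + ((n - 2) / n) * (1 - sqrt((n - 1) * v))
  min(max(i_raw, 0), 1)
}

#' Per-patient regularity scores for a cohort
#'
#' Applies [sperrin_index()] to each cohort patient's encounter dates.
#' Patients with fewer than 2 distinct dates (or zero span) are excluded,
#' mirroring the "at least 2 encounters" eligibility of the index.
#'
#' @param bundle An [ehr_bundle()].
#' @param cohort Character vector of patient identifiers.
#' @return Tibble `patient_id`, `n_encounters`, `I`.
#' @export
sperrin_scores <- function(bundle, cohort) {
  enc <- filter(bundle$encounters, .data$patient_id %in% cohort)
  enc |>
    group_by(.data$patient_id) |>
    summarise(n_encounters = dplyr::n_distinct(.data$date),
              span = as.numeric(max(.data$date) - min(.data$date)),
              dates = list(.data$date), .groups = "drop") |>
    filter(.data$n_encounters >= 2, .data$span > 0) |>
    mutate(I = purrr::map_dbl(.data$dates, sperrin_index)) |>
    select("patient_id", "n_encounters", "I")
}

#' Cohen's kappa for a two-reviewer, two-category table
#'
#' Chance-corrected agreement from the 2x2 cross-tabulation of two
#' reviewers' approve/reject votes.
#'
#' @param n_both_approve,n_both_reject,n_disagree_ab,n_disagree_ba Cell
#'   counts: both approve; both reject; reviewer A approves / B rejects;
#'   A rejects / B approves.
#' @return A `kappa_agreement` object (numeric kappa in `[-1, 1]` with the
#'   table attached).
#' @export
#' @examples
#' cohens_kappa(140, 304, 11, 11)
cohens_kappa <- function(n_both_approve, n_both_reject,
                         n_disagree_ab, n_disagree_ba) {
  cells <- c(n_both_approve, n_both_reject, n_disagree_ab, n_disagree_ba)
  if (any(cells < 0) || sum(cells) == 0) {
    stop_field("agreement table needs non-negative cells with a positive total")
  }
  n <- sum(cells)
  po <- (n_both_approve + n_both_reject) / n
  p_a1 <- (n_both_approve + n_disagree_ab) / n  # reviewer A approves
  p_b1 <- (n_both_approve + n_disagree_ba) / n  # reviewer B approves
  pe <- p_a1 * p_b1 + (1 - p_a1) * (1 - p_b1)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    stop_field("expected agreement is 1 (degenerate marginals); kappa undefined",
               class = "litcomorbid_undefined")
  }
  structure((po - pe) / (1 - pe), class = "kappa_agreement",
            table = c(both_approve = n_both_approve, both_reject = n_both_reject,
                      disagree_ab = n_disagree_ab, disagree_ba = n_disagree_ba))
}

#' @export
print.kappa_agreement <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (n = %d items)\n",
              unclass(x), sum(attr(x, "table"))))
  invisible(x)
}

#' @rdname cohens_kappa
#' @param x A `kappa_agreement`.
#' @param ... Unused.
#' @method tidy kappa_agreement
#' @export
tidy.kappa_agreement <- function(x, ...) {
  tb <- attr(x, "table")
  tibble(kappa = as.numeric(x), n_items = sum(tb),
         n_both_approve = tb[["both_approve"]],
         n_both_reject = tb[["both_reject"]],
         n_disagree = tb[["disagree_ab"]] + tb[["disagree_ba"]])
}

#' Tie-aware Spearman rank correlation
#'
#' Average ranks are assigned to ties in each vector; rho is the Pearson
#' correlation of the rank vectors (the standard tie-corrected Spearman
#' coefficient, computed via [stats::cor()]).
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Tibble `rho`, `n`, `tie_method`.
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_field("x and y must have equal length >= 3")
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop_field("Spearman's rho is undefined for a constant vector",
               class = "litcomorbid_undefined")
  }
  tibble(rho = cor(x, y, method = "spearman"), n = length(x),
         tie_method = "average_rank")
}

#' Comorbidity burden: prevalence of at least one panel disease
#'
#' Collapses phenotype calls to the per-patient indicator "has at least one
#' panel disease" and estimates its prevalence via [prevalence_ci()].
#'
#' @param calls A `phenotype_calls` tibble from [combine_sources()].
#' @param alpha Significance level.
#' @return A one-row `prevalence_estimate` (`dui = "any"`).
#' @export
burden_summary <- function(calls, alpha = 0.05) {
  per_patient <- calls |>
    group_by(.data$patient_id) |>
    summarise(any_disease = any(.data$present), .groups = "drop")
  prevalence_ci(sum(per_patient$any_disease), nrow(per_patient),
                alpha = alpha, dui = "any")
}
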