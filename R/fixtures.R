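# Machine-readable reference tables for the celiac-disease case study:
# the published literature ranking, prevalence table and review partition.

#' Reference tables of the celiac-disease case study
#'
#' Returns the published reference values of the autoimmune-comorbidity
#' study of celiac disease as machine-readable constants:
#'
#' * `panel`: the 15 autoimmune diseases most co-occurring with celiac
#'   disease in MEDLINE, with citation counts and the compact ICD-10
#'   pattern used for diagnosis extraction (`*` = all descending nodes,
#'   `|` = OR).
#' * `prevalence`: the published per-disease case counts over the 741
#'   included patients with the printed per-1000 estimates and interval
#'   bounds (`wilson_flagged` marks rows footnoted as Wilson intervals).
#'   One panel disease (IgA glomerulonephritis) had no detected case and
#'   no printed row; it is absent here and counts as 0 cases downstream.
#' * `review`: the two-reviewer vote partition over text-candidate items.
#' * `n_cohort`: the cohort size (741).
#' * `index_dui`: the celiac-disease descriptor (D002446).
#' * `subtree_root`: the autoimmune-disease MeSH subtree (C20.111).
#'
#' @return A list with elements `panel`, `prevalence`, `review`,
#'   `n_cohort`, `index_dui`, `subtree_root`.
#' @export
#' @examples
#' fixture_tables()$panel
fixture_tables <- function() {
  panel <- tibble(
    rank = 1:15,
    name = c("Diabetes Mellitus, Type 1", "Dermatitis Herpetiformis",
             "Thyroiditis, Autoimmune", "Arthritis, Rheumatoid",
             "Lupus Erythematosus, Systemic", "Multiple Sclerosis",
             "Sjogren's Syndrome", "Addison Disease", "Arthritis, Juvenile",
             "Hepatitis, Autoimmune", "Graves' Disease",
             "Glomerulonephritis, IGA", "Myasthenia Gravis",
             "Polyendocrinopathies, Autoimmune", "Antiphospholipid Syndrome"),
    dui = c("D003922", "D003874", "D013967", "D001172", "D008180", "D009103",
            "D012859", "D000224", "D001171", "D019693", "D006111", "D005922",
            "D009157", "D016884", "D016736"),
    n_cooccurrence = c(523L, 478L, 96L, 87L, 73L, 44L, 43L, 42L, 37L, 35L,
                       30L, 27L, 22L, 15L, 12L),
    icd = c("E10*", "L130", "E063", "M069*", "M32*", "G35", "M350",
            "E271|E272", "M089*", "K754", "E050|E05*", "N0330|N0170",
            "G700", "E31*", "D686*")
  )
  prevalence <- tibble(
    name = c("Autoimmune thyroiditis", "Type 1 diabetes mellitus",
             "Dermatitis herpetiformis", "Rheumatoid arthritis",
             "Autoimmune hepatitis", "Graves' disease", "Sjogren's syndrome",
             "Addison disease", "Systemic lupus erythematosus",
             "Juvenile arthritis", "Multiple sclerosis",
             "Autoimmune Polyendocrinopathies", "Antiphospholipid syndrome",
             "Myasthenia gravis"),
    dui = c("D013967", "D003922", "D003874", "D001172", "D019693", "D006111",
            "D012859", "D000224", "D008180", "D001171", "D009103", "D016884",
            "D016736", "D009157"),
    n_cases = c(93L, 17L, 15L, 7L, 7L, 6L, 6L, 3L, 2L, 1L, 1L, 1L, 0L, 0L),
    printed_per_1000 = c(125.5, 22.9, 20.2, 9.4, 9.4, 8.1, 8.1, 4, 2.7,
                         1.3, 1.3, 1.3, 0, 0),
    printed_ci_low = c(101, 12.1, 10, 2.5, 2.5, 1.6, 1.6, 1.4, 0.7, 0.1,
                       0.1, 0.1, 0, 0),
    printed_ci_high = c(149, 33.5, 30.2, 16.3, 16.3, 14.5, 14.5, 11.8, 9.8,
                        7.6, 7.6, 7.6, 5.2, 5.2),
    wilson_flagged = c(rep(FALSE, 8), rep(TRUE, 6))
  )
  review <- list(n_items = 466L, n_both_approve = 140L, n_both_reject = 304L,
                 n_disagree = 22L)
  list(panel = panel, prevalence = prevalence, review = review,
       n_cohort = 741L, index_dui = "D002446", subtree_root = "C20.111")
}
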