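test_that("prevalence point estimates and interval selection match the method", {
  est <- prevalence_ci(c(93, 17, 15, 3, 0), 741)
  expect_equal(round(est$p_per_1000, 1), c(125.5, 22.9, 20.2, 4.0, 0))
  expect_equal(est$method, c("normal", "normal", "normal", "wilson", "wilson"))
  # Wilson rows reproduce the published bounds at 1 decimal
  expect_equal(round(est$ci_low_per_1000[4], 1), 1.4)
  expect_equal(round(est$ci_high_per_1000[4], 1), 11.8)
  expect_equal(round(est$ci_high_per_1000[5], 1), 5.2)
  expect_equal(est$ci_low_per_1000[5], 0)  # Wilson lower is exactly 0 at x=0

  expect_error(prevalence_ci(1, 0), "n_total")
  expect_error(prevalence_ci(5, 4), "n_cases")
})

test_that("Wilson bounds agree with the score-test oracle and stay in range", {
  for (x in c(0, 1, 2, 3, 10, 93, 370, 741)) {
    mine <- prevalence_ci(x, 741)
    if (mine$method == "wilson") {
      oracle <- prop.test(x, 741, correct = FALSE)$conf.int
      expect_equal(mine$ci_low_per_1000, 1000 * oracle[1], tolerance = 1e-10)
      expect_equal(mine$ci_high_per_1000, 1000 * oracle[2], tolerance = 1e-10)
    }
    expect_gte(mine$ci_low_per_1000, 0)
    expect_lte(mine$ci_low_per_1000, mine$p_per_1000)
    expect_gte(mine$ci_high_per_1000, mine$p_per_1000)
  }
  # extremes are exact
  expect_equal(prevalence_ci(0, 50)$p_per_1000, 0)
  expect_equal(prevalence_ci(50, 50)$p_per_1000, 1000)
  # forced-Wilson bounds never leave [0, 1000] for any count
  all_wilson <- prevalence_ci(0:30, 30)
  wil <- all_wilson[all_wilson$method == "wilson", ]
  expect_true(all(wil$ci_low_per_1000 >= 0 & wil$ci_high_per_1000 <= 1000))
})

test_that("regularity index is 1 for equal spacing and n = 2, matches hand oracle", {
  expect_equal(sperrin_index(as.Date("2005-01-01") + seq(0, 900, by = 100)), 1)
  expect_equal(sperrin_index(c(0, 365)), 1)
  # hand-evaluated case: dates {0, 1, 10}, gaps 0.1/0.9, Var = 0.16,
  # I = 2/3 + (1/3)(1 - sqrt(0.32))
  expect_equal(sperrin_index(c(0, 1, 10)),
               2 / 3 + (1 / 3) * (1 - sqrt(0.32)), tolerance = 1e-12)
  expect_equal(round(sperrin_index(c(0, 1, 10)), 4), 0.8114)
})

test_that("regularity index is affine-invariant and correctly undefined", {
  set.seed(3)
  for (i in 1:10) {
    d <- cumsum(runif(sample(3:12, 1), 1, 50))
    expect_equal(sperrin_index(d * 7.3 + 1e5), sperrin_index(d),
                 tolerance = 1e-9)
    expect_gte(sperrin_index(d), 0)
    expect_lte(sperrin_index(d), 1)
  }
  expect_error(sperrin_index(5), class = "litcomorbid_undefined")
  expect_error(sperrin_index(c(3, 3, 3)), class = "litcomorbid_undefined")
})

test_that("kappa matches the independent cross-tabulation oracle", {
  skip_if_not_installed("e1071")
  set.seed(9)
  for (i in 1:20) {
    cells <- sample(0:50, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    tab <- matrix(c(cells[1], cells[3], cells[4], cells[2]), nrow = 2)
    ok <- tryCatch({
      mine <- cohens_kappa(cells[1], cells[2], cells[3], cells[4]); TRUE
    }, litcomorbid_undefined = function(e) FALSE)
    if (ok) {
      expect_equal(as.numeric(mine), e1071::classAgreement(tab)$kappa,
                   tolerance = 1e-12)
      # symmetry under swapping raters
      swapped <- cohens_kappa(cells[1], cells[2], cells[4], cells[3])
      expect_equal(as.numeric(mine), as.numeric(swapped))
    }
  }
})

test_that("kappa hits its anchor points", {
  expect_equal(as.numeric(cohens_kappa(30, 20, 0, 0)), 1)
  # marginal independence: observed agreement equals chance agreement
  expect_equal(as.numeric(cohens_kappa(1, 1, 1, 1)), 0)
  expect_error(cohens_kappa(10, 0, 0, 0), class = "litcomorbid_undefined")
  expect_error(cohens_kappa(0, 0, 0, 0), "positive total")
})

test_that("Spearman's rho equals the rank-then-Pearson oracle, ties averaged", {
  x <- c(1, 2, 2, 3, 5, 5)
  perms <- list(c(1, 2, 3, 4, 5, 6), c(6, 5, 4, 3, 2, 1),
                c(2, 2, 1, 5, 4, 4), c(1, 3, 2, 6, 5, 4),
                c(4, 4, 4, 1, 1, 2))
  for (y in perms) {
    oracle <- cor(rank(x, ties.method = "average"),
                  rank(y, ties.method = "average"))
    expect_equal(spearman_rho(x, y)$rho, oracle, tolerance = 1e-12)
  }
  expect_equal(spearman_rho(1:5, 1:5)$rho, 1)
  # invariance under strictly monotone transforms
  expect_equal(spearman_rho(exp(x), perms[[3]]^3)$rho,
               spearman_rho(x, perms[[3]])$rho)
  expect_error(spearman_rho(c(1, 1, 1), 1:3), class = "litcomorbid_undefined")
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("burden summary collapses calls to the any-disease indicator", {
  cohort <- sprintf("P%02d", 1:10)
  none <- combine_sources(tibble::tibble(patient_id = character(),
                                         dui = character()),
                          tibble::tibble(patient_id = character(),
                                         dui = character()),
                          tibble::tibble(patient_id = character(),
                                         dui = character()),
                          cohort, c("D000001", "D000002"))
  b0 <- burden_summary(none)
  expect_equal(b0$p_per_1000, 0)
  expect_equal(b0$method, "wilson")

  all_icd <- tibble::tibble(patient_id = cohort, dui = "D000001")
  full <- combine_sources(all_icd, all_icd[0, ], all_icd[0, ], cohort,
                          c("D000001", "D000002"))
  b1 <- burden_summary(full)
  expect_equal(b1$p_per_1000, 1000)
  expect_equal(b1$method, "normal")
  expect_equal(b1$n_total, 10L)
})
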