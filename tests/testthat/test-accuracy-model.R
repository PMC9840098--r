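# independent oracle: expected-count cross-tabulation of the 2x2x2 table
# (disease x screen x linkage-assigned outcome) at large N
oracle_apparent <- function(se_s, sp_s, se_m, sp_m, p, N = 1e7) {
  cells <- expand.grid(disease = c(TRUE, FALSE), screen = c(TRUE, FALSE),
                       linked = c(TRUE, FALSE))
  n <- apply(cells, 1, function(row) {
    d <- row[["disease"]]; s <- row[["screen"]]; l <- row[["linked"]]
    pd <- if (d) p else 1 - p
    ps <- if (d) (if (s) se_s else 1 - se_s) else
                 (if (s) 1 - sp_s else sp_s)
    pl <- if (d) (if (l) se_m else 1 - se_m) else
                 (if (l) 1 - sp_m else sp_m)
    N * pd * ps * pl
  })
  apparent_pos <- cells$linked   # linkage assigns the outcome label
  se <- sum(n[cells$screen & apparent_pos]) / sum(n[apparent_pos])
  sp <- sum(n[!cells$screen & !apparent_pos]) / sum(n[!apparent_pos])
  ppv <- sum(n[cells$screen & apparent_pos]) / sum(n[cells$screen])
  list(se = se, sp = sp, ppv = ppv)
}

test_that("closed forms agree with expected-count cross-tabulation", {
  set.seed(60)
  for (i in 1:100) {
    se_s <- runif(1, 0.3, 1); sp_s <- runif(1, 0.5, 1)
    se_m <- runif(1, 0.3, 1); sp_m <- runif(1, 0.9, 1)
    p <- runif(1, 1e-4, 0.2)
    a <- apparent_screening_accuracy(se_s, sp_s, se_m, sp_m, p)
    o <- oracle_apparent(se_s, sp_s, se_m, sp_m, p)
    expect_equal(a$se, o$se, tolerance = 1e-10)
    expect_equal(a$sp, o$sp, tolerance = 1e-10)
    expect_equal(a$ppv, o$ppv, tolerance = 1e-10)
  }
})

test_that("oracle-derived spot value for matching (85%, 99.9%)", {
  # frozen from the expected-count oracle at N = 1e7
  o <- oracle_apparent(0.9, 0.9, 0.85, 0.999, 0.007757)
  expect_equal(round_half_up(100 * o$se, 2), 79.54)
  a <- apparent_screening_accuracy(0.9, 0.9, 0.85, 0.999)
  expect_equal(a$se_pct, 79.54)
})

test_that("boundary identities hold exactly", {
  grid <- expand.grid(se_s = c(0.6, 0.75, 0.9), sp_s = c(0.8, 0.9, 0.99),
                      p = c(0.001, 0.007757, 0.1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    # perfect matching reproduces the true values and PPV
    a <- apparent_screening_accuracy(g$se_s, g$sp_s, 1, 1, g$p)
    expect_equal(a$se, g$se_s)
    expect_equal(a$sp, g$sp_s)
    expect_equal(round_half_up(100 * a$ppv, 1), true_ppv(g$se_s, g$sp_s, g$p))
    # Sp_m = 1 leaves sensitivity unchanged; Se_m = 1 leaves specificity
    a <- apparent_screening_accuracy(g$se_s, g$sp_s, 0.7, 1, g$p)
    expect_equal(a$se, g$se_s)
    expect_true(a$se_unaffected)
    a <- apparent_screening_accuracy(g$se_s, g$sp_s, 1, 0.995, g$p)
    expect_equal(a$sp, g$sp_s)
    expect_true(a$sp_unaffected)
  }
})

test_that("apparent accuracy is monotone in the matching accuracy", {
  sp_seq <- vapply(c(1, 0.9999, 0.999, 0.998, 0.99),
                   function(spm) apparent_screening_accuracy(
                     0.9, 0.9, 1, spm)$se, 0)
  expect_true(all(diff(sp_seq) < 0))
  se_seq <- vapply(c(1, 0.9, 0.85, 0.5, 0.2),
                   function(sem) apparent_screening_accuracy(
                     0.9, 0.9, sem, 1)$sp, 0)
  expect_true(all(diff(se_seq) < 0))
})

test_that("true PPV matches its closed form", {
  expect_equal(true_ppv(0.9, 0.9, 0.007757), 6.6)
  expect_equal(true_ppv(0.6, 0.9, 0.007757), 4.5)
  expect_equal(true_ppv(0.9, 1, 0.007757), 100)
  expect_error(true_ppv(0.9, 0.9, 0), "positive")
})

test_that("risk-ratio propagation attenuates only via matching specificity", {
  expect_equal(apparent_cohort_rr(2, 0.007757, 0.6, 1), 2)
  expect_equal(apparent_cohort_rr(3.5, 0.01, 1, 1), 3.5)
  att <- apparent_cohort_rr(2, 0.007757, 0.8871, 0.998)
  expect_lt(att, 2)
  expect_gt(att, 1)
  # attenuation worsens as specificity drops
  att2 <- apparent_cohort_rr(2, 0.007757, 0.8871, 0.99)
  expect_lt(att2, att)
  expect_error(apparent_cohort_rr(2, 0, 1, 1), "incidence")
  expect_error(apparent_cohort_rr(200, 0.1, 1, 1), "exceeds 1")
})

test_that("odds-ratio propagation shrinks toward the null", {
  expect_equal(apparent_case_control_or(3, 0.1, 1, 1), 3)
  # a null association stays null under any matching accuracy
  for (m in list(c(0.9, 0.99), c(0.5, 0.9), c(1, 0.98)))
    expect_equal(apparent_case_control_or(1, 0.2, m[1], m[2]), 1)
  att <- apparent_case_control_or(3, 0.1, 0.9, 0.99)
  expect_lt(att, 3)
  expect_gt(att, 1)
  # rarer exposure suffers more
  att_rare <- apparent_case_control_or(3, 0.01, 0.9, 0.99)
  expect_lt(att_rare, att)
  expect_error(apparent_case_control_or(3, 1, 0.9, 0.99), "prevalence")
})

test_that("the scenario grid has the published shape", {
  tab <- scenario_table()
  expect_identical(nrow(tab), 16L)
  # identity cells print NA except in the experimental rows
  expect_true(all(is.na(tab$se_est[tab$sp_match == 100 & !tab$experimental])))
  expect_true(all(is.na(tab$sp_est[tab$se_match == 100 & !tab$experimental])))
  expect_true(all(!is.na(tab$se_est[tab$experimental])))
  expect_true(all(!is.na(tab$sp_est[tab$experimental])))
  expect_true(all(!is.na(tab$ppv_est)))
})
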