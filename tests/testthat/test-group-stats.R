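# Paired/independent t-tests, BH correction, cohort comparison tables.

test_that("paired test matches the closed-form t distribution", {
  # no change at all: exact tie
  r <- paired_ttest(c(1, 1.2, 0.9), c(1, 1.2, 0.9))
  expect_identical(c(r$t, r$p), c(0, 1))
  # constant non-zero shift: no finite statistic, flagged as degenerate
  r2 <- paired_ttest(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_true(is.na(r2$p))
  expect_match(r2$note, "zero-variance")
  # closed-form oracle on fixed differences
  d <- c(0.2, 0.1, 0.15, 0.05, 0.2)
  r3 <- paired_ttest(rep(1, 5), 1 + d)
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  p_ref <- 2 * pt(-abs(t_ref), df = 4)
  expect_equal(r3$t, t_ref, tolerance = 1e-10)
  expect_equal(r3$p, p_ref, tolerance = 1e-6)
  expect_error(paired_ttest(1:3, 1:4), "paired")
  expect_error(paired_ttest(1, 2), "n >= 2")
})

test_that("independent test is antisymmetric and pools variance", {
  a <- c(1.1, 1.3, 0.9, 1.2); b <- c(0.8, 1.0, 0.95)
  r <- independent_ttest(a, b)
  rs <- independent_ttest(b, a)
  expect_equal(r$t, -rs$t)
  expect_equal(r$p, rs$p)
  # pooled-variance closed form
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(r$t, t_ref, tolerance = 1e-10)
  expect_identical(independent_ttest(c(1, 1), c(1, 1))$p, 1)
  expect_true(is.na(independent_ttest(c(1, 1), c(2, 2))$p))
  # Welch flag reaches stats::t.test
  rw <- independent_ttest(a, b, equal_var = FALSE)
  expect_equal(rw$p, t.test(a, b)$p.value)
})

test_that("BH correction reproduces the step-up rule", {
  expect_true(benjamini_hochberg(0.01, q = 0.2)$reject)
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.5, 0.9), q = 0.2)
  expect_identical(bh$reject, c(TRUE, TRUE, FALSE, FALSE))
  # adjusted values are monotone in the raw order
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(1:10, 1))
    bh <- benjamini_hochberg(p, q = 0.2)
    expect_identical(bh$reject, bh_stepup_oracle(p, 0.2))
    expect_true(all(diff(bh$adjusted[order(p)]) >= -1e-15))
  }
  # NA entries shrink the family instead of inflating m
  bh2 <- benjamini_hochberg(c(0.01, NA, 0.04), q = 0.2)
  expect_identical(bh2$m, 2L)
  expect_true(is.na(bh2$adjusted[2]))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  expect_error(benjamini_hochberg(0.5, q = 0), "q")
})

test_that("comparison tables carry the published shape and BH families", {
  cs <- cohort_spec(seed = 41)
  summ <- simulate_cohort_summaries(cs, measurement_sd = 0.03)
  res <- build_comparison_tables(summ, q = 0.2)
  expect_named(res$tables, c("cbf", "cbv", "mtt"))
  for (tab in res$tables) {
    expect_identical(nrow(tab), 20L)   # 5 territories x 4 row quantities
    expect_identical(names(tab),
                     c("territory", "quantity", "all", "chs", "non_chs",
                       "p_across"))
    expect_setequal(unique(tab$territory),
                    c("ACA-terminal", "ACA-central", "MCA-terminal",
                      "MCA-central", "PCA-terminal"))
    expect_identical(unique(tab$quantity),
                     c("Pre", "Intra", "%increase", "P-value (Pre vs Intra)"))
    # across-group p-values sit on the Intra and %increase rows only
    expect_true(all(is.na(tab$p_across[tab$quantity == "Pre"])))
    expect_true(all(!is.na(tab$p_across[tab$quantity == "%increase"])))
  }
  # one BH family of 15 per parameter, flags consistent with the oracle
  st <- res$stats
  expect_identical(nrow(st), 45L)
  for (param in c("cbf", "cbv", "mtt")) {
    fam <- st[st$parameter == param, ]
    ok <- !is.na(fam$p)
    expect_identical(fam$significant[ok], bh_stepup_oracle(fam$p[ok], 0.2))
  }
  # group means agree with direct aggregation
  mca_pre <- summ$relative_cbf[summ$territory == "MCA-terminal" &
                                 summ$session == "pre" & summ$group == "CHS"]
  tab <- res$tables$cbf
  expect_equal(tab$chs[tab$territory == "MCA-terminal" & tab$quantity == "Pre"],
               mean(mca_pre))
})

test_that("degenerate cohorts are reported, not fatal", {
  cs <- cohort_spec(n_chs = 1, n_nonchs = 3, seed = 42)
  summ <- simulate_cohort_summaries(cs, measurement_sd = 0.03)
  res <- build_comparison_tables(summ)
  tab <- res$tables$cbf
  # single-subject group: its paired test and the across-group tests are
  # not computable, but the table is still emitted in full
  expect_identical(nrow(tab), 20L)
  expect_true(all(is.na(tab$chs[tab$quantity == "P-value (Pre vs Intra)"])))
  expect_true(all(is.na(tab$p_across[tab$quantity == "%increase"])))
  # missing sessions are named
  broken <- summ[!(summ$subject_id == "S01" & summ$session == "intra"), ]
  expect_error(build_comparison_tables(broken), "S01")
})

test_that("designed CHS effect surfaces where it was injected", {
  cs <- cohort_spec(seed = 43)
  res <- build_comparison_tables(simulate_cohort_summaries(cs))
  st <- res$stats[res$stats$parameter == "cbf" & res$stats$test == "pct_across", ]
  expect_identical(st$territory[which.min(st$p)], "MCA-terminal")
  tab <- res$tables$cbf
  inc <- tab[tab$quantity == "%increase" & tab$territory == "MCA-terminal", ]
  expect_equal(inc$chs, 14.3, tolerance = 0.6)      # designed +14.3%
  expect_lt(abs(inc$non_chs), 8)                     # null group near zero
})
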