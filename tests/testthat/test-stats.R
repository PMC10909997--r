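level_table <- function(values_by_level, subjects = NULL) {
  # values_by_level: named list level -> numeric vector over subjects
  n <- length(values_by_level[[1]])
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_len(n))
  dplyr::bind_rows(lapply(names(values_by_level), function(lv) {
    tibble::tibble(subject = subjects, cl = 1L, pl = lv,
                   value = values_by_level[[lv]])
  }))
}

test_that("identical values across levels give a null Friedman result", {
  tab <- level_table(list(none = rep(5, 8), medium = rep(5, 8),
                          high = rep(5, 8)))
  res <- compare_repeated(tab, "value", "pl")
  omni <- res[res$contrast == "omnibus", ]
  expect_identical(omni$test, "friedman")
  expect_equal(omni$statistic, 0)
  expect_equal(omni$p_value, 1)
  expect_true(all(res$p_value[res$contrast != "omnibus"] == 1))
})

test_that("clearly normal differences route to rmANOVA with paired t contrasts", {
  set.seed(41)
  base <- rnorm(20, 100, 10)
  tab <- level_table(list(none = base, medium = base + rnorm(20, 5, 2),
                          high = base + rnorm(20, 10, 2)))
  res <- compare_repeated(tab, "value", "pl")
  expect_identical(res$test[res$contrast == "omnibus"], "rmANOVA")
  expect_true(all(res$test[res$contrast != "omnibus"] == "paired_t"))
  expect_lt(res$p_value[res$contrast == "omnibus"], 0.01)
  expect_equal(nrow(res), 4)  # omnibus + 3 pairwise
})

test_that("heavy-tailed differences route to Friedman with Wilcoxon contrasts", {
  set.seed(42)
  base <- rnorm(20, 100, 5)
  shift <- exp(rnorm(20, 1.2, 1.2))  # lognormal: Shapiro should fail
  tab <- level_table(list(none = base, high = base + shift))
  res <- compare_repeated(tab, "value", "pl")
  expect_identical(res$test[res$contrast == "omnibus"], "friedman")
  expect_identical(res$test[res$contrast != "omnibus"], "wilcoxon_signed_rank")
  expect_lt(res$p_value[res$contrast != "omnibus"], 0.05)
  expect_equal(res$direction[res$contrast != "omnibus"], 1)
})

test_that("the reported Wilcoxon statistic equals a manual signed-rank sum", {
  set.seed(43)
  for (i in 1:20) {
    a <- rnorm(8, 50, 10)
    d <- rcauchy(8, 1, 3)  # non-normal differences
    tab <- level_table(list(lo = a, hi = a + d))
    res <- compare_repeated(tab, "value", "pl")
    w_row <- res[res$test == "wilcoxon_signed_rank", ]
    if (nrow(w_row) == 1) {
      # contrast is 'second level vs first' in pivot order: lo first -> hi - lo
      expect_equal(w_row$statistic, oracle_signed_rank(d), tolerance = 1e-9)
    }
  }
})

test_that("type-I error of the nonparametric path stays near nominal", {
  set.seed(44)
  rej <- replicate(80, {
    a <- rnorm(12, 100, 10)
    d <- rcauchy(12, 0, 5)
    tab <- level_table(list(lo = a, hi = a + d))
    res <- compare_repeated(tab, "value", "pl")
    any(res$p_value[res$contrast != "omnibus"] < 0.05)
  })
  expect_lt(mean(rej), 0.15)
})

test_that("Spearman correlations recover monotone and anti-monotone relations", {
  x <- seq(-3, 3, length.out = 30)
  tab <- tibble::tibble(subject = sprintf("S%02d", 1:30), cl = 1L,
                        pl = "none", feat = x, TLX_total = 2 * x + 1,
                        MRT = -x^3)
  res <- correlate_load(tab, "feat", c("TLX_total", "MRT"))
  expect_equal(res$rho[res$measure == "TLX_total"], 1)
  expect_equal(res$rho[res$measure == "MRT"], -1)
})

test_that("constant columns produce an NA correlation marker", {
  tab <- tibble::tibble(subject = sprintf("S%02d", 1:10), cl = 1L,
                        pl = "none", feat = rep(4, 10), TLX_total = rnorm(10))
  res <- correlate_load(tab, "feat", "TLX_total")
  expect_true(is.na(res$rho))
})

test_that("null correlations are small for independent normals", {
  set.seed(45)
  big <- abs(replicate(60, {
    tab <- tibble::tibble(subject = sprintf("S%03d", 1:300), cl = 1L,
                          pl = "none", feat = rnorm(300),
                          TLX_total = rnorm(300))
    correlate_load(tab, "feat", "TLX_total")$rho
  }))
  expect_gte(mean(big < 0.15), 0.95)
})

test_that("preconditions: levels, subjects, columns", {
  tab <- level_table(list(a = rnorm(2), b = rnorm(2)))
  expect_error(compare_repeated(tab, "value", "pl"), "3 complete subjects")
  expect_error(compare_repeated(tab, "missing", "pl"), "needs columns")
})

test_that("the three-stage study analysis populates every stage", {
  ds <- gen_study_dataset(4, seed = 6, duration_s = 90)
  rep <- run_study_analysis(ds)
  expect_s3_class(rep, "study_report")
  expect_gt(nrow(rep$stage1_load), 0)
  expect_true(all(c("TLX_total", "MRT", "SDRT", "CNR") %in%
                    rep$stage1_load$feature))
  expect_equal(sort(unique(rep$stage2_hrv$cl)), 1:3)
  expect_setequal(unique(rep$stage3_correlation$pl),
                  c("none", "medium", "high"))
  expect_true(all(rep$stage1_load$p_value >= 0 &
                    rep$stage1_load$p_value <= 1, na.rm = TRUE))
})

test_that("missing stage inputs raise an error naming the stage", {
  ds <- gen_study_dataset(4, seed = 7, duration_s = 90)
  ft <- study_feature_table(ds)
  expect_error(run_study_analysis(ft[setdiff(names(ft), "TLX_total")]),
               "stage 1")
  expect_error(run_study_analysis(ft[setdiff(names(ft), "nHF")]), "stage 2")
})
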