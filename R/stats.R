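#' Repeated-measures comparison of a feature across load levels
#'
#' Reproduces the assumption-gated analysis layer: for one feature and one
#' within-subject factor (cognitive or physical load), normality of the
#' within-subject difference scores is tested per level pair
#' (Shapiro-Wilk, alpha = 0.05). When every pair passes, a repeated-measures
#' ANOVA omnibus with paired t post-hoc contrasts is used; otherwise the
#' Friedman omnibus with Wilcoxon signed-rank pairwise contrasts. All
#' pairwise contrasts are always reported. If the other factor varies in the
#' table, values are first averaged within subject x level. No
#' multiple-testing correction is applied by default (raw p at alpha 0.05);
#' `p_adjust = "holm"` enables Holm adjustment of the pairwise p-values.
#'
#' @param table long-format data frame with columns `subject`, `cl`, `pl`,
#'   and the feature column.
#' @param feature name of the feature column.
#' @param factor `"cl"` or `"pl"`.
#' @param alpha significance level of the normality gate.
#' @param p_adjust `"none"` (default) or `"holm"` for the pairwise contrasts.
#' @return A tibble of test results: one omnibus row plus one row per
#'   pairwise contrast, with columns `feature`, `factor`, `contrast`,
#'   `test`, `statistic`, `p_value`, `n`, `direction` (sign of the mean
#'   difference level2 - level1 for contrasts).
#' @export
compare_repeated <- function(table, feature, factor = c("cl", "pl"),
                             alpha = 0.05, p_adjust = c("none", "holm")) {
  factor <- match.arg(factor)
  p_adjust <- match.arg(p_adjust)
  stop_if(!all(c("subject", factor, feature) %in% names(table)),
          "table needs columns subject, ", factor, ", ", feature)
  lv <- table[[factor]]
  lv_order <- if (is.factor(lv)) levels(lv)[levels(lv) %in% unique(as.character(lv))]
              else unique(as.character(lv))
  df <- tibble::tibble(subject = table$subject,
                       level = base::factor(as.character(lv), levels = lv_order),
                       value = table[[feature]])
  df <- dplyr::summarise(dplyr::group_by(df, subject, level),
                         value = mean(value, na.rm = TRUE), .groups = "drop")
  wide <- tidyr::pivot_wider(df, names_from = "level", values_from = "value")
  wide <- wide[c("subject", lv_order)]
  wide <- wide[stats::complete.cases(wide), ]
  levels_ <- lv_order
  stop_if(length(levels_) < 2L, "need at least 2 levels of ", factor)
  stop_if(nrow(wide) < 3L, "need at least 3 complete subjects")
  n <- nrow(wide)
  pairs <- utils::combn(levels_, 2, simplify = FALSE)
  # normality gate on within-subject difference scores, per level pair
  normal_ok <- vapply(pairs, function(pr) {
    d <- wide[[pr[2]]] - wide[[pr[1]]]
    if (sd(d) == 0) return(FALSE)
    shapiro.test(d)$p.value > alpha
  }, logical(1))
  parametric <- all(normal_ok)
  long <- tidyr::pivot_longer(wide, -"subject", names_to = "level",
                              values_to = "value")
  if (parametric) {
    long$subject <- base::factor(long$subject)
    long$level <- base::factor(long$level, levels = levels_)
    fit <- aov(value ~ level + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    omni <- tibble::tibble(
      feature = feature, factor = factor, contrast = "omnibus",
      test = "rmANOVA", statistic = tab["level", "F value"],
      p_value = tab["level", "Pr(>F)"], n = n, direction = NA_real_)
    post <- lapply(pairs, function(pr) {
      tt <- t.test(wide[[pr[2]]], wide[[pr[1]]], paired = TRUE)
      tibble::tibble(feature = feature, factor = factor,
                     contrast = paste(pr[2], "vs", pr[1]),
                     test = "paired_t", statistic = unname(tt$statistic),
                     p_value = tt$p.value, n = n,
                     direction = sign(mean(wide[[pr[2]]] - wide[[pr[1]]])))
    })
  } else {
    mat <- as.matrix(wide[levels_])
    fr <- friedman.test(mat)
    omni <- tibble::tibble(
      feature = feature, factor = factor, contrast = "omnibus",
      test = "friedman",
      # all-tied data: the rank variance is zero and the statistic degenerates
      statistic = if (is.nan(fr$statistic)) 0 else unname(fr$statistic),
      p_value = if (is.nan(fr$p.value)) 1 else fr$p.value,
      n = n, direction = NA_real_)
    post <- lapply(pairs, function(pr) {
      d <- wide[[pr[2]]] - wide[[pr[1]]]
      wt <- suppressWarnings(
        wilcox.test(wide[[pr[2]]], wide[[pr[1]]], paired = TRUE,
                    exact = sum(d != 0) < 25, correct = TRUE))
      tibble::tibble(feature = feature, factor = factor,
                     contrast = paste(pr[2], "vs", pr[1]),
                     test = "wilcoxon_signed_rank",
                     statistic = unname(wt$statistic),
                     p_value = if (all(d == 0)) 1 else wt$p.value, n = n,
                     direction = sign(mean(d)))
    })
  }
  post <- dplyr::bind_rows(post)
  if (p_adjust == "holm") post$p_value <- stats::p.adjust(post$p_value, "holm")
  dplyr::bind_rows(omni, post)
}

#' Spearman correlations between HRV features and load measures
#'
#' Within each physical-load stratum, correlates each HRV feature with each
#' load measure (e.g., the weighted TLX total and mean reaction time) by
#' Spearman's rank correlation, pooling the cognitive-load levels within
#' subjects (each subject contributes one pair per cognitive level; the
#' repeated contributions are a noted limitation, not modelled). Constant
#' columns yield an `NA` correlation marker.
#'
#' @param table long-format data frame with columns `subject`, `cl`, `pl`,
#'   the HRV feature columns and the load-measure columns.
#' @param hrv_features character vector of HRV feature column names.
#' @param load_measures character vector of load-measure column names.
#' @return A tibble: `pl`, `feature`, `measure`, `rho`, `p_value`, `n`.
#' @export
correlate_load <- function(table, hrv_features,
                           load_measures = c("TLX_total", "MRT")) {
  stop_if(!all(c("pl", hrv_features, load_measures) %in% names(table)),
          "table is missing required columns")
  out <- list()
  for (stratum in unique(as.character(table$pl))) {
    sub <- table[as.character(table$pl) == stratum, ]
    for (fe in hrv_features) for (me in load_measures) {
      x <- sub[[fe]]; y <- sub[[me]]
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      if (n < 5 || sd(x) == 0 || sd(y) == 0) {
        res <- tibble::tibble(pl = stratum, feature = fe, measure = me,
                              rho = NA_real_, p_value = NA_real_, n = n)
      } else {
        ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
        res <- tibble::tibble(pl = stratum, feature = fe, measure = me,
                              rho = unname(ct$estimate),
                              p_value = ct$p.value, n = n)
      }
      out[[length(out) + 1L]] <- res
    }
  }
  dplyr::bind_rows(out)
}

#' Run the three-stage study analysis
#'
#' Executes the study's analysis sequence on a feature table (or a synthetic
#' dataset, which is first reduced to features): (1) subjective workload and
#' task performance across cognitive levels (mental-load manipulation
#' check) and across physical levels; (2) the effect of physical load on
#' every HRV feature, within each cognitive level; (3) Spearman correlations
#' of HRV features with the TLX total and mean RT, per physical-load
#' stratum.
#'
#' @param x a study dataset from [gen_study_dataset] or a feature table from
#'   [study_feature_table].
#' @param hrv_cols HRV feature columns used in stages 2-3.
#' @param load_cols stage-1 workload/performance columns.
#' @param ... passed to [study_feature_table] when `x` is a dataset.
#' @return A list of class `study_report`: `stage1_load`, `stage2_hrv`
#'   (tibbles of test results), `stage3_correlation`, plus the feature table.
#' @export
run_study_analysis <- function(x,
                               hrv_cols = c("meanHR", "SDNN", "RMSSD", "pNN50",
                                            "aLF", "aHF", "LF_HF", "nLF", "nHF"),
                               load_cols = c("TLX_total", "MRT", "SDRT", "CNR"),
                               ...) {
  features <- if (inherits(x, "study_dataset")) study_feature_table(x, ...) else x
  stop_if(!all(c("subject", "cl", "pl") %in% names(features)),
          "feature table needs subject, cl, pl columns")
  missing_load <- setdiff(load_cols, names(features))
  stop_if(length(missing_load) > 0,
          "stage 1 (load manipulation): missing columns ",
          paste(missing_load, collapse = ", "))
  stage1 <- dplyr::bind_rows(lapply(load_cols, function(fe) {
    dplyr::bind_rows(compare_repeated(features, fe, "cl"),
                     compare_repeated(features, fe, "pl"))
  }))
  missing_hrv <- setdiff(hrv_cols, names(features))
  stop_if(length(missing_hrv) > 0, "stage 2 (HRV vs load): missing columns ",
          paste(missing_hrv, collapse = ", "))
  stage2 <- dplyr::bind_rows(lapply(sort(unique(features$cl)), function(level) {
    sub <- features[features$cl == level, ]
    dplyr::bind_rows(lapply(hrv_cols, function(fe) {
      dplyr::mutate(compare_repeated(sub, fe, "pl"), cl = level,
                    .before = 1)
    }))
  }))
  stage3 <- correlate_load(features, hrv_cols,
                           intersect(c("TLX_total", "MRT"), names(features)))
  structure(list(stage1_load = stage1, stage2_hrv = stage2,
                 stage3_correlation = stage3, features = features),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  stage 1 (workload/performance vs load): %d tests\n",
              nrow(x$stage1_load)))
  cat(sprintf("  stage 2 (HRV vs physical load, per CL): %d tests\n",
              nrow(x$stage2_hrv)))
  cat(sprintf("  stage 3 (Spearman HRV ~ load measures): %d cells\n",
              nrow(x$stage3_correlation)))
  invisible(x)
}
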