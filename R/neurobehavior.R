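#' Fisher z-transformation of a correlation coefficient
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to ROI-to-ROI
#' Pearson correlations before they enter the neurobehavioral analysis.
#'
#' @param r Correlation value(s), strictly inside (-1, 1).
#' @return The z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("`r` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  atanh(r)
}

#' ROI-to-ROI connectivity profile from seed time series
#'
#' Pearson correlations between the mean time courses of the four auditory
#' seeds (lHG, rHG, lSTG, rSTG), Fisher z-transformed, for all six unordered
#' pairs.
#'
#' @param ts A numeric matrix or data frame with one column per ROI, named
#'   `lHG`, `rHG`, `lSTG`, `rSTG`; at least 30 samples, no missing values.
#' @param participant_id Identifier attached to the profile.
#' @return Tibble: `participant_id`, `pair`, `r`, `z`. A zero-variance ROI
#'   yields flagged-missing (`NA`) pairs with a warning; effectively
#'   duplicated series (|r| rounding to 1) are an error.
#' @export
roi_pairwise_fc <- function(ts, participant_id = "p01") {
  ts <- as.data.frame(ts)
  want <- c("lHG", "rHG", "lSTG", "rSTG")
  if (!all(want %in% names(ts))) {
    stop("`ts` needs columns ", paste(want, collapse = ", "), call. = FALSE)
  }
  ts <- ts[want]
  if (nrow(ts) < 30) stop(">= 30 samples required", call. = FALSE)
  if (anyNA(ts)) stop("missing values in ROI time series", call. = FALSE)
  sds <- vapply(ts, stats::sd, numeric(1))
  pairs <- strsplit(fc_pair_labels(), "-", fixed = TRUE)
  out <- lapply(pairs, function(p) {
    if (sds[p[1]] == 0 || sds[p[2]] == 0) {
      warning("zero-variance ROI in pair ", paste(p, collapse = "-"),
              "; pair flagged missing", call. = FALSE)
      return(tibble::tibble(pair = paste(p, collapse = "-"),
                            r = NA_real_, z = NA_real_))
    }
    r <- stats::cor(ts[[p[1]]], ts[[p[2]]])
    if (abs(r) >= 1 - 1e-12) {
      stop("ROI pair ", paste(p, collapse = "-"),
           " is perfectly correlated; Fisher z undefined", call. = FALSE)
    }
    tibble::tibble(pair = paste(p, collapse = "-"), r = r, z = fisher_z(r))
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(participant_id = participant_id, .before = 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha Family-wise alpha (default 0.05).
#' @param n_tests Number of independent tests per behavioral variable
#'   (default 7: six ROI pairs plus digit span).
#' @return The corrected per-test threshold (0.05/7 reported as 0.007).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests = 7) {
  family_alpha / n_tests
}

#' Neurobehavioral correlation table
#'
#' Pearson product-moment correlations between each behavioral/structural
#' measure and each predictor (six Fisher-z ROI-pair values plus digit
#' span), with two-sided p-values and a significance flag at the
#' Bonferroni-corrected threshold `family_alpha / n_tests` applied per
#' behavioral variable across its predictors. Missing values are handled by
#' pairwise-complete deletion and the effective n is reported per cell.
#'
#' @param fc Long tibble of z values (`participant_id`, `pair`, `z`), as
#'   from [simulate_fc()] or [roi_pairwise_fc()].
#' @param measures Tibble of per-participant measures (must contain
#'   `participant_id`; all remaining numeric columns are correlated), e.g.
#'   from [cohort_measures()].
#' @param digit_span Optional tibble (`participant_id`, `digit_span`) added
#'   as the seventh predictor.
#' @param family_alpha,n_tests Bonferroni family (see [bonferroni_alpha()]).
#' @return Tibble: `measure`, `predictor`, `r`, `p`, `n`, `significant`.
#'   Constant columns yield flagged-missing (`NA`) cells with a warning.
#' @export
correlate_behavior <- function(fc, measures, digit_span = NULL,
                               family_alpha = 0.05, n_tests = 7) {
  wide_fc <- tidyr_pivot(fc)
  pred <- wide_fc
  if (!is.null(digit_span)) {
    pred <- dplyr::left_join(pred, digit_span, by = "participant_id")
  }
  stopifnot(nrow(measures) >= 3)
  df <- dplyr::inner_join(measures, pred, by = "participant_id")
  measure_cols <- setdiff(names(measures), "participant_id")
  measure_cols <- measure_cols[vapply(measures[measure_cols], is.numeric,
                                      logical(1))]
  pred_cols <- setdiff(names(pred), "participant_id")
  alpha <- bonferroni_alpha(family_alpha, n_tests)
  grid <- expand.grid(measure = measure_cols, predictor = pred_cols,
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(k) {
    x <- df[[grid$measure[k]]]
    y <- df[[grid$predictor[k]]]
    keep <- stats::complete.cases(x, y)
    n_eff <- sum(keep)
    if (n_eff < 3 || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      warning("constant or insufficient data for ", grid$measure[k], " x ",
              grid$predictor[k], "; cell flagged missing", call. = FALSE)
      return(tibble::tibble(measure = grid$measure[k],
                            predictor = grid$predictor[k],
                            r = NA_real_, p = NA_real_, n = n_eff,
                            significant = NA))
    }
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson",
                          alternative = "two.sided")
    tibble::tibble(measure = grid$measure[k], predictor = grid$predictor[k],
                   r = unname(ct$estimate), p = ct$p.value, n = n_eff,
                   significant = ct$p.value < alpha)
  })
  out <- dplyr::bind_rows(cells)
  attr(out, "corrected_alpha") <- round(alpha, 3)
  out
}

# Long (participant, pair, z) -> wide, one column per ROI pair.
tidyr_pivot <- function(fc) {
  ids <- unique(fc$participant_id)
  cols <- lapply(fc_pair_labels(), function(p) {
    z <- fc$z[fc$pair == p][match(ids, fc$participant_id[fc$pair == p])]
    stats::setNames(list(z), p)
  })
  tibble::as_tibble(c(list(participant_id = ids), unlist(cols,
                                                         recursive = FALSE)))
}

#' Group-level descriptive statistics with one-sample Wilcoxon tests
#'
#' Per measure: median, mean, and a two-sided one-sample Wilcoxon
#' signed-rank test against 0. Zero differences are dropped, ties receive
#' average ranks, and the tie-corrected normal approximation supplies the
#' reported Z (common practice for n > 25). An all-zero measure leaves the
#' test flagged undefined.
#'
#' @param measures Tibble of per-participant measures (numeric columns).
#' @return Tibble: `measure`, `n`, `median`, `mean`, `V` (positive-rank
#'   sum), `z`, `p`.
#' @export
group_descriptives <- function(measures) {
  cols <- names(measures)[vapply(measures, is.numeric, logical(1))]
  if (nrow(measures) < 5) stop(">= 5 participants required", call. = FALSE)
  rows <- lapply(cols, function(m) {
    x <- measures[[m]]
    x <- x[!is.na(x)]
    nz <- x[x != 0]
    if (length(nz) == 0) {
      return(tibble::tibble(measure = m, n = length(x),
                            median = stats::median(x), mean = mean(x),
                            V = NA_real_, z = NA_real_, p = NA_real_))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x, mu = 0, alternative = "two.sided",
                         exact = FALSE, correct = FALSE)
    )
    rk <- rank(abs(nz))
    v <- sum(rk[nz > 0])
    n <- length(nz)
    ties <- table(rk)
    mu_v <- n * (n + 1) / 4
    sigma_v <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                      sum(ties^3 - ties) / 48)
    tibble::tibble(measure = m, n = length(x), median = stats::median(x),
                   mean = mean(x), V = v,
                   z = (v - mu_v) / sigma_v, p = wt$p.value)
  })
  dplyr::bind_rows(rows)
}

#' Write the neurobehavioral report
#'
#' Writes the correlation table as CSV plus a human-readable fixed-width
#' table in which cells significant under the Bonferroni-corrected
#' threshold are marked with `**` (the report's bolding marker). The CSV
#' round-trips through [readr::read_csv()].
#'
#' @param table A [correlate_behavior()] result.
#' @param descriptives An optional [group_descriptives()] result, appended
#'   to the text report.
#' @param path Output path stem: `<path>.csv` and `<path>.txt` are written.
#' @return Invisibly, the two paths.
#' @export
render_report <- function(table, descriptives = NULL, path) {
  csv <- paste0(path, ".csv")
  txt <- paste0(path, ".txt")
  readr::write_csv(table, csv)
  preds <- unique(table$predictor)
  lines <- c(
    sprintf("Pearson correlations; ** marks p < %.3f (Bonferroni)",
            attr(table, "corrected_alpha") %||% 0.007),
    sprintf("%-24s %s", "measure",
            paste(sprintf("%12s", preds), collapse = " "))
  )
  for (m in unique(table$measure)) {
    row <- table[table$measure == m, ]
    cells <- vapply(preds, function(p) {
      cell <- row[row$predictor == p, ]
      if (nrow(cell) == 0 || is.na(cell$r)) return(sprintf("%12s", "NA"))
      mark <- if (isTRUE(cell$significant)) "**" else ""
      sprintf("%12s", paste0(mark, sprintf("%.2f", cell$r), mark))
    }, character(1))
    lines <- c(lines, sprintf("%-24s %s", m, paste(cells, collapse = " ")))
  }
  if (!is.null(descriptives)) {
    lines <- c(lines, "", "Group descriptives (one-sample Wilcoxon vs 0):",
               utils::capture.output(print(as.data.frame(descriptives),
                                           digits = 3)))
  }
  writeLines(lines, txt)
  invisible(c(csv = csv, txt = txt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
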