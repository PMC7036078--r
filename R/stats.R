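# Cohort statistics: Kolmogorov-Smirnov normality gate, two-group
# comparison (pooled-variance t test when both samples pass the gate,
# Mann-Whitney U / Wilcoxon signed-rank otherwise) and the grouped
# intrinsic-vs-paced summary report.

#' One-sample Kolmogorov-Smirnov test against a normal distribution
#'
#' Tests the sample against a normal reference. By default the reference
#' mean/SD are the sample's own estimates (the procedure of mainstream
#' statistics packages; note the resulting null p-values are conservative).
#' Supplying the true `mean`/`sd` gives the classical KS test with exact
#' uniform null p-values. A constant sample is degenerate and flagged
#' non-normal.
#'
#' @param x numeric sample, `n >= 3`.
#' @param mean,sd reference parameters; default the sample estimates.
#' @param alpha significance level for the `normal` flag.
#' @return list with `statistic` (D), `p.value`, `normal`.
#' @export
ks_normality <- function(x, mean = NULL, sd = NULL, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 observations")
  if (is.null(mean)) mean <- base::mean(x)
  if (is.null(sd)) sd <- stats::sd(x)
  if (sd == 0) {
    return(list(statistic = 1, p.value = 0, normal = FALSE))
  }
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean, sd))
  list(
    statistic = unname(kt$statistic), p.value = kt$p.value,
    normal = kt$p.value > alpha
  )
}

#' Two-group comparison with a normality gate
#'
#' If both samples pass [ks_normality()] at `alpha` the comparison uses a t
#' test (pooled-variance independent-samples, or paired when `paired =
#' TRUE`); otherwise the Mann-Whitney U test (Wilcoxon signed-rank when
#' paired), with exact p-values for small untied samples and the
#' normal approximation with tie correction otherwise. The `method` argument
#' can force either path.
#'
#' @param a,b numeric samples (equal length when paired).
#' @param paired within-patient pairing flag (default `FALSE`: the
#'   independent-samples test).
#' @param alpha significance level.
#' @param method `"auto"` (normality gate), `"t"` or `"wilcoxon"`.
#' @return object of class `comparison_result`: list with `test`,
#'   `statistic`, `p.value`, `significant`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `n_a`, `n_b`, `paired`.
#' @export
compare_two_groups <- function(a, b, paired = FALSE, alpha = 0.05,
                               method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (paired && length(a) != length(b)) {
    stop("paired comparison needs equal-length samples")
  }
  if (min(length(a), length(b)) < 2) {
    return(structure(
      list(
        test = "insufficient n", statistic = NA_real_, p.value = NA_real_,
        significant = FALSE,
        mean_a = base::mean(a), sd_a = stats::sd(a),
        mean_b = base::mean(b), sd_b = stats::sd(b),
        n_a = length(a), n_b = length(b), paired = paired
      ),
      class = "comparison_result"
    ))
  }
  if (method == "auto") {
    # normality is untestable below n = 3; fall through to the t path there
    method <- if (min(length(a), length(b)) < 3 ||
      (ks_normality(a, alpha = alpha)$normal &&
        ks_normality(b, alpha = alpha)$normal)) {
      "t"
    } else {
      "wilcoxon"
    }
  }
  degenerate <- stats::sd(c(a, b)) == 0 ||
    (paired && stats::sd(a - b) == 0) ||
    (!paired && stats::sd(a) == 0 && stats::sd(b) == 0 &&
      base::mean(a) == base::mean(b))
  if (degenerate) {
    test <- if (method == "t") "t (degenerate)" else "wilcoxon (degenerate)"
    statistic <- 0
    p <- 1
  } else if (method == "t") {
    test <- if (paired) "paired t" else "independent t"
    no_spread <- if (paired) stats::sd(a - b) == 0 else
      stats::sd(a) == 0 && stats::sd(b) == 0
    if (no_spread) { # constant data, unequal means: infinite evidence
      statistic <- sign(base::mean(a) - base::mean(b)) * Inf
      p <- 0
    } else {
      tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
      statistic <- unname(tt$statistic)
      p <- tt$p.value
    }
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
    test <- if (paired) "wilcoxon signed-rank" else "mann-whitney U"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
    if (is.na(p)) p <- 1 # fully tied samples
  }
  structure(
    list(
      test = test, statistic = statistic, p.value = p,
      significant = p < alpha,
      mean_a = base::mean(a), sd_a = stats::sd(a),
      mean_b = base::mean(b), sd_b = stats::sd(b),
      n_a = length(a), n_b = length(b), paired = paired
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "%s: %.2f +/- %.2f (n=%d) vs %.2f +/- %.2f (n=%d), statistic %.3f, p = %.4g%s\n",
    x$test, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
    x$statistic, x$p.value, if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Grouped intrinsic-vs-paced summary report
#'
#' Mean +/- SD per metric for the intrinsic and paced state with the
#' between-state p-value, computed over all patients and within the apical
#' and septal subgroups (subgroups without patients are omitted). The
#' comparison defaults to the independent-samples test; set `paired = TRUE`
#' for the within-patient paired variant. Optionally applies Holm adjustment
#' across metrics within each group (off by default).
#'
#' @param cohort a `cohort_table`.
#' @param paired use paired tests (default `FALSE`).
#' @param alpha significance level.
#' @param holm apply Holm multiplicity adjustment per group.
#' @return data.frame with one row per metric x group: `metric`, `group`,
#'   `n`, `intrinsic_mean`, `intrinsic_sd`, `paced_mean`, `paced_sd`,
#'   `test`, `statistic`, `p_value`, `significant`.
#' @export
table2_report <- function(cohort, paired = FALSE, alpha = 0.05, holm = FALSE) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  cohort <- cohort[order(cohort$patient_id, cohort$state), ]
  cols <- c("vvsync_ms", "vvtat_ms", "lvtat_ms", "lvdisp_ms", "wfa_deg")
  groups <- c("all", intersect(c("apical", "septal"), cohort$lead_position))
  rows <- list()
  for (g in groups) {
    sub <- if (g == "all") cohort else cohort[cohort$lead_position == g, ]
    intr <- sub[sub$state == "intrinsic", ]
    pac <- sub[sub$state == "paced", ]
    if (nrow(intr) == 0 || nrow(intr) != nrow(pac)) {
      stop("cohort must hold one intrinsic and one paced record per patient")
    }
    res <- lapply(cols, function(cl) {
      compare_two_groups(intr[[cl]], pac[[cl]], paired = paired, alpha = alpha)
    })
    p <- vapply(res, function(r) r$p.value, numeric(1))
    if (holm) p <- stats::p.adjust(p, method = "holm")
    rows[[g]] <- data.frame(
      metric = sub("_(ms|deg)$", "", cols), group = g, n = nrow(intr),
      intrinsic_mean = vapply(res, function(r) r$mean_a, numeric(1)),
      intrinsic_sd = vapply(res, function(r) r$sd_a, numeric(1)),
      paced_mean = vapply(res, function(r) r$mean_b, numeric(1)),
      paced_sd = vapply(res, function(r) r$sd_b, numeric(1)),
      test = vapply(res, function(r) r$test, character(1)),
      statistic = vapply(res, function(r) r$statistic, numeric(1)),
      p_value = p,
      significant = !is.na(p) & p < alpha,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
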