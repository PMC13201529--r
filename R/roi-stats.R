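#' Aggregate parametric maps over regions of interest
#'
#' Region value = mean over in-mask voxels. Bilateral regions (given as a
#' left/right mask pair) are averaged across hemispheres; unilateral
#' regions are kept as-is; empty masks are marked missing and skipped.
#'
#' @param maps A `zap_maps` object or a named list of 3D arrays.
#' @param masks Named list: each element either a logical array (unilateral)
#'   or a list of two logical arrays (bilateral pair).
#' @param metrics Which map names to aggregate.
#' @param subject_id Optional id attached to the rows.
#' @param age,group Optional covariates attached to the rows.
#' @return `cohort_table`-shaped rows (`subject_id`, `age`, `group`,
#'   `region`, `metric`, `value`); missing regions are omitted.
#' @export
aggregate_roi <- function(maps, masks,
                          metrics = c("f_f", "t2f_us", "t2r_us"),
                          subject_id = "S001", age = NA_real_,
                          group = NA_character_) {
  one_side <- function(map, mask) {
    if (!any(mask)) return(NA_real_)
    mean(map[mask], na.rm = TRUE)
  }
  out <- list()
  for (region in names(masks)) {
    m <- masks[[region]]
    sides <- if (is.list(m)) m else list(m)
    for (metric in metrics) {
      map <- maps[[metric]]
      if (is.null(map)) next
      vals <- vapply(sides, function(s) one_side(map, s), numeric(1))
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next                 # region missing: skip
      out[[length(out) + 1L]] <- data.frame(
        subject_id = subject_id, age = age, group = group,
        region = region, metric = metric, value = mean(vals))
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  class(res) <- c("cohort_table", "data.frame")
  res
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Rank correlation with midranks for ties; the 95% CI comes from the
#' Fisher z-transform with standard error `1/sqrt(n - 3)` and the two-sided
#' p-value from the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Paired observations (e.g. age and a regional metric).
#' @param conf_level Confidence level of the interval.
#' @return A list of class `roi_stat`: `rho`, `ci95`, `p`, `n`,
#'   `test_used = "spearman"`. Constant input yields `rho = NA` with a
#'   warning.
#' @export
spearman_ci <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; rho undefined")
    return(structure(list(rho = NA_real_, ci95 = c(NA_real_, NA_real_),
                          p = NA_real_, n = n, test_used = "spearman"),
                     class = "roi_stat"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
    ci <- c(sign(rho), sign(rho))
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    zr <- atanh(rho)
    zq <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
    ci <- tanh(c(zr - zq, zr + zq))
  }
  structure(list(rho = rho, ci95 = ci, p = p, n = n,
                 test_used = "spearman"),
            class = "roi_stat")
}

#' Normality-gated two-group comparison
#'
#' Each group is tested for normality (Shapiro-Wilk at alpha = 0.05). When
#' both groups pass, an independent two-sample t-test is used and groups
#' are summarised as mean (SD); otherwise a Mann-Whitney U test (exact when
#' sample sizes permit and no ties) with median (IQR) summaries. Groups
#' smaller than 3 skip the normality gate and go straight to the
#' nonparametric branch.
#'
#' @param values Numeric vector of metric values.
#' @param groups Factor-like with exactly two levels.
#' @param alpha_normality Gate level for Shapiro-Wilk.
#' @param test `"auto"` (normality-gated, the default) or force `"t"` /
#'   `"mann-whitney"`.
#' @return A list of class `roi_stat`: `p`, `test_used` ("t" or
#'   "mann-whitney"), `estimate` (difference level1 - level2 location),
#'   `group_summaries` (per level: n, mean, sd, median, iqr, label),
#'   `significant` at p < 0.05, `n`.
#' @export
group_compare <- function(values, groups, alpha_normality = 0.05,
                          test = c("auto", "t", "mann-whitney")) {
  test <- match.arg(test)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  if (!length(g1) || !length(g2)) stop("both groups must be non-empty")
  if (test == "auto") {
    small <- min(length(g1), length(g2)) < 3L
    if (small) {
      warning("group size < 3; normality gate skipped, using Mann-Whitney")
      normal <- FALSE
    } else {
      sw_ok <- function(g) {
        if (stats::sd(g) == 0) return(FALSE)
        stats::shapiro.test(g)$p.value >= alpha_normality
      }
      normal <- sw_ok(g1) && sw_ok(g2)
    }
  } else {
    normal <- test == "t"
  }
  if (normal) {
    ht <- stats::t.test(g1, g2, var.equal = TRUE)
    test_used <- "t"
    est <- mean(g1) - mean(g2)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(g1, g2))
    test_used <- "mann-whitney"
    est <- stats::median(g1) - stats::median(g2)
  }
  summ <- lapply(list(g1, g2), function(g) {
    list(n = length(g), mean = mean(g), sd = stats::sd(g),
         median = stats::median(g),
         iqr = stats::quantile(g, c(0.25, 0.75), names = FALSE),
         label = if (test_used == "t")
           sprintf("%.2f (%.2f)", mean(g), stats::sd(g))
         else sprintf("%.2f (%.2f-%.2f)", stats::median(g),
                      stats::quantile(g, 0.25), stats::quantile(g, 0.75)))
  })
  names(summ) <- levels(groups)
  structure(list(p = ht$p.value, test_used = test_used, estimate = est,
                 group_summaries = summ, significant = ht$p.value < 0.05,
                 n = length(values)),
            class = "roi_stat")
}

#' @export
print.roi_stat <- function(x, ...) {
  if (identical(x$test_used, "spearman")) {
    cat(sprintf("Spearman rho = %.3f (95%% CI %.3f to %.3f), p = %.4g, n = %d\n",
                x$rho, x$ci95[1], x$ci95[2], x$p, x$n))
  } else {
    cat(sprintf("%s test: p = %.4g%s\n", x$test_used, x$p,
                if (isTRUE(x$significant)) " *" else ""))
    for (nm in names(x$group_summaries))
      cat(sprintf("  %s: %s\n", nm, x$group_summaries[[nm]]$label))
  }
  invisible(x)
}

#' Build the region-wise aging report from a cohort table
#'
#' For every region/metric cell: Spearman correlation of value with age
#' (with CI and p), and the normality-gated younger/older comparison with
#' the matching summary convention. Optional CEST detection columns (a
#' logical `detected` metric) are reported as detection-rate strings.
#' No multiple-testing correction is applied by default, matching the
#' per-cell p < 0.05 convention; set `p_adjust = "BH"` for
#' Benjamini-Hochberg adjusted columns.
#'
#' @param cohort A `cohort_table`.
#' @param group_cut Age split (years) if `group` is absent.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A list of class `zap_report`: `correlations` and `comparisons`
#'   data frames, and `detection` (possibly empty).
#' @export
build_report <- function(cohort, group_cut = 65, p_adjust = "none") {
  stopifnot(all(c("age", "region", "metric", "value") %in% names(cohort)))
  if (!"group" %in% names(cohort) || all(is.na(cohort$group)))
    cohort$group <- ifelse(cohort$age >= group_cut, "older", "younger")
  cohort$group <- factor(cohort$group, levels = c("younger", "older"))
  cells <- unique(cohort[, c("region", "metric")])
  cors <- list(); cmps <- list(); dets <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- cohort[cohort$region == cells$region[i] &
                    cohort$metric == cells$metric[i], ]
    if (all(is.na(sub$value))) {
      warning(sprintf("metric %s empty in region %s; omitted",
                      cells$metric[i], cells$region[i]))
      next
    }
    if (grepl("^detected", cells$metric[i])) {
      dr <- detection_rate(sub$value > 0)
      dets[[length(dets) + 1L]] <- data.frame(
        region = cells$region[i], metric = cells$metric[i],
        rate = dr$rate, label = dr$label)
      next
    }
    sp <- spearman_ci(sub$age, sub$value)
    cors[[length(cors) + 1L]] <- data.frame(
      region = cells$region[i], metric = cells$metric[i],
      n = sp$n, rho = sp$rho, ci_lo = sp$ci95[1], ci_hi = sp$ci95[2],
      p = sp$p)
    gc <- group_compare(sub$value, sub$group)
    cmps[[length(cmps) + 1L]] <- data.frame(
      region = cells$region[i], metric = cells$metric[i],
      test = gc$test_used,
      younger = gc$group_summaries$younger$label,
      older = gc$group_summaries$older$label,
      p = gc$p)
  }
  bindf <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame()
  correlations <- bindf(cors); comparisons <- bindf(cmps)
  if (nrow(correlations)) {
    if (p_adjust != "none") {
      correlations$p_adj <- stats::p.adjust(correlations$p, p_adjust)
      comparisons$p_adj <- stats::p.adjust(comparisons$p, p_adjust)
    }
    correlations$significant <- correlations$p < 0.05
    comparisons$significant <- comparisons$p < 0.05
  }
  structure(list(correlations = correlations, comparisons = comparisons,
                 detection = bindf(dets)),
            class = "zap_report")
}

#' @export
print.zap_report <- function(x, ...) {
  cat("Age correlations (Spearman):\n")
  if (nrow(x$correlations)) {
    df <- x$correlations
    df$cell <- sprintf("%.3f (%.3f)%s", df$rho, df$p,
                       ifelse(df$significant, " *", ""))
    print(df[, c("region", "metric", "n", "cell")], row.names = FALSE)
  }
  cat("\nYounger vs older comparisons:\n")
  if (nrow(x$comparisons))
    print(x$comparisons[, c("region", "metric", "test", "younger",
                            "older", "p")], row.names = FALSE)
  if (nrow(x$detection)) {
    cat("\nDetection rates:\n")
    print(x$detection[, c("region", "metric", "label")], row.names = FALSE)
  }
  invisible(x)
}
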