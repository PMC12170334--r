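# Per-case statistical analysis relating wall shear to fibrosis and
# electrical scar: pairwise Pearson correlations, TAWSS quartile analysis,
# threshold classification, pooled chi-square, Fisher-z group comparison and
# normality-driven test selection.

#' Per-case Pearson correlations between hemodynamic and clinical fields
#'
#' Pearson r with two-sided p for the canonical variable pairs
#' (TAWSS-BV, TAWSS-IIR, TAWSS-BA, BA-BV, BV-IIR), or any pairs present in
#' the table. Undefined entries are deleted pairwise; per-pair exclusion
#' counts are reported.
#'
#' @param case_table data frame with (a subset of) columns `tawss`, `osi`,
#'   `ecap`, `rrt`, `holmes`, `wssg`, `ba`, `bv`, `iir`.
#' @param pairs 2-column character matrix of variable pairs; default the
#'   five canonical pairs restricted to available columns.
#' @return tibble with `var1`, `var2`, `n`, `n_excluded`, `r`, `p`.
#' @export
per_case_correlations <- function(case_table, pairs = NULL) {
  if (is.null(pairs)) {
    canonical <- rbind(c("tawss", "bv"), c("tawss", "iir"), c("tawss", "ba"),
                       c("ba", "bv"), c("bv", "iir"))
    keep <- canonical[, 1] %in% names(case_table) &
      canonical[, 2] %in% names(case_table)
    pairs <- canonical[keep, , drop = FALSE]
  }
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    x <- case_table[[pairs[k, 1]]]
    y <- case_table[[pairs[k, 2]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 10)
      return(tibble::tibble(var1 = pairs[k, 1], var2 = pairs[k, 2],
                            n = n, n_excluded = length(x) - n,
                            r = NA_real_, p = NA_real_,
                            note = "fewer than 10 paired defined values"))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(tibble::tibble(var1 = pairs[k, 1], var2 = pairs[k, 2],
                            n = n, n_excluded = length(x) - n,
                            r = NA_real_, p = NA_real_,
                            note = "zero variance"))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                          alternative = "two.sided")
    tibble::tibble(var1 = pairs[k, 1], var2 = pairs[k, 2], n = n,
                   n_excluded = length(x) - n,
                   r = unname(ct$estimate), p = ct$p.value, note = "")
  })
  do.call(rbind, res)
}

#' Assign empirical quartiles of a variable
#'
#' Cut points at the empirical 25/50/75 percentiles; boundary values go to
#' the lower quartile. Assignment is invariant to adding a constant.
#'
#' @param x numeric vector (NA allowed).
#' @return integer vector of quartile numbers 1-4 (NA where x is NA).
#' @export
assign_quartiles <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  out <- rep(NA_integer_, length(x))
  ok <- is.finite(x)
  out[ok] <- 1L + (x[ok] > q[1]) + (x[ok] > q[2]) + (x[ok] > q[3])
  out
}

#' Quartile analysis of responses across TAWSS quartiles
#'
#' Splits the case at the empirical TAWSS quartiles and summarizes each
#' response variable per quartile (mean, SD, median, IQR, n), with a
#' two-sided Kruskal-Wallis test across the four groups per response.
#'
#' @param case_table data frame with a `tawss` column and response columns.
#' @param responses character vector of response column names (default all
#'   of `bv`, `iir`, `ba` that are present).
#' @return list with `summary` (tibble: response, quartile, n, mean, sd,
#'   median, iqr), `tests` (tibble: response, statistic, df, p), and the
#'   `quartile` assignment vector.
#' @export
quartile_analysis <- function(case_table, responses = NULL) {
  stopifnot("tawss" %in% names(case_table))
  if (is.null(responses))
    responses <- intersect(c("bv", "iir", "ba"), names(case_table))
  qt <- assign_quartiles(case_table$tawss)
  if (length(unique(stats::na.omit(qt))) < 4L)
    warning("heavy ties collapsed a quartile; boundary values kept in the ",
            "lower quartile")
  summ <- list(); tst <- list()
  for (v in responses) {
    y <- case_table[[v]]
    ok <- is.finite(y) & !is.na(qt)
    g <- factor(qt[ok], levels = 1:4)
    s <- tibble::tibble(
      response = v,
      quartile = paste0("Q", 1:4),
      n = as.integer(table(g)),
      mean = as.numeric(tapply(y[ok], g, mean)),
      sd = as.numeric(tapply(y[ok], g, stats::sd)),
      median = as.numeric(tapply(y[ok], g, stats::median)),
      iqr = as.numeric(tapply(y[ok], g, stats::IQR)))
    kw <- stats::kruskal.test(y[ok], g)
    summ[[v]] <- s
    tst[[v]] <- tibble::tibble(response = v,
                               statistic = unname(kw$statistic),
                               df = unname(kw$parameter), p = kw$p.value)
  }
  list(summary = do.call(rbind, summ), tests = do.call(rbind, tst),
       quartile = qt)
}

#' Classify fibrosis and electrical scar from IIR and BV
#'
#' Fibrosis: image intensity ratio at or above the threshold (inclusive).
#' Electrical scar: bipolar voltage strictly below the threshold.
#'
#' @param iir [scalar_field()] or numeric, image intensity ratio.
#' @param bv [scalar_field()] or numeric, bipolar voltage in mV.
#' @param iir_threshold inclusive fibrosis threshold (default 1.2).
#' @param bv_threshold_mV strict scar threshold in mV (default 0.5).
#' @return list with logical vectors `fibrosis`, `scar`, the thresholds,
#'   and `counts`.
#' @export
classify_fibrosis <- function(iir, bv, iir_threshold = 1.2,
                              bv_threshold_mV = 0.5) {
  iir <- as.numeric(iir); bv <- as.numeric(bv)
  fibrosis <- iir >= iir_threshold
  scar <- bv < bv_threshold_mV
  list(fibrosis = fibrosis, scar = scar,
       iir_threshold = iir_threshold, bv_threshold_mV = bv_threshold_mV,
       counts = c(fibrosis = sum(fibrosis, na.rm = TRUE),
                  scar = sum(scar, na.rm = TRUE)))
}

#' Pooled chi-square of flag prevalence across TAWSS quartiles
#'
#' 4 x 2 contingency (quartile x flag) chi-square without continuity
#' correction, pooled over cases, with per-quartile prevalence.
#'
#' @param flags logical vector (e.g. fibrosis or scar flags, pooled).
#' @param quartiles integer vector of quartile numbers 1-4, same length.
#' @return list with `statistic`, `df`, `p`, `prevalence` (per quartile),
#'   and the contingency `table`.
#' @export
pooled_quartile_chisq <- function(flags, quartiles) {
  ok <- !is.na(flags) & !is.na(quartiles)
  flags <- flags[ok]; quartiles <- quartiles[ok]
  if (!all(1:4 %in% unique(quartiles))) stop("empty quartile")
  tab <- table(factor(quartiles, levels = 1:4),
               factor(flags, levels = c(FALSE, TRUE)))
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts < 5))
    warning("expected count below 5 in the contingency table")
  cs <- stats::chisq.test(tab, correct = FALSE)
  prev <- tab[, 2] / rowSums(tab)
  list(statistic = unname(cs$statistic), df = unname(cs$parameter),
       p = cs$p.value, prevalence = as.numeric(prev), table = tab)
}

#' Compare two groups of correlation coefficients via Fisher z
#'
#' Each r is variance-stabilized by the Fisher transform `atanh(r)`; the
#' group means of the transformed values are compared with a Welch t-test
#' (two-sided).
#'
#' @param group_a,group_b numeric vectors of per-case correlations, each in
#'   (-1, 1), at least 2 per group.
#' @return list with `statistic`, `p`, `df`, and the transformed group
#'   means `z_mean_a`, `z_mean_b`.
#' @export
compare_correlations_fisher <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (any(abs(c(group_a, group_b)) >= 1))
    stop("|r| = 1 overflows the Fisher transform")
  za <- atanh(group_a); zb <- atanh(group_b)
  if (stats::sd(za) == 0 && stats::sd(zb) == 0 && mean(za) == mean(zb))
    return(list(statistic = 0, p = 1, df = NA_real_,
                z_mean_a = mean(za), z_mean_b = mean(zb)))
  tt <- stats::t.test(za, zb, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), z_mean_a = mean(za), z_mean_b = mean(zb))
}

#' Normality-driven selection of a group-comparison test
#'
#' Mirrors the analysis plan for continuous variables: Shapiro-Wilk per
#' group at alpha = 0.05; if any group is non-normal, Kruskal-Wallis;
#' otherwise Levene's test (Brown-Forsythe form, absolute deviations from
#' the median) decides between classical ANOVA (variances homogeneous) and
#' Welch's ANOVA.
#'
#' @param groups list of numeric vectors (>= 2 groups, >= 3 values each).
#' @param alpha decision level (default 0.05).
#' @return list with `test` (one of `"anova"`, `"welch"`,
#'   `"kruskal-wallis"`), `statistic`, `p`, and a `decision_trail` tibble
#'   (step, statistic, p, decision).
#' @export
auto_test_selection <- function(groups, alpha = 0.05) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 3))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  trail <- list()
  sw_p <- vapply(groups, function(x) {
    if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0)
      return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  if (anyNA(sw_p)) {
    warning("Shapiro-Wilk not applicable to a group; using Kruskal-Wallis")
    kw <- stats::kruskal.test(y, g)
    return(list(test = "kruskal-wallis", statistic = unname(kw$statistic),
                p = kw$p.value,
                decision_trail = tibble::tibble(
                  step = "shapiro-wilk", statistic = NA_real_, p = NA_real_,
                  decision = "not applicable -> kruskal-wallis")))
  }
  trail[[1]] <- tibble::tibble(step = "shapiro-wilk",
                               statistic = NA_real_, p = min(sw_p),
                               decision = if (any(sw_p < alpha))
                                 "non-normal -> kruskal-wallis"
                               else "normal -> check variances")
  if (any(sw_p < alpha)) {
    kw <- stats::kruskal.test(y, g)
    return(list(test = "kruskal-wallis", statistic = unname(kw$statistic),
                p = kw$p.value, decision_trail = do.call(rbind, trail)))
  }
  # Brown-Forsythe / Levene: ANOVA on |y - median(group)|
  dev <- unlist(lapply(groups, function(x) abs(x - stats::median(x))))
  lev <- stats::oneway.test(dev ~ g, var.equal = TRUE)
  trail[[2]] <- tibble::tibble(step = "levene",
                               statistic = unname(lev$statistic),
                               p = lev$p.value,
                               decision = if (lev$p.value < alpha)
                                 "heteroscedastic -> welch" else
                                   "homoscedastic -> anova")
  if (lev$p.value < alpha) {
    w <- stats::oneway.test(y ~ g, var.equal = FALSE)
    list(test = "welch", statistic = unname(w$statistic), p = w$p.value,
         decision_trail = do.call(rbind, trail))
  } else {
    a <- stats::oneway.test(y ~ g, var.equal = TRUE)
    list(test = "anova", statistic = unname(a$statistic), p = a$p.value,
         decision_trail = do.call(rbind, trail))
  }
}

#' Assemble a per-case vertex table
#'
#' Collects the per-vertex hemodynamic indices, mapped clinical fields,
#' region labels and TAWSS quartiles into one table, the input to the
#' statistical operations.
#'
#' @param indices a `shear_index_set`.
#' @param ba optional blood-age [scalar_field()].
#' @param bv,iir optional clinical `scalar_field`s.
#' @param unfolded optional `unfolded_map` with regions assigned.
#' @param case_id case identifier.
#' @return tibble with one row per vertex. Undefined ECAP/RRT are NA.
#' @export
case_vertex_table <- function(indices, ba = NULL, bv = NULL, iir = NULL,
                              unfolded = NULL, case_id = "case") {
  n <- length(indices$tawss)
  tb <- tibble::tibble(
    case = case_id,
    vertex = seq_len(n),
    tawss = indices$tawss,
    osi = indices$osi,
    ecap = ifelse(indices$ecap_defined, indices$ecap, NA_real_),
    rrt = ifelse(indices$rrt_defined, indices$rrt, NA_real_),
    holmes = indices$holmes)
  if (!is.null(ba)) tb$ba <- as.numeric(ba)
  if (!is.null(bv)) tb$bv <- as.numeric(bv)
  if (!is.null(iir)) tb$iir <- as.numeric(iir)
  if (!is.null(unfolded) && !is.null(unfolded$region))
    tb$region <- unfolded$region
  tb$quartile <- assign_quartiles(tb$tawss)
  tb
}
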