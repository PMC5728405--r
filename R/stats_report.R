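# Condition-level statistics shared by all assays: mean +/- SEM, two-tailed
# t-tests with the figure-legend star conventions, and clonogenic
# surviving-fraction arithmetic.

#' Mean and standard error of the mean
#'
#' SEM uses the n-1 denominator standard deviation; with a single value the
#' mean is returned and the SEM is `NA` (flagged undefined).
#'
#' @param values numeric vector, n >= 1.
#' @return list: `n`, `mean`, `sem`.
#' @export
mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("mean_sem needs at least one value", call. = FALSE)
  list(n = n, mean = mean(values),
       sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_)
}

#' Two-tailed two-sample t-test p-value
#'
#' Student's pooled-variance test by default (the figure-legend convention),
#' Welch available.  Identical groups give p = 1.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return two-sided p-value.
#' @export
two_tailed_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b, var.equal = variant == "student")$p.value
}

#' Significance stars for a p-value
#'
#' The figure-legend convention: `***` below 0.0005, `**` below 0.005, `*`
#' below 0.05, `ns` otherwise.  Tiers are configurable (some legends use
#' `**` for p < 0.001 instead).
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param tiers decreasing thresholds for `*`, `**`, `***`.
#' @return character vector of labels.
#' @export
star_annotation <- function(p, tiers = c(0.05, 0.005, 0.0005)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), length(tiers) == 3,
            all(diff(tiers) < 0))
  out <- rep("ns", length(p))
  out[p < tiers[1]] <- "*"
  out[p < tiers[2]] <- "**"
  out[p < tiers[3]] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Clonogenic surviving fraction
#'
#' `SF = (colonies / seeded) / plating_efficiency`, where the plating
#' efficiency is the untreated colonies-per-cell-seeded of the same
#' treatment arm, so the untreated point is 1 by self-normalisation.
#'
#' @param colonies colonies counted (>= 0).
#' @param seeded cells seeded (> 0).
#' @param plating_efficiency untreated colonies/seeded for the same arm
#'   (> 0).
#' @return surviving fraction(s).
#' @export
surviving_fraction <- function(colonies, seeded, plating_efficiency) {
  stopifnot(all(colonies >= 0))
  if (any(seeded <= 0)) stop("seeded must be positive", call. = FALSE)
  if (any(plating_efficiency <= 0))
    stop("plating efficiency must be positive", call. = FALSE)
  (colonies / seeded) / plating_efficiency
}

#' Condition summary with t-test against a control
#'
#' Per-condition mean +/- SEM plus a two-tailed t-test p-value and star
#' annotation against the control condition.
#'
#' @param values numeric vector of per-replicate (or per-cell) values.
#' @param condition condition label per value.
#' @param control label of the control condition.
#' @param variant t-test variant, see [two_tailed_t()].
#' @param tiers star tiers, see [star_annotation()].
#' @return data.frame, one row per condition: `condition`, `n`, `mean`,
#'   `sem`, `p_vs_control`, `stars`.
#' @export
condition_stats <- function(values, condition, control,
                            variant = c("student", "welch"),
                            tiers = c(0.05, 0.005, 0.0005)) {
  variant <- match.arg(variant)
  stopifnot(length(values) == length(condition), control %in% condition)
  ctrl <- values[condition == control]
  out <- do.call(rbind, lapply(unique(condition), function(cond) {
    v <- values[condition == cond]
    s <- mean_sem(v)
    p <- if (cond == control) NA_real_ else two_tailed_t(v, ctrl, variant)
    data.frame(condition = cond, n = s$n, mean = s$mean, sem = s$sem,
               p_vs_control = p,
               stars = if (is.na(p)) NA_character_ else star_annotation(p, tiers))
  }))
  rownames(out) <- NULL
  out
}
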