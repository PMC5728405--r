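# Standard-curve relative quantification and derived splicing/export
# indices: log-linear fit per primer set, efficiency from the slope,
# reference-gene normalisation, fractionation-purity and RT-minus QC.

#' Fit a qPCR standard curve
#'
#' Least-squares line `Cq ~ log10(concentration)` over an in-run dilution
#' series; amplification efficiency is `10^(-1/slope)` (2.0 for a perfect
#' doubling per cycle).
#'
#' @param dilution_log10 log10 relative concentrations of the standards.
#' @param cq measured Cq values, same length.
#' @return list of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n_points`.
#' @export
fit_standard_curve <- function(dilution_log10, cq) {
  stopifnot(length(dilution_log10) == length(cq))
  ok <- is.finite(dilution_log10) & is.finite(cq)
  dilution_log10 <- dilution_log10[ok]; cq <- cq[ok]
  if (length(cq) < 3)
    stop("standard-curve fit needs at least 3 points", call. = FALSE)
  if (length(unique(dilution_log10)) < 2)
    stop("standard-curve fit needs at least 2 distinct dilutions", call. = FALSE)
  fit <- stats::lm(cq ~ dilution_log10)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-8)
    stop("degenerate standard curve: zero slope", call. = FALSE)
  if (slope > 0)
    warning("positive standard-curve slope; check dilution orientation")
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope), r_squared = r2,
                 n_points = length(cq)),
            class = "standard_curve")
}

#' Relative concentration from a Cq value
#'
#' Inverts the standard curve: `10^((cq - intercept) / slope)`, in the
#' relative units of the dilution series.
#'
#' @param cq Cq value(s).
#' @param curve a [fit_standard_curve()] result.
#' @return relative concentration(s); `NA` Cq (no amplification) maps to 0.
#' @export
quantify <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  out <- 10^((cq - curve$intercept) / curve$slope)
  out[is.na(cq)] <- 0
  out
}

#' Normalise target concentrations to a reference gene
#'
#' Elementwise target/reference over matched samples; samples with a
#' non-positive reference are flagged `NA`.
#'
#' @param target,reference numeric vectors of relative concentrations,
#'   matched by position.
#' @return normalised values, `NA` where the reference is not positive.
#' @export
normalize_to_reference <- function(target, reference) {
  stopifnot(length(target) == length(reference))
  out <- ifelse(reference > 0, target / reference, NA_real_)
  if (anyNA(out)) attr(out, "flagged") <- which(is.na(out))
  out
}

#' Fractionation purity check via a nuclear-retained transcript
#'
#' The cytoplasmic fraction passes when the cytoplasmic/nuclear level of the
#' nuclear-retained control RNA (e.g. MALAT1) does not exceed `max_ratio`.
#'
#' @param marker_cyto,marker_nuc relative levels of the nuclear-retained
#'   control transcript in the cytoplasmic and nuclear fractions.
#' @param max_ratio maximum tolerated cytoplasmic/nuclear ratio (default
#'   0.1).
#' @return `"pass"`, `"fail"`, or `"indeterminate"` (nuclear level zero).
#' @export
purity_check <- function(marker_cyto, marker_nuc, max_ratio = 0.1) {
  stopifnot(marker_cyto >= 0, marker_nuc >= 0, max_ratio > 0)
  if (marker_nuc == 0) return("indeterminate")
  if (marker_cyto / marker_nuc > max_ratio) "fail" else "pass"
}

#' RT-minus contamination check per primer
#'
#' A primer fails when its RT-minus well amplified (a finite Cq where the
#' no-amplification sentinel `NA` was expected), indicating genomic DNA
#' contamination.
#'
#' @param cq_rt_minus named numeric vector of RT-minus Cq values per primer;
#'   `NA` = no amplification.
#' @return named character vector, `"pass"`/`"fail"` per primer.
#' @export
rt_minus_check <- function(cq_rt_minus) {
  out <- ifelse(is.na(cq_rt_minus), "pass", "fail")
  stats::setNames(out, names(cq_rt_minus))
}

#' End-to-end quantification of a Cq table
#'
#' Fits the in-run standard curve of every primer, converts unknown wells to
#' relative concentrations, and averages technical replicates (on the
#' concentration scale by default).
#'
#' @param cq_table data.frame as produced by [generate_cq_table()].
#' @param average `"concentration"` (default) or `"cq"` — the scale on which
#'   technical replicates are combined.
#' @return list with `curves` (per-primer [fit_standard_curve()] results),
#'   `concentrations` (data.frame: `primer`, `sample`, `condition`,
#'   `compartment`, `concentration`) and `rt_minus` (QC per primer).
#' @export
quantify_cq_table <- function(cq_table, average = c("concentration", "cq")) {
  average <- match.arg(average)
  primers <- unique(cq_table$primer)
  curves <- lapply(stats::setNames(primers, primers), function(p) {
    std <- cq_table[cq_table$primer == p & cq_table$sample_type == "standard", ]
    if (nrow(std) == 0) stop("no standards for primer ", p, call. = FALSE)
    fit_standard_curve(std$log10_conc, std$cq)
  })
  unk <- cq_table[cq_table$sample_type == "unknown", ]
  key <- interaction(unk$primer, unk$sample, unk$condition, unk$compartment,
                     drop = TRUE)
  conc <- do.call(rbind, lapply(split(unk, key), function(g) {
    curve <- curves[[g$primer[1]]]
    value <- if (average == "concentration") {
      mean(quantify(g$cq, curve))
    } else {
      quantify(mean(g$cq), curve)
    }
    data.frame(primer = g$primer[1], sample = g$sample[1],
               condition = g$condition[1], compartment = g$compartment[1],
               concentration = value)
  }))
  rownames(conc) <- NULL
  rtm <- cq_table[cq_table$sample_type == "rt_minus", ]
  rt_qc <- rt_minus_check(stats::setNames(rtm$cq, rtm$primer))
  list(curves = curves, concentrations = conc, rt_minus = rt_qc)
}

#' Splicing and export indices from normalised concentrations
#'
#' Builds, per transcript and condition, the reference-normalised pre- and
#' post-spliced levels in each compartment and the nuclear/cytoplasmic ratio
#' of each splice form.  Missing compartments yield `NA` ratios with a flag.
#'
#' @param norm data.frame with columns `transcript`, `condition`,
#'   `compartment` (`"nuclear"`/`"cytoplasmic"`), `splice_form`
#'   (`"pre"`/`"post"`) and `value` (reference-normalised concentration).
#' @return data.frame per transcript x condition: `pre_nuclear`,
#'   `post_nuclear`, `pre_cytoplasmic`, `post_cytoplasmic`, `nc_ratio_pre`,
#'   `nc_ratio_post`, `flag_missing_compartment`.
#' @export
splicing_export_indices <- function(norm) {
  need <- c("transcript", "condition", "compartment", "splice_form", "value")
  if (!all(need %in% names(norm)))
    stop("norm must have columns ", paste(need, collapse = ", "), call. = FALSE)
  key <- unique(norm[c("transcript", "condition")])
  get1 <- function(tr, cond, comp, form) {
    v <- norm$value[norm$transcript == tr & norm$condition == cond &
                      norm$compartment == comp & norm$splice_form == form]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    tr <- key$transcript[i]; cond <- key$condition[i]
    pn <- get1(tr, cond, "nuclear", "pre"); qn <- get1(tr, cond, "nuclear", "post")
    pc <- get1(tr, cond, "cytoplasmic", "pre"); qc <- get1(tr, cond, "cytoplasmic", "post")
    ratio <- function(nuc, cyt)
      if (is.na(nuc) || is.na(cyt) || cyt <= 0) NA_real_ else nuc / cyt
    data.frame(transcript = tr, condition = cond,
               pre_nuclear = pn, post_nuclear = qn,
               pre_cytoplasmic = pc, post_cytoplasmic = qc,
               nc_ratio_pre = ratio(pn, pc), nc_ratio_post = ratio(qn, qc),
               flag_missing_compartment = anyNA(c(pn, qn, pc, qc)))
  }))
  rownames(out) <- NULL
  out
}
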