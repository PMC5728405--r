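# Differential filtering of the cytoplasmic fraction, FDR control, and the
# gene-set overlap arithmetic that defines knockdown target-gene lists.

table_to_matrix <- function(table, condition, compartment) {
  sub <- table[table$condition == condition & table$compartment == compartment, ]
  if (nrow(sub) == 0)
    stop("no rows for condition '", condition, "', compartment '",
         compartment, "'", call. = FALSE)
  genes <- sort(unique(sub$gene))
  reps <- sort(unique(sub$replicate))
  m <- matrix(NA_real_, length(genes), length(reps),
              dimnames = list(genes, reps))
  m[cbind(match(sub$gene, genes), match(sub$replicate, reps))] <- sub$value
  if (anyNA(m)) stop("incomplete replicate structure", call. = FALSE)
  m
}

#' Differential expression of the cytoplasmic fraction
#'
#' Per-gene fold-change (condition/control ratio of mean abundances) in the
#' chosen compartment and a two-sided two-sample t-test on log2 replicate
#' values, with Benjamini-Hochberg adjustment.  The default is Student's
#' pooled-variance test (the convention stated for every other comparison in
#' this assay family; with triplicate groups the Welch approximation loses
#' most of its degrees of freedom and has little power at stringent FDR
#' levels); set `var_equal = FALSE` for Welch.  Genes with zero variance in
#' both groups get p = 1 when the means are equal and p = 0 (flagged) when
#' they differ.
#'
#' @param table tidy expression data.frame (`gene`, `condition`, `replicate`,
#'   `compartment`, `value`).
#' @param control,condition condition labels to compare (condition vs
#'   control).
#' @param compartment compartment analysed (default `"cytoplasmic"`).
#' @param var_equal pooled-variance Student test (default) or Welch
#'   (`FALSE`).
#' @return data.frame: `gene`, `fold_change`, `t`, `df`, `p_value`,
#'   `p_adjusted`, `flag_zero_variance`.
#' @export
differential_cytoplasmic <- function(table, control, condition,
                                     compartment = "cytoplasmic",
                                     var_equal = TRUE) {
  a <- table_to_matrix(table, condition, compartment)  # condition group
  b <- table_to_matrix(table, control, compartment)    # control group
  if (!identical(rownames(a), rownames(b)))
    stop("condition and control cover different gene sets", call. = FALSE)
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 replicates per group", call. = FALSE)
  la <- log2(a); lb <- log2(b)
  m1 <- rowMeans(la); m2 <- rowMeans(lb)
  v1 <- rowSums((la - m1)^2) / (n1 - 1)
  v2 <- rowSums((lb - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se == 0 | !is.finite(se)
  eq <- degenerate & m1 == m2
  ne <- degenerate & m1 != m2
  tt[eq] <- 0; p[eq] <- 1
  p[ne] <- 0
  fc <- rowMeans(a) / rowMeans(b)
  data.frame(gene = rownames(a), fold_change = fc, t = tt, df = df,
             p_value = p, p_adjusted = bh_adjust(p),
             flag_zero_variance = degenerate, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Filter for significantly down-regulated genes
#'
#' Retains genes down-regulated by more than `fc_threshold`-fold (i.e.
#' `fold_change < 1/fc_threshold`, strict by default) and passing the
#' significance rule: FDR-adjusted p (the single-knockdown rule) or raw p
#' (the double-knockdown rule) below `alpha`.
#'
#' @param diff data.frame from [differential_cytoplasmic()].
#' @param fc_threshold fold-change threshold (> 0, default 1.5).
#' @param alpha significance level (default 0.01).
#' @param p_column `"p_adjusted"` (FDR rule, default) or `"p_value"` (raw-p
#'   rule).
#' @param strict use strict inequality for the fold-change cut (default).
#' @param label condition label carried on the returned set.
#' @return a `gene_set`: list with `label` and sorted `genes`.
#' @export
filter_down <- function(diff, fc_threshold = 1.5, alpha = 0.01,
                        p_column = c("p_adjusted", "p_value"),
                        strict = TRUE, label = "down") {
  stopifnot(fc_threshold > 0, alpha > 0)
  p_column <- match.arg(p_column)
  cut <- 1 / fc_threshold
  down <- if (strict) diff$fold_change < cut else diff$fold_change <= cut
  keep <- down & diff[[p_column]] < alpha
  structure(list(label = label, genes = sort(diff$gene[keep])),
            class = "gene_set")
}

as_gene_vector <- function(x) {
  if (inherits(x, "gene_set")) x$genes else as.character(x)
}

#' Overlap arithmetic between two gene sets
#'
#' Reports set sizes, intersection, union and the intersection as a percent
#' of the union, rounded half-up to one decimal (the convention of printed
#' overlap percentages).
#'
#' @param a,b `gene_set` objects or character vectors.
#' @return list: `n_a`, `n_b`, `n_intersection`, `n_union`,
#'   `pct_intersection_of_union`.
#' @export
overlap_stats <- function(a, b) {
  a <- unique(as_gene_vector(a)); b <- unique(as_gene_vector(b))
  ni <- length(intersect(a, b)); nu <- length(union(a, b))
  list(n_a = length(a), n_b = length(b), n_intersection = ni, n_union = nu,
       pct_intersection_of_union =
         if (nu > 0) round_half_up(100 * ni / nu, 1) else NA_real_)
}

#' Overlap percentage from printed set counts
#'
#' The counts-only form of [overlap_stats()]: intersection as a percent of
#' the union `|A| + |B| - |A∩B|`, rounded half-up to one decimal.
#'
#' @param n_a,n_b,n_intersection set and intersection sizes.
#' @return percentage, one decimal.
#' @export
overlap_pct_from_counts <- function(n_a, n_b, n_intersection) {
  stopifnot(n_intersection <= min(n_a, n_b))
  round_half_up(100 * n_intersection / (n_a + n_b - n_intersection), 1)
}

#' Set size as a percent of the gene universe
#'
#' @param set `gene_set`, character vector, or a count.
#' @param universe_size number of genes examined (> 0).
#' @return percentage, rounded half-up to one decimal.
#' @export
fraction_of_universe <- function(set, universe_size) {
  if (universe_size <= 0) stop("universe_size must be positive", call. = FALSE)
  n <- if (is.numeric(set) && length(set) == 1) set else length(unique(as_gene_vector(set)))
  stopifnot(n <= universe_size)
  round_half_up(100 * n / universe_size, 1)
}
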