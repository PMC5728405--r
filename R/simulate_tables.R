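# Synthetic expression tables, 3' UTR sequence sets and qPCR Cq tables,
# each returned together with the ground truth the generator committed to.

#' Generate a synthetic nuclear/cytoplasmic expression table
#'
#' Abundances are `2^(baseline + planted_effect + noise)`: per-gene lognormal
#' baselines shared across conditions and compartments, planted fold-changes
#' applied to the stated compartment of the stated condition, and Gaussian
#' replicate noise on the log2 scale.  With zero noise and no planted sets
#' all conditions are identical by construction.
#'
#' @param spec an [expression_spec()].
#' @return list with `table` (tidy data.frame: `gene`, `condition`,
#'   `replicate`, `compartment`, `value`) and `truth` (per-condition planted
#'   gene sets with true fold-changes, plus baselines).
#' @export
generate_expression_table <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  if (spec$n_replicates < 2)
    stop("at least 2 replicates per condition are required", call. = FALSE)
  with_seed(spec$seed, {
    genes <- sprintf("g%05d", seq_len(spec$n_genes))
    base_log2 <- rnorm(spec$n_genes, spec$baseline_mean_log2, spec$baseline_sd_log2)

    effect <- array(0, dim = c(spec$n_genes, length(spec$conditions), 2),
                    dimnames = list(genes, spec$conditions,
                                    c("nuclear", "cytoplasmic")))
    for (p in spec$planted_down) {
      comp <- p$compartment %||% "cytoplasmic"
      effect[p$genes, p$condition, comp] <-
        effect[p$genes, p$condition, comp] + log2(p$fold_change)
    }

    grid <- expand.grid(gene = genes, condition = spec$conditions,
                        replicate = seq_len(spec$n_replicates),
                        compartment = c("nuclear", "cytoplasmic"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gi <- match(grid$gene, genes)
    ci <- match(grid$condition, spec$conditions)
    ki <- match(grid$compartment, c("nuclear", "cytoplasmic"))
    log2v <- base_log2[gi] + effect[cbind(gi, ci, ki)] +
      rnorm(nrow(grid), 0, spec$noise_sd_log2)
    grid$value <- 2^log2v

    truth <- list(planted = lapply(spec$planted_down, function(p) {
      list(condition = p$condition, compartment = p$compartment %||% "cytoplasmic",
           genes = genes[p$genes], fold_change = p$fold_change)
    }), baseline_log2 = stats::setNames(base_log2, genes))
    list(table = grid, truth = truth)
  })
}

#' Generate a synthetic 3' UTR sequence set
#'
#' Carrier sequences (a `planted_fraction` random subset) receive exactly one
#' copy of the planted motif at a recorded position; every other position is
#' i.i.d. from the background nucleotide distribution.
#'
#' @param spec a [utr_spec()].
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame `name`, `carrier`, `position` — 1-based motif start, NA for
#'   non-carriers).
#' @export
generate_utr_set <- function(spec) {
  stopifnot(inherits(spec, "utr_spec"))
  with_seed(spec$seed, {
    n <- spec$n_sequences; L <- spec$length_nt
    k <- nchar(spec$planted_motif)
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(bases, L, replace = TRUE, prob = spec$background_probs),
            collapse = ""), character(1))
    names(seqs) <- sprintf("utr_%03d", seq_len(n))
    n_carrier <- round(spec$planted_fraction * n)
    carriers <- sort(sample.int(n, n_carrier))
    pos <- rep(NA_integer_, n)
    for (i in carriers) {
      p <- sample.int(L - k + 1, 1)
      substr(seqs[i], p, p + k - 1) <- spec$planted_motif
      pos[i] <- p
    }
    list(sequences = seqs,
         truth = data.frame(name = names(seqs),
                            carrier = seq_len(n) %in% carriers,
                            position = pos))
  })
}

#' Generate a synthetic qPCR Cq table with in-run standards
#'
#' Applies the log-linear model `Cq = intercept - log(conc)/log(efficiency)`
#' plus Gaussian Cq noise.  Each primer receives a dilution-series standard
#' (noise-free known concentrations, measured with the same Cq noise) and one
#' RT-minus row whose Cq is `NA` (no amplification) unless the primer is
#' planted as contaminated.
#'
#' @param spec a [cq_spec()].
#' @return list with `table` (data.frame: `primer`, `sample`, `condition`,
#'   `compartment`, `replicate`, `sample_type` in standard/unknown/rt_minus,
#'   `log10_conc` — known for standards, NA otherwise — and `cq`) and `truth`
#'   (the spec's primers, samples and contamination flags).
#' @export
generate_cq_table <- function(spec) {
  stopifnot(inherits(spec, "cq_spec"))
  with_seed(spec$seed, {
    model_cq <- function(conc, eff, intercept)
      intercept - log(conc) / log(eff)
    rows <- list()
    for (i in seq_len(nrow(spec$primers))) {
      pr <- spec$primers[i, ]
      std <- data.frame(primer = pr$primer, sample = "standard",
                        condition = "standard", compartment = "standard",
                        replicate = seq_along(spec$standard_concs),
                        sample_type = "standard",
                        log10_conc = log10(spec$standard_concs),
                        cq = model_cq(spec$standard_concs, pr$efficiency,
                                      pr$intercept) +
                          rnorm(length(spec$standard_concs), 0, spec$noise_sd))
      contaminated <- pr$primer %in% spec$contaminated
      rtm <- data.frame(primer = pr$primer, sample = "rt_minus",
                        condition = "rt_minus", compartment = "rt_minus",
                        replicate = 1L, sample_type = "rt_minus",
                        log10_conc = NA_real_,
                        cq = if (contaminated) pr$intercept + 5 else NA_real_)
      rows[[length(rows) + 1L]] <- rbind(std, rtm)
    }
    for (j in seq_len(nrow(spec$samples))) {
      sm <- spec$samples[j, ]
      pr <- spec$primers[match(sm$primer, spec$primers$primer), ]
      rows[[length(rows) + 1L]] <-
        data.frame(primer = sm$primer, sample = sm$sample,
                   condition = sm$condition, compartment = sm$compartment,
                   replicate = seq_len(spec$n_replicates),
                   sample_type = "unknown", log10_conc = NA_real_,
                   cq = model_cq(sm$true_conc, pr$efficiency, pr$intercept) +
                     rnorm(spec$n_replicates, 0, spec$noise_sd))
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(primers = spec$primers, samples = spec$samples,
                      contaminated = spec$contaminated))
  })
}
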