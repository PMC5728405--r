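# Exhaustive k-mer over-representation scanning of 3' UTR sequence sets.
#
# A deliberately simple, fully specified alternative to PWM/EM motif
# discovery: every k-mer of widths k_min..k_max present in at least
# min_support sequences is scored by the one-sided binomial tail of its
# sequence count against an order-0 background, with Bonferroni correction
# whose family size is every distinct k-mer observed in the scan (the
# support filter only restricts which of them are reported; counting just
# the supported ones would understate the selection and admit spurious
# hits on null input).  Sequences are scanned single-stranded (mRNA):
# reverse complements are NOT collapsed.

coerce_seqs <- function(seqs) {
  if (inherits(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || length(seqs) == 0)
    stop("empty sequence input", call. = FALSE)
  toupper(seqs)
}

#' Order-0 background nucleotide frequencies
#'
#' Pooled A/C/G/T frequencies over all sequences with a pseudocount per
#' base.  Ambiguity codes are not counted.
#'
#' @param seqs character vector or `DNAStringSet`.
#' @param pseudocount added to each base count (default 1).
#' @return named numeric vector (A, C, G, T) summing to 1.
#' @export
background_model <- function(seqs, pseudocount = 1) {
  seqs <- coerce_seqs(seqs)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b)
    sum(vapply(seqs, function(s)
      lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))), numeric(1))),
    numeric(1))
  freq <- counts + pseudocount
  freq / sum(freq)
}

# Split a sequence at ambiguity codes into clean ACGT stretches.
clean_windows <- function(s) {
  parts <- strsplit(s, "[^ACGT]+")[[1]]
  parts[nchar(parts) > 0]
}

# Per-sequence probability that a k-mer with per-window match probability
# p_kmer occurs at least once, under the independent-window approximation
# 1 - (1 - p)^(n_windows).
per_seq_occurrence_prob <- function(p_kmer, seq_lengths, k) {
  nw <- pmax(seq_lengths - k + 1, 0)
  1 - (1 - p_kmer)^nw
}

#' Scan a sequence set for over-represented k-mers
#'
#' For each width in `k_min:k_max`, counts the number of sequences carrying
#' each k-mer at least once (ambiguity codes break windows), computes the
#' expected sequence count under the order-0 background, and scores each
#' k-mer supported by at least `min_support` sequences by the one-sided
#' binomial tail probability of seeing at least the observed count.  Hits
#' are ranked by score (ties broken lexicographically) and
#' Bonferroni-corrected with the family size taken as every distinct k-mer
#' observed across all widths; significant hits nested inside a longer
#' significant hit are annotated.
#'
#' @param seqs character vector or `DNAStringSet` of UTR sequences.
#' @param k_min,k_max inclusive width range (default 8 to 20).
#' @param min_support minimum number of carrier sequences for a k-mer to be
#'   tested (default 5).
#' @param alpha familywise significance level after Bonferroni (default
#'   0.01).
#' @param background order-0 frequencies from [background_model()]; computed
#'   from `seqs` when `NULL`.
#' @param max_report cap on returned rows (best-ranked first).
#' @return data.frame ranked by score: `kmer`, `width`, `observed`,
#'   `expected`, `log10_p`, `score` (-log10 binomial tail), `p_bonferroni`,
#'   `significant`, `nested_in`; attribute `n_tested` carries the Bonferroni
#'   family size.
#' @export
scan_kmers <- function(seqs, k_min = 8, k_max = 20, min_support = 5,
                       alpha = 0.01, background = NULL, max_report = 50) {
  seqs <- coerce_seqs(seqs)
  if (k_min > k_max) stop("k_min must be <= k_max", call. = FALSE)
  if (k_min < 1) stop("k_min must be >= 1", call. = FALSE)
  windows <- lapply(seqs, clean_windows)
  max_len <- max(vapply(windows, function(w)
    if (length(w)) max(nchar(w)) else 0L, numeric(1)))
  if (k_max > max_len)
    stop("k_max exceeds the longest clean sequence stretch", call. = FALSE)
  if (is.null(background)) background <- background_model(seqs)
  n_seq <- length(seqs)
  seq_lengths <- vapply(windows, function(w) sum(nchar(w)), numeric(1))

  hits <- list()
  n_tested <- 0L
  log_bg <- log(background)
  for (k in k_min:k_max) {
    per_seq <- lapply(windows, function(w) {
      w <- w[nchar(w) >= k]
      if (!length(w)) return(character(0))
      unique(unlist(lapply(w, function(s)
        substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))))
    })
    counts <- table(unlist(per_seq))
    n_tested <- n_tested + length(counts)  # every observed k-mer is tested
    counts <- counts[counts >= min_support]
    if (!length(counts)) next
    kmers <- names(counts)
    obs <- as.integer(counts)
    # order-0 probability of each k-mer at a single window
    comp <- vapply(strsplit(kmers, ""), function(b) sum(log_bg[b]), numeric(1))
    p_kmer <- exp(comp)
    p_seq <- vapply(p_kmer, function(p)
      mean(per_seq_occurrence_prob(p, seq_lengths, k)), numeric(1))
    expected <- n_seq * p_seq
    logp <- stats::pbinom(obs - 1L, n_seq, p_seq, lower.tail = FALSE,
                          log.p = TRUE)
    hits[[length(hits) + 1L]] <-
      data.frame(kmer = kmers, width = k, observed = obs,
                 expected = expected, log10_p = logp / log(10),
                 row.names = NULL)
  }
  if (!length(hits))
    return(structure(data.frame(kmer = character(0), width = integer(0),
                                observed = integer(0), expected = numeric(0),
                                log10_p = numeric(0), score = numeric(0),
                                p_bonferroni = numeric(0),
                                significant = logical(0),
                                nested_in = character(0)),
                     n_tested = n_tested))
  res <- do.call(rbind, hits)
  res$score <- -res$log10_p
  res$p_bonferroni <- pmin(1, exp(res$log10_p * log(10) + log(max(n_tested, 1L))))
  res$significant <- res$log10_p + log10(max(n_tested, 1L)) < log10(alpha)
  res <- res[order(-res$score, res$kmer), ]
  res$rank <- seq_len(nrow(res))
  res <- res[seq_len(min(nrow(res), max_report)), ]

  res$nested_in <- NA_character_
  sig <- which(res$significant)
  for (i in sig) {
    longer <- sig[res$width[sig] > res$width[i]]
    for (j in longer) {
      if (grepl(res$kmer[i], res$kmer[j], fixed = TRUE)) {
        res$nested_in[i] <- res$kmer[j]
        break  # hits are rank-ordered, so the first containing hit is best
      }
    }
  }
  rownames(res) <- NULL
  structure(res, n_tested = n_tested)
}
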