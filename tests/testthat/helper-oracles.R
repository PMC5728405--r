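# Independent brute-force oracles.  These deliberately re-derive results
# from definitions (per-pixel loops, step-up definition, closed-form t),
# sharing no code path with the implementation they check.

# Per-pixel Chebyshev erosion: a pixel survives iff every pixel of the
# (2r+1)^2 neighbourhood (clipped neighbours outside the image count as
# background) is inside the mask.
oracle_erode <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    ok <- TRUE
    for (di in -r:r) {
      for (dj in -r:r) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    out[i, j] <- ok
  }
  out
}

# Per-pixel nearest-nucleus Chebyshev distance band: for every pixel compute
# the Chebyshev distance to each label's pixel set; the ring at (gap, width]
# is assigned to the nearest label, ties to the smaller label, nuclei
# excluded.
oracle_ring <- function(labels, gap, width) {
  nr <- nrow(labels); nc <- ncol(labels)
  n <- max(labels)
  px <- lapply(seq_len(n), function(k) which(labels == k, arr.ind = TRUE))
  ring <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (labels[i, j] > 0) next
    best_d <- Inf; best_k <- 0L
    for (k in seq_len(n)) {
      d <- min(pmax(abs(px[[k]][, 1] - i), abs(px[[k]][, 2] - j)))
      if (d < best_d) { best_d <- d; best_k <- k }
    }
    if (best_d > gap && best_d <= gap + width) ring[i, j] <- best_k
  }
  ring
}

# Benjamini-Hochberg step-up from the definition: sort, p_(i) * m / i,
# cumulative minimum from the largest rank down, cap at 1, unsort.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ps)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Closed-form two-sided two-sample t-test.
oracle_t <- function(a, b, pooled = TRUE) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (mean(a) - mean(b)) / se
  2 * pt(-abs(tt), df)
}

# Exact probability that an i.i.d. sequence of length L over {A,C,G,T} with
# probabilities `probs` contains `motif` at least once, by dynamic
# programming over the KMP prefix automaton (independent of the package's
# independent-window approximation).
oracle_occurrence_prob <- function(motif, L, probs = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  names(probs) <- bases
  mo <- strsplit(motif, "")[[1]]
  k <- length(mo)
  # failure links
  fail <- integer(k)
  for (q in 2:k) {
    s <- fail[q - 1]
    while (s > 0 && mo[s + 1] != mo[q]) s <- fail[s]
    fail[q] <- if (mo[s + 1] == mo[q]) s + 1 else 0
  }
  delta <- function(state, ch) {
    while (state > 0 && mo[state + 1] != ch) state <- fail[state]
    if (mo[state + 1] == ch) state + 1 else 0
  }
  # state distribution over 0..k-1 plus absorbing hit probability
  pr <- c(1, numeric(k - 1)); hit <- 0
  for (step in seq_len(L)) {
    nxt <- numeric(k)
    for (s in 0:(k - 1)) {
      if (pr[s + 1] == 0) next
      for (ch in bases) {
        ns <- delta(s, ch)
        w <- pr[s + 1] * probs[ch]
        if (ns == k) hit <- hit + w else nxt[ns + 1] <- nxt[ns + 1] + w
      }
    }
    pr <- nxt
  }
  unname(hit)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Small FISH field used by unit tests (full ring geometry, few cells).
small_fish_spec <- function(seed = 1, n_cells = 6, ...) {
  fish_image_spec(image_shape = c(384L, 384L), n_cells = n_cells, seed = seed,
                  ...)
}
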