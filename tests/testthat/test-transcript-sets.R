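make_tidy <- function(mat_cond, mat_ctrl, compartment = "cytoplasmic") {
  # two genes x replicates matrices into the tidy table layout
  tidy1 <- function(m, cond) {
    do.call(rbind, lapply(seq_len(ncol(m)), function(r)
      data.frame(gene = rownames(m), condition = cond, replicate = r,
                 compartment = compartment, value = m[, r])))
  }
  rbind(tidy1(mat_cond, "kd"), tidy1(mat_ctrl, "ctrl"))
}

test_that("identical groups give unit fold-change and p = 1", {
  m <- matrix(2^rnorm(30, 8), 10, 3,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  d <- differential_cytoplasmic(make_tidy(m, m), "ctrl", "kd")
  expect_equal(d$fold_change, rep(1, 10))
  expect_equal(d$t, rep(0, 10))
  expect_equal(d$p_value, rep(1, 10))
  expect_false(any(d$flag_zero_variance))  # replicates vary, groups don't
})

test_that("a noiseless planted 2-fold-down gene has fold-change 0.5 exactly", {
  sp <- expression_spec(n_genes = 20, noise_sd_log2 = 0, seed = 3,
                        planted_down = list(list(condition = "siTHRAP3",
                                                 genes = 1:4, fold_change = 0.5)))
  tab <- generate_expression_table(sp)$table
  d <- differential_cytoplasmic(tab, "siCtrl", "siTHRAP3")
  expect_equal(d$fold_change[1:4], rep(0.5, 4), tolerance = 1e-12)
  expect_equal(d$p_value[1:4], rep(0, 4))  # zero variance, unequal means
  expect_true(all(d$flag_zero_variance[1:4]))
})

test_that("vectorised t statistics match per-gene t.test recomputation", {
  set.seed(21)
  n_genes <- 60
  a <- matrix(2^rnorm(n_genes * 3, 8, 1), n_genes, 3,
              dimnames = list(sprintf("g%02d", 1:n_genes), NULL))
  b <- matrix(2^rnorm(n_genes * 4, 8, 1), n_genes, 4,
              dimnames = list(sprintf("g%02d", 1:n_genes), NULL))
  for (pooled in c(TRUE, FALSE)) {
    d <- differential_cytoplasmic(make_tidy(a, b), "ctrl", "kd",
                                  var_equal = pooled)
    for (g in seq_len(n_genes)) {
      ref <- t.test(log2(a[g, ]), log2(b[g, ]), var.equal = pooled)
      expect_equal(d$p_value[g], ref$p.value, tolerance = 1e-12)
      expect_equal(d$t[g], unname(ref$statistic), tolerance = 1e-12)
    }
  }
})

test_that("missing conditions or compartments raise schema errors", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), NULL))
  tab <- make_tidy(m, m)
  expect_error(differential_cytoplasmic(tab, "ctrl", "nope"), "no rows")
  expect_error(differential_cytoplasmic(tab, "ctrl", "kd",
                                        compartment = "nuclear"), "no rows")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.01), 0.01)                       # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:60) {
    m <- sample(1:8, 1)
    p <- round(runif(m), sample(1:3, 1))  # ties included
    expect_equal(bh_adjust(p), oracle_bh(p))
    # the rejected set at alpha equals the step-up definition's
    alpha <- 0.05
    k <- max(c(0, which(sort(p) <= alpha * seq_len(m) / m)))
    stepup_reject <- if (k > 0) p <= sort(p)[k] else rep(FALSE, m)
    expect_equal(bh_adjust(p) <= alpha, stepup_reject)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("the down-filter applies both fold-change and significance rules", {
  d <- data.frame(gene = c("a", "b", "c", "d"),
                  fold_change = c(0.5, 0.8, 0.5, 0.66),
                  p_value = c(0.001, 0.001, 0.2, 0.001),
                  p_adjusted = c(0.001, 0.001, 0.4, 0.001))
  gs <- filter_down(d, 1.5, 0.01)
  expect_equal(gs$genes, c("a", "d"))  # b fails fold cut, c fails significance
  # strict boundary: fold-change exactly 1/1.5 is excluded unless strict = FALSE
  d2 <- data.frame(gene = "x", fold_change = 1 / 1.5, p_value = 1e-5,
                   p_adjusted = 1e-5)
  expect_length(filter_down(d2, 1.5, 0.01)$genes, 0)
  expect_equal(filter_down(d2, 1.5, 0.01, strict = FALSE)$genes, "x")
  # raw-p rule for the double knockdown
  d3 <- data.frame(gene = "y", fold_change = 0.5, p_value = 0.03,
                   p_adjusted = 0.2)
  expect_length(filter_down(d3, 1.5, 0.05)$genes, 0)
  expect_equal(filter_down(d3, 1.5, 0.05, p_column = "p_value")$genes, "y")
})

test_that("the filtered set shrinks as thresholds tighten", {
  set.seed(9)
  d <- data.frame(gene = sprintf("g%03d", 1:300),
                  fold_change = exp(rnorm(300, 0, 0.7)),
                  p_value = runif(300))
  d$p_adjusted <- bh_adjust(d$p_value)
  prev <- NULL
  for (fc in c(1.2, 1.5, 2, 3)) {
    cur <- filter_down(d, fc, 0.5)$genes
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- NULL
  for (alpha in c(0.5, 0.2, 0.05, 0.01)) {
    cur <- filter_down(d, 1.5, alpha)$genes
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("overlap reports match brute-force set arithmetic and are symmetric", {
  set.seed(2)
  universe <- sprintf("g%03d", 1:200)
  for (i in 1:20) {
    a <- sample(universe, sample(0:50, 1))
    b <- sample(universe, sample(1:50, 1))
    ov <- overlap_stats(a, b)
    expect_equal(ov$n_intersection, length(intersect(a, b)))
    expect_equal(ov$n_union, length(a) + length(b) - ov$n_intersection)
    expect_true(ov$n_intersection <= min(ov$n_a, ov$n_b))
    ba <- overlap_stats(b, a)
    expect_equal(ov$pct_intersection_of_union, ba$pct_intersection_of_union)
    # relabelling invariance
    perm <- setNames(sample(universe), universe)
    ov2 <- overlap_stats(unname(perm[a]), unname(perm[b]))
    expect_equal(ov2$pct_intersection_of_union, ov$pct_intersection_of_union)
  }
  same <- overlap_stats(c("a", "b"), c("b", "a"))
  expect_equal(same$pct_intersection_of_union, 100.0)
})

test_that("universe fractions round half-up to one decimal", {
  expect_equal(fraction_of_universe(0, 100), 0.0)
  expect_equal(fraction_of_universe(26501, 26501), 100.0)
  expect_equal(fraction_of_universe(1, 800), 0.1)  # 0.125 rounds half-up
  expect_error(fraction_of_universe(5, 0), "positive")
})
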