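test_that("noiseless tables with no planted sets are identical across conditions", {
  sp <- expression_spec(n_genes = 50, noise_sd_log2 = 0, seed = 1)
  tab <- generate_expression_table(sp)$table
  ctrl <- tab[tab$condition == "siCtrl", ]
  for (cond in setdiff(sp$conditions, "siCtrl")) {
    other <- tab[tab$condition == cond, ]
    expect_equal(other$value, ctrl$value)
  }
})

test_that("a planted fold-change is exact in the noiseless cytoplasmic fraction", {
  sp <- expression_spec(n_genes = 30, noise_sd_log2 = 0, seed = 2,
                        planted_down = list(list(condition = "siTHRAP3",
                                                 genes = 1:5, fold_change = 0.5)))
  tab <- generate_expression_table(sp)$table
  get <- function(cond, comp) {
    s <- tab[tab$condition == cond & tab$compartment == comp &
               tab$replicate == 1, ]
    s$value[order(s$gene)]
  }
  ratio <- get("siTHRAP3", "cytoplasmic") / get("siCtrl", "cytoplasmic")
  expect_equal(ratio[1:5], rep(0.5, 5), tolerance = 1e-12)
  expect_equal(ratio[6:30], rep(1, 25), tolerance = 1e-12)
  # nuclear fraction untouched by a cytoplasmic planting
  expect_equal(get("siTHRAP3", "nuclear"), get("siCtrl", "nuclear"))
})

test_that("fewer than two replicates is rejected", {
  expect_no_error(generate_expression_table(
    expression_spec(n_genes = 5, n_replicates = 2)))
  sp <- expression_spec(n_genes = 5)
  sp$n_replicates <- 1L
  expect_error(generate_expression_table(sp), "2 replicates")
})

test_that("planted UTR motifs are exactly where the ground truth says", {
  sp <- utr_spec(n_sequences = 50, planted_fraction = 1, seed = 7)
  out <- generate_utr_set(sp)
  k <- nchar(sp$planted_motif)
  expect_true(all(out$truth$carrier))
  for (i in seq_len(50)) {
    p <- out$truth$position[i]
    expect_identical(substr(out$sequences[[i]], p, p + k - 1),
                     sp$planted_motif)
  }
  # every record has at least one exact occurrence
  expect_true(all(grepl(sp$planted_motif, out$sequences, fixed = TRUE)))
})

test_that("planted fraction scales the number of carriers; zero plants nothing", {
  out0 <- generate_utr_set(utr_spec(n_sequences = 40, planted_fraction = 0,
                                    seed = 3))
  expect_false(any(out0$truth$carrier))
  expect_true(all(is.na(out0$truth$position)))
  out5 <- generate_utr_set(utr_spec(n_sequences = 40, planted_fraction = 0.5,
                                    seed = 3))
  expect_equal(sum(out5$truth$carrier), 20)
})

test_that("non-ACGT motifs are rejected", {
  expect_error(utr_spec(planted_motif = "GGANGC"), "only A, C, G, T")
})

test_that("noiseless standards space by log2(10) cycles at efficiency 2", {
  sp <- cq_spec(samples = data.frame(primer = "ACTB", sample = "s",
                                     condition = "c", compartment = "nuclear",
                                     true_conc = 1),
                noise_sd = 0, seed = 1)
  tab <- generate_cq_table(sp)$table
  std <- tab[tab$primer == "ACTB" & tab$sample_type == "standard", ]
  spacing <- diff(std$cq[order(std$log10_conc, decreasing = TRUE)])
  expect_equal(spacing, rep(log2(10), 4), tolerance = 1e-9)  # 3.3219 cycles
})

test_that("Cq reflects concentration: equal concs tie, doubling lowers Cq by one cycle", {
  samples <- data.frame(primer = "ACTB", sample = c("a", "b", "c"),
                        condition = "c", compartment = "nuclear",
                        true_conc = c(0.2, 0.2, 0.4))
  tab <- generate_cq_table(cq_spec(samples = samples, noise_sd = 0, seed = 1))$table
  unk <- tab[tab$sample_type == "unknown" & tab$replicate == 1, ]
  cq <- setNames(unk$cq, unk$sample)
  expect_equal(cq[["a"]], cq[["b"]])
  expect_equal(cq[["a"]] - cq[["c"]], 1, tolerance = 1e-9)
})

test_that("RT-minus rows carry the no-amplification sentinel unless contaminated", {
  samples <- data.frame(primer = c("ACTB", "MALAT1"), sample = "s",
                        condition = "c", compartment = "nuclear",
                        true_conc = 1)
  tab <- generate_cq_table(cq_spec(samples = samples, contaminated = "MALAT1",
                                   seed = 1))$table
  rtm <- tab[tab$sample_type == "rt_minus", ]
  expect_true(is.na(rtm$cq[rtm$primer == "ACTB"]))
  expect_false(is.na(rtm$cq[rtm$primer == "MALAT1"]))
})

test_that("non-positive concentrations are rejected", {
  expect_error(cq_spec(samples = data.frame(primer = "ACTB", sample = "s",
                                            condition = "c",
                                            compartment = "nuclear",
                                            true_conc = 0)),
               "positive")
})
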