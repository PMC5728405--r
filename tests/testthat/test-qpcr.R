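test_that("a perfect 10-fold series recovers efficiency 2 from its slope", {
  dil <- 0:-4
  cq <- 20 - log(10^dil) / log(2)       # spacing log2(10) = 3.3219 cycles
  curve <- fit_standard_curve(dil, cq)
  expect_equal(curve$efficiency, 2, tolerance = 1e-6)
  expect_equal(curve$slope, -log2(10), tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)
})

test_that("degenerate standard curves are rejected", {
  expect_error(fit_standard_curve(c(0, -1), c(20, 23)), "3 points")
  expect_error(fit_standard_curve(c(0, 0, 0), c(20, 21, 22)), "distinct")
  expect_error(fit_standard_curve(c(0, -1, -2), c(20, 20, 20)), "zero slope")
})

test_that("quantification inverts the curve", {
  curve <- fit_standard_curve(0:-3, 20 - log(10^(0:-3)) / log(2))
  expect_equal(quantify(curve$intercept, curve), 1, tolerance = 1e-12)
  # one cycle earlier at efficiency 2 means twice the template
  expect_equal(quantify(curve$intercept - 1, curve) /
                 quantify(curve$intercept, curve), 2, tolerance = 1e-9)
  expect_equal(quantify(NA, curve), 0)  # no amplification
})

test_that("the noiseless generate-fit-quantify chain recovers true concentrations", {
  primers <- data.frame(primer = c("ACTB", "FANCD2_post"),
                        efficiency = c(2, 1.87), intercept = c(20, 25))
  samples <- expand.grid(primer = primers$primer, sample = "s1",
                         condition = c("siCtrl", "siTHRAP3+siBCLAF1"),
                         compartment = c("nuclear", "cytoplasmic"),
                         stringsAsFactors = FALSE)
  samples$true_conc <- c(1, 0.5, 1, 0.1, 1, 0.45, 1, 0.02)
  out <- generate_cq_table(cq_spec(primers = primers, samples = samples,
                                   noise_sd = 0, seed = 3))
  q <- quantify_cq_table(out$table)
  for (p in primers$primer) {
    expect_equal(q$curves[[p]]$efficiency,
                 primers$efficiency[primers$primer == p], tolerance = 1e-9)
    expect_equal(q$curves[[p]]$intercept,
                 primers$intercept[primers$primer == p], tolerance = 1e-9)
  }
  got <- merge(q$concentrations, samples,
               by = c("primer", "sample", "condition", "compartment"))
  expect_equal(got$concentration, got$true_conc, tolerance = 1e-9)
})

test_that("reference normalisation is elementwise with flagged zero references", {
  expect_equal(normalize_to_reference(c(2, 4), c(2, 4)), c(1, 1))
  expect_equal(normalize_to_reference(c(4, 8), c(2, 4)), c(2, 2))
  out <- normalize_to_reference(c(1, 1), c(1, 0))
  expect_true(is.na(out[2]))
  expect_equal(attr(out, "flagged"), 2L)
})

test_that("fractionation purity verdicts follow the marker ratio monotonically", {
  expect_equal(purity_check(0, 5), "pass")
  expect_equal(purity_check(5, 5, max_ratio = 0.1), "fail")
  expect_equal(purity_check(1, 0), "indeterminate")
  verdicts <- vapply(c(0.5, 0.2, 0.1, 0.05, 0.01),
                     function(mr) purity_check(0.8, 10, max_ratio = mr),
                     character(1))
  # pass set shrinks as the threshold tightens: pass..pass then fail..fail
  expect_false(is.unsorted(rev(verdicts == "pass")))
})

test_that("RT-minus wells gate primers on amplification", {
  qc <- rt_minus_check(c(ACTB = NA, MALAT1 = NA))
  expect_equal(unname(qc), c("pass", "pass"))
  qc2 <- rt_minus_check(c(ACTB = NA, MALAT1 = 31.2))
  expect_equal(qc2[["MALAT1"]], "fail")
  # planted contamination is recovered through the generated table
  samples <- data.frame(primer = "ACTB", sample = "s", condition = "c",
                        compartment = "nuclear", true_conc = 1)
  tab <- generate_cq_table(cq_spec(samples = samples, contaminated = "ACTB",
                                   seed = 1))$table
  q <- quantify_cq_table(tab)
  expect_equal(unname(q$rt_minus["ACTB"]), "fail")
})

test_that("splicing and export indices reproduce planted defect factors", {
  base <- expand.grid(transcript = "ATM", condition = c("siCtrl", "kd"),
                      compartment = c("nuclear", "cytoplasmic"),
                      splice_form = c("pre", "post"), stringsAsFactors = FALSE)
  # control: post = 1 everywhere, pre = 0.2; export defect in kd scales the
  # cytoplasmic post-spliced level by 1/e; splicing defect doubles pre
  base$value <- ifelse(base$splice_form == "post", 1, 0.2)
  base$value[base$condition == "kd" & base$splice_form == "post" &
               base$compartment == "cytoplasmic"] <- exp(-1)
  base$value[base$condition == "kd" & base$splice_form == "pre"] <- 0.4
  idx <- splicing_export_indices(base)
  ctl <- idx[idx$condition == "siCtrl", ]
  kd <- idx[idx$condition == "kd", ]
  expect_equal(ctl$nc_ratio_post, 1)
  expect_equal(kd$nc_ratio_post, exp(1), tolerance = 1e-12)
  expect_equal(kd$pre_nuclear / ctl$pre_nuclear, 2, tolerance = 1e-12)
  # identical compartments give unit ratios, missing compartments flag
  miss <- base[base$compartment == "nuclear", ]
  idx2 <- splicing_export_indices(miss)
  expect_true(all(is.na(idx2$nc_ratio_post)))
  expect_true(all(idx2$flag_missing_compartment))
})

test_that("indices are invariant under a common rescaling of all true concentrations", {
  primers <- data.frame(primer = c("ACTB", "ATM_pre", "ATM_post"),
                        efficiency = c(2, 1.9, 2), intercept = c(20, 26, 22))
  samples <- expand.grid(primer = primers$primer, sample = "s1",
                         condition = "siCtrl",
                         compartment = c("nuclear", "cytoplasmic"),
                         stringsAsFactors = FALSE)
  samples$true_conc <- c(1, 0.2, 0.8, 1, 0.05, 0.9)
  run <- function(scale) {
    s <- samples; s$true_conc <- s$true_conc * scale
    tab <- generate_cq_table(cq_spec(primers = primers, samples = s,
                                     noise_sd = 0, seed = 2))$table
    q <- quantify_cq_table(tab)
    conc <- q$concentrations
    ref <- conc$concentration[conc$primer == "ACTB"]
    names(ref) <- conc$compartment[conc$primer == "ACTB"]
    targ <- conc[conc$primer != "ACTB", ]
    targ$value <- targ$concentration / ref[targ$compartment]
    targ$transcript <- "ATM"
    targ$splice_form <- sub("ATM_", "", targ$primer)
    splicing_export_indices(targ)
  }
  expect_equal(run(1), run(7.3), tolerance = 1e-9)
})

test_that("technical replicates can be combined on either scale", {
  curve <- fit_standard_curve(0:-3, 20 - log(10^(0:-3)) / log(2))
  tab <- data.frame(primer = "P", sample = "s", condition = "c",
                    compartment = "n", replicate = 1:3,
                    sample_type = "unknown", log10_conc = NA,
                    cq = c(19, 20, 21))
  std <- data.frame(primer = "P", sample = "std", condition = "std",
                    compartment = "std", replicate = 1:4,
                    sample_type = "standard", log10_conc = 0:-3,
                    cq = 20 - log(10^(0:-3)) / log(2))
  full <- rbind(tab, std)
  conc_scale <- quantify_cq_table(full, average = "concentration")
  cq_scale <- quantify_cq_table(full, average = "cq")
  expect_equal(conc_scale$concentrations$concentration,
               mean(quantify(c(19, 20, 21), curve)), tolerance = 1e-9)
  expect_equal(cq_scale$concentrations$concentration,
               quantify(20, curve), tolerance = 1e-9)
  expect_gt(conc_scale$concentrations$concentration,
            cq_scale$concentrations$concentration)  # Jensen gap
})
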