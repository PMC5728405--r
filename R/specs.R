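# Specification objects for the synthetic-data generators.  Each constructor
# validates its fields once; generators then trust the spec.  A spec plus a
# seed fully determines the generated data (bit-identical reruns).

new_spec <- function(fields, class) {
  structure(fields, class = c(class, "ddr_spec"))
}

#' @export
print.ddr_spec <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Specification for a synthetic RNA-FISH field of view
#'
#' Describes a field of fluorescent cells: a DAPI channel with elliptical
#' nuclei and a signal channel whose noiseless per-cell nuclear/cytoplasmic
#' mean intensity ratio equals `true_nc_ratio` exactly.  Nuclei are placed
#' without overlap and far enough apart that no cell's cytoplasm covers
#' another cell's nucleus; the cytoplasm is the Chebyshev annulus of width
#' `cytoplasm_extent_px` around each nucleus.
#'
#' @param image_shape integer (rows, cols) of the field in pixels.
#' @param n_cells number of cells to place (>= 0).
#' @param nucleus_radius_px mean nuclear semi-axis, pixels.
#' @param radius_jitter relative jitter of the two semi-axes (0 = circles of
#'   fixed radius).
#' @param true_nc_ratio condition-level true nuclear/cytoplasmic signal ratio.
#' @param ratio_cv per-cell lognormal coefficient of variation of the true
#'   ratio around `true_nc_ratio` (0 = all cells share the condition ratio).
#' @param cytoplasm_extent_px width of the cytoplasmic annulus, pixels. Must
#'   cover the measurement ring (gap + ring width) for ring means to be pure
#'   cytoplasm.
#' @param signal_base cytoplasmic signal intensity (16-bit scale).
#' @param background_level signal intensity outside cells.
#' @param dapi_level DAPI intensity inside nuclei.
#' @param noise_sd additive Gaussian noise s.d. on the signal channel.
#' @param seed integer RNG seed.
#' @return a `fish_image_spec` object.
#' @export
fish_image_spec <- function(image_shape = c(896L, 896L),
                            n_cells = 50,
                            nucleus_radius_px = 12,
                            radius_jitter = 0.15,
                            true_nc_ratio = 2,
                            ratio_cv = 0,
                            cytoplasm_extent_px = 36,
                            signal_base = 8000,
                            background_level = 400,
                            dapi_level = 30000,
                            noise_sd = 0,
                            seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 32),
            n_cells >= 0, n_cells == round(n_cells),
            nucleus_radius_px > 0, radius_jitter >= 0, radius_jitter < 1,
            true_nc_ratio > 0, ratio_cv >= 0,
            cytoplasm_extent_px >= 1, signal_base > 0,
            background_level >= 0, noise_sd >= 0)
  new_spec(list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
                nucleus_radius_px = nucleus_radius_px, radius_jitter = radius_jitter,
                true_nc_ratio = true_nc_ratio, ratio_cv = ratio_cv,
                cytoplasm_extent_px = as.integer(cytoplasm_extent_px),
                signal_base = signal_base, background_level = background_level,
                dapi_level = dapi_level, noise_sd = noise_sd,
                seed = as.integer(seed)),
           "fish_image_spec")
}

#' Specification for a synthetic DNA-repair focus field of view
#'
#' Geometry and noise follow [fish_image_spec()]; the signal channel instead
#' carries, for nucleus k, exactly `foci_counts[k]` disjoint bright spots of
#' radius `focus_radius_px` wholly inside that nucleus.
#'
#' @inheritParams fish_image_spec
#' @param foci_counts integer vector (length `n_cells`, recycled) of planted
#'   focus counts per nucleus; all >= 0.
#' @param focus_radius_px focus disc radius, pixels.
#' @param focus_amplitude intensity added on a focus above background.
#' @return a `foci_image_spec` object.
#' @export
foci_image_spec <- function(image_shape = c(512L, 512L),
                            n_cells = 12,
                            foci_counts = 0L,
                            nucleus_radius_px = 14,
                            radius_jitter = 0.1,
                            focus_radius_px = 2,
                            focus_amplitude = 12000,
                            background_level = 400,
                            dapi_level = 30000,
                            noise_sd = 0,
                            seed = 1L) {
  foci_counts <- rep_len(as.integer(foci_counts), n_cells)
  stopifnot(all(foci_counts >= 0), focus_radius_px >= 1,
            focus_amplitude > 0, n_cells >= 0, noise_sd >= 0)
  new_spec(list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
                foci_counts = foci_counts, nucleus_radius_px = nucleus_radius_px,
                radius_jitter = radius_jitter, focus_radius_px = focus_radius_px,
                focus_amplitude = focus_amplitude, background_level = background_level,
                dapi_level = dapi_level, noise_sd = noise_sd, seed = as.integer(seed)),
           "foci_image_spec")
}

#' Specification for a synthetic two-channel reporter field of view
#'
#' Each cell expresses a denominator channel at `denominator_base` and a
#' numerator channel at `denominator_base * true_ratios[k]`, uniformly over
#' the whole cell (nucleus plus cytoplasm).  Cells listed in `untransfected`
#' express background only in both channels.
#'
#' @inheritParams fish_image_spec
#' @param true_ratios per-cell true numerator/denominator ratio (recycled);
#'   all >= 0.
#' @param denominator_base denominator-channel intensity in expressing cells.
#' @param untransfected integer indices of cells expressing neither channel.
#' @return a `reporter_image_spec` object.
#' @export
reporter_image_spec <- function(image_shape = c(512L, 512L),
                                n_cells = 12,
                                true_ratios = 1,
                                denominator_base = 10000,
                                untransfected = integer(0),
                                nucleus_radius_px = 12,
                                radius_jitter = 0.1,
                                cytoplasm_extent_px = 10,
                                background_level = 200,
                                dapi_level = 30000,
                                noise_sd = 0,
                                seed = 1L) {
  true_ratios <- rep_len(true_ratios, n_cells)
  stopifnot(all(true_ratios >= 0), denominator_base > 0, n_cells >= 0,
            all(untransfected %in% seq_len(n_cells)), noise_sd >= 0)
  new_spec(list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
                true_ratios = true_ratios, denominator_base = denominator_base,
                untransfected = as.integer(untransfected),
                nucleus_radius_px = nucleus_radius_px, radius_jitter = radius_jitter,
                cytoplasm_extent_px = as.integer(cytoplasm_extent_px),
                background_level = background_level, dapi_level = dapi_level,
                noise_sd = noise_sd, seed = as.integer(seed)),
           "reporter_image_spec")
}

#' Specification for a synthetic nuclear/cytoplasmic expression table
#'
#' Emulates a replicate expression experiment over knockdown conditions with
#' both nuclear and cytoplasmic fractions.  Per-gene baselines are lognormal
#' and shared across conditions; `planted_down` lists gene sets whose
#' abundance in one compartment of one condition is multiplied by a true
#' fold-change; replicate noise is Gaussian on the log2 scale.
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per condition (>= 2; two-sample tests are
#'   undefined below that).
#' @param conditions character vector of condition labels; the first is the
#'   control by convention.
#' @param planted_down list of lists with fields `condition`, `genes`
#'   (integer indices), `fold_change` (> 0) and optional `compartment`
#'   (default `"cytoplasmic"`).
#' @param noise_sd_log2 replicate noise s.d. on the log2 scale.
#' @param baseline_mean_log2,baseline_sd_log2 lognormal baseline parameters.
#' @param seed integer RNG seed.
#' @return an `expression_spec` object.
#' @export
expression_spec <- function(n_genes = 5100,
                            n_replicates = 3,
                            conditions = c("siCtrl", "siTHRAP3", "siBCLAF1",
                                           "siTHRAP3+siBCLAF1"),
                            planted_down = list(),
                            noise_sd_log2 = 0.05,
                            baseline_mean_log2 = 8,
                            baseline_sd_log2 = 1.5,
                            seed = 1L) {
  stopifnot(n_genes >= 1, n_replicates >= 2, length(conditions) >= 2,
            noise_sd_log2 >= 0, baseline_sd_log2 >= 0)
  for (p in planted_down) {
    stopifnot(p$condition %in% conditions,
              all(p$genes >= 1), all(p$genes <= n_genes),
              p$fold_change > 0,
              (p$compartment %||% "cytoplasmic") %in% c("nuclear", "cytoplasmic"))
  }
  new_spec(list(n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
                conditions = conditions, planted_down = planted_down,
                noise_sd_log2 = noise_sd_log2,
                baseline_mean_log2 = baseline_mean_log2,
                baseline_sd_log2 = baseline_sd_log2, seed = as.integer(seed)),
           "expression_spec")
}

#' Specification for a synthetic 3' UTR sequence set
#'
#' Background positions are i.i.d. from `background_probs`; a fraction of
#' sequences carries exactly one planted instance of `planted_motif` at a
#' recorded position.
#'
#' @param n_sequences number of sequences.
#' @param length_nt length of every sequence, nucleotides.
#' @param background_probs probabilities for A, C, G, T (normalised).
#' @param planted_motif ACGT string planted in carrier sequences.
#' @param planted_fraction fraction of sequences carrying one instance,
#'   in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return a `utr_spec` object.
#' @export
utr_spec <- function(n_sequences = 200,
                     length_nt = 300,
                     background_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     planted_motif = "GGAGGCTGGGGC",
                     planted_fraction = 1,
                     seed = 1L) {
  stopifnot(n_sequences >= 1, length_nt >= nchar(planted_motif),
            length(background_probs) == 4, all(background_probs >= 0),
            sum(background_probs) > 0,
            planted_fraction >= 0, planted_fraction <= 1)
  if (grepl("[^ACGT]", planted_motif))
    stop("planted_motif must contain only A, C, G, T", call. = FALSE)
  new_spec(list(n_sequences = as.integer(n_sequences), length_nt = as.integer(length_nt),
                background_probs = background_probs / sum(background_probs),
                planted_motif = planted_motif, planted_fraction = planted_fraction,
                seed = as.integer(seed)),
           "utr_spec")
}

#' Specification for a synthetic qPCR Cq table
#'
#' Cq values follow the log-linear amplification model
#' `Cq = intercept - log(concentration) / log(efficiency) + noise`, so that
#' at efficiency 2 a doubling of template lowers Cq by exactly one cycle.
#' Each primer gets an in-run dilution-series standard; RT-minus wells are
#' emitted with a no-amplification sentinel (`NA`) unless the primer is
#' listed as contaminated.
#'
#' @param primers data.frame with columns `primer`, `efficiency` (fold per
#'   cycle, in (1, 2]) and `intercept` (Cq at relative concentration 1).
#' @param samples data.frame with columns `primer`, `sample`, `condition`,
#'   `compartment`, `true_conc` (> 0); one row per unknown to measure.
#' @param standard_concs relative concentrations of the standard series
#'   (default a 10-fold, 5-point series).
#' @param n_replicates technical replicates per unknown well.
#' @param noise_sd Cq noise s.d., cycles.
#' @param contaminated character vector of primers whose RT-minus well
#'   amplifies (genomic contamination planted for QC testing).
#' @param seed integer RNG seed.
#' @return a `cq_spec` object.
#' @export
cq_spec <- function(primers = data.frame(primer = c("ACTB", "MALAT1"),
                                         efficiency = c(2, 2),
                                         intercept = c(20, 24)),
                    samples,
                    standard_concs = 10^(0:-4),
                    n_replicates = 3,
                    noise_sd = 0,
                    contaminated = character(0),
                    seed = 1L) {
  stopifnot(is.data.frame(primers),
            all(c("primer", "efficiency", "intercept") %in% names(primers)),
            all(primers$efficiency > 1), all(primers$efficiency <= 2),
            is.data.frame(samples),
            all(c("primer", "sample", "condition", "compartment", "true_conc")
                %in% names(samples)),
            all(samples$primer %in% primers$primer),
            length(standard_concs) >= 3, all(standard_concs > 0),
            n_replicates >= 1, noise_sd >= 0,
            all(contaminated %in% primers$primer))
  if (any(samples$true_conc <= 0))
    stop("all true concentrations must be positive", call. = FALSE)
  new_spec(list(primers = primers, samples = samples,
                standard_concs = standard_concs,
                n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
                contaminated = contaminated, seed = as.integer(seed)),
           "cq_spec")
}
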