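# Pipeline configuration and the end-to-end driver binding all stages.

default_config <- function() {
  list(
    seed = 1L,
    # image quantification
    erosion_px = 2L, ring_gap_px = 2L, ring_width_px = 30L,
    min_area_px = 40L, min_foci = 5L, min_denominator = 1000,
    # transcript sets
    fc_threshold = 1.5, fdr_alpha = 0.01, p_double = 0.05,
    # motif scan
    kmer_min = 8L, kmer_max = 20L, motif_alpha = 0.01, min_support = 5L,
    # statistics
    star_tiers = c(0.05, 0.005, 0.0005),
    # qPCR
    reference_gene = "ACTB", purity_marker = "MALAT1", purity_max_ratio = 0.1,
    # demo problem sizes for the simulate stage
    simulate = list(fish_n_cells = 8L, fish_shape = c(448L, 448L),
                    fish_true_ratio = 2,
                    foci_counts = c(0L, 3L, 5L, 8L),
                    expr_n_genes = 800L, expr_n_planted = 30L,
                    expr_fold_change = 0.4,
                    utr_n = 80L, utr_length = 300L,
                    utr_motif = "GGAGGCTGGGGC", utr_fraction = 0.6)
  )
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults (erosion 2 px, ring gap 2 px, ring width
#' 30 px, >= 5 foci scoring, 1.5-fold / FDR 0.01 filtering, k-mer widths
#' 8-20) and applies overrides from a YAML file and/or a named list.
#' Unknown keys are rejected.
#'
#' @param yaml_path optional YAML file of overrides.
#' @param overrides optional named list of overrides (applied after the
#'   file).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(yaml_path = NULL, overrides = list()) {
  cfg <- default_config()
  apply_over <- function(cfg, over, where) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (k in names(over)) {
      if (k == "simulate") {
        cfg$simulate <- apply_over(cfg$simulate, over$simulate, "simulate")
      } else cfg[[k]] <- over[[k]]
    }
    cfg
  }
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) stop("missing config file: ", yaml_path, call. = FALSE)
    cfg <- apply_over(cfg, yaml::read_yaml(yaml_path), yaml_path)
  }
  cfg <- apply_over(cfg, overrides, "overrides")
  stopifnot(cfg$erosion_px >= 0, cfg$ring_gap_px >= 0, cfg$ring_width_px >= 0,
            cfg$min_foci >= 1, cfg$fc_threshold > 0, cfg$fdr_alpha > 0,
            cfg$kmer_min >= 1, cfg$kmer_min <= cfg$kmer_max,
            length(cfg$star_tiers) == 3)
  structure(cfg, class = c("pipeline_config", "list"))
}

stage_path <- function(out_dir, ...) file.path(out_dir, ...)

#' Run the full synthetic-data pipeline
#'
#' Executes the requested stages in order, reading every stage's inputs from
#' disk (so all formats round-trip) and writing per-stage outputs plus a
#' provenance record under `out_dir`.  Deterministic given the config seed;
#' any stage failure halts with a stage-tagged error.
#'
#' Stages: `simulate` (writes synthetic images/tables and ground truth under
#' `data/`), `quantify` (N/C ratios and focus scores), `sets` (differential
#' filtering and overlaps), `motif` (k-mer scan), `qpcr` (standard-curve
#' quantification and indices), `annotate` (codon arithmetic for configured
#' variants) and `report` (condition summaries + provenance).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run, in pipeline order.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "quantify", "sets", "motif",
                                    "qpcr", "annotate", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(stage_path(out_dir, "data"), recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stop_stage(name, conditionMessage(e)))
  }

  run_stage("simulate", function() stage_simulate(config, out_dir))
  run_stage("quantify", function() stage_quantify(config, out_dir))
  run_stage("sets", function() stage_sets(config, out_dir))
  run_stage("motif", function() stage_motif(config, out_dir))
  run_stage("qpcr", function() stage_qpcr(config, out_dir))
  run_stage("annotate", function() stage_annotate(config, out_dir))
  run_stage("report", function() stage_report(config, out_dir))
  invisible(out_dir)
}

stage_simulate <- function(config, out_dir) {
  sim <- config$simulate
  data_dir <- stage_path(out_dir, "data")
  conds <- c("siCtrl", "siTHRAP3", "siBCLAF1", "siTHRAP3+siBCLAF1")
  ratios <- stats::setNames(c(1, sim$fish_true_ratio, 1.2 * 1, sim$fish_true_ratio),
                            conds)
  for (i in seq_along(conds)) {
    sp <- fish_image_spec(image_shape = sim$fish_shape,
                          n_cells = sim$fish_n_cells,
                          true_nc_ratio = ratios[i],
                          seed = config$seed + i)
    img <- generate_fish_image(sp)
    safe <- gsub("[^A-Za-z0-9]+", "_", conds[i])
    write_image_tiff(img$channels, stage_path(data_dir, paste0("fish_", safe, ".tif")))
    write_label_tiff(img$truth$nucleus_labels,
                     stage_path(data_dir, paste0("fish_", safe, "_truth_mask.tif")))
    write_table_csv(img$truth$cells,
                    stage_path(data_dir, paste0("fish_", safe, "_truth.csv")))
  }
  fsp <- foci_image_spec(n_cells = length(sim$foci_counts),
                         foci_counts = sim$foci_counts, seed = config$seed + 11L)
  fimg <- generate_foci_image(fsp)
  write_image_tiff(fimg$channels, stage_path(data_dir, "foci.tif"))
  write_label_tiff(fimg$truth$nucleus_labels, stage_path(data_dir, "foci_truth_mask.tif"))
  write_table_csv(fimg$truth$cells, stage_path(data_dir, "foci_truth.csv"))

  esp <- expression_spec(n_genes = sim$expr_n_genes,
                         planted_down = list(
                           list(condition = "siTHRAP3",
                                genes = 1:sim$expr_n_planted,
                                fold_change = sim$expr_fold_change),
                           list(condition = "siBCLAF1",
                                genes = seq(sim$expr_n_planted %/% 2,
                                            sim$expr_n_planted * 2),
                                fold_change = sim$expr_fold_change),
                           list(condition = "siTHRAP3+siBCLAF1",
                                genes = 1:(sim$expr_n_planted * 3),
                                fold_change = sim$expr_fold_change)),
                         seed = config$seed + 21L)
  ex <- generate_expression_table(esp)
  write_table_csv(ex$table, stage_path(data_dir, "expression.csv"))

  usp <- utr_spec(n_sequences = sim$utr_n, length_nt = sim$utr_length,
                  planted_motif = sim$utr_motif,
                  planted_fraction = sim$utr_fraction, seed = config$seed + 31L)
  utr <- generate_utr_set(usp)
  write_fasta(utr$sequences, stage_path(data_dir, "utr.fasta"))
  write_table_csv(utr$truth, stage_path(data_dir, "utr_truth.csv"))

  cq <- generate_cq_table(demo_cq_spec(config$seed + 41L))
  write_table_csv(cq$table, stage_path(data_dir, "cq.csv"))
  invisible(NULL)
}

# Two-condition qPCR scenario: an export defect (cytoplasmic target scaled
# down) in the knockdown condition, plus reference and purity-marker wells.
demo_cq_spec <- function(seed) {
  primers <- data.frame(primer = c("ACTB", "MALAT1", "ATM_pre", "ATM_post"),
                        efficiency = c(2, 2, 1.95, 1.98),
                        intercept = c(20, 24, 28, 23))
  grid <- expand.grid(primer = c("ACTB", "MALAT1", "ATM_pre", "ATM_post"),
                      condition = c("siCtrl", "siTHRAP3+siBCLAF1"),
                      compartment = c("nuclear", "cytoplasmic"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conc <- function(primer, condition, compartment) {
    kd <- condition != "siCtrl"
    switch(primer,
           ACTB = 1,
           MALAT1 = if (compartment == "nuclear") 1 else 0.02,
           ATM_pre = if (compartment == "nuclear") (if (kd) 0.6 else 0.2) else 0.02,
           ATM_post = {
             base <- if (compartment == "nuclear") 1 else 1
             if (kd) base * (if (compartment == "cytoplasmic") 0.25 else 0.5) else base
           })
  }
  grid$true_conc <- mapply(conc, grid$primer, grid$condition, grid$compartment)
  grid$sample <- paste(grid$condition, grid$compartment, sep = "_")
  cq_spec(primers = primers, samples = grid, noise_sd = 0.05, seed = seed)
}

stage_quantify <- function(config, out_dir) {
  data_dir <- stage_path(out_dir, "data")
  fish_files <- sort(list.files(data_dir, pattern = "^fish_.*\\.tif$",
                                full.names = TRUE))
  fish_files <- fish_files[!grepl("truth", fish_files)]
  if (!length(fish_files)) stop("missing input: no fish images under data/")
  summaries <- list(); per_cell <- list()
  for (f in fish_files) {
    cond <- sub("^fish_(.*)\\.tif$", "\\1", basename(f))
    ch <- read_image_tiff(f)
    labels <- segment_nuclei(ch[[1]], min_area_px = config$min_area_px)
    regions <- build_region_pair(labels, config$erosion_px,
                                 config$ring_gap_px, config$ring_width_px)
    meas <- measure_nc_ratio(ch[[2]], regions)
    meas$condition <- cond
    per_cell[[cond]] <- meas
    summaries[[cond]] <- condition_imaging_summary(meas, cond, config$min_foci)
  }
  write_table_csv(do.call(rbind, per_cell), stage_path(out_dir, "fish_per_cell.csv"))
  write_table_csv(do.call(rbind, summaries), stage_path(out_dir, "fish_summary.csv"))

  ch <- read_image_tiff(stage_path(data_dir, "foci.tif"))
  mask <- read_label_tiff(stage_path(data_dir, "foci_truth_mask.tif"))
  sc <- score_foci(ch[[2]], mask, min_foci = config$min_foci)
  write_table_csv(sc$cells, stage_path(out_dir, "foci_per_cell.csv"))
  write_json_report(list(fraction_positive = sc$fraction_positive,
                         min_foci = config$min_foci),
                    stage_path(out_dir, "foci_summary.json"))
  invisible(NULL)
}

stage_sets <- function(config, out_dir) {
  tab <- read_table_csv(stage_path(out_dir, "data", "expression.csv"))
  kds <- c("siTHRAP3", "siBCLAF1")
  sets <- lapply(stats::setNames(kds, kds), function(kd) {
    d <- differential_cytoplasmic(tab, "siCtrl", kd)
    filter_down(d, config$fc_threshold, config$fdr_alpha, label = kd)
  })
  d2 <- differential_cytoplasmic(tab, "siCtrl", "siTHRAP3+siBCLAF1")
  double_set <- filter_down(d2, config$fc_threshold, config$p_double,
                            p_column = "p_value", label = "siTHRAP3+siBCLAF1")
  for (s in c(sets, list(double_set)))
    write_gene_set(s, stage_path(out_dir, paste0(
      "down_", gsub("[^A-Za-z0-9]+", "_", s$label), ".txt")))
  ov <- overlap_stats(sets$siTHRAP3, sets$siBCLAF1)
  universe <- length(unique(tab$gene))
  write_json_report(list(
    overlap_single_knockdowns = ov,
    pct_double_of_universe = fraction_of_universe(double_set, universe),
    universe = universe), stage_path(out_dir, "sets_report.json"))
  invisible(NULL)
}

stage_motif <- function(config, out_dir) {
  seqs <- read_fasta(stage_path(out_dir, "data", "utr.fasta"))
  hits <- scan_kmers(seqs, config$kmer_min, config$kmer_max,
                     min_support = config$min_support,
                     alpha = config$motif_alpha)
  write_table_csv(hits, stage_path(out_dir, "motif_hits.csv"))
  write_json_report(list(top_hit = if (nrow(hits)) hits$kmer[1] else NA,
                         n_tested = attr(hits, "n_tested")),
                    stage_path(out_dir, "motif_report.json"))
  invisible(NULL)
}

stage_qpcr <- function(config, out_dir) {
  tab <- read_table_csv(stage_path(out_dir, "data", "cq.csv"))
  q <- quantify_cq_table(tab)
  conc <- q$concentrations
  ref <- conc[conc$primer == config$reference_gene, ]
  key <- paste(conc$condition, conc$compartment)
  refkey <- paste(ref$condition, ref$compartment)
  conc$normalized <- normalize_to_reference(
    conc$concentration, ref$concentration[match(key, refkey)])
  write_table_csv(conc, stage_path(out_dir, "qpcr_concentrations.csv"))

  mk <- conc[conc$primer == config$purity_marker, ]
  purity <- vapply(unique(mk$condition), function(cond) {
    purity_check(mk$concentration[mk$condition == cond &
                                    mk$compartment == "cytoplasmic"],
                 mk$concentration[mk$condition == cond &
                                    mk$compartment == "nuclear"],
                 config$purity_max_ratio)
  }, character(1))

  targ <- conc[grepl("_(pre|post)$", conc$primer), ]
  targ$transcript <- sub("_(pre|post)$", "", targ$primer)
  targ$splice_form <- sub("^.*_", "", targ$primer)
  targ$value <- targ$normalized
  idx <- splicing_export_indices(targ)
  write_table_csv(idx, stage_path(out_dir, "splicing_indices.csv"))
  write_json_report(list(purity = as.list(purity), rt_minus = as.list(q$rt_minus),
                         curves = lapply(q$curves, unclass)),
                    stage_path(out_dir, "qpcr_qc.json"))
  invisible(NULL)
}

stage_annotate <- function(config, out_dir) {
  variants <- data.frame(cds_position = c(301L, 2509L),
                         ref = "C", alt = "T")
  ann <- cbind(codon_of(variants$cds_position),
               substitution = paste0(variants$ref, variants$cds_position,
                                     ">", variants$alt))
  write_table_csv(ann, stage_path(out_dir, "variant_codons.csv"))
  invisible(NULL)
}

stage_report <- function(config, out_dir) {
  prov <- list(
    package = "ddrquant",
    version = as.character(utils::packageVersion("ddrquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config))
  cfg_path <- stage_path(out_dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  prov$config_md5 <- unname(tools::md5sum(cfg_path))
  write_json_report(prov, stage_path(out_dir, "provenance.json"))
  invisible(NULL)
}
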