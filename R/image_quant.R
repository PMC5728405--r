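# Image quantification: nuclear segmentation from the DAPI channel, eroded
# nuclear mask + surrounding cytoplasmic ring, per-cell nuclear/cytoplasmic
# signal ratio, per-nucleus focus scoring and two-channel reporter ratios.

as_img_matrix <- function(x, name = "image") {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a 2-D numeric matrix", call. = FALSE)
  x
}

#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, minimum-area
#' filter and (optionally) a distance-transform watershed to split touching
#' nuclei.  Labels are relabelled to contiguous positive integers.
#'
#' @param dapi 2-D numeric matrix, DAPI channel.
#' @param min_area_px minimum nucleus area in pixels (components below are
#'   dropped).
#' @param split_touching split touching nuclei by watershed on the distance
#'   map of the binary mask.
#' @param blur_sigma Gaussian smoothing s.d. in pixels before thresholding.
#' @return integer label matrix (0 = background), with attribute `params`.
#' @export
segment_nuclei <- function(dapi, min_area_px = 40, split_touching = FALSE,
                           blur_sigma = 2) {
  dapi <- as_img_matrix(dapi, "dapi")
  stopifnot(min_area_px >= 1)
  mx <- max(dapi)
  if (mx <= 0) {
    out <- matrix(0L, nrow(dapi), ncol(dapi))
    attr(out, "params") <- list(min_area_px = min_area_px,
                                split_touching = split_touching,
                                blur_sigma = blur_sigma)
    return(out)
  }
  img <- dapi / mx
  if (blur_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(img, sigma = blur_sigma))
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  bw <- EBImage::fillHull(EBImage::Image(img > thr))
  labels <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(bw), tolerance = 1)
  } else {
    EBImage::bwlabel(bw)
  }
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(dapi), ncol(dapi))
  # area filter + contiguous relabelling
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_area_px)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  attr(labels, "params") <- list(min_area_px = min_area_px,
                                 split_touching = split_touching,
                                 blur_sigma = blur_sigma, otsu = thr)
  labels
}

#' Build eroded nuclear masks and cytoplasmic rings
#'
#' For each labelled nucleus the nuclear measurement region is the nucleus
#' eroded by `erosion_px` (Chebyshev metric), and the cytoplasmic ring is the
#' set of pixels whose Chebyshev distance from the nucleus boundary lies in
#' `(ring_gap_px, ring_gap_px + ring_width_px]`, excluding all nuclei; a
#' pixel reachable from several nuclei is assigned to the nearest one.
#' Nuclei that vanish under erosion are flagged, as are nuclei whose ring
#' band is truncated by the image border.
#'
#' @param mask integer label matrix from [segment_nuclei()] (or a ground
#'   truth mask).
#' @param erosion_px pixels eroded from the nucleus perimeter (default 2).
#' @param ring_gap_px gap between the nucleus boundary and the inner ring
#'   edge (default 2).
#' @param ring_width_px ring width in pixels (default 30).
#' @return list with integer matrices `nuclear` and `ring` (label images of
#'   the measurement regions) and a data.frame `cells` (label, nucleus area,
#'   eroded area, ring area, `flag_empty_nucleus`, `flag_empty_ring`,
#'   `flag_border`).
#' @export
build_region_pair <- function(mask, erosion_px = 2, ring_gap_px = 2,
                              ring_width_px = 30) {
  mask <- as_img_matrix(mask, "mask")
  storage.mode(mask) <- "integer"
  stopifnot(erosion_px >= 0, ring_gap_px >= 0, ring_width_px >= 0)
  n <- max(mask, 0L)
  nuclear <- matrix(0L, nrow(mask), ncol(mask))
  pos <- which(mask > 0L, arr.ind = TRUE)
  for (k in seq_len(n)) {
    px <- pos[mask[pos] == k, , drop = FALSE]
    # erode within the label's padded bounding box; padding keeps the border
    # semantics (outside the box is background for an isolated component,
    # and any neighbouring label also counts as background)
    rs <- max(1L, min(px[, 1]) - 1L):min(nrow(mask), max(px[, 1]) + 1L)
    cs <- max(1L, min(px[, 2]) - 1L):min(ncol(mask), max(px[, 2]) + 1L)
    er <- erode_chebyshev(mask[rs, cs, drop = FALSE] == k, erosion_px)
    nuclear[rs, cs][er] <- k
  }
  outer_d <- ring_gap_px + ring_width_px
  bands <- label_distance_bands(mask, outer_d)
  ring <- matrix(0L, nrow(mask), ncol(mask))
  in_ring <- !is.na(bands$dist) & bands$dist > ring_gap_px & bands$dist <= outer_d
  ring[in_ring] <- bands$label[in_ring]
  ring[mask > 0L] <- 0L

  # border flag: the cell's full distance band reaches the image border, so
  # part of its ring would fall outside the field of view
  band_px <- !is.na(bands$dist)
  border <- rep(FALSE, n)
  if (n > 0) {
    edge_labels <- unique(c(bands$label[1, ], bands$label[nrow(mask), ],
                            bands$label[, 1], bands$label[, ncol(mask)]))
    edge_labels <- edge_labels[edge_labels > 0L & !is.na(edge_labels)]
    border[edge_labels] <- TRUE
  }
  nuc_area <- tabulate(mask[mask > 0L], n)
  ero_area <- tabulate(nuclear[nuclear > 0L], n)
  ring_area <- tabulate(ring[ring > 0L], n)
  cells <- data.frame(label = seq_len(n), nucleus_area = nuc_area,
                      eroded_area = ero_area, ring_area = ring_area,
                      flag_empty_nucleus = ero_area == 0L,
                      flag_empty_ring = ring_area == 0L,
                      flag_border = border)
  list(nuclear = nuclear, ring = ring, cells = cells,
       params = list(erosion_px = erosion_px, ring_gap_px = ring_gap_px,
                     ring_width_px = ring_width_px))
}

label_means <- function(img, labels, n) {
  if (n == 0L) return(numeric(0))
  idx <- labels > 0L
  if (!any(idx)) return(rep(NaN, n))
  sums <- rowsum(img[idx], labels[idx])
  counts <- tabulate(labels[idx], n)
  out <- rep(NaN, n)
  out[as.integer(rownames(sums))] <- sums[, 1]
  ifelse(counts > 0, out / counts, NaN)
}

#' Measure per-cell nuclear/cytoplasmic signal ratios
#'
#' Computes the mean signal intensity over each cell's eroded nuclear mask
#' and cytoplasmic ring and their ratio.  Cells with an empty ring, an empty
#' eroded nucleus, a non-positive ring mean or a border-truncated ring are
#' flagged; flagged cells carry `NA` ratios and are excluded from condition
#' summaries by default.
#'
#' @param signal 2-D numeric matrix, same shape as the mask.
#' @param regions output of [build_region_pair()].
#' @return data.frame with one row per cell: `label`, `nuclear_mean`,
#'   `cyto_mean`, `nc_ratio` and QC flag columns.
#' @export
measure_nc_ratio <- function(signal, regions) {
  signal <- as_img_matrix(signal, "signal")
  stopifnot(all(dim(signal) == dim(regions$nuclear)))
  n <- nrow(regions$cells)
  nm <- label_means(signal, regions$nuclear, n)
  cm <- label_means(signal, regions$ring, n)
  out <- regions$cells
  out$nuclear_mean <- nm
  out$cyto_mean <- cm
  out$flag_zero_denominator <- is.na(cm) | !is.finite(cm) | cm <= 0
  bad <- out$flag_empty_nucleus | out$flag_empty_ring |
    out$flag_zero_denominator | out$flag_border
  out$nc_ratio <- ifelse(bad, NA_real_, nm / cm)
  out
}

#' Count DNA-repair foci per nucleus
#'
#' Detects bright puncta inside each nucleus with a white top-hat transform
#' (grayscale opening with a disc of twice the expected focus radius),
#' thresholded per nucleus at `median + k_mad * MAD` of the top-hat signal
#' within the nucleus, followed by connected-component counting with a
#' minimum spot area.  Returns per-cell counts and the fraction of nuclei
#' with at least `min_foci` foci (the "≥ min_foci" scoring convention).
#'
#' @param foci 2-D numeric matrix, focus channel.
#' @param mask integer nucleus label matrix.
#' @param min_foci scoring threshold, >= 1; a cell scores positive when its
#'   count is `>= min_foci` (default 5).
#' @param focus_radius_px expected focus radius, used to size the top-hat
#'   structuring element.
#' @param k_mad robust threshold multiplier (default 5).
#' @param min_spot_area_px minimum connected-spot area in pixels (default 2).
#' @return list with `cells` (data.frame `label`, `foci_count`,
#'   `scored_positive`) and `fraction_positive`.
#' @export
score_foci <- function(foci, mask, min_foci = 5, focus_radius_px = 2,
                       k_mad = 5, min_spot_area_px = 2) {
  foci <- as_img_matrix(foci, "foci")
  mask <- as_img_matrix(mask, "mask")
  storage.mode(mask) <- "integer"
  stopifnot(all(dim(foci) == dim(mask)))
  if (min_foci < 1) stop("min_foci must be >= 1", call. = FALSE)
  n <- max(mask, 0L)
  counts <- integer(n)
  if (n > 0) {
    brush_size <- 2L * (2L * as.integer(focus_radius_px)) + 1L
    brush <- EBImage::makeBrush(brush_size, shape = "disc")
    opened <- EBImage::imageData(EBImage::opening(EBImage::Image(foci / max(foci, 1)),
                                                  brush)) * max(foci, 1)
    tophat <- foci - opened
    spots_all <- matrix(FALSE, nrow(mask), ncol(mask))
    for (k in seq_len(n)) {
      px <- mask == k
      v <- tophat[px]
      thr <- stats::median(v) + k_mad * stats::mad(v)
      spots_all <- spots_all | (px & tophat > thr)
    }
    lab <- EBImage::bwlabel(EBImage::Image(spots_all))
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0L])
      ok <- which(areas >= min_spot_area_px)
      for (s in ok) {
        # assign the spot to the nucleus owning its pixels (spots are inside
        # a single nucleus by construction of the threshold mask)
        owner <- mask[lab == s]
        owner <- owner[owner > 0L]
        if (length(owner)) counts[owner[1]] <- counts[owner[1]] + 1L
      }
    }
  }
  cells <- data.frame(label = seq_len(n), foci_count = counts,
                      scored_positive = counts >= min_foci)
  list(cells = cells,
       fraction_positive = if (n > 0) mean(cells$scored_positive) else 0)
}

#' Per-cell two-channel reporter ratios
#'
#' Measures, for each cell region in the mask, the mean numerator and
#' denominator intensity and their ratio.  Cells whose denominator mean is
#' below `min_denominator` (untransfected) are excluded; the condition mean
#' is taken over retained cells.
#'
#' @param numerator,denominator 2-D numeric matrices, same shape as `mask`.
#' @param mask integer label matrix of cell regions.
#' @param min_denominator exclusion threshold on the denominator mean.
#' @return list with `cells` (retained cells only: `label`, `num_mean`,
#'   `den_mean`, `ratio`), `excluded` (labels dropped) and `condition_mean`.
#' @export
reporter_ratio <- function(numerator, denominator, mask, min_denominator = 0) {
  numerator <- as_img_matrix(numerator, "numerator")
  denominator <- as_img_matrix(denominator, "denominator")
  mask <- as_img_matrix(mask, "mask")
  storage.mode(mask) <- "integer"
  stopifnot(all(dim(numerator) == dim(mask)), all(dim(denominator) == dim(mask)))
  n <- max(mask, 0L)
  nm <- label_means(numerator, mask, n)
  dm <- label_means(denominator, mask, n)
  keep <- !is.na(dm) & dm >= min_denominator & dm > 0
  if (n == 0 || !any(keep))
    stop("all cells excluded: no denominator-positive cells", call. = FALSE)
  cells <- data.frame(label = which(keep), num_mean = nm[keep],
                      den_mean = dm[keep], ratio = nm[keep] / dm[keep])
  list(cells = cells, excluded = which(!keep),
       condition_mean = mean(cells$ratio))
}

#' Mean nuclear signal across a cell population
#'
#' Mean of the per-nucleus mean intensities, with the SEM over cells
#' (the readout used for nuclear fluorescent-reporter assays).
#'
#' @param signal 2-D numeric matrix.
#' @param mask integer nucleus label matrix.
#' @return list with `cells` (per-nucleus means), `mean` and `sem`.
#' @export
mean_nuclear_signal <- function(signal, mask) {
  signal <- as_img_matrix(signal, "signal")
  mask <- as_img_matrix(mask, "mask")
  storage.mode(mask) <- "integer"
  n <- max(mask, 0L)
  if (n == 0) stop("no nuclei in mask", call. = FALSE)
  m <- label_means(signal, mask, n)
  s <- mean_sem(m)
  list(cells = data.frame(label = seq_len(n), nuclear_mean = m),
       mean = s$mean, sem = s$sem)
}

#' Summarise per-cell imaging measurements for one condition
#'
#' @param measurements data.frame from [measure_nc_ratio()], optionally with
#'   a `foci_count` column merged in.
#' @param condition condition label to attach.
#' @param min_foci focus-positivity threshold for the foci fraction.
#' @return one-row data.frame: condition, n cells retained, mean and SEM of
#'   the N/C ratio, and (when counts are present) the fraction of cells with
#'   `foci_count >= min_foci`.
#' @export
condition_imaging_summary <- function(measurements, condition = "condition",
                                      min_foci = 5) {
  ok <- !is.na(measurements$nc_ratio)
  s <- if (any(ok)) mean_sem(measurements$nc_ratio[ok]) else list(mean = NA_real_, sem = NA_real_)
  frac <- if ("foci_count" %in% names(measurements))
    mean(measurements$foci_count >= min_foci) else NA_real_
  data.frame(condition = condition, n_cells = sum(ok),
             nc_ratio_mean = s$mean, nc_ratio_sem = s$sem,
             foci_fraction = frac)
}
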