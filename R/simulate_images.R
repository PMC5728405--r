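# Synthetic fluorescence-microscopy fields with recorded ground truth.
#
# Nuclei are filled ellipses; cytoplasm is the Chebyshev annulus of stated
# extent around each nucleus.  Signal intensities are piecewise constant
# (background / cytoplasm / nucleus), so the noiseless per-cell
# nuclear/cytoplasmic mean ratio over the generator's own masks equals the
# spec's true ratio exactly, and additive Gaussian noise is the only noise
# source (shot noise is deliberately not modelled).  Images are plain
# numeric matrices on a 16-bit intensity scale, (row, col) indexed.

# Rejection-sample `n` cell centres with pairwise distance >= min_dist and
# distance >= margin from every border.  Errors out after bounded retries.
place_centers <- function(shape, n, min_dist, margin, max_tries = 2000L * max(n, 1L)) {
  if (n == 0) return(data.frame(row = numeric(0), col = numeric(0)))
  lo <- margin + 1
  if (shape[1] - margin < lo || shape[2] - margin < lo)
    stop("placement error: image too small for requested cell geometry", call. = FALSE)
  rows <- numeric(0); cols <- numeric(0); tries <- 0L
  while (length(rows) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement error: could not place ", n,
           " non-overlapping cells after ", max_tries, " tries", call. = FALSE)
    r <- runif(1, lo, shape[1] - margin)
    c <- runif(1, lo, shape[2] - margin)
    if (length(rows) == 0 || all((rows - r)^2 + (cols - c)^2 >= min_dist^2)) {
      rows <- c(rows, r); cols <- c(cols, c)
    }
  }
  data.frame(row = round(rows), col = round(cols))
}

# Linear pixel indices of a filled rotated ellipse clipped to the image.
ellipse_pixels <- function(shape, row, col, a, b, theta) {
  rmax <- ceiling(max(a, b))
  rs <- max(1, row - rmax):min(shape[1], row + rmax)
  cs <- max(1, col - rmax):min(shape[2], col + rmax)
  rg <- outer(rs - row, rep(1, length(cs)))
  cg <- outer(rep(1, length(rs)), cs - col)
  u <- cos(theta) * rg + sin(theta) * cg
  v <- -sin(theta) * rg + cos(theta) * cg
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside)
  rr <- rs[(idx - 1) %% length(rs) + 1]
  cc <- cs[(idx - 1) %/% length(rs) + 1]
  cbind(rr, cc)
}

# Draw ellipse parameters and render the nucleus label mask.
render_nuclei <- function(shape, centers, radius, jitter) {
  n <- nrow(centers)
  labels <- matrix(0L, shape[1], shape[2])
  cells <- data.frame(label = seq_len(n), row = centers$row, col = centers$col,
                      a = rep(NA_real_, n), b = rep(NA_real_, n),
                      theta = rep(NA_real_, n))
  for (k in seq_len(n)) {
    a <- radius * (1 + runif(1, -jitter, jitter))
    b <- radius * (1 + runif(1, -jitter, jitter))
    th <- runif(1, 0, pi)
    px <- ellipse_pixels(shape, centers$row[k], centers$col[k], a, b, th)
    labels[px] <- k
    cells$a[k] <- a; cells$b[k] <- b; cells$theta[k] <- th
  }
  list(labels = labels, cells = cells)
}

blur_dapi <- function(dapi, sigma = 2) {
  if (sigma <= 0) return(dapi)
  matrix(EBImage::imageData(EBImage::gblur(dapi, sigma = sigma)),
         nrow(dapi), ncol(dapi))
}

add_noise <- function(img, sd) {
  if (sd <= 0) return(img)
  img + matrix(rnorm(length(img), 0, sd), nrow(img), ncol(img))
}

#' Generate a synthetic RNA-FISH image with ground truth
#'
#' Renders the DAPI and signal channels described by a [fish_image_spec()].
#' The signal channel is `background_level` outside cells, `signal_base` on
#' each cell's cytoplasmic annulus and `signal_base * true_ratio` on its
#' nucleus, so the noiseless nuclear/cytoplasmic mean ratio over the
#' ground-truth masks is exact by construction.
#'
#' @param spec a [fish_image_spec()].
#' @return list with `channels` (matrices `dapi`, `signal`), `truth` (nucleus
#'   label mask `nucleus_labels`, cytoplasm label mask `cyto_labels`, per-cell
#'   table `cells` with 0-based centroids and `true_ratio`) and `spec`.
#' @export
generate_fish_image <- function(spec) {
  stopifnot(inherits(spec, "fish_image_spec"))
  shape <- spec$image_shape
  with_seed(spec$seed, {
    max_r <- spec$nucleus_radius_px * (1 + spec$radius_jitter)
    centers <- place_centers(shape, spec$n_cells,
                             min_dist = 2 * max_r + spec$cytoplasm_extent_px + 2,
                             margin = ceiling(max_r + spec$cytoplasm_extent_px + 4))
    nuc <- render_nuclei(shape, centers, spec$nucleus_radius_px, spec$radius_jitter)
    bands <- label_distance_bands(nuc$labels, spec$cytoplasm_extent_px)
    cyto <- bands$label
    cyto[nuc$labels > 0L] <- 0L

    ratios <- spec$true_nc_ratio *
      exp(rnorm(spec$n_cells, 0, spec$ratio_cv))
    signal <- matrix(spec$background_level, shape[1], shape[2])
    signal[cyto > 0L] <- spec$signal_base
    for (k in seq_len(spec$n_cells))
      signal[nuc$labels == k] <- spec$signal_base * ratios[k]
    signal <- add_noise(signal, spec$noise_sd)

    dapi <- matrix(0, shape[1], shape[2])
    dapi[nuc$labels > 0L] <- spec$dapi_level
    dapi <- blur_dapi(dapi)

    cells <- nuc$cells
    cells$row0 <- cells$row - 1L; cells$col0 <- cells$col - 1L
    cells$true_ratio <- if (spec$n_cells) ratios else numeric(0)
    list(channels = list(dapi = dapi, signal = signal),
         truth = list(nucleus_labels = nuc$labels, cyto_labels = cyto,
                      cells = cells),
         spec = spec)
  })
}

#' Generate a synthetic DNA-repair focus image with ground truth
#'
#' Plants exactly the requested number of disjoint bright discs inside each
#' nucleus; the focus channel is flat background elsewhere.
#'
#' @param spec a [foci_image_spec()].
#' @return list with `channels` (`dapi`, `foci`), `truth` (`nucleus_labels`,
#'   per-cell `cells` with `n_foci`, per-focus table `foci` with 0-based
#'   centres) and `spec`.
#' @export
generate_foci_image <- function(spec) {
  stopifnot(inherits(spec, "foci_image_spec"))
  shape <- spec$image_shape
  with_seed(spec$seed, {
    max_r <- spec$nucleus_radius_px * (1 + spec$radius_jitter)
    centers <- place_centers(shape, spec$n_cells,
                             min_dist = 2 * max_r + 4, margin = ceiling(max_r + 3))
    nuc <- render_nuclei(shape, centers, spec$nucleus_radius_px, spec$radius_jitter)
    fr <- spec$focus_radius_px
    foci_rows <- integer(0); foci_cols <- integer(0); foci_lab <- integer(0)
    for (k in seq_len(spec$n_cells)) {
      want <- spec$foci_counts[k]
      if (want == 0) next
      eligible <- which(erode_chebyshev(nuc$labels == k, fr + 1L), arr.ind = TRUE)
      if (nrow(eligible) < want)
        stop("placement error: nucleus ", k, " too small for ", want, " foci",
             call. = FALSE)
      # greedy pass over shuffled candidate centres, restarted a few times;
      # centres >= 2 fr + 2 apart keep the discs disjoint AND non-adjacent
      # (a one-pixel gap, so 8-connected labelling cannot merge them)
      min_sep2 <- (2 * fr + 2)^2
      got_r <- integer(0)
      for (attempt in 1:25) {
        ord <- sample.int(nrow(eligible))
        got_r <- integer(0); got_c <- integer(0)
        for (i in ord) {
          r <- eligible[i, 1]; c <- eligible[i, 2]
          if (length(got_r) == 0 ||
              all((got_r - r)^2 + (got_c - c)^2 >= min_sep2)) {
            got_r <- c(got_r, r); got_c <- c(got_c, c)
            if (length(got_r) == want) break
          }
        }
        if (length(got_r) == want) break
      }
      if (length(got_r) < want)
        stop("placement error: cannot fit ", want,
             " disjoint foci in nucleus ", k, call. = FALSE)
      foci_rows <- c(foci_rows, got_r); foci_cols <- c(foci_cols, got_c)
      foci_lab <- c(foci_lab, rep(k, want))
    }
    foci <- matrix(spec$background_level, shape[1], shape[2])
    for (i in seq_along(foci_rows)) {
      px <- ellipse_pixels(shape, foci_rows[i], foci_cols[i], fr, fr, 0)
      foci[px] <- spec$background_level + spec$focus_amplitude
    }
    foci <- add_noise(foci, spec$noise_sd)
    dapi <- matrix(0, shape[1], shape[2])
    dapi[nuc$labels > 0L] <- spec$dapi_level
    dapi <- blur_dapi(dapi)
    cells <- nuc$cells
    cells$n_foci <- spec$foci_counts
    list(channels = list(dapi = dapi, foci = foci),
         truth = list(nucleus_labels = nuc$labels, cells = cells,
                      foci = data.frame(label = foci_lab,
                                        row0 = foci_rows - 1L,
                                        col0 = foci_cols - 1L)),
         spec = spec)
  })
}

#' Generate a synthetic two-channel reporter image with ground truth
#'
#' Each expressing cell is uniform over its whole area (nucleus plus
#' cytoplasm) in both channels, with numerator = denominator x true ratio;
#' untransfected cells carry background only.
#'
#' @param spec a [reporter_image_spec()].
#' @return list with `channels` (`dapi`, `numerator`, `denominator`), `truth`
#'   (`nucleus_labels`, `cell_labels` covering nucleus + cytoplasm, per-cell
#'   table with `true_ratio` and `transfected`) and `spec`.
#' @export
generate_reporter_image <- function(spec) {
  stopifnot(inherits(spec, "reporter_image_spec"))
  shape <- spec$image_shape
  with_seed(spec$seed, {
    max_r <- spec$nucleus_radius_px * (1 + spec$radius_jitter)
    ext <- spec$cytoplasm_extent_px
    centers <- place_centers(shape, spec$n_cells,
                             min_dist = 2 * (max_r + ext) + 2,
                             margin = ceiling(max_r + ext + 2))
    nuc <- render_nuclei(shape, centers, spec$nucleus_radius_px, spec$radius_jitter)
    bands <- label_distance_bands(nuc$labels, ext)
    cell_labels <- bands$label

    transfected <- !(seq_len(spec$n_cells) %in% spec$untransfected)
    den <- matrix(spec$background_level, shape[1], shape[2])
    num <- matrix(spec$background_level, shape[1], shape[2])
    for (k in seq_len(spec$n_cells)) {
      if (!transfected[k]) next
      px <- cell_labels == k
      den[px] <- spec$denominator_base
      num[px] <- spec$denominator_base * spec$true_ratios[k]
    }
    den <- add_noise(den, spec$noise_sd)
    num <- add_noise(num, spec$noise_sd)
    dapi <- matrix(0, shape[1], shape[2])
    dapi[nuc$labels > 0L] <- spec$dapi_level
    dapi <- blur_dapi(dapi)
    cells <- nuc$cells
    cells$true_ratio <- if (spec$n_cells) spec$true_ratios else numeric(0)
    cells$transfected <- transfected
    list(channels = list(dapi = dapi, numerator = num, denominator = den),
         truth = list(nucleus_labels = nuc$labels, cell_labels = cell_labels,
                      cells = cells),
         spec = spec)
  })
}
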