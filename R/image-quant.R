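#' Segmentation parameters for field quantification
#'
#' @param lowpass_sigma Gaussian low-pass SD in pixels (0 disables smoothing).
#' @param threshold either `"otsu"` (default; parameter-free, robust for
#'   bimodal fluorescence fields) or a fixed numeric intensity threshold.
#' @param min_object_area smallest connected component kept, pixels^2.
#' @param max_object_area largest component kept (default `Inf`).
#' @param solidity_range objects outside this solidity interval are discarded
#'   as unlikely to be single cells (merged clumps, debris).
#' @param fill_holes fill interior holes before measuring objects.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(lowpass_sigma = 2, threshold = "otsu",
                                min_object_area = 50, max_object_area = Inf,
                                solidity_range = c(0.3, 1),
                                fill_holes = TRUE) {
  stopifnot(lowpass_sigma >= 0, min_object_area >= 1,
            max_object_area >= min_object_area,
            length(solidity_range) == 2L,
            solidity_range[1] >= 0, solidity_range[2] <= 1,
            solidity_range[1] <= solidity_range[2])
  if (!(identical(threshold, "otsu") ||
        (is.numeric(threshold) && length(threshold) == 1L)))
    stop("threshold must be \"otsu\" or a single numeric value")
  structure(list(lowpass_sigma = lowpass_sigma, threshold = threshold,
                 min_object_area = min_object_area,
                 max_object_area = max_object_area,
                 solidity_range = solidity_range, fill_holes = fill_holes),
            class = "segmentation_params")
}

#' Low-pass filter and binarise a channel
#'
#' Gaussian smoothing with `lowpass_sigma` followed by thresholding. With the
#' Otsu threshold the image is first rescaled to `[0, 1]`, making the mask
#' invariant to intensity rescaling; a constant image yields an all-background
#' mask (documented behaviour, not an error).
#'
#' @param channel numeric matrix of finite, non-negative intensities.
#' @param params a [segmentation_params()].
#' @return Logical mask with the same dimensions as `channel`.
#' @export
lowpass_binarise <- function(channel, params = segmentation_params()) {
  stopifnot(is.matrix(channel), all(is.finite(channel)))
  img <- channel
  if (params$lowpass_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = params$lowpass_sigma))
  if (identical(params$threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
    scaled <- (img - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
    img > rng[1] + th * diff(rng)
  } else {
    img > params$threshold
  }
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a small union-find pass; surviving labels are
# renumbered 1..n in order of their original (raster-order) label.
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(mask),
                                                              nrow(mask)))))
  nmax <- max(lab)
  if (nmax < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  dr <- cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1]))   # down-right
  dl <- cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  pairs <- rbind(dr, dl)
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(nmax)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nmax), find, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

#' Remove small connected components from a binary mask
#'
#' Components (8-connectivity) smaller than `min_object_area` pixels are
#' removed; larger components are untouched. Idempotent.
#'
#' @param mask logical matrix.
#' @param min_object_area area cutoff in pixels^2.
#' @return Filtered logical mask.
#' @export
size_filter <- function(mask, min_object_area) {
  stopifnot(is.matrix(mask), min_object_area >= 1)
  mask <- mask > 0
  if (min_object_area <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_object_area)
  lab %in% keep & mask
}

#' Positive-area fraction of a binary mask
#'
#' The marker-positive proportion of the field: true pixels over total pixels.
#'
#' @param mask logical matrix; must be non-empty.
#' @return Fraction in `[0, 1]`.
#' @export
positive_area_fraction <- function(mask) {
  stopifnot(is.matrix(mask))
  if (length(mask) == 0L) stop("positive_area_fraction: empty image")
  mean(mask > 0)
}

# solidity = pixel area / convex hull area, hull taken over pixel centres and
# dilated by half a pixel (shoelace area + perimeter/2 + 1, Pick-style) to
# approximate the rasterised hull; clamped to [0, 1]
mask_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2L) return(1)
  pts <- unique(cbind(cols, rows))
  if (nrow(pts) <= 2L) return(1)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[hull, , drop = FALSE]
  if (nrow(hp) < 3L) return(1)
  x <- hp[, 1]; y <- hp[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  min(n / (area + per / 2 + 1), 1)
}

#' Segment cells in a phase-contrast channel and measure shape features
#'
#' Low-pass binarisation, optional hole filling, 8-connected component
#' labelling, then size and solidity filtering; the high-intensity regions
#' surviving this thresholding typically correspond to single cells (merged
#' clumps are handled by the solidity filter; no watershed splitting).
#' Eccentricity is the second-central-moment definition
#' `sqrt(1 - (minor/major)^2)`: 0 for a circle, approaching 1 for a line.
#'
#' @param channel numeric matrix.
#' @param params a [segmentation_params()].
#' @return data.frame of per-object features (label, area, centroid_row,
#'   centroid_col, eccentricity, solidity), ordered by label (raster order of
#'   first pixel); zero rows is a valid result.
#' @export
segment_cells <- function(channel, params = segmentation_params()) {
  mask <- lowpass_binarise(channel, params)
  empty <- data.frame(label = integer(), area = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      eccentricity = numeric(), solidity = numeric())
  if (!any(mask)) return(empty)
  if (params$fill_holes)
    mask <- as.matrix(EBImage::imageData(
      EBImage::fillHull(matrix(as.numeric(mask), nrow(mask))))) > 0
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(empty)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  areas <- tabulate(lab[lab > 0], nbins = n)
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[lab > 0]
  sol <- vapply(seq_len(n), function(i) {
    sel <- labv == i
    mask_solidity(idx[sel, 1], idx[sel, 2])
  }, numeric(1))
  feats <- data.frame(label = seq_len(n), area = areas,
                      centroid_row = mom[, "m.cx"],
                      centroid_col = mom[, "m.cy"],
                      eccentricity = mom[, "m.eccentricity"],
                      solidity = sol)
  keep <- feats$area >= params$min_object_area &
    feats$area <= params$max_object_area &
    feats$solidity >= params$solidity_range[1] &
    feats$solidity <= params$solidity_range[2]
  out <- feats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean eccentricity of a segmented field
#'
#' Unweighted mean over the objects surviving filtering; `NA` when no objects
#' survive.
#'
#' @param features data.frame from [segment_cells()].
#' @return Numeric value or `NA_real_`.
#' @export
frame_mean_eccentricity <- function(features) {
  if (is.null(features) || nrow(features) == 0L) return(NA_real_)
  mean(features$eccentricity)
}

#' Quantify a manifest of fields and compare condition groups
#'
#' For each field the marker-positive area fraction (`mode = "area"`) or mean
#' cell eccentricity (`mode = "eccentricity"`) is computed; fields are averaged
#' within wells, wells are summarised per condition group (mean +/- SEM) and
#' the two groups compared with an unpaired two-tailed Welch t-test on the
#' per-well values.
#'
#' @param manifest data.frame with columns `well`, `condition` and either
#'   `path` (image files) or `value` (precomputed per-field values).
#' @param params a [segmentation_params()].
#' @param mode `"area"` or `"eccentricity"`.
#' @param reader function mapping a path to a numeric matrix.
#' @return List with `fields` (per-field values), `wells` (per-well means),
#'   `groups` (mean, SEM, n per condition) and `test` (Welch t statistic, df,
#'   two-sided p; `NA` with a note when a group has < 2 wells).
#' @export
quantify_wells <- function(manifest, params = segmentation_params(),
                           mode = c("area", "eccentricity"),
                           reader = read_field_image) {
  mode <- match.arg(mode)
  stopifnot(all(c("well", "condition") %in% names(manifest)))
  if (!"value" %in% names(manifest)) {
    stopifnot("path" %in% names(manifest))
    manifest$value <- vapply(manifest$path, function(p) {
      img <- reader(p)
      if (mode == "area") {
        m <- lowpass_binarise(img, params)
        m <- size_filter(m, params$min_object_area)
        positive_area_fraction(m)
      } else {
        frame_mean_eccentricity(segment_cells(img, params))
      }
    }, numeric(1))
  }
  wells <- stats::aggregate(value ~ condition + well, manifest, mean,
                            na.rm = TRUE)
  groups <- do.call(rbind, lapply(split(wells, wells$condition), function(g)
    data.frame(condition = g$condition[1], n_wells = nrow(g),
               mean = mean(g$value),
               sem = stats::sd(g$value) / sqrt(nrow(g)))))
  rownames(groups) <- NULL
  conds <- unique(wells$condition)
  test <- if (length(conds) == 2L) {
    welch_t(wells$value[wells$condition == conds[1]],
            wells$value[wells$condition == conds[2]])
  } else {
    list(statistic = NA_real_, df = NA_real_, p.value = NA_real_,
         note = "t-test needs exactly two condition groups")
  }
  list(fields = manifest, wells = wells, groups = groups, test = test)
}
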