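#' Specification of a synthetic ellipse field
#'
#' Describes one synthetic immunofluorescence field: elliptical cells of
#' controlled shape placed on a noisy background, from which the image
#' quantifiers can be validated against exact rendered ground truth.
#'
#' @param image_size integer length-2, (height, width) in pixels.
#' @param n_objects number of cells to place (>= 0).
#' @param semi_major_range,semi_minor_range pixel ranges the object axes are
#'   drawn from; every draw enforces semi-major >= semi-minor > 0.
#' @param intensity_fg,intensity_bg foreground / background intensity
#'   (arbitrary units).
#' @param psf_sigma Gaussian point-spread blur applied after rendering, pixels.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param allow_overlap if FALSE (default), objects are placed without overlap
#'   and fully inside the frame.
#' @return An object of class `ellipse_field_spec`.
#' @export
ellipse_field_spec <- function(image_size = c(256L, 256L),
                               n_objects = 12L,
                               semi_major_range = c(18, 40),
                               semi_minor_range = c(8, 20),
                               intensity_fg = 0.8,
                               intensity_bg = 0.05,
                               psf_sigma = 1,
                               noise_sd = 0.02,
                               allow_overlap = FALSE) {
  stopifnot(length(image_size) == 2L, all(image_size >= 8),
            n_objects >= 0,
            semi_major_range[1] > 0, semi_minor_range[1] > 0,
            semi_major_range[2] >= semi_minor_range[1],
            psf_sigma >= 0, noise_sd >= 0,
            intensity_fg > intensity_bg)
  structure(list(image_size = as.integer(image_size),
                 n_objects = as.integer(n_objects),
                 semi_major_range = semi_major_range,
                 semi_minor_range = semi_minor_range,
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 psf_sigma = psf_sigma, noise_sd = noise_sd,
                 allow_overlap = allow_overlap),
            class = "ellipse_field_spec")
}

# logical (h x w) mask of pixel centres inside the rotated ellipse
render_ellipse_mask <- function(h, w, centre, a, b, theta = 0) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - centre[1]; dx <- cols - centre[2]
  # rotate into the ellipse frame (theta measured from the column axis)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# second-central-moment eccentricity of a pixel set; independent of EBImage
# so the quantifier can be validated against it
mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(NA_real_)
  r <- idx[, 1] - mean(idx[, 1]); c <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(1 - l2 / l1, 0))
}

#' Generate a synthetic immunofluorescence field with ground truth
#'
#' Renders `n_objects` non-overlapping ellipses (marker channel) with one
#' nuclear disc per cell (nuclear channel), applies a Gaussian PSF and additive
#' noise, and records ground truth measured from the *rendered* pre-noise mask
#' rather than from the analytic ellipse formula, so that quantifier accuracy
#' is judged against what was actually drawn.
#'
#' @param spec an [ellipse_field_spec()].
#' @param seed integer seed; two seeds give different placements but the same
#'   object count.
#' @param max_attempts placement attempts per object before generation is
#'   reported as failed.
#' @return A list with elements `marker`, `nuclear` (numeric matrices),
#'   `mask` (logical ground-truth mask), `truth` (per-object data.frame with
#'   centre, axes, orientation and rendered-mask eccentricity) and
#'   `area_fraction` (ground-truth positive-area fraction).
#' @export
gen_if_image <- function(spec, seed = NULL, max_attempts = 200L) {
  stopifnot(inherits(spec, "ellipse_field_spec"))
  with_seed(seed, {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    mask <- matrix(FALSE, h, w)
    truth <- data.frame(label = integer(), row = numeric(), col = numeric(),
                        a = numeric(), b = numeric(), theta = numeric(),
                        eccentricity = numeric())
    placed <- list()
    if (spec$n_objects > 0) {
      for (i in seq_len(spec$n_objects)) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          a <- stats::runif(1, spec$semi_major_range[1], spec$semi_major_range[2])
          b <- stats::runif(1, spec$semi_minor_range[1],
                            min(a, spec$semi_minor_range[2]))
          th <- stats::runif(1, 0, pi)
          ctr <- c(stats::runif(1, a + 1, h - a - 1),
                   stats::runif(1, a + 1, w - a - 1))
          if (!spec$allow_overlap && length(placed)) {
            sep <- vapply(placed, function(p)
              sqrt(sum((p$ctr - ctr)^2)) > (p$a + a + 1), logical(1))
            if (!all(sep)) next
          }
          ok <- TRUE
          break
        }
        if (!ok)
          stop("gen_if_image: could not place ", spec$n_objects,
               " non-overlapping objects in a ", h, "x", w, " field")
        m <- render_ellipse_mask(h, w, ctr, a, b, th)
        mask <- mask | m
        placed[[i]] <- list(ctr = ctr, a = a)
        truth[i, ] <- list(i, ctr[1], ctr[2], a, b, th, mask_eccentricity(m))
      }
    }
    marker <- matrix(spec$intensity_bg, h, w)
    marker[mask] <- spec$intensity_fg
    nuclear <- matrix(spec$intensity_bg, h, w)
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        nm <- render_ellipse_mask(h, w, c(truth$row[i], truth$col[i]),
                                  max(3, truth$b[i] / 3),
                                  max(3, truth$b[i] / 3), 0)
        nuclear[nm] <- spec$intensity_fg
      }
    }
    if (spec$psf_sigma > 0) {
      marker <- as.matrix(EBImage::gblur(marker, sigma = spec$psf_sigma))
      nuclear <- as.matrix(EBImage::gblur(nuclear, sigma = spec$psf_sigma))
    }
    if (spec$noise_sd > 0) {
      marker <- marker + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      nuclear <- nuclear + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    marker <- pmax(marker, 0); nuclear <- pmax(nuclear, 0)
    list(marker = marker, nuclear = nuclear, mask = mask, truth = truth,
         area_fraction = mean(mask))
  })
}

#' Write a single-channel field as a 16-bit grayscale TIFF
#'
#' Filenames follow the `{well}_{time_min}_{channel}.tif` convention used by
#' the time-lapse manifest.
#'
#' @param img numeric matrix; values are clipped to `[0, max_intensity]` and
#'   scaled to the 16-bit range.
#' @param path output file path.
#' @param max_intensity intensity mapped to the top of the 16-bit range.
#' @export
write_field_tiff <- function(img, path, max_intensity = 1) {
  scaled <- pmin(pmax(img / max_intensity, 0), 1)
  EBImage::writeImage(EBImage::Image(scaled), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read a single-channel field image (TIFF/PNG) as a numeric matrix
#' @param path image file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_field_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) > 2L) img <- img[, , 1]
  as.matrix(EBImage::imageData(img))
}
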