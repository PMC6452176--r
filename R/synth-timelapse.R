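#' Mean-eccentricity trajectory for one cell line
#'
#' Builds the target mean-eccentricity time course used by the time-lapse
#' simulator. Within the analysis window (first 48 h) the trajectory is a
#' degree-6 polynomial whose derivative is, by construction,
#' `(1 + late_weight * t/tail_time) * (t - t1)(t - t2)(t - t3)(t - tail_time)`:
#' its derivative changes sign exactly at the three requested turning times and
#' nowhere else before `window_end`. Beyond the window the curve continues with
#' a C1 cubic to a maturation plateau and a gentle late decline (myotube
#' contraction), keeping eccentricity inside `[0, 1)` over the full schedule.
#'
#' @param turning_times three increasing times (min) within `(0, window_end)`;
#'   alignment maximum, fusion minimum, myotube-formation maximum.
#' @param baseline eccentricity at time 0 (confluent myoblasts).
#' @param amplitude height of the first (alignment) peak above baseline. The
#'   amplitude is capped automatically if the implied dip at the window end
#'   would push eccentricity below `floor`.
#' @param tail_time time (min) of the fourth derivative root, placed after
#'   `window_end` so the window holds exactly three turning points.
#' @param late_weight nonnegative weight deepening the later extrema relative
#'   to the alignment peak (the observed curves show pronounced fusion and
#'   myotube phases, which an unweighted root product cannot reproduce).
#' @param window_end end of the polynomial regime (min), default 2880 (48 h).
#' @param t_mat,mat_value time and value of the maturation plateau.
#' @param t_end,end_value end of schedule and late (contraction) value; if
#'   `NULL`, `mat_value - 0.05`.
#' @param floor lowest eccentricity the polynomial regime may reach.
#' @return A function `f(t)` mapping minutes to eccentricity, with the spec
#'   stored in attributes.
#' @export
make_trajectory <- function(turning_times, baseline = 0.35, amplitude = 0.35,
                            tail_time = 2950, late_weight = 1,
                            window_end = 2880, t_mat = 5040, mat_value = 0.45,
                            t_end = 7200, end_value = NULL, floor = 0.03) {
  stopifnot(length(turning_times) == 3L, all(diff(turning_times) > 0),
            turning_times[1] > 0, turning_times[3] < window_end,
            tail_time > window_end, baseline > 0, baseline < 1,
            late_weight >= 0, floor >= 0)
  if (is.null(end_value)) end_value <- mat_value - 0.05
  roots <- c(turning_times, tail_time)
  # ascending coefficients of prod(t - r), time in units of 1000 min
  cf <- 1
  for (r in roots / 1000) cf <- c(-r * cf, 0) + c(0, cf)
  cf <- c(cf, 0) + c(0, (late_weight / (tail_time / 1000)) * cf)
  icf <- c(0, cf / seq_along(cf))
  f0 <- function(t) drop(outer(t / 1000, seq_along(icf) - 1, "^") %*% icf)
  # the polynomial regime runs to tail_time, where the derivative is zero;
  # amplitude is capped so the dip there stays above `floor`
  base <- f0(seq(0, tail_time, by = 5)) - f0(0)
  peak <- f0(turning_times[1]) - f0(0)
  amp <- min(amplitude,
             (baseline - floor) / max(-min(base / peak), 1e-9))
  B <- amp / peak
  pv <- function(t) baseline + B * (f0(t) - f0(0))
  vj <- pv(tail_time)
  f <- function(t) {
    t <- as.numeric(t)
    y <- numeric(length(t))
    a <- t <= tail_time
    y[a] <- pv(t[a])
    b <- t > tail_time & t <= t_mat
    if (any(b)) {   # zero-slope smoothstep: C1 join, no overshoot
      u <- (t[b] - tail_time) / (t_mat - tail_time)
      y[b] <- vj + (mat_value - vj) * u^2 * (3 - 2 * u)
    }
    cc <- t > t_mat
    if (any(cc)) {
      u <- pmin((t[cc] - t_mat) / (t_end - t_mat), 1)
      y[cc] <- mat_value + (end_value - mat_value) * u^2 * (3 - 2 * u)
    }
    y
  }
  vals <- f(seq(0, t_end - 1, by = 5))
  if (any(vals < 0) || any(vals >= 1))
    stop("trajectory leaves [0, 1); adjust baseline/amplitude/plateau values")
  attr(f, "turning_times") <- turning_times
  attr(f, "amplitude") <- amp
  attr(f, "baseline") <- baseline
  f
}

#' Default trajectories for the control and FSHD lines
#'
#' The control line turns at 440, 1355 and 1860 min (alignment, initiation of
#' fusion, myotube formation); the FSHD line shares the shape but is delayed
#' (530, 1505, 2165 min) and damped (amplitude x 0.8), reflecting slower, less
#' extreme morphological change.
#'
#' @return Named list of two trajectory functions, `control` and `fshd`.
#' @export
default_trajectories <- function() {
  list(
    control = make_trajectory(c(440, 1355, 1860), baseline = 0.35,
                              amplitude = 0.35, tail_time = 2950,
                              late_weight = 1, mat_value = 0.45),
    fshd = make_trajectory(c(530, 1505, 2165), baseline = 0.35,
                           amplitude = 0.8 * 0.35, tail_time = 3050,
                           late_weight = 8, mat_value = 0.42)
  )
}

#' Time-lapse schedule and trajectory specification
#'
#' @param trajectories named list of trajectory functions, one per cell line
#'   (see [make_trajectory()], [default_trajectories()]).
#' @param interval_min imaging interval, minutes (default 5).
#' @param duration_min total imaging duration, minutes (default 7200 = 5 days);
#'   must be a multiple of `interval_min`.
#' @param wells_per_line replicate wells per line (default 3).
#' @param noise_sd SD of the replicate noise added to each well's per-frame
#'   mean eccentricity (default 0.02).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(trajectories = default_trajectories(),
                            interval_min = 5, duration_min = 7200,
                            wells_per_line = 3, noise_sd = 0.02) {
  stopifnot(length(trajectories) >= 1, !is.null(names(trajectories)),
            interval_min > 0, duration_min > 0,
            duration_min %% interval_min == 0,
            wells_per_line >= 1, noise_sd >= 0)
  structure(list(trajectories = trajectories, interval_min = interval_min,
                 duration_min = duration_min, wells_per_line = wells_per_line,
                 noise_sd = noise_sd),
            class = "trajectory_spec")
}

#' Simulate a time-lapse experiment with ground-truth eccentricity traces
#'
#' Emits `duration_min / interval_min` frames per well. The per-frame
#' ground-truth mean eccentricity is the trajectory value plus a recorded
#' replicate noise term; frames are rendered to disk only when `render_dir`
#' is given (one 16-bit TIFF per frame, `{well}_{time}_phase.tif`).
#'
#' @param spec a [trajectory_spec()].
#' @param seed integer seed driving replicate noise (and rendering).
#' @param render_dir directory for rendered phase-contrast-like frames, or
#'   `NULL` (default) to emit the manifest and truth table only.
#' @param field_spec an [ellipse_field_spec()] controlling rendered fields.
#' @return A list with `manifest` (well, line, time_min, frame, path) and
#'   `truth` (well, line, time_min, mean_eccentricity) data.frames.
#' @export
gen_timelapse <- function(spec, seed = 1L, render_dir = NULL,
                          field_spec = ellipse_field_spec(
                            image_size = c(256L, 256L), n_objects = 6L,
                            semi_major_range = c(14, 26),
                            semi_minor_range = c(5, 20))) {
  stopifnot(inherits(spec, "trajectory_spec"))
  times <- seq(0, spec$duration_min - spec$interval_min, by = spec$interval_min)
  lines <- names(spec$trajectories)
  wells <- expand.grid(rep = seq_len(spec$wells_per_line), line = lines,
                       stringsAsFactors = FALSE)
  wells$well <- sprintf("%s_w%d", wells$line, wells$rep)
  manifest <- do.call(rbind, lapply(seq_len(nrow(wells)), function(i) {
    data.frame(well = wells$well[i], line = wells$line[i], time_min = times,
               frame = seq_along(times), path = NA_character_,
               stringsAsFactors = FALSE)
  }))
  truth <- with_seed(seed, {
    tr <- manifest[c("well", "line", "time_min")]
    target <- numeric(nrow(tr))
    for (ln in lines) {
      sel <- tr$line == ln
      target[sel] <- spec$trajectories[[ln]](tr$time_min[sel])
    }
    tr$mean_eccentricity <- pmin(pmax(
      target + stats::rnorm(nrow(tr), 0, spec$noise_sd), 0), 0.999)
    tr
  })
  if (!is.null(render_dir)) {
    dir.create(render_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      fs <- field_spec
      img <- render_eccentric_field(fs, truth$mean_eccentricity[i],
                                    seed = child_seed(seed, i))
      p <- file.path(render_dir, sprintf("%s_%d_phase.tif",
                                         manifest$well[i],
                                         manifest$time_min[i]))
      write_field_tiff(img, p)
      manifest$path[i] <- p
    }
    utils::write.csv(manifest, file.path(render_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, truth = truth)
}

# render a field whose objects have mean eccentricity ~ target; cells are
# placed without overlap (merged cells would inflate measured eccentricity)
render_eccentric_field <- function(field_spec, target_ecc, seed = NULL,
                                   ecc_jitter = 0.03, max_attempts = 100L) {
  with_seed(seed, {
    h <- field_spec$image_size[1]; w <- field_spec$image_size[2]
    n <- field_spec$n_objects
    img <- matrix(field_spec$intensity_bg, h, w)
    ecc <- pmin(pmax(stats::rnorm(n, target_ecc, ecc_jitter), 0.02), 0.98)
    placed <- list()
    for (i in seq_len(n)) {
      for (att in seq_len(max_attempts)) {
        a <- stats::runif(1, field_spec$semi_major_range[1],
                          field_spec$semi_major_range[2])
        b <- a * sqrt(1 - ecc[i]^2)
        th <- stats::runif(1, 0, pi)
        ctr <- c(stats::runif(1, a + 1, h - a - 1),
                 stats::runif(1, a + 1, w - a - 1))
        clear <- all(vapply(placed, function(p)
          sqrt(sum((p$ctr - ctr)^2)) > p$a + a + 1, logical(1)))
        if (clear) {
          img[render_ellipse_mask(h, w, ctr, a, b, th)] <-
            field_spec$intensity_fg
          placed[[length(placed) + 1L]] <- list(ctr = ctr, a = a)
          break
        }
      }
    }
    if (field_spec$psf_sigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = field_spec$psf_sigma))
    if (field_spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, field_spec$noise_sd), h, w)
    pmax(img, 0)
  })
}
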