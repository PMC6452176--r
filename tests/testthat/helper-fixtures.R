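# shared fixture builders; everything is generated in code at test time

# noise-free field with a single rotated ellipse
one_ellipse_field <- function(a, b, theta = 0, size = c(128L, 128L),
                              fg = 0.8, bg = 0.05) {
  m <- myodyn:::render_ellipse_mask(size[1], size[2],
                                    centre = size / 2, a = a, b = b,
                                    theta = theta)
  img <- matrix(bg, size[1], size[2])
  img[m] <- fg
  list(img = img, mask = m)
}

# replicate-well trace around a target function of time
make_trace <- function(f, times, wells = 3, noise_sd = 0, seed = NULL,
                       line = "l", prefix = line) {
  myodyn:::with_seed(seed, do.call(rbind, lapply(seq_len(wells), function(w)
    data.frame(time_min = times, well = sprintf("%s%d", prefix, w),
               line = line,
               mean_eccentricity = f(times) +
                 stats::rnorm(length(times), 0, noise_sd)))))
}

# polynomial (ascending coefficients over scaled time in [0,1]) evaluator,
# independent of the fitting code
eval_poly <- function(coef, s) drop(outer(s, seq_along(coef) - 1, "^") %*% coef)

# polynomial with derivative roots exactly at `roots` (on the scaled axis),
# integrated analytically; the independent oracle for turning-point tests
poly_with_turnpoints <- function(roots, scale = 1, base = 0.5) {
  cf <- 1
  for (r in roots) cf <- c(-r * cf, 0) + c(0, cf)
  icf <- c(base, scale * cf / seq_along(cf))
  icf
}

# upper-tail hypergeometric by explicit combinatorial summation; the
# independent oracle for Fisher enrichment p-values
brute_hyper_upper <- function(k, m, N, L) {
  jmax <- min(m, L)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(choose(m, j) * choose(N - m, L - j)) / choose(N, L)
}
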