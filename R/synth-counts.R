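#' Sample design for the main differentiation time course
#'
#' Two cell lines (control and FSHD) harvested in triplicate at the eight
#' nodal time points gives the 48-sample main batch.
#'
#' @param lines named numeric vector mapping cell-line id to FSHD status (0/1).
#' @param times_min harvest times in minutes.
#' @param replicates replicates per line x time.
#' @param batch batch label.
#' @return data.frame with sample_id, cell_line, fshd_status, time_min,
#'   replicate, batch.
#' @export
design_timecourse <- function(lines = c(ctrl = 0, fshd = 1),
                              times_min = c(0, 440, 530, 1355, 1505,
                                            1860, 2165, 5040),
                              replicates = 3, batch = "timecourse") {
  stopifnot(all(lines %in% c(0, 1)), all(times_min >= 0), replicates >= 1)
  d <- expand.grid(replicate = seq_len(replicates), time_min = times_min,
                   cell_line = names(lines), stringsAsFactors = FALSE)
  d$fshd_status <- unname(lines[d$cell_line])
  d$batch <- batch
  d$sample_id <- sprintf("%s_t%d_r%d", d$cell_line, d$time_min, d$replicate)
  d[c("sample_id", "cell_line", "fshd_status", "time_min", "replicate", "batch")]
}

#' The three internally-controlled batch designs
#'
#' The main 48-sample time course plus two validation batches: four sibling
#' lines at two time points in triplicate (24 samples) and three mosaic-derived
#' lines at the same two time points (18 samples); 90 samples in total. The
#' batches are analysed separately.
#'
#' @return Named list of three design data.frames.
#' @export
fshd_batch_designs <- function() {
  list(
    timecourse = design_timecourse(),
    validation_siblings = design_timecourse(
      lines = c("16Ubic" = 0, "12Ubic" = 0, "16Abic" = 1, "12Abic" = 1),
      times_min = c(0, 5040), batch = "validation_siblings"),
    validation_mosaic = design_timecourse(
      lines = c("54-A10" = 0, "54-2" = 1, "54-A5" = 1),
      times_min = c(0, 5040), batch = "validation_mosaic")
  )
}

#' Ground-truth coefficients for the count simulator
#'
#' Draws per-gene true coefficients of the log2-scale model
#' `beta0 + a * FSHD + b * T + c * FSHD * T` (T in days) and designates a
#' "suppressed in FSHD differentiation" gene set with a stated excess of
#' negative-interaction genes relative to background: `set_n_negative` of the
#' `set_size` member genes carry `c = c_set`, while background genes are
#' negative with probability `bg_neg_frac` (and positive with `bg_pos_frac`,
#' zero otherwise), with magnitudes drawn from `bg_c_range`.
#'
#' @param n_genes gene universe size.
#' @param seed integer seed.
#' @param set_size designated set size.
#' @param set_n_negative members of the designated set with negative
#'   interaction.
#' @param c_set interaction coefficient of designated negative genes.
#' @param bg_neg_frac,bg_pos_frac background sign probabilities.
#' @param bg_c_range magnitude range of nonzero background interactions.
#' @param beta0_range baseline log2 abundance range.
#' @param a_sd,b_sd SDs of the disease and differentiation main effects.
#' @param dispersion negative-binomial dispersion, common to all genes.
#' @return List of class `counts_truth` with `genes` (per-gene coefficient
#'   data.frame), `sets` (named list; first element is the designated set) and
#'   `dispersion`.
#' @export
counts_ground_truth <- function(n_genes = 10000L, seed = 1L,
                                set_size = 100L, set_n_negative = 80L,
                                c_set = -1,
                                bg_neg_frac = 0.25, bg_pos_frac = 0.25,
                                bg_c_range = c(0.1, 0.8),
                                beta0_range = c(5, 9),
                                a_sd = 0.3, b_sd = 0.5,
                                dispersion = 0.05) {
  stopifnot(n_genes >= set_size, set_n_negative <= set_size,
            bg_neg_frac + bg_pos_frac <= 1, dispersion >= 0)
  with_seed(seed, {
    gene <- sprintf("gene%05d", seq_len(n_genes))
    beta0 <- stats::runif(n_genes, beta0_range[1], beta0_range[2])
    a <- stats::rnorm(n_genes, 0, a_sd)
    b <- stats::rnorm(n_genes, 0, b_sd)
    sgn <- sample(c(-1, 1, 0), n_genes, replace = TRUE,
                  prob = c(bg_neg_frac, bg_pos_frac,
                           1 - bg_neg_frac - bg_pos_frac))
    cc <- sgn * stats::runif(n_genes, bg_c_range[1], bg_c_range[2])
    set_genes <- sample(gene, set_size)
    neg_members <- set_genes[seq_len(set_n_negative)]
    cc[match(neg_members, gene)] <- c_set
    cc[match(setdiff(set_genes, neg_members), gene)] <- 0
    structure(list(
      genes = data.frame(gene = gene, beta0 = beta0, a = a, b = b, c = cc,
                         dispersion = dispersion, stringsAsFactors = FALSE),
      sets = list(PGC1A_TARGETS_SYN = sort(set_genes)),
      dispersion = dispersion), class = "counts_truth")
  })
}

#' Simulate a read-count matrix from a design and ground truth
#'
#' Counts are negative binomial with
#' `mean = sizefactor_s * 2^(beta0 + a*FSHD_s + b*T_s + c*FSHD_s*T_s)` where
#' `T_s = time_min / 1440` (days) and per-gene dispersion from the truth
#' object; `dispersion = 0` gives Poisson counts.
#'
#' @param design sample design data.frame (see [design_timecourse()]); needs
#'   columns `sample_id`, `fshd_status` (0/1), `time_min`, `replicate`.
#' @param truth a [counts_ground_truth()] object.
#' @param seed integer seed.
#' @param size_factor_range true library-size multipliers are drawn uniformly
#'   from this range (set `c(1, 1)` for none).
#' @return List with `counts` (genes x samples integer matrix), `design`
#'   (with a `true_size_factor` column) and `truth`.
#' @export
gen_counts <- function(design, truth, seed = 1L,
                       size_factor_range = c(0.7, 1.4)) {
  stopifnot(inherits(truth, "counts_truth"),
            all(c("sample_id", "fshd_status", "time_min") %in% names(design)),
            all(design$fshd_status %in% c(0, 1)), all(design$time_min >= 0))
  g <- truth$genes
  with_seed(seed, {
    sf <- stats::runif(nrow(design), size_factor_range[1], size_factor_range[2])
    tday <- design$time_min / 1440
    logmu <- outer(g$a, design$fshd_status) + outer(g$b, tday) +
      outer(g$c, design$fshd_status * tday) + g$beta0
    mu <- sweep(2^logmu, 2, sf, "*")
    if (any(!is.finite(mu)))
      stop("gen_counts: non-finite negative-binomial means; check coefficients")
    n <- length(mu)
    counts <- if (truth$dispersion == 0) {
      stats::rpois(n, lambda = mu)
    } else {
      stats::rnbinom(n, mu = mu, size = 1 / truth$dispersion)
    }
    counts <- matrix(as.integer(counts), nrow = nrow(g),
                     dimnames = list(g$gene, design$sample_id))
    design$true_size_factor <- sf
    list(counts = counts, design = design, truth = truth)
  })
}

#' Generate a gene-set collection around a simulated truth
#'
#' Bundles the designated (enriched) set from the truth object with random
#' control sets drawn from the gene universe, ready to write as GMT.
#'
#' @param truth a [counts_ground_truth()] object.
#' @param sizes integer vector of control-set sizes (all >= 1 and <= universe).
#' @param seed integer seed.
#' @return Named list of character vectors; the designated set comes first.
#' @export
gen_gene_sets <- function(truth, sizes = rep(c(50, 100, 200), length.out = 19),
                          seed = 1L) {
  stopifnot(inherits(truth, "counts_truth"))
  universe <- truth$genes$gene
  if (any(sizes < 1))
    stop("gen_gene_sets: control set sizes must be >= 1")
  if (any(sizes > length(universe)))
    stop("gen_gene_sets: requested set size exceeds the gene universe")
  with_seed(seed, {
    ctrl <- lapply(seq_along(sizes), function(i) sort(sample(universe, sizes[i])))
    names(ctrl) <- sprintf("RANDOM_SET_%02d", seq_along(sizes))
    c(truth$sets, ctrl)
  })
}
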