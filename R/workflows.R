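#' Morphodynamics workflow: traces to nodal time points
#'
#' Runs the imaging-side analysis chain: per-line polynomial fits of the mean
#' eccentricity trajectory, optional empirical-Bayes differential-eccentricity
#' testing between the first two lines, turning-point detection and nodal
#' time-point selection. Outputs (fit JSON, differential table TSV, nodal
#' list) carry provenance headers and are byte-identical on rerun with the
#' same config.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{traces}{long data.frame (`time_min`, `well`, `line`,
#'       `mean_eccentricity`) or a CSV path.}
#'     \item{degree}{polynomial degree (default 6).}
#'     \item{window}{fit/search window in minutes (default `c(0, 2880)`).}
#'     \item{t_start,t_end}{endpoints for the nodal list (default 0, 5040).}
#'     \item{tol}{nodal merge tolerance, minutes (default 5).}
#'     \item{run_eb}{toggle the differential stage (default TRUE).}
#'     \item{out_dir}{output directory, or `NULL` for no files.}
#'   }
#' @return List with `fits` (per line), `diff_ecc` (or `NULL`), and
#'   `nodal_timepoints`.
#' @export
run_morpho_workflow <- function(config) {
  cfg <- modify_defaults(list(degree = 6L, window = c(0, 2880),
                              t_start = 0, t_end = 5040, tol = 5,
                              run_eb = TRUE, out_dir = NULL), config)
  traces <- if (is.character(cfg$traces)) read_traces(cfg$traces) else cfg$traces
  stopifnot(is.data.frame(traces),
            all(c("time_min", "well", "line", "mean_eccentricity") %in%
                  names(traces)))
  lines <- unique(traces$line)
  if (length(lines) < 2L)
    stop("run_morpho_workflow: need at least two cell lines")
  fits <- lapply(lines, function(ln)
    fit_polynomial(traces[traces$line == ln, ], degree = cfg$degree,
                   window = cfg$window))
  names(fits) <- lines
  de <- NULL
  if (isTRUE(cfg$run_eb))
    de <- eb_differential(traces[traces$line == lines[1], ],
                          traces[traces$line == lines[2], ])
  nodal <- select_nodal_timepoints(fits[[1]], fits[[2]],
                                   t_start = cfg$t_start, t_end = cfg$t_end,
                                   window = cfg$window, tol = cfg$tol)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- list(degree = cfg$degree, window = cfg$window, tol = cfg$tol)
    for (ln in lines) {
      f <- fits[[ln]]
      jsonlite::write_json(
        list(line = ln, degree = f$degree, coefficients = f$coefficients,
             t0 = f$t0, t1 = f$t1, rmse = f$rmse,
             turning_points = turning_points(f, cfg$window)),
        file.path(cfg$out_dir, sprintf("fit_%s.json", ln)),
        auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(de))
      write_tsv_prov(de$table, file.path(cfg$out_dir, "diff_ecc.tsv"),
                     c(prov, list(prior_df = de$d0, prior_var = de$s02)))
    write_tsv_prov(data.frame(time_min = nodal),
                   file.path(cfg$out_dir, "nodal_timepoints.tsv"), prov)
  }
  list(fits = fits, diff_ecc = de, nodal_timepoints = nodal)
}

#' Dynamic differential-expression workflow: counts to enrichment
#'
#' Normalises a count matrix (median-of-ratios size factors, log2 scale),
#' fits the per-gene disease-by-time interaction regression, emits all six
#' top-K gene lists (a/b/c x positive/negative) and, when a gene-set
#' collection is supplied, a Fisher's-exact enrichment table per list.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{counts}{genes x samples matrix or TSV path (gene ids in the
#'       first column).}
#'     \item{metadata}{sample metadata data.frame or TSV path; needs
#'       `sample_id`, `fshd_status`, `time_min`.}
#'     \item{sets}{named list of gene sets, a GMT path, or `NULL` (enrichment
#'       skipped with a warning).}
#'     \item{K}{list length (default 500).}
#'     \item{min_frac_expressed}{expression filter: keep genes with >= 1
#'       count in at least this fraction of samples (default 0.25).}
#'     \item{intercept}{include an intercept in the design (default TRUE).}
#'     \item{out_dir}{output directory, or `NULL`.}
#'   }
#' @return List with `size_factors`, `fit`, `ranked` (named list of six gene
#'   lists) and `enrichment` (named list of data.frames, or `NULL`).
#' @export
run_de_workflow <- function(config) {
  cfg <- modify_defaults(list(K = 500L, min_frac_expressed = 0.25,
                              intercept = TRUE, sets = NULL, out_dir = NULL),
                         config)
  counts <- cfg$counts
  if (is.character(counts)) {
    tab <- utils::read.delim(counts, check.names = FALSE)
    counts <- as.matrix(tab[, -1]); rownames(counts) <- tab[[1]]
  }
  meta <- cfg$metadata
  if (is.character(meta)) meta <- utils::read.delim(meta)
  stopifnot(identical(colnames(counts), meta$sample_id))
  sets <- cfg$sets
  if (is.character(sets)) sets <- read_gmt(sets)
  expressed <- rowMeans(counts >= 1) >= cfg$min_frac_expressed
  counts <- counts[expressed, , drop = FALSE]
  if (cfg$K > nrow(counts))
    stop("run_de_workflow: K (", cfg$K, ") exceeds the ", nrow(counts),
         " genes surviving the expression filter")
  sf <- size_factors(counts)
  expr <- normalise_log(counts, sf)
  fit <- fit_gene_models(expr, build_design(meta, intercept = cfg$intercept))
  combos <- expand.grid(coefficient = c("a", "b", "c"),
                        direction = c("positive", "negative"),
                        stringsAsFactors = FALSE)
  ranked <- lapply(seq_len(nrow(combos)), function(i)
    rank_select(fit, combos$coefficient[i], combos$direction[i], K = cfg$K))
  names(ranked) <- paste(combos$coefficient, combos$direction, sep = "_")
  enrichment <- NULL
  if (is.null(sets) || length(sets) == 0L) {
    if (!is.null(cfg$sets))
      warning("run_de_workflow: empty gene-set collection; enrichment skipped")
  } else {
    universe <- rownames(fit$coef)
    enrichment <- lapply(ranked, fisher_gsea, universe = universe, sets = sets)
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- list(K = cfg$K, min_frac_expressed = cfg$min_frac_expressed,
                 intercept = cfg$intercept)
    write_tsv_prov(data.frame(sample_id = names(sf), size_factor = sf),
                   file.path(cfg$out_dir, "size_factors.tsv"), prov)
    write_tsv_prov(gene_fit_table(fit),
                   file.path(cfg$out_dir, "regression.tsv"), prov)
    for (nm in names(ranked))
      writeLines(ranked[[nm]],
                 file.path(cfg$out_dir, sprintf("top%d_%s.txt", cfg$K, nm)))
    for (nm in names(enrichment))
      write_tsv_prov(enrichment[[nm]],
                     file.path(cfg$out_dir,
                               sprintf("enrichment_%s.tsv", nm)), prov)
  }
  list(size_factors = sf, fit = fit, ranked = ranked,
       enrichment = enrichment)
}

#' Flatten a gene_fit into a long results table
#' @param fit a [fit_gene_models()] result.
#' @return data.frame: gene, term, coef, se, t, p_pos, p_neg.
#' @export
gene_fit_table <- function(fit) {
  stopifnot(inherits(fit, "gene_fit"))
  terms <- colnames(fit$coef)
  do.call(rbind, lapply(terms, function(tm)
    data.frame(gene = rownames(fit$coef), term = tm,
               coef = fit$coef[, tm], se = fit$se[, tm], t = fit$t[, tm],
               p_pos = fit$p_pos[, tm], p_neg = fit$p_neg[, tm],
               row.names = NULL)))
}

# shallow defaults merge for workflow configs
modify_defaults <- function(defaults, config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), c(names(defaults), "traces", "counts",
                                      "metadata"))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  defaults[names(config)] <- config
  defaults
}
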