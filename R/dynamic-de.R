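#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with nonzero
#' counts in every sample) of the ratio of the gene's count to its geometric
#' mean across samples. Corrects library-depth differences.
#'
#' @param counts genes x samples matrix of non-negative counts (>= 2 samples).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2L, all(counts >= 0))
  expressed <- rowSums(counts > 0) == ncol(counts)
  if (!any(expressed))
    stop("size_factors: no gene has nonzero counts in every sample")
  lc <- log(counts[expressed, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) stats::median(exp(x - loggeo)))
  stats::setNames(sf, colnames(counts))
}

#' Log2 normalisation of a count matrix
#'
#' `log2(count / size_factor + 1)`, the response scale for the per-gene
#' linear model.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample size factors (see [size_factors()]).
#' @return Numeric matrix of the same dimensions.
#' @export
normalise_log <- function(counts, factors = size_factors(counts)) {
  stopifnot(ncol(counts) == length(factors), all(factors > 0))
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' Design matrix for the disease-by-time interaction model
#'
#' Columns: intercept (optional), FSHD status (0/1), differentiation time in
#' days (`time_min / 1440`), and their product. The model the per-gene
#' regression fits is
#' `E_i = a_i * FSHD + b_i * Time + c_i * (FSHD : Time)`:
#' `a` captures constitutive disease differences, `b` the differentiation
#' programme, and `c` how the differentiation slope differs in disease. An
#' intercept is included by default so that baseline abundance does not
#' contaminate the disease main effect; `intercept = FALSE` gives the strict
#' no-intercept parameterisation.
#'
#' @param metadata data.frame with `fshd_status` (0/1) and `time_min` columns.
#' @param intercept include an intercept column (default TRUE).
#' @return Numeric design matrix with rownames from `metadata$sample_id`
#'   (when present) and columns among `intercept`, `a`, `b`, `c`.
#' @export
build_design <- function(metadata, intercept = TRUE) {
  stopifnot(all(c("fshd_status", "time_min") %in% names(metadata)),
            all(metadata$fshd_status %in% c(0, 1)),
            all(metadata$time_min >= 0))
  tday <- metadata$time_min / 1440
  X <- cbind(a = metadata$fshd_status, b = tday,
             c = metadata$fshd_status * tday)
  if (intercept) X <- cbind(intercept = 1, X)
  if ("sample_id" %in% names(metadata)) rownames(X) <- metadata$sample_id
  X
}

#' Per-gene interaction regression
#'
#' Fits the linear model defined by `design` to every gene of a (log2
#' normalised) expression matrix by ordinary least squares and reports, per
#' coefficient, one-sided p-values for positivity and for negativity from the
#' t distribution on the residual df (they sum to one). Genes with no signal
#' (all values identical) are excluded and flagged.
#'
#' @param expr genes x samples numeric matrix (see [normalise_log()]).
#' @param design design matrix from [build_design()]; must be full rank with
#'   residual df >= 1.
#' @return Object of class `gene_fit`: matrices `coef`, `se`, `t`, `p_pos`,
#'   `p_neg` (genes x terms), residual `df`, and `excluded` gene ids.
#' @export
fit_gene_models <- function(expr, design) {
  stopifnot(is.matrix(expr), is.matrix(design),
            ncol(expr) == nrow(design))
  p <- ncol(design); n <- nrow(design)
  if (n - p < 1L) stop("fit_gene_models: residual df < 1")
  qrx <- qr(design)
  if (qrx$rank < p)
    stop("fit_gene_models: rank-deficient design matrix")
  keep <- matrixStats_rowVars(expr) > 0
  excluded <- rownames(expr)[!keep]
  Y <- t(expr[keep, , drop = FALSE])
  cf <- qr.coef(qrx, Y)                      # p x G
  res <- Y - design %*% cf
  df <- n - p
  s2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qrx))
  se <- sqrt(outer(diag(xtxi), s2))          # p x G
  tt <- cf / se
  tt[se == 0] <- 0
  p_pos <- stats::pt(tt, df = df, lower.tail = FALSE)
  p_neg <- stats::pt(tt, df = df, lower.tail = TRUE)
  dimn <- list(rownames(expr)[keep], colnames(design))
  orient <- function(m) { m <- t(m); dimnames(m) <- dimn; m }
  structure(list(coef = orient(cf), se = orient(se), t = orient(tt),
                 p_pos = orient(p_pos), p_neg = orient(p_neg),
                 df = df, excluded = excluded),
            class = "gene_fit")
}

# rowVars without a matrixStats dependency
matrixStats_rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("gene_fit: %d genes x %d terms (%s), residual df %d\n",
              nrow(x$coef), ncol(x$coef),
              paste(colnames(x$coef), collapse = ", "), x$df))
  if (length(x$excluded))
    cat(sprintf("  %d constant genes excluded\n", length(x$excluded)))
  invisible(x)
}

#' Rank genes on a coefficient and select the top K
#'
#' Genes are ordered by the chosen one-sided p-value ascending (the most
#' significantly positive or negative coefficient first); ties are broken by
#' coefficient magnitude (larger first), then by gene id.
#'
#' @param fit a [fit_gene_models()] result.
#' @param coefficient term name: `"a"` (disease), `"b"` (time) or `"c"`
#'   (interaction).
#' @param direction `"positive"` or `"negative"`.
#' @param K list length (default 500); must not exceed the number of tested
#'   genes.
#' @param by `"significance"` (default) or `"magnitude"` (rank on the raw
#'   coefficient value instead of its one-sided p).
#' @return Character vector of K gene ids, ordered.
#' @export
rank_select <- function(fit, coefficient = c("c", "a", "b"),
                        direction = c("negative", "positive"), K = 500L,
                        by = c("significance", "magnitude")) {
  stopifnot(inherits(fit, "gene_fit"))
  coefficient <- match.arg(coefficient)
  direction <- match.arg(direction)
  by <- match.arg(by)
  if (!coefficient %in% colnames(fit$coef))
    stop("rank_select: coefficient '", coefficient, "' not in the fit")
  genes <- rownames(fit$coef)
  if (K > length(genes))
    stop("rank_select: K exceeds the number of tested genes")
  cf <- fit$coef[, coefficient]
  key <- if (by == "significance") {
    if (direction == "positive") fit$p_pos[, coefficient]
    else fit$p_neg[, coefficient]
  } else {
    if (direction == "positive") -cf else cf
  }
  ord <- order(key, -abs(cf), genes)
  genes[ord][seq_len(K)]
}

#' Fisher's exact gene-set over-representation
#'
#' One-sided (enrichment) Fisher's exact test of the overlap between a gene
#' list and each gene set, against a gene universe; the p-value is the
#' hypergeometric upper tail of the 2x2 table. Sets are intersected with the
#' universe before testing; BH adjustment is applied across sets.
#'
#' @param gene_list character vector, a subset of `universe`.
#' @param universe character vector of all tested genes.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @return data.frame per set: overlap, set_size (within universe), list_size,
#'   universe_size, p_value, p_bh, and an `empty` flag for sets with no genes
#'   in the universe (reported with p = 1).
#' @export
fisher_gsea <- function(gene_list, universe, sets) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe))
    stop("fisher_gsea: gene_list must be a subset of universe")
  N <- length(universe); L <- length(gene_list)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    m <- length(s)
    k <- length(intersect(s, gene_list))
    p <- if (m == 0L) 1 else
      stats::phyper(k - 1, m, N - m, L, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = m, list_size = L,
               universe_size = N, p_value = p, empty = m == 0L,
               stringsAsFactors = FALSE)
  }))
  res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res[c("set", "overlap", "set_size", "list_size", "universe_size",
        "p_value", "p_bh", "empty")]
}

#' Mean-signature score per sample with a two-group comparison
#'
#' The unweighted mean of the (log2 normalised) expression of a gene list in
#' each sample, compared between two labelled groups with an unpaired
#' two-tailed Welch t-test.
#'
#' @param expr genes x samples matrix.
#' @param gene_list genes to average; must all be rows of `expr`.
#' @param groups per-sample group labels (exactly two levels for the test).
#' @return List with `scores` (per-sample means) and `test` (statistic, df,
#'   p.value; `NA` with a note when a group has < 2 samples).
#' @export
signature_score <- function(expr, gene_list, groups) {
  stopifnot(length(groups) == ncol(expr))
  missing <- setdiff(gene_list, rownames(expr))
  if (length(missing))
    stop("signature_score: genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sc <- colMeans(expr[gene_list, , drop = FALSE])
  lv <- unique(groups)
  test <- if (length(lv) == 2L)
    welch_t(sc[groups == lv[1]], sc[groups == lv[2]])
  else list(statistic = NA_real_, df = NA_real_, p.value = NA_real_,
            note = "signature test needs exactly two groups")
  list(scores = sc, test = test)
}

#' Within-pair z-normalisation followed by an unpaired Wilcoxon test
#'
#' Expression values are z-scored within each patient-control pair (mean 0,
#' SD 1 across that pair's samples), pooled, and compared between disease and
#' control groups with a two-sided unpaired Wilcoxon rank-sum test (exact for
#' group sizes up to 25, normal approximation with continuity correction
#' above). Pairs with zero variance are dropped with a warning.
#'
#' @param values numeric vector (one gene's normalised expression per sample).
#' @param pair per-sample pair identifiers.
#' @param group per-sample 0/1 (control/disease) labels.
#' @return List: `p_value`, `statistic`, the pooled `z` scores and group
#'   sizes `n`.
#' @export
paired_z_wilcoxon <- function(values, pair, group) {
  stopifnot(length(values) == length(pair), length(values) == length(group),
            all(group %in% c(0, 1)))
  z <- rep(NA_real_, length(values))
  for (p in unique(pair)) {
    sel <- pair == p
    s <- stats::sd(values[sel])
    if (!is.finite(s) || s == 0) {
      warning("paired_z_wilcoxon: pair '", p,
              "' has zero variance and was dropped")
      next
    }
    z[sel] <- (values[sel] - mean(values[sel])) / s
  }
  ok <- is.finite(z)
  z1 <- z[ok & group == 1]; z0 <- z[ok & group == 0]
  if (!length(z1) || !length(z0))
    stop("paired_z_wilcoxon: a group has no usable samples")
  exact <- max(length(z1), length(z0)) <= 25
  wt <- suppressWarnings(stats::wilcox.test(z1, z0, exact = exact,
                                            correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic), z = z,
       n = c(disease = length(z1), control = length(z0)))
}
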