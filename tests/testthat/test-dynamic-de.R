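test_that("size factors follow the median-of-ratios construction", {
  # sample B at exactly twice sample A: factors {1/sqrt(2), sqrt(2)}
  a <- c(10, 20, 50, 100, 7)
  counts <- cbind(A = a, B = 2L * a)
  rownames(counts) <- sprintf("g%d", 1:5)
  expect_equal(unname(size_factors(counts)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # identical samples: all factors one
  expect_equal(unname(size_factors(cbind(a, a, a))), rep(1, 3))

  # genes with a zero anywhere are excluded from the median
  counts2 <- rbind(counts, zero = c(0L, 1000L))
  expect_equal(size_factors(counts2), size_factors(counts))
  expect_error(size_factors(rbind(c(0, 5), c(5, 0))), "no gene")

  # multiplying one sample by k multiplies its factor by k and leaves
  # normalised values unchanged (up to the geometric-mean renormalisation)
  set.seed(1)
  m <- matrix(rnbinom(600, mu = 50, size = 2) + 1L, 100, 6,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:6)))
  f1 <- size_factors(m)
  m2 <- m; m2[, 3] <- 5L * m2[, 3]
  f2 <- size_factors(m2)
  scale <- 5^(1 / 6)  # geometric mean of every gene shifts by 5^(1/6)
  expect_equal(unname(f2[3] / f1[3]), 5 / scale, tolerance = 1e-10)
  expect_equal(unname(f2[-3] / f1[-3]), rep(1 / scale, 5), tolerance = 1e-10)
  # normalised counts of the scaled sample are unchanged up to the common
  # geometric-mean renormalisation (between-sample ratios are preserved)
  expect_equal(m2[, 3] / f2[3], (m[, 3] / f1[3]) * scale, tolerance = 1e-10)
  expect_equal((m2[, 3] / f2[3]) / (m2[, 1] / f2[1]),
               (m[, 3] / f1[3]) / (m[, 1] / f1[1]), tolerance = 1e-10)
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  m <- matrix(rnbinom(99 * 8, mu = 80, size = 1) + 1L, 99, 8)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("log normalisation has the documented fixed points", {
  cm <- matrix(c(0, 7, 14), 3, 1, dimnames = list(c("g1", "g2", "g3"), "s"))
  expect_equal(unname(normalise_log(cm, 1)[, 1]), c(0, 3, log2(15)))
  expect_equal(unname(normalise_log(cm, 2)["g3", ]), 3)
})

test_that("per-gene regression recovers constructed truths exactly", {
  meta <- design_timecourse()
  X <- build_design(meta)
  # noiseless expression built from the model is interpolated exactly
  expr <- rbind(g1 = 1 + 2 * X[, "a"] + 3 * X[, "b"] - 1.5 * X[, "c"],
                g2 = 5 - X[, "a"] + 0 * X[, "b"] + 2 * X[, "c"])
  fit <- fit_gene_models(expr, X)
  expect_equal(unname(fit$coef["g1", ]), c(1, 2, 3, -1.5), tolerance = 1e-12)
  expect_equal(unname(fit$coef["g2", ]), c(5, -1, 0, 2), tolerance = 1e-12)

  # one-sided p-values are complementary and reverse-ranked
  set.seed(3)
  expr2 <- expr + matrix(rnorm(length(expr), 0, 0.1), nrow(expr))
  rownames(expr2) <- c("g1", "g2")
  fit2 <- fit_gene_models(expr2, X)
  expect_equal(fit2$p_pos + fit2$p_neg,
               matrix(1, 2, 4, dimnames = dimnames(fit2$p_pos)))
  expect_equal(order(fit2$p_pos[, "c"]), rev(order(fit2$p_neg[, "c"])))

  # constant genes are excluded and flagged; rank deficiency is an error
  expr3 <- rbind(expr2, flat = rep(0, nrow(X)))
  fit3 <- fit_gene_models(expr3, X)
  expect_equal(fit3$excluded, "flat")
  expect_equal(nrow(fit3$coef), 2)
  Xbad <- cbind(X, dup = X[, "a"])
  expect_error(fit_gene_models(expr, Xbad), "rank-deficient")
})

test_that("regression coefficients are recovered from count simulations", {
  tru <- counts_ground_truth(n_genes = 800, seed = 4, set_size = 10,
                             set_n_negative = 0, dispersion = 0.05)
  idx <- 1:200
  tru$genes$c[idx] <- rep(c(-1, 1), 100)   # planted strong interactions
  cm <- gen_counts(design_timecourse(), tru, seed = 5)
  fit <- fit_gene_models(normalise_log(cm$counts), build_design(cm$design))
  g <- tru$genes[match(rownames(fit$coef), tru$genes$gene), ]
  for (term in c("a", "b", "c"))
    expect_lt(abs(mean(fit$coef[, term] - g[[term]])), 0.05)
  sel <- match(tru$genes$gene[idx], rownames(fit$coef))
  expect_gte(mean(sign(fit$coef[sel, "c"]) == sign(g$c[sel])), 0.95)
})

test_that("ranking orders by one-sided significance with stated tie-breaks", {
  coef <- c(gA = -2, gB = 3, gC = -2, gD = 0.5)
  se <- c(1, 1, 0.4, 0.1)
  expr <- NULL  # build a gene_fit directly from its parts
  tt <- coef / se
  df <- 10
  fit <- structure(list(
    coef = matrix(coef, ncol = 1, dimnames = list(names(coef), "c")),
    se = matrix(se, ncol = 1, dimnames = list(names(coef), "c")),
    t = matrix(tt, ncol = 1, dimnames = list(names(coef), "c")),
    p_pos = matrix(pt(tt, df, lower.tail = FALSE), ncol = 1,
                   dimnames = list(names(coef), "c")),
    p_neg = matrix(pt(tt, df), ncol = 1,
                   dimnames = list(names(coef), "c")),
    df = df, excluded = character()), class = "gene_fit")
  expect_equal(rank_select(fit, "c", "negative", K = 1), "gC")
  expect_equal(rank_select(fit, "c", "negative", K = 4),
               c("gC", "gA", "gB", "gD"))
  # most significantly positive, not largest coefficient: gD (t = 5) beats
  # gB (t = 3)
  expect_equal(rank_select(fit, "c", "positive", K = 1), "gD")
  expect_error(rank_select(fit, "c", "negative", K = 5), "exceeds")

  # exact p ties break on coefficient magnitude
  fit$p_neg[] <- 0.5
  expect_equal(rank_select(fit, "c", "negative", K = 2), c("gB", "gA"))

  # two genes with t = +5 / -5: the negative one wins the negative list
  t2 <- c(up = 5, dn = -5)
  fit2 <- structure(list(
    coef = matrix(t2, ncol = 1, dimnames = list(names(t2), "c")),
    se = matrix(1, 2, 1, dimnames = list(names(t2), "c")),
    t = matrix(t2, ncol = 1, dimnames = list(names(t2), "c")),
    p_pos = matrix(pt(t2, 10, lower.tail = FALSE), ncol = 1,
                   dimnames = list(names(t2), "c")),
    p_neg = matrix(pt(t2, 10), ncol = 1, dimnames = list(names(t2), "c")),
    df = 10, excluded = character()), class = "gene_fit")
  expect_equal(rank_select(fit2, "c", "negative", K = 1), "dn")
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  universe <- sprintf("g%02d", 1:20)
  glist <- universe[1:5]
  set4 <- universe[c(1:4, 10)]              # overlap 4 of 5
  res <- fisher_gsea(glist, universe, list(s = set4))
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$overlap, 4)

  # disjoint set: one-sided enrichment p is large, never below the floor
  res0 <- fisher_gsea(glist, universe, list(s = universe[6:10]))
  expect_gte(res0$p_value, 0.5)

  # set identical to the list: the single most extreme table
  res1 <- fisher_gsea(glist, universe, list(s = glist))
  expect_equal(res1$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # empty-in-universe set is flagged with p = 1
  res2 <- fisher_gsea(glist, universe, list(s = c("zz1", "zz2")))
  expect_true(res2$empty)
  expect_equal(res2$p_value, 1)

  # randomised agreement with the combinatorial oracle
  set.seed(6)
  for (i in 1:50) {
    N <- sample(5:50, 1)
    uni <- sprintf("u%02d", 1:N)
    L <- sample(seq_len(N - 1), 1)
    m <- sample(seq_len(N), 1)
    gl <- sample(uni, L); st <- sample(uni, m)
    k <- length(intersect(gl, st))
    p <- fisher_gsea(gl, uni, list(s = st))$p_value
    expect_equal(p, brute_hyper_upper(k, m, N, L), tolerance = 1e-12)
    # and with R's own Fisher test as a second, independent route
    tab <- matrix(c(k, L - k, m - k, N - m - L + k), 2)
    expect_equal(p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("signature scores average genes and compare groups", {
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(3, 4, 5, 6))
  colnames(expr) <- sprintf("s%d", 1:4)
  sc <- signature_score(expr, c("g1", "g2"), groups = c("a", "a", "b", "b"))
  expect_equal(unname(sc$scores), c(2, 3, 4, 5))
  # a single-gene list is that gene's value
  expect_equal(unname(signature_score(expr, "g1",
                                      c("a", "a", "b", "b"))$scores),
               c(1, 2, 3, 4))
  # identical groups: p = 1
  e2 <- cbind(expr, expr); colnames(e2) <- sprintf("s%d", 1:8)
  sc2 <- signature_score(e2, c("g1", "g2"),
                         groups = rep(c("a", "b"), each = 4))
  expect_equal(sc2$test$p.value, 1)
  # shifted groups with tiny noise are significant
  set.seed(7)
  base <- matrix(rnorm(60, 5, 0.01), 10, 6)
  rownames(base) <- sprintf("g%d", 1:10)
  colnames(base) <- sprintf("s%d", 1:6)
  shifted <- base; shifted[, 4:6] <- shifted[, 4:6] + 1
  sc3 <- signature_score(shifted, rownames(base),
                         groups = rep(c("a", "b"), each = 3))
  expect_lt(sc3$test$p.value, 0.01)
  expect_error(signature_score(expr, c("g1", "nope"), c("a", "a", "b", "b")),
               "absent")
})

test_that("within-pair z-normalised Wilcoxon matches rank enumeration", {
  # complete separation, 6 vs 6 across three pairs: p = 2 / C(12, 6)
  pair <- rep(c("p1", "p2", "p3"), each = 4)
  group <- rep(c(0, 0, 1, 1), 3)
  values <- c(10, 11, 1, 2,   20, 21, 5, 6,   30, 31, 8, 9)
  res <- paired_z_wilcoxon(values, pair, group)
  expect_equal(res$p_value, 2 / choose(12, 6), tolerance = 1e-12)

  # single pair, 3 vs 3, complete separation: p = 2 / C(6, 3) = 0.1
  res2 <- paired_z_wilcoxon(c(5, 6, 7, 1, 2, 3), rep("p", 6),
                            c(1, 1, 1, 0, 0, 0))
  expect_equal(res2$p_value, 0.1, tolerance = 1e-12)

  # identical disease and control values within every pair: p = 1
  res3 <- paired_z_wilcoxon(c(1, 2, 1, 2, 5, 9, 5, 9),
                            rep(c("p1", "p2"), each = 4),
                            rep(c(0, 0, 1, 1), 2))
  expect_equal(res3$p_value, 1)

  # zero-variance pairs are dropped with a warning
  expect_warning(
    res4 <- paired_z_wilcoxon(c(3, 3, 3, 3, 1, 2, 8, 9),
                              rep(c("pa", "pb"), each = 4),
                              rep(c(0, 0, 1, 1), 2)),
    "zero variance")
  expect_equal(unname(res4$n), c(2, 2))
})
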