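# small helper: hand-built ITR results + DE tables for signature assembly
itr_fixture <- function(contrib_per_contrast, directions) {
  contrasts <- names(contrib_per_contrast)
  itr <- data.frame(
    regulator = "CTNNB1", contrast = contrasts,
    overlap = lengths(contrib_per_contrast), p = 0.001, z = -3,
    state = "inhibited", rank = 1L,
    contributing_genes = vapply(contrib_per_contrast, paste,
                                character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  de <- do.call(rbind, lapply(contrasts, function(ct) {
    genes <- contrib_per_contrast[[ct]]
    if (length(genes) == 0) return(NULL)
    data.frame(contrast = ct, gene = genes,
               log2fc = directions[genes] * 2, padj = 0.001,
               stringsAsFactors = FALSE)
  }))
  list(itr = itr, de = de)
}

test_that("signature keeps genes supported by >= min_contrasts with majority direction", {
  dirs <- c(a = -1, b = -1, c = 1, d = 1)
  fx <- itr_fixture(list(c1 = c("a", "b", "c"), c2 = c("a", "b"),
                         c3 = c("a", "d"), c4 = character(),
                         c5 = c("d")), dirs)
  sig <- build_signature(fx$itr, "CTNNB1", fx$de)
  expect_setequal(sig$gene, c("a", "b", "d"))     # c supported once: excluded
  expect_equal(sig$support[sig$gene == "a"], 3L)
  expect_equal(sig$direction[sig$gene == "a"], -1)
  expect_equal(sig$direction[sig$gene == "d"], 1)
  expect_error(build_signature(fx$itr, "NOBODY", fx$de), "not found")
})

test_that("tied observed directions yield an unknown (0) direction", {
  fx <- itr_fixture(list(c1 = "a", c2 = "a"), c(a = 1))
  fx$de$log2fc <- c(2, -2)    # up in c1, down in c2
  sig <- build_signature(fx$itr, "CTNNB1", fx$de)
  expect_equal(sig$direction, 0)
})

test_that("signature construction is invariant to contrast order and matches set algebra", {
  set.seed(41)
  genes <- paste0("g", 1:40)
  dirs <- setNames(sample(c(-1, 1), 40, TRUE), genes)
  sets <- lapply(1:5, function(i) sample(genes, sample(5:20, 1)))
  names(sets) <- paste0("c", 1:5)
  fx <- itr_fixture(sets, dirs)
  sig <- build_signature(fx$itr, "CTNNB1", fx$de)
  # brute-force multiset count oracle
  counts <- table(unlist(sets))
  expect_setequal(sig$gene, names(counts)[counts >= 2])
  # permute contrast order
  perm <- sample(nrow(fx$itr))
  sig2 <- build_signature(fx$itr[perm, ], "CTNNB1", fx$de)
  expect_equal(sig, sig2)
})

test_that("per-gene MYCN models recover planted coefficients", {
  set.seed(101)
  n <- 500
  amp <- rbinom(n, 1, 0.2)
  mycn <- ifelse(amp == 1, rnorm(n, 12, 0.8), rnorm(n, 9, 1))
  y_planted <- 2 * mycn + rnorm(n, 0, 0.5)
  y_null <- rnorm(n)
  y_exact <- mycn
  expr <- rbind(planted = y_planted, null = y_null, exact = y_exact,
                const = rep(3, n))
  fit <- fit_mycn_model(expr, mycn, amp)
  expect_gt(fit["planted", "b1"], 1.9); expect_lt(fit["planted", "b1"], 2.1)
  expect_lt(fit["null", "partial_r2"], 0.02)
  expect_equal(fit["exact", "b1"], 1, tolerance = 1e-10)
  expect_equal(fit["exact", "partial_r2"], 1, tolerance = 1e-10)
  expect_equal(fit["const", "b1"], 0)
  expect_equal(fit["const", "partial_r2"], 0)
})

test_that("MYCN model inputs are validated", {
  expr <- matrix(rnorm(40), 2, 20, dimnames = list(c("a", "b"), NULL))
  expect_error(fit_mycn_model(expr, rnorm(19), rbinom(20, 1, .5)),
               "one entry per sample")
  expect_error(fit_mycn_model(expr, rnorm(20), rep(1, 20)), "both amplification")
  expect_error(fit_mycn_model(expr, rep(2, 20), rbinom(20, 1, .5)), "constant")
  expect_error(fit_mycn_model(expr[, 1:5], rnorm(5), c(0, 0, 1, 1, 1)),
               ">= 10 samples")
})

test_that("correction removes exactly the MYCN-expression component", {
  set.seed(103)
  n <- 500
  amp <- rbinom(n, 1, 0.2)
  mycn <- ifelse(amp == 1, rnorm(n, 12, 0.8), rnorm(n, 9, 1))
  expr <- t(vapply(1:30, function(i)
    rnorm(1, 0, 1) * mycn + 1.5 * amp + rnorm(n, 0, 0.5), numeric(n)))
  rownames(expr) <- paste0("p", 1:30)
  colnames(expr) <- paste0("s", 1:n)
  fit <- fit_mycn_model(expr, mycn, amp)
  corr <- correct_matrix(expr, fit, mycn)

  # per-row partial correlation with mycn controlling for amp is ~0
  resid_m <- resid(lm(mycn ~ amp))
  pc <- apply(corr, 1, function(y) cor(resid(lm(y ~ amp)), resid_m))
  expect_lt(max(abs(pc)), 0.02)

  # amplification effect retained: group-mean gap equals b2 before/after
  refit <- fit_mycn_model(corr, mycn, amp)
  expect_equal(refit$b2, fit$b2, tolerance = 1e-8)
  # idempotence: refit slope on corrected data is ~0, second pass is a no-op
  expect_lt(max(abs(refit$b1)), 1e-8)
  expect_equal(correct_matrix(corr, refit, mycn), corr, tolerance = 1e-8)

  # b1 = 0 model is a no-op
  zero <- fit; zero$b1[] <- 0
  expect_identical(correct_matrix(expr, zero, mycn), expr)
  expect_error(correct_matrix(expr[, 1:10], fit, mycn), "mycn_expr length")
})

test_that("correction agrees with limma's covariate removal up to row centring", {
  skip_if_not_installed("limma")
  set.seed(104)
  n <- 100
  amp <- rbinom(n, 1, 0.3)
  mycn <- rnorm(n, 10, 1.2)
  expr <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(paste0("p", 1:20), paste0("s", 1:n)))
  expr <- expr + outer(runif(20, -1, 2), mycn)
  fit <- fit_mycn_model(expr, mycn, amp)
  ours <- correct_matrix(expr, fit, mycn)
  lm_out <- limma::removeBatchEffect(expr, covariates = mycn,
                                     design = model.matrix(~amp))
  expect_equal(ours - rowMeans(ours), lm_out - rowMeans(lm_out),
               tolerance = 1e-8)
})

test_that("clustering recovers planted sample blocks and fixes polarity by score", {
  set.seed(105)
  n <- 60
  truth <- rep(c(1, 0), each = n / 2)
  sig <- data.frame(gene = paste0("g", 1:10),
                    direction = rep(c(1, -1), 5))
  expr <- t(vapply(1:10, function(i)
    sig$direction[i] * truth * 3 + rnorm(n), numeric(n)))
  rownames(expr) <- sig$gene
  colnames(expr) <- paste0("s", 1:n)
  asg <- cluster_signature(expr, sig)
  expect_identical(unname(asg$group[truth == 1]),
                   factor(rep("signature_plus", n / 2),
                          levels = levels(asg$group)))
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(asg$group, truth), 1)
})

test_that("clustering is invariant to sample order and respects a forced split", {
  set.seed(106)
  n <- 40
  vals <- rep(c(-2, 2), each = n / 2) + rnorm(n, 0, 0.01)
  expr <- rbind(g1 = vals, g2 = vals + rnorm(n, 0, 0.01))
  colnames(expr) <- paste0("s", 1:n)
  sig <- data.frame(gene = c("g1", "g2"), direction = c(1, 1))
  asg <- cluster_signature(expr, sig)
  expect_identical(unname(asg$group), factor(
    rep(c("signature_minus", "signature_plus"), each = n / 2),
    levels = levels(asg$group)))
  perm <- sample(n)
  asg2 <- cluster_signature(expr[, perm], sig)
  expect_identical(asg$group[colnames(expr)[perm]], asg2$group)
  expect_error(cluster_signature(expr[1, , drop = FALSE], sig), "fewer than 2")
})

test_that("probe maps route many probes to one signature gene", {
  set.seed(107)
  n <- 30
  truth <- rep(c(1, 0), each = n / 2)
  expr <- rbind(p1 = truth * 3 + rnorm(n, 0, .3),
                p2 = truth * 3 + rnorm(n, 0, .3),
                p3 = -truth * 3 + rnorm(n, 0, .3))
  colnames(expr) <- paste0("s", 1:n)
  pm <- data.frame(probe = c("p1", "p2", "p3"), gene = c("gA", "gA", "gB"))
  sig <- data.frame(gene = c("gA", "gB"), direction = c(1, -1))
  asg <- cluster_signature(expr, sig, probe_map = pm)
  expect_setequal(asg$probes, c("p1", "p2", "p3"))
  expect_true(all(asg$group[truth == 1] == "signature_plus"))
})

test_that("MNA separation F-test equals squared t and flags shifted probes", {
  set.seed(108)
  amp <- rep(c(0, 1), each = 200)
  score <- rnorm(400) + 2 * amp          # 2-SD planted shift
  res <- mna_separation_test(score, amp)
  expect_lt(res$p, 1e-10)
  tt <- t.test(score[amp == 1], score[amp == 0], var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$df, c(1, 398))

  # null scores: F moderate, p not extreme
  null_res <- mna_separation_test(rnorm(400), amp)
  expect_gt(null_res$p, 1e-4)

  expr <- rbind(shifted = rnorm(400) + amp, flat = rnorm(400))
  res2 <- mna_separation_test(score, amp, expr = expr)
  expect_true("shifted" %in% res2$significant_probes)
  expect_true(all(res2$probe_table$padj >= res2$probe_table$p))
  expect_error(mna_separation_test(score[1:3], c(0, 1, 1)), ">= 2 samples")
})
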