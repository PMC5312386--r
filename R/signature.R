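#' Build a regulator gene signature from per-contrast ITR results
#'
#' Collects, for one regulator, the contributing genes (targets that were
#' differentially expressed) across contrasts and keeps those supported by
#' at least `min_contrasts` contrasts. Each kept gene carries an expected
#' regulation direction: the majority sign of its observed log2 fold
#' changes across supporting contrasts, or 0 (unknown) on a tie.
#'
#' @param itr_results an `itr_result` from [infer_regulators()], covering
#'   at least two contrasts for `regulator`.
#' @param regulator regulator id to extract.
#' @param de the DE table the ITR run scored (columns `contrast`, `gene`,
#'   `log2fc`, `padj`); supplies the observed directions.
#' @param min_contrasts minimum supporting contrasts (default 2).
#' @return A `signature` data.frame: `gene`, `direction` (+1/-1/0),
#'   `support`; attribute `regulator`.
#' @export
build_signature <- function(itr_results, regulator, de, min_contrasts = 2) {
  x <- as.data.frame(itr_results)
  x <- x[x$regulator == regulator, , drop = FALSE]
  if (nrow(x) == 0)
    stop(sprintf("regulator '%s' not found in ITR results", regulator))
  if (nrow(x) < 2)
    stop("need ITR results for >= 2 contrasts to build a signature")
  contrib <- lapply(seq_len(nrow(x)), function(i) {
    genes <- strsplit(x$contributing_genes[i], ";", fixed = TRUE)[[1]]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) return(NULL)
    d <- de[de$contrast == x$contrast[i] & de$gene %in% genes, , drop = FALSE]
    data.frame(gene = d$gene, dir = sign(d$log2fc), stringsAsFactors = FALSE)
  })
  contrib <- do.call(rbind, contrib)
  if (is.null(contrib) || nrow(contrib) == 0)
    stop(sprintf("regulator '%s' has no contributing genes in any contrast", regulator))
  support <- table(contrib$gene)
  keep <- names(support)[support >= min_contrasts]
  if (length(keep) == 0)
    warning(sprintf("no gene is supported by >= %d contrasts", min_contrasts))
  direction <- vapply(keep, function(g) {
    s <- sum(contrib$dir[contrib$gene == g])
    if (s > 0) 1 else if (s < 0) -1 else 0
  }, numeric(1))
  out <- data.frame(gene = keep,
                    direction = unname(direction),
                    support = as.integer(support[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "regulator") <- regulator
  class(out) <- c("signature", "data.frame")
  out
}

#' Per-gene linear models of expression on MYCN level and amplification
#'
#' Fits, for every row of the expression matrix, the ordinary
#' least-squares model
#' `y = b0 + b1 * mycn_expr + b2 * amplified + e`
#' and reports the partial R-squared of the MYCN-expression covariate:
#' the residual-sum-of-squares reduction of the full model relative to
#' the model containing intercept and amplification only. This is the
#' per-gene estimate of how much expression is explained by MYCN level
#' beyond amplification status.
#'
#' @param expr numeric matrix, rows = probes/genes, columns = samples.
#' @param mycn_expr per-sample log2 MYCN expression (length = ncol(expr)).
#' @param amp_status per-sample amplification indicator (0/1 or logical).
#' @return A `mycn_model` data.frame (one row per expression row):
#'   `b0`, `b1`, `b2`, `partial_r2`.
#' @export
fit_mycn_model <- function(expr, mycn_expr, amp_status) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  if (length(mycn_expr) != n || length(amp_status) != n)
    stop("mycn_expr and amp_status must have one entry per sample column")
  if (n < 10) stop("need >= 10 samples to fit the MYCN model")
  amp <- as.numeric(amp_status)
  if (length(unique(amp)) < 2)
    stop("both amplification classes must be present")
  if (stats::var(mycn_expr) == 0)
    stop("mycn_expr is constant; the model is unidentifiable")
  r <- abs(stats::cor(mycn_expr, amp))
  if (r > 0.999)
    warning(sprintf("mycn_expr and amplification nearly collinear (|r| = %.4f)", r))
  X <- cbind(intercept = 1, mycn = mycn_expr, amp = amp)
  X0 <- X[, c(1, 3)]
  qr1 <- qr(X); qr0 <- qr(X0)
  Y <- t(expr)                                  # samples x genes
  B <- qr.coef(qr1, Y)                          # 3 x genes
  rss1 <- colSums(qr.resid(qr1, Y)^2)
  rss0 <- colSums(qr.resid(qr0, Y)^2)
  pr2 <- ifelse(rss0 > 0, pmax(0, (rss0 - rss1) / rss0), 0)
  const <- apply(expr, 1, stats::var) == 0
  out <- data.frame(b0 = B[1, ], b1 = B[2, ], b2 = B[3, ], partial_r2 = pr2,
                    row.names = rownames(expr))
  out$b1[const] <- 0; out$b2[const] <- 0; out$partial_r2[const] <- 0
  out$b0[const] <- expr[const, 1]
  class(out) <- c("mycn_model", "data.frame")
  out
}

#' Remove the MYCN-expression effect from an expression matrix
#'
#' Covariate subtraction in the style of batch-effect removal: each row
#' loses only its fitted MYCN-expression component,
#' `y_corrected = y - b1 * (mycn_expr - mean(mycn_expr))`.
#' The amplification effect (b2) is deliberately retained, so group
#' differences attributable to amplification survive correction.
#'
#' @param expr numeric matrix (rows x samples) the model was fitted on.
#' @param model a `mycn_model` from [fit_mycn_model()] with matching rows.
#' @param mycn_expr the same per-sample MYCN expression vector.
#' @return corrected matrix, same dimensions and dimnames.
#' @export
correct_matrix <- function(expr, model, mycn_expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) != nrow(model))
    stop("model and matrix row counts differ")
  if (length(mycn_expr) != ncol(expr))
    stop("mycn_expr length must equal the number of samples")
  centred <- mycn_expr - mean(mycn_expr)
  expr - outer(model$b1, centred)
}

#' Two-group sample assignment from signature-gene clustering
#'
#' Restricts the (corrected) expression matrix to the signature's probes,
#' standardizes each probe row to zero mean / unit variance, clusters the
#' samples hierarchically and cuts the top merge into two groups. The
#' per-sample signature score is the mean over direction-known probes of
#' the direction-aligned standardized expression, and the group with the
#' higher mean score is labelled `signature_plus` — so polarity is fixed
#' by the score, not by cluster size or dendrogram orientation.
#'
#' @param expr expression matrix (probes x samples), typically
#'   MYCN-corrected ([correct_matrix()]).
#' @param signature a [build_signature()] result.
#' @param probe_map optional data.frame `probe`, `gene` mapping matrix
#'   rows to signature genes (many probes per gene allowed); by default
#'   rows are matched to signature genes by name.
#' @param linkage hclust linkage (default `"ward.D2"`).
#' @param distance distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @return A `group_assignment` list: `group` (named factor
#'   `signature_plus`/`signature_minus`), `score` (named numeric),
#'   `hclust`, `probes` used.
#' @export
cluster_signature <- function(expr, signature, probe_map = NULL,
                              linkage = "ward.D2", distance = "euclidean") {
  expr <- as.matrix(expr)
  if (ncol(expr) < 4) stop("need >= 4 samples to cluster")
  if (is.null(probe_map)) {
    probe_map <- data.frame(probe = rownames(expr), gene = rownames(expr),
                            stringsAsFactors = FALSE)
  }
  pm <- probe_map[probe_map$gene %in% signature$gene &
                    probe_map$probe %in% rownames(expr), , drop = FALSE]
  if (nrow(pm) < 2) {
    missing <- setdiff(signature$gene, probe_map$gene[probe_map$probe %in% rownames(expr)])
    stop("fewer than 2 signature probes found in the matrix; missing genes: ",
         paste(missing, collapse = ", "))
  }
  sub <- expr[pm$probe, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    pm <- pm[sds > 0, , drop = FALSE]
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(sub) < 2) stop("fewer than 2 signature probes with non-zero variance")
  }
  Z <- (sub - rowMeans(sub)) / sds
  hc <- stats::hclust(stats::dist(t(Z), method = distance), method = linkage)
  cl <- stats::cutree(hc, k = 2)
  dir <- signature$direction[match(pm$gene, signature$gene)]
  known <- dir != 0
  score <- if (any(known)) colMeans(Z[known, , drop = FALSE] * dir[known])
           else colMeans(Z)   # all-unknown signature: unsigned mean
  plus_cluster <- which.max(tapply(score, cl, mean))
  group <- factor(ifelse(cl == as.integer(names(plus_cluster)),
                         "signature_plus", "signature_minus"),
                  levels = c("signature_plus", "signature_minus"))
  names(group) <- colnames(expr)
  names(score) <- colnames(expr)
  structure(list(group = group, score = score, hclust = hc,
                 probes = pm$probe),
            class = "group_assignment")
}

#' MYCN-amplification separation test of a signature score
#'
#' One-way analysis of variance of the per-sample signature score by
#' amplification status (the F-test of group separation, df 1 and n - 2),
#' plus optional per-probe two-group Welch tests on the corrected
#' expression matrix with Benjamini-Hochberg adjustment.
#'
#' @param score per-sample numeric score (e.g. from
#'   [cluster_signature()]).
#' @param amp_status per-sample amplification indicator, both classes
#'   with >= 2 samples.
#' @param expr optional probes x samples matrix for the per-probe tests.
#' @return list: `f` (F statistic), `df` (c(1, n - 2)), `p`;
#'   when `expr` is given, `probe_table` (`probe`, `p`, `padj`) and
#'   `significant_probes` (padj < 0.05).
#' @export
mna_separation_test <- function(score, amp_status, expr = NULL) {
  amp <- factor(as.numeric(amp_status), levels = c(0, 1))
  if (any(table(amp) < 2))
    stop("each amplification class needs >= 2 samples for the F-test")
  fit <- stats::anova(stats::lm(score ~ amp))
  out <- list(f = fit$`F value`[1],
              df = c(fit$Df[1], fit$Df[2]),
              p = fit$`Pr(>F)`[1])
  if (!is.null(expr)) {
    expr <- as.matrix(expr)
    p <- apply(expr, 1, function(y) {
      if (stats::sd(y) == 0) return(1)
      stats::t.test(y[amp == 1], y[amp == 0])$p.value
    })
    padj <- stats::p.adjust(p, method = "BH")
    out$probe_table <- data.frame(probe = rownames(expr), p = p, padj = padj,
                                  row.names = NULL, stringsAsFactors = FALSE)
    out$significant_probes <- out$probe_table$probe[padj < 0.05]
  }
  out
}

#' Export / import a signature as GMT gene sets
#'
#' Writes one set per direction (`<REGULATOR>_UP`, `<REGULATOR>_DOWN`,
#' and `<REGULATOR>_UNKNOWN` when present) in standard GMT layout:
#' name, description, tab-separated members.
#'
#' @param signature a [build_signature()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_gmt <- function(signature, path) {
  reg <- attr(signature, "regulator")
  if (is.null(reg)) reg <- "SIGNATURE"
  sets <- list(UP = signature$gene[signature$direction == 1],
               DOWN = signature$gene[signature$direction == -1],
               UNKNOWN = signature$gene[signature$direction == 0])
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  write_gmt(stats::setNames(sets, paste(reg, names(sets), sep = "_")), path)
}

#' Read / write a signature TSV (`gene,direction,support`)
#'
#' @param path file path.
#' @return a `signature` data.frame for the reader; `path` for the writer.
#' @param regulator regulator id recorded on the imported signature.
#' @export
read_signature <- function(path, regulator = NA_character_) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "direction", "support")
  if (!all(needed %in% names(x)))
    stop("signature TSV needs columns: ", paste(needed, collapse = ", "))
  attr(x, "regulator") <- regulator
  class(x) <- c("signature", "data.frame")
  x
}

#' @rdname read_signature
#' @param signature a `signature` data.frame.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(as.data.frame(signature), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
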