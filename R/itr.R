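#' Construct a signed, weighted regulator-target network
#'
#' The prior for inferred-transcriptional-regulator (ITR) scoring: one
#' edge per (regulator, target) pair with a predicted regulation sign
#' (+1 activating, -1 repressing, NA unknown) and a non-negative weight.
#'
#' @param edges data.frame with columns `regulator`, `target`, `sign`
#'   (values in `{1, -1, NA}`) and optionally `weight` (default 1).
#' @return A `regulator_network` data.frame.
#' @export
regulator_network <- function(edges) {
  needed <- c("regulator", "target", "sign")
  if (!all(needed %in% names(edges)))
    stop("network needs columns: ", paste(needed, collapse = ", "))
  x <- as.data.frame(edges)
  if (!"weight" %in% names(x)) x$weight <- 1
  x <- x[, c("regulator", "target", "sign", "weight")]
  if (anyDuplicated(x[, c("regulator", "target")]))
    stop("duplicate (regulator, target) pairs in network")
  if (!all(x$sign %in% c(1, -1) | is.na(x$sign)))
    stop("edge sign must be 1, -1 or NA")
  if (any(!is.finite(x$weight) | x$weight < 0))
    stop("edge weights must be finite and >= 0")
  class(x) <- c("regulator_network", "data.frame")
  x
}

#' Read / write a regulator-target network TSV
#'
#' Columns `regulator,target,sign,weight`; `sign` in `{1,-1,NA}`.
#' @param path file path.
#' @return [regulator_network()] for the reader; `path` for the writer.
#' @export
read_network <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  regulator_network(x)
}

#' @rdname read_network
#' @param network a `regulator_network`.
#' @export
write_network <- function(network, path) {
  utils::write.table(as.data.frame(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hypergeometric overlap p-value of a target set with a DE set
#'
#' Right-tail probability of observing at least the seen overlap between
#' a regulator's known targets and the differentially expressed genes,
#' when `|de_genes|` genes are drawn without replacement from the
#' background universe containing `|targets|` marked genes.
#'
#' @param targets character vector of target gene ids.
#' @param de_genes character vector of differentially expressed gene ids.
#' @param background character vector: the measured gene universe.
#' @return single p-value in (0, 1].
#' @export
overlap_pvalue <- function(targets, de_genes, background) {
  targets <- unique(targets); de_genes <- unique(de_genes)
  background <- unique(background)
  if (length(background) == 0) stop("background universe is empty")
  if (!all(targets %in% background) || !all(de_genes %in% background))
    stop("targets and de_genes must be subsets of the background universe")
  if (length(targets) == 0 || length(de_genes) == 0) {
    warning("empty target or DE set; overlap p-value is 1")
    return(1)
  }
  q <- length(intersect(targets, de_genes))
  stats::phyper(q - 1, m = length(targets),
                n = length(background) - length(targets),
                k = length(de_genes), lower.tail = FALSE)
}

#' Activation z-score of one regulator
#'
#' Direction-concordance statistic `z = sum(w * x) / sqrt(sum(w^2))`
#' where, for each scored edge, `x = +1` if the target's observed
#' fold-change direction matches the direction predicted under the
#' regulator-active hypothesis and `x = -1` if it contradicts it. Edges
#' with unknown predicted sign or unknown observed direction are
#' excluded. `|z| >= 2` conventionally calls the regulator activated
#' (z positive) or inhibited (z negative).
#'
#' @param predicted_sign numeric vector in `{1, -1, NA}` per edge.
#' @param observed_direction numeric vector in `{1, -1, NA}`: sign of the
#'   target's log2 fold change (NA if the target is not DE).
#' @param weight non-negative edge weights (default 1).
#' @return z, or `NA_real_` (undetermined) when no edge is scorable.
#' @export
activation_zscore <- function(predicted_sign, observed_direction,
                              weight = rep(1, length(predicted_sign))) {
  stopifnot(length(predicted_sign) == length(observed_direction),
            length(weight) == length(predicted_sign))
  use <- !is.na(predicted_sign) & !is.na(observed_direction) &
    observed_direction != 0 & weight > 0
  if (!any(use)) return(NA_real_)
  x <- ifelse(predicted_sign[use] == observed_direction[use], 1, -1)
  w <- weight[use]
  sum(w * x) / sqrt(sum(w^2))
}

#' Score candidate upstream regulators against DE results
#'
#' For every regulator in the network and every contrast in the DE table:
#' the DE set is the genes with adjusted p at or below `de_padj`; the
#' regulator gets a hypergeometric overlap p-value ([overlap_pvalue()]) of
#' its targets with that set, an activation z-score
#' ([activation_zscore()]) over the DE targets with known predicted sign,
#' and a state call (`activated` if `z >= z_cutoff`, `inhibited` if
#' `z <= -z_cutoff`, else `undetermined`). Regulators are ranked per
#' contrast by overlap p, ties broken by |z| (larger first) then
#' regulator id.
#'
#' @param network a [regulator_network()].
#' @param de data.frame with columns `contrast`, `gene`, `log2fc`, `padj`.
#' @param de_padj adjusted-p inclusion cutoff for the DE set (default 0.05).
#' @param z_cutoff state-call cutoff on |z| (default 2).
#' @param background gene universe; defaults to all genes in the DE table
#'   (the measured universe). Network targets outside it are ignored.
#' @return An `itr_result` data.frame: `regulator`, `contrast`, `overlap`,
#'   `p`, `z`, `state`, `rank`, `contributing_genes` (semicolon-joined).
#' @export
infer_regulators <- function(network, de, de_padj = 0.05, z_cutoff = 2,
                             background = NULL) {
  network <- if (inherits(network, "regulator_network")) network
             else regulator_network(network)
  needed <- c("contrast", "gene", "log2fc", "padj")
  if (!all(needed %in% names(de)))
    stop("DE table needs columns: ", paste(needed, collapse = ", "))
  if (any(de$padj < 0 | de$padj > 1, na.rm = TRUE))
    stop("adjusted p-values must lie in [0, 1]")
  res <- lapply(split(de, de$contrast), function(d) {
    bg <- if (is.null(background)) unique(d$gene) else unique(background)
    de_genes <- unique(d$gene[!is.na(d$padj) & d$padj <= de_padj])
    if (length(de_genes) == 0)
      warning(sprintf("contrast '%s': no genes pass padj <= %g", d$contrast[1], de_padj))
    dir_map <- sign(d$log2fc)[match(de_genes, d$gene)]
    names(dir_map) <- de_genes
    regs <- split(network, network$regulator)
    per_reg <- lapply(names(regs), function(rg) {
      ed <- regs[[rg]]
      ed <- ed[ed$target %in% bg, , drop = FALSE]
      targets <- unique(ed$target)
      contrib <- intersect(targets, de_genes)
      p <- if (length(targets) == 0 || length(de_genes) == 0) 1 else
        overlap_pvalue(targets, de_genes, bg)
      obs <- dir_map[match(ed$target, names(dir_map))]
      z <- activation_zscore(ed$sign, unname(obs), ed$weight)
      state <- if (is.na(z)) "undetermined"
               else if (z >= z_cutoff) "activated"
               else if (z <= -z_cutoff) "inhibited"
               else "undetermined"
      data.frame(regulator = rg, contrast = d$contrast[1],
                 overlap = length(contrib), p = p, z = z, state = state,
                 contributing_genes = paste(sort(contrib), collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per_reg)
    o <- order(tab$p, -abs(ifelse(is.na(tab$z), 0, tab$z)), tab$regulator)
    tab <- tab[o, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    tab
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out <- out[, c("regulator", "contrast", "overlap", "p", "z", "state",
                 "rank", "contributing_genes")]
  class(out) <- c("itr_result", "data.frame")
  out
}

#' Rank regulators by target overlap with a direction-less gene set
#'
#' The binary variant of [infer_regulators()] for inputs without fold
#' changes (e.g. ChIP-bound gene lists): only the hypergeometric overlap
#' p-value and rank are computed; z is undefined.
#'
#' @param network a [regulator_network()].
#' @param bound_genes character vector of genes in the query set.
#' @param background gene universe containing `bound_genes`.
#' @return data.frame `regulator`, `overlap`, `p`, `rank`,
#'   `contributing_genes`, ranked by p (ties by regulator id).
#' @export
rank_regulators_binary <- function(network, bound_genes, background) {
  network <- if (inherits(network, "regulator_network")) network
             else regulator_network(network)
  bound_genes <- unique(bound_genes)
  background <- unique(background)
  if (!all(bound_genes %in% background))
    stop("bound_genes must be a subset of the background universe")
  per_reg <- lapply(split(network, network$regulator), function(ed) {
    targets <- unique(ed$target[ed$target %in% background])
    contrib <- intersect(targets, bound_genes)
    p <- if (length(targets) == 0) 1 else
      overlap_pvalue(targets, bound_genes, background)
    data.frame(regulator = ed$regulator[1], overlap = length(contrib), p = p,
               contributing_genes = paste(sort(contrib), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_reg)
  tab <- tab[order(tab$p, tab$regulator), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("regulator", "overlap", "p", "rank", "contributing_genes")]
}

#' Read / write a per-contrast DE table TSV
#'
#' Columns `contrast,gene,log2fc,padj`.
#' @param path file path.
#' @return data.frame for the reader; `path` for the writer.
#' @export
read_de_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("contrast", "gene", "log2fc", "padj")
  if (!all(needed %in% names(x)))
    stop("DE table needs columns: ", paste(needed, collapse = ", "))
  x
}

#' @rdname read_de_table
#' @param de a DE table data.frame.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
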