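#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates via the survival package, returned as a tidy
#' step-function table. The curve for each group starts at 1 and is
#' non-increasing; a group with no events yields a flat curve (with a
#' warning).
#'
#' @param time survival times (days, > 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @param group group label per subject (single group allowed).
#' @return data.frame: `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event, group = rep("all", length(time))) {
  stopifnot(length(time) == length(event), length(group) == length(time))
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) == 0) warning("no events: all survival curves are flat at 1")
  group <- as.factor(group)
  for (g in levels(group)) {
    if (sum(event[group == g]) == 0 && sum(event) > 0)
      warning(sprintf("group '%s' has no events; its curve stays at 1", g))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (is.null(fit$strata)) {
    grp <- rep(levels(group)[1], length(fit$time))
  } else {
    grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test of survival-curve equality
#'
#' Standard log-rank chi-squared with `groups - 1` degrees of freedom,
#' accumulating observed-minus-expected event counts over event times
#' (hypergeometric variance, ties pooled at each event time).
#'
#' @inheritParams km_estimate
#' @return list: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("log-rank test needs >= 2 non-empty groups")
  if (sum(event) == 0) stop("log-rank test needs >= 1 event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Stratify a cohort by an expression value or score
#'
#' `method = "median"` splits samples at the median into `high`/`low` and
#' reports the log-rank test. `method = "scan"` (the best-cutoff scan used
#' by probe-level survival platforms) evaluates every cutoff leaving at
#' least `min_frac` of samples on each side, reports the minimal raw
#' log-rank p together with a Bonferroni adjustment over the number of
#' cutoffs tried. The adjusted p is what should be quoted: the minimal
#' raw p of a scan is anti-conservative by construction.
#'
#' @param x per-sample expression value or signature score.
#' @param time,event survival time and event indicator, matched to `x`.
#' @param method `"median"` (default) or `"scan"`.
#' @param min_frac minimum fraction of samples per side for scan cutoffs
#'   (default 0.1).
#' @return A `stratification` list: `group` (factor high/low), `cutoff`,
#'   `chisq`, `df`, `p`, `p_adjusted` (Bonferroni; equals `p` for the
#'   median split), `n_cutoffs`, `method`.
#' @export
stratify_by_expression <- function(x, time, event,
                                   method = c("median", "scan"),
                                   min_frac = 0.1) {
  method <- match.arg(method)
  stopifnot(length(x) == length(time), length(time) == length(event))
  if (length(x) < 4) stop("need >= 4 samples to stratify")
  if (stats::var(x) == 0)
    stop("expression is constant: no cutoff can split the cohort")
  split_at <- function(cut) factor(ifelse(x > cut, "high", "low"),
                                   levels = c("low", "high"))
  if (method == "median") {
    cut <- stats::median(x)
    grp <- split_at(cut)
    if (any(table(grp) == 0))
      stop("median split leaves an empty group (heavily tied values)")
    lr <- logrank_test(time, event, grp)
    return(structure(list(group = grp, cutoff = cut, chisq = lr$chisq,
                          df = lr$df, p = lr$p, p_adjusted = lr$p,
                          n_cutoffs = 1L, method = "median"),
                     class = "stratification"))
  }
  n <- length(x)
  floor_n <- max(2L, ceiling(min_frac * n))
  sx <- sort(unique(x))
  cuts <- sx[-length(sx)]                      # split between consecutive values
  keep <- vapply(cuts, function(cc) {
    nh <- sum(x > cc); nh >= floor_n && (n - nh) >= floor_n
  }, logical(1))
  cuts <- cuts[keep]
  if (length(cuts) == 0) stop("no cutoff satisfies the group-size floor")
  ps <- vapply(cuts, function(cc) logrank_test(time, event, split_at(cc))$p,
               numeric(1))
  best <- which.min(ps)
  grp <- split_at(cuts[best])
  lr <- logrank_test(time, event, grp)
  structure(list(group = grp, cutoff = cuts[best], chisq = lr$chisq,
                 df = lr$df, p = lr$p,
                 p_adjusted = min(1, lr$p * length(cuts)),
                 n_cutoffs = length(cuts), method = "scan"),
            class = "stratification")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' `rho` is the Pearson correlation of midranks; the two-sided p-value
#' uses `t = rho * sqrt((n - 2) / (1 - rho^2))` against Student's t with
#' n - 2 degrees of freedom. For `|rho| = 1` the limiting p of 0 is
#' returned with attribute `exact = TRUE`.
#'
#' @param x,y numeric vectors, n >= 4; ties handled by midranks.
#' @return list: `rho`, `p`, `n`.
#' @examples
#' spearman_rho_t_pvalue(1:5, c(5, 4, 3, 1, 2))  # rho = -0.9, p ~ 0.037
#' @export
spearman_rho_t_pvalue <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4 for the t approximation")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
    attr(p, "exact") <- TRUE
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Read / write a clinical table TSV
#'
#' Columns `sample,time_days,event,mycn_amp,mycn_expr`.
#' @param path file path.
#' @return validated data.frame for the reader; `path` for the writer.
#' @export
read_clinical <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample", "time_days", "event", "mycn_amp", "mycn_expr")
  if (!all(needed %in% names(x)))
    stop("clinical table needs columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(x$sample)) stop("duplicate sample ids in clinical table")
  if (any(x$time_days <= 0)) stop("survival times must be positive")
  if (!all(x$event %in% c(0, 1))) stop("event must be 0/1")
  x
}

#' @rdname read_clinical
#' @param clinical a clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
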