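#' Loess spatial normalization of screen plates ("sample fraction" only)
#'
#' Removes smooth spatial artifacts from plate-format viability readouts.
#' Per plate and induction condition a degree-1 local-regression surface
#' over the (row, column) grid is fitted on log2 signals of *sample wells
#' only*, omitting the control columns (default 1, 2, 23, 24) so the
#' control lines never influence the fit. Every non-empty well, controls
#' included, then receives
#' `normalized = log2(signal) - fitted + median(log2 signal of fit wells)`,
#' so normalized values stay on the plate's own log2 scale.
#'
#' @param plates a [plate_set()].
#' @param span loess span in (0, 1]; fraction of fit wells in each local
#'   neighbourhood. Default 0.7.
#' @param excluded_cols integer columns excluded from the fit (control
#'   lines). Default `c(1, 2, 23, 24)`.
#' @param log2_scale fit and report on the log2 scale (default `TRUE`;
#'   `FALSE` fits the raw scale, for diagnostics only).
#' @return A `normalized_screen`: data.frame of all non-empty wells with
#'   columns of the input plus `normalized` and attributes `span`,
#'   `excluded_cols`, `fit_surface` (per-well fitted values for QC).
#' @seealso [call_hits()], [robust_z()]
#' @export
loess_normalize <- function(plates, span = 0.7, excluded_cols = c(1, 2, 23, 24),
                            log2_scale = TRUE) {
  plates <- if (inherits(plates, "plate_set")) plates else plate_set(plates)
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1)
    stop("span must be a single number in (0, 1]")
  x <- as.data.frame(plates)
  x <- x[x$well_type != "empty", , drop = FALSE]
  x$value <- if (log2_scale) log2(x$signal) else x$signal
  x$normalized <- NA_real_
  x$fitted <- NA_real_
  for (pl in unique(x$plate)) {
    for (cond in unique(x$condition[x$plate == pl])) {
      idx <- which(x$plate == pl & x$condition == cond)
      sub <- x[idx, , drop = FALSE]
      fit_idx <- sub$well_type == "sample" & !(sub$col %in% excluded_cols)
      if (!any(sub$well_type == "sample" & TRUE) || sum(fit_idx) == 0)
        stop(sprintf(
          "degenerate layout: plate %s (%s) has no sample wells outside the excluded columns",
          pl, cond))
      if (sum(fit_idx) < 10)
        stop(sprintf(
          "plate %s (%s): need >= 10 sample wells outside excluded columns, found %d",
          pl, cond, sum(fit_idx)))
      # symmetric (Tukey biweight) fitting: strong hit wells are outliers
      # of the spatial trend and must not bend the surface
      fit <- stats::loess(value ~ row + col, data = sub[fit_idx, ],
                          span = span, degree = 1, family = "symmetric",
                          control = stats::loess.control(surface = "direct"))
      surf <- stats::predict(fit, newdata = sub[, c("row", "col")])
      med <- stats::median(sub$value[fit_idx])
      x$fitted[idx] <- surf
      x$normalized[idx] <- sub$value - surf + med
    }
  }
  out <- x[, c("plate", "row", "col", "gene", "well_type", "condition",
               "signal", "normalized")]
  attr(out, "span") <- span
  attr(out, "excluded_cols") <- excluded_cols
  attr(out, "log2_scale") <- log2_scale
  attr(out, "fit_surface") <- x[, c("plate", "row", "col", "condition", "fitted")]
  class(out) <- c("normalized_screen", "data.frame")
  out
}

#' Robust z-scores from median and MAD
#'
#' `z = (x - median(x)) / (1.4826 * MAD)`, the normal-consistent median
#' absolute deviation scaling. Affine-equivariant: unchanged under
#' `x -> a*x + b`, `a > 0`.
#'
#' @param values numeric vector, length >= 3.
#' @param center,scale optional fixed location/scale; by default the
#'   median and normal-consistent MAD of `values`.
#' @return numeric vector of z-scores.
#' @export
robust_z <- function(values, center = stats::median(values),
                     scale = stats::mad(values, center = center)) {
  if (length(values) < 3) stop("robust_z needs at least 3 values")
  if (!is.finite(scale) || scale <= 0)
    stop("zero-spread distribution: MAD of the supplied values is 0")
  (values - center) / scale
}

# Normal-consistency constant beta(k) = E[min(|Z|, k)^2], Z ~ N(0,1).
huber_beta <- function(k) {
  2 * stats::pnorm(k) - 1 - 2 * k * stats::dnorm(k) +
    2 * k^2 * stats::pnorm(k, lower.tail = FALSE)
}

#' Huber's Proposal 2 simultaneous location/scale estimate
#'
#' Fixed-point iteration for the robust location mu and scale sigma in
#' which observations are winsorized at `mu +/- k*sigma`: each sweep sets
#' mu to the mean of the winsorized sample and
#' `sigma^2 = sum((w - mu)^2) / (n * beta(k))`, where
#' `beta(k) = E[min(|Z|, k)^2]` for standard-normal Z makes sigma
#' consistent for the SD of Gaussian data. The default `k = 1.5`
#' winsorizes at 1.5 SD. As `k -> Inf` the estimate reduces to the
#' classical mean and (population-divisor) SD.
#'
#' @param values numeric vector, n >= 4, not all identical.
#' @param k winsorization constant in SD units (default 1.5).
#' @param tol convergence tolerance on successive (mu, sigma) changes.
#' @param max_iter iteration cap.
#' @return A `robust_scale` list: `mu`, `sigma`, `k`, `iterations`,
#'   `converged`.
#' @examples
#' set.seed(1)
#' huber_proposal2(rnorm(1000))$sigma  # ~ 1
#' @export
huber_proposal2 <- function(values, k = 1.5, tol = 1e-8, max_iter = 200) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 4) stop("huber_proposal2 needs at least 4 finite values")
  if (stats::var(x) == 0)
    stop("zero-scale distribution: all values are identical")
  beta <- huber_beta(k)
  mu <- stats::median(x)
  sigma <- stats::mad(x)
  if (sigma == 0) sigma <- stats::sd(x)
  s_init <- max(sigma, stats::sd(x))
  for (it in seq_len(max_iter)) {
    w <- pmin(pmax(x, mu - k * sigma), mu + k * sigma)
    mu_new <- mean(w)
    sigma_new <- sqrt(sum((w - mu_new)^2) / (n * beta))
    if (sigma_new < 1e-6 * s_init) {
      # more than half the winsorized mass sits at one point: the scale
      # equation has no positive root and the estimate degenerates
      warning("Huber scale collapsed to zero (majority of values coincide)")
      out <- list(mu = mu_new, sigma = 0, k = k, iterations = it,
                  converged = TRUE)
      class(out) <- "robust_scale"
      return(out)
    }
    done <- abs(mu_new - mu) < tol * max(1, sigma) &&
      abs(sigma_new - sigma) < tol * max(1, sigma)
    mu <- mu_new
    sigma <- sigma_new
    if (done) {
      out <- list(mu = mu, sigma = sigma, k = k, iterations = it,
                  converged = TRUE)
      class(out) <- "robust_scale"
      return(out)
    }
  }
  stop(sprintf(
    "huber_proposal2 did not converge in %d iterations (last mu = %.8g, sigma = %.8g)",
    max_iter, mu, sigma))
}

#' @export
print.robust_scale <- function(x, ...) {
  cat(sprintf("Huber Proposal 2 scale: mu = %.6g, sigma = %.6g (k = %g, %d iterations)\n",
              x$mu, x$sigma, x$k, x$iterations))
  invisible(x)
}

#' Three-sigma hit calling on a normalized screen
#'
#' For each induction condition the library-wide distribution of
#' normalized *sample* wells defines the median and a Huber Proposal 2
#' scale (winsorized at 1.5 SD); a well is a hit if its normalized value
#' lies at least `threshold_sd` of those robust SDs from the median
#' (boundary inclusive). Hits below the median are anti-proliferative,
#' above it pro-proliferative. Controls never enter the median, the scale
#' or the hit distribution. Robust z-scores (median/MAD) over the same
#' distribution are reported alongside.
#'
#' @param normalized a `normalized_screen` from [loess_normalize()].
#' @param threshold_sd hit threshold in robust SD units (default 3).
#' @param scope `"library"` (default) pools sample wells across plates per
#'   condition; `"plate"` computes median/scale per plate.
#' @param k winsorization constant passed to [huber_proposal2()].
#' @return A `hit_table` data.frame: `gene`, `condition`, `value`, `z`,
#'   `hit`, `direction` (and `plate` for traceability).
#' @export
call_hits <- function(normalized, threshold_sd = 3, scope = c("library", "plate"),
                      k = 1.5) {
  scope <- match.arg(scope)
  x <- as.data.frame(normalized)
  if (!"normalized" %in% names(x))
    stop("call_hits expects the output of loess_normalize()")
  s <- x[x$well_type == "sample", , drop = FALSE]
  grp <- if (scope == "library") s$condition else paste(s$plate, s$condition)
  out <- do.call(rbind, lapply(split(s, grp), function(d) {
    if (nrow(d) < 50)
      warning(sprintf(
        "only %d sample wells in '%s': scale estimate may be unstable",
        nrow(d), d$condition[1]))
    med <- stats::median(d$normalized)
    sigma <- huber_proposal2(d$normalized, k = k)$sigma
    z <- robust_z(d$normalized)
    hit <- abs(d$normalized - med) >= threshold_sd * sigma
    direction <- ifelse(!hit, "none",
                        ifelse(d$normalized <= med, "anti-proliferative",
                               "pro-proliferative"))
    data.frame(gene = d$gene, condition = d$condition, plate = d$plate,
               value = d$normalized, z = z, hit = hit, direction = direction,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$condition, out$gene), ]
  rownames(out) <- NULL
  attr(out, "threshold_sd") <- threshold_sd
  attr(out, "scope") <- scope
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Condition-dependent knockdown responses
#'
#' Joins hit tables from two induction conditions on gene and flags genes
#' whose robust z-scores differ by at least `delta_threshold`, i.e. whose
#' knockdown response depends on the induction state.
#'
#' @param hits_induced,hits_uninduced `hit_table`s from [call_hits()].
#' @param delta_threshold flag threshold on `|z_induced - z_uninduced|`
#'   (default 2).
#' @return data.frame: `gene`, `z_induced`, `z_uninduced`, `delta_z`,
#'   `condition_dependent`.
#' @export
differential_response <- function(hits_induced, hits_uninduced,
                                  delta_threshold = 2) {
  a <- as.data.frame(hits_induced)[, c("gene", "value", "z")]
  b <- as.data.frame(hits_uninduced)[, c("gene", "value", "z")]
  m <- merge(a, b, by = "gene", suffixes = c("_induced", "_uninduced"))
  if (nrow(m) == 0) {
    warning("gene sets of the two hit tables are disjoint; empty output")
    return(data.frame(gene = character(), z_induced = numeric(),
                      z_uninduced = numeric(), delta_z = numeric(),
                      condition_dependent = logical()))
  }
  out <- data.frame(gene = m$gene, z_induced = m$z_induced,
                    z_uninduced = m$z_uninduced,
                    delta_z = m$z_induced - m$z_uninduced,
                    stringsAsFactors = FALSE)
  out$condition_dependent <- abs(out$delta_z) >= delta_threshold
  out[order(out$gene), , drop = FALSE]
}

#' Write a hit table as TSV
#'
#' Columns `gene,condition,value,z,hit,direction`.
#' @param hits a `hit_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(
    as.data.frame(hits)[, c("gene", "condition", "value", "z", "hit", "direction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
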