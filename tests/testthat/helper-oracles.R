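# Independent reference implementations used only as oracles in tests.
# Each solves the same problem as the package by a different route
# (root-finding instead of fixed-point iteration, exhaustive enumeration,
# hand-rolled product-limit arithmetic) so agreement is informative.

# Huber Proposal 2 via profiled root-finding: for each trial sigma the
# location is the exact root of the winsorized-mean equation, and sigma
# solves the winsorized sum-of-squares equation.
huber_oracle <- function(x, k = 1.5) {
  n <- length(x)
  beta <- 2 * pnorm(k) - 1 - 2 * k * dnorm(k) +
    2 * k^2 * pnorm(k, lower.tail = FALSE)
  mu_of <- function(sigma) {
    g <- function(mu) mean(pmin(pmax(x, mu - k * sigma), mu + k * sigma)) - mu
    uniroot(g, lower = min(x), upper = max(x), tol = 1e-14,
            extendInt = "yes")$root
  }
  h <- function(sigma) {
    mu <- mu_of(sigma)
    w <- pmin(pmax(x, mu - k * sigma), mu + k * sigma)
    sum((w - mu)^2) - n * beta * sigma^2
  }
  # the scale equation can have several roots on skewed small samples;
  # the stable solution (the fixed-point attractor) is where h crosses
  # from positive to negative as sigma grows
  s0 <- sd(x)
  grid <- s0 * 10^seq(-4, 1, length.out = 400)
  hv <- vapply(grid, h, numeric(1))
  cross <- which(hv[-length(hv)] > 0 & hv[-1] <= 0)
  if (length(cross) == 0) stop("huber_oracle: no stable root found")
  i <- cross[length(cross)]
  sigma <- uniroot(h, lower = grid[i], upper = grid[i + 1], tol = 1e-14)$root
  list(mu = mu_of(sigma), sigma = sigma)
}

# Right-tail overlap probability by exhaustive enumeration of every draw
# of |de| genes from the background (feasible for |background| <= 12).
hyper_oracle <- function(targets, de_genes, background) {
  q <- length(intersect(targets, de_genes))
  draws <- combn(background, length(de_genes))
  hits <- apply(draws, 2, function(s) length(intersect(s, targets)) >= q)
  mean(hits)
}

# Product-limit estimator by hand (single group).
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    n_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = tt, survival = surv)
}

# Two-group log-rank chi-squared from first principles: observed minus
# expected events accumulated over event times, hypergeometric variance
# with ties pooled.
logrank_oracle <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  g1 <- levels(group)[1]
  O1 <- E1 <- V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Spearman rho without cor(): 1 - 6*sum(d^2)/(n(n^2-1)), valid when
# there are no ties.
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Minimal normalized-screen table for exercising call_hits() on values
# drawn directly from a known distribution (no plates, no loess).
fake_normalized <- function(values, genes = paste0("g", seq_along(values)),
                            condition = "uninduced", plate = "p1") {
  out <- data.frame(plate = plate, row = 1L, col = 1L, gene = genes,
                    well_type = "sample", condition = condition,
                    signal = 2^values, normalized = values,
                    stringsAsFactors = FALSE)
  class(out) <- c("normalized_screen", "data.frame")
  out
}

# A one-plate layout builder for loess_normalize tests: 16x24 grid,
# columns 1,2,23,24 controls, everything else sample wells.
grid_plate <- function(signal_fun, plate = "P1", condition = "uninduced",
                       control_value = 1000) {
  d <- expand.grid(row = 1:16, col = 1:24)
  d$plate <- plate
  d$condition <- condition
  d$well_type <- ifelse(d$col %in% c(1, 2, 23, 24), "control", "sample")
  d$gene <- ifelse(d$well_type == "control", "CTRL",
                   paste0("g", seq_len(nrow(d))))
  d$signal <- ifelse(d$well_type == "control", control_value,
                     signal_fun(d$row, d$col))
  plate_set(d[, c("plate", "row", "col", "gene", "well_type", "condition",
                  "signal")])
}
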