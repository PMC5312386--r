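test_that("plate_set validates addresses, signals and row letters", {
  df <- data.frame(plate = "P1", row = rep(LETTERS[1:16], each = 24),
                   col = rep(1:24, 16), gene = paste0("g", 1:384),
                   well_type = "sample", condition = "uninduced",
                   signal = 1000, stringsAsFactors = FALSE)
  ps <- plate_set(df)
  expect_s3_class(ps, "plate_set")
  expect_identical(sort(unique(ps$row)), 1:16)

  dup <- rbind(df, df[1, ])
  expect_error(plate_set(dup), "duplicate well address")
  bad <- df; bad$signal[3] <- -1
  expect_error(plate_set(bad), "finite and > 0")
  bad2 <- df; bad2$col[1] <- 25
  expect_error(plate_set(bad2), "columns must be 1-24")
  bad3 <- df; bad3$well_type <- "empty"
  expect_error(plate_set(bad3), "at least one sample well")
})

test_that("loess normalization maps a spatially uniform plate to a flat log2 surface", {
  ps <- grid_plate(function(r, c) 1024, control_value = 1024)
  nm <- loess_normalize(ps)
  expect_equal(nm$normalized, rep(log2(1024), nrow(nm)), tolerance = 1e-10)
})

test_that("control wells never influence the fitted surface", {
  set.seed(11)
  noise <- matrix(rnorm(16 * 24, 0, 0.1), 16, 24)
  base <- function(r, c) 2^(10 + 0.05 * r + noise[cbind(r, c)])
  with_ctrl <- grid_plate(base, control_value = 2^15)  # controls offset +5 log2
  without <- grid_plate(base, control_value = 1000)
  surf1 <- attr(loess_normalize(with_ctrl), "fit_surface")
  surf2 <- attr(loess_normalize(without), "fit_surface")
  expect_equal(surf1$fitted, surf2$fitted, tolerance = 1e-12)
})

test_that("a planted row gradient is removed (post-fit correlation with row ~ 0)", {
  set.seed(21)
  noise <- matrix(rnorm(16 * 24, 0, 0.1), 16, 24)
  grad <- function(r, c) 2^(10 + 1.0 * (r - 8.5) / 15 + noise[cbind(r, c)])
  nm <- loess_normalize(grid_plate(grad))
  s <- nm[nm$well_type == "sample", ]
  expect_gt(abs(cor(log2(s$signal), s$row)), 0.5)  # gradient present before
  expect_lt(abs(cor(s$normalized, s$row)), 0.05)   # and removed after
})

test_that("normalization is idempotent on an exactly linear surface", {
  ps <- grid_plate(function(r, c) 2^(10 + 0.08 * r - 0.03 * c))
  nm1 <- loess_normalize(ps)
  renorm_input <- nm1
  renorm_input$signal <- 2^nm1$normalized
  nm2 <- loess_normalize(plate_set(renorm_input[, c("plate", "row", "col",
                                                    "gene", "well_type",
                                                    "condition", "signal")]))
  expect_lt(max(abs(nm2$normalized - nm1$normalized)), 1e-6)
})

test_that("degenerate layouts and bad spans are rejected", {
  ps <- grid_plate(function(r, c) 1000)
  expect_error(loess_normalize(ps, excluded_cols = 1:24), "degenerate layout")
  expect_error(loess_normalize(ps, span = 0), "span")
  expect_error(loess_normalize(ps, span = 1.5), "span")
})

test_that("robust z-scores match hand values and are affine invariant", {
  x <- c(1, 2, 3, 4, 5)
  z <- robust_z(x)
  expect_equal(z[3], 0)
  expect_equal(z[5], 2 / 1.4826, tolerance = 1e-10)
  expect_equal(robust_z(-x), -z)                      # odd symmetry
  expect_equal(robust_z(3 * x + 7), z)                # affine invariance
  expect_error(robust_z(rep(2, 10)), "zero-spread")
  expect_error(robust_z(c(1, 2)), "at least 3")
})

test_that("Huber Proposal 2 agrees with the root-finding oracle", {
  set.seed(303)
  for (i in 1:20) {
    x <- rnorm(80, sd = runif(1, 0.5, 4)) +
      ifelse(runif(80) < 0.1, rnorm(80, 0, 10), 0)
    p <- huber_proposal2(x, tol = 1e-12)
    o <- huber_oracle(x)
    expect_equal(p$mu, o$mu, tolerance = 1e-9)
    expect_equal(p$sigma, o$sigma, tolerance = 1e-9)
  }
})

test_that("Huber scale is consistent on Gaussian data and bounds outliers", {
  set.seed(7)
  x <- rnorm(10000)
  h <- huber_proposal2(x)
  expect_true(h$converged)
  expect_gt(h$sigma, 0.97); expect_lt(h$sigma, 1.03)
  # winsorization bounds a gross outlier: degenerate majority collapses
  # the scale to its honest limit, still strictly below the classical SD
  h2 <- suppressWarnings(huber_proposal2(c(0, 0, 0, 0, 10)))
  expect_lt(h2$sigma, sd(c(0, 0, 0, 0, 10)))
  # cross-check against the independent MASS implementation
  skip_if_not_installed("MASS")
  m <- MASS::hubers(x)
  expect_equal(h$mu, m$mu, tolerance = 1e-3)
  expect_equal(h$sigma, m$s, tolerance = 5e-3)
})

test_that("Huber estimate reduces to classical mean/SD as k grows", {
  set.seed(31)
  x <- rnorm(500, 3, 2)
  h <- huber_proposal2(x, k = 100)
  expect_equal(h$mu, mean(x), tolerance = 1e-6)
  expect_equal(h$sigma, sd(x) * sqrt((length(x) - 1) / length(x)),
               tolerance = 1e-6)
})

test_that("symmetric samples give an exactly symmetric location", {
  x <- c(-3, -1, 1, 3)
  expect_equal(huber_proposal2(x)$mu, 0)
  expect_error(huber_proposal2(rep(4, 10)), "zero-scale")
  expect_error(huber_proposal2(c(1, 2, 3)), "at least 4")
})

test_that("hit calls follow the inclusive three-sigma rule on the library distribution", {
  set.seed(77)
  vals <- rnorm(2000)
  nm <- fake_normalized(vals)
  hits <- call_hits(nm)
  med <- median(vals)
  sigma <- huber_proposal2(vals)$sigma
  expect_identical(hits$hit, abs(hits$value - med) >= 3 * sigma)
  expect_true(all(hits$direction[hits$hit & hits$value <= med] ==
                    "anti-proliferative"))
  expect_true(all(hits$direction[hits$hit & hits$value > med] ==
                    "pro-proliferative"))
  expect_true(all(hits$direction[!hits$hit] == "none"))
})

test_that("spiked genes are recalled and the null tail matches 2*pnorm(-3)", {
  set.seed(55)
  vals <- rnorm(2000)
  spiked <- sample(2000, 20)
  vals[spiked] <- -6  # -6 sigma on the N(0,1) null
  hits <- call_hits(fake_normalized(vals))
  sp_genes <- paste0("g", spiked)
  expect_true(all(hits$hit[hits$gene %in% sp_genes]))
  expect_true(all(hits$direction[hits$gene %in% sp_genes] ==
                    "anti-proliferative"))

  set.seed(56)
  null_vals <- rnorm(10000)
  nh <- sum(call_hits(fake_normalized(null_vals))$hit)
  expected <- 10000 * 2 * pnorm(-3)
  band <- 3 * sqrt(10000 * 2 * pnorm(-3) * (1 - 2 * pnorm(-3)))
  expect_lt(abs(nh - expected), band)
})

test_that("hit calling is invariant to plate relabeling and well order", {
  set.seed(88)
  vals <- rnorm(500)
  nm <- fake_normalized(vals)
  base <- call_hits(nm)
  perm <- nm[sample(nrow(nm)), ]
  perm$plate <- sample(c("pA", "pB"), nrow(perm), replace = TRUE)
  class(perm) <- class(nm)
  shuffled <- call_hits(perm)
  shuffled$plate <- base$plate
  expect_equal(base[, c("gene", "value", "z", "hit", "direction")],
               shuffled[, c("gene", "value", "z", "hit", "direction")])
})

test_that("hit recall is monotone in spike effect size", {
  recalls <- vapply(c(2, 4, 6), function(eff) {
    set.seed(99)
    vals <- rnorm(2000)
    vals[1:50] <- vals[1:50] - eff
    hits <- call_hits(fake_normalized(vals))
    mean(hits$hit[hits$gene %in% paste0("g", 1:50)])
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  expect_equal(recalls[3], 1)
})

test_that("differential response flags condition-dependent knockdowns", {
  set.seed(12)
  vals <- rnorm(300)
  hu <- call_hits(fake_normalized(vals, condition = "uninduced"))
  hi <- call_hits(fake_normalized(vals, condition = "induced"))
  same <- differential_response(hi, hu)
  expect_true(all(same$delta_z == 0))
  expect_false(any(same$condition_dependent))

  vals2 <- vals; vals2[1:10] <- vals2[1:10] - 4
  hi2 <- call_hits(fake_normalized(vals2, condition = "induced"))
  dr <- differential_response(hi2, hu)
  flagged <- dr$gene[dr$condition_dependent]
  expect_true(all(paste0("g", 1:10) %in% flagged))
  expect_lt(sum(dr$condition_dependent) - 10, 15)  # few false flags

  empty_a <- hu[hu$gene == "g1", ]; empty_b <- hu[hu$gene == "g2", ]
  expect_warning(differential_response(empty_a, empty_b), "disjoint")
})
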