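#' Simulate a plate-format RNAi viability screen with planted truth
#'
#' Emulates 384-well screen plates (16 rows x 24 columns) read in two
#' induction conditions. Columns 1, 2, 23 and 24 carry control wells at a
#' constant baseline; the remaining 320 wells per plate hold one gene
#' each. Log2 signals are
#' `baseline + spatial surface + gene effect + N(0, noise_sd)`,
#' where the spatial artifact is a random low-order polynomial in
#' (row, column) rescaled so its peak-to-peak range equals
#' `gradient_amplitude` log2 units, redrawn per plate, and gene effects
#' are 0 except for spiked genes, whose planted effects are given in
#' noise-SD units (signed; negative = viability loss).
#'
#' @param n_genes number of library genes (one well per gene per
#'   condition).
#' @param n_plates number of plates; default just enough for the library.
#' @param gradient_amplitude peak-to-peak spatial artifact size in log2
#'   units (0 disables).
#' @param noise_sd well-level log2 noise SD.
#' @param spikes data.frame `gene`, `condition`, `effect` (in noise-SD
#'   units); `condition = NA` applies to both conditions. NULL for none.
#' @param conditions character vector of condition labels.
#' @param baseline log2 baseline signal (default 10, i.e. 1024 counts).
#' @param control_cols columns reserved for controls.
#' @param seed RNG seed.
#' @return list: `plates` (a [plate_set()]), `truth` (spike table and
#'   per-plate surface matrices).
#' @export
simulate_screen <- function(n_genes, n_plates = ceiling(n_genes / 320),
                            gradient_amplitude = 1, noise_sd = 0.3,
                            spikes = NULL,
                            conditions = c("uninduced", "induced"),
                            baseline = 10, control_cols = c(1, 2, 23, 24),
                            seed = 1) {
  set.seed(seed)
  sample_cols <- setdiff(1:24, control_cols)
  capacity <- n_plates * 16 * length(sample_cols)
  if (n_genes > capacity)
    stop(sprintf("capacity error: %d genes exceed %d sample wells (%d plates)",
                 n_genes, capacity, n_plates))
  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes)
    stopifnot(all(c("gene", "effect") %in% names(spikes)))
    if (!"condition" %in% names(spikes)) spikes$condition <- NA_character_
    bad <- setdiff(spikes$gene, paste0("gene", seq_len(n_genes)))
    if (length(bad))
      stop("spiked genes not on plates: ", paste(bad, collapse = ", "))
  }
  genes <- paste0("gene", seq_len(n_genes))
  layout <- expand.grid(row = 1:16, col = 1:24)
  layout <- layout[order(layout$col, layout$row), ]
  wells <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    d <- layout
    d$plate <- sprintf("plate%02d", p)
    d$well_type <- ifelse(d$col %in% control_cols, "control", "sample")
    d$gene <- NA_character_
    d$gene[d$well_type == "control"] <- "CTRL"
    idx_sample <- which(d$well_type == "sample")
    offset <- (p - 1) * length(idx_sample)
    take <- seq_along(idx_sample) + offset
    assigned <- take <= n_genes
    # genes are dispensed in randomized well order, as screening libraries
    # are plated, so planted effects are never spatially clustered
    d$gene[sample(idx_sample)[seq_len(sum(assigned))]] <-
      genes[take[assigned]]
    empty <- idx_sample[d$well_type[idx_sample] == "sample" &
                          is.na(d$gene[idx_sample])]
    d$well_type[empty] <- "empty"
    d
  }))
  # one smooth artifact surface per plate, shared across conditions
  surfaces <- lapply(seq_len(n_plates), function(p) {
    a <- stats::runif(5, -1, 1)
    r <- (1:16 - 8.5) / 7.5
    cc <- (1:24 - 12.5) / 11.5
    s <- outer(r, cc, function(ri, ci)
      a[1] * ri + a[2] * ci + a[3] * ri * ci + a[4] * ri^2 + a[5] * ci^2)
    if (gradient_amplitude > 0 && diff(range(s)) > 0) {
      s <- gradient_amplitude * (s - mean(s)) / diff(range(s))
    } else {
      s <- s * 0
    }
    s
  })
  names(surfaces) <- sprintf("plate%02d", seq_len(n_plates))
  out <- do.call(rbind, lapply(conditions, function(cond) {
    d <- wells
    d$condition <- cond
    surf <- vapply(seq_len(nrow(d)), function(i)
      surfaces[[d$plate[i]]][d$row[i], d$col[i]], numeric(1))
    eff <- numeric(nrow(d))
    if (!is.null(spikes)) {
      sp <- spikes[is.na(spikes$condition) | spikes$condition == cond, ,
                   drop = FALSE]
      m <- match(d$gene, sp$gene)
      eff[!is.na(m)] <- sp$effect[m[!is.na(m)]] * noise_sd
    }
    log2sig <- baseline + surf + eff +
      stats::rnorm(nrow(d), 0, noise_sd)
    log2sig[d$well_type == "control"] <- baseline
    d$signal <- 2^log2sig
    d$signal[d$well_type == "empty"] <- NA_real_
    d
  }))
  rownames(out) <- NULL
  list(plates = plate_set(out[, c("plate", "row", "col", "gene",
                                  "well_type", "condition", "signal")]),
       truth = list(spikes = spikes, surfaces = surfaces,
                    noise_sd = noise_sd, baseline = baseline))
}

#' Simulate a signed regulator-target network
#'
#' Regulators get disjoint target blocks drawn from a common gene pool;
#' signs are random, weights 1. A convenience prior for testing the ITR
#' statistics.
#'
#' @param n_regulators number of regulators.
#' @param targets_per_regulator targets per regulator.
#' @param frac_unknown_sign fraction of edges with unknown predicted sign.
#' @param seed RNG seed.
#' @return a [regulator_network()].
#' @export
simulate_network <- function(n_regulators = 10, targets_per_regulator = 20,
                             frac_unknown_sign = 0, seed = 1) {
  set.seed(seed)
  n_edges <- n_regulators * targets_per_regulator
  edges <- data.frame(
    regulator = rep(sprintf("REG%02d", seq_len(n_regulators)),
                    each = targets_per_regulator),
    target = paste0("tgt", seq_len(n_edges)),
    sign = sample(c(1, -1), n_edges, replace = TRUE),
    weight = 1,
    stringsAsFactors = FALSE)
  if (frac_unknown_sign > 0) {
    unk <- stats::runif(n_edges) < frac_unknown_sign
    edges$sign[unk] <- NA
  }
  regulator_network(edges)
}

#' Simulate per-contrast DE tables from planted regulator activity
#'
#' Each contrast has a planted activity state per regulator (+1 active,
#' -1 inhibited, 0 silent). Targets of a non-silent regulator with known
#' predicted sign receive `log2FC = state * sign * effect_mu + noise`;
#' all other genes (including `n_null_genes` extra background genes)
#' receive pure noise. Adjusted p-values are generated structurally: a
#' monotone map of |log2FC| calibrated so that a fraction
#' `background_de_rate` of null genes passes padj <= 0.05.
#'
#' @param network a [regulator_network()].
#' @param activity data.frame `regulator`, `contrast`, `state` with state
#'   in `{-1, 0, 1}`; regulators must exist in the network.
#' @param effect_mu planted absolute log2FC of regulated targets (> 0).
#' @param noise_sd log2FC noise SD.
#' @param background_de_rate fraction of null genes passing the 0.05
#'   cutoff.
#' @param n_null_genes extra unregulated genes in each table.
#' @param seed RNG seed.
#' @return list: `de` (columns `contrast`, `gene`, `log2fc`, `padj`),
#'   `truth` (the activity table plus per-contrast regulated gene sets).
#' @export
simulate_contrasts <- function(network, activity, effect_mu = 2,
                               noise_sd = 0.5, background_de_rate = 0.05,
                               n_null_genes = 500, seed = 1) {
  set.seed(seed)
  network <- if (inherits(network, "regulator_network")) network
             else regulator_network(network)
  if (effect_mu <= 0) stop("effect_mu must be > 0")
  activity <- as.data.frame(activity)
  stopifnot(all(c("regulator", "contrast", "state") %in% names(activity)))
  bad <- setdiff(activity$regulator, network$regulator)
  if (length(bad))
    stop("activity names regulators absent from the network: ",
         paste(bad, collapse = ", "))
  genes <- c(unique(network$target), paste0("null", seq_len(n_null_genes)))
  thr <- noise_sd * stats::qnorm(1 - background_de_rate / 2)
  truth_targets <- list()
  de <- do.call(rbind, lapply(unique(activity$contrast), function(ct) {
    lfc <- stats::setNames(stats::rnorm(length(genes), 0, noise_sd), genes)
    act <- activity[activity$contrast == ct & activity$state != 0, ,
                    drop = FALSE]
    regulated <- character()
    for (i in seq_len(nrow(act))) {
      ed <- network[network$regulator == act$regulator[i] &
                      !is.na(network$sign), , drop = FALSE]
      lfc[ed$target] <- lfc[ed$target] + act$state[i] * ed$sign * effect_mu
      regulated <- union(regulated, ed$target)
    }
    truth_targets[[ct]] <<- regulated
    padj <- ifelse(abs(lfc) > 0, pmin(1, 0.05 * (thr / abs(lfc))^2), 1)
    data.frame(contrast = ct, gene = genes, log2fc = unname(lfc),
               padj = unname(padj), stringsAsFactors = FALSE)
  }))
  rownames(de) <- NULL
  list(de = de, truth = list(activity = activity,
                             regulated_genes = truth_targets,
                             effect_mu = effect_mu, noise_sd = noise_sd))
}

#' Simulate a tumour cohort with a planted signature and survival
#'
#' Emulates the structure of a large neuroblastoma expression cohort: a
#' minority of samples is MYCN-amplified and draws higher MYCN
#' expression; a binary latent regulator-activity state (high in the
#' amplified group) shifts each signature gene along its expected
#' direction by `activity_effect` noise-SD units; every signature gene is
#' additionally coupled to MYCN expression with planted slope
#' `mycn_coupling`; `n_null_genes` background genes carry pure noise.
#' Survival is exponential with hazard multiplied by
#' `hazard_ratio_per_unit` per activity unit; independent uniform
#' censoring is calibrated numerically to the requested rate.
#'
#' @param n_samples cohort size (default 478).
#' @param frac_amplified fraction of MYCN-amplified samples, in (0, 1).
#' @param signature a [build_signature()]-style data.frame (`gene`,
#'   `direction`); non-empty.
#' @param activity_effect per-gene shift of the high-activity group, in
#'   units of `noise_sd`.
#' @param mycn_coupling planted per-gene slope on MYCN expression.
#' @param noise_sd residual SD of expression values.
#' @param hazard_ratio_per_unit hazard ratio per latent activity unit
#'   (> 0; 1 = no survival effect).
#' @param censor_rate target fraction of censored samples.
#' @param n_null_genes unregulated background genes.
#' @param baseline_hazard events per day in the low-activity group.
#' @param probes_per_gene emulate many-to-one probe sets by replicating
#'   each signature gene over this many probes (default 1).
#' @param seed RNG seed.
#' @return list: `expr` (matrix probes x samples, includes a `MYCN` row),
#'   `clinical` (`sample`, `time_days`, `event`, `mycn_amp`,
#'   `mycn_expr`), `probe_map` (`probe`, `gene`), `truth` (latent
#'   activity, planted slopes, hazard ratio).
#' @export
simulate_cohort <- function(n_samples = 478, frac_amplified = 0.2,
                            signature, activity_effect = 2,
                            mycn_coupling = 0.5, noise_sd = 0.5,
                            hazard_ratio_per_unit = 3, censor_rate = 0.3,
                            n_null_genes = 100, baseline_hazard = 1 / 1500,
                            probes_per_gene = 1, seed = 1) {
  set.seed(seed)
  if (frac_amplified <= 0 || frac_amplified >= 1)
    stop("frac_amplified must lie strictly between 0 and 1")
  if (hazard_ratio_per_unit <= 0) stop("hazard ratio must be > 0")
  signature <- as.data.frame(signature)
  if (nrow(signature) == 0) stop("signature must be non-empty")
  if (!"direction" %in% names(signature)) signature$direction <- 1
  samples <- sprintf("S%03d", seq_len(n_samples))
  n_amp <- max(1, round(frac_amplified * n_samples))
  amp <- rep(0L, n_samples)
  amp[sample.int(n_samples, n_amp)] <- 1L
  mycn_expr <- ifelse(amp == 1, stats::rnorm(n_samples, 12, 0.8),
                      stats::rnorm(n_samples, 9, 1))
  activity <- as.numeric(amp)                 # latent state, high in MNA
  sig_genes <- signature$gene
  dirs <- signature$direction
  probes <- if (probes_per_gene > 1)
    paste0(rep(sig_genes, each = probes_per_gene), "_p",
           seq_len(probes_per_gene)) else sig_genes
  probe_map <- data.frame(probe = probes,
                          gene = rep(sig_genes, each = probes_per_gene),
                          stringsAsFactors = FALSE)
  dirs_p <- rep(dirs, each = probes_per_gene)
  sig_mat <- t(vapply(seq_along(probes), function(i)
    dirs_p[i] * activity * activity_effect * noise_sd +
      mycn_coupling * mycn_expr + stats::rnorm(n_samples, 0, noise_sd),
    numeric(n_samples)))
  rownames(sig_mat) <- probes
  null_mat <- matrix(stats::rnorm(n_null_genes * n_samples, 8, noise_sd),
                     nrow = n_null_genes,
                     dimnames = list(paste0("bg", seq_len(n_null_genes)), NULL))
  mycn_row <- matrix(mycn_expr + stats::rnorm(n_samples, 0, 0.1), nrow = 1,
                     dimnames = list("MYCN", NULL))
  expr <- rbind(sig_mat, null_mat, mycn_row)
  colnames(expr) <- samples
  hazard <- baseline_hazard *
    exp(log(hazard_ratio_per_unit) * activity)
  t_event <- stats::rexp(n_samples, rate = hazard)
  if (censor_rate > 0) {
    mean_censor <- function(cm) {
      pc <- (1 - exp(-hazard * cm)) / (hazard * cm)   # P(C < T) per subject
      mean(pc)
    }
    cm <- stats::uniroot(function(cm) mean_censor(cm) - censor_rate,
                         lower = 1e-3, upper = 1e8, tol = 1e-6)$root
    t_cens <- stats::runif(n_samples, 0, cm)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n_samples)
    time <- t_event
  }
  clinical <- data.frame(sample = samples, time_days = time, event = event,
                         mycn_amp = amp, mycn_expr = mycn_expr,
                         stringsAsFactors = FALSE)
  list(expr = expr, clinical = clinical, probe_map = probe_map,
       truth = list(activity = stats::setNames(activity, samples),
                    b1 = stats::setNames(rep(mycn_coupling, length(probes)),
                                         probes),
                    directions = stats::setNames(dirs_p, probes),
                    hazard_ratio = hazard_ratio_per_unit,
                    activity_effect = activity_effect,
                    noise_sd = noise_sd))
}
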