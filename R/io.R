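#' Read an expression matrix TSV
#'
#' First column = row ids (probes or genes), remaining columns = samples.
#' Duplicate row or column ids and non-numeric cells are rejected with
#' the offending id / line named; ragged rows are a parse error.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_expression <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("expression TSV needs at least one sample column")
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample column: ", samples[duplicated(samples)][1])
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nf != length(header))
  if (length(bad))
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad[1], nf[bad[1]], length(header)))
  x <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- x[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row id: ", ids[duplicated(ids)][1])
  vals <- suppressWarnings(
    vapply(x[-1], as.numeric, numeric(nrow(x))))
  if (nrow(x) == 1) vals <- matrix(vals, nrow = 1)
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at line %d, column '%s'",
                 idx[1] + 1L, samples[idx[2]]))
  }
  rownames(vals) <- ids
  colnames(vals) <- samples
  vals
}

#' Write an expression matrix TSV
#'
#' Inverse of [read_expression()]: first column `id`, then one column per
#' sample; round-trips losslessly for canonical files.
#'
#' @param expr numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs row and column names")
  df <- data.frame(id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member genes (>= 1 member). Member order is preserved.
#'
#' @param path file path.
#' @return named list of character vectors, with a `description`
#'   attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error: line with fewer than 3 fields: ",
           substr(l, 1, 40))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop("GMT parse error: empty member list for set ", f[1])
    structure(members, description = f[2], name = f[1])
  })
  names(sets) <- vapply(sets, attr, character(1), "name")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors (set members).
#' @param descriptions optional per-set descriptions (default the set
#'   name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  if (any(vapply(sets, length, integer(1)) == 0))
    stop("refusing to write an empty gene set")
  if (is.null(descriptions)) {
    descriptions <- vapply(sets, function(s) {
      d <- attr(s, "description"); if (is.null(d)) NA_character_ else d
    }, character(1))
    descriptions[is.na(descriptions)] <- names(sets)[is.na(descriptions)]
  }
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every tunable of the end-to-end synthetic run with its documented
#' default. Unknown keys passed to [run_pipeline()] are rejected.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    # screen
    n_genes = 960, gradient_amplitude = 1, noise_sd_screen = 0.3,
    n_spikes = 20, spike_effect = -6, span = 0.7,
    excluded_cols = c(1, 2, 23, 24), threshold_sd = 3, delta_threshold = 2,
    # network / contrasts
    n_regulators = 10, targets_per_regulator = 20, n_contrasts = 5,
    active_regulator = "REG01", active_state = -1, effect_mu = 2,
    noise_sd_de = 0.5, background_de_rate = 0.05,
    de_padj = 0.05, z_cutoff = 2, min_contrasts = 2,
    # cohort
    n_samples = 478, frac_amplified = 0.2, activity_effect = 2,
    mycn_coupling = 0.5, noise_sd_cohort = 0.5, hazard_ratio = 3,
    censor_rate = 0.3, linkage = "ward.D2", distance = "euclidean",
    stratify_method = "median")
}

#' Run the full synthetic pipeline
#'
#' Deterministic end-to-end driver: simulate a screen, normalize and call
#' hits in both induction conditions; simulate a regulator network and DE
#' contrasts with one planted non-silent regulator, score ITRs and build
#' its gene signature; simulate a patient cohort around that signature,
#' correct the expression matrix for MYCN, cluster into Signature(+)/(-)
#' groups, test MYCN-amplification separation, and stratify survival by
#' signature group. All interchange files are written under
#' `config$out_dir` (when set) together with a provenance record of
#' parameters and output checksums.
#'
#' @param config named list of overrides of [default_config()]; unknown
#'   keys raise an error before any computation.
#' @return invisible list: `hits_induced`, `hits_uninduced`,
#'   `differential`, `itr`, `signature`, `cohort`, `model`, `assignment`,
#'   `mna_test`, `survival`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character()
  stage <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage=%s wall=%.2fs", name,
                                       proc.time()[["elapsed"]] - t1))
    res
  }

  scr <- stage("simulate_screen", {
    spikes <- data.frame(gene = paste0("gene", seq_len(cfg$n_spikes)),
                         condition = "induced", effect = cfg$spike_effect)
    simulate_screen(n_genes = cfg$n_genes,
                    gradient_amplitude = cfg$gradient_amplitude,
                    noise_sd = cfg$noise_sd_screen, spikes = spikes,
                    seed = cfg$seed)
  })
  norm <- stage("loess_normalize",
                loess_normalize(scr$plates, span = cfg$span,
                                excluded_cols = cfg$excluded_cols))
  hits <- stage("call_hits", call_hits(norm, threshold_sd = cfg$threshold_sd))
  hits_i <- hits[hits$condition == "induced", ]
  hits_u <- hits[hits$condition == "uninduced", ]
  diff_resp <- stage("differential_response",
                     differential_response(hits_i, hits_u,
                                           delta_threshold = cfg$delta_threshold))

  net <- stage("simulate_network",
               simulate_network(cfg$n_regulators, cfg$targets_per_regulator,
                                seed = cfg$seed + 1))
  activity <- expand.grid(regulator = unique(net$regulator),
                          contrast = paste0("contrast", seq_len(cfg$n_contrasts)),
                          stringsAsFactors = FALSE)
  activity$state <- ifelse(activity$regulator == cfg$active_regulator,
                           cfg$active_state, 0)
  contrasts <- stage("simulate_contrasts",
                     simulate_contrasts(net, activity, effect_mu = cfg$effect_mu,
                                        noise_sd = cfg$noise_sd_de,
                                        background_de_rate = cfg$background_de_rate,
                                        seed = cfg$seed + 2))
  itr <- stage("infer_regulators",
               infer_regulators(net, contrasts$de, de_padj = cfg$de_padj,
                                z_cutoff = cfg$z_cutoff))
  sig <- stage("build_signature",
               build_signature(itr, cfg$active_regulator, contrasts$de,
                               min_contrasts = cfg$min_contrasts))

  cohort <- stage("simulate_cohort",
                  simulate_cohort(n_samples = cfg$n_samples,
                                  frac_amplified = cfg$frac_amplified,
                                  signature = sig,
                                  activity_effect = cfg$activity_effect,
                                  mycn_coupling = cfg$mycn_coupling,
                                  noise_sd = cfg$noise_sd_cohort,
                                  hazard_ratio_per_unit = cfg$hazard_ratio,
                                  censor_rate = cfg$censor_rate,
                                  seed = cfg$seed + 3))
  model <- stage("fit_mycn_model",
                 fit_mycn_model(cohort$expr, cohort$clinical$mycn_expr,
                                cohort$clinical$mycn_amp))
  corrected <- stage("correct_matrix",
                     correct_matrix(cohort$expr, model,
                                    cohort$clinical$mycn_expr))
  assign <- stage("cluster_signature",
                  cluster_signature(corrected, sig,
                                    probe_map = cohort$probe_map,
                                    linkage = cfg$linkage,
                                    distance = cfg$distance))
  mna <- stage("mna_separation_test",
               mna_separation_test(assign$score, cohort$clinical$mycn_amp,
                                   expr = corrected[assign$probes, ,
                                                    drop = FALSE]))
  surv <- stage("survival", {
    lr <- logrank_test(cohort$clinical$time_days, cohort$clinical$event,
                       assign$group)
    km <- km_estimate(cohort$clinical$time_days, cohort$clinical$event,
                      assign$group)
    strat <- stratify_by_expression(corrected["MYCN", ],
                                    cohort$clinical$time_days,
                                    cohort$clinical$event,
                                    method = cfg$stratify_method)
    list(logrank_signature = lr, km = km, mycn_stratification = strat)
  })

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(cfg$out_dir, f)
    write_screen_csv(scr$plates, p("screen_plates.csv"))
    write_hit_table(hits, p("hit_table.tsv"))
    utils::write.table(diff_resp, p("differential_response.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(net, p("network.tsv"))
    write_de_table(contrasts$de, p("de_tables.tsv"))
    utils::write.table(as.data.frame(itr), p("itr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_signature(sig, p("signature.tsv"))
    write_signature_gmt(sig, p("signature.gmt"))
    write_expression(cohort$expr, p("expression.tsv"))
    write_expression(corrected, p("expression_mycn_corrected.tsv"))
    write_clinical(cohort$clinical, p("clinical.tsv"))
    groups <- data.frame(sample = names(assign$group),
                         group = as.character(assign$group),
                         score = unname(assign$score))
    utils::write.table(groups, p("signature_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- list.files(cfg$out_dir, full.names = TRUE)
    outputs <- outputs[!grepl("provenance", outputs)]
    sums <- tools::md5sum(outputs)
    prov <- c(sprintf("# pipeline provenance"),
              sprintf("param\t%s\t%s", names(cfg),
                      vapply(cfg, function(v) paste(format(v), collapse = ","),
                             character(1))),
              log_lines,
              sprintf("md5\t%s\t%s", basename(names(sums)), unname(sums)),
              sprintf("total_wall=%.2fs", proc.time()[["elapsed"]] - t0))
    writeLines(prov, p("provenance.txt"))
  }
  invisible(list(hits_induced = hits_i, hits_uninduced = hits_u,
                 differential = diff_resp, itr = itr, signature = sig,
                 cohort = cohort, model = model, assignment = assign,
                 mna_test = mna, survival = surv, config = cfg))
}
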