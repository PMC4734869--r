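# Pipeline stages as shell-runnable commands over a plain-text key=value
# configuration. Each stage reads its predecessors' files, writes its own
# outputs plus a manifest, and can be driven from inst/scripts/genopred.

#' Run configuration
#'
#' Plain-text `key=value` configuration (one pair per line, `#` comments).
#' Unknown keys are rejected; values are type-converted against the defaults
#' of [default_run_config()]. Keys cover simulation scale (`n_sires`,
#' `n_dams`, `n_offspring`, `n_chrom`, `markers_per_chrom`, `trait`, `h2`,
#' `n_qtl`), QC thresholds (`maf`, `hwe_p`, `marker_callrate`,
#' `sample_callrate`, `gencall`, `ld_window`, `ld_r2`), defect rates
#' (`defect_*`), chain settings (`n_iter`, `burn_in`, `thin`), evaluation
#' (`models`, `responses`, `k`), `seed` and `out_dir`.
#'
#' @param path Path of the configuration file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- default_run_config()
  cfg <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop_arg("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (!key %in% names(defaults))
      stop_arg("unknown config key: ", key)
    proto <- defaults[[key]]
    cfg[[key]] <- if (is.numeric(proto)) as.numeric(val) else val
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  structure(list(
    n_sires = 294, n_dams = 1546, n_offspring = 2000,
    n_chrom = 10, markers_per_chrom = 500, chrom_len_cm = 100,
    ld_block_len = 5, ld_rho = 0.93, missing_rate = 0.003,
    trait = "REA", h2 = -1, n_qtl = 300,
    defect_maf = 0, defect_hwe = 0, defect_marker_callrate = 0,
    defect_dup_position = 0, defect_dup_column = 0, defect_gencall = 0,
    defect_sample_callrate = 0,
    maf = 0.02, hwe_p = 1e-5, marker_callrate = 0.98,
    sample_callrate = 0.90, gencall = 0.70, ld_window = 100, ld_r2 = 0.995,
    outlier_sd = 3.5, min_cg = 3,
    n_iter = 20000, burn_in = 4000, thin = 10,
    models = "BRR,BayesC,BL", responses = "Ystar,EBV", k = 5,
    seed = 1, out_dir = "genopred_run"), class = "run_config")
}

validate_run_config <- function(cfg) {
  check_count(cfg$seed, "seed", min = 0L)
  check_count(cfg$k, "k", min = 2L)
  if (cfg$h2 > 0) check_proportion(cfg$h2, "h2", open = TRUE)
  for (nm in grep("^defect_", names(cfg), value = TRUE))
    check_proportion(cfg[[nm]], nm)
  check_proportion(cfg$missing_rate, "missing_rate")
  structure(cfg, class = "run_config")
}

write_manifest <- function(cfg, dir, stage) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c(sprintf("# genopred %s manifest", stage),
             vapply(names(cfg), function(k)
               sprintf("%s=%s", k, format(cfg[[k]], scientific = FALSE)),
               character(1)))
  writeLines(lines, file.path(dir, sprintf("manifest_%s.txt", stage)))
}

cfg_trait_config <- function(cfg) {
  tc <- trait_config(cfg$trait, n_qtl = cfg$n_qtl)
  if (cfg$h2 > 0) tc$h2 <- cfg$h2
  tc
}

stage_log <- function(...) message(sprintf(...))

#' Pipeline stage: simulate a study population
#'
#' Generates the synthetic bundle defined by the configuration (genotypes as
#' PLINK PED/MAP, pedigree/phenotype/truth TSVs, manifest) into
#' `cfg$out_dir`. Planted QC defects are applied when any `defect_*` rate is
#' positive, and the planted labels are saved to `planted_defects.tsv`.
#'
#' @param cfg A `run_config` (path or list).
#' @param force Overwrite a non-empty output directory.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(cfg, force = FALSE) {
  cfg <- as_run_config(cfg)
  dir <- cfg$out_dir
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop_arg("output directory not empty (use force = TRUE): ", dir)
  sim <- sim_halfsib_population(
    n_sires = cfg$n_sires, n_dams = cfg$n_dams,
    n_offspring = cfg$n_offspring, n_chrom = cfg$n_chrom,
    markers_per_chrom = cfg$markers_per_chrom,
    chrom_len_cm = cfg$chrom_len_cm, ld_block_len = cfg$ld_block_len,
    ld_rho = cfg$ld_rho, config = cfg_trait_config(cfg),
    missing_rate = cfg$missing_rate, seed = cfg$seed)
  spec <- defect_spec(maf = cfg$defect_maf, hwe = cfg$defect_hwe,
                      marker_callrate = cfg$defect_marker_callrate,
                      dup_position = cfg$defect_dup_position,
                      dup_column = cfg$defect_dup_column,
                      gencall = cfg$defect_gencall,
                      sample_callrate = cfg$defect_sample_callrate)
  if (any(unlist(spec) > 0)) {
    sim$genotypes <- inject_qc_defects(sim$genotypes, spec,
                                       seed = cfg$seed + 17)
    planted <- attr(sim$genotypes, "planted")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.table(planted, file.path(dir, "planted_defects.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_sim_bundle(sim, dir, trait = cfg$trait, seed = cfg$seed)
  write_manifest(cfg, dir, "simulate")
  stage_log("simulate: %d animals x %d markers written to %s",
            nrow(sim$genotypes$codes), ncol(sim$genotypes$codes), dir)
  invisible(dir)
}

#' Pipeline stage: genotype quality control
#'
#' Reads the bundle's PED/MAP, runs [iterative_qc()] with the configured
#' thresholds, and writes the surviving matrix (TSV dialect), the QC report
#' and the mean adjacent-marker LD to the run directory.
#'
#' @inheritParams cmd_simulate
#' @return The output directory, invisibly.
#' @export
cmd_qc <- function(cfg) {
  cfg <- as_run_config(cfg)
  dir <- cfg$out_dir
  prefix <- file.path(dir, "genotypes")
  if (!file.exists(paste0(prefix, ".ped")))
    stop_arg("missing input: ", paste0(prefix, ".ped"))
  geno <- read_plink(prefix)
  # GenCall scores are not representable in PED/MAP; restore planted scores
  planted_path <- file.path(dir, "planted_defects.tsv")
  if (file.exists(planted_path)) {
    planted <- read.table(planted_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
    low <- planted$id[planted$class == "low_gencall"]
    geno$markers$gencall[geno$markers$id %in% low] <- 0.5
  }
  thr <- qc_thresholds(maf = cfg$maf, hwe_p = cfg$hwe_p,
                       marker_callrate = cfg$marker_callrate,
                       sample_callrate = cfg$sample_callrate,
                       gencall = cfg$gencall, ld_window = cfg$ld_window,
                       ld_r2 = cfg$ld_r2)
  res <- iterative_qc(geno, thr, verbose = TRUE)
  write_geno_tsv(res$genotypes, file.path(dir, "genotypes_qc.tsv"))
  write_qc_report(res$report, file.path(dir, "qc_report.tsv"))
  ld <- adjacent_ld_summary(res$genotypes)
  writeLines(sprintf("mean_adjacent_r2\t%.4f", ld),
             file.path(dir, "ld_summary.tsv"))
  write_manifest(cfg, dir, "qc")
  stage_log("qc: %d iterations, %d markers and %d samples removed, mean adjacent r2 = %.3f",
            res$report$iterations, nrow(res$report$removed_markers),
            nrow(res$report$removed_samples), ld)
  invisible(dir)
}

#' Pipeline stage: step-1 animal model
#'
#' Filters contemporary-group outliers, fits [animal_model()] on the
#' phenotypes and pedigree of the bundle, and writes the variance-component
#' summary, EBV/accuracy table and pseudo-phenotype table.
#'
#' @inheritParams cmd_simulate
#' @return The output directory, invisibly.
#' @export
cmd_blup <- function(cfg) {
  cfg <- as_run_config(cfg)
  dir <- cfg$out_dir
  ph_path <- file.path(dir, "phenotypes.tsv")
  ped_path <- file.path(dir, "pedigree.tsv")
  for (p in c(ph_path, ped_path))
    if (!file.exists(p)) stop_arg("missing input: ", p)
  ph <- read_phenotypes_tsv(ph_path)
  ped <- read_pedigree_tsv(ped_path)
  ph <- filter_outliers_cg(ph, k = cfg$outlier_sd, min_cg = cfg$min_cg)
  fit <- animal_model(value ~ cg + age, ph, ped,
                      n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                      thin = cfg$thin, seed = cfg$seed + 101)
  vc <- summary(fit)$varcomp
  write.table(cbind(parameter = rownames(vc), vc),
              file.path(dir, "varcomp.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ps <- pseudo_phenotypes(fit)
  write.table(data.frame(animal = names(fit$ebv), ebv = unname(fit$ebv),
                         pev = unname(fit$pev),
                         accuracy = ebv_accuracy(unname(fit$pev),
                                                 fit$sigma_a2)),
              file.path(dir, "ebv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ps, file.path(dir, "pseudo_phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sprintf("h2\t%.4f", fit$h2), file.path(dir, "h2.txt"))
  write_manifest(cfg, dir, "blup")
  stage_log("blup: %d records, h2 = %.3f, mean EBV accuracy = %.3f",
            length(fit$y), fit$h2, mean(ebv_weights(fit)))
  invisible(dir)
}

#' Pipeline stage: whole-genome regression on all data
#'
#' Fits the first configured model to the configured response on the full
#' QC-passed matrix and writes marker effects, chain summary and DGV.
#'
#' @inheritParams cmd_simulate
#' @return The output directory, invisibly.
#' @export
cmd_gp <- function(cfg) {
  cfg <- as_run_config(cfg)
  dir <- cfg$out_dir
  inp <- pipeline_wgr_inputs(cfg)
  model <- strsplit(cfg$models, ",")[[1L]][1L]
  response <- strsplit(cfg$responses, ",")[[1L]][1L]
  y <- if (response == "Ystar") inp$pseudo$ystar else inp$pseudo$ebv
  wt <- if (response == "Ystar") inp$pseudo$ystar_weight
        else inp$pseudo$ebv_weight
  fit <- wgr(y, inp$W, model = model, weights = pmax(wt, 1e-6),
             n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
             seed = cfg$seed + 202)
  eff <- data.frame(marker = names(coef(fit)), g_hat = unname(coef(fit)))
  if (!is.null(fit$inclusion_prob))
    eff$inclusion_prob <- unname(fit$inclusion_prob)
  write.table(eff, file.path(dir, "marker_effects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = seq_len(nrow(fit$chains)), fit$chains),
              file.path(dir, "chain_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dgv <- predict(fit, inp$W)
  write.table(data.frame(animal = names(dgv), dgv = unname(dgv)),
              file.path(dir, "dgv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(cfg, dir, "gp")
  stage_log("gp: %s on %s, %d markers", model, response, fit$p)
  invisible(dir)
}

#' Pipeline stage: cross-validated evaluation
#'
#' Runs [run_cv()] for every configured model x response combination and
#' writes the tidy results table (per-fold and aggregated rows including
#' maxr/mean5/mean10) plus a manifest.
#'
#' @inheritParams cmd_simulate
#' @return The results `data.frame`, invisibly.
#' @export
cmd_cv <- function(cfg) {
  cfg <- as_run_config(cfg)
  dir <- cfg$out_dir
  inp <- pipeline_wgr_inputs(cfg)
  h2 <- as.numeric(sub("h2\t", "", readLines(file.path(dir, "h2.txt"))[1L]))
  models <- strsplit(cfg$models, ",")[[1L]]
  responses <- strsplit(cfg$responses, ",")[[1L]]
  G <- vanraden_g(inp$W)
  results <- list()
  for (model in models) for (response in responses) {
    cv <- run_cv(inp$W, inp$pseudo, response_type = response, model = model,
                 h2 = h2, k = cfg$k, seed = cfg$seed + 303,
                 chain = list(n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                              thin = cfg$thin), G = G)
    results[[paste(model, response)]] <- cv_results_table(cv)
    stage_log("cv: %s on %s -> accuracy %.3f", model, response,
              cv$aggregate$accuracy[1L])
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  write.table(out, file.path(dir, "cv_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(cfg, dir, "cv")
  invisible(out)
}

# shared input loader for gp/cv stages
pipeline_wgr_inputs <- function(cfg) {
  dir <- cfg$out_dir
  geno_path <- file.path(dir, "genotypes_qc.tsv")
  ps_path <- file.path(dir, "pseudo_phenotypes.tsv")
  for (p in c(geno_path, ps_path))
    if (!file.exists(p)) stop_arg("missing input: ", p)
  geno <- impute_genotypes(read_geno_tsv(geno_path))
  pseudo <- read.table(ps_path, sep = "\t", header = TRUE,
                       colClasses = c(animal = "character"),
                       stringsAsFactors = FALSE)
  common <- intersect(geno$samples, pseudo$animal)
  list(W = geno$codes[common, , drop = FALSE],
       pseudo = pseudo[match(common, pseudo$animal), ])
}

as_run_config <- function(cfg) {
  if (inherits(cfg, "run_config")) return(cfg)
  if (is.character(cfg)) return(read_run_config(cfg))
  if (is.list(cfg)) {
    base <- default_run_config()
    unknown <- setdiff(names(cfg), names(base))
    if (length(unknown))
      stop_arg("unknown config key: ", paste(unknown, collapse = ", "))
    base[names(cfg)] <- cfg
    return(validate_run_config(base))
  }
  stop_arg("`cfg` must be a run_config, a list, or a file path")
}
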