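# End-to-end orchestration: configuration, staged execution, manifest and
# reporting. Every stochastic stage carries an explicit seed and the
# manifest records the config hash, seeds and per-stage row counts so a
# rerun from the same config is numerically identical.

#' Default pipeline configuration
#'
#' A nested list covering every stage; amend fields and pass to
#' [run_pipeline()]. Round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param seed Master seed; per-stage seeds default to offsets of it.
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    simulate = list(
      enabled = TRUE,
      n_chromosomes = 6L, chromosome_length_cM = 50, markers_per_chromosome = 25L,
      n_lines = 153L, n_intercross_generations = 10L,
      qtl = list(list(chrom = "V", pos_cM = 25, param = "tau", effect = 1.0)),
      sd_line = list(alpha = 0.04, beta = 0.08, tau = 0.5),
      sd_within = 0.05,
      baseline = list(alpha = 0.6, beta = -0.9, tau = 35),
      temps = list(from = 25, to = 41, by = 1),
      n_individuals = 45L,
      floor_offset = 0.08,
      map_seed = seed, geno_seed = seed + 1L, pheno_seed = seed + 2L
    ),
    qc = list(min_per_temperature = 25L, min_per_strain = 40L,
              exceptions = list()),
    fit = list(metric = "li7", half = "hot"),
    traits = list(moving_threshold = 0.1),
    pca = list(enabled = TRUE, n_components = 8L),
    scan = list(
      phenotypes = c("alpha", "beta", "tau"),
      method = "imp", n_imputations = 128L, grid_step = 0.5,
      map_expansion = 3, error_rate = 1e-4,
      n_perm = 1000L, alpha = 0.05 / 12, coverage = 0.95,
      imp_seed = seed + 3L, perm_seed = seed + 4L
    ),
    scantwo = list(enabled = FALSE, min_separation = 5, n_perm = 200L,
                   alpha = 0.05, seed = seed + 5L)
  )
}

#' @rdname default_config
#' @param config Configuration list.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

pipeline_stop <- function(stage, message) {
  stop(structure(class = c("pipeline_error", "error", "condition"),
                 list(message = sprintf("[stage %s] %s", stage, message),
                      call = NULL, stage = stage)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "pipeline_error")) stop(e)
    pipeline_stop(stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load), metrics
#' (normalization), QC, logistic fits, trait table, PCA, single-QTL scans
#' with permutation thresholds, Bayes intervals and heritability, optional
#' two-dimensional scan — writing every intermediate table plus a JSON
#' manifest into `out_dir`. Any stage failure aborts with the stage name in
#' the error.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param assay_table,genotypes,map Optional user-supplied inputs replacing
#'   the simulate stage (all three must be given together with
#'   `config$simulate$enabled = FALSE`).
#' @return Invisibly, a list with the main stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         assay_table = NULL, genotypes = NULL, map = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("tpcmap")),
                   r_version = as.character(getRversion()),
                   config_hash = rlang::hash(config),
                   seed = config$seed, stages = list())
  log_stage <- function(name, rows) {
    manifest$stages[[name]] <<- list(rows = rows,
                                     at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    message(sprintf("stage %-10s rows: %s", name, paste(rows, collapse = "/")))
  }

  # -- simulate ---------------------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    sim <- config$simulate
    run_stage("simulate", {
      map <- simulate_map(sim$n_chromosomes, sim$chromosome_length_cM,
                           sim$markers_per_chromosome, seed = sim$map_seed)
      genotypes <- simulate_ril_genotypes(
        map, sim$n_lines, sim$n_intercross_generations, seed = sim$geno_seed)
      mt <- add_mt_pseudomarkers(genotypes, map)
      genotypes <- mt$genotypes
      map <- mt$map
      qtl_df <- do.call(rbind, lapply(sim$qtl, as.data.frame))
      if (is.null(qtl_df))
        qtl_df <- data.frame(chrom = character(), pos_cM = numeric(),
                             param = character(), effect = numeric())
      spec <- qtl_spec(qtl_df, unlist(sim$sd_line), sim$sd_within)
      assay_table <- simulate_tpc_phenotypes(
        genotypes, map, spec, baseline = unlist(sim$baseline),
        temps = seq(sim$temps$from, sim$temps$to, by = sim$temps$by),
        n_individuals = sim$n_individuals, floor_offset = sim$floor_offset,
        seed = sim$pheno_seed)
    })
    write_genetic_map(map, file.path(out_dir, "map.csv"),
                      comment = sprintf("seed: %d", config$seed))
    write_genotypes(genotypes, file.path(out_dir, "genotypes.csv"),
                    comment = sprintf("seed: %d", config$seed))
    write_assay_table(assay_table, file.path(out_dir, "assay_raw.csv"),
                      comment = sprintf("seed: %d", config$seed))
  } else if (is.null(assay_table) || is.null(genotypes) || is.null(map)) {
    pipeline_stop("simulate",
                  "simulation disabled but assay_table/genotypes/map not supplied")
  }
  log_stage("simulate", nrow(assay_table))

  # -- metrics ----------------------------------------------------------
  normalized <- run_stage("metrics", normalize_assay(assay_table))
  log_stage("metrics", nrow(normalized))

  # -- qc ---------------------------------------------------------------
  qc <- run_stage("qc", qc_filter(normalized,
                                  config$qc$min_per_temperature,
                                  config$qc$min_per_strain,
                                  unlist(config$qc$exceptions)))
  utils::write.csv(qc$report, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  write_assay_table(qc$table, file.path(out_dir, "assay_qc.csv"))
  log_stage("qc", nrow(qc$table))

  # -- fit --------------------------------------------------------------
  fits <- run_stage("fit", {
    if (!nrow(qc$table)) stop("no strains left after QC; nothing to fit")
    fit_strains(qc$table, metric = config$fit$metric, half = config$fit$half)
  })
  write_fit_results(fits, csv_path = file.path(out_dir, "fits.csv"),
                    json_path = file.path(out_dir, "fits.json"))
  log_stage("fit", nrow(attr(fits, "summary")))

  # -- trait table ------------------------------------------------------
  traits <- run_stage("traits",
                      build_trait_table(qc$table, fits,
                                        moving_threshold = config$traits$moving_threshold))
  utils::write.csv(data.frame(strain = rownames(traits$table), traits$table,
                              check.names = FALSE),
                   file.path(out_dir, "trait_table.csv"), row.names = FALSE)
  log_stage("traits", dim(traits$table))

  # -- pca --------------------------------------------------------------
  pca <- NULL
  if (isTRUE(config$pca$enabled)) {
    pca <- run_stage("pca", pca_scaled(traits$table, config$pca$n_components))
    utils::write.csv(data.frame(strain = rownames(pca$scores), pca$scores),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(metric = rownames(pca$loadings), pca$loadings),
                     file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
    log_stage("pca", nrow(pca$scores))
  }

  # -- scans ------------------------------------------------------------
  sc <- config$scan
  scan_results <- run_stage("scan", {
    fit_summ <- attr(fits, "summary")
    keep_lines <- intersect(genotypes$line_ids, fit_summ$strain)
    gsub <- genotypes
    gsub$calls <- gsub$calls[keep_lines, , drop = FALSE]
    gsub$line_ids <- keep_lines
    gsub$cross_direction <- genotypes$cross_direction[
      match(keep_lines, genotypes$line_ids)]
    grid <- build_grid(map, sc$grid_step)
    gp <- genotype_probabilities(gsub, map, grid, sc$error_rate,
                                 sc$map_expansion)
    imp <- if (identical(sc$method, "imp"))
      impute_genotypes(gsub, map, grid, sc$n_imputations, sc$error_rate,
                       sc$map_expansion, seed = sc$imp_seed) else NULL
    out <- list(geno_prob = gp, scans = list())
    for (ph in sc$phenotypes) {
      y <- stats::setNames(fit_summ[[ph]], fit_summ$strain)[keep_lines]
      prof <- scanone(y, gp, method = sc$method, imputations = imp)
      thr <- permutation_threshold(y, gp, n_perm = sc$n_perm,
                                   alpha = sc$alpha, seed = sc$perm_seed)
      pk <- peak_lod(prof)
      ci <- bayes_interval(prof, pk$chrom, sc$coverage)
      out$scans[[ph]] <- list(
        profile = prof, threshold = thr$threshold, peak = pk, interval = ci,
        h2 = heritability_from_lod(pk$lod, length(keep_lines)),
        significant = pk$lod > thr$threshold)
      utils::write.csv(prof, file.path(out_dir, sprintf("lod_%s.csv", ph)),
                       row.names = FALSE)
    }
    out
  })
  qtl_summary <- do.call(rbind, lapply(names(scan_results$scans), function(ph) {
    s <- scan_results$scans[[ph]]
    data.frame(phenotype = ph, chrom = s$peak$chrom, pos_cM = s$peak$pos_cM,
               lod = s$peak$lod, threshold = s$threshold,
               significant = s$significant, ci_lo = s$interval$lo,
               ci_hi = s$interval$hi, h2 = s$h2, stringsAsFactors = FALSE)
  }))
  utils::write.csv(qtl_summary, file.path(out_dir, "qtl_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(qtl_summary, file.path(out_dir, "qtl_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("scan", nrow(qtl_summary))

  # -- scantwo ----------------------------------------------------------
  st <- NULL
  if (isTRUE(config$scantwo$enabled)) {
    st <- run_stage("scantwo", {
      fit_summ <- attr(fits, "summary")
      keep_lines <- intersect(genotypes$line_ids, fit_summ$strain)
      ph <- sc$phenotypes[[1]]
      y <- stats::setNames(fit_summ[[ph]], fit_summ$strain)[keep_lines]
      s2 <- scantwo(y, scan_results$geno_prob, config$scantwo$min_separation)
      thr <- scantwo_permutations(y, scan_results$geno_prob,
                                  config$scantwo$min_separation,
                                  n_perm = config$scantwo$n_perm,
                                  alpha = config$scantwo$alpha,
                                  seed = config$scantwo$seed)
      list(result = s2, thresholds = thr)
    })
    utils::write.csv(scantwo_table(st$result),
                     file.path(out_dir, "scantwo.csv"), row.names = FALSE)
    log_stage("scantwo", nrow(st$result$positions))
  }

  manifest$stages_run <- names(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(map = map, genotypes = genotypes, assay = qc$table,
                 fits = fits, traits = traits, pca = pca,
                 scans = scan_results$scans, scantwo = st,
                 qtl_summary = qtl_summary, manifest = manifest,
                 out_dir = out_dir))
}

#' Render summary plots and tables from a completed run
#'
#' Produces the static report artifacts of a run directory: TPC curves with
#' logistic fits for example strains, LOD profiles with thresholds and
#' credible intervals, and a PCA variance table. Missing stage outputs are
#' listed as unavailable; the report is still produced.
#'
#' @param run A result of [run_pipeline()] (or a run directory path
#'   containing its CSV outputs).
#' @param out_dir Directory for report files (defaults to the run
#'   directory).
#' @return Character vector of files written.
#' @export
report_run <- function(run, out_dir = NULL) {
  if (is.character(run)) {
    dirpath <- run
    run <- NULL
  } else dirpath <- run$out_dir
  if (is.null(out_dir)) out_dir <- dirpath
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  unavailable <- character(0)

  fits_path <- file.path(dirpath, "fits.csv")
  assay_path <- file.path(dirpath, "assay_qc.csv")
  if (file.exists(fits_path) && file.exists(assay_path)) {
    fits <- utils::read.csv(fits_path)
    assay <- read_assay_table(assay_path)
    pick <- utils::head(fits$strain[order(-fits$tau)], 4)
    means <- stats::aggregate(li7 ~ strain + assay_temp,
                              assay[assay$strain %in% pick, ], mean)
    curves <- do.call(rbind, lapply(pick, function(s) {
      fr <- fits[fits$strain == s, ]
      tg <- seq(min(means$assay_temp), max(means$assay_temp), length.out = 100)
      data.frame(strain = s, assay_temp = tg,
                 li7 = logistic_tpc(tg, fr$alpha, fr$beta, fr$tau))
    }))
    p <- ggplot2::ggplot(means, ggplot2::aes(.data$assay_temp, .data$li7,
                                             color = .data$strain)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(data = curves) +
      ggplot2::labs(x = "assay temperature (°C)",
                    y = "normalized locomotion index (LI7)",
                    title = "Strain-mean TPCs with logistic fits") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, "tpc_fits.pdf")
    ggplot2::ggsave(f, p, width = 7, height = 5)
    written <- c(written, f)
  } else unavailable <- c(unavailable, "fits/assay")

  qtl_path <- file.path(dirpath, "qtl_summary.csv")
  lod_files <- list.files(dirpath, "^lod_.*\\.csv$", full.names = TRUE)
  if (file.exists(qtl_path) && length(lod_files)) {
    qtl <- utils::read.csv(qtl_path)
    profs <- do.call(rbind, lapply(lod_files, function(f) {
      d <- utils::read.csv(f)
      d$phenotype <- sub("^lod_(.*)\\.csv$", "\\1", basename(f))
      d
    }))
    profs$chrom <- factor(profs$chrom, unique(profs$chrom))
    p <- ggplot2::ggplot(profs, ggplot2::aes(.data$pos_cM, .data$lod,
                                             color = .data$phenotype)) +
      ggplot2::geom_line() +
      ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
      ggplot2::geom_hline(data = qtl,
                          ggplot2::aes(yintercept = .data$threshold,
                                       color = .data$phenotype),
                          linetype = "dashed") +
      ggplot2::labs(x = "position (cM)", y = "LOD",
                    title = "Genome scans with permutation thresholds") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, "lod_profiles.pdf")
    ggplot2::ggsave(f, p, width = 9, height = 4)
    written <- c(written, f)
  } else unavailable <- c(unavailable, "qtl scans")

  summary_lines <- c("run report",
                     sprintf("written: %s", paste(basename(written),
                                                  collapse = ", ")),
                     if (length(unavailable))
                       sprintf("unavailable: %s",
                               paste(unavailable, collapse = ", ")))
  f <- file.path(out_dir, "report.txt")
  writeLines(summary_lines, f)
  c(written, f)
}
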