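## One entry point orchestrating simulate -> pi -> downstream analyses
## with a config, deterministic seeding, a manifest, and skip-if-current
## reruns.

#' Build and validate a pipeline configuration
#'
#' Defaults define a complete synthetic study at desk scale. Values can
#' be overridden by arguments or loaded from a plain key=value text file
#' (\code{config_file}); explicit arguments win over the file.
#'
#' @param out Output directory.
#' @param seed Integer master seed; every stage derives its RNG stream
#'   from it and it is recorded in every output header.
#' @param n_genes,depth,n_cells,n_timepoints Synthetic-data sizes.
#' @param pi_threshold,fpkm_min,tssr_floor,h3k4me3_fold,fold_change
#'   Analysis thresholds (all must be positive).
#' @param kmer_k K-mer length for the promoter scan.
#' @param config_file Optional key=value file (one pair per line,
#'   \code{#} comments allowed).
#' @param ... Further overrides of any default.
#' @return list of class \code{pause_config}.
#' @export
pause_config <- function(out = "pausekit_run", seed = 1,
                         n_genes = 300, depth = 2e5, n_cells = 60,
                         n_timepoints = 4,
                         pi_threshold = 2, fpkm_min = 1,
                         tssr_floor = 0.001, h3k4me3_fold = 4,
                         fold_change = 2, kmer_k = 5,
                         config_file = NULL, ...) {
  supplied <- intersect(names(match.call())[-1L],
                        setdiff(names(formals()), c("config_file", "...")))
  cfg <- list(out = out, seed = seed, n_genes = n_genes, depth = depth,
              n_cells = n_cells, n_timepoints = n_timepoints,
              pi_threshold = pi_threshold, fpkm_min = fpkm_min,
              tssr_floor = tssr_floor, h3k4me3_fold = h3k4me3_fold,
              fold_change = fold_change, kmer_k = kmer_k)
  if (!is.null(config_file)) {
    lines <- readLines(config_file)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1L]); val <- trimws(kv[2L])
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- if (key == "out") val else as.numeric(val)
    }
  }
  # explicitly supplied arguments win over the config file
  explicit <- mget(supplied)
  dots <- list(...)
  for (key in names(dots)) {
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
  }
  for (key in names(explicit)) cfg[[key]] <- explicit[[key]]
  for (key in names(dots)) cfg[[key]] <- dots[[key]]
  numeric_keys <- c("pi_threshold", "fpkm_min", "tssr_floor",
                    "h3k4me3_fold", "fold_change")
  for (key in numeric_keys) {
    if (!is.finite(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("config: ", key, " must be positive")
    }
  }
  if (cfg$n_genes < 10) stop("config: n_genes must be >= 10")
  if (cfg$depth < 1000) stop("config: depth must be >= 1000")
  class(cfg) <- "pause_config"
  cfg
}

write_tsv_stage <- function(df, path, seed, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pausekit ", stage, "; seed=", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Stages, in dependency order: \code{simulate} (annotation, RNAP2
#' ChIP/input and H3K4me3 libraries, bulk/single-cell/time-course
#' expression), \code{pi} (the pausing-index table), \code{kmers}
#' (promoter k-mer enrichment), \code{expression} (overlap, trend, CV,
#' response labels, PI-shift tests), \code{landscape} (hexbin, trend,
#' inflection) and \code{chromatin} (mark enrichments, linear model,
#' profile, density-change labels). Each stage writes TSVs carrying the
#' seed in a header comment; a manifest records every output with its
#' producing stage. When the output directory already holds a manifest
#' produced from an identical configuration, stages whose outputs exist
#' are skipped.
#'
#' @param config A \code{\link{pause_config}}.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest data.frame (file, stage, skipped).
#' @export
run_pipeline <- function(config = pause_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pause_config"))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say <- function(...) if (!quiet) message("[pausekit] ", ...)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  cfg_path <- file.path(out, "config.json")
  unchanged <- file.exists(cfg_path) &&
    identical(paste(readLines(cfg_path), collapse = ""),
              as.character(cfg_json))
  writeLines(as.character(cfg_json), cfg_path)

  manifest <- list()
  # manifest paths are relative to the output directory so reruns in
  # different locations stay byte-identical
  note <- function(files, stage, skipped) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(files), stage = stage, skipped = skipped,
      stringsAsFactors = FALSE)
  }
  stage_files <- function(...) file.path(out, c(...))
  current <- function(files) unchanged && all(file.exists(files))

  ## --- simulate ---------------------------------------------------------
  ann <- generate_annotation(config$n_genes, seed = seed)
  genes <- ann$genes
  set.seed(seed + 1L)
  planted_pi <- exp(stats::runif(nrow(genes), log(0.25), log(32)))
  libs <- simulate_chip_library(genes, planted_pi, depth = config$depth,
                                chrom_length = ann$chrom_length,
                                seed = seed + 2L)
  k4 <- simulate_mark_library(genes, weight = 1,
                              depth = max(round(config$depth / 4), 1000),
                              chrom_length = ann$chrom_length,
                              seed = seed + 3L)
  sim_out <- stage_files("genes.bed", "truth.tsv")
  if (!current(sim_out)) {
    write_gene_models(genes, file.path(out, "genes.bed"))
    truth <- ann$truth
    truth$planted_pi <- planted_pi
    write_tsv_stage(truth, file.path(out, "truth.tsv"), seed, "simulate")
    note(sim_out, "simulate", FALSE)
    say("simulate: ", nrow(genes), " genes, ", config$depth, " reads")
  } else {
    note(sim_out, "simulate", TRUE)
    say("simulate: up to date, skipped")
  }

  ## --- pi ---------------------------------------------------------------
  pt <- pause_index(genes, libs$chip, libs$input,
                    h3k4me3 = k4$chip, h3k4me3_input = k4$input,
                    pi_threshold = config$pi_threshold,
                    tssr_floor = config$tssr_floor,
                    h3k4me3_fold = config$h3k4me3_fold)
  pi_out <- stage_files("pi.tsv")
  if (!current(pi_out)) {
    write_tsv_stage(as.data.frame(pt), file.path(out, "pi.tsv"), seed, "pi")
    note(pi_out, "pi", FALSE)
    say("pi: ", sum(!is.na(pt$pi)), " genes with assigned PI, ",
        sum(pt$paused), " paused")
  } else {
    note(pi_out, "pi", TRUE)
  }

  ## --- kmers ------------------------------------------------------------
  proms <- ann$promoters[pt$gene_id]
  paused_ids <- pt$gene_id[pt$paused]
  other_ids <- setdiff(pt$gene_id, paused_ids)
  km_out <- stage_files("kmers.tsv")
  if (!current(km_out)) {
    km <- kmer_enrichment(proms[paused_ids], proms[other_ids],
                          k = config$kmer_k)
    write_tsv_stage(as.data.frame(km), file.path(out, "kmers.tsv"),
                    seed, "kmers")
    note(km_out, "kmers", FALSE)
    say("kmers: top = ", km$kmer[1L])
  } else {
    note(km_out, "kmers", TRUE)
  }

  ## --- expression -------------------------------------------------------
  expr_out <- stage_files("overlap.tsv", "trend.tsv", "cv_by_quantile.tsv",
                          "response_labels.tsv", "shift_tests.tsv")
  # couple bulk FPKM to planted pausing: hill-shaped around log10 PI = 0.5
  set.seed(seed + 4L)
  hill <- 2.5 - 1.2 * (log10(planted_pi) - 0.5)^2
  fpkm <- 10^(hill / 2.5 + stats::rnorm(nrow(genes), 0, 0.35))
  names(fpkm) <- genes$gene_id
  cells <- simulate_expression(pt$gene_id, "single_cell",
                               n_cells = config$n_cells,
                               cv_group = ifelse(pt$paused, "low", "high"),
                               seed = seed + 5L)
  tc <- simulate_expression(pt$gene_id, "time_course", seed = seed + 6L)
  if (!current(expr_out)) {
    ov <- expressed_paused_overlap(pt$pi, fpkm[pt$gene_id],
                                   fpkm_min = config$fpkm_min,
                                   pi_threshold = config$pi_threshold)
    write_tsv_stage(data.frame(expressed = ov$expressed,
                               expressed_paused = ov$expressed_paused,
                               all = ov$all),
                    file.path(out, "overlap.tsv"), seed, "expression")
    tr <- pi_expression_trend(pt$pi, fpkm[pt$gene_id])
    write_tsv_stage(tr$grid, file.path(out, "trend.tsv"), seed, "expression")
    cvres <- single_cell_cv(cells, pt$paused, fpkm_min = config$fpkm_min)
    write_tsv_stage(cvres, file.path(out, "cv_by_quantile.tsv"),
                    seed, "expression")
    labels <- classify_response(tc, fold = config$fold_change,
                                fpkm_min = config$fpkm_min)
    write_tsv_stage(labels, file.path(out, "response_labels.tsv"),
                    seed, "expression")
    pi_by_time <- matrix(rep(pt$pi, ncol(tc)), ncol = ncol(tc),
                         dimnames = list(pt$gene_id, colnames(tc)))
    shifts <- pi_shift_test(pi_by_time, labels, seed = seed + 7L)
    write_tsv_stage(shifts, file.path(out, "shift_tests.tsv"),
                    seed, "expression")
    note(expr_out, "expression", FALSE)
    say("expression: ", ov$expressed_paused, "/", ov$expressed,
        " expressed genes paused")
  } else {
    note(expr_out, "expression", TRUE)
  }

  ## --- landscape --------------------------------------------------------
  land_out <- stage_files("hexbin.tsv", "landscape_trend.tsv",
                          "inflection.tsv")
  if (!current(land_out)) {
    okd <- !is.na(pt$tssr_density) & pt$tssr_density > 0 &
      !is.na(pt$gb_density) & pt$gb_density > 0
    hb <- hexbin_summary(log10(pt$tssr_density[okd]),
                         log10(pt$gb_density[okd]),
                         z = log10(pmax(fpkm[pt$gene_id][okd], 1e-3)))
    write_tsv_stage(hb, file.path(out, "hexbin.tsv"), seed, "landscape")
    if (sum(okd) >= 100L) {
      dtr <- fit_density_trend(pt$tssr_density, pt$gb_density)
      write_tsv_stage(predict(dtr), file.path(out, "landscape_trend.tsv"),
                      seed, "landscape")
      infl <- find_inflection(dtr)
      infl_df <- data.frame(x_star = infl$x_star,
                            curvature = infl$curvature,
                            low_curvature = infl$low_curvature)
    } else {
      # too few genes for a stable trend: record the gap, keep the run
      write_tsv_stage(data.frame(x = numeric(0), y = numeric(0)),
                      file.path(out, "landscape_trend.tsv"),
                      seed, "landscape")
      infl_df <- data.frame(x_star = NA_real_, curvature = NA_real_,
                            low_curvature = NA)
    }
    write_tsv_stage(infl_df, file.path(out, "inflection.tsv"),
                    seed, "landscape")
    note(land_out, "landscape", FALSE)
    say("landscape: inflection at log10 TSSR density ",
        format(infl$x_star, digits = 3))
  } else {
    note(land_out, "landscape", TRUE)
  }

  ## --- chromatin --------------------------------------------------------
  chrom_out <- stage_files("enrichment.tsv", "model_coefficients.tsv",
                           "profile.tsv", "change_labels.tsv")
  if (!current(chrom_out)) {
    # two synthetic marks: one tracking pausing, one independent
    w1 <- planted_pi / mean(planted_pi)
    m1 <- simulate_mark_library(genes, weight = w1,
                                depth = max(round(config$depth / 4), 1000),
                                chrom_length = ann$chrom_length,
                                seed = seed + 8L)
    set.seed(seed + 9L)
    w2 <- stats::rlnorm(nrow(genes), 0, 0.5)
    m2 <- simulate_mark_library(genes, weight = w2,
                                depth = max(round(config$depth / 4), 1000),
                                chrom_length = ann$chrom_length,
                                seed = seed + 10L)
    enr <- enrichment_table(genes, list(mark_pi = m1, mark_null = m2))
    write_tsv_stage(data.frame(gene_id = rownames(enr), enr),
                    file.path(out, "enrichment.tsv"), seed, "chromatin")
    lmfit <- fit_pi_linear_model(enr[pt$gene_id, , drop = FALSE], pt$pi)
    write_tsv_stage(data.frame(term = names(lmfit$coefficients),
                               beta = unname(lmfit$coefficients),
                               r_squared = lmfit$r_squared, n = lmfit$n),
                    file.path(out, "model_coefficients.tsv"),
                    seed, "chromatin")
    top_q <- pt[!is.na(pt$pi) & pt$pi >= stats::quantile(pt$pi, 0.75,
                                                         na.rm = TRUE), ]
    prof <- tss_profile(libs$chip,
                        genes[genes$gene_id %in% top_q$gene_id, ])
    write_tsv_stage(prof, file.path(out, "profile.tsv"), seed, "chromatin")
    # knockdown contrast: halve pausing, re-estimate, classify changes
    libs2 <- simulate_chip_library(genes, pmax(planted_pi / 2, 0.05),
                                   depth = config$depth,
                                   chrom_length = ann$chrom_length,
                                   seed = seed + 11L)
    pt2 <- pause_index(genes, libs2$chip, libs2$input,
                       h3k4me3 = k4$chip, h3k4me3_input = k4$input,
                       pi_threshold = config$pi_threshold,
                       tssr_floor = config$tssr_floor,
                       h3k4me3_fold = config$h3k4me3_fold)
    changes <- classify_density_change(pt, pt2, fold = config$fold_change)
    write_tsv_stage(changes, file.path(out, "change_labels.tsv"),
                    seed, "chromatin")
    note(chrom_out, "chromatin", FALSE)
    say("chromatin: model R^2 = ", format(lmfit$r_squared, digits = 3))
  } else {
    note(chrom_out, "chromatin", TRUE)
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
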