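# End-to-end orchestration: simulate -> profile -> screen -> filter ->
# summarize, as one reproducible run with a flat config, per-stage logging
# and a manifest. Every stage output is a pure function of its declared
# inputs and the seed; the same seed yields byte-identical TSVs.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    # generator
    n_species = 2L, genome_length = 5000L, genes_per_genome = 6L,
    mean_depth = 150, error_rate = 0, n_replicates = 6L,
    planted_induced = 8L, planted_artifact = 5L, planted_natural = 5L,
    induced_allele_freq = 0.6, transition_bias = 2,
    focal_species = "Lp082", correlation_design = "positive,negative",
    n_filler_species = 4L, abundance_noise = 0.3,
    # caller (emulated tool defaults: -c 100 -f 0.49)
    min_coverage = 100L, min_freq = 0.49, min_alt_count = 1L,
    # screen
    screen_p = 0.05, screen_rho = 0.5,
    # filter
    aggregation = "union", stage1_scope = "all_days",
    log_level = "info"
  )
}

pipeline_ranges <- function() {
  list(
    seed = function(v) v >= 0 && v < 2^31 - 2000,
    n_species = function(v) v >= 1,
    genome_length = function(v) v >= 1000,
    genes_per_genome = function(v) v >= 1,
    mean_depth = function(v) v > 0,
    error_rate = function(v) v >= 0 && v < 0.25,
    n_replicates = function(v) v >= 1,
    planted_induced = function(v) v >= 0,
    planted_artifact = function(v) v >= 0,
    planted_natural = function(v) v >= 0,
    induced_allele_freq = function(v) v > 0 && v <= 1,
    transition_bias = function(v) v > 0,
    min_coverage = function(v) v >= 1,
    min_freq = function(v) v > 0 && v <= 1,
    min_alt_count = function(v) v >= 1,
    screen_p = function(v) v > 0 && v < 1,
    screen_rho = function(v) v >= 0 && v < 1,
    n_filler_species = function(v) v >= 0,
    abundance_noise = function(v) v >= 0,
    aggregation = function(v) v %in% c("union", "majority", "intersection"),
    stage1_scope = function(v) v %in% c("all_days", "day_matched"),
    focal_species = function(v) is.character(v) && nzchar(v),
    correlation_design = function(v) is.character(v) &&
      all(strsplit(v, ",")[[1]] %in% c("positive", "negative", "none")),
    log_level = function(v) v %in% c("info", "quiet")
  )
}

#' Validate and normalize a pipeline run configuration
#'
#' Accepts a YAML file path or a named list. Unknown keys are rejected by
#' name; missing keys are filled with defaults (caller thresholds 100 and
#' 0.49, screen thresholds p < 0.05 and |rho| > 0.5); type/range violations
#' are reported all at once.
#'
#' @param config YAML file path or named list of overrides.
#' @return Normalized config list of class `run_config`, with attribute
#'   `overridden` naming every key the user set explicitly.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    src <- config
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
    attr(config, "source") <- src
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  ranges <- pipeline_ranges()
  merged <- defaults
  for (k in intersect(names(config), names(defaults))) {
    v <- config[[k]]
    if (length(v) != 1L) {
      errs <- c(errs, paste0(k, ": must be a single value"))
      next
    }
    if (is.numeric(defaults[[k]]) && !is.numeric(v)) {
      errs <- c(errs, paste0(k, ": must be numeric"))
      next
    }
    if (!ranges[[k]](v)) {
      errs <- c(errs, paste0(k, ": value ", v, " out of range"))
      next
    }
    merged[[k]] <- if (is.integer(defaults[[k]])) as.integer(v) else v
  }
  cd <- strsplit(merged$correlation_design, ",")[[1]]
  if (length(cd) != merged$n_species)
    errs <- c(errs, sprintf(
      "correlation_design: %d entries for n_species = %d",
      length(cd), merged$n_species))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(merged, class = "run_config",
            overridden = intersect(names(config), names(defaults)),
            source = attr(config, "source"))
}

run_config_to_sim <- function(config) {
  sim_config(seed = config$seed, n_species = config$n_species,
             genome_length = config$genome_length,
             genes_per_genome = config$genes_per_genome,
             mean_depth = config$mean_depth, error_rate = config$error_rate,
             n_replicates = config$n_replicates,
             planted_counts = c(induced = config$planted_induced,
                                artifact = config$planted_artifact,
                                natural = config$planted_natural),
             induced_allele_freq = config$induced_allele_freq,
             transition_bias = config$transition_bias,
             focal_species = config$focal_species,
             correlation_design = strsplit(config$correlation_design,
                                           ",")[[1]],
             n_filler_species = config$n_filler_species,
             abundance_noise = config$abundance_noise)
}

#' Run the full pipeline
#'
#' Stages: simulate (genomes, pileups, abundance, metadata, truth) ->
#' profile (per-sample SNV calling + classification) -> screen (taxa
#' correlated with the focal probiotic, per segment) -> filter (two-stage
#' provenance filter) -> summarize (count matrix, mutation breakdown,
#' substitution spectrum, position track, SNV-vs-abundance regression).
#' All outputs land under `out_dir`; `manifest.yaml` records the package
#' version, the seed, the full effective config, which keys were
#' overridden, and per-stage row counts. A stage failure aborts with the
#' stage name in the error.
#'
#' @param config A `run_config` from [validate_config()], a YAML path, or a
#'   named list of overrides.
#' @param out_dir Output directory (created; must not require parents).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  t0 <- Sys.time()
  log_msg <- function(...) if (config$log_level != "quiet")
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  log_msg("stage simulate: seed %d, %d species x %d bp",
          config$seed, config$n_species, config$genome_length)
  sim <- stage("simulate", {
    simulate_dataset(run_config_to_sim(config), out_dir)
  })
  counts$planted_variants <- nrow(sim$truth)

  log_msg("stage profile: calling SNVs in %d samples", nrow(sim$design))
  params <- caller_params(config$min_coverage, config$min_freq,
                          config$min_alt_count)
  snv_dir <- file.path(out_dir, "snvs")
  dir.create(snv_dir, showWarnings = FALSE)
  records <- stage("profile", {
    recs <- vector("list", nrow(sim$design))
    for (i in seq_len(nrow(sim$design))) {
      sid <- sim$design$sample_id[i]
      pile <- read_pileup(sim$paths$pileups[[sid]])
      per_sp <- lapply(sim$genomes, function(g) {
        sub <- pile[pile$contig %in% names(g$contigs), , drop = FALSE]
        annotate_snvs(sub, g, params)
      })
      r <- do.call(rbind, per_sp)
      r$sample_id <- rep(sid, nrow(r))
      r <- r[, c("sample_id", setdiff(names(r), "sample_id"))]
      rownames(r) <- NULL
      write_snv_table(r, file.path(snv_dir, paste0(sid, ".SNVs.tsv")))
      recs[[i]] <- r
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
  counts$called_records <- nrow(records)

  log_msg("stage screen: focal %s", config$focal_species)
  edges <- stage("screen", {
    out <- list()
    for (seg in c("small", "large")) {
      e <- screen_taxa(sim$abundance, sim$design, config$focal_species,
                       segment = seg, p_max = config$screen_p,
                       rho_min = config$screen_rho)
      edge_table_export(e, file.path(out_dir,
                                     sprintf("edges_%s.tsv", seg)))
      out[[seg]] <- e
    }
    out
  })
  counts$edges_small <- nrow(edges$small)
  counts$edges_large <- nrow(edges$large)

  log_msg("stage filter: %s aggregation, stage-1 scope %s",
          config$aggregation, config$stage1_scope)
  filt <- stage("filter", {
    filter_induced_snvs(records, sim$design, mode = config$aggregation,
                        stage1_scope = config$stage1_scope)
  })
  filtered_dir <- file.path(out_dir, "filtered")
  dir.create(filtered_dir, showWarnings = FALSE)
  ret <- filt$retained
  ret_tsv <- ret
  if (nrow(ret_tsv))
    ret_tsv <- ret_tsv[, c(SNV_TSV_COLUMNS), drop = FALSE]
  else ret_tsv <- empty_snv_records()
  write_snv_table(ret_tsv, file.path(filtered_dir, "induced.SNVs.tsv"))
  write_filter_report(filt$report, file.path(filtered_dir,
                                             "filter_report.tsv"))
  counts$retained_induced <- nrow(ret)

  log_msg("stage summarize")
  summaries <- stage("summarize", {
    sp <- species_ids(run_config_to_sim(config))
    cm <- snv_count_matrix(ret, sp)
    bd <- mutation_breakdown(ret, species = sp)
    spec <- substitution_spectrum(ret)
    track <- position_frequency_track(ret)
    sum_dir <- file.path(out_dir, "summary")
    dir.create(sum_dir, showWarnings = FALSE)
    fwrite(data.frame(species_id = rownames(cm), cm, check.names = FALSE),
           file.path(sum_dir, "counts.tsv"), sep = "\t")
    bd_out <- bd
    for (cc in grep("^prop_", names(bd_out), value = TRUE))
      bd_out[[cc]] <- ifelse(is.na(bd_out[[cc]]), ".",
                             sprintf("%.6f", bd_out[[cc]]))
    fwrite(bd_out, file.path(sum_dir, "breakdown.tsv"), sep = "\t")
    fwrite(data.frame(substitution = names(spec$counts),
                      count = as.integer(spec$counts)),
           file.path(sum_dir, "spectrum.tsv"), sep = "\t")
    fwrite(data.frame(
      transitions = spec$transitions, transversions = spec$transversions,
      titv = if (is.na(spec$titv)) "." else sprintf("%.6f", spec$titv)),
      file.path(sum_dir, "spectrum_summary.tsv"), sep = "\t")
    track_out <- track
    if (nrow(track_out))
      track_out$allele_freq <- sprintf("%.6f", track_out$allele_freq)
    fwrite(track_out, file.path(sum_dir, "position_track.tsv"), sep = "\t")
    # SNV count vs abundance: one point per (species, segment, day) cell,
    # x = mean treatment-arm relative abundance in that cell
    reg <- NULL
    if (nrow(filt$report) >= 3L) {
      ab <- sim$abundance
      x <- numeric(nrow(filt$report))
      for (i in seq_len(nrow(filt$report))) {
        m <- sim$design
        sel <- m$sample_id[m$group == "treatment" &
                           m$segment == filt$report$segment[i] &
                           m$day == filt$report$day[i]]
        x[i] <- mean(ab[filt$report$species_id[i], sel])
      }
      if (var(x) > 0) {
        reg <- abundance_snv_regression(filt$report$n_retained, x)
        fwrite(data.frame(slope = reg$slope, intercept = reg$intercept,
                          r_squared = reg$r_squared, p_slope = reg$p_slope,
                          n = reg$n),
               file.path(sum_dir, "regression.tsv"), sep = "\t")
      }
    }
    list(count_matrix = cm, breakdown = bd, spectrum = spec,
         regression = reg)
  })

  manifest <- list(
    package = "probiosnv",
    version = as.character(packageVersion("probiosnv")),
    seed = config$seed,
    config = unclass(config)[order(names(unclass(config)))],
    overridden_keys = as.list(attr(config, "overridden") %||% character()),
    config_file_md5 = if (!is.null(attr(config, "source")))
      unname(tools::md5sum(attr(config, "source"))) else NULL,
    stage_counts = counts,
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                        2)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  log_msg("done in %.1f s", manifest$elapsed_sec)
  invisible(list(config = config, simulation = sim, records = records,
                 edges = edges, filter = filt, summaries = summaries,
                 manifest = manifest))
}
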