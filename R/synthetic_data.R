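# Synthetic metagenomic study generator.
#
# Emulates the full 2-group x 2-segment x 3-day x n-replicate design with
# planted SNVs of three provenance classes:
#   induced  - present only in treatment samples of their segment (all days),
#   artifact - reference-selection artifacts, present in every sample of
#              their segment (both groups, all days),
#   natural  - temporal variation, present in both groups of their segment
#              on one designated day.
# Pileups carry Poisson(mean_depth) coverage; at a variant site present in a
# sample, alternate reads are Binomial(depth, planted allele frequency).
# Everything is deterministic given the config seed: each stage and each
# sample derives its own fixed sub-seed, so any sample's pileup can be
# regenerated in isolation.

#' Simulation configuration
#'
#' Defaults encode the study design the package targets: two arms of six
#' replicates ("six mice from each group"), two intestinal segments, days
#' 1/3/7 after a single gavage, ~150x coverage, and a planted-variant allele
#' frequency of 0.6 (above the 0.49 calling threshold).
#'
#' @param seed Integer master seed; all stage/sample seeds derive from it.
#' @param n_species Number of reference genomes to simulate.
#' @param genome_length Genome length in bp per species.
#' @param genes_per_genome Number of non-overlapping CDS genes per genome
#'   (two RNA genes are added on top).
#' @param mean_depth Expected reads per site (Poisson mean).
#' @param error_rate Per-base miscall probability in `[0, 0.25)`.
#' @param n_replicates Replicates per (group, segment, day) cell.
#' @param planted_counts Named integer vector `c(induced=, artifact=,
#'   natural=)`: planted SNVs per species and provenance class.
#' @param induced_allele_freq Allele frequency of planted variants in the
#'   samples carrying them, in `(0, 1]`.
#' @param transition_bias Transition:transversion odds used when drawing
#'   alternate bases (default 2, i.e. 2:1, so spectra are testably
#'   transition-heavy).
#' @param focal_species Name of the focal probiotic taxon in the abundance
#'   table.
#' @param correlation_design Character vector over
#'   `{"positive","negative","none"}`, one per species, giving each species'
#'   engineered relation to the focal taxon.
#' @param n_filler_species Additional independent ("none") background taxa
#'   in the abundance table.
#' @param abundance_noise Log-normal noise sd on abundances (0 = exact
#'   monotone relations).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 5L,
                       genome_length = 50000L,
                       genes_per_genome = 40L,
                       mean_depth = 150,
                       error_rate = 0,
                       n_replicates = 6L,
                       planted_counts = c(induced = 30L, artifact = 15L,
                                          natural = 15L),
                       induced_allele_freq = 0.6,
                       transition_bias = 2,
                       focal_species = "Lp082",
                       correlation_design = NULL,
                       n_filler_species = 5L,
                       abundance_noise = 0.3) {
  if (is.null(correlation_design)) {
    correlation_design <- rep(c("positive", "positive", "negative", "none"),
                              length.out = n_species)
  }
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              genome_length = as.integer(genome_length),
              genes_per_genome = as.integer(genes_per_genome),
              mean_depth = mean_depth, error_rate = error_rate,
              n_replicates = as.integer(n_replicates),
              planted_counts = planted_counts,
              induced_allele_freq = induced_allele_freq,
              transition_bias = transition_bias,
              focal_species = focal_species,
              correlation_design = correlation_design,
              n_filler_species = as.integer(n_filler_species),
              abundance_noise = abundance_noise)
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(cfg$seed >= 0 && cfg$seed < 2^31 - 1000, "seed out of range")
  chk(cfg$n_species >= 1, "n_species must be >= 1")
  chk(cfg$genome_length >= 1000, "genome_length must be >= 1000")
  chk(cfg$genes_per_genome >= 1, "genes_per_genome must be >= 1")
  chk(cfg$mean_depth > 0, "mean_depth must be positive")
  chk(cfg$error_rate >= 0 && cfg$error_rate < 0.25,
      "error_rate must be in [0, 0.25)")
  chk(cfg$n_replicates >= 1, "n_replicates must be >= 1")
  chk(all(c("induced", "artifact", "natural") %in% names(cfg$planted_counts)),
      "planted_counts must name induced, artifact, natural")
  chk(all(cfg$planted_counts >= 0), "planted_counts must be >= 0")
  chk(cfg$induced_allele_freq > 0 && cfg$induced_allele_freq <= 1,
      "induced_allele_freq must be in (0, 1]")
  chk(cfg$transition_bias > 0, "transition_bias must be positive")
  chk(length(cfg$correlation_design) == cfg$n_species,
      "correlation_design must have one entry per species")
  chk(all(cfg$correlation_design %in% c("positive", "negative", "none")),
      "correlation_design entries must be positive/negative/none")
  chk(cfg$n_filler_species >= 0, "n_filler_species must be >= 0")
  chk(cfg$abundance_noise >= 0, "abundance_noise must be >= 0")
  if (length(errs)) stop("invalid sim_config: ", paste(errs, collapse = "; "),
                         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Small, fast demo preset of [sim_config()]
#' @param seed Master seed.
#' @return A `sim_config` with 2 species x 5 kb genomes, suitable for
#'   end-to-end runs in seconds.
#' @export
sim_config_demo <- function(seed = 1L) {
  sim_config(seed = seed, n_species = 2L, genome_length = 5000L,
             genes_per_genome = 6L,
             planted_counts = c(induced = 8L, artifact = 5L, natural = 5L),
             correlation_design = c("positive", "negative"),
             n_filler_species = 4L)
}

#' Near-threshold preset: planted frequencies straddling the 0.49 cutoff
#'
#' Plants variants at exactly the calling threshold frequency and just below
#' it, to pin down the inclusive (`>=`) boundary semantics of the caller.
#' @param seed Master seed.
#' @param freq Planted allele frequency (use 0.49 or 0.45).
#' @return A small `sim_config` with `induced_allele_freq = freq`.
#' @export
sim_config_near_threshold <- function(seed = 1L, freq = 0.49) {
  sim_config(seed = seed, n_species = 1L, genome_length = 5000L,
             genes_per_genome = 4L,
             planted_counts = c(induced = 10L, artifact = 0L, natural = 0L),
             induced_allele_freq = freq,
             correlation_design = "positive", n_filler_species = 4L)
}

species_ids <- function(config) sprintf("species_%02d", seq_len(config$n_species))

#' The full factorial sample design for a config
#'
#' Sample ids follow the A/B/C/D group coding of the emulated study:
#' A = treatment small intestine, B = treatment large, C = control small,
#' D = control large; e.g. `AD3_2` is treatment/small, day 3, replicate 2.
#'
#' @param config A `sim_config`.
#' @return Metadata data.frame (`sample_id`, `group`, `segment`, `day`,
#'   `replicate`), 2 x 2 x 3 x `n_replicates` rows.
#' @export
sample_design <- function(config) {
  d <- expand.grid(replicate = seq_len(config$n_replicates),
                   day = c(1L, 3L, 7L),
                   segment = c("small", "large"),
                   group = c("treatment", "control"),
                   stringsAsFactors = FALSE)
  code <- ifelse(d$group == "treatment",
                 ifelse(d$segment == "small", "A", "B"),
                 ifelse(d$segment == "small", "C", "D"))
  d$sample_id <- sprintf("%sD%d_%d", code, d$day, d$replicate)
  d[, c("sample_id", "group", "segment", "day", "replicate")]
}

#' Generate random reference genomes with non-overlapping gene models
#'
#' Sequences are i.i.d. uniform over A/C/G/T. Each genome gets
#' `genes_per_genome` non-overlapping CDSs (lengths divisible by 3, mixed
#' strands) plus two RNA genes. Deterministic given the config seed.
#'
#' @param config A `sim_config`.
#' @return Named list of `genome_annotation` objects (one contig each).
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_feats <- config$genes_per_genome + 2L
  # worst-case footprint: CDS up to 600 bp, RNA gene up to 90 bp,
  # preceding gap up to 80 bp each
  if (config$genes_per_genome * 680L + 2L * 170L > config$genome_length)
    stop("genes_per_genome infeasible for genome_length", call. = FALSE)
  set.seed(config$seed + 1L)
  products <- c("alpha-glucosidase", "glycerate kinase",
                "DMT family transporter",
                "LytTR family DNA-binding domain protein",
                "hypothetical protein", "ABC transporter permease")
  out <- list()
  for (sp in species_ids(config)) {
    seq <- paste(sample(BASES, config$genome_length, replace = TRUE),
                 collapse = "")
    contig <- paste0(sp, "_c1")
    is_rna <- sample(rep(c(FALSE, TRUE), c(config$genes_per_genome, 2L)))
    pos <- 1L
    rows <- vector("list", n_feats)
    for (i in seq_len(n_feats)) {
      gap <- sample(20:80, 1L)
      len <- if (is_rna[i]) sample(72:90, 1L) else 3L * sample(60:200, 1L)
      start <- pos + gap
      rows[[i]] <- data.frame(
        gene_id = sprintf("%s_g%03d", sp, i),
        contig_id = contig, start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1L),
        feature_class = if (is_rna[i]) "rna_gene" else "CDS",
        product = if (is_rna[i]) "tRNA" else sample(products, 1L),
        stringsAsFactors = FALSE
      )
      pos <- start + len
    }
    genes <- do.call(rbind, rows)
    out[[sp]] <- genome_annotation(sp, setNames(seq, contig), genes)
  }
  out
}

#' Plant provenance-labelled variants into simulated genomes
#'
#' Positions are drawn uniformly without collision within each genome; the
#' alternate base differs from the reference and is a transition with odds
#' `transition_bias : 1`. Each variant is assigned a segment; natural
#' variants additionally get one designated day.
#'
#' @param genomes List from [generate_genomes()].
#' @param config The same `sim_config`.
#' @return data.frame of class `snv_truth`: `species_id`, `contig`, `pos`,
#'   `ref_base`, `alt_base`, `provenance`, `segment`, `day` (NA except for
#'   natural variants).
#' @export
plant_variants <- function(genomes, config) {
  stopifnot(inherits(config, "sim_config"))
  n_tot <- sum(config$planted_counts)
  if (n_tot > config$genome_length)
    stop("requested planted SNVs exceed available positions", call. = FALSE)
  set.seed(config$seed + 2L)
  p_ti <- config$transition_bias / (config$transition_bias + 1)
  ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
  rows <- list()
  for (sp in names(genomes)) {
    if (n_tot == 0L) next
    g <- genomes[[sp]]
    contig <- names(g$contigs)[1L]
    pos <- sort(sample.int(nchar(g$contigs[[1L]]), n_tot))
    chars <- strsplit(g$contigs[[1L]], "", fixed = TRUE)[[1L]]
    ref <- chars[pos]
    is_ti <- runif(n_tot) < p_ti
    alt <- character(n_tot)
    alt[is_ti] <- ti_partner[ref[is_ti]]
    for (j in which(!is_ti)) {
      tv <- setdiff(BASES, c(ref[j], ti_partner[ref[j]]))
      alt[j] <- sample(tv, 1L)
    }
    prov <- sample(rep(c("induced", "artifact", "natural"),
                       config$planted_counts[c("induced", "artifact",
                                               "natural")]))
    seg <- sample(c("small", "large"), n_tot, replace = TRUE)
    day <- rep(NA_integer_, n_tot)
    day[prov == "natural"] <- sample(c(1L, 3L, 7L), sum(prov == "natural"),
                                     replace = TRUE)
    rows[[sp]] <- data.frame(species_id = sp, contig = contig, pos = pos,
                             ref_base = ref, alt_base = alt,
                             provenance = prov, segment = seg, day = day,
                             stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(), contig = character(),
               pos = integer(), ref_base = character(),
               alt_base = character(), provenance = character(),
               segment = character(), day = integer(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  class(truth) <- c("snv_truth", "data.frame")
  truth
}

#' Which planted variants are present in a given sample
#' @noRd
truth_visible_in <- function(truth, group, segment, day) {
  vis <- truth$segment == segment &
    (truth$provenance == "artifact" |
     (truth$provenance == "induced" & group == "treatment") |
     (truth$provenance == "natural" & !is.na(truth$day) & truth$day == day))
  truth[vis, , drop = FALSE]
}

#' Simulate the pileup of one sample
#'
#' Depth per site is Poisson(`mean_depth`). At a non-variant site all reads
#' are reference, miscalled uniformly onto the other three bases with
#' probability `error_rate`. At a variant site present in this sample,
#' alternate reads are Binomial(depth, `induced_allele_freq`) and remaining
#' reads are reference. Deterministic: the sample's seed is
#' `seed + 1000 + row index` in the [sample_design()] order.
#'
#' @param genomes List from [generate_genomes()].
#' @param truth `snv_truth` from [plant_variants()].
#' @param config The `sim_config`.
#' @param sample_row One row of [sample_design()].
#' @param sample_index Its row index in the design (drives the sub-seed).
#' @return Pileup data.frame over all species' genomes.
#' @export
simulate_sample_pileup <- function(genomes, truth, config, sample_row,
                                   sample_index) {
  set.seed(config$seed + 1000L + as.integer(sample_index))
  vis <- truth_visible_in(truth, sample_row$group, sample_row$segment,
                          sample_row$day)
  parts <- vector("list", length(genomes))
  for (si in seq_along(genomes)) {
    g <- genomes[[si]]
    contig <- names(g$contigs)[1L]
    L <- nchar(g$contigs[[1L]])
    depth <- rpois(L, config$mean_depth)
    ref_idx <- match(strsplit(g$contigs[[1L]], "", fixed = TRUE)[[1L]], BASES)
    cnt <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
    if (config$error_rate > 0) {
      err <- rbinom(L, depth, config$error_rate)
      e1 <- rbinom(L, err, 1 / 3)
      e2 <- rbinom(L, err - e1, 1 / 2)
      e3 <- err - e1 - e2
      others <- matrix(c(2L, 3L, 4L, 1L, 3L, 4L, 1L, 2L, 4L, 1L, 2L, 3L),
                       nrow = 4L, byrow = TRUE)  # non-ref base indices
      cnt[cbind(seq_len(L), others[ref_idx, 1L])] <- e1
      cnt[cbind(seq_len(L), others[ref_idx, 2L])] <- e2
      cnt[cbind(seq_len(L), others[ref_idx, 3L])] <- e3
      cnt[cbind(seq_len(L), ref_idx)] <- depth - err
    } else {
      cnt[cbind(seq_len(L), ref_idx)] <- depth
    }
    v <- vis[vis$species_id == g$species_id, , drop = FALSE]
    if (nrow(v)) {
      d_v <- depth[v$pos]
      alt_reads <- rbinom(nrow(v), d_v, config$induced_allele_freq)
      cnt[v$pos, ] <- 0L
      cnt[cbind(v$pos, match(v$alt_base, BASES))] <- alt_reads
      cnt[cbind(v$pos, match(v$ref_base, BASES))] <-
        cnt[cbind(v$pos, match(v$ref_base, BASES))] + (d_v - alt_reads)
    }
    parts[[si]] <- data.frame(contig = contig, pos = seq_len(L),
                              A = cnt[, 1L], C = cnt[, 2L], G = cnt[, 3L],
                              T = cnt[, 4L], stringsAsFactors = FALSE)
  }
  p <- do.call(rbind, parts)
  p$depth <- as.integer(p$A + p$C + p$G + p$T)
  rownames(p) <- NULL
  p
}

#' Write per-sample pileup files plus the truth table
#'
#' @param genomes List from [generate_genomes()].
#' @param truth `snv_truth` from [plant_variants()].
#' @param config The `sim_config`.
#' @param out_dir Output directory (created if needed); pileups are written
#'   as `pileup_<sample_id>.tsv`, the truth as `truth.tsv`.
#' @return Named character vector of pileup paths, invisibly.
#' @export
emit_pileups <- function(genomes, truth, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- sample_design(config)
  paths <- setNames(character(nrow(design)), design$sample_id)
  for (i in seq_len(nrow(design))) {
    p <- simulate_sample_pileup(genomes, truth, config, design[i, ], i)
    paths[i] <- file.path(out_dir,
                          paste0("pileup_", design$sample_id[i], ".tsv"))
    write_pileup(p, paths[i])
  }
  write_truth(truth, file.path(out_dir, "truth.tsv"))
  invisible(paths)
}

#' Write / read the planted-variant truth table
#' @param truth `snv_truth` data.frame.
#' @param path TSV path.
#' @return `path` (write) or the truth data.frame (read).
#' @export
write_truth <- function(truth, path) {
  out <- as.data.frame(truth)
  out$day[is.na(out$day)] <- "."
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  t <- fread(path, sep = "\t", data.table = FALSE, showProgress = FALSE,
             colClasses = list(character = "day"))
  t$day <- suppressWarnings(as.integer(ifelse(t$day == ".", NA, t$day)))
  class(t) <- c("snv_truth", "data.frame")
  t
}

#' Generate the species-by-sample abundance table
#'
#' The table is constructed directly in relative-abundance (share) space,
#' which keeps the engineered relations exact under compositional closure.
#' The focal probiotic's share decays over days in treatment samples
#' (0.05, 0.02, 0.005 on days 1/3/7) and is exactly 0 in controls (single
#' gavage, transient carriage). Positive-design species have shares
#' `base * (1 + 25 * focal)` (exactly increasing); none-design species and
#' fillers have constant shares (independent of the focal); negative-design
#' species split the remaining share mass, so they absorb the focal's and
#' positive species' gains and are exactly decreasing. When no
#' negative-design species exists, the fillers absorb the remainder
#' instead (and are then no longer focal-independent). All shares then
#' receive multiplicative log-normal noise of sd `abundance_noise` and
#' columns are renormalized to sum 1 (a no-op at zero noise).
#'
#' @param config A `sim_config`.
#' @return List with `table` (matrix species x samples, columns sum 1),
#'   `signs` (named vector of engineered correlation signs `+`/`-`/`0`
#'   for species and fillers) and `design` (the sample metadata).
#' @export
generate_abundance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  design <- sample_design(config)
  ns <- nrow(design)
  focal_curve <- c(`1` = 0.05, `3` = 0.02, `7` = 0.005)
  # noiseless carriage level per sample; species respond to this level,
  # with observation noise applied afterwards
  F0 <- ifelse(design$group == "treatment",
               focal_curve[as.character(design$day)], 0)
  sp <- species_ids(config)
  base <- 0.02 + 0.004 * seq_along(sp)          # fixed minor-species bases
  des <- config$correlation_design
  nf <- config$n_filler_species
  filler_ids <- sprintf("filler_%02d", seq_len(nf))

  rows <- list()
  rows[[config$focal_species]] <- F0
  signs <- setNames(rep("0", length(sp) + nf), c(sp, filler_ids))
  for (i in which(des == "positive")) {
    rows[[sp[i]]] <- base[i] * (1 + 25 * F0)
    signs[sp[i]] <- "+"
  }
  for (i in which(des == "none")) rows[[sp[i]]] <- rep(base[i], ns)
  for (f in filler_ids) rows[[f]] <- rep(0.12, ns)
  remainder <- 1 - Reduce(`+`, rows)
  if (any(remainder <= 0.02))
    stop("species shares exceed the unit total; reduce n_species or ",
         "n_filler_species", call. = FALSE)
  neg_i <- which(des == "negative")
  if (length(neg_i)) {
    w <- base[neg_i] / sum(base[neg_i])
    for (k in seq_along(neg_i)) {
      rows[[sp[neg_i[k]]]] <- remainder * w[k]
      signs[sp[neg_i[k]]] <- "-"
    }
  } else if (nf > 0L) {
    for (f in filler_ids) rows[[f]] <- remainder / nf
  } else {
    stop("need a negative-design or filler species to absorb the focal's ",
         "share", call. = FALSE)
  }
  ord <- c(config$focal_species, sp, filler_ids)
  tabl <- do.call(rbind, rows[ord])
  rownames(tabl) <- ord
  colnames(tabl) <- design$sample_id
  if (config$abundance_noise > 0) {
    tabl <- tabl * matrix(exp(rnorm(length(tabl), 0,
                                    config$abundance_noise)),
                          nrow(tabl), ns)
    tabl <- sweep(tabl, 2L, colSums(tabl), "/")
  }
  list(table = tabl, signs = signs, design = design)
}

#' Simulate and write a complete study dataset
#'
#' Writes reference FASTA + GFF3 per species, per-sample pileups, the truth
#' table, the sample metadata and the abundance table under `out_dir`.
#' Deterministic given `config$seed` (byte-identical files).
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory `genomes`, `truth`,
#'   `design`, `abundance` and all file paths.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- generate_genomes(config)
  truth <- plant_variants(genomes, config)
  ab <- generate_abundance(config)
  ref_dir <- file.path(out_dir, "reference")
  dir.create(ref_dir, showWarnings = FALSE)
  fasta <- gff <- setNames(character(length(genomes)), names(genomes))
  for (sp in names(genomes)) {
    fasta[sp] <- file.path(ref_dir, paste0(sp, ".fna"))
    gff[sp] <- file.path(ref_dir, paste0(sp, ".gff3"))
    write_fasta(genomes[[sp]], fasta[sp])
    write_gff3(genomes[[sp]]$genes, gff[sp])
  }
  pileups <- emit_pileups(genomes, truth, config,
                          file.path(out_dir, "pileups"))
  meta_path <- file.path(out_dir, "metadata.tsv")
  write_metadata(ab$design, meta_path)
  ab_path <- file.path(out_dir, "abundance.tsv")
  write_abundance(ab$table, ab_path)
  invisible(list(genomes = genomes, truth = truth, design = ab$design,
                 abundance = ab$table, abundance_signs = ab$signs,
                 paths = list(fasta = fasta, gff = gff, pileups = pileups,
                              metadata = meta_path, abundance = ab_path,
                              truth = file.path(out_dir, "pileups",
                                                "truth.tsv"))))
}
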