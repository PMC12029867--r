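# Shared fixtures: a small hand-built genome with known gene structure,
# pileup builders, random SNV records, and the whole-protein brute-force
# translation oracle used to cross-check codon classification.

# 60 bp contig:
#   1-9    intergenic (A*9)
#   10-18  CDS g1, + strand: GCC TTG ATC (Ala Leu Ile)
#   19-24  intergenic (C*6)
#   25-32  tRNA t1
#   33-39  intergenic (G*7)
#   40-51  CDS g2, - strand: genomic AGCCATGGCGGC
#   52-60  intergenic (T*9)
hand_genome <- function() {
  seq <- paste0("AAAAAAAAA", "GCCTTGATC", "CCCCCC", "ACGTACGT",
                "GGGGGGG", "AGCCATGGCGGC", "TTTTTTTTT")
  stopifnot(nchar(seq) == 60L)
  genes <- data.frame(
    gene_id = c("g1", "t1", "g2"),
    contig_id = "chr1",
    start = c(10L, 25L, 40L),
    end = c(18L, 32L, 51L),
    strand = c("+", "+", "-"),
    feature_class = c("CDS", "rna_gene", "CDS"),
    product = c("alpha-glucosidase", "tRNA", "hypothetical protein"),
    stringsAsFactors = FALSE
  )
  genome_annotation("handsp", c(chr1 = seq), genes)
}

# pileup with given per-position count overrides; default: clean reference
# coverage at depth for every listed position
make_pileup <- function(genome, pos, depth = 150L, overrides = list()) {
  chars <- strsplit(genome$contigs[[1L]], "", fixed = TRUE)[[1L]]
  contig <- names(genome$contigs)[1L]
  p <- data.frame(contig = contig, pos = as.integer(pos),
                  A = 0L, C = 0L, G = 0L, T = 0L,
                  stringsAsFactors = FALSE)
  for (i in seq_along(pos)) p[i, chars[pos[i]]] <- depth
  for (nm in names(overrides)) {
    i <- match(as.integer(nm), p$pos)
    p[i, c("A", "C", "G", "T")] <- as.list(overrides[[nm]])
  }
  p$depth <- as.integer(rowSums(p[, c("A", "C", "G", "T")]))
  p
}

# n random, internally consistent SNV records (allele_freq at 6 decimals so
# TSV round-trips are identity)
random_snv_records <- function(n, seed = 1) {
  if (n == 0L) {
    return(data.frame(
      species_id = character(), contig = character(), pos = integer(),
      ref_base = character(), alt_base = character(),
      ref_count = integer(), alt_count = integer(), depth = integer(),
      allele_freq = numeric(), region_class = character(),
      mutation_class = character(), gene_id = character(),
      substitution = character(), is_transition = logical(),
      stringsAsFactors = FALSE
    ))
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  depth <- sample(100:300, n, TRUE)
  alt_count <- pmax(1L, as.integer(round(depth * runif(n, 0.49, 0.95))))
  region <- sample(c("coding", "noncoding_genic", "intergenic"), n, TRUE)
  data.frame(
    species_id = sample(sprintf("sp%02d", 1:3), n, TRUE),
    contig = "c1",
    pos = sample.int(1e6, n),
    ref_base = ref, alt_base = unname(alt),
    ref_count = depth - alt_count, alt_count = alt_count, depth = depth,
    allele_freq = round(alt_count / depth, 6L),
    region_class = region,
    mutation_class = ifelse(region == "coding",
                            sample(c("synonymous", "nonsynonymous"), n, TRUE),
                            NA_character_),
    gene_id = ifelse(region == "intergenic", NA_character_, "g1"),
    substitution = paste0(ref, ">", unname(alt)),
    is_transition = paste0(ref, ">", unname(alt)) %in%
      c("A>G", "G>A", "C>T", "T>C"),
    stringsAsFactors = FALSE
  )
}

# brute-force oracle: mutate the full genome, translate the whole CDS on its
# coding strand, and diff the protein sequences
brute_mutation_class <- function(genome, gene, pos, alt) {
  seq <- genome$contigs[[gene$contig_id]]
  mut <- seq
  substr(mut, pos, pos) <- alt
  cds_of <- function(s) {
    cds <- substr(s, gene$start, gene$end)
    if (gene$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    cds
  }
  code <- Biostrings::getGeneticCode("11")
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), genetic.code = code, no.init.codon = TRUE))
  p_ref <- tr(cds_of(seq))
  p_alt <- tr(cds_of(mut))
  if (identical(p_ref, p_alt)) "synonymous" else "nonsynonymous"
}

# random CDS-bearing genome for oracle sweeps: one gene covering the whole
# contig on the requested strand
random_cds_genome <- function(len = 300L, strand = "+", seed = 1) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  genes <- data.frame(gene_id = "gX", contig_id = "c1", start = 1L,
                      end = len, strand = strand, feature_class = "CDS",
                      product = ".", stringsAsFactors = FALSE)
  genome_annotation("oracle_sp", c(c1 = seq), genes)
}

# stacked per-sample records for filter tests: one row per (sample, key)
make_keyed_records <- function(sample_id, species, pos_vec,
                               alt = "G", ref = "A") {
  n <- length(pos_vec)
  if (n == 0L) {
    out <- random_snv_records(0)
    out$sample_id <- character(0)
    return(out[, c("sample_id", setdiff(names(out), "sample_id"))])
  }
  data.frame(
    sample_id = sample_id, species_id = species, contig = "c1",
    pos = as.integer(pos_vec), ref_base = ref, alt_base = alt,
    ref_count = 60L, alt_count = 90L, depth = 150L,
    allele_freq = 0.6, region_class = "intergenic",
    mutation_class = NA_character_, gene_id = NA_character_,
    substitution = paste0(ref, ">", alt),
    is_transition = paste0(ref, ">", alt) %in% c("A>G", "G>A", "C>T", "T>C"),
    stringsAsFactors = FALSE
  )
}

# a minimal 2-group 1-segment design used by filter unit tests
tiny_metadata <- function(n_rep = 6L, segment = "small") {
  d <- expand.grid(replicate = seq_len(n_rep), day = c(1L, 3L, 7L),
                   segment = segment, group = c("treatment", "control"),
                   stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_d%d_r%d", substr(d$group, 1, 1), d$segment,
                         d$day, d$replicate)
  d[, c("sample_id", "group", "segment", "day", "replicate")]
}

# cache for the full clean-configuration study run shared by the
# recovery/filter acceptance blocks (computed once per test session)
.clean_run_env <- new.env(parent = emptyenv())

clean_run <- function(seed = 101L) {
  key <- as.character(seed)
  if (!is.null(.clean_run_env[[key]])) return(.clean_run_env[[key]])
  cfg <- sim_config(seed = seed)   # study defaults: 5 sp x 50 kb, 72 samples
  genomes <- generate_genomes(cfg)
  truth <- plant_variants(genomes, cfg)
  design <- sample_design(cfg)
  params <- caller_params()
  recs <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    p <- simulate_sample_pileup(genomes, truth, cfg, design[i, ], i)
    r <- do.call(rbind, lapply(genomes, function(g)
      call_snvs(p[p$contig %in% names(g$contigs), , drop = FALSE], g, params)))
    r$sample_id <- rep(design$sample_id[i], nrow(r))
    recs[[i]] <- r
  }
  recs <- do.call(rbind, recs)
  rownames(recs) <- NULL
  out <- list(config = cfg, genomes = genomes, truth = truth,
              design = design, records = recs)
  .clean_run_env[[key]] <- out
  out
}

variant_key <- function(df) paste(df$species_id, df$pos, df$alt_base)
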