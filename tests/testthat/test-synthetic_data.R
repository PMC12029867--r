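# Synthetic study generator: determinism, genome structure, planted truth,
# pileup composition, abundance design.

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config_demo(seed = 9)
  g1 <- generate_genomes(cfg)
  g2 <- generate_genomes(cfg)
  expect_identical(g1, g2)
  t1 <- plant_variants(g1, cfg)
  expect_identical(t1, plant_variants(g2, cfg))
  des <- sample_design(cfg)
  p1 <- simulate_sample_pileup(g1, t1, cfg, des[5, ], 5)
  p2 <- simulate_sample_pileup(g1, t1, cfg, des[5, ], 5)
  expect_identical(p1, p2)
  a1 <- generate_abundance(cfg)
  expect_identical(a1$table, generate_abundance(cfg)$table)
})

test_that("genomes have uniform composition and valid gene models", {
  cfg <- sim_config(seed = 3, n_species = 1L, genome_length = 50000L,
                    genes_per_genome = 40L)
  g <- generate_genomes(cfg)[[1]]
  comp <- table(strsplit(g$contigs[[1]], "")[[1]]) / g$total_length
  expect_true(all(abs(comp - 0.25) < 0.02))   # binomial bound at 50 kb

  genes <- g$genes
  expect_equal(nrow(genes), 42L)              # 40 CDS + 2 RNA genes
  cds <- genes[genes$feature_class == "CDS", ]
  expect_equal(nrow(cds), 40L)
  expect_true(all((cds$end - cds$start + 1L) %% 3L == 0L))
  expect_true(sum(genes$feature_class == "rna_gene") >= 1L)
  o <- genes[order(genes$start), ]
  expect_true(all(o$start[-1] > o$end[-nrow(o)]))   # pairwise non-overlap
  expect_true(all(genes$end <= g$total_length))
})

test_that("infeasible gene packing is a config error", {
  cfg <- sim_config(seed = 1, genome_length = 1000L, genes_per_genome = 50L)
  expect_error(generate_genomes(cfg), "infeasible")
})

test_that("planted variants honor counts, uniqueness and transition bias", {
  cfg0 <- sim_config(seed = 4, n_species = 1L, genome_length = 50000L,
                     planted_counts = c(induced = 0L, artifact = 0L,
                                        natural = 0L))
  expect_equal(nrow(plant_variants(generate_genomes(cfg0), cfg0)), 0L)

  cfg <- sim_config(seed = 4, n_species = 1L, genome_length = 50000L,
                    planted_counts = c(induced = 100L, artifact = 100L,
                                       natural = 100L))
  tr <- plant_variants(generate_genomes(cfg), cfg)
  expect_equal(nrow(tr), 300L)
  expect_equal(anyDuplicated(tr$pos), 0L)
  expect_true(all(tr$ref_base != tr$alt_base))
  expect_equal(unname(table(tr$provenance)[c("induced", "artifact",
                                             "natural")]),
               c(100L, 100L, 100L), ignore_attr = TRUE)
  expect_true(all(!is.na(tr$day[tr$provenance == "natural"])))
  expect_true(all(is.na(tr$day[tr$provenance != "natural"])))
  ti <- mean(paste0(tr$ref_base, ">", tr$alt_base) %in%
             c("A>G", "G>A", "C>T", "T>C"))
  expect_lt(abs(ti - 2 / 3), 0.06)            # binomial bound at n = 300

  cfg_over <- sim_config(seed = 4, n_species = 1L, genome_length = 1000L,
                         genes_per_genome = 1L,
                         planted_counts = c(induced = 600L, artifact = 300L,
                                            natural = 300L))
  expect_error(plant_variants(generate_genomes(cfg_over), cfg_over),
               "exceed available positions")
})

test_that("truth round-trips through truth.tsv", {
  cfg <- sim_config_demo(seed = 2)
  tr <- plant_variants(generate_genomes(cfg), cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(tr, f)
  expect_equal(as.data.frame(read_truth(f)), as.data.frame(tr))
})

test_that("pileups carry the planted signal and nothing else", {
  cfg <- sim_config(seed = 6, n_species = 1L, genome_length = 5000L,
                    genes_per_genome = 4L, error_rate = 0,
                    planted_counts = c(induced = 10L, artifact = 5L,
                                       natural = 5L))
  g <- generate_genomes(cfg)
  tr <- plant_variants(g, cfg)
  des <- sample_design(cfg)

  i_t <- which(des$group == "treatment")[1]
  pt <- simulate_sample_pileup(g, tr, cfg, des[i_t, ], i_t)
  chars <- strsplit(g[[1]]$contigs[[1]], "")[[1]]
  vis <- tr[tr$segment == des$segment[i_t] &
            (tr$provenance != "natural" | tr$day %in% des$day[i_t]), ]
  nonvar <- setdiff(seq_len(5000L), vis$pos)
  cnt <- as.matrix(pt[nonvar, c("A", "C", "G", "T")])
  ref_col <- cnt[cbind(seq_along(nonvar), match(chars[nonvar], BASES))]
  expect_equal(unname(ref_col), pt$depth[nonvar])   # error_rate 0: ref only

  at_var <- pt[match(vis$pos, pt$pos), ]
  alt_n <- as.matrix(at_var[, c("A", "C", "G", "T")])[
    cbind(seq_len(nrow(vis)), match(vis$alt_base, BASES))]
  expect_true(all(abs(alt_n / at_var$depth - 0.6) < 0.15))

  # control sample: day-matched natural + artifact, never induced
  i_c <- which(des$group == "control" & des$segment == des$segment[i_t] &
               des$day == des$day[i_t])[1]
  pc <- simulate_sample_pileup(g, tr, cfg, des[i_c, ], i_c)
  ind <- tr[tr$provenance == "induced" & tr$segment == des$segment[i_c], ]
  if (nrow(ind)) {
    cnt_i <- as.matrix(pc[match(ind$pos, pc$pos), c("A", "C", "G", "T")])
    alt_i <- cnt_i[cbind(seq_len(nrow(ind)), match(ind$alt_base, BASES))]
    expect_true(all(alt_i == 0L))
  }
  art <- tr[tr$provenance == "artifact" & tr$segment == des$segment[i_c], ]
  if (nrow(art)) {
    cnt_a <- as.matrix(pc[match(art$pos, pc$pos), c("A", "C", "G", "T")])
    alt_a <- cnt_a[cbind(seq_len(nrow(art)), match(art$alt_base, BASES))]
    expect_true(all(alt_a > 0L))
  }
})

test_that("emit_pileups writes one file per sample plus the truth", {
  cfg <- sim_config(seed = 8, n_species = 1L, genome_length = 1200L,
                    genes_per_genome = 1L, n_replicates = 1L,
                    planted_counts = c(induced = 2L, artifact = 1L,
                                       natural = 1L))
  g <- generate_genomes(cfg)
  tr <- plant_variants(g, cfg)
  out <- withr::local_tempdir()
  paths <- emit_pileups(g, tr, cfg, out)
  expect_length(paths, 12L)                    # 2x2x3x1 design
  expect_true(all(file.exists(paths)))
  expect_true(file.exists(file.path(out, "truth.tsv")))
  expect_equal(nrow(read_pileup(paths[1])), 1200L)
})

test_that("abundance table encodes the correlation designs", {
  cfg <- sim_config(seed = 12, n_species = 3L, genome_length = 5000L,
                    genes_per_genome = 4L,
                    correlation_design = c("positive", "negative", "none"),
                    abundance_noise = 0)
  ab <- generate_abundance(cfg)
  expect_equal(unname(colSums(ab$table)), rep(1, ncol(ab$table)),
               tolerance = 1e-12)
  expect_equal(unname(ab$signs[c("species_01", "species_02", "species_03")]),
               c("+", "-", "0"))

  m <- ab$design
  ctrl <- m$sample_id[m$group == "control"]
  expect_true(all(ab$table[cfg$focal_species, ctrl] == 0))

  treat <- m$sample_id[m$group == "treatment" & m$segment == "large"]
  focal <- ab$table[cfg$focal_species, treat]
  expect_equal(cor(rank(focal), rank(ab$table["species_01", treat])), 1)
  expect_equal(cor(rank(focal), rank(ab$table["species_02", treat])), -1)

  # focal decays over days in treatment samples (noise 0)
  by_day <- tapply(focal, m$day[match(treat, m$sample_id)], mean)
  expect_true(all(diff(by_day[order(as.integer(names(by_day)))]) < 0))
})
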