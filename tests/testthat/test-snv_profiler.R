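# Consensus caller, region/codon classification, spectra.

test_that("caller applies inclusive coverage and frequency thresholds", {
  g <- hand_genome()
  # ref at pos 3 is A
  p <- make_pileup(g, 3L, overrides = list(
    `3` = c(A = 70L, C = 0L, G = 80L, T = 0L)))
  r <- call_snvs(p, g)
  expect_equal(nrow(r), 1L)
  expect_equal(r$alt_base, "G")
  expect_equal(r$allele_freq, 80 / 150, tolerance = 1e-12)
  expect_equal(r$substitution, "A>G")
  expect_true(r$is_transition)

  # pure reference: no call
  expect_equal(nrow(call_snvs(make_pileup(g, 3L, depth = 150L), g)), 0L)

  # coverage gate: depth 90 at alt fraction 0.9
  p2 <- make_pileup(g, 3L, overrides = list(
    `3` = c(A = 9L, C = 0L, G = 81L, T = 0L)))
  expect_equal(nrow(call_snvs(p2, g)), 0L)

  # boundary semantics: exactly depth 100 and frequency 0.49 is called
  p3 <- make_pileup(g, 3L, overrides = list(
    `3` = c(A = 51L, C = 49L, G = 0L, T = 0L)))
  r3 <- call_snvs(p3, g)
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$allele_freq, 0.49)
  p4 <- make_pileup(g, 3L, overrides = list(
    `3` = c(A = 52L, C = 48L, G = 0L, T = 0L)))
  expect_equal(nrow(call_snvs(p4, g)), 0L)   # 0.48 < 0.49

  # alt ties break by fixed base order A < C < G < T
  p5 <- make_pileup(g, 3L, overrides = list(
    `3` = c(A = 0L, C = 75L, G = 75L, T = 0L)))
  expect_equal(call_snvs(p5, g)$alt_base, "C")

  # errors: unknown contig, position beyond contig
  bad <- make_pileup(g, 3L)
  bad$contig <- "nope"
  expect_error(call_snvs(bad, g), "absent from genome")
  far <- make_pileup(g, 3L)
  far$pos <- 1000L
  expect_error(call_snvs(far, g), "beyond contig")
})

test_that("caller is monotone in both thresholds (nested call sets)", {
  g <- hand_genome()
  set.seed(5)
  pos <- 1:60
  p <- make_pileup(g, pos, depth = 0L)
  chars <- strsplit(g$contigs[[1]], "")[[1]]
  for (i in pos) {
    depth <- sample(60:200, 1)
    alt <- sample(setdiff(BASES, chars[i]), 1)
    a_n <- rbinom(1, depth, runif(1, 0.2, 0.8))
    p[i, chars[i]] <- depth - a_n
    p[i, alt] <- a_n
  }
  p$depth <- as.integer(rowSums(p[, BASES]))
  grid <- expand.grid(c = c(50L, 100L, 150L), f = c(0.3, 0.49, 0.7))
  sets <- lapply(seq_len(nrow(grid)), function(i) {
    r <- call_snvs(p, g, caller_params(grid$c[i], grid$f[i]))
    paste(r$pos, r$alt_base)
  })
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$c[i] <= grid$c[j] && grid$f[i] <= grid$f[j])
      expect_true(all(sets[[j]] %in% sets[[i]]))
  }
})

test_that("region classification distinguishes CDS, RNA gene, intergenic", {
  g <- hand_genome()
  mk <- function(pos) {
    r <- random_snv_records(1)
    r$contig <- "chr1"; r$pos <- pos
    r$region_class <- NA_character_; r$gene_id <- NA_character_
    r$mutation_class <- NA_character_
    r
  }
  inside_cds <- classify_region(mk(12L), g$genes)
  expect_equal(inside_cds$region_class, "coding")
  expect_equal(inside_cds$gene_id, "g1")
  in_trna <- classify_region(mk(28L), g$genes)
  expect_equal(in_trna$region_class, "noncoding_genic")
  expect_equal(in_trna$gene_id, "t1")
  between <- classify_region(mk(20L), g$genes)
  expect_equal(between$region_class, "intergenic")
  expect_true(is.na(between$gene_id))

  # overlapping CDSs: one record per gene context
  genes2 <- rbind(g$genes, data.frame(
    gene_id = "g1b", contig_id = "chr1", start = 10L, end = 15L,
    strand = "+", feature_class = "CDS", product = ".",
    stringsAsFactors = FALSE))
  both <- classify_region(mk(12L), genes2)
  expect_equal(nrow(both), 2L)
  expect_setequal(both$gene_id, c("g1", "g1b"))
})

test_that("codon classification reproduces the worked substitutions", {
  # CDS spelling out the alpha-glucosidase context: GCC TTG ATC AAG CAA
  seq <- "GCCTTGATCAAGCAA"
  genes <- data.frame(gene_id = "agl", contig_id = "c1", start = 1L,
                      end = 15L, strand = "+", feature_class = "CDS",
                      product = "alpha-glucosidase", stringsAsFactors = FALSE)
  g <- genome_annotation("sp", c(c1 = seq), genes)
  call_at <- function(pos, alt) {
    counts <- setNames(rep(0L, 4), BASES)
    counts[substr(seq, pos, pos)] <- 60L
    counts[alt] <- 90L
    p <- make_pileup(g, pos, overrides =
                       setNames(list(counts), as.character(pos)))
    annotate_snvs(p, g)
  }
  # GCC -> GAC: Ala -> Asp, nonsynonymous (middle base C>A)
  r1 <- call_at(2L, "A")
  expect_equal(r1$codon_ref, "GCC")
  expect_equal(r1$codon_alt, "GAC")
  expect_equal(r1$aa_ref, "A"); expect_equal(r1$aa_alt, "D")
  expect_equal(r1$mutation_class, "nonsynonymous")
  # CAA -> AAA: Gln -> Lys, nonsynonymous (first base C>A)
  r2 <- call_at(13L, "A")
  expect_equal(r2$codon_ref, "CAA")
  expect_equal(r2$codon_alt, "AAA")
  expect_equal(r2$aa_ref, "Q"); expect_equal(r2$aa_alt, "K")
  expect_equal(r2$mutation_class, "nonsynonymous")
  # third-position change within TTG/CTN-family leucine: synonymous
  r3 <- call_at(6L, "A")                      # TTG -> TTA, both Leu
  expect_equal(r3$mutation_class, "synonymous")
  expect_equal(r3$aa_ref, "L"); expect_equal(r3$aa_alt, "L")
})

test_that("alt alleles creating stop codons are nonsynonymous with aa '*'", {
  seq <- "ATGTATGGA"                           # ATG TAT GGA
  genes <- data.frame(gene_id = "gS", contig_id = "c1", start = 1L,
                      end = 9L, strand = "+", feature_class = "CDS",
                      product = ".", stringsAsFactors = FALSE)
  g <- genome_annotation("sp", c(c1 = seq), genes)
  counts <- c(A = 90L, C = 0L, G = 0L, T = 60L)
  p <- make_pileup(g, 6L, overrides = list(`6` = counts))  # TAT -> TAA
  r <- annotate_snvs(p, g)
  expect_equal(r$codon_alt, "TAA")
  expect_equal(r$aa_alt, "*")
  expect_equal(r$mutation_class, "nonsynonymous")
})

test_that("minus-strand codons are extracted on the coding strand", {
  g <- hand_genome()                           # g2: 40-51, minus strand
  # pos 51 is the last reference base = first coding-strand base
  counts51 <- c(A = 0L, C = 60L, G = 0L, T = 90L)
  p <- make_pileup(g, 51L, overrides = list(`51` = counts51))
  r <- annotate_snvs(p, g)
  expect_equal(r$region_class, "coding")
  expect_equal(r$gene_id, "g2")
  expect_equal(r$ref_base, "C")                # reference-strand orientation
  expect_equal(r$alt_base, "T")
  expect_equal(r$codon_ref, "GCC")             # revcomp of genomic 49-51
  expect_equal(r$codon_alt, "ACC")             # coding-strand alt is A
  expect_equal(r$mutation_class, "nonsynonymous")
  expect_equal(brute_mutation_class(g, g$genes[3, ], 51L, "T"),
               "nonsynonymous")

  # pos 49 G>A: third codon position on the coding strand, synonymous
  counts49 <- c(A = 90L, C = 0L, G = 60L, T = 0L)
  p2 <- make_pileup(g, 49L, overrides = list(`49` = counts49))
  r2 <- annotate_snvs(p2, g)
  expect_equal(r2$codon_ref, "GCC")
  expect_equal(r2$codon_alt, "GCT")
  expect_equal(r2$mutation_class, "synonymous")
  expect_equal(brute_mutation_class(g, g$genes[3, ], 49L, "A"),
               "synonymous")
})

test_that("codon classifier agrees with the brute-force oracle", {
  # spot check here (the exhaustive 20-CDS sweep runs in the acceptance
  # suite): every substitution of two random 99-bp CDSs, both strands
  for (strand in c("+", "-")) {
    g <- random_cds_genome(len = 99L, strand = strand,
                           seed = if (strand == "+") 31 else 32)
    gene <- g$genes[1, ]
    chars <- strsplit(g$contigs[[1]], "")[[1]]
    recs <- data.frame()
    for (pos in seq_len(99L)) {
      for (alt in setdiff(BASES, chars[pos])) {
        r <- random_snv_records(1)
        r$contig <- "c1"; r$pos <- pos
        r$ref_base <- chars[pos]; r$alt_base <- alt
        r$region_class <- "coding"; r$gene_id <- "gX"
        r$mutation_class <- NA_character_
        recs <- rbind(recs, r)
      }
    }
    got <- classify_codon(recs, g, g$genes)$mutation_class
    want <- mapply(function(pos, alt)
      brute_mutation_class(g, gene, pos, alt), recs$pos, recs$alt_base)
    expect_equal(got, unname(want))
  }
})

test_that("substitution spectra count, conserve, and summarise ti/tv", {
  empty <- substitution_spectrum(random_snv_records(0))
  expect_equal(sum(empty$counts), 0L)
  expect_true(is.na(empty$titv))

  recs <- random_snv_records(10)
  recs$substitution <- "A>G"
  s <- substitution_spectrum(recs)
  expect_equal(unname(s$counts["A>G"]), 10L)
  expect_equal(s$transversions, 0L)
  expect_true(is.na(s$titv))

  r2 <- random_snv_records(200, seed = 8)
  s2 <- substitution_spectrum(r2)
  expect_equal(sum(s2$counts), 200L)           # conservation
  expect_equal(s2$transitions + s2$transversions, 200L)
})

test_that("position track is sorted and keeps per-sample duplicates", {
  recs <- random_snv_records(5, seed = 2)
  recs$sample_id <- c("s1", "s2", "s1", "s2", "s1")
  recs$pos <- c(50L, 10L, 30L, 30L, 20L)
  tr <- position_frequency_track(recs)
  expect_equal(tr$pos, c(10L, 20L, 30L, 30L, 50L))
  expect_true("sample_id" %in% names(tr))
  expect_equal(nrow(position_frequency_track(random_snv_records(0))), 0L)
})
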