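# Consensus-threshold SNV calling and classification.
#
# A site is called when depth >= min_coverage AND the most frequent
# non-reference base reaches min_freq of the depth (both thresholds
# inclusive, ">="). The reference base comes from the reference genome, not
# the pileup majority: a site whose read majority differs from the reference
# is precisely an SNV candidate (consensus-style calling; with min_freq near
# 0.5 the caller targets near-consensus divergence from the reference).

#' Caller thresholds
#'
#' @param min_coverage Minimum read depth at a site (default 100).
#' @param min_freq Minimum fraction of the depth carried by the top
#'   non-reference base (default 0.49).
#' @param min_alt_count Minimum absolute read count of the alternate base
#'   (default 1; exposed rather than guessed, see package vignette).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_coverage = 100L, min_freq = 0.49,
                          min_alt_count = 1L) {
  stopifnot(length(min_coverage) == 1L, min_coverage >= 1,
            length(min_freq) == 1L, min_freq > 0, min_freq <= 1,
            length(min_alt_count) == 1L, min_alt_count >= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_freq = as.numeric(min_freq),
                 min_alt_count = as.integer(min_alt_count)),
            class = "caller_params")
}

empty_snv_records <- function(sample_id = FALSE) {
  df <- data.frame(
    species_id = character(), contig = character(), pos = integer(),
    ref_base = character(), alt_base = character(),
    ref_count = integer(), alt_count = integer(), depth = integer(),
    allele_freq = numeric(), region_class = character(),
    mutation_class = character(), gene_id = character(),
    substitution = character(), is_transition = logical(),
    stringsAsFactors = FALSE
  )
  if (sample_id) df <- cbind(data.frame(sample_id = character()), df)
  df
}

#' Call SNVs from a pileup under coverage/frequency thresholds
#'
#' A site is called iff `depth >= min_coverage` and
#' `(max non-reference count) / depth >= min_freq` (and the alternate count
#' reaches `min_alt_count`). The alternate allele is the most frequent
#' non-reference base; ties break by the fixed order A < C < G < T. Only the
#' single top non-reference allele is reported per site. Sites whose
#' reference base is `N` (masked) are never called.
#'
#' @param pileup Pileup data.frame (see [read_pileup()]).
#' @param genome `genome_annotation` supplying the reference bases.
#' @param params [caller_params()].
#' @return SNV record data.frame (region/codon columns unfilled: region
#'   `"intergenic"` placeholder is *not* inserted; use [classify_region()] /
#'   [classify_codon()] or [annotate_snvs()]).
#' @export
call_snvs <- function(pileup, genome, params = caller_params()) {
  stopifnot(inherits(genome, "genome_annotation"),
            inherits(params, "caller_params"))
  unknown <- setdiff(unique(pileup$contig), names(genome$contigs))
  if (length(unknown))
    stop("pileup contig absent from genome '", genome$species_id, "': ",
         unknown[1L], call. = FALSE)
  n <- nrow(pileup)
  if (n == 0L) return(empty_snv_records())
  clen <- nchar(genome$contigs)[pileup$contig]
  if (any(pileup$pos > clen))
    stop("pileup position beyond contig length (row ",
         which(pileup$pos > clen)[1L], ")", call. = FALSE)

  ref <- character(n)
  for (ct in unique(pileup$contig)) {
    idx <- pileup$contig == ct
    chars <- strsplit(genome$contigs[[ct]], "", fixed = TRUE)[[1L]]
    ref[idx] <- chars[pileup$pos[idx]]
  }
  cnt <- as.matrix(pileup[, BASES])
  depth <- as.integer(rowSums(cnt))
  ref_idx <- match(ref, BASES)           # NA for masked (N) sites
  nonref <- cnt
  ok <- !is.na(ref_idx)
  nonref[cbind(which(ok), ref_idx[ok])] <- -1L
  alt_idx <- max.col(nonref, ties.method = "first")  # fixed A<C<G<T tie order
  alt_count <- nonref[cbind(seq_len(n), alt_idx)]
  called <- ok & depth >= params$min_coverage &
    alt_count >= params$min_alt_count &
    alt_count / depth >= params$min_freq
  if (!any(called)) return(empty_snv_records())

  i <- which(called)
  alt <- BASES[alt_idx[i]]
  sub <- paste0(ref[i], ">", alt)
  data.frame(
    species_id = genome$species_id,
    contig = pileup$contig[i],
    pos = as.integer(pileup$pos[i]),
    ref_base = ref[i],
    alt_base = alt,
    ref_count = cnt[cbind(i, ref_idx[i])],
    alt_count = as.integer(alt_count[i]),
    depth = depth[i],
    allele_freq = alt_count[i] / depth[i],
    region_class = NA_character_,
    mutation_class = NA_character_,
    gene_id = NA_character_,
    substitution = sub,
    is_transition = sub %in% TRANSITIONS,
    stringsAsFactors = FALSE
  )
}

#' Classify SNVs by genomic region
#'
#' `coding` if the position falls inside a CDS, `noncoding_genic` if inside
#' an RNA gene only, `intergenic` otherwise. A record overlapping several
#' CDSs is emitted once per gene context (`gene_id` disambiguates), so no
#' gene context is silently lost.
#'
#' @param records SNV record data.frame.
#' @param genes Gene-model data.frame.
#' @return The records with `region_class` and `gene_id` filled (possibly
#'   more rows than the input if CDSs overlap).
#' @export
classify_region <- function(records, genes) {
  if (nrow(records) == 0L) return(records)
  cds <- genes[genes$feature_class == "CDS", , drop = FALSE]
  rna <- genes[genes$feature_class == "rna_gene", , drop = FALSE]
  out <- vector("list", nrow(records))
  for (k in seq_len(nrow(records))) {
    rec <- records[k, , drop = FALSE]
    in_cds <- which(cds$contig_id == rec$contig &
                    cds$start <= rec$pos & cds$end >= rec$pos)
    if (length(in_cds)) {
      rows <- rec[rep(1L, length(in_cds)), , drop = FALSE]
      rows$region_class <- "coding"
      rows$gene_id <- cds$gene_id[in_cds]
      out[[k]] <- rows
    } else {
      in_rna <- which(rna$contig_id == rec$contig &
                      rna$start <= rec$pos & rna$end >= rec$pos)
      rec$region_class <- if (length(in_rna)) "noncoding_genic" else "intergenic"
      rec$gene_id <- if (length(in_rna)) rna$gene_id[in_rna[1L]] else NA_character_
      out[[k]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify coding SNVs as synonymous or nonsynonymous
#'
#' For each coding record the affected codon is extracted on the coding
#' strand (reverse complement for minus-strand genes), the alternate base is
#' substituted at its in-codon position, and both codons are translated with
#' the bacterial genetic code (NCBI table 11; identical to the standard code
#' for all sense-codon substitutions). A substitution is synonymous iff the
#' amino acids agree. An alternate allele creating a stop codon is
#' nonsynonymous with `aa_alt = "*"`. Reported `ref_base`/`alt_base` stay in
#' reference-strand orientation regardless of gene strand.
#'
#' @param records SNV records with `region_class` filled (see
#'   [classify_region()]).
#' @param genome `genome_annotation` the records were called against.
#' @param genes Gene-model data.frame.
#' @return Records with `mutation_class`, `codon_ref`, `codon_alt`,
#'   `aa_ref`, `aa_alt` filled for coding rows (`NA` elsewhere).
#' @export
classify_codon <- function(records, genome, genes) {
  records$codon_ref <- NA_character_
  records$codon_alt <- NA_character_
  records$aa_ref <- NA_character_
  records$aa_alt <- NA_character_
  if (nrow(records) == 0L) return(records)
  code <- genetic_code_11()
  coding <- which(records$region_class == "coding")
  for (k in coding) {
    gene <- genes[genes$gene_id == records$gene_id[k] &
                  genes$feature_class == "CDS", , drop = FALSE]
    if (nrow(gene) == 0L)
      stop("coding record references unknown CDS: ", records$gene_id[k],
           call. = FALSE)
    gene <- gene[1L, ]
    seq <- genome$contigs[[gene$contig_id]]
    pos <- records$pos[k]
    if (gene$strand == "+") {
      off <- pos - gene$start                 # 0-based offset within CDS
      codon_i <- off %/% 3L
      within <- off %% 3L + 1L
      cstart <- gene$start + 3L * codon_i
      codon_ref <- substr(seq, cstart, cstart + 2L)
      alt_cs <- records$alt_base[k]
    } else {
      off <- gene$end - pos                   # offset on the coding strand
      codon_i <- off %/% 3L
      within <- off %% 3L + 1L
      cend <- gene$end - 3L * codon_i
      codon_ref <- revcomp_chr(substr(seq, cend - 2L, cend))
      alt_cs <- chartr("ACGT", "TGCA", records$alt_base[k])
    }
    codon_alt <- codon_ref
    substr(codon_alt, within, within) <- alt_cs
    aa_ref <- unname(code[codon_ref])
    aa_alt <- unname(code[codon_alt])
    records$codon_ref[k] <- codon_ref
    records$codon_alt[k] <- codon_alt
    records$aa_ref[k] <- aa_ref
    records$aa_alt[k] <- aa_alt
    records$mutation_class[k] <- if (identical(aa_ref, aa_alt))
      "synonymous" else "nonsynonymous"
  }
  records
}

#' Call and fully classify SNVs for one sample/species
#'
#' Convenience composition of [call_snvs()], [classify_region()] and
#' [classify_codon()].
#'
#' @inheritParams call_snvs
#' @return Fully annotated SNV record data.frame.
#' @export
annotate_snvs <- function(pileup, genome, params = caller_params()) {
  if (is.null(genome$genes))
    stop("genome has no gene models; attach them or use call_snvs()",
         call. = FALSE)
  recs <- call_snvs(pileup, genome, params)
  recs <- classify_region(recs, genome$genes)
  classify_codon(recs, genome, genome$genes)
}

#' Substitution spectrum over the 12 directed types
#'
#' Counts each record into its directed substitution type (e.g. `A>G`) and
#' summarises transitions versus transversions. The 12 counts always
#' partition the record set.
#'
#' @param records SNV record data.frame.
#' @return List with `counts` (named vector over the 12 directed types),
#'   `transitions`, `transversions` and `titv` (transition/transversion
#'   ratio; `NA` when there are no transversions, rendered "." on export).
#' @export
substitution_spectrum <- function(records) {
  types <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, ">", b)))
  types <- types[substr(types, 1L, 1L) != substr(types, 3L, 3L)]
  counts <- setNames(integer(length(types)), sort(types))
  if (nrow(records)) {
    tab <- table(records$substitution)
    counts[names(tab)] <- as.integer(tab)
  }
  ti <- sum(counts[TRANSITIONS])
  tv <- sum(counts) - ti
  list(counts = counts, transitions = ti, transversions = tv,
       titv = if (tv == 0L) NA_real_ else ti / tv)
}

#' Per-locus position/frequency track
#'
#' One row per record, sorted by position; suitable for circular genome-plot
#' ingestion. Duplicate positions across samples are retained (disambiguated
#' by `sample_id` when present).
#'
#' @param records SNV record data.frame (optionally with `sample_id`).
#' @return data.frame sorted by `contig`, `pos` with columns `contig`, `pos`,
#'   `substitution`, `allele_freq` (plus `species_id`/`sample_id` if present).
#' @export
position_frequency_track <- function(records) {
  cols <- intersect(c("sample_id", "species_id", "contig", "pos",
                      "substitution", "allele_freq"), names(records))
  out <- records[, cols, drop = FALSE]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
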