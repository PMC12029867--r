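# External representations: FASTA, GFF3, pileup TSV, abundance TSV,
# metadata TSV, SNVs.tsv. Fixed dialects: all TSVs are UTF-8, tab-delimited,
# "." for missing. Coordinates are 1-based inclusive everywhere externally.
# Readers reject rather than silently repair; every writer round-trips through
# its paired reader (bit-identically modulo stated float precision).

#' Construct a genome annotation object
#'
#' Bundles a species label, its contig sequences and (optionally) its gene
#' models into the coordinate frame that every SNV lives in.
#'
#' @param species_id Short species label.
#' @param contigs Named character vector of nucleotide sequences over
#'   `A,C,G,T` (uppercased; `N` is tolerated only as an explicit mask).
#' @param genes Optional data.frame of gene models as returned by
#'   [read_gff3()]: columns `gene_id`, `contig_id`, `start`, `end`, `strand`,
#'   `feature_class`, `product`.
#' @return An object of class `genome_annotation` with elements `species_id`,
#'   `contigs`, `genes` and `total_length` (sum of contig lengths in bp).
#' @export
genome_annotation <- function(species_id, contigs, genes = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            is.character(contigs), length(contigs) >= 1L)
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("all contigs must be named", call. = FALSE)
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig ids: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "),
         call. = FALSE)
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig ", names(contigs)[bad][1L],
         " contains characters outside {A,C,G,T}", call. = FALSE)
  if (!is.null(genes) && nrow(genes) > 0L) {
    genes <- validate_gene_models(genes, contigs)
  }
  structure(
    list(species_id = species_id, contigs = contigs, genes = genes,
         total_length = sum(nchar(contigs))),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d contig(s), %s bp, %s gene model(s)\n",
              x$species_id, length(x$contigs),
              format(x$total_length, big.mark = ","),
              if (is.null(x$genes)) "no" else nrow(x$genes)))
  invisible(x)
}

validate_gene_models <- function(genes, contigs) {
  required <- c("gene_id", "contig_id", "start", "end", "strand",
                "feature_class", "product")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("gene model table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(genes$start > genes$end))
    stop("gene model with start > end: ",
         genes$gene_id[genes$start > genes$end][1L], call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'", call. = FALSE)
  if (!all(genes$feature_class %in% c("CDS", "rna_gene")))
    stop("feature_class must be 'CDS' or 'rna_gene'", call. = FALSE)
  unknown <- setdiff(genes$contig_id, names(contigs))
  if (length(unknown))
    stop("gene model references unknown contig: ", unknown[1L], call. = FALSE)
  clen <- nchar(contigs)[genes$contig_id]
  if (any(genes$start < 1L) || any(genes$end > clen))
    stop("gene model outside contig bounds: ",
         genes$gene_id[genes$start < 1L | genes$end > clen][1L], call. = FALSE)
  cds <- genes$feature_class == "CDS"
  badlen <- cds & ((genes$end - genes$start + 1L) %% 3L != 0L)
  if (any(badlen))
    stop("CDS length not divisible by 3: ",
         genes$gene_id[badlen][1L], call. = FALSE)
  genes
}

#' Read a FASTA file into a (partial) genome annotation
#'
#' Sequences are uppercased on read. IUPAC ambiguity codes are rejected by
#' default (with the offending record and position named) or masked to `N`.
#'
#' @param path FASTA file.
#' @param species_id Species label; default the file name without extension.
#' @param ambiguity `"reject"` (default) errors on any non-A/C/G/T character;
#'   `"mask"` replaces such characters with `N` (masked sites are never
#'   callable).
#' @return A `genome_annotation` with `genes = NULL`.
#' @export
read_fasta <- function(path, species_id = NULL, ambiguity = c("reject", "mask")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate contig ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  contigs <- toupper(as.character(seqs))
  names(contigs) <- ids
  bad <- regexpr("[^ACGT]", contigs)
  if (ambiguity == "reject") {
    hit <- which(bad > 0L)
    if (length(hit))
      stop(sprintf("non-ACGT character '%s' in record '%s' at position %d of %s",
                   substr(contigs[hit[1L]], bad[hit[1L]], bad[hit[1L]]),
                   ids[hit[1L]], bad[hit[1L]], path), call. = FALSE)
  } else {
    contigs <- gsub("[^ACGT]", "N", contigs)
  }
  genome_annotation(species_id %||% sub("\\.[^.]*$", "", basename(path)), contigs)
}

#' Write contigs of a genome annotation to FASTA
#'
#' @param genome A `genome_annotation`.
#' @param path Output file.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome$contigs)) {
    s <- genome$contigs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", id), substring(s, starts, starts + width - 1L)), con)
  }
  invisible(path)
}

# ---- GFF3 ------------------------------------------------------------------

#' Read gene models from a GFF3 file
#'
#' CDS rows become `feature_class = "CDS"`; the configured RNA feature types
#' become `feature_class = "rna_gene"`. A CDS whose length is not divisible by
#' 3 is excluded with a warning; `start > end` is a format error. Coordinates
#' are 1-based inclusive per the GFF3 standard.
#'
#' @param path GFF3 file.
#' @param rna_types GFF3 feature types mapped to `rna_gene`.
#' @return data.frame of gene models (`gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `feature_class`, `product`).
#' @export
read_gff3 <- function(path, rna_types = c("rRNA", "tRNA")) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gff <- ape::read.gff(path, GFF3 = TRUE)
  gff <- gff[gff$type %in% c("CDS", rna_types), , drop = FALSE]
  if (any(gff$start > gff$end))
    stop("GFF3 record with start > end at ", path, " (",
         gff$seqid[gff$start > gff$end][1L], ":",
         gff$start[gff$start > gff$end][1L], ")", call. = FALSE)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[hit] <- sub(paste0("^(;)?", key, "="), "", sub("^;", "", m))
    out
  }
  gene_id <- attr_field(gff$attributes, "ID")
  lt <- attr_field(gff$attributes, "locus_tag")
  gene_id[is.na(gene_id)] <- lt[is.na(gene_id)]
  gene_id[is.na(gene_id)] <- sprintf("feature_%04d", which(is.na(gene_id)))
  product <- attr_field(gff$attributes, "product")
  product[is.na(product)] <- "."
  genes <- data.frame(
    gene_id = gene_id,
    contig_id = as.character(gff$seqid),
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    strand = as.character(gff$strand),
    feature_class = ifelse(gff$type == "CDS", "CDS", "rna_gene"),
    product = product,
    stringsAsFactors = FALSE
  )
  badlen <- genes$feature_class == "CDS" &
    (genes$end - genes$start + 1L) %% 3L != 0L
  if (any(badlen)) {
    warning("excluded ", sum(badlen),
            " CDS with length not divisible by 3: ",
            paste(genes$gene_id[badlen], collapse = ", "), call. = FALSE)
    genes <- genes[!badlen, , drop = FALSE]
  }
  rownames(genes) <- NULL
  genes
}

#' Write gene models to GFF3
#'
#' Paired writer for [read_gff3()]; emits standard 9-column GFF3 with `ID`
#' and `product` attributes.
#'
#' @param genes Gene-model data.frame.
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "probiosnv") {
  type <- ifelse(genes$feature_class == "CDS", "CDS", "tRNA")
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;product=%s",
                   genes$contig_id, source, type,
                   genes$start, genes$end, genes$strand,
                   ifelse(genes$feature_class == "CDS", "0", "."),
                   genes$gene_id, genes$product)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# ---- pileup TSV ------------------------------------------------------------

#' Read a per-sample nucleotide pileup table
#'
#' The canonical alignment-evidence format: one row per reference position
#' with columns `contig`, `pos` (1-based), and read counts `A`, `C`, `G`, `T`.
#'
#' @param path Pileup TSV.
#' @return data.frame with the five columns above plus `depth`.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path, call. = FALSE)
  p <- fread(path, sep = "\t", data.table = FALSE, showProgress = FALSE)
  required <- c("contig", "pos", "A", "C", "G", "T")
  if (!identical(names(p)[seq_along(required)], required))
    stop("pileup ", path, " must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  cnt <- as.matrix(p[, BASES])
  if (any(cnt < 0L) || any(cnt != floor(cnt)))
    stop("pileup counts must be non-negative integers (row ",
         which(rowSums(cnt < 0 | cnt != floor(cnt)) > 0)[1L], ")", call. = FALSE)
  if (any(p$pos < 1L))
    stop("pileup positions must be >= 1 (1-based)", call. = FALSE)
  p$depth <- as.integer(rowSums(cnt))
  p[, c(required, "depth")]
}

#' Write a pileup table
#' @param pileup data.frame with columns `contig`, `pos`, `A`, `C`, `G`, `T`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  fwrite(pileup[, c("contig", "pos", BASES)], path, sep = "\t")
  invisible(path)
}

# ---- sample metadata -------------------------------------------------------

#' Read the sample metadata table
#'
#' Columns `sample_id`, `group` (`treatment`/`control`), `segment`
#' (`small`/`large`), `day` (1/3/7), `replicate`. The combination
#' (group, segment, day, replicate) must be unique.
#'
#' @param path Metadata TSV.
#' @return data.frame of sample metadata.
#' @export
read_metadata <- function(path) {
  m <- fread(path, sep = "\t", data.table = FALSE, showProgress = FALSE,
             colClasses = list(character = c("sample_id", "group", "segment")))
  validate_metadata(m)
}

validate_metadata <- function(m) {
  required <- c("sample_id", "group", "segment", "day", "replicate")
  if (!all(required %in% names(m)))
    stop("metadata must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  if (!all(m$group %in% c("treatment", "control")))
    stop("metadata group must be 'treatment' or 'control'", call. = FALSE)
  if (!all(m$segment %in% c("small", "large")))
    stop("metadata segment must be 'small' or 'large'", call. = FALSE)
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  key <- paste(m$group, m$segment, m$day, m$replicate)
  if (anyDuplicated(key))
    stop("metadata (group, segment, day, replicate) not unique", call. = FALSE)
  m[, required]
}

#' Write the sample metadata table
#' @param metadata Metadata data.frame.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  fwrite(validate_metadata(metadata), path, sep = "\t")
  invisible(path)
}

# ---- abundance table -------------------------------------------------------

#' Read a species-by-sample relative abundance table
#'
#' First column species names, remaining columns one per sample. Columns are
#' renormalized to sum to 1 on load (tolerating percent-scaled input); the
#' original scale is reported via a message.
#'
#' @param path Abundance TSV.
#' @return Numeric matrix (species x samples), each column summing to 1.
#' @export
read_abundance <- function(path) {
  a <- fread(path, sep = "\t", data.table = FALSE, showProgress = FALSE)
  if (ncol(a) < 2L) stop("abundance table needs >= 1 sample column", call. = FALSE)
  species <- as.character(a[[1L]])
  if (anyDuplicated(species)) stop("duplicate species labels", call. = FALSE)
  mat <- as.matrix(a[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(mat))) stop("duplicate sample labels", call. = FALSE)
  if (any(mat < 0)) stop("abundances must be non-negative", call. = FALSE)
  rownames(mat) <- species
  cs <- colSums(mat)
  if (any(cs == 0)) stop("all-zero sample column: ",
                         colnames(mat)[cs == 0][1L], call. = FALSE)
  scale <- stats::median(cs)
  if (abs(scale - 1) > 1e-6)
    message(sprintf("abundance columns rescaled to sum 1 (input scale ~%.4g)", scale))
  sweep(mat, 2L, cs, "/")
}

#' Write a species-by-sample abundance table
#' @param table Numeric matrix, species as rows.
#' @param path Output TSV.
#' @param digits Decimal digits for abundances.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, digits = 8L) {
  df <- data.frame(species = rownames(table),
                   formatC(table, digits = digits, format = "f"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("species", colnames(table))
  fwrite(df, path, sep = "\t")
  invisible(path)
}

# ---- SNVs.tsv --------------------------------------------------------------

#' Write called/filtered SNV records to the SNVs.tsv dialect
#'
#' Fixed column order (`species_id`, `contig`, `pos`, `ref_base`, `alt_base`,
#' `ref_count`, `alt_count`, `depth`, `allele_freq`, `region_class`,
#' `mutation_class`, `gene_id`, `substitution`, `is_transition`), allele
#' frequency at 6 decimals, "." for missing. An optional `sample_id` column
#' is preserved when present. Round-trips through [read_snv_table()].
#'
#' @param records SNV record data.frame.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_snv_table <- function(records, path) {
  cols <- SNV_TSV_COLUMNS
  if ("sample_id" %in% names(records)) cols <- c("sample_id", cols)
  if (nrow(records) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("SNV records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- records[, cols, drop = FALSE]
  out$allele_freq <- sprintf("%.6f", out$allele_freq)
  out$mutation_class[is.na(out$mutation_class)] <- "."
  out$gene_id[is.na(out$gene_id)] <- "."
  out$is_transition <- ifelse(out$is_transition, "true", "false")
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an SNVs.tsv file
#'
#' @param path SNVs.tsv written by [write_snv_table()].
#' @return SNV record data.frame; `mutation_class` is `NA` outside coding
#'   regions, `gene_id` is `NA` for intergenic records.
#' @export
read_snv_table <- function(path) {
  if (!file.exists(path)) stop("SNV table not found: ", path, call. = FALSE)
  r <- fread(path, sep = "\t", data.table = FALSE, showProgress = FALSE,
             colClasses = list(character = c("mutation_class", "gene_id",
                                             "is_transition")))
  missing_cols <- setdiff(SNV_TSV_COLUMNS, names(r))
  if (length(missing_cols))
    stop("malformed SNV table ", path, ": missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(r) == 0L) return(r)
  bad <- !(r$ref_base %in% BASES) | !(r$alt_base %in% BASES) |
    r$ref_base == r$alt_base | r$pos < 1L | r$depth < 1L |
    r$allele_freq <= 0 | r$allele_freq > 1 |
    !(r$region_class %in% REGION_CLASSES) |
    !(r$is_transition %in% c("true", "false"))
  if (any(bad))
    stop("malformed SNV record at data row ", which(bad)[1L], " of ", path,
         call. = FALSE)
  r$mutation_class[r$mutation_class == "."] <- NA_character_
  r$gene_id[r$gene_id == "."] <- NA_character_
  r$is_transition <- r$is_transition == "true"
  r
}
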