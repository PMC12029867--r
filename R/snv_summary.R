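# Downstream summaries: SNV count matrices, SNV-vs-abundance regression,
# mutation-class breakdowns, and the codon-level change verifier.

#' Species-by-day SNV count matrix
#'
#' Zero-filled for screened species with no retained SNVs (species with no
#' variants are part of the reported result, not dropped).
#'
#' @param records Retained SNV records carrying `species_id` and `day`.
#' @param species Character vector of species to report (rows).
#' @param days Days to report (columns), default `c(1, 3, 7)`.
#' @return Integer matrix species x day.
#' @export
snv_count_matrix <- function(records, species, days = c(1L, 3L, 7L)) {
  m <- matrix(0L, nrow = length(species), ncol = length(days),
              dimnames = list(species, paste0("day", days)))
  if (nrow(records)) {
    keep <- records$species_id %in% species & records$day %in% days
    tab <- table(factor(records$species_id[keep], levels = species),
                 factor(records$day[keep], levels = days))
    m[, ] <- as.integer(tab)
  }
  m
}

#' Ordinary least squares of SNV count on relative abundance
#'
#' Fits `count ~ abundance`, tests the slope two-sided, and returns a 95%
#' pointwise confidence band around the fitted line (symmetric about it).
#'
#' @param counts Numeric vector of SNV counts.
#' @param abundances Paired relative abundances (same length, n >= 3,
#'   non-constant).
#' @return List of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `n`, and `band` (data.frame `x`, `fit`, `lwr`,
#'   `upr`, `half_width`).
#' @export
abundance_snv_regression <- function(counts, abundances) {
  stopifnot(length(counts) == length(abundances))
  n <- length(counts)
  if (n < 3L) stop("need n >= 3 paired observations", call. = FALSE)
  if (var(abundances) == 0)
    stop("zero variance in abundances; slope undefined", call. = FALSE)
  df <- data.frame(x = abundances, y = counts)
  fit <- lm(y ~ x, data = df)
  # exact fits are legitimate inputs; summary.lm warns on them
  sm <- suppressWarnings(summary(fit))
  ci <- predict(fit, newdata = df, interval = "confidence", level = 0.95)
  band <- data.frame(x = df$x, fit = ci[, "fit"], lwr = ci[, "lwr"],
                     upr = ci[, "upr"],
                     half_width = (ci[, "upr"] - ci[, "lwr"]) / 2)
  p_slope <- sm$coefficients["x", "Pr(>|t|)"]
  structure(list(slope = unname(coef(fit)["x"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared,
                 p_slope = if (is.nan(p_slope)) 1 else p_slope,
                 n = n, band = band),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> n=%d slope=%.4g (p=%.3g) R^2=%.3f\n",
              x$n, x$slope, x$p_slope, x$r_squared))
  invisible(x)
}

#' Mutation-class breakdown per species and day
#'
#' Partitions retained SNVs into coding-synonymous, coding-nonsynonymous,
#' noncoding-genic and intergenic counts, with proportions over the
#' per-(species, day) total. Cells with no SNVs get zero counts and `NA`
#' proportions (rendered "." on export).
#'
#' @param records Retained SNV records with `species_id`, `day`,
#'   `region_class`, `mutation_class`.
#' @param species Species to report; default those present.
#' @param days Days to report, default `c(1, 3, 7)`.
#' @return data.frame with one row per (species, day): counts
#'   `n_synonymous`, `n_nonsynonymous`, `n_noncoding_genic`, `n_intergenic`,
#'   `n_total` and matching `prop_*` columns.
#' @export
mutation_breakdown <- function(records, species = NULL, days = c(1L, 3L, 7L)) {
  if (is.null(species)) species <- sort(unique(records$species_id))
  grid <- expand.grid(species_id = species, day = days,
                      stringsAsFactors = FALSE)
  cls <- function(rc, mc) {
    ifelse(rc == "coding" & mc == "synonymous", "synonymous",
    ifelse(rc == "coding" & mc == "nonsynonymous", "nonsynonymous",
    ifelse(rc == "noncoding_genic", "noncoding_genic", "intergenic")))
  }
  cats <- c("synonymous", "nonsynonymous", "noncoding_genic", "intergenic")
  out <- grid
  for (cc in cats) out[[paste0("n_", cc)]] <- 0L
  if (nrow(records)) {
    k <- cls(records$region_class, records$mutation_class)
    tab <- table(paste(records$species_id, records$day),
                 factor(k, levels = cats))
    key <- paste(grid$species_id, grid$day)
    hit <- key %in% rownames(tab)
    for (cc in cats)
      out[hit, paste0("n_", cc)] <- as.integer(tab[key[hit], cc])
  }
  out$n_total <- rowSums(out[, paste0("n_", cats)])
  for (cc in cats)
    out[[paste0("prop_", cc)]] <-
      ifelse(out$n_total > 0, out[[paste0("n_", cc)]] / out$n_total, NA_real_)
  out
}

#' Verify a codon-level worked example from paired sequence contexts
#'
#' Aligns two equal-length, in-frame nucleotide strings codon by codon,
#' translates both with the bacterial genetic code, and reports every
#' changed codon with its amino acids and a synonymous/nonsynonymous
#' verdict.
#'
#' @param control_context,variant_context Equal-length nucleotide strings;
#'   length minus `frame_offset` must be divisible by 3.
#' @param frame_offset Bases to skip before the first complete codon (0-2).
#' @return List with `report` (data.frame `codon_index`, `codon_ref`,
#'   `codon_alt`, `aa_ref`, `aa_alt`, `status`), `n_nonsynonymous`,
#'   `n_synonymous` and `diff_positions` (1-based offsets of differing
#'   bases in the input strings).
#' @export
verify_codon_example <- function(control_context, variant_context,
                                 frame_offset = 0L) {
  a <- toupper(control_context); b <- toupper(variant_context)
  if (nchar(a) != nchar(b))
    stop("contexts must have equal length", call. = FALSE)
  if (frame_offset < 0L || frame_offset > 2L)
    stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  if ((nchar(a) - frame_offset) %% 3L != 0L)
    stop("in-frame length not divisible by 3", call. = FALSE)
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("contexts must be over A/C/G/T", call. = FALSE)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  diff_positions <- which(ca != cb)
  starts <- seq(frame_offset + 1L, nchar(a) - 2L, by = 3L)
  code <- genetic_code_11()
  cod_a <- substring(a, starts, starts + 2L)
  cod_b <- substring(b, starts, starts + 2L)
  changed <- which(cod_a != cod_b)
  report <- data.frame(
    codon_index = changed,
    codon_ref = cod_a[changed], codon_alt = cod_b[changed],
    aa_ref = unname(code[cod_a[changed]]),
    aa_alt = unname(code[cod_b[changed]]),
    stringsAsFactors = FALSE
  )
  report$status <- ifelse(report$aa_ref == report$aa_alt,
                          "synonymous", "nonsynonymous")
  list(report = report,
       n_nonsynonymous = sum(report$status == "nonsynonymous"),
       n_synonymous = sum(report$status == "synonymous"),
       diff_positions = diff_positions)
}
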