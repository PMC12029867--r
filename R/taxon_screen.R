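# Spearman screening of taxa against the focal probiotic.
#
# rho is the tie-aware rank correlation (Pearson correlation of midranks).
# The two-sided p value is exact by full enumeration of all n! permutations
# of the observed y values for n <= exact_n (default 8) - which is also
# tie-aware - and uses the t approximation otherwise. The screen applies the
# strict thresholds |rho| > 0.5 and p < 0.05.

# all permutations of 1..n as an (n! x n) matrix; n <= 8 keeps this small
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Tie-aware Spearman correlation with exact small-sample p value
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param exact_n Largest n for which the two-sided p value is computed by
#'   full enumeration of the n! rank permutations (default 8); beyond that
#'   the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used.
#' @return List with `rho`, `p_value`, `n`, `method` (`"exact"` or
#'   `"t_approx"`), `estimable` (FALSE when either vector is constant, in
#'   which case rho and p are `NA` and the result is excluded from any
#'   screen).
#' @export
spearman_test <- function(x, y, exact_n = 8L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined", estimable = FALSE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_n) {
    perms <- permutations_of(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- (matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tt), df = n - 2))
    p <- max(p, .Machine$double.xmin)
    method <- "t_approx"
  }
  list(rho = rho, p_value = p, n = n, method = method, estimable = TRUE)
}

#' Screen taxa correlated with the focal probiotic
#'
#' Computes the Spearman correlation of every candidate species with the
#' focal species over the selected samples and keeps species passing the
#' strict thresholds `p < p_max` and `|rho| > rho_min`. By default the
#' correlation pools all treatment-arm samples within one segment
#' (n = 3 days x replicates); the sample set is configurable because the
#' emulated workflow leaves it open.
#'
#' @param table Species x samples relative abundance matrix.
#' @param metadata Sample metadata (see [read_metadata()]); may be `NULL`
#'   if `samples` is given explicitly.
#' @param focal_species Row name of the focal taxon; must be present.
#' @param segment Restrict to `"small"` or `"large"` (NULL = both).
#' @param group Restrict to `"treatment"` (default), `"control"`, or NULL
#'   for both arms.
#' @param samples Explicit character vector of sample ids (overrides
#'   `metadata`/`segment`/`group`).
#' @param p_max,rho_min Strict screen thresholds (defaults 0.05 and 0.5).
#' @param p_adjust Optional multiple-testing adjustment for the screen
#'   (`"none"` default; `"BH"` available).
#' @return data.frame of class `correlation_edges` (one row per passing
#'   species): `species_id`, `rho`, `p_value`, `sign`, `n`; the focal
#'   species name is attached as attribute `focal`. Species with undefined
#'   rho (constant abundance) are excluded and listed in attribute
#'   `unestimable`.
#' @export
screen_taxa <- function(table, metadata = NULL, focal_species,
                        segment = NULL, group = "treatment", samples = NULL,
                        p_max = 0.05, rho_min = 0.5, p_adjust = "none") {
  if (!focal_species %in% rownames(table))
    stop("focal species '", focal_species, "' absent from table",
         call. = FALSE)
  if (is.null(samples)) {
    if (is.null(metadata)) {
      samples <- colnames(table)
    } else {
      keep <- rep(TRUE, nrow(metadata))
      if (!is.null(segment)) keep <- keep & metadata$segment == segment
      if (!is.null(group)) keep <- keep & metadata$group == group
      samples <- metadata$sample_id[keep]
    }
  }
  missing_s <- setdiff(samples, colnames(table))
  if (length(missing_s))
    stop("samples absent from abundance table: ", missing_s[1L],
         call. = FALSE)
  sub <- table[, samples, drop = FALSE]
  focal <- sub[focal_species, ]
  candidates <- setdiff(rownames(sub), focal_species)
  rows <- list(); unest <- character()
  for (sp in candidates) {
    st <- spearman_test(focal, sub[sp, ])
    if (!st$estimable) { unest <- c(unest, sp); next }
    rows[[sp]] <- data.frame(species_id = sp, rho = st$rho,
                             p_value = st$p_value, n = st$n,
                             stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(), rho = numeric(),
               p_value = numeric(), n = integer(), stringsAsFactors = FALSE)
  if (nrow(edges)) edges$p_value <- p.adjust(edges$p_value, p_adjust)
  pass <- edges$p_value < p_max & abs(edges$rho) > rho_min   # both strict
  edges <- edges[pass, , drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "+", "-")
  edges <- edges[order(-abs(edges$rho)),
                 c("species_id", "rho", "p_value", "sign", "n")]
  rownames(edges) <- NULL
  attr(edges, "focal") <- focal_species
  attr(edges, "unestimable") <- unest
  class(edges) <- c("correlation_edges", "data.frame")
  edges
}

#' Export screen edges as a network-ready TSV
#'
#' Two-column source/target plus `rho` and `p_value`, loadable as a
#' Cytoscape edge table. Values round-trip at the printed precision
#' (6 decimals).
#'
#' @param edges Result of [screen_taxa()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
edge_table_export <- function(edges, path) {
  focal <- attr(edges, "focal") %||% "focal"
  out <- data.frame(source = rep(focal, nrow(edges)),
                    target = edges$species_id,
                    rho = sprintf("%.6f", edges$rho),
                    p_value = sprintf("%.6g", edges$p_value),
                    stringsAsFactors = FALSE)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
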