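# Supporting community statistics: alpha diversity, group tests,
# Bray-Curtis, PCoA, PERMANOVA. Thin, contract-enforcing surfaces over the
# vegan/stats machinery a practitioner would use directly.

#' Shannon and Simpson alpha diversity per sample
#'
#' Shannon is `-sum(p log p)` in nats over `p > 0`; Simpson is the
#' Gini-Simpson index `1 - sum(p^2)` by default (the convention of the
#' package family this field uses), with the plain dominance `sum(p^2)`
#' available by flag. Both are invariant to species order and to
#' zero-abundance species.
#'
#' @param table Species x samples matrix of relative abundances (columns sum
#'   to 1; renormalized internally after a tolerance check).
#' @param simpson `"gini"` (default, `1 - sum p^2`) or `"dominance"`
#'   (`sum p^2`).
#' @return data.frame with `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(table, simpson = c("gini", "dominance")) {
  simpson <- match.arg(simpson)
  cs <- colSums(table)
  if (any(cs <= 0)) stop("all-zero sample: ",
                         colnames(table)[cs <= 0][1L], call. = FALSE)
  if (any(abs(cs - 1) > 1e-6))
    stop("abundance columns must sum to 1 (renormalize on load)",
         call. = FALSE)
  p <- t(sweep(table, 2L, cs, "/"))           # samples x species for vegan
  sh <- vegan::diversity(p, index = "shannon")
  si <- vegan::diversity(p, index = "simpson")
  if (simpson == "dominance") si <- 1 - si
  data.frame(sample_id = colnames(table), shannon = unname(sh),
             simpson = unname(si), stringsAsFactors = FALSE)
}

#' Omnibus + pairwise group comparison with a normality/homogeneity gate
#'
#' `method = "auto"` applies Shapiro-Wilk per group and Levene's test
#' (both at alpha = 0.05); if no gate rejects, one-way ANOVA with Tukey HSD
#' pairwise comparisons is used, otherwise Kruskal-Wallis (tie-corrected H,
#' chi-square approximation) with Dunn pairwise z tests. The degenerate
#' all-values-equal case returns H = 0, p = 1.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (same length as `values`), >= 2 groups with
#'   >= 2 observations each.
#' @param method `"auto"`, `"anova_tukey"` or `"kruskal"`.
#' @param p_adjust Adjustment applied to pairwise p values (`"none"`
#'   default, matching the practice the package mirrors; `"BH"` available).
#' @return List with `method_used`, `omnibus_p`, `statistic`, `pairwise`
#'   (data.frame `group1`, `group2`, `p_value`) and `gates` (Shapiro/Levene
#'   p values when `method = "auto"`).
#' @export
group_compare <- function(values, groups,
                          method = c("auto", "anova_tukey", "kruskal"),
                          p_adjust = "none") {
  method <- match.arg(method)
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  n_per <- table(g)
  if (any(n_per < 2L))
    stop("every group needs >= 2 observations (offender: ",
         names(n_per)[n_per < 2L][1L], ")", call. = FALSE)
  gates <- NULL
  if (method == "auto") {
    degenerate <- vapply(split(values, g), function(v) length(unique(v)) == 1L,
                         logical(1))
    if (all(degenerate) || length(unique(values)) == 1L) {
      method <- "kruskal"
    } else {
      sw <- vapply(split(values, g), function(v) {
        if (length(unique(v)) == 1L) return(0)   # constant group: not normal
        shapiro.test(v)$p.value
      }, numeric(1))
      lev <- car::leveneTest(values ~ g)[["Pr(>F)"]][1L]
      gates <- list(shapiro_p = sw, levene_p = lev)
      method <- if (all(sw > 0.05) && lev > 0.05) "anova_tukey" else "kruskal"
    }
  }
  if (method == "anova_tukey") {
    fit <- aov(values ~ g)
    an <- summary(fit)[[1L]]
    tuk <- TukeyHSD(fit)$g
    pairs <- do.call(rbind, strsplit(rownames(tuk), "-", fixed = TRUE))
    pairwise <- data.frame(group1 = pairs[, 2L], group2 = pairs[, 1L],
                           p_value = p.adjust(tuk[, "p adj"], p_adjust),
                           stringsAsFactors = FALSE)
    out <- list(method_used = "anova_tukey",
                omnibus_p = an[["Pr(>F)"]][1L],
                statistic = an[["F value"]][1L],
                pairwise = pairwise, gates = gates)
  } else {
    if (length(unique(values)) == 1L) {
      combos <- utils::combn(levels(g), 2L)
      out <- list(method_used = "kruskal", omnibus_p = 1, statistic = 0,
                  pairwise = data.frame(group1 = combos[1L, ],
                                        group2 = combos[2L, ],
                                        p_value = 1,
                                        stringsAsFactors = FALSE),
                  gates = gates)
    } else {
      kw <- kruskal.test(values, g)
      dunn <- dunn_pairwise(values, g)
      dunn$p_value <- p.adjust(dunn$p_value, p_adjust)
      out <- list(method_used = "kruskal",
                  omnibus_p = kw$p.value,
                  statistic = unname(kw$statistic),
                  pairwise = dunn, gates = gates)
    }
  }
  rownames(out$pairwise) <- NULL
  out
}

# Dunn's pairwise post-hoc on ranks with tie correction
dunn_pairwise <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  combos <- utils::combn(levels(g), 2L)
  z <- p <- numeric(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    a <- combos[1L, j]; b <- combos[2L, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = combos[1L, ], group2 = combos[2L, ], z = z,
             p_value = p, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i,j) = sum |x - y| / sum (x + y)`: symmetric, zero diagonal, in
#' `[0, 1]` for non-negative data.
#'
#' @param table Species x samples matrix of non-negative abundances.
#' @return Symmetric distance matrix (samples x samples).
#' @export
bray_curtis <- function(table) {
  if (any(table < 0)) stop("abundances must be non-negative", call. = FALSE)
  cs <- colSums(table)
  if (any(cs == 0))
    stop("all-zero sample (Bray-Curtis undefined): ",
         colnames(table)[cs == 0][1L], call. = FALSE)
  as.matrix(vegan::vegdist(t(table), method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centering plus eigendecomposition. Axes are ordered by eigenvalue;
#' negative eigenvalues (Bray-Curtis is not Euclidean) are excluded from the
#' proportion denominator and their count is reported. No Cailliez
#' correction is applied.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return List of class `pcoa_result`: `points` (samples x positive axes),
#'   `eigenvalues` (positive ones), `proportions` (fraction of the
#'   positive-eigenvalue total, non-increasing), `n_negative`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; expected here
  mds <- suppressWarnings(cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- mds$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- which(eig > tol)
  pts <- mds$points[, pos, drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_along(pos))
  structure(list(points = pts, eigenvalues = eig[pos],
                 proportions = eig[pos] / sum(eig[pos]),
                 n_negative = sum(eig < -tol)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d positive axes (%d negative eigenvalues dropped)\n",
              nrow(x$points), ncol(x$points), x$n_negative))
  cat("axis proportions:",
      paste(sprintf("%.1f%%", 100 * x$proportions[seq_len(min(4, length(x$proportions)))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from the among/within sum-of-squares partition of the distance
#' matrix, with a permutation p value
#' `(1 + #permuted F >= observed F) / (1 + n_perm)`. Deterministic given
#' `seed`.
#'
#' @param d Symmetric distance matrix.
#' @param groups Group labels, one per sample; >= 2 groups, and no
#'   singleton group when only 2 groups exist.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @return List with `pseudo_f`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL) {
  d <- as.matrix(d)
  g <- factor(groups)
  if (length(g) != nrow(d)) stop("one group label per sample", call. = FALSE)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  sizes <- table(g)
  if (nlevels(g) == 2L && any(sizes < 2L))
    stop("a group of size 1 with only 2 groups is untestable", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(g = g)
  fit <- vegan::adonis2(as.dist(d) ~ g, data = df, permutations = n_perm)
  list(pseudo_f = fit$F[1L], p_value = fit$`Pr(>F)`[1L],
       n_perm = as.integer(n_perm))
}
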