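# Two-stage set-theoretic provenance filter.
#
# Variant identity (the "SNV key") is (species_id, contig, pos, alt_base):
# two different alternate bases at one position are distinct variants, and
# neither allele frequency nor day enters the identity.
#
# Stage 1 (reference-selection artifacts): remove every treatment-arm key
# present in the union of control-arm sets - over all days of the segment by
# default, since a reference-vs-resident-strain discrepancy is visible in
# controls regardless of day.
# Stage 2 (natural temporal variation): remove keys present in the
# day-matched control set. Both stages are set subtractions against fixed
# sets, so their order cannot change the retained set; it only changes stage
# attribution, which is fixed as artifact-first.

snv_key <- function(df) {
  paste(df$species_id, df$contig, df$pos, df$alt_base, sep = "\r")
}

#' Aggregate per-sample SNV records to group-level variant sets
#'
#' @param records SNV record data.frame carrying a `sample_id` column
#'   (stacked over samples).
#' @param metadata Sample metadata resolving every `sample_id`.
#' @param mode `"union"` (default: present in >= 1 replicate),
#'   `"majority"` (present in more than half of the cell's replicates) or
#'   `"intersection"` (present in all of them).
#' @return data.frame with one row per (group, segment, day, species,
#'   variant): metadata columns, the SNV key columns, `n_support` (number
#'   of replicates carrying the variant), summed read counts, mean allele
#'   frequency, and the annotation columns of the first supporting record.
#' @export
aggregate_replicates <- function(records, metadata,
                                 mode = c("union", "majority",
                                          "intersection")) {
  mode <- match.arg(mode)
  if (!"sample_id" %in% names(records))
    stop("records must carry a sample_id column", call. = FALSE)
  unknown <- setdiff(unique(records$sample_id), metadata$sample_id)
  if (length(unknown))
    stop("unknown sample id in records: ", unknown[1L], call. = FALSE)
  m <- metadata[match(records$sample_id, metadata$sample_id), ]
  rec <- cbind(records,
               m[, c("group", "segment", "day")],
               row.names = NULL)
  cell_reps <- stats::aggregate(replicate ~ group + segment + day,
                                metadata, length)
  key <- paste(rec$group, rec$segment, rec$day, snv_key(rec), sep = "\n")
  first <- !duplicated(key)
  agg <- rec[first, , drop = FALSE]
  agg$n_support <- as.integer(table(key)[key[first]])
  sums <- rowsum(rec[, c("ref_count", "alt_count", "depth")], key)
  agg[, c("ref_count", "alt_count", "depth")] <- sums[key[first], ]
  agg$allele_freq <- round(as.numeric(
    rowsum(rec$allele_freq, key)[key[first], 1L] / agg$n_support), 6L)
  agg$sample_id <- NULL
  ri <- match(paste(agg$group, agg$segment, agg$day),
              paste(cell_reps$group, cell_reps$segment, cell_reps$day))
  n_rep <- cell_reps$replicate[ri]
  keep <- switch(mode,
                 union = rep(TRUE, nrow(agg)),
                 majority = agg$n_support > n_rep / 2,
                 intersection = agg$n_support == n_rep)
  agg <- agg[keep, , drop = FALSE]
  agg <- agg[order(agg$group, agg$segment, agg$day, agg$species_id,
                   agg$contig, agg$pos, agg$alt_base), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Stage 1: remove reference-selection artifacts
#'
#' Removes every treatment-arm variant key present in the union of the
#' control sets (all days of the same segment by default).
#'
#' @param treatment_set,control_set SNV record data.frames (same segment and
#'   species frame on both sides); `control_set` is the union of control
#'   observations the stage is scoped to.
#' @return List with `surviving` and `removed` record data.frames.
#' @export
remove_reference_artifacts <- function(treatment_set, control_set) {
  hit <- snv_key(treatment_set) %in% snv_key(control_set)
  list(surviving = treatment_set[!hit, , drop = FALSE],
       removed = treatment_set[hit, , drop = FALSE])
}

#' Stage 2: remove natural (temporal) variation
#'
#' Removes surviving keys present in the day-matched control set; what
#' remains are the intervention-induced candidates.
#'
#' @param surviving_set Stage-1 survivors for one (segment, day, species).
#' @param control_day_set Control-arm records of the same day and segment.
#' @return List with `retained` and `removed` record data.frames.
#' @export
remove_natural_variation <- function(surviving_set, control_day_set) {
  hit <- snv_key(surviving_set) %in% snv_key(control_day_set)
  list(retained = surviving_set[!hit, , drop = FALSE],
       removed = surviving_set[hit, , drop = FALSE])
}

#' Run the full two-stage provenance filter
#'
#' Aggregates per-sample records to group-level sets, then, for every
#' (species, segment, day), subtracts the stage-1 negative-control set and
#' the stage-2 day-matched control set from the treatment set. Enforces the
#' bookkeeping invariant `n_input = n_removed_artifact + n_removed_natural +
#' n_retained` per cell (removals are disjoint; artifact takes precedence).
#'
#' @param records Stacked per-sample SNV records with `sample_id`.
#' @param metadata Sample metadata.
#' @param mode Replicate aggregation mode (see [aggregate_replicates()]).
#' @param stage1_scope `"all_days"` (default) or `"day_matched"`: which
#'   control observations count as reference-artifact evidence.
#' @return List of class `filter_result`: `retained` (records labelled
#'   `provenance = "induced"`), `removed_artifact`, `removed_natural`, and
#'   `report` (a `filter_report` data.frame with per-cell counts).
#' @export
filter_induced_snvs <- function(records, metadata, mode = "union",
                                stage1_scope = c("all_days", "day_matched")) {
  stage1_scope <- match.arg(stage1_scope)
  agg <- aggregate_replicates(records, metadata, mode)
  treat <- agg[agg$group == "treatment", , drop = FALSE]
  ctrl <- agg[agg$group == "control", , drop = FALSE]
  cells <- unique(treat[, c("species_id", "segment", "day")])
  retained <- removed_a <- removed_n <- list()
  rep_rows <- list()
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    t_set <- treat[treat$species_id == ci$species_id &
                   treat$segment == ci$segment & treat$day == ci$day, ,
                   drop = FALSE]
    c_seg <- ctrl[ctrl$species_id == ci$species_id &
                  ctrl$segment == ci$segment, , drop = FALSE]
    c_stage1 <- if (stage1_scope == "all_days") c_seg else
      c_seg[c_seg$day == ci$day, , drop = FALSE]
    s1 <- remove_reference_artifacts(t_set, c_stage1)
    c_day <- c_seg[c_seg$day == ci$day, , drop = FALSE]
    s2 <- remove_natural_variation(s1$surviving, c_day)
    n_in <- nrow(t_set)
    n_art <- nrow(s1$removed); n_nat <- nrow(s2$removed)
    n_ret <- nrow(s2$retained)
    if (n_in != n_art + n_nat + n_ret)
      stop("internal error: filter conservation violated for ",
           ci$species_id, "/", ci$segment, "/day", ci$day, call. = FALSE)
    rep_rows[[i]] <- data.frame(species_id = ci$species_id,
                                segment = ci$segment, day = ci$day,
                                n_input = n_in, n_removed_artifact = n_art,
                                n_removed_natural = n_nat,
                                n_retained = n_ret, stringsAsFactors = FALSE)
    retained[[i]] <- s2$retained
    removed_a[[i]] <- s1$removed
    removed_n[[i]] <- s2$removed
  }
  bindr <- function(lst) {
    out <- do.call(rbind, lst)
    if (is.null(out)) out <- treat[0, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  ret <- bindr(retained)
  if (nrow(ret)) ret$provenance <- "induced"
  report <- bindr(rep_rows)
  class(report) <- c("filter_report", "data.frame")
  structure(list(retained = ret, removed_artifact = bindr(removed_a),
                 removed_natural = bindr(removed_n), report = report),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d cells: %d input, %d artifact, %d natural, %d retained (induced)\n",
              nrow(x$report), sum(x$report$n_input),
              sum(x$report$n_removed_artifact),
              sum(x$report$n_removed_natural), sum(x$report$n_retained)))
  invisible(x)
}

#' Write / read the per-cell filter report
#' @param report `filter_report` data.frame.
#' @param path TSV path.
#' @return `path` (write) or the report (read).
#' @export
write_filter_report <- function(report, path) {
  fwrite(as.data.frame(report), path, sep = "\t")
  invisible(path)
}

#' @rdname write_filter_report
#' @export
read_filter_report <- function(path) {
  r <- fread(path, sep = "\t", data.table = FALSE, showProgress = FALSE)
  bad <- r$n_input !=
    r$n_removed_artifact + r$n_removed_natural + r$n_retained
  if (any(bad))
    stop("filter report violates conservation at row ", which(bad)[1L],
         call. = FALSE)
  class(r) <- c("filter_report", "data.frame")
  r
}
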