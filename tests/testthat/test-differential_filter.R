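# Replicate aggregation and the two-stage provenance filter.

test_that("replicate aggregation modes behave as specified", {
  meta <- tiny_metadata(n_rep = 6L)
  treps <- meta$sample_id[meta$group == "treatment" & meta$day == 1L]
  # variant at pos 100 in 1 of 6 replicates; pos 200 in 4 of 6
  recs <- rbind(
    make_keyed_records(treps[1], "sp01", 100L),
    do.call(rbind, lapply(treps[1:4], function(s)
      make_keyed_records(s, "sp01", 200L)))
  )
  u <- aggregate_replicates(recs, meta, "union")
  expect_setequal(u$pos, c(100L, 200L))
  expect_equal(u$n_support[u$pos == 100L], 1L)
  expect_equal(u$n_support[u$pos == 200L], 4L)
  m <- aggregate_replicates(recs, meta, "majority")
  expect_equal(m$pos, 200L)                    # 4/6 > half; 1/6 is not
  i <- aggregate_replicates(recs, meta, "intersection")
  expect_equal(nrow(i), 0L)

  # aggregated counts sum over supporting replicates
  expect_equal(u$depth[u$pos == 200L], 4L * 150L)
  expect_equal(u$allele_freq[u$pos == 200L], 0.6)

  bad <- make_keyed_records("ghost", "sp01", 1L)
  expect_error(aggregate_replicates(bad, meta), "unknown sample id")
})

test_that("stage subtractions follow the set-difference contracts", {
  t_set <- make_keyed_records("t", "sp01", c(10L, 20L))
  c_set <- make_keyed_records("c", "sp01", 20L)
  s1 <- remove_reference_artifacts(t_set, c_set)
  expect_equal(s1$surviving$pos, 10L)
  expect_equal(s1$removed$pos, 20L)

  # control empty: identity
  s_id <- remove_reference_artifacts(t_set, t_set[0, ])
  expect_equal(s_id$surviving$pos, c(10L, 20L))
  # treatment subset of control: empty survivors
  s_all <- remove_reference_artifacts(t_set,
                                      make_keyed_records("c", "sp01",
                                                         c(10L, 20L, 30L)))
  expect_equal(nrow(s_all$surviving), 0L)

  # same alt-base sensitivity: a different alt at the same pos is distinct
  other_alt <- make_keyed_records("c", "sp01", 20L, alt = "T")
  s_alt <- remove_reference_artifacts(t_set, other_alt)
  expect_equal(nrow(s_alt$surviving), 2L)

  s2 <- remove_natural_variation(t_set, c_set)
  expect_equal(s2$retained$pos, 10L)
  s2i <- remove_natural_variation(t_set, other_alt)
  expect_equal(nrow(s2i$retained), 2L)
})

test_that("filter retains exactly the planted induced set on clean data", {
  cfg <- sim_config_demo(seed = 14)
  g <- generate_genomes(cfg)
  tr <- plant_variants(g, cfg)
  des <- sample_design(cfg)
  recs <- list()
  for (i in seq_len(nrow(des))) {
    p <- simulate_sample_pileup(g, tr, cfg, des[i, ], i)
    r <- do.call(rbind, lapply(g, function(gg)
      call_snvs(p[p$contig %in% names(gg$contigs), , drop = FALSE], gg)))
    r$sample_id <- rep(des$sample_id[i], nrow(r))
    recs[[i]] <- r
  }
  recs <- do.call(rbind, recs)
  f <- filter_induced_snvs(recs, des)

  ind <- tr[tr$provenance == "induced", ]
  for (seg in c("small", "large")) for (d in c(1L, 3L, 7L)) {
    got <- f$retained[f$retained$segment == seg & f$retained$day == d, ]
    expect_setequal(variant_key(got),
                    variant_key(ind[ind$segment == seg, ]))
  }
  expect_true(all(f$retained$provenance == "induced"))
  # conservation per cell
  expect_equal(f$report$n_input,
               f$report$n_removed_artifact + f$report$n_removed_natural +
                 f$report$n_retained)
  # retained is always a subset of the treatment input
  agg <- aggregate_replicates(recs, des, "union")
  treat_keys <- variant_key(agg[agg$group == "treatment", ])
  expect_true(all(variant_key(f$retained) %in% treat_keys))
})

test_that("filter is idempotent and stage order cannot change retention", {
  meta <- tiny_metadata(n_rep = 2L)
  t1 <- meta$sample_id[meta$group == "treatment" & meta$day == 1L][1]
  c1 <- meta$sample_id[meta$group == "control" & meta$day == 1L][1]
  c3 <- meta$sample_id[meta$group == "control" & meta$day == 3L][1]
  recs <- rbind(
    make_keyed_records(t1, "sp01", c(1L, 2L, 3L, 4L)),
    make_keyed_records(c3, "sp01", 2L),        # artifact evidence (other day)
    make_keyed_records(c1, "sp01", 3L)         # day-matched control evidence
  )
  f <- filter_induced_snvs(recs, meta)
  d1 <- f$retained[f$retained$day == 1L, ]
  expect_setequal(d1$pos, c(1L, 4L))

  # artifact-first attribution: day-matched control evidence is already in
  # the all-days union, so it is removed (and attributed) at stage 1
  rep1 <- f$report[f$report$day == 1L, ]
  expect_equal(rep1$n_removed_artifact, 2L)
  expect_equal(rep1$n_removed_natural, 0L)

  # order invariance of the retained set: subtracting day-matched first
  # then the union leaves the same survivors
  t_set <- make_keyed_records(t1, "sp01", c(1L, 2L, 3L, 4L))
  ctrl_all <- rbind(make_keyed_records(c3, "sp01", 2L),
                    make_keyed_records(c1, "sp01", 3L))
  ctrl_day <- make_keyed_records(c1, "sp01", 3L)
  a_first <- remove_natural_variation(
    remove_reference_artifacts(t_set, ctrl_all)$surviving, ctrl_day)$retained
  n_first <- remove_reference_artifacts(
    remove_natural_variation(t_set, ctrl_day)$retained, ctrl_all)$surviving
  expect_setequal(a_first$pos, n_first$pos)

  # idempotence: filtering the retained records again changes nothing
  again <- remove_reference_artifacts(a_first, ctrl_all)$surviving
  again <- remove_natural_variation(again, ctrl_day)$retained
  expect_equal(again$pos, a_first$pos)
})

test_that("day-matched stage-1 scope is narrower and is honoured", {
  meta <- tiny_metadata(n_rep = 2L)
  t1 <- meta$sample_id[meta$group == "treatment" & meta$day == 1L][1]
  c3 <- meta$sample_id[meta$group == "control" & meta$day == 3L][1]
  recs <- rbind(
    make_keyed_records(t1, "sp01", c(1L, 2L)),
    make_keyed_records(c3, "sp01", 2L)          # control evidence on day 3
  )
  all_days <- filter_induced_snvs(recs, meta, stage1_scope = "all_days")
  expect_setequal(all_days$retained$pos[all_days$retained$day == 1L], 1L)
  matched <- filter_induced_snvs(recs, meta, stage1_scope = "day_matched")
  expect_setequal(matched$retained$pos[matched$retained$day == 1L],
                  c(1L, 2L))                    # day-3 evidence out of scope
})

test_that("filter reports round-trip and enforce conservation on read", {
  rep_df <- data.frame(species_id = "sp01", segment = "small", day = 1L,
                       n_input = 10L, n_removed_artifact = 3L,
                       n_removed_natural = 2L, n_retained = 5L,
                       stringsAsFactors = FALSE)
  class(rep_df) <- c("filter_report", "data.frame")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_filter_report(rep_df, f)
  back <- read_filter_report(f)
  expect_equal(as.data.frame(back), as.data.frame(rep_df))

  bad <- rep_df
  bad$n_retained <- 6L
  write_filter_report(bad, f)
  expect_error(read_filter_report(f), "conservation")
})
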