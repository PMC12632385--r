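test_that("generator is byte-deterministic under its seed", {
  cfg <- synth_config(n_lnc = 20, n_coding = 30, n_peaks = 60, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  a1 <- generate_annotation(cfg, dir = d1)
  a2 <- generate_annotation(cfg, dir = d2)
  expect_identical(a1, a2)
  t1 <- generate_diff_tables(cfg, a1, dir = d1)
  t2 <- generate_diff_tables(cfg, a2, dir = d2)
  expect_identical(t1, t2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  a3 <- generate_annotation(synth_config(n_lnc = 20, n_coding = 30,
                                         n_peaks = 60, seed = 8))
  expect_false(identical(a1$genes, a3$genes))
})

test_that("annotation respects coupling placement and density limits", {
  cfg <- synth_config(n_lnc = 40, n_coding = 40, n_peaks = 200,
                      frac_coupled = 1.0,
                      chrom_lengths = c(chr1 = 8e6, chr2 = 8e6), seed = 5)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$coupled_pairs), 40L)
  lmid <- (ann$genes$start + ann$genes$end) %/% 2
  names(lmid) <- ann$genes$gene_id
  pmid <- (ann$peaks$start + ann$peaks$end) %/% 2
  names(pmid) <- ann$peaks$peak_id
  d <- abs(lmid[ann$coupled_pairs$lnc_id] - pmid[ann$coupled_pairs$peak_id])
  chrom_l <- ann$genes$chrom[match(ann$coupled_pairs$lnc_id,
                                   ann$genes$gene_id)]
  chrom_p <- ann$peaks$chrom[match(ann$coupled_pairs$peak_id,
                                   ann$peaks$peak_id)]
  expect_identical(unname(chrom_l), unname(chrom_p))
  # partner summit within 50 kb of the lncRNA midpoint, so midpoints are
  # within 50 kb plus half a peak width
  expect_true(all(d <= 51000))

  expect_error(generate_annotation(
    synth_config(n_lnc = 500, n_coding = 500, n_peaks = 10,
                 chrom_lengths = c(chr1 = 1e5), seed = 1)), "too small")
})

test_that("every coupled pair is recovered by local pairing", {
  for (seed in 1:5) {
    cfg <- synth_config(n_lnc = 50, n_coding = 50, n_peaks = 150,
                        frac_coupled = 0.4,
                        chrom_lengths = c(chr1 = 1e7), seed = seed)
    ann <- generate_annotation(cfg)
    lnc <- ann$genes[ann$genes$biotype == "lncRNA", ]
    pr <- find_local_pairs(lnc, ann$peaks)
    key <- paste(pr$lnc_id, pr$peak_id)
    expect_true(all(paste(ann$coupled_pairs$lnc_id,
                          ann$coupled_pairs$peak_id) %in% key))
  }
})

test_that("generator outputs parse cleanly through the package readers", {
  cfg <- synth_config(n_lnc = 15, n_coding = 25, n_peaks = 50, seed = 9)
  d <- tempfile()
  ann <- generate_annotation(cfg, dir = d)
  generate_diff_tables(cfg, ann, dir = d)
  genes <- read_gene_models(file.path(d, "genes.gtf"))
  expect_equal(sort(genes$gene_id), sort(ann$genes$gene_id))
  g <- genes[match(ann$genes$gene_id, genes$gene_id), ]
  expect_equal(g$start, ann$genes$start)
  expect_equal(g$end, ann$genes$end)
  expect_equal(g$tss, ann$genes$tss)
  expect_equal(g$biotype, ann$genes$biotype)
  peaks <- read_peaks(file.path(d, "peaks.narrowPeak"))
  expect_equal(peaks, ann$peaks, ignore_attr = TRUE)
  rec <- read_tsv_file(file.path(d, "diff_records.tsv"))
  expect_equal(nrow(rec), nrow(ann$genes) * 8)
})

test_that("differential planting separates planted from null cells", {
  cfg <- synth_config(n_lnc = 60, n_coding = 60, n_peaks = 30,
                      frac_diff = 0.25, null_p_min = 0.1, seed = 21)
  ann <- generate_annotation(cfg)
  tabs <- generate_diff_tables(cfg, ann)
  rec <- tabs$records
  key <- paste(rec$feature_id, rec$sex, rec$week)
  tm <- tabs$truth$diff_members
  planted <- key %in% paste(tm$feature_id, tm$sex, tm$week)
  expect_true(all(rec$p_value[planted] < 1e-4))
  expect_true(all(rec$p_value[!planted] > 0.1))
  # planted features always pass the expression gate
  expect_true(all(unique(tm$feature_id) %in% tabs$truth$expressed_features))
  # frac_diff = 0 yields an empty truth set
  cfg0 <- synth_config(n_lnc = 30, n_coding = 30, n_peaks = 30,
                       frac_diff = 0, seed = 3)
  t0 <- generate_diff_tables(cfg0, generate_annotation(cfg0))
  expect_equal(nrow(t0$truth$diff_members), 0L)
})

test_that("coupled-trajectory correlation is calibrated to coupling_r", {
  mean_r <- vapply(1:50, function(seed) {
    cfg <- synth_config(n_lnc = 40, n_coding = 10, n_peaks = 100,
                        frac_coupled = 0.5, coupling_r = 0.9,
                        noise_sd = 0.2, chrom_lengths = c(chr1 = 1e7),
                        seed = seed)
    ann <- generate_annotation(cfg)
    tabs <- generate_diff_tables(cfg, ann)
    cp <- tabs$truth$coupled_pairs
    cols <- traj_columns()
    lt <- as.matrix(tabs$lnc_traj[match(cp$lnc_id,
                                        tabs$lnc_traj$feature_id), cols])
    pt <- as.matrix(tabs$peak_traj[match(cp$peak_id,
                                         tabs$peak_traj$feature_id), cols])
    mean(vapply(seq_len(nrow(cp)),
                function(i) cor(lt[i, ], pt[i, ]), numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(mean_r) - 0.9), 0.05)
})

test_that("noise-free coupling gives perfect correlation", {
  cfg <- synth_config(n_lnc = 10, n_coding = 10, n_peaks = 40,
                      frac_coupled = 1, coupling_r = 0.95, noise_sd = 0,
                      chrom_lengths = c(chr1 = 5e6), seed = 2)
  ann <- generate_annotation(cfg)
  tabs <- generate_diff_tables(cfg, ann)
  cp <- tabs$truth$coupled_pairs
  cols <- traj_columns()
  for (i in seq_len(nrow(cp))) {
    r <- cor(as.numeric(tabs$lnc_traj[
      tabs$lnc_traj$feature_id == cp$lnc_id[i], cols]),
      as.numeric(tabs$peak_traj[
        tabs$peak_traj$feature_id == cp$peak_id[i], cols]))
    expect_equal(r, 1.0)
  }
})

test_that("random sequences hit the GC target and carry planted ORFs", {
  gen <- generate_sequences(100, length_range = c(500, 500),
                            gc_target = 0.5, seed = 6)
  expect_equal(length(gen$sequences), 100L)
  gc <- mean(gc_content(gen$sequences))
  expect_gt(gc, 45); expect_lt(gc, 55)
  gen2 <- generate_sequences(100, length_range = c(500, 500),
                             gc_target = 0.5, seed = 6)
  expect_identical(gen$sequences, gen2$sequences)

  planted <- generate_sequences(20, length_range = c(300, 400),
                                gc_target = 0.5, seed = 8,
                                plant_orf_len = 60)
  expect_equal(nrow(planted$orf_truth), 20L)
  for (i in seq_len(nrow(planted$orf_truth))) {
    tr <- planted$orf_truth[i, ]
    orfs <- find_smorfs(planted$sequences[[tr$seq_id]], min_len = 30)
    hit <- orfs[orfs$start_nt == tr$start_nt, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$nt_len, 60L)
  }
})
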