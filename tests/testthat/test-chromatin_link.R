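test_that("local pairing respects the inclusive 500 kb midpoint window", {
  lnc <- make_genes("chr1", 99500, len = 1000L, ids = "lncA")  # midpoint 1e5
  peaks <- make_peaks("chr1", c(550000, 600000, 650000), half = 0L,
                      ids = c("near", "edge", "far"))
  peaks$start <- peaks$summit - 50L
  peaks$end <- peaks$summit + 50L
  pr <- find_local_pairs(lnc, peaks)
  expect_equal(sort(pr$peak_id), c("edge", "near"))
  expect_equal(pr$midpoint_distance[pr$peak_id == "near"], 450000)
  expect_equal(pr$midpoint_distance[pr$peak_id == "edge"], 500000)
  # different chromosome never pairs
  lnc2 <- make_genes("chr2", 99500, ids = "lncB")
  expect_equal(nrow(find_local_pairs(lnc2, peaks)), 0L)
  # degenerate window pairs only coincident midpoints
  expect_equal(nrow(find_local_pairs(lnc, peaks, window = 0L)), 0L)
})

test_that("local pairing equals the all-pairs scan on a synthetic genome", {
  cfg <- synth_config(n_lnc = 60, n_coding = 40, n_peaks = 250,
                      chrom_lengths = c(chr1 = 6e6, chr2 = 6e6), seed = 17)
  ann <- generate_annotation(cfg)
  lnc <- ann$genes[ann$genes$biotype == "lncRNA", ]
  pr <- find_local_pairs(lnc, ann$peaks)
  expect_equal(sort(paste(pr$lnc_id, pr$peak_id)),
               oracle_local_pairs(lnc, ann$peaks, 500000))
  expect_true(all(pr$midpoint_distance <= 500000))
})

test_that("pair correlation matches the definitional Pearson formula", {
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  expect_equal(correlate_pair(x, 2 * x), 1.0)
  expect_equal(correlate_pair(x, -x), -1.0)
  expect_equal(correlate_pair(c(1, 2, 3), c(1, 3, 2)), 0.5)
  set.seed(3)
  for (i in 1:50) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(correlate_pair(a, b), oracle_pearson(a, b),
                 tolerance = 1e-12)
  }
  expect_error(correlate_pair(1:4, 1:5), "equal length")
  expect_warning(r0 <- correlate_pair(rep(1, 8), rnorm(8)), "zero-variance")
  expect_true(is.na(r0))
})

test_that("table-level correlation fills r and flags zero-variance pairs", {
  cols <- traj_columns()
  lt <- data.frame(feature_id = c("l1", "l2"),
                   rbind(1:8, rep(2, 8)))
  names(lt) <- c("feature_id", cols)
  pt <- data.frame(feature_id = c("p1", "p2"),
                   rbind(seq(2, 16, 2), rnorm(8)))
  names(pt) <- c("feature_id", cols)
  pairs <- data.frame(lnc_id = c("l1", "l2"), peak_id = c("p1", "p2"),
                      chrom = "chr1", midpoint_distance = c(10, 20),
                      r = NA_real_)
  expect_warning(out <- correlate_pairs(pairs, lt, pt), "zero-variance")
  expect_equal(out$r[1], 1.0)
  expect_true(is.na(out$r[2]))
})

test_that("nearest coding TSS ignores lncRNAs and breaks ties lexicographically", {
  genes <- rbind(
    make_genes("chr1", c(9000, 12500), len = 100L,
               biotype = "protein_coding", ids = c("pcB", "pcA")),
    make_genes("chr1", 10100, len = 100L, ids = "lncNear"))
  pk <- make_peaks("chr1", 10000, half = 50L, ids = "pk1")
  nt <- nearest_coding_tss(pk, genes)
  expect_equal(nt$gene_id, "pcB")       # lncRNA at 10100 ignored
  expect_equal(nt$tss_distance, 1000)

  atz <- make_peaks("chr1", 9000, half = 50L, ids = "pk2")
  expect_equal(nearest_coding_tss(atz, genes)$tss_distance, 0)

  # equidistant coding TSSs: lexicographically smallest gene id wins
  eq <- rbind(
    make_genes("chr1", 900, len = 50L, biotype = "protein_coding",
               ids = "pcZ"),
    make_genes("chr1", 1100, len = 50L, biotype = "protein_coding",
               ids = "pcM"))
  mid <- make_peaks("chr1", 1000, half = 20L, ids = "pk3")
  expect_equal(nearest_coding_tss(mid, eq)$gene_id, "pcM")

  # chromosome without coding genes warns and yields NA
  lonely <- make_peaks("chr9", 5000, half = 50L, ids = "pk4")
  expect_warning(nt4 <- nearest_coding_tss(lonely, genes), "without")
  expect_true(is.na(nt4$gene_id))
})

test_that("activity score is distance-damped correlation with preserved sign", {
  expect_equal(activity_score(1.0, 0), 1.0)
  expect_equal(activity_score(0.8, 7), 0.1)
  expect_equal(activity_score(-0.5, 0), -0.5)
  expect_error(activity_score(0.5, -1), ">= 0")
  # exhaustive grid: sign preserved, |score| <= |r|, strictly decreasing
  rs <- seq(-1, 1, by = 0.05)
  ds <- c(0, 1, 2, 5, 10, 100, 1000, 5e5)
  grid <- expand.grid(r = rs, d = ds)
  sc <- activity_score(grid$r, grid$d)
  expect_true(all(sign(sc) == sign(grid$r)))
  expect_true(all(abs(sc) <= abs(grid$r) + 1e-15))
  expect_true(all((abs(sc) == abs(grid$r)) == (grid$d == 0 | grid$r == 0)))
  for (r in rs[rs > 0]) {
    expect_true(all(diff(activity_score(r, ds)) < 0))
  }
})

test_that("triads keep r >= 0.5, deduplicate per gene and direction-label genes", {
  genes <- make_genes("chr1", c(1000, 40000, 90000), len = 500L,
                      biotype = "protein_coding",
                      ids = c("pcA", "pcB", "pcC"))
  peaks <- make_peaks("chr1", c(1200, 1800, 39000), half = 100L,
                      ids = c("pkA", "pkB", "pkC"))
  pairs <- data.frame(
    lnc_id = c("l1", "l2", "l3", "l4"),
    peak_id = c("pkA", "pkB", "pkC", "pkA"),
    chrom = "chr1",
    midpoint_distance = c(100, 700, 37000, 200),
    r = c(0.9, 0.8, 0.6, 0.4))
  tri <- build_triads(pairs, peaks, genes, de_genes_up = "pcA",
                      de_genes_down = "pcB")
  # l4 dropped (r < 0.5); pkA and pkB both map to pcA -> best score kept
  expect_equal(nrow(tri), 2L)
  expect_false(any(duplicated(tri$gene_id)))
  a <- tri[tri$gene_id == "pcA", ]
  expect_equal(a$lnc_id, "l1")
  expect_equal(a$peak_id, "pkA")
  expect_equal(a$activity_score, 0.9 / (abs(1200 - 1000) + 1))
  expect_equal(a$gene_direction, "up")
  expect_equal(tri$gene_direction[tri$gene_id == "pcB"], "down")
  expect_equal(tri$activity_score, sort(tri$activity_score,
                                        decreasing = TRUE))
  expect_error(build_triads(pairs, peaks, genes, "pcA", "pcA"), "disjoint")
})

test_that("per-gene deduplication equals brute force on seeded synthetic runs", {
  for (seed in 1:50) {
    cfg <- synth_config(n_lnc = 25, n_coding = 30, n_peaks = 70,
                        chrom_lengths = c(chr1 = 3e6), frac_coupled = 0.3,
                        seed = seed)
    ann <- generate_annotation(cfg)
    tabs <- generate_diff_tables(cfg, ann)
    lnc <- ann$genes[ann$genes$biotype == "lncRNA", ]
    pairs <- find_local_pairs(lnc, ann$peaks)
    pairs <- suppressWarnings(
      correlate_pairs(pairs, tabs$lnc_traj, tabs$peak_traj))
    tri <- build_triads(pairs, ann$peaks, ann$genes)
    expect_false(any(duplicated(tri$gene_id)))
    if (!nrow(tri)) next
    # rebuild candidate list independently and compare the per-gene winner
    keep <- pairs[!is.na(pairs$r) & pairs$r >= 0.5, ]
    nt <- suppressWarnings(nearest_coding_tss(
      ann$peaks[match(unique(keep$peak_id), ann$peaks$peak_id), ],
      ann$genes))
    cand <- merge(keep, nt, by = "peak_id")
    cand <- cand[!is.na(cand$gene_id), ]
    cand$activity_score <- cand$r / (cand$tss_distance + 1)
    best <- oracle_triad_dedup(cand)
    best <- best[order(best$gene_id), ]
    got <- tri[order(tri$gene_id), ]
    expect_equal(got$gene_id, best$gene_id)
    expect_equal(got$activity_score, best$activity_score)
    expect_equal(got$lnc_id, best$lnc_id)
  }
})

test_that("couplings planted near peaks raise |r| at short distances", {
  # couplings exist only below 50 kb: mean |r| within 10 kb must exceed
  # the background level beyond 100 kb
  rs_near <- c(); rs_far <- c()
  for (seed in 1:5) {
    cfg <- synth_config(n_lnc = 80, n_coding = 40, n_peaks = 400,
                        chrom_lengths = c(chr1 = 8e6), frac_coupled = 0.5,
                        coupling_r = 0.9, noise_sd = 0.1, seed = seed)
    ann <- generate_annotation(cfg)
    tabs <- generate_diff_tables(cfg, ann)
    lnc <- ann$genes[ann$genes$biotype == "lncRNA", ]
    pairs <- find_local_pairs(lnc, ann$peaks)
    pairs <- suppressWarnings(
      correlate_pairs(pairs, tabs$lnc_traj, tabs$peak_traj))
    rs_near <- c(rs_near, pairs$r[pairs$midpoint_distance < 10000])
    rs_far <- c(rs_far, pairs$r[pairs$midpoint_distance > 100000])
  }
  expect_gt(mean(abs(rs_near), na.rm = TRUE),
            mean(abs(rs_far), na.rm = TRUE))
})
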