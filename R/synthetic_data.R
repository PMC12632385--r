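# Seeded synthetic multi-tissue training-response data with ground truth.
# The generator emulates the study design the package analyses: four
# training weeks (1, 2, 4, 8), two sexes, per-tissue differential-result
# tables against sex-matched sedentary controls, ATAC peaks with summits
# and a peak-by-sample count matrix, and log2FC trajectory tables on the
# fixed sex-by-week grid. Differential features are planted with a
# two-sided z-model (planted p-values far below the null), and a fraction
# of lncRNAs is coupled to a nearby peak through a shared latent trajectory
# calibrated so the expected Pearson correlation equals `coupling_r`.

#' Configuration for the synthetic data generator
#'
#' Defaults emulate the study conditions at desk scale: a two-chromosome
#' genome, a few hundred genes, planted differential fractions and effect
#' sizes that place planted cells far beyond the differential thresholds
#' (|log2FC| mean 2 against trajectory noise sd 0.2), and one in ten
#' lncRNAs coupled to a peak within 50 kb.
#'
#' @param n_lnc,n_coding,n_peaks Numbers of lncRNA genes, protein-coding
#'   genes and ATAC peaks.
#' @param tissues Character vector of tissue labels.
#' @param chrom_lengths Named integer vector of chromosome lengths in bases.
#' @param frac_diff Fraction of features planted differential (per class).
#' @param effect_size Mean planted |log2FC|.
#' @param noise_sd Trajectory noise standard deviation (log2FC units).
#' @param frac_coupled Fraction of lncRNAs coupled to a nearby peak.
#' @param coupling_r Target Pearson correlation of coupled trajectories.
#' @param frac_low_fpkm Fraction of non-planted features placed below the
#'   FPKM >= 1 expression gate.
#' @param frac_low_count Fraction of peaks planted to fail the
#'   "at least 10 reads in 4 or more samples" count filter.
#' @param n_samples Number of samples in the peak count matrix.
#' @param null_p_min Lower bound of the null p-value distribution
#'   (null p ~ Uniform(`null_p_min`, 1]; default 0).
#' @param min_spacing Minimum spacing between placed gene starts, bases.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   outputs.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_lnc = 200L, n_coding = 300L, n_peaks = 1000L,
                         tissues = "tissue1",
                         chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
                         frac_diff = 0.2, effect_size = 2.0, noise_sd = 0.2,
                         frac_coupled = 0.1, coupling_r = 0.9,
                         frac_low_fpkm = 0.2, frac_low_count = 0.05,
                         n_samples = 10L, null_p_min = 0,
                         min_spacing = 2000L, seed = 1L) {
  stopifnot(
    n_lnc >= 1, n_coding >= 1, n_peaks >= 1,
    frac_diff >= 0, frac_diff <= 1,
    frac_coupled >= 0, frac_coupled <= 1,
    coupling_r > -1, coupling_r < 1,
    frac_low_fpkm >= 0, frac_low_fpkm <= 1,
    null_p_min >= 0, null_p_min < 1,
    noise_sd >= 0, !is.null(names(chrom_lengths))
  )
  structure(as.list(environment()), class = "synth_config")
}

# Allocate n items over chromosomes proportionally to length (largest
# remainder), then sample distinct slot positions per chromosome so placed
# features respect the minimum spacing.
place_on_slots <- function(chrom_lengths, n, slot_width, margin) {
  usable <- pmax(chrom_lengths - 2 * margin, 0)
  n_slots <- floor(usable / slot_width)
  if (sum(n_slots) < n) {
    stop("chromosomes too small to place ", n,
         " features at the requested spacing", call. = FALSE)
  }
  share <- n * n_slots / sum(n_slots)
  alloc <- floor(share)
  rem <- n - sum(alloc)
  if (rem > 0) {
    extra <- order(share - alloc, decreasing = TRUE)
    take <- extra[seq_len(rem)]
    alloc[take] <- pmin(alloc[take] + 1, n_slots[take])
    while (sum(alloc) < n) {  # spill over if a chromosome saturated
      room <- which(alloc < n_slots)
      alloc[room[1L]] <- alloc[room[1L]] + 1
    }
  }
  out <- data.frame(chrom = character(), pos = numeric())
  for (i in seq_along(chrom_lengths)) {
    if (alloc[i] == 0) next
    slots <- sort(sample.int(n_slots[i], alloc[i]))
    pos <- margin + (slots - 1) * slot_width +
      floor(runif(alloc[i], 0, slot_width * 0.2))
    out <- rbind(out, data.frame(chrom = names(chrom_lengths)[i],
                                 pos = pos, stringsAsFactors = FALSE))
  }
  out
}

#' Generate a synthetic genome annotation with peaks
#'
#' Places lncRNA and protein-coding genes on the configured chromosomes with
#' minimum spacing, gives each coupled lncRNA a partner peak whose summit
#' lies within 50 kb of the lncRNA midpoint, and places the remaining peak
#' summits independently on a spacing grid (so summit-trimmed 200-bp windows
#' never merge). Deterministic under the configuration seed.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory; when given, writes `genes.gtf` and
#'   `peaks.narrowPeak`.
#' @return List with `genes` (gene-model `data.frame`), `peaks` (peak
#'   `data.frame`) and `coupled_pairs` (`data.frame` of `lnc_id`,
#'   `peak_id`).
#' @export
generate_annotation <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    n_genes <- config$n_lnc + config$n_coding
    gene_len_max <- 10000L
    gpos <- place_on_slots(config$chrom_lengths, n_genes,
                           slot_width = config$min_spacing + gene_len_max,
                           margin = 60000)
    ord <- sample.int(n_genes)  # interleave biotypes across the genome
    biotype <- rep(c("lncRNA", "protein_coding"),
                   c(config$n_lnc, config$n_coding))[order(ord)]
    len <- floor(runif(n_genes, 500, gene_len_max))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    ids <- character(n_genes)
    ids[biotype == "lncRNA"] <- sprintf("lnc_%04d",
                                        seq_len(config$n_lnc))
    ids[biotype == "protein_coding"] <- sprintf("pcg_%04d",
                                                seq_len(config$n_coding))
    start <- as.integer(gpos$pos)
    end <- as.integer(gpos$pos + len)
    genes <- data.frame(
      gene_id = ids, chrom = gpos$chrom, start = start, end = end,
      strand = strand, biotype = biotype,
      tss = ifelse(strand == "-", end - 1L, start),
      stringsAsFactors = FALSE
    )
    genes$exons <- I(lapply(seq_len(n_genes), function(i) {
      genes[i, c("chrom", "start", "end")]
    }))

    # peak summits on a 1 kb grid (jitter < 400 bp keeps summits > 600 bp
    # apart, so 200 bp trimmed windows stay disjoint)
    peak_slot <- 1000L
    n_coupled <- round(config$frac_coupled * config$n_lnc)
    ppos <- place_on_slots(config$chrom_lengths, config$n_peaks,
                           slot_width = peak_slot, margin = 2000)
    summit <- as.integer(ppos$pos)
    pchrom <- ppos$chrom

    coupled <- data.frame(lnc_id = character(), peak_id = character(),
                          stringsAsFactors = FALSE)
    if (n_coupled > 0) {
      lnc_rows <- which(genes$biotype == "lncRNA")
      pick <- sort(sample(lnc_rows, n_coupled))
      lmid <- (genes$start[pick] + genes$end[pick]) %/% 2L
      used <- integer(0)
      for (k in seq_along(pick)) {
        chrom_k <- genes$chrom[pick[k]]
        len_k <- config$chrom_lengths[[chrom_k]]
        # pick an unused summit slot and move it to within 50 kb of the
        # lncRNA midpoint, keeping >= 600 bp from every other summit so
        # 200 bp trimmed windows never merge
        free <- setdiff(seq_along(summit), used)
        same <- free[pchrom[free] == chrom_k]
        slot <- if (length(same)) {
          same[which.min(abs(summit[same] - lmid[k]))]
        } else free[1L]
        others <- summit[setdiff(which(pchrom == chrom_k), slot)]
        target <- NA_integer_
        for (try in seq_len(500)) {
          cand <- lmid[k] + sample(c(-1L, 1L), 1) * floor(runif(1, 0, 50000))
          cand <- as.integer(min(max(cand, 2000), len_k - 2000))
          if (abs(cand - lmid[k]) > 50000) next
          if (!length(others) || min(abs(others - cand)) >= 600) {
            target <- cand
            break
          }
        }
        if (is.na(target)) {
          stop("could not place a coupled peak within 50 kb of ",
               genes$gene_id[pick[k]], call. = FALSE)
        }
        summit[slot] <- target
        pchrom[slot] <- chrom_k
        used <- c(used, slot)
        coupled <- rbind(coupled, data.frame(
          lnc_id = genes$gene_id[pick[k]], peak_id = sprintf("tmp_%d", slot),
          stringsAsFactors = FALSE))
      }
    }
    o <- order(pchrom, summit)
    rank <- match(seq_along(summit), o)
    peak_ids <- sprintf("peak_%05d", rank)
    width_half <- floor(runif(config$n_peaks, 150, 400))
    peaks <- data.frame(
      peak_id = peak_ids[o],
      chrom = pchrom[o],
      start = as.integer(pmax(summit - width_half, 0))[o],
      end = as.integer(summit + width_half)[o],
      summit = summit[o],
      stringsAsFactors = FALSE
    )
    if (nrow(coupled)) {
      slot_idx <- as.integer(sub("tmp_", "", coupled$peak_id))
      coupled$peak_id <- peak_ids[slot_idx]
    }
    out <- list(genes = genes, peaks = peaks, coupled_pairs = coupled)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_gene_models_gtf(genes, file.path(dir, "genes.gtf"))
      write_peaks_narrowpeak(peaks, file.path(dir, "peaks.narrowPeak"))
    }
    out
  })
}

# Latent-trajectory coupling: observed = latent + N(0, noise_sd) for both
# members, latent sd chosen so the population correlation equals coupling_r.
coupling_latent_sd <- function(coupling_r, noise_sd) {
  if (noise_sd == 0) return(1)
  noise_sd * sqrt(coupling_r / (1 - coupling_r))
}

#' Generate differential-result tables, trajectories and ground truth
#'
#' For each tissue, plants `frac_diff` of each gene class as differential:
#' planted cells draw log2FC from `N(sign * effect_size, noise_sd)` and get
#' p-values from the two-sided z-model `2 * pnorm(-|log2fc| / noise_sd)`;
#' null cells draw log2FC from `N(0, noise_sd)` and p from
#' `Uniform(null_p_min, 1]`. Planted sex patterns are `both`/`M`/`F`.
#' Coupled lncRNA-peak pairs (from [generate_annotation()]) share a latent
#' 8-point trajectory plus independent noise calibrated so the expected
#' Pearson correlation equals `coupling_r`; coupled lncRNAs are drawn from
#' the non-differential pool so coupling lives purely in trajectory space.
#' Peak-level per-sex p-values are planted small for significant peaks
#' (coupled partners plus `frac_diff` of the rest) and uniform otherwise,
#' and the count matrix plants `frac_low_count` of uncoupled peaks below
#' the read-support filter. Mean FPKM is log-normal with `frac_low_fpkm`
#' of non-planted features below the expression gate.
#'
#' @param config A [synth_config()].
#' @param annotation Result of [generate_annotation()] for the same config.
#' @param dir Optional output directory; when given, writes the TSV tables
#'   and `truth.json`.
#' @return List with `records` (differential-result table over all tissues),
#'   `lnc_traj`, `peak_traj` (trajectory tables for the first tissue),
#'   `peak_pvalues` (`peak_id`, `p_male`, `p_female`, `stratum`), `counts`
#'   (peak-by-sample matrix as a `data.frame`) and `truth` (list:
#'   `expressed_features`, `diff_members`, `diff_features`,
#'   `coupled_pairs`, `sig_peaks`, `low_count_peaks`).
#' @export
generate_diff_tables <- function(config, annotation, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  genes <- annotation$genes
  peaks <- annotation$peaks
  coupled <- annotation$coupled_pairs
  cols <- traj_columns()
  local_seed(config$seed + 1L, {
    n_cells <- length(cols)

    ## ---- per-tissue differential records for all genes ----
    coupled_lnc <- coupled$lnc_id
    records <- list()
    truth_members <- list()
    diff_feats <- list()
    lnc_traj_mat <- NULL
    for (ti in seq_along(config$tissues)) {
      tissue <- config$tissues[ti]
      # plant per class, excluding coupled lncRNAs (trajectory-only nulls)
      plantable <- split(genes$gene_id, genes$biotype)
      planted <- unlist(lapply(c("lncRNA", "protein_coding"), function(b) {
        pool <- setdiff(plantable[[b]], coupled_lnc)
        sort(sample(pool, min(round(config$frac_diff * length(plantable[[b]])),
                              length(pool))))
      }), use.names = FALSE)
      sex_pattern <- sample(c("both", "M", "F"), length(planted),
                            replace = TRUE, prob = c(0.4, 0.3, 0.3))
      sign_f <- sample(c(-1, 1), length(planted), replace = TRUE)

      grid <- expand.grid(sex = STUDY_SEXES, week = STUDY_WEEKS,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      n_feat <- nrow(genes)
      rec <- data.frame(
        feature_id = rep(genes$gene_id, each = nrow(grid)),
        tissue = tissue,
        sex = rep(grid$sex, n_feat),
        week = rep(grid$week, n_feat),
        stringsAsFactors = FALSE
      )
      rec$log2fc <- rnorm(nrow(rec), 0, config$noise_sd)
      rec$p_value <- config$null_p_min +
        runif(nrow(rec)) * (1 - config$null_p_min)
      pidx <- match(rec$feature_id, planted)
      is_planted_cell <- !is.na(pidx) &
        (sex_pattern[pidx] == "both" | sex_pattern[pidx] == rec$sex)
      k <- which(is_planted_cell)
      if (length(k)) {
        rec$log2fc[k] <- rnorm(length(k), sign_f[pidx[k]] * config$effect_size,
                               config$noise_sd)
        se <- max(config$noise_sd, 1e-12)
        rec$p_value[k] <- pmax(2 * pnorm(-abs(rec$log2fc[k]) / se), 1e-300)
      }
      rec$adj_p <- NA_real_

      # mean FPKM per feature: planted features always expressed
      low_pool <- setdiff(genes$gene_id, planted)
      n_low <- round(config$frac_low_fpkm * length(low_pool))
      low <- sort(sample(low_pool, n_low))
      fpkm <- 1 + rlnorm(n_feat, meanlog = 1.2, sdlog = 1)
      fpkm[match(low, genes$gene_id)] <- runif(n_low, 0.01, 0.99)
      rec$mean_fpkm <- fpkm[match(rec$feature_id, genes$gene_id)]

      records[[ti]] <- rec
      truth_members[[ti]] <- data.frame(
        feature_id = rec$feature_id[k], tissue = rep(tissue, length(k)),
        sex = rec$sex[k], week = rec$week[k], stringsAsFactors = FALSE)
      diff_feats[[ti]] <- planted

      if (ti == 1L) {
        # lncRNA trajectories for the linking tissue = the log2fc cells
        lnc <- genes$gene_id[genes$biotype == "lncRNA"]
        m <- matrix(NA_real_, length(lnc), n_cells,
                    dimnames = list(lnc, cols))
        key <- paste(ifelse(rec$sex == "M", "m", "f"), "_wk", rec$week,
                     sep = "")
        for (cc in cols) {
          sel <- rec$feature_id %in% lnc & key == cc
          m[rec$feature_id[sel], cc] <- rec$log2fc[sel]
        }
        lnc_traj_mat <- m
        expressed1 <- setdiff(genes$gene_id, low)
      }
    }
    records <- do.call(rbind, records)

    ## ---- peak trajectories, p-values, counts (first tissue) ----
    n_peaks <- nrow(peaks)
    peak_traj_mat <- matrix(rnorm(n_peaks * n_cells, 0, config$noise_sd),
                            n_peaks, n_cells,
                            dimnames = list(peaks$peak_id, cols))
    if (nrow(coupled)) {
      s_lat <- coupling_latent_sd(config$coupling_r, config$noise_sd)
      for (i in seq_len(nrow(coupled))) {
        latent <- rnorm(n_cells, 0, s_lat)
        lnc_traj_mat[coupled$lnc_id[i], ] <-
          latent + rnorm(n_cells, 0, config$noise_sd)
        peak_traj_mat[coupled$peak_id[i], ] <-
          latent + rnorm(n_cells, 0, config$noise_sd)
      }
      # keep the records table consistent with the trajectory table
      key <- paste(ifelse(records$sex == "M", "m", "f"), "_wk",
                   records$week, sep = "")
      first_tissue <- records$tissue == config$tissues[1L]
      for (i in seq_len(nrow(coupled))) {
        sel <- which(first_tissue & records$feature_id == coupled$lnc_id[i])
        records$log2fc[sel] <- lnc_traj_mat[coupled$lnc_id[i], key[sel]]
      }
    }

    sig_pool <- setdiff(peaks$peak_id, coupled$peak_id)
    sig_extra <- sort(sample(sig_pool,
                             round(config$frac_diff * length(sig_pool))))
    sig_peaks <- sort(c(coupled$peak_id, sig_extra))
    is_sig <- peaks$peak_id %in% sig_peaks
    p_m <- runif(n_peaks)
    p_f <- runif(n_peaks)
    p_m[is_sig] <- pmax(2 * pnorm(-abs(rnorm(sum(is_sig), 6, 1))), 1e-300)
    p_f[is_sig] <- pmax(2 * pnorm(-abs(rnorm(sum(is_sig), 6, 1))), 1e-300)
    peak_pvalues <- data.frame(peak_id = peaks$peak_id, p_male = p_m,
                               p_female = p_f,
                               stratum = config$tissues[1L],
                               stringsAsFactors = FALSE)

    low_count_pool <- setdiff(peaks$peak_id, coupled$peak_id)
    low_count <- sort(sample(low_count_pool,
                             round(config$frac_low_count *
                                     length(low_count_pool))))
    cnt <- matrix(rnbinom(n_peaks * config$n_samples, mu = 60, size = 20),
                  n_peaks, config$n_samples)
    cnt[match(low_count, peaks$peak_id), ] <-
      rnbinom(length(low_count) * config$n_samples, mu = 2, size = 5)
    counts <- data.frame(peak_id = peaks$peak_id, cnt,
                         stringsAsFactors = FALSE)
    names(counts) <- c("peak_id", sprintf("s%02d", seq_len(config$n_samples)))

    lnc_traj <- data.frame(feature_id = rownames(lnc_traj_mat),
                           lnc_traj_mat, stringsAsFactors = FALSE,
                           row.names = NULL)
    peak_traj <- data.frame(feature_id = rownames(peak_traj_mat),
                            peak_traj_mat, stringsAsFactors = FALSE,
                            row.names = NULL)
    truth <- list(
      expressed_features = sort(expressed1),
      diff_members = do.call(rbind, truth_members),
      diff_features = sort(unique(unlist(diff_feats))),
      coupled_pairs = coupled,
      sig_peaks = sig_peaks,
      low_count_peaks = low_count
    )
    out <- list(records = records, lnc_traj = lnc_traj,
                peak_traj = peak_traj, peak_pvalues = peak_pvalues,
                counts = counts, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv_file(records, file.path(dir, "diff_records.tsv"))
      write_tsv_file(lnc_traj, file.path(dir, "lnc_trajectories.tsv"))
      write_tsv_file(peak_traj, file.path(dir, "peak_trajectories.tsv"))
      write_tsv_file(peak_pvalues, file.path(dir, "peak_pvalues.tsv"))
      write_tsv_file(counts, file.path(dir, "peak_counts.tsv"))
      jsonlite::write_json(
        list(expressed_features = truth$expressed_features,
             diff_members = truth$diff_members,
             diff_features = truth$diff_features,
             coupled_pairs = truth$coupled_pairs,
             sig_peaks = truth$sig_peaks,
             low_count_peaks = truth$low_count_peaks),
        file.path(dir, "truth.json"))
    }
    out
  })
}

#' Generate random nucleotide sequences with a target GC content
#'
#' Draws i.i.d. bases with `P(G or C) = gc_target` (split evenly between G
#' and C, and between A and T). Optionally plants one ORF per sequence --
#' `ATG`, stop-free random codons, then `TAA` -- at a recorded offset, for
#' testing ORF discovery against known truth.
#'
#' @param n Number of sequences.
#' @param length_range Length range (bases), inclusive.
#' @param gc_target Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param plant_orf_len Optional planted ORF length in nucleotides (multiple
#'   of 3, >= 6); `NULL` plants nothing.
#' @param fasta Optional output FASTA path.
#' @return List with `sequences` (named character vector) and `orf_truth`
#'   (`data.frame` of `seq_id`, `start_nt`, `nt_len`; empty when nothing is
#'   planted).
#' @export
generate_sequences <- function(n, length_range = c(200L, 2000L),
                               gc_target = 0.5, seed = 1L,
                               plant_orf_len = NULL, fasta = NULL) {
  stopifnot(gc_target > 0, gc_target < 1, length_range[1] >= 30)
  local_seed(seed, {
    probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
               G = gc_target / 2, T = (1 - gc_target) / 2)
    lens <- floor(runif(n, length_range[1], length_range[2] + 1))
    seqs <- vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(seqs) <- sprintf("seq_%04d", seq_len(n))
    truth <- data.frame(seq_id = character(), start_nt = integer(),
                        nt_len = integer(), stringsAsFactors = FALSE)
    if (!is.null(plant_orf_len)) {
      stopifnot(plant_orf_len %% 3 == 0, plant_orf_len >= 6)
      n_mid <- plant_orf_len / 3 - 2
      safe <- c("GCT", "GCC", "TGT", "GAT", "GAA", "TTT", "GGA", "CAT",
                "ATT", "AAA", "CTG", "ATG", "AAT", "CCT", "CAA", "CGT",
                "TCT", "ACT", "GTT", "TGG", "TAC")
      for (i in seq_len(n)) {
        if (lens[i] < plant_orf_len + 6) next
        off <- sample.int(lens[i] - plant_orf_len, 1) - 1L
        orf <- paste0("ATG",
                      paste(sample(safe, n_mid, replace = TRUE),
                            collapse = ""), "TAA")
        seqs[i] <- paste0(substr(seqs[i], 1, off), orf,
                          substr(seqs[i], off + plant_orf_len + 1, lens[i]))
        truth <- rbind(truth, data.frame(seq_id = names(seqs)[i],
                                         start_nt = off,
                                         nt_len = plant_orf_len,
                                         stringsAsFactors = FALSE))
      }
    }
    if (!is.null(fasta)) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
    }
    list(sequences = seqs, orf_truth = truth)
  })
}
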