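# The core integration: pair lncRNAs with nearby training-responsive ATAC
# peaks (midpoint distance <= 500 kb on the same chromosome), correlate
# their log2FC trajectories across the sex-by-week grid, attach the nearest
# protein-coding TSS to each peak summit, and score triads by
# activity = r / (TSS distance + 1), keeping one triad per gene.

#' Find local lncRNA-peak pairs within a genomic window
#'
#' Emits every (lncRNA, peak) pair on the same chromosome whose interval
#' midpoints (`floor((start + end) / 2)`) lie within `window` bases of each
#' other, boundary inclusive. The caller restricts `peaks` to
#' training-significant peaks when pairing against the significant panel.
#'
#' @param lnc_models Gene-model `data.frame` (rows with any biotype are
#'   accepted; pass the lncRNA subset).
#' @param peaks Peak `data.frame`.
#' @param window Maximum midpoint distance in bases (default 500000).
#' @return `data.frame` with columns `lnc_id`, `peak_id`, `chrom`,
#'   `midpoint_distance` and `r` (unset, `NA`).
#' @export
find_local_pairs <- function(lnc_models, peaks, window = 500000L) {
  check_intervals(lnc_models, "lncRNA locus")
  check_intervals(peaks, "peak")
  empty <- data.frame(lnc_id = character(), peak_id = character(),
                      chrom = character(), midpoint_distance = numeric(),
                      r = numeric(), stringsAsFactors = FALSE)
  if (!nrow(lnc_models) || !nrow(peaks)) return(empty)
  lmid <- (lnc_models$start + lnc_models$end) %/% 2L
  pmid <- (peaks$start + peaks$end) %/% 2L
  out <- vector("list", 0L)
  for (chrom in intersect(unique(lnc_models$chrom), unique(peaks$chrom))) {
    li <- which(lnc_models$chrom == chrom)
    pi <- which(peaks$chrom == chrom)
    ord <- pi[order(pmid[pi])]
    pm <- pmid[ord]
    # first/last sorted peak midpoint within [mid - window, mid + window]
    lo <- findInterval(lmid[li] - window - 0.5, pm) + 1L
    hi <- findInterval(lmid[li] + window + 0.5, pm)
    nhit <- pmax(hi - lo + 1L, 0L)
    keep <- which(nhit > 0L)
    if (!length(keep)) next
    idx <- sequence(nhit[keep]) + rep(lo[keep], nhit[keep]) - 1L
    lrep <- rep(li[keep], nhit[keep])
    prep <- ord[idx]
    out[[length(out) + 1L]] <- data.frame(
      lnc_id = lnc_models$gene_id[lrep],
      peak_id = peaks$peak_id[prep],
      chrom = chrom,
      midpoint_distance = abs(lmid[lrep] - pmid[prep]),
      r = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(out$lnc_id, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation of two trajectory vectors
#'
#' Sample Pearson correlation of two equal-length log2FC trajectories.
#' Zero-variance vectors cannot be correlated: the result is `NA` with a
#' warning, and such pairs are excluded downstream rather than scored.
#'
#' @param lnc_traj,peak_traj Numeric vectors, equal length >= 3.
#' @return Pearson r in \[-1, 1\], or `NA` for zero-variance input.
#' @export
correlate_pair <- function(lnc_traj, peak_traj) {
  if (length(lnc_traj) != length(peak_traj)) {
    stop("trajectories must have equal length", call. = FALSE)
  }
  if (length(lnc_traj) < 3L) stop("trajectories must have length >= 3")
  if (sd(lnc_traj) == 0 || sd(peak_traj) == 0) {
    warning("zero-variance trajectory: correlation recorded as NA")
    return(NA_real_)
  }
  cor(lnc_traj, peak_traj)
}

#' Attach trajectory correlations to a pair table
#'
#' Vectorised [correlate_pair()] over all rows of a local-pair table, using
#' trajectory tables with a `feature_id` column and the eight columns of
#' [traj_columns()]. Pairs whose lncRNA or peak trajectory has zero variance
#' get `r = NA` (one warning reports how many).
#'
#' @param pairs Pair `data.frame` from [find_local_pairs()].
#' @param lnc_traj,peak_traj Trajectory tables (`feature_id` +
#'   `traj_columns()`).
#' @return `pairs` with the `r` column filled in.
#' @export
correlate_pairs <- function(pairs, lnc_traj, peak_traj) {
  if (!nrow(pairs)) return(pairs)
  cols <- traj_columns()
  for (tb in list(lnc_traj, peak_traj)) {
    if (!all(c("feature_id", cols) %in% names(tb))) {
      stop("trajectory table must have feature_id and columns ",
           paste(cols, collapse = ", "), call. = FALSE)
    }
  }
  lm <- as.matrix(lnc_traj[match(pairs$lnc_id, lnc_traj$feature_id), cols])
  pm <- as.matrix(peak_traj[match(pairs$peak_id, peak_traj$feature_id), cols])
  if (anyNA(lm) || anyNA(pm)) {
    stop("missing trajectory for some paired features", call. = FALSE)
  }
  n <- ncol(lm)
  lc <- lm - rowMeans(lm)
  pc <- pm - rowMeans(pm)
  lv <- rowSums(lc^2)
  pv <- rowSums(pc^2)
  r <- rep(NA_real_, nrow(pairs))
  ok <- lv > 0 & pv > 0
  r[ok] <- rowSums(lc[ok, , drop = FALSE] * pc[ok, , drop = FALSE]) /
    sqrt(lv[ok] * pv[ok])
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) with a zero-variance trajectory: ",
            "r recorded as NA and excluded downstream")
  }
  pairs$r <- r
  pairs
}

#' Nearest protein-coding TSS for each peak summit
#'
#' For each peak, finds the protein-coding gene on the same chromosome whose
#' transcription start site minimises the absolute distance to the peak
#' summit. Ties (equidistant TSSs) are broken by the lexicographically
#' smallest `gene_id`. Peaks on chromosomes without any coding gene get `NA`
#' with a warning and are skipped by [build_triads()].
#'
#' @param peaks Peak `data.frame`.
#' @param genes Gene-model `data.frame`; only `biotype == "protein_coding"`
#'   rows are considered.
#' @return `data.frame` with columns `peak_id`, `gene_id`, `tss_distance`.
#' @export
nearest_coding_tss <- function(peaks, genes) {
  check_intervals(peaks, "peak")
  coding <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  out <- data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                    tss_distance = NA_real_, stringsAsFactors = FALSE)
  for (chrom in unique(peaks$chrom)) {
    pidx <- which(peaks$chrom == chrom)
    cc <- coding[coding$chrom == chrom, , drop = FALSE]
    if (!nrow(cc)) next
    # one candidate per distinct TSS position: the lexicographically
    # smallest gene_id (equal positions share the same distance)
    cc <- cc[order(cc$tss, cc$gene_id), , drop = FALSE]
    first <- !duplicated(cc$tss)
    tss <- cc$tss[first]
    ids <- cc$gene_id[first]
    s <- peaks$summit[pidx]
    left <- findInterval(s, tss)
    right <- pmin(left + 1L, length(tss))
    left <- pmax(left, 1L)
    dl <- abs(s - tss[left])
    dr <- abs(s - tss[right])
    use_right <- dr < dl
    gene <- ifelse(use_right, ids[right], ids[left])
    dist <- pmin(dl, dr)
    tie <- which(dl == dr & left != right)
    if (length(tie)) {
      gene[tie] <- pmin(ids[left[tie]], ids[right[tie]])
    }
    out$gene_id[pidx] <- gene
    out$tss_distance[pidx] <- dist
  }
  if (anyNA(out$gene_id)) {
    warning(sum(is.na(out$gene_id)),
            " peak(s) on chromosomes without protein-coding genes")
  }
  out
}

#' Distance-weighted activity score
#'
#' `score = r / (tss_distance + 1)`: the trajectory correlation damped by the
#' genomic distance (in bases) between the peak summit and the nearest
#' protein-coding TSS. The score keeps the sign of `r`, never exceeds `|r|`,
#' equals `r` at distance 0 and decreases strictly with distance, so it
#' prioritises proximal, putatively cis-regulatory associations.
#'
#' @param r Pearson correlation(s).
#' @param tss_distance Non-negative distance(s) in bases.
#' @return Numeric score(s).
#' @export
activity_score <- function(r, tss_distance) {
  if (any(tss_distance < 0, na.rm = TRUE)) {
    stop("tss_distance must be >= 0", call. = FALSE)
  }
  r / (tss_distance + 1)
}

#' Build prioritised lncRNA-peak-gene triads
#'
#' Keeps pairs with `r >= r_min` (pairs with missing `r` are dropped),
#' attaches each peak's nearest protein-coding TSS and activity score, and
#' retains, per gene, only the triad with the highest activity score (ties
#' broken by smaller TSS distance, then lexicographic `lnc_id`). Genes are
#' labelled `up`, `down` or `ns` from the differential coding-gene sets.
#'
#' @param pairs Pair `data.frame` with `r` filled in (see
#'   [correlate_pairs()]).
#' @param peaks Peak `data.frame` (provides summits for TSS distances).
#' @param genes Gene-model `data.frame` (provides protein-coding TSSs).
#' @param de_genes_up,de_genes_down Disjoint character vectors of up- and
#'   downregulated differential coding genes.
#' @param r_min Minimum trajectory correlation (default 0.5).
#' @return `data.frame` sorted by decreasing `activity_score` with columns
#'   `lnc_id`, `peak_id`, `gene_id`, `r`, `tss_distance`, `activity_score`,
#'   `gene_direction`.
#' @export
build_triads <- function(pairs, peaks, genes, de_genes_up = character(),
                         de_genes_down = character(), r_min = 0.5) {
  if (length(intersect(de_genes_up, de_genes_down))) {
    stop("up- and downregulated gene sets must be disjoint", call. = FALSE)
  }
  empty <- data.frame(lnc_id = character(), peak_id = character(),
                      gene_id = character(), r = numeric(),
                      tss_distance = numeric(), activity_score = numeric(),
                      gene_direction = character(), stringsAsFactors = FALSE)
  keep <- !is.na(pairs$r) & pairs$r >= r_min
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  pk_idx <- match(unique(pairs$peak_id), peaks$peak_id)
  if (anyNA(pk_idx)) {
    stop("pair table references peaks absent from the peak table",
         call. = FALSE)
  }
  nt <- nearest_coding_tss(peaks[pk_idx, , drop = FALSE], genes)
  hit <- match(pairs$peak_id, nt$peak_id)
  tri <- data.frame(
    lnc_id = pairs$lnc_id,
    peak_id = pairs$peak_id,
    gene_id = nt$gene_id[hit],
    r = pairs$r,
    tss_distance = nt$tss_distance[hit],
    stringsAsFactors = FALSE
  )
  tri <- tri[!is.na(tri$gene_id), , drop = FALSE]
  if (!nrow(tri)) return(empty)
  tri$activity_score <- activity_score(tri$r, tri$tss_distance)
  # one triad per gene: maximum activity score, then smaller TSS distance,
  # then lexicographic lnc_id
  ord <- order(tri$gene_id, -tri$activity_score, tri$tss_distance,
               tri$lnc_id)
  tri <- tri[ord, , drop = FALSE]
  tri <- tri[!duplicated(tri$gene_id), , drop = FALSE]
  tri$gene_direction <- ifelse(
    tri$gene_id %in% de_genes_up, "up",
    ifelse(tri$gene_id %in% de_genes_down, "down", "ns")
  )
  tri <- tri[order(-tri$activity_score, tri$gene_id), , drop = FALSE]
  rownames(tri) <- NULL
  tri
}
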