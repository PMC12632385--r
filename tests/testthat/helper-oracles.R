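# Independent brute-force oracles. Each is written from the definition of
# the quantity it checks, deliberately on a different code path from the
# package implementation.

# Chi-square(4) upper tail in closed form: exp(-x/2) * (1 + x/2).
oracle_chisq4_sf <- function(x) exp(-x / 2) * (1 + x / 2)

# Benjamini-Hochberg step-up by explicit double loop over the sorted
# p-values: q_(i) = min(1, min_{j >= i} m/j * p_(j)), mapped back.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) {
      best <- min(best, m / j * ps[j])
    }
    qs[i] <- min(1, best)
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# Definitional Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# All-pairs scan for local lncRNA-peak pairs.
oracle_local_pairs <- function(genes, peaks, window) {
  out <- character(0)
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(peaks))) {
      if (genes$chrom[i] != peaks$chrom[j]) next
      lmid <- (genes$start[i] + genes$end[i]) %/% 2
      pmid <- (peaks$start[j] + peaks$end[j]) %/% 2
      if (abs(lmid - pmid) <= window) {
        out <- c(out, paste(genes$gene_id[i], peaks$peak_id[j]))
      }
    }
  }
  sort(out)
}

# Row-by-row scan of the peak count filter.
oracle_count_filter <- function(peaks, counts, min_reads, min_samples) {
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    row <- counts[counts$peak_id == peaks$peak_id[i], -1]
    keep[i] <- sum(as.numeric(row) >= min_reads) >= min_samples
  }
  peaks$peak_id[keep & grepl("^(chr)?([0-9]+|[XY])$", peaks$chrom)]
}

# ORF scan by walking codons with substr from each ATG occurrence.
oracle_smorfs <- function(s, min_len) {
  s <- toupper(s)
  out <- data.frame(start_nt = integer(), end_nt = integer(),
                    nt_len = integer())
  hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(out)
  for (a in as.integer(hits)) {
    pos <- a + 3L
    repeat {
      if (pos + 2L > nchar(s)) break
      cod <- substr(s, pos, pos + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- pos + 3L - a
        if (len >= min_len) {
          out <- rbind(out, data.frame(start_nt = a - 1L,
                                       end_nt = a + len - 1L,
                                       nt_len = len))
        }
        break
      }
      pos <- pos + 3L
    }
  }
  out[order(out$start_nt, out$end_nt), , drop = FALSE]
}

# Per-gene triad deduplication by explicit split and scan.
oracle_triad_dedup <- function(candidates) {
  picks <- lapply(split(candidates, candidates$gene_id), function(d) {
    d <- d[order(-d$activity_score, d$tss_distance, d$lnc_id), ]
    d[1, ]
  })
  do.call(rbind, unname(picks))
}

# ceRNA edges by explicit double loop.
oracle_cerna <- function(targets, up, lnc) {
  edges <- character(0)
  for (m in names(targets)) {
    edges <- c(edges, paste(lnc, m, "lnc_mirna"))
    for (g in targets[[m]]) {
      if (g %in% up) edges <- c(edges, paste(m, g, "mirna_gene"))
    }
  }
  sort(edges)
}
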