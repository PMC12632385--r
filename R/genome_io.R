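# Genomic annotation, peak and sequence I/O plus master-peak-list
# construction. All internal coordinates are 0-based half-open; GTF input
# (1-based closed) is converted on read, BED passes through unchanged.

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF and returns one row per `gene` record with
#' coordinates converted to the package's internal 0-based half-open
#' convention. The transcription start site (TSS) is the interval start for
#' `+` or unstranded genes and `end - 1` for `-` strand genes. Biotypes other
#' than `lncRNA` and `protein_coding` are mapped to `"other"`.
#'
#' Exon records, when present, are attached as a list-column `exons` (one
#' `data.frame` of 0-based half-open intervals per gene, sorted by start);
#' genes without exon records get their own interval as a single exon.
#'
#' @param path Path to a GTF file with `gene_id` and `gene_biotype`
#'   attributes.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `tss` and list-column `exons`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    stop("malformed GTF line ", body[which(nfield < 9L)[1L]], " in ", path,
         ": expected 9 tab-separated fields", call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  md <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(md)) stop("GTF lacks gene_id attributes: ", path)
  types <- if ("type" %in% names(md)) as.character(md$type) else
    rep("gene", length(gr))
  is_gene <- types == "gene"
  if (!any(is_gene)) stop("no gene records in GTF: ", path)
  g <- gr[is_gene]
  gid <- as.character(S4Vectors::mcols(g)$gene_id)
  if (anyDuplicated(gid)) {
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  biotype <- as.character(S4Vectors::mcols(g)$gene_biotype)
  if (all(is.na(biotype))) biotype <- rep("other", length(g))
  biotype[is.na(biotype)] <- "other"
  biotype[!biotype %in% c("lncRNA", "protein_coding")] <- "other"
  strand <- as.character(BiocGenerics::strand(g))
  strand[strand == "*"] <- "."
  start0 <- BiocGenerics::start(g) - 1L
  end0 <- BiocGenerics::end(g)
  genes <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = start0,
    end = end0,
    strand = strand,
    biotype = biotype,
    tss = ifelse(strand == "-", end0 - 1L, start0),
    stringsAsFactors = FALSE
  )
  check_intervals(genes, "gene model")

  ex <- gr[types == "exon"]
  exon_list <- rep(list(NULL), nrow(genes))
  names(exon_list) <- genes$gene_id
  if (length(ex)) {
    exdf <- data.frame(
      gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
      chrom = as.character(GenomicRanges::seqnames(ex)),
      start = BiocGenerics::start(ex) - 1L,
      end = BiocGenerics::end(ex),
      stringsAsFactors = FALSE
    )
    split_ex <- split(exdf[c("chrom", "start", "end")], exdf$gene_id)
    for (id in names(split_ex)) {
      d <- split_ex[[id]]
      exon_list[[id]] <- d[order(d$start), , drop = FALSE]
    }
  }
  for (i in seq_len(nrow(genes))) {
    if (is.null(exon_list[[i]])) {
      exon_list[[i]] <- genes[i, c("chrom", "start", "end")]
    }
  }
  genes$exons <- I(unname(exon_list))
  rownames(genes) <- NULL
  genes
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gene_models()]: emits one `gene` record per row (plus one
#' `exon` record per entry of the `exons` list-column when present),
#' converting internal 0-based half-open coordinates back to GTF's 1-based
#' closed convention.
#'
#' @param genes Gene-model `data.frame` as returned by [read_gene_models()].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(genes, path) {
  check_intervals(genes, "gene model")
  strand <- ifelse(genes$strand == ".", "*", genes$strand)
  rows <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = strand
  )
  S4Vectors::mcols(rows) <- S4Vectors::DataFrame(
    source = "exlnc", type = "gene",
    gene_id = genes$gene_id, gene_biotype = genes$biotype
  )
  out <- rows
  if (!is.null(genes$exons)) {
    exn <- vapply(genes$exons, nrow, integer(1))
    exdf <- do.call(rbind, genes$exons)
    exgr <- GenomicRanges::GRanges(
      exdf$chrom, IRanges::IRanges(exdf$start + 1L, exdf$end),
      strand = rep(strand, exn)
    )
    S4Vectors::mcols(exgr) <- S4Vectors::DataFrame(
      source = "exlnc", type = "exon",
      gene_id = rep(genes$gene_id, exn),
      gene_biotype = rep(genes$biotype, exn)
    )
    out <- c(rows, exgr)
  }
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Read accessibility peaks from a BED or narrowPeak file
#'
#' BED coordinates (0-based half-open) are kept as-is. For ENCODE narrowPeak
#' input (10 columns) the summit is `start + offset` when the offset in
#' column 10 is non-negative; otherwise, and for plain BED, the summit falls
#' back to the interval midpoint `floor((start + end) / 2)`.
#'
#' @param path Path to a BED3/BED6 or narrowPeak file.
#' @return A `data.frame` with columns `peak_id`, `chrom`, `start`, `end`,
#'   `summit`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- lines[nzchar(lines) & !startsWith(lines, "track") &
                  !startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(), summit = integer(),
                      stringsAsFactors = FALSE))
  }
  ncol1 <- length(strsplit(body[1L], "\t", fixed = TRUE)[[1L]])
  gr <- tryCatch({
    if (ncol1 >= 10L) {
      rtracklayer::import(path, format = "BED",
                          extraCols = c(signalValue = "numeric",
                                        pValue = "numeric",
                                        qValue = "numeric",
                                        peak = "integer"))
    } else {
      rtracklayer::import(path, format = "BED")
    }
  }, error = function(e) {
    stop("failed to parse peak file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (any(start0 >= end0)) {
    stop("invalid peak interval (start >= end) in ", path, call. = FALSE)
  }
  nm <- S4Vectors::mcols(gr)$name
  ids <- if (!is.null(nm) && !all(is.na(nm)) && !anyDuplicated(nm)) {
    as.character(nm)
  } else {
    sprintf("peak_%05d", seq_along(gr))
  }
  mid <- (start0 + end0) %/% 2L
  summit <- mid
  off <- S4Vectors::mcols(gr)$peak
  if (!is.null(off)) {
    off <- as.integer(off)
    use <- !is.na(off) & off >= 0L
    summit[use] <- start0[use] + off[use]
  }
  bad <- which(summit < start0 | summit >= end0)
  if (length(bad)) {
    stop("summit outside interval for peak ", ids[bad[1L]], " in ", path,
         call. = FALSE)
  }
  out <- data.frame(peak_id = ids, chrom = as.character(
    GenomicRanges::seqnames(gr)), start = start0, end = end0,
    summit = summit, stringsAsFactors = FALSE)
  check_intervals(out, "peak")
  out
}

#' Write peaks as a narrowPeak file
#'
#' Emits the 10-column ENCODE narrowPeak layout so that the summit survives a
#' round trip through [read_peaks()] (column 10 holds the summit offset from
#' the interval start).
#'
#' @param peaks Peak `data.frame` (`peak_id`, `chrom`, `start`, `end`,
#'   `summit`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_narrowpeak <- function(peaks, path) {
  check_intervals(peaks, "peak")
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   0L, ".", 0, -1, -1, peaks$summit - peaks$start)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Internal: replace each peak by the fixed-width window around its summit.
trim_peaks <- function(peaks, half_width = 100L) {
  check_intervals(peaks, "peak")
  start <- peaks$summit - half_width
  clamped <- start < 0L
  if (any(clamped)) {
    warning(sum(clamped), " trimmed peak window(s) clamped at position 0")
    start[clamped] <- 0L
  }
  out <- peaks
  out$start <- as.integer(start)
  out$end <- as.integer(peaks$summit + half_width)
  out
}

#' Merge overlapping or book-ended peaks
#'
#' Per chromosome, overlapping and book-ended (end == next start) intervals
#' are merged; the merged peak's summit is the midpoint of the merged
#' interval. A merged interval covering exactly one input peak keeps that
#' peak's identifier (and its summit); merged clusters get a positional
#' identifier. Output is sorted by (chrom, start) and non-overlapping, so
#' applying `merge_peaks()` to its own output returns it unchanged.
#'
#' @param peaks Peak `data.frame`.
#' @return Merged peak `data.frame`.
#' @export
merge_peaks <- function(peaks) {
  check_intervals(peaks, "peak")
  if (nrow(peaks) == 0L) return(peaks)
  lev <- sort(unique(peaks$chrom))
  gr <- GenomicRanges::GRanges(
    factor(peaks$chrom, levels = lev),
    IRanges::IRanges(peaks$start + 1L, peaks$end)
  )
  red <- BiocGenerics::sort(GenomicRanges::reduce(gr))
  hits <- GenomicRanges::findOverlaps(red, gr)
  nmember <- tabulate(S4Vectors::queryHits(hits), nbins = length(red))
  start0 <- BiocGenerics::start(red) - 1L
  end0 <- BiocGenerics::end(red)
  chrom <- as.character(GenomicRanges::seqnames(red))
  ids <- sprintf("mpeak_%s_%d", chrom, start0)
  summit <- (start0 + end0) %/% 2L
  single <- which(nmember == 1L)
  if (length(single)) {
    src <- S4Vectors::subjectHits(hits)[match(single,
                                              S4Vectors::queryHits(hits))]
    ids[single] <- peaks$peak_id[src]
    summit[single] <- peaks$summit[src]
  }
  data.frame(peak_id = ids, chrom = chrom, start = start0, end = end0,
             summit = as.integer(summit), stringsAsFactors = FALSE)
}

#' Build a master peak list by summit trimming and merging
#'
#' Each input peak is replaced by the window of `2 * half_width` bases centred
#' on its summit (clamped at position 0 with a warning); windows from all
#' input sets are then merged per chromosome with [merge_peaks()]. With the
#' default `half_width = 100` every pre-merge window is exactly 200 bp, the
#' convention used for master-peak-list construction in multi-condition
#' ATAC-seq designs.
#'
#' @param ... One or more peak `data.frame`s (or a single list of them).
#' @param half_width Half window width in bases (default 100, i.e. 200-bp
#'   windows).
#' @return Merged, sorted, non-overlapping peak `data.frame`.
#' @export
trim_and_merge_peaks <- function(..., half_width = 100L) {
  sets <- list(...)
  if (length(sets) == 1L && is.data.frame(sets[[1L]])) {
    sets <- sets[1L]
  } else if (length(sets) == 1L && is.list(sets[[1L]])) {
    sets <- sets[[1L]]
  }
  if (!length(sets)) stop("no peak sets supplied")
  all_peaks <- do.call(rbind, sets)
  all_peaks$peak_id <- make.unique(all_peaks$peak_id)
  merge_peaks(trim_peaks(all_peaks, half_width = half_width))
}

#' Chromosome names kept by default in peak filtering
#'
#' Matches autosomes and the X and Y sex chromosomes, with or without a
#' `chr` prefix (e.g. `chr1`, `20`, `chrX`), excluding scaffolds and other
#' non-standard contigs.
#'
#' @param chroms Character vector of chromosome names.
#' @return Logical vector: is each name a standard chromosome?
#' @export
is_standard_chromosome <- function(chroms) {
  grepl("^(chr)?([0-9]+|[XY])$", chroms)
}

#' Filter peaks by read support across samples
#'
#' Keeps a peak when at least `min_samples` samples have at least `min_reads`
#' reads, and the peak lies on an allowed chromosome (by default autosomes
#' and sex chromosomes, see [is_standard_chromosome()]).
#'
#' @param peaks Peak `data.frame`.
#' @param counts `data.frame` with a `peak_id` column followed by one
#'   non-negative integer column per sample; every peak must have a row.
#' @param min_reads Read threshold per sample (default 10).
#' @param min_samples Number of samples that must reach `min_reads`
#'   (default 4).
#' @param keep_chroms Either `"standard"` (default) or an explicit character
#'   allow-list of chromosome names; `NULL` keeps all chromosomes.
#' @return The subset of `peaks` passing both filters.
#' @export
filter_peaks_by_counts <- function(peaks, counts, min_reads = 10L,
                                   min_samples = 4L,
                                   keep_chroms = "standard") {
  check_intervals(peaks, "peak")
  idx <- match(peaks$peak_id, counts$peak_id)
  if (anyNA(idx)) {
    stop("no counts row for peak(s): ",
         paste(head(peaks$peak_id[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(counts[idx, setdiff(names(counts), "peak_id"),
                          drop = FALSE])
  if (any(mat < 0, na.rm = TRUE)) stop("negative peak counts")
  keep <- rowSums(mat >= min_reads) >= min_samples
  if (is.null(keep_chroms)) {
    chrom_ok <- rep(TRUE, nrow(peaks))
  } else if (identical(keep_chroms, "standard")) {
    chrom_ok <- is_standard_chromosome(peaks$chrom)
  } else {
    chrom_ok <- peaks$chrom %in% keep_chroms
  }
  out <- peaks[keep & chrom_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}
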