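# Small fixtures built in code at test time.

# Hand-written GTF text (1-based closed coordinates), independent of the
# package's GTF writer.
write_fixture_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_gene_line <- function(chrom, start, end, strand, gene_id, biotype,
                          type = "gene") {
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
          chrom, type, start, end, strand, gene_id, biotype)
}

write_fixture_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

narrowpeak_line <- function(chrom, start, end, name, summit_offset) {
  sprintf("%s\t%d\t%d\t%s\t0\t.\t0\t-1\t-1\t%d",
          chrom, start, end, name, summit_offset)
}

make_peaks <- function(chrom, summits, half = 250L, ids = NULL) {
  n <- length(summits)
  data.frame(
    peak_id = if (is.null(ids)) sprintf("pk_%03d", seq_len(n)) else ids,
    chrom = rep_len(chrom, n),
    start = as.integer(summits - half),
    end = as.integer(summits + half),
    summit = as.integer(summits),
    stringsAsFactors = FALSE
  )
}

make_genes <- function(chrom, starts, len = 1000L, biotype = "lncRNA",
                       ids = NULL, strand = "+") {
  n <- length(starts)
  start <- as.integer(starts)
  end <- as.integer(starts + len)
  strand <- rep_len(strand, n)
  data.frame(
    gene_id = if (is.null(ids)) sprintf("g_%03d", seq_len(n)) else ids,
    chrom = rep_len(chrom, n),
    start = start,
    end = end,
    strand = strand,
    biotype = rep_len(biotype, n),
    tss = ifelse(strand == "-", end - 1L, start),
    stringsAsFactors = FALSE
  )
}

make_records <- function(feature_id, log2fc, p_value, mean_fpkm = 10,
                         tissue = "t1", sex = "M", week = 1L,
                         adj_p = NA_real_) {
  data.frame(feature_id = feature_id, tissue = tissue, sex = sex,
             week = week, log2fc = log2fc, p_value = p_value,
             adj_p = adj_p, mean_fpkm = mean_fpkm, stringsAsFactors = FALSE)
}
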