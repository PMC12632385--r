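# Sequence-level characterisation of lncRNAs vs protein-coding transcripts:
# GC content, small open reading frame (smORF) discovery over the three
# sense frames, microprotein search-database construction, and the group
# tests (Mann-Whitney U for length/GC, Kolmogorov-Smirnov for MFE).

#' Exonic GC content of nucleotide sequences
#'
#' Percentage `100 * (G + C) / (A + C + G + T)`, case-insensitive, with `U`
#' treated as `T`. `N` and other ambiguity codes are excluded from both the
#' numerator and the denominator so unknown bases do not bias the estimate.
#'
#' @param sequence Character vector of nucleotide sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @return Numeric vector of GC percentages in \[0, 100\].
#' @export
#' @examples
#' gc_content(c("ATGC", "GCNN"))
gc_content <- function(sequence) {
  s <- chartr("U", "T", toupper(as.character(sequence)))
  gc <- nchar(gsub("[^GC]", "", s))
  denom <- nchar(gsub("[^ACGT]", "", s))
  if (any(denom == 0L)) {
    stop("sequence with no unambiguous A/C/G/T bases", call. = FALSE)
  }
  100 * gc / denom
}

# Internal: translate a vector of codons with the standard code; unknown
# codons (ambiguity bases) become "X".
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

find_smorfs_one <- function(s, min_len, seq_id) {
  s <- chartr("U", "T", toupper(s))
  n <- nchar(s)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    if (!length(atg) || !length(stp)) next
    # first in-frame stop at or after each ATG (an ATG is never a stop)
    nxt <- findInterval(atg - 1L, stp) + 1L
    ok <- nxt <= length(stp)
    atg <- atg[ok]
    stop_i <- stp[nxt[ok]]
    nt_len <- (stop_i - atg + 1L) * 3L
    keep <- nt_len >= min_len
    if (!any(keep)) next
    atg <- atg[keep]
    stop_i <- stop_i[keep]
    nt_len <- nt_len[keep]
    pep <- vapply(seq_along(atg), function(i) {
      translate_codons(codons[atg[i]:(stop_i[i] - 1L)])
    }, character(1))
    out[[length(out) + 1L]] <- data.frame(
      seq_id = seq_id, frame = frame,
      start_nt = frame + (atg - 1L) * 3L,
      end_nt = frame + stop_i * 3L,
      nt_len = nt_len, peptide = pep, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(), frame = integer(),
                      start_nt = integer(), end_nt = integer(),
                      nt_len = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start_nt, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find small open reading frames (smORFs)
#'
#' Scans the three sense-strand frames 5' to 3'. An ORF runs from an `ATG` to
#' the first in-frame stop codon (`TAA`/`TAG`/`TGA`), stop included, and is
#' reported when its nucleotide length (ATG through stop, inclusive) is at
#' least `min_len` -- so the default `min_len = 30` corresponds to a 9-residue
#' peptide. Every `ATG` starts a candidate, including ATGs nested inside a
#' reported ORF; ORFs lacking an in-frame stop are not reported.
#'
#' @param sequence A single nucleotide string, a named character vector, or a
#'   [Biostrings::DNAStringSet]; names become `seq_id`s.
#' @param min_len Minimum ORF length in nucleotides, stop codon included
#'   (default 30).
#' @param longest_only Report only the longest ORF per sequence (ties broken
#'   by smaller start, then frame; default FALSE reports all).
#' @return `data.frame` with columns `seq_id`, `frame` (0/1/2), `start_nt`
#'   (0-based offset of the A of ATG), `end_nt` (exclusive offset past the
#'   stop), `nt_len`, `peptide` (amino acids, stop not included).
#' @export
find_smorfs <- function(sequence, min_len = 30L, longest_only = FALSE) {
  nm <- names(sequence)
  seqs <- as.character(sequence)
  names(seqs) <- nm
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1L) "seq" else
      sprintf("seq_%04d", seq_along(seqs))
  }
  res <- do.call(rbind, lapply(names(seqs), function(id) {
    find_smorfs_one(seqs[[id]], min_len = min_len, seq_id = id)
  }))
  if (longest_only && nrow(res)) {
    res <- res[order(res$seq_id, -res$nt_len, res$start_nt, res$frame), ,
               drop = FALSE]
    res <- res[!duplicated(res$seq_id), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Build a microprotein search database from lncRNA sequences
#'
#' Collects the peptides of all smORFs over the three sense frames (see
#' [find_smorfs()]), deduplicated per sequence by `(seq_id, peptide)`, into a
#' protein FASTA suitable for augmenting a proteomics search database with
#' putative lncRNA-encoded microproteins. Headers encode
#' `seq_id|frame<k>|<start>-<end>` in 0-based coordinates.
#'
#' @param lnc_sequences Path to a nucleotide FASTA, a named character
#'   vector, or a [Biostrings::DNAStringSet].
#' @param min_len Minimum ORF length in nucleotides (default 30).
#' @param out_fasta Optional output FASTA path for the peptides.
#' @return An [Biostrings::AAStringSet] of peptides (invisibly when
#'   `out_fasta` is given).
#' @export
build_microprotein_db <- function(lnc_sequences, min_len = 30L,
                                  out_fasta = NULL) {
  if (is.character(lnc_sequences) && length(lnc_sequences) == 1L &&
      file.exists(lnc_sequences)) {
    lnc_sequences <- Biostrings::readDNAStringSet(lnc_sequences)
  }
  orfs <- find_smorfs(lnc_sequences, min_len = min_len)
  if (nrow(orfs)) {
    orfs <- orfs[!duplicated(orfs[c("seq_id", "peptide")]), , drop = FALSE]
  }
  peptides <- Biostrings::AAStringSet(orfs$peptide)
  names(peptides) <- sprintf("%s|frame%d|%d-%d", orfs$seq_id, orfs$frame,
                             orfs$start_nt, orfs$end_nt)
  if (!is.null(out_fasta)) {
    Biostrings::writeXStringSet(peptides, out_fasta)
    return(invisible(peptides))
  }
  peptides
}

#' Compare two groups of sequence features
#'
#' Two-sided group comparison as used for lncRNA vs protein-coding feature
#' distributions: `test = "rank"` runs the Mann-Whitney U test (exact
#' enumeration when `n * m <= 400` and there are no ties, otherwise the
#' normal approximation with tie correction); `test = "distribution"` runs
#' the two-sample Kolmogorov-Smirnov test (exact for small samples).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param test `"rank"` (Mann-Whitney U) or `"distribution"`
#'   (Kolmogorov-Smirnov).
#' @return List with `statistic` (U or D), `p_value`, `test_name`, `n_a`,
#'   `n_b`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("rank", "distribution")) {
  test <- match.arg(test)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group must have at least 2 values", call. = FALSE)
  }
  if (test == "rank") {
    nm <- length(values_a) * length(values_b)
    ht <- suppressWarnings(
      wilcox.test(values_a, values_b, exact = nm <= 400,
                  alternative = "two.sided")
    )
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test_name = "mann_whitney_u",
         n_a = length(values_a), n_b = length(values_b))
  } else {
    ht <- suppressWarnings(ks.test(values_a, values_b,
                                   alternative = "two.sided"))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test_name = "kolmogorov_smirnov",
         n_a = length(values_a), n_b = length(values_b))
  }
}
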