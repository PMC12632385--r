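# Differential lncRNA set construction: the expression (FPKM) gate, the
# sensitive raw-p scheme (p <= 0.01, |log2FC| >= 1) and the stringent FDR
# scheme (BH q <= 0.10, |log2FC| >= 0.5), plus per-tissue sex-overlap and
# Z-score trajectory summaries and the ceRNA cross-reference network.
#
# A differential-result table ("records") has one row per feature x tissue x
# sex x week contrast against the sex-matched sedentary controls, with
# columns feature_id, tissue, sex (M/F), week (1/2/4/8), log2fc, p_value,
# adj_p, mean_fpkm.

check_records <- function(records) {
  need <- c("feature_id", "tissue", "sex", "week", "log2fc", "p_value")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records)) {
    if (!all(records$sex %in% STUDY_SEXES)) stop("sex must be one of M, F")
    if (!all(records$week %in% STUDY_WEEKS)) {
      stop("week must be one of ", paste(STUDY_WEEKS, collapse = ", "))
    }
    p <- records$p_value
    if (anyNA(p) || any(p <= 0) || any(p > 1)) {
      stop("p_value must lie in (0, 1]", call. = FALSE)
    }
  }
  invisible(records)
}

#' Apply the expression (FPKM) gate
#'
#' Keeps features whose mean expression across all samples of the tissue is
#' at least `fpkm_min` fragments per kilobase per million mapped reads
#' (inclusive boundary). When a feature carries several records, its
#' per-record `mean_fpkm` values are averaged first.
#'
#' @param records Differential-result table; `mean_fpkm` must be present and
#'   non-missing.
#' @param fpkm_min Expression threshold (default 1).
#' @param strict Use a strict `>` comparison instead of `>=` (default FALSE).
#' @return Sorted character vector of feature identifiers passing the gate.
#' @export
filter_expressed <- function(records, fpkm_min = 1.0, strict = FALSE) {
  check_records(records)
  if (nrow(records) == 0L) return(character(0))
  if (!"mean_fpkm" %in% names(records) || anyNA(records$mean_fpkm)) {
    bad <- if ("mean_fpkm" %in% names(records)) {
      unique(records$feature_id[is.na(records$mean_fpkm)])
    } else unique(records$feature_id)
    stop("mean_fpkm missing for feature(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  mfpkm <- tapply(records$mean_fpkm, records$feature_id, mean)
  keep <- if (strict) mfpkm > fpkm_min else mfpkm >= fpkm_min
  sort(names(mfpkm)[keep])
}

new_diff_set <- function(members, scheme) {
  members <- members[order(members$feature_id, members$sex, members$week), ,
                     drop = FALSE]
  rownames(members) <- NULL
  structure(
    list(
      tissues = sort(unique(members$tissue)),
      scheme = scheme,
      members = members,
      unique_features = sort(unique(members$feature_id))
    ),
    class = "diff_set"
  )
}

#' @export
print.diff_set <- function(x, ...) {
  cat("Differential set (scheme: ", x$scheme, ")\n", sep = "")
  cat("  tissues: ", paste(x$tissues, collapse = ", "), "\n", sep = "")
  cat("  member cells: ", nrow(x$members),
      "; unique features: ", length(x$unique_features), "\n", sep = "")
  invisible(x)
}

#' Call differential features with the sensitive raw-p scheme
#'
#' A (feature, sex, week) cell is a member when `p_value <= p_max` and
#' `|log2fc| >= lfc_min` (both boundaries inclusive by default). Records are
#' expected to be expression-filtered already (see [filter_expressed()]).
#'
#' @param records Differential-result table.
#' @param p_max Raw p-value threshold (default 0.01).
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @param strict Use strict `<` / `>` comparisons (default FALSE).
#' @return A `diff_set` object (scheme `"primary"`) with elements `tissues`,
#'   `scheme`, `members` (data.frame of member cells) and `unique_features`.
#' @export
call_differential <- function(records, p_max = 0.01, lfc_min = 1.0,
                              strict = FALSE) {
  check_records(records)
  keep <- if (strict) {
    records$p_value < p_max & abs(records$log2fc) > lfc_min
  } else {
    records$p_value <= p_max & abs(records$log2fc) >= lfc_min
  }
  new_diff_set(records[keep, , drop = FALSE], scheme = "primary")
}

#' Call differential features with the stringent FDR scheme
#'
#' A cell is a member when its adjusted p-value (`adj_p`, Benjamini-Hochberg
#' within tissue, see [bh_adjust()]) is at most `fdr` and
#' `|log2fc| >= lfc_min`.
#'
#' @param records Differential-result table with non-missing `adj_p`.
#' @param fdr FDR threshold (default 0.10).
#' @param lfc_min Absolute log2 fold-change threshold (default 0.5).
#' @param strict Use strict comparisons (default FALSE).
#' @return A `diff_set` object (scheme `"stringent"`).
#' @export
call_differential_fdr <- function(records, fdr = 0.10, lfc_min = 0.5,
                                  strict = FALSE) {
  check_records(records)
  if (!"adj_p" %in% names(records) || anyNA(records$adj_p)) {
    stop("adj_p missing: compute it with bh_adjust() within tissue first",
         call. = FALSE)
  }
  keep <- if (strict) {
    records$adj_p < fdr & abs(records$log2fc) > lfc_min
  } else {
    records$adj_p <= fdr & abs(records$log2fc) >= lfc_min
  }
  new_diff_set(records[keep, , drop = FALSE], scheme = "stringent")
}

#' Summarise the overlap of male and female differential sets
#'
#' `shared_pct` is `100 * |intersection| / |union|` (0 when both sets are
#' empty), a symmetric, bounded measure of how much of the differential
#' landscape the sexes share.
#'
#' @param male_set,female_set Character vectors of feature identifiers.
#' @return List with `shared`, `male_only`, `female_only` (sorted character
#'   vectors) and `shared_pct`.
#' @export
sex_overlap_summary <- function(male_set, female_set) {
  male_set <- unique(as.character(male_set))
  female_set <- unique(as.character(female_set))
  shared <- sort(intersect(male_set, female_set))
  un <- union(male_set, female_set)
  list(
    shared = shared,
    male_only = sort(setdiff(male_set, female_set)),
    female_only = sort(setdiff(female_set, male_set)),
    shared_pct = if (length(un)) 100 * length(shared) / length(un) else 0
  )
}

#' Standardise a matrix row-wise to Z-scores
#'
#' Each row is centred and scaled to mean 0, sd 1 (the convention used for
#' expression heatmaps); constant rows become all-zero.
#'
#' @param mat Numeric matrix (features in rows).
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, sd)
  s[s == 0 | is.na(s)] <- 1
  (mat - mu) / s
}

#' Z-score trajectory summary over a differential set
#'
#' Given a feature-by-week matrix of standardised expression (columns for
#' weeks 1, 2, 4 and 8), restricted to the differential features, reports the
#' grand mean Z-score and the change in mean Z-score from week 1 to week 8.
#'
#' @param z_table Numeric matrix or data.frame with columns named
#'   `"1", "2", "4", "8"` (or `wk1` ... `wk8`) and features in rows.
#' @param diff_features Character vector of differential feature identifiers
#'   (must match rownames of `z_table`).
#' @return List with `mean_z`, `delta_z_w8_w1` and `n_features`.
#' @export
trajectory_summary <- function(z_table, diff_features) {
  mat <- as.matrix(z_table)
  cn <- sub("^wk", "", colnames(mat))
  need <- as.character(STUDY_WEEKS)
  if (!all(need %in% cn)) {
    stop("z_table must have columns for weeks ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  colnames(mat) <- cn
  rows <- intersect(rownames(mat), diff_features)
  if (!length(rows)) stop("empty differential set", call. = FALSE)
  mat <- mat[rows, need, drop = FALSE]
  list(
    mean_z = mean(mat),
    delta_z_w8_w1 = mean(mat[, "8"]) - mean(mat[, "1"]),
    n_features = nrow(mat)
  )
}

#' Build a ceRNA (lncRNA-miRNA-mRNA) cross-reference network
#'
#' A lncRNA acting as a competing endogenous RNA sequesters miRNAs, relieving
#' repression of their targets. The network links the lncRNA to each miRNA it
#' binds, and each miRNA to those of its predicted target genes that are in
#' the upregulated differential protein-coding set.
#'
#' @param mirna_targets Named list: miRNA identifier -> character vector of
#'   target gene identifiers (each non-empty).
#' @param up_degs Character vector of upregulated differential coding genes.
#' @param lnc_id The lncRNA identifier.
#' @return `data.frame` with columns `from`, `to`, `edge_type`
#'   (`"lnc_mirna"` or `"mirna_gene"`).
#' @export
build_cerna_network <- function(mirna_targets, up_degs, lnc_id) {
  if (!length(mirna_targets) || is.null(names(mirna_targets))) {
    stop("mirna_targets must be a non-empty named list", call. = FALSE)
  }
  if (any(!lengths(mirna_targets))) {
    stop("each miRNA must have a non-empty target set", call. = FALSE)
  }
  edges <- data.frame(from = lnc_id, to = names(mirna_targets),
                      edge_type = "lnc_mirna", stringsAsFactors = FALSE)
  for (m in names(mirna_targets)) {
    hit <- sort(intersect(mirna_targets[[m]], up_degs))
    if (length(hit)) {
      edges <- rbind(edges, data.frame(from = m, to = hit,
                                       edge_type = "mirna_gene",
                                       stringsAsFactors = FALSE))
    }
  }
  rownames(edges) <- NULL
  edges
}
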