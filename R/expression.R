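# RPKM profiling, self-normalization, clustering and qPCR analytics.

#' RPKM from raw counts
#'
#' RPKM = 1e9 * c / (N * L) with c the read count, N the library size and
#' L the transcript length (summed exon length, bp). When `library_sizes`
#' is `NULL` the column sums of the count matrix are used — the standard
#' fallback when per-sample mapped-read totals are not available.
#'
#' @param counts a counts tibble (`gene_id` + one column per sample).
#' @param gene_lengths a data frame with columns `gene_id` and `length_bp`.
#' @param library_sizes optional named numeric vector of per-sample totals.
#' @return a tibble of the same shape with RPKM values.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  samples <- setdiff(names(counts), "gene_id")
  L <- gene_lengths$length_bp[match(counts$gene_id, gene_lengths$gene_id)]
  if (any(is.na(L))) stop("missing gene length for ",
                          counts$gene_id[is.na(L)][1], call. = FALSE)
  if (any(L <= 0)) stop("non-positive gene length", call. = FALSE)
  mat <- as.matrix(counts[, samples, drop = FALSE])
  if (any(mat < 0)) stop("negative counts", call. = FALSE)
  N <- if (is.null(library_sizes)) colSums(mat) else library_sizes[samples]
  if (any(is.na(N)) || any(N <= 0)) stop("invalid library sizes", call. = FALSE)
  out <- sweep(sweep(mat, 2, N, "/"), 1, L, "/") * 1e9
  bind_cols(counts["gene_id"], as_tibble(out))
}

#' Self-normalize an expression matrix
#'
#' log2(x + 1) followed by a per-gene (row) z-score, the "self-normalized
#' log-converted" convention of clustering heatmap viewers. Constant rows
#' map to all zeros.
#'
#' @param mat an expression tibble (`gene_id` + sample columns).
#' @return a tibble of the same shape; each non-constant row has mean 0 and
#'   sd 1.
#' @export
normalize_expression <- function(mat) {
  samples <- setdiff(names(mat), "gene_id")
  m <- log2(as.matrix(mat[, samples, drop = FALSE]) + 1)
  z <- t(apply(m, 1, function(r) {
    s <- sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  colnames(z) <- samples
  bind_cols(mat["gene_id"], as_tibble(z))
}

#' Hierarchical clustering of expression rows
#'
#' Agglomerative clustering with correlation distance (1 - Pearson) and
#' average linkage; the heatmap-ready matrix is returned with rows in
#' dendrogram order.
#'
#' @param mat a normalized expression tibble (`gene_id` + sample columns).
#' @return a list with `hclust` (the stats::hclust object), `order`
#'   (gene ids in leaf order) and `matrix` (the reordered tibble).
#' @export
cluster_expression <- function(mat) {
  samples <- setdiff(names(mat), "gene_id")
  m <- as.matrix(mat[, samples, drop = FALSE])
  rownames(m) <- mat$gene_id
  if (nrow(m) < 2) stop("need at least 2 genes to cluster", call. = FALSE)
  cc <- suppressWarnings(cor(t(m)))
  cc[is.na(cc)] <- 0 # constant rows: undefined correlation -> distance 1
  diag(cc) <- 1
  hc <- hclust(as.dist(1 - cc), method = "average")
  ord <- rownames(m)[hc$order]
  list(hclust = hc, order = ord,
       matrix = mat[match(ord, mat$gene_id), , drop = FALSE])
}

#' Relative qPCR quantification (ddCt)
#'
#' Per replicate, dCt = Ct(target) - Ct(reference gene in the same sample);
#' ddCt subtracts the mean dCt of the calibrator group for the same target
#' gene; the fold change is 2^(-ddCt). Replicate-level folds are retained
#' for downstream statistics.
#'
#' @param records a tibble with columns `sample`, `gene`, `ct`, `replicate`
#'   and `group`.
#' @param reference_gene the internal reference (housekeeping) gene name.
#' @param calibrator_group the group whose mean dCt anchors ddCt = 0.
#' @return a tibble with one row per target-gene replicate: `gene`,
#'   `group`, `replicate`, `dct`, `ddct`, `fold`.
#' @export
ddct <- function(records, reference_gene, calibrator_group) {
  stopifnot(all(c("sample", "gene", "ct", "replicate", "group") %in% names(records)))
  if (any(records$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  ref <- records[records$gene == reference_gene, ]
  targets <- records[records$gene != reference_gene, ]
  key <- function(d) paste(d$sample, d$replicate, sep = "\r")
  ref_ct <- setNames(ref$ct, key(ref))
  missing_ref <- !(key(targets) %in% names(ref_ct))
  if (any(missing_ref)) {
    stop("missing reference-gene Ct for sample ",
         targets$sample[missing_ref][1], " replicate ",
         targets$replicate[missing_ref][1], call. = FALSE)
  }
  targets$dct <- targets$ct - unname(ref_ct[key(targets)])
  cal <- targets[targets$group == calibrator_group, ] |>
    group_by(.data$gene) |>
    summarise(cal_dct = mean(.data$dct), .groups = "drop")
  out <- left_join(targets, cal, by = "gene")
  if (any(is.na(out$cal_dct))) {
    stop("no calibrator-group measurements for gene ",
         out$gene[is.na(out$cal_dct)][1], call. = FALSE)
  }
  out$ddct <- out$dct - out$cal_dct
  out$fold <- 2^(-out$ddct)
  out[, c("gene", "group", "replicate", "dct", "ddct", "fold")]
}

#' Significance stars from a p-value
#'
#' `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star annotations.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Two-sample t-test with star annotation
#'
#' Two-sided Student's t-test (equal variance by default; set
#' `var_equal = FALSE` for Welch) between two groups, annotated with the
#' conventional significance stars.
#'
#' @param group_a,group_b numeric vectors.
#' @param var_equal assume equal variances (Student) or not (Welch).
#' @return a one-row tibble with `t`, `p`, `stars`.
#' @export
ttest_annotate <- function(group_a, group_b, var_equal = TRUE) {
  if (sd(group_a) == 0 && sd(group_b) == 0 && mean(group_a) == mean(group_b)) {
    return(tibble(t = 0, p = 1, stars = ""))
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  tibble(t = unname(tt$statistic), p = tt$p.value,
         stars = significance_stars(tt$p.value))
}
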