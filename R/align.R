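# Progressive multiple alignment: k-mer distances -> UPGMA guide tree ->
# profile-profile global alignment with BLOSUM62 and affine gaps.

#' Build a progressive multiple sequence alignment
#'
#' Pairwise distances are fractional shared 3-mers, the guide tree is UPGMA
#' (average-linkage agglomeration) and profiles are merged by
#' profile-profile Needleman-Wunsch with BLOSUM62 column scores (expected
#' substitution score between column residue frequencies; gap fractions
#' contribute zero) and affine gap penalties.
#'
#' @param records a tibble with columns `id` and `sequence` (>= 2 rows).
#' @param gap_open,gap_extend affine gap penalties for the profile merge.
#' @return an alignment tibble with columns `id` and `aligned` (gapped
#'   sequences of equal length, gap character `-`), rows in input order.
#' @export
build_msa <- function(records, gap_open = 10, gap_extend = 0.5) {
  if (nrow(records) < 2) stop("alignment needs at least 2 sequences", call. = FALSE)
  if (anyDuplicated(records$id)) stop("duplicate sequence id", call. = FALSE)
  assert_aa(records$sequence)
  seqs <- toupper(records$sequence)
  n <- length(seqs)

  kmers <- function(s) {
    L <- nchar(s)
    if (L < 3) return(character(0))
    unique(substring(s, 1:(L - 2), 3:L))
  }
  ks <- lapply(seqs, kmers)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sum(ks[[i]] %in% ks[[j]])
      denom <- max(1L, min(length(ks[[i]]), length(ks[[j]])))
      D[i, j] <- D[j, i] <- 1 - shared / denom
    }
  }
  merges <- if (n == 2) {
    matrix(c(-1L, -2L), 1, 2)
  } else {
    hclust(as.dist(D), method = "average")$merge
  }

  B <- blosum62()
  alpha <- rownames(B)
  profile_freq <- function(gapped) {
    mat <- do.call(rbind, strsplit(gapped, "", fixed = TRUE))
    L <- ncol(mat)
    P <- matrix(0, length(alpha), L, dimnames = list(alpha, NULL))
    for (a in alpha) P[a, ] <- colMeans(mat == a)
    P
  }
  merge_profiles <- function(ga, gb) {
    PA <- profile_freq(ga); PB <- profile_freq(gb)
    S <- t(PA) %*% B %*% PB
    path <- cpp_global_path(S, gap_open, gap_extend)
    ia <- 0L; ib <- 0L
    ca <- lapply(ga, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    cb <- lapply(gb, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    outa <- vector("list", length(ca)); outb <- vector("list", length(cb))
    for (k in seq_along(ca)) outa[[k]] <- character(length(path))
    for (k in seq_along(cb)) outb[[k]] <- character(length(path))
    for (p in seq_along(path)) {
      mv <- path[p]
      if (mv == 1L || mv == 2L) ia <- ia + 1L
      if (mv == 1L || mv == 3L) ib <- ib + 1L
      for (k in seq_along(ca)) outa[[k]][p] <- if (mv == 3L) "-" else ca[[k]][ia]
      for (k in seq_along(cb)) outb[[k]][p] <- if (mv == 2L) "-" else cb[[k]][ib]
    }
    c(vapply(outa, paste, "", collapse = ""), vapply(outb, paste, "", collapse = ""))
  }

  profiles <- list() # per merge step: list(idx = leaf indices, gapped = rows)
  leaf <- function(i) list(idx = i, gapped = seqs[i])
  for (s in seq_len(nrow(merges))) {
    a <- merges[s, 1]; b <- merges[s, 2]
    pa <- if (a < 0) leaf(-a) else profiles[[a]]
    pb <- if (b < 0) leaf(-b) else profiles[[b]]
    gapped <- merge_profiles(pa$gapped, pb$gapped)
    profiles[[s]] <- list(idx = c(pa$idx, pb$idx), gapped = gapped)
  }
  final <- profiles[[nrow(merges)]]
  ord <- order(final$idx)
  tibble(id = records$id[final$idx][ord], aligned = final$gapped[ord])
}

#' Read a precomputed aligned FASTA
#'
#' Accepts gapped amino-acid sequences (gap character `-`) of equal length,
#' bypassing [build_msa()].
#'
#' @param path path to an aligned FASTA file.
#' @return an alignment tibble with columns `id` and `aligned`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("empty alignment file", call. = FALSE)
  aligned <- toupper(as.character(set))
  if (length(unique(nchar(aligned))) != 1) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  id <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(id)) stop("duplicate id in alignment", call. = FALSE)
  tibble(id = unname(id), aligned = unname(aligned))
}

alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$aligned, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Pairwise p-distances from a multiple alignment
#'
#' The p-distance between two rows is the proportion of differing residues
#' among compared positions. With `complete_deletion` every column
#' containing a gap or missing residue (`-` or `X`) in any row is dropped
#' before comparison; with `pairwise_deletion` positions are dropped per
#' pair of rows.
#'
#' @param aln an alignment tibble (`id`, `aligned`).
#' @param gap_mode column-deletion mode.
#' @return a symmetric numeric matrix with ids as dimnames, entries in
#'   `[0, 1]`, zero diagonal.
#' @export
p_distance <- function(aln, gap_mode = c("complete_deletion", "pairwise_deletion")) {
  gap_mode <- match.arg(gap_mode)
  if (nrow(aln) < 2) stop("need at least 2 aligned rows", call. = FALSE)
  M <- alignment_matrix(aln)
  usable <- M != "-" & M != "X"
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  if (gap_mode == "complete_deletion") {
    keep <- colSums(usable) == n
    if (!any(keep)) stop("no usable columns after complete deletion", call. = FALSE)
    M2 <- M[, keep, drop = FALSE]
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- mean(M2[i, ] != M2[j, ])
      }
    }
  } else {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- usable[i, ] & usable[j, ]
        if (!any(ok)) stop("no usable columns for pair ", aln$id[i], "/",
                           aln$id[j], call. = FALSE)
        D[i, j] <- D[j, i] <- mean(M[i, ok] != M[j, ok])
      }
    }
  }
  D
}
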