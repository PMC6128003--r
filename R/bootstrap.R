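# Bootstrap supports and bipartition utilities.

# Tips descending from each node, as a list indexed by node number.
tips_under <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(n)) out[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1]; ch <- ord[e, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# Canonical keys for the non-trivial bipartitions (internal edges) of an
# unrooted tree. Each side is normalized to exclude the lexicographically
# smallest tip label (so keys are invariant to tip numbering) and encoded
# as the sorted tip labels it contains.
bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- match(min(tree$tip.label), tree$tip.label)
  tu <- tips_under(tree)
  keys <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next # pendant edge: trivial split
    side <- tu[[ch]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (anchor %in% side) side <- setdiff(seq_len(n), side)
    keys <- c(keys, paste(sort(tree$tip.label[side]), collapse = "|"))
    nodes <- c(nodes, ch)
  }
  tibble(node = nodes, key = keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times (seeded
#' RNG); each replicate is run through [p_distance()] and
#' [neighbor_joining()], and the support of every internal edge of the
#' full-data tree is the percentage of replicate trees containing the same
#' bipartition, rounded to an integer. Under `complete_deletion` the
#' resampling pool is the set of columns retained after deletion.
#'
#' @param aln an alignment tibble (`id`, `aligned`).
#' @param n_reps number of bootstrap replicates (published convention:
#'   1000).
#' @param seed integer RNG seed.
#' @param gap_mode passed to [p_distance()].
#' @return the full-data NJ tree with integer supports in `node.label`
#'   (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1,
                              gap_mode = c("complete_deletion", "pairwise_deletion")) {
  gap_mode <- match.arg(gap_mode)
  full <- neighbor_joining(p_distance(aln, gap_mode))
  n <- nrow(aln)
  M <- alignment_matrix(aln)
  usable <- M != "-" & M != "X"

  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  if (gap_mode == "complete_deletion") {
    keep <- which(colSums(usable) == n)
    if (length(keep) == 0) stop("no usable columns after complete deletion", call. = FALSE)
    Mk <- M[, keep, drop = FALSE]
    L <- length(keep)
    MM <- matrix(0, np, L) # mismatch indicator per pair x column
    for (p in seq_len(np)) {
      MM[p, ] <- Mk[pairs[1, p], ] != Mk[pairs[2, p], ]
    }
    UU <- NULL
  } else {
    L <- ncol(M)
    MM <- matrix(0, np, L); UU <- matrix(0, np, L)
    for (p in seq_len(np)) {
      ok <- usable[pairs[1, p], ] & usable[pairs[2, p], ]
      UU[p, ] <- ok
      MM[p, ] <- ok & (M[pairs[1, p], ] != M[pairs[2, p], ])
    }
  }

  W <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    }, numeric(L))
  })
  num <- MM %*% W
  den <- if (is.null(UU)) matrix(L, np, n_reps) else UU %*% W

  full_keys <- bipartition_keys(full)
  counts <- setNames(numeric(nrow(full_keys)), full_keys$key)
  ids <- aln$id
  for (r in seq_len(n_reps)) {
    d <- num[, r] / pmax(den[, r], 1)
    Dm <- matrix(0, n, n, dimnames = list(ids, ids))
    Dm[t(pairs)] <- d
    Dm[t(pairs[2:1, , drop = FALSE])] <- d
    rep_keys <- bipartition_keys(neighbor_joining(Dm))$key
    hit <- full_keys$key %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  support <- as.integer(round(100 * counts / n_reps))

  nlab <- rep("", full$Nnode)
  ntip <- length(full$tip.label)
  nlab[full_keys$node - ntip] <- as.character(support)
  full$node.label <- nlab
  full
}
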