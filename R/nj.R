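# Classic neighbor-joining from a distance matrix.

# Build an ape::phylo object from an edge list over arbitrary node ids.
# `tips` maps tip ids 1..n to labels; internal ids are renumbered so the
# root becomes n+1 (ape convention).
build_phylo <- function(edges, root, tip_labels) {
  n <- length(tip_labels)
  internal <- unique(c(root, edges$parent[edges$parent > n]))
  internal <- c(root, setdiff(internal, root))
  # preorder renumbering from the root
  kids <- split(seq_len(nrow(edges)), edges$parent)
  newid <- integer(0)
  newid[as.character(root)] <- n + 1L
  nxt <- n + 2L
  stack <- root
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    for (e in kids[[as.character(v)]]) {
      ch <- edges$child[e]
      if (ch > n) {
        newid[as.character(ch)] <- nxt
        nxt <- nxt + 1L
        stack <- c(stack, ch)
      }
    }
  }
  remap <- function(v) ifelse(v > n, newid[as.character(v)], v)
  em <- cbind(vapply(edges$parent, remap, numeric(1)),
              vapply(edges$child, remap, numeric(1)))
  tr <- list(edge = em, edge.length = edges$length,
             tip.label = tip_labels, Nnode = length(internal))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: at each step the pair minimizing
#' Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k) is joined and
#' branch lengths follow the standard two-point formula
#' L_i = d(i, j) / 2 + (r_i - r_j) / (2 (n - 2)). Ties in Q are broken by
#' the lexicographically smallest node-index pair, so runs are
#' deterministic. A negative branch length is clamped to zero with the
#' deficit moved to its sister edge (total length preserved). The result is
#' the conventional unrooted NJ tree, represented with a trifurcating root
#' at the last join.
#'
#' @param D a symmetric distance matrix with row/column names (n >= 3).
#' @return an `ape::phylo` tree whose tips carry the matrix ids.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12) stop("non-symmetric distance matrix", call. = FALSE)
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs n >= 3", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # distances keyed by node id; leaves are 1..n, joins create n+1, n+2, ...
  ids <- seq_len(n)
  dm <- D
  dimnames(dm) <- list(ids, ids)
  active <- ids
  next_id <- n + 1L
  edges <- list(parent = numeric(0), child = numeric(0), length = numeric(0))
  add_edge <- function(p, ch, len) {
    edges$parent <<- c(edges$parent, p)
    edges$child <<- c(edges$child, ch)
    edges$length <<- c(edges$length, len)
  }

  while (length(active) > 3) {
    m <- length(active)
    sub <- dm[as.character(active), as.character(active)]
    r <- rowSums(sub)
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * sub[i, j] - r[i] - r[j]
        if (q < best - 1e-12) { best <- q; bi <- i; bj <- j }
      }
    }
    i <- active[bi]; j <- active[bj]
    dij <- sub[bi, bj]
    li <- dij / 2 + (r[bi] - r[bj]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    u <- next_id; next_id <- next_id + 1L
    add_edge(u, i, li); add_edge(u, j, lj)
    # distances from the new node
    rest <- setdiff(active, c(i, j))
    duk <- (dm[as.character(i), as.character(rest)] +
            dm[as.character(j), as.character(rest)] - dij) / 2
    dm <- rbind(cbind(dm, 0), 0)
    rownames(dm)[nrow(dm)] <- colnames(dm)[ncol(dm)] <- as.character(u)
    dm[as.character(u), as.character(rest)] <- duk
    dm[as.character(rest), as.character(u)] <- duk
    active <- c(rest, u)
  }

  a <- active[1]; b <- active[2]; c3 <- active[3]
  dab <- dm[as.character(a), as.character(b)]
  dac <- dm[as.character(a), as.character(c3)]
  dbc <- dm[as.character(b), as.character(c3)]
  la <- max((dab + dac - dbc) / 2, 0)
  lb <- max((dab + dbc - dac) / 2, 0)
  lc <- max((dac + dbc - dab) / 2, 0)
  v <- next_id
  add_edge(v, a, la); add_edge(v, b, lb); add_edge(v, c3, lc)

  build_phylo(as.data.frame(edges), root = v, tip_labels = labels)
}
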