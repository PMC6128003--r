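# Independent oracles and fixture builders used across the suite.

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

random_peptide <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force tandem-duplication oracle: test all family-gene pairs against
# the linking rule, then take connected components with union-find.
tde_oracle <- function(placements, max_interrupt = 1, window = 1e6) {
  events <- list()
  for (sid in unique(placements$seq_id)) {
    ch <- placements[placements$seq_id == sid, ]
    fam <- ch[ch$is_family, ]
    fam <- fam[order(fam$rank), ]
    nf <- nrow(fam)
    if (nf < 2) next
    parent <- seq_len(nf)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        gap <- abs(fam$rank[j] - fam$rank[i]) - 1L
        lo <- which.min(c(fam$start[i], fam$start[j]))
        hi <- 3 - lo
        bp <- fam$start[c(i, j)][hi] - fam$end[c(i, j)][lo]
        linked <- gap <= max_interrupt ||
          (gap == max_interrupt + 1L && bp <= window)
        if (linked) parent[find(j)] <- find(i)
      }
    }
    roots <- vapply(seq_len(nf), find, 1L)
    for (r in unique(roots)) {
      ids <- fam$gene_id[roots == r]
      if (length(ids) >= 2) events[[length(events) + 1L]] <-
          paste(sort(ids), collapse = "+")
    }
  }
  out <- unlist(events)
  if (is.null(out)) character(0) else sort(out)
}

canon_events <- function(tde) {
  sort(vapply(tde$gene_ids, function(g) paste(sort(g), collapse = "+"), ""))
}

# Random toy genome of placements: one chromosome, random family flags and
# coordinates (already in rank order).
random_toy_genome <- function(n_genes = 25, p_family = 0.35) {
  start <- cumsum(sample(c(2000:30000, 5e5, 1.5e6), n_genes, replace = TRUE))
  len <- sample(1000:5000, n_genes, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    seq_id = "chr1",
    rank = seq_len(n_genes) - 1L,
    start = as.integer(start),
    end = as.integer(start + len),
    is_family = runif(n_genes) < p_family,
    subgenome = "A"
  )
}

# Additive distance matrix from a random tree; returns both.
random_additive_matrix <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.05, 0.6)))
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# Dense grid-search oracle for the isoelectric point (step 1e-4 pH).
pi_grid_oracle <- function(sequence) {
  pka <- rlkfam::pka_bjellqvist()
  ch <- strsplit(sequence, "")[[1]]
  counts <- vapply(c("K","R","H","D","E","C","Y"),
                   function(a) sum(ch == a), integer(1))
  charge <- function(pH) {
    nt <- unname(pka$nterm[ch[1]])
    if (length(nt) != 1 || is.na(nt)) nt <- pka$nterm_default
    pos <- c(nt, rep(pka$side[["K"]], counts[["K"]]),
             rep(pka$side[["R"]], counts[["R"]]),
             rep(pka$side[["H"]], counts[["H"]]))
    neg <- c(pka$cterm, rep(pka$side[["D"]], counts[["D"]]),
             rep(pka$side[["E"]], counts[["E"]]),
             rep(pka$side[["C"]], counts[["C"]]),
             rep(pka$side[["Y"]], counts[["Y"]]))
    sum(1 / (1 + 10^(pH - pos))) - sum(1 / (1 + 10^(neg - pH)))
  }
  grid <- seq(0, 14, by = 1e-4)
  grid[which.min(abs(vapply(grid, charge, 0)))]
}

# Pairwise global-alignment score oracle (Gotoh, gap of length g costs
# open + g * extend), plain R implementation.
nw_score_oracle <- function(a, b, open = 10, extend = 0.5) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb); NEG <- -1e30
  H <- matrix(NEG, m + 1, n + 1); E <- H; F <- H
  H[1, 1] <- 0
  for (j in 2:(n + 1)) { E[1, j] <- -(open + (j - 1) * extend); H[1, j] <- E[1, j] }
  for (i in 2:(m + 1)) { F[i, 1] <- -(open + (i - 1) * extend); H[i, 1] <- F[i, 1] }
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(H[i - 1, j - 1] + B[ca[i - 1], cb[j - 1]], E[i, j], F[i, j])
    }
  }
  H[m + 1, n + 1]
}

# Score of a computed pairwise alignment (two gapped rows) under BLOSUM62
# and the same affine convention.
alignment_score <- function(ga, gb, open = 10, extend = 0.5) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  sc <- 0; in_gap <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] == "-" || cb[k] == "-") {
      gap_id <- if (ca[k] == "-") 1L else 2L
      sc <- sc - extend - if (in_gap == gap_id) 0 else open
      in_gap <- gap_id
    } else {
      sc <- sc + B[ca[k], cb[k]]
      in_gap <- 0L
    }
  }
  sc
}

# Regex-based oracle for the 24-residue LRR consensus (independent of the
# package's sliding-window implementation).
lrr_scan_oracle <- function(sequence) {
  pat <- "(?=[LI]..[LI]..[LI]..[LI].[LI]..N.[LI]..G.[VI]P.)"
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Brute-force average-linkage agglomeration oracle over 1 - Pearson.
avg_link_oracle_merge_heights <- function(m) {
  d <- 1 - cor(t(m)); diag(d) <- 0
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}
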