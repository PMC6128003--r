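mk_models <- function(df) {
  df$exons <- lapply(seq_len(nrow(df)), function(k) {
    tibble::tibble(start = df$start[k], end = df$end[k])
  })
  df$protein_id <- NA_character_
  df$strand <- "+"
  df
}

test_that("gene placement ranks per chromosome and classes subgenomes", {
  gm <- mk_models(tibble::tibble(
    gene_id = c("f1", "f2", "f3", "n1", "s1"),
    seq_id = c("A09", "A09", "A09", "A09", "scaffold1841.1"),
    start = c(100L, 5000L, 900L, 200L, 50L),
    end = c(400L, 5400L, 1400L, 350L, 500L)))
  pl <- place_genes(gm, member_ids = c("f1", "f2", "f3", "s1"))
  expect_equal(sort(pl$rank[pl$seq_id == "A09"]), 0:3)
  expect_equal(pl$rank[pl$gene_id == "f1"], 0L)
  expect_equal(pl$rank[pl$gene_id == "f2"], 3L)
  dist <- distribution_table(pl)
  expect_equal(dist$by_subgenome$n_family[dist$by_subgenome$subgenome == "A"], 3L)
  expect_equal(dist$by_subgenome$n_family[dist$by_subgenome$subgenome == "scaffold"], 1L)

  empty <- distribution_table(place_genes(gm, member_ids = character(0)))
  expect_true(all(empty$by_subgenome$n_family == 0))

  # equal starts: deterministic rank by end
  gm2 <- mk_models(tibble::tibble(
    gene_id = c("a", "b"), seq_id = "A01",
    start = c(100L, 100L), end = c(900L, 500L)))
  pl2 <- place_genes(gm2, "a")
  expect_equal(pl2$rank[pl2$gene_id == "b"], 0L)
  expect_equal(pl2$rank[pl2$gene_id == "a"], 1L)
})

place_from_layout <- function(layout, gaps_bp = NULL) {
  n <- length(layout)
  gap <- if (is.null(gaps_bp)) rep(20000, n) else gaps_bp
  start <- integer(n); pos <- 0L
  for (k in seq_len(n)) {
    start[k] <- pos + gap[k]
    pos <- start[k] + 2000L
  }
  tibble::tibble(gene_id = sprintf("%s%02d", layout, seq_len(n)),
                 seq_id = "chr", rank = seq_len(n) - 1L,
                 start = start, end = start + 2000L,
                 is_family = layout == "F", subgenome = "A")
}

test_that("tandem-duplication rule handles the canonical layouts", {
  # one interruption always links
  t1 <- call_tandem_duplications(place_from_layout(c("F", "x", "F")))
  expect_equal(nrow(t1), 1)
  expect_equal(sort(t1$gene_ids[[1]]), c("F01", "F03"))

  # two interruptions link only within 1 Mb
  far <- place_from_layout(c("F", "x", "x", "F"),
                           gaps_bp = c(20000, 7e5, 7e5, 7e5))
  expect_equal(nrow(call_tandem_duplications(far)), 0)
  near <- place_from_layout(c("F", "x", "x", "F"))
  t2 <- call_tandem_duplications(near)
  expect_equal(nrow(t2), 1)

  # chain merges transitively; distant gene excluded
  t3 <- call_tandem_duplications(
    place_from_layout(c("F", "F", "x", "F", "x", "x", "x", "F")))
  expect_equal(nrow(t3), 1)
  expect_equal(sort(t3$gene_ids[[1]]), c("F01", "F02", "F04"))
})

test_that("TDE caller equals the brute-force all-pairs oracle on random genomes", {
  withr::local_seed(2024)
  for (rep in 1:200) {
    pl <- random_toy_genome(n_genes = sample(8:30, 1))
    got <- canon_events(call_tandem_duplications(pl))
    expect_equal(got, tde_oracle(pl))
  }
})

test_that("TDE events partition genes and survive order reversal", {
  withr::local_seed(77)
  for (rep in 1:20) {
    pl <- random_toy_genome(n_genes = 20)
    tde <- call_tandem_duplications(pl)
    genes <- unlist(tde$gene_ids)
    expect_equal(anyDuplicated(genes), 0)
    expect_equal(sum(tde$n_genes), length(genes))

    # reverse the chromosome: mirror coordinates and ranks
    L <- max(pl$end) + 1000L
    rev_pl <- pl
    rev_pl$rank <- max(pl$rank) - pl$rank
    s <- L - pl$end; e <- L - pl$start
    rev_pl$start <- s; rev_pl$end <- e
    rev_pl <- rev_pl[order(rev_pl$rank), ]
    expect_equal(canon_events(call_tandem_duplications(rev_pl)),
                 canon_events(tde))
  }
})

test_that("exon-intron arithmetic is 1-based inclusive", {
  gm <- tibble::tibble(
    gene_id = "g1", seq_id = "A01", start = 100L, end = 1000L, strand = "+",
    protein_id = NA_character_,
    exons = list(tibble::tibble(start = c(100L, 500L), end = c(300L, 1000L))))
  st <- exon_structure(gm)
  expect_equal(st$exon_lengths[[1]], c(201L, 501L))
  expect_equal(st$intron_lengths[[1]], 199L)
  expect_equal(st$cds_span, 901L)

  single <- gm
  single$exons <- list(tibble::tibble(start = 100L, end = 1000L))
  expect_equal(exon_structure(single)$intron_lengths[[1]], integer(0))

  two <- dplyr::bind_rows(gm, gm)
  two$gene_id <- c("g1", "g2")
  two$exons[[2]] <- tibble::tibble(start = c(100L, 260L, 420L, 700L),
                                   end = c(200L, 400L, 600L, 1000L))
  agg <- summarize_exon_structure(exon_structure(two),
                                  tibble::tibble(gene_id = c("g1", "g2"),
                                                 group = "I"))
  expect_equal(agg$mean_exons, 3)
})
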