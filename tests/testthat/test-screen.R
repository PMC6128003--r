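test_that("self-hit of a 300-aa protein scores far below the screening threshold", {
  withr::local_seed(1)
  s <- random_peptide(300)
  hits <- similarity_search(tibble::tibble(id = "q", sequence = s),
                            tibble::tibble(id = "t", sequence = s))
  expect_equal(nrow(hits), 1)
  expect_lt(hits$evalue, 1e-50)
  expect_equal(c(hits$q_start, hits$q_end), c(1L, 300L))
  expect_equal(c(hits$s_start, hits$s_end), c(1L, 300L))
})

test_that("seeded search equals the exhaustive Smith-Waterman oracle on gated pairs", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  withr::local_seed(1)
  for (rep in 1:5) {
    q <- random_peptide(120)
    s <- if (rep <= 3) {
      # related subject: mutated copy embedded in noise
      paste0(random_peptide(40),
             paste(rev(strsplit(q, "")[[1]]), collapse = ""), random_peptide(40))
    } else {
      random_peptide(300)
    }
    hits <- similarity_search(tibble::tibble(id = "q", sequence = q),
                              tibble::tibble(id = "s", sequence = s))
    oracle <- Biostrings::score(Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = e$BLOSUM62,
      gapOpening = 11, gapExtension = 1))
    mine <- if (nrow(hits)) hits$raw_score else 0
    expect_lte(mine, oracle + 1e-9)
    if (nrow(hits)) expect_equal(mine, oracle)
  }
})

test_that("candidate screening thresholds, deduplicates, and is monotone in E_max", {
  hits <- tibble::tibble(
    query_id = c("q1", "q2", "q1", "q3"),
    subject_id = c("p1", "p2", "p1", "p1"),
    evalue = c(1e-12, 1e-9, 1e-30, 1e-15))
  expect_equal(screen_candidates(hits), "p1")
  expect_equal(screen_candidates(hits[0, ]), character(0))

  withr::local_seed(42)
  ev <- 10^runif(50, -40, 2)
  h <- tibble::tibble(query_id = "q", subject_id = sprintf("p%02d", 1:50),
                      evalue = ev)
  thresholds <- sort(10^runif(8, -30, 0))
  sets <- lapply(thresholds, function(e) screen_candidates(h, e_max = e))
  for (k in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  }
})

test_that("membership rule requires one LRR, one kinase and one TM", {
  dh <- tibble::tibble(
    protein_id = c("a", "a", "a", "b", "b", "b", "b", "c"),
    category = c("LRR", "LRR", "kinase", "LRR", "LRR", "LRR", "kinase", "kinase"))
  tm <- tibble::tibble(protein_id = c("a", "c"), start = c(600, 500),
                       end = c(622, 522))
  dec <- classify_membership(c("a", "b", "c"), dh, tm)
  expect_equal(dec$is_member, c(TRUE, FALSE, FALSE))
  expect_equal(dec$reasons[[1]], NULL)
  expect_equal(dec$reasons[[2]], "TM")
  expect_equal(dec$reasons[[3]], "LRR")
  expect_equal(dec$n_lrr, c(2L, 3L, 0L))
  # decision invariant: is_member <=> all three criteria
  expect_equal(dec$is_member,
               dec$n_lrr >= 1 & dec$has_kinase & dec$n_tm >= 1)
})

test_that("search errors on empty input sets", {
  p <- tibble::tibble(id = "x", sequence = "MKLVANNNA")
  expect_error(similarity_search(p[0, ], p), "empty query")
  expect_error(similarity_search(p, p[0, ]), "empty subject")
})
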