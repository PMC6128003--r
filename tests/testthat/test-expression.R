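test_that("RPKM follows the closed form and is scale invariant", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10L, 0L))
  lens <- tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(1000L, 500L))
  r <- rpkm(counts, lens, library_sizes = c(s1 = 1e6))
  expect_equal(r$s1, c(10, 0))

  withr::local_seed(5)
  counts2 <- tibble::tibble(gene_id = paste0("g", 1:6),
                            a = rpois(6, 40), b = rpois(6, 60))
  lens2 <- tibble::tibble(gene_id = counts2$gene_id,
                          length_bp = sample(500:3000, 6))
  r1 <- rpkm(counts2, lens2)
  doubled <- counts2
  doubled$a <- doubled$a * 2L; doubled$b <- doubled$b * 2L
  r2 <- rpkm(doubled, lens2)
  expect_equal(r1, r2)
})

test_that("self-normalization gives zero-mean unit-sd rows and keeps order", {
  m <- tibble::tibble(gene_id = "g1", s1 = 1, s2 = 2, s3 = 3)
  z <- normalize_expression(m)
  v <- as.numeric(z[1, -1])
  logd <- log2(c(1, 2, 3) + 1)
  expect_equal(v, (logd - mean(logd)) / sd(logd))
  expect_equal(mean(v), 0, tolerance = 1e-9)
  expect_equal(sd(v), 1, tolerance = 1e-9)
  expect_equal(order(v), order(c(1, 2, 3)))

  const <- normalize_expression(tibble::tibble(gene_id = "g", a = 5, b = 5, c = 5))
  expect_equal(as.numeric(const[1, -1]), c(0, 0, 0))
})

test_that("hierarchical clustering matches brute-force average linkage", {
  m <- tibble::tibble(gene_id = c("g1", "g2"),
                      a = c(1, 1), b = c(2, 2), c = c(5, 5))
  cl <- cluster_expression(m)
  expect_equal(cl$hclust$height, 0)

  withr::local_seed(14)
  m3 <- matrix(rnorm(15), 3, 5)
  tb <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:3)),
                         tibble::as_tibble(as.data.frame(m3)))
  cl3 <- cluster_expression(tb)
  expect_equal(cl3$hclust$height, avg_link_oracle_merge_heights(m3),
               tolerance = 1e-12)
  expect_setequal(cl3$order, tb$gene_id)
  expect_setequal(cl3$matrix$gene_id, tb$gene_id)
})

test_that("ddCt reproduces the worked example and degenerate cases", {
  rec <- tibble::tibble(
    sample = c("t1", "t1", "c1", "c1"),
    gene = c("tg", "ref", "tg", "ref"),
    ct = c(20, 15, 22, 15),
    replicate = 1L,
    group = c("treatment", "treatment", "control", "control"))
  out <- ddct(rec, reference_gene = "ref", calibrator_group = "control")
  tr <- out[out$group == "treatment", ]
  expect_equal(tr$ddct, -2)
  expect_equal(tr$fold, 4)
  expect_equal(out$fold[out$group == "control"], 1)

  same <- rec
  same$ct[same$gene == "tg"] <- same$ct[same$gene == "ref"]
  expect_true(all(ddct(same, "ref", "control")$fold == 1))

  noref <- rec[rec$gene != "ref" | rec$sample != "t1", ]
  expect_error(ddct(noref, "ref", "control"), "missing reference")
})

test_that("calibrator-group fold changes centre on 1", {
  withr::local_seed(3)
  rows <- list()
  for (i in 1:6) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample = paste0("c", i), gene = "ref", ct = rnorm(1, 15, 0.1),
      replicate = i, group = "control")
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample = paste0("c", i), gene = "tg",
      ct = 20 + rnorm(1, 0, 0.1), replicate = i, group = "control")
  }
  out <- ddct(dplyr::bind_rows(rows), "ref", "control")
  expect_equal(exp(mean(log(out$fold))), 1, tolerance = 0.05)
})

test_that("t-test annotation matches the analytic t distribution", {
  same <- c(1, 2, 3)
  res <- ttest_annotate(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$stars, "")

  a <- c(5.1, 4.8, 5.6, 5.0, 5.3)
  b <- c(6.0, 6.4, 5.9, 6.2, 6.6)
  res2 <- ttest_annotate(a, b)
  # closed-form Student t with pooled variance
  sp <- sqrt(((4) * var(a) + (4) * var(b)) / 8)
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(2 / 5))
  pval <- 2 * pt(-abs(tstat), df = 8)
  expect_equal(res2$t, tstat, tolerance = 1e-9)
  expect_equal(res2$p, pval, tolerance = 1e-6)

  expect_equal(significance_stars(c(0.03, 0.005, 0.2)), c("*", "**", ""))
})
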