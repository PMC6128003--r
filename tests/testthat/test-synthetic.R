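test_that("generation is byte-identical for the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(sim_config(), seed = 13, dir = d1)
  generate_dataset(sim_config(), seed = 13, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  d3 <- withr::local_tempdir()
  generate_dataset(sim_config(), seed = 14, dir = d3)
  expect_false(identical(readLines(file.path(d1, "proteome.faa")),
                         readLines(file.path(d3, "proteome.faa"))))
})

test_that("truth reflects the configured members, decoys and planted events", {
  cfg <- sim_config()
  ds <- generate_dataset(cfg, seed = 2)
  expect_equal(nrow(ds$truth$members),
               cfg$n_members * length(cfg$subclades))
  expect_equal(nrow(ds$truth$decoys), cfg$n_decoys)
  expect_setequal(unique(ds$truth$decoys$violated), c("LRR", "kinase", "TM"))
  # layouts plant exactly three linked events (adjacent, one-interruption,
  # two-interruption-within-window); the >1 Mb and three-interruption
  # layouts must not be declared
  expect_equal(nrow(ds$truth$tde_events), 3)
  expect_true(all(lengths(ds$truth$tde_events$gene_ids) == 2))
})

test_that("every generated file re-parses through the io layer", {
  d <- withr::local_tempdir()
  ds <- generate_dataset(sim_config(), seed = 3, dir = d)
  expect_equal(nrow(read_fasta(ds$paths[["proteome"]])), nrow(ds$proteome))
  expect_equal(nrow(read_fasta(ds$paths[["references"]])), nrow(ds$references))
  gm <- read_gff3(ds$paths[["gff"]])
  expect_equal(nrow(gm), nrow(ds$gene_models))
  dh <- read_domain_table(ds$paths[["domains"]], dialect = "tsv")
  expect_equal(nrow(dh), nrow(ds$domain_hits))
  expect_setequal(unique(dh$category), c("LRR", "kinase", "malectin"))
  expect_equal(nrow(read_tm_table(ds$paths[["tm"]])), nrow(ds$tm_calls))
  expect_equal(nrow(read_sp_table(ds$paths[["sp"]])), nrow(ds$sp_calls))
  expect_equal(read_counts(ds$paths[["counts"]]), ds$counts)
  q <- utils::read.csv(ds$paths[["qpcr"]])
  expect_true(all(c("sample", "gene", "ct", "replicate", "group") %in% names(q)))
})

test_that("zero-noise recovery is exact at every stage", {
  ds <- generate_dataset(sim_config(), seed = 17)
  rec <- end_to_end_recovery(ds)
  expect_equal(rec$membership_precision, 1)
  expect_equal(rec$membership_recall, 1)
  expect_equal(rec$subclade_accuracy, 1)
  expect_true(rec$tde_exact_match)
})

test_that("missing TM evidence lowers recall but never precision", {
  ds <- generate_dataset(sim_config(tm_miss_rate = 0.2), seed = 23)
  rec <- end_to_end_recovery(ds, use_similarity = FALSE)
  expect_lt(rec$membership_recall, 1)
  expect_equal(rec$membership_precision, 1)
})

test_that("planted fiber-high genes co-cluster in the expression dendrogram", {
  hits <- 0; n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    ds <- generate_dataset(sim_config(), seed = 100 + s)
    norm <- normalize_expression(rpkm(ds$counts, ds$gene_lengths))
    cl <- cluster_expression(norm)
    k2 <- cutree(cl$hclust, k = 2)
    truth <- ds$truth$expression_pattern
    high <- truth$gene_id[truth$pattern == "fiber_high"]
    grp <- k2[high]
    frac <- max(table(grp)) / length(high)
    if (frac >= 0.9) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})
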