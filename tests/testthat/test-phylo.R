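test_that("progressive alignment handles identical and near-identical pairs", {
  rec <- tibble::tibble(id = c("a", "b"),
                        sequence = c("MKLVANNNA", "MKLVANNNA"))
  aln <- build_msa(rec)
  expect_false(any(grepl("-", aln$aligned)))
  expect_equal(aln$aligned[1], aln$aligned[2])

  rec2 <- tibble::tibble(id = c("a", "b"), sequence = c("ACDEFG", "ACEFG"))
  aln2 <- build_msa(rec2)
  expect_equal(unique(nchar(aln2$aligned)), 6)
  expect_equal(sum(strsplit(aln2$aligned[2], "")[[1]] == "-"), 1)
  # the two-profile merge must reach the exact pairwise DP optimum
  got <- alignment_score(aln2$aligned[1], aln2$aligned[2])
  expect_equal(got, nw_score_oracle("ACDEFG", "ACEFG"))
})

test_that("alignment width is at least the longest input", {
  withr::local_seed(11)
  for (rep in 1:5) {
    rec <- tibble::tibble(id = paste0("s", 1:4),
                          sequence = vapply(sample(20:60, 4), random_peptide, ""))
    aln <- build_msa(rec)
    expect_equal(length(unique(nchar(aln$aligned))), 1)
    expect_gte(unique(nchar(aln$aligned)), max(nchar(rec$sequence)))
    # de-gapping restores the inputs
    expect_equal(gsub("-", "", aln$aligned[match(rec$id, aln$id)]),
                 rec$sequence)
  }
})

test_that("p-distance matches hand enumeration under both deletion modes", {
  aln <- tibble::tibble(id = c("r1", "r2"), aligned = c("ACDE", "ACDF"))
  D <- p_distance(aln)
  expect_equal(D["r1", "r2"], 0.25)
  expect_equal(diag(D), c(r1 = 0, r2 = 0))

  aln2 <- tibble::tibble(id = c("a", "b", "c"),
                         aligned = c("A-CDE", "AXCDE", "AYCDF"))
  # complete deletion: columns 2 (gap/X) dropped -> 4 usable columns
  Dc <- p_distance(aln2, "complete_deletion")
  expect_equal(Dc["a", "b"], 0)
  expect_equal(Dc["a", "c"], 1 / 4)
  expect_equal(Dc["b", "c"], 1 / 4)
  # pairwise deletion: per-pair usable columns
  Dp <- p_distance(aln2, "pairwise_deletion")
  expect_equal(Dp["a", "b"], 0)      # cols 1,3,4,5
  expect_equal(Dp["a", "c"], 1 / 4)  # cols 1,3,4,5 ; E vs F differs
  expect_equal(Dp["b", "c"], 1 / 4)  # X excluded for b

  gapped <- tibble::tibble(id = c("a", "b"), aligned = c("A-", "-A"))
  expect_error(p_distance(gapped, "complete_deletion"), "no usable columns")
})

test_that("NJ solves the three-taxon closed form and breaks ties deterministically", {
  D <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["B"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["C"]], (5 + 4 - 3) / 2)

  # fully tied matrix: two runs give identical trees
  Dt <- matrix(1, 5, 5) - diag(5)
  dimnames(Dt) <- list(letters[1:5], letters[1:5])
  expect_equal(write_newick(neighbor_joining(Dt)),
               write_newick(neighbor_joining(Dt)))
})

test_that("NJ reconstructs additive matrices exactly (topology and lengths)", {
  skip_if_not_installed("ape")
  withr::local_seed(7)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    am <- random_additive_matrix(n)
    tr <- neighbor_joining(am$D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), am$tree)), 0)
    pat <- ape::cophenetic.phylo(tr)[rownames(am$D), colnames(am$D)]
    expect_lt(max(abs(pat - am$D)), 1e-9)
  }
})

test_that("NJ also agrees with the independent ape implementation", {
  withr::local_seed(3)
  n <- 9
  M <- matrix(runif(n * n, 0.1, 1), n, n)
  D <- (M + t(M)) / 2; diag(D) <- 0
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  mine <- neighbor_joining(D)
  theirs <- ape::nj(as.dist(D))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs))), 0)
})

test_that("bootstrap gives 100% support to a split present in every column", {
  aln <- tibble::tibble(
    id = c("A", "B", "C", "D"),
    aligned = c(strrep("K", 30), strrep("K", 30),
                strrep("E", 30), strrep("E", 30)))
  tr <- bootstrap_support(aln, n_reps = 50, seed = 5)
  sup <- suppressWarnings(as.integer(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_equal(sup, 100)
})

test_that("bootstrap supports are valid percentages, seeded, and leaf-order invariant", {
  withr::local_seed(21)
  # unequal per-sequence mutation loads over a long core keep pairwise
  # distances tie-free, so the NJ topology is permutation-stable
  base <- random_peptide(200)
  rec <- tibble::tibble(
    id = paste0("s", 1:6),
    sequence = vapply(1:6, function(i) {
      ch <- strsplit(base, "")[[1]]
      mut <- sample(200, 15 + 11 * i)
      ch[mut] <- sample(AA, length(mut), replace = TRUE)
      paste(ch, collapse = "")
    }, ""))
  aln <- build_msa(rec)
  t1 <- bootstrap_support(aln, n_reps = 60, seed = 9)
  t2 <- bootstrap_support(aln, n_reps = 60, seed = 9)
  sup <- suppressWarnings(as.integer(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_identical(t1$node.label, t2$node.label)

  perm <- aln[sample(nrow(aln)), ]
  t3 <- bootstrap_support(perm, n_reps = 60, seed = 9)
  k1 <- rlkfam:::bipartition_keys(t1)
  k3 <- rlkfam:::bipartition_keys(t3)
  expect_setequal(k1$key, k3$key)
  s1 <- setNames(as.integer(t1$node.label[k1$node - 6]), k1$key)
  s3 <- setNames(as.integer(t3$node.label[k3$node - 6]), k3$key)
  # per-replicate Q ties may resolve differently under row permutation;
  # supports agree up to those few replicates
  expect_lte(max(abs(s1[sort(names(s1))] - s3[sort(names(s1))])), 10)
})

test_that("subclade assignment follows the smallest reference-anchored cluster", {
  # query sister to a single subclade-III reference
  tr <- ape::read.tree(text = "((q1:1,refIII:1):1,(refXI:1,refXII:1):1,out:3);")
  labs <- tibble::tibble(id = c("refIII", "refXI", "refXII", "out"),
                         subclade = c("III", "XI", "XII", "X"))
  a <- assign_subclades(tr, labs)
  expect_equal(a$subclade[a$query_id == "q1"], "III")
  expect_equal(a$support[a$query_id == "q1"], 1)

  # majority vote 2/3 inside a mixed cluster, verified against exhaustive
  # bipartition enumeration
  tr2 <- ape::read.tree(
    text = "((q2:1,((rA:1,rB:1):1,rC:2):1):1,(o1:1,o2:1):2,(o3:1,o4:1):2);")
  labs2 <- tibble::tibble(id = c("rA", "rB", "rC", "o1", "o2", "o3", "o4"),
                          subclade = c("XII", "XII", "XI", "V", "V", "V", "V"))
  a2 <- assign_subclades(tr2, labs2)
  q2 <- a2[a2$query_id == "q2", ]
  expect_equal(q2$subclade, "XII")
  expect_equal(q2$support, 2 / 3)

  # outlier attaching outside all reference clusters -> unassigned
  tr3 <- ape::read.tree(
    text = "(((r1:1,r2:1):1,(r3:1,r4:1):1):1,((r5:1,r6:1):1,(r7:1,r8:1):1):1,far:30);")
  labs3 <- tibble::tibble(id = paste0("r", 1:8),
                          subclade = rep(c("I", "III", "XI", "XII"), each = 2))
  a3 <- assign_subclades(tr3, labs3)
  expect_equal(a3$subclade[a3$query_id == "far"], "unassigned")
})
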