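test_that("molecular weight is residue-additive plus one water", {
  expect_equal(molecular_weight("G"), 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(round(molecular_weight("G"), 2), 75.07)
  expect_equal(molecular_weight("GG") - molecular_weight("G"), 57.0519,
               tolerance = 1e-6)
  withr::local_seed(4)
  a <- random_peptide(30); b <- random_peptide(45)
  expect_equal(molecular_weight(paste0(a, b)),
               molecular_weight(a) + molecular_weight(b) - 18.01524,
               tolerance = 1e-6)
  expect_error(molecular_weight(""), "empty")
})

test_that("pI of a bare dipeptide is the terminal-pKa midpoint", {
  # "AA": only the A-type N-terminus (7.59) and the C-terminus (3.55)
  expect_equal(isoelectric_point("AA"), (7.59 + 3.55) / 2, tolerance = 0.002)
})

test_that("pI bisection matches the dense grid-search oracle", {
  withr::local_seed(10)
  for (rep in 1:25) {
    p <- random_peptide(sample(10:80, 1))
    expect_equal(isoelectric_point(p), pi_grid_oracle(p), tolerance = 0.01)
  }
})

test_that("acidic residues never raise the pI", {
  withr::local_seed(12)
  for (rep in 1:10) {
    p <- random_peptide(sample(10:50, 1))
    expect_lte(isoelectric_point(paste0(p, "D")), isoelectric_point(p) + 1e-3)
  }
})

test_that("LRR consensus scan finds planted motifs and nothing else", {
  motif <- "LAALAALAALALAANALAAGAVPA"
  expect_equal(scan_lrr_consensus(motif), 1L)
  expect_equal(scan_lrr_consensus(strrep("A", 100)), integer(0))
  expect_equal(scan_lrr_consensus(paste0(motif, motif)), c(1L, 25L))
})

test_that("LRR consensus scan equals the regex oracle on random strings", {
  withr::local_seed(33)
  # enriched alphabet so matches actually occur
  rich <- c(AA, rep(c("L", "I", "N", "G", "P", "V"), 8))
  for (rep in 1:30) {
    s <- random_peptide(sample(30:200, 1), alphabet = rich)
    expect_equal(scan_lrr_consensus(s), lrr_scan_oracle(s))
  }
})

test_that("hydropathy TM scan flags hydrophobic stretches only", {
  p <- tibble::tibble(id = c("hydro", "polar"),
                      sequence = c(strrep("I", 19), strrep("R", 19)))
  tm <- hydropathy_tm_scan(p)
  expect_equal(tm$protein_id, "hydro")
  expect_equal(c(tm$start, tm$end), c(1L, 19L))

  # mixed sequence against an exhaustive window-mean oracle
  withr::local_seed(8)
  s <- paste0(random_peptide(30, c("D","E","K","R","S","T")),
              strrep("L", 25),
              random_peptide(30, c("D","E","K","R","S","T")))
  got <- hydropathy_tm_scan(tibble::tibble(id = "m", sequence = s))
  kd <- c(A=1.8,R=-4.5,N=-3.5,D=-3.5,C=2.5,Q=-3.5,E=-3.5,G=-0.4,H=-3.2,
          I=4.5,L=3.8,K=-3.9,M=1.9,F=2.8,P=-1.6,S=-0.8,T=-0.7,W=-0.9,
          Y=-1.3,V=4.2)
  ch <- strsplit(s, "")[[1]]
  above <- vapply(1:(length(ch) - 18), function(i) {
    mean(kd[ch[i:(i + 18)]]) > 1.6
  }, TRUE)
  runs <- which(above)
  expect_equal(got$start, min(runs))
  expect_equal(got$end, max(runs) + 18L)
})

test_that("architecture tokens are ordered by coordinate", {
  dh <- tibble::tibble(protein_id = "p",
                       domain_name = c("Malectin_like", "LRR_8", "Pkinase"),
                       category = c("malectin", "LRR", "kinase"),
                       env_start = c(30L, 340L, 700L),
                       env_end = c(330L, 365L, 950L),
                       score = 10, evalue = 1e-10)
  tm <- tibble::tibble(protein_id = "p", start = 620L, end = 642L)
  sp <- tibble::tibble(protein_id = "p", start = 1L, end = 22L, cleavage = 22L)
  arch <- architecture_string("p", dh, tm, sp)
  expect_equal(arch$architecture, "SP-Malectin-LRR-TM-KD")

  mp <- malectin_position(dh)
  expect_true(mp$malectin_nterm)
})

test_that("subclade property summary collapses to min=max for singletons", {
  props <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
                          length_aa = c(900L, 500L, 700L),
                          mol_weight_da = c(98000, 55000, 77000),
                          pI = c(5.1, 6.4, 8.0),
                          n_lrr_domains = c(3L, 1L, 2L),
                          n_lrr_consensus = c(3L, 1L, 2L),
                          architecture = "LRR-TM-KD")
  asg <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
                        subclade = c("I", "XII", "XII"))
  summ <- summarize_subclades(props, asg)
  s1 <- summ[summ$subclade == "I", ]
  expect_equal(s1$protein_aa_min, s1$protein_aa_max)
  expect_equal(s1$pI_min, s1$pI_max)
  s2 <- summ[summ$subclade == "XII", ]
  expect_equal(s2$n_genes, 2L)
  expect_equal(s2$protein_aa_min, 500L)
  expect_equal(s2$protein_aa_max, 700L)
})
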