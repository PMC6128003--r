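# Seeded generator of complete toy datasets with planted ground truth.

HYDROPHOBIC <- c("A", "I", "L", "F", "V")
HYDROPHILIC <- c("D", "E", "N", "Q", "S", "T", "G", "K", "R")

rand_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  ch <- seq_to_chars(s)
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(a) sample(setdiff(AA20, a), 1), "")
  }
  paste(ch, collapse = "")
}

# One instantiated 24-aa LRR consensus unit: fixed positions per the
# consensus, free positions random.
lrr_unit <- function() {
  w <- sample(AA20, 24, replace = TRUE)
  w[c(1, 4, 7, 10, 12, 17)] <- sample(c("L", "I"), 6, replace = TRUE)
  w[15] <- "N"; w[20] <- "G"
  w[22] <- sample(c("V", "I"), 1)
  w[23] <- "P"
  paste(w, collapse = "")
}

#' Synthetic-dataset configuration
#'
#' Defaults describe a small allotetraploid-style toy genome: four
#' subclades with five members and two labeled references each, six decoys
#' (two per violated membership criterion), member sequences diverged
#' 0.10 substitutions/site from their subclade ancestor, chromosomes named
#' `A01`/`A02`/`D01`/`D02` plus an unanchored scaffold, and planted tandem
#' duplication layouts covering the linked and unlinked cases of the
#' calling rule. See the methods vignette for the rationale behind each
#' default.
#'
#' @param n_members members per subclade.
#' @param n_refs labeled references per subclade.
#' @param n_decoys total decoys (cycled over the LRR/kinase/TM violations).
#' @param mutation_rate member divergence from the subclade ancestor
#'   (substitutions/site).
#' @param subclade_divergence ancestor divergence from the family seed.
#' @param subclades subclade labels.
#' @param malectin_subclades subclades whose members carry an N-terminal
#'   malectin-like block.
#' @param lrr_copies copies of the LRR consensus unit per member (recycled
#'   over subclades).
#' @param kinase_len,malectin_len,sp_len,tm_len block lengths (aa).
#' @param chromosomes chromosome/scaffold names.
#' @param filler_genes non-family genes per chromosome.
#' @param tm_miss_rate,domain_miss_rate per-call probability that a true
#'   TM segment / domain hit is dropped from the evidence tables.
#' @param fiber_high_subclades subclades with planted fiber-high
#'   expression.
#' @param nb_size,base_mean,high_mean negative-binomial parameters for the
#'   count matrix.
#' @param qpcr_fold planted treatment fold change for the qPCR target.
#' @param physio_n biological replicates per physiology group.
#' @param chl_effect,el_effect planted silenced-vs-control effects
#'   (multiplicative).
#' @param physio_sigma coefficient of variation of the physiology noise.
#' @return a config list.
#' @export
sim_config <- function(n_members = 5, n_refs = 2, n_decoys = 6,
                       mutation_rate = 0.10, subclade_divergence = 0.35,
                       subclades = c("I", "III", "XI", "XII"),
                       malectin_subclades = "I",
                       lrr_copies = c(3, 2, 4, 2),
                       kinase_len = 260, malectin_len = 120,
                       sp_len = 22, tm_len = 19,
                       chromosomes = c("A01", "A02", "D01", "D02",
                                       "scaffold1841.1"),
                       filler_genes = 12,
                       tm_miss_rate = 0, domain_miss_rate = 0,
                       fiber_high_subclades = c("XI", "XII"),
                       nb_size = 5, base_mean = 50, high_mean = 400,
                       qpcr_fold = 4, physio_n = 5,
                       chl_effect = 1.3, el_effect = 0.6,
                       physio_sigma = 0.10) {
  as.list(environment())
}

build_protein <- function(ancestor, cfg, rate, drop = NULL) {
  blocks <- ancestor$blocks
  if (!is.null(drop)) blocks <- blocks[names(blocks) != drop]
  seqs <- character(0)
  coords <- tibble(block = character(), start = integer(), end = integer())
  pos <- 0L
  for (b in names(blocks)) {
    s <- if (b == "sp" || b == "tm") blocks[[b]] else mutate_seq(blocks[[b]], rate)
    seqs <- c(seqs, s)
    coords <- bind_rows(coords, tibble(block = b, start = pos + 1L,
                                       end = pos + nchar(s)))
    pos <- pos + nchar(s)
  }
  list(sequence = paste(seqs, collapse = ""), coords = coords)
}

# Ancestor block set for one subclade (or decoy lineage).
make_ancestor <- function(cfg, kinase_seed, n_lrr, with_malectin) {
  blocks <- list()
  blocks$sp <- paste0("M", rand_aa(cfg$sp_len - 1, HYDROPHOBIC))
  if (with_malectin) blocks$malectin <- rand_aa(cfg$malectin_len)
  for (k in seq_len(n_lrr)) blocks[[paste0("lrr", k)]] <- lrr_unit()
  blocks$linker <- rand_aa(8, HYDROPHILIC)
  blocks$tm <- rand_aa(cfg$tm_len, HYDROPHOBIC)
  blocks$kinase <- mutate_seq(kinase_seed, cfg$subclade_divergence)
  list(blocks = blocks)
}

evidence_from_coords <- function(protein_id, coords) {
  dom <- coords[grepl("^lrr|^kinase|^malectin", coords$block), ]
  domain <- tibble(
    protein_id = protein_id,
    domain_name = ifelse(grepl("^lrr", dom$block), "LRR_8",
                         ifelse(dom$block == "kinase", "Pkinase", "Malectin_like")),
    env_start = dom$start, env_end = dom$end,
    evalue = 1e-20, score = 100
  )
  tm <- coords[coords$block == "tm", ]
  tmc <- tibble(protein_id = protein_id, start = tm$start, end = tm$end)
  sp <- coords[coords$block == "sp", ]
  spc <- tibble(protein_id = protein_id, start = sp$start, end = sp$end,
                cleavage = sp$end)
  list(domain = domain, tm = tmc, sp = spc)
}

#' Generate a complete synthetic dataset with planted truth
#'
#' Writes a toy proteome (FASTA), annotated genome (GFF3), labeled
#' reference sequences, evidence tables (generic-TSV domain hits, TM and SP
#' calls), a stage-structured count matrix, a qPCR Ct table and a
#' physiology table, all derived from one seed; the returned `truth`
#' object fully determines the expected output of every downstream stage
#' at zero noise. One global seed fans out to independent per-component
#' streams, so adding a component never perturbs earlier draws.
#'
#' @param config a [sim_config()] list.
#' @param seed integer seed.
#' @param dir output directory (created if needed); `NULL` keeps
#'   everything in memory only.
#' @return a list with tibbles `proteome`, `references`, `ref_labels`,
#'   `gene_models`, `domain_hits`, `tm_calls`, `sp_calls`, `counts`,
#'   `gene_lengths`, `qpcr`, `physiology`, the `truth` list and, when
#'   `dir` is given, a named `paths` vector of the files written.
#' @export
generate_dataset <- function(config = sim_config(), seed = 1, dir = NULL) {
  cfg <- config
  ns <- length(cfg$subclades)
  lrr_copies <- rep(cfg$lrr_copies, length.out = ns)

  ## --- proteome, references, evidence -----------------------------------
  prot <- withr::with_seed(component_seed(seed, "proteome"), {
    kinase_seed <- rand_aa(cfg$kinase_len)
    ancestors <- lapply(seq_len(ns), function(i) {
      make_ancestor(cfg, kinase_seed, lrr_copies[i],
                    cfg$subclades[i] %in% cfg$malectin_subclades)
    })
    members <- list(); refs <- list(); evid <- list()
    truth_members <- list()
    for (i in seq_len(ns)) {
      sc <- cfg$subclades[i]
      for (m in seq_len(cfg$n_members)) {
        pid <- sprintf("M%s_%02d", sc, m)
        bp <- build_protein(ancestors[[i]], cfg, cfg$mutation_rate)
        members[[pid]] <- bp$sequence
        evid[[pid]] <- evidence_from_coords(pid, bp$coords)
        truth_members[[length(truth_members) + 1L]] <-
          tibble(protein_id = pid, subclade = sc)
      }
      for (r in seq_len(cfg$n_refs)) {
        rid <- sprintf("REF%s_%02d", sc, r)
        bp <- build_protein(ancestors[[i]], cfg, cfg$mutation_rate)
        refs[[rid]] <- bp$sequence
      }
    }
    # decoys: cycle over the three single-criterion violations; decoy
    # lineages descend from the subclade ancestors so they still screen in
    violations <- rep(c("LRR", "kinase", "TM"), length.out = cfg$n_decoys)
    truth_decoys <- list()
    for (d in seq_len(cfg$n_decoys)) {
      v <- violations[d]
      pid <- sprintf("DEC_%02d", d)
      anc <- ancestors[[(d - 1L) %% ns + 1L]]
      drop <- c(LRR = "lrr", kinase = "kinase", TM = "tm")[[v]]
      if (v == "LRR") {
        anc2 <- anc
        anc2$blocks <- anc2$blocks[!grepl("^lrr", names(anc2$blocks))]
        bp <- build_protein(anc2, cfg, cfg$mutation_rate)
      } else {
        bp <- build_protein(anc, cfg, cfg$mutation_rate, drop = drop)
      }
      members[[pid]] <- bp$sequence
      evid[[pid]] <- evidence_from_coords(pid, bp$coords)
      truth_decoys[[d]] <- tibble(protein_id = pid, violated = v)
    }
    list(members = members, refs = refs, evid = evid,
         truth_members = bind_rows(truth_members),
         truth_decoys = bind_rows(truth_decoys))
  })

  proteome <- tibble(id = names(prot$members),
                     sequence = unname(unlist(prot$members)),
                     description = "")
  references <- tibble(id = names(prot$refs),
                       sequence = unname(unlist(prot$refs)),
                       description = "")
  ref_labels <- tibble(id = references$id,
                       subclade = sub("^REF([^_]+)_.*$", "\\1", references$id))

  domain_hits <- bind_rows(lapply(prot$evid, `[[`, "domain"))
  tm_calls <- bind_rows(lapply(prot$evid, `[[`, "tm"))
  sp_calls <- bind_rows(lapply(prot$evid, `[[`, "sp"))
  if (cfg$domain_miss_rate > 0 || cfg$tm_miss_rate > 0) {
    ev <- withr::with_seed(component_seed(seed, "noise"), {
      dh <- domain_hits[stats::runif(nrow(domain_hits)) >= cfg$domain_miss_rate, ]
      tc <- tm_calls[stats::runif(nrow(tm_calls)) >= cfg$tm_miss_rate, ]
      list(dh = dh, tc = tc)
    })
    domain_hits <- ev$dh; tm_calls <- ev$tc
  }
  domain_hits$category <- map_domain_category(domain_hits$domain_name,
                                              default_domain_categories())
  domain_hits <- domain_hits[, c("protein_id", "domain_name", "category",
                                 "env_start", "env_end", "score", "evalue")]

  ## --- genome: gene placement with planted TDE layouts ------------------
  member_pids <- prot$truth_members$protein_id
  gene_of <- function(pid) paste0("g", pid)
  genome <- withr::with_seed(component_seed(seed, "genome"), {
    # TDE layouts: F=family, x=filler; gap_bp overrides the default
    # intergenic gap BEFORE the following gene
    layouts <- list(
      list(pattern = c("F", "F"), gaps = NULL, event = TRUE),
      list(pattern = c("F", "x", "F"), gaps = NULL, event = TRUE),
      list(pattern = c("F", "x", "x", "F"), gaps = NULL, event = TRUE),
      list(pattern = c("F", "x", "x", "F"), gaps = c(NA, 6e5, 6e5, 6e5),
           event = FALSE),
      list(pattern = c("F", "x", "x", "x", "F"), gaps = NULL, event = FALSE)
    )
    fam_pool <- sample(member_pids) # placement order
    n_layout_fam <- sum(vapply(layouts, function(l) sum(l$pattern == "F"), 0L))
    stopifnot(length(fam_pool) >= n_layout_fam)
    models <- list(); truth_events <- list(); fi <- 0L; filler_i <- 0L
    chrom_plan <- vector("list", length(cfg$chromosomes))
    names(chrom_plan) <- cfg$chromosomes
    for (ch in cfg$chromosomes) chrom_plan[[ch]] <- list()
    # spread layouts over the first chromosomes, isolated members after
    for (k in seq_along(layouts)) {
      ch <- cfg$chromosomes[(k - 1L) %% length(cfg$chromosomes) + 1L]
      chrom_plan[[ch]] <- c(chrom_plan[[ch]], list(layouts[[k]]))
    }
    iso <- fam_pool[(n_layout_fam + 1L):length(fam_pool)]
    rows <- list()
    iso_i <- 0L
    for (ch in cfg$chromosomes) {
      specs <- list() # per gene: list(kind, pid, gap_before)
      add <- function(kind, pid = NA, gap = NA) {
        specs[[length(specs) + 1L]] <<- list(kind = kind, pid = pid, gap = gap)
      }
      for (f in seq_len(3)) add("x")
      for (lay in chrom_plan[[ch]]) {
        pat <- lay$pattern
        gaps <- if (is.null(lay$gaps)) rep(NA, length(pat)) else lay$gaps
        ev_genes <- character(0)
        for (p in seq_along(pat)) {
          if (pat[p] == "F") {
            fi <- fi + 1L
            pid <- fam_pool[fi]
            add("F", pid, gaps[p])
            ev_genes <- c(ev_genes, gene_of(pid))
          } else add("x", gap = gaps[p])
        }
        if (lay$event) {
          truth_events[[length(truth_events) + 1L]] <-
            tibble(seq_id = ch, gene_ids = list(ev_genes))
        }
        for (f in seq_len(4)) add("x") # insulate layouts from each other
      }
      # isolated members, insulated by >= 3 fillers
      n_iso_here <- ceiling(length(iso) / length(cfg$chromosomes))
      while (iso_i < length(iso) && n_iso_here > 0) {
        iso_i <- iso_i + 1L; n_iso_here <- n_iso_here - 1L
        add("F", iso[iso_i])
        for (f in seq_len(3)) add("x")
      }
      for (f in seq_len(max(0, cfg$filler_genes - sum(vapply(specs, function(s)
        s$kind == "x", TRUE))))) add("x")
      # assign coordinates
      pos <- 1L
      for (s in specs) {
        gap <- if (is.na(s$gap)) sample(15000:25000, 1) else as.integer(s$gap)
        start <- pos + gap
        n_ex <- sample(2:4, 1)
        ex_len <- sample(200:600, n_ex, replace = TRUE)
        intr <- sample(100:400, max(n_ex - 1, 0), replace = TRUE)
        ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + intr))
        ex_end <- ex_start + ex_len - 1L
        end <- max(ex_end)
        if (s$kind == "F") {
          gid <- gene_of(s$pid); pid <- s$pid
        } else {
          filler_i <- filler_i + 1L
          gid <- sprintf("gx_%03d", filler_i); pid <- NA_character_
        }
        rows[[length(rows) + 1L]] <- tibble(
          gene_id = gid, seq_id = ch, start = start, end = end,
          strand = sample(c("+", "-"), 1), protein_id = pid,
          exons = list(tibble(start = as.integer(ex_start),
                              end = as.integer(ex_end))))
        pos <- end
      }
    }
    list(models = bind_rows(rows), truth_events = bind_rows(truth_events))
  })
  gene_models <- genome$models

  ## --- expression counts -------------------------------------------------
  samples <- c("-3dpa", "-1dpa", "0dpa", "1dpa", "3dpa", "5dpa", "10dpa",
               "20dpa", "25dpa", "leaf")
  fiber_samples <- c("1dpa", "3dpa", "5dpa", "10dpa", "20dpa", "25dpa")
  fam_genes <- unname(vapply(member_pids, gene_of, ""))
  pattern <- ifelse(prot$truth_members$subclade %in% cfg$fiber_high_subclades,
                    "fiber_high", "flat")
  counts <- withr::with_seed(component_seed(seed, "counts"), {
    m <- matrix(0L, length(fam_genes), length(samples),
                dimnames = list(fam_genes, samples))
    for (g in seq_along(fam_genes)) {
      for (s in seq_along(samples)) {
        mu <- if (pattern[g] == "fiber_high" && samples[s] %in% fiber_samples)
          cfg$high_mean else cfg$base_mean
        m[g, s] <- stats::rnbinom(1, size = cfg$nb_size, mu = mu)
      }
    }
    m
  })
  counts_tbl <- bind_cols(tibble(gene_id = fam_genes),
                          as_tibble(as.data.frame(counts, check.names = FALSE)))
  exlen <- vapply(seq_len(nrow(gene_models)), function(k) {
    ex <- gene_models$exons[[k]]
    sum(ex$end - ex$start + 1L)
  }, integer(1))
  gene_lengths <- tibble(gene_id = gene_models$gene_id, length_bp = exlen)

  ## --- qPCR ---------------------------------------------------------------
  qpcr <- withr::with_seed(component_seed(seed, "qpcr"), {
    target <- member_pids[1]
    rows <- list()
    for (grp in c("control", "treatment")) {
      for (rep_i in 1:3) {
        sample_id <- paste0(grp, "_", rep_i)
        ref_ct <- stats::rnorm(1, 15, 0.1)
        dct <- if (grp == "treatment") -log2(cfg$qpcr_fold) else 0
        rows[[length(rows) + 1L]] <- tibble(
          sample = sample_id, gene = "GhActin2", ct = ref_ct,
          replicate = rep_i, group = grp)
        rows[[length(rows) + 1L]] <- tibble(
          sample = sample_id, gene = target,
          ct = ref_ct + 5 + dct + stats::rnorm(1, 0, 0.05),
          replicate = rep_i, group = grp)
      }
    }
    bind_rows(rows)
  })

  ## --- physiology ----------------------------------------------------------
  physiology <- withr::with_seed(component_seed(seed, "physiology"), {
    rows <- list()
    for (grp in c("control", "silenced")) {
      chl_scale <- if (grp == "silenced") cfg$chl_effect else 1
      el_ratio <- 0.6 * (if (grp == "silenced") cfg$el_effect else 1)
      for (i in seq_len(cfg$physio_n)) {
        noise <- function() stats::rnorm(1, 1, cfg$physio_sigma)
        # one pigment-level noise per sample: biological variation scales
        # the extract concentration, hence both absorbances together
        pigment <- max(chl_scale * noise(), 0.01)
        a663 <- 0.9 * pigment
        a645 <- 0.32 * pigment
        el2 <- 100 * noise()
        el1 <- min(el_ratio * el2 * noise(), el2)
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = paste0(grp, "_", i), group = grp,
          a663 = a663, a645 = a645, v = 15, w = 300,
          el1 = el1, el2 = el2)
      }
    }
    bind_rows(rows)
  })

  truth <- list(
    members = mutate(prot$truth_members,
                     gene_id = unname(vapply(prot$truth_members$protein_id,
                                             gene_of, ""))),
    decoys = prot$truth_decoys,
    tde_events = genome$truth_events,
    expression_pattern = tibble(gene_id = fam_genes, pattern = pattern),
    qpcr_fold = cfg$qpcr_fold,
    physio_effects = c(chl = cfg$chl_effect, el = cfg$el_effect),
    seed = seed
  )

  out <- list(proteome = proteome, references = references,
              ref_labels = ref_labels, gene_models = gene_models,
              domain_hits = domain_hits, tm_calls = tm_calls,
              sp_calls = sp_calls, counts = counts_tbl,
              gene_lengths = gene_lengths, qpcr = qpcr,
              physiology = physiology, truth = truth, config = cfg)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    write_fasta(proteome, p("proteome.faa"))
    write_fasta(references, p("references.faa"))
    utils::write.table(ref_labels, p("reference_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gff3(gene_models, p("genome.gff3"))
    dh <- domain_hits
    writeLines(paste(dh$protein_id, dh$domain_name, dh$env_start, dh$env_end,
                     format(dh$evalue, scientific = TRUE), dh$score,
                     sep = "\t"), p("domains.tsv"))
    utils::write.table(tm_calls, p("tm_calls.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sp_calls, p("sp_calls.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_counts(counts_tbl, p("counts.tsv"))
    utils::write.table(gene_lengths, p("gene_lengths.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(qpcr, p("qpcr.csv"), row.names = FALSE)
    utils::write.csv(physiology, p("physiology.csv"), row.names = FALSE)
    out$paths <- c(proteome = p("proteome.faa"), references = p("references.faa"),
                   ref_labels = p("reference_labels.tsv"), gff = p("genome.gff3"),
                   domains = p("domains.tsv"), tm = p("tm_calls.tsv"),
                   sp = p("sp_calls.tsv"), counts = p("counts.tsv"),
                   gene_lengths = p("gene_lengths.tsv"), qpcr = p("qpcr.csv"),
                   physiology = p("physiology.csv"))
  }
  out
}

#' Run the full pipeline on a synthetic dataset and score it against truth
#'
#' Screens candidates with the internal similarity search (references vs
#' proteome), applies the membership rule to the evidence tables, assigns
#' subclades through alignment + p-distance + neighbor joining, calls
#' tandem duplication events, and scores each stage against the planted
#' truth.
#'
#' @param dataset output of [generate_dataset()].
#' @param e_max screening E-value threshold.
#' @param gap_mode passed to [p_distance()].
#' @param use_similarity run the internal search for candidate screening
#'   (`TRUE`) or take every protein with any evidence as candidate.
#' @return a list with `membership_precision`, `membership_recall`,
#'   `subclade_accuracy`, `tde_exact_match`, plus the intermediate tables
#'   (`membership`, `assignments`, `tde`).
#' @export
end_to_end_recovery <- function(dataset, e_max = 1e-10,
                                gap_mode = "complete_deletion",
                                use_similarity = TRUE) {
  truth <- dataset$truth
  if (use_similarity) {
    hits <- similarity_search(dataset$references, dataset$proteome)
    candidates <- screen_candidates(hits, e_max = e_max)
  } else {
    candidates <- sort(unique(c(dataset$domain_hits$protein_id,
                                dataset$tm_calls$protein_id)))
  }
  membership <- classify_membership(candidates, dataset$domain_hits,
                                    dataset$tm_calls)
  called <- membership$protein_id[membership$is_member]
  truth_set <- truth$members$protein_id
  tp <- length(intersect(called, truth_set))
  precision <- if (length(called)) tp / length(called) else NA_real_
  recall <- tp / length(truth_set)

  assignments <- NULL
  subclade_accuracy <- NA_real_
  if (length(called) >= 1) {
    pool <- bind_rows(
      dataset$proteome[dataset$proteome$id %in% called,
                       c("id", "sequence")],
      dataset$references[, c("id", "sequence")]
    )
    aln <- build_msa(pool)
    D <- p_distance(aln, gap_mode = gap_mode)
    tree <- neighbor_joining(D)
    assignments <- assign_subclades(tree, dataset$ref_labels)
    merged <- left_join(assignments,
                        truth$members[, c("protein_id", "subclade")],
                        by = c(query_id = "protein_id"),
                        suffix = c("", "_truth"))
    scored <- merged[!is.na(merged$subclade_truth), ]
    subclade_accuracy <- mean(scored$subclade == scored$subclade_truth)
  }

  placements <- place_genes(dataset$gene_models,
                            truth$members$gene_id[truth$members$protein_id %in% called])
  tde <- call_tandem_duplications(placements)
  canon <- function(sets) {
    sort(vapply(sets, function(g) paste(sort(g), collapse = "+"), ""))
  }
  tde_exact_match <- identical(canon(tde$gene_ids),
                               canon(truth$tde_events$gene_ids))

  list(membership_precision = precision, membership_recall = recall,
       subclade_accuracy = subclade_accuracy,
       tde_exact_match = tde_exact_match,
       membership = membership, assignments = assignments, tde = tde)
}
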