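# Orchestration, census/report assembly, tidy/glance methods.

#' Published LRR-RLK subclade census tables
#'
#' Per-subclade member counts of the LRR-RLK family as reported in the
#' genome-wide surveys of the cultivated tetraploid cotton (G. hirsutum
#' TM-1) and Arabidopsis proteomes, shipped as plain data under
#' `inst/extdata`. These printed counts are inputs for report arithmetic
#' (totals and percentage columns), not values the package recomputes.
#'
#' @param species `"cotton"` or `"arabidopsis"`.
#' @return a tibble with columns `subclade` and `n`.
#' @export
family_census <- function(species = c("cotton", "arabidopsis")) {
  species <- match.arg(species)
  f <- system.file("extdata",
                   paste0(if (species == "cotton") "gh" else "at",
                          "_subclade_census.tsv"),
                   package = "rlkfam", mustWork = TRUE)
  as_tibble(utils::read.delim(f, stringsAsFactors = FALSE))
}

#' Reported genome-partition counts for the cotton family survey
#'
#' Chromosomal distribution of family members over the A/D subgenomes and
#' unanchored scaffolds, tandem-duplication-event counts per compartment,
#' and the subclade-I N-terminal-malectin tally, as printed in the survey;
#' inputs for consistency arithmetic.
#'
#' @return a list of tibbles: `subgenome` (`compartment`, `n_genes`),
#'   `tde` (`compartment`, `n_events`), `malectin` (`n_nterm_malectin`,
#'   `n_members`).
#' @export
reported_partitions <- function() {
  f <- function(name) {
    as_tibble(utils::read.delim(
      system.file("extdata", name, package = "rlkfam", mustWork = TRUE),
      stringsAsFactors = FALSE))
  }
  list(subgenome = f("gh_subgenome_counts.tsv"),
       tde = f("gh_tde_counts.tsv"),
       malectin = f("gh_malectin_subclade1.tsv"))
}

#' Subclade census with percentage column
#'
#' Adds the report-style percentage column: 100 * n / total, rounded half
#' up to one decimal (the convention of printed family-census tables).
#'
#' @param counts a data frame with columns `subclade` and `n`.
#' @return a tibble with `subclade`, `n`, `percent`; the total is
#'   available as `sum(n)`.
#' @export
subclade_census <- function(counts) {
  stopifnot(all(c("subclade", "n") %in% names(counts)))
  mutate(as_tibble(counts),
         percent = round_half_up(100 * .data$n / sum(.data$n), 1))
}

#' Pipeline configuration
#'
#' Bundles file paths and tunables for [run_pipeline()], validating that
#' thresholds are positive and referenced files exist before any compute.
#'
#' @param proteome,gff,references,ref_labels,domains,tm_calls paths to the
#'   required inputs (protein FASTA, GFF3, reference FASTA, reference label
#'   TSV with `id`/`subclade` columns, domain-hit table, TM-call TSV).
#' @param sp_calls,hits,counts,gene_lengths optional input paths
#'   (signal-peptide calls, precomputed outfmt-6 similarity hits, count
#'   matrix, gene-length table).
#' @param domain_dialect dialect of the domain table.
#' @param e_max screening E-value threshold.
#' @param tde_window tandem-duplication bp window.
#' @param n_boot bootstrap replicates (0 skips supports).
#' @param seed RNG seed (bootstrap).
#' @param gap_mode p-distance gap handling.
#' @param chlorophyll_mode see [chlorophyll()].
#' @param var_equal t-test flavor (Student vs Welch).
#' @return a validated config list of class `rlk_config`.
#' @export
pipeline_config <- function(proteome, gff, references, ref_labels,
                            domains, tm_calls, sp_calls = NULL,
                            hits = NULL, counts = NULL, gene_lengths = NULL,
                            domain_dialect = "tsv",
                            e_max = 1e-10, tde_window = 1e6,
                            n_boot = 0, seed = 1,
                            gap_mode = "complete_deletion",
                            chlorophyll_mode = "as_printed",
                            var_equal = TRUE) {
  cfg <- as.list(environment())
  if (e_max <= 0 || tde_window <= 0 || n_boot < 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  required <- c("proteome", "gff", "references", "ref_labels", "domains",
                "tm_calls")
  for (nm in required) {
    if (!is.character(cfg[[nm]]) || !file.exists(cfg[[nm]])) {
      stop("configuration error: missing input file for '", nm, "': ",
           cfg[[nm]], call. = FALSE)
    }
  }
  for (nm in c("sp_calls", "hits", "counts", "gene_lengths")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop("configuration error: missing input file for '", nm, "': ",
           cfg[[nm]], call. = FALSE)
    }
  }
  structure(cfg, class = "rlk_config")
}

#' Run the full family-analysis pipeline
#'
#' Orchestrates screening, membership classification, phylogenetic
#' subclade assignment, chromosomal distribution, tandem-duplication
#' calling, protein characterization and (when counts are supplied)
#' expression profiling, and assembles the report tables. Deterministic
#' given the config seed.
#'
#' @param config an [pipeline_config()] object.
#' @param quiet suppress per-stage log lines.
#' @return an object of class `rlk_report`: a list of tibbles
#'   (`membership`, `assignments`, `census`, `distribution`, `tde`,
#'   `properties`, `subclade_summary`, `expression` when available) plus
#'   the tree and the config.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "rlk_config"))
  say <- function(...) if (!quiet) message("[rlkfam] ", ...)

  say("reading inputs")
  proteome <- read_fasta(config$proteome)
  references <- read_fasta(config$references)
  ref_labels <- as_tibble(utils::read.delim(config$ref_labels,
                                            stringsAsFactors = FALSE))
  gene_models <- read_gff3(config$gff)
  domain_hits <- read_domain_table(config$domains, dialect = config$domain_dialect)
  tm_calls <- read_tm_table(config$tm_calls)
  sp_calls <- if (!is.null(config$sp_calls)) read_sp_table(config$sp_calls)

  say("screening candidates")
  hits <- if (!is.null(config$hits)) {
    read_similarity_table(config$hits)
  } else {
    similarity_search(references, proteome)
  }
  candidates <- screen_candidates(hits, e_max = config$e_max)

  say("classifying membership (", length(candidates), " candidates)")
  membership <- classify_membership(candidates, domain_hits, tm_calls)
  members <- membership$protein_id[membership$is_member]
  if (length(members) < 1) stop("no family members recovered", call. = FALSE)

  say("building phylogeny (", length(members), " members + ",
      nrow(references), " references)")
  pool <- bind_rows(proteome[proteome$id %in% members, c("id", "sequence")],
                    references[, c("id", "sequence")])
  aln <- build_msa(pool)
  tree <- if (config$n_boot > 0) {
    bootstrap_support(aln, n_reps = config$n_boot, seed = config$seed,
                      gap_mode = config$gap_mode)
  } else {
    neighbor_joining(p_distance(aln, gap_mode = config$gap_mode))
  }
  assignments <- assign_subclades(tree, ref_labels)
  assignments <- assignments[assignments$query_id %in% members, ]

  census <- assignments |>
    group_by(subclade = .data$subclade) |>
    summarise(n = n(), .groups = "drop") |>
    subclade_census()

  say("mapping genes")
  member_genes <- gene_models$gene_id[!is.na(gene_models$protein_id) &
                                        gene_models$protein_id %in% members]
  placements <- place_genes(gene_models, member_genes)
  distribution <- distribution_table(placements)
  tde <- call_tandem_duplications(placements, window = config$tde_window)

  say("characterizing proteins")
  props <- protein_properties(proteome[proteome$id %in% members, ],
                              domain_hits, tm_calls, sp_calls)
  gl <- gene_models[!is.na(gene_models$protein_id), ]
  gene_len <- tibble(protein_id = gl$protein_id,
                     gene_length = as.integer(gl$end - gl$start + 1L))
  subclade_summary <- summarize_subclades(props, assignments, gene_len)

  expression <- NULL
  if (!is.null(config$counts)) {
    say("profiling expression")
    counts <- read_counts(config$counts)
    lengths <- if (!is.null(config$gene_lengths)) {
      as_tibble(utils::read.delim(config$gene_lengths, stringsAsFactors = FALSE))
    } else {
      ex <- exon_structure(gene_models)
      tibble(gene_id = ex$gene_id,
             length_bp = vapply(ex$exon_lengths, sum, integer(1)))
    }
    normalized <- normalize_expression(rpkm(counts, lengths))
    expression <- cluster_expression(normalized)
  }

  structure(list(membership = membership, assignments = assignments,
                 census = census, distribution = distribution, tde = tde,
                 properties = props, subclade_summary = subclade_summary,
                 expression = expression, tree = tree, config = config),
            class = "rlk_report")
}

#' @export
print.rlk_report <- function(x, ...) {
  cat("LRR-RLK family analysis report\n")
  cat("  members:        ", sum(x$membership$is_member), "of",
      nrow(x$membership), "candidates\n")
  cat("  subclades:      ", nrow(x$census), "\n")
  cat("  TDE events:     ", nrow(x$tde), "involving",
      sum(x$tde$n_genes), "genes\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x an `rlk_report`.
#' @param ... unused.
#' @export
tidy.rlk_report <- function(x, ...) {
  left_join(x$membership[, c("protein_id", "is_member")],
            rename(x$assignments[, c("query_id", "subclade", "support")],
                   protein_id = "query_id"),
            by = "protein_id")
}

#' @rdname run_pipeline
#' @export
glance.rlk_report <- function(x, ...) {
  tibble(n_candidates = nrow(x$membership),
         n_members = sum(x$membership$is_member),
         n_subclades = nrow(x$census),
         n_tde_events = nrow(x$tde),
         n_tde_genes = sum(x$tde$n_genes))
}
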