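#' Default chromosome-name patterns for subgenome classing
#'
#' Allotetraploid cotton assemblies name chromosomes `A01`..`A13` and
#' `D01`..`D13` with unanchored scaffolds as `scaffoldNNN.N`; naming
#' conventions differ across assemblies, so the patterns are data the
#' caller can replace.
#'
#' @return a tibble with columns `pattern` and `subgenome`.
#' @export
default_subgenome_patterns <- function() {
  tibble(pattern = c("^A\\d+", "^D\\d+", "^scaffold"),
         subgenome = c("A", "D", "scaffold"))
}

#' Rank genes along each chromosome
#'
#' All annotated genes (family and non-family alike) are ranked 0-based by
#' start coordinate within each chromosome/scaffold; ties break by end,
#' then by gene id, so ranks are deterministic. Ranks over the complete
#' annotation are what the tandem-duplication rule counts interruptions
#' against.
#'
#' @param gene_models a gene-model tibble ([read_gff3()]).
#' @param member_ids character vector of family-member gene ids.
#' @param subgenome_patterns see [default_subgenome_patterns()].
#' @return a tibble with columns `gene_id`, `seq_id`, `rank`, `start`,
#'   `end`, `is_family`, `subgenome`.
#' @export
place_genes <- function(gene_models, member_ids,
                        subgenome_patterns = default_subgenome_patterns()) {
  pl <- gene_models |>
    select("gene_id", "seq_id", "start", "end") |>
    arrange(.data$seq_id, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$seq_id) |>
    mutate(rank = dplyr::row_number() - 1L) |>
    ungroup() |>
    mutate(is_family = .data$gene_id %in% member_ids)
  sg <- rep(NA_character_, nrow(pl))
  pats <- subgenome_patterns
  for (k in seq_len(nrow(pats))) {
    hit <- is.na(sg) & grepl(pats$pattern[k], pl$seq_id)
    sg[hit] <- pats$subgenome[k]
  }
  pl$subgenome <- sg
  pl[, c("gene_id", "seq_id", "rank", "start", "end", "is_family", "subgenome")]
}

#' Family gene counts per chromosome and per subgenome
#'
#' @param placements output of [place_genes()].
#' @return a list with `by_seq` (family count per seq_id) and
#'   `by_subgenome` (family count per subgenome class) tibbles.
#' @export
distribution_table <- function(placements) {
  by_seq <- placements |>
    group_by(.data$seq_id) |>
    summarise(n_family = sum(.data$is_family), .groups = "drop")
  by_sub <- placements |>
    group_by(.data$subgenome) |>
    summarise(n_family = sum(.data$is_family), .groups = "drop")
  list(by_seq = by_seq, by_subgenome = by_sub)
}

#' Call tandem duplication events among family genes
#'
#' Two family genes on the same chromosome are pair-linked when at most one
#' gene of any type lies between them in annotation rank order, or when
#' exactly two genes intervene and the genomic gap (end of the upstream
#' gene to start of the downstream gene) is within `window` bp. Events are
#' the connected components of the pair-link graph, so chains of linked
#' genes merge transitively into one maximal event.
#'
#' Because the linking condition only loosens as genes get closer, scanning
#' consecutive family genes in rank order recovers exactly the components
#' of the all-pairs link graph.
#'
#' @param placements output of [place_genes()] (must contain family and
#'   non-family genes so interruptions can be counted).
#' @param max_interrupt rank-interruption limit for the unconditional link.
#' @param window bp window for the two-gene-interruption link.
#' @return a tibble with one row per event: `event_id`, `seq_id`,
#'   `gene_ids` (list-column, ordered by start), `n_genes`, `span_bp`.
#' @export
call_tandem_duplications <- function(placements, max_interrupt = 1,
                                     window = 1e6) {
  stopifnot(all(c("gene_id", "seq_id", "rank", "start", "end", "is_family")
                %in% names(placements)))
  events <- list()
  for (sid in unique(placements$seq_id)) {
    ch <- placements[placements$seq_id == sid, ]
    if (anyDuplicated(ch$rank) || !setequal(ch$rank, seq_len(nrow(ch)) - 1L)) {
      stop("ranks on ", sid, " are not a 0..(n-1) permutation; placements ",
           "from mixed rank systems?", call. = FALSE)
    }
    fam <- ch[ch$is_family, ]
    fam <- fam[order(fam$rank), ]
    if (nrow(fam) < 2) next
    linked <- logical(nrow(fam) - 1)
    for (k in seq_len(nrow(fam) - 1)) {
      gap_genes <- fam$rank[k + 1] - fam$rank[k] - 1L
      if (gap_genes <= max_interrupt) {
        linked[k] <- TRUE
      } else if (gap_genes == max_interrupt + 1L) {
        linked[k] <- (fam$start[k + 1] - fam$end[k]) <= window
      }
    }
    comp <- cumsum(c(TRUE, !linked))
    for (cc in unique(comp)) {
      members <- fam[comp == cc, ]
      if (nrow(members) < 2) next
      events[[length(events) + 1L]] <- tibble(
        seq_id = sid,
        gene_ids = list(members$gene_id[order(members$start)]),
        n_genes = nrow(members),
        span_bp = max(members$end) - min(members$start) + 1L
      )
    }
  }
  if (length(events) == 0) {
    return(tibble(event_id = character(), seq_id = character(),
                  gene_ids = list(), n_genes = integer(), span_bp = integer()))
  }
  out <- bind_rows(events)
  out <- out[order(out$seq_id), ]
  out$event_id <- sprintf("TDE%03d", seq_len(nrow(out)))
  out[, c("event_id", "seq_id", "gene_ids", "n_genes", "span_bp")]
}

#' Exon-intron structure per gene
#'
#' Lengths use 1-based inclusive arithmetic (length = end - start + 1);
#' intron k is the gap between exon k and exon k + 1.
#'
#' @param gene_models a gene-model tibble ([read_gff3()]).
#' @return a tibble with columns `gene_id`, `n_exons`, `exon_lengths` and
#'   `intron_lengths` (list-columns), `cds_span` (first exon start to last
#'   exon end) and `gene_length`.
#' @export
exon_structure <- function(gene_models) {
  rows <- lapply(seq_len(nrow(gene_models)), function(k) {
    ex <- gene_models$exons[[k]]
    el <- as.integer(ex$end - ex$start + 1L)
    il <- if (nrow(ex) > 1) as.integer(ex$start[-1] - ex$end[-nrow(ex)] - 1L) else integer(0)
    tibble(gene_id = gene_models$gene_id[k],
           n_exons = nrow(ex),
           exon_lengths = list(el), intron_lengths = list(il),
           cds_span = if (nrow(ex)) as.integer(max(ex$end) - min(ex$start) + 1L) else NA_integer_,
           gene_length = as.integer(gene_models$end[k] - gene_models$start[k] + 1L))
  })
  bind_rows(rows)
}

#' Aggregate exon-intron structure per group
#'
#' @param structure output of [exon_structure()].
#' @param groups a data frame with columns `gene_id` and `group` (e.g.
#'   subclade labels).
#' @return a tibble with per-group mean exon count and mean exon/intron
#'   length.
#' @export
summarize_exon_structure <- function(structure, groups) {
  merged <- left_join(structure, groups, by = "gene_id")
  merged |>
    group_by(.data$group) |>
    summarise(
      n_genes = n(),
      mean_exons = mean(.data$n_exons),
      mean_exon_length = mean(unlist(.data$exon_lengths)),
      mean_intron_length = if (length(unlist(.data$intron_lengths)))
        mean(unlist(.data$intron_lengths)) else NA_real_,
      .groups = "drop"
    )
}
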