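#' Read gene models from a GFF3 annotation
#'
#' Parses `gene`, `mRNA` and `exon` features, attaches exons to their parent
#' gene through the `Parent` attribute chain, and keeps all coordinates
#' 1-based inclusive (native GFF3). Exons are validated against the gene
#' span; orphan `Parent` references and out-of-span exons are errors.
#'
#' @param path path to a GFF3 file.
#' @return a tibble with one row per gene: `gene_id`, `seq_id`, `start`,
#'   `end`, `strand`, `protein_id` (the mRNA/protein link, `NA` if absent)
#'   and `exons`, a list-column of tibbles with `start`/`end`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  g <- as.data.frame(rtracklayer::readGFF(path,
    columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent", "protein_id")))
  g$Parent <- vapply(g$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  g$seqid <- as.character(g$seqid)
  g$strand <- as.character(g$strand)

  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type == "mRNA", , drop = FALSE]
  exons <- g[g$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path, call. = FALSE)
  if (anyDuplicated(genes$ID)) stop("duplicate gene ID in ", path, call. = FALSE)
  if (any(genes$start > genes$end)) stop("gene with start > end in ", path, call. = FALSE)
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene with undefined strand in ", path, call. = FALSE)
  }

  # resolve exon -> gene through the mRNA layer when present
  mrna_gene <- setNames(mrnas$Parent, mrnas$ID)
  if (any(!is.na(mrnas$Parent) & !mrnas$Parent %in% genes$ID)) {
    stop("mRNA with orphan Parent in ", path, call. = FALSE)
  }
  exon_parent <- exons$Parent
  if (any(is.na(exon_parent))) stop("exon without Parent in ", path, call. = FALSE)
  exon_gene <- ifelse(exon_parent %in% names(mrna_gene),
                      mrna_gene[exon_parent], exon_parent)
  if (any(!exon_gene %in% genes$ID)) {
    stop("exon with orphan Parent '", exon_parent[!exon_gene %in% genes$ID][1],
         "' in ", path, call. = FALSE)
  }

  prot <- setNames(rep(NA_character_, nrow(genes)), genes$ID)
  if ("protein_id" %in% names(mrnas) && nrow(mrnas) > 0) {
    has <- !is.na(mrnas$protein_id)
    prot[mrnas$Parent[has]] <- as.character(mrnas$protein_id[has])
  }

  exon_by_gene <- split(exons[, c("start", "end")], exon_gene)
  out <- tibble(
    gene_id = genes$ID,
    seq_id = genes$seqid,
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = genes$strand,
    protein_id = unname(prot[genes$ID]),
    exons = lapply(genes$ID, function(gid) {
      ex <- exon_by_gene[[gid]]
      if (is.null(ex)) return(tibble(start = integer(), end = integer()))
      ex <- ex[order(ex$start, ex$end), , drop = FALSE]
      as_tibble(lapply(ex, as.integer))
    })
  )
  validate_gene_models(out)
  out
}

validate_gene_models <- function(models) {
  for (k in seq_len(nrow(models))) {
    ex <- models$exons[[k]]
    if (nrow(ex) == 0) next
    if (any(ex$start > ex$end)) {
      stop("exon with start > end in gene ", models$gene_id[k], call. = FALSE)
    }
    if (any(ex$start < models$start[k]) || any(ex$end > models$end[k])) {
      stop("exon outside gene span in gene ", models$gene_id[k], call. = FALSE)
    }
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene ", models$gene_id[k], call. = FALSE)
    }
  }
  invisible(models)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and exon features; the inverse of [read_gff3()].
#'
#' @param models a gene-model tibble as returned by [read_gff3()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (k in seq_len(nrow(models))) {
    gid <- models$gene_id[k]
    base <- c(models$seq_id[k], "rlkfam")
    span <- c(models$start[k], models$end[k])
    st <- models$strand[k]
    lines <- c(lines, paste(c(base, "gene", span, ".", st, ".",
                              paste0("ID=", gid)), collapse = "\t"))
    mid <- paste0(gid, ".t1")
    attr_m <- paste0("ID=", mid, ";Parent=", gid)
    if (!is.na(models$protein_id[k])) {
      attr_m <- paste0(attr_m, ";protein_id=", models$protein_id[k])
    }
    lines <- c(lines, paste(c(base, "mRNA", span, ".", st, ".", attr_m),
                            collapse = "\t"))
    ex <- models$exons[[k]]
    for (e in seq_len(nrow(ex))) {
      lines <- c(lines, paste(c(base, "exon", ex$start[e], ex$end[e], ".", st,
                                ".", paste0("ID=", mid, ".exon", e, ";Parent=", mid)),
                              collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
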