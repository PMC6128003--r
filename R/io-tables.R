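#' Default domain-name to category mapping
#'
#' HMM profile names are mapped onto the three evidence categories of the
#' family membership rule. Names beginning `LRR` count as LRR repeats,
#' `Pkinase`/`PK_Tyr_Ser-Thr` as kinase domains and names beginning
#' `Malectin` as malectin-like domains; anything else is `other`. The exact
#' profile names counted as "kinase domain" by upstream web tools are not
#' standardized, so the mapping is data a caller can replace, not hard-coded
#' truth.
#'
#' @return a tibble with columns `pattern` (regular expression, anchored at
#'   the start of the domain name) and `category`.
#' @export
default_domain_categories <- function() {
  tibble(
    pattern = c("^LRR", "^LRRNT", "^Pkinase", "^PK_Tyr_Ser-Thr", "^Malectin"),
    category = c("LRR", "LRR", "kinase", "kinase", "malectin")
  )
}

map_domain_category <- function(domain_name, category_map) {
  out <- rep("other", length(domain_name))
  for (k in seq_len(nrow(category_map))) {
    hit <- grepl(category_map$pattern[k], domain_name)
    out[hit & out == "other"] <- category_map$category[k]
  }
  out
}

#' Read per-protein domain hits
#'
#' Two dialects are supported: HMMER3 `domtblout` (whitespace-separated,
#' comment lines starting `#`; the target name, query name, full-sequence
#' E-value, bit score and envelope coordinates are used) and a generic
#' header-less TSV with columns `protein_id`, `domain_name`, `env_start`,
#' `env_end`, `evalue` and optionally `score`. Envelope ("env") coordinates
#' are taken as the domain extent in both dialects.
#'
#' @param path path to the table.
#' @param dialect `"domtblout"` or `"tsv"`.
#' @param category_map mapping from domain names to evidence categories,
#'   see [default_domain_categories()].
#' @return a tibble with columns `protein_id`, `domain_name`, `category`,
#'   `env_start`, `env_end`, `score`, `evalue`.
#' @export
read_domain_table <- function(path, dialect = c("domtblout", "tsv"),
                              category_map = default_domain_categories()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("domain table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(protein_id = character(), domain_name = character(),
                  category = character(), env_start = integer(),
                  env_end = integer(), score = double(), evalue = double()))
  }
  if (dialect == "domtblout") {
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 23)) {
      stop("unmappable domtblout row (fewer than 23 columns) at line ",
           which(nf < 23)[1], call. = FALSE)
    }
    # domtblout: 1 target(domain) name, 4 query(protein) name, 7 full-seq
    # E-value, 8 full-seq score, 20-21 env coords
    out <- tibble(
      protein_id = vapply(fields, `[[`, "", 4),
      domain_name = vapply(fields, `[[`, "", 1),
      env_start = as.integer(vapply(fields, `[[`, "", 20)),
      env_end = as.integer(vapply(fields, `[[`, "", 21)),
      score = as.numeric(vapply(fields, `[[`, "", 8)),
      evalue = as.numeric(vapply(fields, `[[`, "", 7))
    )
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 5)) {
      stop("unmappable TSV row (fewer than 5 columns) at line ",
           which(nf < 5)[1], call. = FALSE)
    }
    out <- tibble(
      protein_id = vapply(fields, `[[`, "", 1),
      domain_name = vapply(fields, `[[`, "", 2),
      env_start = as.integer(vapply(fields, `[[`, "", 3)),
      env_end = as.integer(vapply(fields, `[[`, "", 4)),
      score = vapply(fields, function(f) {
        if (length(f) >= 6) as.numeric(f[[6]]) else NA_real_
      }, numeric(1)),
      evalue = as.numeric(vapply(fields, `[[`, "", 5))
    )
  }
  if (any(is.na(out$env_start)) || any(is.na(out$env_end)) || any(is.na(out$evalue))) {
    stop("unmappable row in domain table: non-numeric coordinates or E-value",
         call. = FALSE)
  }
  if (any(out$env_end < out$env_start)) {
    stop("domain hit with env_end < env_start for protein ",
         out$protein_id[out$env_end < out$env_start][1], call. = FALSE)
  }
  if (any(out$evalue < 0)) stop("negative E-value in domain table", call. = FALSE)
  out$category <- map_domain_category(out$domain_name, category_map)
  out[, c("protein_id", "domain_name", "category", "env_start", "env_end",
          "score", "evalue")]
}

#' Read transmembrane-segment or signal-peptide call tables
#'
#' Plain TSVs with a header row. TM tables need columns `protein_id`,
#' `start`, `end` (1-based residues); SP tables need `protein_id`,
#' `start`, `end`, `cleavage` and every signal-peptide segment must begin
#' at residue 1.
#'
#' @param path path to the TSV.
#' @return a tibble of calls.
#' @export
read_tm_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "start", "end") %in% names(d)))
  if (any(d$start > d$end)) stop("TM segment with start > end", call. = FALSE)
  if (nrow(d) > 0 && any(d$start < 1)) stop("TM segment start < 1", call. = FALSE)
  as_tibble(d[, c("protein_id", "start", "end")])
}

#' @rdname read_tm_table
#' @export
read_sp_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "start", "end", "cleavage") %in% names(d)))
  if (any(d$start != 1)) stop("signal peptide not starting at residue 1", call. = FALSE)
  if (any(d$start > d$end)) stop("SP segment with start > end", call. = FALSE)
  as_tibble(d[, c("protein_id", "start", "end", "cleavage")])
}

#' Read a BLAST tabular (outfmt 6) similarity table
#'
#' Expects the 12 standard columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore); scientific E-value
#' notation including `1e-180` and `0.0` is parsed as a real number.
#'
#' @param path path to the tab-separated hit table.
#' @return a tibble with columns `query_id`, `subject_id`, `pident`,
#'   `length`, `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `score`.
#' @export
read_similarity_table <- function(path) {
  if (!file.exists(path)) stop("similarity table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  pident = double(), length = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = double(), score = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    stop("similarity table row with ", nf[nf != 12][1],
         " columns (12 expected) at line ", which(nf != 12)[1], call. = FALSE)
  }
  f <- function(i) vapply(fields, `[[`, "", i)
  out <- tibble(
    query_id = f(1), subject_id = f(2),
    pident = as.numeric(f(3)), length = as.integer(f(4)),
    q_start = as.integer(f(7)), q_end = as.integer(f(8)),
    s_start = as.integer(f(9)), s_end = as.integer(f(10)),
    evalue = as.numeric(f(11)), score = as.numeric(f(12))
  )
  if (any(is.na(out$evalue)) || any(out$evalue < 0)) {
    stop("invalid E-value in similarity table", call. = FALSE)
  }
  out
}

#' Write similarity hits in BLAST tabular (outfmt 6) layout
#'
#' @param hits a tibble as returned by [read_similarity_table()] or
#'   [similarity_search()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(hits, path) {
  pident <- if ("pident" %in% names(hits)) hits$pident else NA
  len <- if ("length" %in% names(hits)) hits$length else hits$q_end - hits$q_start + 1L
  rows <- paste(hits$query_id, hits$subject_id,
                ifelse(is.na(pident), 0, pident), len, 0, 0,
                hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                format(hits$evalue, scientific = TRUE, digits = 3),
                hits$score, sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Read and write gene-by-sample count matrices
#'
#' Counts tables are TSVs with a `gene_id` column followed by one column per
#' sample. Gene ids must be unique and counts non-negative integers.
#'
#' @param path path to the TSV.
#' @return a tibble with `gene_id` plus one numeric column per sample.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene_id") stop("counts table must start with gene_id", call. = FALSE)
  if (anyDuplicated(d$gene_id)) stop("duplicate gene row in counts table", call. = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  as_tibble(d)
}

#' @rdname read_counts
#' @param counts a counts tibble.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a phylogenetic tree to Newick text
#'
#' Branch lengths are kept and integer bootstrap supports (if present as
#' `node.label`) become internal node labels.
#'
#' @param tree an `ape::phylo` tree.
#' @param path optional output file; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
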