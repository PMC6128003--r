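#' Internal protein similarity search
#'
#' A word-seeded Smith-Waterman search: a query/subject pair is aligned only
#' when the two sequences share at least one exact k-mer (default k = 3);
#' gated pairs get a full optimal local alignment with BLOSUM62 and affine
#' gaps (a gap of length g costs `gap_open + g * gap_extend`). E-values come
#' from the Karlin-Altschul formula E = K * m * n * exp(-lambda * S) with
#' the gapped BLOSUM62 11/1 constants lambda = 0.267, K = 0.041; edge-effect
#' correction is omitted at desk scale. The best hit per (query, subject)
#' pair is reported. Because gated pairs are aligned exactly, the reported
#' score never exceeds the unseeded Smith-Waterman optimum and equals it
#' whenever the two sequences share an exact seed of length >= k.
#'
#' @param queries,subjects tibbles with columns `id` and `sequence`.
#' @param k seed word length.
#' @param gap_open,gap_extend affine gap parameters.
#' @param lambda,kappa Karlin-Altschul constants for the E-value.
#' @param exclude_self drop hits with `query_id == subject_id` (on by
#'   default, for searches where the query set is part of the subject set).
#' @return a tibble with columns `query_id`, `subject_id`, `raw_score`
#'   (Smith-Waterman score), `score` (bit score), `evalue`, and 1-based
#'   aligned intervals `q_start`, `q_end`, `s_start`, `s_end`, sorted by
#'   E-value.
#' @export
similarity_search <- function(queries, subjects, k = 3,
                              gap_open = 11, gap_extend = 1,
                              lambda = 0.267, kappa = 0.041,
                              exclude_self = TRUE) {
  if (nrow(queries) == 0) stop("empty query set", call. = FALSE)
  if (nrow(subjects) == 0) stop("empty subject set", call. = FALSE)
  assert_aa(queries$sequence, "query sequence")
  assert_aa(subjects$sequence, "subject sequence")
  if (any(nchar(queries$sequence) < k) || any(nchar(subjects$sequence) < k)) {
    stop("sequence shorter than the seed length k = ", k, call. = FALSE)
  }
  B <- blosum62()
  kmers <- function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  qk <- lapply(queries$sequence, kmers)
  sk <- lapply(subjects$sequence, kmers)
  qc <- lapply(queries$sequence, seq_to_chars)
  sc <- lapply(subjects$sequence, seq_to_chars)

  rows <- list()
  for (i in seq_len(nrow(queries))) {
    for (j in seq_len(nrow(subjects))) {
      if (exclude_self && queries$id[i] == subjects$id[j]) next
      if (!any(qk[[i]] %in% sk[[j]])) next
      S <- B[qc[[i]], sc[[j]], drop = FALSE]
      al <- cpp_local_align(S, gap_open, gap_extend)
      if (al$score <= 0) next
      m <- length(qc[[i]]); n <- length(sc[[j]])
      rows[[length(rows) + 1L]] <- tibble(
        query_id = queries$id[i], subject_id = subjects$id[j],
        raw_score = al$score,
        score = (lambda * al$score - log(kappa)) / log(2),
        evalue = kappa * m * n * exp(-lambda * al$score),
        q_start = al$q_start, q_end = al$q_end,
        s_start = al$s_start, s_end = al$s_end
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  raw_score = double(), score = double(), evalue = double(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer()))
  }
  arrange(bind_rows(rows), .data$evalue, .data$query_id, .data$subject_id)
}

#' Screen similarity hits for family candidates
#'
#' Collects the non-redundant set of sequences hit at or below an E-value
#' threshold. The published screen queries reference-family proteins against
#' a target proteome, so candidates are hit *subjects* by default; set
#' `direction = "query"` when the search ran the other way around.
#'
#' @param hits a similarity-hit tibble ([similarity_search()] or
#'   [read_similarity_table()]).
#' @param e_max E-value threshold (default 1e-10).
#' @param direction which side of the hit is the candidate.
#' @return a character vector of unique candidate ids, sorted.
#' @export
screen_candidates <- function(hits, e_max = 1e-10,
                              direction = c("subject", "query")) {
  direction <- match.arg(direction)
  col <- if (direction == "subject") "subject_id" else "query_id"
  sort(unique(hits[[col]][hits$evalue <= e_max]))
}

#' Classify candidate proteins with the three-evidence membership rule
#'
#' A protein is a family member iff it has at least one LRR-category domain
#' hit, at least one kinase-category domain hit, and at least one
#' transmembrane segment. Failed criteria are listed per protein so that
#' borderline sequences surface in the output rather than silently
#' disappearing.
#'
#' @param protein_ids character vector of candidate protein ids.
#' @param domain_hits domain-hit tibble ([read_domain_table()]).
#' @param tm_calls transmembrane-call tibble ([read_tm_table()] or
#'   [hydropathy_tm_scan()]).
#' @return a tibble with columns `protein_id`, `n_lrr`, `has_kinase`,
#'   `n_tm`, `is_member` and `reasons` (list-column naming each missing
#'   criterion among `"LRR"`, `"kinase"`, `"TM"`).
#' @export
classify_membership <- function(protein_ids, domain_hits, tm_calls) {
  n_lrr <- vapply(protein_ids, function(p) {
    sum(domain_hits$protein_id == p & domain_hits$category == "LRR")
  }, integer(1))
  n_kin <- vapply(protein_ids, function(p) {
    sum(domain_hits$protein_id == p & domain_hits$category == "kinase")
  }, integer(1))
  n_tm <- vapply(protein_ids, function(p) sum(tm_calls$protein_id == p), integer(1))
  is_member <- n_lrr >= 1 & n_kin >= 1 & n_tm >= 1
  reasons <- lapply(seq_along(protein_ids), function(i) {
    c(if (n_lrr[i] < 1) "LRR", if (n_kin[i] < 1) "kinase", if (n_tm[i] < 1) "TM")
  })
  tibble(protein_id = unname(protein_ids), n_lrr = unname(n_lrr),
         has_kinase = unname(n_kin >= 1), n_tm = unname(n_tm),
         is_member = unname(is_member), reasons = reasons)
}
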