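#' Assign query leaves to reference-anchored subclades
#'
#' For each unlabeled leaf, the smallest edge-delimited cluster (bipartition
#' side) containing the query and at least one labeled reference votes: the
#' query receives the majority reference label within that cluster, ties
#' broken by the reference with the smallest patristic distance to the
#' query. A query whose smallest reference-containing cluster spans more
#' than `max_cluster_frac` of all leaves is considered to attach outside
#' every reference cluster and is reported `"unassigned"` — the behaviour
#' expected for phylogenetic outliers that co-cluster with no reference
#' subclade.
#'
#' @param tree an `ape::phylo` tree containing reference and query leaves.
#' @param reference_labels a data frame with columns `id` and `subclade`
#'   labeling the reference leaves.
#' @param max_cluster_frac largest tolerated cluster size, as a fraction of
#'   all leaves, before a query is declared unassigned.
#' @return a tibble with columns `query_id`, `subclade` (label or
#'   `"unassigned"`), `support` (fraction of cluster reference votes for the
#'   winning label), `nearest_ref` and `nearest_dist` (patristic).
#' @export
assign_subclades <- function(tree, reference_labels, max_cluster_frac = 0.5) {
  tips <- tree$tip.label
  n <- length(tips)
  lab <- setNames(reference_labels$subclade, reference_labels$id)
  refs <- tips[tips %in% names(lab)]
  if (length(refs) == 0) stop("tree contains no labeled reference", call. = FALSE)
  queries <- setdiff(tips, refs)

  tu <- tips_under(tree)
  # every edge yields one side (tips under the child); the complement is the
  # other side of the same bipartition
  sides <- lapply(seq_len(nrow(tree$edge)), function(e) tu[[tree$edge[e, 2]]])
  pat <- ape::cophenetic.phylo(tree)

  rows <- lapply(queries, function(q) {
    qi <- match(q, tips)
    cand <- list()
    for (s in sides) {
      cand[[length(cand) + 1L]] <- if (qi %in% s) s else setdiff(seq_len(n), s)
    }
    sizes <- lengths(cand)
    ord <- order(sizes)
    chosen <- NULL
    for (k in ord) {
      side_ids <- tips[cand[[k]]]
      side_refs <- side_ids[side_ids %in% refs]
      if (length(side_refs) > 0) { chosen <- list(ids = side_ids, refs = side_refs); break }
    }
    dq <- pat[q, refs]
    nearest <- refs[which.min(dq)]
    if (is.null(chosen) || length(chosen$ids) > max_cluster_frac * n) {
      return(tibble(query_id = q, subclade = "unassigned", support = 0,
                    nearest_ref = nearest, nearest_dist = unname(min(dq))))
    }
    votes <- table(lab[chosen$refs])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      # tie: label of the patristically nearest reference among tied labels
      tied_refs <- chosen$refs[lab[chosen$refs] %in% top]
      top <- unname(lab[tied_refs[which.min(pat[q, tied_refs])]])
    }
    tibble(query_id = q, subclade = top,
           support = unname(max(votes)) / length(chosen$refs),
           nearest_ref = nearest, nearest_dist = unname(min(dq)))
  })
  bind_rows(rows)
}
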