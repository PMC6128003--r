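# Physicochemical properties and sequence-level scans.

# Average (not monoisotopic) residue masses in Da; X gets the mean residue
# mass. Matches the convention of common proteomics property calculators.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

#' Average molecular weight of a protein
#'
#' Sum of average-isotopic residue masses plus one water. `X` contributes
#' the mean residue mass.
#'
#' @param sequence character vector of amino-acid sequences.
#' @return numeric vector of masses in Da.
#' @export
molecular_weight <- function(sequence) {
  assert_aa(sequence)
  masses <- c(AA_AVG_MASS, X = mean(AA_AVG_MASS))
  vapply(toupper(sequence), function(s) {
    sum(masses[seq_to_chars(s)]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Bjellqvist pKa set
#'
#' The pKa values used by the common web pI calculators (Bjellqvist-style):
#' side chains for D, E, C, Y, H, K, R, a C-terminal carboxyl pKa, and an
#' N-terminal amine pKa that depends on the first residue. The set is plain
#' data so an alternative scale can be swapped in.
#'
#' @return a list with elements `cterm`, `nterm_default`, `nterm` (named
#'   overrides by first residue) and `side` (named side-chain pKas).
#' @export
pka_bjellqvist <- function() {
  list(
    cterm = 3.55,
    nterm_default = 7.5,
    nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.70, G = 7.50),
    side = c(D = 4.05, E = 4.45, H = 5.98, C = 9.00, Y = 10.00, K = 10.00,
             R = 12.00)
  )
}

# Net charge of a peptide at a given pH under Henderson-Hasselbalch.
peptide_charge <- function(counts, first_res, pka, pH) {
  nt <- unname(pka$nterm[first_res])
  if (length(nt) != 1 || is.na(nt)) nt <- pka$nterm_default
  pos_pk <- c(nt,
              rep(pka$side[["K"]], counts[["K"]]),
              rep(pka$side[["R"]], counts[["R"]]),
              rep(pka$side[["H"]], counts[["H"]]))
  neg_pk <- c(pka$cterm,
              rep(pka$side[["D"]], counts[["D"]]),
              rep(pka$side[["E"]], counts[["E"]]),
              rep(pka$side[["C"]], counts[["C"]]),
              rep(pka$side[["Y"]], counts[["Y"]]))
  sum(1 / (1 + 10^(pH - pos_pk))) - sum(1 / (1 + 10^(neg_pk - pH)))
}

#' Theoretical isoelectric point
#'
#' Bisection on the Henderson-Hasselbalch net charge with the
#' [pka_bjellqvist()] pKa set, to a tolerance of 0.001 pH.
#'
#' @param sequence character vector of amino-acid sequences.
#' @param pka pKa set, see [pka_bjellqvist()].
#' @param tol bisection tolerance in pH units.
#' @return numeric vector of pI values.
#' @export
isoelectric_point <- function(sequence, pka = pka_bjellqvist(), tol = 0.001) {
  assert_aa(sequence)
  vapply(toupper(sequence), function(s) {
    ch <- seq_to_chars(s)
    counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(a) sum(ch == a), integer(1))
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (peptide_charge(counts, ch[1], pka, mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan for the LRR consensus motif
#'
#' Slides a 24-residue window over the sequence and reports every (possibly
#' overlapping) start position matching the leucine-rich-repeat consensus
#' `L--L--L--L-L--N-L--G-IP-`: positions 1, 4, 7, 10, 12 and 17 must be Leu
#' or Ile, position 15 Asn, position 20 Gly, position 22 Val or Ile,
#' position 23 Pro; the remaining positions are free.
#'
#' @param sequence a single amino-acid sequence.
#' @return integer vector of 1-based match start positions.
#' @export
scan_lrr_consensus <- function(sequence) {
  assert_aa(sequence)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 24) return(integer(0))
  ch <- seq_to_chars(s)
  starts <- integer(0)
  li <- c(1, 4, 7, 10, 12, 17)
  for (p in 1:(n - 23)) {
    w <- ch[p:(p + 23)]
    if (all(w[li] %in% c("L", "I")) && w[15] == "N" && w[20] == "G" &&
        w[22] %in% c("V", "I") && w[23] == "P") {
      starts <- c(starts, p)
    }
  }
  starts
}

# Kyte-Doolittle hydropathy scale; X scores 0.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

#' Hydropathy-based transmembrane segment scan
#'
#' A stand-in predictor for when no dedicated transmembrane-call table is
#' supplied: the Kyte-Doolittle hydropathy mean over a sliding window is
#' thresholded and maximal runs of above-cutoff windows are merged into
#' segments (reported as full window extents, 1-based inclusive).
#'
#' @param proteins a tibble with columns `id` and `sequence`.
#' @param window sliding window width in residues.
#' @param cutoff mean-hydropathy threshold.
#' @return a TM-call tibble with columns `protein_id`, `start`, `end`.
#' @export
hydropathy_tm_scan <- function(proteins, window = 19, cutoff = 1.6) {
  assert_aa(proteins$sequence)
  rows <- lapply(seq_len(nrow(proteins)), function(k) {
    ch <- seq_to_chars(proteins$sequence[k])
    n <- length(ch)
    if (n < window) return(NULL)
    h <- KD_SCALE[ch]
    means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 1))
    starts_above <- which(!is.na(means) & means > cutoff) - window + 1L
    if (length(starts_above) == 0) return(NULL)
    runs <- split(starts_above, cumsum(c(1L, diff(starts_above) != 1L)))
    bind_rows(lapply(runs, function(r) {
      tibble(protein_id = proteins$id[k],
             start = as.integer(min(r)),
             end = as.integer(max(r) + window - 1L))
    }))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) tibble(protein_id = character(), start = integer(),
                             end = integer()) else out
}

#' Domain architecture token string
#'
#' Orders per-protein evidence (signal peptide, malectin-like, LRR,
#' transmembrane, kinase) by start coordinate into a token list over
#' `{SP, Malectin, LRR, TM, KD}`. Runs of consecutive LRR hits collapse to
#' a single `LRR` token.
#'
#' @param protein_ids character vector of protein ids.
#' @param domain_hits domain-hit tibble.
#' @param tm_calls TM-call tibble.
#' @param sp_calls optional SP-call tibble.
#' @param collapse_lrr collapse consecutive LRR tokens.
#' @return a tibble with `protein_id`, `architecture` (string like
#'   `"SP-Malectin-LRR-TM-KD"`) and `tokens` (list-column).
#' @export
architecture_string <- function(protein_ids, domain_hits, tm_calls,
                                sp_calls = NULL, collapse_lrr = TRUE) {
  rows <- lapply(protein_ids, function(p) {
    segs <- tibble(token = character(), start = integer())
    dh <- domain_hits[domain_hits$protein_id == p, ]
    if (nrow(dh) > 0) {
      tok <- c(LRR = "LRR", kinase = "KD", malectin = "Malectin")[dh$category]
      keep <- !is.na(tok)
      segs <- bind_rows(segs, tibble(token = tok[keep], start = dh$env_start[keep]))
    }
    tm <- tm_calls[tm_calls$protein_id == p, ]
    if (nrow(tm) > 0) segs <- bind_rows(segs, tibble(token = "TM", start = tm$start))
    if (!is.null(sp_calls)) {
      sp <- sp_calls[sp_calls$protein_id == p, ]
      if (nrow(sp) > 0) segs <- bind_rows(segs, tibble(token = "SP", start = sp$start))
    }
    segs <- segs[order(segs$start), ]
    toks <- segs$token
    if (collapse_lrr && length(toks) > 1) {
      toks <- toks[c(TRUE, !(toks[-1] == "LRR" & toks[-length(toks)] == "LRR"))]
    }
    tibble(protein_id = p, architecture = paste(toks, collapse = "-"),
           tokens = list(toks))
  })
  bind_rows(rows)
}

#' Classify malectin-domain position
#'
#' A malectin-like domain is N-terminal iff it starts before the first LRR
#' hit of the same protein (proteins without LRR hits count as N-terminal).
#'
#' @param domain_hits domain-hit tibble.
#' @return a tibble with `protein_id`, `has_malectin`, `malectin_nterm`.
#' @export
malectin_position <- function(domain_hits) {
  ids <- unique(domain_hits$protein_id)
  rows <- lapply(ids, function(p) {
    dh <- domain_hits[domain_hits$protein_id == p, ]
    mal <- dh[dh$category == "malectin", ]
    if (nrow(mal) == 0) {
      return(tibble(protein_id = p, has_malectin = FALSE, malectin_nterm = NA))
    }
    lrr <- dh[dh$category == "LRR", ]
    nterm <- nrow(lrr) == 0 || min(mal$env_start) < min(lrr$env_start)
    tibble(protein_id = p, has_malectin = TRUE, malectin_nterm = nterm)
  })
  bind_rows(rows)
}

#' Per-protein property table
#'
#' @param proteins a tibble with columns `id`, `sequence`.
#' @param domain_hits domain-hit tibble (for LRR domain counts).
#' @param tm_calls TM-call tibble.
#' @param sp_calls optional SP-call tibble.
#' @return a tibble with `protein_id`, `length_aa`, `mol_weight_da`, `pI`,
#'   `n_lrr_domains` (LRR-category hits), `n_lrr_consensus` (consensus-scan
#'   matches) and `architecture`.
#' @export
protein_properties <- function(proteins, domain_hits, tm_calls,
                               sp_calls = NULL) {
  arch <- architecture_string(proteins$id, domain_hits, tm_calls, sp_calls)
  tibble(
    protein_id = proteins$id,
    length_aa = nchar(proteins$sequence),
    mol_weight_da = molecular_weight(proteins$sequence),
    pI = isoelectric_point(proteins$sequence),
    n_lrr_domains = vapply(proteins$id, function(p) {
      sum(domain_hits$protein_id == p & domain_hits$category == "LRR")
    }, integer(1)),
    n_lrr_consensus = vapply(proteins$sequence,
                             function(s) length(scan_lrr_consensus(s)), integer(1))
  ) |> left_join(arch[, c("protein_id", "architecture")], by = "protein_id")
}

#' Subclade-level molecular property summary
#'
#' Census-table style ranges (min-max) of gene size, protein size, pI,
#' molecular weight and LRR count per subclade.
#'
#' @param properties output of [protein_properties()].
#' @param assignments a data frame with columns `protein_id` (or
#'   `query_id`) and `subclade`.
#' @param gene_lengths optional data frame with `protein_id` and
#'   `gene_length` (bp) for the gene-size range.
#' @return a tibble with one row per subclade: `subclade`, `n_genes`, and
#'   min/max columns for each property.
#' @export
summarize_subclades <- function(properties, assignments, gene_lengths = NULL) {
  asg <- assignments
  if ("query_id" %in% names(asg) && !"protein_id" %in% names(asg)) {
    asg <- rename(asg, protein_id = "query_id")
  }
  d <- left_join(asg[, c("protein_id", "subclade")], properties, by = "protein_id")
  if (!is.null(gene_lengths)) {
    d <- left_join(d, gene_lengths, by = "protein_id")
  } else {
    d$gene_length <- NA_integer_
  }
  d |>
    group_by(.data$subclade) |>
    summarise(
      n_genes = n(),
      gene_size_kb_min = min(.data$gene_length) / 1000,
      gene_size_kb_max = max(.data$gene_length) / 1000,
      protein_aa_min = min(.data$length_aa),
      protein_aa_max = max(.data$length_aa),
      pI_min = min(.data$pI), pI_max = max(.data$pI),
      mw_kda_min = min(.data$mol_weight_da) / 1000,
      mw_kda_max = max(.data$mol_weight_da) / 1000,
      n_lrr_min = min(.data$n_lrr_domains),
      n_lrr_max = max(.data$n_lrr_domains),
      .groups = "drop"
    )
}
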