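# Shared internal helpers.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published gene-family census tables
#' conventionally round half up (e.g. 128/543 prints as 23.6%). Used for all
#' percentage columns in reports.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(100 * 128 / 543, 1) # 23.6
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate an amino-acid sequence vector (20 standard letters + X).
assert_aa <- function(sequence, what = "sequence") {
  if (length(sequence) == 0) stop(what, " must be non-empty", call. = FALSE)
  if (any(is.na(sequence)) || any(nchar(sequence) < 1)) {
    stop(what, " contains empty or missing entries", call. = FALSE)
  }
  bad <- grepl(paste0("[^", paste(c(AA20, "X"), collapse = ""), "]"),
               toupper(sequence))
  if (any(bad)) {
    stop(what, " contains non-amino-acid characters in entry ",
         which(bad)[1], call. = FALSE)
  }
  invisible(TRUE)
}

# Fan one user seed out to reproducible per-component sub-seeds, so adding a
# pipeline stage never perturbs the random draws of earlier stages.
component_seed <- function(seed, component) {
  offsets <- c(proteome = 11L, genome = 23L, reference = 37L, evidence = 47L,
               counts = 59L, qpcr = 67L, physiology = 79L, bootstrap = 97L,
               noise = 103L)
  if (!component %in% names(offsets)) stop("unknown seed component: ", component)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[component]]
}

# BLOSUM62 substitution matrix (from Biostrings' distributed data),
# subset and cached for the 20 standard residues plus X.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
      cache <<- m
    }
    cache
  }
})

# Split sequences into character matrices / integer codes.
seq_to_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]
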