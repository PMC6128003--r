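# Salt-stress physiology: chlorophyll content and electrolyte leakage.

#' Chlorophyll content from acetone-extract absorbance
#'
#' Chlorophyll a, b and total (mg per g fresh weight) from absorbance at
#' 663 and 645 nm, extract volume V (ml) and fresh weight W (mg):
#'
#' \deqn{chl_a = (12.7 A_{663} - 2.69 A_{645}) V / W / 1000}
#' \deqn{chl_b = (22.9 A_{645} - 4.86 A_{663}) V / W / 1000}
#'
#' Two conventions exist for the total. `as_printed` (the default) uses
#' \eqn{(8.02 A_{663} - 20.20 A_{645}) V / W / 1000}, reproducing a widely
#' circulated transcription of Arnon's equations verbatim;
#' `arnon_corrected` flips the second sign to
#' \eqn{(8.02 A_{663} + 20.20 A_{645})}, which is internally consistent
#' with chl_a + chl_b (the two differ only in the 7.84 vs 8.02 coefficient
#' residual, about 0.2%). Both are exposed because the printed form
#' contradicts the sum of its own a and b equations.
#'
#' @param a663,a645 absorbance readings (non-negative).
#' @param v extract volume in ml.
#' @param w fresh weight in mg.
#' @param mode `"as_printed"` or `"arnon_corrected"`.
#' @return a tibble with columns `chl_a`, `chl_b`, `chl_total` (mg/g).
#' @export
chlorophyll <- function(a663, a645, v, w, mode = c("as_printed", "arnon_corrected")) {
  mode <- match.arg(mode)
  if (any(a663 < 0) || any(a645 < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (any(v <= 0) || any(w <= 0)) stop("volume and weight must be > 0", call. = FALSE)
  f <- v / w / 1000
  chl_a <- (12.7 * a663 - 2.69 * a645) * f
  chl_b <- (22.9 * a645 - 4.86 * a663) * f
  chl_total <- if (mode == "as_printed") {
    (8.02 * a663 - 20.20 * a645) * f
  } else {
    (8.02 * a663 + 20.20 * a645) * f
  }
  tibble(chl_a = chl_a, chl_b = chl_b, chl_total = chl_total)
}

#' Electrolyte leakage percentage
#'
#' EL1 is the conductivity of the leaked ions after incubation, EL2 the
#' total releasable conductivity after boiling; leakage is reported as
#' 100 * EL1 / EL2.
#'
#' @param el1,el2 conductivities (same units; `0 <= el1 <= el2`, `el2 > 0`).
#' @return numeric vector of leakage percentages.
#' @export
electrolyte_leakage <- function(el1, el2) {
  if (any(el2 <= 0)) stop("EL2 must be > 0", call. = FALSE)
  if (any(el1 < 0) || any(el1 > el2)) {
    stop("EL1 must satisfy 0 <= EL1 <= EL2", call. = FALSE)
  }
  100 * el1 / el2
}

#' Group-wise physiology report
#'
#' Computes chlorophyll content and electrolyte leakage per sample, then
#' group means, standard deviations and t-test star annotations for the
#' silenced-vs-control contrast.
#'
#' @param measurements a tibble with columns `sample_id`, `group`
#'   (`control`/`silenced`), `a663`, `a645`, `v`, `w`, `el1`, `el2`.
#' @param chlorophyll_mode passed to [chlorophyll()].
#' @param var_equal passed to [ttest_annotate()].
#' @return a tibble with one row per measured trait (`chl_total`,
#'   `el_percent`): group means and sds, `t`, `p`, `stars`.
#' @export
physiology_report <- function(measurements,
                              chlorophyll_mode = "as_printed",
                              var_equal = TRUE) {
  need <- c("sample_id", "group", "a663", "a645", "v", "w", "el1", "el2")
  stopifnot(all(need %in% names(measurements)))
  chl <- chlorophyll(measurements$a663, measurements$a645,
                     measurements$v, measurements$w, mode = chlorophyll_mode)
  d <- bind_cols(measurements[, c("sample_id", "group")], chl)
  d$el_percent <- electrolyte_leakage(measurements$el1, measurements$el2)
  traits <- c("chl_total", "el_percent")
  rows <- lapply(traits, function(tr) {
    a <- d[[tr]][d$group == "control"]
    b <- d[[tr]][d$group == "silenced"]
    tt <- ttest_annotate(a, b, var_equal = var_equal)
    tibble(trait = tr,
           control_mean = mean(a), control_sd = sd(a),
           silenced_mean = mean(b), silenced_sd = sd(b),
           t = tt$t, p = tt$p, stars = tt$stars)
  })
  bind_rows(rows)
}
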