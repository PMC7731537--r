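#' Natural isotope abundance table
#'
#' Per-element natural-abundance mass-offset distributions used when building
#' natural-abundance correction matrices. Offsets are integer mass units above
#' the lightest isotope; abundances for each element sum to 1. Defaults are
#' the IUPAC representative values for C, H, N, O, Si and S, which cover the
#' TBDMS/ethoxime-derivatized fragments monitored by GC-MS SIM.
#'
#' @param overrides optional named list replacing the distribution of one or
#'   more elements; each entry is a numeric vector of abundances whose names
#'   are integer mass offsets (e.g. `list(C = c("0" = 0.99, "1" = 0.01))`).
#' @return a named list of numeric abundance vectors indexed by mass offset
#'   (position 1 = offset 0), one per element, with class `isotope_table`.
#' @examples
#' tab <- isotope_table()
#' tab$C   # 12C, 13C
#' @export
isotope_table <- function(overrides = NULL) {
  tab <- list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
  )
  if (!is.null(overrides)) {
    for (el in names(overrides)) {
      v <- overrides[[el]]
      if (!is.null(names(v))) {
        off <- as.integer(names(v))
        full <- numeric(max(off) + 1L)
        full[off + 1L] <- as.numeric(v)
        v <- full
      }
      tab[[el]] <- as.numeric(v)
    }
  }
  for (el in names(tab)) {
    s <- sum(tab[[el]])
    if (abs(s - 1) > 1e-9)
      stop("isotope abundances for element '", el, "' sum to ", s, ", not 1")
    if (any(tab[[el]] < 0))
      stop("negative abundance for element '", el, "'")
  }
  structure(tab, class = "isotope_table")
}

# Convolve two integer-offset mass distributions (index 1 = offset 0).
convolve_dist <- function(a, b) {
  if (length(a) == 0L) return(b)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] != 0)
      out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# Mass-offset distribution of `count` atoms of one element at natural
# abundance, by repeated convolution of the single-atom distribution.
element_dist <- function(single, count) {
  out <- 1
  if (count <= 0L) return(out)
  for (k in seq_len(count)) out <- convolve_dist(out, single)
  out
}

# Natural-abundance mass-offset distribution of a whole composition
# (named counts, e.g. c(C = 19, H = 42, N = 1, O = 4, Si = 3)).
composition_dist <- function(composition, isotopes, truncate_at = NULL) {
  out <- 1
  for (el in names(composition)) {
    cnt <- as.integer(composition[[el]])
    if (cnt == 0L) next
    if (is.null(isotopes[[el]]))
      stop("element '", el, "' missing from isotope table")
    out <- convolve_dist(out, element_dist(isotopes[[el]], cnt))
    if (!is.null(truncate_at) && length(out) > truncate_at + 64L)
      out <- out[seq_len(truncate_at + 64L)]
  }
  out
}
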