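#' Fragment specification for a monitored GC-MS SIM ion
#'
#' @param metabolite metabolite name.
#' @param backbone_carbons number of biological backbone carbons that can
#'   carry tracer label.
#' @param composition named integer vector of elemental counts of the whole
#'   derivatized fragment (C, H, N, O, Si, S); `C` must be at least
#'   `backbone_carbons` since derivatization adds carbon.
#' @param m0_mz nominal m/z of the M0 SIM channel (stored, never computed).
#' @return object of class `fragment_spec`.
#' @export
fragment_spec <- function(metabolite, backbone_carbons, composition, m0_mz) {
  backbone_carbons <- as.integer(backbone_carbons)
  composition <- composition[composition > 0]
  if (is.null(composition[["C"]]) || composition[["C"]] < backbone_carbons)
    stop("fragment carbon count must be >= backbone_carbons")
  if (m0_mz <= 0) stop("m0_mz must be positive")
  structure(list(metabolite = metabolite,
                 backbone_carbons = backbone_carbons,
                 composition = composition, m0_mz = m0_mz),
            class = "fragment_spec")
}

#' Read a fragment catalog
#'
#' Loads fragment specifications (elemental composition, backbone carbons,
#' SIM M0 m/z) from a CSV catalog. The packaged default describes the
#' TBDMS/ethoxime \[M-57\]+ fragments of the TCA-cycle panel; it is an
#' example configuration — users monitoring different derivatives supply
#' their own catalog in the same format.
#'
#' @param path catalog CSV (columns metabolite, backbone_carbons, C, H, N,
#'   O, Si, S, m0_mz; `#` comment lines allowed); packaged catalog when
#'   omitted.
#' @return named list of [fragment_spec()] objects.
#' @export
read_fragment_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fragment_catalog.csv",
                        package = "glntrace")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  frags <- lapply(seq_len(nrow(df)), function(i) {
    comp <- c(C = df$C[i], H = df$H[i], N = df$N[i], O = df$O[i],
              Si = df$Si[i], S = df$S[i])
    fragment_spec(df$metabolite[i], df$backbone_carbons[i], comp,
                  df$m0_mz[i])
  })
  setNames(frags, df$metabolite)
}

#' Build a natural-abundance correction matrix
#'
#' Column `j` (j = 0..n backbone labels) is the theoretical measured SIM
#' spectrum, M0..M(n+2), of a fragment carrying exactly `j` tracer-labeled
#' backbone carbons: the convolution of (a) the natural-abundance mass
#' distributions of every atom except the `j` labeled carbons and (b) the
#' binomial isotopic-purity distribution of those `j` carbons, truncated to
#' the monitored channels. Columns sum to slightly less than 1 because mass
#' isotopomers beyond M(n+2) fall outside the SIM window.
#'
#' @param frag a [fragment_spec()].
#' @param isotopes an [isotope_table()].
#' @param tracer_purity probability that a nominally labeled carbon is 13C
#'   (0 < purity <= 1); commercial tracers are typically 0.99.
#' @return `(n+3) x (n+1)` matrix with rows M0..M(n+2) and columns L0..Ln.
#' @examples
#' frag <- read_fragment_catalog()[["succinate"]]
#' M <- build_correction_matrix(frag, isotope_table())
#' colSums(M)
#' @export
build_correction_matrix <- function(frag, isotopes = isotope_table(),
                                    tracer_purity = 0.99) {
  stopifnot(inherits(frag, "fragment_spec"))
  if (tracer_purity <= 0 || tracer_purity > 1)
    stop("tracer_purity must lie in (0, 1]")
  n <- frag$backbone_carbons
  nrows <- n + 3L
  M <- matrix(0, nrow = nrows, ncol = n + 1L,
              dimnames = list(paste0("M", 0:(n + 2L)),
                              paste0("L", 0:n)))
  for (j in 0:n) {
    comp <- frag$composition
    comp[["C"]] <- comp[["C"]] - j
    nat <- composition_dist(comp, isotopes, truncate_at = nrows)
    # purity distribution of the j labeled carbons: offsets j-k for the k
    # impure (12C) positions, then the fixed shift of the pure 13C atoms
    pur <- element_dist(c(1 - tracer_purity, tracer_purity), j)
    col <- convolve_dist(nat, pur)
    col <- col[seq_len(min(length(col), nrows))]
    M[seq_along(col), j + 1L] <- col
  }
  M
}

#' Correct a raw MID for natural abundance
#'
#' Solves the linear system relating the measured SIM channel fractions to
#' the underlying backbone labeling by nonnegativity-constrained least
#' squares, then truncates to M0..Mn and renormalizes. Nonnegative least
#' squares is used instead of direct inversion so that noisy measurements
#' cannot produce negative isotopologue fractions. The result is invariant
#' to uniform scaling of the raw intensities, so raw ion counts can be
#' passed directly.
#'
#' @param raw numeric vector of raw channel intensities or fractions,
#'   length `n + 3` (M0..M(n+2)) matching the matrix rows.
#' @param matrix a [build_correction_matrix()] result.
#' @return corrected MID, length `n + 1`, nonnegative, summing to 1, with
#'   attribute `kind = "corrected"`.
#' @export
correct_mid <- function(raw, matrix) {
  raw <- as.numeric(raw)
  if (length(raw) != nrow(matrix))
    stop("raw vector length ", length(raw), " does not match the ",
         nrow(matrix), " matrix rows")
  if (any(!is.finite(raw))) stop("raw intensities must be finite")
  tot <- sum(raw)
  if (tot <= 0) stop("raw intensity vector is all zero")
  if (kappa(matrix) > 1e10)
    stop("correction matrix is ill-conditioned; check the fragment ",
         "composition")
  x <- pracma::lsqnonneg(matrix, raw / tot)$x
  if (sum(x) <= 0) stop("correction produced an empty distribution")
  x <- x / sum(x)
  structure(x, names = paste0("M", seq_along(x) - 1L), kind = "corrected")
}

#' Mole percent enrichment of backbone carbons
#'
#' Summarizes a corrected MID as the carbon-weighted average fraction of
#' labeled backbone carbons, `sum(i * Mi) / n`, the precursor-product
#' quantity used for enrichment normalization. The simpler "fraction of
#' molecules carrying any label" is available as [fraction_labeled()].
#'
#' @param corrected corrected MID (M0..Mn), summing to 1.
#' @return scalar in \[0, 1\].
#' @examples
#' mole_percent_enrichment(c(0.98, 0, 0, 0, 0.02, 0, 0))  # citrate, M4
#' @export
mole_percent_enrichment <- function(corrected) {
  corrected <- as.numeric(corrected)
  if (abs(sum(corrected) - 1) > 1e-6)
    stop("corrected MID must sum to 1")
  n <- length(corrected) - 1L
  sum((0:n) * corrected) / n
}

#' Fraction of molecules carrying at least one tracer carbon
#'
#' @inheritParams mole_percent_enrichment
#' @return scalar in \[0, 1\]: `1 - M0`.
#' @export
fraction_labeled <- function(corrected) {
  corrected <- as.numeric(corrected)
  if (abs(sum(corrected) - 1) > 1e-6)
    stop("corrected MID must sum to 1")
  1 - corrected[1L]
}

#' Correct a tidy SIM intensity table
#'
#' Applies [correct_mid()] and [mole_percent_enrichment()] per sample and
#' metabolite to a tidy intensity table.
#'
#' @param intensities data.frame with columns `sample_id`, `metabolite`,
#'   `channel` ("M0".."Mn+2") and `intensity`.
#' @param fragments fragment catalog from [read_fragment_catalog()].
#' @param isotopes an [isotope_table()].
#' @param tracer_purity see [build_correction_matrix()].
#' @return list with `mids` (tidy corrected MID table: sample_id,
#'   metabolite, channel, fraction) and `mpe` (sample_id, metabolite, mpe,
#'   fraction_labeled).
#' @export
correct_intensity_table <- function(intensities, fragments,
                                    isotopes = isotope_table(),
                                    tracer_purity = 0.99) {
  need <- c("sample_id", "metabolite", "channel", "intensity")
  miss <- setdiff(need, names(intensities))
  if (length(miss))
    stop("intensity table lacks column(s): ", paste(miss, collapse = ", "))
  mats <- lapply(fragments, build_correction_matrix, isotopes = isotopes,
                 tracer_purity = tracer_purity)
  mid_rows <- list()
  mpe_rows <- list()
  for (sm in split(intensities,
                   list(intensities$sample_id, intensities$metabolite),
                   drop = TRUE)) {
    met <- sm$metabolite[1L]
    if (is.null(fragments[[met]]))
      stop("metabolite '", met, "' not in the fragment catalog")
    n <- fragments[[met]]$backbone_carbons
    chan <- paste0("M", 0:(n + 2L))
    idx <- match(chan, sm$channel)
    if (anyNA(idx))
      stop("sample '", sm$sample_id[1L], "', metabolite '", met,
           "': missing channel(s) ", paste(chan[is.na(idx)], collapse = ","))
    corr <- correct_mid(sm$intensity[idx], mats[[met]])
    mid_rows[[length(mid_rows) + 1L]] <- data.frame(
      sample_id = sm$sample_id[1L], metabolite = met,
      channel = names(corr), fraction = as.numeric(corr))
    mpe_rows[[length(mpe_rows) + 1L]] <- data.frame(
      sample_id = sm$sample_id[1L], metabolite = met,
      mpe = mole_percent_enrichment(corr),
      fraction_labeled = fraction_labeled(corr))
  }
  list(mids = do.call(rbind, mid_rows), mpe = do.call(rbind, mpe_rows))
}
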