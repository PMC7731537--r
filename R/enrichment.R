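#' Precursor-normalized relative enrichment
#'
#' Expresses each metabolite's mole percent enrichment relative to the
#' steady-state plasma glutamine enrichment of the same subject, the
#' precursor-product normalization that makes tracer dose and plateau level
#' cancel out of between-subject comparisons.
#'
#' @param mpe data.frame with columns `sample_id`, `metabolite`, `mpe`.
#' @param plasma_enrichment data.frame with columns `sample_id` (or
#'   `subject_id`) and `enrichment` (plasma glutamine tracer fraction); one
#'   row per sample.
#' @param by name of the key column joining the two tables
#'   (default `"sample_id"`).
#' @return data.frame `sample_id`, `metabolite`, `mpe`,
#'   `plasma_enrichment`, `relative_enrichment`.
#' @export
normalize_to_precursor <- function(mpe, plasma_enrichment,
                                   by = "sample_id") {
  stopifnot(all(c(by, "metabolite", "mpe") %in% c(names(mpe), "metabolite",
                                                  "mpe")))
  if (!all(c(by, "enrichment") %in% names(plasma_enrichment)))
    stop("plasma_enrichment needs columns '", by, "' and 'enrichment'")
  idx <- match(mpe[[by]], plasma_enrichment[[by]])
  if (anyNA(idx)) {
    missing_ids <- unique(mpe[[by]][is.na(idx)])
    stop("no plasma enrichment for: ", paste(missing_ids, collapse = ", "))
  }
  e <- plasma_enrichment$enrichment[idx]
  bad <- !is.finite(e) | e <= 0
  if (any(bad))
    stop("zero or missing precursor enrichment for: ",
         paste(unique(mpe[[by]][bad]), collapse = ", "))
  out <- mpe[c(by, "metabolite", "mpe")]
  out$plasma_enrichment <- e
  out$relative_enrichment <- out$mpe / e
  out
}

#' CD138+/CD138- fractional enrichment ratio
#'
#' Per subject and metabolite, the ratio of relative enrichment in sorted
#' CD138+ plasma cells over the paired CD138- mononuclear cells; a ratio
#' above 1 means the metabolite is more tracer-labeled in the plasma-cell
#' fraction. Pairs with a zero denominator are returned flagged
#' (`ratio = NA`, `flagged = TRUE`) and should be excluded from group tests.
#'
#' @param pos,neg numeric relative enrichments for the CD138+ and CD138-
#'   fractions of the same subjects/metabolites, aligned.
#' @return data.frame `ratio`, `flagged`.
#' @export
fractional_ratio <- function(pos, neg) {
  if (length(pos) != length(neg))
    stop("pos and neg must be aligned vectors of equal length")
  flagged <- !is.finite(neg) | neg == 0
  ratio <- ifelse(flagged, NA_real_, pos / neg)
  if (any(flagged))
    warning(sum(flagged), " pair(s) with zero denominator flagged and ",
            "excluded from summaries")
  data.frame(ratio = ratio, flagged = flagged)
}

#' Paired two-sided t test for the CD138+ vs CD138- contrast
#'
#' Thin wrapper around [stats::t.test()] with the degenerate identical-pair
#' case returned as `t = 0, p = 1` rather than an error. Significance at
#' 0.05 is the study convention but is reported, never used to filter.
#'
#' @param values_pos,values_neg paired numeric vectors (same subjects, same
#'   order).
#' @return list `mean_difference`, `t`, `df`, `p`, `n`.
#' @export
paired_group_test <- function(values_pos, values_neg) {
  if (length(values_pos) != length(values_neg))
    stop("paired vectors must have equal length")
  keep <- is.finite(values_pos) & is.finite(values_neg)
  values_pos <- values_pos[keep]; values_neg <- values_neg[keep]
  n <- length(values_pos)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- values_pos - values_neg
  if (sd(d) == 0) {
    return(list(mean_difference = mean(d), t = 0, df = n - 1L,
                p = if (mean(d) == 0) 1 else NA_real_, n = n))
  }
  tt <- t.test(values_pos, values_neg, paired = TRUE)
  list(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, n = n)
}

#' Mann-Whitney U test for unpaired group comparisons
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test via
#' [stats::wilcox.test()]: exact p for small samples (both arms <= 8,
#' no ties), normal approximation with tie correction otherwise. Used for
#' the non-normally distributed absolute metabolite concentrations.
#'
#' @param values_a,values_b numeric vectors, each of length >= 3.
#' @return list `U`, `p`, `n_a`, `n_b`.
#' @export
unpaired_group_test <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a < 3L || n_b < 3L) stop("need at least 3 values per group")
  if (length(unique(c(values_a, values_b))) == 1L)
    return(list(U = n_a * n_b / 2, p = 1, n_a = n_a, n_b = n_b))
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  use_exact <- n_a <= 8L && n_b <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = use_exact, correct = !use_exact))
  list(U = unname(wt$statistic), p = wt$p.value, n_a = n_a, n_b = n_b)
}

#' Ordinary least-squares correlation
#'
#' OLS line plus Pearson correlation, used for concentration-vs-tumor-burden
#' plots and cross-platform concordance.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list `slope`, `intercept`, `r`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete (x, y) pairs")
  if (sd(x) == 0) stop("x has zero variance; no line can be fitted")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r = cor(x, y), n = length(x))
}

#' Per-metabolite paired contrast table for a sorted-fraction experiment
#'
#' Runs the paired CD138+ vs CD138- contrast per metabolite on a relative
#' enrichment table, and summarizes per-subject fractional ratios by their
#' geometric mean (ratios are multiplicative). Enrichment summaries are
#' mean +/- SEM, the convention for these data. Subjects missing one
#' metabolite are dropped per metabolite, not listwise. An optional
#' Benjamini-Hochberg adjustment is off by default, mirroring per-metabolite
#' reporting.
#'
#' @param rel data.frame with columns `subject_id`, `fraction` (values
#'   `"CD138+"`/`"CD138-"`), `metabolite`, `relative_enrichment`.
#' @param adjust apply Benjamini-Hochberg across metabolites
#'   (default `FALSE`).
#' @return data.frame, one row per metabolite: means and SEMs per fraction,
#'   mean paired difference, t, p (and `p_adj` if requested), geometric
#'   mean ratio, n pairs.
#' @export
enrichment_contrast <- function(rel, adjust = FALSE) {
  need <- c("subject_id", "fraction", "metabolite", "relative_enrichment")
  if (!all(need %in% names(rel)))
    stop("rel needs columns: ", paste(need, collapse = ", "))
  sem <- function(v) sd(v) / sqrt(length(v))
  rows <- lapply(split(rel, rel$metabolite), function(m) {
    pos <- m[m$fraction == "CD138+", ]
    neg <- m[m$fraction == "CD138-", ]
    ids <- intersect(pos$subject_id, neg$subject_id)
    p <- pos$relative_enrichment[match(ids, pos$subject_id)]
    q <- neg$relative_enrichment[match(ids, neg$subject_id)]
    keep <- is.finite(p) & is.finite(q)
    p <- p[keep]; q <- q[keep]
    tt <- paired_group_test(p, q)
    rr <- fractional_ratio(p, q)
    ok <- !rr$flagged
    data.frame(metabolite = m$metabolite[1L], n = tt$n,
               mean_pos = mean(p), sem_pos = sem(p),
               mean_neg = mean(q), sem_neg = sem(q),
               mean_difference = tt$mean_difference, t = tt$t, p = tt$p,
               geomean_ratio = exp(mean(log(rr$ratio[ok & rr$ratio > 0]))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
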