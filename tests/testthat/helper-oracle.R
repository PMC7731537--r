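# Brute-force oracle for natural-abundance spectra: enumerates every
# isotope assignment over the individual atoms of a small fragment
# (feasible up to ~12 atoms) and accumulates probability by total mass
# offset. Independent of the convolution implementation in the package.
brute_force_spectrum <- function(composition, isotopes, n_labeled = 0L,
                                 purity = 1, max_offset = NULL) {
  dists <- list()
  for (el in names(composition)) {
    cnt <- composition[[el]]
    if (cnt > 0L)
      dists <- c(dists, rep(list(isotopes[[el]]), cnt))
  }
  if (n_labeled > 0L) {
    # labeled backbone carbons replace natural carbons: 13C w.p. purity
    dists <- c(dists, rep(list(c(1 - purity, purity)), n_labeled))
  }
  choices <- lapply(dists, function(d) seq_along(d) - 1L)
  grid <- do.call(expand.grid, choices)
  probs <- rep(1, nrow(grid))
  for (k in seq_along(dists))
    probs <- probs * dists[[k]][grid[[k]] + 1L]
  offsets <- rowSums(grid)
  out_len <- if (is.null(max_offset)) max(offsets) + 1L else max_offset + 1L
  spec <- numeric(out_len)
  for (i in seq_along(probs)) {
    o <- offsets[i] + 1L
    if (o <= out_len) spec[o] <- spec[o] + probs[i]
  }
  spec
}

# Random valid MID (nonnegative, sums to 1) of length n + 1.
random_mid <- function(n) {
  v <- runif(n + 1L)
  v / sum(v)
}
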