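#' Load carbon atom maps for the tracer pathway
#'
#' Atom maps encode, reaction by reaction, where each backbone carbon of a
#' product comes from. The packaged default describes glutamine anaplerosis
#' through the first oxidative turn of the TCA cycle:
#' glutamine -> glutamate -> alpha-ketoglutarate -> (CO2 loss of C1) ->
#' succinate -> fumarate -> malate -> oxaloacetate -> aspartate and
#' citrate (condensation with unlabeled acetyl-CoA). Succinate and fumarate
#' are flagged symmetric: both molecular orientations are chemically
#' indistinguishable and are carried as equiprobable positional states.
#'
#' @param path path to a YAML atom-map file; the packaged TCA map is used
#'   when omitted. The format is documented in the shipped file
#'   (`system.file("extdata", "tca_atom_maps.yaml", package = "glntrace")`).
#' @return a list with elements `metabolites` (named integer backbone carbon
#'   counts), `reactions`, `tracer_substrate` and `version`, of class
#'   `atom_maps`.
#' @export
load_atom_maps <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tca_atom_maps.yaml", package = "glntrace")
  cfg <- yaml::read_yaml(path)
  mets <- vapply(cfg$metabolites, as.integer, integer(1))
  rxns <- lapply(cfg$reactions, function(r) {
    m <- r$map
    dest <- as.integer(names(m))
    src <- vapply(m, as.integer, integer(1))
    n_to <- mets[[r$to]]
    if (!setequal(dest, seq_len(n_to)))
      stop("reaction '", r$name, "': every destination carbon of '", r$to,
           "' must have exactly one source")
    lost <- as.integer(unlist(r$lost))
    mapped <- src[src > 0L]
    if (length(intersect(lost, mapped)))
      stop("reaction '", r$name, "': lost carbons overlap mapped sources")
    list(name = r$name, from = r$from, to = r$to,
         map = setNames(src, dest)[as.character(seq_len(n_to))],
         lost = lost,
         symmetric_product = isTRUE(r$symmetric_product))
  })
  structure(list(metabolites = mets, reactions = rxns,
                 tracer_substrate = cfg$tracer_substrate,
                 version = cfg$version),
            class = "atom_maps")
}

#' Define a 13C-glutamine tracer
#'
#' @param name tracer name; the shortcuts `"u13c5"` (uniformly labeled
#'   \[13C5\]-glutamine) and `"5c13"` (\[5-13C\]-glutamine) fill in
#'   `labeled_positions` automatically.
#' @param labeled_positions integer carbon positions (1-based, glutamine
#'   C1-C5) carrying 13C.
#' @param enrichment tracer fraction of plasma glutamine in \[0, 1\]; the
#'   infusion protocols of interest reach plateaus of roughly 0.03-0.10.
#' @return an object of class `tracer_spec`.
#' @examples
#' tracer_spec("u13c5", enrichment = 0.05)
#' tracer_spec("custom", labeled_positions = c(1, 5), enrichment = 0.04)
#' @export
tracer_spec <- function(name, labeled_positions = NULL, enrichment = 0.05) {
  if (is.null(labeled_positions)) {
    labeled_positions <- switch(name,
      u13c5 = 1:5,
      "5c13" = 5L,
      stop("labeled_positions must be given for tracer '", name, "'"))
  }
  labeled_positions <- sort(unique(as.integer(labeled_positions)))
  if (length(labeled_positions) && (min(labeled_positions) < 1L ||
                                    max(labeled_positions) > 5L))
    stop("tracer positions out of range: glutamine has carbons 1-5")
  if (!is.numeric(enrichment) || enrichment < 0 || enrichment > 1)
    stop("enrichment must lie in [0, 1]")
  structure(list(name = name, labeled_positions = labeled_positions,
                 enrichment = enrichment),
            class = "tracer_spec")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat("<tracer_spec> ", x$name, ": 13C at glutamine C{",
      paste(x$labeled_positions, collapse = ","), "}, plasma enrichment ",
      x$enrichment, "\n", sep = "")
  invisible(x)
}

#' Track tracer carbons position by position through the pathway
#'
#' Propagates the labeled-carbon pattern of the tracer molecule through every
#' reaction of the atom map, keeping the full set of positional label states.
#' Symmetric products (succinate, fumarate) split each state into its two
#' equiprobable orientations; the nominal mass shift is invariant under the
#' flip even though individual positions differ.
#'
#' @param tracer a [tracer_spec()].
#' @param atom_maps an [load_atom_maps()] result (packaged TCA map by
#'   default).
#' @return a named list, one entry per metabolite, each a list of
#'   `(positions = logical vector, prob = numeric)` states summing to
#'   probability 1.
#' @seealso [propagate_first_turn()] for the mass-shift summary.
#' @export
propagate_label_states <- function(tracer, atom_maps = load_atom_maps()) {
  stopifnot(inherits(tracer, "tracer_spec"))
  mets <- atom_maps$metabolites
  sub <- atom_maps$tracer_substrate
  n0 <- mets[[sub]]
  start <- rep(FALSE, n0)
  start[tracer$labeled_positions] <- TRUE
  states <- list()
  states[[sub]] <- list(list(positions = start, prob = 1))
  for (r in atom_maps$reactions) {
    if (is.null(states[[r$from]]))
      stop("reaction '", r$name, "': substrate '", r$from,
           "' not yet reachable from the tracer")
    out <- list()
    for (st in states[[r$from]]) {
      dest <- vapply(r$map, function(s)
        if (s == 0L) FALSE else st$positions[s], logical(1))
      if (r$symmetric_product) {
        out[[length(out) + 1L]] <- list(positions = dest,
                                        prob = st$prob / 2)
        out[[length(out) + 1L]] <- list(positions = rev(dest),
                                        prob = st$prob / 2)
      } else {
        out[[length(out) + 1L]] <- list(positions = dest, prob = st$prob)
      }
    }
    # merge duplicate positional states
    keys <- vapply(out, function(s) paste(as.integer(s$positions),
                                          collapse = ""), character(1))
    merged <- lapply(unique(keys), function(k) {
      sel <- out[keys == k]
      list(positions = sel[[1L]]$positions,
           prob = sum(vapply(sel, `[[`, numeric(1), "prob")))
    })
    states[[r$to]] <- merged
  }
  states
}

#' First-turn nominal mass shifts of TCA intermediates
#'
#' For a given glutamine tracer, returns the number of tracer-derived 13C
#' atoms retained by each pathway metabolite after one oxidative turn — the
#' nominal isotopologue mass shift. Under uniformly labeled
#' \[13C5\]-glutamine the first turn yields m+5 glutamate and
#' alpha-ketoglutarate and m+4 succinate, fumarate, malate, aspartate and
#' citrate (C1 is released as CO2 at the alpha-ketoglutarate dehydrogenase
#' step and acetyl-CoA enters unlabeled); under \[5-13C\]-glutamine every
#' intermediate is m+1.
#'
#' @inheritParams propagate_label_states
#' @return named integer vector of mass shifts, one per pathway metabolite.
#' @examples
#' propagate_first_turn(tracer_spec("u13c5"))
#' propagate_first_turn(tracer_spec("5c13"))
#' @export
propagate_first_turn <- function(tracer, atom_maps = load_atom_maps()) {
  states <- propagate_label_states(tracer, atom_maps)
  vapply(states, function(sl) {
    shifts <- vapply(sl, function(s) sum(s$positions), integer(1))
    if (length(unique(shifts)) != 1L)
      stop("positional states of one metabolite disagree on mass shift")
    shifts[[1L]]
  }, integer(1))
}

#' Idealized first-turn mass isotopomer distribution
#'
#' Forward model of backbone labeling used by the synthetic-data generator:
#' a fraction `f` of the metabolite pool was made from plasma glutamine
#' (anaplerotic fraction), of which a fraction `tracer$enrichment` carried
#' the tracer, so the MID is a two-component mixture of M0 and the
#' single-turn shifted isotopologue.
#'
#' @inheritParams propagate_label_states
#' @param metabolite pathway metabolite name.
#' @param f anaplerotic fractional contribution in \[0, 1\].
#' @return numeric MID of length `n + 1` (M0..Mn, `n` backbone carbons),
#'   summing to 1, with attributes `metabolite` and `kind = "ideal"`.
#' @examples
#' ideal_mid(tracer_spec("u13c5", enrichment = 0.05), "malate", f = 0.5)
#' @export
ideal_mid <- function(tracer, metabolite, f,
                      atom_maps = load_atom_maps()) {
  if (!is.numeric(f) || f < 0 || f > 1)
    stop("anaplerotic fraction f must lie in [0, 1]")
  if (!metabolite %in% names(atom_maps$metabolites))
    stop("unknown metabolite '", metabolite, "'")
  n <- atom_maps$metabolites[[metabolite]]
  shift <- propagate_first_turn(tracer, atom_maps)[[metabolite]]
  mid <- numeric(n + 1L)
  labeled <- if (shift > 0L) f * tracer$enrichment else 0
  mid[1L] <- 1 - labeled
  mid[shift + 1L] <- mid[shift + 1L] + labeled
  structure(mid, names = paste0("M", 0:n),
            metabolite = metabolite, kind = "ideal")
}
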