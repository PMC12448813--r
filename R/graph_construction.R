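# Per-anchor layered graph construction: the local graph is seeded by
# first-order interaction partners, the non-local graph by high-order
# (two-hop bipartite) partners; both are expanded by directed multi-hop
# propagation through the knowledge graph with a per-layer triple budget.

check_anchor <- function(side, index, im) {
  side <- match.arg(side, c("microbe", "drug"))
  n <- if (side == "microbe") nrow(im$values) else ncol(im$values)
  index <- as.integer(index)
  if (index < 1L || index > n)
    stop_mdalink("anchor index ", index, " out of range for side ", side)
  list(side = side, index = index)
}

#' Direct interaction partners of an anchor node
#'
#' For a microbe, the drugs it is known to interact with; for a drug, the
#' microbes (symmetric treatment of the bipartite matrix).
#'
#' @param side `"microbe"` or `"drug"`.
#' @param index 1-based anchor index on that side.
#' @param im an [interaction_matrix()].
#' @return sorted integer vector of counterpart indices (possibly empty).
#' @export
direct_counterparts <- function(side, index, im) {
  a <- check_anchor(side, index, im)
  if (a$side == "microbe") unname(which(im$values[a$index, ] == 1L))
  else unname(which(im$values[, a$index] == 1L))
}

#' Layer-0 entity seeds of the local graph
#'
#' The aligned entities of the anchor's direct counterparts, plus the
#' anchor's own aligned entity (so isolated anchors still receive a layer-0
#' representation).
#'
#' @inheritParams direct_counterparts
#' @param alignment an [entity_alignment()].
#' @return sorted integer vector of entity indices.
#' @export
local_seed_entities <- function(side, index, im, alignment) {
  a <- check_anchor(side, index, im)
  cp <- direct_counterparts(side, index, im)
  if (a$side == "microbe") {
    own <- alignment$microbe_entity[a$index]
    cpe <- alignment$drug_entity[cp]
  } else {
    own <- alignment$drug_entity[a$index]
    cpe <- alignment$microbe_entity[cp]
  }
  sort(unique(c(own, cpe)))
}

#' Microbes sharing at least one interacting drug with the anchor microbe
#'
#' The anchor itself is excluded, so the set carries strictly
#' collaborative-filtering information.
#'
#' @param index anchor microbe index.
#' @param im an [interaction_matrix()].
#' @return sorted integer vector of microbe indices.
#' @export
similar_microbes <- function(index, im) {
  check_anchor("microbe", index, im)
  dr <- which(im$values[index, ] == 1L)
  if (length(dr) == 0L) return(integer(0))
  hits <- unname(which(rowSums(im$values[, dr, drop = FALSE]) > 0L))
  setdiff(hits, index)
}

#' High-order drug set of an anchor microbe
#'
#' Drugs interacted with by [similar_microbes()] of the anchor, minus the
#' anchor's own direct drugs: the strictly higher-order CF signal.
#'
#' @inheritParams similar_microbes
#' @return sorted integer vector of drug indices.
#' @export
high_order_drugs <- function(index, im) {
  ms <- similar_microbes(index, im)
  if (length(ms) == 0L) return(integer(0))
  dp <- unname(which(colSums(im$values[ms, , drop = FALSE]) > 0L))
  setdiff(dp, unname(which(im$values[index, ] == 1L)))
}

#' Drugs sharing at least one interacting microbe with the anchor drug
#' @param index anchor drug index.
#' @param im an [interaction_matrix()].
#' @return sorted integer vector of drug indices (anchor excluded).
#' @export
similar_drugs <- function(index, im) {
  check_anchor("drug", index, im)
  mi <- which(im$values[, index] == 1L)
  if (length(mi) == 0L) return(integer(0))
  hits <- unname(which(colSums(im$values[mi, , drop = FALSE]) > 0L))
  setdiff(hits, index)
}

#' High-order microbe set of an anchor drug (mirror of [high_order_drugs()])
#' @inheritParams similar_drugs
#' @return sorted integer vector of microbe indices.
#' @export
high_order_microbes <- function(index, im) {
  ds <- similar_drugs(index, im)
  if (length(ds) == 0L) return(integer(0))
  mp <- unname(which(rowSums(im$values[, ds, drop = FALSE]) > 0L))
  setdiff(mp, unname(which(im$values[, index] == 1L)))
}

#' Layer-0 entity seeds of the non-local graph
#'
#' Aligned entities of the anchor's high-order counterparts.  An empty
#' high-order set yields empty seeds (and thus empty non-local layers).
#'
#' @inheritParams local_seed_entities
#' @return sorted integer vector of entity indices (possibly empty).
#' @export
nonlocal_seed_entities <- function(side, index, im, alignment) {
  a <- check_anchor(side, index, im)
  if (a$side == "microbe") {
    sort(unique(alignment$drug_entity[high_order_drugs(a$index, im)]))
  } else {
    sort(unique(alignment$microbe_entity[high_order_microbes(a$index, im)]))
  }
}

#' Multi-hop propagation of an entity frontier through the knowledge graph
#'
#' Layer `l` collects every triple whose head lies in the layer `l-1` entity
#' set, uniformly subsampled without replacement to at most `budget` triples;
#' the layer-`l` entity set is the set of retained tails.  Propagation
#' follows directed head-to-tail edges only.  An empty frontier leaves that
#' layer and all deeper layers empty (recorded, not an error).
#'
#' @param kg a [knowledge_graph()].
#' @param seeds integer vector of layer-0 entity indices.
#' @param n_layers number of propagation layers `L` (>= 1).
#' @param budget per-layer triple budget (may be `Inf`).
#' @param seed optional integer seed for the subsampling; with `NULL` the
#'   current RNG stream is used.
#' @return list with `triples` (length-`L` list of triple matrices) and
#'   `entities` (length-`L+1` list of entity-index vectors, layer 0 first).
#' @export
propagate <- function(kg, seeds, n_layers, budget = Inf, seed = NULL) {
  stopifnot(n_layers >= 1L, budget >= 1)
  run <- function() {
    ents <- vector("list", n_layers + 1L)
    trs <- vector("list", n_layers)
    ents[[1L]] <- sort(unique(as.integer(seeds)))
    frontier <- ents[[1L]]
    for (l in seq_len(n_layers)) {
      cand <- unlist(kg$head_index[frontier], use.names = FALSE)
      if (length(cand) == 0L) {
        trs[[l]] <- matrix(integer(0), ncol = 3L)
        ents[[l + 1L]] <- integer(0)
        frontier <- integer(0)
        next
      }
      if (is.finite(budget) && length(cand) > budget)
        cand <- sort(sample(cand, budget))
      tri <- kg$triples[cand, , drop = FALSE]
      trs[[l]] <- tri
      frontier <- sort(unique(tri[, 3L]))
      ents[[l + 1L]] <- frontier
    }
    list(triples = trs, entities = ents)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Build layered local and non-local graphs for every anchor
#'
#' Deterministic given `seed`; anchors are processed microbes first, then
#' drugs, local context before non-local.
#'
#' @param kg a [knowledge_graph()].
#' @param im an [interaction_matrix()].
#' @param alignment an [entity_alignment()].
#' @param n_layers propagation depth `L`.
#' @param budget per-layer triple budget.
#' @param seed integer seed for layer subsampling.
#' @return object of class `layered_graphs`: lists `microbe` and `drug` of
#'   per-anchor records, each holding `local`/`nonlocal` propagation results
#'   and a `nonlocal_empty` flag.
#' @export
build_all_graphs <- function(kg, im, alignment, n_layers = 3L, budget = 64L,
                             seed = 1L) {
  build_side <- function(side, n) {
    lapply(seq_len(n), function(i) {
      loc <- propagate(kg, local_seed_entities(side, i, im, alignment),
                       n_layers, budget)
      nl <- propagate(kg, nonlocal_seed_entities(side, i, im, alignment),
                      n_layers, budget)
      list(local = loc, nonlocal = nl,
           nonlocal_empty = any(vapply(nl$entities, length, 1L) == 0L))
    })
  }
  withr::with_seed(seed, {
    res <- list(microbe = build_side("microbe", nrow(im$values)),
                drug = build_side("drug", ncol(im$values)),
                n_layers = n_layers, budget = budget, seed = seed)
  })
  class(res) <- "layered_graphs"
  res
}

# Flatten layered graphs into 0-based integer arrays for the C++ engine.
# Blocks are ordered anchor-major (microbes then drugs), context-major
# (local, nonlocal), layer 1..L; seed groups likewise.
pack_graphs <- function(graphs) {
  L <- graphs$n_layers
  anchors <- c(graphs$microbe, graphs$drug)
  bh <- br <- bt <- vector("list", length(anchors) * 2L * L)
  sd <- vector("list", length(anchors) * 2L)
  for (a in seq_along(anchors)) {
    for (c in 1:2) {
      prop <- if (c == 1L) anchors[[a]]$local else anchors[[a]]$nonlocal
      g <- (a - 1L) * 2L + c
      sd[[g]] <- prop$entities[[1L]] - 1L
      for (l in seq_len(L)) {
        b <- ((a - 1L) * 2L + (c - 1L)) * L + l
        tri <- prop$triples[[l]]
        bh[[b]] <- tri[, 1L] - 1L
        br[[b]] <- tri[, 2L] - 1L
        bt[[b]] <- tri[, 3L] - 1L
      }
    }
  }
  list(bh = as.integer(unlist(bh)), br = as.integer(unlist(br)),
       bt = as.integer(unlist(bt)),
       boff = c(0L, cumsum(vapply(bh, length, 1L))),
       sd = as.integer(unlist(sd)),
       soff = c(0L, cumsum(vapply(sd, length, 1L))),
       L = as.integer(L),
       n_anchor = length(anchors),
       n_microbe = length(graphs$microbe))
}

#' Dump layered graphs as JSON lines (debug aid)
#'
#' Writes one JSON object per anchor and context with the per-layer entity
#' sets and triple counts, using entity labels.
#'
#' @param graphs a `layered_graphs` object from [build_all_graphs()].
#' @param kg the companion [knowledge_graph()] (for labels).
#' @param path output path.
#' @export
write_graph_dump <- function(graphs, kg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(side, i, ctx_name, prop) {
    rec <- list(
      side = side, index = i, context = ctx_name,
      layers = lapply(prop$entities, function(e) kg$entity_labels[e]),
      triples_per_layer = vapply(prop$triples, nrow, 1L))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  for (i in seq_along(graphs$microbe)) {
    emit("microbe", i, "local", graphs$microbe[[i]]$local)
    emit("microbe", i, "nonlocal", graphs$microbe[[i]]$nonlocal)
  }
  for (i in seq_along(graphs$drug)) {
    emit("drug", i, "local", graphs$drug[[i]]$local)
    emit("drug", i, "nonlocal", graphs$drug[[i]]$nonlocal)
  }
  invisible(path)
}
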