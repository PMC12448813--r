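# Loading, validation and serialization of knowledge graphs, interaction
# matrices and node->entity alignments.  All public file formats carry string
# labels; dense integer indices (1-based) are an internal storage detail.

#' Construct a knowledge graph from an integer triple matrix
#'
#' @param triples integer matrix with columns (head, relation, tail), 1-based
#'   indices into `entity_labels` / `relation_labels`.  Duplicate rows are
#'   dropped.
#' @param entity_labels character vector of entity labels.
#' @param relation_labels character vector of relation labels.
#' @return An object of class `knowledge_graph` with fields `triples`,
#'   `entity_labels`, `relation_labels` and `head_index` (a list mapping each
#'   entity to the row indices of triples having it as head).
#' @export
knowledge_graph <- function(triples, entity_labels, relation_labels) {
  if (is.null(triples) || length(triples) == 0L) {
    triples <- matrix(integer(0), ncol = 3L)
  }
  triples <- matrix(as.integer(triples), ncol = 3L,
                    dimnames = list(NULL, c("head", "relation", "tail")))
  n_ent <- length(entity_labels)
  n_rel <- length(relation_labels)
  if (nrow(triples)) {
    if (any(triples[, c(1L, 3L)] < 1L) || any(triples[, c(1L, 3L)] > n_ent))
      stop_mdalink("triple refers to an entity index outside 1..", n_ent)
    if (any(triples[, 2L] < 1L) || any(triples[, 2L] > n_rel))
      stop_mdalink("triple refers to a relation index outside 1..", n_rel)
    triples <- triples[!duplicated(triples), , drop = FALSE]
  }
  structure(list(
    triples = triples,
    entity_labels = as.character(entity_labels),
    relation_labels = as.character(relation_labels),
    head_index = build_head_index(triples, n_ent)
  ), class = "knowledge_graph")
}

#' Rebuild the head-indexed adjacency of a triple matrix
#'
#' Groups triple row indices by head entity; used both by the constructor and
#' by tests that compare against a naive per-triple grouping.
#'
#' @param triples integer triple matrix (head, relation, tail).
#' @param n_entities number of entities in the owning graph.
#' @return list of length `n_entities`; element `e` holds the row indices of
#'   triples whose head is `e`.
#' @export
build_head_index <- function(triples, n_entities) {
  if (n_entities == 0L) return(list())
  grp <- split(seq_len(nrow(triples)),
               factor(triples[, 1L], levels = seq_len(n_entities)))
  lapply(unname(grp), as.integer)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d entities, %d relations, %d triples\n",
              length(x$entity_labels), length(x$relation_labels),
              nrow(x$triples)))
  invisible(x)
}

entity_count <- function(kg) length(kg$entity_labels)
relation_count <- function(kg) length(kg$relation_labels)

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop_mdalink("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], numbers = which(keep))
}

#' Read a knowledge graph from a tab-separated triple file
#'
#' Each non-comment line must contain at least three tab-separated fields
#' (head label, relation label, tail label); `#` starts a comment line.
#' Labels are interned to dense indices in first-appearance order (head, then
#' tail, per line) and are never normalized.  Duplicate triples are dropped.
#'
#' @param path path to the triple TSV.
#' @param undirected if `TRUE`, an inverse triple with relation
#'   `<relation>_inv` is added for every loaded triple, so that directed
#'   head-to-tail propagation can also walk edges backwards.
#' @return a [knowledge_graph()].
#' @export
read_triples <- function(path, undirected = FALSE) {
  parsed <- read_tsv_lines(path)
  if (length(parsed$lines) == 0L) {
    return(knowledge_graph(NULL, character(0), character(0)))
  }
  parts <- strsplit(parsed$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop_mdalink("malformed triple line ", parsed$numbers[bad[1L]],
                 ": expected 3 tab-separated fields")
  }
  h <- vapply(parts, `[[`, character(1), 1L)
  r <- vapply(parts, `[[`, character(1), 2L)
  t <- vapply(parts, `[[`, character(1), 3L)
  if (undirected) {
    h2 <- c(h, t); t <- c(t, h); r <- c(r, paste0(r, "_inv")); h <- h2
  }
  ents <- unique(as.vector(rbind(h, t)))
  rels <- unique(r)
  knowledge_graph(cbind(match(h, ents), match(r, rels), match(t, ents)),
                  ents, rels)
}

#' Write a knowledge graph as a triple TSV
#' @param kg a [knowledge_graph()].
#' @param path output path.
#' @export
write_triples <- function(kg, path) {
  df <- data.frame(h = kg$entity_labels[kg$triples[, 1L]],
                   r = kg$relation_labels[kg$triples[, 2L]],
                   t = kg$entity_labels[kg$triples[, 3L]])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a binary microbe-by-drug interaction matrix
#'
#' @param values binary matrix (microbes in rows, drugs in columns).
#' @param microbe_labels,drug_labels label vectors matching the dimensions.
#' @return object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(values, microbe_labels, drug_labels) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1)))
    stop_mdalink("interaction values must be 0 or 1")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_mdalink("interaction matrix needs at least one microbe and one drug")
  if (nrow(values) != length(microbe_labels) ||
      ncol(values) != length(drug_labels))
    stop_mdalink("label lengths do not match matrix dimensions")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(microbe_labels, drug_labels)
  structure(list(values = values,
                 microbe_labels = as.character(microbe_labels),
                 drug_labels = as.character(drug_labels)),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d microbes x %d drugs, %d positives\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Read an interaction matrix from TSV
#'
#' Two on-disk dialects are supported.  An *edge list* has rows
#' `microbe<TAB>drug[<TAB>value]` with a default value of 1; a *dense* table
#' has an empty first header field, drug labels across the header and one row
#' per microbe.  With `format = "auto"` a leading empty header field selects
#' the dense reader.
#'
#' @param path input TSV path.
#' @param format one of `"auto"`, `"edgelist"`, `"dense"`.
#' @return an [interaction_matrix()].
#' @export
read_interactions <- function(path, format = c("auto", "edgelist", "dense")) {
  format <- match.arg(format)
  parsed <- read_tsv_lines(path)
  if (length(parsed$lines) == 0L)
    stop_mdalink("empty interaction file: no microbes/drugs inferable")
  parts <- strsplit(parsed$lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (parts[[1L]][1L] %in% c("", "id")) "dense" else "edgelist"
  }
  if (format == "dense") {
    drug_labels <- parts[[1L]][-1L]
    rows <- parts[-1L]
    if (length(rows) == 0L) stop_mdalink("dense interaction file has no rows")
    microbe_labels <- vapply(rows, `[[`, character(1), 1L)
    vals <- lapply(rows, function(p) {
      if (length(p) != length(drug_labels) + 1L)
        stop_mdalink("dense row for '", p[1L], "' has wrong field count")
      v <- suppressWarnings(as.numeric(p[-1L]))
      if (anyNA(v) || !all(v %in% c(0, 1)))
        stop_mdalink("non-binary value in dense row '", p[1L], "'")
      v
    })
    return(interaction_matrix(do.call(rbind, vals), microbe_labels,
                              drug_labels))
  }
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop_mdalink("malformed edge-list line ", parsed$numbers[bad[1L]])
  m <- vapply(parts, `[[`, character(1), 1L)
  d <- vapply(parts, `[[`, character(1), 2L)
  v <- vapply(parts, function(p) {
    if (length(p) >= 3L) {
      x <- suppressWarnings(as.numeric(p[3L]))
      if (is.na(x) || !x %in% c(0, 1))
        stop_mdalink("non-binary interaction value '", p[3L], "'")
      x
    } else 1
  }, numeric(1))
  key <- paste(m, d, sep = "\r")
  agg <- tapply(v, key, function(x) length(unique(x)))
  if (any(agg > 1L)) {
    k <- names(agg)[which(agg > 1L)[1L]]
    stop_mdalink("conflicting duplicate interaction for pair ",
                 gsub("\r", " / ", k))
  }
  microbe_labels <- unique(m)
  drug_labels <- unique(d)
  values <- matrix(0L, length(microbe_labels), length(drug_labels))
  values[cbind(match(m, microbe_labels), match(d, drug_labels))] <-
    as.integer(v)
  interaction_matrix(values, microbe_labels, drug_labels)
}

#' Write an interaction matrix as TSV
#'
#' The edge-list writer emits all positive pairs plus zero-valued marker rows
#' for isolated microbes/drugs so that round-tripping preserves the label
#' universe; the dense writer emits the full 0/1 table.
#'
#' @param im an [interaction_matrix()].
#' @param path output path.
#' @param format `"edgelist"` or `"dense"`.
#' @export
write_interactions <- function(im, path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  if (format == "dense") {
    header <- paste(c("", im$drug_labels), collapse = "\t")
    rows <- vapply(seq_along(im$microbe_labels), function(i) {
      paste(c(im$microbe_labels[i], im$values[i, ]), collapse = "\t")
    }, character(1))
    writeLines(c(header, rows), path)
  } else {
    pos <- which(im$values == 1L, arr.ind = TRUE)
    lines <- sprintf("%s\t%s\t1", im$microbe_labels[pos[, 1L]],
                     im$drug_labels[pos[, 2L]])
    iso_m <- which(rowSums(im$values) == 0L)
    iso_d <- which(colSums(im$values) == 0L)
    lines <- c(lines,
               sprintf("%s\t%s\t0", im$microbe_labels[iso_m],
                       im$drug_labels[1L]),
               sprintf("%s\t%s\t0", im$microbe_labels[1L],
                       im$drug_labels[iso_d]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Construct a node-to-entity alignment
#'
#' @param microbe_entity integer vector: entity index aligned to each microbe.
#' @param drug_entity integer vector: entity index aligned to each drug.
#' @param kg companion [knowledge_graph()] used to validate indices.
#' @return object of class `entity_alignment`.
#' @export
entity_alignment <- function(microbe_entity, drug_entity, kg) {
  microbe_entity <- as.integer(microbe_entity)
  drug_entity <- as.integer(drug_entity)
  n_ent <- entity_count(kg)
  if (anyNA(microbe_entity) || anyNA(drug_entity))
    stop_mdalink("alignment contains missing entity indices")
  if (any(c(microbe_entity, drug_entity) < 1L) ||
      any(c(microbe_entity, drug_entity) > n_ent))
    stop_mdalink("aligned entity index outside 1..", n_ent)
  if (anyDuplicated(microbe_entity))
    stop_mdalink("two microbes aligned to the same entity")
  if (anyDuplicated(drug_entity))
    stop_mdalink("two drugs aligned to the same entity")
  structure(list(microbe_entity = microbe_entity, drug_entity = drug_entity),
            class = "entity_alignment")
}

#' Read a node-to-entity alignment table
#'
#' Rows are `node-label<TAB>entity-label`.  Every microbe and drug label of
#' the interaction matrix must appear exactly once; entity labels must exist
#' in the knowledge graph.  Unmapped KG entities (attribute entities) are
#' allowed.
#'
#' @param path alignment TSV path.
#' @param kg companion [knowledge_graph()].
#' @param im companion [interaction_matrix()].
#' @return an [entity_alignment()].
#' @export
read_alignment <- function(path, kg, im) {
  parsed <- read_tsv_lines(path)
  parts <- strsplit(parsed$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop_mdalink("malformed alignment line ", parsed$numbers[bad[1L]])
  node <- vapply(parts, `[[`, character(1), 1L)
  ent <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(node))
    stop_mdalink("node '", node[anyDuplicated(node)],
                 "' appears more than once in alignment")
  lookup <- function(labels, side) {
    i <- match(labels, node)
    if (anyNA(i)) stop_mdalink("missing ", side, " in alignment: ",
                               labels[which(is.na(i))[1L]])
    e <- match(ent[i], kg$entity_labels)
    if (anyNA(e)) stop_mdalink("unknown KG entity label: ",
                               ent[i][which(is.na(e))[1L]])
    e
  }
  entity_alignment(lookup(im$microbe_labels, "microbe"),
                   lookup(im$drug_labels, "drug"), kg)
}

#' Build the identity alignment where nodes are themselves KG entities
#' @inheritParams read_alignment
#' @return an [entity_alignment()] mapping each microbe/drug label to the KG
#'   entity carrying the same label.
#' @export
identity_alignment <- function(kg, im) {
  me <- match(im$microbe_labels, kg$entity_labels)
  de <- match(im$drug_labels, kg$entity_labels)
  if (anyNA(me)) stop_mdalink("microbe label absent from KG entities: ",
                              im$microbe_labels[which(is.na(me))[1L]])
  if (anyNA(de)) stop_mdalink("drug label absent from KG entities: ",
                              im$drug_labels[which(is.na(de))[1L]])
  entity_alignment(me, de, kg)
}

#' Write an alignment table as TSV
#' @param alignment an [entity_alignment()].
#' @param kg,im the companion graph and interaction matrix (for labels).
#' @param path output path.
#' @export
write_alignment <- function(alignment, kg, im, path) {
  df <- data.frame(
    node = c(im$microbe_labels, im$drug_labels),
    entity = kg$entity_labels[c(alignment$microbe_entity,
                                alignment$drug_entity)])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Structural validation report for a loaded dataset
#'
#' Report-only: lists isolated microbes/drugs (all-zero rows/columns), the
#' positive-edge count and a KG out-degree summary.  Never raises.
#'
#' @param kg a [knowledge_graph()].
#' @param im an [interaction_matrix()].
#' @param alignment an [entity_alignment()].
#' @return object of class `mdalink_validation`.
#' @export
validate_dataset <- function(kg, im, alignment) {
  outdeg <- lengths(kg$head_index)
  structure(list(
    n_microbes = nrow(im$values),
    n_drugs = ncol(im$values),
    n_positives = sum(im$values),
    isolated_microbes = which(rowSums(im$values) == 0L),
    isolated_drugs = which(colSums(im$values) == 0L),
    n_entities = entity_count(kg),
    n_relations = relation_count(kg),
    n_triples = nrow(kg$triples),
    kg_out_degree = summary(outdeg),
    aligned_entities = length(unique(c(alignment$microbe_entity,
                                       alignment$drug_entity)))
  ), class = "mdalink_validation")
}

#' @export
print.mdalink_validation <- function(x, ...) {
  cat(sprintf("dataset: %d microbes x %d drugs, %d positive edges\n",
              x$n_microbes, x$n_drugs, x$n_positives))
  cat(sprintf("isolated: %d microbes, %d drugs\n",
              length(x$isolated_microbes), length(x$isolated_drugs)))
  cat(sprintf("KG: %d entities, %d relations, %d triples\n",
              x$n_entities, x$n_relations, x$n_triples))
  cat("KG out-degree: "); print(x$kg_out_degree)
  invisible(x)
}
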