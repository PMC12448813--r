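# Synthetic benchmark generator: interaction matrices with planted low-rank
# microbe-drug signal and companion knowledge graphs whose attribute links
# encode the same latent factors, so signal recovery by the full pipeline is
# measurable without any external download.

#' Specification of a synthetic benchmark
#'
#' The generative model is a logistic low-rank one, matching the
#' dot-product-plus-sigmoid decoder used for final scoring: interaction
#' probabilities are `plogis(scale * U V' + bias)` with factors drawn i.i.d.
#' standard normal and the bias solved numerically so the expected density
#' hits `interaction_density`.  The knowledge graph links every microbe/drug
#' entity to the attribute entities whose latent direction best aligns with
#' its factor vector (in both edge directions, so that two-hop
#' microbe-attribute-microbe paths exist under directed propagation); a
#' fraction `attribute_noise` of those links is rewired uniformly at random.
#'
#' @param n_microbes,n_drugs dimensions of the interaction matrix.
#' @param latent_rank rank of the planted factor model (>= 1).
#' @param interaction_density target expected fraction of positive entries,
#'   in (0, 1).
#' @param n_attribute_entities number of shared attribute entities in the KG
#'   (must be >= `latent_rank` so the factors can be encoded).
#' @param n_relations number of KG relation types.
#' @param kg_edges_per_node outgoing attribute links per microbe/drug entity.
#' @param attribute_noise fraction of attribute links rewired at random,
#'   in \[0, 1\].
#' @param scale slope applied to the latent dot products before the logistic;
#'   larger values plant a sharper signal.
#' @param seed integer seed; every generated object is fully determined by it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_microbes = 100L, n_drugs = 200L,
                           latent_rank = 4L, interaction_density = 0.05,
                           n_attribute_entities = 300L, n_relations = 5L,
                           kg_edges_per_node = 8L, attribute_noise = 0.1,
                           scale = 3, seed = 42L) {
  spec <- list(n_microbes = as.integer(n_microbes),
               n_drugs = as.integer(n_drugs),
               latent_rank = as.integer(latent_rank),
               interaction_density = interaction_density,
               n_attribute_entities = as.integer(n_attribute_entities),
               n_relations = as.integer(n_relations),
               kg_edges_per_node = as.integer(kg_edges_per_node),
               attribute_noise = attribute_noise,
               scale = scale,
               seed = as.integer(seed))
  if (spec$latent_rank < 1L) stop_mdalink("latent_rank must be >= 1")
  if (spec$interaction_density <= 0 || spec$interaction_density >= 1)
    stop_mdalink("interaction_density must lie in (0, 1)")
  if (spec$attribute_noise < 0 || spec$attribute_noise > 1)
    stop_mdalink("attribute_noise must lie in [0, 1]")
  if (spec$n_microbes < 1L || spec$n_drugs < 1L)
    stop_mdalink("need at least one microbe and one drug")
  if (spec$kg_edges_per_node < 1L)
    stop_mdalink("kg_edges_per_node must be >= 1")
  if (spec$n_relations < 1L) stop_mdalink("n_relations must be >= 1")
  structure(spec, class = "synthetic_spec")
}

# Solve the logistic bias so that mean(plogis(z + b)) == target.
solve_density_bias <- function(z, target, tol = 1e-10) {
  f <- function(b) mean(plogis(z + b)) - target
  span <- max(abs(z[is.finite(z)]), 1) + 60
  lo <- -span; hi <- span
  if (f(lo) > 0 || f(hi) < 0)
    stop_mdalink("bisection cannot bracket the target density")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate an interaction matrix with planted low-rank signal
#'
#' @param spec a [synthetic_spec()].
#' @return list with `interactions` (an [interaction_matrix()]), `factors`
#'   (list `U`, `V`, `bias`) and `probabilities` (the Bernoulli means).
#' @export
generate_interactions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    U <- matrix(rnorm(spec$n_microbes * spec$latent_rank),
                spec$n_microbes, spec$latent_rank)
    V <- matrix(rnorm(spec$n_drugs * spec$latent_rank),
                spec$n_drugs, spec$latent_rank)
    z <- spec$scale * tcrossprod(U, V)
    b <- solve_density_bias(z, spec$interaction_density)
    p <- plogis(z + b)
    a <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p))
  })
  im <- interaction_matrix(a,
                           sprintf("M%03d", seq_len(spec$n_microbes)),
                           sprintf("D%03d", seq_len(spec$n_drugs)))
  list(interactions = im, factors = list(U = U, V = V, bias = b),
       probabilities = p)
}

#' Generate a knowledge graph encoding the planted factors
#'
#' Entities are one per microbe, one per drug, plus
#' `n_attribute_entities` shared attribute entities, each assigned a random
#' unit latent direction.  Every microbe/drug entity links (with a uniformly
#' drawn relation) to the `kg_edges_per_node` attribute entities whose
#' direction has the largest dot product with its factor vector; each link is
#' emitted in both directions so directed propagation can traverse
#' node-attribute-node paths.  A fraction `attribute_noise` of link targets
#' is rewired uniformly at random.
#'
#' @param spec a [synthetic_spec()].
#' @param factors the `factors` element returned by
#'   [generate_interactions()].
#' @param directions optional matrix (`n_attribute_entities` x
#'   `latent_rank`) of attribute directions, overriding the random draw.
#' @return list with `kg` (a [knowledge_graph()]) and `alignment` (an
#'   [entity_alignment()] mapping each microbe/drug to its own entity).
#' @export
generate_kg <- function(spec, factors, directions = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_attribute_entities < spec$latent_rank)
    stop_mdalink("n_attribute_entities must be >= latent_rank ",
                 "(cannot encode the factors)")
  n_attr <- spec$n_attribute_entities
  k <- min(spec$kg_edges_per_node, n_attr)
  fac <- rbind(factors$U, factors$V)
  n_nodes <- nrow(fac)
  withr::with_seed(spec$seed + 1L, {
    if (is.null(directions)) {
      directions <- matrix(rnorm(n_attr * spec$latent_rank), n_attr)
      directions <- directions / sqrt(rowSums(directions^2))
    }
    align_scores <- fac %*% t(directions)       # n_nodes x n_attr
    triples <- vector("list", n_nodes)
    for (i in seq_len(n_nodes)) {
      tgt <- order(-align_scores[i, ], seq_len(n_attr))[seq_len(k)]
      rewire <- runif(k) < spec$attribute_noise
      # rewired links draw a fresh target uniformly over all attributes
      tgt[rewire] <- sample.int(n_attr, sum(rewire), replace = TRUE)
      rel <- sample.int(spec$n_relations, k, replace = TRUE)
      node_ent <- i
      attr_ent <- n_nodes + tgt
      triples[[i]] <- cbind(c(rep(node_ent, k), attr_ent),
                            c(rel, rel),
                            c(attr_ent, rep(node_ent, k)))
    }
  })
  ent_labels <- c(sprintf("M%03d", seq_len(spec$n_microbes)),
                  sprintf("D%03d", seq_len(spec$n_drugs)),
                  sprintf("A%03d", seq_len(n_attr)))
  kg <- knowledge_graph(do.call(rbind, triples), ent_labels,
                        sprintf("R%d", seq_len(spec$n_relations)))
  alignment <- entity_alignment(seq_len(spec$n_microbes),
                                spec$n_microbes + seq_len(spec$n_drugs), kg)
  list(kg = kg, alignment = alignment)
}

#' Generate a complete synthetic benchmark
#'
#' Bundles [generate_interactions()] and [generate_kg()] with a
#' deterministic list of all positive pairs (column-major scan order) for
#' fold splitting.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `kg`, `interactions`, `alignment`, `positives`
#'   (two-column integer matrix: microbe, drug), `factors` and `spec`.
#' @export
make_benchmark <- function(spec = synthetic_spec()) {
  gi <- generate_interactions(spec)
  gk <- generate_kg(spec, gi$factors)
  pos <- which(gi$interactions$values == 1L, arr.ind = TRUE)
  dimnames(pos) <- list(NULL, c("microbe", "drug"))
  list(kg = gk$kg, interactions = gi$interactions,
       alignment = gk$alignment, positives = pos,
       factors = gi$factors, spec = spec)
}
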