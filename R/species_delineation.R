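# Species delineation from ANI and dDDH matrices under dual thresholds
# (conventionally 95% ANI and 70% dDDH). A pair of genomes is conspecific
# when both metrics exceed their thresholds; putative species are the
# connected components of the resulting graph, so non-transitive pass
# patterns are surfaced as non-clique components rather than hidden.

#' Delineate putative species from similarity matrices
#'
#' @param matrices a `similarity_matrices` object.
#' @param ani_threshold,dddh_threshold species thresholds in percent.
#' @param combine_rule `"both"` (a pair passes only if ANI and dDDH both
#'   pass; the default) or `"either"`.
#' @param strict use strict `>` at the thresholds (default; values must
#'   exceed the threshold) or `>=` when `FALSE`.
#' @return list of class `species_clusters`: `clusters` (tibble
#'   `genome_id`, `cluster`), `pairs` (tibble per unordered pair with the
#'   metric values, per-metric passes and the combined `pass`),
#'   `non_clique_clusters` (cluster ids whose members are not all pairwise
#'   linked) and the thresholds used.
#' @export
delineate <- function(matrices, ani_threshold = 95, dddh_threshold = 70,
                      combine_rule = c("both", "either"), strict = TRUE) {
  combine_rule <- match.arg(combine_rule)
  if (ani_threshold <= 0 || ani_threshold >= 100 ||
    dddh_threshold <= 0 || dddh_threshold >= 100) {
    stop("thresholds must lie in (0, 100)", call. = FALSE)
  }
  ids <- matrices$genome_ids
  n <- length(ids)
  cmp <- if (strict) `>` else `>=`
  pairs <- NULL
  if (n > 1) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ani_v <- matrices$ani[idx]
    dddh_v <- matrices$dddh[idx]
    ani_pass <- cmp(ani_v, ani_threshold)
    dddh_pass <- cmp(dddh_v, dddh_threshold)
    pass <- if (combine_rule == "both") {
      ani_pass & dddh_pass
    } else {
      ani_pass | dddh_pass
    }
    pairs <- tibble(
      genome_a = ids[idx[, 1]], genome_b = ids[idx[, 2]],
      ani = ani_v, dddh = dddh_v,
      ani_pass = ani_pass, dddh_pass = dddh_pass, pass = pass
    )
  } else {
    pairs <- tibble(
      genome_a = character(0), genome_b = character(0),
      ani = numeric(0), dddh = numeric(0),
      ani_pass = logical(0), dddh_pass = logical(0), pass = logical(0)
    )
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  linked <- pairs[pairs$pass, c("genome_a", "genome_b")]
  if (nrow(linked)) {
    g <- igraph::add_edges(g, rbind(
      match(linked$genome_a, ids),
      match(linked$genome_b, ids)
    ))
  }
  comp <- igraph::components(g)
  membership <- comp$membership
  clusters <- tibble(genome_id = ids, cluster = as.integer(membership))
  # flag components that are not cliques (some member pair failed)
  non_clique <- integer(0)
  for (cl in unique(clusters$cluster)) {
    members <- clusters$genome_id[clusters$cluster == cl]
    k <- length(members)
    if (k < 3) next
    sub <- pairs[pairs$genome_a %in% members & pairs$genome_b %in% members, ]
    if (any(!sub$pass)) non_clique <- c(non_clique, cl)
  }
  structure(
    list(
      clusters = clusters, pairs = pairs,
      non_clique_clusters = non_clique,
      ani_threshold = ani_threshold, dddh_threshold = dddh_threshold,
      combine_rule = combine_rule, strict = strict
    ),
    class = "species_clusters"
  )
}

#' Members of the cluster containing a genome
#'
#' @param delineation a `species_clusters` object.
#' @param genome_id query genome.
#' @return character vector of cluster members (including the query).
#' @export
cluster_members <- function(delineation, genome_id) {
  cl <- delineation$clusters
  hit <- cl$cluster[cl$genome_id == genome_id]
  if (!length(hit)) stop("unknown genome: ", genome_id, call. = FALSE)
  sort(cl$genome_id[cl$cluster == hit])
}
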