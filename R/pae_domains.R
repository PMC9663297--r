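#' Build a residue graph from a PAE matrix
#'
#' The possibly asymmetric PAE is min-symmetrized -- a residue pair counts as
#' rigid if either direction is confidently placed:
#' `e(i, j) = min(PAE(i, j), PAE(j, i))`. Residues become nodes; an edge is
#' drawn whenever `e(i, j) < pae_cutoff`, weighted `(1 / e)^power` with `e`
#' floored at 0.2 A so zero-error pairs get a finite weight.
#'
#' @param pae a [pae_matrix()].
#' @param pae_cutoff edge cutoff in A (> 0), default 5.
#' @param power exponent on the inverse error weight, default 1.
#' @param floor minimum error used for weighting (A), default 0.2.
#' @return An [igraph::graph] with `weight` edge attributes; vertex names are
#'   0-based residue indices.
#' @export
pae_graph <- function(pae, pae_cutoff = 5, power = 1, floor = 0.2) {
  stopifnot(inherits(pae, "pae_matrix"))
  if (pae_cutoff <= 0) stop("pae_cutoff must be > 0")
  e <- pmin(pae$values, t(pae$values))
  adj <- ifelse(e < pae_cutoff, (1 / pmax(e, floor))^power, 0)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max", weighted = TRUE)
  igraph::V(g)$name <- as.character(seq_len(pae$n) - 1L)
  g
}

#' Cluster a PAE graph into rigid-domain communities
#'
#' Greedy agglomerative modularity maximization over the weighted residue
#' graph; communities smaller than `min_size` residues are discarded. The
#' algorithm is deterministic, so `seed` is accepted for interface stability
#' but does not change the result.
#'
#' @param graph graph from [pae_graph()].
#' @param resolution reserved for interface compatibility (the greedy
#'   algorithm optimizes plain modularity); must be 1.
#' @param min_size minimum community size in residues, default 10.
#' @param seed ignored (deterministic algorithm).
#' @return A `domain_partition` list: `communities` (list of 0-based residue
#'   index vectors, largest first), `modularity`, `params`.
#' @export
cluster_domains <- function(graph, resolution = 1.0, min_size = 10,
                            seed = NULL) {
  if (resolution != 1.0) {
    stop("greedy modularity clustering supports resolution = 1 only")
  }
  if (igraph::vcount(graph) == 0 || igraph::ecount(graph) == 0) {
    return(structure(list(communities = list(), modularity = NA_real_,
                          params = list(min_size = min_size)),
                     class = "domain_partition"))
  }
  cl <- igraph::cluster_fast_greedy(graph,
                                    weights = igraph::E(graph)$weight)
  mem <- igraph::membership(cl)
  mod <- max(igraph::modularity(cl))
  if (mod < 1e-9) {
    # no split beats the trivial partition (Q = 0): fall back to connected
    # components so a uniformly confident matrix yields one community
    mem <- igraph::components(graph)$membership
  }
  resid <- as.integer(igraph::V(graph)$name)
  comms <- split(resid, mem)
  comms <- lapply(comms, sort)
  comms <- comms[vapply(comms, length, integer(1)) >= min_size]
  # largest first; ties broken by lowest residue index
  o <- order(-vapply(comms, length, integer(1)),
             vapply(comms, function(x) x[1], integer(1)))
  structure(list(communities = unname(comms[o]),
                 modularity = mod,
                 params = list(min_size = min_size, resolution = resolution)),
            class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  sizes <- vapply(x$communities, length, integer(1))
  cat(sprintf("<domain_partition> %d communities (sizes: %s), modularity %.3f\n",
              length(sizes), paste(sizes, collapse = ", "), x$modularity))
  invisible(x)
}

#' Extract a rigid core for molecular replacement
#'
#' Keeps only the residues of the largest PAE community whose pLDDT is
#' strictly above `plddt_floor` (residues with pLDDT <= 50 are excluded under
#' the default), and sets every B-factor to the constant `b_constant` -- the
#' preparation used before handing a predicted model to a
#' molecular-replacement program. Chain ids and author numbering are
#' preserved.
#'
#' @param model an [af2_model()].
#' @param partition a `domain_partition` computed on this model's PAE.
#' @param plddt_floor confidence floor (exclusive), default 50.
#' @param b_constant constant B-factor written into the output, default 50.
#' @return A trimmed [af2_model()] whose `plddt`/atom B columns hold
#'   `b_constant`.
#' @export
extract_rigid_core <- function(model, partition, plddt_floor = 50,
                               b_constant = 50) {
  stopifnot(inherits(model, "af2_model"),
            inherits(partition, "domain_partition"))
  if (!length(partition$communities)) stop("no confident core: empty partition")
  core <- partition$communities[[1]]
  keep <- intersect(core,
                    model$residues$index[model$residues$plddt > plddt_floor])
  if (!length(keep)) {
    stop("no confident core: no residue in the largest community has pLDDT > ",
         plddt_floor)
  }
  out <- model_subset(model, keep)
  out$residues$plddt <- b_constant
  if (!is.null(out$atoms)) out$atoms$b <- b_constant
  out
}
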