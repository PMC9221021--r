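# Leading-eigenvector spectral community detection on grammar networks
# (Newman's recursive bisection of the modularity matrix).

#' Weighted modularity of a partition
#'
#' `Q = (1/2m) sum_ij (W_ij - k_i k_j / 2m) [c_i = c_j]` over the weighted
#' adjacency W (diagonal ignored).
#'
#' @param W symmetric non-negative weight matrix (diagonal treated as 0).
#' @param membership community labels, one per node.
#' @return scalar modularity; 0 for an edgeless graph.
#' @export
graph_modularity <- function(W, membership) {
  W <- as.matrix(W)
  diag(W) <- 0
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  B <- W - outer(k, k) / m2
  same <- outer(membership, membership, `==`)
  sum(B[same]) / m2
}

# Orient an eigenvector so the entry of the lexicographically smallest node is
# non-negative; zero entries always go to the positive side.
orient_eigenvector <- function(v, node_names) {
  ord <- order(node_names)
  lead <- v[ord][which(abs(v[ord]) > 1e-12)[1]]
  if (!is.na(lead) && lead < 0) v <- -v
  v
}

#' Spectral (leading-eigenvector) community detection on a grammar network
#'
#' Builds a graph on the non-missing families with edges where the pairwise
#' correlation exceeds `edge_threshold` (edge weight = r), then recursively
#' bisects by the sign pattern of the eigenvector of the (generalized)
#' modularity matrix belonging to its largest positive eigenvalue. A group is
#' left intact when no positive eigenvalue exists or the split does not
#' increase modularity. Deterministic: eigenvectors are oriented so the entry
#' of the lexicographically smallest node is non-negative, and zero entries
#' join the positive side.
#'
#' @param grammar a `grammar_matrix`, or a symmetric weight matrix with
#'   dimnames (diagonal ignored).
#' @param edge_threshold retain edges with weight strictly greater than this
#'   (default 0).
#' @return object of class `grammar_network`: list (nodes, weights,
#'   communities (named integer vector), modularity, n_communities).
#' @export
spectral_communities <- function(grammar, edge_threshold = 0) {
  if (inherits(grammar, "grammar_matrix")) {
    keep <- setdiff(grammar$families, grammar$missing)
    if (length(keep) < 2)
      stop("at least 2 non-missing families required")
    W <- grammar$r[keep, keep, drop = FALSE]
  } else {
    W <- as.matrix(grammar)
    stopifnot(!is.null(rownames(W)), isTRUE(all.equal(W, t(W))))
  }
  nodes <- rownames(W)
  diag(W) <- 0
  W[W <= edge_threshold] <- 0
  if (sum(W) == 0) {
    warning("no edges above threshold; returning a single trivial community")
    comm <- stats::setNames(rep(1L, length(nodes)), nodes)
    return(structure(list(nodes = nodes, weights = W, communities = comm,
                          modularity = 0, n_communities = 1L),
                     class = "grammar_network"))
  }
  m2 <- sum(W)
  k <- rowSums(W)
  B <- W - outer(k, k) / m2
  membership <- stats::setNames(rep(1L, length(nodes)), nodes)
  next_label <- 2L
  tol <- 1e-12
  divide <- function(group) {
    if (length(group) < 2) return()
    Bg <- B[group, group, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    eg <- eigen(Bg, symmetric = TRUE)
    lambda <- eg$values[1]
    if (lambda <= tol) return()
    v <- orient_eigenvector(eg$vectors[, 1], group)
    s <- ifelse(v >= 0, 1, -1)
    if (all(s == 1) || all(s == -1)) return()
    dQ <- as.numeric(t(s) %*% Bg %*% s) / (2 * m2)
    if (dQ <= tol) return()
    neg <- group[s < 0]
    membership[neg] <<- next_label
    next_label <<- next_label + 1L
    divide(group[s > 0])
    divide(neg)
  }
  divide(nodes)
  # renumber communities by first appearance in node order
  labs <- unique(membership)
  comm <- stats::setNames(match(membership, labs), nodes)
  structure(list(nodes = nodes, weights = W, communities = comm,
                 modularity = graph_modularity(W, comm),
                 n_communities = length(labs)),
            class = "grammar_network")
}
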