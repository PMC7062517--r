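#' Library-size log-normalization
#'
#' `value = log(1 + scale * count / library_size)` with the library size
#' recomputed on the current (post-filtering) matrix. Preserves the zero
#' pattern exactly.
#'
#' @param m count matrix (no all-zero columns).
#' @param scale size factor target (default 10,000).
#' @return sparse real-valued matrix of the same shape.
#' @export
normalize_log <- function(m, scale = 10000) {
  stopifnot(scale > 0)
  lib <- Matrix::colSums(m)
  if (any(lib == 0)) stop("zero library size: remove empty cells before normalizing")
  x <- as(as(m, "CsparseMatrix"), "generalMatrix")
  j <- rep(seq_len(ncol(x)), diff(x@p))
  x@x <- log1p(scale * x@x / lib[j])
  x
}

#' Principal-component embedding of cells
#'
#' Gene-centered singular value decomposition of the cells x genes matrix.
#' Deterministic: each component's sign is fixed by forcing its
#' largest-magnitude gene loading positive.
#'
#' @param m real-valued genes x cells matrix (e.g. [normalize_log()] output).
#' @param n_components number of components
#'   (<= min(n_cells, n_genes)).
#' @return object of class `pca_embedding`: list with `scores` (cells x
#'   components, rownames = barcodes), `var_share` (non-increasing variance
#'   shares in \[0,1\]), `loadings` (genes x components) and `n_components`.
#' @export
pca_embed <- function(m, n_components) {
  x <- t(as.matrix(m))                      # cells x genes
  k <- as.integer(n_components)
  if (k > min(dim(x))) {
    stop("n_components exceeds min(n_cells, n_genes)")
  }
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc)
  flip <- vapply(seq_len(k), function(c) {
    v <- sv$v[, c]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k) %*% diag(flip, k, k)
  rownames(scores) <- colnames(m)
  loadings <- sv$v[, seq_len(k), drop = FALSE] %*% diag(flip, k, k)
  rownames(loadings) <- rownames(m)
  tot <- sum(sv$d^2)
  var_share <- if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k)
  structure(
    list(scores = scores, var_share = var_share, loadings = loadings,
         n_components = k),
    class = "pca_embedding"
  )
}

#' Modularity clustering on a kNN graph in PC space
#'
#' Builds an (undirected, union) k-nearest-neighbor graph on Euclidean
#' distance between embedded cells, then runs greedy modularity maximization
#' (hierarchical agglomeration) with deterministic tie handling. Clustering
#' is done in principal-component space; any t-SNE/UMAP map is
#' visualization only.
#'
#' @param embedding a [pca_embed()] result (or a plain cells x dims matrix).
#' @param k_neighbors neighbors per cell (< number of cells).
#' @return object of class `cluster_labels`: list with `labels` (integer
#'   community per cell, contiguous from 0, named by barcode) and
#'   `modularity`.
#' @export
cluster_modularity <- function(embedding, k_neighbors = 15L) {
  scores <- if (inherits(embedding, "pca_embedding")) embedding$scores else embedding
  n <- nrow(scores)
  k <- as.integer(k_neighbors)
  if (k >= n) stop("k_neighbors must be smaller than the number of cells")
  d <- as.matrix(stats::dist(scores))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    o <- order(d[i, ], seq_len(n))          # ties broken by index
    nb <- setdiff(o, i)[seq_len(k)]
    edges[[i]] <- cbind(i, nb)
  }
  em <- do.call(rbind, edges)
  em <- t(apply(em, 1L, sort))
  em <- unique(em)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comm <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(comm)
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(labels) <- rownames(scores)
  structure(
    list(labels = labels, modularity = igraph::modularity(g, memb)),
    class = "cluster_labels"
  )
}
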