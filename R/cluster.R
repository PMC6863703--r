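# Clustering of networks on the coordinates of their central functional
# groups.  Clustering interpolates between treating every network
# independently during matching (k = N) and pooling all side-chain
# conformations into one calculation (k = 1).

#' Feature vector of a network: central functional-group coordinates
#'
#' The central atom of each group is its interacting heavy atom on the
#' ligand-facing edge that generated the placement (falling back to the
#' template's first heavy atom), expressed in the ligand canonical frame.
#' Features are the concatenation of these coordinates in spec group order.
#'
#' @param network a \code{network_configuration}
#' @param spec an \code{active_site_spec}
#' @return numeric vector of length 3 x number of groups
#' @export
network_features <- function(network, spec) {
  out <- lapply(spec$groups$label, function(lab) {
    p <- network$assignment[[lab]]
    anchor <- p$ref_atom
    if (is.null(anchor) || !anchor %in% rownames(p$atoms))
      anchor <- fg_template(p$fg_name)$heavy_atoms[1L]
    p$atoms[anchor, ]
  })
  as.numeric(do.call(c, out))
}

#' Cluster networks on their feature vectors
#'
#' Seeded k-means.  Requested clusters that come out empty (or duplicate
#' feature vectors at k close to N) reduce the returned number of clusters,
#' so the effective k' can be below the target.  Deterministic given the seed.
#'
#' @param features N x d feature matrix (rows = networks), e.g. built with
#'   \code{\link{network_features}}
#' @param k target number of clusters, 1 <= k <= N
#' @param seed RNG seed for the k-means initialisation
#' @return object of class \code{cluster_set}: \code{k} (clusters returned),
#'   \code{assignment} (network -> cluster id in 1..k), \code{centroids}
#' @export
cluster_networks <- function(features, k, seed = 2019) {
  features <- as.matrix(features)
  N <- nrow(features)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > N)
    stop("hbnetforge value error: k must satisfy 1 <= k <= number of networks")
  k <- as.integer(k)
  uf <- unique(features)
  k_eff <- min(k, nrow(uf))
  if (k_eff == nrow(uf)) {
    # every distinct feature vector its own cluster
    ids <- match(key_string(round(features, 9L) * 1e9), key_string(round(uf, 9L) * 1e9))
    centroids <- uf
    assignment <- ids
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    km <- stats::kmeans(features, centers = k_eff, nstart = 5L, iter.max = 100L)
    assignment <- km$cluster
    centroids <- km$centers
  }
  # drop empty clusters and densify ids
  used <- sort(unique(assignment))
  assignment <- match(assignment, used)
  centroids <- centroids[used, , drop = FALSE]
  structure(list(k = length(used), assignment = assignment,
                 centroids = unname(centroids), seed = seed),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d cluster(s) over %d network(s) (seed %s)\n",
              x$k, length(x$assignment), format(x$seed)))
  invisible(x)
}
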