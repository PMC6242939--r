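#' Density-based clustering with HDBSCAN
#'
#' Hierarchical density-based clustering: core distances are taken to the
#' `min_samples`-th nearest neighbour, pairwise distances are replaced by
#' mutual reachability distances, a single-linkage hierarchy is built,
#' condensed with minimum cluster size `min_cluster_size`, and flat
#' clusters are extracted by excess-of-mass stability. Points that only
#' ever belong to the hierarchy root are labeled `-1` (outliers); cluster
#' labels are `0..K-1`.
#'
#' @param coords numeric matrix of cell coordinates (rows = cells),
#'   typically a 2-D embedding.
#' @param min_cluster_size smallest allowed cluster (default 7).
#' @param min_samples neighbourhood size for core distances (default 9).
#' @return A list of class `sct_clusters` with `labels` (integer, -1 for
#'   outliers), `min_cluster_size`, `min_samples`, `embedding`.
#' @export
cluster_hdbscan <- function(coords, min_cluster_size = 7, min_samples = 9) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < min_cluster_size) {
    warning("fewer points (", n, ") than min_cluster_size; all labeled outliers")
    return(structure(list(labels = rep(-1L, n),
                          min_cluster_size = min_cluster_size,
                          min_samples = min_samples, embedding = coords),
                     class = "sct_clusters"))
  }
  d <- as.matrix(dist(coords))
  k <- min(min_samples, n - 1L)
  core <- vapply(seq_len(n), function(i) sort(d[i, -i], partial = k)[k], numeric(1))
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- hclust(as.dist(mr), method = "single")
  labels <- extract_eom_clusters(hc, n, min_cluster_size)
  structure(list(labels = labels, min_cluster_size = min_cluster_size,
                 min_samples = min_samples, embedding = coords),
            class = "sct_clusters")
}

# Condensed-tree construction and excess-of-mass cluster extraction from
# a single-linkage hclust object. Returns integer labels, -1 = noise.
extract_eom_clusters <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- hc$height
  n_nodes <- nrow(merge)
  # members and sizes of each dendrogram node
  members <- vector("list", n_nodes)
  node_size <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    get_m <- function(ch) if (ch < 0) -ch else members[[ch]]
    members[[i]] <- c(get_m(merge[i, 1]), get_m(merge[i, 2]))
    node_size[i] <- length(members[[i]])
  }
  lam <- 1 / pmax(height, 1e-12)

  # condensed clusters
  cl_parent <- integer(0); cl_birth <- numeric(0)
  cl_stab <- numeric(0); cl_children <- list()
  pt_cluster <- integer(n)   # condensed cluster each point fell out of
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_parent)]] <<- integer(0)
    id <- length(cl_parent)
    if (parent > 0) cl_children[[parent]] <<- c(cl_children[[parent]], id)
    id
  }
  root <- new_cluster(0L, 0)
  stack <- list(list(node = n_nodes, cl = root))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- fr$node; cl <- fr$cl
    l <- lam[node]
    ch <- merge[node, ]
    sz <- ifelse(ch < 0, 1L, node_size[pmax(ch, 1L)])
    big <- sz >= mcs
    if (all(big)) {
      cl_stab[cl] <- cl_stab[cl] + sum(sz) * (l - cl_birth[cl])
      for (j in 1:2)
        stack[[length(stack) + 1L]] <- list(node = ch[j], cl = new_cluster(cl, l))
    } else if (any(big)) {
      small <- which(!big); keep <- which(big)
      pts <- if (ch[small] < 0) -ch[small] else members[[ch[small]]]
      pt_cluster[pts] <- cl
      cl_stab[cl] <- cl_stab[cl] + length(pts) * (l - cl_birth[cl])
      stack[[length(stack) + 1L]] <- list(node = ch[keep], cl = cl)
    } else {
      pts <- c(if (ch[1] < 0) -ch[1] else members[[ch[1]]],
               if (ch[2] < 0) -ch[2] else members[[ch[2]]])
      pt_cluster[pts] <- cl
      cl_stab[cl] <- cl_stab[cl] + length(pts) * (l - cl_birth[cl])
    }
  }

  n_cl <- length(cl_parent)
  if (n_cl == 1L) return(rep(-1L, n))  # no split survived the size filter
  # excess of mass, bottom-up (children always have larger ids)
  selected <- logical(n_cl)
  subtree_stab <- cl_stab
  for (cl in rev(seq_len(n_cl))) {
    kids <- cl_children[[cl]]
    if (!length(kids)) { selected[cl] <- TRUE; subtree_stab[cl] <- cl_stab[cl]; next }
    child_sum <- sum(subtree_stab[kids])
    if (cl != root && cl_stab[cl] > child_sum) {
      selected[cl] <- TRUE
      subtree_stab[cl] <- cl_stab[cl]
      desc <- kids
      while (length(desc)) {
        selected[desc] <- FALSE
        desc <- unlist(cl_children[desc])
      }
    } else {
      subtree_stab[cl] <- child_sum
    }
  }
  selected[root] <- FALSE
  sel_ids <- which(selected)
  labels <- rep(-1L, n)
  if (length(sel_ids)) {
    # nearest selected ancestor of the cluster each point fell out of
    map <- integer(n_cl)
    for (cl in seq_len(n_cl)) {
      cur <- cl
      map[cl] <- -1L
      while (cur > 0) {
        if (selected[cur]) { map[cl] <- match(cur, sel_ids) - 1L; break }
        cur <- cl_parent[cur]
      }
    }
    labels <- map[pt_cluster]
  }
  labels
}
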