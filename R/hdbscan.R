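## Hierarchical density-based clustering (HDBSCAN), following the reference
## formulation: core distances -> mutual-reachability minimum spanning tree ->
## single-linkage hierarchy -> condensed tree at min_cluster_size ->
## excess-of-mass cluster selection. The root cluster itself is never
## selectable, so data forming one undifferentiated blob come back as noise
## (the reference implementation's behaviour without allow_single_cluster).

## core distance: distance to the min_samples-th nearest *other* point,
## the convention of the reference Python implementation
.core_distances <- function(coords, min_samples) {
  n <- nrow(coords)
  if (min_samples >= n)
    stop("min_samples must be smaller than the number of points", call. = FALSE)
  if (min_samples == 0L) return(numeric(n))
  FNN::knn.dist(coords, k = min_samples)[, min_samples]
}

## single-linkage hierarchy over the mutual-reachability MST.
## Nodes 1..n are leaves; node n+e is created by the e-th (sorted) edge.
.sl_tree <- function(coords, min_samples) {
  n <- nrow(coords)
  core <- .core_distances(coords, min_samples)
  mst <- mst_mutual_reachability(coords, core)
  ord <- order(mst[, 3])
  a <- as.integer(mst[ord, 1]); b <- as.integer(mst[ord, 2])
  w <- mst[ord, 3]

  nn <- 2L * n - 1L
  parent <- seq_len(nn)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  size <- integer(n - 1L)
  left <- integer(n - 1L); right <- integer(n - 1L)
  szof <- c(rep(1L, n), size)
  for (e in seq_len(n - 1L)) {
    ra <- find(a[e]); rb <- find(b[e])
    node <- n + e
    left[e] <- ra; right[e] <- rb
    size[e] <- szof[ra] + szof[rb]
    szof[node] <- size[e]
    parent[ra] <- node; parent[rb] <- node
  }
  list(n = n, left = left, right = right, dist = w, size = size)
}

## leaves of the subtree rooted at `node`
.subtree_leaves <- function(tree, node) {
  n <- tree$n
  if (node <= n) return(node)
  out <- integer(tree$size[node - n]); no <- 0L
  st <- integer(32L); st[1L] <- node; sp <- 1L
  while (sp > 0L) {
    x <- st[sp]; sp <- sp - 1L
    if (x <= n) {
      no <- no + 1L; out[no] <- x
    } else {
      if (sp + 2L > length(st)) st <- c(st, integer(length(st)))
      st[sp + 1L] <- tree$left[x - n]
      st[sp + 2L] <- tree$right[x - n]
      sp <- sp + 2L
    }
  }
  out[seq_len(no)]
}

## condensed tree: clusters are labelled 1.. in breadth-first order (root = 1);
## rows record either a child cluster (child encoded as n + label) splitting
## off at lambda = 1/distance, or a point (child <= n) falling out of its
## cluster at that lambda.
.condense_tree <- function(tree, min_cluster_size) {
  n <- tree$n
  m <- min_cluster_size
  root <- 2L * n - 1L
  relabel <- integer(root)
  relabel[root] <- 1L
  next_label <- 2L

  cap <- 2L * n
  P <- integer(cap); C <- integer(cap); L <- numeric(cap); S <- integer(cap)
  nr <- 0L
  queue <- integer(n); queue[1L] <- root; qh <- 1L; qt <- 1L

  while (qh <= qt) {
    node <- queue[qh]; qh <- qh + 1L
    e <- node - n
    l <- tree$left[e]; r <- tree$right[e]
    d <- tree$dist[e]
    lam <- if (d > 0) 1 / d else Inf
    szl <- if (l <= n) 1L else tree$size[l - n]
    szr <- if (r <= n) 1L else tree$size[r - n]
    lab <- relabel[node]

    drop_leaves <- function(sub) {
      leaves <- .subtree_leaves(tree, sub)
      k <- length(leaves)
      P[nr + seq_len(k)] <<- lab
      C[nr + seq_len(k)] <<- leaves
      L[nr + seq_len(k)] <<- lam
      S[nr + seq_len(k)] <<- 1L
      nr <<- nr + k
    }

    if (szl >= m && szr >= m) {
      relabel[l] <- next_label
      nr <- nr + 1L
      P[nr] <- lab; C[nr] <- n + next_label; L[nr] <- lam; S[nr] <- szl
      next_label <- next_label + 1L
      relabel[r] <- next_label
      nr <- nr + 1L
      P[nr] <- lab; C[nr] <- n + next_label; L[nr] <- lam; S[nr] <- szr
      next_label <- next_label + 1L
      qt <- qt + 1L; queue[qt] <- l
      qt <- qt + 1L; queue[qt] <- r
    } else if (szl < m && szr < m) {
      drop_leaves(l)
      drop_leaves(r)
    } else if (szl < m) {
      relabel[r] <- lab
      drop_leaves(l)
      qt <- qt + 1L; queue[qt] <- r
    } else {
      relabel[l] <- lab
      drop_leaves(r)
      qt <- qt + 1L; queue[qt] <- l
    }
  }
  list(parent = P[seq_len(nr)], child = C[seq_len(nr)],
       lambda = L[seq_len(nr)], size = S[seq_len(nr)],
       n = n, n_labels = next_label - 1L)
}

## excess-of-mass cluster selection on the condensed tree; returns 0-based
## cluster labels with -1 for noise
.eom_labels <- function(cond) {
  n <- cond$n
  nl <- cond$n_labels
  if (nl < 2L) return(rep(-1L, n))

  is_cl_row <- cond$child > n
  ## births
  birth <- numeric(nl)
  birth[cond$child[is_cl_row] - n] <- cond$lambda[is_cl_row]
  ## stability: sum over child rows of (lambda - birth[parent]) * size
  contrib <- (cond$lambda - birth[cond$parent]) * cond$size
  contrib[is.nan(contrib)] <- 0     # Inf - Inf for duplicate-point clusters
  stab <- numeric(nl)
  agg <- rowsum(contrib, cond$parent)
  stab[as.integer(rownames(agg))] <- agg[, 1L]

  cl_child <- cond$child[is_cl_row] - n
  cl_parent <- cond$parent[is_cl_row]
  parent_of <- integer(nl)
  parent_of[cl_child] <- cl_parent
  kids_of <- split(cl_child, cl_parent)

  is_cluster <- rep(TRUE, nl)
  is_cluster[1L] <- FALSE           # the root is never a selectable cluster
  deselect_below <- function(node) {
    st <- node
    while (length(st)) {
      x <- st[[1L]]; st <- st[-1L]
      kk <- kids_of[[as.character(x)]]
      if (!is.null(kk)) {
        is_cluster[kk] <<- FALSE
        st <- c(st, kk)
      }
    }
  }
  for (node in rev(seq_len(nl))[-nl]) {  # nl, nl-1, ..., 2
    kk <- kids_of[[as.character(node)]]
    sub <- if (is.null(kk)) 0 else sum(stab[kk])
    if (sub > stab[node]) {
      is_cluster[node] <- FALSE
      stab[node] <- sub
    } else {
      deselect_below(node)
    }
  }

  ## resolve each cluster label to its lowest selected ancestor (0 = none);
  ## parents always carry smaller labels, so one increasing pass suffices
  resolve <- integer(nl)
  for (lab in seq_len(nl)[-1L])
    resolve[lab] <- if (is_cluster[lab]) lab else resolve[parent_of[lab]]

  pt <- !is_cl_row
  out <- rep(0L, n)
  out[cond$child[pt]] <- resolve[cond$parent[pt]]

  ## renumber selected clusters 0..K-1 by decreasing size, ties by the
  ## smallest member index, for deterministic downstream ids
  sel <- sort(unique(out[out > 0L]))
  if (!length(sel)) return(rep(-1L, n))
  csize <- vapply(sel, function(s) sum(out == s), integer(1))
  first <- vapply(sel, function(s) which(out == s)[1L], integer(1))
  ord <- order(-csize, first)
  map <- integer(max(sel))
  map[sel[ord]] <- seq_along(sel) - 1L
  final <- rep(-1L, n)
  final[out > 0L] <- map[out[out > 0L]]
  final
}

.hdbscan_from_tree <- function(tree, min_cluster_size) {
  .eom_labels(.condense_tree(tree, min_cluster_size))
}

## full HDBSCAN on a coordinate matrix
.hdbscan <- function(coords, min_cluster_size, min_samples) {
  n <- nrow(coords)
  if (n < min_cluster_size || n <= min_samples) return(rep(-1L, n))
  tree <- .sl_tree(coords, min_samples)
  .hdbscan_from_tree(tree, min_cluster_size)
}
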