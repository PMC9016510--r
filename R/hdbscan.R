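# HDBSCAN on a distance matrix.
#
# Steps: (1) core distance of each point = distance to its min_samples-th
# nearest neighbour; (2) mutual-reachability distance
# mr(i,j) = max(core_i, core_j, d(i,j)); (3) single-linkage hierarchy on the
# mutual reachabilities (equivalent to the minimum-spanning-tree hierarchy);
# (4) condensed tree: walking the hierarchy top-down (lambda = 1/distance),
# a split is kept only when both sides hold >= min_cluster_size points,
# otherwise the small side "falls out" of its cluster; (5) cluster stability
# = sum over members of (lambda_leave - lambda_birth), and the flat
# clustering maximizes total stability (excess-of-mass), never selecting the
# hierarchy root; unclaimed points are outliers (-1).

hdbscan_engine <- function(dmat, min_cluster_size, min_samples) {
  n <- nrow(dmat)
  stopifnot(n >= 2L, min_cluster_size >= 2L)
  k <- min(min_samples, n - 1L)
  # sort(row)[k+1]: the row includes the zero self-distance, so the (k+1)-th
  # order statistic is the distance to the k-th nearest other point
  core <- apply(dmat, 1L, function(row) sort(row)[k + 1L])
  mr <- pmax(outer(core, rep(1, n)), outer(rep(1, n), core), dmat)
  diag(mr) <- 0
  hc <- hclust(as.dist(mr), method = "single")
  heights <- hc$height
  merge <- hc$merge
  h_floor <- if (any(heights > 0)) min(heights[heights > 0]) else 1
  lam_of <- function(h) 1 / max(h, h_floor)

  # leaves under each internal node
  leaves_of <- vector("list", n - 1L)
  sizes <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- merge[i, ]
    lv <- c(if (kids[1] < 0) -kids[1] else integer(0),
            if (kids[1] > 0) leaves_of[[kids[1]]] else integer(0),
            if (kids[2] < 0) -kids[2] else integer(0),
            if (kids[2] > 0) leaves_of[[kids[2]]] else integer(0))
    leaves_of[[i]] <- lv
    sizes[i] <- length(lv)
  }

  # cluster registry
  cl_parent <- c(NA_integer_)      # root = cluster 1
  cl_birth <- c(0)
  cl_size <- c(n)
  cl_stability <- c(0)
  cl_children <- list(integer(0))
  n_cl <- 1L

  cluster_of_node <- integer(n - 1L)
  cluster_of_node[n - 1L] <- 1L
  point_parent <- integer(n)       # cluster a point falls out of
  point_lambda <- numeric(n)
  records <- list()                # condensed-tree rows

  new_cluster <- function(parent, birth, size) {
    n_cl <<- n_cl + 1L
    cl_parent[n_cl] <<- parent
    cl_birth[n_cl] <<- birth
    cl_size[n_cl] <<- size
    cl_stability[n_cl] <<- 0
    cl_children[[n_cl]] <<- integer(0)
    cl_children[[parent]] <<- c(cl_children[[parent]], n_cl)
    n_cl
  }

  for (i in rev(seq_len(n - 1L))) {
    cl <- cluster_of_node[i]
    # nodes inside a subtree that already fell out carry no cluster: their
    # points were recorded when the subtree left its cluster
    if (cl == 0L) next
    lam <- lam_of(heights[i])
    kids <- merge[i, ]
    ksz <- ifelse(kids < 0, 1L, sizes[pmax(kids, 1L)])
    if (all(ksz >= min_cluster_size)) {
      # true split: both sides persist as new clusters
      cl_stability[cl] <- cl_stability[cl] + (lam - cl_birth[cl]) * sum(ksz)
      for (s in 1:2) {
        child_cl <- new_cluster(cl, lam, ksz[s])
        records[[length(records) + 1L]] <-
          c(parent = cl, child_cl = child_cl, child_point = NA_integer_,
            lambda = lam, size = ksz[s])
        cluster_of_node[kids[s]] <- child_cl
      }
    } else {
      for (s in 1:2) {
        if (ksz[s] < min_cluster_size) {
          pts <- if (kids[s] < 0) -kids[s] else leaves_of[[kids[s]]]
          cl_stability[cl] <- cl_stability[cl] + (lam - cl_birth[cl]) * length(pts)
          point_parent[pts] <- cl
          point_lambda[pts] <- lam
          for (p in pts) {
            records[[length(records) + 1L]] <-
              c(parent = cl, child_cl = NA_integer_, child_point = p,
                lambda = lam, size = 1L)
          }
        } else {
          cluster_of_node[kids[s]] <- cl
        }
      }
    }
  }

  # excess-of-mass selection, bottom-up (children always created after parent,
  # so decreasing id order is a valid topological order); root never selected
  selected <- rep(FALSE, n_cl)
  subtree_value <- numeric(n_cl)
  descendants <- function(cl) {
    out <- cl_children[[cl]]
    for (ch in cl_children[[cl]]) out <- c(out, descendants(ch))
    out
  }
  for (cl in rev(seq_len(n_cl))) {
    ch <- cl_children[[cl]]
    if (length(ch) == 0L) {
      subtree_value[cl] <- cl_stability[cl]
      selected[cl] <- cl != 1L
    } else {
      child_sum <- sum(subtree_value[ch])
      if (cl != 1L && cl_stability[cl] >= child_sum) {
        selected[cl] <- TRUE
        selected[descendants(cl)] <- FALSE
        subtree_value[cl] <- cl_stability[cl]
      } else {
        subtree_value[cl] <- child_sum
      }
    }
  }

  sel <- which(selected)
  labels <- rep(-1L, n)
  persistence <- numeric(0)
  if (length(sel) > 0L) {
    ord <- order(cl_birth[sel], -cl_size[sel], sel)   # detection order
    sel <- sel[ord]
    label_of_cluster <- rep(NA_integer_, n_cl)
    label_of_cluster[sel] <- seq_along(sel) - 1L
    for (p in seq_len(n)) {
      cl <- point_parent[p]
      while (!is.na(cl) && is.na(label_of_cluster[cl])) cl <- cl_parent[cl]
      if (!is.na(cl)) labels[p] <- label_of_cluster[cl]
    }
    persistence <- cl_stability[sel] / cl_size[sel]
  }

  rec <- do.call(rbind, records)
  condensed <- tibble::tibble(
    parent = n + as.integer(rec[, "parent"]),
    child = ifelse(is.na(rec[, "child_cl"]), as.integer(rec[, "child_point"]),
                   n + as.integer(rec[, "child_cl"])),
    lambda = rec[, "lambda"],
    child_size = as.integer(rec[, "size"])
  )

  list(labels = labels,
       persistence = tibble::tibble(
         cluster = seq_along(sel) - 1L,
         persistence = persistence,
         stability = cl_stability[sel],
         size = as.integer(tabulate(labels + 2L, nbins = length(sel) + 1L)[-1L])),
       condensed_tree = condensed)
}

#' Detect density clusters in a 2-D embedding (HDBSCAN)
#'
#' Runs HDBSCAN on embedded coordinates: clusters are the most persistent
#' dense regions of the density hierarchy, numbered 0..k-1 in the order they
#' are detected (split off) in the condensed tree; points in no persistent
#' dense region are labelled -1 (outliers). The procedure is deterministic;
#' `seed` is accepted for interface symmetry with the stochastic stages.
#'
#' @param coords n x 2 coordinate matrix (original, non-synthetic points
#'   only), or a `pcg_embedding`.
#' @param min_cluster_size Smallest group treated as a cluster; default
#'   `max(15, round(0.02 * n))`.
#' @param min_samples Neighbourhood size for the core-distance estimate;
#'   default `4 * min_cluster_size` (capped at n - 1). MDS embeddings of
#'   binary profiles pile duplicated patterns onto single positions, and a
#'   neighbourhood as small as one cluster turns every such pile into its own
#'   density peak; the wider default smooths the density estimate over
#'   several piles so clusters form at the profile-mix level.
#' @param seed Ignored (deterministic algorithm).
#' @return A `pcg_clusters`: `labels` (-1 or 0..k-1 per point),
#'   `persistence` tibble (per-cluster stability / persistence / size),
#'   `condensed_tree` tibble (`parent`, `child`, `lambda`, `child_size`;
#'   point ids 1..n, cluster ids > n), and the hyperparameters used.
#' @export
detect_clusters <- function(coords, min_cluster_size = NULL, min_samples = NULL,
                            seed = NULL) {
  if (inherits(coords, "pcg_embedding")) coords <- coords$coords
  coords <- as.matrix(coords)
  n <- nrow(coords)
  min_cluster_size <- as.integer(min_cluster_size %||% max(15, round(0.02 * n)))
  min_cluster_size <- max(2L, min_cluster_size)
  min_samples <- as.integer(min_samples %||% min(4L * min_cluster_size, n - 1L))

  if (n < min_cluster_size || n < 2L) {
    warn(sprintf("fewer points (%d) than min_cluster_size (%d); all labelled -1.",
                 n, min_cluster_size))
    return(new_pcg_clusters(rep(-1L, n),
                            tibble::tibble(cluster = integer(0),
                                           persistence = numeric(0),
                                           stability = numeric(0),
                                           size = integer(0)),
                            tibble::tibble(parent = integer(0), child = integer(0),
                                           lambda = numeric(0),
                                           child_size = integer(0)),
                            min_cluster_size, min_samples))
  }

  dmat <- as.matrix(dist(coords))
  fit <- hdbscan_engine(dmat, min_cluster_size, min_samples)

  if (nrow(fit$persistence) == 0L && n >= min_cluster_size &&
      max(dmat) < .Machine$double.eps^0.25) {
    # degenerate case: every point at the same position is one dense mass;
    # otherwise an empty selection means everything is noise (-1)
    fit$labels <- rep(0L, n)
    fit$persistence <- tibble::tibble(cluster = 0L, persistence = NA_real_,
                                      stability = NA_real_, size = n)
  }
  new_pcg_clusters(fit$labels, fit$persistence, fit$condensed_tree,
                   min_cluster_size, min_samples)
}

new_pcg_clusters <- function(labels, persistence, condensed_tree,
                             min_cluster_size, min_samples) {
  structure(list(labels = labels, persistence = persistence,
                 condensed_tree = condensed_tree,
                 min_cluster_size = min_cluster_size, min_samples = min_samples),
            class = "pcg_clusters")
}

#' @export
print.pcg_clusters <- function(x, ...) {
  k <- nrow(x$persistence)
  cat(sprintf("<pcg_clusters> %d points, %d cluster(s), %d outlier(s)\n",
              length(x$labels), k, sum(x$labels == -1L)))
  if (k > 0) print(x$persistence)
  invisible(x)
}

#' @export
#' @method tidy pcg_clusters
tidy.pcg_clusters <- function(x, ...) {
  tibble::tibble(point = seq_along(x$labels), label = x$labels)
}

#' @export
#' @method glance pcg_clusters
glance.pcg_clusters <- function(x, ...) {
  tibble::tibble(n_points = length(x$labels),
                 n_clusters = nrow(x$persistence),
                 outlier_fraction = mean(x$labels == -1L),
                 min_cluster_size = x$min_cluster_size,
                 min_samples = x$min_samples)
}
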