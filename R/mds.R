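validate_distance <- function(distance) {
  distance <- as.matrix(distance)
  if (nrow(distance) != ncol(distance)) {
    abort("distance matrix must be square.", class = "pcg_validation_error")
  }
  if (max(abs(distance - t(distance))) > 1e-8) {
    abort("distance matrix must be symmetric.", class = "pcg_validation_error")
  }
  if (any(diag(distance) != 0)) {
    abort("distance matrix must have a zero diagonal.", class = "pcg_validation_error")
  }
  if (any(distance < 0)) {
    abort("distances must be nonnegative.", class = "pcg_validation_error")
  }
  distance
}

#' Normalized stress (stress-1) of a configuration
#'
#' `sqrt( sum_(i<j) (dhat_ij - d_ij)^2 / sum_(i<j) d_ij^2 )`, where `d` are
#' the input distances and `dhat` the Euclidean distances between the rows of
#' `coords`. Zero means the distances are reproduced exactly; a configuration
#' collapsed to a single point scores 1.
#'
#' @param coords An n x k coordinate matrix.
#' @param distance An n x n symmetric distance matrix with zero diagonal.
#' @return Normalized stress (a nonnegative scalar).
#' @export
stress_of <- function(coords, distance) {
  distance <- validate_distance(distance)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(distance)) {
    abort("coords and distance dimensions do not match.",
          class = "pcg_validation_error")
  }
  dhat <- as.matrix(dist(coords))
  lo <- lower.tri(distance)
  denom <- sum(distance[lo]^2)
  if (denom <= 0) return(0)
  sqrt(sum((distance[lo] - dhat[lo])^2) / denom)
}

#' Project a distance matrix to 2-D by metric MDS
#'
#' Metric multidimensional scaling by stress majorization (SMACOF with unit
#' weights). The first start is the classical-scaling (Torgerson) solution;
#' the remaining `n_init - 1` starts are random. The lowest-stress
#' configuration wins.
#'
#' @param distance Symmetric distance matrix, zero diagonal, entries in
#'   `[0, 1]` for RF distances (any nonnegative scale is accepted).
#' @param n_init Number of restarts (default 4).
#' @param max_iter Majorization iterations per start (default 300).
#' @param tol Convergence tolerance on the stress-1 change (default 1e-4).
#' @param seed Seed for the random restarts.
#' @return A `pcg_embedding`: `coords` (n x 2), `stress` (normalized
#'   stress-1), `n_init`, `seed`.
#' @export
#' @examples
#' d <- matrix(0.5, 3, 3); diag(d) <- 0
#' emb <- mds_embed(d, seed = 1)
#' emb$stress  # ~0: an equilateral triangle is exactly planar
mds_embed <- function(distance, n_init = 4L, max_iter = 300L, tol = 1e-4,
                      seed = 1L) {
  distance <- validate_distance(distance)
  n <- nrow(distance)
  if (n == 1L) {
    return(new_embedding(matrix(0, 1, 2), 0, n_init, seed))
  }
  inits <- with_preserved_seed(as.integer(seed), {
    first <- suppressWarnings(cmdscale(distance, k = min(2L, n - 1L)))
    if (ncol(first) < 2) first <- cbind(first, matrix(0, n, 2 - ncol(first)))
    c(list(first),
      purrr::map(seq_len(max(0L, n_init - 1L)),
                 ~ matrix(runif(n * 2, -0.5, 0.5), n, 2)))
  })
  best <- NULL
  for (x0 in inits) {
    fit <- smacof_engine(distance, x0, as.integer(max_iter), tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  new_embedding(best$X, best$stress, n_init, seed)
}

new_embedding <- function(coords, stress, n_init, seed) {
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, stress = stress,
                 n_init = as.integer(n_init), seed = as.integer(seed)),
            class = "pcg_embedding")
}

#' @export
print.pcg_embedding <- function(x, ...) {
  cat(sprintf("<pcg_embedding> %d points in 2-D, normalized stress %.4f\n",
              nrow(x$coords), x$stress))
  invisible(x)
}

#' @export
#' @method tidy pcg_embedding
tidy.pcg_embedding <- function(x, ...) {
  cx <- x$coords[, 1]
  cy <- x$coords[, 2]
  tibble::tibble(point = seq_along(cx), x = cx, y = cy)
}

#' @export
#' @method glance pcg_embedding
glance.pcg_embedding <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$coords), stress = x$stress,
                 n_init = x$n_init, seed = x$seed)
}

#' @export
#' @method autoplot pcg_embedding
autoplot.pcg_embedding <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6, ...) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "MDS projection of the random-forest distance matrix",
      subtitle = sprintf("normalized stress %.3f", object$stress)
    )
}

#' Persist an embedding
#'
#' Coordinates as CSV (`point_id`, `x`, `y`) plus a JSON sidecar with the
#' stress, seed and restart count.
#'
#' @param x A `pcg_embedding`.
#' @param path Basename; writes `<path>.csv` and `<path>.json`.
#' @param point_id Optional identifiers (default row numbers).
#' @export
write_embedding <- function(x, path, point_id = NULL) {
  ids <- point_id %||% seq_len(nrow(x$coords))
  coord_x <- x$coords[, 1]
  coord_y <- x$coords[, 2]
  readr::write_csv(tibble::tibble(point_id = ids, x = coord_x, y = coord_y),
                   paste0(path, ".csv"))
  jsonlite::write_json(list(stress = x$stress, seed = x$seed, n_init = x$n_init),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
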