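## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Pairwise Euclidean distance matrix between two point sets
#'
#' @param a,b numeric matrices with columns x, y (b defaults to a).
#' @return |a| x |b| matrix of distances.
#' @keywords internal
#' @noRd
cross_dist <- function(a, b = a) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

## Ray-casting point-in-polygon; polygon is a closed or open ring (matrix
## with columns x, y). Points on an edge count as inside (sufficient for
## exclusion-region semantics).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Min-max rescale to [0, 1]; a constant image is clamped into [0, 1]
## unchanged so downstream gamma adjustment has a well-defined fixed point.
rescale01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(pmin(pmax(x, 0), 1))
  (x - lo) / (hi - lo)
}

## Enumerate permutations of 1..n (n small; used for label matching).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}

#' Match estimated topics/clusters to reference ones by best permutation
#'
#' Exhaustive search over permutations (rows of `est` reordered) maximising
#' the summed cosine similarity with rows of `ref`. Suitable for small K.
#'
#' @param est,ref matrices with the same dimensions, one distribution per row.
#' @return list with `perm` (est row order) and `cosine` (per-ref-row
#'   similarity after matching).
#' @export
match_topics <- function(est, ref) {
  stopifnot(nrow(est) == nrow(ref), ncol(est) == ncol(ref))
  K <- nrow(ref)
  if (K > 7L) stopf("exhaustive matching supports at most 7 rows, got %d", K)
  cos_sim <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(0)
    sum(u * v) / (nu * nv)
  }
  S <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) S[i, j] <- cos_sim(ref[i, ], est[j, ])
  best <- NULL; best_val <- -Inf
  for (p in all_permutations(K)) {
    v <- sum(S[cbind(seq_len(K), p)])
    if (v > best_val) { best_val <- v; best <- p }
  }
  list(perm = best, cosine = S[cbind(seq_len(K), best)])
}

## k-means++ seeding (stats::kmeans has no such initialiser).
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

## Seeded K-means with k-means++ initialisation; tolerates duplicate rows.
seeded_kmeans <- function(x, k, seed, iter.max = 100L) {
  set.seed(seed)
  x <- as.matrix(x)
  uniq <- unique(x)
  if (nrow(uniq) <= k) {
    ## fewer distinct rows than requested clusters: each distinct row a center
    centers <- uniq
    lab <- apply(cross_dist_sq(x, centers), 1L, which.min)
    return(list(cluster = as.integer(lab), centers = centers,
                reseeded = nrow(uniq) < k))
  }
  centers <- kmeanspp_centers(x, k)
  fit <- suppressWarnings(stats::kmeans(x, centers = centers, iter.max = iter.max))
  list(cluster = fit$cluster, centers = fit$centers, reseeded = FALSE)
}

cross_dist_sq <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(ncol(a))) out <- out + outer(a[, j], b[, j], "-")^2
  out
}

## Symmetric kNN graph (union of directed kNN edges) as an igraph object.
knn_graph <- function(x, k) {
  n <- nrow(x)
  if (n <= k) stopf("need more than k = %d observations, got %d", k, n)
  d <- cross_dist_sq(as.matrix(x), as.matrix(x))
  diag(d) <- Inf
  edges <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::simplify(g)
}
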