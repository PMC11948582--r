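## Tumor-cell neighborhood modeling: stromal composition within 100 um of
## each tumor cell, decomposed into topics by a latent Dirichlet allocation
## with spatial coupling, then clustered into named neighborhoods.

#' Build neighborhood documents around tumor cells
#'
#' One document per tumor (epithelial) anchor cell: counts of each
#' non-epithelial cell type within `radius_um` (inclusive). Anchors with
#' all-zero documents are retained but flagged.
#'
#' @param table cell table with cell types assigned.
#' @param radius_um document radius (default 100).
#' @return a `neighborhood_documents` list: `counts` (anchor x type integer
#'   matrix), `anchors` (data frame cell_id, patient_id, x_um, y_um),
#'   `empty` (logical flag per anchor), `radius_um`.
#' @export
build_documents <- function(table, radius_um = 100) {
  cells <- as.data.frame(table)[!table$excluded, , drop = FALSE]
  anchors <- which(cells$lineage == "epithelial")
  if (!length(anchors)) stopf("no tumor (epithelial) cells to anchor on")
  stroma <- which(cells$lineage != "epithelial" & !is.na(cells$cell_type))
  types <- sort(unique(cells$cell_type[stroma]))
  counts <- matrix(0L, length(anchors), length(types),
                   dimnames = list(NULL, types))
  if (length(stroma) && length(types)) {
    d <- cross_dist(cbind(cells$x_um[anchors], cells$y_um[anchors]),
                    cbind(cells$x_um[stroma], cells$y_um[stroma]))
    within <- d <= radius_um
    tfac <- factor(cells$cell_type[stroma], levels = types)
    for (k in seq_along(anchors)) {
      sel <- within[k, ]
      if (any(sel)) counts[k, ] <- as.integer(table(tfac[sel]))
    }
  }
  structure(list(counts = counts,
                 anchors = cells[anchors, c("cell_id", "patient_id",
                                            "x_um", "y_um")],
                 empty = rowSums(counts) == 0L,
                 radius_um = radius_um),
            class = "neighborhood_documents")
}

## Variational E-step for LDA with optional neighbor-mean coupling of the
## document-topic posteriors. N: D x V counts; log_beta: K x V.
.lda_estep <- function(N, log_beta, alpha, gamma, coupling, nbr,
                       inner = 30L, tol = 1e-5) {
  D <- nrow(N); K <- nrow(log_beta); V <- ncol(N)
  tot <- rowSums(N)
  for (it in seq_len(inner)) {
    g_use <- gamma
    if (coupling > 0 && !is.null(nbr)) {
      theta <- gamma / rowSums(gamma)
      nbr_theta <- nbr %*% theta            # row-normalised adjacency
      theta_s <- (theta + coupling * nbr_theta) / (1 + coupling)
      g_use <- theta_s * rowSums(gamma)
    }
    elog_theta <- digamma(g_use) - digamma(rowSums(g_use))
    gamma_new <- matrix(alpha, D, K)
    ## suff stats: for each word w, phi_dk ∝ exp(elog_theta + log_beta[,w])
    ss <- matrix(0, K, V)
    for (w in seq_len(V)) {
      has <- N[, w] > 0
      if (!any(has)) next
      lp <- sweep(elog_theta[has, , drop = FALSE], 2L, log_beta[, w], "+")
      lp <- lp - apply(lp, 1L, max)
      phi <- exp(lp); phi <- phi / rowSums(phi)
      gamma_new[has, ] <- gamma_new[has, ] + phi * N[has, w]
      ss[, w] <- colSums(phi * N[has, w])
    }
    delta <- max(abs(gamma_new - gamma)) / max(tot, 1)
    gamma <- gamma_new
    if (delta < tol) break
  }
  list(gamma = gamma, ss = ss)
}

#' Fit a spatially coupled topic model on neighborhood documents
#'
#' Latent Dirichlet allocation fit by variational EM. Spatial coupling
#' shrinks each anchor's topic-proportion estimate toward the mean of its
#' within-radius anchor neighbors with weight `coupling` at every E-step
#' (adjacent tumor cells are encouraged to share topics); `coupling = 0`
#' recovers standard LDA. Deterministic for a fixed seed. Held-out
#' perplexity is reported on a 10% document fold-in.
#'
#' @param docs a [build_documents()] result.
#' @param K number of topics (default 8).
#' @param coupling spatial coupling weight (default 0.1; 0 disables).
#' @param seed integer seed.
#' @param iters maximum EM iterations.
#' @param alpha Dirichlet prior on document-topic proportions (default 1/K).
#' @param eta Dirichlet prior on topic-type weights (default 0.1).
#' @param tol relative ELBO-proxy convergence tolerance.
#' @return a `spatial_lda` object: `topics` (K x type, rows sum to 1),
#'   `theta` (anchor x K, rows sum to 1), `K`, `coupling`, `perplexity`,
#'   `empty` flags, `anchors`.
#' @export
fit_spatial_lda <- function(docs, K = 8L, coupling = 0.1, seed = 1L,
                            iters = 100L, alpha = NULL, eta = 0.1,
                            tol = 1e-4) {
  stopifnot(inherits(docs, "neighborhood_documents"))
  N_all <- docs$counts
  nonempty <- which(!docs$empty)
  if (length(nonempty) < K)
    stopf("K = %d exceeds the %d nonempty documents", K, length(nonempty))
  alpha <- alpha %||% 1 / K
  N <- N_all[nonempty, , drop = FALSE]
  D <- nrow(N); V <- ncol(N)
  set.seed(seed)

  ## held-out fold for perplexity
  n_hold <- max(1L, floor(0.1 * D))
  hold <- sample.int(D, n_hold)
  train <- setdiff(seq_len(D), hold)

  ## neighbor adjacency among training anchors (row-normalised)
  xy <- as.matrix(docs$anchors[nonempty[train], c("x_um", "y_um")])
  nbr <- NULL
  if (coupling > 0) {
    d <- cross_dist(xy)
    A <- (d <= docs$radius_um) * 1
    diag(A) <- 0
    rs <- rowSums(A)
    rs[rs == 0] <- 1
    nbr <- A / rs
  }

  beta <- matrix(stats::rgamma(K * V, 100, 100), K, V) + eta
  beta <- beta / rowSums(beta)
  Ntr <- N[train, , drop = FALSE]
  gamma <- matrix(alpha + rowSums(Ntr) / K, nrow(Ntr), K) *
    matrix(stats::runif(nrow(Ntr) * K, 0.9, 1.1), nrow(Ntr), K)
  prev <- -Inf
  for (em in seq_len(iters)) {
    es <- .lda_estep(Ntr, log(beta), alpha, gamma, coupling, nbr)
    gamma <- es$gamma
    beta <- es$ss + eta
    beta <- beta / rowSums(beta)
    ## ELBO proxy: in-sample log likelihood of the point estimates
    theta <- gamma / rowSums(gamma)
    ll <- sum(Ntr * log(theta %*% beta + 1e-300))
    if (is.finite(prev) && abs(ll - prev) < tol * abs(prev)) break
    prev <- ll
  }

  ## fold in all documents (held-out and training) with frozen topics
  gamma_all <- matrix(alpha + rowSums(N) / K, D, K)
  nbr_all <- NULL
  if (coupling > 0) {
    d <- cross_dist(as.matrix(docs$anchors[nonempty, c("x_um", "y_um")]))
    A <- (d <= docs$radius_um) * 1
    diag(A) <- 0
    rs <- rowSums(A); rs[rs == 0] <- 1
    nbr_all <- A / rs
  }
  es <- .lda_estep(N, log(beta), alpha, gamma_all, coupling, nbr_all)
  theta_ne <- es$gamma / rowSums(es$gamma)

  ho_ll <- sum(N[hold, , drop = FALSE] *
                 log(theta_ne[hold, , drop = FALSE] %*% beta + 1e-300))
  ho_n <- sum(N[hold, , drop = FALSE])
  perplexity <- exp(-ho_ll / max(ho_n, 1))

  theta <- matrix(1 / K, nrow(N_all), K)
  theta[nonempty, ] <- theta_ne
  structure(list(topics = beta, theta = theta, K = K, coupling = coupling,
                 seed = seed, perplexity = perplexity,
                 empty = docs$empty, anchors = docs$anchors,
                 radius_um = docs$radius_um,
                 types = colnames(N_all)),
            class = "spatial_lda")
}

#' @export
print.spatial_lda <- function(x, ...) {
  cat(sprintf("Spatial LDA: %d topics over %d cell types, %d anchors (%d empty)\n",
              x$K, length(x$types), nrow(x$theta), sum(x$empty)))
  cat(sprintf("coupling = %g, held-out perplexity = %.2f\n",
              x$coupling, x$perplexity))
  invisible(x)
}

#' @export
summary.spatial_lda <- function(object, n_top = 3L, ...) {
  cat(sprintf("Spatial LDA (K = %d, coupling = %g)\n", object$K,
              object$coupling))
  for (k in seq_len(object$K)) {
    ord <- order(object$topics[k, ], decreasing = TRUE)[seq_len(
      min(n_top, length(object$types)))]
    cat(sprintf("topic %d: %s\n", k,
                paste(sprintf("%s (%.2f)", object$types[ord],
                              object$topics[k, ord]), collapse = ", ")))
  }
  invisible(object)
}

#' Cluster anchors into neighborhoods on their topic proportions
#'
#' K-means (k-means++ initialisation, seeded) on the anchor x topic matrix;
#' a per-cluster mean topic-fraction summary is attached as attribute
#' `cluster_topics`.
#'
#' @param result a fitted `spatial_lda`.
#' @param k number of neighborhoods (default 8).
#' @param seed integer seed.
#' @return integer neighborhood labels per anchor.
#' @export
cluster_topics <- function(result, k = 8L, seed = 1L) {
  stopifnot(inherits(result, "spatial_lda"))
  km <- seeded_kmeans(result$theta, k, seed)
  lab <- km$cluster
  summ <- t(vapply(sort(unique(lab)), function(cl)
    colMeans(result$theta[lab == cl, , drop = FALSE]),
    numeric(ncol(result$theta))))
  structure(as.integer(lab), cluster_topics = summ,
            reseeded = km$reseeded)
}

#' Per-patient neighborhood fractions
#'
#' @param labels neighborhood label per anchor.
#' @param patients patient id per anchor.
#' @return patient x neighborhood fraction matrix (rows sum to 1).
#' @export
neighborhood_fractions <- function(labels, patients) {
  if (length(labels) != length(patients))
    stopf("labels and patients must have equal length")
  tab <- table(patients, labels)
  m <- sweep(tab, 1L, rowSums(tab), "/")
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Direct K-means on neighborhood count documents
#'
#' Comparator for the topic-model route: K-means on row-normalised count
#' documents (empty documents get label NA).
#'
#' @param docs a [build_documents()] result.
#' @param k number of clusters.
#' @param seed integer seed.
#' @return integer labels per anchor (NA for empty documents); attribute
#'   `reseeded` reports whether duplicate documents collapsed clusters.
#' @export
direct_kmeans_neighborhoods <- function(docs, k, seed = 1L) {
  stopifnot(inherits(docs, "neighborhood_documents"))
  nonempty <- which(!docs$empty)
  if (length(nonempty) < k)
    stopf("k = %d exceeds the %d nonempty documents", k, length(nonempty))
  X <- docs$counts[nonempty, , drop = FALSE]
  X <- X / rowSums(X)
  km <- seeded_kmeans(X, k, seed)
  out <- rep(NA_integer_, nrow(docs$counts))
  out[nonempty] <- km$cluster
  structure(out, reseeded = km$reseeded)
}

#' Mean topic-vector distance between neighboring anchors
#'
#' Mean Euclidean distance between the topic proportions of anchor pairs
#' within the document radius; used to quantify the effect of spatial
#' coupling.
#'
#' @param result fitted `spatial_lda`.
#' @return mean pairwise neighbor distance.
#' @export
neighbor_topic_distance <- function(result) {
  xy <- as.matrix(result$anchors[, c("x_um", "y_um")])
  d <- cross_dist(xy)
  sel <- upper.tri(d) & d <= result$radius_um
  if (!any(sel)) return(NA_real_)
  th <- result$theta
  td <- sqrt(cross_dist_sq(th, th))
  mean(td[sel])
}
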