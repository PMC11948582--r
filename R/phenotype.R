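## Cell typing: SD scaling, kNN + Leiden clustering, threshold gating of
## lineages, cluster annotation, and agreement between the two routes.

#' Scale marker features for clustering
#'
#' Each selected feature column is divided by its standard deviation
#' (computed over non-excluded cells) without zero-centering and clipped
#' above `clip_sd`. Nuclear area (and, for panels that use it, eccentricity)
#' can be appended via `extra_features` and is scaled the same way.
#'
#' @param table cell table with intensity columns.
#' @param markers character vector of markers to use.
#' @param compartments named character vector marker -> compartment; markers
#'   absent from it use the [default_panel()] compartment.
#' @param extra_features additional numeric columns to append (default
#'   nuclear area).
#' @param clip_sd clipping bound in SD units (default 20).
#' @return numeric matrix (non-excluded cells x features).
#' @export
scale_markers <- function(table, markers,
                          compartments = NULL,
                          extra_features = "nuclear_area_um2",
                          clip_sd = 20) {
  keep <- !table$excluded
  tab <- table[keep, , drop = FALSE]
  pan <- default_panel()
  comp_of <- function(m) {
    if (!is.null(compartments) && m %in% names(compartments))
      compartments[[m]]
    else if (m %in% pan$marker) pan$compartment[pan$marker == m]
    else "cytoplasm"
  }
  cols <- vapply(markers, function(m) paste0(m, "_", comp_of(m)), character(1))
  missing <- setdiff(c(cols, extra_features), names(tab))
  if (length(missing))
    stopf("columns not present in table: %s", paste(missing, collapse = ", "))
  x <- as.matrix(tab[, c(cols, extra_features), drop = FALSE])
  colnames(x) <- c(markers, extra_features)
  for (j in seq_len(ncol(x))) {
    s <- stats::sd(x[, j])
    if (is.na(s) || s == 0)
      stopf("feature '%s' has zero standard deviation", colnames(x)[j])
    x[, j] <- pmin(x[, j] / s, clip_sd)
  }
  x
}

#' Cluster cells on a kNN graph with Leiden community detection
#'
#' Builds a symmetric k-nearest-neighbor graph on the scaled feature matrix
#' and partitions it with the Leiden algorithm (modularity objective). The
#' resolution is found by bisection over `bracket` until the cluster count
#' falls in `target_clusters`; if the bracket is exhausted the closest
#' achievable partition is returned with a warning.
#'
#' @param x scaled feature matrix (rows = cells).
#' @param k_neighbors neighbors for the graph (default 30).
#' @param target_clusters integer range `c(lo, hi)` of acceptable cluster
#'   counts (default 20-25).
#' @param bracket resolution search bracket.
#' @param max_iter bisection iterations.
#' @param seed integer seed (Leiden refinement is stochastic).
#' @return integer cluster labels, with the chosen resolution and cluster
#'   count in attributes `resolution` and `n_clusters`.
#' @export
cluster_cells <- function(x, k_neighbors = 30L, target_clusters = c(20L, 25L),
                          bracket = c(0.01, 3), max_iter = 25L, seed = 1L) {
  n <- nrow(x)
  if (n <= k_neighbors)
    stopf("need more than k_neighbors = %d cells, got %d", k_neighbors, n)
  g <- knn_graph(x, k_neighbors)
  run <- function(res) {
    set.seed(seed)
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 3L))
  }
  lo <- bracket[1]; hi <- bracket[2]
  lab_lo <- run(lo); lab_hi <- run(hi)
  best <- NULL; best_gap <- Inf
  consider <- function(lab, res) {
    k <- length(unique(lab))
    gap <- if (k < target_clusters[1]) target_clusters[1] - k
    else if (k > target_clusters[2]) k - target_clusters[2] else 0
    if (gap < best_gap) { best <<- list(lab = lab, res = res, k = k); best_gap <<- gap }
    gap
  }
  g_lo <- consider(lab_lo, lo); g_hi <- consider(lab_hi, hi)
  if (best_gap > 0) {
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      lab <- run(mid)
      k <- length(unique(lab))
      consider(lab, mid)
      if (best_gap == 0) break
      if (k < target_clusters[1]) lo <- mid else hi <- mid
    }
  }
  if (best_gap > 0)
    warnf("resolution bracket exhausted; returning closest partition (%d clusters)",
          best$k)
  structure(as.integer(best$lab), resolution = best$res,
            n_clusters = best$k)
}

#' Threshold gating rules for lineage assignment
#'
#' Default definitions: fibroblast if any of Vim/FN/ColI is above threshold;
#' epithelial if any of Ecad/panCK/bcatenin; endothelial if CD31; immune if
#' CD45; cells positive for none are other stroma. Multi-positive cells are
#' resolved by `precedence` (first match wins).
#'
#' @param thresholds named numeric vector of per-marker gate thresholds
#'   (markers without an entry default to `default_threshold`).
#' @param default_threshold fallback gate value.
#' @param definitions named list lineage -> character vector of markers.
#' @param precedence order in which positive lineages claim a cell.
#' @return a `gating_rules` list.
#' @export
gating_rules <- function(thresholds = c(), default_threshold = 3,
                         definitions = list(
                           epithelial = c("Ecad", "panCK", "bcatenin"),
                           immune = "CD45",
                           endothelial = "CD31",
                           fibroblast = c("Vim", "FN", "ColI")),
                         precedence = c("epithelial", "immune",
                                        "endothelial", "fibroblast")) {
  if (any(thresholds < 0)) stopf("thresholds must be >= 0")
  if (!setequal(precedence, names(definitions)))
    stopf("precedence must totally order the positive lineages")
  structure(list(thresholds = thresholds,
                 default_threshold = default_threshold,
                 definitions = definitions, precedence = precedence),
            class = "gating_rules")
}

#' Assign lineages by threshold gating
#'
#' @param table cell table with intensity columns.
#' @param rules a [gating_rules()] object.
#' @param compartments optional named vector marker -> compartment.
#' @return character vector of lineages, one per cell (excluded cells get
#'   NA).
#' @export
gate_lineages <- function(table, rules = gating_rules(),
                          compartments = NULL) {
  pan <- default_panel()
  comp_of <- function(m) {
    if (!is.null(compartments) && m %in% names(compartments))
      compartments[[m]]
    else if (m %in% pan$marker) pan$compartment[pan$marker == m]
    else "cytoplasm"
  }
  thr_of <- function(m) {
    if (m %in% names(rules$thresholds)) rules$thresholds[[m]]
    else rules$default_threshold
  }
  used <- unique(unlist(rules$definitions))
  used <- intersect(used, sub("_(nucleus|cytoplasm)$", "",
                              grep("_(nucleus|cytoplasm)$", names(table),
                                   value = TRUE)))
  out <- rep("stromal", nrow(table))
  for (lin in rev(rules$precedence)) {
    marks <- intersect(rules$definitions[[lin]], used)
    if (!length(marks)) {
      if (!any(rules$definitions[[lin]] %in% used))
        stopf("no gating marker for lineage '%s' present in table", lin)
    }
    pos <- rep(FALSE, nrow(table))
    for (m in marks) {
      col <- paste0(m, "_", comp_of(m))
      if (!col %in% names(table)) stopf("missing marker column: %s", col)
      pos <- pos | (!is.na(table[[col]]) & table[[col]] > thr_of(m))
    }
    out[pos] <- lin
  }
  out[table$excluded] <- NA_character_
  out
}

#' Single-cell label agreement
#'
#' Fraction of cells with identical labels (accuracy over paired labelings).
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return number in \[0,1\].
#' @export
agreement_score <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("label vectors differ in length")
  if (!length(labels_a)) return(NA_real_)
  mean(labels_a == labels_b)
}

#' Cluster annotation map
#'
#' @param map data frame with columns `cluster`, `cell_type`, `lineage`.
#' @param splits optional list of split rules, each
#'   `list(cluster =, marker =, threshold =, pos = c(cell_type, lineage),
#'   neg = c(cell_type, lineage))`: cluster members above the gate take the
#'   `pos` labels, the rest the `neg` labels (e.g., a CD44+ cluster split
#'   into CD44+ tumor and CD44+ stroma on an epithelial gate).
#' @return a `cluster_annotation` list.
#' @export
cluster_annotation <- function(map, splits = list()) {
  stopifnot(is.data.frame(map),
            all(c("cluster", "cell_type", "lineage") %in% names(map)))
  for (s in splits)
    if (!s$cluster %in% map$cluster)
      stopf("split rule references unknown cluster %s", s$cluster)
  structure(list(map = map, splits = splits), class = "cluster_annotation")
}

#' Annotate clusters with cell types and lineages
#'
#' Applies a total annotation map to cluster labels, applies any split rules
#' via their marker gates, and attaches a cluster x marker mean-expression
#' audit matrix as attribute `cluster_means`.
#'
#' @param labels integer cluster labels (one per non-excluded cell of
#'   `table`, or per row when lengths match).
#' @param table cell table.
#' @param annotation a [cluster_annotation()].
#' @param compartments optional marker -> compartment map for split gates.
#' @return the table with `cell_type` and `lineage` filled.
#' @export
annotate_clusters <- function(labels, table, annotation,
                              compartments = NULL) {
  idx <- if (length(labels) == nrow(table)) seq_len(nrow(table))
         else which(!table$excluded)
  if (length(labels) != length(idx))
    stopf("labels length matches neither all nor non-excluded cells")
  unmapped <- setdiff(unique(labels), annotation$map$cluster)
  if (length(unmapped))
    stopf("annotation missing cluster(s): %s",
          paste(sort(unmapped), collapse = ", "))
  m <- annotation$map
  table$cell_type[idx] <- m$cell_type[match(labels, m$cluster)]
  table$lineage[idx] <- m$lineage[match(labels, m$cluster)]
  pan <- default_panel()
  for (s in annotation$splits) {
    comp <- if (!is.null(compartments) && s$marker %in% names(compartments))
      compartments[[s$marker]]
    else if (s$marker %in% pan$marker) pan$compartment[pan$marker == s$marker]
    else "cytoplasm"
    col <- paste0(s$marker, "_", comp)
    if (!col %in% names(table)) stopf("missing marker column: %s", col)
    members <- idx[labels == s$cluster]
    hi <- table[[col]][members] > s$threshold
    table$cell_type[members] <- ifelse(hi, s$pos[1], s$neg[1])
    table$lineage[members] <- ifelse(hi, s$pos[2], s$neg[2])
  }
  icols <- grep("_(nucleus|cytoplasm)$", names(table), value = TRUE)
  means <- t(vapply(sort(unique(labels)), function(cl) {
    colMeans(as.matrix(table[idx[labels == cl], icols, drop = FALSE]),
             na.rm = TRUE)
  }, numeric(length(icols))))
  rownames(means) <- sort(unique(labels))
  attr(table, "cluster_means") <- means
  table
}
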