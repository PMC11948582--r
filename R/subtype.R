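## Patient-level subtyping from compartment composition vectors.

#' Patient x cell-type composition matrix for a tissue compartment
#'
#' Counts are pooled over each patient's samples before fractions are taken
#' (multi-core patients contribute summed counts). Fractions are of the
#' compartment total per patient: the epithelial compartment holds cells of
#' epithelial lineage, the stromal compartment all others. Cell types whose
#' pooled-cohort share of the compartment falls below `rare_threshold` are
#' dropped (rare types may be platform artifacts).
#'
#' @param tables list of cell tables with `cell_type` and `lineage` assigned.
#' @param compartment `"epithelial"` or `"stromal"`.
#' @param rare_threshold pooled-cohort fraction below which a type is
#'   excluded (default 0.04 epithelial, 0.02 stromal).
#' @param platforms optional named vector patient_id -> platform, attached
#'   for downstream platform-aware steps.
#' @return a `composition_matrix`: numeric matrix patients x cell types,
#'   with attributes `compartment`, `rare_threshold`, `platform`.
#' @export
composition <- function(tables, compartment = c("epithelial", "stromal"),
                        rare_threshold = NULL, platforms = NULL) {
  compartment <- match.arg(compartment)
  rare_threshold <- rare_threshold %||%
    if (compartment == "epithelial") 0.04 else 0.02
  all <- do.call(rbind, lapply(tables, function(t)
    as.data.frame(t)[!t$excluded,
                     c("patient_id", "cell_type", "lineage")]))
  if (is.null(all) || !nrow(all)) {
    out <- matrix(numeric(0), 0, 0)
    attr(out, "compartment") <- compartment
    attr(out, "rare_threshold") <- rare_threshold
    class(out) <- c("composition_matrix", class(out))
    return(out)
  }
  pats <- unique(all$patient_id)
  in_comp <- if (compartment == "epithelial") all$lineage == "epithelial"
             else all$lineage != "epithelial"
  all <- all[in_comp & !is.na(all$cell_type), , drop = FALSE]
  counts <- table(factor(all$patient_id, levels = pats), all$cell_type)
  totals <- rowSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warnf("patient(s) with zero %s-compartment cells excluded: %s",
          compartment, paste(pats[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
    totals <- totals[!empty]
    pats <- pats[!empty]
  }
  cohort_frac <- colSums(counts) / sum(counts)
  keep <- cohort_frac >= rare_threshold
  frac <- sweep(counts, 1L, totals, "/")[, keep, drop = FALSE]
  out <- matrix(as.numeric(frac), nrow(frac), ncol(frac),
                dimnames = list(pats, colnames(frac)))
  attr(out, "compartment") <- compartment
  attr(out, "rare_threshold") <- rare_threshold
  if (!is.null(platforms)) attr(out, "platform") <- platforms[pats]
  class(out) <- c("composition_matrix", class(out))
  out
}

#' Z-score composition columns within each platform
#'
#' Each column is centered to mean 0 and scaled to SD 1 within each platform
#' block, removing platform-level offsets while preserving within-platform
#' ranks. A constant column within a block maps to zeros.
#'
#' @param m composition matrix (patients x types).
#' @param platforms platform label per patient row; defaults to the matrix's
#'   `platform` attribute.
#' @return matrix of the same shape.
#' @export
zscore_within_platform <- function(m, platforms = attr(m, "platform")) {
  if (is.null(platforms)) platforms <- rep("all", nrow(m))
  if (length(platforms) != nrow(m))
    stopf("platforms length must match rows")
  out <- unclass(m)
  attr(out, "compartment") <- NULL; attr(out, "rare_threshold") <- NULL
  attr(out, "platform") <- NULL
  for (p in unique(platforms)) {
    rows <- which(platforms == p)
    if (length(rows) < 2L)
      stopf("platform '%s' has fewer than 2 patients", p)
    for (j in seq_len(ncol(out))) {
      v <- out[rows, j]
      s <- stats::sd(v)
      out[rows, j] <- if (s == 0) 0 else (v - mean(v)) / s
    }
  }
  out
}

#' Cluster patients into subtypes
#'
#' Leiden partitioning of a patient kNN graph on the (Z-scored) composition
#' matrix. In `"epithelial"` mode a resolution grid is scanned and, among
#' partitions whose cluster count lies in `k_range`, the one minimising the
#' platform-association chi-square statistic is returned (platform-balanced
#' subtypes). In `"stromal"` mode the grid is scanned upward and the first
#' partition in which some cluster's top-enriched cell type is the T-cell
#' type is returned (the minimum number of clusters separating T cells).
#'
#' @param m numeric matrix patients x types (Z-scored recommended).
#' @param mode `"epithelial"` or `"stromal"`.
#' @param platforms platform per patient (epithelial mode).
#' @param t_cell_type column name of the T-cell type (stromal mode).
#' @param k_range acceptable cluster-count range (epithelial mode).
#' @param resolutions resolution grid.
#' @param k_neighbors graph neighbors (capped at n-1).
#' @param seed integer seed.
#' @return integer subtype labels with attribute `resolution`.
#' @export
cluster_patients <- function(m, mode = c("epithelial", "stromal"),
                             platforms = attr(m, "platform"),
                             t_cell_type = "CD3 T",
                             k_range = c(2L, 8L),
                             resolutions = seq(0.1, 2.5, by = 0.1),
                             k_neighbors = 15L, seed = 1L) {
  mode <- match.arg(mode)
  n <- nrow(m)
  if (n < 10L) stopf("need at least 10 patients, got %d", n)
  k <- min(k_neighbors, n - 1L)
  g <- knn_graph(unclass(m), k)
  run <- function(res) {
    set.seed(seed)
    as.integer(igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 3L)))
  }
  if (mode == "epithelial") {
    if (is.null(platforms)) stopf("epithelial mode needs platform labels")
    best <- NULL; best_stat <- Inf
    for (res in resolutions) {
      lab <- run(res)
      nk <- length(unique(lab))
      if (nk < k_range[1] || nk > k_range[2]) next
      stat <- suppressWarnings(
        stats::chisq.test(table(lab, platforms), correct = FALSE)$statistic)
      if (is.na(stat)) next
      if (stat < best_stat) { best_stat <- stat; best <- list(lab = lab, res = res) }
    }
    if (is.null(best))
      stopf("no partition with cluster count in [%d, %d] on the grid",
            k_range[1], k_range[2])
    return(structure(best$lab, resolution = best$res))
  }
  ## stromal mode
  if (!t_cell_type %in% colnames(m))
    stopf("T-cell type '%s' is not a column of the matrix", t_cell_type)
  for (res in resolutions) {
    lab <- run(res)
    if (length(unique(lab)) < 2L) next
    top <- vapply(sort(unique(lab)), function(cl) {
      colnames(m)[which.max(colMeans(m[lab == cl, , drop = FALSE]))]
    }, character(1))
    if (t_cell_type %in% top)
      return(structure(lab, resolution = res))
  }
  stopf(paste0("no partition separates T cells ('%s') on the resolution ",
               "grid; max resolution tried %.2f"),
        t_cell_type, max(resolutions))
}

#' Chi-square association between subtype labels and platform
#'
#' @param labels subtype labels.
#' @param platforms platform labels.
#' @return list with `chi2`, `p` and the contingency `table`.
#' @export
platform_association <- function(labels, platforms) {
  tab <- table(labels, platforms)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stopf("need at least 2 clusters and 2 platforms")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}
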