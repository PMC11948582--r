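## Per-sample spatial statistics. Distances are Euclidean between nuclear
## centroids, all radii inclusive (d <= r). Each statistic is simple enough
## to be checked against a direct O(n^2) enumeration, and the test suite
## does exactly that.

#' Build a radius neighbor graph over cell centroids
#'
#' Edges connect all and only pairs of non-excluded cells at Euclidean
#' distance at most `radius_um` (inclusive boundary, no self edges).
#'
#' @param table cell table.
#' @param radius_um neighborhood radius in micrometers (> 0).
#' @return a `neighbor_graph`: list with `edges` (data frame `i`, `j`,
#'   `dist`; i < j as row indices into `cells`), `cells` (the retained
#'   cells), `radius_um`.
#' @export
build_graph <- function(table, radius_um) {
  if (radius_um <= 0) stopf("radius_um must be > 0")
  cells <- as.data.frame(table)[!table$excluded, , drop = FALSE]
  n <- nrow(cells)
  if (n < 2L) {
    edges <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  } else {
    d <- cross_dist(cbind(cells$x_um, cells$y_um))
    hit <- which(upper.tri(d) & d <= radius_um, arr.ind = TRUE)
    edges <- data.frame(i = hit[, 1], j = hit[, 2],
                        dist = d[hit])
  }
  structure(list(edges = edges, cells = cells, radius_um = radius_um),
            class = "neighbor_graph")
}

## Per-cell count of neighbors belonging to a set of row indices.
.neighbor_counts <- function(g, of = NULL) {
  n <- nrow(g$cells)
  cnt <- integer(n)
  e <- g$edges
  if (!nrow(e)) return(cnt)
  sel_i <- if (is.null(of)) rep(TRUE, nrow(e)) else e$i %in% of
  sel_j <- if (is.null(of)) rep(TRUE, nrow(e)) else e$j %in% of
  ## neighbor j of i counts for i when j is in `of`, and vice versa
  t1 <- table(factor(e$i[sel_j], levels = seq_len(n)))
  t2 <- table(factor(e$j[sel_i], levels = seq_len(n)))
  as.integer(t1) + as.integer(t2)
}

#' Mean typed neighbor count
#'
#' Mean over cells of type/lineage `type_a` of their `type_b` neighbor count
#' in the graph (self excluded; a = b permitted).
#'
#' @param g neighbor_graph.
#' @param type_a,type_b labels matched against `by` column.
#' @param by column of the cell table holding the labels (`"cell_type"` or
#'   `"lineage"`).
#' @return mean count (error if no type_a cell).
#' @export
mean_neighbors <- function(g, type_a, type_b, by = "cell_type") {
  a <- which(!is.na(g$cells[[by]]) & g$cells[[by]] == type_a)
  if (!length(a)) stopf("no cell with %s = '%s'", by, type_a)
  b <- which(!is.na(g$cells[[by]]) & g$cells[[by]] == type_b)
  cnt <- .neighbor_counts(g, of = b)
  mean(cnt[a])
}

#' Tumor-immune mixing score
#'
#' Ratio of tumor-immune edges to immune-immune edges in a 25 um neighbor
#' graph (lineages: tumor = epithelial, immune = immune). With no
#' immune-immune edges the score is undefined and flagged missing.
#'
#' @param g25 neighbor_graph built at the mixing radius (25 um).
#' @return list with `value` and `missing_reason` (NULL when defined).
#' @export
mixing_score <- function(g25) {
  lin <- g25$cells$lineage
  e <- g25$edges
  li <- lin[e$i]; lj <- lin[e$j]
  hetero <- sum((li == "epithelial" & lj == "immune") |
                  (li == "immune" & lj == "epithelial"), na.rm = TRUE)
  homo <- sum(li == "immune" & lj == "immune", na.rm = TRUE)
  if (homo == 0)
    return(list(value = NA_real_, missing_reason = "no immune-immune edges"))
  list(value = hetero / homo, missing_reason = NULL)
}

#' Tumoral and isolated lymphocytes
#'
#' A lymphocyte is tumoral when at least one tumor (epithelial) cell lies
#' within `radius_um`; it is isolated when fewer than `isolation_count`
#' lymphocytes (self excluded) lie within the same radius. Reported are the
#' tumoral count, the count of tumoral lymphocytes that are isolated, and
#' their ratio.
#'
#' @param table cell table with lineages/cell types.
#' @param lymphocyte_types cell types counted as lymphocytes.
#' @param radius_um radius (default 20).
#' @param isolation_count neighbor count below which a lymphocyte is
#'   isolated (default 5).
#' @return list `n_tumoral`, `n_isolated`, `fraction` (NA when no tumoral
#'   lymphocyte).
#' @export
isolated_lymphocytes <- function(table, lymphocyte_types = c("CD3 T", "CD20 B"),
                                 radius_um = 20, isolation_count = 5L) {
  cells <- as.data.frame(table)[!table$excluded, , drop = FALSE]
  ly <- which(cells$cell_type %in% lymphocyte_types)
  tum <- which(cells$lineage == "epithelial")
  if (!length(ly))
    return(list(n_tumoral = 0L, n_isolated = 0L, fraction = NA_real_))
  xy <- cbind(cells$x_um, cells$y_um)
  tumoral <- if (length(tum)) {
    d <- cross_dist(xy[ly, , drop = FALSE], xy[tum, , drop = FALSE])
    apply(d <= radius_um, 1L, any)
  } else rep(FALSE, length(ly))
  dly <- cross_dist(xy[ly, , drop = FALSE])
  nly <- rowSums(dly <= radius_um) - 1L   # self excluded
  isolated <- nly < isolation_count
  n_t <- sum(tumoral)
  n_i <- sum(tumoral & isolated)
  list(n_tumoral = as.integer(n_t), n_isolated = as.integer(n_i),
       fraction = if (n_t) n_i / n_t else NA_real_)
}

## Occupied grid boxes at size s for a point set; boxes are axis-aligned and
## anchored at the field origin (optionally shifted).
.occupied_boxes <- function(x, y, s, origin = c(0, 0)) {
  unique(paste(floor((x - origin[1]) / s), floor((y - origin[2]) / s)))
}

#' Lymphocyte occupancy AUC across grid scales
#'
#' For each box size, a grid anchored at the field origin is overlaid;
#' occupancy is the number of boxes containing at least one tumoral
#' lymphocyte of the class divided by the number of boxes containing any
#' cell (a cell-derived tissue proxy). The AUC is the trapezoidal integral
#' over box size, normalised by the size range, so the result lies in
#' \[0,1\].
#'
#' @param table cell table.
#' @param cell_class lymphocyte cell type(s) scored.
#' @param box_sizes grid box sizes in micrometers (default 10-300 by 10).
#' @param tumor_radius_um radius defining tumoral lymphocytes (default 20).
#' @param origin grid anchor (field origin).
#' @return list with `value`, `curve` (data frame size/occupancy) and
#'   `missing_reason`.
#' @export
occupancy_auc <- function(table, cell_class = c("CD3 T", "CD20 B"),
                          box_sizes = seq(10, 300, by = 10),
                          tumor_radius_um = 20, origin = c(0, 0)) {
  cells <- as.data.frame(table)[!table$excluded, , drop = FALSE]
  ly <- which(cells$cell_type %in% cell_class)
  tum <- which(cells$lineage == "epithelial")
  if (!length(ly) || !length(tum))
    return(list(value = NA_real_, curve = NULL,
                missing_reason = "no tumoral lymphocytes"))
  xy <- cbind(cells$x_um, cells$y_um)
  d <- cross_dist(xy[ly, , drop = FALSE], xy[tum, , drop = FALSE])
  tly <- ly[apply(d <= tumor_radius_um, 1L, any)]
  if (!length(tly))
    return(list(value = NA_real_, curve = NULL,
                missing_reason = "no tumoral lymphocytes"))
  occ <- vapply(box_sizes, function(s) {
    n_ly <- length(.occupied_boxes(cells$x_um[tly], cells$y_um[tly], s, origin))
    n_all <- length(.occupied_boxes(cells$x_um, cells$y_um, s, origin))
    n_ly / n_all
  }, numeric(1))
  auc <- sum(diff(box_sizes) * (utils::head(occ, -1) + utils::tail(occ, -1)) / 2) /
    diff(range(box_sizes))
  list(value = auc, curve = data.frame(size = box_sizes, occupancy = occ),
       missing_reason = NULL)
}

#' Box-counting fractal dimension of a point set
#'
#' Least-squares slope of log(occupied box count) against log(1/box size):
#' about 2 for space-filling patterns, about 1 for collinear ones.
#'
#' @param x,y point coordinates.
#' @param box_sizes grid box sizes.
#' @param origin grid anchor.
#' @return slope estimate.
#' @export
box_fd <- function(x, y, box_sizes = seq(10, 300, by = 10), origin = c(0, 0)) {
  counts <- vapply(box_sizes, function(s)
    length(.occupied_boxes(x, y, s, origin)), numeric(1))
  stats::coef(stats::lm(log(counts) ~ log(1 / box_sizes)))[[2]]
}

#' Fractal-dimension difference: tumoral lymphocytes minus tumor cells
#'
#' Both dimensions are computed on identical grids; using the tumor cells as
#' the reference set normalises for tissue geometry. Tissues without tumoral
#' lymphocytes, or with fewer than `min_occupied_boxes` occupied 10 um boxes
#' of any cell (intact-tissue guard), are flagged missing.
#'
#' @param table cell table.
#' @param cell_class lymphocyte cell type(s).
#' @param box_sizes grid box sizes.
#' @param tumor_radius_um tumoral definition radius.
#' @param min_occupied_boxes eligibility floor on occupied 10 um boxes.
#' @return list with `value` and `missing_reason`.
#' @export
fd_difference <- function(table, cell_class = c("CD3 T", "CD20 B"),
                          box_sizes = seq(10, 300, by = 10),
                          tumor_radius_um = 20, min_occupied_boxes = 3L) {
  cells <- as.data.frame(table)[!table$excluded, , drop = FALSE]
  ly <- which(cells$cell_type %in% cell_class)
  tum <- which(cells$lineage == "epithelial")
  if (!length(ly) || !length(tum))
    return(list(value = NA_real_, missing_reason = "no tumoral lymphocytes"))
  n_tissue <- length(.occupied_boxes(cells$x_um, cells$y_um, 10))
  if (n_tissue < min_occupied_boxes)
    return(list(value = NA_real_, missing_reason = "insufficient intact tissue"))
  xy <- cbind(cells$x_um, cells$y_um)
  d <- cross_dist(xy[ly, , drop = FALSE], xy[tum, , drop = FALSE])
  tly <- ly[apply(d <= tumor_radius_um, 1L, any)]
  if (!length(tly))
    return(list(value = NA_real_, missing_reason = "no tumoral lymphocytes"))
  fd_ly <- box_fd(cells$x_um[tly], cells$y_um[tly], box_sizes)
  fd_tu <- box_fd(cells$x_um[tum], cells$y_um[tum], box_sizes)
  list(value = fd_ly - fd_tu, missing_reason = NULL)
}

## Translation-correction weights for a rectangular window.
.trans_weights <- function(dx, dy, W, H) {
  (W * H) / ((W - abs(dx)) * (H - abs(dy)))
}

#' Ripley's L at a fixed radius (translation-corrected)
#'
#' `L(r) = sqrt(K(r)/pi)` with the translation-corrected K estimator on a
#' rectangular window; under complete spatial randomness `L(r) = r` in
#' expectation.
#'
#' @param x,y point coordinates.
#' @param r radius (default 50 um).
#' @param window rectangular window `c(xmin, xmax, ymin, ymax)`.
#' @return L(r).
#' @export
ripleys_l <- function(x, y, r = 50, window) {
  n <- length(x)
  if (n < 2L) stopf("need at least 2 points")
  W <- window[2] - window[1]; H <- window[4] - window[3]
  area <- W * H
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  d <- sqrt(dx^2 + dy^2)
  sel <- upper.tri(d) & d <= r
  wts <- .trans_weights(dx[sel], dy[sel], W, H)
  K <- area * 2 * sum(wts) / (n * (n - 1))
  sqrt(K / pi)
}

#' Cross-type K (on the L scale) and G functions at a fixed radius
#'
#' `Lcross(r)` uses the translation-corrected cross-K double sum; under
#' independence of the two patterns its expectation is r. `Gcross(r)` is the
#' uncorrected empirical fraction of type-a points whose nearest type-b
#' neighbor lies within r.
#'
#' @param ax,ay,bx,by coordinates of the two point sets (both nonempty).
#' @param r radius (default 50).
#' @param window rectangular window `c(xmin, xmax, ymin, ymax)`.
#' @return list with `Kcross_L` and `Gcross`.
#' @export
cross_type_stats <- function(ax, ay, bx, by, r = 50, window) {
  na <- length(ax); nb <- length(bx)
  if (!na || !nb) stopf("both point sets must be nonempty")
  W <- window[2] - window[1]; H <- window[4] - window[3]
  area <- W * H
  dx <- outer(ax, bx, "-"); dy <- outer(ay, by, "-")
  d <- sqrt(dx^2 + dy^2)
  sel <- d <= r
  wts <- .trans_weights(dx[sel], dy[sel], W, H)
  K <- area * sum(wts) / (na * nb)
  g <- mean(apply(d, 1L, min) <= r)
  list(Kcross_L = sqrt(K / pi), Gcross = g)
}

## ------------------------------------------------ Delaunay (Bowyer-Watson)

.circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(c(0, 0, Inf))
  a2 <- a[1]^2 + a[2]^2; b2 <- b[1]^2 + b[2]^2; c2 <- c[1]^2 + c[2]^2
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

#' Delaunay triangulation edges (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation; returns the unique edges of the
#' final triangulation. Exactly cocircular configurations are resolved by
#' insertion order (either diagonal of a square is a valid Delaunay choice).
#'
#' @param x,y point coordinates (at least 3 points in general position).
#' @return two-column integer matrix of point-index pairs (i < j).
#' @export
delaunay_edges <- function(x, y) {
  n <- length(x)
  if (n < 3L) stopf("need at least 3 points")
  span <- max(diff(range(x)), diff(range(y)), 1)
  cx <- mean(range(x)); cy <- mean(range(y))
  P <- rbind(cbind(x, y),
             c(cx - 30 * span, cy - 10 * span),
             c(cx + 30 * span, cy - 10 * span),
             c(cx, cy + 30 * span))
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1L, 3L)
  cc <- matrix(.circumcircle(P[n + 1L, ], P[n + 2L, ], P[n + 3L, ]), 1L, 3L)
  for (i in seq_len(n)) {
    p <- P[i, ]
    d2 <- (p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2
    bad <- which(d2 < cc[, 3] * (1 - 1e-12) |
                   (is.infinite(cc[, 3]) & TRUE))
    if (!length(bad)) {
      ## numerical fallback: point on a circumcircle boundary
      bad <- which(d2 <= cc[, 3] * (1 + 1e-9))
    }
    edges <- rbind(tri[bad, c(1, 2), drop = FALSE],
                   tri[bad, c(2, 3), drop = FALSE],
                   tri[bad, c(1, 3), drop = FALSE])
    edges <- t(apply(edges, 1L, sort))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      t_new <- c(boundary[e, 1], boundary[e, 2], i)
      tri <- rbind(tri, t_new)
      cc <- rbind(cc, .circumcircle(P[t_new[1], ], P[t_new[2], ], P[t_new[3], ]))
    }
  }
  keep <- tri[apply(tri <= n, 1L, all), , drop = FALSE]
  if (!nrow(keep)) stopf("degenerate (collinear) point set")
  ed <- rbind(keep[, c(1, 2)], keep[, c(2, 3)], keep[, c(1, 3)])
  ed <- t(apply(ed, 1L, sort))
  unique(ed)
}

#' Voronoi-adjacency interaction statistic
#'
#' Adjacency between cells is realised as Delaunay edges (the dual of the
#' Voronoi tessellation) capped at `max_edge_um` to suppress hull artifacts;
#' the statistic is the number of adjacent pairs in which both cells carry
#' the positive flag, divided by the number of positive cells.
#'
#' @param table cell table.
#' @param positive logical vector (per cell) or the name of a logical
#'   column.
#' @param max_edge_um adjacency length cap (default 100).
#' @return list with `value` and `missing_reason`.
#' @export
voronoi_interactions <- function(table, positive, max_edge_um = 100) {
  cells <- as.data.frame(table)[!table$excluded, , drop = FALSE]
  if (is.character(positive) && length(positive) == 1L)
    positive <- cells[[positive]]
  else positive <- positive[!table$excluded]
  n <- nrow(cells)
  if (n < 4L) stopf("need at least 4 cells")
  xy <- cbind(cells$x_um, cells$y_um)
  if (qr(sweep(xy, 2L, colMeans(xy)))$rank < 2L)
    stopf("cells are collinear; Voronoi adjacency undefined")
  n_pos <- sum(positive)
  if (n_pos == 0)
    return(list(value = NA_real_, missing_reason = "no positive cells"))
  ed <- delaunay_edges(cells$x_um, cells$y_um)
  len <- sqrt((cells$x_um[ed[, 1]] - cells$x_um[ed[, 2]])^2 +
                (cells$y_um[ed[, 1]] - cells$y_um[ed[, 2]])^2)
  ed <- ed[len <= max_edge_um, , drop = FALSE]
  n_int <- sum(positive[ed[, 1]] & positive[ed[, 2]])
  list(value = n_int / n_pos, missing_reason = NULL)
}

## ------------------------------------------------------------ metric table

#' Assemble per-sample spatial metrics in long form
#'
#' Computes the standard metric panel for one sample: mean lineage neighbor
#' counts at 40 um, the 25 um tumor-immune mixing score, isolated-lymphocyte
#' fraction at 20 um, occupancy AUC and fractal-dimension difference over
#' the 10-300 um grid, Ripley's L(50) for immune cells, and cross-type
#' L/G(50) between epithelial and immune cells. Undefined metrics are
#' emitted as flagged rows with a reason and no value.
#'
#' @param table cell table (one sample).
#' @param sample sample_info (window bounds).
#' @param lymphocyte_types cell types treated as lymphocytes.
#' @return data frame `id`, `metric`, `params`, `value`, `missing_reason`.
#' @export
compute_spatial_metrics <- function(table, sample,
                                    lymphocyte_types = c("CD3 T", "CD20 B")) {
  rows <- list()
  add <- function(metric, params, value, reason = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = sample$sample_id, metric = metric, params = params,
      value = if (is.null(reason)) value else NA_real_,
      missing_reason = if (is.null(reason)) NA_character_ else reason,
      stringsAsFactors = FALSE)
  }
  g40 <- build_graph(table, 40)
  lin <- unique(stats::na.omit(g40$cells$lineage))
  for (a in lin) for (b in lin)
    add(sprintf("mean_neighbors|%s|%s", a, b), "r=40",
        mean_neighbors(g40, a, b, by = "lineage"))
  ms <- mixing_score(build_graph(table, 25))
  add("mixing_score", "r=25", ms$value, ms$missing_reason)
  il <- isolated_lymphocytes(table, lymphocyte_types)
  add("isolated_lymphocyte_fraction", "r=20",
      il$fraction, if (is.na(il$fraction)) "no tumoral lymphocytes" else NULL)
  for (cls in lymphocyte_types) {
    oc <- occupancy_auc(table, cls)
    add(sprintf("occupancy_auc|%s", cls), "s=10..300", oc$value,
        oc$missing_reason)
    fd <- fd_difference(table, cls)
    add(sprintf("fd_difference|%s", cls), "s=10..300", fd$value,
        fd$missing_reason)
  }
  win <- c(0, sample$field_width_um, 0, sample$field_height_um)
  imm <- table[!table$excluded & table$lineage == "immune", ]
  epi <- table[!table$excluded & table$lineage == "epithelial", ]
  if (nrow(imm) >= 2)
    add("ripleys_l|immune", "r=50", ripleys_l(imm$x_um, imm$y_um, 50, win))
  else add("ripleys_l|immune", "r=50", NA_real_, "insufficient cells")
  if (nrow(imm) >= 1 && nrow(epi) >= 1) {
    cs <- cross_type_stats(epi$x_um, epi$y_um, imm$x_um, imm$y_um, 50, win)
    add("kcross_l|epithelial|immune", "r=50", cs$Kcross_L)
    add("gcross|epithelial|immune", "r=50", cs$Gcross)
  } else {
    add("kcross_l|epithelial|immune", "r=50", NA_real_, "empty type set")
    add("gcross|epithelial|immune", "r=50", NA_real_, "empty type set")
  }
  out <- do.call(rbind, rows)
  dup <- duplicated(out[c("id", "metric", "params")])
  out[!dup, , drop = FALSE]
}

#' Pearson correlation between spatial metrics and cell-type abundance
#'
#' Pairwise-complete Pearson correlations (with two-sided p-values) between
#' each metric column and each abundance column over patients; pairs with
#' fewer than `min_n` complete observations are NA.
#'
#' @param metrics data frame/matrix of per-patient metric values (rows named
#'   or aligned with `composition`).
#' @param composition patient x cell-type abundance matrix.
#' @param min_n minimum complete pairs (default 3).
#' @return list of matrices `r` and `p` (metrics x abundances).
#' @export
metric_abundance_correlation <- function(metrics, composition, min_n = 3L) {
  metrics <- as.matrix(metrics); composition <- as.matrix(composition)
  if (nrow(metrics) != nrow(composition))
    stopf("metrics and composition must cover the same patients")
  r <- matrix(NA_real_, ncol(metrics), ncol(composition),
              dimnames = list(colnames(metrics), colnames(composition)))
  p <- r
  for (i in seq_len(ncol(metrics))) for (j in seq_len(ncol(composition))) {
    ok <- stats::complete.cases(metrics[, i], composition[, j])
    if (sum(ok) < min_n) next
    if (stats::sd(metrics[ok, i]) == 0 || stats::sd(composition[ok, j]) == 0)
      next
    ct <- stats::cor.test(metrics[ok, i], composition[ok, j])
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  list(r = r, p = p)
}
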