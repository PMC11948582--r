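test_that("radius graph contains all and only pairs within the radius", {
  tab <- make_cells(c(0, 40), c(0, 0))
  g <- build_graph(tab, 40)
  expect_equal(nrow(g$edges), 1L)          # inclusive boundary

  tab <- make_cells(c(0, 30, 60), c(0, 0, 0))
  g <- build_graph(tab, 40)
  expect_equal(unname(as.matrix(g$edges[, c("i", "j")])),
               matrix(c(1L, 2L, 2L, 3L), 2, 2, byrow = TRUE))

  g1 <- build_graph(make_cells(5, 5), 40)
  expect_equal(nrow(g1$edges), 0L)

  expect_error(build_graph(tab, 0), "radius")
})

test_that("graph matches the O(n^2) oracle on random fixtures", {
  for (seed in 1:5) {
    tab <- random_tissue_fixture(seed, 40, 120)
    g <- build_graph(tab, 40)
    ora <- oracle_edges(as.data.frame(tab), 40)
    got <- as.matrix(g$edges[, c("i", "j")])
    expect_equal(nrow(got), nrow(ora))
    expect_true(all(paste(got[, 1], got[, 2]) %in% paste(ora[, 1], ora[, 2])))
  }
})

test_that("mean typed neighbor counts follow the worked examples", {
  tab <- make_cells(c(0, 10, 5), c(0, 0, 8))       # mutually adjacent triangle
  expect_equal(mean_neighbors(build_graph(tab, 40), "CD3 T", "CD3 T"), 2)

  tab <- make_cells(c(0, 30, 60), c(0, 0, 0))
  expect_equal(mean_neighbors(build_graph(tab, 40), "CD3 T", "CD3 T"), 4 / 3)

  tab <- make_cells(c(0, 100), c(0, 0), cell_type = c("CD3 T", "CD20 B"))
  expect_equal(mean_neighbors(build_graph(tab, 40), "CD3 T", "CD20 B"), 0)
  expect_error(mean_neighbors(build_graph(tab, 40), "CD3 T", "CD20 B",
                              by = "lineage"), "no cell")
})

test_that("mixing score follows its definition and flags a zero denominator", {
  ## separated compartments: no hetero edges
  tab <- make_cells(c(0, 10, 100, 110), c(0, 0, 0, 0),
                    lineage = c("epithelial", "epithelial", "immune", "immune"),
                    cell_type = c("t", "t", "i", "i"))
  expect_equal(mixing_score(build_graph(tab, 25))$value, 0)

  ## 20 um square: 2 hetero edges / 1 immune-immune edge
  tab <- make_cells(c(0, 20, 0, 20), c(0, 0, 20, 20),
                    lineage = c("epithelial", "epithelial", "immune", "immune"),
                    cell_type = c("t", "t", "i", "i"))
  expect_equal(mixing_score(build_graph(tab, 25))$value, 2.0)

  ## no immune-immune edge -> flagged
  tab <- make_cells(c(0, 10), c(0, 0),
                    lineage = c("epithelial", "immune"),
                    cell_type = c("t", "i"))
  ms <- mixing_score(build_graph(tab, 25))
  expect_true(is.na(ms$value))
  expect_match(ms$missing_reason, "immune")
})

test_that("isolated tumoral lymphocytes follow the radius and count rules", {
  ## lone lymphocyte 15 um from tumor: tumoral and isolated
  tab <- make_cells(c(0, 15), c(0, 0),
                    lineage = c("epithelial", "immune"),
                    cell_type = c("t", "CD3 T"))
  il <- isolated_lymphocytes(tab)
  expect_equal(il$n_tumoral, 1L)
  expect_equal(il$n_isolated, 1L)

  ## clique of 6 pairwise-adjacent lymphocytes near tumor: none isolated
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  tab <- make_cells(c(0, 8 * cos(ang)), c(0, 8 * sin(ang)),
                    lineage = c("epithelial", rep("immune", 6)),
                    cell_type = c("t", rep("CD3 T", 6)))
  il <- isolated_lymphocytes(tab)
  expect_equal(il$n_tumoral, 6L)
  expect_equal(il$n_isolated, 0L)

  ## 25 um from nearest tumor: not tumoral
  tab <- make_cells(c(0, 25), c(0, 0),
                    lineage = c("epithelial", "immune"),
                    cell_type = c("t", "CD3 T"))
  expect_equal(isolated_lymphocytes(tab)$n_tumoral, 0L)
})

test_that("isolated-lymphocyte counts match the oracle on random fixtures", {
  for (seed in 6:9) {
    tab <- random_tissue_fixture(seed, 40, 150)
    got <- isolated_lymphocytes(tab)
    ora <- oracle_isolated(as.data.frame(tab))
    expect_equal(got$n_tumoral, unname(ora["n_tumoral"]))
    expect_equal(got$n_isolated, unname(ora["n_isolated"]))
  }
})

test_that("occupancy curve equals direct quadrat enumeration", {
  sizes <- seq(10, 100, by = 10)
  tab <- random_tissue_fixture(11, 60, 120, field = 200)
  got <- occupancy_auc(tab, c("CD3 T", "CD20 B"), box_sizes = sizes)
  ora <- oracle_occupancy_curve(as.data.frame(tab), c("CD3 T", "CD20 B"),
                                sizes)
  expect_equal(got$curve$occupancy, ora, tolerance = 1e-12)
  auc_ora <- sum(diff(sizes) * (head(ora, -1) + tail(ora, -1)) / 2) /
    (max(sizes) - min(sizes))
  expect_equal(got$value, auc_ora, tolerance = 1e-12)
})

test_that("occupancy is 1 when lymphocytes fill every occupied box", {
  ## every cell is a tumoral lymphocyte colocated with a tumor cell
  set.seed(2)
  x <- runif(80, 0, 200); y <- runif(80, 0, 200)
  tab <- make_cells(c(x, x), c(y, y),
                    lineage = rep(c("epithelial", "immune"), each = 80),
                    cell_type = rep(c("t", "CD3 T"), each = 80))
  expect_equal(occupancy_auc(tab, "CD3 T")$value, 1.0)
})

test_that("occupancy flags tissues without tumoral lymphocytes", {
  tab <- make_cells(c(0, 500), c(0, 500),
                    lineage = c("epithelial", "immune"),
                    cell_type = c("t", "CD3 T"))
  oc <- occupancy_auc(tab, "CD3 T")
  expect_true(is.na(oc$value))
  expect_match(oc$missing_reason, "tumoral")
})

test_that("box-counting dimension hits the space-filling and linear limits", {
  set.seed(3)
  n <- 20000                      # dense enough to occupy every 10 um box
  x <- runif(n, 0, 500); y <- runif(n, 0, 500)
  expect_equal(box_fd(x, y, seq(10, 300, 10)), 2, tolerance = 0.15 / 2)

  t <- runif(2000, 0, 1000)
  expect_equal(box_fd(t, 0.3 * t + 5, seq(10, 300, 10)), 1,
               tolerance = 0.15 / 1)
})

test_that("fd difference is near zero for exchangeable point processes", {
  set.seed(4)
  diffs <- replicate(50, {
    n <- 300                      # dense: nearly every lymphocyte is tumoral
    tab <- make_cells(runif(2 * n, 0, 300), runif(2 * n, 0, 300),
                      lineage = rep(c("epithelial", "immune"), each = n),
                      cell_type = rep(c("t", "CD3 T"), each = n))
    fd_difference(tab, "CD3 T")$value
  })
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.1)
})

test_that("fd difference applies the intact-tissue and lymphocyte guards", {
  tab <- make_cells(c(0, 5), c(0, 5),
                    lineage = c("epithelial", "immune"),
                    cell_type = c("t", "CD3 T"))
  fd <- fd_difference(tab, "CD3 T")
  expect_true(is.na(fd$value))
  expect_match(fd$missing_reason, "tissue")
})

test_that("Ripley's L matches the brute-force oracle and detects inhibition", {
  ## printed 5-point set in a 200x200 window
  x <- c(10, 50, 90, 150, 170); y <- c(20, 160, 80, 40, 120)
  win <- c(0, 200, 0, 200)
  expect_equal(ripleys_l(x, y, 50, win), oracle_ripley_l(x, y, 50, win),
               tolerance = 1e-12)

  ## hard-core pattern with 60 um minimum spacing: L(50) < 50
  set.seed(5)
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < 60) {
    p <- runif(2, 0, 1000)
    if (!nrow(pts) || min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) > 60)
      pts <- rbind(pts, p)
  }
  expect_lt(ripleys_l(pts[, 1], pts[, 2], 50, c(0, 1000, 0, 1000)), 50)

  expect_error(ripleys_l(1, 1, 50, win), "at least 2")
})

test_that("cross-type K and G match the oracle and saturate correctly", {
  win <- c(0, 200, 0, 200)
  ax <- c(20, 100, 180); ay <- c(30, 90, 150)
  bx <- c(60, 140); by <- c(50, 160)
  got <- cross_type_stats(ax, ay, bx, by, 50, win)
  ora <- oracle_cross(ax, ay, bx, by, 50, win)
  expect_equal(got$Kcross_L, ora$Kcross_L, tolerance = 1e-12)
  expect_equal(got$Gcross, ora$Gcross, tolerance = 1e-12)

  ## every a within 10 um of a b -> Gcross(50) = 1
  got <- cross_type_stats(ax, ay, ax + 5, ay, 50, win)
  expect_equal(got$Gcross, 1.0)

  expect_error(cross_type_stats(numeric(0), numeric(0), bx, by, 50, win),
               "nonempty")
})

test_that("Delaunay edges match the exhaustive circumcircle oracle", {
  for (seed in 12:15) {
    set.seed(seed)
    n <- 30
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    got <- delaunay_edges(x, y)
    ora <- oracle_delaunay_edges(x, y)
    key <- function(e) sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    expect_equal(key(got), key(ora))
  }
})

test_that("Voronoi interaction statistic follows the worked examples", {
  ## unit square, all positive: 5 Delaunay edges / 4 cells
  tab <- make_cells(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(voronoi_interactions(tab, rep(TRUE, 4))$value, 1.25)

  vi <- voronoi_interactions(tab, rep(FALSE, 4))
  expect_true(is.na(vi$value))
  expect_match(vi$missing_reason, "positive")

  ## positives pairwise farther than the cap -> 0
  tab <- make_cells(c(0, 300, 0, 300), c(0, 0, 300, 300))
  expect_equal(voronoi_interactions(tab, rep(TRUE, 4), max_edge_um = 100)$value,
               0)
})

test_that("metric-abundance correlations hit the degenerate limits", {
  set.seed(6)
  ab <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  met <- cbind(same = ab[, 1], anti = -ab[, 2])
  out <- metric_abundance_correlation(met, ab)
  expect_equal(out$r["same", "a"], 1, tolerance = 1e-12)
  expect_equal(out$r["anti", "b"], -1, tolerance = 1e-12)

  ## independent columns give uniform p-values
  set.seed(7)
  ps <- replicate(200, {
    m <- cbind(x = rnorm(15)); a <- cbind(y = rnorm(15))
    metric_abundance_correlation(m, a)$p[1, 1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("spatial statistics are invariant under rigid translation", {
  tab <- random_tissue_fixture(20, 80, 150)
  shift <- function(t, dx, dy) { t$x_um <- t$x_um + dx; t$y_um <- t$y_um + dy; t }
  t2 <- shift(tab, 37.5, 81.2)
  expect_equal(mixing_score(build_graph(tab, 25))$value,
               mixing_score(build_graph(t2, 25))$value)
  expect_equal(isolated_lymphocytes(tab)$fraction,
               isolated_lymphocytes(t2)$fraction)
  expect_equal(mean_neighbors(build_graph(tab, 40), "CD3 T", "luminal tumor"),
               mean_neighbors(build_graph(t2, 40), "CD3 T", "luminal tumor"))
})

test_that("grid-anchored metrics shift boundedly under a half-box origin move", {
  tab <- random_tissue_fixture(21, 150, 250, field = 400)
  a <- occupancy_auc(tab, c("CD3 T", "CD20 B"))$value
  b <- occupancy_auc(tab, c("CD3 T", "CD20 B"), origin = c(-5, -5))$value
  expect_lt(abs(a - b), 0.15)
  fa <- fd_difference(tab, c("CD3 T", "CD20 B"))$value
  fb <- fd_difference(tab, c("CD3 T", "CD20 B"),
                      box_sizes = seq(10, 300, 10))$value
  expect_equal(fa, fb)
})

test_that("the long-format metric table is unique and flags missing values", {
  tab <- random_tissue_fixture(22, 80, 150)
  info <- sample_info("s1", "p1", field_width_um = 300, field_height_um = 300)
  m <- compute_spatial_metrics(tab, info)
  expect_false(any(duplicated(m[c("id", "metric", "params")])))
  expect_true(all(is.na(m$value) == !is.na(m$missing_reason)))
})
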