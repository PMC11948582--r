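## Shared fixture builders and independent brute-force oracles. Oracles are
## deliberately written as plain double loops so they share no code with the
## package implementations they check.

make_cells <- function(x, y, cell_type = "CD3 T", lineage = "immune",
                       sample_id = "s1", patient_id = "p1",
                       excluded = FALSE) {
  n <- length(x)
  cell_table(data.frame(
    cell_id = seq_len(n), sample_id = rep(sample_id, n),
    patient_id = rep(patient_id, n),
    x_um = x, y_um = y, nuclear_area_um2 = rep(30, n),
    eccentricity = rep(0.2, n),
    lineage = rep_len(lineage, n), cell_type = rep_len(cell_type, n),
    excluded = rep_len(excluded, n), stringsAsFactors = FALSE))
}

random_tissue_fixture <- function(seed, n_min = 50, n_max = 300,
                                  field = 300) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  types <- data.frame(
    cell_type = c("luminal tumor", "CD3 T", "CD20 B", "Vim+ fibroblast",
                  "quiescent stroma"),
    lineage = c("epithelial", "immune", "immune", "fibroblast", "stromal"),
    stringsAsFactors = FALSE)
  pick <- sample(nrow(types), n, replace = TRUE,
                 prob = c(0.4, 0.2, 0.1, 0.15, 0.15))
  make_cells(runif(n, 0, field), runif(n, 0, field),
             cell_type = types$cell_type[pick],
             lineage = types$lineage[pick])
}

## ---- oracles -------------------------------------------------------------

oracle_edges <- function(tab, r) {
  tab <- tab[!tab$excluded, ]
  out <- matrix(0L, 0, 2)
  n <- nrow(tab)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((tab$x_um[i] - tab$x_um[j])^2 + (tab$y_um[i] - tab$y_um[j])^2)
    if (d <= r) out <- rbind(out, c(i, j))
  }
  out
}

oracle_mean_neighbors <- function(tab, r, a, b, by = "cell_type") {
  tab <- tab[!tab$excluded, ]
  ia <- which(tab[[by]] == a)
  cnt <- numeric(length(ia))
  for (k in seq_along(ia)) {
    i <- ia[k]
    for (j in seq_len(nrow(tab))) {
      if (j == i || is.na(tab[[by]][j]) || tab[[by]][j] != b) next
      d <- sqrt((tab$x_um[i] - tab$x_um[j])^2 + (tab$y_um[i] - tab$y_um[j])^2)
      if (d <= r) cnt[k] <- cnt[k] + 1
    }
  }
  mean(cnt)
}

oracle_mixing <- function(tab, r = 25) {
  tab <- tab[!tab$excluded, ]
  het <- 0L; hom <- 0L
  n <- nrow(tab)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((tab$x_um[i] - tab$x_um[j])^2 + (tab$y_um[i] - tab$y_um[j])^2)
    if (d > r) next
    li <- tab$lineage[i]; lj <- tab$lineage[j]
    if ((li == "epithelial" && lj == "immune") ||
        (li == "immune" && lj == "epithelial")) het <- het + 1L
    if (li == "immune" && lj == "immune") hom <- hom + 1L
  }
  if (hom == 0) NA_real_ else het / hom
}

oracle_isolated <- function(tab, lymph = c("CD3 T", "CD20 B"), r = 20,
                            k_iso = 5) {
  tab <- tab[!tab$excluded, ]
  ly <- which(tab$cell_type %in% lymph)
  tum <- which(tab$lineage == "epithelial")
  n_t <- 0L; n_i <- 0L
  for (i in ly) {
    tumoral <- FALSE
    for (j in tum) {
      d <- sqrt((tab$x_um[i] - tab$x_um[j])^2 + (tab$y_um[i] - tab$y_um[j])^2)
      if (d <= r) { tumoral <- TRUE; break }
    }
    if (!tumoral) next
    n_t <- n_t + 1L
    nn <- 0L
    for (j in ly) {
      if (j == i) next
      d <- sqrt((tab$x_um[i] - tab$x_um[j])^2 + (tab$y_um[i] - tab$y_um[j])^2)
      if (d <= r) nn <- nn + 1L
    }
    if (nn < k_iso) n_i <- n_i + 1L
  }
  c(n_tumoral = n_t, n_isolated = n_i)
}

## direct quadrat enumeration over explicit box loops
oracle_occupancy_curve <- function(tab, cls, sizes, tumor_r = 20) {
  tab <- tab[!tab$excluded, ]
  ly <- which(tab$cell_type %in% cls)
  tum <- which(tab$lineage == "epithelial")
  tly <- integer(0)
  for (i in ly) for (j in tum) {
    d <- sqrt((tab$x_um[i] - tab$x_um[j])^2 + (tab$y_um[i] - tab$y_um[j])^2)
    if (d <= tumor_r) { tly <- c(tly, i); break }
  }
  vapply(sizes, function(s) {
    maxb <- ceiling(max(tab$x_um, tab$y_um) / s) + 1
    n_ly <- 0L; n_all <- 0L
    for (bx in 0:maxb) for (by in 0:maxb) {
      inbox <- tab$x_um >= bx * s & tab$x_um < (bx + 1) * s &
        tab$y_um >= by * s & tab$y_um < (by + 1) * s
      if (any(inbox)) n_all <- n_all + 1L
      if (any(which(inbox) %in% tly)) n_ly <- n_ly + 1L
    }
    n_ly / n_all
  }, numeric(1))
}

oracle_ripley_l <- function(x, y, r, win) {
  n <- length(x)
  W <- win[2] - win[1]; H <- win[4] - win[3]
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (sqrt(dx^2 + dy^2) <= r)
      acc <- acc + (W * H) / ((W - abs(dx)) * (H - abs(dy)))
  }
  K <- W * H * acc / (n * (n - 1))
  sqrt(K / pi)
}

oracle_cross <- function(ax, ay, bx, by, r, win) {
  na <- length(ax); nb <- length(bx)
  W <- win[2] - win[1]; H <- win[4] - win[3]
  acc <- 0; ghit <- 0L
  for (i in seq_len(na)) {
    nn <- Inf
    for (j in seq_len(nb)) {
      dx <- ax[i] - bx[j]; dy <- ay[i] - by[j]
      d <- sqrt(dx^2 + dy^2)
      nn <- min(nn, d)
      if (d <= r)
        acc <- acc + (W * H) / ((W - abs(dx)) * (H - abs(dy)))
    }
    if (nn <= r) ghit <- ghit + 1L
  }
  list(Kcross_L = sqrt((W * H * acc / (na * nb)) / pi),
       Gcross = ghit / na)
}

## Delaunay edge set by exhaustive empty-circumcircle test (O(n^4)); valid
## for points in general position.
oracle_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- matrix(0L, 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    empty <- TRUE
    for (m in seq_len(n)) {
      if (m %in% c(i, j, k)) next
      if ((x[m] - ux)^2 + (y[m] - uy)^2 < r2 * (1 - 1e-12)) {
        empty <- FALSE; break
      }
    }
    if (empty)
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  unique(edges)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## Direct (tissue-free) survival cohort for framework tests: metric columns
## are independent normals; the first carries the planted log hazard ratio
## through a median split.
sim_surv_cohort <- function(n, beta, n_metrics = 5, censoring = 0.2,
                            platforms = c("CycIF", "IMC"), seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n))
  met <- matrix(rnorm(n * n_metrics), n, n_metrics)
  colnames(met) <- paste0("m", seq_len(n_metrics))
  hi <- met[, 1] > median(met[, 1])
  rate <- 0.012 * exp(beta * hi)
  t_event <- rexp(n, rate)
  if (censoring > 0) {
    t_c <- pmin(rexp(n, 0.012 * censoring / (1 - censoring)), 120)
  } else t_c <- rep(Inf, n)
  clin <- data.frame(
    patient_id = ids,
    platform = sample(platforms, n, replace = TRUE),
    subtype = "TNBC",
    os_time = pmax(pmin(t_event, t_c), 1e-6),
    os_event = as.integer(t_event <= t_c),
    rfs_time = pmax(pmin(t_event * runif(n, 0.6, 1), t_c), 1e-6),
    rfs_event = as.integer(t_event <= t_c),
    age_years = round(rnorm(n, 60, 10)),
    tumor_size = round(exp(rnorm(n, log(20), 0.4)), 1),
    stage = sample(1:3, n, replace = TRUE),
    stringsAsFactors = FALSE)
  list(metrics = data.frame(patient_id = ids, met, stringsAsFactors = FALSE),
       clinical = clin)
}

## Document fixture drawn from known topic-type distributions; anchors get
## spatial positions so the coupling penalty has a geometry to act on.
topic_docs <- function(D = 600, n_words = 40, topics = NULL, smooth = FALSE,
                       seed = 1, field = 500) {
  set.seed(seed)
  if (is.null(topics)) {
    topics <- rbind(c(0.60, 0.30, 0.05, 0.02, 0.02, 0.01),
                    c(0.02, 0.05, 0.55, 0.30, 0.05, 0.03),
                    c(0.03, 0.02, 0.05, 0.05, 0.35, 0.50))
  }
  K <- nrow(topics); V <- ncol(topics)
  x <- runif(D, 0, field); y <- runif(D, 0, field)
  if (smooth) {
    ## topic mixture varies smoothly with x so neighbors share topics
    w <- sapply(seq_len(K), function(k)
      exp(-((x / field) - (k - 1) / (K - 1))^2 / 0.08))
    th <- w / rowSums(w)
  } else {
    th <- t(rmultinom(D, 1, rep(1 / K, K)))
    th <- 0.85 * th + 0.15 * matrix(1 / K, D, K)
  }
  N <- t(vapply(seq_len(D), function(d)
    rmultinom(1, n_words, as.numeric(th[d, ] %*% topics))[, 1],
    integer(V)))
  colnames(N) <- paste0("type", seq_len(V))
  structure(list(counts = N,
                 anchors = data.frame(cell_id = seq_len(D),
                                      patient_id = "p1", x_um = x, y_um = y),
                 empty = rowSums(N) == 0L, radius_um = 100),
            class = "neighborhood_documents")
}
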