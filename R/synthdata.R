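## Synthetic tissues, images and cohorts with known ground truth.
##
## The generators exist so that every downstream stage -- phenotyping, spatial
## statistics, neighborhood topic models, and the discovery/validation survival
## framework -- can be exercised against planted truth without any external
## imaging data.

LINEAGES <- c("epithelial", "immune", "fibroblast", "endothelial", "stromal")
PLATFORMS <- c("CycIF", "IMC", "MIBI")
SUBTYPES <- c("ER+", "TNBC", "HER2+")

## ---------------------------------------------------------------- cell table

#' Construct / validate a single-cell table
#'
#' A CellTable is a plain data frame with one row per segmented cell:
#' `cell_id` (unique within sample), `sample_id`, `patient_id`, centroid
#' `x_um`/`y_um` in micrometers (origin top-left, y increasing downward),
#' `nuclear_area_um2`, `eccentricity`, `lineage` (one of epithelial, immune,
#' fibroblast, endothelial, stromal, or NA), `cell_type`, `excluded`, plus
#' one intensity column per marker/compartment named `<marker>_<compartment>`.
#'
#' @param df data frame carrying at least the core columns.
#' @return the validated data frame (classed `cell_table`).
#' @export
cell_table <- function(df) {
  core <- c("cell_id", "sample_id", "patient_id", "x_um", "y_um",
            "nuclear_area_um2", "eccentricity", "lineage", "cell_type",
            "excluded")
  missing <- setdiff(core, names(df))
  if (length(missing)) stopf("cell table lacks columns: %s",
                             paste(missing, collapse = ", "))
  if (nrow(df)) {
    if (anyNA(df$x_um) || anyNA(df$y_um) ||
        any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
      stopf("cell centroids must be finite")
    if (any(df$nuclear_area_um2 < 0, na.rm = TRUE))
      stopf("nuclear areas must be nonnegative")
    set <- !is.na(df$lineage)
    if (any(!(df$lineage[set] %in% LINEAGES)))
      stopf("lineage labels must be one of: %s", paste(LINEAGES, collapse = ", "))
    dup <- duplicated(df[c("sample_id", "cell_id")])
    if (any(dup)) stopf("cell_id values must be unique within a sample")
  }
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Per-sample acquisition metadata
#'
#' @param sample_id,patient_id identifiers.
#' @param platform one of CycIF, IMC, MIBI.
#' @param subtype clinical subtype (ER+, TNBC, HER2+).
#' @param tma_id tissue-microarray identifier.
#' @param pixel_size_um pixel size in micrometers (> 0); platform defaults are
#'   0.325 (CycIF), 1.0 (IMC) and 0.5 (MIBI).
#' @param field_width_um,field_height_um field of view in micrometers.
#' @param exclusion_polygons list of closed polygons (matrices with columns
#'   x, y, in micrometers) marking regions whose cells are excluded.
#' @return a `sample_info` list.
#' @export
sample_info <- function(sample_id, patient_id, platform = "CycIF",
                        subtype = "TNBC", tma_id = "TMA1",
                        pixel_size_um = NULL,
                        field_width_um = 600, field_height_um = 600,
                        exclusion_polygons = list()) {
  platform <- match.arg(platform, PLATFORMS)
  subtype <- match.arg(subtype, SUBTYPES)
  if (is.null(pixel_size_um))
    pixel_size_um <- c(CycIF = 0.325, IMC = 1.0, MIBI = 0.5)[[platform]]
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  if (field_width_um <= 0 || field_height_um <= 0)
    stopf("field dimensions must be positive (zero-area field rejected)")
  for (p in exclusion_polygons) {
    if (any(p[, 1] < 0 | p[, 1] > field_width_um |
            p[, 2] < 0 | p[, 2] > field_height_um))
      stopf("exclusion polygons must lie within the field bounds")
  }
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 platform = platform, subtype = subtype, tma_id = tma_id,
                 pixel_size_um = pixel_size_um,
                 field_width_um = field_width_um,
                 field_height_um = field_height_um,
                 exclusion_polygons = exclusion_polygons),
            class = "sample_info")
}

## ------------------------------------------------------------- tissue spec

#' Default synthetic cell-type mix
#'
#' One row per cell type: lineage, expected density (cells per square
#' micrometer of the type's region), placement process (`"poisson"` for
#' complete spatial randomness or `"thomas"` for a Poisson-parent /
#' Gaussian-offspring cluster process) and region (`"tumor"` for the nest
#' discs, `"stroma"` for their complement, `"any"`). Densities are of the
#' order seen in packed tissue (~1 cell per 20 um square overall).
#'
#' @return data frame of cell-type parameters.
#' @export
default_cell_types <- function() {
  data.frame(
    cell_type = c("luminal tumor", "luminal ER+ tumor", "CD3 T", "CD20 B",
                  "macrophage", "Vim+ fibroblast", "quiescent stroma",
                  "endothelial"),
    lineage = c("epithelial", "epithelial", "immune", "immune", "immune",
                "fibroblast", "stromal", "endothelial"),
    density = c(0.0020, 0.0008, 0.0007, 0.00025, 0.00025, 0.0009, 0.0009,
                0.00025),
    placement = c("poisson", "poisson", "thomas", "thomas", "poisson",
                  "poisson", "poisson", "thomas"),
    region = c("tumor", "tumor", "stroma", "stroma", "stroma", "stroma",
               "stroma", "stroma"),
    thomas_mean_offspring = 8,
    thomas_sigma_um = 15,
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic tissue
#'
#' Describes a bounded 2-D tissue: field geometry, tumor-nest compartments,
#' per-type densities and placement processes, and planted spatial effects.
#' `mixing` in \[0,1\] controls tumor-immune intermixing (0 plants complete
#' separation: no tumor cell within 25 um of an immune cell); when
#' `isolated_fraction` is set, lymphocytes are planted near tumor either as
#' spaced singletons (isolated: fewer than 5 lymphocyte neighbors within
#' 20 um) or as dense cliques, in that proportion.
#'
#' @param field_width_um,field_height_um field size in micrometers.
#' @param cell_types data frame as from [default_cell_types()].
#' @param n_tumor_nests,nest_radius_um tumor-nest disc geometry.
#' @param mixing planted tumor-immune mixing level in \[0,1\], or NULL to
#'   leave immune placement to its stated process.
#' @param isolated_fraction optional planted fraction of tumoral lymphocytes
#'   that are isolated.
#' @param platform,subtype,tma_id,pixel_size_um,exclusion_polygons passed to
#'   [sample_info()].
#' @return a `tissue_spec` list.
#' @export
tissue_spec <- function(field_width_um = 600, field_height_um = 600,
                        cell_types = default_cell_types(),
                        n_tumor_nests = 3, nest_radius_um = 110,
                        mixing = NULL, isolated_fraction = NULL,
                        platform = "CycIF", subtype = "TNBC", tma_id = "TMA1",
                        pixel_size_um = NULL, exclusion_polygons = list()) {
  if (field_width_um <= 0 || field_height_um <= 0)
    stopf("degenerate geometry: field must have positive area")
  stopifnot(is.data.frame(cell_types))
  need <- c("cell_type", "lineage", "density", "placement", "region")
  missing <- setdiff(need, names(cell_types))
  if (length(missing)) stopf("cell_types lacks columns: %s",
                             paste(missing, collapse = ", "))
  if (any(cell_types$density < 0)) stopf("densities must be nonnegative")
  if (!is.null(mixing) && (mixing < 0 || mixing > 1))
    stopf("mixing must be in [0, 1]")
  if (!is.null(isolated_fraction) &&
      (isolated_fraction < 0 || isolated_fraction > 1))
    stopf("isolated_fraction must be in [0, 1]")
  structure(list(field_width_um = field_width_um,
                 field_height_um = field_height_um,
                 cell_types = cell_types,
                 n_tumor_nests = n_tumor_nests,
                 nest_radius_um = nest_radius_um,
                 mixing = mixing, isolated_fraction = isolated_fraction,
                 platform = platform, subtype = subtype, tma_id = tma_id,
                 pixel_size_um = pixel_size_um,
                 exclusion_polygons = exclusion_polygons),
            class = "tissue_spec")
}

## Region membership and area (area of disc-union by a 2-um grid sum).
.nest_centers <- function(spec) {
  k <- spec$n_tumor_nests
  if (k < 1) return(matrix(numeric(0), 0, 2))
  m <- min(spec$nest_radius_um, spec$field_width_um / 2,
           spec$field_height_um / 2)
  cbind(stats::runif(k, m, spec$field_width_um - m),
        stats::runif(k, m, spec$field_height_um - m))
}

.in_tumor_region <- function(x, y, nests, r) {
  if (nrow(nests) == 0) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(nests)))
    inside <- inside | ((x - nests[i, 1])^2 + (y - nests[i, 2])^2 <= r^2)
  inside
}

.tumor_fraction <- function(spec, nests) {
  if (nrow(nests) == 0) return(0)
  step <- max(min(spec$field_width_um, spec$field_height_um) / 100, 1)
  gx <- seq(step / 2, spec$field_width_um, by = step)
  gy <- seq(step / 2, spec$field_height_um, by = step)
  inside <- rep(FALSE, length(gx) * length(gy))
  X <- rep(gx, times = length(gy)); Y <- rep(gy, each = length(gx))
  mean(.in_tumor_region(X, Y, nests, spec$nest_radius_um))
}

.region_area <- function(spec, nests, region, tumor_frac = NULL) {
  A <- spec$field_width_um * spec$field_height_um
  if (region == "any") return(A)
  frac <- tumor_frac %||% .tumor_fraction(spec, nests)
  if (region == "tumor") A * frac else A * (1 - frac)
}

## Rejection-sample n uniform points inside a region.
.sample_region <- function(n, spec, nests, region) {
  out <- matrix(numeric(0), 0, 2)
  guard <- 0L
  while (nrow(out) < n && guard < 200L) {
    m <- max(2L * (n - nrow(out)), 32L)
    x <- stats::runif(m, 0, spec$field_width_um)
    y <- stats::runif(m, 0, spec$field_height_um)
    keep <- switch(region,
      any = rep(TRUE, m),
      tumor = .in_tumor_region(x, y, nests, spec$nest_radius_um),
      stroma = !.in_tumor_region(x, y, nests, spec$nest_radius_um))
    out <- rbind(out, cbind(x[keep], y[keep]))
    guard <- guard + 1L
  }
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}

.thomas_points <- function(expected_n, spec, nests, region, mu, sigma,
                           tumor_frac = NULL) {
  area <- .region_area(spec, nests, region, tumor_frac)
  if (area <= 0 || expected_n <= 0) return(matrix(numeric(0), 0, 2))
  kappa <- expected_n / (mu * area)
  n_par <- stats::rpois(1L, kappa * area)
  if (n_par == 0) return(matrix(numeric(0), 0, 2))
  parents <- .sample_region(n_par, spec, nests, region)
  pts <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(parents))) {
    k <- stats::rpois(1L, mu)
    if (k == 0) next
    px <- stats::rnorm(k, parents[i, 1], sigma)
    py <- stats::rnorm(k, parents[i, 2], sigma)
    ok <- px >= 0 & px <= spec$field_width_um &
      py >= 0 & py <= spec$field_height_um
    if (region != "any") {
      inr <- .in_tumor_region(px, py, nests, spec$nest_radius_um)
      ok <- ok & if (region == "tumor") inr else !inr
    }
    pts <- rbind(pts, cbind(px[ok], py[ok]))
  }
  pts
}

#' Generate a synthetic tissue
#'
#' Realises a [tissue_spec()] as a cell table plus sample metadata. The
#' result is deterministic for a fixed seed; counts are Poisson with mean
#' density x region area; every cell carries its ground-truth cell type and
#' lineage. Planted effects: at `mixing = 0` no tumor cell lies within 25 um
#' of an immune cell; at `mixing = 1` immune cells are packed against tumor
#' cells; `isolated_fraction` plants the stated fraction of tumoral
#' lymphocytes as isolated singletons.
#'
#' @param spec a `tissue_spec`.
#' @param seed integer seed.
#' @param sample_id,patient_id identifiers for the generated sample.
#' @return list with `table` (cell_table) and `sample` (sample_info).
#' @export
generate_tissue <- function(spec, seed, sample_id = "S1", patient_id = "P1") {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(seed)
  nests <- .nest_centers(spec)
  tumor_frac <- .tumor_fraction(spec, nests)
  ct <- spec$cell_types
  xs <- list()
  for (i in seq_len(nrow(ct))) {
    region <- ct$region[i]
    area <- .region_area(spec, nests, region, tumor_frac)
    lam <- ct$density[i] * area
    if (ct$placement[i] == "thomas") {
      mu <- ct$thomas_mean_offspring[i] %||% 8
      sg <- ct$thomas_sigma_um[i] %||% 15
      pts <- .thomas_points(lam, spec, nests, region, mu, sg, tumor_frac)
    } else {
      n <- stats::rpois(1L, lam)
      pts <- .sample_region(n, spec, nests, region)
    }
    if (nrow(pts))
      xs[[length(xs) + 1L]] <- data.frame(
        x_um = pts[, 1], y_um = pts[, 2],
        cell_type = ct$cell_type[i], lineage = ct$lineage[i],
        stringsAsFactors = FALSE)
  }
  df <- if (length(xs)) do.call(rbind, xs) else
    data.frame(x_um = numeric(0), y_um = numeric(0),
               cell_type = character(0), lineage = character(0),
               stringsAsFactors = FALSE)

  df <- .apply_mixing(df, spec)
  df <- .apply_isolation(df, spec)

  n <- nrow(df)
  df$cell_id <- seq_len(n)
  df$sample_id <- rep(sample_id, n)
  df$patient_id <- rep(patient_id, n)
  df$nuclear_area_um2 <- if (n) exp(stats::rnorm(n, log(30), 0.2)) else numeric(0)
  df$eccentricity <- if (n) stats::rbeta(n, 2, 2) else numeric(0)
  df$excluded <- rep(FALSE, n)
  df <- df[c("cell_id", "sample_id", "patient_id", "x_um", "y_um",
             "nuclear_area_um2", "eccentricity", "lineage", "cell_type",
             "excluded")]
  info <- sample_info(sample_id, patient_id, platform = spec$platform,
                      subtype = spec$subtype, tma_id = spec$tma_id,
                      pixel_size_um = spec$pixel_size_um,
                      field_width_um = spec$field_width_um,
                      field_height_um = spec$field_height_um,
                      exclusion_polygons = spec$exclusion_polygons)
  list(table = cell_table(df), sample = info)
}

## Reposition immune cells according to the planted mixing level.
.apply_mixing <- function(df, spec) {
  if (is.null(spec$mixing) || !nrow(df)) return(df)
  tum <- df[df$lineage == "epithelial", c("x_um", "y_um")]
  imm <- which(df$lineage == "immune")
  if (!nrow(tum) || !length(imm)) return(df)
  ## The dial acts through two monotone mechanisms: an exclusion buffer of
  ## 25 * (1 - m) um around tumor cells applied to non-attracted immune
  ## cells, and an attracted fraction m/2 re-placed around random tumor
  ## cells with a 15-um Gaussian kernel. At m = 0 this yields complete
  ## separation (no tumor cell within 25 um of an immune cell); at m = 1
  ## immune cells intermix freely and pack against the tumor compartment.
  m <- spec$mixing
  txy <- cbind(tum$x_um, tum$y_um)
  nearest_tumor <- function(px, py)
    apply(cross_dist(cbind(px, py), txy), 1L, min)
  near <- stats::runif(length(imm)) < m / 2
  ni <- imm[near]
  if (length(ni)) {
    j <- sample.int(nrow(txy), length(ni), replace = TRUE)
    df$x_um[ni] <- pmin(pmax(stats::rnorm(length(ni), txy[j, 1], 15), 0),
                        spec$field_width_um)
    df$y_um[ni] <- pmin(pmax(stats::rnorm(length(ni), txy[j, 2], 15), 0),
                        spec$field_height_um)
  }
  buffer <- 25 * (1 - m)
  fi <- imm[!near]
  if (length(fi) && buffer > 0) {
    bad <- fi[nearest_tumor(df$x_um[fi], df$y_um[fi]) <= buffer]
    guard <- 0L
    while (length(bad) && guard < 200L) {
      xx <- stats::runif(length(bad), 0, spec$field_width_um)
      yy <- stats::runif(length(bad), 0, spec$field_height_um)
      ok <- nearest_tumor(xx, yy) > buffer
      df$x_um[bad[ok]] <- xx[ok]
      df$y_um[bad[ok]] <- yy[ok]
      bad <- bad[!ok]
      guard <- guard + 1L
    }
    if (length(bad)) df <- df[-bad, , drop = FALSE]
  }
  df
}

## Plant isolated vs clique lymphocytes near tumor cells.
.apply_isolation <- function(df, spec) {
  if (is.null(spec$isolated_fraction) || !nrow(df)) return(df)
  lymph_types <- c("CD3 T", "CD20 B")
  tum <- df[df$lineage == "epithelial", c("x_um", "y_um")]
  ly <- which(df$cell_type %in% lymph_types)
  if (!nrow(tum) || !length(ly)) return(df)
  n_iso <- round(spec$isolated_fraction * length(ly))
  placed <- matrix(numeric(0), 0, 2)
  place_near_tumor <- function(sd) {
    j <- sample.int(nrow(tum), 1L)
    repeat {
      x <- stats::rnorm(1, tum$x_um[j], sd)
      y <- stats::rnorm(1, tum$y_um[j], sd)
      if (x >= 0 && x <= spec$field_width_um &&
          y >= 0 && y <= spec$field_height_um &&
          min((tum$x_um - x)^2 + (tum$y_um - y)^2) <= 15^2)
        return(c(x, y))
    }
  }
  k <- 0L
  for (i in ly) {
    k <- k + 1L
    if (k <= n_iso) {
      ## spaced singleton: > 20 um from all previously placed lymphocytes
      guard <- 0L
      repeat {
        p <- place_near_tumor(10)
        guard <- guard + 1L
        if (!nrow(placed) ||
            min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) > 22^2 ||
            guard > 500L) break
      }
    } else {
      ## clique member: within 8 um of an existing clique anchor
      if (k == n_iso + 1L || stats::runif(1) < 0.15) {
        p <- place_near_tumor(10)   # new clique anchor
        anchor <- p
      } else {
        p <- anchor + stats::rnorm(2, 0, 5)
        p[1] <- min(max(p[1], 0), spec$field_width_um)
        p[2] <- min(max(p[2], 0), spec$field_height_um)
      }
    }
    placed <- rbind(placed, p)
    df$x_um[i] <- p[1]; df$y_um[i] <- p[2]
  }
  df
}

## ------------------------------------------------------------- intensities

#' Default marker panel
#'
#' Marker names with the compartment used for quantification (nucleus or
#' cytoplasm), reflecting expected subcellular distribution.
#'
#' @return data frame with columns `marker` and `compartment`.
#' @export
default_panel <- function() {
  data.frame(
    marker = c("DNA", "Ecad", "panCK", "CD45", "CD3", "CD20", "CD68",
               "CD31", "Vim", "ColI", "ER", "Ki67"),
    compartment = c("nucleus", "cytoplasm", "cytoplasm", "cytoplasm",
                    "cytoplasm", "cytoplasm", "cytoplasm", "cytoplasm",
                    "cytoplasm", "cytoplasm", "nucleus", "nucleus"),
    stringsAsFactors = FALSE
  )
}

## Which markers each ground-truth cell type stains positive for.
.default_marker_model <- function() {
  list(
    "luminal tumor"     = c("DNA", "Ecad", "panCK"),
    "luminal ER+ tumor" = c("DNA", "Ecad", "panCK", "ER"),
    "basal tumor"       = c("DNA", "panCK"),
    "CD3 T"             = c("DNA", "CD45", "CD3"),
    "CD20 B"            = c("DNA", "CD45", "CD20"),
    "macrophage"        = c("DNA", "CD45", "CD68"),
    "Vim+ fibroblast"   = c("DNA", "Vim", "ColI"),
    "quiescent stroma"  = c("DNA"),
    "endothelial"       = c("DNA", "CD31", "Vim")
  )
}

#' Simulate marker intensities conditional on ground-truth cell type
#'
#' Each (cell type, marker) pair is drawn from a lognormal model: positive
#' cells from `lognormal(log(separation), fg_sdlog)`, negative cells from
#' background `lognormal(0, bg_sdlog)`; intensity units are arbitrary and
#' only rank/threshold behavior matters downstream. Columns are added to the
#' table as `<marker>_nucleus` and `<marker>_cytoplasm` (the off-target
#' compartment receives background-level signal).
#'
#' @param table cell table with ground-truth `cell_type` on every cell.
#' @param panel marker panel data frame (see [default_panel()]).
#' @param seed integer seed.
#' @param separation fold separation between positive and negative medians.
#' @param fg_sdlog,bg_sdlog lognormal sd (log scale) of foreground and
#'   background draws.
#' @param marker_model named list: cell type -> character vector of positive
#'   markers; defaults cover the types of [default_cell_types()].
#' @return the cell table with intensity columns appended.
#' @export
simulate_intensities <- function(table, panel = default_panel(), seed = 1L,
                                 separation = 10, fg_sdlog = 0.35,
                                 bg_sdlog = 0.35,
                                 marker_model = NULL) {
  marker_model <- marker_model %||% .default_marker_model()
  if (nrow(table) == 0) {
    for (m in panel$marker) {
      table[[paste0(m, "_nucleus")]] <- numeric(0)
      table[[paste0(m, "_cytoplasm")]] <- numeric(0)
    }
    return(table)
  }
  if (anyNA(table$cell_type))
    stopf("every cell needs a ground-truth cell_type")
  unknown <- setdiff(unique(table$cell_type), names(marker_model))
  if (length(unknown))
    stopf("no intensity model entry for cell type(s): %s",
          paste(unknown, collapse = ", "))
  set.seed(seed)
  n <- nrow(table)
  for (j in seq_len(nrow(panel))) {
    m <- panel$marker[j]
    pos <- vapply(table$cell_type,
                  function(ct) m %in% marker_model[[ct]], logical(1))
    fg <- stats::rlnorm(n, meanlog = log(separation), sdlog = fg_sdlog)
    bg <- stats::rlnorm(n, meanlog = 0, sdlog = bg_sdlog)
    signal <- ifelse(pos, fg, bg)
    other_bg <- stats::rlnorm(n, meanlog = 0, sdlog = bg_sdlog)
    if (panel$compartment[j] == "nucleus") {
      table[[paste0(m, "_nucleus")]] <- signal
      table[[paste0(m, "_cytoplasm")]] <- other_bg
    } else {
      table[[paste0(m, "_cytoplasm")]] <- signal
      table[[paste0(m, "_nucleus")]] <- other_bg
    }
  }
  table
}

## ------------------------------------------------------------------ cohort

#' Specify a synthetic multi-platform cohort
#'
#' @param n_patients patients per platform cohort (recycled along
#'   `platforms`, so per-platform sizes may differ).
#' @param effects data frame with columns `metric` and `log_hr`: each planted
#'   biomarker contributes `log_hr` to the log hazard of patients whose
#'   realized metric value exceeds the cohort median. Metric names must be
#'   columns of the computed metric panel: `frac_<cell type>` or
#'   `mixing_score`.
#' @param baseline_rate exponential baseline hazard (events per month).
#' @param censoring_rate target fraction censored, in \[0, 1); 0 disables
#'   dropout and the administrative horizon.
#' @param horizon_months administrative censoring horizon.
#' @param platforms platform labels, one cohort each.
#' @param subtype clinical subtype of the simulated patients.
#' @param tissue base `tissue_spec` realised (with per-patient composition
#'   noise) for each patient.
#' @param composition_sdlog lognormal sd of per-patient density multipliers.
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 50,
                        effects = data.frame(metric = character(0),
                                             log_hr = numeric(0)),
                        baseline_rate = 0.012, censoring_rate = 0.2,
                        horizon_months = 120,
                        platforms = c("CycIF", "IMC", "MIBI"),
                        subtype = "TNBC",
                        tissue = NULL, composition_sdlog = 0.5,
                        seed = 1L) {
  if (censoring_rate < 0 || censoring_rate >= 1)
    stopf("censoring_rate must be in [0, 1)")
  if (baseline_rate <= 0) stopf("baseline_rate must be > 0")
  if (is.null(tissue))
    tissue <- tissue_spec(field_width_um = 350, field_height_um = 350,
                          n_tumor_nests = 2, nest_radius_um = 80,
                          subtype = subtype)
  structure(list(n_patients = n_patients, effects = effects,
                 baseline_rate = baseline_rate,
                 censoring_rate = censoring_rate,
                 horizon_months = horizon_months, platforms = platforms,
                 subtype = subtype, tissue = tissue,
                 composition_sdlog = composition_sdlog, seed = seed),
            class = "cohort_spec")
}

## Metric panel computed on each simulated tissue: per-type fractions plus
## the tumor-immune mixing score.
.cohort_metrics <- function(table) {
  types <- unique(table$cell_type)
  out <- as.list(table(factor(table$cell_type, levels = types)) / nrow(table))
  names(out) <- paste0("frac_", types)
  g <- build_graph(table, radius_um = 25)
  ms <- mixing_score(g)
  out$mixing_score <- if (is.na(ms$value)) NA_real_ else ms$value
  out
}

#' Simulate a multi-platform survival cohort with planted spatial biomarkers
#'
#' For each patient a tissue is generated (with per-patient composition and
#' mixing variation), a metric panel is computed from the realized tissue,
#' and survival is drawn from an exponential proportional-hazards model whose
#' linear predictor sums `log_hr` over planted metrics whose realized value
#' exceeds the cohort median. Censoring combines an administrative horizon
#' with exponential early dropout tuned to the requested censoring rate;
#' with `censoring_rate = 0` every patient is an event.
#'
#' @param cspec a [cohort_spec()].
#' @return list with `tables` (per-patient cell tables), `clinical`
#'   (patient-level data frame with OS/RFS, age, tumor size, stage, platform,
#'   subtype) and `metrics` (patient x metric data frame).
#' @export
simulate_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  set.seed(cspec$seed)
  np <- rep_len(cspec$n_patients, length(cspec$platforms))
  pats <- data.frame(
    i = unlist(lapply(np, seq_len)),
    platform = rep(cspec$platforms, np),
    stringsAsFactors = FALSE)
  n <- nrow(pats)
  pats$patient_id <- sprintf("%s_P%03d", pats$platform, pats$i)
  tissue_seeds <- sample.int(.Machine$integer.max, n)

  tables <- vector("list", n)
  metric_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- cspec$tissue
    sp$platform <- pats$platform[i]
    sp$subtype <- cspec$subtype
    mult <- exp(stats::rnorm(nrow(sp$cell_types), 0, cspec$composition_sdlog))
    sp$cell_types$density <- sp$cell_types$density * mult
    sp$mixing <- stats::runif(1)
    tab <- generate_tissue(sp, seed = tissue_seeds[i],
                           sample_id = paste0(pats$patient_id[i], "_c1"),
                           patient_id = pats$patient_id[i])$table
    tables[[i]] <- tab
    metric_rows[[i]] <- .cohort_metrics(tab)
  }
  all_names <- unique(unlist(lapply(metric_rows, names)))
  metrics <- as.data.frame(
    do.call(rbind, lapply(metric_rows, function(r) {
      vapply(all_names, function(nm) as.numeric(r[[nm]] %||% 0), numeric(1))
    })))
  names(metrics) <- all_names
  metrics <- cbind(patient_id = pats$patient_id, metrics,
                   stringsAsFactors = FALSE)

  bad <- setdiff(cspec$effects$metric, all_names)
  if (length(bad))
    stopf("effect table references uncomputable metric(s): %s",
          paste(bad, collapse = ", "))
  lp <- rep(0, n)
  for (j in seq_len(nrow(cspec$effects))) {
    v <- metrics[[cspec$effects$metric[j]]]
    med <- stats::median(v, na.rm = TRUE)
    hi <- !is.na(v) & v > med
    lp <- lp + cspec$effects$log_hr[j] * hi
  }

  draw_surv <- function() {
    t_event <- stats::rexp(n, rate = cspec$baseline_rate * exp(lp))
    if (cspec$censoring_rate == 0) {
      list(time = t_event, event = rep(1L, n))
    } else {
      r_c <- cspec$baseline_rate * cspec$censoring_rate /
        (1 - cspec$censoring_rate)
      t_cens <- pmin(stats::rexp(n, rate = r_c), cspec$horizon_months)
      list(time = pmax(pmin(t_event, t_cens), 1e-6),
           event = as.integer(t_event <= t_cens))
    }
  }
  os <- draw_surv(); rfs <- draw_surv()
  clinical <- data.frame(
    patient_id = pats$patient_id, platform = pats$platform,
    subtype = cspec$subtype,
    os_time = os$time, os_event = os$event,
    rfs_time = rfs$time, rfs_event = rfs$event,
    age_years = round(stats::rnorm(n, 60, 10)),
    tumor_size = round(exp(stats::rnorm(n, log(20), 0.4)), 1),
    stage = sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2)),
    stringsAsFactors = FALSE)
  list(tables = tables, clinical = clinical, metrics = metrics)
}

## ------------------------------------------------------------------ images

#' Render a cell table as a multichannel image plus label masks
#'
#' Each cell is drawn as a nucleus disc inside a cell disc; per channel, the
#' nucleus disc carries the cell's `<marker>_nucleus` intensity and the
#' cytoplasmic annulus its `<marker>_cytoplasm` intensity, plus seeded
#' Gaussian noise. Hot pixels are planted at known coordinates with values
#' far above the local median so that hot-pixel removal can be validated
#' against ground truth. The returned nucleus/cell masks share the cell ids
#' of the table.
#'
#' @param table cell table with intensity columns.
#' @param sample sample_info providing field size and pixel size (a pixel
#'   size may be passed to override).
#' @param panel marker panel.
#' @param pixel_size_um pixel size; defaults to the sample's.
#' @param nucleus_radius_um,cell_radius_um disc radii.
#' @param hot_pixels number of hot pixels planted per channel.
#' @param noise_sd Gaussian noise sd added per pixel (0 = exact rendering).
#' @param seed integer seed.
#' @return list with `channels` (named list of matrices, row = y), `nuc_mask`,
#'   `cell_mask`, `hot_pixel_coords` (data frame marker/row/col) and
#'   `pixel_size_um`.
#' @export
render_image <- function(table, sample, panel = default_panel(),
                         pixel_size_um = NULL, nucleus_radius_um = 3,
                         cell_radius_um = 6, hot_pixels = 0, noise_sd = 0,
                         seed = 1L) {
  px <- pixel_size_um %||% sample$pixel_size_um
  W <- ceiling(sample$field_width_um / px)
  H <- ceiling(sample$field_height_um / px)
  if (W > 2048 || H > 2048)
    stopf("field does not fit in 2048^2 pixels at pixel size %g", px)
  set.seed(seed)
  nuc <- matrix(0L, H, W)
  cel <- matrix(0L, H, W)
  channels <- lapply(panel$marker, function(m) matrix(0, H, W))
  names(channels) <- panel$marker
  if (nrow(table)) {
    ## nudge apart overlapping nuclei (re-placement contract)
    xy <- cbind(table$x_um, table$y_um)
    min_sep <- 2 * nucleus_radius_um
    for (it in seq_len(50L)) {
      d <- cross_dist(xy); diag(d) <- Inf
      clash <- which(d < min_sep, arr.ind = TRUE)
      clash <- clash[clash[, 1] < clash[, 2], , drop = FALSE]
      if (!nrow(clash)) break
      if (it == 1L) warnf("%d overlapping nuclei re-placed", nrow(clash))
      for (r in seq_len(nrow(clash))) {
        i <- clash[r, 1]; j <- clash[r, 2]
        v <- xy[j, ] - xy[i, ]
        nv <- sqrt(sum(v^2))
        v <- if (nv < 1e-9) c(min_sep, 0) else v / nv * (min_sep - nv + 0.5)
        xy[j, ] <- pmin(pmax(xy[j, ] + v, 0),
                        c(sample$field_width_um, sample$field_height_um))
      }
    }
    table$x_um <- xy[, 1]; table$y_um <- xy[, 2]

    rn <- nucleus_radius_um / px
    rc <- cell_radius_um / px
    disc <- function(i, r) {
      cx <- table$x_um[i] / px + 0.5
      cy <- table$y_um[i] / px + 0.5
      cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
      rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
      dd <- outer((rows - cy)^2, (cols - cx)^2, "+")
      list(rows = rows, cols = cols, inside = dd <= r^2)
    }
    ## two passes keep channels consistent with the masks when discs of
    ## neighboring cells overlap: cytoplasm paint first, nuclei on top
    for (i in seq_len(nrow(table))) {
      d <- disc(i, rc)
      id <- table$cell_id[i]
      sub <- cel[d$rows, d$cols]; sub[d$inside] <- id
      cel[d$rows, d$cols] <- sub
      for (m in panel$marker) {
        vc <- table[[paste0(m, "_cytoplasm")]][i] %||% 0
        s <- channels[[m]][d$rows, d$cols]; s[d$inside] <- vc
        channels[[m]][d$rows, d$cols] <- s
      }
    }
    for (i in seq_len(nrow(table))) {
      d <- disc(i, rn)
      id <- table$cell_id[i]
      sub <- nuc[d$rows, d$cols]; sub[d$inside] <- id
      nuc[d$rows, d$cols] <- sub
      for (m in panel$marker) {
        vn <- table[[paste0(m, "_nucleus")]][i] %||% 0
        s <- channels[[m]][d$rows, d$cols]; s[d$inside] <- vn
        channels[[m]][d$rows, d$cols] <- s
      }
    }
  }
  if (noise_sd > 0)
    channels <- lapply(channels, function(ch)
      pmax(ch + matrix(stats::rnorm(H * W, 0, noise_sd), H, W), 0))
  hot <- data.frame(marker = character(0), row = integer(0), col = integer(0))
  if (hot_pixels > 0) {
    for (m in panel$marker) {
      idx <- sample.int(H * W, hot_pixels)
      rr <- (idx - 1L) %% H + 1L
      cc <- (idx - 1L) %/% H + 1L
      spike <- max(channels[[m]]) * 20 + 1000 * (stats::sd(channels[[m]]) + 1)
      channels[[m]][cbind(rr, cc)] <- spike
      hot <- rbind(hot, data.frame(marker = m, row = rr, col = cc))
    }
  }
  list(channels = channels, nuc_mask = nuc, cell_mask = cel,
       hot_pixel_coords = hot, pixel_size_um = px)
}

## ---------------------------------------------------------------------- IO

#' Write / read a cell table as CSV
#'
#' @param table cell table; @param path file path.
#' @return `read_cell_table` returns a validated cell table.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("lineage" %in% names(df)) df$lineage <- as.character(df$lineage)
  cell_table(df)
}
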