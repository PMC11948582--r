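## Pixel-level QC, segmentation-input preparation, mask algebra and per-cell
## feature extraction. Images are plain numeric matrices (row = y, col = x);
## label masks are integer matrices with 0 = background.

#' Median filter with a small square kernel
#'
#' The k x k window is anchored with the target pixel at its top-left corner
#' (matching the even-kernel convention of the hot-pixel rule) and clipped at
#' the image border.
#'
#' @param img numeric matrix.
#' @param kernel window side length (>= 2).
#' @return matrix of the same shape.
#' @export
median_filter <- function(img, kernel = 2L) {
  if (!is.matrix(img)) stopf("median_filter expects a 2-D matrix")
  k <- as.integer(kernel)
  if (k < 2L) stopf("kernel must be >= 2")
  H <- nrow(img); W <- ncol(img)
  stack <- matrix(NA_real_, H * W, k * k)
  s <- 0L
  for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
    s <- s + 1L
    sh <- matrix(NA_real_, H, W)
    sh[seq_len(H - dr), seq_len(W - dc)] <-
      img[seq_len(H - dr) + dr, seq_len(W - dc) + dc]
    stack[, s] <- as.vector(sh)
  }
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  matrix(med, H, W)
}

#' Remove hot pixels
#'
#' Pixels exceeding the 2 x 2 median-filtered image by more than `n_sd`
#' standard deviations of the residual image (image minus its median filter,
#' SD taken over the whole field) are replaced by the median-filter value;
#' all other pixels are unchanged.
#'
#' @param img nonnegative numeric matrix.
#' @param kernel median-filter kernel size (default 2).
#' @param n_sd threshold in residual SDs (default 10).
#' @return list with `image` (cleaned matrix) and `hot` (logical matrix of
#'   replaced pixels).
#' @export
remove_hot_pixels <- function(img, kernel = 2L, n_sd = 10) {
  if (!is.matrix(img)) stopf("remove_hot_pixels expects a 2-D matrix")
  if (n_sd <= 0) stopf("n_sd must be > 0")
  mf <- median_filter(img, kernel)
  resid <- img - mf
  s <- stats::sd(as.vector(resid))
  if (is.na(s) || s == 0) {
    return(list(image = img, hot = matrix(FALSE, nrow(img), ncol(img))))
  }
  hot <- resid > n_sd * s
  out <- img
  out[hot] <- mf[hot]
  list(image = pmax(out, 0), hot = hot)
}

#' Subtract a scaled autofluorescence image
#'
#' The autofluorescence image is scaled by the ratio of exposure times
#' (target over autofluorescence) before subtraction; the result is clipped
#' at zero.
#'
#' @param img,af numeric matrices of identical shape.
#' @param img_exposure,af_exposure exposure times (> 0).
#' @return matrix `pmax(img - af * img_exposure / af_exposure, 0)`.
#' @export
subtract_autofluorescence <- function(img, af, img_exposure, af_exposure) {
  if (!identical(dim(img), dim(af))) stopf("image shapes differ")
  if (missing(img_exposure) || missing(af_exposure) ||
      is.null(img_exposure) || is.null(af_exposure))
    stopf("both exposure times are required")
  if (img_exposure <= 0 || af_exposure <= 0)
    stopf("exposure times must be > 0")
  pmax(img - af * (img_exposure / af_exposure), 0)
}

## Chambolle's projection algorithm for total-variation denoising.
tv_denoise <- function(img, weight, n_iter = 100L, tol = 1e-4) {
  if (weight <= 0) return(img)
  H <- nrow(img); W <- ncol(img)
  px <- matrix(0, H, W); py <- matrix(0, H, W)
  tau <- 0.25
  u <- img
  for (it in seq_len(n_iter)) {
    ## divergence of p
    div <- matrix(0, H, W)
    div <- div + px - cbind(0, px[, -W])
    div <- div + py - rbind(0, py[-H, ])
    u_new <- img + weight * div
    gx <- cbind(u_new[, -1] - u_new[, -W], 0)
    gy <- rbind(u_new[-1, ] - u_new[-H, ], 0)
    norm <- sqrt(gx^2 + gy^2)
    px <- (px + (tau / weight) * gx) / (1 + (tau / weight) * norm)
    py <- (py + (tau / weight) * gy) / (1 + (tau / weight) * norm)
    if (max(abs(u_new - u)) < tol * max(abs(img), 1e-12) && it > 1L) {
      u <- u_new; break
    }
    u <- u_new
  }
  u
}

#' Prepare the 2-channel nucleus + cytoplasm segmentation input
#'
#' Cytoplasmic channels are combined by per-pixel maximum projection. Each of
#' the two output channels is clipped to
#' `[quantile(clip_low_q), clip_high_factor * quantile(0.99999)]`, min-max
#' rescaled to \[0,1\], gamma-adjusted (`x^gamma`) and Chambolle
#' total-variation denoised with the stated weight. A constant image is a
#' fixed point of the rescale/TV steps (only the gamma map applies).
#'
#' @param nuclear nuclear channel matrix.
#' @param cytoplasm list of one or more cytoplasmic channel matrices.
#' @param clip_low_q lower clip quantile (default 0.03).
#' @param clip_high_factor multiplier of the 0.99999 quantile for the upper
#'   clip (default 1.5).
#' @param gamma gamma adjustment (0.6 for MIBI-style, 0.4 for IMC-style data).
#' @param tv_weight,tv_weight_cyto Chambolle TV weights for the nuclear and
#'   cytoplasmic channel (0.1 typical; 0.05 for IMC cytoplasm); 0 disables.
#' @return list with matrices `nuclear` and `cytoplasm`, both in \[0,1\].
#' @export
prepare_segmentation_input <- function(nuclear, cytoplasm,
                                       clip_low_q = 0.03,
                                       clip_high_factor = 1.5,
                                       gamma = 0.6, tv_weight = 0.1,
                                       tv_weight_cyto = tv_weight) {
  if (is.matrix(cytoplasm)) cytoplasm <- list(cytoplasm)
  if (!length(cytoplasm)) stopf("at least one cytoplasmic channel is required")
  cyto <- Reduce(pmax, cytoplasm)
  prep <- function(x, w) {
    lo <- stats::quantile(x, clip_low_q, names = FALSE)
    hi <- clip_high_factor * stats::quantile(x, 0.99999, names = FALSE)
    if (hi > lo) x <- pmin(pmax(x, lo), hi)
    x <- rescale01(x)^gamma
    tv_denoise(x, w)
  }
  list(nuclear = prep(nuclear, tv_weight),
       cytoplasm = prep(cyto, tv_weight_cyto))
}

## Pixel sets per label as a named list of linear indices.
.label_pixels <- function(mask) {
  idx <- which(mask > 0)
  split(idx, mask[idx])
}

#' Match nucleus and cell masks by maximal overlap
#'
#' Each cell object carrying at least one nucleus pixel is relabeled to the
#' id of the nucleus it overlaps most (ties broken toward the lower nucleus
#' id); cell objects overlapping no nucleus are dropped; a nucleus claimed by
#' several cells keeps only the cell with greatest overlap (ties toward the
#' lower original cell id). The returned masks carry identical id sets.
#'
#' @param nuc,cell integer label masks of identical shape.
#' @return list with relabeled `nuc` and `cell` masks.
#' @export
match_masks <- function(nuc, cell) {
  if (!identical(dim(nuc), dim(cell))) stopf("mask shapes differ")
  both <- nuc > 0 & cell > 0
  if (!any(both)) {
    return(list(nuc = matrix(0L, nrow(nuc), ncol(nuc)),
                cell = matrix(0L, nrow(nuc), ncol(nuc))))
  }
  ov <- table(cell = cell[both], nuc = nuc[both])
  cell_ids <- as.integer(rownames(ov))
  nuc_ids <- as.integer(colnames(ov))
  ## per cell: best nucleus (max overlap, ties -> lower nucleus id)
  best_nuc <- nuc_ids[apply(ov, 1L, which.max)]
  best_ov <- apply(ov, 1L, max)
  ## per nucleus: keep the cell with greatest overlap
  keep <- rep(TRUE, length(cell_ids))
  for (nid in unique(best_nuc)) {
    cand <- which(best_nuc == nid)
    if (length(cand) > 1L) {
      win <- cand[order(-best_ov[cand], cell_ids[cand])][1L]
      keep[setdiff(cand, win)] <- FALSE
    }
  }
  cell_ids <- cell_ids[keep]; best_nuc <- best_nuc[keep]
  new_cell <- matrix(0L, nrow(cell), ncol(cell))
  for (k in seq_along(cell_ids))
    new_cell[cell == cell_ids[k]] <- best_nuc[k]
  new_nuc <- nuc
  new_nuc[!(nuc %in% best_nuc)] <- 0L
  list(nuc = new_nuc, cell = new_cell)
}

#' Derive the cytoplasm mask
#'
#' Cytoplasm pixels are the cell pixels minus all nuclear pixels (the masks
#' must already be matched: identical id sets). A cell whose nucleus fills it
#' has an empty cytoplasm for that id.
#'
#' @param cell,nuc matched label masks.
#' @return cytoplasm label mask.
#' @export
derive_cytoplasm <- function(cell, nuc) {
  if (!identical(dim(nuc), dim(cell))) stopf("mask shapes differ")
  ids_c <- sort(unique(cell[cell > 0]))
  ids_n <- sort(unique(nuc[nuc > 0]))
  if (!identical(ids_c, ids_n))
    stopf("masks are not matched: cell and nucleus id sets differ")
  cyto <- cell
  cyto[nuc > 0] <- 0L
  cyto
}

## Eccentricity from second central moments of a pixel set (region-property
## definition: sqrt(1 - minor/major eigenvalue ratio)).
.eccentricity <- function(rows, cols) {
  if (length(rows) < 2L) return(0)
  mu_rr <- stats::var(rows) * (length(rows) - 1) / length(rows) + 1 / 12
  mu_cc <- stats::var(cols) * (length(cols) - 1) / length(cols) + 1 / 12
  mu_rc <- stats::cov(rows, cols) * (length(rows) - 1) / length(rows)
  tr <- mu_rr + mu_cc
  det <- mu_rr * mu_cc - mu_rc^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(1 - l2 / l1, 0))
}

#' Extract per-cell features from channels and matched masks
#'
#' Computes, per cell id: mean intensity per marker and compartment
#' (`<marker>_nucleus` from the nucleus mask, `<marker>_cytoplasm` from the
#' cytoplasm mask; a cell with an empty cytoplasm gets NA there), nuclear
#' area in square micrometers, nuclear eccentricity, and the nuclear centroid
#' in micrometers (pixel centers, origin at the field top-left, y downward).
#' Cells whose centroid falls inside an exclusion polygon, or whose
#' last-round DAPI mean falls below `dapi_threshold` when `last_round_dapi`
#' is supplied, are marked `excluded`.
#'
#' @param channels named list of channel matrices (names = markers).
#' @param nuc,cell,cyto matched label masks.
#' @param sample sample_info (pixel size, field bounds, exclusion polygons).
#' @param last_round_dapi optional matrix for tissue-loss detection.
#' @param dapi_threshold exclusion threshold on last-round DAPI nuclear mean.
#' @return a cell table.
#' @export
extract_features <- function(channels, nuc, cell, cyto, sample,
                             last_round_dapi = NULL, dapi_threshold = 0) {
  ids <- sort(unique(nuc[nuc > 0]))
  px <- sample$pixel_size_um
  npx_n <- .label_pixels(nuc)
  npx_cy <- .label_pixels(cyto)
  H <- nrow(nuc)
  n <- length(ids)
  out <- data.frame(cell_id = ids,
                    sample_id = rep(sample$sample_id, n),
                    patient_id = rep(sample$patient_id, n),
                    x_um = numeric(n), y_um = numeric(n),
                    nuclear_area_um2 = numeric(n), eccentricity = numeric(n),
                    lineage = rep(NA_character_, n),
                    cell_type = rep(NA_character_, n),
                    excluded = rep(FALSE, n), stringsAsFactors = FALSE)
  for (m in names(channels)) {
    out[[paste0(m, "_nucleus")]] <- rep(NA_real_, n)
    out[[paste0(m, "_cytoplasm")]] <- rep(NA_real_, n)
  }
  for (k in seq_len(n)) {
    id <- as.character(ids[k])
    pix <- npx_n[[id]]
    if (is.null(pix) || !length(pix))
      stopf("id %s present in mask but has zero pixels", id)
    rows <- (pix - 1L) %% H + 1L
    cols <- (pix - 1L) %/% H + 1L
    out$x_um[k] <- (mean(cols) - 0.5) * px
    out$y_um[k] <- (mean(rows) - 0.5) * px
    out$nuclear_area_um2[k] <- length(pix) * px^2
    out$eccentricity[k] <- .eccentricity(rows, cols)
    cy <- npx_cy[[id]]
    for (m in names(channels)) {
      out[[paste0(m, "_nucleus")]][k] <- mean(channels[[m]][pix])
      out[[paste0(m, "_cytoplasm")]][k] <-
        if (is.null(cy) || !length(cy)) NA_real_ else mean(channels[[m]][cy])
    }
    if (!is.null(last_round_dapi) &&
        mean(last_round_dapi[pix]) < dapi_threshold)
      out$excluded[k] <- TRUE
  }
  for (poly in sample$exclusion_polygons) {
    out$excluded <- out$excluded |
      point_in_polygon(out$x_um, out$y_um, poly)
  }
  cell_table(out)
}

#' Clamp extracted marker features to configured bounds
#'
#' Threshold-based channel artifact handling (bright antibody aggregates,
#' nonspecific background): per marker column, values above `upper` mark the
#' cell excluded, and `lower` is subtracted with a floor at zero.
#'
#' @param table cell table.
#' @param config named list: column name -> list(lower =, upper =).
#' @return the adjusted table.
#' @export
apply_marker_qc <- function(table, config) {
  for (col in names(config)) {
    if (!col %in% names(table)) stopf("unknown feature column: %s", col)
    cfg <- config[[col]]
    if (!is.null(cfg$upper))
      table$excluded <- table$excluded | (table[[col]] > cfg$upper)
    if (!is.null(cfg$lower))
      table[[col]] <- pmax(table[[col]] - cfg$lower, 0)
  }
  table
}

#' Estrogen-receptor staining QC (automated stand-in)
#'
#' A sample passes if at least `min_fraction` of its epithelial cells exceed
#' `er_threshold` in nuclear ER intensity, matching the sample's clinical ER
#' status (ER+ must pass, ER- must fail). The original procedure was a
#' blinded human sort of QC images; this is a thresholded surrogate.
#'
#' @param table cell table with `ER_nucleus` and lineages assigned.
#' @param er_positive logical: the sample's clinical ER status.
#' @param er_threshold intensity threshold for a positive nucleus.
#' @param min_fraction minimum fraction of positive epithelial nuclei.
#' @return logical: keep the sample.
#' @export
er_qc <- function(table, er_positive, er_threshold = 5, min_fraction = 0.1) {
  epi <- table[!is.na(table$lineage) & table$lineage == "epithelial", ]
  if (!nrow(epi)) return(FALSE)
  frac <- mean(epi$ER_nucleus > er_threshold)
  stain_pos <- frac >= min_fraction
  stain_pos == er_positive
}
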