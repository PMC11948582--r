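test_that("hot-pixel removal replaces only spikes and is idempotent", {
  img <- matrix(10, 30, 30)
  img[15, 15] <- 1000
  out <- remove_hot_pixels(img)
  expect_equal(out$image[15, 15], 10)
  expect_equal(sum(out$hot), 1L)
  expect_equal(out$image, matrix(10, 30, 30))

  flat <- matrix(7, 20, 20)
  expect_equal(remove_hot_pixels(flat)$image, flat)

  again <- remove_hot_pixels(out$image)
  expect_equal(sum(again$hot), 0L)
  expect_equal(again$image, out$image)

  expect_error(remove_hot_pixels(1:10), "2-D")
  expect_error(remove_hot_pixels(img, n_sd = 0), "n_sd")
})

test_that("autofluorescence subtraction scales by exposure and clips at zero", {
  img <- matrix(100, 5, 5); af <- matrix(30, 5, 5)
  expect_equal(subtract_autofluorescence(img, af, 2, 1), matrix(40, 5, 5))
  expect_equal(subtract_autofluorescence(img, img, 1, 1), matrix(0, 5, 5))
  expect_equal(subtract_autofluorescence(img, matrix(0, 5, 5), 1, 1), img)
  expect_error(subtract_autofluorescence(img, matrix(0, 4, 4), 1, 1), "shape")
  expect_error(subtract_autofluorescence(img, af, NULL, 1), "exposure")
})

test_that("segmentation input preparation follows its degenerate paths", {
  set.seed(1)
  a <- matrix(runif(400), 20, 20)
  ## single cytoplasmic channel: the max projection is that channel
  out <- prepare_segmentation_input(a, list(a), gamma = 1, tv_weight = 0,
                                    clip_low_q = 0, clip_high_factor = 100)
  expect_equal(out$cytoplasm, (a - min(a)) / (max(a) - min(a)),
               tolerance = 1e-12)

  ## constant image: value = constant^gamma, TV fixed point
  const <- matrix(0.5, 10, 10)
  out <- prepare_segmentation_input(const, list(const), gamma = 0.6,
                                    tv_weight = 0.1)
  expect_equal(out$nuclear, matrix(0.5^0.6, 10, 10), tolerance = 1e-6)

  ## multi-channel max projection
  b <- matrix(0, 20, 20); b[1, 1] <- 2
  out <- prepare_segmentation_input(a, list(a * 0, b), gamma = 1,
                                    tv_weight = 0, clip_low_q = 0,
                                    clip_high_factor = 100)
  expect_equal(which.max(out$cytoplasm), 1L)

  expect_error(prepare_segmentation_input(a, list()), "cytoplasmic")
})

test_that("TV denoising smooths noise while keeping the mean", {
  set.seed(2)
  img <- matrix(0.5, 40, 40) + matrix(rnorm(1600, 0, 0.1), 40, 40)
  sm <- spatmark:::tv_denoise(img, 0.2)
  expect_lt(sd(sm), sd(img))
  expect_equal(mean(sm), mean(img), tolerance = 1e-2)
})

.disc_mask <- function(H, W, cx, cy, r, id) {
  m <- matrix(0L, H, W)
  for (i in 1:H) for (j in 1:W)
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- id
  m
}

test_that("mask matching relabels by maximal overlap and drops orphans", {
  ## two disjoint nucleus/cell pairs, cells labeled 7 and 9
  nuc <- .disc_mask(40, 40, 10, 10, 3, 1L) + .disc_mask(40, 40, 30, 30, 3, 2L)
  cell <- .disc_mask(40, 40, 10, 10, 6, 7L) + .disc_mask(40, 40, 30, 30, 6, 9L)
  out <- match_masks(nuc, cell)
  expect_setequal(unique(out$cell[out$cell > 0]), c(1L, 2L))
  expect_equal(out$cell > 0, cell > 0)

  ## a cell overlapping nucleus 1 by 10 px and nucleus 2 by 3 px takes id 1
  nuc <- matrix(0L, 10, 10)
  nuc[1, 1:10] <- 1L
  nuc[5, 1:3] <- 2L
  cell <- matrix(0L, 10, 10); cell[1:5, ] <- 9L
  out <- match_masks(nuc, cell)
  expect_equal(unique(out$cell[out$cell > 0]), 1L)

  ## a cell with zero nucleus overlap disappears
  nuc <- .disc_mask(40, 40, 10, 10, 3, 1L)
  cell <- .disc_mask(40, 40, 10, 10, 6, 5L) + .disc_mask(40, 40, 30, 30, 6, 6L)
  out <- match_masks(nuc, cell)
  expect_false(6L %in% out$cell)
  expect_setequal(unique(out$cell[out$cell > 0]),
                  unique(out$nuc[out$nuc > 0]))

  expect_error(match_masks(nuc, cell[1:10, ]), "shape")
})

test_that("cytoplasm derivation subtracts nuclei and respects matching", {
  nuc <- .disc_mask(40, 40, 20, 20, 3, 1L)
  cell <- .disc_mask(40, 40, 20, 20, 8, 1L)
  cyto <- derive_cytoplasm(cell, nuc)
  expect_equal(sum(cyto == 1L), sum(cell == 1L) - sum(nuc == 1L))
  expect_true(all(cyto[nuc > 0] == 0L))
  expect_true(all(cyto[cell == 0] == 0L))

  ## nucleus filling the whole cell leaves an empty cytoplasm
  cyto2 <- derive_cytoplasm(nuc, nuc)
  expect_true(all(cyto2 == 0L))

  bad <- .disc_mask(40, 40, 10, 10, 3, 2L)
  expect_error(derive_cytoplasm(cell, bad), "matched")
})

test_that("feature extraction recovers geometry and applies exclusions", {
  ## circular nucleus radius 10 px at pixel size 0.5: area ~ 25*pi um^2
  nuc <- .disc_mask(64, 64, 32, 32, 10, 1L)
  cell <- .disc_mask(64, 64, 32, 32, 14, 1L)
  cyto <- derive_cytoplasm(cell, nuc)
  ch <- list(DNA = matrix(3, 64, 64))
  info <- sample_info("s", "p", pixel_size_um = 0.5, field_width_um = 32,
                      field_height_um = 32)
  tab <- extract_features(ch, nuc, cell, cyto, info)
  expect_equal(tab$nuclear_area_um2, pi * 25, tolerance = 0.05)
  expect_lt(tab$eccentricity, 0.1)
  expect_equal(tab$DNA_nucleus, 3)
  expect_equal(tab$x_um, 0.5 * (32 - 0.5), tolerance = 0.3)

  ## exclusion polygon covering the whole field excludes every cell
  info2 <- sample_info("s", "p", pixel_size_um = 0.5, field_width_um = 32,
                       field_height_um = 32,
                       exclusion_polygons = list(cbind(c(0, 32, 32, 0),
                                                       c(0, 0, 32, 32))))
  tab2 <- extract_features(ch, nuc, cell, cyto, info2)
  expect_true(all(tab2$excluded))

  ## last-round DAPI loss marks cells excluded
  tab3 <- extract_features(ch, nuc, cell, cyto, info,
                           last_round_dapi = matrix(0, 64, 64),
                           dapi_threshold = 1)
  expect_true(all(tab3$excluded))
})

test_that("extraction inverts rendering exactly at zero noise", {
  sp <- tissue_spec(field_width_um = 130, field_height_um = 130,
                    cell_types = data.frame(
                      cell_type = c("CD3 T", "luminal tumor"),
                      lineage = c("immune", "epithelial"),
                      density = c(0.0004, 0.0004),
                      placement = "poisson", region = "any",
                      thomas_mean_offspring = 8, thomas_sigma_um = 15))
  tt <- generate_tissue(sp, seed = 51)
  tab <- simulate_intensities(tt$table, seed = 52)
  img <- suppressWarnings(render_image(tab, tt$sample, pixel_size_um = 1,
                                       seed = 53))
  matched <- match_masks(img$nuc_mask, img$cell_mask)
  cyto <- derive_cytoplasm(matched$cell, matched$nuc)
  feat <- extract_features(img$channels, matched$nuc, matched$cell, cyto,
                           tt$sample)
  ord <- match(feat$cell_id, tab$cell_id)
  for (col in c("DNA_nucleus", "CD3_cytoplasm", "Ecad_cytoplasm")) {
    expect_identical(feat[[col]], tab[[col]][ord])
  }
  expect_equal(feat$x_um, tab$x_um[ord], tolerance = 1.2)
})

test_that("marker QC clamps features and ER QC matches clinical status", {
  tab <- make_cells(c(1, 2, 3), c(1, 2, 3))
  tab$PD1_cytoplasm <- c(1, 5, 100)
  out <- apply_marker_qc(tab, list(PD1_cytoplasm = list(lower = 1, upper = 50)))
  expect_equal(out$excluded, c(FALSE, FALSE, TRUE))
  expect_equal(out$PD1_cytoplasm, c(0, 4, 99))
  expect_error(apply_marker_qc(tab, list(nope = list(upper = 1))), "unknown")

  epi <- make_cells(1:20, 1:20, cell_type = "luminal ER+ tumor",
                    lineage = "epithelial")
  epi$ER_nucleus <- c(rep(10, 10), rep(0.1, 10))
  expect_true(er_qc(epi, er_positive = TRUE))
  expect_false(er_qc(epi, er_positive = FALSE))
})
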