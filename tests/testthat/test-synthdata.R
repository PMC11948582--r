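test_that("tissue generation is deterministic, validates, and handles empties", {
  sp <- tissue_spec(field_width_um = 300, field_height_um = 300)
  a <- generate_tissue(sp, seed = 11)
  b <- generate_tissue(sp, seed = 11)
  expect_identical(a$table, b$table)
  expect_true(all(a$table$x_um >= 0 & a$table$x_um <= 300))
  expect_true(all(a$table$lineage %in%
                    c("epithelial", "immune", "fibroblast", "endothelial",
                      "stromal")))
  expect_false(anyNA(a$table$cell_type))

  ct0 <- default_cell_types(); ct0$density <- 0
  empty <- generate_tissue(tissue_spec(cell_types = ct0), seed = 1)
  expect_equal(nrow(empty$table), 0L)
  expect_s3_class(empty$table, "cell_table")
  expect_equal(empty$sample$field_width_um, 600)

  expect_error(tissue_spec(field_width_um = 0), "degenerate")
})

test_that("uniform-Poisson counts are consistent with the stated density", {
  ct <- data.frame(cell_type = "luminal tumor", lineage = "epithelial",
                   density = 0.002, placement = "poisson", region = "any",
                   thomas_mean_offspring = 8, thomas_sigma_um = 15)
  sp <- tissue_spec(field_width_um = 300, field_height_um = 300,
                    cell_types = ct, n_tumor_nests = 0)
  counts <- vapply(1:100, function(s) nrow(generate_tissue(sp, seed = s)$table),
                   numeric(1))
  lam <- 0.002 * 300 * 300
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam) / sqrt(100) * 3)
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam))
})

test_that("planted mixing level 0 keeps tumor at least 25 um from immune cells", {
  sp <- tissue_spec(field_width_um = 400, field_height_um = 400, mixing = 0)
  tab <- generate_tissue(sp, seed = 5)$table
  tum <- tab[tab$lineage == "epithelial", ]
  imm <- tab[tab$lineage == "immune", ]
  d <- outer(tum$x_um, imm$x_um, "-")^2 + outer(tum$y_um, imm$y_um, "-")^2
  expect_gt(min(sqrt(d)), 25)
})

test_that("intensity simulation separates positives and recovers medians", {
  ## noiseless separable construction: gating recovers every lineage
  sp <- tissue_spec(field_width_um = 400, field_height_um = 400)
  tab <- generate_tissue(sp, seed = 3)$table
  tab <- simulate_intensities(tab, seed = 4, separation = 100,
                              fg_sdlog = 0.01, bg_sdlog = 0.01)
  gates <- gate_lineages(tab)
  expect_equal(mean(gates == tab$lineage), 1.0)

  ## two types, one defining marker: medians within 10% at n = 2000
  tab2 <- make_cells(runif(2000, 0, 1000), runif(2000, 0, 1000),
                     cell_type = rep(c("CD3 T", "quiescent stroma"), 1000),
                     lineage = rep(c("immune", "stromal"), 1000))
  tab2 <- simulate_intensities(tab2, seed = 9, separation = 10)
  pos <- tab2$cell_type == "CD3 T"
  expect_equal(median(tab2$CD3_cytoplasm[pos]), 10, tolerance = 0.1)
  expect_equal(median(tab2$CD3_cytoplasm[!pos]), 1, tolerance = 0.1)
  expect_gt(median(tab2$CD3_cytoplasm[pos]),
            median(tab2$CD3_cytoplasm[!pos]))

  ## empty table stays empty but gains the intensity columns
  e <- simulate_intensities(make_cells(numeric(0), numeric(0)))
  expect_equal(nrow(e), 0L)
  expect_true("CD3_cytoplasm" %in% names(e))

  ## unknown cell type is named in the error
  bad <- make_cells(1, 1, cell_type = "mystery cell")
  expect_error(simulate_intensities(bad), "mystery cell")
})

test_that("cohort simulation is PH-consistent and respects censoring", {
  cs <- cohort_spec(n_patients = 30, censoring_rate = 0,
                    platforms = "CycIF", seed = 2)
  sim <- simulate_cohort(cs)
  expect_true(all(sim$clinical$os_event == 1L))
  expect_true(all(sim$clinical$os_time > 0))
  expect_equal(nrow(sim$clinical), 30L)
  expect_equal(length(sim$tables), 30L)

  bad <- cohort_spec(effects = data.frame(metric = "no_such", log_hr = 1))
  expect_error(simulate_cohort(bad), "no_such")
})

test_that("a planted hazard ratio is recovered by Cox regression", {
  hits <- 0L
  n_rep <- 12L
  for (r in seq_len(n_rep)) {
    cs <- cohort_spec(n_patients = 150, platforms = "CycIF",
                      effects = data.frame(metric = "frac_CD3 T",
                                           log_hr = log(3)),
                      censoring_rate = 0.15, seed = 400 + r)
    sim <- simulate_cohort(cs)
    v <- sim$metrics$`frac_CD3 T`
    hi <- v > median(v)
    fit <- survival::coxph(
      survival::Surv(os_time, os_event) ~ hi, data = sim$clinical)
    hr <- exp(coef(fit))
    if (hr >= 2 && hr <= 4.5) hits <- hits + 1L
  }
  expect_gte(hits, round(0.8 * n_rep))
})

test_that("null cohorts give nominal log-rank rejection on the true split", {
  small <- tissue_spec(field_width_um = 220, field_height_um = 220,
                       n_tumor_nests = 1, nest_radius_um = 70)
  rej <- vapply(1:150, function(r) {
    cs <- cohort_spec(n_patients = 40, platforms = "CycIF", tissue = small,
                      censoring_rate = 0.2, seed = 7000 + r)
    sim <- simulate_cohort(cs)
    v <- sim$metrics$`frac_CD3 T`
    hi <- v > median(v)
    sd <- survival::survdiff(
      survival::Surv(os_time, os_event) ~ hi, data = sim$clinical)
    pchisq(sd$chisq, df = 1, lower.tail = FALSE) < 0.05
  }, logical(1))
  ## binomial 99% band around 0.05 at 150 replicates
  band <- 2.58 * sqrt(0.05 * 0.95 / 150)
  expect_lt(abs(mean(rej) - 0.05), band + 1e-9)
})

test_that("rendered images invert exactly at zero noise", {
  sp <- tissue_spec(field_width_um = 120, field_height_um = 120,
                    cell_types = data.frame(
                      cell_type = "CD3 T", lineage = "immune",
                      density = 0.0006, placement = "poisson", region = "any",
                      thomas_mean_offspring = 8, thomas_sigma_um = 15))
  tt <- generate_tissue(sp, seed = 21)
  tab <- simulate_intensities(tt$table, seed = 22)
  img <- suppressWarnings(
    render_image(tab, tt$sample, pixel_size_um = 1, seed = 23))
  expect_equal(sort(unique(as.vector(img$nuc_mask[img$nuc_mask > 0]))),
               sort(tab$cell_id))
  ## per-cell mask means equal the table values exactly
  for (id in tab$cell_id) {
    pix <- which(img$nuc_mask == id)
    expect_identical(mean(img$channels$DNA[pix]),
                     tab$DNA_nucleus[tab$cell_id == id])
  }
  ## empty table -> zero image, empty masks
  e <- render_image(make_cells(numeric(0), numeric(0)),
                    sample_info("s", "p", field_width_um = 50,
                                field_height_um = 50),
                    pixel_size_um = 1)
  expect_true(all(e$channels$DNA == 0))
  expect_true(all(e$nuc_mask == 0))

  big <- sample_info("s", "p", field_width_um = 5000, field_height_um = 5000)
  expect_error(render_image(make_cells(1, 1), big, pixel_size_um = 1),
               "2048")
})

test_that("planted hot pixels are exactly the ones the filter detects", {
  sp <- tissue_spec(field_width_um = 150, field_height_um = 150,
                    cell_types = data.frame(
                      cell_type = "CD3 T", lineage = "immune",
                      density = 0.0005, placement = "poisson", region = "any",
                      thomas_mean_offspring = 8, thomas_sigma_um = 15))
  tt <- generate_tissue(sp, seed = 31)
  tab <- simulate_intensities(tt$table, seed = 32)
  img <- suppressWarnings(
    render_image(tab, tt$sample, pixel_size_um = 1, hot_pixels = 10,
                 seed = 33))
  hp <- img$hot_pixel_coords[img$hot_pixel_coords$marker == "DNA", ]
  out <- remove_hot_pixels(img$channels$DNA)
  got <- which(out$hot, arr.ind = TRUE)
  expect_equal(nrow(got), 10L)
  expect_setequal(paste(got[, 1], got[, 2]), paste(hp$row, hp$col))
})

test_that("cell tables round-trip through CSV and specs through JSON", {
  tab <- random_tissue_fixture(41, 20, 40)
  f <- tempfile(fileext = ".csv")
  write_cell_table(tab, f)
  back <- read_cell_table(f)
  expect_equal(back$x_um, tab$x_um, tolerance = 1e-12)
  expect_equal(back$cell_type, tab$cell_type)

  sp <- tissue_spec(mixing = 0.3)
  j <- tempfile(fileext = ".json")
  write_tissue_spec_json(sp, j)
  sp2 <- read_tissue_spec_json(j)
  expect_equal(sp2$mixing, 0.3)
  expect_equal(sp2$cell_types$density, sp$cell_types$density)
})

test_that("images and masks round-trip through TIFF within float precision", {
  ch <- list(DNA = matrix(runif(64) * 40, 8, 8),
             CD3 = matrix(runif(64) * 5, 8, 8))
  f <- tempfile(fileext = ".tif")
  sc <- write_multichannel_tiff(ch, f)
  back <- read_multichannel_tiff(f, c("DNA", "CD3"), scale = sc)
  expect_equal(back$DNA, ch$DNA, tolerance = 1e-6)
  expect_equal(back$CD3, ch$CD3, tolerance = 1e-6)

  mask <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
  fm <- tempfile(fileext = ".tif")
  write_label_mask_tiff(mask, fm)
  expect_identical(read_label_mask_tiff(fm, max_id = 7L), mask)
})
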