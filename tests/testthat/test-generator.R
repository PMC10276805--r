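test_that("configuration invariants are enforced", {
  expect_error(generator_config(nucleus_radius_benign = c(mean = 5, sd = 0.5),
                                nucleus_radius_malignant = c(mean = 4, sd = 0.5)),
               "malignant mean nucleus radius")
  expect_error(generator_config(detail_contrast_benign = 0.5,
                                detail_contrast_malignant = 0.3),
               "detail contrast")
  expect_error(generator_config(nucleus_radius_benign = c(mean = 3, sd = 0)),
               "sd must be > 0")
  expect_error(generator_config(stain_artifact_level = -1), "stain_artifact_level")
  expect_error(generator_config(malignant_fraction = 1.2), "probability")
  expect_s3_class(generator_config(), "generator_config")
})

test_that("identical configuration and seed give byte-identical datasets", {
  cfg <- generator_config(n_patients = 2, clusters_per_patient = c(1, 2), seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$manifest, d2$manifest)
  for (id in names(d1$samples)) {
    expect_identical(d1$samples[[id]]$color_image, d2$samples[[id]]$color_image)
    expect_identical(d1$samples[[id]]$ri_image, d2$samples[[id]]$ri_image)
    expect_identical(d1$samples[[id]]$nucleus_mask, d2$samples[[id]]$nucleus_mask)
  }
})

test_that("malignant_fraction = 0 yields only benign labels", {
  cfg <- generator_config(n_patients = 12, malignant_fraction = 0, seed = 3)
  man <- dataset_manifest(cfg)
  expect_true(all(man$label == "benign"))
})

test_that("malignant cluster share is near its configured value", {
  cfg <- generator_config(seed = 5)
  man <- dataset_manifest(cfg)
  share <- mean(man$label == "malignant")
  # labels are assigned per patient, so the binomial SE uses n_patients
  se <- sqrt(0.265 * 0.735 / cfg$n_patients)
  expect_lt(abs(share - 0.265), 3 * se)
})

test_that("cluster samples satisfy their structural invariants", {
  for (s in small_clusters()) {
    expect_true(all(dim(s$color_image)[1:2] == dim(s$ri_image)))
    expect_true(all(dim(s$nucleus_mask) == dim(s$ri_image)))
    expect_true(all(s$ri_image >= 0))
    expect_true(is.integer(s$color_image))
    expect_true(all(s$color_image >= 0 & s$color_image <= 255))
    labs <- sort(unique(as.vector(s$nucleus_mask)))
    expect_identical(labs, c(0L, seq_len(max(labs))))
    counts <- tabulate(s$nucleus_mask[s$nucleus_mask > 0L])
    expect_equal(s$nucleus_table$area_um2,
                 counts * (26.1 / 256)^2, tolerance = 1e-12)
  }
})

test_that("malignant nuclei are larger than benign nuclei in ground truth", {
  areas <- lapply(small_clusters(8), function(s) {
    data.frame(label = s$label, area = s$nucleus_table$area_um2)
  })
  areas <- do.call(rbind, areas)
  expect_gte(sum(areas$label == "malignant"), 30)
  expect_gte(sum(areas$label == "benign"), 30)
  w <- stats::wilcox.test(area ~ label, data = areas, alternative = "less",
                          exact = FALSE)
  # 'benign' sorts first, so 'less' tests benign < malignant
  expect_lt(w$p.value, 0.01)
  expect_gt(mean(areas$area[areas$label == "malignant"]),
            mean(areas$area[areas$label == "benign"]))
})

test_that("rendered color images behave like bright-background brightfield", {
  cfg <- generator_config(seed = 2)
  empty <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0), r_um = numeric(0))
  bg <- render_color(empty, cfg, seed = 9)
  expect_equal(mean(bg), cfg$color_background_level, tolerance = 0.5)

  one <- data.frame(cx = 512, cy = 512, a = 60, b = 60, theta = 0, r_um = 6)
  img <- render_color(one, cfg, seed = 9)
  centre <- mean(img[385:640, 385:640, ])
  corner <- mean(img[1:256, 1:256, ])
  expect_lt(centre, corner)
})

test_that("nearly all patches of generated clusters pass the color filter", {
  infos <- lapply(small_clusters(8), function(s) tile_pair(s)$info)
  mc <- do.call(rbind, infos)$mean_color
  expect_gte(mean(mc >= 170), 0.99)
})

test_that("detail contrast drives interior Brenner gradient in the RI channel", {
  cfg <- generator_config(seed = 4)
  nuc <- sample_nuclei(cfg, "benign", seed = 11)
  lo <- nuc
  attr(lo, "detail_contrast") <- 0
  hi <- nuc
  attr(hi, "detail_contrast") <- 0.45
  ri_lo <- render_ri(lo, cfg, seed = 11)
  ri_hi <- render_ri(hi, cfg, seed = 11)
  roi <- function(img) {
    k <- which.max(nuc$r_um)
    rows <- round(nuc$cy[k] + (-20:20))
    cols <- round(nuc$cx[k] + (-20:20))
    brenner_gradient(img[rows, cols])
  }
  expect_gt(roi(ri_hi), roi(ri_lo))

  blank <- render_ri(structure(nuc[0, ], detail_contrast = 0), cfg, seed = 12)
  expect_true(all(blank >= 0))
  expect_lt(mean(blank), 4 * cfg$noise_sd_ri)
})

test_that("stain artifacts are additive, sparse and seeded", {
  img <- matrix(0, 512, 512)
  expect_identical(add_stain_artifacts(img, 0, seed = 1), img)
  out1 <- add_stain_artifacts(img, 0.8, seed = 21, max_area_fraction = 0.05)
  out2 <- add_stain_artifacts(img, 0.8, seed = 21, max_area_fraction = 0.05)
  expect_identical(out1, out2)
  delta <- out1 - img
  expect_true(all(delta >= 0))
  expect_lte(mean(delta > 1e-9), 0.05 * 1.05)
  expect_error(add_stain_artifacts(img, -0.1, seed = 1), "level")
})
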