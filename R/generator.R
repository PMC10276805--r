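#' Configuration for the synthetic correlative cytology generator
#'
#' Defines the study conditions under which registered color
#' (Papanicolaou-style brightfield) and 2D-projected refractive-index (RI)
#' images of thyroid cell clusters are synthesised, together with
#' ground-truth nuclear masks. The two class-discriminative axes mirror what
#' the two imaging modalities carry in real correlative cytology: malignant
#' nuclei are larger on average (visible in both modalities, dominant in
#' color), and malignant nuclei show stronger nuclear-envelope and
#' intranuclear detail (chromatin margination, central clearing, granularity)
#' which is expressed only in the RI channel.
#'
#' The RI nucleus body is rendered as a dome of fixed integrated "dry mass"
#' regardless of class, so a larger nucleus is dimmer in proportion; at
#' coarse spatial scales the RI size signal is therefore weak and the RI
#' class signal rides on the detail amplitude. Staining artifacts are added
#' to the RI channel only, as smooth spurious blobs.
#'
#' @param n_patients Number of patients.
#' @param clusters_per_patient Integer range `c(lo, hi)`; the number of
#'   clusters per patient is drawn uniformly from it.
#' @param malignant_fraction Probability that a patient (and hence all of the
#'   patient's clusters) is malignant.
#' @param image_size Square image side in pixels.
#' @param pixel_pitch Pixel pitch in micrometres per pixel.
#' @param nuclei_per_cluster Integer range for the number of nuclei.
#' @param nucleus_radius_benign,nucleus_radius_malignant Named numeric
#'   `c(mean=, sd=)` of the equivalent-circle nucleus radius in micrometres.
#' @param detail_contrast_benign,detail_contrast_malignant Dimensionless
#'   amplitude of nuclear-envelope ring, central clearing and intranuclear
#'   speckle in the RI channel.
#' @param color_background_level 8-bit background level of the color image.
#' @param stain_artifact_level Dimensionless amplitude of staining artifacts
#'   added to the RI channel; 0 disables them.
#' @param noise_sd_color,noise_sd_ri Per-pixel Gaussian noise standard
#'   deviations (8-bit counts and RI units respectively).
#' @param seed Master seed; every cluster derives its own stream from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 124,
                             clusters_per_patient = c(1, 2),
                             malignant_fraction = 0.265,
                             image_size = 1024,
                             pixel_pitch = 26.1 / 256,
                             nuclei_per_cluster = c(8, 18),
                             nucleus_radius_benign = c(mean = 3.5, sd = 0.5),
                             nucleus_radius_malignant = c(mean = 5.0, sd = 0.8),
                             detail_contrast_benign = 0.15,
                             detail_contrast_malignant = 0.45,
                             color_background_level = 200,
                             stain_artifact_level = 0.6,
                             noise_sd_color = 3,
                             noise_sd_ri = 0.02,
                             seed = 1) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    clusters_per_patient = as.integer(clusters_per_patient),
    malignant_fraction = malignant_fraction,
    image_size = as.integer(image_size),
    pixel_pitch = pixel_pitch,
    nuclei_per_cluster = as.integer(nuclei_per_cluster),
    nucleus_radius_benign = nucleus_radius_benign,
    nucleus_radius_malignant = nucleus_radius_malignant,
    detail_contrast_benign = detail_contrast_benign,
    detail_contrast_malignant = detail_contrast_malignant,
    color_background_level = color_background_level,
    stain_artifact_level = stain_artifact_level,
    noise_sd_color = noise_sd_color,
    noise_sd_ri = noise_sd_ri,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid generator configuration: ", msg, call. = FALSE)
  if (cfg$n_patients < 1) stop_cfg("n_patients must be >= 1")
  if (length(cfg$clusters_per_patient) != 2 || any(cfg$clusters_per_patient < 1) ||
      cfg$clusters_per_patient[1] > cfg$clusters_per_patient[2]) {
    stop_cfg("clusters_per_patient must be an increasing positive range")
  }
  if (cfg$malignant_fraction < 0 || cfg$malignant_fraction > 1) {
    stop_cfg("malignant_fraction must be a probability")
  }
  if (cfg$image_size < 256) stop_cfg("image_size must be >= 256")
  rb <- cfg$nucleus_radius_benign
  rm_ <- cfg$nucleus_radius_malignant
  if (is.null(names(rb)) || is.null(names(rm_)) ||
      !all(c("mean", "sd") %in% names(rb)) || !all(c("mean", "sd") %in% names(rm_))) {
    stop_cfg("nucleus radii must be named c(mean=, sd=) vectors")
  }
  if (rm_[["mean"]] <= rb[["mean"]]) {
    stop_cfg("malignant mean nucleus radius must exceed the benign mean")
  }
  if (rb[["sd"]] <= 0 || rm_[["sd"]] <= 0) {
    stop_cfg("radius sd must be > 0 so the class distributions overlap")
  }
  if (cfg$detail_contrast_malignant <= cfg$detail_contrast_benign) {
    stop_cfg("malignant detail contrast must exceed the benign detail contrast")
  }
  if (cfg$detail_contrast_benign < 0) stop_cfg("detail contrast must be >= 0")
  if (cfg$stain_artifact_level < 0) stop_cfg("stain_artifact_level must be >= 0")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic correlative cytology generator\n")
  cat(sprintf("  patients: %d, clusters/patient: %d-%d, malignant fraction: %.3f\n",
              x$n_patients, x$clusters_per_patient[1], x$clusters_per_patient[2],
              x$malignant_fraction))
  cat(sprintf("  image: %d px @ %.4f um/px\n", x$image_size, x$pixel_pitch))
  cat(sprintf("  nucleus radius (um): benign %.2f+-%.2f, malignant %.2f+-%.2f\n",
              x$nucleus_radius_benign[["mean"]], x$nucleus_radius_benign[["sd"]],
              x$nucleus_radius_malignant[["mean"]], x$nucleus_radius_malignant[["sd"]]))
  cat(sprintf("  RI detail contrast: benign %.2f, malignant %.2f; artifacts %.2f\n",
              x$detail_contrast_benign, x$detail_contrast_malignant,
              x$stain_artifact_level))
  invisible(x)
}

#' Patient/cluster manifest implied by a generator configuration
#'
#' Assigns every cluster a patient, a class label (shared by all clusters of
#' a patient, as a thyroid nodule is diagnosed per patient) and a private
#' render seed derived from the master seed, so clusters can be materialised
#' independently and reproducibly.
#'
#' @param config A [generator_config()].
#' @return A data.frame with one row per cluster: `cluster_id`, `patient_id`,
#'   `label`, `render_seed`.
#' @export
dataset_manifest <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    lab_patient <- rbinom(config$n_patients, 1, config$malignant_fraction)
    ncl <- sample(seq(config$clusters_per_patient[1], config$clusters_per_patient[2]),
                  config$n_patients, replace = TRUE)
    patient <- rep(seq_len(config$n_patients), ncl)
    n <- length(patient)
    data.frame(
      cluster_id = sprintf("cl%04d", seq_len(n)),
      patient_id = sprintf("pt%03d", patient),
      label = ifelse(lab_patient[patient] == 1, "malignant", "benign"),
      render_seed = vapply(seq_len(n), function(i) derive_seed(config$seed, i), integer(1)),
      stringsAsFactors = FALSE
    )
  })
}

# ---- nucleus geometry ------------------------------------------------------

#' Sample nucleus geometry for one cluster
#'
#' Nuclei are ellipses (axis ratio in \[0.75, 1\], i.e. eccentricity <= 0.7)
#' of class-dependent equivalent radius, placed as a Gaussian spatial clump
#' around the image centre with a minimum centre-to-centre separation.
#'
#' @param config A [generator_config()].
#' @param label `"benign"` or `"malignant"`.
#' @param seed Integer seed for this cluster's stream.
#' @return A data.frame with columns `cx`, `cy` (pixel centres), `a`, `b`
#'   (semi-axes, px), `theta` (orientation, rad), `r_um` (equivalent radius).
#' @export
sample_nuclei <- function(config, label, seed) {
  with_seed(seed, {
    H <- config$image_size
    rpar <- if (label == "malignant") config$nucleus_radius_malignant else config$nucleus_radius_benign
    n <- sample(seq(config$nuclei_per_cluster[1], config$nuclei_per_cluster[2]), 1)
    clump_sd <- 0.27 * H
    c0 <- H / 2 + rnorm(2, 0, 0.04 * H)
    out <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0), r_um = numeric(0))
    for (k in seq_len(n)) {
      r_um <- max(rnorm(1, rpar[["mean"]], rpar[["sd"]]), 1.2)
      r_px <- r_um / config$pixel_pitch
      q <- runif(1, 0.75, 1)         # axis ratio b/a; eccentricity <= 0.7
      a <- r_px / sqrt(q)
      b <- r_px * sqrt(q)
      theta <- runif(1, 0, pi)
      placed <- FALSE
      for (try in 1:40) {
        p <- c0 + rnorm(2, 0, clump_sd)
        p <- pmin(pmax(p, a + 4), H - a - 4)
        if (nrow(out) == 0 ||
            all((out$cx - p[1])^2 + (out$cy - p[2])^2 > (2.0 * r_px)^2)) {
          placed <- TRUE
          break
        }
      }
      if (placed) {
        out <- rbind(out, data.frame(cx = p[1], cy = p[2], a = a, b = b,
                                     theta = theta, r_um = r_um))
      }
    }
    attr(out, "detail_contrast") <- if (label == "malignant") {
      config$detail_contrast_malignant
    } else {
      config$detail_contrast_benign
    }
    out
  })
}

# ---- rendering -------------------------------------------------------------

#' Render the Papanicolaou-style color image of one cluster
#'
#' Bright background near `color_background_level` counts with darker
#' blue-purple nuclei surrounded by a faint cytoplasm tint, plus per-channel
#' Gaussian noise. The color modality intentionally carries no intranuclear
#' detail; its class signal is nucleus size.
#'
#' @param nuclei Output of [sample_nuclei()].
#' @param config A [generator_config()].
#' @param seed Integer seed for the noise field.
#' @return An `image_size` x `image_size` x 3 integer array of 8-bit counts.
#' @export
render_color <- function(nuclei, config, seed, cyto_field = NULL) {
  H <- config$image_size
  L <- config$color_background_level
  base <- L + c(5, -8, 3)                 # channel offsets, pooled mean == L
  d_cyto <- c(8, 14, 3)
  d_nuc <- c(62, 80, 36)
  cov_c <- if (is.null(cyto_field)) cytoplasm_field(nuclei, H) else cyto_field
  cov_n <- cov_field_cpp(H, nuclei$cx, nuclei$cy, nuclei$a, nuclei$b,
                         nuclei$theta, 1.0, 0.06)
  finalize_color_cpp(cov_c, cov_n, base, d_cyto, d_nuc,
                     config$noise_sd_color, derive_seed(seed, 1L))
}

#' Render the projected refractive-index image of one cluster
#'
#' Each nucleus contributes a dome of projected RI excess whose integrated
#' mass is class-independent (fixed dry mass: larger nuclei are
#' proportionally dimmer), a nuclear-envelope ring, a central chromatin
#' clearing and intranuclear speckles whose amplitudes scale with the class
#' detail contrast, plus a faint cytoplasm plateau and Gaussian noise clipped
#' at zero. Values are non-negative "projected RI excess" in arbitrary units.
#'
#' @inheritParams render_color
#' @return An `image_size` x `image_size` numeric matrix, values >= 0.
#' @export
render_ri <- function(nuclei, config, seed, cyto_field = NULL) {
  H <- config$image_size
  detail <- attr(nuclei, "detail_contrast")
  if (is.null(detail)) {
    stop("nuclei must carry a 'detail_contrast' attribute (see sample_nuclei)", call. = FALSE)
  }
  r_ref <- config$nucleus_radius_benign[["mean"]] / config$pixel_pitch
  geom <- with_seed(derive_seed(seed, 2L), {
    n <- nrow(nuclei)
    # fixed dry mass per nucleus (log-normal jitter): dome height scales
    # inversely with nucleus area, so bigger nuclei are dimmer; the dome is
    # kept faint relative to envelope/speckle detail
    mass <- 0.3 * pi * r_ref^2 * exp(rnorm(n, 0, 0.15))
    h_c <- 1.5 * mass / (pi * nuclei$a * nuclei$b)
    spk <- lapply(seq_len(n), function(k) {
      n_spk <- rpois(1, 3 + 14 * detail)
      if (n_spk == 0) return(NULL)
      # uniform positions inside 0.75 of the envelope (rejection sampling)
      uv <- matrix(numeric(0), ncol = 2)
      while (nrow(uv) < n_spk) {
        cand <- matrix(runif(2 * n_spk, -0.75, 0.75), ncol = 2)
        cand <- cand[rowSums(cand^2) <= 0.75^2, , drop = FALSE]
        uv <- rbind(uv, cand)
      }
      uv <- uv[seq_len(n_spk), , drop = FALSE]
      ct <- cos(nuclei$theta[k])
      st <- sin(nuclei$theta[k])
      data.frame(
        px = nuclei$cx[k] + uv[, 1] * nuclei$a[k] * ct - uv[, 2] * nuclei$b[k] * st,
        py = nuclei$cy[k] + uv[, 1] * nuclei$a[k] * st + uv[, 2] * nuclei$b[k] * ct,
        rs = runif(n_spk, 1.5, 3.0),
        amp = detail * runif(n_spk, 0.8, 1.8)
      )
    })
    list(h_c = h_c, spk = do.call(rbind, spk))
  })
  spk <- geom$spk
  if (is.null(spk)) spk <- data.frame(px = numeric(0), py = numeric(0),
                                      rs = numeric(0), amp = numeric(0))
  # ring amplitude scales inversely with nucleus radius (fixed ring mass),
  # so the envelope signal tracks detail contrast rather than nucleus size
  ring_amp <- 1.2 * detail * r_ref / sqrt(nuclei$a * nuclei$b)
  ri <- ri_geom_cpp(H, nuclei$cx, nuclei$cy, nuclei$a, nuclei$b, nuclei$theta,
                    geom$h_c, detail, ring_amp, spk$px, spk$py, spk$rs, spk$amp)
  cov_c <- if (is.null(cyto_field)) cytoplasm_field(nuclei, H) else cyto_field
  finalize_ri_cpp(ri, cov_c, 0.03, config$noise_sd_ri, derive_seed(seed, 3L))
}

# Shared soft coverage field of the cytoplasm halo (2.1x the nuclear
# ellipse); identical in both modalities since the images are registered.
cytoplasm_field <- function(nuclei, H) {
  cov_field_cpp(H, nuclei$cx, nuclei$cy, nuclei$a, nuclei$b, nuclei$theta,
                2.1, 0.10)
}

#' Add staining artifacts to an RI image
#'
#' Staining contaminates the RI modality with sparse spurious signal. The
#' artifacts are smooth, compactly supported raised-cosine blobs and streaks
#' (elongated blobs) added to the image; `level = 0` returns the input
#' unchanged, and the summed support of the blobs is capped at
#' `max_area_fraction` of the image.
#'
#' @param ri_image Non-negative numeric matrix.
#' @param level Dimensionless artifact amplitude, >= 0.
#' @param seed Integer seed.
#' @param max_area_fraction Cap on the artifact support area fraction.
#' @return The contaminated RI image (elementwise >= the input).
#' @export
add_stain_artifacts <- function(ri_image, level, seed, max_area_fraction = 0.03) {
  if (level < 0) stop("invalid configuration: stain artifact level must be >= 0", call. = FALSE)
  if (level == 0) return(ri_image)
  H <- nrow(ri_image)
  W <- ncol(ri_image)
  blobs <- with_seed(seed, {
    budget <- max_area_fraction * H * W
    used <- 0
    rows <- list()
    for (i in 1:60) {
      r1 <- runif(1, 18, 50)
      q <- runif(1, 0.25, 1)
      a <- r1 / sqrt(q)
      b <- r1 * sqrt(q)
      if (used + pi * a * b > budget) break
      used <- used + pi * a * b
      rows[[i]] <- data.frame(cx = runif(1, 1, W), cy = runif(1, 1, H),
                              a = a, b = b, theta = runif(1, 0, pi),
                              amp = level * runif(1, 0.35, 1.1))
    }
    do.call(rbind, rows)
  })
  if (is.null(blobs)) return(ri_image)
  add_bumps_cpp(ri_image, blobs$cx, blobs$cy, blobs$a, blobs$b, blobs$theta,
                blobs$amp)
}

# Ground-truth nucleus label map (hard ellipse membership, first nucleus wins)
# and the per-nucleus area table derived from it.
nucleus_mask <- function(nuclei, H, pixel_pitch) {
  mask <- mask_field_cpp(H, nuclei$cx, nuclei$cy, nuclei$a, nuclei$b,
                         nuclei$theta)
  # relabel consecutively in case a nucleus was fully occluded
  present <- sort(unique(mask[mask > 0L]))
  relab <- integer(max(c(0L, present)))
  relab[present] <- seq_along(present)
  if (length(present) > 0 && !identical(present, seq_along(present))) {
    idx <- mask > 0L
    mask[idx] <- relab[mask[idx]]
  }
  counts <- tabulate(mask[mask > 0L], nbins = length(present))
  tab <- data.frame(
    nucleus = seq_along(present),
    cx = nuclei$cx[present],
    cy = nuclei$cy[present],
    r_um = nuclei$r_um[present],
    area_um2 = counts * pixel_pitch^2
  )
  list(mask = mask, table = tab)
}

#' Materialise one cluster sample
#'
#' Renders the registered color and RI images, the ground-truth nucleus mask
#' and the per-nucleus area table for one row of [dataset_manifest()].
#' Rendering is fully determined by the row's `render_seed`.
#'
#' @param config A [generator_config()].
#' @param meta One manifest row (or a list with `cluster_id`, `patient_id`,
#'   `label`, `render_seed`).
#' @return An object of class `cluster_sample`: a list with `cluster_id`,
#'   `patient_id`, `label`, `color_image` (H x W x 3 integer), `ri_image`
#'   (H x W numeric, >= 0), `nucleus_mask` (H x W integer label map) and
#'   `nucleus_table`.
#' @export
render_cluster <- function(config, meta) {
  seed <- meta$render_seed
  nuclei <- sample_nuclei(config, meta$label, seed)
  mk <- nucleus_mask(nuclei, config$image_size, config$pixel_pitch)
  cyto <- cytoplasm_field(nuclei, config$image_size)
  color <- render_color(nuclei, config, seed, cyto_field = cyto)
  ri <- render_ri(nuclei, config, seed, cyto_field = cyto)
  ri <- add_stain_artifacts(ri, config$stain_artifact_level, derive_seed(seed, 4L),
                            max_area_fraction = 0.12)
  structure(list(
    cluster_id = meta$cluster_id,
    patient_id = meta$patient_id,
    label = meta$label,
    color_image = color,
    ri_image = ri,
    nucleus_mask = mk$mask,
    nucleus_table = mk$table
  ), class = "cluster_sample")
}

#' @export
print.cluster_sample <- function(x, ...) {
  cat(sprintf("cluster_sample %s (%s, patient %s): %d x %d px, %d nuclei\n",
              x$cluster_id, x$label, x$patient_id,
              nrow(x$ri_image), ncol(x$ri_image), nrow(x$nucleus_table)))
  invisible(x)
}

#' Generate a full synthetic dataset
#'
#' Materialises every cluster of [dataset_manifest()]. Identical
#' configurations (including the seed) produce identical datasets. Intended
#' for moderate sizes; large experiments should iterate over
#' [render_cluster()] to keep one cluster in memory at a time.
#'
#' @param config A [generator_config()].
#' @return A list with `manifest` and `samples` (list of `cluster_sample`),
#'   of class `cluster_dataset`.
#' @export
generate_dataset <- function(config) {
  manifest <- dataset_manifest(config)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    render_cluster(config, manifest[i, ])
  })
  names(samples) <- manifest$cluster_id
  structure(list(manifest = manifest, samples = samples), class = "cluster_dataset")
}

#' @export
print.cluster_dataset <- function(x, ...) {
  cat(sprintf("cluster_dataset: %d clusters from %d patients (%.1f%% malignant)\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id)),
              100 * mean(x$manifest$label == "malignant")))
  invisible(x)
}
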