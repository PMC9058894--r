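#' Default H&E optical-density stain vectors
#'
#' Unit-norm hematoxylin and eosin OD vectors in the usual range for
#' routine H&E scans; used by the synthetic slide renderer and available
#' as a normalization reference.
#'
#' @return 3 x 2 matrix, columns H and E.
#' @export
default_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  cbind(h = h / sqrt(sum(h^2)), e = e / sqrt(sum(e^2)))
}

#' Texture specification for synthetic H&E-like slides
#'
#' Two simple texture families emulate the class signal a tile
#' classifier exploits: class 1 ("MSI-like") renders dense small
#' hematoxylin discs reminiscent of lymphocyte-rich tissue; class 0
#' ("MSS-like") renders larger ring/gland-like structures. The
#' primitives are deliberately simple -- the goal is a learnable,
#' controllable class signal, not histological realism.
#'
#' @param label tile/slide class (1 = MSI-like, 0 = MSS-like).
#' @param primitive `"disc"` or `"ring"`.
#' @param density primitives per mm^2.
#' @param radius_um two-element range of primitive radii, micrometres.
#' @param h_conc,e_conc two-element ranges of hematoxylin / eosin
#'   concentration (OD scale) inside a primitive and its halo.
#' @param stain_vectors 3 x 2 OD matrix used for Beer--Lambert rendering.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(label,
                         primitive = if (label == 1) "disc" else "ring",
                         density = if (label == 1) 1500 else 250,
                         radius_um = if (label == 1) c(3, 6) else c(12, 20),
                         h_conc = c(0.6, 1.1), e_conc = c(0.15, 0.35),
                         stain_vectors = default_stain_vectors()) {
  primitive <- match.arg(primitive, c("disc", "ring"))
  stopifnot(density >= 0, length(radius_um) == 2L, all(radius_um > 0))
  structure(list(label = as.integer(label), primitive = primitive,
                 density = density, radius_um = radius_um,
                 h_conc = h_conc, e_conc = e_conc,
                 stain_vectors = stain_vectors),
            class = "texture_spec")
}

#' Render a synthetic H&E-like slide
#'
#' Places texture primitives as hematoxylin/eosin concentration fields
#' and composes them to RGB through the Beer--Lambert model
#' `I = 256 * 10^(-(c_h * v_h + c_e * v_e)) - 1` with the texture spec's stain
#' vectors; the background stays near-white. A pure function of
#' `(spec, size, scale, seed)`.
#'
#' @param spec a [texture_spec()].
#' @param size_px slide edge, pixels (square slide).
#' @param microns_per_pixel physical scale.
#' @param seed integer seed.
#' @param slide_id,patient_id identifiers.
#' @return List: `slide` (a [slide_raster()]) and `tile_class` (the
#'   generating class, shared by all tiles of the slide).
#' @export
make_synthetic_slide <- function(spec, size_px = 512, microns_per_pixel = 1,
                                 seed = 1L, slide_id = "synth",
                                 patient_id = slide_id) {
  stopifnot(inherits(spec, "texture_spec"), size_px >= 8)
  area_mm2 <- (size_px * microns_per_pixel / 1000)^2
  n <- max(0L, as.integer(round(spec$density * area_mm2)))
  ch <- matrix(0, size_px, size_px)
  ce <- matrix(0, size_px, size_px)
  if (n > 0) with_local_seed(seed, {
    cx <- stats::runif(n, 1, size_px)
    cy <- stats::runif(n, 1, size_px)
    rad <- stats::runif(n, spec$radius_um[1], spec$radius_um[2]) /
      microns_per_pixel
    hc <- stats::runif(n, spec$h_conc[1], spec$h_conc[2])
    ec <- stats::runif(n, spec$e_conc[1], spec$e_conc[2])
    for (k in seq_len(n)) {
      r <- rad[k]
      halo <- 1.8 * r
      r0 <- max(1L, floor(cy[k] - halo)); r1 <- min(size_px, ceiling(cy[k] + halo))
      c0 <- max(1L, floor(cx[k] - halo)); c1 <- min(size_px, ceiling(cx[k] + halo))
      yy <- r0:r1; xx <- c0:c1
      dist <- sqrt(outer((yy - cy[k])^2, (xx - cx[k])^2, "+"))
      if (spec$primitive == "disc") {
        core <- dist <= r
      } else {
        core <- dist <= r & dist >= 0.65 * r
      }
      ch[yy, xx][core] <- pmin(ch[yy, xx][core] + hc[k], 1.6)
      halo_m <- dist <= halo
      ce[yy, xx][halo_m] <- pmin(ce[yy, xx][halo_m] + ec[k], 0.8)
    }
  })
  sv <- spec$stain_vectors
  od <- cbind(c(ch), c(ce)) %*% t(sv)
  px <- array(od_to_rgb(od), c(size_px, size_px, 3))
  list(slide = slide_raster(px, microns_per_pixel, slide_id, patient_id),
       tile_class = spec$label)
}

#' Cohort specification for synthetic patient-score tables
#'
#' Patient labels are Bernoulli draws at the given prevalence (default
#' 0.12, the approximate MSI/dMMR rate in colorectal cancer); patient
#' scores are drawn from class-conditional Beta distributions. The
#' defaults Beta(4, 2) for positives versus Beta(2, 4) for negatives
#' give a generating-model AUROC of about 0.9, the regime of a
#' well-performing slide classifier.
#'
#' @param n_patients cohort size.
#' @param prevalence positive-class probability.
#' @param beta_pos,beta_neg two-element shape vectors of the
#'   class-conditional Beta score models.
#' @param tiles_range range of per-patient tile counts (metadata only).
#' @param cohort_id identifier.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, prevalence = 0.12,
                        beta_pos = c(4, 2), beta_neg = c(2, 4),
                        tiles_range = c(50, 500), cohort_id = "synth") {
  stopifnot(n_patients >= 1, prevalence > 0, prevalence < 1,
            all(beta_pos > 0), all(beta_neg > 0))
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence, beta_pos = beta_pos,
                 beta_neg = beta_neg, tiles_range = tiles_range,
                 cohort_id = as.character(cohort_id)),
            class = "cohort_spec")
}

#' Simulate a labeled patient-score cohort
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return Data frame `patient_id`, `cohort_id`, `label`, `score`,
#'   `n_tiles`.
#' @export
make_synthetic_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(seed, {
    n <- spec$n_patients
    label <- stats::rbinom(n, 1, spec$prevalence)
    score <- ifelse(label == 1,
                    stats::rbeta(n, spec$beta_pos[1], spec$beta_pos[2]),
                    stats::rbeta(n, spec$beta_neg[1], spec$beta_neg[2]))
    data.frame(
      patient_id = sprintf("%s_p%04d", spec$cohort_id, seq_len(n)),
      cohort_id = spec$cohort_id, label = label, score = score,
      n_tiles = sample(spec$tiles_range[1]:spec$tiles_range[2], n,
                       replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Closed-form AUROC of two Beta score models
#'
#' `P(X1 > X0)` for `X1 ~ Beta(a1, b1)` (positives) and
#' `X0 ~ Beta(a0, b0)` (negatives), by numerical integration; the ground
#' truth against which empirical AUROCs of synthetic cohorts are judged.
#'
#' @param beta_pos,beta_neg two-element shape vectors.
#' @return A number in `[0, 1]`.
#' @export
beta_model_auroc <- function(beta_pos = c(4, 2), beta_neg = c(2, 4)) {
  stats::integrate(function(x)
    stats::dbeta(x, beta_pos[1], beta_pos[2]) *
      stats::pbeta(x, beta_neg[1], beta_neg[2]),
    0, 1, rel.tol = 1e-10)$value
}

#' Inject slide-level artifacts
#'
#' Emulates common slide-quality failure modes so the QC stage can be
#' stress-tested: `"blur"` applies Gaussian smoothing (sigma =
#' `6 * severity` px), `"fold"` overlays a darkened duplicated band, and
#' `"overstain"` scales all optical densities by `1 + severity`.
#' Severity 0 is the identity; results are deterministic per seed.
#'
#' @param slide a [slide_raster()].
#' @param kind `"blur"`, `"fold"`, or `"overstain"`.
#' @param severity nonnegative severity.
#' @param seed integer seed (used by `"fold"` band placement).
#' @return The degraded [slide_raster()].
#' @export
inject_artifacts <- function(slide, kind, severity = 1, seed = 1L) {
  kind <- match.arg(kind, c("blur", "fold", "overstain"))
  stopifnot(inherits(slide, "slide_raster"), severity >= 0)
  if (severity == 0) return(slide)
  px <- slide$pixels
  d <- dim(px)
  if (kind == "blur") {
    for (ch in 1:3) px[, , ch] <- EBImage::gblur(px[, , ch],
                                                 sigma = 6 * severity)
  } else if (kind == "fold") {
    band <- max(2L, as.integer(round(d[1] * 0.08 * min(severity, 3))))
    top <- with_local_seed(seed, sample.int(d[1] - 2L * band, 1L))
    rows <- top + seq_len(band)
    px[rows + band, , ] <- clamp8(0.5 * px[rows, , ] + 0.5 * px[rows + band, , ] -
                                    40 * severity)
  } else {
    od <- rgb_to_od(px)
    px <- array(od_to_rgb((1 + severity) * od), d)
  }
  slide$pixels <- clamp8(px)
  slide
}

#' Emit a complete synthetic study to disk
#'
#' Renders one slide per patient (texture class = patient label), writes
#' slide PNGs, a manifest CSV (`patient_id`, `cohort_id`, `label`,
#' `slide_path`, `microns_per_pixel`) and a ground-truth JSON, so the
#' full pipeline can be run from files alone.
#'
#' @param out_dir output directory (created if missing).
#' @param n_cohorts,patients_per_cohort study size.
#' @param prevalence positive-class probability per cohort.
#' @param size_px,microns_per_pixel slide geometry.
#' @param seed integer seed.
#' @return Path of the manifest CSV, invisibly.
#' @export
make_synthetic_study <- function(out_dir, n_cohorts = 4,
                                 patients_per_cohort = 8, prevalence = 0.5,
                                 size_px = 256, microns_per_pixel = 1,
                                 seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truth <- list()
  k <- 0L
  for (ci in seq_len(n_cohorts)) {
    cid <- sprintf("cohort%02d", ci)
    labels <- with_local_seed(seed + 1000L * ci, {
      l <- stats::rbinom(patients_per_cohort, 1, prevalence)
      # guarantee both classes so every cohort is evaluable
      if (sum(l) == 0) l[1] <- 1L
      if (sum(l) == patients_per_cohort) l[1] <- 0L
      l
    })
    for (pi in seq_len(patients_per_cohort)) {
      k <- k + 1L
      pid <- sprintf("%s_p%03d", cid, pi)
      sl <- make_synthetic_slide(texture_spec(labels[pi]), size_px,
                                 microns_per_pixel, seed = seed + k,
                                 slide_id = pid, patient_id = pid)
      path <- file.path(out_dir, paste0(pid, ".png"))
      write_png_image(sl$slide, path)
      rows[[k]] <- data.frame(patient_id = pid, cohort_id = cid,
                              label = labels[pi], slide_path = path,
                              microns_per_pixel = microns_per_pixel,
                              stringsAsFactors = FALSE)
      truth[[pid]] <- list(label = labels[pi], tile_class = sl$tile_class)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(mpath)
}
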