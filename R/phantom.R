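#' Parametric description of a synthetic thorax phantom
#'
#' A `phantom_spec` fixes everything about a synthetic CT cohort except the
#' per-case random draws: grid shape and spacing, the per-case pathology
#' probabilities, and the HU intensity model per tissue class. Two calls with
#' the same spec and seed produce bit-identical cases.
#'
#' The phantom emulates thoracic CT at the appearance-class level: air near
#' -1000 HU, aerated lung around -740 HU, soft tissue near +40 HU, bone
#' several hundred HU, plus optional dense pathologies (pleural effusion,
#' consolidation, tumour) and pneumothorax. Effusion, consolidation and
#' tumour voxels are part of the lung ground truth (dense anomalies are
#' deliberately included in the target masks); the trachea and pneumothorax
#' air are excluded.
#'
#' @param shape integer length-3 `(z, y, x)` grid size; at least
#'   `c(16, 32, 32)`.
#' @param spacing numeric length-3 voxel size in mm `(z, y, x)`.
#' @param pathology_mix named probabilities over
#'   `c("none", "effusion", "consolidation", "tumour", "pneumothorax")`;
#'   each in \[0, 1\], normalised to a per-case categorical draw.
#' @param intensity_model named list of `c(mean, sd)` HU pairs per tissue
#'   class (`air`, `lung`, `soft`, `bone`, `effusion`, `consolidation`,
#'   `tumour`, `pneumothorax`).
#' @param noise_sigma global additive Gaussian noise, HU.
#' @param seed integer master seed used by [generate_cohort()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(16, 96, 96),
                         spacing = c(5, 1.8, 1.8),
                         pathology_mix = c(none = 0.4, effusion = 0.2,
                                           consolidation = 0.2, tumour = 0.2),
                         intensity_model = default_intensity_model(),
                         noise_sigma = 20,
                         seed = 0L) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3 && all(shape >= c(16L, 32L, 32L)),
              "shape must be (z, y, x) with z >= 16 and y, x >= 32")
  assert_that(is.numeric(spacing) && length(spacing) == 3 && all(spacing > 0),
              "spacing must be three strictly positive numbers")
  known <- c("none", "effusion", "consolidation", "tumour", "pneumothorax")
  assert_that(length(pathology_mix) > 0 && !is.null(names(pathology_mix)) &&
                all(names(pathology_mix) %in% known),
              "pathology_mix names must be among none/effusion/consolidation/tumour/pneumothorax")
  assert_that(all(pathology_mix >= 0 & pathology_mix <= 1),
              "pathology_mix probabilities must lie in [0, 1]")
  assert_that(sum(pathology_mix) > 0, "pathology_mix must have positive total mass")
  im <- modifyList(default_intensity_model(), as.list(intensity_model))
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         pathology_mix = pathology_mix / sum(pathology_mix),
         intensity_model = im, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @rdname phantom_spec
#' @export
default_intensity_model <- function() {
  list(air = c(-1000, 0), lung = c(-740, 40), soft = c(40, 15),
       bone = c(600, 120), effusion = c(10, 15), consolidation = c(40, 20),
       tumour = c(30, 20), pneumothorax = c(-1000, 0))
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%dx%d voxels @ %.3g/%.3g/%.3g mm, noise sd %g HU\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$noise_sigma))
  cat("  pathology mix:",
      paste(sprintf("%s %.2f", names(x$pathology_mix), x$pathology_mix), collapse = ", "),
      "\n")
  invisible(x)
}

# ellipsoid membership on the (z,y,x) grid (0-based voxel indices)
ellipsoid_mask <- function(shape, centre, radii) {
  z <- (seq_len(shape[1]) - 1 - centre[1]) / radii[1]
  y <- (seq_len(shape[2]) - 1 - centre[2]) / radii[2]
  x <- (seq_len(shape[3]) - 1 - centre[3]) / radii[3]
  outer(outer(z^2, y^2, `+`), x^2, `+`) <= 1
}

phantom_geometry <- function(shape) {
  cz <- (shape[1] - 1) / 2; cy <- (shape[2] - 1) / 2; cx <- (shape[3] - 1) / 2
  list(
    cz = cz, cy = cy, cx = cx,
    body_r = c(Inf, 0.38 * shape[2], 0.44 * shape[3]),
    # the thorax is chiral: the right lung is wider and shorter, the left
    # carries the cardiac notch; phantom laterality cues mirror that
    lung_r_right = c(0.30 * shape[1], 0.25 * shape[2], 0.165 * shape[3]),
    lung_r_left = c(0.32 * shape[1], 0.25 * shape[2], 0.14 * shape[3]),
    lung_cx = c(right = cx - 0.21 * shape[3], left = cx + 0.22 * shape[3]),
    heart_c = c(0.30 * (shape[1] - 1), cy - 0.08 * shape[2], cx + 0.10 * shape[3]),
    heart_r = c(0.34 * shape[1], 0.20 * shape[2], 0.17 * shape[3]),
    trachea_r = max(1.5, 0.025 * shape[3]),
    spine_r = max(2, 0.06 * shape[2])
  )
}

draw_hu <- function(n, class_pair) {
  if (class_pair[2] <= 0) rep(class_pair[1], n) else rnorm(n, class_pair[1], class_pair[2])
}

#' Generate one synthetic thorax phantom
#'
#' Builds a soft-tissue body ellipsoid containing two disjoint lung
#' ellipsoids (label 1 = right lung at lower x, label 2 = left), a tubular
#' trachea excluded from the lung mask, a vertebral column, and (depending
#' on the per-case pathology draw) one of pleural effusion, consolidation,
#' tumour, or pneumothorax. Voxels outside the body are air near -1000 HU.
#'
#' @param spec a [phantom_spec()].
#' @param case_seed integer RNG seed for this case; fully determines the
#'   output together with `spec`.
#' @return An object of class `phantom_case`: a list with `volume`
#'   ([ct_volume()]), `lung_mask` ([lung_mask()]), `pathology_map` (integer
#'   array: 0 none, 1 effusion, 2 consolidation, 3 tumour, 4 pneumothorax),
#'   `pathology` (character), `spec`, and `case_seed`.
#' @export
generate_phantom <- function(spec, case_seed = spec$seed) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  withr::with_seed(as.integer(case_seed), generate_phantom_impl(spec, case_seed))
}

generate_phantom_impl <- function(spec, case_seed) {
  shp <- spec$shape
  g <- phantom_geometry(shp)
  im <- spec$intensity_model

  # per-case anatomical variability: habitus varies, and each lung varies
  # *independently* in size and position, as real lungs do — so neither a
  # memorised grid position nor the contralateral lung predicts where a
  # lung (or the dense pathology replacing part of it) has to be
  s_body <- runif(1, 0.92, 1.08)
  s_right <- c(runif(1, 0.88, 1.10), runif(1, 0.92, 1.08), runif(1, 0.90, 1.10))
  s_left <- c(runif(1, 0.88, 1.10), runif(1, 0.92, 1.08), runif(1, 0.90, 1.10))
  jit_r <- runif(2, -0.04, 0.04) * shp[2:3]
  jit_l <- runif(2, -0.04, 0.04) * shp[2:3]
  body <- ellipsoid_mask(shp, c(g$cz, g$cy, g$cx), g$body_r * c(1, s_body, s_body))
  lungs <- list(
    right = ellipsoid_mask(shp, c(g$cz, g$cy + jit_r[1], g$lung_cx["right"] + jit_r[2]),
                           g$lung_r_right * s_right),
    left = ellipsoid_mask(shp, c(g$cz, g$cy + jit_l[1], g$lung_cx["left"] - jit_l[2]),
                          g$lung_r_left * s_left)
  )
  heart <- ellipsoid_mask(shp, g$heart_c + c(0, jit_l[1], jit_l[2]),
                          g$heart_r * c(1, s_body, s_body))
  lungs <- lapply(lungs, function(m) m & body & !heart)
  trachea <- ellipsoid_mask(shp, c(shp[1] - 1, g$cy - 0.06 * shp[2], g$cx),
                            c(0.55 * shp[1], g$trachea_r, g$trachea_r))
  trachea <- trachea & body & !lungs$right & !lungs$left
  spine <- ellipsoid_mask(shp, c(g$cz, g$cy + 0.30 * shp[2], g$cx),
                          c(Inf, g$spine_r, g$spine_r)) & body
  spine <- spine & !lungs$right & !lungs$left

  pathology <- sample(names(spec$pathology_mix), 1, prob = spec$pathology_mix)
  pmap <- array(0L, shp)
  side <- sample(c("right", "left"), 1)
  lung_r <- (if (side == "right") g$lung_r_right * s_right
             else g$lung_r_left * s_left)
  jit <- if (side == "right") jit_r else jit_l

  if (pathology == "effusion") {
    # gravity-layered (supine): fluid fills the posterior part of the
    # caudal lung while aerated lung floats anteriorly on the same slices
    zidx <- which(apply(lungs[[side]], 1, any))
    ncaudal <- max(1L, floor(runif(1, 0.5, 0.8) * length(zidx)))
    yfrac <- runif(1, 0.35, 0.60)
    yidx <- which(apply(lungs[[side]], 2, any))
    ypost <- max(1L, floor(yfrac * length(yidx)))
    sel <- array(FALSE, shp)
    sel[zidx[seq_len(ncaudal)], yidx[(length(yidx) - ypost + 1L):length(yidx)], ] <- TRUE
    region <- lungs[[side]] & sel
    pmap[region] <- 1L
  } else if (pathology == "consolidation") {
    centre <- c(g$cz + runif(1, -0.1, 0.1) * shp[1],
                g$cy + jit[1] + runif(1, -0.08, 0.08) * shp[2],
                g$lung_cx[side] + (if (side == "right") jit[2] else -jit[2]) +
                  runif(1, -0.05, 0.05) * shp[3])
    radii <- lung_r * runif(3, 0.35, 0.6)
    region <- ellipsoid_mask(shp, centre, pmax(radii, 1)) & lungs[[side]]
    pmap[region] <- 2L
  } else if (pathology == "tumour") {
    diam_mm <- runif(1, 8, 25)
    radii_vox <- (diam_mm / 2) / spec$spacing
    if (any(radii_vox >= lung_r)) {
      abort(sprintf("tumour of %.1f mm cannot fit inside a lung of this phantom shape", diam_mm),
            class = "thoraxseg_sizing_error")
    }
    # centre drawn near the pleural border, pulled inward so the sphere
    # fits; re-draw if the spot falls in carved-out anatomy (cardiac notch)
    region <- NULL
    for (attempt in 1:8) {
      theta <- runif(1, 0, 2 * pi)
      u <- runif(1, 0.55, 0.85)
      centre <- c(g$cz + u * (lung_r[1] - radii_vox[1]) * sin(theta),
                  g$cy + jit[1],
                  g$lung_cx[side] + (if (side == "right") -1 else 1) *
                    u * (lung_r[3] - radii_vox[3]) * cos(theta))
      cand <- ellipsoid_mask(shp, centre, radii_vox) & lungs[[side]]
      if (sum(cand) >= 0.4 * sum(ellipsoid_mask(shp, centre, radii_vox))) {
        region <- cand
        break
      }
    }
    if (is.null(region)) { # fall back to the lung centroid
      idx <- which(lungs[[side]], arr.ind = TRUE)
      centre <- colMeans(idx) - 1
      region <- ellipsoid_mask(shp, centre, radii_vox) & lungs[[side]]
    }
    if (!any(region)) {
      abort("tumour region does not fit inside the lung", class = "thoraxseg_sizing_error")
    }
    pmap[region] <- 3L
  } else if (pathology == "pneumothorax") {
    scale <- runif(1, 0.70, 0.85)
    cx_s <- g$lung_cx[side] + (if (side == "right") jit[2] else -jit[2])
    shrunk <- ellipsoid_mask(shp, c(g$cz, g$cy + jit[1], cx_s), lung_r * scale) & body
    lateral <- array(FALSE, shp)
    xs <- seq_len(shp[3]) - 1
    lat_sel <- if (side == "right") xs < cx_s else xs > cx_s
    lateral[, , lat_sel] <- TRUE
    region <- lungs[[side]] & !shrunk & lateral
    pmap[region] <- 4L
    lungs[[side]] <- shrunk # the collapsed lung is the ground-truth lung
  }

  labels <- array(0L, shp)
  labels[lungs$right] <- 1L
  labels[lungs$left] <- 2L
  labels[trachea] <- 0L
  # dense pathologies stay inside the lung ground truth; pneumothorax air is
  # pleural space, not lung
  pmap[pmap %in% 1:3 & labels == 0L] <- 0L

  hu <- array(draw_hu(prod(shp), im$air), shp)
  assign_class <- function(mask, pair) {
    n <- sum(mask)
    if (n > 0) hu[mask] <<- draw_hu(n, pair)
  }
  assign_class(body, im$soft)
  assign_class(lungs$right | lungs$left, im$lung)
  assign_class(spine, im$bone)
  assign_class(trachea, im$air)
  assign_class(pmap == 1L, im$effusion)
  assign_class(pmap == 2L, im$consolidation)
  assign_class(pmap == 3L, im$tumour)
  assign_class(pmap == 4L, im$pneumothorax)
  if (spec$noise_sigma > 0) hu <- hu + rnorm(prod(shp), 0, spec$noise_sigma)
  hu[pmap == 4L] <- pmin(hu[pmap == 4L], -950) # pleural air stays air-like
  hu <- pmin(pmax(hu, -1024), 3071) # scanner dynamic range

  id <- sprintf("phantom_%010d", as.integer(case_seed))
  structure(
    list(volume = ct_volume(hu, spec$spacing, id = id),
         lung_mask = lung_mask(labels, spec$spacing, id = id),
         pathology_map = pmap, pathology = pathology,
         spec = spec, case_seed = as.integer(case_seed)),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case '%s'> pathology: %s; lung voxels right %d / left %d\n",
              x$volume$id, x$pathology,
              sum(x$lung_mask$labels == 1L), sum(x$lung_mask$labels == 2L)))
  invisible(x)
}

#' Generate a cohort of phantoms
#'
#' Per-case seeds are derived deterministically from the cohort seed, so the
#' same `(spec, n, seed)` always reproduces the same cases, and the i-th
#' case never depends on `n`.
#'
#' @param spec a [phantom_spec()].
#' @param n number of cases (>= 1).
#' @param seed cohort seed; defaults to `spec$seed`.
#' @return A list of `phantom_case` objects.
#' @export
generate_cohort <- function(spec, n, seed = spec$seed) {
  assert_that(is_scalar_number(n) && n >= 1, "n must be >= 1")
  seeds <- derive_seeds(seed, n)
  lapply(seeds, function(s) generate_phantom(spec, s))
}

#' Write a phantom cohort to disk
#'
#' Each case becomes three NIfTI files (`<id>_ct.nii.gz` int16 HU,
#' `<id>_mask.nii.gz` and `<id>_pathology.nii.gz` uint8) plus one cohort
#' manifest CSV with case id, seed, and the pathology present.
#'
#' @param cases list of `phantom_case` objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest as a tibble.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(cases, function(cs) {
    id <- cs$volume$id
    write_volume(cs$volume, file.path(dir, paste0(id, "_ct.nii.gz")))
    write_mask(cs$lung_mask, file.path(dir, paste0(id, "_mask.nii.gz")))
    img <- nifti_from_canonical(cs$pathology_map, cs$volume$spacing,
                                cs$volume$origin)
    RNifti::writeNifti(img, file.path(dir, paste0(id, "_pathology.nii.gz")),
                       datatype = "uint8")
    tibble(case = id, seed = cs$case_seed, pathology = cs$pathology)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
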