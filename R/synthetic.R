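## Synthetic multispectral scenes and trial datasets with known ground
## truth. A scene is a lobed star-convex plant blob (high NIR, low red)
## on a spectrally flat low-NDVI background, with per-band programmed
## pixel shifts emulating the close-range lens displacement of the sensor
## and seeded Gaussian noise. A trial is a long-format feature table drawn
## from per-treatment weekly growth models with multiplicative noise.
## All randomness flows from explicit seeds; no hidden global state.

#' Scene specification
#'
#' Defaults emulate the study conditions: a 960 x 1280 px frame whose blob
#' sits at the centre of the standard AOI, plant reflectances giving
#' NDVI ~ 0.8 against a background of NDVI = 0.
#'
#' @param dim image size c(rows, cols).
#' @param center blob centre c(row, col); default = centre of the default
#'   AOI.
#' @param base_radius mean blob radius in pixels.
#' @param lobes number of sinusoidal lobes on the blob outline.
#' @param lobe_amp relative lobe amplitude in (0, 1).
#' @param rotation lobe phase in radians.
#' @param plant_reflectance,background_reflectance named vectors over the
#'   four bands.
#' @param shifts named list band -> c(dx, dy) programmed displacement
#'   applied to that band (simulating sensor misalignment); default none.
#' @param noise_sd additive Gaussian noise sd per band.
#' @param seed integer RNG seed.
#' @export
scene_spec <- function(dim = c(960L, 1280L),
                       center = NULL,
                       base_radius = 120,
                       lobes = 7L,
                       lobe_amp = 0.25,
                       rotation = 0,
                       plant_reflectance = c(green = 0.12, red = 0.06,
                                             red_edge = 0.35, nir = 0.55),
                       background_reflectance = c(green = 0.18, red = 0.20,
                                                  red_edge = 0.20,
                                                  nir = 0.20),
                       shifts = NULL,
                       noise_sd = 0.01,
                       seed = 1L) {
  dim <- as.integer(dim)
  ## default: AOI centre for full-size frames, image centre otherwise
  if (is.null(center))
    center <- if (all(dim == c(960L, 1280L))) c(550L, 600L)
              else round(dim / 2)
  if (is.null(shifts))
    shifts <- stats::setNames(rep(list(c(0L, 0L)), 4), BANDS)
  stopifnot(all(BANDS %in% names(plant_reflectance)),
            all(BANDS %in% names(background_reflectance)),
            all(BANDS %in% names(shifts)))
  p_ndvi <- (plant_reflectance["nir"] - plant_reflectance["red"]) /
    (plant_reflectance["nir"] + plant_reflectance["red"])
  b_ndvi <- (background_reflectance["nir"] - background_reflectance["red"]) /
    (background_reflectance["nir"] + background_reflectance["red"])
  if (!(p_ndvi > b_ndvi))
    stop_arg("plant NDVI must exceed background NDVI")
  structure(list(dim = as.integer(dim), center = center,
                 base_radius = base_radius, lobes = as.integer(lobes),
                 lobe_amp = lobe_amp, rotation = rotation,
                 plant_reflectance = plant_reflectance,
                 background_reflectance = background_reflectance,
                 shifts = shifts, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

## analytic area of the lobed blob: integral of r(theta)^2 / 2
blob_area <- function(base_radius, lobe_amp) {
  pi * base_radius^2 * (1 + lobe_amp^2 / 2)
}

## radius that gives a target analytic area
radius_for_area <- function(area, lobe_amp) {
  sqrt(area / (pi * (1 + lobe_amp^2 / 2)))
}

.render_blob <- function(spec) {
  nr <- spec$dim[1]; nc <- spec$dim[2]
  rmax <- spec$base_radius * (1 + spec$lobe_amp)
  if (spec$center[1] - rmax < 1 || spec$center[1] + rmax > nr ||
      spec$center[2] - rmax < 1 || spec$center[2] + rmax > nc)
    stop_arg("blob exceeds image bounds")
  dr <- row(matrix(0, nr, nc)) - spec$center[1]
  dc <- col(matrix(0, nr, nc)) - spec$center[2]
  dist <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  radius <- spec$base_radius *
    (1 + spec$lobe_amp * sin(spec$lobes * theta + spec$rotation))
  dist <= radius
}

#' Generate a four-band scene with ground truth
#'
#' @param spec a [scene_spec()].
#' @return list with `bands` (named list of [band_image()]s, each already
#'   displaced by its programmed shift and noise-corrupted), `truth` (the
#'   un-shifted [plant_mask()]) and `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  mask <- .render_blob(spec)
  set.seed(spec$seed)
  bands <- list()
  for (b in BANDS) {
    m <- matrix(spec$background_reflectance[[b]], spec$dim[1], spec$dim[2])
    m[mask] <- spec$plant_reflectance[[b]]
    s <- spec$shifts[[b]]
    if (any(s != 0))
      m <- shift_matrix(m, s[1], s[2],
                        fill = spec$background_reflectance[[b]])
    if (spec$noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, spec$noise_sd),
                      nrow(m), ncol(m))
    m[m < 0] <- 0
    bands[[b]] <- band_image(m, b)
  }
  list(bands = bands,
       truth = plant_mask(mask, source = list(strategy = "ground_truth")),
       spec = spec)
}

#' Default weekly growth models per treatment
#'
#' Growth of seven camera-derived features (pixel units) against weeks
#' after transplant, as degree-1 or degree-2 polynomials. The T0 (control)
#' and T3 (recommended fertilizer dose) coefficients are the package's
#' reference parameterization; T1 and T2 default to dose-weighted blends
#' of the T0 and T3 curves (weights 0.25 and 0.5, the fertilizer dose
#' ratios 6.25/25 and 12.5/25).
#'
#' @return named list variable -> treatment -> list(degree, coefficients)
#'   with coefficients highest degree first.
#' @export
growth_models <- function() {
  ref <- list(
    Area            = list(T0 = c(10070, 26550), T3 = c(2825, 3078, 8909)),
    FilledArea      = list(T0 = c(6766, 8284),   T3 = c(3118, 2072, 13130)),
    Perimeter       = list(T0 = c(164.5, 2211),  T3 = c(381.7, -1065, 3265)),
    EquivDiameter   = list(T0 = c(21.93, 114.4), T3 = c(52.65, 80.43)),
    ConvexArea      = list(T0 = c(2984, -8845, 56880),
                           T3 = c(19530, -60980, 95950)),
    MajorAxisLength = list(T0 = c(16.53, -112.2, 522.2),
                           T3 = c(27.41, -106.9, 452.5)),
    MinorAxisLength = list(T0 = c(-4.833, 61.4, 77.95), T3 = c(71.54, 69.48))
  )
  pad <- function(co) c(rep(0, 3 - length(co)), co)  # to quadratic
  blend <- function(a, b, w) {
    co <- (1 - w) * pad(a) + w * pad(b)
    if (abs(co[1]) < 1e-12) co <- co[-1]
    co
  }
  out <- lapply(ref, function(v) {
    models <- list(T0 = v$T0,
                   T1 = blend(v$T0, v$T3, 0.25),
                   T2 = blend(v$T0, v$T3, 0.5),
                   T3 = v$T3)
    lapply(models, function(co)
      list(degree = length(co) - 1L, coefficients = co))
  })
  out
}

## evaluate a model (coefficients highest degree first) at x
eval_model <- function(model, x) {
  co <- rev(model$coefficients)
  vapply(x, function(xi) sum(co * xi^(seq_along(co) - 1L)), numeric(1))
}

#' Trial specification
#'
#' Defaults are the study conditions: four treatments, six replicate
#' plants, eight weekly acquisitions (weeks 0-7), 10% coefficient of
#' variation on feature values.
#'
#' @param models per-variable, per-treatment growth models; default
#'   [growth_models()].
#' @param replicates plants per treatment.
#' @param weeks integer vector of weeks.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param seed integer RNG seed.
#' @export
trial_spec <- function(models = growth_models(), replicates = 6L,
                       weeks = 0:7, cv = 0.10, seed = 1L) {
  if (replicates < 2L) stop_arg("need >= 2 replicates")
  for (v in names(models)) for (tr in names(models[[v]]))
    if (any(eval_model(models[[v]][[tr]], weeks) <= 0))
      stop_arg("model ", v, "/", tr, " non-positive over the week range")
  structure(list(models = models, replicates = as.integer(replicates),
                 weeks = as.integer(weeks), cv = cv,
                 seed = as.integer(seed)),
            class = "trial_spec")
}

#' Generate a long-format trial table
#'
#' value(plant, week) = model_treatment(week) * (1 + eps),
#' eps ~ Normal(0, cv^2), seeded. With the defaults each variable yields
#' 4 treatments x 6 plants x 8 weeks = 192 records, one per plant-week.
#'
#' @param spec a [trial_spec()].
#' @return data.frame `plant_id, treatment, week, variable, value`.
#' @export
generate_trial <- function(spec = trial_spec()) {
  stopifnot(inherits(spec, "trial_spec"))
  set.seed(spec$seed)
  rows <- list()
  for (v in names(spec$models)) {
    for (tr in names(spec$models[[v]])) {
      mod <- spec$models[[v]][[tr]]
      mu <- eval_model(mod, spec$weeks)
      for (p in seq_len(spec$replicates)) {
        eps <- if (spec$cv > 0)
          stats::rnorm(length(spec$weeks), 0, spec$cv) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = sprintf("%s_p%d", tr, p), treatment = tr,
          week = spec$weeks, variable = v, value = mu * (1 + eps),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a weekly series of scenes tracking an area model
#'
#' The blob radius each week is set so the analytic blob area equals the
#' model value; the rasterized mask area tracks it within rasterization
#' error (about 2% for radii >= 30 px).
#'
#' @param spec base [scene_spec()] (radius is overridden per week).
#' @param weeks integer vector of weeks.
#' @param growth list(degree, coefficients) area model in pixels, positive
#'   over `weeks`.
#' @return list of scenes (as from [generate_scene()]), one per week.
#' @export
grow_scene_series <- function(spec = scene_spec(), weeks = 0:7,
                              growth = growth_models()$Area$T3) {
  areas <- eval_model(growth, weeks)
  if (any(areas <= 0)) stop_arg("area model must be positive over weeks")
  lapply(seq_along(weeks), function(i) {
    s <- spec
    s$base_radius <- radius_for_area(areas[i], spec$lobe_amp)
    s$seed <- .derive_seed(spec$seed, weeks[i])
    generate_scene(s)
  })
}

#' Write a scene's bands as per-band TIFF files
#'
#' Produces the same single-channel TIFF layout the reader expects.
#'
#' @param scene output of [generate_scene()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return named list of band file paths.
#' @export
write_scene_tiffs <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (b in BANDS) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, b))
    write_band_tiff(scene$bands[[b]], p)
    paths[[b]] <- p
  }
  paths
}

#' Simulate a full acquisition session on disk
#'
#' Writes per-band TIFFs for every plant-week combination plus a JSON
#' manifest, ready for [run_pipeline()]. Plant blob areas follow a simple
#' linear growth so masks differ across weeks; the scene geometry is scaled
#' to the requested frame size.
#'
#' @param dir output directory.
#' @param treatments treatment labels to simulate.
#' @param replicates plants per treatment.
#' @param weeks integer vector of weeks.
#' @param dim frame size c(rows, cols).
#' @param noise_sd per-band noise sd.
#' @param seed integer RNG seed.
#' @return path of the manifest JSON.
#' @export
simulate_session <- function(dir, treatments = c("T0", "T3"),
                             replicates = 1L, weeks = 0:1,
                             dim = c(240L, 320L), noise_sd = 0.005,
                             seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base_r <- round(min(dim) / 8)
  entries <- list()
  k <- 0L
  for (tr in treatments) for (p in seq_len(replicates)) for (w in weeks) {
    k <- k + 1L
    growth_mult <- 1 + 0.15 * w + 0.1 * match(tr, c("T0", "T1", "T2", "T3"))
    sp <- scene_spec(dim = dim, center = round(dim / 2),
                     base_radius = base_r * sqrt(growth_mult),
                     noise_sd = noise_sd,
                     seed = .derive_seed(seed, k))
    scene <- generate_scene(sp)
    pid <- sprintf("%s_p%d", tr, p)
    paths <- write_scene_tiffs(scene, dir,
                               prefix = sprintf("%s_w%d", pid, w))
    entries[[k]] <- list(plant_id = pid, treatment = tr, week = w,
                         camera_height_m = if (w <= 4) 0.7 else 1.4,
                         band_paths = paths)
  }
  manifest <- file.path(dir, "manifest.json")
  write_manifest(entries, manifest)
  manifest
}
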