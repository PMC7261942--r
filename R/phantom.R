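# Synthetic multi-sequence phantoms with ground-truth CSVD lesions.
#
# The generator inverts the radiological definition table of the four imaging
# signs: each (lesion class, modality) pair has a contrast direction (DOWN /
# NEUTRAL / UP) relative to normal white matter, and each class has a diameter
# range in mm. Brains are rendered as a three-compartment ellipsoid (WM core,
# GM shell, CSF ventricles) — enough anatomy for white-matter peak
# normalization and plausible lesion context, with no claim to atlas realism.

.default_contrast_table <- function() {
  # rows: class, cols: modality. Ambiguous "down-or-neutral" table entries are
  # resolved to NEUTRAL so every pair has one deterministic direction; the
  # unambiguous directions are: lacune hypointense (CSF-like) on T1, WMH
  # hyperintense on FLAIR, acute infarct hyperintense on DWI/FLAIR and
  # hypointense on T1, microbleed hypointense on T2*-weighted GRE.
  tab <- matrix("NEUTRAL", 4, 4,
                dimnames = list(csvd_classes(), csvd_modalities()))
  tab["LACUNE", "T1"] <- "DOWN"
  tab["WMH", "T2FLAIR"] <- "UP"
  tab["INFARCT", "DWI_B1000"] <- "UP"
  tab["INFARCT", "T1"] <- "DOWN"
  tab["INFARCT", "T2FLAIR"] <- "UP"
  tab["MICROBLEED", "T2STAR"] <- "DOWN"
  tab
}

# base compartment intensities (arbitrary units) per modality; only the
# orderings matter: T1 CSF-dark/WM-bright, FLAIR CSF-suppressed/WMH-bright,
# DWI CSF-dark, T2* CSF-bright. WM is always the dominant compartment so the
# histogram mode lands on it.
.tissue_intensity <- function() {
  rbind(
    T1        = c(WM = 300, GM = 170, CSF = 60),
    T2FLAIR   = c(WM = 200, GM = 150, CSF = 40),
    DWI_B1000 = c(WM = 260, GM = 150, CSF = 70),
    T2STAR    = c(WM = 200, GM = 150, CSF = 230)
  )
}

.lesion_factor <- c(DOWN = 0.35, NEUTRAL = 1.0, UP = 1.6)

# lacunes are "CSF-like" hypointense, not merely hypointense: they render at
# the CSF level (0.2 x WM on T1), which also distinguishes them from acute
# infarcts, whose plain T1 hypointensity sits at 0.35 x WM
.lesion_down_factor <- c(LACUNE = 0.2, WMH = 0.35, INFARCT = 0.35,
                         MICROBLEED = 0.35)

#' Configuration of the synthetic phantom generator
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' in-plane pixel spacing 0.36-1.44 mm, slice spacing 6-8 mm, lacune
#' diameters 3-15 mm, infarct diameters up to 20 mm, microbleed diameters
#' 2-10 mm, WMH of variable extent, and the default contrast-direction table
#' (see [sample_lesion_geometry()] and [generate_study()]).
#'
#' @param grid_shape integer `(slices, rows, cols)` of the voxel grid.
#' @param in_plane_spacing_range mm interval the per-study in-plane spacing is
#'   drawn from.
#' @param slice_spacing_range mm interval for the spacing between slices.
#' @param lesion_counts named list `class -> c(min, max)` lesion count range.
#' @param diameter_ranges_mm named list `class -> c(lo, hi)` of in-plane
#'   diameters in mm (`WMH` is unconstrained; its entry sizes individual blob
#'   seeds of the irregular confluent footprint).
#' @param contrast_table character matrix `class x modality` with entries
#'   `"DOWN"`, `"NEUTRAL"`, `"UP"`.
#' @param noise_sd standard deviation of the additive Gaussian noise, in the
#'   same arbitrary intensity units as the compartment table (white matter
#'   sits at 200-300 units depending on modality).
#' @param allow_overlap permit lesions of different classes to claim the same
#'   voxels. Off by default: a voxel can only be rendered with one class's
#'   appearance, so overlapping ground truth necessarily mislabels the
#'   overwritten class and acts as label noise during training. Enable it to
#'   stress the mask-combination stage with genuinely conflicting truth.
#' @param seed integer RNG seed; a fixed seed makes [generate_study()]
#'   bit-reproducible.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(10L, 96L, 96L),
                           in_plane_spacing_range = c(0.36, 1.44),
                           slice_spacing_range = c(6, 8),
                           lesion_counts = list(
                             LACUNE = c(1L, 3L), WMH = c(1L, 3L),
                             INFARCT = c(1L, 2L), MICROBLEED = c(1L, 4L)
                           ),
                           diameter_ranges_mm = list(
                             LACUNE = c(3, 15), WMH = c(4, 18),
                             INFARCT = c(2, 20), MICROBLEED = c(2, 10)
                           ),
                           contrast_table = .default_contrast_table(),
                           noise_sd = 5,
                           allow_overlap = FALSE,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            noise_sd >= 0, length(seed) == 1L)
  stopifnot(all(csvd_classes() %in% rownames(contrast_table)),
            all(csvd_modalities() %in% colnames(contrast_table)),
            all(contrast_table %in% c("DOWN", "NEUTRAL", "UP")))
  structure(
    list(
      grid_shape = as.integer(grid_shape),
      in_plane_spacing_range = as.numeric(in_plane_spacing_range),
      slice_spacing_range = as.numeric(slice_spacing_range),
      lesion_counts = lesion_counts,
      diameter_ranges_mm = diameter_ranges_mm,
      contrast_table = contrast_table,
      noise_sd = as.numeric(noise_sd),
      allow_overlap = isTRUE(allow_overlap),
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

# -- tissue model --------------------------------------------------------------

# label codes: 0 background, 1 WM, 2 GM, 3 CSF
#' Render the three-compartment ellipsoidal brain model
#'
#' @param grid_shape integer `(slices, rows, cols)`.
#' @return integer 3D label array with codes 0 = background, 1 = white matter,
#'   2 = gray matter shell, 3 = CSF (two ventricle ellipsoids).
#' @export
build_tissue_map <- function(grid_shape) {
  ns <- grid_shape[1]; nr <- grid_shape[2]; nc <- grid_shape[3]
  cs <- (ns + 1) / 2; cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  as_ <- ns * 0.48; ar <- nr * 0.44; ac <- nc * 0.44
  s <- slice.index(array(0, grid_shape), 1)
  r <- slice.index(array(0, grid_shape), 2)
  cl <- slice.index(array(0, grid_shape), 3)
  ell <- function(ds, dr, dc, a1, a2, a3) {
    (ds / a1)^2 + (dr / a2)^2 + (dc / a3)^2 <= 1
  }
  brain <- ell(s - cs, r - cr, cl - cc, as_, ar, ac)
  wm <- ell(s - cs, r - cr, cl - cc, 0.90 * as_, 0.88 * ar, 0.88 * ac)
  vent <- ell(s - cs, r - cr, cl - (cc - 0.10 * nc), 0.35 * as_, 0.20 * ar, 0.07 * ac) |
    ell(s - cs, r - cr, cl - (cc + 0.10 * nc), 0.35 * as_, 0.20 * ar, 0.07 * ac)
  lab <- array(0L, grid_shape)
  lab[brain] <- 2L
  lab[wm] <- 1L
  lab[vent & wm] <- 3L
  lab
}

# -- lesion geometry -----------------------------------------------------------

#' Sample a lesion footprint with a diameter in the configured range
#'
#' Draws a connected, roughly ellipsoidal voxel footprint whose maximal
#' in-plane extent, measured in mm as pixel count times the in-plane spacing,
#' falls inside the class's configured diameter range. WMH footprints are
#' irregular unions of several overlapping blobs, emulating the variable,
#' confluent extent of white matter hyperintensities, and carry no diameter
#' constraint. Consumes the current R RNG stream.
#'
#' @param lesion_class one of `csvd_classes()`.
#' @param config a [phantom_config()].
#' @param in_plane_spacing mm per pixel for the study being generated.
#' @param grid_shape grid the footprint indices refer to.
#' @param center optional `(slice, row, col)` center; drawn uniformly inside
#'   the grid when `NULL`.
#' @return Integer matrix with columns `slice`, `row`, `col`; attribute
#'   `diameter_mm` records the realized maximal in-plane extent.
#' @export
sample_lesion_geometry <- function(lesion_class, config,
                                   in_plane_spacing = 1.0,
                                   grid_shape = config$grid_shape,
                                   center = NULL) {
  lesion_class <- match.arg(lesion_class, csvd_classes())
  rng_mm <- config$diameter_ranges_mm[[lesion_class]]
  if (is.null(rng_mm) || length(rng_mm) != 2L || rng_mm[2] < rng_mm[1]) {
    abort(paste0("empty or invalid diameter range for ", lesion_class),
          class = "csvdseg_error_config")
  }
  if (lesion_class == "WMH") {
    if (is.null(center)) center <- .center_with_margin(grid_shape, 8L)
    return(.sample_wmh_footprint(config, in_plane_spacing, grid_shape, center))
  }
  # achievable pixel extents: n pixels spans n * spacing mm
  n_lo <- max(1L, as.integer(ceiling(rng_mm[1] / in_plane_spacing)))
  n_hi <- as.integer(floor(rng_mm[2] / in_plane_spacing))
  if (n_hi < n_lo) {
    # spacing too coarse to honor the lower bound exactly; take the single
    # feasible extent closest to the range (only possible for sub-voxel lows)
    n_lo <- n_hi <- max(1L, n_hi)
  }
  n_major <- .sample1(n_lo:n_hi)
  n_minor <- .sample1(max(1L, ceiling(n_major / 2)):n_major)
  if (runif(1) < 0.5) { nr_ext <- n_major; nc_ext <- n_minor } else {
    nr_ext <- n_minor; nc_ext <- n_major
  }
  n_slices <- if (lesion_class == "INFARCT") .sample1(1:2) else 1L
  if (is.null(center)) {
    # keep the whole footprint on the grid so clipping cannot shrink the
    # realized extent below the configured range
    center <- .center_with_margin(grid_shape, max(nr_ext, nc_ext))
  }
  fp <- .ellipse_footprint(center, nr_ext, nc_ext, n_slices, grid_shape)
  ext_px <- max(diff(range(fp[, "row"])) + 1L, diff(range(fp[, "col"])) + 1L)
  attr(fp, "diameter_mm") <- ext_px * in_plane_spacing
  fp
}

# sample() treats a length-1 numeric as 1:x; guard every scalar range draw
.sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

.center_with_margin <- function(grid_shape, ext_px) {
  half <- as.integer(ceiling(ext_px / 2)) + 1L
  pick <- function(n) {
    lo <- min(half + 1L, max(1L, n %/% 2L))
    hi <- max(lo, n - half)
    if (hi < lo) lo else .sample1(lo:hi)
  }
  c(sample.int(grid_shape[1], 1L), pick(grid_shape[2]), pick(grid_shape[3]))
}

# pixel-exact ellipse: the footprint's row extent is exactly nr_ext pixels and
# col extent exactly nc_ext pixels (before clipping to the grid)
.ellipse_footprint <- function(center, nr_ext, nc_ext, n_slices, grid_shape) {
  # half-integer center offset makes even extents exact
  cr <- center[2] + if (nr_ext %% 2L == 0L) 0.5 else 0
  cc <- center[3] + if (nc_ext %% 2L == 0L) 0.5 else 0
  ar <- (nr_ext - 1) / 2 + 0.49
  ac <- (nc_ext - 1) / 2 + 0.49
  rows <- seq.int(floor(cr - ar), ceiling(cr + ar))
  cols <- seq.int(floor(cc - ac), ceiling(cc + ac))
  grid <- expand.grid(row = rows, col = cols)
  keep <- ((grid$row - cr) / ar)^2 + ((grid$col - cc) / ac)^2 <= 1
  grid <- grid[keep, , drop = FALSE]
  slices <- center[1] + seq_len(n_slices) - 1L
  out <- do.call(rbind, lapply(slices, function(s) {
    cbind(slice = rep.int(s, nrow(grid)), row = grid$row, col = grid$col)
  }))
  out <- out[out[, 1] >= 1 & out[, 1] <= grid_shape[1] &
               out[, 2] >= 1 & out[, 2] <= grid_shape[2] &
               out[, 3] >= 1 & out[, 3] <= grid_shape[3], , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

.sample_wmh_footprint <- function(config, spacing, grid_shape, center) {
  rng_mm <- config$diameter_ranges_mm[["WMH"]]
  n_blobs <- sample(2:4, 1L)
  # cap blob seeds at a fifth of the in-plane grid so confluent unions stay
  # placeable inside the white matter of small desk-scale phantoms
  cap <- max(2L, min(grid_shape[2], grid_shape[3]) %/% 5L)
  parts <- vector("list", n_blobs)
  for (b in seq_len(n_blobs)) {
    d_mm <- runif(1, rng_mm[1], rng_mm[2])
    n_ext <- min(cap, max(2L, as.integer(round(d_mm / spacing))))
    jitter <- if (b == 1L) c(0L, 0L) else
      as.integer(round(runif(2, -n_ext / 2, n_ext / 2)))
    ctr <- c(center[1], center[2] + jitter[1], center[3] + jitter[2])
    m_ext <- .sample1(max(1L, ceiling(n_ext / 2)):n_ext)
    parts[[b]] <- .ellipse_footprint(ctr, n_ext, m_ext, 1L, grid_shape)
  }
  fp <- unique(do.call(rbind, parts))
  if (nrow(fp) == 0L) fp <- .ellipse_footprint(center, 2L, 2L, 1L, grid_shape)
  ext_px <- max(diff(range(fp[, "row"])) + 1L, diff(range(fp[, "col"])) + 1L)
  attr(fp, "diameter_mm") <- ext_px * spacing
  fp
}

# -- study generation ----------------------------------------------------------

#' Generate one synthetic co-registered multi-sequence study
#'
#' Renders the three-compartment brain in each requested modality, carves the
#' configured lesions into it with the contrast direction given by the
#' contrast table (lesion voxels are set to `factor x` the modality's white
#' matter intensity: hypointense 0.35x, hyperintense 1.6x, neutral 1x), adds
#' i.i.d. Gaussian noise, and returns the study together with its ground
#' truth. Deterministic for a fixed `config$seed`.
#'
#' @param config a [phantom_config()].
#' @param classes lesion classes to generate; lesion counts are drawn from
#'   `config$lesion_counts` for these and forced to zero for the others.
#' @param modalities which sequence volumes to render.
#' @param patient_id identifier stored in the returned study.
#' @return `list(study = patient_study, truth = list(masks = <class ->
#'   lesion_mask>, tissue_map = <label array>))`.
#' @export
generate_study <- function(config, classes = csvd_classes(),
                           modalities = csvd_modalities(),
                           patient_id = "phantom") {
  set.seed(config$seed)
  gs <- config$grid_shape
  in_plane <- runif(1, config$in_plane_spacing_range[1],
                    config$in_plane_spacing_range[2])
  slice_sp <- runif(1, config$slice_spacing_range[1],
                    config$slice_spacing_range[2])
  tissue <- build_tissue_map(gs)
  brain <- tissue > 0L

  masks <- list()
  occupied <- array(FALSE, gs)  # voxels claimed by another class
  for (cls in csvd_classes()) {
    vals <- array(0L, gs)
    if (cls %in% classes) {
      cnt_rng <- config$lesion_counts[[cls]] %||% c(0L, 0L)
      n_lesions <- if (cnt_rng[2] >= cnt_rng[1] && cnt_rng[2] > 0L) {
        .sample1(cnt_rng[1]:cnt_rng[2])
      } else 0L
      for (k in seq_len(n_lesions)) {
        fp <- .place_lesion(cls, config, in_plane, gs, tissue,
                            occupied = if (config$allow_overlap %||% FALSE)
                              NULL else occupied)
        vals[fp] <- 1L
      }
    }
    occupied <- occupied | (vals == 1L)
    masks[[cls]] <- lesion_mask(vals, cls, in_plane, slice_sp)
  }

  tint <- .tissue_intensity()
  volumes <- lapply(modalities, function(mod) {
    base <- c(0, tint[mod, c("WM", "GM", "CSF")])[tissue + 1L]
    img <- array(base, gs)
    wm_val <- tint[mod, "WM"]
    # later classes overwrite earlier on overlap; infarct rendered after WMH
    # and lacune, matching the precedence the mask combination enforces
    for (cls in c("WMH", "LACUNE", "INFARCT", "MICROBLEED")) {
      dir <- config$contrast_table[cls, mod]
      sel <- masks[[cls]]$values == 1L
      if (any(sel) && dir != "NEUTRAL") {
        f <- if (dir == "DOWN") .lesion_down_factor[[cls]] else
          .lesion_factor[[dir]]
        img[sel] <- wm_val * f
      }
    }
    if (config$noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, config$noise_sd), gs)
    }
    img[img < 0] <- 0
    img[!brain] <- 0
    sequence_volume(img, mod, in_plane, slice_sp)
  })

  list(
    study = patient_study(patient_id, volumes),
    truth = list(masks = masks, tissue_map = tissue)
  )
}

# place one lesion fully inside white matter, bounded retries. Restricting
# footprints to WM keeps the NEUTRAL contrast contract exact: a footprint
# overlapping GM or CSF would shift the lesion mean even on sequences where
# the lesion is invisible.
.place_lesion <- function(cls, config, in_plane, gs, tissue, occupied = NULL,
                          max_tries = 80L) {
  wm_idx <- which(tissue == 1L)
  for (try in seq_len(max_tries)) {
    ctr_lin <- wm_idx[sample.int(length(wm_idx), 1L)]
    ctr <- arrayInd(ctr_lin, gs)[1, ]
    fp <- sample_lesion_geometry(cls, config, in_plane, gs, center = ctr)
    if (nrow(fp) == 0L) next
    if (all(tissue[fp] == 1L) &&
        (is.null(occupied) || !any(occupied[fp]))) return(fp)
  }
  abort(
    paste0("could not place a ", cls, " lesion inside the brain after ",
           max_tries, " attempts; grid too small for the requested diameter"),
    class = "csvdseg_error_placement"
  )
}

# -- cohorts -------------------------------------------------------------------

#' Generate a cohort of phantom patients
#'
#' Each class is present in a patient with the requested positive fraction
#' (independent Bernoulli draws), emulating cohorts where only part of the
#' scans carry a given sign — e.g. roughly 42% of microbleed-protocol scans
#' being positive while nearly all lacune/WMH scans are. Negative patients get
#' an all-zero mask for that class. Per-patient seeds are derived from
#' `config$seed`, so the cohort is reproducible as a whole.
#'
#' @param config a [phantom_config()].
#' @param n_patients number of phantoms.
#' @param positive_fractions named vector `class -> fraction in [0, 1]`;
#'   defaults mirror a stroke-registry training cohort (98.3% lacune, 98.3%
#'   WMH, 85.15% infarct, 41.78% microbleed positivity).
#' @param modalities sequences to render for every patient.
#' @return List of `list(study =, truth =)`, one element per patient, named by
#'   patient id.
#' @export
generate_cohort <- function(config, n_patients,
                            positive_fractions = c(
                              LACUNE = 0.983, WMH = 0.983,
                              INFARCT = 0.8515, MICROBLEED = 0.4178
                            ),
                            modalities = csvd_modalities()) {
  if (n_patients <= 0L) {
    abort("n_patients must be positive", class = "csvdseg_error_config")
  }
  if (any(positive_fractions < 0 | positive_fractions > 1)) {
    abort("positive fractions must lie in [0, 1]",
          class = "csvdseg_error_config")
  }
  set.seed(config$seed)
  pos <- sapply(csvd_classes(), function(cls) {
    fr <- positive_fractions[[cls]] %||% 1
    runif(n_patients) < fr
  })
  pos <- matrix(pos, nrow = n_patients,
                dimnames = list(NULL, csvd_classes()))
  patient_seeds <- (config$seed + 9973L * seq_len(n_patients)) %% .Machine$integer.max

  out <- lapply(seq_len(n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    cfg_i <- config
    cfg_i$seed <- as.integer(patient_seeds[i])
    present <- csvd_classes()[pos[i, ]]
    generate_study(cfg_i, classes = present, modalities = modalities,
                   patient_id = pid)
  })
  names(out) <- vapply(out, function(x) x$study$patient_id, character(1))
  out
}
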