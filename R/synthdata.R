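#' Specify a synthetic longitudinal imaging cohort
#'
#' Describes the study conditions a synthetic image cohort should emulate:
#' two response groups whose texture parameters drift over the treatment
#' fractions at group-dependent rates, per-patient random offsets,
#' per-fraction voxel noise, a low/high motion-blur nuisance split and two
#' scanner noise/smoothing profiles. Nuisance assignments are stratified
#' by response group, matching how acquisition effects are assessed
#' (within strata of equal pathological response).
#'
#' The generator controls texture indirectly through four knobs whose
#' effect on extracted features is monotone; for `"mean"`, `"std"` and
#' `"kurtosis"` the planted slope is in feature units per fraction (the
#' intensity marginal is shaped exactly via a t-distribution copula
#' transform), while `"coarseness"` scales the Gaussian-field correlation
#' length and is controlled in direction only.
#'
#' @param n_good,n_bad Patients per response group.
#' @param n_fractions Imaging time points per patient (default 28, five
#'   per treatment week).
#' @param volume_shape Voxel dimensions of each volume.
#' @param voxel_spacing Voxel spacing in mm.
#' @param planted_features Data frame with columns `feature` (one of
#'   `"mean"`, `"std"`, `"kurtosis"`, `"coarseness"`), `slope_good`,
#'   `slope_bad` (per-fraction drift).
#' @param patient_sd Relative sd of per-patient random offsets on the
#'   texture knobs (dimensionless).
#' @param noise_sd Per-fraction additive voxel noise sd (intensity units).
#' @param motion_fraction Proportion of patients assigned high motion.
#' @param scanner_fraction Proportion assigned scanner "B".
#' @param base_texture Baseline texture knobs: `mean`, `std` (intensity
#'   units), `kurtosis` (Pearson, >= 3.05) and `lambda` (Gaussian-field
#'   correlation length in voxels; 0 gives a white field). Note that on
#'   strongly correlated fields the sample kurtosis of a finite ROI is
#'   shrunk toward 3 (few effective independent voxels), so planted
#'   kurtosis slopes are recovered faithfully only for small `lambda`.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return Object of class `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_good, n_bad, n_fractions = 28L,
                        volume_shape = c(24L, 24L, 12L),
                        voxel_spacing = c(0.98, 0.98, 3),
                        planted_features = NULL,
                        patient_sd = 0.02, noise_sd = 5,
                        motion_fraction = 1 / 3, scanner_fraction = 0.44,
                        base_texture = list(mean = 100, std = 60,
                                            kurtosis = 4, lambda = 1.5),
                        seed = 1L) {
  if (!is_count(n_good) || !is_count(n_bad))
    stop("n_good and n_bad must be >= 1")
  if (!is_count(n_fractions, 2L)) stop("n_fractions must be >= 2")
  if (patient_sd < 0 || noise_sd < 0) stop("sd parameters must be >= 0")
  if (motion_fraction < 0 || motion_fraction > 1 ||
      scanner_fraction < 0 || scanner_fraction > 1)
    stop("motion_fraction and scanner_fraction must be in [0, 1]")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 9L))
    stop("volume too small to contain the ellipsoid ROI; minimum shape is 9 x 9 x 9")
  if (!is.null(planted_features)) {
    planted_features <- as.data.frame(planted_features)
    need <- c("feature", "slope_good", "slope_bad")
    if (!all(need %in% names(planted_features)))
      stop("planted_features needs columns feature, slope_good, slope_bad")
    ok <- planted_features$feature %in% c("mean", "std", "kurtosis",
                                          "coarseness")
    if (!all(ok))
      stop("controllable knobs are: mean, std, kurtosis, coarseness")
  }
  structure(list(n_good = n_good, n_bad = n_bad,
                 n_fractions = as.integer(n_fractions),
                 volume_shape = volume_shape,
                 voxel_spacing = as.numeric(voxel_spacing),
                 planted_features = planted_features,
                 patient_sd = patient_sd, noise_sd = noise_sd,
                 motion_fraction = motion_fraction,
                 scanner_fraction = scanner_fraction,
                 base_texture = utils::modifyList(
                   list(mean = 100, std = 60, kurtosis = 4, lambda = 1.5),
                   as.list(base_texture)),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## separable Gaussian smoothing with edge renormalization
gauss_smooth3 <- function(a, sd) {
  if (all(sd <= 0)) return(a)
  for (ax in 1:3) {
    s <- if (length(sd) == 3L) sd[ax] else sd
    if (s <= 0) next
    hw <- max(1L, ceiling(3 * s))
    kk <- exp(-(-hw:hw)^2 / (2 * s^2))
    num <- array(0, dim(a)); den <- array(0, dim(a))
    one <- array(1, dim(a))
    for (o in -hw:hw) {
      sh <- c(0L, 0L, 0L); sh[ax] <- o
      num <- num + kk[o + hw + 1] * shift_array3(a, sh[1], sh[2], sh[3])
      den <- den + kk[o + hw + 1] * shift_array3(one, sh[1], sh[2], sh[3])
    }
    a <- num / den
  }
  a
}

## balanced stratified nuisance assignment within one response group
assign_nuisance <- function(ids, fraction, levels_) {
  k <- round(length(ids) * fraction)
  chosen <- if (k > 0) sample(ids, k) else character(0)
  setNames(ifelse(ids %in% chosen, levels_[2], levels_[1]), ids)
}

#' Generate a synthetic longitudinal image cohort
#'
#' Renders one textured-ellipsoid ROI volume per patient and fraction.
#' Each patient has a fixed white-noise base field; at fraction `n` it is
#' smoothed at the fraction's correlation length, its marginal is shaped
#' to the fraction's mean/std/kurtosis knob values via a t-copula
#' transform, and fresh voxel noise is added. Knobs evolve linearly with
#' the fraction at the response group's planted slope plus a per-patient
#' relative offset, so with all slopes and sds zero every fraction of a
#' patient is the identical array. High-motion patients get an extra
#' anisotropic blur along the first axis; scanner-B patients a distinct
#' smoothing kernel and noise level. The ellipsoid mask is shared across
#' fractions (contours are propagated between registered fractions, so
#' the synthetic equivalent is one mask per patient). Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `images` (named list with
#'   elements `patient`, `fraction`, `roi`), `labels`, `motion`,
#'   `scanner` (named by patient), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  dims <- spec$volume_shape
  ctr <- (dims + 1) / 2
  rad <- pmax(2, floor(dims * 0.35))
  gx <- ((seq_len(dims[1]) - ctr[1]) / rad[1])^2
  gy <- ((seq_len(dims[2]) - ctr[2]) / rad[2])^2
  gz <- ((seq_len(dims[3]) - ctr[3]) / rad[3])^2
  mask <- outer(outer(gx, gy, `+`), gz, `+`) <= 1
  if (sum(mask) < 27L)
    stop("volume too small to contain the ellipsoid ROI; minimum shape is 9 x 9 x 9")

  pf <- spec$planted_features
  slope_of <- function(knob, grp) {
    if (is.null(pf)) return(0)
    i <- match(knob, pf$feature)
    if (is.na(i)) return(0)
    if (grp == "good") pf$slope_good[i] else pf$slope_bad[i]
  }
  base <- spec$base_texture

  ids <- sprintf("P%03d", seq_len(spec$n_good + spec$n_bad))
  labels <- setNames(rep(c("good", "bad"), c(spec$n_good, spec$n_bad)), ids)

  with_seed(spec$seed, {
    motion <- scanner <- character(0)
    for (g in c("good", "bad")) {
      gi <- ids[labels == g]
      motion <- c(motion, assign_nuisance(gi, spec$motion_fraction,
                                          c("low", "high")))
      scanner <- c(scanner, assign_nuisance(gi, spec$scanner_fraction,
                                            c("A", "B")))
    }
    motion <- motion[ids]; scanner <- scanner[ids]

    images <- list()
    for (id in ids) {
      grp <- labels[[id]]
      u <- rnorm(4, 0, spec$patient_sd)  # mean, std, kurt, lambda offsets
      W <- array(rnorm(prod(dims)), dims)
      for (n in seq_len(spec$n_fractions)) {
        mv <- base$mean * (1 + u[1]) + slope_of("mean", grp) * n
        sv <- max(base$std * (1 + u[2]) + slope_of("std", grp) * n, 1)
        kv <- max(base$kurtosis * (1 + u[3]) + slope_of("kurtosis", grp) * n,
                  3.05)
        lv <- max(base$lambda * (1 + u[4]) * (1 + slope_of("coarseness", grp) * n),
                  0.2)
        nu <- 4 + 6 / (kv - 3)
        z <- gauss_smooth3(W, lv)
        z <- (z - mean(z)) / sd(z)
        p <- pmin(pmax(pnorm(z), 1e-12), 1 - 1e-12)
        vol <- mv + sv * qt(p, df = nu) / sqrt(nu / (nu - 2))
        vol[!mask] <- -120
        if (spec$noise_sd > 0)
          vol <- vol + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
        if (motion[[id]] == "high")
          vol <- gauss_smooth3(vol, c(1.2, 0, 0))
        if (scanner[[id]] == "B") {
          vol <- gauss_smooth3(vol, 0.6)
          if (spec$noise_sd > 0)
            vol <- vol + array(rnorm(prod(dims), 0, 0.5 * spec$noise_sd),
                               dims)
        }
        images[[paste(id, n, sep = "_")]] <-
          list(patient = id, fraction = n,
               roi = image_roi(vol, mask, spec$voxel_spacing))
      }
    }
    structure(list(images = images, labels = labels, motion = motion,
                   scanner = scanner, spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (%d good / %d bad) x %d fractions = %d volumes\n",
              length(x$labels), sum(x$labels == "good"),
              sum(x$labels == "bad"), x$spec$n_fractions,
              length(x$images)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Volumes and masks as compressed NIfTI, a manifest CSV (patient,
#' fraction, label, motion group, scanner, paths) and the generating
#' parameters as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$images, function(img) {
    ip <- file.path(dir, sprintf("%s_f%02d_image.nii.gz",
                                 img$patient, img$fraction))
    mp <- file.path(dir, sprintf("%s_f%02d_mask.nii.gz",
                                 img$patient, img$fraction))
    RNifti::writeNifti(RNifti::asNifti(img$roi$intensities,
                                       pixdim = img$roi$spacing), ip)
    RNifti::writeNifti(RNifti::asNifti(img$roi$mask + 0,
                                       pixdim = img$roi$spacing), mp)
    data.frame(patient = img$patient, fraction = img$fraction,
               label = cohort$labels[[img$patient]],
               motion_group = cohort$motion[[img$patient]],
               scanner = cohort$scanner[[img$patient]],
               image_path = basename(ip), mask_path = basename(mp),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(spec[setdiff(names(spec), "planted_features")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  if (!is.null(spec$planted_features))
    write.csv(spec$planted_features, file.path(dir, "planted.csv"),
              row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the NIfTI pairs.
#' @return A `synthetic_cohort`-shaped list (without the generating spec).
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  images <- list()
  for (i in seq_len(nrow(manifest))) {
    vol <- as.array(RNifti::readNifti(file.path(dir, manifest$image_path[i])))
    msk <- as.array(RNifti::readNifti(file.path(dir, manifest$mask_path[i])))
    sp <- RNifti::pixdim(RNifti::readNifti(file.path(dir,
                                                     manifest$image_path[i])))
    images[[paste(manifest$patient[i], manifest$fraction[i], sep = "_")]] <-
      list(patient = manifest$patient[i], fraction = manifest$fraction[i],
           roi = image_roi(vol, msk > 0.5, sp[seq_len(3)]))
  }
  labels <- setNames(manifest$label, manifest$patient)
  labels <- labels[!duplicated(names(labels))]
  motion <- setNames(manifest$motion_group, manifest$patient)
  motion <- motion[!duplicated(names(motion))]
  scanner <- setNames(manifest$scanner, manifest$patient)
  scanner <- scanner[!duplicated(names(scanner))]
  structure(list(images = images, labels = labels, motion = motion,
                 scanner = scanner, spec = NULL),
            class = "synthetic_cohort")
}
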