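# Synthetic phantoms and cohorts.
#
# The generator is the forward model of the analysis: voxel intensities are
# the concentration-weighted sum of the characteristic GM and WM T1 values
# plus Gaussian noise. Regions are ellipsoids; each carries a radial
# concentration profile c(r) = 1 - r^p spanning pure WM at the border
# (r = 1) to pure GM at the center (r = 0). Over a solid ellipsoid the
# induced concentration histogram is f(c) = (3/p) (1-c)^(3/p - 1): p = 3
# gives an exactly uniform concentration distribution (the estimator's
# reference model), p > 3 gives near-homogeneous high-GM interiors with a
# partial-volume falloff at the border. Profiles span the full [0, 1]
# range so that the characteristic intensities are identifiable from each
# region (both pure tissues are realized).

#' Default region geometry for the synthetic phantom
#'
#' Ellipsoid centers and semi-axes in fractions of the grid dimensions
#' (scaled and rounded to voxels at generation time), plus the radial
#' concentration profile exponent per region. Each region has a pure-GM
#' core (relative radius 0.25 by default), so both pure-tissue intensities
#' are realized by multiple voxels and the characteristic intensities are
#' well identified.
#'
#' @return A named list of region definitions.
#' @export
default_regions <- function() {
  list(
    thalamus = list(center = c(0.344, 0.500, 0.469),
                    semiaxes = c(0.125, 0.156, 0.141), profile_exponent = 3),
    caudate  = list(center = c(0.625, 0.375, 0.563),
                    semiaxes = c(0.078, 0.125, 0.078), profile_exponent = 6),
    putamen  = list(center = c(0.688, 0.625, 0.438),
                    semiaxes = c(0.094, 0.141, 0.078), profile_exponent = 4),
    pallidum = list(center = c(0.406, 0.750, 0.375),
                    semiaxes = c(0.078, 0.094, 0.063), profile_exponent = 3)
  )
}

#' Ground truth for a single phantom
#'
#' @param intensities Named list of per-region `c(mu_gm, mu_wm)` pairs
#'   (ms). Defaults are plausible 3T values.
#' @param regions Region geometry, see [default_regions].
#' @param noise_sd Gaussian noise SD (ms) added to every region voxel.
#' @param lesions Optional data.frame with columns `region`, `radius`
#'   (voxels) and optionally `cx, cy, cz` (voxel center; drawn inside the
#'   region if absent). Lesion T1 is elevated by 20% (hyperintense) and
#'   the voxels are flagged in the returned mask.
#' @param seed Seed making the phantom reproducible.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(intensities = list(thalamus = c(1389, 912),
                                             caudate = c(1400, 910),
                                             putamen = c(1380, 895),
                                             pallidum = c(1320, 855)),
                          regions = default_regions(),
                          noise_sd = 50, lesions = NULL, seed = 1L) {
  stopifnot(noise_sd >= 0)
  for (r in names(intensities)) {
    mus <- intensities[[r]]
    if (length(mus) != 2 || mus[1] <= mus[2])
      stop("region ", r, ": intensities must be c(mu_gm, mu_wm) with mu_gm > mu_wm",
           call. = FALSE)
  }
  if (!all(names(intensities) %in% names(regions)))
    stop("intensities name a region without geometry", call. = FALSE)
  structure(list(intensities = intensities,
                 regions = regions[names(intensities)],
                 noise_sd = noise_sd, lesions = lesions, seed = seed),
            class = "phantom_truth")
}

# voxel-space geometry of one region on a given grid
region_voxels <- function(def, dim) {
  center <- round(def$center * dim)
  semi <- pmax(round(def$semiaxes * dim), 2)
  rng <- lapply(1:3, function(k)
    max(1, center[k] - semi[k]):min(dim[k], center[k] + semi[k]))
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  r2 <- ((g$x - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2
  keep <- r2 <= 1
  list(idx = (g$z[keep] - 1L) * dim[1] * dim[2] + (g$y[keep] - 1L) * dim[1] +
         g$x[keep],
       r = sqrt(r2[keep]), center = center, semi = semi)
}

#' Generate a phantom T1 volume with labels and lesion mask
#'
#' Builds the forward model `y = mu_gm * c + mu_wm * (1 - c) + noise`
#' inside each ellipsoidal region (background 0). Reproducible: the same
#' truth (including its seed) gives a bit-identical volume.
#'
#' @param truth A [phantom_truth].
#' @param dim Grid dimensions (default 64^3 at 1 mm isotropic).
#' @param subject_id Identifier stored in the volume.
#' @return A list with `t1` ([t1_volume]), `labels` ([label_volume]),
#'   `lesions` ([binary_mask]) and `concentrations` (list of per-region
#'   true concentration vectors, ordered like the region voxel indices).
#' @export
generate_phantom <- function(truth, dim = c(64, 64, 64),
                             subject_id = "phantom") {
  stopifnot(inherits(truth, "phantom_truth"), length(dim) == 3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(truth$seed)

  vals <- array(0, dim = dim)
  labs <- array(0L, dim = dim)
  les <- array(FALSE, dim = dim)
  dict <- default_region_labels()
  extra <- setdiff(names(truth$regions), names(dict))
  if (length(extra))
    dict <- c(dict, stats::setNames(max(dict) + seq_along(extra), extra))
  conc <- list()
  geom <- list()
  for (r in names(truth$regions)) {
    def <- truth$regions[[r]]
    rv <- region_voxels(def, dim)
    if (any(rv$center - rv$semi < 1) || any(rv$center + rv$semi > dim))
      stop("region ", r, " does not fit inside the grid", call. = FALSE)
    if (any(labs[rv$idx] != 0))
      stop("overlapping region specification: ", r, call. = FALSE)
    r0 <- if (is.null(def$core_radius)) 0.25 else def$core_radius
    cgm <- pmin(1, (1 - rv$r^def$profile_exponent) /
                  (1 - r0^def$profile_exponent))
    mus <- truth$intensities[[r]]
    y <- mus[1] * cgm + mus[2] * (1 - cgm)
    if (truth$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, truth$noise_sd)
    vals[rv$idx] <- y
    labs[rv$idx] <- dict[[r]]
    conc[[r]] <- cgm
    geom[[r]] <- rv
  }
  if (!is.null(truth$lesions) && nrow(truth$lesions) > 0) {
    for (i in seq_len(nrow(truth$lesions))) {
      lr <- truth$lesions[i, ]
      def <- truth$regions[[lr$region]]
      if (is.null(def)) stop("lesion in unknown region ", lr$region, call. = FALSE)
      rv <- geom[[lr$region]]
      if (lr$radius >= min(rv$semi))
        stop("lesion radius ", lr$radius, " does not fit inside region ",
             lr$region, call. = FALSE)
      if (all(c("cx", "cy", "cz") %in% names(lr)) && !is.na(lr$cx)) {
        lc <- c(lr$cx, lr$cy, lr$cz)
      } else {
        # draw a center such that the sphere stays inside the ellipsoid box
        off <- vapply(rv$semi, function(s)
          sample(seq(-max(s - lr$radius - 1, 0), max(s - lr$radius - 1, 0)), 1),
          numeric(1))
        lc <- rv$center + round(off / 2)
      }
      rng <- lapply(1:3, function(k)
        max(1, lc[k] - lr$radius):min(dim[k], lc[k] + lr$radius))
      g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
      d2 <- (g$x - lc[1])^2 + (g$y - lc[2])^2 + (g$z - lc[3])^2
      li <- (g$z[d2 <= lr$radius^2] - 1L) * dim[1] * dim[2] +
        (g$y[d2 <= lr$radius^2] - 1L) * dim[1] + g$x[d2 <= lr$radius^2]
      les[li] <- TRUE
      vals[li] <- vals[li] * 1.2          # hyperintense lesion tissue
    }
  }
  affine <- diag(4)
  list(t1 = t1_volume(vals, affine, subject_id = subject_id),
       labels = label_volume(labs, dictionary = dict, affine = affine),
       lesions = binary_mask(les, affine),
       concentrations = conc)
}

#' Cohort specification for the synthetic study
#'
#' Defaults emulate the comparison of 19 healthy controls against 43
#' relapsing-remitting MS patients: the thalamic characteristic
#' intensities are drawn from GM 1389 +/- 47 ms (HC) vs 1427 +/- 40 ms
#' (patients) and WM 912 +/- 18 ms vs 918 +/- 14 ms; the putamen carries
#' small sub-significant shifts in both components; caudate and pallidum
#' are null regions. Subject-level variation enters through the
#' characteristic intensities; the concentration profiles are common to
#' all subjects. Patients additionally receive small spherical lesions
#' (excluded from analysis as normal-appearing tissue is retained).
#'
#' @param n_control,n_patient Group sizes (default 19 and 43).
#' @param group_means Named list: per region, a list with `HC` and
#'   `PATIENT` entries of `c(mu_gm, mu_wm)` means (ms).
#' @param group_sds Same shape, SDs of the subject-level draws (ms).
#' @param regions Region geometry ([default_regions]).
#' @param profile_exponent_sd Between-subject SD of each region's radial
#'   profile exponent (default 0.5, which reproduces a realistic
#'   between-subject spread of the concentration ratio). This is what gives the concentration
#'   ratio a realistic between-subject spread; setting it to 0 freezes the
#'   concentration pattern across subjects.
#' @param noise_sd Voxel noise SD (ms, default 50).
#' @param lesion_count,lesion_radius Number and radius (voxels) of
#'   spherical lesions per patient (default 2 lesions of radius 2,
#'   mimicking a low lesion load).
#' @param age_mean,age_sd Named (`HC`, `PATIENT`) age distributions in
#'   years (defaults 33 +/- 9.3 and 35.2 +/- 10).
#' @param p_female Named probabilities of female sex (defaults 11/19 and
#'   27/43).
#' @param dim Grid dimensions.
#' @param seed Top-level seed; all randomness flows from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 19, n_patient = 43,
                        group_means = list(
                          thalamus = list(HC = c(1389, 912), PATIENT = c(1427, 918)),
                          caudate  = list(HC = c(1400, 910), PATIENT = c(1400, 910)),
                          putamen  = list(HC = c(1380, 895), PATIENT = c(1402, 903)),
                          pallidum = list(HC = c(1320, 855), PATIENT = c(1320, 855))),
                        group_sds = list(
                          thalamus = list(HC = c(47, 18), PATIENT = c(40, 14)),
                          caudate  = list(HC = c(45, 16), PATIENT = c(45, 16)),
                          putamen  = list(HC = c(45, 16), PATIENT = c(45, 16)),
                          pallidum = list(HC = c(40, 15), PATIENT = c(40, 15))),
                        regions = default_regions(),
                        profile_exponent_sd = 0.5,
                        noise_sd = 50,
                        lesion_count = 2, lesion_radius = 2,
                        age_mean = c(HC = 33, PATIENT = 35.2),
                        age_sd = c(HC = 9.3, PATIENT = 10),
                        p_female = c(HC = 11 / 19, PATIENT = 27 / 43),
                        dim = c(64, 64, 64), seed = 1L) {
  stopifnot(n_control >= 1, n_patient >= 1, noise_sd >= 0,
            lesion_count >= 0, lesion_radius >= 1)
  if (!setequal(names(group_means), names(group_sds)))
    stop("group_means and group_sds must name the same regions", call. = FALSE)
  for (r in names(group_sds))
    for (g in c("HC", "PATIENT"))
      if (any(group_sds[[r]][[g]] < 0)) stop("SDs must be >= 0", call. = FALSE)
  stopifnot(profile_exponent_sd >= 0)
  structure(list(n_control = n_control, n_patient = n_patient,
                 group_means = group_means, group_sds = group_sds,
                 regions = regions[names(group_means)],
                 profile_exponent_sd = profile_exponent_sd,
                 noise_sd = noise_sd,
                 lesion_count = lesion_count, lesion_radius = lesion_radius,
                 age_mean = age_mean, age_sd = age_sd, p_female = p_female,
                 dim = dim, seed = seed),
            class = "cohort_spec")
}

draw_subject_truth <- function(spec, group) {
  ints <- lapply(names(spec$group_means), function(r) {
    m <- spec$group_means[[r]][[group]]
    s <- spec$group_sds[[r]][[group]]
    repeat {
      mus <- stats::rnorm(2, m, s)
      if (mus[1] > mus[2] + 1) return(mus)
    }
  })
  stats::setNames(ints, names(spec$group_means))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject, per-region characteristic intensities from the
#' group distributions of `spec`, builds a phantom volume per subject
#' ([generate_phantom]), assigns ages and sexes, and places lesions in
#' patients. With `out_dir` the volumes are written as gzipped NIfTI and
#' the tables as CSV (`cohort.csv`, `truth_manifest.csv`); without it the
#' volumes are returned in memory.
#'
#' @param spec A [cohort_spec].
#' @param out_dir Optional output directory (created if needed).
#' @param seed Overrides `spec$seed` when given.
#' @return A list with `cohort` (data.frame), `truth` (data.frame, one row
#'   per subject x region with the drawn values and the seed), and
#'   `volumes` (named list of per-subject volume lists; `NULL` when
#'   writing to disk).
#' @export
generate_cohort <- function(spec, out_dir = NULL, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  write_out <- !is.null(out_dir)
  if (write_out) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
    if (file.access(out_dir, 2) != 0) stop(out_dir, " is not writable", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  groups <- rep(c("HC", "PATIENT"), c(spec$n_control, spec$n_patient))
  n <- length(groups)
  ids <- sprintf("sub%03d", seq_len(n))
  cohort <- data.frame(subject_id = ids, group = groups,
                       age = NA_real_, sex = NA_character_,
                       t1_path = NA_character_, labels_path = NA_character_,
                       lesion_path = NA_character_, stringsAsFactors = FALSE)
  truth_rows <- list()
  volumes <- if (write_out) NULL else list()
  labels_path <- if (write_out) file.path(out_dir, "labels.nii.gz") else NA

  for (i in seq_len(n)) {
    g <- groups[i]
    cohort$age[i] <- max(18, stats::rnorm(1, spec$age_mean[[g]], spec$age_sd[[g]]))
    cohort$sex[i] <- if (stats::runif(1) < spec$p_female[[g]]) "F" else "M"
    ints <- draw_subject_truth(spec, g)
    regions_i <- spec$regions
    if (spec$profile_exponent_sd > 0) {
      for (r in names(regions_i))
        regions_i[[r]]$profile_exponent <-
          max(1.5, stats::rnorm(1, regions_i[[r]]$profile_exponent,
                                spec$profile_exponent_sd))
    }
    lesions <- NULL
    if (g == "PATIENT" && spec$lesion_count > 0) {
      lesions <- data.frame(
        region = sample(names(spec$regions), spec$lesion_count, replace = TRUE),
        radius = spec$lesion_radius)
    }
    truth <- phantom_truth(intensities = ints, regions = regions_i,
                           noise_sd = spec$noise_sd, lesions = lesions,
                           seed = (seed + 104729L * i) %% .Machine$integer.max)
    ph <- generate_phantom(truth, dim = spec$dim, subject_id = ids[i])
    for (r in names(ints))
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject_id = ids[i], region = r, group = g,
        mu_gm = ints[[r]][1], mu_wm = ints[[r]][2],
        profile_exponent = regions_i[[r]]$profile_exponent,
        noise_sd = spec$noise_sd, seed = seed, stringsAsFactors = FALSE)
    if (write_out) {
      t1p <- file.path(out_dir, paste0(ids[i], "_t1.nii.gz"))
      write_t1_volume(ph$t1, t1p)
      cohort$t1_path[i] <- t1p
      if (i == 1) write_label_volume(ph$labels, labels_path)
      cohort$labels_path[i] <- labels_path
      if (any(ph$lesions$mask)) {
        lp <- file.path(out_dir, paste0(ids[i], "_lesions.nii.gz"))
        write_mask(ph$lesions, lp)
        cohort$lesion_path[i] <- lp
      }
    } else {
      volumes[[ids[i]]] <- list(t1 = ph$t1, labels = ph$labels,
                                lesions = if (any(ph$lesions$mask)) ph$lesions else NULL)
    }
  }
  truth_df <- do.call(rbind, truth_rows)
  if (write_out) {
    write_cohort_table(cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(truth_df, file.path(out_dir, "truth_manifest.csv"),
                     row.names = FALSE)
  }
  list(cohort = cohort, truth = truth_df, volumes = volumes)
}
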