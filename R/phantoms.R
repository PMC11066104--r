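# Synthetic 3D "brain" phantoms with planted lesions.
#
# Every downstream stage (classifier, relevance engine, validation battery,
# longitudinal analyses) is exercisable on these fixtures: ellipsoidal brain
# volumes on a shared cubic grid, an integer-labelled region atlas, a
# reference map built from known regions, and longitudinal visit tables.

#' Build a synthetic region atlas on an ellipsoidal brain mask
#'
#' The brain mask is an axis-aligned ellipsoid covering roughly 80% of the
#' grid extent; interior voxels are partitioned into `n_regions` contiguous
#' regions by nearest-seed (Voronoi) assignment, so every brain voxel lies in
#' exactly one region and region ids are contiguous from 1.
#'
#' @param grid cubic grid side length (voxels).
#' @param n_regions number of atlas regions.
#' @param seed RNG seed controlling region seed placement.
#' @return object of class `synthetic_atlas`: `labels` (integer 3D array,
#'   0 = background), `names` (region id -> name), `brain_mask` (logical 3D),
#'   `grid`.
#' @export
synthetic_atlas <- function(grid = 48, n_regions = 12, seed = 1) {
  stopifnot(grid >= 8, n_regions >= 1)
  ctr <- (grid + 1) / 2
  semi <- grid / 2 * c(0.80, 0.76, 0.72)
  idx <- seq_len(grid)
  gx <- (idx - ctr) / semi[1]
  gy <- (idx - ctr) / semi[2]
  gz <- (idx - ctr) / semi[3]
  rho2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  brain <- rho2 <= 1
  vox <- which(brain, arr.ind = TRUE)
  if (nrow(vox) < n_regions)
    stop("grid too small to contain ", n_regions, " atlas regions")

  seeds <- with_seed(seed, vox[sample.int(nrow(vox), n_regions), , drop = FALSE])
  # nearest seed in voxel coordinates; ties broken by lowest region id
  d2 <- matrix(0, nrow(vox), n_regions)
  for (r in seq_len(n_regions))
    d2[, r] <- (vox[, 1] - seeds[r, 1])^2 + (vox[, 2] - seeds[r, 2])^2 +
      (vox[, 3] - seeds[r, 3])^2
  lab <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dim = c(grid, grid, grid))
  labels[vox] <- lab
  structure(
    list(labels = labels,
         names = stats::setNames(sprintf("region_%02d", seq_len(n_regions)),
                                 seq_len(n_regions)),
         brain_mask = brain,
         grid = grid,
         rho2 = rho2),
    class = "synthetic_atlas")
}

#' @export
print.synthetic_atlas <- function(x, ...) {
  cat(sprintf("<synthetic_atlas> grid %d^3, %d regions, %d brain voxels\n",
              x$grid, length(x$names), sum(x$brain_mask)))
  invisible(x)
}

# Smooth baseline tissue intensity inside the brain mask, in [~0.4, 0.75].
#' @noRd
baseline_intensity <- function(atlas) {
  base <- 0.4 + 0.35 * pmax(1 - atlas$rho2, 0)
  base[!atlas$brain_mask] <- 0
  base
}

#' Generate a labelled phantom cohort
#'
#' Cases differ from controls only by a multiplicative intensity reduction
#' (`1 - effect`, simulated atrophy) inside the lesion regions, plus i.i.d.
#' Gaussian voxel noise inside the brain. Optionally, a second, orthogonal
#' "dimorphism" signal tied to `sex` (used by the alternative-task null
#' pipeline) reduces intensity in `sex_regions` for one sex; sex is assigned
#' independently of the diagnostic label.
#'
#' @param n_per_class phantoms per class (controls and cases).
#' @param atlas a [synthetic_atlas()].
#' @param lesion_regions integer region ids carrying the case signal.
#' @param effect fractional intensity reduction in lesioned voxels (> 0 for a
#'   real signal; 0 yields a null cohort).
#' @param noise_sd standard deviation of the additive voxel noise.
#' @param sex_regions optional region ids carrying a sex-linked signal.
#' @param sex_effect fractional reduction in `sex_regions` for female phantoms.
#' @param seed RNG seed; identical seeds give voxel-identical cohorts.
#' @return list of `phantom` objects, each with fields `volume`, `label`,
#'   `lesion_mask`, `subject_id`, `site`, `age`, `sex`.
#' @export
generate_cohort <- function(n_per_class, atlas, lesion_regions,
                            effect = 0.3, noise_sd = 0.05,
                            sex_regions = integer(0), sex_effect = 0,
                            seed = 1) {
  stopifnot(n_per_class >= 0, effect >= 0, noise_sd >= 0)
  check_regions(atlas, lesion_regions)
  if (length(sex_regions)) check_regions(atlas, sex_regions)
  if (n_per_class == 0) return(list())

  base <- baseline_intensity(atlas)
  lesion <- atlas$labels %in% lesion_regions
  dim(lesion) <- dim(atlas$labels)
  dimo <- atlas$labels %in% sex_regions
  dim(dimo) <- dim(atlas$labels)
  nb <- sum(atlas$brain_mask)

  with_seed(seed, {
    n <- 2L * n_per_class
    labels <- rep(c(0L, 1L), each = n_per_class)
    sexes <- rep_len(c("F", "M"), n)[sample.int(n)]
    sites <- rep_len(c("site_a", "site_b"), n)[sample.int(n)]
    ages <- runif(n, 55, 90)
    lapply(seq_len(n), function(i) {
      vol <- base
      if (labels[i] == 1L && effect > 0)
        vol[lesion] <- vol[lesion] * (1 - effect)
      if (sexes[i] == "F" && sex_effect > 0 && length(sex_regions))
        vol[dimo] <- vol[dimo] * (1 - sex_effect)
      vol[atlas$brain_mask] <- vol[atlas$brain_mask] + rnorm(nb, sd = noise_sd)
      vol <- array(pmin(pmax(vol, 0), 1), dim(base))
      vol[!atlas$brain_mask] <- 0
      structure(
        list(volume = vol,
             label = labels[i],
             lesion_mask = if (labels[i] == 1L && effect > 0) lesion
                           else array(FALSE, dim(lesion)),
             subject_id = sprintf("sub_%04d", i),
             site = sites[i],
             age = ages[i],
             sex = sexes[i]),
        class = "phantom")
    })
  })
}

#' @noRd
check_regions <- function(atlas, regions) {
  regions <- as.integer(regions)
  known <- as.integer(names(atlas$names))
  bad <- setdiff(regions, known)
  if (length(bad))
    stop("unknown atlas region id(s): ", paste(bad, collapse = ", "))
  invisible(regions)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s> label %d, %s, %s, age %.1f, %d lesion voxels\n",
              x$subject_id, x$label, x$sex, x$site, x$age, sum(x$lesion_mask)))
  invisible(x)
}

#' Extract cohort metadata as a data frame
#' @param cohort list of phantoms from [generate_cohort()].
#' @return data.frame with subject_id, site, age, sex, label.
#' @export
cohort_metadata <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    site = vapply(cohort, `[[`, "", "site"),
    age = vapply(cohort, `[[`, 0, "age"),
    sex = vapply(cohort, `[[`, "", "sex"),
    label = vapply(cohort, `[[`, 0L, "label"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic reference map from known regions
#'
#' Stand-in for an externally supplied meta-analytic consensus map `G`: the
#' indicator of the chosen "hot" regions, optionally box-blurred (3 passes,
#' approximating a Gaussian) so it decays smoothly outside them, re-masked to
#' the brain and scaled to a maximum of 1.
#'
#' @param atlas a [synthetic_atlas()].
#' @param hot_regions nonempty integer region ids.
#' @param blur odd box-kernel width in voxels; 0 disables blurring, in which
#'   case the support of the map equals the union of the hot regions exactly.
#' @return 3D numeric array `G` on the atlas grid.
#' @export
generate_reference_map <- function(atlas, hot_regions, blur = 3) {
  if (!length(hot_regions)) stop("hot_regions must be nonempty")
  check_regions(atlas, hot_regions)
  stopifnot(blur == 0 || (is_odd(blur) && blur > 0))
  g <- (atlas$labels %in% hot_regions) * 1.0
  dim(g) <- dim(atlas$labels)
  if (blur > 0) for (i in 1:3) g <- box_blur3d(g, blur)
  g[!atlas$brain_mask] <- 0
  g / max(g)
}

#' Generate a longitudinal visit table
#'
#' Emulates a memory-clinic cohort with mild cognitive impairment at
#' inclusion. Each subject follows one of four trajectory grammars:
#' `stable` (MCI throughout), `improving` (MCI then CN), `progressive`
#' (MCI visits, then a first DEM visit and DEM thereafter), and `ambiguous`
#' (diagnosis bounces, e.g. MCI -> DEM -> MCI; meant to be excluded
#' downstream).
#'
#' @param n_subjects number of subjects.
#' @param trajectory_mix named proportions over
#'   `c("stable", "progressive", "improving", "ambiguous")`; must sum to 1.
#' @param visit_gap range (days) of the uniform inter-visit gap.
#' @param n_visits_range inclusive range of visits per subject (ambiguous
#'   subjects get at least 3).
#' @param seed RNG seed.
#' @return data.frame with columns `subject_id`, `visit_date` (integer days
#'   since each subject's baseline), `diagnosis` (`CN`/`MCI`/`DEM`), and the
#'   generating `trajectory` (ground truth, for testing only).
#' @export
generate_visit_table <- function(n_subjects,
                                 trajectory_mix = c(stable = 0.55,
                                                    progressive = 0.30,
                                                    improving = 0.10,
                                                    ambiguous = 0.05),
                                 visit_gap = c(180, 400),
                                 n_visits_range = c(3, 7),
                                 seed = 1) {
  stopifnot(n_subjects >= 0, abs(sum(trajectory_mix) - 1) < 1e-8,
            all(trajectory_mix >= 0))
  kinds <- c("stable", "progressive", "improving", "ambiguous")
  stopifnot(all(names(trajectory_mix) %in% kinds))
  if (n_subjects == 0)
    return(data.frame(subject_id = character(), visit_date = integer(),
                      diagnosis = character(), trajectory = character(),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    traj <- sample(names(trajectory_mix), n_subjects, replace = TRUE,
                   prob = trajectory_mix)
    rows <- lapply(seq_len(n_subjects), function(i) {
      nv <- sample(seq(n_visits_range[1], n_visits_range[2]), 1)
      if (traj[i] == "ambiguous") nv <- max(nv, 3L)
      gaps <- round(runif(nv - 1, visit_gap[1], visit_gap[2]))
      days <- as.integer(c(0, cumsum(gaps)))
      dx <- switch(traj[i],
        stable = rep("MCI", nv),
        improving = {
          m <- sample(seq_len(nv - 1), 1)
          c(rep("MCI", m), rep("CN", nv - m))
        },
        progressive = {
          m <- sample(seq_len(nv - 1), 1)
          c(rep("MCI", m), rep("DEM", nv - m))
        },
        ambiguous = c("MCI", rep("DEM", nv - 2), "MCI"))
      data.frame(subject_id = sprintf("mci_%04d", i), visit_date = days,
                 diagnosis = dx, trajectory = traj[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write a phantom cohort to disk
#'
#' Volumes are written as NIfTI (`<subject_id>.nii.gz`) with an identity
#' affine and metadata as a TSV sidecar (`participants.tsv`).
#'
#' @param cohort list of phantoms.
#' @param dir output directory (created if needed).
#' @return the sidecar path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ph in cohort)
    write_nifti(ph$volume, file.path(dir, paste0(ph$subject_id, ".nii.gz")))
  meta <- cohort_metadata(cohort)
  path <- file.path(dir, "participants.tsv")
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
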