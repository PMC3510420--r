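#' Synthetic template-space label atlas
#'
#' Draws a deterministic "MNI-like" digital phantom atlas: a cerebral
#' ellipsoid whose cortical shell is parcellated into 15 cortical regions,
#' 8 subcortical nuclei embedded in a white-matter core, and a separate
#' cerebellar ellipsoid used as the reference region — 23 grey-matter
#' regions of interest in total, plus cerebellum and white matter. All
#' geometry scales with the grid, so the same atlas can be rendered at
#' full desk resolution (64 x 64 x 48 at 3 mm) or reduced Monte-Carlo
#' resolution.
#'
#' @param dim integer length-3 grid size (default `c(64, 64, 48)`).
#' @param vox_mm isotropic voxel size in mm (default 3).
#' @return an object of class `pet_atlas`: list with `labels` (integer
#'   volume; 0 = background), `lut` (data.frame: `id`, `name`, `tissue`),
#'   `neocortical` (names of the composite regions), `vox_mm`, `dim`.
#' @export
build_atlas <- function(dim = c(64L, 64L, 48L), vox_mm = 3) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 16L))
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]

  lut <- data.frame(
    id = 1:25,
    name = c("frontal_L", "frontal_R", "sensorimotor_L", "sensorimotor_R",
             "parietal_L", "parietal_R", "occipital_L", "occipital_R",
             "temporal_latbas_L", "temporal_latbas_R",
             "temporal_medial_L", "temporal_medial_R",
             "cingulate_ant", "cingulate_post", "precuneus",
             "hippocampus_L", "hippocampus_R", "caudate_L", "caudate_R",
             "putamen_L", "putamen_R", "thalamus_L", "thalamus_R",
             "cerebellum", "white_matter"),
    tissue = c(rep("cortical", 15), rep("subcortical", 8),
               "cerebellum", "white"),
    stringsAsFactors = FALSE
  )

  # voxel-centre coordinates
  xs <- rep(seq_len(nx), times = ny * nz)
  ys <- rep(rep(seq_len(ny), each = nx), times = nz)
  zs <- rep(seq_len(nz), each = nx * ny)

  # cerebrum ellipsoid (+y anterior, +z superior)
  cc <- c(0.50 * nx, 0.55 * ny, 0.62 * nz)
  cr <- c(0.40 * nx, 0.42 * ny, 0.33 * nz)
  ux <- (xs - cc[1]) / cr[1]
  uy <- (ys - cc[2]) / cr[2]
  uz <- (zs - cc[3]) / cr[3]
  rho2 <- ux^2 + uy^2 + uz^2

  lab <- integer(nx * ny * nz)

  in_cerebrum <- rho2 <= 1
  wm_core <- 0.62
  lab[in_cerebrum] <- 25L                              # white matter core
  shell <- in_cerebrum & rho2 > wm_core^2

  # cortical parcellation of the shell, first match wins
  medial <- abs(ux) < 0.22 & uz > 0.15
  # medial wall
  lab[shell & medial & uy > 0.35] <- 13L               # anterior cingulate
  lab[shell & medial & uy <= 0.35 & uy > -0.25] <- 14L # posterior cingulate
  lab[shell & medial & uy <= -0.25] <- 15L             # precuneus
  hemiR <- ux >= 0
  rest <- shell & !medial
  inf <- rest & uz <= -0.25
  lab[inf & uy > -0.2 & abs(ux) >= 0.45] <- ifelse(hemiR[inf & uy > -0.2 & abs(ux) >= 0.45], 10L, 9L)  # lateral/basal temporal
  lab[inf & uy > -0.2 & abs(ux) < 0.45]  <- ifelse(hemiR[inf & uy > -0.2 & abs(ux) < 0.45], 12L, 11L)  # medial temporal
  lab[inf & uy <= -0.2] <- ifelse(hemiR[inf & uy <= -0.2], 8L, 7L)           # occipital (posterior-inferior)
  sup <- rest & uz > -0.25
  lab[sup & uy > 0.3]               <- ifelse(hemiR[sup & uy > 0.3], 2L, 1L)               # frontal
  lab[sup & uy <= 0.3 & uy > 0]     <- ifelse(hemiR[sup & uy <= 0.3 & uy > 0], 4L, 3L)     # sensorimotor
  lab[sup & uy <= 0 & uy > -0.5]    <- ifelse(hemiR[sup & uy <= 0 & uy > -0.5], 6L, 5L)    # parietal
  lab[sup & uy <= -0.5]             <- ifelse(hemiR[sup & uy <= -0.5], 8L, 7L)             # occipital

  # subcortical nuclei (centres/radii in cerebrum-radius units); carved out
  # of the white-matter core, mirrored across the midline
  nuclei <- list(
    hippocampus = list(c(0.42, -0.25, -0.35), c(0.18, 0.24, 0.28)),
    caudate     = list(c(0.18,  0.28,  0.08), c(0.17, 0.22, 0.28)),
    putamen     = list(c(0.42,  0.08, -0.08), c(0.17, 0.22, 0.28)),
    thalamus    = list(c(0.18, -0.05, -0.10), c(0.18, 0.22, 0.28))
  )
  nucleus_ids <- c(hippocampus = 16L, caudate = 18L, putamen = 20L, thalamus = 22L)
  for (nm in names(nuclei)) {
    ctr <- nuclei[[nm]][[1]]; rad <- nuclei[[nm]][[2]]
    for (side in 0:1) {                                 # 0 = L, 1 = R
      cx <- if (side == 0) -ctr[1] else ctr[1]
      d2 <- ((ux - cx) / rad[1])^2 + ((uy - ctr[2]) / rad[2])^2 +
            ((uz - ctr[3]) / rad[3])^2
      lab[in_cerebrum & d2 <= 1] <- nucleus_ids[[nm]] + side
    }
  }

  # cerebellum: separate posterior-inferior ellipsoid
  bc <- c(0.50 * nx, 0.26 * ny, 0.20 * nz)
  br <- c(0.20 * nx, 0.14 * ny, 0.12 * nz)
  d2 <- ((xs - bc[1]) / br[1])^2 + ((ys - bc[2]) / br[2])^2 +
        ((zs - bc[3]) / br[3])^2
  lab[d2 <= 1 & lab == 0L] <- 24L

  labels <- array(lab, dim = dim)
  attr(labels, "vox_mm") <- vox_mm
  structure(
    list(labels = labels, lut = lut,
         neocortical = c("frontal_L", "frontal_R", "parietal_L", "parietal_R",
                         "temporal_latbas_L", "temporal_latbas_R"),
         vox_mm = vox_mm, dim = dim),
    class = "pet_atlas"
  )
}

#' @export
print.pet_atlas <- function(x, ...) {
  cat("pet_atlas:", paste(x$dim, collapse = " x "), "voxels @", x$vox_mm,
      "mm;", sum(x$labels > 0), "brain voxels,",
      nrow(x$lut) - 2L, "grey-matter ROIs + cerebellum + white matter\n")
  invisible(x)
}

#' Grey-matter indicator volume of an atlas
#'
#' Grey matter comprises the 23 cortical/subcortical ROIs and the
#' cerebellum; white matter and background are excluded.
#'
#' @param atlas a `pet_atlas`.
#' @return binary volume (0/1) on the atlas grid.
#' @export
atlas_gm_indicator <- function(atlas) {
  gm_ids <- atlas$lut$id[atlas$lut$tissue %in% c("cortical", "subcortical", "cerebellum")]
  v <- array(as.numeric(atlas$labels %in% gm_ids), dim = atlas$dim)
  attr(v, "vox_mm") <- atlas$vox_mm
  v
}

#' Names of the 23 grey-matter regions of interest
#' @param atlas a `pet_atlas`.
#' @export
atlas_roi_names <- function(atlas) {
  atlas$lut$name[atlas$lut$tissue %in% c("cortical", "subcortical")]
}
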