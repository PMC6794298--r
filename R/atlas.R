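## Schematic digital rat-brain label atlas.
##
## Geometry is deliberately schematic: rectangular VOIs inside a
## superellipsoid brain mask, mirrored across the sagittal midplane for
## paired structures. Only the label bookkeeping (pairing, subregion
## merging, a dedicated rest-of-brain label) and partial-volume behavior
## under a finite PSF matter for the analyses this package supports;
## anatomical fidelity is a non-goal.

## Layout in the reference 64 x 64 x 32 frame, scaled proportionally to
## other grid shapes. x is left-right (mirrored), y dorso-ventral-ish,
## z rostro-caudal (forebrain at low z, medulla at high z).
.atlas_layout <- function() {
  cort <- cortical_regions()
  lay <- list()
  ycent <- c(20, 32, 44)
  zcent <- c(6, 10, 14, 18)
  slots <- list(
    c(1, 1), c(1, 2), c(1, 3),    # frontal assoc, medial prefrontal, orbitofrontal
    c(2, 1), c(2, 2), c(2, 3),    # motor, cingulate, insular
    c(3, 1), c(3, 2), c(3, 3),    # somatosensory, parietal assoc, auditory
    c(4, 1), c(4, 2))             # visual, retro-splenial
  ord <- c("frontal association cortex", "medial prefrontal cortex",
           "orbitofrontal cortex", "motor cortex", "cingulate cortex",
           "insular cortex", "somatosensory cortex",
           "parietal association cortex", "auditory cortex",
           "visual cortex", "retro-splenial cortex")
  stopifnot(setequal(ord, cort))
  for (i in seq_along(ord)) {
    s <- slots[[i]]
    lay[[length(lay) + 1L]] <- list(
      region = ord[i], merge_group = ord[i], paired = TRUE,
      cx = 20, cy = ycent[s[2]], cz = zcent[s[1]], hw = c(4, 4, 1))
  }
  lay[[length(lay) + 1L]] <- list(region = "hippocampus (dorsal)",
    merge_group = "hippocampus", paired = TRUE,
    cx = 28, cy = 32, cz = 14, hw = c(3, 3, 1))
  lay[[length(lay) + 1L]] <- list(region = "hippocampus (ventral)",
    merge_group = "hippocampus", paired = TRUE,
    cx = 28, cy = 42, cz = 18, hw = c(3, 3, 1))
  lay[[length(lay) + 1L]] <- list(region = "thalamus",
    merge_group = "thalamus", paired = TRUE,
    cx = 28, cy = 32, cz = 10, hw = c(3, 3, 1))
  lay[[length(lay) + 1L]] <- list(region = "midbrain",
    merge_group = "midbrain", paired = FALSE,
    cx = 32.5, cy = 32, cz = 21, hw = c(5.5, 5.5, 1))
  lay[[length(lay) + 1L]] <- list(region = "pons",
    merge_group = "pons", paired = FALSE,
    cx = 32.5, cy = 32, cz = 25, hw = c(3.5, 3.5, 1))
  lay[[length(lay) + 1L]] <- list(region = "medulla",
    merge_group = "medulla", paired = FALSE,
    cx = 32.5, cy = 32, cz = 29, hw = c(3.5, 3.5, 1))
  lay
}

.REF_SHAPE <- c(64L, 64L, 32L)

#' Build a schematic rat-brain label atlas
#'
#' Constructs a 3D integer label volume with one left and one right label for
#' each paired cortical/subcortical structure, midline labels for the
#' brainstem regions, subregion labels for the hippocampus (merged at
#' analysis time), and a dedicated rest-of-brain label that serves as the
#' whole-brain reference VOI. The whole-brain VOI is its own label (the brain
#' mask minus all named VOIs) rather than the union of the analysis regions,
#' so its uptake can be simulated and quantified independently.
#'
#' Placement is deterministic up to a small seeded dorso-ventral jitter of
#' the paired structures; the same seed always yields a voxel-identical
#' volume.
#'
#' @param scheme a [region_scheme()].
#' @param grid_shape integer triple, voxel grid dimensions.
#' @param spacing_mm numeric triple, voxel size in mm (default
#'   `c(0.2, 0.2, 0.8)`, the reconstruction grid of the motivating scanner
#'   protocol).
#' @param seed integer seed controlling placement jitter.
#' @return An object of class `label_atlas`: list with `labels` (3D integer
#'   array, 0 = background), `spacing_mm`, and `lookup` (data frame with
#'   columns `label`, `region`, `hemisphere`, `merge_group`).
#' @examples
#' atl <- build_atlas(region_scheme(), seed = 1)
#' table(atl$lookup$hemisphere)
#' @export
build_atlas <- function(scheme = region_scheme(),
                        grid_shape = c(64L, 64L, 32L),
                        spacing_mm = c(0.2, 0.2, 0.8),
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  lay <- .atlas_layout()
  sc <- grid_shape / .REF_SHAPE

  labels <- array(0L, dim = grid_shape)
  lookup <- data.frame(label = integer(), region = character(),
                       hemisphere = character(), merge_group = character(),
                       stringsAsFactors = FALSE)
  next_id <- 1L

  ## per-merge-group dorso-ventral jitter, mirrored across hemispheres
  groups <- unique(vapply(lay, `[[`, "", "merge_group"))
  jit <- stats::setNames(
    with_seed(seed, sample(-1:1, length(groups), replace = TRUE)), groups)

  place <- function(region, merge_group, hemisphere, cx, cy, cz, hw) {
    cxs <- cx * sc[1]; cys <- (cy + jit[[merge_group]]) * sc[2]; czs <- cz * sc[3]
    hws <- pmax(1, round(hw * sc))
    x <- max(1L, round(cxs - hws[1])):min(grid_shape[1], round(cxs + hws[1]))
    y <- max(1L, round(cys - hws[2])):min(grid_shape[2], round(cys + hws[2]))
    z <- max(1L, round(czs - hws[3])):min(grid_shape[3], round(czs + hws[3]))
    n_vox <- length(x) * length(y) * length(z)
    if (n_vox < 20L)
      stop("grid too small to place region '", region, "' (",
           n_vox, " voxels < 20)")
    block <- labels[x, y, z]
    if (any(block != 0L))
      stop("placement collision for region '", region,
           "': grid too small for disjoint placement")
    labels[x, y, z] <<- next_id
    lookup[nrow(lookup) + 1L, ] <<- list(next_id, region, hemisphere, merge_group)
    next_id <<- next_id + 1L
    invisible(NULL)
  }

  for (item in lay) {
    if (item$paired) {
      place(item$region, item$merge_group, "left",
            item$cx, item$cy, item$cz, item$hw)
      place(item$region, item$merge_group, "right",
            .REF_SHAPE[1] + 1 - item$cx, item$cy, item$cz, item$hw)
    } else {
      place(item$region, item$merge_group, "midline",
            item$cx, item$cy, item$cz, item$hw)
    }
  }

  ## brain mask: superellipsoid; unassigned mask voxels become the
  ## rest-of-brain (whole-brain reference) label
  ctr <- (grid_shape + 1) / 2
  semi <- c(0.41, 0.41, 0.47) * grid_shape
  ax <- ((seq_len(grid_shape[1]) - ctr[1]) / semi[1])^4
  ay <- ((seq_len(grid_shape[2]) - ctr[2]) / semi[2])^4
  az <- ((seq_len(grid_shape[3]) - ctr[3]) / semi[3])^4
  mask <- outer(outer(ax, ay, `+`), az, `+`) <= 1
  wb_vox <- mask & labels == 0L
  if (sum(wb_vox) < 20L)
    stop("grid too small to place region '", whole_brain_region(), "'")
  labels[wb_vox] <- next_id
  lookup[nrow(lookup) + 1L, ] <- list(next_id, whole_brain_region(),
                                      "midline", whole_brain_region())

  atl <- structure(
    list(labels = labels, spacing_mm = as.numeric(spacing_mm), lookup = lookup),
    class = "label_atlas")
  .validate_atlas(atl, scheme)
  atl
}

.validate_atlas <- function(atlas, scheme = NULL) {
  lk <- atlas$lookup
  present <- sort(unique(as.vector(atlas$labels)))
  present <- present[present != 0L]
  if (!all(present %in% lk$label))
    stop("labels present in volume but missing from lookup: ",
         paste(setdiff(present, lk$label), collapse = ", "))
  paired <- lk[lk$hemisphere %in% c("left", "right"), ]
  for (g in unique(paired$merge_group)) {
    sides <- table(paired$hemisphere[paired$merge_group == g])
    if (!identical(unname(sides[["left"]]), unname(sides[["right"]])))
      stop("merge group '", g, "' has unbalanced left/right labels")
  }
  if (!is.null(scheme)) {
    need <- c(scheme$analysis_regions, scheme$whole_brain)
    missing <- setdiff(need, unique(lk$merge_group))
    if (length(missing))
      stop("atlas lacks labels for analysis regions: ",
           paste(missing, collapse = ", "))
  }
  invisible(atlas)
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("Label atlas:", paste(dim(x$labels), collapse = " x "),
      "voxels, spacing", paste(x$spacing_mm, collapse = " x "), "mm\n")
  cat(" ", nrow(x$lookup), "labels,",
      length(unique(x$lookup$merge_group)), "analysis VOIs (incl. whole brain)\n")
  invisible(x)
}

#' Voxel counts per atlas label
#' @param atlas a `label_atlas`.
#' @return named integer vector, voxels per label id.
#' @export
atlas_voxel_counts <- function(atlas) {
  v <- atlas$labels[atlas$labels != 0L]
  tab <- table(factor(v, levels = atlas$lookup$label))
  stats::setNames(as.integer(tab), names(tab))
}
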