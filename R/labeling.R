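#' Label volume container
#'
#' Per-voxel tissue categories coded 0 = excluded (CSF / invalid / outside
#' brain), 1 = ischemic core (IC), 2 = penumbra, 3 = normal tissue (NT),
#' 4 = contralateral parenchyma.  Categories are mutually exclusive and
#' exhaustive over the grid; penumbra and NT lie in the ipsilateral
#' hemisphere only.
#'
#' @param labels 3D integer array with codes 0-4.
#' @param hemisphere 3D integer array (0 = outside parenchyma,
#'   1 = ipsilateral, 2 = contralateral), as from [split_hemispheres()].
#' @param voxel_size mm per axis.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, hemisphere, voxel_size) {
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:4)) stopf("label codes must be in 0..4")
  if (!is.null(hemisphere) && !all(dim(hemisphere) == dim(labels)))
    stopf("hemisphere map does not match label grid")
  if (!is.null(hemisphere)) {
    if (any(labels %in% c(2L, 3L) & hemisphere == 2L))
      stopf("penumbra/NT voxels found in the contralateral hemisphere")
  }
  structure(list(labels = labels, hemisphere = hemisphere,
                 voxel_size = voxel_size),
            class = "label_volume")
}

LABEL_CODES <- c(excluded = 0L, IC = 1L, penumbra = 2L, NT = 3L,
                 contralateral = 4L)

#' Split the parenchyma into hemispheres by a midline plane
#'
#' Assigns every parenchyma voxel to the ipsilateral (lesioned) or
#' contralateral hemisphere by the sign of its distance to the supplied
#' midline plane; the ipsilateral hemisphere is the negative half-space of
#' the plane normal.
#'
#' @param mask 3D logical parenchyma mask.
#' @param midline list with `point` and `normal` (grid coordinates, voxel
#'   units); the plane must intersect the grid.
#' @return 3D integer array: 0 outside mask, 1 ipsilateral,
#'   2 contralateral.
#' @export
split_hemispheres <- function(mask, midline) {
  if (is.null(midline) || is.null(midline$point) || is.null(midline$normal))
    stopf("midline plane missing: no atlas fallback is available")
  d <- dim(mask)
  idx <- seq_len(prod(d))
  co <- vox_coords(idx, d)
  sd_ <- sweep(co, 2, midline$point) %*% midline$normal
  if (all(sd_ >= 0) || all(sd_ <= 0))
    stopf("midline plane does not intersect the grid")
  hemi <- array(0L, d)
  hemi[mask & array(sd_ < 0, d)] <- 1L
  hemi[mask & array(sd_ >= 0, d)] <- 2L
  hemi
}

#' Delineate core, penumbra and normal tissue by perfusion-diffusion mismatch
#'
#' Applies the mismatch rules with contralateral-hemisphere reference
#' values: the ischemic core is the set of ipsilateral voxels whose MD
#' falls at least `md_reduction` (default 30%) below the mean MD of the
#' contralateral parenchyma; the perfusion deficit is a relative CBF at
#' least `cbf_reduction` (default 46%) below the contralateral mean; the
#' penumbra is the hypoperfused territory outside the core, and ipsilateral
#' tissue without a CBF deficit is normal tissue.  Small components are
#' then removed by [contiguity_correct()].
#'
#' @param metrics CSF-excluded `metric_maps` (the MD map and parenchyma
#'   mask are used).
#' @param cbf 3D relative-CBF map on the same grid (e.g. the `rcbf` field
#'   of [compute_perfusion_maps()]).
#' @param hemis hemisphere map from [split_hemispheres()].
#' @param md_reduction,cbf_reduction fractional reduction thresholds.
#' @param min_size minimum connected-component size kept by the contiguity
#'   correction; set 0 to skip it.
#' @return a [label_volume()] with attributes `md_ref` and `cbf_ref`.
#' @export
delineate <- function(metrics, cbf, hemis, md_reduction = 0.30,
                      cbf_reduction = 0.46, min_size = 10L) {
  stopifnot(inherits(metrics, "metric_maps"))
  if (!all(dim(cbf) == metrics$dim)) stopf("CBF map grid mismatch")
  par_mask <- metrics$brain_mask
  contra <- par_mask & hemis == 2L
  ipsi <- par_mask & hemis == 1L
  if (!any(contra)) stopf("empty contralateral parenchyma")
  md <- metrics$MD
  md_ref <- mean(md[contra], na.rm = TRUE)
  cbf_ref <- mean(cbf[contra], na.rm = TRUE)
  ok <- ipsi & is.finite(md) & is.finite(cbf)
  ic <- ok & md < (1 - md_reduction) * md_ref
  hypo <- ok & cbf < (1 - cbf_reduction) * cbf_ref
  labels <- array(LABEL_CODES[["excluded"]], metrics$dim)
  labels[contra] <- LABEL_CODES[["contralateral"]]
  labels[ok & !hypo & !ic] <- LABEL_CODES[["NT"]]
  labels[hypo & !ic] <- LABEL_CODES[["penumbra"]]
  labels[ic] <- LABEL_CODES[["IC"]]
  lv <- label_volume(labels, hemis, metrics$voxel_size)
  if (min_size > 0) lv <- contiguity_correct(lv, min_size)
  attr(lv, "md_ref") <- md_ref
  attr(lv, "cbf_ref") <- cbf_ref
  lv
}

## 26-connected components of a 3D logical mask; integer labels, 0 = background
connected_components <- function(mask) {
  d <- dim(mask)
  nvox <- prod(d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  comp <- array(0L, d)
  todo <- which(mask)
  if (!length(todo)) return(comp)
  in_mask <- array(FALSE, d); in_mask[todo] <- TRUE
  visited <- array(FALSE, d)
  lab <- 0L
  for (s in todo) {
    if (visited[s]) next
    lab <- lab + 1L
    frontier <- s
    visited[s] <- TRUE
    comp[s] <- lab
    while (length(frontier)) {
      co <- vox_coords(frontier, d)
      nxt <- integer(0)
      for (r in seq_len(nrow(offs))) {
        ni <- co[, 1] + offs[r, 1]
        nj <- co[, 2] + offs[r, 2]
        nk <- co[, 3] + offs[r, 3]
        okc <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] &
          nk >= 1L & nk <= d[3]
        if (!any(okc)) next
        nidx <- (nk[okc] - 1L) * d[1] * d[2] + (nj[okc] - 1L) * d[1] + ni[okc]
        nidx <- nidx[in_mask[nidx] & !visited[nidx]]
        if (length(nidx)) {
          visited[nidx] <- TRUE
          comp[nidx] <- lab
          nxt <- c(nxt, nidx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  comp
}

#' Remove small connected components from a label volume
#'
#' Connected components (26-connectivity) of the core and of the penumbra
#' smaller than `min_size` voxels are reassigned to the surrounding
#' majority category (ties broken in the order NT, penumbra, contralateral,
#' core, excluded).  The operation is idempotent.
#'
#' @param lv a [label_volume()].
#' @param min_size minimum component size in voxels (>= 1).
#' @return the corrected [label_volume()].
#' @export
contiguity_correct <- function(lv, min_size = 10L) {
  stopifnot(inherits(lv, "label_volume"))
  if (min_size < 1L) stopf("min_size must be >= 1")
  labels <- lv$labels
  d <- dim(labels)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  pref <- c(3L, 2L, 4L, 1L, 0L)                 # tie-break preference
  for (cls in c(LABEL_CODES[["IC"]], LABEL_CODES[["penumbra"]])) {
    comp <- connected_components(labels == cls)
    if (!max(comp)) next
    sizes <- tabulate(comp[comp > 0L])
    for (ci in which(sizes < min_size)) {
      vox <- which(comp == ci)
      co <- vox_coords(vox, d)
      neigh <- integer(0)
      for (r in seq_len(nrow(offs))) {
        ni <- co[, 1] + offs[r, 1]; nj <- co[, 2] + offs[r, 2]
        nk <- co[, 3] + offs[r, 3]
        okc <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] &
          nk >= 1L & nk <= d[3]
        neigh <- c(neigh, (nk[okc] - 1L) * d[1] * d[2] +
                     (nj[okc] - 1L) * d[1] + ni[okc])
      }
      neigh <- setdiff(unique(neigh), vox)
      cand <- labels[neigh]
      cand <- cand[cand != cls]
      if (!length(cand)) next
      tab <- table(cand)
      best <- as.integer(names(tab)[tab == max(tab)])
      labels[vox] <- pref[which(pref %in% best)[1]]
    }
  }
  out <- label_volume(labels, lv$hemisphere, lv$voxel_size)
  attributes(out) <- utils::modifyList(attributes(lv), attributes(out))
  out
}

#' Penumbral volume in mm^3
#'
#' Sums the penumbral cross-sectional areas slice by slice and multiplies
#' by the slice thickness.
#'
#' @param lv a [label_volume()] (or a 3D logical penumbra mask together
#'   with `voxel_size`).
#' @param voxel_size mm per axis; taken from `lv` when it is a
#'   `label_volume`.
#' @return volume in mm^3.
#' @export
compute_pv <- function(lv, voxel_size = NULL) {
  if (inherits(lv, "label_volume")) {
    mask <- lv$labels == LABEL_CODES[["penumbra"]]
    voxel_size <- lv$voxel_size
  } else mask <- lv
  if (is.null(voxel_size)) stopf("voxel_size required")
  area <- voxel_size[1] * voxel_size[2]
  slice_counts <- apply(mask, 3, sum)
  sum(slice_counts * area) * voxel_size[3]
}
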