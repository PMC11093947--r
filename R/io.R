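## NIfTI image carrying the voxel dimensions in its header
nifti_with_voxels <- function(x, voxel_size, datatype = NULL) {
  img <- RNifti::asNifti(x)
  img <- RNifti::`pixdim<-`(img, voxel_size)   # before any datatype change:
  if (!is.null(datatype)) img <- RNifti::asNifti(img, datatype = datatype)
  img                                          # internal images are frozen
}

#' Write metric maps as NIfTI volumes
#'
#' One file per metric plus the brain and CSF masks.
#'
#' @param metrics a `metric_maps` object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths written, invisibly.
#' @export
write_metric_maps <- function(metrics, dir, prefix = "metric") {
  stopifnot(inherits(metrics, "metric_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in metric_names()) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(nifti_with_voxels(metrics[[nm]],
                                         metrics$voxel_size), p)
    paths <- c(paths, p)
  }
  for (nm in c("brain_mask", "csf_mask")) {
    m <- metrics[[nm]]
    if (is.null(m)) next
    storage.mode(m) <- "integer"
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(nifti_with_voxels(m, metrics$voxel_size, "uint8"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write perfusion maps as NIfTI volumes
#'
#' @param pm a `perfusion_maps` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param voxel_size mm per axis.
#' @return paths written, invisibly.
#' @export
write_perfusion_maps <- function(pm, dir, prefix = "perfusion",
                                 voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(pm, "perfusion_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(c("rcbv", "rmtt", "rcbf"), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(nifti_with_voxels(pm[[nm]], voxel_size), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read / write label volumes as uint8 NIfTI
#'
#' Codes: 0 excluded, 1 core, 2 penumbra, 3 normal tissue,
#' 4 contralateral.  The hemisphere map is not stored in the file.
#'
#' @param lv a [label_volume()].
#' @param path NIfTI file path.
#' @return `write_label_volume`: the path, invisibly;
#'   `read_label_volume`: a [label_volume()] (without hemisphere map).
#' @export
write_label_volume <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  lab <- lv$labels
  storage.mode(lab) <- "integer"
  RNifti::writeNifti(nifti_with_voxels(lab, lv$voxel_size, "uint8"), path)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  label_volume(array(as.integer(img), dim(img)), NULL, vs)
}

#' Write a feature table as CSV with a JSON schema sidecar
#'
#' @param table a feature table from [extract_features()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.schema.json`.
#' @return the CSV path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  schema <- list(columns = lapply(names(table), function(nm)
    list(name = nm, type = class(table[[nm]])[1])),
    n_rows = nrow(table),
    n_features = length(intersect(names(table), feature_names())),
    n_dropped = attr(table, "n_dropped") %||% 0L)
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("label" %in% names(tab))
    tab$label <- factor(tab$label, levels = c("NT", "penumbra"))
  tab
}

#' Diagnostic plot of an NCA tuning curve
#'
#' Mean cross-validated classification loss against the regularisation
#' strength, with the selected value marked.
#'
#' @param x an `nca_result`.
#' @param ... passed to [plot()].
#' @export
plot.nca_result <- function(x, ...) {
  plot(x$lambda_grid, x$loss, log = "x", type = "b", pch = 16,
       xlab = expression(lambda), ylab = "mean CV classification loss",
       ...)
  graphics::abline(v = x$lambda_best, lty = 2)
  invisible(x)
}

#' Correlation and Bland-Altman plots of penumbral-volume agreement
#'
#' @param ml_pvs model-estimated volumes (mm^3).
#' @param pdm_pvs reference volumes (mm^3), paired.
#' @return the [pv_agreement()] statistics, invisibly.
#' @export
plot_pv_agreement <- function(ml_pvs, pdm_pvs) {
  ag <- pv_agreement(ml_pvs, pdm_pvs)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  plot(pdm_pvs, ml_pvs, pch = 16, xlab = "PDM-defined PV (mm^3)",
       ylab = "ML-estimated PV (mm^3)",
       main = sprintf("r = %.3f", ag$r %||% NA))
  graphics::abline(0, 1, lty = 2)
  means <- (ml_pvs + pdm_pvs) / 2
  diffs <- ml_pvs - pdm_pvs
  plot(means, diffs, pch = 16, xlab = "mean of methods (mm^3)",
       ylab = "difference (mm^3)",
       main = sprintf("bias %.2f [%.2f, %.2f]", ag$bias, ag$loa[1],
                      ag$loa[2]))
  graphics::abline(h = c(ag$bias, ag$loa), lty = c(1, 2, 2))
  invisible(ag)
}
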