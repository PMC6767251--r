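# Serialisation: 32-bit float TIFF for images/sinograms (with a JSON sidecar
# carrying the affine scale, since TIFF storage is defined on [0, 1]),
# directory bundles for paired datasets, and RDS checkpoints for models.

#' Write an image or sinogram matrix as 32-bit TIFF
#'
#' Values are affinely mapped to \[0, 1\] for storage; the original range is
#' kept in a `<path>.json` sidecar so [read_image_tiff()] restores the data
#' losslessly (to float precision).
#'
#' @param image Numeric matrix.
#' @param path Output file path (`.tif`).
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  scaled <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
            else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  jsonlite::write_json(list(min = rng[1], max = rng[2],
                            n_rows = nrow(image), n_cols = ncol(image)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path TIFF file path.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    img <- img * (meta$max - meta$min) + meta$min
  }
  img
}

#' Save a paired dataset as a directory bundle
#'
#' One TIFF pair (`input_NNNN.tif`, `label_NNNN.tif`) per sample plus a
#' `meta.json` with the geometry, per-sample deletion window, mask and
#' normalisation scale.
#'
#' @param dataset A `paired_dataset` from [build_dataset()].
#' @param dir Output directory (created if missing).
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- dataset[[1]]$label_sino$geometry
  meta <- list(geometry = unclass(g), n = length(dataset), samples = list())
  for (i in seq_along(dataset)) {
    smp <- dataset[[i]]
    tag <- sprintf("%04d", i)
    write_image_tiff(smp$input_sino$values,
                     file.path(dir, paste0("input_", tag, ".tif")))
    write_image_tiff(smp$label_sino$values,
                     file.path(dir, paste0("label_", tag, ".tif")))
    meta$samples[[i]] <- list(
      window = unclass(smp$window),
      valid_mask = smp$input_sino$valid_mask,
      smin = attr(smp$label_sino, "smin"),
      srange = attr(smp$label_sino, "srange"))
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a dataset bundle written by [save_dataset()]
#'
#' @param dir Bundle directory.
#' @return A `paired_dataset`.
#' @export
load_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  gm <- meta$geometry
  g <- scan_geometry(gm$mode, gm$n_views, gm$angular_range_deg, gm$n_bins,
                     gm$bin_size, gm$source_to_object, gm$source_to_detector)
  out <- vector("list", meta$n)
  for (i in seq_len(meta$n)) {
    tag <- sprintf("%04d", i)
    sm <- if (is.data.frame(meta$samples)) meta$samples[i, ]
          else meta$samples[[i]]
    label <- sinogram(read_image_tiff(
      file.path(dir, paste0("label_", tag, ".tif"))), g)
    attr(label, "smin") <- sm$smin
    attr(label, "srange") <- sm$srange
    input <- sinogram(read_image_tiff(
      file.path(dir, paste0("input_", tag, ".tif"))), g,
      valid_mask = unlist(sm$valid_mask))
    w <- deletion_window(unlist(sm$window)[1], unlist(sm$window)[2])
    out[[i]] <- structure(list(input_sino = input, label_sino = label,
                               source_image = NULL, window = w),
                          class = "paired_sample")
  }
  structure(out, class = "paired_dataset")
}

#' Save a trained model checkpoint
#'
#' Single-file RDS containing the generator and discriminator (specs +
#' weights), training configuration, geometry, loss history and seed.
#'
#' @param checkpoint A `sigan_checkpoint` from [train()].
#' @param path Output `.rds` path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "sigan_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return A `sigan_checkpoint`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "sigan_checkpoint"))
  ck
}
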