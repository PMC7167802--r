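# Readers/writers for image+mask stacks: multi-page TIFF for EM-like
# grayscale data, per-slice PNG directories for multi-channel data, and
# a JSON manifest recording generator parameters and seeds.

.need <- function(pkg) {
  .assert(requireNamespace(pkg, quietly = TRUE),
          paste0("package '", pkg, "' is required for this operation"))
}

#' Write samples as image/mask stacks with a manifest
#'
#' Grayscale (1-channel) samples are written as two multi-page TIFF
#' stacks (`images.tif`, `masks.tif`); multi-channel samples as
#' per-slice, per-channel PNG files. A `manifest.json` records the
#' layout, shapes and each sample's generator metadata.
#'
#' @param samples Sample list from [generate_em_like()] or
#'   [generate_brats_like()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_sample_set <- function(samples, dir) {
  .assert(length(samples) >= 1L, "no samples to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  C <- if (is.matrix(samples[[1L]]$image)) 1L else dim(samples[[1L]]$image)[3L]
  if (C == 1L) {
    .need("tiff")
    imgs <- lapply(samples, function(s) matrix(s$image, nrow(s$image), ncol(s$image)))
    msks <- lapply(samples, function(s) {
      m <- if (is.matrix(s$mask)) s$mask else s$mask[, , 1L]
      matrix(as.numeric(m > 0), nrow(m), ncol(m))
    })
    tiff::writeTIFF(imgs, file.path(dir, "images.tif"), bits.per.sample = 16L)
    tiff::writeTIFF(msks, file.path(dir, "masks.tif"), bits.per.sample = 16L)
    layout <- "tiff_stack"
  } else {
    .need("png")
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      for (ch in seq_len(C))
        png::writePNG(s$image[, , ch],
                      file.path(dir, sprintf("img_%03d_ch%d.png", i, ch)))
      lab <- s$labels %||% apply(s$mask, c(1L, 2L), which.max) - 1L
      png::writePNG(lab / 255, file.path(dir, sprintf("lab_%03d.png", i)))
    }
    layout <- "png_slices"
  }
  manifest <- list(layout = layout, n = length(samples), channels = C,
                   height = nrow(samples[[1L]]$image),
                   width = ncol(samples[[1L]]$image),
                   meta = lapply(samples, function(s) s$meta))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a sample set written by [write_sample_set()]
#'
#' @param dir Directory containing the stacks and `manifest.json`.
#' @return A list of samples (`image`, `mask`, `labels` where
#'   available, `meta`).
#' @export
read_sample_set <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  .assert(file.exists(mf_path), "no manifest.json in directory")
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  n <- mf$n
  if (identical(mf$layout, "tiff_stack")) {
    .need("tiff")
    imgs <- tiff::readTIFF(file.path(dir, "images.tif"), all = TRUE)
    msks <- tiff::readTIFF(file.path(dir, "masks.tif"), all = TRUE)
    out <- lapply(seq_len(n), function(i) {
      m <- matrix(as.integer(msks[[i]] > 0.5), nrow(msks[[i]]), ncol(msks[[i]]))
      list(image = array(imgs[[i]], c(dim(imgs[[i]]), 1L)), mask = m,
           labels = label_components(m), meta = NULL)
    })
  } else {
    .need("png")
    C <- mf$channels
    out <- lapply(seq_len(n), function(i) {
      img <- array(0, c(mf$height, mf$width, C))
      for (ch in seq_len(C))
        img[, , ch] <- png::readPNG(file.path(dir, sprintf("img_%03d_ch%d.png", i, ch)))
      lab <- round(png::readPNG(file.path(dir, sprintf("lab_%03d.png", i))) * 255)
      K <- max(lab) + 1L
      onehot <- array(0, c(mf$height, mf$width, max(K, 2L)))
      for (k in seq_len(dim(onehot)[3L])) onehot[, , k][lab == k - 1L] <- 1
      list(image = img, mask = onehot, labels = matrix(as.integer(lab), mf$height),
           meta = NULL)
    })
  }
  out
}

#' Read a grayscale image stack (multi-page TIFF or NIfTI volume)
#'
#' NIfTI volumes are sliced along the third axis into 2-D images.
#'
#' @param path `.tif`/`.tiff` or `.nii`/`.nii.gz` file.
#' @return `(N, H, W, 1)` array.
#' @export
read_image_stack <- function(path) {
  .assert(file.exists(path), paste0("no such file: ", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    .need("tiff")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (is.matrix(p)) p else p[, , 1L])
    out <- array(0, c(length(pages), dim(pages[[1L]]), 1L))
    for (i in seq_along(pages)) out[i, , , 1L] <- pages[[i]]
    return(out)
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    .need("RNifti")
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    .assert(length(d) >= 3L, "expected a 3-D NIfTI volume")
    out <- array(0, c(d[3L], d[1L], d[2L], 1L))
    for (i in seq_len(d[3L])) out[i, , , 1L] <- vol[, , i]
    rng <- range(out)
    if (diff(rng) > 0) out <- (out - rng[1L]) / diff(rng)
    return(out)
  }
  stop("unsupported stack format: ", path, call. = FALSE)
}

#' Write a probability stack as multi-page TIFF
#'
#' @param probs `(N, H, W, 1)` array in `[0, 1]`.
#' @param path Output `.tif` path.
#' @export
write_image_stack <- function(probs, path) {
  .need("tiff")
  .assert(.is_arr4(probs), "probs must be (N, H, W, 1)")
  pages <- lapply(seq_len(dim(probs)[1L]), function(i)
    matrix(pmin(pmax(probs[i, , , 1L], 0), 1), dim(probs)[2L], dim(probs)[3L]))
  tiff::writeTIFF(pages, path)
  invisible(path)
}
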