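# NIfTI volume loading, slice extraction, contrast stretching, resizing and
# preprocessed-slice caching. This module owns the [0,1] <-> [-1,1]
# conversion boundary: slices leave here in unit range; the diffusion layer
# converts at its own edge.

.axialAxis <- function(img) {
  tryCatch({
    orn <- RNifti::orientation(img)
    pos <- regexpr("[SI]", orn)[1]
    if (pos > 0) as.integer(pos) else 3L
  }, error = function(e) 3L)
}

#' Load a NIfTI volume (and optional ground-truth mask)
#'
#' Reads a `.nii` / `.nii.gz` volume, identifies the axial slice axis from
#' the header orientation (the superior-inferior axis; falls back to the
#' third axis), and records the trainable slice range as a central fraction
#' of the stack -- the top and bottom slices of a head volume carry little
#' anatomy worth training on.
#'
#' @param path Volume file path.
#' @param maskPath Optional mask volume of identical shape.
#' @param trainableFraction Length-2 fractions (lo, hi) of the slice stack
#'   considered trainable; the default keeps the central ~24% (about 60 of
#'   256 slices).
#' @return A [VolumeRecord-class].
#' @export
loadVolume <- function(path, maskPath = NULL,
                       trainableFraction = c(0.38, 0.62)) {
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))  # strip the niftiImage class
  if (length(dim(vox)) == 4L && dim(vox)[4] == 1L)
    vox <- array(vox, dim(vox)[1:3])
  if (length(dim(vox)) != 3L)
    stop("expected a 3D volume, got dims ", paste(dim(vox), collapse = "x"),
         call. = FALSE)
  ax <- .axialAxis(img)
  n <- dim(vox)[ax]
  lo <- max(1L, as.integer(floor(n * trainableFraction[1])) + 1L)
  hi <- min(n, as.integer(ceiling(n * trainableFraction[2])))
  mask <- array(numeric(0), c(0L, 0L, 0L))
  if (!is.null(maskPath)) {
    mask <- as.array(RNifti::readNifti(maskPath))
    attributes(mask) <- list(dim = dim(mask))
    if (length(dim(mask)) == 4L && dim(mask)[4] == 1L)
      mask <- array(mask, dim(mask)[1:3])
    if (!identical(dim(mask), dim(vox)))
      stop("mask shape does not match volume shape", call. = FALSE)
  }
  new("VolumeRecord", voxels = vox, sliceAxis = ax,
      trainableRange = c(lo, hi), mask = mask)
}

#' Percentile contrast stretching
#'
#' Maps the `[pLo, pHi]` percentile window of the pixel intensities
#' linearly onto `[0, 1]`, clipping outside the window. A constant slice
#' maps to all zeros rather than erroring.
#'
#' @param slice A [GrayImage-class] or matrix.
#' @param pLo,pHi Percentiles in `[0, 100]`, `pLo < pHi`.
#' @return A unit-range [GrayImage-class].
#' @export
contrastStretch <- function(slice, pLo = 1, pHi = 99) {
  if (pLo < 0 || pHi > 100 || pLo >= pHi)
    stop("need 0 <= pLo < pHi <= 100", call. = FALSE)
  m <- .asPixelMatrix(slice)
  q <- stats::quantile(m, c(pLo, pHi) / 100, names = FALSE)
  if (q[2] <= q[1]) return(grayImage(matrix(0, nrow(m), ncol(m)), "unit"))
  grayImage(.clamp((m - q[1]) / (q[2] - q[1]), 0, 1), "unit")
}

.resizeNearest <- function(m, size) {
  ri <- pmin(nrow(m), floor((seq_len(size) - 0.5) * nrow(m) / size) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(size) - 0.5) * ncol(m) / size) + 1L)
  m[ri, ci, drop = FALSE]
}

.resizeBilinear <- function(m, size) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  out <- EBImage::resize(m, w = size, h = size, filter = "bilinear")
  matrix(as.numeric(out), size, size)
}

.extractSlice <- function(vox, axis, index) {
  switch(axis,
         vox[index, , , drop = TRUE],
         vox[, index, , drop = TRUE],
         vox[, , index, drop = TRUE])
}

#' Extract, preprocess and resize one axial slice
#'
#' Pulls a slice (by index, or a seeded random draw from the trainable
#' range), contrast-stretches it into unit range, and resizes it to a
#' square: bilinear for intensities, nearest-neighbour for the ground-truth
#' mask (which therefore stays strictly binary and is never touched by
#' intensity preprocessing).
#'
#' @param vol A [VolumeRecord-class].
#' @param index Slice index, or `NULL` for a random draw.
#' @param seed Seed for the random draw.
#' @param size Output side length (e.g. 256 for full scale, 64 for
#'   desk-scale work).
#' @param pLo,pHi Contrast-stretch percentiles.
#' @return List with `image` (unit-range [GrayImage-class]), `mask`
#'   ([BinaryMask-class] or `NULL`) and `index`.
#' @export
getSlice <- function(vol, index = NULL, seed = NULL, size = 256L,
                     pLo = 1, pHi = 99) {
  rng <- vol@trainableRange
  if (is.null(index))
    index <- withSeed(seed, sample(seq(rng[1], rng[2]), 1L))
  n <- dim(vol@voxels)[vol@sliceAxis]
  if (index < 1L || index > n)
    stop(sprintf("slice index %d out of range 1..%d", index, n), call. = FALSE)
  sl <- .extractSlice(vol@voxels, vol@sliceAxis, index)
  img <- contrastStretch(sl, pLo, pHi)
  img <- grayImage(.clamp(.resizeBilinear(img@pixels, size), 0, 1), "unit")
  mask <- NULL
  if (length(vol@mask)) {
    ms <- .extractSlice(vol@mask, vol@sliceAxis, index) > 0.5
    mask <- new("BinaryMask", values = .resizeNearest(ms, size),
                provenance = list(source = "ground-truth", index = index))
  }
  list(image = img, mask = mask, index = as.integer(index))
}

#' Preprocess a directory of volumes into a cached slice array
#'
#' Applies the full preprocessing chain (trainable-range trimming, contrast
#' stretch, resize) to every volume matching `pattern` and persists the
#' slices plus a JSON manifest of the preprocessing configuration. A later
#' call with the same configuration loads the cache; a changed configuration
#' invalidates and rebuilds it.
#'
#' @param dir Directory of `.nii` / `.nii.gz` volumes.
#' @param cacheFile Path of the cache (`.rds`; a `.json` manifest is written
#'   alongside).
#' @param pattern Regular expression selecting volume files.
#' @param excludePattern Regular expression of files to skip (e.g. masks).
#' @param size,trainableFraction,pLo,pHi Preprocessing settings (see
#'   [getSlice()] and [loadVolume()]).
#' @return List with `slices` (H x W x n array, unit range), `manifest`,
#'   and `fromCache`.
#' @export
cacheDataset <- function(dir, cacheFile,
                         pattern = "\\.nii(\\.gz)?$",
                         excludePattern = "_mask", size = 256L,
                         trainableFraction = c(0.38, 0.62),
                         pLo = 1, pHi = 99) {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (nzchar(excludePattern))
    files <- files[!grepl(excludePattern, basename(files))]
  if (length(files) == 0L) stop("no volumes found in ", dir, call. = FALSE)
  manifest <- list(files = basename(files), size = as.integer(size),
                   trainableFraction = trainableFraction,
                   pLo = pLo, pHi = pHi)
  if (file.exists(cacheFile)) {
    cached <- readRDS(cacheFile)
    if (identical(cached$manifest, manifest))
      return(list(slices = cached$slices, manifest = manifest,
                  fromCache = TRUE))
  }
  slices <- list()
  for (f in files) {
    vol <- loadVolume(f, trainableFraction = trainableFraction)
    for (idx in seq(vol@trainableRange[1], vol@trainableRange[2]))
      slices[[length(slices) + 1L]] <-
        getSlice(vol, index = idx, size = size, pLo = pLo, pHi = pHi)$image@pixels
  }
  arr <- array(unlist(slices), c(size, size, length(slices)))
  saveRDS(list(slices = arr, manifest = manifest), cacheFile)
  jsonlite::write_json(manifest, paste0(tools::file_path_sans_ext(cacheFile),
                                        "_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(slices = arr, manifest = manifest, fromCache = FALSE)
}
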