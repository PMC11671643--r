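# Synthetic phantoms: a single-class "healthy" population (a soft-edged,
# smoothly textured ellipse on a zero background -- the desk-scale analogue
# of skull-stripped axial brain slices) and anomalous variants with exact
# ground-truth masks. Every stage of the pipeline is testable against these
# with no external data.

#' Construct a phantom specification
#'
#' Defaults describe a 64 x 64 population whose shape, orientation and
#' smooth internal texture jitter slightly per sample (single-class
#' coherence), with one bright disk anomaly of radius 4-8 px and intensity
#' offset +0.4. The base intensity (0.5) and texture amplitude (0.05) are
#' chosen so the default offset keeps all pixels inside [0, 1].
#'
#' @param size Image side length.
#' @param nHealthy Default population size.
#' @param anatomy,anomaly Named lists overriding individual fields of the
#'   defaults (see [PhantomSpec-class]).
#' @param seed Master seed.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(seed = 7)
#' imgs <- genHealthy(spec, n = 3)
#' @export
phantomSpec <- function(size = 64L, nHealthy = 200L, anatomy = list(),
                        anomaly = list(), seed = 1L) {
  an <- list(semiAxisA = c(20, 25), semiAxisB = c(14, 19),
             rotation = c(-0.3, 0.3), centerJitter = 1.5,
             baseIntensity = 0.5, textureAmp = 0.05,
             textureScale = 10, edgeSoftness = 2)
  an[names(anatomy)] <- anatomy
  am <- list(radius = c(4, 8), offset = 0.4, count = 1L, edge = 0.5)
  am[names(anomaly)] <- anomaly
  new("PhantomSpec", size = as.integer(size), nHealthy = as.integer(nHealthy),
      anatomy = an, anomaly = am, seed = as.integer(seed))
}

.smoothstep <- function(x) {
  x <- .clamp(x, 0, 1)
  x * x * (3 - 2 * x)
}

# One phantom; all randomness from the current RNG stream.
.drawPhantom <- function(spec) {
  an <- spec@anatomy
  s <- spec@size
  a <- runif(1, an$semiAxisA[1], an$semiAxisA[2]) * s / 64
  b <- runif(1, an$semiAxisB[1], an$semiAxisB[2]) * s / 64
  th <- runif(1, an$rotation[1], an$rotation[2])
  cx <- (s + 1) / 2 + runif(1, -an$centerJitter, an$centerJitter)
  cy <- (s + 1) / 2 + runif(1, -an$centerJitter, an$centerJitter)
  xg <- matrix(rep(seq_len(s), each = s), s, s) - cx   # column coordinate
  yg <- matrix(rep(seq_len(s), times = s), s, s) - cy  # row coordinate
  xr <- cos(th) * xg + sin(th) * yg
  yr <- -sin(th) * xg + cos(th) * yg
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  # soft interior edge; exactly zero outside the ellipse boundary
  factor <- .smoothstep((1 - rho) * min(a, b) / an$edgeSoftness)
  tex <- matrix(0, s, s)
  for (k in 1:3) {
    wl <- runif(1, 0.7, 1.5) * an$textureScale
    ang <- runif(1, 0, 2 * pi)
    ph <- runif(1, 0, 2 * pi)
    tex <- tex + (an$textureAmp / 3) *
      cos(2 * pi / wl * (cos(ang) * xg + sin(ang) * yg) + ph)
  }
  grayImage((an$baseIntensity + tex) * factor, "unit")
}

#' Generate a healthy phantom population
#'
#' Seeded and deterministic: the same spec yields the same population.
#' Samples share global structure (pairwise correlation is high) with
#' per-sample jitter in shape, orientation and texture.
#'
#' @param spec A [PhantomSpec-class].
#' @param n Population size (default `spec@nHealthy`).
#' @return List of unit-range [GrayImage-class] objects.
#' @export
genHealthy <- function(spec, n = NULL) {
  n <- as.integer(n %||% spec@nHealthy)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  withSeed(spec@seed, lapply(seq_len(n), function(i) .drawPhantom(spec)))
}

#' Inject a disk anomaly with an exact ground-truth mask
#'
#' Adds `count` soft-rimmed disk(s) of the configured intensity offset at
#' seeded random interior locations (far enough from the boundary that the
#' disk fits). The returned mask is exact by construction: it marks
#' precisely the painted pixels, and the image is unchanged outside it.
#' A radius range of `c(0, 0)` returns the image unchanged with an empty
#' mask.
#'
#' @param healthy A unit-range [GrayImage-class] from [genHealthy()].
#' @param spec The [PhantomSpec-class] (its `anomaly` block is used).
#' @param seed Seed for placement and radius.
#' @return List with `image` ([GrayImage-class]) and `mask`
#'   ([BinaryMask-class]).
#' @export
injectAnomaly <- function(healthy, spec, seed = 1L) {
  am <- spec@anomaly
  s <- spec@size
  img <- .asPixelMatrix(healthy)
  mask <- matrix(FALSE, s, s)
  if (max(am$radius) <= 0)
    return(list(image = grayImage(img, "unit"),
                mask = new("BinaryMask", values = mask,
                           provenance = list(source = "synthetic"))))
  withSeed(seed, {
    support <- img > 0
    dmap <- EBImage::distmap(support * 1)
    for (bi in seq_len(am$count)) {
      r <- runif(1, am$radius[1], am$radius[2])
      tries <- 0L
      repeat {
        cand <- which(dmap > r + 1)
        if (length(cand)) break
        r <- r - 1
        tries <- tries + 1L
        if (r <= 0 || tries > 5L)
          stop("no interior location fits the requested anomaly radius",
               call. = FALSE)
      }
      ctr <- cand[sample.int(length(cand), 1L)]
      ci <- (ctr - 1L) %% s + 1L
      cj <- (ctr - 1L) %/% s + 1L
      dist <- sqrt(outer((seq_len(s) - ci)^2, (seq_len(s) - cj)^2, `+`))
      inside <- dist < r
      profile <- .clamp((r - dist) / max(am$edge, 1e-8), 0, 1)
      img <- img + am$offset * profile * inside
      mask <- mask | inside
    }
  })
  list(image = grayImage(.clamp(img, 0, 1), "unit"),
       mask = new("BinaryMask", values = mask,
                  provenance = list(source = "synthetic")))
}

#' Write phantom slices as NIfTI fixture volumes
#'
#' Stacks images (and optional masks) into small NIfTI volumes consumable
#' by [loadVolume()] / [getSlice()], exercising the full I/O path. Mask
#' volumes are written next to the image volumes with a `_mask` suffix.
#'
#' @param images List of [GrayImage-class] objects (equal sizes).
#' @param masks Optional list of matching [BinaryMask-class] objects.
#' @param dir Output directory (created if needed).
#' @param slicesPerVolume Slices stacked into each volume.
#' @param prefix File-name prefix.
#' @return Data.frame with columns `image` and `mask` (NA when no masks).
#' @export
writeNiftiFixture <- function(images, masks = NULL, dir,
                              slicesPerVolume = 10L, prefix = "phantom") {
  if (length(images) == 0L) stop("no images to write", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(images)
  starts <- seq(1L, n, by = slicesPerVolume)
  out <- data.frame(image = character(0), mask = character(0))
  for (v in seq_along(starts)) {
    idx <- starts[v]:min(n, starts[v] + slicesPerVolume - 1L)
    vox <- array(unlist(lapply(images[idx], .asPixelMatrix)),
                 c(dim(images[[1]])[1], dim(images[[1]])[2], length(idx)))
    ip <- file.path(dir, sprintf("%s%02d.nii.gz", prefix, v))
    RNifti::writeNifti(vox, ip)
    mp <- NA_character_
    if (!is.null(masks)) {
      mvox <- array(unlist(lapply(masks[idx], function(m) .maskValues(m) * 1)),
                    dim(vox))
      mp <- file.path(dir, sprintf("%s%02d_mask.nii.gz", prefix, v))
      RNifti::writeNifti(mvox, mp)
    }
    out <- rbind(out, data.frame(image = ip, mask = mp))
  }
  out
}
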