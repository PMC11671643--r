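# YAML configuration profiles. "full" carries the full-scale reference
# hyperparameters; "mini" is the desk-scale profile used throughout the
# test suite and the worked examples.

#' Read a configuration profile
#'
#' @param name Profile name (`"mini"` or `"full"`) or a path to a YAML
#'   file of the same structure.
#' @return Named list with blocks `diffusion`, `noise`, `model`,
#'   `training`, `segmentation`.
#' @examples
#' p <- readProfile("mini")
#' p$model$image_size
#' @export
readProfile <- function(name = "mini") {
  path <- if (file.exists(name)) name
          else system.file("extdata", "profiles", paste0(name, ".yaml"),
                           package = "diffAnomaly")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown profile: ", name, call. = FALSE)
  yaml::read_yaml(path)
}

#' Build package objects from a profile
#'
#' Convenience constructors turning profile blocks into the corresponding
#' package objects.
#'
#' @param profile A list from [readProfile()].
#' @param seed Seed for objects that carry one.
#' @return `profileSchedule`: a [ScheduleTable-class];
#'   `profileDenoiserConfig`: a [denoiserConfig()] list;
#'   `profileTrainConfig`: a [trainConfig()] list;
#'   `profileNoiseSpec`: a [NoiseSpec-class];
#'   `profilePostConfig`: a [postConfig()] list.
#' @export
profileSchedule <- function(profile) scheduleFromConfig(profile$diffusion)

#' @rdname profileSchedule
#' @export
profileDenoiserConfig <- function(profile) {
  m <- profile$model
  denoiserConfig(imageSize = m$image_size, baseChannels = m$base_channels,
                 channelMult = unlist(m$channel_mult),
                 numResBlocks = m$res_blocks,
                 attnResolutions = unlist(m$attention_resolutions),
                 numHeads = m$attention_heads, dropout = m$dropout %||% 0)
}

#' @rdname profileSchedule
#' @export
profileTrainConfig <- function(profile, seed = 1L) {
  tr <- profile$training
  trainConfig(iterations = tr$iterations, batchSize = tr$batch_size %||% 1L,
              learningRate = tr$learning_rate,
              weightDecay = tr$weight_decay %||% 0,
              adamBetas = c(tr$adam_beta1 %||% 0.9, tr$adam_beta2 %||% 0.999),
              emaDecay = tr$ema_decay,
              timesteps = profile$diffusion$timesteps, seed = seed)
}

#' @rdname profileSchedule
#' @export
profileNoiseSpec <- function(profile, seed = 1L) {
  nz <- profile$noise
  if (identical(nz$kind, "gaussian")) return(gaussianSpec(seed))
  simplexSpec(baseFrequency = nz$base_frequency %||% 2^-6,
              octaves = nz$octaves %||% 6L, decay = nz$decay %||% 0.8,
              seed = seed)
}

#' @rdname profileSchedule
#' @export
profilePostConfig <- function(profile) {
  sg <- profile$segmentation
  postConfig(kernel = sg$kernel %||% 3L, keepK = sg$keep_k %||% 1L,
             minArea = sg$min_area %||% 5L)
}
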