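# Variance schedules for the diffusion chain.

#' Linear variance schedule
#'
#' Builds the per-timestep table of \eqn{\beta_t} (linearly interpolated from
#' `betaStart` to `betaEnd`), \eqn{\alpha_t = 1 - \beta_t} and the cumulative
#' signal retention \eqn{\bar\alpha_t = \prod_{s\le t}\alpha_s}. Defaults are
#' the standard DDPM setting (T = 1000, \eqn{\beta} from 1e-4 to 0.02), under
#' which \eqn{\bar\alpha_T \approx 4\times 10^{-5}}: near-total destruction
#' of the image signal at the end of the chain.
#'
#' @param steps Chain length T (>= 1).
#' @param betaStart First variance, in (0, 1).
#' @param betaEnd Last variance, in (0, 1), `>= betaStart`.
#' @return A [ScheduleTable-class].
#' @examples
#' sched <- linearSchedule(1000, 1e-4, 0.02)
#' alphaBar(sched, 300)
#' @export
linearSchedule <- function(steps = 1000L, betaStart = 1e-4, betaEnd = 0.02) {
  steps <- as.integer(steps)
  if (length(steps) != 1L || is.na(steps) || steps < 1L)
    stop("steps must be a positive integer", call. = FALSE)
  if (betaStart <= 0 || betaEnd >= 1 || betaStart > betaEnd)
    stop("need 0 < betaStart <= betaEnd < 1", call. = FALSE)
  beta <- if (steps == 1L) betaStart else seq(betaStart, betaEnd, length.out = steps)
  alpha <- 1 - beta
  new("ScheduleTable", steps = steps, beta = beta, alpha = alpha,
      alphaBar = cumprod(alpha))
}

#' Build a schedule from a configuration block
#'
#' Accepts a named list as read from a YAML profile. Only the linear
#' schedule is implemented; `"cosine"` is a recognized-but-rejected name so
#' that configs for it fail loudly rather than silently fall back.
#'
#' @param config Named list with `schedule` (name), `timesteps`,
#'   `beta_start`, `beta_end`.
#' @return A [ScheduleTable-class].
#' @export
scheduleFromConfig <- function(config) {
  name <- tolower(config$schedule %||% "linear")
  if (name == "cosine")
    stop("the 'cosine' schedule is reserved and not implemented", call. = FALSE)
  if (name != "linear")
    stop("unknown schedule name: ", name, call. = FALSE)
  linearSchedule(config$timesteps %||% 1000L,
                 config$beta_start %||% 1e-4,
                 config$beta_end %||% 0.02)
}

#' Cumulative signal retention at a timestep
#' @param sched A [ScheduleTable-class].
#' @param t Timestep(s) in 1..T.
#' @return \eqn{\bar\alpha_t}.
#' @export
alphaBar <- function(sched, t) {
  .checkT(sched, t)
  sched@alphaBar[t]
}

.checkT <- function(sched, t) {
  if (any(t < 1L) || any(t > sched@steps))
    stop(sprintf("timestep out of range: t must lie in 1..%d", sched@steps),
         call. = FALSE)
  invisible(TRUE)
}
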