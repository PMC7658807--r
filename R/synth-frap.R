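#' Simulate a FRAP recovery trace
#'
#' Emits a fluorescence recovery after photobleaching trace with known
#' ground truth: `n_prebleach` scans at the pre-bleach level, then
#' post-bleach intensities following the single-exponential recovery
#' \deqn{F(t) = F_0 + M_f (F_{pre} - F_0)(1 - e^{-t \ln 2 / t_{1/2}})}
#' with bleach floor \eqn{F_0 = F_{pre}(1 - \mathrm{bleach\_depth})}. The
#' whole series is attenuated by `(1 - acquisition_bleach_rate)^frame_index`
#' (zero-based over all emitted frames) to mimic imaging-induced bleaching,
#' then Gaussian noise is added. Defaults mirror a typical membrane-protein
#' FRAP design: three pre-bleach scans, one frame per minute over 40 min.
#'
#' @param pre_bleach_level steady-state intensity before the bleach.
#' @param bleach_depth fraction of intensity removed by the bleach, in
#'   `(0, 1]`.
#' @param mobile_fraction recoverable fraction `Mf` in `[0, 1]`.
#' @param t_half recovery halftime in minutes (> 0).
#' @param n_prebleach number of pre-bleach scans (>= 1).
#' @param n_frames number of post-bleach frames.
#' @param frame_interval minutes between frames.
#' @param noise_sigma additive Gaussian noise, intensity units.
#' @param acquisition_bleach_rate per-frame attenuation fraction (>= 0).
#' @param seed integer seed (pure function of arguments).
#' @return A list with `trace` (a [frap_trace]; pre-bleach times are
#'   negative, the first post-bleach frame is at t = 0) and `truth`
#'   (`mobile_fraction`, `t_half`, `f0` on the normalized scale).
#' @export
make_frap_trace <- function(pre_bleach_level = 100,
                            bleach_depth = 0.7,
                            mobile_fraction = 0.7,
                            t_half = 5,
                            n_prebleach = 3,
                            n_frames = 41,
                            frame_interval = 1,
                            noise_sigma = 0,
                            acquisition_bleach_rate = 0,
                            seed = 1L) {
  if (!is_number(pre_bleach_level) || pre_bleach_level <= 0) {
    abort("'pre_bleach_level' must be positive")
  }
  if (!is_number(bleach_depth) || bleach_depth <= 0 || bleach_depth > 1) {
    abort("'bleach_depth' must lie in (0, 1]")
  }
  if (!is_number(mobile_fraction) || mobile_fraction < 0 || mobile_fraction > 1) {
    abort("'mobile_fraction' must lie in [0, 1]")
  }
  if (!is_number(t_half) || t_half <= 0) abort("'t_half' must be > 0")
  if (!is_count(n_prebleach)) abort("'n_prebleach' must be >= 1")
  if (!is_count(n_frames)) abort("'n_frames' must be >= 1")
  if (!is_number(acquisition_bleach_rate) || acquisition_bleach_rate < 0 ||
      acquisition_bleach_rate >= 1) {
    abort("'acquisition_bleach_rate' must lie in [0, 1)")
  }
  if (!is_number(noise_sigma) || noise_sigma < 0) abort("'noise_sigma' must be >= 0")

  withr::local_preserve_seed()
  set.seed(as.integer(seed))

  t_pre <- seq.int(-n_prebleach, -1L) * frame_interval
  t_post <- seq.int(0L, n_frames - 1L) * frame_interval
  f0 <- pre_bleach_level * (1 - bleach_depth)
  model_post <- f0 + mobile_fraction * (pre_bleach_level - f0) *
    (1 - exp(-t_post * log(2) / t_half))
  intensities <- c(rep(pre_bleach_level, n_prebleach), model_post)
  atten <- (1 - acquisition_bleach_rate)^(seq_along(intensities) - 1L)
  intensities <- intensities * atten +
    rnorm(length(intensities), 0, noise_sigma)

  trace <- frap_trace(times = c(t_pre, t_post), intensities = intensities,
                      n_prebleach = n_prebleach,
                      roi_diameter = 2, zone = "simulated")
  list(trace = trace,
       truth = list(mobile_fraction = mobile_fraction, t_half = t_half,
                    f0 = 1 - bleach_depth))
}
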