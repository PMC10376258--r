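# Spatial-domain (SD) features: cross-channel ratios between muscle groups
# (flexor-tagged versus extensor-tagged channels), computed once per segment
# rather than per channel. Denominators are guarded by a small epsilon and
# the ratio capped so all-quiet extensor channels still yield a finite value.

SD_RATIO_CAP <- 1e6

group_ratio <- function(window, roles, stat) {
  fl <- which(roles == "flexor")
  ex <- which(roles == "extensor")
  if (length(fl) == 0L || length(ex) == 0L)
    abort_config("spatial features need both flexor- and extensor-tagged channels")
  num <- mean(vapply(fl, function(ch) stat(window[, ch]), numeric(1)))
  den <- mean(vapply(ex, function(ch) stat(window[, ch]), numeric(1)))
  min(num / max(den, 1e-12), SD_RATIO_CAP)
}

#' Spatial (cross-channel) feature values
#'
#' Flexor-to-extensor ratios of aggregate power, MAV, RMS, waveform length
#' and SSI for one segment.
#'
#' @param window Numeric matrix (time x channels).
#' @param roles Per-channel role tags.
#' @return Named numeric vector of the five spatial ratios.
#' @export
spatial_features <- function(window, roles) {
  c(SDPR   = group_ratio(window, roles, function(x) mean(x^2)),
    SDMAVR = group_ratio(window, roles, function(x) mean(abs(x))),
    SDRMSR = group_ratio(window, roles, function(x) sqrt(mean(x^2))),
    SDWLR  = group_ratio(window, roles, function(x) sum(abs(diff(x)))),
    SDSSIR = group_ratio(window, roles, function(x) sum(x^2)))
}

feat_spatial <- function(name) {
  force(name)
  function(window, roles) unname(spatial_features(window, roles)[name])
}
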