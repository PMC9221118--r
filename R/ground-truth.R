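#' Planted arousal/valence targets for the synthetic EEG generator
#'
#' The synthetic generator plants, for each stimulus emotion, a target
#' arousal (the dimensionless beta/alpha band-power ratio summed over AF3,
#' AF4, F3, F4) and a target valence (the alpha-power difference F4 minus F3,
#' in uV^2). Targets are what the downstream feature extractor should recover
#' from the generated signal.
#'
#' The default places the four emotions on the Thayer plane in their
#' conventional quadrants: happy is high-arousal/positive-valence, angry and
#' fear are high-arousal/negative-valence, sad is low-arousal/negative-valence.
#'
#' @param happy,sad,angry,fear Length-2 numeric vectors
#'   `c(target_arousal, target_valence)`; arousal must be positive (it is a
#'   ratio of powers), valence is a signed power difference in uV^2.
#'
#' @return A tibble of class `affect_ground_truth` with columns `emotion`,
#'   `target_arousal`, `target_valence`.
#' @examples
#' affect_ground_truth()
#' @export
affect_ground_truth <- function(happy = c(2.0, 1.0),
                                sad = c(0.5, -0.5),
                                angry = c(2.5, -1.0),
                                fear = c(2.2, -0.8)) {
  vals <- list(happy = happy, sad = sad, angry = angry, fear = fear)
  for (e in names(vals)) {
    v <- vals[[e]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v))) {
      abort(sprintf("`%s` must be c(target_arousal, target_valence).", e))
    }
    if (v[1] <= 0) {
      abort(sprintf("target arousal for '%s' must be positive (power ratio).", e))
    }
  }
  out <- tibble(
    emotion = emotion_levels,
    target_arousal = unname(vapply(vals, `[`, numeric(1), 1)[emotion_levels]),
    target_valence = unname(vapply(vals, `[`, numeric(1), 2)[emotion_levels])
  )
  class(out) <- c("affect_ground_truth", class(out))
  out
}

#' Expected quadrant layout of emotions on the Thayer plane
#'
#' Sign pattern (valence sign, arousal sign) each emotion is expected to
#' occupy after normalization: happy (+, +), sad (-, -), angry (-, +),
#' fear (-, +). Used by [quadrant_agreement()].
#'
#' @return A tibble with columns `emotion`, `valence_sign`, `arousal_sign`
#'   (each sign is -1 or +1).
#' @examples
#' emotion_layout()
#' @export
emotion_layout <- function() {
  tibble(
    emotion = emotion_levels,
    valence_sign = c(1, -1, -1, -1),
    arousal_sign = c(1, -1, 1, 1)
  )
}
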