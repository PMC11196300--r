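# Controlled vocabularies and the rating-scale registry.

ROLE_LEVELS <- c("family", "friend", "romantic_partner",
                 "fellow_student_or_colleague", "acquaintance", "other")
GENDER_LEVELS <- c("female", "male", "other", "unknown")
ORIGIN_LEVELS <- c("wave1", "esm", "wave2")
MODE_LEVELS <- c("face_to_face", "video_call", "phone_call")
PROMPT_KINDS <- c("morning", "evening", "random")
AGE_BRACKETS <- c("<20", "20-29", "30-39", "40-49", "50-59", "60+")
FLAG_ITEMS <- c("gives_emotional_support", "gives_practical_support",
                "can_be_myself", "discuss_personal_issues")
ORDINAL_ITEMS <- c("closeness", "contact_freq_in_person", "contact_freq_online")

#' Rating-scale registry
#'
#' Declares the numeric range of every ordinal rating used across the
#' package: closeness and all quality/affect indicators run 0-10 (the
#' granularity of "rated 7 out of 10"), contact frequency is a 7-point
#' ordinal (0-6). Centralised so the ranges are changeable in one place.
#'
#' @return A named list of `c(min, max)` ranges keyed by item family:
#'   `closeness`, `contact_freq`, `quality`, `affect`, `company_perception`.
#' @export
#' @examples
#' scale_registry()$closeness
scale_registry <- function() {
  list(
    closeness          = c(0, 10),
    contact_freq       = c(0, 6),
    quality            = c(0, 10),
    affect             = c(0, 10),
    company_perception = c(0, 10)
  )
}

scale_range <- function(item) {
  reg <- scale_registry()
  reg[[item]] %||% stop("unknown scale item: ", item, call. = FALSE)
}
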