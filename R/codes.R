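# Controlled vocabulary of behavior codes.

.infant_codes <- c(
  "Stand (Object support)",
  "Stand (Mother help)",
  "Stand Independently",
  "Sit (Object support)",
  "Sit (Mother help)",
  "Sit Independently",
  "Lie (All)",
  "Lie Still",
  "Babble",
  "Cry",
  "Reach",
  "Crawl",
  "Play (Passive)",
  "Play (Motor-Social)",
  "Play (Object)"
)

.maternal_codes <- c(
  "Rocks/Jiggles Infant",
  "Lifts Infant",
  "Assists Locomotion",
  "Stimulates Gross Motor",
  "Shifts Infant",
  "Holds Object",
  "Points to Object",
  "Offers Object",
  "Manipulates Object",
  "Speech to Infant",
  "Affectionate Touch"
)

#' Behavior-code vocabulary
#'
#' The 26-code controlled vocabulary used for coding dyadic mother-infant
#' interaction: 15 infant codes (posture, locomotion, vocalization, reaching
#' and dyadic play frames) and 11 maternal codes (physical handling,
#' object-mediated interaction, infant-directed speech and affectionate
#' touch). The order returned here is stable and defines the default
#' variable ordering of monthly panels, and hence the default Cholesky
#' ordering used by the impulse-response machinery.
#'
#' @param role Which subset to return: `"all"` (default), `"infant"` or
#'   `"maternal"`.
#' @return Character vector of code names.
#' @examples
#' length(behavior_codes())          # 26
#' length(behavior_codes("infant"))  # 15
#' @export
behavior_codes <- function(role = c("all", "infant", "maternal")) {
  role <- match.arg(role)
  switch(role,
    all      = c(.infant_codes, .maternal_codes),
    infant   = .infant_codes,
    maternal = .maternal_codes
  )
}

#' Classify behavior codes by actor
#'
#' @param codes Character vector of code names.
#' @return Character vector, `"infant"`, `"maternal"` or `NA` for codes
#'   outside the standard vocabulary.
#' @export
code_role <- function(codes) {
  ifelse(codes %in% .infant_codes, "infant",
         ifelse(codes %in% .maternal_codes, "maternal", NA_character_))
}
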