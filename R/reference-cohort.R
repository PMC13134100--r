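#' Published accounting of the NHS Talking Therapies reference cohort
#'
#' The sample accounting of the large UK primary-care psychological-therapy
#' (NHS Talking Therapies) cohort this methodology was developed for: the
#' screening waterfall from all assessed patients down to the analysed
#' complete-case sample, the eleven ONS-based ethnic-group sizes, and the
#' gender counts.  The analysed sample is the full assessment pool minus
#' patients with missing item-level scores and minus those with missing
#' demographics.  These published counts drive the package's
#' sample-accounting checks and the unbalanced default scenario of the
#' synthetic generator; percentages should always be recomputed from the
#' counts.
#'
#' @return A list with \code{screened} (assessed, missing_items,
#'   missing_demographics), \code{group_sizes} (named integer vector, 11
#'   groups), \code{gender} (female/male counts) and \code{analysed_n}
#'   (the screening-waterfall total, 147,037).  Note the published
#'   per-group sizes sum to 146,677 — 360 fewer than the reported overall
#'   sample; the overall figure is consistent with the screening waterfall
#'   and with the gender counts, and is used as the percentage denominator.
#' @examples
#' ref <- ttad_cohort_summary()
#' ref$screened$assessed - ref$screened$missing_items -
#'   ref$screened$missing_demographics  # analysed sample size
#' @export
ttad_cohort_summary <- function() {
  group_sizes <- c(`White British` = 65138L, `White Irish` = 3994L,
                   `White other` = 29260L, Mixed = 10054L, Indian = 6602L,
                   Pakistani = 3449L, Bangladeshi = 3191L,
                   `Asian-other-or-Chinese` = 6363L,
                   `Black African` = 7458L, `Black Caribbean` = 8421L,
                   `Black other` = 2747L)
  list(screened = list(assessed = 483683L, missing_items = 316282L,
                       missing_demographics = 20364L),
       group_sizes = group_sizes,
       gender = c(female = 98926L, male = 48111L),
       analysed_n = 483683L - 316282L - 20364L)
}
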