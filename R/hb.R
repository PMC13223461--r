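# Hemoglobin gold-standard grading.

#' Class labels of the anemia gradation
#'
#' The three screening classes, in the fixed (lexicographic) order used
#' throughout the package.
#'
#' @return Character vector `c("anemic", "moderate", "normal")`.
#' @export
hb_classes <- function() c("anemic", "moderate", "normal")

#' Grade hemoglobin into the three-class anemia gradation
#'
#' Maps measured hemoglobin (g/dL, the CBC gold standard) and sex to the
#' screening label. Both sexes are anemic below 10.5 g/dL. Males are
#' moderate in the closed band 10.5-13.5 g/dL and normal above; females
#' are moderate in 10.5-12 g/dL and normal above. Boundary values belong
#' to the moderate band. The map is a total deterministic partition of the
#' plausible range.
#'
#' @param sex Character vector, `"male"` or `"female"` (recycled).
#' @param hb Numeric vector of hemoglobin values in g/dL, each in the
#'   plausibility window `(0, 25)`.
#' @return Factor with levels [hb_classes()].
#' @export
label_from_hb <- function(sex, hb) {
  n <- max(length(sex), length(hb))
  sex <- rep_len(as.character(sex), n)
  hb <- rep_len(as.numeric(hb), n)
  if (!all(sex %in% c("male", "female")))
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  if (anyNA(hb) || any(hb <= 0) || any(hb >= 25))
    stop("hemoglobin outside the plausibility window (0, 25) g/dL",
         call. = FALSE)
  upper <- ifelse(sex == "male", 13.5, 12)
  lab <- ifelse(hb < 10.5, "anemic", ifelse(hb <= upper, "moderate",
                                            "normal"))
  factor(lab, levels = hb_classes())
}

# Per class x sex hemoglobin intervals [lo, hi] used by the synthetic
# generator; boundaries consistent with label_from_hb (moderate owns its
# endpoints, so the open ends are nudged inward when sampling).
hb_intervals <- function() {
  list(
    anemic   = list(male = c(6.0, 10.5),  female = c(6.0, 10.5)),
    moderate = list(male = c(10.5, 13.5), female = c(10.5, 12.0)),
    normal   = list(male = c(13.5, 17.5), female = c(12.0, 15.5))
  )
}
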