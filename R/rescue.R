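#' Gap-normalized percent rescue
#'
#' For an event dysregulated between control and disease, percent
#' rescue measures how far a treated condition's PSI has moved back
#' toward the control value, normalized by the control-disease gap:
#' \deqn{100 \cdot \frac{\psi_{treated} - \psi_{disease}}
#'                      {\psi_{control} - \psi_{disease}}}
#' +100 is a full return to the control PSI, 0 no change, negative a
#' shift away from control. Vectorized.
#'
#' @param psi_control,psi_disease,psi_treated PSI percentages.
#' @return signed percent rescue.
#' @examples
#' percentRescue(30, 60, 36.6)  # 78
#' @export
percentRescue <- function(psi_control, psi_disease, psi_treated) {
  gap <- psi_control - psi_disease
  if (any(gap == 0, na.rm = TRUE))
    stop("degenerate gap: psi_control equals psi_disease")
  100 * (psi_treated - psi_disease) / gap
}

#' Classify therapeutic rescue of missplicing
#'
#' Four-way classification of each (control, disease, treated) PSI
#' triple, applied to events already significantly dysregulated in the
#' control-vs-disease comparison. The rules, in order and with strict
#' comparisons:
#' \enumerate{
#'   \item treated PSI absent (NA): \code{no_information};
#'   \item the treated-vs-disease shift |psi_treated - psi_disease| is
#'     at most \code{delta_min} percentage points: \code{non_rescue}
#'     (the minimum-shift gate precedes direction);
#'   \item percent rescue > \code{rescue_min}: \code{rescued};
#'   \item percent rescue < -\code{rescue_min}: \code{opposite_effect}
#'     (a shift away from the control PSI);
#'   \item otherwise \code{non_rescue}.
#' }
#'
#' @param psi_control,psi_disease,psi_treated PSI percentages in
#'   [0, 100]; \code{psi_treated} may be NA. Vectorized.
#' @param rescue_min minimum |percent rescue| (percent-rescue units,
#'   default 10).
#' @param delta_min minimum treated-vs-disease shift (PSI percentage
#'   points, default 5).
#' @return data.frame with the three PSI columns, \code{percent_rescue}
#'   (NA when treated is absent) and \code{category} (factor with
#'   levels rescued, opposite_effect, non_rescue, no_information).
#' @examples
#' classifyRescue(30, 60, 36.6)$category  # rescued
#' classifyRescue(30, 60, 70)$category    # opposite_effect
#' @export
classifyRescue <- function(psi_control, psi_disease, psi_treated,
                           rescue_min = 10, delta_min = 5) {
  n <- max(length(psi_control), length(psi_disease), length(psi_treated))
  psi_control <- rep_len(psi_control, n)
  psi_disease <- rep_len(psi_disease, n)
  psi_treated <- rep_len(psi_treated, n)
  rng <- c(psi_control, psi_disease, psi_treated)
  if (any(rng < 0 | rng > 100, na.rm = TRUE))
    stop("PSI values must lie in [0, 100]")
  if (any(psi_control == psi_disease, na.rm = TRUE))
    stop("degenerate gap: psi_control equals psi_disease; ",
         "classification applies only to dysregulated events")
  pr <- rep(NA_real_, n)
  has_t <- !is.na(psi_treated)
  pr[has_t] <- percentRescue(psi_control[has_t], psi_disease[has_t],
                             psi_treated[has_t])
  cat_ <- rep("no_information", n)
  shift <- abs(psi_treated - psi_disease)
  small <- has_t & shift <= delta_min
  cat_[small] <- "non_rescue"
  big <- has_t & !small
  cat_[big & pr > rescue_min] <- "rescued"
  cat_[big & pr < -rescue_min] <- "opposite_effect"
  cat_[big & pr >= -rescue_min & pr <= rescue_min] <- "non_rescue"
  data.frame(psi_control = psi_control, psi_disease = psi_disease,
             psi_treated = psi_treated, percent_rescue = pr,
             category = factor(cat_, levels = RESCUE_LEVELS))
}

RESCUE_LEVELS <- c("rescued", "opposite_effect", "non_rescue",
                   "no_information")

#' Count rescue categories
#'
#' @param calls a data.frame from \code{\link{classifyRescue}} (or a
#'   factor/character vector of categories).
#' @return named integer vector over the four categories; sums to the
#'   number of calls.
#' @export
rescueSummary <- function(calls) {
  cats <- if (is.data.frame(calls)) calls$category else calls
  cats <- factor(as.character(cats), levels = RESCUE_LEVELS)
  tab <- table(cats)
  stats::setNames(as.integer(tab), names(tab))
}
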