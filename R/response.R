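#' Visit closest to a target assessment time
#'
#' Follow-up visits fall on a quarterly grid, so the "12-month" assessment
#' is taken as the visit nearest to the target time; ties are broken toward
#' the earlier visit.
#'
#' @param months Visit times in months, strictly increasing.
#' @param diameter_mm Tumor diameter at each visit, mm.
#' @param target_months Target assessment time (months).
#' @return List with `months` and `diameter_mm` of the selected visit.
#' @export
nearest_assessment <- function(months, diameter_mm, target_months = 12) {
  stopifnot(length(months) >= 1, length(months) == length(diameter_mm))
  d <- abs(months - target_months)
  i <- which(d == min(d))[1]  # visits increasing, so first hit is earliest
  list(months = months[i], diameter_mm = diameter_mm[i])
}

#' Classify a longitudinal diameter series into CR/PR/SD/PD
#'
#' Response categories follow size-based response rules on the largest
#' axial tumor diameter. Complete response (CR) is declared at the first
#' visit within 12 months at which the lesion has disappeared
#' (diameter <= `cr_epsilon`), and assessment stops there. All other
#' patients are assessed at 12 months (nearest visit, earlier tie-break):
#' partial response (PR) requires a decrease in diameter of strictly more
#' than 30% from baseline; progressive disease (PD) an increase of at
#' least 20%; anything between is stable disease (SD). CR and PR form the
#' responder group, SD and PD the non-responder group. Patients with no
#' visit at or before 12 months cannot be assessed and are flagged
#' excluded.
#'
#' @param baseline_mm Baseline largest axial diameter, mm, > 0.
#' @param months Follow-up times in months, strictly increasing, in
#'   (0, 18].
#' @param diameter_mm Diameters (mm, >= 0) at each follow-up.
#' @param cr_epsilon Diameter at or below which the lesion counts as
#'   disappeared (mm); default 0.
#' @return List with `category` ("CR", "PR", "SD", "PD" or NA if
#'   excluded), `group` ("responder"/"non-responder"), `decided_at_months`
#'   and `excluded`.
#' @examples
#' classify_response(40, c(3, 6, 9, 12), c(35, 30, 27, 25))$category  # "PR"
#' @export
classify_response <- function(baseline_mm, months, diameter_mm,
                              cr_epsilon = 0) {
  if (!is.finite(baseline_mm) || baseline_mm <= 0)
    stopf("baseline_mm must be > 0")
  stopifnot(length(months) == length(diameter_mm), length(months) >= 1)
  if (any(diff(months) <= 0)) stopf("follow-up times must be strictly increasing")
  if (any(months <= 0) || any(months > 18))
    stopf("follow-up times must lie in (0, 18] months")
  if (any(!is.finite(diameter_mm)) || any(diameter_mm < 0))
    stopf("diameters must be >= 0")
  if (!any(months <= 12))
    return(list(category = NA_character_, group = NA_character_,
                decided_at_months = NA_real_, excluded = TRUE))
  cr_at <- which(months <= 12 & diameter_mm <= cr_epsilon)
  if (length(cr_at) > 0) {
    return(list(category = "CR", group = "responder",
                decided_at_months = months[cr_at[1]], excluded = FALSE))
  }
  at12 <- nearest_assessment(months, diameter_mm, 12)
  change <- (at12$diameter_mm - baseline_mm) / baseline_mm
  category <- if (change < -0.30) "PR"        # strictly more than 30% decrease
              else if (change >= 0.20) "PD"   # at least 20% increase
              else "SD"
  group <- if (category %in% c("CR", "PR")) "responder" else "non-responder"
  list(category = category, group = group,
       decided_at_months = at12$months, excluded = FALSE)
}

#' Classify every patient of a trajectory table
#'
#' @param baselines Data frame with columns `patient_id`, `baseline_mm`.
#' @param visits Data frame with columns `patient_id`, `months`,
#'   `diameter_mm` (long format).
#' @param cr_epsilon Passed to [classify_response()].
#' @return Data frame with columns `patient_id`, `category`, `group`,
#'   `decided_at_months`, `excluded`.
#' @export
classify_cohort <- function(baselines, visits, cr_epsilon = 0) {
  out <- lapply(seq_len(nrow(baselines)), function(i) {
    pid <- baselines$patient_id[i]
    v <- visits[visits$patient_id == pid, , drop = FALSE]
    v <- v[order(v$months), , drop = FALSE]
    cls <- classify_response(baselines$baseline_mm[i], v$months,
                             v$diameter_mm, cr_epsilon)
    data.frame(patient_id = pid, category = cls$category, group = cls$group,
               decided_at_months = cls$decided_at_months,
               excluded = cls$excluded)
  })
  do.call(rbind, out)
}
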