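#' Tumor volume from perpendicular caliper diameters
#'
#' Converts two perpendicular caliper diameters (mm) into a tumor volume
#' (mm^3). Two conventions are available: `"as-printed"` computes
#' `(a*b)^2 / 2`, the formula as stated in the study protocol this package
#' implements; `"conventional"` computes the standard ellipsoid
#' approximation `a * b^2 / 2`. The printed form is dimensionally anomalous
#' (mm^4) but is kept as the default for fidelity; every downstream metric
#' in this package is a ratio of volumes (RTV, TGI, RTVV), so results are
#' invariant to the convention as long as one is used throughout a study.
#'
#' @param a largest perpendicular diameter, mm.
#' @param b smallest perpendicular diameter, mm; requires `a >= b > 0`.
#' @param convention `"as-printed"` or `"conventional"`.
#' @return numeric volume(s), mm^3.
#' @examples
#' volume_from_diameters(10, 6)                  # 1800
#' volume_from_diameters(10, 6, "conventional")  # 180
#' @export
volume_from_diameters <- function(a, b,
                                  convention = c("as-printed", "conventional")) {
  convention <- match.arg(convention)
  if (length(a) != length(b))
    pdx_validation_error("diameter vectors must have equal length")
  bad <- !is.finite(a) | !is.finite(b) | b <= 0 | a < b
  if (any(bad))
    pdx_validation_error(sprintf(
      "invalid diameters at position(s) %s: need a >= b > 0",
      paste(which(bad), collapse = ", ")))
  switch(convention,
    "as-printed"   = (a * b)^2 / 2,
    "conventional" = a * b^2 / 2
  )
}

#' Construct a single-mouse tumor growth curve
#'
#' A growth curve is one mouse's ordered series of tumor volumes. Day 1 is
#' treatment initiation and must carry the first measurement; the day-1
#' volume is the baseline V1 against which relative tumor volumes (RTV) are
#' computed.
#'
#' @param mouse_id identifier.
#' @param days integer measurement days (day 1 = treatment start), strictly
#'   increasing, first element 1.
#' @param volumes tumor volumes, mm^3, strictly positive, same length as
#'   `days`.
#' @param arm_label study-arm label the mouse belongs to.
#' @param terminal_status `"alive-at-study-end"` or `"sacrificed"`.
#' @return an object of class `growth_curve`.
#' @examples
#' gc <- growth_curve("m1", c(1, 8, 15), c(100, 250, 400), "control")
#' rtv_series(gc)
#' @export
growth_curve <- function(mouse_id, days, volumes, arm_label = NA_character_,
                         terminal_status = c("alive-at-study-end",
                                             "sacrificed")) {
  terminal_status <- match.arg(terminal_status)
  if (length(days) != length(volumes) || length(days) < 1L)
    pdx_validation_error("days and volumes must be non-empty and equal length")
  if (!all(is_whole(days)) || any(days < 1))
    pdx_validation_error("days must be whole numbers >= 1")
  days <- as.integer(round(days))
  if (days[1] != 1L)
    pdx_validation_error(sprintf(
      "curve '%s': first measurement must be on day 1 (treatment initiation)",
      mouse_id))
  if (any(diff(days) <= 0))
    pdx_validation_error(sprintf("curve '%s': days must be strictly increasing",
                                 mouse_id))
  if (!all(is.finite(volumes)) || any(volumes <= 0))
    pdx_validation_error(sprintf("curve '%s': volumes must be positive",
                                 mouse_id))
  structure(list(
    mouse_id = as.character(mouse_id),
    arm_label = as.character(arm_label),
    days = days,
    volumes = as.numeric(volumes),
    baseline_volume = as.numeric(volumes[1]),
    terminal_status = terminal_status
  ), class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> mouse %s (arm %s), %d measurements, days %d-%d, %s\n",
              x$mouse_id, x$arm_label, length(x$days), min(x$days),
              max(x$days), x$terminal_status))
  invisible(x)
}

#' Relative tumor volume series
#'
#' RTV on day x is `V_x / V_1`, the volume normalized to the day-1 baseline,
#' so every curve has RTV exactly 1 on day 1.
#'
#' @param curve a [growth_curve()].
#' @return data.frame with columns `day`, `rtv`.
#' @export
rtv_series <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  data.frame(day = curve$days, rtv = curve$volumes / curve$baseline_volume)
}

# RTV of one curve at a given day; NA if the mouse was not measured then.
rtv_at <- function(curve, day) {
  i <- match(day, curve$days)
  if (is.na(i)) NA_real_ else curve$volumes[i] / curve$baseline_volume
}

#' Construct a study arm
#'
#' @param name arm name (e.g. `"control"`, `"palbociclib"`).
#' @param curves list of [growth_curve()] objects; curves with an `NA` arm
#'   label are stamped with `name`, any other label must match `name`.
#' @return an object of class `study_arm`.
#' @export
study_arm <- function(name, curves) {
  if (length(curves) < 1L)
    pdx_validation_error(sprintf("arm '%s' must contain at least one curve", name))
  curves <- lapply(curves, function(gc) {
    stopifnot(inherits(gc, "growth_curve"))
    if (is.na(gc$arm_label)) gc$arm_label <- as.character(name)
    if (!identical(gc$arm_label, as.character(name)))
      pdx_validation_error(sprintf(
        "curve '%s' labelled '%s' cannot join arm '%s'",
        gc$mouse_id, gc$arm_label, name))
    gc
  })
  ids <- vapply(curves, `[[`, "", "mouse_id")
  if (anyDuplicated(ids))
    pdx_validation_error(sprintf("arm '%s': duplicate mouse ids: %s", name,
                                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  structure(list(name = as.character(name),
                 treatment_label = as.character(name),
                 curves = curves),
            class = "study_arm")
}

#' @export
print.study_arm <- function(x, ...) {
  cat(sprintf("<study_arm> %s: %d mice\n", x$name, length(x$curves)))
  invisible(x)
}

#' Assemble arms into a study
#'
#' @param arms list of [study_arm()] objects.
#' @param control name of the control arm (default `"control"` if present,
#'   otherwise the first arm).
#' @return an object of class `pdx_study`.
#' @export
pdx_study <- function(arms, control = NULL) {
  if (length(arms) < 1L) pdx_validation_error("a study needs at least one arm")
  stopifnot(all(vapply(arms, inherits, TRUE, "study_arm")))
  names(arms) <- vapply(arms, `[[`, "", "name")
  if (anyDuplicated(names(arms)))
    pdx_validation_error("duplicate arm names")
  if (is.null(control))
    control <- if ("control" %in% names(arms)) "control" else names(arms)[1]
  if (!control %in% names(arms))
    pdx_validation_error(sprintf("control arm '%s' not found", control))
  structure(list(arms = arms, control = control), class = "pdx_study")
}

#' @export
print.pdx_study <- function(x, ...) {
  cat(sprintf("<pdx_study> %d arms (control = %s)\n", length(x$arms), x$control))
  for (a in x$arms) print(a)
  invisible(x)
}

# days at which >= min_n curves of the arm were measured
evaluable_days <- function(arm, min_n = 1L) {
  tab <- table(unlist(lapply(arm$curves, `[[`, "days")))
  as.integer(names(tab)[tab >= min_n])
}

#' Median RTV of an arm at a given day
#'
#' Median over the mice measured on that day; with an even count, the
#' arithmetic mean of the two central values.
#'
#' @param arm a [study_arm()].
#' @param day measurement day.
#' @return unitless median RTV.
#' @export
median_rtv <- function(arm, day) {
  stopifnot(inherits(arm, "study_arm"))
  r <- vapply(arm$curves, rtv_at, 0, day = day)
  r <- r[!is.na(r)]
  if (length(r) == 0L)
    pdx_not_evaluable(sprintf("arm '%s': no mouse measured on day %d",
                              arm$name, as.integer(day)))
  median(r)
}

#' Tumor growth inhibition series
#'
#' TGI on day d is `100 - 100 * RTVt / RTVc`, where `RTVt` and `RTVc` are
#' the median RTVs of the treated and control arms on that day. A TGI of at
#' least 50% is flagged as a biologically meaningful effect. Days enter the
#' series only when both arms have at least `min_n` measured mice (medians
#' of near-empty arms are unstable).
#'
#' @param treated,control [study_arm()] objects.
#' @param min_n minimum measured mice per arm per evaluable day (default 2).
#' @return data.frame with columns `day`, `rtv_treated_median`,
#'   `rtv_control_median`, `tgi_percent`, `meaningful`.
#' @export
tgi_series <- function(treated, control, min_n = 2L) {
  stopifnot(inherits(treated, "study_arm"), inherits(control, "study_arm"))
  days <- intersect(evaluable_days(treated, min_n),
                    evaluable_days(control, min_n))
  if (length(days) == 0L)
    pdx_not_evaluable(sprintf(
      "arms '%s' and '%s' share no day with >= %d measured mice each",
      treated$name, control$name, min_n))
  days <- sort(days)
  rt <- vapply(days, function(d) median_rtv(treated, d), 0)
  rc <- vapply(days, function(d) median_rtv(control, d), 0)
  tgi <- 100 - 100 * rt / rc
  data.frame(day = days,
             rtv_treated_median = rt,
             rtv_control_median = rc,
             tgi_percent = tgi,
             meaningful = tgi >= 50)
}

#' Optimal (maximal) TGI over the study
#'
#' Returns the row of [tgi_series()] with the largest TGI; ties go to the
#' earliest day.
#'
#' @inheritParams tgi_series
#' @return one-row data.frame as in [tgi_series()].
#' @export
optimal_tgi <- function(treated, control, min_n = 2L) {
  ser <- tgi_series(treated, control, min_n = min_n)
  ser[which.max(ser$tgi_percent), , drop = FALSE]
}

# Last day shared by (any mouse of) both arms; the default "end of
# treatment" for response classification.
last_common_day <- function(arm_a, arm_b, min_n = 1L) {
  days <- intersect(evaluable_days(arm_a, min_n), evaluable_days(arm_b, min_n))
  if (length(days) == 0L)
    pdx_not_evaluable(sprintf("arms '%s' and '%s' share no measurement day",
                              arm_a$name, arm_b$name))
  max(days)
}

#' Classify one mouse's response (RTVV / ORR)
#'
#' The relative tumor variation RTVV of a treated mouse is its RTV divided
#' by the control arm's median RTV at the end of treatment; the per-mouse
#' overall response rate is `ORR = RTVV - 1`, and the mouse is a responder
#' when ORR is strictly below -0.5 (i.e. its tumor reached less than half
#' the typical control RTV). A mouse sacrificed before `evaluation_day`
#' contributes its last recorded RTV and is flagged `carried_forward`.
#'
#' @param curve the treated mouse's [growth_curve()].
#' @param control the control [study_arm()].
#' @param evaluation_day end-of-treatment day at which RTVs are compared.
#' @return one-row data.frame: `mouse_id`, `arm`, `evaluation_day`, `rtv`,
#'   `rtvv`, `orr`, `responder`, `carried_forward`.
#' @export
classify_response <- function(curve, control, evaluation_day) {
  stopifnot(inherits(curve, "growth_curve"), inherits(control, "study_arm"))
  mrtvc <- median_rtv(control, evaluation_day)
  if (mrtvc == 0)
    pdx_not_evaluable("control median RTV is zero; RTVV undefined")
  r <- rtv_at(curve, evaluation_day)
  carried <- is.na(r)
  if (carried) {
    ser <- rtv_series(curve)
    ser <- ser[ser$day <= evaluation_day, , drop = FALSE]
    if (nrow(ser) == 0L)
      pdx_not_evaluable(sprintf(
        "mouse '%s' has no measurement on or before day %d",
        curve$mouse_id, as.integer(evaluation_day)))
    r <- ser$rtv[nrow(ser)]
  }
  rtvv <- r / mrtvc
  data.frame(mouse_id = curve$mouse_id,
             arm = curve$arm_label,
             evaluation_day = as.integer(evaluation_day),
             rtv = r,
             rtvv = rtvv,
             orr = rtvv - 1,
             responder = (rtvv - 1) < -0.5,
             carried_forward = carried)
}

#' Classify every mouse of a treated arm
#'
#' @param arm treated [study_arm()].
#' @param control control [study_arm()].
#' @param evaluation_day defaults to the last measurement day shared by the
#'   two arms.
#' @return data.frame of [classify_response()] rows, one per mouse.
#' @export
classify_arm_responses <- function(arm, control, evaluation_day = NULL) {
  if (is.null(evaluation_day))
    evaluation_day <- last_common_day(arm, control)
  do.call(rbind, lapply(arm$curves, classify_response,
                        control = control, evaluation_day = evaluation_day))
}

#' Responder contingency table across treated arms
#'
#' Counts responders (ORR < -0.5) and non-responders per treated arm and
#' reports the responder fraction as a percentage rounded half-up to one
#' decimal.
#'
#' @param arms list of treated [study_arm()] objects.
#' @param control control [study_arm()].
#' @param evaluation_day optional fixed evaluation day; default per arm is
#'   its last day in common with the control arm.
#' @return data.frame: `arm`, `responders`, `non_responders`, `n`,
#'   `responder_pct`; the per-mouse records are attached as attribute
#'   `"responses"`.
#' @export
orr_table <- function(arms, control, evaluation_day = NULL) {
  if (length(arms) == 0L) pdx_validation_error("no treated arms supplied")
  if (inherits(arms, "study_arm")) arms <- list(arms)
  resp <- do.call(rbind, lapply(arms, classify_arm_responses,
                                control = control,
                                evaluation_day = evaluation_day))
  tab <- do.call(rbind, lapply(split(resp, resp$arm), function(d) {
    data.frame(arm = d$arm[1],
               responders = sum(d$responder),
               non_responders = sum(!d$responder),
               n = nrow(d),
               responder_pct = round_half_up(100 * mean(d$responder), 1))
  }))
  # preserve the supplied arm order
  tab <- tab[match(vapply(arms, `[[`, "", "name"), tab$arm), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "responses") <- resp
  tab
}

#' Extract a 2x2 responder table for two arms
#'
#' @param tab output of [orr_table()].
#' @param arm_a,arm_b arm names to compare.
#' @return 2x2 integer matrix, rows = arms, columns = responders /
#'   non-responders, suitable for [fisher_exact()] / [compare_orr()].
#' @export
orr_matrix <- function(tab, arm_a, arm_b) {
  ia <- match(arm_a, tab$arm); ib <- match(arm_b, tab$arm)
  if (is.na(ia) || is.na(ib))
    pdx_validation_error("arm not present in ORR table")
  m <- rbind(as.integer(c(tab$responders[ia], tab$non_responders[ia])),
             as.integer(c(tab$responders[ib], tab$non_responders[ib])))
  dimnames(m) <- list(c(arm_a, arm_b), c("responders", "non_responders"))
  m
}
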