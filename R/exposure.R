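#' Construct the parental attained-age exposure
#'
#' Joins each index person to their parents and computes maternal,
#' paternal, and mean parental attained age.  The analysis exposure is the
#' arithmetic mean of the two parents' attained ages by default; the
#' maternal-only and paternal-only variants support the corresponding
#' sensitivity analyses.
#'
#' @param persons,parents tables after [apply_exclusions()].
#' @param variant which attained age is used as the exposure.
#' @return A data.frame with `person_id`, `maternal_attained_age`,
#'   `paternal_attained_age`, `mean_parental_attained_age`, `exposure`.
#' @export
build_exposure <- function(persons, parents,
                           variant = c("mean", "maternal", "paternal")) {
  variant <- match.arg(variant)
  att <- attained_age(parents$death_age, parents$alive_at_admin,
                      parents$attained_age)
  im <- match(persons$mother_id, parents$id)
  ip <- match(persons$father_id, parents$id)
  if (anyNA(im) || anyNA(ip)) {
    stop_parage("persons reference parents absent from the parent table")
  }
  out <- data.frame(
    person_id = persons$id,
    maternal_attained_age = att[im],
    paternal_attained_age = att[ip]
  )
  out$mean_parental_attained_age <-
    (out$maternal_attained_age + out$paternal_attained_age) / 2
  out$exposure <- switch(variant,
                         mean = out$mean_parental_attained_age,
                         maternal = out$maternal_attained_age,
                         paternal = out$paternal_attained_age)
  attr(out, "variant") <- variant
  out
}

#' Assign exposure quartiles
#'
#' Divides an exposure into four groups, either at supplied boundaries or
#' at the empirical quartiles of the data at hand.  Intervals are
#' lower-open / upper-closed, with Q1 closed at its minimum, so a value
#' exactly on a printed boundary (e.g. 76.5 on the Q1/Q2 boundary) falls
#' in the lower quartile.
#'
#' @param x numeric exposure values.
#' @param boundaries either `NULL` (derive the three empirical quartile
#'   cut points from `x`), a length-3 vector of inner cut points, or a
#'   length-5 vector including outer bounds.  With outer bounds, values
#'   outside them are assigned to the nearest extreme quartile with a
#'   warning.
#' @return Factor with levels `Q1`-`Q4` and attribute `"boundaries"` (the
#'   inner cut points).
#' @export
#' @examples
#' assign_quartiles(c(60, 76.5, 80, 90), boundaries = c(76.5, 82, 86.9))
assign_quartiles <- function(x, boundaries = NULL) {
  if (is.null(boundaries)) {
    inner <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                    na.rm = FALSE))
  } else if (length(boundaries) == 3L) {
    inner <- boundaries
  } else if (length(boundaries) == 5L) {
    inner <- boundaries[2:4]
    if (any(x < boundaries[1] | x > boundaries[5])) {
      warning("exposure outside the quartile bounds; assigned to the ",
              "nearest extreme quartile")
    }
  } else {
    stop_parage("boundaries must be NULL or of length 3 or 5")
  }
  if (any(diff(inner) <= 0)) stop_parage("boundaries must be strictly increasing")
  q <- cut(x, breaks = c(-Inf, inner, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  attr(q, "boundaries") <- inner
  q
}
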