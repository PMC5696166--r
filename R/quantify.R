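# Direct quantification formulas used on gamma-counter and imaging data.

#' Percent injected dose per gram
#'
#' Converts raw gamma-counter counts into %ID/g by comparison with a counting
#' standard representing 100% of the injected dose, normalised by sample mass.
#' The result is independent of counter efficiency as long as sample and
#' standard are counted on the same instrument and geometry.
#'
#' @param sample_counts counts in the tissue sample (same units as standard).
#' @param standard_counts counts corresponding to 100% of the injected dose.
#' @param mass_g sample mass in grams.
#' @return %ID/g (vectorised).
#' @export
#' @examples
#' percent_id_per_gram(5000, 1e5, 0.5) # 10
percent_id_per_gram <- function(sample_counts, standard_counts, mass_g) {
  assert_nonnegative(sample_counts, "sample_counts")
  assert_positive(standard_counts, "standard_counts")
  assert_positive(mass_g, "mass_g")
  (sample_counts / standard_counts) * 100 / mass_g
}

#' Tumor-to-background ratio
#'
#' Contrast metric of targeting: tumor uptake divided by a background tissue's
#' uptake (blood or muscle), both in %ID/g. Summaries report both the
#' per-animal mean of ratios and the ratio of group means; see
#' [summarize_study()].
#'
#' @param tumor tumor uptake, %ID/g.
#' @param background background uptake, %ID/g; must be positive.
#' @return ratio (vectorised).
#' @export
tumor_to_background <- function(tumor, background) {
  assert_nonnegative(tumor, "tumor")
  assert_positive(background, "background")
  tumor / background
}

#' Remaining uptake under receptor blocking
#'
#' Percentage of target uptake remaining when excess unlabeled antibody is
#' pre-administered ("reduced to X%" convention): `blocked / unblocked * 100`.
#'
#' @param unblocked uptake without blocking, %ID/g; must be positive.
#' @param blocked uptake in the blocking arm, %ID/g.
#' @return remaining uptake in percent.
#' @export
#' @examples
#' blocking_fraction(100, 50) # 50
blocking_fraction <- function(unblocked, blocked) {
  assert_positive(unblocked, "unblocked")
  assert_nonnegative(blocked, "blocked")
  blocked / unblocked * 100
}

#' Specific cell-bound radioactivity percentage
#'
#' `(total bound - nonspecific) / applied * 100`. Negative specific binding
#' (nonspecific exceeding total) signals an assay problem; it is reported
#' as-is with a warning rather than clamped, so raw evidence is preserved.
#'
#' @param total_bound total cell-bound counts.
#' @param nonspecific counts bound in the presence of excess cold antibody.
#' @param applied total applied counts; must be positive.
#' @return percent bound (vectorised).
#' @export
cell_bound_percent <- function(total_bound, nonspecific, applied) {
  assert_nonnegative(total_bound, "total_bound")
  assert_nonnegative(nonspecific, "nonspecific")
  assert_positive(applied, "applied")
  out <- (total_bound - nonspecific) / applied * 100
  if (any(out < 0)) {
    warning("negative specific binding: nonspecific exceeds total bound; ",
            "reporting the raw value", call. = FALSE)
  }
  out
}

#' Caliper tumor volume
#'
#' Standard ellipsoid approximation `long * short^2 / 2` in mm^3.
#'
#' @param long_mm long diameter, mm.
#' @param short_mm short diameter, mm.
#' @return volume in mm^3 (vectorised).
#' @export
#' @examples
#' tumor_volume(10, 10) # 500
tumor_volume <- function(long_mm, short_mm) {
  assert_positive(long_mm, "long_mm")
  assert_positive(short_mm, "short_mm")
  if (any(long_mm < short_mm)) {
    warning("long diameter smaller than short diameter; check caliper axes",
            call. = FALSE)
  }
  long_mm * short_mm^2 / 2
}

#' Standardized uptake value
#'
#' `SUV = tissue concentration * body weight / injected activity`, with
#' concentration and injected activity in the same activity units and body
#' weight in grams. Equivalently `(%ID/g) / 100 * body weight (g)`.
#'
#' @param tissue_concentration activity per gram of tissue.
#' @param injected_activity injected activity, same units.
#' @param body_weight_g body weight in grams.
#' @return dimensionless SUV.
#' @export
#' @examples
#' suv(0.05, 1, 20) # 1.0 : 5 %ID/g in a 20-g mouse
suv <- function(tissue_concentration, injected_activity, body_weight_g) {
  assert_nonnegative(tissue_concentration, "tissue_concentration")
  assert_positive(injected_activity, "injected_activity")
  assert_positive(body_weight_g, "body_weight_g")
  tissue_concentration * body_weight_g / injected_activity
}
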