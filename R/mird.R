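# MIRD-schema absorbed dose calculation: D(target) = sum_src tau_src * S(target<-src).

#' Self-dose S value from local energy deposition
#'
#' Default S value when no phantom S-value matrix is supplied: all
#' non-penetrating (electron/beta) energy is absorbed in the source region
#' itself, photons escape. With 1 MBq h = 3.6e9 decays,
#'
#' `S_self = 3.6e9 * E_np(keV) * 1.602e-16 J/keV / m(kg)` in Gy/(MBq h),
#'
#' reported in mGy/(MBq h). This is the dominant dose term for a pure
#' beta-emitter such as Lu-177; cross-organ photon dose requires an S matrix
#' (see [read_s_matrix()]) and its absence is flagged in every report.
#'
#' @param nuclide a [nuclide_spec()].
#' @param organ_mass_g region mass in grams (vectorised).
#' @return S value(s) in mGy/(MBq h).
#' @export
#' @examples
#' # 1000 keV per decay in 1 g: 576.7 mGy/(MBq h)
#' self_dose_factor(nuclide_spec("x", 10, 1000), 1)
self_dose_factor <- function(nuclide, organ_mass_g) {
  stopifnot(inherits(nuclide, "nuclide_spec"))
  assert_positive(organ_mass_g, "organ_mass_g")
  joules_per_mbqh <- 3.6e9 * nuclide$mean_np_kev * 1.602e-16
  gy <- joules_per_mbqh / (organ_mass_g * 1e-3)
  gy * 1e3
}

#' Read an S-value matrix from delimited text
#'
#' Layout: columns `target`, `source`, `s_mGy_per_MBq_h`; optional header
#' directives `# phantom:` and `# nuclide:`. Every source must carry a
#' self-dose (diagonal) entry.
#'
#' @param path file path.
#' @return object of class `s_matrix`: list with `s` (data.frame), `phantom`,
#'   `nuclide_name`.
#' @export
read_s_matrix <- function(path) {
  if (!file.exists(path)) {
    abort_mirdose(sprintf("S-matrix file not found: %s", path),
                  class = "mirdose_config_error")
  }
  meta <- parse_header_meta(path)
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("target", "source", "s_mGy_per_MBq_h") %in% names(tab))) {
    abort_mirdose("S-matrix needs columns target, source, s_mGy_per_MBq_h",
                  class = "mirdose_schema_error")
  }
  tab$target <- canonical_organ_label(tab$target)
  tab$source <- canonical_organ_label(tab$source)
  if (any(tab$s_mGy_per_MBq_h < 0)) {
    abort_mirdose("S values must be non-negative",
                  class = "mirdose_schema_error")
  }
  for (src in unique(tab$source)) {
    if (!any(tab$target == src & tab$source == src)) {
      abort_mirdose(sprintf("missing self-dose entry for source '%s'", src),
                    class = "mirdose_dosimetry_error")
    }
  }
  structure(list(s = tab, phantom = meta$phantom %||% "unspecified",
                 nuclide_name = meta$nuclide %||% "unspecified"),
            class = "s_matrix")
}

#' Organ absorbed doses from residence times
#'
#' MIRD schema: `D(target) = sum_source tau(source) * S(target <- source)`,
#' linear in the residence times. With the default self-dose engine each
#' organ receives only its own non-penetrating emissions
#' ([self_dose_factor()] at the phantom organ mass); supplying an `s_matrix`
#' activates full cross-organ dosimetry and includes the remainder if the
#' matrix lists a `remainder` source. The whole-body dose is computed from
#' total retention via [whole_body_dose()] in either mode.
#'
#' @param residence a [extrapolate_residence_times()] result.
#' @param phantom a [human_phantom()] (masses for the self-dose engine).
#' @param s_matrix optional [read_s_matrix()] result.
#' @return object of class `dose_report`: list with `doses` (data.frame
#'   `organ`, `mGy_per_MBq`, `rad_per_mCi`), `whole_body_mGy_per_MBq`,
#'   `engine`, `nuclide`, `notes`.
#' @export
organ_doses <- function(residence, phantom, s_matrix = NULL) {
  stopifnot(inherits(residence, "residence_time_set"),
            inherits(phantom, "human_phantom"))
  nuc <- residence$nuclide
  tau <- residence$times
  if (any(tau < 0)) abort_mirdose("residence times must be non-negative")

  if (is.null(s_matrix)) {
    engine <- "self-dose (local electron deposition; photon cross-dose not included)"
    missing_mass <- setdiff(names(tau), names(phantom$organ_masses))
    if (length(missing_mass)) {
      abort_mirdose(sprintf("no phantom mass for organ(s): %s",
                            paste(missing_mass, collapse = ", ")),
                    class = "mirdose_dosimetry_error")
    }
    d <- vapply(names(tau), function(o) {
      tau[[o]] * self_dose_factor(nuc, phantom$organ_masses[[o]])
    }, numeric(1))
  } else {
    engine <- sprintf("S-matrix (%s phantom, %s)", s_matrix$phantom,
                      s_matrix$nuclide_name)
    s <- s_matrix$s
    sources <- c(names(tau),
                 if (residence$remainder_h > 0) "remainder")
    tau_all <- c(tau, if (residence$remainder_h > 0)
      stats::setNames(residence$remainder_h, "remainder"))
    known <- intersect(sources, unique(s$source))
    dropped <- setdiff(sources, known)
    if (length(dropped)) {
      warning("source(s) absent from S matrix dropped: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    targets <- unique(s$target)
    d <- vapply(targets, function(tg) {
      rows <- s[s$target == tg & s$source %in% known, ]
      sum(rows$s_mGy_per_MBq_h * tau_all[rows$source])
    }, numeric(1))
  }

  wb <- whole_body_dose(residence, nuc, phantom$body_mass_kg)
  doses <- data.frame(organ = names(d), mGy_per_MBq = unname(d),
                      rad_per_mCi = unname(d) * 3.7)
  doses <- doses[order(doses$organ), ]
  rownames(doses) <- NULL
  structure(
    list(doses = doses, whole_body_mGy_per_MBq = wb,
         whole_body_rad_per_mCi = wb * 3.7, engine = engine,
         nuclide = nuc$name),
    class = "dose_report"
  )
}

#' Whole-body absorbed dose
#'
#' Total non-penetrating energy emitted over all decays in the body, divided
#' by body mass: `D_wb = tau_total * S_self(nuclide, body mass)` in mGy/MBq.
#' Uses the residence-time total (organ sum plus remainder); if the set has
#' no remainder accounting the organ sum alone is used with a warning.
#'
#' @param residence a `residence_time_set`, or a single total residence time
#'   in hours.
#' @param nuclide a [nuclide_spec()].
#' @param body_mass_kg body mass in kg.
#' @return dose in mGy/MBq.
#' @export
whole_body_dose <- function(residence, nuclide, body_mass_kg = 70) {
  assert_positive(body_mass_kg, "body_mass_kg")
  tau_total <- if (inherits(residence, "residence_time_set")) {
    if (is.null(residence$remainder_h)) {
      warning("no remainder accounting; whole-body dose over listed sources only",
              call. = FALSE)
      sum(residence$times)
    } else {
      sum(residence$times) + residence$remainder_h
    }
  } else {
    assert_nonnegative(residence, "residence")
    residence
  }
  tau_total * self_dose_factor(nuclide, body_mass_kg * 1e3)
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> %s | engine: %s\n", x$nuclide, x$engine))
  print(x$doses, digits = 4, row.names = FALSE)
  cat(sprintf("whole body: %.4g mGy/MBq (%.4g rad/mCi)\n",
              x$whole_body_mGy_per_MBq, x$whole_body_rad_per_mCi))
  invisible(x)
}

#' Write a dose report as delimited text
#'
#' Organ rows with `mGy/MBq` and `rad/mCi` columns and a whole-body row,
#' preceded by a header stating the dose engine (and, for the self-dose
#' engine, the omission of photon cross-dose).
#'
#' @param report a [organ_doses()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dose_report <- function(report, path) {
  stopifnot(inherits(report, "dose_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# nuclide: %s", report$nuclide),
               sprintf("# engine: %s", report$engine)), con)
  out <- rbind(report$doses,
               data.frame(organ = "whole_body",
                          mGy_per_MBq = report$whole_body_mGy_per_MBq,
                          rad_per_mCi = report$whole_body_rad_per_mCi))
  out$mGy_per_MBq <- sprintf("%.4E", out$mGy_per_MBq)
  out$rad_per_mCi <- sprintf("%.4E", out$rad_per_mCi)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
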