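#' Radionuclide physical constants
#'
#' A `nuclide_spec` bundles the physical-decay and emission constants the
#' dosimetry chain needs: half-life, the mean non-penetrating (electron/beta)
#' energy emitted per decay, and the principal photon lines. Photons are
#' carried for reporting but ignored by the default local-energy-deposition
#' dose engine.
#'
#' @param name short label, e.g. "lu177".
#' @param half_life_h physical half-life in hours; must be positive.
#' @param mean_np_kev mean non-penetrating (electron + beta) energy per decay
#'   in keV; must be non-negative.
#' @param photons optional data.frame with columns `energy_kev` and
#'   `yield` (per decay, in \[0, 1\]).
#' @return an object of class `nuclide_spec`.
#' @export
#' @examples
#' lu <- nuclide_spec("lu177", half_life_h = 159.528, mean_np_kev = 147.9)
#' decay_factor(lu, 159.528) # 0.5
nuclide_spec <- function(name, half_life_h, mean_np_kev,
                         photons = NULL) {
  assert_positive(half_life_h, "half_life_h")
  assert_nonnegative(mean_np_kev, "mean_np_kev")
  if (is.null(photons)) {
    photons <- data.frame(energy_kev = numeric(0), yield = numeric(0))
  }
  stopifnot(is.data.frame(photons),
            all(c("energy_kev", "yield") %in% names(photons)))
  if (nrow(photons) && (any(photons$yield < 0) || any(photons$yield > 1))) {
    abort_mirdose("photon yields must lie in [0, 1]")
  }
  structure(
    list(name = name, half_life_h = half_life_h,
         mean_np_kev = mean_np_kev, photons = photons,
         lambda_phys = LN2 / half_life_h),
    class = "nuclide_spec"
  )
}

#' Load a packaged radionuclide
#'
#' Reads the nuclide constants shipped with the package
#' (`inst/extdata/nuclides.tsv`; see that file's header for the decay-data
#' compilation the values are taken from). Currently packaged: `"lu177"`
#' (T1/2 = 6.647 d) and `"cu64"` (T1/2 = 12.701 h).
#'
#' @param name nuclide label, case-insensitive.
#' @param path optional path to an alternative constants table with the same
#'   columns.
#' @return a [nuclide_spec()].
#' @export
#' @examples
#' nuclide("lu177")$half_life_h # 159.528
nuclide <- function(name, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nuclides.tsv", package = "mirdose")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  hit <- tab[tolower(tab$name) == tolower(name), , drop = FALSE]
  if (nrow(hit) != 1) {
    abort_mirdose(sprintf("unknown nuclide '%s'; packaged: %s", name,
                          paste(tab$name, collapse = ", ")),
                  class = "mirdose_config_error")
  }
  photons <- parse_photon_field(hit$photons)
  nuclide_spec(hit$name, hit$half_life_h, hit$mean_np_kev, photons)
}

# "208.366:0.1038;112.95:0.0620" -> data.frame(energy_kev, yield)
parse_photon_field <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(data.frame(energy_kev = numeric(0), yield = numeric(0)))
  }
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  mat <- do.call(rbind, lapply(parts, function(p) {
    as.numeric(strsplit(p, ":", fixed = TRUE)[[1]])
  }))
  data.frame(energy_kev = mat[, 1], yield = mat[, 2])
}

#' Physical decay factor
#'
#' Fraction of activity remaining after `t_h` hours of physical decay,
#' `exp(-ln2 * t / T1/2)`. Decay-correcting a raw measurement back to
#' injection time divides by this factor.
#'
#' @param nuclide a [nuclide_spec()].
#' @param t_h time since injection in hours; must be >= 0 (vectorised).
#' @return numeric vector of fractions in (0, 1].
#' @export
decay_factor <- function(nuclide, t_h) {
  stopifnot(inherits(nuclide, "nuclide_spec"))
  if (any(!is.finite(t_h)) || any(t_h < 0)) {
    abort_mirdose("`t_h` must be non-negative")
  }
  exp(-nuclide$lambda_phys * t_h)
}

#' @export
print.nuclide_spec <- function(x, ...) {
  cat(sprintf("<nuclide_spec> %s: T1/2 = %.4g h, mean e- energy = %.4g keV, %d photon line(s)\n",
              x$name, x$half_life_h, x$mean_np_kev, nrow(x$photons)))
  invisible(x)
}
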