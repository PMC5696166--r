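# Biodistribution study container, file I/O and summary tables.

#' Build a biodistribution study
#'
#' The central data object: one row per (organ, animal, timepoint) with the
#' tissue mass and the decay-corrected %ID/g. Values may be supplied directly
#' (`pidg` column) or as raw counts (`counts` column) together with
#' `standard_counts`, in which case [percent_id_per_gram()] is applied.
#'
#' @param samples data.frame with columns `organ`, `animal_id`, `time_h`,
#'   `mass_g` (NA allowed when `pidg` is given) and one of `pidg` or `counts`.
#' @param nuclide a [nuclide_spec()] or packaged nuclide name.
#' @param injected_mbq injected activity per animal in MBq.
#' @param decay_corrected logical flag: are the stored %ID/g values corrected
#'   back to injection time? The dosimetry stages reintroduce physical decay
#'   explicitly, so this is `TRUE` in normal use (gamma counters apply the
#'   correction at read-out).
#' @param arm study arm, `"baseline"` or `"blocking"`.
#' @param injected_ug optional injected antibody mass in micrograms.
#' @param standard_counts counts equivalent to 100% of the injected dose;
#'   required when `samples` carries `counts` instead of `pidg`.
#' @return object of class `biodist_study`.
#' @export
biodist_study <- function(samples, nuclide, injected_mbq = NA_real_,
                          decay_corrected = TRUE, arm = "baseline",
                          injected_ug = NULL, standard_counts = NULL) {
  if (is.character(nuclide)) nuclide <- nuclide(nuclide)
  stopifnot(inherits(nuclide, "nuclide_spec"), is.data.frame(samples))
  req <- c("organ", "animal_id", "time_h")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    abort_mirdose(paste0("missing required column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  class = "mirdose_schema_error")
  }
  if (!"mass_g" %in% names(samples)) samples$mass_g <- NA_real_
  if (!"pidg" %in% names(samples)) {
    if (!"counts" %in% names(samples)) {
      abort_mirdose("need a `pidg` or `counts` column",
                    class = "mirdose_schema_error")
    }
    if (is.null(standard_counts)) {
      abort_mirdose("`standard_counts` is required to convert raw counts",
                    class = "mirdose_config_error")
    }
    if (any(is.na(samples$mass_g))) {
      abort_mirdose("`mass_g` must be present for every row when converting counts",
                    class = "mirdose_schema_error")
    }
    samples$pidg <- percent_id_per_gram(samples$counts, standard_counts,
                                        samples$mass_g)
  }
  samples$organ <- canonical_organ_label(samples$organ)
  if (any(!is.finite(samples$time_h)) || any(samples$time_h < 0)) {
    abort_mirdose("time_h must be non-negative", class = "mirdose_schema_error")
  }
  bad_mass <- !is.na(samples$mass_g) & samples$mass_g <= 0
  if (any(bad_mass)) {
    abort_mirdose(sprintf("non-positive mass in row %d",
                          which(bad_mass)[1]), class = "mirdose_schema_error")
  }
  if (any(is.finite(samples$pidg) & samples$pidg < 0)) {
    abort_mirdose("negative %ID/g value", class = "mirdose_schema_error")
  }
  key <- paste(samples$organ, samples$animal_id, samples$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    abort_mirdose(sprintf(
      "duplicate (organ, animal, time) row %d: %s / %s / %g h",
      d, samples$organ[d], samples$animal_id[d], samples$time_h[d]),
      class = "mirdose_schema_error")
  }
  structure(
    list(samples = samples[order(samples$organ, samples$time_h,
                                 samples$animal_id), , drop = FALSE],
         nuclide = nuclide,
         injected_mbq = injected_mbq,
         injected_ug = injected_ug,
         decay_corrected = isTRUE(decay_corrected),
         arm = match.arg(arm, c("baseline", "blocking"))),
    class = "biodist_study"
  )
}

# Lower-case, trimmed, punctuation-light organ labels: "S.I." -> "s.i.",
# "Small Intestine" -> "small_intestine".
canonical_organ_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ -]+", "_", x)
}

#' Read a biodistribution study from delimited text
#'
#' Expects one row per (organ, animal, timepoint). Comma- or tab-separated;
#' `#` starts a comment. Required columns: `organ`, `animal_id`, `time`;
#' optional: `time_unit` (`h` or `d`, default hours; a single `time_unit`
#' value may also be declared in the header), `mass_g`, and one of `pidg` or
#' `counts`. Study metadata may be declared as header comment directives, e.g.
#'
#' ```
#' # nuclide: lu177
#' # injected_mbq: 3.7
#' # decay_corrected: true
#' # arm: baseline
#' ```
#'
#' Function arguments override header directives.
#'
#' @param path file path.
#' @inheritParams biodist_study
#' @param nuclide,injected_mbq,decay_corrected,arm optional overrides of the
#'   header directives.
#' @return a [biodist_study()].
#' @export
read_study <- function(path, nuclide = NULL, injected_mbq = NULL,
                       decay_corrected = NULL, arm = NULL,
                       standard_counts = NULL) {
  if (!file.exists(path)) {
    abort_mirdose(sprintf("file not found: %s", path),
                  class = "mirdose_config_error")
  }
  sep <- detect_sep(path)
  meta <- parse_header_meta(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!"time" %in% names(tab) && !"time_h" %in% names(tab)) {
    abort_mirdose("missing required column `time`",
                  class = "mirdose_schema_error")
  }
  if (!"time_h" %in% names(tab)) {
    unit <- if ("time_unit" %in% names(tab)) {
      tolower(tab$time_unit)
    } else {
      rep(tolower(meta$time_unit %||% "h"), nrow(tab))
    }
    if (!all(unit %in% c("h", "hr", "hours", "d", "day", "days"))) {
      abort_mirdose("time_unit must be hours ('h') or days ('d')",
                    class = "mirdose_schema_error")
    }
    tab$time_h <- tab$time * ifelse(substr(unit, 1, 1) == "d", 24, 1)
  }
  nuc <- nuclide %||% meta$nuclide %||%
    abort_mirdose("nuclide not given (argument or '# nuclide:' header)",
                  class = "mirdose_config_error")
  dc <- decay_corrected %||%
    (tolower(meta$decay_corrected %||% "true") %in% c("true", "yes", "1"))
  biodist_study(
    tab,
    nuclide = nuc,
    injected_mbq = as.numeric(injected_mbq %||% meta$injected_mbq %||% NA),
    decay_corrected = dc,
    arm = arm %||% meta$arm %||% "baseline",
    injected_ug = as.numeric(meta$injected_ug %||% NA),
    standard_counts = standard_counts
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study back to delimited text
#'
#' Lossless round-trip counterpart of [read_study()]: numeric fields are
#' written at full precision with the study metadata as header directives.
#'
#' @param study a [biodist_study()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "biodist_study"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# nuclide: %s", study$nuclide$name),
    sprintf("# injected_mbq: %.15g", study$injected_mbq),
    sprintf("# decay_corrected: %s", tolower(study$decay_corrected)),
    sprintf("# arm: %s", study$arm)
  ), con)
  out <- study$samples[, intersect(c("organ", "animal_id", "time_h", "mass_g",
                                     "pidg"), names(study$samples))]
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a study as mean +/- SD per organ and timepoint
#'
#' Produces the per-organ uptake summary and the target-to-background ratio
#' rows of a standard biodistribution table. Ratios are reported two ways:
#' the mean over animals of per-animal ratios (`mean_of_ratios`, the default
#' display statistic, appropriate when each animal contributes both tissues)
#' and the ratio of the group means (`ratio_of_means`, the statistic that
#' reproduces ratios computed from a published mean table). SD uses the
#' sample (n - 1) convention.
#'
#' @param study a [biodist_study()].
#' @param ratio_pairs list of c(numerator_organ, denominator_organ); defaults
#'   to tumor/blood and tumor/muscle when those organs are present.
#' @return object of class `summary_table`: list with data.frames `uptake`
#'   (organ, time_h, mean, sd, n), `ratios` and `peaks` (per-organ maximum of
#'   the mean curve).
#' @export
summarize_study <- function(study, ratio_pairs = NULL) {
  stopifnot(inherits(study, "biodist_study"))
  s <- study$samples
  agg <- stats::aggregate(pidg ~ organ + time_h, data = s, function(v) {
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      n = length(v))
  })
  uptake <- data.frame(organ = agg$organ, time_h = agg$time_h,
                       mean = agg$pidg[, "mean"], sd = agg$pidg[, "sd"],
                       n = as.integer(agg$pidg[, "n"]))
  uptake <- uptake[order(uptake$organ, uptake$time_h), ]
  rownames(uptake) <- NULL

  if (is.null(ratio_pairs)) {
    ratio_pairs <- Filter(
      function(p) all(p %in% uptake$organ),
      list(c("tumor", "blood"), c("tumor", "muscle"))
    )
  }
  ratios <- do.call(rbind, lapply(ratio_pairs, function(p) {
    ratio_pair_summary(s, uptake, p[1], p[2])
  }))

  peaks <- do.call(rbind, lapply(split(uptake, uptake$organ), function(u) {
    u[which.max(u$mean), c("organ", "time_h", "mean")]
  }))
  rownames(peaks) <- NULL

  structure(list(uptake = uptake, ratios = ratios, peaks = peaks,
                 arm = study$arm, nuclide = study$nuclide$name),
            class = "summary_table")
}

ratio_pair_summary <- function(samples, uptake, num, den) {
  times <- sort(unique(samples$time_h))
  out <- lapply(times, function(tt) {
    a <- samples[samples$organ == num & samples$time_h == tt, ]
    b <- samples[samples$organ == den & samples$time_h == tt, ]
    m <- merge(a[, c("animal_id", "pidg")], b[, c("animal_id", "pidg")],
               by = "animal_id", suffixes = c("_num", "_den"))
    m <- m[m$pidg_den > 0, , drop = FALSE]
    per_animal <- m$pidg_num / m$pidg_den
    mean_num <- uptake$mean[uptake$organ == num & uptake$time_h == tt]
    mean_den <- uptake$mean[uptake$organ == den & uptake$time_h == tt]
    data.frame(
      pair = paste0(num, "/", den), time_h = tt,
      mean_of_ratios = if (length(per_animal)) mean(per_animal) else NA_real_,
      sd_of_ratios = if (length(per_animal) > 1) stats::sd(per_animal) else NA_real_,
      ratio_of_means = if (length(mean_den) && mean_den > 0)
        mean_num / mean_den else NA_real_,
      n = length(per_animal)
    )
  })
  do.call(rbind, out)
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("<summary_table> %s, %s arm\n", x$nuclide, x$arm))
  cat("uptake (%ID/g):\n")
  print(x$uptake, digits = 3)
  if (!is.null(x$ratios) && nrow(x$ratios)) {
    cat("ratios:\n")
    print(x$ratios, digits = 3)
  }
  invisible(x)
}

#' Write a summary table in the layout of a published biodistribution table
#'
#' Organ rows by timepoint columns, cells either `"mean +/- SD"` strings
#' (`style = "pm"`) or split mean/SD columns (`style = "split"`), followed by
#' the ratio rows (mean-of-ratios by default). Cells are rounded to one
#' decimal, half-up.
#'
#' @param summary a [summarize_study()] result.
#' @param path output file.
#' @param style `"pm"` or `"split"`.
#' @param ratio_statistic which ratio column to display,
#'   `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @param digits decimals for display rounding.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, style = c("pm", "split"),
                          ratio_statistic = c("mean_of_ratios",
                                              "ratio_of_means"),
                          digits = 1) {
  stopifnot(inherits(summary, "summary_table"))
  style <- match.arg(style)
  ratio_statistic <- match.arg(ratio_statistic)
  up <- summary$uptake
  times <- sort(unique(up$time_h))
  organs <- unique(up$organ)
  fmt <- function(m, s) {
    if (is.na(m)) return("")
    if (style == "pm") {
      if (is.na(s)) sprintf("%.*f", digits, round_half_up(m, digits))
      else sprintf("%.*f ± %.*f", digits, round_half_up(m, digits),
                   digits, round_half_up(s, digits))
    } else sprintf("%.*f", digits, round_half_up(m, digits))
  }
  rows <- lapply(organs, function(o) {
    vapply(times, function(tt) {
      i <- which(up$organ == o & up$time_h == tt)
      if (!length(i)) "" else fmt(up$mean[i], up$sd[i])
    }, character(1))
  })
  labels <- organs
  if (!is.null(summary$ratios) && nrow(summary$ratios)) {
    r <- summary$ratios
    for (p in unique(r$pair)) {
      rp <- r[r$pair == p, ]
      rows <- c(rows, list(vapply(times, function(tt) {
        i <- which(rp$time_h == tt)
        if (!length(i)) "" else fmt(rp[[ratio_statistic]][i],
                                    rp$sd_of_ratios[i])
      }, character(1))))
      labels <- c(labels, p)
    }
  }
  wide <- data.frame(organ = labels, do.call(rbind, rows),
                     check.names = FALSE)
  names(wide)[-1] <- sprintf("%g h", times)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nuclide: %s | arm: %s | ratio statistic: %s",
                     summary$nuclide, summary$arm, ratio_statistic), con)
  utils::write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one organ's time-activity curve
#'
#' Mean %ID/g over animals at each timepoint, the input to the
#' pharmacokinetic fitting stage (curves are fitted on group means, matching
#' standard small-animal dosimetry practice).
#'
#' @param study a [biodist_study()].
#' @param organ organ label.
#' @return a `tac` object; see [tac()].
#' @export
organ_tac <- function(study, organ) {
  stopifnot(inherits(study, "biodist_study"))
  organ <- canonical_organ_label(organ)
  up <- summarize_study(study, ratio_pairs = list())$uptake
  up <- up[up$organ == organ, ]
  if (!nrow(up)) {
    abort_mirdose(sprintf("organ '%s' not in study (has: %s)", organ,
                          paste(unique(study$samples$organ), collapse = ", ")),
                  class = "mirdose_data_error")
  }
  tac(time_h = up$time_h, value = up$mean, sd = up$sd, n = up$n,
      organ = organ, nuclide = study$nuclide,
      decay_corrected = study$decay_corrected, units = "pidg")
}

#' Time-activity curve
#'
#' Ordered (time, activity) points for one region, in `%ID/g`
#' (`units = "pidg"`) or organ-total `%ID` (`units = "pid"`), plus the
#' nuclide and the decay-correction flag.
#'
#' @param time_h timepoints in hours, strictly increasing.
#' @param value mean activity values.
#' @param sd,n optional per-point SD and group size.
#' @param organ region label.
#' @param nuclide a [nuclide_spec()].
#' @param decay_corrected flag; `TRUE` when values are corrected to
#'   injection time.
#' @param units `"pidg"` or `"pid"`.
#' @return object of class `tac` (a data.frame with attributes).
#' @export
tac <- function(time_h, value, sd = NA_real_, n = NA_integer_, organ = "organ",
                nuclide, decay_corrected = TRUE, units = c("pidg", "pid")) {
  units <- match.arg(units)
  if (is.character(nuclide)) nuclide <- nuclide(nuclide)
  stopifnot(inherits(nuclide, "nuclide_spec"))
  if (is.unsorted(time_h, strictly = TRUE)) {
    abort_mirdose("timepoints must be strictly increasing")
  }
  assert_nonnegative(time_h, "time_h")
  df <- data.frame(time_h = time_h, value = value, sd = sd, n = n)
  structure(df, organ = organ, nuclide = nuclide,
            decay_corrected = isTRUE(decay_corrected), units = units,
            class = c("tac", "data.frame"))
}

#' @export
print.biodist_study <- function(x, ...) {
  cat(sprintf(
    "<biodist_study> %s, %s arm, %.3g MBq injected, %d organs x %d timepoints, decay_corrected = %s\n",
    x$nuclide$name, x$arm, x$injected_mbq,
    length(unique(x$samples$organ)), length(unique(x$samples$time_h)),
    x$decay_corrected))
  invisible(x)
}
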