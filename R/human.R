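# Mouse-to-human extrapolation of organ kinetics.

#' Reference human phantom (organ masses)
#'
#' Loads an organ-mass table for a standard adult. The packaged default
#' (`inst/extdata/phantom_adult_70kg.tsv`) is a nominal 70-kg adult with
#' organ masses from the hermaphroditic adult mathematical phantom used by
#' organ-level dose codes; see the file header for provenance. Any
#' user-supplied file with the same layout (`organ<TAB>mass_g` plus a
#' `# body_mass_kg:` header directive) can be substituted.
#'
#' @param path phantom file; `NULL` for the packaged default.
#' @return object of class `human_phantom`: list with `body_mass_kg`,
#'   `organ_masses` (named numeric, grams), `name`.
#' @export
human_phantom <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phantom_adult_70kg.tsv",
                        package = "mirdose")
  }
  if (!file.exists(path)) {
    abort_mirdose(sprintf("phantom file not found: %s", path),
                  class = "mirdose_config_error")
  }
  meta <- parse_header_meta(path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("organ", "mass_g") %in% names(tab)))
  masses <- stats::setNames(tab$mass_g, canonical_organ_label(tab$organ))
  if (any(masses <= 0)) abort_mirdose("phantom organ masses must be positive")
  body <- as.numeric(meta$body_mass_kg %||% 70)
  structure(list(body_mass_kg = body, organ_masses = masses,
                 name = meta$name %||% basename(path)),
            class = "human_phantom")
}

#' @export
print.human_phantom <- function(x, ...) {
  cat(sprintf("<human_phantom> %s: %.3g kg body, %d organs\n",
              x$name, x$body_mass_kg, length(x$organ_masses)))
  invisible(x)
}

#' Organ alias table
#'
#' Maps biodistribution organ labels (e.g. `"S.I."`) to phantom organ names.
#' The packaged table can be extended with a user file of `alias<TAB>organ`
#' rows.
#'
#' @param extra_path optional additional alias file.
#' @return named character vector alias -> canonical organ.
#' @export
organ_aliases <- function(extra_path = NULL) {
  path <- system.file("extdata", "organ_aliases.tsv", package = "mirdose")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!is.null(extra_path)) {
    tab <- rbind(tab, utils::read.delim(extra_path, comment.char = "#",
                                        stringsAsFactors = FALSE))
  }
  stats::setNames(canonical_organ_label(tab$organ),
                  canonical_organ_label(tab$alias))
}

resolve_organ <- function(label, phantom, aliases = organ_aliases()) {
  lab <- canonical_organ_label(label)
  if (lab %in% names(aliases)) lab <- unname(aliases[lab])
  if (lab %in% names(phantom$organ_masses)) lab else NA_character_
}

#' Scale mouse %ID/g to human organ-total %ID
#'
#' The relative-organ-mass ("percent-kg/g") extrapolation: the concentration
#' relative to whole-body concentration is assumed conserved across species,
#' so
#'
#' `%ID_human(organ) = %IDg_mouse * body_mouse(kg) * mass_organ_human(g) / body_human(kg)`
#'
#' @param pidg_mouse mouse uptake, %ID/g (vectorised).
#' @param mouse_body_kg mouse body mass, kg.
#' @param organ_mass_human_g human organ mass, g.
#' @param human_body_kg human body mass, kg.
#' @return human organ-total %ID.
#' @export
#' @examples
#' human_percent_id(10, 0.02, 1000, 70) # 2.857...
human_percent_id <- function(pidg_mouse, mouse_body_kg, organ_mass_human_g,
                             human_body_kg) {
  assert_nonnegative(pidg_mouse, "pidg_mouse")
  assert_positive(mouse_body_kg, "mouse_body_kg")
  assert_positive(organ_mass_human_g, "organ_mass_human_g")
  assert_positive(human_body_kg, "human_body_kg")
  pidg_mouse * mouse_body_kg * organ_mass_human_g / human_body_kg
}

#' Human source-organ residence times from a mouse study
#'
#' For every study organ that maps onto the phantom, the mouse mean %ID/g
#' curve is scaled timepoint-wise to a human organ-total %ID curve
#' ([human_percent_id()]; `method = "direct"` instead multiplies %ID/g by the
#' measured mouse organ mass, with no inter-species mass adjustment), then
#' fitted and integrated through the same pharmacokinetic path as the mouse
#' data ([fit_study()] schemes).
#'
#' The remainder-of-body residence time is the total-body residence bound
#' minus the organ sum, floored at 0. Total-body retention is taken from a
#' `whole_body` curve if the study has one (values read as organ-total %ID);
#' otherwise the physical-decay bound `T1/2 / ln 2` is used with a warning
#' (every injected atom decays somewhere in the body when excretion data are
#' absent).
#'
#' @param study a [biodist_study()].
#' @param phantom a [human_phantom()].
#' @param mouse_body_kg mouse body mass in kg (default 0.020).
#' @param method `"percent-kg-g"` (default) or `"direct"`.
#' @param scheme,tail,fit_method forwarded to the kinetics stage.
#' @param aliases organ alias map, see [organ_aliases()].
#' @return object of class `residence_time_set`: list with `times` (named
#'   numeric, hours, per phantom organ), `remainder_h`, `total_h`, `scale`,
#'   `nuclide`, `schemes` (per-organ integration scheme), `skipped` (study
#'   organs with no phantom counterpart).
#' @export
extrapolate_residence_times <- function(study, phantom,
                                        mouse_body_kg = 0.020,
                                        method = c("percent-kg-g", "direct"),
                                        scheme = "auto", tail = "physical",
                                        fit_method = "loglinear",
                                        aliases = organ_aliases()) {
  stopifnot(inherits(study, "biodist_study"),
            inherits(phantom, "human_phantom"))
  method <- match.arg(method)
  assert_positive(mouse_body_kg, "mouse_body_kg")
  nuc <- study$nuclide
  organs <- sort(unique(study$samples$organ))
  organs <- setdiff(organs, "whole_body")
  injected <- if (is.finite(study$injected_mbq)) study$injected_mbq else 1

  times <- numeric(0)
  schemes <- character(0)
  skipped <- character(0)
  for (o in organs) {
    target <- resolve_organ(o, phantom, aliases)
    if (is.na(target)) {
      skipped <- c(skipped, o)
      next
    }
    crv <- organ_tac(study, o)
    if (method == "percent-kg-g") {
      hv <- human_percent_id(crv$value, mouse_body_kg,
                             phantom$organ_masses[[target]],
                             phantom$body_mass_kg)
    } else {
      mass <- study$samples$mass_g[study$samples$organ == o]
      if (all(is.na(mass))) {
        abort_mirdose(sprintf(
          "direct method needs measured organ masses (organ '%s')", o),
          class = "mirdose_data_error")
      }
      hv <- crv$value * mean(mass, na.rm = TRUE)
    }
    hcrv <- tac(crv$time_h, hv, organ = target, nuclide = nuc,
                decay_corrected = study$decay_corrected, units = "pid")
    if (all(hv <= 0)) {
      tau <- 0
      sch <- "none"
    } else {
      fit <- fit_monoexp(hcrv, method = fit_method)
      use_hybrid <- scheme == "hybrid" ||
        (scheme == "auto" && fit$lambda_bio_raw < 0)
      ca <- if (use_hybrid) {
        cumulated_activity_hybrid(hcrv, injected, tail = tail,
                                  t0 = if (target == "blood") "extrapolate"
                                       else "zero")
      } else {
        cumulated_activity_monoexp(fit, injected)
      }
      tau <- ca$residence_time_h
      sch <- ca$scheme
    }
    prev <- if (target %in% names(times)) times[[target]] else 0
    times[target] <- prev + tau  # two study tissues may map to one phantom organ
    schemes[target] <- sch
  }
  if (!length(times)) {
    abort_mirdose("no study organ maps onto the phantom",
                  class = "mirdose_mapping_error")
  }

  bound <- nuc$half_life_h / LN2
  if ("whole_body" %in% unique(study$samples$organ)) {
    wb <- organ_tac(study, "whole_body")
    wb_pid <- tac(wb$time_h, wb$value, organ = "whole_body", nuclide = nuc,
                  decay_corrected = study$decay_corrected, units = "pid")
    fitwb <- fit_monoexp(wb_pid)
    total <- if (fitwb$lambda_bio_raw < 0) {
      cumulated_activity_hybrid(wb_pid, injected,
                                t0 = "extrapolate")$residence_time_h
    } else {
      cumulated_activity_monoexp(fitwb, injected)$residence_time_h
    }
  } else {
    warning("no whole-body curve; using the physical-decay bound T1/2/ln2 ",
            "for total-body retention", call. = FALSE)
    total <- bound
  }
  remainder <- max(0, total - sum(times))

  structure(
    list(times = times, remainder_h = remainder, total_h = total,
         scale = "human", nuclide = nuc, schemes = schemes,
         skipped = skipped, phantom = phantom$name,
         mouse_body_kg = mouse_body_kg, method = method),
    class = "residence_time_set"
  )
}

#' @export
print.residence_time_set <- function(x, ...) {
  cat(sprintf("<residence_time_set> %s scale, %s, total %.4g h (remainder %.4g h)\n",
              x$scale, x$nuclide$name, x$total_h, x$remainder_h))
  df <- data.frame(organ = names(x$times),
                   residence_time_h = unname(x$times),
                   scheme = unname(x$schemes[names(x$times)]))
  print(df, digits = 4, row.names = FALSE)
  if (length(x$skipped)) {
    cat("skipped (no phantom counterpart):",
        paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
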