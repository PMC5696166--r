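# Shared fixtures: tiny studies built in code, written to tempfiles on demand.

lu177 <- nuclide("lu177")
cu64 <- nuclide("cu64")

# Two organs, two timepoints, two animals with hand-computable means/SDs.
tiny_samples <- function() {
  data.frame(
    organ = rep(c("tumor", "blood"), each = 4),
    animal_id = rep(c("a1", "a2"), 4),
    time_h = rep(rep(c(2, 24), each = 2), 2),
    mass_g = 0.2,
    pidg = c(2, 4, 10, 14,   # tumor: means 3, 12
             30, 26, 12, 8)  # blood: means 28, 10
  )
}

tiny_study <- function(...) {
  biodist_study(tiny_samples(), nuclide = lu177, injected_mbq = 3.7, ...)
}

write_tiny_study_file <- function(path = tempfile(fileext = ".csv")) {
  s <- tiny_samples()
  con <- file(path, "w")
  writeLines(c("# nuclide: lu177", "# injected_mbq: 3.7",
               "# decay_corrected: true"), con)
  write.table(
    data.frame(organ = s$organ, animal_id = s$animal_id, time = s$time_h,
               time_unit = "h", mass_g = s$mass_g, pidg = s$pidg),
    con, sep = ",", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

# Packaged published-mean fixtures
lu177_means_file <- function() {
  system.file("extdata", "biodist_lu177_snu1066_means.tsv",
              package = "mirdose")
}
cu64_means_file <- function() {
  system.file("extdata", "biodist_cu64_snu1066_means.tsv",
              package = "mirdose")
}

# A noiseless mono-exponential TAC from known parameters.
monoexp_tac <- function(a0 = 10, lambda_bio = 0.01,
                        times = c(2, 24, 72, 120, 168, 336),
                        nuc = lu177, units = "pidg", organ = "organ") {
  tac(times, a0 * exp(-lambda_bio * times), organ = organ, nuclide = nuc,
      units = units)
}
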