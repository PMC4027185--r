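#' Packaged synthetic motif sets
#'
#' The package ships synthetic stand-ins for the external motif resources a
#' real screen would use: four SR-protein-style position weight matrices
#' (widths matching the published ESEfinder matrices), a 238-member
#' enhancer hexamer list (the size of the published RESCUE-ESE set) and a
#' 103-member scored silencer hexamer set (the size of the published
#' FAS-hex3 set). They emulate the documented file formats and set shapes
#' only; they are **not** the published motifs, which cannot be
#' redistributed here. All hermetic tests use generated motif sets instead.
#'
#' @return A list with elements `pwms` (list of [pwm()]), `ese`
#'   (a [hexamer_set()]) and `ess` (a scored [hexamer_set()]).
#' @export
packaged_motifs <- function() {
  dir <- system.file("extdata", package = "splicescreen")
  pwm_files <- list.files(dir, pattern = "\\.pwm\\.tsv$", full.names = TRUE)
  list(
    pwms = lapply(pwm_files, read_pwm),
    ese = read_hexamers(
      file.path(dir, "synthetic_rescue_ese_hexamers.tsv"),
      name = "synthetic_rescue_ese", kind = "ESE_HEX"
    ),
    ess = read_hexamers(
      file.path(dir, "synthetic_fas_hex3_ess.tsv"),
      name = "synthetic_fas_hex3", kind = "ESS_HEX"
    )
  )
}
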