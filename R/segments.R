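# Segment inertial parameters for the planar foot-shank-thigh-HAT model.
#
# Two standard anthropometric tables are provided. Fractions are per single
# limb segment; the head-arms-trunk (HAT) segment takes the remaining body
# mass. Lengths scale with standing height, masses with body mass.

seg_tables <- list(
  # Winter, Biomechanics and Motor Control of Human Movement:
  # mass fraction of BM, segment length fraction of height,
  # COM position fraction from the proximal end, radius of gyration about the
  # COM as a fraction of segment length.
  winter = list(
    foot  = c(mass = 0.0145, length = 0.152, com = 0.50,  rog = 0.475),
    shank = c(mass = 0.0465, length = 0.246, com = 0.433, rog = 0.302),
    thigh = c(mass = 0.100,  length = 0.245, com = 0.433, rog = 0.323),
    hat   = c(mass = 0.678,  length = 0.295, com = 0.626, rog = 0.496)
  ),
  # de Leva (adjusted Zatsiorsky), male values; HAT closes the mass budget and
  # reuses the Winter HAT geometry (de Leva tabulates trunk/head separately).
  deleva = list(
    foot  = c(mass = 0.0137, length = 0.152, com = 0.4415, rog = 0.257),
    shank = c(mass = 0.0433, length = 0.246, com = 0.4459, rog = 0.251),
    thigh = c(mass = 0.1416, length = 0.245, com = 0.4095, rog = 0.329),
    hat   = c(mass = NA,     length = 0.295, com = 0.626,  rog = 0.496)
  )
)

#' Scaled segment inertial parameters
#'
#' Builds per-segment mass, length, centre-of-mass position and moment of
#' inertia for the planar foot-shank-thigh-HAT linkage from an anthropometric
#' table, scaled to a subject's body mass and height. The HAT segment absorbs
#' whatever body mass the two legs do not account for, so segment masses always
#' sum to body mass.
#'
#' @param mass body mass in kg (> 0).
#' @param height standing height in m (> 0).
#' @param table `"winter"` (default) or `"deleva"`.
#' @return An object of class `jw_segparams`: per segment, `m` (kg), `L` (m),
#'   `com` (fraction from proximal end), `I` (kg m^2 about the segment COM),
#'   plus foot geometry (`ankle_height`, `foot_com_y`, `foot_com_z`, `heel_y`,
#'   `toe_y`, all m, in a frame with the ankle at y = 0) and the `mass_fractions`
#'   actually used.
#' @export
segment_parameters <- function(mass, height, table = c("winter", "deleva")) {
  table <- match.arg(table)
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0) {
    jw_abort("mass must be a single positive number", "jw_argument_error")
  }
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0) {
    jw_abort("height must be a single positive number", "jw_argument_error")
  }
  tb <- seg_tables[[table]]
  leg_frac <- tb$foot["mass"] + tb$shank["mass"] + tb$thigh["mass"]
  hat_frac <- 1 - 2 * leg_frac
  segs <- list()
  for (nm in c("foot", "shank", "thigh", "hat")) {
    row <- tb[[nm]]
    mfrac <- unname(if (nm == "hat") hat_frac else row["mass"])
    L <- unname(row["length"]) * height
    m <- mfrac * mass
    segs[[nm]] <- list(
      m = m, L = L, com = unname(row["com"]),
      I = m * (unname(row["rog"]) * L)^2
    )
  }
  foot_len <- segs$foot$L
  structure(
    list(
      table = table,
      mass = mass, height = height,
      foot = segs$foot, shank = segs$shank, thigh = segs$thigh, hat = segs$hat,
      # ankle joint sits above a point 25% of foot length from the heel
      ankle_height = 0.039 * height,
      heel_y = -0.25 * foot_len,
      toe_y = 0.75 * foot_len,
      foot_com_y = 0.25 * foot_len,
      foot_com_z = 0.0195 * height,
      mass_fractions = c(foot = unname(tb$foot["mass"]), shank = unname(tb$shank["mass"]),
                         thigh = unname(tb$thigh["mass"]), hat = unname(hat_frac))
    ),
    class = "jw_segparams"
  )
}
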