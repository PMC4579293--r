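#' Canonical superior colliculus to amygdala phantom
#'
#' Builds the package's reference phantom on a 40 x 60 x 40 grid at 1 mm
#' isotropic resolution. A main bundle ascends dorsolaterally from a
#' midbrain "SC" sphere to the dorsolateral pole of a "pulvinar" sphere,
#' then arcs rostrally above a signal-void "temporal horn" cavity before
#' turning medially into a lateral "amygdala" sphere. With
#' `two_bundle = TRUE` a second, "stria terminalis" bundle leaves the
#' amygdala, runs adjacent to (and partially overlapping) the main bundle
#' above the temporal horn, then climbs medially past a frontal-horn
#' waypoint sphere to a "BNST" termination sphere. The overlap stretch is
#' the crossing-fiber confound the exclusion-mask protocol must resolve.
#'
#' ROI spheres shipped with the phantom: `sc` (seed), `pulvinar` (waypoint),
#' `amygdala` (termination), `stria_frontal` (waypoint) and `bnst`
#' (termination).
#'
#' @param two_bundle include the stria-terminalis decoy bundle.
#' @param snr b0 signal-to-noise ratio (`Inf` for noiseless).
#' @param rng_seed seed for the noise draw.
#' @param f,d stick fraction and diffusivity of both bundles.
#' @return A [phantom_spec()].
#' @examples
#' spec <- sc_amygdala_phantom(two_bundle = FALSE)
#' sim <- simulate_phantom(spec, make_scheme(12, 1000, n_b0 = 1))
#' @export
sc_amygdala_phantom <- function(two_bundle = TRUE, snr = Inf, rng_seed = 1,
                                f = 0.7, d = 1.2e-3) {
  # Both bundles attach to the amygdala sphere at opposite poles (main:
  # dorsal-posterior; stria: inferior-anterior), separated by isotropic
  # amygdala "gray matter", so streamlines cannot run straight through the
  # amygdala from one bundle into the other.
  main <- rbind(
    c(16, 12, 14),       # SC
    c(20, 16, 22),
    c(24, 22, 27),       # dorsolateral pulvinar pole
    c(29, 28, 24),
    c(29, 36, 21.5),     # above the temporal horn
    c(29, 44, 21),
    c(27.8, 46.2, 18))   # dorsal amygdala attachment
  stria <- rbind(
    c(27.4, 49.6, 13.4),  # inferior amygdala attachment
    c(29.5, 47, 14.5),
    c(31, 44, 17),
    c(30.7, 40, 19.3),
    c(30.7, 36, 20.3),    # adjacent / overlapping stretch
    c(30.7, 31, 21.3),
    c(32, 24, 24.5),
    c(28, 20, 31.5),      # subjacent to the frontal horn
    c(23.5, 16, 28.5))    # BNST
  bundles <- list(bundle_spec("sc_amygdala", main, radius = 2.5,
                              f = f, d = d))
  if (two_bundle) {
    bundles <- c(bundles, list(bundle_spec("stria", stria, radius = 2,
                                           f = f, d = d)))
  }
  phantom_spec(
    grid_shape = c(40, 60, 40),
    voxel_size = c(1, 1, 1),
    bundles = bundles,
    voids = list(list(type = "ellipsoid", center = c(29, 37, 13),
                      semiaxes = c(4, 7.5, 4))),  # temporal horn
    rois = list(
      sc = list(center = c(16, 12, 14), radius = 3, role = "seed"),
      pulvinar = list(center = c(24, 22, 27), radius = 3, role = "waypoint"),
      amygdala = list(center = c(27, 48, 16), radius = 3.5,
                      role = "termination"),
      stria_frontal = list(center = c(28, 20, 31.5), radius = 2,
                           role = "waypoint"),
      bnst = list(center = c(23.5, 16, 28.5), radius = 2,
                  role = "termination")),
    snr = snr, rng_seed = rng_seed)
}
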