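#' Virtual specimen observed by the simulated hardware
#'
#' A seeded synthetic sample: point emitters scattered in a square field,
#' each hybridizing with exactly one sequential probe (read out in the
#' probe's laser channel) and, optionally, carrying a fiducial label that
#' is visible in the fiducial channel in every cycle. The focal surface
#' (`surface_z_um`) drifts with a linear rate plus a random walk, driven by
#' the virtual clock, which is what the autofocus loop has to fight.
#'
#' Which probe is currently hybridized is simulation-side state
#' (`active_probe`), set by the task engine after a hybridization sequence
#' and cleared by a bleaching sequence.
#'
#' @export
VirtualSample <- R6::R6Class("VirtualSample",
  public = list(
    #' @field emitters Data frame: x_um, y_um, z_um, brightness (photons/ms),
    #'   probe (character), laser_nm (readout line), fiducial (logical).
    emitters = NULL,
    #' @field surface_z_um Current axial position of the focal surface (µm).
    surface_z_um = NULL,
    #' @field field_um Side length of the square field containing emitters.
    field_um = NULL,
    #' @field drift_nm_s Linear drift rate of the focal surface (nm/s).
    drift_nm_s = 0,
    #' @field diffusion_nm2_s Random-walk diffusion of the surface (nm^2/s).
    diffusion_nm2_s = 0,
    #' @field fiducial_laser_nm Laser line in which fiducial labels emit.
    fiducial_laser_nm = 561,
    #' @field active_probe Currently hybridized probe name, or NA.
    active_probe = NA_character_,
    #' @field seed Seed the sample was generated from.
    seed = NULL,

    #' @description Construct; prefer [generate_sample()].
    #' @param emitters,surface_z_um,field_um,drift_nm_s,diffusion_nm2_s
    #'   See fields.
    #' @param fiducial_laser_nm Fiducial readout line (nm).
    #' @param seed Root seed (drift noise uses substream "sample").
    initialize = function(emitters, surface_z_um = 50, field_um = 200,
                          drift_nm_s = 0, diffusion_nm2_s = 0,
                          fiducial_laser_nm = 561, seed = 0) {
      self$emitters <- emitters
      self$surface_z_um <- surface_z_um
      self$field_um <- field_um
      self$drift_nm_s <- drift_nm_s
      self$diffusion_nm2_s <- diffusion_nm2_s
      self$fiducial_laser_nm <- fiducial_laser_nm
      self$seed <- seed
      private$rng <- rng_stream(derive_seed(seed, "sample"))
    },

    #' @description Attach to a clock so the surface drifts with time.
    #' @param clock A [SimClock].
    bind_clock = function(clock) {
      clock$on_advance(function(dt) self$drift(dt), name = "sample")
      invisible(self)
    },

    #' @description Advance the focal-surface drift process by `dt` seconds.
    #' @param dt Time step (s).
    drift = function(dt) {
      if (dt <= 0) return(invisible(self))
      dz_nm <- self$drift_nm_s * dt
      if (self$diffusion_nm2_s > 0) {
        dz_nm <- dz_nm + rng_draw(private$rng,
          stats::rnorm(1, 0, sqrt(self$diffusion_nm2_s * dt)))
      }
      self$surface_z_um <- self$surface_z_um + dz_nm / 1000
      invisible(self)
    },

    #' @description Set (or clear with NA) the hybridized probe.
    #' @param probe Probe name or NA.
    set_active_probe = function(probe) {
      self$active_probe <- probe
      invisible(self)
    },

    #' @description Emitters visible under a given laser line.
    #' @param laser_nm Active excitation line (nm).
    #' @return Subset of the emitter table.
    visible_emitters = function(laser_nm) {
      e <- self$emitters
      if (nrow(e) == 0L) return(e)
      vis <- (e$fiducial & laser_nm == self$fiducial_laser_nm) |
        (!is.na(self$active_probe) & e$probe == self$active_probe &
           e$laser_nm == laser_nm)
      e[vis, , drop = FALSE]
    }
  ),
  private = list(rng = NULL)
)

#' Generate a reproducible virtual sample
#'
#' Emitters are placed uniformly in a square field centered on the stage
#' origin; axial positions are drawn from a thin Gaussian slab so a default
#' z-stack brackets them. Each emitter is assigned to exactly one probe
#' (readout in `readout_laser_nm`); a fraction additionally carries the
#' fiducial label visible at `fiducial_laser_nm` in every cycle.
#'
#' @param n_emitters Number of point emitters (>= 0).
#' @param field_um Side of the square field (µm), centered on (0, 0).
#' @param n_probes Number of sequential probes to partition emitters over.
#' @param drift_nm_s Linear focal-surface drift (nm/s).
#' @param diffusion_nm2_s Random-walk surface diffusion (nm^2/s).
#' @param seed Root seed; generation uses substream "sample_gen".
#' @param surface_z_um Initial focal-surface height (µm, piezo frame).
#' @param brightness_photons_ms Mean emitter brightness (photons/ms).
#' @param fiducial_fraction Fraction of emitters carrying the fiducial label.
#' @param fiducial_laser_nm Fiducial readout laser line (nm).
#' @param readout_laser_nm Probe readout laser line (nm).
#' @param z_sd_um SD of emitter axial positions about the surface (µm).
#' @return A [VirtualSample].
#' @export
generate_sample <- function(n_emitters, field_um = 200, n_probes = 3,
                            drift_nm_s = 0, diffusion_nm2_s = 0, seed = 0,
                            surface_z_um = 50, brightness_photons_ms = 100,
                            fiducial_fraction = 0.5, fiducial_laser_nm = 561,
                            readout_laser_nm = 640, z_sd_um = 0.3) {
  if (!is.numeric(n_emitters) || n_emitters < 0) {
    stop("generate_sample: n_emitters must be >= 0")
  }
  if (n_probes < 1) stop("generate_sample: n_probes must be >= 1")
  n_emitters <- as.integer(n_emitters)
  probes <- sprintf("RT%02d", seq_len(n_probes))
  gen <- rng_stream(derive_seed(seed, "sample_gen"))
  emitters <- rng_draw(gen, {
    half <- field_um / 2
    data.frame(
      x_um = stats::runif(n_emitters, -half, half),
      y_um = stats::runif(n_emitters, -half, half),
      z_um = stats::rnorm(n_emitters, 0, z_sd_um),
      brightness = stats::rexp(n_emitters, 1 / brightness_photons_ms),
      probe = if (n_emitters > 0) {
        probes[1 + (seq_len(n_emitters) - 1L) %% n_probes]
      } else character(0),
      laser_nm = rep(readout_laser_nm, n_emitters),
      fiducial = stats::runif(n_emitters) < fiducial_fraction,
      stringsAsFactors = FALSE
    )
  })
  # brightness must be strictly positive; rexp can underflow to ~0
  emitters$brightness <- pmax(emitters$brightness, 1)
  VirtualSample$new(emitters, surface_z_um = surface_z_um,
                    field_um = field_um, drift_nm_s = drift_nm_s,
                    diffusion_nm2_s = diffusion_nm2_s,
                    fiducial_laser_nm = fiducial_laser_nm, seed = seed)
}
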