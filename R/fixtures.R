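# Synthetic experimental-data generator: spot tables emulating the imaging
# regimes of the tracking experiments, with known ground truth.

#' Fixture specification for an experimental regime
#'
#' Presets emulate the four imaging regimes of the tracking experiments:
#' \describe{
#'   \item{\code{bead_100ms}}{200 nm microsphere tracers, 100 ms exposure,
#'     100 frames; slow intrinsic diffusion so whole-condensate motion
#'     dominates the untethered signal.}
#'   \item{\code{bead_20ms}}{same tracers at 20 ms, where bead displacement
#'     stays within the static localization error.}
#'   \item{\code{mRNA_200ms}}{structured mRNA guest molecules at 200 ms:
#'     slow, mildly subdiffusive (emulation preset D = 0.004 um^2/s,
#'     alpha = 0.8 motivated by the observed regime, not ground truth of any
#'     experiment).}
#'   \item{\code{polyU_20ms}}{unstructured poly(U) RNA at 20 ms: fast
#'     diffusion (preset D = 0.5 um^2/s, alpha = 0.85) whose timescale
#'     separation makes tethering unnecessary.}
#' }
#'
#' @param regime one of the preset names.
#' @param ... overrides for any field (\code{D}, \code{alpha}, \code{dt},
#'   \code{n_steps}, \code{n_tracks}, \code{sigma_nm}, \code{diameter},
#'   \code{tethered}).
#' @return an object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(regime = c("bead_100ms", "bead_20ms", "mRNA_200ms",
                                    "polyU_20ms"), ...) {
  regime <- match.arg(regime)
  preset <- switch(regime,
    bead_100ms = list(D = 0.001, alpha = 1.0, dt = 0.1, n_steps = 99L,
                      n_tracks = 50L, sigma_nm = 15, diameter = 1,
                      tethered = TRUE),
    bead_20ms = list(D = 0.001, alpha = 1.0, dt = 0.02, n_steps = 99L,
                     n_tracks = 50L, sigma_nm = 15, diameter = 1,
                     tethered = TRUE),
    mRNA_200ms = list(D = 0.004, alpha = 0.8, dt = 0.2, n_steps = 20L,
                      n_tracks = 100L, sigma_nm = 30, diameter = 1,
                      tethered = TRUE),
    polyU_20ms = list(D = 0.5, alpha = 0.85, dt = 0.02, n_steps = 20L,
                      n_tracks = 100L, sigma_nm = 30, diameter = 1,
                      tethered = TRUE))
  spec <- utils::modifyList(preset, list(...))
  spec$regime <- regime
  if (spec$D < 0 || spec$dt <= 0 || spec$n_tracks < 1 || spec$sigma_nm < 0 ||
      spec$diameter <= 0)
    stop_domain("invalid fixture spec")
  structure(spec, class = "fixture_spec")
}

#' Generate an experiment-like fixture
#'
#' Simulates the regime with \code{\link{simulate_condensate}}, adds i.i.d.
#' Gaussian localization noise of the specified sigma to every coordinate,
#' and (optionally) writes a dialect-conformant spot CSV plus a JSON
#' ground-truth sidecar.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param seed RNG master seed.
#' @param dir output directory; NULL returns the tracks without writing.
#' @param name file stem (default the regime name plus tether state).
#' @return list with \code{tracks}, \code{sim} (the noise-free
#'   \code{smt_condensate}), and when written, \code{csv} and \code{sidecar}
#'   paths.
#' @export
generate_fixture <- function(spec, seed = 1L, dir = NULL, name = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  params <- sim_params(D = spec$D, alpha = spec$alpha,
                       diameter = spec$diameter, dt = spec$dt,
                       n_steps = spec$n_steps, n_molecules = spec$n_tracks,
                       rotation_enabled = !spec$tethered, seed = seed)
  sim <- simulate_condensate(params)
  sigma_um <- spec$sigma_nm * 1e-3
  set.seed(child_seed(seed, 777000777L))
  tracks <- lapply(sim$tracks, function(tr) {
    if (sigma_um > 0) {
      tr$x <- tr$x + stats::rnorm(length(tr$x), 0, sigma_um)
      tr$y <- tr$y + stats::rnorm(length(tr$y), 0, sigma_um)
    }
    tr
  })
  out <- list(tracks = tracks, sim = sim)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    name <- name %||% paste0(spec$regime,
                             if (spec$tethered) "_tethered" else "_untethered")
    out$csv <- file.path(dir, paste0(name, ".csv"))
    out$sidecar <- file.path(dir, paste0(name, ".json"))
    write_spot_table(tracks, out$csv)
    write_provenance(unclass(spec), seed, out$sidecar,
                     extra = list(kind = "synthetic_fixture",
                                  localization_sigma_nm = spec$sigma_nm))
  }
  out
}
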