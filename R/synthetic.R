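# Synthetic SERS cohort generator: Lorentzian/Gaussian band models on a
# 600-2300 cm^-1 grid at 2 cm^-1, exponential fluorescence baselines,
# per-sample band-amplitude variability, replicate jitter and white noise.
# Stands in for undeposited patient spectra so the whole pipeline is
# testable; amplitudes and noise levels are free parameters, not measured
# values.

#' Configuration of the synthetic SERS cohort generator
#'
#' Defaults mirror the study design the pipeline targets: spectra on a
#' 600-2300 cm^-1 grid at 2 cm^-1 resolution, cohort sizes 83 FM / 54 non-FM
#' / 9 healthy controls, four replicates per sample, and class-dependent
#' intensity effects concentrated at the eight discriminant bands. Each
#' sample draws per-band lognormal amplitude variability and a lognormal
#' fluorescence-baseline scale; each replicate adds multiplicative jitter
#' and white noise. Per-sample random streams are derived from the master
#' seed by counter, so a cohort is reproducible sample-by-sample.
#'
#' @param n_fm,n_nonfm,n_nc cohort sizes (defaults 83 / 54 / 9).
#' @param replicates replicate spectra per sample (default 4).
#' @param grid wavenumber axis (default `seq(600, 2300, by = 2)`).
#' @param bands band table as from [default_band_table()].
#' @param effect_scale global multiplier on all per-band class effects
#'   (default 0.5; 0 gives a null cohort with no class signal).
#' @param noise_sd additive white-noise standard deviation per point
#'   (default 0.02, in band-amplitude units).
#' @param replicate_sd standard deviation of the per-replicate multiplicative
#'   intensity jitter (default 0.05).
#' @param band_jitter_sdlog lognormal sd of per-sample per-band amplitude
#'   variability (default 0.1).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   per-sample fluorescence baseline amplitude (defaults log(2), 0.3).
#' @param baseline_tau exponential decay constant of the baseline in cm^-1
#'   (default 800).
#' @param seed master integer seed.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_fm = 83L, n_nonfm = 54L, n_nc = 9L,
                             replicates = 4L,
                             grid = seq(600, 2300, by = 2),
                             bands = default_band_table(),
                             effect_scale = 0.5, noise_sd = 0.02,
                             replicate_sd = 0.05, band_jitter_sdlog = 0.1,
                             baseline_meanlog = log(2), baseline_sdlog = 0.3,
                             baseline_tau = 800, seed = 1L) {
  if (any(c(n_fm, n_nonfm, n_nc, replicates) < 0)) stop("counts must be >= 0")
  if (noise_sd < 0 || replicate_sd < 0) stop("noise levels must be >= 0")
  if (is.null(bands) || nrow(bands) == 0L) stop("band table must be non-empty")
  structure(list(n_fm = as.integer(n_fm), n_nonfm = as.integer(n_nonfm),
                 n_nc = as.integer(n_nc), replicates = as.integer(replicates),
                 grid = as.numeric(grid), bands = bands,
                 effect_scale = effect_scale, noise_sd = noise_sd,
                 replicate_sd = replicate_sd,
                 band_jitter_sdlog = band_jitter_sdlog,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 baseline_tau = baseline_tau, seed = as.integer(seed)),
            class = "synthetic_config")
}

band_profile <- function(grid, position, width, shape) {
  if (shape == "gaussian") {
    s <- width / sqrt(2 * log(2))
    exp(-(grid - position)^2 / (2 * s^2))
  } else {
    1 / (1 + ((grid - position) / width)^2)
  }
}

sample_seed <- function(master, k) {
  as.integer((as.numeric(master) * 1000003 + 7919 * k) %% 2147483629)
}

#' Generate a labelled synthetic SERS cohort
#'
#' Each spectrum is a sum of band peaks (per-band amplitude times the
#' class-effect factor 1 +/- class_effect * effect_scale / 2, FM up and
#' non-FM/NC down, with per-sample lognormal jitter), plus a per-sample
#' exponential fluorescence baseline, plus replicate-level multiplicative
#' jitter and additive white noise. Replicates share their sample's band
#' realization. The same configuration (including seed) always yields a
#' bit-identical cohort.
#'
#' @param cfg a [synthetic_config()].
#' @return A `spectra_set` with `replicates` rows per sample and labels
#'   `"FM"`, `"NONFM"`, `"NC"`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (nrow(cfg$bands) == 0L) stop("band table must be non-empty")
  labels1 <- rep(c("FM", "NONFM", "NC"), c(cfg$n_fm, cfg$n_nonfm, cfg$n_nc))
  counts <- c(FM = cfg$n_fm, NONFM = cfg$n_nonfm, NC = cfg$n_nc)
  ids1 <- unlist(lapply(names(counts), function(l)
    sprintf("%s%03d", l, seq_len(counts[[l]]))), use.names = FALSE)
  ntot <- length(ids1)
  profiles <- sapply(seq_len(nrow(cfg$bands)), function(j)
    band_profile(cfg$grid, cfg$bands$position[j], cfg$bands$width[j],
                 cfg$bands$shape[j]))           # npts x nbands
  npts <- length(cfg$grid)
  nrep <- cfg$replicates
  X <- matrix(0, ntot * nrep, npts)
  row <- 0L
  for (k in seq_len(ntot)) {
    set.seed(sample_seed(cfg$seed, k))
    eff <- cfg$bands$class_effect * cfg$effect_scale
    cls_factor <- if (labels1[k] == "FM") 1 + eff / 2 else 1 - eff / 2
    jit <- stats::rlnorm(nrow(cfg$bands), 0, cfg$band_jitter_sdlog)
    amps <- cfg$bands$amplitude * cls_factor * jit
    a <- stats::rlnorm(1, cfg$baseline_meanlog, cfg$baseline_sdlog)
    template <- drop(profiles %*% amps)
    baseline <- a * exp(-(cfg$grid - cfg$grid[1L]) / cfg$baseline_tau)
    for (r in seq_len(nrep)) {
      scale_r <- 1 + stats::rnorm(1, 0, cfg$replicate_sd)
      y <- (template + baseline) * scale_r +
        stats::rnorm(npts, 0, cfg$noise_sd)
      row <- row + 1L
      X[row, ] <- y
    }
  }
  spectra_set(cfg$grid, X,
              sample_id = rep(ids1, each = nrep),
              replicate = rep(seq_len(nrep), ntot),
              label = rep(labels1, each = nrep))
}

#' Inject a photodegradation artifact band
#'
#' Adds the broad amorphous-carbon band at 1535 cm^-1 that appears when the
#' laser burns a dried sample, scaled by `severity`. Used to exercise the QC
#' flag in closed loop.
#'
#' @param s a `spectrum` whose grid covers 1535 cm^-1.
#' @param severity non-negative amplitude of the artifact (0 = identity).
#' @param width half-width of the artifact band (default 15 cm^-1, broader
#'   than the molecular bands).
#' @return The modified `spectrum`.
#' @export
inject_photodegradation <- function(s, severity, width = 15) {
  stopifnot(inherits(s, "spectrum"))
  if (severity < 0) stop("severity must be >= 0")
  if (min(s$wavenumber) > 1535 || max(s$wavenumber) < 1535)
    stop("grid does not cover 1535 cm^-1")
  s$intensity <- s$intensity +
    severity * band_profile(s$wavenumber, 1535, width, "lorentzian")
  s
}

#' QC flag for laser-damaged ("burned") spectra
#'
#' A baseline-corrected spectrum is flagged when the local prominence of the
#' 1535 +/- 10 cm^-1 window — its maximum minus the straight line through
#' the window edges — exceeds `threshold` times the median absolute
#' intensity of the 750-1750 cm^-1 fingerprint region. The 1535 cm^-1 band
#' (amorphous carbon) indicates photodegradation; flagged spectra should be
#' re-acquired, not modelled.
#'
#' @param s a baseline-corrected `spectrum` covering 1525-1545 cm^-1.
#' @param threshold prominence multiplier (default 0.5).
#' @return TRUE if the spectrum shows the artifact.
#' @export
qc_flag_burned <- function(s, threshold = 0.5) {
  stopifnot(inherits(s, "spectrum"))
  if (min(s$wavenumber) > 1525 || max(s$wavenumber) < 1545)
    stop("grid does not cover the 1535 +/- 10 cm^-1 window")
  win <- s$wavenumber >= 1525 & s$wavenumber <= 1545
  wx <- s$wavenumber[win]; wy <- s$intensity[win]
  edge <- stats::approx(wx[c(1L, length(wx))], wy[c(1L, length(wy))],
                        xout = wx)$y
  prominence <- max(wy - edge)
  reg <- s$wavenumber >= 750 & s$wavenumber <= 1750
  if (!any(reg)) reg <- rep(TRUE, length(s$wavenumber))
  ref <- stats::median(abs(s$intensity[reg]))
  prominence > threshold * ref
}
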