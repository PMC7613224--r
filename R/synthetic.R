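#' Load the plasma metabolite peak library
#'
#' Returns the built-in library of plasma 1H resonances (positions in ppm,
#' per-position relative amplitudes, Lorentzian full width at half maximum,
#' and a baseline concentration in arbitrary units). Positions follow
#' standard plasma assignments; the library is representative of the ~70
#' soluble metabolites visible in a CPMG plasma spectrum, not exhaustive.
#'
#' @param overrides Optional list of peaks (each a list with `name`,
#'   `positions`, `relative_amplitudes`, `linewidth`, optional `baseline`).
#'   An override whose name matches a built-in entry replaces it; a new name
#'   is appended. Override names must be unique.
#' @return A named list of metabolite peak definitions.
#' @export
build_peak_library <- function(overrides = NULL) {
  path <- system.file("extdata", "peak_library.json", package = "metabodx")
  stop_if(!nzchar(path), "built-in peak library not found")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lib <- lapply(raw, function(p) {
    validate_peak(list(
      name = p$name,
      positions = unlist(p$positions),
      relative_amplitudes = unlist(p$relative_amplitudes),
      linewidth = p$linewidth,
      baseline = if (is.null(p$baseline)) 1 else p$baseline
    ))
  })
  names(lib) <- vapply(lib, `[[`, "", "name")
  if (!is.null(overrides)) {
    onames <- vapply(overrides, `[[`, "", "name")
    dup <- onames[duplicated(onames)]
    stop_if(length(dup) > 0, "duplicate override metabolite name: %s", dup[1])
    for (p in overrides) {
      p <- validate_peak(p)
      lib[[p$name]] <- p
    }
  }
  lib
}

validate_peak <- function(p) {
  stop_if(is.null(p$name) || !nzchar(p$name), "peak must have a name")
  stop_if(length(p$positions) < 1L, "peak '%s' has no positions", p$name)
  stop_if(any(p$positions < 0.20 | p$positions > 9.68),
          "peak '%s' has positions outside [0.20, 9.68] ppm", p$name)
  stop_if(length(p$relative_amplitudes) != length(p$positions),
          "peak '%s': one amplitude per position required", p$name)
  stop_if(any(p$relative_amplitudes <= 0),
          "peak '%s': amplitudes must be positive", p$name)
  stop_if(is.null(p$linewidth) || p$linewidth <= 0,
          "peak '%s': linewidth must be > 0", p$name)
  if (is.null(p$baseline)) p$baseline <- 1
  p
}

#' Simulate one plasma NMR spectrum
#'
#' Forward model: each metabolite contributes unit-area Lorentzian lines at
#' its library positions, scaled by its concentration and per-position
#' relative amplitude; a single Gaussian ppm offset per metabolite mimics
#' pH-dependent chemical-shift jitter; additive Gaussian noise mimics the
#' baseline noise floor.
#'
#' @param concentrations Named numeric vector, metabolite -> concentration
#'   (arbitrary units, nonnegative). Names must exist in `library`.
#' @param library Peak library from [build_peak_library()].
#' @param axis ppm axis (either orientation, strictly monotone).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param shift_jitter_sd Standard deviation (ppm) of the per-metabolite
#'   shift offset.
#' @param seed Integer seed; the spectrum is deterministic given the seed.
#' @param sample_id Sample identifier.
#' @return An [new_spectrum()] object on the axis as supplied.
#' @export
simulate_spectrum <- function(concentrations, library, axis,
                              noise_sd = 0, shift_jitter_sd = 0,
                              seed = NULL, sample_id = "sim") {
  stop_if(length(axis) < 2L, "axis needs >= 2 points")
  d <- diff(axis)
  stop_if(!(all(d > 0) || all(d < 0)), "axis must be strictly monotone")
  unknown <- setdiff(names(concentrations), names(library))
  stop_if(length(unknown) > 0, "unknown metabolite: %s", unknown[1])
  stop_if(any(concentrations < 0), "negative concentration supplied")

  with_seed(seed, {
    intensity <- numeric(length(axis))
    for (m in names(concentrations)) {
      conc <- concentrations[[m]]
      if (conc == 0) next
      p <- library[[m]]
      jit <- if (shift_jitter_sd > 0) stats::rnorm(1, 0, shift_jitter_sd) else 0
      g <- p$linewidth / 2  # Lorentzian scale = half width at half maximum
      for (k in seq_along(p$positions)) {
        intensity <- intensity + conc * p$relative_amplitudes[k] *
          stats::dcauchy(axis, location = p$positions[k] + jit, scale = g)
      }
    }
    if (noise_sd > 0) {
      intensity <- intensity + stats::rnorm(length(axis), 0, noise_sd)
    }
    new_spectrum(axis, intensity, sample_id = sample_id,
                 meta = list(seed = seed))
  })
}

#' Default cancer-vs-noncancer effect panel
#'
#' Directions of change in the positive (solid tumor) class relative to the
#' unwell-noncancer class: lipoprotein methyl/methylene and saturated lipid
#' resonances decreased; glucose, N-acetyl glycoprotein (NAC1) and threonine
#' increased.
#'
#' @param log2fc Absolute log2 fold change applied to each panel member.
#' @return Named numeric vector of log2 fold changes.
#' @export
default_effects <- function(log2fc = 0.7) {
  c(lipoprotein_CH3 = -log2fc,
    lipoprotein_CH2 = -log2fc,
    saturated_lipid = -log2fc,
    glucose = log2fc,
    NAC1 = log2fc,
    threonine = log2fc)
}

#' Cohort generator configuration
#'
#' Defaults emulate the study cohort: 284 patients with an 8.2% solid-tumor
#' prevalence, a six-metabolite effect panel at |log2FC| = 0.7, 25%
#' multiplicative biological variation, and 0.002 ppm shift jitter.
#'
#' @param n_samples Number of samples (>= 4).
#' @param prevalence Positive-class fraction in (0, 1).
#' @param effects Named numeric vector of log2 fold changes (positive =
#'   elevated in the positive class).
#' @param biological_cv Lognormal sigma of per-sample concentrations.
#' @param noise_sd Additive spectral noise standard deviation.
#' @param shift_jitter_sd Per-metabolite ppm jitter standard deviation.
#' @param points_per_spectrum Axis resolution (>= 1000).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 284L, prevalence = 0.082,
                          effects = default_effects(),
                          biological_cv = 0.25, noise_sd = 1.0,
                          shift_jitter_sd = 0.002,
                          points_per_spectrum = 32768L, seed = 1L) {
  stop_if(n_samples < 4L, "n_samples must be >= 4")
  stop_if(prevalence <= 0 || prevalence >= 1, "prevalence must be in (0,1)")
  stop_if(prevalence * n_samples < 1, "prevalence * n_samples must be >= 1")
  stop_if(points_per_spectrum < 1000L, "points_per_spectrum must be >= 1000")
  stop_if(biological_cv <= 0, "biological_cv must be positive")
  stop_if(noise_sd < 0 || shift_jitter_sd < 0, "noise/jitter sd must be >= 0")
  stop_if(any(!is.finite(effects)), "effects must be finite")
  structure(list(n_samples = as.integer(n_samples), prevalence = prevalence,
                 effects = effects, biological_cv = biological_cv,
                 noise_sd = noise_sd, shift_jitter_sd = shift_jitter_sd,
                 points_per_spectrum = as.integer(points_per_spectrum),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a labeled plasma NMR cohort
#'
#' Per-sample metabolite concentrations are drawn lognormal around
#' class-specific medians: the library baseline for the negative class,
#' scaled by 2^log2FC for the positive class. Labels are assigned by exact
#' count `round(prevalence * n)` and shuffled by the seed.
#'
#' @param config A [cohort_config()].
#' @param library Peak library from [build_peak_library()].
#' @return A list with `spectra` (list of spectra), `labels` (+1 positive /
#'   -1 negative), `truth` (samples x metabolites concentration matrix),
#'   `referral_order`, and the `config`.
#' @export
simulate_cohort <- function(config, library = build_peak_library()) {
  stopifnot(inherits(config, "cohort_config"))
  unknown <- setdiff(names(config$effects), names(library))
  stop_if(length(unknown) > 0,
          "effect references unknown metabolite: %s", unknown[1])

  n <- config$n_samples
  n_pos <- as.integer(round(config$prevalence * n))
  mets <- names(library)
  base <- vapply(library, `[[`, 0, "baseline")
  l2fc <- setNames(numeric(length(mets)), mets)
  l2fc[names(config$effects)] <- config$effects

  axis <- default_ppm_axis(config$points_per_spectrum)

  with_seed(config$seed, {
    labels <- rep(-1L, n)
    labels[sample.int(n, n_pos)] <- 1L
    truth <- matrix(NA_real_, n, length(mets),
                    dimnames = list(sprintf("S%03d", seq_len(n)), mets))
    spectra <- vector("list", n)
    for (i in seq_len(n)) {
      med <- base * 2 ^ (l2fc * (labels[i] == 1L))
      conc <- med * exp(stats::rnorm(length(mets), 0, config$biological_cv))
      truth[i, ] <- conc
      spectra[[i]] <- simulate_spectrum(
        setNames(conc, mets), library, axis,
        noise_sd = config$noise_sd,
        shift_jitter_sd = config$shift_jitter_sd,
        seed = child_seed(config$seed, i),
        sample_id = rownames(truth)[i])
    }
    list(spectra = spectra, labels = labels, truth = truth,
         referral_order = seq_len(n), config = config)
  })
}

#' Diagnostic (principal) bucket per metabolite
#'
#' For each metabolite, chooses the library position with the best ratio of
#' its own signal to the summed background of all other metabolites at that
#' chemical shift (baseline concentrations, Lorentzian heights). This is
#' the resonance a spectroscopist would quantify from: e.g. threonine is
#' read at its resolved 4.24 ppm line, not at the lactate-overlapped methyl
#' doublet. Purely a function of the library, independent of any data.
#'
#' @param library Peak library from [build_peak_library()].
#' @param region,width Bucket grid the centers are reported on.
#' @return Named numeric vector: metabolite -> bucket center (ppm).
#' @export
principal_buckets <- function(library, region = c(0.20, 9.68),
                              width = 0.01) {
  height_at <- function(p, x) {
    g <- p$linewidth / 2
    sum(p$baseline * p$relative_amplitudes * stats::dcauchy(x, p$positions, g))
  }
  out <- vapply(names(library), function(m) {
    p <- library[[m]]
    ratio <- vapply(p$positions, function(x) {
      own <- height_at(p, x)
      bg <- sum(vapply(library[names(library) != m], height_at, 0, x = x))
      own / (own + bg)
    }, 0)
    pos <- p$positions[which.max(ratio)]
    region[1] + (floor((pos - region[1]) / width) + 0.5) * width
  }, 0)
  out
}
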