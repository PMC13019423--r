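# Synthetic AFM-IR EV spectra. Rows are built as
#   sum_bands(group template, jittered amplitudes)
#     + albumin_fraction * sum_bands(albumin bands)
#     + random degree-`baseline_order` polynomial baseline
#     + iid Gaussian noise,
# with the between-group contrast planted at the O-P-O symmetric phosphate
# band (977/978/982 cm-1) and the glycosidic-linkage band (1035/1038 cm-1),
# the two regions where the real isolation methods separate.

# Base peak heights by assignment family (arbitrary intensity units). Values
# are part of the frozen generator calibration.
.base_amplitudes <- c(
  "CO stretching-phospholipid-membrane packing" = 0.3,
  "CO stretching-phospholipid" = 0.6,
  "Amide I - beta-sheet (antiparallel)" = 1.3,
  "Amide I random coil/turn/loop (protein-lipid interaction)" = 1.2,
  "Amide I alpha-helix" = 0.7,
  "CN, CC, nucleic acids" = 0.8,
  "Amide II - proteins" = 1.3,
  "Amide II alpha-helix/beta-sheet ratio" = 0.35,
  "deprotonated carboxylic groups in fatty acids or phospholipids" = 0.7,
  "CH/CH3 - lipid methylation" = 0.7,
  "Asymmetric SO, sulfated lipids glycosaminoglycans" = 0.4,
  "C-O stretch/PO2- of phospholipids, nucleic acids" = 0.5,
  "PO2- symmetric phosphate stretching; phosphate vibration; collagen and phosphodiester groups of nucleic acids" = 0.9,
  "C-O stretch/PO2- of glycosidic linkages" = 1.1,
  "O-P-O symmetric stretching of phospholipids" = 1.1
)

# Group-specific amplitude multipliers at the two discriminant bands.
.discriminant_multipliers <- list(
  "O-P-O symmetric stretching of phospholipids" =
    c(TEIR = 0.8, UC = 1.45, SEC = 2.2),
  "C-O stretch/PO2- of glycosidic linkages" =
    c(TEIR = 2.05, UC = 1.3, SEC = 0.65)
)

#' Build per-group band templates from the assignment table
#'
#' Each isolation method's template carries one pseudo-Voigt band per AFM-IR
#' entry of the assignment table for that method (range entries at their
#' midpoint). Peak heights follow a fixed per-assignment scale, with
#' group-specific amplitude multipliers planted at the O-P-O symmetric
#' phosphate band (977/978/982 cm-1) and the glycosidic-linkage band
#' (1035/1038 cm-1) so the between-group contrast concentrates there.
#'
#' @param band_table a [read_band_table()] result containing AFM-IR rows for
#'   TEIR, UC and SEC.
#' @param fwhm default band FWHM, cm-1.
#' @param eta default Gaussian/Lorentzian mixing fraction.
#' @return Named list (`TEIR`, `UC`, `SEC`) of lists of [pv_band()].
#' @export
default_group_templates <- function(band_table = read_band_table(),
                                    fwhm = 18, eta = 0.5) {
  groups <- c("TEIR", "UC", "SEC")
  afm <- band_table[band_table$modality == "AFM-IR", , drop = FALSE]
  out <- list()
  for (g in groups) {
    rows <- afm[afm$method == g, , drop = FALSE]
    if (nrow(rows) == 0L) stop("band table has no AFM-IR rows for group ", g)
    bands <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      assn <- rows$assignment[i]
      amp <- unname(.base_amplitudes[assn])
      if (is.na(amp)) amp <- 0.8
      mult <- .discriminant_multipliers[[assn]]
      if (!is.null(mult)) amp <- amp * unname(mult[g])
      bands[[i]] <- pv_band(rows$wn_mid[i], fwhm, eta, amp, assn)
    }
    out[[g]] <- bands
  }
  out
}

#' Synthetic-spectra generator configuration
#'
#' Bundles every knob of the generator. The packaged defaults are the frozen
#' calibration used throughout the workflow: 40 spectra per isolation method
#' on a 950-1920 cm-1 axis at 2 cm-1, log-normal amplitude jitter with CV
#' 0.15 (0.3 for the heterogeneous UC group), group-specific albumin corona
#' fractions, a random cubic baseline, and additive Gaussian noise.
#'
#' @param n_per_group spectra per isolation method (>= 2).
#' @param axis wavenumber axis.
#' @param group_templates named list of band lists, one per group.
#' @param albumin_bands albumin corona band model.
#' @param albumin_fraction_mean named per-group mean of the additive albumin
#'   mixing weight, each in `[0, 1)`.
#' @param albumin_fraction_sd spread of the per-spectrum albumin weight.
#' @param baseline_order polynomial degree of the drifting baseline.
#' @param baseline_coeff_scale scale of the uniform baseline coefficients,
#'   intensity units.
#' @param noise_sd additive Gaussian noise standard deviation, intensity units.
#' @param amplitude_jitter_cv named per-group coefficient of variation of the
#'   multiplicative log-normal amplitude jitter.
#' @param seed integer RNG seed; mandatory for reproducibility.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 40,
                             axis = default_axis(),
                             group_templates = default_group_templates(),
                             albumin_bands = albumin_reference_bands(),
                             albumin_fraction_mean = c(TEIR = 0.22, UC = 0.30, SEC = 0.14),
                             albumin_fraction_sd = 0.12,
                             baseline_order = 3,
                             baseline_coeff_scale = 0.25,
                             noise_sd = 0.40,
                             amplitude_jitter_cv = c(TEIR = 0.35, UC = 0.50, SEC = 0.35),
                             seed = 20260917) {
  cfg <- structure(list(
    n_per_group = n_per_group, axis = axis,
    group_templates = group_templates, albumin_bands = albumin_bands,
    albumin_fraction_mean = albumin_fraction_mean,
    albumin_fraction_sd = albumin_fraction_sd,
    baseline_order = baseline_order,
    baseline_coeff_scale = baseline_coeff_scale,
    noise_sd = noise_sd, amplitude_jitter_cv = amplitude_jitter_cv,
    seed = seed), class = "generator_config")
  problems <- validate_config(cfg)
  if (length(problems)) stop("invalid generator config:\n  ",
                             paste(problems, collapse = "\n  "))
  cfg
}

#' Validate a generator configuration
#'
#' @param config a [generator_config()]-shaped list.
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (!is.numeric(config$n_per_group) || config$n_per_group < 2)
    note("n_per_group: must be >= 2")
  if (length(config$axis) < 2 || any(diff(config$axis) <= 0) ||
      any(!is.finite(config$axis)) || any(config$axis <= 0))
    note("axis: must be strictly increasing, finite and positive")
  if (!is.list(config$group_templates) || is.null(names(config$group_templates)))
    note("group_templates: must be a named list of band lists")
  for (g in names(config$group_templates)) for (b in config$group_templates[[g]]) {
    if (b$fwhm <= 0) note(sprintf("group_templates[%s]: fwhm must be > 0", g))
    if (b$eta < 0 || b$eta > 1) note(sprintf("group_templates[%s]: eta must lie in [0, 1]", g))
    if (b$amplitude < 0) note(sprintf("group_templates[%s]: amplitude must be >= 0", g))
  }
  if (any(config$albumin_fraction_mean < 0) || any(config$albumin_fraction_mean >= 1))
    note("albumin_fraction_mean: each mean must lie in [0, 1)")
  if (config$albumin_fraction_sd < 0) note("albumin_fraction_sd: must be >= 0")
  if (!is.numeric(config$baseline_order) || config$baseline_order < 0)
    note("baseline_order: must be a nonnegative integer")
  if (config$baseline_coeff_scale < 0) note("baseline_coeff_scale: must be >= 0")
  if (config$noise_sd < 0) note("noise_sd: must be >= 0")
  if (any(config$amplitude_jitter_cv < 0)) note("amplitude_jitter_cv: must be >= 0")
  if (is.null(config$seed) || !is.finite(config$seed))
    note("seed: an integer seed is mandatory")
  problems
}

# Chebyshev-like random polynomial baseline on axis rescaled to [-1, 1].
.random_baseline <- function(axis, order, scale) {
  u <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  coeff <- stats::runif(order + 1, -1, 1) * scale
  list(values = drop(outer(u, 0:order, `^`) %*% coeff), coefficients = coeff)
}

.lognormal_jitter <- function(k, cv) {
  if (cv <= 0) return(rep(1, k))
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(k, meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
}

.generate_impl <- function(config, null_model) {
  groups <- names(config$group_templates)
  n <- config$n_per_group
  axis <- config$axis
  p <- length(axis)
  ntot <- n * length(groups)
  alb_spec <- sum_bands(axis, config$albumin_bands)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  mat <- matrix(0, ntot, p)
  labels <- rep(groups, each = n)
  truth <- list(albumin_fraction = numeric(ntot),
                baseline_coefficients = vector("list", ntot),
                band_amplitudes = vector("list", ntot))
  shared_template <- config$group_templates[[1]]
  shared_cv <- config$amplitude_jitter_cv[[1]]
  shared_alb_mean <- mean(config$albumin_fraction_mean)
  row <- 0L
  for (g in groups) {
    template <- if (null_model) shared_template else config$group_templates[[g]]
    cv <- if (null_model) shared_cv else config$amplitude_jitter_cv[[g]]
    alb_mean <- if (null_model) shared_alb_mean else config$albumin_fraction_mean[[g]]
    base_amp <- vapply(template, function(b) b$amplitude, numeric(1))
    for (i in seq_len(n)) {
      row <- row + 1L
      amps <- base_amp * .lognormal_jitter(length(template), cv)
      spec <- numeric(p)
      for (k in seq_along(template)) {
        b <- template[[k]]
        spec <- spec + pseudo_voigt(axis, pv_band(b$center, b$fwhm, b$eta,
                                                  amps[k], b$assignment))
      }
      f <- min(max(stats::rnorm(1, alb_mean, config$albumin_fraction_sd), 0), 0.95)
      bl <- .random_baseline(axis, config$baseline_order, config$baseline_coeff_scale)
      spec <- spec + f * alb_spec + bl$values +
        stats::rnorm(p, 0, config$noise_sd)
      mat[row, ] <- spec
      truth$albumin_fraction[row] <- f
      truth$baseline_coefficients[[row]] <- bl$coefficients
      truth$band_amplitudes[[row]] <- amps
    }
  }
  ids <- sprintf("%s_%03d", labels, unlist(lapply(groups, function(g) seq_len(n))))
  set <- spectra_set(axis, mat, labels, ids,
                     provenance = list(generator = if (null_model) "null" else "planted",
                                       seed = config$seed))
  attr(set, "ground_truth") <- truth
  set
}

#' Generate a synthetic EV spectra dataset
#'
#' Draws `n_per_group` spectra for each isolation method from its band
#' template, adds a per-spectrum albumin corona contribution, a random
#' polynomial baseline, and Gaussian noise. Bit-identical output for
#' identical config and seed; the per-row ground truth (albumin fraction,
#' baseline coefficients, jittered band amplitudes) is attached as attribute
#' `"ground_truth"`.
#'
#' @param config a [generator_config()].
#' @return A [spectra_set()] with `3 * n_per_group` rows.
#' @export
generate_dataset <- function(config = generator_config()) {
  problems <- validate_config(config)
  if (length(problems)) stop(paste(problems, collapse = "; "))
  .generate_impl(config, null_model = FALSE)
}

#' Generate a null dataset with no group differences
#'
#' As [generate_dataset()], but every group draws from one shared template,
#' one shared jitter CV and one shared albumin fraction, so the labels carry
#' no information. Used to check the type-I error of the permutation test.
#'
#' @param config a [generator_config()].
#' @return A [spectra_set()].
#' @export
generate_null_dataset <- function(config = generator_config()) {
  problems <- validate_config(config)
  if (length(problems)) stop(paste(problems, collapse = "; "))
  .generate_impl(config, null_model = TRUE)
}
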