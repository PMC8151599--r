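#' Specification for a synthetic brain phantom
#'
#' The phantom emulates a T1-weighted structural scan as nested ellipsoids:
#' a white-matter core inside a gray-matter band inside a CSF rim inside
#' background, with per-tissue mean intensities (WM brightest, as in T1W
#' contrast), additive Gaussian noise and a smooth multiplicative bias field.
#' Labels are exact (noise-free).  All randomness is fixed by `seed`.
#'
#' @param shape Volume shape `c(H, W, S)`.  Default `c(208, 176, 176)`, the
#'   axial OASIS-like case; `c(256, 128, 256)` matches the IBSR-like case.
#' @param tissue_means Mean intensity per class, named
#'   background/csf/gm/wm.  Defaults give strong, distinct T1W-like contrast.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units).
#' @param bias_amplitude Relative strength of the low-frequency multiplicative
#'   bias field (0 disables it).
#' @param geometry Semi-axis fractions of the half-extent for the three
#'   nested ellipsoids, named `wm`, `gm`, `csf`; each must be increasing and
#'   at most 1 so the geometry fits the volume.
#' @param seed RNG seed fixing noise, bias phases, and cohort jitter.
#' @return A `squseg_phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(208L, 176L, 176L),
                         tissue_means = c(background = 10, csf = 60,
                                          gm = 120, wm = 200),
                         noise_sd = 8,
                         bias_amplitude = 0.1,
                         geometry = c(wm = 0.38, gm = 0.55, csf = 0.68),
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(tissue_means) == 4L,
            anyDuplicated(tissue_means) == 0L,
            noise_sd >= 0, bias_amplitude >= 0,
            length(geometry) == 3L)
  if (!(geometry[1] < geometry[2] && geometry[2] < geometry[3])) {
    stop("geometry fractions must be strictly increasing (wm < gm < csf)")
  }
  if (geometry[3] > 1) stop("geometry exceeds the volume bounds")
  structure(list(shape = as.integer(shape), tissue_means = tissue_means,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 geometry = geometry, seed = as.integer(seed)),
            class = "squseg_phantom_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic brain phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a `squseg_volume`) and `labels`
#'   (a `squseg_labels`), deterministic given `spec$seed`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "squseg_phantom_spec"))
  d <- spec$shape
  half <- (d - 1) / 2
  gx <- (seq_len(d[1]) - 1 - half[1]) / half[1]
  gy <- (seq_len(d[2]) - 1 - half[2]) / half[2]
  gz <- (seq_len(d[3]) - 1 - half[3]) / half[3]
  # normalised squared radius per axis, combined by outer sums
  r2 <- function(frac) {
    x2 <- (gx / frac)^2; y2 <- (gy / frac)^2; z2 <- (gz / frac)^2
    outer(outer(x2, y2, `+`), z2, `+`)
  }
  labels <- array(0L, d)
  labels[r2(spec$geometry[["csf"]]) <= 1] <- CLASS_CODES[["csf"]]
  labels[r2(spec$geometry[["gm"]]) <= 1] <- CLASS_CODES[["gm"]]
  labels[r2(spec$geometry[["wm"]]) <= 1] <- CLASS_CODES[["wm"]]
  intens <- spec$tissue_means[labels + 1L]
  with_seed(spec$seed, {
    if (spec$bias_amplitude > 0) {
      ph <- runif(3, 0, 2 * pi)
      bias <- spec$bias_amplitude *
        outer(outer(cos(pi * gx + ph[1]), cos(pi * gy + ph[2]), `+`),
              cos(pi * gz + ph[3]), `+`) / 3
      intens <- intens * (1 + as.numeric(bias))
    }
    if (spec$noise_sd > 0) {
      intens <- intens + rnorm(length(intens), 0, spec$noise_sd)
    }
  })
  vol <- array(as.numeric(intens), d)
  list(volume = as_volume(vol), labels = as_label_volume(labels))
}

#' Generate a cohort of jittered phantoms
#'
#' Stands in for a multi-subject dataset: each subject gets its own seed
#' (derived deterministically from the base seed) and its geometry fractions
#' and tissue means are jittered uniformly within the given relative ranges.
#'
#' @param n Number of subjects.
#' @param base_spec Base [phantom_spec()].
#' @param jitter List with relative ranges `geometry` and `intensity`
#'   (e.g. 0.05 = +/-5%). Use 0 for identical subjects.
#' @return List of `n` phantom lists (`volume`, `labels`, `spec`).
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            jitter = list(geometry = 0.05, intensity = 0.05)) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    sub_seed <- (base_spec$seed * 1000L + i) %% .Machine$integer.max
    jit <- with_seed(sub_seed, {
      list(g = runif(3, -jitter$geometry, jitter$geometry),
           m = runif(3, -jitter$intensity, jitter$intensity))
    })
    geom <- base_spec$geometry * (1 + jit$g)
    geom <- pmin(sort(geom), 1)  # keep nested and inside the volume
    names(geom) <- names(base_spec$geometry)
    means <- base_spec$tissue_means
    means[2:4] <- means[2:4] * (1 + jit$m)
    spec <- phantom_spec(shape = base_spec$shape, tissue_means = means,
                         noise_sd = base_spec$noise_sd,
                         bias_amplitude = base_spec$bias_amplitude,
                         geometry = geom, seed = sub_seed)
    c(generate_phantom(spec), list(spec = spec))
  })
}
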