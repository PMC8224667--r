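# Synthetic lesion-shape generator. A shape is a star-convex region whose
# boundary radius is a base ellipse modulated by low-order radial
# harmonics plus smooth seeded jitter; the harmonic amplitudes are a
# single dial that provably controls fold asymmetry, which is what makes
# the generator a usable stand-in for segmented lesion masks in tests.

#' Specify a synthetic radial-harmonic lesion shape
#'
#' The boundary is `rho(phi) = r_ell(phi) * (1 + sum_k a_k cos(k phi +
#' psi_k)) + jitter(phi)`, where `r_ell` is the radius of an ellipse with
#' semi-axes `radii` rotated by `rotation`, and `jitter` is a smooth
#' random ripple of scale `noise_sd` pixels drawn deterministically from
#' `seed`. A pixel is foreground iff its polar radius about `center` is at
#' most `rho(phi)`.
#'
#' @param canvas `c(M, N)` canvas size in pixels.
#' @param center `c(r, c)` 0-based shape center (default: canvas middle).
#' @param radii `c(a, b)` semi-axes in pixels, `a` along the rotated
#'   x-axis.
#' @param rotation rotation of the base ellipse, radians.
#' @param harmonics list of `c(order, amplitude, phase)` triples; positive
#'   amplitudes `< 1` keep the boundary radius positive.
#' @param noise_sd boundary jitter scale in pixels.
#' @param seed seed for the jitter (per-shape determinism).
#' @return a list of class `shape_spec`.
#' @export
shape_spec <- function(canvas = c(64, 64), center = (canvas - 1) / 2,
                       radii = c(18, 12), rotation = 0,
                       harmonics = list(), noise_sd = 0, seed = 1) {
  stopifnot(length(canvas) == 2L, all(canvas >= 4), all(radii > 0),
            noise_sd >= 0)
  for (h in harmonics) {
    if (length(h) != 3L || h[1L] < 1 || h[2L] < 0)
      stop("each harmonic must be c(order >= 1, amplitude >= 0, phase)",
           call. = FALSE)
  }
  structure(list(canvas = as.integer(canvas), center = as.numeric(center),
                 radii = as.numeric(radii), rotation = as.numeric(rotation),
                 harmonics = harmonics, noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "shape_spec")
}

# Smooth seeded boundary jitter: a short random Fourier series in phi.
jitter_fun <- function(noise_sd, seed) {
  if (noise_sd <= 0) return(function(phi) 0)
  coefs <- with_seed(seed, stats::rnorm(8L))
  orders <- 6:9
  function(phi) {
    out <- 0
    for (i in seq_along(orders)) {
      out <- out + coefs[2 * i - 1] * cos(orders[i] * phi) +
                   coefs[2 * i] * sin(orders[i] * phi)
    }
    noise_sd * out / sqrt(8)
  }
}

#' Rasterize a synthetic shape specification to a binary mask
#'
#' @param spec a [shape_spec()].
#' @return a [binary_mask] of the spec's canvas size.
#' @export
rasterize_shape <- function(spec) {
  M <- spec$canvas[1L]; N <- spec$canvas[2L]
  a <- spec$radii[1L]; b <- spec$radii[2L]
  jit <- jitter_fun(spec$noise_sd, spec$seed)
  rho <- function(phi) {
    phi_e <- phi - spec$rotation
    re <- a * b / sqrt((b * cos(phi_e))^2 + (a * sin(phi_e))^2)
    mod <- 1
    for (h in spec$harmonics) mod <- mod + h[2L] * cos(h[1L] * phi + h[3L])
    pmax(re * mod + jit(phi), 0.5)
  }
  # reject shapes that would clip at the canvas border
  phis <- seq(0, 2 * pi, length.out = 720L)
  rmax <- max(rho(phis))
  if (spec$center[1L] - rmax < -0.5 || spec$center[1L] + rmax > M - 0.5 ||
      spec$center[2L] - rmax < -0.5 || spec$center[2L] + rmax > N - 0.5)
    stop("shape exceeds the canvas; enlarge `canvas` or shrink `radii`",
         call. = FALSE)
  dy <- matrix(rep(0:(M - 1L), N), M, N) - spec$center[1L]
  dx <- matrix(rep(0:(N - 1L), each = M), M, N) - spec$center[2L]
  rad <- sqrt(dx * dx + dy * dy)
  phi <- atan2(dy, dx)
  binary_mask(rad <= rho(phi))
}

#' Default class recipes for the synthetic dataset
#'
#' Parameter ranges per lesion class, chosen so the classes form an
#' asymmetry gradient: `nevus` shapes are near-symmetric ellipses with a
#' whisper of even-order modulation, `dysplastic` shapes carry moderate
#' mixed harmonics with random phases, and `melanoma` shapes have
#' high-amplitude odd harmonics plus boundary jitter. The amplitudes are
#' tuned constants giving essentially non-overlapping class-conditional
#' `A2` distributions; they are modelling conveniences, not claims about
#' real lesion geometry.
#'
#' @return a named list of recipes; each recipe holds ranges used by
#'   [make_dataset()].
#' @export
default_recipes <- function() {
  list(
    nevus = list(
      radii_a = c(18, 26), radii_b = c(13, 18),
      harmonics = list(c(order = 2, lo = 0.00, hi = 0.02)),
      noise_sd = c(0.0, 0.05)
    ),
    melanoma = list(
      radii_a = c(18, 26), radii_b = c(10, 16),
      harmonics = list(c(order = 3, lo = 0.26, hi = 0.38),
                       c(order = 4, lo = 0.10, hi = 0.18),
                       c(order = 5, lo = 0.06, hi = 0.14)),
      noise_sd = c(0.4, 0.8), phase_margin = 0.45
    ),
    dysplastic = list(
      radii_a = c(18, 26), radii_b = c(12, 18),
      harmonics = list(c(order = 2, lo = 0.03, hi = 0.06),
                       c(order = 3, lo = 0.09, hi = 0.13),
                       c(order = 5, lo = 0.035, hi = 0.07)),
      noise_sd = c(0.1, 0.3), phase_margin = 0.45
    )
  )
}

draw_spec <- function(recipe, canvas, shape_seed) {
  a <- stats::runif(1, recipe$radii_a[1L], recipe$radii_a[2L])
  b <- stats::runif(1, recipe$radii_b[1L], recipe$radii_b[2L])
  rot <- stats::runif(1, 0, pi)
  harmonics <- lapply(recipe$harmonics, function(h) {
    ord <- h[["order"]]
    amp <- stats::runif(1, h[["lo"]], h[["hi"]])
    margin <- recipe$phase_margin
    if (!is.null(margin) && ord %% 2 == 1) {
      # Anchor odd-harmonic phases to the ellipse axis: an odd harmonic
      # contributes |sin(k*rot + psi)| to the major fold mismatch and
      # |cos(k*rot + psi)| to the minor one; keeping k*rot + psi away
      # from every quarter-turn guarantees both folds stay asymmetric,
      # which removes the near-symmetric lower tail of A2.
      u <- stats::runif(1, margin, pi / 2 - margin)
      x <- sample(0:3, 1) * (pi / 2) + u
      psi <- (x - ord * rot) %% (2 * pi)
    } else {
      psi <- stats::runif(1, 0, 2 * pi)
    }
    c(ord, amp, psi)
  })
  shape_spec(canvas = canvas,
             radii = c(a, b),
             rotation = rot,
             harmonics = harmonics,
             noise_sd = stats::runif(1, recipe$noise_sd[1L], recipe$noise_sd[2L]),
             seed = shape_seed)
}

#' Generate a labeled synthetic lesion dataset
#'
#' Draws `n_per_class` shapes per class from the recipes and rasterizes
#' them. Fully deterministic for a given seed.
#'
#' @param recipes class recipes (default [default_recipes()]).
#' @param n_per_class shapes per class, >= 1.
#' @param seed master seed.
#' @param canvas canvas size for every mask.
#' @return a list with `manifest` (a data frame of `sample_id`, `label`,
#'   `dataset = "synthetic"`, with empty `mask_path`/`image_path` columns)
#'   and `masks`, a named list of [binary_mask] objects keyed by
#'   `sample_id`.
#' @export
make_dataset <- function(recipes = default_recipes(), n_per_class = 100,
                         seed = 1, canvas = c(100, 100)) {
  if (n_per_class < 1) stop("`n_per_class` must be at least 1", call. = FALSE)
  validate_labels(names(recipes))
  specs <- with_seed(seed, {
    out <- list()
    for (lab in names(recipes)) {
      for (i in seq_len(n_per_class)) {
        shape_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        out[[sprintf("%s_%03d", lab, i)]] <-
          list(label = lab, spec = draw_spec(recipes[[lab]], canvas, shape_seed))
      }
    }
    out
  })
  masks <- lapply(specs, function(s) rasterize_shape(s$spec))
  manifest <- data.frame(
    sample_id = names(specs),
    mask_path = "", image_path = "",
    label = factor(vapply(specs, `[[`, "", "label"), levels = lesion_classes),
    dataset = "synthetic",
    stringsAsFactors = FALSE
  )
  list(manifest = manifest, masks = masks)
}

#' One-parameter lobe-amplitude family
#'
#' A third-order lobe with a weaker fourth-order companion and random
#' phases: a single amplitude dial along which fold asymmetry grows, used
#' to check that the indices respond monotonically to shape asymmetry.
#'
#' @param amplitude lobe amplitude, `>= 0` (0 gives an ellipse).
#' @param seed per-shape seed for the phases.
#' @param canvas canvas size.
#' @return a [shape_spec()].
#' @export
lobe_family <- function(amplitude, seed = 1, canvas = c(64, 64)) {
  stopifnot(amplitude >= 0)
  phases <- with_seed(seed, stats::runif(2, 0, 2 * pi))
  shape_spec(canvas = canvas, radii = c(16, 11),
             rotation = with_seed(seed + 1L, stats::runif(1, 0, pi)),
             harmonics = list(c(3, amplitude, phases[1L]),
                              c(4, 0.6 * amplitude, phases[2L])),
             noise_sd = 0, seed = seed)
}
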