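# Rendering ground-truth networks into multi-channel fluorescence fields.

#' Rendering specification
#'
#' Optical/acquisition parameters for [render_field()]. With identical seed
#' and parameters the rendered field is bit-identical.
#'
#' @param psf_sigma Gaussian point-spread sigma in pixels (> 0), applied to
#'   the structural marker channels (mitochondria, ER).
#' @param tube_radius mitochondrial tube radius in pixels (>= 1); the
#'   skeleton is dilated by a disc of this radius before blurring.
#' @param background_level additive background intensity (AU, >= 0), common
#'   to all channels.
#' @param noise_sd additive Gaussian read-noise sd (AU, >= 0).
#' @param poisson if `TRUE`, Poisson shot noise is applied to the
#'   deterministic signal before read noise (off by default).
#' @param mito_peak,er_peak peak marker intensities above background.
#' @param pixel_size micrometres per pixel (> 0).
#' @param seed integer seed for the noise draws (`NULL`: current stream).
#' @return list of class `render_spec`.
#' @export
render_spec <- function(psf_sigma = 1, tube_radius = 2, background_level = 10,
                        noise_sd = 5, poisson = FALSE, mito_peak = 150,
                        er_peak = 120, pixel_size = 0.1, seed = NULL) {
  stopifnot(psf_sigma > 0, tube_radius >= 1, background_level >= 0,
            noise_sd >= 0, mito_peak > 0, er_peak > 0, pixel_size > 0)
  structure(list(psf_sigma = psf_sigma, tube_radius = tube_radius,
                 background_level = background_level, noise_sd = noise_sd,
                 poisson = poisson, mito_peak = mito_peak, er_peak = er_peak,
                 pixel_size = pixel_size, seed = seed),
            class = "render_spec")
}

#' ER texture specification
#'
#' The ER channel is emulated as a set of round blobs placed away from the
#' mitochondrial tubes so the marker masks are disjoint by construction.
#'
#' @param n_blobs number of ER blobs.
#' @param radius_range blob radius range in pixels.
#' @return list of class `er_texture_spec`.
#' @export
er_texture_spec <- function(n_blobs = 6, radius_range = c(4, 9)) {
  stopifnot(n_blobs >= 0, radius_range[1] >= 1,
            radius_range[2] >= radius_range[1])
  structure(list(n_blobs = n_blobs, radius_range = radius_range),
            class = "er_texture_spec")
}

#' True compartment calcium levels
#'
#' Absolute calcium-channel intensities (background included) inside the
#' whole-cell, mitochondrial and ER compartments; each must be at least the
#' render background.
#'
#' @param whole_cell,mito,er intensities in AU.
#' @return named numeric vector.
#' @export
calcium_levels <- function(whole_cell = 40, mito = 100, er = 60) {
  c(whole_cell = whole_cell, mito = mito, er = er)
}

disc_mask <- function(shape, center, radius) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

dilate_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  k <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), k)) > 0.5
}

blur <- function(img, sigma) {
  EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma))
}

add_noise <- function(signal, spec) {
  x <- signal
  if (isTRUE(spec$poisson)) {
    x <- matrix(rpois(length(x), pmax(x, 0)), nrow = nrow(x))
  }
  if (spec$noise_sd > 0) {
    x <- x + matrix(rnorm(length(x), 0, spec$noise_sd), nrow = nrow(x))
  }
  pmax(x, 0)
}

#' Render a ground-truth network into a three-channel fluorescence field
#'
#' The mitochondrial channel is the skeleton dilated to a tube, blurred by a
#' Gaussian PSF and scaled to `mito_peak` above background; the ER channel
#' renders disc blobs the same way. The calcium channel is piecewise
#' constant over the true compartment masks (cell < ER/mito, all over
#' background) without PSF blur, so that the masked mean equals the
#' requested true level exactly in expectation; noise is then added to all
#' channels. Negative-control images (background + noise only) are attached
#' per stain, and the generating truth (masks, levels, topology) is stored
#' in `$truth` for recovery tests.
#'
#' @param network a [generate_network()] result.
#' @param er_spec an [er_texture_spec()].
#' @param calcium named vector from [calcium_levels()]; all levels must be
#'   `>= background_level`.
#' @param spec a [render_spec()].
#' @param katp_level,rotenone,replicate_id,field_id condition metadata.
#' @return object of class `fluorescence_field`: channels `calcium`,
#'   `mito`, `er`, per-stain `controls`, metadata, and `truth`.
#' @export
render_field <- function(network, er_spec = er_texture_spec(),
                         calcium = calcium_levels(), spec = render_spec(),
                         katp_level = NA_character_,
                         rotenone = NA_character_,
                         replicate_id = NA_character_,
                         field_id = NA_character_) {
  stopifnot(inherits(network, "ground_truth_network"),
            all(calcium >= spec$background_level))
  sh <- dim(network$skeleton)
  with_seed(spec$seed, {
    tube <- dilate_mask(network$skeleton, spec$tube_radius)

    # ER blobs away from the tubes (disjoint marker masks)
    er_mask <- matrix(FALSE, sh[1], sh[2])
    skpts <- which(network$skeleton, arr.ind = TRUE)
    placed <- 0
    blob_centers <- matrix(numeric(0), 0, 2)
    guard <- 0
    while (placed < er_spec$n_blobs && guard < 400) {
      guard <- guard + 1
      rad <- runif(1, er_spec$radius_range[1], er_spec$radius_range[2])
      ctr <- c(runif(1, rad + 3, sh[1] - rad - 2),
               runif(1, rad + 3, sh[2] - rad - 2))
      clearance <- rad + spec$tube_radius + 3 * spec$psf_sigma
      if (chebyshev_min_dist(ctr, skpts) < clearance) next
      if (chebyshev_min_dist(ctr, blob_centers) <
          rad + er_spec$radius_range[2] + 2) next
      er_mask <- er_mask | disc_mask(sh, ctr, rad)
      blob_centers <- rbind(blob_centers, ctr)
      placed <- placed + 1
    }

    cell_mask <- dilate_mask(tube | er_mask, 10)
    cell_mask <- EBImage::imageData(
      EBImage::fillHull(EBImage::Image(cell_mask * 1))) > 0.5

    bg <- spec$background_level
    mito_sig <- bg + spec$mito_peak * blur(tube * 1, spec$psf_sigma)
    er_sig <- bg + spec$er_peak * blur(er_mask * 1, spec$psf_sigma)
    ca_sig <- matrix(bg, sh[1], sh[2])
    ca_sig[cell_mask] <- calcium["whole_cell"]
    ca_sig[er_mask] <- calcium["er"]
    ca_sig[tube] <- calcium["mito"]
    # exact expected background-corrected means per compartment mask (the
    # whole-cell mask contains the organelle regions, so its expectation is
    # the area-weighted mixture of the requested levels)
    expected_means <- c(
      whole_cell = if (any(cell_mask)) mean(ca_sig[cell_mask]) - bg else NA,
      mito = if (any(tube)) mean(ca_sig[tube]) - bg else NA,
      er = if (any(er_mask)) mean(ca_sig[er_mask]) - bg else NA)

    field <- list(
      calcium = add_noise(ca_sig, spec),
      mito = add_noise(mito_sig, spec),
      er = add_noise(er_sig, spec),
      controls = list(
        calcium = add_noise(matrix(bg, sh[1], sh[2]), spec),
        mito = add_noise(matrix(bg, sh[1], sh[2]), spec),
        er = add_noise(matrix(bg, sh[1], sh[2]), spec)),
      pixel_size = spec$pixel_size,
      katp_level = katp_level, rotenone = rotenone,
      replicate_id = replicate_id, field_id = field_id,
      truth = list(network = network[c("true_branch_count",
                                       "true_junction_count",
                                       "true_rod_count",
                                       "true_branch_lengths")],
                   mito_mask = tube, er_mask = er_mask,
                   cell_mask = cell_mask,
                   calcium = calcium, expected_means = expected_means,
                   background = bg,
                   render_spec = spec))
    class(field) <- "fluorescence_field"
    field
  })
}

#' @export
print.fluorescence_field <- function(x, ...) {
  cat("fluorescence field", paste(dim(x$calcium), collapse = "x"),
      "px; condition:", x$katp_level, "/", x$rotenone,
      "replicate", x$replicate_id, "field", x$field_id, "\n")
  invisible(x)
}

#' Construct a fluorescence field from raw channel matrices
#'
#' @param calcium,mito,er numeric intensity matrices of identical shape.
#' @param pixel_size micrometres per pixel.
#' @param controls optional named list of per-stain negative-control images.
#' @param katp_level,rotenone,replicate_id,field_id condition metadata.
#' @return a `fluorescence_field`.
#' @export
fluorescence_field <- function(calcium, mito, er, pixel_size = 1,
                               controls = NULL,
                               katp_level = NA_character_,
                               rotenone = NA_character_,
                               replicate_id = NA_character_,
                               field_id = NA_character_) {
  stopifnot(is.matrix(calcium), identical(dim(calcium), dim(mito)),
            identical(dim(calcium), dim(er)),
            all(is.finite(calcium)), all(is.finite(mito)),
            all(is.finite(er)),
            all(calcium >= 0), all(mito >= 0), all(er >= 0),
            pixel_size > 0)
  structure(list(calcium = calcium, mito = mito, er = er,
                 controls = controls, pixel_size = pixel_size,
                 katp_level = katp_level, rotenone = rotenone,
                 replicate_id = replicate_id, field_id = field_id,
                 truth = NULL),
            class = "fluorescence_field")
}
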