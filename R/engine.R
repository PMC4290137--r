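#' Segmentation configuration
#'
#' All evolution parameters, defaulting to the fixed set used throughout the
#' experiments: `dt = 4.0`, `alpha = 0.01`, `beta = 0.5`, `sigma = 3.0`,
#' `eps = 1.0`, `k = 0.9`. `alpha` weights the region force (intensity above
#' the local threshold grows the contour), `beta` the geodesic edge force,
#' `sigma` the Gaussian scale (voxels) of the local threshold map, `eps` the
#' Heaviside/Dirac band width, `k` the threshold adjustment coefficient, `c`
#' and `sigma_edge` the edge-indicator scope and pre-smoothing.
#'
#' Setting `global_mu` replaces the local threshold map with that constant,
#' which is exactly the original global-threshold hybrid model — the same
#' code path, so model comparisons isolate the effect of localization alone.
#'
#' The evolution stops when the inside/outside labelling changes at no more
#' than `tol_voxels` voxels for 3 consecutive iterations, or at `max_iters`.
#'
#' A diffusion number `dt * beta * max(delta_eps) = dt * beta / (pi * eps)`
#' above 1 triggers a warning: beyond that the explicit curvature step can
#' destabilize even with per-iteration reinitialization.
#'
#' @param dt time step.
#' @param alpha region-force weight.
#' @param beta edge-force weight.
#' @param sigma threshold map Gaussian scale, voxels.
#' @param eps Heaviside/Dirac regularization width, voxels.
#' @param k threshold adjustment coefficient in [0.5, 1] (warns outside).
#' @param c edge indicator scope.
#' @param sigma_edge edge map smoothing scale, voxels.
#' @param max_iters iteration cap.
#' @param tol_voxels stopping threshold on changed voxels per iteration.
#' @param global_mu optional constant threshold (original hybrid baseline).
#' @param normalize rescale intensities to [0, 1] before evolving; thresholds
#'   are then in normalized units.
#' @param strict_paper_steps evaluate the Dirac weight and gradient of the
#'   edge step on the pre-region-update field instead of the freshly
#'   reinitialized one (for A/B comparison of the two step-ordering
#'   readings).
#' @param record_phi keep a copy of the field after every iteration (memory
#'   heavy; intended for small grids and equivalence checks).
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(dt = 4.0, alpha = 0.01, beta = 0.5, sigma = 3.0,
                       eps = 1.0, k = 0.9, c = 1.0, sigma_edge = 1.0,
                       max_iters = 500L, tol_voxels = 0L, global_mu = NULL,
                       normalize = FALSE, strict_paper_steps = FALSE,
                       record_phi = FALSE) {
  for (nm in c("dt", "alpha", "beta", "sigma", "eps", "c", "sigma_edge")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a positive scalar", call. = FALSE)
  }
  if (k < 0.5 || k > 1)
    warning("`k` = ", k, " is outside the recommended range [0.5, 1]",
            call. = FALSE)
  if (max_iters < 1) stop("`max_iters` must be >= 1", call. = FALSE)
  if (tol_voxels < 0) stop("`tol_voxels` must be >= 0", call. = FALSE)
  if (!is.null(global_mu) &&
      (!is.numeric(global_mu) || length(global_mu) != 1L))
    stop("`global_mu` must be a scalar", call. = FALSE)
  diffusion <- dt * beta / (pi * eps)
  if (diffusion > 1)
    warning("dt * beta / (pi * eps) = ", signif(diffusion, 3),
            " exceeds 1; the explicit curvature step may be unstable",
            call. = FALSE)
  structure(list(dt = dt, alpha = alpha, beta = beta, sigma = sigma,
                 eps = eps, k = k, c = c, sigma_edge = sigma_edge,
                 max_iters = as.integer(max_iters),
                 tol_voxels = as.integer(tol_voxels), global_mu = global_mu,
                 normalize = isTRUE(normalize),
                 strict_paper_steps = isTRUE(strict_paper_steps),
                 record_phi = isTRUE(record_phi), diffusion = diffusion),
            class = "seg_config")
}

#' @export
print.seg_config <- function(x, ...) {
  model <- if (is.null(x$global_mu)) "localized hybrid"
    else sprintf("original hybrid (global mu = %g)", x$global_mu)
  cat(sprintf(
    "seg_config [%s]: dt=%g alpha=%g beta=%g sigma=%g eps=%g k=%g c=%g\n",
    model, x$dt, x$alpha, x$beta, x$sigma, x$eps, x$k, x$c))
  invisible(x)
}

#' Read / write a flat key-value configuration file
#'
#' One `key = value` pair per line, `#` comments; keys mirror the arguments
#' of [seg_config()]. Unset keys take the default values.
#'
#' @param path config file path.
#' @return [read_seg_config()] returns a `seg_config`;
#'   [write_seg_config()] the path, invisibly.
#' @export
read_seg_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) != 2) stop("malformed config line: ", paste(p, collapse = "="),
                             call. = FALSE)
    key <- trimws(p[1]); val <- trimws(p[2])
    args[[key]] <- if (val %in% c("TRUE", "FALSE", "true", "false"))
      toupper(val) == "TRUE" else as.numeric(val)
  }
  do.call(seg_config, args)
}

#' @rdname read_seg_config
#' @param config a [seg_config()].
#' @export
write_seg_config <- function(config, path) {
  keep <- setdiff(names(config), "diffusion")
  lines <- vapply(keep, function(nm) {
    v <- config[[nm]]
    if (is.null(v)) return(NA_character_)
    paste0(nm, " = ", format(v, digits = 17))
  }, character(1))
  writeLines(lines[!is.na(lines)], path)
  invisible(path)
}

#' Seed primitives and seed specifications
#'
#' Seeds initialize the contour. A ball seed is a center in 0-based voxel
#' coordinates plus a radius in voxels; a mask seed is an explicit
#' [binary_mask()]. A `seed_spec` collects one or more primitives whose
#' union forms the initial interior region.
#'
#' @param center numeric length-3, 0-based voxel coordinates.
#' @param radius positive radius in voxels.
#' @return a seed primitive, or for [seed_spec()] a `seed_spec` list.
#' @export
seed_ball <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 3L) stop("`center` must have 3 coordinates", call. = FALSE)
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  structure(list(type = "ball", center = center, radius = radius),
            class = "lh_seed")
}

#' @rdname seed_ball
#' @param mask a [binary_mask()] with at least one foreground voxel.
#' @export
seed_mask <- function(mask) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask",
                                           call. = FALSE)
  if (sum(mask$data) == 0) stop("seed mask is empty", call. = FALSE)
  structure(list(type = "mask", mask = mask), class = "lh_seed")
}

#' @rdname seed_ball
#' @param ... seed primitives ([seed_ball()] / [seed_mask()]).
#' @export
seed_spec <- function(...) {
  seeds <- list(...)
  if (length(seeds) == 1L && is.list(seeds[[1]]) &&
      !inherits(seeds[[1]], "lh_seed"))
    seeds <- seeds[[1]]
  if (length(seeds) == 0) stop("at least one seed is required", call. = FALSE)
  if (!all(vapply(seeds, inherits, logical(1), "lh_seed")))
    stop("all seeds must be seed_ball() or seed_mask() primitives",
         call. = FALSE)
  structure(seeds, class = "seed_spec")
}

#' Initialize the level-set field from seeds
#'
#' Builds the signed distance field of the union of the seed regions,
#' positive inside: ball seeds contribute their analytic sphere distance
#' (exact), mask seeds the signed distance transform of their voxel set, and
#' the union is the pointwise maximum.
#'
#' @param shape integer length-3 volume extents.
#' @param seeds a [seed_spec()] (or a single seed primitive).
#' @return a [levelset_field()] with `is_sdf = TRUE`.
#' @export
initialize_phi <- function(shape, seeds) {
  shape <- as.integer(shape)
  if (inherits(seeds, "lh_seed")) seeds <- seed_spec(seeds)
  if (!inherits(seeds, "seed_spec")) stop("`seeds` must be a seed_spec",
                                          call. = FALSE)
  phi <- array(-Inf, shape)
  for (s in seeds) {
    if (s$type == "ball") {
      if (any(s$center < 0) || any(s$center > shape - 1))
        stop("seed center ", paste(s$center, collapse = ","),
             " lies outside the volume", call. = FALSE)
      dx2 <- (seq_len(shape[1]) - 1 - s$center[1])^2
      dy2 <- (seq_len(shape[2]) - 1 - s$center[2])^2
      dz2 <- (seq_len(shape[3]) - 1 - s$center[3])^2
      phi_s <- s$radius - sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    } else {
      if (!identical(dim(s$mask$data), shape))
        stop("seed mask shape does not match the volume", call. = FALSE)
      phi_s <- reinitialize_sdf(array(ifelse(s$mask$data == 1L, 1, -1),
                                      shape))$data
    }
    phi <- pmax(phi, phi_s)
  }
  if (!any(phi >= 0)) stop("seed region is empty within the volume",
                           call. = FALSE)
  if (all(phi >= 0))
    stop(structure(
      class = c("lhvessel_degenerate_interface", "error", "condition"),
      list(message = "degenerate interface: seeds cover the whole domain",
           call = sys.call())))
  levelset_field(array(phi, shape), is_sdf = TRUE)
}

#' Extract the binary mask of the current contour interior
#'
#' @param phi a [levelset_field()] or 3D array; interior is `phi >= 0`.
#' @param spacing voxel spacing carried into the mask.
#' @return a [binary_mask()].
#' @export
extract_mask <- function(phi, spacing = c(1, 1, 1)) {
  data <- as_field_data(phi, "levelset_field")
  binary_mask(data >= 0, spacing = spacing)
}

#' Rescale intensities to the unit interval
#'
#' Explicit affine normalization to [0, 1]. Kept separate from reading so
#' that raw-unit thresholds retain their meaning unless normalization is
#' requested.
#'
#' @param volume an [image_volume()].
#' @return an [image_volume()] with `intensity_range` c(0, 1).
#' @export
normalize_intensity <- function(volume) {
  if (!inherits(volume, "image_volume")) stop("`volume` must be an image_volume",
                                              call. = FALSE)
  rng <- volume$intensity_range
  if (rng[2] <= rng[1])
    stop("cannot normalize a constant volume", call. = FALSE)
  image_volume((volume$data - rng[1]) / (rng[2] - rng[1]),
               spacing = volume$spacing, origin = volume$origin)
}

#' Run the hybrid level-set evolution
#'
#' Evolves the contour by the two-force update, per iteration:
#' \enumerate{
#'   \item reinitialize `phi` to a signed distance field;
#'   \item the local threshold map `mu(u)` (precomputed once — it depends
#'     only on the image; with `global_mu` set it is that constant, the
#'     original hybrid baseline);
#'   \item region force `delta_eps(phi) (I - mu)`;
#'   \item `phi' = phi + dt alpha delta_eps(phi) (I - mu)`;
#'   \item reinitialize `phi'`;
#'   \item `phi <- phi' + dt beta delta_eps(.) div(g grad .)`, evaluated on
#'     the reinitialized field (or on the step-1 field when
#'     `strict_paper_steps`).
#' }
#' The edge map `g` is computed once on the [0, 1]-normalized image so the
#' default `c` is scale-free. Inside is `phi >= 0`: intensity above the local
#' lower-bound threshold pushes the contour outward. The run is fully
#' deterministic.
#'
#' @param volume an [image_volume()].
#' @param phi0 initial [levelset_field()] (see [initialize_phi()]).
#' @param config a [seg_config()].
#' @return an object of class `vessel_segmentation`: fields `phi`
#'   (final [levelset_field()]), `mask` ([binary_mask()]), `trace`
#'   (per-iteration data.frame: `iteration`, `interior_voxels`,
#'   `changed_voxels`, `band_mean_abs_diff` = mean `|I - mu|` on the
#'   interface band), `iterations`, `converged`, `config`, and `snapshots`
#'   when `record_phi`.
#' @export
evolve <- function(volume, phi0, config = seg_config()) {
  if (!inherits(volume, "image_volume")) stop("`volume` must be an image_volume",
                                              call. = FALSE)
  if (!inherits(config, "seg_config")) stop("`config` must be a seg_config",
                                            call. = FALSE)
  phi <- as_field_data(phi0, "levelset_field")
  if (!identical(dim(phi), dim(volume$data)))
    stop("`phi0` shape does not match the volume", call. = FALSE)

  if (config$normalize) volume <- normalize_intensity(volume)
  V <- volume$data
  dims <- dim(V)

  # edge map on the unit-normalized image (constant image -> g = 1)
  rng <- range(V)
  Vn <- if (rng[2] > rng[1]) (V - rng[1]) / (rng[2] - rng[1]) else V * 0
  g <- edge_indicator(array(Vn, dims), c = config$c,
                      sigma_edge = config$sigma_edge)$data

  mu <- if (!is.null(config$global_mu)) {
    array(as.double(config$global_mu), dims)
  } else {
    local_threshold_map(V, sigma = config$sigma, k = config$k)$data
  }

  res <- .evolve_loop(as.double(phi), as.double(V), as.double(mu),
                      as.double(g), dims, config$dt, config$alpha,
                      config$beta, config$eps, config$max_iters,
                      config$tol_voxels, config$strict_paper_steps,
                      config$record_phi)

  if (res$status == 2L)
    stop(structure(
      class = c("lhvessel_degenerate_interface", "error", "condition"),
      list(message = sprintf(
        "degenerate interface at iteration %d: contour vanished or filled the domain",
        res$iters), call = sys.call(), iteration = res$iters)))
  if (res$status == 3L)
    stop("non-finite values in the level-set field at iteration ", res$iters,
         call. = FALSE)

  niter <- res$iters
  tr <- res$trace[seq_len(niter), , drop = FALSE]
  trace <- data.frame(iteration = as.integer(tr[, 1]),
                      interior_voxels = as.integer(tr[, 2]),
                      changed_voxels = as.integer(tr[, 3]),
                      band_mean_abs_diff = tr[, 4])
  phi_final <- levelset_field(array(res$phi, dims), is_sdf = FALSE)
  out <- list(phi = phi_final,
              mask = extract_mask(phi_final, spacing = volume$spacing),
              trace = trace, iterations = niter,
              converged = res$status == 0L, config = config)
  if (config$record_phi)
    out$snapshots <- lapply(res$snapshots[seq_len(niter)],
                            function(p) array(p, dims))
  structure(out, class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf(
    "vessel_segmentation: %d iterations (%s), %d interior voxels\n",
    x$iterations, if (x$converged) "converged" else "iteration cap",
    sum(x$mask$data)))
  invisible(x)
}
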