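#' Specify a synthetic TMA core scene
#'
#' Describes one circular tissue core imaged over three rounds of
#' immunofluorescence. Each round carries a nuclei channel (DNA stain), a
#' protein channel and a glycan channel; the glycan channel is TRA (round 1,
#' pre-sialidase), CA19-9 (round 2) and sTRA (round 3, post-sialidase).
#' Planted regions of `dual`, `ca199_only` or `stra_only` expression add
#' intensity to the matching glycan channel(s); regions of class `none` add
#' to the protein channel only.
#'
#' @param core_diameter_um core diameter in micrometres (default 1000, a
#'   standard 1-mm TMA core).
#' @param pixel_size_um pixel pitch; the default 1 um/px maps a 500 x 400 um
#'   field of view to 500 x 400 px, so 6-9 tiles cover a core.
#' @param fov_width_um,fov_height_um field-of-view (tile) size in um.
#' @param regions list of regions; each is a list with `shape` (see
#'   [region_disk()] / [region_polygon()]), `marker_class` (one of
#'   `"dual"`, `"ca199_only"`, `"stra_only"`, `"none"`), `mean_intensity`
#'   (added on top of the tissue background) and `texture_sd`.
#' @param background_mean,background_sd tissue autofluorescence level and
#'   Gaussian noise SD (clipped at 0).
#' @param nuclei_density expected nuclei per square micrometre.
#' @param nuclei_intensity,protein_intensity added intensity of nucleus
#'   stamps and of the tissue-wide protein stain.
#' @param seed integer seed; the scene is deterministic given the spec.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(core_diameter_um = 1000, pixel_size_um = 1,
                       fov_width_um = 500, fov_height_um = 400,
                       regions = list(),
                       background_mean = 100, background_sd = 8,
                       nuclei_density = 5e-4,
                       nuclei_intensity = 600, protein_intensity = 80,
                       seed = 1L) {
  stopifnot(core_diameter_um > 0, pixel_size_um > 0,
            fov_width_um > 0, fov_height_um > 0,
            background_mean >= 0, background_sd >= 0,
            nuclei_density >= 0)
  classes <- c("dual", "ca199_only", "stra_only", "none")
  r_core <- core_diameter_um / 2
  for (rg in regions) {
    stopifnot(is.list(rg), rg$marker_class %in% classes,
              rg$mean_intensity >= 0, rg$texture_sd >= 0)
    if (rg$shape$type == "disk") {
      d <- sqrt(sum(rg$shape$center_um^2)) + rg$shape$radius_um
      if (d > r_core + 1e-9)
        stop("region extends outside the core disk")
    } else {
      if (any(rg$shape$x^2 + rg$shape$y^2 > r_core^2 + 1e-9))
        stop("region extends outside the core disk")
    }
  }
  structure(list(core_diameter_um = core_diameter_um,
                 pixel_size_um = pixel_size_um,
                 fov_width_um = fov_width_um, fov_height_um = fov_height_um,
                 regions = regions,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 nuclei_density = nuclei_density,
                 nuclei_intensity = nuclei_intensity,
                 protein_intensity = protein_intensity,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Region shapes for [scene_spec()]
#'
#' Coordinates are micrometres relative to the core centre.
#'
#' @param center_um length-2 numeric, disk centre.
#' @param radius_um disk radius.
#' @param marker_class,mean_intensity,texture_sd region attributes, see
#'   [scene_spec()].
#' @return a region list suitable for the `regions` argument of
#'   [scene_spec()].
#' @export
region_disk <- function(center_um, radius_um, marker_class,
                        mean_intensity = 200, texture_sd = 15) {
  list(shape = list(type = "disk", center_um = center_um,
                    radius_um = radius_um),
       marker_class = marker_class, mean_intensity = mean_intensity,
       texture_sd = texture_sd)
}

#' @rdname region_disk
#' @param x,y polygon vertex coordinates (um, core-centred).
#' @export
region_polygon <- function(x, y, marker_class, mean_intensity = 200,
                           texture_sd = 15) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  list(shape = list(type = "polygon", x = x, y = y),
       marker_class = marker_class, mean_intensity = mean_intensity,
       texture_sd = texture_sd)
}

# even-odd point-in-polygon, vectorized over points
.in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

.region_mask <- function(shape, xg, yg) {
  if (shape$type == "disk") {
    (xg - shape$center_um[1])^2 + (yg - shape$center_um[2])^2 <=
      shape$radius_um^2
  } else {
    m <- .in_polygon(as.vector(xg), as.vector(yg), shape$x, shape$y)
    matrix(m, nrow = nrow(xg))
  }
}

#' Render a synthetic core
#'
#' Renders the nine channel images (3 rounds x nuclei/protein/glycan) of a
#' core described by a [scene_spec()], together with ground-truth masks.
#' Rendering is deterministic for a fixed spec (including its seed). Region
#' intensity is additive on the tissue background, so a region with
#' `mean_intensity = k * background_sd` has contrast k sigma.
#'
#' @param spec a `scene_spec`.
#' @return object of class `rendered_core`: `channels` (nested list
#'   `round1..round3` each with `nuclei`, `protein`, `glycan` matrices),
#'   `truth` (logical matrices `tissue`, `dual`, `ca199_only`, `stra_only`,
#'   `ca199`, `stra`), `tile_map` (integer matrix of tile ids) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  r_core <- spec$core_diameter_um / 2
  n <- ceiling(spec$core_diameter_um / spec$pixel_size_um)
  # pixel-centre coordinates, core-centred
  ax <- (seq_len(n) - 0.5) * spec$pixel_size_um - r_core
  xg <- matrix(ax, n, n, byrow = TRUE)   # column -> x
  yg <- matrix(ax, n, n)                 # row -> y
  tissue <- xg^2 + yg^2 <= r_core^2

  glycan_classes <- c("dual", "ca199_only", "stra_only")
  class_masks <- lapply(setNames(nm = c(glycan_classes, "none")),
                        function(cl) matrix(FALSE, n, n))
  for (rg in spec$regions) {
    m <- .region_mask(rg$shape, xg, yg) & tissue
    cl <- rg$marker_class
    other <- setdiff(c(glycan_classes, "none"), cl)
    for (oc in other)
      if (any(m & class_masks[[oc]]))
        stop("overlapping regions of different marker classes: ",
             cl, " vs ", oc)
    class_masks[[cl]] <- class_masks[[cl]] | m
  }

  base_layer <- function() {
    img <- matrix(0, n, n)
    nt <- sum(tissue)
    img[tissue] <- pmax(0, spec$background_mean +
                          rnorm(nt, 0, spec$background_sd))
    img
  }
  add_region_signal <- function(img, classes) {
    for (cl in classes) {
      m <- class_masks[[cl]]
      k <- sum(m)
      if (k == 0) next
      for (rg in spec$regions) {
        if (rg$marker_class != cl) next
        rm <- .region_mask(rg$shape, xg, yg) & tissue
        img[rm] <- img[rm] + pmax(0, rg$mean_intensity +
                                    rnorm(sum(rm), 0, rg$texture_sd))
      }
    }
    img
  }

  # nuclei: fixed positions across rounds (single physical section)
  area_um2 <- pi * r_core^2
  n_nuc <- rpois(1, spec$nuclei_density * area_um2)
  theta <- runif(n_nuc, 0, 2 * pi)
  rad <- r_core * sqrt(runif(n_nuc))
  nx <- rad * cos(theta); ny <- rad * sin(theta)
  nuc_mask <- matrix(FALSE, n, n)
  r_nuc_px <- max(1, round(3 / spec$pixel_size_um))
  for (i in seq_len(n_nuc)) {
    ci <- round((ny[i] + r_core) / spec$pixel_size_um + 0.5)
    cj <- round((nx[i] + r_core) / spec$pixel_size_um + 0.5)
    ri <- max(1, ci - r_nuc_px):min(n, ci + r_nuc_px)
    rj <- max(1, cj - r_nuc_px):min(n, cj + r_nuc_px)
    sub <- outer((ri - ci)^2, (rj - cj)^2, "+") <= r_nuc_px^2
    nuc_mask[ri, rj] <- nuc_mask[ri, rj] | sub
  }
  nuc_mask <- nuc_mask & tissue

  make_round <- function(glycan_classes_on) {
    nuclei <- base_layer()
    nuclei[nuc_mask] <- nuclei[nuc_mask] +
      pmax(0, rnorm(sum(nuc_mask), spec$nuclei_intensity,
                    spec$background_sd))
    protein <- base_layer()
    protein[tissue] <- protein[tissue] +
      pmax(0, rnorm(sum(tissue), spec$protein_intensity,
                    spec$background_sd))
    protein <- add_region_signal(protein, "none")
    glycan <- add_region_signal(base_layer(), glycan_classes_on)
    list(nuclei = nuclei, protein = protein, glycan = glycan)
  }
  channels <- list(
    round1 = make_round(character(0)),              # TRA pre-sialidase
    round2 = make_round(c("dual", "ca199_only")),   # CA19-9
    round3 = make_round(c("dual", "stra_only"))     # sTRA
  )

  truth <- list(tissue = tissue,
                dual = class_masks$dual,
                ca199_only = class_masks$ca199_only,
                stra_only = class_masks$stra_only)
  truth$ca199 <- truth$dual | truth$ca199_only
  truth$stra <- truth$dual | truth$stra_only

  tw <- max(1L, round(spec$fov_width_um / spec$pixel_size_um))
  th <- max(1L, round(spec$fov_height_um / spec$pixel_size_um))
  row_band <- (seq_len(n) - 1L) %/% th
  col_band <- (seq_len(n) - 1L) %/% tw
  tile_map <- outer(row_band, col_band,
                    function(r, c) r * (max(col_band) + 1L) + c + 1L)

  structure(list(channels = channels, truth = truth, tile_map = tile_map,
                 spec = spec),
            class = "rendered_core")
}

#' Split a rendered core into field-of-view tiles
#'
#' Tiles partition the core bounding box row- and column-wise at the
#' field-of-view size; edge tiles are clipped. Reassembling the tiles
#' reproduces the full-core images bit-exactly.
#'
#' @param core a `rendered_core`.
#' @return list of tiles, each with `tile_id`, `rows`, `cols`, cropped
#'   `channels` and cropped `truth` masks.
#' @export
render_fov_tiles <- function(core) {
  stopifnot(inherits(core, "rendered_core"))
  spec <- core$spec
  n <- nrow(core$truth$tissue)
  tw <- max(1L, round(spec$fov_width_um / spec$pixel_size_um))
  th <- max(1L, round(spec$fov_height_um / spec$pixel_size_um))
  row_starts <- seq(1L, n, by = th)
  col_starts <- seq(1L, n, by = tw)
  tiles <- list()
  id <- 0L
  for (rs in row_starts) {
    for (cs in col_starts) {
      id <- id + 1L
      rows <- rs:min(n, rs + th - 1L)
      cols <- cs:min(n, cs + tw - 1L)
      crop <- function(m) m[rows, cols, drop = FALSE]
      tiles[[id]] <- list(
        tile_id = id, rows = range(rows), cols = range(cols),
        channels = lapply(core$channels, function(rd) lapply(rd, crop)),
        truth = lapply(core$truth, crop))
    }
  }
  tiles
}

#' Build a scene whose planted marker areas match target percentages
#'
#' Places up to three non-overlapping disks (dual, CA19-9-only, sTRA-only)
#' whose areas are the requested percent of the core disk. Geometry caps
#' each marker at 18 percent of the core; larger requests are clipped with
#' a warning.
#'
#' @param pct_dual,pct_ca199_only,pct_stra_only target percent of tissue
#'   pixels (0-18 each).
#' @param mean_intensity,texture_sd intensity of the planted regions.
#' @param ... passed to [scene_spec()].
#' @return a `scene_spec`.
#' @export
scene_from_markers <- function(pct_dual, pct_ca199_only, pct_stra_only,
                               mean_intensity = 200, texture_sd = 15, ...) {
  pcts <- c(dual = pct_dual, ca199_only = pct_ca199_only,
            stra_only = pct_stra_only)
  if (any(pcts > 18)) {
    warning("marker percentages clipped at 18% for the disk layout")
    pcts <- pmin(pcts, 18)
  }
  base <- scene_spec(...)
  r_core <- base$core_diameter_um / 2
  angles <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  regions <- list()
  for (i in seq_along(pcts)) {
    if (pcts[i] <= 0) next
    rr <- r_core * sqrt(pcts[i] / 100)
    ctr <- 0.55 * r_core * c(cos(angles[i]), sin(angles[i]))
    regions[[length(regions) + 1L]] <-
      region_disk(ctr, rr, names(pcts)[i], mean_intensity, texture_sd)
  }
  base$regions <- regions
  base
}
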