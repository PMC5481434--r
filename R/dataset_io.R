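#' Write a synthetic dataset to disk
#'
#' Writes one 16-bit TIFF per channel per round per tile for each core,
#' whole-core truth masks as 8-bit TIFF, a tile manifest CSV linking
#' patient to core to tile files, the cohort CSV, and a JSON sidecar
#' echoing the generation parameters.
#'
#' @param cores list of core entries, each a list with `core_id`,
#'   `patient_id`, `tissue_type` (`"tumor"` or `"adjacent"`) and `core`
#'   (a `rendered_core`).
#' @param cohort a `cohort_table` (may have zero rows).
#' @param dir output directory (created if needed).
#' @param params optional list echoed to `params.json`.
#' @param overwrite refuse to overwrite an existing `manifest.csv` unless
#'   `TRUE`.
#' @return the manifest data.frame, invisibly.
#' @export
write_dataset <- function(cores, cohort, dir, params = NULL,
                          overwrite = FALSE) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists in ", dir, "; use overwrite = TRUE")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  rows <- list()
  for (entry in cores) {
    stopifnot(inherits(entry$core, "rendered_core"))
    tiles <- render_fov_tiles(entry$core)
    for (tile in tiles) {
      for (rd in seq_along(tile$channels)) {
        for (ch in names(tile$channels[[rd]])) {
          fn <- sprintf("%s_r%d_%s_t%02d.tif", entry$core_id, rd, ch,
                        tile$tile_id)
          write_tiff(tile$channels[[rd]][[ch]],
                     file.path(dir, "images", fn), bits = 16L)
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = entry$patient_id, core_id = entry$core_id,
            tissue_type = entry$tissue_type, tile_id = tile$tile_id,
            round = rd, channel = ch, file = file.path("images", fn),
            stringsAsFactors = FALSE)
        }
      }
    }
    for (tm in c("tissue", "dual", "ca199_only", "stra_only")) {
      write_tiff(entry$core$truth[[tm]] * 255L,
                 file.path(dir, "truth",
                           sprintf("%s_truth_%s.tif", entry$core_id, tm)),
                 bits = 8L)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), core_id = character(),
               tissue_type = character(), tile_id = integer(),
               round = integer(), channel = character(), file = character(),
               stringsAsFactors = FALSE)
  write.csv(manifest, manifest_path, row.names = FALSE)
  write.csv(as.data.frame(cohort), file.path(dir, "cohort.csv"),
            row.names = FALSE)
  jsonlite::write_json(if (is.null(params)) list() else params,
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset manifest written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return the manifest data.frame.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", dir)
  read.csv(path, stringsAsFactors = FALSE)
}
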