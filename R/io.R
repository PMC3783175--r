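# Standard-format I/O: 32-bit float TIFF height maps with YAML sidecars,
# trace/ground-truth CSVs and JSON reports.

#' Write an AFM image as float TIFF plus YAML sidecar
#'
#' Heights are stored normalized to `[0, 1]` (the TIFF writer clamps values
#' outside that range); the sidecar records `height_scale_nm` so the
#' round-trip is exact, together with `pixel_nm` and the seed.
#'
#' @param image an [afm_image].
#' @param path output TIFF path (`.tif`); the sidecar is `path` with a
#'   `.yaml` extension appended.
#' @param seed seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_afm_tiff <- function(image, path, seed = NA_integer_) {
  H <- image$heights
  lo <- min(H, 0)
  scale <- max(H - lo, 1e-12)
  tiff::writeTIFF((H - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(pixel_nm = image$pixel_nm,
                        height_scale_nm = scale, height_offset_nm = lo,
                        seed = if (is.na(seed)) NULL else as.integer(seed)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read an AFM image (TIFF or whitespace-delimited text grid)
#'
#' TIFFs written by [write_afm_tiff()] are denormalized using their YAML
#' sidecar; plain TIFFs or text grids are taken as heights in nm directly.
#'
#' @param path image path.
#' @param pixel_nm nm per pixel; overrides the sidecar value if given.
#' @return an [afm_image].
#' @export
read_afm <- function(path, pixel_nm = NULL) {
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    H <- tiff::readTIFF(path)
    if (length(dim(H)) == 3) H <- H[, , 1]
    if (!is.null(meta$height_scale_nm))
      H <- H * meta$height_scale_nm +
        (if (is.null(meta$height_offset_nm)) 0 else meta$height_offset_nm)
  } else {
    H <- as.matrix(utils::read.table(path))
    dimnames(H) <- NULL
  }
  px <- if (!is.null(pixel_nm)) pixel_nm else meta$pixel_nm
  if (is.null(px)) stop("pixel_nm not given and no sidecar found",
                        call. = FALSE)
  afm_image(H, px)
}

#' Write traces to CSV
#'
#' Columns: `molecule_id`, `point_index`, `x_nm`, `y_nm`, `step_nm`,
#' `closed`.
#'
#' @param traces list of [trace_result].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(molecule_id = tr$molecule_id,
               point_index = seq_len(nrow(tr$points)) - 1L,
               x_nm = tr$points[, 1], y_nm = tr$points[, 2],
               step_nm = tr$step_nm, closed = tr$closed)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read traces from CSV written by [write_traces_csv()]
#' @param path CSV path.
#' @return list of [trace_result].
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$molecule_id), function(d) {
    d <- d[order(d$point_index), ]
    trace_result(cbind(d$x_nm, d$y_nm), d$step_nm[1], d$closed[1],
                 as.character(d$molecule_id[1]))
  })
}

#' Write ground-truth polymers as CSV plus JSON manifest
#'
#' Vertex CSV columns: `molecule_id`, `x_nm`, `y_nm`. The manifest holds
#' each molecule's true parameters.
#'
#' @param polymers list of [polymer2d].
#' @param csv_path vertex CSV path.
#' @param manifest_path JSON manifest path.
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(polymers, csv_path, manifest_path) {
  rows <- do.call(rbind, lapply(seq_along(polymers), function(i) {
    p <- polymers[[i]]
    data.frame(molecule_id = sprintf("mol%03d", i),
               x_nm = p$vertices[, 1], y_nm = p$vertices[, 2])
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  manifest <- lapply(seq_along(polymers), function(i) {
    p <- polymers[[i]]
    list(molecule_id = sprintf("mol%03d", i), closed = p$closed,
         true_lp_nm = p$true_lp, true_contour_nm = p$true_contour,
         seed = p$seed, label = p$label)
  })
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' Write a JSON report
#' @param report named list.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
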