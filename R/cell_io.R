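# I/O and containers for cell-object tables, tumor masks and clinical
# tables. Coordinates are physical micrometres (image convention, y down);
# any pixel-to-um conversion is the exporter's responsibility.

#' Construct a panel table of phenotype-marked cell centroids
#'
#' A panel table holds all detected cells of one double-IHC stain panel on
#' one slide: panel `"A_CCR8_FOXP3"` carries boolean `CCR8` and `FOXP3`
#' marks, panel `"B_CD8_GZMB"` carries `CD8` and `GZMB`. A `GZMB`-positive
#' cell that is `CD8`-negative is permitted on input but ignored by every
#' CD8-denominated metric.
#'
#' @param cells data.frame with columns `cell_id`, `x_um`, `y_um` and one
#'   logical column per panel marker.
#' @param panel `"A_CCR8_FOXP3"` or `"B_CD8_GZMB"`.
#' @param slide_id,patient_id identifiers.
#' @param frame coordinate-frame tag; a patient's two panels must share it
#'   before joint (matched-field) analysis.
#' @return object of class `panel_table`.
#' @export
panel_table <- function(cells, panel, slide_id = "slide1",
                        patient_id = "patient1", frame = "slide") {
  panel <- match.arg(panel, c(PANEL_A, PANEL_B))
  markers <- panel_markers(panel)
  need <- c("cell_id", "x_um", "y_um", markers)
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) {
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cells <- cells[, need, drop = FALSE]
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um))) {
    stop("non-finite cell coordinates", call. = FALSE)
  }
  for (m in markers) cells[[m]] <- as.logical(cells[[m]])
  structure(
    list(slide_id = slide_id, patient_id = patient_id, panel = panel,
         frame = frame, cells = cells),
    class = "panel_table"
  )
}

#' @export
print.panel_table <- function(x, ...) {
  cat(sprintf("<panel_table> panel %s, slide %s, patient %s: %d cells\n",
              x$panel, x$slide_id, x$patient_id, nrow(x$cells)))
  for (m in panel_markers(x$panel)) {
    cat(sprintf("  %s+: %d\n", m, sum(x$cells[[m]], na.rm = TRUE)))
  }
  invisible(x)
}

n_cells <- function(table) nrow(table$cells)

#' Read a cell-object table exported by an image-analysis platform
#'
#' Ingests one CSV of detected cells (one row per cell). Column names are
#' mapped through `column_map` so different exporters' headers can be
#' absorbed without editing files. Marker columns accept `0/1`,
#' `true/false` (any case), or `+/-` encodings.
#'
#' @param path CSV file path.
#' @param panel stain panel of the file, `"A_CCR8_FOXP3"` or
#'   `"B_CD8_GZMB"`.
#' @param column_map optional named character vector mapping canonical
#'   names (`cell_id`, `x_um`, `y_um`, marker names) to the file's
#'   headers, e.g. `c(x_um = "Cell X Position")`.
#' @param slide_id,patient_id,frame identifiers; if the file has
#'   `slide_id`/`patient_id` columns they are used unless overridden here.
#' @return a [panel_table()].
#' @export
read_cell_table <- function(path, panel, column_map = NULL,
                            slide_id = NULL, patient_id = NULL,
                            frame = "slide") {
  panel <- match.arg(panel, c(PANEL_A, PANEL_B))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  markers <- panel_markers(panel)
  want <- c("cell_id", "x_um", "y_um", markers)
  map <- stats::setNames(want, want)
  if (!is.null(column_map)) map[names(column_map)] <- unlist(column_map)
  miss <- map[!(map %in% names(raw))]
  if (length(miss) > 0) {
    stop("column(s) not found in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("empty cell table: ", basename(path), call. = FALSE)
    cells <- data.frame(cell_id = character(), x_um = numeric(),
                        y_um = numeric())
    for (m in markers) cells[[m]] <- logical()
  } else {
    cells <- data.frame(cell_id = raw[[map["cell_id"]]],
                        stringsAsFactors = FALSE)
    for (cc in c("x_um", "y_um")) {
      v <- suppressWarnings(as.numeric(raw[[map[cc]]]))
      bad <- which(is.na(v) & nzchar(trimws(raw[[map[cc]]])))
      if (length(bad) > 0 || anyNA(v)) {
        row <- if (length(bad) > 0) bad[1] else which(is.na(v))[1]
        stop("non-numeric ", cc, " at data row ", row, " of ",
             basename(path), call. = FALSE)
      }
      cells[[cc]] <- v
    }
    for (m in markers) cells[[m]] <- parse_marker(raw[[map[m]]], m, path)
  }
  if (is.null(slide_id)) {
    slide_id <- if ("slide_id" %in% names(raw) && nrow(raw) > 0)
      raw$slide_id[1] else "slide1"
  }
  if (is.null(patient_id)) {
    patient_id <- if ("patient_id" %in% names(raw) && nrow(raw) > 0)
      raw$patient_id[1] else "patient1"
  }
  panel_table(cells, panel, slide_id = slide_id, patient_id = patient_id,
              frame = frame)
}

parse_marker <- function(v, name, path) {
  s <- tolower(trimws(v))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "+", "pos")] <- TRUE
  out[s %in% c("0", "false", "f", "-", "−", "neg")] <- FALSE
  if (anyNA(out)) {
    stop("unparseable ", name, " value '", v[which(is.na(out))[1]],
         "' in ", basename(path), call. = FALSE)
  }
  out
}

#' Write a panel table to CSV
#'
#' Inverse of [read_cell_table()]; the round trip is lossless.
#'
#' @param table a [panel_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  stopifnot(inherits(table, "panel_table"))
  out <- table$cells
  out$slide_id <- table$slide_id
  out$patient_id <- table$patient_id
  for (m in panel_markers(table$panel)) out[[m]] <- as.integer(out[[m]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Construct a tumor mask from polygons
#'
#' The mask is the pathologist-delineated tumor region; all whole-tumor
#' densities are counts divided by its area.
#'
#' @param polygons a single n x 2 matrix or a list of them (um
#'   coordinates, vertices in order, no repeated closing vertex).
#' @return object of class `tumor_mask` with derived `area_mm2`.
#' @export
tumor_mask <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (nrow(p) > 3 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), ]
    if (nrow(p) < 3) stop("mask polygon has fewer than 3 vertices",
                          call. = FALSE)
    if (!polygon_is_simple(p)) stop("self-intersecting mask polygon",
                                    call. = FALSE)
    unname(p)
  })
  area <- sum(vapply(polygons, polygon_area_um2, numeric(1))) / 1e6
  if (area <= 0) stop("tumor mask has zero area", call. = FALSE)
  structure(list(polygons = polygons, area_mm2 = area),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %d polygon(s), %.4f mm^2\n",
              length(x$polygons), x$area_mm2))
  invisible(x)
}

mask_bbox <- function(mask) bbox_of(mask$polygons)

#' Read a tumor mask from GeoJSON
#'
#' Accepts Polygon and MultiPolygon geometries (RFC 7946 layout, CRS-less,
#' coordinates in um). Interior rings (holes) are not supported and raise
#' an error.
#'
#' @param path GeoJSON file path.
#' @return a [tumor_mask()].
#' @export
read_tumor_mask <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(g$type,
    FeatureCollection = lapply(g$features, `[[`, "geometry"),
    Feature = list(g$geometry),
    Polygon = ,
    MultiPolygon = list(g),
    stop("unsupported GeoJSON type: ", g$type, call. = FALSE)
  )
  rings <- list()
  for (geom in geoms) {
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    for (p in polys) {
      if (length(p) > 1) {
        stop("mask polygons with interior rings (holes) are not supported",
             call. = FALSE)
      }
      ring <- do.call(rbind, lapply(p[[1]], function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      rings <- c(rings, list(ring))
    }
  }
  tumor_mask(rings)
}

#' Write a tumor mask to GeoJSON
#'
#' @param mask a [tumor_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tumor_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tumor_mask"))
  features <- lapply(mask$polygons, function(p) {
    ring <- rbind(p, p[1, , drop = FALSE])
    coords <- lapply(seq_len(nrow(ring)), function(i) as.list(ring[i, ]))
    list(type = "Feature", properties = list(role = "tumor"),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restrict a panel table to cells inside the tumor mask
#'
#' Keeps exactly the cells whose centroid lies inside any mask polygon;
#' points on a polygon boundary count as inside. Idempotent.
#'
#' @param table a [panel_table()].
#' @param mask a [tumor_mask()].
#' @return the filtered `panel_table`, carrying the mask bounding box as
#'   its `bbox` attribute for downstream field-grid placement.
#' @export
filter_to_tumor <- function(table, mask) {
  stopifnot(inherits(table, "panel_table"), inherits(mask, "tumor_mask"))
  keep <- rep(FALSE, n_cells(table))
  for (poly in mask$polygons) {
    keep <- keep | points_in_polygon(table$cells$x_um, table$cells$y_um,
                                     poly)
  }
  table$cells <- table$cells[keep, , drop = FALSE]
  rownames(table$cells) <- NULL
  attr(table, "bbox") <- mask_bbox(mask)
  table
}

#' Read / write a clinical table
#'
#' The clinical CSV has one row per patient with columns `patient_id`,
#' `pfs_months` (progression-free survival, months), `event` (1 =
#' progression/death, 0 = censored) and one column per clinicopathological
#' covariate.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "pfs_months", "event")
  miss <- setdiff(need, names(cl))
  if (length(miss) > 0) {
    stop("clinical table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(cl$pfs_months)) || any(cl$pfs_months <= 0)) {
    stop("pfs_months must be finite and positive", call. = FALSE)
  }
  cl$event <- as.integer(cl$event)
  cl
}

#' @rdname read_clinical
#' @param clinical data.frame as above.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}
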