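#' Region annotations: tumor, stroma and excluded histology
#'
#' An annotation set carries simple (non-self-intersecting) polygons, in the
#' same micrometer image coordinates as the cells, classified by role:
#' `tumor` (tumor core), `stroma`, and `exclude` (bone, bone marrow, blood
#' vessels, autofluorescent tissue -- regions dropped from all analyses).
#' On overlap, exclusion takes precedence over tumor, and tumor over stroma.
#'
#' @param specimen_id Identifier the annotations belong to.
#' @param tumor,stroma,exclude Lists of polygons; each polygon is a 2-column
#'   matrix (x, y in micrometers) of vertices, not closed (first vertex not
#'   repeated).
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(specimen_id, tumor = list(), stroma = list(),
                           exclude = list()) {
  check <- function(polys, role) {
    lapply(seq_along(polys), function(i) {
      p <- as.matrix(polys[[i]])
      storage.mode(p) <- "double"
      if (ncol(p) != 2 || nrow(p) < 3) {
        abort(sprintf("%s polygon %d: need >= 3 (x, y) vertices", role, i))
      }
      # drop an explicitly closed ring
      if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
      if (.polygon_self_intersects(p)) {
        abort(sprintf("%s polygon %d is self-intersecting", role, i))
      }
      dimnames(p) <- NULL
      p
    })
  }
  structure(list(specimen_id = as.character(specimen_id),
                 tumor = check(tumor, "tumor"),
                 stroma = check(stroma, "stroma"),
                 exclude = check(exclude, "exclude")),
            class = "annotation_set")
}

# Shoelace signed area; positive magnitude in um^2.
.polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Proper-crossing test between non-adjacent edges (shared endpoints allowed).
.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read region annotations from a GeoJSON file
#'
#' Expects a `FeatureCollection` of `Polygon` features, each with a `role`
#' property in `{tumor, stroma, exclude}`.  Coordinates are micrometers in
#' the image convention.  Holes (additional rings) are not supported.
#'
#' @param path GeoJSON file.
#' @param specimen_id Identifier to attach; defaults to a top-level
#'   `specimen_id` property if present, else the file name.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(g$type, "FeatureCollection")) {
    abort("annotation file must be a GeoJSON FeatureCollection")
  }
  if (is.null(specimen_id)) {
    specimen_id <- g$properties$specimen_id %||%
      sub("\\.[^.]*$", "", basename(path))
  }
  polys <- list(tumor = list(), stroma = list(), exclude = list())
  for (k in seq_along(g$features)) {
    f <- g$features[[k]]
    if (!identical(f$geometry$type, "Polygon")) {
      abort(sprintf("feature %d: geometry type must be Polygon, got '%s'",
                    k, f$geometry$type %||% "<none>"))
    }
    role <- f$properties$role
    if (is.null(role) || !role %in% c("tumor", "stroma", "exclude")) {
      abort(sprintf(
        "feature %d: unknown role '%s' (expected tumor/stroma/exclude)",
        k, role %||% "<missing>"))
    }
    ring <- f$geometry$coordinates[[1]]
    mat <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    polys[[role]] <- c(polys[[role]], list(mat))
  }
  annotation_set(specimen_id, tumor = polys$tumor, stroma = polys$stroma,
                 exclude = polys$exclude)
}

#' Write region annotations as GeoJSON
#'
#' Inverse of [read_annotations()]; vertex coordinates are written at full
#' precision so round trips preserve them exactly.
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    abort(sprintf("file exists (use overwrite = TRUE): %s", path))
  }
  feat <- list()
  for (role in c("tumor", "stroma", "exclude")) {
    for (p in ann[[role]]) {
      ring <- lapply(seq_len(nrow(p)), function(i) list(p[i, 1], p[i, 2]))
      ring <- c(ring, ring[1])  # close the ring per GeoJSON convention
      feat <- c(feat, list(list(
        type = "Feature",
        properties = list(role = role),
        geometry = list(type = "Polygon", coordinates = list(ring)))))
    }
  }
  obj <- list(type = "FeatureCollection",
              properties = list(specimen_id = ann$specimen_id),
              features = feat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
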