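#' Labeled femoral point cloud
#'
#' The package's universal input is a tibble with one row per point: columns
#' `x`, `y`, `z` (millimetres) and an integer `label` coding the femoral
#' region (0 = head, 1 = neck, 2 = shaft). `labeled_cloud()` validates and
#' normalizes any data-frame-like input into this form.
#'
#' @param points Data frame with columns `x`, `y`, `z`, `label`, or an
#'   n x 3 matrix combined with `labels`.
#' @param labels Integer vector of region codes, required when `points` has
#'   no `label` column.
#' @param id Free-text specimen identifier stored in the `"id"` attribute.
#' @return A tibble of class `"labeled_cloud"` with columns `x,y,z,label`.
#' @examples
#' labeled_cloud(data.frame(x = 0:3, y = 0, z = 0, label = c(0, 1, 2, 2)))
#' @export
labeled_cloud <- function(points, labels = NULL, id = "specimen") {
  if (is.data.frame(points) && "label" %in% names(points) && is.null(labels)) {
    labels <- points$label
  }
  pts <- as_xyz_matrix(points)
  if (is.null(labels)) {
    abort("per-point `labels` are required", class = "nsafit_validation")
  }
  if (length(labels) != nrow(pts)) {
    abort(
      sprintf("%d points but %d labels", nrow(pts), length(labels)),
      class = "nsafit_validation"
    )
  }
  if (nrow(pts) < 4L) {
    abort("a labeled cloud needs at least 4 points", class = "nsafit_validation")
  }
  lab <- as.integer(labels)
  if (anyNA(lab) || any(abs(labels - lab) > 0)) {
    abort("labels must be integers", class = "nsafit_validation")
  }
  bad <- which(!lab %in% c(0L, 1L, 2L))
  if (length(bad) > 0L) {
    abort(
      sprintf("unknown label %d at point %d (labels are 0=head, 1=neck, 2=shaft)",
              lab[bad[1]], bad[1]),
      class = "nsafit_validation"
    )
  }
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3], label = lab)
  attr(out, "id") <- id
  class(out) <- c("labeled_cloud", class(out))
  out
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf(
    "<labeled_cloud> '%s': %d points (head %d, neck %d, shaft %d)\n",
    cloud_id(x), nrow(x), sum(x$label == 0), sum(x$label == 1), sum(x$label == 2)
  ))
  NextMethod()
}

cloud_id <- function(cloud) {
  id <- attr(cloud, "id", exact = TRUE)
  if (is.null(id)) "specimen" else id
}

region_points <- function(cloud, code, name) {
  pts <- as_xyz_matrix(cloud[cloud$label == code, c("x", "y", "z")])
  if (nrow(pts) == 0L) {
    abort(
      sprintf("cloud has no points labeled '%s' (%d)", name, code),
      class = "nsafit_validation"
    )
  }
  pts
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = "ply", xyz = "xyz", csv = "csv", txt = "xyz",
    abort(
      sprintf("cannot infer point-cloud format from '%s'; pass `format`", path),
      class = "nsafit_format"
    )
  )
}

#' Read a labeled point cloud
#'
#' Reads PLY (ascii or binary little-endian, requiring vertex properties
#' `x`, `y`, `z` and an integer property `label`), or 4-column XYZ/CSV text
#' (`x y z label`, comma- or whitespace-delimited with an optional header).
#' Point order is preserved from the file.
#'
#' @param path Input file path.
#' @param format One of `"ply"`, `"xyz"`, `"csv"`; inferred from the file
#'   extension by default.
#' @param id Specimen identifier; defaults to the file name without extension.
#' @return A [labeled_cloud()] tibble.
#' @export
read_cloud <- function(path, format = NULL, id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "nsafit_io")
  }
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("ply", "xyz", "csv"))
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  tab <- switch(format,
    ply = read_ply_table(path),
    xyz = read_delim_table(path),
    csv = read_delim_table(path)
  )
  labeled_cloud(tab, id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- delimited text (xyz / csv) ---------------------------------------------

read_delim_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("%s: empty file", path), class = "nsafit_format")
  }
  split_line <- function(s) {
    s <- trimws(s)
    if (grepl(",", s, fixed = TRUE)) {
      trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    } else {
      strsplit(s, "[[:space:]]+")[[1]]
    }
  }
  first <- split_line(lines[1])
  start <- 1L
  if (suppressWarnings(anyNA(as.numeric(first)))) {
    start <- 2L # header line
    if (length(lines) < 2L) {
      abort(sprintf("%s: header but no data rows", path), class = "nsafit_format")
    }
  }
  body <- lines[start:length(lines)]
  parsed <- lapply(seq_along(body), function(i) {
    f <- split_line(body[i])
    if (length(f) < 4L) {
      abort(
        sprintf("%s line %d: expected >= 4 columns (x y z label), got %d",
                path, i + start - 1L, length(f)),
        class = "nsafit_format"
      )
    }
    v <- suppressWarnings(as.numeric(f[1:4]))
    if (anyNA(v) || any(!is.finite(v[1:3]))) {
      abort(
        sprintf("%s line %d: non-finite or non-numeric coordinate", path, i + start - 1L),
        class = "nsafit_parse"
      )
    }
    v
  })
  m <- do.call(rbind, parsed)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], label = m[, 4])
}

# --- PLY --------------------------------------------------------------------

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4L, signed = FALSE),
    float = , float32 = list(what = "numeric", size = 4L, signed = TRUE),
    double = , float64 = list(what = "numeric", size = 8L, signed = TRUE),
    abort(sprintf("unsupported PLY property type '%s'", type), class = "nsafit_format")
  )
}

parse_ply_header <- function(con, path) {
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) {
    abort(sprintf("%s: not a PLY file", path), class = "nsafit_format")
  }
  format <- NULL
  elements <- list()
  current <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      abort(sprintf("%s: truncated PLY header", path), class = "nsafit_format")
    }
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      format <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(current)) elements[[current$name]] <- current
      current <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (identical(tok[2], "list")) {
        current$props[[length(current$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], item_type = tok[4])
      } else {
        current$props[[length(current$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(current)) elements[[current$name]] <- current
      break
    }
  }
  if (is.null(format) ||
      !format %in% c("ascii", "binary_little_endian")) {
    abort(
      sprintf("%s: unsupported PLY format '%s'", path, format %||% "<missing>"),
      class = "nsafit_format"
    )
  }
  list(format = format, elements = elements)
}

read_ply_table <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con, path)
  vert <- hdr$elements[["vertex"]]
  if (is.null(vert)) {
    abort(sprintf("%s: PLY has no vertex element", path), class = "nsafit_format")
  }
  pnames <- vapply(vert$props, `[[`, "", "name")
  need <- c("x", "y", "z", "label")
  missing <- setdiff(need, pnames)
  if (length(missing) > 0L) {
    abort(
      sprintf("%s: PLY vertex element lacks propert%s %s",
              path, if (length(missing) > 1) "ies" else "y",
              paste(missing, collapse = ", ")),
      class = "nsafit_format"
    )
  }
  if (any(vapply(vert$props, `[[`, TRUE, "list"))) {
    abort(sprintf("%s: list properties on vertex element are unsupported", path),
          class = "nsafit_format")
  }
  # vertex must be the first element for a sequential read; it always is for
  # the clouds this package writes and for common exporters
  if (names(hdr$elements)[1] != "vertex") {
    abort(sprintf("%s: vertex must be the first PLY element", path),
          class = "nsafit_format")
  }
  n <- vert$count
  np <- length(vert$props)
  if (hdr$format == "ascii") {
    lines <- readLines(con, n = n)
    if (length(lines) < n) {
      abort(sprintf("%s: expected %d vertex lines, found %d", path, n, length(lines)),
            class = "nsafit_parse")
    }
    vals <- lapply(seq_len(n), function(i) {
      f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]))
      if (length(f) < np || anyNA(f[seq_len(np)])) {
        abort(sprintf("%s: malformed vertex record %d", path, i), class = "nsafit_parse")
      }
      f[seq_len(np)]
    })
    m <- do.call(rbind, vals)
  } else {
    infos <- lapply(vert$props, function(p) ply_type_info(p$type))
    sizes <- vapply(infos, `[[`, 0L, "size")
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = n * stride)
    if (length(raw) < n * stride) {
      abort(sprintf("%s: truncated PLY vertex data", path), class = "nsafit_parse")
    }
    m <- matrix(0, n, np)
    offset <- c(0L, cumsum(sizes))
    for (j in seq_len(np)) {
      idx <- rep(offset[j] + seq_len(sizes[j]), n) +
        rep((seq_len(n) - 1L) * stride, each = sizes[j])
      col <- readBin(
        raw[idx], infos[[j]]$what, n = n, size = sizes[j],
        signed = if (sizes[j] >= 4L) TRUE else infos[[j]]$signed,
        endian = "little"
      )
      m[, j] <- col
    }
  }
  colnames(m) <- pnames
  bad <- which(!is.finite(m[, "x"]) | !is.finite(m[, "y"]) | !is.finite(m[, "z"]))
  if (length(bad) > 0L) {
    abort(sprintf("%s: non-finite coordinate at vertex %d", path, bad[1]),
          class = "nsafit_parse")
  }
  data.frame(x = m[, "x"], y = m[, "y"], z = m[, "z"], label = m[, "label"])
}

#' Write a labeled point cloud
#'
#' Writes PLY (ascii by default, or binary little-endian), or XYZ/CSV text.
#' Coordinates survive a round trip through [read_cloud()] to at least 1e-6
#' mm (text formats use 9 significant digits; binary PLY stores doubles) and
#' labels survive exactly.
#'
#' @param cloud A [labeled_cloud()] (or data frame with `x,y,z,label`).
#' @param path Output file path.
#' @param format `"ply"`, `"xyz"` or `"csv"`; inferred from the extension by
#'   default.
#' @param binary Write binary little-endian PLY instead of ascii.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = NULL, binary = FALSE) {
  cloud <- labeled_cloud(cloud, id = cloud_id(cloud))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("ply", "xyz", "csv"))
  ok <- tryCatch({
    switch(format,
      ply = write_ply(cloud, path, binary),
      xyz = writeLines(
        sprintf("%.9g %.9g %.9g %d", cloud$x, cloud$y, cloud$z, cloud$label),
        path
      ),
      csv = writeLines(
        c("x,y,z,label",
          sprintf("%.9g,%.9g,%.9g,%d", cloud$x, cloud$y, cloud$z, cloud$label)),
        path
      )
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
          class = "nsafit_io")
  }
  invisible(path)
}

write_ply <- function(cloud, path, binary = FALSE) {
  n <- nrow(cloud)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", n),
    "property double x", "property double y", "property double z",
    "property int label",
    "end_header"
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    for (i in seq_len(n)) {
      writeBin(c(cloud$x[i], cloud$y[i], cloud$z[i]), con,
               size = 8L, endian = "little")
      writeBin(cloud$label[i], con, size = 4L, endian = "little")
    }
  } else {
    writeLines(
      c(header, sprintf("%.9g %.9g %.9g %d", cloud$x, cloud$y, cloud$z, cloud$label)),
      path
    )
  }
  invisible(path)
}
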