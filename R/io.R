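#' Read a point cloud from PLY, OBJ or XYZ
#'
#' ASCII dialects only; coordinates are taken as stored with no unit
#' conversion, and colour/normal attributes are ignored.  XYZ files may
#' contain `#` comment lines.
#'
#' @param path file path.
#' @param format `"ply"`, `"obj"` or `"xyz"`; default inferred from the file
#'   extension.
#' @param frame frame label for the returned cloud.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = NULL, frame = "raw") {
  format <- .guess_format(path, format, c("ply", "obj", "xyz"))
  lines <- .read_nonempty(path)
  pts <- switch(format,
    xyz = .parse_xyz(lines, path),
    obj = .parse_obj(lines, path)$vertices,
    ply = .parse_ply(lines, path)$vertices)
  if (nrow(pts) == 0)
    stop(sprintf("no points found in '%s'", path))
  point_cloud(pts, frame)
}

#' Read a triangle mesh from PLY or OBJ
#'
#' @inheritParams read_point_cloud
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL, frame = "world") {
  format <- .guess_format(path, format, c("ply", "obj"))
  lines <- .read_nonempty(path)
  parsed <- if (format == "obj") .parse_obj(lines, path)
            else .parse_ply(lines, path)
  if (is.null(parsed$faces) || nrow(parsed$faces) == 0)
    stop(sprintf("'%s' contains no faces", path))
  triangle_mesh(parsed$vertices, parsed$faces, frame)
}

#' Write a point cloud
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"ply"`, `"obj"` or `"xyz"` (default from extension).
#' @param digits significant digits written (default 9); `NA` writes full
#'   binary-exact precision (`%.17g`).
#' @export
write_point_cloud <- function(cloud, path, format = NULL, digits = 9) {
  cloud <- as_point_cloud(cloud)
  format <- .guess_format(path, format, c("ply", "obj", "xyz"))
  num <- .num_formatter(digits)
  rows <- apply(cloud$points, 1, function(r) paste(num(r), collapse = " "))
  txt <- switch(format,
    xyz = c("# x y z (metres)", rows),
    obj = paste("v", rows),
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(cloud$points)),
            "property double x", "property double y", "property double z",
            "element face 0", "property list uchar int vertex_indices",
            "end_header", rows))
  writeLines(txt, path)
  invisible(path)
}

#' Write a triangle mesh to PLY or OBJ
#'
#' The mesh must validate (watertight, consistently wound); vertices are
#' written at the stated precision and faces as stored, so winding and signed
#' volume survive a round trip.  OBJ face indices are 1-based on disk.
#'
#' @param mesh a [triangle_mesh()].
#' @inheritParams write_point_cloud
#' @export
write_mesh <- function(mesh, path, format = NULL, digits = 9) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  .assert_integrable(mesh)
  format <- .guess_format(path, format, c("ply", "obj"))
  num <- .num_formatter(digits)
  vrows <- apply(mesh$vertices, 1, function(r) paste(num(r), collapse = " "))
  txt <- if (format == "obj") {
    c(paste("v", vrows),
      paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]))
  } else {
    c("ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(mesh$vertices)),
      "property double x", "property double y", "property double z",
      sprintf("element face %d", nrow(mesh$faces)),
      "property list uchar int vertex_indices",
      "end_header", vrows,
      paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
            mesh$faces[, 3] - 1L))
  }
  writeLines(txt, path)
  invisible(path)
}

.guess_format <- function(path, format, allowed) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, allowed)
  format
}

.num_formatter <- function(digits) {
  fmt <- if (is.na(digits)) "%.17g" else paste0("%.", digits, "g")
  function(x) sprintf(fmt, x)
}

.read_nonempty <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop(sprintf("'%s' is empty", path))
  lines
}

.parse_xyz <- function(lines, path) {
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  vals <- lapply(keep, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) < 3 || anyNA(v[1:3]))
      stop(sprintf("%s:%d: cannot parse coordinates from '%s'",
                   path, i, lines[i]), call. = FALSE)
    v[1:3]
  })
  do.call(rbind, vals)
}

.parse_obj <- function(lines, path) {
  vidx <- grep("^v\\s", lines)
  fidx <- grep("^f\\s", lines)
  verts <- lapply(vidx, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]][-1]))
    if (length(v) < 3 || anyNA(v[1:3]))
      stop(sprintf("%s:%d: malformed vertex line", path, i), call. = FALSE)
    v[1:3]
  })
  faces <- lapply(fidx, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
    v <- suppressWarnings(as.integer(sub("/.*$", "", tok)))
    if (length(v) != 3 || anyNA(v))
      stop(sprintf("%s:%d: only triangular faces are supported", path, i),
           call. = FALSE)
    v
  })
  list(vertices = do.call(rbind, verts),
       faces = if (length(faces)) do.call(rbind, faces) else NULL)
}

.parse_ply <- function(lines, path) {
  if (trimws(lines[1]) != "ply")
    stop(sprintf("%s:1: not a PLY file (missing 'ply' magic)", path),
         call. = FALSE)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end))
    stop(sprintf("%s: PLY header has no end_header", path), call. = FALSE)
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (any(grepl("^format\\s+binary", hdr)))
    stop(sprintf("%s: binary PLY is not supported; export ASCII", path),
         call. = FALSE)
  elem_lines <- grep("^element\\s", hdr)
  elems <- list()
  for (k in seq_along(elem_lines)) {
    tok <- strsplit(hdr[elem_lines[k]], "\\s+")[[1]]
    upto <- if (k < length(elem_lines)) elem_lines[k + 1] - 1 else length(hdr)
    props <- hdr[seq(elem_lines[k] + 1, upto)]
    props <- props[grepl("^property\\s", props)]
    elems[[tok[2]]] <- list(count = as.integer(tok[3]), props = props)
  }
  if (is.null(elems$vertex))
    stop(sprintf("%s: PLY file has no vertex element", path), call. = FALSE)
  vp <- vapply(strsplit(elems$vertex$props, "\\s+"), function(t) t[length(t)], "")
  ixyz <- match(c("x", "y", "z"), vp)
  if (anyNA(ixyz))
    stop(sprintf("%s: PLY vertex element lacks x/y/z properties", path),
         call. = FALSE)
  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  nv <- elems$vertex$count
  if (length(body) < nv)
    stop(sprintf("%s: header promises %d vertices, found %d data rows",
                 path, nv, length(body)), call. = FALSE)
  verts <- t(vapply(seq_len(nv), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (anyNA(v[ixyz]))
      stop(sprintf("%s: vertex row %d is malformed", path, i), call. = FALSE)
    v[ixyz]
  }, numeric(3)))
  faces <- NULL
  nf <- if (is.null(elems$face)) 0L else elems$face$count
  if (nf > 0) {
    frows <- body[nv + seq_len(nf)]
    faces <- t(vapply(seq_len(nf), function(i) {
      v <- suppressWarnings(as.integer(strsplit(trimws(frows[i]), "\\s+")[[1]]))
      if (anyNA(v) || v[1] != 3L)
        stop(sprintf("%s: face row %d is not a triangle", path, i),
             call. = FALSE)
      v[2:4] + 1L
    }, integer(3)))
  }
  list(vertices = verts, faces = faces)
}

#' Read and write landmark sets as JSON
#'
#' Format: one JSON object mapping landmark names to `[x, y, z]` in metres.
#'
#' @param path file path.
#' @param landmarks a [landmark_set()].
#' @return `read_landmarks()` returns a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(lapply(obj, as.numeric))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- stats::setNames(
    lapply(seq_len(nrow(landmarks)),
           function(i) c(landmarks$x[i], landmarks$y[i], landmarks$z[i])),
    landmarks$name)
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write segmentation configurations (YAML or JSON)
#'
#' The configuration mirrors [body_segmentation()]: a top-level `segments`
#' list, each entry with `name`, `side`, `density_kg_m3`, `proximal`,
#' `distal`, `axis`, optional `group`, and `planes` (each with `origin`,
#' `normal` -- a two-name landmark pair or a literal 3-vector -- and `side`
#' `"+"`/`"-"`).
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param seg a [body_segmentation()].
#' @return `read_segmentation()` returns a [body_segmentation()].
#' @export
read_segmentation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$segments)) stop("segmentation config needs a 'segments' list")
  segs <- lapply(obj$segments, function(s) {
    planes <- lapply(s$planes, function(p) {
      nrm <- if (is.character(unlist(p$normal))) as.character(unlist(p$normal))
             else as.numeric(unlist(p$normal))
      plane(p$origin, nrm, p$side)
    })
    segment_spec(s$name, s$side %||% "central",
                 s$density_kg_m3 %||% 1000, planes,
                 proximal = s$proximal, distal = s$distal,
                 axis = s$axis %||% "z", group = s$group)
  })
  body_segmentation(segs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_segmentation
#' @export
write_segmentation <- function(seg, path) {
  ext <- tolower(tools::file_ext(path))
  obj <- list(segments = lapply(unname(seg$segments), function(s) {
    list(name = s$name, side = s$side, group = s$group,
         density_kg_m3 = s$density,
         proximal = s$proximal, distal = s$distal, axis = s$axis,
         planes = lapply(s$planes, function(p)
           list(origin = p$origin, normal = p$normal, side = p$side)))
  }))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Write a BSP report
#'
#' CSV: a `#`-prefixed header block (subject id, mass, height, pro-rata
#' factor, options, column units) followed by one row per segment with the
#' fields of the `segments` table, numbers at 6 significant digits.  JSON:
#' the same content at full precision.
#'
#' @param bsp a [body_bsp()] result.
#' @param path output path (`.csv` or `.json`).
#' @param timestamp include a generation timestamp in the header (off by
#'   default so identical runs produce byte-identical reports).
#' @export
write_bsp_report <- function(bsp, path, timestamp = FALSE) {
  stopifnot(inherits(bsp, "body_bsp"))
  ext <- tolower(tools::file_ext(path))
  header <- list(
    subject_id = bsp$subject$id,
    subject_mass_kg = bsp$subject$mass,
    subject_height_m = bsp$subject$height,
    scaling_factor_s = bsp$scaling_factor,
    unscaled_hull_mass_total_kg = bsp$unscaled_hull_mass_total,
    subdivided_groups = paste(bsp$options$subdivide, collapse = ","),
    cut_fractions = paste(bsp$options$cut_fractions, collapse = ","),
    foot_factor = bsp$options$foot_factor,
    note = paste("volumes are unscaled hull volumes (foot-corrected);",
                 "masses and inertia are scaled by s;",
                 "inertia about segment CoM in segment-anatomical axes;",
                 "products of inertia signed (Ixy = -integral rho x y dV)"))
  if (timestamp) header$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  if (ext == "json") {
    seg <- bsp$segments
    seg$abs_Ixy <- abs(seg$Ixy); seg$abs_Ixz <- abs(seg$Ixz)
    seg$abs_Iyz <- abs(seg$Iyz)
    jsonlite::write_json(list(header = header, segments = seg), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    lines <- c(sprintf("# %s: %s", names(header),
                       vapply(header, function(v) paste(format(v), collapse = ","), "")),
               "# units: lengths m, volume m^3, mass kg, inertia kg*m^2, com/mass percentages %")
    df <- bsp$segments
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, 6)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(lines, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  invisible(path)
}
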