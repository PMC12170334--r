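# ASCII readers/writers for the surface-mesh formats used in clinical
# hemodynamics pipelines (VTK legacy polydata, VTP, STL, PLY) plus CSV for
# waveforms and electroanatomical clouds. Labels travel as an integer
# point-data array "region_label" where the format supports fields.

label_to_int <- function(labels) match(labels, LABEL_LEVELS) - 1L
int_to_label <- function(codes) LABEL_LEVELS[codes + 1L]

#' Write a surface mesh (format inferred from the extension)
#'
#' Supports `.vtk` (legacy ASCII polydata), `.vtp` (XML polydata, ASCII),
#' `.stl` (ASCII; drops labels and fields with a warning) and `.ply`
#' (ASCII, labels as a per-vertex integer property). Scalar fields are
#' written as point-data arrays where supported.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; extension picks the format.
#' @param fields named list of per-vertex numeric vectors to attach.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, fields = list()) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = write_vtk_legacy(mesh, path, fields),
         vtp = write_vtp(mesh, path, fields),
         stl = {
           if (length(fields) || length(unique(mesh$labels)) > 1L)
             warning("STL stores geometry only; labels and fields dropped")
           write_stl_ascii(mesh, path)
         },
         ply = write_ply_ascii(mesh, path),
         stop("unknown mesh format: .", ext))
  invisible(path)
}

#' Read a surface mesh (format inferred from the extension)
#' @param path input path (`.vtk`, `.vtp`, `.stl`, `.ply`).
#' @return a [surface_mesh()]; point-data arrays are attached as the
#'   `"fields"` attribute (named list).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = read_vtk_legacy(path),
         vtp = read_vtp(path),
         stl = read_stl_ascii(path),
         ply = read_ply_ascii(path),
         stop("unknown mesh format: .", ext))
}

fmt_num <- function(x) sprintf("%.17g", x)

write_vtk_legacy <- function(mesh, path, fields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; tr <- mesh$triangles
  writeLines(c("# vtk DataFile Version 3.0", "surface mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(apply(v, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4L * nrow(tr)), con)
  writeLines(apply(tr - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
  writeLines(c("SCALARS region_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(label_to_int(mesh$labels)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(fmt_num(as.numeric(fields[[nm]])), con)
  }
  path
}

read_vtk_legacy <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  if (!length(ip)) stop("malformed VTK file (no POINTS) at line 1: ", path)
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nums <- scan(text = lines[(ip + 1):length(lines)], what = numeric(),
               n = 3L * np, quiet = TRUE)
  v <- matrix(nums, np, 3L, byrow = TRUE)
  ipoly <- grep("^POLYGONS", lines)
  if (!length(ipoly)) stop("malformed VTK file (no POLYGONS): ", path)
  hdr <- strsplit(lines[ipoly], "\\s+")[[1]]
  nf <- as.integer(hdr[2]); ntok <- as.integer(hdr[3])
  toks <- scan(text = lines[(ipoly + 1):length(lines)], what = integer(),
               n = ntok, quiet = TRUE)
  conn <- matrix(toks, nf, ntok / nf, byrow = TRUE)
  if (any(conn[, 1] != 3L)) stop("non-triangular polygon in ", path)
  tr <- conn[, 2:4, drop = FALSE] + 1L
  labels <- NULL
  fields <- list()
  isc <- grep("^SCALARS", lines)
  for (s in isc) {
    nm <- strsplit(lines[s], "\\s+")[[1]][2]
    vals <- scan(text = lines[(s + 2):length(lines)], what = numeric(),
                 n = np, quiet = TRUE)
    if (nm == "region_label") labels <- int_to_label(as.integer(vals))
    else fields[[nm]] <- vals
  }
  m <- surface_mesh(v, tr, labels)
  attr(m, "fields") <- fields
  m
}

write_vtp <- function(mesh, path, fields = list()) {
  v <- mesh$vertices; tr <- mesh$triangles
  doc <- xml2::xml_new_root("VTKFile", type = "PolyData", version = "0.1",
                            byte_order = "LittleEndian")
  pd <- xml2::xml_add_child(doc, "PolyData")
  piece <- xml2::xml_add_child(pd, "Piece",
                               NumberOfPoints = as.character(nrow(v)),
                               NumberOfPolys = as.character(nrow(tr)))
  pdata <- xml2::xml_add_child(piece, "PointData")
  lab_arr <- xml2::xml_add_child(pdata, "DataArray", type = "Int32",
                                 Name = "region_label", format = "ascii")
  xml2::xml_text(lab_arr) <- paste(label_to_int(mesh$labels), collapse = " ")
  for (nm in names(fields)) {
    arr <- xml2::xml_add_child(pdata, "DataArray", type = "Float64",
                               Name = nm, format = "ascii")
    xml2::xml_text(arr) <- paste(fmt_num(as.numeric(fields[[nm]])),
                                 collapse = " ")
  }
  pts <- xml2::xml_add_child(piece, "Points")
  parr <- xml2::xml_add_child(pts, "DataArray", type = "Float64",
                              NumberOfComponents = "3", format = "ascii")
  xml2::xml_text(parr) <- paste(fmt_num(as.numeric(t(v))), collapse = " ")
  polys <- xml2::xml_add_child(piece, "Polys")
  conn <- xml2::xml_add_child(polys, "DataArray", type = "Int32",
                              Name = "connectivity", format = "ascii")
  xml2::xml_text(conn) <- paste(as.integer(t(tr)) - 1L, collapse = " ")
  offs <- xml2::xml_add_child(polys, "DataArray", type = "Int32",
                              Name = "offsets", format = "ascii")
  xml2::xml_text(offs) <- paste(seq_len(nrow(tr)) * 3L, collapse = " ")
  xml2::write_xml(doc, path)
  path
}

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("malformed VTP (no Piece): ", path)
  np <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  parr <- xml2::xml_find_first(piece, ".//Points/DataArray")
  v <- matrix(scan(text = xml2::xml_text(parr), what = numeric(),
                   quiet = TRUE), np, 3L, byrow = TRUE)
  conn <- xml2::xml_find_first(piece,
                               ".//Polys/DataArray[@Name='connectivity']")
  tr <- matrix(scan(text = xml2::xml_text(conn), what = integer(),
                    quiet = TRUE), ncol = 3L, byrow = TRUE) + 1L
  labels <- NULL; fields <- list()
  for (arr in xml2::xml_find_all(piece, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(arr, "Name")
    vals <- scan(text = xml2::xml_text(arr), what = numeric(), quiet = TRUE)
    if (identical(nm, "region_label"))
      labels <- int_to_label(as.integer(vals))
    else fields[[nm]] <- vals
  }
  m <- surface_mesh(v, tr, labels)
  attr(m, "fields") <- fields
  m
}

write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nrm <- cross3(e1, e2)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  writeLines("solid mesh", con)
  for (t in seq_len(nrow(tr))) {
    writeLines(sprintf("  facet normal %s", paste(fmt_num(nrm[t, ]),
                                                  collapse = " ")), con)
    writeLines("    outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("      vertex %s",
                         paste(fmt_num(v[tr[t, k], ]), collapse = " ")), con)
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
  path
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl)) stop("malformed STL (no vertex lines): ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  key <- apply(nums, 1, paste, collapse = "|")
  uniq <- !duplicated(key)
  vmap <- match(key, key[uniq])
  v <- nums[uniq, , drop = FALSE]
  tr <- matrix(vmap, ncol = 3L, byrow = TRUE)
  surface_mesh(v, tr)
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; tr <- mesh$triangles
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               "property int region_label",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  lab <- label_to_int(mesh$labels)
  writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3]), lab),
             con)
  writeLines(paste(3L, tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  path
}

read_ply_ascii <- function(path) {
  lines <- readLines(path)
  he <- match("end_header", lines)
  if (is.na(he)) stop("malformed PLY (no end_header): ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vlines <- lines[(he + 1):(he + nv)]
  vt <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), as.numeric))
  flines <- lines[(he + nv + 1):(he + nv + nf)]
  ft <- do.call(rbind, lapply(strsplit(flines, "\\s+"), as.integer))
  labels <- if (ncol(vt) >= 4) int_to_label(as.integer(vt[, 4])) else NULL
  surface_mesh(vt[, 1:3, drop = FALSE], ft[, 2:4, drop = FALSE] + 1L, labels)
}

#' Write / read an electroanatomical point cloud as CSV
#'
#' Columns `x_mm`, `y_mm`, `z_mm`, `bv_mV`.
#' @param cloud list with `points` (n x 3) and `bv`.
#' @param path file path.
#' @return `read_cloud_csv` returns a list with `points` and `bv`.
#' @export
write_cloud_csv <- function(cloud, path) {
  df <- data.frame(x_mm = cloud$points[, 1], y_mm = cloud$points[, 2],
                   z_mm = cloud$points[, 3], bv_mV = cloud$bv)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @export
read_cloud_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm", "bv_mV")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cloud CSV schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  list(points = as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), bv = df$bv_mV)
}

#' Write / read a velocity waveform as CSV
#'
#' Columns `time_s`, `velocity_m_per_s`; the period is stored as a comment
#' header line `# period_s=<T>`.
#' @param waveform a [velocity_waveform()].
#' @param path file path.
#' @return `read_waveform_csv` returns a [velocity_waveform()] (continuous
#'   evaluator rebuilt as a periodic spline).
#' @export
write_waveform_csv <- function(waveform, path) {
  con <- file(path, "w")
  writeLines(sprintf("# period_s=%s", fmt_num(waveform$period)), con)
  close(con)
  df <- data.frame(time_s = waveform$times,
                   velocity_m_per_s = waveform$velocity)
  suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  first <- readLines(path, n = 1L)
  period <- as.numeric(sub("# period_s=", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "velocity_m_per_s") %in% names(df)))
    stop("waveform CSV schema error: need time_s, velocity_m_per_s")
  velocity_waveform(df$time_s, df$velocity_m_per_s, period)
}
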