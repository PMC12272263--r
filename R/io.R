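#' Read and write surface meshes as ASCII PLY
#'
#' Minimal PLY support sufficient for triangle meshes: `write_ply` emits
#' ASCII PLY 1.0 with vertex x/y/z (and nx/ny/nz) and triangular faces;
#' `read_ply` reads ASCII PLY files with those elements (normals optional,
#' recomputed when absent). Binary PLY is not supported.
#'
#' @param mesh A [surface_mesh()].
#' @param path File path.
#' @return `read_ply` returns a [surface_mesh()]; `write_ply` returns `path`
#'   invisibly.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  writeLines(c(
    "ply", "format ascii 1.0", "comment tmstarget surface patch",
    paste("element vertex", nv),
    "property float x", "property float y", "property float z",
    "property float nx", "property float ny", "property float nz",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  vtx <- cbind(mesh$vertices, mesh$normals)
  writeLines(apply(format(vtx, digits = 9, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop_input("not a PLY file: ", path)
  if (!grepl("ascii", lines[2]))
    stop_input("only ASCII PLY is supported")
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vprops <- sub(".* ", "", grep("^property (float|double)", hdr, value = TRUE))
  vlines <- lines[hdr_end + seq_len(nv)]
  vm <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
               nrow = nv, byrow = TRUE)
  colnames(vm) <- vprops[seq_len(ncol(vm))]
  flines <- lines[hdr_end + nv + seq_len(nf)]
  fm <- matrix(as.integer(unlist(strsplit(trimws(flines), "\\s+"))),
               nrow = nf, byrow = TRUE)
  if (any(fm[, 1] != 3L)) stop_input("only triangular faces are supported")
  normals <- if (all(c("nx", "ny", "nz") %in% colnames(vm)))
    vm[, c("nx", "ny", "nz")] else NULL
  surface_mesh(vm[, c("x", "y", "z")], fm[, 2:4] + 1L, normals)
}

#' Parcellation, metric and placement table I/O
#'
#' Plain TSV interchange formats: parcellations as `vertex_index` (0-based)
#' plus `label`; per-vertex metrics (field magnitude, connectivity, EFSI) as
#' `vertex_index` plus a named value column; coil placements as a manifest
#' with `row`, `col`, `theta_deg` and the coil center coordinates.
#'
#' @param labels,path,values,name,placements Objects to write / file paths.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
write_parcellation <- function(labels, path) {
  df <- data.frame(vertex_index = seq_along(labels) - 1L,
                   label = as.integer(unclass(labels)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(as.integer(df$label[order(df$vertex_index)]),
            class = "parcellation_map")
}

#' @rdname write_parcellation
#' @export
write_metric <- function(values, path, name = "value") {
  df <- data.frame(vertex_index = seq_along(values) - 1L,
                   value = as.numeric(values))
  names(df)[2] <- name
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_metric <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  as.numeric(df[order(df$vertex_index), 2])
}

#' @rdname write_parcellation
#' @export
write_placements <- function(placements, path) {
  utils::write.table(placements, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_placements <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  class(df) <- c("coil_grid", class(df))
  df
}

#' Time-series matrix I/O
#'
#' Small fixtures travel as TSV (vertices in rows, timepoints in columns,
#' TR recorded on a leading comment line); larger matrices as a flat binary
#' of doubles with a JSON sidecar giving the dimensions and TR.
#'
#' @param ts A `time_series_matrix` (see [simulate_rfmri()]).
#' @param path Output path; the sidecar for binary I/O is `<path>.json`.
#' @param format `"tsv"` or `"bin"`.
#' @return Readers return a `time_series_matrix`; writers `path` invisibly.
#' @export
write_timeseries <- function(ts, path, format = c("tsv", "bin")) {
  format <- match.arg(format)
  tr <- attr(ts, "TR")
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# TR=%.10g", tr), con)
    utils::write.table(unclass(ts), con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    writeBin(as.vector(unclass(ts)), path, size = 8)
    jsonlite::write_json(
      list(n_vertices = nrow(ts), n_timepoints = ncol(ts), TR = tr),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, format = c("tsv", "bin")) {
  format <- match.arg(format)
  if (format == "tsv") {
    first <- readLines(path, n = 1)
    tr <- as.numeric(sub("# TR=", "", first))
    m <- as.matrix(utils::read.table(path, skip = 1, sep = "\t"))
    dimnames(m) <- NULL
  } else {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    m <- matrix(readBin(path, "double", meta$n_vertices * meta$n_timepoints),
                nrow = meta$n_vertices)
    tr <- meta$TR
  }
  time_series_matrix(m, tr)
}
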