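# Readers and writers for the standard formats the pipeline touches: NIfTI
# label volumes (via RNifti), NRRD label volumes (minimal attached-header
# reader/writer, raw or gzip encoded), 3D Slicer markups JSON control points,
# and per-frame measurement CSV/JSON.

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_nrrd_path <- function(path) grepl("\\.nrrd$", path, ignore.case = TRUE)

#' Read a label volume
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) or NRRD label volumes, populating voxels,
#' spacing and the voxel-to-world affine from the file metadata. Labels not in
#' the legend are reported with a warning.
#'
#' @param path file path.
#' @param legend named integer vector of expected labels.
#' @return a `label_volume`.
#' @export
read_label_volume <- function(path, legend = mv_label_legend()) {
  if (!file.exists(path)) mv_error("mv_format_error", paste("file not found:", path))
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim(img))
    affine <- matrix(c(RNifti::xform(img)), 4, 4)
    spacing <- RNifti::pixdim(img)[1:3]
  } else if (is_nrrd_path(path)) {
    nr <- read_nrrd(path)
    arr <- nr$data; affine <- nr$affine; spacing <- nr$spacing
  } else {
    mv_error("mv_format_error", "unsupported volume format (use .nii, .nii.gz or .nrrd)")
  }
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    mv_error("mv_metadata_error", "volume is missing positive voxel spacing metadata")
  if (is.double(arr)) {
    if (max(abs(arr - round(arr))) > 1e-6)
      mv_error("mv_format_error", "volume contains non-integer label values")
    arr <- round(arr)
  }
  storage.mode(arr) <- "integer"
  stray <- setdiff(unique(as.vector(arr)), legend)
  if (length(stray))
    warning(sprintf("volume contains labels outside the legend: {%s}",
                    paste(sort(stray), collapse = ", ")), call. = FALSE)
  label_volume(arr, spacing, affine, legend)
}

#' Write a label volume
#'
#' @param vol a `label_volume`.
#' @param path output path (`.nii`, `.nii.gz` or `.nrrd`).
#' @return the path, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  if (is_nifti_path(path)) {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$spacing_mm
    RNifti::qform(img) <- structure(vol$affine, code = 2L)
    RNifti::sform(img) <- structure(vol$affine, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (is_nrrd_path(path)) {
    write_nrrd(vol$voxels, path, affine = vol$affine)
  } else {
    mv_error("mv_format_error", "unsupported volume format")
  }
  invisible(path)
}

# ---- minimal NRRD (attached header, raw/gzip, little endian) ----

#' Read an NRRD volume (minimal attached-header support)
#'
#' Supports 3D integer/float data with `raw` or `gzip` encoding, `space
#' directions` and `space origin` metadata.
#'
#' @param path file path.
#' @return list with `data`, `spacing`, `affine`.
#' @export
read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # attached header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  for (t in seq_along(nl[-1])) {
    if (nl[t + 1L] == nl[t] + 1L ||
        (nl[t + 1L] == nl[t] + 2L && bytes[nl[t] + 1L] == as.raw(13L))) {
      hdr_end <- nl[t + 1L]; break
    }
  }
  if (is.na(hdr_end)) mv_error("mv_format_error", "NRRD header has no terminating blank line")
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) mv_error("mv_format_error", "not an NRRD file")
  fields <- list()
  for (line in hdr[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) fields[[trimws(tolower(kv[1]))]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  enc <- fields$encoding
  nbytes <- switch(type,
    "unsigned char" = , "uchar" = , "uint8" = , "uint8_t" = 1L,
    "short" = , "int16" = , "int16_t" = , "signed short" = 2L,
    "int" = , "int32" = , "int32_t" = , "signed int" = 4L,
    "float" = 4L, "double" = 8L,
    mv_error("mv_format_error", paste("unsupported NRRD type:", type)))
  raw_rest <- bytes[(hdr_end + 1L):length(bytes)]
  if (identical(enc, "gzip") || identical(enc, "gz")) {
    raw_rest <- memDecompress(raw_rest, type = "gzip")
  } else if (!identical(enc, "raw")) {
    mv_error("mv_format_error", paste("unsupported NRRD encoding:", enc))
  }
  n <- prod(sizes)
  what <- if (type %in% c("float", "double")) "double" else "integer"
  sz <- if (type == "double") 8L else if (type == "float") 4L else nbytes
  signed <- !(nbytes == 1L)
  vals <- readBin(raw_rest, what, n = n, size = sz, signed = signed,
                  endian = "little")
  data <- array(vals, dim = sizes)
  spacing <- rep(1, 3); affine <- NULL
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    M <- vapply(dirs, function(d)
      as.numeric(strsplit(gsub("[()]", "", d), ",")[[1]]), numeric(3))
    spacing <- sqrt(colSums(M^2))
    affine <- diag(4)
    affine[1:3, 1:3] <- M
  }
  if (!is.null(fields[["space origin"]])) {
    org <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
    if (is.null(affine)) affine <- diag(4)
    affine[1:3, 4] <- org
  }
  if (is.null(affine)) {
    if (!is.null(fields$spacings))
      spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
    affine <- diag(c(spacing, 1))
  }
  list(data = data, spacing = spacing, affine = affine)
}

#' Write an NRRD volume (attached header, gzip encoding)
#'
#' @param data 3D integer array.
#' @param path output path.
#' @param affine 4x4 voxel-to-world affine.
#' @return the path, invisibly.
#' @export
write_nrrd <- function(data, path, affine = diag(4)) {
  storage.mode(data) <- "integer"
  d <- dim(data)
  dirs <- paste(vapply(1:3, function(c)
    sprintf("(%g,%g,%g)", affine[1, c], affine[2, c], affine[3, c]), character(1)),
    collapse = " ")
  hdr <- c("NRRD0004",
           "# generated by mvquant",
           "type: int32",
           "dimension: 3",
           "space: left-posterior-superior",
           paste("sizes:", paste(d, collapse = " ")),
           paste("space directions:", dirs),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: gzip",
           sprintf("space origin: (%g,%g,%g)", affine[1, 4], affine[2, 4], affine[3, 4]),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  payload <- writeBin(as.vector(data), raw(), size = 4L, endian = "little")
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}

# ---- Slicer markups JSON ----

#' Read annulus control points from Slicer markups JSON
#'
#' Accepts both the modern `"position"` and legacy `"Position"` control-point
#' dialects. The coordinate convention is taken from the file's
#' `coordinateSystem` field unless overridden.
#'
#' @param path `.mrk.json` file path.
#' @param coords optional coordinate-convention override (e.g. "RAS", "LPS").
#' @return a `control_point_set`.
#' @export
read_markups <- function(path, coords = NULL) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) mv_error("mv_format_error",
                                               paste("malformed markups JSON:", conditionMessage(e))))
  mk <- doc$markups[[1]]
  if (is.null(mk)) mv_error("mv_format_error", "no markups entry in file")
  cp <- mk$controlPoints
  if (is.null(cp) || length(cp) < 4L)
    mv_error("mv_fit_error", "markups file must contain at least 4 control points")
  pts <- t(vapply(cp, function(p) {
    pos <- p$position %||% p$Position
    if (is.null(pos)) mv_error("mv_format_error", "control point without position")
    as.numeric(unlist(pos))
  }, numeric(3)))
  control_point_set(pts, frame_of_reference = coords %||% mk$coordinateSystem %||% "LPS")
}

#' Write control points as Slicer markups JSON
#'
#' @param cps a `control_point_set`.
#' @param path output `.mrk.json` path.
#' @return the path, invisibly.
#' @export
write_markups <- function(cps, path) {
  pts <- cps$points
  doc <- list(
    `@schema` = "https://raw.githubusercontent.com/slicer/slicer/master/Modules/Loadable/Markups/Resources/Schema/markups-schema-v1.0.3.json#",
    markups = list(list(
      type = "ClosedCurve",
      coordinateSystem = cps$frame_of_reference,
      controlPoints = lapply(seq_len(nrow(pts)), function(i)
        list(id = as.character(i), label = sprintf("A-%d", i),
             position = as.numeric(pts[i, ])))
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- measurements ----

#' Write per-frame measurements and curve summary
#'
#' Writes a CSV with one row per frame (frame, anterior_mm2, posterior_mm2,
#' annulus_mm2, ea_mm2) in frame order with fixed numeric formatting (so
#' identical inputs give byte-identical files), plus an optional JSON summary
#' (peak frame, mean/min/max effective area, frame count, gaps).
#'
#' @param curve an `ea_curve` from [compute_ea_curve()].
#' @param csv_path output CSV path.
#' @param summary_path optional output JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_measurements <- function(curve, csv_path, summary_path = NULL) {
  if (!inherits(curve, "ea_curve")) mv_error("mv_argument_error", "expected an ea_curve")
  rows <- lapply(curve$measurements, function(m) {
    a <- m$structure_areas_mm2
    data.frame(frame = m$frame_index,
               anterior_mm2 = sprintf("%.6f", a[["anterior"]]),
               posterior_mm2 = sprintf("%.6f", a[["posterior"]]),
               annulus_mm2 = sprintf("%.6f", a[["annulus"]]),
               ea_mm2 = sprintf("%.6f", m$effective_area_mm2))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$frame), ]
  con <- file(csv_path, "wb")
  write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  if (!is.null(summary_path)) {
    s <- summarize_curve(curve)
    s$gaps <- curve$gaps
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(csv_path)
}

#' Read a 4D sequence of label volumes
#'
#' Accepts either a directory of per-frame files (frame order = lexicographic
#' filename order) or a single 4D NIfTI file.
#'
#' @param path directory or 4D NIfTI path.
#' @param legend label legend passed to [read_label_volume()].
#' @return list of `label_volume` objects.
#' @export
read_frames <- function(path, legend = mv_label_legend()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(nii(\\.gz)?|nrrd)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(files) == 0L)
      mv_error("mv_format_error", "no volume files found in directory")
    return(lapply(files, read_label_volume, legend = legend))
  }
  if (!is_nifti_path(path))
    mv_error("mv_format_error", "expected a directory or a 4D NIfTI file")
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) != 4L) mv_error("mv_format_error", "file is not 4D")
  affine <- matrix(c(RNifti::xform(img)), 4, 4)
  spacing <- RNifti::pixdim(img)[1:3]
  lapply(seq_len(dim(arr)[4]), function(f) {
    a <- arr[, , , f]
    if (is.double(a)) a <- round(a)
    storage.mode(a) <- "integer"
    label_volume(a, spacing, affine, legend)
  })
}

#' Write a phantom sequence to disk
#'
#' Writes one NIfTI file per frame (`frame_000.nii.gz`, ...), a matching
#' markups file of annulus control points, and a truth JSON sidecar with the
#' analytic plane, per-frame effective areas and peak frame.
#'
#' @param seq result of [make_phantom_sequence()].
#' @param dir output directory (created if needed).
#' @param spec the `phantom_spec` used (for the control points).
#' @param n_control_points control points to export.
#' @return `dir`, invisibly.
#' @export
write_phantom_sequence <- function(seq, dir, spec, n_control_points = 12L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(seq$frames)) {
    write_label_volume(seq$frames[[f]],
                       file.path(dir, sprintf("frame_%03d.nii.gz", f - 1L)))
  }
  write_markups(make_annulus_control_points(spec, n_control_points),
                file.path(dir, "annulus.mrk.json"))
  truth <- seq$truth
  jsonlite::write_json(
    list(plane_normal = truth$plane_normal, plane_point = truth$plane_point,
         ea_per_frame_mm2 = truth$ea_per_frame_mm2, peak_frame = truth$peak_frame),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}
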