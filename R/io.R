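#' Construct a tree point cloud
#'
#' A `tree_cloud` is the basic container of the pipeline: one tree's 3D
#' points (meters, z up, z = 0 at the lowest generated/recorded point is not
#' enforced — all measurements are taken relative to the cloud's own lowest
#' point).
#'
#' @param points numeric matrix or data frame with columns x, y, z (m).
#' @param tree_id identifier.
#' @param source free-text provenance tag.
#' @return Object of class `tree_cloud`.
#' @export
tree_cloud <- function(points, tree_id = "tree", source = "") {
  m <- as.matrix(points)[, 1:3, drop = FALSE]
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  if (nrow(m) == 0) stopf("empty point cloud for tree '%s'", tree_id)
  if (!all(is.finite(m))) stopf("non-finite coordinates in cloud '%s'", tree_id)
  structure(list(tree_id = as.character(tree_id), points = m,
                 source = as.character(source)), class = "tree_cloud")
}

#' @export
print.tree_cloud <- function(x, ...) {
  bb <- apply(x$points, 2, range)
  cat(sprintf("<tree_cloud> '%s': %d points (%s)\n", x$tree_id,
              nrow(x$points), x$source))
  cat(sprintf("  x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] m\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' @export
plot.tree_cloud <- function(x, ..., max_points = 20000L) {
  p <- x$points
  if (nrow(p) > max_points)
    p <- p[seq(1L, nrow(p), length.out = max_points), , drop = FALSE]
  plot(p[, "x"], p[, "z"], pch = ".", xlab = "x (m)", ylab = "z (m)",
       main = sprintf("%s side elevation", x$tree_id), asp = 1, ...)
  invisible(x)
}

#' Read a point cloud from disk
#'
#' Supports whitespace-separated ASCII XYZ (`x y z [label]` per line) and
#' binary little-endian PLY with float64 (or float32) `x`, `y`, `z`
#' properties and an optional `uint32` tree label. Coordinates are returned
#' unchanged (no recentring).
#'
#' @param path file path.
#' @param format `"xyz"`, `"ply"`, or `"auto"` (by extension).
#' @param tree_id identifier for the resulting cloud.
#' @return A [tree_cloud()]; if the file carries labels, they are attached as
#'   attribute `"label"` on the points matrix.
#' @export
read_cloud <- function(path, format = c("auto", "xyz", "ply"), tree_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  m <- if (format == "xyz") read_xyz(path) else read_ply(path)
  id <- tree_id %||% sub("\\.[^.]*$", "", basename(path))
  lab <- attr(m, "label")
  cl <- tree_cloud(m, tree_id = id, source = sprintf("%s:%s", format, path))
  if (!is.null(lab)) attr(cl$points, "label") <- lab
  bb <- apply(cl$points, 2, range)
  tb_log("read %d points from %s; bbox x[%.2f,%.2f] y[%.2f,%.2f] z[%.2f,%.2f]",
         nrow(cl$points), path, bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2],
         bb[1, 3], bb[2, 3])
  cl
}

#' @noRd
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty point cloud file: %s", path)
  parts <- strsplit(trimws(lines), "[ \t,]+")
  ncol <- lengths(parts)
  bad <- which(ncol < 3L)
  if (length(bad))
    stopf("parse error in %s at line %d: expected 'x y z [label]'", path, bad[1])
  vals <- suppressWarnings(lapply(parts, as.numeric))
  nonfinite <- which(vapply(vals, function(v) any(!is.finite(v[1:3])), logical(1)))
  if (length(nonfinite))
    stopf("parse error in %s at line %d: non-numeric or non-finite coordinate",
          path, nonfinite[1])
  m <- do.call(rbind, lapply(vals, function(v) v[1:3]))
  colnames(m) <- c("x", "y", "z")
  if (any(ncol >= 4L)) {
    lab <- vapply(vals, function(v) if (length(v) >= 4) v[4] else NA_real_,
                  numeric(1))
    if (any(is.na(lab))) stopf("mixed labelled/unlabelled lines in %s", path)
    attr(m, "label") <- as.integer(lab)
  }
  m
}

#' Write a point cloud to disk
#'
#' @param cloud a [tree_cloud()] or a numeric matrix with columns x, y, z and
#'   optionally a 4th label column.
#' @param path output path.
#' @param format `"xyz"` (ASCII) or `"ply"` (binary little-endian float64).
#' @param digits significant digits for ASCII output (default keeps full
#'   float64 round-trip precision).
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "xyz", "ply"),
                        digits = 17L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  m <- if (inherits(cloud, "tree_cloud")) cloud$points else as.matrix(cloud)
  lab <- attr(m, "label")
  if (is.null(lab) && ncol(m) >= 4L) { lab <- as.integer(m[, 4]); m <- m[, 1:3] }
  if (format == "xyz") {
    txt <- apply(format(m[, 1:3, drop = FALSE], digits = digits,
                        scientific = FALSE, trim = TRUE), 1, paste,
                 collapse = " ")
    if (!is.null(lab)) txt <- paste(txt, lab)
    writeLines(txt, path)
  } else {
    write_ply(m, path, label = lab)
  }
  invisible(path)
}

#' @noRd
write_ply <- function(m, path, label = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(m)),
           "property double x", "property double y", "property double z")
  if (!is.null(label)) hdr <- c(hdr, "property uint32 tree")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con, sep = "\n")
  if (is.null(label)) {
    writeBin(as.vector(t(m[, 1:3, drop = FALSE])), con, size = 8,
             endian = "little")
  } else {
    # interleave per-vertex: 3 doubles + uint32
    for (i in seq_len(nrow(m))) {
      writeBin(as.double(m[i, 1:3]), con, size = 8, endian = "little")
      writeBin(as.integer(label[i]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' @noRd
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stopf("parse error in %s: missing end_header", path)
    hdr <- c(hdr, ln)
    if (identical(ln, "end_header")) break
  }
  if (!identical(hdr[1], "ply")) stopf("parse error in %s: not a PLY file", path)
  if (!any(grepl("binary_little_endian", hdr)))
    stopf("parse error in %s: only binary_little_endian PLY supported", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   hdr, value = TRUE)[1]))
  if (is.na(nv) || nv < 1) stopf("empty point cloud file: %s", path)
  props <- sub("^property ", "", grep("^property", hdr, value = TRUE))
  types <- vapply(strsplit(props, " "), `[`, "", 1L)
  names(types) <- vapply(strsplit(props, " "), `[`, "", 2L)
  sizes <- c(double = 8L, float64 = 8L, float = 4L, float32 = 4L,
             uint32 = 4L, int32 = 4L, uint = 4L, int = 4L)
  if (any(!types %in% names(sizes)))
    stopf("parse error in %s: unsupported property type", path)
  rec <- sum(sizes[types])
  raw <- readBin(con, "raw", n = nv * rec)
  if (length(raw) < nv * rec) stopf("parse error in %s: truncated payload", path)
  offs <- cumsum(c(0L, sizes[types][-length(types)]))
  names(offs) <- names(types)
  get_col <- function(nm) {
    tp <- types[[nm]]; sz <- sizes[[tp]]
    idx <- as.vector(outer(seq_len(sz), (seq_len(nv) - 1L) * rec + offs[[nm]], `+`))
    what <- if (tp %in% c("double", "float64", "float", "float32")) "double" else "integer"
    readBin(raw[idx], what, n = nv, size = sz, endian = "little")
  }
  m <- cbind(x = get_col("x"), y = get_col("y"), z = get_col("z"))
  if (any(!is.finite(m))) stopf("parse error in %s: non-finite coordinate", path)
  lab_name <- intersect(c("tree", "label"), names(types))
  if (length(lab_name)) attr(m, "label") <- as.integer(get_col(lab_name[1]))
  m
}

#' Split a labelled plot cloud into per-tree clouds
#'
#' Splitting is purely by the provided labels (segmentation of unlabelled
#' field data is out of scope and expected to be done upstream). Total point
#' count is conserved exactly.
#'
#' @param cloud matrix with columns x, y, z, label, or a [tree_cloud()] whose
#'   points carry a `"label"` attribute.
#' @param manifest optional manifest data frame (from [generate_plot()]);
#'   when given, tree ids are taken from it and unknown labels are an error.
#' @return List of [tree_cloud()]s, one per label.
#' @export
split_plot <- function(cloud, manifest = NULL) {
  if (inherits(cloud, "tree_cloud")) {
    lab <- attr(cloud$points, "label")
    if (is.null(lab)) stopf("cloud carries no labels")
    m <- cloud$points
  } else {
    m <- as.matrix(cloud)
    if (ncol(m) < 4) stopf("plot cloud must have a 4th label column")
    lab <- as.integer(m[, 4]); m <- m[, 1:3, drop = FALSE]
  }
  if (any(is.na(lab))) stopf("every point must be labelled")
  labs <- sort(unique(lab))
  if (!is.null(manifest)) {
    if (length(labs) > nrow(manifest) || any(labs < 1) ||
        any(labs > nrow(manifest)))
      stopf("unknown tree label(s): %s",
            paste(setdiff(labs, seq_len(nrow(manifest))), collapse = ", "))
  }
  out <- lapply(labs, function(l) {
    id <- if (!is.null(manifest)) manifest$tree_id[l] else sprintf("tree_%03d", l)
    tree_cloud(m[lab == l, , drop = FALSE], tree_id = id, source = "split_plot")
  })
  names(out) <- vapply(out, function(cl) cl$tree_id, "")
  out
}

#' Default pipeline configuration
#'
#' Central knobs of the measurement pipeline, with the slab and alpha-shape
#' settings used throughout: the DBH/fDBH slab is 1.2–1.4 m and the DTB slab
#' 4.0–4.5 m above the cloud's lowest point, and the concave hull uses a
#' tightness of alpha = 4 m^-1 (triangles kept when their circumradius is at
#' most 1/alpha).
#'
#' @param slice_dbh,slice_dtb numeric length-2 slabs `c(z_lo, z_hi)` in m.
#' @param alpha alpha-shape tightness (m^-1).
#' @param wood_density_kg_m3 wood density used to convert volume to mass.
#' @param patch_sizes_m QSM ensemble shell widths (m).
#' @param runs_per_size QSM runs per patch size.
#' @param monte_carlo_n Monte-Carlo draws for uncertainty propagation.
#' @param seed master seed; all stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(slice_dbh = c(1.2, 1.4), slice_dtb = c(4.0, 4.5),
                            alpha = 4.0, wood_density_kg_m3 = 330,
                            patch_sizes_m = c(0.3, 0.5, 0.8),
                            runs_per_size = 3L, monte_carlo_n = 1000L,
                            seed = 1L) {
  if (slice_dbh[1] >= slice_dbh[2] || slice_dtb[1] >= slice_dtb[2])
    stopf("slab z_lo must be below z_hi")
  assert_scalar_num(alpha, "alpha", 0, strict_lower = TRUE)
  assert_scalar_num(wood_density_kg_m3, "wood_density_kg_m3", 0,
                    strict_lower = TRUE)
  if (monte_carlo_n < 100) stopf("monte_carlo_n must be >= 100")
  structure(list(slice_dbh = slice_dbh, slice_dtb = slice_dtb, alpha = alpha,
                 wood_density_kg_m3 = wood_density_kg_m3,
                 patch_sizes_m = patch_sizes_m,
                 runs_per_size = as.integer(runs_per_size),
                 monte_carlo_n = as.integer(monte_carlo_n),
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys fall back
#' to the defaults.
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- formals(pipeline_config)
  args <- list()
  for (nm in names(defaults))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(pipeline_config, args)
}

#' Write a plot manifest as CSV
#'
#' Header: tree_id, height_true_m, dbh_true_m, total_volume_m3,
#' trunk_volume_m3, surface_area_m2, seed.
#' @param manifest manifest data frame from [generate_plot()].
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("tree_id", "height_true_m", "dbh_true_m", "total_volume_m3",
            "trunk_volume_m3", "surface_area_m2", "seed")
  write.csv(manifest[, cols], path, row.names = FALSE)
  invisible(path)
}
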