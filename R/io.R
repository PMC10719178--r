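#' Read and write voxel volumes as NIfTI-1
#'
#' Volumes are stored as `.nii.gz` with voxel sizes in the header; the
#' quantity tag goes into the NIfTI description-like sidecar written next to
#' the image (`<path>.json`).
#'
#' @param vol a `voxel_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  img <- RNifti::asNifti(vol$values, pixdim = vol$grid$voxel_size_mm)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(quantity = vol$quantity,
                            origin_mm = vol$grid$origin_mm,
                            voxel_size_mm = vol$grid$voxel_size_mm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @param path path of a previously written volume.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list(quantity = "other", origin_mm = NULL,
            voxel_size_mm = RNifti::pixdim(img)[1:3])
  vals <- array(as.numeric(img), dim(img))
  grid <- voxel_grid(dim(vals), as.numeric(meta$voxel_size_mm),
                     if (is.null(meta$origin_mm)) NULL
                     else as.numeric(meta$origin_mm))
  voxel_volume(vals, grid, meta$quantity)
}

#' Read and write projection sets
#'
#' The per-view bin values are stored as a 3-D NIfTI image
#' (`nu x nv x n_views`) and the acquisition geometry, kind tag and any
#' provenance in a JSON sidecar.
#'
#' @param p a `projection_set`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param provenance optional list stored alongside (seeds, histories, ...).
#' @export
write_projections <- function(p, path, provenance = NULL) {
  stopifnot(inherits(p, "projection_set"))
  img <- RNifti::asNifti(p$values,
                         pixdim = c(p$geometry$pitch_mm, 1))
  RNifti::writeNifti(img, path)
  g <- p$geometry
  jsonlite::write_json(list(kind = p$kind, n_views = g$n_views,
                            angles_deg = g$angles_deg, nu = g$nu, nv = g$nv,
                            pitch_mm = g$pitch_mm, radius_mm = g$radius_mm,
                            window_keV = g$window_keV,
                            provenance = provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- projection_geometry(n_views = meta$n_views, nu = meta$nu,
                              nv = meta$nv,
                              pitch_mm = as.numeric(meta$pitch_mm),
                              radius_mm = meta$radius_mm,
                              window_keV = as.numeric(meta$window_keV))
  p <- projection_set(array(as.numeric(img), dim(img)), geom, meta$kind)
  p$provenance <- meta$provenance
  p
}

#' Flat key-value configuration files
#'
#' A minimal TOML-style flat format: one `key = value` per line, `#`
#' comments, strings quoted, logicals `true`/`false`, numeric vectors in
#' square brackets. All seeds are mandatory, explicit entries - there is no
#' hidden entropy in pipeline configs.
#'
#' @param config a named list of scalars / numeric vectors / strings.
#' @param path file path.
#' @export
write_flat_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) ifelse(v, "true", "false")
    else if (length(v) > 1) paste0("[", paste(format(v, digits = 15), collapse = ", "), "]")
    else format(v, digits = 15)
  }
  lines <- vapply(names(config), function(k) paste(k, "=", fmt(config[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_flat_config
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("read_flat_config: cannot parse line: ", ln)
    key <- kv[2]; val <- trimws(kv[3])
    out[[key]] <-
      if (grepl('^".*"$', val)) sub('^"(.*)"$', "\\1", val)
      else if (val %in% c("true", "false")) val == "true"
      else if (grepl("^\\[.*\\]$", val))
        as.numeric(strsplit(gsub("[][]", "", val), ",")[[1]])
      else as.numeric(val)
  }
  out
}

# stable md5 hash of an R object (via serialisation to a temp file)
config_hash <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(obj, tf, version = 2)
  unname(tools::md5sum(tf))
}
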