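# File formats: NIfTI image series, Gmsh MSH 2.2 and legacy VTK meshes,
# CSV strain tables, YAML configuration, JSON reports.  The mesh formats
# are written/parsed here directly (ASCII, full precision) so that
# exported artifacts round-trip losslessly.

WS_REGION_PHYS_OFFSET <- 10L  # region physical ids = 11, 12, 13 in MSH

#' Write / read a cine image series as NIfTI
#'
#' Either a single 4D NIfTI volume or one 3D NIfTI per frame, in both
#' cases with a JSON sidecar carrying frame times and the ES/ED indices.
#'
#' @param series an [image_series()].
#' @param path output `.nii` file (4D) or directory (per-frame).
#' @param format `"4d"` or `"frames"`.
#' @return the main path, invisibly.
#' @export
write_image_series <- function(series, path, format = c("4d", "frames")) {
  format <- match.arg(format)
  meta <- list(frame_times = series$frame_times, es_index = series$es_index,
               ed_index = series$ed_index, normalized = series$normalized)
  if (format == "4d") {
    arr <- array(unlist(series$frames),
                 dim = c(dim(series$frames[[1]]), length(series$frames)))
    img <- RNifti::asNifti(arr, datatype = "double")
    img <- RNifti::`sform<-`(img, structure(series$affine, code = 2L))
    RNifti::writeNifti(img, path)
    sidecar <- paste0(tools::file_path_sans_ext(path, compression = TRUE), ".json")
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (f in seq_along(series$frames)) {
      img <- RNifti::asNifti(series$frames[[f]], datatype = "double")
      img <- RNifti::`sform<-`(img, structure(series$affine, code = 2L))
      RNifti::writeNifti(img, file.path(path, sprintf("frame_%03d.nii", f - 1)))
    }
    jsonlite::write_json(meta, file.path(path, "series.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^frame_\\d+\\.nii(\\.gz)?$",
                             full.names = TRUE))
    if (length(files) == 0) ws_stopf("no frame_*.nii files in %s", path)
    imgs <- lapply(files, RNifti::readNifti)
    frames <- lapply(imgs, function(x) array(as.numeric(x), dim = dim(x)))
    affine <- unclass(RNifti::xform(imgs[[1]]))
    meta <- jsonlite::read_json(file.path(path, "series.json"),
                                simplifyVector = TRUE)
  } else {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 4) ws_stopf("%s is not a 4D volume", path)
    frames <- lapply(seq_len(dim(img)[4]), function(f)
      array(as.numeric(img[, , , f]), dim = dim(img)[1:3]))
    affine <- unclass(RNifti::xform(img))
    sidecar <- paste0(tools::file_path_sans_ext(path, compression = TRUE), ".json")
    meta <- if (file.exists(sidecar))
      jsonlite::read_json(sidecar, simplifyVector = TRUE)
    else list(es_index = 1L, ed_index = 0L, frame_times = NULL,
              normalized = FALSE)
  }
  image_series(frames, affine, meta$frame_times, meta$es_index,
               meta$ed_index, normalized = isTRUE(meta$normalized))
}

# --- Gmsh MSH 2.2 -----------------------------------------------------------

#' Write / import a mesh (Gmsh MSH 2.2 or legacy VTK)
#'
#' The MSH file carries boundary triangles and tetrahedra as elements with
#' physical groups named after the surface tags and region labels; a
#' private `$LongAxis` section preserves the apex-to-base axis.  The VTK
#' file is a legacy ASCII unstructured grid with `region` and `surface`
#' cell-data arrays.  `import_mesh` dispatches on the file extension,
#' remaps tags through `tag_map`, and validates the result (every
#' boundary facet tagged, all four canonical surface tags present,
#' inverted tetrahedra re-oriented).
#'
#' @param mesh a [biv_mesh()].
#' @param path file path (`.msh` or `.vtk`).
#' @param tag_map optional named character vector renaming file tags to
#'   canonical ones, e.g. `c(lv = "LV_ENDO")`.
#' @return `import_mesh` returns a [biv_mesh()].
#' @export
write_mesh <- function(mesh, path) {
  switch(tolower(tools::file_ext(path)),
         msh = ws_write_msh(mesh, path),
         vtk = ws_write_vtk_mesh(mesh, path),
         ws_stopf("unsupported mesh format: .%s", tools::file_ext(path)))
  invisible(path)
}

#' @rdname write_mesh
#' @export
import_mesh <- function(path, tag_map = NULL) {
  if (!file.exists(path)) ws_stopf("mesh file not found: %s", path)
  raw <- switch(tolower(tools::file_ext(path)),
                msh = ws_read_msh(path),
                vtk = ws_read_vtk_mesh(path),
                ws_stopf("unsupported mesh format: .%s", tools::file_ext(path)))
  tags <- raw$facet_tags
  if (!is.null(tag_map)) {
    hit <- tags %in% names(tag_map)
    tags[hit] <- tag_map[tags[hit]]
  }
  biv_mesh(raw$nodes, raw$cells, facets = raw$facets, facet_tags = tags,
           regions = raw$regions, long_axis = raw$long_axis %||% c(0, 0, 1),
           require_tags = TRUE)
}

ws_write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  has_regions <- !is.null(mesh$regions)
  phys <- c(sprintf('2 %d "%s"', WS_TAG_IDS, WS_TAGS),
            if (has_regions)
              sprintf('3 %d "%s"', WS_REGION_IDS + WS_REGION_PHYS_OFFSET,
                      WS_REGIONS))
  wl("$PhysicalNames", as.character(length(phys)), phys, "$EndPhysicalNames")
  wl("$Nodes", as.character(nrow(mesh$nodes)),
     sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$nodes)),
             mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]),
     "$EndNodes")
  ft <- WS_TAG_IDS[mesh$facet_tags]
  ft[is.na(ft)] <- 0L
  tri <- sprintf("%d 2 2 %d %d %d %d %d", seq_len(nrow(mesh$facets)),
                 ft, ft, mesh$facets[, 1], mesh$facets[, 2], mesh$facets[, 3])
  rid <- if (has_regions) WS_REGION_IDS[mesh$regions] + WS_REGION_PHYS_OFFSET
         else rep(0L, nrow(mesh$cells))
  tet <- sprintf("%d 4 2 %d %d %d %d %d %d",
                 nrow(mesh$facets) + seq_len(nrow(mesh$cells)),
                 rid, rid, mesh$cells[, 1], mesh$cells[, 2],
                 mesh$cells[, 3], mesh$cells[, 4])
  wl("$Elements", as.character(length(tri) + length(tet)), tri, tet,
     "$EndElements")
  wl("$LongAxis", sprintf("%.17g %.17g %.17g", mesh$long_axis[1],
                          mesh$long_axis[2], mesh$long_axis[3]),
     "$EndLongAxis")
}

ws_read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1))
      return(NULL)
    lines[(i0 + 1):(i1 - 1)]
  }
  nl <- sec("Nodes")
  if (is.null(nl)) ws_stopf("corrupt MSH file %s: no $Nodes section", path)
  n <- as.integer(nl[1])
  nm <- matrix(scan(text = nl[1 + seq_len(n)], quiet = TRUE), ncol = 4,
               byrow = TRUE)
  nodes <- nm[order(nm[, 1]), 2:4, drop = FALSE]
  pn <- sec("PhysicalNames")
  phys_names <- character(0)
  if (!is.null(pn)) {
    for (ln in pn[-1]) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) >= 3)
        phys_names[parts[2]] <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
    }
  }
  el <- sec("Elements")
  if (is.null(el)) ws_stopf("corrupt MSH file %s: no $Elements section", path)
  ne <- as.integer(el[1])
  tris <- list(); tritag <- list(); tets <- list(); tetreg <- list()
  for (i in seq_len(ne)) {
    v <- as.integer(strsplit(trimws(el[1 + i]), "\\s+")[[1]])
    type <- v[2]; ntags <- v[3]
    phys <- if (ntags >= 1) v[4] else 0L
    conn <- v[(4 + ntags - 1 + 1):length(v)]
    if (type == 2) {
      tris[[length(tris) + 1]] <- conn
      tritag[[length(tritag) + 1]] <- phys
    } else if (type == 4) {
      tets[[length(tets) + 1]] <- conn
      tetreg[[length(tetreg) + 1]] <- phys
    }
  }
  if (length(tets) == 0) ws_stopf("MSH file %s contains no tetrahedra", path)
  tag_ids <- unlist(tritag)
  facet_tags <- unname(phys_names[as.character(tag_ids)])
  fall <- is.na(facet_tags) & tag_ids %in% WS_TAG_IDS
  facet_tags[fall] <- WS_TAGS[tag_ids[fall]]
  regions <- NULL
  reg_ids <- unlist(tetreg)
  if (length(reg_ids) > 0 && any(reg_ids > 0)) {
    rn <- unname(phys_names[as.character(reg_ids)])
    rfall <- is.na(rn) & (reg_ids - WS_REGION_PHYS_OFFSET) %in% WS_REGION_IDS
    rn[rfall] <- WS_REGIONS[reg_ids[rfall] - WS_REGION_PHYS_OFFSET]
    if (!anyNA(rn) && all(rn %in% WS_REGIONS)) regions <- rn
  }
  la <- sec("LongAxis")
  long_axis <- if (!is.null(la)) scan(text = la[1], quiet = TRUE) else NULL
  list(nodes = nodes,
       cells = do.call(rbind, tets),
       facets = if (length(tris)) do.call(rbind, tris) else NULL,
       facet_tags = if (length(tris)) facet_tags else NULL,
       regions = regions, long_axis = long_axis)
}

# --- legacy VTK unstructured grid ------------------------------------------

ws_write_vtk_mesh <- function(mesh, path, cell_vectors = NULL,
                              point_vectors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$cells); f <- nrow(mesh$facets)
  wl("# vtk DataFile Version 3.0", "warpstrain biventricular mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID",
     sprintf("POINTS %d double", n),
     sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
             mesh$nodes[, 3]),
     sprintf("CELLS %d %d", m + f, 5 * m + 4 * f),
     sprintf("4 %d %d %d %d", mesh$cells[, 1] - 1, mesh$cells[, 2] - 1,
             mesh$cells[, 3] - 1, mesh$cells[, 4] - 1),
     sprintf("3 %d %d %d", mesh$facets[, 1] - 1, mesh$facets[, 2] - 1,
             mesh$facets[, 3] - 1),
     sprintf("CELL_TYPES %d", m + f),
     rep("10", m), rep("5", f))
  rid <- if (is.null(mesh$regions)) rep(0L, m)
         else as.integer(WS_REGION_IDS[mesh$regions])
  ft <- WS_TAG_IDS[mesh$facet_tags]
  ft[is.na(ft)] <- 0L
  wl(sprintf("CELL_DATA %d", m + f),
     "SCALARS region int 1", "LOOKUP_TABLE default",
     as.character(c(rid, rep(0L, f))),
     "SCALARS surface int 1", "LOOKUP_TABLE default",
     as.character(c(rep(0L, m), ft)))
  if (!is.null(cell_vectors))
    for (nm in names(cell_vectors)) {
      v <- cell_vectors[[nm]]
      pad <- matrix(0, f, 3)
      vv <- rbind(v, pad)
      wl(sprintf("VECTORS %s double", nm),
         sprintf("%.17g %.17g %.17g", vv[, 1], vv[, 2], vv[, 3]))
    }
  if (!is.null(point_vectors)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(point_vectors)) {
      v <- point_vectors[[nm]]
      wl(sprintf("VECTORS %s double", nm),
         sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]))
    }
  }
}

ws_read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  find <- function(pat) grep(pat, lines)[1]
  ip <- find("^POINTS ")
  if (is.na(ip)) ws_stopf("corrupt VTK file %s: no POINTS (line %d)", path, 1)
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- find("^CELLS ")
  nc <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cell_lines <- lines[(ic + 1):(ic + nc)]
  conn <- lapply(strsplit(trimws(cell_lines), "\\s+"), as.integer)
  sizes <- vapply(conn, function(x) x[1], integer(1))
  tets <- do.call(rbind, lapply(conn[sizes == 4], function(x) x[-1] + 1L))
  tris <- if (any(sizes == 3))
    do.call(rbind, lapply(conn[sizes == 3], function(x) x[-1] + 1L)) else NULL
  get_scalar <- function(name) {
    i <- grep(paste0("^SCALARS ", name, " "), lines)[1]
    if (is.na(i)) return(NULL)
    vals <- scan(text = lines[(i + 2):(i + 1 + nc)], quiet = TRUE)
    vals
  }
  reg <- get_scalar("region")
  srf <- get_scalar("surface")
  regions <- NULL
  if (!is.null(reg)) {
    r <- reg[sizes == 4]
    if (all(r %in% WS_REGION_IDS)) regions <- WS_REGIONS[r]
  }
  facet_tags <- NULL
  if (!is.null(srf) && !is.null(tris)) {
    s <- srf[sizes == 3]
    facet_tags <- ifelse(s %in% WS_TAG_IDS, WS_TAGS[s], NA_character_)
  }
  list(nodes = nodes, cells = tets, facets = tris, facet_tags = facet_tags,
       regions = regions, long_axis = NULL)
}

#' Export a direction field for visual audit
#'
#' Writes the mesh with the triad vectors (`e_C`, `e_L`, `e_R`) as VTK
#' cell-data vectors.
#'
#' @param mesh a [biv_mesh()].
#' @param dirs a [build_directions()] field.
#' @param path output `.vtk` file.
#' @export
export_directions_vtk <- function(mesh, dirs, path) {
  ws_write_vtk_mesh(mesh, path,
                    cell_vectors = list(e_C = dirs$e_C, e_L = dirs$e_L,
                                        e_R = dirs$e_R))
  invisible(path)
}

#' Export a motion solution as per-frame VTK files
#'
#' One legacy VTK file per frame with nodal displacement vectors and the
#' per-cell Jacobian, plus a JSON run log.
#'
#' @param sol a `motion_solution` from [track_cycle()].
#' @param mesh the tracked [biv_mesh()].
#' @param dir output directory.
#' @export
write_motion_vtk <- function(sol, mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(sol$u)) {
    ws_write_vtk_mesh(mesh, file.path(dir, sprintf("frame_%03d.vtk", f - 1)),
                      cell_vectors = list(jacobian = cbind(sol$J[, f], 0, 0)),
                      point_vectors = list(displacement = sol$u[[f]]))
  }
  u_df <- do.call(rbind, lapply(seq_along(sol$u), function(f)
    data.frame(frame = f - 1, node = seq_len(nrow(sol$u[[f]])),
               ux = sol$u[[f]][, 1], uy = sol$u[[f]][, 2],
               uz = sol$u[[f]][, 3])))
  utils::write.csv(u_df, file.path(dir, "displacements.csv"),
                   row.names = FALSE)
  log <- lapply(sol$log, function(l)
    l[c("frame", "iterations", "energy", "converged", "line_search_failed")])
  jsonlite::write_json(list(es_index = sol$es_index, ed_index = sol$ed_index,
                            frames = log),
                       file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# --- tables and configs -----------------------------------------------------

#' Write / read strain-time curves as CSV
#'
#' Long format with columns region, component, frame, time_s,
#' strain_percent.
#'
#' @param curves a `strain_curves` object.
#' @param path CSV path.
#' @return `read_strain_csv` returns the data frame.
#' @export
write_strain_csv <- function(curves, path) {
  df <- as.data.frame(curves)
  utils::write.csv(df[, c("region", "component", "frame", "time_s",
                          "strain_percent")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strain_csv
#' @export
read_strain_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize / restore a phantom spec or warp config as YAML
#'
#' @param x a [phantom_spec()] or [warp_config()].
#' @param path YAML path.
#' @return the restored object, for the readers.
#' @export
write_config_yaml <- function(x, path) {
  obj <- unclass(x)
  obj$.class <- class(x)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class %||% ws_stopf("%s does not contain a warpstrain config", path)
  obj$.class <- NULL
  switch(cls,
         phantom_spec = do.call(phantom_spec, obj),
         warp_config = do.call(warp_config, obj),
         ws_stopf("unknown config class in %s: %s", path, cls))
}

#' Round-trip validation of produced files
#'
#' Re-reads files produced by this package and verifies that their
#' contents survive a write/read cycle (bitwise for NIfTI voxel data and
#' mesh connectivity; at stored precision for CSV).
#'
#' @param paths named list with any of `image` (a NIfTI path or frame
#'   directory), `mesh` (`.msh` or `.vtk`), `curves` (CSV), `config`
#'   (YAML).
#' @return named logical vector of per-file verdicts.
#' @export
read_write_roundtrips <- function(paths) {
  out <- logical(0)
  td <- tempfile("roundtrip")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  if (!is.null(paths$image)) {
    s1 <- read_image_series(paths$image)
    p2 <- file.path(td, "img.nii")
    write_image_series(s1, p2)
    s2 <- read_image_series(p2)
    out["image"] <- identical(s1$frames, s2$frames)
  }
  if (!is.null(paths$mesh)) {
    m1 <- import_mesh(paths$mesh)
    p2 <- file.path(td, "mesh.msh")
    write_mesh(m1, p2)
    m2 <- import_mesh(p2)
    out["mesh"] <- identical(m1$nodes, m2$nodes) &&
      identical(m1$cells, m2$cells) &&
      identical(m1$facet_tags, m2$facet_tags)
  }
  if (!is.null(paths$curves)) {
    d1 <- read_strain_csv(paths$curves)
    p2 <- file.path(td, "curves.csv")
    utils::write.csv(d1, p2, row.names = FALSE)
    d2 <- read_strain_csv(p2)
    out["curves"] <- isTRUE(all.equal(d1, d2, tolerance = 1e-12))
  }
  if (!is.null(paths$config)) {
    c1 <- read_config_yaml(paths$config)
    p2 <- file.path(td, "config.yaml")
    write_config_yaml(c1, p2)
    out["config"] <- isTRUE(all.equal(read_config_yaml(p2), c1,
                                      tolerance = 1e-9))
  }
  out
}
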