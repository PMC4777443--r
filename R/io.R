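# Plain-text interchange: aberrometry files (CSV with a metadata comment, or
# a one-object JSON form) and scene configuration files (YAML or JSON).

#' Write aberrometry to CSV
#'
#' Format: a `# pupil_radius_mm: <r>` comment line, then
#' `osa_index,coefficient_um` rows.
#' @param z a [zernike_coefficients()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aberrometry_csv <- function(z, path) {
  stopifnot(inherits(z, "zernike_coefficients"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pupil_radius_mm: %.10g", z$pupil_radius), con)
  utils::write.csv(data.frame(osa_index = seq_along(z$coeffs) - 1L,
                              coefficient_um = z$coeffs),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read aberrometry from CSV or JSON
#'
#' CSV: `osa_index,coefficient_um` columns plus a `# pupil_radius_mm:`
#' comment (or supply `pupil_radius`). JSON: one object with fields
#' `pupil_radius_mm` and `coefficients` (map from OSA index to um). Missing
#' indices read as zero.
#'
#' @param path input path (`.csv` or `.json`).
#' @param pupil_radius fallback pupil radius in mm if the file carries none.
#' @return a [zernike_coefficients()] object.
#' @export
read_aberrometry <- function(path, pupil_radius = NULL) {
  if (!file.exists(path)) stop("aberrometry file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    co <- unlist(obj$coefficients)
    return(zernike_coefficients(co, obj$pupil_radius_mm,
                                source_label = basename(path)))
  }
  hdr <- readLines(path, n = 3)
  m <- regmatches(hdr, regexpr("pupil_radius_mm:\\s*[0-9.]+", hdr))
  if (length(m)) pupil_radius <- as.numeric(sub(".*:\\s*", "", m[[1]]))
  if (is.null(pupil_radius))
    stop("no pupil radius in file and none supplied")
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("osa_index", "coefficient_um") %in% names(df)))
    stop("expected columns osa_index, coefficient_um")
  zernike_coefficients(stats::setNames(df$coefficient_um, df$osa_index),
                       pupil_radius, source_label = basename(path))
}

#' Write aberrometry to a one-object JSON file
#' @inheritParams write_aberrometry_csv
#' @export
write_aberrometry_json <- function(z, path) {
  stopifnot(inherits(z, "zernike_coefficients"))
  jsonlite::write_json(
    list(pupil_radius_mm = z$pupil_radius,
         coefficients = as.list(stats::setNames(z$coeffs,
                                                seq_along(z$coeffs) - 1L))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene configuration (YAML or JSON)
#'
#' Recognized keys: `eye` (aberrometry file path, resolved relative to the
#' config), `pupil_radius_mm`, `vertex_distance_mm`, `lenses` (list of
#' `[S, C, axis]` triples), `jcc` (`power`, `axis`, `flipped`, `active`,
#' `mode`), `contact_lens` (`zones`: list of `[outer_radius_mm, add_D]`).
#'
#' @param path config file path.
#' @return a [refraction_session()] with the configured scene.
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop("scene config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  eye_path <- cfg$eye
  if (!is.null(eye_path) && !file.exists(eye_path))
    eye_path <- file.path(dirname(path), eye_path)
  z <- if (is.null(eye_path)) make_eye("emmetrope") else
    read_aberrometry(eye_path)
  cl <- if (!is.null(cfg$contact_lens)) {
    zones <- do.call(rbind, lapply(cfg$contact_lens$zones, unlist))
    multifocal_design(data.frame(outer_radius = zones[, 1],
                                 add_power = zones[, 2]))
  } else NULL
  session <- refraction_session(
    z,
    pupil_radius = cfg$pupil_radius_mm %||% min(z$pupil_radius, 3),
    vertex_distance = cfg$vertex_distance_mm %||% 0,
    cl = cl)
  if (!is.null(cfg$lenses)) {
    lenses <- lapply(cfg$lenses, function(l) {
      l <- unlist(l); sphero_cylinder(l[1], l[2], l[3]) })
    session$phoropter$lenses <- lenses
  }
  if (!is.null(cfg$jcc)) {
    session$jcc <- jcc_state(
      power = cfg$jcc$power %||% 0.5, axis = cfg$jcc$axis %||% 0,
      flipped = isTRUE(cfg$jcc$flipped),
      active = !isFALSE(cfg$jcc$active),
      mode = cfg$jcc$mode %||% "axis-search")
  }
  session
}

`%||%` <- function(a, b) if (is.null(a)) b else a
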