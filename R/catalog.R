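# Examination catalog: the 40 whole-body joint RoM examination angles and the
# 13 IMU placement sites, loaded from a versioned YAML resource and validated.

.EXPECTED_SITES <- c("forehead", "th4", "l5s1",
                     "upper_arm_L", "upper_arm_R",
                     "forearm_L", "forearm_R",
                     "hand_L", "hand_R",
                     "upper_leg_L", "upper_leg_R",
                     "lower_leg_L", "lower_leg_R")

#' Path of the bundled examination catalog
#' @return file path of the default YAML catalog resource.
#' @export
default_catalog_path <- function() {
  system.file("extdata", "exam_catalog.yaml", package = "romexam",
              mustWork = TRUE)
}

#' Load and validate an examination catalog
#'
#' Reads a YAML catalog with `sites:` and `examinations:` lists and validates
#' the structural invariants of the whole-body examination set: exactly 13
#' sensor sites, 40 examination angles (10 active, 30 passive), unique ids,
#' orthonormal neutral segment axes, and resolvable site references.
#'
#' @param path path to a catalog YAML file; defaults to the bundled catalog.
#' @return an object of class `rom_catalog`: list with `sites` (named list of
#'   `SensorSite`) and `examinations` (named list of `ExaminationAngle`).
#' @export
load_catalog <- function(path = default_catalog_path()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("catalog parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(raw$sites) || is.null(raw$examinations))
    stop("catalog validation error: file must contain 'sites:' and 'examinations:' lists")

  sites <- lapply(raw$sites, .validate_site)
  names(sites) <- vapply(sites, `[[`, "", "site_id")
  if (anyDuplicated(names(sites)))
    stop("catalog validation error: duplicate site_id(s): ",
         paste(unique(names(sites)[duplicated(names(sites))]), collapse = ", "))
  if (length(sites) != 13L)
    stop("catalog validation error: expected 13 sensor sites, found ",
         length(sites))
  missing_sites <- setdiff(.EXPECTED_SITES, names(sites))
  if (length(missing_sites))
    stop("catalog validation error: missing sensor site(s): ",
         paste(missing_sites, collapse = ", "))

  exams <- lapply(raw$examinations, .validate_exam, site_ids = names(sites))
  ids <- vapply(exams, `[[`, "", "angle_id")
  if (anyDuplicated(ids))
    stop("catalog validation error: duplicate angle_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(exams) <- ids
  if (length(exams) != 40L)
    stop("catalog validation error: expected 40 examination angles, found ",
         length(exams))
  modes <- vapply(exams, `[[`, "", "mode")
  if (sum(modes == "active") != 10L || sum(modes == "passive") != 30L)
    stop("catalog validation error: expected 10 active and 30 passive entries, found ",
         sum(modes == "active"), " active / ", sum(modes == "passive"),
         " passive")

  structure(list(sites = sites, examinations = exams,
                 catalog_version = raw$catalog_version %||% 1L),
            class = "rom_catalog")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_site <- function(s) {
  for (f in c("site_id", "segment", "placement_note", "long_axis",
              "sagittal_axis"))
    if (is.null(s[[f]]))
      stop("catalog validation error: site entry missing field '", f, "'")
  long <- as.numeric(s$long_axis); sag <- as.numeric(s$sagittal_axis)
  if (length(long) != 3L || length(sag) != 3L)
    stop("catalog validation error: site '", s$site_id,
         "': neutral axes must be 3-vectors")
  if (abs(sum(long^2) - 1) > 1e-9 || abs(sum(sag^2) - 1) > 1e-9 ||
      abs(sum(long * sag)) > 1e-9)
    stop("catalog validation error: site '", s$site_id,
         "': neutral segment axes must be orthonormal (tolerance 1e-9)")
  structure(list(site_id = s$site_id, segment = s$segment,
                 placement_note = s$placement_note,
                 long_axis = long, sagittal_axis = sag),
            class = "rom_sensor_site")
}

.validate_exam <- function(e, site_ids) {
  for (f in c("angle_id", "joint", "nomenclature", "side", "mode", "method",
              "distal_site", "jcs_axis", "sign", "ref_range_1", "ref_range_2"))
    if (is.null(e[[f]]))
      stop("catalog validation error: examination entry ",
           e$angle_id %||% "<unnamed>", " missing field '", f, "'")
  if (!e$mode %in% c("active", "passive"))
    stop("catalog validation error: '", e$angle_id, "': bad mode '", e$mode, "'")
  if (!e$method %in% c("two_imu_relative", "single_imu_vs_start"))
    stop("catalog validation error: '", e$angle_id, "': bad method '",
         e$method, "'")
  if (!e$side %in% c("L", "R", "midline"))
    stop("catalog validation error: '", e$angle_id, "': bad side '", e$side, "'")
  if (!e$jcs_axis %in% c("flexion", "abduction", "rotation"))
    stop("catalog validation error: '", e$angle_id, "': bad jcs_axis '",
         e$jcs_axis, "'")
  if (!e$sign %in% c(1L, -1L, 1, -1))
    stop("catalog validation error: '", e$angle_id, "': sign must be +1 or -1")
  prox <- e$proximal_site
  if (e$method == "two_imu_relative") {
    if (is.null(prox))
      stop("catalog validation error: '", e$angle_id,
           "': two_imu_relative requires a proximal_site")
    if (!prox %in% site_ids)
      stop("catalog validation error: '", e$angle_id,
           "': unknown proximal_site '", prox, "'")
    if (identical(prox, e$distal_site))
      stop("catalog validation error: '", e$angle_id,
           "': proximal and distal sites must differ")
  } else if (!is.null(prox)) {
    stop("catalog validation error: '", e$angle_id,
         "': single_imu_vs_start must not name a proximal_site")
  }
  if (!e$distal_site %in% site_ids)
    stop("catalog validation error: '", e$angle_id, "': unknown distal_site '",
         e$distal_site, "'")
  r1 <- as.numeric(e$ref_range_1)
  if (length(r1) == 1L) r1 <- c(r1, r1)
  if (length(r1) != 2L || r1[1] > r1[2])
    stop("catalog validation error: '", e$angle_id,
         "': ref_range_1 must be a value or [low, high] with low <= high")
  structure(list(angle_id = e$angle_id, joint = e$joint,
                 nomenclature = e$nomenclature, side = e$side, mode = e$mode,
                 method = e$method, proximal_site = prox,
                 distal_site = e$distal_site, jcs_axis = e$jcs_axis,
                 sign = as.integer(e$sign), ref_range_1 = r1,
                 ref_range_2 = as.numeric(e$ref_range_2)),
            class = "rom_examination_angle")
}

#' Look up one examination angle
#' @param catalog a `rom_catalog`.
#' @param angle_id examination angle identifier, e.g. `"elbow_flexion_R"`.
#' @return the `ExaminationAngle` entry.
#' @export
lookup_examination <- function(catalog, angle_id) {
  stopifnot(inherits(catalog, "rom_catalog"))
  e <- catalog$examinations[[angle_id]]
  if (is.null(e))
    stop("examination angle not found in catalog: '", angle_id, "'")
  e
}

#' Look up one sensor site
#' @param catalog a `rom_catalog`.
#' @param site_id sensor site identifier, e.g. `"forearm_L"`.
#' @return the `SensorSite` entry.
#' @export
lookup_site <- function(catalog, site_id) {
  stopifnot(inherits(catalog, "rom_catalog"))
  s <- catalog$sites[[site_id]]
  if (is.null(s)) stop("sensor site not found in catalog: '", site_id, "'")
  s
}

#' Write a catalog back to YAML
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(cat, f))`
#' reproduces an identical catalog.
#'
#' @param catalog a `rom_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "rom_catalog"))
  sites <- lapply(unname(catalog$sites), function(s) {
    list(site_id = s$site_id, segment = s$segment,
         placement_note = s$placement_note,
         long_axis = as.list(s$long_axis),
         sagittal_axis = as.list(s$sagittal_axis))
  })
  exams <- lapply(unname(catalog$examinations), function(e) {
    out <- list(angle_id = e$angle_id, joint = e$joint,
                nomenclature = e$nomenclature, side = e$side, mode = e$mode,
                method = e$method, proximal_site = e$proximal_site,
                distal_site = e$distal_site, jcs_axis = e$jcs_axis,
                sign = e$sign, ref_range_1 = as.list(e$ref_range_1),
                ref_range_2 = e$ref_range_2)
    if (is.null(out$proximal_site)) out$proximal_site <- NULL
    out
  })
  yaml::write_yaml(list(catalog_version = catalog$catalog_version,
                        sites = sites, examinations = exams), path)
  invisible(path)
}

# World orientation (segment frame -> world) of a site's neutral posture.
# Segment frame: x = sagittal, z = long, y = z cross x (right-handed).
.site_neutral_quat <- function(site) {
  z <- site$long_axis; x <- site$sagittal_axis
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  quat_from_matrix(cbind(x, y, z))
}

#' @export
print.rom_catalog <- function(x, ...) {
  modes <- vapply(x$examinations, `[[`, "", "mode")
  cat("Joint RoM examination catalog (version ", x$catalog_version, ")\n",
      "  sensor sites:       ", length(x$sites), "\n",
      "  examination angles: ", length(x$examinations), " (",
      sum(modes == "active"), " active, ", sum(modes == "passive"),
      " passive)\n", sep = "")
  invisible(x)
}
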