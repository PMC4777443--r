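# Deterministic example eyes, defined by their summary properties only: one
# eye with pure low-order aberrations equivalent to a stated
# sphero-cylinder, and one eye with seeded random higher-order content
# scaled to a higher-order RMS of exactly 1.44 um. These are synthetic
# stand-ins generated from (kind, seed) — no real subject's individual
# coefficients are reproduced.

#' Build the aberrometry of an example eye
#'
#' * `"emmetrope"` — all-zero coefficients.
#' * `"P1_like"` — low-order-only eye whose full correction is
#'   `refraction` (default plano sphere with -0.75 D cylinder axis 180):
#'   the second-order terms are the negation of that correcting lens phase.
#' * `"P2_like"` — irregular-astigmatism eye: seeded random coefficients over
#'   radial orders 3-6 rescaled so the higher-order RMS is exactly
#'   `rms_hoa` (1.44 um), plus a fixed second-order component.
#' * `"random_loa"` — low-order-only eye with seeded sphere in
#'   `[-3, 3]` D and cylinder in `[-2, 0]` D at a random axis (parameter-
#'   recovery batteries); the generating refraction is attached as attribute
#'   `"refraction"`.
#'
#' @param kind one of `"P1_like"`, `"P2_like"`, `"emmetrope"`, `"random_loa"`.
#' @param seed integer seed for the random kinds.
#' @param pupil_radius measurement pupil radius in mm (default 3).
#' @param refraction the correcting [sphero_cylinder()] for `"P1_like"` /
#'   the default centre of `"random_loa"`.
#' @param rms_hoa target higher-order RMS in micrometres for `"P2_like"`
#'   (default 1.44).
#' @return a [zernike_coefficients()] object.
#' @export
make_eye <- function(kind = c("P1_like", "P2_like", "emmetrope", "random_loa"),
                     seed = 1L, pupil_radius = 3,
                     refraction = sphero_cylinder(0, -0.75, 180),
                     rms_hoa = 1.44) {
  kind <- match.arg(kind)
  eye_from_refraction <- function(sc) {
    z <- sphero_cylinder_to_zernike(sc, pupil_radius)
    zernike_coefficients(-z$coeffs, pupil_radius, source_label = kind)
  }
  if (kind == "emmetrope") {
    return(zernike_coefficients(numeric(15), pupil_radius,
                                source_label = "emmetrope"))
  }
  if (kind == "P1_like") {
    return(eye_from_refraction(as_sphero_cylinder(refraction)))
  }
  if (kind == "random_loa") {
    rng <- local({ set.seed(seed); list(
      s = round_quarter(stats::runif(1, -3, 3)),
      c = round_quarter(stats::runif(1, -2, 0)),
      a = sample(0:35, 1) * 5) })
    sc <- sphero_cylinder(rng$s, rng$c, rng$a)
    out <- eye_from_refraction(sc)
    attr(out, "refraction") <- sc
    return(out)
  }
  # P2_like: orders 3-6 random, scaled to the exact target RMS, plus a
  # fixed irregular second-order component (about -0.50 DS / -1.00 DC).
  j_hi <- nm_to_osa(3, -3):nm_to_osa(6, 6)     # OSA 6..27
  set.seed(seed)
  hi <- stats::rnorm(length(j_hi))
  nh <- osa_to_nm(j_hi)$n
  hi <- hi / nh                                 # damp the highest orders
  hi <- hi * (rms_hoa / sqrt(sum(hi^2)))
  lo <- -sphero_cylinder_to_zernike(sphero_cylinder(-0.5, -1.0, 60),
                                    pupil_radius)$coeffs
  co <- numeric(max(j_hi) + 1)
  co[seq_along(lo)] <- lo
  co[j_hi + 1] <- hi
  zernike_coefficients(stats::setNames(co, seq_along(co) - 1), pupil_radius,
                       source_label = "P2_like (synthetic)")
}

#' Load a two-subject coefficient table
#'
#' Reads a user-supplied CSV of OSA-ordered Zernike coefficients for two
#' measured subjects (columns `osa_index`, `P1`, `P2`, coefficients in um; a
#' `# pupil_radius_mm: <r>` comment line carries the measurement pupil).
#' Validates that the second subject's higher-order RMS is close to 1.44 um
#' and warns on mismatch.
#'
#' @param path path to the CSV file.
#' @param pupil_radius fallback measurement pupil radius in mm (default 3).
#' @return a list with `P1` and `P2` [zernike_coefficients()] objects.
#' @export
load_subject_table <- function(path, pupil_radius = 3) {
  if (!file.exists(path))
    stop("coefficient table not found at '", path, "'; no measured table ",
         "is bundled — generate synthetic stand-in eyes with make_eye()")
  hdr <- readLines(path, n = 5)
  m <- regmatches(hdr, regexpr("pupil_radius_mm[:,]\\s*[0-9.]+", hdr))
  if (length(m))
    pupil_radius <- as.numeric(sub(".*[:,]\\s*", "", m[[1]]))
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("osa_index", "P1", "P2")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  as_z <- function(col, label) {
    zernike_coefficients(stats::setNames(df[[col]], df$osa_index),
                         pupil_radius, source_label = label)
  }
  out <- list(P1 = as_z("P1", "P1"), P2 = as_z("P2", "P2"))
  rms2 <- zernike_rms(out$P2, 3)
  if (abs(rms2 - 1.44) > 0.05)
    warning(sprintf(
      "second subject's higher-order RMS is %.3f um (expected about 1.44)",
      rms2))
  out
}
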