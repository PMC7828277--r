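#' Compute a leadfield matrix for the cuffed nerve
#'
#' Maps unit source currents at positions inside the nerve to potentials at
#' the cuff contacts. Entry (i, j) is `1 / (4 * pi * sigma_eff * d)` where
#' `d` is the Euclidean source-contact distance and `sigma_eff` is the
#' length-weighted series (harmonic-mean) conductivity along the straight
#' segment from source j to contact i, split at its intersections with the
#' nested layer boundaries: endoneurium inside each fascicle, the
#' perineurium shell, the epineurium cylinder, and the epineurium-to-cuff
#' annulus divided at the encapsulation/saline boundary. The anisotropic
#' endoneurium contributes `sigma_long * cos(a)^2 + sigma_rad * sin(a)^2`
#' for a segment at angle `a` to the nerve axis.
#'
#' This is a straight-ray layered-conductivity approximation of a full
#' volume-conductor solution: it preserves the geometry, conductivity and
#' perturbation (encapsulation fill, cuff rotation) dependence of the gains
#' at desk scale, not absolute field accuracy.
#'
#' @param geometry A [cuff_geometry()].
#' @param tissue A [tissue_model()] (its `cuff_radius_mm` must match the
#'   geometry's).
#' @param source_positions N x 3 matrix of source coordinates in mm,
#'   strictly inside the epineurium.
#' @param rotation_deg Cuff rotation in degrees (default 0).
#' @param confinement Include the insulating-cuff confinement term
#'   (default TRUE). Inside an insulating cuff the far-field return
#'   current is squeezed into the conductive cross-section, so potentials
#'   acquire a quasi-one-dimensional component along the nerve axis: a
#'   "tent" profile `z_min * (L - z_max) / L` between the source and
#'   contact axial positions, scaled by the total axial conductance of
#'   the cross-section (endoneurium longitudinal + perineurium +
#'   epineurium + annulus, with the annulus conductivity the
#'   area-weighted mix of encapsulation and saline). The term is gated by
#'   the cuff/saline insulation contrast `1 - sigma_cuff / sigma_saline`,
#'   so it vanishes exactly in a homogeneous medium. No free parameters:
#'   geometry and conductivities determine it. This is the component
#'   through which encapsulation changes the spatial shape (not just the
#'   scale) of CAP signatures.
#' @return A `leadfield` object with fields `gains` (M x N, ohm),
#'   `source_positions`, `contact_positions`, `rotation_deg`,
#'   `encapsulation_fill`.
#' @export
compute_leadfield <- function(geometry, tissue, source_positions,
                              rotation_deg = 0, confinement = TRUE) {
  stopifnot(inherits(geometry, "cuff_geometry"),
            inherits(tissue, "tissue_model"))
  source_positions <- as.matrix(source_positions)
  if (ncol(source_positions) != 3L) {
    stop("`source_positions` must be an N x 3 matrix", call. = FALSE)
  }
  if (abs(geometry$cuff_radius_mm - tissue$cuff_radius_mm) > 1e-9) {
    stop("geometry and tissue disagree on the cuff radius", call. = FALSE)
  }
  r_src <- sqrt(source_positions[, 1]^2 + source_positions[, 2]^2)
  if (any(r_src >= tissue$epineurium_radius_mm)) {
    stop("all sources must lie strictly inside the epineurium",
         call. = FALSE)
  }
  contacts <- build_contact_positions(geometry, rotation_deg)
  n_src <- nrow(source_positions)
  gains <- matrix(NA_real_, nrow = geometry$n_contacts, ncol = n_src)
  circles <- boundary_circles(tissue)
  for (i in seq_len(geometry$n_contacts)) {
    p1 <- contacts[i, ]
    for (j in seq_len(n_src)) {
      gains[i, j] <- leadfield_entry(source_positions[j, ], p1,
                                     tissue, circles)
    }
  }
  if (confinement) {
    gains <- gains + confinement_gains(geometry, tissue, source_positions)
  }
  structure(list(
    gains = gains,
    source_positions = source_positions,
    contact_positions = contacts,
    contact_index = contact_index(geometry),
    rotation_deg = rotation_deg,
    encapsulation_fill = tissue$encapsulation_fill
  ), class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf(
    "<leadfield> %d contacts x %d sources, rotation %g deg, fill %.3f\n",
    nrow(x$gains), ncol(x$gains), x$rotation_deg, x$encapsulation_fill))
  invisible(x)
}

# Cylindrical boundaries (as xy circles) that a ray can cross, innermost out:
# each fascicle's endoneurium and perineurium surface, the epineurium
# surface, and the encapsulation/saline boundary when it is strictly inside
# the annulus.
boundary_circles <- function(tissue) {
  f <- tissue$fascicles
  th <- tissue$perineurium_thickness_mm
  circles <- list()
  for (k in seq_len(nrow(f))) {
    circles[[length(circles) + 1L]] <-
      c(f$center_x_mm[k], f$center_y_mm[k], f$radius_mm[k])
    circles[[length(circles) + 1L]] <-
      c(f$center_x_mm[k], f$center_y_mm[k], f$radius_mm[k] + th)
  }
  circles[[length(circles) + 1L]] <- c(0, 0, tissue$epineurium_radius_mm)
  r_enc <- encapsulation_boundary_mm(tissue)
  if (r_enc > tissue$epineurium_radius_mm + 1e-12 &&
      r_enc < tissue$cuff_radius_mm - 1e-12) {
    circles[[length(circles) + 1L]] <- c(0, 0, r_enc)
  }
  circles
}

# Single leadfield entry: harmonic (series) conductivity along the segment
# p0 -> p1, then the point-source kernel 1/(4 pi sigma d).
leadfield_entry <- function(p0, p1, tissue, circles = boundary_circles(tissue)) {
  delta <- p1 - p0
  d_mm <- sqrt(sum(delta^2))
  if (d_mm <= 0) stop("source coincides with a contact", call. = FALSE)
  # segment crossing parameters with each boundary circle (xy projection)
  dx <- delta[1]; dy <- delta[2]
  a <- dx * dx + dy * dy
  ts <- c(0, 1)
  if (a > 0) {
    for (cc in circles) {
      ex <- p0[1] - cc[1]; ey <- p0[2] - cc[2]
      b <- dx * ex + dy * ey
      c0 <- ex * ex + ey * ey - cc[3]^2
      disc <- b * b - a * c0
      if (disc > 0) {
        sq <- sqrt(disc)
        t1 <- (-b - sq) / a
        t2 <- (-b + sq) / a
        if (t1 > 0 && t1 < 1) ts <- c(ts, t1)
        if (t2 > 0 && t2 < 1) ts <- c(ts, t2)
      }
    }
  }
  ts <- sort(ts)
  tm <- (ts[-1] + ts[-length(ts)]) / 2 # midpoints classify each piece
  w <- diff(ts)
  keep <- w > 1e-12
  tm <- tm[keep]; w <- w[keep]
  # anisotropic endoneurium conductivity for this ray direction
  cos2 <- (delta[3] / d_mm)^2
  cond <- tissue$conductivities
  sigma_endo <- cond$endoneurium_longitudinal * cos2 +
    cond$endoneurium_radial * (1 - cos2)
  mx <- p0[1] + tm * dx
  my <- p0[2] + tm * dy
  sigma <- segment_sigmas(mx, my, tissue, sigma_endo)
  sigma_eff <- 1 / sum(w / sigma)
  1 / (4 * pi * sigma_eff * (d_mm * 1e-3))
}

# Classify xy points into tissue layers and return conductivities.
segment_sigmas <- function(mx, my, tissue, sigma_endo) {
  cond <- tissue$conductivities
  f <- tissue$fascicles
  th <- tissue$perineurium_thickness_mm
  sigma <- rep(NA_real_, length(mx))
  for (k in seq_len(nrow(f))) {
    dk <- sqrt((mx - f$center_x_mm[k])^2 + (my - f$center_y_mm[k])^2)
    inner <- is.na(sigma) & dk < f$radius_mm[k]
    shell <- is.na(sigma) & !inner & dk < f$radius_mm[k] + th
    sigma[inner] <- sigma_endo
    sigma[shell] <- cond$perineurium
  }
  r <- sqrt(mx^2 + my^2)
  r_enc <- encapsulation_boundary_mm(tissue)
  open <- is.na(sigma)
  sigma[open & r < tissue$epineurium_radius_mm] <- cond$epineurium
  open <- is.na(sigma)
  sigma[open & r < r_enc] <- cond$encapsulation
  open <- is.na(sigma)
  sigma[open & r <= tissue$cuff_radius_mm + 1e-9] <- cond$saline
  sigma[is.na(sigma)] <- cond$cuff
  sigma
}

#' Axial conductance of the cuffed cross-section
#'
#' Sum over layers of conductivity times cross-sectional area
#' (endoneurium uses its longitudinal conductivity; the annulus between
#' epineurium and cuff mixes encapsulation and saline by area according
#' to the fill fraction). Units: S * m (conductivity in S/m times area in
#' m^2).
#'
#' @param tissue A [tissue_model()].
#' @return Axial conductance in S * m.
#' @export
axial_conductance <- function(tissue) {
  cond <- tissue$conductivities
  f <- tissue$fascicles
  th <- tissue$perineurium_thickness_mm
  a_endo <- sum(pi * f$radius_mm^2)
  a_peri <- sum(pi * ((f$radius_mm + th)^2 - f$radius_mm^2))
  a_epi <- pi * tissue$epineurium_radius_mm^2 - a_endo - a_peri
  a_ann <- pi * (tissue$cuff_radius_mm^2 - tissue$epineurium_radius_mm^2)
  fill <- tissue$encapsulation_fill
  sigma_ann <- fill * cond$encapsulation + (1 - fill) * cond$saline
  g_mm2 <- cond$endoneurium_longitudinal * a_endo +
    cond$perineurium * a_peri +
    cond$epineurium * max(a_epi, 0) +
    sigma_ann * a_ann
  g_mm2 * 1e-6 # mm^2 -> m^2
}

# Quasi-1D cuff-confinement component of the leadfield: tent profile along
# the cuff between source and contact, scaled by the axial conductance and
# gated by the cuff insulation contrast.
confinement_gains <- function(geometry, tissue, source_positions) {
  cond <- tissue$conductivities
  eta <- max(0, min(1, 1 - cond$cuff / cond$saline))
  n_src <- nrow(source_positions)
  m <- geometry$n_contacts
  if (eta == 0) return(matrix(0, m, n_src))
  l_mm <- geometry$cuff_length_mm
  g_ax <- axial_conductance(tissue)
  z_c <- geometry$ring_axial_positions_mm[contact_index(geometry)$ring]
  z_s <- source_positions[, 3]
  inside <- z_s >= 0 & z_s <= l_mm
  z_lo <- outer(z_c, z_s, pmin)
  z_hi <- outer(z_c, z_s, pmax)
  tent_mm <- z_lo * (l_mm - z_hi) / l_mm
  tent_mm[, !inside] <- 0
  eta * (tent_mm * 1e-3) / g_ax
}
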