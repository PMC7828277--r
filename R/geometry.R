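#' Cuff electrode geometry
#'
#' Describes a multi-contact nerve cuff: `n_rings` rings of
#' `contacts_per_ring` contacts each, on the inner surface of a cylinder of
#' radius `cuff_radius_um` micrometres and length `cuff_length_mm`
#' millimetres. The default is the 7 x 8 = 56 contact layout used
#' throughout the study. Channels are numbered ring-major (ring 1 is the
#' proximal ring; within a ring, slots run counter-clockwise viewed from the
#' proximal end, slot 1 at angle 0 before any rotation offset).
#'
#' @param n_rings Number of contact rings (default 7).
#' @param contacts_per_ring Contacts per ring (default 8).
#' @param cuff_radius_um Inner cuff radius in micrometres (default 800).
#' @param cuff_length_mm Cuff length in millimetres (default 23).
#' @param ring_axial_positions_mm Axial (z) coordinates of the rings in mm,
#'   z = 0 at the proximal cuff edge. Default: evenly spaced with a 2.5 mm
#'   margin at each end.
#' @param rotation_offset_deg Rotation of the whole cuff around the nerve
#'   axis, in degrees (default 0).
#' @return A `cuff_geometry` object.
#' @export
cuff_geometry <- function(n_rings = 7L,
                          contacts_per_ring = 8L,
                          cuff_radius_um = 800,
                          cuff_length_mm = 23,
                          ring_axial_positions_mm = NULL,
                          rotation_offset_deg = 0) {
  n_rings <- as.integer(n_rings)
  contacts_per_ring <- as.integer(contacts_per_ring)
  stopifnot(n_rings >= 1L, contacts_per_ring >= 1L,
            cuff_radius_um > 0, cuff_length_mm > 0)
  stop_if_not_scalar_finite(rotation_offset_deg, "rotation_offset_deg")
  if (is.null(ring_axial_positions_mm)) {
    margin <- 2.5
    ring_axial_positions_mm <- seq(margin, cuff_length_mm - margin,
                                   length.out = n_rings)
  }
  stopifnot(length(ring_axial_positions_mm) == n_rings,
            all(ring_axial_positions_mm >= 0),
            all(ring_axial_positions_mm <= cuff_length_mm))
  structure(list(
    n_rings = n_rings,
    contacts_per_ring = contacts_per_ring,
    n_contacts = n_rings * contacts_per_ring,
    cuff_radius_mm = cuff_radius_um / 1000,
    cuff_length_mm = cuff_length_mm,
    ring_axial_positions_mm = as.numeric(ring_axial_positions_mm),
    contact_angles_deg = (seq_len(contacts_per_ring) - 1) *
      (360 / contacts_per_ring),
    rotation_offset_deg = rotation_offset_deg %% 360
  ), class = "cuff_geometry")
}

#' @export
print.cuff_geometry <- function(x, ...) {
  cat(sprintf(
    "<cuff_geometry> %d rings x %d contacts (%d channels), radius %.3f mm, length %g mm, rotation %g deg\n",
    x$n_rings, x$contacts_per_ring, x$n_contacts,
    x$cuff_radius_mm, x$cuff_length_mm, x$rotation_offset_deg))
  invisible(x)
}

#' Map a channel index to its (ring, slot) position
#'
#' Channel numbering is ring-major: channel `(r - 1) * contacts_per_ring + s`
#' sits on ring `r`, angular slot `s`.
#'
#' @param geometry A [cuff_geometry()].
#' @return A data frame with columns `channel`, `ring`, `slot`.
#' @export
contact_index <- function(geometry) {
  stopifnot(inherits(geometry, "cuff_geometry"))
  data.frame(
    channel = seq_len(geometry$n_contacts),
    ring = rep(seq_len(geometry$n_rings), each = geometry$contacts_per_ring),
    slot = rep(seq_len(geometry$contacts_per_ring), times = geometry$n_rings)
  )
}

#' Compute 3-D contact positions, optionally rotated around the nerve axis
#'
#' Rotation models the cuff turning around the central axis of the nerve:
#' every contact angle gains `rotation_deg`, axial positions are unchanged.
#' A rotation of `360 / contacts_per_ring` degrees (45 deg for 8 slots)
#' places every contact exactly at the original position of its angular
#' neighbour.
#'
#' @param geometry A [cuff_geometry()].
#' @param rotation_deg Additional rotation in degrees, `0 <= rotation < 360`.
#' @return Matrix `n_contacts x 3` of (x, y, z) coordinates in mm, rows in
#'   ring-major channel order.
#' @export
build_contact_positions <- function(geometry, rotation_deg = 0) {
  stopifnot(inherits(geometry, "cuff_geometry"))
  stop_if_not_scalar_finite(rotation_deg, "rotation_deg")
  if (rotation_deg < 0 || rotation_deg >= 360) {
    stop("`rotation_deg` must lie in [0, 360)", call. = FALSE)
  }
  idx <- contact_index(geometry)
  theta <- (geometry$contact_angles_deg[idx$slot] +
              geometry$rotation_offset_deg + rotation_deg) * pi / 180
  r <- geometry$cuff_radius_mm
  pos <- cbind(
    x = r * cos(theta),
    y = r * sin(theta),
    z = geometry$ring_axial_positions_mm[idx$ring]
  )
  rownames(pos) <- NULL
  pos
}

#' Channel permutation induced by a whole-slot cuff rotation
#'
#' A rotation by `k_slots * (360 / contacts_per_ring)` degrees moves each
#' contact into the former position of another contact, ring-wise. The
#' returned permutation `p` satisfies: leadfield rows computed at rotation
#' `k_slots` slots equal `L0[p, ]`, where `L0` was computed at rotation 0.
#'
#' @param geometry A [cuff_geometry()].
#' @param k_slots Integer number of slots, `0 <= k_slots < contacts_per_ring`.
#' @return Integer vector of length `n_contacts`: new channel `i` occupies
#'   the old position of channel `p[i]`.
#' @export
rotation_permutation <- function(geometry, k_slots) {
  stopifnot(inherits(geometry, "cuff_geometry"))
  k_slots <- as.integer(k_slots)
  if (k_slots < 0 || k_slots >= geometry$contacts_per_ring) {
    stop("`k_slots` must lie in [0, contacts_per_ring)", call. = FALSE)
  }
  idx <- contact_index(geometry)
  cpr <- geometry$contacts_per_ring
  new_slot <- ((idx$slot - 1L + k_slots) %% cpr) + 1L
  (idx$ring - 1L) * cpr + new_slot
}
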