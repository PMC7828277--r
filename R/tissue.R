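#' Layered tissue model of the cuffed nerve
#'
#' A straight-cylinder idealization of a rat sciatic nerve inside a cuff:
#' three fascicles (tibial, peroneal, sural), each an endoneurium cylinder
#' wrapped in a thin perineurium shell, embedded in epineurium; the annulus
#' between the epineurium surface and the cuff is saline at implant time and
#' fills progressively with encapsulation tissue afterwards. Conductivities
#' are in S/m; the endoneurium is anisotropic (longitudinal vs radial).
#'
#' The default fascicle layout places the three fascicles off-center with
#' radii ordered tibial > peroneal > sural, which is what makes their
#' spatiotemporal signatures separable at the cuff surface.
#'
#' @param fascicles Data frame with columns `label`, `center_offset_mm`,
#'   `center_angle_deg`, `radius_mm`; one row per fascicle.
#' @param perineurium_thickness_mm Perineurium shell thickness (default 0.065).
#' @param epineurium_radius_mm Outer epineurium radius (default 0.70).
#' @param conductivities Named list of conductivities in S/m. Defaults:
#'   endoneurium radial 8.26e-2, endoneurium longitudinal 5.71e-1,
#'   perineurium 2.10e-3, epineurium 8.26e-2, encapsulation 6.59e-2,
#'   saline 2.00e-1, cuff 1e-7.
#' @param encapsulation_fill Fraction in `[0, 1]` of the epineurium-to-cuff
#'   annulus occupied by encapsulation tissue (0 = fresh implant).
#' @param cuff_radius_mm Inner cuff radius in mm (must exceed the
#'   epineurium radius; default 0.8).
#' @return A `tissue_model` object.
#' @export
tissue_model <- function(fascicles = default_fascicles(),
                         perineurium_thickness_mm = 0.065,
                         epineurium_radius_mm = 0.70,
                         conductivities = default_conductivities(),
                         encapsulation_fill = 0,
                         cuff_radius_mm = 0.8) {
  stopifnot(is.data.frame(fascicles),
            all(c("label", "center_offset_mm", "center_angle_deg",
                  "radius_mm") %in% names(fascicles)))
  req <- c("endoneurium_radial", "endoneurium_longitudinal", "perineurium",
           "epineurium", "encapsulation", "saline", "cuff")
  missing <- setdiff(req, names(conductivities))
  if (length(missing)) {
    stop("missing conductivities: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(conductivities[req]) <= 0)) {
    stop("all conductivities must be > 0", call. = FALSE)
  }
  if (encapsulation_fill < 0 || encapsulation_fill > 1) {
    stop("`encapsulation_fill` must lie in [0, 1]", call. = FALSE)
  }
  if (epineurium_radius_mm >= cuff_radius_mm) {
    stop("epineurium radius must be smaller than the cuff radius",
         call. = FALSE)
  }
  # the endoneurium proper must fit inside the epineurium; the thin
  # perineurium shell may touch the epineurium surface
  outer <- fascicles$center_offset_mm + fascicles$radius_mm
  if (any(outer > epineurium_radius_mm)) {
    stop("fascicles must lie inside the epineurium", call. = FALSE)
  }
  th <- fascicles$center_angle_deg * pi / 180
  fascicles$center_x_mm <- fascicles$center_offset_mm * cos(th)
  fascicles$center_y_mm <- fascicles$center_offset_mm * sin(th)
  structure(list(
    fascicles = fascicles,
    perineurium_thickness_mm = perineurium_thickness_mm,
    epineurium_radius_mm = epineurium_radius_mm,
    cuff_radius_mm = cuff_radius_mm,
    conductivities = conductivities,
    encapsulation_fill = encapsulation_fill
  ), class = "tissue_model")
}

#' Default three-fascicle layout (tibial, peroneal, sural)
#'
#' Sizes ordered tibial > peroneal > sural. The fascicles are clustered,
#' adjacent to one another, as in a rat sciatic nerve cross-section at
#' cuff level where the nerve has not yet branched; this adjacency is what
#' makes the three pathways' cuff signatures genuinely confusable.
#' Configurable; not derived from imaging data.
#'
#' @return Data frame with one row per fascicle.
#' @export
default_fascicles <- function() {
  data.frame(
    label = c("tibial", "peroneal", "sural"),
    center_offset_mm = c(0.28, 0.42, 0.52),
    center_angle_deg = c(90, 215, 285),
    radius_mm = c(0.35, 0.25, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Default tissue conductivities (S/m)
#' @return Named list of layer conductivities.
#' @export
default_conductivities <- function() {
  list(
    endoneurium_radial = 8.26e-2,
    endoneurium_longitudinal = 5.71e-1,
    perineurium = 2.10e-3,
    epineurium = 8.26e-2,
    encapsulation = 6.59e-2,
    saline = 2.00e-1,
    cuff = 1e-7
  )
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf(
    "<tissue_model> %d fascicles, epineurium %.2f mm, cuff %.2f mm, encapsulation fill %.3f\n",
    nrow(x$fascicles), x$epineurium_radius_mm, x$cuff_radius_mm,
    x$encapsulation_fill))
  invisible(x)
}

#' Set the encapsulation fill fraction of a tissue model
#'
#' Encapsulation tissue grows inward-out from the epineurium surface toward
#' the cuff: a fill fraction `f` places the encapsulation/saline boundary at
#' radius `epineurium_radius + f * (cuff_radius - epineurium_radius)`.
#' The study's four time points Base, ET1, ET2, ET3 use fills 0, 1/3, 2/3, 1.
#'
#' @param tissue A [tissue_model()].
#' @param fill Fill fraction in `[0, 1]`.
#' @return A copy of `tissue` with the new fill.
#' @export
apply_encapsulation <- function(tissue, fill) {
  stopifnot(inherits(tissue, "tissue_model"))
  stop_if_not_scalar_finite(fill, "fill")
  if (fill < 0 || fill > 1) {
    stop("`fill` must lie in [0, 1]", call. = FALSE)
  }
  tissue$encapsulation_fill <- fill
  tissue
}

#' Radius of the encapsulation/saline boundary
#' @param tissue A [tissue_model()].
#' @return Boundary radius in mm.
#' @export
encapsulation_boundary_mm <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_model"))
  tissue$epineurium_radius_mm + tissue$encapsulation_fill *
    (tissue$cuff_radius_mm - tissue$epineurium_radius_mm)
}

#' Standard encapsulation time points
#' @return Named numeric vector of fill fractions for Base, ET1, ET2, ET3.
#' @export
encapsulation_fills <- function() {
  c(Base = 0, ET1 = 1 / 3, ET2 = 2 / 3, ET3 = 1)
}
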