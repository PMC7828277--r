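#' Fiber class parameters
#'
#' Two myelinated fiber classes are modeled: Aalpha fibers (tibial and
#' peroneal pathways) with node-of-Ranvier spacing 1.70 mm and conduction
#' velocity 94.86 m/s, and Abeta fibers (sural pathway) with spacing
#' 1.16 mm and velocity 64.72 m/s.
#'
#' @param fiber_class `"Aalpha"` or `"Abeta"`.
#' @return A `fiber_spec` object with `node_spacing_mm` and
#'   `conduction_velocity_m_s`.
#' @export
fiber_spec <- function(fiber_class = c("Aalpha", "Abeta")) {
  fiber_class <- match.arg(fiber_class)
  p <- switch(fiber_class,
    Aalpha = list(node_spacing_mm = 1.70, conduction_velocity_m_s = 94.86),
    Abeta = list(node_spacing_mm = 1.16, conduction_velocity_m_s = 64.72)
  )
  structure(c(list(fiber_class = fiber_class), p), class = "fiber_spec")
}

#' Fiber class used by each pathway
#' @param label `"tibial"`, `"peroneal"` or `"sural"`.
#' @return A [fiber_spec()].
#' @export
pathway_fiber <- function(label) {
  switch(label,
    tibial = fiber_spec("Aalpha"),
    peroneal = fiber_spec("Aalpha"),
    sural = fiber_spec("Abeta"),
    stop("unknown pathway label: ", label, call. = FALSE)
  )
}

#' Build an arc-length parameterized pathway through a fascicle
#'
#' Interpolates the control points with natural cubic splines per
#' coordinate and reparameterizes by arc length, so that nodes of Ranvier
#' can be placed at equal arc-length spacing along the curve.
#'
#' @param label Pathway label (`"tibial"`, `"peroneal"`, `"sural"`).
#' @param control_points K x 3 matrix of (x, y, z) points in mm, ordered
#'   proximal to distal.
#' @param fiber A [fiber_spec()]; defaults to the class for `label`.
#' @param n_dense Number of dense samples used for the arc-length table.
#' @return A `pathway_spec` with `curve_at(s)` mapping arc length (mm) to
#'   3-D position and total `arc_length_mm`.
#' @export
pathway_spec <- function(label, control_points, fiber = pathway_fiber(label),
                         n_dense = 2000L) {
  control_points <- as.matrix(control_points)
  stopifnot(ncol(control_points) == 3L, nrow(control_points) >= 2L)
  chord <- sqrt(rowSums(diff(control_points)^2))
  if (any(chord <= 0)) stop("control points must be distinct", call. = FALSE)
  u <- c(0, cumsum(chord))
  fx <- stats::splinefun(u, control_points[, 1], method = "natural")
  fy <- stats::splinefun(u, control_points[, 2], method = "natural")
  fz <- stats::splinefun(u, control_points[, 3], method = "natural")
  uu <- seq(0, max(u), length.out = n_dense)
  pts <- cbind(fx(uu), fy(uu), fz(uu))
  seg <- sqrt(rowSums(diff(pts)^2))
  s_tab <- c(0, cumsum(seg))
  total <- s_tab[length(s_tab)]
  u_of_s <- stats::approxfun(s_tab, uu, rule = 2)
  curve_at <- function(s) {
    ui <- u_of_s(s)
    cbind(fx(ui), fy(ui), fz(ui))
  }
  structure(list(
    label = label,
    fiber = fiber,
    control_points = control_points,
    arc_length_mm = total,
    curve_at = curve_at
  ), class = "pathway_spec")
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat(sprintf("<pathway_spec> %s (%s), arc length %.2f mm\n",
              x$label, x$fiber$fiber_class, x$arc_length_mm))
  invisible(x)
}

#' Place nodes of Ranvier along a pathway
#'
#' Nodes are spaced at the fiber's node spacing along arc length, starting
#' at the proximal end and covering the full curve:
#' `floor(L / spacing) + 1` nodes for a curve of length `L`.
#'
#' @param pathway A [pathway_spec()].
#' @return N x 3 matrix of node positions in mm, with the arc length of
#'   each node (mm, from the proximal end) in attribute `"arc_length_mm"`.
#' @export
place_nodes <- function(pathway) {
  stopifnot(inherits(pathway, "pathway_spec"))
  spacing <- pathway$fiber$node_spacing_mm
  if (pathway$arc_length_mm < spacing) {
    stop("pathway is shorter than one node spacing", call. = FALSE)
  }
  s <- seq(0, pathway$arc_length_mm, by = spacing)
  nodes <- pathway$curve_at(s)
  attr(nodes, "arc_length_mm") <- s
  nodes
}

#' Build a bank of source trajectories for one pathway
#'
#' Generates `n_traj` gently meandering fiber trajectories at distinct
#' radial offsets inside the pathway's fascicle (a sunflower-pattern spread
#' over the fascicle cross-section), emulating CAPs initiated at differing
#' spatial locations within the fascicle. Deterministic: the offsets and
#' wiggle phases are fixed functions of the trajectory index.
#'
#' @param tissue A [tissue_model()].
#' @param label Pathway label.
#' @param n_traj Number of trajectories (default 20).
#' @param z_range Axial extent in mm of the modeled nerve segment
#'   (default `c(-4, 27)`, covering the 23 mm cuff with margin on each
#'   side of at least two node spacings).
#' @param n_control Control points per trajectory (default 9).
#' @param wiggle_frac Wiggle amplitude as a fraction of the fascicle radius
#'   (default 0.05).
#' @return List of [pathway_spec()] objects.
#' @export
pathway_bank <- function(tissue, label, n_traj = 20L,
                         z_range = c(-4, 27), n_control = 9L,
                         wiggle_frac = 0.05) {
  stopifnot(inherits(tissue, "tissue_model"))
  f <- tissue$fascicles[tissue$fascicles$label == label, ]
  if (nrow(f) != 1L) stop("unknown fascicle label: ", label, call. = FALSE)
  fiber <- pathway_fiber(label)
  golden <- pi * (3 - sqrt(5))
  z <- seq(z_range[1], z_range[2], length.out = n_control)
  span <- diff(z_range)
  lapply(seq_len(n_traj), function(k) {
    # sunflower layout keeps offsets within 80% of the fascicle radius
    rho <- 0.8 * f$radius_mm * sqrt(k / n_traj) * (1 - wiggle_frac)
    phi <- k * golden
    amp <- wiggle_frac * f$radius_mm
    cp <- cbind(
      f$center_x_mm + rho * cos(phi) + amp * sin(2 * pi * z / span + phi),
      f$center_y_mm + rho * sin(phi) + amp * cos(2 * pi * z / span + phi),
      z
    )
    pw <- pathway_spec(label, cp, fiber)
    # invariant: the curve must stay inside its fascicle
    dense <- pw$curve_at(seq(0, pw$arc_length_mm, length.out = 200))
    dd <- sqrt((dense[, 1] - f$center_x_mm)^2 +
                 (dense[, 2] - f$center_y_mm)^2)
    if (any(dd >= f$radius_mm)) {
      stop("trajectory leaves its fascicle; reduce offsets or wiggle",
           call. = FALSE)
    }
    pw
  })
}
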