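# Spatial scaffold: ellipsoidal nuclei, uniform neuron placement with an
# electrode-canal exclusion, electrode contact geometry and distances.

#' Ellipsoidal nucleus volume
#'
#' @param center 3-vector (mm).
#' @param semi_axes semi-principal axes `c(a, b, c)` (mm), all positive.
#' @return An object of class `"ellipsoid"`.
#' @export
ellipsoid <- function(center = c(0, 0, 0), semi_axes) {
  stopifnot(length(center) == 3, length(semi_axes) == 3, all(semi_axes > 0))
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes)),
            class = "ellipsoid")
}

#' Default STN ellipsoid (semi-axes 2.5 x 6.0 x 3.0 mm)
#' @param center optional center (mm); default origin.
#' @return An `"ellipsoid"`.
#' @export
stn_ellipsoid <- function(center = c(0, 0, 0)) ellipsoid(center, c(2.5, 6.0, 3.0))

#' Default GPe ellipsoid (semi-axes 4.6 x 12.3 x 3.2 mm)
#'
#' Only the STN geometry matters for stimulation; by default the GPe
#' ellipsoid shares the STN frame with a configurable offset.
#' @param center optional center (mm); default origin.
#' @return An `"ellipsoid"`.
#' @export
gpe_ellipsoid <- function(center = c(0, 0, 0)) ellipsoid(center, c(4.6, 12.3, 3.2))

#' Analytic ellipsoid volume
#'
#' \eqn{V = \frac{4}{3}\pi abc}. The default STN semi-axes give
#' 188.5 mm^3.
#' @param e an `"ellipsoid"`.
#' @return Volume (mm^3).
#' @export
ellipsoid_volume <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  4 / 3 * pi * prod(e$semi_axes)
}

#' Ellipsoid membership test
#'
#' @param e an `"ellipsoid"`.
#' @param xyz n x 3 matrix of positions (mm).
#' @return Logical vector: \eqn{(x/a)^2+(y/b)^2+(z/c)^2 \le 1} in
#'   center-relative coordinates.
#' @export
in_ellipsoid <- function(e, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  rel <- sweep(xyz, 2, e$center)
  rowSums(sweep(rel, 2, e$semi_axes, "/")^2) <= 1
}

#' Depth-electrode specification
#'
#' A linear array of `M` cylindrical contacts modelled as points on the
#' electrode axis for distance computation; the contact length `l_c`
#' enters only the field decay profile [field_profile()]. The electrode
#' canal (radius `canal_radius` about the axis) excludes neuron
#' positions, which also enforces the minimal neuron-contact distance
#' `d_min` that regularizes the field singularity.
#'
#' @param axis_origin point on the electrode axis (mm); contacts are
#'   centred about this point.
#' @param axis_direction axis direction (normalized internally);
#'   default +y, the implantation direction.
#' @param n_contacts number of contacts M (default 4).
#' @param spacing centre-to-centre contact spacing (mm, default 2).
#' @param contact_length cylindrical contact length l_c (mm, default 1.5).
#' @param canal_radius electrode canal radius (mm, default 0.7).
#' @param d_min minimal admissible neuron-contact distance (mm,
#'   default 0.7).
#' @return An object of class `"electrode_spec"`.
#' @export
electrode_spec <- function(axis_origin = c(0, 0, 0), axis_direction = c(0, 1, 0),
                           n_contacts = 4, spacing = 2.0, contact_length = 1.5,
                           canal_radius = 0.7, d_min = 0.7) {
  stopifnot(n_contacts >= 1, canal_radius > 0, spacing > 0)
  u <- axis_direction / sqrt(sum(axis_direction^2))
  offs <- (seq_len(n_contacts) - (n_contacts + 1) / 2) * spacing
  centers <- t(vapply(offs, function(o) axis_origin + o * u, numeric(3)))
  structure(list(axis_origin = as.numeric(axis_origin), axis_direction = u,
                 n_contacts = n_contacts, spacing = spacing,
                 contact_centers = centers, contact_length = contact_length,
                 canal_radius = canal_radius, d_min = d_min),
            class = "electrode_spec")
}

#' Contact centre positions
#' @param spec an `"electrode_spec"`.
#' @return M x 3 matrix of contact centres (mm).
#' @export
contact_positions <- function(spec) spec$contact_centers

#' Distance from a point to the electrode axis
#' @param xyz n x 3 matrix of positions (mm).
#' @param spec an `"electrode_spec"`.
#' @return Perpendicular distances (mm).
#' @export
distance_to_axis <- function(xyz, spec) {
  xyz <- matrix(xyz, ncol = 3)
  rel <- sweep(xyz, 2, spec$axis_origin)
  along <- rel %*% spec$axis_direction
  perp <- rel - along %*% t(spec$axis_direction)
  sqrt(rowSums(perp^2))
}

#' Distance from neurons to one stimulation contact
#'
#' Euclidean distance to the contact-centre point, floored at `d_min` so
#' that the line-charge field profile stays finite.
#'
#' @param xyz n x 3 matrix of neuron positions (mm).
#' @param spec an `"electrode_spec"`.
#' @param j contact index in 1..M.
#' @return Distances (mm), all `>= d_min`.
#' @export
distance_to_contact <- function(xyz, spec, j) {
  if (j < 1 || j > spec$n_contacts) stop("invalid contact index: ", j)
  xyz <- matrix(xyz, ncol = 3)
  rel <- sweep(xyz, 2, spec$contact_centers[j, ])
  pmax(sqrt(rowSums(rel^2)), spec$d_min)
}

#' Fill an ellipsoid with uniformly distributed point neurons
#'
#' Rejection sampling from the bounding box gives uniform density over
#' the ellipsoid; when an electrode `exclusion` is supplied, positions
#' inside the canal cylinder (perpendicular distance to the electrode
#' axis below `canal_radius`) are also rejected, so accepted positions
#' are uniform over the admissible region.
#'
#' @param e an `"ellipsoid"`.
#' @param n number of neurons to place (>= 1).
#' @param exclusion optional `"electrode_spec"` whose canal excludes
#'   positions (used for the STN, the implantation target).
#' @param seed optional integer seed; placement is deterministic under a
#'   fixed seed.
#' @param max_tries cap on rejection rounds before signalling a
#'   misconfiguration (cylinder covering the ellipsoid).
#' @return An n x 3 matrix of positions (mm).
#' @export
place_neurons <- function(e, n, exclusion = NULL, seed = NULL, max_tries = 1000) {
  stopifnot(inherits(e, "ellipsoid"), n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  out <- matrix(numeric(0), ncol = 3)
  tries <- 0
  while (nrow(out) < n) {
    tries <- tries + 1
    if (tries > max_tries) stop("rejection sampling failed; exclusion cylinder may cover the ellipsoid")
    m <- max(2L * (n - nrow(out)), 100L)
    cand <- sweep(matrix(stats::runif(3 * m, -1, 1), ncol = 3), 2, e$semi_axes, "*")
    cand <- sweep(cand, 2, e$center, "+")
    keep <- in_ellipsoid(e, cand)
    if (!is.null(exclusion)) {
      keep <- keep & distance_to_axis(cand, exclusion) >= exclusion$canal_radius
    }
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
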