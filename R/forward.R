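#' Spherical head model
#'
#' Single-shell conducting-sphere head model used for closed-form (Sarvas)
#' forward fields. Coordinates follow the head frame: x through the
#' preauricular axis (+x right), y through the nasion (+y anterior), z up,
#' origin at the sphere center.
#'
#' @param center Numeric 3-vector, sphere center in meters.
#' @param scalp_radius Scalp radius in meters.
#' @param source_radius Radius of the source shell in meters; must be
#'   strictly inside the scalp.
#' @return An object of class `sphere_head`.
#' @export
sphere_head <- function(center = c(0, 0, 0), scalp_radius = 0.09,
                        source_radius = 0.07) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, all(is.finite(center)),
            is.finite(scalp_radius), is.finite(source_radius))
  if (!(source_radius > 0 && source_radius < scalp_radius))
    stop("require 0 < source_radius < scalp_radius")
  structure(list(center = center, scalp_radius = scalp_radius,
                 source_radius = source_radius),
            class = "sphere_head")
}

#' Sensor array container
#'
#' @param names Character vector of unique channel names.
#' @param positions n x 3 matrix of sensor positions \[m\].
#' @param orientations n x 3 matrix of unit vectors along each sensor's
#'   sensitive axis.
#' @param is_reference Logical vector flagging reference channels.
#' @return An object of class `sensor_array`.
#' @export
sensor_array <- function(names, positions, orientations, is_reference) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  n <- length(names)
  stopifnot(nrow(positions) == n, nrow(orientations) == n,
            ncol(positions) == 3, ncol(orientations) == 3,
            length(is_reference) == n)
  if (anyDuplicated(names)) stop("channel names must be unique")
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("orientations must be unit vectors")
  structure(list(names = as.character(names), positions = positions,
                 orientations = orientations,
                 is_reference = as.logical(is_reference)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d channels (%d scalp, %d reference)\n",
              length(x$names), sum(!x$is_reference), sum(x$is_reference)))
  invisible(x)
}

# Idealized 10-05 angle table for the left-hemisphere labels used by the
# default layout. alpha: anterior(+)/posterior(-) tilt from the vertical,
# beta: lateral angle from the vertex toward the left ear. 10% of the
# ear-to-ear (or nasion-to-inion) surface arc corresponds to 18 degrees.
.ten_five_table <- function() {
  lat <- c("1" = 18, "3" = 36, "5" = 54, "7" = 72, "9" = 90)
  rows <- c(FC = 18, C = 0, CP = -18)
  labs <- c("FC1", "C1", "CP1", "FC3", "C3", "CP3", "FC5", "C5", "CP5",
            "FC7", "C7", "CP7", "C9")
  out <- data.frame(label = labs, alpha = NA_real_, beta = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    row <- sub("[0-9]+$", "", labs[i])
    idx <- sub("^[A-Z]+", "", labs[i])
    out$alpha[i] <- rows[[row]]
    out$beta[i] <- lat[[idx]]
  }
  out
}

# Unit vector on the sphere for angles (alpha anterior tilt, beta lateral
# toward the left), degrees. Start at vertex, rotate toward -x (left) by
# beta about the anterior axis, then tilt anterior (+y) by alpha.
.angles_to_unit <- function(alpha, beta) {
  a <- alpha * pi / 180
  b <- beta * pi / 180
  c(-sin(b), cos(b) * sin(a), cos(b) * cos(a))
}

#' Build the default 16-channel partial-coverage array
#'
#' Thirteen radially oriented scalp sensors at idealized spherical 10-05
#' positions over the left sensorimotor strip (FC1, C1, CP1, FC3, C3, CP3,
#' FC5, C5, CP5, FC7, C7, CP7, C9), plus three reference magnetometers
#' with mutually orthogonal sensitive axes fixed 35-40 cm from the scalp
#' in the superior, posterior, and left directions.
#'
#' @param head A [sphere_head()].
#' @param standoff Scalp-to-sensor distance in meters (sensor cell housing).
#' @return A [sensor_array()] with 16 channels.
#' @export
build_default_array <- function(head, standoff = 0.01) {
  stopifnot(inherits(head, "sphere_head"))
  tab <- .ten_five_table()
  n_scalp <- nrow(tab)
  pos <- matrix(NA_real_, n_scalp + 3, 3)
  ori <- matrix(NA_real_, n_scalp + 3, 3)
  r <- head$scalp_radius + standoff
  for (i in seq_len(n_scalp)) {
    u <- .angles_to_unit(tab$alpha[i], tab$beta[i])
    pos[i, ] <- head$center + r * u
    ori[i, ] <- u
  }
  # references: ~0.35-0.40 m beyond the scalp, orthogonal axes
  ref_dir <- rbind(c(0, 0, 1),    # superior
                   c(0, -1, 0),   # posterior
                   c(-1, 0, 0))   # left
  ref_dist <- c(0.37, 0.38, 0.36)
  for (k in 1:3) {
    pos[n_scalp + k, ] <- head$center +
      (head$scalp_radius + ref_dist[k]) * ref_dir[k, ]
    ori[n_scalp + k, ] <- ref_dir[k, ]
  }
  sensor_array(c(tab$label, c("RefSup", "RefPost", "RefLeft")),
               pos, ori, c(rep(FALSE, n_scalp), rep(TRUE, 3)))
}

#' Build a synthetic whole-cap comparison array
#'
#' Radially oriented magnetometers spread quasi-uniformly (Fibonacci
#' lattice) over the upper hemisphere, for contrasting full-coverage and
#' partial-coverage behavior (e.g. HFC lead-field attenuation).
#'
#' @param head A [sphere_head()].
#' @param n Number of sensors.
#' @param standoff Scalp-to-sensor distance in meters.
#' @return A [sensor_array()] with `n` scalp channels and no references.
#' @export
build_whole_cap_array <- function(head, n = 64, standoff = 0.01) {
  stopifnot(inherits(head, "sphere_head"), n >= 4)
  golden <- pi * (3 - sqrt(5))
  # z from just above equator to the vertex
  z <- seq(0.05, 0.98, length.out = n)
  theta <- golden * seq_len(n)
  u <- cbind(sqrt(1 - z^2) * cos(theta), sqrt(1 - z^2) * sin(theta), z)
  r <- head$scalp_radius + standoff
  pos <- sweep(u * r, 2, head$center, "+")
  sensor_array(sprintf("CAP%02d", seq_len(n)), pos, u, rep(FALSE, n))
}

#' Sarvas forward field of a current dipole in a conducting sphere
#'
#' Closed-form magnetic field outside a homogeneous conducting sphere
#' produced by a current dipole inside it. Volume currents make radial
#' source components externally silent, and the external radial field
#' component equals that of the primary current alone.
#'
#' @param dipole_pos 3-vector, dipole location \[m\] (strictly inside the
#'   scalp).
#' @param dipole_moment 3-vector, dipole moment \[A·m\].
#' @param field_point 3-vector, measurement point \[m\] (outside the scalp).
#' @param head A [sphere_head()].
#' @return 3-vector magnetic field \[T\].
#' @export
sarvas_field <- function(dipole_pos, dipole_moment, field_point, head) {
  stopifnot(inherits(head, "sphere_head"))
  mu0_4pi <- 1e-7
  r0 <- as.numeric(dipole_pos) - head$center
  r <- as.numeric(field_point) - head$center
  R <- sqrt(sum(r^2))
  if (R <= head$scalp_radius)
    stop("field_point must lie outside the scalp")
  if (sqrt(sum(r0^2)) >= head$scalp_radius)
    stop("dipole_pos must lie strictly inside the scalp")
  q <- as.numeric(dipole_moment)
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  F_s <- a * (R * a + R^2 - sum(r0 * r))
  grad_F <- (a^2 / R + sum(a_vec * r) / a + 2 * a + 2 * R) * r -
    (a + 2 * R + sum(a_vec * r) / a) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  if (sum(qxr0^2) == 0) return(c(0, 0, 0))
  mu0_4pi / F_s^2 * (F_s * qxr0 - sum(qxr0 * r) * grad_F)
}

#' Source grid container
#'
#' @param vertices m x 3 matrix of source locations \[m\], all on the
#'   source shell.
#' @param orientations m x 3 matrix of tangential unit vectors.
#' @param roi_labels Character vector of ROI names, one per vertex.
#' @param head The [sphere_head()] the grid belongs to.
#' @return An object of class `source_grid`.
#' @export
source_grid <- function(vertices, orientations, roi_labels, head) {
  vertices <- as.matrix(vertices)
  orientations <- as.matrix(orientations)
  m <- nrow(vertices)
  stopifnot(inherits(head, "sphere_head"), nrow(orientations) == m,
            length(roi_labels) == m)
  rad <- sqrt(rowSums(sweep(vertices, 2, head$center)^2))
  if (any(abs(rad - head$source_radius) > 1e-9))
    stop("all vertices must lie on the source shell")
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("orientations must be unit vectors")
  rhat <- sweep(sweep(vertices, 2, head$center), 1, rad, "/")
  if (any(abs(rowSums(rhat * orientations)) > 1e-6))
    stop("orientations must be tangential")
  structure(list(vertices = vertices, orientations = orientations,
                 roi_labels = as.character(roi_labels), head = head),
            class = "source_grid")
}

#' The six sensorimotor ROI names, anterior to posterior
#' @return Character vector of length 6.
#' @export
roi_names <- function() {
  c("superior precentral sulcus", "precentral gyrus", "central sulcus",
    "postcentral gyrus", "postcentral sulcus", "superior parietal lobule")
}

#' Build the default six-ROI source grid
#'
#' Six contiguous equal-width anterior-to-posterior strips on the source
#' shell beneath the scalp sensors, carrying the sensorimotor ROI names.
#' The strip band is placed so the postcentral-gyrus strip sits centered
#' under the array. Source orientations are tangential, along the local
#' anterior-posterior direction (sulcal-bank-like sources; radial sources
#' are externally silent in a sphere).
#'
#' @param head A [sphere_head()].
#' @param per_strip Vertices per strip (default 20: 2 anterior-posterior
#'   rows x 10 lateral columns).
#' @return A [source_grid()] with `6 * per_strip` vertices.
#' @export
build_default_grid <- function(head, per_strip = 20) {
  stopifnot(inherits(head, "sphere_head"), per_strip >= 2)
  strips <- roi_names()
  # strip band alpha in [+31.5, -22.5] deg, 9 deg strips; lateral band
  # beta in [18, 72] deg (under the FC/C/CP 1..7 sensor columns)
  alpha_hi <- 31.5
  width <- 9
  n_a <- 2
  n_b <- per_strip / n_a
  if (n_b != round(n_b)) { n_a <- 1; n_b <- per_strip }
  verts <- NULL; oris <- NULL; labs <- character(0)
  for (s in seq_along(strips)) {
    a_edges <- seq(alpha_hi - (s - 1) * width, alpha_hi - s * width,
                   length.out = n_a + 2)
    a_vals <- a_edges[2:(n_a + 1)]
    b_vals <- seq(20, 70, length.out = n_b)
    for (a in a_vals) for (b in b_vals) {
      u <- .angles_to_unit(a, b)
      v <- head$center + head$source_radius * u
      # tangential anterior-posterior axis (posterior-pointing unit);
      # with this convention the generator's default SEF (negative first
      # lobe) produces a negative N20m deflection at the high-lead
      # central/centroparietal sensors of the default array, matching
      # the conventional SEF polarity at those sites
      t_ap <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
      t_ap <- -t_ap / sqrt(sum(t_ap^2))
      verts <- rbind(verts, v)
      oris <- rbind(oris, t_ap)
      labs <- c(labs, strips[s])
    }
  }
  source_grid(verts, oris, labs, head)
}

#' Compute the lead field of a sensor array over a source grid
#'
#' Entry (i, j) is the projection onto scalp sensor i's sensitive axis of
#' the Sarvas field of a unit dipole (1 A·m) at grid vertex j along its
#' orientation. Reference channels are excluded.
#'
#' @param array A [sensor_array()].
#' @param grid A [source_grid()].
#' @param head A [sphere_head()].
#' @return A list of class `lead_field` with `matrix`
#'   (n_scalp x m, T per A·m), `channel_names`, and `source_index`.
#' @export
compute_lead_field <- function(array, grid, head) {
  stopifnot(inherits(array, "sensor_array"), inherits(grid, "source_grid"),
            inherits(head, "sphere_head"))
  rad <- sqrt(rowSums(sweep(grid$vertices, 2, head$center)^2))
  if (any(abs(rad - head$source_radius) > 1e-9))
    stop("grid vertex off the source shell")
  keep <- which(!array$is_reference)
  m <- nrow(grid$vertices)
  L <- matrix(NA_real_, length(keep), m)
  for (j in seq_len(m)) {
    for (k in seq_along(keep)) {
      i <- keep[k]
      B <- sarvas_field(grid$vertices[j, ], grid$orientations[j, ],
                        array$positions[i, ], head)
      L[k, j] <- sum(array$orientations[i, ] * B)
    }
  }
  structure(list(matrix = L, channel_names = array$names[keep],
                 source_index = seq_len(m), grid = grid),
            class = "lead_field")
}

#' Lead-field sensitivity map
#'
#' Sensitivity at each vertex is the Euclidean norm over channels of its
#' lead-field column for a unit source (default 1 A·m), i.e. expected
#' sensor signal strength per unit source activity. Per-ROI sensitivity
#' is the mean across the ROI's member vertices; when maps from several
#' subjects are supplied the across-subject SD is reported as well.
#'
#' @param lead A `lead_field`, or a list of subject `lead_field`s.
#' @param unit_moment Source magnitude in A·m.
#' @return A list of class `sensitivity_map` with `values` (vertex
#'   sensitivities \[T per A·m\]), `roi` (data.frame with per-ROI mean and
#'   SD across subjects).
#' @export
sensitivity_map <- function(lead, unit_moment = 1.0) {
  leads <- if (inherits(lead, "lead_field")) list(lead) else lead
  stopifnot(all(vapply(leads, inherits, TRUE, "lead_field")))
  grid <- leads[[1]]$grid
  vals <- vapply(leads,
                 function(l) sqrt(colSums(l$matrix^2)) * unit_moment,
                 numeric(ncol(leads[[1]]$matrix)))
  vals <- matrix(vals, ncol = length(leads))
  if (!all(is.finite(vals))) stop("lead field must be finite")
  labs <- grid$roi_labels
  rois <- unique(labs)
  per_subj_roi <- vapply(rois, function(r) {
    idx <- which(labs == r)
    if (!length(idx)) stop("empty ROI: ", r)
    colMeans(vals[idx, , drop = FALSE])
  }, numeric(length(leads)))
  per_subj_roi <- matrix(per_subj_roi, nrow = length(leads))
  roi <- data.frame(
    roi = rois,
    mean = colMeans(per_subj_roi),
    sd = apply(per_subj_roi, 2, stats::sd),
    stringsAsFactors = FALSE)
  structure(list(values = rowMeans(vals), roi = roi,
                 unit_moment = unit_moment),
            class = "sensitivity_map")
}

#' Write / read a sensor array or source grid as TSV
#'
#' Columns: name, x, y, z, ox, oy, oz, is_reference, roi_label; positions
#' in meters with six significant digits.
#'
#' @param x A `sensor_array` or `source_grid`.
#' @param path Output file.
#' @export
write_geometry_tsv <- function(x, path) {
  if (inherits(x, "sensor_array")) {
    df <- data.frame(name = x$names,
                     x = signif(x$positions[, 1], 6),
                     y = signif(x$positions[, 2], 6),
                     z = signif(x$positions[, 3], 6),
                     ox = signif(x$orientations[, 1], 6),
                     oy = signif(x$orientations[, 2], 6),
                     oz = signif(x$orientations[, 3], 6),
                     is_reference = x$is_reference,
                     roi_label = NA_character_)
  } else if (inherits(x, "source_grid")) {
    df <- data.frame(name = sprintf("v%03d", seq_len(nrow(x$vertices))),
                     x = signif(x$vertices[, 1], 6),
                     y = signif(x$vertices[, 2], 6),
                     z = signif(x$vertices[, 3], 6),
                     ox = signif(x$orientations[, 1], 6),
                     oy = signif(x$orientations[, 2], 6),
                     oz = signif(x$orientations[, 3], 6),
                     is_reference = FALSE,
                     roi_label = x$roi_labels)
  } else stop("unsupported object")
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_geometry_tsv
#' @param path Input TSV file.
#' @param head Optional [sphere_head()]; if supplied and the rows carry
#'   ROI labels, a `source_grid` is returned, else a `sensor_array`.
#' @export
read_geometry_tsv <- function(path, head = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  ori <- as.matrix(df[, c("ox", "oy", "oz")])
  ori <- ori / sqrt(rowSums(ori^2))  # renormalize after rounding
  if (!is.null(head) && !all(is.na(df$roi_label))) {
    rad <- sqrt(rowSums(sweep(pos, 2, head$center)^2))
    pos <- sweep(sweep(pos, 2, head$center), 1,
                 head$source_radius / rad, "*")
    pos <- sweep(pos, 2, head$center, "+")
    # re-tangentialize after 6-digit rounding
    rhat <- sweep(sweep(pos, 2, head$center), 1,
                  sqrt(rowSums(sweep(pos, 2, head$center)^2)), "/")
    ori <- ori - rhat * rowSums(ori * rhat)
    ori <- ori / sqrt(rowSums(ori^2))
    source_grid(pos, ori, df$roi_label, head)
  } else {
    sensor_array(df$name, pos, ori, df$is_reference)
  }
}
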