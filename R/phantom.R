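#' Build the breast phantom
#'
#' Constructs the 2D plane-strain phantom: a semi-elliptical breast
#' cross-section resting on a fixed base, containing a stiff circular
#' tumor, discretized on a structured quadrilateral grid (cells whose
#' center falls inside the outline are material; the boundary staircase
#' is accepted at the chosen spacing).  The top of the phantom is
#' compressed by a rigid flat platen; boundary nodes are tagged
#' `fixed_base`, `platen_contact` (candidates under the platen footprint)
#' or `free`.
#'
#' Geometry arguments are in millimetres.  The default geometry is a
#' 100 mm x 40 mm semi-ellipse with a 10 mm tumor whose center sits
#' 20 mm above the base and 38 mm from the rightmost point of the
#' outline (i.e. 12 mm right of the midline), compressed by a 45 mm wide
#' platen centered on the midline.
#'
#' @param width,height outline dimensions (mm).
#' @param tumor_center tumor center `c(x, y)` in mm; origin at the base
#'   center, x rightward, y upward.
#' @param tumor_diameter tumor diameter (mm); 0 gives a pure background
#'   phantom.
#' @param spacing grid spacing (mm) of the mechanical mesh.
#' @param materials named list of [material_params()]; must contain
#'   `background_label` and, if the tumor is present, `tumor_label`.
#' @param tumor_label,background_label names into `materials`.
#' @param shape `"semi-ellipse"` or `"rectangle"`.
#' @param platen_width rigid platen footprint (mm); `Inf` for full width.
#' @param base_bc `"fixed"` (base clamped in all directions) or
#'   `"roller"` (vertical support only).
#' @return object of class `phantom_model`.
#' @examples
#' ph <- build_phantom(spacing = 2)
#' ph
#' @export
build_phantom <- function(width = 100, height = 40,
                          tumor_center = c(12, 20), tumor_diameter = 10,
                          spacing = 1, materials = load_materials(),
                          tumor_label = "tumor",
                          background_label = "benign",
                          shape = c("semi-ellipse", "rectangle"),
                          platen_width = 45, base_bc = c("fixed", "roller")) {
  shape <- match.arg(shape)
  base_bc <- match.arg(base_bc)
  if (spacing <= 0) nlswei_abort("spacing must be positive", "nlswei_invalid_input")
  W <- mm(width); H <- mm(height); h <- mm(spacing)
  tc <- mm(tumor_center); td <- mm(tumor_diameter)
  a <- W / 2; b <- H
  inside <- function(x, y) {
    if (shape == "semi-ellipse") (x / a)^2 + (y / b)^2 <= 1 & y >= 0
    else abs(x) <= a & y >= 0 & y <= H
  }
  if (td > 0) {
    th <- seq(0, 2 * pi, length.out = 73)
    px <- tc[1] + td / 2 * cos(th); py <- tc[2] + td / 2 * sin(th)
    if (!all(inside(px, py)))
      nlswei_abort("tumor disc is not fully inside the phantom outline",
                   "nlswei_geometry_error")
  }
  nx <- max(2L, as.integer(round(W / h)))
  ny <- max(2L, as.integer(round(H / h)))
  xc <- -W / 2 + (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  cx <- matrix(xc, nx, ny)
  cy <- matrix(yc, nx, ny, byrow = TRUE)
  active <- inside(cx, cy)
  lab <- matrix(1L, nx, ny)
  if (td > 0) lab[(cx - tc[1])^2 + (cy - tc[2])^2 <= (td / 2)^2] <- 2L
  lab[!active] <- NA_integer_
  mat_labels <- c(background_label, tumor_label)
  if (is.null(materials[[background_label]]))
    nlswei_abort("materials must contain the background label",
                 "nlswei_invalid_input")
  if (any(lab == 2L, na.rm = TRUE) && is.null(materials[[tumor_label]]))
    nlswei_abort("materials must contain the tumor label",
                 "nlswei_invalid_input")
  mats <- list(materials[[background_label]],
               materials[[tumor_label]] %||% materials[[background_label]])
  names(mats) <- mat_labels
  ph <- finish_phantom(list(
    width = W, height = H, spacing = h, shape = shape,
    tumor_center = tc, tumor_diameter = td,
    active = active, label = lab, materials = mats,
    platen_width = mm(platen_width), platen_center = 0,
    base_bc = base_bc))
  ph
}

# node numbering, element table and boundary tags from the cell mask
#' @noRd
finish_phantom <- function(ph) {
  nx <- nrow(ph$active); ny <- ncol(ph$active)
  h <- ph$spacing
  used <- matrix(FALSE, nx + 1, ny + 1)
  ij <- which(ph$active, arr.ind = TRUE)
  for (d in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
    used[cbind(ij[, 1] + d[1], ij[, 2] + d[2])] <- TRUE
  node_id <- matrix(0L, nx + 1, ny + 1)
  node_id[used] <- seq_len(sum(used))
  idx <- which(used, arr.ind = TRUE)  # row order matches the id sequence
  node_xy <- cbind(-ph$width / 2 + (idx[, 1] - 1) * h, (idx[, 2] - 1) * h)
  elems <- cbind(node_id[ij],
                 node_id[cbind(ij[, 1] + 1, ij[, 2])],
                 node_id[cbind(ij[, 1] + 1, ij[, 2] + 1)],
                 node_id[cbind(ij[, 1], ij[, 2] + 1)]) - 1L  # 0-based, ccw
  elem_mat <- ph$label[ij] - 1L                              # 0-based
  elem_cell <- ij
  base_nodes <- which(abs(node_xy[, 2]) < h / 4)
  # topmost used node of each node column (platen contact candidates)
  top_nodes <- vapply(seq_len(nx + 1), function(i) {
    js <- which(used[i, ])
    if (!length(js)) return(NA_integer_)
    node_id[i, max(js)]
  }, integer(1))
  top_nodes <- top_nodes[!is.na(top_nodes)]
  tags <- rep("free", nrow(node_xy))
  tags[top_nodes] <- "platen_contact"
  tags[base_nodes] <- "fixed_base"
  ph$node_xy <- node_xy
  ph$elems <- elems
  ph$elem_mat <- elem_mat
  ph$elem_cell <- elem_cell
  ph$base_nodes <- base_nodes
  ph$top_nodes <- top_nodes
  ph$bc_tags <- tags
  class(ph) <- "phantom_model"
  ph
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model> %s %.0f x %.0f mm, spacing %.2g mm\n",
              x$shape, x$width * 1e3, x$height * 1e3, x$spacing * 1e3))
  cat(sprintf("  %d cells (%d tumor), %d nodes, platen %.0f mm, base %s\n",
              sum(x$active), sum(x$label == 2L, na.rm = TRUE),
              nrow(x$node_xy), x$platen_width * 1e3, x$base_bc))
  invisible(x)
}

#' Element centroid coordinates (m)
#' @param phantom a `phantom_model`.
#' @return matrix (n_elements x 2).
#' @export
element_centers <- function(phantom) {
  ij <- phantom$elem_cell
  h <- phantom$spacing
  cbind(-phantom$width / 2 + (ij[, 1] - 0.5) * h, (ij[, 2] - 0.5) * h)
}

#' Small phantoms with known analytic properties
#'
#' Test-surface generator: rectangular phantoms that are homogeneous,
#' split into two horizontal layers, or carry a circular inclusion.
#' Materials are linear Mooney-Rivlin (c10 = c01 = mu0/4, no second-order
#' terms) unless supplied explicitly.
#'
#' @param kind fixture type.
#' @param width,height,spacing geometry in mm.
#' @param mu0 initial shear modulus (Pa): one value for `"homogeneous"`,
#'   `c(bottom, top)` for `"layered"`, `c(background, inclusion)` for
#'   `"inclusion"`.
#' @param inclusion_center,inclusion_diameter inclusion geometry (mm).
#' @param base_bc base support, see [build_phantom()].
#' @param platen_width platen footprint (mm), full width by default.
#' @return a `phantom_model`.
#' @export
make_test_fixture <- function(kind = c("homogeneous", "layered", "inclusion"),
                              width = 20, height = 10, spacing = 1,
                              mu0 = 4000,
                              inclusion_center = c(0, height / 2),
                              inclusion_diameter = height / 3,
                              base_bc = "roller", platen_width = Inf) {
  kind <- match.arg(kind)
  mk <- function(mu, label) material_params(mu / 4, mu / 4, 0, 0, 0,
                                            label = label, unit = "Pa")
  if (kind == "homogeneous") {
    mats <- list(bg = mk(mu0[1], "bg"), inc = mk(mu0[1], "inc"))
    ph <- build_phantom(width, height, tumor_diameter = 0,
                        tumor_center = c(0, height / 2), spacing = spacing,
                        materials = mats, tumor_label = "inc",
                        background_label = "bg", shape = "rectangle",
                        platen_width = platen_width, base_bc = base_bc)
  } else if (kind == "inclusion") {
    if (length(mu0) < 2) mu0 <- c(mu0, mu0)
    mats <- list(bg = mk(mu0[1], "bg"), inc = mk(mu0[2], "inc"))
    ph <- build_phantom(width, height, tumor_center = inclusion_center,
                        tumor_diameter = inclusion_diameter,
                        spacing = spacing, materials = mats,
                        tumor_label = "inc", background_label = "bg",
                        shape = "rectangle", platen_width = platen_width,
                        base_bc = base_bc)
  } else {
    if (length(mu0) < 2) mu0 <- c(mu0, mu0)
    mats <- list(bottom = mk(mu0[1], "bottom"), top = mk(mu0[2], "top"))
    ph <- build_phantom(width, height, tumor_diameter = 0,
                        tumor_center = c(0, height / 2), spacing = spacing,
                        materials = mats, tumor_label = "top",
                        background_label = "bottom", shape = "rectangle",
                        platen_width = platen_width, base_bc = base_bc)
    # relabel the upper half as the second material
    cy <- matrix((seq_len(ncol(ph$label)) - 0.5) * ph$spacing,
                 nrow(ph$label), ncol(ph$label), byrow = TRUE)
    ph$label[ph$active & cy > ph$height / 2] <- 2L
    ph <- finish_phantom(ph)
  }
  ph
}
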