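#' Cylindrical airway phantom object
#'
#' An air-filled cylinder of lumen diameter `D` with a concentric wall of
#' muscle-like tissue of thickness `d`, axis perpendicular to the beam.
#' This is the canonical isolated-bronchus geometry: edge enhancement at
#' the air/wall interface is what makes sub-2-mm airways visible in
#' phase-contrast radiography.
#'
#' @param lumen_diameter Lumen diameter D in mm (> 0).
#' @param wall_thickness Wall thickness d in mm (>= 0).
#' @param center_offset Transverse position of the axis in mm.
#' @param lumen_material,wall_material Material names.
#' @return Object of class `cylinder_airway`.
#' @export
cylinder_airway <- function(lumen_diameter, wall_thickness = 0,
                            center_offset = 0,
                            lumen_material = "air", wall_material = "muscle") {
  stopifnot(lumen_diameter > 0, wall_thickness >= 0)
  structure(
    list(lumen_diameter = lumen_diameter, wall_thickness = wall_thickness,
         center_offset = center_offset,
         lumen_material = lumen_material, wall_material = wall_material,
         outer_radius = lumen_diameter / 2 + wall_thickness),
    class = c("cylinder_airway", "phantom_object")
  )
}

#' Spherical nodule phantom object
#'
#' Solid sphere of muscle-equivalent tissue (the standard solitary-nodule
#' surrogate, 6--20 mm diameter) embedded in parenchyma.
#'
#' @param diameter Diameter in mm (> 0).
#' @param center Center position in mm: scalar for 1D profiles, length-2
#'   `(x, y)` for 2D scenes.
#' @param material Material name.
#' @return Object of class `sphere_nodule`.
#' @export
sphere_nodule <- function(diameter, center = 0, material = "muscle") {
  stopifnot(diameter > 0, length(center) %in% c(1L, 2L))
  structure(
    list(diameter = diameter, center = center, material = material,
         outer_radius = diameter / 2),
    class = c("sphere_nodule", "phantom_object")
  )
}

#' Phantom scene: objects embedded in a homogeneous background slab
#'
#' Every ray traverses `background_thickness` of `background_material`;
#' embedded objects displace background along their chord, so per-ray total
#' thickness is conserved exactly.
#'
#' @param objects List of phantom objects ([cylinder_airway()],
#'   [sphere_nodule()]).
#' @param background_material Material name (default lung parenchyma).
#' @param background_thickness Slab thickness traversed by every ray, mm.
#' @param extent Transverse field width in mm; must cover all objects plus
#'   a margin.
#' @param margin Required clearance between any object and the field edge, mm.
#' @return Object of class `phantom_scene`.
#' @export
phantom_scene <- function(objects = list(),
                          background_material = "lung_parenchyma",
                          background_thickness = 100,
                          extent = 8, margin = 0.5) {
  stopifnot(background_thickness > 0, extent > 0, margin >= 0)
  for (ob in objects) {
    if (!inherits(ob, "phantom_object")) stop("objects must be phantom objects")
    if (2 * ob$outer_radius > background_thickness) {
      stop("object chord (", 2 * ob$outer_radius,
           " mm) exceeds background thickness (", background_thickness, " mm)")
    }
    cx <- ob[["center_offset"]] %||% ob$center[1L]
    if (abs(cx) + ob$outer_radius + margin > extent / 2) {
      stop("object at offset ", cx, " mm does not fit inside extent ",
           extent, " mm with margin ", margin, " mm")
    }
  }
  # pairwise overlap is a modelling error in v1 (thicknesses would double-count)
  if (length(objects) > 1L) {
    for (i in seq_len(length(objects) - 1L)) {
      for (j in seq((i + 1L), length(objects))) {
        ci <- objects[[i]][["center_offset"]] %||% objects[[i]]$center
        cj <- objects[[j]][["center_offset"]] %||% objects[[j]]$center
        ci <- if (length(ci) == 1L) c(ci, 0) else ci
        cj <- if (length(cj) == 1L) c(cj, 0) else cj
        if (sqrt(sum((ci - cj)^2)) <
            objects[[i]]$outer_radius + objects[[j]]$outer_radius) {
          stop("objects ", i, " and ", j, " overlap")
        }
      }
    }
  }
  structure(
    list(objects = objects, background_material = background_material,
         background_thickness = background_thickness,
         extent = extent, margin = margin),
    class = "phantom_scene"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %d object(s) in %g mm %s slab, extent %g mm\n",
              length(x$objects), x$background_thickness,
              x$background_material, x$extent))
  invisible(x)
}

#' Canonical isolated-airway scene
#'
#' The reference small-airway scenario: a 2-mm air lumen with a muscle wall
#' of thickness `d` (0.1--0.4 mm in the wall-thickening sweep), embedded in
#' a homogeneous lung-parenchyma slab. The slab thickness is largely
#' irrelevant because intensities are normalized to the parenchyma-only
#' region; 100 mm is the package default.
#'
#' @param wall_thickness Wall thickness d in mm, in (0, 1].
#' @param lumen_diameter Lumen diameter in mm (default 2).
#' @param background_thickness Parenchyma slab thickness in mm.
#' @param extent Transverse field width in mm.
#' @return A `phantom_scene`.
#' @export
airway_scene <- function(wall_thickness, lumen_diameter = 2,
                         background_thickness = 100, extent = 8) {
  if (!(wall_thickness > 0 && wall_thickness <= 1)) {
    stop("wall_thickness must be in (0, 1] mm; got ", wall_thickness)
  }
  phantom_scene(
    objects = list(cylinder_airway(lumen_diameter, wall_thickness)),
    background_material = "lung_parenchyma",
    background_thickness = background_thickness,
    extent = extent
  )
}

#' Nodule-in-parenchyma scene (2D region of interest)
#'
#' @param diameter Nodule diameter in mm (6--20 mm is the clinical sweep).
#' @param extent Transverse field width in mm.
#' @param background_thickness Parenchyma slab thickness in mm.
#' @return A `phantom_scene` with one centered `sphere_nodule`.
#' @export
nodule_scene <- function(diameter = 8, extent = 4 * ceiling(diameter / 2) + 8,
                         background_thickness = 100) {
  phantom_scene(
    objects = list(sphere_nodule(diameter, center = c(0, 0))),
    background_material = "lung_parenchyma",
    background_thickness = background_thickness,
    extent = extent
  )
}

#' Chord length of a circle
#'
#' Length of the intersection of the line at transverse distance `offset`
#' from the center with a disc of the given radius:
#' `2 * sqrt(radius^2 - offset^2)` inside, 0 at or beyond tangency.
#'
#' @param offset Signed transverse distance from the center, mm (vectorized).
#' @param radius Circle radius, mm (>= 0).
#' @return Chord length in mm.
#' @export
chord_length_circle <- function(offset, radius) {
  stopifnot(radius >= 0)
  h2 <- radius^2 - offset^2
  ifelse(h2 > 0, 2 * sqrt(pmax(h2, 0)), 0)
}

#' Simulation grid specification
#'
#' Transverse sample positions are `pitch * (i - N/2)` for i = 0..N-1, so a
#' symmetric grid straddles 0; N is forced even. 1D grids model a cylinder
#' cross-section profile; 2D grids (ny > 1) model square-pixel images.
#'
#' @param pitch Sample pitch x_s in mm (> 0).
#' @param extent Field width in mm; the sample count is `round(extent/pitch)`
#'   rounded up to even.
#' @param ny Number of rows for a 2D grid; default 1 (profile mode).
#' @return Object of class `grid_spec` with fields `pitch`, `n`, `ny`, `x`
#'   (and `y` when 2D).
#' @export
grid_spec <- function(pitch, extent, ny = 1L) {
  stopifnot(pitch > 0, extent > 0, ny >= 1L)
  n <- round(extent / pitch)
  if (n %% 2L == 1L) n <- n + 1L
  x <- pitch * (seq_len(n) - 1L - n / 2)
  g <- list(pitch = pitch, n = as.integer(n), ny = as.integer(ny), x = x)
  if (ny > 1L) {
    if (ny %% 2L == 1L) g$ny <- as.integer(ny + 1L)
    g$y <- pitch * (seq_len(g$ny) - 1L - g$ny / 2)
  }
  structure(g, class = "grid_spec")
}

#' Check the wavefront-sampling requirement
#'
#' Fresnel propagation over distance z at wavelength lambda needs the grid
#' sampled at least twice per first-Fresnel-zone width:
#' `x_s <= sqrt(lambda * z) / 2`. Returns the bound, the ratio
#' `x_s / bound`, and pass/fail; z = 0 passes trivially (no propagation).
#'
#' @param pitch Grid pitch x_s in mm.
#' @param wavelength Wavelength in mm.
#' @param z Propagation distance in mm (>= 0).
#' @return List with `pass`, `bound_mm`, `ratio`, `no_propagation`.
#' @export
check_sampling <- function(pitch, wavelength, z) {
  stopifnot(pitch > 0, wavelength > 0, z >= 0)
  if (z == 0) {
    return(list(pass = TRUE, bound_mm = Inf, ratio = 0, no_propagation = TRUE))
  }
  bound <- sqrt(wavelength * z) / 2
  list(pass = pitch <= bound, bound_mm = bound, ratio = pitch / bound,
       no_propagation = FALSE)
}

#' Per-material projected thickness map
#'
#' @param grid A [grid_spec()].
#' @param thickness Named list of numeric vectors (1D) or matrices (2D),
#'   one per material, thickness in mm at each sample.
#' @param background_thickness Per-ray total thickness, mm (conservation:
#'   the per-material thicknesses sum to this everywhere).
#' @return Object of class `thickness_map`.
#' @export
thickness_map <- function(grid, thickness, background_thickness) {
  stopifnot(inherits(grid, "grid_spec"), is.list(thickness),
            length(names(thickness)) == length(thickness))
  for (tm in thickness) {
    if (any(tm < -1e-12)) stop("negative thickness in map")
  }
  tot <- Reduce(`+`, thickness)
  if (max(abs(tot - background_thickness)) > 1e-9 * background_thickness) {
    stop("thickness map violates per-ray conservation")
  }
  structure(list(grid = grid, thickness = thickness,
                 background_thickness = background_thickness),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %s grid, %d sample(s) at %g um pitch; materials: %s\n",
              if (x$grid$ny > 1L) "2D" else "1D",
              x$grid$n * x$grid$ny, x$grid$pitch * 1e3,
              paste(names(x$thickness), collapse = ", ")))
  invisible(x)
}

# chords of one object on the grid: list of per-material thickness arrays
# (only the object's materials) plus the displaced total
object_chords <- function(ob, grid) {
  UseMethod("object_chords")
}

#' @export
object_chords.cylinder_airway <- function(ob, grid) {
  off <- grid$x - ob$center_offset
  inner <- chord_length_circle(off, ob$lumen_diameter / 2)
  outer <- chord_length_circle(off, ob$outer_radius)
  if (grid$ny > 1L) {  # cylinder axis along y: replicate across rows
    inner <- matrix(inner, nrow = grid$ny, ncol = grid$n, byrow = TRUE)
    outer <- matrix(outer, nrow = grid$ny, ncol = grid$n, byrow = TRUE)
  }
  out <- list()
  out[[ob$lumen_material]] <- inner
  out[[ob$wall_material]] <- (out[[ob$wall_material]] %||% 0) + (outer - inner)
  list(thickness = out, displaced = outer)
}

#' @export
object_chords.sphere_nodule <- function(ob, grid) {
  if (grid$ny > 1L) {
    dx <- outer(rep(1, grid$ny), grid$x - ob$center[1L])
    dy <- outer(grid$y - (if (length(ob$center) > 1L) ob$center[2L] else 0),
                rep(1, grid$n))
    r <- sqrt(dx^2 + dy^2)
  } else {
    r <- abs(grid$x - ob$center[1L])
  }
  ch <- chord_length_circle(r, ob$outer_radius)
  out <- list(); out[[ob$material]] <- ch
  list(thickness = out, displaced = ch)
}

#' Project a single airway into a thickness map
#'
#' At transverse position x the lumen thickness is the chord of the inner
#' circle, the wall thickness the chord difference of outer and inner
#' circles, and the background is reduced by the outer chord (displacement).
#' The grid must resolve the wall (`pitch <= wall_thickness`) unless
#' `allow_unresolved = TRUE`.
#'
#' @param airway A [cylinder_airway()].
#' @param grid A [grid_spec()].
#' @param background_material,background_thickness Slab the airway displaces.
#' @param allow_unresolved Skip the wall-resolution guard.
#' @return A `thickness_map`.
#' @export
project_airway <- function(airway, grid,
                           background_material = "lung_parenchyma",
                           background_thickness = 100,
                           allow_unresolved = FALSE) {
  stopifnot(inherits(airway, "cylinder_airway"), inherits(grid, "grid_spec"))
  if (airway$wall_thickness > 0 && grid$pitch > airway$wall_thickness &&
      !allow_unresolved) {
    stop("grid pitch ", grid$pitch, " mm does not resolve the ",
         airway$wall_thickness,
         " mm wall; refine the grid or set allow_unresolved = TRUE")
  }
  scene <- phantom_scene(list(airway), background_material,
                         background_thickness,
                         extent = grid$n * grid$pitch, margin = 0)
  project_scene(scene, grid)
}

#' Project a phantom scene into a per-material thickness map
#'
#' Sums the analytic chord projections of all objects; the background is
#' reduced by the total displaced chord so that the per-ray total thickness
#' equals the slab thickness exactly.
#'
#' @param scene A [phantom_scene()].
#' @param grid A [grid_spec()]; `grid$n * grid$pitch` should not exceed the
#'   scene extent.
#' @return A `thickness_map`.
#' @export
project_scene <- function(scene, grid) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(grid, "grid_spec"))
  if (grid$n * grid$pitch > scene$extent + 1e-9) {
    stop("grid (", grid$n * grid$pitch, " mm) is wider than the scene extent (",
         scene$extent, " mm)")
  }
  zero <- if (grid$ny > 1L) matrix(0, grid$ny, grid$n) else numeric(grid$n)
  thick <- list()
  displaced <- zero
  for (ob in scene$objects) {
    ch <- object_chords(ob, grid)
    for (nm in names(ch$thickness)) {
      thick[[nm]] <- (thick[[nm]] %||% zero) + ch$thickness[[nm]]
    }
    displaced <- displaced + ch$displaced
  }
  bg <- scene$background_thickness - displaced
  if (any(bg < 0)) stop("objects displace more than the background thickness")
  thick[[scene$background_material]] <-
    (thick[[scene$background_material]] %||% zero) + bg
  thickness_map(grid, thick, scene$background_thickness)
}

#' Project a voxelized phantom by nearest-neighbor ray summation
#'
#' Utility for user-supplied small voxel grids: sums voxel path lengths
#' along the beam axis per material code. Intended for desk-scale grids;
#' no edge-preserving upsampling is performed.
#'
#' @param voxels Integer array (nx-by-nz for 1D profiles) of material codes.
#' @param materials Character vector mapping code `i` to `materials[i]`.
#' @param voxel_pitch Voxel size in mm (isotropic).
#' @param grid A [grid_spec()] whose pitch is an integer divisor of
#'   `voxel_pitch` (nearest-neighbor supersampling) or equal to it.
#' @param background_thickness Total per-ray thickness; the part of the ray
#'   outside the voxel box is filled with `background_material`.
#' @param background_material Fill material name.
#' @return A `thickness_map`.
#' @export
project_voxels <- function(voxels, materials, voxel_pitch, grid,
                           background_thickness,
                           background_material = "lung_parenchyma") {
  stopifnot(is.matrix(voxels), voxel_pitch > 0, inherits(grid, "grid_spec"),
            grid$ny == 1L)
  nx <- nrow(voxels)
  box_depth <- ncol(voxels) * voxel_pitch
  if (box_depth > background_thickness) {
    stop("voxel box deeper than the background slab")
  }
  zero <- numeric(grid$n)
  thick <- list()
  half <- nx * voxel_pitch / 2
  for (i in seq_len(grid$n)) {
    ix <- floor((grid$x[i] + half) / voxel_pitch) + 1L  # nearest-neighbor column
    if (ix < 1L || ix > nx) next
    codes <- voxels[ix, ]
    for (code in unique(codes)) {
      nm <- materials[code]
      thick[[nm]] <- thick[[nm]] %||% zero
      thick[[nm]][i] <- thick[[nm]][i] + sum(codes == code) * voxel_pitch
    }
  }
  inside <- Reduce(`+`, thick) %||% zero
  thick[[background_material]] <-
    (thick[[background_material]] %||% zero) + (background_thickness - inside)
  thickness_map(grid, thick, background_thickness)
}
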