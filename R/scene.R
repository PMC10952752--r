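#' Analytic scene components: spheres, ellipsoids and boxes
#'
#' A `scene_component` is an analytic solid with a proton-density-like
#' amplitude `s0` and an effective transverse relaxation time `t2star_ms`;
#' the acquired signal at echo time TE follows the mono-exponential
#' `s0 * exp(-TE / T2*)` (see [signal_te()]). `radii` is the half-extent
#' per axis: for a sphere all three entries are equal, for a box they are
#' half edge lengths.
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"box"`.
#' @param center world position (mm) of the component center.
#' @param radii numeric length 3 (scalar recycled), half-extents in mm, all > 0.
#' @param s0 signal amplitude at TE = 0, > 0.
#' @param t2star_ms effective T2* in ms, > 0.
#' @return An object of class `scene_component`.
#' @export
scene_component <- function(kind = c("sphere", "ellipsoid", "box"),
                            center = c(0, 0, 0), radii = 1,
                            s0 = 100, t2star_ms = 60) {
  kind <- match.arg(kind)
  center <- as.numeric(rep_len(center, 3L))
  radii <- as.numeric(rep_len(radii, 3L))
  if (any(radii <= 0)) {
    abort("`radii` must all be > 0", class = "fetaltrack_argument_error")
  }
  if (s0 <= 0 || t2star_ms <= 0) {
    abort("`s0` and `t2star_ms` must be > 0", class = "fetaltrack_argument_error")
  }
  structure(list(kind = kind, center = center, radii = radii,
                 s0 = s0, t2star_ms = t2star_ms),
            class = "scene_component")
}

#' Assemble an analytic world scene
#'
#' A `world_scene` is an ordered list of [scene_component()]s (later
#' components overwrite earlier ones where they overlap) plus a uniform
#' background compartment. `target_index` points at the component the
#' tracking loop follows.
#'
#' @param components list of [scene_component()]s, non-empty.
#' @param target_index 1-based index of the tracked component.
#' @param background_s0 amplitude of the background compartment (>= 0);
#'   0 means air.
#' @param background_t2star_ms T2* (ms) of the background compartment.
#' @return An object of class `world_scene`.
#' @export
world_scene <- function(components, target_index = 1L,
                        background_s0 = 0, background_t2star_ms = 30) {
  if (!is.list(components) || length(components) == 0 ||
      !all(vapply(components, inherits, logical(1), "scene_component"))) {
    abort("`components` must be a non-empty list of scene_component objects",
          class = "fetaltrack_argument_error")
  }
  target_index <- as.integer(target_index)
  if (target_index < 1L || target_index > length(components)) {
    abort("`target_index` must point at a component",
          class = "fetaltrack_argument_error")
  }
  if (background_s0 < 0) {
    abort("`background_s0` must be >= 0", class = "fetaltrack_argument_error")
  }
  structure(list(components = components, target_index = target_index,
                 background_s0 = background_s0,
                 background_t2star_ms = background_t2star_ms),
            class = "world_scene")
}

#' Sphere phantom scene
#'
#' Emulates a spherical agarose phantom with relaxation properties similar
#' to fetal brain tissue: a single sphere centered at the world origin,
#' which is also the tracked target. With the default 3 mm isotropic
#' acquisition a 45 mm radius fills about half the FOV extent.
#'
#' @param radius_mm sphere radius in mm, > 0.
#' @param s0,t2star_ms signal parameters of the sphere.
#' @param background_s0 background amplitude (default 0, air).
#' @return A [world_scene()] with `target_index = 1`.
#' @export
make_sphere_world <- function(radius_mm = 45, s0 = 100, t2star_ms = 60,
                              background_s0 = 0) {
  if (radius_mm <= 0) {
    abort("`radius_mm` must be > 0", class = "fetaltrack_argument_error")
  }
  world_scene(
    list(scene_component("sphere", c(0, 0, 0), radius_mm, s0, t2star_ms)),
    target_index = 1L, background_s0 = background_s0
  )
}

#' Fetal-head-like scene with an optional confounding blob
#'
#' An ellipsoidal "head" target in a dim uniform background, optionally with
#' a smaller high-signal blob standing in for the maternal stomach — the
#' structure that intensity-similar segmentations are prone to latch onto.
#' The confounder's longer T2* makes it comparably bright or brighter than
#' the head at typical echo times, so it cannot be rejected on intensity
#' alone.
#'
#' @param head_radii_mm ellipsoid half-axes of the head in mm.
#' @param head_center world position of the head center (mm).
#' @param confounder a [scene_component()], or `NULL` for none.
#' @param background_s0 background amplitude (maternal tissue), >= 0.
#' @param s0,t2star_ms signal parameters of the head.
#' @return A [world_scene()] whose target is the head.
#' @export
make_fetal_world <- function(head_radii_mm = c(30, 25, 25),
                             head_center = c(0, 0, 0),
                             confounder = scene_component("sphere",
                                                          center = c(65, 0, 0),
                                                          radii = 13,
                                                          s0 = 100,
                                                          t2star_ms = 80),
                             background_s0 = 20,
                             s0 = 100, t2star_ms = 60) {
  head <- scene_component("ellipsoid", head_center, head_radii_mm, s0, t2star_ms)
  comps <- if (is.null(confounder)) list(head) else list(head, confounder)
  world_scene(comps, target_index = 1L, background_s0 = background_s0,
              background_t2star_ms = 30)
}

# logical array: voxel centers of `geometry` inside component displaced by `offset`
component_inside <- function(component, geometry, offset = c(0, 0, 0)) {
  ax <- axis_world_coords(geometry)
  ctr <- component$center + offset
  if (component$kind == "box") {
    ix <- abs(ax[[1]] - ctr[1]) <= component$radii[1]
    iy <- abs(ax[[2]] - ctr[2]) <= component$radii[2]
    iz <- abs(ax[[3]] - ctr[3]) <= component$radii[3]
    return(outer(outer(ix, iy, "&"), iz, "&"))
  }
  qx <- ((ax[[1]] - ctr[1]) / component$radii[1])^2
  qy <- ((ax[[2]] - ctr[2]) / component$radii[2])^2
  qz <- ((ax[[3]] - ctr[3]) / component$radii[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

#' Point-in-component membership test
#'
#' @param scene a [world_scene()].
#' @param point world coordinates (mm), vector of 3 or n x 3 matrix.
#' @param component_index which component to test (default the target).
#' @param offset world-frame displacement applied to the component.
#' @return Logical vector.
#' @export
scene_membership <- function(scene, point,
                             component_index = scene$target_index,
                             offset = c(0, 0, 0)) {
  comp <- scene$components[[component_index]]
  p <- if (is.matrix(point)) point else matrix(point, 1L)
  q <- sweep(p, 2, comp$center + offset)
  if (comp$kind == "box") {
    apply(abs(q) <= matrix(comp$radii, nrow(q), 3, byrow = TRUE), 1, all)
  } else {
    rowSums(sweep(q, 2, comp$radii, "/")^2) <= 1
  }
}
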