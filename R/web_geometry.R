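#' Geometric parameters of an orb web
#'
#' Bundles the measured geometry of a 'large frame' *Argiope* orb web:
#' a circular capture area spanned by evenly spaced radial threads and a
#' single capture spiral, suspended in a square support frame. Defaults are
#' the published mean values for *A. radon* (SI units, metres).
#'
#' The spiral is laid down at a constant pitch, so the geometry is
#' consistent when `internal_radius + spiral_pitch * spiral_turns ==
#' external_radius`; a mismatch triggers a warning in [build_web()] and the
#' crossing radii are taken from the pitch formula.
#'
#' @param external_radius Outer radius of the capture spiral (m).
#' @param internal_radius Radius of the hub ring where the spiral starts (m).
#' @param support_width,support_height Dimensions of the square support
#'   frame the web hangs in (m). Half the width must exceed the external
#'   radius so the web fits inside the frame.
#' @param spiral_pitch Radial distance between consecutive spiral turns (m).
#' @param spiral_turns Number of spiral turns (integer >= 1).
#' @param radial_strands Number of radial threads (integer >= 3).
#'
#' @return An object of class `"web_geometry_params"`.
#' @examples
#' p <- web_geometry_params()
#' p$external_radius
#' @seealso [build_web()], [impact_points()]
#' @export
web_geometry_params <- function(external_radius = 0.183,
                                internal_radius = 0.011,
                                support_width = 0.5,
                                support_height = 0.5,
                                spiral_pitch = 0.004,
                                spiral_turns = 43L,
                                radial_strands = 31L) {
  spiral_turns <- as.integer(spiral_turns)
  radial_strands <- as.integer(radial_strands)
  if (!isTRUE(external_radius > internal_radius) || !isTRUE(internal_radius > 0))
    stop("need external_radius > internal_radius > 0", call. = FALSE)
  if (is.na(spiral_turns) || spiral_turns < 1L)
    stop("spiral_turns must be a positive integer", call. = FALSE)
  if (is.na(radial_strands) || radial_strands < 3L)
    stop("radial_strands must be an integer >= 3", call. = FALSE)
  if (spiral_pitch <= 0) stop("spiral_pitch must be positive", call. = FALSE)
  if (support_width / 2 <= external_radius || support_height / 2 <= external_radius)
    stop("web does not fit inside the support frame (support/2 must exceed external_radius)",
         call. = FALSE)
  structure(
    list(external_radius = external_radius,
         internal_radius = internal_radius,
         support_width = support_width,
         support_height = support_height,
         spiral_pitch = spiral_pitch,
         spiral_turns = spiral_turns,
         radial_strands = radial_strands),
    class = "web_geometry_params")
}

#' @export
print.web_geometry_params <- function(x, ...) {
  cat("Orb-web geometry (m):\n")
  cat(sprintf("  external radius %.4g, internal radius %.4g\n",
              x$external_radius, x$internal_radius))
  cat(sprintf("  support frame %.3g x %.3g\n", x$support_width, x$support_height))
  cat(sprintf("  spiral: %d turns at pitch %.4g; %d radial strands\n",
              x$spiral_turns, x$spiral_pitch, x$radial_strands))
  invisible(x)
}

# Radial thread directions in the web plane. The seam of the spiral (the one
# omitted spiral link, between the last and the first radial) is centred on
# the upward vertical, which makes the whole link set mirror-symmetric about
# the vertical axis through the hub -- a property the dynamics tests rely on.
radial_angles <- function(n) {
  offset <- pi / 2 + pi / n
  offset + 2 * pi * (seq_len(n) - 1L) / n
}

# Where a radial ray meets the square support boundary.
anchor_radius <- function(theta, half_w, half_h) {
  pmin(half_w / pmax(abs(cos(theta)), .Machine$double.eps),
       half_h / pmax(abs(sin(theta)), .Machine$double.eps))
}

#' Build the orb-web node/link model
#'
#' Constructs the web graph: one hub centre node, a hub ring node per radial
#' at the internal radius, one crossing node per radial per spiral turn at
#' radii `internal_radius + k * spiral_pitch`, a fixed perimeter anchor where
#' each radial meets the square support, and the four fixed frame corners.
#' Each radial carries `spiral_turns + 2` links (centre to hub ring, hub ring
#' through the crossings, last crossing to anchor). The spiral is represented
#' as concentric rings of links joining same-turn crossings on adjacent
#' radials, with a single seam opening, and four frame links join the corner
#' nodes around the perimeter. For the default geometry this reproduces the
#' published census of 2731 links.
#'
#' Coordinates: the web plane is the vertical plane `x = 0`, with `y` the
#' vertical (gravity acts along `-y`) and `z` the horizontal in-plane axis;
#' a projectile travels along `+x`, the horizontal normal. The hub centre is
#' the origin.
#'
#' @param params A [web_geometry_params()] object.
#' @return An object of class `"spider_web"`: a list with elements `params`,
#'   `nodes` (data frame: `id`, `x`, `y`, `z`, `fixed`, `role`, `radial`,
#'   `turn`) and `links` (data frame: `id`, `node_a`, `node_b`,
#'   `thread_type`, `natural_length`, `broken`).
#' @examples
#' web <- build_web(web_geometry_params(spiral_turns = 3, radial_strands = 5))
#' count_links(web)
#' @export
build_web <- function(params = web_geometry_params()) {
  stopifnot(inherits(params, "web_geometry_params"))
  nr <- params$radial_strands
  nt <- params$spiral_turns
  r_int <- params$internal_radius
  r_ext <- params$external_radius
  pitch <- params$spiral_pitch

  if (abs(r_int + pitch * nt - r_ext) > 1e-9 * max(r_ext, 1)) {
    warning(sprintf(paste0("inconsistent geometry: internal_radius + pitch * turns = %.6g ",
                           "but external_radius = %.6g; using crossing radii from the pitch formula"),
                    r_int + pitch * nt, r_ext), call. = FALSE)
  }

  theta <- radial_angles(nr)
  cu <- cos(theta); sv <- sin(theta)
  half_w <- params$support_width / 2
  half_h <- params$support_height / 2

  # node ids: 1 centre | 2..(1+nr) hub ring | crossings | anchors | corners
  id_center <- 1L
  id_hub <- 1L + seq_len(nr)
  id_cross <- function(i, k) 1L + nr + (i - 1L) * nt + k   # i radial, k turn
  n_cross <- nr * nt
  id_anchor <- 1L + nr + n_cross + seq_len(nr)
  id_corner <- 1L + nr + n_cross + nr + seq_len(4L)
  n_nodes <- 1L + nr + n_cross + nr + 4L

  u <- numeric(n_nodes); v <- numeric(n_nodes)
  role <- character(n_nodes); fixed <- logical(n_nodes)
  radial_of <- rep(NA_integer_, n_nodes); turn_of <- rep(NA_integer_, n_nodes)

  role[id_center] <- "center"
  u[id_hub] <- r_int * cu; v[id_hub] <- r_int * sv
  role[id_hub] <- "hub_ring"; radial_of[id_hub] <- seq_len(nr)
  for (k in seq_len(nt)) {
    r_k <- r_int + k * pitch
    ids <- id_cross(seq_len(nr), k)
    u[ids] <- r_k * cu; v[ids] <- r_k * sv
    role[ids] <- "crossing"; radial_of[ids] <- seq_len(nr); turn_of[ids] <- k
  }
  r_a <- anchor_radius(theta, half_w, half_h)
  u[id_anchor] <- r_a * cu; v[id_anchor] <- r_a * sv
  role[id_anchor] <- "perimeter_anchor"; fixed[id_anchor] <- TRUE
  radial_of[id_anchor] <- seq_len(nr)
  u[id_corner] <- c(half_w, -half_w, -half_w, half_w)
  v[id_corner] <- c(half_h, half_h, -half_h, -half_h)
  role[id_corner] <- "frame_corner"; fixed[id_corner] <- TRUE

  nodes <- data.frame(id = seq_len(n_nodes), x = 0, y = v, z = u,
                      fixed = fixed, role = role,
                      radial = radial_of, turn = turn_of)

  # radial links: per radial, centre->hub, hub->crossing 1, consecutive
  # crossings, last crossing->anchor  (= turns + 2 links each)
  a <- integer(0); b <- integer(0)
  for (i in seq_len(nr)) {
    chain <- c(id_center, id_hub[i], id_cross(i, seq_len(nt)), id_anchor[i])
    a <- c(a, chain[-length(chain)]); b <- c(b, chain[-1L])
  }
  type <- rep("radial", length(a))

  # spiral links: same-turn crossings on adjacent radials, cyclic, with one
  # seam opening at the outermost turn between the last and first radial
  for (k in seq_len(nt)) {
    i <- seq_len(nr)
    j <- c(seq_len(nr)[-1L], 1L)
    keep <- !(k == nt & i == nr)           # the seam
    a <- c(a, id_cross(i[keep], k)); b <- c(b, id_cross(j[keep], k))
    type <- c(type, rep("spiral", sum(keep)))
  }

  # frame links join the four fixed corners around the perimeter
  a <- c(a, id_corner); b <- c(b, id_corner[c(2L, 3L, 4L, 1L)])
  type <- c(type, rep("frame", 4L))

  len <- sqrt((nodes$x[a] - nodes$x[b])^2 +
              (nodes$y[a] - nodes$y[b])^2 +
              (nodes$z[a] - nodes$z[b])^2)
  links <- data.frame(id = seq_along(a), node_a = a, node_b = b,
                      thread_type = type, natural_length = len,
                      broken = FALSE)

  structure(list(params = params, nodes = nodes, links = links),
            class = "spider_web")
}

#' Count links by thread class
#'
#' Tallies the web's links per thread type. For a web built by [build_web()]
#' the counts follow `radial = (turns + 2) * radials`,
#' `spiral = turns * radials - 1` and `frame = 4`; the default geometry gives
#' the published total of 2731.
#'
#' @param web A `"spider_web"` object.
#' @return An object of class `"link_census"`: a list with `radial`,
#'   `spiral`, `frame` and `total` counts.
#' @examples
#' count_links(build_web())
#' @export
count_links <- function(web) {
  stopifnot(inherits(web, "spider_web"))
  tt <- web$links$thread_type
  out <- list(radial = sum(tt == "radial"),
              spiral = sum(tt == "spiral"),
              frame = sum(tt == "frame"))
  out$total <- out$radial + out$spiral + out$frame
  structure(out, class = "link_census")
}

#' @export
print.link_census <- function(x, ...) {
  cat(sprintf("Link census: %d radial + %d spiral + %d frame = %d total\n",
              x$radial, x$spiral, x$frame, x$total))
  invisible(x)
}

#' @export
print.spider_web <- function(x, ...) {
  cat(sprintf("Orb-web model: %d nodes (%d fixed), ", nrow(x$nodes), sum(x$nodes$fixed)))
  print(count_links(x))
  invisible(x)
}

#' Impact target grid on the web surface
#'
#' Generates the in-plane target points at which projectile impacts are
#' simulated. The default 23-point pattern is one centre point, 8 points
#' equally spaced on a ring at 0.35 of the external radius, and 14 points on
#' a ring at 0.70 of the external radius, the outer ring rotated by half its
#' angular spacing. Any other `n` falls back to a centre point plus a single
#' ring of `n - 1` points at half the external radius (`n = 1` gives the
#' centre alone).
#'
#' @param params A [web_geometry_params()] object.
#' @param n Number of target points.
#' @return An object of class `"impact_grid"`: a data frame with columns
#'   `point`, `u` (horizontal in-plane, m) and `v` (vertical, m), relative
#'   to the hub centre.
#' @examples
#' g <- impact_points(web_geometry_params())
#' nrow(g)           # 23
#' max(sqrt(g$u^2 + g$v^2))
#' @export
impact_points <- function(params = web_geometry_params(), n = 23L) {
  stopifnot(inherits(params, "web_geometry_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  R <- params$external_radius
  ring <- function(m, r, phase = 0) {
    ang <- phase + 2 * pi * (seq_len(m) - 1L) / m
    cbind(u = r * cos(ang), v = r * sin(ang))
  }
  if (n == 23L) {
    pts <- rbind(c(0, 0),
                 ring(8L, 0.35 * R),
                 ring(14L, 0.70 * R, phase = pi / 14))
  } else if (n == 1L) {
    pts <- matrix(0, 1L, 2L)
  } else {
    pts <- rbind(c(0, 0), ring(n - 1L, 0.5 * R))
  }
  structure(data.frame(point = seq_len(n), u = pts[, 1L], v = pts[, 2L]),
            class = c("impact_grid", "data.frame"))
}

#' Render the web and impact grid
#'
#' Base-graphics sketch of the web model in the web plane, optionally with
#' the impact target points overlaid.
#'
#' @param x A `"spider_web"` object.
#' @param points Optional [impact_points()] grid to overlay.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spider_web <- function(x, points = NULL, ...) {
  nd <- x$nodes; lk <- x$links
  graphics::plot(NA, xlim = range(nd$z), ylim = range(nd$y), asp = 1,
                 xlab = "horizontal (m)", ylab = "vertical (m)", ...)
  col <- c(radial = "grey30", spiral = "steelblue", frame = "grey60")
  graphics::segments(nd$z[lk$node_a], nd$y[lk$node_a],
                     nd$z[lk$node_b], nd$y[lk$node_b],
                     col = col[lk$thread_type], lwd = ifelse(lk$thread_type == "frame", 2, 0.4))
  if (!is.null(points))
    graphics::points(points$u, points$v, pch = 21, bg = "orange")
  invisible(x)
}

#' Write an SVG rendering of the web
#'
#' @param web A `"spider_web"` object.
#' @param file Output SVG path.
#' @param points Optional impact grid to overlay.
#' @return `file`, invisibly.
#' @export
render_web_svg <- function(web, file, points = NULL) {
  grDevices::svg(file, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  plot(web, points = points, main = "Orb-web model")
  invisible(file)
}
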