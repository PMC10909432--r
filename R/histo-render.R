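#' Histology rendering style
#'
#' Colour palette emulating Perls' Prussian blue with nuclear fast red
#' counterstain and a DAB-brown vessel stain: iron (endogenous or MPIO)
#' renders blue, vessel walls brown rings, background pink. Colours are
#' RGB in \[0, 1\]; the iron colour satisfies the blue-dominance rule used
#' by [segment_iron()] (B − max(R, G) above the margin) while background
#' and vessel colours do not.
#'
#' @param background,vessel,iron RGB triplets in \[0, 1\].
#' @param vessel_wall_um Vessel wall (ring) thickness in um.
#' @return An object of class `histo_style`.
#' @export
histo_style <- function(background = c(0.98, 0.86, 0.88),
                        vessel = c(0.55, 0.35, 0.16),
                        iron = c(0.16, 0.25, 0.60),
                        vessel_wall_um = 2) {
  structure(list(background = background, vessel = vessel, iron = iron,
                 vessel_wall_um = vessel_wall_um),
            class = "histo_style")
}

# Linear pixel indices of an annulus/disc. Pixel (row r, col c) has physical
# centre ((c - 0.5) * psz, (r - 0.5) * psz): rows index y, columns index x.
disc_pixels <- function(cx, cy, r_out, psz, ny, nx, r_in = 0) {
  c_lo <- max(1L, floor((cx - r_out) / psz)); c_hi <- min(nx, ceiling((cx + r_out) / psz) + 1L)
  r_lo <- max(1L, floor((cy - r_out) / psz)); r_hi <- min(ny, ceiling((cy + r_out) / psz) + 1L)
  if (c_lo > c_hi || r_lo > r_hi) return(integer(0))
  cols <- c_lo:c_hi; rows <- r_lo:r_hi
  px <- (cols - 0.5) * psz; py <- (rows - 0.5) * psz
  d2 <- outer((py - cy)^2, (px - cx)^2, "+")
  sel <- which(d2 <= r_out^2 & d2 >= r_in^2, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(integer(0))
  rows[sel[, 1]] + (cols[sel[, 2]] - 1L) * ny
}

#' Render a histology scene to an RGB image
#'
#' Rasterises a [generate_histo_scene()] scene: pink background, brown
#' vessel-wall annuli (from lumen radius outward by the wall thickness),
#' blue macrophage discs (disc area equal to the scene's iron area) and
#' blue 1-um MPIO discs, drawn in that order so iron always overdraws
#' vessel walls. Every non-clipped object maps to a connected region of
#' its colour class; disjoint scene objects yield one connected blue
#' component each.
#'
#' @param scene A `histo_scene`.
#' @param style A [histo_style()].
#' @param mpio_diameter_um Rendered bead diameter in um.
#' @return Numeric array `height x width x 3` in \[0, 1\] with attribute
#'   `pixel_size_um`.
#' @export
render_histo <- function(scene, style = histo_style(), mpio_diameter_um = 1) {
  stopifnot(inherits(scene, "histo_scene"))
  psz <- scene$pixel_size_um
  assert_scalar_pos(psz, "pixel_size_um")
  nx <- round(scene$field_um[1] / psz)
  ny <- round(scene$field_um[2] / psz)
  # per-channel planes painted in place (no whole-image copies per object)
  red <- matrix(style$background[1], ny, nx)
  green <- matrix(style$background[2], ny, nx)
  blue <- matrix(style$background[3], ny, nx)
  idx_list <- c(
    lapply(seq_len(nrow(scene$vessels)), function(i) {
      v <- scene$vessels[i, ]
      disc_pixels(v$x, v$y, v$lumen_radius + style$vessel_wall_um,
                  psz, ny, nx, r_in = v$lumen_radius)
    }),
    lapply(seq_len(nrow(scene$macrophages)), function(i) {
      m <- scene$macrophages[i, ]
      disc_pixels(m$x, m$y, sqrt(m$iron_area / pi), psz, ny, nx)
    }),
    lapply(seq_len(nrow(scene$single_mpio)), function(i) {
      b <- scene$single_mpio[i, ]
      disc_pixels(b$x, b$y, mpio_diameter_um / 2, psz, ny, nx)
    }))
  cols <- c(rep(list(style$vessel), nrow(scene$vessels)),
            rep(list(style$iron),
                nrow(scene$macrophages) + nrow(scene$single_mpio)))
  for (i in seq_along(idx_list)) {
    idx <- idx_list[[i]]
    red[idx] <- cols[[i]][1]
    green[idx] <- cols[[i]][2]
    blue[idx] <- cols[[i]][3]
  }
  img <- array(c(red, green, blue), dim = c(ny, nx, 3))
  attr(img, "pixel_size_um") <- psz
  img
}
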