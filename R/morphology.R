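#' Stylized layer-5 pyramidal-cell morphology
#'
#' Programmatically generated passive morphology mimicking the gross geometry
#' of a cortical layer-5 pyramidal cell: a bush of basal dendrites around the
#' soma, an apical trunk ascending roughly 1 mm, a few oblique branches, and
#' an apical tuft. Synthetic by construction — it is not a reconstructed
#' neuron; population-level asymmetry (basal vs apical input regions) and
#' total depth extent are the properties that matter for kernel building.
#'
#' Coordinates are local (soma at the origin) until the cell is placed; the
#' apical trunk points in +z. Segment azimuths are drawn from the seed, so
#' the same seed always yields the same morphology.
#'
#' @param seed integer seed controlling branch azimuths.
#' @param soma_z if non-`NULL`, translate the cell so the soma sits at this
#'   depth (micrometers, negative below the cortical surface).
#' @param rotation rotation about the z axis (radians).
#' @param n_basal number of basal dendrites.
#' @param n_tuft number of tuft branches.
#' @param seg_len target segment length (micrometers).
#' @return An object of class `morphology`: data.frame with columns
#'   `id`, `label` (soma/basal/trunk/oblique/tuft), `x0,y0,z0`, `x1,y1,z1`,
#'   `diam` and `parent` (0 for the root soma).
#' @export
build_stylized_l5 <- function(seed = 1, soma_z = NULL, rotation = 0,
                              n_basal = 8, n_tuft = 6, seg_len = 25) {
  set.seed(seed)
  rows <- list()
  add <- function(label, p0, p1, diam, parent) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = length(rows) + 1L, label = label,
      x0 = p0[1], y0 = p0[2], z0 = p0[3],
      x1 = p1[1], y1 = p1[2], z1 = p1[3],
      diam = diam, parent = parent)
    length(rows)
  }
  # cylindrical soma, treated as a point source in the volume conductor
  soma <- add("soma", c(0, 0, -10), c(0, 0, 10), 20, 0L)

  grow <- function(label, parent, p0, dir, total_len, diam0, diam1) {
    n <- max(1L, ceiling(total_len / seg_len))
    l <- total_len / n
    for (k in seq_len(n)) {
      p1 <- p0 + dir * l
      d <- diam0 + (diam1 - diam0) * (k - 0.5) / n
      parent <- add(label, p0, p1, d, parent)
      p0 <- p1
    }
    list(parent = parent, tip = p0)
  }
  unit <- function(v) v / sqrt(sum(v^2))

  # basal bush: dendrites radiating outward and downward
  for (b in seq_len(n_basal)) {
    phi <- 2 * pi * (b - 1) / n_basal + stats::runif(1, -0.2, 0.2)
    tilt <- stats::runif(1, -65, -25) * pi / 180    # below horizontal
    dir <- c(cos(phi) * cos(tilt), sin(phi) * cos(tilt), sin(tilt))
    grow("basal", soma, c(0, 0, -10), unit(dir),
         stats::runif(1, 150, 220), 2, 0.8)
  }
  # apical trunk to ~1000 um, with a slight wobble
  trunk_tip <- c(0, 0, 10)
  parent <- soma
  n_tr <- ceiling(1000 / seg_len)
  for (k in seq_len(n_tr)) {
    dir <- unit(c(stats::runif(1, -0.06, 0.06), stats::runif(1, -0.06, 0.06), 1))
    p1 <- trunk_tip + dir * (1000 / n_tr)
    parent <- add("trunk", trunk_tip, p1, 4.5 - 2.5 * k / n_tr, parent)
    trunk_tip <- p1
    # two oblique branches off the lower trunk
    if (k %in% c(3L, 7L)) {
      phi <- stats::runif(1, 0, 2 * pi)
      odir <- unit(c(cos(phi), sin(phi), 0.25))
      grow("oblique", parent, trunk_tip, odir, 150, 1.5, 0.7)
    }
  }
  # tuft branches fanning out and upward from the trunk tip
  for (b in seq_len(n_tuft)) {
    phi <- 2 * pi * (b - 1) / n_tuft + stats::runif(1, -0.3, 0.3)
    tilt <- stats::runif(1, 15, 55) * pi / 180
    dir <- c(cos(phi) * cos(tilt), sin(phi) * cos(tilt), sin(tilt))
    grow("tuft", parent, trunk_tip, unit(dir), stats::runif(1, 150, 230),
         1.2, 0.6)
  }
  m <- do.call(rbind, rows)
  class(m) <- c("morphology", "data.frame")
  m <- place_morphology(m, soma_z = 0, rotation = rotation)
  if (!is.null(soma_z)) m <- place_morphology(m, soma_z = soma_z)
  m
}

#' Place (rotate and translate) a morphology
#'
#' Rotates the cell about its somatic z axis and translates it so the soma
#' midpoint lands at (`x`, `y`, `soma_z`). Rotation leaves z coordinates
#' unchanged.
#'
#' @param m a `morphology`.
#' @param soma_z target soma depth (micrometers).
#' @param x,y target horizontal soma position (micrometers).
#' @param rotation rotation about the z axis (radians).
#' @return the transformed `morphology`.
#' @export
place_morphology <- function(m, soma_z = 0, x = 0, y = 0, rotation = 0) {
  stopifnot(inherits(m, "morphology"))
  soma_idx <- which(m$label == "soma")[1L]
  cx <- (m$x0[soma_idx] + m$x1[soma_idx]) / 2
  cy <- (m$y0[soma_idx] + m$y1[soma_idx]) / 2
  cz <- (m$z0[soma_idx] + m$z1[soma_idx]) / 2
  for (p in list(c("x0", "y0"), c("x1", "y1"))) {
    xx <- m[[p[1]]] - cx; yy <- m[[p[2]]] - cy
    m[[p[1]]] <- cos(rotation) * xx - sin(rotation) * yy
    m[[p[2]]] <- sin(rotation) * xx + cos(rotation) * yy
  }
  m$z0 <- m$z0 - cz; m$z1 <- m$z1 - cz
  m$x0 <- m$x0 + x; m$x1 <- m$x1 + x
  m$y0 <- m$y0 + y; m$y1 <- m$y1 + y
  m$z0 <- m$z0 + soma_z; m$z1 <- m$z1 + soma_z
  m
}

#' @export
print.morphology <- function(x, ...) {
  cat("morphology:", nrow(x), "segments;",
      paste(names(table(x$label)), as.integer(table(x$label)),
            collapse = ", "),
      "\n  z extent:", round(min(pmin(x$z0, x$z1))), "..",
      round(max(pmax(x$z0, x$z1))), "um\n")
  invisible(x)
}

# segment midpoints (n x 3), lengths and membrane areas (um, um^2)
.segment_geometry <- function(m) {
  mid <- cbind((m$x0 + m$x1) / 2, (m$y0 + m$y1) / 2, (m$z0 + m$z1) / 2)
  len <- sqrt((m$x1 - m$x0)^2 + (m$y1 - m$y0)^2 + (m$z1 - m$z0)^2)
  area <- pi * m$diam * len
  list(mid = mid, len = len, area = area)
}

#' Write / read morphologies as SWC text
#'
#' Standard SWC sample list: `id type x y z radius parent`, one sample per
#' point (the root soma contributes its start and end points; every other
#' segment contributes its end point, attached to the sample at its start).
#' Types: 1 soma, 3 basal, 4 apical trunk, 5 oblique, 6 tuft.
#'
#' @param m a `morphology`.
#' @param path file path.
#' @export
write_morphology <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  type_code <- c(soma = 1L, basal = 3L, trunk = 4L, oblique = 5L, tuft = 6L)
  n <- nrow(m)
  # sample 1 = root start, sample i+1 = end point of segment i
  end_sample <- seq_len(n) + 1L
  par_sample <- integer(n)
  par_sample[1L] <- 1L
  for (i in which(m$parent > 0L)) {
    pr <- m$parent[i]
    d_end <- (m$x0[i] - m$x1[pr])^2 + (m$y0[i] - m$y1[pr])^2 +
      (m$z0[i] - m$z1[pr])^2
    d_start <- (m$x0[i] - m$x0[pr])^2 + (m$y0[i] - m$y0[pr])^2 +
      (m$z0[i] - m$z0[pr])^2
    par_sample[i] <- if (d_end <= d_start) end_sample[pr]
    else if (pr == 1L) 1L else end_sample[m$parent[pr]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("1 1 %.9g %.9g %.9g %.9g -1",
                     m$x0[1L], m$y0[1L], m$z0[1L], m$diam[1L] / 2), con)
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     end_sample, type_code[m$label], m$x1, m$y1, m$z1,
                     m$diam / 2, par_sample), con)
  invisible(path)
}

#' @rdname write_morphology
#' @export
read_morphology <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  df <- df[order(df$id), ]
  labels <- c(`1` = "soma", `3` = "basal", `4` = "trunk", `5` = "oblique",
              `6` = "tuft")
  segs <- which(df$parent > 0)              # every non-root sample = segment
  seg_of_sample <- integer(nrow(df))
  seg_of_sample[df$id[segs]] <- seq_along(segs)
  p <- match(df$parent[segs], df$id)
  label <- labels[as.character(df$type[segs])]
  soma_row <- which(label == "soma")[1L]
  # segments hanging off the root start sample attach to the soma segment;
  # the soma edge itself is the tree root
  parent <- ifelse(df$parent[segs] == 1L, soma_row,
                   seg_of_sample[df$parent[segs]])
  parent[soma_row] <- 0L
  m <- data.frame(
    id = seq_along(segs), label = label,
    x0 = df$x[p], y0 = df$y[p], z0 = df$z[p],
    x1 = df$x[segs], y1 = df$y[segs], z1 = df$z[segs],
    diam = 2 * df$radius[segs], parent = parent)
  class(m) <- c("morphology", "data.frame")
  m
}
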