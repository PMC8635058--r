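# Electrode montage: 2-D azimuthal projection of the scalp onto the unit
# disc, nose towards +y. Coordinates are derived from nominal 10-10 system
# angles (inclination from the vertex, azimuth from the nose direction),
# projected as r = inclination / 90 deg.

.montage_angles <- function() {
  # name, inclination (deg from Cz), azimuth (deg from nose, + to the right)
  m <- rbind(
    c("Fp1", 90, -18), c("Fp2", 90, 18),
    c("F7",  90, -54), c("F3",  60, -39), c("Fz", 45, 0),
    c("F4",  60,  39), c("F8",  90,  54),
    c("FC5", 71, -69), c("FC1", 32, -45), c("FCz", 22, 0),
    c("FC2", 32,  45), c("FC6", 71,  69),
    c("T7",  90, -90), c("C3",  45, -90), c("Cz", 0, 0),
    c("C4",  45,  90), c("T8",  90,  90),
    c("CP5", 71, -111), c("CP1", 32, -135), c("CPz", 22, 180),
    c("CP2", 32,  135), c("CP6", 71,  111),
    c("P7",  90, -126), c("P3",  60, -141), c("Pz", 45, 180),
    c("P4",  60,  141), c("P8",  90,  126),
    c("POz", 67, 180),
    c("O1",  90, -162), c("Oz",  90, 180), c("O2", 90, 162)
  )
  data.frame(name = m[, 1], inc = as.numeric(m[, 2]), azi = as.numeric(m[, 3]),
             stringsAsFactors = FALSE)
}

#' Default 31-channel EEG montage
#'
#' A 31-channel 10-10 style montage projected azimuthally onto the unit
#' disc (nose at +y). This is the electrode layout used by the synthetic
#' study emulation and by the scalp-topogram renderer.
#'
#' @return a `montage` data frame with columns `name`, `x`, `y`.
#' @export
#' @examples
#' m <- default_montage()
#' nrow(m)  # 31
default_montage <- function() {
  a <- .montage_angles()
  r <- a$inc / 90
  montage(data.frame(
    name = a$name,
    x = r * sin(a$azi * pi / 180),
    y = r * cos(a$azi * pi / 180),
    stringsAsFactors = FALSE
  ))
}

#' Construct a montage object
#'
#' @param df data frame with columns `name`, `x`, `y`; coordinates are a
#'   2-D head projection with the scalp mapped inside the unit disc.
#' @return a validated `montage` data frame.
#' @export
montage <- function(df) {
  stopifnot(is.data.frame(df), all(c("name", "x", "y") %in% names(df)))
  if (anyDuplicated(df$name)) stop("duplicate channel names in montage")
  d <- as.matrix(stats::dist(df[, c("x", "y")]))
  diag(d) <- Inf
  if (any(d < 1e-9)) stop("duplicate electrode coordinates in montage")
  structure(df, class = c("montage", "data.frame"))
}

#' Read / write a montage as CSV
#'
#' Plain `name,x,y` CSV, the interchange format for electrode layouts.
#'
#' @param path file path.
#' @return `read_montage` returns a `montage`; `write_montage` its path,
#'   invisibly.
#' @export
read_montage <- function(path) {
  montage(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_montage
#' @param m a `montage`.
#' @export
write_montage <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Spatial channel neighbourhood graph
#'
#' Channels closer than `max_dist` (in projected-montage units, head radius
#' = 1) are neighbours. With the default montage and distance the median
#' degree is in the 4-6 range typical of sensor-space cluster correction
#' templates. The graph is symmetric and irreflexive.
#'
#' @param m a `montage`.
#' @param max_dist neighbourhood radius; default 0.45.
#' @return a `neighbor_graph`: named list mapping each channel to a character
#'   vector of its spatial neighbours, with the logical adjacency matrix in
#'   attribute `adjacency`.
#' @export
channel_neighbors <- function(m, max_dist = 0.45) {
  stopifnot(inherits(m, "montage"), max_dist > 0)
  d <- as.matrix(stats::dist(m[, c("x", "y")]))
  adj <- d <= max_dist
  diag(adj) <- FALSE
  dimnames(adj) <- list(m$name, m$name)
  g <- lapply(seq_len(nrow(adj)), function(i) m$name[adj[i, ]])
  names(g) <- m$name
  structure(g, adjacency = adj, class = "neighbor_graph")
}
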