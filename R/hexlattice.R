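# Periodic hexagonal lattice: geometry, concentric-ring templates, local
# density, initial conditions and plain-text state snapshots.
#
# Storage is "odd-row offset": site (i, j) with i in 0..I-1, j in 0..J-1 sits
# at x = (i + (j mod 2)/2) * delta, y = j * sqrt(3)/2 * delta, so odd rows are
# shifted half a spacing to the right.  J must be even for the offset pattern
# to wrap consistently under vertical periodicity.

#' Periodic hexagonal lattice geometry
#'
#' @param I number of columns; the physical domain width is `L = I * delta`.
#' @param J number of rows (must be even).  All reported quantities are
#'   column averages, so the physical height `J * sqrt(3)/2 * delta` need not
#'   equal `L`.
#' @param delta nearest-neighbour spacing.
#' @return An object of class `hex_geometry`.
#' @export
hex_geometry <- function(I, J = I, delta = 1) {
  stopifnot(I >= 1, J >= 2, delta > 0)
  I <- as.integer(I); J <- as.integer(J)
  if (J %% 2L != 0L) {
    stop("J must be even for a consistent periodic wrap of the offset rows",
         call. = FALSE)
  }
  structure(list(I = I, J = J, delta = delta, L = I * delta,
                 n_sites = I * J),
            class = "hex_geometry")
}

#' @export
print.hex_geometry <- function(x, ...) {
  cat(sprintf("<hex geometry> %d x %d sites, delta = %g (L = %g)\n",
              x$I, x$J, x$delta, x$L))
  invisible(x)
}

# site id (1-based) <-> (i, j) with i, j 0-based
site_id <- function(geom, i, j) 1L + i + geom$I * j
site_ij <- function(geom, s) {
  s0 <- s - 1L
  list(i = s0 %% geom$I, j = s0 %/% geom$I)
}

#' Cartesian coordinates of lattice sites
#'
#' @param geom a [hex_geometry].
#' @param site 1-based site ids (default: all sites).
#' @return A data frame with columns `i`, `j`, `x`, `y`.
#' @export
hex_coordinates <- function(geom, site = seq_len(geom$n_sites)) {
  ij <- site_ij(geom, site)
  data.frame(i = ij$i, j = ij$j,
             x = (ij$i + (ij$j %% 2) / 2) * geom$delta,
             y = ij$j * sqrt(3) / 2 * geom$delta)
}

# axial coordinates (odd-row offset convention) for distance computations
offset_to_axial <- function(i, j) list(q = i - (j - j %% 2) %/% 2, r = j)

#' Concentric-ring template of neighbouring sites
#'
#' The template `N_r` of diameter `r` consists of all sites within hexagonal
#' graph distance `1..r` of a focal site, i.e. `r` concentric rings holding
#' `|N_r| = 3 r (r + 1)` sites in total.
#'
#' @param r ring diameter, integer `>= 1`.
#' @return An object of class `hex_template` with fields `r`, `axial` (a
#'   `size x 2` matrix of axial offsets) and `size`.
#' @examples
#' template_offsets(1)$size  # 6
#' template_offsets(4)$size  # 60
#' @export
template_offsets <- function(r) {
  stopifnot(length(r) == 1, r >= 1, r == as.integer(r))
  r <- as.integer(r)
  dq <- rep(-r:r, each = 2 * r + 1)
  dr <- rep(-r:r, times = 2 * r + 1)
  dist <- (abs(dq) + abs(dr) + abs(dq + dr)) %/% 2
  keep <- dist >= 1L & dist <= r
  axial <- cbind(q = dq[keep], r = dr[keep])
  stopifnot(nrow(axial) == 3 * r * (r + 1))
  structure(list(r = r, axial = axial, size = nrow(axial)),
            class = "hex_template")
}

#' @export
print.hex_template <- function(x, ...) {
  cat(sprintf("<hex template> r = %d, |N_r| = %d sites\n", x$r, x$size))
  invisible(x)
}

# Per-parity offset-coordinate displacements of a template.  For a site in a
# row of parity p, the neighbour at axial offset (dq, dr) is at
# (i + di, j + dr) with di depending only on p and (dq, dr).
template_offsets_by_parity <- function(template) {
  ax <- template$axial
  lapply(0:1, function(p) {
    jp <- p + ax[, "r"]              # unwrapped neighbour row
    di <- ax[, "q"] + floor(jp / 2) - floor(p / 2)
    cbind(di = as.integer(di), dj = as.integer(ax[, "r"]))
  })
}

#' Neighbour table for a template on a periodic lattice
#'
#' @param geom a [hex_geometry].
#' @param template a [hex_template] (or integer diameter `r`).
#' @return An integer matrix of `n_sites` rows and `|N_r|` columns holding
#'   1-based site ids of each site's template neighbours under periodic wrap.
#' @export
neighbor_table <- function(geom, template) {
  if (is.numeric(template)) template <- template_offsets(template)
  stopifnot(inherits(template, "hex_template"))
  if (2 * template$r >= min(geom$I, geom$J)) {
    stop("template diameter too large for the lattice: need 2r < min(I, J) ",
         "so that periodic images of a site do not overlap its own template",
         call. = FALSE)
  }
  offs <- template_offsets_by_parity(template)
  nb <- matrix(0L, nrow = geom$n_sites, ncol = template$size)
  all_i <- (seq_len(geom$n_sites) - 1L) %% geom$I
  all_j <- (seq_len(geom$n_sites) - 1L) %/% geom$I
  for (p in 0:1) {
    rows <- which(all_j %% 2L == p)
    o <- offs[[p + 1]]
    for (k in seq_len(template$size)) {
      ni <- (all_i[rows] + o[k, "di"]) %% geom$I
      nj <- (all_j[rows] + o[k, "dj"]) %% geom$J
      nb[rows, k] <- 1L + ni + geom$I * nj
    }
  }
  nb
}

#' Lattice occupancy state
#'
#' @param geom a [hex_geometry].
#' @param occupancy integer/logical vector over sites (`0` vacant, `1`
#'   occupied), in site-id order.
#' @return An object of class `hex_state` with fields `geometry`, `occupancy`
#'   and agent count `Q`.
#' @export
hex_state <- function(geom, occupancy) {
  stopifnot(inherits(geom, "hex_geometry"),
            length(occupancy) == geom$n_sites,
            all(occupancy %in% c(0L, 1L)))
  occupancy <- as.integer(occupancy)
  structure(list(geometry = geom, occupancy = occupancy,
                 Q = sum(occupancy)),
            class = "hex_state")
}

#' @export
print.hex_state <- function(x, ...) {
  cat(sprintf("<hex state> %d x %d lattice, Q = %d agents (density %.3f)\n",
              x$geometry$I, x$geometry$J, x$Q, x$Q / x$geometry$n_sites))
  invisible(x)
}

#' Central vertical strip initial condition
#'
#' Occupies every site of the columns whose x-position `i * delta` lies in
#' `[(L - w)/2, (L + w)/2)`; both row parities of a column are filled, so the
#' occupied column count is `round(w / delta)` and `Q = round(w/delta) * J`.
#'
#' @param geom a [hex_geometry].
#' @param w strip width in length units, `0 <= w <= L`.
#' @return A [hex_state].
#' @export
init_strip <- function(geom, w) {
  stopifnot(inherits(geom, "hex_geometry"))
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > geom$L) {
    stop("strip width w must lie in [0, L]", call. = FALSE)
  }
  xcol <- (0:(geom$I - 1)) * geom$delta
  inside <- xcol >= (geom$L - w) / 2 & xcol < (geom$L + w) / 2
  occ <- rep(as.integer(inside), times = geom$J)
  hex_state(geom, occ)
}

#' Uniformly random ("well-mixed") initial condition
#'
#' Each site is occupied independently with probability `C0`.  Uses the
#' current R random number generator state.
#'
#' @param geom a [hex_geometry].
#' @param C0 occupancy probability.
#' @return A [hex_state].
#' @export
init_uniform <- function(geom, C0) {
  stopifnot(C0 >= 0, C0 <= 1)
  hex_state(geom, as.integer(stats::runif(geom$n_sites) < C0))
}

#' Local density seen by a site through a template
#'
#' The fraction of occupied sites among the template neighbours of `site`
#' (the focal site itself is excluded by construction of the template).
#'
#' @param state a [hex_state].
#' @param site 1-based site id.
#' @param template a [hex_template] (or integer diameter).
#' @return `K` in `[0, 1]`.
#' @export
local_density <- function(state, site, template) {
  if (is.numeric(template)) template <- template_offsets(template)
  geom <- state$geometry
  stopifnot(site >= 1, site <= geom$n_sites)
  ij <- site_ij(geom, site)
  offs <- template_offsets_by_parity(template)[[ij$j %% 2 + 1]]
  ni <- (ij$i + offs[, "di"]) %% geom$I
  nj <- (ij$j + offs[, "dj"]) %% geom$J
  mean(state$occupancy[1L + ni + geom$I * nj])
}

#' Column density of a lattice state
#'
#' Sites are grouped by column index `i` (bin width `delta`, ignoring the
#' half-spacing stagger of odd rows); the column density is the occupied
#' fraction of each column.
#'
#' @param state a [hex_state].
#' @return A numeric vector of length `I`, with `x = i * delta` as names.
#' @export
column_density <- function(state) {
  geom <- state$geometry
  m <- matrix(state$occupancy, nrow = geom$I)
  d <- rowMeans(m)
  names(d) <- format((0:(geom$I - 1)) * geom$delta, trim = TRUE)
  d
}

# ---------------------------------------------------------------------------
# snapshot formats

#' Write a lattice state snapshot
#'
#' Two lossless plain-text formats: a site-list CSV with columns
#' `i, j, x, y, occupied`, and a compact run-length format (`value count`
#' pairs over the site-id order, after a geometry header).
#'
#' @param state a [hex_state].
#' @param file output path.
#' @param format `"csv"` or `"rle"`.
#' @return `file`, invisibly.
#' @export
write_hex_state <- function(state, file, format = c("csv", "rle")) {
  format <- match.arg(format)
  geom <- state$geometry
  if (format == "csv") {
    co <- hex_coordinates(geom)
    co$occupied <- state$occupancy
    utils::write.csv(co, file, row.names = FALSE)
  } else {
    rl <- rle(state$occupancy)
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("hexstate %d %d %.17g", geom$I, geom$J, geom$delta), con)
    writeLines(paste(rl$values, rl$lengths), con)
  }
  invisible(file)
}

#' Read a lattice state snapshot written by [write_hex_state()]
#'
#' @param file input path.
#' @param format `"csv"` or `"rle"`.
#' @param geom for `"csv"`, the [hex_geometry] the snapshot belongs to
#'   (the CSV stores sites, not the spacing-independent geometry fields).
#' @return A [hex_state].
#' @export
read_hex_state <- function(file, format = c("csv", "rle"), geom = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- utils::read.csv(file)
    if (is.null(geom)) {
      geom <- hex_geometry(max(tab$i) + 1L, max(tab$j) + 1L,
                           delta = if (max(tab$i) > 0)
                             max(tab$x[tab$j %% 2 == 0]) / max(tab$i) else 1)
    }
    occ <- integer(geom$n_sites)
    occ[site_id(geom, tab$i, tab$j)] <- tab$occupied
    hex_state(geom, occ)
  } else {
    lines <- readLines(file)
    hdr <- strsplit(lines[1], " ")[[1]]
    stopifnot(hdr[1] == "hexstate")
    geom <- hex_geometry(as.integer(hdr[2]), as.integer(hdr[3]),
                         as.numeric(hdr[4]))
    pairs <- do.call(rbind, strsplit(lines[-1], " "))
    occ <- rep(as.integer(pairs[, 1]), times = as.integer(pairs[, 2]))
    hex_state(geom, occ)
  }
}
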