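#' Livewire link-cost model
#'
#' Weights of the four edge features in the livewire link cost
#' `c(p, q) = w_z f_z(q) + w_c f_c(q) + w_G f_G(q) + w_D f_D(p, q)`.
#' The defaults (4, 4, 1, 1) weight the two binary detectors four times as
#' heavily as the gradient-magnitude and gradient-direction terms.
#'
#' @param w_z,w_c,w_G,w_D non-negative feature weights (zero-crossing,
#'   Canny, gradient magnitude, gradient direction); at least one positive.
#' @param diagonal_scaling if `TRUE` (default), diagonal link costs are
#'   multiplied by `1/sqrt(2)`; `FALSE` applies the formula literally to
#'   all 8 neighbours.
#' @return an object of class `link_cost_model`.
#' @export
link_cost_model <- function(w_z = 4, w_c = 4, w_G = 1, w_D = 1,
                            diagonal_scaling = TRUE) {
  w <- c(w_z, w_c, w_G, w_D)
  if (!all(is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  if (all(w == 0)) stop("at least one weight must be positive")
  structure(list(w_z = w_z, w_c = w_c, w_G = w_G, w_D = w_D,
                 diagonal_scaling = isTRUE(diagonal_scaling)),
            class = "link_cost_model")
}

#' Livewire link cost between two adjacent pixels
#'
#' Evaluates the weighted edge cost of stepping from pixel `p` to pixel `q`
#' in the 8-connected pixel graph. The gradient-direction term is the
#' intelligent-scissors formulation
#' `f_D(p,q) = (2/(3*pi)) * (acos(d_p) + acos(d_q))` where `d_p`, `d_q` are
#' the inner products of the edge-tangent unit vectors at `p` and `q` with
#' the unit link vector from `p` to `q`, the link vector being flipped so
#' that `d_p >= 0`. `f_D` lies in \[0, 1\]: it vanishes when the link runs
#' along the local edge tangent and is maximal when the path cuts across a
#' strong edge.
#'
#' @param p,q integer (row, col) pixel coordinates, 0-based, 8-adjacent.
#' @param stack a `feature_stack` from [compute_feature_stack()].
#' @param model a [link_cost_model()].
#' @return a single non-negative cost.
#' @export
link_cost <- function(p, q, stack, model = link_cost_model()) {
  nr <- nrow(stack$f_G); nc <- ncol(stack$f_G)
  p <- as.integer(p); q <- as.integer(q)
  if (any(p < 0L) || any(q < 0L) || p[1] >= nr || q[1] >= nr ||
      p[2] >= nc || q[2] >= nc)
    stop("pixel outside image")
  dd <- q - p
  if (max(abs(dd)) != 1L) stop("pixels are not 8-adjacent")
  qi <- cbind(q[1] + 1L, q[2] + 1L)
  pi_ <- cbind(p[1] + 1L, p[2] + 1L)

  len <- sqrt(sum(dd^2))
  Lr <- dd[1] / len; Lc <- dd[2] / len
  dpr <- stack$dir_r[pi_]; dpc <- stack$dir_c[pi_]
  if (dpr * Lr + dpc * Lc < 0) { Lr <- -Lr; Lc <- -Lc }
  dp <- dpr * Lr + dpc * Lc
  dq <- stack$dir_r[qi] * Lr + stack$dir_c[qi] * Lc
  dp <- min(max(dp, -1), 1); dq <- min(max(dq, -1), 1)
  fD <- (2 / (3 * pi)) * (acos(dp) + acos(dq))

  cost <- model$w_z * stack$f_z[qi] + model$w_c * stack$f_c[qi] +
    model$w_G * stack$f_G[qi] + model$w_D * fD
  if (all(dd != 0L) && model$diagonal_scaling) cost <- cost / sqrt(2)
  as.numeric(cost)
}

#' Minimum-cost boundary segment between two pixels
#'
#' Runs Dijkstra's algorithm over the 8-connected pixel graph with
#' [link_cost()] edge weights and returns the optimal path from `seed` to
#' `target`. Among equal-cost paths the result is deterministic: nodes are
#' settled in order of (cost, linear pixel index) and predecessors are
#' updated on strict improvement only.
#'
#' @param seed,target (row, col) pixel coordinates, 0-based, inside the
#'   image.
#' @inheritParams link_cost
#' @return a list with `coords` (n x 2 integer matrix of 0-based (row, col)
#'   positions from `seed` to `target`) and `cost` (sum of link costs along
#'   the path; 0 when `seed == target`).
#' @export
shortest_boundary <- function(seed, target, stack, model = link_cost_model()) {
  nr <- nrow(stack$f_G); nc <- ncol(stack$f_G)
  seed <- as.integer(seed); target <- as.integer(target)
  for (pt in list(seed, target))
    if (length(pt) != 2L || any(pt < 0L) || pt[1] >= nr || pt[2] >= nc)
      stop("seed/target pixel outside image")
  si <- seed[1] + seed[2] * nr
  ti <- target[1] + target[2] * nr
  if (si == ti)
    return(list(coords = matrix(seed, 1, 2,
                                dimnames = list(NULL, c("row", "col"))),
                cost = 0))
  res <- .lw_dijkstra(stack$f_z, stack$f_c, stack$f_G,
                      stack$dir_r, stack$dir_c,
                      c(model$w_z, model$w_c, model$w_G, model$w_D),
                      model$diagonal_scaling, si, ti)
  if (!is.finite(res$dist[ti + 1L])) stop("target unreachable")  # cannot occur on a grid
  # walk predecessors back from target
  path <- integer(0)
  u <- ti
  while (u != -1L) {
    path <- c(path, u)
    u <- res$pred[u + 1L]
  }
  path <- rev(path)
  coords <- cbind(row = path %% nr, col = path %/% nr)
  list(coords = coords, cost = res$dist[ti + 1L])
}

#' Construct a contour object
#'
#' An ordered 8-connected pixel boundary. Closed contours additionally have
#' their first point 8-adjacent to their last; the first point is *not*
#' repeated in memory (only in the serialized CSV form).
#'
#' @param coords n x 2 integer matrix of 0-based (row, col) pixel positions.
#' @param closed logical; closed boundary.
#' @param cost total link cost of the traced path (optional).
#' @return an object of class `contour`.
#' @export
contour <- function(coords, closed = TRUE, cost = NA_real_) {
  coords <- matrix(as.integer(coords), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  n <- nrow(coords)
  if (n < 1L) stop("empty contour")
  if (n > 1L) {
    st <- abs(diff(coords))
    if (any(pmax(st[, 1], st[, 2]) != 1L))
      stop("consecutive contour points must be 8-adjacent and distinct")
    if (closed) {
      wrap <- abs(coords[1, ] - coords[n, ])
      if (max(wrap) > 1L || all(wrap == 0L))
        stop("closed contour requires first point 8-adjacent to last")
    }
  }
  structure(list(coords = coords, closed = isTRUE(closed),
                 cost = as.numeric(cost)),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d px, %s, cost %.4g\n", nrow(x$coords),
              if (x$closed) "closed" else "open", x$cost))
  invisible(x)
}

# signed shoelace area of a closed pixel walk (pixel-centre polygon)
shoelace_area <- function(coords) {
  r <- coords[, 1]; cc <- coords[, 2]
  n <- length(r)
  j <- c(2:n, 1L)
  sum(r * cc[j] - r[j] * cc) / 2
}

# remove self-intersection loops from a closed pixel walk, keeping at each
# repeated pixel the sub-loop with the larger enclosed area (the outer loop)
clean_closed_walk <- function(coords) {
  repeat {
    key <- coords[, 1] * (max(coords[, 2]) + 1L) + coords[, 2]
    dup <- anyDuplicated(key)
    if (dup == 0L) return(coords)
    i <- match(key[dup], key)
    loop_in <- coords[i:(dup - 1L), , drop = FALSE]
    keep_out <- seq_len(nrow(coords))[-(i:(dup - 1L))]
    loop_out <- coords[keep_out, , drop = FALSE]
    a_in <- abs(shoelace_area(loop_in))
    a_out <- abs(shoelace_area(loop_out))
    coords <- if (a_in > a_out) loop_in else loop_out
  }
}

#' Trace a closed tubule contour through ordered seed points
#'
#' Connects consecutive seed points (wrapping from the last back to the
#' first) by minimum-cost livewire segments, removes duplicate junction
#' pixels, and resolves self-intersections by keeping the outer loop.
#'
#' @param seeds n x 2 integer matrix (n >= 3) of 0-based (row, col) seed
#'   pixels on the intended boundary, in order (either orientation).
#' @inheritParams link_cost
#' @return a closed [contour()] whose `cost` is the sum of the segment
#'   costs.
#' @export
trace_closed_contour <- function(seeds, stack, model = link_cost_model()) {
  seeds <- matrix(as.integer(seeds), ncol = 2)
  if (nrow(seeds) < 3L) stop("need at least 3 seed points")
  if (any(rowSums(abs(diff(seeds))) == 0L))
    stop("consecutive seeds must be distinct")
  nr <- nrow(stack$f_G); nc <- ncol(stack$f_G)
  if (any(seeds < 0L) || any(seeds[, 1] >= nr) || any(seeds[, 2] >= nc))
    stop("seed outside image bounds")

  n <- nrow(seeds)
  # canonicalize orientation (counter-clockwise seed polygon, same first
  # seed) so clockwise and counter-clockwise seed lists trace the same
  # directed segments and return the identical pixel set
  if (n >= 3L && shoelace_area(seeds) < 0)
    seeds <- seeds[c(1L, n:2L), , drop = FALSE]
  pieces <- vector("list", n)
  total <- 0
  for (i in seq_len(n)) {
    a <- seeds[i, ]
    b <- seeds[if (i == n) 1L else i + 1L, ]
    seg <- shortest_boundary(a, b, stack, model)
    total <- total + seg$cost
    # drop the terminal pixel: it is the next segment's first pixel
    pieces[[i]] <- seg$coords[-nrow(seg$coords), , drop = FALSE]
  }
  coords <- do.call(rbind, pieces)
  coords <- clean_closed_walk(coords)
  if (nrow(coords) < 4L || abs(shoelace_area(coords)) < 1)
    stop("degenerate contour: seeds collapse to a zero-area loop")
  contour(coords, closed = TRUE, cost = total)
}

## ---- seed / contour CSV formats -------------------------------------------

#' Read seed lists from CSV
#'
#' Expected columns: `tubule_id`, `point_index`, `row`, `col`, and an
#' optional `boundary` column with values `"outer"` (default) or `"lumen"`.
#' Coordinates are 0-based (row, col) from the top-left pixel.
#'
#' @param path CSV file path.
#' @return a named list per tubule, each a list with integer matrices
#'   `outer` and (possibly NULL) `lumen`, seed rows ordered by
#'   `point_index`.
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tubule_id", "point_index", "row", "col")
  if (!all(need %in% names(df)))
    stop("seed CSV must have columns: ", paste(need, collapse = ", "))
  df$row <- suppressWarnings(as.numeric(df$row))
  df$col <- suppressWarnings(as.numeric(df$col))
  bad <- which(!is.finite(df$row) | !is.finite(df$col))
  if (length(bad))  # report 1-based file lines (header is line 1)
    stop("malformed seed CSV row(s): ", paste(bad + 1L, collapse = ", "))
  if (is.null(df$boundary)) df$boundary <- rep("outer", nrow(df))
  out <- list()
  for (id in unique(df$tubule_id)) {
    sub <- df[df$tubule_id == id, ]
    grab <- function(kind) {
      s <- sub[sub$boundary == kind, ]
      if (!nrow(s)) return(NULL)
      s <- s[order(s$point_index), ]
      cbind(row = as.integer(s$row), col = as.integer(s$col))
    }
    out[[as.character(id)]] <- list(outer = grab("outer"), lumen = grab("lumen"))
  }
  out
}

#' Write closed contours to CSV
#'
#' Serialized closed contours repeat the first vertex once at the end.
#' Columns: `tubule_id`, `boundary` (`outer`/`lumen`), `vertex_index`,
#' `row`, `col`.
#'
#' @param contours named list per tubule of lists with `outer` and optional
#'   `lumen` [contour()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  rows <- list()
  for (id in names(contours)) {
    for (kind in c("outer", "lumen")) {
      ct <- contours[[id]][[kind]]
      if (is.null(ct)) next
      co <- ct$coords
      if (ct$closed) co <- rbind(co, co[1, ])
      rows[[length(rows) + 1L]] <- data.frame(
        tubule_id = id, boundary = kind,
        vertex_index = seq_len(nrow(co)) - 1L,
        row = co[, 1], col = co[, 2])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read contours written by [write_contours()]
#'
#' @param path CSV file path.
#' @return named list per tubule of lists with `outer`/`lumen` [contour()]
#'   objects (the serialized repeated first vertex is removed).
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tubule_id", "boundary", "vertex_index", "row", "col")
  if (!all(need %in% names(df)))
    stop("contour CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(df$tubule_id)) {
    sub <- df[df$tubule_id == id, ]
    entry <- list()
    for (kind in c("outer", "lumen")) {
      s <- sub[sub$boundary == kind, ]
      if (!nrow(s)) next
      s <- s[order(s$vertex_index), ]
      co <- cbind(s$row, s$col)
      if (nrow(co) > 1L && all(co[1, ] == co[nrow(co), ]))
        co <- co[-nrow(co), , drop = FALSE]
      entry[[kind]] <- contour(co, closed = TRUE)
    }
    out[[as.character(id)]] <- entry
  }
  out
}
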