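# Independent oracles, coded separately from the package internals.

# independently coded weighted link-cost sum (mirrors the printed formula,
# not the package code path)
oracle_link_cost <- function(stack, p, q, w = c(4, 4, 1, 1),
                             diag_scale = TRUE) {
  dd <- q - p
  L <- dd / sqrt(sum(dd^2))
  Dp <- c(stack$dir_r[p[1] + 1, p[2] + 1], stack$dir_c[p[1] + 1, p[2] + 1])
  Dq <- c(stack$dir_r[q[1] + 1, q[2] + 1], stack$dir_c[q[1] + 1, q[2] + 1])
  if (sum(Dp * L) < 0) L <- -L
  dp <- max(-1, min(1, sum(Dp * L)))
  dq <- max(-1, min(1, sum(Dq * L)))
  fD <- (2 / (3 * pi)) * (acos(dp) + acos(dq))
  cost <- w[1] * stack$f_z[q[1] + 1, q[2] + 1] +
          w[2] * stack$f_c[q[1] + 1, q[2] + 1] +
          w[3] * stack$f_G[q[1] + 1, q[2] + 1] + w[4] * fD
  if (all(dd != 0) && diag_scale) cost <- cost / sqrt(2)
  cost
}

# textbook O(V^2) single-source Dijkstra on the 8-connected pixel graph
oracle_dijkstra_cost <- function(stack, seed, target, w = c(4, 4, 1, 1),
                                 diag_scale = TRUE) {
  nr <- nrow(stack$f_G); nc <- ncol(stack$f_G); n <- nr * nc
  dist <- rep(Inf, n); done <- rep(FALSE, n)
  si <- seed[1] + seed[2] * nr + 1L
  ti <- target[1] + target[2] * nr + 1L
  dist[si] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    if (u == ti) break
    ur <- (u - 1L) %% nr; uc <- (u - 1L) %/% nr
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      vr <- ur + dr; vc <- uc + dc
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) next
      v <- vr + vc * nr + 1L
      nd <- dist[u] + oracle_link_cost(stack, c(ur, uc), c(vr, vc), w,
                                       diag_scale)
      if (nd < dist[v]) dist[v] <- nd
    }
  }
  dist[ti]
}

# even-odd scanline point-in-polygon rasterizer (counts boundary separately)
oracle_even_odd_count <- function(coords, shape) {
  vy <- coords[, 1]; vx <- coords[, 2]
  n <- length(vy); j <- c(n, seq_len(n - 1L))
  grid <- expand.grid(r = seq_len(shape[1]) - 1L, c = seq_len(shape[2]) - 1L)
  inside <- rep(FALSE, nrow(grid))
  for (k in seq_len(n)) {
    yi <- vy[k]; xi <- vx[k]; yj <- vy[j[k]]; xj <- vx[j[k]]
    if (yi == yj) next
    cr <- ((yi > grid$r) != (yj > grid$r)) &
      (grid$c < (xj - xi) * (grid$r - yi) / (yj - yi) + xi)
    inside <- xor(inside, cr)
  }
  onb <- matrix(FALSE, shape[1], shape[2])
  onb[coords + 1L] <- TRUE
  sum(inside | onb[cbind(grid$r + 1L, grid$c + 1L)])
}

# brute-force symmetric mean nearest-boundary distance between pixel sets
oracle_boundary_dist <- function(a, b) {
  d <- function(p, q) {
    apply(p, 1, function(x) min(sqrt((x[1] - q[, 1])^2 + (x[2] - q[, 2])^2)))
  }
  (mean(d(a, b)) + mean(d(b, a))) / 2
}

# digital circle contour: ordered, 8-connected pixel ring
digital_circle <- function(centre, radius, n = max(720L, round(16 * radius))) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- cbind(round(centre[1] + radius * cos(th)),
               round(centre[2] + radius * sin(th)))
  pts <- pts[!duplicated(pts), , drop = FALSE]
  contour(pts, closed = TRUE)
}

# axis-aligned square ring contour with inclusive corners lo..hi (0-based)
square_contour <- function(lo, hi) {
  s <- lo:hi
  pts <- rbind(cbind(lo, s), cbind(s[-1], hi),
               cbind(hi, rev(s)[-1]), cbind(rev(s)[-c(1, length(s))], lo))
  contour(pts, closed = TRUE)
}

# random feature stack on an n x n grid (valid invariants)
random_stack <- function(n, seed) {
  set.seed(seed)
  ang <- matrix(runif(n * n, 0, 2 * pi), n, n)
  zero <- matrix(runif(n * n) < 0.1, n, n)
  dr <- cos(ang); dc <- sin(ang)
  dr[zero] <- 0; dc[zero] <- 0
  structure(list(
    f_z = matrix(sample(0:1, n * n, TRUE), n, n) + 0,
    f_c = matrix(sample(0:1, n * n, TRUE), n, n) + 0,
    f_G = matrix(runif(n * n), n, n),
    dir_r = dr, dir_c = dc), class = "feature_stack")
}

# balanced nested endpoint table from group/animal/tubule draws
nested_table <- function(k = 5, b = 5, m = 30, means = rep(0, k),
                         sd_animal = 25, sd_tubule = 40, seed = 1) {
  set.seed(seed)
  g <- rep(paste0("g", seq_len(k)), each = b * m)
  a <- rep(sprintf("g%d_a%d", rep(seq_len(k), each = b), seq_len(b)),
           each = m)
  y <- rep(means, each = b * m) +
    rep(rnorm(k * b, 0, sd_animal), each = m) + rnorm(k * b * m, 0, sd_tubule)
  data.frame(animal_id = a, group = g, value = y, stringsAsFactors = FALSE)
}

# single-annulus phantom helper used across test files
annulus_spec <- function(outer = 110, lumen = 55, size = 320L, noise = 0.02,
                         seed = 1L, ellipticity = 0) {
  phantom_spec(size = c(size, size), pixel_size = 1,
               tubules = data.frame(center_r = size / 2, center_c = size / 2,
                                    outer_um = outer, lumen_um = lumen,
                                    ellipticity = ellipticity),
               noise_sd = noise, seed = seed)
}
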