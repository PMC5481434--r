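# Shared fixture builders. Scenes in unit tests are scaled down (small cores,
# small fields of view) to keep the suite fast; geometry ratios keep the
# 6-tile layout of the full-size default (2 x 3 bands).

small_scene <- function(regions = list(), seed = 1L, ...) {
  scene_spec(core_diameter_um = 120, pixel_size_um = 1,
             fov_width_um = 60, fov_height_um = 40,
             regions = regions, seed = seed, ...)
}

# a 120-um core with one planted region per marker class, contrast in units
# of background_sd (texture_sd = 0 so the planted contrast is exact)
planted_scene <- function(contrast_sd = 20, seed = 1L, background_sd = 8) {
  amp <- contrast_sd * background_sd
  small_scene(regions = list(
    region_disk(c(0, 25), 18, "dual", amp, 0),
    region_disk(c(-28, -22), 14, "ca199_only", amp, 0),
    region_disk(c(28, -22), 14, "stra_only", amp, 0)),
    seed = seed, background_sd = background_sd)
}

# per-tile marker quantification via the full detection path
quantify_core <- function(core) {
  tiles <- render_fov_tiles(core)
  lapply(tiles, function(tl) {
    ti <- compute_tissue_mask(tl$channels$round2)
    quantify_markers(find_signal(tl$channels$round2$glycan, ti),
                     find_signal(tl$channels$round3$glycan, ti), ti)
  })
}

# unweighted per-tile mean of truth marker percentages (the comparator for
# aggregate_core, which averages equally over tiles)
truth_tile_mean <- function(core) {
  tiles <- render_fov_tiles(core)
  mat <- vapply(tiles, function(tl) {
    nt <- sum(tl$truth$tissue)
    v <- c(ca199 = sum(tl$truth$ca199), stra = sum(tl$truth$stra),
           ca199_only = sum(tl$truth$ca199_only),
           stra_only = sum(tl$truth$stra_only),
           dual = sum(tl$truth$dual))
    if (nt == 0) v * 0 else 100 * v / nt
  }, numeric(5))
  rowMeans(mat)
}

random_logical_matrix <- function(nr, nc, p = 0.3) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# independent per-pixel brute-force oracle for boolean scan expressions:
# walks the AST with scalar logic at every pixel
oracle_eval_pixelwise <- function(expr, maps, tissue) {
  ev1 <- function(node, i) {
    switch(node$kind,
           scan = maps[[node$name]][i] && tissue[i],
           and = ev1(node$a, i) && ev1(node$b, i),
           or = ev1(node$a, i) || ev1(node$b, i),
           not = tissue[i] && !ev1(node$a, i))
  }
  out <- vapply(seq_along(tissue), function(i) ev1(expr, i), logical(1))
  matrix(out, nrow = nrow(tissue))
}

random_expression <- function(names, depth = 3) {
  if (depth == 0 || runif(1) < 0.3)
    return(list(kind = "scan", name = sample(names, 1)))
  kind <- sample(c("and", "or", "not"), 1)
  if (kind == "not")
    list(kind = "not", a = random_expression(names, depth - 1))
  else
    list(kind = kind, a = random_expression(names, depth - 1),
         b = random_expression(names, depth - 1))
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% r)
  min(1, 2 * min(mean(sums >= v - 1e-9), mean(sums <= v + 1e-9)))
}

# exact two-sided rank-sum p by enumerating all subsets of ranks
oracle_rank_sum_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  w <- sum(rank(c(a, b))[seq_len(na)])
  combs <- utils::combn(n, na)
  sums <- colSums(matrix(seq_len(n)[combs], nrow = na))
  min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
}

# Mantel-Cox log-rank chi-square from the per-event-time 2x2 tables
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1L
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1))
  }
  (O - E)^2 / V
}
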