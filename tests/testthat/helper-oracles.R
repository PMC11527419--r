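# Independent oracles used against the package implementations. These are
# deliberately naive (per-voxel loops, explicit enumeration) and share no
# code with the functions they check.

# Exhaustive steepest-ascent basin assignment: each positive voxel climbs to
# the max-valued voxel among itself and its 26 neighbours (ties to the
# smallest linear index) until it stops moving; the terminus determines the
# label via `seed_label` (linear index -> parcel id; 0 where not a seed).
oracle_ascent_labels <- function(field, seed_label) {
  d <- dim(field)
  steepest_step <- function(v) {
    ijk <- arrayInd(v, d)
    best_v <- v
    best_val <- field[v]
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      p <- ijk + c(di, dj, dk)
      if (any(p < 1) || any(p > d)) next
      u <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
      if (field[u] > best_val || (field[u] == best_val && u < best_v)) {
        best_val <- field[u]; best_v <- u
      }
    }
    best_v
  }
  term <- integer(length(field)) # 0 = unresolved; else terminus index
  for (v in which(field > 0)) {
    path <- integer(0)
    u <- v
    while (term[u] == 0L) {
      nxt <- steepest_step(u)
      if (nxt == u) { term[u] <- u; break }
      path <- c(path, u)
      u <- nxt
    }
    if (length(path)) term[path] <- term[u]
  }
  labels <- array(0L, d)
  pos <- which(field > 0)
  labels[pos] <- seed_label[term[pos]]
  labels
}

# Pearson correlation over the explicitly enumerated in-mask sphere around a
# center (1-based ijk), Euclidean radius in voxels, center included.
oracle_sphere_pearson <- function(a, b, mask, center, radius) {
  d <- dim(a)
  va <- c(); vb <- c()
  r <- floor(radius)
  for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
    if (di^2 + dj^2 + dk^2 > radius^2) next
    p <- center + c(di, dj, dk)
    if (any(p < 1) || any(p > d)) next
    if (!mask[p[1], p[2], p[3]]) next
    va <- c(va, a[p[1], p[2], p[3]])
    vb <- c(vb, b[p[1], p[2], p[3]])
  }
  if (length(va) < 3 || sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  cor(va, vb)
}

# A smooth non-negative random field with plenty of zeros, for watershed
# exercising: thresholded smoothed white noise.
random_watershed_field <- function(shape = c(20, 20, 20), seed = 1,
                                   fwhm = 4) {
  set.seed(seed)
  x <- gaussian_smooth_3d(array(rnorm(prod(shape)), shape), fwhm,
                          c(1, 1, 1))
  x <- x / sd(x)
  pmax(x, 0)
}

# Small structured-block fixture built from package generators.
tiny_block <- function(tokens, stim_ms = 460, isi_ms = 20,
                       domain = "syllable", condition = "structured") {
  slgcss:::new_block_sequence(domain, condition, tokens, stim_ms, isi_ms)
}
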