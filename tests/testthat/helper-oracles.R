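# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package.

# Connected-component labeling by repeated queue-free flood fill over an
# explicit neighbour list.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    frontier <- list(c(i, j))
    lab[i, j] <- cur
    while (length(frontier)) {
      p <- frontier[[1]]
      frontier <- frontier[-1]
      for (q in seq_len(nrow(nbrs))) {
        ii <- p[1] + nbrs$dr[q]; jj <- p[2] + nbrs$dc[q]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          frontier[[length(frontier) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Per-pixel median over explicit clipped neighbourhoods.
oracle_median_filter <- function(x, k) {
  h <- k %/% 2
  out <- x
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    out[i, j] <- median(x[max(1, i - h):min(nrow(x), i + h),
                          max(1, j - h):min(ncol(x), j + h)])
  }
  out
}

# Two-sided Fisher exact p by exhaustive enumeration of all 2x2 tables with
# the observed margins: sum the hypergeometric probabilities of every table
# no more probable than the observed one.
oracle_fisher <- function(k1, n1, k2, n2) {
  kk <- k1 + k2
  support <- max(0, kk - n2):min(n1, kk)
  probs <- dhyper(support, n1, n2, kk)
  p_obs <- dhyper(k1, n1, n2, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Compact letter display for exactly three items by exhaustive assignment:
# enumerate all subsets, keep maximal all-nonsignificant cliques, letter them
# in the given order.
oracle_letters3 <- function(nonsig12, nonsig23, nonsig13) {
  adj <- matrix(TRUE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- nonsig12
  adj[2, 3] <- adj[3, 2] <- nonsig23
  adj[1, 3] <- adj[3, 1] <- nonsig13
  subsets <- list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  cliques <- Filter(function(s) all(adj[s, s]), subsets)
  maximal <- Filter(function(s) {
    !any(vapply(cliques, function(o) length(o) > length(s) && all(s %in% o),
                logical(1)))
  }, cliques)
  maximal <- maximal[order(vapply(maximal, min, numeric(1)))]
  out <- rep("", 3)
  for (i in seq_along(maximal)) {
    out[maximal[[i]]] <- paste0(out[maximal[[i]]], letters[i])
  }
  out
}

# A small noise-free reflectance phantom plus its segmentation inputs.
tiny_phantom <- function(modality = "reflectance", c_true = 0.2,
                         noise = 0, seed = 1L, ...) {
  make_swir_phantom(phantom_config(
    image_height = 80L, image_width = 120L, modality = modality,
    lesion_contrast_true = c_true, lesion_axes = c(12L, 9L),
    noise_sigma = noise, seed = seed, ...
  ))
}
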