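# Independent brute-force oracles used to check the vectorized paths.
# These are written from the definitions (explicit loops, dense matrices),
# deliberately sharing no code with the implementation.

# Symmetric reflection / wrap / zero boundary index for a single coordinate.
oracle_map1 <- function(i, n, boundary) {
  if (i >= 1 && i <= n) return(i)
  switch(boundary,
    reflect = {
      while (i < 1 || i > n) {
        if (i < 1) i <- 1 - i
        if (i > n) i <- 2 * n + 1 - i
      }
      i
    },
    wrap = ((i - 1) %% n) + 1,
    constant = 0L
  )
}

# Dense n x n matrix of the uniform-blur forward map (column-major pixel
# order), built entry by entry from the windowed-sum definition.
oracle_blur_matrix <- function(h, w, kernel, boundary = "reflect") {
  r <- (nrow(kernel) - 1L) %/% 2L
  n <- h * w
  H <- matrix(0, n, n)
  for (j in 1:w) {
    for (i in 1:h) {
      q <- i + (j - 1L) * h
      for (dx in -r:r) {
        for (dy in -r:r) {
          si <- oracle_map1(i + dy, h, boundary)
          sj <- oracle_map1(j + dx, w, boundary)
          if (si > 0 && sj > 0) {
            p <- si + (sj - 1L) * h
            H[q, p] <- H[q, p] + kernel[dy + r + 1L, dx + r + 1L]
          }
        }
      }
    }
  }
  H
}

# Same for a per-pixel kernel field.
oracle_field_matrix <- function(field, boundary = "reflect") {
  h <- field$height; w <- field$width; r <- field$radius
  n <- h * w
  H <- matrix(0, n, n)
  for (j in 1:w) {
    for (i in 1:h) {
      q <- i + (j - 1L) * h
      o <- 0L
      for (dx in -r:r) {
        for (dy in -r:r) {
          o <- o + 1L
          si <- oracle_map1(i + dy, h, boundary)
          sj <- oracle_map1(j + dx, w, boundary)
          if (si > 0 && sj > 0) {
            p <- si + (sj - 1L) * h
            H[q, p] <- H[q, p] + field$weights[i, j, o]
          }
        }
      }
    }
  }
  H
}

# Dense 5-point Laplacian matrix under reflect boundary.
oracle_laplacian_matrix <- function(h, w) {
  n <- h * w
  L <- matrix(0, n, n)
  for (j in 1:w) {
    for (i in 1:h) {
      q <- i + (j - 1L) * h
      L[q, q] <- L[q, q] + 4
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        si <- oracle_map1(i + d[1], h, "reflect")
        sj <- oracle_map1(j + d[2], w, "reflect")
        L[q, si + (sj - 1L) * h] <- L[q, si + (sj - 1L) * h] - 1
      }
    }
  }
  L
}

# Graph penalty by explicit loop over the edge list.
oracle_graph_penalty <- function(x, edges) {
  xv <- as.vector(x)
  total <- 0
  for (e in seq_len(nrow(edges))) {
    total <- total + edges$w[e] * (xv[edges$i[e]] - xv[edges$j[e]])^2
  }
  total
}

# Dense weighted graph Laplacian from an i<j edge list.
oracle_dense_laplacian <- function(edges, n) {
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    W[edges$i[e], edges$j[e]] <- W[edges$i[e], edges$j[e]] + edges$w[e]
    W[edges$j[e], edges$i[e]] <- W[edges$j[e], edges$i[e]] + edges$w[e]
  }
  diag(rowSums(W)) - W
}

# Exhaustive O(n^2) graph construction (union-symmetrized k-NN with
# distance threshold), for comparison against build_graph on small images.
oracle_exhaustive_graph <- function(fmat, eps, beta, k) {
  n <- nrow(fmat)
  pairs <- list()
  for (i in 1:n) {
    d2 <- rep(0, n)
    for (j in 1:n) d2[j] <- sum((fmat[i, ] - fmat[j, ])^2)
    d2[i] <- Inf
    ord <- order(d2)[1:k]
    keep <- ord[d2[ord] <= eps^2]
    for (j in keep) pairs[[length(pairs) + 1L]] <- c(min(i, j), max(i, j), d2[j])
  }
  if (!length(pairs)) return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
  m <- do.call(rbind, pairs)
  m <- m[!duplicated(m[, 1:2, drop = FALSE]), , drop = FALSE]
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  w <- exp(-m[, 3] / beta)
  keep <- w >= 1e-4   # declared weak-edge floor of the construction
  data.frame(i = m[keep, 1], j = m[keep, 2], w = w[keep])
}

# Central finite differences of a scalar function of a matrix.
oracle_fd_gradient <- function(f, x, h = 1e-6) {
  g <- matrix(0, nrow(x), ncol(x))
  for (q in seq_along(x)) {
    xp <- x; xp[q] <- xp[q] + h
    xm <- x; xm[q] <- xm[q] - h
    g[q] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Naive double-loop scale alignment loss over a coarse-to-fine level list.
oracle_alignment_loss <- function(levels) {
  total <- 0
  S <- length(levels)
  if (S < 2) return(0)
  down <- function(x) {
    h2 <- nrow(x) %/% 2; w2 <- ncol(x) %/% 2
    out <- matrix(0, h2, w2)
    for (a in 1:h2) for (b in 1:w2) {
      out[a, b] <- mean(x[(2 * a - 1):(2 * a), (2 * b - 1):(2 * b)])
    }
    out
  }
  for (s in 1:(S - 1)) {
    d <- down(levels[[s + 1]])
    for (a in seq_len(nrow(d))) for (b in seq_len(ncol(d))) {
      total <- total + (d[a, b] - levels[[s]][a, b])^2
    }
  }
  total
}

# Random test image in [0,1].
rand_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}
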