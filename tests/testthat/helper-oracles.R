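# Independent brute-force oracles used to validate the package
# implementations. Deliberately naive: plain loops, no shared code with R/.

# least-squares affine fit by explicit normal equations
oracle_affine <- function(src, dst) {
  A <- cbind(src[, 1], src[, 2], 1)
  beta <- solve(t(A) %*% A) %*% t(A) %*% dst  # 3 x 2
  c(a = beta[1, 1], b = beta[2, 1], tx = beta[3, 1],
    c = beta[1, 2], d = beta[2, 2], ty = beta[3, 2])
}

# O(n^2) mean silhouette with the singleton-0 convention
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# even-odd point-in-polygon, scalar loop
oracle_pip <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py)) {
      xint <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
        (poly[j, 2] - poly[i, 2]) + poly[i, 1]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# stack-based flood-fill component labeling
oracle_label <- function(M, connectivity = 4) {
  h <- nrow(M); w <- ncol(M)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 4) rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  nxt <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!M[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, c)); lab[r, c] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            M[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# naive O(n^3) complete-linkage agglomeration; returns sorted merge heights
oracle_complete_linkage_heights <- function(X) {
  clusters <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  denom <- (sum_a + sum_b) / 2 - exp_idx
  if (denom == 0) return(as.numeric(sum_ij == exp_idx))  # both trivial
  (sum_ij - exp_idx) / denom
}

# planted label of each dataset pixel from a phantom truth image
truth_labels <- function(ph) {
  as.matrix(ph$truth)[cbind(ph$dataset$coords[, 2] + 1,
                            ph$dataset$coords[, 1] + 1)]
}

# random blob mask: union of seeded rectangles and points
random_mask <- function(h, w, n_blobs = 3, seed = 1) {
  set.seed(seed)
  M <- matrix(FALSE, h, w)
  for (i in seq_len(n_blobs)) {
    r <- sort(sample(h, 2)); c <- sort(sample(w, 2))
    M[r[1]:r[2], c[1]:c[2]] <- TRUE
  }
  M[cbind(sample(h, 5, replace = TRUE), sample(w, 5, replace = TRUE))] <- TRUE
  M
}
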