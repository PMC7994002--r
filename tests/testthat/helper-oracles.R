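# Brute-force oracles and shared fixtures. Oracles are deliberately naive
# (per-voxel / all-pairs searches) and independent of the package's
# transform-based implementations.

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# standard jagged atlas fixture: 12 labels (core + 2 shells x 5 sectors +
# fragmented ID 9999), per-plane jitter 2
std_atlas <- function() {
  memo_fixture("std_atlas", function() {
    make_synthetic_atlas(shape = c(128, 128, 128), jitter = 2,
                         fragmented_label = TRUE, seed = 42)
  })
}

small_atlas <- function() {
  memo_fixture("small_atlas", function() {
    make_synthetic_atlas(shape = c(48, 48, 48), n_shells = 1L, n_sectors = 3L,
                         jitter = 2, seed = 7)
  })
}

# standard clean nuclei phantom: 200 nuclei, SNR 5, 128^3
std_nuclei <- function() {
  memo_fixture("std_nuclei", function() {
    make_synthetic_nuclei_volume(seed = 11)
  })
}

# detection on the standard phantom, unchunked and chunked
std_detection <- function() {
  memo_fixture("std_detection", function() {
    fx <- std_nuclei()
    p <- detect_params(nucleus_radius = 5, preprocess = FALSE)
    list(params = p,
         single = detect_blobs(fx$vol$data, params = p),
         chunked = detect_whole_volume(fx$vol$data, p))
  })
}

# edge-aware refinement of the standard 96^3 degraded fixture
std_refined <- function() {
  memo_fixture("std_refined", function() {
    fx <- memo_fixture("refine_fixture", function() {
      make_synthetic_atlas(shape = c(96, 96, 96), jitter = 2, seed = 7)
    })
    p <- refine_params(seed_erosion = 4, skeleton_erosion = 2,
                       post_smooth = smooth_params("adaptive_opening", size = 2))
    refine_atlas(fx$vol, fx$degraded, p, edge_map_params(gaussian_sigma = 2))
  })
}

ball_mask <- function(r, n = 2 * r + 7) {
  ctr <- (n + 1) / 2
  i2 <- (seq_len(n) - ctr)^2
  outer(outer(i2, i2, `+`), i2, `+`) <= r^2
}

# nearest labeled voxel per target voxel, lowest linear index on ties
brute_inpaint <- function(labels, target, spacing = c(1, 1, 1)) {
  d <- dim(labels)
  out <- labels
  donors <- which(labels != 0L)
  dw <- arrayInd(donors, d)
  for (v in which(target & labels == 0L)) {
    w <- arrayInd(v, d)
    dd <- (dw[, 1] - w[1])^2 * spacing[1]^2 + (dw[, 2] - w[2])^2 * spacing[2]^2 +
      (dw[, 3] - w[3])^2 * spacing[3]^2
    out[v] <- labels[donors[which.min(dd)]]
  }
  out
}

# voxel is surface iff labeled and any face neighbour (or border) differs
brute_surface <- function(labels) {
  d <- dim(labels)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- labels[i, j, k]
    if (v == 0L) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    surf <- FALSE
    for (t in 1:6) {
      p <- nb[t, ]
      if (any(p < 1) || any(p > d)) {
        surf <- TRUE
      } else if (labels[p[1], p[2], p[3]] != v) {
        surf <- TRUE
      }
    }
    out[i, j, k] <- surf
  }
  out
}

# per-surface-voxel nearest-edge distance sums
brute_edge_dist <- function(labels, edge, spacing = c(1, 1, 1)) {
  ew <- which(edge)
  stopifnot(length(ew) > 0)
  ec <- arrayInd(ew, dim(edge))
  surf <- brute_surface(labels)
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  sums <- vapply(ids, function(id) {
    sel <- which(surf & labels == id)
    if (!length(sel)) return(0)
    sc <- arrayInd(sel, dim(labels))
    tot <- 0
    for (t in seq_len(nrow(sc))) {
      dd <- sqrt((ec[, 1] - sc[t, 1])^2 * spacing[1]^2 +
                 (ec[, 2] - sc[t, 2])^2 * spacing[2]^2 +
                 (ec[, 3] - sc[t, 3])^2 * spacing[3]^2)
      tot <- tot + min(dd)
    }
    tot
  }, 0)
  list(per_label = sums, total = sum(sums))
}

# DBSCAN by explicit density-reachability closure; returns list(core, noise,
# n_clusters, labels) with border points assigned to the first core cluster
# reaching them in index order
brute_dbscan <- function(pts, eps, min_samples) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  nbr <- D <= eps
  core <- rowSums(nbr) >= min_samples
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      if (!core[p]) next
      for (q in which(nbr[p, ])) {
        if (lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  list(core = core, noise = lab == 0L, n_clusters = cur, labels = lab)
}

brute_knn_kth <- function(pts, k) {
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  apply(D, 1, function(r) sort(r)[k])
}

# all-permutations optimal assignment for tiny square cost matrices
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) {
      best_cost <- cc
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}

mean_label_dsc <- function(a, b) {
  da <- if (is.list(a)) a$data else a
  db <- if (is.list(b)) b$data else b
  ids <- sort(setdiff(unique(as.vector(da)), 0L))
  mean(vapply(ids, function(id) dice(da == id, db == id), 0))
}
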