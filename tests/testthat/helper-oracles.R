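# Independent oracles used to check the package implementations.
# These deliberately take the dumbest correct route: explicit matrix
# inverses, exhaustive enumeration, and sliding windows.

# BM covariance by explicit pairwise MRCA depth search ----------------------
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2L]] <- tree$edge[k, 1L]
    elen[tree$edge[k, 2L]] <- tree$edge.length[k]
  }
  root <- n + 1L
  path_to_root <- function(node) {
    p <- node
    while (node != root) {
      node <- parent[node]
      p <- c(p, node)
    }
    p
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + elen[node]
      node <- parent[node]
    }
    d
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    pi <- path_to_root(i)
    for (j in i:n) {
      pj <- path_to_root(j)
      common <- intersect(pi, pj)
      mrca <- common[which.max(vapply(common, depth, numeric(1)))]
      C[i, j] <- C[j, i] <- depth(mrca)
    }
  }
  C
}

# Blomberg's K by direct evaluation with explicit inverses ------------------
oracle_k <- function(tree, trait) {
  C <- oracle_vcv(tree)
  y <- trait[rownames(C)]
  n <- length(y)
  Cinv <- solve(C)
  ones <- rep(1, n)
  ahat <- as.numeric((t(ones) %*% Cinv %*% y) / (t(ones) %*% Cinv %*% ones))
  r <- y - ahat
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(t(r) %*% Cinv %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / as.numeric(t(ones) %*% Cinv %*% ones)) /
    (n - 1)
  (mse0 / mse) / expected
}

# affine-gap global alignment score by iterative DP in plain R --------------
oracle_align_score <- function(a, b, sub, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -gap_open - (i - 1L) * gap_extend
  for (j in seq_len(m)) Y[1L, j + 1L] <- -gap_open - (j - 1L) * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[av[i], bv[j]]
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open,
                               X[i, j + 1L] - gap_extend,
                               Y[i, j + 1L] - gap_open)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open,
                               Y[i + 1L, j] - gap_extend,
                               X[i + 1L, j] - gap_open)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# truly exhaustive alignment enumeration (tiny inputs only) -----------------
oracle_align_enum <- function(a, b, sub, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  score_moves <- function(moves) {
    s <- 0
    i <- 0L; j <- 0L
    rle_m <- rle(moves)
    for (k in seq_along(rle_m$values)) {
      v <- rle_m$values[k]; L <- rle_m$lengths[k]
      if (v != "M") s <- s - gap_open - gap_extend * (L - 1L)
    }
    for (v in moves) {
      if (v == "M") {
        i <- i + 1L; j <- j + 1L
        s <- s + sub[av[i], bv[j]]
      } else if (v == "X") i <- i + 1L else j <- j + 1L
    }
    s
  }
  best <- -Inf
  recurse <- function(i, j, moves) {
    if (i == length(av) && j == length(bv)) {
      best <<- max(best, score_moves(moves))
      return(invisible())
    }
    if (i < length(av) && j < length(bv)) recurse(i + 1L, j + 1L, c(moves, "M"))
    if (i < length(av)) recurse(i + 1L, j, c(moves, "X"))
    if (j < length(bv)) recurse(i, j + 1L, c(moves, "Y"))
  }
  recurse(0L, 0L, character())
  best
}

# sliding-window motif scan -------------------------------------------------
oracle_scan <- function(seq, motifs) {
  s <- strsplit(seq, "")[[1L]]
  out <- list()
  for (k in seq_len(nrow(motifs))) {
    pat <- strsplit(motifs$pattern[k], "")[[1L]]
    L <- length(pat)
    if (L > length(s)) next
    for (i in seq_len(length(s) - L + 1L)) {
      w <- s[i:(i + L - 1L)]
      if (all(pat == "x" | pat == w))
        out[[length(out) + 1L]] <- data.frame(motif = motifs$name[k],
                                              start = i,
                                              match = paste(w, collapse = ""),
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(motif = character(), start = integer(),
                                      match = character(),
                                      stringsAsFactors = FALSE))
  o <- do.call(rbind, out)
  o <- o[order(o$start, o$motif), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# small fixture trees (<= 8 tips) for the K oracle --------------------------
fixture_trees <- function() {
  trees <- list(
    ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"),
    ape::read.tree(text = "(((A:0.5,B:0.5):0.5,C:1):1,D:2);"),
    ape::read.tree(text = "((A:0.2,B:0.9):0.4,(C:1.1,(D:0.3,E:0.3):0.8):0.2);")
  )
  set.seed(99)
  for (n in 6:8) {
    tr <- ape::rtree(n)
    tr$edge.length <- abs(tr$edge.length) + 0.1
    trees[[length(trees) + 1L]] <- tr
  }
  trees
}

rand_seq <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

cluster_coords_for_test <- function(model, label)
  as.matrix(model$atoms[model$cluster_groups[[label]], c("x", "y", "z")])
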