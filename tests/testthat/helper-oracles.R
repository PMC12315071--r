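## Independent oracles used across the suite.  These deliberately share
## no code with the package internals they check.

## ---- d-separation by moralised ancestral graphs -------------------
## adj: logical matrix, adj[i, j] TRUE for edge i -> j.
oracle_dsep <- function(adj, u, v, Z) {
  n <- nrow(adj)
  ## ancestors of a node set (including the set)
  anc <- function(set) {
    res <- set
    repeat {
      pa <- which(rowSums(adj[, res, drop = FALSE]) > 0)
      new <- setdiff(pa, res)
      if (!length(new)) break
      res <- c(res, new)
    }
    res
  }
  A <- sort(anc(unique(c(u, v, Z))))
  sub <- adj[A, A, drop = FALSE]
  m <- sub | t(sub)               # undirected skeleton
  ## moralise: marry parents of every child
  for (k in seq_along(A)) {
    pa <- which(sub[, k])
    if (length(pa) > 1L)
      for (a in pa) for (b in pa) if (a != b) m[a, b] <- TRUE
  }
  keep <- !(A %in% Z)
  m <- m[keep, keep, drop = FALSE]
  ids <- A[keep]
  iu <- match(u, ids); iv <- match(v, ids)
  if (is.na(iu) || is.na(iv)) return(TRUE)
  ## BFS connectivity u -> v
  seen <- rep(FALSE, length(ids)); seen[iu] <- TRUE
  frontier <- iu
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(i) which(m[i, ]))))
    nxt <- nxt[!seen[nxt]]
    if (iv %in% nxt) return(FALSE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  TRUE
}

## Enumerate every labelled DAG on n nodes as a list of adjacency
## matrices.  Every DAG is a permutation of an upper-triangular mask
## (edges from earlier to later in some order); relabelling by all
## permutations and deduplicating yields the full labelled family.
enumerate_dags <- function(n) {
  stopifnot(n >= 1, n <= 5)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  n_e <- nrow(pairs)
  perms <- all_perms(n)
  seen <- new.env(hash = TRUE)
  out <- list()
  for (mask in 0:(2^n_e - 1)) {
    bits <- bitwAnd(mask, 2^(seq_len(n_e) - 1L)) > 0
    from <- pairs[bits, 1L]; to <- pairs[bits, 2L]
    for (p in perms) {
      adj <- matrix(FALSE, n, n)
      if (length(from)) adj[cbind(p[from], p[to])] <- TRUE
      key <- paste0("k", paste(which(adj), collapse = ","))
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- adj
      }
    }
  }
  out
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (i in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = i)
  out
}

## ---- naive stability reference ------------------------------------
## Straight-line reimplementation of the five metrics with explicit
## loops; used as the oracle for stability_profile().
naive_profile <- function(mat) {
  n <- nrow(mat); s <- ncol(mat)
  detr <- function(y) {
    t_ <- 0:(n - 1)
    fit <- stats::lm(y ~ t_)
    stats::resid(fit)
  }
  res <- sapply(seq_len(s), function(j) detr(mat[, j]))
  mu <- sapply(seq_len(s), function(j) mean(mat[, j]))
  sig <- apply(res, 2, stats::sd)
  tot_res <- rowSums(res)
  TS <- sum(mu) / stats::sd(tot_res)
  PS <- sum(mu) / sum(sig)
  phi <- stats::var(tot_res) / sum(sig)^2
  SA <- sum(sig) / sqrt(sum(sig^2))
  bc <- numeric(0)
  for (t in seq_len(n - 1)) {
    u <- mat[t, ]; v <- mat[t + 1, ]
    if (sum(u) + sum(v) > 0)
      bc <- c(bc, sum(abs(u - v)) / sum(u + v))
  }
  CS <- 1 - mean(bc)
  list(TS = TS, PS = PS, phi = phi, asynchrony = 1 - phi, SA = SA, CS = CS)
}

## Random census-by-taxon cover matrix with guaranteed variability.
random_cover_matrix <- function(n_taxa, n_cens = 11L) {
  m <- matrix(stats::runif(n_taxa * n_cens, 0, 40), n_cens, n_taxa)
  ## sprinkle zeros but keep every taxon varying
  m[sample(length(m), floor(length(m) / 10))] <- 0
  m
}

## Small design used across model tests.
test_design <- function(seed = 1) generate_design(5, 7, c(0.1, 0.9), seed)
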