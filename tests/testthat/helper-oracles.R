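# Brute-force oracles, independent of the package's implementation paths:
# role classification by direct degree counting, all-pairs shortest paths
# by Floyd-Warshall on the adjacency matrix, exhaustive simple-cycle and
# simple-path enumeration by plain recursion. Meant for graphs of <= 8
# nodes.

# adjacency matrix (0/1) and sign matrix from a causal_map, in concept order
oracle_matrices <- function(map) {
  ids <- map$concepts$id
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  S <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(map$edges))) {
    A[map$edges$src[k], map$edges$dst[k]] <- 1L
    S[map$edges$src[k], map$edges$dst[k]] <- map$edges$polarity[k]
  }
  list(A = A, S = S, ids = ids)
}

oracle_roles <- function(map) {
  om <- oracle_matrices(map)
  outd <- rowSums(om$A); ind <- colSums(om$A)
  role <- ifelse(outd == 0 & ind == 0, "isolated",
          ifelse(ind == 0, "source",
          ifelse(outd == 0, "receiver", "transmitter")))
  stats::setNames(as.character(role), map$concepts$label)
}

# Floyd-Warshall; returns matrix of shortest path lengths (Inf unreachable)
oracle_dist <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

oracle_diameter <- function(map, mode = "directed") {
  om <- oracle_matrices(map)
  A <- om$A
  if (mode == "undirected") A <- pmax(A, t(A))
  D <- oracle_dist(A)
  fin <- D[is.finite(D) & D > 0]
  if (length(fin) == 0L) NA_integer_ else as.integer(max(fin))
}

# exhaustive vertex-simple cycles by plain recursion over the adjacency
# matrix; each cycle reported once as a canonical key rotated to start at
# its lexicographically smallest vertex, with its edge-sign product
oracle_cycles <- function(map) {
  om <- oracle_matrices(map)
  n <- nrow(om$A)
  if (n == 0L) return(character())
  found <- character()
  walk <- function(path) {
    v <- path[length(path)]
    for (w in which(om$A[v, ] == 1L)) {
      if (w == path[1L] && length(path) >= 2L) {
        rot <- which(om$ids[path] == min(om$ids[path]))[1L]
        cyc <- c(path, path)[rot:(rot + length(path) - 1L)]
        sgn <- prod(om$S[cbind(cyc, c(cyc[-1L], cyc[1L]))])
        found[[length(found) + 1L]] <<-
          paste0(paste(om$ids[cyc], collapse = "|"), "=", sgn)
      } else if (!(w %in% path) && w > path[1L]) {
        walk(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  sort(unique(found))
}

# the same canonical keys from a cycle_census() result
census_cycle_keys <- function(map, cc) {
  if (nrow(cc$cycles) == 0L) return(character())
  keys <- vapply(seq_len(nrow(cc$cycles)), function(i) {
    labs <- strsplit(cc$cycles$nodes[i], " -> ", fixed = TRUE)[[1]]
    labs <- labs[-length(labs)]
    ids <- norm_label(labs)
    rot <- which(ids == min(ids))[1L]
    ids <- c(ids, ids)[rot:(rot + length(ids) - 1L)]
    paste0(paste(ids, collapse = "|"), "=", cc$cycles$sign[i])
  }, character(1))
  sort(keys)
}

# multiset of sign products over simple u -> v paths (ids), by recursion
oracle_path_signs <- function(map, u, v) {
  om <- oracle_matrices(map)
  iu <- match(u, om$ids); iv <- match(v, om$ids)
  out <- integer()
  walk <- function(path, sgn) {
    w0 <- path[length(path)]
    for (w in which(om$A[w0, ] == 1L)) {
      s2 <- sgn * om$S[w0, w]
      if (w == iv) out[[length(out) + 1L]] <<- s2
      else if (!(w %in% path) && w != iu) walk(c(path, w), s2)
    }
  }
  if (!is.na(iu) && !is.na(iv) && iu != iv) walk(iu, 1L)
  sort(out)
}
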