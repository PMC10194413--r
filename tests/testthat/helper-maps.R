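# Builders shared across test files.

# mk_map("A +B", "B -C") builds a map with edges A->B (+1), B->C (-1).
mk_map <- function(..., map_id = "m", focal = NULL) {
  m <- causal_map(map_id = map_id, focal = focal)
  for (e in c(...)) {
    i <- regexpr(" [+-]", e)
    stopifnot(i > 0L)
    sgn <- if (substr(e, i + 1L, i + 1L) == "-") -1L else 1L
    m <- add_edge(m, substr(e, 1L, i - 1L), substring(e, i + 2L), sgn)
  }
  m
}

# random signed digraph on n nodes with edge probability p
rand_map <- function(n, p = 0.25, p_neg = 0.3, map_id = "r") {
  labels <- paste0("n", seq_len(n))
  m <- causal_map(map_id = map_id)
  for (lab in labels) m <- add_concept(m, lab)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && runif(1) < p) {
      m <- add_edge(m, labels[i], labels[j],
                    if (runif(1) < p_neg) -1L else 1L)
    }
  }
  m
}

# edge table keyed for set comparison: "src>dst:sign"
edge_keys <- function(map) {
  e <- map$edges
  if (nrow(e) == 0L) return(character())
  sort(paste0(e$src, ">", e$dst, ":",
              ifelse(is.na(e$polarity), "?", e$polarity)))
}

map_identical <- sysmapr:::map_identical
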