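# Structural validation and census of a causal map: node typology
# (source / receiver / transmitter / isolated), density, degree statistics,
# diameter, signed feedback-loop census, and the advisory QC checks applied
# to each elicited map before aggregation.

#' Classify concepts by structural role
#'
#' Causal impacts can start at a node (*source*: out-degree >= 1, in-degree
#' 0; typically a model parameter), end at a node (*receiver*: in-degree
#' >= 1, out-degree 0; typically an output), or pass through a node
#' (*transmitter*: both). Concepts with no edges are *isolated*. The four
#' roles partition the concept set.
#'
#' @param map a `causal_map`.
#' @return a character vector of roles named by concept display label, in
#'   concept order.
#' @examples
#' m <- add_edge(add_edge(causal_map(), "A", "B", 1), "B", "C", 1)
#' classify_nodes(m) # A source, B transmitter, C receiver
#' @export
classify_nodes <- function(map) {
  stopifnot(inherits(map, "causal_map"))
  outd <- table(factor(map$edges$src, levels = map$concepts$id))
  ind <- table(factor(map$edges$dst, levels = map$concepts$id))
  role <- ifelse(outd == 0 & ind == 0, "isolated",
          ifelse(ind == 0, "source",
          ifelse(outd == 0, "receiver", "transmitter")))
  stats::setNames(as.character(role), map$concepts$label)
}

#' Density of a causal map
#'
#' Directed density: `m / (n * (n - 1))`, the fraction of ordered concept
#' pairs connected by an edge (self-loops are excluded by construction).
#' Elicited maps are expected to be very sparse.
#'
#' @param map a `causal_map` with at least 2 concepts.
#' @return a ratio in `[0, 1]`.
#' @export
map_density <- function(map) {
  n <- n_concepts(map)
  if (n < 2L) stop("density undefined for fewer than 2 concepts")
  n_edges(map) / (n * (n - 1))
}

#' Degree statistics
#'
#' Total degree (in + out) per concept; the average degree of a directed
#' graph is `2 m / n`. Ties for the maximum are all reported, in
#' lexicographic label order.
#'
#' @param map a `causal_map` with at least 1 concept.
#' @return a list with `avg_degree`, `max_degree`, `max_degree_concepts`
#'   (display labels) and the full `degree` vector named by label.
#' @export
degree_stats <- function(map) {
  n <- n_concepts(map)
  if (n < 1L) stop("degree statistics undefined for an empty map")
  outd <- table(factor(map$edges$src, levels = map$concepts$id))
  ind <- table(factor(map$edges$dst, levels = map$concepts$id))
  deg <- as.integer(outd + ind)
  names(deg) <- map$concepts$label
  mx <- max(deg)
  argmax <- map$concepts$label[deg == mx]
  argmax <- argmax[order(norm_label(argmax), method = "radix")]
  list(avg_degree = 2 * n_edges(map) / n, max_degree = mx,
       max_degree_concepts = argmax, degree = deg)
}

#' Diameter of a causal map
#'
#' Maximum finite shortest-path length over ordered pairs of distinct
#' concepts; unreachable pairs are ignored. The directed mode (default)
#' measures how elaborated the causal chains are; the undirected mode
#' measures spread of the underlying skeleton. Both are offered because
#' published map summaries do not always state their convention.
#'
#' @param map a `causal_map` with at least one edge.
#' @param mode "directed" or "undirected".
#' @return an integer count of edges on the longest shortest path.
#' @export
map_diameter <- function(map, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  if (n_edges(map) == 0L) stop("diameter undefined for a map with no edges")
  g <- as_igraph(map)
  d <- igraph::distances(g, mode = if (mode == "directed") "out" else "all")
  fin <- d[is.finite(d) & d > 0]
  as.integer(max(fin))
}

# adjacency list of integer neighbour indices, concepts in map order
.adj_list <- function(map) {
  idx <- stats::setNames(seq_len(n_concepts(map)), map$concepts$id)
  adj <- rep(list(integer()), n_concepts(map))
  for (k in seq_len(n_edges(map))) {
    i <- idx[[map$edges$src[k]]]
    adj[[i]] <- c(adj[[i]], idx[[map$edges$dst[k]]])
  }
  lapply(adj, sort)
}

#' Feedback-loop census
#'
#' Detects whether the map has any directed cycle (via strongly connected
#' components) and enumerates vertex-simple cycles up to a length cap,
#' with each cycle's sign: the product of its edge polarities. A positive
#' product is a reinforcing loop, a negative product a balancing loop; a
#' cycle through a sign-conflicted edge has sign `NA`. Enumeration uses a
#' bounded depth-first search (each cycle found once, rooted at its
#' smallest vertex) and aborts with a `truncated` flag if the count cap is
#' hit, since simple-cycle counts grow exponentially.
#'
#' @param map a `causal_map`.
#' @param max_len maximum cycle length to enumerate (default 7).
#' @param max_cycles abort enumeration beyond this many cycles
#'   (default 10000).
#' @return a list: `has_cycles`, `n_nontrivial_sccs`, `cycles` (data.frame
#'   with columns `nodes` — "A -> B -> A" style label path —, `length`,
#'   `sign`, `type` in reinforcing/balancing/unknown), `truncated`.
#' @export
cycle_census <- function(map, max_len = 7L, max_cycles = 10000L) {
  stopifnot(inherits(map, "causal_map"))
  if (max_len < 2L) stop("max_len must be >= 2")
  g <- as_igraph(map)
  comp <- igraph::components(g, mode = "strong")
  n_scc <- sum(comp$csize > 1L)
  adj <- .adj_list(map)
  n <- n_concepts(map)
  pol <- stats::setNames(map$edges$polarity,
                         paste(map$edges$src, map$edges$dst, sep = "\r"))
  ids <- map$concepts$id
  found <- list(); count <- 0L; truncated <- FALSE
  record <- function(path) {
    if (count >= max_cycles) { truncated <<- TRUE; return(FALSE) }
    count <<- count + 1L
    found[[count]] <<- path
    TRUE
  }
  dfs <- function(v, s, path, visited) {
    if (truncated) return()
    for (w in adj[[v]]) {
      if (truncated) return()
      if (w == s && length(path) >= 2L) {
        record(path)
      } else if (w > s && !visited[w] && length(path) < max_len) {
        visited[w] <- TRUE
        dfs(w, s, c(path, w), visited)
        visited[w] <- FALSE
      }
    }
  }
  if (n > 0L && n_scc > 0L) {
    # only vertices inside a nontrivial SCC can lie on a cycle
    in_scc <- comp$csize[comp$membership] > 1L
    visited <- logical(n)
    for (s in seq_len(n)) {
      if (!in_scc[s] || truncated) next
      visited[s] <- TRUE
      dfs(s, s, s, visited)
      visited[s] <- FALSE
    }
  }
  labs <- map$concepts$label
  cyc <- if (length(found) == 0L) {
    data.frame(nodes = character(), length = integer(), sign = integer(),
               type = character(), stringsAsFactors = FALSE)
  } else {
    sgn <- vapply(found, function(p) {
      e <- paste0(ids[p], "\r", ids[c(p[-1L], p[1L])])
      prod(pol[e])  # NA if any edge conflicted
    }, numeric(1))
    data.frame(
      nodes = vapply(found, function(p)
        paste(c(labs[p], labs[p[1L]]), collapse = " -> "), character(1)),
      length = lengths(found),
      sign = as.integer(sgn),
      type = ifelse(is.na(sgn), "unknown",
                    ifelse(sgn > 0, "reinforcing", "balancing")),
      stringsAsFactors = FALSE)
  }
  list(has_cycles = n_scc > 0L, n_nontrivial_sccs = n_scc, cycles = cyc,
       truncated = truncated)
}

#' Advisory structural QC of an elicited map
#'
#' Checks the qualitative expectations for a well-elicited individual map:
#' it should contain feedback loops (interviewees need facilitation to
#' articulate them), its causal chains should be elaborated (diameter not
#' too small), it should not be dominated by parameters (source fraction),
#' and it should be sparse. Findings are warnings for a human reviewer,
#' never errors.
#'
#' @param map a `causal_map`.
#' @param thresholds a [pipeline_config()] or any list with
#'   `diameter_floor`, `source_fraction_max`, `density_max`.
#' @return a data.frame of findings: criterion, message, value, threshold.
#'   Zero rows means all checks passed.
#' @export
validate_map <- function(map, thresholds = pipeline_config()) {
  f <- list()
  add <- function(criterion, message, value, threshold)
    f[[length(f) + 1L]] <<- data.frame(criterion = criterion,
                                       message = message, value = value,
                                       threshold = threshold,
                                       stringsAsFactors = FALSE)
  if (n_edges(map) > 0L) {
    g <- as_igraph(map)
    comp <- igraph::components(g, mode = "strong")
    if (!any(comp$csize > 1L))
      add("cycles", "no feedback loops: interviewees may not have been prompted for them",
          0, 1)
    dia <- map_diameter(map)
    if (dia < thresholds$diameter_floor)
      add("diameter", "short causal chains: arguments may not be well elaborated",
          dia, thresholds$diameter_floor)
  } else {
    add("cycles", "no edges at all", 0, 1)
    add("diameter", "no edges at all", 0, thresholds$diameter_floor)
  }
  if (n_concepts(map) >= 2L) {
    roles <- classify_nodes(map)
    sf <- mean(roles == "source")
    if (sf > thresholds$source_fraction_max)
      add("source_fraction", "many parameters: drivers may not yet be interrelated",
          sf, thresholds$source_fraction_max)
    dens <- map_density(map)
    if (dens > thresholds$density_max)
      add("density", "denser than expected for an elicited map",
          dens, thresholds$density_max)
  }
  if (length(f) == 0L)
    return(data.frame(criterion = character(), message = character(),
                      value = numeric(), threshold = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, f)
}

#' Structural census of a causal map
#'
#' Computes the full structural summary of a map: node and edge counts,
#' the node-role partition, density, average/maximum degree, diameter,
#' cycle presence, and degree concentration (the fraction of all edges
#' incident to the single highest-degree concept, a centralization
#' indicator).
#'
#' @param map a `causal_map`.
#' @param diameter_mode "directed" (default) or "undirected".
#' @return an object of class `map_census` (a list of the fields above);
#'   `diameter` is `NA` when the map has no edges, `density` is `NA` when
#'   it has fewer than two concepts.
#' @export
census <- function(map, diameter_mode = c("directed", "undirected")) {
  diameter_mode <- match.arg(diameter_mode)
  n <- n_concepts(map); m <- n_edges(map)
  roles <- if (n > 0L) classify_nodes(map) else character()
  ds <- if (n > 0L) degree_stats(map) else
    list(avg_degree = NA_real_, max_degree = NA_integer_,
         max_degree_concepts = character())
  has_cyc <- if (m > 0L) {
    comp <- igraph::components(as_igraph(map), mode = "strong")
    any(comp$csize > 1L)
  } else FALSE
  structure(list(
    n_nodes = n, n_edges = m,
    n_sources = sum(roles == "source"),
    n_receivers = sum(roles == "receiver"),
    n_transmitters = sum(roles == "transmitter"),
    n_isolated = sum(roles == "isolated"),
    density = if (n >= 2L) map_density(map) else NA_real_,
    avg_degree = ds$avg_degree,
    max_degree = ds$max_degree,
    max_degree_concepts = ds$max_degree_concepts,
    diameter = if (m > 0L) map_diameter(map, diameter_mode) else NA_integer_,
    diameter_mode = diameter_mode,
    has_cycles = has_cyc,
    degree_concentration = if (m > 0L) ds$max_degree / m else NA_real_
  ), class = "map_census")
}

#' @export
print.map_census <- function(x, ...) {
  fmt <- function(v, d = 3) {
    if (is.na(v)) "NA" else if (v == round(v)) format(v) else
      sprintf("%.*f (%.6g at full precision)", d, v, v)
  }
  rows <- c(
    "Number of nodes" = format(x$n_nodes),
    "Number of source nodes" = format(x$n_sources),
    "Number of receiver nodes" = format(x$n_receivers),
    "Number of edges" = format(x$n_edges),
    "Density" = fmt(x$density),
    "Average degree" = fmt(x$avg_degree),
    "Maximum degree" = sprintf("%s (%s)", format(x$max_degree),
                               paste(x$max_degree_concepts, collapse = ", ")),
    "Diameter" = sprintf("%s [%s]", format(x$diameter), x$diameter_mode))
  w <- max(nchar(names(rows)))
  cat("Structural census\n")
  for (i in seq_along(rows))
    cat(sprintf("  %-*s  %s\n", w, names(rows)[i], rows[i]))
  cat(sprintf("  %-*s  %s\n", w, "Transmitters / isolated",
              paste(x$n_transmitters, "/", x$n_isolated)))
  cat(sprintf("  %-*s  %s\n", w, "Feedback loops present",
              ifelse(x$has_cycles, "yes", "no")))
  cat(sprintf("  %-*s  %s\n", w, "Degree concentration",
              fmt(x$degree_concentration)))
  invisible(x)
}

#' Census as a two-column data.frame (for CSV/JSON export)
#' @param census_obj a `map_census`.
#' @return data.frame with `characteristic` and `value` columns.
#' @export
census_table <- function(census_obj) {
  stopifnot(inherits(census_obj, "map_census"))
  data.frame(
    characteristic = c("Number of nodes", "Number of source nodes",
                       "Number of receiver nodes", "Number of edges",
                       "Density", "Average degree", "Maximum degree",
                       "Diameter", "Number of transmitter nodes",
                       "Number of isolated nodes", "Has cycles",
                       "Degree concentration"),
    value = c(census_obj$n_nodes, census_obj$n_sources,
              census_obj$n_receivers, census_obj$n_edges,
              round(census_obj$density, 3), round(census_obj$avg_degree, 3),
              census_obj$max_degree, census_obj$diameter,
              census_obj$n_transmitters, census_obj$n_isolated,
              as.integer(census_obj$has_cycles),
              round(census_obj$degree_concentration, 3)),
    stringsAsFactors = FALSE)
}
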