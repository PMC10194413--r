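# Core data model: signed causal maps.
#
# A causal map is a signed directed graph. Nodes are concepts named by a
# canonical display label; edges assert that an increase in the source
# concept increases (+1) or decreases (-1) the target concept. Every edge
# carries provenance: the multiset of (origin map, sign) assertions that
# produced it, so that a panel of expert maps can be merged without losing
# who said what.

#' Normalize a concept label for identity
#'
#' Concept identity is decided on a normalized form: whitespace is trimmed
#' and collapsed, and the label is case-folded. The original (squished)
#' casing is kept for display.
#'
#' @param x character vector of raw labels.
#' @return character vector of normalized labels.
#' @examples
#' norm_label(c("  Structural   Racism ", "structural racism"))
#' @export
norm_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

# display form: squish whitespace, keep case
.squish <- function(x) gsub("\\s+", " ", trimws(as.character(x)))

#' Create an empty causal map
#'
#' @param map_id identifier for this map (used as default edge provenance
#'   origin, e.g. the expert or file the map came from).
#' @param focal optional label of the focal problem concept the map was
#'   elicited around; created as a concept if supplied.
#' @return an object of class `causal_map`.
#' @examples
#' m <- causal_map("sme01", focal = "suicide ideation")
#' m <- add_edge(m, "hopelessness", "suicide ideation", +1)
#' m
#' @export
causal_map <- function(map_id = "map", focal = NULL) {
  m <- structure(list(
    concepts = data.frame(id = character(), label = character(),
                          protected = logical(), stringsAsFactors = FALSE),
    edges = data.frame(src = character(), dst = character(),
                       polarity = integer(), conflicted = logical(),
                       n_pos = integer(), n_neg = integer(),
                       stringsAsFactors = FALSE),
    focal = NA_character_,
    map_id = as.character(map_id)
  ), class = "causal_map")
  m$concepts$aliases <- list()
  m$edges$provenance <- list()
  if (!is.null(focal)) {
    m <- add_concept(m, focal)
    m$focal <- norm_label(focal)
  }
  m
}

#' Add a concept to a map
#'
#' No-op if a concept with the same normalized label already exists (but
#' a differently-cased raw label is remembered as an alias).
#'
#' @param map a `causal_map`.
#' @param label raw concept label; identity is its [norm_label()] form.
#' @param protected logical; protected concepts are exempt from
#'   simplification (never pruned or contracted).
#' @return the updated map.
#' @export
add_concept <- function(map, label, protected = FALSE) {
  stopifnot(inherits(map, "causal_map"))
  disp <- .squish(label)
  id <- norm_label(label)
  if (!nzchar(id)) stop("concept label is empty after whitespace normalization")
  i <- match(id, map$concepts$id)
  if (is.na(i)) {
    map$concepts <- rbind(map$concepts, data.frame(
      id = id, label = disp, protected = isTRUE(protected),
      aliases = I(list(character())), stringsAsFactors = FALSE))
  } else {
    if (!identical(disp, map$concepts$label[i]) &&
        !(disp %in% map$concepts$aliases[[i]])) {
      map$concepts$aliases[[i]] <- sort(unique(c(map$concepts$aliases[[i]], disp)))
    }
    if (isTRUE(protected)) map$concepts$protected[i] <- TRUE
  }
  map
}

# majority polarity under the conflict policy: exact tie -> conflicted
# (polarity NA) and the edge is excluded from sign-dependent operations.
.derive_polarity <- function(n_pos, n_neg) {
  polarity <- rep(NA_integer_, length(n_pos))
  polarity[n_pos > n_neg] <- 1L
  polarity[n_neg > n_pos] <- -1L
  list(polarity = polarity,
       conflicted = n_pos == n_neg & (n_pos + n_neg) > 0L)
}

#' Add (or reinforce) a signed causal edge
#'
#' Creates missing concepts, appends a provenance assertion, and recomputes
#' the edge polarity as the majority sign over all assertions; an exact tie
#' marks the edge as conflicted (polarity `NA`) until more evidence arrives.
#' Self-loop requests are rejected with a warning and leave the map
#' unchanged (feedback in this formalism is a multi-node cycle, not a
#' one-node loop).
#'
#' @param map a `causal_map`.
#' @param src,dst raw labels of the cause and effect concepts.
#' @param sign `+1` or `-1`.
#' @param origin provenance tag for the assertion; defaults to the map id.
#' @return the updated map.
#' @examples
#' m <- causal_map("m")
#' m <- add_edge(m, "A", "B", +1, origin = "sme1")
#' m <- add_edge(m, "A", "B", -1, origin = "sme2")
#' m <- add_edge(m, "A", "B", +1, origin = "sme3")
#' edges_df(m) # polarity +1 by majority, n_pos = 2, n_neg = 1
#' @export
add_edge <- function(map, src, dst, sign, origin = map$map_id) {
  stopifnot(inherits(map, "causal_map"))
  sign <- as.integer(sign)
  if (!sign %in% c(1L, -1L)) stop("sign must be +1 or -1")
  s <- norm_label(src); d <- norm_label(dst)
  if (identical(s, d)) {
    warning(sprintf("self-loop rejected for concept '%s'", .squish(src)))
    return(map)
  }
  map <- add_concept(map, src)
  map <- add_concept(map, dst)
  i <- which(map$edges$src == s & map$edges$dst == d)
  prov <- data.frame(origin = as.character(origin), sign = sign,
                     stringsAsFactors = FALSE)
  if (length(i) == 0L) {
    row <- data.frame(src = s, dst = d, polarity = sign, conflicted = FALSE,
                      n_pos = as.integer(sign == 1L),
                      n_neg = as.integer(sign == -1L),
                      provenance = I(list(prov)), stringsAsFactors = FALSE)
    map$edges <- rbind(map$edges, row)
  } else {
    map$edges$provenance[[i]] <- rbind(map$edges$provenance[[i]], prov)
    map$edges$n_pos[i] <- map$edges$n_pos[i] + as.integer(sign == 1L)
    map$edges$n_neg[i] <- map$edges$n_neg[i] + as.integer(sign == -1L)
    p <- .derive_polarity(map$edges$n_pos[i], map$edges$n_neg[i])
    map$edges$polarity[i] <- p$polarity
    map$edges$conflicted[i] <- p$conflicted
  }
  map
}

# Bulk constructor from an assertion table with columns
# src, dst (raw labels), sign (+1/-1), origin. Self-loops are dropped with
# one warning listing the rows. Much faster than repeated add_edge().
.bulk_map <- function(assertions, map_id = "map", focal = NULL,
                      warn_self_loops = TRUE) {
  m <- causal_map(map_id = map_id, focal = focal)
  if (nrow(assertions) == 0L) return(m)
  a <- assertions
  a$src_id <- norm_label(a$src); a$dst_id <- norm_label(a$dst)
  self <- a$src_id == a$dst_id
  if (any(self) && warn_self_loops) {
    warning(sprintf("%d self-loop assertion(s) dropped (%s)", sum(self),
                    paste(unique(.squish(a$src[self])), collapse = ", ")))
  }
  a <- a[!self, , drop = FALSE]
  # register concepts in first-appearance order
  raw <- c(rbind(a$src, a$dst))
  ids <- norm_label(raw)
  keep <- !duplicated(ids)
  for (k in which(keep)) m <- add_concept(m, raw[k])
  # remember alternative raw spellings as aliases
  alt <- !keep & !duplicated(paste(ids, .squish(raw), sep = "\r"))
  for (k in which(alt)) m <- add_concept(m, raw[k])
  if (nrow(a) > 0L) {
    key <- paste0(a$src_id, "\r", a$dst_id)
    grp <- match(key, unique(key))
    n_pos <- as.integer(tapply(a$sign == 1L, grp, sum))
    n_neg <- as.integer(tapply(a$sign == -1L, grp, sum))
    first <- !duplicated(grp)
    pol <- .derive_polarity(n_pos, n_neg)
    prov <- lapply(split(seq_len(nrow(a)), grp), function(ix)
      data.frame(origin = as.character(a$origin[ix]),
                 sign = as.integer(a$sign[ix]), stringsAsFactors = FALSE))
    m$edges <- data.frame(src = a$src_id[first], dst = a$dst_id[first],
                          polarity = pol$polarity, conflicted = pol$conflicted,
                          n_pos = n_pos, n_neg = n_neg,
                          provenance = I(unname(prov)),
                          stringsAsFactors = FALSE)
  }
  m
}

#' Numbers of concepts and edges
#' @param map a `causal_map`.
#' @return integer count.
#' @export
n_concepts <- function(map) nrow(map$concepts)

#' @rdname n_concepts
#' @export
n_edges <- function(map) nrow(map$edges)

#' Edge table of a map
#'
#' @param map a `causal_map`.
#' @return a data.frame with one row per directed edge: source and target
#'   display labels, polarity (`NA` while sign-conflicted), and provenance
#'   counts `n_pos` / `n_neg`.
#' @export
edges_df <- function(map) {
  lab <- stats::setNames(map$concepts$label, map$concepts$id)
  data.frame(src = unname(lab[map$edges$src]), dst = unname(lab[map$edges$dst]),
             polarity = map$edges$polarity, conflicted = map$edges$conflicted,
             n_pos = map$edges$n_pos, n_neg = map$edges$n_neg,
             stringsAsFactors = FALSE)
}

#' Concept table of a map
#' @param map a `causal_map`.
#' @return data.frame with label, protected flag and known aliases.
#' @export
concepts_df <- function(map) {
  data.frame(label = map$concepts$label, protected = map$concepts$protected,
             n_aliases = lengths(map$concepts$aliases), stringsAsFactors = FALSE)
}

#' Mark concepts as protected from simplification
#' @param map a `causal_map`.
#' @param labels concept labels to protect.
#' @return the updated map.
#' @export
set_protected <- function(map, labels) {
  i <- match(norm_label(labels), map$concepts$id)
  if (anyNA(i)) stop("unknown concept(s): ",
                     paste(labels[is.na(i)], collapse = ", "))
  map$concepts$protected[i] <- TRUE
  map
}

#' Set the focal problem concept
#' @param map a `causal_map`.
#' @param label label of an existing concept (created if absent).
#' @return the updated map.
#' @export
set_focal <- function(map, label) {
  map <- add_concept(map, label)
  map$focal <- norm_label(label)
  map
}

#' Convert a causal map to an igraph graph
#'
#' Vertices are normalized concept ids with a `label` attribute; edges carry
#' `polarity` (NA while conflicted), `n_pos`, `n_neg`.
#'
#' @param map a `causal_map`.
#' @return a directed [igraph::igraph] object.
#' @export
as_igraph <- function(map) {
  v <- data.frame(name = map$concepts$id, label = map$concepts$label,
                  stringsAsFactors = FALSE)
  e <- map$edges[, c("src", "dst", "polarity", "n_pos", "n_neg")]
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}

# structural identity used by tests and the merge invariants: same concept
# id set, same signed edge set, same provenance counts (origins ignored
# unless compare_origins).
map_identical <- function(a, b, compare_origins = FALSE) {
  if (!setequal(a$concepts$id, b$concepts$id)) return(FALSE)
  ka <- paste(a$edges$src, a$edges$dst, sep = "\r")
  kb <- paste(b$edges$src, b$edges$dst, sep = "\r")
  if (!setequal(ka, kb)) return(FALSE)
  i <- match(ka, kb)
  if (!identical(a$edges$polarity, b$edges$polarity[i])) return(FALSE)
  if (!identical(a$edges$n_pos, b$edges$n_pos[i])) return(FALSE)
  if (!identical(a$edges$n_neg, b$edges$n_neg[i])) return(FALSE)
  if (compare_origins) {
    for (k in seq_along(ka)) {
      pa <- a$edges$provenance[[k]]; pb <- b$edges$provenance[[i[k]]]
      oa <- sort(paste0(pa$origin, ":", pa$sign))
      ob <- sort(paste0(pb$origin, ":", pb$sign))
      if (!identical(oa, ob)) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.causal_map <- function(x, ...) {
  cat(sprintf("<causal_map '%s'> %d concepts, %d edges", x$map_id,
              n_concepts(x), n_edges(x)))
  if (!is.na(x$focal)) {
    cat(sprintf(", focal: %s",
                x$concepts$label[match(x$focal, x$concepts$id)]))
  }
  nc <- sum(x$edges$conflicted)
  if (nc > 0) cat(sprintf(" (%d sign-conflicted)", nc))
  cat("\n")
  invisible(x)
}
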