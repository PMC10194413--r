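# Synthetic subject-matter-expert maps and panels. The generator emulates
# the shape of interview-elicited causal maps, not their content: a
# two-phase growth process first builds a star of proximal causes and
# consequences around the focal problem, then elaborates distal chains,
# cross-links between levels, and back-edges that close feedback loops.
# Panels draw concepts from a shared canonical pool and inject per-expert
# lexical variants, with the ground truth (pooled graph + thesaurus) kept
# for oracle comparisons, so merge, simplify, and metrics are testable
# without any interview data.

#' Parameters of the synthetic map generator
#'
#' Defaults are calibrated to the structure of real elicited maps: about
#' 85 causal links per interview with roughly 15 of them concentrated on
#' the single most connected concept, diameters around 8, feedback loops
#' present, a panel of 15 experts, and terms that collide across experts
#' appearing under ~4 linguistic variants.
#'
#' @param n_concept_pool size of the shared canonical vocabulary panels
#'   draw from.
#' @param n_smes number of synthetic experts in a panel.
#' @param edges_per_map exact number of causal links per map.
#' @param max_degree_target expected degree of the busiest concept (the
#'   focal problem's star); per-map max degree varies by +-2 around it.
#' @param target_diameter directed diameter the growth process aims for
#'   (upstream and downstream chain depth caps are derived from it).
#' @param p_negative probability that an edge is a decrease (-1).
#' @param p_backedge probability that a growth step closes a loop by
#'   linking a downstream concept back to an upstream one; any positive
#'   value guarantees at least one loop per map.
#' @param alias_rate probability that a concept appears in a given map
#'   under a map-specific lexical variant rather than its canonical name.
#' @param variants_per_aliased_term mean number of distinct variant forms
#'   available per aliased term (drawn per term, clipped to 2..6).
#' @param conflict_rate probability that an expert asserts the opposite of
#'   the panel's latent sign for an edge; 0 (default) guarantees
#'   conflict-free panels so aggregation can be checked exactly.
#' @param seed integer seed; the same seed reproduces a byte-identical
#'   map or panel.
#' @return a list of class `generator_params`.
#' @export
generator_params <- function(n_concept_pool = 300L, n_smes = 15L,
                             edges_per_map = 85L, max_degree_target = 15L,
                             target_diameter = 8L, p_negative = 0.25,
                             p_backedge = 0.15, alias_rate = 0.3,
                             variants_per_aliased_term = 4,
                             conflict_rate = 0, seed = NULL) {
  p <- list(n_concept_pool = as.integer(n_concept_pool),
            n_smes = as.integer(n_smes),
            edges_per_map = as.integer(edges_per_map),
            max_degree_target = as.integer(max_degree_target),
            target_diameter = as.integer(target_diameter),
            p_negative = p_negative, p_backedge = p_backedge,
            alias_rate = alias_rate,
            variants_per_aliased_term = variants_per_aliased_term,
            conflict_rate = conflict_rate, seed = seed)
  for (nm in c("p_negative", "p_backedge", "alias_rate", "conflict_rate"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  if (p$n_smes < 1L) stop("n_smes must be >= 1")
  # floor below which the star plus both chain directions cannot be built
  # (and a forced back-edge would have nowhere to go)
  if (p$edges_per_map < p$max_degree_target + 5L)
    stop("edges_per_map must be at least max_degree_target + 5")
  if (p$n_concept_pool <= p$edges_per_map)
    stop("concept pool too small: a map of ", p$edges_per_map,
         " edges may need up to that many distinct concepts")
  if (p$target_diameter < 4L) stop("target_diameter must be >= 4")
  structure(p, class = "generator_params")
}

# deterministic canonical vocabulary: qualifier x core-concept grid,
# shuffled with the caller's RNG
.concept_pool <- function(n) {
  qualifiers <- c("chronic", "acute", "perceived", "parental", "family",
                  "peer", "community", "school", "economic", "social",
                  "emotional", "physical", "untreated", "childhood",
                  "adolescent", "neighborhood", "household", "structural",
                  "interpersonal", "cultural", "financial", "early",
                  "persistent", "severe")
  cores <- c("stress", "trauma", "abuse", "neglect", "isolation", "support",
             "conflict", "instability", "poverty", "violence", "depression",
             "anxiety", "stigma", "bullying", "connectedness", "resilience",
             "substance use", "housing insecurity", "food insecurity",
             "hopelessness", "impulsivity", "care access", "coping skills",
             "self-esteem", "discrimination")
  grid <- as.vector(outer(qualifiers, cores, paste))
  if (n > length(grid)) stop("concept pool capped at ", length(grid),
                             " canonical terms")
  sample(grid, n)
}

# deterministic lexical transforms; variant k of a canonical label
.variant_form <- function(label, k) {
  w <- strsplit(label, " ", fixed = TRUE)[[1L]]
  switch(((k - 1L) %% 6L) + 1L,
    if (length(w) > 1L)
      paste0(paste(w[-1L], collapse = " "), " (", w[1L], ")")
    else paste0(label, " (general)"),
    paste0("level of ", label),
    paste0(label, " among youth"),
    paste0("exposure to ", label),
    paste0("high ", label),
    if (length(w) > 1L) paste(rev(w), collapse = ", ")
    else paste0(label, " problems"))
}

# grow one map's canonical assertion table (src, dst, sign). Uses the
# current RNG stream. `registry` (an environment), when given, fixes one
# latent sign per canonical ordered pair so panels agree across experts.
.grow_sme_edges <- function(params, focal, pool, registry = NULL) {
  up_cap <- max(2L, floor(params$target_diameter / 2))
  down_cap <- max(2L, ceiling(params$target_diameter / 2))
  deg_cap <- max(6L, ceiling(params$max_degree_target / 2))
  avail <- setdiff(pool, focal)
  avail <- sample(avail, length(avail))
  next_label <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > length(avail)) stop("concept pool exhausted during growth")
      avail[i]
    }
  })
  k_star <- params$max_degree_target + sample(-2:2, 1L)
  k_star <- min(k_star, params$edges_per_map - 4L)
  n_causes <- min(max(rbinom(1L, k_star, 0.5), 2L), k_star - 2L)

  draw_sign <- function(src, dst) {
    if (is.null(registry)) {
      s <- if (runif(1) < params$p_negative) -1L else 1L
      return(s)
    }
    key <- paste0(norm_label(src), "\r", norm_label(dst))
    if (is.null(registry[[key]]))
      registry[[key]] <- if (runif(1) < params$p_negative) -1L else 1L
    s <- registry[[key]]
    if (params$conflict_rate > 0 && runif(1) < params$conflict_rate) s <- -s
    s
  }

  nodes <- focal; level <- 0L; deg <- 0L
  src <- character(); dst <- character(); sgn <- integer()
  has_edge <- new.env(hash = TRUE)
  push <- function(a, b) {
    src <<- c(src, a); dst <<- c(dst, b)
    sgn <<- c(sgn, draw_sign(a, b))
    assign(paste0(a, "\r", b), TRUE, envir = has_edge)
    ia <- match(a, nodes); ib <- match(b, nodes)
    deg[ia] <<- deg[ia] + 1L; deg[ib] <<- deg[ib] + 1L
  }
  grow_node <- function(lvl) {
    lab <- next_label()
    nodes <<- c(nodes, lab); level <<- c(level, lvl); deg <<- c(deg, 0L)
    lab
  }
  exists_edge <- function(a, b)
    !is.null(get0(paste0(a, "\r", b), envir = has_edge))

  # phase 1: proximal star around the focal problem
  for (i in seq_len(n_causes)) push(grow_node(-1L), focal)
  for (i in seq_len(k_star - n_causes)) push(focal, grow_node(1L))

  n_back <- 0L
  m_target <- params$edges_per_map
  while (length(src) < m_target) {
    force_back <- params$p_backedge > 0 && n_back == 0L &&
      length(src) == m_target - 1L
    r <- runif(1)
    op <- if (force_back) "back"
          else if (r < params$p_backedge) "back"
          else if (r < params$p_backedge + 0.12) "cross"
          else "extend"
    done <- FALSE
    if (op == "back") {
      down <- which(level > 0L & deg < deg_cap)
      up <- which(level < 0L & deg < deg_cap)
      if (length(down) > 0L && length(up) > 0L) {
        pairs <- expand.grid(d = down, u = up)
        pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
        for (k in seq_len(nrow(pairs))) {
          a <- nodes[pairs$d[k]]; b <- nodes[pairs$u[k]]
          if (!exists_edge(a, b)) {
            push(a, b); n_back <- n_back + 1L; done <- TRUE; break
          }
        }
      }
    } else if (op == "cross") {
      for (try in 1:8) {
        cand <- which(nodes != focal & deg < deg_cap)
        if (length(cand) < 2L) break
        i <- sample(cand, 1L)
        step <- sample(1:2, 1L, prob = c(0.8, 0.2))
        j <- which(nodes != focal & level == level[i] + step & deg < deg_cap)
        j <- setdiff(j, i)
        if (length(j) == 0L) next
        j <- if (length(j) == 1L) j else sample(j, 1L)
        if (!exists_edge(nodes[i], nodes[j])) {
          push(nodes[i], nodes[j]); done <- TRUE; break
        }
      }
    }
    if (op == "extend" || !done) {
      elig <- which(nodes != focal &
                    ((level < 0L & level > -up_cap) |
                     (level > 0L & level < down_cap)) & deg < deg_cap)
      if (length(elig) == 0L)  # all chains at depth cap: attach anywhere legal
        elig <- which(nodes != focal & deg < deg_cap &
                      abs(level) < max(up_cap, down_cap) + 2L)
      i <- if (length(elig) == 1L) elig else sample(elig, 1L)
      if (level[i] < 0L) push(grow_node(level[i] - 1L), nodes[i])
      else push(nodes[i], grow_node(level[i] + 1L))
    }
  }
  data.frame(src = src, dst = dst, sign = sgn, stringsAsFactors = FALSE)
}

#' Generate one synthetic expert map
#'
#' Grows a weakly connected signed map around a focal problem concept with
#' the two-phase process described in [generator_params()]: exact edge
#' count, focal star near the target maximum degree, chain depths derived
#' from the target diameter, and at least one feedback loop whenever
#' `p_backedge > 0`. With `p_backedge = 0` every edge points strictly
#' forward through the cause -> focal -> consequence levels, so the map is
#' acyclic.
#'
#' @param params a [generator_params()] object; `params$seed`, if set,
#'   seeds the RNG (otherwise the current RNG stream is used).
#' @param focal label of the focal problem concept.
#' @param map_id map identifier.
#' @return a `causal_map`.
#' @export
generate_sme_map <- function(params = generator_params(),
                             focal = "suicide ideation", map_id = "sme01") {
  stopifnot(inherits(params, "generator_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  pool <- .concept_pool(params$n_concept_pool)
  edges <- .grow_sme_edges(params, .squish(focal), pool)
  edges$origin <- map_id
  .bulk_map(edges, map_id = map_id, focal = focal)
}

#' Generate a synthetic panel of expert maps with ground truth
#'
#' Draws `n_smes` maps around one shared focal problem from a common
#' canonical concept pool. Each canonical ordered pair carries one latent
#' sign shared by all experts (so the default panel is conflict-free;
#' `conflict_rate` flips individual assertions). Concepts are then given
#' map-specific lexical variants at `alias_rate`; every variant string
#' used is recorded in the ground-truth thesaurus. The focal term itself
#' is never aliased (the interviewer fixes its wording).
#'
#' @param params a [generator_params()] object; `params$seed`, if set,
#'   seeds the RNG.
#' @param focal label of the shared focal problem concept.
#' @return a list with `maps` (list of `causal_map`) and `truth`: the
#'   `pooled_map` over canonical labels (provenance = which experts
#'   asserted each edge), `true_thesaurus`, and `per_map_membership`
#'   (canonical src/dst/sign data.frame per expert).
#' @export
generate_panel <- function(params = generator_params(),
                           focal = "suicide ideation") {
  stopifnot(inherits(params, "generator_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  focal <- .squish(focal)
  pool <- .concept_pool(params$n_concept_pool)
  registry <- new.env(hash = TRUE)
  n_variants <- pmin(6L, pmax(2L, stats::rpois(params$n_concept_pool,
                                               params$variants_per_aliased_term)))
  names(n_variants) <- pool
  maps <- vector("list", params$n_smes)
  membership <- vector("list", params$n_smes)
  th_var <- character(); th_can <- character()
  for (i in seq_len(params$n_smes)) {
    id <- sprintf("sme%02d", i)
    edges <- .grow_sme_edges(params, focal, pool, registry)
    membership[[i]] <- edges
    # per-map surface forms: one consistent rendering per concept
    used <- setdiff(unique(c(edges$src, edges$dst)), focal)
    aliased <- used[stats::runif(length(used)) < params$alias_rate]
    surface <- stats::setNames(used, used)
    for (lab in aliased) {
      v <- .variant_form(lab, sample.int(n_variants[[lab]], 1L))
      surface[[lab]] <- v
      th_var <- c(th_var, v); th_can <- c(th_can, lab)
    }
    surface[[focal]] <- focal
    se <- data.frame(src = unname(surface[edges$src]),
                     dst = unname(surface[edges$dst]),
                     sign = edges$sign, origin = id,
                     stringsAsFactors = FALSE)
    maps[[i]] <- .bulk_map(se, map_id = id, focal = focal)
  }
  pooled_edges <- do.call(rbind, lapply(seq_along(membership), function(i) {
    e <- membership[[i]]
    e$origin <- sprintf("sme%02d", i)
    e
  }))
  pooled <- .bulk_map(pooled_edges, map_id = "pooled", focal = focal)
  keep <- !duplicated(norm_label(th_var))
  truth <- list(pooled_map = pooled,
                true_thesaurus = thesaurus(th_var[keep], th_can[keep]),
                per_map_membership = membership)
  list(maps = maps, truth = truth)
}
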