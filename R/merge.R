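# Canonicalization and aggregation: resolve each concept label through the
# thesaurus, collapse concepts that become identical, and union a panel of
# individual expert maps into one combined map, keeping per-expert
# provenance on every edge. Language varies across interviewees, so this
# stage is where "structural racism" and "racial injustice" become one
# "racism" node.

#' Canonicalize a map's concept labels through a thesaurus
#'
#' Every concept label is replaced by its canonical form. Concepts that
#' collapse onto the same canonical term are united (alias sets merged,
#' protection kept if any member was protected); parallel edges created by
#' the collapse are united with their provenance concatenated and polarity
#' re-derived by majority; edges that become self-loops are dropped and
#' recorded. Canonicalization is idempotent.
#'
#' @param map a `causal_map`.
#' @param th a [thesaurus()] (chain-free by construction).
#' @return the canonicalized `causal_map`, with a `canonicalize_report`
#'   attribute: `n_relabeled` concepts and `collapsed_self_loops`
#'   (data.frame src/dst/canonical of dropped edges).
#' @export
canonicalize <- function(map, th) {
  stopifnot(inherits(map, "causal_map"), inherits(th, "thesaurus"))
  old_lab <- map$concepts$label
  new_lab <- th_lookup(th, old_lab)
  new_id <- norm_label(new_lab)
  relabeled <- new_id != map$concepts$id
  trans <- stats::setNames(new_lab, map$concepts$id)

  # expand every provenance assertion under the new labels
  src <- character(); dst <- character(); s <- integer(); o <- character()
  drop_src <- character(); drop_dst <- character(); drop_can <- character()
  lab_of <- stats::setNames(old_lab, map$concepts$id)
  for (k in seq_len(n_edges(map))) {
    a <- trans[[map$edges$src[k]]]; b <- trans[[map$edges$dst[k]]]
    if (identical(norm_label(a), norm_label(b))) {
      drop_src <- c(drop_src, lab_of[[map$edges$src[k]]])
      drop_dst <- c(drop_dst, lab_of[[map$edges$dst[k]]])
      drop_can <- c(drop_can, a)
      next
    }
    p <- map$edges$provenance[[k]]
    src <- c(src, rep(a, nrow(p))); dst <- c(dst, rep(b, nrow(p)))
    s <- c(s, p$sign); o <- c(o, p$origin)
  }
  out <- .bulk_map(data.frame(src = src, dst = dst, sign = s, origin = o,
                              stringsAsFactors = FALSE),
                   map_id = map$map_id, warn_self_loops = FALSE)
  # concept roster: keep isolates, merge aliases and protection per group
  for (g in split(seq_len(nrow(map$concepts)), new_id)) {
    can <- new_lab[g[1L]]
    out <- add_concept(out, can, protected = any(map$concepts$protected[g]))
    i <- match(norm_label(can), out$concepts$id)
    extra <- setdiff(unique(c(old_lab[g], unlist(map$concepts$aliases[g]))),
                     out$concepts$label[i])
    out$concepts$aliases[[i]] <-
      sort(unique(c(out$concepts$aliases[[i]], extra)))
  }
  if (!is.na(map$focal)) out$focal <- norm_label(trans[[map$focal]])
  attr(out, "canonicalize_report") <- list(
    n_relabeled = sum(relabeled),
    collapsed_self_loops = data.frame(src = drop_src, dst = drop_dst,
                                      canonical = drop_can,
                                      stringsAsFactors = FALSE))
  out
}

#' Aggregate a panel of individual maps into one combined map
#'
#' Each map is canonicalized through the thesaurus, then concepts and
#' signed edges are unioned. Every edge of the combined map carries the
#' full provenance multiset of (map id, sign) assertions; polarity is the
#' majority sign, with exact ties flagged as conflicted. Aggregation is
#' order-invariant and `aggregate_maps(list(m))` equals
#' `canonicalize(m, th)`.
#'
#' @param maps a non-empty list of `causal_map` objects.
#' @param th a [thesaurus()]; `NULL` skips lexical resolution (labels are
#'   still whitespace/case-normalized).
#' @param map_id id for the combined map.
#' @return a list with `map` (the combined `causal_map`) and `report`
#'   (class `merge_report`): number of maps, canonical terms that absorbed
#'   2+ observed surface forms, the variants-per-term distribution, sign
#'   conflict count, and edges dropped as self-loops during collapse.
#' @export
aggregate_maps <- function(maps, th = NULL, map_id = "combined") {
  if (!is.list(maps) || length(maps) == 0L ||
      !all(vapply(maps, inherits, logical(1), "causal_map")))
    stop("maps must be a non-empty list of causal_map objects")
  if (is.null(th)) th <- thesaurus()
  canon <- lapply(maps, canonicalize, th = th)

  # observed surface forms per canonical term, across the whole panel
  obs <- do.call(rbind, lapply(maps, function(m) {
    data.frame(raw = m$concepts$label,
               canonical = norm_label(th_lookup(th, m$concepts$label)),
               stringsAsFactors = FALSE)
  }))
  obs <- unique(data.frame(raw = norm_label(obs$raw),
                           canonical = obs$canonical,
                           stringsAsFactors = FALSE))
  per_term <- table(obs$canonical)
  resolved <- per_term[per_term >= 2L]

  src <- character(); dst <- character(); s <- integer(); o <- character()
  for (m in canon) {
    lab <- stats::setNames(m$concepts$label, m$concepts$id)
    for (k in seq_len(n_edges(m))) {
      p <- m$edges$provenance[[k]]
      src <- c(src, rep(lab[[m$edges$src[k]]], nrow(p)))
      dst <- c(dst, rep(lab[[m$edges$dst[k]]], nrow(p)))
      s <- c(s, p$sign); o <- c(o, p$origin)
    }
  }
  out <- .bulk_map(data.frame(src = src, dst = dst, sign = s, origin = o,
                              stringsAsFactors = FALSE),
                   map_id = map_id, warn_self_loops = FALSE)
  # roster union (isolates, aliases, protection); first non-empty focal wins
  for (m in canon) {
    for (i in seq_len(nrow(m$concepts))) {
      out <- add_concept(out, m$concepts$label[i],
                         protected = m$concepts$protected[i])
      j <- match(m$concepts$id[i], out$concepts$id)
      out$concepts$aliases[[j]] <- sort(unique(c(
        out$concepts$aliases[[j]],
        setdiff(m$concepts$aliases[[i]], out$concepts$label[j]))))
    }
    if (is.na(out$focal) && !is.na(m$focal)) out$focal <- m$focal
  }
  loops <- do.call(rbind, lapply(canon, function(m)
    attr(m, "canonicalize_report")$collapsed_self_loops))
  report <- structure(list(
    n_maps = length(maps),
    n_terms_resolved = length(resolved),
    mean_variants = if (length(resolved)) mean(as.integer(resolved)) else NA_real_,
    variants_per_term = sort(per_term, decreasing = TRUE),
    n_sign_conflicts = sum(out$edges$n_pos > 0L & out$edges$n_neg > 0L),
    collapsed_self_loops = loops
  ), class = "merge_report")
  list(map = out, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf("<merge_report> %d map(s) aggregated\n", x$n_maps))
  cat(sprintf("  terms that appeared under 2+ names: %d", x$n_terms_resolved))
  if (!is.na(x$mean_variants))
    cat(sprintf(" (mean %.2f variants each)", x$mean_variants))
  cat("\n")
  cat(sprintf("  edges with both signs asserted: %d\n", x$n_sign_conflicts))
  cat(sprintf("  edges dropped as self-loops during collapse: %d\n",
              nrow(x$collapsed_self_loops)))
  invisible(x)
}

#' Suggest candidate alias pairs across a panel of maps
#'
#' Ranks pairs of concept labels from different maps by normalized string
#' similarity, for human triage when curating the thesaurus. Similarity is
#' the larger of a Levenshtein-based ratio on the normalized labels and
#' the same ratio after sorting each label's word tokens (so "family
#' financial stress" and "financial stress (family)" score 1). Never
#' merges anything itself: concept resolution is an expert judgement.
#'
#' @param maps list of at least two `causal_map` objects.
#' @param similarity_floor minimum similarity to report (default 0.8).
#' @return data.frame of `label1`, `label2`, `similarity`, sorted by
#'   decreasing similarity; zero rows if nothing clears the floor.
#' @export
suggest_aliases <- function(maps, similarity_floor = 0.8) {
  if (!is.list(maps) || length(maps) < 2L)
    stop("need at least two maps to compare vocabularies")
  vocab <- lapply(maps, function(m) unique(m$concepts$id))
  labels <- unique(unlist(lapply(maps, function(m) m$concepts$label)))
  ids <- norm_label(labels)
  first <- !duplicated(ids)
  labels <- labels[first]; ids <- ids[first]
  n <- length(ids)
  if (n < 2L) return(data.frame(label1 = character(), label2 = character(),
                                similarity = numeric()))
  # which maps mention each normalized label
  inmap <- lapply(ids, function(id)
    which(vapply(vocab, function(v) id %in% v, logical(1))))
  toksort <- vapply(ids, function(x)
    paste(sort(strsplit(gsub("[^a-z0-9 ]", " ", x), "\\s+")[[1]]),
          collapse = " "), character(1), USE.NAMES = FALSE)
  ratio <- function(x) {
    len <- pmax(nchar(x), 1L)
    1 - utils::adist(x) / outer(len, len, pmax)
  }
  sim <- pmax(ratio(ids), ratio(toksort))
  cand <- which(upper.tri(sim) & sim >= similarity_floor, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    # cross-map only: drop pairs whose two labels occur solely in one and
    # the same map (nothing to reconcile across interviewees there)
    keep <- vapply(seq_len(nrow(cand)), function(k) {
      a <- inmap[[cand[k, 1L]]]; b <- inmap[[cand[k, 2L]]]
      !(length(a) == 1L && identical(a, b))
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0L)
    return(data.frame(label1 = character(), label2 = character(),
                      similarity = numeric()))
  res <- data.frame(label1 = labels[cand[, 1L]], label2 = labels[cand[, 2L]],
                    similarity = sim[cand], stringsAsFactors = FALSE)
  res[order(-res$similarity, res$label1, res$label2, method = "radix"), ,
      drop = FALSE]
}
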