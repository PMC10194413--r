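# Simplification of a combined map so all parts sit at a comparable level
# of granularity: (i) extract source and receiver concepts for expert
# review and prune the approved ones; (ii) contract approved pass-through
# concepts (in-degree 1, out-degree 1), replacing A -> B -> C by A -> C
# with the product of the two edge signs, so the net direction of
# influence along every surviving path is preserved. Which endpoints
# matter is an expert judgement, so both steps run plan -> approve ->
# execute; nothing is removed without an explicit list.

#' Propose a simplification plan
#'
#' Lists every source and receiver concept for endpoint review, and every
#' *skippable* intermediate: a transmitter with in-degree 1 and out-degree
#' 1 (excluding protected and focal concepts), eligible for sign-preserving
#' contraction. Approval lists start empty.
#'
#' @param map a `causal_map`.
#' @return an object of class `simplification_plan`: lists
#'   `endpoints_for_review` (`$sources`, `$receivers`, protected members
#'   flagged in `$protected`), `skippable`, and empty `to_remove` /
#'   `to_contract`.
#' @export
propose_plan <- function(map) {
  stopifnot(inherits(map, "causal_map"))
  roles <- classify_nodes(map)
  ind <- table(factor(map$edges$dst, levels = map$concepts$id))
  outd <- table(factor(map$edges$src, levels = map$concepts$id))
  excl <- map$concepts$protected | map$concepts$id %in% map$focal
  skip <- map$concepts$label[ind == 1L & outd == 1L & !excl]
  srt <- function(x) x[order(norm_label(x), method = "radix")]
  structure(list(
    endpoints_for_review = list(
      sources = srt(names(roles)[roles == "source"]),
      receivers = srt(names(roles)[roles == "receiver"]),
      protected = srt(intersect(names(roles)[roles %in% c("source", "receiver")],
                                map$concepts$label[excl]))),
    skippable = srt(skip),
    to_remove = character(),
    to_contract = character()
  ), class = "simplification_plan")
}

#' @export
print.simplification_plan <- function(x, ...) {
  cat(sprintf("<simplification_plan> %d source(s), %d receiver(s) for review; %d skippable intermediate(s)\n",
              length(x$endpoints_for_review$sources),
              length(x$endpoints_for_review$receivers),
              length(x$skippable)))
  cat(sprintf("  approved: %d to remove, %d to contract\n",
              length(x$to_remove), length(x$to_contract)))
  invisible(x)
}

#' Prune approved endpoint concepts
#'
#' Removes the listed source/receiver concepts and their incident edges.
#' Refuses transmitters, isolated concepts, and protected or focal
#' concepts, naming the offender. With `iterative = TRUE` the newly
#' exposed sources/receivers are reported (in the `newly_exposed`
#' attribute) for the next round of review — never auto-removed, since the
#' decision to drop an endpoint belongs to the experts.
#'
#' @param map a `causal_map`.
#' @param to_remove labels of currently-source-or-receiver concepts.
#' @param iterative report newly exposed endpoints after removal.
#' @return the pruned `causal_map`.
#' @export
prune_endpoints <- function(map, to_remove, iterative = FALSE) {
  stopifnot(inherits(map, "causal_map"))
  if (length(to_remove) == 0L) return(map)
  ids <- norm_label(to_remove)
  miss <- is.na(match(ids, map$concepts$id))
  if (any(miss)) stop("unknown concept(s): ",
                      paste(to_remove[miss], collapse = ", "))
  roles <- classify_nodes(map)
  names(roles) <- map$concepts$id
  bad <- ids[!roles[ids] %in% c("source", "receiver")]
  if (length(bad) > 0L)
    stop("not a source or receiver, cannot prune: ",
         paste(bad, collapse = ", "))
  prot <- ids[map$concepts$protected[match(ids, map$concepts$id)] |
              ids %in% map$focal]
  if (length(prot) > 0L)
    stop("protected or focal concept(s) cannot be pruned: ",
         paste(prot, collapse = ", "))
  before <- if (iterative) classify_nodes(map) else NULL
  keep_c <- !(map$concepts$id %in% ids)
  keep_e <- !(map$edges$src %in% ids) & !(map$edges$dst %in% ids)
  map$concepts <- map$concepts[keep_c, , drop = FALSE]
  map$edges <- map$edges[keep_e, , drop = FALSE]
  if (iterative) {
    after <- classify_nodes(map)
    exposed <- names(after)[after %in% c("source", "receiver") &
                            !(before[names(after)] %in%
                              c("source", "receiver"))]
    attr(map, "newly_exposed") <- exposed[order(norm_label(exposed),
                                                method = "radix")]
  }
  map
}

#' Contract approved pass-through concepts, preserving path signs
#'
#' For each approved concept B with single incident edges A -> B (sign s1)
#' and B -> C (sign s2): B is removed and A -> C added with sign s1 * s2 —
#' two decreases chain into a net increase — and the union of both edges'
#' provenance. Chains of several approved concepts contract transitively
#' with the full sign product. Refusals (reported, never fatal):
#' * a concept whose in/out-degree is no longer exactly 1 at execution
#'   time (e.g. after an earlier contraction) is skipped;
#' * either incident edge sign-conflicted: skipped (no defined product);
#' * A equals C: contraction would create a self-loop, so B is retained —
#'   this keeps elicited 2-node feedback loops intact.
#' If A -> C already exists, provenance is merged; an existing polarity
#' that disagrees with the path product marks the edge conflicted rather
#' than silently overwriting either claim.
#'
#' @param map a `causal_map`.
#' @param to_contract labels of approved skippable intermediates.
#' @return the contracted `causal_map`, with a `contract_report` attribute
#'   (data.frame label/status: contracted, skipped-degree,
#'   skipped-conflicted, skipped-self-loop, unknown).
#' @export
contract_chains <- function(map, to_contract) {
  stopifnot(inherits(map, "causal_map"))
  want <- unique(norm_label(to_contract))
  status <- stats::setNames(rep("pending", length(want)), want)
  status[!(want %in% map$concepts$id)] <- "unknown"
  prot <- map$concepts$id[map$concepts$protected]
  status[want %in% c(prot, map$focal)] <- "skipped-protected"
  repeat {
    progress <- FALSE
    for (b in want[status[want] == "pending"]) {
      i_in <- which(map$edges$dst == b)
      i_out <- which(map$edges$src == b)
      if (length(i_in) != 1L || length(i_out) != 1L) next  # retry next pass
      if (map$edges$conflicted[i_in] || map$edges$conflicted[i_out]) {
        status[b] <- "skipped-conflicted"; next
      }
      a <- map$edges$src[i_in]; c_ <- map$edges$dst[i_out]
      if (identical(a, c_)) { status[b] <- "skipped-self-loop"; next }
      s <- map$edges$polarity[i_in] * map$edges$polarity[i_out]
      prov <- rbind(map$edges$provenance[[i_in]],
                    map$edges$provenance[[i_out]])
      j <- which(map$edges$src == a & map$edges$dst == c_)
      if (length(j) == 1L) {
        merged <- rbind(map$edges$provenance[[j]], prov)
        map$edges$provenance[[j]] <- merged
        map$edges$n_pos[j] <- sum(merged$sign == 1L)
        map$edges$n_neg[j] <- sum(merged$sign == -1L)
        if (map$edges$conflicted[j] ||
            is.na(map$edges$polarity[j]) || map$edges$polarity[j] != s) {
          map$edges$polarity[j] <- NA_integer_
          map$edges$conflicted[j] <- TRUE
        }
        map$edges <- map$edges[-c(i_in, i_out), , drop = FALSE]
      } else {
        row <- data.frame(src = a, dst = c_, polarity = s, conflicted = FALSE,
                          n_pos = sum(prov$sign == 1L),
                          n_neg = sum(prov$sign == -1L),
                          provenance = I(list(prov)), stringsAsFactors = FALSE)
        map$edges <- rbind(map$edges[-c(i_in, i_out), , drop = FALSE], row)
      }
      map$concepts <- map$concepts[map$concepts$id != b, , drop = FALSE]
      status[b] <- "contracted"
      progress <- TRUE
    }
    if (!progress) break
  }
  status[status == "pending"] <- "skipped-degree"
  attr(map, "contract_report") <- data.frame(
    label = names(status), status = unname(status), stringsAsFactors = FALSE)
  map
}
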