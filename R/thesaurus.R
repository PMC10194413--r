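# Thesaurus: curated mapping from linguistic variants of a concept
# ("structural racism", "racial injustice") to one canonical term
# ("racism"). Matching is case-insensitive and whitespace-normalized;
# redirect chains (X -> Y while Y -> Z) are forbidden so that one lookup
# always lands on a canonical term.

#' Build a thesaurus from variant/canonical pairs
#'
#' @param variants character vector of variant labels.
#' @param canonicals character vector of the canonical label each variant
#'   resolves to.
#' @param flatten if `TRUE`, redirect chains are flattened transitively
#'   (X->Y, Y->Z becomes X->Z) with a warning; if `FALSE` (default) a chain
#'   is an error. Cyclic redirects are always an error.
#' @return an object of class `thesaurus`.
#' @examples
#' th <- thesaurus(c("structural racism", "racial injustice"),
#'                 c("racism", "racism"))
#' th_lookup(th, c("Structural  Racism", "racism", "poverty"))
#' @export
thesaurus <- function(variants = character(), canonicals = character(),
                      flatten = FALSE) {
  stopifnot(length(variants) == length(canonicals))
  v <- norm_label(variants)
  can_disp <- .squish(canonicals)
  # identity rows are harmless but redundant
  keep <- v != norm_label(can_disp)
  v <- v[keep]; can_disp <- can_disp[keep]
  if (anyDuplicated(v)) {
    dup <- v[duplicated(v)]
    bad <- unique(dup[vapply(dup, function(d)
      length(unique(norm_label(can_disp[v == d]))) > 1L, logical(1))])
    if (length(bad) > 0L)
      stop("variant(s) mapped to more than one canonical term: ",
           paste(bad, collapse = ", "))
    first <- !duplicated(v)
    v <- v[first]; can_disp <- can_disp[first]
  }
  entries <- stats::setNames(can_disp, v)
  chained <- norm_label(entries) %in% v
  if (any(chained)) {
    if (!flatten)
      stop("redirect chain(s) in thesaurus (canonical also appears as a ",
           "variant): ", paste(unique(norm_label(entries[chained])),
                               collapse = ", "),
           "; re-read with flatten = TRUE to resolve transitively")
    warning(sprintf("%d redirect chain(s) flattened transitively",
                    sum(chained)))
    for (k in seq_along(entries)) {
      seen <- names(entries)[k]
      while (norm_label(entries[k]) %in% v) {
        nxt <- entries[[match(norm_label(entries[k]), v)]]
        if (norm_label(nxt) %in% seen)
          stop("cyclic redirect in thesaurus involving '", seen[1L], "'")
        seen <- c(seen, norm_label(entries[k]))
        entries[k] <- nxt
      }
    }
  }
  structure(list(entries = entries), class = "thesaurus")
}

#' Resolve labels through a thesaurus
#'
#' Lookup is on the normalized form; a label with no entry (including any
#' canonical term itself) is returned unchanged apart from whitespace
#' squishing, so canonical terms are fixed points.
#'
#' @param th a `thesaurus`.
#' @param x character vector of labels.
#' @return character vector of canonical display labels.
#' @export
th_lookup <- function(th, x) {
  stopifnot(inherits(th, "thesaurus"))
  out <- .squish(x)
  i <- match(norm_label(x), names(th$entries))
  hit <- !is.na(i)
  out[hit] <- unname(th$entries[i[hit]])
  out
}

#' Number of entries in a thesaurus
#' @param x a `thesaurus`.
#' @param ... ignored.
#' @export
length.thesaurus <- function(x) length(x$entries)

#' @export
print.thesaurus <- function(x, ...) {
  cat(sprintf("<thesaurus> %d variant(s) -> %d canonical term(s)\n",
              length(x$entries), length(unique(norm_label(x$entries)))))
  invisible(x)
}

#' Summary statistics of a thesaurus
#'
#' Reports, over canonical terms that absorb at least `min_variants`
#' variants, how many such terms there are and the distribution of variants
#' per term. A term's variant count is the number of distinct variant keys
#' resolving to it.
#'
#' @param object a `thesaurus`.
#' @param min_variants minimum number of variants for a term to count as
#'   "resolved" (default 2, i.e. the term appeared under different names).
#' @param ... ignored.
#' @return a list with `n_terms_resolved`, `mean_variants`, and the full
#'   `variants_per_term` table (named integer vector).
#' @export
summary.thesaurus <- function(object, min_variants = 2L, ...) {
  per_term <- table(norm_label(object$entries))
  resolved <- per_term[per_term >= min_variants]
  list(n_terms_resolved = length(resolved),
       mean_variants = if (length(resolved)) mean(as.integer(resolved)) else NA_real_,
       variants_per_term = sort(per_term, decreasing = TRUE))
}
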