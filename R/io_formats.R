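# Readers and writers for the concrete file formats the pipeline touches:
# signed edge-list CSV, MentalModeler-style signed adjacency CSV, thesaurus
# CSV, and GraphML / JSON exports of a causal map.

#' Edge-list dialect description
#'
#' Controls how a signed edge list is parsed: the delimiter, whether a
#' header row is present, and which polarity tokens are accepted. Signed
#' numerics are always accepted and reduced to their sign (elicitation
#' yields polarity only, so any weight in an input file is collapsed to
#' +1/-1); a numeric 0 means "no edge" and the row is skipped with a
#' warning.
#'
#' @param delimiter field separator (default ",").
#' @param header does the file start with a header row?
#' @param polarity_vocabulary named integer vector mapping accepted tokens
#'   to signs.
#' @return a list of class `edgelist_dialect`.
#' @export
edgelist_dialect <- function(delimiter = ",", header = TRUE,
                             polarity_vocabulary = c(
                               "+" = 1L, "-" = -1L, "+1" = 1L, "-1" = -1L,
                               "1" = 1L, "increase" = 1L, "decrease" = -1L,
                               "positive" = 1L, "negative" = -1L)) {
  stopifnot(all(polarity_vocabulary %in% c(1L, -1L)))
  structure(list(delimiter = delimiter, header = isTRUE(header),
                 polarity_vocabulary = polarity_vocabulary),
            class = "edgelist_dialect")
}

# token -> sign under a dialect; returns +1/-1, 0 for "no edge", NA unknown
.parse_sign <- function(tok, dialect) {
  tok <- tolower(trimws(as.character(tok)))
  out <- rep(NA_integer_, length(tok))
  i <- match(tok, tolower(names(dialect$polarity_vocabulary)))
  out[!is.na(i)] <- unname(dialect$polarity_vocabulary[i[!is.na(i)]])
  left <- is.na(out)
  num <- suppressWarnings(as.numeric(tok[left]))
  out[left] <- ifelse(is.na(num), NA_integer_, as.integer(sign(num)))
  out
}

#' Read a causal map from a signed edge list
#'
#' Expects at least three columns: source, target, polarity. The canonical
#' on-disk dialect written by [write_map()] additionally carries provenance
#' counts (`n_pos`, `n_neg`); when those columns are present they take
#' precedence over the polarity token, so conflicted edges survive a
#' round trip. Self-loop rows and zero-weight rows are skipped with a
#' warning; unknown polarity tokens are a fatal error naming the line.
#'
#' @param path file to read.
#' @param dialect an [edgelist_dialect()].
#' @param map_id map identifier; defaults to the file name without
#'   extension.
#' @param focal optional focal concept label.
#' @return a `causal_map`; skipped rows are recorded in
#'   `attr(map, "issues")`.
#' @export
read_edgelist <- function(path, dialect = edgelist_dialect(),
                          map_id = sub("\\.[^.]*$", "", basename(path)),
                          focal = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, sep = dialect$delimiter, header = dialect$header,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character"),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    warning("empty edge list: ", path)
    return(causal_map(map_id = map_id, focal = focal))
  }
  if (ncol(df) < 3L) stop("edge list needs >= 3 columns (source, target, ",
                          "polarity): ", path)
  nm <- tolower(names(df))
  col <- function(cands, default) {
    i <- match(cands, nm); i <- i[!is.na(i)]
    if (length(i)) i[1L] else default
  }
  i_src <- col(c("source", "src", "from", "cause"), 1L)
  i_dst <- col(c("target", "dst", "to", "effect"), 2L)
  i_pol <- col(c("polarity", "sign", "weight"), 3L)
  i_np <- col("n_pos", NA_integer_); i_nn <- col("n_neg", NA_integer_)
  line0 <- if (dialect$header) 1L else 0L  # file line of row 0

  sgn <- .parse_sign(df[[i_pol]], dialect)
  has_counts <- !is.na(i_np) && !is.na(i_nn)
  if (has_counts) {
    np <- suppressWarnings(as.integer(df[[i_np]]))
    nn <- suppressWarnings(as.integer(df[[i_nn]]))
    has_counts_row <- !is.na(np) & !is.na(nn) & (np + nn) > 0L
  } else has_counts_row <- rep(FALSE, nrow(df))

  unknown <- is.na(sgn) & !has_counts_row
  if (any(unknown))
    stop("unknown polarity token(s) '",
         paste(unique(df[[i_pol]][unknown]), collapse = "', '"),
         "' at line(s) ", paste(which(unknown) + line0, collapse = ", "),
         " of ", path)

  issues <- data.frame(line = integer(), problem = character(),
                       stringsAsFactors = FALSE)
  zero <- !is.na(sgn) & sgn == 0L & !has_counts_row
  if (any(zero)) {
    warning(sprintf("%d zero-weight row(s) skipped (no edge) at line(s) %s",
                    sum(zero), paste(which(zero) + line0, collapse = ", ")))
    issues <- rbind(issues, data.frame(line = which(zero) + line0,
                                       problem = "zero weight"))
  }
  keep <- !zero
  self <- norm_label(df[[i_src]]) == norm_label(df[[i_dst]]) & keep
  if (any(self)) {
    warning(sprintf("self-loop row(s) skipped at line(s) %s (concept %s)",
                    paste(which(self) + line0, collapse = ", "),
                    paste(unique(.squish(df[[i_src]][self])), collapse = ", ")))
    issues <- rbind(issues, data.frame(line = which(self) + line0,
                                       problem = "self-loop"))
  }
  keep <- keep & !self

  # expand to one assertion per provenance count (counts dialect) or one
  # assertion per row (plain dialect)
  rows <- which(keep)
  src <- character(); dst <- character(); s <- integer()
  for (r in rows) {
    if (has_counts_row[r]) {
      k <- np[r] + nn[r]
      src <- c(src, rep(df[[i_src]][r], k))
      dst <- c(dst, rep(df[[i_dst]][r], k))
      s <- c(s, rep(c(1L, -1L), c(np[r], nn[r])))
    } else {
      src <- c(src, df[[i_src]][r]); dst <- c(dst, df[[i_dst]][r])
      s <- c(s, sgn[r])
    }
  }
  m <- .bulk_map(data.frame(src = src, dst = dst, sign = s, origin = map_id,
                            stringsAsFactors = FALSE),
                 map_id = map_id, focal = focal, warn_self_loops = FALSE)
  attr(m, "issues") <- issues
  m
}

#' Read a causal map from a signed adjacency matrix
#'
#' MentalModeler-style export: the first row and first column hold concept
#' labels, and cell (i, j) is the signed weight of the edge i -> j. Edges
#' are created exactly where cells are nonzero, with polarity the sign of
#' the cell. Nonzero diagonal cells (self-loops) are skipped with a
#' warning. A non-square matrix is a fatal parse error.
#'
#' @param path CSV file to read.
#' @param map_id map identifier; defaults to the file name.
#' @param focal optional focal concept label.
#' @return a `causal_map` (isolated concepts are kept).
#' @export
read_adjacency_matrix <- function(path,
                                  map_id = sub("\\.[^.]*$", "", basename(path)),
                                  focal = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (nrow(raw) < 2L || ncol(raw) < 2L)
    stop("adjacency matrix too small to parse: ", path)
  labels <- .squish(unlist(raw[1L, -1L], use.names = FALSE))
  row_labels <- .squish(raw[[1L]][-1L])
  if (length(labels) != length(row_labels))
    stop("non-square adjacency matrix in ", path, ": ", length(row_labels),
         " rows vs ", length(labels), " columns")
  if (anyDuplicated(norm_label(labels)))
    stop("duplicate concept labels after normalization in ", path)
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw[-1L, -1L])), nrow = length(row_labels)))
  if (anyNA(vals)) stop("non-numeric cell(s) in adjacency matrix ", path)
  m <- causal_map(map_id = map_id, focal = focal)
  for (lab in labels) m <- add_concept(m, lab)
  nz <- which(vals != 0, arr.ind = TRUE)
  diag_nz <- nz[nz[, 1L] == nz[, 2L], , drop = FALSE]
  if (nrow(diag_nz) > 0L)
    warning("nonzero diagonal cell(s) skipped (self-loop) for: ",
            paste(labels[diag_nz[, 1L]], collapse = ", "))
  nz <- nz[nz[, 1L] != nz[, 2L], , drop = FALSE]
  if (nrow(nz) > 0L) {
    a <- data.frame(src = row_labels[nz[, 1L]], dst = labels[nz[, 2L]],
                    sign = as.integer(sign(vals[nz])), origin = map_id,
                    stringsAsFactors = FALSE)
    mm <- .bulk_map(a, map_id = map_id, warn_self_loops = FALSE)
    # keep the full concept roster, including isolates
    for (lab in labels[!norm_label(labels) %in% mm$concepts$id])
      mm <- add_concept(mm, lab)
    mm$focal <- m$focal
    m <- mm
  }
  m
}

#' Read a thesaurus from a two-column CSV
#'
#' Columns are (variant, canonical). Redirect chains are fatal unless
#' `flatten = TRUE`, in which case they are flattened transitively with a
#' warning; a variant mapped to two different canonicals is always fatal.
#'
#' @param path CSV file; a header row named variant/canonical (in any
#'   order-insensitive casing) is detected and skipped.
#' @param flatten flatten redirect chains instead of failing.
#' @return a [thesaurus()].
#' @export
read_thesaurus <- function(path, flatten = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop("thesaurus needs two columns (variant, canonical)")
  if (nrow(df) > 0L &&
      all(tolower(.squish(unlist(df[1L, 1:2]))) %in%
          c("variant", "canonical", "from", "to", "alias", "term")))
    df <- df[-1L, , drop = FALSE]
  thesaurus(df[[1L]], df[[2L]], flatten = flatten)
}

#' Write a causal map to disk
#'
#' Output is bit-stable for a given map: concepts and edges are emitted in
#' normalized-label lexicographic (byte) order, so two writes of the same
#' map are byte-identical.
#'
#' Formats:
#' * `edgelist`: CSV `source,target,polarity,n_pos,n_neg` with polarity
#'   "+1"/"-1" ("0" while sign-conflicted; the counts disambiguate on
#'   re-read). Isolated concepts cannot be represented and trigger a
#'   warning.
#' * `graphml`: typed node attributes (label, protected) and edge
#'   attributes (polarity, conflicted, n_pos, n_neg).
#' * `json`: nodes + links arrays, links carrying the full provenance
#'   multiset; the only lossless format for per-origin provenance.
#'
#' @param map a `causal_map`.
#' @param path output file.
#' @param format one of "edgelist", "graphml", "json"; guessed from the
#'   file extension when omitted.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, format = c("auto", "edgelist", "graphml",
                                            "json")) {
  stopifnot(inherits(map, "causal_map"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(sub(".*\\.", "", path)),
                     csv = "edgelist", graphml = "graphml", xml = "graphml",
                     json = "json",
                     stop("cannot guess format from extension of ", path))
  }
  co <- order(map$concepts$id, method = "radix")
  eo <- order(map$edges$src, map$edges$dst, method = "radix")
  concepts <- map$concepts[co, , drop = FALSE]
  edges <- map$edges[eo, , drop = FALSE]
  lab <- stats::setNames(concepts$label, concepts$id)
  switch(format,
    edgelist = {
      iso <- !(concepts$id %in% c(edges$src, edges$dst))
      if (any(iso))
        warning("edge-list format cannot represent isolated concept(s): ",
                paste(concepts$label[iso], collapse = ", "))
      pol <- ifelse(is.na(edges$polarity), "0", sprintf("%+d", edges$polarity))
      lines <- c("source,target,polarity,n_pos,n_neg",
                 sprintf("%s,%s,%s,%d,%d",
                         .csv_quote(lab[edges$src]), .csv_quote(lab[edges$dst]),
                         pol, edges$n_pos, edges$n_neg))
      writeLines(lines, path)
    },
    graphml = .write_graphml(concepts, edges, map, path),
    json = {
      nodes <- lapply(seq_len(nrow(concepts)), function(i) list(
        id = concepts$id[i], label = concepts$label[i],
        protected = concepts$protected[i],
        aliases = as.list(concepts$aliases[[i]])))
      links <- lapply(seq_len(nrow(edges)), function(i) {
        p <- edges$provenance[[i]]
        p <- p[order(p$origin, p$sign, method = "radix"), , drop = FALSE]
        list(source = edges$src[i], target = edges$dst[i],
             polarity = if (is.na(edges$polarity[i])) NULL else
               edges$polarity[i],
             conflicted = edges$conflicted[i],
             n_pos = edges$n_pos[i], n_neg = edges$n_neg[i],
             provenance = lapply(seq_len(nrow(p)), function(k)
               list(origin = p$origin[k], sign = p$sign[k])))
      })
      obj <- list(map_id = map$map_id,
                  focal = if (is.na(map$focal)) NULL else map$focal,
                  nodes = nodes, links = links)
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA, null = "null"), path)
    })
  invisible(path)
}

.csv_quote <- function(x) {
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

.write_graphml <- function(concepts, edges, map, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydef <- function(id, dom, type) {
    k <- xml2::xml_add_child(doc, "key")
    xml2::xml_set_attrs(k, c(id = id, `for` = dom, attr.name = id,
                             attr.type = type))
  }
  keydef("label", "node", "string"); keydef("protected", "node", "boolean")
  keydef("polarity", "edge", "int"); keydef("conflicted", "edge", "boolean")
  keydef("n_pos", "edge", "int"); keydef("n_neg", "edge", "int")
  g <- xml2::xml_add_child(doc, "graph", id = map$map_id,
                           edgedefault = "directed")
  if (!is.na(map$focal)) xml2::xml_set_attr(g, "focal", map$focal)
  dat <- function(parent, key, value) {
    d <- xml2::xml_add_child(parent, "data", key = key)
    xml2::xml_set_text(d, as.character(value))
  }
  for (i in seq_len(nrow(concepts))) {
    nd <- xml2::xml_add_child(g, "node", id = concepts$id[i])
    dat(nd, "label", concepts$label[i])
    dat(nd, "protected", tolower(concepts$protected[i]))
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(g, "edge", source = edges$src[i],
                              target = edges$dst[i])
    if (!is.na(edges$polarity[i])) dat(ed, "polarity", edges$polarity[i])
    dat(ed, "conflicted", tolower(edges$conflicted[i]))
    dat(ed, "n_pos", edges$n_pos[i]); dat(ed, "n_neg", edges$n_neg[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a causal map written by [write_map()]
#'
#' @param path file to read.
#' @param format one of "edgelist", "graphml", "json"; guessed from the
#'   extension when omitted.
#' @param map_id override the stored map id.
#' @return a `causal_map`.
#' @export
read_map <- function(path, format = c("auto", "edgelist", "graphml", "json"),
                     map_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(sub(".*\\.", "", path)),
                     csv = "edgelist", graphml = "graphml", xml = "graphml",
                     json = "json",
                     stop("cannot guess format from extension of ", path))
  }
  m <- switch(format,
    edgelist = read_edgelist(path),
    graphml = .read_graphml(path),
    json = .read_json_map(path))
  if (!is.null(map_id)) m$map_id <- map_id
  m
}

.read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  g <- xml2::xml_find_first(doc, ".//graph")
  m <- causal_map(map_id = xml2::xml_attr(g, "id"))
  getdata <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf("./data[@key='%s']", key))
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  for (nd in xml2::xml_find_all(g, "./node")) {
    m <- add_concept(m, getdata(nd, "label"),
                     protected = identical(getdata(nd, "protected"), "true"))
  }
  labs <- stats::setNames(m$concepts$label, m$concepts$id)
  src <- character(); dst <- character(); s <- integer()
  for (ed in xml2::xml_find_all(g, "./edge")) {
    a <- xml2::xml_attr(ed, "source"); b <- xml2::xml_attr(ed, "target")
    np <- as.integer(getdata(ed, "n_pos")); nn <- as.integer(getdata(ed, "n_neg"))
    if (is.na(np)) np <- 0L
    if (is.na(nn)) nn <- 0L
    if (np + nn == 0L) {
      np <- as.integer(identical(getdata(ed, "polarity"), "1"))
      nn <- 1L - np
    }
    src <- c(src, rep(labs[[a]], np + nn))
    dst <- c(dst, rep(labs[[b]], np + nn))
    s <- c(s, rep(c(1L, -1L), c(np, nn)))
  }
  mm <- .bulk_map(data.frame(src = src, dst = dst, sign = s,
                             origin = m$map_id, stringsAsFactors = FALSE),
                  map_id = m$map_id)
  # restore roster (isolates, protection) from the node list
  for (i in seq_len(nrow(m$concepts)))
    mm <- add_concept(mm, m$concepts$label[i],
                      protected = m$concepts$protected[i])
  focal <- xml2::xml_attr(g, "focal")
  if (!is.na(focal)) mm$focal <- focal
  mm
}

.read_json_map <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  m <- causal_map(map_id = obj$map_id)
  for (nd in obj$nodes) {
    m <- add_concept(m, nd$label, protected = isTRUE(nd$protected))
    i <- match(norm_label(nd$label), m$concepts$id)
    m$concepts$aliases[[i]] <-
      sort(unique(c(m$concepts$aliases[[i]], unlist(nd$aliases))))
  }
  labs <- stats::setNames(m$concepts$label, m$concepts$id)
  src <- character(); dst <- character(); s <- integer(); o <- character()
  for (lk in obj$links) {
    for (p in lk$provenance) {
      src <- c(src, labs[[lk$source]]); dst <- c(dst, labs[[lk$target]])
      s <- c(s, as.integer(p$sign)); o <- c(o, p$origin)
    }
  }
  mm <- .bulk_map(data.frame(src = src, dst = dst, sign = s, origin = o,
                             stringsAsFactors = FALSE), map_id = m$map_id)
  for (i in seq_len(nrow(m$concepts))) {
    mm <- add_concept(mm, m$concepts$label[i],
                      protected = m$concepts$protected[i])
    j <- match(m$concepts$id[i], mm$concepts$id)
    mm$concepts$aliases[[j]] <-
      sort(unique(c(mm$concepts$aliases[[j]], m$concepts$aliases[[i]])))
  }
  if (!is.null(obj$focal)) mm$focal <- obj$focal
  mm
}
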