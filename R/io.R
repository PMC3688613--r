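# Plain-text interchange formats: edge-list CSV, Pajek .net, genotype /
# coordinate / pedigree / relatedness / assignment CSVs, fit JSON.

#' Read an undirected network from edge-list CSV or Pajek .net
#'
#' Duplicate edges are collapsed and self-loops dropped, each with a
#' warning. Pajek files use 1-based vertex numbering with (possibly quoted)
#' labels; numbering is converted back to the labels.
#'
#' @param path file path.
#' @param format `"csv"` (two id columns) or `"pajek"`; `NULL` infers from
#'   the extension (`.net` = Pajek).
#' @return an undirected simple [igraph::graph].
#' @export
read_network <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.net$", path, ignore.case = TRUE)) "pajek" else "csv")
  format <- match.arg(format, c("csv", "pajek"))
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character")
    if (ncol(df) < 2) stop("edge-list CSV needs two id columns: ", path)
    edges <- df[, 1:2]
    iso <- character(0)
  } else {
    p <- parse_pajek_(path)
    edges <- p$edges
    iso <- p$isolated
  }
  if (nrow(edges) > 0) {
    self <- edges[, 1] == edges[, 2]
    if (any(self)) {
      warning(sum(self), " self-loop(s) dropped")
      edges <- edges[!self, , drop = FALSE]
    }
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
                 sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sum(dup), " duplicate edge(s) collapsed")
      edges <- edges[!dup, , drop = FALSE]
    }
  }
  g <- if (nrow(edges) == 0) igraph::make_empty_graph(0, directed = FALSE)
       else igraph::graph_from_data_frame(edges, directed = FALSE)
  if (length(iso) > 0)
    g <- igraph::add_vertices(g, length(iso), name = iso)
  g
}

parse_pajek_ <- function(path) {
  lines <- readLines(path)
  vh <- grep("^\\*vertices", lines, ignore.case = TRUE)
  if (length(vh) != 1)
    stop("malformed Pajek file (no *Vertices header): ", path)
  nv <- suppressWarnings(as.integer(sub("^\\S+\\s+", "", lines[vh])))
  if (is.na(nv)) stop("malformed *Vertices count at line ", vh)
  labs <- character(nv)
  for (i in seq_len(nv)) {
    ln <- lines[vh + i]
    m <- regmatches(ln, regexec('^\\s*(\\d+)\\s+"([^"]*)"', ln))[[1]]
    if (length(m) == 0)
      m <- regmatches(ln, regexec("^\\s*(\\d+)\\s+(\\S+)", ln))[[1]]
    if (length(m) == 0) stop("malformed vertex at line ", vh + i)
    labs[as.integer(m[2])] <- m[3]
  }
  eh <- grep("^\\*(edges|arcs)", lines, ignore.case = TRUE)
  if (length(eh) == 0) stop("malformed Pajek file (no *Edges): ", path)
  from <- integer(0); to <- integer(0)
  body <- if (eh[1] < length(lines)) (eh[1] + 1):length(lines) else integer(0)
  for (j in body) {
    ln <- trimws(lines[j])
    if (ln == "" || grepl("^\\*", ln)) next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 2) stop("malformed edge at line ", j)
    a <- as.integer(parts[1]); b <- as.integer(parts[2])
    if (is.na(a) || is.na(b) || a < 1 || b < 1 || a > nv || b > nv)
      stop("vertex number out of range at line ", j)
    from <- c(from, a); to <- c(to, b)
  }
  edges <- data.frame(from = labs[from], to = labs[to],
                      stringsAsFactors = FALSE)
  list(edges = edges, isolated = setdiff(labs, c(edges$from, edges$to)))
}

#' Write an undirected network to edge-list CSV or Pajek .net
#'
#' Round-trips through [read_network()]: the edge set (and for Pajek the
#' full vertex set) is preserved exactly. Pajek labels are always quoted.
#'
#' @param network an [igraph::graph].
#' @param path output path.
#' @param format `"csv"` or `"pajek"`; `NULL` infers from the extension.
#' @return the path, invisibly.
#' @export
write_network <- function(network, path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.net$", path, ignore.case = TRUE)) "pajek" else "csv")
  format <- match.arg(format, c("csv", "pajek"))
  ids <- igraph::V(network)$name %||% as.character(seq_len(igraph::vcount(network)))
  el <- igraph::as_edgelist(network, names = TRUE)
  if (format == "csv") {
    utils::write.csv(data.frame(from = el[, 1], to = el[, 2]),
                     path, row.names = FALSE, quote = TRUE)
  } else {
    idx <- stats::setNames(seq_along(ids), ids)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("*Vertices %d", length(ids)), con)
    writeLines(sprintf('%d "%s"', seq_along(ids), ids), con)
    writeLines("*Edges", con)
    if (nrow(el) > 0)
      writeLines(sprintf("%d %d", idx[el[, 1]], idx[el[, 2]]), con)
  }
  invisible(path)
}

#' Write / read a genotype table
#'
#' One row per individual, an `id` column, then two columns per locus
#' (`L01.1, L01.2, ...`); blank cells are missing data.
#' @param genotypes integer genotype matrix, rownames = ids.
#' @param path file path.
#' @return `write_genotypes()` the path invisibly; `read_genotypes()` an
#'   integer matrix with rownames.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- as.character(df$id)
  g
}

#' Write / read stand coordinates (`id, x, y, species`)
#' @param stand a `"stand"` object or a data frame `id, x, y, species`.
#' @param path file path.
#' @export
write_coordinates <- function(stand, path) {
  df <- if (inherits(stand, "stand")) stand$individuals else stand
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coordinates
#' @export
read_coordinates <- function(path) {
  utils::read.csv(path, colClasses = c(id = "character"))
}

#' Write / read a pedigree table (`offspring_id, mother_id, true_father_id`)
#' @param pedigree data frame.
#' @param path file path.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  utils::read.csv(path, colClasses = "character")
}

#' Write / read a relatedness matrix in long format (`id1, id2, r`)
#'
#' Only defined (non-missing) pairs are written. Reading reconstructs a
#' symmetric `"relmatrix"` object (per-pair locus counts are not stored in
#' this exchange format and read back as `NA`).
#' @param relmatrix an [estimate_relatedness()] object.
#' @param path file path.
#' @export
write_relatedness <- function(relmatrix, path) {
  R <- relmatrix$r
  ut <- which(upper.tri(R) & !is.na(R), arr.ind = TRUE)
  df <- data.frame(id1 = rownames(R)[ut[, 1]], id2 = colnames(R)[ut[, 2]],
                   r = R[ut])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relatedness
#' @export
read_relatedness <- function(path) {
  df <- utils::read.csv(path, colClasses = c(id1 = "character",
                                             id2 = "character"))
  ids <- sort(unique(c(df$id1, df$id2)))
  R <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  R[cbind(df$id1, df$id2)] <- df$r
  R[cbind(df$id2, df$id1)] <- df$r
  L <- matrix(NA_integer_, length(ids), length(ids),
              dimnames = list(ids, ids))
  structure(list(r = R, n_loci = L, ids = ids), class = "relmatrix")
}

#' Write / read an assignment table (`id` plus one column per criterion)
#' @param table assignment data frame.
#' @param path file path.
#' @export
write_assignments <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = "")
  df
}

#' Serialize a C-SBM fit to JSON
#'
#' Stores Q, the connectivity matrix, per-node membership rows, logL, AIC
#' and the fitting settings; deterministic output (no timestamps).
#' @param fit a [csbm()] fit.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(Q = fit$Q, nodes = fit$nodes, B = fit$B,
              U = apply(fit$U, 1, function(r) r, simplify = FALSE),
              logL = fit$logL, aic = fit$aic, df = fit$df,
              converged = fit$converged, iterations = fit$iterations,
              n_restarts = fit$n_restarts_used, best_restart = fit$best_restart,
              seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
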