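#' Area adjacency graphs
#'
#' An `adjacency_graph` is a plain list with elements `area_ids` (character
#' vector, the canonical area ordering) and `neighbors` (named list; for each
#' area the character vector of adjacent area ids). Graphs are always
#' symmetric and free of self-loops; both properties are enforced at
#' construction and on file read.
#'
#' @param area_ids character vector of area identifiers.
#' @param neighbors named list of character vectors, one entry per area.
#' @return object of class `adjacency_graph`.
#' @export
adjacency_graph <- function(area_ids, neighbors) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) stop("duplicated area ids")
  if (!setequal(names(neighbors), area_ids))
    stop("neighbor list names must match area ids")
  neighbors <- lapply(neighbors[area_ids], as.character)
  for (a in area_ids) {
    nb <- neighbors[[a]]
    if (a %in% nb) stop("self-loop at area ", a)
    bad <- setdiff(nb, area_ids)
    if (length(bad)) stop("unknown neighbor id(s): ", paste(bad, collapse = ", "))
    for (b in nb) {
      if (!a %in% neighbors[[b]])
        stop("asymmetric adjacency: ", a, " lists ", b,
             " but not vice versa")
    }
  }
  structure(list(area_ids = area_ids, neighbors = neighbors),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  ne <- sum(lengths(x$neighbors)) / 2
  cat("adjacency_graph:", length(x$area_ids), "areas,", ne, "edges,",
      length(graph_components(x)$sizes), "component(s)\n")
  invisible(x)
}

#' Number of areas in a graph
#' @param graph an `adjacency_graph`.
#' @export
n_areas <- function(graph) length(graph$area_ids)

#' Binary adjacency matrix (dense)
#' @param graph an `adjacency_graph`.
#' @return symmetric 0/1 matrix with dimnames = area ids.
#' @export
adjacency_matrix <- function(graph) {
  ids <- graph$area_ids
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in ids) W[a, graph$neighbors[[a]]] <- 1
  W
}

#' Connected components of an adjacency graph
#' @param graph an `adjacency_graph`.
#' @return list with `membership` (integer vector named by area id) and
#'   `sizes` (component sizes).
#' @export
graph_components <- function(graph) {
  ids <- graph$area_ids
  memb <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  comp <- 0L
  for (start in ids) {
    if (!is.na(memb[start])) next
    comp <- comp + 1L
    queue <- start
    memb[start] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- graph$neighbors[[cur]]
      new <- nb[is.na(memb[nb])]
      memb[new] <- comp
      queue <- c(queue, new)
    }
  }
  list(membership = memb, sizes = as.integer(table(memb)))
}

#' Generate a synthetic area adjacency graph
#'
#' Builds an artificial municipality map: either the rook adjacency of the
#' most-square `r x c` grid with `r * c >= n_areas` truncated to `n_areas`
#' nodes, or a random planar-ish graph obtained by connecting each area to
#' its nearest spatial neighbors on random coordinates (symmetrized).
#'
#' @param n_areas number of areas (>= 2).
#' @param layout `"grid"` or `"random-planar"`.
#' @param seed integer seed (only used by the random layout).
#' @return an `adjacency_graph` with area ids `"A001", "A002", ...`.
#' @export
generate_adjacency <- function(n_areas, layout = c("grid", "random-planar"),
                               seed = 1L) {
  if (!is.numeric(n_areas) || n_areas < 2)
    stop("n_areas must be an integer >= 2")
  n_areas <- as.integer(n_areas)
  layout <- match.arg(layout)
  ids <- sprintf("A%03d", seq_len(n_areas))
  nb <- stats::setNames(vector("list", n_areas), ids)
  for (i in seq_len(n_areas)) nb[[i]] <- character()
  add_edge <- function(i, j) {
    nb[[i]] <<- union(nb[[i]], ids[j])
    nb[[j]] <<- union(nb[[j]], ids[i])
  }
  if (layout == "grid") {
    r <- floor(sqrt(n_areas))
    while (r * ceiling(n_areas / r) < n_areas) r <- r - 1
    cmax <- ceiling(n_areas / r)
    # node k (1-based) sits at row (k-1) %/% cmax, col (k-1) %% cmax
    for (k in seq_len(n_areas)) {
      row <- (k - 1) %/% cmax
      col <- (k - 1) %% cmax
      if (col + 1 < cmax && k + 1 <= n_areas && (k %% cmax) != 0)
        add_edge(k, k + 1)
      if (k + cmax <= n_areas) add_edge(k, k + cmax)
    }
  } else {
    set.seed(as.integer(seed))
    xy <- cbind(stats::runif(n_areas), stats::runif(n_areas))
    k <- min(4L, n_areas - 1L)
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    for (i in seq_len(n_areas)) {
      for (j in order(d[i, ])[seq_len(k)]) add_edge(i, j)
    }
  }
  adjacency_graph(ids, nb)
}

#' Read a neighbor-list adjacency file
#'
#' Format: one line per area, whitespace-separated — the area id followed by
#' its neighbor ids (GAL-style neighbor list). The file must describe a
#' symmetric graph; asymmetry or self-loops are errors naming the offending
#' pair, never silently repaired.
#'
#' @param path file path.
#' @return an `adjacency_graph`.
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty adjacency file: ", path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  ids <- vapply(toks, `[[`, character(1), 1L)
  nb <- stats::setNames(lapply(toks, function(t) t[-1]), ids)
  adjacency_graph(ids, nb)
}

#' Write a neighbor-list adjacency file
#' @param graph an `adjacency_graph`.
#' @param path output path.
#' @export
write_adjacency <- function(graph, path) {
  lines <- vapply(graph$area_ids, function(a)
    paste(c(a, graph$neighbors[[a]]), collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' Computes Moran's I of `x` under binary contiguity weights from `graph`
#' and a Monte-Carlo permutation p-value for the one-sided alternative of
#' positive spatial autocorrelation.
#'
#' @param x numeric vector ordered as `graph$area_ids`.
#' @param graph an `adjacency_graph`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return list with `I` (observed statistic) and `p_value`.
#' @export
morans_i <- function(x, graph, n_perm = 499, seed = 1L) {
  stopifnot(length(x) == n_areas(graph))
  W <- adjacency_matrix(graph)
  s0 <- sum(W)
  n <- length(x)
  stat <- function(z) {
    zc <- z - mean(z)
    n / s0 * sum(W * outer(zc, zc)) / sum(zc^2)
  }
  I <- stat(x)
  set.seed(as.integer(seed))
  perm <- replicate(n_perm, stat(sample(x)))
  p <- (1 + sum(perm >= I)) / (n_perm + 1)
  list(I = I, p_value = p)
}
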