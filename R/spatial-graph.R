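#' Build an area adjacency graph
#'
#' Areas are small administrative districts; two areas are neighbours
#' (w_ik = 1) when they share a boundary. The graph drives the intrinsic
#' CAR prior: each area's spatial effect is shrunk towards the mean of its
#' neighbours' effects. Edges are stored as unordered index pairs; the
#' symmetric closure is applied and duplicates collapsed.
#'
#' @param edges two-column matrix or data.frame of area ids (one row per
#'   adjacency), or NULL for an edgeless graph.
#' @param areas character vector of all area ids; ordering is sorted id
#'   order, matching [multilevel_dataset()].
#' @return Object of class `area_graph`: `areas`, `n`, `edges` (2-column
#'   integer matrix, i < k), `w_plus` (neighbour counts), `component`
#'   (integer membership vector), `n_components`.
#' @examples
#' g <- area_graph(cbind(c("a", "b"), c("b", "c")), areas = c("a", "b", "c"))
#' g$w_plus # path graph: 1 2 1
#' @export
area_graph <- function(edges, areas) {
  areas <- sort(unique(as.character(areas)))
  n <- length(areas)
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(0), 0, 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
    a <- match(as.character(edges[, 1L]), areas)
    b <- match(as.character(edges[, 2L]), areas)
    if (anyNA(a) || anyNA(b))
      stop("edge references unknown area id: ",
           paste(utils::head(unique(c(edges[, 1L][is.na(a)],
                                      edges[, 2L][is.na(b)])), 5L),
                 collapse = ", "), call. = FALSE)
    if (any(a == b)) stop("self-loop adjacency is not allowed", call. = FALSE)
    em <- cbind(pmin(a, b), pmax(a, b))
    em <- unique(em)
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  w_plus <- tabulate(c(em[, 1L], em[, 2L]), nbins = n)
  if (any(w_plus == 0L) && n > 0L)
    warning(sum(w_plus == 0L), " island area(s) with no neighbours; their CAR ",
            "effect is fixed at 0", call. = FALSE)

  # connected components by repeated label propagation
  comp <- seq_len(n)
  if (nrow(em)) {
    repeat {
      new <- comp
      # propagate the smaller label across each edge until stable
      for (s in seq_len(nrow(em))) {
        i <- em[s, 1L]; k <- em[s, 2L]
        m <- min(new[i], new[k]); new[i] <- m; new[k] <- m
      }
      if (identical(new, comp)) break
      comp <- new
    }
  }
  comp <- match(comp, sort(unique(comp)))
  structure(list(areas = areas, n = n, edges = em, w_plus = w_plus,
                 component = comp, n_components = length(unique(comp))),
            class = "area_graph")
}

#' @export
print.area_graph <- function(x, ...) {
  cat("<area_graph> ", x$n, " areas, ", nrow(x$edges), " edges, ",
      x$n_components, " component(s)\n", sep = "")
  invisible(x)
}

#' Read an adjacency edge list from CSV
#'
#' Two columns (`area_id_a`, `area_id_b` or the first two columns), one row
#' per adjacent pair.
#'
#' @param path CSV path.
#' @param areas area ids; defaults to the ids appearing in the file.
#' @return An [area_graph()].
#' @export
read_edges <- function(path, areas = NULL) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("edge file needs two columns", call. = FALSE)
  areas <- areas %||% unique(c(df[[1L]], df[[2L]]))
  area_graph(df[, 1:2], areas)
}

#' Read a GAL-format neighbour file
#'
#' The GAL dialect written by common GIS tools: a header line whose last
#' field (or only field) is the number of areas, then for each area one line
#' `id count` followed by one line listing the neighbour ids.
#'
#' @param path GAL file path.
#' @return An [area_graph()].
#' @export
read_gal <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  hdr <- strsplit(trimws(ln[1L]), "\\s+")[[1L]]
  n <- as.integer(hdr[min(2L, length(hdr))])
  if (is.na(n)) n <- as.integer(hdr[1L])
  ids <- character(0); from <- character(0); to <- character(0)
  pos <- 2L
  for (i in seq_len(n)) {
    rec <- strsplit(trimws(ln[pos]), "\\s+")[[1L]]
    id <- rec[1L]; cnt <- as.integer(rec[2L])
    ids <- c(ids, id)
    if (cnt > 0L) {
      nb <- strsplit(trimws(ln[pos + 1L]), "\\s+")[[1L]]
      if (length(nb) != cnt) stop("GAL neighbour count mismatch for area ", id,
                                  call. = FALSE)
      from <- c(from, rep(id, cnt)); to <- c(to, nb)
      pos <- pos + 2L
    } else pos <- pos + 1L
  }
  area_graph(cbind(from, to), ids)
}

#' Sparse intrinsic CAR precision structure
#'
#' Q has diagonal w_i+ (neighbour counts) and off-diagonal -1 for each
#' adjacent pair: the joint improper density of the intrinsic CAR is
#' proportional to exp(-u' Q u / (2 sigma_u2)). Q is singular with rank
#' N - (number of connected components); its null space is spanned by the
#' per-component indicator vectors, which is why a sum-to-zero constraint
#' per component identifies u.
#'
#' @param graph an [area_graph()].
#' @return Dense symmetric N x N matrix (areas here number in the hundreds,
#'   where dense linear algebra is the simpler and fast choice).
#' @export
car_precision <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  Q <- diag(as.numeric(graph$w_plus), graph$n)
  if (nrow(graph$edges)) {
    Q[graph$edges] <- Q[graph$edges] - 1
    Q[graph$edges[, 2:1, drop = FALSE]] <- Q[graph$edges[, 2:1, drop = FALSE]] - 1
  }
  dimnames(Q) <- list(graph$areas, graph$areas)
  Q
}

#' Rank of the intrinsic CAR precision
#'
#' @param graph an [area_graph()].
#' @return N minus the number of connected components (islands count as
#'   their own component).
#' @export
car_rank <- function(graph) graph$n - graph$n_components

#' Full conditional of one CAR effect
#'
#' Under the intrinsic CAR, u_i given all other effects is normal with mean
#' the arithmetic average of its neighbours' effects and variance
#' sigma_u2 / w_i+.
#'
#' @param graph an [area_graph()].
#' @param u numeric effect vector of length N.
#' @param i area index (position in the fixed area order).
#' @param sigma_u2 conditional variance parameter, > 0.
#' @return list(mean, variance).
#' @export
car_conditional <- function(graph, u, i, sigma_u2) {
  stopifnot(inherits(graph, "area_graph"), length(u) == graph$n,
            i >= 1, i <= graph$n, sigma_u2 > 0)
  wi <- graph$w_plus[i]
  if (wi == 0L)
    stop("area ", graph$areas[i], " is an island; the CAR conditional is undefined",
         call. = FALSE)
  nb <- c(graph$edges[graph$edges[, 1L] == i, 2L],
          graph$edges[graph$edges[, 2L] == i, 1L])
  list(mean = mean(u[nb]), variance = sigma_u2 / wi)
}

#' Sample from the sum-to-zero constrained intrinsic CAR
#'
#' Draws u with covariance sigma_u2 * Q^+ (Moore-Penrose generalized
#' inverse), realized through the spectral decomposition of Q: independent
#' normal coordinates on the eigenvectors with non-zero eigenvalue, scaled
#' by sqrt(sigma_u2 / lambda). Each connected component automatically sums
#' to zero, and islands receive exactly 0.
#'
#' @param graph an [area_graph()].
#' @param sigma_u2 conditional variance parameter, >= 0 (0 gives the zero
#'   vector).
#' @param n number of draws.
#' @return If `n == 1` a numeric vector of length N, else an `n` x N matrix.
#' @export
sample_car <- function(graph, sigma_u2, n = 1L) {
  stopifnot(inherits(graph, "area_graph"), sigma_u2 >= 0, n >= 1)
  N <- graph$n
  if (sigma_u2 == 0) {
    out <- matrix(0, n, N)
    return(if (n == 1L) out[1L, ] else out)
  }
  eg <- eigen(car_precision(graph), symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  sd <- sqrt(sigma_u2 / eg$values[pos])
  z <- matrix(stats::rnorm(n * sum(pos)), n, sum(pos))
  out <- tcrossprod(sweep(z, 2L, sd, `*`), V)
  if (n == 1L) out[1L, ] else out
}

#' Generalized-inverse covariance of the constrained intrinsic CAR
#'
#' The covariance matrix sigma_u2 * Q^+ that [sample_car()] realizes; used
#' as an oracle for the sampler and for reporting marginal spatial
#' variances.
#'
#' @param graph an [area_graph()].
#' @param sigma_u2 conditional variance parameter.
#' @return N x N covariance matrix.
#' @export
car_covariance <- function(graph, sigma_u2) {
  eg <- eigen(car_precision(graph), symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  sigma_u2 * V %*% (t(V) / eg$values[pos])
}

#' Rook-adjacency rectangular lattice graph
#'
#' The synthetic stand-in for a province's district map: `nr` x `nc` cells,
#' each adjacent to its 4-neighbours. Connected by construction with mean
#' neighbour count close to 4, similar to real district adjacency.
#'
#' @param nr,nc lattice dimensions.
#' @param prefix area id prefix; ids are `prefix` followed by a zero-padded
#'   index so sorted order equals lattice order.
#' @return An [area_graph()].
#' @export
lattice_graph <- function(nr, nc, prefix = "A") {
  stopifnot(nr >= 1, nc >= 1)
  n <- nr * nc
  ids <- sprintf("%s%0*d", prefix, nchar(n), seq_len(n))
  idx <- function(r, c) (r - 1L) * nc + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (cc < nc) { from <- c(from, idx(r, cc)); to <- c(to, idx(r, cc + 1L)) }
    if (r < nr)  { from <- c(from, idx(r, cc)); to <- c(to, idx(r + 1L, cc)) }
  }
  area_graph(cbind(ids[from], ids[to]), ids)
}

#' Greedy proper colouring of an area graph
#'
#' Adjacent areas receive different colours; used by the sampler to update
#' non-adjacent CAR effects in parallel (their full conditionals are
#' mutually independent given the rest).
#'
#' @param graph an [area_graph()].
#' @return Integer colour vector of length N.
#' @export
graph_coloring <- function(graph) {
  n <- graph$n
  nb <- vector("list", n)
  for (s in seq_len(nrow(graph$edges))) {
    i <- graph$edges[s, 1L]; k <- graph$edges[s, 2L]
    nb[[i]] <- c(nb[[i]], k); nb[[k]] <- c(nb[[k]], i)
  }
  col <- integer(n)
  for (i in order(graph$w_plus, decreasing = TRUE)) {
    used <- col[nb[[i]]]
    col[i] <- min(setdiff(seq_len(n), used))
  }
  col
}
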