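#' Generalized-variance scaling of the ICAR precision
#'
#' For each connected component of the graph, computes the geometric mean of
#' the marginal variances of the intrinsic CAR effect under the
#' per-component sum-to-zero constraint (the diagonal of the constrained
#' pseudo-inverse of `Q = D - W`). Multiplying `Q` by this factor gives the
#' "scaled" structured component of the BYM2 parameterization, whose
#' generalized marginal variance is 1, so that the total scale `sigma` is
#' interpretable regardless of the graph.
#'
#' Singleton components carry no structured effect (it is defined as 0
#' there); their scaling factor is returned as `NA`.
#'
#' @param graph an `adjacency_graph`.
#' @return named numeric vector, one entry per connected component (names
#'   are the component indices from [graph_components()]).
#' @export
scale_icar <- function(graph) {
  comps <- graph_components(graph)
  memb <- comps$membership
  W <- adjacency_matrix(graph)
  Q <- diag(rowSums(W), n_areas(graph)) - W
  out <- stats::setNames(rep(NA_real_, length(comps$sizes)),
                         as.character(seq_along(comps$sizes)))
  for (cc in seq_along(comps$sizes)) {
    idx <- which(memb == cc)
    if (length(idx) < 2L) next
    Qc <- Q[idx, idx, drop = FALSE]
    e <- eigen(Qc, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-9
    # diagonal of the sum-to-zero constrained pseudo-inverse
    marg <- rowSums(sweep(e$vectors[, pos, drop = FALSE]^2, 2,
                          e$values[pos], "/"))
    out[cc] <- exp(mean(log(marg)))
  }
  out
}

# scaled ICAR precision for the whole graph (dense), plus the constraint
# rows: sum-to-zero per non-singleton component and u = 0 for singletons
icar_structure <- function(graph) {
  n <- n_areas(graph)
  comps <- graph_components(graph)
  memb <- comps$membership
  W <- adjacency_matrix(graph)
  Q <- diag(rowSums(W), n) - W
  sc <- scale_icar(graph)
  Qs <- matrix(0, n, n)
  Crows <- list()
  for (cc in seq_along(comps$sizes)) {
    idx <- which(memb == cc)
    if (length(idx) >= 2L) {
      Qs[idx, idx] <- Q[idx, idx] * sc[cc]
      r <- rep(0, n); r[idx] <- 1
      Crows[[length(Crows) + 1L]] <- r
    } else {
      r <- rep(0, n); r[idx] <- 1  # pin singleton structured effect at 0
      Crows[[length(Crows) + 1L]] <- r
    }
  }
  list(Qs = Qs, C = do.call(rbind, Crows), membership = memb)
}
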