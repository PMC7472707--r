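#' Gaussian Markov random field precision structures
#'
#' A `precision_structure` holds the unit-precision (tau = 1) sparse matrix of
#' one of the three improper GMRF priors used in the model, together with its
#' known rank deficiency and a description of the null space:
#' \itemize{
#'   \item ICAR (Besag) over districts: \eqn{Q = D - A}, rank deficiency 1
#'     (constants) on a connected graph;
#'   \item RW1 over ranked knots: first-difference penalty, rank deficiency 1;
#'   \item RW2: second-difference penalty, rank deficiency 2 (constants and
#'     linear trend).
#' }
#' The prior density of a field x is proportional to
#' \eqn{\tau^{(K-d)/2} \exp(-\tau x' Q x / 2)} with d the rank deficiency.
#'
#' @name precision_structure
NULL

new_precision_structure <- function(matrix, rank_deficiency, kind, constraint) {
  structure(list(matrix = matrix, rank_deficiency = rank_deficiency,
                 kind = kind, constraint = constraint),
            class = "precision_structure")
}

#' @export
print.precision_structure <- function(x, ...) {
  cat("precision_structure:", x$kind, "on", nrow(x$matrix),
      "nodes; rank deficiency", x$rank_deficiency,
      "(null space:", x$constraint, ")\n")
  invisible(x)
}

#' ICAR (Besag) precision matrix of an adjacency graph
#'
#' Builds the intrinsic CAR unit precision \eqn{Q} with \eqn{Q_{jj} = m_j} and
#' \eqn{Q_{jk} = -1} for neighbouring districts. The implied full conditionals
#' are \eqn{b_j | b_{-j} \sim N(\bar b_j, \sigma_b^2 / m_j)} where
#' \eqn{\bar b_j} is the mean over the m_j neighbours: the conditional-variance
#' parameterization (no marginal rescaling).
#'
#' @param graph a valid, connected `adjacency_graph`.
#' @return A `precision_structure` of kind `"ICAR"` (sparse symmetric matrix,
#'   rank deficiency 1).
#' @export
build_icar_precision <- function(graph) {
  validate_graph(graph)
  n <- length(graph$unit_ids)
  el <- graph_edge_matrix(graph)
  if (nrow(el) == 0) stop("graph has no edges")
  Q <- Matrix::sparseMatrix(
    i = c(seq_len(n), el[, 1], el[, 2]),
    j = c(seq_len(n), el[, 2], el[, 1]),
    x = c(as.numeric(graph$m), rep(-1, 2 * nrow(el))),
    dims = c(n, n), symmetric = FALSE
  )
  Q <- Matrix::forceSymmetric(Q)
  new_precision_structure(Q, 1L, "ICAR", "constant vector")
}

#' Random-walk precision matrix on ordered knots
#'
#' Builds the unit precision \eqn{Q = D'D} of a random walk of order 1 or 2 on
#' K equally-treated ordered knots, where D is the order-th difference
#' operator. RW1 penalizes first differences (null space: constants); RW2
#' penalizes second differences (null space: constants and linear trend).
#' Knot spacing is ignored (unit-spacing walk).
#'
#' @param K number of knots; at least 2 (RW1) or 3 (RW2).
#' @param order 1 or 2.
#' @return A `precision_structure` of kind `"RW1"` or `"RW2"`.
#' @export
build_rw_precision <- function(K, order = 1) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (K < order + 1L) stop("K too small for RW", order, " (need K >= ", order + 1L, ")")
  D <- diff(diag(K), differences = order)
  Q <- Matrix::Matrix(crossprod(D), sparse = TRUE)
  Q <- Matrix::forceSymmetric(Q)
  new_precision_structure(
    Q, order, paste0("RW", order),
    if (order == 1L) "constant vector" else "constant and linear-trend vectors"
  )
}
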