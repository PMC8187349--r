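#' Construct a solution model over a signed network
#'
#' A solution model assigns each network edge a real weight whose sign
#' matches the edge sign and whose magnitude lies in (0, 1], plus an
#' optional per-node bias (default 0). Signal propagation is a damped,
#' saturating fixed-point iteration
#' \deqn{s_j \leftarrow (1-\lambda)\,s_j + \lambda \tanh\Big(\sum_{i \to j} w_{ij} s_i + b_j\Big)}
#' run synchronously from the all-zero state with drug-target nodes clamped,
#' which keeps every state sign-interpretable in \eqn{[-1, 1]}.
#'
#' @param network A [signed_network()].
#' @param weights Numeric vector of edge weights aligned with
#'   `network$edges` rows, or `NULL` for all magnitudes 1.
#' @param bias Named numeric vector of per-node biases (missing nodes get 0).
#' @param lambda Damping factor in (0, 1]; 1 is an undamped update.
#' @param tau Convergence tolerance on the largest per-iteration state change.
#' @param max_iter Iteration cap; non-convergent runs return their last
#'   damped state with `converged = FALSE`.
#' @return An object of class `solution_model`.
#' @export
solution_model <- function(network, weights = NULL, bias = NULL,
                           lambda = 0.5, tau = 1e-6, max_iter = 200L) {
  stopifnot(inherits(network, "signed_network"))
  m <- nrow(network$edges)
  if (is.null(weights)) weights <- as.numeric(network$edges$sign)
  if (length(weights) != m) {
    stop("`weights` must have one entry per network edge", call. = FALSE)
  }
  if (any(!is.finite(weights))) stop("non-finite edge weight", call. = FALSE)
  if (any(sign(weights) != network$edges$sign)) {
    stop("weight signs must match edge signs", call. = FALSE)
  }
  if (any(abs(weights) > 1)) stop("weight magnitudes must be <= 1", call. = FALSE)
  b <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  if (!is.null(bias)) {
    if (is.null(names(bias)) || !all(names(bias) %in% network$nodes)) {
      stop("`bias` must be named by network nodes", call. = FALSE)
    }
    b[names(bias)] <- bias
  }
  stopifnot(lambda > 0, lambda <= 1, tau > 0, max_iter >= 1)
  structure(
    list(
      network = network, weights = as.numeric(weights), bias = b,
      config = list(lambda = lambda, tau = tau, max_iter = as.integer(max_iter))
    ),
    class = "solution_model"
  )
}

#' @export
print.solution_model <- function(x, ...) {
  cat("<solution_model> ", length(x$network$nodes), " nodes, ",
    length(x$weights), " weighted edges (lambda = ", x$config$lambda, ")\n",
    sep = ""
  )
  invisible(x)
}

# 0-based edge index arrays for the compiled core
edge_index <- function(model) {
  nodes <- model$network$nodes
  list(
    n = length(nodes),
    from = match(model$network$edges$from, nodes) - 1L,
    to = match(model$network$edges$to, nodes) - 1L
  )
}

#' Propagate clamped perturbations through a solution model
#'
#' Clamped nodes are fixed at their input value for every iteration; all
#' other nodes start at 0 and follow the damped tanh update until the
#' largest state change drops below the model's tolerance or the iteration
#' cap is hit.
#'
#' @param model A [solution_model()].
#' @param inputs Named numeric vector of clamp values in \eqn{[-1, 1]}
#'   (typically -1 or +1), named by network nodes.
#' @return A tibble of class `state_vector` with columns `node` and `state`,
#'   and attributes `converged` (logical) and `iterations` (integer).
#' @examples
#' net <- signed_network(data.frame(from = "A", to = "B", sign = 1))
#' m <- solution_model(net, lambda = 1)
#' propagate(m, c(A = -1)) # state(B) = tanh(-1)
#' @export
propagate <- function(model, inputs = numeric()) {
  stopifnot(inherits(model, "solution_model"))
  nodes <- model$network$nodes
  if (length(inputs)) {
    if (is.null(names(inputs))) stop("`inputs` must be named", call. = FALSE)
    absent <- setdiff(names(inputs), nodes)
    if (length(absent)) {
      stop("clamped node(s) not in network: ", paste(absent, collapse = ", "),
        call. = FALSE
      )
    }
    if (any(!is.finite(inputs)) || any(abs(inputs) > 1)) {
      stop("clamp values must be finite and within [-1, 1]", call. = FALSE)
    }
  }
  idx <- edge_index(model)
  res <- propagate_cpp(
    idx$n, idx$from, idx$to, model$weights, unname(model$bias),
    match(names(inputs), nodes) - 1L, as.numeric(inputs),
    model$config$lambda, model$config$tau, model$config$max_iter
  )
  out <- tibble::tibble(node = nodes, state = res$states)
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  class(out) <- c("state_vector", class(out))
  out
}

#' Simulate a drug on a disease phenotype
#'
#' Each drug target is clamped at its modulation sign, the perturbation is
#' propagated, and the resulting activity `y` is read at every disease
#' effector alongside its pathological sign `v` and motif.
#'
#' @param model A [solution_model()].
#' @param drug A [drug_profile()]; targets must exist in the network.
#' @param disease A [disease_profile()].
#' @return A tibble of class `effector_outputs` with columns `protein`,
#'   `motif`, `v` (pathological sign) and `y` (simulated activity), plus a
#'   `converged` attribute.
#' @export
simulate_drug <- function(model, drug, disease) {
  stopifnot(inherits(drug, "drug_profile"), inherits(disease, "disease_profile"))
  clamps <- stats::setNames(as.numeric(drug$targets$modulation), drug$targets$protein)
  states <- propagate(model, clamps)
  y <- stats::setNames(states$state, states$node)
  absent <- setdiff(disease$effectors$protein, names(y))
  if (length(absent)) {
    stop("effector(s) not in network: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    protein = disease$effectors$protein,
    motif = disease$effectors$motif,
    v = disease$effectors$sign,
    y = unname(y[disease$effectors$protein])
  )
  attr(out, "converged") <- attr(states, "converged")
  class(out) <- c("effector_outputs", class(out))
  out
}

#' Serialize a solution model to JSON
#'
#' Stores edge weights, biases and propagation configuration so an ensemble
#' can be persisted as a directory of model files.
#'
#' @param model A [solution_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solution_model <- function(model, path) {
  stopifnot(inherits(model, "solution_model"))
  obj <- list(
    edges = data.frame(
      from = model$network$edges$from, to = model$network$edges$to,
      sign = model$network$edges$sign, weight = model$weights
    ),
    bias = as.list(model$bias[model$bias != 0]),
    config = model$config
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a solution model from JSON
#'
#' @param path Path written by [write_solution_model()].
#' @return A [solution_model()].
#' @export
read_solution_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- signed_network(obj$edges[, c("from", "to", "sign")])
  ord <- match(
    paste(net$edges$from, net$edges$to),
    paste(obj$edges$from, obj$edges$to)
  )
  bias <- unlist(obj$bias)
  solution_model(
    net,
    weights = obj$edges$weight[ord],
    bias = if (length(bias)) bias else NULL,
    lambda = obj$config$lambda, tau = obj$config$tau,
    max_iter = obj$config$max_iter
  )
}
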