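# Fixture builders and independent oracles used across the suite.

# A linear chain N1 -> N2 -> ... with the given edge signs.
chain_network <- function(signs) {
  n <- length(signs) + 1
  nodes <- paste0("N", seq_len(n))
  signed_network(tibble::tibble(
    from = nodes[-n], to = nodes[-1], sign = signs
  ))
}

# Random directed network (cycles allowed), unique pairs, no self-loops.
rand_network <- function(n_nodes, n_edges, seed, inhibition = 0.4) {
  set.seed(seed)
  nodes <- sprintf("R%02d", seq_len(n_nodes))
  pairs <- tidyr::expand_grid(from = nodes, to = nodes)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample.int(nrow(pairs), n_edges), ]
  pick$sign <- ifelse(runif(n_edges) < inhibition, -1L, 1L)
  signed_network(pick)
}

rand_model <- function(network, seed, lambda = 0.5) {
  set.seed(seed)
  w <- network$edges$sign * runif(nrow(network$edges), 0.05, 1)
  solution_model(network, weights = w, lambda = lambda)
}

# Independent term-by-term evaluation of the Dirac-delta reversal count:
# #Eff = sum_i delta(v_i/|v_i| + y_i/|y_i|), with |y| < eps contributing 0.
brute_eff_count <- function(v, y, eps = 1e-3) {
  total <- 0
  for (i in seq_along(v)) {
    if (abs(y[i]) < eps) next
    term <- v[i] / abs(v[i]) + y[i] / abs(y[i])
    if (term == 0) total <- total + 1
  }
  total
}

# Reference Benjamini-Hochberg step-up, written directly from the
# procedure: sort p ascending, adjusted_(i) = min over j >= i of p_(j)*n/j,
# capped at 1, mapped back to input order.
bh_reference <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# One-pass topological-order evaluation of the propagation fixed point on
# a DAG: at convergence s_j = tanh(sum_i w_ij s_i + b_j) for unclamped j.
topo_eval <- function(model, clamps) {
  net <- model$network
  g <- as_igraph(net)
  ord <- names(igraph::topo_sort(g, mode = "out"))
  s <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  s[names(clamps)] <- clamps
  b <- model$bias
  for (node in ord) {
    if (node %in% names(clamps)) next
    inc <- net$edges$to == node
    s[node] <- tanh(sum(model$weights[inc] * s[net$edges$from[inc]]) + b[node])
  }
  s
}

# Tiny solvable planted instance: DAG, strong planted weights, noiseless
# restrictions read off the planted model's drug-on states.
planted_instance <- function(seed, n_nodes = 12, mean_out_degree = 2) {
  net <- sim_network(
    n_nodes = n_nodes, mean_out_degree = mean_out_degree,
    inhibition_fraction = 0.3, seed = seed
  )
  sim_scenario(net,
    n_targets = 2, n_effectors = 4, n_motifs = 2,
    rho = 1, restriction_noise = 0, seed = seed
  )
}
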