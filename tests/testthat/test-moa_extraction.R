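# Two parallel target->effector routes: T -> A -> E and T -> B -> E.
parallel_net <- function() {
  signed_network(tibble::tibble(
    from = c("T", "A", "T", "B", "X"),
    to = c("A", "E", "B", "E", "E"),
    sign = c(1L, 1L, 1L, -1L, 1L)
  ))
}

# ensemble of hand-built models with chosen weight magnitudes per edge
manual_ensemble <- function(net, weight_list, drug, restrictions) {
  models <- lapply(weight_list, function(w) solution_model(net, weights = w))
  structure(
    list(
      models = models,
      accuracies = rep(1, length(models)),
      seed = 0L, run_seeds = seq_along(models),
      schedule = anneal_schedule(), eps = 1e-3,
      drug = drug, restrictions = restrictions
    ),
    class = "model_ensemble"
  )
}

moa_fixture <- function() {
  net <- parallel_net()
  drug <- drug_profile("d", data.frame(protein = "T", modulation = -1))
  disease <- disease_profile("p", data.frame(protein = "E", sign = 1, motif = "m"))
  res <- restriction_set(data.frame(protein = "E", sign = -1))
  # edge order (arranged by from, to): A->E, B->E, T->A, T->B, X->E
  w_full <- c(1, -1, 1, 1, 1) * 0.9
  w_upper <- c(0.9, -0.05, 0.9, 0.05, 0.9) # B-route below threshold
  list(net = net, drug = drug, disease = disease, res = res,
    w_full = w_full, w_upper = w_upper)
}

test_that("edge support counts path membership across the ensemble", {
  fx <- moa_fixture()
  # identical models -> support is 0 or 1 per edge
  ens <- manual_ensemble(fx$net, list(fx$w_full, fx$w_full), fx$drug, fx$res)
  sup <- edge_support(ens, fx$disease, w_min = 0.1)
  expect_true(all(sup$support %in% c(0, 1)))
  # X->E never lies on a target->effector path
  expect_equal(sup$support[sup$from == "X"], 0)
  # all T-rooted edges do
  expect_equal(sup$support[sup$from == "T"], c(1, 1))

  # mixed ensemble: upper route always active, lower route in half the
  # models. Exhaustive path enumeration oracle: T->A->E in 2/2 models,
  # T->B->E in 1/2.
  ens2 <- manual_ensemble(fx$net, list(fx$w_full, fx$w_upper), fx$drug, fx$res)
  sup2 <- edge_support(ens2, fx$disease, w_min = 0.1)
  expect_equal(sup2$support[sup2$from == "T" & sup2$to == "A"], 1)
  expect_equal(sup2$support[sup2$from == "T" & sup2$to == "B"], 0.5)
  expect_equal(sup2$support[sup2$from == "B"], 0.5)
  expect_equal(
    sup2$mean_abs_weight[sup2$from == "T" & sup2$to == "B"],
    mean(c(0.9, 0.05))
  )
})

test_that("extract_moa keeps the best-supported paths and prunes the rest", {
  fx <- moa_fixture()
  ens <- manual_ensemble(fx$net, list(fx$w_full, fx$w_upper), fx$drug, fx$res)
  sup <- edge_support(ens, fx$disease, w_min = 0.1)

  # k_paths = 1: only the support-1.0 route survives (dominance)
  top1 <- extract_moa(fx$net, sup, fx$drug, fx$disease, k_paths = 1)
  expect_setequal(top1$nodes$protein, c("T", "A", "E"))
  expect_setequal(
    paste(top1$edges$from, top1$edges$to),
    c("T A", "A E")
  )
  expect_equal(top1$nodes$role[top1$nodes$protein == "T"], "target")
  expect_equal(top1$nodes$role[top1$nodes$protein == "A"], "intermediate")
  expect_equal(top1$nodes$role[top1$nodes$protein == "E"], "effector")

  # k_paths = 2, low threshold: both routes retained, equal to the
  # brute-force enumeration of all simple paths ranked by product support
  top2 <- extract_moa(fx$net, sup, fx$drug, fx$disease,
    k_paths = 2, min_support = 0.2
  )
  expect_setequal(
    paste(top2$edges$from, top2$edges$to),
    c("T A", "A E", "T B", "B E")
  )

  # pruning monotonicity: raising min_support never adds nodes or edges
  tighter <- extract_moa(fx$net, sup, fx$drug, fx$disease,
    k_paths = 2, min_support = 0.6
  )
  expect_true(all(tighter$nodes$protein %in% top2$nodes$protein))
  expect_true(all(
    paste(tighter$edges$from, tighter$edges$to) %in%
      paste(top2$edges$from, top2$edges$to)
  ))

  # every retained effector is reachable from a target inside the subnetwork
  g <- igraph::graph_from_data_frame(as.data.frame(top2$edges[, 1:2]))
  reach <- names(igraph::subcomponent(g, "T", mode = "out"))
  expect_true(all(top2$nodes$protein[top2$nodes$role == "effector"] %in% reach))

  # impossible threshold -> empty subnetwork with warning
  expect_warning(
    none <- extract_moa(fx$net, sup, fx$drug, fx$disease, min_support = 1.1),
    "no target-to-effector path"
  )
  expect_equal(nrow(none$edges), 0)
})

test_that("extraction matches exhaustive enumeration on a random toy ensemble", {
  set.seed(31)
  net <- sim_network(n_nodes = 10, mean_out_degree = 2, seed = 31)
  drug <- drug_profile("d", data.frame(
    protein = net$nodes[1], modulation = -1
  ))
  sinks <- setdiff(net$nodes, net$edges$from)
  disease <- disease_profile("p", data.frame(
    protein = sinks[1], sign = 1, motif = "m"
  ))
  res <- restriction_set(data.frame(protein = sinks[1], sign = -1))
  weight_list <- lapply(1:6, function(i) {
    net$edges$sign * runif(nrow(net$edges), 0.02, 1)
  })
  ens <- manual_ensemble(net, weight_list, drug, res)
  sup <- edge_support(ens, disease, w_min = 0.1)

  # oracle: enumerate all simple paths, score by product of edge supports
  g <- as_igraph(net)
  paths <- igraph::all_simple_paths(g, drug$targets$protein, disease$effectors$protein,
    mode = "out"
  )
  if (length(paths) > 1) {
    key <- function(p) paste(names(p)[-length(p)], names(p)[-1])
    supmap <- stats::setNames(sup$support, paste(sup$from, sup$to))
    scores <- vapply(paths, function(p) prod(supmap[key(p)]), numeric(1))
    if (sum(scores == max(scores)) == 1) {
      best_edges <- key(paths[[which.max(scores)]])
      got <- extract_moa(net, sup, drug, disease, k_paths = 1, min_support = 0)
      expect_setequal(paste(got$edges$from, got$edges$to), best_edges)
    }
  }
})

test_that("subnetworks export to SIF/GraphML/DOT and SIF round-trips", {
  fx <- moa_fixture()
  ens <- manual_ensemble(fx$net, list(fx$w_full, fx$w_upper), fx$drug, fx$res)
  sup <- edge_support(ens, fx$disease, w_min = 0.1)
  sub <- extract_moa(fx$net, sup, fx$drug, fx$disease, k_paths = 2, min_support = 0.2)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_moa(sub, sif)
  back <- read_moa_sif(sif)
  expect_equal(
    dplyr::arrange(back$edges, from, to),
    dplyr::arrange(sub$edges, from, to),
    ignore_attr = TRUE
  )
  expect_equal(
    dplyr::arrange(back$nodes, protein),
    dplyr::arrange(sub$nodes, protein),
    ignore_attr = TRUE
  )

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_moa(sub, gml, format = "graphml")
  doc <- paste(readLines(gml), collapse = "\n")
  expect_equal(lengths(regmatches(doc, gregexpr("<edge ", doc))), nrow(sub$edges))
  expect_match(doc, "support")

  dot <- withr::local_tempfile(fileext = ".dot")
  export_moa(sub, dot, format = "dot")
  expect_match(paste(readLines(dot), collapse = "\n"), "digraph")

  expect_error(export_moa(sub, sif, format = "png"), "unknown export format")

  # empty subnetwork still writes valid (empty) documents
  suppressWarnings(
    empty <- extract_moa(fx$net, sup, fx$drug, fx$disease, min_support = 1.1)
  )
  sif2 <- withr::local_tempfile(fileext = ".sif")
  export_moa(empty, sif2)
  expect_equal(length(readLines(sif2)), 0)
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_moa(empty, gml2, format = "graphml")
  expect_match(paste(readLines(gml2), collapse = "\n"), "graphml")
})
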