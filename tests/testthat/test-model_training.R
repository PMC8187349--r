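test_that("accuracy is the fraction of satisfied restrictions", {
  # star: T feeds four outputs, two activating, two inhibiting.
  # Clamp T = -1: signs are (-, -, +, +) at (O1, O2, O3, O4).
  net <- signed_network(tibble::tibble(
    from = "T", to = c("O1", "O2", "O3", "O4"), sign = c(1L, 1L, -1L, -1L)
  ))
  drug <- drug_profile("d", data.frame(protein = "T", modulation = -1))
  m <- solution_model(net)
  # require (-, -, +, -): three of four match -> 0.75
  res <- restriction_set(data.frame(
    protein = c("O1", "O2", "O3", "O4"), sign = c(-1, -1, 1, -1)
  ))
  expect_equal(model_accuracy(m, drug, res), 0.75)

  # restriction-row ordering does not matter
  res_shuffled <- restriction_set(res$entries[c(3, 1, 4, 2), ])
  expect_equal(model_accuracy(m, drug, res_shuffled), 0.75)

  # dead network: every |y| below the dead-band counts as unsatisfied
  net2 <- signed_network(
    tibble::tibble(from = "T", to = "M", sign = 1L),
    nodes = c("T", "M", "O1")
  )
  m2 <- solution_model(net2)
  res2 <- restriction_set(data.frame(protein = "O1", sign = 1))
  expect_equal(model_accuracy(m2, drug, res2), 0)

  # empty restriction set -> undefined accuracy
  empty <- restriction_set(data.frame(protein = character(), sign = integer()))
  expect_error(model_accuracy(m, drug, empty), "undefined")
})

test_that("accuracy equals a brute-force re-simulation count on random instances", {
  for (seed in 1:5) {
    scen <- sim_scenario(seed = seed, restriction_noise = 0.3)
    m <- rand_model(scen$network, seed = seed + 10)
    acc <- model_accuracy(m, scen$drug, scen$restrictions)
    states <- propagate(
      m,
      stats::setNames(
        as.numeric(scen$drug$targets$modulation),
        scen$drug$targets$protein
      )
    )
    y <- stats::setNames(states$state, states$node)[scen$restrictions$entries$protein]
    hits <- sum(abs(y) >= 1e-3 & sign(y) == scen$restrictions$entries$sign)
    expect_equal(acc, hits / nrow(scen$restrictions$entries))
  }
})

test_that("annealing solves planted solvable instances and tracks the best model", {
  scen <- planted_instance(seed = 1)
  fit <- anneal_model(scen$network, scen$drug, scen$restrictions, seed = 1)
  expect_gte(attr(fit, "accuracy"), 0.9)
  # stored best-ever objective never increases across temperatures
  trace <- attr(fit, "objective_trace")
  expect_true(all(diff(trace) <= 1e-12))
  # returned weights respect sign and magnitude invariants
  expect_true(all(sign(fit$weights) == scen$network$edges$sign))
  expect_true(all(abs(fit$weights) <= 1 & abs(fit$weights) > 0))
})

test_that("annealing is deterministic given a seed and validates its schedule", {
  scen <- planted_instance(seed = 2)
  a <- anneal_model(scen$network, scen$drug, scen$restrictions, seed = 7)
  b <- anneal_model(scen$network, scen$drug, scen$restrictions, seed = 7)
  expect_identical(a$weights, b$weights)
  expect_error(anneal_schedule(gamma = 1.2), "gamma")
  expect_error(anneal_schedule(gamma = 1), "gamma")
  expect_error(anneal_schedule(t0 = -1), "schedule")
  empty <- restriction_set(data.frame(protein = character(), sign = integer()))
  expect_error(
    anneal_model(scen$network, scen$drug, empty, seed = 1),
    "undefined"
  )
})

test_that("ensembles have the requested size, reproducibility and accuracies", {
  scen <- planted_instance(seed = 3)
  ens <- fit_ensemble(scen$network, scen$drug, scen$restrictions,
    n_models = 5, seed = 11
  )
  expect_length(ens$models, 5)
  expect_length(ens$accuracies, 5)
  # stored accuracies are recomputable from the stored models
  recomputed <- vapply(
    ens$models,
    function(m) model_accuracy(m, scen$drug, scen$restrictions),
    numeric(1)
  )
  expect_equal(ens$accuracies, recomputed)

  # same global seed -> identical accuracy vector
  ens2 <- fit_ensemble(scen$network, scen$drug, scen$restrictions,
    n_models = 5, seed = 11
  )
  expect_identical(ens$accuracies, ens2$accuracies)

  # N = 1 equals a single anneal run at the derived seed
  ens1 <- fit_ensemble(scen$network, scen$drug, scen$restrictions,
    n_models = 1, seed = 11
  )
  single <- anneal_model(scen$network, scen$drug, scen$restrictions,
    seed = ens1$run_seeds[1]
  )
  expect_identical(ens1$models[[1]]$weights, single$weights)

  g <- glance(ens)
  expect_equal(g$n_models, 5)
  expect_equal(g$mean_accuracy, mean(ens$accuracies))
  expect_equal(nrow(tidy(ens)), 5)
})

test_that("mean ensemble accuracy recovers planted noiseless ground truth", {
  scen <- planted_instance(seed = 4)
  ens <- fit_ensemble(scen$network, scen$drug, scen$restrictions,
    n_models = 8, seed = 4
  )
  expect_gte(mean(ens$accuracies), 0.9)
})

test_that("ensembles persist to a model directory and reload", {
  scen <- planted_instance(seed = 5)
  ens <- fit_ensemble(scen$network, scen$drug, scen$restrictions,
    n_models = 3, seed = 5
  )
  d <- withr::local_tempdir()
  write_ensemble(ens, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- read_ensemble(d)
  expect_equal(back$accuracies, ens$accuracies)
  expect_equal(back$run_seeds, ens$run_seeds)
  expect_equal(back$models[[2]]$weights, ens$models[[2]]$weights)
  expect_equal(
    back$restrictions$entries,
    ens$restrictions$entries,
    ignore_attr = TRUE
  )
})
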