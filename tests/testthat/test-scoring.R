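test_that("intensity counts sign reversals exactly as the delta formula", {
  out <- tibble::tibble(
    protein = c("P1", "P2", "P3"), motif = "m1",
    v = c(1, 1, -1), y = c(-0.4, 0.2, 0.9)
  )
  res <- intensity(out)
  overall <- res[res$motif == "overall", ]
  expect_equal(overall$eff_count, 2)
  expect_equal(overall$percent, 100 * 2 / 3, tolerance = 1e-12)

  # full reversal scores 100
  full <- tibble::tibble(
    protein = c("a", "b"), motif = c("m1", "m2"), v = c(1, -1), y = c(-0.5, 0.8)
  )
  expect_equal(intensity(full)$percent[intensity(full)$motif == "overall"], 100)

  # dead-band: |y| < eps never counts as achieving the signal
  dead <- tibble::tibble(protein = "a", motif = "m", v = 1, y = -1e-9)
  expect_equal(intensity(dead)$eff_count, c(0, 0))

  # unknown motif is a lookup error; known motif restricts the result
  expect_error(intensity(out, motif = "nope"), "motif")
  expect_equal(intensity(out, motif = "m1")$n, 3)
})

test_that("intensity equals the brute-force delta-formula oracle on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    v <- sample(c(-1L, 1L), n, replace = TRUE)
    y <- runif(n, -1, 1)
    y[sample(n, 2)] <- runif(2, -5e-4, 5e-4) # some inside the dead-band
    out <- tibble::tibble(
      protein = paste0("p", 1:n),
      motif = sample(c("m1", "m2", "m3"), n, replace = TRUE),
      v = v, y = y
    )
    res <- intensity(out)
    expect_equal(
      res$eff_count[res$motif == "overall"],
      brute_eff_count(v, y)
    )
    # per-motif counts sum to the overall count
    expect_equal(
      sum(res$eff_count[res$motif != "overall"]),
      res$eff_count[res$motif == "overall"]
    )
    # permutation invariance
    perm <- sample(n)
    res2 <- intensity(out[perm, ])
    expect_equal(
      res2$eff_count[res2$motif == "overall"],
      res$eff_count[res$motif == "overall"]
    )
  }
})

test_that("single-target ablation isolates the effective target", {
  # P1 reaches the effectors; P2 is a decoy with no outgoing edges
  net <- signed_network(
    tibble::tibble(
      from = c("P1", "M"), to = c("M", "E"), sign = c(1L, 1L)
    ),
    nodes = c("P1", "P2", "M", "E")
  )
  drug <- drug_profile("d", data.frame(
    protein = c("P1", "P2"), modulation = c(-1, -1)
  ))
  disease <- disease_profile("p", data.frame(protein = "E", sign = 1, motif = "m"))
  res <- restriction_set(data.frame(protein = "E", sign = -1))
  ens <- fit_ensemble(net, drug, res, n_models = 3, seed = 1)
  tc <- target_contribution(ens, disease)
  overall <- tc[tc$motif == "overall", ]
  expect_gt(
    overall$percent[overall$target == "P1"],
    overall$percent[overall$target == "P2"]
  )
  # a target with no outgoing edges contributes nothing
  expect_equal(overall$percent[overall$target == "P2"], 0)
  expect_error(target_contribution(ens, disease, targets = "ZZ"), "not a target")

  # single-target drug: contribution equals the full-drug intensity
  drug1 <- drug_profile("d1", data.frame(protein = "P1", modulation = -1))
  ens1 <- fit_ensemble(net, drug1, res, n_models = 3, seed = 1)
  tc1 <- target_contribution(ens1, disease)
  full <- ensemble_intensity(ens1, disease)
  expect_equal(
    tc1$percent[tc1$motif == "overall"],
    full$percent[full$motif == "overall"]
  )
})

test_that("drug benchmarking emits one row set per drug and respects coverage", {
  # sign-determined toy DAG: T1 reverses E1, T2 reverses E2
  net <- signed_network(tibble::tibble(
    from = c("T1", "T2"), to = c("E1", "E2"), sign = c(1L, 1L)
  ))
  disease <- disease_profile("p", data.frame(
    protein = c("E1", "E2"), sign = c(1, 1), motif = c("m1", "m2")
  ))
  res <- restriction_set(data.frame(protein = c("E1", "E2"), sign = c(-1, -1)))
  both <- drug_profile("both", data.frame(
    protein = c("T1", "T2"), modulation = c(-1, -1)
  ))
  one <- drug_profile("one", data.frame(protein = "T1", modulation = -1))
  bench <- benchmark_drugs(net, list(both, one), disease, res,
    n_models = 2, seed = 3
  )
  wide <- tidyr::pivot_wider(
    bench[, c("drug", "motif", "percent")],
    names_from = "motif", values_from = "percent"
  )
  # superset drug dominates row-wise on every motif
  expect_true(all(wide[wide$drug == "both", -1] >= wide[wide$drug == "one", -1]))

  # identical target profiles produce identical rows
  twin <- drug_profile("twin", data.frame(
    protein = c("T1", "T2"), modulation = c(-1, -1)
  ))
  b2 <- benchmark_drugs(net, list(both, twin), disease, res, n_models = 2, seed = 3)
  expect_equal(
    b2$percent[b2$drug == "both"],
    b2$percent[b2$drug == "twin"]
  )

  # invalid drugs are reported per drug, others proceed
  ghost <- drug_profile("ghost", data.frame(protein = "ZZ", modulation = -1))
  b3 <- benchmark_drugs(net, list(ghost, one), disease, res, n_models = 2, seed = 3)
  expect_match(b3$status[b3$drug == "ghost"], "invalid")
  expect_true(all(b3$status[b3$drug == "one"] == "ok"))

  # empty drug list -> empty table
  expect_equal(nrow(benchmark_drugs(net, list(), disease, res)), 0)
})

test_that("proximity score behaves at its fixed points and under the null", {
  net <- rand_network(15, 40, seed = 13)
  set_a <- net$nodes[1:4]
  # identical sets: distance 0, no null draw can do better, ties count
  ps <- proximity_score(net, set_a, set_a, n_null = 200, seed = 1)
  expect_equal(ps$observed, 0)
  expect_equal(ps$score, 100)

  # degenerate config: no null draws -> raw distance, undefined score
  ps0 <- proximity_score(net, set_a, net$nodes[5:8], n_null = 0)
  expect_true(is.na(ps0$score))
  expect_gt(ps0$observed, 0)

  expect_error(proximity_score(net, character(), set_a), "non-empty")
  expect_error(proximity_score(net, "nope", set_a), "not in network")
})

test_that("cross-component singleton sets score near 50 under a symmetric null", {
  # two topologically identical components; a and its twin sit in
  # different components, so the observed distance is the unreachable cap.
  # Monte-Carlo oracle: a degree-matched relabelling lands the pair in
  # different components about half the time, so the percentile is ~50.
  base <- rand_network(10, 22, seed = 17)
  twin_edges <- dplyr::mutate(
    base$edges,
    from = sub("^R", "S", .data$from), to = sub("^R", "S", .data$to)
  )
  net <- signed_network(
    dplyr::bind_rows(base$edges, twin_edges),
    nodes = c(base$nodes, sub("^R", "S", base$nodes))
  )
  ps <- proximity_score(net, "R01", "S01", n_null = 10000, seed = 42)
  expect_gt(ps$score, 40)
  expect_lt(ps$score, 60)
})
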