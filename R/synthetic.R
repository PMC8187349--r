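#' Generate a sparse signed scale-free network
#'
#' Grows a directed graph by preferential attachment: each new node
#' receives `max(1, Poisson(mean_out_degree))` parent edges from existing
#' nodes chosen proportionally to their current out-degree (plus one).
#' Edges always point from older to newer nodes, so the graph is acyclic,
#' every node is reachable from the first (source-layer) node, early nodes
#' become high-out-degree hubs and late nodes are sinks -- the shape a
#' drug-target-to-effector cascade needs. Each edge is inhibitory with the
#' stated probability.
#'
#' @param n_nodes Number of proteins (>= 2).
#' @param mean_out_degree Mean number of parents per added node; must be
#'   < `n_nodes`.
#' @param inhibition_fraction Probability an edge carries sign -1.
#' @param seed Integer seed; the same seed reproduces the network exactly.
#' @return A [signed_network()] with nodes `P001`, `P002`, ...
#' @export
sim_network <- function(n_nodes = 50L, mean_out_degree = 2,
                        inhibition_fraction = 0.3, seed = 1L) {
  if (n_nodes < 2 || mean_out_degree >= n_nodes || mean_out_degree <= 0) {
    stop("infeasible network parameters", call. = FALSE)
  }
  if (inhibition_fraction < 0 || inhibition_fraction > 1) {
    stop("inhibition_fraction must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  nodes <- sprintf("P%03d", seq_len(n_nodes))
  out_deg <- numeric(n_nodes)
  from <- to <- integer()
  for (j in 2:n_nodes) {
    k <- min(j - 1L, max(1L, stats::rpois(1, mean_out_degree)))
    parents <- sample.int(j - 1L, k, prob = out_deg[seq_len(j - 1L)] + 1)
    out_deg[parents] <- out_deg[parents] + 1
    from <- c(from, parents)
    to <- c(to, rep(j, k))
  }
  sg <- ifelse(stats::runif(length(from)) < inhibition_fraction, -1L, 1L)
  signed_network(tibble::tibble(from = nodes[from], to = nodes[to], sign = sg))
}

#' Plant a ground-truth mechanism scenario on a network
#'
#' Samples a ground-truth solution model (weight magnitudes uniform on
#' \[0.2, 1\] so the planted signal clears the sign dead-band), picks drug
#' targets among the highest-out-degree nodes (clamped at -1, a
#' drug-like inhibitor), and picks effectors among reachable low-out-degree
#' nodes whose planted drug-on activity is decisive. Effectors are
#' partitioned uniformly at random into motifs, and their pathological
#' signs are set so that the planted drug reverses exactly a fraction
#' `rho` of them: `v = -sign(y)` for the reversed subset, `v = +sign(y)`
#' for the rest. Restrictions are the planted drug-on signs of all
#' decisive non-target nodes, each flipped independently with probability
#' `restriction_noise`.
#'
#' @param network A [signed_network()]; defaults to [sim_network()] with
#'   the same seed.
#' @param n_targets,n_effectors,n_motifs Scenario dimensions.
#' @param rho Planted reversal fraction in [0, 1].
#' @param restriction_noise Per-entry sign-flip probability.
#' @param seed Integer seed.
#' @param margin Minimum planted |activity| for a node to serve as an
#'   effector or restriction (keeps planted signs decisive).
#' @param lambda,tau,max_iter Propagation configuration of the planted
#'   model.
#' @return An object of class `moa_scenario`: a list with `network`,
#'   `true_model`, `drug`, `disease`, `restrictions`, `rho`,
#'   `planted_outputs` (tibble of effector activities under the true
#'   model), `n_flipped` (restriction entries flipped by noise) and
#'   `params`.
#' @export
sim_scenario <- function(network = NULL, n_targets = 3L, n_effectors = 10L,
                         n_motifs = 5L, rho = 0.6, restriction_noise = 0.05,
                         seed = 1L, margin = 0.05,
                         lambda = 0.5, tau = 1e-6, max_iter = 200L) {
  stopifnot(rho >= 0, rho <= 1, restriction_noise >= 0, restriction_noise <= 1)
  if (is.null(network)) network <- sim_network(seed = seed)
  set.seed(seed + 1L)
  nodes <- network$nodes
  m <- nrow(network$edges)

  w <- network$edges$sign * stats::runif(m, 0.2, 1)
  true_model <- solution_model(network,
    weights = w, lambda = lambda, tau = tau,
    max_iter = max_iter
  )

  out_deg <- table(factor(network$edges$from, levels = nodes))
  targets <- names(sort(out_deg, decreasing = TRUE))[seq_len(n_targets)]
  drug <- drug_profile(
    "synthetic-inhibitor",
    tibble::tibble(protein = targets, modulation = -1L)
  )

  states <- propagate(true_model, stats::setNames(rep(-1, n_targets), targets))
  y <- stats::setNames(states$state, states$node)
  decisive <- setdiff(nodes[abs(y[nodes]) >= margin], targets)
  if (length(decisive) < n_effectors) {
    stop("not enough reachable nodes with decisive planted activity; ",
      "grow the network or lower `margin`",
      call. = FALSE
    )
  }
  # effectors: decisive nodes with the lowest out-degree (sinks first)
  eff <- decisive[order(out_deg[decisive], sample.int(length(decisive)))]
  eff <- eff[seq_len(n_effectors)]
  n_rev <- round(rho * n_effectors)
  rev_idx <- sample.int(n_effectors, n_rev)
  v <- as.integer(sign(y[eff]))
  v[rev_idx] <- -v[rev_idx] # drug reverses these: v opposite to drug-on sign
  disease <- disease_profile(
    "synthetic-phenotype",
    tibble::tibble(
      protein = eff,
      sign = v,
      motif = sample(sprintf("motif_%d", seq_len(n_motifs)), n_effectors,
        replace = TRUE
      )
    )
  )

  res_sign <- as.integer(sign(y[decisive]))
  flips <- stats::runif(length(decisive)) < restriction_noise
  res_sign[flips] <- -res_sign[flips]
  restrictions <- restriction_set(
    tibble::tibble(protein = decisive, sign = res_sign),
    provenance = "manual"
  )

  structure(
    list(
      network = network, true_model = true_model, drug = drug,
      disease = disease, restrictions = restrictions, rho = rho,
      planted_outputs = tibble::tibble(
        protein = eff, motif = disease$effectors$motif,
        v = disease$effectors$sign, y = unname(y[eff])
      ),
      n_flipped = sum(flips),
      params = list(
        n_targets = n_targets, n_effectors = n_effectors,
        n_motifs = n_motifs, rho = rho,
        restriction_noise = restriction_noise, seed = seed,
        margin = margin, lambda = lambda, tau = tau, max_iter = max_iter
      )
    ),
    class = "moa_scenario"
  )
}

#' @export
print.moa_scenario <- function(x, ...) {
  cat("<moa_scenario> ", length(x$network$nodes), " nodes; ",
    nrow(x$drug$targets), " targets; ", nrow(x$disease$effectors),
    " effectors (planted reversal ", 100 * x$rho, "%); ",
    nrow(x$restrictions$entries), " restrictions\n",
    sep = ""
  )
  invisible(x)
}

#' Generate two-cohort expression matrices with known ground truth
#'
#' Per-gene values are Gaussian with unit within-group SD around a
#' gene-specific baseline. A stated fraction of genes is truly shifted in
#' the case cohort by `effect_size` SD units, half up and half down at
#' random. Truth labels are returned for recall/FDR evaluation.
#'
#' @param n_genes Number of genes.
#' @param shifted_fraction Fraction of genes truly shifted in cases.
#' @param effect_size Shift size in within-group SD units.
#' @param n_case,n_control Cohort sizes (>= 2).
#' @param seed Integer seed.
#' @return A list with `case` and `control` (gene x sample matrices) and
#'   `truth` (tibble: `gene`, `shifted`, `direction`).
#' @export
sim_expression <- function(n_genes = 500L, shifted_fraction = 0.1,
                           effect_size = 2, n_case = 10L, n_control = 10L,
                           seed = 1L) {
  if (n_case < 2 || n_control < 2) {
    stop("each cohort needs at least 2 samples", call. = FALSE)
  }
  stopifnot(shifted_fraction >= 0, shifted_fraction <= 1)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  baseline <- stats::rnorm(n_genes, mean = 8, sd = 2)
  n_shifted <- round(shifted_fraction * n_genes)
  shifted <- c(rep(TRUE, n_shifted), rep(FALSE, n_genes - n_shifted))
  direction <- integer(n_genes)
  direction[shifted] <- sample(c(-1L, 1L), n_shifted, replace = TRUE)
  control <- matrix(
    stats::rnorm(n_genes * n_control, mean = baseline, sd = 1),
    nrow = n_genes,
    dimnames = list(genes, sprintf("ctrl_%02d", seq_len(n_control)))
  )
  case <- matrix(
    stats::rnorm(n_genes * n_case, mean = baseline + direction * effect_size, sd = 1),
    nrow = n_genes,
    dimnames = list(genes, sprintf("case_%02d", seq_len(n_case)))
  )
  list(
    case = case, control = control,
    truth = tibble::tibble(gene = genes, shifted = shifted, direction = direction)
  )
}

default_bioflag_metadata <- function() {
  tibble::tibble(
    analyte = c("NOS2", "NLRP3", "TGFB1"),
    range_min = c(15.6, 156, 15.6),
    range_max = c(1000, 10000, 1000),
    units = "pg/mL",
    sensitivity = c(5.5, 80, NA_real_)
  )
}

#' Generate a paired bioflag panel with a planted mean decline
#'
#' Baseline concentrations are lognormal around each assay's geometric
#' midrange with multiplicative coefficient of variation `cv`; follow-up
#' values are `baseline * (1 + decline/100)` times mean-one lognormal
#' noise, so the expected delta change of cohort means equals the planted
#' decline.
#'
#' @param n_patients Number of paired patients.
#' @param declines Named numeric vector of planted percent declines per
#'   analyte (negative = decrease). The default panel carries the three
#'   HFpEF bioflags with their published assay ranges.
#' @param cv Multiplicative coefficient of variation (>= 0).
#' @param seed Integer seed.
#' @param metadata Assay metadata tibble (`analyte`, `range_min`,
#'   `range_max`, ...); analytes in `declines` must be present.
#' @return A [bioflag_panel()] with timepoints `baseline` and `month12`.
#' @export
sim_bioflags <- function(n_patients = 20L,
                         declines = c(NOS2 = -14, NLRP3 = -6, TGFB1 = -17),
                         cv = 0.3, seed = 1L,
                         metadata = default_bioflag_metadata()) {
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  if (is.null(names(declines))) stop("`declines` must be named by analyte", call. = FALSE)
  absent <- setdiff(names(declines), metadata$analyte)
  if (length(absent)) {
    stop("no metadata for analyte(s): ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  set.seed(seed)
  rows <- purrr::imap(declines, function(decline, analyte) {
    meta <- metadata[metadata$analyte == analyte, ]
    midrange <- sqrt(meta$range_min * meta$range_max)
    baseline <- stats::rlnorm(n_patients, meanlog = log(midrange), sdlog = cv)
    noise <- exp(stats::rnorm(n_patients, 0, cv) - cv^2 / 2) # mean-one
    followup <- baseline * (1 + decline / 100) * noise
    tibble::tibble(
      patient_id = sprintf("pt_%03d", seq_len(n_patients)),
      analyte = analyte,
      baseline = baseline,
      month12 = followup
    )
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_longer(c("baseline", "month12"),
      names_to = "timepoint", values_to = "concentration"
    )
  bioflag_panel(rows, metadata)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates every input the pipeline reads -- network SIF, drug/disease/
#' restriction TSVs, two-cohort expression CSVs, bioflag CSV with YAML
#' metadata -- plus a `manifest.json` documenting every parameter and
#' seed. Regenerating with the same seed reproduces the bundle
#' byte-identically.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed governing all generators.
#' @param scenario_params,expression_params,bioflag_params Named lists of
#'   overrides passed to [sim_scenario()], [sim_expression()] and
#'   [sim_bioflags()].
#' @return `dir`, invisibly; side effect: files written.
#' @export
write_scenario_bundle <- function(dir, seed = 1L, scenario_params = list(),
                                  expression_params = list(),
                                  bioflag_params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scen <- do.call(sim_scenario, c(list(seed = seed), scenario_params))
  expr <- do.call(sim_expression, c(list(seed = seed + 1L), expression_params))
  panel <- do.call(sim_bioflags, c(list(seed = seed + 2L), bioflag_params))

  write_signed_network(scen$network, file.path(dir, "network.sif"))
  readr::write_tsv(scen$drug$targets, file.path(dir, "drug.tsv"))
  readr::write_tsv(scen$disease$effectors, file.path(dir, "disease.tsv"))
  readr::write_tsv(scen$restrictions$entries, file.path(dir, "restrictions.tsv"))
  write_expression_csv <- function(m, path) {
    df <- tibble::as_tibble(m, rownames = "gene")
    readr::write_csv(df, path)
  }
  write_expression_csv(expr$case, file.path(dir, "expression_case.csv"))
  write_expression_csv(expr$control, file.path(dir, "expression_control.csv"))
  readr::write_csv(expr$truth, file.path(dir, "expression_truth.csv"))
  readr::write_csv(panel$measurements, file.path(dir, "bioflags.csv"))
  meta_list <- split(panel$metadata, panel$metadata$analyte) |>
    purrr::map(function(r) {
      list(
        range_min = r$range_min, range_max = r$range_max,
        units = r$units, sensitivity = r$sensitivity
      )
    })
  yaml::write_yaml(meta_list, file.path(dir, "bioflag_metadata.yaml"))
  manifest <- list(
    seed = seed,
    scenario = scen$params,
    expression = utils::modifyList(
      list(
        n_genes = 500L, shifted_fraction = 0.1, effect_size = 2,
        n_case = 10L, n_control = 10L, seed = seed + 1L
      ),
      expression_params
    ),
    bioflags = utils::modifyList(
      list(
        n_patients = 20L,
        declines = as.list(c(NOS2 = -14, NLRP3 = -6, TGFB1 = -17)),
        cv = 0.3, seed = seed + 2L
      ),
      bioflag_params
    ),
    planted = list(
      rho = scen$rho,
      n_restrictions = nrow(scen$restrictions$entries),
      n_flipped = scen$n_flipped
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
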