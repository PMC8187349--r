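#' Default simulated-annealing schedule
#'
#' Geometric cooling from `t0` by factor `gamma` down to `t_floor`, with
#' `steps` Metropolis proposals per temperature. The defaults are sized for
#' desk-scale networks (a few hundred nodes or fewer).
#'
#' @param t0 Initial temperature (> 0).
#' @param gamma Cooling factor in (0, 1).
#' @param steps Proposals per temperature (>= 1).
#' @param t_floor Floor temperature (> 0, < `t0`).
#' @return A list with the four schedule parameters.
#' @export
anneal_schedule <- function(t0 = 1, gamma = 0.95, steps = 50L, t_floor = 1e-3) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma >= 1) {
    stop("cooling factor `gamma` must lie in (0, 1)", call. = FALSE)
  }
  if (t0 <= 0 || t_floor <= 0 || t_floor >= t0 || steps < 1) {
    stop("invalid annealing schedule", call. = FALSE)
  }
  list(t0 = t0, gamma = gamma, steps = as.integer(steps), t_floor = t_floor)
}

restriction_index <- function(restrictions, nodes) {
  if (!nrow(restrictions$entries)) {
    stop("restriction set is empty; accuracy is undefined", call. = FALSE)
  }
  absent <- setdiff(restrictions$entries$protein, nodes)
  if (length(absent)) {
    stop("restriction protein(s) not in network: ",
      paste(absent, collapse = ", "),
      "; drop them first with prune_restrictions()",
      call. = FALSE
    )
  }
  list(
    idx = match(restrictions$entries$protein, nodes) - 1L,
    sign = restrictions$entries$sign
  )
}

#' Accuracy of a solution model against a restriction set
#'
#' The drug targets are clamped at their modulation signs, the model is
#' propagated, and accuracy is the fraction of restriction entries whose
#' simulated sign matches the required sign. States inside the `eps`
#' dead-band count as unsatisfied: a silent protein achieves no direction.
#'
#' @param model A [solution_model()].
#' @param drug A [drug_profile()].
#' @param restrictions A non-empty [restriction_set()] whose proteins all
#'   exist in the network (see [prune_restrictions()]).
#' @param eps Dead-band below which a state is treated as zero.
#' @return Accuracy in \eqn{[0, 1]}.
#' @export
model_accuracy <- function(model, drug, restrictions, eps = 1e-3) {
  stopifnot(inherits(model, "solution_model"), inherits(restrictions, "restriction_set"))
  ri <- restriction_index(restrictions, model$network$nodes)
  clamps <- stats::setNames(as.numeric(drug$targets$modulation), drug$targets$protein)
  states <- propagate(model, clamps)
  accuracy_cpp(states$state, ri$idx, ri$sign, eps)
}

#' Fit one solution model by simulated annealing
#'
#' Starting from seed-randomised weight magnitudes (edge signs are fixed by
#' the network), single-weight proposals rescale one magnitude by
#' `exp(U(-0.5, 0.5))`, clipped to (0, 1], and are accepted by the
#' Metropolis rule on the objective `1 - accuracy`. The best-ever model is
#' tracked and returned; its objective trace is monotone non-increasing.
#'
#' @inheritParams model_accuracy
#' @param network A [signed_network()].
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed; the run is fully reproducible given it.
#' @param lambda,tau,max_iter Propagation configuration, as in
#'   [solution_model()].
#' @return A [solution_model()] with attributes `accuracy` (best accuracy)
#'   and `objective_trace` (best objective after each temperature).
#' @export
anneal_model <- function(network, drug, restrictions,
                         schedule = anneal_schedule(), seed = NULL,
                         eps = 1e-3, lambda = 0.5, tau = 1e-6, max_iter = 200L) {
  stopifnot(inherits(network, "signed_network"))
  if (!is.null(seed)) set.seed(seed)
  ri <- restriction_index(restrictions, network$nodes)
  m <- nrow(network$edges)
  nodes <- network$nodes
  absent <- setdiff(drug$targets$protein, nodes)
  if (length(absent)) {
    stop("drug target(s) not in network: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  w0 <- network$edges$sign * pmax(stats::runif(m), 1e-6)
  fit <- anneal_cpp(
    length(nodes),
    match(network$edges$from, nodes) - 1L,
    match(network$edges$to, nodes) - 1L,
    network$edges$sign, w0, numeric(length(nodes)),
    match(drug$targets$protein, nodes) - 1L,
    as.numeric(drug$targets$modulation),
    ri$idx, ri$sign,
    eps, lambda, tau, as.integer(max_iter),
    schedule$t0, schedule$gamma, schedule$steps, schedule$t_floor
  )
  model <- solution_model(network,
    weights = fit$weights,
    lambda = lambda, tau = tau, max_iter = max_iter
  )
  attr(model, "accuracy") <- fit$accuracy
  attr(model, "objective_trace") <- fit$objective_trace
  model
}

#' Fit an ensemble of plausible solution models
#'
#' Runs `n_models` independent annealing fits with per-run seeds derived
#' deterministically from the global seed, mirroring the practice of
#' summarising a mechanism by the agreement of many independently trained
#' solutions rather than a single fit.
#'
#' @inheritParams anneal_model
#' @param n_models Ensemble size (>= 1).
#' @param seed Global integer seed.
#' @return An object of class `model_ensemble`: models, per-model
#'   accuracies, run seeds, schedule and the restriction set used. Use
#'   [tidy()][generics::tidy] and [glance()][generics::glance] to inspect.
#' @export
fit_ensemble <- function(network, drug, restrictions, n_models = 250L,
                         seed = 1L, schedule = anneal_schedule(),
                         eps = 1e-3, lambda = 0.5, tau = 1e-6, max_iter = 200L) {
  stopifnot(n_models >= 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_models)
  models <- purrr::map(run_seeds, function(s) {
    anneal_model(network, drug, restrictions,
      schedule = schedule, seed = s,
      eps = eps, lambda = lambda, tau = tau, max_iter = max_iter
    )
  })
  structure(
    list(
      models = models,
      accuracies = purrr::map_dbl(models, attr, "accuracy"),
      seed = as.integer(seed),
      run_seeds = run_seeds,
      schedule = schedule,
      eps = eps,
      drug = drug,
      restrictions = restrictions
    ),
    class = "model_ensemble"
  )
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("<model_ensemble> ", length(x$models), " solution(s); mean accuracy ",
    sprintf("%.3f", mean(x$accuracies)), " (sd ",
    sprintf("%.3f", stats::sd(x$accuracies)), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model ensemble
#'
#' @param x A `model_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per solution: `model`, `seed`, `accuracy`.
#' @export
tidy.model_ensemble <- function(x, ...) {
  tibble::tibble(
    model = seq_along(x$models),
    seed = x$run_seeds,
    accuracy = x$accuracies
  )
}

#' One-row ensemble summary
#'
#' @param x A `model_ensemble`.
#' @param ... Unused.
#' @return A tibble with `n_models`, `mean_accuracy`, `sd_accuracy`,
#'   `min_accuracy`, `max_accuracy`.
#' @export
glance.model_ensemble <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$models),
    mean_accuracy = mean(x$accuracies),
    sd_accuracy = stats::sd(x$accuracies),
    min_accuracy = min(x$accuracies),
    max_accuracy = max(x$accuracies)
  )
}

#' Persist an ensemble as a directory of model files
#'
#' Writes one JSON per solution plus a `manifest.json` recording the global
#' seed, per-run seeds, schedule, accuracies and the restriction entries
#' the ensemble was trained against.
#'
#' @param ensemble A `model_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("model_%03d.json", seq_along(ensemble$models)))
  purrr::walk2(ensemble$models, paths, write_solution_model)
  manifest <- list(
    n_models = length(ensemble$models),
    seed = ensemble$seed,
    run_seeds = ensemble$run_seeds,
    schedule = ensemble$schedule,
    eps = ensemble$eps,
    accuracies = ensemble$accuracies,
    drug = list(
      name = ensemble$drug$name,
      targets = as.data.frame(ensemble$drug$targets)
    ),
    restrictions = list(
      provenance = ensemble$restrictions$provenance,
      entries = as.data.frame(ensemble$restrictions$entries)
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' @param dir Ensemble directory.
#' @return A `model_ensemble`.
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  paths <- file.path(dir, sprintf("model_%03d.json", seq_len(manifest$n_models)))
  structure(
    list(
      models = purrr::map(paths, read_solution_model),
      accuracies = manifest$accuracies,
      seed = manifest$seed,
      run_seeds = manifest$run_seeds,
      schedule = manifest$schedule,
      eps = manifest$eps,
      drug = drug_profile(manifest$drug$name, manifest$drug$targets),
      restrictions = restriction_set(
        manifest$restrictions$entries,
        manifest$restrictions$provenance
      )
    ),
    class = "model_ensemble"
  )
}
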