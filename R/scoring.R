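#' Intensity of response: the effector sign-reversal statistic
#'
#' A drug is expected to revert a disease phenotype: inactivate its
#' pathologically active effectors and activate the inactive ones. With
#' `v_i` the pathological sign of effector `i` and `y_i` its simulated
#' activity under the drug, the number of effectors achieving the expected
#' (opposite) signal is
#' \deqn{\#Eff = \sum_{i=1}^{n} \delta\!\left(\frac{v_i}{|v_i|} + \frac{y_i}{|y_i|}\right)}
#' where \eqn{\delta(0) = 1} and 0 otherwise: the delta fires exactly when
#' the two unit signs cancel. Effectors with \eqn{|y_i|} inside the `eps`
#' dead-band contribute 0 (the formula's \eqn{y_i/|y_i|} is undefined at 0;
#' a silent effector does not achieve the expected signal). The intensity
#' is reported as `100 * #Eff / n`, overall and per motif.
#'
#' @param outputs An `effector_outputs` tibble from [simulate_drug()], or
#'   any data frame with columns `protein`, `motif`, `v`, `y`.
#' @param motif Optional motif label to restrict the result to; must be one
#'   of the motifs present.
#' @param eps Dead-band below which `y` is treated as zero.
#' @return A tibble of class `intensity_result` with columns `motif`
#'   (including an `"overall"` row unless `motif` was given), `n`,
#'   `eff_count` and `percent`.
#' @examples
#' out <- tibble::tibble(
#'   protein = c("P1", "P2", "P3"),
#'   motif = "m1",
#'   v = c(1, 1, -1),
#'   y = c(-0.4, 0.2, 0.9)
#' )
#' intensity(out) # 2 of 3 reversed
#' @export
intensity <- function(outputs, motif = NULL, eps = 1e-3) {
  outputs <- tibble::as_tibble(outputs)
  stopifnot(all(c("motif", "v", "y") %in% names(outputs)))
  if (!is.null(motif)) {
    if (!motif %in% outputs$motif) {
      stop("motif '", motif, "' not present in outputs", call. = FALSE)
    }
    outputs <- outputs[outputs$motif == motif, ]
  }
  reversed <- abs(outputs$y) >= eps & sign(outputs$y) == -outputs$v
  per_motif <- outputs |>
    dplyr::mutate(reversed = reversed) |>
    dplyr::summarise(
      n = dplyr::n(), eff_count = sum(.data$reversed),
      .by = "motif"
    )
  res <- if (is.null(motif)) {
    dplyr::bind_rows(
      tibble::tibble(
        motif = "overall", n = nrow(outputs), eff_count = sum(reversed)
      ),
      per_motif
    )
  } else {
    per_motif
  }
  res$percent <- 100 * res$eff_count / res$n
  class(res) <- c("intensity_result", class(res))
  res
}

#' Ensemble-averaged intensity of response
#'
#' Simulates the drug under every solution in the ensemble and averages
#' the per-motif intensity percentages over solutions.
#'
#' @param ensemble A `model_ensemble` from [fit_ensemble()].
#' @param drug A [drug_profile()]; defaults to the drug the ensemble was
#'   trained with.
#' @param disease A [disease_profile()].
#' @param eps Dead-band below which a state is treated as zero.
#' @return A tibble of class `intensity_result` with columns `motif`, `n`,
#'   `eff_count` (mean over solutions) and `percent` (mean over solutions).
#' @export
ensemble_intensity <- function(ensemble, disease, drug = ensemble$drug, eps = ensemble$eps) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  per_model <- purrr::map(ensemble$models, function(m) {
    intensity(simulate_drug(m, drug, disease), eps = eps)
  })
  res <- dplyr::bind_rows(per_model) |>
    dplyr::summarise(
      n = .data$n[1],
      eff_count = mean(.data$eff_count),
      percent = mean(.data$percent),
      .by = "motif"
    )
  class(res) <- c("intensity_result", class(res))
  res
}

#' Per-target contribution to the drug's intensity
#'
#' Ablates the drug down to a single target (keeping its modulation sign),
#' re-simulates every ensemble solution, and reports the mean intensity per
#' motif -- the in-silico analogue of asking which target carries the
#' drug's effect.
#'
#' @inheritParams ensemble_intensity
#' @param targets Character vector of target proteins to evaluate; defaults
#'   to every target in the drug profile. Each must be a drug target.
#' @return A tibble of class `target_contribution` with columns `target`,
#'   `motif`, `n` and `percent`.
#' @export
target_contribution <- function(ensemble, disease, targets = NULL,
                                drug = ensemble$drug, eps = ensemble$eps) {
  stopifnot(inherits(ensemble, "model_ensemble"), inherits(drug, "drug_profile"))
  if (is.null(targets)) targets <- drug$targets$protein
  absent <- setdiff(targets, drug$targets$protein)
  if (length(absent)) {
    stop("not a target of ", drug$name, ": ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  res <- purrr::map(targets, function(tg) {
    reduced <- drug_profile(
      paste0(drug$name, ":", tg),
      drug$targets[drug$targets$protein == tg, ]
    )
    out <- ensemble_intensity(ensemble, disease, drug = reduced, eps = eps)
    dplyr::mutate(tibble::as_tibble(out), target = tg, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("target", "motif", "n", "percent")
  class(res) <- c("target_contribution", class(res))
  res
}

#' Benchmark several drugs on one disease model
#'
#' Evaluates each drug's overall and per-motif intensity on the shared
#' network and restriction set, training one solution ensemble per drug
#' (or using a caller-supplied factory, e.g. to reuse cached ensembles).
#' Drugs failing validation against the network are reported in the
#' `status` column and skipped; the others proceed.
#'
#' @param network A [signed_network()].
#' @param drugs A list of [drug_profile()] objects.
#' @param disease A [disease_profile()].
#' @param restrictions A [restriction_set()].
#' @param n_models Ensemble size per drug.
#' @param seed Global seed; per-drug seeds are derived from it.
#' @param ensemble_factory Optional `function(drug, seed)` returning a
#'   `model_ensemble`; defaults to [fit_ensemble()] with the arguments
#'   above.
#' @param eps Dead-band below which a state is treated as zero.
#' @return A tibble of class `moa_benchmark` with columns `drug`, `status`
#'   (`"ok"` or the validation failure), `motif`, `n`, `percent` and
#'   `mean_accuracy`.
#' @export
benchmark_drugs <- function(network, drugs, disease, restrictions,
                            n_models = 25L, seed = 1L,
                            ensemble_factory = NULL, eps = 1e-3) {
  if (!length(drugs)) {
    out <- tibble::tibble(
      drug = character(), status = character(), motif = character(),
      n = integer(), percent = numeric(), mean_accuracy = numeric()
    )
    class(out) <- c("moa_benchmark", class(out))
    return(out)
  }
  set.seed(seed)
  drug_seeds <- sample.int(.Machine$integer.max - 1L, length(drugs))
  if (is.null(ensemble_factory)) {
    ensemble_factory <- function(drug, seed) {
      fit_ensemble(network, drug, restrictions,
        n_models = n_models, seed = seed, eps = eps
      )
    }
  }
  rows <- purrr::map2(drugs, drug_seeds, function(drug, ds) {
    report <- validate_inputs(network, drug, disease, restrictions)
    fatal <- report[report$level == "fatal", ]
    if (nrow(fatal)) {
      return(tibble::tibble(
        drug = drug$name,
        status = paste0(
          "invalid: ", paste(unique(fatal$protein), collapse = ", "),
          " absent from network"
        ),
        motif = NA_character_, n = NA_integer_,
        percent = NA_real_, mean_accuracy = NA_real_
      ))
    }
    ens <- ensemble_factory(drug, ds)
    int <- ensemble_intensity(ens, disease, drug = drug, eps = eps)
    tibble::tibble(
      drug = drug$name, status = "ok",
      motif = int$motif, n = int$n, percent = int$percent,
      mean_accuracy = mean(ens$accuracies)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("moa_benchmark", class(out))
  out
}

#' Network proximity score between two protein sets
#'
#' The observed statistic is the mean, over proteins in `set_a`, of the
#' shortest undirected path length to the nearest protein of `set_b`. A
#' null distribution is built from degree-preserving random draws: each set
#' is relabelled within log2-degree bins, keeping set sizes and the degree
#' profile. The score is the percentage of null draws whose statistic is at
#' least the observed one (ties count), so 100 means the sets are as close
#' as or closer than every null draw. Unreachable pairs contribute the
#' network diameter plus one.
#'
#' @param network A [signed_network()].
#' @param set_a,set_b Non-empty character vectors of proteins present in
#'   the network.
#' @param n_null Number of null draws (default 1000). With `n_null = 0`
#'   the raw distance is returned and `score` is `NA`.
#' @param seed Optional seed for the null draws.
#' @return A one-row tibble: `observed` (mean nearest distance), `score`
#'   (percentile in [0, 100], `NA` if `n_null = 0`) and `n_null`.
#' @export
proximity_score <- function(network, set_a, set_b, n_null = 1000L, seed = NULL) {
  stopifnot(inherits(network, "signed_network"))
  if (!length(set_a) || !length(set_b)) {
    stop("both protein sets must be non-empty", call. = FALSE)
  }
  absent <- setdiff(c(set_a, set_b), network$nodes)
  if (length(absent)) {
    stop("protein(s) not in network: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(network)
  d <- igraph::distances(g, mode = "all")
  finite <- d[is.finite(d)]
  cap <- max(finite) + 1 # unreachable pairs: diameter + 1
  d[!is.finite(d)] <- cap

  stat <- function(a, b) mean(apply(d[a, b, drop = FALSE], 1, min))
  observed <- stat(set_a, set_b)
  if (n_null < 1) {
    return(tibble::tibble(observed = observed, score = NA_real_, n_null = 0L))
  }

  deg <- igraph::degree(g, mode = "all")
  bins <- floor(log2(pmax(deg, 1)))
  bin_members <- split(network$nodes, bins[network$nodes])
  draw_like <- function(set) {
    unlist(lapply(split(set, bins[set]), function(members) {
      pool <- bin_members[[as.character(bins[members[1]])]]
      sample(pool, length(members), replace = length(pool) < length(members))
    }), use.names = FALSE)
  }
  null_stats <- vapply(
    seq_len(n_null),
    function(i) stat(draw_like(set_a), draw_like(set_b)),
    numeric(1)
  )
  tibble::tibble(
    observed = observed,
    score = 100 * mean(null_stats >= observed),
    n_null = as.integer(n_null)
  )
}
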