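#' Per-edge ensemble support statistics
#'
#' For every network edge, computes its mean absolute weight across the
#' ensemble and its support: the fraction of solutions in which the edge
#' lies on at least one directed target-to-effector path whose edges all
#' carry a magnitude of at least `w_min`. Support operationalises "most
#' probable mechanism" as ensemble agreement.
#'
#' @param ensemble A non-empty `model_ensemble`.
#' @param disease A [disease_profile()].
#' @param drug A [drug_profile()]; defaults to the ensemble's drug.
#' @param w_min Weight-magnitude threshold for an edge to count as active
#'   within one solution.
#' @return A tibble with columns `from`, `to`, `sign`, `mean_abs_weight`
#'   and `support`.
#' @export
edge_support <- function(ensemble, disease, drug = ensemble$drug, w_min = 0.1) {
  stopifnot(inherits(ensemble, "model_ensemble"), length(ensemble$models) >= 1)
  net <- ensemble$models[[1]]$network
  nodes <- net$nodes
  targets <- intersect(drug$targets$protein, nodes)
  effectors <- intersect(disease$effectors$protein, nodes)
  m <- nrow(net$edges)
  on_path_count <- numeric(m)
  abs_w_sum <- numeric(m)
  for (model in ensemble$models) {
    w <- model$weights
    abs_w_sum <- abs_w_sum + abs(w)
    active <- abs(w) >= w_min
    sub <- igraph::graph_from_data_frame(
      as.data.frame(net$edges[active, c("from", "to")]),
      directed = TRUE, vertices = data.frame(name = nodes)
    )
    reach_fwd <- if (length(targets)) {
      unique(unlist(lapply(
        igraph::ego(sub, order = length(nodes), nodes = targets, mode = "out"),
        names
      )))
    } else {
      character()
    }
    reach_bwd <- if (length(effectors)) {
      unique(unlist(lapply(
        igraph::ego(sub, order = length(nodes), nodes = effectors, mode = "in"),
        names
      )))
    } else {
      character()
    }
    # an active edge (u, v) lies on a target->effector path iff u is
    # reachable from a target and v reaches an effector in the active graph
    on_path <- active &
      net$edges$from %in% reach_fwd &
      net$edges$to %in% reach_bwd
    on_path_count <- on_path_count + on_path
  }
  tibble::tibble(
    from = net$edges$from, to = net$edges$to, sign = net$edges$sign,
    mean_abs_weight = abs_w_sum / length(ensemble$models),
    support = on_path_count / length(ensemble$models)
  )
}

#' Extract the most-supported mechanism-of-action subnetwork
#'
#' For each (target, effector) pair, enumerates simple directed paths up to
#' `max_hops` long, scores each path by the product of its edge supports,
#' and retains the `k_paths` best-supported paths (ties broken by shorter
#' path, then lexicographic node order). Edges with support below
#' `min_support` are pruned from the result, and nodes are tagged by role:
#' target, effector or intermediate.
#'
#' @param network A [signed_network()].
#' @param supports Edge-support tibble from [edge_support()].
#' @param drug A [drug_profile()].
#' @param disease A [disease_profile()].
#' @param k_paths Paths kept per (target, effector) pair (>= 1).
#' @param min_support Support threshold for retained edges, in [0, 1].
#' @param max_hops Length cap for enumerated simple paths.
#' @return An object of class `moa_subnetwork`: a list with `nodes`
#'   (tibble: `protein`, `role`) and `edges` (tibble: `from`, `to`, `sign`,
#'   `mean_abs_weight`, `support`). Empty (with a warning) if no path
#'   survives.
#' @export
extract_moa <- function(network, supports, drug, disease,
                        k_paths = 3L, min_support = 0.5, max_hops = 8L) {
  stopifnot(inherits(network, "signed_network"), k_paths >= 1)
  g <- as_igraph(network)
  edge_key <- paste(supports$from, supports$to, sep = "\r")
  sup <- stats::setNames(supports$support, edge_key)
  targets <- intersect(drug$targets$protein, network$nodes)
  effectors <- intersect(disease$effectors$protein, network$nodes)

  kept_edges <- character()
  for (tg in sort(targets)) {
    for (ef in sort(effectors)) {
      if (tg == ef) next
      paths <- igraph::all_simple_paths(g, from = tg, to = ef,
        mode = "out", cutoff = max_hops
      )
      if (!length(paths)) next
      scored <- purrr::map(paths, function(p) {
        nm <- names(p)
        keys <- paste(nm[-length(nm)], nm[-1], sep = "\r")
        list(
          keys = keys,
          support = prod(sup[keys]),
          len = length(keys),
          lex = paste(nm, collapse = "\r")
        )
      })
      ord <- order(
        -purrr::map_dbl(scored, "support"),
        purrr::map_int(scored, "len"),
        purrr::map_chr(scored, "lex")
      )
      top <- scored[ord[seq_len(min(k_paths, length(scored)))]]
      kept_edges <- c(kept_edges, unlist(purrr::map(top, "keys")))
    }
  }
  kept_edges <- unique(kept_edges)
  kept_edges <- kept_edges[sup[kept_edges] >= min_support]

  if (!length(kept_edges)) {
    warning("no target-to-effector path survives the support threshold",
      call. = FALSE
    )
    out <- list(
      nodes = tibble::tibble(protein = character(), role = character()),
      edges = supports[0, ]
    )
    class(out) <- "moa_subnetwork"
    return(out)
  }
  edges <- supports[edge_key %in% kept_edges, ]
  prots <- sort(unique(c(edges$from, edges$to)))
  nodes <- tibble::tibble(
    protein = prots,
    role = dplyr::case_when(
      prots %in% targets ~ "target",
      prots %in% effectors ~ "effector",
      TRUE ~ "intermediate"
    )
  )
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "moa_subnetwork"
  out
}

#' @export
print.moa_subnetwork <- function(x, ...) {
  cat("<moa_subnetwork> ", nrow(x$nodes), " nodes (",
    sum(x$nodes$role == "target"), " targets, ",
    sum(x$nodes$role == "effector"), " effectors), ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}

moa_igraph <- function(sub) {
  igraph::graph_from_data_frame(
    as.data.frame(dplyr::rename(sub$edges,
      interaction = "sign",
      support = "support", mean_abs_weight = "mean_abs_weight"
    )),
    directed = TRUE,
    vertices = as.data.frame(dplyr::rename(sub$nodes, name = "protein"))
  )
}

#' Export a mechanism-of-action subnetwork
#'
#' Writes the subnetwork in one of three formats. `"sif"` writes an
#' activates/inhibits edge list plus a TSV attribute sidecar
#' (`<path>.attrs.tsv` with support and mean absolute weight per edge) and
#' reloads losslessly via [read_moa_sif()]. `"graphml"` and `"dot"` carry
#' sign, support and weight as edge attributes for rendering tools.
#'
#' @param sub A `moa_subnetwork` from [extract_moa()].
#' @param path Output path.
#' @param format One of `"sif"`, `"graphml"`, `"dot"`.
#' @return `path`, invisibly.
#' @export
export_moa <- function(sub, path, format = c("sif", "graphml", "dot")) {
  stopifnot(inherits(sub, "moa_subnetwork"))
  format <- tryCatch(match.arg(format),
    error = function(e) stop("unknown export format", call. = FALSE)
  )
  if (format == "sif") {
    token <- ifelse(sub$edges$sign > 0, "activates", "inhibits")
    writeLines(paste(sub$edges$from, token, sub$edges$to, sep = "\t"), path)
    attrs <- dplyr::mutate(sub$edges,
      role_from = sub$nodes$role[match(.data$from, sub$nodes$protein)],
      role_to = sub$nodes$role[match(.data$to, sub$nodes$protein)]
    )
    readr::write_tsv(attrs, paste0(path, ".attrs.tsv"))
  } else if (format == "graphml") {
    igraph::write_graph(moa_igraph(sub), path, format = "graphml")
  } else {
    igraph::write_graph(moa_igraph(sub), path, format = "dot")
  }
  invisible(path)
}

#' Read a SIF-exported mechanism subnetwork back
#'
#' @param path Path previously written by [export_moa()] with
#'   `format = "sif"`; the `.attrs.tsv` sidecar must sit next to it.
#' @return A `moa_subnetwork`.
#' @export
read_moa_sif <- function(path) {
  attrs <- readr::read_tsv(paste0(path, ".attrs.tsv"),
    col_types = readr::cols(
      from = readr::col_character(), to = readr::col_character(),
      sign = readr::col_integer(), mean_abs_weight = readr::col_double(),
      support = readr::col_double(),
      role_from = readr::col_character(), role_to = readr::col_character()
    )
  )
  nodes <- dplyr::bind_rows(
    tibble::tibble(protein = attrs$from, role = attrs$role_from),
    tibble::tibble(protein = attrs$to, role = attrs$role_to)
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$protein)
  out <- list(
    nodes = nodes,
    edges = dplyr::select(attrs, "from", "to", "sign", "mean_abs_weight", "support")
  )
  class(out) <- "moa_subnetwork"
  out
}
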