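#' Construct a signed directed protein network
#'
#' A signed network is a directed graph over protein identifiers in which
#' every edge carries a sign: `+1` for activation, `-1` for inhibition.
#' Identifiers are opaque, case-sensitive strings; no mapping to external
#' nomenclatures is attempted.
#'
#' @param edges A data frame with columns `from`, `to` and `sign`
#'   (`+1`/`-1`, or the tokens `"activates"`/`"inhibits"`).
#' @param nodes Optional character vector of node identifiers. Nodes
#'   appearing in `edges` are always included; `nodes` may add isolated ones.
#' @param allow_self_loops Permit edges with `from == to`. Off by default:
#'   autoregulatory loops are usually curation artefacts in signed networks.
#'
#' @return An object of class `signed_network`: a list with `edges`
#'   (tibble: `from`, `to`, `sign`) and `nodes` (character vector).
#' @examples
#' net <- signed_network(data.frame(
#'   from = c("A", "B"), to = c("B", "C"), sign = c(1, -1)
#' ))
#' net
#' @export
signed_network <- function(edges = NULL, nodes = character(), allow_self_loops = FALSE) {
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character(), sign = integer())
  }
  edges <- tibble::as_tibble(edges)
  required <- c("from", "to", "sign")
  if (!all(required %in% names(edges))) {
    stop("`edges` must have columns from, to, sign", call. = FALSE)
  }
  edges <- dplyr::select(edges, dplyr::all_of(required))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- parse_sign(edges$sign)
  if (anyNA(edges$sign)) {
    stop("edge signs must be +1/-1 or activates/inhibits", call. = FALSE)
  }
  if (!allow_self_loops && any(edges$from == edges$to)) {
    bad <- edges$from[edges$from == edges$to][1]
    stop("self-loop on node '", bad, "' (set allow_self_loops = TRUE to permit)",
      call. = FALSE
    )
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- split(edges$sign, key)
    conflicting <- names(dup)[vapply(dup, function(s) length(unique(s)) > 1L, logical(1))]
    if (length(conflicting)) {
      pair <- strsplit(conflicting[1], "\r", fixed = TRUE)[[1]]
      stop("conflicting signs for edge ", pair[1], " -> ", pair[2], call. = FALSE)
    }
    edges <- edges[!duplicated(key), ]
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(
    list(edges = dplyr::arrange(edges, .data$from, .data$to), nodes = nodes),
    class = "signed_network"
  )
}

parse_sign <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
    out[!out %in% c(-1L, 1L)] <- NA_integer_
    return(out)
  }
  x <- tolower(trimws(as.character(x)))
  dplyr::case_match(
    x,
    c("1", "+1", "activates", "activate", "activation", "up", "active") ~ 1L,
    c("-1", "−1", "inhibits", "inhibit", "inhibition", "down", "inactive") ~ -1L,
    .default = NA_integer_
  )
}

#' @export
print.signed_network <- function(x, ...) {
  n_inh <- sum(x$edges$sign == -1L)
  cat(
    "<signed_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
    " edges (", n_inh, " inhibitory)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as_tibble.signed_network <- function(x, ...) x$edges

#' Read a signed network from a SIF-dialect edge list
#'
#' Accepts tab-separated rows `source  interaction  target` where
#' `interaction` is `activates`/`inhibits` or `+1`/`-1`. Row order does not
#' affect the result. Duplicate `(source, target)` pairs with conflicting
#' signs are an error; exact duplicates are collapsed.
#'
#' @param path Path to the edge-list file.
#' @inheritParams signed_network
#' @return A [signed_network()].
#' @export
read_signed_network <- function(path, allow_self_loops = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(signed_network())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed network row at line ", bad[1],
      ": expected 3 tab-separated fields",
      call. = FALSE
    )
  }
  m <- do.call(rbind, parts)
  sg <- parse_sign(m[, 2])
  if (anyNA(sg)) {
    stop("unknown interaction token at line ", which(is.na(sg))[1], call. = FALSE)
  }
  signed_network(
    tibble::tibble(from = m[, 1], to = m[, 3], sign = sg),
    allow_self_loops = allow_self_loops
  )
}

#' Write a signed network as a SIF-dialect edge list
#'
#' @param network A [signed_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signed_network <- function(network, path) {
  stopifnot(inherits(network, "signed_network"))
  token <- ifelse(network$edges$sign > 0, "activates", "inhibits")
  writeLines(paste(network$edges$from, token, network$edges$to, sep = "\t"), path)
  invisible(path)
}

#' Convert a signed network to an igraph object
#'
#' Edge signs are carried in the `sign` edge attribute.
#'
#' @param network A [signed_network()].
#' @return An [igraph::igraph] directed graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  igraph::graph_from_data_frame(
    as.data.frame(network$edges),
    directed = TRUE,
    vertices = data.frame(name = network$nodes)
  )
}

#' Cross-validate pipeline inputs against a network
#'
#' Checks that drug targets and disease effectors exist in the network
#' (fatal findings), that restriction proteins exist (warnings -- such
#' entries are dropped downstream), and that every effector is reachable
#' from at least one drug target along directed edges (warnings).
#'
#' @param network A [signed_network()].
#' @param drug A [drug_profile()].
#' @param disease A [disease_profile()].
#' @param restrictions A [restriction_set()] or `NULL`.
#' @return A tibble of class `validation_report` with columns `level`
#'   (`"fatal"`/`"warning"`), `check` and `protein`. Zero rows means all
#'   checks passed.
#' @export
validate_inputs <- function(network, drug, disease, restrictions = NULL) {
  stopifnot(inherits(network, "signed_network"))
  findings <- list()
  missing_targets <- setdiff(drug$targets$protein, network$nodes)
  if (length(missing_targets)) {
    findings <- c(findings, list(tibble::tibble(
      level = "fatal", check = "target_in_network", protein = missing_targets
    )))
  }
  missing_eff <- setdiff(disease$effectors$protein, network$nodes)
  if (length(missing_eff)) {
    findings <- c(findings, list(tibble::tibble(
      level = "fatal", check = "effector_in_network", protein = missing_eff
    )))
  }
  if (!is.null(restrictions)) {
    missing_res <- setdiff(restrictions$entries$protein, network$nodes)
    if (length(missing_res)) {
      findings <- c(findings, list(tibble::tibble(
        level = "warning", check = "restriction_in_network", protein = missing_res
      )))
    }
  }
  present_targets <- intersect(drug$targets$protein, network$nodes)
  present_eff <- intersect(disease$effectors$protein, network$nodes)
  if (length(present_targets) && length(present_eff)) {
    g <- as_igraph(network)
    reach <- unique(unlist(lapply(
      igraph::ego(g, order = length(network$nodes), nodes = present_targets, mode = "out"),
      names
    )))
    unreachable <- setdiff(present_eff, reach)
    if (length(unreachable)) {
      findings <- c(findings, list(tibble::tibble(
        level = "warning", check = "effector_reachable", protein = unreachable
      )))
    }
  }
  out <- if (length(findings)) {
    dplyr::bind_rows(findings)
  } else {
    tibble::tibble(level = character(), check = character(), protein = character())
  }
  class(out) <- c("validation_report", class(out))
  out
}
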