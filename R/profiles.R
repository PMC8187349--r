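#' Construct a drug profile
#'
#' A drug is represented by its direct protein targets, each with a
#' modulation sign (`+1` the drug activates the target, `-1` it inhibits
#' it), plus an optional list of bioflag proteins: circulating analytes
#' used as observable proxies of the predicted effect.
#'
#' @param name Drug name.
#' @param targets Data frame with columns `protein` and `modulation`
#'   (`+1`/`-1` or `activate`/`inhibit` tokens).
#' @param bioflags Optional character vector of bioflag protein names.
#' @return An object of class `drug_profile`.
#' @examples
#' empagliflozin_like <- drug_profile(
#'   "empagliflozin",
#'   data.frame(
#'     protein = c("SGLT2", "NHE1", "NHE3"),
#'     modulation = c(-1, -1, -1)
#'   )
#' )
#' @export
drug_profile <- function(name, targets, bioflags = character()) {
  targets <- tibble::as_tibble(targets)
  if (!all(c("protein", "modulation") %in% names(targets))) {
    stop("`targets` must have columns protein, modulation", call. = FALSE)
  }
  targets <- dplyr::transmute(
    targets,
    protein = as.character(.data$protein),
    modulation = parse_sign(.data$modulation)
  )
  if (!nrow(targets)) stop("drug profile needs at least one target", call. = FALSE)
  if (anyNA(targets$modulation)) {
    stop("unknown modulation token in drug profile", call. = FALSE)
  }
  if (anyDuplicated(targets$protein)) {
    stop("duplicate target protein '",
      targets$protein[duplicated(targets$protein)][1], "' in drug profile",
      call. = FALSE
    )
  }
  structure(
    list(name = as.character(name), targets = targets, bioflags = as.character(bioflags)),
    class = "drug_profile"
  )
}

#' @export
print.drug_profile <- function(x, ...) {
  cat("<drug_profile> ", x$name, ": ", nrow(x$targets), " target(s), ",
    length(x$bioflags), " bioflag(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Construct a disease profile
#'
#' A disease phenotype is characterised by protein effectors, each carrying
#' a pathological sign `v` (`+1` pathologically active, `-1` pathologically
#' inactive) and a pathophysiological motif label grouping effectors into
#' named processes (e.g. oxidative stress, systemic inflammation). A
#' successful drug is expected to reverse the pathological sign of its
#' effectors.
#'
#' @param name Disease name.
#' @param effectors Data frame with columns `protein`, `sign` and `motif`.
#' @return An object of class `disease_profile` with `effectors` (tibble)
#'   and `motifs` (character vector, in first-appearance order).
#' @export
disease_profile <- function(name, effectors) {
  effectors <- tibble::as_tibble(effectors)
  if (!all(c("protein", "sign", "motif") %in% names(effectors))) {
    stop("`effectors` must have columns protein, sign, motif", call. = FALSE)
  }
  effectors <- dplyr::transmute(
    effectors,
    protein = as.character(.data$protein),
    sign = parse_sign(.data$sign),
    motif = as.character(.data$motif)
  )
  if (anyNA(effectors$sign)) {
    stop("unknown pathological sign token in disease profile", call. = FALSE)
  }
  if (anyDuplicated(effectors$protein)) {
    stop("duplicate effector protein '",
      effectors$protein[duplicated(effectors$protein)][1], "' in disease profile",
      call. = FALSE
    )
  }
  structure(
    list(
      name = as.character(name),
      effectors = effectors,
      motifs = unique(effectors$motif)
    ),
    class = "disease_profile"
  )
}

#' @export
print.disease_profile <- function(x, ...) {
  cat("<disease_profile> ", x$name, ": ", nrow(x$effectors), " effector(s) in ",
    length(x$motifs), " motif(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Construct a restriction set
#'
#' Restrictions are required output signs for proteins -- typically the
#' up/down direction of differentially expressed genes -- used to frame
#' model training: a solution model is scored by the fraction of
#' restrictions whose simulated sign matches the required one.
#'
#' @param entries Data frame with columns `protein` and `sign`
#'   (`+1`/up, `-1`/down).
#' @param provenance Either `"manual"` or `"derived-from-expression"`.
#' @return An object of class `restriction_set`.
#' @export
restriction_set <- function(entries, provenance = c("manual", "derived-from-expression")) {
  provenance <- match.arg(provenance)
  entries <- tibble::as_tibble(entries)
  if (!all(c("protein", "sign") %in% names(entries))) {
    stop("`entries` must have columns protein, sign", call. = FALSE)
  }
  entries <- dplyr::transmute(
    entries,
    protein = as.character(.data$protein),
    sign = parse_sign(.data$sign)
  )
  if (anyNA(entries$sign)) stop("unknown sign token in restriction set", call. = FALSE)
  if (anyDuplicated(entries$protein)) {
    dup <- entries$protein[duplicated(entries$protein)][1]
    stop("duplicate restriction for protein '", dup, "'", call. = FALSE)
  }
  structure(
    list(entries = entries, provenance = provenance),
    class = "restriction_set"
  )
}

#' @export
print.restriction_set <- function(x, ...) {
  cat("<restriction_set> ", nrow(x$entries), " entries (", x$provenance, ")\n", sep = "")
  invisible(x)
}

read_signed_tsv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path,
      call. = FALSE
    )
  }
  df
}

#' Read a drug profile from TSV
#'
#' Expects columns `protein` and `modulation`; an optional `bioflag` column
#' (values `yes`/`no`) marks rows that are bioflags rather than targets.
#'
#' @param path TSV path.
#' @param name Drug name; defaults to the file stem.
#' @return A [drug_profile()].
#' @export
read_drug_profile <- function(path, name = NULL) {
  df <- read_signed_tsv(path, c("protein", "modulation"))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  bioflags <- character()
  if ("bioflag" %in% names(df)) {
    is_bf <- tolower(df$bioflag) %in% c("yes", "true", "1")
    bioflags <- df$protein[is_bf]
    df <- df[!is_bf, ]
  }
  drug_profile(name, df, bioflags)
}

#' Read a disease profile from TSV
#'
#' Expects columns `protein`, `sign` and `motif`.
#'
#' @inheritParams read_drug_profile
#' @return A [disease_profile()].
#' @export
read_disease_profile <- function(path, name = NULL) {
  df <- read_signed_tsv(path, c("protein", "sign", "motif"))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  disease_profile(name, df)
}

#' Read a restriction set from TSV
#'
#' Expects columns `protein` and `sign`.
#'
#' @param path TSV path.
#' @param provenance Provenance tag recorded on the result.
#' @return A [restriction_set()].
#' @export
read_restriction_set <- function(path, provenance = "manual") {
  df <- read_signed_tsv(path, c("protein", "sign"))
  restriction_set(df, provenance)
}

#' Read drug, disease and restriction inputs together
#'
#' Convenience loader for the three profile files of a study.
#'
#' @param drug_path,disease_path,restrictions_path TSV paths; the
#'   restrictions path may be `NULL`.
#' @return A list with elements `drug`, `disease`, `restrictions`.
#' @export
read_profiles <- function(drug_path, disease_path, restrictions_path = NULL) {
  list(
    drug = read_drug_profile(drug_path),
    disease = read_disease_profile(disease_path),
    restrictions = if (!is.null(restrictions_path)) {
      read_restriction_set(restrictions_path, "manual")
    }
  )
}

#' Drop restriction entries absent from a network
#'
#' Restrictions naming proteins outside the network are dropped with a
#' warning (reporting the count) rather than treated as fatal, so a partial
#' network remains usable.
#'
#' @param restrictions A [restriction_set()].
#' @param network A [signed_network()].
#' @return A filtered [restriction_set()].
#' @export
prune_restrictions <- function(restrictions, network) {
  stopifnot(inherits(restrictions, "restriction_set"))
  keep <- restrictions$entries$protein %in% network$nodes
  if (!all(keep)) {
    warning(
      sum(!keep), " restriction(s) dropped: protein(s) absent from network",
      call. = FALSE
    )
  }
  structure(
    list(entries = restrictions$entries[keep, ], provenance = restrictions$provenance),
    class = "restriction_set"
  )
}
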