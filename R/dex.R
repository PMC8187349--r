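#' Choose the two-sample test for one gene via a normality gate
#'
#' Both groups are screened with the Lilliefors (Kolmogorov-Smirnov)
#' normality test at `alpha`. If both pass, a (Welch) t-test is used;
#' otherwise the Wilcoxon rank-sum test. The Lilliefors screen is applied
#' for group sizes of 5 and above (its statistic is well defined there and
#' its critical values extend to large n); groups of 4 or fewer fall back
#' to Wilcoxon, since normality cannot be usefully assessed.
#'
#' @param values_a,values_b Numeric vectors for the two cohorts
#'   (each n >= 2).
#' @param alpha Normality screening level.
#' @return `"t"` or `"wilcoxon"`.
#' @export
normality_gate <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  normal <- function(x) {
    if (length(x) <= 4) return(FALSE)
    if (stats::sd(x) == 0) return(FALSE) # degenerate; Lilliefors undefined
    nortest::lillie.test(x)$p.value >= alpha
  }
  if (normal(values_a) && normal(values_b)) "t" else "wilcoxon"
}

#' Two-cohort differential expression with BH correction
#'
#' Per gene, the test is chosen by [normality_gate()]; the (Welch, two
#' sided) t-test is used when both cohorts look normal and the Wilcoxon
#' rank-sum test otherwise. Raw p-values are corrected across all genes by
#' the Benjamini-Hochberg step-up procedure, and genes with FDR below
#' `fdr_threshold` are flagged significant. Direction is the sign of the
#' case-minus-control mean difference. Genes constant in both cohorts get
#' p = 1 with a warning.
#'
#' @param case_matrix,control_matrix Numeric matrices (genes x samples)
#'   with identical rownames (gene identifiers), or data frames whose
#'   first column is the gene identifier.
#' @param fdr_threshold Significance threshold on the adjusted p-value.
#' @param alpha Normality screening level passed to [normality_gate()].
#' @return A tibble of class `dex_result` with columns `gene`, `test`,
#'   `mean_case`, `mean_control`, `direction` (+1 case > control),
#'   `p_value`, `fdr` and `significant`.
#' @export
diff_expression <- function(case_matrix, control_matrix,
                            fdr_threshold = 0.05, alpha = 0.05) {
  case_matrix <- as_gene_matrix(case_matrix)
  control_matrix <- as_gene_matrix(control_matrix)
  if (anyDuplicated(rownames(case_matrix)) || anyDuplicated(rownames(control_matrix))) {
    stop("duplicate gene rows in expression matrix", call. = FALSE)
  }
  if (!identical(rownames(case_matrix), rownames(control_matrix))) {
    stop("case and control matrices must share identical gene rows", call. = FALSE)
  }
  if (ncol(case_matrix) < 2 || ncol(control_matrix) < 2) {
    stop("each cohort needs at least 2 samples", call. = FALSE)
  }
  genes <- rownames(case_matrix)
  res <- purrr::map(genes, function(g) {
    a <- case_matrix[g, ]
    b <- control_matrix[g, ]
    constant <- stats::sd(a) == 0 && stats::sd(b) == 0
    if (constant) {
      return(tibble::tibble(
        gene = g, test = "none", mean_case = mean(a), mean_control = mean(b),
        p_value = 1, constant = TRUE
      ))
    }
    test <- normality_gate(a, b, alpha = alpha)
    p <- if (test == "t") {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    tibble::tibble(
      gene = g, test = test, mean_case = mean(a), mean_control = mean(b),
      p_value = p, constant = FALSE
    )
  }) |>
    dplyr::bind_rows()
  if (any(res$constant)) {
    warning(sum(res$constant), " gene(s) constant in both cohorts; p set to 1",
      call. = FALSE
    )
  }
  out <- res |>
    dplyr::mutate(
      direction = ifelse(.data$mean_case >= .data$mean_control, 1L, -1L),
      fdr = stats::p.adjust(.data$p_value, method = "BH"),
      significant = .data$fdr < fdr_threshold
    ) |>
    dplyr::select(
      "gene", "test", "mean_case", "mean_control",
      "direction", "p_value", "fdr", "significant"
    )
  class(out) <- c("dex_result", class(out))
  out
}

as_gene_matrix <- function(x) {
  if (is.data.frame(x)) {
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- genes
    return(m)
  }
  if (is.null(rownames(x))) stop("expression matrix needs gene rownames", call. = FALSE)
  x
}

#' Read a gene-by-sample expression matrix from CSV
#'
#' First column is the gene identifier, remaining columns are samples.
#'
#' @param path CSV path.
#' @return A numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double(),
    gene = readr::col_character()
  ))
  as_gene_matrix(df[, c("gene", setdiff(names(df), "gene"))])
}

#' Turn differential-expression calls into a restriction set
#'
#' Significant genes become restriction entries whose required sign is the
#' direction of differential expression (up in cases: +1). This realises
#' the practice of framing model training with the up/down-regulated
#' genes observed in the disease cohort.
#'
#' @param dex A `dex_result` from [diff_expression()].
#' @return A [restriction_set()] with provenance
#'   `"derived-from-expression"`; empty (with a warning) when nothing is
#'   significant.
#' @export
restrictions_from_dex <- function(dex) {
  stopifnot(inherits(dex, "dex_result"))
  sig <- dex[dex$significant, ]
  if (!nrow(sig)) {
    warning("no significant genes; restriction set is empty", call. = FALSE)
  }
  restriction_set(
    tibble::tibble(protein = sig$gene, sign = sig$direction),
    provenance = "derived-from-expression"
  )
}
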