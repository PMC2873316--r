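## Paired differential expression: median normalization and a paired test on
## per-pair log2 differences, yielding the transcriptomics "list of interest".

#' Construct a paired expression object
#'
#' Holds a genes x samples matrix of non-negative intensities together with
#' the lesional/non-lesional pairing of its columns.
#'
#' @param values numeric matrix, rows = genes (rownames required),
#'   columns = samples (colnames required)
#' @param pair_map data.frame with character columns `lesional` and
#'   `nonlesional`; every sample column must appear in exactly one pair
#' @return object of class `paired_expression`
#' @export
paired_expression <- function(values, pair_map) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values))) {
    nr_validation_error("values must be a matrix with row and column names")
  }
  if (!is.data.frame(pair_map) ||
      !all(c("lesional", "nonlesional") %in% names(pair_map))) {
    nr_validation_error(
      "pair_map must be a data.frame with columns lesional, nonlesional")
  }
  pair_map <- data.frame(lesional = as.character(pair_map$lesional),
                         nonlesional = as.character(pair_map$nonlesional),
                         stringsAsFactors = FALSE)
  ids <- c(pair_map$lesional, pair_map$nonlesional)
  if (anyDuplicated(ids)) {
    nr_validation_error("each sample may appear in exactly one pair")
  }
  missing <- setdiff(ids, colnames(values))
  if (length(missing)) {
    nr_validation_error(sprintf("pair_map samples absent from matrix: %s",
                                paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    nr_validation_error("expression values must be finite and non-negative")
  }
  structure(list(values = values, pair_map = pair_map,
                 gene_ids = rownames(values)),
            class = "paired_expression")
}

#' @export
print.paired_expression <- function(x, ...) {
  cat(sprintf("paired_expression: %d genes, %d pairs (%d samples)\n",
              nrow(x$values), nrow(x$pair_map), ncol(x$values)))
  invisible(x)
}

#' Read a paired expression matrix and pair map from TSV files
#'
#' The expression TSV has the gene identifier in its first column and one
#' column per sample; the pair-map TSV has header `lesional\tnonlesional`.
#'
#' @param expr_path expression matrix TSV
#' @param pair_path pair map TSV
#' @return a `paired_expression`
#' @export
read_expression <- function(expr_path, pair_path) {
  tab <- read_tsv_file(expr_path, "expression file")
  if (ncol(tab) < 3) {
    nr_parse_error("expression file must have a gene column and >= 2 samples")
  }
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    nr_parse_error("duplicate gene identifiers in expression file")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  pm <- read_tsv_file(pair_path, "pair-map file")
  paired_expression(m, pm)
}

#' Median-normalize each sample column
#'
#' Divides every column by its own median so that all samples share median 1,
#' unifying the intensity distributions before fold-change computation.
#'
#' @param x a `paired_expression`
#' @return a `paired_expression` with every column median equal to 1
#' @export
median_normalize <- function(x) {
  stopifnot(inherits(x, "paired_expression"))
  med <- apply(x$values, 2, median)
  if (any(med <= 0)) {
    nr_validation_error(sprintf(
      "sample '%s' has non-positive median; cannot median-normalize",
      colnames(x$values)[which(med <= 0)[1]]))
  }
  x$values <- sweep(x$values, 2, med, "/")
  x
}

#' Paired differential-expression test
#'
#' For every gene, computes a paired test on per-pair log2 differences
#' (lesional minus non-lesional), Benjamini-Hochberg adjusts the p-values
#' across genes, and computes the fold change as the ratio of group means on
#' the (normalized) linear scale.  A gene passes when its fold change
#' strictly exceeds `fc_threshold` and its adjusted p-value is strictly
#' below `q_threshold`.
#'
#' The default test is the standard paired test: a one-sample t-test of the
#' per-pair log2 differences against zero.  `method = "unpaired_welch"`
#' instead applies Welch's unequal-variance two-sample t-test of log2
#' lesional vs log2 non-lesional values, ignoring the pairing.
#'
#' @param x a `paired_expression` (normalized; see [median_normalize()])
#' @param fc_threshold fold-change cut-off (strict `>`), default 2.5
#' @param q_threshold FDR cut-off (strict `<`), default 0.01
#' @param method `"paired"` (default) or `"unpaired_welch"`
#' @param direction `"up"` (default; only overexpression passes) or
#'   `"both"` (the fold-change criterion is applied to max(FC, 1/FC))
#' @param fc_method `"ratio_of_means"` (default) or `"mean_of_ratios"`
#' @return object of class `de_result`: a data.frame with columns `gene`,
#'   `fold_change`, `p_value`, `q_value`, `passes`, plus threshold
#'   attributes
#' @export
paired_de_test <- function(x, fc_threshold = 2.5, q_threshold = 0.01,
                           method = c("paired", "unpaired_welch"),
                           direction = c("up", "both"),
                           fc_method = c("ratio_of_means", "mean_of_ratios")) {
  stopifnot(inherits(x, "paired_expression"))
  method <- match.arg(method)
  direction <- match.arg(direction)
  fc_method <- match.arg(fc_method)
  n_pairs <- nrow(x$pair_map)
  if (n_pairs < 2) nr_validation_error("need >= 2 sample pairs")

  eps <- .Machine$double.xmin
  les <- x$values[, x$pair_map$lesional, drop = FALSE]
  non <- x$values[, x$pair_map$nonlesional, drop = FALSE]
  l_les <- log2(pmax(les, eps))
  l_non <- log2(pmax(non, eps))

  if (method == "paired") {
    d <- l_les - l_non
    m <- rowMeans(d)
    s <- sqrt(rowSums((d - m)^2) / (n_pairs - 1))
    tt <- m / (s / sqrt(n_pairs))
    df <- n_pairs - 1
  } else {
    m1 <- rowMeans(l_les); m2 <- rowMeans(l_non)
    v1 <- rowSums((l_les - m1)^2) / (n_pairs - 1)
    v2 <- rowSums((l_non - m2)^2) / (n_pairs - 1)
    se2 <- v1 / n_pairs + v2 / n_pairs
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n_pairs)^2 / (n_pairs - 1) +
                     (v2 / n_pairs)^2 / (n_pairs - 1))
  }
  p <- 2 * pt(abs(tt), df = df, lower.tail = FALSE)
  # 0/0 statistic (gene identical in every pair): no evidence, p = 1
  p[is.na(p)] <- 1
  q <- p.adjust(p, method = "BH")

  mean_les <- rowMeans(les)
  mean_non <- rowMeans(non)
  if (fc_method == "ratio_of_means") {
    fc <- mean_les / mean_non
    zero_den <- mean_non == 0
  } else {
    fc <- rowMeans(les / pmax(non, eps))
    zero_den <- apply(non == 0, 1, any)
  }
  if (any(zero_den)) {
    fc[zero_den & mean_les > 0] <- Inf
    warning(sprintf(
      "%d gene(s) with zero denominator mean: fold change reported as Inf",
      sum(zero_den)), call. = FALSE)
  }

  eff_fc <- if (direction == "both") pmax(fc, 1 / fc) else fc
  passes <- eff_fc > fc_threshold & q < q_threshold

  res <- data.frame(gene = x$gene_ids, fold_change = fc, p_value = p,
                    q_value = q, passes = passes, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(res, class = c("de_result", "data.frame"),
            fc_threshold = fc_threshold, q_threshold = q_threshold,
            method = method, direction = direction, n_pairs = n_pairs)
}

#' Extract the differentially expressed gene set
#'
#' @param r a `de_result`
#' @param name name for the resulting set (default `"DE_up"`)
#' @return a `gene_set` of all genes with `passes = TRUE` (possibly empty;
#'   downstream statistics refuse empty lists of interest)
#' @export
de_gene_set <- function(r, name = "DE_up") {
  stopifnot(inherits(r, "de_result"))
  gene_set(name, r$gene[r$passes])
}
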