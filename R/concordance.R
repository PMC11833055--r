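#' L1 distance between two studies' fold-change profiles
#'
#' The cross-model transcriptome distance: the sum over shared genes of the
#' absolute difference of log2 fold changes,
#' S = sum_g |FC_a(g) - FC_b(g)|. Smaller S means the two models perturb the
#' shared transcriptome more similarly. All shared genes contribute; no
#' significance filtering or winsorizing is applied.
#'
#' @param matrix A `shared_gene_matrix` from [intersect_profiles()].
#' @param a,b Study labels (columns of `matrix`).
#' @return An object of class `distance_result`: list with `study_a`,
#'   `study_b`, `s_value` (raw L1 sum, log2 units), `s_per_gene`
#'   (`s_value / n_genes`) and `n_genes`.
#' @export
l1_fc_distance <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "shared_gene_matrix"))
  for (lab in c(a, b))
    if (!lab %in% matrix$studies) stop("unknown study label: ", lab)
  if (length(matrix$genes) == 0L)
    stop("empty shared-gene matrix: distance undefined")
  s <- sum(abs(matrix$fc[, a] - matrix$fc[, b]))
  structure(list(study_a = a, study_b = b, s_value = s,
                 s_per_gene = s / length(matrix$genes),
                 n_genes = length(matrix$genes)),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("S_%s/%s = %.4f over %d shared genes (%.4f per gene)\n",
              x$study_a, x$study_b, x$s_value, x$n_genes, x$s_per_gene))
  invisible(x)
}

#' All pairwise L1 fold-change distances
#'
#' @param matrix A `shared_gene_matrix` with at least two studies.
#' @return An object of class `fc_distance_matrix`: list with `labels`,
#'   `values` (square symmetric matrix of S values, zero diagonal) and
#'   `n_genes`.
#' @export
distance_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "shared_gene_matrix"))
  labs <- matrix$studies
  if (length(labs) < 2L) stop("need at least two studies")
  k <- length(labs)
  vals <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      s <- l1_fc_distance(matrix, labs[i], labs[j])$s_value
      vals[i, j] <- s
      vals[j, i] <- s
    }
  }
  structure(list(labels = labs, values = vals,
                 n_genes = length(matrix$genes)),
            class = "fc_distance_matrix")
}

#' @export
print.fc_distance_matrix <- function(x, ...) {
  cat("<fc_distance_matrix> over", x$n_genes, "shared genes\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Rank studies by similarity to a reference
#'
#' Orders the non-reference studies by ascending L1 distance to the
#' reference (most similar first); ties are broken lexicographically by
#' label.
#'
#' @param dm An `fc_distance_matrix` from [distance_matrix()].
#' @param reference Reference study label (e.g. the spaceflight profile).
#' @return A data.frame with columns `label` and `s_value`, sorted
#'   ascending by `s_value`.
#' @export
rank_by_similarity <- function(dm, reference) {
  stopifnot(inherits(dm, "fc_distance_matrix"))
  if (!reference %in% dm$labels) stop("unknown reference label: ", reference)
  others <- setdiff(dm$labels, reference)
  s <- dm$values[others, reference]
  ord <- order(s, others, method = "radix")
  data.frame(label = others[ord], s_value = unname(s[ord]),
             stringsAsFactors = FALSE)
}

#' Per-gene contributions to an L1 distance
#'
#' Decomposes S(a, b) into its per-gene terms |FC_a(g) - FC_b(g)| and
#' returns the largest `top_k`. The contributions over all shared genes sum
#' exactly to the S value, which makes the statistic interpretable gene by
#' gene.
#'
#' @param matrix A `shared_gene_matrix`.
#' @param a,b Study labels.
#' @param top_k Number of genes to return (>= 1).
#' @return A data.frame with columns `gene_id` and `abs_delta_log2fc`,
#'   sorted descending by contribution, ties lexicographic.
#' @export
gene_contributions <- function(matrix, a, b, top_k = 10L) {
  stopifnot(inherits(matrix, "shared_gene_matrix"))
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1)
    stop("top_k must be a positive integer")
  for (lab in c(a, b))
    if (!lab %in% matrix$studies) stop("unknown study label: ", lab)
  delta <- abs(matrix$fc[, a] - matrix$fc[, b])
  ord <- order(-delta, matrix$genes, method = "radix")
  k <- min(as.integer(top_k), length(delta))
  data.frame(gene_id = matrix$genes[ord][seq_len(k)],
             abs_delta_log2fc = unname(delta[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}
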