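#' Differential-expression calling criteria
#'
#' The default thresholds call a gene differentially expressed when its raw
#' p-value is below 0.05 and its linear fold change (2^log2fc) exceeds 1.5 or
#' falls below the down threshold. The default down threshold is the exact
#' reciprocal 1/1.5 = 0.6667 (symmetric in log space); pass
#' `literal_0.667 = TRUE` to use the rounded 0.667 bound instead, which can
#' shift calls for genes within ~0.0007 of the boundary. All inequalities are
#' strict: a gene sitting exactly on a threshold is not called.
#'
#' @param p_threshold P-value cutoff in (0, 1]; default 0.05.
#' @param fc_up Linear fold-change upper threshold (> 1); default 1.5.
#' @param fc_down Linear fold-change lower threshold in (0, 1); default
#'   `1 / fc_up`.
#' @param literal_0.667 If `TRUE`, set `fc_down = 0.667` (the printed,
#'   rounded bound) instead of the exact reciprocal.
#' @return An object of class `deg_criteria`.
#' @export
deg_criteria <- function(p_threshold = 0.05, fc_up = 1.5,
                         fc_down = 1 / fc_up, `literal_0.667` = FALSE) {
  if (isTRUE(`literal_0.667`)) fc_down <- 0.667
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1L,
            p_threshold > 0, p_threshold <= 1,
            is.numeric(fc_up), length(fc_up) == 1L, fc_up > 1,
            is.numeric(fc_down), length(fc_down) == 1L,
            fc_down > 0, fc_down < 1)
  structure(list(p_threshold = p_threshold, fc_up = fc_up, fc_down = fc_down),
            class = "deg_criteria")
}

#' Classify genes as up, down or not significant
#'
#' Vectorized over genes. `up` iff `p < p_threshold` and `2^log2fc > fc_up`;
#' `down` iff `p < p_threshold` and `2^log2fc < fc_down`; otherwise
#' `not_significant`. Boundary values are excluded (strict inequalities).
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param pvalue Numeric vector of p-values, same length.
#' @param criteria A [deg_criteria] object.
#' @return Character vector in `{"up", "down", "not_significant"}`.
#' @export
classify_gene <- function(log2fc, pvalue, criteria = deg_criteria()) {
  stopifnot(inherits(criteria, "deg_criteria"),
            length(log2fc) == length(pvalue))
  fc <- 2^log2fc
  sig <- pvalue < criteria$p_threshold
  out <- rep("not_significant", length(log2fc))
  out[which(sig & fc > criteria$fc_up)] <- "up"
  out[which(sig & fc < criteria$fc_down)] <- "down"
  out
}

#' Differentially expressed gene set of a study
#'
#' @param profile A [study_profile].
#' @param criteria A [deg_criteria] object.
#' @return Character vector of gene ids called `up` or `down`, in the
#'   profile's row order.
#' @export
deg_set <- function(profile, criteria = deg_criteria()) {
  stopifnot(inherits(profile, "study_profile"))
  call <- classify_gene(profile$effects$log2fc, profile$effects$pvalue,
                        criteria)
  profile$effects$gene_id[call != "not_significant"]
}

#' Three-way overlap partition of DEG sets
#'
#' Partitions three gene sets into the seven disjoint regions of a
#' three-set Venn diagram. Membership is by gene id regardless of
#' fold-change direction.
#'
#' @param set_a,set_b,set_c Character vectors of gene ids (duplicates are
#'   collapsed; empty sets allowed).
#' @param labels Length-3 character vector naming the sets.
#' @return An object of class `venn_partition`: list with `labels`, `counts`
#'   (named integer vector over regions `a_only`, `b_only`, `c_only`, `ab`,
#'   `ac`, `bc`, `abc`) and `genes` (named list of sorted gene-id vectors,
#'   one per region).
#' @export
venn_partition <- function(set_a, set_b, set_c,
                           labels = c("A", "B", "C")) {
  stopifnot(length(labels) == 3L, !anyDuplicated(labels))
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  c_ <- unique(as.character(set_c))
  all_genes <- unique(c(a, b, c_))
  in_a <- all_genes %in% a
  in_b <- all_genes %in% b
  in_c <- all_genes %in% c_
  region <- function(keep) sort(all_genes[keep], method = "radix")
  genes <- list(
    a_only = region(in_a & !in_b & !in_c),
    b_only = region(!in_a & in_b & !in_c),
    c_only = region(!in_a & !in_b & in_c),
    ab     = region(in_a & in_b & !in_c),
    ac     = region(in_a & !in_b & in_c),
    bc     = region(!in_a & in_b & in_c),
    abc    = region(in_a & in_b & in_c))
  counts <- vapply(genes, length, integer(1))
  structure(list(labels = labels, counts = counts, genes = genes),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> ", paste(x$labels, collapse = "/"), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Select genes for the cross-model heatmap
#'
#' Restricts to the genes shared by all studies in `matrix` and keeps those
#' called differentially expressed (default: p < 0.05 and linear fold change
#' > 2 or < 0.5, the stricter heatmap rule) in at least one study. The gene's
#' p-value and fold change are taken from each study's full profile.
#'
#' @param matrix A `shared_gene_matrix` from [intersect_profiles()].
#' @param profiles List of [study_profile] objects covering every study
#'   label in `matrix`.
#' @param criteria A [deg_criteria]; defaults to the heatmap thresholds
#'   `deg_criteria(0.05, fc_up = 2, fc_down = 0.5)`.
#' @return Character vector of selected gene ids in lexicographic order.
#' @export
select_heatmap_genes <- function(matrix, profiles,
                                 criteria = deg_criteria(fc_up = 2,
                                                         fc_down = 0.5)) {
  stopifnot(inherits(matrix, "shared_gene_matrix"))
  labels <- vapply(profiles, `[[`, character(1), "label")
  missing_lab <- setdiff(matrix$studies, labels)
  if (length(missing_lab))
    stop("no profile supplied for study label(s): ",
         paste(missing_lab, collapse = ", "))
  selected <- rep(FALSE, length(matrix$genes))
  for (lab in matrix$studies) {
    p <- profiles[[match(lab, labels)]]
    idx <- match(matrix$genes, p$effects$gene_id)
    call <- classify_gene(p$effects$log2fc[idx], p$effects$pvalue[idx],
                          criteria)
    selected <- selected | (call != "not_significant")
  }
  sort(matrix$genes[selected], method = "radix")
}
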