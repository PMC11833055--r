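#' Construct a gene x sample count matrix
#'
#' @param counts Integer-like matrix, genes in rows, samples in columns;
#'   nonnegative. Row names are gene ids, column names sample ids.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  structure(list(genes = rownames(counts), samples = colnames(counts),
                 counts = counts),
            class = "count_matrix")
}

#' Two-group sample design
#'
#' Maps each sample to one of exactly two groups and declares which group is
#' the control and which the treated arm (fold changes are treated over
#' control).
#'
#' @param sample Character vector of sample ids.
#' @param group Character vector of group labels, same length.
#' @param control,treated The two group labels.
#' @return An object of class `group_design`.
#' @export
group_design <- function(sample, group, control = "control",
                         treated = "treated") {
  sample <- as.character(sample)
  group <- as.character(group)
  stopifnot(length(sample) == length(group), !anyDuplicated(sample))
  if (!setequal(unique(group), c(control, treated)))
    stop("design must contain exactly the two groups '", control,
         "' and '", treated, "'")
  structure(list(sample = sample, group = group,
                 control = control, treated = treated),
            class = "group_design")
}

group_samples <- function(design, which) {
  design$sample[design$group == design[[which]]]
}

#' Counts-per-million normalization
#'
#' Scales each sample's column so it sums to one million.
#'
#' @param cm A [count_matrix].
#' @return Numeric matrix of CPM values, same dimnames as the counts.
#' @export
cpm_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  tot <- colSums(cm$counts)
  zero <- tot == 0
  if (any(zero))
    stop("sample(s) with zero total count: ",
         paste(cm$samples[zero], collapse = ", "))
  sweep(cm$counts, 2L, tot, "/") * 1e6
}

#' Per-gene log2 fold change from grouped counts
#'
#' log2 of the ratio of group-mean CPM values with a pseudocount:
#' `log2((mean treated CPM + pc) / (mean control CPM + pc))`. The
#' pseudocount stabilizes low-count genes and is the main small-count bias
#' knob.
#'
#' @param cm A [count_matrix].
#' @param design A [group_design] over the matrix's samples.
#' @param pseudocount Positive pseudocount added to both group means
#'   (default 0.5).
#' @return Named numeric vector of log2 fold changes, one per gene.
#' @export
estimate_log2fc <- function(cm, design, pseudocount = 0.5) {
  stopifnot(inherits(design, "group_design"), pseudocount > 0)
  check_design_samples(cm, design)
  cpm <- cpm_normalize(cm)
  mt <- rowMeans(cpm[, group_samples(design, "treated"), drop = FALSE])
  mc <- rowMeans(cpm[, group_samples(design, "control"), drop = FALSE])
  log2((mt + pseudocount) / (mc + pseudocount))
}

check_design_samples <- function(cm, design) {
  missing_s <- setdiff(design$sample, cm$samples)
  if (length(missing_s))
    stop("design sample(s) not in count matrix: ",
         paste(missing_s, collapse = ", "))
  invisible(TRUE)
}

# Vectorized two-sided Welch t-test across rows of a matrix.
# Returns p-values; rows with zero pooled standard error get p = 1 when the
# group means are equal and p = 0 otherwise.
welch_rows <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, nrow(x))
  pos <- se2 > 0
  tt <- (m1[pos] - m2[pos]) / sqrt(se2[pos])
  df <- se2[pos]^2 / ((v1[pos] / n1)^2 / (n1 - 1L) +
                      (v2[pos] / n2)^2 / (n2 - 1L))
  p[pos] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  degen_diff <- !pos & (m1 != m2)
  p[degen_diff] <- 0
  p
}

#' Per-gene Welch test on log2 CPM
#'
#' A two-sided Welch (unequal-variance) t-test on `log2(CPM + pseudocount)`
#' per gene between the two design groups. Genes whose values are constant
#' within both groups get p = 1 when the group means coincide and p = 0
#' otherwise. This is a calibrated, dependency-light significance source for
#' synthetic counts; real studies should supply precomputed DE tables.
#'
#' @inheritParams estimate_log2fc
#' @param adjust If `"BH"`, return Benjamini-Hochberg adjusted p-values
#'   instead of raw ones (off by default; the DEG criteria use raw P).
#' @return Named numeric vector of p-values, one per gene.
#' @export
welch_de <- function(cm, design, pseudocount = 0.5, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(design, "group_design"), pseudocount > 0)
  check_design_samples(cm, design)
  s1 <- group_samples(design, "treated")
  s2 <- group_samples(design, "control")
  if (length(s1) < 2L || length(s2) < 2L)
    stop("each group needs at least two samples")
  logc <- log2(cpm_normalize(cm) + pseudocount)
  p <- welch_rows(logc, match(s1, cm$samples), match(s2, cm$samples))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  names(p) <- cm$genes
  p
}

#' Build a study profile from grouped counts
#'
#' Runs [estimate_log2fc()] and [welch_de()] and assembles the per-gene
#' results into a [study_profile], genes in lexicographic order.
#'
#' @inheritParams welch_de
#' @param label Study label for the resulting profile.
#' @return A [study_profile].
#' @export
build_profile <- function(cm, design, label, pseudocount = 0.5) {
  fc <- estimate_log2fc(cm, design, pseudocount)
  p <- welch_de(cm, design, pseudocount)
  ord <- order(cm$genes, method = "radix")
  study_profile(label, cm$genes[ord], fc[ord], p[ord])
}

#' Read a count matrix and sample sheet from TSV
#'
#' The count TSV has a `gene_id` first column and one column per sample; the
#' sample sheet has columns `sample` and `group`.
#'
#' @param counts_path Path to the count TSV.
#' @param sheet_path Path to the sample sheet TSV.
#' @param control,treated Group labels in the sheet.
#' @return List with elements `counts` (a [count_matrix]) and `design`
#'   (a [group_design]).
#' @export
read_counts_tsv <- function(counts_path, sheet_path,
                            control = "control", treated = "treated") {
  tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$gene_id
  sheet <- utils::read.table(sheet_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  list(counts = count_matrix(m),
       design = group_design(sheet$sample, sheet$group,
                             control = control, treated = treated))
}
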