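#' Construct a study profile
#'
#' A study profile is one study's per-gene differential-expression result:
#' for each gene a log2 fold change (treated vs control) and a p-value.
#' Gene identifiers must be unique; matching across studies is exact,
#' case-sensitive string equality (no ortholog or alias mapping).
#'
#' @param label Study label, e.g. `"CS"`, `"HU"`, `"FL"`.
#' @param gene_id Character vector of non-empty, unique gene identifiers.
#' @param log2fc Numeric vector of finite log2 fold changes.
#' @param pvalue Numeric vector of p-values in `[0, 1]`.
#' @return An object of class `study_profile`: a list with elements `label`
#'   and `effects` (a data.frame with columns `gene_id`, `log2fc`, `pvalue`).
#' @export
study_profile <- function(label, gene_id, log2fc, pvalue) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  gene_id <- as.character(gene_id)
  log2fc <- as.numeric(log2fc)
  pvalue <- as.numeric(pvalue)
  n <- length(gene_id)
  if (length(log2fc) != n || length(pvalue) != n)
    stop("gene_id, log2fc and pvalue must have equal length")
  if (any(!nzchar(gene_id)) || anyNA(gene_id))
    stop("gene_id must be non-empty strings")
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    stop("duplicate gene_id in profile '", label, "': ",
         paste(utils::head(unique(dup), 5L), collapse = ", "))
  if (any(!is.finite(log2fc)))
    stop("log2fc must be finite")
  if (anyNA(pvalue) || any(pvalue < 0 | pvalue > 1))
    stop("pvalue must lie in [0, 1]")
  structure(
    list(label = label,
         effects = data.frame(gene_id = gene_id, log2fc = log2fc,
                              pvalue = pvalue, stringsAsFactors = FALSE)),
    class = "study_profile")
}

#' @export
print.study_profile <- function(x, ...) {
  cat("<study_profile> ", x$label, ": ", nrow(x$effects), " genes\n", sep = "")
  invisible(x)
}

#' Read a per-study differential-expression table
#'
#' Reads a delimited text table with a header into a [study_profile].
#' Rows whose log2 fold change or p-value is missing or non-finite are
#' dropped with a warning stating how many were removed.
#'
#' @param path Path to the delimited file.
#' @param label Study label to attach.
#' @param sep Field delimiter; TAB by default, use `","` for CSV.
#' @param gene_col,fc_col,p_col Header names of the gene identifier,
#'   log2 fold-change and p-value columns.
#' @return A [study_profile].
#' @export
read_profile <- function(path, label, sep = "\t",
                         gene_col = "gene_id", fc_col = "log2fc",
                         p_col = "pvalue") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  need <- c(gene_col, fc_col, p_col)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  gene <- as.character(tab[[gene_col]])
  fc <- suppressWarnings(as.numeric(tab[[fc_col]]))
  p <- suppressWarnings(as.numeric(tab[[p_col]]))
  keep <- is.finite(fc) & is.finite(p)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    warning(n_drop, " row(s) with missing or non-finite values dropped from '",
            path, "'")
  study_profile(label, gene[keep], fc[keep], p[keep])
}

#' Write a study profile as a delimited table
#'
#' Inverse of [read_profile()]: writes `gene_id`, `log2fc`, `pvalue` columns
#' with a header. Round-tripping preserves all fields for finite inputs.
#'
#' @param profile A [study_profile].
#' @param path Output path.
#' @param sep Field delimiter (TAB default).
#' @export
write_profile <- function(profile, path, sep = "\t") {
  stopifnot(inherits(profile, "study_profile"))
  utils::write.table(profile$effects, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align studies on their shared genes
#'
#' Builds the shared-gene log2 fold-change matrix over the exact intersection
#' of the input profiles' gene sets — the "genes consistently detected in all
#' models" on which the cross-model distance is computed. A gene missing from
#' any study is excluded. Rows (genes) are ordered lexicographically for
#' deterministic output; columns follow the input profile order.
#'
#' @param profiles A list of two or more [study_profile] objects with
#'   distinct labels.
#' @return An object of class `shared_gene_matrix`: a list with `genes`
#'   (sorted gene ids), `studies` (labels) and `fc` (genes x studies numeric
#'   matrix of log2 fold changes).
#' @export
intersect_profiles <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop("need at least two profiles")
  ok <- vapply(profiles, inherits, logical(1), "study_profile")
  if (!all(ok)) stop("all elements must be study_profile objects")
  labels <- vapply(profiles, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate study labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  shared <- Reduce(intersect, lapply(profiles, function(p) p$effects$gene_id))
  if (length(shared) == 0L)
    stop("empty gene intersection: distance over shared genes is undefined")
  shared <- sort(shared, method = "radix")
  fc <- vapply(profiles, function(p) {
    v <- p$effects$log2fc[match(shared, p$effects$gene_id)]
    v
  }, numeric(length(shared)))
  fc <- matrix(fc, nrow = length(shared), ncol = length(profiles),
               dimnames = list(shared, labels))
  structure(list(genes = shared, studies = labels, fc = fc),
            class = "shared_gene_matrix")
}

#' @export
print.shared_gene_matrix <- function(x, ...) {
  cat("<shared_gene_matrix> ", length(x$genes), " shared genes x ",
      length(x$studies), " studies (", paste(x$studies, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Write a shared-gene matrix as TSV
#'
#' First column `gene_id`, then one log2 fold-change column per study label.
#'
#' @param matrix A `shared_gene_matrix` from [intersect_profiles()].
#' @param path Output path.
#' @export
write_shared_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "shared_gene_matrix"))
  out <- data.frame(gene_id = matrix$genes, matrix$fc,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a shared-gene matrix from TSV
#'
#' @param path Path to a TSV written by [write_shared_matrix()].
#' @return A `shared_gene_matrix`.
#' @export
read_shared_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "gene_id") stop("first column must be gene_id")
  genes <- as.character(tab$gene_id)
  fc <- as.matrix(tab[, -1L, drop = FALSE])
  ord <- order(genes, method = "radix")
  genes <- genes[ord]
  fc <- fc[ord, , drop = FALSE]
  rownames(fc) <- genes
  structure(list(genes = genes, studies = colnames(fc), fc = fc),
            class = "shared_gene_matrix")
}
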