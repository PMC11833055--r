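# Brute-force oracles and random-instance generators, written independently
# of the package internals (plain loops, no vectorized shortcuts shared with
# the implementation).

random_profile <- function(label, n, gene_pool = NULL) {
  ids <- if (is.null(gene_pool)) {
    paste0("gene_", sample.int(10 * n, n))
  } else {
    sample(gene_pool, n)
  }
  study_profile(label, ids,
                log2fc = round(stats::rnorm(n, 0, 2), 6),
                pvalue = round(stats::runif(n), 6))
}

random_shared_matrix <- function(n_genes, n_studies) {
  genes <- sort(paste0("g", sample.int(10 * n_genes, n_genes)))
  labs <- LETTERS[seq_len(n_studies)]
  fc <- matrix(stats::rnorm(n_genes * n_studies, 0, 2), n_genes, n_studies,
               dimnames = list(genes, labs))
  structure(list(genes = genes, studies = labs, fc = fc),
            class = "shared_gene_matrix")
}

# Nested-loop membership intersection over profiles' gene vectors.
oracle_intersect_genes <- function(profiles) {
  shared <- character(0)
  for (g in profiles[[1]]$effects$gene_id) {
    in_all <- TRUE
    for (p in profiles[-1]) {
      found <- FALSE
      for (h in p$effects$gene_id) if (h == g) { found <- TRUE; break }
      if (!found) { in_all <- FALSE; break }
    }
    if (in_all) shared <- c(shared, g)
  }
  sort(shared)
}

# Per-gene filter loop applying the DEG rule literally.
oracle_deg_set <- function(profile, criteria) {
  out <- character(0)
  for (i in seq_len(nrow(profile$effects))) {
    fc <- 2^profile$effects$log2fc[i]
    p <- profile$effects$pvalue[i]
    if (p < criteria$p_threshold &&
        (fc > criteria$fc_up || fc < criteria$fc_down))
      out <- c(out, profile$effects$gene_id[i])
  }
  out
}

# Membership enumeration over the union, one gene at a time.
oracle_venn_counts <- function(a, b, c_) {
  a <- unique(a); b <- unique(b); c_ <- unique(c_)
  counts <- c(a_only = 0L, b_only = 0L, c_only = 0L,
              ab = 0L, ac = 0L, bc = 0L, abc = 0L)
  for (g in unique(c(a, b, c_))) {
    ia <- g %in% a; ib <- g %in% b; ic <- g %in% c_
    key <- if (ia && ib && ic) "abc"
      else if (ia && ib) "ab"
      else if (ia && ic) "ac"
      else if (ib && ic) "bc"
      else if (ia) "a_only" else if (ib) "b_only" else "c_only"
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Elementwise accumulation loop for the L1 distance.
oracle_l1 <- function(matrix, a, b) {
  s <- 0
  for (g in matrix$genes) s <- s + abs(matrix$fc[g, a] - matrix$fc[g, b])
  s
}

# Double loop over genes x studies applying the heatmap rule per cell.
oracle_heatmap <- function(matrix, profiles, criteria) {
  labs <- vapply(profiles, `[[`, character(1), "label")
  keep <- character(0)
  for (g in matrix$genes) {
    hit <- FALSE
    for (lab in matrix$studies) {
      eff <- profiles[[match(lab, labs)]]$effects
      row <- eff[eff$gene_id == g, ]
      fc <- 2^row$log2fc
      if (row$pvalue < criteria$p_threshold &&
          (fc > criteria$fc_up || fc < criteria$fc_down)) {
        hit <- TRUE
        break
      }
    }
    if (hit) keep <- c(keep, g)
  }
  sort(keep)
}

null_nb_count_matrix <- function(n_genes = 2000L, n_per_group = 6L,
                                 phi = 0.3) {
  mu <- exp(stats::rnorm(n_genes, 5, 1.5))
  n <- 2L * n_per_group
  cnt <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / phi),
                n_genes, n,
                dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n))))
  list(cm = count_matrix(cnt),
       design = group_design(colnames(cnt),
                             rep(c("control", "treated"),
                                 each = n_per_group)))
}
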