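#' Simulator configuration for a multi-study panel
#'
#' Describes a panel of two-group RNA-seq studies sharing a reference effect
#' vector. A fraction `f_de` of genes is differential in the reference with
#' log2 effects drawn N(0, `sigma_beta`^2). Each study's planted effect on a
#' DE gene is `rho * beta_ref + sqrt(1 - rho^2) * eta`, `eta ~ N(0,
#' sigma_beta^2)`, so `rho` is the correlation of the study's true effects
#' with the reference (the study-level concordance). Counts are negative
#' binomial with variance `mu + phi * mu^2` around log-normal baseline means.
#'
#' Defaults mirror the three-model design the pipeline targets: a reference
#' study (`FL`, rho = 1) and two ground models of differing concordance
#' (`CS` at 0.8, `HU` at 0.2), 6 animals per group, 5000 genes with 10%
#' differential, unit-SD effects and moderate dispersion 0.3.
#'
#' @param n_genes Number of genes G (>= 10).
#' @param n_per_group Samples per group in every study (>= 2).
#' @param f_de Fraction of genes differential in the reference, in (0, 1].
#' @param sigma_beta SD of reference log2 effects (> 0), log2 units.
#' @param rho Named numeric vector of per-study concordances in [0, 1];
#'   names are the study labels.
#' @param phi NB dispersion (> 0); variance is `mu + phi * mu^2`.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and SD of the
#'   log-normal per-gene baseline means.
#' @param reference Label of the reference study; must have `rho = 1`.
#'   Defaults to the first study with `rho == 1`.
#' @param seed Master seed; per-study substreams are derived from it and the
#'   study label, so adding a study never perturbs existing ones.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L, n_per_group = 6L, f_de = 0.1,
                       sigma_beta = 1, rho = c(FL = 1, CS = 0.8, HU = 0.2),
                       phi = 0.3, baseline_log_mean = 5,
                       baseline_log_sd = 1.5, reference = NULL,
                       seed = 1L) {
  stopifnot(n_genes >= 10L, n_per_group >= 2L,
            f_de > 0, f_de <= 1, sigma_beta > 0, phi > 0,
            baseline_log_sd > 0,
            is.numeric(rho), length(rho) >= 1L,
            !is.null(names(rho)), all(nzchar(names(rho))),
            !anyDuplicated(names(rho)),
            all(rho >= 0 & rho <= 1))
  if (is.null(reference)) {
    hit <- names(rho)[rho == 1]
    reference <- if (length(hit)) hit[1L] else NA_character_
  } else if (!reference %in% names(rho) || rho[[reference]] != 1) {
    stop("reference must be a study with rho = 1")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 f_de = f_de, sigma_beta = sigma_beta, rho = rho,
                 phi = phi, baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 reference = reference, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-(seed, label) substream seed in [0, 2^31 - 2]:
# a polynomial string hash over the label folded into the master seed.
substream_seed <- function(seed, label) {
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% m
  as.integer(h)
}

sim_gene_ids <- function(n) sprintf("g%06d", seq_len(n))

#' Draw the planted per-study effect truth
#'
#' Deterministic given the config seed. `round(G * f_de)` genes are chosen
#' as differential; non-DE genes have zero effect in the reference and in
#' every study. A study with rho = 1 reproduces the reference effects
#' exactly; rho = 0 gives independent effects of the same scale.
#'
#' @param config A [sim_config].
#' @return An object of class `effect_truth`: list with `genes`, `is_de`
#'   (logical), `beta_ref` (numeric), `beta_study` (genes x studies matrix),
#'   `mu_baseline` (per-gene NB means, shared across studies) and `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  genes <- sim_gene_ids(g)
  # separate substreams for the reference, the baseline and each study's
  # idiosyncratic effects, so adding a study never perturbs the others
  set.seed(substream_seed(config$seed, "truth"))
  n_de <- round(g * config$f_de)
  de_idx <- sort(sample.int(g, n_de))
  is_de <- rep(FALSE, g)
  is_de[de_idx] <- TRUE
  beta_ref <- numeric(g)
  beta_ref[de_idx] <- stats::rnorm(n_de, 0, config$sigma_beta)
  studies <- names(config$rho)
  beta_study <- matrix(0, g, length(studies),
                       dimnames = list(genes, studies))
  for (s in studies) {
    rho <- config$rho[[s]]
    set.seed(substream_seed(config$seed, paste0("effects:", s)))
    eta <- stats::rnorm(n_de, 0, config$sigma_beta)
    beta_study[de_idx, s] <- rho * beta_ref[de_idx] +
      sqrt(1 - rho^2) * eta
  }
  set.seed(substream_seed(config$seed, "baseline"))
  mu_baseline <- exp(stats::rnorm(g, config$baseline_log_mean,
                                  config$baseline_log_sd))
  names(mu_baseline) <- genes
  structure(list(genes = genes, is_de = is_de, beta_ref = beta_ref,
                 beta_study = beta_study, mu_baseline = mu_baseline,
                 config = config),
            class = "effect_truth")
}

#' Simulate one study's count matrix and design
#'
#' Counts are NB with mean `mu_g * 2^(beta_study * x)` where x = 1 for
#' treated samples and 0 for controls, and variance `mu + phi * mu^2`
#' (`size = 1/phi` in [stats::rnbinom()]). Deterministic given the config
#' seed and study label.
#'
#' @param truth An `effect_truth` from [simulate_truth()].
#' @param config The [sim_config] used to draw `truth`.
#' @param study Study label present in `truth`.
#' @return List with `counts` (a [count_matrix]) and `design`
#'   (a [group_design]).
#' @export
simulate_counts <- function(truth, config, study) {
  stopifnot(inherits(truth, "effect_truth"), inherits(config, "sim_config"))
  if (!study %in% colnames(truth$beta_study))
    stop("unknown study label: ", study)
  set.seed(substream_seed(config$seed, paste0("counts:", study)))
  n <- config$n_per_group
  g <- config$n_genes
  samples <- c(sprintf("%s_control_%d", study, seq_len(n)),
               sprintf("%s_treated_%d", study, seq_len(n)))
  groups <- rep(c("control", "treated"), each = n)
  beta <- truth$beta_study[, study]
  mu <- cbind(matrix(truth$mu_baseline, g, n),
              matrix(truth$mu_baseline * 2^beta, g, n))
  counts <- matrix(stats::rnbinom(g * 2L * n, mu = mu, size = 1 / config$phi),
                   g, 2L * n, dimnames = list(truth$genes, samples))
  list(counts = count_matrix(counts),
       design = group_design(samples, groups))
}

#' Simulate a full multi-study panel
#'
#' Draws the effect truth and one (counts, design) bundle per configured
#' study, ready to feed through the DE engine, profile intersection and the
#' distance ranking.
#'
#' @param config A [sim_config] naming a reference study (rho = 1) and at
#'   least two comparison studies.
#' @return An object of class `sim_panel`: list with `truth`, `studies`
#'   (named list of `counts`/`design` bundles) and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.na(config$reference))
    stop("config must name a reference study with rho = 1")
  if (length(config$rho) < 3L)
    stop("need the reference plus at least two comparison studies")
  truth <- simulate_truth(config)
  studies <- lapply(names(config$rho), function(s)
    simulate_counts(truth, config, s))
  names(studies) <- names(config$rho)
  structure(list(truth = truth, studies = studies, config = config),
            class = "sim_panel")
}

#' Run the full concordance pipeline on a simulated panel
#'
#' Convenience wrapper: builds a profile per study with the Welch DE engine,
#' intersects the profiles, computes all pairwise L1 distances and ranks the
#' non-reference studies by similarity to the reference.
#'
#' @param panel A `sim_panel` from [simulate_panel()].
#' @param pseudocount Passed to [build_profile()].
#' @return List with `profiles`, `matrix` (shared-gene matrix), `dm`
#'   (distance matrix) and `ranking` (data.frame from
#'   [rank_by_similarity()]).
#' @export
run_panel_pipeline <- function(panel, pseudocount = 0.5) {
  stopifnot(inherits(panel, "sim_panel"))
  profiles <- lapply(names(panel$studies), function(s)
    build_profile(panel$studies[[s]]$counts, panel$studies[[s]]$design,
                  label = s, pseudocount = pseudocount))
  m <- intersect_profiles(profiles)
  dm <- distance_matrix(m)
  list(profiles = profiles, matrix = m, dm = dm,
       ranking = rank_by_similarity(dm, panel$config$reference))
}

#' Write a simulated study to TSV files
#'
#' Writes the count matrix (`gene_id` + one column per sample) and the
#' sample sheet (`sample`, `group`) for one simulated study.
#'
#' @param bundle A `counts`/`design` list from [simulate_counts()].
#' @param counts_path,sheet_path Output paths.
#' @export
write_study_tsv <- function(bundle, counts_path, sheet_path) {
  cm <- bundle$counts
  out <- data.frame(gene_id = cm$genes, cm$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = bundle$design$sample,
                                group = bundle$design$group),
                     sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}
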