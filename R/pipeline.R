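# End-to-end orchestration: score -> permute -> cluster -> lineage TDT ->
# Monte Carlo, with every stage's table written as plain TSV plus a YAML
# manifest recording all parameters and seeds. Logging goes to standard
# error; data only to files.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full detection pipeline on a pedigree file
#'
#' Reads a pedigree, scores carrier posteriors, runs the sex-permutation
#' suite, clusters high-likelihood individuals into putative distorter
#' families, scans every patrilineal lineage with the TDT (FDR-corrected
#' over the large lineages), and applies the Monte Carlo family test to the
#' most significant lineage. All reports are written under `out_dir` and
#' are reproducible byte-for-byte from `(input, parameters, seed)`.
#'
#' @param ped_path Path to a PED-style pedigree file.
#' @param out_dir Output directory (created if needed).
#' @param mode,penetrance,allele_freq,de_novo_rate Model parameters, as in
#'   [model_params()].
#' @param n_perm Permutations for the significance suite.
#' @param threshold,link_radius Clustering parameters, as in
#'   [cluster_relatives()].
#' @param min_offspring Lineage size filter, as in [scan_lineages()].
#' @param mc_reps Monte Carlo replicates for the top lineage.
#' @param seed Master seed; all stage seeds derive from it.
#' @param validation `"strict"` or `"permissive"` pedigree validation.
#' @inheritParams run_belief_propagation
#' @return Invisibly, a list with the written file paths and a `summary`
#'   list of headline numbers.
#' @export
run_full_pipeline <- function(ped_path, out_dir,
                              mode = c("male_bias_Y", "female_bias_X"),
                              penetrance = 0.90, allele_freq = 0.01,
                              de_novo_rate = 1e-6,
                              n_perm = 200L, threshold = 0.40,
                              link_radius = 2, min_offspring = 75,
                              mc_reps = 10000L, seed = 1L,
                              validation = c("strict", "permissive"),
                              tol = 1e-9, max_sweeps = 100L, damping = 1) {
  mode <- match.arg(mode)
  validation <- match.arg(validation)
  if (!file.exists(ped_path)) {
    stop(sprintf("pedigree file not found: %s", ped_path))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(...) message("[drivescan] ", sprintf(...))
  stage_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))

  log_("reading pedigree %s", ped_path)
  ped <- read_pedigree(ped_path, mode = validation)
  params <- model_params(penetrance = penetrance, allele_freq = allele_freq,
                         de_novo_rate = de_novo_rate, mode = mode)

  log_("scoring carrier posteriors (%d individuals)", nrow(ped))
  post <- run_warp(ped, params, tol = tol, max_sweeps = max_sweeps,
                   damping = damping)
  o <- order(names(post$values), method = "radix")
  paths <- list()
  paths$posteriors <- write_tsv(
    data.frame(id = names(post$values)[o],
               posterior = unname(post$values)[o],
               n_sweeps = post$n_sweeps, converged = post$converged),
    file.path(out_dir, "posteriors.tsv"))

  log_("permutation suite (%d permutations)", n_perm)
  suite <- run_permutation_suite(ped, params, n_perm = n_perm,
                                 seed = stage_seeds[[1L]], tol = tol,
                                 max_sweeps = max_sweeps, damping = damping)
  perm_df <- do.call(rbind, lapply(
    suite[c("max_likelihood", "z_max", "focal_rank")], function(r) {
      data.frame(method = r$method, observed_stat = r$observed_stat,
                 p_value = r$p_value, n_perm = r$n_permutations,
                 seed = r$seed, stringsAsFactors = FALSE)
    }))
  paths$permutations <- write_tsv(perm_df, file.path(out_dir, "perm_report.tsv"))

  log_("clustering high-likelihood individuals (threshold %.2f)", threshold)
  nodes <- high_likelihood_nodes(post, threshold)
  clusters <- cluster_relatives(ped, nodes, link_radius, posterior = post)
  paths$clusters <- write_tsv(cluster_table(clusters, post),
                              file.path(out_dir, "clusters.tsv"))

  log_("TDT scan of patrilineal lineages")
  scan <- scan_lineages(ped, min_offspring = min_offspring)
  paths$tdt <- write_tsv(scan, file.path(out_dir, "tdt.tsv"))
  paths$scatter <- write_tsv(lineage_scatter(scan),
                             file.path(out_dir, "lineage_scatter.tsv"))

  top <- NULL
  mc <- NULL
  candidates <- which(!is.na(scan$p_value))
  if (length(candidates)) {
    top <- candidates[[which.min(scan$p_value[candidates])]]
    favored <- if (mode == "male_bias_Y") scan$n_male[[top]] else scan$n_female[[top]]
    nsexed <- scan$n_male[[top]] + scan$n_female[[top]]
    log_("Monte Carlo on top lineage %s (%d of %d favored)",
         scan$lineage_id[[top]], favored, nsexed)
    mc <- monte_carlo_family(nsexed, favored, n_reps = mc_reps,
                             seed = stage_seeds[[2L]])
    paths$montecarlo <- write_tsv(
      data.frame(lineage_id = scan$lineage_id[[top]],
                 n_transmissions = mc$n_transmissions,
                 n_favored = mc$n_favored_observed, n_reps = mc$n_reps,
                 n_at_least_as_extreme = mc$n_at_least_as_extreme,
                 p_value = mc$p_value, seed = mc$seed,
                 sidedness = mc$sidedness, stringsAsFactors = FALSE),
      file.path(out_dir, "montecarlo.tsv"))
  }

  summary <- list(
    n_individuals = nrow(ped),
    male_fraction = if (nrow(ped)) mean(ped$sex == "male") else NA_real_,
    n_lineages = nrow(scan),
    n_lineages_passing_filter = sum(scan$passed_size_filter),
    n_high_likelihood = length(nodes),
    n_clusters = length(clusters),
    perm_p_max_likelihood = suite$max_likelihood$p_value,
    perm_p_z_max = suite$z_max$p_value,
    perm_p_focal_rank = suite$focal_rank$p_value,
    focal_id = suite$focal_id,
    top_lineage_id = if (!is.null(top)) scan$lineage_id[[top]] else NA_character_,
    top_lineage_p = if (!is.null(top)) scan$p_value[[top]] else NA_real_,
    top_lineage_p_fdr = if (!is.null(top)) scan$p_fdr[[top]] else NA_real_,
    top_lineage_male_proportion =
      if (!is.null(top)) scan$male_proportion[[top]] else NA_real_,
    montecarlo_p = if (!is.null(mc)) mc$p_value else NA_real_
  )
  paths$summary <- write_tsv(
    data.frame(key = names(summary),
               value = vapply(summary, function(x) format(x, digits = 10), ""),
               stringsAsFactors = FALSE),
    file.path(out_dir, "summary.tsv"))

  manifest <- list(
    input = normalizePath(ped_path),
    parameters = list(mode = mode, penetrance = penetrance,
                      allele_freq = allele_freq, de_novo_rate = de_novo_rate,
                      n_perm = n_perm, threshold = threshold,
                      link_radius = link_radius,
                      min_offspring = min_offspring, mc_reps = mc_reps,
                      validation = validation, tol = tol,
                      max_sweeps = max_sweeps, damping = damping),
    seed = seed,
    stage_seeds = list(permutations = stage_seeds[[1L]],
                       montecarlo = stage_seeds[[2L]]),
    outputs = lapply(paths, basename)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  log_("done: %d reports in %s", length(paths), out_dir)
  invisible(list(paths = paths, summary = summary))
}
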