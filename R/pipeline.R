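#' Read and validate a pipeline configuration
#'
#' The YAML config holds every tunable threshold of the analysis
#' (edge_alpha, association_alpha, null_alpha, k_hubs, top_modules,
#' rare_threshold_percent, n_perm, n_null_graphs, seed), the output
#' directory, and either a \code{simulate:} block (synthetic study) or an
#' \code{inputs:} block with file paths. Missing thresholds take the
#' study defaults.
#'
#' @param config a YAML file path or an equivalent named list.
#' @return validated config list with defaults filled in.
#' @export
readPipelineConfig <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(edge_alpha = 0.01, association_alpha = 0.01,
                   null_alpha = 0.05, k_hubs = 10L, top_modules = 4L,
                   rare_threshold_percent = 0.005, n_perm = 199L,
                   n_null_graphs = 99L, seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("edge_alpha", "association_alpha", "null_alpha"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop("config error: ", nm, " must lie in (0, 1)")
  if (cfg$k_hubs < 1) stop("config error: k_hubs must be >= 1")
  if (cfg$top_modules < 1) stop("config error: top_modules must be >= 1")
  if (cfg$rare_threshold_percent < 0 || cfg$rare_threshold_percent > 100)
    stop("config error: rare_threshold_percent must lie in [0, 100]")
  if (cfg$n_perm < 99) stop("config error: n_perm must be >= 99")
  if (cfg$n_null_graphs < 99)
    stop("config error: n_null_graphs must be >= 99")
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config error: either a simulate: or an inputs: block is required")
  if (!is.null(cfg$simulate)) {
    sim_defaults <- list(n_samples = 20L, n_taxa = 40L, n_modules = 4L,
                         coupling = 2, dispersion = 5,
                         site = "non_urban", compartment = "rhizosphere",
                         trait_effect = 2, trait_noise_sd = 0.1)
    for (nm in names(sim_defaults))
      if (is.null(cfg$simulate[[nm]]))
        cfg$simulate[[nm]] <- sim_defaults[[nm]]
  }
  cfg
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

.merge_arms <- function(untreated, treated) {
  cu <- t(counts(untreated)); ct <- t(counts(treated))
  rownames(cu) <- paste0("U_", rownames(cu))
  rownames(ct) <- paste0("T_", rownames(ct))
  mu <- sampleData(untreated); mt <- sampleData(treated)
  mu$sample_id <- rownames(cu); mt$sample_id <- rownames(ct)
  md <- rbind(mu, mt)
  rownames(md) <- md$sample_id
  AbundanceTable(rbind(cu, ct), md,
                 phylum = SummarizedExperiment::rowData(untreated)$phylum)
}

.simulate_study <- function(cfg) {
  sim <- cfg$simulate
  seed <- as.integer(cfg$seed)
  arm <- function(treatment, arm_seed) {
    generateCommunity(sim$n_samples, sim$n_taxa, sim$n_modules,
                      coupling = sim$coupling,
                      dispersion = sim$dispersion, seed = arm_seed,
                      site = sim$site, compartment = sim$compartment,
                      treatment = treatment)
  }
  u <- arm("untreated", seed)
  t <- arm("biochar", seed + 1L)
  # one trait coupled to module 1 in both arms, one coupled to module 2
  # only under treatment, one pure noise: the treated-only coupling is the
  # planted "new" association
  mk_traits <- function(truth, modules, trait_seed, prefix) {
    tt <- generateTraits(truth, modules, effect = sim$trait_effect,
                         noiseSd = sim$trait_noise_sd, seed = trait_seed)
    v <- tt@values
    colnames(v) <- c("trait_shared", "trait_treated_only", "trait_noise")
    rownames(v) <- paste0(prefix, rownames(v))
    TraitTable(v)
  }
  tr_u <- mk_traits(u$truth, c(1L, 0L, 0L), seed + 2L, "U_")
  tr_t <- mk_traits(t$truth, c(1L, 2L, 0L), seed + 3L, "T_")
  list(untreated = u, treated = t, traits_untreated = tr_u,
       traits_treated = tr_t)
}

.load_study <- function(cfg) {
  ip <- cfg$inputs
  at <- readAbundanceTable(ip$abundance, ip$metadata,
                           taxaAsRows = isTRUE(ip$taxa_as_rows))
  list(untreated = list(table = subsetCondition(at, treatment = "untreated")),
       treated = list(table = subsetCondition(at, treatment = "biochar")),
       traits_untreated = readTraitTable(ip$traits_untreated),
       traits_treated = readTraitTable(ip$traits_treated))
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes, in dependency order: data simulation (or loading), rare-taxon
#' filtering, alpha/beta diversity with PERMANOVA and differential
#' abundance across the treatment contrast, per-arm co-occurrence
#' networks with topology metrics and G(n, m) null-model validation, hub
#' detection and hub-shift classification, module detection with
#' maximum-Jaccard label matching, module-trait Spearman associations
#' with Mantel confirmation, and new/maintained/missed shift
#' classification. All stage outputs (TSV/JSON) plus a machine-readable
#' manifest land in \code{out_dir}; identical config and seed give
#' byte-identical numeric outputs.
#'
#' @param config a YAML path or config list (see
#'   \code{\link{readPipelineConfig}}).
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config) {
  cfg <- readPipelineConfig(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  stages <- character(0)
  log_decisions <- c(
    "correlation screen on relative abundances (spearman)",
    "sample sd (n-1) convention in the mean + 2 SD hotspot threshold",
    "percent hotspot area denominator = hotspot + background pixels",
    "rare-filter boundary: retain at exactly the threshold (>=)",
    "hub ties broken by degree desc, betweenness desc, label",
    "module labels matched across arms by maximum Jaccard overlap")

  data <- if (!is.null(cfg$simulate)) .simulate_study(cfg)
  else .load_study(cfg)
  if (!is.null(cfg$simulate)) {
    writeAbundanceTable(data$untreated$table,
                        file.path(out, "abundance_untreated.tsv"),
                        file.path(out, "metadata_untreated.tsv"))
    writeAbundanceTable(data$treated$table,
                        file.path(out, "abundance_treated.tsv"),
                        file.path(out, "metadata_treated.tsv"))
    writeTraitTable(data$traits_untreated,
                    file.path(out, "traits_untreated.tsv"))
    writeTraitTable(data$traits_treated,
                    file.path(out, "traits_treated.tsv"))
    stages <- c(stages, "simulate")
  } else stages <- c(stages, "load")

  merged <- .merge_arms(data$untreated$table, data$treated$table)
  merged <- filterRare(merged, cfg$rare_threshold_percent)
  writeAbundanceTable(merged, file.path(out, "abundance_filtered.tsv"))

  alpha <- alphaDiversity(merged, factors = "treatment")
  utils::write.table(
    data.frame(sample_id = names(alpha$shannon), shannon = alpha$shannon),
    file.path(out, "alpha_diversity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  d_bc <- brayCurtis(merged)
  utils::write.table(data.frame(sample_id = rownames(d_bc), d_bc,
                                check.names = FALSE),
                     file.path(out, "bray_curtis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  perm <- permanova(d_bc, sampleData(merged)$treatment,
                    nPerm = cfg$n_perm, seed = seed + 10L)
  .write_json(list(kruskal_wallis = alpha$tests,
                   permanova = perm[c("pseudo_F", "p_value",
                                      "n_permutations")]),
              file.path(out, "community_tests.json"))
  da <- differentialAbundance(merged, contrast = "treatment",
                              alphaQ = 0.05)
  utils::write.table(da, file.path(out, "differential_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "community")

  arms <- list(untreated = subsetCondition(merged, treatment = "untreated"),
               treated = subsetCondition(merged, treatment = "biochar"))
  nets <- list(); parts <- list(); assoc <- list()
  for (nm in names(arms)) {
    at <- arms[[nm]]
    scr <- correlationScreen(at)
    cond <- unlist(sampleData(at)[1, c("site", "compartment", "treatment")])
    net <- buildNetwork(scr, edgeAlpha = cfg$edge_alpha, condition = cond)
    nets[[nm]] <- net
    writeNetwork(net, file.path(out, paste0("network_", nm, ".tsv")))
    writeNetwork(net, file.path(out, paste0("network_", nm, ".graphml")),
                 format = "graphml")
    tm <- topologyMetrics(net, seed = seed + 20L)
    .write_json(tm[c("n_nodes", "n_edges", "clustering_coefficient",
                     "average_path_length", "modularity")],
                file.path(out, paste0("topology_", nm, ".json")))
    nullc <- nullEnsemble(net, nGraphs = cfg$n_null_graphs,
                          seed = seed + 30L, nullAlpha = cfg$null_alpha)
    .write_json(list(metrics = nullc@metrics, n_graphs = nullc@nGraphs,
                     non_random = nullc@nonRandom),
                file.path(out, paste0("null_comparison_", nm, ".json")))
    parts[[nm]] <- detectModules(net, seed = seed + 40L)
    utils::write.table(
      data.frame(genus = names(parts[[nm]]@membership),
                 module = parts[[nm]]@membership),
      file.path(out, paste0("modules_", nm, ".tsv")), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  stages <- c(stages, "network", "null_models", "modules")

  hubs <- lapply(nets, topHubs, k = cfg$k_hubs)
  shift <- hubShift(hubs$untreated, hubs$treated)
  utils::write.table(
    data.frame(genus = c(shift@maintained, shift@lost, shift@gained),
               status = rep(c("maintained", "lost", "gained"),
                            c(length(shift@maintained),
                              length(shift@lost), length(shift@gained)))),
    file.path(out, "hub_shift.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  stages <- c(stages, "hubs")

  match <- matchModules(parts$untreated, parts$treated)
  traits <- list(untreated = data$traits_untreated,
                 treated = data$traits_treated)
  for (nm in names(arms)) {
    part <- parts[[nm]]
    top <- topModules(part, cfg$top_modules)
    # label treated modules by their matched untreated module id so the
    # two association matrices are comparable
    lab_of <- function(m) {
      if (nm == "untreated") return(paste0("M", m))
      hit <- match$reference[match$other == m]
      if (length(hit)) paste0("M", hit) else paste0("M", m, "t")
    }
    prof <- vapply(top, function(m) moduleProfile(arms[[nm]], part, m),
                   numeric(ncol(arms[[nm]])))
    rownames(prof) <- colnames(arms[[nm]])
    colnames(prof) <- vapply(top, lab_of, "")
    am <- associate(prof, traits[[nm]], alpha = cfg$association_alpha)
    mt <- mantelTest(stats::dist(prof),
                     stats::dist(traits[[nm]]@values[rownames(prof), ,
                                                     drop = FALSE]),
                     nPerm = cfg$n_perm, seed = seed + 50L)
    am@mantel <- data.frame(pair = "module_profiles_vs_traits",
                            mantel_r = mt$mantel_r, p_value = mt$p_value)
    assoc[[nm]] <- am
    utils::write.table(
      data.frame(module = rep(rownames(am@rho), ncol(am@rho)),
                 trait = rep(colnames(am@rho), each = nrow(am@rho)),
                 rho = as.vector(am@rho), p = as.vector(am@p),
                 significant = as.vector(am@significant)),
      file.path(out, paste0("associations_", nm, ".tsv")), sep = "\t",
      quote = FALSE, row.names = FALSE)
    .write_json(am@mantel, file.path(out, paste0("mantel_", nm, ".json")))
  }
  ashift <- classifyShift(assoc$untreated, assoc$treated)
  .write_json(list(new = ashift@new, maintained = ashift@maintained,
                   missed = ashift@missed),
              file.path(out, "association_shift.json"))
  stages <- c(stages, "associations", "shift_classification")

  manifest <- list(
    package = "rhizoChar",
    version = as.character(utils::packageVersion("rhizoChar")),
    seed = seed,
    stages = stages,
    parameters = cfg[c("edge_alpha", "association_alpha", "null_alpha",
                       "k_hubs", "top_modules", "rare_threshold_percent",
                       "n_perm", "n_null_graphs")],
    decisions = log_decisions,
    module_matching = match)
  .write_json(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}
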